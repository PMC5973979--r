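#' Nearest-fibre (Voronoi) pixel assignment
#'
#' Assigns every in-FoV pixel center to its nearest fibre in Euclidean
#' distance — exactly the Voronoi partition of the pixel grid restricted to
#' the field of view. Distance ties are broken deterministically in favour
#' of the lowest fibre index. Out-of-FoV pixels are `NA`.
#'
#' @param lattice a [fibre_lattice()].
#' @param grid_shape integer (rows, cols).
#' @return an object of class `pixel_assignment`: a list with `index`
#'   (integer matrix of 1-based fibre indices, `NA` outside the FoV),
#'   `grid_shape` and `n_fibres`.
#' @export
nearest_fibre_map <- function(lattice, grid_shape) {
  stopifnot(inherits(lattice, "fibre_lattice"))
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L))
  idx <- cpp_nearest_map(lattice$positions, grid_shape[1], grid_shape[2],
                         lattice$fov_center[1], lattice$fov_center[2],
                         lattice$fov_radius)
  structure(list(index = idx, grid_shape = grid_shape,
                 n_fibres = lattice$n_fibres,
                 positions = lattice$positions),
            class = "pixel_assignment")
}

#' Delaunay triangulation of a fibre lattice
#'
#' Triangulates the fibre positions so scattered per-fibre signals can be
#' interpolated piecewise-linearly back onto the pixel grid. To pin down
#' the triangulation of exactly co-circular configurations (e.g. perfect
#' unjittered lattices), positions are perturbed by a fixed deterministic
#' displacement of `1e-9` times the lattice pitch before triangulating;
#' at that magnitude the empty-circumcircle property still holds to high
#' accuracy for any non-degenerate lattice.
#'
#' @param lattice a [fibre_lattice()].
#' @return an object of class `triangulation`: a list with `simplices`
#'   (m x 3 integer matrix of fibre indices, each row sorted ascending)
#'   and `n_fibres`.
#' @export
triangulate <- function(lattice) {
  stopifnot(inherits(lattice, "fibre_lattice"))
  pos <- lattice$positions
  pitch <- lattice$generator_params$pitch
  if (is.null(pitch)) pitch <- hex_pitch(lattice$n_fibres, lattice$fov_radius)
  # deterministic, seed-free perturbation: golden-ratio angle sequence
  i <- seq_len(nrow(pos))
  ang <- 2 * pi * ((i * 0.6180339887498949) %% 1)
  eps <- 1e-9 * pitch
  pos_p <- pos + eps * cbind(cos(ang), sin(ang))
  simplices <- cpp_delaunay(pos_p)
  if (nrow(simplices) == 0L)
    stop("degenerate geometry: fibre positions are collinear")
  structure(list(simplices = simplices, n_fibres = lattice$n_fibres),
            class = "triangulation")
}

#' @export
print.triangulation <- function(x, ...) {
  cat(sprintf("<triangulation> %d simplices over %d fibres\n",
              nrow(x$simplices), x$n_fibres))
  invisible(x)
}
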