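#' Fibre lattice objects
#'
#' A `fibre_lattice` describes the sampling geometry of a coherent fibre
#' bundle: continuous (row, col) positions of the fibre cores, in pixel
#' units, plus the circular field of view (FoV) that the bundle images.
#' Pixel centers sit at integer coordinates, 1-based, so a position of
#' `c(1, 1)` coincides with the top-left pixel center.
#'
#' @param positions numeric matrix with one (row, col) position per fibre.
#' @param fov_center numeric length-2 (row, col) center of the FoV disc.
#' @param fov_radius FoV radius in pixels.
#' @param seed integer seed recorded for provenance, or `NULL`.
#' @param generator_params list of parameters recorded for provenance.
#' @return an object of class `fibre_lattice`.
#' @export
fibre_lattice <- function(positions, fov_center, fov_radius, seed = NULL,
                          generator_params = list()) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 2L) stop("positions must be an n x 2 matrix")
  n <- nrow(positions)
  if (n < 3L) stop("a fibre lattice needs at least 3 fibres")
  fov_center <- as.numeric(fov_center)
  stopifnot(length(fov_center) == 2L, is.numeric(fov_radius), fov_radius > 0)
  d <- sqrt((positions[, 1] - fov_center[1])^2 + (positions[, 2] - fov_center[2])^2)
  if (any(d > fov_radius + 1e-9))
    stop("all fibre positions must lie inside the field-of-view disc")
  if (n <= 5000L) {
    if (min(stats::dist(positions)) <= 0) stop("fibre positions must be pairwise distinct")
  } else if (anyDuplicated(positions)) {
    stop("fibre positions must be pairwise distinct")
  }
  structure(
    list(positions = positions, fov_center = fov_center,
         fov_radius = as.numeric(fov_radius), n_fibres = n,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         generator_params = generator_params),
    class = "fibre_lattice")
}

#' @export
print.fibre_lattice <- function(x, ...) {
  cat(sprintf("<fibre_lattice> %d fibres, FoV radius %.4g px at (%.4g, %.4g)\n",
              x$n_fibres, x$fov_radius, x$fov_center[1], x$fov_center[2]))
  invisible(x)
}

#' Hexagonal pitch for a target fibre count
#'
#' Pitch of a hexagonally packed lattice that places approximately
#' `n_fibres` sites inside a disc of the given radius.
#' @keywords internal
hex_pitch <- function(n_fibres, fov_radius) {
  sqrt(2 * pi * fov_radius^2 / (sqrt(3) * n_fibres))
}

#' Generate a jittered hexagonal fibre lattice
#'
#' Real fibre bundles are near-hexagonally packed with manufacturing
#' irregularity. This generator lays down a hexagonal lattice whose pitch
#' is chosen so that approximately `n_fibres` sites fall inside the FoV
#' disc, displaces every site by an independent uniform jitter of magnitude
#' at most `jitter_frac` times the pitch (uniform over a disc), and keeps
#' the `n_fibres` sites nearest the FoV center among those inside the disc
#' (the pitch is shrunk slightly when the discrete hexagonal shells leave
#' fewer than `n_fibres` sites inside, so the returned count is exact).
#'
#' @param n_fibres target number of fibres (>= 3).
#' @param fov_radius FoV radius in pixels.
#' @param fov_center (row, col) FoV center; default places the FoV at
#'   `(fov_radius + 1, fov_radius + 1)`.
#' @param jitter_frac jitter magnitude as a fraction of the lattice pitch,
#'   in `[0, 0.5]`. Default 0.25.
#' @param seed integer seed; the same seed reproduces the same lattice.
#' @return a [fibre_lattice()].
#' @examples
#' lat <- generate_fibre_lattice(600, fov_radius = 120,
#'                               fov_center = c(128.5, 128.5), seed = 1)
#' lat$n_fibres
#' @export
generate_fibre_lattice <- function(n_fibres, fov_radius,
                                   fov_center = c(fov_radius + 1, fov_radius + 1),
                                   jitter_frac = 0.25, seed = 1L) {
  if (!is.numeric(n_fibres) || n_fibres < 3) stop("n_fibres must be at least 3")
  if (!is.numeric(fov_radius) || fov_radius <= 0) stop("fov_radius must be positive")
  if (!is.numeric(jitter_frac) || jitter_frac < 0 || jitter_frac > 0.5)
    stop("jitter_frac must lie in [0, 0.5]")
  pitch <- hex_pitch(n_fibres, fov_radius)
  lay_out <- function(pitch) {
    row_step <- pitch * sqrt(3) / 2
    half <- fov_radius + pitch
    ri <- seq.int(-ceiling(half / row_step), ceiling(half / row_step))
    ci <- seq.int(-ceiling(half / pitch), ceiling(half / pitch))
    grid <- expand.grid(ri = ri, ci = ci)
    r <- fov_center[1] + grid$ri * row_step
    c <- fov_center[2] + grid$ci * pitch + (grid$ri %% 2) * pitch / 2
    pos <- with_seed(seed, {
      if (jitter_frac > 0) {
        m <- length(r)
        rad <- jitter_frac * pitch * sqrt(runif(m))
        ang <- runif(m, 0, 2 * pi)
        cbind(r + rad * cos(ang), c + rad * sin(ang))
      } else {
        cbind(r, c)
      }
    })
    d <- sqrt((pos[, 1] - fov_center[1])^2 + (pos[, 2] - fov_center[2])^2)
    pos[d <= fov_radius, , drop = FALSE]
  }
  # hexagonal shells are discrete: shrink the pitch until at least n sites
  # land inside the disc, then keep the n nearest the center
  pos <- lay_out(pitch)
  tries <- 0L
  while (nrow(pos) < n_fibres && tries < 300L) {
    pitch <- pitch * 0.97
    pos <- lay_out(pitch)
    tries <- tries + 1L
  }
  if (nrow(pos) < 3L) stop("fewer than 3 fibres fell inside the field of view")
  if (nrow(pos) > n_fibres) {
    d <- sqrt((pos[, 1] - fov_center[1])^2 + (pos[, 2] - fov_center[2])^2)
    pos <- pos[order(d, seq_len(nrow(pos)))[seq_len(n_fibres)], , drop = FALSE]
  }
  fibre_lattice(pos, fov_center, fov_radius, seed = seed,
                generator_params = list(n_fibres = n_fibres,
                                        jitter_frac = jitter_frac,
                                        pitch = pitch))
}

#' Write or read a fibre lattice as JSON
#'
#' The JSON stores positions, FoV geometry, the generator seed and the
#' generator parameters; reading restores an identical lattice.
#'
#' @param lattice a [fibre_lattice()].
#' @param path file path.
#' @return `write_lattice` returns `path` invisibly; `read_lattice` returns
#'   a [fibre_lattice()].
#' @export
write_lattice <- function(lattice, path) {
  stopifnot(inherits(lattice, "fibre_lattice"))
  obj <- list(positions = unname(lattice$positions),
              fov_center = lattice$fov_center,
              fov_radius = lattice$fov_radius,
              seed = lattice$seed,
              generator_params = lattice$generator_params)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fibre_lattice(obj$positions, obj$fov_center, obj$fov_radius,
                seed = obj$seed,
                generator_params = as.list(obj$generator_params))
}

#' Field-of-view mask
#'
#' Logical matrix marking pixels whose center lies within `fov_radius` of
#' `fov_center`.
#'
#' @param lattice a [fibre_lattice()].
#' @param grid_shape integer (rows, cols).
#' @return logical matrix of dimension `grid_shape`.
#' @export
fov_mask <- function(lattice, grid_shape) {
  stopifnot(inherits(lattice, "fibre_lattice"))
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L))
  r <- seq_len(grid_shape[1]) - lattice$fov_center[1]
  c <- seq_len(grid_shape[2]) - lattice$fov_center[2]
  outer(r^2, c^2, `+`) <= lattice$fov_radius^2
}
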