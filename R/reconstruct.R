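#' Piecewise-linear reconstruction of fibre signals
#'
#' Maps irregular per-fibre signals back to a Cartesian image: every in-FoV
#' pixel inside the convex hull of the fibre positions receives the
#' barycentric-weighted combination of its enclosing Delaunay simplex's
#' three fibre values (pixels on a shared edge are attributed to the
#' lowest-index simplex; the interpolated value is unaffected up to float
#' error). In-FoV pixels outside the hull — a thin rim near the FoV
#' boundary — are filled with the nearest fibre's value, so the
#' reconstruction is defined over the whole FoV. Out-of-FoV pixels are 0
#' with a false mask.
#'
#' @param fs [fibre_signals()] aligned with `lattice`.
#' @param tri a [triangulate()] result built from the same lattice.
#' @param lattice the [fibre_lattice()].
#' @param grid_shape integer (rows, cols) of the output grid.
#' @return a [cartesian_image()]; `meta$in_hull` is a logical matrix marking
#'   pixels covered by the triangulation (rim pixels are `FALSE`).
#' @export
interpolate_linear <- function(fs, tri, lattice, grid_shape) {
  stopifnot(inherits(fs, "fibre_signals"), inherits(tri, "triangulation"),
            inherits(lattice, "fibre_lattice"))
  if (fs$n_fibres != lattice$n_fibres || tri$n_fibres != lattice$n_fibres)
    stop("signals, triangulation and lattice refer to different fibre counts")
  grid_shape <- as.integer(grid_shape)
  mask <- fov_mask(lattice, grid_shape)
  res <- cpp_interp_linear(lattice$positions, tri$simplices, fs$values,
                           grid_shape[1], grid_shape[2], mask)
  cartesian_image(res$pixels, mask,
                  meta = list(in_hull = res$in_hull,
                              rim_fill = "nearest_fibre",
                              noisy = fs$noisy))
}

#' Simulate a low-resolution pCLE frame from a high-resolution image
#'
#' The full fibre-bundle forward pipeline: pool the HR signal per fibre,
#' corrupt the fibre signals with the bundle noise model, and reconstruct a
#' Cartesian frame by Delaunay piecewise-linear interpolation. The output
#' shares the input's pixel grid — the low resolution comes from fibre
#' sampling, not from fewer pixels — so LR/HR pairs are perfectly aligned
#' by construction.
#'
#' @param hr a [cartesian_image()] (or matrix) high-resolution frame.
#' @param lattice a [fibre_lattice()].
#' @param params a [noise_params()]; use `sigma_m = 0, sigma_a_coeff = 0`
#'   for a noise-free simulation.
#' @param extraction how fibres pool the HR signal: `"voronoi"` (mean over
#'   the fibre's Voronoi cell, the default), `"knn"` (mean of the `k`
#'   nearest pixels, the standard acquisition variant), or `"point"`
#'   (exact bilinear sampling at the fibre core).
#' @param k neighbourhood size for `extraction = "knn"`.
#' @param tri optionally a precomputed [triangulate()] result.
#' @param assignment optionally a precomputed [nearest_fibre_map()].
#' @return a [cartesian_image()] with provenance in `meta`.
#' @examples
#' lat <- generate_fibre_lattice(200, fov_radius = 28, seed = 3)
#' hr <- generate_phantom_hr(c(64, 64), lat, n_blobs = 30, seed = 4)
#' lr <- simulate_lr(hr, lat, noise_params(seed = 5))
#' @export
simulate_lr <- function(hr, lattice, params = noise_params(),
                        extraction = c("voronoi", "knn", "point"), k = 7L,
                        tri = NULL, assignment = NULL) {
  hr <- as_image(hr)
  stopifnot(inherits(lattice, "fibre_lattice"))
  extraction <- match.arg(extraction)
  grid_shape <- dim(hr$pixels)
  fs <- switch(extraction,
    voronoi = {
      if (is.null(assignment)) assignment <- nearest_fibre_map(lattice, grid_shape)
      extract_fibre_signals(hr, assignment)
    },
    knn = extract_fibre_signals_neighbourhood(hr, lattice, k = k),
    point = extract_fibre_signals_point(hr, lattice))
  nfs <- if (params$sigma_m == 0 && params$sigma_a_coeff == 0) fs
         else apply_noise(fs, params)
  if (is.null(tri)) tri <- triangulate(lattice)
  out <- interpolate_linear(nfs, tri, lattice, grid_shape)
  out$meta <- c(out$meta,
                list(source = hr$meta$source, extraction = extraction,
                     noise = list(sigma_m = params$sigma_m,
                                  sigma_a_coeff = params$sigma_a_coeff,
                                  seed = params$seed),
                     n_fibres = lattice$n_fibres))
  out
}
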