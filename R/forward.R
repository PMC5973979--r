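#' Per-fibre signal container
#'
#' Scalar intensity per fibre, index-aligned with a [fibre_lattice()].
#' `noisy` records whether the bundle noise model has been applied, so a
#' signal vector cannot be corrupted twice.
#'
#' @param values numeric vector, one finite value per fibre.
#' @param lattice_ref identifier binding the signals to a lattice (the
#'   lattice's fibre count is the minimal binding used for validation).
#' @param n_fibres fibre count of the referenced lattice.
#' @param noisy logical; has noise been applied?
#' @return an object of class `fibre_signals`.
#' @export
fibre_signals <- function(values, n_fibres = length(values),
                          lattice_ref = NULL, noisy = FALSE) {
  values <- as.numeric(values)
  if (length(values) != n_fibres)
    stop("length(values) must equal the fibre count of the lattice")
  if (any(!is.finite(values))) stop("fibre signals must be finite")
  structure(list(values = values, n_fibres = as.integer(n_fibres),
                 lattice_ref = lattice_ref, noisy = isTRUE(noisy)),
            class = "fibre_signals")
}

#' @export
print.fibre_signals <- function(x, ...) {
  cat(sprintf("<fibre_signals> %d fibres, %s, range [%.4g, %.4g]\n",
              x$n_fibres, if (x$noisy) "noisy" else "clean",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Extract fibre signals by Voronoi-cell averaging
#'
#' Each fibre integrates the tissue signal over its catchment area; this is
#' modelled by averaging the high-resolution pixel values inside the
#' fibre's Voronoi cell (restricted to the FoV). A fibre whose cell
#' contains no in-FoV pixel (possible at sparse desk-scale densities)
#' receives the image value at the pixel nearest its position.
#'
#' @param hr a [cartesian_image()] (or matrix) of high-resolution signal.
#' @param assignment a [nearest_fibre_map()] result on the same grid.
#' @return clean [fibre_signals()].
#' @export
extract_fibre_signals <- function(hr, assignment) {
  hr <- as_image(hr)
  stopifnot(inherits(assignment, "pixel_assignment"))
  if (!identical(dim(hr$pixels), as.integer(assignment$grid_shape)) &&
      !identical(dim(hr$pixels), assignment$grid_shape))
    stop("image and assignment grid shapes differ")
  idx <- assignment$index
  n <- assignment$n_fibres
  sums <- rowsum(hr$pixels[!is.na(idx)], idx[!is.na(idx)])
  cnt <- tabulate(idx[!is.na(idx)], nbins = n)
  vals <- numeric(n)
  have <- cnt > 0L
  vals[have] <- sums[, 1] / cnt[have]
  if (any(!have)) {
    # empty Voronoi cell: nearest pixel's value
    empty <- which(!have)
    gs <- dim(hr$pixels)
    pos <- assignment$positions
    for (i in empty) {
      r <- min(max(round(pos[i, 1]), 1L), gs[1])
      c <- min(max(round(pos[i, 2]), 1L), gs[2])
      vals[i] <- hr$pixels[r, c]
    }
  }
  fibre_signals(vals, n, noisy = FALSE)
}

#' Extract fibre signals from pixel neighbourhoods
#'
#' The standard pCLE acquisition model: each fibre reads the average of the
#' `k` pixel values nearest its core position (default `k = 7`, the fibre
#' core plus its immediate neighbourhood). Distance ties are broken by the
#' lower row-major pixel index.
#'
#' @param image a [cartesian_image()] or matrix covering all fibre positions.
#' @param lattice a [fibre_lattice()].
#' @param k number of nearest pixels to average (>= 1).
#' @return clean [fibre_signals()].
#' @export
extract_fibre_signals_neighbourhood <- function(image, lattice, k = 7L) {
  image <- as_image(image)
  stopifnot(inherits(lattice, "fibre_lattice"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > length(image$pixels)) stop("k exceeds the pixel count")
  vals <- cpp_knn_mean(lattice$positions, image$pixels, k)
  fibre_signals(vals, lattice$n_fibres, noisy = FALSE)
}

#' Extract fibre signals by point sampling
#'
#' Bilinear interpolation of the image at each fibre core position. This is
#' the idealized acquisition in which a fibre reads the tissue signal
#' exactly at its core; it reproduces affine intensity fields exactly and
#' anchors the interpolation-exactness checks.
#'
#' @inheritParams extract_fibre_signals_neighbourhood
#' @return clean [fibre_signals()].
#' @export
extract_fibre_signals_point <- function(image, lattice) {
  image <- as_image(image)
  stopifnot(inherits(lattice, "fibre_lattice"))
  px <- image$pixels
  gs <- dim(px)
  r <- pmin(pmax(lattice$positions[, 1], 1), gs[1])
  c <- pmin(pmax(lattice$positions[, 2], 1), gs[2])
  r0 <- pmin(floor(r), gs[1] - 1L); c0 <- pmin(floor(c), gs[2] - 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- px[cbind(r0, c0)];     v10 <- px[cbind(r0 + 1, c0)]
  v01 <- px[cbind(r0, c0 + 1)]; v11 <- px[cbind(r0 + 1, c0 + 1)]
  vals <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
          (1 - fr) * fc * v01 + fr * fc * v11
  fibre_signals(vals, lattice$n_fibres, noisy = FALSE)
}

#' Bundle noise parameters
#'
#' Parameters of the fibre-signal noise model
#' `nfs = (1 + m) * fs + a`, with per-fibre independent draws
#' `m ~ N(0, sigma_m^2)` and `a ~ N(0, (sigma_a_coeff * (max fs - min fs))^2)`.
#' The defaults `sigma_m = 0.05` and `sigma_a_coeff = 0.01` reproduce the
#' visual noise level of device-acquired frames.
#'
#' @param sigma_m standard deviation of the multiplicative Gaussian.
#' @param sigma_a_coeff additive Gaussian standard deviation expressed as a
#'   fraction of the clean-signal range.
#' @param seed integer seed for the noise draws.
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(sigma_m = 0.05, sigma_a_coeff = 0.01, seed = 1L) {
  stopifnot(is.numeric(sigma_m), sigma_m >= 0,
            is.numeric(sigma_a_coeff), sigma_a_coeff >= 0)
  structure(list(sigma_m = sigma_m, sigma_a_coeff = sigma_a_coeff,
                 seed = as.integer(seed)),
            class = "noise_params")
}

#' Apply the bundle noise model to clean fibre signals
#'
#' Draws per-fibre multiplicative and additive Gaussian noise and returns
#' `nfs = (1 + m) * fs + a`. The additive standard deviation scales with
#' the range of the clean signals of this frame. No clipping is applied;
#' downstream per-frame standardization makes the absolute range
#' irrelevant, and clipping would distort the Gaussian model. Applying
#' noise twice is an error.
#'
#' @param fs clean [fibre_signals()].
#' @param params a [noise_params()].
#' @return noisy [fibre_signals()]; deterministic for a fixed seed.
#' @export
apply_noise <- function(fs, params = noise_params()) {
  stopifnot(inherits(fs, "fibre_signals"), inherits(params, "noise_params"))
  if (fs$noisy) stop("signals are already noisy; refusing to corrupt twice")
  n <- fs$n_fibres
  rng <- max(fs$values) - min(fs$values)
  nfs <- with_seed(params$seed, {
    m <- rnorm(n, 0, params$sigma_m)
    a <- rnorm(n, 0, params$sigma_a_coeff * rng)
    (1 + m) * fs$values + a
  })
  fibre_signals(nfs, n, lattice_ref = fs$lattice_ref, noisy = TRUE)
}
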