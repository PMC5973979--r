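#' Generate a phantom high-resolution frame
#'
#' Synthetic stand-in for registration-derived pseudo-ground-truth frames:
#' cell-like anisotropic Gaussian blobs scattered over a smooth
#' low-frequency background, plus a fine-grained texture field below the
#' blob scale, normalized to `[0, 1]` inside the FoV and zero outside.
#' The default blob sizes span roughly half to twice the fibre pitch of
#' the default 600-fibre bundle — in real endomicroscopy the fibre spacing
#' is sub-cellular — while the fine texture emulates the sub-resolution
#' cellular detail (and high SNR) of registration-fused frames. Two
#' texture regimes are provided via `texture_params` presets so datasets
#' can carry distinct strata (emulating different tissue types).
#'
#' @param grid_shape integer (rows, cols).
#' @param fov a [fibre_lattice()] supplying the FoV geometry, or a list
#'   with `fov_center` and `fov_radius`, or `NULL` for a full-frame FoV.
#' @param n_blobs number of blobs (>= 0).
#' @param texture_params list with elements `sigma_range` (blob axis sd
#'   range, px), `aspect_range` (anisotropy ratio range), `amp_range`
#'   (blob amplitude range), `background` (flat level before blobs),
#'   `bg_mod_amp` (amplitude of the smooth background modulation; 0
#'   disables it), `bg_smooth_sigma` (background correlation length, px),
#'   `fine_amp` (sd of the fine-texture field; 0 disables it) and
#'   `fine_sigma` (fine-texture correlation length, px).
#' @param seed integer seed; the same seed reproduces the same phantom.
#' @return a [cartesian_image()] with values in `[0, 1]` inside the FoV.
#' @export
generate_phantom_hr <- function(grid_shape, fov = NULL, n_blobs = 150L,
                                texture_params = phantom_texture("a"),
                                seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 4L), n_blobs >= 0)
  tp <- texture_params
  mask <- if (is.null(fov)) matrix(TRUE, grid_shape[1], grid_shape[2])
          else if (inherits(fov, "fibre_lattice")) fov_mask(fov, grid_shape)
          else {
    r <- seq_len(grid_shape[1]) - fov$fov_center[1]
    c <- seq_len(grid_shape[2]) - fov$fov_center[2]
    outer(r^2, c^2, `+`) <= fov$fov_radius^2
  }
  if (is.null(tp$fine_amp)) tp$fine_amp <- 0
  if (is.null(tp$fine_sigma)) tp$fine_sigma <- 1.3
  img <- with_seed(seed, {
    acc <- matrix(tp$background, grid_shape[1], grid_shape[2])
    # smooth low-frequency background modulation
    if (tp$bg_mod_amp > 0) {
      lowres <- matrix(runif(64, -1, 1), 8, 8)
      up <- bilinear_upsample(lowres, grid_shape)
      acc <- acc + tp$bg_mod_amp * blur_gaussian(up, tp$bg_smooth_sigma / 4)
    }
    if (n_blobs > 0) {
      cr <- runif(n_blobs, 1, grid_shape[1])
      cc <- runif(n_blobs, 1, grid_shape[2])
      s1 <- runif(n_blobs, tp$sigma_range[1], tp$sigma_range[2])
      asp <- runif(n_blobs, tp$aspect_range[1], tp$aspect_range[2])
      s2 <- s1 / asp
      th <- runif(n_blobs, 0, pi)
      amp <- runif(n_blobs, tp$amp_range[1], tp$amp_range[2]) *
        sample(c(-1, 1), n_blobs, replace = TRUE, prob = c(0.3, 0.7))
      for (i in seq_len(n_blobs)) {
        ext <- ceiling(3.5 * max(s1[i], s2[i]))
        r0 <- max(1L, floor(cr[i] - ext)); r1 <- min(grid_shape[1], ceiling(cr[i] + ext))
        c0 <- max(1L, floor(cc[i] - ext)); c1 <- min(grid_shape[2], ceiling(cc[i] + ext))
        if (r0 > r1 || c0 > c1) next
        rr <- seq.int(r0, r1) - cr[i]
        cc2 <- seq.int(c0, c1) - cc[i]
        ct <- cos(th[i]); st <- sin(th[i])
        u <- outer(rr * ct, cc2 * st, `+`)
        v <- outer(-rr * st, cc2 * ct, `+`)
        g <- amp[i] * exp(-(u^2 / (2 * s1[i]^2) + v^2 / (2 * s2[i]^2)))
        acc[r0:r1, c0:c1] <- acc[r0:r1, c0:c1] + g
      }
    }
    if (tp$fine_amp > 0) {
      # fine cellular texture below the blob scale
      f <- blur_gaussian(matrix(rnorm(prod(grid_shape)), grid_shape[1]),
                         tp$fine_sigma)
      acc <- acc + tp$fine_amp * f / sd(f)
    }
    acc
  })
  inr <- range(img[mask])
  if (inr[2] > inr[1]) {
    img <- (img - inr[1]) / (inr[2] - inr[1])
  } else {
    img[] <- tp$background
  }
  img[!mask] <- 0
  cartesian_image(img, mask,
                  meta = list(kind = "phantom", n_blobs = n_blobs, seed = seed,
                              texture = tp$name))
}

#' Phantom texture presets
#'
#' Two texture regimes with distinct blob-size and anisotropy statistics,
#' used as synthetic stratum labels when building datasets.
#'
#' @param stratum `"a"` (small, round, cell-like blobs) or `"b"` (larger,
#'   elongated, gland-like structures).
#' @return a texture parameter list for [generate_phantom_hr()].
#' @export
phantom_texture <- function(stratum = c("a", "b")) {
  stratum <- match.arg(stratum)
  if (stratum == "a") {
    list(name = "a", sigma_range = c(3.5, 9), aspect_range = c(1, 1.8),
         amp_range = c(0.3, 1.0), background = 0.25, bg_mod_amp = 0.15,
         bg_smooth_sigma = 24, fine_amp = 0.08, fine_sigma = 1.3)
  } else {
    list(name = "b", sigma_range = c(6, 16), aspect_range = c(1.5, 4),
         amp_range = c(0.25, 0.9), background = 0.35, bg_mod_amp = 0.15,
         bg_smooth_sigma = 40, fine_amp = 0.08, fine_sigma = 1.3)
  }
}

# nearest-corner anchored bilinear upsampling of a coarse grid
bilinear_upsample <- function(coarse, grid_shape) {
  nr <- nrow(coarse); nc <- ncol(coarse)
  r <- seq(1, nr, length.out = grid_shape[1])
  c <- seq(1, nc, length.out = grid_shape[2])
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m00 <- coarse[r0, c0, drop = FALSE]; m10 <- coarse[r0 + 1, c0, drop = FALSE]
  m01 <- coarse[r0, c0 + 1, drop = FALSE]; m11 <- coarse[r0 + 1, c0 + 1, drop = FALSE]
  wr <- matrix(fr, grid_shape[1], grid_shape[2])
  wc <- matrix(fc, grid_shape[1], grid_shape[2], byrow = TRUE)
  (1 - wr) * (1 - wc) * m00 + wr * (1 - wc) * m10 +
    (1 - wr) * wc * m01 + wr * wc * m11
}
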