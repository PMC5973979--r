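#' Unsharp-mask contrast enhancement
#'
#' Classical sharpening baseline: `image + amount * (image -
#' gaussian_blur(image, radius))`, clipped to `[0, 1]`.
#'
#' @param image a [cartesian_image()] or matrix with values in `[0, 1]`.
#' @param amount sharpening strength (>= 0); 0 is the identity.
#' @param radius Gaussian blur sigma in pixels.
#' @return image of the same type and size.
#' @export
baseline_sharpen <- function(image, amount = 1, radius = 2) {
  stopifnot(amount >= 0, radius > 0)
  img <- as_image(image)
  out <- img$pixels + amount * (img$pixels - blur_gaussian(img$pixels, radius))
  out <- pmin(pmax(out, 0), 1)
  out[!img$fov_mask] <- 0
  if (inherits(image, "cartesian_image"))
    cartesian_image(out, img$fov_mask, img$meta) else out
}

#' Wiener deconvolution with a Gaussian point-spread function
#'
#' Frequency-domain Wiener filter assuming a Gaussian PSF of standard
#' deviation `psf_sigma` (default 2, matching the blur scale of bundle
#' reconstructions) and a constant noise-to-signal power ratio `nsr`. The
#' image is reflect-padded before the FFT to suppress wrap-around
#' artifacts. As `nsr` grows the filter gain vanishes and the output goes
#' to zero.
#'
#' @param image a [cartesian_image()] or matrix.
#' @param psf_sigma Gaussian PSF standard deviation in pixels.
#' @param nsr constant noise-to-signal ratio (>= 0).
#' @return image of the same type and size.
#' @export
baseline_wiener <- function(image, psf_sigma = 2, nsr = 0.01) {
  stopifnot(psf_sigma > 0, nsr >= 0)
  img <- as_image(image)
  px <- img$pixels
  pad <- as.integer(ceiling(4 * psf_sigma)) + 4L
  padded <- pad_reflect(px, pad)
  nr <- nrow(padded); nc <- ncol(padded)
  # centered-at-origin Gaussian PSF on the periodic grid
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  gr <- exp(-fr^2 / (2 * psf_sigma^2))
  gc <- exp(-fc^2 / (2 * psf_sigma^2))
  psf <- outer(gr, gc)
  psf <- psf / sum(psf)
  H <- stats::fft(psf)
  G <- Conj(H) / (Mod(H)^2 + nsr)
  out <- Re(stats::fft(stats::fft(padded) * G, inverse = TRUE)) / (nr * nc)
  out <- out[pad + seq_len(nrow(px)), pad + seq_len(ncol(px))]
  out[!img$fov_mask] <- 0
  if (inherits(image, "cartesian_image"))
    cartesian_image(out, img$fov_mask, img$meta) else out
}

pad_reflect <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(pad)), seq_len(nr), nr - seq_len(pad) + 1)
  ci <- c(rev(seq_len(pad)), seq_len(nc), nc - seq_len(pad) + 1)
  m[ri, ci]
}
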