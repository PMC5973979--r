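#' Normalized 1-D Gaussian kernel
#'
#' @param size odd kernel length.
#' @param sigma standard deviation in pixels.
#' @return numeric vector of length `size` summing to 1.
#' @keywords internal
gaussian_kernel <- function(size, sigma) {
  stopifnot(size >= 1, size %% 2 == 1, sigma > 0)
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable 2-D correlation
#'
#' Applies a 1-D kernel along both axes. Mode `"valid"` shrinks the output,
#' `"full"` grows it (zero padding), `"same_reflect"` and `"same_zero"` keep
#' the input size with symmetric or zero boundary handling. With a symmetric
#' kernel, `"full"` is the adjoint of `"valid"`.
#'
#' @param img numeric matrix.
#' @param kernel numeric vector (1-D kernel, applied to rows and columns).
#' @param mode one of `"valid"`, `"full"`, `"same_reflect"`, `"same_zero"`.
#' @return filtered matrix.
#' @export
sep_filter <- function(img, kernel, mode = "same_reflect") {
  stopifnot(is.matrix(img), is.numeric(kernel))
  cpp_sepconv(img, as.numeric(kernel), mode)
}

#' Gaussian blur
#'
#' Isotropic Gaussian smoothing with symmetric boundary handling; the kernel
#' is truncated at 4 sigma (odd length).
#'
#' @param img numeric matrix.
#' @param sigma blur standard deviation in pixels.
#' @return blurred matrix of the same size.
#' @export
blur_gaussian <- function(img, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(img)
  size <- 2L * as.integer(ceiling(4 * sigma)) + 1L
  sep_filter(img, gaussian_kernel(size, sigma), "same_reflect")
}
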