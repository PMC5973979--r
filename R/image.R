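#' Cartesian image with field-of-view mask
#'
#' A single-channel intensity image on a rectangular pixel grid together
#' with a logical FoV validity mask (pixels outside the bundle's circular
#' field of view carry no signal) and a free-form provenance record.
#'
#' @param pixels numeric matrix of intensities.
#' @param fov_mask logical matrix of the same dimension, or `NULL` for an
#'   all-true mask.
#' @param meta named list of provenance metadata.
#' @return an object of class `cartesian_image`.
#' @export
cartesian_image <- function(pixels, fov_mask = NULL, meta = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(fov_mask)) fov_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  fov_mask <- as.matrix(fov_mask)
  if (!identical(dim(pixels), dim(fov_mask)))
    stop("pixels and fov_mask must have identical dimensions")
  if (!is.logical(fov_mask)) storage.mode(fov_mask) <- "logical"
  if (any(!is.finite(pixels[fov_mask])))
    stop("pixels must be finite inside the field of view")
  structure(list(pixels = pixels, fov_mask = fov_mask, meta = meta),
            class = "cartesian_image")
}

#' @export
print.cartesian_image <- function(x, ...) {
  rng <- range(x$pixels[x$fov_mask])
  cat(sprintf("<cartesian_image> %d x %d, %d in-FoV px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$fov_mask), rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.cartesian_image <- function(x) dim(x$pixels)

as_image <- function(x) {
  if (inherits(x, "cartesian_image")) x else cartesian_image(x)
}

#' Read and write images
#'
#' Images are stored as single-channel 32-bit float TIFF (lossless for the
#' simulation pipeline). `write_image_png` exports a 16-bit PNG for
#' viewing, clipping to `[0, 1]`.
#'
#' @param image a [cartesian_image()] or numeric matrix.
#' @param path file path.
#' @return `read_image` returns a [cartesian_image()] with an all-true
#'   mask (masks travel separately, e.g. via the dataset lattice);
#'   writers return `path` invisibly.
#' @export
write_image <- function(image, path) {
  image <- as_image(image)
  tiff::writeTIFF(image$pixels, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  cartesian_image(px, meta = list(source = path))
}

#' @rdname write_image
#' @export
write_image_png <- function(image, path) {
  image <- as_image(image)
  px <- pmin(pmax(image$pixels, 0), 1)
  png::writePNG(px, path, dpi = NULL)
  invisible(path)
}
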