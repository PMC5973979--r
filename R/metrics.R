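#' SSIM parameters
#'
#' Windowed structural-similarity settings: Gaussian window of odd size
#' (default 11, sigma 1.5) and the customary stabilization constants
#' `k1 = 0.01`, `k2 = 0.03` relative to `data_range`.
#'
#' @param window odd window size (>= 3).
#' @param sigma Gaussian window standard deviation.
#' @param k1,k2 stabilization constants.
#' @param data_range value range of the images being compared.
#' @return an object of class `ssim_params`.
#' @export
ssim_params <- function(window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                        data_range = 1.0) {
  window <- as.integer(window)
  stopifnot(window >= 3L, window %% 2L == 1L, k1 > 0, k2 > 0, data_range > 0,
            sigma > 0)
  structure(list(window = window, sigma = sigma, k1 = k1, k2 = k2,
                 data_range = data_range), class = "ssim_params")
}

# local SSIM map over valid window centers; optionally the gradient of
# mean(map * weight) wrt x. Windows are 'valid' (no padding), so the map is
# (H-w+1) x (W-w+1); the gradient has the full image size.
ssim_map_grad <- function(x, y, params, want_grad = FALSE, center_weight = NULL) {
  g <- gaussian_kernel(params$window, params$sigma)
  V <- function(z) cpp_sepconv(z, g, "valid")
  c1 <- (params$k1 * params$data_range)^2
  c2 <- (params$k2 * params$data_range)^2
  mx <- V(x); my <- V(y)
  sxx <- V(x * x) - mx * mx
  syy <- V(y * y) - my * my
  sxy <- V(x * y) - mx * my
  a1 <- 2 * mx * my + c1; a2 <- 2 * sxy + c2
  b1 <- mx^2 + my^2 + c1; b2 <- sxx + syy + c2
  s <- (a1 * a2) / (b1 * b2)
  if (!want_grad) return(list(map = s))
  w <- center_weight
  dmu <- (2 * my * b1 - 2 * mx * a1) / b1^2 * (a2 / b2) * w
  dsxx <- -(a1 * a2) / (b1 * b2^2) * w
  dsxy <- 2 * a1 / (b1 * b2) * w
  Ft <- function(z) cpp_sepconv(z, g, "full")
  grad <- Ft(dmu - 2 * mx * dsxx - my * dsxy) +
    2 * x * Ft(dsxx) + y * Ft(dsxy)
  list(map = s, grad = grad)
}

#' Structural similarity index
#'
#' Mean local SSIM between two images over valid window centers, restricted
#' to a mask. The local statistics use a Gaussian window (default 11 x 11,
#' sigma 1.5) without padding, so centers closer than half a window to the
#' border are not scored.
#'
#' @param a,b [cartesian_image()]s or numeric matrices of identical shape.
#' @param params an [ssim_params()].
#' @param mask logical matrix (image-sized) restricting which window
#'   centers are averaged; `NULL` uses `a`'s FoV mask if `a` is a
#'   [cartesian_image()], otherwise the full frame. Pass `NA` to force
#'   full-frame scoring.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, params = ssim_params(), mask = NULL) {
  if (is.null(mask) && inherits(a, "cartesian_image")) mask <- a$fov_mask
  ax <- if (inherits(a, "cartesian_image")) a$pixels else as.matrix(a)
  bx <- if (inherits(b, "cartesian_image")) b$pixels else as.matrix(b)
  if (!identical(dim(ax), dim(bx))) stop("images must have identical shapes")
  if (min(dim(ax)) < params$window) stop("image smaller than the SSIM window")
  res <- ssim_map_grad(ax, bx, params)
  r <- (params$window - 1L) / 2L
  if (is.null(mask) || (length(mask) == 1L && is.na(mask))) {
    return(mean(res$map))
  }
  mask <- as.matrix(mask)
  stopifnot(identical(dim(mask), dim(ax)))
  mc <- mask[(r + 1):(nrow(ax) - r), (r + 1):(ncol(ax) - r), drop = FALSE]
  if (!any(mc)) stop("mask leaves no valid window centers")
  mean(res$map[mc])
}

#' Global contrast factor
#'
#' Reference-free multi-resolution contrast measure. Pixel values are
#' treated as display intensities in `[0, 1]`: gamma-linearized luminance
#' `l = v^2.2` is block-averaged into superpixels of sizes 1, 2, 4, 8, 16,
#' 25, 50, 100 and 200, perceptual lightness is `L = 100 * sqrt(l)`, the
#' local contrast of a superpixel is the mean absolute lightness difference
#' to its 4-neighbours, the level contrast `C_i` is the mean local
#' contrast, and GCF is the weighted sum of the `C_i` with weights
#' `w_i = (-0.406385 * i/7 + 0.334573) * (i/7) + 0.0877526`. Levels whose
#' superpixel grid is smaller than 2 x 2 are skipped. With a mask, block
#' averages use only in-mask pixels and empty blocks are dropped. When a
#' superpixel size does not divide the grid evenly the trailing blocks are
#' ragged, so the value is exactly flip-invariant only on grids that all
#' levels tile evenly (e.g. multiples of 400).
#'
#' @param image a [cartesian_image()] or numeric matrix with values in
#'   `[0, 1]` (rescale first, e.g. with [rescale_unit()]).
#' @param mask optional logical matrix; defaults to the image's FoV mask.
#' @return non-negative scalar; 0 for a constant image.
#' @export
gcf <- function(image, mask = NULL) {
  if (is.null(mask) && inherits(image, "cartesian_image")) mask <- image$fov_mask
  px <- if (inherits(image, "cartesian_image")) image$pixels else as.matrix(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  vals <- px[mask]
  if (any(vals < -1e-6 | vals > 1 + 1e-6))
    stop("gcf expects display intensities in [0, 1]; rescale first")
  if (length(vals) == 0L || max(vals) - min(vals) == 0) return(0)
  px <- pmin(pmax(px, 0), 1)
  l <- px^2.2
  l[!mask] <- 0
  sizes <- c(1L, 2L, 4L, 8L, 16L, 25L, 50L, 100L, 200L)
  total <- 0
  for (i in seq_along(sizes)) {
    w <- sizes[i]
    nr2 <- ceiling(nrow(px) / w); nc2 <- ceiling(ncol(px) / w)
    if (nr2 < 2L || nc2 < 2L) next
    rg <- ceiling(seq_len(nrow(px)) / w)
    cg <- ceiling(seq_len(ncol(px)) / w)
    sums <- t(rowsum(t(rowsum(l, rg)), cg))
    cnts <- t(rowsum(t(rowsum(mask + 0, rg)), cg))
    lavg <- matrix(NA_real_, nr2, nc2)
    lavg[cnts > 0] <- sums[cnts > 0] / cnts[cnts > 0]
    L <- 100 * sqrt(lavg)
    lc <- local_contrast_4n(L)
    if (all(is.na(lc))) next
    wi <- (-0.406385 * i / 7 + 0.334573) * (i / 7) + 0.0877526
    total <- total + wi * mean(lc, na.rm = TRUE)
  }
  total
}

# mean absolute difference to available (non-NA) 4-neighbours; NA where the
# superpixel itself is invalid or has no valid neighbour
local_contrast_4n <- function(L) {
  nr <- nrow(L); nc <- ncol(L)
  acc <- matrix(0, nr, nc); cnt <- matrix(0L, nr, nc)
  add <- function(acc, cnt, d, valid) {
    ok <- !is.na(d) & valid
    acc[ok] <- acc[ok] + abs(d[ok])
    cnt[ok] <- cnt[ok] + 1L
    list(acc, cnt)
  }
  pad_shift <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- L[rs[okr], cs[okc], drop = FALSE]
    out
  }
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pad_shift(d[1], d[2])
    res <- add(acc, cnt, L - nb, !is.na(L))
    acc <- res[[1]]; cnt <- res[[2]]
  }
  out <- matrix(NA_real_, nr, nc)
  ok <- cnt > 0
  out[ok] <- acc[ok] / cnt[ok]
  out
}

#' Contrast difference between two images
#'
#' `gcf(a) - gcf(b)`: positive when `a` has more global contrast.
#'
#' @param a,b images accepted by [gcf()].
#' @param mask optional mask applied to both.
#' @return scalar.
#' @export
delta_gcf <- function(a, b, mask = NULL) {
  gcf(a, mask) - gcf(b, mask)
}

#' Composite quality score across methods
#'
#' Combines, per method, the mean SSIM against the reference and the mean
#' contrast gain over the input: each factor is min-max normalized to
#' `[0, 1]` across the compared methods (include the LR baseline row in the
#' inputs) and the two normalized factors are averaged. If a factor is
#' constant across methods it carries no ranking information and is set to
#' the neutral value 0.5 for all methods.
#'
#' @param ssim_means named numeric vector, one mean SSIM per method.
#' @param dgcf_lr_means named numeric vector, mean GCF gain over LR per
#'   method, aligned with `ssim_means`.
#' @return named numeric vector of composite scores in `[0, 1]`.
#' @export
composite_score <- function(ssim_means, dgcf_lr_means) {
  stopifnot(length(ssim_means) == length(dgcf_lr_means),
            length(ssim_means) >= 2L)
  norm01 <- function(v) {
    rng <- range(v)
    if (rng[2] - rng[1] <= 0) return(rep(0.5, length(v)))
    (v - rng[1]) / (rng[2] - rng[1])
  }
  out <- (norm01(ssim_means) + norm01(dgcf_lr_means)) / 2
  names(out) <- names(ssim_means)
  out
}

#' Paired two-sided t-test
#'
#' Standard paired t-test on per-image score differences.
#'
#' @param x,y numeric vectors of equal length (>= 2), scores of the same
#'   images under two methods.
#' @return list with `t` and `p` (two-sided).
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1))
    stop("degenerate input: zero variance of differences")
  }
  ht <- t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Evaluate one super-resolution method
#'
#' Computes the six quality scores of a method over aligned image lists:
#' mean and sd of (i) SSIM(SR, HR), (ii) GCF(SR) - GCF(LR), and (iii)
#' GCF(SR) - GCF(HR). Inputs are expected in display range (the
#' preprocessing pipeline already scales each frame to `[0, 1]`); values
#' outside `[0, 1]` — e.g. over-/undershoot in network predictions — are
#' clipped rather than re-stretched, because a per-frame min-max stretch
#' is collapsed by single outlier pixels. The identity method `SR := LR`
#' serves as the baseline row.
#'
#' @param sr_images,lr_images,hr_images equal-length lists of
#'   [cartesian_image()]s or matrices.
#' @param mask optional logical matrix applied to all images.
#' @param params an [ssim_params()].
#' @return an object of class `quality_report`: the six aggregate scores,
#'   `n_images`, and per-image vectors (`ssim`, `dgcf_lr`, `dgcf_hr`).
#' @export
evaluate_method <- function(sr_images, lr_images, hr_images, mask = NULL,
                            params = ssim_params()) {
  n <- length(sr_images)
  if (length(lr_images) != n || length(hr_images) != n)
    stop("sr, lr and hr lists must have equal length")
  stopifnot(n >= 1L)
  ss <- dl <- dh <- numeric(n)
  for (i in seq_len(n)) {
    get_m <- function(x) if (inherits(x, "cartesian_image")) x else cartesian_image(as.matrix(x), mask)
    clip01 <- function(img) {
      px <- pmin(pmax(img$pixels, 0), 1)
      px[!img$fov_mask] <- 0
      cartesian_image(px, img$fov_mask, img$meta)
    }
    sr <- clip01(get_m(sr_images[[i]]))
    lr <- clip01(get_m(lr_images[[i]]))
    hr <- clip01(get_m(hr_images[[i]]))
    m <- if (is.null(mask)) sr$fov_mask else mask
    ss[i] <- ssim(sr$pixels, hr$pixels, params, mask = m)
    g_sr <- gcf(sr$pixels, m); g_lr <- gcf(lr$pixels, m); g_hr <- gcf(hr$pixels, m)
    dl[i] <- g_sr - g_lr
    dh[i] <- g_sr - g_hr
  }
  structure(list(ssim_mean = mean(ss), ssim_sd = if (n > 1) sd(ss) else 0,
                 dgcf_lr_mean = mean(dl), dgcf_lr_sd = if (n > 1) sd(dl) else 0,
                 dgcf_hr_mean = mean(dh), dgcf_hr_sd = if (n > 1) sd(dh) else 0,
                 n_images = n, ssim = ss, dgcf_lr = dl, dgcf_hr = dh),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(paste0("<quality_report> n=%d  SSIM %.4f+/-%.4f  ",
                     "dGCF(LR) %+.4f+/-%.4f  dGCF(HR) %+.4f+/-%.4f\n"),
              x$n_images, x$ssim_mean, x$ssim_sd, x$dgcf_lr_mean,
              x$dgcf_lr_sd, x$dgcf_hr_mean, x$dgcf_hr_sd))
  invisible(x)
}

#' Quality table across methods with composite score
#'
#' Evaluates each method plus the LR identity baseline and appends the
#' composite score (min-max normalized across all rows, baseline included).
#'
#' @param sr_by_method named list; each element is a list of SR images
#'   aligned with `lr_images`/`hr_images`.
#' @param lr_images,hr_images aligned image lists.
#' @param mask optional logical matrix.
#' @param params an [ssim_params()].
#' @return a data.frame, one row per method (plus `"lr"`), with the six
#'   scores, `tot_cs` and `n_images`; the per-method reports are attached
#'   as attribute `"reports"`.
#' @export
quality_table <- function(sr_by_method, lr_images, hr_images, mask = NULL,
                          params = ssim_params()) {
  stopifnot(is.list(sr_by_method), length(names(sr_by_method)) == length(sr_by_method))
  methods <- c(names(sr_by_method), "lr")
  reports <- c(lapply(sr_by_method, evaluate_method, lr_images = lr_images,
                      hr_images = hr_images, mask = mask, params = params),
               list(lr = evaluate_method(lr_images, lr_images, hr_images,
                                         mask = mask, params = params)))
  ssim_means <- vapply(reports, function(r) r$ssim_mean, 0)
  dgcf_means <- vapply(reports, function(r) r$dgcf_lr_mean, 0)
  tot <- composite_score(ssim_means, dgcf_means)
  df <- data.frame(method = methods,
                   ssim_mean = ssim_means, ssim_sd = vapply(reports, function(r) r$ssim_sd, 0),
                   dgcf_lr_mean = dgcf_means, dgcf_lr_sd = vapply(reports, function(r) r$dgcf_lr_sd, 0),
                   dgcf_hr_mean = vapply(reports, function(r) r$dgcf_hr_mean, 0),
                   dgcf_hr_sd = vapply(reports, function(r) r$dgcf_hr_sd, 0),
                   tot_cs = tot,
                   n_images = vapply(reports, function(r) r$n_images, 0L),
                   row.names = NULL)
  attr(df, "reports") <- reports
  df
}
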