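#' Aligned LR/HR image pair
#'
#' @param lr,hr [cartesian_image()]s on identical grids with identical FoV
#'   masks (the LR frame is derived from the HR frame, so alignment is
#'   perfect by construction).
#' @param pair_id identifier string.
#' @param stratum categorical label used for stratified splitting.
#' @return an object of class `image_pair`.
#' @export
image_pair <- function(lr, hr, pair_id = "pair", stratum = "a") {
  lr <- as_image(lr); hr <- as_image(hr)
  if (!identical(dim(lr$pixels), dim(hr$pixels)))
    stop("lr and hr must share one pixel grid")
  if (!identical(lr$fov_mask, hr$fov_mask))
    stop("lr and hr must share one FoV mask")
  structure(list(lr = lr, hr = hr, pair_id = as.character(pair_id),
                 stratum = as.character(stratum)),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> '%s' (stratum %s), %d x %d\n", x$pair_id,
              x$stratum, nrow(x$lr$pixels), ncol(x$lr$pixels)))
  invisible(x)
}

#' Standardize an LR/HR pair by the LR frame statistics
#'
#' First preprocessing step: both frames are shifted and scaled by the mean
#' and standard deviation of the LR frame's in-FoV pixels, so the LR output
#' has in-FoV mean 0 and sd 1 and the HR frame stays on the same intensity
#' scale as its LR counterpart.
#'
#' @param pair an [image_pair()].
#' @return the standardized [image_pair()].
#' @export
standardize_pair <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  m <- pair$lr$fov_mask
  mu <- mean(pair$lr$pixels[m])
  s <- sd(pair$lr$pixels[m])
  if (!is.finite(s) || s <= 0) stop("degenerate input: constant LR frame")
  tf <- function(img) {
    px <- (img$pixels - mu) / s
    px[!m] <- 0
    cartesian_image(px, m, c(img$meta, list(standardized = c(mean = mu, sd = s))))
  }
  image_pair(tf(pair$lr), tf(pair$hr), pair$pair_id, pair$stratum)
}

#' Rescale a frame to the unit interval
#'
#' Second preprocessing step: affinely maps the in-FoV pixels of one frame
#' so the minimum becomes 0 and the maximum 1. Out-of-FoV pixels are set
#' to 0. Idempotent.
#'
#' @param image a [cartesian_image()] or matrix.
#' @return the rescaled [cartesian_image()].
#' @export
rescale_unit <- function(image) {
  image <- as_image(image)
  m <- image$fov_mask
  rng <- range(image$pixels[m])
  if (rng[2] <= rng[1]) stop("degenerate input: constant frame")
  px <- (image$pixels - rng[1]) / (rng[2] - rng[1])
  px[!m] <- 0
  cartesian_image(px, m, image$meta)
}

#' Extract aligned non-overlapping training patches
#'
#' Tiles the FoV bounding box with non-overlapping `patch_size` x
#' `patch_size` tiles (origin at the bounding-box top-left, so the yield is
#' invariant to grid padding) and keeps a tile iff its in-FoV pixel
#' fraction is at least `coverage`. LR and HR patches are cut at identical
#' locations. The default `coverage = 1` keeps only patches fully inside
#' the FoV.
#'
#' @param pair an [image_pair()].
#' @param patch_size patch side length in pixels (default 64).
#' @param coverage minimum in-FoV fraction in `[0, 1]` for a tile to be kept.
#' @return an object of class `patch_set`: list with `lr`, `hr` (arrays of
#'   dimension `patch_size x patch_size x n`), `origins` (n x 2 matrix of
#'   top-left corners), `patch_size`, `pair_ids`.
#' @export
extract_patches <- function(pair, patch_size = 64L, coverage = 1.0) {
  stopifnot(inherits(pair, "image_pair"))
  patch_size <- as.integer(patch_size)
  gs <- dim(pair$lr$pixels)
  if (patch_size > min(gs)) stop("patch_size larger than the image grid")
  stopifnot(coverage >= 0, coverage <= 1)
  m <- pair$lr$fov_mask
  rows_in <- which(rowSums(m) > 0); cols_in <- which(colSums(m) > 0)
  if (length(rows_in) == 0) stop("empty FoV mask")
  r0 <- rows_in[1]; c0 <- cols_in[1]
  r_starts <- seq.int(r0, rows_in[length(rows_in)] - patch_size + 1L, by = patch_size)
  c_starts <- seq.int(c0, cols_in[length(cols_in)] - patch_size + 1L, by = patch_size)
  origins <- NULL
  for (rs in r_starts) for (cs in c_starts) {
    frac <- mean(m[rs:(rs + patch_size - 1L), cs:(cs + patch_size - 1L)])
    if (frac >= coverage) origins <- rbind(origins, c(rs, cs))
  }
  n <- if (is.null(origins)) 0L else nrow(origins)
  lr <- array(0, c(patch_size, patch_size, n))
  hr <- array(0, c(patch_size, patch_size, n))
  for (i in seq_len(n)) {
    rs <- origins[i, 1]; cs <- origins[i, 2]
    lr[, , i] <- pair$lr$pixels[rs:(rs + patch_size - 1L), cs:(cs + patch_size - 1L)]
    hr[, , i] <- pair$hr$pixels[rs:(rs + patch_size - 1L), cs:(cs + patch_size - 1L)]
  }
  structure(list(lr = lr, hr = hr,
                 origins = if (is.null(origins)) matrix(0L, 0, 2) else origins,
                 patch_size = patch_size,
                 pair_ids = rep(pair$pair_id, n)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d\n",
              dim(x$lr)[3], x$patch_size, x$patch_size))
  invisible(x)
}

#' Concatenate patch sets
#' @param ... `patch_set` objects of identical patch size.
#' @return a combined `patch_set`.
#' @export
bind_patches <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "patch_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "patch_set")))
  ps <- sets[[1]]$patch_size
  stopifnot(all(vapply(sets, function(s) s$patch_size == ps, TRUE)))
  n <- sum(vapply(sets, function(s) dim(s$lr)[3], 1L))
  lr <- array(0, c(ps, ps, n)); hr <- array(0, c(ps, ps, n))
  ids <- character(0); orig <- matrix(0L, 0, 2); at <- 0L
  for (s in sets) {
    k <- dim(s$lr)[3]
    if (k > 0) {
      lr[, , at + seq_len(k)] <- s$lr
      hr[, , at + seq_len(k)] <- s$hr
      ids <- c(ids, s$pair_ids); orig <- rbind(orig, s$origins)
      at <- at + k
    }
  }
  structure(list(lr = lr, hr = hr, origins = orig, patch_size = ps,
                 pair_ids = ids), class = "patch_set")
}

#' Stratified train/validation/test split
#'
#' Splits pairs into three disjoint, exhaustive subsets. Within each
#' stratum the subset sizes follow `fractions` via largest-remainder
#' rounding, so every tissue stratum is proportionally represented in each
#' subset. Deterministic for a fixed seed.
#'
#' @param pairs list of [image_pair()]s (or any objects with a `stratum`
#'   field).
#' @param fractions length-3 numeric summing to 1; default `(0.70, 0.15,
#'   0.15)`.
#' @param seed integer seed for the within-stratum shuffle.
#' @return a list with elements `train`, `val`, `test` (lists of pairs) and
#'   `membership` (character vector aligned with `pairs`).
#' @export
split_dataset <- function(pairs, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(is.list(pairs), length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  strata <- vapply(pairs, function(p) p$stratum, "")
  membership <- character(length(pairs))
  for (s in sort(unique(strata))) {
    idx <- which(strata == s)
    idx <- with_seed(derive_seed(seed, sum(utf8ToInt(s))), sample(idx))
    n <- length(idx)
    base <- floor(fractions * n)
    rem <- fractions * n - base
    short <- n - sum(base)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      base[add] <- base[add] + 1
    }
    lab <- rep(c("train", "val", "test"), times = base)
    membership[idx] <- lab
  }
  list(train = pairs[membership == "train"],
       val = pairs[membership == "val"],
       test = pairs[membership == "test"],
       membership = membership)
}

#' Build a paired synthetic dataset on disk
#'
#' Orchestrates the full data-generation pipeline: one fibre lattice,
#' `n_pairs` phantom HR frames (alternating between the two texture
#' strata), the fibre-bundle forward simulation of each LR counterpart
#' (per-frame noise streams derived from the global seed, so regeneration
#' is order-independent), the stratified split, and serialization as
#' 32-bit float TIFFs plus a JSON manifest. Frames are affinely encoded to
#' `[0, 1]` for TIFF storage; the per-frame `range` entries in the
#' manifest restore the original values on load.
#'
#' @param config list; recognised entries (with defaults): `n_pairs` (12),
#'   `grid_shape` (c(256, 256)), `n_fibres` (600), `fov_radius` (120),
#'   `jitter_frac` (0.25), `sigma_m` (0.05), `sigma_a_coeff` (0.01),
#'   `n_blobs` (150), `fractions` (c(.7, .15, .15)), `seed` (1).
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly; files are written under `out_dir`
#'   as `train/ val/ test/ <pair_id>_{lr,hr}.tiff`, `lattice.json`,
#'   `manifest.json`.
#' @export
build_dataset <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(list(
    n_pairs = 12L, grid_shape = c(256L, 256L), n_fibres = 600L,
    fov_radius = 120, jitter_frac = 0.25, sigma_m = 0.05,
    sigma_a_coeff = 0.01, n_blobs = 150L,
    fractions = c(0.70, 0.15, 0.15), seed = 1L), config)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output dir: ", out_dir)
  }
  gs <- as.integer(cfg$grid_shape)
  lattice <- generate_fibre_lattice(cfg$n_fibres, cfg$fov_radius,
                                    fov_center = (gs + 1) / 2,
                                    jitter_frac = cfg$jitter_frac,
                                    seed = derive_seed(cfg$seed, 0))
  tri <- triangulate(lattice)
  assignment <- nearest_fibre_map(lattice, gs)
  pairs <- vector("list", cfg$n_pairs)
  for (i in seq_len(cfg$n_pairs)) {
    stratum <- if (i %% 2L == 1L) "a" else "b"
    hr <- generate_phantom_hr(gs, lattice, n_blobs = cfg$n_blobs,
                              texture_params = phantom_texture(stratum),
                              seed = derive_seed(cfg$seed, i))
    np <- noise_params(cfg$sigma_m, cfg$sigma_a_coeff,
                       seed = derive_seed(cfg$seed, i + cfg$n_pairs))
    lr <- simulate_lr(hr, lattice, np, tri = tri, assignment = assignment)
    pairs[[i]] <- image_pair(lr, hr, pair_id = sprintf("pair%03d", i),
                             stratum = stratum)
  }
  sp <- split_dataset(pairs, cfg$fractions, seed = derive_seed(cfg$seed, 10^6))
  write_lattice(lattice, file.path(out_dir, "lattice.json"))
  entries <- vector("list", cfg$n_pairs)
  for (i in seq_len(cfg$n_pairs)) {
    p <- pairs[[i]]
    sub <- sp$membership[i]
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
    enc <- function(img, which) {
      m <- img$fov_mask
      rng <- range(img$pixels[m])
      px <- if (rng[2] > rng[1]) (img$pixels - rng[1]) / (rng[2] - rng[1])
            else img$pixels * 0
      px[!m] <- 0
      f <- file.path(out_dir, sub, sprintf("%s_%s.tiff", p$pair_id, which))
      write_image(cartesian_image(px, m), f)
      list(file = file.path(sub, basename(f)), range = rng)
    }
    e_lr <- enc(p$lr, "lr"); e_hr <- enc(p$hr, "hr")
    entries[[i]] <- list(pair_id = p$pair_id, stratum = p$stratum,
                         split = sub, lr = e_lr, hr = e_hr,
                         noise = p$lr$meta$noise)
  }
  manifest <- list(config = cfg, pairs = entries,
                   grid_shape = gs, n_fibres = lattice$n_fibres)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a dataset written by [build_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `pairs` (list of [image_pair()]s), `split` (list of
#'   pair lists `train`/`val`/`test`), `lattice`, `manifest`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lattice <- read_lattice(file.path(dir, "lattice.json"))
  gs <- as.integer(unlist(manifest$grid_shape))
  mask <- fov_mask(lattice, gs)
  dec <- function(entry) {
    img <- read_image(file.path(dir, entry$file))
    rng <- as.numeric(unlist(entry$range))
    px <- img$pixels * (rng[2] - rng[1]) + rng[1]
    px[!mask] <- 0
    cartesian_image(px, mask)
  }
  pairs <- lapply(manifest$pairs, function(e)
    image_pair(dec(e$lr), dec(e$hr), e$pair_id, e$stratum))
  membership <- vapply(manifest$pairs, function(e) e$split, "")
  list(pairs = pairs,
       split = list(train = pairs[membership == "train"],
                    val = pairs[membership == "val"],
                    test = pairs[membership == "test"]),
       lattice = lattice, manifest = manifest)
}

#' Preprocess an LR/HR pair for training or evaluation
#'
#' The two-step protocol: standardize both frames by the LR in-FoV
#' statistics, then rescale each frame individually to `[0, 1]`.
#'
#' @param pair an [image_pair()].
#' @return the preprocessed [image_pair()].
#' @export
preprocess_pair <- function(pair) {
  p <- standardize_pair(pair)
  image_pair(rescale_unit(p$lr), rescale_unit(p$hr), p$pair_id, p$stratum)
}
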