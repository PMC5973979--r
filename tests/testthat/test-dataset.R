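make_pair <- function(seed = 1, n_fibres = 150, gs = c(96, 96), stratum = "a") {
  lat <- generate_fibre_lattice(n_fibres, 0.45 * gs[1], (gs + 1) / 2, seed = seed)
  hr <- generate_phantom_hr(gs, lat, n_blobs = 40,
                            texture_params = phantom_texture(stratum),
                            seed = seed + 1)
  lr <- simulate_lr(hr, lat, noise_params(seed = seed + 2))
  image_pair(lr, hr, sprintf("p%d", seed), stratum)
}

test_that("phantom generation is deterministic and spans the intensity range", {
  lat <- generate_fibre_lattice(300, 120, c(128.5, 128.5), seed = 1)
  h1 <- generate_phantom_hr(c(256, 256), lat, n_blobs = 150, seed = 5)
  h2 <- generate_phantom_hr(c(256, 256), lat, n_blobs = 150, seed = 5)
  expect_identical(h1$pixels, h2$pixels)
  v <- h1$pixels[h1$fov_mask]
  expect_lte(min(v), 0.05)
  expect_gte(max(v), 0.95)
  expect_gt(sd(v), 0.08)
  expect_true(all(v >= 0 & v <= 1))
  # contrast exceeds a blurred copy of itself
  blur <- pmin(pmax(blur_gaussian(h1$pixels, 3), 0), 1)
  expect_gt(gcf(h1), gcf(blur, h1$fov_mask))
  # flat, featureless configuration stays constant
  flat <- generate_phantom_hr(c(64, 64), NULL, n_blobs = 0,
                              texture_params = list(name = "flat",
                                sigma_range = c(1, 2), aspect_range = c(1, 1),
                                amp_range = c(0, 0), background = 0.5,
                                bg_mod_amp = 0, bg_smooth_sigma = 1,
                                fine_amp = 0), seed = 1)
  expect_equal(unique(as.numeric(flat$pixels)), 0.5)
})

test_that("standardization uses the LR statistics for both frames", {
  pair <- make_pair(1)
  std <- standardize_pair(pair)
  m <- pair$lr$fov_mask
  expect_equal(mean(std$lr$pixels[m]), 0, tolerance = 1e-9)
  expect_equal(sd(std$lr$pixels[m]), 1, tolerance = 1e-9)
  mu <- mean(pair$lr$pixels[m]); s <- sd(pair$lr$pixels[m])
  expect_equal(std$hr$pixels[m], (pair$hr$pixels[m] - mu) / s, tolerance = 1e-12)
  # hr == lr gives identical outputs
  pp <- image_pair(pair$lr, pair$lr, "same", "a")
  stdp <- standardize_pair(pp)
  expect_identical(stdp$lr$pixels, stdp$hr$pixels)
  const <- image_pair(cartesian_image(matrix(1, 8, 8)),
                      cartesian_image(matrix(1, 8, 8)))
  expect_error(standardize_pair(const), "constant")
})

test_that("unit rescaling maps the in-FoV range to [0,1] and is idempotent", {
  pair <- make_pair(2)
  m <- pair$lr$fov_mask
  x <- pair$lr$pixels * 5 - 2
  img <- cartesian_image(x, m)
  r1 <- rescale_unit(img)
  expect_equal(range(r1$pixels[m]), c(0, 1))
  expect_identical(which.min(r1$pixels[m]), which.min(x[m]))
  expect_identical(which.max(r1$pixels[m]), which.max(x[m]))
  r2 <- rescale_unit(r1)
  expect_equal(r2$pixels, r1$pixels, tolerance = 1e-12)
  expect_error(rescale_unit(cartesian_image(matrix(2, 4, 4))), "constant")
})

test_that("preprocessing order (standardize then rescale) preserves SSIM up to rescale", {
  pair <- make_pair(3)
  pre <- preprocess_pair(pair)
  direct_lr <- rescale_unit(pair$lr)
  # per-frame standardization + rescale is one affine map per frame
  expect_equal(pre$lr$pixels, direct_lr$pixels, tolerance = 1e-12)
  s1 <- ssim(pre$lr$pixels, pre$hr$pixels, mask = pair$lr$fov_mask)
  s2 <- ssim(direct_lr$pixels, rescale_unit(pair$hr)$pixels,
             mask = pair$lr$fov_mask)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("patch extraction tiles the FoV bounding box", {
  full <- image_pair(cartesian_image(matrix(runif(256^2), 256)),
                     cartesian_image(matrix(runif(256^2), 256)))
  ps <- extract_patches(full, 64, coverage = 1)
  expect_identical(dim(ps$lr)[3], 16L)
  expect_identical(nrow(unique(ps$origins)), 16L)
  # patches are disjoint and aligned between lr and hr
  expect_true(all(diff(sort(ps$origins[, 1] + 256 * ps$origins[, 2])) > 0))
  i <- 7L
  rs <- ps$origins[i, 1]; cs <- ps$origins[i, 2]
  expect_identical(ps$hr[, , i],
                   full$hr$pixels[rs:(rs + 63), cs:(cs + 63)])
  expect_error(extract_patches(full, 300), "larger")
})

test_that("patch FoV coverage rule matches brute-force counting", {
  pair <- make_pair(4, n_fibres = 300, gs = c(256, 256))
  m <- pair$lr$fov_mask
  for (cov in c(1, 0.6, 0)) {
    ps <- extract_patches(pair, 64, coverage = cov)
    # brute force: enumerate the tiling and count mask pixels per tile
    rows_in <- range(which(rowSums(m) > 0)); cols_in <- range(which(colSums(m) > 0))
    expected <- 0L
    for (rs in seq(rows_in[1], rows_in[2] - 63, by = 64))
      for (cs in seq(cols_in[1], cols_in[2] - 63, by = 64))
        if (mean(m[rs:(rs + 63), cs:(cs + 63)]) >= cov) expected <- expected + 1L
    expect_identical(dim(ps$lr)[3], expected)
  }
})

test_that("stratified split respects fractions, balance and partitioning", {
  pairs <- lapply(1:100, function(i) list(stratum = "a", id = i))
  sp <- split_dataset(pairs, seed = 1)
  expect_identical(lengths(sp[c("train", "val", "test")]),
                   c(train = 70L, val = 15L, test = 15L))
  # two strata of 10 pairs each stay balanced in every subset
  pairs2 <- c(lapply(1:10, function(i) list(stratum = "a", id = i)),
              lapply(1:10, function(i) list(stratum = "b", id = i)))
  sp2 <- split_dataset(pairs2, seed = 2)
  for (part in sp2[c("train", "val", "test")]) {
    strata <- vapply(part, `[[`, "", "stratum")
    expect_identical(sum(strata == "a"), sum(strata == "b"))
  }
  # disjoint and exhaustive
  ids <- lapply(sp2[c("train", "val", "test")],
                function(part) vapply(part, `[[`, 0, "id") +
                  100 * (vapply(part, `[[`, "", "stratum") == "b"))
  expect_equal(sort(unname(unlist(ids))), c(1:10, 101:110))
  expect_identical(sum(lengths(ids)), 20L)
  expect_error(split_dataset(pairs2, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
  # determinism
  expect_identical(split_dataset(pairs2, seed = 3)$membership,
                   split_dataset(pairs2, seed = 3)$membership)
})

test_that("dataset building writes a reloadable, reproducible directory", {
  cfg <- list(n_pairs = 12L, grid_shape = c(96L, 96L), n_fibres = 150L,
              fov_radius = 44, n_blobs = 40L, seed = 1L)
  d1 <- withr::local_tempdir()
  man1 <- build_dataset(cfg, d1)
  expect_length(man1$pairs, 12L)
  splits <- vapply(man1$pairs, `[[`, "", "split")
  expect_identical(as.integer(table(factor(splits, c("train", "val", "test")))),
                   c(8L, 2L, 2L))
  # rebuild: byte-identical manifest
  d2 <- withr::local_tempdir()
  build_dataset(cfg, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  expect_identical(unname(tools::md5sum(file.path(d1, "train",
                     sort(list.files(file.path(d1, "train")))))),
                   unname(tools::md5sum(file.path(d2, "train",
                     sort(list.files(file.path(d2, "train")))))))
  # reload restores pairs up to float32 storage precision
  ds <- read_dataset(d1)
  expect_length(ds$pairs, 12L)
  expect_identical(vapply(ds$pairs, function(p) p$pair_id, ""),
                   vapply(man1$pairs, `[[`, "", "pair_id"))
  p1 <- ds$pairs[[1]]
  expect_identical(dim(p1$lr$pixels), c(96L, 96L))
  expect_identical(p1$lr$fov_mask, p1$hr$fov_mask)
  rng <- range(p1$hr$pixels[p1$hr$fov_mask])
  expect_equal(rng, c(0, 1), tolerance = 1e-6)
})
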