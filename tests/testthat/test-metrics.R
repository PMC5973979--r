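test_that("ssim identity, symmetry and bounds", {
  set.seed(1)
  x <- matrix(runif(32 * 32), 32)
  y <- matrix(runif(32 * 32), 32)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_true(ssim(x, y) >= -1 && ssim(x, y) <= 1)
  expect_error(ssim(x, y[1:16, ]), "identical shapes")
})

test_that("ssim matches the direct windowed formula and detects anticorrelation", {
  cb <- outer(1:24, 1:24, function(r, c) (r + c) %% 2)
  s <- ssim(cb, 1 - cb)
  expect_lt(s, 0)
  expect_equal(s, bf_ssim(cb, 1 - cb), tolerance = 1e-10)
  set.seed(2)
  a <- matrix(runif(24 * 24), 24)
  b <- a + matrix(rnorm(24 * 24, 0, 0.1), 24)
  expect_equal(ssim(a, b), bf_ssim(a, b), tolerance = 1e-10)
})

test_that("ssim honours the mask", {
  set.seed(3)
  a <- matrix(runif(40 * 40), 40)
  b <- a
  b[1:15, ] <- runif(15 * 40)  # corrupt the top; keep a window-width margin
  m_bottom <- rbind(matrix(FALSE, 20, 40), matrix(TRUE, 20, 40))
  expect_equal(ssim(a, b, mask = m_bottom), 1, tolerance = 1e-9)
  expect_lt(ssim(a, b, mask = NA), 1)
})

test_that("gcf of a constant image is exactly zero", {
  expect_identical(gcf(matrix(0.5, 64, 64)), 0)
  expect_identical(gcf(matrix(0, 16, 16)), 0)
})

test_that("gcf level-1 contrast matches a hand computation on a 2x2 image", {
  img <- matrix(c(0, 0, 1, 1), 2, 2)  # columns: (0,0), (1,1)
  # linear luminance 0 and 1, lightness L = 0 and 100; every pixel has two
  # neighbours: one equal (|d|=0), one across (|d|=100) -> lc = 50 each,
  # C_1 = 50; only level 1 fits a 2x2 grid
  w1 <- (-0.406385 * 1 / 7 + 0.334573) * (1 / 7) + 0.0877526
  expect_equal(gcf(img), w1 * 50, tolerance = 1e-12)
})

test_that("gcf decreases under blur and is flip-invariant", {
  lat <- generate_fibre_lattice(100, 30, seed = 1)
  hr <- generate_phantom_hr(c(64, 64), lat, n_blobs = 30, seed = 2)
  g0 <- gcf(hr)
  gb <- gcf(pmin(pmax(blur_gaussian(hr$pixels, 2), 0), 1), hr$fov_mask)
  expect_gt(g0, gb)
  # checkerboard sharp vs blurred
  cb <- outer(1:32, 1:32, function(r, c) (r + c) %% 2)
  expect_gt(gcf(cb), gcf(pmin(pmax(blur_gaussian(cb, 2), 0), 1)))
  # flips do not change the value (on a grid every level tiles evenly)
  set.seed(8)
  big <- matrix(runif(400 * 400), 400)
  expect_equal(gcf(big), gcf(big[400:1, ]), tolerance = 1e-12)
  expect_equal(gcf(big), gcf(big[, 400:1]), tolerance = 1e-12)
  expect_error(gcf(hr$pixels * 3), "\\[0, 1\\]")
})

test_that("delta_gcf is an antisymmetric difference", {
  set.seed(4)
  a <- matrix(runif(32 * 32), 32)
  b <- pmin(pmax(blur_gaussian(a, 2), 0), 1)
  expect_identical(delta_gcf(a, a), 0)
  expect_equal(delta_gcf(a, b), -delta_gcf(b, a), tolerance = 1e-12)
  expect_gt(delta_gcf(a, b), 0)
})

test_that("composite score normalizes across methods", {
  s <- c(m1 = 0.8, m2 = 0.7)
  d <- c(m1 = 0.3, m2 = 0.1)
  tot <- composite_score(s, d)
  expect_equal(unname(tot), c(1, 0))
  # dominance: a method best on both factors scores 1
  s3 <- c(a = 0.9, b = 0.7, c = 0.6); d3 <- c(a = 0.5, b = 0.4, c = 0.1)
  expect_equal(unname(composite_score(s3, d3)["a"]), 1)
  # permutation invariance
  perm <- c(3, 1, 2)
  expect_equal(composite_score(s3[perm], d3[perm]),
               composite_score(s3, d3)[perm])
  # a constant factor is neutral at 0.5
  tot2 <- composite_score(c(a = 0.5, b = 0.5), c(a = 0.2, b = 0.4))
  expect_equal(unname(tot2), c(0.5 / 2 + 0, 0.5 / 2 + 0.5))
})

test_that("composite score is invariant to joint affine rescaling of one factor", {
  set.seed(5)
  s <- runif(4); d <- runif(4)
  names(s) <- names(d) <- letters[1:4]
  expect_equal(composite_score(10 * s - 3, d), composite_score(s, d),
               tolerance = 1e-12)
  expect_equal(composite_score(s, 0.2 * d + 7), composite_score(s, d),
               tolerance = 1e-12)
})

test_that("paired t-test agrees with the closed form", {
  expect_identical(paired_ttest(1:5, 1:5), list(t = 0, p = 1))
  set.seed(6)
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20, 0.3)
    got <- paired_ttest(x, y)
    want <- bf_paired_t(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  # hand-computed 5-point example
  x <- c(1, 2, 3, 4, 5); y <- c(1.1, 1.8, 3.3, 3.6, 5.2)
  got <- paired_ttest(x, y)
  d <- x - y
  expect_equal(got$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  # |t| grows as sqrt(n) for a near-constant difference
  set.seed(7)
  mk <- function(n) {
    x <- rnorm(n); d <- 0.5 + rnorm(n, 0, 1e-3)
    abs(paired_ttest(x + d, x)$t)
  }
  expect_gt(mk(400) / mk(100), 1.5)
  expect_error(paired_ttest(c(1, 2), c(0, 1)), "zero variance")
})

test_that("evaluate_method scores oracle and baseline methods correctly", {
  lat <- generate_fibre_lattice(150, 28, seed = 1)
  hrs <- lapply(1:3, function(s) generate_phantom_hr(c(64, 64), lat, 30, seed = s))
  lrs <- lapply(seq_along(hrs), function(i)
    simulate_lr(hrs[[i]], lat, noise_params(seed = 10 + i)))
  rep_hr <- evaluate_method(hrs, lrs, hrs)
  expect_equal(rep_hr$ssim_mean, 1, tolerance = 1e-9)
  expect_equal(rep_hr$dgcf_hr_mean, 0, tolerance = 1e-12)
  rep_lr <- evaluate_method(lrs, lrs, hrs)
  expect_equal(rep_lr$dgcf_lr_mean, 0, tolerance = 1e-12)
  # aggregates equal direct recomputation from the per-image vectors
  expect_equal(rep_lr$ssim_mean, mean(rep_lr$ssim))
  expect_equal(rep_lr$dgcf_hr_sd, sd(rep_lr$dgcf_hr))
  expect_error(evaluate_method(hrs[1:2], lrs, hrs), "equal length")
})

test_that("quality_table ranks the perfect method above the baseline", {
  lat <- generate_fibre_lattice(150, 28, seed = 2)
  hrs <- lapply(4:6, function(s) generate_phantom_hr(c(64, 64), lat, 30, seed = s))
  lrs <- lapply(seq_along(hrs), function(i)
    simulate_lr(hrs[[i]], lat, noise_params(seed = 20 + i)))
  qt <- quality_table(list(oracle = hrs), lrs, hrs)
  expect_setequal(qt$method, c("oracle", "lr"))
  expect_gt(qt$tot_cs[qt$method == "oracle"], qt$tot_cs[qt$method == "lr"])
  expect_true(all(qt$tot_cs >= 0 & qt$tot_cs <= 1))
})
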