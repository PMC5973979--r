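test_that("model parameter counts match the closed-form architecture sums", {
  # fsrcnn-like (d=56, s=12, m=4): 5x5 head, 1x1 shrink, m 3x3 mappings,
  # 1x1 expand, 9x9 stride-1 reconstruction
  d <- 56; s <- 12; m <- 4
  want <- (25 * d + d) + (d * s + s) + m * (9 * s * s + s) +
    (s * d + d) + (81 * d + 1)
  expect_identical(n_parameters(model_spec("fsrcnn_like")), as.integer(want))
  # edsr-like (w=32, B=4): 3x3 head, B blocks of two 3x3 convs, 3x3 tail
  w <- 32; B <- 4
  want2 <- (9 * w + w) + B * 2 * (9 * w * w + w) + (9 * w + 1)
  expect_identical(n_parameters(model_spec("edsr_like")), as.integer(want2))
})

test_that("networks are fully convolutional and seed-deterministic", {
  spec <- model_spec("edsr_like", width = 8, depth = 2)
  m1 <- build_model(spec, seed = 3)
  m2 <- build_model(spec, seed = 3)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(spec, seed = 4)
  expect_false(identical(m1$params, m3$params))
  for (dims in list(c(64, 64), c(97, 123))) {
    x <- matrix(runif(prod(dims)), dims[1])
    out <- predict(m1, x)
    expect_identical(dim(out$pixels), as.integer(dims))
  }
  expect_error(model_spec("vgg"), "arg")
})

test_that("zero-initialized edsr tail makes the untrained network an identity", {
  m <- build_model(model_spec("edsr_like", width = 8, depth = 2), seed = 1)
  x <- matrix(runif(40 * 40), 40)
  out <- predict(m, x)
  expect_lt(max(abs(out$pixels - x)), 1e-5)
})

test_that("losses obey their closed forms and limits", {
  set.seed(1)
  p <- matrix(runif(32 * 32), 32); tg <- matrix(runif(32 * 32), 32)
  expect_identical(loss_l1(p, p), 0)
  expect_equal(loss_ssim_l1(p, p, 0.84), 0, tolerance = 1e-12)
  expect_identical(loss_ssim_l1(p, tg, 0), loss_l1(p, tg))
  expect_equal(loss_ssim_l1(p, tg, 1), 1 - ssim(p, tg, mask = NA),
               tolerance = 1e-12)
  delta <- 0.17
  expect_equal(loss_l1(p + delta, p), delta, tolerance = 1e-12)
  expect_error(loss_l1(p, tg[1:10, ]), "shape")
})

test_that("analytic loss gradients match finite differences", {
  # smooth objective (pure SSIM) probed through both architectures
  set.seed(2)
  x <- array(runif(14 * 14 * 2), c(14, 14, 2))
  y <- array(runif(14 * 14 * 2), c(14, 14, 2))
  sp <- ssim_params(window = 5)
  for (spec in list(model_spec("edsr_like", width = 4, depth = 1),
                    model_spec("fsrcnn_like", width = 6, depth = 1, shrink = 3))) {
    mod <- build_model(spec, seed = 5)
    fw <- pclesr:::cpp_cnn_forward(mod$arch, mod$params, x, TRUE)
    lg <- pclesr:::loss_with_grad(fw$pred, y, "ssim_l1", 1, sp)
    gr <- pclesr:::cpp_cnn_backward(mod$arch, mod$params, fw$cache, lg$grad)
    eps <- 1e-3
    for (j in seq_along(mod$params)) {
      ii <- sample(length(mod$params[[j]]$W), 2)
      for (i in ii) {
        pp <- mod$params; pp[[j]]$W[i] <- pp[[j]]$W[i] + eps
        lp <- loss_ssim_l1(pclesr:::cpp_cnn_forward(mod$arch, pp, x, FALSE)$pred,
                           y, 1, sp)
        pm <- mod$params; pm[[j]]$W[i] <- pm[[j]]$W[i] - eps
        lm <- loss_ssim_l1(pclesr:::cpp_cnn_forward(mod$arch, pm, x, FALSE)$pred,
                           y, 1, sp)
        fd <- (lp - lm) / (2 * eps)
        expect_equal(gr[[j]]$W[i], fd, tolerance = 5e-3)
      }
    }
  }
})

test_that("training descends on a learnable task and is reproducible", {
  # small denoising task: recover clean patches from noisy ones
  set.seed(3)
  n <- 60
  clean <- array(0, c(16, 16, n))
  for (i in seq_len(n))
    clean[, , i] <- blur_gaussian(matrix(runif(256), 16), 1.5)
  noisy <- clean + array(rnorm(length(clean), 0, 0.1), dim(clean))
  mk <- function(idx) structure(list(lr = noisy[, , idx, drop = FALSE],
                                     hr = clean[, , idx, drop = FALSE],
                                     origins = matrix(0L, length(idx), 2),
                                     patch_size = 16L,
                                     pair_ids = rep("x", length(idx))),
                                class = "patch_set")
  tr <- mk(1:48); va <- mk(49:60)
  spec <- model_spec("edsr_like", width = 8, depth = 1)
  cfg <- train_config(minibatch = 16, max_steps = 200, lr = 1e-3, loss = "l1",
                      seed = 11, val_interval = 40)
  mod <- build_model(spec, seed = 10)
  t1 <- train_sr(mod, tr, va, cfg)
  # validation loss fell below the identity mapping's loss (step-0 network
  # is the identity by construction)
  id_loss <- loss_l1(va$lr, va$hr)
  expect_lt(t1$best_val_loss, id_loss)
  expect_lt(t1$history$train_loss[200], t1$history$train_loss[1])
  t2 <- train_sr(build_model(spec, seed = 10), tr, va, cfg)
  expect_equal(t1$history$train_loss, t2$history$train_loss, tolerance = 1e-10)
  expect_error(train_sr(mod, mk(integer(0)), va, cfg), "empty")
})

test_that("inference commutes with interior cropping (fully-convolutional contract)", {
  set.seed(4)
  mod <- build_model(model_spec("edsr_like", width = 6, depth = 1), seed = 6)
  # give it non-trivial weights
  mod$params <- lapply(mod$params, function(p) {
    p$W <- p$W + array(rnorm(length(p$W), 0, 0.05), dim(p$W)); p
  })
  big <- matrix(runif(80 * 80), 80)
  out_big <- predict(mod, big)$pixels
  inner <- 21:60
  out_crop <- predict(mod, big[inner, inner])$pixels
  rf <- receptive_field(mod)
  core <- (rf + 1):(40 - rf)
  expect_lt(max(abs(out_big[inner, inner][core, core] - out_crop[core, core])),
            1e-5)
  expect_error(predict(mod, matrix(0.5, 4, 4)), "receptive field")
})

test_that("unsharp masking sharpens and respects its limits", {
  lat <- generate_fibre_lattice(150, 28, seed = 1)
  hr <- generate_phantom_hr(c(64, 64), lat, 30, seed = 2)
  expect_equal(baseline_sharpen(hr, amount = 0)$pixels, hr$pixels)
  cst <- cartesian_image(matrix(0.4, 32, 32))
  expect_equal(baseline_sharpen(cst, amount = 1)$pixels, cst$pixels,
               tolerance = 1e-12)
  sharp <- baseline_sharpen(hr, amount = 1, radius = 2)
  expect_gt(gcf(sharp), gcf(hr))
  expect_true(all(sharp$pixels >= 0 & sharp$pixels <= 1))
})

test_that("Wiener deconvolution restores Gaussian blur and vanishes at high NSR", {
  lat <- generate_fibre_lattice(150, 28, seed = 3)
  hr <- generate_phantom_hr(c(64, 64), lat, 30, seed = 4)
  blurred <- cartesian_image(blur_gaussian(hr$pixels, 2), hr$fov_mask)
  rest <- baseline_wiener(blurred, psf_sigma = 2, nsr = 1e-4)
  m <- hr$fov_mask
  expect_lt(mean(abs(rest$pixels[m] - hr$pixels[m])),
            mean(abs(blurred$pixels[m] - hr$pixels[m])))
  dead <- baseline_wiener(blurred, psf_sigma = 2, nsr = 1e8)
  expect_lt(max(abs(dead$pixels)), 1e-4)
  expect_identical(formals(baseline_wiener)$psf_sigma, 2)
})

test_that("model checkpoints round-trip through disk", {
  mod <- build_model(model_spec("fsrcnn_like", width = 8, depth = 1, shrink = 4),
                     seed = 7)
  d <- withr::local_tempdir()
  save_model(mod, d)
  mod2 <- load_model(d)
  expect_equal(mod2$params, mod$params, tolerance = 1e-15)
  x <- matrix(runif(40 * 40), 40)
  expect_equal(predict(mod2, x)$pixels, predict(mod, x)$pixels,
               tolerance = 1e-12)
})
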