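#' Training losses
#'
#' `loss_l1` is the mean absolute error. `loss_ssim_l1` is the mixed
#' objective `alpha * (1 - SSIM(pred, target)) + (1 - alpha) * L1`, with
#' SSIM computed with the same windowed definition as [ssim()] (valid
#' Gaussian windows) and averaged over the batch. The default mixing
#' weight `alpha = 0.84` follows the restoration-loss literature.
#'
#' @param pred,target numeric matrices or arrays `(H, W, N)` of identical
#'   shape.
#' @param alpha SSIM mixing weight in `[0, 1]`.
#' @param params an [ssim_params()].
#' @return scalar loss.
#' @export
loss_l1 <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  mean(abs(pred - target))
}

#' @rdname loss_l1
#' @export
loss_ssim_l1 <- function(pred, target, alpha = 0.84, params = ssim_params()) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  stopifnot(alpha >= 0, alpha <= 1)
  if (alpha == 0) return(loss_l1(pred, target))
  alpha * (1 - batch_ssim(pred, target, params)) +
    (1 - alpha) * loss_l1(pred, target)
}

as_batch <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

batch_ssim <- function(pred, target, params) {
  p <- as_batch(pred); t <- as_batch(target)
  n <- dim(p)[3]
  mean(vapply(seq_len(n), function(i)
    mean(ssim_map_grad(p[, , i], t[, , i], params)$map), 0))
}

# loss and gradient wrt pred for the training loop
loss_with_grad <- function(pred, target, loss, alpha, params) {
  p <- as_batch(pred); tg <- as_batch(target)
  n <- dim(p)[3]
  l1 <- mean(abs(p - tg))
  g <- sign(p - tg) / length(p)
  if (loss == "l1" || alpha == 0)
    return(list(loss = l1, grad = g))
  ssim_vals <- numeric(n)
  gs <- array(0, dim(p))
  for (i in seq_len(n)) {
    r <- ssim_map_grad(p[, , i], tg[, , i], params, want_grad = TRUE,
                       center_weight = 1)
    ssim_vals[i] <- mean(r$map)
    nc <- length(r$map)
    gs[, , i] <- r$grad / nc
  }
  total <- alpha * (1 - mean(ssim_vals)) + (1 - alpha) * l1
  grad <- -alpha * gs / n + (1 - alpha) * g
  list(loss = total, grad = grad)
}

#' Training configuration
#'
#' @param minibatch patches per step (default 54).
#' @param max_steps optimization steps.
#' @param lr Adam learning rate.
#' @param loss `"ssim_l1"` or `"l1"`.
#' @param alpha SSIM mixing weight for `"ssim_l1"`.
#' @param seed run seed (initialization is the model's own seed; this one
#'   drives patch shuffling).
#' @param val_interval steps between validation evaluations.
#' @param patience validation checks without improvement before stopping
#'   early; `Inf` disables early stopping.
#' @param val_max_patches cap on validation patches scored per check.
#' @return an object of class `train_config`.
#' @export
train_config <- function(minibatch = 54L, max_steps = 1500L, lr = 1e-4,
                         loss = c("ssim_l1", "l1"), alpha = 0.84, seed = 1L,
                         val_interval = 50L, patience = Inf,
                         val_max_patches = 108L) {
  loss <- match.arg(loss)
  stopifnot(minibatch >= 1L, max_steps >= 1L, lr > 0, alpha >= 0, alpha <= 1)
  structure(list(minibatch = as.integer(minibatch),
                 max_steps = as.integer(max_steps), lr = lr, loss = loss,
                 alpha = alpha, seed = as.integer(seed),
                 val_interval = as.integer(val_interval), patience = patience,
                 val_max_patches = as.integer(val_max_patches),
                 optimizer = "adam", beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
            class = "train_config")
}

#' Train a super-resolution model on patch pairs
#'
#' Stochastic patch-based training: minibatches are drawn from a per-epoch
#' shuffle of the training patches (sampling with replacement only if there
#' are fewer patches than the minibatch size) and optimized with Adam.
#' Validation loss is evaluated every `val_interval` steps and the
#' best-on-validation parameters are returned, which guards against
#' overfitting. Deterministic given the seeds.
#'
#' @param model an untrained or trained `sr_model` (training continues from
#'   its current parameters).
#' @param train_patches,val_patches [extract_patches()] results (LR input,
#'   HR target).
#' @param config a [train_config()].
#' @return the trained `sr_model`; `$history` holds per-step training loss
#'   and periodic validation loss.
#' @export
train_sr <- function(model, train_patches, val_patches, config = train_config()) {
  stopifnot(inherits(model, "sr_model"), inherits(train_patches, "patch_set"),
            inherits(val_patches, "patch_set"), inherits(config, "train_config"))
  ntr <- dim(train_patches$lr)[3]
  nva <- dim(val_patches$lr)[3]
  if (ntr == 0L || nva == 0L) stop("empty patch set")
  sp <- ssim_params()
  params <- model$params
  mstate <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  vstate <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  nva_use <- min(nva, config$val_max_patches)
  val_x <- val_patches$lr[, , seq_len(nva_use), drop = FALSE]
  val_y <- val_patches$hr[, , seq_len(nva_use), drop = FALSE]
  val_loss_of <- function(par) {
    pred <- cpp_cnn_forward(model$arch, par, val_x, FALSE)$pred
    if (config$loss == "l1") loss_l1(pred, val_y)
    else loss_ssim_l1(pred, val_y, config$alpha, sp)
  }
  hist_step <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  best_val <- Inf; best_params <- params; bad_checks <- 0
  with_seed(config$seed, {
    order_pool <- integer(0)
    t_adam <- 0
    for (step in seq_len(config$max_steps)) {
      if (ntr < config$minibatch) {
        take <- sample.int(ntr, config$minibatch, replace = TRUE)
      } else {
        if (length(order_pool) < config$minibatch)
          order_pool <- c(order_pool, sample.int(ntr))
        take <- order_pool[seq_len(config$minibatch)]
        order_pool <- order_pool[-seq_len(config$minibatch)]
      }
      x <- train_patches$lr[, , take, drop = FALSE]
      y <- train_patches$hr[, , take, drop = FALSE]
      fw <- cpp_cnn_forward(model$arch, params, x, TRUE)
      lg <- loss_with_grad(fw$pred, y, config$loss, config$alpha, sp)
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged (non-finite loss) at step %d", step))
      grads <- cpp_cnn_backward(model$arch, params, fw$cache, lg$grad)
      t_adam <- t_adam + 1
      bc1 <- 1 - config$beta1^t_adam; bc2 <- 1 - config$beta2^t_adam
      for (j in seq_along(params)) {
        for (f in c("W", "b")) {
          g <- grads[[j]][[f]]
          mstate[[j]][[f]] <- config$beta1 * mstate[[j]][[f]] + (1 - config$beta1) * g
          vstate[[j]][[f]] <- config$beta2 * vstate[[j]][[f]] + (1 - config$beta2) * g^2
          params[[j]][[f]] <- params[[j]][[f]] -
            config$lr * (mstate[[j]][[f]] / bc1) /
            (sqrt(vstate[[j]][[f]] / bc2) + config$eps)
        }
      }
      hist_step <- c(hist_step, step)
      hist_train <- c(hist_train, lg$loss)
      if (step %% config$val_interval == 0L || step == config$max_steps) {
        vl <- val_loss_of(params)
        hist_val <- c(hist_val, vl)
        if (vl < best_val) {
          best_val <- vl; best_params <- params; bad_checks <- 0
        } else {
          bad_checks <- bad_checks + 1
          if (bad_checks >= config$patience) break
        }
      } else {
        hist_val <- c(hist_val, NA_real_)
      }
    }
  })
  model$params <- best_params
  model$trained <- TRUE
  model$config <- config
  model$history <- data.frame(step = hist_step, train_loss = hist_train,
                              val_loss = hist_val)
  model$best_val_loss <- best_val
  model
}

#' Full-frame inference
#'
#' The networks are fully convolutional, so test frames are processed full
#' size in a single pass — no patching at inference time. The FoV mask of
#' the input is propagated; out-of-FoV pixels are zeroed.
#'
#' @param object an `sr_model`.
#' @param image a [cartesian_image()] or numeric matrix; each dimension
#'   must be at least the model's [receptive_field()].
#' @param ... unused.
#' @return a [cartesian_image()] of the same size.
#' @export
predict.sr_model <- function(object, image, ...) {
  img <- as_image(image)
  rf <- receptive_field(object)
  if (min(dim(img$pixels)) < rf)
    stop(sprintf("image smaller than the receptive field (%d px)", rf))
  x <- array(img$pixels, c(dim(img$pixels), 1L))
  pred <- cpp_cnn_forward(object$arch, object$params, x, FALSE)$pred[, , 1]
  pred[!img$fov_mask] <- 0
  cartesian_image(pred, img$fov_mask,
                  c(img$meta, list(sr_family = object$spec$family)))
}

#' @rdname predict.sr_model
#' @param model an `sr_model`.
#' @param lr the low-resolution input image.
#' @export
infer <- function(model, lr) predict(model, lr)
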