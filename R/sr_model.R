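#' Super-resolution model specification
#'
#' Desk-scale fully-convolutional enhancement networks at scale factor 1
#' (LR and HR share one pixel grid, so no upsampling stage is needed):
#'
#' * `fsrcnn_like`: feature extraction (5x5, `width` channels), channel
#'   shrinking (1x1 to `shrink`), `depth` 3x3 mapping layers, expansion
#'   (1x1 back to `width`) and a 9x9 stride-1 reconstruction layer — the
#'   sparse-coding-style design with the deconvolution replaced by a
#'   stride-1 convolution.
#' * `edsr_like`: a 3x3 head, `depth` residual blocks (conv-ReLU-conv with
#'   identity skip, no batch normalization), and a 3x3 tail whose weights
#'   are zero-initialized, plus a global input skip — so a freshly built
#'   network is exactly the identity.
#'
#' @param family `"fsrcnn_like"` or `"edsr_like"`.
#' @param width feature channels (default 56 for fsrcnn, 32 for edsr).
#' @param depth mapping layers (fsrcnn) or residual blocks (edsr).
#' @param shrink shrunk channel count for `fsrcnn_like` (default 12).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("fsrcnn_like", "edsr_like"),
                       width = NULL, depth = NULL, shrink = 12L) {
  family <- match.arg(family)
  if (family == "fsrcnn_like") {
    width <- if (is.null(width)) 56L else as.integer(width)
    depth <- if (is.null(depth)) 4L else as.integer(depth)
  } else {
    width <- if (is.null(width)) 32L else as.integer(width)
    depth <- if (is.null(depth)) 4L else as.integer(depth)
  }
  stopifnot(width >= 1L, depth >= 0L, shrink >= 1L)
  structure(list(family = family, width = width, depth = depth,
                 shrink = as.integer(shrink), scale = 1L),
            class = "model_spec")
}

# layer list consumed by the C++ engine
build_arch <- function(spec) {
  conv <- function(k, cin, cout, act = "linear", add_input_of = 0L)
    list(k = as.integer(k), cin = as.integer(cin), cout = as.integer(cout),
         act = act, add_input_of = as.integer(add_input_of))
  if (spec$family == "fsrcnn_like") {
    layers <- c(list(conv(5, 1, spec$width, "relu"),
                     conv(1, spec$width, spec$shrink, "relu")),
                rep(list(conv(3, spec$shrink, spec$shrink, "relu")), spec$depth),
                list(conv(1, spec$shrink, spec$width, "relu"),
                     conv(9, spec$width, 1, "linear")))
    list(layers = layers, global_skip = FALSE)
  } else {
    layers <- list(conv(3, 1, spec$width, "linear"))
    for (b in seq_len(spec$depth)) {
      i <- length(layers) + 1L
      layers[[i]] <- conv(3, spec$width, spec$width, "relu")
      layers[[i + 1L]] <- conv(3, spec$width, spec$width, "linear",
                               add_input_of = i)
    }
    layers[[length(layers) + 1L]] <- conv(3, spec$width, 1, "linear")
    list(layers = layers, global_skip = TRUE)
  }
}

#' Build and initialize a model
#'
#' He-normal weight initialization (fan-in), zero biases; the `edsr_like`
#' tail convolution is zero-initialized so the network starts as the exact
#' identity map, which stabilizes early training of the residual.
#' Deterministic for a fixed seed.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return an object of class `sr_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  arch <- build_arch(spec)
  nl <- length(arch$layers)
  params <- with_seed(seed, lapply(seq_len(nl), function(j) {
    l <- arch$layers[[j]]
    fan_in <- l$k^2 * l$cin
    sdv <- sqrt(2 / fan_in)
    W <- array(rnorm(l$k^2 * l$cin * l$cout, 0, sdv),
               c(l$k, l$k, l$cin, l$cout))
    if (spec$family == "edsr_like" && j == nl) W[] <- 0
    list(W = W, b = numeric(l$cout))
  }))
  structure(list(spec = spec, arch = arch, params = params,
                 trained = FALSE, history = NULL, seed = as.integer(seed)),
            class = "sr_model")
}

#' Number of trainable parameters
#' @param model an `sr_model` or [model_spec()].
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  arch <- if (inherits(model, "sr_model")) model$arch
          else build_arch(model)
  as.integer(sum(vapply(arch$layers, function(l) l$k^2 * l$cin * l$cout + l$cout, 0)))
}

#' Receptive field side length of a model
#' @param model an `sr_model` or [model_spec()].
#' @return integer; inputs must be at least this large in each dimension.
#' @export
receptive_field <- function(model) {
  arch <- if (inherits(model, "sr_model")) model$arch else build_arch(model)
  1L + sum(vapply(arch$layers, function(l) l$k - 1L, 0L))
}

#' @export
print.sr_model <- function(x, ...) {
  cat(sprintf("<sr_model> %s width %d depth %d, %d parameters%s\n",
              x$spec$family, x$spec$width, x$spec$depth, n_parameters(x),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds the spec as JSON, the flattened weights as
#' a plain-text numeric file, and (if present) the training history as CSV.
#'
#' @param model an `sr_model`.
#' @param dir checkpoint directory.
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "sr_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(model$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- unlist(lapply(model$params, function(p) c(as.numeric(p$W), p$b)))
  writeLines(format(flat, digits = 17, scientific = TRUE, trim = TRUE),
             file.path(dir, "weights.txt"))
  if (!is.null(model$history))
    write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  sp <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- model_spec(sp$family, sp$width, sp$depth, sp$shrink)
  model <- build_model(spec, seed = 1L)
  flat <- as.numeric(readLines(file.path(dir, "weights.txt")))
  at <- 0L
  for (j in seq_along(model$params)) {
    nw <- length(model$params[[j]]$W); nb <- length(model$params[[j]]$b)
    model$params[[j]]$W[] <- flat[at + seq_len(nw)]
    model$params[[j]]$b <- flat[at + nw + seq_len(nb)]
    at <- at + nw + nb
  }
  hist_file <- file.path(dir, "history.csv")
  if (file.exists(hist_file)) {
    model$history <- utils::read.csv(hist_file)
    model$trained <- TRUE
  }
  model
}
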