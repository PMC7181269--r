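#' Specification of the patch-level convolutional classifier
#'
#' The architecture is a stack of eight unpadded 3x3 convolutions (each
#' shrinking the spatial side by 2) with ReLU activations and dropout,
#' followed by global average pooling, one ReLU dense layer, a 2-unit
#' logits layer and a softmax. At full scale the convolutional widths are
#' 256, 256, 512, 512, 1024, 1024, 1024, 1024 and the dense layer has 256
#' units. `scale` multiplies every width (spatial arithmetic is
#' unaffected), so the same depth can be trained at desk scale: the 0.0625
#' default for synthetic experiments gives widths 16, 16, 32, 32, 64, 64,
#' 64, 64 and a 16-unit dense layer.
#'
#' Note an arithmetic subtlety of the full-scale design: the eight
#' unpadded convolutions take an 87-pixel side down to 71 before pooling
#' (successive conv inputs 87, 85, ..., 73), and the pooling here is true
#' global averaging over all remaining positions.
#'
#' @param input_side Patch side in pixels (>= 17 so eight unpadded 3x3
#'   convolutions fit).
#' @param input_bands Spectral channels of the input patch (275 for
#'   reduced hyperspectral cubes, 3 for the RGB baseline — the two
#'   variants differ in nothing else).
#' @param scale Multiplier on channel widths; scaled widths round to >= 1.
#' @param dropout_rate Dropout probability after every convolution and the
#'   first dense layer.
#' @return A `model_spec` object.
#' @export
model_spec <- function(input_side = 87L, input_bands = 275L, scale = 1,
                       dropout_rate = 0.10) {
  input_side <- as.integer(input_side)
  if (input_side < 17L) {
    abort("`input_side` must be at least 17: eight unpadded 3x3 convolutions remove 16 pixels.")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) abort("`dropout_rate` must lie in [0, 1).")
  widths_full <- c(256L, 256L, 512L, 512L, 1024L, 1024L, 1024L, 1024L)
  widths <- pmax(1L, as.integer(round(widths_full * scale)))
  dense <- pmax(1L, as.integer(round(256L * scale)))
  structure(list(input_side = input_side, input_bands = as.integer(input_bands),
                 conv_widths = widths, dense_units = dense, classes = 2L,
                 dropout_rate = dropout_rate, scale = scale),
            class = "model_spec")
}

#' Layer-by-layer shape table of the classifier
#'
#' @param spec A [model_spec()].
#' @return Tibble with one row per layer: `layer`, `kernel`, input
#'   dimensions (`input_lines`, `input_samples`, `input_channels`) and a
#'   formatted `input_size` string.
#' @export
layer_shapes <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  sides <- spec$input_side - 2L * (0:8)
  ch_in <- c(spec$input_bands, spec$conv_widths)
  rows <- list()
  for (k in 1:8) {
    rows[[k]] <- tibble(layer = sprintf("Conv2D_%d", k), kernel = "3 x 3",
                        input_lines = sides[k], input_samples = sides[k],
                        input_channels = ch_in[k])
  }
  rows[[9]] <- tibble(layer = "GlobalAvgPool", kernel = "global",
                      input_lines = sides[9], input_samples = sides[9],
                      input_channels = ch_in[9])
  rows[[10]] <- tibble(layer = "Dense", kernel = sprintf("%d neurons", spec$dense_units),
                       input_lines = 1L, input_samples = 1L,
                       input_channels = spec$conv_widths[8])
  rows[[11]] <- tibble(layer = "Dense_logits", kernel = "logits",
                       input_lines = 1L, input_samples = 1L,
                       input_channels = spec$dense_units)
  rows[[12]] <- tibble(layer = "Softmax", kernel = "classifier",
                       input_lines = 1L, input_samples = 1L,
                       input_channels = spec$classes)
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, input_size = sprintf("%d x %d x %d", .data$input_lines,
                                          .data$input_samples, .data$input_channels))
}

#' Construct the classifier
#'
#' Convolution and first-dense weights are He-initialized under
#' `init_seed`; the final logits layer starts at zero, so an untrained
#' model outputs probability 0.5 for every patch. [train_cnn()]
#' re-initializes from its own config seed for fully reproducible runs.
#'
#' @param spec A [model_spec()].
#' @param init_seed Seed for the weight initialization.
#' @return An `hsi_cnn` model object (spec, parameters, input
#'   normalization slot, training history slot).
#' @export
build_cnn <- function(spec, init_seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  params <- withr::with_seed(split_seed(init_seed, 11L), init_params(spec))
  structure(list(spec = spec, params = params, norm = NULL,
                 history = NULL, config = NULL),
            class = "hsi_cnn")
}

#' @export
print.hsi_cnn <- function(x, ...) {
  cat(sprintf("<hsi_cnn> input %d x %d x %d | conv widths %s | dense %d | %s\n",
              x$spec$input_side, x$spec$input_side, x$spec$input_bands,
              paste(x$spec$conv_widths, collapse = ","), x$spec$dense_units,
              if (is.null(x$history)) "untrained" else
                sprintf("trained (best val AUC %.3f)", max(x$history$val_auc))))
  invisible(x)
}

# `logits = "zero"` (the build_cnn default) makes an untrained model output
# exactly 0.5; training re-initializes with small random logits so gradients
# reach every layer from the first step.
init_params <- function(spec, logits = c("zero", "he")) {
  logits <- match.arg(logits)
  ch_in <- c(spec$input_bands, spec$conv_widths)
  conv <- vector("list", 8L)
  for (k in 1:8) {
    fan_in <- 9L * ch_in[k]
    conv[[k]] <- list(W = matrix(rnorm(fan_in * ch_in[k + 1], 0, sqrt(2 / fan_in)),
                                 fan_in, ch_in[k + 1]),
                      b = numeric(ch_in[k + 1]))
  }
  c8 <- spec$conv_widths[8]
  d <- spec$dense_units
  W2 <- if (logits == "zero") matrix(0, d, spec$classes) else
    matrix(rnorm(d * spec$classes, 0, sqrt(2 / d)), d, spec$classes)
  list(conv = conv,
       W1 = matrix(rnorm(c8 * d, 0, sqrt(2 / c8)), c8, d),
       b1 = numeric(d),
       W2 = W2,
       b2 = numeric(spec$classes))
}

# --- im2col machinery -------------------------------------------------------

# Index map cache for the 3x3 valid-convolution gather, keyed by input side.
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(s) {
  key <- as.character(s)
  entry <- .im2col_cache[[key]]
  if (is.null(entry)) {
    t <- s - 2L
    base <- as.vector(outer(seq_len(t), (seq_len(t) - 1L) * s, `+`))  # t^2 positions
    offs <- as.vector(outer(0:2, (0:2) * s, `+`))                     # 9 kernel taps
    idx <- outer(base, offs, `+`)                                     # t^2 x 9
    entry <- list(t2 = t * t, vec = as.vector(idx))
    .im2col_cache[[key]] <- entry
  }
  entry
}

# Gather an s^2 x C activation matrix into the (s-2)^2 x 9C patch matrix
# whose GEMM with a (9C x K) kernel matrix performs the convolution.
im2col <- function(xmat, s) {
  e <- im2col_index(s)
  xcol <- xmat[e$vec, , drop = FALSE]
  dim(xcol) <- c(e$t2, 9L * ncol(xmat))
  xcol
}

# Scatter-add transpose of im2col: (s-2)^2 x 9C gradient back to s^2 x C.
col2im <- function(dxcol, s, channels) {
  e <- im2col_index(s)
  dim(dxcol) <- c(e$t2 * 9L, channels)
  rowsum(dxcol, group = e$vec, reorder = TRUE)
}

# --- forward / backward -----------------------------------------------------

# Forward pass over one normalized patch given as an s^2 x C matrix.
# Returns softmax probabilities and, when training, the caches needed by
# cnn_backward. Dropout draws come from the active RNG stream.
cnn_forward <- function(params, spec, xmat, training = FALSE) {
  rate <- if (training) spec$dropout_rate else 0
  s <- spec$input_side
  caches <- if (training) vector("list", 8L) else NULL
  a <- xmat
  for (k in 1:8) {
    xcol <- im2col(a, s)
    z <- xcol %*% params$conv[[k]]$W
    z <- z + rep(params$conv[[k]]$b, each = nrow(z))
    relu <- z > 0
    z[!relu] <- 0
    mask <- NULL
    if (rate > 0) {
      mask <- (runif(length(z)) >= rate) / (1 - rate)
      dim(mask) <- dim(z)
      z <- z * mask
    }
    if (training) caches[[k]] <- list(input = a, relu = relu, mask = mask)
    a <- z
    s <- s - 2L
  }
  pooled <- colMeans(a)                      # global average pooling
  z1 <- as.vector(pooled %*% params$W1) + params$b1
  relu1 <- z1 > 0
  a1 <- ifelse(relu1, z1, 0)
  mask1 <- NULL
  if (rate > 0) {
    mask1 <- (runif(length(a1)) >= rate) / (1 - rate)
    a1 <- a1 * mask1
  }
  logits <- as.vector(a1 %*% params$W2) + params$b2
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  if (!training) return(list(probs = probs))
  list(probs = probs,
       caches = caches, pool_input = a, pooled = pooled,
       relu1 = relu1, a1 = a1, mask1 = mask1)
}

# Backward pass for one patch; `y` is the true class index (1 = non_tumor,
# 2 = tumor). Returns gradients in the same structure as the parameters.
cnn_backward <- function(params, spec, fwd, y) {
  dlogits <- fwd$probs
  dlogits[y] <- dlogits[y] - 1

  grads <- list(conv = vector("list", 8L))
  grads$W2 <- outer(fwd$a1, dlogits)
  grads$b2 <- dlogits
  da1 <- as.vector(params$W2 %*% dlogits)
  if (!is.null(fwd$mask1)) da1 <- da1 * fwd$mask1
  da1[!fwd$relu1] <- 0
  grads$W1 <- outer(fwd$pooled, da1)
  grads$b1 <- da1
  dpool <- as.vector(params$W1 %*% da1)

  t2 <- nrow(fwd$pool_input)
  da <- matrix(rep(dpool / t2, each = t2), t2, length(dpool))
  for (k in 8:1) {
    cache <- fwd$caches[[k]]
    s_in <- spec$input_side - 2L * (k - 1L)
    if (!is.null(cache$mask)) da <- da * cache$mask
    da[!cache$relu] <- 0
    xcol <- im2col(cache$input, s_in)
    grads$conv[[k]] <- list(W = crossprod(xcol, da), b = colSums(da))
    if (k > 1L) {
      dxcol <- tcrossprod(da, params$conv[[k]]$W)
      da <- col2im(dxcol, s_in, ncol(cache$input))
    }
  }
  grads
}

# Elementwise fold over the parameter tree.
param_map2 <- function(a, b, f) {
  out <- a
  for (k in 1:8) {
    out$conv[[k]]$W <- f(a$conv[[k]]$W, b$conv[[k]]$W)
    out$conv[[k]]$b <- f(a$conv[[k]]$b, b$conv[[k]]$b)
  }
  for (nm in c("W1", "b1", "W2", "b2")) out[[nm]] <- f(a[[nm]], b[[nm]])
  out
}

param_scale <- function(a, alpha) param_map2(a, a, function(x, y) x * alpha)

zero_like <- function(params) param_scale(params, 0)

# --- training ---------------------------------------------------------------

#' Training configuration
#'
#' Optimization follows stochastic gradient descent at learning rate 1e-3
#' with classical momentum, in its per-sample form by default
#' (`batch_size = 1`): desk-scale training sets are small, so update count
#' — not gradient quality — limits convergence. Epoch count, batch size
#' and the best-validation-AUC selection rule are package defaults
#' recorded here so every run is self-describing.
#'
#' @param learning_rate SGD learning rate.
#' @param momentum Classical momentum coefficient (0 disables it).
#' @param epochs Number of passes over the training set.
#' @param batch_size Patches per gradient update.
#' @param seed Integer seed controlling weight initialization, shuffling
#'   and dropout; identical configs reproduce runs exactly.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, momentum = 0.9, epochs = 10L,
                         batch_size = 1L, seed = 1L) {
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  structure(list(optimizer = "sgd", learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the patch classifier
#'
#' Re-initializes the model's weights from `config$seed`, standardizes
#' inputs per band with training-set statistics (stored in the model and
#' re-applied at prediction), and optimizes the softmax cross-entropy with
#' SGD. After each epoch the validation AUC is recorded; the returned model
#' carries the weights of the best-validation-AUC epoch and a `history`
#' tibble (`epoch`, `train_loss`, `val_auc`).
#'
#' @param model An `hsi_cnn` from [build_cnn()].
#' @param train,val `patch_set`s for training and validation; their
#'   patients must be disjoint (leakage check) and the training set must
#'   contain both classes.
#' @param config A [train_config()].
#' @param normalization Input standardization mode, stored in the model and
#'   re-applied at prediction. `"patch"` (default) standardizes every patch
#'   by its own per-band mean and standard deviation, which cancels
#'   patient- and slide-level staining intensity and forces the classifier
#'   onto spatial/compositional structure — the property that generalizes
#'   across patients. `"global"` standardizes with training-set per-band
#'   statistics instead.
#' @return The trained `hsi_cnn`.
#' @export
train_cnn <- function(model, train, val, config = train_config(),
                      normalization = c("patch", "global")) {
  normalization <- match.arg(normalization)
  normalization <- if (normalization == "global") {
    mu <- apply(train$tensors, 4L, mean)
    sigma <- apply(train$tensors, 4L, sd)
    sigma[sigma < 1e-8] <- 1
    list(type = "global", center = mu, scale = sigma)
  } else {
    list(type = "patch")
  }
  stopifnot(inherits(model, "hsi_cnn"), inherits(train, "patch_set"),
            inherits(val, "patch_set"), inherits(config, "train_config"))
  spec <- model$spec
  check_bands(train, spec)
  check_bands(val, spec)
  tr_info <- retained_info(train)
  va_info <- retained_info(val)
  overlap <- intersect(unique(tr_info$patient_id), unique(va_info$patient_id))
  if (length(overlap)) {
    abort(sprintf("Patient-level leakage: %s appear in both train and validation.",
                  paste(overlap, collapse = ", ")))
  }
  if (length(unique(tr_info$label)) < 2L) abort("Training set contains a single class.")

  y <- ifelse(tr_info$label == "tumor", 2L, 1L)
  yv <- ifelse(va_info$label == "tumor", 1L, 0L)
  n <- nrow(tr_info)

  model$norm <- normalization

  withr::with_seed(config$seed, {
    params <- init_params(spec, logits = "he")
    velocity <- zero_like(params)
    best <- list(auc = -Inf, params = params, epoch = 0L)
    history <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(n)
      done <- 0L
      while (done < n) {
        batch <- ord[seq.int(done + 1L, min(done + config$batch_size, n))]
        acc <- zero_like(params)
        for (i in batch) {
          xmat <- normalize_patch(train$tensors[tr_info$tensor_idx[i], , , ,
                                                drop = TRUE], model)
          fwd <- cnn_forward(params, spec, xmat, training = TRUE)
          losses[done + match(i, batch)] <- -log(max(fwd$probs[y[i]], 1e-12))
          acc <- param_map2(acc, cnn_backward(params, spec, fwd, y[i]),
                            function(a, g) a + g)
        }
        acc <- param_scale(acc, 1 / length(batch))
        velocity <- param_map2(
          param_scale(velocity, config$momentum),
          param_scale(acc, config$learning_rate),
          function(v, g) v - g)
        params <- param_map2(params, velocity, `+`)
        done <- done + length(batch)
      }

      model$params <- params
      pv <- predict_tensors(model, val$tensors, va_info$tensor_idx)
      val_auc <- roc_auc(pv, yv)
      history[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                                 val_auc = val_auc)
      if (!is.na(val_auc) && val_auc > best$auc) {
        best <- list(auc = val_auc, params = params, epoch = epoch)
      }
    }

    model$params <- if (is.finite(best$auc)) best$params else params
    model$history <- dplyr::bind_rows(history)
    model$config <- config
    model$best_epoch <- best$epoch
    model
  })
}

check_bands <- function(patches, spec) {
  if (patches$bands != spec$input_bands) {
    abort(sprintf("Band mismatch: model expects %d input bands, patches have %d.",
                  spec$input_bands, patches$bands))
  }
  if (patches$patch != spec$input_side) {
    abort(sprintf("Patch-size mismatch: model expects side %d, patches have %d.",
                  spec$input_side, patches$patch))
  }
  invisible(TRUE)
}

normalize_patch <- function(x, model) {
  ps <- dim(x)[1]
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  xmat <- x
  dim(xmat) <- c(ps * ps, dim(x)[3])
  norm <- model$norm
  if (is.null(norm)) return(xmat)
  if (identical(norm$type, "patch")) {
    mu <- colMeans(xmat)
    sigma <- sqrt(colMeans(xmat^2) - mu^2)
    sigma[!is.finite(sigma) | sigma < 1e-8] <- 1
    return(sweep(sweep(xmat, 2L, mu, `-`), 2L, sigma, `/`))
  }
  sweep(sweep(xmat, 2L, norm$center, `-`), 2L, norm$scale, `/`)
}

# Tumor probabilities for an n x s x s x B tensor array (inference mode:
# no dropout, fully deterministic).
predict_tensors <- function(model, tensors, idx = NULL) {
  idx <- idx %||% seq_len(dim(tensors)[1])
  vapply(idx, function(i) {
    xmat <- normalize_patch(tensors[i, , , , drop = TRUE], model)
    cnn_forward(model$params, model$spec, xmat, training = FALSE)$probs[2L]
  }, numeric(1))
}

#' Per-patch tumor probabilities
#'
#' Runs the classifier in inference mode (dropout disabled, so duplicated
#' patches receive identical probabilities) over every retained patch.
#'
#' @param model A (typically trained) `hsi_cnn`.
#' @param patches A `patch_set` whose band count and patch side match the
#'   model's input; a mismatch is an error naming both.
#' @return The retained-patch metadata tibble with columns `p_tumor` and
#'   `p_non_tumor` appended (each pair sums to 1 within 1e-6).
#' @export
predict_patches <- function(model, patches) {
  stopifnot(inherits(model, "hsi_cnn"), inherits(patches, "patch_set"))
  check_bands(patches, model$spec)
  info <- retained_info(patches)
  p <- predict_tensors(model, patches$tensors, info$tensor_idx)
  dplyr::mutate(info, p_tumor = p, p_non_tumor = 1 - p)
}

#' @method glance hsi_cnn
#' @export
glance.hsi_cnn <- function(x, ...) {
  tibble(
    input_side = x$spec$input_side, input_bands = x$spec$input_bands,
    scale = x$spec$scale, n_parameters = count_params(x$params),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_auc = if (is.null(x$history)) NA_real_ else max(x$history$val_auc, na.rm = TRUE))
}

#' @method tidy hsi_cnn
#' @export
tidy.hsi_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(), train_loss = numeric(), val_auc = numeric()))
  }
  x$history
}

count_params <- function(p) {
  sum(vapply(p$conv, function(l) length(l$W) + length(l$b), 0)) +
    length(p$W1) + length(p$b1) + length(p$W2) + length(p$b2)
}

#' Training-history plot
#' @param object A trained `hsi_cnn`.
#' @param ... Unused.
#' @return A ggplot of training loss and validation AUC per epoch.
#' @method autoplot hsi_cnn
#' @export
autoplot.hsi_cnn <- function(object, ...) {
  if (is.null(object$history)) abort("Model has no training history to plot.")
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_auc"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
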