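test_that("the full-scale layer-shape table reproduces the architecture's arithmetic", {
  spec <- model_spec(input_side = 87, input_bands = 275, scale = 1)
  tab <- layer_shapes(spec)

  # first convolution consumes the 87 x 87 x 275 patch and emits side 85
  expect_equal(tab$input_size[1], "87 x 87 x 275")
  expect_equal(tab$input_lines[2], 85)
  expect_equal(tab$input_channels[2], 256)

  # successive conv inputs: 87, 85, ..., 73, with widths 256,256,512,512,1024...
  conv <- tab[grepl("^Conv2D", tab$layer), ]
  expect_equal(conv$input_lines, seq(87, 73, by = -2))
  expect_equal(conv$input_channels, c(275, 256, 256, 512, 512, 1024, 1024, 1024))

  # global pooling sees the last conv's output; dense stack is 1024 -> 256 -> 2
  expect_equal(tab$input_channels[tab$layer == "GlobalAvgPool"], 1024)
  expect_equal(tab$input_channels[tab$layer == "Dense"], 1024)
  expect_equal(tab$kernel[tab$layer == "Dense"], "256 neurons")
  expect_equal(tab$input_channels[tab$layer == "Dense_logits"], 256)
  expect_equal(tab$input_channels[tab$layer == "Softmax"], 2)

  # spatial-side recurrence s_{k+1} = s_k - 2 at any scale
  tab_small <- layer_shapes(model_spec(input_side = 21, input_bands = 8, scale = 0.01))
  conv_small <- tab_small[grepl("^Conv2D", tab_small$layer), ]
  expect_equal(diff(conv_small$input_lines), rep(-2, 7))
})

test_that("width scaling touches channels only and input floors are enforced", {
  spec <- model_spec(input_side = 87, input_bands = 275, scale = 0.0625)
  expect_equal(spec$conv_widths, c(16, 16, 32, 32, 64, 64, 64, 64))
  expect_equal(spec$dense_units, 16)
  conv <- layer_shapes(spec)[1:8, ]
  expect_equal(conv$input_lines, seq(87, 73, by = -2))  # unchanged by scale
  expect_error(model_spec(input_side = 15), "at least 17")
  # HSI and RGB variants differ only in input bands
  a <- model_spec(input_bands = 275, scale = 0.0625)
  b <- model_spec(input_bands = 3, scale = 0.0625)
  expect_equal(a[setdiff(names(a), "input_bands")], b[setdiff(names(b), "input_bands")])
})

test_that("the im2col convolution equals a direct triple-loop convolution", {
  set.seed(31)
  s <- 9; cin <- 3; cout <- 4
  x <- array(rnorm(s * s * cin), c(s, s, cin))
  W <- matrix(rnorm(9 * cin * cout), 9 * cin, cout)
  b <- rnorm(cout)

  xmat <- x; dim(xmat) <- c(s * s, cin)
  fast <- hsipath:::im2col(xmat, s) %*% W
  fast <- fast + rep(b, each = nrow(fast))

  t <- s - 2
  naive <- array(0, c(t, t, cout))
  for (r in 1:t) for (cc in 1:t) for (co in 1:cout) {
    acc <- b[co]
    for (dr in 0:2) for (dc in 0:2) for (ci in 1:cin) {
      k <- dr + 3 * dc + 1
      acc <- acc + x[r + dr, cc + dc, ci] * W[k + 9 * (ci - 1), co]
    }
    naive[r, cc, co] <- acc
  }
  dim(naive) <- c(t * t, cout)
  expect_equal(unname(fast), unname(naive), tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients", {
  spec <- model_spec(input_side = 17, input_bands = 2, scale = 1 / 256,
                     dropout_rate = 0)
  params <- withr::with_seed(5, hsipath:::init_params(spec))
  # give the zero logits layer structure so gradients reach every layer
  params$W2 <- matrix(rnorm(length(params$W2), 0, 0.3), nrow(params$W2))
  x <- withr::with_seed(6, matrix(rnorm(17 * 17 * 2), 17 * 17, 2))
  y <- 2L

  loss_at <- function(p) {
    -log(hsipath:::cnn_forward(p, spec, x, training = FALSE)$probs[y])
  }
  fwd <- hsipath:::cnn_forward(params, spec, x, training = TRUE)
  grads <- hsipath:::cnn_backward(params, spec, fwd, y)

  eps <- 1e-5
  check <- function(get, set, gval, label) {
    p_plus <- set(params, get(params) + eps)
    p_minus <- set(params, get(params) - eps)
    num <- (loss_at(p_plus) - loss_at(p_minus)) / (2 * eps)
    expect_equal(gval, num, tolerance = 1e-4, label = label)
  }
  withr::with_seed(9, {
    for (k in c(1, 4, 8)) {
      ij <- c(sample(nrow(params$conv[[k]]$W), 1), sample(ncol(params$conv[[k]]$W), 1))
      check(function(p) p$conv[[k]]$W[ij[1], ij[2]],
            function(p, v) { p$conv[[k]]$W[ij[1], ij[2]] <- v; p },
            grads$conv[[k]]$W[ij[1], ij[2]], sprintf("conv%d W", k))
      bi <- sample(length(params$conv[[k]]$b), 1)
      check(function(p) p$conv[[k]]$b[bi],
            function(p, v) { p$conv[[k]]$b[bi] <- v; p },
            grads$conv[[k]]$b[bi], sprintf("conv%d b", k))
    }
    for (nm in c("W1", "b1", "W2", "b2")) {
      i <- sample(length(params[[nm]]), 1)
      check(function(p) p[[nm]][i],
            function(p, v) { p[[nm]][i] <- v; p },
            grads[[nm]][i], nm)
    }
  })
})

test_that("an untrained model is maximally uncertain and softmax is normalized", {
  ps <- tiny_patch_set(side = 17, bands_in = 24, per_class = 2, seed = 3)
  model <- build_cnn(model_spec(input_side = 17, input_bands = ps$bands,
                                scale = 1 / 64))
  pred <- predict_patches(model, ps)
  expect_true(all(pred$p_tumor == 0.5))  # zero-initialized logits layer
  expect_true(all(abs(pred$p_tumor + pred$p_non_tumor - 1) < 1e-6))
  expect_true(all(pred$p_tumor >= 0 & pred$p_tumor <= 1))
})

test_that("inference is deterministic: duplicated patches get identical probabilities", {
  ps <- tiny_patch_set(side = 17, bands_in = 24, per_class = 2, seed = 13)
  dup <- hsipath:::subset_patches(ps, c(1, 1, 2, 2))
  model <- build_cnn(model_spec(17, ps$bands, scale = 1 / 64), init_seed = 4)
  model$params$W2 <- matrix(rnorm(length(model$params$W2), 0, 0.5),
                            nrow(model$params$W2))
  pred <- predict_patches(model, dup)
  expect_identical(pred$p_tumor[1], pred$p_tumor[2])
  expect_identical(pred$p_tumor[3], pred$p_tumor[4])
})

test_that("band and patch-size mismatches are reported with expected/got", {
  ps <- tiny_patch_set(side = 17, bands_in = 24, per_class = 1, seed = 2)
  model <- build_cnn(model_spec(17, ps$bands + 1, scale = 1 / 64))
  expect_error(predict_patches(model, ps),
               sprintf("expects %d input bands, patches have %d", ps$bands + 1, ps$bands))
})

test_that("training is seed-reproducible and learns separable synthetic classes", {
  ps <- tiny_patch_set(side = 17, bands_in = 24, patients = c("PA", "PB", "PC"),
                       per_class = 4, seed = 21, noise_sd = 2)
  info <- hsipath:::retained_info(ps)
  train <- hsipath:::subset_patches(ps, which(info$patient_id %in% c("PA", "PB")))
  val <- hsipath:::subset_patches(ps, which(info$patient_id == "PC"))
  spec <- model_spec(17, ps$bands, scale = 0.0625)
  cfg <- train_config(epochs = 10, batch_size = 1, seed = 99)

  m1 <- train_cnn(build_cnn(spec), train, val, cfg, normalization = "global")
  m2 <- train_cnn(build_cnn(spec), train, val, cfg, normalization = "global")
  expect_identical(m1$history$train_loss[1], m2$history$train_loss[1])
  expect_identical(m1$history, m2$history)

  # separable classes: validation AUC reaches a high value quickly
  expect_gte(max(m1$history$val_auc), 0.95)
  expect_equal(nrow(m1$history), 10)
  expect_true(all(c("epoch", "train_loss", "val_auc") %in% names(tidy(m1))))
  expect_equal(glance(m1)$best_epoch, m1$best_epoch)
})

test_that("training refuses leaking patients and single-class training sets", {
  ps <- tiny_patch_set(side = 17, bands_in = 24, per_class = 2, seed = 33)
  info <- hsipath:::retained_info(ps)
  pa <- hsipath:::subset_patches(ps, which(info$patient_id == "PA"))
  spec <- model_spec(17, ps$bands, scale = 1 / 64)
  expect_error(train_cnn(build_cnn(spec), pa, pa, train_config(epochs = 1)),
               "leakage")
  tumor_only <- hsipath:::subset_patches(
    ps, which(info$patient_id == "PA" & info$label == "tumor"))
  pb <- hsipath:::subset_patches(ps, which(info$patient_id == "PB"))
  expect_error(train_cnn(build_cnn(spec), tumor_only, pb, train_config(epochs = 1)),
               "single class")
})
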