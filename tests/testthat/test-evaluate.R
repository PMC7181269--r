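test_that("confusion counts tally correctly, ties predicted positive", {
  cc <- confusion_counts(c(0.9, 0.2), c("tumor", "non_tumor"))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L), ignore_attr = TRUE)

  # threshold is inclusive: p = 0.5 predicts tumor
  cc <- confusion_counts(rep(0.5, 7), rep("tumor", 7))
  expect_equal(cc$TP, 7); expect_equal(cc$FN, 0)

  # brute-force oracle on a random instance
  withr::with_seed(8, {
    p <- runif(200); y <- sample(c("tumor", "non_tumor"), 200, replace = TRUE)
  })
  cc <- confusion_counts(p, y, threshold = 0.5)
  brute <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:200) {
    pred <- p[i] >= 0.5; truth <- y[i] == "tumor"
    brute[if (pred && truth) "TP" else if (pred) "FP"
          else if (truth) "FN" else "TN"] <-
      brute[if (pred && truth) "TP" else if (pred) "FP"
            else if (truth) "FN" else "TN"] + 1
  }
  expect_equal(unlist(unclass(cc))[names(brute)], brute, ignore_attr = TRUE)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 200)
  expect_error(confusion_counts(numeric(), character()), "empty")
})

test_that("metrics follow their defining ratios with NA for empty denominators", {
  m <- classification_metrics(structure(list(TP = 9, FN = 1, TN = 8, FP = 2),
                                        class = "confusion_counts"))
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$accuracy, 0.85)

  # no tumor patches at all: sensitivity undefined
  m <- classification_metrics(structure(list(TP = 0, FN = 0, TN = 5, FP = 1),
                                        class = "confusion_counts"))
  expect_true(is.na(m$sensitivity)); expect_equal(m$specificity, 5 / 6)

  # tumor-only test set: specificity undefined
  m <- classification_metrics(structure(list(TP = 4, FN = 2, TN = 0, FP = 0),
                                        class = "confusion_counts"))
  expect_true(is.na(m$specificity)); expect_equal(m$sensitivity, 4 / 6)
})

test_that("accuracy decomposes exactly into the class-weighted sensitivity/specificity", {
  withr::with_seed(3, {
    for (i in 1:20) {
      cc <- structure(as.list(stats::setNames(sample(1:40, 4, TRUE),
                                              c("TP", "FP", "TN", "FN"))),
                      class = "confusion_counts")
      m <- classification_metrics(cc)
      P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
      expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
    }
  })
})

test_that("roc_auc equals the exhaustive pairwise tie-corrected count", {
  pair_auc <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(5:30, 1)
      y <- c(0, 1, sample(0:1, n - 2, TRUE))     # both classes guaranteed
      p <- round(runif(n), sample(c(1, 2, 7), 1))  # coarse rounding forces ties
      expect_equal(roc_auc(p, y), pair_auc(p, y), tolerance = 1e-12)
    }
  })
})

test_that("roc_auc edge cases and invariances hold", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)   # inverted labels
  expect_true(is.na(roc_auc(runif(5), rep(1, 5))))

  # invariance under strictly monotone transforms
  withr::with_seed(4, {
    p <- runif(50); y <- sample(0:1, 50, TRUE); y[1:2] <- 0:1
    base <- roc_auc(p, y)
    expect_equal(roc_auc(log(p + 1), y), base)
    expect_equal(roc_auc(p^3, y), base)
    expect_equal(roc_auc(qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)), y), base)
  })
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    p <- runif(80); y <- sample(0:1, 80, TRUE); y[1:2] <- 0:1
  })
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(p, y), ref, tolerance = 1e-12)
})

test_that("per-patient evaluation marks undefined columns NA and applies exclusions", {
  preds <- tibble::tibble(
    patient_id = rep(c("P1", "P9"), each = 4),
    roi_id = rep(c("N1", "T1", "T1", "T1"), 2),
    label = rep(c("non_tumor", "tumor", "tumor", "tumor"), 2),
    p_tumor = c(0.1, 0.8, 0.9, 0.4,   # P1: both classes
                0.2, 0.9, 0.7, 0.6))  # P9 rows: first roi will be excluded
  preds$label[5] <- "tumor"; preds$roi_id[5] <- "T0"  # P9 tumor-only
  rep1 <- evaluate_patients(preds)
  expect_equal(nrow(rep1), 2)
  p1 <- rep1[rep1$patient_id == "P1", ]
  expect_false(is.na(p1$specificity))
  p9 <- rep1[rep1$patient_id == "P9", ]
  expect_true(is.na(p9$specificity)); expect_true(is.na(p9$auc))
  expect_false(is.na(p9$sensitivity))

  # excluding P9's defective cube drops its patches without touching P1
  man <- tibble::tibble(
    patient_id = c("P1", "P1", "P9", "P9"),
    roi_id = c("N1", "T1", "T0", "T1"),
    cube_path = "x", reference_path = "r",
    label = c("non_tumor", "tumor", "tumor", "tumor"),
    excluded = c(FALSE, FALSE, TRUE, FALSE),
    exclusion_reason = c("none", "none", "ink", "none"))
  rep2 <- evaluate_patients(preds, manifest = validate_manifest(man))
  expect_equal(rep2$n_patches[rep2$patient_id == "P9"], 3)
  expect_equal(rep2$n_patches[rep2$patient_id == "P1"], 4)
})

test_that("aggregation reproduces the worked per-patient table examples", {
  # 13-patient accuracy column whose per-patient mean prints as 80
  acc <- c(92, 77, 85, 57, 69, 37, 59, 96, 99, 89, 92, 92, 99)
  agg <- aggregate_metrics(tibble::tibble(accuracy = acc))
  expect_equal(agg$display_mean[agg$metric == "accuracy"], 80)

  # 7-patient specificity column whose mean prints as 77
  spc <- c(96, 83, 80, 58, 64, 63, 96)
  agg <- aggregate_metrics(tibble::tibble(specificity = spc))
  expect_equal(agg$display_mean[agg$metric == "specificity"], 77)

  # single row: mean is the row, sd 0 by convention
  agg <- aggregate_metrics(tibble::tibble(accuracy = 91))
  expect_equal(agg$mean, 91); expect_equal(agg$sd, 0)

  # an all-NA column aggregates to NA, not an error
  agg <- aggregate_metrics(tibble::tibble(auc = NA_real_))
  expect_true(is.na(agg$mean))
})

test_that("display rounding is half-away-from-zero, applied after averaging", {
  expect_equal(hsipath:::round_half_up(76.5), 77)
  expect_equal(hsipath:::round_half_up(77.5), 78)   # base round() would give 78 anyway; 76.5 is the test
  expect_equal(hsipath:::round_half_up(-0.5), -1)
  expect_equal(hsipath:::round_half_up(0.755, 2), 0.76)
  agg <- aggregate_metrics(tibble::tibble(auc = c(0.75, 0.76)))
  expect_equal(agg$display_mean, 0.76)  # mean 0.755 rounds up, not to even
})
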