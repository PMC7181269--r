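test_that("Beer-Lambert transmittance obeys its algebraic identities", {
  m <- stain_model(default_wavelengths(40))
  wl <- m$wavelengths_nm
  # zero concentration transmits everything
  expect_equal(stain_transmittance(wl, c(hematoxylin = 0, eosin = 0), m),
               rep(1, length(wl)))
  # doubling one concentration squares its transmittance, element-wise
  t1 <- stain_transmittance(wl, c(hematoxylin = 0.7, eosin = 0), m)
  t2 <- stain_transmittance(wl, c(hematoxylin = 1.4, eosin = 0), m)
  expect_equal(t2, t1^2, tolerance = 1e-12)
  # concentrations compose multiplicatively across stains
  th <- stain_transmittance(wl, c(hematoxylin = 0.5, eosin = 0), m)
  te <- stain_transmittance(wl, c(hematoxylin = 0, eosin = 0.8), m)
  both <- stain_transmittance(wl, c(hematoxylin = 0.5, eosin = 0.8), m)
  expect_equal(both, th * te, tolerance = 1e-12)
  expect_true(all(both > 0 & both <= 1))
  expect_error(stain_transmittance(wl, c(hematoxylin = -0.1, eosin = 0), m),
               "non-negative")
})

test_that("a noiseless spectrum inverts to its concentration by log-linear least squares", {
  m <- stain_model(default_wavelengths(101))
  wl <- m$wavelengths_nm
  a <- hsipath:::stain_absorbance(wl, m$stains$hematoxylin)
  for (conc in c(0.3, 1.0, 2.7)) {
    tr <- stain_transmittance(wl, c(hematoxylin = conc, eosin = 0), m)
    chat <- sum(a * (-log(tr))) / sum(a * a)  # closed-form 1-D inversion
    expect_equal(chat, conc, tolerance = 1e-6)
  }
})

test_that("slide generation is bit-identical under a fixed seed", {
  m <- stain_model(default_wavelengths(15))
  spec <- scene_spec("tumor", lines = 50, samples = 60, seed = 11)
  a <- generate_slide(spec, m)
  b <- generate_slide(spec, m)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$reference$data, b$reference$data)
  expect_identical(a$nucleus_mask, b$nucleus_mask)
})

test_that("with no blank region and no noise every radiance/illumination ratio is in (0,1]", {
  m <- stain_model(default_wavelengths(20))
  spec <- scene_spec("non_tumor", lines = 40, samples = 50, blank_fraction = 0,
                     noise_sd = 0, seed = 5)
  sl <- generate_slide(spec, m, keep_scene = TRUE)
  # illumination per band recoverable from the noiseless reference
  illum <- colMeans(sl$reference$data, dims = 2L)
  ratio <- sweep(sl$cube$data, 3L, illum, `/`)
  expect_true(all(ratio > 0 & ratio <= 1 + 1e-12))
})

test_that("tumor scenes carry denser nuclear coverage than non-tumor scenes", {
  m <- stain_model(default_wavelengths(5))
  wins <- 0L
  n_trials <- 50L
  for (i in seq_len(n_trials)) {
    tu <- generate_slide(scene_spec("tumor", lines = 80, samples = 80,
                                    blank_fraction = 0, seed = 1000 + i), m)
    nt <- generate_slide(scene_spec("non_tumor", lines = 80, samples = 80,
                                    blank_fraction = 0, seed = 5000 + i), m)
    wins <- wins + (mean(tu$nucleus_mask) > mean(nt$nucleus_mask))
  }
  expect_gte(wins / n_trials, 0.95)
})

test_that("nucleus and blank pixels are linearly separable at zero noise", {
  m <- stain_model(default_wavelengths(25))
  sl <- generate_slide(scene_spec("tumor", lines = 60, samples = 80,
                                  blank_fraction = 0.3, noise_sd = 0, seed = 2), m)
  tc <- flat_field_correct(sl$cube, sl$reference)
  flat <- matrix(tc$data, ncol = dim(tc$data)[3])
  is_nuc <- as.vector(sl$nucleus_mask)
  is_blank <- as.vector(sl$blank_mask)
  # nearest-centroid discriminant along the class-mean difference direction
  w <- colMeans(flat[is_nuc, , drop = FALSE]) - colMeans(flat[is_blank, , drop = FALSE])
  proj <- flat %*% w
  cut <- (mean(proj[is_nuc]) + mean(proj[is_blank])) / 2
  pred_nuc <- proj > cut
  acc <- mean(c(pred_nuc[is_nuc], !pred_nuc[is_blank]))
  expect_equal(acc, 1)
})

test_that("per-patient stain factors put more spectral variance between than within patients", {
  n_pat <- 6; per_pat <- 3
  m <- stain_model(default_wavelengths(12))
  means <- matrix(0, n_pat * per_pat, 12)
  pat <- integer(n_pat * per_pat)
  k <- 0
  for (p in seq_len(n_pat)) {
    fx <- withr::with_seed(3000 + p, c(hematoxylin = exp(rnorm(1, 0, 0.2)),
                                       eosin = exp(rnorm(1, 0, 0.2))))
    for (r in seq_len(per_pat)) {
      k <- k + 1
      sl <- generate_slide(scene_spec("non_tumor", lines = 40, samples = 50,
                                      blank_fraction = 0, patient_effects = fx,
                                      seed = 100 * p + r), m)
      tc <- flat_field_correct(sl$cube, sl$reference)
      means[k, ] <- apply(tc$data, 3, mean)
      pat[k] <- p
    }
  }
  # variance decomposition on the first spectral principal axis
  v <- prcomp(means)$x[, 1]
  fit <- stats::aov(v ~ factor(pat))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  expect_gt(ms[1], ms[2])  # between-patient exceeds within-patient
})

test_that("cohort generation mirrors the campaign shape and is reproducible", {
  dir <- withr::local_tempdir()
  man <- generate_cohort(file.path(dir, "a"), n_patients = 5, tumor_only_patients = 2,
                         lines = 30, samples = 40, n_bands = 8, seed = 9)
  smry <- manifest_summary(man)
  expect_equal(sum(smry$classes == "tumor_only"), 2)
  expect_equal(sum(smry$classes == "both"), 3)
  expect_true(all(file.exists(file.path(dir, "a", man$cube_path))))
  expect_true(all(file.exists(file.path(dir, "a", man$reference_path))))

  man2 <- generate_cohort(file.path(dir, "b"), n_patients = 5, tumor_only_patients = 2,
                          lines = 30, samples = 40, n_bands = 8, seed = 9)
  sums_a <- tools::md5sum(list.files(file.path(dir, "a"), full.names = TRUE))
  sums_b <- tools::md5sum(list.files(file.path(dir, "b"), full.names = TRUE))
  expect_identical(unname(sums_a), unname(sums_b))

  # all-both-class cohorts have no single-class patient
  man3 <- generate_cohort(file.path(dir, "c"), n_patients = 4, tumor_only_patients = 0,
                          lines = 20, samples = 20, n_bands = 5, seed = 1)
  expect_true(all(manifest_summary(man3)$classes == "both"))
  expect_error(generate_cohort(file.path(dir, "d"), n_patients = 3), "4 patients")
})
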