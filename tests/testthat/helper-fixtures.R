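# Shared fixtures: everything is generated in code, nothing read from disk.

# A small random cube of any stage, for round-trip and invariant tests.
random_cube <- function(lines = 6, samples = 7, bands = 5, stage = "radiance",
                        label = "unknown", seed = 1) {
  withr::with_seed(seed, {
    vals <- switch(stage,
      radiance = array(runif(lines * samples * bands, 0, 900), c(lines, samples, bands)),
      array(runif(lines * samples * bands), c(lines, samples, bands)))
    hs_cube(vals, seq(420, 980, length.out = bands), stage = stage,
            patient_id = "P01", roi_id = "R1", label = label)
  })
}

# Manifest with the cohort shape of the study: n patients, the last k of
# which are tumor-only; one cube per ROI.
toy_manifest <- function(n_patients = 13, tumor_only = 5) {
  ids <- sprintf("P%02d", seq_len(n_patients))
  tonly <- ids[seq.int(n_patients - tumor_only + 1, length.out = tumor_only)]
  rows <- lapply(ids, function(p) {
    labs <- if (p %in% tonly) "tumor" else c("tumor", "non_tumor")
    tibble::tibble(
      patient_id = p, roi_id = paste0(ifelse(labs == "tumor", "T", "N"), "1"),
      cube_path = sprintf("%s_%s.raw", p, labs),
      reference_path = sprintf("%s_ref.raw", p),
      label = labs, excluded = FALSE, exclusion_reason = "none")
  })
  validate_manifest(dplyr::bind_rows(rows))
}

# A tiny trained-model-sized fixture: patches small enough that CNN unit
# tests run in seconds. Nuclear densities are raised so a 17-pixel patch
# still spans several (small) nuclei, preserving the "patch contains
# multiple cells" property the classifier relies on at realistic sizes.
tiny_patch_set <- function(side = 17, bands_in = 12, patients = c("PA", "PB"),
                           classes = c("tumor", "non_tumor"), per_class = 6,
                           seed = 7, noise_sd = 2, blank_fraction = 0) {
  model <- stain_model(default_wavelengths(bands_in))
  sets <- list()
  k <- 0
  for (p in patients) {
    for (cl in classes) {
      for (r in seq_len(per_class)) {
        k <- k + 1
        spec <- scene_spec(cl, lines = side, samples = side,
                           blank_fraction = blank_fraction,
                           nuclear_density = if (cl == "tumor") 300 else 100,
                           nucleus_radius_mean = 2.2,
                           nucleus_radius_sd = if (cl == "tumor") 0.8 else 0.4,
                           noise_sd = noise_sd, seed = seed + 100 * k)
        slide <- generate_slide(spec, model, patient_id = p,
                                roi_id = sprintf("%s%d", substr(cl, 1, 1), r))
        red <- reduce_bands(flat_field_correct(slide$cube, slide$reference))
        sets[[k]] <- extract_patches(red, rejection_rule(), patch = side)
      }
    }
  }
  bind_patch_sets(sets)
}
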