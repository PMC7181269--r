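#' Scene specification for a synthetic slide
#'
#' Describes one virtual field of view. The class-discriminating property is
#' spatial: tumor scenes carry a higher nuclear density and a larger nucleus
#' radius variance (a pleomorphism proxy) than non-tumor scenes, mirroring
#' the hypercellularity that a patch classifier exploits in real
#' glioblastoma slides. A vertical strip of pure illumination ("blank
#' light") at the right edge emulates specimen-free regions so that
#' blank-patch rejection has something to reject.
#'
#' @param class `"tumor"` or `"non_tumor"`.
#' @param lines,samples Spatial size in pixels.
#' @param nuclear_density Expected nuclei per 100x100 pixel area. Defaults:
#'   20 (tumor) / 8 (non-tumor).
#' @param nucleus_radius_mean Mean nucleus radius in pixels.
#' @param nucleus_radius_sd Radius standard deviation; defaults are larger
#'   for tumor (2.5 vs 1.2).
#' @param blank_fraction Fraction of image columns carrying blank light,
#'   in \[0, 1).
#' @param patient_effects Named multiplicative stain-concentration factors
#'   `c(hematoxylin=, eosin=)`, the per-patient staining-intensity handle.
#' @param noise_sd Additive white Gaussian noise sd, in radiance counts.
#' @param seed Integer seed; identical specs generate bit-identical slides.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(class = c("tumor", "non_tumor"),
                       lines = 800L, samples = 1004L,
                       nuclear_density = NULL,
                       nucleus_radius_mean = 6,
                       nucleus_radius_sd = NULL,
                       blank_fraction = 0.15,
                       patient_effects = c(hematoxylin = 1, eosin = 1),
                       noise_sd = 5,
                       seed = 1L) {
  class <- match.arg(class)
  nuclear_density <- nuclear_density %||% if (class == "tumor") 20 else 8
  nucleus_radius_sd <- nucleus_radius_sd %||% if (class == "tumor") 2.5 else 1.2
  if (blank_fraction < 0 || blank_fraction >= 1) abort("`blank_fraction` must lie in [0, 1).")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(list(class = class, lines = as.integer(lines), samples = as.integer(samples),
                 nuclear_density = nuclear_density,
                 nucleus_radius_mean = nucleus_radius_mean,
                 nucleus_radius_sd = nucleus_radius_sd,
                 blank_fraction = blank_fraction,
                 patient_effects = patient_effects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate one synthetic hyperspectral slide with its blank reference
#'
#' Nuclei are placed by a seeded Poisson point process and rasterized as
#' jittered ellipses; nucleus pixels are hematoxylin-dominant, the tissue
#' background is eosin-dominant, and blank columns carry the illumination
#' only. Radiance is illumination x Beer-Lambert transmittance plus white
#' Gaussian noise, clipped at zero. The paired reference cube images a blank
#' field under the same (per-slide jittered) illumination and noise level,
#' exactly what a flat-field correction needs.
#'
#' @param spec A [scene_spec()].
#' @param model A [stain_model()]; its wavelength grid sets the band count.
#' @param patient_id,roi_id Provenance written into the cubes.
#' @param reference_lines Number of scan lines in the blank reference cube
#'   (the correction averages over reference lines, so it need not match the
#'   slide height).
#' @param keep_scene If `TRUE`, also return the noise-free scene
#'   transmittance array (ground truth for testing the correction).
#' @return A list with elements `cube` (radiance [hs_cube()]), `reference`
#'   (radiance `hs_cube` over a blank field), `nucleus_mask` (logical
#'   lines x samples matrix), `blank_mask` (logical matrix marking
#'   illumination-only pixels) and, if requested, `scene_transmittance`.
#' @export
generate_slide <- function(spec, model = stain_model(),
                           patient_id = "P00", roi_id = "R1",
                           reference_lines = 64L, keep_scene = FALSE) {
  stopifnot(inherits(spec, "scene_spec"), inherits(model, "stain_model"))
  wl <- model$wavelengths_nm
  nl <- spec$lines; ns <- spec$samples; nb <- length(wl)

  withr::with_seed(spec$seed, {
    n_blank_cols <- round(spec$blank_fraction * ns)
    tissue_cols <- ns - n_blank_cols
    if (tissue_cols < 1) {
      warn("blank_fraction leaves no tissue columns; slide is pure light.")
      tissue_cols <- 0L
    }
    blank_mask <- matrix(FALSE, nl, ns)
    if (n_blank_cols > 0) blank_mask[, seq.int(tissue_cols + 1L, ns)] <- TRUE

    nucleus_mask <- matrix(FALSE, nl, ns)
    if (tissue_cols > 0) {
      n_nuclei <- rpois(1L, spec$nuclear_density * nl * tissue_cols / 1e4)
      if (n_nuclei > 0) {
        cy <- runif(n_nuclei, 1, nl)
        cx <- runif(n_nuclei, 1, tissue_cols)
        r <- pmax(1.5, rnorm(n_nuclei, spec$nucleus_radius_mean, spec$nucleus_radius_sd))
        ecc <- runif(n_nuclei, -0.3, 0.3)
        theta <- runif(n_nuclei, 0, pi)
        for (i in seq_len(n_nuclei)) {
          a <- r[i] * exp(ecc[i]); b <- r[i] * exp(-ecc[i])
          rmax <- max(a, b)
          ys <- max(1L, floor(cy[i] - rmax)):min(nl, ceiling(cy[i] + rmax))
          xs <- max(1L, floor(cx[i] - rmax)):min(tissue_cols, ceiling(cx[i] + rmax))
          if (!length(ys) || !length(xs)) next
          dy <- ys - cy[i]; dx <- xs - cx[i]
          DX <- matrix(dx, length(ys), length(xs), byrow = TRUE)
          DY <- matrix(dy, length(ys), length(xs))
          u <- (DX * cos(theta[i]) + DY * sin(theta[i])) / a
          v <- (-DX * sin(theta[i]) + DY * cos(theta[i])) / b
          nucleus_mask[ys, xs] <- nucleus_mask[ys, xs] | (u^2 + v^2 <= 1)
        }
      }
    }

    f <- spec$patient_effects
    fh <- f[["hematoxylin"]]; fe <- f[["eosin"]]
    npix <- nl * ns
    in_nuc <- as.vector(nucleus_mask)
    in_blank <- as.vector(blank_mask)
    # Base concentrations with mild per-pixel jitter (staining texture).
    c_h <- ifelse(in_nuc, 1.1 * fh, 0.12 * fh) * pmax(0, 1 + rnorm(npix, 0, 0.05))
    c_e <- ifelse(in_nuc, 0.25 * fe, 0.90 * fe) * pmax(0, 1 + rnorm(npix, 0, 0.05))
    c_h[in_blank] <- 0; c_e[in_blank] <- 0

    a_h <- stain_absorbance(wl, model$stains$hematoxylin)
    a_e <- stain_absorbance(wl, model$stains$eosin)
    trans <- exp(-(outer(c_h, a_h) + outer(c_e, a_e)))  # npix x nb

    gain <- runif(1L, 0.9, 1.1)  # per-slide illumination intensity jitter
    illum <- model$illumination * gain
    radiance <- trans * rep(illum, each = npix)
    if (spec$noise_sd > 0) radiance <- radiance + rnorm(npix * nb, 0, spec$noise_sd)
    radiance <- pmax(radiance, 0)
    dim(radiance) <- c(nl, ns, nb)

    ref <- rep(illum, each = reference_lines * ns)
    if (spec$noise_sd > 0) ref <- ref + rnorm(reference_lines * ns * nb, 0, spec$noise_sd)
    ref <- pmax(ref, 0)
    dim(ref) <- c(reference_lines, ns, nb)

    out <- list(
      cube = hs_cube(radiance, wl, stage = "radiance",
                     patient_id = patient_id, roi_id = roi_id, label = spec$class),
      reference = hs_cube(ref, wl, stage = "radiance",
                          patient_id = patient_id, roi_id = roi_id, label = "unknown"),
      nucleus_mask = nucleus_mask,
      blank_mask = blank_mask)
    if (keep_scene) {
      dim(trans) <- c(nl, ns, nb)
      out$scene_transmittance <- trans
    }
    out
  })
}

#' Generate a synthetic patient cohort on disk
#'
#' Writes ENVI cube/reference pairs, plain-text nucleus-mask bitmaps and a
#' manifest CSV for a cohort shaped like a real acquisition campaign: the
#' last `tumor_only_patients` patients contribute tumor ROIs only, the rest
#' contribute one tumor and one non-tumor ROI each. Per-patient stain
#' factors are drawn once per patient (log-normal, sd 0.2), making
#' between-patient spectral variability exceed within-patient variability.
#' All randomness derives from `seed` through a counter-based splitting
#' scheme, so any slide can be regenerated independently.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_patients Total number of patients (at least 4, so a 4-fold
#'   patient-disjoint partition is feasible).
#' @param tumor_only_patients How many patients carry tumor samples only.
#' @param n_cubes_per_roi Cubes acquired per tumor ROI.
#' @param n_non_tumor_cubes_per_roi Cubes per non-tumor ROI; the default
#'   (twice the tumor count) mirrors the roughly 2:1 non-tumor:tumor
#'   imbalance of real campaigns, which is what rotation balancing then
#'   corrects during training.
#' @param lines,samples Spatial cube size.
#' @param n_bands Number of spectral bands over 400-1000 nm.
#' @param noise_sd,blank_fraction Passed to every [scene_spec()].
#' @param seed Master integer seed.
#' @param data_type ENVI numeric type for the rasters (4 = float32 default
#'   for synthetic cohorts; 5 = float64).
#' @return The manifest (invisible), with attribute `"dir"` set to
#'   `out_dir`; cube paths inside it are relative to that directory.
#' @export
generate_cohort <- function(out_dir, n_patients = 13L, tumor_only_patients = 5L,
                            n_cubes_per_roi = 1L,
                            n_non_tumor_cubes_per_roi = 2L * n_cubes_per_roi,
                            lines = 800L, samples = 1004L,
                            n_bands = 826L, noise_sd = 5, blank_fraction = 0.15,
                            seed = 1L, data_type = 4L) {
  if (n_patients < 4L) abort("Need at least 4 patients for a feasible 4-fold design.")
  if (tumor_only_patients > n_patients) abort("`tumor_only_patients` cannot exceed `n_patients`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- stain_model(default_wavelengths(n_bands))

  ids <- sprintf("P%02d", seq_len(n_patients))
  tumor_only <- ids[seq.int(n_patients - tumor_only_patients + 1L, length.out = tumor_only_patients)]

  rows <- list()
  counter <- 0L
  for (p in seq_along(ids)) {
    pid <- ids[p]
    fx <- withr::with_seed(split_seed(seed, p), {
      c(hematoxylin = exp(rnorm(1, 0, 0.2)), eosin = exp(rnorm(1, 0, 0.2)))
    })
    rois <- if (pid %in% tumor_only) c(T1 = "tumor") else c(T1 = "tumor", N1 = "non_tumor")
    for (ri in seq_along(rois)) {
      roi <- names(rois)[ri]; lab <- rois[[ri]]
      n_k <- if (lab == "tumor") n_cubes_per_roi else n_non_tumor_cubes_per_roi
      for (k in seq_len(n_k)) {
        counter <- counter + 1L
        spec <- scene_spec(lab, lines = lines, samples = samples,
                           blank_fraction = blank_fraction,
                           patient_effects = fx, noise_sd = noise_sd,
                           seed = split_seed(seed, 1000L + counter))
        slide <- generate_slide(spec, model, patient_id = pid,
                                roi_id = sprintf("%s_c%d", roi, k))
        stem <- sprintf("%s_%s_c%d", pid, roi, k)
        write_cube(slide$cube, file.path(out_dir, paste0(stem, ".raw")), data_type = data_type)
        write_cube(slide$reference, file.path(out_dir, paste0(stem, "_ref.raw")), data_type = data_type)
        write_mask_pbm(slide$nucleus_mask, file.path(out_dir, paste0(stem, "_mask.pbm")))
        rows[[length(rows) + 1L]] <- tibble(
          patient_id = pid, roi_id = sprintf("%s_c%d", roi, k),
          cube_path = paste0(stem, ".raw"), reference_path = paste0(stem, "_ref.raw"),
          label = lab, excluded = FALSE, exclusion_reason = "none")
      }
    }
  }
  manifest <- validate_manifest(dplyr::bind_rows(rows), dir = out_dir)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}

# Plain-text portable bitmap (PBM P1) writer for ground-truth masks.
write_mask_pbm <- function(mask, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P1", sprintf("%d %d", ncol(mask), nrow(mask))), con)
  writeLines(apply(mask * 1L, 1L, paste, collapse = " "), con)
  invisible(path)
}
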