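#' Flat-field correction: radiance to normalized transmittance
#'
#' Divides specimen radiance by a blank-area reference, removing the
#' illumination spectrum and per-sample sensor response. The reference cube
#' is first averaged over its scan lines — the push-broom geometry makes the
#' fixed-pattern response a per-(sample, band) property, so one reference
#' spectrum per sensor sample both suppresses reference noise and respects
#' the optics. The result is clamped to \[0, 1\]: values above 1 arise only
#' from noise and would violate downstream invariants.
#'
#' The operation is scale-invariant (multiplying cube and reference by one
#' positive constant changes nothing) and deterministic.
#'
#' @param cube Radiance [hs_cube()].
#' @param reference Radiance `hs_cube` of a blank area, sharing the cube's
#'   samples and bands dimensions (its line count is free).
#' @return The cube in stage `"transmittance"`.
#' @export
flat_field_correct <- function(cube, reference) {
  stopifnot(inherits(cube, "hs_cube"), inherits(reference, "hs_cube"))
  if (cube$stage != "radiance") abort("`cube` must be at stage 'radiance'.")
  if (reference$stage != "radiance") abort("`reference` must be at stage 'radiance'.")
  dc <- dim(cube$data); dr <- dim(reference$data)
  if (dc[2] != dr[2] || dc[3] != dr[3]) {
    abort(sprintf("Cube (%d samples x %d bands) and reference (%d x %d) must agree on samples and bands.",
                  dc[2], dc[3], dr[2], dr[3]))
  }
  # Reference profile: one spectrum per sensor sample.
  profile <- colMeans(reference$data, dims = 1L)  # samples x bands
  bad <- which(profile <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    show <- head(bad, 5L)
    abort(sprintf(
      "Reference profile is non-positive at %d (sample, band) position(s), e.g.: %s",
      nrow(bad),
      paste(sprintf("(%d,%d)", show[, 1], show[, 2]), collapse = " ")))
  }
  trans <- cube$data / rep(profile, each = dc[1])
  trans[trans > 1] <- 1
  trans[trans < 0] <- 0
  hs_cube(trans, cube$wavelengths_nm, stage = "transmittance",
          patient_id = cube$patient_id, roi_id = cube$roi_id, label = cube$label)
}

#' Spectral band-reduction plan
#'
#' Adjacent spectral bands of this instrument are highly correlated;
#' averaging consecutive non-overlapping groups reduces dimensionality (826
#' bands to 275 with groups of 3) while slightly suppressing white noise
#' (the variance of a mean of g i.i.d. bands is 1/g of the band variance).
#'
#' @param group_size Bands per group (default 3).
#' @param tail_policy What to do with a residual group smaller than
#'   `group_size`: `"drop_last"` discards it (826 = 3 x 275 + 1, so the
#'   lone final band is dropped), `"fold_into_last"` averages it into the
#'   final group.
#' @return A `band_plan` object.
#' @export
band_plan <- function(group_size = 3L, tail_policy = c("drop_last", "fold_into_last")) {
  tail_policy <- match.arg(tail_policy)
  if (group_size < 1L) abort("`group_size` must be at least 1.")
  structure(list(group_size = as.integer(group_size), tail_policy = tail_policy),
            class = "band_plan")
}

#' Reduce spectral bands by grouped averaging
#'
#' @param cube Transmittance [hs_cube()].
#' @param plan A [band_plan()].
#' @return An `hs_cube` at stage `"reduced"` with `floor(bands/group_size)`
#'   bands; output wavelengths are per-group means. Commutes exactly with
#'   spatial cropping.
#' @export
reduce_bands <- function(cube, plan = band_plan()) {
  stopifnot(inherits(cube, "hs_cube"), inherits(plan, "band_plan"))
  if (cube$stage != "transmittance") abort("`cube` must be at stage 'transmittance'.")
  g <- plan$group_size
  nb <- dim(cube$data)[3]
  n_out <- nb %/% g
  if (n_out < 1L) abort(sprintf("Cannot form any group of %d from %d bands.", g, nb))

  used <- n_out * g
  fold <- plan$tail_policy == "fold_into_last" && used < nb

  d <- dim(cube$data)
  flat <- cube$data
  dim(flat) <- c(d[1] * d[2], d[3])
  sums <- matrix(0, d[1] * d[2], n_out)
  for (j in seq_len(g)) sums <- sums + flat[, seq.int(j, used, by = g), drop = FALSE]
  counts <- rep(g, n_out)
  wl_sums <- colSums(matrix(cube$wavelengths_nm[seq_len(used)], nrow = g))
  if (fold) {
    for (k in seq.int(used + 1L, nb)) sums[, n_out] <- sums[, n_out] + flat[, k]
    counts[n_out] <- counts[n_out] + (nb - used)
    wl_sums[n_out] <- wl_sums[n_out] + sum(cube$wavelengths_nm[seq.int(used + 1L, nb)])
  }
  red <- sweep(sums, 2L, counts, `/`)
  dim(red) <- c(d[1], d[2], n_out)

  wl <- wl_sums / counts
  hs_cube(red, wl, stage = "reduced",
          patient_id = cube$patient_id, roi_id = cube$roi_id, label = cube$label)
}

#' Colour-matching observer weights
#'
#' Tabulates the CIE 1931 standard observer on an arbitrary wavelength grid
#' using the published multi-lobe Gaussian analytic approximation (Wyman,
#' Sloan & Shirley 2013), clamped at zero. Deterministic and bit-stable.
#'
#' @param wavelengths_nm Wavelength grid.
#' @return Matrix with columns `x`, `y`, `z` (red-, green-, blue-weighted
#'   sensitivity curves).
#' @export
cie_observer <- function(wavelengths_nm) {
  g <- function(x, mu, s1, s2) exp(-0.5 * ((x - mu) / ifelse(x < mu, s1, s2))^2)
  x <- 1.056 * g(wavelengths_nm, 599.8, 37.9, 31.0) +
       0.362 * g(wavelengths_nm, 442.0, 16.0, 26.7) -
       0.065 * g(wavelengths_nm, 501.1, 20.4, 26.2)
  y <- 0.821 * g(wavelengths_nm, 568.8, 46.9, 40.5) +
       0.286 * g(wavelengths_nm, 530.9, 16.3, 31.1)
  z <- 1.217 * g(wavelengths_nm, 437.0, 11.8, 36.0) +
       0.681 * g(wavelengths_nm, 459.0, 26.0, 13.8)
  cbind(x = pmax(x, 0), y = pmax(y, 0), z = pmax(z, 0))
}

#' Synthesize an RGB image from a transmittance cube
#'
#' Each colour channel is the inner product of the pixel spectrum with a
#' colour-matching weight curve emulating the spectral response of the
#' human eye, normalized so that a unit (all-ones) spectrum maps to
#' (1, 1, 1) — i.e. blank light renders as white.
#'
#' @param cube [hs_cube()] at stage `"transmittance"` or `"reduced"`; its
#'   wavelengths must cover the visible range (reach at most 480 nm at the
#'   blue end and at least 620 nm at the red end).
#' @return lines x samples x 3 array in \[0, 1\], channels R, G, B.
#' @export
synthesize_rgb <- function(cube) {
  stopifnot(inherits(cube, "hs_cube"))
  if (!cube$stage %in% c("transmittance", "reduced")) {
    abort("`cube` must be at stage 'transmittance' or 'reduced'.")
  }
  wl <- cube$wavelengths_nm
  if (min(wl) > 480 || max(wl) < 620) {
    abort(sprintf("Wavelengths cover %.0f-%.0f nm; RGB synthesis needs the visible range (<=480 to >=620 nm).",
                  min(wl), max(wl)))
  }
  w <- cie_observer(wl)
  w <- sweep(w, 2L, colSums(w), `/`)  # unit spectrum -> (1,1,1)
  d <- dim(cube$data)
  flat <- cube$data
  dim(flat) <- c(d[1] * d[2], d[3])
  rgb <- flat %*% w
  rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  dim(rgb) <- c(d[1], d[2], 3L)
  rgb
}
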