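#' Hyperspectral cube container
#'
#' An `hs_cube` wraps a 3-D raster of a push-broom hyperspectral acquisition
#' together with its wavelength axis and provenance. The axis convention is
#' fixed throughout the package: axis 1 = scan lines, axis 2 = sensor samples,
#' axis 3 = spectral bands (0-based offsets are used wherever grid positions
#' are reported). The instrument this models scans 800 lines of 1004 samples
#' over 826 bands between 400 and 1000 nm; smaller cubes with the same
#' structure are accepted so that synthetic desk-scale data can flow through
#' the identical code paths.
#'
#' @param data 3-D numeric array, lines x samples x bands.
#' @param wavelengths_nm Strictly ascending numeric vector of band-centre
#'   wavelengths in nanometres, within \[400, 1000\]; length must equal
#'   `dim(data)[3]`.
#' @param stage Processing stage: `"radiance"` (raw non-negative counts),
#'   `"transmittance"` (flat-field corrected, in \[0, 1\]) or `"reduced"`
#'   (band-averaged transmittance, in \[0, 1\]).
#' @param patient_id,roi_id Provenance identifiers (free-form strings).
#' @param label Per-cube class label: `"tumor"`, `"non_tumor"` or `"unknown"`.
#'   Labels are weak, i.e. shared by every pixel and patch of the cube.
#'
#' @return An object of class `hs_cube`.
#' @export
#' @examples
#' cube <- hs_cube(array(0.5, c(4, 5, 3)), c(450, 550, 650),
#'                 stage = "transmittance", label = "tumor")
#' dim(cube$data)
hs_cube <- function(data, wavelengths_nm, stage = c("radiance", "transmittance", "reduced"),
                    patient_id = "", roi_id = "", label = c("unknown", "tumor", "non_tumor")) {
  stage <- match.arg(stage)
  label <- match.arg(label)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array (lines x samples x bands).")
  }
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != dim(data)[3]) {
    abort(sprintf("Band mismatch: data has %d bands but %d wavelengths were given.",
                  dim(data)[3], length(wavelengths_nm)))
  }
  if (any(diff(wavelengths_nm) <= 0)) abort("Wavelengths must be strictly ascending.")
  if (min(wavelengths_nm) < 400 || max(wavelengths_nm) > 1000) {
    abort("Wavelengths must lie within [400, 1000] nm.")
  }
  if (stage == "radiance") {
    if (any(data < 0)) abort("Radiance values must be non-negative.")
  } else {
    if (any(data < 0) || any(data > 1)) {
      abort(sprintf("Stage '%s' requires values in [0, 1]; clamp before constructing.", stage))
    }
  }
  structure(
    list(data = data, wavelengths_nm = wavelengths_nm, stage = stage,
         patient_id = as.character(patient_id), roi_id = as.character(roi_id),
         label = label),
    class = "hs_cube")
}

#' @export
print.hs_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hs_cube> %d lines x %d samples x %d bands [%s]\n", d[1], d[2], d[3], x$stage))
  cat(sprintf("  wavelengths: %.1f-%.1f nm | patient: %s | roi: %s | label: %s\n",
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              if (nzchar(x$patient_id)) x$patient_id else "<none>",
              if (nzchar(x$roi_id)) x$roi_id else "<none>", x$label))
  invisible(x)
}

#' Spatially crop a cube
#'
#' Returns the sub-cube covering `lines` and `samples` (1-based index
#' vectors); all bands and metadata are kept.
#'
#' @param cube An [hs_cube()].
#' @param lines,samples Integer index vectors into the two spatial axes.
#' @return An `hs_cube` with the cropped raster.
#' @export
crop_cube <- function(cube, lines, samples) {
  stopifnot(inherits(cube, "hs_cube"))
  out <- cube
  out$data <- cube$data[lines, samples, , drop = FALSE]
  out
}

cube_id <- function(cube) {
  paste(cube$patient_id, cube$roi_id, sep = "/")
}
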