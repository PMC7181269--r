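#' Stain optics model for synthetic H&E slides
#'
#' Transmitted-light microscopy of stained tissue is emulated with a
#' Beer-Lambert model: each stain contributes an absorbance spectrum built
#' from two Gaussian bands, and a pixel's transmittance is
#' `exp(-sum_s conc_s * A_s(lambda))`. The defaults place the
#' hematoxylin-like absorption peak at 590 nm (nuclei transmit blue-purple)
#' and the eosin-like peak at 525 nm (cytoplasm/stroma transmit pink), which
#' makes nucleus and background spectra clearly distinct below 700 nm and
#' flat and bright in the 700-1000 nm tail — a qualitative target, not
#' calibrated stain chemistry. The illumination spectrum is a smooth
#' halogen-like ramp rising towards the red/near-infrared.
#'
#' @param wavelengths_nm Wavelength grid of the virtual instrument
#'   (default: 826 bands evenly covering 400-1000 nm).
#' @param peak_counts Illumination scale, in radiance counts, at 1000 nm.
#' @return An object of class `stain_model`: the wavelength grid, per-stain
#'   Gaussian absorbance bands (`peak_nm`, `width_nm`, `amplitude`), and the
#'   illumination spectrum.
#' @export
#' @examples
#' m <- stain_model(seq(400, 1000, by = 10))
#' tr <- stain_transmittance(m$wavelengths_nm, c(hematoxylin = 1, eosin = 0.2), m)
#' range(tr)
stain_model <- function(wavelengths_nm = default_wavelengths(826L), peak_counts = 1000) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (any(diff(wavelengths_nm) <= 0)) abort("Wavelengths must be strictly ascending.")
  stains <- list(
    hematoxylin = list(bands = list(c(peak_nm = 590, width_nm = 70, amplitude = 1.6),
                                    c(peak_nm = 445, width_nm = 40, amplitude = 0.40))),
    eosin       = list(bands = list(c(peak_nm = 525, width_nm = 45, amplitude = 1.2),
                                    c(peak_nm = 490, width_nm = 35, amplitude = 0.50))))
  illum <- peak_counts * (0.35 + 0.65 * (wavelengths_nm - 400) / 600)
  structure(list(wavelengths_nm = wavelengths_nm, stains = stains,
                 illumination = illum),
            class = "stain_model")
}

#' Default instrument wavelength grid
#' @param n_bands Number of bands spread evenly over 400-1000 nm.
#' @return Numeric vector of band-centre wavelengths.
#' @export
default_wavelengths <- function(n_bands = 826L) {
  seq(400, 1000, length.out = n_bands)
}

# Absorbance spectrum of one stain on a wavelength grid.
stain_absorbance <- function(wavelengths_nm, stain) {
  a <- numeric(length(wavelengths_nm))
  for (b in stain$bands) {
    a <- a + b[["amplitude"]] * exp(-0.5 * ((wavelengths_nm - b[["peak_nm"]]) / b[["width_nm"]])^2)
  }
  a
}

#' Beer-Lambert transmittance for given stain concentrations
#'
#' @param wavelengths_nm Wavelength grid to evaluate on.
#' @param concentrations Named (or positional, matching the model's stain
#'   order) non-negative concentrations, one per stain.
#' @param model A [stain_model()].
#' @return Transmittance spectrum in (0, 1], one value per wavelength;
#'   strictly decreasing in each concentration wherever that stain absorbs.
#' @export
stain_transmittance <- function(wavelengths_nm, concentrations, model) {
  if (any(concentrations < 0)) abort("Concentrations must be non-negative.")
  if (length(concentrations) != length(model$stains)) {
    abort(sprintf("Expected %d concentrations (one per stain), got %d.",
                  length(model$stains), length(concentrations)))
  }
  if (!is.null(names(concentrations)) && all(nzchar(names(concentrations)))) {
    concentrations <- concentrations[names(model$stains)]
    if (anyNA(concentrations)) abort("Concentration names do not match the model's stains.")
  }
  total <- numeric(length(wavelengths_nm))
  for (i in seq_along(model$stains)) {
    total <- total + concentrations[[i]] * stain_absorbance(wavelengths_nm, model$stains[[i]])
  }
  exp(-total)
}
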