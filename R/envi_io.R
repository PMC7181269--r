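#' Read a hyperspectral cube from an ENVI-style header/raster pair
#'
#' Cubes are stored as a plain-text ENVI header (`<path>.hdr`) next to a raw
#' binary raster. The header is the single source of truth for dimensions,
#' interleave, numeric type, wavelengths and the package's provenance fields
#' (`stage`, `patient id`, `roi id`, `label`). No other function in the
#' package parses files.
#'
#' @param path Path to the raster file, or to its `.hdr` header.
#' @return An [hs_cube()] with data normalized to lines x samples x bands,
#'   whatever the on-disk interleave.
#' @seealso [write_cube()]
#' @export
read_cube <- function(path) {
  paths <- envi_paths(path)
  if (!file.exists(paths$hdr)) abort(sprintf("Header not found: %s", paths$hdr))
  if (!file.exists(paths$raw)) abort(sprintf("Raster not found: %s", paths$raw))
  hdr <- parse_envi_header(paths$hdr)

  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    abort(sprintf("Header %s is missing required field(s): %s",
                  paths$hdr, paste(miss, collapse = ", ")))
  }
  lines <- as.integer(hdr[["lines"]]); samples <- as.integer(hdr[["samples"]])
  bands <- as.integer(hdr[["bands"]])
  dtype <- as.integer(hdr[["data type"]])
  if (!dtype %in% c(4L, 5L)) {
    abort(sprintf("Unsupported ENVI data type %d (field 'data type'); only 4 (float32) and 5 (float64) are handled.", dtype))
  }
  interleave <- tolower(hdr[["interleave"]])
  if (!interleave %in% c("bil", "bip", "bsq")) {
    abort(sprintf("Unknown interleave '%s' (field 'interleave').", interleave))
  }

  wl <- hdr[["wavelength"]]
  if (is.null(wl)) abort(sprintf("Header %s lacks a 'wavelength' block.", paths$hdr))
  wl <- as.numeric(strsplit(wl, ",")[[1]])
  if (length(wl) != bands) {
    abort(sprintf("Header field 'wavelength' lists %d values but 'bands' = %d.",
                  length(wl), bands))
  }

  n <- lines * samples * bands
  size <- if (dtype == 5L) 8L else 4L
  raw_n <- file.size(paths$raw)
  if (raw_n != n * size) {
    abort(sprintf("Raster %s holds %d bytes but header dimensions require %d.",
                  paths$raw, raw_n, n * size))
  }
  con <- file(paths$raw, "rb"); on.exit(close(con))
  vec <- readBin(con, "double", n = n, size = size, endian = "little")

  # Normalize interleave to lines x samples x bands in memory.
  data <- switch(interleave,
    bil = aperm(array(vec, dim = c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(vec, dim = c(bands, samples, lines)), c(3, 2, 1)),
    bsq = aperm(array(vec, dim = c(samples, lines, bands)), c(2, 1, 3)))

  hs_cube(data, wl,
          stage = hdr[["stage"]] %||% "radiance",
          patient_id = hdr[["patient id"]] %||% "",
          roi_id = hdr[["roi id"]] %||% "",
          label = hdr[["label"]] %||% "unknown")
}

#' Write a hyperspectral cube as an ENVI-style header/raster pair
#'
#' @param cube An [hs_cube()]; its invariants are re-validated before
#'   anything touches disk.
#' @param path Raster path to create; the header is written at `<path>.hdr`.
#' @param data_type ENVI numeric type code: 5 (float64, the default; exact
#'   round trip) or 4 (float32; halves disk footprint for large syntheses).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, data_type = 5L) {
  stopifnot(inherits(cube, "hs_cube"))
  # Re-validate: cubes can be mutated in place between construction and write.
  cube <- hs_cube(cube$data, cube$wavelengths_nm, cube$stage,
                  cube$patient_id, cube$roi_id, cube$label)
  if (!data_type %in% c(4L, 5L)) abort("`data_type` must be 4 (float32) or 5 (float64).")
  paths <- envi_paths(path)
  d <- dim(cube$data)

  hdr <- c(
    "ENVI",
    "description = {hsipath hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    "interleave = bil",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}", paste(format(cube$wavelengths_nm, digits = 15, trim = TRUE, scientific = FALSE), collapse = ", ")),
    sprintf("stage = %s", cube$stage),
    sprintf("patient id = %s", cube$patient_id),
    sprintf("roi id = %s", cube$roi_id),
    sprintf("label = %s", cube$label))
  writeLines(hdr, paths$hdr)

  vec <- as.vector(aperm(cube$data, c(2, 3, 1)))  # BIL: sample fastest, then band, then line
  con <- file(paths$raw, "wb"); on.exit(close(con))
  writeBin(vec, con, size = if (data_type == 5L) 8L else 4L, endian = "little")
  invisible(path)
}

envi_paths <- function(path) {
  if (grepl("\\.hdr$", path)) list(hdr = path, raw = sub("\\.hdr$", "", path))
  else list(hdr = paste0(path, ".hdr"), raw = path)
}

# ENVI headers are "key = value" lines; values may be {}-blocks spanning
# several lines. Returns a named list of strings ({}-blocks are flattened).
parse_envi_header <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || trimws(txt[1]) != "ENVI") {
    abort(sprintf("%s is not an ENVI header (missing leading 'ENVI' line).", path))
  }
  joined <- paste(txt[-1], collapse = "\n")
  out <- list()
  # Pull {}-blocks first so embedded newlines/commas survive.
  block_rx <- "(?ms)^\\s*([^=\\n]+?)\\s*=\\s*\\{(.*?)\\}"
  m <- gregexpr(block_rx, joined, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      piece <- substr(joined, m[i], m[i] + attr(m, "match.length")[i] - 1L)
      key <- tolower(trimws(sub("(?ms)^\\s*([^=\\n]+?)\\s*=.*$", "\\1", piece, perl = TRUE)))
      val <- sub("(?ms)^.*?\\{(.*)\\}\\s*$", "\\1", piece, perl = TRUE)
      out[[key]] <- gsub("\\s+", " ", trimws(val))
    }
    joined <- gsub(block_rx, "", joined, perl = TRUE)
  }
  for (line in strsplit(joined, "\n")[[1]]) {
    line <- trimws(line)
    if (!nzchar(line) || startsWith(line, ";") || !grepl("=", line, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    out[[key]] <- val
  }
  out
}
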