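#' Load and validate a dataset manifest
#'
#' The manifest is the bookkeeping table of an acquisition campaign: one row
#' per cube, carrying patient and ROI identifiers, the cube and blank-area
#' reference paths, the weak per-cube class label, and quality-control
#' exclusion flags. Exclusions are metadata only — they are applied at
#' evaluation time (defective cubes are dropped from test sets without
#' retraining), never silently at read time.
#'
#' @param path CSV file with columns `patient_id`, `roi_id`, `cube_path`,
#'   `reference_path`, `label`, `excluded`, `exclusion_reason`.
#' @param check_paths If `TRUE`, verify that every referenced raster exists
#'   (relative paths resolve against the manifest's directory).
#' @return A tibble of class `hsi_manifest`.
#' @export
load_manifest <- function(path, check_paths = FALSE) {
  cols <- readr::cols(
    patient_id = readr::col_character(), roi_id = readr::col_character(),
    cube_path = readr::col_character(), reference_path = readr::col_character(),
    label = readr::col_character(), excluded = readr::col_logical(),
    exclusion_reason = readr::col_character())
  df <- readr::read_csv(path, col_types = cols)
  if (nrow(df) == 0 && ncol(df) == 0) {
    df <- tibble(patient_id = character(), roi_id = character(),
                 cube_path = character(), reference_path = character(),
                 label = character(), excluded = logical(),
                 exclusion_reason = character())
  }
  validate_manifest(df, dir = dirname(path), check_paths = check_paths)
}

#' @rdname load_manifest
#' @param manifest A data frame with the manifest columns, validated in place.
#' @param dir Directory against which relative raster paths resolve.
#' @export
validate_manifest <- function(manifest, dir = ".", check_paths = FALSE) {
  need <- c("patient_id", "roi_id", "cube_path", "reference_path",
            "label", "excluded", "exclusion_reason")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) abort(sprintf("Manifest is missing column(s): %s", paste(miss, collapse = ", ")))
  df <- as_tibble(manifest)

  bad <- which(!df$label %in% c("tumor", "non_tumor"))
  if (length(bad)) abort(sprintf("Unknown label(s) in manifest row(s): %s",
                                 paste(head(bad, 10), collapse = ", ")))
  reasons <- c("none", "ink", "unfocused", "artifact", "blood", "necrosis")
  bad <- which(!df$exclusion_reason %in% reasons)
  if (length(bad)) abort(sprintf("Unknown exclusion_reason in row(s): %s",
                                 paste(head(bad, 10), collapse = ", ")))
  # excluded=TRUE <=> a concrete reason; the two must never disagree.
  bad <- which(df$excluded != (df$exclusion_reason != "none"))
  if (length(bad)) abort(sprintf("excluded flag and exclusion_reason disagree in row(s): %s",
                                 paste(head(bad, 10), collapse = ", ")))
  bad <- which(is.na(df$reference_path) | !nzchar(df$reference_path))
  if (length(bad)) abort(sprintf("Missing reference_path in row(s): %s",
                                 paste(head(bad, 10), collapse = ", ")))
  if (check_paths) {
    resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(dir, p))
    for (col in c("cube_path", "reference_path")) {
      bad <- which(!file.exists(resolve(df[[col]])))
      if (length(bad)) abort(sprintf("Dangling %s in row(s): %s", col,
                                     paste(head(bad, 10), collapse = ", ")))
    }
  }
  class(df) <- c("hsi_manifest", class(tibble()))
  df
}

#' Write a manifest to CSV
#' @param manifest An `hsi_manifest` (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(as_tibble(manifest), path)
  invisible(path)
}

#' Per-patient class composition of a manifest
#'
#' @param manifest An `hsi_manifest`.
#' @return A tibble with one row per patient: cube counts per class and a
#'   `classes` summary (`"both"`, `"tumor_only"` or `"non_tumor_only"`).
#' @export
manifest_summary <- function(manifest) {
  manifest |>
    dplyr::count(.data$patient_id, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n", values_fill = 0L) |>
    (\(d) { for (col in c("tumor", "non_tumor")) if (!col %in% names(d)) d[[col]] <- 0L; d })() |>
    dplyr::mutate(classes = dplyr::case_when(
      .data$tumor > 0 & .data$non_tumor > 0 ~ "both",
      .data$tumor > 0 ~ "tumor_only",
      TRUE ~ "non_tumor_only")) |>
    dplyr::arrange(.data$patient_id)
}
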