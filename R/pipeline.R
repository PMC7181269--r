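#' Preprocess every cube of a cohort into one labeled patch set
#'
#' For each manifest row: read the cube and its blank reference, flat-field
#' correct to transmittance, reduce bands, then tile into patches with
#' blank-light rejection. Cubes are processed one at a time, so memory use
#' is bounded by a single cube.
#'
#' @param manifest An `hsi_manifest`; relative raster paths resolve against
#'   `dir`.
#' @param dir Root directory of the raster files (defaults to the
#'   manifest's `"dir"` attribute).
#' @param plan A [band_plan()].
#' @param rule A [rejection_rule()].
#' @param patch Patch side in pixels.
#' @return A `patch_set` covering the whole cohort (exclusion flags are
#'   carried in the metadata, not applied here).
#' @export
preprocess_cohort <- function(manifest, dir = attr(manifest, "dir"),
                              plan = band_plan(), rule = rejection_rule(),
                              patch = 87L) {
  dir <- dir %||% "."
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(dir, p))
  sets <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cube <- read_cube(resolve(manifest$cube_path[i]))
    ref <- read_cube(resolve(manifest$reference_path[i]))
    reduced <- reduce_bands(flat_field_correct(cube, ref), plan)
    sets[[i]] <- extract_patches(reduced, rule, patch = patch)
  }
  bind_patch_sets(sets)
}

#' Split a cohort patch set by the roles of one fold
#'
#' @param patches A cohort-wide `patch_set`.
#' @param plan A `fold_plan` from [make_folds()].
#' @param fold Fold number.
#' @return Named list of `patch_set`s: `train`, `validation`, `test`.
#' @export
fold_patches <- function(patches, plan, fold) {
  info <- retained_info(patches)
  pick <- function(role) {
    ids <- plan$patient_id[plan$fold == fold & plan$role == role]
    subset_patches(patches, which(info$patient_id %in% ids))
  }
  list(train = pick("train"), validation = pick("validation"), test = pick("test"))
}

#' Randomly permute the labels of a patch set
#'
#' The label-randomization null control: training on shuffled labels must
#' destroy generalization (held-out AUC near 0.5), which bounds how much
#' apparent skill could come from leakage or evaluation artifacts.
#'
#' @param patches A `patch_set`.
#' @param seed Integer seed for the permutation.
#' @return The `patch_set` with retained-patch labels permuted.
#' @export
shuffle_labels <- function(patches, seed = 1L) {
  stopifnot(inherits(patches, "patch_set"))
  info <- retained_info(patches)
  perm <- withr::with_seed(seed, sample(nrow(info)))
  rows <- match(info$tensor_idx, patches$info$tensor_idx)
  patches$info$label[rows] <- info$label[perm]
  patches
}

#' Train and evaluate the classifier on one fold
#'
#' The training set is class-balanced by rotation augmentation, the model
#' is trained with validation-AUC selection, and patch probabilities are
#' produced for the held-out test patients.
#'
#' @param patches Cohort `patch_set`.
#' @param plan A `fold_plan`.
#' @param fold Fold number to run.
#' @param scale Width multiplier for [model_spec()].
#' @param config A [train_config()].
#' @param angle Rotation angle for [balance_by_rotation()].
#' @param shuffle_seed If non-`NULL`, permute the training labels with
#'   [shuffle_labels()] first — the null-control run.
#' @return List: `model` (trained `hsi_cnn`), `predictions`
#'   (test-set tibble from [predict_patches()]), `fold`.
#' @export
run_fold <- function(patches, plan, fold, scale = 0.0625,
                     config = train_config(), angle = 180,
                     shuffle_seed = NULL) {
  parts <- fold_patches(patches, plan, fold)
  if (!is.null(shuffle_seed)) parts$train <- shuffle_labels(parts$train, shuffle_seed)
  train <- balance_by_rotation(parts$train, angle = angle)
  spec <- model_spec(input_side = patches$patch, input_bands = patches$bands,
                     scale = scale)
  model <- build_cnn(spec)
  model <- train_cnn(model, train, parts$validation, config)
  preds <- predict_patches(model, parts$test)
  list(model = model, predictions = preds, fold = fold)
}
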