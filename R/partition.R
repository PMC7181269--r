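#' Build patient-disjoint cross-validation folds
#'
#' Patients are partitioned so that (i) within a fold the train, validation
#' and test patient sets are pairwise disjoint, (ii) across folds every
#' patient appears in exactly one test set, (iii) each fold has exactly one
#' validation patient and that patient carries both classes, and (iv) every
#' test set contains at least one both-class patient. With 13 patients (5
#' of them tumor-only) and 4 folds, the test sets come out as three folds
#' of 3 patients and one of 4. Assignment is random under `seed` except
#' where the constraints force choices.
#'
#' @param manifest An `hsi_manifest` (see [load_manifest()]).
#' @param n_folds Number of folds (default 4).
#' @param seed Integer seed; identical seeds give identical plans.
#' @param policy `"random"` (default) for pure constrained randomization,
#'   or `"size_aware"` to mimic a manual adjustment sometimes used for the
#'   unbalanced last fold: the single-class patients with the fewest cubes
#'   go to the largest test set and the patient with the most cubes goes to
#'   its training set.
#' @return A `fold_plan`: tibble with columns `fold`, `role`
#'   (`train`/`validation`/`test`) and `patient_id`; attribute `seed`.
#' @export
make_folds <- function(manifest, n_folds = 4L, seed = 1L, policy = c("random", "size_aware")) {
  policy <- match.arg(policy)
  smry <- manifest_summary(manifest)
  patients <- smry$patient_id
  n <- length(patients)
  if (n < n_folds) abort(sprintf("Cannot build %d folds from %d patients.", n_folds, n))
  both <- smry$patient_id[smry$classes == "both"]
  single <- setdiff(patients, both)
  if (length(both) < n_folds) {
    abort(sprintf(
      "Infeasible: %d both-class patients but %d folds each need a both-class validation patient.",
      length(both), n_folds))
  }

  withr::with_seed(split_seed(seed, 7L), {
    both <- sample(both)
    single <- if (length(single)) sample(single) else character()

    sizes <- rep(n %/% n_folds, n_folds)
    extra <- n %% n_folds
    if (extra > 0) sizes[sample.int(n_folds, extra)] <- sizes[1] + 1L

    if (policy == "size_aware" && length(single) >= 2L && extra > 0) {
      counts <- dplyr::count(manifest, .data$patient_id)
      sz <- counts$n[match(single, counts$patient_id)]
      single <- single[order(sz)]  # smallest single-class patients placed first
    }

    # Deal both-class patients round-robin (each test set needs >= 1), then
    # single-class patients into remaining slots.
    test_sets <- rep(list(character()), n_folds)
    fold_order <- order(-sizes)  # larger test sets are served first
    i <- 0L
    for (p in c(both, single)) {
      placed <- FALSE
      for (k in seq_len(n_folds)) {
        f <- fold_order[((i + k - 1L) %% n_folds) + 1L]
        if (length(test_sets[[f]]) < sizes[f]) {
          test_sets[[f]] <- c(test_sets[[f]], p)
          placed <- TRUE
          i <- i + 1L
          break
        }
      }
      if (!placed) abort("Internal error: failed to place a patient in any test set.")
    }

    # Validation: a both-class patient outside the fold's test set; prefer
    # patients not yet used for validation elsewhere.
    val <- character(n_folds)
    for (f in seq_len(n_folds)) {
      cand <- setdiff(both, test_sets[[f]])
      if (!length(cand)) {
        abort(sprintf("Infeasible: no both-class patient available to validate fold %d.", f))
      }
      fresh <- setdiff(cand, val)
      val[f] <- if (length(fresh)) fresh[1] else cand[1]
    }

    # Everyone not testing or validating a fold trains it, so the largest
    # patient automatically trains the big-test fold under "size_aware".
    train_sets <- lapply(seq_len(n_folds), function(f) {
      setdiff(patients, c(test_sets[[f]], val[f]))
    })

    plan <- dplyr::bind_rows(lapply(seq_len(n_folds), function(f) {
      dplyr::bind_rows(
        tibble(fold = f, role = "train", patient_id = sort(train_sets[[f]])),
        tibble(fold = f, role = "validation", patient_id = val[f]),
        tibble(fold = f, role = "test", patient_id = sort(test_sets[[f]])))
    }))
    attr(plan, "seed") <- seed
    class(plan) <- c("fold_plan", class(tibble()))
    assert_fold_plan(plan, manifest)
    plan
  })
}

#' Check a fold plan against the patient-disjointness constraints
#'
#' Verifies, for a given plan and manifest: pairwise-disjoint roles within
#' each fold, every patient tested exactly once across folds, exactly one
#' both-class validation patient per fold, and at least one both-class
#' patient per test set.
#'
#' @param plan A `fold_plan`.
#' @param manifest The manifest it was built from.
#' @return `TRUE` (invisibly); errors describing the violated constraint
#'   otherwise.
#' @export
assert_fold_plan <- function(plan, manifest) {
  smry <- manifest_summary(manifest)
  both <- smry$patient_id[smry$classes == "both"]
  patients <- smry$patient_id
  folds <- sort(unique(plan$fold))
  for (f in folds) {
    sub <- plan[plan$fold == f, ]
    tr <- sub$patient_id[sub$role == "train"]
    va <- sub$patient_id[sub$role == "validation"]
    te <- sub$patient_id[sub$role == "test"]
    if (length(intersect(tr, te)) || length(intersect(tr, va)) || length(intersect(va, te))) {
      abort(sprintf("Fold %d: train/validation/test patient sets overlap.", f))
    }
    if (length(va) != 1L) abort(sprintf("Fold %d: expected exactly 1 validation patient, found %d.", f, length(va)))
    if (!va %in% both) abort(sprintf("Fold %d: validation patient %s lacks both classes.", f, va))
    if (!any(te %in% both)) abort(sprintf("Fold %d: test set has no both-class patient.", f))
  }
  tested <- plan$patient_id[plan$role == "test"]
  if (anyDuplicated(tested)) abort("A patient appears in more than one test set.")
  missing <- setdiff(patients, tested)
  if (length(missing)) {
    abort(sprintf("Patient(s) never tested: %s", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Balance classes by duplicating rotated minority patches
#'
#' The minority class (detected from the data, typically tumor) is doubled
#' by adding one spatially rotated copy of each minority patch; the
#' spectral axis is untouched and the majority class is left as is.
#' Rotations are lossless right-angle permutations, so each rotated patch
#' keeps its per-band mean exactly.
#'
#' @param train A `patch_set` containing both classes (training data).
#' @param angle Rotation in degrees: 90, 180 (default) or 270.
#' @return A `patch_set` whose new copies carry `augmented = TRUE`.
#' @export
balance_by_rotation <- function(train, angle = 180) {
  stopifnot(inherits(train, "patch_set"))
  if (!angle %in% c(90, 180, 270)) abort("`angle` must be 90, 180 or 270 degrees.")
  info <- retained_info(train)
  tab <- table(info$label)
  if (length(tab) < 2L) abort("Training set must contain both classes to balance.")
  minority <- names(tab)[which.min(tab)]
  idx <- which(info$label == minority)

  n0 <- n_patches(train)
  add <- length(idx)
  ps <- train$patch
  tensors <- array(0, c(n0 + add, ps, ps, train$bands))
  tensors[seq_len(n0), , , ] <- train$tensors
  for (k in seq_along(idx)) {
    x <- train$tensors[info$tensor_idx[idx[k]], , , , drop = TRUE]
    if (train$bands == 1L) dim(x) <- c(ps, ps, 1L)
    tensors[n0 + k, , , ] <- rotate_patch(x, angle)
  }
  extra <- info[idx, , drop = FALSE]
  extra$augmented <- TRUE
  extra$tensor_idx <- n0 + seq_len(add)
  new_patch_set(tensors, dplyr::bind_rows(train$info, extra),
                bands = train$bands, patch = ps)
}

# Right-angle spatial rotation of an s x s x B tensor (spectral axis fixed).
rotate_patch <- function(x, angle) {
  s <- dim(x)[1]
  switch(as.character(angle),
    "90"  = aperm(x, c(2, 1, 3))[s:1, , , drop = FALSE],
    "180" = x[s:1, s:1, , drop = FALSE],
    "270" = aperm(x, c(2, 1, 3))[, s:1, , drop = FALSE],
    abort("`angle` must be 90, 180 or 270 degrees."))
}
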