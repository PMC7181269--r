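#' Non-overlapping tile grid over an image
#'
#' Tiles are anchored at the top-left corner at offsets `(i*patch, j*patch)`
#' (0-based), `i < floor(lines/patch)`, `j < floor(samples/patch)`; residual
#' margins at the far edges are discarded. An 800 x 1004 cube with 87-pixel
#' patches yields a 9 x 11 grid — 99 tile positions.
#'
#' @param lines,samples Image size in pixels.
#' @param patch Patch side in pixels (default 87).
#' @return Tibble of 0-based offsets (`row0`, `col0`) with their grid
#'   indices (`grid_row`, `grid_col`), in row-major order; empty when the
#'   image is smaller than the patch.
#' @export
tile_grid <- function(lines, samples, patch = 87L) {
  if (patch < 1L) abort("`patch` must be at least 1.")
  nr <- lines %/% patch; nc <- samples %/% patch
  if (nr < 1L || nc < 1L) {
    return(tibble(grid_row = integer(), grid_col = integer(),
                  row0 = integer(), col0 = integer()))
  }
  grid <- expand.grid(grid_col = seq_len(nc) - 1L, grid_row = seq_len(nr) - 1L)
  tibble(grid_row = grid$grid_row, grid_col = grid$grid_col,
         row0 = grid$grid_row * patch, col0 = grid$grid_col * patch)
}

#' Blank-light rejection rule
#'
#' A patch is discarded when more than `max_light_fraction` of its pixels
#' are background light. Pixels are classified from the patch's RGB
#' rendering in hue-saturation-value space: the binarized hue marks light
#' versus specimen, with an explicit saturation floor for the achromatic
#' degenerate case (white light has no defined hue, so near-zero saturation
#' is classified as light regardless of the hue value).
#'
#' @param hue_threshold Pixels with hue below this are light. On the
#'   synthetic stain model, tissue hues sit in the cyan-to-magenta range
#'   (nucleus mode near 0.69, stroma mode near 0.88) and blank light at
#'   hue 0, so the default is the midpoint of the gap between the blank
#'   and the nearest tissue mode.
#' @param sat_floor Saturation at or below this marks light.
#' @param max_light_fraction Rejection threshold; "more than" is strict, a
#'   patch at exactly this fraction is retained.
#' @return A `rejection_rule` object.
#' @export
rejection_rule <- function(hue_threshold = 0.35, sat_floor = 0.05,
                           max_light_fraction = 0.5) {
  if (hue_threshold < 0 || hue_threshold > 1) abort("`hue_threshold` must lie in [0, 1].")
  if (max_light_fraction <= 0 || max_light_fraction >= 1) {
    abort("`max_light_fraction` must lie in (0, 1).")
  }
  structure(list(hue_threshold = hue_threshold, sat_floor = sat_floor,
                 max_light_fraction = max_light_fraction),
            class = "rejection_rule")
}

#' Fraction of background-light pixels in an RGB region
#'
#' @param rgb_region h x w x 3 array in \[0, 1\] (from [synthesize_rgb()]).
#' @param rule A [rejection_rule()].
#' @return Scalar in \[0, 1\].
#' @export
light_fraction <- function(rgb_region, rule = rejection_rule()) {
  stopifnot(length(dim(rgb_region)) == 3L, dim(rgb_region)[3] == 3L)
  mean(light_mask(rgb_region, rule))
}

# Logical h x w mask of light pixels.
light_mask <- function(rgb_region, rule) {
  d <- dim(rgb_region)
  m <- matrix(aperm(rgb_region, c(3, 1, 2)), nrow = 3L)
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  light <- hsv["h", ] < rule$hue_threshold | hsv["s", ] <= rule$sat_floor
  matrix(light, d[1], d[2])
}

#' Extract labeled patches from a cube, rejecting blank-light tiles
#'
#' Tiles the cube on the [tile_grid()], renders each tile's RGB footprint,
#' and retains a tile iff its light fraction does not exceed the rule's
#' threshold. Every retained patch inherits the cube's weak label.
#' Decisions are local to each patch footprint, hence order-independent.
#'
#' @param cube Labeled [hs_cube()] (stage `"reduced"` or
#'   `"transmittance"`); an unlabeled cube is an error.
#' @param rule A [rejection_rule()].
#' @param patch Patch side in pixels.
#' @param rgb Optional precomputed RGB rendering of the whole cube (saves
#'   recomputation); defaults to `synthesize_rgb(cube)`.
#' @return A `patch_set`: list with `tensors` (n_retained x patch x patch x
#'   bands array, `NULL` when nothing is retained) and `info`, a tibble
#'   with one row per *tiled* position (cube id, patient, roi, label, grid
#'   position, `light_fraction`, `retained`, and `tensor_idx` indexing into
#'   `tensors` for retained rows).
#' @export
extract_patches <- function(cube, rule = rejection_rule(), patch = 87L, rgb = NULL) {
  stopifnot(inherits(cube, "hs_cube"))
  if (cube$label == "unknown") abort("Cube must carry a class label to be patched.")
  d <- dim(cube$data)
  grid <- tile_grid(d[1], d[2], patch)
  rgb <- rgb %||% synthesize_rgb(cube)

  n <- nrow(grid)
  lf <- numeric(n)
  for (i in seq_len(n)) {
    rows <- grid$row0[i] + seq_len(patch)
    cols <- grid$col0[i] + seq_len(patch)
    lf[i] <- light_fraction(rgb[rows, cols, , drop = FALSE], rule)
  }
  retained <- lf <= rule$max_light_fraction

  tensors <- NULL
  if (any(retained)) {
    keep <- which(retained)
    tensors <- array(0, c(length(keep), patch, patch, d[3]))
    for (k in seq_along(keep)) {
      i <- keep[k]
      tensors[k, , , ] <- cube$data[grid$row0[i] + seq_len(patch),
                                    grid$col0[i] + seq_len(patch), , drop = FALSE]
    }
  }
  info <- dplyr::mutate(grid,
    cube_id = cube_id(cube), patient_id = cube$patient_id, roi_id = cube$roi_id,
    label = cube$label, light_fraction = lf, retained = retained,
    augmented = FALSE,
    tensor_idx = ifelse(retained, cumsum(retained), NA_integer_),
    .before = 1L)
  new_patch_set(tensors, info, bands = d[3], patch = patch)
}

new_patch_set <- function(tensors, info, bands, patch) {
  structure(list(tensors = tensors, info = info, bands = bands, patch = patch),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d retained / %d tiled patches (%d x %d x %d)\n",
              n_patches(x), nrow(x$info), x$patch, x$patch, x$bands))
  if (n_patches(x)) print(table(retained_info(x)$label))
  invisible(x)
}

#' Number of retained patches in a patch set
#' @param patches A `patch_set`.
#' @return Integer count.
#' @export
n_patches <- function(patches) {
  if (is.null(patches$tensors)) 0L else dim(patches$tensors)[1]
}

# Metadata of retained patches only, ordered by tensor index.
retained_info <- function(patches) {
  info <- dplyr::filter(patches$info, .data$retained)
  dplyr::arrange(info, .data$tensor_idx)
}

#' Combine patch sets from several cubes
#' @param ... `patch_set` objects with identical patch size and band count.
#' @return A single `patch_set`.
#' @export
bind_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "patch_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) > 0L, all(vapply(sets, inherits, TRUE, "patch_set")))
  patch <- sets[[1]]$patch; bands <- sets[[1]]$bands
  for (s in sets) {
    if (s$patch != patch || s$bands != bands) {
      abort("All patch sets must share patch size and band count.")
    }
  }
  counts <- vapply(sets, n_patches, 0L)
  total <- sum(counts)
  tensors <- NULL
  if (total > 0L) {
    tensors <- array(0, c(total, patch, patch, bands))
    at <- 0L
    for (s in sets) {
      if (n_patches(s) > 0L) {
        tensors[at + seq_len(n_patches(s)), , , ] <- s$tensors
        at <- at + n_patches(s)
      }
    }
  }
  offset <- c(0L, cumsum(counts))[seq_along(sets)]
  info <- dplyr::bind_rows(lapply(seq_along(sets), function(i) {
    dplyr::mutate(sets[[i]]$info,
                  tensor_idx = .data$tensor_idx + offset[i])
  }))
  new_patch_set(tensors, info, bands = bands, patch = patch)
}

# Subset retained patches of a set by tensor index; drops non-retained rows.
subset_patches <- function(patches, idx) {
  stopifnot(inherits(patches, "patch_set"))
  info <- retained_info(patches)[idx, , drop = FALSE]
  tensors <- patches$tensors[info$tensor_idx, , , , drop = FALSE]
  info$tensor_idx <- seq_len(nrow(info))
  new_patch_set(tensors, info, bands = patches$bands, patch = patches$patch)
}
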