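#' Sliding-window offsets over an image
#'
#' Windows of side `patch` anchored every `stride` pixels while they fit,
#' row-major. Overlapping windows (stride 23 against an 87-pixel window by
#' default) trade patch-level granularity for enough heat-map resolution
#' to be interpretable; with `stride = patch` the offsets reduce exactly
#' to the non-overlapping [tile_grid()].
#'
#' @param lines,samples Image size in pixels.
#' @param patch Window side (default 87).
#' @param stride Step between window anchors (default 23).
#' @return Tibble of 0-based `(row0, col0)` offsets with grid indices;
#'   empty when the image is smaller than the window.
#' @export
sliding_offsets <- function(lines, samples, patch = 87L, stride = 23L) {
  if (stride < 1L) abort("`stride` must be at least 1.")
  if (lines < patch || samples < patch) {
    return(tibble(grid_row = integer(), grid_col = integer(),
                  row0 = integer(), col0 = integer()))
  }
  nr <- (lines - patch) %/% stride + 1L
  nc <- (samples - patch) %/% stride + 1L
  grid <- expand.grid(grid_col = seq_len(nc) - 1L, grid_row = seq_len(nr) - 1L)
  tibble(grid_row = grid$grid_row, grid_col = grid$grid_col,
         row0 = grid$grid_row * stride, col0 = grid$grid_col * stride)
}

#' Render a tumor-probability heat map over a whole cube
#'
#' Scores every sliding window with the classifier (no blank-light
#' rejection is applied at inference — specimen-free windows simply score
#' low) and distributes window probabilities back to pixels: each pixel's
#' overlay value is the unweighted mean of all windows covering it, an
#' order-independent convex combination that stays in \[0, 1\]. Edge
#' margins not covered by any full window inherit the nearest covered
#' pixel's value for rendering only; the probability grid itself contains
#' no extrapolated cells.
#'
#' @param model An `hsi_cnn`, or — mainly for testing — any function
#'   mapping an `s x s x B` window tensor to a tumor probability.
#' @param cube A labeled or unlabeled [hs_cube()] whose band count matches
#'   the model input.
#' @param patch Window side (default: the model's input side).
#' @param stride Anchor step in pixels (default 23).
#' @return A `heat_map`: probability `grid` (matrix, windows as cells),
#'   pixel `overlay` (lines x samples matrix), the offsets used, and the
#'   source cube id.
#' @export
render_heatmap <- function(model, cube, patch = NULL, stride = 23L) {
  stopifnot(inherits(cube, "hs_cube"))
  d <- dim(cube$data)
  if (inherits(model, "hsi_cnn")) {
    patch <- patch %||% model$spec$input_side
    if (model$spec$input_bands != d[3]) {
      abort(sprintf("Band mismatch: model expects %d bands, cube has %d.",
                    model$spec$input_bands, d[3]))
    }
    score <- function(x) {
      cnn_forward(model$params, model$spec, normalize_patch(x, model),
                  training = FALSE)$probs[2L]
    }
  } else if (is.function(model)) {
    patch <- patch %||% 87L
    score <- model
  } else {
    abort("`model` must be an hsi_cnn or a scoring function.")
  }

  offsets <- sliding_offsets(d[1], d[2], patch, stride)
  nr <- if (nrow(offsets)) max(offsets$grid_row) + 1L else 0L
  nc <- if (nrow(offsets)) max(offsets$grid_col) + 1L else 0L
  grid <- matrix(NA_real_, nr, nc)

  acc <- matrix(0, d[1], d[2]); cov <- matrix(0, d[1], d[2])
  for (i in seq_len(nrow(offsets))) {
    rows <- offsets$row0[i] + seq_len(patch)
    cols <- offsets$col0[i] + seq_len(patch)
    p <- score(cube$data[rows, cols, , drop = FALSE])
    grid[offsets$grid_row[i] + 1L, offsets$grid_col[i] + 1L] <- p
    acc[rows, cols] <- acc[rows, cols] + p
    cov[rows, cols] <- cov[rows, cols] + 1
  }

  overlay <- matrix(NA_real_, d[1], d[2])
  covered <- cov > 0
  overlay[covered] <- acc[covered] / cov[covered]
  if (any(covered) && !all(covered)) {
    # Edge margins: replicate the nearest covered row/column (rendering only).
    cov_rows <- which(rowSums(covered) > 0)
    cov_cols <- which(colSums(covered) > 0)
    nearest <- function(i, pool) pool[which.min(abs(pool - i))]
    for (i in seq_len(d[1])) {
      src_r <- nearest(i, cov_rows)
      for (j in which(is.na(overlay[i, ]))) {
        overlay[i, j] <- overlay[src_r, nearest(j, cov_cols)]
      }
    }
  }

  structure(list(grid = grid, overlay = overlay, offsets = offsets,
                 patch = patch, stride = stride, cube_id = cube_id(cube),
                 label = cube$label),
            class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("<heat_map> %d x %d windows (patch %d, stride %d) over cube %s\n",
              nrow(x$grid), ncol(x$grid), x$patch, x$stride, x$cube_id))
  invisible(x)
}

#' @method tidy heat_map
#' @export
tidy.heat_map <- function(x, ...) {
  dplyr::mutate(x$offsets,
                p_tumor = as.vector(t(x$grid))[x$grid_row * ncol(x$grid) + x$grid_col + 1L])
}

#' Heat-map rendering
#'
#' Blue-to-red tumor-probability overlay, the usual reading in digital
#' pathology review (red = likely tumor).
#'
#' @param object A `heat_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot heat_map
#' @export
autoplot.heat_map <- function(object, ...) {
  df <- expand.grid(line = seq_len(nrow(object$overlay)),
                    sample = seq_len(ncol(object$overlay)))
  df$p <- as.vector(object$overlay)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$line, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "blue", high = "red", limits = c(0, 1),
                                 name = "P(tumor)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$cube_id, x = NULL, y = NULL)
}
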