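#' Fit a principal-component model on training feature vectors
#'
#' Mean-centered PCA (no scaling, no whitening) of the 285-element
#' normalized spectrogram vectors, computed by singular value decomposition
#' via [stats::prcomp]. The first `n_components` directions, ordered by
#' decreasing explained variance, are retained. Component signs are fixed
#' deterministically: the coordinate of largest absolute value in each
#' direction is made positive, so repeated fits on the same data are
#' identical.
#'
#' The model must only ever be fitted on training data; validation and
#' test vectors are projected through the frozen model ([pca_project]).
#'
#' @param train_vectors Numeric matrix, one row per training segment
#'   (columns = 285 features), or a list of equal-length vectors.
#' @param n_components Number of directions to keep (default 25). If the
#'   training set cannot support that many (rank deficit), fewer are
#'   returned with a warning.
#' @return A `pca_model` with `mean` (length-p), `components`
#'   (k x p, orthonormal rows) and `explained_variance` (length-k,
#'   non-increasing).
#' @export
fit_pca <- function(train_vectors, n_components = 25L) {
  if (is.list(train_vectors) && !is.data.frame(train_vectors)) {
    train_vectors <- do.call(rbind, train_vectors)
  }
  x <- as.matrix(train_vectors)
  if (nrow(x) == 0) stopf("no training vectors supplied")
  k_max <- min(nrow(x) - 1L, ncol(x))
  k <- min(n_components, k_max)
  if (k < n_components) {
    warning(sprintf(
      "training set supports only %d components (requested %d)", k,
      n_components), call. = FALSE)
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  comps <- t(p$rotation)            # k x p
  # deterministic sign: largest-|coordinate| entry positive
  for (i in seq_len(nrow(comps))) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  structure(
    list(mean = p$center, components = comps,
         explained_variance = p$sdev[seq_len(k)]^2),
    class = "pca_model"
  )
}

#' Project feature vectors onto a fitted PCA model
#'
#' Scores are `components %*% (x - mean)`; test vectors use the
#' training-fitted model unchanged.
#'
#' @param model A `pca_model` from [fit_pca].
#' @param vectors A single vector or a matrix with one row per segment.
#' @return A matrix of scores (rows = inputs, columns = components); a
#'   single input vector yields a 1-row matrix.
#' @export
pca_project <- function(model, vectors) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (ncol(vectors) != length(model$mean)) {
    stopf("vectors have %d columns, model expects %d",
          ncol(vectors), length(model$mean))
  }
  sweep(vectors, 2, model$mean) %*% t(model$components)
}

# Center-out spiral layout for a (2r+1) x (2r+1) grid: rank 1 at the
# center; each ring starts immediately right of center on its row and
# proceeds clockwise (right edge down, bottom edge leftwards, left edge
# up, top edge rightwards). Returns an n x 2 matrix of (row, col), 1-based.
spiral_layout <- function(side = 5L) {
  c0 <- (side + 1L) %/% 2L
  cells <- matrix(c(c0, c0), 1, 2)
  for (r in seq_len(c0 - 1L)) {
    ring <- rbind(
      cbind(c0:(c0 + r), c0 + r),               # start right of center, go down
      cbind(c0 + r, (c0 + r - 1):(c0 - r)),     # bottom edge, leftwards
      cbind((c0 + r - 1):(c0 - r), c0 - r),     # left edge, upwards
      cbind(c0 - r, (c0 - r + 1):(c0 + r)),     # top edge, rightwards
      if (r >= 2) cbind((c0 - r + 1):(c0 - 1), c0 + r)  # right edge, down to start
    )
    cells <- rbind(cells, ring)
  }
  dimnames(cells) <- list(NULL, c("row", "col"))
  cells
}

#' Fixed rank-to-cell layout of the 5 x 5 PC grid
#'
#' The published constant mapping from principal-component rank (1-25) to
#' grid cell: rank 1 (the most significant PC) sits at the center cell
#' (row 3, column 3); ranks 2-9 fill the inner ring clockwise starting
#' immediately right of center; ranks 10-25 fill the outer ring the same
#' way. The mapping is a bijection, frozen by a golden test.
#'
#' @return A 25 x 2 integer matrix of 1-based `(row, col)` positions,
#'   indexed by PC rank.
#' @export
pc_grid_layout <- function() {
  layout <- spiral_layout(5L)
  storage.mode(layout) <- "integer"
  layout
}

#' Arrange 25 PC scores into the center-out 5 x 5 grid
#'
#' @param scores Numeric vector of exactly 25 scores, ordered by PC rank
#'   (most significant first).
#' @return A `pc_grid`: a 5 x 5 matrix with score 1 at the center cell.
#' @seealso [flatten_grid] for the inverse, [pc_grid_layout] for the
#'   rank-to-cell table.
#' @export
arrange_center_out <- function(scores) {
  if (length(scores) != 25) {
    stopf("expected exactly 25 scores, got %d", length(scores))
  }
  g <- matrix(0, 5, 5)
  g[pc_grid_layout()] <- as.numeric(scores)
  structure(g, class = c("pc_grid", "matrix"))
}

#' @rdname arrange_center_out
#' @param grid A 5 x 5 `pc_grid`.
#' @return `flatten_grid` returns the scores in PC-rank order (inverse of
#'   `arrange_center_out`).
#' @export
flatten_grid <- function(grid) {
  if (!all(dim(grid) == c(5, 5))) stopf("expected a 5 x 5 grid")
  grid[pc_grid_layout()]
}

# Rearrange an n x 25 score matrix into n x 25 grid-flattened rows
# (column-major 5x5 layout), the input format the CNN consumes.
scores_to_grid_rows <- function(scores) {
  lin <- as.integer((pc_grid_layout()[, "col"] - 1L) * 5L +
                      pc_grid_layout()[, "row"])
  out <- matrix(0, nrow(scores), 25L)
  out[, lin] <- scores
  out
}

#' Per-stage variability of the leading principal component
#'
#' The scalar EMG summary statistic: the sample standard deviation
#' (n - 1 denominator) of the first PC score across all segments of one
#' stage of one leg.
#'
#' @param pc1_scores Numeric vector of first-PC scores (>= 2 values).
#' @return A single non-negative number.
#' @export
emg_feature_std <- function(pc1_scores) {
  pc1_scores <- as.numeric(pc1_scores)
  if (length(pc1_scores) < 2) {
    stopf("need at least 2 scores to compute a standard deviation")
  }
  stats::sd(pc1_scores)
}
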