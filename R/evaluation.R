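#' Cross-validation result container
#'
#' @param protocol One of `"binary_10fold"`, `"lolo_binary"`,
#'   `"multiclass_10fold"`, `"hourly_binary_10fold"`.
#' @param accuracies Per-unit accuracies in percent (per fold, or per
#'   held-out leg for LOLO).
#' @param unit_names Names of the evaluation units.
#' @param confusion K x K count matrix, predicted classes on rows, true
#'   classes on columns.
#' @param class_labels Class names in label order.
#' @return A `cv_result`; `$mean` and `$std` are the sample mean and
#'   standard deviation of the per-unit accuracies.
#' @export
cv_result <- function(protocol, accuracies, unit_names, confusion,
                      class_labels) {
  protocol <- match.arg(protocol, c("binary_10fold", "lolo_binary",
                                    "multiclass_10fold",
                                    "hourly_binary_10fold"))
  accuracies <- as.numeric(accuracies)
  if (any(accuracies < 0 | accuracies > 100)) {
    stopf("accuracies must be percentages in [0, 100]")
  }
  k <- length(class_labels)
  confusion <- matrix(as.numeric(confusion), k, k,
                      dimnames = list(predicted = class_labels,
                                      true = class_labels))
  structure(
    list(protocol = protocol, accuracies = accuracies,
         unit_names = as.character(unit_names),
         mean = mean(accuracies),
         std = if (length(accuracies) > 1) stats::sd(accuracies) else 0,
         confusion = confusion, class_labels = as.character(class_labels)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %.1f +/- %.1f%% over %d unit(s)\n",
              x$protocol, x$mean, x$std, length(x$accuracies)))
  cat("  units:", paste(sprintf("%s=%.1f", x$unit_names, x$accuracies),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Overall accuracy implied by a confusion matrix
#' @param confusion Square count matrix (predicted x true).
#' @return Percentage, `100 * trace / total`.
#' @export
accuracy_from_confusion <- function(confusion) {
  100 * sum(diag(as.matrix(confusion))) / sum(confusion)
}

#' Random 10-fold partition with a fixed rotation schedule
#'
#' Segments are partitioned into `k` folds of sizes differing by at most
#' one. With `strata` given (the usual case: stage labels), assignment is
#' stratified so every fold sees every class. The rotation schedule is
#' fixed: in rotation `f`, fold `f` is the test set, fold `(f mod k) + 1`
#' the validation set, and the remaining `k - 2` folds the training set;
#' every fold is the test fold exactly once.
#'
#' @param n_segments Number of segments to partition.
#' @param k Number of folds (default 10).
#' @param seed Integer seed; identical seeds give identical plans.
#' @param strata Optional length-`n_segments` grouping vector for
#'   stratified assignment.
#' @return A `fold_plan`: `$fold` (fold id per segment, 1..k), `$k`, and
#'   `$rotations`, a list of `k` lists with `test`, `val`, `train` fold
#'   ids.
#' @export
make_folds <- function(n_segments, k = 10L, seed = 1L, strata = NULL) {
  n_segments <- as.integer(n_segments)
  k <- as.integer(k)
  if (n_segments < k) {
    stopf("cannot split %d segments into %d folds", n_segments, k)
  }
  if (is.null(strata)) strata <- rep(1L, n_segments)
  stopifnot(length(strata) == n_segments)
  fold <- integer(n_segments)
  with_seed(derive_seed(seed, 0L), {
    ctr <- 0L
    for (lev in unique(strata)) {
      idx <- which(strata == lev)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((ctr + seq_along(idx) - 1L) %% k) + 1L
      ctr <- ctr + length(idx)
    }
  })
  rotations <- lapply(seq_len(k), function(f) {
    v <- (f %% k) + 1L
    list(test = f, val = v, train = setdiff(seq_len(k), c(f, v)))
  })
  structure(list(fold = fold, k = k, rotations = rotations),
            class = "fold_plan")
}

#' Confusion matrix with predicted classes on rows
#'
#' @param true_labels,predicted_labels Equal-length 0-based integer label
#'   vectors.
#' @param k Number of classes.
#' @param class_labels Optional class names (length `k`).
#' @return K x K count matrix; entry `(p, t)` counts items predicted `p`
#'   with true class `t`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, k,
                             class_labels = NULL) {
  stopifnot(length(true_labels) == length(predicted_labels))
  true_labels <- check_labels(true_labels, k)
  predicted_labels <- check_labels(predicted_labels, k)
  if (is.null(class_labels)) class_labels <- as.character(seq_len(k) - 1L)
  m <- matrix(0, k, k, dimnames = list(predicted = class_labels,
                                       true = class_labels))
  for (i in seq_along(true_labels)) {
    m[predicted_labels[i] + 1L, true_labels[i] + 1L] <-
      m[predicted_labels[i] + 1L, true_labels[i] + 1L] + 1
  }
  m
}

#' Chance-level accuracy for a k-class problem
#'
#' @param k Number of classes (>= 2).
#' @return `100 / k`, rounded to one decimal (50 for 2 classes, 11.1 for
#'   9).
#' @export
chance_level <- function(k) {
  if (!is.numeric(k) || k < 2) stopf("k must be at least 2")
  round(100 / k, 1)
}

# Protocol definitions: stages used and 0-based label per stage.
protocol_spec <- function(protocol) {
  switch(protocol,
    binary = list(stages = c("T-1", "T1"),
                  labels = c("T-1" = 0L, "T1" = 1L),
                  classes = c("T-1", "T1"), n_classes = 2L,
                  result = "binary_10fold"),
    multiclass = list(stages = STAGES,
                      labels = stats::setNames(0:8, STAGES),
                      classes = STAGES, n_classes = 9L,
                      result = "multiclass_10fold"),
    hourly = list(stages = paste0("T", 1:8),
                  labels = stats::setNames(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
                                           paste0("T", 1:8)),
                  classes = c("T1-T4", "T5-T8"), n_classes = 2L,
                  result = "hourly_binary_10fold"),
    stopf("unknown protocol '%s'", protocol))
}

# Shared per-rotation pipeline: leakage-safe refit of normalization and
# PCA on training rows only, then CNN train/predict.
fit_and_score <- function(raw_mat, labels, train_idx, val_idx, test_idx,
                          config, scope_id, rotation_seed) {
  norm <- fit_norm_stats(list(raw_mat[train_idx, , drop = FALSE]), scope_id)
  v <- if (norm$hi > norm$lo) {
    pmin(pmax((raw_mat - norm$lo) / (norm$hi - norm$lo), 0), 1)
  } else raw_mat * 0
  pca <- fit_pca(v[train_idx, , drop = FALSE], 25L)
  grids <- scores_to_grid_rows(pca_project(pca, v))
  cfg <- config
  cfg$seed <- rotation_seed
  model <- build_cnn(cfg)
  model <- train_cnn(model, grids[train_idx, , drop = FALSE],
                     labels[train_idx],
                     grids[val_idx, , drop = FALSE], labels[val_idx])
  pred <- predict_cnn(model, grids[test_idx, , drop = FALSE])
  list(true = labels[test_idx], predicted = pred$labels, pca = pca,
       norm = norm)
}

#' Within-leg 10-fold cross-validation
#'
#' Runs one of the three within-leg protocols on a single leg: `"binary"`
#' (baseline `T-1` vs first post-surgery point `T1`), `"multiclass"` (all
#' nine stages), or `"hourly"` (`T1`-`T4` vs `T5`-`T8`, segments pooled by
#' hour group). Segments of the requested stages are partitioned into 10
#' stratified folds; in each of the 10 rotations the normalization
#' percentiles and the PCA are refit on the 8 training folds only, the CNN
#' is trained with the validation fold for early stopping, and accuracy is
#' measured on the test fold. The result carries the 10 per-fold
#' accuracies and the confusion matrix pooled over rotations, so its total
#' equals the number of segments.
#'
#' @param leg A [leg_dataset] containing the protocol's stages.
#' @param protocol `"binary"`, `"multiclass"` or `"hourly"`.
#' @param config Optional [cnn_config]; defaults to the standard
#'   architecture for the protocol's class count. Its `n_classes` must
#'   match the protocol.
#' @param seed Integer seed for fold assignment and per-rotation training.
#' @return A [cv_result].
#' @export
run_per_leg_cv <- function(leg, protocol = c("binary", "multiclass",
                                             "hourly"),
                           config = NULL, seed = 1L) {
  protocol <- match.arg(protocol)
  ps <- protocol_spec(protocol)
  if (is.null(config)) config <- cnn_config(ps$n_classes, seed = seed)
  if (config$n_classes != ps$n_classes) {
    stopf("config has %d classes but protocol '%s' needs %d",
          config$n_classes, protocol, ps$n_classes)
  }
  dat <- leg_spectrograms(leg, ps$stages)
  raw_mat <- do.call(rbind, lapply(dat$spectrograms, vectorize_spectrogram))
  labels <- unname(ps$labels[dat$stage])
  plan <- make_folds(dat$n, 10L, seed = seed, strata = dat$stage)
  scope <- paste0(leg$pig_id, "-", leg$leg)
  conf <- matrix(0, ps$n_classes, ps$n_classes)
  accs <- numeric(plan$k)
  for (f in seq_len(plan$k)) {
    rot <- plan$rotations[[f]]
    sc <- fit_and_score(
      raw_mat, labels,
      train_idx = which(plan$fold %in% rot$train),
      val_idx = which(plan$fold == rot$val),
      test_idx = which(plan$fold == rot$test),
      config = config, scope_id = scope,
      rotation_seed = derive_seed(seed, f))
    cm <- confusion_matrix(sc$true, sc$predicted, ps$n_classes, ps$classes)
    conf <- conf + cm
    accs[f] <- accuracy_from_confusion(cm)
  }
  cv_result(ps$result, accs, sprintf("fold%02d", seq_len(plan$k)),
            conf, ps$classes)
}

#' Leave-one-leg-out binary cross-validation
#'
#' The cross-subject protocol: for each leg in turn, the normalization
#' percentiles and the PCA are fitted on the pooled segments of the other
#' legs only, the CNN is trained on those legs (with an internal seeded,
#' label-stratified 90/10 train/validation split for early stopping), and
#' accuracy is measured on every segment of the held-out leg. The held-out
#' leg never contributes to normalization, PCA, or training.
#'
#' @param legs List of at least two [leg_dataset]s, each containing both
#'   `T-1` and `T1`.
#' @param config Optional binary [cnn_config].
#' @param seed Integer seed.
#' @return A [cv_result] with one accuracy per held-out leg.
#' @export
run_lolo_cv <- function(legs, config = NULL, seed = 1L) {
  if (length(legs) < 2) stopf("LOLO needs at least 2 legs")
  ps <- protocol_spec("binary")
  if (is.null(config)) config <- cnn_config(2L, seed = seed)
  if (config$n_classes != 2L) stopf("LOLO is a binary protocol")
  dats <- lapply(legs, leg_spectrograms, stages = ps$stages)
  mats <- lapply(dats, function(d) {
    do.call(rbind, lapply(d$spectrograms, vectorize_spectrogram))
  })
  labs <- lapply(dats, function(d) unname(ps$labels[d$stage]))
  unit <- vapply(legs, function(l) paste0(l$pig_id, "-", l$leg), "")
  if (anyDuplicated(unit)) stopf("legs must have distinct pig/leg identities")
  conf <- matrix(0, 2, 2)
  accs <- numeric(length(legs))
  for (h in seq_along(legs)) {
    tr_mat <- do.call(rbind, mats[-h])
    tr_lab <- unlist(labs[-h])
    n_tr <- nrow(tr_mat)
    # stacked matrix: training legs first, held-out leg last
    raw_mat <- rbind(tr_mat, mats[[h]])
    labels <- c(tr_lab, labs[[h]])
    test_idx <- n_tr + seq_len(nrow(mats[[h]]))
    # internal stratified 90/10 split of the training legs' segments
    val_idx <- with_seed(derive_seed(seed, 50L + h), {
      unlist(lapply(split(seq_len(n_tr), tr_lab), function(ix) {
        sample(ix, max(1L, round(0.1 * length(ix))))
      }), use.names = FALSE)
    })
    train_idx <- setdiff(seq_len(n_tr), val_idx)
    sc <- fit_and_score(raw_mat, labels, train_idx, val_idx, test_idx,
                        config, scope_id = paste0("not-", unit[h]),
                        rotation_seed = derive_seed(seed, h))
    cm <- confusion_matrix(sc$true, sc$predicted, 2L, ps$classes)
    conf <- conf + cm
    accs[h] <- accuracy_from_confusion(cm)
  }
  cv_result("lolo_binary", accs, unit, conf, ps$classes)
}
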