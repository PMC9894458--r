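test_that("make_folds partitions with near-equal sizes and full rotation", {
  plan <- make_folds(599, 10, seed = 1)
  expect_length(plan$fold, 599)
  sizes <- tabulate(plan$fold, 10)
  expect_equal(sort(sizes), c(59, rep(60, 9)))  # 599 = 9*60 + 59
  expect_setequal(unique(plan$fold), 1:10)
  # every fold is the test fold exactly once; roles partition the folds
  tests <- vapply(plan$rotations, `[[`, 0L, "test")
  expect_setequal(tests, 1:10)
  for (rot in plan$rotations) {
    expect_length(rot$train, 8)
    expect_setequal(c(rot$test, rot$val, rot$train), 1:10)
  }
  expect_identical(make_folds(599, 10, seed = 1)$fold, plan$fold)
  expect_false(identical(make_folds(599, 10, seed = 2)$fold, plan$fold))
  expect_error(make_folds(5, 10), "cannot split")
})

test_that("stratified folds see every class", {
  strata <- rep(c("a", "b"), each = 100)
  plan <- make_folds(200, 10, seed = 3, strata = strata)
  tab <- table(plan$fold, strata)
  expect_true(all(tab == 10))
})

test_that("confusion_matrix counts predicted x true and implies accuracy", {
  tr <- c(0, 0, 1, 1, 2, 2); pr <- c(0, 1, 1, 1, 2, 0)
  m <- confusion_matrix(tr, pr, 3)
  expect_equal(sum(m), 6)
  expect_equal(m[2, 1], 1)  # predicted 1, true 0
  expect_equal(accuracy_from_confusion(m), 100 * mean(tr == pr))
  # perfect predictions -> diagonal
  mp <- confusion_matrix(0:2, 0:2, 3)
  expect_equal(unname(mp), diag(3))
  # all predicted class 0 -> only row 1 populated
  m0 <- confusion_matrix(c(0, 1, 1), c(0, 0, 0), 2)
  expect_equal(sum(m0[2, ]), 0)
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 2), "labels")
})

test_that("chance levels match the printed values", {
  expect_equal(chance_level(2), 50)
  expect_equal(chance_level(9), 11.1)
  expect_equal(chance_level(4), 25)
  expect_error(chance_level(1), "at least 2")
})

test_that("cv_result validates and summarizes", {
  r <- cv_result("binary_10fold", c(90, 100), c("f1", "f2"),
                 matrix(c(10, 1, 0, 9), 2), c("T-1", "T1"))
  expect_equal(r$mean, 95)
  expect_equal(r$std, stats::sd(c(90, 100)))
  expect_error(cv_result("binary_10fold", 120, "f1", diag(2), c("a", "b")),
               "percentages")
})

test_that("per-rotation preprocessing never reads the test fold", {
  # sentinel: replace the test rows with a huge marker; the fitted
  # normalization stats and PCA must be bit-identical
  set.seed(50)
  raw <- matrix(rexp(60 * 285), 60, 285)
  labels <- rep(0:1, 30)
  train_idx <- 1:40; val_idx <- 41:50; test_idx <- 51:60
  cfg <- quick_cfg(2, epochs = 2)
  a <- vibemg:::fit_and_score(raw, labels, train_idx, val_idx, test_idx,
                              cfg, "legX", 7L)
  raw2 <- raw
  raw2[test_idx, ] <- 1e6
  b <- vibemg:::fit_and_score(raw2, labels, train_idx, val_idx, test_idx,
                              cfg, "legX", 7L)
  expect_identical(a$norm$lo, b$norm$lo)
  expect_identical(a$norm$hi, b$norm$hi)
  expect_identical(a$pca$mean, b$pca$mean)
  expect_identical(a$pca$components, b$pca$components)
})

test_that("binary CV on a strong-effect synthetic leg is near-perfect", {
  leg <- tiny_leg(duration_s = 10, seed = 13)
  res <- run_per_leg_cv(leg, "binary", config = quick_cfg(2, epochs = 25,
                                                          patience = 8),
                        seed = 1)
  expect_s3_class(res, "cv_result")
  expect_gte(res$mean, 95)
  # confusion totals equal the number of segments over all rotations
  n_seg <- 2 * length(segment_signal(leg$recordings[["T-1"]]))
  expect_equal(sum(res$confusion), n_seg)
  # reported mean +/- std equals recomputation from stored accuracies
  expect_equal(res$mean, mean(res$accuracies))
  expect_equal(res$std, stats::sd(res$accuracies))
})

test_that("binary CV on a null leg sits at chance", {
  leg <- null_leg(duration_s = 10, seed = 17)
  res <- run_per_leg_cv(leg, "binary", config = quick_cfg(2, epochs = 15,
                                                          patience = 5),
                        seed = 1)
  expect_gte(res$mean, 40)
  expect_lte(res$mean, 60)
})

test_that("protocol selection, labels and validation", {
  leg <- tiny_leg(duration_s = 6, seed = 19)
  res <- run_per_leg_cv(leg, "hourly", config = quick_cfg(2, epochs = 8,
                                                          patience = 3),
                        seed = 1)
  expect_identical(res$class_labels, c("T1-T4", "T5-T8"))
  expect_identical(res$protocol, "hourly_binary_10fold")
  n_seg <- 8 * length(segment_signal(leg$recordings[["T1"]]))
  expect_equal(sum(res$confusion), n_seg)
  # missing stage errors
  part <- leg_dataset(leg$recordings[c("T-1", "T1")])
  expect_error(run_per_leg_cv(part, "multiclass"), "missing stage")
  expect_error(run_per_leg_cv(leg, "binary", config = quick_cfg(9)),
               "needs 2")
})

test_that("multiclass accuracy beats the max-class-frequency baseline", {
  leg <- tiny_leg(duration_s = 6, seed = 23)
  res <- run_per_leg_cv(leg, "multiclass",
                        config = quick_cfg(9, epochs = 12, patience = 4),
                        seed = 1)
  baseline <- 100 * max(colSums(res$confusion)) / sum(res$confusion)
  expect_gt(res$mean, baseline)
  expect_equal(accuracy_from_confusion(res$confusion),
               100 * sum(diag(res$confusion)) / sum(res$confusion))
})

test_that("LOLO holds the test leg out of every fitted statistic", {
  legs <- suppressWarnings(generate_cohort(3, shared_effect = TRUE,
                                           heterogeneity = 0, seed = 5,
                                           duration_s = 5))
  res <- run_lolo_cv(legs, config = quick_cfg(2, epochs = 10, patience = 4),
                     seed = 1)
  expect_length(res$accuracies, 3)
  expect_identical(res$unit_names, c("P1-L", "P1-R", "P2-L"))
  n_per_leg <- 2 * length(segment_signal(legs[[1]]$recordings[["T-1"]]))
  expect_equal(sum(res$confusion), 3 * n_per_leg)
  expect_error(run_lolo_cv(legs[1]), "at least 2")
  # a leg missing one protocol stage is rejected
  broken <- legs
  broken[[2]] <- leg_dataset(legs[[2]]$recordings[c("T-1", "T2")])
  expect_error(run_lolo_cv(broken, config = quick_cfg(2)), "missing stage")
})
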