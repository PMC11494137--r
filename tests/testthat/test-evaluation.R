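test_that("confusion tallies predictions against labels", {
  expect_equal(
    confusion(c(1, 1, 0, 0), c(.9, .8, .1, .2), 0.5),
    c(TP = 2L, TN = 2L, FP = 0L, FN = 0L)
  )
  expect_equal(confusion(rep(1, 5), rep(0.1, 5), 0.5)[["FN"]], 5L)
  expect_error(confusion(c(1, 0), c(.5)), "equal length")
  expect_error(confusion(integer(), numeric()), "empty")
})

test_that("metrics reproduce the hand-computable confusion cases", {
  perfect <- metrics_report(rep(c(1, 0), each = 50), rep(c(.9, .1), each = 50))
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$MCC, 1)
  expect_equal(perfect$Sn, 1)
  expect_equal(perfect$Sp, 1)
  expect_equal(perfect$F1, 1)

  # balanced random confusion TP=TN=FP=FN=25
  labs <- rep(c(1, 1, 0, 0), each = 25)
  scores <- rep(c(.9, .1, .9, .1), each = 25)
  bal <- metrics_report(labs, scores)
  expect_equal(bal$ACC, 0.5)
  expect_equal(bal$MCC, 0)
  expect_equal(c(bal$TP, bal$TN, bal$FP, bal$FN), rep(25L, 4))

  m <- metrics_report(rep(c(1, 0), each = 10), c(rep(.9, 8), rep(.1, 2), rep(.9, 2), rep(.1, 8)))
  expect_equal(m$ACC, 0.8) # (8+8)/20
  expect_equal(m$Sn, 0.8)
  expect_equal(m$Sp, 0.8)
})

test_that("MCC sign flips when predictions are inverted", {
  set.seed(51)
  labs <- rbinom(200, 1, 0.5)
  scores <- ifelse(labs == 1, stats::rnorm(200, 0.7, 0.2), stats::rnorm(200, 0.3, 0.2))
  m1 <- metrics_report(labs, scores)
  m2 <- metrics_report(labs, 1 - scores)
  expect_equal(m2$MCC, -m1$MCC, tolerance = 1e-12)
})

test_that("roc_curve endpoints, symmetry, and monotone invariance", {
  labs <- c(1, 1, 0, 0)
  r <- roc_curve(labs, c(.9, .8, .2, .1))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  set.seed(52)
  labs <- rbinom(300, 1, 0.5)
  scores <- stats::runif(300)
  r1 <- roc_curve(labs, scores)
  expect_equal(roc_curve(labs, 1 - scores)$auc, 1 - r1$auc, tolerance = 1e-12)
  # AUC invariant under strictly monotone transforms
  expect_equal(roc_curve(labs, exp(3 * scores))$auc, r1$auc, tolerance = 1e-12)
  expect_error(roc_curve(rep(1, 10), stats::runif(10)), "both classes")
})

test_that("roc AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  labs <- rbinom(250, 1, 0.5)
  scores <- stats::runif(250) + 0.3 * labs
  ours <- roc_curve(labs, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labs, scores, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("label-independent scores give AUC near one half", {
  set.seed(54)
  labs <- rbinom(10000, 1, 0.5)
  expect_equal(roc_curve(labs, stats::runif(10000))$auc, 0.5, tolerance = 0.02)
})

test_that("kfold_cv produces a stratified partition with pooled counts", {
  ft <- blob_features(40, d = 4, sep = 4, seed = 55)
  cv <- kfold_cv(ft, fast_config(seed = 9), k = 4)
  # partition: every id exactly once
  expect_setequal(cv$assignment$id, ft$id)
  expect_equal(anyDuplicated(cv$assignment$id), 0L)
  expect_equal(sort(unique(cv$assignment$fold)), 1:4)
  # stratification: both classes in every fold
  joined <- dplyr::left_join(cv$assignment, ft[c("id", "label")], by = "id")
  per_fold <- dplyr::count(joined, .data$fold, .data$label)
  expect_equal(nrow(per_fold), 8L)
  expect_true(all(per_fold$n == 10L))
  # pooled confusion counts sum to dataset size
  expect_equal(cv$pooled$TP + cv$pooled$TN + cv$pooled$FP + cv$pooled$FN, nrow(ft))
  expect_equal(nrow(tidy(cv)), 4L)
  expect_equal(ncol(glance(cv)), 6L)
  expect_error(kfold_cv(ft[c(1:6, 41:46), ], fast_config(), k = 10), "fewer members")
})

test_that("independent_test refuses id leakage and learns separable data", {
  ft <- blob_features(120, d = 5, sep = 5, seed = 56)
  sp <- train_test_split(ft, 0.25, seed = 1)
  rep <- independent_test(sp$train, sp$test, model_config("MLP", max_epochs = 60, seed = 10))
  expect_gte(rep$ACC, 0.9)
  expect_error(independent_test(ft, ft[1:10, ], fast_config()), "leakage")
})

test_that("self_consistency is reproducible and bounded by memorization", {
  ft <- blob_features(10, d = 4, sep = 8, seed = 57)
  cfg <- model_config("MLP", max_epochs = 80, seed = 12)
  r1 <- self_consistency(ft, cfg)
  r2 <- self_consistency(ft, cfg)
  expect_equal(r1$ACC, 1) # wide separation, tiny set: memorized
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("decision_boundary_map splits well-separated blobs across the midline", {
  ft <- blob_features(80, d = 6, sep = 8, seed = 58)
  bm <- decision_boundary_map(ft, model_config("MLP", max_epochs = 60, seed = 13),
    grid_resolution = 21
  )
  expect_equal(nrow(bm$grid), 21L * 21L)
  # classify each lattice cell by which blob centroid it is nearer to
  cent0 <- colMeans(bm$points[bm$points$label == 0, c("pc1", "pc2")])
  cent1 <- colMeans(bm$points[bm$points$label == 1, c("pc1", "pc2")])
  d0 <- sqrt((bm$grid$pc1 - cent0[1])^2 + (bm$grid$pc2 - cent0[2])^2)
  d1 <- sqrt((bm$grid$pc1 - cent1[1])^2 + (bm$grid$pc2 - cent1[2])^2)
  nearer1 <- d1 < d0
  agree <- mean((bm$grid$prob >= 0.5) == nearer1)
  expect_gte(agree, 0.95)
  # tiny lattice contract
  bm2 <- decision_boundary_map(ft, fast_config(seed = 13), grid_resolution = 2)
  expect_equal(nrow(bm2$grid), 4L)
  # constant features cannot be projected
  flat <- ft
  flat[sprintf("f%03d", 0:5)] <- 1
  expect_error(decision_boundary_map(flat, fast_config()), "degenerate")
})

test_that("metrics JSON report round-trips the panel fields", {
  ft <- blob_features(30, d = 4, sep = 5, seed = 59)
  rep <- self_consistency(ft, fast_config(seed = 14))
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(list(MLP = rep), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$reports$MLP$ACC, rep$ACC)
  expect_true(all(c("ACC", "MCC", "Sn", "Sp", "AucRoc", "F1") %in% names(back$reports$MLP)))
})

test_that("plot methods return ggplot objects", {
  ft <- blob_features(30, d = 4, sep = 5, seed = 60)
  r <- roc_curve(ft$label, stats::runif(nrow(ft)) + ft$label)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  cv <- kfold_cv(ft, fast_config(seed = 15), k = 3)
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
  bm <- decision_boundary_map(ft, fast_config(seed = 16), grid_resolution = 5)
  expect_s3_class(ggplot2::autoplot(bm), "ggplot")
  fit <- attr(self_consistency(ft, fast_config(seed = 17)), "model")
  expect_s3_class(plot_training_history(fit), "ggplot")
})
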