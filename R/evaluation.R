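#' Confusion counts at a threshold
#'
#' Tallies predictions (`score >= threshold` is a positive call) against
#' binary labels.
#'
#' @param labels Binary 0/1 label vector.
#' @param scores Numeric score/probability vector of the same length.
#' @param threshold Decision threshold in (0, 1); default 0.5.
#' @return A named integer vector `c(TP, TN, FP, FN)`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(.9, .8, .1, .2))
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  if (!length(labels)) stop("empty input", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)", call. = FALSE)
  y <- as.integer(labels)
  if (anyNA(y) || !all(y %in% 0:1)) stop("labels must be binary 0/1", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  c(
    TP = sum(pred == 1L & y == 1L),
    TN = sum(pred == 0L & y == 0L),
    FP = sum(pred == 1L & y == 0L),
    FN = sum(pred == 0L & y == 1L)
  )
}

.mcc <- function(cm) {
  tp <- as.numeric(cm[["TP"]])
  tn <- as.numeric(cm[["TN"]])
  fp <- as.numeric(cm[["FP"]])
  fn <- as.numeric(cm[["FN"]])
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) return(0) # standard convention when any margin is empty
  (tp * tn - fp * fn) / denom
}

#' Classification metrics report
#'
#' Computes the full metric panel from labels and scores: accuracy
#' `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, Matthews
#' correlation coefficient (0 when any denominator margin is empty), F1
#' `2TP/(2TP+FP+FN)`, and threshold-free AUC-ROC by trapezoidal integration
#' of the ROC curve (`NA` when only one class is present).
#'
#' @inheritParams confusion
#' @return A one-row tibble of class `idp_metrics` with columns `ACC`,
#'   `MCC`, `Sn`, `Sp`, `AucRoc`, `F1`, the confusion counts `TP`, `TN`,
#'   `FP`, `FN`, `n`, and `threshold`.
#' @examples
#' metrics_report(c(1, 1, 0, 0), c(.9, .4, .6, .1))
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  cm <- confusion(labels, scores, threshold)
  tp <- as.numeric(cm[["TP"]])
  tn <- as.numeric(cm[["TN"]])
  fp <- as.numeric(cm[["FP"]])
  fn <- as.numeric(cm[["FN"]])
  n <- tp + tn + fp + fn
  auc <- if (length(unique(labels)) < 2L) NA_real_ else roc_curve(labels, scores)$auc
  out <- tibble::tibble(
    ACC = (tp + tn) / n,
    MCC = .mcc(cm),
    Sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    Sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    AucRoc = auc,
    F1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    TP = cm[["TP"]], TN = cm[["TN"]], FP = cm[["FP"]], FN = cm[["FN"]],
    n = as.integer(n), threshold = threshold
  )
  class(out) <- c("idp_metrics", class(out))
  out
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores, from calling
#' everything negative to calling everything positive, and returns the
#' (FPR, TPR) path with endpoints (0,0) and (1,1) plus its trapezoidal area.
#' The AUC is invariant under any strictly monotone transform of the scores.
#'
#' @inheritParams confusion
#' @return A list of class `idp_roc`: `points` (tibble with `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_curve(c(1, 0, 1, 0), c(.9, .2, .7, .4))$auc
#' @export
roc_curve <- function(labels, scores) {
  y <- as.integer(labels)
  if (length(y) != length(scores)) stop("labels and scores must have equal length", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  n_pos <- sum(ys == 1L)
  n_neg <- sum(ys == 0L)
  tp <- cumsum(ys == 1L)
  fp <- cumsum(ys == 0L)
  # collapse tied scores: keep the last index of each tie block
  keep <- c(ss[-1] != ss[-length(ss)], TRUE)
  tpr <- c(0, tp[keep] / n_pos)
  fpr <- c(0, fp[keep] / n_neg)
  thr <- c(Inf, ss[keep])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(
      points = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
      auc = auc
    ),
    class = "idp_roc"
  )
}

#' @export
print.idp_roc <- function(x, ...) {
  cat("<idp_roc> ", nrow(x$points), " points, AUC = ", signif(x$auc, 4), "\n", sep = "")
  invisible(x)
}

# stratified fold assignment: within each class, shuffled ids dealt
# round-robin; the deal continues across classes so remainder members land on
# different folds and total fold sizes differ by at most one
.stratified_folds <- function(labels, k, seed) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      stop("class ", cls, " has fewer members (", length(idx), ") than folds (", k, ")",
        call. = FALSE
      )
    }
    fold[sample(idx)] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Partitions the dataset into `k` stratified folds (seeded by
#' `config$seed`), trains a fresh model of `config$kind` on each training
#' split — feature standardization refitted inside each split, so no
#' information leaks from held-out folds — and scores the held-out fold.
#' Reports per-fold metrics and the pooled metrics over the concatenated
#' held-out predictions; the pooled report is the primary one, with the
#' per-fold mean and sd as a secondary summary.
#'
#' @param features A labeled feature table (from [feature_table()]), or a
#'   labeled sequence tibble (with `residues`), in which case features are
#'   extracted first.
#' @param config An [model_config()].
#' @param k Number of folds (default 10).
#' @return An object of class `idp_cv`: `pooled` (an `idp_metrics` row),
#'   `per_fold` (metrics tibble with a `fold` column), `assignment` (tibble
#'   `id`, `fold`), `predictions` (tibble `id`, `label`, `score`, `fold`),
#'   `k`, `seed`.
#' @export
kfold_cv <- function(features, config, k = 10L) {
  stopifnot(inherits(config, "idp_config"), k >= 2L)
  features <- .ensure_features(features)
  if (!"label" %in% names(features) || anyNA(features$label)) {
    stop("cross-validation requires labels on every sequence", call. = FALSE)
  }
  fold <- .stratified_folds(features$label, k, config$seed)
  preds <- vector("list", k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    train_tbl <- features[fold != f, , drop = FALSE]
    test_tbl <- features[fold == f, , drop = FALSE]
    fit <- fit_model(config, train_tbl)
    p <- predict_proba(fit, test_tbl)
    preds[[f]] <- tibble::tibble(
      id = test_tbl$id, label = test_tbl$label, score = p, fold = f
    )
    per_fold[[f]] <- dplyr::mutate(
      metrics_report(test_tbl$label, p, config$threshold),
      fold = f, .before = 1L
    )
  }
  all_preds <- dplyr::bind_rows(preds)
  structure(
    list(
      pooled = metrics_report(all_preds$label, all_preds$score, config$threshold),
      per_fold = dplyr::bind_rows(per_fold),
      assignment = tibble::tibble(id = features$id, fold = fold),
      predictions = all_preds,
      k = as.integer(k),
      seed = config$seed,
      kind = config$kind
    ),
    class = "idp_cv"
  )
}

#' @export
print.idp_cv <- function(x, ...) {
  cat("<idp_cv> ", x$kind, ", ", x$k, "-fold, seed ", x$seed, "\n", sep = "")
  cat("pooled: ")
  print(glance(x))
  invisible(x)
}

#' Per-fold cross-validation metrics
#'
#' @param x An `idp_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per fold.
#' @method tidy idp_cv
#' @export
tidy.idp_cv <- function(x, ...) x$per_fold

#' Pooled cross-validation metrics
#'
#' @param x An `idp_cv` object.
#' @param ... Unused.
#' @return A one-row tibble of pooled metrics over all held-out predictions.
#' @method glance idp_cv
#' @export
glance.idp_cv <- function(x, ...) {
  dplyr::select(x$pooled, "ACC", "MCC", "Sn", "Sp", "AucRoc", "F1")
}

#' Independent-test evaluation
#'
#' Fits a model on the training set only — including its feature
#' standardization — and reports metrics on a disjoint test set. Overlapping
#' ids are refused as leakage.
#'
#' @param train,test Labeled feature tables or sequence tibbles.
#' @param config An [model_config()].
#' @return An `idp_metrics` row with attribute `model` (the fitted model).
#' @export
independent_test <- function(train, test, config) {
  stopifnot(inherits(config, "idp_config"))
  train <- .ensure_features(train)
  test <- .ensure_features(test)
  overlap <- intersect(train$id, test$id)
  if (length(overlap)) {
    stop(
      "train/test leakage: id(s) present in both sets: ",
      paste(utils::head(overlap, 5), collapse = ", "),
      call. = FALSE
    )
  }
  fit <- fit_model(config, train)
  p <- predict_proba(fit, test)
  out <- metrics_report(test$label, p, config$threshold)
  attr(out, "model") <- fit
  out
}

#' Seeded stratified train/test split
#'
#' The default construction of an independent test set: a stratified split
#' performed before any training touches the data.
#'
#' @param features A labeled feature table or sequence tibble.
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer RNG seed.
#' @return A list with elements `train` and `test`.
#' @export
train_test_split <- function(features, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  lab <- features$label
  test_idx <- unlist(lapply(unique(lab), function(cls) {
    idx <- which(lab == cls)
    sample(idx, max(1L, round(length(idx) * test_fraction)))
  }))
  list(
    train = features[-test_idx, , drop = FALSE],
    test = features[test_idx, , drop = FALSE]
  )
}

#' Self-consistency (resubstitution) evaluation
#'
#' Trains on the full dataset and evaluates on the same samples. This is the
#' optimistic upper bound of the three protocols: in expectation it is at
#' least as good as matched cross-validation.
#'
#' @param features A labeled feature table or sequence tibble.
#' @param config An [model_config()].
#' @return An `idp_metrics` row with attribute `model`.
#' @export
self_consistency <- function(features, config) {
  stopifnot(inherits(config, "idp_config"))
  features <- .ensure_features(features)
  if (!nrow(features)) stop("empty dataset", call. = FALSE)
  fit <- fit_model(config, features)
  p <- predict_proba(fit, features)
  out <- metrics_report(features$label, p, config$threshold)
  attr(out, "model") <- fit
  out
}

# accept sequences (id/residues) or a ready feature table
.ensure_features <- function(x) {
  stopifnot(is.data.frame(x))
  if ("residues" %in% names(x) && !any(grepl("^f\\d{3}$", names(x)))) {
    return(feature_table(x))
  }
  x
}

#' Decision-boundary map over a 2-D projection
#'
#' Standardizes the features, projects them onto their first two principal
#' components, retrains the configured classifier on the 2-D projection, and
#' evaluates its positive-class probability over a square lattice spanning
#' the projected points with a 10% margin. The result visualizes how the
#' classifier partitions feature space: red regions (high probability) are
#' the disordered-class subspace, blue the ordered one.
#'
#' @param features A labeled feature table or sequence tibble.
#' @param config An [model_config()].
#' @param grid_resolution Lattice points per axis (default 60).
#' @return An object of class `idp_boundary`: `grid` (tibble `pc1`, `pc2`,
#'   `prob`), `points` (tibble `pc1`, `pc2`, `label`), `variance_explained`
#'   (length-2), and `model`.
#' @export
decision_boundary_map <- function(features, config, grid_resolution = 60L) {
  stopifnot(inherits(config, "idp_config"), grid_resolution >= 2L)
  features <- .ensure_features(features)
  if (!"label" %in% names(features) || anyNA(features$label)) {
    stop("decision boundary map requires labels", call. = FALSE)
  }
  if (min(table(features$label)) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  X <- .as_feature_matrix(features)
  sdv <- apply(X, 2L, stats::sd)
  if (all(sdv == 0)) {
    stop("degenerate projection: features have zero variance", call. = FALSE)
  }
  keep <- sdv > 0
  pca <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  if (ncol(pca$x) < 2L || pca$sdev[2] == 0) {
    stop("degenerate projection: fewer than two non-trivial principal components",
      call. = FALSE
    )
  }
  proj <- pca$x[, 1:2, drop = FALSE]
  colnames(proj) <- c("pc1", "pc2")
  proj_tbl <- tibble::tibble(
    pc1 = proj[, 1], pc2 = proj[, 2], label = features$label
  )
  fit <- fit_model(build_model(config, 2L), proj, labels = features$label)
  pad <- function(r) r + c(-1, 1) * 0.1 * diff(r)
  rx <- pad(range(proj[, 1]))
  ry <- pad(range(proj[, 2]))
  grid <- expand.grid(
    pc1 = seq(rx[1], rx[2], length.out = grid_resolution),
    pc2 = seq(ry[1], ry[2], length.out = grid_resolution)
  )
  gp <- predict_proba(fit, as.matrix(grid))
  structure(
    list(
      grid = tibble::as_tibble(cbind(grid, prob = gp)),
      points = proj_tbl,
      variance_explained = (pca$sdev^2 / sum(pca$sdev^2))[1:2],
      model = fit
    ),
    class = "idp_boundary"
  )
}

#' @export
print.idp_boundary <- function(x, ...) {
  cat(
    "<idp_boundary> ", nrow(x$grid), " lattice cells, ",
    nrow(x$points), " projected points; PC1+PC2 explain ",
    round(100 * sum(x$variance_explained), 1), "% of variance\n",
    sep = ""
  )
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' Serializes one or more metric reports (e.g. one per model kind) as a JSON
#' object keyed by report name, fields matching the metric panel headers.
#'
#' @param reports A named list of `idp_metrics` rows (or a single one).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(reports, path) {
  if (inherits(reports, "idp_metrics")) reports <- list(report = reports)
  payload <- lapply(reports, function(r) {
    as.list(dplyr::select(
      tibble::as_tibble(r),
      "ACC", "MCC", "Sn", "Sp", "AucRoc", "F1", "TP", "TN", "FP", "FN", "threshold"
    ))
  })
  jsonlite::write_json(
    list(schema_version = 1L, reports = payload),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
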