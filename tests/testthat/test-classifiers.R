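test_that("model_config validates kinds and rates", {
  cfg <- model_config("cnn", seed = 1)
  expect_equal(cfg$kind, "CNN")
  expect_error(model_config("SVM", seed = 1), "unknown model kind")
  expect_error(model_config("MLP", learning_rate = -1, seed = 1))
})

test_that("build_model produces the documented interfaces", {
  for (k in MODEL_KINDS) {
    m <- build_model(model_config(k, seed = 2), 150L)
    expect_s3_class(m, "idp_model")
    expect_false(m$trained)
    expect_gt(m$n_params, 100)
  }
  # architectures adapt to narrow inputs (used by the boundary map)
  m2 <- build_model(model_config("CNN", seed = 2), 2L)
  expect_s3_class(m2, "idp_model")
})

test_that("analytic gradients match numerical gradients for every head", {
  ns <- asNamespace("idpmoments")
  set.seed(41)
  X <- matrix(stats::rnorm(6 * 20), 6)
  y <- rep(c(0, 1), 3)
  for (k in MODEL_KINDS) {
    layers <- build_model(model_config(k, dropout = 0, hidden = 4L, seed = 3), 20L)$layers
    fw <- ns$.net_forward(layers, X, training = FALSE)
    z <- as.vector(fw$out)
    grads <- ns$.net_backward(layers, fw$caches, matrix(ns$.bce_grad(z, y), ncol = 1))
    worst <- 0
    for (i in seq_along(layers)) {
      for (nm in names(grads[[i]])) {
        P <- layers[[i]]$params[[nm]]
        G <- as.array(grads[[i]][[nm]])
        for (j in sample(length(P), min(5, length(P)))) {
          eps <- 1e-5
          lp <- layers
          lp[[i]]$params[[nm]][j] <- P[j] + eps
          lm <- layers
          lm[[i]]$params[[nm]][j] <- P[j] - eps
          num <- (ns$.bce_loss(as.vector(ns$.net_forward(lp, X)$out), y) -
            ns$.bce_loss(as.vector(ns$.net_forward(lm, X)$out), y)) / (2 * eps)
          worst <- max(worst, abs(num - G[j]) / max(1e-6, abs(num) + abs(G[j])))
        }
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("MLP fits a linearly separable set to near-perfect training accuracy", {
  ft <- blob_features(200, d = 6, sep = 6, seed = 42)
  fit <- fit_model(model_config("MLP", max_epochs = 60, seed = 5), ft)
  p <- predict_proba(fit, ft)
  acc <- mean((p >= 0.5) == ft$label)
  expect_gte(acc, 0.99)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("training is deterministic under a fixed seed", {
  ft <- blob_features(60, d = 4, sep = 3, seed = 43)
  f1 <- fit_model(fast_config(seed = 11), ft)
  f2 <- fit_model(fast_config(seed = 11), ft)
  expect_identical(predict_proba(f1, ft), predict_proba(f2, ft))
  expect_identical(f1$history, f2$history)
})

test_that("fit_model rejects degenerate inputs", {
  ft <- blob_features(30, seed = 44)
  one_class <- dplyr::filter(ft, .data$label == 1)
  expect_error(fit_model(fast_config(), one_class), "single class")
  bad <- ft
  bad$f000[1] <- NA_real_
  expect_error(fit_model(fast_config(), bad), "non-finite")
  expect_error(fit_model(fast_config(), ft, labels = rep(2, nrow(ft))), "binary")
})

test_that("predict_proba enforces training width and row identity", {
  ft <- blob_features(40, d = 4, seed = 45)
  fit <- fit_model(fast_config(seed = 2), ft)
  expect_error(predict_proba(fit, ft[, 1:5]), "width")
  # identical rows must get identical probabilities
  two <- ft[c(1, 1), ]
  p <- predict_proba(fit, two)
  expect_identical(p[1], p[2])
  expect_error(predict_proba(build_model(fast_config(), 4L), ft), "not.*trained")
})

test_that("standardization statistics derive from training data only", {
  ft <- blob_features(50, d = 4, seed = 46)
  fit <- fit_model(fast_config(seed = 3), ft)
  X <- as.matrix(ft[sprintf("f%03d", 0:3)])
  expect_equal(unname(fit$standardization$mean), unname(colMeans(X)))
  expect_equal(unname(fit$standardization$sd), unname(apply(X, 2, stats::sd)))
})

test_that("checkpoints round-trip through JSON", {
  ft <- blob_features(40, d = 4, seed = 47)
  fit <- fit_model(fast_config(seed = 4), ft)
  dir <- withr::local_tempdir()
  save_checkpoint(fit, dir)
  back <- load_checkpoint(dir)
  expect_equal(predict_proba(back, ft), predict_proba(fit, ft), tolerance = 1e-12)
  expect_error(load_checkpoint(file.path(dir, "nope")), "checkpoint")
})

test_that("tidy and glance summarize a fitted model", {
  ft <- blob_features(40, d = 4, seed = 48)
  fit <- fit_model(fast_config(seed = 6), ft)
  td <- tidy(fit)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$kind, "MLP")
  expect_equal(gl$epochs_run, nrow(td))
})
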