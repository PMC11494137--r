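#' Classifier kinds
#'
#' The six trainable heads over the 150-value descriptor.
#' @export
MODEL_KINDS <- c("CNN", "DNN", "MLP", "RNN", "LSTM", "GRU")

#' Classifier configuration
#'
#' Bundles the architecture kind, training hyperparameters, and the seed that
#' makes a training run reproducible. All randomness in model initialization,
#' minibatch shuffling, dropout, and the internal validation split flows from
#' `seed`; there is no implicit global state.
#'
#' @param kind One of `"CNN"`, `"DNN"`, `"MLP"`, `"RNN"`, `"LSTM"`, `"GRU"`.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience, in epochs without validation-loss
#'   improvement (default 10).
#' @param dropout Dropout rate for the dense heads (default 0.3).
#' @param hidden Width of the recurrent layer / dense head (default 64).
#' @param validation_fraction Fraction of the training data held out
#'   internally for early stopping (default 0.1).
#' @param threshold Probability threshold for the positive class used by
#'   downstream confusion metrics (default 0.5).
#' @param seed Integer RNG seed; required for reproducibility.
#' @return An object of class `idp_config` (a list).
#' @examples
#' model_config("MLP", seed = 1)
#' @export
model_config <- function(kind, learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 100L, patience = 10L, dropout = 0.3,
                         hidden = 64L, validation_fraction = 0.1,
                         threshold = 0.5, seed = 1L) {
  kind <- toupper(kind)
  if (!kind %in% MODEL_KINDS) {
    stop(
      "unknown model kind '", kind, "'; must be one of ",
      paste(MODEL_KINDS, collapse = ", "),
      call. = FALSE
    )
  }
  stopifnot(
    learning_rate > 0, batch_size >= 1, max_epochs >= 1,
    patience >= 1, dropout >= 0, dropout < 1, hidden >= 1,
    validation_fraction > 0, validation_fraction < 0.5,
    threshold > 0, threshold < 1
  )
  structure(
    list(
      kind = kind, learning_rate = learning_rate,
      batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
      patience = as.integer(patience), dropout = dropout,
      hidden = as.integer(hidden),
      validation_fraction = validation_fraction,
      threshold = threshold, seed = as.integer(seed)
    ),
    class = "idp_config"
  )
}

#' @export
print.idp_config <- function(x, ...) {
  cat(
    "<idp_config> ", x$kind,
    " | lr ", x$learning_rate, ", batch ", x$batch_size,
    ", epochs <=", x$max_epochs, ", patience ", x$patience,
    ", dropout ", x$dropout, ", seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# how a length-L vector is read as a T x F sequence by the recurrent heads:
# 5 features per step when L divides evenly (150 -> 30 x 5, block-aligned
# with the feature layout), otherwise one feature per step
.seq_shape <- function(input_width) {
  if (input_width %% 5L == 0L && input_width >= 10L) {
    c(steps = input_width %/% 5L, feat = 5L)
  } else {
    c(steps = input_width, feat = 1L)
  }
}

# architecture layer stacks; kernel/pool sizes degrade gracefully for narrow
# inputs (the decision-boundary map retrains heads on 2-D projections)
.build_layers <- function(config, input_width) {
  h <- config$hidden
  drop <- config$dropout
  switch(config$kind,
    MLP = list(
      .layer_dense(input_width, 64L, "relu"),
      .layer_dropout(drop),
      .layer_dense(64L, 32L, "relu"),
      .layer_dropout(drop),
      .layer_dense(32L, 1L, "linear")
    ),
    DNN = list(
      .layer_dense(input_width, 256L, "relu"),
      .layer_dropout(drop),
      .layer_dense(256L, 128L, "relu"),
      .layer_dropout(drop),
      .layer_dense(128L, 64L, "relu"),
      .layer_dropout(drop),
      .layer_dense(64L, 1L, "linear")
    ),
    CNN = {
      k1 <- min(5L, input_width)
      l1 <- input_width - k1 + 1L
      layers <- list(
        .layer_reshape_channel(input_width),
        .layer_conv1d(k1, 1L, 32L, input_width)
      )
      l_cur <- l1
      if (l_cur >= 2L) {
        layers <- c(layers, list(.layer_maxpool2(l_cur, 32L)))
        l_cur <- l_cur %/% 2L
      }
      k2 <- min(3L, l_cur)
      layers <- c(layers, list(.layer_conv1d(k2, 32L, 64L, l_cur)))
      l_cur <- l_cur - k2 + 1L
      c(layers, list(
        .layer_globalmaxpool(l_cur, 64L),
        .layer_dense(64L, 64L, "relu"),
        .layer_dropout(drop),
        .layer_dense(64L, 1L, "linear")
      ))
    },
    RNN = ,
    LSTM = ,
    GRU = {
      shp <- .seq_shape(input_width)
      list(
        .layer_reshape_seq(shp[["steps"]], shp[["feat"]]),
        .layer_recurrent(tolower(config$kind), shp[["feat"]], h),
        .layer_dense(h, 1L, "linear")
      )
    }
  )
}

#' Build an untrained classifier
#'
#' Instantiates the architecture for `config$kind` over inputs of width
#' `input_width`, with seeded weight initialization. The six heads:
#' \describe{
#'   \item{CNN}{the vector as a single-channel 1-D signal: conv(32, kernel 5,
#'     ReLU), max-pool 2, conv(64, kernel 3, ReLU), global max-pool, dense 64
#'     ReLU with dropout, sigmoid output.}
#'   \item{DNN}{dense 256-128-64-1, ReLU, dropout between layers.}
#'   \item{MLP}{dense 64-32-1, ReLU, dropout.}
#'   \item{RNN/LSTM/GRU}{the vector reshaped to a 30-step x 5-feature
#'     sequence (for width 150), one recurrent layer of width `hidden`, dense
#'     sigmoid output on the final hidden state.}
#' }
#'
#' @param config An [model_config()] object.
#' @param input_width Feature-vector width (default 150).
#' @return An object of class `idp_model` with untrained weights;
#'   `$n_params` reports the parameter count.
#' @export
build_model <- function(config, input_width = 150L) {
  stopifnot(inherits(config, "idp_config"), input_width >= 1L)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  layers <- .build_layers(config, as.integer(input_width))
  structure(
    list(
      config = config, layers = layers, input_width = as.integer(input_width),
      n_params = .n_params(layers), trained = FALSE,
      standardization = NULL, history = NULL
    ),
    class = "idp_model"
  )
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# accept a feature table (id/label + f-columns) or a bare numeric matrix
.as_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    return(features)
  }
  stopifnot(is.data.frame(features))
  cols <- setdiff(names(features), c("id", "label"))
  as.matrix(features[cols])
}

#' Train a classifier
#'
#' Fits the model to a feature table by minibatch Adam on binary
#' cross-entropy, with per-column standardization (mean zero, unit variance)
#' learned from the training rows only — the moment blocks span many orders
#' of magnitude and unscaled optimization diverges. A stratified internal
#' split (`validation_fraction`) drives early stopping: training stops after
#' `patience` epochs without validation-loss improvement and the best-epoch
#' weights are restored. With a fixed seed the run is deterministic.
#'
#' @param model An untrained [build_model()] object (or an [model_config()],
#'   in which case the model is built for the width of `features`).
#' @param features A feature table (tibble with `id`, `label`, feature
#'   columns) or a numeric matrix of rows-by-features.
#' @param labels Optional binary label vector; taken from `features$label`
#'   when omitted.
#' @return The trained `idp_model`, with `$standardization`, `$history`
#'   (per-epoch train/validation loss), and `$trained = TRUE`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(generator_spec(n_per_class = 30, seed = 1))
#' ft <- feature_table(ds)
#' fit <- fit_model(model_config("MLP", max_epochs = 5, seed = 1), ft)
#' }
#' @export
fit_model <- function(model, features, labels = NULL) {
  if (inherits(model, "idp_config")) {
    X <- .as_feature_matrix(features)
    model <- build_model(model, ncol(X))
  }
  stopifnot(inherits(model, "idp_model"))
  config <- model$config
  X <- .as_feature_matrix(features)
  if (ncol(X) != model$input_width) {
    stop(
      "feature width ", ncol(X), " does not match model input width ",
      model$input_width,
      call. = FALSE
    )
  }
  if (is.null(labels)) {
    if (!is.data.frame(features) || !"label" %in% names(features)) {
      stop("labels must be supplied (or present as a 'label' column)", call. = FALSE)
    }
    labels <- features$label
  }
  y <- as.numeric(labels)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("labels must be binary 0/1 with no missing values", call. = FALSE)
  }
  if (length(y) != nrow(X)) stop("labels length does not match feature rows", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class; need both labels", call. = FALSE)
  }
  if (min(table(y)) < 2L) stop("need at least 2 samples per class", call. = FALSE)
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values", call. = FALSE)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)

  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2L, mu, `-`), 2L, sdv, `/`)

  # stratified validation split for early stopping
  idx_pos <- which(y == 1)
  idx_neg <- which(y == 0)
  n_vpos <- max(1L, round(length(idx_pos) * config$validation_fraction))
  n_vneg <- max(1L, round(length(idx_neg) * config$validation_fraction))
  val_idx <- c(sample(idx_pos, n_vpos), sample(idx_neg, n_vneg))
  tr_idx <- setdiff(seq_along(y), val_idx)
  Xtr <- Xs[tr_idx, , drop = FALSE]
  ytr <- y[tr_idx]
  Xval <- Xs[val_idx, , drop = FALSE]
  yval <- y[val_idx]

  layers <- model$layers
  state <- .adam_init(layers)
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  stall <- 0L
  step <- 0L
  history <- list()
  n_tr <- nrow(Xtr)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n_tr)
    ep_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      take <- perm[start:min(start + config$batch_size - 1L, n_tr)]
      xb <- Xtr[take, , drop = FALSE]
      yb <- ytr[take]
      fw <- .net_forward(layers, xb, training = TRUE)
      z <- as.vector(fw$out)
      loss <- .bce_loss(z, yb)
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch, call. = FALSE)
      }
      dz <- matrix(.bce_grad(z, yb), ncol = 1L)
      grads <- .net_backward(layers, fw$caches, dz)
      step <- step + 1L
      upd <- .adam_step(layers, grads, state, config$learning_rate, step)
      layers <- upd$layers
      state <- upd$state
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L
    }
    val_z <- as.vector(.net_forward(layers, Xval, training = FALSE)$out)
    val_loss <- .bce_loss(val_z, yval)
    history[[epoch]] <- c(epoch = epoch, train_loss = ep_loss / n_batches, val_loss = val_loss)
    if (val_loss < best$loss - 1e-7) {
      best <- list(loss = val_loss, layers = layers, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  model$layers <- best$layers
  model$standardization <- list(mean = mu, sd = sdv)
  model$history <- tibble::as_tibble(do.call(rbind, history))
  model$best_epoch <- best$epoch
  model$val_loss <- best$loss
  model$trained <- TRUE
  model
}

#' Predict class probabilities
#'
#' Scores new feature rows with a trained model, applying the
#' standardization learned during training. The returned values are
#' probabilities of the positive (disordered) class; thresholding into hard
#' labels is left to the caller (the evaluation functions use
#' `config$threshold`, default 0.5).
#'
#' @param model A trained `idp_model`.
#' @param features Feature table or numeric matrix with the training width.
#' @return A numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "idp_model"))
  if (!isTRUE(model$trained)) stop("model has not been trained", call. = FALSE)
  X <- .as_feature_matrix(features)
  if (ncol(X) != model$input_width) {
    stop(
      "feature width ", ncol(X), " does not match model input width ",
      model$input_width,
      call. = FALSE
    )
  }
  Xs <- sweep(sweep(X, 2L, model$standardization$mean, `-`), 2L,
    model$standardization$sd, `/`
  )
  z <- as.vector(.net_forward(model$layers, Xs, training = FALSE)$out)
  .sigmoid(z)
}

#' @export
predict.idp_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else as.integer(p >= object$config$threshold)
}

#' @export
print.idp_model <- function(x, ...) {
  cat(
    "<idp_model> ", x$config$kind, " | input width ", x$input_width,
    " | ", format(x$n_params, big.mark = ","), " parameters | ",
    if (isTRUE(x$trained)) {
      paste0("trained (best epoch ", x$best_epoch, ", val loss ",
        signif(x$val_loss, 4), ")")
    } else {
      "untrained"
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted classifier
#'
#' @param x A trained `idp_model`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `train_loss`, `val_loss`.
#' @method tidy idp_model
#' @export
tidy.idp_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), train_loss = double(), val_loss = double()))
  }
  x$history
}

#' One-row summary of a fitted classifier
#'
#' @param x A trained `idp_model`.
#' @param ... Unused.
#' @return A tibble with kind, parameter count, epochs run, best epoch and
#'   validation loss, and seed.
#' @method glance idp_model
#' @export
glance.idp_model <- function(x, ...) {
  tibble::tibble(
    kind = x$config$kind,
    n_params = x$n_params,
    input_width = x$input_width,
    epochs_run = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    val_loss = x$val_loss %||% NA_real_,
    seed = x$config$seed
  )
}

#' Save / load a model checkpoint directory
#'
#' A checkpoint directory holds the weights (`weights.json`), the
#' configuration and standardization statistics (`config.json`), all as
#' plain JSON so checkpoints are portable and diffable.
#'
#' @param model A trained `idp_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly (`save_checkpoint`); the restored `idp_model`
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "idp_model"), isTRUE(model$trained))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  weights <- lapply(model$layers, function(l) {
    lapply(l$params, function(p) {
      list(dim = dim(as.array(p)), data = as.vector(p))
    })
  })
  jsonlite::write_json(
    list(
      config = unclass(model$config),
      input_width = model$input_width,
      standardization = model$standardization,
      best_epoch = model$best_epoch,
      val_loss = model$val_loss
    ),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(weights, file.path(dir, "weights.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  w_path <- file.path(dir, "weights.json")
  if (!file.exists(cfg_path) || !file.exists(w_path)) {
    stop("not a checkpoint directory (missing config.json/weights.json): ", dir,
      call. = FALSE
    )
  }
  meta <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  config <- do.call(model_config, meta$config[names(meta$config) != "kind"] |>
    (\(x) c(list(kind = meta$config$kind), x))())
  model <- build_model(config, meta$input_width)
  weights <- jsonlite::read_json(w_path, simplifyVector = TRUE)
  for (i in seq_along(model$layers)) {
    for (nm in names(model$layers[[i]]$params)) {
      w <- weights[[i]][[nm]]
      model$layers[[i]]$params[[nm]] <- array(w$data, dim = w$dim)
    }
  }
  model$standardization <- list(
    mean = as.numeric(meta$standardization$mean),
    sd = as.numeric(meta$standardization$sd)
  )
  model$best_epoch <- meta$best_epoch
  model$val_loss <- meta$val_loss
  model$trained <- TRUE
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
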