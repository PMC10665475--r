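#' Fusion architecture specification
#'
#' Selects one of the four fusion strategies over a set of sensor
#' signals:
#' * `early` — one network whose first convolutional layer ingests all
#'   selected channels jointly (fusion inside the convolution);
#' * `signal_late` — one convolutional branch per signal, feature maps
#'   concatenated before the dense layer;
#' * `sensor_late` — two independently initialized convolutional branches
#'   per signal (a richer feature set), concatenated likewise;
#' * `hybrid` — majority vote over the predictions of the other three
#'   (an ensemble; see [train_hybrid], it cannot be built directly).
#'
#' @param strategy One of `"early"`, `"signal_late"`, `"sensor_late"`,
#'   `"hybrid"`.
#' @param signals Ordered non-empty subset of
#'   `c("piezo", "acc", "video_belt", "video_chest")` (or any channel
#'   names present in the snippet sets).
#' @param config A [pipeline_config] supplying the hyperparameters
#'   (4 filters of length 20, dropout 0.5, pooling, threshold, seed).
#' @return An object of class `fusion_spec`.
#' @export
fusion_spec <- function(strategy = c("early", "signal_late", "sensor_late",
                                     "hybrid"),
                        signals = c("piezo", "acc", "video_belt",
                                    "video_chest"),
                        config = pipeline_config()) {
  strategy <- match.arg(strategy)
  signals <- as.character(signals)
  if (length(signals) < 1L || anyDuplicated(signals)) {
    stop("fusion_spec: signals must be a non-empty set without duplicates")
  }
  structure(list(strategy = strategy, signals = signals,
                 n_filters = config$n_filters, filter_len = config$filter_len,
                 dropout = config$dropout, pool_size = config$pool_size,
                 threshold = config$threshold, seed = config$seed),
            class = "fusion_spec")
}

#' Build an untrained fusion model
#'
#' Instantiates the branch topology of the chosen strategy for
#' `snippet_len`-sample windows: 1 branch (early), one per signal
#' (signal_late) or two per signal (sensor_late); each branch is
#' conv(`n_filters` x `filter_len`) -> ReLU -> dropout -> max-pool ->
#' flatten, and all branch features feed one sigmoid dense unit. Weights
#' are initialized from the spec seed, so the construction is
#' reproducible. The hybrid strategy is an ensemble of the other three
#' and is refused here; use [train_hybrid].
#'
#' @param spec A [fusion_spec].
#' @param snippet_len Window length in samples.
#' @return An object of class `fusion_model` (untrained).
#' @export
build_model <- function(spec, snippet_len = 201L) {
  stopifnot(inherits(spec, "fusion_spec"))
  if (spec$strategy == "hybrid") {
    stop("build_model: hybrid fusion is an ensemble; train it with train_hybrid()")
  }
  k <- length(spec$signals)
  branch_channels <- switch(spec$strategy,
    early = list(seq_len(k)),
    signal_late = as.list(seq_len(k)),
    sensor_late = as.list(rep(seq_len(k), each = 2L)))
  P <- snippet_len - spec$filter_len + 1L
  nP <- P %/% spec$pool_size
  feat_per_branch <- nP * spec$n_filters
  n_feat <- feat_per_branch * length(branch_channels)

  set.seed(spec$seed)
  branches <- lapply(branch_channels, function(ch) {
    br <- branch_init(length(ch), spec$filter_len, spec$n_filters)
    br$channels <- ch
    br
  })
  dense <- list(w = stats::rnorm(n_feat, sd = sqrt(1 / n_feat)), b = 0)

  structure(list(
    strategy = spec$strategy, signals = spec$signals,
    channel_order = spec$signals,
    branches = branches, dense = dense,
    feat_per_branch = feat_per_branch, snippet_len = as.integer(snippet_len),
    hyper = list(n_filters = spec$n_filters, filter_len = spec$filter_len,
                 dropout = spec$dropout, pool_size = spec$pool_size),
    threshold = spec$threshold, seed = spec$seed,
    trained = FALSE, history = numeric(0)),
    class = "fusion_model")
}

#' Number of convolutional branches of a model
#' @param model A `fusion_model`.
#' @return Integer branch count (1, k or 2k for early / signal_late /
#'   sensor_late with k signals).
#' @export
n_branches <- function(model) length(model$branches)

#' Total trainable parameter count of a model
#' @param model A `fusion_model`.
#' @return Integer: conv weights + conv biases + dense weights + bias.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$branches,
             function(br) length(br$Wc) + length(br$bc), numeric(1))) +
    length(model$dense$w) + 1L
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model %s: %d branch(es) over [%s], %d parameters%s>\n",
              x$strategy, n_branches(x), paste(x$signals, collapse = ", "),
              n_parameters(x), if (x$trained) ", trained" else ""))
  invisible(x)
}

# align a snippet set's channel dimension with the model's channel order
set_channel_slab <- function(model, set) {
  idx <- match(model$channel_order, set$channels)
  if (anyNA(idx)) {
    stop("channel-order mismatch: model expects [",
         paste(model$channel_order, collapse = ", "), "], set provides [",
         paste(set$channels, collapse = ", "), "]")
  }
  if (identical(idx, seq_along(set$channels))) return(set$data)
  set$data[, idx, , drop = FALSE]
}

#' Train a fusion model
#'
#' Minibatch Adam on the binary cross-entropy; with
#' `config$class_weighting` the two classes are weighted inversely to
#' their frequency, so the sparse positive class (windows centred on a
#' breathing peak) is not drowned out. Deterministic given the model
#' seed: initialization, shuffling order and dropout draws are all
#' derived from it.
#'
#' @param model An untrained (or to-be-refined) `fusion_model`.
#' @param train_set Labeled [snippet_set] containing both classes.
#' @param config A [pipeline_config] (epochs, batch size, learning rate).
#' @return The trained model; the mean loss per epoch is in `$history`.
#' @export
train_fusion <- function(model, train_set, config = pipeline_config()) {
  stopifnot(inherits(model, "fusion_model"), inherits(train_set, "snippet_set"))
  y <- train_set$labels
  if (is.null(y)) stop("train_fusion: training set is unlabeled")
  n <- length(y)
  if (n == 0L) stop("train_fusion: empty training set")
  if (length(unique(y)) < 2L) {
    stop("train_fusion: training set contains a single class")
  }
  if (dim(train_set$data)[3] != model$snippet_len) {
    stop("train_fusion: snippet length differs from the model's")
  }
  X <- set_channel_slab(model, train_set)

  cw <- c(1, 1)
  if (config$class_weighting) {
    n1 <- sum(y)
    cw <- c(n / (2 * (n - n1)), n / (2 * n1)) # weight for class 0, class 1
  }
  w <- cw[y + 1L]

  set.seed(model$seed + 1L)
  opt <- adam_new()
  params <- model_params(model)
  bs <- config$batch_size
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      model <- model_set_params(model, params)
      lg <- model_loss_grads(model, X[idx, , , drop = FALSE], y[idx], w[idx])
      upd <- adam_step(opt, lg$grads, params, config$learning_rate)
      opt <- upd$state
      params <- upd$params
      losses <- c(losses, lg$loss)
    }
    history[ep] <- mean(losses)
    rf_log(sprintf("epoch %d/%d: loss %.4f", ep, config$epochs, history[ep]))
  }
  model <- model_set_params(model, params)
  model$trained <- TRUE
  model$history <- c(model$history, history)
  model
}

#' Predict snippet labels with a trained fusion model
#'
#' @param object A trained `fusion_model`.
#' @param set A [snippet_set] whose channels cover the model's channel
#'   order (checked; mismatch is an error).
#' @param batch Snippets per forward pass (memory knob only; the result
#'   is independent of it).
#' @param ... Unused.
#' @return An object of class `prediction_vector`: list with `scores`
#'   (sigmoid outputs in `[0,1]`), `Y` (binary labels by the model's
#'   threshold) and `threshold`.
#' @export
predict.fusion_model <- function(object, set, batch = 4096L, ...) {
  stopifnot(inherits(set, "snippet_set"))
  if (!object$trained) {
    rf_log("predict: model has not been trained", force = TRUE)
  }
  X <- set_channel_slab(object, set)
  n <- dim(X)[1]
  scores <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    scores[idx] <- model_forward(object, X[idx, , , drop = FALSE])$scores
  }
  structure(list(scores = scores,
                 Y = as.integer(scores >= object$threshold),
                 threshold = object$threshold),
            class = "prediction_vector")
}

#' Elementwise majority vote of three binary label vectors
#'
#' The hybrid fusion rule: each snippet's final label is the label at
#' least two of the three member strategies agree on (three binary votes
#' cannot tie).
#'
#' @param y_early,y_signal_late,y_sensor_late Equal-length binary
#'   vectors.
#' @return Integer binary vector of majority labels.
#' @export
majority_vote <- function(y_early, y_signal_late, y_sensor_late) {
  n <- length(y_early)
  if (length(y_signal_late) != n || length(y_sensor_late) != n) {
    stop("majority_vote: vectors differ in length")
  }
  votes <- as.integer(y_early) + as.integer(y_signal_late) +
    as.integer(y_sensor_late)
  if (any(!c(y_early, y_signal_late, y_sensor_late) %in% c(0L, 1L))) {
    stop("majority_vote: votes must be binary")
  }
  as.integer(votes >= 2L)
}

#' Train the hybrid (majority-vote) ensemble
#'
#' Trains the early, signal-based late and sensor-based late models on
#' identical data with the same seed schedule; prediction applies
#' [majority_vote] to the three members' binary outputs.
#'
#' @param train_set Labeled [snippet_set].
#' @param config A [pipeline_config].
#' @param signals Signal subset handed to every member.
#' @return An object of class `hybrid_model` with `$members`.
#' @export
train_hybrid <- function(train_set, config = pipeline_config(),
                         signals = c("piezo", "acc", "video_belt",
                                     "video_chest")) {
  members <- lapply(c("early", "signal_late", "sensor_late"), function(st) {
    m <- build_model(fusion_spec(st, signals, config),
                     snippet_len = config$snippet_len)
    train_fusion(m, train_set, config)
  })
  names(members) <- c("early", "signal_late", "sensor_late")
  structure(list(members = members, signals = signals,
                 threshold = config$threshold),
            class = "hybrid_model")
}

#' @rdname train_hybrid
#' @param object A `hybrid_model`.
#' @param set A [snippet_set].
#' @param ... Passed to the member `predict` methods.
#' @export
predict.hybrid_model <- function(object, set, ...) {
  preds <- lapply(object$members, predict, set = set, ...)
  Y <- majority_vote(preds$early$Y, preds$signal_late$Y,
                     preds$sensor_late$Y)
  structure(list(scores = (preds$early$scores + preds$signal_late$scores +
                             preds$sensor_late$scores) / 3,
                 Y = Y, threshold = object$threshold,
                 member_Y = lapply(preds, `[[`, "Y")),
            class = "prediction_vector")
}

#' Save / load a trained model with a JSON architecture descriptor
#'
#' The checkpoint is a directory: `architecture.json` (strategy, signals,
#' hyperparameters, channel order, seed) plus plain-text weight matrices,
#' so checkpoints survive text-only transport.
#'
#' @param model A `fusion_model`.
#' @param path Checkpoint directory.
#' @return `save_model` invisibly returns `path`; `load_model` the
#'   restored `fusion_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fusion_model"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  desc <- list(strategy = model$strategy, signals = model$signals,
               channel_order = model$channel_order,
               snippet_len = model$snippet_len, hyper = model$hyper,
               threshold = model$threshold, seed = model$seed,
               trained = model$trained, history = model$history,
               feat_per_branch = model$feat_per_branch,
               n_branches = n_branches(model),
               branch_channels = lapply(model$branches, `[[`, "channels"))
  jsonlite::write_json(desc, file.path(path, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(model$branches)) {
    utils::write.table(model$branches[[i]]$Wc,
                       file.path(path, sprintf("branch%02d_Wc.txt", i)),
                       row.names = FALSE, col.names = FALSE)
    writeLines(format(model$branches[[i]]$bc, digits = 17),
               file.path(path, sprintf("branch%02d_bc.txt", i)))
  }
  utils::write.table(cbind(model$dense$w),
                     file.path(path, "dense_w.txt"),
                     row.names = FALSE, col.names = FALSE)
  writeLines(format(model$dense$b, digits = 17),
             file.path(path, "dense_b.txt"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  desc <- jsonlite::read_json(file.path(path, "architecture.json"),
                              simplifyVector = TRUE)
  branches <- lapply(seq_len(desc$n_branches), function(i) {
    Wc <- as.matrix(utils::read.table(
      file.path(path, sprintf("branch%02d_Wc.txt", i))))
    dimnames(Wc) <- NULL
    list(channels = as.integer(unlist(desc$branch_channels[i])),
         c_in = length(unlist(desc$branch_channels[i])),
         Wc = Wc,
         bc = as.numeric(readLines(file.path(path,
                                             sprintf("branch%02d_bc.txt", i)))))
  })
  dense <- list(
    w = as.numeric(utils::read.table(file.path(path, "dense_w.txt"))[[1]]),
    b = as.numeric(readLines(file.path(path, "dense_b.txt"))))
  structure(list(
    strategy = desc$strategy, signals = desc$signals,
    channel_order = desc$channel_order, branches = branches, dense = dense,
    feat_per_branch = desc$feat_per_branch,
    snippet_len = as.integer(desc$snippet_len),
    hyper = as.list(desc$hyper), threshold = desc$threshold,
    seed = desc$seed, trained = isTRUE(desc$trained),
    history = as.numeric(desc$history)),
    class = "fusion_model")
}
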