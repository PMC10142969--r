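#' Training configuration for the OCT image classifiers
#'
#' Collects the hyperparameters of the convolutional image models. The
#' defaults are the selected final settings of the published pipeline:
#' a 2.5D residual network on wavelet-edge input, batch size 4, learning
#' rate 3.4e-6, weight decay 0.036, dropout 0.24, up to 100 Adam epochs with
#' best-epoch selection on a held-out fold. `channels`, `n_blocks` and
#' `width` control backbone capacity so that desk-scale experiments can
#' shrink the networks; augmentation can be disabled for deterministic
#' fitting on tiny tasks.
#'
#' @param cnn_type `"resnet2p5d"` (shared 2D residual backbone per scan with
#'   cross-scan feature averaging) or `"cam3d"` (six 3D convolutional
#'   layers with global pooling).
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate (> 0).
#' @param weight_decay L2 penalty added to weight gradients.
#' @param dropout dropout rate on the pooled feature vector, in [0, 1).
#' @param use_wavelet_input train on Daubechies-1 edge maps instead of raw
#'   intensities.
#' @param background_level optional [foreground_config()]; when given,
#'   backgrounds are zeroed before the model sees a volume.
#' @param max_epochs maximum training epochs (>= 1).
#' @param augment re-draw per-volume affine augmentations in every epoch.
#' @param fold index of the cross-validation fold held out for best-epoch
#'   selection (bookkeeping; callers pass the matching `holdout_idx`).
#' @param channels,n_blocks 2.5D backbone width and residual depth.
#' @param width 3D network base channel count.
#' @param seed integer seed fixing initialisation, data order, dropout and
#'   augmentation draws.
#' @return object of class `training_config`.
#' @export
training_config <- function(cnn_type = c("resnet2p5d", "cam3d"),
                            batch_size = 4L, learning_rate = 3.4e-6,
                            weight_decay = 0.036, dropout = 0.24,
                            use_wavelet_input = TRUE,
                            background_level = NULL,
                            max_epochs = 100L, augment = TRUE, fold = 1L,
                            channels = 8L, n_blocks = 2L, width = 4L,
                            seed = 1L) {
  cnn_type <- match.arg(cnn_type)
  if (learning_rate <= 0) stop_config("'learning_rate' must be > 0")
  if (dropout < 0 || dropout >= 1) stop_config("'dropout' must be in [0, 1)")
  check_count(max_epochs, "max_epochs", min = 0L)
  check_count(batch_size, "batch_size")
  if (!is.null(background_level) &&
      !inherits(background_level, "foreground_config"))
    stop_config("'background_level' must be a foreground_config()")
  structure(list(cnn_type = cnn_type, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout = dropout, use_wavelet_input = use_wavelet_input,
                 background_level = background_level,
                 max_epochs = as.integer(max_epochs), augment = augment,
                 fold = as.integer(fold), channels = as.integer(channels),
                 n_blocks = as.integer(n_blocks), width = as.integer(width),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Build an untrained OCT volume classifier
#'
#' Constructs one of the two convolutional architectures: the 2.5D model
#' applies a single shared 2D residual backbone to every scan and averages
#' the per-scan feature vectors across the volume (so its output is
#' invariant to scan order); the 3D model stacks six 3D convolutional
#' layers with global average pooling. Both end in a sigmoid head trained
#' with binary cross-entropy.
#'
#' @param config a [training_config()].
#' @return object of class `oct_cnn`.
#' @export
build_cnn <- function(config) {
  if (!inherits(config, "training_config"))
    stop_config("'config' must be created by training_config()")
  set.seed(config$seed)
  params <- switch(config$cnn_type,
                   resnet2p5d = init_resnet2p5d(config$channels, config$n_blocks),
                   cam3d = init_cam3d(config$width),
                   stop_config("unknown cnn_type"))
  structure(list(type = config$cnn_type, params = params, config = config,
                 trained = FALSE, best_epoch = NA_integer_, history = NULL),
            class = "oct_cnn")
}

#' @export
print.oct_cnn <- function(x, ...) {
  cat(sprintf("OCT CNN (%s), %s; parameters: %d\n", x$type,
              if (x$trained) sprintf("trained (best epoch %d)", x$best_epoch)
              else "untrained",
              sum(vapply(x$params, length, 1L))))
  invisible(x)
}

as_volume_array <- function(v) {
  if (inherits(v, "preprocessed_volume")) v$data
  else if (inherits(v, "oct_volume")) v$data
  else if (is.array(v) && length(dim(v)) == 3) v
  else stop_config("volumes must be 3D arrays or (pre)processed volumes")
}

# deterministic input transforms: background zeroing then wavelet edges
prepare_volume_input <- function(arr, config) {
  if (!is.null(config$background_level))
    arr <- remove_volume_background(arr, config$background_level)
  if (isTRUE(config$use_wavelet_input)) {
    for (s in seq_len(dim(arr)[1])) {
      e <- wavelet_edge_map(arr[s, , ])
      attributes(e) <- attributes(e)["dim"]
      arr[s, , ] <- e
    }
  }
  arr
}

cnn_forward_volume <- function(model, arr, keep = FALSE, drop_mask = NULL) {
  p <- model$params
  if (model$type == "resnet2p5d") {
    ns <- dim(arr)[1]
    feats <- matrix(0, length(p$head.b) * nrow(p$head.W), ns)
    caches <- if (keep) vector("list", ns)
    for (s in seq_len(ns)) {
      fs <- resnet_scan_forward(arr[s, , ], p, model$config$n_blocks,
                                keep = keep)
      feats[, s] <- fs$feat
      if (keep) caches[[s]] <- fs$caches
    }
    feat <- rowMeans(feats)
  } else {
    fs <- cam3d_forward(arr, p, model$config$width, keep = keep)
    feat <- fs$feat
    caches <- if (keep) fs$caches
  }
  fd <- if (is.null(drop_mask)) feat else feat * drop_mask
  z <- sum(fd * p$head.W) + p$head.b
  list(score = sigmoid(z), feat = feat, feat_dropped = fd,
       caches = if (keep) caches)
}

cnn_backward_volume <- function(model, fwd, dz, drop_mask = NULL) {
  p <- model$params
  g <- list(head.W = matrix(fwd$feat_dropped * dz, ncol = 1), head.b = dz)
  dfeat <- as.numeric(p$head.W) * dz
  if (!is.null(drop_mask)) dfeat <- dfeat * drop_mask
  if (model$type == "resnet2p5d") {
    ns <- length(fwd$caches)
    acc <- NULL
    for (s in seq_len(ns)) {
      gs <- resnet_scan_backward(dfeat / ns, p, model$config$n_blocks,
                                 fwd$caches[[s]])
      acc <- accumulate_grads(acc, gs)
    }
    g <- c(g, acc)
  } else {
    g <- c(g, cam3d_backward(dfeat, p, model$config$width, fwd$caches))
  }
  g
}

#' Score OCT volumes with a CNN
#'
#' Applies the configured deterministic input transforms (background
#' zeroing, wavelet edges) and returns one score in [0, 1] per volume.
#' Inference is deterministic: no augmentation and no dropout.
#'
#' @param object an `oct_cnn`.
#' @param volumes list of volumes (3D arrays or `preprocessed_volume`s).
#' @param transform apply the configured input transforms (default `TRUE`;
#'   set `FALSE` if inputs are already transformed).
#' @param ... unused.
#' @return numeric vector of scores.
#' @export
predict.oct_cnn <- function(object, volumes, transform = TRUE, ...) {
  vapply(volumes, function(v) {
    arr <- as_volume_array(v)
    if (transform) arr <- prepare_volume_input(arr, object$config)
    cnn_forward_volume(object, arr)$score
  }, numeric(1))
}

#' Train an image classifier with Adam and best-epoch selection
#'
#' Trains for up to `config$max_epochs` epochs of minibatch Adam on binary
#' cross-entropy. When augmentation is enabled, a fresh per-volume affine
#' augmentation is drawn in every epoch. After each epoch the model is
#' scored on the held-out set and the weights of the epoch with the highest
#' held-out AUROC are kept (ties resolved to the latest such epoch).
#'
#' @param model an `oct_cnn` (freshly built, or already trained for
#'   transfer retraining).
#' @param volumes list of volumes.
#' @param labels binary outcome per volume (1 = residual fluid).
#' @param config a [training_config()]; defaults to the model's own.
#' @param holdout_idx indices of `volumes` held out for epoch selection
#'   (e.g. one of five cross-validation folds). When `NULL`, a seeded
#'   class-stratified fifth is held out.
#' @return the fitted `oct_cnn` with `best_epoch` and a per-epoch `history`
#'   data frame (training loss, held-out AUROC).
#' @export
train_image_model <- function(model, volumes, labels, config = model$config,
                              holdout_idx = NULL) {
  if (!inherits(model, "oct_cnn")) stop_config("'model' must be an oct_cnn")
  labels <- as.numeric(labels)
  n <- length(volumes)
  if (length(labels) != n) stop_config("labels must match volumes")
  if (length(unique(labels)) < 2)
    stop_config("training set must contain both classes")
  set.seed(config$seed)
  if (is.null(holdout_idx)) {
    pos <- which(labels == 1); neg <- which(labels == 0)
    holdout_idx <- c(pos[sample.int(length(pos), max(1, round(length(pos) / 5)))],
                     neg[sample.int(length(neg), max(1, round(length(neg) / 5)))])
  }
  train_idx <- setdiff(seq_len(n), holdout_idx)
  if (length(unique(labels[train_idx])) < 2)
    stop_config("training set must contain both classes")
  if (length(unique(labels[holdout_idx])) < 2)
    stop_config("held-out set must contain both classes")

  raw <- lapply(volumes, as_volume_array)
  static_train <- if (!config$augment)
    lapply(raw[train_idx], prepare_volume_input, config = config)
  hold_arr <- lapply(raw[holdout_idx], prepare_volume_input, config = config)

  best <- list(auc = -Inf, params = model$params, epoch = 0L)
  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(), loss = numeric(), auroc = numeric())
  wdecay_names <- grep("\\.W$", names(model$params), value = TRUE)

  for (epoch in seq_len(config$max_epochs)) {
    if (config$augment) {
      epoch_arr <- lapply(raw[train_idx], function(a)
        prepare_volume_input(augment_volume(a, draw_augmentation_params()),
                             config = config))
    } else epoch_arr <- static_train
    ord <- sample(seq_along(train_idx))
    losses <- numeric(0)
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      batch <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
      acc <- NULL
      for (i in batch) {
        y <- labels[train_idx[i]]
        mask <- if (config$dropout > 0)
          stats::rbinom(length(model$params$head.W), 1, 1 - config$dropout) /
            (1 - config$dropout) else NULL
        fwd <- cnn_forward_volume(model, epoch_arr[[i]], keep = TRUE,
                                  drop_mask = mask)
        pr <- min(max(fwd$score, 1e-12), 1 - 1e-12)
        losses <- c(losses, -(y * log(pr) + (1 - y) * log(1 - pr)))
        g <- cnn_backward_volume(model, fwd, dz = fwd$score - y,
                                 drop_mask = mask)
        acc <- accumulate_grads(acc, g, scale = 1 / length(batch))
      }
      for (nm in wdecay_names)
        acc[[nm]] <- acc[[nm]] + config$weight_decay * model$params[[nm]]
      st <- adam_step(model$params, acc, opt, config$learning_rate)
      model$params <- st$params; opt <- st$state
    }
    hold_scores <- vapply(hold_arr, function(a)
      cnn_forward_volume(model, a)$score, numeric(1))
    auc <- auroc(hold_scores, labels[holdout_idx])
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses), auroc = auc))
    # ties resolve to the later epoch: with a small held-out fold the AUROC
    # is coarse, and at equal held-out performance more training is preferred
    if (auc >= best$auc) best <- list(auc = auc, params = model$params,
                                      epoch = epoch)
  }
  model$params <- best$params
  model$trained <- TRUE
  model$best_epoch <- if (config$max_epochs > 0) best$epoch else NA_integer_
  model$history <- history
  model$config <- config
  model
}

#' Transfer-retrain a trained CNN on a new subcohort
#'
#' Initialises from the weights of a model trained on the standard-protocol
#' subcohort and retrains all layers on the short-protocol tuning data with
#' the same best-epoch selection rule. With `max_epochs = 0` the source
#' weights are returned unchanged.
#'
#' @param standard_cnn a trained `oct_cnn`.
#' @param volumes,labels tuning data of the target subcohort.
#' @param config retraining [training_config()]; architecture fields must
#'   match the source model.
#' @param holdout_idx see [train_image_model()].
#' @return retrained `oct_cnn`.
#' @export
transfer_retrain <- function(standard_cnn, volumes, labels,
                             config = standard_cnn$config,
                             holdout_idx = NULL) {
  if (!inherits(standard_cnn, "oct_cnn")) stop_config("'standard_cnn' must be an oct_cnn")
  if (config$cnn_type != standard_cnn$type ||
      (config$cnn_type == "resnet2p5d" &&
       (config$channels != standard_cnn$config$channels ||
        config$n_blocks != standard_cnn$config$n_blocks)) ||
      (config$cnn_type == "cam3d" && config$width != standard_cnn$config$width))
    stop_config("architecture of 'config' does not match the source model")
  if (config$max_epochs == 0L) {
    standard_cnn$config <- config
    return(standard_cnn)
  }
  train_image_model(standard_cnn, volumes, labels, config = config,
                    holdout_idx = holdout_idx)
}

#' Random hyperparameter search
#'
#' Draws `budget` configurations uniformly (log-uniformly where requested)
#' from a search space, scores each with a user-supplied evaluation
#' function (typically: train with the configuration and return validation
#' AUROC), and returns the best trial with the full trial log.
#'
#' @param space named list; each element is either a vector of discrete
#'   choices, or `list(min =, max =, log = TRUE/FALSE)` for a continuous
#'   range.
#' @param budget number of trials (>= 1).
#' @param seed integer seed fixing the trial sequence.
#' @param eval_fn function taking a named list of sampled values and
#'   returning a single numeric score (higher is better).
#' @return list with `best_config`, `best_score`, and `trials` (data frame
#'   of sampled values and scores).
#' @export
random_hyperparameter_search <- function(space, budget, seed, eval_fn) {
  if (length(space) == 0) stop_config("empty search space")
  check_count(budget, "budget")
  set.seed(seed)
  draws <- vector("list", budget)
  for (b in seq_len(budget)) {     # all draws first: trial list is fixed by
    draws[[b]] <- lapply(space, function(el) {   # the seed alone
      if (is.list(el)) {
        u <- stats::runif(1)
        if (isTRUE(el$log)) exp(log(el$min) + u * (log(el$max) - log(el$min)))
        else el$min + u * (el$max - el$min)
      } else el[[sample.int(length(el), 1)]]
    })
  }
  scores <- vapply(draws, eval_fn, numeric(1))
  trials <- cbind(do.call(rbind, lapply(draws, function(d)
    as.data.frame(d, stringsAsFactors = FALSE))), score = scores)
  best <- which.max(scores)
  list(best_config = draws[[best]], best_score = scores[best], trials = trials)
}
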