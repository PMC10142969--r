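# L2-penalised logistic regression by direct optimisation; used for the
# score stacker, where the design has at most a handful of columns and
# single-column fits must be possible.
ridge_logit <- function(X, y, lambda) {
  X <- as.matrix(X)
  p <- ncol(X)
  nll <- function(th) {
    eta <- th[1] + X %*% th[-1]
    -sum(y * eta - log1p(exp(eta))) + lambda / 2 * sum(th[-1]^2)
  }
  grad <- function(th) {
    mu <- as.numeric(sigmoid(th[1] + X %*% th[-1]))
    c(-sum(y - mu), -crossprod(X, y - mu) + lambda * th[-1])
  }
  fit <- stats::optim(numeric(p + 1), nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  stats::setNames(fit$par, c("(Intercept)", colnames(X)))
}

cv_ridge_logit <- function(X, y, lambda_grid, nfolds = 5L, seed = 1L) {
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), length(y)))
  loss <- vapply(lambda_grid, function(lam) {
    ll <- 0
    for (f in seq_len(nfolds)) {
      tr <- foldid != f
      if (length(unique(y[tr])) < 2) next
      th <- ridge_logit(X[tr, , drop = FALSE], y[tr], lam)
      mu <- sigmoid(th[1] + X[!tr, , drop = FALSE] %*% th[-1])
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      ll <- ll - sum(y[!tr] * log(mu) + (1 - y[!tr]) * log(1 - mu))
    }
    ll
  }, numeric(1))
  # ties towards the stronger penalty for determinism
  lambda_grid[max(which(loss == min(loss)))]
}

#' Fit the score-stacking ensemble
#'
#' Stacks per-model outcome scores (each in [0, 1]) into a single
#' classifier: an L2-regularised logistic regression on the score columns,
#' with the penalty strength tuned by 5-fold cross-validation. Scores are
#' passed to the stacker untransformed.
#'
#' @param scores numeric matrix or data frame of model scores, one column
#'   per model, one row per eye; an optional `eye_id` column is used to
#'   check alignment against `names(labels)`.
#' @param labels binary outcome per eye.
#' @param lambda_grid candidate penalty strengths.
#' @param nfolds CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return object of class `model_ensemble` with elements
#'   `selected_models`, `coef`, `lambda`.
#' @export
fit_stacker <- function(scores, labels, lambda_grid = 10^seq(-3, 2, 0.5),
                        nfolds = 5L, seed = 1L) {
  if (is.data.frame(scores)) {
    if ("eye_id" %in% names(scores)) {
      if (!is.null(names(labels)) &&
          !identical(as.character(scores$eye_id), names(labels)))
        stop_config("eye ids of scores and labels are not aligned")
      scores <- scores[, setdiff(names(scores), "eye_id"), drop = FALSE]
    }
    scores <- as.matrix(scores)
  }
  labels <- as.numeric(labels)
  if (nrow(scores) != length(labels)) stop_config("scores/labels length mismatch")
  if (anyNA(scores) || any(scores < 0 | scores > 1))
    stop_config("model scores must lie in [0, 1]")
  if (length(unique(labels)) < 2) stop_config("both classes must be present")
  lam <- cv_ridge_logit(scores, labels, lambda_grid, nfolds, seed)
  th <- ridge_logit(scores, labels, lam)
  structure(list(selected_models = colnames(scores), coef = th, lambda = lam),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("Score-stacking ensemble (L2 logistic regression)\n")
  cat("  models:", paste(x$selected_models, collapse = ", "), "\n")
  cat("  lambda:", format(x$lambda), "\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
coef.model_ensemble <- function(object, ...) object$coef

#' Score eyes with the ensemble
#'
#' @param object a `model_ensemble`.
#' @param scores matrix/data frame holding at least the stacked models'
#'   score columns.
#' @param ... unused.
#' @return numeric vector of ensemble scores in [0, 1].
#' @export
predict.model_ensemble <- function(object, scores, ...) {
  if (is.data.frame(scores)) scores <- as.matrix(
    scores[, object$selected_models, drop = FALSE])
  else scores <- scores[, object$selected_models, drop = FALSE]
  as.numeric(sigmoid(object$coef[1] +
                       scores %*% object$coef[object$selected_models]))
}

#' Greedy forward selection of ensemble inputs
#'
#' Starting from the empty set, repeatedly adds the candidate model whose
#' inclusion yields the largest validation AUROC of a stacker fitted on the
#' training scores, and stops when no candidate improves validation AUROC
#' by more than `tol`. The first step always admits the best single model.
#' Ties break deterministically by the fixed candidate order.
#'
#' @param train_scores,train_labels training scores (columns = models) and
#'   labels used to fit each candidate stacker.
#' @param val_scores,val_labels validation data used to judge candidates.
#' @param candidates candidate model names in tie-break order (default
#'   `c("cnn", "clinical", "fft_lasso")`, intersected with available
#'   columns).
#' @param tol minimum strict AUROC improvement to keep adding (default
#'   1e-4).
#' @param ... passed to [fit_stacker()].
#' @return list with `selected` (ordered character vector) and `trace`
#'   (data frame of step-wise candidate AUROCs).
#' @export
forward_feature_selection <- function(train_scores, train_labels,
                                      val_scores, val_labels,
                                      candidates = c("cnn", "clinical",
                                                     "fft_lasso"),
                                      tol = 1e-4, ...) {
  train_scores <- as.matrix(as.data.frame(train_scores)[
    , intersect(candidates, colnames(as.data.frame(train_scores))), drop = FALSE])
  candidates <- colnames(train_scores)
  if (length(candidates) < 1) stop_config("no candidate models available")
  val_scores <- as.matrix(as.data.frame(val_scores)[, candidates, drop = FALSE])

  selected <- character(0)
  best_auc <- -Inf
  trace <- data.frame(step = integer(), candidate = character(),
                      auroc = numeric(), accepted = logical())
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    aucs <- vapply(remaining, function(cand) {
      cols <- c(selected, cand)
      st <- fit_stacker(train_scores[, cols, drop = FALSE], train_labels, ...)
      auroc(predict(st, val_scores[, cols, drop = FALSE]), val_labels)
    }, numeric(1))
    pick <- which.max(aucs)
    improved <- length(selected) == 0 || aucs[pick] > best_auc + tol
    trace <- rbind(trace, data.frame(step = length(selected) + 1L,
                                     candidate = remaining[pick],
                                     auroc = aucs[pick],
                                     accepted = improved))
    if (!improved) break
    selected <- c(selected, remaining[pick])
    best_auc <- aucs[pick]
  }
  list(selected = selected, trace = trace)
}
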