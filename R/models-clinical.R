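#' L2-regularised clinical logistic regression
#'
#' Fits a ridge-penalised logistic regression on the normalised clinical
#' features (standardised age, visual acuity letters, log CST, TRV, the
#' female-sex indicator and clinic one-hot columns), with the penalty
#' strength tuned by 5-fold cross-validation. Features are expected already
#' standardised by [normalize_clinical()], so no further scaling is applied
#' and the per-feature absolute coefficients are directly comparable.
#'
#' @param features a `clinical_features` object or a numeric matrix.
#' @param labels binary outcome per row.
#' @param nfolds CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return object of class `clinical_logreg`.
#' @export
fit_clinical_logreg <- function(features, labels, nfolds = 5L, seed = 1L) {
  x <- if (inherits(features, "clinical_features")) features$x else features
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) stop_config("both classes must be present")
  if (nrow(x) != length(labels)) stop_config("labels must match feature rows")
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
  cv <- glmnet::cv.glmnet(x, labels, family = "binomial", alpha = 0,
                          foldid = foldid, standardize = FALSE)
  structure(list(cv = cv, feature_names = colnames(x)),
            class = "clinical_logreg")
}

#' @export
print.clinical_logreg <- function(x, ...) {
  cat("Clinical L2 logistic regression\n")
  cat("Top contributors (|coefficient|):\n")
  r <- coef_ranking(x)
  print(utils::head(r, 5))
  invisible(x)
}

#' @export
coef.clinical_logreg <- function(object, ...) {
  cf <- stats::coef(object$cv, s = "lambda.min")
  stats::setNames(as.numeric(cf), rownames(cf))
}

#' Rank clinical features by absolute coefficient
#'
#' @param object a `clinical_logreg`.
#' @param drop_clinic exclude clinic one-hot columns from the ranking
#'   (default `TRUE`).
#' @return named numeric vector of absolute coefficients, descending.
#' @export
coef_ranking <- function(object, drop_clinic = TRUE) {
  cf <- coef(object)
  cf <- cf[setdiff(names(cf), "(Intercept)")]
  if (drop_clinic) cf <- cf[!startsWith(names(cf), "clinic_")]
  sort(abs(cf), decreasing = TRUE)
}

#' Score eyes with the clinical model
#'
#' @param object a `clinical_logreg`.
#' @param features `clinical_features` object or matrix (same columns as
#'   at fit time).
#' @param ... unused.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict.clinical_logreg <- function(object, features, ...) {
  x <- if (inherits(features, "clinical_features")) features$x else features
  as.numeric(stats::predict(object$cv, newx = x, s = "lambda.min",
                            type = "response"))
}
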