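#' Training-defined FFT frequency mask
#'
#' Computes the 2D FFT magnitude of every training scan, averages the
#' magnitudes over scans, and retains the `keep_fraction` of frequency
#' coefficients with the largest training-mean magnitude (about a 85%
#' reduction at the default 0.15). The mask is defined on training data
#' only and applied unchanged to validation and test scans.
#'
#' @param train_scans list of scan matrices, or list of 3D volume arrays
#'   (all scans are used).
#' @param keep_fraction fraction of coefficients retained (default 0.15).
#' @return object of class `fft_mask`: `idx` (sorted linear indices),
#'   `dim`, `keep_fraction`.
#' @export
fit_fft_mask <- function(train_scans, keep_fraction = 0.15) {
  scans <- flatten_scans(train_scans)
  d <- dim(scans[[1]])
  acc <- matrix(0, d[1], d[2])
  for (s in scans) {
    if (!all(dim(s) == d)) stop_config("all scans must share one size")
    acc <- acc + Mod(stats::fft(s))
  }
  acc <- acc / length(scans)
  n_keep <- round_half_up(keep_fraction * length(acc))
  idx <- sort(order(acc, decreasing = TRUE)[seq_len(n_keep)])
  structure(list(idx = idx, dim = d, keep_fraction = keep_fraction),
            class = "fft_mask")
}

flatten_scans <- function(x) {
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3)
    return(lapply(seq_len(dim(x)[1]), function(s) x[s, , ]))
  if (is.list(x)) return(do.call(c, lapply(x, flatten_scans)))
  stop_config("expected scan matrices or 3D volume arrays")
}

#' Reduced frequency features of one scan
#'
#' Applies a training-defined [fit_fft_mask()] to the 2D FFT magnitude of a
#' scan, flattening the retained coefficients to a feature vector.
#'
#' @param scan numeric matrix matching the mask's dimensions.
#' @param mask an `fft_mask`.
#' @return numeric vector of length `length(mask$idx)`.
#' @export
extract_fft_features <- function(scan, mask) {
  if (!inherits(mask, "fft_mask")) stop_config("'mask' must be an fft_mask")
  if (!all(dim(scan) == mask$dim))
    stop_config("scan size does not match the mask")
  Mod(stats::fft(scan))[mask$idx]
}

#' Lasso scan classifier on reduced FFT features
#'
#' Fits an L1-regularised logistic regression on per-scan FFT features,
#' with every scan inheriting its volume's outcome label. The
#' regularisation strength is tuned by 5-fold cross-validation with whole
#' volumes kept together in folds (scans of one eye never straddle a CV
#' fold). A volume is scored by the arithmetic mean of its scan scores.
#'
#' @param volumes list of 3D volume arrays (or `preprocessed_volume`s).
#' @param labels binary outcome per volume.
#' @param mask optional precomputed [fit_fft_mask()]; computed from
#'   `volumes` when `NULL`.
#' @param keep_fraction passed to [fit_fft_mask()] when computing the mask.
#' @param nfolds CV folds for the regularisation path (default 5).
#' @param seed integer seed for fold assignment.
#' @return object of class `fft_lasso`.
#' @export
fit_fft_lasso <- function(volumes, labels, mask = NULL, keep_fraction = 0.15,
                          nfolds = 5L, seed = 1L) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop_config("both classes must be present")
  arrs <- lapply(volumes, as_volume_array)
  if (is.null(mask)) mask <- fit_fft_mask(arrs, keep_fraction)
  ns <- vapply(arrs, function(a) dim(a)[1], 1L)
  X <- do.call(rbind, lapply(arrs, function(a)
    t(vapply(seq_len(dim(a)[1]),
             function(s) extract_fft_features(a[s, , ], mask),
             numeric(length(mask$idx))))))
  y <- rep(labels, ns)
  set.seed(seed)
  vol_fold <- sample(rep_len(seq_len(nfolds), length(arrs)))
  foldid <- rep(vol_fold, ns)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = TRUE)
  structure(list(cv = cv, mask = mask, n_features = length(mask$idx)),
            class = "fft_lasso")
}

#' @export
print.fft_lasso <- function(x, ...) {
  nz <- sum(as.numeric(stats::coef(x$cv, s = "lambda.min")) != 0) - 1
  cat(sprintf("FFT + lasso scan classifier: %d features, %d nonzero at lambda.min\n",
              x$n_features, nz))
  invisible(x)
}

#' Score volumes with the FFT-lasso model
#'
#' @param object an `fft_lasso`.
#' @param volumes list of volumes.
#' @param ... unused.
#' @return numeric vector: per-volume mean of scan probabilities.
#' @export
predict.fft_lasso <- function(object, volumes, ...) {
  vapply(volumes, function(v) {
    a <- as_volume_array(v)
    X <- t(vapply(seq_len(dim(a)[1]),
                  function(s) extract_fft_features(a[s, , ], object$mask),
                  numeric(length(object$mask$idx))))
    mean(stats::predict(object$cv, newx = X, s = "lambda.min",
                        type = "response"))
  }, numeric(1))
}
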