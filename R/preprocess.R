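#' Evenly spaced subsampling indices for a fixed 20-scan stack
#'
#' Selects 20 scans at regular intervals from a volume of `n_scans` B-scans:
#' index_k = round(k * (n_scans - 1) / 19) for k = 0..19 (half-up rounding),
#' returned 1-based. For volumes with fewer than 20 scans this evenly
#' duplicates scans; order is always preserved and the first and last scans
#' are always included.
#'
#' @param n_scans number of scans in the source volume (>= 1).
#' @param n_out number of output scans (default 20).
#' @return integer vector of `n_out` 1-based, non-decreasing indices.
#' @examples
#' subsample_indices(49)  # 20 distinct indices from 1 to 49
#' subsample_indices(20)  # identity
#' @export
subsample_indices <- function(n_scans, n_out = 20L) {
  check_count(n_scans, "n_scans")
  k <- seq(0L, n_out - 1L)
  round_half_up(k * (n_scans - 1) / (n_out - 1)) + 1L
}

resize_bilinear <- function(scan, height, width) {
  # EBImage's first dimension is 'w'; our matrices are height x width
  EBImage::resize(scan, w = height, h = width, filter = "bilinear")
}

#' Standardise an OCT volume to a 20 x 200 x 300 intensity matrix
#'
#' Applies the deterministic three-step standardisation: (1) each B-scan is
#' resized by bilinear interpolation to `height` x `width` in volume order;
#' (2) the stack is subsampled (or evenly duplicated) to exactly 20 scans
#' via [subsample_indices()]; (3) the whole resulting matrix is linearly
#' rescaled so that its empirical 1st and 99th percentiles map to -1 and +1
#' (linear-interpolated percentiles; values beyond the percentiles are not
#' clipped). No common intensity reference across eyes is used.
#'
#' @param volume an `oct_volume` or a plain 3D array (scans x rows x cols).
#' @param height,width target scan size (defaults 200 x 300).
#' @param n_out number of output scans (default 20).
#' @return object of class `preprocessed_volume`: list with `data`
#'   (`n_out x height x width` array), `source_eye`, `percentiles_used`
#'   (p1, p99 on the resized, subsampled stack).
#' @export
preprocess_volume <- function(volume, height = 200L, width = 300L,
                              n_out = 20L) {
  eye <- "volume"
  if (inherits(volume, "oct_volume")) {
    eye <- volume$eye_id
    volume <- volume$data
  }
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop_config("'volume' must be a 3D array of B-scans")
  ns <- dim(volume)[1]
  if (ns < 1) stop_config("empty volume")

  resized <- array(0, dim = c(ns, height, width))
  same_size <- dim(volume)[2] == height && dim(volume)[3] == width
  for (s in seq_len(ns))
    resized[s, , ] <- if (same_size) volume[s, , ] else
      resize_bilinear(volume[s, , ], height, width)
  out <- resized[subsample_indices(ns, n_out), , , drop = FALSE]

  p <- stats::quantile(out, c(0.01, 0.99), names = FALSE, type = 7)
  if (p[2] <= p[1])
    stop_config("degenerate volume: 1st and 99th percentile coincide")
  out <- 2 * (out - p[1]) / (p[2] - p[1]) - 1

  structure(list(data = out, source_eye = eye,
                 percentiles_used = c(p1 = p[1], p99 = p[2])),
            class = "preprocessed_volume")
}

#' @export
print.preprocessed_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Preprocessed volume '%s': %d x %d x %d, p1/p99 = %.4g / %.4g\n",
              x$source_eye, d[1], d[2], d[3],
              x$percentiles_used[1], x$percentiles_used[2]))
  invisible(x)
}

#' Normalise clinical features with training-set statistics only
#'
#' Builds the clinical feature matrix used by the clinical classifier:
#' numeric features (`age`, `va_letters`, `log(cst)`, `trv`) are centred and
#' scaled to training-set mean 0 and SD 1 (unbiased SD); CST is
#' log-transformed before standardisation because it is strictly positive
#' and right-skewed. Missing numerics are imputed with 0 (the training mean)
#' after standardisation, with an imputation mask recording which entries
#' were imputed. Sex is encoded as a female indicator and clinic is one-hot
#' encoded over the clinics seen in training; unseen clinics map to an
#' all-zero row. Statistics are estimated on `training_ids` rows only and
#' applied unchanged to every row, so validation and test rows never
#' influence them.
#'
#' @param records eye-record data frame.
#' @param training_ids eye ids of the training rows.
#' @return object of class `clinical_features`: list with `x` (numeric
#'   matrix, rownames = eye ids), `mask` (0/1 imputation matrix for the
#'   numeric block), `center`, `scale`, `numeric_cols`, `clinic_levels`.
#' @export
normalize_clinical <- function(records, training_ids) {
  if (length(training_ids) == 0) stop_config("'training_ids' is empty")
  if (!all(training_ids %in% records$eye_id))
    stop_config("some training ids are not present in records")
  train <- records$eye_id %in% training_ids
  if (any(records$cst <= 0, na.rm = TRUE))
    stop_config("CST must be strictly positive")

  num <- cbind(age = records$age,
               va_letters = records$va_letters,
               log_cst = log(records$cst),
               trv = records$trv)
  center <- apply(num[train, , drop = FALSE], 2, mean, na.rm = TRUE)
  scale <- apply(num[train, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  keep <- is.finite(scale) & scale > 0
  if (!all(keep))
    warning("dropping constant column(s): ",
            paste(colnames(num)[!keep], collapse = ", "), call. = FALSE)
  num <- num[, keep, drop = FALSE]
  center <- center[keep]; scale <- scale[keep]

  z <- sweep(sweep(num, 2, center), 2, scale, "/")
  mask <- 1 * is.na(z)
  z[is.na(z)] <- 0

  sex_female <- as.numeric(records$sex %in% c("F", "female", "Female", 1))
  clinic_levels <- sort(unique(records$clinic[train]))
  clin <- sapply(clinic_levels, function(l) as.numeric(records$clinic == l))
  if (length(clinic_levels) == 1) clin <- matrix(clin, ncol = 1)
  colnames(clin) <- paste0("clinic_", clinic_levels)

  x <- cbind(z, sex_female = sex_female, clin)
  rownames(x) <- records$eye_id
  rownames(mask) <- records$eye_id
  structure(list(x = x, mask = mask, center = center, scale = scale,
                 numeric_cols = colnames(num), clinic_levels = clinic_levels),
            class = "clinical_features")
}
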