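#' Single-level 2D Daubechies-1 (Haar) decomposition
#'
#' Orthonormal single-level analysis with the 2x2 Haar filters. Odd image
#' dimensions are handled by edge replication before filtering. With even
#' dimensions the transform is orthonormal, so total energy is conserved
#' across the four subbands (Parseval).
#'
#' @param img numeric matrix.
#' @return list with subbands `LL` (approximation), `LH` (horizontal
#'   detail), `HL` (vertical detail), `HH` (diagonal detail), each of size
#'   `ceiling(dim(img)/2)`.
#' @export
haar_decompose <- function(img) {
  H <- nrow(img); W <- ncol(img)
  if (H %% 2 == 1) img <- rbind(img, img[H, , drop = FALSE])
  if (W %% 2 == 1) img <- cbind(img, img[, ncol(img), drop = FALSE])
  ro <- seq(1, nrow(img), by = 2); re <- ro + 1
  a <- (img[ro, , drop = FALSE] + img[re, , drop = FALSE]) / sqrt(2)
  d <- (img[ro, , drop = FALSE] - img[re, , drop = FALSE]) / sqrt(2)
  co <- seq(1, ncol(img), by = 2); ce <- co + 1
  list(LL = (a[, co, drop = FALSE] + a[, ce, drop = FALSE]) / sqrt(2),
       LH = (a[, co, drop = FALSE] - a[, ce, drop = FALSE]) / sqrt(2),
       HL = (d[, co, drop = FALSE] + d[, ce, drop = FALSE]) / sqrt(2),
       HH = (d[, co, drop = FALSE] - d[, ce, drop = FALSE]) / sqrt(2))
}

#' Wavelet edge map of a B-scan
#'
#' Computes the single-level Daubechies-1 detail magnitudes |LH| + |HL| +
#' |HH|, replicates them back to the input resolution (so the matrix size is
#' unchanged), and optionally standardises the result to mean 0 and SD 1.
#' A constant input has identically zero details; standardisation is then
#' skipped and the all-zero map is flagged with attribute `constant`.
#'
#' @param scan numeric matrix (any size; the pipeline uses 200 x 300).
#' @param standardize standardise output to mean 0, SD 1 (default `TRUE`).
#' @return numeric matrix of `dim(scan)`; attribute `constant` is `TRUE`
#'   for degenerate input.
#' @export
wavelet_edge_map <- function(scan, standardize = TRUE) {
  if (!all(is.finite(scan))) stop_config("scan must be finite")
  sub <- haar_decompose(scan)
  e <- abs(sub$LH) + abs(sub$HL) + abs(sub$HH)
  up <- kronecker(e, matrix(1, 2, 2))[seq_len(nrow(scan)), seq_len(ncol(scan)),
                                      drop = FALSE]
  s <- stats::sd(up)
  if (!is.finite(s) || s == 0) {
    out <- matrix(0, nrow(scan), ncol(scan))
    attr(out, "constant") <- TRUE
    return(out)
  }
  if (standardize) up <- (up - mean(up)) / s
  attr(up, "constant") <- FALSE
  up
}

#' Foreground-detection configuration
#'
#' Parameters of the composite retinal foreground detector: the wavelet-edge
#' significance multiplier, the upper and lower luminosity-threshold
#' multipliers (the tunable "background level"), the regression of
#' column luminosity towards whole-image luminosity, and the luminosity
#' statistic itself (column/image mean by default, or a percentile).
#'
#' @param edge_sd_multiplier edge is significant at
#'   `mean(edge) + edge_sd_multiplier * sd(edge)` (default 2).
#' @param upper_luminosity_multiplier,lower_luminosity_multiplier positive
#'   multipliers applied to the blended luminosity threshold for the upper
#'   and lower boundary (defaults 1.5).
#' @param luminosity_blend weight of the column statistic in the blend with
#'   the whole-image statistic (default 0.5, i.e. regression towards the
#'   image by 50%).
#' @param luminosity_statistic `NULL` for the mean, or a percentile in
#'   (0, 100].
#' @return object of class `foreground_config`.
#' @export
foreground_config <- function(edge_sd_multiplier = 2,
                              upper_luminosity_multiplier = 1.5,
                              lower_luminosity_multiplier = 1.5,
                              luminosity_blend = 0.5,
                              luminosity_statistic = NULL) {
  if (upper_luminosity_multiplier <= 0 || lower_luminosity_multiplier <= 0)
    stop_config("luminosity multipliers must be > 0")
  check_prob(luminosity_blend, "luminosity_blend")
  if (!is.null(luminosity_statistic) &&
      (luminosity_statistic <= 0 || luminosity_statistic > 100))
    stop_config("'luminosity_statistic' must be a percentile in (0, 100]")
  structure(list(edge_sd_multiplier = edge_sd_multiplier,
                 upper_luminosity_multiplier = upper_luminosity_multiplier,
                 lower_luminosity_multiplier = lower_luminosity_multiplier,
                 luminosity_blend = luminosity_blend,
                 luminosity_statistic = luminosity_statistic),
            class = "foreground_config")
}

lum_stat <- function(x, statistic) {
  if (is.null(statistic)) mean(x)
  else stats::quantile(x, statistic / 100, names = FALSE, type = 7)
}

#' Composite retinal foreground detection
#'
#' Finds, per image column, the first row of retinal tissue from the top and
#' the last from the bottom. The upper boundary uses a composite criterion:
#' a significant wavelet edge (at least `edge_sd_multiplier` SDs above the
#' edge-map mean, statistics computed per scan) OR intensity exceeding a
#' baseline luminosity threshold. The threshold is the column luminosity
#' statistic regressed towards the whole-image statistic by
#' `1 - luminosity_blend`, multiplied by the respective boundary multiplier.
#' The lower boundary uses the intensity threshold alone, since no distinct
#' edge marks the choroid side. Columns with no qualifying row (or an
#' inverted pair) are marked fully background (`NA`).
#'
#' @param scan numeric matrix of intensities.
#' @param edge_map matching edge-magnitude matrix, or `NULL` to compute the
#'   (unstandardised) wavelet edge map internally.
#' @param config a [foreground_config()].
#' @return list with integer vectors `top` and `bottom` (length
#'   `ncol(scan)`, `NA` where fully background).
#' @export
detect_foreground <- function(scan, edge_map = NULL,
                              config = foreground_config()) {
  if (is.null(edge_map)) edge_map <- wavelet_edge_map(scan, standardize = FALSE)
  if (!all(dim(scan) == dim(edge_map)))
    stop_config("scan and edge_map must have the same shape")
  b <- config$luminosity_blend
  l_img <- lum_stat(scan, config$luminosity_statistic)
  l_col <- apply(scan, 2, lum_stat, statistic = config$luminosity_statistic)
  t_up <- config$upper_luminosity_multiplier * (b * l_col + (1 - b) * l_img)
  t_low <- config$lower_luminosity_multiplier * (b * l_col + (1 - b) * l_img)
  # a degenerate edge map (constant scan) carries no significant edges;
  # luminosity must strictly surpass its threshold, so a flat scan at the
  # threshold level stays background
  edge_sd <- stats::sd(edge_map)
  cond_top <- sweep(scan, 2, t_up, ">")
  if (is.finite(edge_sd) && edge_sd > 0)
    cond_top <- cond_top |
      (edge_map >= mean(edge_map) + config$edge_sd_multiplier * edge_sd)
  cond_bot <- sweep(scan, 2, t_low, ">")

  top <- apply(cond_top, 2, function(v) if (any(v)) which(v)[1] else NA_integer_)
  bottom <- apply(cond_bot, 2, function(v) {
    w <- which(v); if (length(w)) w[length(w)] else NA_integer_
  })
  bad <- is.na(top) | is.na(bottom) | top > bottom
  top[bad] <- NA_integer_; bottom[bad] <- NA_integer_
  list(top = as.integer(top), bottom = as.integer(bottom))
}

#' Zero image background outside detected boundaries
#'
#' Sets every pixel above the top boundary or below the bottom boundary of
#' each column exactly to 0, leaving foreground pixels untouched. Fully
#' background columns (`NA` boundaries) are zeroed entirely.
#'
#' @param x a scan matrix, or a 3D volume array (scans first).
#' @param boundaries for a matrix, a list with `top` and `bottom` vectors
#'   (as from [detect_foreground()]); for a volume, a list of such lists,
#'   one per scan.
#' @return object of the same shape with background zeroed.
#' @export
zero_background <- function(x, boundaries) {
  if (is.matrix(x)) return(zero_background_scan(x, boundaries))
  if (is.array(x) && length(dim(x)) == 3) {
    if (length(boundaries) != dim(x)[1])
      stop_config("need one boundary list per scan")
    for (s in seq_len(dim(x)[1]))
      x[s, , ] <- zero_background_scan(x[s, , ], boundaries[[s]])
    return(x)
  }
  stop_config("'x' must be a matrix or 3D array")
}

zero_background_scan <- function(scan, bounds) {
  rows <- seq_len(nrow(scan))
  for (c in seq_len(ncol(scan))) {
    t <- bounds$top[c]; b <- bounds$bottom[c]
    if (is.na(t) || is.na(b)) scan[, c] <- 0
    else scan[c(rows < t | rows > b), c] <- 0
  }
  scan
}

#' Remove background from a preprocessed volume
#'
#' Runs foreground detection on each scan of a percentile-normalised volume
#' and zeroes the background on the normalised scale. Because normalised
#' intensities can be negative, the luminosity criterion is evaluated on a
#' per-scan copy shifted to a zero minimum; boundaries are then applied to
#' the original scan.
#'
#' @param pvolume a [preprocess_volume()] result or 3D array.
#' @param config a [foreground_config()].
#' @return object of the same type with backgrounds set to 0.
#' @export
remove_volume_background <- function(pvolume, config = foreground_config()) {
  arr <- if (inherits(pvolume, "preprocessed_volume")) pvolume$data else pvolume
  for (s in seq_len(dim(arr)[1])) {
    scan <- arr[s, , ]
    shifted <- scan - min(scan)
    bounds <- detect_foreground(shifted, config = config)
    arr[s, , ] <- zero_background_scan(scan, bounds)
  }
  if (inherits(pvolume, "preprocessed_volume")) {
    pvolume$data <- arr
    pvolume
  } else arr
}

#' Per-volume affine augmentation parameters
#'
#' One parameter set describes the single affine transform applied
#' identically to every scan of a volume: horizontal flip, scale (zoom in up
#' to 50% or out up to 20%), rotation within +/-20 degrees and translation
#' within +/-10 pixels per axis.
#'
#' @param rotation degrees in [-20, 20].
#' @param translation length-2 numeric (rows, cols), each in [-10, 10].
#' @param hflip logical, horizontal (left-right) flip.
#' @param scale factor in [0.8, 1.5].
#' @return object of class `augmentation_params`.
#' @export
augmentation_params <- function(rotation = 0, translation = c(0, 0),
                                hflip = FALSE, scale = 1) {
  if (abs(rotation) > 20) stop_config("rotation must be within [-20, 20] degrees")
  if (length(translation) != 2 || any(abs(translation) > 10))
    stop_config("translation must be two values within [-10, 10] pixels")
  if (scale < 0.8 || scale > 1.5)
    stop_config("scale must be within [0.8, 1.5]")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 hflip = isTRUE(hflip), scale = scale),
            class = "augmentation_params")
}

#' Draw random augmentation parameters
#'
#' Rotation ~ U(-20, 20) degrees, translation ~ U(-10, 10) pixels per axis,
#' flip with probability 0.5, and scale zooming in by 0--50% or out by
#' 0--20% with equal probability.
#'
#' @param seed optional integer seed.
#' @return an [augmentation_params()] object.
#' @export
draw_augmentation_params <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scale <- if (stats::runif(1) < 0.5) stats::runif(1, 1, 1.5)
           else stats::runif(1, 0.8, 1)
  augmentation_params(rotation = stats::runif(1, -20, 20),
                      translation = stats::runif(2, -10, 10),
                      hflip = stats::runif(1) < 0.5,
                      scale = scale)
}

# forward affine map acting on (row, col) pixel-centre coordinates about the
# image centre: p' = s * R(theta) * F * (p - centre) + centre + t.
# Coordinates place the centre of pixel i at i - 0.5 (so the image centre is
# (H/2, W/2)), matching the resampler's convention.
augment_matrix <- function(params, H, W) {
  th <- params$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  F <- diag(c(1, if (params$hflip) -1 else 1))
  A <- params$scale * R %*% F
  centre <- c(H / 2, W / 2)
  offset <- centre + params$translation - A %*% centre
  list(A = A, offset = as.numeric(offset))
}

#' Apply one affine augmentation consistently to a whole volume
#'
#' Applies flip, then scale, then rotation, then translation (as a single
#' composed affine map about the image centre, bilinear interpolation,
#' zero fill) to every scan of the volume with identical parameters.
#'
#' @param volume 3D array (scans x rows x cols) or `preprocessed_volume`.
#' @param params an [augmentation_params()] object.
#' @return augmented object of the same type and shape.
#' @export
augment_volume <- function(volume, params) {
  if (!inherits(params, "augmentation_params"))
    stop_config("'params' must be created by augmentation_params()")
  arr <- if (inherits(volume, "preprocessed_volume")) volume$data else volume
  d <- dim(arr)
  m <- augment_matrix(params, d[2], d[3])
  # EBImage::affine maps input to output coordinates as [x y] %*% t(A) + b
  ebm <- rbind(t(m$A), m$offset)
  for (s in seq_len(d[1]))
    arr[s, , ] <- EBImage::affine(arr[s, , ], ebm, filter = "bilinear",
                                  output.dim = c(d[2], d[3]), bg.col = 0)
  if (inherits(volume, "preprocessed_volume")) {
    volume$data <- arr
    volume
  } else arr
}
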