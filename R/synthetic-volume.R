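#' Configuration for the synthetic OCT volume generator
#'
#' Describes a phantom OCT raster volume: a stack of B-scans, each holding a
#' bright, layered, sinusoidally undulating retinal band over a dark
#' background, optionally with dark ellipsoidal fluid pockets embedded inside
#' the band across contiguous scans. Scan counts mirror the acquisition
#' protocols in routine use (19, 25, 31 or 49 line scans).
#'
#' @param n_scans number of B-scans; one of 19, 25, 31, 49 in the emulated
#'   acquisition protocols, but any count >= 1 is accepted.
#' @param height,width native B-scan size in pixels (before standardisation).
#' @param n_fluid_pockets number of fluid pockets when fluid is requested.
#' @param fluid_contrast intensity drop of fluid relative to surrounding
#'   tissue, as a fraction of the [0,1] intensity scale.
#' @param noise_sd SD of additive Gaussian noise, same scale.
#' @param seed integer seed; fixes the phantom exactly.
#' @return an object of class `volume_config`.
#' @export
volume_config <- function(n_scans = 25L, height = 320L, width = 384L,
                          n_fluid_pockets = 3L, fluid_contrast = 0.5,
                          noise_sd = 0.03, seed = 1L) {
  check_count(n_scans, "n_scans")
  check_count(height, "height", min = 16L)
  check_count(width, "width", min = 16L)
  check_count(n_fluid_pockets, "n_fluid_pockets", min = 0L)
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_config("'noise_sd' must be >= 0")
  if (!is.numeric(fluid_contrast) || fluid_contrast <= 0 || fluid_contrast > 1)
    stop_config("'fluid_contrast' must be in (0, 1]")
  structure(list(n_scans = as.integer(n_scans), height = as.integer(height),
                 width = as.integer(width),
                 n_fluid_pockets = as.integer(n_fluid_pockets),
                 fluid_contrast = fluid_contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "volume_config")
}

#' Generate a phantom OCT volume
#'
#' Builds an ordered stack of B-scans containing a smooth two-boundary
#' retinal band (base intensity 0.45--0.80 with layered sinusoidal texture
#' and a bright inner-limiting-membrane-like top line at 0.9) over a 0.05
#' background. When `has_fluid` is `TRUE`, dark ellipsoidal pockets of
#' reduced intensity are embedded strictly inside the band, spanning
#' contiguous scans. Pixel intensities are in [0, 1] before noise; Gaussian
#' noise of SD `config$noise_sd` is then added without clipping.
#'
#' The generator emits its own ground truth: per-scan, per-column top and
#' bottom band boundary rows, which downstream foreground detection is
#' checked against.
#'
#' @param config a [volume_config()] object.
#' @param has_fluid embed fluid pockets?
#' @param eye_id optional identifier stored with the volume.
#' @return an object of class `oct_volume`: list with `data` (array
#'   `n_scans x height x width`), `truth` (list of `top` and `bottom`
#'   integer matrices, `n_scans x width`), `has_fluid`, `eye_id`, `config`.
#' @examples
#' vol <- generate_oct_volume(volume_config(n_scans = 19, seed = 3), has_fluid = TRUE)
#' dim(vol$data)
#' @export
generate_oct_volume <- function(config, has_fluid = FALSE, eye_id = "eye-1") {
  if (!inherits(config, "volume_config"))
    stop_config("'config' must be created by volume_config()")
  set.seed(config$seed)
  ns <- config$n_scans; H <- config$height; W <- config$width

  # band geometry parameters (drawn once per volume)
  base_top <- H * stats::runif(1, 0.25, 0.35)
  amp1 <- H * stats::runif(1, 0.03, 0.07)
  amp2 <- H * stats::runif(1, 0.01, 0.03)
  ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
  thick0 <- H * stats::runif(1, 0.30, 0.38)
  thick_amp <- H * stats::runif(1, 0.01, 0.03)
  drift <- stats::runif(1, -0.5, 0.5)       # slow through-volume tilt

  pockets <- NULL
  if (has_fluid && config$n_fluid_pockets > 0) {
    k <- config$n_fluid_pockets
    pockets <- data.frame(
      s0 = stats::runif(k, 1, ns),
      c0 = stats::runif(k, 0.15 * W, 0.85 * W),
      d0 = stats::runif(k, 0.3, 0.7),                 # depth fraction in band
      rs = pmax(1, ns * stats::runif(k, 0.08, 0.2)),  # radius in scans
      rc = W * stats::runif(k, 0.06, 0.14),           # radius in columns
      rd = stats::runif(k, 0.15, 0.28)                # radius in depth fraction
    )
  }

  cols <- seq_len(W)
  data <- array(0.05, dim = c(ns, H, W))
  top_truth <- bottom_truth <- matrix(0L, ns, W)
  Rmat <- matrix(seq_len(H), H, W)

  for (s in seq_len(ns)) {
    sfrac <- (s - 1) / max(1, ns - 1)
    top_c <- base_top + drift * H * 0.05 * sfrac +
      amp1 * sin(2 * pi * cols / W + ph1 + 0.6 * sfrac) +
      amp2 * sin(4 * pi * cols / W + ph2)
    thick_c <- thick0 + thick_amp * sin(2 * pi * cols / W + ph2 + 1 + 0.4 * sfrac)
    topi <- pmax(3L, pmin(H - 6L, round_half_up(top_c)))
    boti <- pmax(topi + 4L, pmin(H - 2L, round_half_up(top_c + thick_c)))
    top_truth[s, ] <- topi
    bottom_truth[s, ] <- boti

    TOP <- matrix(topi, H, W, byrow = TRUE)
    BOT <- matrix(boti, H, W, byrow = TRUE)
    band <- Rmat >= TOP & Rmat <= BOT
    depth <- (Rmat - TOP) / (BOT - TOP)
    img <- matrix(0.05, H, W)
    img[band] <- 0.45 + 0.175 * (1 + sin(2 * pi * 3 * depth[band]))
    ilm <- Rmat >= TOP & Rmat <= TOP + 1          # bright top line
    img[ilm] <- 0.9

    if (!is.null(pockets)) {
      for (p in seq_len(nrow(pockets))) {
        pk <- pockets[p, ]
        ds <- (s - pk$s0) / pk$rs
        if (abs(ds) > 1) next
        dist2 <- ds^2 + ((col(img) - pk$c0) / pk$rc)^2 + ((depth - pk$d0) / pk$rd)^2
        inside <- band & dist2 <= 1 & depth > 0.08 & depth < 0.92
        img[inside] <- pmax(0.05, img[inside] - config$fluid_contrast)
      }
    }
    data[s, , ] <- img
  }

  if (config$noise_sd > 0)
    data <- data + stats::rnorm(length(data), 0, config$noise_sd)

  structure(list(data = data, truth = list(top = top_truth, bottom = bottom_truth),
                 has_fluid = has_fluid, eye_id = eye_id, config = config),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("OCT volume '%s': %d scans of %d x %d, fluid: %s\n",
              x$eye_id, d[1], d[2], d[3], x$has_fluid))
  invisible(x)
}

#' Write / read an OCT volume as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per B-scan (32-bit float); the sidecar carries the eye id,
#' scan count, fluid flag and the generator's ground-truth band boundaries.
#'
#' @param volume an `oct_volume`.
#' @param path base path without extension; writes `<path>.tif` and
#'   `<path>.json`.
#' @return `read_oct_volume` returns the reconstructed `oct_volume`.
#' @export
write_oct_volume <- function(volume, path) {
  # TIFF float storage is defined for [0, 1]; noisy phantoms can exceed it,
  # so intensities are stored affinely rescaled and restored on read
  lo <- min(volume$data); hi <- max(volume$data)
  span <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(volume$data)[1]),
                  function(s) (volume$data[s, , ] - lo) / span)
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32,
                  reduce = FALSE)
  meta <- list(eye_id = volume$eye_id,
               n_scans = dim(volume$data)[1],
               height = dim(volume$data)[2], width = dim(volume$data)[3],
               has_fluid = volume$has_fluid,
               intensity_range = c(lo, hi),
               truth_top = volume$truth$top,
               truth_bottom = volume$truth$bottom)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_oct_volume
#' @export
read_oct_volume <- function(path) {
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (s in seq_along(pages)) data[s, , ] <- pages[[s]]
  if (!is.null(meta$intensity_range)) {
    lo <- meta$intensity_range[1]; hi <- meta$intensity_range[2]
    data <- data * (if (hi > lo) hi - lo else 1) + lo
  }
  truth <- NULL
  if (!is.null(meta$truth_top))
    truth <- list(top = matrix(as.integer(meta$truth_top), nrow = meta$n_scans),
                  bottom = matrix(as.integer(meta$truth_bottom), nrow = meta$n_scans))
  structure(list(data = data, truth = truth,
                 has_fluid = isTRUE(meta$has_fluid),
                 eye_id = meta$eye_id %||% basename(path), config = NULL),
            class = "oct_volume")
}
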