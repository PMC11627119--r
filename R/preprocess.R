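#' Preprocessing configuration
#'
#' Contrast settings applied to raw scans before volume correlation:
#' contrast-limited adaptive histogram equalization (CLAHE) followed, by
#' default, by a gamma correction of 1.75. CLAHE tile count and clip limit
#' are not dictated by the imaging protocol; the defaults (8 x 8 tiles,
#' clip 0.01) were chosen by the baseline-error sweep in the error-analysis
#' module.
#'
#' @param clahe_tile Tiles per axis for CLAHE (default 8).
#' @param clahe_clip Clip limit as a fraction of the tile histogram
#'   (default 0.01), in (0, 1].
#' @param gamma Gamma exponent (default 1.75), positive.
#' @param gamma_first Apply gamma before CLAHE instead of after
#'   (default `FALSE`).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(clahe_tile = 8, clahe_clip = 0.01,
                              gamma = 1.75, gamma_first = FALSE) {
  stopifnot(gamma > 0, clahe_clip > 0, clahe_clip <= 1, clahe_tile >= 1)
  structure(list(clahe_tile = as.integer(clahe_tile), clahe_clip = clahe_clip,
                 gamma = gamma, gamma_first = gamma_first),
            class = "preprocess_config")
}

#' Contrast-limited adaptive histogram equalization of one scan
#'
#' Applies CLAHE with the configured tile grid and clip limit and returns an
#' 8-bit image. Degenerate (constant) images are returned unchanged since
#' there is no contrast to redistribute.
#'
#' @param scan Numeric matrix of intensities in `[0, 255]` (one B-scan,
#'   `n_r x n_z`).
#' @param config A [preprocess_config()].
#' @return Matrix of the same shape, values in `[0, 255]`.
#' @export
enhance_contrast <- function(scan, config = preprocess_config()) {
  if (!is.matrix(scan) || length(scan) == 0) stop("scan must be a non-empty matrix")
  if (!all(is.finite(scan))) stop("scan intensities must be finite")
  rng <- range(scan)
  if (rng[1] == rng[2]) return(scan)
  # EBImage clahe needs tile sizes dividing evenly; it pads internally.
  nx <- min(config$clahe_tile, floor(nrow(scan) / 2))
  ny <- min(config$clahe_tile, floor(ncol(scan) / 2))
  # clip limit expressed as a fraction of a flat tile histogram; the
  # backend's relative limit is that fraction times the bin count
  out <- EBImage::clahe(EBImage::Image(scan / 255), nx = max(nx, 1),
                        ny = max(ny, 1), limit = config$clahe_clip * 256,
                        bins = 256)
  matrix(pmin(pmax(round(EBImage::imageData(out) * 255), 0), 255),
         nrow(scan), ncol(scan))
}

#' Gamma correction of an 8-bit image
#'
#' `out = round(255 * (in / 255)^gamma)`; the endpoints 0 and 255 are fixed
#' points and the map is monotone non-decreasing.
#'
#' @param scan Numeric matrix or array of intensities in `[0, 255]`.
#' @param gamma Positive exponent (default 1.75).
#' @return Same shape as `scan`, 8-bit values.
#' @examples
#' gamma_correct(matrix(c(0, 128, 255), 1), 1.75)  # 0, 76, 255
#' @export
gamma_correct <- function(scan, gamma = 1.75) {
  if (gamma <= 0) stop("gamma must be positive")
  out <- round(255 * (pmin(pmax(scan, 0), 255) / 255)^gamma)
  out
}

#' Preprocess a whole radial volume
#'
#' Runs [enhance_contrast()] and [gamma_correct()] on every scan of a
#' session volume, in the configured order (CLAHE then gamma by default).
#'
#' @param volume A [radial_volume()].
#' @param config A [preprocess_config()].
#' @return A preprocessed [radial_volume()].
#' @export
preprocess_volume <- function(volume, config = preprocess_config()) {
  g <- volume_geometry(volume)
  out <- array(0, dim(volume))
  for (s in seq_len(g$n_scans)) {
    img <- volume[, s, ]
    if (config$gamma_first) {
      img <- enhance_contrast(gamma_correct(img, config$gamma), config)
    } else {
      img <- gamma_correct(enhance_contrast(img, config), config$gamma)
    }
    out[, s, ] <- img
  }
  radial_volume(out, g)
}
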