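#' Radial scan volume
#'
#' One session's set of radial B-scans held as a 3-D array indexed
#' `[i_r, scan, i_z]` with the acquisition geometry attached. Intensities
#' are 8-bit (0..255) stored as numeric.
#'
#' @param data Numeric array of dimension `c(n_r, n_scans, n_z)`.
#' @param geometry A [radial_scan_geometry()] matching `dim(data)`.
#' @return An object of class `radial_volume`.
#' @export
radial_volume <- function(data, geometry) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!identical(dim(data),
                 c(geometry$n_r, geometry$n_scans, geometry$n_z))) {
    stop("data dimensions do not match geometry (expected n_r x n_scans x n_z)")
  }
  structure(data, geometry = geometry, class = c("radial_volume", "array"))
}

#' @export
print.radial_volume <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("<radial_volume> %d x %d x %d (r x scan x z), intensities [%g, %g]\n",
              g$n_r, g$n_scans, g$n_z, min(x), max(x)))
  invisible(x)
}

#' Geometry of a radial volume or derived field
#' @param x A `radial_volume`, `displacement_field` or `strain_field`.
#' @return The attached [radial_scan_geometry()].
#' @export
volume_geometry <- function(x) {
  g <- attr(x, "geometry")
  if (is.null(g) && is.list(x)) g <- x$geometry
  if (is.null(g)) stop("no geometry attached")
  g
}

# Resolve a continuous scan coordinate onto stored planes.
#
# Scans span 180 deg; continuing past the last scan returns to the first
# diameter rotated 180 deg, i.e. the same plane with the lateral axis
# mirrored about the scan centre. The full period in scan index is therefore
# 2 * n_scans, with the second half mirrored.
resolve_scan_plane <- function(p, n_scans) {
  m <- (round(p) - 1) %% (2L * n_scans)
  mirrored <- m >= n_scans
  plane <- ifelse(mirrored, m - n_scans, m) + 1L
  list(plane = as.integer(plane), mirrored = mirrored)
}

catmull_rom_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  list(
    (-t3 + 2 * t2 - t) / 2,
    (3 * t3 - 5 * t2 + 2) / 2,
    (-3 * t3 + 4 * t2 + t) / 2,
    (t3 - t2) / 2
  )
}

# Bicubic (Catmull-Rom) sample of one stored scan plane at fractional
# (i_r, i_z); indices clamped to the image (edge replication).
sample_plane_cubic <- function(slice, i_r, i_z) {
  n_r <- nrow(slice); n_z <- ncol(slice)
  i_r <- pmin(pmax(i_r, 1), n_r)
  i_z <- pmin(pmax(i_z, 1), n_z)
  r0 <- floor(i_r); fr <- i_r - r0
  z0 <- floor(i_z); fz <- i_z - z0
  wr <- catmull_rom_weights(fr)
  wz <- catmull_rom_weights(fz)
  out <- numeric(length(i_r))
  for (dz in -1:2) {
    zi <- pmin(pmax(z0 + dz, 1), n_z)
    col_acc <- numeric(length(i_r))
    for (dr in -1:2) {
      ri <- pmin(pmax(r0 + dr, 1), n_r)
      col_acc <- col_acc + wr[[dr + 2]] * slice[cbind(ri, zi)]
    }
    out <- out + wz[[dz + 2]] * col_acc
  }
  out
}

# Bilinear sample of one plane (used for label/zero-order needs).
sample_plane_linear <- function(slice, i_r, i_z) {
  n_r <- nrow(slice); n_z <- ncol(slice)
  i_r <- pmin(pmax(i_r, 1), n_r)
  i_z <- pmin(pmax(i_z, 1), n_z)
  r0 <- pmin(floor(i_r), n_r - 1); fr <- i_r - r0
  z0 <- pmin(floor(i_z), n_z - 1); fz <- i_z - z0
  v00 <- slice[cbind(r0, z0)];     v10 <- slice[cbind(r0 + 1, z0)]
  v01 <- slice[cbind(r0, z0 + 1)]; v11 <- slice[cbind(r0 + 1, z0 + 1)]
  (1 - fz) * ((1 - fr) * v00 + fr * v10) + fz * ((1 - fr) * v01 + fr * v11)
}

#' Sample a radial volume at fractional index positions
#'
#' Interpolates intensities at continuous array coordinates: cubic
#' (Catmull-Rom) within each scan plane and linear across the scan-index
#' axis, which is periodic with period `2 * n_scans` (continuing past the
#' last scan re-enters the first scan with the lateral axis mirrored, since
#' each scan is a full diameter). Positions outside the lateral/depth range
#' are clamped to the image edge.
#'
#' @param volume A [radial_volume()].
#' @param i_r,scan,i_z Equal-length numeric vectors of fractional array
#'   coordinates (1-based).
#' @param in_plane `"cubic"` (default) or `"linear"`.
#' @return Numeric vector of interpolated intensities.
#' @export
sample_volume <- function(volume, i_r, scan, i_z, in_plane = c("cubic", "linear")) {
  in_plane <- match.arg(in_plane)
  g <- volume_geometry(volume)
  n <- length(i_r)
  stopifnot(length(scan) == n, length(i_z) == n)
  sampler <- if (in_plane == "cubic") sample_plane_cubic else sample_plane_linear
  s0 <- floor(scan)
  fs <- scan - s0
  out <- numeric(n)
  for (side in 0:1) {
    p <- resolve_scan_plane(s0 + side, g$n_scans)
    w <- if (side == 0) 1 - fs else fs
    live <- which(w > 0)
    if (!length(live)) next
    ir_eff <- ifelse(p$mirrored, 2 * g$scan_center - i_r, i_r)
    for (pl in unique(p$plane[live])) {
      idx <- live[p$plane[live] == pl]
      slice <- volume[, pl, , drop = TRUE]
      out[idx] <- out[idx] + w[idx] * sampler(slice, ir_eff[idx], i_z[idx])
    }
  }
  out
}

#' Add intensity noise to a volume
#'
#' Adds i.i.d. Gaussian intensity noise at a given signal-to-noise ratio and
#' requantises to 8-bit. Used to build replicate ("back-to-back") phantom
#' pairs for baseline-error analysis.
#'
#' @param volume A [radial_volume()].
#' @param snr_db Signal-to-noise ratio in dB; noise SD is
#'   `sd(volume) / 10^(snr_db / 20)`.
#' @param seed Integer seed.
#' @return A new [radial_volume()].
#' @export
perturb_volume <- function(volume, snr_db = 20, seed = 1L) {
  g <- volume_geometry(volume)
  sdn <- stats::sd(volume) / 10^(snr_db / 20)
  noisy <- withr::with_seed(seed, volume + stats::rnorm(length(volume), 0, sdn))
  radial_volume(array(pmin(pmax(round(noisy), 0), 255), dim = dim(volume)), g)
}

#' Write / read a radial volume as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per radial scan (rows = depth, columns = lateral, 8-bit)
#' plus a JSON sidecar holding the scan geometry.
#'
#' @param volume A [radial_volume()].
#' @param path TIFF file path; the sidecar is written at `paste0(path, ".json")`.
#' @return `write_radial_volume` returns `path` invisibly;
#'   `read_radial_volume` returns a [radial_volume()].
#' @export
write_radial_volume <- function(volume, path) {
  g <- volume_geometry(volume)
  pages <- lapply(seq_len(g$n_scans), function(s) t(volume[, s, ]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  jsonlite::write_json(unclass(g), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_radial_volume
#' @export
read_radial_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  gl <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- radial_scan_geometry(
    n_scans = gl$n_scans, angular_step = gl$angular_step,
    n_r = gl$n_r, n_z = gl$n_z, res_r = gl$res_r, res_z = gl$res_z,
    scan_center = gl$scan_center
  )
  arr <- array(0, c(g$n_r, g$n_scans, g$n_z))
  for (s in seq_len(g$n_scans)) arr[, s, ] <- round(t(pages[[s]]) * 255)
  radial_volume(arr, g)
}
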