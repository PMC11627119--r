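#' Radial OCT scan geometry
#'
#' Describes one acquisition session's radial scan pattern: `n_scans` B-scans
#' spaced `angular_step` degrees apart so that they span a half turn
#' (`n_scans * angular_step == 180`). Each B-scan is a full diameter through
#' the scan axis, so the signed radial coordinate `r` runs from
#' `-extent` to `+extent` across a scan and the `r < 0` half of the scan at
#' angle `theta` covers the en-face direction `theta + 180` degrees; together
#' the 180 degrees of scans tile the full circle.
#'
#' @param n_scans Number of radial B-scans per session (device default 24).
#' @param angular_step Angle between adjacent scans in degrees (default 7.5).
#' @param n_r Pixels along the lateral (R) axis of each B-scan (default 768).
#' @param n_z Pixels along the depth (Z) axis (default 495).
#' @param res_r Lateral resolution in micrometres per pixel. The device
#'   calibration varies per eye between about 5.33 and 6.94 um/px; the
#'   default 6.0 is a mid-range value. Downsampled phantoms use larger
#'   values.
#' @param res_z Depth resolution in micrometres per pixel (device value
#'   3.87 um/px, uniform across eyes).
#' @param scan_center Lateral pixel coordinate (1-based, may be fractional)
#'   of the scan axis `r = 0`. Defaults to the image centre `(n_r + 1) / 2`.
#'
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- radial_scan_geometry()
#' g$angular_step * g$n_scans  # 180
#' @export
radial_scan_geometry <- function(n_scans = 24, angular_step = 180 / n_scans,
                                 n_r = 768, n_z = 495,
                                 res_r = 6.0, res_z = 3.87,
                                 scan_center = (n_r + 1) / 2) {
  stopifnot(n_scans >= 2, n_r >= 4, n_z >= 4)
  if (abs(n_scans * angular_step - 180) > 1e-8) {
    stop("radial scans must span a half turn: n_scans * angular_step == 180")
  }
  if (res_r <= 0 || res_z <= 0) stop("pixel resolutions must be positive")
  if (scan_center < 1 || scan_center > n_r) {
    stop("scan_center must lie within the lateral pixel range")
  }
  structure(
    list(n_scans = as.integer(n_scans), angular_step = angular_step,
         n_r = as.integer(n_r), n_z = as.integer(n_z),
         res_r = res_r, res_z = res_z, scan_center = scan_center),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> %d radial scans every %g deg, %d x %d px (res %g x %g um/px)\n",
    x$n_scans, x$angular_step, x$n_r, x$n_z, x$res_r, x$res_z))
  invisible(x)
}

#' Scan angles in degrees
#' @param geometry A [radial_scan_geometry()] object.
#' @return Numeric vector `0, angular_step, ...` of length `n_scans`.
#' @export
scan_angles <- function(geometry) {
  (seq_len(geometry$n_scans) - 1) * geometry$angular_step
}

#' Map a pixel to cylindrical physical coordinates
#'
#' Converts a pixel position on one radial scan to physical cylindrical
#' coordinates about the scan axis. The radial coordinate is signed along the
#' scan (`r = (i_r - scan_center) * res_r`); the reported angle is the scan
#' angle for `r >= 0` and the scan angle plus 180 degrees for the `r < 0`
#' half, with `r` reported as `|r|`, so `(r, theta)` is the usual en-face
#' polar position. Depth is `z = (i_z - 1) * res_z` (1-based pixel centres).
#'
#' @param geometry A [radial_scan_geometry()] object.
#' @param scan_index Scan number, 1-based, in `1..n_scans` (vectorised).
#' @param i_r,i_z Pixel indices, 1-based, may be fractional (vectorised).
#' @return A tibble with columns `r` (um, non-negative), `theta` (degrees in
#'   `[0, 360)`), `z` (um) and the signed radial coordinate `r_signed` (um).
#' @examples
#' g <- radial_scan_geometry()
#' pixel_to_cylindrical(g, 1, g$scan_center + 100, 101)
#' @export
pixel_to_cylindrical <- function(geometry, scan_index, i_r, i_z) {
  n <- max(length(scan_index), length(i_r), length(i_z))
  scan_index <- rep_len(scan_index, n)
  i_r <- rep_len(i_r, n)
  i_z <- rep_len(i_z, n)
  if (any(scan_index < 1 | scan_index > geometry$n_scans)) {
    stop("scan_index out of range")
  }
  if (any(i_r < 0.5 | i_r > geometry$n_r + 0.5 |
          i_z < 0.5 | i_z > geometry$n_z + 0.5)) {
    stop("pixel out of bounds")
  }
  r_signed <- (i_r - geometry$scan_center) * geometry$res_r
  theta <- (scan_index - 1) * geometry$angular_step + ifelse(r_signed < 0, 180, 0)
  tibble::tibble(
    r = abs(r_signed),
    theta = theta %% 360,
    z = (i_z - 1) * geometry$res_z,
    r_signed = r_signed
  )
}

#' Map cylindrical physical coordinates back to a pixel
#'
#' Inverse of [pixel_to_cylindrical()]: folds the en-face angle onto the
#' nearest scan (angles in `[180, 360)` map to the negative-`r` half of the
#' scan at `theta - 180`). Round-trips with [pixel_to_cylindrical()] to
#' within half a pixel (exactly, when `theta` is a scan angle).
#'
#' @inheritParams pixel_to_cylindrical
#' @param r Radial distance in um (non-negative).
#' @param theta En-face angle in degrees.
#' @param z Depth in um.
#' @return A tibble with columns `scan_index`, `i_r`, `i_z` (fractional).
#' @export
cylindrical_to_pixel <- function(geometry, r, theta, z) {
  n <- max(length(r), length(theta), length(z))
  r <- rep_len(r, n); theta <- rep_len(theta, n); z <- rep_len(z, n)
  if (any(r < 0)) stop("r must be non-negative")
  theta <- theta %% 360
  lower <- theta < 180
  scan_theta <- ifelse(lower, theta, theta - 180)
  scan_index <- round(scan_theta / geometry$angular_step) + 1
  # folding theta = 180 - eps rounding up wraps to scan 1 mirrored
  wrap <- scan_index > geometry$n_scans
  scan_index[wrap] <- 1L
  lower[wrap] <- !lower[wrap]
  r_signed <- ifelse(lower, r, -r)
  r_signed[wrap] <- -r_signed[wrap]
  tibble::tibble(
    scan_index = as.integer(scan_index),
    i_r = geometry$scan_center + r_signed / geometry$res_r,
    i_z = z / geometry$res_z + 1
  )
}

#' Cartesian en-face coordinates of scan pixels
#'
#' Physical (x, y, z) positions (um) of every voxel of a session volume, in
#' array order (`i_r` fastest, then scan, then `i_z`). Used by the phantom
#' generator; exported because phantom truth fields are defined in these
#' coordinates.
#'
#' @inheritParams pixel_to_cylindrical
#' @return A list of numeric vectors `x`, `y`, `z`, each of length
#'   `n_r * n_scans * n_z`.
#' @export
scan_voxel_positions <- function(geometry) {
  g <- geometry
  r_signed <- (seq_len(g$n_r) - g$scan_center) * g$res_r
  ang <- scan_angles(g) * pi / 180
  z <- (seq_len(g$n_z) - 1) * g$res_z
  cosr <- outer(r_signed, cos(ang))        # n_r x n_scans
  sinr <- outer(r_signed, sin(ang))
  nrs <- g$n_r * g$n_scans
  list(
    x = rep(as.vector(cosr), times = g$n_z),
    y = rep(as.vector(sinr), times = g$n_z),
    z = rep(z, each = nrs)
  )
}

# Signed radial coordinates (um) of the lateral pixel axis.
r_signed_axis <- function(geometry) {
  (seq_len(geometry$n_r) - geometry$scan_center) * geometry$res_r
}

# Depth coordinates (um) of the z pixel axis.
z_axis <- function(geometry) {
  (seq_len(geometry$n_z) - 1) * geometry$res_z
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(
    a$n_scans == b$n_scans, a$n_r == b$n_r, a$n_z == b$n_z,
    abs(a$angular_step - b$angular_step) < tol,
    abs(a$res_r - b$res_r) < tol, abs(a$res_z - b$res_z) < tol,
    abs(a$scan_center - b$scan_center) < tol
  )
}
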