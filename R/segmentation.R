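#' Piecewise-linear anterior lamina border
#'
#' Interpolates the manually marked anterior lamina cribrosa border samples
#' of one scan into a continuous piecewise-linear depth curve `z(i_r)`
#' (pixel units). Outside the marked span the end segments are extended
#' linearly to the lateral borders of the region.
#'
#' @param landmarks A `landmark_set` (see [make_lc_landmarks()]).
#' @param scan_index Scan number (1-based).
#' @return A function `z(i_r)` returning the border depth in pixel units
#'   (vectorised).
#' @export
interpolate_border <- function(landmarks, scan_index) {
  b <- landmarks$scans[[scan_index]]$border
  if (nrow(b) < 2) stop("need at least 2 border samples per scan")
  if (anyDuplicated(b[, "i_r"])) stop("border samples with duplicate r")
  ord <- order(b[, "i_r"])
  x <- b[ord, "i_r"]; y <- b[ord, "i_z"]
  n <- length(x)
  slope_lo <- (y[2] - y[1]) / (x[2] - x[1])
  slope_hi <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  function(i_r) {
    out <- stats::approx(x, y, xout = i_r, rule = 2)$y
    lo <- i_r < x[1]; hi <- i_r > x[n]
    out[lo] <- y[1] + slope_lo * (i_r[lo] - x[1])
    out[hi] <- y[n] + slope_hi * (i_r[hi] - x[n])
    out
  }
}

# Posterior border as normal offset of the anterior border polyline:
# each anterior point is pushed `thickness` um along its local normal
# (pointing posteriorly), and the resulting curve re-parameterised as
# z_post(r). Falls back to a pure depth offset when `normal_offset = FALSE`.
posterior_border_fun <- function(border_fun, geometry, thickness,
                                 normal_offset = TRUE) {
  g <- geometry
  if (!normal_offset) {
    return(function(i_r) border_fun(i_r) + thickness / g$res_z)
  }
  ir <- seq(1, g$n_r, by = 0.5)
  r_um <- (ir - g$scan_center) * g$res_r
  z_um <- (border_fun(ir) - 1) * g$res_z
  # tangent in physical units; normal = (-tz, tr) normalised, z-positive side
  dr <- diff(r_um); dz <- diff(z_um)
  len <- sqrt(dr^2 + dz^2)
  nr <- c(-dz / len, 0); nz <- c(dr / len, 0)
  nr[length(nr)] <- nr[length(nr) - 1]; nz[length(nz)] <- nz[length(nz) - 1]
  flip <- nz < 0
  nr[flip] <- -nr[flip]; nz[flip] <- -nz[flip]
  r_off <- r_um + thickness * nr
  z_off <- z_um + thickness * nz
  ord <- order(r_off)
  function(i_r) {
    r_q <- (i_r - g$scan_center) * g$res_r
    z_q <- stats::approx(r_off[ord], z_off[ord], xout = r_q, rule = 2)$y
    z_q / g$res_z + 1
  }
}

#' Build the lamina cribrosa analysis region
#'
#' Converts per-scan landmarks into the LC analysis region: laterally
#' bounded by verticals dropped from the Bruch's membrane opening (BMO)
#' endpoints, anteriorly by the interpolated border and posteriorly by the
#' curve `thickness` um posterior to it (offset along the border normal by
#' default, or a pure depth offset). Pixels are labelled by zone (central
#' within `bmo_diameter / 4` of the BMO centre, else peripheral) and by
#' en-face quadrant.
#'
#' A pixel (1-based centre) belongs to the region iff its lateral position
#' lies within the BMO span and its depth satisfies
#' `z_anterior(r) <= z < z_posterior(r)` (half-open in depth).
#'
#' @param landmarks A `landmark_set`.
#' @param geometry A [radial_scan_geometry()].
#' @param thickness Region thickness in um (default 250).
#' @param normal_offset Use the normal-offset posterior border (default
#'   `TRUE`); `FALSE` gives a pure depth offset.
#' @param laterality `"OD"` (right eye, default) or `"OS"`; mirrors the
#'   nasal/temporal quadrant labels.
#' @param axis_orientation En-face angle (degrees) of the nasal axis.
#' @return An object of class `lc_region` with per-scan depth bounds
#'   (`z_lo`, `z_hi`, um, `n_r x n_scans`, `NA` outside the BMO span),
#'   per-pixel-column `zone` and `quadrant` labels, `bmo_center` (en-face
#'   x, y in um) and `bmo_diameter` (um).
#' @export
build_lc_region <- function(landmarks, geometry, thickness = 250,
                            normal_offset = TRUE, laterality = c("OD", "OS"),
                            axis_orientation = 0) {
  laterality <- match.arg(laterality)
  if (thickness <= 0) stop("thickness must be positive")
  g <- geometry
  n <- g$n_scans
  z_lo <- z_hi <- matrix(NA_real_, g$n_r, n)
  span <- matrix(FALSE, g$n_r, n)
  bmo_xy <- matrix(0, 0, 2)
  ang <- scan_angles(g) * pi / 180
  for (s in seq_len(n)) {
    lm <- landmarks$scans[[s]]
    bf <- interpolate_border(landmarks, s)
    pf <- posterior_border_fun(bf, g, thickness, normal_offset)
    ir_lo <- min(lm$bmo[, "i_r"]); ir_hi <- max(lm$bmo[, "i_r"])
    ir <- seq_len(g$n_r)
    inside <- ir >= ir_lo & ir <= ir_hi
    z_lo[inside, s] <- (bf(ir[inside]) - 1) * g$res_z
    z_hi[inside, s] <- (pf(ir[inside]) - 1) * g$res_z
    span[, s] <- inside
    r_ends <- (lm$bmo[, "i_r"] - g$scan_center) * g$res_r
    bmo_xy <- rbind(bmo_xy, cbind(r_ends * cos(ang[s]), r_ends * sin(ang[s])))
  }
  center <- colMeans(bmo_xy)
  bmo_diameter <- 2 * mean(sqrt(rowSums(
    sweep(bmo_xy, 2, center)^2)))
  # en-face position and labels per pixel column (i_r, scan)
  r_signed <- r_signed_axis(g)
  x <- outer(r_signed, cos(ang)) ; y <- outer(r_signed, sin(ang))
  dx <- x - center[1]; dy <- y - center[2]
  rho <- sqrt(dx^2 + dy^2)
  zone <- ifelse(rho < bmo_diameter / 4, "central", "peripheral")
  theta_enface <- (atan2(dy, dx) * 180 / pi) %% 360
  quadrant <- matrix(quadrant_of(pmax(rho, 1e-9), theta_enface,
                                 axis_orientation, laterality),
                     g$n_r, n)
  zone[!span] <- NA; quadrant[!span] <- NA
  structure(list(z_lo = z_lo, z_hi = z_hi, zone = zone, quadrant = quadrant,
                 bmo_center = center, bmo_diameter = bmo_diameter,
                 thickness = thickness, laterality = laterality,
                 geometry = g),
            class = "lc_region")
}

#' @export
print.lc_region <- function(x, ...) {
  cat(sprintf("<lc_region> BMO diameter %.0f um, thickness %g um, %s\n",
              x$bmo_diameter, x$thickness, x$laterality))
  invisible(x)
}

#' Region membership of pixels
#'
#' Tests whether pixel centres lie inside the LC analysis region.
#'
#' @param region An `lc_region`.
#' @param scan_index,i_r Scan and lateral pixel indices (vectorised;
#'   `i_r` is rounded to the nearest pixel column).
#' @param z_um Depth in um.
#' @return Logical vector.
#' @export
region_contains <- function(region, scan_index, i_r, z_um) {
  n <- max(length(scan_index), length(i_r), length(z_um))
  scan_index <- rep_len(as.integer(round(scan_index)), n)
  col <- rep_len(as.integer(round(i_r)), n)
  z_um <- rep_len(z_um, n)
  ok <- scan_index >= 1 & scan_index <= ncol(region$z_lo) &
    col >= 1 & col <= nrow(region$z_lo)
  out <- logical(n)
  idx <- cbind(col[ok], scan_index[ok])
  lo <- region$z_lo[idx]; hi <- region$z_hi[idx]
  out[ok] <- !is.na(lo) & z_um[ok] >= lo & z_um[ok] < hi
  out
}

#' En-face quadrant of a point
#'
#' Assigns superior / inferior / nasal / temporal labels with quadrant
#' boundaries on the +/-45 degree diagonals about the nasal-temporal axis.
#' The boundary itself belongs to the vertical (superior/inferior) sector.
#' Nasal and temporal swap between right (OD) and left (OS) eyes.
#'
#' @param r En-face radius (um), must be positive.
#' @param theta En-face angle in degrees (90 = superior).
#' @param axis_orientation Angle of the nasal axis in degrees (default 0,
#'   i.e. nasal at theta = 0 in OD).
#' @param laterality `"OD"` or `"OS"`.
#' @return Character vector of quadrant labels.
#' @examples
#' quadrant_of(500, 90)   # "superior"
#' quadrant_of(500, 0)    # "nasal" (OD)
#' quadrant_of(500, 0, laterality = "OS")  # "temporal"
#' @export
quadrant_of <- function(r, theta, axis_orientation = 0,
                        laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  if (any(r <= 0)) stop("quadrant undefined at r = 0")
  a <- (theta - axis_orientation) %% 360
  out <- character(n)
  out[a >= 45 & a <= 135] <- "superior"
  out[a >= 225 & a <= 315] <- "inferior"
  horiz1 <- a < 45 | a > 315
  horiz2 <- a > 135 & a < 225
  if (laterality == "OD") {
    out[horiz1] <- "nasal"; out[horiz2] <- "temporal"
  } else {
    out[horiz1] <- "temporal"; out[horiz2] <- "nasal"
  }
  out
}

#' Landmark JSON round trip
#'
#' Writes landmark sets as JSON (`{scans: [{bmo: [[i_r, i_z], ...],
#' border: [[i_r, i_z], ...]}, ...]}`) and reads them back.
#'
#' @param landmarks A `landmark_set`.
#' @param path File path.
#' @param geometry Geometry to attach on read.
#' @return `write_landmarks` returns `path` invisibly; `read_landmarks`
#'   returns a `landmark_set`.
#' @export
write_landmarks <- function(landmarks, path) {
  payload <- list(scans = lapply(landmarks$scans, function(s) {
    list(bmo = unname(apply(s$bmo, 1, function(p) unname(p), simplify = FALSE)),
         border = unname(apply(s$border, 1, function(p) unname(p),
                               simplify = FALSE)))
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path, geometry = NULL) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  scans <- lapply(seq_len(length(payload$scans$bmo)), function(i) {
    bmo <- payload$scans$bmo[[i]]; border <- payload$scans$border[[i]]
    colnames(bmo) <- colnames(border) <- c("i_r", "i_z")
    list(bmo = bmo, border = border)
  })
  structure(list(scans = scans), geometry = geometry, class = "landmark_set")
}
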