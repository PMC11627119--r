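#' Anterior lamina depth change
#'
#' Measures the depth change of the anterior lamina cribrosa border between
#' sessions, relative to the Bruch's membrane opening (BMO) reference line.
#' For every marked border point the axial displacement `U_z` is sampled
#' from the field and referenced to the axial displacement of the straight
#' line joining the two BMO endpoints (each endpoint's displacement sampled
#' from the field, interpolated linearly along the line):
#' `ALD = U_z(border) - U_z(BMO line at the same lateral position)`.
#' Positive values are posterior movement (deeper into the nerve head),
#' negative values anterior movement. The measure cancels global axial
#' motion by construction.
#'
#' Scans where the field is invalid at either BMO endpoint are omitted with
#' a warning; border points where the field cannot be sampled are dropped.
#'
#' @param landmarks A `landmark_set`.
#' @param field A `displacement_field` (filtered; unsmoothed or smoothed).
#' @param geometry Optional [radial_scan_geometry()]; defaults to the
#'   field's.
#' @param fallback_um Search radius (um) for the nearest valid grid point
#'   when the field is invalid exactly at a BMO endpoint (default 200).
#' @return An object of class `ald_result`: tibble `per_scan`
#'   (`scan`, `mean_ald`, `n_points`), `overall` (um, the valid-point mean
#'   pooled across scans) and `n_points`.
#' @export
ald_change <- function(landmarks, field, geometry = NULL,
                       fallback_um = 200) {
  g <- if (is.null(geometry)) field$geometry else geometry
  per_scan <- list()
  all_vals <- numeric(0)
  for (s in seq_along(landmarks$scans)) {
    lm <- landmarks$scans[[s]]
    r_bmo <- (lm$bmo[, "i_r"] - g$scan_center) * g$res_r
    z_bmo <- (lm$bmo[, "i_z"] - 1) * g$res_z
    uz_bmo <- sample_field(field, r_bmo, rep(s, 2), z_bmo,
                           components = "U_z")$U_z
    # BMO marks sit at the lateral edge of the analysis region where the
    # field may be filtered out; fall back to the nearest valid grid point
    # of the same scan within `fallback_um`
    miss <- which(is.na(uz_bmo))
    for (m in miss) {
      uz_bmo[m] <- nearest_valid_uz(field, g, s, r_bmo[m], z_bmo[m],
                                    fallback_um)
    }
    if (all(is.na(uz_bmo))) {
      warning("field invalid at both BMO endpoints; scan ", s, " omitted")
      next
    }
    if (any(is.na(uz_bmo))) uz_bmo[is.na(uz_bmo)] <- uz_bmo[!is.na(uz_bmo)][1]
    r_b <- (lm$border[, "i_r"] - g$scan_center) * g$res_r
    z_b <- (lm$border[, "i_z"] - 1) * g$res_z
    uz_b <- sample_field(field, r_b, rep(s, length(r_b)), z_b,
                         components = "U_z")$U_z
    # axial displacement of the BMO line, linear in lateral position
    t <- (r_b - r_bmo[1]) / (r_bmo[2] - r_bmo[1])
    uz_line <- (1 - t) * uz_bmo[1] + t * uz_bmo[2]
    ald <- uz_b - uz_line
    ald <- ald[is.finite(ald)]
    if (!length(ald)) next
    per_scan[[length(per_scan) + 1]] <-
      tibble::tibble(scan = s, mean_ald = mean(ald), n_points = length(ald))
    all_vals <- c(all_vals, ald)
  }
  if (!length(all_vals)) stop("no scans with a valid BMO reference")
  structure(list(per_scan = dplyr::bind_rows(per_scan),
                 overall = mean(all_vals),
                 n_points = length(all_vals)),
            class = "ald_result")
}

#' @export
print.ald_result <- function(x, ...) {
  cat(sprintf("<ald_result> overall %+.2f um over %d border points (%d scans)\n",
              x$overall, x$n_points, nrow(x$per_scan)))
  invisible(x)
}

# Nearest valid grid point of one scan, in physical (r, z) distance.
nearest_valid_uz <- function(field, g, scan, r_um, z_um, max_um) {
  si <- match(scan, field$grid$scan)
  if (is.na(si)) si <- which.min(abs(field$grid$scan - scan))
  v <- field$valid[, si, ]
  if (!any(v)) return(NA_real_)
  idx <- which(v, arr.ind = TRUE)
  rg <- field$grid$r_um[idx[, 1]]
  zg <- field$grid$z_um[idx[, 2]]
  d2 <- (rg - r_um)^2 + (zg - z_um)^2
  i <- which.min(d2)
  if (sqrt(d2[i]) > max_um) return(NA_real_)
  field$U_z[idx[i, 1], si, idx[i, 2]]
}

#' @rdname ald_change
#' @param x An `ald_result`.
#' @param ... Unused.
#' @method tidy ald_result
#' @export
tidy.ald_result <- function(x, ...) x$per_scan
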