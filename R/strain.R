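quad_design <- function(dr, ds, dz) {
  cbind(1, dr, ds, dz, dr^2, ds^2, dz^2, dr * ds, dr * dz, ds * dz)
}

#' Smooth a displacement field
#'
#' Replaces each physical displacement component by the value at the centre
#' of a moving local least-squares quadratic fit over the valid grid
#' neighbours within `window_radius` grid steps (a Savitzky-Golay-type
#' smoother in three dimensions). Constant and linear fields are reproduced
#' exactly, so uniform strain is unbiased. Points with fewer than 12 valid
#' neighbours (including themselves) are invalidated.
#'
#' @param field A `displacement_field`.
#' @param window_radius Window half-width in grid points (default 2).
#' @return The smoothed `displacement_field`.
#' @export
smooth_displacement <- function(field, window_radius = 2) {
  w <- as.integer(window_radius)
  stopifnot(w >= 1)
  gd <- dim(field$q)
  off <- expand.grid(dr = -w:w, ds = -w:w, dz = -w:w)
  X_full <- quad_design(off$dr, off$ds, off$dz)
  # centre-evaluation kernel for fully valid interior neighbourhoods
  kern <- solve(crossprod(X_full), t(X_full))[1, ]
  valid <- field$valid
  comps <- c("U_r", "U_theta", "U_z")
  sm <- lapply(comps, function(c) array(NA_real_, gd))
  names(sm) <- comps
  new_valid <- array(FALSE, gd)
  # classify points: interior with full valid block -> kernel; else per-point
  nvalid <- block_count(valid, w)
  interior <- array(FALSE, gd)
  if (all(gd > 2 * w)) {
    interior[(w + 1):(gd[1] - w), , (w + 1):(gd[3] - w)] <- TRUE
    # the scan axis is periodic only at spacing-aligned wrap; treat its ends
    # as interior only if the grid covers every scan period step
  }
  full <- interior & nvalid == nrow(off) & valid
  if (any(full)) {
    for (c in comps) {
      conv <- block_apply(field[[c]], w, kern)
      sm[[c]][full] <- conv[full]
    }
    new_valid[full] <- TRUE
  }
  rest <- which(valid & !full, arr.ind = TRUE)
  for (row in seq_len(nrow(rest))) {
    i <- rest[row, 1]; j <- rest[row, 2]; k <- rest[row, 3]
    ri <- max(1, i - w):min(gd[1], i + w)
    sj <- max(1, j - w):min(gd[2], j + w)
    zk <- max(1, k - w):min(gd[3], k + w)
    vsub <- valid[ri, sj, zk, drop = FALSE]
    if (sum(vsub) < 12) next
    d <- expand.grid(dr = ri - i, ds = sj - j, dz = zk - k)
    X <- quad_design(d$dr, d$ds, d$dz)[as.vector(vsub), , drop = FALSE]
    ok <- TRUE
    for (c in comps) {
      y <- field[[c]][ri, sj, zk, drop = FALSE][vsub]
      fit <- stats::lm.fit(X, y)
      b0 <- fit$coefficients[1]
      if (!is.finite(b0)) { ok <- FALSE; break }
      sm[[c]][i, j, k] <- b0
    }
    if (ok) new_valid[i, j, k] <- TRUE
  }
  field$U_r <- sm$U_r; field$U_theta <- sm$U_theta; field$U_z <- sm$U_z
  field$valid <- new_valid
  field$smoothed <- TRUE
  field
}

# Count of TRUE values in each (2w+1)^3 block (edges truncated).
block_count <- function(valid, w) {
  block_apply(array(as.numeric(valid), dim(valid)), w,
              rep(1, (2 * w + 1)^3))
}

# Apply a (2w+1)^3 kernel by shifting; out-of-range neighbours contribute 0.
block_apply <- function(a, w, kern) {
  gd <- dim(a)
  out <- array(0, gd)
  idx <- 0
  for (dz in -w:w) for (ds in -w:w) for (dr in -w:w) {
    idx <- idx + 1
    if (kern[idx] == 0) next
    src_r <- pmin(pmax(seq_len(gd[1]) + dr, 1), gd[1])
    src_s <- pmin(pmax(seq_len(gd[2]) + ds, 1), gd[2])
    src_z <- pmin(pmax(seq_len(gd[3]) + dz, 1), gd[3])
    shifted <- a[src_r, src_s, src_z, drop = FALSE]
    # zero out truly out-of-range (clamped) positions
    bad_r <- seq_len(gd[1]) + dr < 1 | seq_len(gd[1]) + dr > gd[1]
    bad_s <- seq_len(gd[2]) + ds < 1 | seq_len(gd[2]) + ds > gd[2]
    bad_z <- seq_len(gd[3]) + dz < 1 | seq_len(gd[3]) + dz > gd[3]
    if (any(bad_r)) shifted[bad_r, , ] <- 0
    if (any(bad_s)) shifted[, bad_s, ] <- 0
    if (any(bad_z)) shifted[, , bad_z] <- 0
    out <- out + kern[idx] * shifted
  }
  dim(out) <- gd
  out
}

# Fetch the grid-neighbour plane along the scan axis with the half-turn
# mirror: stepping past the last scan plane returns the first plane with
# the lateral grid axis reversed and the in-plane physical components
# (U_r, U_theta) negated.
shift_scan <- function(a, step, flip) {
  gd <- dim(a)
  n_s <- gd[2]
  out <- array(NA_real_, gd)
  for (j in seq_len(n_s)) {
    jj <- j + step
    if (jj >= 1 && jj <= n_s) {
      out[, j, ] <- a[, jj, ]
    } else {
      jw <- ((jj - 1) %% n_s) + 1
      v <- a[rev(seq_len(gd[1])), jw, , drop = FALSE]
      if (flip) v <- -v
      out[, j, ] <- v
    }
  }
  out
}

shift_axis <- function(a, axis, step) {
  gd <- dim(a)
  out <- array(NA_real_, gd)
  src <- seq_len(gd[axis]) + step
  ok <- src >= 1 & src <= gd[axis]
  if (axis == 1) out[ok, , ] <- a[src[ok], , ]
  if (axis == 3) out[, , ok] <- a[, , src[ok]]
  out
}

#' Cylindrical Green-Lagrange strain field
#'
#' Differentiates a (smoothed) displacement field by central differences on
#' its grid and forms the Green-Lagrange tensor
#' `E = (H + H' + H'H) / 2` in the cylindrical physical basis, where the
#' displacement gradient `H` includes the curvature terms `-u_theta / r`
#' and `+u_r / r`, and circumferential derivatives are taken across
#' adjacent grid scan planes (spacing `r * dtheta`, periodic across the
#' half turn). The tensor is exact for rigid motion (zero strain).
#' Points lacking a full stencil of valid neighbours are invalidated, as
#' are points inside the axis-exclusion radius where the circumferential
#' terms are singular.
#'
#' Shear components are reported in the outward-radial physical basis on
#' both halves of each scan. `E_max` and `Gamma_max` are the in-plane
#' (R-Z) maximum principal and maximum shear strains from
#' [principal_rz()].
#'
#' @param field A `displacement_field` (ideally smoothed).
#' @param geometry Optional [radial_scan_geometry()]; defaults to the
#'   field's.
#' @param engineering_shear Report `Gamma_max` as engineering shear
#'   (twice the tensorial value); default `FALSE`.
#' @return An object of class `strain_field` with component arrays
#'   `e_rr, e_tt, e_zz, e_rt, e_zt, e_rz, e_max, gamma_max` on the field's
#'   grid and a validity mask.
#' @export
green_lagrange <- function(field, geometry = NULL,
                           engineering_shear = FALSE) {
  g <- if (is.null(geometry)) field$geometry else geometry
  gd <- dim(field$q)
  grid <- field$grid
  if (length(grid$i_r) < 3 || length(grid$i_z) < 3) {
    stop("grid too small for central differences")
  }
  dr_um <- (grid$i_r[2] - grid$i_r[1]) * g$res_r
  dz_um <- (grid$i_z[2] - grid$i_z[1]) * g$res_z
  ds_rad <- (if (length(grid$scan) > 1) grid$scan[2] - grid$scan[1]
             else g$n_scans) * g$angular_step * pi / 180
  r_um <- grid$r_um
  R <- array(rep(r_um, prod(gd[2:3])), gd)

  U <- list(r = field$U_r, t = field$U_theta, z = field$U_z)
  flip <- c(r = TRUE, t = TRUE, z = FALSE)
  V <- array(as.numeric(field$valid), gd)

  d_dr <- lapply(U, function(a) (shift_axis(a, 1, 1) - shift_axis(a, 1, -1)) /
                   (2 * dr_um))
  d_dz <- lapply(U, function(a) (shift_axis(a, 3, 1) - shift_axis(a, 3, -1)) /
                   (2 * dz_um))
  d_ds <- Map(function(a, f) (shift_scan(a, 1, f) - shift_scan(a, -1, f)) /
                (2 * ds_rad), U, flip)

  stencil_ok <- field$valid &
    (shift_axis(V, 1, 1) == 1) & (shift_axis(V, 1, -1) == 1) &
    (shift_axis(V, 3, 1) == 1) & (shift_axis(V, 3, -1) == 1) &
    (shift_scan(V, 1, FALSE) == 1) & (shift_scan(V, -1, FALSE) == 1)
  stencil_ok[is.na(stencil_ok)] <- FALSE

  # displacement gradient in the cylindrical basis (signed radius)
  H <- list(
    rr = d_dr$r, rt = (d_ds$r - U$t) / R, rz = d_dz$r,
    tr = d_dr$t, tt = (d_ds$t + U$r) / R, tz = d_dz$t,
    zr = d_dr$z, zt = d_ds$z / R,         zz = d_dz$z
  )
  E <- list(
    e_rr = H$rr + (H$rr^2 + H$tr^2 + H$zr^2) / 2,
    e_tt = H$tt + (H$rt^2 + H$tt^2 + H$zt^2) / 2,
    e_zz = H$zz + (H$rz^2 + H$tz^2 + H$zz^2) / 2,
    e_rt = (H$rt + H$tr + H$rr * H$rt + H$tr * H$tt + H$zr * H$zt) / 2,
    e_zt = (H$tz + H$zt + H$rt * H$rz + H$tt * H$tz + H$zt * H$zz) / 2,
    e_rz = (H$rz + H$zr + H$rr * H$rz + H$tr * H$tz + H$zr * H$zz) / 2
  )
  # report shears in the outward-radial basis on the negative-r half
  neg <- R < 0
  E$e_rz[neg] <- -E$e_rz[neg]
  E$e_zt[neg] <- -E$e_zt[neg]

  pr <- principal_rz(E$e_rr, E$e_zz, E$e_rz,
                     engineering_shear = engineering_shear)
  E$e_max <- array(pr$e_max, gd)
  E$gamma_max <- array(pr$gamma_max, gd)
  ok <- stencil_ok & Reduce(`&`, lapply(E, is.finite))
  for (nm in names(E)) E[[nm]][!ok] <- NA_real_
  structure(c(list(grid = grid, valid = ok, geometry = g,
                   engineering_shear = engineering_shear), E),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %s grid, %.1f%% valid\n",
              paste(dim(x$valid), collapse = " x "), 100 * mean(x$valid)))
  invisible(x)
}

#' In-plane principal and maximum shear strain
#'
#' For the 2 x 2 strain submatrix in the scan (R-Z) plane:
#' `E_max = (E_rr + E_zz)/2 + sqrt(((E_rr - E_zz)/2)^2 + E_rz^2)` and the
#' tensorial maximum shear
#' `Gamma_max = sqrt(((E_rr - E_zz)/2)^2 + E_rz^2)` (half the difference of
#' the in-plane principal strains; engineering shear is twice that).
#'
#' @param e_rr,e_zz,e_rz In-plane strain components (vectorised).
#' @param engineering_shear Double `Gamma_max` (default `FALSE`).
#' @return A list with `e_max` and `gamma_max`.
#' @examples
#' principal_rz(0.005, -0.005, 0)  # e_max 0.005, gamma_max 0.005
#' @export
principal_rz <- function(e_rr, e_zz, e_rz, engineering_shear = FALSE) {
  rad <- sqrt(((e_rr - e_zz) / 2)^2 + e_rz^2)
  list(e_max = (e_rr + e_zz) / 2 + rad,
       gamma_max = if (engineering_shear) 2 * rad else rad)
}

#' Region summaries of a strain field
#'
#' Valid-point mean and SD of every strain component over the LC analysis
#' region and its partitions. The full-LC mean is the plain valid-point
#' mean (not zone-weighted).
#'
#' @param strain A `strain_field`.
#' @param region An `lc_region`.
#' @param labels Regions to report among `"full"`, `"central"`,
#'   `"peripheral"`, `"superior"`, `"inferior"`, `"nasal"`, `"temporal"`.
#' @return A tibble with columns `region`, `component`, `mean`, `sd`, `n`.
#' @export
summarize_region <- function(strain, region,
                             labels = c("full", "central", "peripheral",
                                        "superior", "inferior", "nasal",
                                        "temporal")) {
  labels <- match.arg(labels, several.ok = TRUE)
  gd <- dim(strain$valid)
  pts <- expand.grid(i_r = strain$grid$i_r, scan = strain$grid$scan,
                     i_z = strain$grid$i_z)
  g <- strain$geometry
  inr <- region_contains(region, pts$scan, pts$i_r,
                         (pts$i_z - 1) * g$res_z)
  col <- pmin(pmax(as.integer(round(pts$i_r)), 1), nrow(region$zone))
  lab_idx <- cbind(col, pts$scan)
  zone <- region$zone[lab_idx]
  quad <- region$quadrant[lab_idx]
  keep <- inr & as.vector(strain$valid)
  if (!any(keep)) stop("no valid strain points in region")
  rows <- list()
  sel_for <- function(lab) {
    switch(lab,
           full = keep,
           central = keep & !is.na(zone) & zone == "central",
           peripheral = keep & !is.na(zone) & zone == "peripheral",
           keep & !is.na(quad) & quad == lab)
  }
  for (lab in labels) {
    sel <- sel_for(lab)
    if (!any(sel)) next
    for (comp in strain_components) {
      v <- as.vector(strain[[comp]])[sel]
      rows[[length(rows) + 1]] <- tibble::tibble(
        region = lab, component = comp,
        mean = mean(v), sd = stats::sd(v), n = length(v))
    }
  }
  dplyr::bind_rows(rows)
}
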