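#' Fast-iterative DVC configuration
#'
#' Controls the subset correlation schedule. Volumes are treated as
#' anisotropic 3-D arrays `(i_r, scan, i_z)` with a periodic (mirrored)
#' scan-index axis. Subsets start at `initial_subset` and halve in-plane
#' each iteration ("decreased by a factor of two") down to `min_subset`;
#' the scan-index extent stays fixed because only `n_scans` samples exist
#' along that axis.
#'
#' @param initial_subset Integer triple `(r, scan, z)` of the first-iteration
#'   subset size in voxels (default `c(64, 8, 64)`).
#' @param min_subset Integer triple of the smallest allowed subset
#'   (default `c(16, 8, 16)`).
#' @param overlap Fractional overlap of neighbouring subsets in `[0, 0.9]`
#'   (default 0.5; grid spacing is `subset * (1 - overlap)`).
#' @param max_iterations Maximum FI-DVC iterations (default 3).
#' @param window_sigma_frac Gaussian window SD as a fraction of the subset
#'   size (default 0.25); the window tapers each subset before
#'   cross-correlation to preserve high-spatial-frequency content.
#' @param convergence_tol Stop when the largest displacement increment falls
#'   below this many voxels (default 0.05).
#' @param search_frac Correlation peak search radius as a fraction of the
#'   subset size (default 0.25).
#' @param axis_exclusion_um Grid points with en-face radius below this are
#'   marked invalid (circumferential conversion is singular at the axis).
#'   Default `NULL` uses half the final in-plane subset extent.
#' @return An object of class `dvc_config`.
#' @export
dvc_config <- function(initial_subset = c(64, 8, 64),
                       min_subset = c(16, 8, 16),
                       overlap = 0.5, max_iterations = 3,
                       window_sigma_frac = 0.25, convergence_tol = 0.05,
                       search_frac = 0.25, axis_exclusion_um = NULL) {
  stopifnot(length(initial_subset) == 3, length(min_subset) == 3,
            all(initial_subset >= min_subset), overlap >= 0, overlap <= 0.9,
            max_iterations >= 1, convergence_tol > 0)
  structure(list(initial_subset = as.integer(initial_subset),
                 min_subset = as.integer(min_subset),
                 overlap = overlap, max_iterations = as.integer(max_iterations),
                 window_sigma_frac = window_sigma_frac,
                 convergence_tol = convergence_tol,
                 search_frac = search_frac,
                 axis_exclusion_um = axis_exclusion_um),
            class = "dvc_config")
}

# Subset sizes at iteration k: in-plane axes halve, scan axis fixed.
subset_schedule <- function(config) {
  lapply(seq_len(config$max_iterations), function(k) {
    s <- pmax(round(config$initial_subset / 2^(k - 1)), config$min_subset)
    s[2] <- config$initial_subset[2]
    as.integer(s)
  })
}

gaussian_window <- function(size, sigma_frac) {
  axes <- lapply(size, function(n) {
    x <- seq_len(n) - (n + 1) / 2
    exp(-x^2 / (2 * (sigma_frac * n)^2))
  })
  outer(outer(axes[[1]], axes[[2]]), axes[[3]])
}

# 3-point subpixel peak offset along one axis given correlation values
# (cm, c0, cp) at lags (-1, 0, +1). Gaussian fit when all positive,
# parabolic otherwise; ties resolved toward the smaller lag.
subpixel_offset <- function(cm, c0, cp) {
  if (any(!is.finite(c(cm, c0, cp)))) return(0)
  if (cm > 0 && c0 > 0 && cp > 0) {
    lm <- log(cm); l0 <- log(c0); lp <- log(cp)
    den <- 2 * (lm + lp - 2 * l0)
    if (den >= 0) return(0)
    off <- (lm - lp) / den
  } else {
    den <- 2 * (cm + cp - 2 * c0)
    if (den >= 0) return(0)
    off <- (cm - cp) / den
  }
  max(min(off, 0.5), -0.5)
}

#' Windowed subset cross-correlation
#'
#' Correlates one reference subset against the corresponding subset of the
#' deformed volume: both blocks are mean-removed under a Gaussian window,
#' cross-correlated by FFT, and the peak located to subpixel precision by a
#' separable three-point Gaussian (or parabolic) fit. The weighted
#' correlation coefficient `q` is the normalized correlation value at the
#' peak and is the quantity thresholded by the correlation filter.
#'
#' @param ref_subset,def_subset Numeric arrays of identical dimension.
#' @param window_sigma_frac Gaussian window SD as a fraction of subset size.
#' @param search Integer vector of per-axis peak search radii (voxels);
#'   default `dim / 4`.
#' @return A list with `du` (length-3 displacement of the deformed subset
#'   relative to the reference, voxels), `q` (weighted correlation
#'   coefficient; 0 for zero-variance subsets) and `valid`.
#' @examples
#' a <- array(rnorm(16 * 4 * 16), c(16, 4, 16))
#' correlate_subset(a, a)$du  # c(0, 0, 0)
#' @export
correlate_subset <- function(ref_subset, def_subset,
                             window_sigma_frac = 0.25, search = NULL) {
  d <- dim(ref_subset)
  if (is.null(d)) d <- c(length(ref_subset), 1, 1)
  stopifnot(identical(dim(ref_subset), dim(def_subset)))
  if (is.null(search)) search <- pmax(1, floor(d / 4))
  search <- pmin(pmax(search, 0), floor((d - 1) / 2))
  w <- gaussian_window(d, window_sigma_frac)
  corr_core(ref_subset, def_subset, w, d, search)
}

corr_core <- function(f, g, w, d, search) {
  sw <- sum(w)
  mf <- sum(w * f) / sw
  mg <- sum(w * g) / sw
  a <- w * (f - mf)
  b <- w * (g - mg)
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 < 1e-12 || nb2 < 1e-12) {
    return(list(du = c(0, 0, 0), q = 0, valid = FALSE))
  }
  C <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    (length(a) * sqrt(na2 * nb2))
  dim(C) <- d
  # circular lags; restrict the peak search to +/- search around zero lag
  lagidx <- lapply(1:3, function(ax) {
    L <- search[ax]
    if (L == 0) return(1L)
    c(seq_len(L + 1), (d[ax] - L + 1):d[ax])
  })
  lags <- lapply(1:3, function(ax) {
    L <- search[ax]
    if (L == 0) return(0L)
    c(0:L, -(L:1))
  })
  sub <- C[lagidx[[1]], lagidx[[2]], lagidx[[3]], drop = FALSE]
  pk <- arrayInd(which.max(sub), dim(sub))
  q <- sub[pk]
  du <- numeric(3)
  for (ax in 1:3) {
    ilag <- lags[[ax]][pk[ax]]
    L <- search[ax]
    if (L == 0 || abs(ilag) >= L) { du[ax] <- ilag; next }
    at <- function(off) {
      idx <- pk; idx[ax] <- match(ilag + off, lags[[ax]])
      sub[matrix(idx, 1)]
    }
    du[ax] <- ilag + subpixel_offset(at(-1), at(0), at(1))
  }
  list(du = du, q = q, valid = TRUE)
}

# Extend a volume array along the scan axis by `pad` planes on each side
# using the half-turn mirror convention, so subset extraction never needs
# per-plane wrap logic. Returns the array plus the scan-index offset.
extend_scan_axis <- function(arr, geometry, pad) {
  g <- geometry
  n_s <- g$n_scans
  mirror_r <- round(2 * g$scan_center - seq_len(g$n_r))
  mirror_r <- pmin(pmax(mirror_r, 1), g$n_r)
  lo <- (n_s - pad + 1):n_s
  hi <- 1:pad
  ext <- array(0, c(g$n_r, n_s + 2 * pad, g$n_z))
  ext[, pad + seq_len(n_s), ] <- arr
  ext[, seq_len(pad), ] <- arr[mirror_r, lo, , drop = FALSE]
  ext[, pad + n_s + seq_len(pad), ] <- arr[mirror_r, hi, , drop = FALSE]
  list(data = ext, offset = pad)
}

# Correlation grid for a given subset size: in-plane positions symmetric
# about the scan centre / mid-depth (so the half-turn mirror maps grid onto
# grid), scan positions every `spacing_s` scans.
make_grid <- function(geometry, subset, overlap) {
  g <- geometry
  sp_r <- max(1, round(subset[1] * (1 - overlap)))
  sp_z <- max(1, round(subset[3] * (1 - overlap)))
  sp_s <- max(1, round(subset[2] * (1 - overlap)))
  half_r <- subset[1] / 2; half_z <- subset[3] / 2
  m_r <- floor((g$scan_center - 1 - half_r) / sp_r)
  c_z <- (g$n_z + 1) / 2
  m_z <- floor((c_z - 1 - half_z) / sp_z)
  if (m_r < 0 || m_z < 0) stop("subset larger than image")
  list(
    i_r = g$scan_center + (-m_r:m_r) * sp_r,
    scan = seq(1, g$n_scans, by = sp_s),
    i_z = c_z + (-m_z:m_z) * sp_z
  )
}

# Trilinear interpolation of a gridded field with the mirrored-periodic
# scan axis. `flip` marks components whose sign reverses across the
# half-turn wrap (the in-plane components u_r and u_theta/u_s).
interp_grid3 <- function(grid, arr, irq, sq, izq, n_scans, flip = FALSE) {
  rpos <- grid$i_r; spos <- grid$scan; zpos <- grid$i_z
  n_rg <- length(rpos); n_sg <- length(spos); n_zg <- length(zpos)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  # r axis
  if (n_rg == 1) { r0 <- rep(1L, length(irq)); tr <- numeric(length(irq)); r1 <- r0 }
  else {
    r0 <- pmin(pmax(findInterval(irq, rpos), 1), n_rg - 1)
    tr <- clamp01((irq - rpos[r0]) / (rpos[r0 + 1] - rpos[r0]))
    r1 <- r0 + 1L
  }
  # z axis
  if (n_zg == 1) { z0 <- rep(1L, length(izq)); tz <- numeric(length(izq)); z1 <- z0 }
  else {
    z0 <- pmin(pmax(findInterval(izq, zpos), 1), n_zg - 1)
    tz <- clamp01((izq - zpos[z0]) / (zpos[z0 + 1] - zpos[z0]))
    z1 <- z0 + 1L
  }
  # scan axis: period 2 * n_scans with mirror in the second half
  ds <- if (n_sg > 1) spos[2] - spos[1] else n_scans
  P <- 2 * n_scans
  u <- (sq - spos[1]) %% P
  j0 <- floor(u / ds)
  ts <- clamp01((u - j0 * ds) / ds)
  n_ext <- 2 * n_sg
  j0 <- j0 %% n_ext
  j1 <- (j0 + 1) %% n_ext
  s_idx <- function(j) as.integer(ifelse(j < n_sg, j + 1, j - n_sg + 1))
  s_mir <- function(j) j >= n_sg
  corner <- function(ri, j, zi) {
    mir <- s_mir(j)
    rid <- ifelse(mir, n_rg + 1L - ri, ri)
    v <- arr[cbind(rid, s_idx(j), zi)]
    if (flip) v <- ifelse(mir, -v, v)
    v
  }
  (1 - ts) * ((1 - tz) * ((1 - tr) * corner(r0, j0, z0) + tr * corner(r1, j0, z0)) +
                tz * ((1 - tr) * corner(r0, j0, z1) + tr * corner(r1, j0, z1))) +
    ts * ((1 - tz) * ((1 - tr) * corner(r0, j1, z0) + tr * corner(r1, j1, z0)) +
            tz * ((1 - tr) * corner(r0, j1, z1) + tr * corner(r1, j1, z1)))
}

# Sample the cumulative index-space displacement at arbitrary voxel
# positions.
displacement_at_voxels <- function(grid, du_r, du_s, du_z, irq, sq, izq,
                                   n_scans) {
  # across the half-turn wrap the lateral index direction reverses, so the
  # du_r component flips sign; the scan-index and depth components do not.
  list(
    r = interp_grid3(grid, du_r, irq, sq, izq, n_scans, flip = TRUE),
    s = interp_grid3(grid, du_s, irq, sq, izq, n_scans, flip = FALSE),
    z = interp_grid3(grid, du_z, irq, sq, izq, n_scans, flip = FALSE)
  )
}

#' Warp a volume through a displacement field
#'
#' Resamples intensities through the (cumulative) field: `toward_ref`
#' samples the volume at `x + u(x)` (pulls the deformed volume back onto
#' the reference frame), `toward_def` samples at `x - u(x)`.
#'
#' @param volume A [radial_volume()].
#' @param field A `displacement_field` from [dvc_register()].
#' @param direction `"toward_ref"` or `"toward_def"`.
#' @return A warped [radial_volume()].
#' @export
warp_volume <- function(volume, field, direction = c("toward_ref", "toward_def")) {
  direction <- match.arg(direction)
  g <- volume_geometry(volume)
  if (any(!is.finite(field$du_r[field$valid])) ||
      any(!is.finite(field$du_s[field$valid])) ||
      any(!is.finite(field$du_z[field$valid]))) {
    stop("NaN displacements inside the valid mask")
  }
  sgn <- if (direction == "toward_ref") 1 else -1
  vox <- expand_voxels(g)
  u <- displacement_at_voxels(field$grid, zero_invalid(field$du_r, field$valid),
                              zero_invalid(field$du_s, field$valid),
                              zero_invalid(field$du_z, field$valid),
                              vox$i_r, vox$scan, vox$i_z, g$n_scans)
  vals <- sample_volume(volume, vox$i_r + sgn * u$r, vox$scan + sgn * u$s,
                        vox$i_z + sgn * u$z)
  radial_volume(array(pmin(pmax(vals, 0), 255), dim = dim(volume)), g)
}

zero_invalid <- function(a, valid) { a[!valid] <- 0; a }

expand_voxels <- function(g) {
  list(
    i_r = rep(seq_len(g$n_r), times = g$n_scans * g$n_z),
    scan = rep(rep(seq_len(g$n_scans), each = g$n_r), times = g$n_z),
    i_z = rep(seq_len(g$n_z), each = g$n_r * g$n_scans)
  )
}

#' Register two radial volumes by fast-iterative DVC
#'
#' Estimates the displacement field mapping the reference ("before") volume
#' to the deformed ("after") volume. Each iteration correlates Gaussian-
#' windowed subsets on a grid, accumulates the displacement increment
#' (`u^k = u^(k-1) + du^k`), warps the deformed volume back toward the
#' reference through the cumulative field, and halves the in-plane subset
#' size. Pixel displacements are converted to physical micrometres via the
#' geometry; the circumferential component uses the local signed radius
#' (`U_theta = du_scan * r * angular_step`), and grid points closer to the
#' scan axis than the axis-exclusion radius are marked invalid.
#'
#' @param ref,def [radial_volume()]s sharing a geometry, 8-bit intensities.
#' @param config A [dvc_config()].
#' @return An object of class `displacement_field`: grid coordinates
#'   (`grid$i_r`, `grid$scan`, `grid$i_z` in array units; `r_um` signed,
#'   `theta_deg`, `z_um` physical), index-unit displacement arrays `du_r`,
#'   `du_s`, `du_z`, physical `U_r`, `U_theta`, `U_z` (um), weighted
#'   correlation coefficient `q`, logical `valid`, per-iteration
#'   `increments` (um, on the same grid), and the iteration count.
#' @export
dvc_register <- function(ref, def, config = dvc_config()) {
  g <- volume_geometry(ref)
  if (!same_geometry(g, volume_geometry(def))) {
    stop("reference and deformed volumes must share geometry")
  }
  sched <- subset_schedule(config)
  final_grid <- make_grid(g, sched[[length(sched)]], config$overlap)
  gd <- lengths(final_grid)
  du_r <- du_s <- du_z <- array(0, gd)
  qarr <- array(0, gd)
  varr <- array(TRUE, gd)
  increments <- list()
  ref_arr <- unclass(ref)
  k_used <- 0L
  for (k in seq_along(sched)) {
    S <- sched[[k]]
    grid_k <- make_grid(g, S, config$overlap)
    pad <- S[2]
    ext_ref <- extend_scan_axis(ref_arr, g, pad)
    def_k <- if (k == 1) def else {
      warp_volume(def, list(grid = final_grid, du_r = du_r, du_s = du_s,
                            du_z = du_z, valid = varr),
                  "toward_ref")
    }
    ext_def <- extend_scan_axis(unclass(def_k), g, pad)
    res <- correlate_on_grid(ext_ref, ext_def, grid_k, S, config, g)
    k_used <- k
    # interpolate this iteration's increment onto the final grid
    fq <- expand.grid(i_r = final_grid$i_r, scan = final_grid$scan,
                      i_z = final_grid$i_z)
    # expand.grid varies the first factor fastest: matches array order
    inc <- displacement_at_voxels(grid_k, res$du_r, res$du_s, res$du_z,
                                  fq$i_r, fq$scan, fq$i_z, g$n_scans)
    inc_r <- array(inc$r, gd); inc_s <- array(inc$s, gd)
    inc_z <- array(inc$z, gd)
    du_r <- du_r + inc_r; du_s <- du_s + inc_s; du_z <- du_z + inc_z
    increments[[k]] <- list(du_r = inc_r, du_s = inc_s, du_z = inc_z)
    qarr[] <- interp_grid3(grid_k, res$q, fq$i_r, fq$scan, fq$i_z, g$n_scans)
    max_inc <- max(abs(c(res$du_r[res$valid], res$du_s[res$valid],
                         res$du_z[res$valid])), 0)
    if (max_inc < config$convergence_tol && k < length(sched)) break
  }
  r_um <- (final_grid$i_r - g$scan_center) * g$res_r
  axis_excl <- config$axis_exclusion_um
  if (is.null(axis_excl)) {
    axis_excl <- sched[[length(sched)]][1] / 2 * g$res_r
  }
  valid <- varr & array(rep(abs(r_um) >= axis_excl, prod(gd[2:3])), gd)
  if (!any(valid)) stop("no valid subsets")
  dtheta_rad <- g$angular_step * pi / 180
  field <- structure(list(
    grid = c(final_grid,
             list(r_um = r_um,
                  theta_deg = (final_grid$scan - 1) * g$angular_step,
                  z_um = (final_grid$i_z - 1) * g$res_z)),
    du_r = du_r, du_s = du_s, du_z = du_z,
    U_r = du_r * g$res_r,
    U_theta = du_s * dtheta_rad *
      array(rep(r_um, prod(gd[2:3])), gd),
    U_z = du_z * g$res_z,
    q = qarr, valid = valid,
    increments = increments, iterations = k_used,
    config = config, geometry = g,
    filter_log = list()
  ), class = "displacement_field")
  field
}

correlate_on_grid <- function(ext_ref, ext_def, grid, S, config, g) {
  nr <- length(grid$i_r); ns <- length(grid$scan); nz <- length(grid$i_z)
  du_r <- du_s <- du_z <- array(0, c(nr, ns, nz))
  qarr <- array(0, c(nr, ns, nz))
  varr <- array(FALSE, c(nr, ns, nz))
  w <- gaussian_window(S, config$window_sigma_frac)
  search <- pmax(1, floor(S * config$search_frac))
  search[2] <- min(search[2], floor((S[2] - 1) / 2))
  off_r <- seq_len(S[1]) - floor(S[1] / 2)
  off_s <- seq_len(S[2]) - floor(S[2] / 2)
  off_z <- seq_len(S[3]) - floor(S[3] / 2)
  for (iz in seq_len(nz)) {
    # floor-based lattice: half-integer grid centres must not produce
    # duplicated rows (round-half-to-even would), which would inject a
    # spurious zero-lag correlation component
    zidx <- pmin(pmax(floor(grid$i_z[iz]) + off_z, 1), g$n_z)
    for (is in seq_len(ns)) {
      sidx <- grid$scan[is] + off_s + ext_ref$offset
      for (ir in seq_len(nr)) {
        ridx <- pmin(pmax(floor(grid$i_r[ir]) + off_r, 1), g$n_r)
        f <- ext_ref$data[ridx, sidx, zidx, drop = FALSE]
        gg <- ext_def$data[ridx, sidx, zidx, drop = FALSE]
        res <- corr_core(f, gg, w, S, search)
        du_r[ir, is, iz] <- res$du[1]
        du_s[ir, is, iz] <- res$du[2]
        du_z[ir, is, iz] <- res$du[3]
        qarr[ir, is, iz] <- res$q
        varr[ir, is, iz] <- res$valid
      }
    }
  }
  du_r[!varr] <- 0; du_s[!varr] <- 0; du_z[!varr] <- 0
  list(du_r = du_r, du_s = du_s, du_z = du_z, q = qarr, valid = varr)
}

#' @export
print.displacement_field <- function(x, ...) {
  gd <- dim(x$q)
  cat(sprintf(
    "<displacement_field> %d x %d x %d grid, %d iteration(s), %.1f%% valid\n",
    gd[1], gd[2], gd[3], x$iterations, 100 * mean(x$valid)))
  invisible(x)
}

#' Sample physical displacement components at cylindrical positions
#'
#' Validity-aware interpolation of a displacement field: corners of the
#' interpolation cell that are invalid are dropped and the weights
#' renormalised; positions whose total valid weight is below `min_weight`
#' return `NA`.
#'
#' @param field A `displacement_field`.
#' @param r_signed_um Signed radial position (um) along the scan.
#' @param scan_index Scan number (may be fractional).
#' @param z_um Depth (um).
#' @param components Character vector among `"U_r"`, `"U_theta"`, `"U_z"`.
#' @param min_weight Minimum total valid interpolation weight (default 0.5).
#' @return A tibble with one column per requested component.
#' @export
sample_field <- function(field, r_signed_um, scan_index, z_um,
                         components = c("U_r", "U_theta", "U_z"),
                         min_weight = 0.5) {
  g <- field$geometry
  irq <- g$scan_center + r_signed_um / g$res_r
  izq <- z_um / g$res_z + 1
  wsum <- interp_grid3(field$grid, array(as.numeric(field$valid),
                                         dim(field$q)),
                       irq, scan_index, izq, g$n_scans)
  out <- lapply(components, function(comp) {
    flip <- comp %in% c("U_r", "U_theta")
    v <- interp_grid3(field$grid, zero_invalid(field[[comp]], field$valid),
                      irq, scan_index, izq, g$n_scans, flip = flip)
    ifelse(wsum >= min_weight, v / pmax(wsum, 1e-12), NA_real_)
  })
  names(out) <- components
  tibble::as_tibble(out)
}
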