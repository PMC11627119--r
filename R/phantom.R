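#' Default anterior lamina border depth profile
#'
#' A gently bowed anterior lamina cribrosa border: depth in um as a function
#' of en-face radial distance rho (um). Used as the default by both the
#' layered speckle generator and [make_lc_landmarks()] so the phantom
#' texture and its landmarks agree.
#'
#' @param rho En-face radial distance from the scan axis, um.
#' @return Depth z in um (positive = deeper / more posterior).
#' @export
default_border_profile <- function(rho) {
  320 - 30 * (pmin(rho, 1200) / 800)^2
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Generate a synthetic radial speckle volume
#'
#' Builds a band-limited random-phase speckle field — a sum of cosine plane
#' waves with isotropic random wave vectors concentrated at spatial
#' frequency `~1/grain_size` — evaluated at the physical position of every
#' voxel of the radial scan pattern, optionally modulated by a layered
#' lamina-like intensity envelope, then contrast-stretched to 8-bit. The
#' field is a continuous function of physical position, so the texture is
#' consistent across neighbouring scans and exactly reproducible.
#'
#' @param geometry A [radial_scan_geometry()].
#' @param grain_size Speckle autocorrelation length (full width) in um. Must
#'   be at least twice the finest pixel resolution so the pattern is
#'   resolvable after warping.
#' @param seed Integer seed; fixed seed gives bit-identical volumes.
#' @param n_components Number of plane-wave components (texture richness).
#' @param layered If `TRUE`, modulate intensity with a depth envelope that is
#'   dim above the anterior lamina border, bright within the lamina plate
#'   (border to border + 300 um) and intermediate below it.
#' @param border_profile Depth profile of the anterior lamina border used by
#'   the layered envelope, as a function of en-face radius (um -> um).
#' @return A [radial_volume()] of 8-bit intensities.
#' @examples
#' g <- radial_scan_geometry(n_scans = 12, n_r = 64, n_z = 48, res_r = 12,
#'                           res_z = 8)
#' v <- generate_speckle_volume(g, grain_size = 30, seed = 1)
#' @export
generate_speckle_volume <- function(geometry, grain_size = 15, seed = 1L,
                                    n_components = 192, layered = TRUE,
                                    border_profile = default_border_profile) {
  finest <- min(geometry$res_r, geometry$res_z)
  if (grain_size < 2 * finest) {
    stop("grain_size must be at least twice the finest pixel resolution (",
         "got ", grain_size, " um vs resolution ", finest, " um)")
  }
  pos <- scan_voxel_positions(geometry)
  k0 <- 3.79 / grain_size  # FWHM of the autocorrelation peak ~ grain_size
  f <- withr::with_seed(seed, {
    u <- stats::rnorm(n_components)
    v <- stats::rnorm(n_components)
    w <- stats::rnorm(n_components)
    nrm <- sqrt(u^2 + v^2 + w^2)
    kmag <- abs(stats::rnorm(n_components, k0, k0 / 6))
    kx <- kmag * u / nrm; ky <- kmag * v / nrm; kz <- kmag * w / nrm
    amp <- stats::rnorm(n_components)
    phase <- stats::runif(n_components, 0, 2 * pi)
    acc <- numeric(length(pos$x))
    for (j in seq_len(n_components)) {
      acc <- acc + amp[j] *
        cos(kx[j] * pos$x + ky[j] * pos$y + kz[j] * pos$z + phase[j])
    }
    acc
  })
  if (layered) {
    rho <- sqrt(pos$x^2 + pos$y^2)
    zb <- border_profile(rho)
    env <- 0.45 + 0.55 * smoothstep((pos$z - (zb - 50)) / 100) -
      0.30 * smoothstep((pos$z - (zb + 300)) / 100)
    f <- f * env
  }
  lo <- stats::quantile(f, 0.005); hi <- stats::quantile(f, 0.995)
  img <- pmin(pmax((f - lo) / (hi - lo), 0), 1) * 255
  radial_volume(array(round(img), c(geometry$n_r, geometry$n_scans,
                                    geometry$n_z)),
                geometry)
}

# ---- Deformation specifications -------------------------------------------
#
# Each spec is an S3 object with closed-form forward map, inverse map and
# Jacobian in physical Cartesian coordinates (um) about the scan axis, from
# which ground-truth displacement and cylindrical Green-Lagrange strain
# follow exactly.

new_deformation_spec <- function(kind, fwd, inv, jac, is_identity, par) {
  structure(list(kind = kind, fwd = fwd, inv = inv, jac = jac,
                 is_identity = is_identity, par = par),
            class = "deformation_spec")
}

#' @export
print.deformation_spec <- function(x, ...) {
  cat("<deformation_spec>", x$kind, "\n")
  utils::str(x$par, give.attr = FALSE)
  invisible(x)
}

#' Deformation specifications for phantom volumes
#'
#' Closed-form deformations applied to phantom volumes in physical
#' coordinates about the scan axis. Each has an exact inverse, Jacobian and
#' hence exact Green-Lagrange strain, so every downstream stage can be
#' checked against ground truth.
#'
#' * `deformation_translation(t)`: rigid translation by `t = c(x, y, z)` um.
#' * `deformation_uniform_strain(e_inplane, e_zz, center_z)`: homogeneous
#'   stretch about the axis, engineering strains (in-plane isotropic and
#'   axial); Green-Lagrange normal strain is `e + e^2/2`.
#' * `deformation_rigid_rotation(alpha_deg)`: rigid rotation about the scan
#'   axis; exactly zero Green-Lagrange strain.
#' * `deformation_depth_shift(d, z_start, ramp)`: depth-dependent axial
#'   shift, `u_z = d * s((z - z_start)/ramp)` with `s` a smoothstep; moves
#'   the lamina region by `d` um while tissue anterior to `z_start` stays
#'   put (used for anterior lamina depth phantoms).
#' * `deformation_composite(...)`: composition (applied left to right).
#'
#' @param t Translation vector `c(x, y, z)` in um.
#' @param e_inplane,e_zz Engineering strains (dimensionless), magnitude at
#'   most 0.05 for phantom validity.
#' @param center_z Fixed point depth (um) of the stretch; default mid-depth
#'   is substituted when the spec is applied.
#' @param alpha_deg Rotation angle in degrees about the scan axis.
#' @param d,z_start,ramp Depth-shift magnitude (um), onset depth (um) and
#'   ramp width (um).
#' @param ... For `deformation_composite`, deformation specs.
#' @return A `deformation_spec`.
#' @name deformation_spec
NULL

#' @rdname deformation_spec
#' @export
deformation_translation <- function(t = c(0, 0, 0)) {
  t <- rep_len(as.numeric(t), 3)
  new_deformation_spec(
    "translation",
    fwd = function(p) sweep(p, 2, t, "+"),
    inv = function(p) sweep(p, 2, t, "-"),
    jac = function(p) rep(list(diag(3)), nrow(p)),
    is_identity = all(t == 0),
    par = list(t = t)
  )
}

#' @rdname deformation_spec
#' @export
deformation_uniform_strain <- function(e_inplane = 0, e_zz = 0,
                                       center_z = NULL) {
  if (max(abs(c(e_inplane, e_zz))) > 0.05) {
    stop("uniform strain components must be within +/-5% for phantom validity")
  }
  F <- diag(c(1 + e_inplane, 1 + e_inplane, 1 + e_zz))
  Finv <- diag(1 / diag(F))
  mk <- function(center_z) {
    c0 <- c(0, 0, center_z)
    new_deformation_spec(
      "uniform_strain",
      fwd = function(p) sweep(sweep(p, 2, c0, "-") %*% t(F), 2, c0, "+"),
      inv = function(p) sweep(sweep(p, 2, c0, "-") %*% t(Finv), 2, c0, "+"),
      jac = function(p) rep(list(F), nrow(p)),
      is_identity = e_inplane == 0 && e_zz == 0,
      par = list(e_inplane = e_inplane, e_zz = e_zz, center_z = center_z)
    )
  }
  if (is.null(center_z)) {
    # defer centre to application time (mid-depth of the target geometry)
    spec <- mk(NA_real_)
    spec$needs_center <- TRUE
    spec$make <- mk
    spec
  } else {
    mk(center_z)
  }
}

#' @rdname deformation_spec
#' @export
deformation_rigid_rotation <- function(alpha_deg) {
  a <- alpha_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  new_deformation_spec(
    "rigid_rotation",
    fwd = function(p) p %*% t(R),
    inv = function(p) p %*% R,
    jac = function(p) rep(list(R), nrow(p)),
    is_identity = alpha_deg == 0,
    par = list(alpha_deg = alpha_deg)
  )
}

#' @rdname deformation_spec
#' @export
deformation_depth_shift <- function(d, z_start = 250, ramp = 80) {
  stopifnot(ramp > 0)
  s <- function(z) smoothstep((z - z_start) / ramp)
  ds <- function(z) {
    t <- (z - z_start) / ramp
    ifelse(t > 0 & t < 1, 6 * t * (1 - t) / ramp, 0)
  }
  new_deformation_spec(
    "depth_shift",
    fwd = function(p) {
      p[, 3] <- p[, 3] + d * s(p[, 3]); p
    },
    inv = function(p) {
      # z' = z + d s(z) is monotone for |d| < ramp / 1.5; invert by Newton
      z <- p[, 3] - d * s(p[, 3])
      for (i in 1:4) z <- z - (z + d * s(z) - p[, 3]) / (1 + d * ds(z))
      p[, 3] <- z; p
    },
    jac = function(p) {
      g <- ds(p[, 3])
      lapply(seq_len(nrow(p)), function(i) {
        J <- diag(3); J[3, 3] <- 1 + d * g[i]; J
      })
    },
    is_identity = d == 0,
    par = list(d = d, z_start = z_start, ramp = ramp)
  )
}

#' @rdname deformation_spec
#' @export
deformation_composite <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, TRUE, "deformation_spec")))
  new_deformation_spec(
    "composite",
    fwd = function(p) Reduce(function(q, s) s$fwd(q), parts, p),
    inv = function(p) Reduce(function(q, s) s$inv(q), rev(parts), p),
    jac = function(p) {
      J <- rep(list(diag(3)), nrow(p))
      q <- p
      for (s in parts) {
        Js <- s$jac(q)
        J <- Map(function(a, b) a %*% b, Js, J)
        q <- s$fwd(q)
      }
      J
    },
    is_identity = all(vapply(parts, function(s) s$is_identity, TRUE)),
    par = list(parts = parts)
  )
}

finalize_spec <- function(spec, geometry) {
  if (isTRUE(spec$needs_center)) {
    spec <- spec$make((geometry$n_z - 1) * geometry$res_z / 2)
  } else if (spec$kind == "composite") {
    spec$par$parts <- lapply(spec$par$parts, finalize_spec, geometry = geometry)
    spec <- do.call(deformation_composite, spec$par$parts)
  }
  spec
}

# Cylindrical Green-Lagrange components from a Cartesian deformation
# gradient F at reference en-face angle phi (radians).
gl_cyl_from_F <- function(F, phi) {
  E <- (t(F) %*% F - diag(3)) / 2
  Q <- matrix(c(cos(phi), sin(phi), 0,
                -sin(phi), cos(phi), 0,
                0, 0, 1), 3, 3)
  Ec <- t(Q) %*% E %*% Q
  c(e_rr = Ec[1, 1], e_tt = Ec[2, 2], e_zz = Ec[3, 3],
    e_rt = Ec[1, 2], e_zt = Ec[2, 3], e_rz = Ec[1, 3])
}

#' Apply a known deformation to a phantom volume
#'
#' Resamples the reference volume through the inverse of the deformation in
#' physical coordinates (cubic interpolation within scan planes, linear
#' across scans) and returns the deformed volume together with exact
#' ground-truth evaluators for the displacement field and the cylindrical
#' Green-Lagrange strain tensor.
#'
#' @param volume Reference [radial_volume()].
#' @param spec A [deformation_spec].
#' @return A list of class `phantom_pair`: `reference`, `deformed`
#'   ([radial_volume()]s), `spec`, and functions
#'   `truth_displacement(r, theta, z)` (cylindrical components `u_r`, `u_t`,
#'   `u_z` in um at reference cylindrical positions, `theta` degrees) and
#'   `truth_strain(r, theta, z)` (tibble of Green-Lagrange components).
#' @examples
#' g <- radial_scan_geometry(n_scans = 12, n_r = 64, n_z = 48, res_r = 12,
#'                           res_z = 8)
#' ref <- generate_speckle_volume(g, grain_size = 30, seed = 1)
#' pair <- apply_deformation(ref, deformation_translation(c(0, 0, 16)))
#' pair$truth_displacement(300, 0, 200)
#' @export
apply_deformation <- function(volume, spec) {
  g <- volume_geometry(volume)
  spec <- finalize_spec(spec, g)

  truth_displacement <- function(r, theta, z) {
    n <- max(length(r), length(theta), length(z))
    r <- rep_len(r, n); theta <- rep_len(theta, n); z <- rep_len(z, n)
    phi <- theta * pi / 180
    P <- cbind(r * cos(phi), r * sin(phi), z)
    U <- unname(spec$fwd(P) - P)
    tibble::tibble(
      u_r = unname(U[, 1] * cos(phi) + U[, 2] * sin(phi)),
      u_t = unname(-U[, 1] * sin(phi) + U[, 2] * cos(phi)),
      u_z = unname(U[, 3])
    )
  }
  truth_strain <- function(r, theta, z) {
    n <- max(length(r), length(theta), length(z))
    r <- rep_len(r, n); theta <- rep_len(theta, n); z <- rep_len(z, n)
    phi <- theta * pi / 180
    P <- cbind(r * cos(phi), r * sin(phi), z)
    J <- spec$jac(P)
    comps <- t(vapply(seq_len(n),
                      function(i) gl_cyl_from_F(J[[i]], phi[i]),
                      numeric(6)))
    tibble::as_tibble(as.data.frame(comps))
  }

  if (spec$is_identity) {
    deformed <- volume
  } else {
    pos <- scan_voxel_positions(g)
    P <- cbind(pos$x, pos$y, pos$z)
    # precondition: displacement within 10% of the volume extent
    probe <- P[seq(1, nrow(P), length.out = min(nrow(P), 4096)), , drop = FALSE]
    dmax <- max(sqrt(rowSums((spec$fwd(probe) - probe)^2)))
    extent <- min(g$n_r * g$res_r, g$n_z * g$res_z)
    if (dmax > 0.1 * extent) {
      stop(sprintf("deformation too large for phantom warping (max |u| = %.1f um, limit %.1f um)",
                   dmax, 0.1 * extent))
    }
    X <- spec$inv(P)
    rho <- sqrt(X[, 1]^2 + X[, 2]^2)
    phi_deg <- (atan2(X[, 2], X[, 1]) * 180 / pi) %% 360
    scan_cont <- phi_deg / g$angular_step + 1
    i_r <- g$scan_center + rho / g$res_r
    i_z <- X[, 3] / g$res_z + 1
    vals <- sample_volume(volume, i_r, scan_cont, i_z)
    deformed <- radial_volume(
      array(pmin(pmax(round(vals), 0), 255), dim = dim(volume)), g)
  }

  structure(list(reference = volume, deformed = deformed, spec = spec,
                 truth_displacement = truth_displacement,
                 truth_strain = truth_strain),
            class = "phantom_pair")
}

#' Synthetic lamina cribrosa landmarks
#'
#' Generates per-scan manual-landmark stand-ins for a phantom session: the
#' two Bruch's membrane opening (BMO) endpoints, symmetric about the scan
#' centre and `bmo_diameter` apart, and anterior lamina border sample points
#' following a depth profile.
#'
#' @param geometry A [radial_scan_geometry()].
#' @param bmo_diameter BMO diameter in um (1000..2500).
#' @param border_depth_profile Function rho (um) -> border depth z (um).
#' @param n_border Border sample points per scan (at least 5).
#' @param bmo_depth Depth of the BMO endpoints in um.
#' @param jitter_um SD of depth jitter added to border samples (um).
#' @param seed Integer seed (used only when `jitter_um > 0`).
#' @return A `landmark_set`: per scan, `bmo` (2 x 2 matrix of pixel
#'   `(i_r, i_z)`) and `border` (n x 2 matrix, ordered in `i_r`).
#' @export
make_lc_landmarks <- function(geometry, bmo_diameter = 1750,
                              border_depth_profile = default_border_profile,
                              n_border = 9, bmo_depth = 180,
                              jitter_um = 0, seed = 1L) {
  if (bmo_diameter < 1000 || bmo_diameter > 2500) {
    stop("bmo_diameter must be within [1000, 2500] um")
  }
  stopifnot(n_border >= 5)
  g <- geometry
  r_bmo <- bmo_diameter / 2
  if (g$scan_center + r_bmo / g$res_r > g$n_r ||
      g$scan_center - r_bmo / g$res_r < 1) {
    stop("BMO span exceeds the lateral image extent")
  }
  fr <- seq(-0.92, 0.92, length.out = n_border)
  jit <- if (jitter_um > 0) {
    withr::with_seed(seed,
      matrix(stats::rnorm(n_border * g$n_scans, 0, jitter_um), g$n_scans))
  } else {
    matrix(0, g$n_scans, n_border)
  }
  scans <- lapply(seq_len(g$n_scans), function(s) {
    r_b <- fr * r_bmo
    z_b <- border_depth_profile(abs(r_b)) + jit[s, ]
    if (any(abs(r_b) >= r_bmo)) stop("border points outside the BMO span")
    list(
      bmo = cbind(i_r = g$scan_center + c(-r_bmo, r_bmo) / g$res_r,
                  i_z = rep(bmo_depth / g$res_z + 1, 2)),
      border = cbind(i_r = g$scan_center + r_b / g$res_r,
                     i_z = z_b / g$res_z + 1)
    )
  })
  structure(list(scans = scans), geometry = g, class = "landmark_set")
}
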