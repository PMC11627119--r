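analytic_field <- function(fun, g = test_geometry(), cfg = test_dvc_config()) {
  field_from_function(g, fun, cfg)
}

test_that("smoothing reproduces constant and linear fields exactly", {
  g <- test_geometry()
  # constant components in the stored (scan-aligned) basis; a field that is
  # constant in physical cylindrical components would be singular at the
  # scan axis and is not a realistic displacement
  const <- analytic_field(function(r, th, z) {
    list(u_r = 0 * r, u_t = 0 * r, u_z = rep(5, length(r)))
  })
  const$U_r[] <- 2
  const$U_theta[] <- -1
  sm <- smooth_displacement(const, 2)
  expect_equal(sm$U_z[sm$valid], rep(5, sum(sm$valid)))
  expect_equal(sm$U_r[sm$valid], rep(2, sum(sm$valid)), tolerance = 1e-10)
  expect_equal(sm$U_theta[sm$valid], rep(-1, sum(sm$valid)),
               tolerance = 1e-10)
  lin <- analytic_field(function(r, th, z) {
    list(u_r = 0 * r, u_t = 0 * r, u_z = 0.01 * z)
  })
  sml <- smooth_displacement(lin, 2)
  zarr <- array(rep((sml$grid$i_z - 1) * g$res_z,
                    each = prod(dim(sml$q)[1:2])), dim(sml$q))
  expect_equal(sml$U_z[sml$valid], 0.01 * zarr[sml$valid], tolerance = 1e-9)
})

test_that("smoothing attenuates white displacement noise at least four-fold", {
  g <- test_geometry()
  lin <- analytic_field(function(r, th, z) {
    list(u_r = 0 * r, u_t = 0 * r, u_z = 0.01 * z)
  })
  clean <- lin$U_z
  set.seed(9)
  vr <- numeric(20)
  for (i in seq_len(20)) {
    noisy <- lin
    eps <- array(stats::rnorm(length(clean), 0, 0.5), dim(clean))
    noisy$U_z <- clean + eps
    sm <- smooth_displacement(noisy, 2)
    interior <- sm$valid
    interior[c(1:2, dim(clean)[1] - 1:0), , ] <- FALSE
    interior[, , c(1:2, dim(clean)[3] - 1:0)] <- FALSE
    vr[i] <- stats::var((sm$U_z - clean)[interior]) / 0.25
  }
  expect_lt(mean(vr), 1 / 4)
})

test_that("insufficiently supported points are invalidated rather than guessed", {
  lin <- analytic_field(function(r, th, z) {
    list(u_r = 0 * r, u_t = 0 * r, u_z = 0.01 * z)
  })
  lin$valid[] <- FALSE
  lin$valid[5, 3, 4] <- TRUE  # isolated point: 1 < 12 neighbours
  sm <- smooth_displacement(lin, 2)
  expect_false(any(sm$valid))
})

test_that("the strain tensor matches closed forms for homogeneous fields", {
  # axial stretch u_z = 0.01 z: E_zz = 0.01 + 0.01^2/2, all else 0
  s1 <- green_lagrange(analytic_field(function(r, th, z) {
    list(u_r = 0 * r, u_t = 0 * r, u_z = 0.01 * z)
  }))
  expect_lt(max(abs(s1$e_zz[s1$valid] - 0.01005)), 1e-4)
  for (comp in c("e_rr", "e_tt", "e_rt", "e_zt", "e_rz")) {
    expect_lt(max(abs(s1[[comp]][s1$valid])), 1e-4)
  }
  # radial expansion u_r = 0.01 r: E_rr = E_tt = 0.01005 (u_r/r term)
  s2 <- green_lagrange(analytic_field(function(r, th, z) {
    list(u_r = 0.01 * r, u_t = 0 * r, u_z = 0 * z)
  }))
  expect_lt(max(abs(s2$e_rr[s2$valid] - 0.01005)), 1e-4)
  expect_lt(max(abs(s2$e_tt[s2$valid] - 0.01005)), 1e-4)
  expect_lt(max(abs(s2$e_zz[s2$valid])), 1e-4)
  # zero field: all zero
  s0 <- green_lagrange(analytic_field(function(r, th, z) {
    list(u_r = 0 * r, u_t = 0 * r, u_z = 0 * z)
  }))
  for (comp in strain_components) {
    expect_lt(max(abs(s0[[comp]][s0$valid])), 1e-12)
  }
})

test_that("rigid rotation about the axis yields exactly zero strain", {
  a <- 5 * pi / 180
  s <- green_lagrange(analytic_field(function(r, th, z) {
    list(u_r = r * (cos(a) - 1), u_t = r * sin(a), u_z = 0 * z)
  }))
  for (comp in c("e_rr", "e_tt", "e_zz", "e_rt", "e_zt", "e_rz")) {
    expect_lt(max(abs(s[[comp]][s$valid])), 1e-6)
  }
})

test_that("in-plane principal and maximum shear strains follow the closed form", {
  p <- principal_rz(0.005, -0.005, 0)
  expect_equal(p$e_max, 0.005)
  expect_equal(p$gamma_max, 0.005)
  # isotropic in-plane: no shear
  expect_equal(principal_rz(0.004, 0.004, 0)$gamma_max, 0)
  # pure shear
  p2 <- principal_rz(0, 0, 0.003)
  expect_equal(p2$e_max, 0.003)
  expect_equal(p2$gamma_max, 0.003)
  # engineering convention doubles the shear
  expect_equal(principal_rz(0, 0, 0.003, engineering_shear = TRUE)$gamma_max,
               0.006)
})

test_that("E_max dominates the normal strains and Gamma_max is rotation-invariant", {
  set.seed(3)
  err <- stats::rnorm(200, 0, 0.01)
  ezz <- stats::rnorm(200, 0, 0.01)
  erz <- stats::rnorm(200, 0, 0.005)
  p <- principal_rz(err, ezz, erz)
  expect_true(all(p$e_max >= err - 1e-12))
  expect_true(all(p$e_max >= ezz - 1e-12))
  expect_true(all(p$gamma_max >= 0))
  # rotate the in-plane tensor by a random angle: gamma_max unchanged
  phi <- stats::runif(200, 0, pi)
  c2 <- cos(phi); s2 <- sin(phi)
  err2 <- c2^2 * err + s2^2 * ezz + 2 * c2 * s2 * erz
  ezz2 <- s2^2 * err + c2^2 * ezz - 2 * c2 * s2 * erz
  erz2 <- (ezz - err) * c2 * s2 + (c2^2 - s2^2) * erz
  p2 <- principal_rz(err2, ezz2, erz2)
  expect_equal(p2$gamma_max, p$gamma_max, tolerance = 1e-10)
  expect_equal(p2$e_max, p$e_max, tolerance = 1e-10)
})

test_that("region summaries average valid points and respect the partition", {
  g <- test_geometry()
  reg <- test_region()
  # constant axial strain built from a linear displacement ramp
  lam <- -1 + sqrt(1 - 2 * 0.0037)  # engineering ramp for E_zz = -0.0037
  s <- green_lagrange(analytic_field(function(r, th, z) {
    list(u_r = 0 * r, u_t = 0 * r, u_z = lam * z)
  }))
  out <- summarize_region(s, reg, labels = "full")
  ezz <- out[out$component == "e_zz", ]
  expect_equal(ezz$mean, -0.0037, tolerance = 1e-6)
  expect_lt(ezz$sd, 1e-8)
  # central + peripheral point counts add up to the full region
  out2 <- summarize_region(s, reg)
  n_full <- out2$n[out2$region == "full" & out2$component == "e_zz"]
  n_cp <- sum(out2$n[out2$region %in% c("central", "peripheral") &
                       out2$component == "e_zz"])
  expect_equal(n_cp, n_full)
  n_quad <- sum(out2$n[out2$region %in% c("superior", "inferior", "nasal",
                                          "temporal") &
                         out2$component == "e_zz"])
  expect_equal(n_quad, n_full)
})

test_that("a radially increasing strain separates central from peripheral means", {
  reg <- test_region()
  # u_r = a r^2 / R0 gives E_rr growing linearly with radius
  s <- green_lagrange(analytic_field(function(r, th, z) {
    list(u_r = 0.01 * r^2 / 800, u_t = 0 * r, u_z = 0 * z)
  }))
  out <- summarize_region(s, reg, labels = c("central", "peripheral"))
  err <- out[out$component == "e_rr", ]
  expect_gt(err$mean[err$region == "peripheral"],
            err$mean[err$region == "central"])
})
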