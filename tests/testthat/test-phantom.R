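test_that("speckle volumes are reproducible, rich in contrast, and resolvable", {
  g <- test_geometry()
  v1 <- generate_speckle_volume(g, grain_size = 30, seed = 1)
  v2 <- generate_speckle_volume(g, grain_size = 30, seed = 1)
  expect_identical(unclass(v1), unclass(v2))
  expect_gte(length(unique(as.vector(v1))), 200)
  expect_true(all(v1 >= 0 & v1 <= 255))
  # grain below twice the finest resolution is unresolvable
  expect_error(generate_speckle_volume(g, grain_size = 10, seed = 1),
               "twice the finest")
})

test_that("identity deformation reproduces the volume bit-exactly", {
  v <- test_speckle()
  pair <- apply_deformation(v, deformation_translation(c(0, 0, 0)))
  expect_identical(unclass(pair$deformed), unclass(v))
  expect_true(pair$spec$is_identity)
})

test_that("axial translation by a whole number of pixels shifts features exactly", {
  v <- test_speckle()
  g <- test_geometry()
  pair <- apply_deformation(v, deformation_translation(c(0, 0, 2 * g$res_z)))
  a <- unclass(v); b <- unclass(pair$deformed)
  expect_equal(b[, , 11:90], a[, , 9:88])
  u <- pair$truth_displacement(400, 0, 200)
  expect_equal(u$u_z, 2 * g$res_z)
  expect_equal(u$u_r, 0)
})

test_that("uniform stretch ground truth matches the engineering/Green-Lagrange relation", {
  # engineering strain e with e + e^2/2 = 0.005
  e <- -1 + sqrt(1 + 2 * 0.005)
  expect_equal(e, 0.0049875, tolerance = 1e-4)
  spec <- deformation_uniform_strain(e_zz = e, center_z = 0)
  pair <- apply_deformation(test_speckle(), spec)
  z <- c(100, 300, 500)
  u <- pair$truth_displacement(400, 0, z)
  slope <- diff(u$u_z) / diff(z)
  expect_equal(slope, rep(e, 2), tolerance = 1e-10)
  tr <- pair$truth_strain(400, 0, 300)
  expect_equal(tr$e_zz, 0.005, tolerance = 1e-12)
  expect_error(deformation_uniform_strain(e_zz = 0.2), "5%")
})

test_that("rigid rotation has exactly zero Green-Lagrange strain", {
  spec <- deformation_rigid_rotation(5)
  pair <- apply_deformation(test_speckle(), spec)
  tr <- pair$truth_strain(c(200, 500), c(0, 90), c(100, 400))
  for (comp in names(tr)) expect_lt(max(abs(tr[[comp]])), 1e-12)
})

test_that("warping back through the truth field recovers the reference", {
  v <- test_speckle()
  g <- test_geometry()
  e <- -1 + sqrt(1 + 2 * 0.005)
  pair <- apply_deformation(v, deformation_uniform_strain(e_zz = e))
  # resample the deformed volume at the forward-mapped position of each voxel
  pos <- scan_voxel_positions(g)
  P <- cbind(pos$x, pos$y, pos$z)
  Xd <- pair$spec$fwd(P)
  rho <- sqrt(Xd[, 1]^2 + Xd[, 2]^2)
  phi <- (atan2(Xd[, 2], Xd[, 1]) * 180 / pi) %% 360
  vals <- sample_volume(pair$deformed, g$scan_center + rho / g$res_r,
                        phi / g$angular_step + 1, Xd[, 3] / g$res_z + 1)
  interior <- array(FALSE, dim(v))
  interior[8:(g$n_r - 7), , 8:(g$n_z - 7)] <- TRUE
  err <- mean(abs(array(vals, dim(v))[interior] - unclass(v)[interior]))
  expect_lt(err, 2)
})

test_that("oversized deformations are rejected", {
  g <- test_geometry()
  # 10% of the smaller extent (z: 96 * 7.74 = 743 um) is ~74 um
  expect_error(apply_deformation(test_speckle(),
                                 deformation_translation(c(0, 0, 200))),
               "too large")
})

test_that("landmarks follow the requested BMO diameter and border profile", {
  g <- test_geometry()
  lm <- make_lc_landmarks(g, bmo_diameter = 1200,
                          border_depth_profile = function(rho) rep(300, length(rho)))
  for (s in seq_len(g$n_scans)) {
    bmo <- lm$scans[[s]]$bmo
    expect_equal(diff(bmo[, "i_r"]) * g$res_r, 1200)
    expect_equal(unname((lm$scans[[s]]$border[, "i_z"] - 1) * g$res_z),
                 rep(300, nrow(lm$scans[[s]]$border)))
    expect_gte(nrow(lm$scans[[s]]$border), 5)
  }
  # bowl profile evaluated at rho = 800
  bowl <- function(rho) 300 - 50 * (rho / 800)^2
  expect_equal(bowl(800), 250)
  lm2 <- make_lc_landmarks(radial_scan_geometry(), bmo_diameter = 1750,
                           border_depth_profile = bowl)
  b <- lm2$scans[[1]]$border
  r_um <- (b[, "i_r"] - radial_scan_geometry()$scan_center) * 6.0
  z_um <- (b[, "i_z"] - 1) * 3.87
  expect_equal(z_um, bowl(abs(r_um)), tolerance = 1e-10)
  expect_error(make_lc_landmarks(g, bmo_diameter = 500), "1000")
})

test_that("landmark sets survive a JSON round trip", {
  g <- test_geometry()
  lm <- test_landmarks()
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  lm2 <- read_landmarks(path, g)
  expect_equal(lm$scans, lm2$scans)
})

test_that("radial volumes survive a TIFF round trip", {
  v <- test_speckle()
  path <- withr::local_tempfile(fileext = ".tif")
  write_radial_volume(v, path)
  v2 <- read_radial_volume(path)
  expect_equal(unclass(v), unclass(v2), ignore_attr = TRUE)
  expect_true(same_geometry <- isTRUE(all.equal(
    unclass(volume_geometry(v)), unclass(volume_geometry(v2)))))
})

test_that("the noiseless cohort model is exactly linear", {
  # -0.05% per mm Hg at dIOP 7.1 must give exactly -0.355% strain
  spec <- cohort_spec(n_eyes = 5, noise_sd = 0, ald_noise_sd = 0,
                      md_effect = c(e_zz = 0),
                      true_compliance = c(e_zz = -0.0005),
                      diop_range = c(7.0999999, 7.1000001), seed = 1)
  rec <- generate_cohort(spec)
  expect_equal(rec$strain_e_zz, rep(-0.00355, 5), tolerance = 1e-6)
  expect_equal(rec$compliance_e_zz * rec$delta_iop, rec$strain_e_zz)
  expect_error(cohort_spec(diop_range = c(0, 0)), "range")
  expect_error(cohort_spec(n_eyes = 1), "n_eyes")
})

test_that("regression on a large synthetic cohort recovers the true compliance", {
  rec <- generate_cohort(cohort_spec(n_eyes = 500, md_effect = c(e_zt = 0),
                                     seed = 11))
  fit <- summary(stats::lm(strain_e_zz ~ delta_iop, data = rec))
  slope <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(slope - (-0.0037 / 7.1)) / se, 3)
})

test_that("cohort noise and effect structure are reproducible under a seed", {
  a <- generate_cohort(cohort_spec(n_eyes = 10, seed = 4))
  b <- generate_cohort(cohort_spec(n_eyes = 10, seed = 4))
  expect_identical(a, b)
})
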