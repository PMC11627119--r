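test_that("subset correlation finds integer and subpixel shifts", {
  tex <- bandlimited_texture()
  # identical subsets: autocorrelation peak at zero lag
  res0 <- correlate_subset(tex[9:40, , 9:40], tex[9:40, , 9:40])
  expect_equal(res0$du, c(0, 0, 0))
  expect_gt(res0$q, 0.99)
  # exact integer shift
  res3 <- correlate_subset(tex[9:40, , 9:40],
                           spectral_shift_z(tex, 3)[9:40, , 9:40])
  expect_equal(res3$du[3], 3, tolerance = 0.1)
  expect_lt(max(abs(res3$du[1:2])), 0.1)
  # half-pixel shift constructed by ideal (spectral) interpolation
  res25 <- correlate_subset(tex[9:40, , 9:40],
                            spectral_shift_z(tex, 2.5)[9:40, , 9:40])
  expect_equal(res25$du[3], 2.5, tolerance = 0.15)
})

test_that("zero-variance subsets are flagged invalid with q = 0", {
  a <- array(5, c(16, 4, 16))
  b <- array(stats::rnorm(16 * 4 * 16), c(16, 4, 16))
  res <- correlate_subset(a, b)
  expect_false(res$valid)
  expect_equal(res$q, 0)
})

test_that("warping through a zero or integer field is exact", {
  v <- test_speckle()
  g <- test_geometry()
  gd <- c(3, 3, 3)
  grid <- list(i_r = c(32.5, 64.5, 96.5), scan = c(1, 5, 9),
               i_z = c(24.5, 48.5, 72.5))
  zero <- structure(list(grid = grid, du_r = array(0, gd),
                         du_s = array(0, gd), du_z = array(0, gd),
                         valid = array(TRUE, gd), geometry = g),
                    class = "displacement_field")
  expect_equal(unclass(warp_volume(v, zero, "toward_ref")), unclass(v),
               ignore_attr = TRUE)
  one <- zero; one$du_z <- array(1, gd)
  w <- warp_volume(v, one, "toward_ref")
  expect_equal(unclass(w)[, , 1:(g$n_z - 1)], unclass(v)[, , 2:g$n_z],
               ignore_attr = TRUE)
  bad <- one; bad$du_z[2, 2, 2] <- NaN
  expect_error(warp_volume(v, bad, "toward_ref"), "NaN")
})

test_that("registration of identical volumes is the zero field", {
  v <- test_speckle()
  f <- dvc_register(v, v, test_dvc_config())
  expect_lt(max(abs(c(f$du_r[f$valid], f$du_s[f$valid], f$du_z[f$valid]))),
            0.1)
})

test_that("pure axial translation is recovered within half a micrometre", {
  g <- test_geometry()
  tf <- test_translation_fields()
  f <- tf$fwd
  expect_equal(mean(f$U_z[f$valid]), 2.5 * g$res_z, tolerance = 0.5 / 19.35)
  expect_lt(abs(mean(f$U_r[f$valid])), 0.5)
  expect_lt(abs(mean(f$U_theta[f$valid])), 0.5)
})

test_that("the cumulative field equals the sum of its increments", {
  f <- test_translation_fields()$fwd
  expect_gte(length(f$increments), 1)
  expect_equal(Reduce(`+`, lapply(f$increments, `[[`, "du_z")), f$du_z)
  expect_equal(Reduce(`+`, lapply(f$increments, `[[`, "du_r")), f$du_r)
})

test_that("forward and backward registration are antisymmetric", {
  tf <- test_translation_fields()
  both <- tf$fwd$valid & tf$bwd$valid
  # compose: u_bwd evaluated at the forward-mapped points cancels u_fwd
  resid <- tf$fwd$du_z[both] + tf$bwd$du_z[both]
  expect_lt(mean(abs(resid)), 0.3)
})

test_that("registration is shift-equivariant over a range of shifts", {
  v <- test_speckle()
  g <- test_geometry()
  cfg <- test_dvc_config(max_iterations = 2)
  for (s_px in c(-3, 1.25)) {
    pair <- apply_deformation(v, deformation_translation(c(0, 0, s_px * g$res_z)))
    f <- dvc_register(v, pair$deformed, cfg)
    expect_equal(mean(f$du_z[f$valid]), s_px, tolerance = 0.08 / abs(s_px))
  }
})

test_that("residual image difference is non-increasing across iterations", {
  v <- test_speckle()
  g <- test_geometry()
  pair <- apply_deformation(v, deformation_translation(c(0, 0, 2.5 * g$res_z)))
  resid <- function(k) {
    f <- dvc_register(v, pair$deformed, test_dvc_config(max_iterations = k))
    w <- warp_volume(pair$deformed, f, "toward_ref")
    interior <- unclass(w)[17:112, , 17:80] - unclass(v)[17:112, , 17:80]
    mean(abs(interior))
  }
  r <- vapply(1:3, resid, numeric(1))
  expect_true(all(diff(r) <= 0.02 * r[1]))
})

test_that("uniform axial strain appears as a linear axial displacement ramp", {
  v <- test_speckle()
  g <- test_geometry()
  e <- -1 + sqrt(1 + 2 * 0.005)
  pair <- apply_deformation(v, deformation_uniform_strain(e_zz = e))
  f <- dvc_register(v, pair$deformed, test_dvc_config())
  df <- generics::tidy(f)
  df <- df[df$valid, ]
  fit <- stats::lm(U_z ~ z_um, data = df)
  expect_gt(coef(fit)[2], 0.0045)
  expect_lt(coef(fit)[2], 0.0055)
})

test_that("registration rejects mismatched geometries", {
  v <- test_speckle()
  g2 <- radial_scan_geometry(n_scans = 12, n_r = 64, n_z = 48,
                             res_r = 12, res_z = 7.74)
  v2 <- generate_speckle_volume(g2, grain_size = 30, seed = 1)
  expect_error(dvc_register(v, v2, test_dvc_config()), "geometry")
})

test_that("subset sizes halve in-plane but never fall below the minimum", {
  cfg <- dvc_config(initial_subset = c(64, 8, 64), min_subset = c(16, 8, 16),
                    max_iterations = 4)
  sched <- lcstrain:::subset_schedule(cfg)
  expect_equal(sched[[1]], c(64L, 8L, 64L))
  expect_equal(sched[[2]], c(32L, 8L, 32L))
  expect_equal(sched[[3]], c(16L, 8L, 16L))
  expect_equal(sched[[4]], c(16L, 8L, 16L))  # clamped at the minimum
  expect_error(dvc_config(initial_subset = c(8, 8, 8),
                          min_subset = c(16, 8, 16)))
})
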