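flat_landmarks <- function(g = test_geometry(), depth = 300,
                           bmo_diameter = 1200) {
  make_lc_landmarks(g, bmo_diameter = bmo_diameter,
                    border_depth_profile = function(rho) rep(depth, length(rho)))
}

test_that("border interpolation is piecewise linear through the samples", {
  g <- test_geometry()
  lm <- flat_landmarks(g)
  bf <- interpolate_border(lm, 1)
  # flat border: constant depth everywhere between the samples
  expect_equal(bf(g$scan_center + 400 / g$res_r), 300 / g$res_z + 1)
  # tent profile: linear midpoint between samples
  lm2 <- lm
  lm2$scans[[1]]$border <- cbind(
    i_r = g$scan_center + c(0, 400, 800) / g$res_r,
    i_z = c(300, 320, 300) / g$res_z + 1)
  bf2 <- interpolate_border(lm2, 1)
  expect_equal((bf2(g$scan_center + 200 / g$res_r) - 1) * g$res_z, 310)
  # samples reproduced exactly
  b <- lm$scans[[2]]$border
  expect_equal(bf(b[, "i_r"]), unname(b[, "i_z"]))
  lm3 <- lm
  lm3$scans[[1]]$border[2, "i_r"] <- lm3$scans[[1]]$border[1, "i_r"]
  expect_error(interpolate_border(lm3, 1), "duplicate")
})

test_that("the LC region is 250 um deep and bounded by the BMO span", {
  g <- radial_scan_geometry()  # device resolution: 250 / 3.87 = 64.6 rows
  lm <- make_lc_landmarks(g, bmo_diameter = 1600,
                          border_depth_profile = function(rho) rep(300, length(rho)))
  reg <- build_lc_region(lm, g)
  inside <- which(!is.na(reg$z_lo[, 1]))
  z <- z_axis(g)
  rows <- vapply(inside, function(i) {
    sum(z >= reg$z_lo[i, 1] & z < reg$z_hi[i, 1])
  }, numeric(1))
  expect_true(all(rows %in% c(64, 65)))
  # lateral span matches the BMO
  r <- r_signed_axis(g)
  expect_lte(max(abs(r[inside])), 800)
  expect_gte(max(abs(r[inside])), 800 - g$res_r)
  expect_error(build_lc_region(lm, g, thickness = -5), "positive")
})

test_that("central zone is the disc of one quarter the BMO diameter", {
  g <- radial_scan_geometry(n_scans = 12, n_r = 160, n_z = 96,
                            res_r = 12, res_z = 7.74)
  reg <- build_lc_region(flat_landmarks(g, bmo_diameter = 1600), g)
  expect_equal(reg$bmo_diameter, 1600, tolerance = 1e-6)
  r <- r_signed_axis(g)
  for (s in c(1, 5)) {
    zl <- reg$zone[, s]
    central_r <- abs(r[!is.na(zl) & zl == "central"])
    expect_lt(max(central_r), 400)
    periph_r <- abs(r[!is.na(zl) & zl == "peripheral"])
    expect_gte(min(periph_r), 400)
  }
  # the point at the BMO centre is central
  expect_equal(reg$zone[which.min(abs(r)), 1], "central")
})

test_that("zones and quadrants partition the region", {
  reg <- test_region()
  in_span <- !is.na(reg$z_lo)
  expect_true(all(!is.na(reg$zone[in_span])))
  expect_true(all(!is.na(reg$quadrant[in_span])))
  expect_equal(sum(reg$zone[in_span] == "central") +
                 sum(reg$zone[in_span] == "peripheral"), sum(in_span))
  expect_equal(sum(table(reg$quadrant[in_span])), sum(in_span))
  expect_setequal(unique(as.vector(reg$quadrant[in_span])),
                  c("superior", "inferior", "nasal", "temporal"))
})

test_that("the posterior border is a constant-distance offset of the anterior", {
  g <- test_geometry()
  lm <- flat_landmarks(g)
  # tilt the border on every scan
  for (s in seq_len(g$n_scans)) {
    b <- lm$scans[[s]]$border
    r_um <- (b[, "i_r"] - g$scan_center) * g$res_r
    lm$scans[[s]]$border[, "i_z"] <- (300 + 0.3 * r_um) / g$res_z + 1
  }
  reg <- build_lc_region(lm, g, thickness = 250)
  i <- which(!is.na(reg$z_lo[, 1]))
  i <- i[i > min(i) + 4 & i < max(i) - 4]
  # distance from each posterior point to the anterior polyline
  r_um <- r_signed_axis(g)
  ant <- cbind(r_um[i], reg$z_lo[i, 1])
  for (j in seq(1, length(i), by = 5)) {
    p <- c(r_um[i[j]], reg$z_hi[i[j], 1])
    d <- min(sqrt((ant[, 1] - p[1])^2 + (ant[, 2] - p[2])^2))
    expect_lt(abs(d - 250), max(g$res_r, g$res_z))
  }
  # pure depth offset alternative
  reg2 <- build_lc_region(lm, g, thickness = 250, normal_offset = FALSE)
  expect_equal(reg2$z_hi[i, 1] - reg2$z_lo[i, 1], rep(250, length(i)))
})

test_that("quadrants follow the 45-degree diagonals with laterality mirroring", {
  expect_equal(quadrant_of(500, 90), "superior")
  expect_equal(quadrant_of(500, 270), "inferior")
  expect_equal(quadrant_of(500, 0), "nasal")
  expect_equal(quadrant_of(500, 180), "temporal")
  expect_equal(quadrant_of(500, 0, laterality = "OS"), "temporal")
  expect_equal(quadrant_of(500, 180, laterality = "OS"), "nasal")
  # boundary belongs to the vertical sector
  expect_equal(quadrant_of(500, 45), "superior")
  expect_equal(quadrant_of(500, 135), "superior")
  expect_equal(quadrant_of(500, 225), "inferior")
  expect_error(quadrant_of(0, 10), "r = 0")
})

test_that("region membership is consistent with the stored depth bounds", {
  g <- test_geometry()
  reg <- test_region()
  lm <- test_landmarks()
  bf <- interpolate_border(lm, 1)
  ir <- round(g$scan_center + 200 / g$res_r)
  z_border <- (bf(ir) - 1) * g$res_z
  expect_true(region_contains(reg, 1, ir, z_border + 5))
  expect_false(region_contains(reg, 1, ir, z_border - 15))
  expect_false(region_contains(reg, 1, ir, z_border + 400))
  expect_false(region_contains(reg, 1, 2, z_border + 5))  # outside BMO span
})
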