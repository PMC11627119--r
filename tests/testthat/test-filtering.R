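constant_field <- function(uz = 0, g = test_geometry(),
                           cfg = test_dvc_config()) {
  field_from_function(g, function(r, th, z) {
    list(u_r = 0 * r, u_t = 0 * r, u_z = rep(uz, length(r)))
  }, cfg)
}

test_that("the correlation filter applies the 0.055 threshold as a hard cut", {
  f <- constant_field()
  f$q[2, 2, 2] <- 0.05
  f$q[3, 3, 3] <- 0.06
  out <- filter_by_correlation(f, 0.055)
  expect_false(out$valid[2, 2, 2])
  expect_true(out$valid[3, 3, 3])
  # all q = 1 leaves the field unchanged
  f2 <- constant_field()
  out2 <- filter_by_correlation(f2, 0.055)
  expect_equal(out2$valid, f2$valid)
})

test_that("forward-backward consistency enforces the 5 um ceiling", {
  fwd <- constant_field(3)
  bwd <- constant_field(-3)
  out <- filter_by_displacement_error(fwd, bwd, 5)
  expect_equal(sum(fwd$valid) - sum(out$valid), 0)
  # a 12 um disagreement (error = 6 um) at one point is removed
  bwd2 <- bwd
  bwd2$U_z[5, 3, 4] <- bwd2$U_z[5, 3, 4] + 24
  out2 <- filter_by_displacement_error(fwd, bwd2, 5)
  expect_false(out2$valid[5, 3, 4])
  expect_equal(sum(fwd$valid) - sum(out2$valid), 1)
  # an infinite ceiling is the identity
  out3 <- filter_by_displacement_error(fwd, bwd2, Inf)
  expect_equal(out3$valid, fwd$valid)
})

test_that("edge and outlier removal leaves smooth fields intact", {
  g <- test_geometry()
  lin <- field_from_function(g, function(r, th, z) {
    list(u_r = 0 * r, u_t = 0 * r, u_z = 0.01 * z)
  }, test_dvc_config())
  out <- remove_edges_and_outliers(lin, filter_config(edge_margin = 0))
  expect_equal(out$valid, lin$valid)
  # a 10-voxel spike is removed, and exactly that point
  sp <- lin
  sp$du_z[6, 3, 5] <- sp$du_z[6, 3, 5] + 10
  sp$U_z[6, 3, 5] <- sp$U_z[6, 3, 5] + 10 * g$res_z
  out2 <- remove_edges_and_outliers(sp, filter_config(edge_margin = 0))
  expect_false(out2$valid[6, 3, 5])
  expect_equal(sum(sp$valid) - sum(out2$valid), 1)
  # edge_margin 0 and infinite outlier_k is the identity
  out3 <- remove_edges_and_outliers(lin, filter_config(edge_margin = 0,
                                                       outlier_k = Inf))
  expect_equal(out3$valid, lin$valid)
  # edge margin removes the boundary shell
  out4 <- remove_edges_and_outliers(lin, filter_config(edge_margin = 1,
                                                       outlier_k = Inf))
  expect_true(all(!out4$valid[1, , ]))
  expect_true(all(!out4$valid[, , 1]))
})

test_that("filters are idempotent and only shrink the valid set", {
  f <- constant_field(2)
  set.seed(5)
  f$q <- array(stats::runif(length(f$q)), dim(f$q))
  bwd <- constant_field(-2)
  bwd$U_z <- bwd$U_z + array(stats::rnorm(length(f$q), 0, 3), dim(f$q))
  cfgf <- filter_config()
  steps <- list(
    function(x) filter_by_correlation(x, cfgf$q_threshold),
    function(x) filter_by_displacement_error(x, bwd, cfgf$displacement_error_max),
    function(x) remove_edges_and_outliers(x, cfgf)
  )
  cur <- f
  for (step in steps) {
    nxt <- step(cur)
    expect_true(all(nxt$valid <= cur$valid))   # monotone shrinkage
    again <- step(nxt)
    expect_equal(again$valid, nxt$valid)       # idempotent
    cur <- nxt
  }
  expect_equal(length(cur$filter_log), 3)
})

test_that("percent area correlated counts grid points inside the region", {
  f <- constant_field()
  f$valid[] <- TRUE  # include the axis-excluded column: all points valid
  reg <- test_region()
  expect_equal(percent_area_correlated(f, reg), 100)
  inr <- lcstrain:::grid_in_region(f, reg)
  idx <- which(inr)
  f2 <- f
  f2$valid[idx[seq(1, length(idx), by = 2)]] <- FALSE
  pct <- percent_area_correlated(f2, reg)
  expect_equal(pct, 100 * (1 - length(seq(1, length(idx), by = 2)) /
                             length(idx)))
  f3 <- f
  f3$valid[] <- FALSE
  expect_equal(percent_area_correlated(f3, reg), 0)
})

test_that("filters keep at least 80% of the LC region on clean phantoms", {
  tf <- test_translation_fields()
  fwd <- apply_filters(tf$fwd, tf$bwd)
  # region fully interior to the correlation grid (the reduced test scans
  # leave little margin around a full-size BMO)
  reg <- build_lc_region(make_lc_landmarks(test_geometry(),
                                           bmo_diameter = 1000),
                         test_geometry())
  expect_gte(percent_area_correlated(fwd, reg), 80)
})
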