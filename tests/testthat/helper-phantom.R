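# Shared phantom fixtures. Unit tests run on a reduced radial geometry
# (12 scans at 15 deg, 128 x 96 px at twice the device pixel pitch) so a
# registration takes seconds; the acceptance tests use the larger
# downsampled session geometry. Fixtures are cached per test run.

.fixtures <- new.env(parent = emptyenv())

test_geometry <- function() {
  radial_scan_geometry(n_scans = 12, n_r = 128, n_z = 96,
                       res_r = 12, res_z = 7.74)
}

acceptance_geometry <- function() {
  radial_scan_geometry(n_scans = 24, n_r = 384, n_z = 248,
                       res_r = 12, res_z = 7.74)
}

test_dvc_config <- function(...) {
  dvc_config(initial_subset = c(32, 4, 32), min_subset = c(16, 4, 16), ...)
}

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

test_speckle <- function(seed = 1) {
  cached(paste0("speckle", seed),
         generate_speckle_volume(test_geometry(), grain_size = 30,
                                 seed = seed))
}

test_landmarks <- function() {
  cached("landmarks", make_lc_landmarks(test_geometry(),
                                        bmo_diameter = 1200))
}

test_region <- function() {
  cached("region", build_lc_region(test_landmarks(), test_geometry()))
}

# registered translation pair reused by several files
test_translation_fields <- function() {
  cached("trans_fields", {
    v <- test_speckle()
    pair <- apply_deformation(v, deformation_translation(c(0, 0, 2.5 * 7.74)))
    cfg <- test_dvc_config()
    list(pair = pair,
         fwd = dvc_register(v, pair$deformed, cfg),
         bwd = dvc_register(pair$deformed, v, cfg))
  })
}

# band-limited periodic 3-D texture plus an exact spectral shifter along z,
# used as the independent oracle for subpixel correlation tests
bandlimited_texture <- function(d = c(48, 8, 48), seed = 2) {
  set.seed(seed)
  a <- array(stats::rnorm(prod(d)), d)
  A <- stats::fft(a)
  keep <- function(n, cut) pmin(0:(n - 1), n - (0:(n - 1))) < cut
  K <- outer(outer(keep(d[1], 8), keep(d[2], 3)), keep(d[3], 8))
  Re(stats::fft(A * K, inverse = TRUE)) / prod(d)
}

spectral_shift_z <- function(a, dz) {
  d <- dim(a)
  n <- d[3]
  k <- 2 * pi / n * ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n)
  A <- apply(a, c(1, 2), stats::fft)       # dims [n3, n1, n2]
  A <- sweep(A, 1, exp(-1i * k * dz), "*")
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    out[i, j, ] <- Re(stats::fft(A[, i, j], inverse = TRUE)) / n
  }
  out
}
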