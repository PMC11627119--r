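#' Baseline (zero-strain) error from replicate volumes
#'
#' Runs the full strain pipeline on a pair of back-to-back volumes of the
#' same session (no real deformation) and reports the region mean and SD of
#' every strain component. The result is the reproducibility floor of the
#' method: measured strains must exceed it to be interpretable.
#'
#' @param rep1,rep2 Replicate [radial_volume()]s of one session.
#' @param region An `lc_region`.
#' @param config A [dvc_config()].
#' @param filters A [filter_config()].
#' @param smoothing_radius Smoothing window radius (grid points).
#' @return A tibble with `component`, `mean`, `sd`, `n`.
#' @export
baseline_error <- function(rep1, rep2, region, config = dvc_config(),
                           filters = filter_config(), smoothing_radius = 2) {
  if (!same_geometry(volume_geometry(rep1), volume_geometry(rep2))) {
    stop("replicates must share geometry")
  }
  fwd <- dvc_register(rep1, rep2, config)
  bwd <- dvc_register(rep2, rep1, config)
  fwd <- apply_filters(fwd, bwd, filters)
  sm <- smooth_displacement(fwd, smoothing_radius)
  strain <- green_lagrange(sm)
  out <- summarize_region(strain, region, labels = "full")
  out$region <- NULL
  out
}

#' Correlation error under a known applied deformation
#'
#' Generates `n_reps` independent speckle phantoms, applies a deformation
#' with closed-form ground truth, runs the full pipeline and reports the
#' bias and RMSE of the recovered region-mean strain per component.
#'
#' @param spec A [deformation_spec].
#' @param geometry A [radial_scan_geometry()].
#' @param config A [dvc_config()].
#' @param n_reps Number of phantom realisations.
#' @param seed Integer seed (phantom `i` uses `seed + i - 1`).
#' @param grain_size Speckle grain in um.
#' @param filters A [filter_config()].
#' @param bmo_diameter BMO diameter of the phantom landmarks (um).
#' @param smoothing_radius Smoothing window radius (grid points).
#' @return A tibble with `component`, `truth`, `mean_recovered`, `bias`,
#'   `rmse`, `n_reps`.
#' @export
correlation_error <- function(spec, geometry, config = dvc_config(),
                              n_reps = 3, seed = 1L, grain_size = 30,
                              filters = filter_config(),
                              bmo_diameter = 1750, smoothing_radius = 2) {
  g <- geometry
  landmarks <- make_lc_landmarks(g, bmo_diameter = bmo_diameter)
  recovered <- list()
  truth_row <- NULL
  for (i in seq_len(n_reps)) {
    ref <- generate_speckle_volume(g, grain_size = grain_size,
                                   seed = seed + i - 1)
    pair <- apply_deformation(ref, spec)
    res <- lc_pipeline(ref, pair$deformed, landmarks, dvc = config,
                       filters = filters,
                       smoothing_radius = smoothing_radius)
    full <- res$summary[res$summary$region == "full", ]
    recovered[[i]] <- stats::setNames(full$mean, full$component)
    if (is.null(truth_row)) {
      # uniform-truth specs: evaluate at a representative region point
      tr <- pair$truth_strain(bmo_diameter / 4, 0,
                              (g$n_z - 1) * g$res_z / 2)
      pr <- principal_rz(tr$e_rr, tr$e_zz, tr$e_rz)
      truth_row <- c(e_rr = tr$e_rr, e_tt = tr$e_tt, e_zz = tr$e_zz,
                     e_rt = tr$e_rt, e_zt = tr$e_zt, e_rz = tr$e_rz,
                     e_max = pr$e_max, gamma_max = pr$gamma_max)
    }
  }
  rec <- do.call(rbind, recovered)
  comps <- intersect(strain_components, colnames(rec))
  tibble::tibble(
    component = comps,
    truth = as.numeric(truth_row[comps]),
    mean_recovered = colMeans(rec[, comps, drop = FALSE]),
    bias = colMeans(rec[, comps, drop = FALSE]) -
      as.numeric(truth_row[comps]),
    rmse = sqrt(colMeans(sweep(rec[, comps, drop = FALSE], 2,
                               truth_row[comps])^2)),
    n_reps = n_reps
  )
}

#' Test measured strains against baseline error
#'
#' Two-sided one-sample comparison of cohort-mean strains against the
#' baseline (reproducibility) error mean: for each component,
#' `t = (mean_measured - mean_baseline) / (sd_measured / sqrt(n_eyes))`
#' with `n_eyes - 1` degrees of freedom. Components with `p <= alpha` are
#' flagged as exceeding baseline error. Inter-eye correlation is not
#' modelled (no generalized estimating equations); see the package
#' vignette for the implied caveat.
#'
#' @param measured Tibble with `component`, `mean`, `sd` columns (per-eye
#'   summary statistics across the cohort).
#' @param baseline Tibble with `component` and `mean` (baseline error mean
#'   per component; e.g. from [baseline_error()] or phantom calibration).
#' @param n_eyes Number of eyes behind `measured` (at least 2).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `component`, `t`, `df`, `p`, `exceeds`.
#' @export
exceeds_baseline <- function(measured, baseline, n_eyes, alpha = 0.05) {
  if (n_eyes < 2) stop("need at least 2 eyes")
  base <- stats::setNames(baseline$mean, baseline$component)
  comps <- measured$component
  tstat <- (measured$mean - as.numeric(base[comps])) /
    (measured$sd / sqrt(n_eyes))
  p <- 2 * stats::pt(abs(tstat), df = n_eyes - 1, lower.tail = FALSE)
  tibble::tibble(component = comps, t = tstat, df = n_eyes - 1, p = p,
                 exceeds = p <= alpha)
}
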