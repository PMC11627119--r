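#' Full strain-measurement pipeline for one eye
#'
#' Runs the complete analysis on a before/after pair of radial volumes:
#' optional contrast preprocessing, forward and backward FI-DVC
#' registration, validity filtering (correlation threshold,
#' forward-backward displacement error, edges, outliers), percent-area
#' coverage of the LC region, anterior lamina depth change, displacement
#' smoothing, cylindrical Green-Lagrange strain and region summaries.
#'
#' @param ref,def Before and after [radial_volume()]s.
#' @param landmarks A `landmark_set` marked on the reference session.
#' @param dvc A [dvc_config()].
#' @param filters A [filter_config()].
#' @param preprocess A [preprocess_config()], or `NULL` to use the volumes
#'   as given.
#' @param smoothing_radius Displacement smoothing window radius in grid
#'   points (default 2).
#' @param thickness LC region thickness in um (default 250).
#' @return An object of class `lc_strain_result`: `field` (filtered
#'   displacement field), `strain`, `region`, `summary` (tibble),
#'   `ald` (an `ald_result`), `pct_area_correlated`.
#' @export
lc_pipeline <- function(ref, def, landmarks, dvc = dvc_config(),
                        filters = filter_config(), preprocess = NULL,
                        smoothing_radius = 2, thickness = 250) {
  g <- volume_geometry(ref)
  if (!is.null(preprocess)) {
    ref <- preprocess_volume(ref, preprocess)
    def <- preprocess_volume(def, preprocess)
  }
  region <- build_lc_region(landmarks, g, thickness = thickness)
  fwd <- dvc_register(ref, def, dvc)
  bwd <- dvc_register(def, ref, dvc)
  fwd <- apply_filters(fwd, bwd, filters)
  pct <- percent_area_correlated(fwd, region)
  ald <- ald_change(landmarks, fwd, g)
  sm <- smooth_displacement(fwd, smoothing_radius)
  strain <- green_lagrange(sm)
  summ <- summarize_region(strain, region)
  structure(list(field = fwd, smoothed_field = sm, strain = strain,
                 region = region, summary = summ, ald = ald,
                 pct_area_correlated = pct),
            class = "lc_strain_result")
}

#' @export
print.lc_strain_result <- function(x, ...) {
  cat(sprintf("<lc_strain_result> %.1f%% of LC region correlated; ALD %+.2f um\n",
              x$pct_area_correlated, x$ald$overall))
  full <- x$summary[x$summary$region == "full", ]
  for (i in seq_len(nrow(full))) {
    cat(sprintf("  %-9s % .4f (SD %.4f, n = %d)\n", full$component[i],
                full$mean[i], full$sd[i], full$n[i]))
  }
  invisible(x)
}

#' @rdname lc_pipeline
#' @param x An `lc_strain_result`.
#' @param ... Unused.
#' @method tidy lc_strain_result
#' @export
tidy.lc_strain_result <- function(x, ...) x$summary

#' @rdname lc_pipeline
#' @method glance lc_strain_result
#' @export
glance.lc_strain_result <- function(x, ...) {
  tibble::tibble(
    pct_area_correlated = x$pct_area_correlated,
    ald_um = x$ald$overall,
    n_strain_points = sum(x$strain$valid),
    iterations = x$field$iterations
  )
}
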