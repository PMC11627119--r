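#' Strain component names
#'
#' Canonical component order used throughout: cylindrical normal strains
#' (`e_rr`, `e_tt`, `e_zz`), shears (`e_rt`, `e_zt`, `e_rz`), and the
#' in-plane maximum principal (`e_max`) and maximum shear (`gamma_max`)
#' strains.
#' @export
strain_components <- c("e_rr", "e_tt", "e_zz", "e_rt", "e_zt", "e_rz",
                       "e_max", "gamma_max")

# Cohort-level study conditions: per-component compliance (strain per mm Hg)
# at the scale reported for the goggle cohort (region-mean strain divided by
# the mean 7.1 mm Hg IOP increase).
default_true_compliance <- c(
  e_rr = 0.0003 / 7.1, e_tt = 0.0015 / 7.1, e_zz = -0.0037 / 7.1,
  e_rt = -0.0014 / 7.1, e_zt = 0.0001 / 7.1, e_rz = 0.0004 / 7.1,
  e_max = 0.0080 / 7.1, gamma_max = 0.0097 / 7.1
)

#' Specification of a synthetic eye cohort
#'
#' Defines the generative model for a cohort of eyes undergoing an acute
#' intraocular pressure (IOP) increase: per-eye IOP rise is uniform on
#' `diop_range`; visual-field mean deviation (MD) is uniform on `md_range`;
#' each strain component follows
#' `strain = (true_compliance + md_effect * MD) * dIOP + N(0, noise_sd)`.
#'
#' @param n_eyes Number of eyes (at least 2).
#' @param diop_range IOP increase range in mm Hg (default `c(3, 16)`, the
#'   included-eye range of the goggle cohort).
#' @param true_compliance Named per-component compliance (strain per mm Hg).
#'   Defaults reproduce the cohort-mean strains at a 7.1 mm Hg increase.
#' @param md_effect Named per-component change in compliance per dB of MD
#'   (default: zero for all components except a small negative `e_zt`
#'   effect, i.e. more positive axial-circumferential shear compliance with
#'   worse field damage).
#' @param noise_sd Residual strain SD (default 0.0013, the baseline-error
#'   scale of repeat imaging).
#' @param md_range MD range in dB (default `c(-12, 1.4)`).
#' @param ald_compliance,ald_noise_sd Anterior lamina depth change per mm Hg
#'   (um) and its residual SD (um).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_eyes = 57, diop_range = c(3, 16),
                        true_compliance = default_true_compliance,
                        md_effect = c(e_zt = -2e-5),
                        noise_sd = 0.0013, md_range = c(-12, 1.4),
                        ald_compliance = -2.49 / 7.1, ald_noise_sd = 4.0,
                        seed = 1L) {
  stopifnot(n_eyes >= 2, noise_sd >= 0, ald_noise_sd >= 0)
  if (diop_range[2] <= 0 || diop_range[2] > 30 || diop_range[1] < 0 ||
      diop_range[1] >= diop_range[2]) {
    stop("diop_range must be an increasing range within (0, 30]")
  }
  tc <- stats::setNames(numeric(length(strain_components)), strain_components)
  tc[names(true_compliance)] <- true_compliance
  me <- stats::setNames(numeric(length(strain_components)), strain_components)
  me[names(md_effect)] <- md_effect
  structure(list(n_eyes = as.integer(n_eyes), diop_range = diop_range,
                 true_compliance = tc, md_effect = me, noise_sd = noise_sd,
                 md_range = md_range, ald_compliance = ald_compliance,
                 ald_noise_sd = ald_noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of compliance records
#'
#' Draws per-eye IOP increases, clinical covariates and strain outcomes from
#' a [cohort_spec()]. Covariates mimic the reported cohort structure: VFI
#' and RNFL co-vary with MD, axial length and age are independent.
#' Compliance columns are definitionally `strain / dIOP`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per eye: `eye`, `delta_iop`, `md`, `vfi`,
#'   `rnfl`, `axial_length`, `age`, `ald`, `strain_*` and `compliance_*`
#'   columns for each of [strain_components].
#' @examples
#' head(generate_cohort(cohort_spec(n_eyes = 10, seed = 2)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_eyes
    diop <- stats::runif(n, spec$diop_range[1], spec$diop_range[2])
    md <- stats::runif(n, spec$md_range[1], spec$md_range[2])
    vfi <- pmin(100, 100 + 2.2 * md + stats::rnorm(n, 0, 1.5))
    rnfl <- pmax(40, 92 + 3.5 * md + stats::rnorm(n, 0, 8))
    axl <- stats::rnorm(n, 24.6, 1.6)
    age <- round(stats::runif(n, 40, 80))
    out <- tibble::tibble(
      eye = paste0("eye", sprintf("%03d", seq_len(n))),
      delta_iop = diop, md = md, vfi = vfi, rnfl = rnfl,
      axial_length = axl, age = age,
      ald = spec$ald_compliance * diop + stats::rnorm(n, 0, spec$ald_noise_sd)
    )
    for (comp in strain_components) {
      s <- (spec$true_compliance[[comp]] + spec$md_effect[[comp]] * md) *
        diop + stats::rnorm(n, 0, spec$noise_sd)
      out[[paste0("strain_", comp)]] <- s
      out[[paste0("compliance_", comp)]] <- s / diop
    }
    out
  })
}
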