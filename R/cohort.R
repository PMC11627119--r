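#' Strain compliance
#'
#' Compliance is the strain measure divided by the eye's intraocular
#' pressure increase: strain per mm Hg. A more compliant lamina deforms
#' more for the same pressure rise (a softer response).
#'
#' @param strain Strain (dimensionless) or ALD change (um); vectorised.
#' @param delta_iop IOP increase in mm Hg, strictly positive.
#' @return Compliance, `strain / delta_iop`.
#' @examples
#' compliance(-0.0033, 7.1)  # -4.65e-4 per mm Hg
#' @export
compliance <- function(strain, delta_iop) {
  if (any(delta_iop <= 0)) stop("delta_iop must be positive")
  strain / delta_iop
}

#' Strain implied by a compliance at a given pressure increase
#'
#' Inverse of [compliance()]: `compliance * delta_iop`.
#'
#' @param compliance Strain per mm Hg.
#' @param delta_iop IOP increase in mm Hg.
#' @return Dimensionless strain (or um for ALD compliance).
#' @examples
#' strain_from_compliance(0.001, 7)  # 0.007, i.e. 0.7%
#' @export
strain_from_compliance <- function(compliance, delta_iop) {
  compliance * delta_iop
}

#' Ratio of two strain magnitudes
#'
#' Convenience for cross-study scale checks (e.g. strain at a large acute
#' IOP elevation over strain at a modest one).
#'
#' @param strain_a,strain_b Strains in any common unit; `strain_b` nonzero.
#' @return `strain_a / strain_b`.
#' @examples
#' scale_ratio(3.96, 0.923)  # ~4.29
#' @export
scale_ratio <- function(strain_a, strain_b) {
  if (any(strain_b == 0)) stop("denominator strain must be nonzero")
  strain_a / strain_b
}

#' Cohort-level summary of compliance records
#'
#' Per-component mean/SD of strains, compliances and ALD change across a
#' cohort, plus ordinary least-squares regressions of each strain on the
#' IOP increase and of each compliance on visual-field covariates (MD and
#' VFI). Slopes come with standard errors and two-sided p-values; a
#' degenerate (constant) covariate yields `NA` slopes. Inter-eye
#' correlation is not modelled (ordinary OLS, not GEE); records can be
#' exported with [write_cohort_csv()] for external modelling.
#'
#' @param records Tibble of compliance records as produced by
#'   [generate_cohort()] (columns `delta_iop`, `ald`, `strain_*`,
#'   `compliance_*`, optionally `md`, `vfi`).
#' @return An object of class `cohort_summary` with tibbles `stats`
#'   (`variable`, `mean`, `sd`, `n`) and `regressions` (`response`,
#'   `covariate`, `slope`, `se`, `p`, `r_squared`).
#' @export
cohort_summary <- function(records) {
  if (nrow(records) < 2) stop("need at least 2 records")
  num_cols <- c("ald",
                paste0("strain_", strain_components),
                paste0("compliance_", strain_components))
  num_cols <- intersect(num_cols, names(records))
  stats_tbl <- dplyr::bind_rows(lapply(num_cols, function(cn) {
    tibble::tibble(variable = cn, mean = mean(records[[cn]]),
                   sd = stats::sd(records[[cn]]), n = nrow(records))
  }))
  ols_row <- function(response, covariate) {
    y <- records[[response]]; x <- records[[covariate]]
    if (stats::sd(x) == 0) {
      return(tibble::tibble(response = response, covariate = covariate,
                            slope = NA_real_, se = NA_real_, p = NA_real_,
                            r_squared = NA_real_))
    }
    fit <- stats::lm(y ~ x)
    # noiseless cohorts fit exactly; the perfect-fit warning is expected
    sm <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    tibble::tibble(response = response, covariate = covariate,
                   slope = sm$coefficients[2, 1], se = sm$coefficients[2, 2],
                   p = sm$coefficients[2, 4], r_squared = sm$r.squared)
  }
  regs <- list()
  for (comp in strain_components) {
    sc <- paste0("strain_", comp); cc <- paste0("compliance_", comp)
    if (sc %in% names(records)) {
      regs[[length(regs) + 1]] <- ols_row(sc, "delta_iop")
    }
    if (cc %in% names(records)) {
      for (cov in intersect(c("md", "vfi"), names(records))) {
        regs[[length(regs) + 1]] <- ols_row(cc, cov)
      }
    }
  }
  structure(list(stats = stats_tbl, regressions = dplyr::bind_rows(regs),
                 n = nrow(records)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d eyes\n", x$n))
  print(x$stats, n = 6)
  invisible(x)
}

#' @rdname cohort_summary
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) x$regressions

#' @rdname cohort_summary
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(n_eyes = x$n, n_variables = nrow(x$stats),
                 n_regressions = nrow(x$regressions))
}

#' Read / write cohort records as CSV
#'
#' Column schema: `eye`, `delta_iop` (mm Hg), clinical covariates (`md` dB,
#' `vfi` %, `rnfl` um, `axial_length` mm, `age` years), `ald` (um) and one
#' `strain_*` / `compliance_*` pair per strain component.
#'
#' @param records Tibble of compliance records.
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a tibble.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
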