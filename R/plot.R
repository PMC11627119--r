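#' Plot a strain component on one scan plane
#'
#' Raster of a strain component over the (R, Z) grid of one radial scan,
#' on the diverging blue-red scale conventional for contraction (negative)
#' versus expansion (positive).
#'
#' @param object A `strain_field`.
#' @param component One of [strain_components] (default `"e_zz"`).
#' @param scan Scan number to display (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot strain_field
#' @export
autoplot.strain_field <- function(object, component = "e_zz", scan = 1, ...) {
  df <- generics::tidy(object)
  theta <- (scan - 1) * object$geometry$angular_step
  df <- df[df$component == component & df$theta_deg == theta & df$valid, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_um, y = .data$z_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = "r (um)", y = "z (um)", fill = component,
                  title = sprintf("%s, scan %d (theta = %g deg)",
                                  component, scan, theta)) +
    ggplot2::theme_minimal()
}

#' Plot a displacement component on one scan plane
#'
#' @param object A `displacement_field`.
#' @param component `"U_r"`, `"U_theta"` or `"U_z"` (default).
#' @param scan Scan number (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot displacement_field
#' @export
autoplot.displacement_field <- function(object, component = "U_z",
                                        scan = 1, ...) {
  df <- generics::tidy(object)
  theta <- (scan - 1) * object$geometry$angular_step
  df <- df[df$theta_deg == theta & df$valid, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_um, y = .data$z_um,
                                   fill = .data[[component]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "r (um)", y = "z (um)",
                  title = sprintf("%s (um), scan %d", component, scan)) +
    ggplot2::theme_minimal()
}

#' Scatter of a compliance component against a clinical covariate
#'
#' @param records Cohort records tibble (see [generate_cohort()]).
#' @param component A strain component name (default `"e_zt"`).
#' @param covariate Covariate column (default `"md"`).
#' @return A ggplot object with an OLS fit line.
#' @export
plot_compliance_vs_covariate <- function(records, component = "e_zt",
                                         covariate = "md") {
  ycol <- paste0("compliance_", component)
  ggplot2::ggplot(records, ggplot2::aes(x = .data[[covariate]],
                                        y = .data[[ycol]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = covariate, y = sprintf("%s compliance (per mm Hg)",
                                             component)) +
    ggplot2::theme_minimal()
}

#' Bar chart of region-mean strains with SD error bars
#'
#' @param object An `lc_strain_result`.
#' @param region Region label (default `"full"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lc_strain_result
#' @export
autoplot.lc_strain_result <- function(object, region = "full", ...) {
  df <- object$summary[object$summary$region == region, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "strain",
                  title = sprintf("Region-mean strains (%s LC)", region)) +
    ggplot2::theme_minimal()
}
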