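#' Displacement field from an analytic function
#'
#' Samples a closed-form displacement field onto the correlation grid that
#' [dvc_register()] would use, bypassing image correlation. Used to validate
#' the strain computation against analytic ground truth.
#'
#' @param geometry A [radial_scan_geometry()].
#' @param fun Function `(r, theta, z)` (um, degrees, um; `r >= 0`) returning
#'   a data frame or list with physical components `u_r`, `u_t`, `u_z` (um).
#' @param config A [dvc_config()]; determines the grid.
#' @return A `displacement_field` with `q = 1` everywhere.
#' @export
field_from_function <- function(geometry, fun, config = dvc_config()) {
  g <- geometry
  sched <- subset_schedule(config)
  grid <- make_grid(g, sched[[length(sched)]], config$overlap)
  gd <- lengths(grid)
  pts <- expand.grid(i_r = grid$i_r, scan = grid$scan, i_z = grid$i_z)
  r_signed <- (pts$i_r - g$scan_center) * g$res_r
  theta <- (pts$scan - 1) * g$angular_step + ifelse(r_signed < 0, 180, 0)
  z <- (pts$i_z - 1) * g$res_z
  u <- fun(abs(r_signed), theta, z)
  # store components in the signed-radius scan basis: on the negative-r
  # half the in-plane basis vectors are the negated physical ones
  sgn <- ifelse(r_signed < 0, -1, 1)
  U_r <- array(u$u_r * sgn, gd)
  U_t <- array(u$u_t * sgn, gd)
  U_z <- array(u$u_z, gd)
  r_um <- (grid$i_r - g$scan_center) * g$res_r
  axis_excl <- config$axis_exclusion_um
  if (is.null(axis_excl)) axis_excl <- sched[[length(sched)]][1] / 2 * g$res_r
  valid <- array(rep(abs(r_um) >= axis_excl, prod(gd[2:3])), gd)
  dtheta_rad <- g$angular_step * pi / 180
  Rarr <- array(rep(r_um, prod(gd[2:3])), gd)
  structure(list(
    grid = c(grid, list(r_um = r_um,
                        theta_deg = (grid$scan - 1) * g$angular_step,
                        z_um = (grid$i_z - 1) * g$res_z)),
    du_r = U_r / g$res_r,
    du_s = ifelse(abs(Rarr) > 0, U_t / (dtheta_rad * Rarr), 0),
    du_z = U_z / g$res_z,
    U_r = U_r, U_theta = U_t, U_z = U_z,
    q = array(1, gd), valid = valid,
    increments = list(), iterations = 0L,
    config = config, geometry = g, filter_log = list()
  ), class = "displacement_field")
}

#' Tidy a displacement field
#'
#' @param x A `displacement_field`.
#' @param ... Unused.
#' @return A tibble with one row per grid point: grid coordinates
#'   (`r_um` signed, `theta_deg`, `z_um`), displacement components (um),
#'   `q` and `valid`.
#' @method tidy displacement_field
#' @export
tidy.displacement_field <- function(x, ...) {
  gd <- dim(x$q)
  pts <- expand.grid(r_um = x$grid$r_um, theta_deg = x$grid$theta_deg,
                     z_um = x$grid$z_um)
  tibble::tibble(
    r_um = pts$r_um, theta_deg = pts$theta_deg, z_um = pts$z_um,
    U_r = as.vector(x$U_r), U_theta = as.vector(x$U_theta),
    U_z = as.vector(x$U_z), q = as.vector(x$q), valid = as.vector(x$valid)
  )
}

#' @rdname tidy.displacement_field
#' @method glance displacement_field
#' @export
glance.displacement_field <- function(x, ...) {
  tibble::tibble(
    n_grid = length(x$q), n_valid = sum(x$valid),
    pct_valid = 100 * mean(x$valid),
    mean_q = mean(x$q[x$valid]),
    iterations = x$iterations
  )
}

#' Tidy a strain field
#'
#' @param x A `strain_field`.
#' @param ... Unused.
#' @return A long tibble with grid coordinates, `component` and `value`.
#' @method tidy strain_field
#' @export
tidy.strain_field <- function(x, ...) {
  pts <- expand.grid(r_um = x$grid$r_um, theta_deg = x$grid$theta_deg,
                     z_um = x$grid$z_um)
  out <- lapply(strain_components, function(comp) {
    tibble::tibble(r_um = pts$r_um, theta_deg = pts$theta_deg,
                   z_um = pts$z_um, component = comp,
                   value = as.vector(x[[comp]]),
                   valid = as.vector(x$valid))
  })
  dplyr::bind_rows(out)
}

#' Write / read a displacement or strain field as CSV with a JSON sidecar
#'
#' Long-format CSV (one row per grid point) plus a JSON sidecar carrying
#' the scan geometry, so fields can be exchanged with other tools.
#'
#' @param field A `displacement_field` or `strain_field`.
#' @param path CSV file path; sidecar at `paste0(path, ".json")`.
#' @return `write_field_csv` returns `path` invisibly.
#' @export
write_field_csv <- function(field, path) {
  df <- generics::tidy(field)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    c(unclass(field$geometry),
      list(filter_log = field$filter_log)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
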