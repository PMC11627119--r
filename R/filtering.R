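#' Displacement-field filter configuration
#'
#' Validity filters applied to a registered displacement field before strain
#' computation: the weighted-correlation-coefficient threshold (0.055), the
#' displacement-error ceiling (5 um, estimated by forward-backward
#' consistency), removal of grid points near the scan edges, and a
#' median/MAD neighbourhood outlier rule.
#'
#' @param q_threshold Weighted correlation coefficient threshold (default
#'   0.055); points with `q` below it are excluded.
#' @param displacement_error_max Forward-backward displacement error ceiling
#'   in um (default 5).
#' @param edge_margin Grid points within this many grid steps of the lateral
#'   or depth image border are removed (default 1).
#' @param outlier_k MAD multiples for the outlier rule (default 3).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(q_threshold = 0.055, displacement_error_max = 5,
                          edge_margin = 1, outlier_k = 3) {
  stopifnot(q_threshold > 0, q_threshold < 1, displacement_error_max > 0)
  structure(list(q_threshold = q_threshold,
                 displacement_error_max = displacement_error_max,
                 edge_margin = as.integer(edge_margin),
                 outlier_k = outlier_k),
            class = "filter_config")
}

log_filter <- function(field, name, before, after) {
  field$filter_log[[length(field$filter_log) + 1]] <-
    list(filter = name, removed = before - after, remaining = after)
  field
}

#' Exclude grid points with weak correlation
#'
#' Invalidates grid points whose weighted correlation coefficient falls
#' below the threshold; all other points are untouched.
#'
#' @param field A `displacement_field`.
#' @param q_threshold Correlation threshold (default 0.055).
#' @return The filtered `displacement_field`.
#' @export
filter_by_correlation <- function(field, q_threshold = 0.055) {
  before <- sum(field$valid)
  field$valid <- field$valid & (field$q >= q_threshold)
  log_filter(field, "correlation", before, sum(field$valid))
}

#' Exclude grid points failing forward-backward consistency
#'
#' Estimates the displacement correlation error at each grid point as
#' `e(x) = 0.5 * |u_fwd(x) + u_bwd(x + u_fwd(x))|` (um): for a perfect
#' registration the backward field evaluated at the forward-mapped position
#' cancels the forward field exactly. Points with error above `max_error`
#' (or where the backward field cannot be evaluated) are invalidated.
#'
#' @param field_fwd Forward `displacement_field` (ref -> def).
#' @param field_bwd Backward field (def -> ref) on a compatible grid.
#' @param max_error Error ceiling in um (default 5). `Inf` disables.
#' @return The filtered forward field.
#' @export
filter_by_displacement_error <- function(field_fwd, field_bwd, max_error = 5) {
  g <- field_fwd$geometry
  if (!same_geometry(g, field_bwd$geometry)) {
    stop("fields registered on incompatible grids")
  }
  before <- sum(field_fwd$valid)
  if (is.finite(max_error)) {
    gd <- dim(field_fwd$q)
    pts <- expand.grid(i_r = field_fwd$grid$i_r, scan = field_fwd$grid$scan,
                       i_z = field_fwd$grid$i_z)
    # forward-mapped position in index units
    ir2 <- pts$i_r + as.vector(field_fwd$du_r)
    s2 <- pts$scan + as.vector(field_fwd$du_s)
    iz2 <- pts$i_z + as.vector(field_fwd$du_z)
    r2_um <- (ir2 - g$scan_center) * g$res_r
    z2_um <- (iz2 - 1) * g$res_z
    bwd <- sample_field(field_bwd, r2_um, s2, z2_um)
    err <- 0.5 * sqrt(
      (as.vector(field_fwd$U_r) + bwd$U_r)^2 +
        (as.vector(field_fwd$U_theta) + bwd$U_theta)^2 +
        (as.vector(field_fwd$U_z) + bwd$U_z)^2)
    bad <- is.na(err) | err > max_error
    field_fwd$valid <- field_fwd$valid & !array(bad, gd)
  }
  field_fwd$displacement_error_max <- max_error
  log_filter(field_fwd, "displacement_error", before, sum(field_fwd$valid))
}

#' Remove scan-edge points and displacement outliers
#'
#' Invalidates grid points within `edge_margin` grid steps of the lateral or
#' depth borders of the scans (the scan-index axis is periodic and has no
#' edge), then flags outliers: a point is an outlier iff any displacement
#' component deviates from the median of its valid 3 x 3 x 3 grid
#' neighbours by more than `outlier_k` times the neighbourhood MAD and by
#' more than one voxel absolutely.
#'
#' @param field A `displacement_field`.
#' @param config A [filter_config()].
#' @return The filtered `displacement_field`.
#' @export
remove_edges_and_outliers <- function(field, config = filter_config()) {
  gd <- dim(field$q)
  before <- sum(field$valid)
  m <- config$edge_margin
  if (m > 0) {
    edge_r <- seq_len(gd[1]) <= m | seq_len(gd[1]) > gd[1] - m
    edge_z <- seq_len(gd[3]) <= m | seq_len(gd[3]) > gd[3] - m
    edge <- outer(outer(edge_r, rep(FALSE, gd[2]), "|"), edge_z, "|")
    field$valid <- field$valid & !edge
  }
  if (is.finite(config$outlier_k)) {
    res <- field$geometry[c("res_r", "res_z")]
    comps <- list(r = list(a = field$du_r, scale = res$res_r),
                  s = list(a = field$du_s, scale = 1),
                  z = list(a = field$du_z, scale = res$res_z))
    out <- array(FALSE, gd)
    valid <- field$valid
    idx <- which(valid, arr.ind = TRUE)
    for (comp in comps) {
      a <- comp$a
      for (row in seq_len(nrow(idx))) {
        i <- idx[row, 1]; j <- idx[row, 2]; k <- idx[row, 3]
        ri <- max(1, i - 1):min(gd[1], i + 1)
        sj <- max(1, j - 1):min(gd[2], j + 1)
        zk <- max(1, k - 1):min(gd[3], k + 1)
        vsub <- valid[ri, sj, zk, drop = FALSE]
        vsub[match(i, ri), match(j, sj), match(k, zk)] <- FALSE  # self
        nb <- a[ri, sj, zk, drop = FALSE][vsub]
        if (length(nb) < 3) next
        med <- stats::median(nb)
        madn <- stats::mad(nb, center = med)
        dev <- abs(a[i, j, k] - med)
        if (dev > config$outlier_k * max(madn, 1e-12) && dev > 1) {
          out[i, j, k] <- TRUE
        }
      }
    }
    field$valid <- field$valid & !out
  }
  log_filter(field, "edges_outliers", before, sum(field$valid))
}

#' Percent of an LC region with valid correlation
#'
#' Fraction (in percent) of displacement-grid points falling inside the LC
#' analysis region that survived the validity filters.
#'
#' @param field A `displacement_field`.
#' @param region An `lc_region` from [build_lc_region()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_area_correlated <- function(field, region) {
  inr <- grid_in_region(field, region)
  if (!any(inr)) stop("region contains no displacement grid points")
  100 * sum(field$valid[inr]) / sum(inr)
}

# Logical array marking displacement-grid points inside the LC region.
grid_in_region <- function(field, region) {
  gd <- dim(field$q)
  pts <- expand.grid(i_r = field$grid$i_r, scan = field$grid$scan,
                     i_z = field$grid$i_z)
  inr <- region_contains(region, pts$scan, pts$i_r,
                         (pts$i_z - 1) * field$geometry$res_z)
  array(inr, gd)
}

#' Apply the standard filter sequence
#'
#' Correlation threshold, forward-backward displacement error, then edge and
#' outlier removal, in that order (outliers are judged against
#' already-cleaned neighbours). Each filter only shrinks the valid set and
#' is idempotent; counts removed per filter are recorded in
#' `field$filter_log`.
#'
#' @param field_fwd Forward `displacement_field`.
#' @param field_bwd Backward field for the displacement-error filter, or
#'   `NULL` to skip it.
#' @param config A [filter_config()].
#' @return The filtered forward field.
#' @export
apply_filters <- function(field_fwd, field_bwd = NULL,
                          config = filter_config()) {
  field_fwd <- filter_by_correlation(field_fwd, config$q_threshold)
  if (!is.null(field_bwd)) {
    field_fwd <- filter_by_displacement_error(
      field_fwd, field_bwd, config$displacement_error_max)
  }
  remove_edges_and_outliers(field_fwd, config)
}
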