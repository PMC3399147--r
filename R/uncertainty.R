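# Ensemble summarization and uncertainty decomposition. Coverage is
# FPC-weighted spherical cell area (continuous km^2), quantile bands use
# linear interpolation between order statistics (stats::quantile type 7),
# and the parameter/climate/emission components follow the stratification
# of the scenario set: quantile width within a scenario, high/low-vs-median
# spread of ensemble means within an IGSM emission group, and the
# difference between emission-group means.

#' FPC-weighted coverage area of one PFT
#'
#' `sum over cells of fpc * cell_area`, with spherical cell areas
#' (`R^2 * dlon * (sin lat2 - sin lat1)`, R = 6371 km). Cover is treated
#' as continuous: no presence threshold is applied (pass `threshold` for
#' the thresholded alternative, which counts a cell's full area when its
#' fpc exceeds the threshold).
#'
#' @param fpc_grid per-cell cover fractions for one PFT-year.
#' @param grid the matching [grid_spec()].
#' @param threshold optional presence threshold in (0, 1\].
#' @return area in km^2.
#' @export
#' @examples
#' g <- grid_spec(res = 10)
#' coverage_area(rep(1, g$n_cells), g) # total grid area
coverage_area <- function(fpc_grid, grid, threshold = NULL) {
  stopifnot(inherits(grid, "grid_spec"),
            length(fpc_grid) == grid$n_cells)
  if (any(fpc_grid < 0 | fpc_grid > 1))
    stop("fpc outside [0, 1]", call. = FALSE)
  if (is.null(threshold)) {
    sum(fpc_grid * grid$cells$area_km2)
  } else {
    sum((fpc_grid >= threshold) * grid$cells$area_km2)
  }
}

#' Coverage-area trajectories of every PFT in a simulation
#'
#' @param result a [run_simulation()] result.
#' @param threshold optional presence threshold, see [coverage_area()].
#' @return year x PFT matrix of km^2.
#' @export
coverage_series <- function(result, threshold = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  ny <- dim(result$fpc)[2]
  np <- dim(result$fpc)[3]
  out <- matrix(0, ny, np, dimnames = list(result$years, result$pft_ids))
  for (p in seq_len(np)) {
    for (y in seq_len(ny)) {
      out[y, p] <- coverage_area(result$fpc[, y, p], result$grid, threshold)
    }
  }
  out
}

#' Ensemble mean, variance and quantile band
#'
#' Per-year mean, variance and the `q_low`/`q_high` quantiles over the
#' ensemble (sample) dimension. Quantiles use linear interpolation between
#' order statistics (`stats::quantile` type 7); the convention is frozen in
#' the tests.
#'
#' @param areas sample x year matrix (any per-year ensemble output: km^2
#'   coverage, mean FPC, ...).
#' @param q_low,q_high band quantiles, defaults 0.10 and 0.90.
#' @return object of class `ensemble_summary`: list with per-year `mean`,
#'   `variance`, `q_low`, `q_high`, plus `n_samples` and the quantile
#'   probabilities.
#' @export
ensemble_band <- function(areas, q_low = 0.10, q_high = 0.90) {
  stopifnot(is.matrix(areas))
  if (nrow(areas) < 2) stop("need at least 2 ensemble members", call. = FALSE)
  stopifnot(q_low < q_high)
  structure(list(
    mean = colMeans(areas),
    variance = apply(areas, 2, stats::var),
    q_low = apply(areas, 2, stats::quantile, probs = q_low, names = FALSE,
                  type = 7),
    q_high = apply(areas, 2, stats::quantile, probs = q_high, names = FALSE,
                   type = 7),
    probs = c(q_low, q_high),
    n_samples = nrow(areas)), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary: %d members, %d years, band (%g, %g)\n",
              x$n_samples, length(x$mean), x$probs[1], x$probs[2]))
  invisible(x)
}

igsm_groups <- list(
  reference = c(median = "X901M", low = "X902L", high = "X903H"),
  stabilization = c(median = "X904M", low = "X905L", high = "X906H"))

#' Decompose projection uncertainty into parameter, climate and emission
#' components
#'
#' Given per-scenario ensemble summaries of one PFT's coverage, computes
#' per year: the parameter-induced width (`q_high - q_low` within each
#' scenario, also averaged over scenarios); the climate-induced width (the
#' larger of |high - median| and |low - median| of the ensemble *means*
#' within each IGSM emission group, parameters averaged out); and the
#' emission-induced width (|mean over the reference group - mean over the
#' stabilization group| of ensemble means).
#'
#' @param results named list of [ensemble_band()] summaries, keyed by
#'   scenario name. All six IGSM scenarios are required for the climate and
#'   emission components; with fewer scenarios those components are
#'   reported as `NULL` (parameter widths are always computed).
#' @param require_groups error (rather than return `NULL` components) when
#'   the IGSM scenarios are missing.
#' @return object of class `uncertainty_components`: list with
#'   `parameter_width` (per scenario, per year), `parameter_width_mean`,
#'   `climate_width` (per IGSM group), `emission_width`.
#' @export
decompose_uncertainty <- function(results, require_groups = FALSE) {
  stopifnot(is.list(results), length(results) >= 1,
            !is.null(names(results)))
  for (r in results) stopifnot(inherits(r, "ensemble_summary"))
  param <- lapply(results, function(r) r$q_high - r$q_low)
  param_mean <- Reduce(`+`, param) / length(param)
  needed <- unlist(igsm_groups, use.names = FALSE)
  have <- needed %in% names(results)
  climate <- emission <- NULL
  if (all(have)) {
    climate <- lapply(igsm_groups, function(g) {
      med <- results[[g[["median"]]]]$mean
      hi <- abs(results[[g[["high"]]]]$mean - med)
      lo <- abs(results[[g[["low"]]]]$mean - med)
      pmax(hi, lo)
    })
    grp_mean <- lapply(igsm_groups, function(g) {
      Reduce(`+`, lapply(g, function(s) results[[s]]$mean)) / length(g)
    })
    emission <- abs(grp_mean$reference - grp_mean$stabilization)
  } else if (require_groups) {
    stop("missing IGSM scenarios: ",
         paste(needed[!have], collapse = ", "), call. = FALSE)
  }
  structure(list(parameter_width = param, parameter_width_mean = param_mean,
                 climate_width = climate, emission_width = emission),
            class = "uncertainty_components")
}

#' Cross-cell regression of mean FPC on a climate statistic
#'
#' Ordinary least-squares fit of the per-cell (2001-2100 mean) FPC of one
#' PFT on one per-cell climate statistic — mean temperature, mean
#' precipitation, or their fitted trends — to quantify how strongly a
#' climate gradient organizes that PFT's distribution.
#'
#' @param per_cell_fpc numeric, one value per cell.
#' @param per_cell_climate_stat numeric, same length, >= 3 cells.
#' @return as [fit_trend()]: `slope`, `ci95`, `r_squared`, `p_value`.
#' @export
regress_fpc_climate <- function(per_cell_fpc, per_cell_climate_stat) {
  if (length(per_cell_fpc) != length(per_cell_climate_stat))
    stop("unequal lengths", call. = FALSE)
  if (length(per_cell_fpc) < 3) stop("need >= 3 cells", call. = FALSE)
  if (stats::var(per_cell_climate_stat) == 0)
    stop("zero-variance regressor", call. = FALSE)
  fit_trend(per_cell_fpc, per_cell_climate_stat)
}
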