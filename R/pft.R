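#' Load the plant-functional-type configuration
#'
#' Reads the structured text (YAML) configuration describing the six PFTs —
#' temperate needleleaved evergreen (TNE), temperate broadleaved evergreen
#' (TBE), temperate broadleaved summergreen (TBS), boreal needleleaved
#' evergreen (BNE), boreal summergreen woody (BSW) and C3 perennial grass
#' (CPG) — together with the shared surrogate-scheme constants. Bioclimatic
#' limits and the fixed physiological constants live in this file, not in
#' code, so alternative configurations can be supplied per run.
#'
#' @param path path to a YAML file; defaults to the configuration shipped
#'   with the package.
#' @return object of class `pft_config`: list with `pfts` (named list of six
#'   per-PFT parameter lists), `constants`, and `ids` (PFT order used by all
#'   simulator output).
#' @export
#' @examples
#' cfg <- default_pft_config()
#' cfg$ids
default_pft_config <- function(path = system.file("extdata",
                                                  "pft_defaults.yml",
                                                  package = "vegens",
                                                  mustWork = TRUE)) {
  default_path <- system.file("extdata", "pft_defaults.yml",
                              package = "vegens", mustWork = TRUE)
  if (path == default_path && !is.null(.vegens_cache$pft_config))
    return(.vegens_cache$pft_config)
  raw <- yaml::read_yaml(path)
  pfts <- raw$pfts
  stopifnot(length(pfts) == 6L, !anyDuplicated(names(pfts)))
  for (id in names(pfts)) {
    p <- pfts[[id]]
    if (is.finite(p$tc_min_est) && is.finite(p$tc_max_est))
      stopifnot(p$tc_min_est < p$tc_max_est)
    stopifnot(p$sla > 0)
    pfts[[id]]$id <- id
  }
  cfg <- structure(list(pfts = pfts, constants = raw$constants,
                        ids = names(pfts)),
                   class = "pft_config")
  if (path == default_path) .vegens_cache$pft_config <- cfg
  cfg
}

.vegens_cache <- new.env(parent = emptyenv())

#' @export
print.pft_config <- function(x, ...) {
  cat("pft_config:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Bioclimatic establishment and survival test for one PFT
#'
#' Establishment requires the (multi-year mean) coldest-month temperature to
#' fall inside the PFT's `[tc_min_est, tc_max_est]` window and the growing
#' degree-day sum (base 5 degC) to reach `gdd5_min`. Survival fails when the
#' warmest-month temperature exceeds the heat ceiling `tw_max` or the
#' coldest month drops below the survival floor `tc_surv`.
#'
#' @param pft one element of `default_pft_config()$pfts`.
#' @param climate_summary list with `tc` (coldest-month mean, degC), `tw`
#'   (warmest-month mean, degC) and `gdd5` (degree-days), each a multi-year
#'   running mean.
#' @return list with logicals `establish` and `survive`.
#' @export
#' @examples
#' cfg <- default_pft_config()
#' bioclim_allows(cfg$pfts$BNE, list(tc = -20, tw = 15, gdd5 = 400))
bioclim_allows <- function(pft, climate_summary) {
  tc <- climate_summary$tc
  tw <- climate_summary$tw
  gdd5 <- climate_summary$gdd5
  establish <- tc >= pft$tc_min_est && tc <= pft$tc_max_est &&
    gdd5 >= pft$gdd5_min
  survive <- tw <= pft$tw_max && tc >= pft$tc_surv
  list(establish = establish, survive = survive)
}

# Vectorized internal form: one row per PFT, columns establish/survive.
bioclim_allows_all <- function(cfg, tc, tw, gdd5) {
  est <- logical(length(cfg$ids))
  srv <- logical(length(cfg$ids))
  for (i in seq_along(cfg$ids)) {
    p <- cfg$pfts[[i]]
    est[i] <- tc >= p$tc_min_est && tc <= p$tc_max_est && gdd5 >= p$gdd5_min
    srv[i] <- tw <= p$tw_max && tc >= p$tc_surv
  }
  list(establish = est, survive = srv)
}

# Annual bioclim inputs from one year of monthly temperature.
climate_year_summary <- function(temp_monthly) {
  list(tc = min(temp_monthly), tw = max(temp_monthly),
       gdd5 = sum(pmax(0, temp_monthly - 5)) * 30.4375)
}
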