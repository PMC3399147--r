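#' Spatial grid over the northern high latitudes
#'
#' Builds a regular latitude/longitude grid of cell centres with spherical
#' cell areas. The default extent is the study domain, 45N poleward. A land
#' mask may be supplied as a logical vector over the cells (row-major in
#' latitude then longitude); by default every cell is land, since the
#' synthetic climatology is zonally symmetric and carries no coastline.
#'
#' @param lat_range,lon_range numeric length-2, degrees.
#' @param res grid spacing in degrees (single number, used for both axes).
#' @param land optional logical vector, one entry per cell.
#' @return object of class `grid_spec`: list with `cells` (data.frame of
#'   `lat`, `lon`, `area_km2` for land cells), `res`, `lat_range`,
#'   `lon_range`, and `n_cells`.
#' @export
#' @examples
#' g <- grid_spec(res = 10)
#' sum(g$cells$area_km2)
grid_spec <- function(lat_range = c(45, 90), lon_range = c(0, 60), res = 5,
                      land = NULL) {
  stopifnot(lat_range[1] < lat_range[2], lon_range[1] < lon_range[2], res > 0)
  lats <- seq(lat_range[1] + res / 2, lat_range[2] - res / 2, by = res)
  lons <- seq(lon_range[1] + res / 2, lon_range[2] - res / 2, by = res)
  cells <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
  if (is.null(land)) land <- rep(TRUE, nrow(cells))
  stopifnot(length(land) == nrow(cells))
  if (!any(land)) stop("empty land mask", call. = FALSE)
  cells <- cells[land, , drop = FALSE]
  rownames(cells) <- NULL
  cells$area_km2 <- cell_area_km2(cells$lat, res, res)
  structure(list(cells = cells, res = res, lat_range = lat_range,
                 lon_range = lon_range, n_cells = nrow(cells)),
            class = "grid_spec")
}

#' Circumpolar study-domain grid with a realistic zonal land fraction
#'
#' Builds a [grid_spec()] over 45-90N in which each latitude ring keeps
#' only the fraction of cells corresponding to the real zonal land
#' fraction (continents give way to the Arctic Ocean poleward of ~70N,
#' with a remnant above 80N for Greenland and the archipelagos). The kept
#' cells of a ring are contiguous in longitude; with a zonally symmetric
#' climatology only the count matters.
#'
#' @param res grid spacing, degrees.
#' @param lon_range longitudes spanned before masking.
#' @return a `grid_spec`.
#' @export
#' @examples
#' sum(study_grid(res = 10)$cells$area_km2) # ~3.4e7 km2 of land
study_grid <- function(res = 5, lon_range = c(0, 360)) {
  full <- grid_spec(lat_range = c(45, 90), lon_range = lon_range, res = res)
  lats <- sort(unique(full$cells$lat))
  nlon <- sum(full$cells$lat == lats[1])
  keep <- logical(nrow(full$cells))
  for (la in lats) {
    ring <- which(full$cells$lat == la)
    n_keep <- max(1, round(land_fraction_zonal(la) * nlon))
    if (land_fraction_zonal(la) <= 0.025) n_keep <- 0
    if (n_keep > 0) keep[ring[seq_len(min(n_keep, length(ring)))]] <- TRUE
  }
  grid_spec(lat_range = c(45, 90), lon_range = lon_range, res = res,
            land = keep)
}

# Approximate present-day zonal land fraction north of 45N.
land_fraction_zonal <- function(lat) {
  ref_lat <- c(45, 50, 55, 60, 65, 70, 75, 80, 85, 90)
  ref_frac <- c(0.52, 0.57, 0.63, 0.78, 0.78, 0.42, 0.18, 0.12, 0.05, 0)
  stats::approx(ref_lat, ref_frac, xout = lat, rule = 2)$y
}

#' Spherical area of a grid cell
#'
#' Area of a `dlat` x `dlon` cell centred at latitude `lat`, on a sphere of
#' radius 6371 km: `R^2 * dlon_rad * (sin(lat2) - sin(lat1))`.
#'
#' @param lat cell-centre latitude(s), degrees.
#' @param dlat,dlon cell extent, degrees.
#' @return area in km^2.
#' @export
cell_area_km2 <- function(lat, dlat, dlon) {
  R <- 6371
  lat1 <- pmax(-90, lat - dlat / 2) * pi / 180
  lat2 <- pmin(90, lat + dlat / 2) * pi / 180
  R^2 * (dlon * pi / 180) * (sin(lat2) - sin(lat1))
}

#' The ten built-in climate-change scenario specifications
#'
#' Four IPCC SRES scenarios (HadCM3 A1FI, A2, B1, B2; smooth warming) and
#' six MIT IGSM scenarios (X901M/X902L/X903H: reference emissions;
#' X904M/X905L/X906H: level-1 stabilization; M/L/H = median/low/high climate
#' response; latitude-amplified warming). Each spec carries the 2001-2100
#' linear trend of domain-mean annual air temperature (degC/yr) and annual
#' precipitation (mm/yr), the CO2 endpoints (ppmv in 2001 and 2100), and
#' interannual noise standard deviations derived so that a fitted 100-year
#' trend reproduces the scenario's published R-squared in expectation.
#'
#' @return list of 10 `scenario_spec` objects, named by scenario.
#' @export
#' @examples
#' builtin_scenarios()[["A1FI"]]$temp_slope
builtin_scenarios <- function() {
  path <- system.file("extdata", "scenario_table.csv", package = "vegens",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- as.list(tab[i, ])
    scenario_spec(
      name = row$name, family = row$family,
      emission_group = row$emission_group,
      response_class = row$response_class,
      temp_slope = row$temp_slope, precip_slope = row$precip_slope,
      co2_start = row$co2_start, co2_end = row$co2_end,
      noise_temp = noise_from_r2(row$temp_slope, row$temp_r2),
      noise_precip = noise_from_r2(row$precip_slope, row$precip_r2))
  })
  stats::setNames(out, tab$name)
}

# sigma such that a 100-year OLS fit of slope*t + N(0, sigma^2) has
# E[R^2] ~ r2: sigma = |slope| * sqrt(Var(t) * (1/r2 - 1)), Var(t) = 833.25
# for t = 0..99. Printed R^2 of 1.00 is a rounded value; floored at 0.995.
noise_from_r2 <- function(slope, r2) {
  r2 <- min(r2, 0.995)
  abs(slope) * sqrt(833.25 * (1 / r2 - 1))
}

#' Construct a climate scenario specification
#'
#' @param name scenario identifier.
#' @param temp_slope,precip_slope imposed linear trend of domain-mean annual
#'   temperature (degC/yr) and annual precipitation (mm/yr) over 2001-2100.
#' @param co2_start,co2_end atmospheric CO2 (ppmv) in 2001 and 2100;
#'   interpolated linearly in between and held at `co2_start` before 2001.
#' @param family `"IPCC-smooth"` (spatially uniform warming) or
#'   `"IGSM-latitude-amplified"` (warming rate increasing with latitude,
#'   zero-mean over the domain so the domain trend is preserved).
#' @param emission_group `"ipcc"`, `"reference"` or `"stabilization"`.
#' @param response_class `"median"`, `"low"`, `"high"` or `"n/a"`.
#' @param noise_temp,noise_precip interannual standard deviations of the
#'   domain-coherent annual anomalies (degC; mm/yr).
#' @param amplification latitude gradient of the warming-rate multiplier
#'   (per degree latitude), IGSM family only.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, temp_slope, precip_slope, co2_start, co2_end,
                          family = c("IPCC-smooth", "IGSM-latitude-amplified"),
                          emission_group = c("ipcc", "reference", "stabilization"),
                          response_class = "n/a",
                          noise_temp = 0, noise_precip = 0,
                          amplification = 0.02) {
  family <- match.arg(family)
  emission_group <- match.arg(emission_group)
  stopifnot(co2_start < co2_end, noise_temp >= 0, noise_precip >= 0)
  structure(list(name = name, family = family,
                 emission_group = emission_group,
                 response_class = response_class,
                 temp_slope = temp_slope, precip_slope = precip_slope,
                 co2_start = co2_start, co2_end = co2_end,
                 noise_temp = noise_temp, noise_precip = noise_precip,
                 amplification = if (family == "IGSM-latitude-amplified")
                   amplification else 0),
            class = "scenario_spec")
}

# Zonally symmetric baseline monthly climatology (cell x 12 matrices).
# Temperature: latitude-dependent annual mean with a sinusoidal seasonal
# cycle whose amplitude grows poleward (continentality), capped where the
# Arctic Ocean moderates it. Calibrated against present-day zonal land
# climate: ~47N mean -0.5 degC, July ~19, January ~ -20; ~67N mean -12.5,
# July ~15, January ~ -40. Precipitation: latitude-declining monthly
# totals with a modest summer peak. Cloud: winter-peaked fraction.
baseline_climatology <- function(grid) {
  lat <- grid$cells$lat
  m <- seq_len(12)
  seas <- -cos(2 * pi * (m - 0.5) / 12)     # -1 in January, +1 in July
  t_mean <- 28 - 0.6 * lat
  t_amp <- pmin(28, 18 + 0.45 * (lat - 45))
  temp <- outer(t_mean, rep(1, 12)) + outer(t_amp, seas)
  p0 <- pmax(5, 42 - 0.3 * (lat - 45))
  prec <- outer(p0, rep(1, 12)) * (1 + 0.3 * matrix(seas, length(lat), 12,
                                                    byrow = TRUE))
  cloud <- matrix(pmin(0.95, pmax(0.05, 0.55 - 0.1 * seas)),
                  length(lat), 12, byrow = TRUE)
  list(temp = temp, prec = prec, cloud = cloud)
}

#' Generate a gridded monthly climate cube for one scenario
#'
#' Produces monthly air temperature (degC), precipitation (mm/month), cloud
#' fraction and annual CO2 (ppmv) on a grid, such that with `noise = FALSE`
#' the area-weighted domain-mean annual temperature and annual-total
#' precipitation follow the configured linear trends *exactly* over
#' 2001-2100 (warming is zero before 2001). IGSM-family scenarios amplify
#' the warming rate linearly with latitude, constructed zero-mean over the
#' (area-weighted) domain so the domain trend is untouched. Interannual
#' noise is a domain-coherent annual anomaly plus independent per-cell
#' anomalies; precipitation is clipped at zero and cloud at \[0, 1\].
#'
#' @param spec a [scenario_spec()].
#' @param grid a [grid_spec()].
#' @param years integer vector of consecutive years within 1901-2100.
#' @param seed integer; the cube is reproducible given
#'   `(spec, grid, years, seed)`.
#' @param noise set `FALSE` for the deterministic trend-only cube.
#' @return object of class `climate_cube`: list with `grid`, `years`,
#'   `temperature`, `precipitation`, `cloud` (arrays cell x 12 x year) and
#'   `co2` (named by year).
#' @export
#' @examples
#' cube <- generate_scenario(builtin_scenarios()$A1FI, grid_spec(res = 15),
#'                           2001:2100, seed = 1, noise = FALSE)
#' fit_trend(domain_annual(cube, "temperature"), cube$years)$slope
generate_scenario <- function(spec, grid, years, seed = 1, noise = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(grid, "grid_spec"))
  if (any(years < 1901 | years > 2100))
    stop("years must lie within 1901-2100", call. = FALSE)
  if (any(diff(years) != 1)) stop("years must be consecutive", call. = FALSE)
  nc <- grid$n_cells
  ny <- length(years)
  clim <- baseline_climatology(grid)
  w <- grid$cells$area_km2 / sum(grid$cells$area_km2)
  lat <- grid$cells$lat
  # warming-rate multiplier, area-weighted mean exactly 1
  g <- 1 + spec$amplification * (lat - sum(w * lat))
  tt <- pmax(0, years - 2001)                     # trend time, yr
  temp <- array(0, c(nc, 12, ny))
  prec <- array(0, c(nc, 12, ny))
  cloudarr <- array(0, c(nc, 12, ny))
  eps_t <- eps_p <- numeric(ny)
  cell_t <- cell_p <- matrix(0, nc, ny)
  cloud_jit <- array(0, c(nc, 12, ny))
  if (noise) {
    with_local_seed(seed, {
      eps_t <- stats::rnorm(ny, 0, spec$noise_temp)
      eps_p <- stats::rnorm(ny, 0, spec$noise_precip)
      cell_t <- matrix(stats::rnorm(nc * ny, 0, spec$noise_temp), nc, ny)
      cell_p <- matrix(stats::rnorm(nc * ny, 0, spec$noise_precip), nc, ny)
      cloud_jit <- array(stats::rnorm(nc * 12 * ny, 0, 0.03), c(nc, 12, ny))
    })
  }
  for (iy in seq_len(ny)) {
    dT <- spec$temp_slope * tt[iy] * g + eps_t[iy] + cell_t[, iy]
    dP <- (spec$precip_slope * tt[iy] + eps_p[iy] + cell_p[, iy]) / 12
    temp[, , iy] <- clim$temp + dT
    prec[, , iy] <- pmax(0, clim$prec + dP)
    cloudarr[, , iy] <- pmin(1, pmax(0, clim$cloud + cloud_jit[, , iy]))
  }
  co2 <- spec$co2_start +
    (spec$co2_end - spec$co2_start) * pmax(0, years - 2001) / 99
  structure(list(grid = grid, years = years, temperature = temp,
                 precipitation = prec, cloud = cloudarr,
                 co2 = stats::setNames(co2, years), scenario = spec$name),
            class = "climate_cube")
}

#' @export
print.climate_cube <- function(x, ...) {
  cat(sprintf("climate_cube: %d cells, years %d-%d%s\n", x$grid$n_cells,
              min(x$years), max(x$years),
              if (!is.null(x$scenario)) paste0(" (", x$scenario, ")") else ""))
  invisible(x)
}

#' Spin-up climate from cyclic replication of a baseline block
#'
#' Returns an `n_years` cube that repeats the first 30 years of `cube`
#' month-by-month, cyclically; CO2 is held at the first year's value. This
#' is the standard spin-up forcing: a fixed baseline climatology cycled
#' until the vegetation reaches quasi-equilibrium.
#'
#' @param cube a [generate_scenario()] result covering at least 30 years.
#' @param n_years length of the spin-up forcing.
#' @return a `climate_cube` whose years are labelled `1:n_years` relative
#'   to the spin-up (negative calendar meaning is irrelevant).
#' @export
generate_spinup <- function(cube, n_years) {
  stopifnot(inherits(cube, "climate_cube"))
  if (length(cube$years) < 30)
    stop("cube must cover at least 30 years", call. = FALSE)
  block <- 30L
  idx <- rep_len(seq_len(block), n_years)
  structure(list(grid = cube$grid, years = seq_len(n_years),
                 temperature = cube$temperature[, , idx, drop = FALSE],
                 precipitation = cube$precipitation[, , idx, drop = FALSE],
                 cloud = cube$cloud[, , idx, drop = FALSE],
                 co2 = stats::setNames(rep(cube$co2[[1]], n_years),
                                       seq_len(n_years)),
                 scenario = paste0(cube$scenario %||% "", "-spinup")),
            class = "climate_cube")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area-weighted domain-mean annual series from a climate cube
#'
#' Temperature and cloud are averaged over months; precipitation is the
#' annual total (mm/yr), matching the units of the scenario trend table.
#'
#' @param cube a `climate_cube`.
#' @param var one of `"temperature"`, `"precipitation"`, `"cloud"`.
#' @return numeric vector, one value per year.
#' @export
domain_annual <- function(cube, var = c("temperature", "precipitation",
                                        "cloud")) {
  var <- match.arg(var)
  arr <- cube[[var]]
  w <- cube$grid$cells$area_km2 / sum(cube$grid$cells$area_km2)
  annual_cell <- if (var == "precipitation") {
    apply(arr, c(1, 3), sum)
  } else {
    apply(arr, c(1, 3), mean)
  }
  as.numeric(crossprod(w, annual_cell))
}

#' Ordinary least-squares linear trend of an annual series
#'
#' @param series numeric values, one per year.
#' @param years numeric, same length, at least 3 distinct values.
#' @return list with `slope` (units/yr), `intercept`, `ci95` (length-2),
#'   `r_squared` (defined as 0 for a constant series), `p_value` (two-sided,
#'   `NA` for a perfect or constant fit where the error variance is 0),
#'   and `n_years`.
#' @export
#' @examples
#' fit_trend(0.1 * (1:50) + 3, 1:50)$slope
fit_trend <- function(series, years) {
  if (length(series) != length(years))
    stop("series and years must have equal length", call. = FALSE)
  if (length(series) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(years) == 0)
    stop("years have zero variance", call. = FALSE)
  fit <- stats::lm(series ~ years)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a perfect-fit warning
  slope <- unname(stats::coef(fit)[2])
  if (stats::var(series) == 0) {
    return(list(slope = 0, intercept = unname(stats::coef(fit)[1]),
                ci95 = c(0, 0), r_squared = 0, p_value = NA_real_,
                n_years = length(years)))
  }
  ci <- unname(suppressWarnings(stats::confint(fit, "years", level = 0.95)))
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       ci95 = as.numeric(ci), r_squared = sm$r.squared,
       p_value = sm$coefficients["years", "Pr(>|t|)"],
       n_years = length(years))
}
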