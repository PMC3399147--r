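# Reduced-form LPJ-style gridcell simulator.
#
# All surrogate process equations live in this file. The model keeps, per
# PFT and grid cell, an average-individual state (carbon pools, allometric
# dimensions, population density) and derives foliage projective cover
# (FPC) from crown area, density and Lambert-Beer light extinction. The
# annual loop is: bioclimatic gating -> production -> allocation/allometry
# -> mortality -> establishment -> cover constraints.

#' Individual foliage projective cover from the Lambert-Beer law
#'
#' `1 - exp(-k_beer * lai)`: the fraction of ground under an individual's
#' crown that its foliage shades, given the individual leaf-area index.
#'
#' @param lai individual leaf-area index, >= 0.
#' @param k_beer light extinction coefficient, > 0.
#' @return fraction in `[0, 1)`, monotone in both arguments.
#' @export
#' @examples
#' lambert_beer_fpc(2, 0.5)  # 1 - exp(-1)
lambert_beer_fpc <- function(lai, k_beer) {
  if (any(lai < 0)) stop("lai must be non-negative", call. = FALSE)
  stopifnot(k_beer > 0)
  1 - exp(-k_beer * lai)
}

#' Allometric dimensions of an average woody individual
#'
#' Stem (sapwood + heartwood) carbon is converted to stem volume through
#' wood density and to diameter through a cylindrical stem of height
#' `k_allom2 * diameter^k_allom3`. Crown area follows the power law
#' `k_allom1 * diameter^k_rp`, capped at `CA_max`. Leaf area is limited by
#' the sapwood cross-sectional area through the leaf-to-sapwood-area ratio
#' `k_la_sa`, and the individual LAI is leaf area over crown area.
#'
#' @param pools list or named numeric with `leaf`, `sapwood`, `heartwood`
#'   (kgC per individual); roots do not enter the allometry.
#' @param params named numeric of sampled parameters (uses `k_allom1`,
#'   `k_allom3`, `k_rp`, `k_la_sa`, `CA_max`).
#' @param pft one per-PFT config entry (uses `k_allom2`, `sla`,
#'   `wood_density`); woody PFTs only.
#' @return list with `height` (m), `crown_area` (m2), `diameter` (m),
#'   `lai` (individual leaf-area index).
#' @export
update_allometry <- function(pools, params, pft) {
  leaf <- pools[["leaf"]]
  sap <- pools[["sapwood"]]
  heart <- pools[["heartwood"]]
  stopifnot(leaf >= 0, sap >= 0, heart >= 0)
  stem <- sap + heart
  if (stem <= 0) {
    if (leaf > 0)
      stop("positive leaf mass with zero stem: no crown to carry it",
           call. = FALSE)
    return(list(height = 0, crown_area = 0, diameter = 0, lai = 0))
  }
  vol <- stem / pft$wood_density
  d <- (4 * vol / (pi * pft$k_allom2))^(1 / (2 + params[["k_allom3"]]))
  h <- pft$k_allom2 * d^params[["k_allom3"]]
  crown <- min(params[["k_allom1"]] * d^params[["k_rp"]], params[["CA_max"]])
  if (crown <= 0 && leaf > 0)
    stop("zero crown area with positive leaf mass", call. = FALSE)
  sap_area <- (sap / stem) * (pi / 4) * d^2
  leaf_area <- min(leaf * pft$sla, params[["k_la_sa"]] * sap_area)
  list(height = h, crown_area = crown, diameter = d,
       lai = if (crown > 0) leaf_area / crown else 0)
}

#' Annual gross and net primary production of one PFT
#'
#' Light-use-efficiency surrogate with non-rectangular-hyperbola
#' colimitation. The light-limited rate is
#' `J_E = alpha_C3 * sum_m APAR_m * f_temp_m`, with APAR from a seasonal
#' solar geometry proxy attenuated by cloud cover and scaled by the PFT's
#' foliage cover. The capacity-limited rate is
#' `J_C = vcap * f_CO2(co2) * w(P)`, with a saturating CO2 response equal
#' to 1 at the reference concentration and an annual water scalar
#' `w = min(1, P * wue / demand)` whose water-use efficiency factor also
#' rises with CO2. Gross production is `alpha_a` times the smaller root of
#' `theta x^2 - (J_E + J_C) x + J_E J_C = 0`; net production subtracts
#' maintenance respiration (proportional to live biomass) and growth
#' respiration (`r_growth` per unit NPP), floored at zero.
#'
#' @param cell_climate list with monthly `temp` (degC), `prec` (mm),
#'   `cloud` (fraction), and the cell `lat` (degrees).
#' @param co2 atmospheric CO2, ppmv.
#' @param params named numeric of sampled parameters (uses `theta`,
#'   `alpha_a`, `alpha_C3`, `r_growth`).
#' @param pft per-PFT config entry.
#' @param fpc the PFT's current foliage projective cover in the cell.
#' @param live_biomass live carbon per m2 ground subject to maintenance
#'   respiration (kgC/m2).
#' @param constants surrogate constants, `default_pft_config()$constants`.
#' @return list with `gpp`, `npp` (kgC/m2 ground/yr), `je`, `jc`, and the
#'   water scalar `w`.
#' @export
annual_production <- function(cell_climate, co2, params, pft, fpc,
                              live_biomass = 0,
                              constants = default_pft_config()$constants) {
  theta <- params[["theta"]]
  if (theta <= 0 || theta > 1)
    stop("theta must lie in (0, 1]", call. = FALSE)
  stopifnot(fpc >= 0, fpc <= 1, co2 > 0)
  temp <- cell_climate$temp
  f_ramp <- pmin(1, pmax(0, temp / constants$f_temp_scale))
  f_temp <- if (pft$phenology %in% c("summergreen", "grass"))
    f_ramp * (temp > 5) else f_ramp
  par_m <- (constants$par_full / 12) *
    solar_rel(cell_climate$lat) *
    (1 - constants$cloud_attenuation * cell_climate$cloud)
  je_unit <- params[["alpha_C3"]] * sum(par_m * f_temp) * 0.012011
  p_ann <- sum(cell_climate$prec)
  wue <- (co2 / constants$co2_ref)^constants$wue_exp
  demand <- constants$demand_base +
    constants$demand_per_degC * max(0, max(temp))
  w <- min(1, p_ann * wue / demand)
  K <- constants$co2_half_sat
  f_co2 <- (co2 / (co2 + K)) * ((constants$co2_ref + K) / constants$co2_ref)
  jc_unit <- constants$vcap * f_co2 * w
  s <- je_unit + jc_unit
  phi <- if (s > 0) (s - sqrt(s^2 - 4 * theta * je_unit * jc_unit)) /
    (2 * theta) else 0
  gpp <- params[["alpha_a"]] * phi * fpc
  r_maint <- pft$maint_resp_coeff * live_biomass * mean(f_ramp)
  npp <- max(0, gpp - r_maint) * (1 - params[["r_growth"]])
  list(gpp = gpp, npp = npp, je = je_unit * fpc, jc = jc_unit * fpc, w = w)
}

# Noon-sun elevation proxy per month: cos(lat - declination), floored at 0.
# Captures both day length and sun angle well enough for a latitude- and
# season-dependent PAR weighting.
solar_rel <- function(lat) {
  m <- seq_len(12)
  delta <- -23.44 * cos(2 * pi * (m - 0.5) / 12)
  pmax(0, cos((lat - delta) * pi / 180))
}

#' Empty (bare-ground) grid-cell state
#'
#' @param cfg a [default_pft_config()].
#' @return object of class `gridcell_state`: per-PFT numeric vectors
#'   `density` (individuals/m2; 1 for an established grass sward), carbon
#'   pools `leaf`, `sapwood`, `heartwood`, `root` (kgC per individual for
#'   woody PFTs, kgC/m2 for grass), allometry `height`, `diameter`,
#'   `crown_area`, `lai`, cover `fpc`, growth efficiency `greff`, and the
#'   scalar `bare` fraction.
#' @export
new_gridcell_state <- function(cfg = default_pft_config()) {
  n <- length(cfg$ids)
  z <- stats::setNames(numeric(n), cfg$ids)
  structure(list(ids = cfg$ids,
                 woody = vapply(cfg$pfts, function(p) isTRUE(p$woody),
                                logical(1)),
                 density = z, leaf = z, sapwood = z, heartwood = z, root = z,
                 height = z, diameter = z, crown_area = z, lai = z,
                 fpc = z, greff = z, bare = 1),
            class = "gridcell_state")
}

#' @export
print.gridcell_state <- function(x, ...) {
  cat("gridcell_state; fpc:\n")
  print(round(x$fpc, 4))
  cat("bare:", round(x$bare, 4), "\n")
  invisible(x)
}

# Recompute fpc of one PFT from its pools/density; used by every step.
pft_fpc <- function(state, i, params, cfg) {
  kb <- params[["k_beer"]]
  if (state$woody[i]) {
    if (state$density[i] <= 0) return(0)
    min(1, state$density[i] * state$crown_area[i] *
          lambert_beer_fpc(state$lai[i], kb))
  } else {
    lambert_beer_fpc(state$leaf[i] * cfg$pfts[[i]]$sla, kb)
  }
}

refresh_allometry <- function(state, i, params, cfg) {
  if (state$woody[i]) {
    al <- update_allometry(list(leaf = state$leaf[i],
                                sapwood = state$sapwood[i],
                                heartwood = state$heartwood[i]),
                           params, cfg$pfts[[i]])
    state$height[i] <- al$height
    state$diameter[i] <- al$diameter
    state$crown_area[i] <- al$crown_area
    state$lai[i] <- al$lai
  } else {
    state$lai[i] <- state$leaf[i] * cfg$pfts[[i]]$sla
  }
  state$fpc[i] <- pft_fpc(state, i, params, cfg)
  state
}

#' Population mortality step
#'
#' The background fractional loss rate is
#' `k_mort1 / (1 + k_mort2 * greff)`: it attains the asymptotic maximum
#' `k_mort1` at zero growth efficiency and declines toward zero for
#' vigorously growing populations. Heat-stressed PFTs incur the additional
#' configured rate, and PFTs whose survival bioclimatic limits have failed
#' are removed outright. FPC never increases in this step.
#'
#' @param state a `gridcell_state`.
#' @param params named numeric of sampled parameters.
#' @param heat_stressed logical per PFT: warmest month above `tw_max` this
#'   year.
#' @param survive_ok logical per PFT from the running-mean bioclimatic
#'   survival test; `FALSE` removes the PFT.
#' @param cfg PFT configuration.
#' @return updated `gridcell_state`.
#' @export
mortality <- function(state, params, heat_stressed,
                      survive_ok = rep(TRUE, length(state$ids)),
                      cfg = default_pft_config()) {
  k1 <- params[["k_mort1"]]
  k2 <- params[["k_mort2"]]
  extra <- cfg$constants$heat_mort_rate
  for (i in seq_along(state$ids)) {
    if (!survive_ok[i]) {
      state$density[i] <- 0
      state$leaf[i] <- state$sapwood[i] <- state$heartwood[i] <-
        state$root[i] <- 0
      state$height[i] <- state$diameter[i] <- state$crown_area[i] <-
        state$lai[i] <- state$fpc[i] <- 0
      next
    }
    if (state$fpc[i] <= 0) next
    rate <- min(1, k1 / (1 + k2 * state$greff[i]) +
                  if (heat_stressed[i]) extra else 0)
    if (state$woody[i]) {
      state$density[i] <- state$density[i] * (1 - rate)
    } else {
      state$leaf[i] <- state$leaf[i] * (1 - rate)
      state$root[i] <- state$root[i] * (1 - rate)
    }
    state <- refresh_allometry(state, i, params, cfg)
  }
  state$bare <- max(0, 1 - sum(state$fpc))
  state
}

#' Sapling and grass establishment step
#'
#' Each woody PFT whose establishment bioclimatic window is open gains
#' `est_max * (1 - sum of woody FPC)` saplings per m2, further attenuated
#' linearly from 1 at a woody cover of 0.95 to 0 at full canopy closure.
#' Saplings enter with the configured initial pools and are merged into
#' the average individual. Permitted grass gains seed biomass proportional
#' to `est_max` and to the fraction not under woody cover. FPC never
#' decreases in this step.
#'
#' @param state a `gridcell_state`.
#' @param params named numeric of sampled parameters (uses `est_max` among
#'   others through the allometry refresh).
#' @param establish_ok logical per PFT.
#' @param cfg PFT configuration.
#' @return updated `gridcell_state`.
#' @export
establishment <- function(state, params, establish_ok,
                          cfg = default_pft_config()) {
  cst <- cfg$constants
  fpc_woody <- sum(state$fpc[state$woody])
  atten <- if (fpc_woody <= 0.95) 1 else max(0, (1 - fpc_woody) / 0.05)
  open_woody <- which(state$woody & establish_ok)
  space <- max(0, 1 - fpc_woody)
  est_each <- params[["est_max"]] * space * atten
  if (length(open_woody) > 0 && est_each > 0) {
    for (i in open_woody) {
      d0 <- state$density[i]
      d1 <- d0 + est_each
      state$leaf[i] <- (d0 * state$leaf[i] + est_each * cst$sapling_leaf) / d1
      state$sapwood[i] <- (d0 * state$sapwood[i] +
                             est_each * cst$sapling_sap) / d1
      state$heartwood[i] <- d0 * state$heartwood[i] / d1
      state$root[i] <- (d0 * state$root[i] + est_each * cst$sapling_root) / d1
      state$density[i] <- d1
      fpc_before <- state$fpc[i]
      state <- refresh_allometry(state, i, params, cfg)
      # net effect of establishment is always a marginal increase in cover
      state$fpc[i] <- max(state$fpc[i], fpc_before)
    }
  }
  grass <- which(!state$woody & establish_ok)
  for (i in grass) {
    seed <- cst$grass_seed_scale * params[["est_max"]] *
      max(0, 1 - sum(state$fpc[state$woody]))
    if (seed <= 0) next
    state$leaf[i] <- state$leaf[i] + seed
    state$root[i] <- state$root[i] + seed
    state$density[i] <- 1
    state <- refresh_allometry(state, i, params, cfg)
  }
  state$bare <- max(0, 1 - sum(state$fpc))
  state
}

#' Enforce the cover constraints of a grid cell
#'
#' If total FPC exceeds 1, herbaceous cover (and biomass, proportionally)
#' is reduced first, reflecting the competitive dominance of taller woody
#' PFTs; if the woody sum alone still exceeds 1, every woody PFT's cover
#' and density are rescaled by the same factor. Afterwards the bare
#' fraction is `1 - sum(fpc)`.
#'
#' @param state a `gridcell_state`.
#' @param params named numeric of sampled parameters.
#' @param cfg PFT configuration.
#' @return updated `gridcell_state` with `sum(fpc) <= 1`.
#' @export
enforce_fpc_constraints <- function(state, params = NULL,
                                    cfg = default_pft_config()) {
  fpc_woody <- sum(state$fpc[state$woody])
  fpc_grass <- sum(state$fpc[!state$woody])
  if (fpc_woody + fpc_grass > 1) {
    allowed <- max(0, 1 - fpc_woody)
    if (fpc_grass > 0) {
      shrink <- allowed / fpc_grass
      gi <- which(!state$woody)
      state$fpc[gi] <- state$fpc[gi] * shrink
      state$leaf[gi] <- state$leaf[gi] * shrink
      state$root[gi] <- state$root[gi] * shrink
      state$lai[gi] <- state$lai[gi] * shrink
    }
  }
  fpc_woody <- sum(state$fpc[state$woody])
  if (fpc_woody > 1) {
    wi <- which(state$woody)
    state$fpc[wi] <- state$fpc[wi] / fpc_woody
    state$density[wi] <- state$density[wi] / fpc_woody
  }
  state$bare <- max(0, 1 - sum(state$fpc))
  state
}

# Allocation and growth: distribute this year's NPP to pools, apply
# turnover, refresh allometry and cover. Internal (the "allocation /
# allometry" stage of the annual loop).
grow_state <- function(state, i, npp_ground, params, cfg) {
  p <- cfg$pfts[[i]]
  cst <- cfg$constants
  if (state$woody[i]) {
    if (state$density[i] <= 0) return(state)
    npp_ind <- npp_ground / state$density[i]
    state$leaf[i] <- state$leaf[i] * (1 - p$leaf_turnover) +
      cst$alloc_leaf * npp_ind
    state$root[i] <- state$root[i] * (1 - p$root_turnover) +
      cst$alloc_root * npp_ind
    moved <- p$sap_turnover * state$sapwood[i]
    state$sapwood[i] <- state$sapwood[i] - moved + cst$alloc_sap * npp_ind
    state$heartwood[i] <- state$heartwood[i] + moved
  } else {
    if (state$density[i] <= 0) return(state)
    state$leaf[i] <- state$leaf[i] * (1 - p$leaf_turnover) + 0.5 * npp_ground
    state$root[i] <- state$root[i] * (1 - p$root_turnover) + 0.5 * npp_ground
  }
  refresh_allometry(state, i, params, cfg)
}

live_biomass_ground <- function(state, i) {
  if (state$woody[i]) {
    state$density[i] * (state$leaf[i] + state$sapwood[i] + state$root[i])
  } else {
    state$leaf[i] + state$root[i]
  }
}

leaf_area_ground <- function(state, i, cfg) {
  if (state$woody[i]) {
    state$density[i] * state$leaf[i] * cfg$pfts[[i]]$sla
  } else {
    state$leaf[i] * cfg$pfts[[i]]$sla
  }
}

#' Simulation run configuration
#'
#' @param spinup_years length of the cyclic-climatology spin-up from bare
#'   ground (200 years by default at desk scale).
#' @param record_spinup also return the spin-up FPC trajectory.
#' @param audit record, per year, the worst violation of the step
#'   directionality rules (establishment non-decreasing, mortality
#'   non-increasing in FPC) and of cover conservation; exact zeros are
#'   expected.
#' @param equilibrium_window,equilibrium_tol the spin-up equilibrium check:
#'   relative change of total FPC across the final window.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(spinup_years = 200, record_spinup = FALSE,
                       audit = FALSE, equilibrium_window = 30,
                       equilibrium_tol = 1e-3) {
  structure(list(spinup_years = spinup_years, record_spinup = record_spinup,
                 audit = audit, equilibrium_window = equilibrium_window,
                 equilibrium_tol = equilibrium_tol),
            class = "sim_config")
}

#' Extract one cell's climate from a cube
#'
#' @param cube a `climate_cube`.
#' @param i cell index into `cube$grid$cells`.
#' @return list with `temp`, `prec`, `cloud` (12 x years matrices), `co2`
#'   (per year), `years`, and `lat`.
#' @export
extract_cell <- function(cube, i) {
  list(temp = cube$temperature[i, , , drop = TRUE],
       prec = cube$precipitation[i, , , drop = TRUE],
       cloud = cube$cloud[i, , , drop = TRUE],
       co2 = cube$co2, years = cube$years,
       lat = cube$grid$cells$lat[i])
}

#' Run the simulator for one grid cell
#'
#' Starts from bare ground, spins up under cyclic replication of the first
#' 30 years of the supplied climate (CO2 held at the first year's value),
#' then runs the transient years. The annual loop is bioclimatic gating ->
#' production -> allocation/allometry -> mortality -> establishment ->
#' cover constraints; the run is fully deterministic.
#'
#' @param params named numeric vector of the 13 sampled parameters (see
#'   [default_parameter_table()]).
#' @param cell_climate from [extract_cell()].
#' @param cfg PFT configuration.
#' @param config a [sim_config()].
#' @return list with `fpc` (years x PFT matrix for the transient period),
#'   `years`, `final_state`, `equilibrium` (logical + relative change), and
#'   when auditing, `audit` (worst step-directionality violations; 0 means
#'   none) plus optionally `fpc_spinup`.
#' @export
run_gridcell <- function(params, cell_climate, cfg = default_pft_config(),
                         config = sim_config()) {
  tm <- cell_climate$temp
  if (anyNA(tm) || anyNA(cell_climate$prec) || anyNA(cell_climate$cloud))
    stop("NaN in climate input for cell at lat ", cell_climate$lat,
         call. = FALSE)
  ny <- ncol(tm)
  n_spin_block <- min(30L, ny)
  W <- cfg$constants$bioclim_window
  n <- length(cfg$ids)
  state <- new_gridcell_state(cfg)
  # running climate summary buffer (tc, tw, gdd5 for the last W years)
  buf <- matrix(NA_real_, 3, 0)
  fpc_out <- matrix(0, ny, n, dimnames = list(cell_climate$years, cfg$ids))
  fpc_spin <- if (config$record_spinup)
    matrix(0, config$spinup_years, n) else NULL
  spin_total <- numeric(config$spinup_years)
  audit <- c(establishment = 0, mortality = 0, cover = 0)

  step_year <- function(state, temp, prec, cloud, co2, buf) {
    s <- climate_year_summary(temp)
    buf <- cbind(buf, c(s$tc, s$tw, s$gdd5))
    if (ncol(buf) > W) buf <- buf[, -1, drop = FALSE]
    mu <- rowMeans(buf)
    bio <- bioclim_allows_all(cfg, mu[1], mu[2], mu[3])
    heat <- vapply(cfg$pfts, function(p) s$tw > p$tw_max, logical(1))
    clim <- list(temp = temp, prec = prec, cloud = cloud,
                 lat = cell_climate$lat)
    # production + allocation/allometry
    for (i in seq_len(n)) {
      if (state$density[i] <= 0 && state$fpc[i] <= 0) next
      pr <- annual_production(clim, co2, params, cfg$pfts[[i]],
                              state$fpc[i], live_biomass_ground(state, i),
                              cfg$constants)
      la <- leaf_area_ground(state, i, cfg)
      state$greff[i] <- if (la > 0) pr$npp / la else 0
      state <- grow_state(state, i, pr$npp, params, cfg)
    }
    f0 <- state$fpc
    state <- mortality(state, params, heat, bio$survive, cfg)
    if (config$audit)
      audit["mortality"] <<- max(audit["mortality"], max(state$fpc - f0))
    f1 <- state$fpc
    state <- establishment(state, params, bio$establish, cfg)
    if (config$audit)
      audit["establishment"] <<- max(audit["establishment"],
                                     max(f1 - state$fpc))
    state <- enforce_fpc_constraints(state, params, cfg)
    if (config$audit)
      audit["cover"] <<- max(audit["cover"], sum(state$fpc) - 1,
                             abs(state$bare - (1 - sum(state$fpc))))
    list(state = state, buf = buf)
  }

  for (y in seq_len(config$spinup_years)) {
    iy <- ((y - 1) %% n_spin_block) + 1
    res <- step_year(state, tm[, iy], cell_climate$prec[, iy],
                     cell_climate$cloud[, iy], cell_climate$co2[[1]], buf)
    state <- res$state
    buf <- res$buf
    spin_total[y] <- sum(state$fpc)
    if (config$record_spinup) fpc_spin[y, ] <- state$fpc
  }
  for (y in seq_len(ny)) {
    res <- step_year(state, tm[, y], cell_climate$prec[, y],
                     cell_climate$cloud[, y], cell_climate$co2[[y]], buf)
    state <- res$state
    buf <- res$buf
    fpc_out[y, ] <- state$fpc
  }
  wlen <- min(config$equilibrium_window, config$spinup_years - 1)
  eq_change <- if (wlen > 0 && config$spinup_years > wlen) {
    recent <- spin_total[(config$spinup_years - wlen):config$spinup_years]
    if (max(recent) > 0) diff(range(recent)) / max(recent) else 0
  } else NA_real_
  out <- list(fpc = fpc_out, years = cell_climate$years,
              final_state = state,
              equilibrium = list(reached = isTRUE(eq_change <=
                                                    config$equilibrium_tol),
                                 rel_change = eq_change))
  if (config$audit) out$audit <- audit
  if (config$record_spinup) out$fpc_spinup <- fpc_spin
  out
}

#' Run the simulator over every cell of a climate cube
#'
#' @param params named numeric vector of the 13 sampled parameters.
#' @param cube a `climate_cube`.
#' @param cfg PFT configuration.
#' @param config a [sim_config()].
#' @return object of class `simulation_result`: list with `fpc` (array
#'   cell x year x PFT), `years`, `grid`, `pft_ids`, and per-cell
#'   `equilibrium` flags (and `audit`, the elementwise-worst step
#'   violations over cells, when auditing).
#' @export
run_simulation <- function(params, cube, cfg = default_pft_config(),
                           config = sim_config()) {
  nc <- cube$grid$n_cells
  ny <- length(cube$years)
  n <- length(cfg$ids)
  fpc <- array(0, c(nc, ny, n),
               dimnames = list(NULL, cube$years, cfg$ids))
  eq <- logical(nc)
  audit <- c(establishment = 0, mortality = 0, cover = 0)
  for (i in seq_len(nc)) {
    r <- run_gridcell(params, extract_cell(cube, i), cfg, config)
    fpc[i, , ] <- r$fpc
    eq[i] <- isTRUE(r$equilibrium$reached)
    if (config$audit) audit <- pmax(audit, r$audit)
  }
  out <- structure(list(fpc = fpc, years = cube$years, grid = cube$grid,
                        pft_ids = cfg$ids, equilibrium = eq,
                        scenario = cube$scenario),
                   class = "simulation_result")
  if (config$audit) out$audit <- audit
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %d cells x %d years x %d PFTs%s\n",
              dim(x$fpc)[1], dim(x$fpc)[2], dim(x$fpc)[3],
              if (!is.null(x$scenario)) paste0(" (", x$scenario, ")") else ""))
  invisible(x)
}
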