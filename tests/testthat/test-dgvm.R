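cfg <- default_pft_config()
pars <- standard_parameters()

test_that("PFT configuration is complete and well-formed", {
  expect_length(cfg$pfts, 6L)
  expect_setequal(cfg$ids, c("TNE", "TBE", "TBS", "BNE", "BSW", "CPG"))
  expect_false(cfg$pfts$CPG$woody)
  expect_equal(sum(vapply(cfg$pfts, function(p) isTRUE(p$woody),
                          logical(1))), 5L)
  expect_equal(cfg$pfts$TBS$phenology, "summergreen")
})

test_that("Lambert-Beer cover follows the closed form", {
  expect_equal(lambert_beer_fpc(0, 0.5), 0)
  expect_equal(lambert_beer_fpc(2, 0.5), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(lambert_beer_fpc(1e6, 0.5), 1)
  expect_error(lambert_beer_fpc(-1, 0.5), "non-negative")
  lais <- seq(0, 10, by = 0.5)
  expect_true(all(diff(lambert_beer_fpc(lais, 0.5)) > 0))
  expect_true(all(lambert_beer_fpc(lais, 0.7) >=
                    lambert_beer_fpc(lais, 0.4)))
})

test_that("bioclimatic limits gate establishment and survival", {
  bne <- cfg$pfts$BNE
  cold <- bioclim_allows(bne, list(tc = bne$tc_min_est - 1, tw = 15,
                                   gdd5 = 700))
  expect_false(cold$establish)
  open <- list(tc = -20, tw = 15, gdd5 = 700)
  expect_true(bioclim_allows(bne, open)$establish)
  expect_true(bioclim_allows(bne, open)$survive)
  # all-infinite limits always allow
  anyp <- bne
  anyp$tc_min_est <- -Inf; anyp$tc_max_est <- Inf
  anyp$gdd5_min <- 0; anyp$tw_max <- Inf; anyp$tc_surv <- -Inf
  expect_true(all(unlist(bioclim_allows(anyp, list(tc = -60, tw = 40,
                                                   gdd5 = 0)))))
  # a warming series crossing tw_max flips survival in the crossing year
  tws <- seq(20, 26, by = 0.5)
  surv <- vapply(tws, function(tw)
    bioclim_allows(bne, list(tc = -20, tw = tw, gdd5 = 700))$survive,
    logical(1))
  expect_equal(surv, tws <= bne$tw_max)
})

test_that("annual production obeys its analytic limits", {
  clim <- list(temp = c(-20, -15, -8, 0, 6, 12, 16, 14, 8, 1, -8, -16),
               prec = rep(40, 12), cloud = rep(0.5, 12), lat = 57.5)
  p0 <- pars
  p0["alpha_C3"] <- 0
  expect_equal(annual_production(clim, 370, p0, cfg$pfts$BNE, 0.5, 0,
                                 cfg$constants)$npp, 0)
  # theta = 1 makes colimitation exactly min(J_E, J_C)
  p1 <- pars
  p1["theta"] <- 1
  out <- annual_production(clim, 370, p1, cfg$pfts$BNE, 1, 0, cfg$constants)
  expect_equal(out$gpp, unname(p1["alpha_a"]) * min(out$je, out$jc),
               tolerance = 1e-10)
  # theta outside (0, 1] is rejected
  pbad <- pars
  pbad["theta"] <- 1.2
  expect_error(annual_production(clim, 370, pbad, cfg$pfts$BNE, 0.5, 0,
                                 cfg$constants), "theta")
  pbad["theta"] <- 0
  expect_error(annual_production(clim, 370, pbad, cfg$pfts$BNE, 0.5, 0,
                                 cfg$constants), "theta")
})

test_that("NPP responds monotonically to CO2", {
  clim <- list(temp = c(-20, -15, -8, 0, 6, 12, 16, 14, 8, 1, -8, -16),
               prec = rep(30, 12), cloud = rep(0.5, 12), lat = 57.5)
  set.seed(42)
  specs <- default_parameter_table(quiet = TRUE)
  draws <- lhs_sample(specs, 20, seed = 8)$values
  for (s in seq_len(nrow(draws))) {
    p <- draws[s, ]
    for (pft in cfg$pfts) {
      lo <- annual_production(clim, 370, p, pft, 0.6, 1, cfg$constants)$npp
      hi <- annual_production(clim, 740, p, pft, 0.6, 1, cfg$constants)$npp
      expect_gte(hi, lo)
    }
  }
})

test_that("woody allometry is consistent and the crown cap binds", {
  bne <- cfg$pfts$BNE
  z <- update_allometry(list(leaf = 0, sapwood = 0, heartwood = 0), pars,
                        bne)
  expect_equal(unlist(z), c(height = 0, crown_area = 0, diameter = 0,
                            lai = 0))
  # independent closed-form check of the diameter/height chain
  pools <- list(leaf = 2, sapwood = 40, heartwood = 60)
  al <- update_allometry(pools, pars, bne)
  vol <- (40 + 60) / bne$wood_density
  d <- (4 * vol / (pi * bne$k_allom2))^(1 / (2 + pars[["k_allom3"]]))
  expect_equal(al$diameter, d, tolerance = 1e-12)
  expect_equal(al$height, bne$k_allom2 * d^pars[["k_allom3"]],
               tolerance = 1e-12)
  expect_equal(al$crown_area,
               min(pars[["k_allom1"]] * d^pars[["k_rp"]], pars[["CA_max"]]))
  # a large stem drives the crown into the CA_max cap
  big <- update_allometry(list(leaf = 5, sapwood = 200, heartwood = 800),
                          pars, bne)
  expect_equal(big$crown_area, unname(pars[["CA_max"]]))
  # doubling the cap (un-binding crown area) halves lai at fixed leaf area
  p2 <- pars
  p2["CA_max"] <- 2 * pars[["CA_max"]]
  big2 <- update_allometry(list(leaf = 5, sapwood = 200, heartwood = 800),
                           p2, bne)
  if (big2$crown_area == unname(p2["CA_max"]))
    expect_equal(big2$lai, big$lai / 2, tolerance = 1e-12)
  expect_error(update_allometry(list(leaf = 1, sapwood = 0, heartwood = 0),
                                pars, bne), "stem")
})

test_that("leaf area is capped by sapwood area through k_la_sa", {
  bne <- cfg$pfts$BNE
  al_lo <- update_allometry(list(leaf = 50, sapwood = 10, heartwood = 10),
                            pars, bne)
  p_hi <- pars
  p_hi["k_la_sa"] <- 8000
  al_hi <- update_allometry(list(leaf = 50, sapwood = 10, heartwood = 10),
                            p_hi, bne)
  expect_gt(al_hi$lai, al_lo$lai)  # cap was binding at k_la_sa = 4000
})

test_that("establishment fills space and respects canopy-closure decline", {
  st <- new_gridcell_state(cfg)
  ok <- rep(TRUE, 6)
  # bare cell: every permitted woody PFT gains est_max saplings
  st1 <- establishment(st, pars, ok, cfg)
  woody <- which(st1$woody)
  expect_equal(unname(st1$density[woody]),
               rep(unname(pars["est_max"]), 5))
  expect_true(all(st1$fpc[woody] > 0))
  expect_state_valid(st1)
  # closed canopy: no woody establishment
  st_closed <- st1
  st_closed$fpc[] <- 0
  st_closed$fpc[woody[1]] <- 1
  d0 <- st_closed$density
  st2 <- establishment(st_closed, pars, ok, cfg)
  expect_equal(st2$density[woody[1]], d0[woody[1]])
  # at woody cover 0.975 the rate is half the unattenuated rate
  st_part <- st1
  st_part$fpc[] <- 0
  st_part$fpc[woody[1]] <- 0.975
  st3 <- establishment(st_part, pars, ok, cfg)
  gain <- st3$density[woody[2]] - st_part$density[woody[2]]
  expect_equal(unname(gain), unname(pars["est_max"] * (1 - 0.975) * 0.5),
               tolerance = 1e-12)
})

test_that("mortality follows the growth-efficiency relation", {
  st <- new_gridcell_state(cfg)
  st <- establishment(st, pars, rep(TRUE, 6), cfg)
  # greff = 0: loss rate is exactly k_mort1
  st$greff[] <- 0
  d0 <- st$density
  stm <- mortality(st, pars, heat_stressed = rep(FALSE, 6),
                   survive_ok = rep(TRUE, 6), cfg = cfg)
  woody <- which(st$woody)
  expect_equal(unname(stm$density[woody] / d0[woody]),
               rep(1 - unname(pars["k_mort1"]), 5), tolerance = 1e-12)
  # k_mort1 = 0.05, k_mort2 = 0.5, greff = 2 -> rate 0.025
  st$greff[] <- 2
  stm2 <- mortality(st, pars, rep(FALSE, 6), rep(TRUE, 6), cfg)
  expect_equal(unname(stm2$density[woody[1]] / d0[woody[1]]),
               1 - 0.05 / (1 + 0.5 * 2), tolerance = 1e-12)
  # enormous growth efficiency: loss rate tends to zero
  st$greff[] <- 1e9
  stm3 <- mortality(st, pars, rep(FALSE, 6), rep(TRUE, 6), cfg)
  expect_equal(unname(stm3$density[woody[1]]), unname(d0[woody[1]]),
               tolerance = 1e-6)
  # heat stress adds the configured extra rate
  st$greff[] <- 0
  heat <- st$ids == "BNE"
  stm4 <- mortality(st, pars, heat, rep(TRUE, 6), cfg)
  i <- which(heat)
  expect_equal(unname(stm4$density[i] / d0[i]),
               1 - unname(pars["k_mort1"]) - cfg$constants$heat_mort_rate,
               tolerance = 1e-12)
  # survival failure removes the PFT outright
  surv <- rep(TRUE, 6); surv[i] <- FALSE
  stm5 <- mortality(st, pars, rep(FALSE, 6), surv, cfg)
  expect_equal(unname(stm5$density[i]), 0)
  expect_equal(unname(stm5$fpc[i]), 0)
})

test_that("mortality never raises cover; establishment never lowers it", {
  st <- new_gridcell_state(cfg)
  for (k in 1:12) {
    st <- establishment(st, pars, rep(TRUE, 6), cfg)
    f_before <- st$fpc
    st$greff[] <- stats::runif(6, 0, 2)
    stm <- mortality(st, pars, stats::runif(6) < 0.3,
                     stats::runif(6) > 0.05, cfg)
    expect_true(all(stm$fpc <= f_before + 1e-12))
    f_mid <- stm$fpc
    st <- establishment(stm, pars, stats::runif(6) > 0.2, cfg)
    expect_true(all(st$fpc >= f_mid - 1e-12))
    st <- enforce_fpc_constraints(st, pars, cfg)
    expect_state_valid(st)
  }
})

test_that("cover constraints reduce herbaceous cover first", {
  st <- new_gridcell_state(cfg)
  woody <- which(st$woody)
  grass <- which(!st$woody)
  # feasible state is untouched
  st$fpc[woody[1]] <- 0.7
  st$fpc[grass] <- 0.2
  expect_equal(enforce_fpc_constraints(st, pars, cfg)$fpc, st$fpc)
  # woody 0.95 + grass 0.15: grass cut to 0.05
  st$fpc[] <- 0
  st$fpc[woody[1]] <- 0.95
  st$fpc[grass] <- 0.15
  st$leaf[grass] <- 0.3
  out <- enforce_fpc_constraints(st, pars, cfg)
  expect_equal(unname(out$fpc[grass]), 0.05, tolerance = 1e-12)
  expect_equal(unname(out$fpc[woody[1]]), 0.95)
  expect_equal(unname(out$leaf[grass]), 0.3 * (0.05 / 0.15),
               tolerance = 1e-12)
  # woody alone above 1: grass to zero, woody rescaled proportionally
  st$fpc[] <- 0
  st$fpc[woody[1]] <- 0.6
  st$fpc[woody[2]] <- 0.5
  st$fpc[grass] <- 0.1
  out2 <- enforce_fpc_constraints(st, pars, cfg)
  expect_equal(unname(out2$fpc[grass]), 0)
  expect_equal(unname(out2$fpc[woody[1]]), 0.6 / 1.1, tolerance = 1e-12)
  expect_equal(unname(out2$fpc[woody[2]]), 0.5 / 1.1, tolerance = 1e-12)
  expect_equal(sum(out2$fpc), 1, tolerance = 1e-12)
})

test_that("a bare cell stays bare without establishment", {
  cube <- boreal_cell_climate(20)
  cc <- extract_cell(cube, 1)
  p0 <- pars
  p0["est_max"] <- 0
  r <- run_gridcell(p0, cc, cfg, quick_sim_config(spinup = 40))
  expect_true(all(r$fpc == 0))
  # and a climate violating every establishment window does the same
  frozen <- cc
  frozen$temp[] <- -40
  r2 <- run_gridcell(pars, frozen, cfg, quick_sim_config(spinup = 40))
  expect_true(all(r2$fpc == 0))
})

test_that("boreal forest assembles from bare ground under standard values", {
  cube <- boreal_cell_climate(30)
  r <- run_gridcell(pars, extract_cell(cube, 1), cfg,
                    sim_config(spinup_years = 150, audit = TRUE))
  expect_gt(r$fpc[30, "BNE"], 0)
  expect_gt(sum(r$fpc[30, ]), 0.5)          # vegetated, not marginal
  expect_true(all(r$audit < 1e-12))         # step directionality exact
  expect_true(all(rowSums(r$fpc) <= 1 + 1e-12))
  # deterministic: identical inputs give identical trajectories
  r2 <- run_gridcell(pars, extract_cell(cube, 1), cfg,
                     sim_config(spinup_years = 150))
  expect_identical(r$fpc, r2$fpc)
})

test_that("NaN climate is reported as a data error", {
  cube <- boreal_cell_climate(10)
  cc <- extract_cell(cube, 1)
  cc$temp[3, 5] <- NaN
  expect_error(run_gridcell(pars, cc, cfg, quick_sim_config(20)), "lat")
})

test_that("alpha_C3 has positive rank influence on woody cover", {
  # small LHS ensemble on one fixed boreal cell: the quantum-efficiency
  # parameter must come out with positive PRCC on mean woody FPC
  specs <- default_parameter_table(quiet = TRUE)
  n <- 40
  draws <- lhs_sample(specs, n, seed = 21)
  cube <- boreal_cell_climate(30)
  cc <- extract_cell(cube, 1)
  scfg <- sim_config(spinup_years = 80)
  y <- vapply(seq_len(n), function(s) {
    r <- run_gridcell(draws$values[s, ], cc, cfg, scfg)
    mean(r$fpc[, c("TNE", "TBE", "TBS", "BNE", "BSW")])
  }, numeric(1))
  pr <- prcc(draws, y, output_name = "mean woody FPC")
  expect_gt(pr$prcc[["alpha_C3"]], 0)
})
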