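test_that("the ten built-in scenarios carry the published configuration", {
  sc <- builtin_scenarios()
  expect_length(sc, 10L)
  fam <- vapply(sc, `[[`, character(1), "family")
  expect_equal(sum(fam == "IPCC-smooth"), 4L)
  expect_equal(sum(fam == "IGSM-latitude-amplified"), 6L)
  a1 <- sc$A1FI
  expect_equal(a1$temp_slope, 0.136)
  expect_equal(a1$precip_slope, 0.166)
  expect_equal(c(a1$co2_start, a1$co2_end), c(368.448, 925.531))
  # X905L is the weakest-warming scenario
  slopes <- vapply(sc, `[[`, numeric(1), "temp_slope")
  expect_equal(names(which.min(slopes)), "X905L")
  expect_equal(sc$X905L$temp_slope, 0.013)
  # IGSM scenario-name -> emission-group mapping
  expect_equal(sc$X901M$emission_group, "reference")
  expect_equal(sc$X903H$emission_group, "reference")
  expect_equal(sc$X904M$emission_group, "stabilization")
  expect_equal(sc$X905L$response_class, "low")
  expect_true(all(vapply(sc, function(s) s$co2_start < s$co2_end,
                         logical(1))))
})

test_that("zero-noise cubes reproduce configured trends exactly", {
  g <- grid_spec(res = 15)
  for (nm in c("A1FI", "B2", "X905L")) {
    spec <- builtin_scenarios()[[nm]]
    cube <- generate_scenario(spec, g, 2001:2100, seed = 1, noise = FALSE)
    ft <- fit_trend(domain_annual(cube, "temperature"), cube$years)
    fp <- fit_trend(domain_annual(cube, "precipitation"), cube$years)
    expect_equal(ft$slope, spec$temp_slope, tolerance = 1e-10)
    expect_equal(fp$slope, spec$precip_slope, tolerance = 1e-10)
    expect_gt(ft$r_squared, 1 - 1e-10)
  }
  # CO2 endpoints as configured
  cube <- generate_scenario(builtin_scenarios()$X902L, g, 2001:2100,
                            seed = 1, noise = FALSE)
  expect_equal(unname(cube$co2["2001"]), 371.228)
  expect_equal(unname(cube$co2["2100"]), 947.953)
})

test_that("a zero-slope scenario yields an exactly constant annual series", {
  g <- grid_spec(res = 15)
  spec <- scenario_spec("flat", 0, 0, 370, 371)
  cube <- generate_scenario(spec, g, 2001:2050, seed = 1, noise = FALSE)
  s <- domain_annual(cube, "temperature")
  expect_equal(max(s) - min(s), 0, tolerance = 1e-12)
})

test_that("IGSM warming is latitude-amplified, IPCC warming is not", {
  g <- grid_spec(res = 10)
  per_cell_rate <- function(cube) {
    vapply(seq_len(cube$grid$n_cells), function(i) {
      ann <- colMeans(cube$temperature[i, , ])
      fit_trend(ann, cube$years)$slope
    }, numeric(1))
  }
  igsm <- generate_scenario(builtin_scenarios()$X903H, g, 2001:2100,
                            seed = 1, noise = FALSE)
  ipcc <- generate_scenario(builtin_scenarios()$A2, g, 2001:2100,
                            seed = 1, noise = FALSE)
  lat <- g$cells$lat
  slope_igsm <- fit_trend(per_cell_rate(igsm), lat)$slope
  slope_ipcc <- fit_trend(per_cell_rate(ipcc), lat)$slope
  expect_gt(slope_igsm, 0)
  expect_equal(slope_ipcc, 0, tolerance = 1e-12)
  # amplification preserves the domain-mean trend exactly
  expect_equal(fit_trend(domain_annual(igsm, "temperature"), igsm$years)$slope,
               0.094, tolerance = 1e-10)
})

test_that("noisy cubes stay physical and are seed-reproducible", {
  g <- grid_spec(res = 10)
  spec <- builtin_scenarios()$A1FI
  a <- generate_scenario(spec, g, 2001:2040, seed = 9)
  b <- generate_scenario(spec, g, 2001:2040, seed = 9)
  c <- generate_scenario(spec, g, 2001:2040, seed = 10)
  expect_identical(a$temperature, b$temperature)
  expect_identical(a$precipitation, b$precipitation)
  expect_false(identical(a$temperature, c$temperature))
  expect_true(all(a$precipitation >= 0))
  expect_true(all(a$cloud >= 0 & a$cloud <= 1))
  expect_true(all(a$co2 > 0))
  # noisy 100-year trends land in the published R^2 neighbourhood
  full <- generate_scenario(spec, g, 2001:2100, seed = 3)
  ft <- fit_trend(domain_annual(full, "temperature"), full$years)
  expect_gt(ft$r_squared, 0.85)
})

test_that("generate_scenario rejects bad domains", {
  g <- grid_spec(res = 15)
  spec <- builtin_scenarios()$B1
  expect_error(generate_scenario(spec, g, 1899:2000, seed = 1), "1901")
  expect_error(grid_spec(res = 15, land = rep(FALSE, 9)), "land")
})

test_that("spin-up forcing cycles the first 30 years and flattens trends", {
  g <- grid_spec(res = 15)
  cube <- generate_scenario(builtin_scenarios()$A1FI, g, 2001:2040,
                            seed = 2, noise = FALSE)
  spin <- generate_spinup(cube, 60)
  expect_equal(spin$temperature[, , 31:60], spin$temperature[, , 1:30])
  expect_equal(unname(spin$co2), rep(unname(cube$co2[1]), 60))
  # strong within-block trend averages out over cycles
  long <- generate_spinup(cube, 150)
  sl <- fit_trend(domain_annual(long, "temperature"), long$years)$slope
  expect_lt(abs(sl), 0.02)  # vs 0.136/yr in the source block
  short <- generate_scenario(builtin_scenarios()$A1FI, g, 2001:2020,
                             seed = 2, noise = FALSE)
  expect_error(generate_spinup(short, 40), "30 years")
})

test_that("fit_trend recovers exact lines and handles degenerate input", {
  yrs <- 2001:2100
  exact <- fit_trend(0.136 * yrs + 3, yrs)
  expect_equal(exact$slope, 0.136, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  const <- fit_trend(rep(5, 10), 1:10)
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)
  expect_error(fit_trend(1:2, 1:2), "3 points")
  expect_error(fit_trend(1:5, rep(2, 5)), "variance")
})

test_that("fit_trend confidence intervals achieve nominal coverage", {
  true <- 0.05
  covered <- vapply(1:200, function(s) {
    set.seed(s)
    y <- true * (1:100) + rnorm(100, 0, 0.5)
    ci <- fit_trend(y, 1:100)$ci95
    ci[1] <= true && true <= ci[2]
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("grid areas follow the spherical formula", {
  # a 0.5 x 0.5 degree cell on the equator is about 3.09e3 km2
  expect_equal(cell_area_km2(0, 0.5, 0.5), 3092, tolerance = 1e-3)
  g <- grid_spec(res = 5)
  expect_true(all(diff(g$cells$area_km2[order(g$cells$lat)]) <= 1e-9))
  # land-masked study grid drops high-Arctic ocean rings
  sg <- study_grid(res = 5)
  expect_lt(max(sg$cells$lat), 88)
  expect_true(sum(sg$cells$area_km2) > 2.5e7 &&
                sum(sg$cells$area_km2) < 4.5e7)
})
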