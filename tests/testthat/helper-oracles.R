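# Independent brute-force oracles and small fixtures shared across tests.

# Partial correlation by explicit normal-equation solve: residuals of x_j
# and y on [1, X_{-j}] via solve(t(Z) %*% Z), then the plain correlation
# of the residuals. Deliberately a different code path from the package
# implementation (which uses QR).
oracle_partial_corr <- function(X, j, y) {
  Z <- cbind(1, X[, -j, drop = FALSE])
  beta_x <- solve(t(Z) %*% Z, t(Z) %*% X[, j])
  beta_y <- solve(t(Z) %*% Z, t(Z) %*% y)
  rx <- X[, j] - Z %*% beta_x
  ry <- y - Z %*% beta_y
  as.numeric(sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2)))
}

# Rank-transform then residual-correlate, column by column.
oracle_prcc <- function(X, y) {
  Xr <- apply(X, 2, rank)
  yr <- rank(y)
  vapply(seq_len(ncol(X)), function(j) oracle_partial_corr(Xr, j, yr),
         numeric(1))
}

# A tiny single-cell climate fixture: one boreal-like cell, constant
# (cyclically repeated) climate, n_years of transient forcing.
boreal_cell_climate <- function(n_years = 40, lat = 57.5, co2 = 370) {
  g <- grid_spec(lat_range = c(lat - 2.5, lat + 2.5),
                 lon_range = c(0, 5), res = 5)
  spec <- scenario_spec("flat", temp_slope = 0, precip_slope = 0,
                        co2_start = co2, co2_end = co2 + 1e-6,
                        family = "IPCC-smooth", emission_group = "ipcc")
  generate_scenario(spec, g, 2001:(2000 + n_years), seed = 1, noise = FALSE)
}

quick_sim_config <- function(spinup = 80) sim_config(spinup_years = spinup)

expect_state_valid <- function(state) {
  expect_true(all(state$fpc >= 0 & state$fpc <= 1))
  expect_lte(sum(state$fpc), 1 + 1e-12)
  expect_equal(state$bare, max(0, 1 - sum(state$fpc)), tolerance = 1e-12)
  expect_true(all(state$leaf >= 0 & state$sapwood >= 0 &
                    state$heartwood >= 0 & state$root >= 0))
}
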