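# shared fixtures and small utilities for the suite

# deterministic 3-lumen chain used for limit-equivalence checks
fixture_chain3 <- function(params) {
  L <- c(0.9, 1.1, 1.0)
  ell <- c(10, 9, 11, 10)
  x <- cumsum(ell[1:3] + L) + c(0, cumsum(L[-3]))
  chain_state(x, L, params = params, L_sys = x[3] + L[3] + ell[4])
}

# ensemble-averaged coarsening exponent with the fixed window rule used
# throughout: bins where the mean count has at least halved but >= n_low
# lumens remain
fit_exponent <- function(trajs, n0, n_low = 5, n_bins = 60) {
  ser <- lumen_count_series(trajs, n_bins = n_bins)
  win <- range(ser$time[ser$n_mean <= n0 / 2 & ser$n_mean >= n_low])
  fit_power_law(ser, win)
}

# time at which a realization first reaches half its initial lumen count
half_count_time <- function(tr) {
  cc <- lumen_count(tr)
  cc$time[which(cc$n <= tr$n0 / 2)[1]]
}

# relative difference helper
rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-300)

expect_close <- function(object, expected, tol) {
  expect_lt(max(rel_err(object, expected)), tol)
}
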