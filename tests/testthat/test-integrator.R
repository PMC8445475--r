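test_that("two identical unpumped lumens shrink symmetrically to collapse", {
  ch <- two_lumen_state(size_ratio = 1, chi_v = 2, chi_s = 1)
  tr <- integrate_chain(ch, 5e3, record_steps = TRUE)
  expect_false(tr$survivor)
  expect_true(all(tr$events$kind == "collapse"))
  seg <- tr$steps[[1]]
  n <- nrow(seg$L)
  # both areas decreasing over the last recorded steps, and identical
  expect_true(all(diff(seg$L[(n - 3):n, 1]) < 0))
  expect_true(all(diff(seg$L[(n - 3):n, 2]) < 0))
  expect_equal(seg$L[, 1], seg$L[, 2], tolerance = 1e-9)
})

test_that("event times are localized to closed-form crossings", {
  # equal hydraulic lumens under pure pumping: L(t) = L0 + t/Tp exactly,
  # so the bridge closes linearly and the collision time is analytic
  p <- dimensionless_params(ell0bar = 1)
  ch <- chain_state(x = c(2, 5), L = c(1, 1), params = p, L_sys = 7)
  Tp <- 2
  tr <- integrate_chain(ch, 100, model = "hydraulic", Th = 1e9, Tp = Tp)
  ell_min <- default_thresholds(ch)$ell_min
  t_star <- (1 - ell_min) * Tp / 2
  expect_equal(tr$events$kind[1], "coalescence")
  expect_lt(rel_err(tr$events$time[1], t_star), 1e-5)
})

test_that("no threshold crossing means no event", {
  p <- dimensionless_params(ell0bar = 1)
  ch <- chain_state(x = c(2, 5), L = c(1, 1), params = p, L_sys = 7)
  tr <- integrate_chain(ch, 0.1, model = "hydraulic", Th = 1e9, Tp = 2)
  expect_identical(nrow(tr$events), 0L)
  expect_identical(tr$status, "t_end")
})

test_that("simultaneous crossings resolve deterministically by lowest id", {
  p <- dimensionless_params(chi_v = 2, chi_s = 1, ell0bar = 1)
  ch <- chain_state(x = c(2, 5, 8), L = c(1, 1, 1), params = p, L_sys = 10)
  ch$lumens$L <- c(0.005, 1, 0.005)  # both below L_min at once
  ev <- detect_events(ch, L_min = 0.01, ell_min = 0.01)
  expect_identical(ev$kind, "collapse")
  expect_identical(ev$i, 1L)
})

test_that("coalescence conserves area and moles over random merges", {
  p <- dimensionless_params()
  set.seed(31)
  for (k in 1:100) {
    n <- sample(3:8, 1)
    ch <- generate_chain(n, seed = 1000 + k, params = p)
    i <- sample(n - 1, 1)
    A0 <- sum(ch$lumens$L[c(i, i + 1)]^2) / p$mu
    N0 <- sum(ch$lumens$N[c(i, i + 1)])
    tot0 <- total_length(ch)
    ch2 <- apply_coalescence(ch, i, i + 1)
    expect_lt(abs(ch2$lumens$L[i]^2 / p$mu - A0), 1e-9)
    expect_lt(abs(ch2$lumens$N[i] - N0), 1e-12)
    expect_lt(abs(total_length(ch2) - tot0), 1e-9)
    expect_identical(nrow(ch2$lumens), n - 1L)
  }
  # equal unit areas merge into area 2, L = sqrt(2 mu)
  ch <- chain_state(x = c(11.5, 24), L = rep(sqrt(p$mu), 2), params = p)
  ch2 <- apply_coalescence(ch, 1, 2)
  expect_equal(ch2$lumens$L[1], sqrt(2 * p$mu), tolerance = 1e-12)
  expect_error(apply_coalescence(ch, 1, 3), "adjacent")
})

test_that("collapse removal fuses bridges and preserves geometry", {
  p <- dimensionless_params(ell0bar = 1)
  ch <- chain_state(x = c(2, 5, 8), L = c(1, 0.8, 1), params = p,
                    L_sys = 10)
  ell0 <- bridge_lengths(ch)
  tot0 <- total_length(ch)
  ch2 <- apply_collapse(ch, 2)
  expect_identical(nrow(ch2$lumens), 2L)
  expect_identical(length(bridge_lengths(ch2)), 3L)
  # fused middle bridge: ell_left + ell_right + 2 L_removed
  expect_equal(bridge_lengths(ch2)[2], ell0[2] + ell0[3] + 2 * 0.8,
               tolerance = 1e-12)
  expect_equal(total_length(ch2), tot0, tolerance = 1e-12)
})

test_that("strong pressure screening collapses the whole chain", {
  p <- dimensionless_params(chi_v = 1e-2, chi_s = 1)
  ch <- generate_chain(10, seed = 21, params = p)
  tr <- integrate_chain(ch, 1e5)
  expect_lte(nrow(tr$final$lumens), 1L)
  expect_false(tr$survivor)
  expect_true(all(tr$events$kind == "collapse"))
})

test_that("halving the tolerances barely moves the event times", {
  p <- dimensionless_params(chi_v = 20, chi_s = 2)
  ch <- generate_chain(10, seed = 9, params = p)
  t1 <- integrate_chain(ch, 1e4)$events$time
  t2 <- integrate_chain(ch, 1e4, rtol = 5e-7, atol = 5e-9)$events$time
  k <- min(length(t1), length(t2))
  expect_lt(max(rel_err(t1[1:k], t2[1:k])), 0.01)
})

test_that("the event log is reproducible bit for bit", {
  p <- dimensionless_params(chi_v = 20, chi_s = 2)
  t1 <- integrate_chain(generate_chain(15, seed = 4, params = p), 1e4)
  t2 <- integrate_chain(generate_chain(15, seed = 4, params = p), 1e4)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$final$lumens, t2$final$lumens)
})

test_that("total length survives arbitrary event sequences", {
  p <- dimensionless_params(chi_v = 50, chi_s = 5)
  pr <- pumping_profile("uniform", j0 = 1)
  ch <- generate_chain(30, seed = 77, params = p, profile = pr)
  tr <- integrate_chain(ch, 1e3)
  expect_gt(sum(tr$events$kind == "coalescence"), 0)
  expect_gt(sum(tr$events$kind == "collapse"), 0)
  expect_lt(abs(total_length(tr$final) - tr$final$L_sys), 1e-9)
  # the count series never increases
  cc <- lumen_count(tr)
  expect_true(all(diff(cc$n) <= 0))
})

test_that("total moles are conserved between events when membranes are solute-tight", {
  # lambda_s -> 0: tau_s and chi_s huge jointly, no pumping
  p <- dimensionless_params(chi_v = 20, chi_s = 1e6, tau_s = 1e10,
                            ell0bar = 10)
  ch <- generate_chain(5, seed = 2, params = p)
  tr <- integrate_chain(ch, 50, record_steps = TRUE)
  for (seg in tr$steps) {
    tot <- rowSums(seg$N)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-8)
  }
})

test_that("the integrator agrees with an independent solver between events", {
  skip_if_not_installed("deSolve")
  ch <- two_lumen_state(ja1 = 3.2e-3, chi_v = 0.68, chi_s = 1)
  tr <- integrate_chain(ch, 40, record_steps = TRUE, rtol = 1e-8,
                        atol = 1e-10)
  p <- ch$params
  rhs_ode <- function(t, y, parms) {
    st <- ch
    st$lumens$L <- y[1:2]; st$lumens$N <- y[3:4]
    r <- chain_rhs(st)
    list(c(r$dL, r$dN))
  }
  y0 <- c(ch$lumens$L, ch$lumens$N)
  times <- seq(0, 40, length.out = 9)
  sol <- deSolve::ode(y0, times, rhs_ode, NULL, rtol = 1e-10, atol = 1e-12)
  seg <- tr$steps[[1]]
  for (i in 1:2) {
    ours <- approx(seg$t, seg$L[, i], xout = times[-1])$y
    expect_lt(max(rel_err(ours, sol[-1, i + 1])), 1e-5)
  }
})
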