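test_that("an isolated lumen at osmotic equilibrium leaks by Laplace pressure", {
  # screening lengths tiny: bridge fluxes negligible, membrane balance only
  p <- dimensionless_params(epsilon = 1e-3, chi_v = 1e-9, chi_s = 1e-9,
                            ell0bar = 1)
  ch <- chain_state(x = 2, L = 1, params = p, L_sys = 4)
  r <- chain_rhs(ch)
  expect_equal(r$dL, -p$mu * p$nu * p$epsilon, tolerance = 1e-6)
  expect_lt(r$dL, 0)
})

test_that("pumping at the Laplace-leak rate is the growth/collapse boundary", {
  p <- dimensionless_params(epsilon = 1e-3, chi_v = 1e-9, chi_s = 1e-9,
                            ell0bar = 1)
  mk <- function(ja) {
    ch <- chain_state(x = 2, L = 1, ja_lumen = ja, params = p, L_sys = 4)
    # quasi-static solute balance: C = 1 + ja
    ch$lumens$N <- (1 + ja) / p$mu
    chain_rhs(ch)$dL
  }
  ja_star <- p$epsilon  # epsilon / L with L = 1
  expect_equal(mk(ja_star), 0, tolerance = 1e-9)
  expect_gt(mk(2 * ja_star), 0)
  expect_lt(mk(0.5 * ja_star), 0)
})

test_that("identical lumens evolve identically and are stationary without tension", {
  p <- dimensionless_params(epsilon = 1e-3, chi_v = 2, chi_s = 1, ell0bar = 1)
  ch <- chain_state(x = c(2, 5), L = c(1, 1), params = p, L_sys = 7)
  r <- chain_rhs(ch)
  expect_equal(r$dL[1], r$dL[2], tolerance = 1e-14)
  expect_equal(r$dN[1], r$dN[2], tolerance = 1e-14)
  # epsilon = 0, ja = 0, all identical at equilibrium: exact fixed point
  p0 <- dimensionless_params(epsilon = 0, chi_v = 2, chi_s = 1,
                             ell0bar = 1)
  ch0 <- chain_state(x = c(2, 5), L = c(1, 1), params = p0, L_sys = 7)
  r0 <- chain_rhs(ch0)
  expect_lt(max(abs(c(r0$dL, r0$dN))), 1e-12)
})

test_that("total length is conserved by construction of the geometry", {
  p <- dimensionless_params(chi_v = 3, chi_s = 1)
  set.seed(8)
  ch <- generate_chain(12, seed = 8, params = p)
  expect_equal(total_length(ch), ch$L_sys, tolerance = 1e-12)
  # d/dt of total length: bridge lengths respond with -(dL_i + dL_j)
  r <- chain_rhs(ch)
  # geometric identity: sum(2 dL) + sum(d ell) = 0 since
  # d ell_j = -(dL_left + dL_right) for every bridge
  dell <- -(c(0, r$dL) + c(r$dL, 0))
  expect_equal(2 * sum(r$dL) + sum(dell), 0, tolerance = 1e-12)
})

test_that("the compiled right-hand side matches the R reference exactly", {
  p <- dimensionless_params(chi_v = 5, chi_s = 0.8, tau_s = 2)
  ch <- generate_chain(10, seed = 3, params = p)
  set.seed(99)
  ch$lumens$N <- ch$lumens$N * runif(10, 0.9, 1.1)
  ch$lumens$ja <- runif(10, 0, 0.1)
  ch$ja_bridge <- runif(11, 0, 0.1)
  r1 <- chain_rhs(ch)
  r2 <- lumenchain:::chain_rhs_cpp(
    ch$lumens$L, ch$lumens$N, ch$lumens$x, ch$lumens$ja, ch$ja_bridge,
    p$mu, p$nu, p$epsilon, p$xi_v, p$xi_s, p$tau_s / p$tau_v, ch$L_sys)
  expect_lt(max(abs(r1$dL - r2$dL)), 1e-12)
  expect_lt(max(abs(r1$dN - r2$dN)), 1e-12)
})

test_that("osmotic equilibrium moles give unit concentration", {
  expect_equal(osmotic_equilibrium_moles(1, 1 / pi), pi)
  expect_equal(osmotic_equilibrium_moles(2, 0.5), 8)
  p <- dimensionless_params()
  ch <- chain_state(x = c(15, 40), L = c(1, 2), params = p)
  expect_equal(concentrations(ch), c(1, 1))
  expect_error(osmotic_equilibrium_moles(-1, 0.5))
})

test_that("net two-lumen flow has the expected structure", {
  # symmetric state: no flow
  expect_equal(net_two_lumen_flow(0, 0, 1, 1), 0, tolerance = 1e-14)
  # pressure asymmetry alone drives flow from high to low pressure
  expect_gt(net_two_lumen_flow(0, 0.25, 1, 1), 0)
  expect_lt(net_two_lumen_flow(0, -0.25, 1, 1), 0)
  # magnitude grows with the pressure screening number
  J <- sapply(c(0.5, 1, 2, 5, 20),
              function(cv) net_two_lumen_flow(0, 0.25, cv, 1))
  expect_true(all(diff(J) > 0))
  # a concentration asymmetry opposes it, but reversal needs a much
  # larger relative asymmetry than the pressure one
  f <- function(dc) net_two_lumen_flow(dc, 0.05, 1, 1)
  expect_gt(f(0.05), 0)        # equal asymmetries: pressure still wins
  dc_star <- uniroot(f, c(0, 0.99))$root
  expect_gt(dc_star, 10 * 0.05)
  expect_error(net_two_lumen_flow(1.2, 0, 1, 1), "-1, 1")
})

test_that("a shrinking lumen concentrates its trapped solutes before collapsing", {
  ch <- two_lumen_state(chi_v = 10, chi_s = 0.01, tau_s = 100, ell0bar = 1)
  tr <- integrate_chain(ch, 1e6, record_steps = TRUE)
  expect_true("collapse" %in% tr$events$kind)
  seg <- tr$steps[[length(tr$steps)]]
  C <- ch$params$mu * seg$N / seg$L^2
  expect_gt(max(C), 1.5)  # concentration rises well above the chemostat
})
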