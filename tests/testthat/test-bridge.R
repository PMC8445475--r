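test_that("symmetric boundary data give mirror-symmetric fluxes", {
  b <- bridge_boundary(0.02, 0.005)
  for (ja in c(0, 0.3)) {
    s <- solve_bridge(b, b, ell = 2, xi_v = 1.5, xi_s = 0.8, ja = ja)
    expect_equal(s$J_v_left, s$J_v_right, tolerance = 1e-14)
    expect_equal(s$J_s_left, s$J_s_right, tolerance = 1e-14)
    expect_equal(s$cd, 0)  # no antisymmetric (sinh) component
    expect_equal(s$pd, 0)
  }
})

test_that("the unscreened limit recovers pure Poiseuille flow", {
  # lambda_v -> 0 (xi_v huge), no concentration jumps, no pumping:
  # linear pressure profile, flux kappa*(dP_L - dP_R)/ell at both ends
  pL <- 0.004; pR <- 0.001; ell <- 2; xiv <- 1e7
  s <- solve_bridge(bridge_boundary(0, pL), bridge_boundary(0, pR),
                    ell, xiv, xi_s = 1)
  poiseuille <- xiv^2 * (pL - pR) / ell
  expect_equal(s$J_v_left, poiseuille, tolerance = 1e-6)
  expect_equal(s$J_v_right, -poiseuille, tolerance = 1e-6)
  prof <- bridge_profile(s, seq(-1, 1, length.out = 11))
  expect_equal(diff(prof$dp, differences = 2), rep(0, 9), tolerance = 1e-9)
})

test_that("analytic fluxes match the finite-difference oracle", {
  bl <- bridge_boundary(0.02, 0.003)
  br <- bridge_boundary(-0.01, 0.001)
  cases <- list(c(1, 2, 1, 0.5),          # generic, with pumping
                c(10, 0.5, 3, 0),         # strongly screened pressure
                c(0.3, 50, 50 * (1 + 1e-8), 0.2),  # resonant xi_v = xi_s
                c(0.3, 50, 50 * (1 + 1e-4), 0.2),  # just past the switch
                c(5, 1e3, 20, 0))         # weakly screened
  for (cs in cases) {
    a <- solve_bridge(bl, br, cs[1], cs[2], cs[3], cs[4])
    f <- fd_oracle_bridge(bl, br, cs[1], cs[2], cs[3], cs[4], n_grid = 2e4)
    for (nm in c("J_v_left", "J_v_right", "J_s_left", "J_s_right"))
      expect_lt(rel_err(a[[nm]], f[[nm]]), 1e-6)
    # interior profiles agree too
    x <- f$x[seq(50, length(f$x) - 50, length.out = 50)]
    pr <- bridge_profile(a, x)
    fc <- approx(f$x, f$dc, xout = x)$y
    fp <- approx(f$x, f$dp, xout = x)$y
    expect_lt(max(abs(pr$dc - fc)) / max(abs(fc)), 1e-6)
    expect_lt(max(abs(pr$dp - fp)) / max(abs(fp)), 1e-6)
  }
})

test_that("solution is continuous across the resonance switch", {
  bl <- bridge_boundary(0.01, 0.002); br <- bridge_boundary(-0.02, 0.004)
  s_deg <- solve_bridge(bl, br, 1.5, 2 * (1 + 1e-8), 2, 0.1)
  s_reg <- solve_bridge(bl, br, 1.5, 2 * (1 + 1e-5), 2, 0.1)
  expect_true(s_deg$degenerate)
  expect_false(s_reg$degenerate)
  for (nm in c("J_v_left", "J_v_right"))
    expect_lt(rel_err(s_deg[[nm]], s_reg[[nm]]), 1e-3)
})

test_that("boundary values reproduce the Dirichlet data", {
  bl <- bridge_boundary(0.017, -0.002); br <- bridge_boundary(-0.03, 0.006)
  s <- solve_bridge(bl, br, 3, 0.7, 1.9, 0.05)
  pr <- bridge_profile(s, c(-1.5, 1.5))
  expect_equal(pr$dc, c(bl$dC, br$dC), tolerance = 1e-10)
  expect_equal(pr$dp, c(bl$dP, br$dP), tolerance = 1e-10)
})

test_that("finite-difference oracle converges at second order", {
  bl <- bridge_boundary(0.02, 0.003); br <- bridge_boundary(-0.01, 0.001)
  a <- solve_bridge(bl, br, 2, 1.2, 0.9, 0.1)
  errs <- sapply(c(400, 800, 1600), function(n) {
    f <- fd_oracle_bridge(bl, br, 2, 1.2, 0.9, 0.1, n_grid = n)
    abs(f$J_v_left - a$J_v_left)
  })
  # doubling the grid divides the error by ~4
  expect_gt(errs[1] / errs[2], 3.3)
  expect_gt(errs[2] / errs[3], 3.3)
})

test_that("wall bridges impose exactly zero flux at the sealed end", {
  lum <- bridge_boundary(0.02, 0.004)
  w <- wall_bridge(lum, ell = 2, xi_v = 1.5, xi_s = 0.7, ja = 0.1)
  expect_identical(w$J_v_right, 0)
  expect_identical(w$J_s_right, 0)
  f <- fd_oracle_bridge(lum, bridge_boundary(kind = "wall"), 2, 1.5, 0.7,
                        0.1, n_grid = 2e4)
  expect_lt(rel_err(w$J_v_left, f$J_v_left), 1e-6)
  expect_lt(rel_err(w$J_s_left, f$J_s_left), 1e-6)
  # unscreened limit: the dead-end bridge mediates no coupling; only the
  # lateral membrane exchange of the bridge itself survives, with the
  # closed-form residuals J_s -> dC * ell and J_v -> (dP - dC) * ell
  w2 <- wall_bridge(bridge_boundary(0.01, 0.002), 1, 1e8, 1e7, 0)
  expect_equal(w2$J_s_left, 0.01 * 1, tolerance = 1e-6)
  expect_equal(w2$J_v_left, (0.002 - 0.01) * 1, tolerance = 1e-3)
})

test_that("solute flux is conserved end to end in the impermeable limit", {
  bl <- bridge_boundary(0.03, 0.001); br <- bridge_boundary(-0.01, 0.002)
  s <- solve_bridge(bl, br, 2, 1, 1e9, 0)
  expect_lt(abs(s$J_s_left + s$J_s_right) /
              max(abs(s$J_s_left), abs(s$J_s_right)), 1e-10)
})

test_that("strong screening hydraulically decouples the two ends", {
  bl <- bridge_boundary(0, 0.005)
  ell <- 10; xiv <- 1  # ell / xi_v = 10
  s1 <- solve_bridge(bl, bridge_boundary(0, 0.001), ell, xiv, 1)
  s2 <- solve_bridge(bl, bridge_boundary(0, 0.009), ell, xiv, 1)
  expect_lt(rel_err(s1$J_v_left, s2$J_v_left), 1e-3)
})

test_that("net solvent flow runs from high to low pressure", {
  # for strongly screened bridges both lumens also leak laterally into
  # the bridge, so the invariant is on the net transfer: the high-pressure
  # end always loses more than the low-pressure end
  for (ell in c(0.3, 1, 5)) for (xiv in c(0.3, 1, 10)) {
    s <- solve_bridge(bridge_boundary(0, 0.006), bridge_boundary(0, 0.002),
                      ell, xiv, 1)
    expect_gt(s$J_v_left, 0)           # leaves the high-pressure lumen
    expect_gt(s$J_v_left, s$J_v_right) # net flow toward low pressure
  }
})

test_that("degenerate inputs are rejected", {
  b <- bridge_boundary(0, 0)
  expect_error(solve_bridge(b, b, 0, 1, 1), "coalescence")
  expect_error(solve_bridge(b, b, -1, 1, 1), "coalescence")
  expect_error(solve_bridge(b, b, 1, 0, 1), "screening")
  expect_error(solve_bridge(bridge_boundary(kind = "wall"),
                            bridge_boundary(kind = "wall"), 1, 1, 1),
               "lumen")
  expect_error(fd_oracle_bridge(b, b, 1, 1, 1, n_grid = 10), "n_grid")
})
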