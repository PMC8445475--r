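# minimal synthetic trajectory carrying only what the observables read
fake_traj <- function(event_times, n0, t0 = 0, model = "full") {
  structure(list(
    events = data.frame(time = event_times, kind = "collapse",
                        i = seq_along(event_times), j = NA_integer_,
                        area_before = 0, area_after = 0, moles_before = 0,
                        moles_after = 0,
                        n_after = n0 - seq_along(event_times)),
    n0 = n0, t0 = t0, model = model, survivor = FALSE),
    class = "lumen_trajectory")
}

test_that("the binned curve reproduces a single step function", {
  tr <- fake_traj(c(1, 2, 4, 8), n0 = 10)
  ser <- lumen_count_series(list(tr), n_bins = 30)
  expected <- approx(c(0, 1, 2, 4, 8), c(10, 9, 8, 7, 6), xout = ser$time,
                     method = "constant", f = 0, rule = 2)$y
  expect_equal(ser$n_mean, expected)
  expect_true(all(is.na(ser$n_sd)))  # sd undefined for one realization
  # two identical realizations: the average is either of them
  ser2 <- lumen_count_series(list(tr, tr), n_bins = 30)
  expect_equal(ser2$n_mean, ser$n_mean)
})

test_that("power-law fits recover exact exponents", {
  tt <- exp(seq(log(1), log(100), length.out = 40))
  for (slope in c(-2 / 5, -1)) {
    ser <- structure(data.frame(time = tt, n_mean = 100 * tt^slope,
                                n_sd = 0, n_realizations = 1),
                     class = c("ensemble_summary", "data.frame"))
    # exact synthetic data: lm warns about a perfect fit, which is the point
    f <- suppressWarnings(fit_power_law(ser, c(1, 100)))
    expect_equal(f$exponent, slope, tolerance = 1e-3)
    expect_lt(f$stderr, 1e-6)
  }
  ser <- structure(data.frame(time = tt[1:4], n_mean = 1, n_sd = 0,
                              n_realizations = 1),
                   class = c("ensemble_summary", "data.frame"))
  expect_error(fit_power_law(ser, c(1, 100)), "5 bins")
})

test_that("the averaged coarsening curve is monotone non-increasing", {
  p <- dimensionless_params(chi_v = 500, chi_s = 5)
  ens <- run_ensemble(8, base_seed = 150, n_lumens = 50, t_end = 1e4,
                      params = p)
  ser <- lumen_count_series(ens$trajectories, n_bins = 40)
  expect_true(all(diff(ser$n_mean) <= 1e-9))
  # binning invariance of the fitted exponent
  f1 <- fit_exponent(ens$trajectories, 50, n_bins = 40)
  f2 <- fit_exponent(ens$trajectories, 50, n_bins = 80)
  expect_lt(abs(f1$exponent - f2$exponent), 0.02)
})

test_that("area distributions are normalized with unit rescaled mean", {
  p <- dimensionless_params(chi_v = 500, chi_s = 5)
  snap <- exp(seq(log(1e-4), log(10), length.out = 60))
  ens <- run_ensemble(6, base_seed = 160, n_lumens = 50, t_end = 10,
                      params = p,
                      integrate_args = list(snapshot_times = snap))
  ad <- area_distribution(ens$trajectories, 1e-3)
  expect_gte(ad$n_pooled, 100)
  expect_equal(mean(ad$areas), 1, tolerance = 1e-12)  # A/A* has mean 1
  w <- diff(ad$density$mid[1:2])
  expect_equal(sum(ad$density$density) * w, 1, tolerance = 0.01)
  # near time zero all areas are close to the initial Gaussian: unimodal
  expect_identical(count_modes(ad$areas, bw = 0.25), 1L)
})

test_that("late pumping-driven coarsening yields a multimodal size distribution", {
  p <- dimensionless_params(chi_v = 50, chi_s = 5)
  pr <- pumping_profile("uniform", j0 = 1)
  snap <- exp(seq(log(1e-2), log(3e2), length.out = 90))
  ens <- run_ensemble(25, base_seed = 950, n_lumens = 60, t_end = 3e2,
                      params = p, profile = pr,
                      integrate_args = list(snapshot_times = snap))
  ad <- area_distribution(ens$trajectories, 40)
  # smoothed at fixed bandwidth 0.1 (A/A* scale): coalescence waves leave
  # distinct subpopulations
  expect_gte(count_modes(ad$areas, bw = 0.1), 2L)
})

test_that("final positions pool survivors only and report exclusions", {
  p <- dimensionless_params(chi_v = 500, chi_s = 1)
  pr <- pumping_profile("gaussian", j0 = 0.2, delta_j = 1, mu_g = 0.4,
                        sigma = 0.05)
  ens <- run_ensemble(12, base_seed = 700, n_lumens = 50, t_end = 1e4,
                      params = p, profile = pr)
  pos <- final_position_distribution(ens$trajectories)
  expect_identical(pos$n_survived + pos$n_collapsed + pos$n_other, 12L)
  expect_true(all(pos$positions >= 0 & pos$positions <= 1))
  w <- diff(pos$histogram$mid[1:2])
  expect_equal(sum(pos$histogram$density) * w, 1, tolerance = 1e-9)
  # the perturbation below threshold drags the survivor toward its center
  expect_lt(abs(mean(pos$positions) - 0.4), 0.06)
  expect_lt(mean(pos$positions), 0.48)
})
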