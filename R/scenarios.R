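#' Active pumping profile along a chain
#'
#' Either a uniform basal rate `j0`, or a uniform rate perturbed by a
#' Gaussian bump, `j(x) = j0 + delta_j / (sqrt(2*pi) * sigma) *
#' exp(-(x - mu_g)^2 / sigma^2)`, with `x` the position as a fraction of
#' the chain length. Note the exponent scale `sigma^2` (not `2*sigma^2`):
#' the bump then integrates to `delta_j / sqrt(2)` over an infinite chain
#' and its +/- 2*sigma window carries a fraction `erf(2)` of that.
#'
#' @param kind `"uniform"` or `"gaussian"`.
#' @param j0 basal dimensionless pumping rate (>= 0).
#' @param delta_j Gaussian perturbation amplitude.
#' @param mu_g perturbation center (fraction of chain length).
#' @param sigma perturbation width (fraction of chain length).
#' @return An object of class `pumping_profile`.
#' @export
#' @examples
#' pr <- pumping_profile("gaussian", j0 = 0.2, delta_j = 1, mu_g = 0.4,
#'                       sigma = 0.05)
#' pumping_rate(pr, c(0.1, 0.4, 0.9))
pumping_profile <- function(kind = c("uniform", "gaussian"), j0 = 0,
                            delta_j = 1, mu_g = 0.4, sigma = 0.05) {
  kind <- match.arg(kind)
  if (j0 < 0) stop("basal pumping must be non-negative")
  if (kind == "gaussian" && (sigma <= 0 || delta_j < 0))
    stop("gaussian perturbation needs sigma > 0 and delta_j >= 0")
  structure(list(kind = kind, j0 = j0, delta_j = delta_j, mu_g = mu_g,
                 sigma = sigma), class = "pumping_profile")
}

#' Evaluate a pumping profile
#'
#' @param profile a [pumping_profile()].
#' @param x positions as fractions of the chain length.
#' @return Pumping rates `j(x)`.
#' @export
pumping_rate <- function(profile, x) {
  stopifnot(inherits(profile, "pumping_profile"))
  if (profile$kind == "uniform") return(rep(profile$j0, length(x)))
  profile$j0 + profile$delta_j / (sqrt(2 * pi) * profile$sigma) *
    exp(-(x - profile$mu_g)^2 / profile$sigma^2)
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Basal-pumping threshold for final-lumen positioning
#'
#' Closed-form threshold separating the regime where a Gaussian pumping
#' perturbation dominates the final-lumen position from the regime where
#' the uniform baseline competes with it:
#' `j_star = delta_j * sigma * sqrt(pi) * erf(2) / (0.6 - 8 * sigma)`.
#' The threshold compares the pumping delivered under the +/- 2*sigma
#' window of the bump with the baseline pumping of the remaining
#' quasi-uniform part of the profile (see [pumping_threshold_numeric()]).
#'
#' @param delta_j Gaussian amplitude.
#' @param sigma Gaussian width (fraction of chain length); must be
#'   `< 0.075` for the denominator to stay positive.
#' @return The threshold basal rate `j_star`.
#' @export
#' @examples
#' pumping_threshold(1, 0.05)  # ~ 0.44
pumping_threshold <- function(delta_j, sigma) {
  if (sigma <= 0 || sigma >= 0.075)
    stop("sigma must lie in (0, 0.075)")
  delta_j * sigma * sqrt(pi) * .erf(2) / (0.6 - 8 * sigma)
}

#' Numeric certification of the pumping threshold
#'
#' Reproduces the area-comparison construction behind
#' [pumping_threshold()] by numerical integration: the excess pumping of
#' the bump (amplitude-`delta_j` Gaussian with exponent scale `sigma^2`)
#' integrated over a window of width `4*sigma` centered on it, equated with
#' the baseline pumping `j0` integrated over the far-side quasi-uniform
#' region of length `(1 - mu_g) - 8*sigma`.
#'
#' @inheritParams pumping_threshold
#' @param mu_g bump center (the closed form fixes `mu_g = 0.4`).
#' @return Numerically integrated threshold.
#' @export
pumping_threshold_numeric <- function(delta_j, sigma, mu_g = 0.4) {
  if (sigma <= 0 || (1 - mu_g) - 8 * sigma <= 0)
    stop("sigma too large for the area comparison")
  bump <- stats::integrate(function(x)
    delta_j * exp(-(x - mu_g)^2 / sigma^2),
    mu_g - 2 * sigma, mu_g + 2 * sigma, rel.tol = 1e-10)$value
  bump / ((1 - mu_g) - 8 * sigma)
}

#' Generate a random initial chain
#'
#' Draws lumen areas and bridge lengths from Gaussian distributions
#' (defaults: areas with mean 1, sd 0.2; bridge lengths with mean 10,
#' sd 2), rejecting and redrawing non-positive values so the distribution
#' shape is preserved. Lumens are placed sequentially from the left sealed
#' wall; every lumen starts at osmotic equilibrium (`C = 1`). The total
#' length implied by the draw is fixed thereafter.
#'
#' @param n_lumens number of lumens (>= 1).
#' @param A_mean,A_sd lumen area distribution (dimensionless).
#' @param ell_mean,ell_sd bridge length distribution (units of the lumen
#'   scale; `ell_mean` should normally equal `params$ell0bar`).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param params a [dimensionless_params()].
#' @param profile optional [pumping_profile()]; evaluated at lumen centers
#'   and bridge midpoints (as fractions of chain length) and re-evaluated
#'   after every topological rewrite.
#' @return A `lumen_chain` with attributes `redraws` (rejection count).
#' @export
generate_chain <- function(n_lumens, A_mean = 1, A_sd = 0.2, ell_mean = 10,
                           ell_sd = 2, seed, params = dimensionless_params(),
                           profile = NULL) {
  stopifnot(n_lumens >= 1, A_mean > 0, A_sd > 0, ell_mean > 0, ell_sd > 0)
  if (missing(seed)) stop("a seed is required for reproducible chains")
  set.seed(seed)
  draw_pos <- function(n, mean, sd) {
    out <- stats::rnorm(n, mean, sd)
    redraws <- 0L
    while (any(out <= 0)) {
      bad <- out <= 0
      redraws <- redraws + sum(bad)
      out[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    attr(out, "redraws") <- redraws
    out
  }
  A <- draw_pos(n_lumens, A_mean, A_sd)
  ell <- draw_pos(n_lumens + 1L, ell_mean, ell_sd)
  redraws <- attr(A, "redraws") + attr(ell, "redraws")
  A <- as.numeric(A); ell <- as.numeric(ell)
  if (redraws > 0.01 * (2 * n_lumens + 1))
    warning("more than 1% of Gaussian draws were non-positive and redrawn")
  L <- half_length_from_area(A, params$mu)
  x <- cumsum(ell[seq_len(n_lumens)] + L) + c(0, cumsum(L[-n_lumens]))
  L_sys <- x[n_lumens] + L[n_lumens] + ell[n_lumens + 1L]
  ch <- chain_state(x, L, params = params, L_sys = L_sys)
  if (!is.null(profile)) {
    ch$profile <- profile
    ch <- .refresh_pumping(ch)
  }
  attr(ch, "redraws") <- redraws
  ch
}

#' Two-lumen experiment at osmotic equilibrium
#'
#' Builds the canonical two-lumen system: two lumens of mean half-length 1
#' with size ratio `L2/L1 = size_ratio`, both at osmotic equilibrium,
#' joined by a central bridge of length `ell0bar` with sealed-wall bridges
#' of the same length at both ends. Pumping acts in the lumens only
#' (rates `ja1`, `ja2`); bridge pumping is zero.
#'
#' @param size_ratio initial size ratio `L2(0)/L1(0)` (> 0).
#' @param ja1,ja2 dimensionless pumping rates of lumens 1 and 2.
#' @param chi_v,chi_s screening numbers.
#' @param tau_s solute relaxation time (units of `tau_v`).
#' @param epsilon tension-to-osmotic-pressure ratio.
#' @param theta contact angle.
#' @param ell0bar initial bridge length in lumen units (default 1).
#' @return A `lumen_chain` with two lumens.
#' @export
two_lumen_state <- function(size_ratio = 1.1, ja1 = 0, ja2 = 0, chi_v = 1,
                            chi_s = 1, tau_s = 1, epsilon = 1e-3,
                            theta = pi / 3, ell0bar = 1) {
  stopifnot(size_ratio > 0)
  params <- dimensionless_params(epsilon = epsilon, chi_v = chi_v,
                                 chi_s = chi_s, tau_v = 1, tau_s = tau_s,
                                 theta = theta, ell0bar = ell0bar)
  L1 <- 2 / (1 + size_ratio)
  L2 <- size_ratio * L1
  x1 <- ell0bar + L1
  x2 <- x1 + L1 + ell0bar + L2
  chain_state(x = c(x1, x2), L = c(L1, L2), ja_lumen = c(ja1, ja2),
              ja_bridge = 0, params = params,
              L_sys = x2 + L2 + ell0bar)
}

#' Classify the fate of a two-lumen trajectory
#'
#' The fate is the first qualitative outcome of the dynamics: coalescence
#' if a merge event occurred; otherwise the signs of the area changes over
#' the three last recorded steps decide between collapse (both lumens
#' shrinking), coarsening (one shrinks, the other grows) and reversed
#' coarsening (the initially smaller lumen is the one growing).
#'
#' @param traj a `lumen_trajectory` integrated from a two-lumen chain with
#'   `record_steps = TRUE`.
#' @return One of `"collapse"`, `"coarsening"`, `"reversed-coarsening"`,
#'   `"coalescence"`. An indeterminate sign pattern (e.g. both lumens
#'   growing with no merge by `t_end`) is an error, never a silent guess.
#' @export
classify_fate <- function(traj) {
  stopifnot(inherits(traj, "lumen_trajectory"), traj$n0 == 2L)
  if (any(traj$events$kind == "coalescence")) return("coalescence")
  if (!length(traj$steps))
    stop("fate classification requires record_steps = TRUE")
  two <- which(vapply(traj$steps, function(s) length(s$ids) == 2L,
                      logical(1)))
  if (!length(two)) stop("no two-lumen segment recorded")
  smaller0 <- which.min(traj$steps[[two[1]]]$L[1, ])
  seg <- traj$steps[[two[length(two)]]]  # last segment with both lumens
  if (nrow(seg$L) < 4L)
    stop("unclassifiable: too few recorded steps before the first event")
  # three final steps, taken on a stepper-independent checkpoint grid
  # spanning the last 6% of the pre-event dynamics (adaptive solver steps
  # become arbitrarily fine next to an event and carry no trend signal)
  tf <- seg$t[length(seg$t)]; t0 <- seg$t[1]
  tcheck <- tf - (3:0) * 0.02 * (tf - t0)
  A1 <- stats::approx(seg$t, seg$L[, 1]^2, xout = tcheck, ties = "ordered")$y
  A2 <- stats::approx(seg$t, seg$L[, 2]^2, xout = tcheck, ties = "ordered")$y
  dA1 <- diff(A1)
  dA2 <- diff(A2)
  s1 <- all(dA1 < 0); g1 <- all(dA1 > 0)
  s2 <- all(dA2 < 0); g2 <- all(dA2 > 0)
  if (s1 && s2) return("collapse")
  if ((s1 && g2) || (g1 && s2)) {
    growing <- if (g1) 1L else 2L
    return(if (growing == smaller0) "reversed-coarsening" else "coarsening")
  }
  stop("unclassified two-lumen fate: sign pattern is indeterminate")
}

#' Two-lumen fate scan over pumping rate and pressure screening
#'
#' Integrates the two-lumen system on a grid of `(ja1, chi_v)` values and
#' classifies each fate.
#'
#' @param ja1_values pumping rates for lumen 1.
#' @param chi_v_values pressure screening numbers.
#' @param t_end integration horizon.
#' @param ... further arguments to [two_lumen_state()].
#' @return data.frame with columns `ja1`, `chi_v`, `fate`.
#' @export
fate_scan <- function(ja1_values, chi_v_values, t_end = 5e3, ...) {
  grid <- expand.grid(ja1 = ja1_values, chi_v = chi_v_values)
  grid$fate <- vapply(seq_len(nrow(grid)), function(k) {
    ch <- two_lumen_state(ja1 = grid$ja1[k], chi_v = grid$chi_v[k], ...)
    classify_fate(integrate_chain(ch, t_end, record_steps = TRUE))
  }, character(1))
  grid
}
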