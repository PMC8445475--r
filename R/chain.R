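#' Construct a lumen chain state
#'
#' A chain is an ordered set of 2-D lumens with fixed centers on
#' `[0, L_sys]`, connected by bridges, with sealed walls at both ends.
#' Bridge lengths are never independent state: they are recomputed from the
#' geometry (`ell_ij = x_j - x_i - L_i - L_j`) at every evaluation, so the
#' total length `2*sum(L) + sum(ell) = L_sys` is conserved identically.
#'
#' @param x lumen center positions (strictly increasing).
#' @param L lumen half-lengths (> 0), same length as `x`.
#' @param N lumen solute moles (> 0); default: osmotic equilibrium
#'   `N = L^2 / mu`.
#' @param ja_lumen per-lumen dimensionless pumping rates (recycled).
#' @param ja_bridge per-bridge pumping rates, length `n + 1` including the
#'   two wall bridges (recycled).
#' @param params a [dimensionless_params()] object.
#' @param L_sys total chain length; default places the right wall so that
#'   the last wall bridge has length `params$ell0bar`.
#' @param time current time (units of `tau_v`).
#' @return An object of class `lumen_chain`.
#' @export
chain_state <- function(x, L, N = NULL, ja_lumen = 0, ja_bridge = 0,
                        params = dimensionless_params(), L_sys = NULL,
                        time = 0) {
  stopifnot(inherits(params, "dimensionless_params"))
  n <- length(x)
  if (length(L) != n) stop("x and L must have the same length")
  if (is.null(N)) N <- osmotic_equilibrium_moles(L, params$mu)
  if (length(N) != n) stop("N must match x")
  if (is.null(L_sys)) L_sys <- x[n] + L[n] + params$ell0bar
  if (any(diff(x) <= 0)) stop("lumen centers must be strictly increasing")
  if (any(L <= 0) || any(N <= 0)) stop("L and N must be > 0")
  ch <- structure(list(
    lumens = data.frame(id = seq_len(n), x = x, L = L, N = N,
                        ja = rep_len(ja_lumen, n)),
    ja_bridge = rep_len(ja_bridge, n + 1L),
    params = params, L_sys = L_sys, time = time), class = "lumen_chain")
  ell <- bridge_lengths(ch)
  if (any(ell < 0)) stop("overlapping lumens: negative bridge length")
  ch
}

#' Bridge lengths of a chain, recomputed from geometry
#'
#' @param chain a `lumen_chain`.
#' @return Numeric vector of length `n + 1`: the two wall bridges and the
#'   `n - 1` interior bridges, ordered left to right.
#' @export
bridge_lengths <- function(chain) {
  lu <- chain$lumens
  n <- nrow(lu)
  c(lu$x[1] - lu$L[1],
    if (n > 1) diff(lu$x) - (lu$L[-n] + lu$L[-1]),
    chain$L_sys - lu$x[n] - lu$L[n])
}

#' Total chain length (conserved quantity)
#'
#' @param chain a `lumen_chain`.
#' @return `2*sum(L) + sum(ell)`; equals `L_sys` up to round-off at all
#'   times, including across topological events.
#' @export
total_length <- function(chain) {
  2 * sum(chain$lumens$L) + sum(bridge_lengths(chain))
}

#' Solute content at osmotic equilibrium
#'
#' A lumen at osmotic equilibrium has concentration equal to the external
#' chemostat (`C = 1` in dimensionless units), i.e. `N = A = L^2 / mu`.
#'
#' @param L half-length(s).
#' @param mu shape factor.
#' @return moles `N = L^2 / mu`.
#' @export
osmotic_equilibrium_moles <- function(L, mu) {
  if (any(L <= 0) || mu <= 0) stop("L and mu must be > 0")
  L^2 / mu
}

#' Lumen concentrations of a chain
#' @param chain a `lumen_chain`.
#' @return `C = mu * N / L^2` per lumen (dimensionless, chemostat = 1).
#' @export
concentrations <- function(chain) {
  with(chain$lumens, chain$params$mu * N / L^2)
}

#' Right-hand side of the chain ODE system (reference implementation)
#'
#' Assembles, from per-bridge analytic fluxes, the dimensionless rates
#' `dL_i/dt = mu*nu*(mu*N_i/L_i^2 - 1 - eps/L_i) - mu/(2*L_i) * Jv_i` and
#' `(tau_s/tau_v) dN_i/dt = 2*nu*L_i*(1 - mu*N_i/L_i^2 + ja_i) - Js_i`,
#' where `Jv_i`, `Js_i` sum the outgoing fluxes into the lumen's adjacent
#' bridges. This R implementation built on [solve_bridge()] is the
#' reference; the integrator uses an identical compiled evaluation (the two
#' are cross-checked in the test suite).
#'
#' @param chain a `lumen_chain`.
#' @return List with `dL`, `dN` (per lumen) and the per-lumen summed
#'   outgoing fluxes `Jv`, `Js`.
#' @export
chain_rhs <- function(chain) {
  p <- chain$params
  lu <- chain$lumens
  n <- nrow(lu)
  dC <- p$mu * lu$N / lu$L^2 - 1
  dP <- p$epsilon / lu$L
  ell <- bridge_lengths(chain)
  Jv <- numeric(n); Js <- numeric(n)
  for (j in seq_len(n + 1L)) {
    il <- j - 1L; ir <- j            # lumen indices left/right of bridge j
    left <- if (il >= 1L) bridge_boundary(dC[il], dP[il]) else
      bridge_boundary(kind = "wall")
    right <- if (ir <= n) bridge_boundary(dC[ir], dP[ir]) else
      bridge_boundary(kind = "wall")
    sol <- solve_bridge(left, right, ell[j], p$xi_v, p$xi_s,
                        chain$ja_bridge[j])
    if (il >= 1L) { Jv[il] <- Jv[il] + sol$J_v_left
                    Js[il] <- Js[il] + sol$J_s_left }
    if (ir <= n)  { Jv[ir] <- Jv[ir] + sol$J_v_right
                    Js[ir] <- Js[ir] + sol$J_s_right }
  }
  dL <- p$mu * p$nu * (p$mu * lu$N / lu$L^2 - 1 - p$epsilon / lu$L) -
    p$mu / (2 * lu$L) * Jv
  dN <- (2 * p$nu * lu$L * (1 - p$mu * lu$N / lu$L^2 + lu$ja) - Js) *
    (p$tau_v / p$tau_s)
  if (any(!is.finite(dL)) || any(!is.finite(dN)))
    stop("non-finite derivative in chain_rhs")
  list(dL = dL, dN = dN, Jv = Jv, Js = Js)
}

#' Instantaneous net solvent flow between two lumens
#'
#' Builds a two-lumen configuration realizing prescribed relative
#' asymmetries of concentration `Delta_C = (C2 - C1)/(C1 + C2)` and
#' pressure `Delta_P = (P2 - P1)/(P1 + P2)`, solves the connecting bridge,
#' and returns the signed net solvent flow toward lumen 1,
#' `J_{2->1} = J2_v - J1_v` (positive: lumen 2 discharges toward lumen 1).
#'
#' Construction convention (the mapping from asymmetries to boundary data
#' is not unique): the asymmetries act on the absolute pressures and
#' concentrations around the external references, with the mean pinned to
#' them: `P_i = p0*(1 -/+ Delta_P)` and `C_i = c0*(1 -/+ Delta_C)` (upper
#' sign: lumen 1), giving bridge Dirichlet data `dp_i = -/+ p0bar*Delta_P`
#' and `dc_i = -/+ Delta_C` with `p0bar = p0/Pi0` (default 1, the
#' physiological regime where reference pressure and osmotic pressure are
#' of the same order). Pressure asymmetry then drives the longitudinal
#' Poiseuille flux directly, while a concentration asymmetry acts only
#' through the osmotic source of the pressure profile, which is why a much
#' larger `Delta_C` than `Delta_P` is needed to reverse the flow.
#'
#' @param Delta_C,Delta_P relative asymmetries, each in `(-1, 1)`.
#' @param chi_v,chi_s screening numbers.
#' @param ja bridge pumping rate.
#' @param p0bar reference pressure in units of the osmotic pressure scale.
#' @param ell bridge length in units of the mean initial bridge length
#'   (default 1).
#' @param ell0bar bridge-length scale in lumen units (default 1).
#' @return Signed dimensionless net flow toward lumen 1.
#' @export
#' @examples
#' net_two_lumen_flow(0, 0.25, chi_v = 1, chi_s = 1) # > 0: toward lumen 1
net_two_lumen_flow <- function(Delta_C, Delta_P, chi_v, chi_s, ja = 0,
                               p0bar = 1, ell = 1, ell0bar = 1) {
  if (abs(Delta_C) >= 1 || abs(Delta_P) >= 1)
    stop("asymmetries must lie in (-1, 1)")
  C1 <- 1 - Delta_C; C2 <- 1 + Delta_C
  P1 <- p0bar * (1 - Delta_P); P2 <- p0bar * (1 + Delta_P)
  if (C1 <= 0 || C2 <= 0 || P1 <= 0 || P2 <= 0)
    stop("infeasible asymmetry combination")
  xi_v <- chi_v * ell0bar; xi_s <- chi_s * ell0bar
  sol <- solve_bridge(bridge_boundary(C1 - 1, P1 - p0bar),
                      bridge_boundary(C2 - 1, P2 - p0bar),
                      ell * ell0bar, xi_v, xi_s, ja)
  sol$J_v_right - sol$J_v_left
}

#' @export
print.lumen_chain <- function(x, ...) {
  n <- nrow(x$lumens)
  cat(sprintf("Lumen chain: %d lumen%s, L_sys = %.6g, t = %.6g\n",
              n, if (n == 1) "" else "s", x$L_sys, x$time))
  cat(sprintf("  <L> = %.4g  <C> = %.4g  total length error = %.2e\n",
              mean(x$lumens$L), mean(concentrations(x)),
              total_length(x) - x$L_sys))
  invisible(x)
}
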