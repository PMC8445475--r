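#' Contact angle of a lumen lens
#'
#' A lumen squeezed between two adhering membranes takes a lens shape whose
#' contact angle with the bridge is set by the balance between the membrane
#' tension `gamma` and the adhesive tension `gamma_c` of the cell-cell
#' contact: `theta = acos(gamma_c / (2 * gamma))`.
#'
#' @param gamma_c adhesive (contact) tension, same units as `gamma`; must
#'   satisfy `0 <= gamma_c < 2 * gamma` for a lens solution to exist.
#' @param gamma membrane tension, > 0.
#' @return Contact angle in radians, in `(0, pi/2]`.
#' @export
#' @examples
#' contact_angle(0, 1)    # pi/2
#' contact_angle(1, 1)    # pi/3
contact_angle <- function(gamma_c, gamma) {
  stopifnot(is.numeric(gamma_c), is.numeric(gamma))
  if (any(gamma <= 0) || any(gamma_c < 0))
    stop("tensions must satisfy gamma > 0 and gamma_c >= 0")
  if (any(gamma_c >= 2 * gamma))
    stop("no lens solution: gamma_c must be < 2 * gamma")
  acos(gamma_c / (2 * gamma))
}

#' Geometric shape factors of a lens-shaped lumen
#'
#' For a 2-D lumen bounded by two circular arcs meeting the bridge at contact
#' angle `theta`, the half-length L and area A are related by `L = sqrt(mu * A)`
#' with `mu = sin(theta)^2 / (2 * theta - sin(2 * theta))`, and the arc length
#' of each membrane is `2 * nu * L` with `nu = theta / sin(theta)`.
#'
#' @param theta contact angle in radians, in `(0, pi/2]`.
#' @return Named list with elements `mu` and `nu`.
#' @export
#' @examples
#' shape_factors(pi / 2)  # mu = 1/pi, nu = pi/2
shape_factors <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L)
  if (theta <= 0 || theta > pi / 2)
    stop("theta must be in (0, pi/2]")
  list(mu = sin(theta)^2 / (2 * theta - sin(2 * theta)),
       nu = theta / sin(theta))
}

#' Convert between lumen area and half-length
#'
#' The lens geometry gives `L = sqrt(mu * A)`, i.e. `A = L^2 / mu`.
#'
#' @param A lumen area (> 0).
#' @param L lumen half-length (> 0).
#' @param mu shape factor from [shape_factors()].
#' @return half-length (resp. area).
#' @export
half_length_from_area <- function(A, mu) {
  if (any(A <= 0) || any(mu <= 0)) stop("A and mu must be > 0")
  sqrt(mu * A)
}

#' @rdname half_length_from_area
#' @export
area_from_half_length <- function(L, mu) {
  if (any(L <= 0) || any(mu <= 0)) stop("L and mu must be > 0")
  L^2 / mu
}

#' Physical parameter set for the dimensional model
#'
#' Collects the dimensional constants of the two-membrane lumen/bridge model
#' and validates their ranges. All internal computation is dimensionless;
#' this object exists for conversion and reporting through
#' [dimensionless_groups()].
#'
#' Concentration convention: `c0` is a 3-D molar concentration (mol/m^3); in
#' the 2-D reduction the solute content of a lumen of area A is `N = C * A`
#' with C in mol/m^2 understood as `c0` times the (constant) slab thickness,
#' which cancels from every dimensionless group. The mole scale is
#' `N0 = c0 * L_scale^2`.
#'
#' The default values form a synthetic embryo-motivated parameter set:
#' bridge thickness 50 nm, water viscosity, and a typical membrane hydraulic
#' permeability chosen so that the pressure screening length
#' `xi_v = sqrt(e0^3 / (24 * eta * lambda_v))` is about 84 micrometres.
#'
#' @param gamma membrane tension (N/m).
#' @param gamma_c adhesive bridge tension (N/m), `0 <= gamma_c < 2*gamma`.
#' @param e0 bridge thickness (m).
#' @param eta solvent viscosity (Pa s).
#' @param lambda_v solvent membrane permeability (m / (Pa s)).
#' @param lambda_s solute membrane permeability (mol / (m^2 s) per unit of
#'   RT-scaled chemical potential).
#' @param D solute diffusion coefficient (m^2/s).
#' @param c0 external reference concentration (mol/m^3).
#' @param p0 reference pressure (Pa).
#' @param RT gas constant times temperature (J/mol).
#' @param L_scale mean initial lumen half-length used for
#'   nondimensionalization (m).
#' @param ell0 mean initial bridge length (m).
#' @param L_sys total chain length (m), `2*sum(L) + sum(ell)`.
#' @return An object of class `physical_params` (named list).
#' @export
physical_params <- function(gamma = 1.2e-4, gamma_c = 1.2e-4, e0 = 5e-8,
                            eta = 1e-3, lambda_v = 7.4e-13, lambda_s = 4e-9,
                            D = 1e-9, c0 = 40, p0 = 1e5, RT = 2478,
                            L_scale = 1e-6, ell0 = 1e-5, L_sys = 1.2e-3) {
  p <- list(gamma = gamma, gamma_c = gamma_c, e0 = e0, eta = eta,
            lambda_v = lambda_v, lambda_s = lambda_s, D = D, c0 = c0,
            p0 = p0, RT = RT, L_scale = L_scale, ell0 = ell0, L_sys = L_sys)
  pos <- c("gamma", "e0", "eta", "lambda_v", "lambda_s", "D", "c0", "RT",
           "L_scale", "ell0", "L_sys")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("physical parameter '", nm, "' must be a positive scalar")
  if (gamma_c < 0 || gamma_c >= 2 * gamma)
    stop("gamma_c must satisfy 0 <= gamma_c < 2 * gamma")
  structure(p, class = "physical_params")
}

#' Dimensionless control parameters of the lumen chain
#'
#' The dimensionless dynamics is controlled by the tension-to-osmotic
#' pressure ratio `epsilon = gamma * sin(theta) / (L_scale * Pi0)` (with
#' `Pi0 = RT * c0`), the screening numbers `chi_v = xi_v / ell0` and
#' `chi_s = xi_s / ell0`, the solvent and solute equilibration times `tau_v`
#' and `tau_s`, and the contact-angle shape factors `mu`, `nu`.
#'
#' Internally all lengths are measured in units of `L_scale` and times in
#' units of `tau_v`; `ell0bar = ell0 / L_scale` carries the bridge-length
#' scale so that the screening lengths in internal units are
#' `xi = chi * ell0bar`.
#'
#' @param epsilon tension-to-osmotic-pressure ratio (> 0; the linearized
#'   model assumes `epsilon << 1`, a warning is issued above 0.1).
#' @param chi_v,chi_s pressure and concentration screening numbers (> 0).
#' @param tau_v,tau_s solvent and solute equilibration times (same time
#'   unit; only the ratio `tau_s/tau_v` enters the dimensionless dynamics).
#' @param theta contact angle (radians).
#' @param ell0bar mean initial bridge length in units of `L_scale`.
#' @return An object of class `dimensionless_params`: named list with
#'   `epsilon, chi_v, chi_s, tau_v, tau_s, theta, mu, nu, ell0bar` and the
#'   internal screening lengths `xi_v, xi_s` (units of `L_scale`).
#' @export
#' @examples
#' dimensionless_params(epsilon = 1e-3, chi_v = 500, chi_s = 5)
dimensionless_params <- function(epsilon = 1e-3, chi_v = 1, chi_s = 1,
                                 tau_v = 1, tau_s = 1, theta = pi / 3,
                                 ell0bar = 10) {
  for (nm in c("chi_v", "chi_s", "tau_v", "tau_s", "ell0bar")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a positive finite scalar")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon < 0)
    stop("'epsilon' must be a non-negative finite scalar")
  if (epsilon > 0.1)
    warning("epsilon > 0.1: outside the validated small-tension regime")
  sf <- shape_factors(theta)
  structure(list(epsilon = epsilon, chi_v = chi_v, chi_s = chi_s,
                 tau_v = tau_v, tau_s = tau_s, theta = theta,
                 mu = sf$mu, nu = sf$nu, ell0bar = ell0bar,
                 xi_v = chi_v * ell0bar, xi_s = chi_s * ell0bar),
            class = "dimensionless_params")
}

#' Derive dimensionless groups and characteristic scales
#'
#' Computes from a [physical_params()] set the screening lengths
#' `xi_v = sqrt(kappa_v / (2 * lambda_v))` and
#' `xi_s = sqrt(D * e0 * c0 / (2 * lambda_s * RT))` (with the bridge
#' hydraulic conductivity `kappa_v = e0^3 / (12 * eta)`), the equilibration
#' times `tau_v = L_scale / (2 * lambda_v * Pi0)` and
#' `tau_s = L_scale * c0 / (2 * lambda_s * RT)`, the screening numbers
#' `chi = xi / ell0`, `epsilon`, the mole scale `N0 = c0 * L_scale^2`, the
#' hydraulic coarsening onset time
#' `Th = 2 * tau_v * ell0 * L_scale / (mu * epsilon * xi_v^2)` and the
#' pumping time `Tp = tau_v / (mu * nu * ja_bar)` (infinite at zero pumping).
#'
#' @param pp a [physical_params()] object.
#' @param ja_bar dimensionless active pumping rate (>= 0) used for `Tp`.
#' @return A list with the derived scales plus a `dimensionless_params`
#'   object under `$params`.
#' @export
dimensionless_groups <- function(pp, ja_bar = 0) {
  stopifnot(inherits(pp, "physical_params"), ja_bar >= 0)
  theta <- contact_angle(pp$gamma_c, pp$gamma)
  sf <- shape_factors(theta)
  Pi0 <- pp$RT * pp$c0
  kappa_v <- pp$e0^3 / (12 * pp$eta)
  xi_v <- sqrt(kappa_v / (2 * pp$lambda_v))
  xi_s <- sqrt(pp$D * pp$e0 * pp$c0 / (2 * pp$lambda_s * pp$RT))
  tau_v <- pp$L_scale / (2 * pp$lambda_v * Pi0)
  tau_s <- pp$L_scale * pp$c0 / (2 * pp$lambda_s * pp$RT)
  epsilon <- pp$gamma * sin(theta) / (pp$L_scale * Pi0)
  Th1 <- 2 * tau_v * pp$ell0 * pp$L_scale / (sf$mu * epsilon * xi_v^2)
  Th2 <- 2 * pp$ell0 * pp$L_scale^3 * 12 * pp$eta /
    (sf$mu * sin(theta) * pp$gamma * pp$e0^3)
  Tp <- if (ja_bar > 0) tau_v / (sf$mu * sf$nu * ja_bar) else Inf
  out <- list(theta = theta, mu = sf$mu, nu = sf$nu, Pi0 = Pi0,
              kappa_v = kappa_v, xi_v = xi_v, xi_s = xi_s,
              chi_v = xi_v / pp$ell0, chi_s = xi_s / pp$ell0,
              tau_v = tau_v, tau_s = tau_s, epsilon = epsilon,
              N0 = pp$c0 * pp$L_scale^2, Th = Th1, Th_alt = Th2, Tp = Tp)
  if (!all(vapply(out, is.finite, logical(1L)) | names(out) == "Tp"))
    stop("non-finite dimensionless group; check the physical parameter set")
  if (abs(Th1 - Th2) > 1e-12 * abs(Th1))
    stop("internal inconsistency between the two forms of Th")
  out$params <- dimensionless_params(
    epsilon = epsilon, chi_v = xi_v / pp$ell0, chi_s = xi_s / pp$ell0,
    tau_v = tau_v, tau_s = tau_s, theta = theta,
    ell0bar = pp$ell0 / pp$L_scale)
  out
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Physical parameters (SI units):\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat(sprintf(
    "Dimensionless parameters: epsilon=%g chi_v=%g chi_s=%g tau_s/tau_v=%g\n",
    x$epsilon, x$chi_v, x$chi_s, x$tau_s / x$tau_v))
  cat(sprintf("  theta=%.4f rad  mu=%.4f  nu=%.4f  ell0bar=%g\n",
              x$theta, x$mu, x$nu, x$ell0bar))
  invisible(x)
}
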