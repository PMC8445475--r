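#' Boundary condition of an intercellular bridge
#'
#' A bridge end either faces a lumen, which imposes Dirichlet values for the
#' dimensionless concentration jump `dC = (C - c0)/c0` and pressure jump
#' `dP = (P - p0)/Pi0`, or a sealed wall, which imposes zero flux.
#'
#' @param dC dimensionless concentration jump at the attached lumen.
#' @param dP dimensionless (Laplace) pressure jump at the attached lumen.
#' @param kind `"lumen"` or `"wall"`.
#' @return An object of class `bridge_boundary`.
#' @export
bridge_boundary <- function(dC = 0, dP = 0, kind = c("lumen", "wall")) {
  kind <- match.arg(kind)
  if (kind == "lumen" && (!is.finite(dC) || !is.finite(dP)))
    stop("lumen boundary values must be finite")
  structure(list(dC = dC, dP = dP, kind = kind), class = "bridge_boundary")
}

# stable ratios cosh(x/xi)/cosh(h/xi) and sinh(x/xi)/sinh(h/xi) for |x|<=h
.cosh_ratio <- function(x, h, xi) {
  (exp((x - h) / xi) + exp(-(x + h) / xi)) / (1 + exp(-2 * h / xi))
}
.sinh_ratio <- function(x, h, xi) {
  (exp((x - h) / xi) - exp(-(x + h) / xi)) / (1 - exp(-2 * h / xi))
}
# sinh(x/xi)/cosh(h/xi) and cosh(x/xi)/sinh(h/xi)
.sc_ratio <- function(x, h, xi) {
  (exp((x - h) / xi) - exp(-(x + h) / xi)) / (1 + exp(-2 * h / xi))
}
.cs_ratio <- function(x, h, xi) {
  (exp((x - h) / xi) + exp(-(x + h) / xi)) / (1 - exp(-2 * h / xi))
}

#' Solve the linearized quasi-static bridge equations
#'
#' Solves analytically, in dimensionless form, the screened diffusion and
#' screened Poiseuille equations along a bridge `x` in `[-ell/2, ell/2]`:
#' `xi_s^2 c'' = c - ja` (concentration, after linearizing the logarithmic
#' membrane exchange) and `xi_v^2 p'' = p - c` (pressure, with the
#' concentration profile as osmotic source), with Dirichlet data at lumen
#' ends taken from the adjacent lumens. Returns the four boundary fluxes
#' with the convention that a positive flux leaves the attached lumen:
#' solvent `J_v = -xi_v^2 * p'(x)` directed out of the lumen, solute
#' `J_s = -xi_s^2 * c'(x)` likewise.
#'
#' All lengths are in units of the lumen scale; `xi_v`, `xi_s` are the
#' screening lengths in those units (`chi * ell0bar`). Hyperbolic terms are
#' evaluated through `tanh`/shifted exponentials so that strongly screened
#' bridges (`ell >> xi`) do not overflow. When `xi_v` and `xi_s` are closer
#' than a relative 1e-6 the resonant (secular) particular solution
#' `x*sinh(x/xi)` is used for the pressure profile.
#'
#' @param left,right [bridge_boundary()] objects. A `"wall"` boundary
#'   imposes zero flux at that end (solved by the method of images).
#' @param ell bridge length (> 0).
#' @param xi_v,xi_s screening lengths (> 0), in lumen-scale units.
#' @param ja dimensionless active pumping rate of the bridge.
#' @return An object of class `bridge_solution`: list with the inputs, the
#'   profile coefficients, and fluxes `J_v_left`, `J_v_right`, `J_s_left`,
#'   `J_s_right` (positive = leaving the attached lumen; exactly 0 at a
#'   wall end).
#' @export
#' @examples
#' b <- solve_bridge(bridge_boundary(0.01, 0.002), bridge_boundary(-0.01, 0.001),
#'                   ell = 1, xi_v = 2, xi_s = 1)
#' c(b$J_v_left, b$J_v_right)
solve_bridge <- function(left, right, ell, xi_v, xi_s, ja = 0) {
  stopifnot(inherits(left, "bridge_boundary"), inherits(right, "bridge_boundary"))
  if (!is.finite(ell) || ell <= 0)
    stop("ell must be > 0 (a vanishing bridge signals a coalescence, not a solve)")
  if (xi_v <= 0 || xi_s <= 0) stop("screening lengths must be > 0")

  if (left$kind == "wall" && right$kind == "wall")
    stop("a bridge needs at least one lumen end")
  if (left$kind == "wall" || right$kind == "wall") {
    lum <- if (left$kind == "wall") right else left
    mir <- solve_bridge(bridge_boundary(lum$dC, lum$dP),
                        bridge_boundary(lum$dC, lum$dP),
                        2 * ell, xi_v, xi_s, ja)
    out <- mir
    out$ell <- ell
    out$wall_side <- if (left$kind == "wall") "left" else "right"
    out$mirrored <- TRUE
    if (left$kind == "wall") {
      out$J_v_left <- 0; out$J_s_left <- 0
      out$J_v_right <- mir$J_v_right; out$J_s_right <- mir$J_s_right
    } else {
      out$J_v_right <- 0; out$J_s_right <- 0
      out$J_v_left <- mir$J_v_left; out$J_s_left <- mir$J_s_left
    }
    return(out)
  }

  h <- ell / 2
  cm0 <- (left$dC + right$dC) / 2 - ja
  cd  <- (right$dC - left$dC) / 2
  pm  <- (left$dP + right$dP) / 2
  pd  <- (right$dP - left$dP) / 2

  Ts <- tanh(h / xi_s)
  Tv <- tanh(h / xi_v)

  degenerate <- abs(xi_v - xi_s) < 1e-6 * xi_s
  if (!degenerate) {
    r <- xi_s^2 / (xi_s^2 - xi_v^2)
    pm0 <- pm - ja - r * cm0
    pd0 <- pd - r * cd
    J_s_left  <- xi_s * (cm0 * Ts - cd / Ts)
    J_s_right <- xi_s * (cm0 * Ts + cd / Ts)
    J_v_left  <- r * xi_v^2 / xi_s * (cm0 * Ts - cd / Ts) +
      xi_v * (pm0 * Tv - pd0 / Tv)
    J_v_right <- r * xi_v^2 / xi_s * (cm0 * Ts + cd / Ts) +
      xi_v * (pm0 * Tv + pd0 / Tv)
    coef <- list(r = r, pm0 = pm0, pd0 = pd0)
  } else {
    xi <- xi_s
    # particular solution A*x*sinh(x/xi) + B*x*cosh(x/xi),
    # A = -a/(2 xi), B = -b/(2 xi) with a*cosh(h/xi) = cm0, b*sinh(h/xi) = cd
    AsinH  <- -cm0 * Ts / (2 * xi)         # A * sinh(h/xi)
    AhcosH <- -cm0 * h / (2 * xi^2)        # (A h / xi) * cosh(h/xi)
    BcosH  <- -cd / Ts / (2 * xi)          # B * cosh(h/xi)
    BhsinH <- -cd * h / (2 * xi^2)         # (B h / xi) * sinh(h/xi)
    pm0 <- pm - ja + cm0 * h * Ts / (2 * xi)      # ap * cosh(h/xi_v)
    pd0 <- pd + cd * h / (Ts * 2 * xi)            # bp * sinh(h/xi_v)
    dp_odd  <- AsinH + AhcosH + pm0 * Tv / xi_v   # odd part of p'(h)
    dp_even <- BcosH + BhsinH + pd0 / (Tv * xi_v) # even part of p'(h)
    J_s_left  <- xi_s * (cm0 * Ts - cd / Ts)
    J_s_right <- xi_s * (cm0 * Ts + cd / Ts)
    J_v_left  <- -xi_v^2 * (-dp_odd + dp_even)
    J_v_right <- xi_v^2 * (dp_odd + dp_even)
    coef <- list(pm0 = pm0, pd0 = pd0)
  }

  structure(list(left = left, right = right, ell = ell, xi_v = xi_v,
                 xi_s = xi_s, ja = ja, cm0 = cm0, cd = cd, pm = pm, pd = pd,
                 coef = coef, degenerate = degenerate, mirrored = FALSE,
                 J_v_left = J_v_left, J_v_right = J_v_right,
                 J_s_left = J_s_left, J_s_right = J_s_right),
            class = "bridge_solution")
}

#' Sealed-wall bridge
#'
#' Convenience wrapper for a bridge with a lumen at one end and the sealed
#' chain border at the other (zero-flux condition at the wall).
#'
#' @param lumen_side a `"lumen"` [bridge_boundary()].
#' @param ell bridge length.
#' @param xi_v,xi_s,ja as in [solve_bridge()].
#' @param wall_side `"right"` (default) or `"left"`: which end is sealed.
#' @return A `bridge_solution`; the flux at the wall end is exactly zero.
#' @export
wall_bridge <- function(lumen_side, ell, xi_v, xi_s, ja = 0,
                        wall_side = c("right", "left")) {
  wall_side <- match.arg(wall_side)
  wall <- bridge_boundary(kind = "wall")
  if (wall_side == "right") solve_bridge(lumen_side, wall, ell, xi_v, xi_s, ja)
  else solve_bridge(wall, lumen_side, ell, xi_v, xi_s, ja)
}

#' Evaluate the concentration and pressure profiles of a bridge solution
#'
#' @param sol a [solve_bridge()] result.
#' @param x positions in `[-ell/2, ell/2]` (lumen-scale units; for a wall
#'   bridge the wall sits at the sealed end of that interval).
#' @return data.frame with columns `x`, `dc` (concentration jump), `dp`
#'   (pressure jump).
#' @export
bridge_profile <- function(sol, x) {
  stopifnot(inherits(sol, "bridge_solution"))
  if (any(x < -sol$ell / 2 - 1e-12) || any(x > sol$ell / 2 + 1e-12))
    stop("x outside the bridge")
  if (isTRUE(sol$mirrored)) {
    # lumen end maps to the outer end of the doubled symmetric bridge
    xm <- if (sol$wall_side == "right") x - sol$ell / 2 else x + sol$ell / 2
    inner <- sol
    inner$mirrored <- FALSE
    inner$ell <- 2 * sol$ell
    prof <- bridge_profile(inner, xm)
    prof$x <- x
    return(prof)
  }
  h <- sol$ell / 2
  xs <- sol$xi_s; xv <- sol$xi_v
  Rc_s <- .cosh_ratio(x, h, xs); Rs_s <- .sinh_ratio(x, h, xs)
  dc <- sol$ja + sol$cm0 * Rc_s + sol$cd * Rs_s
  Rc_v <- .cosh_ratio(x, h, xv); Rs_v <- .sinh_ratio(x, h, xv)
  if (!sol$degenerate) {
    r <- sol$coef$r
    dp <- sol$ja + r * (sol$cm0 * Rc_s + sol$cd * Rs_s) +
      sol$coef$pm0 * Rc_v + sol$coef$pd0 * Rs_v
  } else {
    xi <- xs
    part <- -sol$cm0 * x / (2 * xi) * .sc_ratio(x, h, xi) -
      sol$cd * x / (2 * xi) * .cs_ratio(x, h, xi)
    dp <- sol$ja + part + sol$coef$pm0 * Rc_v + sol$coef$pd0 * Rs_v
  }
  data.frame(x = x, dc = dc, dp = dp)
}

# Thomas algorithm for a tridiagonal system (a: sub, b: diag, c: super)
.thomas <- function(a, b, d, rhs) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- d[1] / b[1]; dp[1] <- rhs[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i - 1] * cp[i - 1]
    cp[i] <- if (i < n) d[i] / m else 0
    dp[i] <- (rhs[i] - a[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Finite-difference oracle for the bridge equations
#'
#' Independent second-order finite-difference solve of the same linearized
#' two-point boundary value problem as [solve_bridge()], used to certify the
#' analytic solution. Boundary fluxes are computed from one-sided
#' second-order differences.
#'
#' @inheritParams solve_bridge
#' @param n_grid number of grid points (>= 100).
#' @return List with `J_v_left`, `J_v_right`, `J_s_left`, `J_s_right`,
#'   and the grid profiles `x`, `dc`, `dp`.
#' @export
fd_oracle_bridge <- function(left, right, ell, xi_v, xi_s, ja = 0,
                             n_grid = 1e4) {
  stopifnot(inherits(left, "bridge_boundary"), inherits(right, "bridge_boundary"))
  if (n_grid < 100) stop("n_grid must be >= 100")
  n <- as.integer(n_grid)
  x <- seq(-ell / 2, ell / 2, length.out = n)
  dx <- x[2] - x[1]

  solve_one <- function(xi, src, bl, br) {
    # xi^2 u'' - u = -src  on interior nodes
    a <- rep(xi^2 / dx^2, n - 1)
    b <- rep(-2 * xi^2 / dx^2 - 1, n)
    d <- rep(xi^2 / dx^2, n - 1)
    rhs <- -src
    if (bl$kind == "lumen") {
      b[1] <- 1; d[1] <- 0; rhs[1] <- bl$value
    } else {
      # zero-flux wall: centered ghost node u0 = u2, second-order accurate
      b[1] <- -2 * xi^2 / dx^2 - 1; d[1] <- 2 * xi^2 / dx^2; rhs[1] <- -src[1]
    }
    if (br$kind == "lumen") {
      b[n] <- 1; a[n - 1] <- 0; rhs[n] <- br$value
    } else {
      b[n] <- -2 * xi^2 / dx^2 - 1; a[n - 1] <- 2 * xi^2 / dx^2; rhs[n] <- -src[n]
    }
    .thomas(a, b, d, rhs)
  }

  bl_c <- list(kind = left$kind, value = left$dC)
  br_c <- list(kind = right$kind, value = right$dC)
  dc <- solve_one(xi_s, rep(ja, n), bl_c, br_c)
  bl_p <- list(kind = left$kind, value = left$dP)
  br_p <- list(kind = right$kind, value = right$dP)
  dp <- solve_one(xi_v, dc, bl_p, br_p)

  dleft  <- function(u) (-3 * u[1] + 4 * u[2] - u[3]) / (2 * dx)
  dright <- function(u) (3 * u[n] - 4 * u[n - 1] + u[n - 2]) / (2 * dx)
  list(J_s_left = if (left$kind == "wall") 0 else -xi_s^2 * dleft(dc),
       J_s_right = if (right$kind == "wall") 0 else xi_s^2 * dright(dc),
       J_v_left = if (left$kind == "wall") 0 else -xi_v^2 * dleft(dp),
       J_v_right = if (right$kind == "wall") 0 else xi_v^2 * dright(dp),
       x = x, dc = dc, dp = dp)
}
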