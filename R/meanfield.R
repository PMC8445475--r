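#' Hydraulic-chain right-hand side (mean-field limit)
#'
#' In the limit of weak pressure screening, fast solute relaxation and
#' strong concentration screening (`chi_v >> 1`, `tau_s << tau_v`,
#' `chi_s << 1`), osmotic effects drop out and the chain reduces to a pure
#' pressure-driven exchange dynamics of thin-film type:
#' `dL_i/dt = (1/Th) * sum_j 1/(ell_ij * L_i) * (1/L_j - 1/L_i)`,
#' the sum running over the (up to two) neighboring lumens, with the
#' bridge length (in units of the mean initial bridge length) acting as a
#' flow resistance. Written in area variables the pair term is
#' antisymmetric, so total area is conserved exactly between events.
#' Sealed chain ends exchange nothing.
#'
#' @param chain a `lumen_chain` (its `N` values are ignored).
#' @param Th hydraulic coarsening timescale; `NULL` derives
#'   `2*ell0bar/(mu*epsilon*xi_v^2)` (units of `tau_v`) from the chain
#'   parameters, the value at which this limit matches the full model.
#' @param Tp pumping timescale; `Inf` for no pumping.
#' @return Vector `dL/dt` per lumen.
#' @export
hydraulic_rhs <- function(chain, Th = NULL, Tp = Inf) {
  p <- chain$params
  if (is.null(Th)) Th <- 2 * p$ell0bar / (p$mu * p$epsilon * p$xi_v^2)
  lu <- chain$lumens
  n <- nrow(lu)
  ell <- bridge_lengths(chain) / p$ell0bar  # resistances in ell0 units
  if (any(ell[2:n] <= 0) && n > 1)
    stop("zero bridge length: coalescence must be handled by the caller")
  L <- lu$L
  dL <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    if (i > 1) s <- s + 1 / (ell[i] * L[i]) * (1 / L[i - 1] - 1 / L[i])
    if (i < n) s <- s + 1 / (ell[i + 1] * L[i]) * (1 / L[i + 1] - 1 / L[i])
    dL[i] <- s / Th
  }
  if (is.finite(Tp)) dL <- dL + 1 / Tp
  dL
}

#' Hydraulic chain with uniform active pumping
#'
#' Adds the pumping growth rate `1/Tp` to every lumen of the hydraulic
#' chain: `dL_i/dt = (exchange term) + 1/Tp`. For `t >> Tp` every lumen
#' grows at `1/Tp` and, centers being fixed, every bridge shrinks at
#' `2/Tp`, which drives the coalescence-dominated regime with
#' `N(t) ~ (t/Tp)^-1`.
#'
#' @inheritParams hydraulic_rhs
#' @return Vector `dL/dt` per lumen.
#' @export
pumped_hydraulic_rhs <- function(chain, Th = NULL, Tp) {
  stopifnot(is.finite(Tp), Tp > 0)
  hydraulic_rhs(chain, Th = Th, Tp = Tp)
}

#' Simulated self-similar size distribution of the hydraulic chain
#'
#' Long-time hydraulic-chain coarsening is self-similar: the distribution
#' of rescaled areas `A/A*` (with `A*` the mean area of the surviving
#' pool) becomes stationary. This function builds that reference
#' distribution empirically from an ensemble of hydraulic-chain
#' simulations, pooled at the snapshot where the surviving fraction is
#' closest to `surviving_frac`.
#'
#' @param n_chains number of realizations.
#' @param n0 initial lumens per chain.
#' @param surviving_frac target surviving fraction for the pooled
#'   snapshot (the scaling regime; default 0.2).
#' @param seed base seed; realization k uses `seed + k - 1`.
#' @param params chain parameters (defaults as in [generate_chain()]).
#' @param t_end integration horizon in units of `Th`.
#' @return List with `rescaled` (pooled `A/A*` values), `A_star`, `time`
#'   (per-realization snapshot times), `density` (a [stats::density()]
#'   fit) and `n_pooled`. Errors if fewer than 100 lumens are pooled.
#' @export
self_similar_reference <- function(n_chains = 20, n0 = 100,
                                   surviving_frac = 0.2, seed = 1,
                                   params = dimensionless_params(
                                     chi_v = 500, chi_s = 5),
                                   t_end = NULL) {
  Th <- 2 * params$ell0bar / (params$mu * params$epsilon * params$xi_v^2)
  if (is.null(t_end)) t_end <- 1e4 * Th * (n0 / 100)^2.5
  areas <- list(); times <- numeric(0)
  for (k in seq_len(n_chains)) {
    ch <- generate_chain(n0, seed = seed + k - 1, params = params)
    snap_t <- exp(seq(log(1e-3 * Th), log(t_end), length.out = 120))
    tr <- integrate_chain(ch, t_end, model = "hydraulic",
                          snapshot_times = snap_t)
    sn <- tr$snapshots
    if (is.null(sn)) next
    tt <- unique(sn$time)
    cnt <- tabulate(match(sn$time, tt))
    tgt <- tt[which.min(abs(cnt - surviving_frac * n0))]
    sel <- sn[sn$time == tgt, ]
    areas[[k]] <- sel$L^2 / params$mu
    times <- c(times, tgt)
  }
  pooled <- unlist(areas)
  if (length(pooled) < 100)
    stop("fewer than 100 pooled lumens; increase n_chains or n0")
  A_star <- mean(pooled)
  rescaled <- pooled / A_star
  list(rescaled = rescaled, A_star = A_star, time = times,
       density = stats::density(rescaled, bw = 0.15, from = 0),
       n_pooled = length(pooled))
}
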