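#' Default collapse / collision thresholds
#'
#' A lumen collapses when its half-length falls to 1% of the initial mean
#' half-length; two lumens collide (coalesce) when their bridge shortens to
#' 1% of the mean initial bridge length. The model itself gives no
#' microscopic cutoff; these are configurable numerical thresholds and the
#' acceptance-level results are checked to be insensitive to halving them.
#'
#' @param chain a `lumen_chain`.
#' @return list with `L_min` and `ell_min`.
#' @export
default_thresholds <- function(chain) {
  list(L_min = 1e-2 * mean(chain$lumens$L),
       ell_min = 1e-2 * chain$params$ell0bar)
}

#' Check a chain for threshold crossings
#'
#' @param chain a `lumen_chain`.
#' @param L_min,ell_min collapse and collision thresholds.
#' @return `NULL` when no threshold is crossed; otherwise a list with
#'   `kind` (`"collapse"` or `"coalescence"`), and participant indices.
#'   Collapses are reported before collisions, lowest index first.
#' @export
detect_events <- function(chain, L_min, ell_min) {
  iL <- which(chain$lumens$L <= L_min)
  if (length(iL))
    return(list(kind = "collapse", i = iL[1]))
  ell <- bridge_lengths(chain)
  jb <- which(ell <= ell_min)
  if (length(jb)) {
    j <- jb[1]
    n <- nrow(chain$lumens)
    if (j == 1L || j == n + 1L)
      return(list(kind = "wall_contact", bridge = j))
    return(list(kind = "coalescence", i = j - 1L, j = j))
  }
  NULL
}

#' Remove a collapsed lumen from a chain
#'
#' The lumen is deleted and its two adjacent bridges fuse into one of
#' combined length `ell_left + ell_right + 2*L_i` (automatic, since bridge
#' lengths are derived from the fixed geometry). The residual moles, bounded
#' by the collapse threshold scale, are discarded.
#'
#' @param chain a `lumen_chain`.
#' @param i index of the collapsing lumen.
#' @return The rewritten chain.
#' @export
apply_collapse <- function(chain, i) {
  n <- nrow(chain$lumens)
  stopifnot(i >= 1, i <= n)
  chain$lumens <- chain$lumens[-i, , drop = FALSE]
  jab <- chain$ja_bridge
  fused <- if (!is.null(chain$profile)) NA else (jab[i] + jab[i + 1]) / 2
  chain$ja_bridge <- c(jab[seq_len(i - 1)], fused,
                       if (i + 2 <= n + 1) jab[(i + 2):(n + 1)])
  .refresh_pumping(chain)
}

#' Merge two colliding lumens
#'
#' Coalescence is instantaneous and conserves the summed area and summed
#' moles of the participants: `A' = A_i + A_j`, `N' = N_i + N_j`,
#' `L' = sqrt(mu * A')`, centered at the area-weighted centroid of the
#' parents. Adjacent bridge lengths are recomputed from the geometry, so
#' the total chain length is conserved by construction.
#'
#' @param chain a `lumen_chain`.
#' @param i,j indices of the two adjacent lumens (`j = i + 1`).
#' @return The rewritten chain.
#' @export
apply_coalescence <- function(chain, i, j) {
  n <- nrow(chain$lumens)
  if (j != i + 1L) stop("can only merge adjacent lumens")
  lu <- chain$lumens
  mu <- chain$params$mu
  Ai <- lu$L[i]^2 / mu; Aj <- lu$L[j]^2 / mu
  xnew <- (Ai * lu$x[i] + Aj * lu$x[j]) / (Ai + Aj)
  Lnew <- sqrt(mu * (Ai + Aj))
  Nnew <- lu$N[i] + lu$N[j]
  janew <- (Ai * lu$ja[i] + Aj * lu$ja[j]) / (Ai + Aj)
  lu$x[i] <- xnew; lu$L[i] <- Lnew; lu$N[i] <- Nnew; lu$ja[i] <- janew
  chain$lumens <- lu[-j, , drop = FALSE]
  chain$ja_bridge <- chain$ja_bridge[-j]
  .refresh_pumping(chain)
}

# slide an end lumen off the sealed border: translating a center exchanges
# length between its two bridges, so total length is conserved exactly
.apply_wall_slide <- function(chain, bridge, ell_min) {
  n <- nrow(chain$lumens)
  lu <- chain$lumens
  ell <- bridge_lengths(chain)
  target <- ell_min + 0.04 * chain$params$ell0bar
  if (bridge == 1L) {
    slack <- ell[2] - 0.5 * ell_min     # keep the interior bridge open
    shift <- min(target - ell[1], slack)
    if (shift > 0) lu$x[1] <- lu$x[1] + shift
  } else {
    slack <- ell[n] - 0.5 * ell_min
    shift <- min(target - ell[n + 1], slack)
    if (shift > 0) lu$x[n] <- lu$x[n] - shift
  }
  chain$lumens <- lu
  .refresh_pumping(chain)
}

# re-evaluate pumping rates from an attached profile after a rewrite
.refresh_pumping <- function(chain) {
  if (is.null(chain$profile)) return(chain)
  chain$lumens$ja <- pumping_rate(chain$profile, chain$lumens$x / chain$L_sys)
  chain$ja_bridge <- pumping_rate(chain$profile,
                                  bridge_midpoints(chain) / chain$L_sys)
  chain
}

#' Bridge midpoint positions
#' @param chain a `lumen_chain`.
#' @return Positions of the `n + 1` bridge midpoints on `[0, L_sys]`.
#' @export
bridge_midpoints <- function(chain) {
  lu <- chain$lumens
  n <- nrow(lu)
  edges_l <- c(0, lu$x + lu$L)            # left ends of bridges 1..n+1
  edges_r <- c(lu$x - lu$L, chain$L_sys)  # right ends
  (edges_l + edges_r) / 2
}

.model_pars <- function(chain, model, Th, Tp) {
  p <- chain$params
  list(mu = p$mu, nu = p$nu, eps = p$epsilon, xiv = p$xi_v, xis = p$xi_s,
       tau_ratio = p$tau_s / p$tau_v, Lsys = chain$L_sys,
       model = if (model == "hydraulic") 1L else 0L,
       Th = if (is.null(Th)) 1 else Th,
       Tp = Tp, ell0bar = p$ell0bar)
}

#' Integrate a lumen chain with topological events
#'
#' Integrates the coupled lumen ODEs with an adaptive Runge-Kutta-Fehlberg
#' 4(5) scheme. After every accepted step the collapse (`L <= L_min`) and
#' collision (`ell <= ell_min`) thresholds are checked; a crossing is
#' localized by bisection on the step (relative time tolerance 1e-6), the
#' integration is halted, the chain is rewritten (lumen removal or merge)
#' and integration restarts. An end lumen reaching the sealed border slides
#' back toward the interior (centers are otherwise fixed); this conserves
#' total length and does not change the lumen count. Integration ends at
#' `t_end`, or early when one lumen remains (its endgame - growth if
#' `ja >= epsilon / L`, collapse otherwise - is recorded, not integrated)
#' or when all lumens have collapsed.
#'
#' @param chain initial `lumen_chain`.
#' @param t_end final time (units of `tau_v`).
#' @param rtol,atol relative and absolute step-error tolerances.
#' @param L_min,ell_min event thresholds; defaults from
#'   [default_thresholds()].
#' @param snapshot_times increasing times at which to record full chain
#'   snapshots (recorded at the first accepted step past each time).
#' @param record_steps record every accepted step (per-segment series);
#'   intended for small chains, e.g. fate classification.
#' @param model `"full"` (hydro-osmotic) or `"hydraulic"` (mean-field
#'   limit: pure pressure-driven exchange).
#' @param Th,Tp hydraulic and pumping timescales for the hydraulic model;
#'   `Th = NULL` derives `2*ell0bar/(mu*epsilon*xi_v^2)` (in `tau_v` units)
#'   from the chain parameters; `Tp = Inf` disables pumping growth.
#' @param h0 initial step size.
#' @param max_steps per-segment step budget.
#' @return An object of class `lumen_trajectory`: list with `events`
#'   (data.frame: time, kind, i, j, area_before, area_after, moles_before,
#'   moles_after, n_after), `snapshots` (long data.frame), `steps` (list of
#'   per-segment recordings), `final` chain, `n0`, `t0`, `t_end`,
#'   `survivor` (logical: did a final lumen survive), `status`, and
#'   integrator statistics.
#' @export
integrate_chain <- function(chain, t_end, rtol = 1e-6, atol = 1e-8,
                            L_min = NULL, ell_min = NULL,
                            snapshot_times = NULL, record_steps = FALSE,
                            model = c("full", "hydraulic"), Th = NULL,
                            Tp = Inf, h0 = 1e-6, max_steps = 5e6) {
  model <- match.arg(model)
  stopifnot(inherits(chain, "lumen_chain"), t_end > chain$time)
  thr <- default_thresholds(chain)
  if (is.null(L_min)) L_min <- thr$L_min
  if (is.null(ell_min)) ell_min <- thr$ell_min
  if (model == "hydraulic" && is.null(Th)) {
    if (chain$params$epsilon <= 0)
      stop("deriving Th requires epsilon > 0; pass Th explicitly")
    Th <- 2 * chain$params$ell0bar /
      (chain$params$mu * chain$params$epsilon * chain$params$xi_v^2)
  }
  pars <- .model_pars(chain, model, Th, Tp)

  n0 <- nrow(chain$lumens)
  t0 <- chain$time
  snap_pending <- sort(snapshot_times)
  events <- list(); snaps <- list(); steps <- list()
  n_acc <- 0; n_rej <- 0
  status <- "t_end"
  h <- h0

  repeat {
    n <- nrow(chain$lumens)
    if (n == 0L) { status <- "all_collapsed"; break }
    if (n == 1L) { status <- "single_lumen"; break }
    lu <- chain$lumens
    res <- integrate_segment_cpp(
      lu$L, lu$N, lu$x, lu$ja, chain$ja_bridge, pars,
      chain$time, t_end, rtol, atol, h, L_min, ell_min,
      if (length(snap_pending)) snap_pending else numeric(0),
      record_steps, max_steps)
    n_acc <- n_acc + res$n_accepted; n_rej <- n_rej + res$n_rejected
    if (length(res$snap_t)) {
      # several pending snapshot times crossed in one accepted step map to
      # the same recorded state; keep one snapshot per distinct step time
      keep <- !duplicated(res$snap_t)
      for (r in which(keep)) {
        st <- res$snaps[r, ]
        snaps[[length(snaps) + 1L]] <- data.frame(
          time = res$snap_t[r], id = lu$id, x = lu$x,
          L = st[seq_len(n)], N = st[n + seq_len(n)])
      }
      snap_pending <- snap_pending[-seq_along(res$snap_t)]
    }
    if (record_steps && length(res$rec_t)) {
      steps[[length(steps) + 1L]] <- list(
        ids = lu$id, t = res$rec_t,
        L = res$recs[, seq_len(n), drop = FALSE],
        N = res$recs[, n + seq_len(n), drop = FALSE])
    }
    chain$lumens$L <- res$L
    chain$lumens$N <- res$N
    chain$time <- res$t
    h <- max(res$h, h0 * 1e-3)
    if (res$status == 0) { status <- "t_end"; break }
    if (res$status != 1) {
      status <- c("2" = "step_failure", "3" = "max_steps",
                  "4" = "invalid_state")[as.character(res$status)]
      warning("integration stopped early: ", status, " at t = ", res$t)
      break
    }
    # apply the localized event and any cascade at the same time
    repeat {
      ev <- detect_events(chain, L_min, ell_min)
      if (is.null(ev) || nrow(chain$lumens) <= 1L) break
      lu <- chain$lumens
      mu <- chain$params$mu
      if (ev$kind == "collapse") {
        rec <- data.frame(time = chain$time, kind = "collapse",
                          i = lu$id[ev$i], j = NA_integer_,
                          area_before = lu$L[ev$i]^2 / mu, area_after = 0,
                          moles_before = lu$N[ev$i], moles_after = 0,
                          n_after = nrow(lu) - 1L)
        chain <- apply_collapse(chain, ev$i)
      } else if (ev$kind == "coalescence") {
        ab <- (lu$L[ev$i]^2 + lu$L[ev$j]^2) / mu
        nb <- lu$N[ev$i] + lu$N[ev$j]
        rec <- data.frame(time = chain$time, kind = "coalescence",
                          i = lu$id[ev$i], j = lu$id[ev$j],
                          area_before = ab, moles_before = nb,
                          n_after = nrow(lu) - 1L)
        chain <- apply_coalescence(chain, ev$i, ev$j)
        k <- ev$i
        rec$area_after <- chain$lumens$L[k]^2 / mu
        rec$moles_after <- chain$lumens$N[k]
        rec <- rec[, c("time", "kind", "i", "j", "area_before", "area_after",
                       "moles_before", "moles_after", "n_after")]
      } else { # wall_contact: slide inward; count unchanged
        end_i <- if (ev$bridge == 1L) 1L else nrow(lu)
        trial <- .apply_wall_slide(chain, ev$bridge, ell_min)
        ell2 <- bridge_lengths(trial)
        wb <- if (ev$bridge == 1L) ell2[1] else ell2[length(ell2)]
        if (wb > ell_min) {
          rec <- data.frame(time = chain$time, kind = "wall_contact",
                            i = lu$id[end_i], j = NA_integer_,
                            area_before = NA_real_, area_after = NA_real_,
                            moles_before = NA_real_, moles_after = NA_real_,
                            n_after = nrow(lu))
          chain <- trial
        } else {
          # no interior slack left: the end lumen absorbs its neighbor
          pair <- if (ev$bridge == 1L) c(1L, 2L) else
            c(nrow(lu) - 1L, nrow(lu))
          ab <- (lu$L[pair[1]]^2 + lu$L[pair[2]]^2) / mu
          nb <- lu$N[pair[1]] + lu$N[pair[2]]
          rec <- data.frame(time = chain$time, kind = "coalescence",
                            i = lu$id[pair[1]], j = lu$id[pair[2]],
                            area_before = ab, area_after = NA_real_,
                            moles_before = nb, moles_after = NA_real_,
                            n_after = nrow(lu) - 1L)
          chain <- apply_coalescence(chain, pair[1], pair[2])
          rec$area_after <- chain$lumens$L[pair[1]]^2 / mu
          rec$moles_after <- chain$lumens$N[pair[1]]
        }
      }
      events[[length(events) + 1L]] <- rec
    }
    if (chain$time >= t_end) { status <- "t_end"; break }
  }

  survivor <- FALSE
  if (nrow(chain$lumens) == 1L) {
    lu <- chain$lumens
    survivor <- if (model == "hydraulic") TRUE else
      lu$ja[1] >= chain$params$epsilon / lu$L[1]
  }

  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), kind = character(0), i = integer(0),
               j = integer(0), area_before = numeric(0),
               area_after = numeric(0), moles_before = numeric(0),
               moles_after = numeric(0), n_after = integer(0))
  snap_df <- if (length(snaps)) do.call(rbind, snaps) else NULL
  if (!is.null(snap_df))
    snap_df$C <- chain$params$mu * snap_df$N / snap_df$L^2

  structure(list(events = ev_df, snapshots = snap_df, steps = steps,
                 final = chain, n0 = n0, t0 = t0, t_end = t_end,
                 model = model, survivor = survivor, status = status,
                 n_accepted = n_acc, n_rejected = n_rej,
                 L_min = L_min, ell_min = ell_min),
            class = "lumen_trajectory")
}

#' Lumen count as a step function of time
#'
#' Reconstructed exactly from the event log: the count starts at `n0` and
#' decreases by one at each collapse or coalescence.
#'
#' @param traj a `lumen_trajectory`.
#' @return data.frame with columns `time` and `n` (count right after each
#'   change), starting at `(t0, n0)`.
#' @export
lumen_count <- function(traj) {
  ev <- traj$events
  ev <- ev[ev$kind %in% c("collapse", "coalescence"), , drop = FALSE]
  data.frame(time = c(traj$t0, ev$time), n = c(traj$n0, ev$n_after))
}

#' @export
print.lumen_trajectory <- function(x, ...) {
  nev <- sum(x$events$kind %in% c("collapse", "coalescence"))
  cat(sprintf(
    "Lumen trajectory (%s model): %d -> %d lumens, %d events, t in [%.3g, %.3g]\n",
    x$model, x$n0, nrow(x$final$lumens), nev, x$t0, x$final$time))
  cat(sprintf("  status: %s; steps accepted %d, rejected %d\n",
              x$status, x$n_accepted, x$n_rejected))
  invisible(x)
}
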