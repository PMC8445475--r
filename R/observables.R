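#' Log-binned ensemble average of the lumen count
#'
#' Each realization yields an exact step function N(t) from its event log.
#' Because adaptive time-stepping gives every realization its own time
#' grid, the ensemble is averaged at predefined log-spaced time points:
#' geometric bin centers spanning (by default) the union of event times
#' across the ensemble. Realizations are carried as constants outside
#' their own event range (N = n0 before the first event, final count after
#' termination).
#'
#' @param trajectories list of `lumen_trajectory` objects.
#' @param n_bins number of log-spaced bins (default 60).
#' @param t_range optional `c(tmin, tmax)` overriding the automatic range.
#' @return data.frame of class `ensemble_summary` with columns `time`
#'   (bin centers), `n_mean`, `n_sd`, `n_realizations`.
#' @export
lumen_count_series <- function(trajectories, n_bins = 60, t_range = NULL) {
  stopifnot(length(trajectories) >= 1)
  counts <- lapply(trajectories, lumen_count)
  if (is.null(t_range)) {
    evt <- unlist(lapply(counts, function(cc) cc$time[-1]))
    if (!length(evt)) stop("no events in the ensemble; nothing to bin")
    t_range <- range(evt)
  }
  if (t_range[1] <= 0) t_range[1] <- min(c(1e-6, t_range[2] / 1e4))
  centers <- exp(seq(log(t_range[1]), log(t_range[2]),
                     length.out = n_bins))
  vals <- vapply(counts, function(cc) {
    stats::approx(cc$time, cc$n, xout = centers, method = "constant",
                  f = 0, rule = 2)$y
  }, numeric(n_bins))
  vals <- matrix(vals, nrow = n_bins)
  out <- data.frame(time = centers,
                    n_mean = rowMeans(vals),
                    n_sd = if (ncol(vals) > 1) apply(vals, 1, stats::sd)
                           else rep(NA_real_, n_bins),
                    n_realizations = length(trajectories))
  class(out) <- c("ensemble_summary", "data.frame")
  out
}

#' Power-law exponent of the averaged lumen count
#'
#' Least-squares slope of `log N` versus `log t` over an explicit time
#' window of an [lumen_count_series()] summary. Window selection is a
#' deliberate user input (recorded in the result); there is no automatic
#' regime detection.
#'
#' @param series an `ensemble_summary`.
#' @param window `c(tmin, tmax)` time window to fit.
#' @return List with `exponent`, `stderr`, `n_bins`, `window`.
#' @export
fit_power_law <- function(series, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  sel <- series$time >= window[1] & series$time <= window[2] &
    is.finite(series$n_mean) & series$n_mean > 0
  if (sum(sel) < 5) stop("fewer than 5 bins in the fit window")
  fit <- stats::lm(log(n_mean) ~ log(time), data = series[sel, ])
  list(exponent = unname(stats::coef(fit)[2]),
       stderr = unname(sqrt(diag(stats::vcov(fit)))[2]),
       n_bins = sum(sel), window = window)
}

#' Pooled lumen area distribution at a common time
#'
#' Pools, across realizations, the snapshot closest to the requested time
#' (each realization contributes its own nearest recorded snapshot) and
#' returns the normalized histogram of areas, by default rescaled by the
#' pooled mean area `A* = mean(A)`.
#'
#' @param trajectories list of `lumen_trajectory` objects that were run
#'   with `snapshot_times`.
#' @param time target time.
#' @param rescale divide areas by the pooled mean (`A/A*`).
#' @param breaks passed to [graphics::hist()] logic via [base::cut()];
#'   either a count or a vector of break points.
#' @return List with `areas` (pooled, possibly rescaled), `A_star`,
#'   `density` (normalized histogram as data.frame `mid`, `density`),
#'   `n_pooled`, `times` (per-realization snapshot times actually used).
#' @export
area_distribution <- function(trajectories, time, rescale = TRUE,
                              breaks = 30) {
  pool <- list(); times <- numeric(0)
  for (tr in trajectories) {
    sn <- tr$snapshots
    if (is.null(sn)) next
    tt <- unique(sn$time)
    tbest <- tt[which.min(abs(tt - time))]
    sel <- sn[sn$time == tbest, ]
    pool[[length(pool) + 1L]] <- sel$L^2 / tr$final$params$mu
    times <- c(times, tbest)
  }
  A <- unlist(pool)
  if (length(A) < 100)
    stop("fewer than 100 pooled lumens at the requested time")
  A_star <- mean(A)
  v <- if (rescale) A / A_star else A
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(areas = v, A_star = A_star,
       density = data.frame(mid = h$mids, density = h$density),
       n_pooled = length(A), times = times)
}

#' Count the modes of a smoothed distribution
#'
#' Helper for multimodality checks: fits a fixed-bandwidth kernel density
#' and counts its interior local maxima.
#'
#' @param x sample values.
#' @param bw kernel bandwidth (fixed, recorded by the caller).
#' @return Number of local maxima of the smoothed density.
#' @export
count_modes <- function(x, bw = 0.25) {
  d <- stats::density(x, bw = bw, from = 0, to = max(x) * 1.1, n = 512)
  y <- d$y
  sum(diff(sign(diff(y))) == -2)
}

#' Distribution of the final-lumen position
#'
#' For an ensemble of chain realizations, collects the center position of
#' the surviving lumen (normalized by the chain length) over realizations
#' that terminated with exactly one survivor; all-collapse realizations
#' are excluded and counted.
#'
#' @param trajectories list of `lumen_trajectory` objects.
#' @param breaks histogram breaks on `[0, 1]` (count or vector).
#' @return List with `positions`, `histogram` (data.frame `mid`,
#'   `density`), `n_survived`, `n_collapsed`, `n_other` (realizations that
#'   hit `t_end` with more than one lumen).
#' @export
final_position_distribution <- function(trajectories,
                                        breaks = seq(0, 1, by = 0.05)) {
  pos <- numeric(0); n_surv <- 0L; n_coll <- 0L; n_other <- 0L
  for (tr in trajectories) {
    nfin <- nrow(tr$final$lumens)
    if (nfin == 1L && tr$survivor) {
      pos <- c(pos, tr$final$lumens$x[1] / tr$final$L_sys)
      n_surv <- n_surv + 1L
    } else if (nfin == 0L || (nfin == 1L && !tr$survivor)) {
      n_coll <- n_coll + 1L
    } else n_other <- n_other + 1L
  }
  h <- if (length(pos)) graphics::hist(pos, breaks = breaks, plot = FALSE)
  list(positions = pos,
       histogram = if (length(pos))
         data.frame(mid = h$mids, density = h$density) else NULL,
       n_survived = n_surv, n_collapsed = n_coll, n_other = n_other)
}
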