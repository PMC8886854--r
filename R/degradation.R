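# Degradation kinetics: degradation-time measurement from FRET ramps, pause
# detection, single-turnover completeness, before/after FRET histograms and
# the processive-vs-distributive classification from the concentration
# dependence of degradation times.

# median-filter helper tolerant of short inputs
run_median <- function(x, window = 3) {
  if (length(x) < window || window < 2) return(x)
  stats::runmed(x, k = window, endrule = "median")
}

running_mean <- function(x, w) {
  if (w <= 1 || length(x) < w) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  # fill the filter's edge NAs with the nearest computed value
  first <- which(!is.na(y))[1]
  last <- max(which(!is.na(y)))
  y[seq_len(first - 1)] <- y[first]
  if (last < length(y)) y[(last + 1):length(y)] <- y[last]
  y
}

#' Measure the degradation time of a FRET ramp
#'
#' The degradation period ends at the first persistent crossing of
#' `E_end - frac * range` and starts at the final departure from the start
#' plateau before that point (the last frame below `E_start + frac * range`
#' preceding the end crossing), both evaluated on a median-filtered FRET
#' series (default window 3, persistence 3 frames).  Anchoring the start to
#' the last low frame rather than the first high one keeps enzyme-waiting
#' time on the start plateau - which scales as 1/concentration - from
#' leaking into the measured duration through noise flicker.  A trace that
#' never leaves the start plateau yields a no-event result rather than an
#' error.
#'
#' @param series A `fret_series` from a degradation-mode experiment.
#' @param E_start,E_end FRET anchors of the intact and fully degraded
#'   substrate.
#' @param frac Threshold fraction of the range (default 0.1, i.e. 10%/90%
#'   crossings).
#' @param persistence Frames a crossing must persist (default 3).
#' @param median_window Median filter window (default 3).
#' @param completion_halfwidth Half-width of the completion window around
#'   `E_end` (default 0.06).
#' @return A `degradation_event`: `t_start`, `t_end`, `duration`,
#'   `completed`, `E_final`, `no_event`.
#' @export
measure_degradation_time <- function(series, E_start, E_end, frac = 0.1,
                                     persistence = 3, median_window = 3,
                                     completion_halfwidth = 0.06) {
  dt <- as.numeric(series$meta$frame_interval_s)
  E <- series$E[series$valid]
  Em <- run_median(E, median_window)
  n <- length(Em)
  rng <- E_end - E_start
  lo <- E_start + frac * rng
  hi <- E_end - frac * rng
  up <- sign(rng) >= 0

  persistent_cross <- function(x, thr, from = 1L) {
    hitx <- if (up) x >= thr else x <= thr
    if (from > 1L) hitx[seq_len(from - 1L)] <- FALSE
    r <- rle(hitx)
    ends <- cumsum(r$lengths)
    i <- which(r$values & r$lengths >= persistence)
    if (!length(i)) return(NA_integer_)
    ends[i[1]] - r$lengths[i[1]] + 1L
  }

  last_k <- min(10L, n)
  E_final <- mean(E[(n - last_k + 1L):n])
  i_lo <- persistent_cross(Em, lo)
  if (is.na(i_lo)) {
    return(structure(list(t_start = NA_real_, t_end = NA_real_,
                          duration = NA_real_, completed = FALSE,
                          E_final = E_final, no_event = TRUE,
                          frame_interval = dt),
                     class = "degradation_event"))
  }
  i_end <- persistent_cross(Em, hi, from = i_lo)
  if (is.na(i_end)) {
    i_start <- i_lo
  } else {
    low_before <- which(if (up) Em < lo else Em > lo)
    low_before <- low_before[low_before < i_end]
    i_start <- if (length(low_before)) max(low_before) + 1L else 1L
  }
  t_start <- (i_start - 1L) * dt
  t_end <- if (is.na(i_end)) NA_real_ else (i_end - 1L) * dt
  completed <- abs(E_final - E_end) <= completion_halfwidth
  structure(list(t_start = t_start, t_end = t_end,
                 duration = t_end - t_start,
                 completed = completed, E_final = E_final,
                 no_event = FALSE, frame_interval = dt),
            class = "degradation_event")
}

#' Detect pauses within a degradation period
#'
#' A pause is a maximal interval inside the degradation period over which
#' the smoothed FRET signal has slope magnitude below a threshold for at
#' least `min_duration` seconds.  The local slope is a central difference of
#' the boxcar-smoothed, median-filtered series; because per-frame slope
#' estimates on noisy data are themselves noisy, the effective threshold is
#' `max(eps, 3 x sigma_slope)` where `sigma_slope` is propagated from a
#' robust (median-absolute-difference) estimate of the frame-to-frame FRET
#' noise, so that a flat segment is not broken up by noise.
#'
#' @param series A `fret_series`.
#' @param event The `degradation_event` delimiting the degradation period
#'   (from [measure_degradation_time()]); traces with `no_event` return an
#'   empty pause table.
#' @param eps Slope floor in FRET/s (default 0.005).
#' @param min_duration Minimum pause duration in seconds (default 1).
#' @param median_window Median filter window (default 3).
#' @param smooth_seconds Boxcar/difference half-window in seconds
#'   (default 0.5).
#' @return Data frame of pauses: `start`, `duration` (seconds).
#' @export
detect_pauses <- function(series, event, eps = 0.005, min_duration = 1,
                          median_window = 3, smooth_seconds = 0.5) {
  empty <- data.frame(start = numeric(0), duration = numeric(0))
  if (isTRUE(event$no_event) || is.na(event$t_end)) return(empty)
  dt <- as.numeric(series$meta$frame_interval_s)
  E <- series$E[series$valid]
  Em <- run_median(E, median_window)
  w <- max(1L, round(smooth_seconds / dt))
  S <- running_mean(Em, w)
  n <- length(S)
  L <- w
  slope <- rep(NA_real_, n)
  idx <- (L + 1L):(n - L)
  if (length(idx) < 1) return(empty)
  slope[idx] <- (S[idx + L] - S[idx - L]) / (2 * L * dt)
  # robust frame-to-frame noise -> slope noise after smoothing/differencing
  sigma_E <- 1.4826 * stats::median(abs(diff(E))) / sqrt(2)
  sigma_slope <- sqrt(2) * (sigma_E / sqrt(w)) / (2 * L * dt)
  thr <- max(eps, 3 * sigma_slope)

  i0 <- max(1L, floor(event$t_start / dt) + 1L)
  i1 <- min(n, floor(event$t_end / dt) + 1L)
  flat <- !is.na(slope) & abs(slope) < thr
  flat[-(i0:i1)] <- FALSE
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # runs clipped by the period boundaries are censored and excluded
  keep <- which(r$values & r$lengths * dt >= min_duration &
                  starts > i0 & ends < i1)
  data.frame(start = (starts[keep] - 1L) * dt,
             duration = r$lengths[keep] * dt)
}

#' Fraction of single-turnover molecules with complete degradation
#'
#' @param events List of `degradation_event` objects (one per molecule).
#' @param E_end Fully-degraded FRET anchor.
#' @param halfwidth Completion window half-width (default 0.06).
#' @return List with `fraction`, `n` and `sem` (binomial standard error).
#' @export
completeness_fraction <- function(events, E_end, halfwidth = 0.06) {
  if (!length(events)) stop("completeness_fraction() needs at least one event")
  ok <- vapply(events, function(e) abs(e$E_final - E_end) <= halfwidth,
               logical(1))
  n <- length(ok)
  f <- mean(ok)
  list(fraction = f, n = n, sem = stats::sd(ok) / sqrt(n))
}

#' Classify degradation as processive or distributive
#'
#' Fits the mechanistic concentration-dependence model
#' `t(C) = t0 + a / C` to per-molecule degradation times by least squares:
#' a distributive enzyme pays a rebinding wait proportional to `1/C` for
#' every dissociation, while a processive enzyme's time is concentration
#' independent.  The verdict is `"distributive"` iff the lower bound of the
#' bootstrap 95% confidence interval for `a` exceeds zero (case resampling
#' within each concentration, 1000 replicates by default).
#'
#' @param times Data frame with columns `concentration` (nM) and `time` (s),
#'   one row per degradation event.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap resampling.
#' @return A `mode_classification`: `fit` (`t0`, `a`), `ci_a`, `verdict`,
#'   per-concentration summary and residual standard error.
#' @export
classify_mode <- function(times, n_boot = 1000, seed = 1) {
  concs <- sort(unique(times$concentration))
  if (length(concs) < 3) {
    stop("classify_mode() needs at least 3 concentrations (got ",
         length(concs), ")")
  }
  if (max(concs) / min(concs) < 10) {
    stop("concentrations must span at least one order of magnitude")
  }
  fit_once <- function(d) {
    f <- stats::lm(time ~ I(1 / concentration), data = d)
    stats::setNames(stats::coef(f), c("t0", "a"))
  }
  co <- fit_once(times)
  boot <- with_local_seed(seed, {
    idx_by_c <- split(seq_len(nrow(times)), times$concentration)
    t(vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(idx_by_c, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }))
      fit_once(times[take, , drop = FALSE])
    }, numeric(2)))
  })
  ci_a <- stats::quantile(boot[, 2], c(0.025, 0.975), names = FALSE)
  per_conc <- do.call(rbind, lapply(concs, function(cc) {
    x <- times$time[times$concentration == cc]
    s <- sem(x)
    data.frame(concentration = cc, mean = s$mean, sem = s$sem, n = s$n)
  }))
  resid_se <- stats::sd(stats::residuals(
    stats::lm(time ~ I(1 / concentration), data = times)))
  structure(list(fit = co,
                 ci_a = ci_a,
                 verdict = if (ci_a[1] > 0) "distributive" else "processive",
                 per_concentration = per_conc,
                 residual_se = resid_se,
                 n_boot = n_boot),
            class = "mode_classification")
}

#' FRET histogram before or after the reaction
#'
#' Histogram of the per-molecule mean FRET over the first (`"before"`) or
#' last (`"after"`) `n_frames` valid frames.
#'
#' @param series_list List of `fret_series`.
#' @param at `"before"` or `"after"`.
#' @param n_frames Frames averaged per molecule (default 10).
#' @param bin_width Histogram bin width (default 0.02).
#' @return List with `breaks`, `counts` and the per-molecule `means`.
#' @export
fret_histogram <- function(series_list, at = c("before", "after"),
                           n_frames = 10, bin_width = 0.02) {
  at <- match.arg(at)
  if (!length(series_list)) stop("fret_histogram() needs at least one trace")
  means <- vapply(series_list, function(s) {
    E <- s$E[s$valid]
    k <- min(n_frames, length(E))
    if (at == "before") mean(E[seq_len(k)])
    else mean(E[(length(E) - k + 1L):length(E)])
  }, numeric(1))
  breaks <- seq(0, 1, by = bin_width)
  counts <- as.integer(table(cut(pmin(pmax(means, 0), 1 - 1e-12),
                                 breaks = breaks, include.lowest = TRUE)))
  list(breaks = breaks, counts = counts, means = means)
}

#' @export
print.mode_classification <- function(x, ...) {
  cat(sprintf(
    "<mode_classification> verdict: %s  (t0 = %.3g s, a = %.3g s*nM, 95%% CI [%.3g, %.3g])\n",
    x$verdict, x$fit["t0"], x$fit["a"], x$ci_a[1], x$ci_a[2]))
  invisible(x)
}

#' @export
print.degradation_event <- function(x, ...) {
  if (x$no_event) {
    cat("<degradation_event> no event (trace stayed on the start plateau)\n")
  } else {
    cat(sprintf(
      "<degradation_event> %.2f -> %.2f s (duration %.2f s), %scomplete (E_final = %.2f)\n",
      x$t_start, x$t_end, x$duration, if (x$completed) "" else "in",
      x$E_final))
  }
  invisible(x)
}
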