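# Trajectory idealization: FRET efficiency from intensities, discrete-state
# segmentation (fixed thresholds or Gaussian HMM + Viterbi) and dwell-time
# extraction with censoring flags.

# default cut-points for binding assays: unbound below 0.15, then site-class
# windows centred between the FRET anchors 0.05 / 0.38 / 0.48 / 0.77
DEFAULT_BINDING_THRESHOLDS <- c(0.15, 0.25, 0.43, 0.62, 0.90)

#' Compute FRET efficiency from a trace
#'
#' Proximity-ratio FRET: `E = (I_A - bg_A) / ((I_A - bg_A) + (I_D - bg_D))`,
#' clipped to `[0, 1]`.  When the trace ends in a persistent low-intensity
#' tail (donor bleach), the per-channel background is estimated from that
#' tail and frames from the bleach point on are masked; otherwise the
#' supplied constants are used.  The valid mask is contiguous from the start.
#'
#' @param trace A `fret_trace`.
#' @param background_donor,background_acceptor Background constants (counts)
#'   used when no bleach tail is present.
#' @param min_total Total-intensity floor below which frames count as dark;
#'   default is 30% of the median total intensity.
#' @return A `fret_series` with `E`, `valid` mask and inherited `meta`.
#' @export
compute_fret <- function(trace, background_donor = 0,
                         background_acceptor = 0, min_total = NULL) {
  total <- trace$donor + trace$acceptor
  n <- length(total)
  if (n == 0) stop("no usable frames: empty trace")
  if (is.null(min_total)) min_total <- 0.3 * stats::median(total)
  low <- total < min_total
  bgD <- background_donor
  bgA <- background_acceptor
  n_valid <- n
  # persistent terminal low run = donor bleach; estimate background from it
  if (low[n]) {
    r <- rle(low)
    tail_len <- r$lengths[length(r$lengths)]
    if (tail_len >= 5) {
      idx <- (n - tail_len + 1L):n
      bgD <- mean(trace$donor[idx])
      bgA <- mean(trace$acceptor[idx])
      n_valid <- n - tail_len
    }
  } else {
    # interior persistent dark run also truncates the usable region
    r <- rle(low)
    ends <- cumsum(r$lengths)
    dark <- which(r$values & r$lengths >= 3)
    if (length(dark)) n_valid <- ends[dark[1]] - r$lengths[dark[1]]
  }
  if (n_valid < 1) stop("no usable frames: trace is dark throughout")
  d <- trace$donor - bgD
  a <- trace$acceptor - bgA
  E <- a / (a + d)
  E[!is.finite(E)] <- 0
  E <- pmin(pmax(E, 0), 1)
  valid <- seq_len(n) <= n_valid
  structure(list(E = E, valid = valid, meta = trace$meta),
            class = "fret_series")
}

#' Idealize a FRET series into discrete states
#'
#' Two interchangeable methods returning the same structure:
#'
#' * `threshold`: fixed cut-points partition E frame-wise into states,
#'   followed by a spike filter that merges adjacent dwells whose mean
#'   levels are statistically indistinguishable given the frame noise
#'   (removing the single-frame and boundary-flicker spikes that cut-point
#'   binning produces), leaving genuine short excursions intact.
#' * `hmm`: Gaussian-emission hidden Markov model with `n_states` states,
#'   parameters fitted by EM from a deterministic quantile initialisation,
#'   state path by Viterbi.
#'
#' @param series A `fret_series`.
#' @param method `"threshold"` or `"hmm"`.
#' @param thresholds Cut-points for the threshold method; default
#'   `c(0.15, 0.25, 0.43, 0.62, 0.90)` (binding-assay windows).
#' @param n_states Number of states for the HMM method.
#' @return An `idealized_trace` with per-frame `state_sequence` (indices into
#'   the ascending `state_levels`), `transitions` table and `method`.
#' @export
idealize <- function(series, method = c("threshold", "hmm"),
                     thresholds = DEFAULT_BINDING_THRESHOLDS,
                     n_states = NULL) {
  method <- match.arg(method)
  E <- series$E[series$valid]
  if (length(E) < 10) stop("idealize() needs at least 10 valid frames")
  if (method == "threshold") {
    states <- findInterval(E, sort(thresholds)) + 1L
  } else {
    if (is.null(n_states)) stop("hmm method needs n_states")
    fit <- fit_ghmm(E, n_states)
    states <- viterbi_ghmm(E, fit)
  }
  states <- clean_state_runs(states, E)
  # relabel occupied states by ascending observed mean level
  levels_raw <- tapply(E, states, mean)
  ord <- order(levels_raw)
  relabel <- integer(max(states))
  relabel[as.integer(names(levels_raw))[ord]] <- seq_along(ord)
  states <- relabel[states]
  state_levels <- as.numeric(levels_raw[ord])

  dt <- as.numeric(series$meta$frame_interval_s)
  cp <- which(diff(states) != 0)
  transitions <- data.frame(
    time = cp * dt,
    E_before = state_levels[states[cp]],
    E_after = state_levels[states[cp + 1L]])
  structure(
    list(state_sequence = states,
         state_levels = state_levels,
         transitions = transitions,
         method = method,
         frame_interval = dt,
         meta = series$meta),
    class = "idealized_trace")
}

# Dwell-sequence cleanup shared by both idealization methods.  Two
# artifact classes of frame-integrated data are removed:
#
# 1. Noise flicker: cut-point binning (and occasionally Viterbi) splits a
#    dwell whenever its level sits within a couple of noise sd of a state
#    boundary.  Adjacent runs whose mean FRET levels are statistically
#    indistinguishable (two-sample z below `nsigma` given the robust frame
#    noise) are merged.  nsigma = 4.5 keeps the expected number of chance
#    splits well below one per trace at typical lengths (~10^3 frames),
#    while genuine excursions (an unbound gap, a hop to another site) differ
#    from their neighbours by many sigma and survive.
# 2. Transition frames: a state change occurring mid-frame renders one frame
#    at an occupancy-weighted intermediate level, which otherwise appears as
#    a spurious one-frame state.  Single-frame runs whose level lies
#    strictly between their neighbours' levels are camera blur and are
#    merged into the closer neighbour; so are single-frame runs lying below
#    two bound neighbours (a sub-frame unbound gap, which an uncorrected
#    idealization cannot resolve).  Runs of the lowest (unbound) state are
#    exempt, so genuine resolved gaps are never removed.
clean_state_runs <- function(states, E, nsigma = 4.5, max_pass = 50) {
  sigma <- 1.4826 * stats::median(abs(diff(E))) / sqrt(2)
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    # --- statistical merge pass (batched) ---
    if (is.finite(sigma) && sigma > 0) {
      r <- rle(states)
      k <- length(r$lengths)
      if (k > 1) {
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        means <- vapply(seq_len(k),
                        function(i) mean(E[starts[i]:ends[i]]), numeric(1))
        lv <- tapply(E, states, mean)
        bottom <- as.integer(names(lv))[which.min(lv)]
        ratio <- abs(diff(means)) /
          (nsigma * sigma * sqrt(1 / r$lengths[-k] + 1 / r$lengths[-1]))
        cand <- which(ratio < 1)
        if (length(cand)) {
          touched <- logical(k)
          merged_any <- FALSE
          for (i in cand[order(ratio[cand])]) {
            if (touched[i] || touched[i + 1]) next
            is_bot <- c(r$values[i] == bottom, r$values[i + 1] == bottom)
            if (xor(is_bot[1], is_bot[2])) {
              # mixed pair: a short noise excursion is absorbed into the
              # unbound state, but a short unbound run (a resolved
              # dissociation gap) is never absorbed into a bound dwell
              bot_idx <- if (is_bot[1]) i else i + 1L
              oth_idx <- if (is_bot[1]) i + 1L else i
              if (r$lengths[oth_idx] > r$lengths[bot_idx]) next
              r$values[oth_idx] <- bottom
            } else if (r$lengths[i] >= r$lengths[i + 1]) {
              r$values[i + 1] <- r$values[i]
            } else {
              r$values[i] <- r$values[i + 1]
            }
            touched[i] <- touched[i + 1] <- TRUE
            merged_any <- TRUE
          }
          if (merged_any) {
            states <- inverse.rle(r)
            changed <- TRUE
          }
        }
      }
    }
    # --- transition-frame bridge pass ---
    r <- rle(states)
    k <- length(r$lengths)
    if (k > 2) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      means <- vapply(seq_len(k),
                      function(i) mean(E[starts[i]:ends[i]]), numeric(1))
      state_levels <- tapply(E, states, mean)
      bottom <- as.integer(names(state_levels))[which.min(state_levels)]
      bottom_level <- min(state_levels)
      touched <- logical(k)
      for (i in which(r$lengths <= 2L)) {
        if (i == 1L || i == k || r$values[i] == bottom) next
        if (touched[i - 1] || touched[i] || touched[i + 1]) next
        x <- means[i]; ml <- means[i - 1]; mr <- means[i + 1]
        # the between case covers the transition frame(s) of a mid-frame
        # state change; a sub-frame gap can blur across two partial frames.
        # Relabelling as unbound requires majority unbound occupancy (below
        # the midpoint to baseline), so a mere noise dip stays put.
        between <- (x - ml) * (x - mr) < 0 &&
          (r$lengths[i] == 1L || r$values[i - 1] == bottom ||
             r$values[i + 1] == bottom)
        below_bound <- x < (min(ml, mr) + bottom_level) / 2 &&
          r$values[i - 1] != bottom && r$values[i + 1] != bottom
        if (between) {
          r$values[i] <- if (abs(x - ml) <= abs(x - mr)) {
            r$values[i - 1]
          } else r$values[i + 1]
          touched[c(i - 1, i, i + 1)] <- TRUE
          changed <- TRUE
        } else if (below_bound) {
          # a significant dip below two bound neighbours is a (sub-frame)
          # dissociation-rebinding gap: relabel as unbound so the episode
          # splits instead of fabricating a site-to-site hop
          r$values[i] <- bottom
          touched[c(i - 1, i, i + 1)] <- TRUE
          changed <- TRUE
        }
      }
      if (any(touched)) states <- inverse.rle(r)
    }
    # --- masked-dissociation junction pass ---
    # a sub-frame gap straddling a state change can blur straight into the
    # next dwell with no intermediate run; if a boundary frame of a
    # bound-to-bound junction sits well below both dwell levels, it records
    # a dissociation and is relabelled unbound
    if (is.finite(sigma) && sigma > 0) {
      r <- rle(states)
      k <- length(r$lengths)
      if (k > 1) {
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        means <- vapply(seq_len(k),
                        function(i) mean(E[starts[i]:ends[i]]), numeric(1))
        lv <- tapply(E, states, mean)
        bottom <- as.integer(names(lv))[which.min(lv)]
        relab <- integer(0)
        for (i in seq_len(k - 1)) {
          if (r$values[i] == bottom || r$values[i + 1] == bottom) next
          floor_E <- min(means[i], means[i + 1]) - 3 * sigma
          for (f in c(ends[i], starts[i + 1])) {
            if (E[f] < floor_E) relab <- c(relab, f)
          }
        }
        if (length(relab)) {
          states[relab] <- bottom
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  states
}

# ---- Gaussian hidden Markov model ------------------------------------------

fit_ghmm <- function(x, K, max_iter = 50, tol = 1e-7) {
  n_distinct <- length(unique(signif(x, 6)))
  if (K > n_distinct) {
    stop("cannot fit ", K, " states: only ", n_distinct,
         " distinct levels achievable")
  }
  n <- length(x)
  km <- tryCatch(
    with_local_seed(20201L, stats::kmeans(x, K, nstart = 5, iter.max = 50)),
    error = function(e) NULL)
  mu <- if (!is.null(km)) sort(as.numeric(km$centers)) else {
    as.numeric(stats::quantile(unique(x), probs = (seq_len(K) - 1) /
                                 max(K - 1, 1)))
  }
  sigma <- rep(max(stats::sd(x) / K, 1e-3), K)
  pi0 <- rep(1 / K, K)
  A <- matrix(0.05 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.95 else 1
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    B <- vapply(seq_len(K),
                function(k) stats::dnorm(x, mu[k], sigma[k]) + 1e-300,
                numeric(n))
    # scaled forward-backward
    alpha <- matrix(0, n, K); beta <- matrix(0, n, K); cvec <- numeric(n)
    a <- pi0 * B[1, ]; cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% A) * B[t, ]
      cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
    }
    beta[n, ] <- 1
    for (t in (n - 1):1) {
      b <- A %*% (B[t + 1, ] * beta[t + 1, ])
      beta[t, ] <- b / cvec[t + 1]
    }
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    bb <- (B[-1, , drop = FALSE] * beta[-1, , drop = FALSE]) / cvec[-1]
    xi_num <- (t(alpha[-n, , drop = FALSE]) %*% bb) * A
    pi0 <- gamma[1, ]
    A <- xi_num / pmax(rowSums(xi_num), 1e-300)
    w <- colSums(gamma)
    mu <- colSums(gamma * x) / w
    sigma <- sqrt(colSums(gamma * (outer(x, mu, "-")^2)) / w)
    sigma <- pmax(sigma, 1e-4)
    ll <- sum(log(cvec))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, pi = pi0, A = A, loglik = ll)
}

viterbi_ghmm <- function(x, fit) {
  K <- length(fit$mu); n <- length(x)
  logB <- vapply(seq_len(K),
                 function(k) stats::dnorm(x, fit$mu[k], fit$sigma[k],
                                          log = TRUE),
                 numeric(n))
  logA <- log(fit$A + 1e-300)
  delta <- matrix(-Inf, n, K); psi <- matrix(0L, n, K)
  delta[1, ] <- log(fit$pi + 1e-300) + logB[1, ]
  for (t in 2:n) {
    m <- delta[t - 1, ] + logA
    psi[t, ] <- max.col(t(m), ties.method = "first")
    delta[t, ] <- m[cbind(psi[t, ], seq_len(K))] + logB[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

# ---- dwell extraction -------------------------------------------------------

#' Extract dwells from an idealized trace
#'
#' Change-point intervals of the state sequence, each labelled with its
#' state index and level.  The first and last dwell of a trace have unknown
#' true duration and are flagged censored; per-state summary statistics
#' exclude censored dwells.
#'
#' @param ideal An `idealized_trace`.
#' @return A `dwell_set`: `dwells` table (`state`, `level`, `start`,
#'   `duration`, `censored`) and per-state `stats` (`n`, `mean`, `sd`,
#'   `sem`, with `insufficient = TRUE` where no uncensored dwell exists).
#' @export
extract_dwells <- function(ideal) {
  r <- rle(ideal$state_sequence)
  dt <- ideal$frame_interval
  k <- length(r$lengths)
  starts <- c(0, cumsum(r$lengths)[-k]) * dt
  dwells <- data.frame(
    state = r$values,
    level = ideal$state_levels[r$values],
    start = starts,
    duration = r$lengths * dt,
    censored = seq_len(k) %in% c(1L, k))
  stats_tbl <- do.call(rbind, lapply(seq_along(ideal$state_levels),
    function(s) {
      d <- dwells$duration[dwells$state == s & !dwells$censored]
      n <- length(d)
      data.frame(state = s, level = ideal$state_levels[s], n = n,
                 mean = if (n) mean(d) else NA_real_,
                 sd = if (n > 1) stats::sd(d) else NA_real_,
                 sem = if (n > 1) stats::sd(d) / sqrt(n) else NA_real_,
                 insufficient = n == 0)
    }))
  structure(list(dwells = dwells, stats = stats_tbl,
                 frame_interval = dt, meta = ideal$meta),
            class = "dwell_set")
}

#' Pool dwell sets from several molecules
#'
#' @param dwell_sets List of `dwell_set` objects (one per molecule).
#' @return A data frame of all dwells with a `molecule` index column.
#' @export
pool_dwells <- function(dwell_sets) {
  do.call(rbind, lapply(seq_along(dwell_sets), function(i) {
    d <- dwell_sets[[i]]$dwells
    if (nrow(d)) d$molecule <- i
    d
  }))
}
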