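# Binding statistics: site assignment of idealized events, transition
# density plots, binding/dissociation frequencies, the dwell-time
# dissociation-constant estimator and standard errors of the mean.

# FRET windows of the three junction classes; BE (E ~ 0.3) falls in the low
# window, inner-region binding (E ~ 0.5) and NJ3p in the mid window, NJ5p in
# the high window
DEFAULT_SITE_WINDOWS <- list(
  low = c(0.25, 0.43),
  mid = c(0.43, 0.62),
  high = c(0.62, 0.90))

UNBOUND_MAX_E <- 0.15

#' Site windows named after a preset's binding sites
#'
#' Maps each site of a kinetic preset to the default FRET class window that
#' contains its bound-state FRET anchor, so events can be labelled with the
#' preset's own site names.
#'
#' @param preset A `kinetic_preset`.
#' @return Named list of `c(lo, hi)` FRET windows.
#' @export
site_windows_for <- function(preset) {
  w <- lapply(seq_len(nrow(preset$sites)), function(i) {
    E <- preset$sites$E_bound[i]
    hit <- Filter(function(win) E >= win[1] && E < win[2],
                  DEFAULT_SITE_WINDOWS)
    if (!length(hit)) {
      stop("no default window contains E_bound = ", E, " of site ",
           preset$sites$site[i])
    }
    hit[[1]]
  })
  names(w) <- preset$sites$site
  w
}

check_windows <- function(windows) {
  if (!length(windows) || is.null(names(windows))) {
    stop("windows must be a named list of c(lo, hi) intervals")
  }
  m <- do.call(rbind, windows)
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  if (any(m[, 2] <= m[, 1])) stop("window upper bound must exceed lower bound")
  if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2] - 1e-12)) {
    stop("site FRET windows must not overlap")
  }
  invisible(windows)
}

window_label <- function(level, windows) {
  for (nm in names(windows)) {
    if (level >= windows[[nm]][1] && level < windows[[nm]][2]) return(nm)
  }
  "unassigned"
}

#' Label idealized dwells with binding sites
#'
#' Splits an idealized trace into unbound dwells and binding episodes.  Each
#' bound-state dwell is labelled by the FRET window containing its state
#' level (or `"unassigned"`).  Consecutive bound dwells without an
#' intervening unbound dwell are one binding episode; a level change inside
#' an episode is recorded as a diffusion (inter-site hop) event.
#'
#' @param ideal An `idealized_trace`.
#' @param windows Named list of non-overlapping FRET windows (default: the
#'   three junction-class windows).
#' @param unbound_max Upper FRET bound of the unbound state (default 0.15).
#' @return A `site_events` list: `events` (one row per dwell: `episode`,
#'   `site`, `level`, `start`, `duration`, `censored`; unbound dwells carry
#'   `site = "unbound"` and `episode = NA`), `diffusion` (one row per hop:
#'   `time`, `from`, `to`) and `n_episodes`.
#' @export
assign_sites <- function(ideal, windows = DEFAULT_SITE_WINDOWS,
                         unbound_max = UNBOUND_MAX_E) {
  check_windows(windows)
  ds <- extract_dwells(ideal)
  d <- ds$dwells
  d$bound <- d$level >= unbound_max
  d$site <- "unbound"
  bnd <- which(d$bound)
  d$site[bnd] <- vapply(d$level[bnd], window_label, character(1),
                        windows = windows)
  # episodes: maximal runs of bound dwells
  ep <- integer(nrow(d)); ep[] <- NA_integer_
  cur <- 0L; in_ep <- FALSE
  for (i in seq_len(nrow(d))) {
    if (d$bound[i]) {
      if (!in_ep) { cur <- cur + 1L; in_ep <- TRUE }
      ep[i] <- cur
    } else in_ep <- FALSE
  }
  d$episode <- ep
  # a diffusion event is a site-to-site label change inside one episode;
  # bound-level flicker within the same window is not a hop
  prev_site <- c(NA_character_, d$site[-nrow(d)])
  prev_bound <- c(FALSE, d$bound[-nrow(d)])
  diff_idx <- which(d$bound & prev_bound &
                      d$site != "unassigned" & prev_site != "unassigned" &
                      d$site != prev_site)
  diffusion <- data.frame(
    time = d$start[diff_idx],
    from = if (length(diff_idx)) d$site[diff_idx - 1L] else character(0),
    to = d$site[diff_idx])
  structure(list(events = d[, c("episode", "site", "level", "start",
                                "duration", "censored")],
                 diffusion = diffusion,
                 n_episodes = cur,
                 frame_interval = ds$frame_interval,
                 meta = ideal$meta),
            class = "site_events")
}

#' Pool site events from several molecules
#'
#' @param ideals List of `idealized_trace` objects.
#' @inheritParams assign_sites
#' @return A list with the pooled `events` and `diffusion` tables (with a
#'   `molecule` column, episodes renumbered globally), `n_episodes`, and the
#'   pooled `transitions` table for TDP construction.
#' @export
assign_sites_pooled <- function(ideals, windows = DEFAULT_SITE_WINDOWS,
                                unbound_max = UNBOUND_MAX_E) {
  ev <- list(); dfn <- list(); trn <- list()
  offset <- 0L; total_ep <- 0L
  for (i in seq_along(ideals)) {
    se <- assign_sites(ideals[[i]], windows, unbound_max)
    e <- se$events; e$molecule <- i
    e$episode <- e$episode + offset
    d <- se$diffusion
    d$molecule <- if (nrow(d)) i else integer(0)
    tr <- ideals[[i]]$transitions
    tr$molecule <- if (nrow(tr)) i else integer(0)
    offset <- offset + se$n_episodes
    total_ep <- total_ep + se$n_episodes
    ev[[i]] <- e; dfn[[i]] <- d; trn[[i]] <- tr
  }
  list(events = do.call(rbind, ev),
       diffusion = do.call(rbind, dfn),
       transitions = do.call(rbind, trn),
       n_episodes = total_ep)
}

#' Build a transition density plot
#'
#' Two-dimensional histogram of `(E_before, E_after)` over all idealized
#' transitions.  Transitions with `|E_before - E_after|` smaller than the
#' bin width cannot leave the diagonal and are dropped, so the diagonal is
#' empty by construction.
#'
#' @param transitions Data frame with columns `E_before` and `E_after`.
#' @param bin_width FRET bin width (default 0.02).
#' @return A `tdp`: `bin_edges`, `counts` matrix (rows = E before, columns =
#'   E after) and `n_transitions`.  An empty transition table gives a zero
#'   matrix with `n_transitions = 0`.
#' @export
build_tdp <- function(transitions, bin_width = 0.02) {
  edges <- seq(0, 1, by = bin_width)
  nb <- length(edges) - 1L
  counts <- matrix(0L, nb, nb)
  n <- 0L
  if (!is.null(transitions) && nrow(transitions)) {
    keep <- abs(transitions$E_before - transitions$E_after) >= bin_width
    tb <- transitions[keep, , drop = FALSE]
    if (nrow(tb)) {
      bin <- function(x) pmin(pmax(findInterval(x, edges,
                                                rightmost.closed = TRUE), 1L),
                              nb)
      idx <- cbind(bin(tb$E_before), bin(tb$E_after))
      for (r in seq_len(nrow(idx))) {
        counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1L
      }
      n <- nrow(tb)
    }
  }
  structure(list(bin_edges = edges, counts = counts, n_transitions = n),
            class = "tdp")
}

#' Binding/dissociation frequencies over TDP regions
#'
#' Percentage of all transition events falling in each rectangular region of
#' the transition density plane:
#' `(events in region) * 100 / (events in all areas)`, where the denominator
#' counts every recorded transition (binding and dissociation directions
#' both).
#'
#' @param transitions Data frame with `E_before`, `E_after` (as pooled by
#'   [assign_sites_pooled()]).
#' @param regions Named list; each element is a list with elements `before`
#'   and `after`, both `c(lo, hi)` FRET intervals.
#' @return Data frame (`region`, `n`, `percent`); with zero total events the
#'   percentages are `NA` and `undefined` is set.
#' @export
binding_frequencies <- function(transitions, regions) {
  total <- if (is.null(transitions)) 0L else nrow(transitions)
  res <- do.call(rbind, lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    n <- if (total) {
      sum(transitions$E_before >= r$before[1] &
            transitions$E_before < r$before[2] &
            transitions$E_after >= r$after[1] &
            transitions$E_after < r$after[2])
    } else 0L
    data.frame(region = nm, n = n,
               percent = if (total) 100 * n / total else NA_real_)
  }))
  attr(res, "n_total") <- total
  attr(res, "undefined") <- total == 0L
  res
}

#' Dwell-time dissociation-constant estimate
#'
#' Implements the dwell-time estimator
#' `Kd = tau_unbound / (tau_bound x concentration)` with per-site
#' partitioning of the unbound time: the site's mean unbound waiting time is
#' the total unbound observation time divided by the number of binding
#' events (episodes starting) at that site.  `tau_bound` is the total
#' uncensored bound time at the site divided by the number of dissociations
#' from that site into the unbound state; on substrates with bound-state
#' inter-site diffusion this remains an unbiased estimate of the site's
#' `1 / k_off`, whereas a naive per-dwell mean would be shortened by hops
#' (dwells then end at rate `k_off + k_diff`).
#'
#' Note this printed estimator is concentration-dependent: under exponential
#' kinetics its analytic value is `k_off / (k_on x C^2)`, not `k_off/k_on`;
#' it is applied here exactly as stated, and every estimate records the
#' concentration it was computed at.
#'
#' @param events Pooled event table from [assign_sites_pooled()] (or the
#'   `events` element of [assign_sites()]), containing unbound dwells.
#' @param site Site/window label to estimate.
#' @param concentration Enzyme concentration in nM.
#' @param batch Optional vector (length `nrow(events)`) of replicate-batch
#'   ids; when given, `sem_kd` is the standard error over per-batch
#'   estimates.
#' @param n_min Minimum number of events below which the estimate is flagged
#'   low-confidence (default 50).
#' @return A `kd_estimate`: `kd` (nM), `tau_bound`, `tau_unbound` (s),
#'   `concentration`, `n_events`, `sem_kd`, `low_confidence`.
#' @export
estimate_kd <- function(events, site, concentration, batch = NULL,
                        n_min = 50) {
  core <- function(ev) {
    n <- nrow(ev)
    unb <- ev$site == "unbound" & !ev$censored
    U <- sum(ev$duration[unb])
    first_of_ep <- !duplicated(ev$episode, incomparables = NA) &
      !is.na(ev$episode)
    n_bind <- sum(first_of_ep & ev$site == site)
    bdw <- ev$site == site & !ev$censored
    mol <- if ("molecule" %in% names(ev)) ev$molecule else rep(1L, n)
    next_unbound <- c(ev$site[-1] == "unbound" & mol[-1] == mol[-n], FALSE)
    n_release <- sum(bdw & next_unbound)
    if (!n_bind || !n_release || !sum(bdw)) {
      return(list(kd = NA_real_, tau_b = NA_real_, tau_u = NA_real_,
                  n = n_bind))
    }
    tau_b <- sum(ev$duration[bdw]) / n_release
    tau_u <- U / n_bind
    list(kd = tau_u / (tau_b * concentration), tau_b = tau_b, tau_u = tau_u,
         n = n_bind)
  }
  est <- core(events)
  sem_kd <- NA_real_
  if (!is.null(batch)) {
    per <- vapply(unique(batch),
                  function(b) core(events[batch == b, , drop = FALSE])$kd,
                  numeric(1))
    per <- per[is.finite(per)]
    if (length(per) >= 2) sem_kd <- stats::sd(per) / sqrt(length(per))
  }
  if (is.na(est$kd)) {
    warning("no usable bound/unbound dwells for site '", site,
            "': Kd undefined")
  }
  structure(list(site = site,
                 kd = est$kd,
                 tau_bound = est$tau_b,
                 tau_unbound = est$tau_u,
                 concentration = concentration,
                 n_events = est$n,
                 sem_kd = sem_kd,
                 low_confidence = est$n < n_min),
            class = "kd_estimate")
}

#' Standard error of the mean
#'
#' `sem = sigma / sqrt(n)` with `sigma` the sample standard deviation
#' (denominator `n - 1`).  A single observation has an undefined s.e.m.
#'
#' @param values Numeric vector (at least one value).
#' @return A `summary_stat` list: `mean`, `sigma`, `n`, `sem`, `undefined`.
#' @export
sem <- function(values) {
  if (!length(values)) stop("sem() needs at least one value")
  n <- length(values)
  sigma <- if (n >= 2) stats::sd(values) else NA_real_
  structure(list(mean = mean(values), sigma = sigma, n = n,
                 sem = if (n >= 2) sigma / sqrt(n) else NA_real_,
                 undefined = n < 2),
            class = "summary_stat")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf(
    "<kd_estimate> site %s: Kd = %.3g nM (tau_b = %.3g s, tau_u = %.3g s, C = %g nM, n = %d%s)\n",
    x$site, x$kd, x$tau_bound, x$tau_unbound, x$concentration, x$n_events,
    if (x$low_confidence) ", low confidence" else ""))
  invisible(x)
}

#' @export
print.tdp <- function(x, ...) {
  cat("<tdp> ", x$n_transitions, " transitions over ",
      length(x$bin_edges) - 1L, "x", length(x$bin_edges) - 1L, " bins\n",
      sep = "")
  invisible(x)
}
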