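# Continuous-time Markov simulation of enzyme-substrate state paths and
# rendering into noisy framed donor/acceptor intensity traces.
#
# The state machine implements the asymmetric degradation model: in
# processive mode the enzyme stays anchored at the 3' overhang junction and
# consumes the RNA 5'->3' one nucleotide at a time; in distributive mode each
# binding event ends with a single cut that releases both the engaged RNA
# segment and the enzyme, so degradation requires repeated rebinding.

SIM_MODES <- c("binding_only", "degradation_mr", "degradation_sr",
               "enzyme_tracking")

# run code under a fixed RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate an enzyme-substrate state path
#'
#' Exact stochastic simulation (competing exponential waiting times) of one
#' substrate molecule under a calibrated kinetic preset.
#'
#' Modes:
#' * `binding_only` - binding/dissociation and bound-state inter-site hops
#'   only; cleavage disabled (the Ca2+ condition).
#' * `degradation_mr` - multiturnover reaction: free enzyme at the given
#'   concentration may rebind after every dissociation.
#' * `degradation_sr` - single-turnover reaction: the path starts with one
#'   prebound enzyme and the on-rate is forced to zero afterwards (buffer
#'   flow removes free enzyme).
#' * `enzyme_tracking` - single-turnover processive path used with the
#'   enzyme-labelled rendering.
#'
#' In degradation modes the remaining RNA extent is tracked; once fewer than
#' `min_rna` ribonucleotides remain the substrate is inert and no further
#' binding or cleavage occurs.
#'
#' @param preset A `kinetic_preset` from [get_preset()].
#' @param mode One of `"binding_only"`, `"degradation_mr"`,
#'   `"degradation_sr"`, `"enzyme_tracking"`.
#' @param concentration Enzyme concentration in nM (ignored after start in
#'   single-turnover modes).
#' @param duration Observation window in seconds.
#' @param seed Integer seed; identical arguments and seed give an identical
#'   path.
#' @return A `state_path`: event table (`time`, `event`, `site`, `position`,
#'   `remaining`), the initial state, and the simulation metadata.
#' @export
simulate_state_path <- function(preset, mode = "binding_only",
                                concentration = preset$calibration_concentration,
                                duration = 300, seed = 1) {
  if (!mode %in% SIM_MODES) {
    stop("unknown mode '", mode, "'; valid modes: ",
         paste(SIM_MODES, collapse = ", "))
  }
  if (duration < 0) stop("duration must be non-negative")
  if (mode %in% c("binding_only", "degradation_mr") && concentration <= 0) {
    stop("concentration must be > 0 for multiturnover/binding modes")
  }
  sites <- preset$sites
  cl <- preset$cleavage
  L <- preset$rna_length
  degrade <- mode != "binding_only"
  single_turnover <- mode %in% c("degradation_sr", "enzyme_tracking")
  processive <- degrade && cl$mode == "processive"

  with_local_seed(seed, {
    n_alloc <- 256L
    ev_time <- numeric(n_alloc); ev_type <- character(n_alloc)
    ev_site <- character(n_alloc); ev_pos <- rep(NA_real_, n_alloc)
    ev_rem <- numeric(n_alloc); n_ev <- 0L
    push <- function(time, type, site, pos, rem) {
      n_ev <<- n_ev + 1L
      if (n_ev > length(ev_time)) {
        grow <- function(x, fill) c(x, rep(fill, length(x)))
        ev_time <<- grow(ev_time, 0); ev_type <<- grow(ev_type, "")
        ev_site <<- grow(ev_site, ""); ev_pos <<- grow(ev_pos, NA_real_)
        ev_rem <<- grow(ev_rem, 0)
      }
      ev_time[n_ev] <<- time; ev_type[n_ev] <<- type
      ev_site[n_ev] <<- site; ev_pos[n_ev] <<- pos; ev_rem[n_ev] <<- rem
    }

    remaining <- if (degrade) L else NA_real_
    # single-turnover paths begin with one prebound enzyme at the primary site
    init_site <- NA_character_
    if (single_turnover) {
      init_site <- sites$site[which.max(sites$k_on)]
    }
    bound <- init_site
    t <- 0
    repeat {
      if (t >= duration || duration == 0) break
      if (is.na(bound)) {
        inert <- degrade && remaining < cl$min_rna
        if (single_turnover || inert) break
        r_bind <- sites$k_on * concentration
        tot <- sum(r_bind)
        if (tot <= 0) break
        t <- t + stats::rexp(1, tot)
        if (t >= duration) break
        j <- sample.int(nrow(sites), 1, prob = r_bind)
        bound <- sites$site[j]
        push(t, "bind", bound, NA_real_, remaining)
      } else {
        j <- match(bound, sites$site)
        if (!degrade) {
          n_other <- nrow(sites) - 1L
          r <- c(release = sites$k_off[j],
                 hop = if (n_other > 0) preset$k_diff else 0)
        } else if (processive) {
          done <- remaining <= 0
          r <- c(release = if (done) sites$k_off[j] else cl$k_release,
                 step = if (!done) cl$k_step else 0)
        } else {
          can_cut <- remaining >= cl$min_rna
          r <- c(release = sites$k_off[j],
                 cut = if (can_cut) cl$k_cut else 0)
        }
        tot <- sum(r)
        t <- t + stats::rexp(1, tot)
        if (t >= duration) break
        what <- names(r)[sample.int(length(r), 1, prob = r)]
        if (what == "release") {
          bound <- NA_character_
          push(t, "release", sites$site[j], NA_real_, remaining)
        } else if (what == "hop") {
          others <- setdiff(seq_len(nrow(sites)), j)
          k <- if (length(others) == 1) others else {
            others[sample.int(length(others), 1)]
          }
          bound <- sites$site[k]
          push(t, "hop", paste0(sites$site[j], "->", sites$site[k]),
               NA_real_, remaining)
        } else if (what == "step") {
          remaining <- remaining - 1
          # 5'->3' position of the nucleotide just removed
          push(t, "step", sites$site[j], L - remaining, remaining)
        } else { # cut: single catalytic event, enzyme leaves with the product
          pos <- ceiling(stats::runif(1) * remaining)
          remaining <- max(remaining - cl$cut_size, 0)
          push(t, "cut", sites$site[j], pos, remaining)
          bound <- NA_character_
        }
      }
    }

    events <- data.frame(
      time = ev_time[seq_len(n_ev)],
      event = ev_type[seq_len(n_ev)],
      site = ev_site[seq_len(n_ev)],
      position = ev_pos[seq_len(n_ev)],
      remaining = ev_rem[seq_len(n_ev)],
      stringsAsFactors = FALSE)

    structure(
      list(events = events,
           duration = duration,
           mode = mode,
           substrate = preset$substrate,
           concentration = concentration,
           init_site = init_site,
           rna_length = L,
           seed = seed),
      class = "state_path")
  })
}

#' Photophysics / camera configuration for trace rendering
#'
#' @param total_intensity Mean summed donor + acceptor intensity (counts).
#' @param noise_sigma Standard deviation of the summed-intensity noise
#'   (counts); each channel receives independent Gaussian noise with
#'   sd `noise_sigma / sqrt(2)`.  Default 8% of the total intensity.
#' @param background Constant background counts added to each channel.
#' @param bleach_rate Donor photobleaching rate (per second); 0 disables
#'   bleaching.
#' @param frame_interval Camera integration time in seconds (0.5 s for
#'   binding assays, 0.1 s for degradation assays).
#' @return A `photophysics_config` list.
#' @export
photophysics_config <- function(total_intensity = 1000,
                                noise_sigma = 0.08 * total_intensity,
                                background = 0,
                                bleach_rate = 0,
                                frame_interval = 0.5) {
  stopifnot(total_intensity > 0, noise_sigma >= 0, background >= 0,
            bleach_rate >= 0, frame_interval > 0)
  structure(list(total_intensity = total_intensity,
                 noise_sigma = noise_sigma,
                 background = background,
                 bleach_rate = bleach_rate,
                 frame_interval = frame_interval),
            class = "photophysics_config")
}

# piecewise-constant true FRET path implied by a state path
true_fret_path <- function(path, preset, E_track_end = 0.15) {
  ev <- path$events
  base <- preset$baseline_E
  L <- path$rna_length
  mode <- path$mode
  sE <- function(site) preset$sites$E_bound[match(site, preset$sites$site)]

  t0 <- 0
  if (mode == "binding_only") {
    v0 <- if (is.na(path$init_site)) base else sE(path$init_site)
    keep <- ev$event %in% c("bind", "release", "hop")
    tt <- ev$time[keep]
    site_after <- ifelse(ev$event[keep] == "release", NA_character_,
                         sub(".*->", "", ev$site[keep]))
    vv <- ifelse(is.na(site_after), base, sE(site_after))
  } else if (mode == "enzyme_tracking") {
    anchor <- sE(path$init_site %||% preset$sites$site[1])
    consumed0 <- 0
    v_of <- function(bound, consumed) {
      if (!bound) base
      else anchor - (anchor - E_track_end) * consumed / L
    }
    bound <- !is.na(path$init_site)
    consumed <- consumed0
    tt <- ev$time
    vv <- numeric(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      switch(ev$event[i],
             bind = { bound <- TRUE },
             release = { bound <- FALSE },
             step = { consumed <- L - ev$remaining[i] },
             cut = { consumed <- L - ev$remaining[i]; bound <- FALSE })
      vv[i] <- v_of(bound, consumed)
    }
    v0 <- v_of(!is.na(path$init_site), 0)
  } else {
    # substrate-labelled degradation: E interpolates linearly in the degraded
    # RNA fraction, independent of enzyme occupancy
    e0 <- preset$E_degraded_start
    e1 <- preset$E_degraded_end
    keep <- ev$event %in% c("cut", "step")
    tt <- ev$time[keep]
    vv <- e0 + (e1 - e0) * (1 - ev$remaining[keep] / L)
    v0 <- e0
  }
  # collapse to breakpoints (strictly increasing times guaranteed)
  list(t = c(t0, tt), v = c(v0, vv))
}

#' Render a state path into a noisy framed intensity trace
#'
#' Each frame's true FRET efficiency is the occupancy-time-weighted average
#' of the state FRET values within the frame.  Donor and acceptor intensities
#' are `I_A = E * T` and `I_D = (1 - E) * T` plus background and independent
#' Gaussian channel noise; after a donor bleach both channels drop to
#' background.
#'
#' @param path A `state_path` from [simulate_state_path()].
#' @param preset The `kinetic_preset` the path was simulated with.
#' @param photo A [photophysics_config()].
#' @param seed Integer seed for noise and bleach time.
#' @param E_track_end Final FRET anchor for enzyme-tracking rendering.
#' @return A `fret_trace` with `time`, `donor`, `acceptor` and `meta`.
#' @export
render_trace <- function(path, preset, photo = photophysics_config(),
                         seed = 1, E_track_end = 0.15) {
  if (!identical(path$substrate, preset$substrate)) {
    stop("state path was simulated for substrate '", path$substrate,
         "', not '", preset$substrate, "'")
  }
  dt <- photo$frame_interval
  n <- floor(path$duration / dt + 1e-9)
  pw <- true_fret_path(path, preset, E_track_end)

  with_local_seed(seed, {
    if (n == 0) {
      E <- numeric(0)
    } else {
      knots <- pw$t
      vals <- pw$v
      # cumulative integral of the piecewise-constant E at the knots
      cum <- c(0, cumsum(vals[-length(vals)] * diff(knots)))
      cum_at <- function(x) {
        idx <- findInterval(x, knots)
        cum[idx] + (x - knots[idx]) * vals[idx]
      }
      starts <- (seq_len(n) - 1) * dt
      E <- (cum_at(starts + dt) - cum_at(starts)) / dt
    }
    Tcts <- photo$total_intensity
    sig <- photo$noise_sigma / sqrt(2)
    t_bleach <- if (photo$bleach_rate > 0) {
      stats::rexp(1, photo$bleach_rate)
    } else Inf
    alive <- (seq_len(n) - 1) * dt + dt <= t_bleach
    acceptor <- photo$background + ifelse(alive, E * Tcts, 0) +
      stats::rnorm(n, 0, sig)
    donor <- photo$background + ifelse(alive, (1 - E) * Tcts, 0) +
      stats::rnorm(n, 0, sig)
    structure(
      list(time = (seq_len(n) - 1) * dt,
           donor = donor,
           acceptor = acceptor,
           meta = list(substrate = path$substrate,
                       concentration_nM = path$concentration,
                       frame_interval_s = dt,
                       mode = path$mode,
                       seed = path$seed,
                       version = as.character(utils::packageVersion("hybridkin")))),
      class = "fret_trace")
  })
}

#' Simulate a multi-molecule experiment
#'
#' Convenience wrapper producing `n_traces` rendered traces together with
#' their ground-truth state paths (the simulation manifest used by the
#' tests).  Per-trace seeds are drawn reproducibly from `seed`.
#'
#' @inheritParams simulate_state_path
#' @param n_traces Number of molecules.
#' @param photo A [photophysics_config()]; its `frame_interval` sets the
#'   rendering grid.
#' @return A list with `traces` (list of `fret_trace`) and `paths` (list of
#'   `state_path`).
#' @export
simulate_experiment <- function(preset, n_traces = 100,
                                mode = "binding_only",
                                concentration = preset$calibration_concentration,
                                duration = 300,
                                photo = photophysics_config(
                                  frame_interval = preset$frame_interval),
                                seed = 1) {
  seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max - 1L, 2L * n_traces))
  paths <- vector("list", n_traces)
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    paths[[i]] <- simulate_state_path(preset, mode, concentration, duration,
                                      seed = seeds[2L * i - 1L])
    traces[[i]] <- render_trace(paths[[i]], preset, photo,
                                seed = seeds[2L * i])
  }
  list(traces = traces, paths = paths)
}

#' @export
print.state_path <- function(x, ...) {
  cat("<state_path> ", x$substrate, " / ", x$mode,
      "  (", nrow(x$events), " events over ", x$duration, " s at ",
      x$concentration, " nM)\n", sep = "")
  invisible(x)
}

#' @export
print.fret_trace <- function(x, ...) {
  cat("<fret_trace> ", x$meta$substrate, " / ", x$meta$mode, "  (",
      length(x$time), " frames @ ", x$meta$frame_interval_s, " s)\n", sep = "")
  invisible(x)
}
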