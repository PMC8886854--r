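# End-to-end convenience pipelines: simulate -> render -> FRET -> idealize ->
# site-labelled events, and the degradation-time / classification runs built
# on top of them.

#' Full binding-assay pipeline on simulated traces
#'
#' Simulates `n_traces` binding-only molecules under a preset, renders them,
#' computes FRET, idealizes every trace and pools the site-labelled events.
#'
#' @inheritParams simulate_experiment
#' @param method Idealization method (`"threshold"` or `"hmm"`).
#' @param n_states States for the HMM method; defaults to one state per
#'   binding site plus the unbound state.
#' @param windows Site windows; default derived from the preset via
#'   [site_windows_for()].
#' @return A list: pooled `events`, `transitions`, `diffusion`,
#'   `n_episodes`, plus the per-trace `ideals` and ground-truth `paths`.
#' @export
binding_pipeline <- function(preset, n_traces = 100, duration = 300,
                             concentration = preset$calibration_concentration,
                             photo = photophysics_config(
                               frame_interval = preset$frame_interval),
                             method = "threshold", n_states = NULL,
                             windows = site_windows_for(preset), seed = 1) {
  ex <- simulate_experiment(preset, n_traces, mode = "binding_only",
                            concentration = concentration,
                            duration = duration, photo = photo, seed = seed)
  if (method == "hmm" && is.null(n_states)) {
    n_states <- nrow(preset$sites) + 1L
  }
  ideals <- lapply(ex$traces, function(tr) {
    idealize(compute_fret(tr), method = method, n_states = n_states)
  })
  pooled <- assign_sites_pooled(ideals, windows = windows)
  pooled$ideals <- ideals
  pooled$paths <- ex$paths
  pooled$concentration <- concentration
  pooled
}

#' Replicated Kd estimation over seeded batches
#'
#' Runs [binding_pipeline()] for `n_batches` independent seeded batches and
#' applies the dwell-time Kd estimator to the pooled events, reporting the
#' batch-to-batch standard error (the replicate structure used for s.e.m.,
#' mirroring repeated experiments).
#'
#' @inheritParams binding_pipeline
#' @param site Site label to estimate.
#' @param n_batches Number of replicate batches (default 3).
#' @return A `kd_estimate` (with `sem_kd` over batches).
#' @export
kd_replicates <- function(preset, site, n_batches = 3, n_traces = 70,
                          duration = 300,
                          concentration = preset$calibration_concentration,
                          method = "threshold", seed = 1) {
  evs <- vector("list", n_batches)
  ep_off <- 0L; mol_off <- 0L
  for (b in seq_len(n_batches)) {
    pl <- binding_pipeline(preset, n_traces = n_traces, duration = duration,
                           concentration = concentration, method = method,
                           seed = seed + 7919L * b)
    e <- pl$events
    e$batch <- b
    e$episode <- e$episode + ep_off
    e$molecule <- e$molecule + mol_off
    ep_off <- ep_off + pl$n_episodes
    mol_off <- mol_off + n_traces
    evs[[b]] <- e
  }
  all_ev <- do.call(rbind, evs)
  estimate_kd(all_ev, site, concentration, batch = all_ev$batch)
}

# rough expected time to full degradation, used to size trace durations
expected_degradation_time <- function(preset, concentration,
                                      mode = "degradation_mr") {
  cl <- preset$cleavage
  L <- preset$rna_length
  if (cl$mode == "processive") {
    ramp <- L / cl$k_step
    wait <- if (mode == "degradation_mr") {
      1 / (sum(preset$sites$k_on) * concentration)
    } else 0
    wait + ramp
  } else {
    n_cuts <- ceiling((L - cl$min_rna + 1) / cl$cut_size)
    gap <- if (mode == "degradation_mr") {
      1 / (sum(preset$sites$k_on) * concentration)
    } else 0
    n_cuts * (gap + 1 / cl$k_cut + 1 / max(preset$sites$k_off))
  }
}

#' Degradation experiment: simulate, measure times and pauses
#'
#' Simulates substrate-labelled degradation traces, measures each molecule's
#' degradation time against the preset's FRET anchors and (optionally)
#' detects pauses within the degradation period.
#'
#' @inheritParams binding_pipeline
#' @param mode `"degradation_mr"` or `"degradation_sr"`.
#' @param duration Trace length in seconds; default is sized from the
#'   expected degradation time at this concentration.
#' @param with_pauses Also run the pause detector on each molecule.
#' @return List with `times` (per-molecule durations, completed events
#'   only), `events` (all `degradation_event`s), `pauses` (pooled pause
#'   table) and `series` (the `fret_series` list).
#' @export
degradation_experiment <- function(preset, mode = "degradation_mr",
                                   concentration = 10, n_traces = 100,
                                   duration = NULL,
                                   photo = photophysics_config(
                                     frame_interval = 0.1),
                                   with_pauses = FALSE, seed = 1) {
  if (is.null(duration)) {
    duration <- 5 * expected_degradation_time(preset, concentration, mode) + 30
  }
  ex <- simulate_experiment(preset, n_traces, mode = mode,
                            concentration = concentration,
                            duration = duration, photo = photo, seed = seed)
  series <- lapply(ex$traces, compute_fret)
  events <- lapply(series, measure_degradation_time,
                   E_start = preset$E_degraded_start,
                   E_end = preset$E_degraded_end)
  ok <- vapply(events, function(e) !e$no_event && !is.na(e$duration),
               logical(1))
  times <- vapply(events[ok], function(e) e$duration, numeric(1))
  pauses <- NULL
  if (with_pauses) {
    pl <- lapply(which(ok), function(i) {
      p <- detect_pauses(series[[i]], events[[i]])
      if (nrow(p)) p$molecule <- i
      p
    })
    pauses <- do.call(rbind, pl[vapply(pl, nrow, 1L) > 0])
  }
  list(times = times, events = events, pauses = pauses, series = series,
       paths = ex$paths, concentration = concentration, duration = duration)
}

#' Concentration series and processivity classification
#'
#' Runs [degradation_experiment()] at each concentration and classifies the
#' mechanism from the concentration dependence of the mean degradation time
#' via [classify_mode()].
#'
#' @inheritParams degradation_experiment
#' @param concentrations Vector of enzyme concentrations (nM), at least 3
#'   spanning an order of magnitude.
#' @param n_traces Molecules per concentration.
#' @return A `mode_classification` (with the per-event `times` table in
#'   `$times`).
#' @export
classification_pipeline <- function(preset, concentrations = c(1, 10, 100),
                                    n_traces = 25, seed = 1, n_boot = 1000) {
  rows <- lapply(seq_along(concentrations), function(i) {
    de <- degradation_experiment(preset, concentration = concentrations[i],
                                 n_traces = n_traces,
                                 seed = seed + 104729L * i)
    if (!length(de$times)) return(NULL)
    data.frame(concentration = concentrations[i], time = de$times)
  })
  times <- do.call(rbind, rows)
  cls <- classify_mode(times, n_boot = n_boot, seed = seed)
  cls$times <- times
  cls
}
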