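# Shared test helpers: hand-built presets, traces and event tables with
# known ground truth.

# minimal single- or multi-site preset with explicit rates (bypasses the
# library calibration so oracle values are set directly by the test)
mock_preset <- function(k_on = 0.5, k_off = 0.5, E_bound = 0.77,
                        site = "S1", k_diff = 0, C = 1,
                        cleavage_mode = "distributive", k_step = 10,
                        k_cut = 100, k_release = 0.01,
                        rna_length = 25, frame_interval = 0.5,
                        E_start = 0.2, E_end = 0.7) {
  n <- length(k_on)
  sites <- data.frame(site = site,
                      E_bound = E_bound,
                      kd_target = k_off / (k_on * C^2),
                      tau_bound = 1 / k_off,
                      tau_unbound = 1 / (k_on * C),
                      k_off = k_off, k_on = k_on)
  structure(list(substrate = "mock", sites = sites, k_diff = k_diff,
                 cleavage = list(mode = cleavage_mode, k_step = k_step,
                                 k_cut = k_cut, k_release = k_release,
                                 cut_size = 4, min_rna = 4),
                 rna_length = rna_length,
                 E_degraded_start = E_start, E_degraded_end = E_end,
                 baseline_E = 0.05,
                 calibration_concentration = C,
                 frame_interval = frame_interval),
            class = "kinetic_preset")
}

# hand-built state path (for deterministic rendering tests)
mock_path <- function(events, duration, mode = "binding_only",
                      substrate = "mock", concentration = 1,
                      init_site = NA_character_, rna_length = 25, seed = 1) {
  structure(list(events = events, duration = duration, mode = mode,
                 substrate = substrate, concentration = concentration,
                 init_site = init_site, rna_length = rna_length, seed = seed),
            class = "state_path")
}

empty_events <- function() {
  data.frame(time = numeric(0), event = character(0), site = character(0),
             position = numeric(0), remaining = numeric(0))
}

# build a fret_trace directly from channel vectors
mock_trace <- function(donor, acceptor, dt = 0.5, meta = list()) {
  base <- list(substrate = "mock", concentration_nM = 1,
               frame_interval_s = dt, mode = "binding_only", seed = 1,
               version = "test")
  base[names(meta)] <- meta
  structure(list(time = (seq_along(donor) - 1) * dt,
                 donor = donor, acceptor = acceptor, meta = base),
            class = "fret_trace")
}

# fret_series straight from an E vector (bypasses intensities)
mock_series <- function(E, dt = 0.1) {
  structure(list(E = E, valid = rep(TRUE, length(E)),
                 meta = list(substrate = "mock", concentration_nM = 1,
                             frame_interval_s = dt, mode = "degradation_mr",
                             seed = 1, version = "test")),
            class = "fret_series")
}

# turn a binding-only state path into an exact site-labelled event table
# (ground-truth dwells, no rendering/idealization) for estimator oracles
path_to_events <- function(path, molecule = 1L) {
  ev <- path$events
  keep <- ev$event %in% c("bind", "release", "hop")
  ev <- ev[keep, , drop = FALSE]
  t0 <- 0; site <- "unbound"; ep <- NA_integer_; nep <- 0L
  rows <- list()
  push <- function(t1, censored = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      episode = ep, site = site, level = NA_real_, start = t0,
      duration = t1 - t0, censored = censored, molecule = molecule)
  }
  for (i in seq_len(nrow(ev))) {
    push(ev$time[i], censored = i == 1L)
    t0 <- ev$time[i]
    if (ev$event[i] == "release") {
      site <- "unbound"; ep <- NA_integer_
    } else if (ev$event[i] == "bind") {
      nep <- nep + 1L; ep <- nep; site <- ev$site[i]
    } else {
      site <- sub(".*->", "", ev$site[i])
    }
  }
  push(path$duration, censored = TRUE)
  out <- do.call(rbind, rows)
  out[out$duration > 0, , drop = FALSE]
}
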