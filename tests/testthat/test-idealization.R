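test_that("FRET efficiency follows the proximity ratio with clipping", {
  tr <- mock_trace(donor = c(500, 300, 1000, 0),
                   acceptor = c(500, 700, 0, 1000))
  s <- compute_fret(tr, min_total = 10)
  expect_equal(s$E, c(0.5, 0.7, 0, 1))
  # background subtraction and clipping at 0
  tr2 <- mock_trace(donor = c(900, 950), acceptor = c(120, 80))
  s2 <- compute_fret(tr2, background_donor = 100, background_acceptor = 100,
                     min_total = 10)
  expect_equal(s2$E[1], 20 / 820)
  expect_equal(s2$E[2], 0) # negative corrected acceptor clips to 0
})

test_that("dark traces raise a no-usable-frames error", {
  tr <- mock_trace(donor = rep(1, 20), acceptor = rep(1, 20))
  expect_error(compute_fret(tr, min_total = 100), "no usable frames")
})

test_that("a post-bleach tail sets the background and truncates the mask", {
  set.seed(8)
  n_live <- 60; n_dark <- 20; bg <- 80
  donor <- c(rnorm(n_live, 500 + bg, 5), rnorm(n_dark, bg, 2))
  acceptor <- c(rnorm(n_live, 500 + bg, 5), rnorm(n_dark, bg, 2))
  s <- compute_fret(mock_trace(donor, acceptor))
  expect_equal(sum(s$valid), n_live)
  expect_true(all(which(s$valid) == seq_len(n_live))) # contiguous from start
  # background estimated from the tail: E near 0.5 for symmetric channels
  expect_equal(mean(s$E[s$valid]), 0.5, tolerance = 0.01)
})

test_that("noiseless two-level series are recovered exactly by both methods", {
  lv <- c(0.05, 0.77)
  runs <- c(12, 7, 20, 5, 15, 9, 18)
  E <- rep(lv[c(1, 2, 1, 2, 1, 2, 1)], runs)
  s <- mock_series(E, dt = 0.5)
  for (cfg in list(list(method = "threshold"),
                   list(method = "hmm", n_states = 2))) {
    id <- idealize(s, method = cfg$method, n_states = cfg$n_states)
    expect_equal(id$state_levels, lv, tolerance = 1e-9, info = cfg$method)
    expect_equal(which(diff(id$state_sequence) != 0), cumsum(runs)[-7],
                 info = cfg$method)
    expect_equal(nrow(id$transitions), 6)
    expect_true(all(diff(id$state_levels) > 0))
  }
})

test_that("a constant series yields one state and no transitions", {
  s <- mock_series(rep(0.48, 30))
  id <- idealize(s)
  expect_length(id$state_levels, 1)
  expect_equal(nrow(id$transitions), 0)
  expect_error(idealize(mock_series(rep(0.4, 5))), "at least 10")
  expect_error(idealize(s, method = "hmm", n_states = 4),
               "distinct levels")
})

test_that("frame accuracy reaches 99% at sigma = 0.08 on 0.05/0.77 levels", {
  # two-state series with Gaussian frame noise drawn directly on the state
  # levels (no camera blur), dwells exponential with means 20 and 8 frames
  set.seed(123)
  lv <- c(0.05, 0.77)
  truth <- integer(0)
  st <- 1L
  while (length(truth) < 6000) {
    len <- 1L + stats::rpois(1, if (st == 1) 19 else 7)
    truth <- c(truth, rep(st, len))
    st <- 3L - st
  }
  E <- pmin(pmax(lv[truth] + rnorm(length(truth), 0, 0.08), 0), 1)
  s <- mock_series(E, dt = 0.5)
  for (m in c("threshold", "hmm")) {
    id <- idealize(s, method = m, n_states = 2)
    det <- (id$state_levels[id$state_sequence] > 0.4) + 1L
    acc <- mean(det == truth[seq_along(det)])
    expect_gt(acc, 0.99)
  }
})

test_that("dwell extraction tiles the trace and reproduces exact durations", {
  runs <- c(4, 9, 6, 11, 3)
  E <- rep(c(0.05, 0.77, 0.05, 0.77, 0.05), runs)
  id <- idealize(mock_series(E, dt = 0.5))
  ds <- extract_dwells(id)
  expect_equal(ds$dwells$duration, runs * 0.5)
  expect_equal(ds$dwells$censored, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(sum(ds$dwells$duration), length(E) * 0.5) # exact tiling
  # censored dwells are excluded from per-state statistics
  st <- ds$stats[ds$stats$level > 0.4, ]
  expect_equal(st$n, 2)
  expect_equal(st$mean, mean(c(9, 11) * 0.5))
})

test_that("a single-state trace flags insufficient uncensored data", {
  ds <- extract_dwells(idealize(mock_series(rep(0.3, 25))))
  expect_equal(nrow(ds$dwells), 1)
  expect_true(all(ds$dwells$censored))
  expect_true(ds$stats$insufficient)
  expect_true(is.na(ds$stats$mean))
})

test_that("pipeline dwell means recover the generating rates within 3 se", {
  # 2 s bound dwells sampled at 50 ms so that sub-frame missed events stay
  # well below the sampling error of 1e4 dwells
  koff <- 0.5; konC <- 0.1
  p <- mock_preset(k_on = konC, k_off = koff, E_bound = 0.77, C = 1,
                   frame_interval = 0.05)
  ph <- photophysics_config(frame_interval = 0.05)
  all_d <- list()
  for (seed in 1:12) {
    path <- simulate_state_path(p, "binding_only", 1, duration = 1.1e4,
                                seed = seed)
    tr <- render_trace(path, p, ph, seed = 500 + seed)
    ds <- extract_dwells(idealize(compute_fret(tr)))
    all_d[[seed]] <- ds$dwells
  }
  d <- do.call(rbind, all_d)
  bound <- d$duration[d$level > 0.4 & !d$censored]
  expect_gt(length(bound), 1e4)
  se <- sd(bound) / sqrt(length(bound))
  expect_lt(abs(mean(bound) - 1 / koff), 3 * se + 0.02)
})

test_that("excluding censored dwells does not increase estimator bias", {
  koff <- 0.2
  p <- mock_preset(k_on = 0.2, k_off = koff, E_bound = 0.77, C = 1)
  ph <- photophysics_config(frame_interval = 0.5)
  d <- list()
  for (seed in 1:40) {
    path <- simulate_state_path(p, "binding_only", 1, duration = 300,
                                seed = seed)
    tr <- render_trace(path, p, ph, seed = 900 + seed)
    d[[seed]] <- extract_dwells(idealize(compute_fret(tr)))$dwells
  }
  d <- do.call(rbind, d)
  bound_all <- d$duration[d$level > 0.4]
  bound_unc <- d$duration[d$level > 0.4 & !d$censored]
  bias_all <- abs(mean(bound_all) - 1 / koff)
  bias_unc <- abs(mean(bound_unc) - 1 / koff)
  se <- sd(bound_unc) / sqrt(length(bound_unc))
  expect_lt(bias_unc, bias_all + 3 * se)
})

test_that("threshold and HMM idealization agree on mean dwells within 5%", {
  p <- mock_preset(k_on = 0.2, k_off = 0.1, E_bound = 0.77, C = 1)
  ph <- photophysics_config(frame_interval = 0.5)
  get_means <- function(method) {
    d <- list()
    for (seed in 1:10) {
      path <- simulate_state_path(p, "binding_only", 1, duration = 2000,
                                  seed = seed)
      tr <- render_trace(path, p, ph, seed = 300 + seed)
      d[[seed]] <- extract_dwells(
        idealize(compute_fret(tr), method = method, n_states = 2))$dwells
    }
    d <- do.call(rbind, d)
    c(bound = mean(d$duration[d$level > 0.4 & !d$censored]),
      unbound = mean(d$duration[d$level <= 0.4 & !d$censored]))
  }
  m_thr <- get_means("threshold")
  m_hmm <- get_means("hmm")
  expect_lt(abs(m_thr["bound"] - m_hmm["bound"]) / m_thr["bound"], 0.05)
  expect_lt(abs(m_thr["unbound"] - m_hmm["unbound"]) / m_thr["unbound"], 0.05)
})
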