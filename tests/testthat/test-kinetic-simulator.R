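test_that("degenerate inputs: zero duration and unknown modes", {
  p <- mock_preset()
  expect_equal(nrow(simulate_state_path(p, duration = 0, seed = 1)$events), 0)
  expect_error(simulate_state_path(p, mode = "nope"), "unknown mode")
  expect_error(simulate_state_path(p, duration = -1), "non-negative")
  expect_error(simulate_state_path(p, concentration = 0), "concentration")
})

test_that("identical seeds give identical paths and traces", {
  p <- mock_preset(k_on = 0.5, k_off = 0.3)
  a <- simulate_state_path(p, duration = 200, seed = 7)
  b <- simulate_state_path(p, duration = 200, seed = 7)
  expect_identical(a$events, b$events)
  d <- simulate_state_path(p, duration = 200, seed = 8)
  expect_false(identical(a$events, d$events))
  ph <- photophysics_config(frame_interval = 0.5)
  t1 <- render_trace(a, p, ph, seed = 3)
  t2 <- render_trace(b, p, ph, seed = 3)
  expect_identical(t1$donor, t2$donor)
  expect_identical(t1$acceptor, t2$acceptor)
})

test_that("simulated dwell means and distributions match the analytic exponentials", {
  koff <- 0.5; kon <- 1 / 3; C <- 1
  p <- mock_preset(k_on = kon, k_off = koff, C = C)
  # one long path provides >= 1e4 of each dwell type
  path <- simulate_state_path(p, "binding_only", concentration = C,
                              duration = 6e4, seed = 21)
  ev <- path$events
  tb <- which(ev$event == "bind")
  tr <- which(ev$event == "release")
  bound <- ev$time[tr] - ev$time[tb[seq_along(tr)]]
  unbound <- ev$time[tb[-1]] - ev$time[tr[seq_len(length(tb) - 1)]]
  expect_gt(length(bound), 1e4)
  expect_lt(abs(mean(bound) - 1 / koff), 3 * sd(bound) / sqrt(length(bound)))
  expect_lt(abs(mean(unbound) - 1 / (kon * C)),
            3 * sd(unbound) / sqrt(length(unbound)))
  # exponentiality at alpha = 0.01 (seeded)
  expect_gt(stats::ks.test(bound, "pexp", koff)$p.value, 0.01)
  expect_gt(stats::ks.test(unbound, "pexp", kon * C)$p.value, 0.01)
})

test_that("path invariants hold across modes and seeds", {
  p3 <- get_preset("3ORDH")
  p5 <- get_preset("5ORDH")
  for (seed in 1:8) {
    for (cfg in list(list(p = p3, mode = "binding_only", C = 0.2),
                     list(p = p3, mode = "degradation_sr", C = 5),
                     list(p = p5, mode = "degradation_mr", C = 10))) {
      path <- simulate_state_path(cfg$p, cfg$mode, cfg$C, duration = 500,
                                  seed = seed)
      ev <- path$events
      if (nrow(ev) < 2) next
      expect_true(all(diff(ev$time) > 0))
      # bind/release alternation: no double bind, no release while unbound
      br <- ev$event[ev$event %in% c("bind", "release")]
      if (cfg$mode == "binding_only" && length(br) > 1) {
        expect_true(all(br[-1] != br[-length(br)]))
      }
      if (cfg$mode != "binding_only") {
        rem <- ev$remaining
        expect_true(all(diff(rem) <= 0))
      }
      if (cfg$mode == "degradation_sr" && identical(cfg$p, p3)) {
        pos <- ev$position[ev$event == "step"]
        if (length(pos) > 1) expect_true(all(diff(pos) > 0))
      }
    }
  }
})

test_that("processive single-turnover paths complete without release when stepping dominates", {
  # competing-exponentials oracle: P(complete) = (k_step/(k_step+k_rel))^L
  kstep <- 50; krel <- 0.004; L <- 25
  p_true <- (kstep / (kstep + krel))^L
  p <- mock_preset(cleavage_mode = "processive", k_step = kstep,
                   k_release = krel, rna_length = L)
  n <- 1500
  done <- logical(n)
  for (i in seq_len(n)) {
    path <- simulate_state_path(p, "degradation_sr", 1, duration = 100,
                                seed = 3000 + i)
    ev <- path$events
    complete <- any(ev$remaining == 0, na.rm = TRUE)
    early_release <- any(ev$event == "release" & ev$remaining > 0)
    done[i] <- complete && !early_release
  }
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(done) - p_true), max(3 * se, 0.01))
  expect_gt(mean(done), 0.99)
})

test_that("distributive single-turnover makes one cut and leaves RNA uncut", {
  p <- get_preset("5ORDH")
  for (seed in 1:20) {
    path <- simulate_state_path(p, "degradation_sr", 5, duration = 300,
                                seed = seed)
    ev <- path$events
    expect_lte(sum(ev$event == "cut"), 1)
    expect_equal(sum(ev$event == "bind"), 0) # no rebinding after flow
    if (any(ev$event == "cut")) {
      expect_equal(min(ev$remaining), p$rna_length - p$cleavage$cut_size)
    }
  }
})

test_that("multiturnover distributive rebind gaps average 1/(sum kon * C)", {
  p <- get_preset("5ORDH")
  C <- 10
  gaps <- c()
  for (seed in 1:80) {
    ev <- simulate_state_path(p, "degradation_mr", C, duration = 400,
                              seed = 100 + seed)$events
    i <- which(ev$event == "bind")
    prev_end <- ev$time[match(ev$event, "cut")]
    # gap = time from each cut/release to the next bind
    ends <- ev$time[ev$event %in% c("cut", "release")]
    for (b in ev$time[i]) {
      e <- ends[ends < b]
      if (length(e)) gaps <- c(gaps, b - max(e))
    }
  }
  mu <- 1 / (sum(p$sites$k_on) * C)
  expect_gt(length(gaps), 300)
  expect_lt(abs(mean(gaps) - mu), 3 * sd(gaps) / sqrt(length(gaps)))
})

test_that("noiseless rendering maps states to exact intensities", {
  p <- mock_preset(E_bound = 0.77)
  path <- mock_path(
    data.frame(time = 0, event = "bind", site = "S1",
               position = NA_real_, remaining = NA_real_),
    duration = 5)
  ph <- photophysics_config(total_intensity = 1000, noise_sigma = 0,
                            frame_interval = 0.5)
  tr <- render_trace(path, p, ph, seed = 1)
  expect_equal(tr$acceptor, rep(770, 10), tolerance = 1e-12)
  expect_equal(tr$donor, rep(230, 10), tolerance = 1e-12)
})

test_that("a dwell occupying half a frame renders the occupancy-weighted FRET", {
  p <- mock_preset(E_bound = 0.8)
  path <- mock_path(
    data.frame(time = c(0, 0.25), event = c("bind", "release"),
               site = "S1", position = NA_real_, remaining = NA_real_),
    duration = 1)
  ph <- photophysics_config(total_intensity = 1000, noise_sigma = 0,
                            frame_interval = 0.5)
  tr <- render_trace(path, p, ph, seed = 1)
  # frame 1: half at E = 0.8, half at baseline 0.05 -> 0.425
  expect_equal(tr$acceptor[1], 425, tolerance = 1e-9)
  expect_equal(tr$acceptor[2], 50, tolerance = 1e-9)
})

test_that("donor bleach drops both channels to background", {
  p <- mock_preset()
  path <- mock_path(
    data.frame(time = 0, event = "bind", site = "S1",
               position = NA_real_, remaining = NA_real_),
    duration = 10)
  ph <- photophysics_config(total_intensity = 1000, noise_sigma = 0,
                            background = 50, bleach_rate = 100,
                            frame_interval = 0.5)
  tr <- render_trace(path, p, ph, seed = 5)
  # with bleach_rate = 100 the donor dies within the first frame
  expect_equal(tr$donor, rep(50, 20), tolerance = 1e-9)
  expect_equal(tr$acceptor, rep(50, 20), tolerance = 1e-9)
})

test_that("rendered degradation observables are monotone in true FRET", {
  p3 <- get_preset("3ORDH")
  ph <- photophysics_config(frame_interval = 0.1, noise_sigma = 0)
  path <- simulate_state_path(p3, "degradation_sr", 5, duration = 10,
                              seed = 2)
  sub <- render_trace(path, p3, ph, seed = 3)
  E_sub <- sub$acceptor / (sub$acceptor + sub$donor)
  expect_true(all(diff(E_sub) >= -1e-12))
  trk <- simulate_state_path(p3, "enzyme_tracking", 5, duration = 10,
                             seed = 2)
  tt <- render_trace(trk, p3, ph, seed = 3)
  E_trk <- tt$acceptor / (tt$acceptor + tt$donor)
  # non-increasing while the enzyme stays engaged (up to final release)
  rel <- trk$events$time[trk$events$event == "release"]
  upto <- if (length(rel)) floor(min(rel) / 0.1) else length(E_trk)
  expect_true(all(diff(E_trk[seq_len(upto)]) <= 1e-12))
})
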