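test_that("generated EEG has the protocol's length, channels and annotations", {
  p <- protocol_spec(EC = 60, EO1 = 60, Circuit = 60, EO2 = 30,
                     Monotonous = 60, EO3 = 30)
  prof <- subject_profile("s", iaf_true = 10, seed = 1)
  g <- generate_eeg(prof, p)
  expect_equal(ncol(g$rec$data), 300 * 125)   # duration x rate
  expect_equal(g$rec$channels, EEG_CHANNELS)
  expect_equal(g$rec$annotations$label, CONDITIONS)
  expect_false(any(diff(g$rec$annotations$start) <= 0))
})

test_that("noise-free unit-amplitude alpha has mean-square energy 1/2", {
  p <- protocol_spec(EC = 60, EO1 = 60, Circuit = 30, EO2 = 30,
                     Monotonous = 30, EO3 = 30)
  prof <- subject_profile("s", iaf_true = 10, seed = 1)
  g <- generate_eeg(prof, p, noise_rms = 0, alpha_amp_uv = 1,
                    blink_rate = 0, artifact_frac = 0)
  # outside EC the gain is 1: a unit sine has mean square 0.5
  eo <- condition_segment(g$rec, "EO1")
  expect_equal(mean(eo$data["Pz", ]^2), 0.5, tolerance = 1e-3)
  # during EC the amplitude is boosted
  ec <- condition_segment(g$rec, "EC")
  expect_equal(mean(ec$data["Pz", ]^2), 0.5 * 4, tolerance = 1e-3)
  # frontal channels carry no alpha in the noise-free case
  expect_equal(max(abs(g$rec$data["AFz", ])), 0)
})

test_that("EEG generation is deterministic under a fixed seed", {
  p <- protocol_spec(EC = 60, EO1 = 40, Circuit = 30, EO2 = 30,
                     Monotonous = 30, EO3 = 30)
  prof <- subject_profile("s", iaf_true = 10.5, seed = 99)
  g1 <- generate_eeg(prof, p)
  g2 <- generate_eeg(prof, p)
  expect_identical(g1$rec$data, g2$rec$data)
  expect_identical(g1$truth, g2$truth)
})

test_that("noise-free parietal periodogram peaks at the true IAF", {
  p <- protocol_spec(EC = 60, EO1 = 40, Circuit = 30, EO2 = 30,
                     Monotonous = 30, EO3 = 30)
  for (iaf in c(8.5, 10.25, 11.5)) {
    prof <- subject_profile("s", iaf_true = iaf, seed = 1)
    g <- generate_eeg(prof, p, noise_rms = 0, alpha_amp_uv = 1,
                      blink_rate = 0, artifact_frac = 0)
    seg <- condition_segment(g$rec, "EC")
    ps <- fatiscope:::psd_welch(seg$data["P3", ], 125)
    peak <- ps$freq[which.max(ps$power)]
    expect_lte(abs(peak - iaf), 1)   # within the 1 Hz resolution
  }
})

test_that("planted blinks stay below the amplitude-rejection threshold", {
  p <- protocol_spec(EC = 60, EO1 = 40, Circuit = 60, EO2 = 30,
                     Monotonous = 120, EO3 = 30)
  prof <- subject_profile("s", seed = 3)
  g <- generate_eeg(prof, p, artifact_frac = 0)
  expect_gt(length(g$truth$blink_times), 0)
  expect_lte(max(abs(g$rec$data)), 200)
})

test_that("planted gaze events honor rate, duration and validity contracts", {
  aois <- default_aois()
  params <- default_gaze_params()
  params$fix_rate_low[] <- 0
  params$fix_rate_low[params$aoi == "Cockpit"] <- 0.3
  params$fix_dur[params$aoi == "Cockpit"] <- 0.2
  params$run_len[] <- 1
  params <- params[params$aoi == "Cockpit", ]
  win <- tibble::tibble(start = 0, end = 10, condition = "low")
  g <- generate_gaze(params, aois, win, seed = 5)
  expect_equal(nrow(g$truth), 3)              # 0.3 events/s x 10 s
  expect_equal(sum(g$truth$end - g$truth$start), 0.6, tolerance = 1e-9)
  expect_true(all(g$gaze$validity))           # zero invalid fraction
  expect_equal(nrow(g$gaze), 1000)
  # fixed seed reproduces the planted event list exactly
  g2 <- generate_gaze(params, aois, win, seed = 5)
  expect_identical(g$truth, g2$truth)
  expect_identical(g$gaze, g2$gaze)
})

test_that("invalid-sample flagging follows the requested fraction", {
  win <- tibble::tibble(start = 0, end = 30, condition = "low")
  g <- generate_gaze(default_gaze_params(), default_aois(), win,
                     invalid_frac = 0.1, seed = 2)
  expect_gt(mean(!g$gaze$validity), 0.05)
  expect_lt(mean(!g$gaze$validity), 0.15)
})

test_that("trace traversal is constant-speed with exact pass geometry", {
  path <- default_path()
  # longest straight is 500 m: at 10 m/s a pass lasts 50 s
  tr <- generate_trace(path, duration = 300, speed = 10, fs = 10)
  durs <- tr$truth$end - tr$truth$start
  full <- durs[tr$truth$start > 0 & tr$truth$end < 300]
  expect_true(all(abs(full - 50) <= 0.2))
  # heading is exactly the edge bearing in the noise-free case
  p1 <- tr$trace[tr$trace$t >= tr$truth$start[2] &
                   tr$trace$t < tr$truth$end[2], ]
  expect_equal(var(p1$heading), 0)
  # ~ duration * speed / perimeter passes over the longest straight
  tr45 <- generate_trace(path, duration = 2700, speed = 11.11, fs = 5)
  expected <- 2700 * 11.11 / path$perimeter
  expect_lte(abs(nrow(tr45$truth) - expected), 1.5)
})

test_that("ambiguous longest straight is rejected", {
  rect <- rbind(c(0, 0), c(400, 0), c(400, 100), c(0, 100))
  expect_error(path_spec(rect), "equal maximal length")
})

test_that("cohort draws honor the vehicle split and effect targets", {
  d <- cohort_design(n = 19)
  m <- draw_metric_cohort(d, seed = 1)
  one <- m[m$metric == "fixation_count_rate" & m$aoi == "Cockpit", ]
  expect_equal(sum(one$vehicle == "van"), 9)
  expect_equal(sum(one$vehicle == "truck"), 10)
  # Monte-Carlo: sample d of the paired difference concentrates near the
  # target at n = 19
  ds <- vapply(1:400, function(s) {
    mm <- draw_metric_cohort(d, seed = s)
    cc <- mm[mm$metric == "fixation_count_rate" & mm$aoi == "Cockpit", ]
    diffs <- cc$low - cc$high
    mean(diffs) / sd(diffs)
  }, numeric(1))
  # sampling SD of d at n = 19 is ~0.26, so +-0.35 captures ~80% of
  # cohorts and the Monte-Carlo mean sits on the target
  expect_gt(mean(abs(ds - 0.806) <= 0.35), 0.72)
  expect_lt(abs(mean(ds) - 0.806), 0.08)
  # null metric: paired t rejects at about the nominal rate
  rej <- vapply(1:400, function(s) {
    mm <- draw_metric_cohort(d, seed = 10000 + s)
    rr <- mm[mm$aoi == "Road", ]
    t.test(rr$low, rr$high, paired = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("non-positive effect variance is rejected", {
  eff <- default_gaze_effects()
  eff$delta_sd[1] <- 0
  expect_error(cohort_design(effects = eff), "positive")
})

test_that("session bundles are deterministic and share one clock", {
  d <- test_design(mono = 400)
  b1 <- generate_session(d, seed = 11)
  b2 <- generate_session(d, seed = 11)
  expect_identical(b1$eeg$data, b2$eeg$data)
  expect_identical(b1$gaze, b2$gaze)
  expect_identical(b1$truth$passes, b2$truth$passes)
  # gaze and trace live inside the monotonous task of the EEG clock
  mono <- b1$eeg$annotations[b1$eeg$annotations$label == "Monotonous", ]
  expect_true(all(b1$gaze$t >= mono$start & b1$gaze$t <= mono$end))
  expect_true(all(b1$trace$t >= mono$start & b1$trace$t <= mono$end))
  # planted fixation time never exceeds the window span per AoI
  per_win <- split(b1$truth$fixations, b1$truth$fixations$window)
  for (w in per_win) {
    expect_lte(sum(w$end - w$start),
               max(w$end) - min(w$start) + 1e-9)
  }
})
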