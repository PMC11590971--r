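grid_gaze <- function(x, y, fs = 100, valid = NULL) {
  n <- length(x)
  tibble::tibble(t = (seq_len(n) - 1) / fs, x = x, y = y,
                 validity = valid %||% rep(TRUE, n))
}

test_that("constant gaze is one long fixation; fast sweeps are none", {
  n <- 500
  g <- grid_gaze(rep(0.5, n), rep(0.5, n))
  fx <- classify_fixations(g)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration, (n - 1) / 100)
  expect_equal(c(fx$x, fx$y), c(0.5, 0.5))
  # pure linear sweep at 3x threshold speed: no fixation at all
  sweep <- grid_gaze(seq(0, 4.5, by = 0.045) %% 1, rep(0.5, 101))
  expect_equal(nrow(classify_fixations(sweep)), 0)
})

test_that("two planted fixations separated by a saccade are both found", {
  g <- generate_gaze(
    tibble::tibble(aoi = "Road", fix_rate_low = 0.4, fix_rate_high = 0.4,
                   fix_dur = 0.3, run_len = 1,
                   visit_share_low = NA, visit_share_high = NA),
    default_aois(),
    tibble::tibble(start = 0, end = 5, condition = "low"), seed = 8)
  expect_equal(nrow(g$truth), 2)
  fx <- classify_fixations(g$gaze)
  expect_equal(nrow(fx), 2)
  tr <- g$truth[order(g$truth$start), ]
  expect_true(all(abs(fx$start - tr$start) <= 0.0101))
  expect_true(all(abs(fx$end - tr$end) <= 0.0101))
})

test_that("all-invalid gaze yields an empty result with a warning", {
  g <- grid_gaze(rep(0.5, 50), rep(0.5, 50), valid = rep(FALSE, 50))
  expect_warning(fx <- classify_fixations(g), "valid")
  expect_equal(nrow(fx), 0)
})

test_that("invalid samples break fixation groups without interpolation", {
  n <- 30
  valid <- rep(TRUE, n); valid[15] <- FALSE
  g <- grid_gaze(rep(0.5, n), rep(0.5, n), valid = valid)
  fx <- classify_fixations(g, merge_gap_s = 0)   # merging disabled
  expect_equal(nrow(fx), 2)
  # with the default merge gap the two halves fuse again
  fx2 <- classify_fixations(g)
  expect_equal(nrow(fx2), 1)
})

test_that("I-VT matches the brute-force oracle on random streams", {
  for (s in 1:200) {
    g <- with_seed(s, {
      n <- sample(5:50, 1)
      # mixture of dwells and jumps mimicking fixation/saccade structure
      x <- cumsum(sample(c(0, 0.002, 0.05), n, replace = TRUE,
                         prob = c(0.5, 0.3, 0.2)))
      y <- 0.5 + cumsum(rnorm(n, 0, 0.002))
      grid_gaze(x %% 1, y %% 1,
                valid = runif(n) > 0.1)
    })
    mine <- classify_fixations(g)
    orc <- oracle_ivt(g)
    expect_equal(nrow(mine), nrow(orc), info = paste("seed", s))
    if (nrow(mine) && nrow(mine) == nrow(orc)) {
      expect_equal(mine$start, orc$start, info = paste("seed", s))
      expect_equal(mine$end, orc$end, info = paste("seed", s))
      expect_equal(mine$x, orc$x, info = paste("seed", s))
    }
  }
})

test_that("AoI assignment respects membership, priority and the display", {
  aois <- default_aois()
  fx <- tibble::tibble(start = 1:5, end = 2:6, duration = 1,
                       x = c(0.5, 0.5, 0.05, 0.5, -1),
                       y = c(0.5, 0.85, 0.05, 0.765, -1), n = 1)
  out <- assign_aoi(fx, aois)
  expect_equal(out$aoi,
               c("Road", "Cockpit", "ExternalEnvironment",
                 # inside CockpitTotal only (below Road, outside Cockpit)
                 "CockpitTotal",
                 NA))
  # a point on the shared Road/ExternalEnvironment boundary goes to the
  # higher-priority AoI (Road)
  edge <- tibble::tibble(start = 1, end = 2, duration = 1,
                         x = 0.15, y = 0.5, n = 1)
  expect_equal(assign_aoi(edge, aois)$aoi, "Road")
  # a vertex shared by Cockpit and CockpitTotal resolves to Cockpit
  vert <- tibble::tibble(start = 1, end = 2, duration = 1,
                         x = 0.40, y = 0.78, n = 1)
  expect_equal(assign_aoi(vert, aois)$aoi, "Cockpit")
})

test_that("visits span unbroken same-AoI runs including saccade time", {
  fx <- tibble::tibble(
    start = c(0, 0.5, 1.2), end = c(0.3, 0.9, 1.5),
    duration = 0.3, x = 0.5, y = 0.5, n = 10,
    aoi = c("Road", "Road", "Cockpit"))
  v <- build_visits(fx)
  expect_equal(nrow(v), 2)
  expect_equal(v$aoi, c("Road", "Cockpit"))
  expect_equal(v$duration[1], 0.9)          # saccade between the two included
  expect_equal(v$n_fixations, c(2L, 1L))
  # alternating AoIs never merge: 8 fixations -> 8 visits
  alt <- tibble::tibble(start = seq(0, 3.5, 0.5), end = seq(0.2, 3.7, 0.5),
                        duration = 0.2, x = 0.5, y = 0.5, n = 5,
                        aoi = rep(c("Road", "Cockpit"), 4))
  expect_equal(nrow(build_visits(alt)), 8)
  # off-AoI fixations break runs and produce no visit
  gap <- fx; gap$aoi <- c("Road", NA, "Road")
  vg <- build_visits(gap)
  expect_equal(nrow(vg), 2)
  expect_equal(vg$aoi, c("Road", "Road"))
})

test_that("planted run structure is recovered as visits exactly", {
  win <- tibble::tibble(start = c(0, 60), end = c(45, 105),
                        condition = c("low", "high"))
  for (s in c(3, 14, 27)) {
    g <- generate_gaze(default_gaze_params(), default_aois(), win, seed = s)
    fx <- assign_aoi(classify_fixations(g$gaze), default_aois())
    v <- build_visits(fx, max_gap_s = 10)
    expect_equal(nrow(v), nrow(g$visits))
    expect_equal(v$aoi, g$visits$aoi)
    expect_equal(v$n_fixations, g$visits$n_fixations)
    expect_true(all(abs(v$duration - g$visits$duration) <= 0.021))
  }
})

test_that("window metrics are rates, shares and averages", {
  aois <- default_aois()
  fx <- tibble::tibble(
    start = c(1, 3, 5), end = c(1.2, 3.2, 5.2), duration = 0.2,
    x = 0.5, y = 0.85, n = 20, aoi = "Cockpit")
  v <- build_visits(fx)
  m <- window_metrics(fx, v, list(start = 0, end = 10), aois)
  ck <- m[m$aoi == "Cockpit", ]
  expect_equal(ck$fixation_count_rate, 0.3)
  expect_equal(ck$avg_fixation_duration, 0.2)
  expect_equal(ck$total_fixation_share, 0.06)
  rd <- m[m$aoi == "Road", ]
  expect_equal(unlist(rd[, -1]), rep(0, 6), ignore_attr = TRUE)
  # per-AoI fixation time never exceeds visit time; shares bounded
  expect_true(all(m$total_fixation_share <= m$total_visit_share + 1e-12))
  expect_true(all(m$total_visit_share <= 1))
})

test_that("rates are invariant to duplicating the window", {
  win1 <- tibble::tibble(start = 0, end = 40, condition = "low")
  win2 <- tibble::tibble(start = c(0, 40), end = c(40, 80),
                         condition = "low")
  g1 <- generate_gaze(default_gaze_params(), default_aois(), win1, seed = 5)
  g2 <- generate_gaze(default_gaze_params(), default_aois(), win2, seed = 5)
  f1 <- assign_aoi(classify_fixations(g1$gaze), default_aois())
  f2 <- assign_aoi(classify_fixations(g2$gaze), default_aois())
  m1 <- window_metrics(f1, build_visits(f1, 10), list(start = 0, end = 40),
                       default_aois())
  m2 <- window_metrics(f2, build_visits(f2, 10), list(start = 0, end = 80),
                       default_aois())
  # both windows were planted at the same rates: doubling the horizon
  # moves rates only by the per-window rounding of planted counts
  expect_true(all(abs(m1$fixation_count_rate - m2$fixation_count_rate)
                  <= 1 / 40))
})

test_that("an empty window warns and returns zeros", {
  aois <- default_aois()
  fx <- tibble::tibble(start = double(), end = double(),
                       duration = double(), x = double(), y = double(),
                       n = integer(), aoi = character())
  expect_warning(
    m <- window_metrics(fx, build_visits(fx), list(start = 5, end = 5),
                        aois),
    "empty")
  expect_true(all(m$fixation_count_rate == 0))
})

test_that("gaze TSV and AoI JSON round-trip", {
  win <- tibble::tibble(start = 0, end = 5, condition = "low")
  g <- generate_gaze(default_gaze_params(), default_aois(), win,
                     invalid_frac = 0.05, seed = 2)
  p1 <- tempfile(fileext = ".tsv")
  write_gaze_tsv(g$gaze, p1)
  back <- read_gaze_tsv(p1)
  expect_equal(back$x, g$gaze$x, tolerance = 1e-12)
  expect_equal(back$validity, g$gaze$validity)
  p2 <- tempfile(fileext = ".json")
  write_aoi_json(default_aois(), p2)
  aback <- read_aoi_json(p2)
  expect_equal(aback$name, default_aois()$name)
  expect_equal(aback$vertices[[2]], default_aois()$vertices[[2]],
               ignore_attr = TRUE)
  unlink(c(p1, p2))
})
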