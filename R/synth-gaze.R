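#' Default per-AoI gaze parameters for the synthetic generator
#'
#' Fixation rates (events/s) and total visit-duration shares for the low-
#' and high-fatigue states, per AoI. Cockpit and External-Environment
#' values mirror the study's reported condition means (Cockpit attention
#' drops under fatigue, External Environment rises); Road carries no
#' fatigue effect and its level, the fixation durations and the run
#' lengths (fixations per visit) are realistic conventions documented in
#' the methods vignette.
#'
#' @return Tibble with columns `aoi, fix_rate_low, fix_rate_high, fix_dur,
#'   run_len, visit_share_low, visit_share_high`.
#' @export
default_gaze_params <- function() {
  tibble::tribble(
    ~aoi,                  ~fix_rate_low, ~fix_rate_high, ~fix_dur, ~run_len,
    ~visit_share_low, ~visit_share_high,
    "Road",                0.60,  0.60,  0.30, 2, 0.280, 0.280,
    "Cockpit",             0.243, 0.190, 0.25, 2, 0.220, 0.162,
    "ExternalEnvironment", 0.141, 0.205, 0.30, 1, NA,    NA,
    "CockpitTotal",        0.02,  0.02,  0.25, 1, NA,    NA
  )
}

# Distance from a point to the nearest polygon edge.
polygon_edge_distance <- function(px, py, v) {
  n <- nrow(v)
  nxt <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  min(point_segment_distance(px, py, v[, 1], v[, 2], nxt[, 1], nxt[, 2]))
}

# Rejection-sample a fixation centroid that (a) lies in the target AoI with
# a safety margin from its boundary and the display edge, and (b) would be
# assigned back to that AoI under the priority rule.
sample_point_in_aoi <- function(aois, name, margin = 0.01, near = NULL,
                                near_sd = 0.01, tries = 400) {
  k <- which(aois$name == name)
  v <- aois$vertices[[k]]
  higher <- if (k > 1) aois$vertices[seq_len(k - 1)] else list()
  lo <- pmax(apply(v, 2, min), margin)
  hi <- pmin(apply(v, 2, max), 1 - margin)
  for (i in seq_len(tries)) {
    if (!is.null(near)) {
      p <- near + rnorm(2, 0, near_sd)
    } else {
      p <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    }
    if (p[1] < margin || p[1] > 1 - margin ||
        p[2] < margin || p[2] > 1 - margin) next
    if (!point_in_polygon(p[1], p[2], v)) next
    if (polygon_edge_distance(p[1], p[2], v) < margin) next
    if (any(vapply(higher, function(h) point_in_polygon(p[1], p[2], h),
                   logical(1)))) next
    return(p)
  }
  if (!is.null(near))
    return(sample_point_in_aoi(aois, name, margin, NULL, tries = tries))
  stop(sprintf("could not place a fixation centroid inside AoI '%s'", name),
       call. = FALSE)
}

# Constant-speed wandering between two anchor points. Returns `n` positions
# strictly between A and B: piecewise-linear sweeps at `sweep_speed`
# (direction changes every ~150 ms; coordinates wrap at the display edge,
# where the wrap chord is fast, never slow), ending far enough from B that
# the chord into the next fixation is itself a fast saccade. Every
# inter-sample speed a velocity classifier sees thus stays above any
# reasonable fixation threshold and no spurious fixation can form.
fill_gap <- function(A, B, n, dt, sweep_speed = 3, saccade_speed = 6) {
  if (n <= 0) return(matrix(numeric(0), ncol = 2))
  step <- sweep_speed * dt
  seg <- pmax(1, round(stats::rexp(n, rate = 1 / 15)))
  seg <- seg[cumsum(seg) - seg < n]
  ang <- rep(runif(length(seg), 0, 2 * pi), times = seg)[seq_len(n)]
  walk <- cbind((A[1] + cumsum(step * cos(ang))) %% 1,
                (A[2] + cumsum(step * sin(ang))) %% 1)
  # the entry saccade into the next fixation is the chord walk[n] -> B;
  # keep it comfortably above threshold speed
  d_end <- sqrt(sum((walk[n, ] - B)^2))
  if (d_end < saccade_speed * dt) {
    u <- walk[n, ] - walk[max(1, n - 1), ]
    nu <- sqrt(sum(u^2))
    u <- if (nu < 1e-9) c(1, 0) else u / nu
    p <- B - saccade_speed * dt * 1.5 * u
    walk[n, ] <- pmin(pmax(p, 0), 1)
  }
  walk
}

# Build the planted event schedule for one window: per-AoI fixation counts
# are grouped into runs (visits); within-run gaps realize the target visit
# spans, between-run gaps absorb the remaining time in shuffled order.
schedule_window <- function(params, condition, w0, w1) {
  T <- w1 - w0
  rate_col <- paste0("fix_rate_", condition)
  share_col <- paste0("visit_share_", condition)
  runs <- list()
  for (r in seq_len(nrow(params))) {
    p <- params[r, ]
    n_f <- round(p[[rate_col]] * T)
    if (n_f < 1) next
    k <- max(1L, as.integer(p$run_len))
    sizes <- rep(k, n_f %/% k)
    if (n_f %% k) sizes <- c(sizes, n_f %% k)
    n_gaps <- n_f - length(sizes)
    # within-run gaps stay above the classifier's merge gap so planted
    # events can never fuse
    g <- 0.1
    share <- p[[share_col]]
    if (!is.na(share) && n_gaps > 0) {
      g <- (share * T - n_f * p$fix_dur) / n_gaps
      g <- min(max(g, 0.1), T / 4)
    }
    for (s in sizes)

      runs[[length(runs) + 1]] <- list(aoi = p$aoi, n = s, fix_dur = p$fix_dur,
                                       gap = g,
                                       span = s * p$fix_dur + (s - 1) * g)
  }
  if (!length(runs)) return(NULL)
  # shuffle runs, avoiding same-AoI adjacency where feasible so planted
  # runs map 1:1 onto visits
  aoi_of <- vapply(runs, `[[`, character(1), "aoi")
  order <- integer(0)
  remaining <- seq_along(runs)
  last <- ""
  while (length(remaining)) {
    cand <- remaining[aoi_of[remaining] != last]
    if (!length(cand)) cand <- remaining
    pick <- cand[sample.int(length(cand), 1)]
    order <- c(order, pick)
    last <- aoi_of[pick]
    remaining <- setdiff(remaining, pick)
  }
  runs <- runs[order]
  # feasibility: extreme tail draws can request more event time than the
  # window holds; drop trailing runs until the schedule fits
  repeat {
    spans <- vapply(runs, `[[`, numeric(1), "span")
    slack <- T - sum(spans)
    if (slack >= 0.2 * (length(runs) + 1) || !length(runs)) break
    runs <- runs[-length(runs)]
  }
  if (!length(runs))
    stop("window too short for any planted fixation run", call. = FALSE)
  w <- runif(length(runs) + 1, 0.2, 1)
  gaps <- 0.15 + (slack - 0.15 * (length(runs) + 1)) * w / sum(w)
  t_cursor <- w0
  events <- list()
  for (i in seq_along(runs)) {
    t_cursor <- t_cursor + gaps[i]
    r <- runs[[i]]
    for (j in seq_len(r$n)) {
      events[[length(events) + 1]] <-
        tibble::tibble(aoi = r$aoi, start = t_cursor,
                       end = t_cursor + r$fix_dur, run = i)
      t_cursor <- t_cursor + r$fix_dur + if (j < r$n) r$gap else 0
    }
  }
  dplyr::bind_rows(events)
}

#' Generate a synthetic gaze stream with planted fixations and visits
#'
#' For each requested window, fixation events are planted per AoI at the
#' condition's rates (grouped into runs realizing the visit-duration
#' targets); gaze samples jitter around each fixation's centroid
#' (sd `jitter_sd`) and move between events at sweep/saccade speeds that a
#' velocity-threshold classifier identifies as saccades. Coordinates are
#' normalized display units in [0,1]^2, origin top-left; time is seconds on
#' the session clock. A configurable fraction of samples is flagged
#' invalid.
#'
#' @param params per-AoI parameter tibble ([default_gaze_params()]) or a
#'   [subject_profile()] carrying one.
#' @param aois an [aoi_set()].
#' @param windows tibble `start, end, condition` with condition `"low"` or
#'   `"high"` (seconds; non-overlapping, increasing).
#' @param fs sampling rate, Hz.
#' @param jitter_sd within-fixation gaze jitter, normalized units.
#' @param sweep_speed inter-event wandering speed, units/s.
#' @param saccade_speed approach-saccade speed, units/s (the generator's
#'   sweeps are calibrated to exceed the default I-VT threshold several
#'   times over).
#' @param invalid_frac fraction of samples flagged invalid.
#' @param seed RNG seed (`NULL`: derive substream from a profile's seed, or
#'   leave the RNG alone).
#' @return List: `gaze` (tibble `t, x, y, validity`) and `truth` (tibble of
#'   planted fixations `aoi, start, end, x, y, run, window, condition`).
#' @export
generate_gaze <- function(params, aois, windows, fs = 100,
                          jitter_sd = 0.003, sweep_speed = 3,
                          saccade_speed = 6, invalid_frac = 0,
                          seed = NULL) {
  if (inherits(params, "subject_profile")) {
    if (is.null(seed)) seed <- substream_seed(params$seed, "gaze")
    params <- params$gaze_params %||% default_gaze_params()
  }
  assert_that(all(windows$end > windows$start), "invalid window intervals")
  run_gen <- function() {
    all_gaze <- list(); all_truth <- list()
    for (wi in seq_len(nrow(windows))) {
      w0 <- windows$start[wi]; w1 <- windows$end[wi]
      ev <- schedule_window(params, windows$condition[wi], w0, w1)
      tt <- seq(w0, w1 - 1 / fs, by = 1 / fs)
      xy <- matrix(NA_real_, length(tt), 2)
      if (!is.null(ev)) {
        # centroids: runs share a neighborhood inside their AoI
        ev$x <- NA_real_; ev$y <- NA_real_
        last_run <- -1; last_p <- NULL
        for (i in seq_len(nrow(ev))) {
          p <- if (ev$run[i] == last_run) {
            sample_point_in_aoi(aois, ev$aoi[i], near = last_p)
          } else sample_point_in_aoi(aois, ev$aoi[i])
          assert_that(all(p >= 0 & p <= 1), "fixation centroid off display")
          ev$x[i] <- p[1]; ev$y[i] <- p[2]
          last_run <- ev$run[i]; last_p <- p
        }
        # fixation samples
        in_fix <- rep(0L, length(tt))
        for (i in seq_len(nrow(ev))) {
          sel <- which(tt >= ev$start[i] & tt < ev$end[i])
          # truncated-Gaussian jitter: radius capped below half a
          # threshold-speed step so within-fixation chords are always slow
          jx <- rnorm(length(sel), 0, jitter_sd)
          jy <- rnorm(length(sel), 0, jitter_sd)
          r <- sqrt(jx^2 + jy^2)
          cap <- 1.65 * jitter_sd
          shrink <- ifelse(r > cap, cap / r, 1)
          xy[sel, 1] <- ev$x[i] + jx * shrink
          xy[sel, 2] <- ev$y[i] + jy * shrink
          in_fix[sel] <- i
        }
        # gap samples
        gap_runs <- rle(in_fix == 0L)
        ends <- cumsum(gap_runs$lengths)
        starts <- ends - gap_runs$lengths + 1
        for (gi in which(gap_runs$values)) {
          a <- starts[gi]; b <- ends[gi]
          A <- if (a == 1) c(runif(1, 0.3, 0.7), runif(1, 0.3, 0.7)) else xy[a - 1, ]
          B <- if (b == length(tt)) NULL else c(ev$x[in_fix[b + 1]], ev$y[in_fix[b + 1]])
          if (is.null(B)) B <- c(runif(1, 0.3, 0.7), runif(1, 0.3, 0.7))
          xy[a:b, ] <- fill_gap(A, B, b - a + 1, 1 / fs, sweep_speed,
                                saccade_speed)
        }
        ev$window <- wi
        ev$condition <- windows$condition[wi]
        all_truth[[wi]] <- ev
      } else {
        xy[] <- fill_gap(c(0.5, 0.5), c(0.5, 0.5), length(tt), 1 / fs,
                         sweep_speed, saccade_speed)
      }
      validity <- runif(length(tt)) >= invalid_frac
      all_gaze[[wi]] <- tibble::tibble(t = tt, x = xy[, 1], y = xy[, 2],
                                       validity = validity)
    }
    truth <- dplyr::bind_rows(all_truth)
    # expected visits: adjacent same-AoI runs (if adjacency was forced)
    # merge, exactly as build_visits will see them
    visits <- NULL
    if (nrow(truth)) {
      key <- paste(truth$window, truth$aoi)
      vid <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
      visits <- dplyr::bind_rows(lapply(split(seq_len(nrow(truth)), vid),
        function(i) tibble::tibble(
          aoi = truth$aoi[i[1]], start = truth$start[i[1]],
          end = truth$end[i[length(i)]], window = truth$window[i[1]],
          condition = truth$condition[i[1]], n_fixations = length(i))))
      visits$duration <- visits$end - visits$start
    }
    list(gaze = dplyr::bind_rows(all_gaze), truth = truth, visits = visits)
  }
  if (is.null(seed)) run_gen() else with_seed(seed, run_gen())
}
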