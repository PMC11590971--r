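#' Default paired effect structure for the ocular metrics
#'
#' Per AoI x metric: the low-fatigue population mean and between-subject
#' SD, and the mean and SD of the per-subject paired difference
#' (low - high), so that `delta_mean / delta_sd` is the targeted
#' standardized paired difference (Cohen's d). Defaults encode the study's
#' reported pattern: Cockpit fixation rate and total visit share drop
#' under high fatigue (d = 0.806 and 0.773), the External-Environment
#' fixation rate rises (d = -0.483), and the Road metrics carry no effect.
#'
#' @return Tibble `aoi, metric, mean_low, sd_low, delta_mean, delta_sd`.
#' @export
default_gaze_effects <- function() {
  tibble::tribble(
    ~aoi, ~metric, ~mean_low, ~sd_low, ~delta_mean, ~delta_sd,
    "Cockpit", "fixation_count_rate", 0.243, 0.086, 0.053, 0.053 / 0.806,
    "Cockpit", "total_visit_share",   0.220, 0.106, 0.058, 0.058 / 0.773,
    "ExternalEnvironment", "fixation_count_rate",
                                      0.141, 0.146, -0.064, 0.064 / 0.483,
    "Road", "fixation_count_rate",    0.600, 0.150, 0.000, 0.080
  )
}

#' Cohort design: the study conditions the generator emulates
#'
#' Bundles everything a synthetic cohort needs: sample size and vehicle
#' split, protocol durations, driving-path geometry and speed, the paired
#' ocular effect structure, alpha-dynamics settings and questionnaire
#' response distributions.
#'
#' @param n number of subjects (default 19; split into van drivers
#'   `floor(n/2)` and truck drivers the rest, i.e. 9/10 at n = 19).
#' @param protocol a [protocol_spec()].
#' @param path a [path_spec()] with a unique longest straight.
#' @param speed vehicle speed, m/s (40 km/h default).
#' @param effects paired effect structure ([default_gaze_effects()]).
#' @param gaze_base per-AoI baseline gaze parameters
#'   ([default_gaze_params()]).
#' @param peak_frac position of the alpha-gain peak within the Monotonous
#'   task (fraction of its duration).
#' @param peak_gain,bump_sigma alpha-bump amplitude and width (s); see
#'   [alpha_gain_bump()].
#' @param snr_ec eyes-closed alpha SNR.
#' @param kss_mu,kss_sd questionnaire sleepiness means (Arrival, Circuit,
#'   Monotonous) and residual SD.
#' @param chalder_p per-condition success probability of the six mental
#'   fatigue items (each item ~ Binomial(3, p)).
#' @param subject_sd between-subject questionnaire random intercept SD.
#' @return List of class `cohort_design`.
#' @export
cohort_design <- function(n = 19,
                          protocol = protocol_spec(),
                          path = default_path(),
                          speed = 11.11,
                          effects = default_gaze_effects(),
                          gaze_base = default_gaze_params(),
                          peak_frac = 0.75, peak_gain = 2, bump_sigma = 120,
                          snr_ec = 3,
                          kss_mu = c(3.0, 3.4, 4.9), kss_sd = 1.1,
                          chalder_p = c(0.22, 0.28, 0.40),
                          subject_sd = 0.8) {
  assert_that(n >= 2, "need at least two subjects")
  assert_that(all(effects$sd_low > 0 & effects$delta_sd > 0),
              "effect SDs must be positive")
  structure(list(n = n, protocol = protocol, path = path, speed = speed,
                 effects = effects, gaze_base = gaze_base,
                 peak_frac = peak_frac, peak_gain = peak_gain,
                 bump_sigma = bump_sigma, snr_ec = snr_ec,
                 kss_mu = kss_mu, kss_sd = kss_sd, chalder_p = chalder_p,
                 subject_sd = subject_sd),
            class = "cohort_design")
}

#' Default driving loop
#'
#' A closed five-edge loop with a unique 500 m longest straight; at
#' 40 km/h a pass over it lasts ~45 s and a lap ~2 min, giving ~22 passes
#' over a 45-min monotonous drive.
#'
#' @return A [path_spec()].
#' @export
default_path <- function() {
  path_spec(rbind(c(0, 0), c(500, 0), c(560, 100), c(240, 180), c(-60, 100)))
}

vehicle_split <- function(n) {
  c(rep("van", floor(n / 2)), rep("truck", n - floor(n / 2)))
}

#' Draw per-subject paired metric values from the design's distributions
#'
#' The statistical core of the cohort generator: for every AoI x metric in
#' the design's effect table, subject i gets
#' `low_i ~ N(mean_low, sd_low)` and `high_i = low_i - delta_i` with
#' `delta_i ~ N(delta_mean, delta_sd)`, so the population standardized
#' paired difference equals `delta_mean / delta_sd` exactly. Values are
#' kept un-truncated here (the paired structure stays exactly Gaussian);
#' physical floors are applied only when events are planted in a session.
#'
#' @param design a [cohort_design()].
#' @param seed RNG seed.
#' @return Tibble `subject, vehicle, aoi, metric, low, high`.
#' @export
draw_metric_cohort <- function(design, seed = 1) {
  n <- design$n
  with_seed(substream_seed(seed, "metrics"), {
    out <- lapply(seq_len(nrow(design$effects)), function(r) {
      e <- design$effects[r, ]
      low <- rnorm(n, e$mean_low, e$sd_low)
      delta <- rnorm(n, e$delta_mean, e$delta_sd)
      high <- low - delta
      tibble::tibble(subject = sprintf("S%02d", seq_len(n)),
                     vehicle = vehicle_split(n),
                     aoi = e$aoi, metric = e$metric, low = low, high = high)
    })
    dplyr::bind_rows(out)
  })
}

#' Synthetic questionnaire responses over the three assessment points
#'
#' Sleepiness ratings are discretized Gaussians around the per-condition
#' means (clamped to 1-9); the six mental fatigue items are
#' Binomial(3, p) draws with condition-dependent p; a per-subject random
#' intercept induces the repeated-measures correlation.
#'
#' @param design a [cohort_design()].
#' @param seed RNG seed.
#' @return Tibble `subject, vehicle, condition, kss, item1..item6,
#'   kss_score, chalder_score`.
#' @export
generate_questionnaires <- function(design, seed = 1) {
  n <- design$n
  conds <- c("Arrival", "Circuit", "Monotonous")
  with_seed(substream_seed(seed, "quest"), {
    subj_int <- rnorm(n, 0, design$subject_sd)
    rows <- list()
    for (i in seq_len(n)) for (j in seq_along(conds)) {
      kss <- round(rnorm(1, design$kss_mu[j] + subj_int[i], design$kss_sd))
      kss <- min(9, max(1, kss))
      p <- min(0.95, max(0.02,
                         design$chalder_p[j] + subj_int[i] * 0.05))
      items <- rbinom(6, 3, p)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = sprintf("S%02d", i), vehicle = vehicle_split(n)[i],
        condition = conds[j], kss = kss,
        item1 = items[1], item2 = items[2], item3 = items[3],
        item4 = items[4], item5 = items[5], item6 = items[6]
      )
    }
    out <- dplyr::bind_rows(rows)
    sc <- score_questionnaires(out$kss,
                               out[, paste0("item", 1:6)])
    dplyr::bind_cols(out, sc)
  })
}

#' Generate a full synthetic cohort of driving sessions
#'
#' Produces one complete session bundle per subject: annotated EEG with a
#' per-subject true IAF and an alpha-gain bump peaking inside a known
#' straight pass of the monotonous drive, the vehicle trace over the
#' design's loop, gaze for every straight pass (the peak pass planted
#' with the subject's high-fatigue parameters, all others with the
#' low-fatigue ones), questionnaire responses, and the ground truth
#' needed to validate every downstream stage.
#'
#' @param n number of subjects (overrides the design's `n` when given).
#' @param design a [cohort_design()].
#' @param seed master cohort seed; per-subject and per-stream seeds are
#'   derived from it.
#' @return List of session bundles; each bundle is a list with
#'   `subject_id, vehicle, profile, eeg, trace, gaze, questionnaires,
#'   truth` (truth: `iaf_true, artifact_epochs, t_peak, peak_pass,
#'   passes, fixations, visits, metrics`).
#' @export
generate_cohort <- function(n = NULL, design = cohort_design(), seed = 1) {
  n <- n %||% design$n
  assert_that(n >= 2, "need at least two subjects")
  metrics <- draw_metric_cohort(
    cohort_design_with_n(design, n), substream_seed(seed, "cohort"))
  quest <- generate_questionnaires(cohort_design_with_n(design, n),
                                   substream_seed(seed, "cohort"))
  vehicles <- vehicle_split(n)
  lapply(seq_len(n), function(i) {
    sid <- sprintf("S%02d", i)
    generate_session(design, subject_id = sid, vehicle = vehicles[i],
                     metrics = metrics[metrics$subject == sid, ],
                     quest = quest[quest$subject == sid, ],
                     seed = substream_seed(seed, paste0("subject", i)))
  })
}

#' Generate a single synthetic driving session
#'
#' The per-subject workhorse behind [generate_cohort()], exposed for
#' scenario tests that need one session at a time.
#'
#' @param design a [cohort_design()].
#' @param subject_id,vehicle identifiers for the bundle.
#' @param metrics one subject's rows of [draw_metric_cohort()] (`NULL`:
#'   drawn fresh from the design).
#' @param quest the subject's questionnaire rows (`NULL`: omitted).
#' @param seed per-subject master seed.
#' @return A session bundle (see [generate_cohort()]).
#' @export
generate_session <- function(design, subject_id = "S01", vehicle = "van",
                             metrics = NULL, quest = NULL, seed = 1) {
  mono <- design$protocol$annotations[
    design$protocol$annotations$label == "Monotonous", ]
  if (is.null(metrics)) {
    m <- draw_metric_cohort(cohort_design_with_n(design, 2),
                            substream_seed(seed, "metrics"))
    metrics <- m[m$subject == "S01", ]
    metrics$subject <- subject_id
  }
  iaf_true <- with_seed(substream_seed(seed, "iaf"), runif(1, 8.5, 11.5))
  tr <- generate_trace(design$path, duration = mono$end - mono$start,
                       speed = design$speed, t0 = mono$start,
                       seed = substream_seed(seed, "trace"))
  passes <- tr$truth
  # the alpha-gain peak is planted at the midpoint of the pass nearest the
  # requested fraction of the drive, so the high-fatigue window has an
  # unambiguous ground truth
  mids <- (passes$start + passes$end) / 2
  target <- mono$start + design$peak_frac * (mono$end - mono$start)
  peak_pass <- passes$pass_index[which.min(abs(mids - target))]
  if (peak_pass == 1 && nrow(passes) > 1) peak_pass <- 2
  t_peak <- mids[peak_pass]
  gp <- subject_gaze_params(design, metrics)
  profile <- subject_profile(
    subject_id, iaf_true = iaf_true, vehicle_group = vehicle,
    alpha_gain = alpha_gain_bump(t_peak, design$peak_gain,
                                 design$bump_sigma),
    gaze_params = gp, seed = seed)
  eeg <- generate_eeg(profile, design$protocol, snr_ec = design$snr_ec)
  windows <- tibble::tibble(
    start = passes$start, end = passes$end,
    condition = ifelse(passes$pass_index == peak_pass, "high", "low"))
  gz <- generate_gaze(profile, default_aois(), windows,
                      seed = substream_seed(seed, "gaze"))
  list(subject_id = subject_id, vehicle = vehicle, profile = profile,
       eeg = eeg$rec, trace = tr$trace, gaze = gz$gaze,
       questionnaires = quest,
       truth = list(iaf_true = iaf_true,
                    artifact_epochs = eeg$truth$artifact_epochs,
                    blink_times = eeg$truth$blink_times,
                    t_peak = t_peak, peak_pass = peak_pass,
                    passes = passes, fixations = gz$truth,
                    visits = gz$visits, metrics = metrics))
}

cohort_design_with_n <- function(design, n) {
  design$n <- n
  design
}

# Per-subject gaze parameter table: the design's baseline with the drawn
# low/high rates and visit shares substituted.
subject_gaze_params <- function(design, m) {
  gp <- design$gaze_base
  for (r in seq_len(nrow(m))) {
    a <- m$aoi[r]
    if (m$metric[r] == "fixation_count_rate") {
      # physical floor: a session cannot plant a negative rate
      gp$fix_rate_low[gp$aoi == a] <- max(m$low[r], 0.02)
      gp$fix_rate_high[gp$aoi == a] <- max(m$high[r], 0.02)
    } else if (m$metric[r] == "total_visit_share") {
      gp$visit_share_low[gp$aoi == a] <- max(m$low[r], 0.02)
      gp$visit_share_high[gp$aoi == a] <- max(m$high[r], 0.02)
    }
  }
  gp
}
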