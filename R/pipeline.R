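#' Analyze one session bundle: EEG to labeled windows to ocular metrics
#'
#' Runs the full single-subject chain: preprocessing, epoching with
#' amplitude/ocular rejection, IAF and strict-alpha band, parietal GFP,
#' MDrow standardization, straight-pass extraction, low/high window
#' labeling, I-VT fixation classification, AoI assignment, visit
#' construction, and the six per-AoI metrics for both windows.
#'
#' @param bundle a session bundle from [generate_cohort()] /
#'   [generate_session()] (or an equivalently shaped list of real data).
#' @param design the [cohort_design()] describing geometry and protocol.
#' @param aois an [aoi_set()].
#' @return List: `iaf`, `mdrow`, `passes`, `windows`, `fixations`,
#'   `visits`, `metrics` (tibble `subject, vehicle, window, aoi, metric,
#'   value`), `resting` (per-EO mean MDrow), `data_loss`.
#' @export
analyze_session <- function(bundle, design, aois = default_aois()) {
  pre <- preprocess_eeg(bundle$eeg)
  ep <- epoch_and_reject(pre)
  iaf <- estimate_iaf(pre, epochs = ep)
  gfp <- compute_gfp(pre, ep, strict_alpha(iaf))
  md <- compute_mdrow(gfp, ep, bundle$eeg$annotations)
  passes <- extract_straight_passes(bundle$trace, design$path)
  fw <- label_windows(md, passes)
  fx <- classify_fixations(bundle$gaze)
  fx <- assign_aoi(fx, aois)
  vis <- build_visits(fx, max_gap_s = 30)
  metric_rows <- lapply(c(low = "low", high = "high"), function(w) {
    win <- fw[[w]]
    m <- window_metrics(fx, vis, win, aois)
    tidyr::pivot_longer(m, -"aoi", names_to = "metric", values_to = "value")
  })
  metrics <- dplyr::bind_rows(metric_rows, .id = "window")
  metrics$subject <- bundle$subject_id
  metrics$vehicle <- bundle$vehicle
  resting <- resting_state_mdrow(md, bundle$eeg$annotations)
  list(iaf = iaf, mdrow = md, passes = passes, windows = fw,
       fixations = fx, visits = vis,
       metrics = metrics[, c("subject", "vehicle", "window", "aoi",
                             "metric", "value")],
       resting = resting, data_loss = attr(ep, "loss_fraction"))
}

#' Statistical comparison layer over a cohort's metric table
#'
#' For every AoI x metric (CockpitTotal excluded by default): Shapiro-Wilk
#' gated paired contrast of low vs high fatigue with Cohen's d, plus a
#' FATIGUE x VEHICLE mixed ANOVA. The resting-state MDrow means get a
#' RESTING STATE x VEHICLE mixed ANOVA, and each questionnaire score a
#' Friedman + Conover/Holm analysis (plus per-vehicle-group agreement).
#'
#' @param metrics tibble `subject, vehicle, window, aoi, metric, value`.
#' @param resting tibble `subject, vehicle, condition, mdrow` (optional).
#' @param quest questionnaire tibble from [generate_questionnaires()]
#'   (optional).
#' @param exclude_aois AoIs left out of the statistics.
#' @return List: `contrasts` (tibble), `fatigue_anova` (tibble),
#'   `resting_anova`, `questionnaires` (list of [friedman_conover()]
#'   results and group agreement).
#' @export
cohort_statistics <- function(metrics, resting = NULL, quest = NULL,
                              exclude_aois = "CockpitTotal") {
  m <- metrics[!(metrics$aoi %in% exclude_aois), ]
  wide <- tidyr::pivot_wider(m, names_from = "window",
                             values_from = "value")
  combos <- unique(wide[, c("aoi", "metric")])
  contrasts <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    d <- wide[wide$aoi == combos$aoi[i] & wide$metric == combos$metric[i], ]
    res <- paired_contrast(d$low, d$high)
    tibble::tibble(aoi = combos$aoi[i], metric = combos$metric[i], res)
  }))
  fatigue_anova <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    d <- m[m$aoi == combos$aoi[i] & m$metric == combos$metric[i], ]
    d <- data.frame(subject = d$subject, vehicle = d$vehicle,
                    condition = d$window, value = d$value)
    a <- mixed_anova(d, within = "condition", between = "vehicle")
    tibble::tibble(aoi = combos$aoi[i], metric = combos$metric[i], a)
  }))
  resting_anova <- NULL
  if (!is.null(resting)) {
    d <- data.frame(subject = resting$subject, vehicle = resting$vehicle,
                    condition = resting$condition, value = resting$mdrow)
    resting_anova <- mixed_anova(d, within = "condition",
                                 between = "vehicle")
  }
  questionnaires <- NULL
  if (!is.null(quest)) {
    to_mat <- function(col) {
      w <- tidyr::pivot_wider(quest[, c("subject", "condition", col)],
                              names_from = "condition",
                              values_from = dplyr::all_of(col))
      as.matrix(w[, c("Arrival", "Circuit", "Monotonous")])
    }
    kss_m <- to_mat("kss_score")
    cha_m <- to_mat("chalder_score")
    groups <- quest$vehicle[quest$condition == "Arrival"]
    questionnaires <- list(
      kss = friedman_conover(kss_m),
      chalder = friedman_conover(cha_m),
      kss_by_vehicle = friedman_by_group(kss_m, groups),
      chalder_by_vehicle = friedman_by_group(cha_m, groups)
    )
  }
  list(contrasts = contrasts, fatigue_anova = fatigue_anova,
       resting_anova = resting_anova, questionnaires = questionnaires)
}

#' Run the whole pipeline: simulate, analyze, compare, report
#'
#' Deterministic end-to-end run: generates a synthetic cohort under the
#' given design, analyzes every session ([analyze_session()]), assembles
#' the cohort metric table and runs the statistical layer
#' ([cohort_statistics()]). When `out_dir` is given, the metric table,
#' contrast table, ANOVA tables, per-subject windows and the resolved
#' configuration are written beside each other.
#'
#' @param design a [cohort_design()].
#' @param seed master seed; the run is reproducible from it.
#' @param n number of subjects (defaults to the design's).
#' @param out_dir optional output directory.
#' @return List of class `run_report`: `subjects` (per-subject analysis
#'   summaries), `metrics`, `stats`, `windows`, `data_loss`, `config`.
#' @export
run_pipeline <- function(design = cohort_design(), seed = 1, n = NULL,
                         out_dir = NULL) {
  n <- n %||% design$n
  cohort <- generate_cohort(n = n, design = design, seed = seed)
  aois <- default_aois()
  analyses <- lapply(cohort, analyze_session, design = design, aois = aois)
  metrics <- dplyr::bind_rows(lapply(analyses, `[[`, "metrics"))
  resting <- dplyr::bind_rows(lapply(seq_along(cohort), function(i) {
    tibble::tibble(subject = cohort[[i]]$subject_id,
                   vehicle = cohort[[i]]$vehicle,
                   condition = names(analyses[[i]]$resting),
                   mdrow = unname(analyses[[i]]$resting))
  }))
  quest <- dplyr::bind_rows(lapply(cohort, `[[`, "questionnaires"))
  stats <- cohort_statistics(metrics, resting, quest)
  windows <- dplyr::bind_rows(lapply(seq_along(cohort), function(i) {
    fw <- analyses[[i]]$windows
    tibble::tibble(subject = cohort[[i]]$subject_id,
                   low_start = fw$low$start, low_end = fw$low$end,
                   high_pass = fw$high$pass_index,
                   high_start = fw$high$start, high_end = fw$high$end,
                   high_score = fw$high_score,
                   truth_peak_pass = cohort[[i]]$truth$peak_pass)
  }))
  config <- list(n = n, seed = seed,
                 protocol = as.list(design$protocol$durations),
                 speed = design$speed, peak_frac = design$peak_frac,
                 peak_gain = design$peak_gain,
                 bump_sigma = design$bump_sigma, snr_ec = design$snr_ec)
  report <- list(
    subjects = tibble::tibble(
      subject = vapply(cohort, `[[`, character(1), "subject_id"),
      vehicle = vapply(cohort, `[[`, character(1), "vehicle"),
      iaf = vapply(analyses, function(a) a$iaf$iaf, numeric(1)),
      iaf_true = vapply(cohort, function(b) b$truth$iaf_true, numeric(1)),
      data_loss = vapply(analyses, `[[`, numeric(1), "data_loss")),
    metrics = metrics, stats = stats, windows = windows,
    resting = resting, config = config)
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(stats$contrasts, file.path(out_dir, "contrasts.csv"),
              row.names = FALSE)
    write.csv(stats$fatigue_anova, file.path(out_dir, "fatigue_anova.csv"),
              row.names = FALSE)
    write.csv(windows, file.path(out_dir, "windows.csv"), row.names = FALSE)
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d subjects, seed %d\n",
              nrow(x$subjects), x$config$seed))
  cat("paired contrasts (low vs high fatigue):\n")
  print(x$stats$contrasts[, c("aoi", "metric", "test_used", "statistic",
                              "p", "d")], n = 20)
  invisible(x)
}
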