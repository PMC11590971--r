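#!/usr/bin/env Rscript

# Thin command-line wrapper over the fatiscope package.
#
#   Rscript scripts/fatiscope.R run      --n 6 --mono 600 --seed 1 --out out/
#   Rscript scripts/fatiscope.R simulate --n 2 --mono 400 --seed 1 --out out/
#   Rscript scripts/fatiscope.R eeg      --in out/S01_eeg.csv --out out/S01_mdrow.csv
#   Rscript scripts/fatiscope.R label    --mdrow out/S01_mdrow.csv --trace out/S01_trace.csv --out out/S01_windows.json
#   Rscript scripts/fatiscope.R gaze     --gaze out/S01_gaze.tsv --aoi out/aois.json --windows out/S01_windows.json --out out/S01_metrics.csv
#   Rscript scripts/fatiscope.R stats    --metrics out/metrics.csv --out out/contrasts.csv

suppressMessages({
  library(optparse)
  library(fatiscope)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[1] else "help"
rest <- args[-1]

opt <- function(list) parse_args(OptionParser(option_list = list), rest)

design_from <- function(o) {
  cohort_design(n = o$n, protocol = protocol_spec(
    EC = 60, EO1 = 40, Circuit = 60, EO2 = 30, Monotonous = o$mono,
    EO3 = 30))
}

switch(cmd,
  run = {
    o <- opt(list(
      make_option("--n", type = "integer", default = 6),
      make_option("--mono", type = "double", default = 600),
      make_option("--seed", type = "integer", default = 1),
      make_option("--out", type = "character", default = "fatiscope-out")))
    rep <- run_pipeline(design = design_from(o), seed = o$seed,
                        out_dir = o$out)
    print(rep)
  },
  simulate = {
    o <- opt(list(
      make_option("--n", type = "integer", default = 2),
      make_option("--mono", type = "double", default = 400),
      make_option("--seed", type = "integer", default = 1),
      make_option("--out", type = "character", default = "fatiscope-out")))
    dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
    d <- design_from(o)
    cohort <- generate_cohort(n = o$n, design = d, seed = o$seed)
    write_aoi_json(default_aois(), file.path(o$out, "aois.json"))
    for (b in cohort) {
      pre <- file.path(o$out, b$subject_id)
      write_eeg_csv(b$eeg, paste0(pre, "_eeg.csv"))
      write_gaze_tsv(b$gaze, paste0(pre, "_gaze.tsv"))
      write_trace_csv(b$trace, paste0(pre, "_trace.csv"))
      jsonlite::write_json(b$truth[c("iaf_true", "artifact_epochs",
                                     "t_peak", "peak_pass")],
                           paste0(pre, "_truth.json"), auto_unbox = TRUE,
                           digits = NA)
    }
    cat("wrote", length(cohort), "session bundles to", o$out, "\n")
  },
  eeg = {
    o <- opt(list(
      make_option("--in", type = "character", dest = "input"),
      make_option("--baseline", type = "character", default = "EO1"),
      make_option("--out", type = "character", default = "mdrow.csv")))
    rec <- read_eeg_csv(o$input)
    pre <- preprocess_eeg(rec)
    ep <- epoch_and_reject(pre)
    iaf <- estimate_iaf(pre, epochs = ep)
    gfp <- compute_gfp(pre, ep, strict_alpha(iaf))
    md <- compute_mdrow(gfp, ep, rec$annotations,
                        baseline_condition = o$baseline)
    write_mdrow_csv(md, o$out)
    cat(sprintf("IAF %.2f Hz; wrote %s\n", iaf$iaf, o$out))
  },
  label = {
    o <- opt(list(
      make_option("--mdrow", type = "character"),
      make_option("--trace", type = "character"),
      make_option("--out", type = "character", default = "windows.json")))
    md <- read.csv(o$mdrow)
    md <- tibble::tibble(t = md$t, gfp_alpha = md$gfp_alpha,
                         mdrow = md$mdrow, mdrow_smooth = md$mdrow_smooth,
                         artifact = md$artifact_flag == 1)
    passes <- extract_straight_passes(read_trace_csv(o$trace),
                                      default_path())
    fw <- label_windows(md, passes)
    jsonlite::write_json(
      list(low = c(fw$low$start, fw$low$end),
           high = c(fw$high$start, fw$high$end),
           high_score = fw$high_score),
      o$out, auto_unbox = TRUE, digits = NA)
    print(fw)
  },
  gaze = {
    o <- opt(list(
      make_option("--gaze", type = "character"),
      make_option("--aoi", type = "character"),
      make_option("--windows", type = "character"),
      make_option("--out", type = "character", default = "metrics.csv")))
    gz <- read_gaze_tsv(o$gaze)
    aois <- read_aoi_json(o$aoi)
    wins <- jsonlite::read_json(o$windows, simplifyVector = TRUE)
    fx <- assign_aoi(classify_fixations(gz), aois)
    vis <- build_visits(fx, max_gap_s = 30)
    out <- dplyr::bind_rows(lapply(c("low", "high"), function(w) {
      m <- window_metrics(fx, vis,
                          list(start = wins[[w]][1], end = wins[[w]][2]),
                          aois)
      m$window <- w
      m
    }))
    write.csv(out, o$out, row.names = FALSE)
    cat("wrote", o$out, "\n")
  },
  stats = {
    o <- opt(list(
      make_option("--metrics", type = "character"),
      make_option("--out", type = "character", default = "contrasts.csv")))
    m <- tibble::as_tibble(read.csv(o$metrics))
    st <- cohort_statistics(m)
    write.csv(st$contrasts, o$out, row.names = FALSE)
    print(st$contrasts)
  },
  {
    cat("usage: Rscript scripts/fatiscope.R <run|simulate|eeg|label|gaze|stats> [options]\n")
    if (cmd != "help") quit(status = 1)
  }
)
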