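#' Build AoI visits from classified fixations
#'
#' A visit is an unbroken run of consecutive same-AoI fixations; it spans
#' from the start of the first to the end of the last fixation of the run,
#' so intervening saccade time is included in the visit duration. The run
#' breaks when the next fixation's AoI differs (fixations outside every
#' AoI break runs too and produce no visit).
#'
#' @param fixations time-ordered tibble from [assign_aoi()] (needs `aoi`).
#' @param max_gap_s additionally break a run when consecutive fixations are
#'   separated by more than this (use for disjoint analysis windows;
#'   default `Inf` = AoI changes only).
#' @return Tibble of visit events: `aoi, start, end, duration, n_fixations`.
#' @export
build_visits <- function(fixations, max_gap_s = Inf) {
  assert_that("aoi" %in% names(fixations),
              "fixations must carry an `aoi` column (see assign_aoi)")
  f <- fixations[order(fixations$start), ]
  if (nrow(f) == 0)
    return(tibble::tibble(aoi = character(), start = double(),
                          end = double(), duration = double(),
                          n_fixations = integer()))
  key <- ifelse(is.na(f$aoi), "<none>", f$aoi)
  gap_break <- if (nrow(f) > 1) {
    f$start[-1] - f$end[-nrow(f)] > max_gap_s
  } else logical(0)
  run_id <- cumsum(c(TRUE, key[-1] != key[-length(key)] | gap_break))
  out <- lapply(split(seq_len(nrow(f)), run_id), function(i) {
    if (is.na(f$aoi[i[1]])) return(NULL)
    tibble::tibble(aoi = f$aoi[i[1]], start = f$start[i[1]],
                   end = f$end[i[length(i)]],
                   n_fixations = length(i))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out)) out$duration <- out$end - out$start
  out[, c("aoi", "start", "end", "duration", "n_fixations")]
}

# Clip events to [w0, w1); returns events with positive overlap, durations
# truncated to the window.
clip_events <- function(ev, w0, w1) {
  if (nrow(ev) == 0) return(ev)
  s <- pmax(ev$start, w0)
  e <- pmin(ev$end, w1)
  keep <- e > s
  ev <- ev[keep, ]
  ev$start <- s[keep]; ev$end <- e[keep]
  ev$duration <- ev$end - ev$start
  ev
}

#' Six per-AoI visual-attention metrics within a time window
#'
#' Events are clipped to the window; counts are divided by the window
#' duration so metrics are rates and shares, comparable across windows of
#' unequal length: fixation count rate (events/s), average fixation
#' duration (s), total fixation duration share (s/s), and the same three
#' for visits.
#'
#' @param fixations [assign_aoi()] output.
#' @param visits [build_visits()] output.
#' @param window one-row pass tibble (or list) with `start` and `end`, s.
#' @param aois an [aoi_set()]; one output row per AoI.
#' @return Tibble: `aoi, fixation_count_rate, avg_fixation_duration,
#'   total_fixation_share, visit_count_rate, avg_visit_duration,
#'   total_visit_share`.
#' @export
window_metrics <- function(fixations, visits, window, aois) {
  dur <- window$end - window$start
  if (!is.finite(dur) || dur <= 0) {
    warning("empty window; all metrics zero")
    dur <- NA_real_
  }
  fx <- clip_events(fixations, window$start, window$end)
  vs <- clip_events(visits, window$start, window$end)
  rows <- lapply(aois$name, function(a) {
    f <- fx[!is.na(fx$aoi) & fx$aoi == a, ]
    v <- vs[vs$aoi == a, ]
    tibble::tibble(
      aoi = a,
      fixation_count_rate = if (is.na(dur)) 0 else nrow(f) / dur,
      avg_fixation_duration = if (nrow(f)) mean(f$duration) else 0,
      total_fixation_share = if (is.na(dur)) 0 else sum(f$duration) / dur,
      visit_count_rate = if (is.na(dur)) 0 else nrow(v) / dur,
      avg_visit_duration = if (nrow(v)) mean(v$duration) else 0,
      total_visit_share = if (is.na(dur)) 0 else sum(v$duration) / dur
    )
  })
  dplyr::bind_rows(rows)
}
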