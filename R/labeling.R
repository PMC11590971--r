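# Perpendicular distance from points to a segment (with endpoint clamping).
point_segment_distance <- function(x, y, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  u <- pmin(1, pmax(0, ((x - x0) * dx + (y - y0) * dy) / len2))
  sqrt((x - (x0 + u * dx))^2 + (y - (y0 + u * dy))^2)
}

circular_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Extract passes over the longest straight segment of the path
#'
#' A pass is a maximal time interval in which the vehicle is within
#' `lane_tol` metres of the longest straight edge and its heading is within
#' `heading_tol` degrees of the edge bearing (either traversal direction).
#' Passes shorter than `min_pass_s` are dropped. Gating all comparisons on
#' these homogeneous straight-driving intervals removes the activity-related
#' variability between the compared windows.
#'
#' @param trace tibble `t, x, y, heading` from [generate_trace()] or a
#'   trajectory reader.
#' @param path the [path_spec()] geometry.
#' @param lane_tol lateral tolerance, m.
#' @param heading_tol heading tolerance, degrees.
#' @param min_pass_s minimal pass duration, s.
#' @return Tibble of class `straight_passes`: `pass_index, start, end`
#'   (seconds, end exclusive), ordered and non-overlapping.
#' @export
extract_straight_passes <- function(trace, path, lane_tol = 3,
                                    heading_tol = 10, min_pass_s = 5) {
  e <- path$edges[path$longest_edge, ]
  d <- point_segment_distance(trace$x, trace$y, e$x0, e$y0, e$x1, e$y1)
  hd <- pmin(circular_diff_deg(trace$heading, e$bearing),
             circular_diff_deg(trace$heading, (e$bearing + 180) %% 360))
  on <- d < lane_tol & hd < heading_tol
  if (!any(on))
    stop("no pass over the longest straight found; trace/geometry mismatch",
         call. = FALSE)
  runs <- rle(on)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  dt <- median(diff(trace$t))
  out <- tibble::tibble(
    start = trace$t[starts[runs$values]],
    end = trace$t[ends[runs$values]] + dt
  )
  out <- out[out$end - out$start >= min_pass_s, ]
  if (nrow(out) == 0)
    stop("all candidate passes shorter than `min_pass_s`", call. = FALSE)
  out$pass_index <- seq_len(nrow(out))
  out <- out[, c("pass_index", "start", "end")]
  class(out) <- c("straight_passes", class(out))
  out
}

#' Label the paired low/high fatigue windows from the MDrow series
#'
#' The low-fatigue window is the first pass over the longest straight (the
#' start of the monotonous drive, assumed minimally fatigued). The
#' high-fatigue window is the pass - excluding the first, so the paired
#' contrast is well-defined even for a flat index - with the highest mean
#' smoothed MDrow; ties go to the later pass. Candidate passes need at
#' least `min_valid_frac` non-artifact epochs.
#'
#' @param mdrow a [compute_mdrow()] series.
#' @param passes an [extract_straight_passes()] table (>= 2 passes).
#' @param min_valid_frac minimal fraction of clean epochs per candidate.
#' @return List of class `fatigue_windows`: `low`, `high` (one-row pass
#'   tibbles), `high_score` (mean smoothed MDrow over the high window).
#' @export
label_windows <- function(mdrow, passes, min_valid_frac = 0.5) {
  assert_that(nrow(passes) >= 2, "need at least two straight passes")
  score <- vapply(seq_len(nrow(passes)), function(i) {
    sel <- mdrow$t >= passes$start[i] & mdrow$t < passes$end[i]
    if (!any(sel)) return(NA_real_)
    if (mean(!mdrow$artifact[sel]) < min_valid_frac) return(NA_real_)
    mean(mdrow$mdrow_smooth[sel], na.rm = TRUE)
  }, numeric(1))
  cand <- score
  cand[1] <- NA                      # first pass is the Low reference
  if (all(is.na(cand)))
    stop("all candidate passes are artifact-dominated", call. = FALSE)
  best <- max(cand, na.rm = TRUE)
  high_i <- max(which(!is.na(cand) & cand >= best - 1e-12))  # tie -> later
  out <- list(low = passes[1, ], high = passes[high_i, ],
              high_score = score[high_i], pass_scores = score)
  class(out) <- "fatigue_windows"
  out
}

#' @export
print.fatigue_windows <- function(x, ...) {
  cat(sprintf(
    "<fatigue_windows> low: pass 1 [%.1f, %.1f) s; high: pass %d [%.1f, %.1f) s (score %.2f)\n",
    x$low$start, x$low$end, x$high$pass_index, x$high$start, x$high$end,
    x$high_score))
  invisible(x)
}
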