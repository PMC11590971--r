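#' I-VT fixation classification
#'
#' Velocity-threshold identification: point-to-point speeds are computed
#' between consecutive valid, gap-free samples, and each sample is
#' classified by the smaller of its two adjacent interval speeds (endpoint
#' samples use their single neighbor), so fixation boundaries are not
#' smeared by the transition interval. A sample is a fixation sample when
#' that speed is at or below `vel_threshold`. Invalid samples break
#' fixation groups - no interpolation. Adjacent groups are merged when the
#' gap between them is shorter than `merge_gap_s` and their centroids are
#' within `merge_dist` (dispersion bound); groups shorter than `min_fix_s`
#' are then discarded. Event duration is the span from first to last member
#' sample; the centroid is the mean of member samples.
#'
#' @param gaze tibble `t, x, y, validity` (t strictly increasing; x, y in
#'   normalized display units).
#' @param vel_threshold speed threshold, normalized units/s.
#' @param min_fix_s minimal fixation duration, s.
#' @param merge_gap_s maximal gap for merging adjacent groups, s.
#' @param merge_dist maximal centroid distance for merging, units.
#' @param max_interval_s intervals longer than this (recording gaps,
#'   window boundaries) always break fixation groups, s.
#' @return Tibble of fixation events: `start, end, duration, x, y, n`.
#' @export
classify_fixations <- function(gaze, vel_threshold = 1.5, min_fix_s = 0.06,
                               merge_gap_s = 0.075, merge_dist = 0.02,
                               max_interval_s = 0.1) {
  empty <- tibble::tibble(start = double(), end = double(),
                          duration = double(), x = double(), y = double(),
                          n = integer())
  assert_that(all(diff(gaze$t) > 0), "gaze timestamps must be increasing")
  valid <- which(gaze$validity)
  if (length(valid) < 2) {
    warning("fewer than two valid gaze samples; no fixations")
    return(empty)
  }
  t <- gaze$t[valid]; x <- gaze$x[valid]; y <- gaze$y[valid]
  m <- length(valid)
  # interval speeds; intervals spanning an invalid sample do not count
  contig <- diff(valid) == 1 & diff(t) <= max_interval_s
  v <- sqrt(diff(x)^2 + diff(y)^2) / diff(t)
  v[!contig] <- Inf
  back <- c(Inf, v)
  fwd <- c(v, Inf)
  slow <- pmin(back, fwd) <= vel_threshold
  # groups: consecutive slow samples not separated by a validity gap
  brk <- c(TRUE, !contig) | !slow
  grp_id <- cumsum(brk)
  groups <- split(which(slow), grp_id[slow])
  if (!length(groups)) return(empty)
  ev <- do.call(rbind, lapply(groups, function(i) {
    data.frame(start = t[i[1]], end = t[i[length(i)]],
               x = mean(x[i]), y = mean(y[i]), n = length(i))
  }))
  ev <- ev[order(ev$start), , drop = FALSE]
  merged <- list()
  cur <- ev[1, ]
  if (nrow(ev) > 1) for (k in 2:nrow(ev)) {
    nxt <- ev[k, ]
    gap <- nxt$start - cur$end
    dist <- sqrt((nxt$x - cur$x)^2 + (nxt$y - cur$y)^2)
    if (gap < merge_gap_s && dist <= merge_dist) {
      w <- c(cur$n, nxt$n)
      cur$x <- sum(c(cur$x, nxt$x) * w) / sum(w)
      cur$y <- sum(c(cur$y, nxt$y) * w) / sum(w)
      cur$end <- nxt$end
      cur$n <- sum(w)
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- nxt
    }
  }
  merged[[length(merged) + 1]] <- cur
  out <- tibble::as_tibble(do.call(rbind, merged))
  out$duration <- out$end - out$start
  out <- out[out$duration >= min_fix_s, ]
  tibble::as_tibble(out[, c("start", "end", "duration", "x", "y", "n")])
}
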