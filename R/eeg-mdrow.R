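#' Mental drowsiness index (MDrow) from parietal alpha GFP
#'
#' Standardizes the per-epoch strict-alpha parietal GFP against a resting
#' baseline condition (first eyes-open rest by default):
#' `mdrow(t) = (gfp(t) - mean_baseline) / sd_baseline`, computed over the
#' baseline's non-artifact epochs, then smoothed with a centered moving
#' average over `smoothing_epochs` non-artifact epochs. The index rises as
#' parietal alpha synchronization (fatigue) builds up. Flagged epochs carry
#' `NA`, never silent zeros.
#'
#' @param gfp per-epoch GFP from [compute_gfp()].
#' @param epochs the matching [epoch_and_reject()] result.
#' @param annotations condition annotations of the source recording.
#' @param baseline_condition label of the standardization baseline.
#' @param smoothing_epochs width (in non-artifact epochs) of the centered
#'   moving average; 1 disables smoothing.
#' @return A tibble of class `mdrow_series`: `t` (epoch start, s),
#'   `gfp_alpha`, `mdrow` (standardized), `mdrow_smooth`, `artifact`.
#' @export
compute_mdrow <- function(gfp, epochs, annotations,
                          baseline_condition = "EO1",
                          smoothing_epochs = 10) {
  ann <- annotations[annotations$label == baseline_condition, ]
  if (nrow(ann) == 0)
    stop(sprintf("baseline condition '%s' not annotated", baseline_condition),
         call. = FALSE)
  flagged <- epochs$artifact | epochs$ocular
  in_base <- epochs$start >= ann$start[1] & epochs$start < ann$end[1] & !flagged
  assert_that(sum(in_base) >= 10,
              "baseline must contain at least 10 clean epochs")
  mu <- mean(gfp[in_base])
  s <- sd(gfp[in_base])
  if (!is.finite(s) || s <= 0)
    stop("baseline GFP variance is zero; cannot standardize", call. = FALSE)
  mdrow <- (gfp - mu) / s
  smooth <- rep(NA_real_, length(mdrow))
  ok <- which(!flagged & is.finite(mdrow))
  if (smoothing_epochs > 1 && length(ok)) {
    k <- min(smoothing_epochs, length(ok))
    smooth[ok] <- zoo::rollapply(mdrow[ok], width = k, FUN = mean,
                                 partial = TRUE, align = "center")
  } else smooth[ok] <- mdrow[ok]
  out <- tibble::tibble(
    t = epochs$start,
    gfp_alpha = gfp,
    mdrow = mdrow,
    mdrow_smooth = smooth,
    artifact = flagged
  )
  attr(out, "baseline_ref") <- baseline_condition
  attr(out, "baseline_mean") <- mu
  attr(out, "baseline_sd") <- s
  class(out) <- c("mdrow_series", class(out))
  out
}

#' Mean MDrow over the eyes-open resting conditions
#'
#' Fatigue is assessed immediately before and after each driving task via
#' the three eyes-open rests; this returns the mean (unsmoothed) MDrow over
#' the non-artifact epochs of each.
#'
#' @param mdrow a [compute_mdrow()] series.
#' @param annotations condition annotations of the source recording.
#' @param conditions eyes-open labels, all of which must be annotated.
#' @return Named numeric vector of per-condition means (`NA` with a warning
#'   for a fully artifactual condition).
#' @export
resting_state_mdrow <- function(mdrow, annotations,
                                conditions = c("EO1", "EO2", "EO3")) {
  missing <- setdiff(conditions, annotations$label)
  if (length(missing))
    stop("missing condition annotation(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- vapply(conditions, function(cond) {
    ann <- annotations[annotations$label == cond, ]
    sel <- mdrow$t >= ann$start[1] & mdrow$t < ann$end[1] & !mdrow$artifact
    if (!any(sel)) {
      warning(sprintf("condition '%s' is fully artifactual", cond))
      return(NA_real_)
    }
    mean(mdrow$mdrow[sel])
  }, numeric(1))
  names(out) <- conditions
  out
}
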