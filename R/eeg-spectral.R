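# Welch power spectral density with Hann windows.
#
# `win_s`-second segments (default 1 s, i.e. 1 Hz resolution), 50% overlap,
# Hann taper, periodograms averaged and compensated by the taper mean square.
# Returns freq (Hz) and power (uV^2 per bin). Hand-built on stats::fft: the
# installed `signal` port has no Welch estimator.
psd_welch <- function(x, fs, win_s = 1, overlap = 0.5, good = NULL) {
  n <- round(win_s * fs)
  assert_that(length(x) >= n, "signal shorter than one analysis window")
  step <- max(1, round(n * (1 - overlap)))
  starts <- seq(1, length(x) - n + 1, by = step)
  if (!is.null(good)) {
    starts <- starts[vapply(starts, function(s) all(good[s:(s + n - 1)]),
                            logical(1))]
    assert_that(length(starts) > 0, "no artifact-free analysis window")
  }
  w <- hann_window(n)
  comp <- mean(w^2)
  nf <- floor(n / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + n - 1)] * w
    p <- abs(fft(seg))^2 / n
    acc <- acc + p[seq_len(nf)]
  }
  pow <- acc / length(starts) / comp / n   # density-like normalization
  list(freq = (seq_len(nf) - 1) * fs / n, power = pow)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

# Three-point parabolic refinement of a spectral peak on log power.
parabolic_peak <- function(freq, power, k) {
  if (k <= 1 || k >= length(power)) return(freq[k])
  y <- log(pmax(power[(k - 1):(k + 1)], .Machine$double.xmin))
  denom <- y[1] - 2 * y[2] + y[3]
  if (!is.finite(denom) || abs(denom) < 1e-300) return(freq[k])
  delta <- 0.5 * (y[1] - y[3]) / denom
  delta <- max(-0.5, min(0.5, delta))
  freq[k] + delta * (freq[2] - freq[1])
}

#' Estimate the Individual Alpha Frequency from eyes-closed rest
#'
#' Averages Welch PSDs (1-s Hann windows, 1 Hz resolution, 50% overlap) over
#' the parietal channels of the eyes-closed segment and takes the frequency
#' of maximal power inside `search_band`, refined by parabolic interpolation
#' of the peak bin. If the peak does not rise above `prominence_min` times
#' the median in-band power (no discernible alpha peak), the canonical 10 Hz
#' fallback is returned with a warning.
#'
#' @param rec an [eeg_recording()] containing an `EC` annotation (or already
#'   restricted to eyes-closed data if it has no annotations).
#' @param search_band frequency window searched for the alpha peak, Hz.
#' @param channels channels averaged (parietal by default).
#' @param condition annotation label of the eyes-closed segment.
#' @param epochs optional [epoch_and_reject()] result for the same
#'   recording; analysis windows overlapping flagged epochs are excluded.
#' @param prominence_min minimal peak / median in-band power ratio.
#' @return A list of class `iaf_estimate`: `iaf` (Hz), `search_band`,
#'   `peak_prominence`, `fallback` (logical).
#' @export
estimate_iaf <- function(rec, search_band = c(7, 13),
                         channels = PARIETAL_CHANNELS,
                         condition = "EC", epochs = NULL,
                         prominence_min = 2) {
  has_cond <- nrow(rec$annotations) && condition %in% rec$annotations$label
  seg <- if (has_cond) condition_segment(rec, condition) else rec
  assert_that(rec_duration(seg) >= 30,
              "eyes-closed segment must be at least 30 s long")
  good <- NULL
  if (!is.null(epochs)) {
    # per-sample clean mask, sliced to the analysed segment
    spe <- round(attr(epochs, "epoch_s") * rec$fs)
    mask <- rep(TRUE, ncol(rec$data))
    for (e in which(epochs$artifact | epochs$ocular))
      mask[((e - 1) * spe + 1):min(ncol(rec$data), e * spe)] <- FALSE
    off <- if (has_cond) {
      floor(rec$annotations$start[rec$annotations$label == condition][1] *
              rec$fs)
    } else 0
    good <- mask[off + seq_len(ncol(seg$data))]
  }
  chans <- intersect(channels, seg$channels)
  assert_that(length(chans) > 0, "no requested channel present")
  psds <- lapply(chans,
                 function(ch) psd_welch(seg$data[ch, ], seg$fs, good = good))
  freq <- psds[[1]]$freq
  power <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
  in_band <- which(freq >= search_band[1] & freq <= search_band[2])
  k <- in_band[which.max(power[in_band])]
  prom <- power[k] / median(power[in_band])
  if (!is.finite(prom) || prom < prominence_min) {
    warning("no prominent alpha peak in search band; falling back to 10 Hz")
    est <- list(iaf = 10, search_band = search_band,
                peak_prominence = prom, fallback = TRUE)
  } else {
    iaf <- parabolic_peak(freq, power, k)
    iaf <- max(search_band[1], min(search_band[2], iaf))
    est <- list(iaf = iaf, search_band = search_band,
                peak_prominence = prom, fallback = FALSE)
  }
  class(est) <- "iaf_estimate"
  est
}

#' @export
print.iaf_estimate <- function(x, ...) {
  cat(sprintf("<iaf_estimate> IAF = %.2f Hz (prominence %.1f%s)\n",
              x$iaf, x$peak_prominence,
              if (x$fallback) ", fallback" else ""))
  invisible(x)
}

#' Subject-specific strict alpha band
#'
#' The 2 Hz-wide band (IAF - 1, IAF + 1), tighter than the conventional
#' (IAF - 2, IAF + 2), to keep theta and beta variation out of the alpha
#' measurements.
#'
#' @param iaf an [estimate_iaf()] result or a plain frequency in Hz.
#' @return Numeric `c(lo, hi)` of class `alpha_band`.
#' @export
strict_alpha <- function(iaf) {
  f <- if (inherits(iaf, "iaf_estimate")) iaf$iaf else iaf
  assert_that(is.finite(f), "IAF must be finite")
  structure(c(lo = f - 1, hi = f + 1), class = "alpha_band")
}

#' Per-epoch parietal global field power in a frequency band
#'
#' The selected channels are band-pass filtered into `band` (4th-order
#' zero-phase Butterworth over the whole recording, so epoch interiors carry
#' no edge transients), each epoch is tapered with a Hann window, and the
#' GFP is the mean over samples of the mean over channels of the squared
#' signal, rescaled by the taper's mean square (3/8) so a unit-amplitude
#' in-band sine yields 0.5. Artifact and ocular epochs yield `NA`.
#'
#' @param rec the preprocessed [eeg_recording()] the epochs were cut from.
#' @param epochs an [epoch_and_reject()] result.
#' @param band an [strict_alpha()] band (or `c(lo, hi)` Hz) within 2-40 Hz.
#' @param channels channel subset (parietal by default).
#' @return Numeric vector of per-epoch GFP (uV^2), `NA` on flagged epochs.
#' @export
compute_gfp <- function(rec, epochs, band, channels = PARIETAL_CHANNELS) {
  band <- as.numeric(band)
  assert_that(band[1] >= 2 && band[2] <= 40 && band[1] < band[2],
              "band must lie within [2, 40] Hz")
  chans <- intersect(channels, rec$channels)
  assert_that(length(chans) == length(channels),
              "requested GFP channel missing from the recording")
  filt <- bandpass_matrix(rec$data[chans, , drop = FALSE], rec$fs, band)
  spe <- round(attr(epochs, "epoch_s") * rec$fs)
  w2 <- hann_window(spe)^2
  comp <- mean(w2)
  gfp <- rep(NA_real_, nrow(epochs))
  keep <- !(epochs$artifact | epochs$ocular)
  for (e in which(keep)) {
    j <- ((e - 1) * spe + 1):(e * spe)
    sq <- colMeans(filt[, j, drop = FALSE]^2)   # mean over channels
    gfp[e] <- mean(sq * w2) / comp
  }
  gfp
}
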