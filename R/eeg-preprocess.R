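# RBJ biquad notch (audio-EQ-cookbook form): centre frequency f0, quality Q.
# `signal` ships Butterworth designs but no notch designer, so the two
# coefficient vectors are computed here and applied with signal::filtfilt.
notch_coefficients <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Standard EEG preprocessing: mains notch and 2-40 Hz band-pass
#'
#' Applies a 50 Hz notch (2nd-order IIR, Q = 30) followed by a 4th-order
#' Butterworth band-pass (2-40 Hz by default). Both filters are run
#' forward-backward (zero phase), so event timing is preserved and the
#' effective attenuation is squared.
#'
#' @param rec an [eeg_recording()], `fs >= 100` Hz.
#' @param notch_hz mains frequency to suppress (Hz); `NULL` disables.
#' @param notch_q notch quality factor.
#' @param band two-element band-pass edges in Hz.
#' @param order band-pass filter order (poles of the one-way filter).
#' @return The filtered `eeg_recording` (same shape and annotations).
#' @export
preprocess_eeg <- function(rec, notch_hz = 50, notch_q = 30,
                           band = c(2, 40), order = 4) {
  assert_that(inherits(rec, "eeg_recording"), "`rec` must be an eeg_recording")
  assert_that(rec$fs >= 100, "sampling rate too low for preprocessing")
  assert_that(band[2] < rec$fs / 2,
              "upper band edge must be below the Nyquist frequency")
  x <- rec$data
  if (!is.null(notch_hz) && notch_hz < rec$fs / 2) {
    nc <- notch_coefficients(notch_hz, rec$fs, notch_q)
    for (i in seq_len(nrow(x)))
      x[i, ] <- signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), x[i, ])
  }
  bf <- signal::butter(order / 2, band / (rec$fs / 2), type = "pass")
  for (i in seq_len(nrow(x)))
    x[i, ] <- signal::filtfilt(bf, x[i, ])
  out <- rec
  out$data <- x
  rownames(out$data) <- rec$channels
  out
}

# Band-pass a channels x samples matrix into [lo, hi] Hz, zero phase.
bandpass_matrix <- function(x, fs, band, order = 4) {
  bf <- signal::butter(order / 2, band / (fs / 2), type = "pass")
  t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
}

#' Cut a recording into 1-s epochs and flag amplitude/ocular artifacts
#'
#' Epochs are contiguous, non-overlapping slices of `epoch_s` seconds (an
#' incomplete tail is dropped). An epoch is flagged `artifact` if any channel
#' sample exceeds `threshold_uv` in absolute value. Separately, epochs whose
#' lateral frontal channels exceed `blink_threshold_uv` are flagged `ocular`
#' (a documented stand-in for dedicated eyeblink-removal algorithms); both
#' kinds are excluded from downstream GFP.
#'
#' @param rec a (preprocessed) [eeg_recording()].
#' @param threshold_uv amplitude-rejection threshold in microvolts.
#' @param epoch_s epoch length in seconds.
#' @param blink_threshold_uv frontal blink threshold in microvolts; `NULL`
#'   disables ocular flagging.
#' @param blink_channels channels inspected for blinks.
#' @return A tibble of class `epoch_set` with columns `epoch`, `start`,
#'   `artifact`, `ocular`; attributes `epoch_s`, `fs`, `loss_fraction`
#'   (flagged / total, amplitude criterion only).
#' @export
epoch_and_reject <- function(rec, threshold_uv = 200, epoch_s = 1,
                             blink_threshold_uv = 120,
                             blink_channels = c("AF7", "AF8")) {
  spe <- round(epoch_s * rec$fs)         # samples per epoch
  n_ep <- floor(ncol(rec$data) / spe)
  assert_that(n_ep >= 1, "recording shorter than one epoch")
  idx <- matrix(seq_len(n_ep * spe), nrow = spe)
  absmax <- apply(idx, 2, function(j) max(abs(rec$data[, j])))
  artifact <- absmax > threshold_uv
  ocular <- rep(FALSE, n_ep)
  bc <- intersect(blink_channels, rec$channels)
  if (!is.null(blink_threshold_uv) && length(bc)) {
    front <- rec$data[bc, , drop = FALSE]
    fmax <- apply(idx, 2, function(j) max(abs(front[, j])))
    ocular <- !artifact & fmax > blink_threshold_uv
  }
  out <- tibble::tibble(
    epoch = seq_len(n_ep),
    start = (seq_len(n_ep) - 1) * epoch_s,
    artifact = artifact,
    ocular = ocular
  )
  attr(out, "epoch_s") <- epoch_s
  attr(out, "fs") <- rec$fs
  attr(out, "loss_fraction") <- mean(artifact)
  class(out) <- c("epoch_set", class(out))
  out
}
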