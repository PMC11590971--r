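#' Experimental protocol specification
#'
#' Ordered condition durations in seconds. Defaults reproduce the study
#' protocol: 1 min eyes closed, 1 min eyes open, 15 min demanding circuit
#' drive, 1 min eyes open, 45 min monotonous drive, 1 min eyes open. Tests
#' and demos pass scaled durations explicitly.
#'
#' @param EC,EO1,Circuit,EO2,Monotonous,EO3 durations in seconds (> 0).
#' @return A list of class `protocol_spec` with `durations` and the derived
#'   non-overlapping annotation table covering the whole session.
#' @export
protocol_spec <- function(EC = 60, EO1 = 60, Circuit = 900, EO2 = 60,
                          Monotonous = 2700, EO3 = 60) {
  durations <- c(EC = EC, EO1 = EO1, Circuit = Circuit, EO2 = EO2,
                 Monotonous = Monotonous, EO3 = EO3)
  assert_that(all(durations > 0), "all protocol durations must be positive")
  ends <- cumsum(durations)
  ann <- tibble::tibble(label = names(durations),
                        start = c(0, head(ends, -1)), end = ends)
  structure(list(durations = durations, annotations = ann,
                 total = sum(durations)),
            class = "protocol_spec")
}

#' Alpha-gain schedules (relative parietal alpha amplitude over time)
#'
#' `alpha_gain_ramp()` is the default fatigue trajectory: gain 1 until
#' `onset`, linear rise to `peak_gain` at `t_peak`, constant afterwards
#' (monotone non-decreasing, >= 1 everywhere). `alpha_gain_bump()` rises to
#' `peak_gain` at `t_peak` and falls off again (Gaussian bump of width
#' `sigma`, still >= 1); it is the scenario used when a recoverable single
#' maximum is needed, since a non-decreasing schedule has no identifiable
#' peak.
#'
#' @param onset,t_peak times in seconds from session start.
#' @param peak_gain maximal relative amplitude (>= 1).
#' @param sigma bump width (s).
#' @return A function `t -> gain`.
#' @export
alpha_gain_ramp <- function(onset, t_peak, peak_gain = 2) {
  assert_that(peak_gain >= 1 && t_peak > onset, "invalid ramp schedule")
  function(t) {
    g <- 1 + (peak_gain - 1) * pmin(1, pmax(0, (t - onset) / (t_peak - onset)))
    g
  }
}

#' @rdname alpha_gain_ramp
#' @export
alpha_gain_bump <- function(t_peak, peak_gain = 2, sigma = 120) {
  assert_that(peak_gain >= 1 && sigma > 0, "invalid bump schedule")
  function(t) 1 + (peak_gain - 1) * exp(-((t - t_peak) / sigma)^2 / 2)
}

#' Ground-truth subject profile for the synthetic generator
#'
#' Houses the quantities the analysis is later asked to recover: the true
#' individual alpha frequency, the alpha-gain trajectory, and per-AoI
#' fixation/visit parameters for the low- and high-fatigue states.
#'
#' @param subject_id identifier string.
#' @param iaf_true true alpha peak frequency, Hz, in `[8, 12]`.
#' @param vehicle_group `"van"` or `"truck"`.
#' @param alpha_gain function `t -> gain` (>= 1); default flat 1.
#' @param gaze_params per-AoI tibble with columns `aoi`, `fix_rate_low`,
#'   `fix_rate_high`, `fix_dur`, `run_len`, `visit_share_low`,
#'   `visit_share_high` (see [cohort_design()]); `NULL` for EEG-only use.
#' @param seed per-subject master seed; substreams are derived per stream.
#' @return List of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, iaf_true = 10,
                            vehicle_group = c("van", "truck"),
                            alpha_gain = NULL, gaze_params = NULL,
                            seed = 1) {
  vehicle_group <- match.arg(vehicle_group)
  assert_that(iaf_true >= 8 && iaf_true <= 12, "iaf_true must lie in [8, 12]")
  if (is.null(alpha_gain)) alpha_gain <- function(t) rep(1, length(t))
  if (!is.null(gaze_params)) {
    rates <- c(gaze_params$fix_rate_low, gaze_params$fix_rate_high)
    assert_that(all(rates > 0), "fixation rates must be strictly positive")
  }
  structure(list(subject_id = subject_id, iaf_true = iaf_true,
                 vehicle_group = vehicle_group, alpha_gain = alpha_gain,
                 gaze_params = gaze_params, seed = seed),
            class = "subject_profile")
}

# 1/f ("pink") noise via frequency-domain synthesis: amplitude ~ f^(-1/2)
# between f_lo and f_hi, random phases, scaled to the requested RMS.
# Also returns the fraction of noise power falling in [band] so callers can
# set an alpha amplitude for a target in-band SNR without re-measuring.
pink_noise <- function(n, fs, rms, f_lo = 0.5, f_hi = 40, band = NULL) {
  nf <- floor(n / 2)
  freq <- (1:nf) * fs / n
  amp <- ifelse(freq >= f_lo & freq <= f_hi, 1 / sqrt(freq), 0)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(phase[nf]))
    full[seq(n, nf + 2)] <- Conj(full[2:nf])
  } else {
    full[seq(n, nf + 1)] <- Conj(full[2:(nf + 1)])
  }
  x <- Re(fft(full, inverse = TRUE))
  x <- x / sd(x) * rms
  band_frac <- if (is.null(band)) NA_real_ else {
    sum(amp[freq >= band[1] & freq <= band[2]]^2) / sum(amp^2)
  }
  list(x = x, band_frac = band_frac)
}

#' Generate a synthetic annotated EEG session
#'
#' Signal model: each channel carries 1/f-shaped background noise; the
#' parietal channels additionally carry a common-phase sinusoid at the
#' subject's true IAF whose amplitude follows the profile's alpha-gain
#' schedule, boosted by `ec_boost` during eyes-closed rest. The alpha
#' amplitude is set so that the in-band (IAF +/- 1 Hz) signal-to-noise power
#' ratio during EC equals `snr_ec`. Frontal channels receive 300 ms half-sine
#' blink transients (which must not trip the +/-200 uV amplitude criterion);
#' randomly chosen epochs receive a high-amplitude in-band artifact burst.
#' Planted blink times and artifact epochs are recorded as ground truth.
#'
#' @param profile a [subject_profile()].
#' @param protocol a [protocol_spec()].
#' @param fs sampling frequency, Hz.
#' @param noise_rms background noise RMS per channel, uV (0 allowed for
#'   noise-free scenarios when `alpha_amp_uv` is given).
#' @param snr_ec in-band alpha SNR during eyes-closed rest.
#' @param alpha_amp_uv explicit baseline (gain 1, eyes open) alpha
#'   amplitude in uV; overrides the SNR-based calibration.
#' @param ec_boost multiplicative alpha boost while eyes are closed.
#' @param blink_rate blinks per second on frontal channels.
#' @param blink_amp_uv blink peak amplitude, uV.
#' @param artifact_frac fraction of epochs receiving a planted artifact.
#' @param artifact_amp_uv artifact burst peak amplitude, uV.
#' @return List: `rec` (an [eeg_recording()]) and `truth` (list with
#'   `artifact_epochs` (1-based epoch indices), `blink_times` (s),
#'   `iaf_true`, `alpha_amp_base`).
#' @export
generate_eeg <- function(profile, protocol, fs = 125, noise_rms = 10,
                         snr_ec = 3, alpha_amp_uv = NULL, ec_boost = 2,
                         blink_rate = 0.15, blink_amp_uv = 150,
                         artifact_frac = 0.05, artifact_amp_uv = 400) {
  assert_that(noise_rms > 0 || !is.null(alpha_amp_uv),
              "zero noise requires an explicit `alpha_amp_uv`")
  assert_that(inherits(protocol, "protocol_spec"), "need a protocol_spec")
  n <- round(protocol$total * fs)
  t <- (seq_len(n) - 1) / fs
  band <- c(profile$iaf_true - 1, profile$iaf_true + 1)
  with_seed(substream_seed(profile$seed, "eeg"), {
    data <- matrix(0, nrow = length(EEG_CHANNELS), ncol = n,
                   dimnames = list(EEG_CHANNELS, NULL))
    band_frac <- NA_real_
    if (noise_rms > 0) for (ch in EEG_CHANNELS) {
      pn <- pink_noise(n, fs, noise_rms, band = band)
      data[ch, ] <- pn$x
      band_frac <- pn$band_frac
    }
    # alpha amplitude: snr_ec = (a_ec^2/2) / (noise_rms^2 * band_frac)
    a_base <- if (!is.null(alpha_amp_uv)) alpha_amp_uv else {
      sqrt(2 * snr_ec * band_frac) * noise_rms / ec_boost
    }
    ec <- protocol$annotations[protocol$annotations$label == "EC", ]
    in_ec <- t >= ec$start & t < ec$end
    gain <- profile$alpha_gain(t)
    amp <- a_base * gain * ifelse(in_ec, ec_boost, 1)
    alpha <- amp * sin(2 * pi * profile$iaf_true * t)
    for (ch in PARIETAL_CHANNELS) data[ch, ] <- data[ch, ] + alpha

    # blinks: half-sine transients on the lateral frontal channels
    n_blink <- rbinom(1, round(protocol$total * blink_rate * 2), 0.5)
    blink_times <- sort(runif(n_blink, 0, protocol$total - 0.3))
    # enforce a refractory gap so two transients never superpose above the
    # amplitude-rejection threshold
    if (length(blink_times) > 1) {
      keep <- blink_times[1]
      for (bt in blink_times[-1])
        if (bt - keep[length(keep)] > 0.4) keep <- c(keep, bt)
      blink_times <- keep
    }
    blen <- round(0.3 * fs)
    bshape <- blink_amp_uv * sin(pi * (seq_len(blen) - 1) / (blen - 1))
    for (bt in blink_times) {
      j <- round(bt * fs) + seq_len(blen)
      j <- j[j <= n]
      for (ch in c("AF7", "AF8"))
        data[ch, j] <- data[ch, j] + bshape[seq_along(j)]
    }

    # planted high-amplitude artifact epochs (in-band Hann-tapered burst so
    # the 2-40 Hz zero-phase filtering leaves the exceedance intact)
    n_ep <- floor(protocol$total)
    n_art <- round(artifact_frac * n_ep)
    art_epochs <- sort(sample(n_ep, n_art))
    spe <- fs
    burst <- artifact_amp_uv * sin(2 * pi * 8 * (seq_len(spe) - 1) / fs) *
      hann_window(spe)
    for (e in art_epochs) {
      j <- ((e - 1) * spe + 1):(e * spe)
      data[, j] <- sweep(data[, j, drop = FALSE], 2, burst, `+`)
    }
  })
  rec <- eeg_recording(data, EEG_CHANNELS, fs, protocol$annotations)
  list(rec = rec,
       truth = list(artifact_epochs = art_epochs, blink_times = blink_times,
                    iaf_true = profile$iaf_true, alpha_amp_base = a_base))
}
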