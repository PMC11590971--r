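test_that("preprocessing suppresses mains, passes alpha, removes DC", {
  fs <- 125; t <- (0:(20 * fs - 1)) / fs
  mk <- function(x) eeg_recording(matrix(rep(x, each = 8), nrow = 8,
                                         byrow = FALSE), EEG_CHANNELS, fs)
  mains <- preprocess_eeg(mk(sin(2 * pi * 50 * t)))
  mid <- (5 * fs):(15 * fs)
  expect_lt(sqrt(mean(mains$data["Pz", mid]^2)), 0.01 * sqrt(0.5))
  alpha <- preprocess_eeg(mk(sin(2 * pi * 10 * t)))
  expect_equal(sqrt(mean(alpha$data["Pz", mid]^2)), sqrt(0.5),
               tolerance = 0.05)
  dc <- preprocess_eeg(mk(rep(100, length(t))))
  expect_lt(abs(mean(dc$data["Pz", mid])), 1)
})

test_that("too-low sampling rates are rejected", {
  rec <- eeg_recording(matrix(0, 8, 500), EEG_CHANNELS, fs = 50)
  expect_error(preprocess_eeg(rec), "sampling rate|Nyquist")
})

test_that("amplitude rejection flags exactly the offending epochs", {
  fs <- 125
  m <- matrix(0, 8, 60 * fs, dimnames = list(EEG_CHANNELS, NULL))
  m["P3", 6 * fs + 17] <- 250        # one spike inside epoch 7
  rec <- eeg_recording(m, EEG_CHANNELS, fs)
  ep <- epoch_and_reject(rec)
  expect_equal(which(ep$artifact), 7L)
  expect_equal(attr(ep, "loss_fraction"), 1 / 60)
  ep0 <- epoch_and_reject(eeg_recording(matrix(0, 8, 60 * fs),
                                        EEG_CHANNELS, fs))
  expect_equal(sum(ep0$artifact), 0L)
})

test_that("frontal blink exceedances are flagged ocular, not artifact", {
  fs <- 125
  m <- matrix(0, 8, 30 * fs, dimnames = list(EEG_CHANNELS, NULL))
  m["AF7", 3 * fs + 10] <- 150       # above blink threshold, below 200
  rec <- eeg_recording(m, EEG_CHANNELS, fs)
  ep <- epoch_and_reject(rec)
  expect_equal(which(ep$ocular), 4L)
  expect_equal(sum(ep$artifact), 0L)
})

test_that("IAF estimation is exact on a pure parietal sine", {
  ann <- tibble::tibble(label = "EC", start = 0, end = 60)
  rec <- sine_recording(freq = 10, dur = 60, annotations = ann)
  est <- estimate_iaf(rec)
  expect_equal(est$iaf, 10, tolerance = 1e-3)
  expect_false(est$fallback)
})

test_that("alpha confined to frontal channels triggers the 10 Hz fallback", {
  ann <- tibble::tibble(label = "EC", start = 0, end = 60)
  prof <- subject_profile("s", iaf_true = 11, seed = 2)
  p <- protocol_spec(EC = 60, EO1 = 30, Circuit = 30, EO2 = 30,
                     Monotonous = 30, EO3 = 30)
  g <- generate_eeg(prof, p, blink_rate = 0, artifact_frac = 0)
  rec <- g$rec
  # move all alpha off the parietal sites: keep only noise there
  noise_only <- generate_eeg(prof, p, blink_rate = 0, artifact_frac = 0,
                             alpha_amp_uv = 0)
  rec$data[PARIETAL_CHANNELS, ] <- noise_only$rec$data[PARIETAL_CHANNELS, ]
  expect_warning(est <- estimate_iaf(rec), "fall")
  expect_equal(est$iaf, 10)
  expect_true(est$fallback)
})

test_that("IAF recovery from realistic eyes-closed segments stays in band", {
  p <- protocol_spec(EC = 60, EO1 = 30, Circuit = 30, EO2 = 30,
                     Monotonous = 30, EO3 = 30)
  errs <- vapply(1:10, function(s) {
    iaf_true <- with_seed(s, runif(1, 8.5, 11.5))
    prof <- subject_profile("s", iaf_true = iaf_true, seed = s)
    g <- generate_eeg(prof, p)
    pre <- preprocess_eeg(g$rec)
    ep <- epoch_and_reject(pre)
    estimate_iaf(pre, epochs = ep)$iaf - iaf_true
  }, numeric(1))
  expect_true(all(abs(errs) <= 0.5))
})

test_that("the strict alpha band is (IAF - 1, IAF + 1)", {
  expect_equal(unclass(strict_alpha(10)), c(lo = 9, hi = 11))
  expect_equal(unclass(strict_alpha(9.5)), c(lo = 8.5, hi = 10.5))
  b <- strict_alpha(12)
  expect_equal(b[["hi"]] - b[["lo"]], 2)
})

test_that("GFP of a unit in-band sine is 1/2 after taper compensation", {
  rec <- sine_recording(freq = 10, dur = 10)
  ep <- epoch_and_reject(rec, blink_threshold_uv = NULL)
  gfp <- compute_gfp(rec, ep, c(9, 11))
  expect_equal(gfp[5], 0.5, tolerance = 0.02)
  # energy is quadratic in amplitude
  rec2 <- sine_recording(freq = 10, amp = 2, dur = 10)
  gfp2 <- compute_gfp(rec2, epoch_and_reject(rec2, blink_threshold_uv = NULL),
                      c(9, 11))
  expect_equal(gfp2[5] / gfp[5], 4, tolerance = 0.01)
  # all-zero epochs give exactly zero
  z <- eeg_recording(matrix(0, 8, 10 * 125), EEG_CHANNELS, 125)
  expect_equal(compute_gfp(z, epoch_and_reject(z, blink_threshold_uv = NULL),
                           c(9, 11))[3], 0)
})

test_that("GFP is channel-order invariant and NA on flagged epochs", {
  rec <- sine_recording(freq = 10, dur = 10)
  rec$data["P3", 3 * 125 + 5] <- 500
  ep <- epoch_and_reject(rec, blink_threshold_uv = NULL)
  gfp <- compute_gfp(rec, ep, c(9, 11))
  expect_true(is.na(gfp[4]))
  expect_false(anyNA(gfp[-4]))
  perm <- rev(EEG_CHANNELS)
  rec_p <- eeg_recording(rec$data[perm, ], perm, 125)
  gfp_p <- compute_gfp(rec_p, ep, c(9, 11))
  expect_equal(gfp, gfp_p)
  expect_error(compute_gfp(rec, ep, c(9, 11), channels = c("Pz", "XX")),
               "missing")
})

test_that("time-domain GFP agrees with a periodogram-bin oracle", {
  # 10 s toy recording: band energy via frequency-domain bin sums
  # alpha-dominated recording: the periodogram-bin oracle assumes a
  # brick-wall band, so the comparison is meaningful when in-band energy
  # is concentrated at the (bin-aligned) alpha line
  prof <- subject_profile("s", iaf_true = 10, seed = 4)
  p <- protocol_spec(EC = 10, EO1 = 10, Circuit = 10, EO2 = 10,
                     Monotonous = 10, EO3 = 10)
  g <- generate_eeg(prof, p, noise_rms = 1, alpha_amp_uv = 5,
                    blink_rate = 0, artifact_frac = 0)
  rec <- g$rec
  ep <- epoch_and_reject(rec, blink_threshold_uv = NULL)
  band <- c(9, 11)
  gfp <- compute_gfp(rec, ep, band)
  # oracle: mean over channels of periodogram power summed inside the band,
  # per 1 s epoch (rectangular-window Parseval energy)
  fs <- 125
  oracle <- vapply(seq_len(nrow(ep)), function(e) {
    j <- ((e - 1) * fs + 1):(e * fs)
    mean(vapply(PARIETAL_CHANNELS, function(ch) {
      sp <- abs(fft(rec$data[ch, j]))^2 / fs^2
      f <- (seq_along(j) - 1) * fs / length(j)
      sel <- (f >= band[1] & f <= band[2]) |
        (f >= fs - band[2] & f <= fs - band[1])
      sum(sp[sel])
    }, numeric(1)))
  }, numeric(1))
  mid <- 3:55
  expect_equal(mean(gfp[mid]), mean(oracle[mid]), tolerance = 0.05)
})

test_that("MDrow standardizes against the baseline and smooths", {
  ep <- tibble::tibble(epoch = 1:40, start = 0:39,
                       artifact = rep(FALSE, 40), ocular = rep(FALSE, 40))
  attr(ep, "epoch_s") <- 1
  ann <- tibble::tibble(label = c("EO1", "Monotonous"),
                        start = c(0, 20), end = c(20, 40))
  base <- rep(c(0.5, 1.5), 10)            # mean 1, sd ~0.513
  gfp <- c(base, rep(2, 20))
  md <- compute_mdrow(gfp, ep, ann, smoothing_epochs = 1)
  expect_equal(md$mdrow[21], (2 - 1) / sd(base))
  # task GFP constant at the baseline mean gives identically zero
  md0 <- compute_mdrow(c(base, rep(1, 20)), ep, ann, smoothing_epochs = 1)
  expect_equal(md0$mdrow[21:40], rep(0, 20))
  # smoothing is a centered moving average over clean epochs
  md10 <- compute_mdrow(gfp, ep, ann, smoothing_epochs = 10)
  expect_equal(md10$mdrow_smooth[30], mean(md10$mdrow[26:35]))
})

test_that("zero baseline variance is an error", {
  ep <- tibble::tibble(epoch = 1:20, start = 0:19,
                       artifact = FALSE, ocular = FALSE)
  attr(ep, "epoch_s") <- 1
  ann <- tibble::tibble(label = "EO1", start = 0, end = 20)
  expect_error(compute_mdrow(rep(1, 20), ep, ann), "variance")
})

test_that("MDrow is invariant under uniform affine channel rescaling", {
  ep <- tibble::tibble(epoch = 1:30, start = 0:29,
                       artifact = rep(c(FALSE, FALSE, TRUE), 10),
                       ocular = FALSE)
  attr(ep, "epoch_s") <- 1
  ann <- tibble::tibble(label = "EO1", start = 0, end = 15)
  gfp <- with_seed(1, runif(30, 0.5, 2))
  gfp[ep$artifact] <- NA
  md1 <- compute_mdrow(gfp, ep, ann)
  md2 <- compute_mdrow(gfp * 7.3, ep, ann)   # amplitude x sqrt(7.3) uniform
  expect_equal(md1$mdrow, md2$mdrow)
  expect_equal(md1$mdrow_smooth, md2$mdrow_smooth)
  expect_true(all(is.na(md1$mdrow_smooth[ep$artifact])))
})

test_that("resting-state means follow the planted alpha gains", {
  p <- protocol_spec(EC = 60, EO1 = 60, Circuit = 60, EO2 = 60,
                     Monotonous = 120, EO3 = 60)
  # gain 1 during EO1, raised from the circuit onwards (ramp reaches its
  # plateau before EO2 and stays: EO2 ~ EO3 > EO1)
  gain <- alpha_gain_ramp(onset = 120, t_peak = 170, peak_gain = 1.6)
  up <- vapply(1:5, function(s) {
    prof <- subject_profile("s", iaf_true = 10, alpha_gain = gain, seed = s)
    g <- generate_eeg(prof, p)
    pre <- preprocess_eeg(g$rec)
    ep <- epoch_and_reject(pre)
    gfp <- compute_gfp(pre, ep, strict_alpha(estimate_iaf(pre, epochs = ep)))
    md <- compute_mdrow(gfp, ep, g$rec$annotations)
    r <- resting_state_mdrow(md, g$rec$annotations)
    (r[["EO2"]] > r[["EO1"]]) && (r[["EO3"]] > r[["EO1"]])
  }, logical(1))
  expect_gte(mean(up), 0.8)
})

test_that("a missing eyes-open annotation is an error", {
  md <- tibble::tibble(t = 0:9, gfp_alpha = 1, mdrow = 0,
                       mdrow_smooth = 0, artifact = FALSE)
  ann <- tibble::tibble(label = c("EO1", "EO2"), start = c(0, 5),
                        end = c(5, 10))
  expect_error(resting_state_mdrow(md, ann), "EO3")
})

test_that("EEG long-CSV round-trips with annotations", {
  ann <- tibble::tibble(label = c("EC", "EO1"), start = c(0, 2),
                        end = c(2, 4))
  rec <- sine_recording(freq = 9, dur = 4, annotations = ann)
  path <- tempfile(fileext = ".csv")
  write_eeg_csv(rec, path)
  back <- read_eeg_csv(path)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_equal(back$fs, 125)
  expect_equal(tibble::as_tibble(back$annotations)$label, ann$label)
  unlink(c(path, paste0(path, ".annotations.json")))
})
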