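# Independent oracles used across the suite. Each re-derives the expected
# quantity from first principles (naive loops, direct formulas), never by
# calling the implementation under test.

# Naive I-VT segmentation: per-sample speed labels (min of adjacent
# interval speeds), explicit run construction, merge and minimum-duration
# passes written as plain loops.
oracle_ivt <- function(gaze, vel_threshold = 1.5, min_fix_s = 0.06,
                       merge_gap_s = 0.075, merge_dist = 0.02,
                       max_interval_s = 0.1) {
  idx <- which(gaze$validity)
  if (length(idx) < 2) return(data.frame())
  t <- gaze$t[idx]; x <- gaze$x[idx]; y <- gaze$y[idx]
  m <- length(idx)
  speed_between <- function(i, j) {
    if (idx[j] - idx[i] != 1) return(Inf)           # validity gap
    if (t[j] - t[i] > max_interval_s) return(Inf)   # recording gap
    sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2) / (t[j] - t[i])
  }
  slow <- logical(m)
  for (i in seq_len(m)) {
    vb <- if (i > 1) speed_between(i - 1, i) else Inf
    vf <- if (i < m) speed_between(i, i + 1) else Inf
    slow[i] <- min(vb, vf) <= vel_threshold
  }
  # runs of slow samples, broken at non-adjacent original indices or gaps
  groups <- list(); cur <- c()
  for (i in seq_len(m)) {
    if (slow[i]) {
      if (length(cur) && (idx[i] - idx[cur[length(cur)]] != 1 ||
                          t[i] - t[cur[length(cur)]] > max_interval_s)) {
        groups[[length(groups) + 1]] <- cur
        cur <- c()
      }
      cur <- c(cur, i)
    } else if (length(cur)) {
      groups[[length(groups) + 1]] <- cur
      cur <- c()
    }
  }
  if (length(cur)) groups[[length(groups) + 1]] <- cur
  ev <- lapply(groups, function(g)
    data.frame(start = t[g[1]], end = t[g[length(g)]],
               x = mean(x[g]), y = mean(y[g]), n = length(g)))
  ev <- do.call(rbind, ev)
  if (is.null(ev)) return(data.frame())
  # merge pass
  out <- ev[1, ]
  if (nrow(ev) > 1) for (k in 2:nrow(ev)) {
    gap <- ev$start[k] - out$end[nrow(out)]
    dd <- sqrt((ev$x[k] - out$x[nrow(out)])^2 +
                 (ev$y[k] - out$y[nrow(out)])^2)
    if (gap < merge_gap_s && dd <= merge_dist) {
      i <- nrow(out)
      w <- out$n[i] + ev$n[k]
      out$x[i] <- (out$x[i] * out$n[i] + ev$x[k] * ev$n[k]) / w
      out$y[i] <- (out$y[i] * out$n[i] + ev$y[k] * ev$n[k]) / w
      out$end[i] <- ev$end[k]
      out$n[i] <- w
    } else out <- rbind(out, ev[k, ])
  }
  out$duration <- out$end - out$start
  out[out$duration >= min_fix_s, , drop = FALSE]
}

# Friedman chi-square and Conover T statistics from raw rank arithmetic.
oracle_friedman_conover <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  R <- colSums(ranks)
  # tie-corrected Friedman statistic
  A <- sum(ranks^2)
  C <- n * k * (k + 1)^2 / 4
  chi2 <- (k - 1) * sum((R - n * (k + 1) / 2)^2) / (A - C)
  B <- sum(R^2) / n
  se <- sqrt(2 * n * (A - B) / ((n - 1) * (k - 1)))
  pairs <- utils::combn(k, 2)
  T <- (R[pairs[1, ]] - R[pairs[2, ]]) / se
  list(chi2 = chi2, T = unname(T), df2 = (n - 1) * (k - 1))
}

# Holm step-down by literal enumeration of the rule.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run_max <- 0
  for (i in seq_len(m)) {
    run_max <- max(run_max, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run_max)
  }
  adj
}

# Mixed-design (split-plot) ANOVA by explicit cell-mean sums of squares;
# supports unbalanced between-group sizes.
oracle_mixed_anova <- function(subject, group, cond, value) {
  d <- data.frame(s = factor(subject), g = factor(group),
                  w = factor(cond), y = value)
  k <- nlevels(d$w)
  subj <- unique(d[, c("s", "g")])
  n <- nrow(subj)
  grand <- mean(d$y)
  subj_mean <- tapply(d$y, d$s, mean)
  grp_of <- setNames(subj$g, subj$s)
  grp_mean <- tapply(d$y, d$g, mean)
  n_g <- table(subj$g)
  ss_between_subj <- k * sum((subj_mean - grand)^2)
  ss_group <- k * sum(n_g * (grp_mean[names(n_g)] - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_w <- n * sum((tapply(d$y, d$w, mean) - grand)^2)
  cell <- tapply(d$y, list(d$g, d$w), mean)
  ss_cells <- sum(outer(as.vector(n_g), rep(1, k)) * (cell - grand)^2)
  ss_int <- ss_cells - ss_group - ss_w
  ss_tot <- sum((d$y - grand)^2)
  ss_resid <- ss_tot - ss_between_subj - ss_w - ss_int
  df_g <- nlevels(d$g) - 1
  df_sw <- n - nlevels(d$g)
  df_w <- k - 1
  df_int <- df_g * df_w
  df_res <- df_sw * df_w
  list(
    F_group = (ss_group / df_g) / (ss_subj_within / df_sw),
    F_within = (ss_w / df_w) / (ss_resid / df_res),
    F_inter = (ss_int / df_int) / (ss_resid / df_res),
    df = c(df_g, df_sw, df_w, df_int, df_res)
  )
}

# Small sine-wave recording on chosen channels.
sine_recording <- function(freq = 10, amp = 1, dur = 10, fs = 125,
                           channels = PARIETAL_CHANNELS,
                           annotations = NULL) {
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  m <- matrix(0, length(EEG_CHANNELS), n,
              dimnames = list(EEG_CHANNELS, NULL))
  for (ch in channels) m[ch, ] <- amp * sin(2 * pi * freq * t)
  eeg_recording(m, EEG_CHANNELS, fs, annotations)
}

# Scaled protocol used throughout the tests (the vignette records these
# reduced durations as the suite's problem sizes).
test_protocol <- function(mono = 500) {
  protocol_spec(EC = 60, EO1 = 40, Circuit = 60, EO2 = 30,
                Monotonous = mono, EO3 = 30)
}

test_design <- function(n = 4, mono = 500, ...) {
  cohort_design(n = n, protocol = test_protocol(mono), ...)
}
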