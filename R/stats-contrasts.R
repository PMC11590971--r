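#' Score fatigue questionnaires
#'
#' The sleepiness item is a single 1 (extremely alert) to 9 (extremely
#' sleepy, fighting sleep) rating and passes through unchanged; the mental
#' fatigue score is the sum of the six mental-subscale items (original
#' items 9-14), each rated 0 (none) to 3 (very high), so it ranges 0-18.
#'
#' @param kss integer vector, each in 1-9.
#' @param chalder_mental integer matrix / data frame with six columns (one
#'   row per respondent), items in 0-3; or a length-6 vector.
#' @return Tibble `kss_score, chalder_score`.
#' @export
score_questionnaires <- function(kss, chalder_mental) {
  if (is.null(dim(chalder_mental)))
    chalder_mental <- matrix(chalder_mental, nrow = 1)
  chalder_mental <- as.matrix(chalder_mental)
  assert_that(ncol(chalder_mental) == 6, "need six mental-subscale items")
  assert_that(all(kss == round(kss) & kss >= 1 & kss <= 9),
              "KSS ratings must be integers in 1-9")
  assert_that(all(chalder_mental == round(chalder_mental) &
                    chalder_mental >= 0 & chalder_mental <= 3),
              "mental-subscale items must be integers in 0-3")
  assert_that(length(kss) == nrow(chalder_mental),
              "one KSS rating per respondent row")
  tibble::tibble(kss_score = as.integer(kss),
                 chalder_score = as.integer(rowSums(chalder_mental)))
}

#' Shapiro-Wilk normality gate for paired contrasts
#'
#' Tests the per-subject paired differences for normality; the paired t
#' test is used when normality is not rejected (`p >= alpha`), otherwise
#' the Wilcoxon signed-rank test. A constant difference vector is
#' degenerate and routes to the rank test with a warning.
#'
#' @param differences per-subject paired differences (n >= 3).
#' @param alpha gate level.
#' @return List: `test_used` (`"paired_t"` or `"wilcoxon"`), `W`, `p`.
#' @export
normality_gate <- function(differences, alpha = 0.05) {
  assert_that(length(differences) >= 3, "need at least 3 paired differences")
  if (sd(differences) == 0) {
    warning("constant differences: normality undefined, using rank test")
    return(list(test_used = "wilcoxon", W = NA_real_, p = NA_real_))
  }
  sw <- shapiro.test(differences)
  list(test_used = if (sw$p.value >= alpha) "paired_t" else "wilcoxon",
       W = unname(sw$statistic), p = sw$p.value)
}

#' Cohen's d for a paired contrast from its t statistic
#'
#' For a paired t test, `d = t / sqrt(n)` - identical to the mean paired
#' difference divided by the standard deviation of the differences.
#'
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' Paired contrast between low- and high-fatigue measurements
#'
#' Computes the paired difference `low - high` per subject, gates it
#' through [normality_gate()], and runs the paired t test (reporting
#' Cohen's d = t/sqrt(n)) or the Wilcoxon signed-rank test. Identical
#' vectors yield t = 0, d = 0 with a warning.
#'
#' @param low,high equal-length per-subject values (n >= 3).
#' @param alpha normality-gate level.
#' @param force_test `NULL` (gate decides), `"paired_t"`, or `"wilcoxon"`.
#' @return One-row tibble: `n, test_used, statistic, df, p, d,
#'   mean_low, mean_high, sd_low, sd_high, shapiro_p`.
#' @export
paired_contrast <- function(low, high, alpha = 0.05, force_test = NULL) {
  assert_that(length(low) == length(high), "low/high length mismatch")
  n <- length(low)
  assert_that(n >= 3, "need at least 3 pairs")
  diffs <- low - high
  gate <- if (is.null(force_test)) {
    if (sd(diffs) == 0) list(test_used = "degenerate", W = NA, p = NA)
    else normality_gate(diffs, alpha)
  } else list(test_used = force_test, W = NA_real_, p = NA_real_)
  base <- tibble::tibble(
    n = n, mean_low = mean(low), mean_high = mean(high),
    sd_low = sd(low), sd_high = sd(high),
    shapiro_p = gate$p %||% NA_real_
  )
  if (gate$test_used == "degenerate") {
    warning("identical paired vectors; reporting t = 0, d = 0")
    return(tibble::tibble(base, test_used = "paired_t",
                          statistic = 0, df = n - 1, p = 1, d = 0)[
                            , c("n", "test_used", "statistic", "df", "p",
                                "d", names(base)[-1])])
  }
  if (gate$test_used == "paired_t") {
    tt <- t.test(low, high, paired = TRUE)
    res <- tibble::tibble(test_used = "paired_t",
                          statistic = unname(tt$statistic),
                          df = unname(tt$parameter), p = tt$p.value,
                          d = cohens_d_from_t(unname(tt$statistic), n))
  } else {
    wt <- suppressWarnings(wilcox.test(low, high, paired = TRUE,
                                       exact = FALSE))
    res <- tibble::tibble(test_used = "wilcoxon",
                          statistic = unname(wt$statistic),
                          df = NA_real_, p = wt$p.value,
                          d = mean(diffs) / sd(diffs))
  }
  tibble::tibble(n = n, res, base[, -1])
}
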