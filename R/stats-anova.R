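#' Mixed two-way ANOVA (within x between)
#'
#' Split-plot ANOVA with one repeated-measures factor (e.g. FATIGUE with
#' levels low/high, or RESTING STATE with the three eyes-open rests) and
#' one between-subjects factor (e.g. VEHICLE: van vs truck; group sizes
#' may differ). Sums of squares follow the standard mixed-design
#' partitioning: the between effect is tested against the subject-within-
#' group stratum, the within effect and the interaction against the
#' subject x within residual stratum (`stats::aov` with
#' `Error(subject/within)`).
#'
#' @param data data frame with columns `subject`, `value`, the within
#'   column and the between column.
#' @param within name of the within-subject factor column.
#' @param between name of the between-subject factor column.
#' @return Tibble: `effect, df1, df2, F, p` for the between and within
#'   main effects and their interaction.
#' @export
mixed_anova <- function(data, within = "condition", between = "vehicle") {
  d <- data.frame(
    subject = factor(data$subject),
    w = factor(data[[within]]),
    b = factor(data[[between]]),
    value = data$value
  )
  assert_that(!anyNA(d$value), "missing values are not allowed")
  tab <- table(d$subject, d$w)
  if (any(tab != 1))
    stop("each subject needs exactly one value per within level",
         call. = FALSE)
  fit <- aov(value ~ b * w + Error(subject / w), data = d)
  s <- summary(fit)
  btw <- as.data.frame(s[["Error: subject"]][[1]])
  wth <- as.data.frame(s[["Error: subject:w"]][[1]])
  row_of <- function(df, key) df[trimws(rownames(df)) == key, , drop = FALSE]
  b_row <- row_of(btw, "b")
  b_res <- row_of(btw, "Residuals")
  w_row <- row_of(wth, "w")
  i_row <- row_of(wth, "b:w")
  w_res <- row_of(wth, "Residuals")
  tibble::tibble(
    effect = c(between, within, paste0(within, ":", between)),
    df1 = c(b_row$Df, w_row$Df, i_row$Df),
    df2 = c(b_res$Df, w_res$Df, w_res$Df),
    F = c(b_row$`F value`, w_row$`F value`, i_row$`F value`),
    p = c(b_row$`Pr(>F)`, w_row$`Pr(>F)`, i_row$`Pr(>F)`)
  )
}
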