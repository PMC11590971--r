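#' Holm step-down multiple-comparison adjustment
#'
#' Classic Bonferroni-Holm: sort ascending, multiply the i-th smallest p by
#' (m - i + 1), enforce monotonicity, clip at 1, return in input order.
#' Thin, validated wrapper over `stats::p.adjust(method = "holm")`.
#'
#' @param pvals p values in `[0, 1]`.
#' @return Adjusted p values in input order.
#' @export
holm_adjust <- function(pvals) {
  assert_that(all(is.finite(pvals) & pvals >= 0 & pvals <= 1),
              "p values must lie in [0, 1]")
  p.adjust(pvals, method = "holm")
}

#' Friedman test with Conover post hoc comparisons
#'
#' Friedman chi-square (average-rank tie handling, via
#' `stats::friedman.test`) over a subjects x conditions matrix; if there
#' are at least two conditions, all pairwise Conover post hoc comparisons
#' are computed on the within-subject rank sums with the classic
#' pooled-variance form,
#' `T = (R_j - R_k) / sqrt(2 n (A - B) / ((n-1)(k-1)))` with
#' `A = sum of all squared ranks`, `B = sum_j R_j^2 / n`, on
#' `df = (n-1)(k-1)`, Holm-adjusted.
#'
#' @param mat numeric matrix / data frame, rows = subjects, columns =
#'   conditions (>= 2 subjects, >= 3 conditions, no missing cells).
#' @return List of class `friedman_conover`: `chi2`, `df`, `p`,
#'   `posthoc` (tibble `pair, T, df, p, p_holm`), `rank_sums`.
#' @export
friedman_conover <- function(mat) {
  mat <- as.matrix(mat)
  assert_that(!anyNA(mat), "missing cells are not allowed (no imputation)")
  n <- nrow(mat); k <- ncol(mat)
  assert_that(n >= 2 && k >= 3, "need >= 2 subjects and >= 3 conditions")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("C", seq_len(k))
  ranks <- t(apply(mat, 1, rank))
  if (all(apply(mat, 1, function(r) length(unique(r))) == 1)) {
    # every subject ranks the conditions identically flat: no evidence of
    # any difference (the tie-corrected statistic is 0/0 here)
    ft <- list(statistic = c(chi2 = 0), parameter = c(df = k - 1),
               p.value = 1)
  } else {
    ft <- friedman.test(mat)
  }
  R <- colSums(ranks)
  A <- sum(ranks^2)
  B <- sum(R^2) / n
  se <- sqrt(pmax(2 * n * (A - B) / ((n - 1) * (k - 1)), 0))
  df2 <- (n - 1) * (k - 1)
  pairs <- utils::combn(k, 2)
  if (se == 0) {                                  # all cells equal
    T_stat <- rep(0, ncol(pairs))
    p_raw <- rep(1, ncol(pairs))
  } else {
    T_stat <- (R[pairs[1, ]] - R[pairs[2, ]]) / se
    p_raw <- 2 * pt(-abs(T_stat), df2)
  }
  posthoc <- tibble::tibble(
    pair = paste(colnames(mat)[pairs[1, ]], "vs", colnames(mat)[pairs[2, ]]),
    T = unname(T_stat), df = df2, p = unname(p_raw),
    p_holm = holm_adjust(unname(p_raw))
  )
  structure(list(chi2 = unname(ft$statistic), df = unname(ft$parameter),
                 p = ft$p.value, posthoc = posthoc, rank_sums = R),
            class = "friedman_conover")
}

#' @export
print.friedman_conover <- function(x, ...) {
  cat(sprintf("<friedman_conover> chi2 = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  print(x$posthoc)
  invisible(x)
}

#' Per-group Friedman analyses with pattern agreement
#'
#' Rank tests with a grouping factor are not recommended, so group
#' differences are probed indirectly: one Friedman (+ Conover/Holm)
#' analysis per group, and the groups are called concordant when the same
#' comparisons are significant in each.
#'
#' @param mat subjects x conditions matrix.
#' @param groups group label per subject (e.g. vehicle type).
#' @param alpha significance level for the agreement check.
#' @return List: `per_group` (named list of [friedman_conover()] results),
#'   `agreement` (logical: identical significance pattern).
#' @export
friedman_by_group <- function(mat, groups, alpha = 0.05) {
  mat <- as.matrix(mat)
  assert_that(nrow(mat) == length(groups), "one group label per subject")
  per_group <- lapply(split(seq_len(nrow(mat)), groups),
                      function(i) friedman_conover(mat[i, , drop = FALSE]))
  sig <- lapply(per_group, function(r) r$posthoc$p_holm < alpha)
  agreement <- all(vapply(sig[-1], identical, logical(1), sig[[1]]))
  list(per_group = per_group, agreement = agreement)
}
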