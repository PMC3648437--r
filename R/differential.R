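# Case/control differential reactivity: exact M-statistic and its
# permutation tail probability, Cantelli/Chebyshev bounds, fold change,
# t / two-group ANOVA tests, the significance filter, and the pre/post
# comparison.

#' Significance and prioritization thresholds
#'
#' Bundles the analysis cutoffs: raw p-value cutoff, linear fold-change
#' cutoff (strict `>`), reactivity Z-score cutoff, and the two
#' differential-expression-ratio (DER) cutoffs of the candidate cascade.
#'
#' @param p_cut Significance level for raw p-values (inclusive `<=`).
#' @param fc_cut Fold-change cutoff (strict `>`).
#' @param z_cut Reactivity Z-score cutoff.
#' @param der1,der2 DER cutoffs for the locus and variant stages of the
#'   prioritization cascade.
#' @return A list of class `thresholds`.
#' @export
thresholds <- function(p_cut = 0.05, fc_cut = 2.0, z_cut = 3.0,
                       der1 = 0.45, der2 = 0.6) {
  stopifnot(p_cut > 0, p_cut <= 1, fc_cut > 0, z_cut > 0,
            der1 > 0, der2 > 0)
  structure(list(p_cut = p_cut, fc_cut = fc_cut, z_cut = z_cut,
                 der1 = der1, der2 = der2),
            class = "thresholds")
}

#' The M-statistic: cases exceeding the control maximum
#'
#' For one feature, `m` is the number of case values strictly greater than
#' the maximum of the control values. Ties with the control maximum never
#' count. Under exchangeability of the two groups its exact null tail
#' probability has the closed form implemented in [m_pvalue()].
#'
#' @param case_values,control_values Numeric vectors, both non-empty.
#' @return Integer count in `0..length(case_values)`.
#' @export
#' @examples
#' m_statistic(c(9, 8, 2), c(7, 1, 0))  # 2
m_statistic <- function(case_values, control_values) {
  if (!length(case_values) || !length(control_values)) {
    stop("validation error: both groups must be non-empty")
  }
  if (anyNA(case_values) || anyNA(control_values)) {
    stop("validation error: missing values in M-statistic input")
  }
  sum(case_values > max(control_values))
}

#' Exact null tail probability of the M-statistic
#'
#' Probability, under exchangeability of group labels, that at least `m`
#' case values exceed every control value:
#' `P(M >= m) = choose(n_case, m) / choose(n_case + n_control, m)`.
#' The event `M >= m` is exactly the event that the top `m` order
#' statistics of the pooled sample all carry case labels, which happens
#' for `choose(N - m, n_case - m)` of the `choose(N, n_case)` equally
#' likely label assignments; the ratio simplifies to the closed form
#' above. Both binomial coefficients are exact integers well within
#' double precision for group sizes used here, so the ratio is an exact
#' integer ratio converted to float once.
#'
#' @param m Observed M-statistic (scalar or vector).
#' @param n_case,n_control Group sizes.
#' @return Tail probability in (0, 1]; `m = 0` gives 1.
#' @export
#' @examples
#' m_pvalue(10, 10, 10)  # 1/184756 ~ 5.41e-6
#' m_pvalue(4, 5, 5)     # 5/210 ~ 0.024
m_pvalue <- function(m, n_case, n_control) {
  stopifnot(n_case >= 1, n_control >= 1)
  if (any(m < 0 | m > n_case)) {
    stop("domain error: m must lie in 0..n_case")
  }
  p <- choose(n_case, m) / choose(n_case + n_control, m)
  p[m == 0] <- 1.0
  p
}

#' Distribution-free tail bound for a standardized deviation
#'
#' One-sided (Cantelli) bound `1/(1 + z^2)` for `z > 0`, else 1; two-sided
#' (Chebyshev) bound `min(1, 1/z^2)`. These are upper bounds on the tail
#' probability valid for any distribution with finite variance, and are
#' reported alongside the exact M-statistic probability as a
#' model-agnostic significance display.
#'
#' @param z Standardized deviation(s); must be finite.
#' @param two_sided Use the two-sided Chebyshev form.
#' @return Probability bound(s) in (0, 1].
#' @export
cantelli_pvalue <- function(z, two_sided = FALSE) {
  if (any(!is.finite(z))) stop("validation error: z must be finite")
  if (two_sided) {
    ifelse(z == 0, 1, pmin(1, 1 / z^2))
  } else {
    ifelse(z > 0, 1 / (1 + z^2), 1)
  }
}

#' Linear-scale fold change of group means
#'
#' @param case_values,control_values Numeric vectors of linear-scale
#'   normalized signal; the control mean must be positive.
#' @return `mean(case) / mean(control)`.
#' @export
fold_change <- function(case_values, control_values) {
  mc <- mean(control_values)
  if (!is.finite(mc) || mc <= 0) {
    stop("validation error: control mean must be positive")
  }
  mean(case_values) / mc
}

#' Two-sided unpaired t-test p-value
#'
#' Welch (default) or pooled-variance two-sample t-test. When both groups
#' are constant with equal means the p-value is 1 by convention (no
#' evidence of a difference); constant groups with different means give 0.
#'
#' @param case_values,control_values Numeric vectors, n >= 2 each.
#' @param welch Use the Welch (unequal-variance) form.
#' @return Two-sided p-value.
#' @export
ttest_unpaired <- function(case_values, control_values, welch = TRUE) {
  if (length(case_values) < 2L || length(control_values) < 2L) {
    stop("validation error: each group needs n >= 2")
  }
  if (stats::var(case_values) == 0 && stats::var(control_values) == 0) {
    return(if (mean(case_values) == mean(control_values)) 1.0 else 0.0)
  }
  stats::t.test(case_values, control_values, var.equal = !welch)$p.value
}

#' Two-sided unpaired t-test from summary statistics
#'
#' Computes the same p-value as [ttest_unpaired()] would on any sample
#' with exactly these per-group means, standard deviations and sizes;
#' useful for re-analyzing published demographic tables.
#'
#' @param mean1,sd1,n1 First group summary (sd >= 0, n >= 2).
#' @param mean2,sd2,n2 Second group summary.
#' @param welch Use the Welch form (default pooled, the usual convention
#'   for demographic tables).
#' @return Two-sided p-value.
#' @export
#' @examples
#' ttest_from_summary(29.6, 12.2, 10, 27.8, 10.7, 10)  # 0.73
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    return(if (mean1 == mean2) 1.0 else 0.0)
  }
  if (welch) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tstat <- (mean1 - mean2) / se
  2 * stats::pt(-abs(tstat), df)
}

#' One-way two-group ANOVA p-value
#'
#' Classical between/within sums-of-squares F-test for two groups; the F
#' statistic equals the square of the pooled t statistic, so the p-value
#' matches `ttest_unpaired(..., welch = FALSE)` exactly.
#'
#' @param case_values,control_values Numeric vectors, n >= 2 each.
#' @return Two-sided p-value.
#' @export
anova_pvalue <- function(case_values, control_values) {
  n1 <- length(case_values)
  n2 <- length(control_values)
  if (n1 < 2L || n2 < 2L) stop("validation error: each group needs n >= 2")
  grand <- mean(c(case_values, control_values))
  ss_between <- n1 * (mean(case_values) - grand)^2 +
    n2 * (mean(control_values) - grand)^2
  ss_within <- sum((case_values - mean(case_values))^2) +
    sum((control_values - mean(control_values))^2)
  df2 <- n1 + n2 - 2
  if (ss_within == 0) {
    return(if (ss_between == 0) 1.0 else 0.0)
  }
  f <- (ss_between / 1) / (ss_within / df2)
  stats::pf(f, 1, df2, lower.tail = FALSE)
}

#' Per-feature differential reactivity table
#'
#' Computes, for every feature of a normalized experiment set, the
#' M-statistic and its exact tail probability, the one-sided Cantelli
#' bound on the standardized case/control mean difference, the
#' linear-scale fold change, Welch t and two-group ANOVA p-values, an
#' optional Benjamini-Hochberg adjusted column, and the significance
#' call at the supplied thresholds (`fold_change > fc_cut` and
#' `p_m <= p_cut`).
#'
#' @param es Output of [rlm_normalize()] (control spots are excluded from
#'   the result).
#' @param th A [thresholds()] object.
#' @param adjust Add a `p_m_bh` Benjamini-Hochberg column (off by default;
#'   the discovery filter uses raw p-values).
#' @return Data frame of class `differential_result`, one row per
#'   non-control feature.
#' @export
differential_table <- function(es, th = thresholds(), adjust = FALSE) {
  x_log2 <- SummarizedExperiment::assay(es, "normalized_log2")
  keep <- !isTRUE_vec(SummarizedExperiment::rowData(es)$is_control)
  x_log2 <- x_log2[keep, , drop = FALSE]
  x_lin <- 2^x_log2
  grp <- SummarizedExperiment::colData(es)$group
  case <- grp == "case"
  ctrl <- grp == "control"
  n1 <- sum(case)
  n2 <- sum(ctrl)
  if (n1 < 2L || n2 < 2L) {
    stop("validation error: need >= 2 case and >= 2 control arrays")
  }

  xc <- x_log2[, case, drop = FALSE]
  xh <- x_log2[, ctrl, drop = FALSE]
  m <- rowSums(xc > apply(xh, 1L, max))
  p_m <- m_pvalue(m, n1, n2)

  mean_c <- rowMeans(xc)
  mean_h <- rowMeans(xh)
  var_c <- rowSums((xc - mean_c)^2) / (n1 - 1)
  var_h <- rowSums((xh - mean_h)^2) / (n2 - 1)
  sd_h <- sqrt(var_h)
  z_feat <- ifelse(sd_h > 0, (mean_c - mean_h) / sd_h, 0)
  p_cheb <- cantelli_pvalue(z_feat)

  fc <- rowMeans(x_lin[, case, drop = FALSE]) /
    rowMeans(x_lin[, ctrl, drop = FALSE])

  # Welch t, vectorized; degenerate zero-variance rows handled by convention
  se2 <- var_c / n1 + var_h / n2
  tstat <- ifelse(se2 > 0, (mean_c - mean_h) / sqrt(se2), 0)
  dfw <- ifelse(se2 > 0,
                se2^2 / ((var_c / n1)^2 / (n1 - 1) + (var_h / n2)^2 / (n2 - 1)),
                n1 + n2 - 2)
  p_t <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), dfw),
                ifelse(mean_c == mean_h, 1, 0))

  # pooled one-way ANOVA, vectorized
  sp2 <- ((n1 - 1) * var_c + (n2 - 1) * var_h) / (n1 + n2 - 2)
  tp <- ifelse(sp2 > 0, (mean_c - mean_h) / sqrt(sp2 * (1 / n1 + 1 / n2)), 0)
  p_anova <- ifelse(sp2 > 0,
                    stats::pf(tp^2, 1, n1 + n2 - 2, lower.tail = FALSE),
                    ifelse(mean_c == mean_h, 1, 0))

  rd <- SummarizedExperiment::rowData(es)[keep, , drop = FALSE]
  out <- data.frame(
    feature_id = rownames(x_log2),
    gene_symbol = if (!is.null(rd$gene_symbol)) rd$gene_symbol else rownames(x_log2),
    m = as.integer(m),
    p_m = p_m,
    p_cheb = p_cheb,
    fold_change = fc,
    p_t = p_t,
    p_anova = p_anova,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (adjust) out$p_m_bh <- stats::p.adjust(out$p_m, method = "BH")
  out$significant <- out$fold_change > th$fc_cut & out$p_m <= th$p_cut
  class(out) <- c("differential_result", class(out))
  out
}

#' Filter and order the discovery list
#'
#' Keeps features with `fold_change > fc_cut` (strict) and `p_m <= p_cut`
#' (inclusive), ordered by ascending `p_m`, then descending fold change,
#' then `feature_id` for a deterministic tie-break.
#'
#' @param results A [differential_table()] result.
#' @param th A [thresholds()] object.
#' @return The filtered, ordered subset.
#' @export
select_significant <- function(results, th = thresholds()) {
  keep <- results$fold_change > th$fc_cut & results$p_m <= th$p_cut
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$p_m, -out$fold_change, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pre- versus post-operative reactivity comparison
#'
#' Applies the M-statistic machinery with groups pre vs post within the
#' subjects sampled at both timepoints. Both directions are reported:
#' `m_active` counts pre-operative (active disease) values above the
#' post-operative maximum, `m_post` the mirrored count for reactivities
#' that rise after surgery. Exact p-values come from [m_pvalue()] with the
#' two timepoint group sizes; the groups are treated as independent (the
#' exact tail probability is a label-exchange argument, not a paired
#' test), and unmatched subjects between timepoints trigger a warning.
#'
#' @param es A normalized experiment set whose `colData` has `timepoint`
#'   (`"pre"`/`"post"`) and `subject_id`.
#' @return Data frame with per-feature `m_active`, `p_active`, `m_post`,
#'   `p_post` and the pre/post linear fold change.
#' @export
prepost_compare <- function(es) {
  tp <- SummarizedExperiment::colData(es)$timepoint
  pre <- tp == "pre"
  post <- tp == "post"
  if (sum(pre) < 1L || sum(post) < 1L) {
    stop("validation error: need samples at both timepoints")
  }
  subj <- SummarizedExperiment::colData(es)$subject_id
  if (!is.null(subj) &&
      !setequal(subj[pre], subj[post])) {
    warning("pre and post samples come from different subject sets; ",
            "groups treated as independent")
  }
  x_log2 <- SummarizedExperiment::assay(es, "normalized_log2")
  keep <- !isTRUE_vec(SummarizedExperiment::rowData(es)$is_control)
  x_log2 <- x_log2[keep, , drop = FALSE]
  xp <- x_log2[, pre, drop = FALSE]
  xq <- x_log2[, post, drop = FALSE]
  m_active <- rowSums(xp > apply(xq, 1L, max))
  m_post <- rowSums(xq > apply(xp, 1L, max))
  data.frame(
    feature_id = rownames(x_log2),
    m_active = as.integer(m_active),
    p_active = m_pvalue(m_active, sum(pre), sum(post)),
    m_post = as.integer(m_post),
    p_post = m_pvalue(m_post, sum(post), sum(pre)),
    fold_change = rowMeans(2^xp) / rowMeans(2^xq),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
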