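test_that("M-statistic counts cases above the control maximum", {
  expect_equal(m_statistic(c(9, 8, 2), c(7, 1, 0)), 2)
  expect_equal(m_statistic(c(1, 2, 3), c(5, 6)), 0)
  expect_error(m_statistic(numeric(0), 1:3), "non-empty")

  # brute-force elementwise oracle over random draws
  set.seed(100)
  for (i in 1:200) {
    cs <- rnorm(10)
    ct <- rnorm(10)
    oracle <- sum(vapply(cs, function(v) all(v > ct), logical(1)))
    expect_identical(m_statistic(cs, ct), oracle)
  }
})

test_that("ties with the control maximum never count toward m", {
  ct <- c(1, 2, 5)
  expect_equal(m_statistic(c(5, 5, 6), ct), 1)
  # adding a case value epsilon below the control max never increases m
  set.seed(101)
  for (i in 1:50) {
    cs <- rnorm(8)
    m0 <- m_statistic(cs, ct)
    expect_equal(m_statistic(c(cs, max(ct) - 1e-12), ct), m0)
  }
})

test_that("exact M p-value matches exhaustive enumeration and closed forms", {
  expect_equal(m_pvalue(2, 3, 3), 3 / 15)
  expect_equal(m_pvalue(0, 7, 4), 1.0)
  expect_equal(m_pvalue(10, 10, 10), 1 / choose(20, 10))
  expect_error(m_pvalue(4, 3, 3), "domain error")

  for (n1 in 2:5) {
    for (n2 in 2:5) {
      for (m in 0:n1) {
        expect_equal(m_pvalue(m, n1, n2), m_pvalue_enum(m, n1, n2),
                     tolerance = 1e-12,
                     label = sprintf("P(M>=%d) for %dv%d", m, n1, n2))
      }
    }
  }
})

test_that("M p-value decreases strictly in m at fixed group sizes", {
  for (n1 in c(5, 10)) {
    p <- m_pvalue(0:n1, n1, 10)
    expect_true(all(diff(p) < 0))
    expect_true(all(p > 0 & p <= 1))
  }
})

test_that("Cantelli/Chebyshev bounds take their closed-form values", {
  expect_equal(cantelli_pvalue(3), 0.1)
  expect_equal(cantelli_pvalue(3, two_sided = TRUE), 1 / 9)
  expect_equal(cantelli_pvalue(0), 1.0)
  expect_equal(cantelli_pvalue(0, two_sided = TRUE), 1.0)
  expect_equal(cantelli_pvalue(-2), 1.0)
  expect_error(cantelli_pvalue(Inf), "finite")
})

test_that("Cantelli bound dominates Gaussian tail frequencies", {
  set.seed(123)
  draws <- rnorm(1e4)
  for (z in 1:3) {
    expect_lte(mean(draws >= z), cantelli_pvalue(z))
  }
})

test_that("fold change is the ratio of linear-scale group means", {
  expect_equal(fold_change(c(150, 250), c(50, 150)), 2.0)
  expect_equal(fold_change(c(7, 9), c(7, 9)), 1.0)
  expect_error(fold_change(1:3, c(0, 0)), "positive")

  # injected 18x feature recovered within 25% at CV 20%, n = 10
  sim <- gen_array_dataset(n_features = 400, n_elevated = 1,
                           fold_range = c(18, 18), n_control_spots = 40,
                           n_prepost_elevated = 0, seed = 12)
  es <- rlm_normalize(sim$experiment)
  lin <- 2^SummarizedExperiment::assay(es, "normalized_log2")
  grp <- SummarizedExperiment::colData(es)$group
  fid <- sim$truth$elevated$feature_id[[1L]]
  fc <- fold_change(lin[fid, grp == "case"], lin[fid, grp == "control"])
  expect_lt(abs(fc - 18) / 18, 0.25)
})

test_that("unpaired t-test handles degenerate groups and matches theory", {
  expect_equal(ttest_unpaired(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(ttest_unpaired(rep(2, 5), rep(2, 4)), 1.0)
  expect_equal(ttest_unpaired(rep(3, 5), rep(2, 4)), 0.0)
  expect_error(ttest_unpaired(1, 1:5), "n >= 2")

  # means 1 vs 0, sd 1, n = 10 each, pooled: closed-form t CDF oracle
  x <- sample_with_moments(10, 1, 1, seed = 31)
  y <- sample_with_moments(10, 0, 1, seed = 32)
  t_expect <- 1 / sqrt(2 / 10)
  p_expect <- 2 * pt(-t_expect, 18)
  expect_equal(ttest_unpaired(x, y, welch = FALSE), p_expect,
               tolerance = 1e-10)
  expect_equal(round(p_expect, 3), 0.038)
})

test_that("summary-statistic t-test equals the sample test at those moments", {
  cases <- list(c(29.6, 12.2, 10, 27.8, 10.7, 10),
                c(5, 2, 8, 4.2, 1.1, 12),
                c(0.3, 0.1, 25, 0.32, 0.2, 14))
  for (cc in cases) {
    for (welch in c(TRUE, FALSE)) {
      x <- sample_with_moments(cc[3], cc[1], cc[2], seed = 41)
      y <- sample_with_moments(cc[6], cc[4], cc[5], seed = 42)
      expect_equal(
        ttest_from_summary(cc[1], cc[2], cc[3], cc[4], cc[5], cc[6],
                           welch = welch),
        ttest_unpaired(x, y, welch = welch),
        tolerance = 1e-9)
    }
  }
  expect_equal(ttest_from_summary(3, 1, 5, 3, 2, 8), 1.0)
  expect_equal(round(ttest_from_summary(29.6, 12.2, 10, 27.8, 10.7, 10), 2),
               0.73)
})

test_that("two-group ANOVA satisfies F = t^2 and a sums-of-squares oracle", {
  expect_equal(anova_pvalue(c(1, 2, 3), c(1, 2, 3)), 1.0)
  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(7)
    y <- rnorm(5, 0.5)
    expect_equal(anova_pvalue(x, y), ttest_unpaired(x, y, welch = FALSE),
                 tolerance = 1e-12)
  }
  # 3-point toy, hand-computed F ratio
  x <- c(1, 2, 3)
  y <- c(2, 4, 6)
  # group means 2 and 4, grand 3; SSB = 3*1 + 3*1 = 6; SSW = 2 + 8 = 10
  f_hand <- (6 / 1) / (10 / 4)
  expect_equal(anova_pvalue(x, y), pf(f_hand, 1, 4, lower.tail = FALSE))
})

test_that("significance filter applies strict fold and inclusive p cuts", {
  res <- data.frame(
    feature_id = c("a", "b", "c", "d", "e"),
    p_m = c(0.05, 0.04, 0.05, 0.01, 0.051),
    fold_change = c(2.0, 2.5, 3.0, 2.1, 9.0)
  )
  out <- select_significant(res)
  expect_equal(out$feature_id, c("d", "b", "c"))  # fc == 2 excluded, p == 0.05 kept
  expect_false("a" %in% out$feature_id)
  expect_false("e" %in% out$feature_id)
  # deterministic tie-break by feature id at equal (p, fc)
  res2 <- data.frame(feature_id = c("z", "y"), p_m = c(0.01, 0.01),
                     fold_change = c(3, 3))
  expect_equal(select_significant(res2)$feature_id, c("y", "z"))
})

test_that("discovery run recovers injected features with few false calls", {
  sim <- gen_array_dataset(seed = 1)
  es <- rlm_normalize(sim$experiment)
  tab <- differential_table(es)
  expect_equal(nrow(tab), 8268 - 100)       # control spots excluded
  sig <- select_significant(tab)
  recall <- mean(sim$truth$elevated$feature_id %in% sig$feature_id)
  false_calls <- sum(!sig$feature_id %in% sim$truth$elevated$feature_id)
  expect_gte(recall, 0.9)
  expect_lte(false_calls, 10)
})

test_that("differential table rows agree with the scalar operations", {
  sim <- gen_array_dataset(n_features = 120, n_case = 6, n_control = 5,
                           n_elevated = 8, n_control_spots = 12,
                           n_prepost_elevated = 3, seed = 77)
  es <- rlm_normalize(sim$experiment)
  tab <- differential_table(es, adjust = TRUE)
  x <- SummarizedExperiment::assay(es, "normalized_log2")
  grp <- SummarizedExperiment::colData(es)$group
  for (fid in sample(tab$feature_id, 10)) {
    cs <- x[fid, grp == "case"]
    ct <- x[fid, grp == "control"]
    row <- tab[tab$feature_id == fid, ]
    expect_equal(row$m, m_statistic(cs, ct))
    expect_equal(row$p_m, m_pvalue(row$m, 6, 5))
    expect_equal(row$fold_change, fold_change(2^cs, 2^ct), tolerance = 1e-12)
    expect_equal(row$p_t, ttest_unpaired(cs, ct), tolerance = 1e-12)
    expect_equal(row$p_anova, anova_pvalue(cs, ct), tolerance = 1e-12)
    expect_equal(row$p_cheb,
                 cantelli_pvalue((mean(cs) - mean(ct)) / sd(ct)))
  }
  expect_equal(tab$p_m_bh, p.adjust(tab$p_m, "BH"))
})

test_that("pre/post comparison reproduces exact 5v5 tail probabilities", {
  expect_equal(m_pvalue(4, 5, 5), 5 / 210)
  expect_equal(round(m_pvalue(4, 5, 5), 2), 0.02)
  expect_equal(m_pvalue(3, 5, 5), 10 / 120)
  expect_equal(round(m_pvalue(3, 5, 5), 2), 0.08)
  expect_equal(m_pvalue(5, 5, 5), 1 / 252)
  expect_equal(m_pvalue(5, 5, 5), m_pvalue_enum(5, 5, 5))

  sim <- gen_array_dataset(n_features = 300, n_elevated = 10,
                           n_control_spots = 30, n_prepost_elevated = 4,
                           seed = 13)
  es <- rlm_normalize(sim$experiment)
  cases <- es[, SummarizedExperiment::colData(es)$group == "case"]
  pp <- prepost_compare(cases)
  hits <- pp$feature_id[pp$p_active <= 0.05]
  expect_true(all(sim$truth$prepost$feature_id %in% hits))
  # mirrored direction present for post-operative trends
  expect_true(all(c("m_active", "m_post", "p_post") %in% names(pp)))

  # unmatched subjects warn
  cd <- SummarizedExperiment::colData(cases)
  cd$subject_id[cd$timepoint == "post"] <- paste0("X", seq_len(sum(cd$timepoint == "post")))
  SummarizedExperiment::colData(cases) <- cd
  expect_warning(prepost_compare(cases), "different subject sets")
})
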