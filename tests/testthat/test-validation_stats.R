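make_panel <- function(n_case = 10, n_control = 8, k = 3, shift = 0,
                       seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  grp <- rep(c("case", "control"), c(n_case, n_control))
  od <- exp(matrix(rnorm(n * k, log(0.5), 0.3), n, k) +
              outer(grp == "case", rep(shift, k)))
  colnames(od) <- paste0("AG", seq_len(k))
  elisa_panel(od, data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                             group = grp,
                             sex = rep_len(c("F", "M"), n)))
}

test_that("panel construction validates dimensions, groups and OD sign", {
  p <- make_panel()
  expect_s3_class(p, "elisa_panel")
  expect_error(elisa_panel(p$od, p$samples[1:3, ]), "dimension")
  expect_error(elisa_panel(-p$od, p$samples), "non-negative")
  bad <- p$samples
  bad$group <- "case"
  expect_error(elisa_panel(p$od, bad), "binary")
})

test_that("group test delegates to the unpaired t-test", {
  p <- make_panel(seed = 3)
  case <- p$samples$group == "case"
  for (a in p$antigens) {
    expect_identical(elisa_group_test(p, a),
                     c(setNames(ttest_unpaired(p$od[case, a], p$od[!case, a]),
                                a)))
  }
  ident <- p
  ident$od[case, ] <- ident$od[!case, ][seq_len(sum(case)) %% sum(!case) + 1, ]
  expect_error(elisa_group_test(p, "MISSING"), "unknown antigen")
})

test_that("group-test power tracks the noncentral-t prediction", {
  n1 <- 46; n2 <- 22; d <- 0.7
  ncp <- d / sqrt(1 / n1 + 1 / n2)
  tc <- qt(0.975, n1 + n2 - 2)
  power_theory <- 1 - pt(tc, n1 + n2 - 2, ncp) + pt(-tc, n1 + n2 - 2, ncp)
  set.seed(17)
  reject <- replicate(400, {
    x <- rnorm(n1, d)
    y <- rnorm(n2)
    ttest_unpaired(x, y, welch = FALSE) < 0.05
  })
  expect_lt(abs(mean(reject) - power_theory), 0.06)
})

test_that("covariate check flags only real covariate structure", {
  p <- make_panel(n_case = 30, n_control = 30, k = 20, seed = 5)
  # covariate equal to the group label reproduces the group test
  p$samples$sex <- p$samples$group
  expect_equal(covariate_check(p, "sex"), elisa_group_test(p))
  # a randomly permuted binary covariate is mostly null
  set.seed(6)
  p$samples$sex <- sample(rep_len(c("F", "M"), 60))
  expect_gte(sum(covariate_check(p, "sex") > 0.05), 18)

  p$samples$sex <- "F"
  expect_error(covariate_check(p, "sex"), "2 levels")
  expect_error(covariate_check(p, "bmi"), "not in sample metadata")
})

test_that("logistic fit recovers closed-form intercepts and flags separation", {
  # constant antigens are dropped -> intercept-only fit at the class log-odds
  sim <- gen_elisa(n_case = 46, n_control = 22, seed = 2)
  p <- sim$panel
  p$od[] <- 1
  expect_warning(fit <- logistic_fit(p), "constant antigen")
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), log(46 / 22),
               tolerance = 1e-9)

  balanced <- make_panel(n_case = 12, n_control = 12, seed = 7)
  balanced$od[] <- 1
  expect_warning(fit0 <- logistic_fit(balanced), "constant")
  expect_equal(unname(fit0$coefficients[["(Intercept)"]]), 0, tolerance = 1e-9)

  # feature identical to the label => complete separation
  sep <- make_panel(n_case = 8, n_control = 8, k = 1, seed = 8)
  sep$od[, 1L] <- ifelse(sep$samples$group == "case", 2, 1)
  fit_sep <- logistic_fit(sep)
  expect_true(fit_sep$separation)
})

test_that("rank AUC equals trapezoidal ROC area and survives monotone maps", {
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(2, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  set.seed(9)
  for (i in 1:10) {
    scores <- c(rnorm(16, 0.6), rnorm(14))
    scores[sample(30, 4)] <- scores[[1L]]  # inject ties
    labels <- rep(c(1, 0), c(16, 14))
    a <- roc_auc(scores, labels)
    expect_equal(a, auc_trapezoid(scores, labels), tolerance = 1e-12)
    expect_equal(roc_auc(exp(3 * scores), labels), a, tolerance = 1e-12)
    expect_equal(roc_auc(rank(scores, ties.method = "average"), labels), a)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  scores <- rnorm(40)
  labels <- rep(c(1, 0), 20)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("confusion metrics reproduce the published operating point", {
  m <- confusion_metrics(tp = 34, fp = 5, tn = 17, fn = 12)
  expect_equal(m$sensitivity_pct, 74)
  expect_equal(m$specificity_pct, 77)
  expect_equal(m$ppv_pct, 87)
  expect_equal(m$npv_pct, 59)
  expect_equal(m$accuracy_pct, 75)

  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_equal(perfect$accuracy_pct, 100)
  even <- confusion_metrics(1, 1, 1, 1)
  expect_true(all(unlist(even[c("sensitivity", "specificity", "ppv", "npv",
                                "accuracy")]) == 0.5))
  # undefined metrics become NA, not zero
  none_pos <- confusion_metrics(0, 0, 5, 0)
  expect_true(is.na(none_pos$sensitivity))
  expect_true(is.na(none_pos$ppv))
  # display rounding is half away from zero
  expect_equal(confusion_metrics(149, 51, 0, 0)$sensitivity_pct, 100)
  expect_equal(confusion_metrics(745, 255, 0, 0)$ppv_pct, 75)
})

test_that("accuracy identity holds exactly for random confusion tables", {
  set.seed(11)
  for (i in 1:50) {
    cts <- rmultinom(1, 60, c(0.3, 0.2, 0.3, 0.2))
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    P <- m$tp + m$fn
    N <- m$tn + m$fp
    if (P > 0 && N > 0) {
      expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N),
                   tolerance = 1e-15)
    }
  }
})

test_that("classifier report matches counts and honours thresholds", {
  sim <- gen_elisa(seed = 4)
  rep0 <- classify(sim$panel, threshold = 0)
  expect_equal(rep0$sensitivity_pct, 100)
  rep1 <- classify(sim$panel, threshold = 1 + 1e-9)
  expect_equal(rep1$specificity_pct, 100)

  rep <- classify(sim$panel)
  expect_equal(rep$tp + rep$fn, 46)
  expect_equal(rep$tn + rep$fp, 22)
  expect_equal(rep$auc, roc_auc(rep$probabilities, sim$panel$samples$group))
  # fitted panel never scores below its own best single antigen
  single <- max(vapply(sim$panel$antigens, function(a)
    roc_auc(sim$panel$od[, a], sim$panel$samples$group), numeric(1)))
  expect_gte(rep$auc + 1e-12, single)
  expect_output(print(rep), "AUC")
})
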