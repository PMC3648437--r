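# ELISA-panel statistics: per-antigen group tests, covariate checks, the
# multi-antigen logistic classifier, rank-based ROC AUC and diagnostic
# metric reporting.

#' Construct an ELISA panel
#'
#' @param od Numeric matrix of OD405 readings, samples x antigens, all
#'   values >= 0; column names are antigen gene symbols.
#' @param samples Data frame with `sample_id`, binary `group`
#'   (`"case"`/`"control"`) and optional covariates (e.g. `sex`), one row
#'   per OD row.
#' @return A list of class `elisa_panel` with `od`, `samples`, `antigens`.
#' @export
elisa_panel <- function(od, samples) {
  od <- as.matrix(od)
  if (!is.numeric(od) || any(od < 0)) {
    stop("validation error: od must be a non-negative numeric matrix")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(od) != nrow(samples)) {
    stop("dimension error: ", nrow(od), " OD rows vs ", nrow(samples),
         " samples")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("validation error: duplicate sample_id")
  }
  if (!all(samples$group %in% c("case", "control")) ||
      length(unique(samples$group)) != 2L) {
    stop("validation error: group must be binary 'case'/'control'")
  }
  if (is.null(colnames(od))) {
    colnames(od) <- paste0("antigen", seq_len(ncol(od)))
  }
  rownames(od) <- samples$sample_id
  structure(list(od = od, samples = samples, antigens = colnames(od)),
            class = "elisa_panel")
}

#' Read / write an ELISA plate CSV
#'
#' Rows are samples; metadata columns `sample_id`, `group`, `sex` precede
#' one OD405 column per antigen.
#'
#' @param path CSV path.
#' @return An [elisa_panel()].
#' @export
read_elisa_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("sample_id", "group", "sex", "subject_id", "age",
                           "timepoint"), names(tab))
  od <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  elisa_panel(od, tab[, meta_cols, drop = FALSE])
}

#' @rdname read_elisa_csv
#' @param panel An `elisa_panel`.
#' @export
write_elisa_csv <- function(panel, path) {
  tab <- cbind(panel$samples, as.data.frame(panel$od, check.names = FALSE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-antigen case/control group test
#'
#' Two-sided unpaired t-test of OD405 between groups, delegating to
#' [ttest_unpaired()].
#'
#' @param panel An [elisa_panel()].
#' @param antigen Antigen name(s); default all.
#' @param welch Use the Welch form.
#' @return Named vector of p-values.
#' @export
elisa_group_test <- function(panel, antigen = panel$antigens, welch = TRUE) {
  stopifnot(inherits(panel, "elisa_panel"))
  missing <- setdiff(antigen, panel$antigens)
  if (length(missing)) {
    stop("validation error: unknown antigen(s): ",
         paste(missing, collapse = ", "))
  }
  case <- panel$samples$group == "case"
  vapply(antigen, function(a) {
    ttest_unpaired(panel$od[case, a], panel$od[!case, a], welch = welch)
  }, numeric(1))
}

#' Per-antigen association with a binary covariate
#'
#' Unpaired t-test of each antigen's OD across the two levels of a
#' covariate (e.g. sex), used to check that panel reactivity tracks
#' disease status rather than demographics.
#'
#' @param panel An [elisa_panel()].
#' @param covariate Column name in `panel$samples`.
#' @param welch Use the Welch form.
#' @return Named vector of p-values, one per antigen.
#' @export
covariate_check <- function(panel, covariate = "sex", welch = TRUE) {
  stopifnot(inherits(panel, "elisa_panel"))
  if (!covariate %in% names(panel$samples)) {
    stop("validation error: covariate '", covariate, "' not in sample metadata")
  }
  v <- panel$samples[[covariate]]
  lev <- unique(v[!is.na(v)])
  if (length(lev) != 2L) {
    stop("validation error: covariate '", covariate,
         "' must have exactly 2 levels, found ", length(lev))
  }
  g1 <- v == lev[[1L]]
  vapply(panel$antigens, function(a) {
    ttest_unpaired(panel$od[g1, a], panel$od[!g1, a], welch = welch)
  }, numeric(1))
}

#' Fit the multi-antigen logistic classifier
#'
#' Maximum-likelihood logistic regression of case status on the
#' internally standardized (mean 0, sd 1) antigen ODs, fitted by
#' Newton-Raphson IRLS (up to 100 iterations). Constant antigens are
#' dropped with a warning. Complete separation (divergent coefficients /
#' degenerate fitted probabilities) is detected and flagged; the fit at
#' the iteration cap is still returned.
#'
#' @param panel An [elisa_panel()].
#' @return A list of class `logistic_model` with `coefficients`
#'   (intercept + one log-odds slope per standardized antigen),
#'   `separation`, `converged`, `center`/`scale`, and `dropped`.
#' @export
logistic_fit <- function(panel) {
  stopifnot(inherits(panel, "elisa_panel"))
  y <- as.integer(panel$samples$group == "case")
  if (sum(y) < 2L || sum(1 - y) < 2L) {
    stop("validation error: need >= 2 samples per class")
  }
  x <- panel$od
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("constant antigen(s) dropped from classifier: ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(x)
  xs <- scale(x, center = ctr, scale = sds)

  separation <- FALSE
  fit <- if (ncol(xs)) {
    withCallingHandlers(
      stats::glm.fit(cbind(`(Intercept)` = 1, xs), y,
                     family = stats::binomial(),
                     control = list(maxit = 100, epsilon = 1e-10)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
  } else {
    list(coefficients = c(`(Intercept)` = stats::qlogis(mean(y))),
         converged = TRUE)
  }
  coefs <- fit$coefficients
  if (!separation && any(abs(coefs[-1L]) > 15)) separation <- TRUE
  structure(
    list(coefficients = coefs, separation = separation,
         converged = isTRUE(fit$converged), center = ctr, scale = sds,
         dropped = dropped, antigens = colnames(xs)),
    class = "logistic_model"
  )
}

#' @export
predict.logistic_model <- function(object, newdata, ...) {
  od <- if (inherits(newdata, "elisa_panel")) newdata$od else as.matrix(newdata)
  eta <- rep(object$coefficients[["(Intercept)"]], nrow(od))
  if (length(object$antigens)) {
    xs <- scale(od[, object$antigens, drop = FALSE],
                center = object$center, scale = object$scale)
    eta <- eta + as.vector(xs %*% object$coefficients[object$antigens])
  }
  stats::plogis(eta)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney form with half credit for ties: the probability that a
#' randomly chosen positive scores above a randomly chosen negative.
#' Identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical, 0/1, or `"case"`/`"control"` labels (positives
#'   are `TRUE`/`1`/`"case"`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "case"
  } else {
    as.logical(labels)
  }
  if (anyNA(pos) || anyNA(scores)) stop("validation error: missing values")
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("validation error: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

pct_display <- function(x) {
  # half away from zero to whole percent (74.5 -> 75); inputs are >= 0
  ifelse(is.na(x), NA_real_, floor(100 * x + 0.5))
}

#' Diagnostic metrics from a confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return A list of class `classifier_metrics`: exact fractions
#'   (`sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`; `NA` where
#'   the denominator is zero) plus display percentages (`*_pct`, rounded
#'   half away from zero) and the counts.
#' @export
#' @examples
#' confusion_metrics(tp = 34, fp = 5, tn = 17, fn = 12)
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("validation error: counts must be non-negative")
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = frac(tp, tp + fn),
    specificity = frac(tn, tn + fp),
    ppv = frac(tp, tp + fp),
    npv = frac(tn, tn + fn),
    accuracy = frac(tp + tn, tp + fp + tn + fn)
  )
  for (metric in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    out[[paste0(metric, "_pct")]] <- pct_display(out[[metric]])
  }
  structure(out, class = "classifier_metrics")
}

#' Evaluate the ELISA-panel classifier
#'
#' Fits (or reuses) the logistic model, thresholds the in-sample
#' predicted probabilities, and reports the confusion matrix, diagnostic
#' metrics and AUC. Evaluation is in-sample (apparent performance); this
#' is the replication path, with no resampling.
#'
#' @param panel An [elisa_panel()].
#' @param threshold Probability threshold for a positive call
#'   (`prob >= threshold`).
#' @param model Optional pre-fitted [logistic_fit()] model.
#' @return A list of class `classifier_report`: `model`, `auc`,
#'   `threshold`, `probabilities` and all [confusion_metrics()] fields.
#' @export
classify <- function(panel, threshold = 0.5, model = NULL) {
  stopifnot(inherits(panel, "elisa_panel"))
  if (is.null(model)) model <- logistic_fit(panel)
  probs <- predict(model, panel)
  truth <- panel$samples$group == "case"
  pred <- probs >= threshold
  metrics <- confusion_metrics(
    tp = sum(pred & truth), fp = sum(pred & !truth),
    tn = sum(!pred & !truth), fn = sum(!pred & truth)
  )
  structure(
    c(list(model = model, auc = roc_auc(probs, truth),
           threshold = threshold, probabilities = probs),
      unclass(metrics)),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("ELISA-panel logistic classifier (in-sample)\n")
  cat(sprintf("  AUC: %.3f   threshold: %.2f\n", x$auc, x$threshold))
  cat(sprintf("  confusion: tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf(
    "  sensitivity %g%%, specificity %g%%, PPV %g%%, NPV %g%%, accuracy %g%%\n",
    x$sensitivity_pct, x$specificity_pct, x$ppv_pct, x$npv_pct,
    x$accuracy_pct))
  if (isTRUE(x$model$separation)) {
    cat("  note: complete separation detected; coefficients unstable\n")
  }
  invisible(x)
}
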