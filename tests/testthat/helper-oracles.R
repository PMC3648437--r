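# Independent oracles and fixture builders shared across the suite.

# Exhaustive-permutation oracle for the M-statistic tail probability:
# enumerate every assignment of n1 case labels to the N pooled ranks and
# count assignments in which at least m case values exceed all controls.
m_pvalue_enum <- function(m, n1, n2) {
  if (m == 0) return(1.0)
  N <- n1 + n2
  combos <- utils::combn(N, n1)
  hits <- apply(combos, 2L, function(case_ranks) {
    ctrl_max <- max(setdiff(seq_len(N), case_ranks))
    sum(case_ranks > ctrl_max) >= m
  })
  mean(hits)
}

# Trapezoidal area under the empirical ROC curve (threshold sweep),
# independent of the rank formula.
auc_trapezoid <- function(scores, labels) {
  pos <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# A sample of size n with exactly the requested mean and sd.
sample_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}

# Minimal GPR text fixture writer.
write_tiny_gpr <- function(path,
                           f635 = c(100, 200, 300),
                           b635 = c(10, 20, 30),
                           names = paste0("protein", seq_along(f635)),
                           ids = paste0("FT", seq_along(f635)),
                           drop_col = NULL,
                           extra_header = '"Scanner=unit test"') {
  cols <- c("Block", "Column", "Row", "Name", "ID",
            "F635 Median", "B635 Median")
  rows <- data.frame(1, seq_along(f635), 1, names, ids, f635, b635,
                     stringsAsFactors = FALSE)
  keep <- if (is.null(drop_col)) rep(TRUE, length(cols)) else cols != drop_col
  lines <- c('"Type=GenePix Results 3"', extra_header,
             paste(cols[keep], collapse = "\t"),
             apply(rows[, keep, drop = FALSE], 1L,
                   function(r) paste(trimws(r), collapse = "\t")))
  writeLines(lines, path)
  path
}

# Small in-memory experiment set with explicit values.
tiny_experiment <- function(net, groups,
                            controls = integer(0),
                            timepoints = NULL,
                            subjects = NULL) {
  n_feat <- nrow(net)
  n_samp <- ncol(net)
  features <- data.frame(
    feature_id = sprintf("FT%03d", seq_len(n_feat)),
    gene_symbol = sprintf("G%03d", seq_len(n_feat)),
    description = "fixture",
    is_control = seq_len(n_feat) %in% controls,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samp)),
    group = groups,
    stringsAsFactors = FALSE
  )
  if (!is.null(timepoints)) {
    samples$timepoint <- timepoints
    samples$subject_id <- if (is.null(subjects)) {
      sprintf("SUBJ%02d", seq_len(n_samp))
    } else {
      subjects
    }
  }
  experiment_set(net, features, samples)
}
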