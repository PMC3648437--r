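# Seeded synthetic-data generators with known ground truth: spot-level
# array datasets, gene annotation tables and ELISA panels emulating the
# study conditions (8268-feature arrays, 10 vs 10 discovery with 165
# elevated reactivities at 2-85x fold change, a 5-pre/5-post case subset,
# and a 46 vs 22 ELISA panel calibrated to a target AUC).

#' Generate a synthetic protein-array dataset with ground truth
#'
#' Signal model: each feature has a lognormal baseline mean; case arrays
#' multiply `n_elevated` randomly chosen features by true fold changes
#' drawn log-uniformly from `fold_range`; every array carries a
#' multiplicative scale effect `2^N(0, array_effect_sd)` (log2 units);
#' multiplicative lognormal noise at coefficient of variation `cv` is
#' applied spot-wise. Designated control spots receive no group effect.
#' Case arrays are structured as `n_case/2` subjects sampled pre- and
#' post-operatively; `n_prepost_elevated` additional features are
#' elevated in the pre-operative (active disease) samples only. Net
#' signals are rounded to integer RFU (scanner counts), so writing with
#' [write_array_dataset()] and re-reading round-trips exactly.
#'
#' @param n_features Total features including control spots.
#' @param n_case,n_control Arrays per group.
#' @param n_elevated Number of case-elevated features.
#' @param fold_range Range of true fold changes (log-uniform draw).
#' @param cv Spot-wise noise coefficient of variation.
#' @param array_effect_sd SD of per-array scale effects, log2 units.
#' @param n_control_spots Number of control features (no group effect).
#' @param n_prepost_elevated Features elevated pre- vs post-operatively
#'   within cases (requires an even `n_case`).
#' @param prepost_fold Pre/post fold change for those features.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline parameters
#'   (natural-log scale).
#' @param array_effects Optional fixed per-array log2 scale effects
#'   (length `n_case + n_control`), overriding the random draw.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return List with `experiment` (a `SummarizedExperiment`, assay `net`)
#'   and `truth` (elevated features with true folds, per-array log2
#'   effects, pre/post features, seed and parameters).
#' @export
gen_array_dataset <- function(n_features = 8268, n_case = 10, n_control = 10,
                              n_elevated = 165, fold_range = c(2, 85),
                              cv = 0.2, array_effect_sd = 0.3,
                              n_control_spots = 100,
                              n_prepost_elevated = 4, prepost_fold = 3,
                              baseline_meanlog = log(500),
                              baseline_sdlog = 0.5,
                              array_effects = NULL,
                              seed = 1) {
  if (n_elevated + n_control_spots + n_prepost_elevated >= n_features) {
    stop("validation error: n_features must exceed elevated + control spots")
  }
  if (n_prepost_elevated > 0 && n_case %% 2 != 0) {
    stop("validation error: pre/post structure requires an even n_case")
  }
  set.seed(seed)
  n_arr <- n_case + n_control

  feature_id <- c(sprintf("CTRL_%04d", seq_len(n_control_spots)),
                  sprintf("PROT_%05d", seq_len(n_features - n_control_spots)))
  gene_symbol <- c(rep("CONTROL", n_control_spots),
                   sprintf("GENE%05d", seq_len(n_features - n_control_spots)))
  is_control <- grepl("^CTRL_", feature_id)

  n_half <- n_case %/% 2L
  case_ids <- c(sprintf("MMD%02d_pre", seq_len(n_half)),
                sprintf("MMD%02d_post", seq_len(n_half)))
  if (length(case_ids) < n_case) {
    case_ids <- c(case_ids, sprintf("MMD_extra%02d",
                                    seq_len(n_case - length(case_ids))))
  }
  samples <- data.frame(
    sample_id = c(case_ids, sprintf("HC%02d", seq_len(n_control))),
    group = rep(c("case", "control"), c(n_case, n_control)),
    timepoint = c(rep(c("pre", "post"), c(n_half, n_half)),
                  rep("na", n_case - 2L * n_half + n_control)),
    subject_id = c(rep(sprintf("S%02d", seq_len(n_half)), 2L),
                   sprintf("HS%02d", seq_len(n_case - 2L * n_half + n_control))),
    age = round(stats::rnorm(n_arr, 30, 10)),
    sex = sample(c("F", "M"), n_arr, replace = TRUE),
    stringsAsFactors = FALSE
  )

  baseline <- stats::rlnorm(n_features, baseline_meanlog, baseline_sdlog)
  candidates <- which(!is_control)
  elev_idx <- sample(candidates, n_elevated)
  folds <- exp(stats::runif(n_elevated, log(fold_range[[1L]]),
                            log(fold_range[[2L]])))
  pp_idx <- sample(setdiff(candidates, elev_idx), n_prepost_elevated)

  array_effect <- if (is.null(array_effects)) {
    stats::rnorm(n_arr, 0, array_effect_sd)  # log2 units
  } else {
    stopifnot(length(array_effects) == n_arr)
    array_effects
  }
  fold_mat <- matrix(1, n_features, n_arr)
  fold_mat[elev_idx, seq_len(n_case)] <- folds
  if (n_prepost_elevated > 0) {
    pre_cols <- which(samples$timepoint == "pre")
    fold_mat[pp_idx, pre_cols] <- prepost_fold
  }

  sdlog_noise <- sqrt(log(1 + cv^2))
  noise <- matrix(stats::rlnorm(n_features * n_arr,
                                -sdlog_noise^2 / 2, sdlog_noise),
                  n_features, n_arr)
  net <- baseline * fold_mat *
    matrix(2^array_effect, n_features, n_arr, byrow = TRUE) * noise
  net <- pmax(round(net), 1)

  features <- data.frame(
    feature_id = feature_id, gene_symbol = gene_symbol,
    description = ifelse(is_control, "normalization control spot",
                         "recombinant human protein"),
    is_control = is_control,
    block = rep(1L, n_features),
    row = ((seq_len(n_features) - 1L) %/% 96L) + 1L,
    column = ((seq_len(n_features) - 1L) %% 96L) + 1L,
    stringsAsFactors = FALSE
  )

  truth <- list(
    elevated = data.frame(feature_id = feature_id[elev_idx],
                          true_fold = folds, stringsAsFactors = FALSE),
    prepost = data.frame(feature_id = feature_id[pp_idx],
                         true_fold = rep(prepost_fold, n_prepost_elevated),
                         stringsAsFactors = FALSE),
    array_effects = stats::setNames(array_effect, samples$sample_id),
    seed = seed,
    params = list(n_features = n_features, n_case = n_case,
                  n_control = n_control, n_elevated = n_elevated,
                  fold_range = fold_range, cv = cv,
                  array_effect_sd = array_effect_sd,
                  n_control_spots = n_control_spots)
  )
  list(experiment = experiment_set(net, features, samples), truth = truth)
}

#' Write a synthetic array dataset as GPR files + metadata + truth
#'
#' One GPR-subset file per array (foreground = net + a synthetic local
#' background, background column carrying that background, so
#' [read_gpr()] + [background_subtract()] recover the net matrix
#' exactly), a tab-delimited sample metadata table, and the ground truth
#' as JSON.
#'
#' @param sim Output of [gen_array_dataset()].
#' @param dir Output directory (created if needed).
#' @param seed Seed for the synthetic background draws.
#' @return Named list of written paths, invisibly.
#' @export
write_array_dataset <- function(sim, dir, seed = sim$truth$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  es <- sim$experiment
  net <- SummarizedExperiment::assay(es, "net")
  ft <- as.data.frame(SummarizedExperiment::rowData(es))
  set.seed(seed + 1L)
  gpr_paths <- character(ncol(net))
  for (j in seq_len(ncol(net))) {
    bg <- round(stats::rlnorm(nrow(net), log(50), 0.3))
    scan <- structure(list(
      sample_id = colnames(net)[[j]],
      foreground = net[, j] + bg,
      background = bg,
      features = data.frame(name = ft$gene_symbol, id = ft$feature_id,
                            gene_symbol = ft$gene_symbol,
                            block = ft$block, column = ft$column,
                            row = ft$row, stringsAsFactors = FALSE),
      header = c(Type = "GenePix Results 3",
                 Source = "seroscreen synthetic generator")
    ), class = "array_scan")
    gpr_paths[[j]] <- file.path(dir, paste0(colnames(net)[[j]], ".gpr"))
    write_gpr(scan, gpr_paths[[j]])
  }
  meta_path <- file.path(dir, "metadata.tsv")
  utils::write.table(as.data.frame(SummarizedExperiment::colData(es)),
                     meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(list(gpr = gpr_paths, metadata = meta_path, truth = truth_path))
}

#' The published six-gene candidate panel annotation
#'
#' The six serum-validated candidate genes with their printed
#' differential-expression ratios (DER), cytobands and
#' neurological-variant flags, as consumed by the prioritization cascade.
#' The per-gene discovery-phase array p-values are included so the
#' cascade can be rerun from the printed record.
#'
#' @return Data frame with `gene_symbol`, `p`, `der`, `cytoband`,
#'   `neuro_variant`.
#' @export
mmd_candidate_panel <- function() {
  data.frame(
    gene_symbol = c("APP", "CTNNB1", "EDIL3", "ROR1", "GPS1", "STRA13"),
    p = c(0.029, 0.0197, 0.0003, 0.0029, 0.07, 0.0021),
    der = c(0.604, 0.555, 0.484, 0.586, 0.46, 0.581),
    cytoband = c("21q21.3", "3p21", "5q14", "1p32-p31", "17q25.3", "17q25.3"),
    neuro_variant = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate a gene annotation table
#'
#' Emits one record per gene: cytoband, DER drawn uniformly on `[0, 1]`,
#' and a Bernoulli neuro-variant flag. With `panel = "mmd"` the six
#' published candidate records ([mmd_candidate_panel()]) are prepended
#' with their printed DER values and cytobands.
#'
#' @param genes Character vector of background gene symbols; defaults to
#'   the (non-control) gene symbols of `truth`'s dataset when supplied
#'   via `sim`, else `n_genes` synthetic symbols.
#' @param sim Optional [gen_array_dataset()] output whose gene symbols to
#'   annotate.
#' @param n_genes Number of background genes when neither `genes` nor
#'   `sim` is given.
#' @param panel `"none"` or `"mmd"`.
#' @param variant_rate Bernoulli rate of the background neuro-variant flag.
#' @param seed Integer seed.
#' @return Data frame with `gene_symbol`, `cytoband`, `der`,
#'   `neuro_variant`.
#' @export
gen_annotation <- function(genes = NULL, sim = NULL, n_genes = 200,
                           panel = c("none", "mmd"), variant_rate = 0.1,
                           seed = 1) {
  panel <- match.arg(panel)
  set.seed(seed)
  if (is.null(genes)) {
    genes <- if (!is.null(sim)) {
      rd <- SummarizedExperiment::rowData(sim$experiment)
      unique(rd$gene_symbol[!rd$is_control])
    } else {
      sprintf("GENE%05d", seq_len(n_genes))
    }
  }
  chroms <- c(as.character(1:22), "X")
  bands <- data.frame(
    gene_symbol = genes,
    cytoband = paste0(sample(chroms, length(genes), replace = TRUE),
                      sample(c("p", "q"), length(genes), replace = TRUE),
                      sample(11:36, length(genes), replace = TRUE),
                      ifelse(stats::runif(length(genes)) < 0.5, "",
                             paste0(".", sample(1:3, length(genes),
                                                replace = TRUE)))),
    der = stats::runif(length(genes)),
    neuro_variant = stats::runif(length(genes)) < variant_rate,
    stringsAsFactors = FALSE
  )
  if (panel == "mmd") {
    six <- mmd_candidate_panel()[, c("gene_symbol", "cytoband", "der",
                                     "neuro_variant")]
    bands <- rbind(six, bands[!bands$gene_symbol %in% six$gene_symbol, ,
                              drop = FALSE])
  }
  rownames(bands) <- NULL
  bands
}

#' Generate a synthetic ELISA panel calibrated to a target AUC
#'
#' Per-antigen standardized effect sizes are set from the normal-theory
#' closed form: the Bayes-optimal linear score over `k` independent
#' Gaussian antigens with equal standardized effects `d` has AUC
#' `pnorm(sqrt(k) * d / sqrt(2))`, so
#' `d = qnorm(target_auc) * sqrt(2) / sqrt(k)` achieves the target in
#' expectation. Log-OD readings are Gaussian with that group shift and
#' are exponentiated, giving positive OD405 values.
#'
#' @param n_case,n_control Group sizes.
#' @param n_antigens Number of antigens; named after the candidate panel
#'   when `n_antigens <= 6`.
#' @param target_auc Target AUC of the optimal score, in (0.5, 1).
#' @param od_meanlog,od_sdlog Control-group log-OD parameters.
#' @param seed Integer seed.
#' @return List with `panel` (an [elisa_panel()]) and `truth`
#'   (per-antigen standardized effect sizes, target, seed).
#' @export
gen_elisa <- function(n_case = 46, n_control = 22, n_antigens = 6,
                      target_auc = 0.76, od_meanlog = log(0.4),
                      od_sdlog = 0.35, seed = 1) {
  if (!(target_auc > 0.5 && target_auc < 1)) {
    stop("validation error: target_auc must lie in (0.5, 1)")
  }
  set.seed(seed)
  d <- rep(stats::qnorm(target_auc) * sqrt(2) / sqrt(n_antigens), n_antigens)
  antigens <- if (n_antigens <= 6L) {
    mmd_candidate_panel()$gene_symbol[seq_len(n_antigens)]
  } else {
    sprintf("AG%02d", seq_len(n_antigens))
  }
  n <- n_case + n_control
  grp <- rep(c("case", "control"), c(n_case, n_control))
  shift <- outer(grp == "case", d * od_sdlog)
  log_od <- matrix(stats::rnorm(n * n_antigens, od_meanlog, od_sdlog),
                   n, n_antigens) + shift
  od <- exp(log_od)
  colnames(od) <- antigens
  samples <- data.frame(
    sample_id = sprintf("V%03d", seq_len(n)),
    group = grp,
    sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(
    panel = elisa_panel(od, samples),
    truth = list(effect_sizes = stats::setNames(d, antigens),
                 target_auc = target_auc, seed = seed)
  )
}
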