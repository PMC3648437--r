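# Pipeline orchestration: schema-validated run configuration, atomic
# artifact writes, a run manifest, and the simulate -> normalize -> diff
# -> prioritize -> validate chain.

#' Default pipeline configuration
#'
#' Nested list consumed by [run_pipeline()]: generator settings,
#' significance thresholds, prioritization preset, classifier options and
#' the seed. All values can be overridden; unknown keys are rejected by
#' [validate_config()].
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_features = 8268L, n_case = 10L, n_control = 10L,
      n_elevated = 165L, fold_min = 2, fold_max = 85,
      cv = 0.2, array_effect_sd = 0.3, n_control_spots = 100L,
      elisa_n_case = 46L, elisa_n_control = 22L, elisa_target_auc = 0.76
    ),
    thresholds = list(p_cut = 0.05, fc_cut = 2.0, z_cut = 3.0,
                      der1 = 0.45, der2 = 0.6),
    prioritization = list(config = "as_stated"),
    classifier = list(threshold = 0.5),
    normalization = list(huber_c = 1.345, tol = 1e-8, max_iter = 50L)
  )
}

config_schema <- function() {
  list(
    seed = "numeric",
    simulate = list(
      n_features = "numeric", n_case = "numeric", n_control = "numeric",
      n_elevated = "numeric", fold_min = "numeric", fold_max = "numeric",
      cv = "numeric", array_effect_sd = "numeric",
      n_control_spots = "numeric", elisa_n_case = "numeric",
      elisa_n_control = "numeric", elisa_target_auc = "numeric"
    ),
    thresholds = list(p_cut = "numeric", fc_cut = "numeric",
                      z_cut = "numeric", der1 = "numeric", der2 = "numeric"),
    prioritization = list(config = "character"),
    classifier = list(threshold = "numeric"),
    normalization = list(huber_c = "numeric", tol = "numeric",
                         max_iter = "numeric")
  )
}

#' Validate a pipeline configuration against the schema
#'
#' Unknown keys and type mismatches raise errors naming the dotted key
#' path (e.g. `thresholds.p_cut`). Values present in the default but
#' absent from `config` are filled in.
#'
#' @param config Nested list, or path to a JSON file holding one.
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  check <- function(cfg, schema, path) {
    unknown <- setdiff(names(cfg), names(schema))
    if (length(unknown)) {
      stop("config schema error: unknown key '",
           paste0(path, unknown[[1L]]), "'")
    }
    for (key in names(cfg)) {
      spec <- schema[[key]]
      if (is.list(spec)) {
        if (!is.list(cfg[[key]])) {
          stop("config schema error: '", path, key, "' must be a section")
        }
        check(cfg[[key]], spec, paste0(path, key, "."))
      } else if (!is(cfg[[key]], spec) ||
                 (spec == "numeric" && !is.numeric(cfg[[key]]))) {
        stop("config schema error: '", path, key, "' must be ", spec,
             ", got ", class(cfg[[key]])[[1L]])
      }
    }
  }
  check(config, config_schema(), "")
  utils::modifyList(default_config(), config)
}

atomic_write <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write_fn(tmp)
  if (!file.rename(tmp, path)) stop("atomic write failed for ", path)
  invisible(path)
}

#' Run pipeline stages
#'
#' Subcommands: `"simulate"` writes the synthetic GPR dataset, metadata,
#' annotation table, ELISA plate and ground truth under `out_dir`;
#' `"normalize"` reads them back and writes the normalized matrix and
#' array effects; `"diff"` writes the differential reactivity table;
#' `"prioritize"` writes the candidate table; `"validate"` writes the
#' classifier report and ROC points; `"all"` chains all five. Every
#' artifact is written atomically (temp file + rename) and recorded,
#' with its checksum, in `manifest.json`. Identical config + seed yield
#' bit-identical tables.
#'
#' @param command One of `"simulate"`, `"normalize"`, `"diff"`,
#'   `"prioritize"`, `"validate"`, `"all"`.
#' @param config Configuration list or JSON path (see
#'   [validate_config()]).
#' @param out_dir Artifact directory.
#' @param seed Optional override of `config$seed`.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(command = c("all", "simulate", "normalize", "diff",
                                     "prioritize", "validate"),
                         config = list(), out_dir = "seroscreen_run",
                         seed = NULL) {
  command <- match.arg(command)
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  th <- do.call(thresholds, config$thresholds)

  stage_simulate <- function() {
    sc <- config$simulate
    sim <- gen_array_dataset(
      n_features = sc$n_features, n_case = sc$n_case,
      n_control = sc$n_control, n_elevated = sc$n_elevated,
      fold_range = c(sc$fold_min, sc$fold_max), cv = sc$cv,
      array_effect_sd = sc$array_effect_sd,
      n_control_spots = sc$n_control_spots, seed = config$seed
    )
    paths <- write_array_dataset(sim, file.path(out_dir, "arrays"))
    ann <- gen_annotation(sim = sim, panel = "mmd", seed = config$seed)
    ann_path <- file.path(out_dir, "annotation.tsv")
    atomic_write(function(p) utils::write.table(ann, p, sep = "\t",
                                                quote = FALSE,
                                                row.names = FALSE), ann_path)
    elisa <- gen_elisa(n_case = sc$elisa_n_case,
                       n_control = sc$elisa_n_control,
                       target_auc = sc$elisa_target_auc, seed = config$seed)
    elisa_path <- file.path(out_dir, "elisa.csv")
    atomic_write(function(p) write_elisa_csv(elisa$panel, p), elisa_path)
    artifacts[c("metadata", "truth", "annotation", "elisa")] <<-
      list(paths$metadata, paths$truth, ann_path, elisa_path)
    artifacts$arrays <<- paths$gpr
  }

  load_experiment <- function() {
    meta <- read_sample_metadata(file.path(out_dir, "arrays", "metadata.tsv"))
    gpr <- file.path(out_dir, "arrays", paste0(meta$sample_id, ".gpr"))
    missing <- gpr[!file.exists(gpr)]
    if (length(missing)) {
      stop("missing input file: ", missing[[1L]],
           " (run the simulate stage first)")
    }
    scans <- lapply(gpr, function(p) background_subtract(read_gpr(p)))
    merge_scans(scans, meta)
  }

  stage_normalize <- function() {
    es <- load_experiment()
    nc <- config$normalization
    es <- rlm_normalize(es, huber_c = nc$huber_c, tol = nc$tol,
                        max_iter = nc$max_iter)
    es <- zscore_arrays(es)
    norm_path <- file.path(out_dir, "normalized.tsv")
    atomic_write(function(p) write_experiment_set(es, p, "normalized_log2"),
                 norm_path)
    eff_path <- file.path(out_dir, "array_effects.json")
    atomic_write(function(p) jsonlite::write_json(
      list(array_effect = stats::setNames(
             as.list(SummarizedExperiment::colData(es)$array_effect),
             colnames(es)),
           convergence = S4Vectors::metadata(es)$normalization),
      p, digits = NA, auto_unbox = TRUE), eff_path)
    artifacts[c("normalized", "array_effects")] <<- list(norm_path, eff_path)
    es
  }

  load_normalized <- function() {
    path <- file.path(out_dir, "normalized.tsv")
    if (!file.exists(path)) {
      stop("missing input file: ", path, " (run the normalize stage first)")
    }
    read_experiment_set(path)
  }

  stage_diff <- function(es = load_normalized()) {
    tab <- differential_table(es, th)
    diff_path <- file.path(out_dir, "differential.tsv")
    atomic_write(function(p) utils::write.table(tab, p, sep = "\t",
                                                quote = FALSE,
                                                row.names = FALSE), diff_path)
    artifacts$differential <<- diff_path
    tab
  }

  stage_prioritize <- function(tab = NULL) {
    if (is.null(tab)) {
      path <- file.path(out_dir, "differential.tsv")
      if (!file.exists(path)) {
        stop("missing input file: ", path, " (run the diff stage first)")
      }
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    ann <- utils::read.delim(file.path(out_dir, "annotation.tsv"),
                             stringsAsFactors = FALSE)
    cfg <- fitsnp_config(config$prioritization$config,
                         der1 = th$der1, der2 = th$der2)
    cand <- suppressWarnings(fitsnp_prioritize(tab, ann, cfg))
    cand_path <- file.path(out_dir, "candidates.tsv")
    atomic_write(function(p) utils::write.table(cand, p, sep = "\t",
                                                quote = FALSE,
                                                row.names = FALSE), cand_path)
    artifacts$candidates <<- cand_path
  }

  stage_validate <- function() {
    path <- file.path(out_dir, "elisa.csv")
    if (!file.exists(path)) {
      stop("missing input file: ", path, " (run the simulate stage first)")
    }
    panel <- read_elisa_csv(path)
    report <- classify(panel, threshold = config$classifier$threshold)
    rep_path <- file.path(out_dir, "report.json")
    atomic_write(function(p) jsonlite::write_json(
      list(coefficients = as.list(report$model$coefficients),
           separation = report$model$separation,
           auc = report$auc, threshold = report$threshold,
           counts = list(tp = report$tp, fp = report$fp,
                         tn = report$tn, fn = report$fn),
           metrics = list(sensitivity = report$sensitivity,
                          specificity = report$specificity,
                          ppv = report$ppv, npv = report$npv,
                          accuracy = report$accuracy)),
      p, digits = NA, auto_unbox = TRUE), rep_path)
    labels <- as.integer(panel$samples$group == "case")
    ord <- order(report$probabilities, decreasing = TRUE)
    roc <- data.frame(
      threshold = report$probabilities[ord],
      tpr = cumsum(labels[ord]) / sum(labels),
      fpr = cumsum(1 - labels[ord]) / sum(1 - labels)
    )
    roc_path <- file.path(out_dir, "roc_points.tsv")
    atomic_write(function(p) utils::write.table(roc, p, sep = "\t",
                                                quote = FALSE,
                                                row.names = FALSE), roc_path)
    artifacts[c("report", "roc_points")] <<- list(rep_path, roc_path)
  }

  switch(command,
    simulate = stage_simulate(),
    normalize = stage_normalize(),
    diff = stage_diff(),
    prioritize = stage_prioritize(),
    validate = stage_validate(),
    all = {
      stage_simulate()
      es <- stage_normalize()
      tab <- stage_diff(es)
      stage_prioritize(tab)
      stage_validate()
    }
  )

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, digits = NA, auto_unbox = TRUE)
  flat <- unlist(artifacts, use.names = TRUE)
  manifest <- list(
    command = command,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = lapply(stats::setNames(as.list(flat), names(flat)),
                       function(p) list(path = p,
                                        md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(artifacts)
}
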