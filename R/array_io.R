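# Spot-level array import: GPR-subset parsing, background handling and
# assembly into a features x samples SummarizedExperiment.

GPR_REQUIRED_COLUMNS <- c("Name", "ID", "F635 Median", "B635 Median")

#' Read a GenePix-style results (GPR) file
#'
#' Parses the tab-delimited GPR dialect: any number of leading header lines
#' (free text or `key=value` pairs, possibly quoted), followed by a column
#' header row containing at least `Name`, `ID`, `F635 Median` and
#' `B635 Median`, followed by one row per spot. Unknown columns are ignored;
#' real GPR files carry ~50 of them and only the four required ones (plus
#' `Block`/`Column`/`Row` grid positions when present) are consumed.
#'
#' @param path Path to a GPR file.
#' @param sample_id Sample identifier for the scan; defaults to the file
#'   base name without extension.
#' @return An object of class `array_scan`: a list with `sample_id`,
#'   numeric vectors `foreground` and `background` (RFU, one entry per spot
#'   row in file order), a `features` data frame (`name`, `id`, and grid
#'   columns when present), and `header`, a named character vector of the
#'   `key=value` header lines.
#' @export
#' @examples
#' path <- system.file("extdata", "example.gpr", package = "seroscreen")
#' scan <- read_gpr(path)
#' head(scan$foreground)
read_gpr <- function(path, sample_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) {
    stop("GPR file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) {
    stop("GPR format error: file has no header and data section: ", path)
  }
  unquote <- function(x) gsub('^"|"$', "", x)
  split_fields <- function(line) unquote(strsplit(line, "\t", fixed = TRUE)[[1L]])

  header_row <- NA_integer_
  for (i in seq_along(lines)) {
    fields <- split_fields(lines[[i]])
    if (all(GPR_REQUIRED_COLUMNS %in% fields)) {
      header_row <- i
      break
    }
  }
  if (is.na(header_row)) {
    present <- unique(unlist(lapply(lines[seq_len(min(64L, length(lines)))],
                                    split_fields)))
    missing <- setdiff(GPR_REQUIRED_COLUMNS, present)
    stop("GPR format error: missing required column(s): ",
         paste(missing, collapse = ", "), " in ", path)
  }

  header_lines <- lines[seq_len(header_row - 1L)]
  kv <- grep("=", unquote(header_lines), fixed = TRUE, value = TRUE)
  header <- if (length(kv)) {
    keys <- sub("=.*$", "", kv)
    stats::setNames(sub("^[^=]*=", "", kv), keys)
  } else {
    stats::setNames(character(0), character(0))
  }

  cols <- split_fields(lines[[header_row]])
  body <- lines[seq.int(header_row + 1L, length(lines))]
  body <- body[nzchar(body)]
  if (!length(body)) {
    stop("GPR format error: no spot rows after column header in ", path)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  n_spot <- length(parts)
  get_col <- function(col) {
    idx <- match(col, cols)
    vapply(parts, function(p) if (idx <= length(p)) unquote(p[[idx]]) else NA_character_,
           character(1))
  }
  num_col <- function(col) {
    raw <- get_col(col)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad)) {
      stop("GPR format error in ", path, ", line ",
           header_row + bad[[1L]], ": non-numeric '", col, "' value '",
           raw[[bad[[1L]]]], "'")
    }
    val
  }

  features <- data.frame(
    name = get_col("Name"),
    id = get_col("ID"),
    stringsAsFactors = FALSE
  )
  for (grid in c("Block", "Column", "Row")) {
    if (grid %in% cols) features[[tolower(grid)]] <- num_col(grid)
  }

  structure(
    list(
      sample_id = sample_id,
      foreground = num_col("F635 Median"),
      background = num_col("B635 Median"),
      features = features,
      header = header,
      n_spots = n_spot
    ),
    class = "array_scan"
  )
}

#' Write a GPR-subset file
#'
#' Emits the tab-delimited dialect read back by [read_gpr()]: quoted
#' `key=value` header lines, a column header row, then one row per spot
#' with columns Block, Column, Row, Name, ID, F635 Median and B635 Median.
#'
#' @param scan An `array_scan` (or list with the same fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(scan, path) {
  ft <- scan$features
  n <- length(scan$foreground)
  blk <- if (!is.null(ft$block)) ft$block else rep(1L, n)
  col <- if (!is.null(ft$column)) ft$column else seq_len(n)
  row <- if (!is.null(ft$row)) ft$row else rep(1L, n)
  header <- scan$header
  if (is.null(header) || !length(header)) {
    header <- c(Type = "GenePix Results 3")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf('"%s=%s"', names(header), unname(header)), con)
  tab <- data.frame(
    Block = blk, Column = col, Row = row,
    Name = ft$name, ID = ft$id,
    `F635 Median` = scan$foreground, `B635 Median` = scan$background,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  suppressWarnings(utils::write.table(tab, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Subtract spot background from foreground signal
#'
#' Net signal is `max(foreground - background, floor)` elementwise. The
#' positive floor keeps the subsequent log2 transform defined for spots
#' whose local background exceeds the foreground.
#'
#' @param scan An `array_scan` from [read_gpr()].
#' @param floor Minimum net signal in RFU; must be positive.
#' @return The scan with a `net` field added (numeric, RFU).
#' @export
background_subtract <- function(scan, floor = 1) {
  stopifnot(inherits(scan, "array_scan"))
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    stop("floor must be a single positive number")
  }
  scan$net <- pmax(scan$foreground - scan$background, floor)
  scan
}

#' Merge background-subtracted scans into an experiment set
#'
#' Assembles one net-signal matrix (features x samples) from a list of
#' scans, validates it against the sample metadata, and returns a
#' [SummarizedExperiment::SummarizedExperiment] with assay `"net"`,
#' feature annotations in `rowData` and sample metadata in `colData`.
#' Column order follows the metadata row order. Duplicate spots printed
#' for the same feature (keyed on the spot `ID`) are collapsed according
#' to `collapse`.
#'
#' @param scans List of `array_scan` objects with `net` computed (see
#'   [background_subtract()]); raw `foreground` is used for any scan
#'   without a `net` field.
#' @param metadata Data frame with columns `sample_id`, `group`
#'   (`"case"`/`"control"`), and optionally `timepoint`
#'   (`"pre"`/`"post"`/`"na"`), `subject_id`, `age`, `sex`.
#' @param collapse How to collapse duplicate spots per feature:
#'   `"mean"` (default), `"median"` or `"first"`.
#' @param control_pattern Regular expression on feature ids marking
#'   normalization control spots (sets `is_control` in `rowData`).
#' @return A `SummarizedExperiment`.
#' @export
merge_scans <- function(scans, metadata, collapse = c("mean", "median", "first"),
                        control_pattern = "^CTRL") {
  collapse <- match.arg(collapse)
  if (!length(scans)) stop("no scans supplied")
  metadata <- validate_sample_metadata(metadata)
  n_spots <- vapply(scans, function(s) length(s$foreground), integer(1))
  if (length(unique(n_spots)) != 1L) {
    stop("dimension error: scans have unequal spot counts (",
         paste(unique(n_spots), collapse = ", "), ")")
  }
  ids <- vapply(scans, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("validation error: duplicate sample_id among scans: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  missing <- setdiff(metadata$sample_id, ids)
  if (length(missing)) {
    stop("validation error: metadata sample(s) with no scan: ",
         paste(missing, collapse = ", "))
  }
  scans <- scans[match(metadata$sample_id, ids)]

  values <- vapply(scans, function(s) {
    if (!is.null(s$net)) s$net else s$foreground
  }, numeric(n_spots[[1L]]))
  values <- matrix(values, nrow = n_spots[[1L]],
                   dimnames = list(NULL, metadata$sample_id))

  ft <- scans[[1L]]$features
  feature_id <- ft$id
  if (anyDuplicated(feature_id)) {
    agg <- switch(collapse,
      mean = rowsum(values, feature_id) / as.vector(table(feature_id)[unique(sort(feature_id))]),
      median = do.call(rbind, lapply(split(seq_along(feature_id), feature_id),
                                     function(i) apply(values[i, , drop = FALSE], 2, stats::median))),
      first = values[!duplicated(feature_id), , drop = FALSE]
    )
    if (collapse == "first") {
      keep <- !duplicated(feature_id)
      ft <- ft[keep, , drop = FALSE]
      values <- agg
      rownames(values) <- feature_id[keep]
    } else {
      # rowsum/split order is sorted by key; restore file order of first occurrence
      first_order <- unique(feature_id)
      values <- agg[first_order, , drop = FALSE]
      ft <- ft[!duplicated(feature_id), , drop = FALSE]
    }
    feature_id <- ft$id
  } else {
    rownames(values) <- feature_id
  }

  features <- data.frame(
    feature_id = feature_id,
    gene_symbol = if (!is.null(ft$gene_symbol)) ft$gene_symbol else ft$name,
    description = ft$name,
    is_control = grepl(control_pattern, feature_id),
    stringsAsFactors = FALSE
  )
  for (grid in c("block", "row", "column")) {
    if (!is.null(ft[[grid]])) features[[grid]] <- ft[[grid]]
  }
  experiment_set(values, features, metadata)
}

#' Construct an experiment set
#'
#' Low-level constructor validating matrix/annotation consistency and
#' returning a `SummarizedExperiment` with assay `"net"`.
#'
#' @param net Numeric matrix, features x samples, net signal in RFU.
#' @param features Data frame with at least `feature_id` (unique) and
#'   `is_control` (logical).
#' @param samples Data frame of sample metadata (see [merge_scans()]).
#' @return A `SummarizedExperiment`.
#' @export
experiment_set <- function(net, features, samples) {
  samples <- validate_sample_metadata(samples)
  if (!is.matrix(net) || !is.numeric(net)) stop("net must be a numeric matrix")
  if (nrow(net) != nrow(features)) {
    stop("dimension error: ", nrow(net), " matrix rows vs ",
         nrow(features), " features")
  }
  if (ncol(net) != nrow(samples)) {
    stop("dimension error: ", ncol(net), " matrix columns vs ",
         nrow(samples), " samples")
  }
  if (anyDuplicated(features$feature_id)) {
    stop("validation error: duplicate feature_id")
  }
  if (any(net < 0)) stop("validation error: negative net signal")
  rownames(net) <- features$feature_id
  colnames(net) <- samples$sample_id
  if (is.null(features$is_control)) features$is_control <- FALSE
  SummarizedExperiment::SummarizedExperiment(
    assays = list(net = net),
    rowData = features,
    colData = samples
  )
}

validate_sample_metadata <- function(metadata) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "group")
  missing <- setdiff(req, names(metadata))
  if (length(missing)) {
    stop("validation error: metadata lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("validation error: duplicate sample_id in metadata")
  }
  bad <- setdiff(unique(metadata$group), c("case", "control"))
  if (length(bad)) {
    stop("validation error: group must be 'case' or 'control', found: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(metadata$timepoint)) metadata$timepoint <- "na"
  bad_tp <- setdiff(unique(metadata$timepoint), c("pre", "post", "na"))
  if (length(bad_tp)) {
    stop("validation error: timepoint must be 'pre', 'post' or 'na', found: ",
         paste(bad_tp, collapse = ", "))
  }
  tp <- metadata$timepoint %in% c("pre", "post")
  if (any(tp) && is.null(metadata$subject_id)) {
    stop("validation error: pre/post samples require a subject_id column")
  }
  metadata
}

#' Read a sample metadata table
#'
#' @param path Tab-delimited file with columns `sample_id`, `group`, and
#'   optionally `timepoint`, `subject_id`, `age`, `sex`.
#' @return A validated data frame.
#' @export
read_sample_metadata <- function(path) {
  validate_sample_metadata(
    utils::read.delim(path, stringsAsFactors = FALSE)
  )
}

#' Serialize / deserialize an experiment set as TSV + JSON sidecar
#'
#' The signal matrix (one assay) is written as a TSV with features as rows
#' and samples as columns; feature annotations and sample metadata go to a
#' JSON sidecar next to it.
#'
#' @param es A `SummarizedExperiment`.
#' @param path Output TSV path; the sidecar is `<path>.json`.
#' @param assay Assay name to write (default first assay).
#' @return `path`, invisibly.
#' @export
write_experiment_set <- function(es, path, assay = SummarizedExperiment::assayNames(es)[[1L]]) {
  mat <- SummarizedExperiment::assay(es, assay)
  tab <- data.frame(feature_id = rownames(mat), mat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    assay = assay,
    features = as.data.frame(SummarizedExperiment::rowData(es)),
    samples = as.data.frame(SummarizedExperiment::colData(es))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_experiment_set
#' @export
read_experiment_set <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab$feature_id
  features <- as.data.frame(sidecar$features, stringsAsFactors = FALSE)
  samples <- as.data.frame(sidecar$samples, stringsAsFactors = FALSE)
  assays <- stats::setNames(list(mat), sidecar$assay)
  SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = features,
    colData = samples
  )
}
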