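#' Tabular formats for mutation data and models
#'
#' SNV tables are TSV/CSV with columns `sample_id`, `gene`, `effect`,
#' `strength`, `impact`.  Copy-number matrices are CSV/TSV with a `gene`
#' first column and one column per sample.  Models are versioned JSON with a
#' base64 payload of little-endian doubles, so a save/load round trip is
#' lossless at double precision.
#'
#' @name helr-io
#' @keywords internal
NULL

# closed category vocabularies (variant-effect-predictor style)
EFFECT_LEVELS <- c("deleterious", "deleterious_low_conf",
                   "tolerated_low_conf", "tolerated")
IMPACT_LEVELS <- c("high", "moderate", "modifier", "low")

norm_category <- function(x, levels, what, case_insensitive = TRUE) {
  x0 <- trimws(x)
  x1 <- if (case_insensitive) tolower(x0) else x0
  # tolerate VEP-style punctuation: "deleterious (low confidence)"
  x1 <- gsub("[ ()-]+", "_", x1)
  x1 <- gsub("_+", "_", x1)
  x1 <- sub("_$", "", x1)
  x1 <- sub("_confidence$", "_conf", x1)
  bad <- which(!(x1 %in% levels))
  if (length(bad) > 0)
    stop(sprintf("unknown %s category %s in row %d (expected one of: %s)",
                 what, dQuote(x0[bad[1]]), bad[1], paste(levels, collapse = ", ")))
  x1
}

#' Read a somatic SNV table
#'
#' One row per single-nucleotide variant: the carrying sample and gene, the
#' qualitative effect call (`deleterious`, `deleterious_low_conf`,
#' `tolerated_low_conf`, `tolerated`), the real-valued effect strength in
#' `[0, 1)`, and the impact-confidence class (`high`, `moderate`, `modifier`,
#' `low`).  A `(sample, gene)` pair may repeat: genes carry multiple SNVs.
#'
#' @param path TSV or CSV file (separator chosen by extension, or set
#'   `dialect$sep`).
#' @param dialect list of options: `sep` (field separator), and
#'   `case_insensitive` (default `TRUE`; category strings are matched after
#'   trimming and lowercasing, since VEP exports vary in case).
#' @return A data frame of validated SNV records.
#' @export
read_snv_table <- function(path, dialect = list()) {
  sep <- dialect$sep
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ci <- if (is.null(dialect$case_insensitive)) TRUE else isTRUE(dialect$case_insensitive)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("sample_id", "gene", "effect", "strength", "impact")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("SNV table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  snv_records(df$sample_id, df$gene, df$effect, df$strength, df$impact,
              case_insensitive = ci)
}

#' Construct validated SNV records
#'
#' @param sample_id,gene character vectors.
#' @param effect,impact category labels (see [read_snv_table()]).
#' @param strength numeric in `[0, 1)`.
#' @param case_insensitive normalize category case before matching.
#' @return A data frame of SNV records.
#' @export
snv_records <- function(sample_id, gene, effect, strength, impact,
                        case_insensitive = TRUE) {
  strength <- as.numeric(strength)
  bad <- which(!is.finite(strength) | strength < 0 | strength >= 1)
  if (length(bad) > 0)
    stop(sprintf("SNV strength %s in row %d is outside [0, 1)",
                 format(strength[bad[1]]), bad[1]))
  data.frame(
    sample_id = as.character(sample_id),
    gene = as.character(gene),
    effect = norm_category(effect, EFFECT_LEVELS, "effect", case_insensitive),
    strength = strength,
    impact = norm_category(impact, IMPACT_LEVELS, "impact", case_insensitive),
    stringsAsFactors = FALSE)
}

#' @rdname read_snv_table
#' @param snv a data frame of SNV records.
#' @export
write_snv_table <- function(snv, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(snv, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-by-sample copy-number matrix
#'
#' Expects a header row of sample identifiers and a first column named
#' `gene`.  Copy-number states are integers in `-2..2` (both copies deleted
#' through both copies duplicated).  Duplicated gene rows and non-integer or
#' out-of-range cells are rejected with their coordinates.
#'
#' @param path CSV or TSV file.
#' @return Integer matrix, genes in rows, samples in columns.
#' @export
read_cnv_matrix <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("copy-number file has no data: need a 'gene' column and sample columns")
  if (names(df)[1] != "gene") stop("first column of a copy-number matrix must be 'gene'")
  genes <- as.character(df$gene)
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0)
    stop("duplicated gene row(s) in copy-number matrix: ",
         paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(!is.finite(m) | m != floor(m) | m < -2 | m > 2, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("copy-number cell (gene %s, sample %s) = %s is not an integer in -2..2",
                 genes[bad[1, 1]], colnames(m)[bad[1, 2]],
                 format(df[bad[1, 1], bad[1, 2] + 1])))
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' @rdname read_cnv_matrix
#' @param cnv integer matrix as returned by `read_cnv_matrix`.
#' @export
write_cnv_matrix <- function(cnv, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(gene = rownames(cnv), cnv, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a patient cohort
#'
#' A cohort couples the per-patient somatic SNV records, the gene-by-sample
#' copy-number matrix, and the cancer-type labels (class ids `0..K-1`).
#' Every labeled sample must appear among the copy-number columns, and there
#' must be at least two classes.
#'
#' @param snv data frame of SNV records ([snv_records()]).
#' @param cnv_matrix integer gene-by-sample matrix.
#' @param labels named integer vector: class id per sample id.
#' @param class_names character vector naming classes `0..K-1`.
#' @param planted optional list of planted driver-gene sets (synthetic truth).
#' @return An object of class `"helr_cohort"`.
#' @export
cohort <- function(snv, cnv_matrix, labels, class_names, planted = NULL) {
  stopifnot(is.data.frame(snv), is.matrix(cnv_matrix))
  labels <- setNames(as.integer(labels), names(labels))
  K <- length(class_names)
  if (K < 2) stop("a cohort needs at least two classes")
  if (any(labels < 0 | labels >= K)) stop("labels must be class ids in 0..K-1")
  missing_samples <- setdiff(names(labels), colnames(cnv_matrix))
  if (length(missing_samples) > 0)
    stop("labeled sample(s) missing from the copy-number matrix: ",
         paste(utils::head(missing_samples, 5), collapse = ", "))
  structure(list(snv = snv, cnv_matrix = cnv_matrix, labels = labels,
                 class_names = as.character(class_names), planted = planted),
            class = "helr_cohort")
}

#' @export
print.helr_cohort <- function(x, ...) {
  cat(sprintf("Somatic-mutation cohort: %d samples, %d classes, %d SNV records, %d genes with CNV\n",
              length(x$labels), length(x$class_names), nrow(x$snv),
              nrow(x$cnv_matrix)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1,
                      labels = x$class_names))
  print(tab)
  invisible(x)
}

#' Write / read a cohort as a directory of plain-text files
#'
#' `snv.tsv`, `cnv.csv`, `labels.csv` and, when synthetic ground truth is
#' present, `truth.json` with the planted gene sets.
#'
#' @param x a `"helr_cohort"`.
#' @param dir directory (created if needed).
#' @return `write_cohort` the directory; `read_cohort` the cohort.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "helr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_snv_table(x$snv, file.path(dir, "snv.tsv"))
  write_cnv_matrix(x$cnv_matrix, file.path(dir, "cnv.csv"))
  utils::write.csv(
    data.frame(sample_id = names(x$labels), label = unname(x$labels),
               class_name = x$class_names[x$labels + 1]),
    file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(x$planted))
    writeLines(jsonlite::toJSON(x$planted), file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  snv <- read_snv_table(file.path(dir, "snv.tsv"))
  cnv <- read_cnv_matrix(file.path(dir, "cnv.csv"))
  lab <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  labels <- setNames(lab$label, lab$sample_id)
  class_names <- vapply(split(lab$class_name, lab$label), function(v) v[1], "")
  planted <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) planted <- jsonlite::fromJSON(tf)
  cohort(snv, cnv, labels, unname(class_names), planted = planted)
}

# ------------------------------------------------------------------ models

MODEL_FORMAT_VERSION <- 1L

b64_doubles <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                         size = 8, endian = "little"))
unb64_doubles <- function(s, n) {
  r <- jsonlite::base64_dec(s)
  if (length(r) != 8 * n) stop("model payload has the wrong length (truncated file?)")
  readBin(r, "numeric", n = n, size = 8, endian = "little")
}

#' Save or load a trained linear model
#'
#' Models are stored as versioned JSON: class and feature names in clear
#' text, weights and biases as base64-encoded little-endian doubles, so the
#' round trip is lossless at double precision and the file stays
#' human-inspectable.  A version mismatch or truncated payload is rejected.
#'
#' @param model a `"helr_model"` (see [train_multiclass_lr()]).
#' @param path JSON file path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "helr_model"))
  obj <- list(
    version = MODEL_FORMAT_VERSION,
    class_names = model$class_names,
    feature_names = model$feature_names,
    weights = b64_doubles(t(model$weights)),   # row-major K x f
    bias = b64_doubles(model$bias),
    lambda_l1 = model$lambda_l1,
    folds = model$folds,
    seed = model$seed)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e)))
  if (is.null(obj$version) || obj$version != MODEL_FORMAT_VERSION)
    stop(sprintf("unsupported model format version %s (expected %d)",
                 format(obj$version), MODEL_FORMAT_VERSION))
  K <- length(obj$class_names)
  f <- length(obj$feature_names)
  W <- matrix(unb64_doubles(obj$weights, K * f), K, f, byrow = TRUE,
              dimnames = list(obj$class_names, obj$feature_names))
  helr_model(weights = W, bias = unb64_doubles(obj$bias, K),
             lambda_l1 = obj$lambda_l1, class_names = obj$class_names,
             feature_names = obj$feature_names,
             folds = obj$folds, seed = obj$seed)
}
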