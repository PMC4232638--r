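#' Construct a raw variant/call table
#'
#' A raw call table couples one record per single nucleotide variant (SNV)
#' with, for each predictor, the predictor's raw output category and/or
#' numeric score. It is the input to harmonization
#' (see [build_call_matrix()]).
#'
#' @param variants A data frame with columns `variant_id`, `gene`,
#'   `gene_class` (`oncogene`, `tsg` or `new_cancer_gene`), `truth_label`
#'   (`non_neutral`, `neutral` or `uncertain`) and logical `in_cosmic`.
#' @param raw A character matrix (variants x predictors) of raw predictor
#'   categories; `NA` marks a missing category.
#' @param score A numeric matrix of the same shape holding raw scores;
#'   `NA` marks a missing score. May be `NULL` if no predictor reports
#'   scores.
#'
#' @return An object of class `raw_call_table` with elements `variants`,
#'   `raw`, `score` and `predictors` (the predictor names, in column
#'   order).
#' @export
raw_call_table <- function(variants, raw, score = NULL) {
  stopifnot(is.data.frame(variants), is.matrix(raw))
  required <- c("variant_id", "gene", "gene_class", "truth_label", "in_cosmic")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variants is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(variants$variant_id)) {
    dup <- variants$variant_id[duplicated(variants$variant_id)][1L]
    stop("duplicate variant_id: ", dup)
  }
  bad <- !variants$truth_label %in% TRUTH_LEVELS
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("row %d (%s): unknown truth_label '%s'",
                 i, variants$variant_id[i], variants$truth_label[i]))
  }
  bad_class <- !variants$gene_class %in% GENE_CLASS_LEVELS
  if (any(bad_class)) {
    i <- which(bad_class)[1L]
    stop(sprintf("row %d (%s): unknown gene_class '%s'",
                 i, variants$variant_id[i], variants$gene_class[i]))
  }
  if (nrow(raw) != nrow(variants)) {
    stop("raw matrix must have one row per variant")
  }
  if (is.null(colnames(raw)) || anyDuplicated(colnames(raw))) {
    stop("raw matrix needs unique predictor column names")
  }
  if (is.null(score)) {
    score <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  }
  stopifnot(identical(dim(score), dim(raw)))
  dimnames(score) <- dimnames(raw)
  rownames(raw) <- rownames(score) <- variants$variant_id
  structure(
    list(variants = variants, raw = raw, score = score,
         predictors = colnames(raw)),
    class = "raw_call_table"
  )
}

#' @export
print.raw_call_table <- function(x, ...) {
  cat(sprintf("raw_call_table: %d variants x %d predictors\n",
              nrow(x$variants), length(x$predictors)))
  cat("truth labels:",
      paste(sprintf("%s=%d", names(table(x$variants$truth_label)),
                    table(x$variants$truth_label)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a tab-delimited variant/call table
#'
#' Parses a TSV file with one row per SNV into a [raw_call_table()]. The
#' column layout is configured through `schema`, because supplementary
#' tables from different sources name their columns differently.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param schema A list naming the file's columns:
#'   `variant_id`, `gene`, `gene_class`, `truth`, `cosmic`, plus
#'   `predictors`, a named list mapping each predictor name to
#'   `list(raw = <column>, score = <column or NULL>)`. Either of
#'   `raw`/`score` may be omitted per predictor. Defaults to
#'   [default_schema()].
#'
#' @return A `raw_call_table`. Columns of the file claimed by neither the
#'   core schema nor a predictor are ignored with a warning.
#' @export
read_variant_call_table <- function(path, schema = default_schema()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  core <- c(variant_id = schema$variant_id, gene = schema$gene,
            gene_class = schema$gene_class, truth = schema$truth,
            cosmic = schema$cosmic)
  missing_core <- core[!core %in% names(df)]
  if (length(missing_core)) {
    stop("file lacks schema column(s): ", paste(missing_core, collapse = ", "))
  }
  preds <- schema$predictors
  if (is.null(preds) || !length(preds)) {
    stop("schema$predictors must name at least one predictor column")
  }
  pred_cols <- unlist(lapply(preds, function(p) c(p$raw, p$score)))
  missing_pred <- setdiff(pred_cols, names(df))
  if (length(missing_pred)) {
    stop("file lacks predictor column(s): ",
         paste(missing_pred, collapse = ", "))
  }
  extra <- setdiff(names(df), c(core, pred_cols))
  if (length(extra)) {
    warning("ignoring unrecognised column(s): ", paste(extra, collapse = ", "))
  }

  variants <- data.frame(
    variant_id = as.character(df[[core[["variant_id"]]]]),
    gene = as.character(df[[core[["gene"]]]]),
    gene_class = as.character(df[[core[["gene_class"]]]]),
    truth_label = as.character(df[[core[["truth"]]]]),
    in_cosmic = as.logical(df[[core[["cosmic"]]]]),
    stringsAsFactors = FALSE
  )
  n <- nrow(variants)
  raw <- matrix(NA_character_, n, length(preds),
                dimnames = list(NULL, names(preds)))
  score <- matrix(NA_real_, n, length(preds),
                  dimnames = list(NULL, names(preds)))
  for (nm in names(preds)) {
    p <- preds[[nm]]
    if (!is.null(p$raw)) raw[, nm] <- as.character(df[[p$raw]])
    if (!is.null(p$score)) score[, nm] <- as.numeric(df[[p$score]])
  }
  raw_call_table(variants, raw, score)
}

#' @rdname read_variant_call_table
#' @param predictors Character vector of predictor names used to build the
#'   default schema, whose file columns are `<name>_call` and
#'   `<name>_score`.
#' @export
default_schema <- function(predictors = character()) {
  preds <- stats::setNames(lapply(predictors, function(nm) {
    list(raw = paste0(nm, "_call"), score = paste0(nm, "_score"))
  }), predictors)
  list(variant_id = "variant_id", gene = "gene", gene_class = "gene_class",
       truth = "truth_label", cosmic = "in_cosmic", predictors = preds)
}

#' Write a raw call table to TSV
#'
#' The written file round-trips through [read_variant_call_table()] with
#' the matching schema.
#'
#' @param table A `raw_call_table`.
#' @param path Output path.
#' @return Invisibly, the schema that reads the file back.
#' @export
write_variant_call_table <- function(table, path) {
  stopifnot(inherits(table, "raw_call_table"))
  df <- table$variants
  for (nm in table$predictors) {
    df[[paste0(nm, "_call")]] <- table$raw[, nm]
    df[[paste0(nm, "_score")]] <- table$score[, nm]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(default_schema(table$predictors))
}

#' Construct a predictor cross-tabulation
#'
#' A cross-tab records, for one predictor, how many variants of each truth
#' class (neutral / non-neutral / uncertain) fell into each of the
#' predictor's raw prediction classes.
#'
#' @param predictor Predictor name.
#' @param classes A data frame with columns `class`, `n_neutral`,
#'   `n_non_neutral`, `n_uncertain`.
#' @return An object of class `cross_tab`.
#' @export
cross_tab <- function(predictor, classes) {
  stopifnot(is.data.frame(classes),
            all(c("class", "n_neutral", "n_non_neutral", "n_uncertain") %in%
                  names(classes)))
  counts <- as.matrix(classes[, c("n_neutral", "n_non_neutral", "n_uncertain")])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cross_tab counts must be non-negative integers")
  }
  structure(list(predictor = predictor, classes = classes),
            class = "cross_tab")
}

#' @export
print.cross_tab <- function(x, ...) {
  cat("cross_tab:", x$predictor, "\n")
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Benchmark cross-tabulations for the 15 reference predictors
#'
#' Loads the published cross-tabulations of 3,591 functionally annotated
#' SNVs (140 neutral, 849 non-neutral, 2,602 uncertain) against the raw
#' prediction classes of 15 mutation effect predictors. These counts are
#' shipped with the package as a plain TSV resource and are the basis of
#' the package's regression tests: all headline performance statistics are
#' recomputable from them.
#'
#' @return A named list of 15 [cross_tab()] objects, one per predictor.
#' @export
load_benchmark_crosstabs <- function() {
  path <- system.file("extdata", "predictor_crosstabs.tsv",
                      package = "mepbench", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  out <- lapply(split(df, factor(df$predictor, levels = unique(df$predictor))),
                function(d) {
                  cross_tab(d$predictor[1L],
                            d[, c("class", "n_neutral", "n_non_neutral",
                                  "n_uncertain")])
                })
  # Defensive check of the shipped fixture: every predictor classified the
  # same cohort, so per-class totals must agree.
  for (ct in out) {
    tot <- colSums(ct$classes[, c("n_neutral", "n_non_neutral", "n_uncertain")])
    if (!identical(unname(tot), c(140, 849, 2602))) {
      stop("corrupt cross-tab fixture for ", ct$predictor)
    }
  }
  out
}

# Column names rendered as percentages (2 dp) by write_table(): the
# percentage-scale columns produced by performance_table(). All other
# numeric columns are rendered to 4 dp (kappa, composite, distances and
# proportion-scale evaluation columns).
.percent_col_pattern <-
  "^(accuracy|sensitivity|specificity|ppv|npv)(_lo|_hi)?$"

#' Write a rectangular result table to TSV
#'
#' Numeric formatting follows the conventions used throughout the package
#' output: percentage-scale metric columns (accuracy, sensitivity,
#' specificity, PPV, NPV and their CI bounds) are written with 2 decimal
#' places; all other non-integer numeric columns (composite scores, kappa
#' values, distances) with 4 decimal places.
#'
#' @param records A data frame (an empty one yields a header-only file).
#' @param path Output path.
#' @return Invisibly, the formatted data frame that was written.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.numeric(col) && !is.integer(col)) {
      digits <- if (grepl(.percent_col_pattern, nm, ignore.case = TRUE)) 2L else 4L
      out[[nm]] <- formatC(col, format = "f", digits = digits)
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
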