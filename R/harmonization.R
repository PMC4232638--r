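#' Define how one predictor's raw output maps to harmonized calls
#'
#' A predictor spec captures everything needed to turn a predictor's raw
#' output into the harmonized vocabulary `non_neutral` / `neutral` /
#' `equivocal`, plus the optional low-confidence rule used in
#' three-category mode:
#' \itemize{
#'   \item `category_map` translates raw output categories (matched
#'     case-insensitively) into harmonized calls;
#'   \item `score_rule` classifies numeric scores: direction `"le"` means
#'     scores at or below `cutoff` are called non-neutral, `"ge"` means at
#'     or above (both cutoffs are inclusive on the calling side);
#'   \item `low_conf_band` is a closed score interval inside which a
#'     prediction is considered low-confidence;
#'   \item `low_conf_categories` are raw categories considered
#'     low-confidence outright (e.g. a predictor's own "possibly
#'     damaging" or "no-call" classes).
#' }
#'
#' @param name Predictor name.
#' @param kind `"single"` for an independent predictor, `"meta"` for a
#'   consensus predictor built from other predictors' scores.
#' @param category_map Named character vector, raw category -> one of
#'   `non_neutral`, `neutral`, `equivocal`. May be empty when a
#'   `score_rule` is given.
#' @param score_rule `list(direction = "le"|"ge", cutoff = <number>)` or
#'   `NULL`.
#' @param low_conf_band Length-2 numeric `c(lo, hi)` with `lo <= hi`, or
#'   `NULL`.
#' @param low_conf_categories Character vector of raw categories, or
#'   `NULL`.
#' @param score_range Plausible support of the score, used only when
#'   simulating scores (see [simulate_scores()]).
#'
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(name, kind = c("single", "meta"),
                           category_map = character(),
                           score_rule = NULL,
                           low_conf_band = NULL,
                           low_conf_categories = NULL,
                           score_range = NULL) {
  kind <- match.arg(kind)
  if (!length(category_map) && is.null(score_rule)) {
    stop("predictor '", name, "': needs a category_map or a score_rule")
  }
  if (length(category_map)) {
    stopifnot(!is.null(names(category_map)))
    if (!all(category_map %in% c("non_neutral", "neutral", "equivocal"))) {
      stop("category_map values must be non_neutral, neutral or equivocal")
    }
    names(category_map) <- norm_category(names(category_map))
  }
  if (!is.null(score_rule)) {
    stopifnot(score_rule$direction %in% c("le", "ge"),
              is.numeric(score_rule$cutoff))
  }
  if (!is.null(low_conf_band)) {
    stopifnot(length(low_conf_band) == 2L, low_conf_band[1] <= low_conf_band[2])
  }
  if (!is.null(low_conf_categories)) {
    low_conf_categories <- norm_category(low_conf_categories)
  }
  structure(
    list(name = name, kind = kind, category_map = category_map,
         score_rule = score_rule, low_conf_band = low_conf_band,
         low_conf_categories = low_conf_categories,
         score_range = score_range),
    class = "predictor_spec"
  )
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat(sprintf("predictor_spec: %s (%s)\n", x$name, x$kind))
  if (length(x$category_map)) {
    cat("  categories:",
        paste(sprintf("%s->%s", names(x$category_map), x$category_map),
              collapse = ", "), "\n")
  }
  if (!is.null(x$score_rule)) {
    cat(sprintf("  score rule: non-neutral when score %s %g\n",
                ifelse(x$score_rule$direction == "le", "<=", ">="),
                x$score_rule$cutoff))
  }
  if (!is.null(x$low_conf_band)) {
    cat(sprintf("  low-confidence band: [%g, %g]\n",
                x$low_conf_band[1], x$low_conf_band[2]))
  }
  if (!is.null(x$low_conf_categories)) {
    cat("  low-confidence categories:",
        paste(x$low_conf_categories, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reference specs for the 15 benchmark predictors
#'
#' Returns the harmonization rules for the 15 predictors of the benchmark
#' panel: 11 single predictors (three tissue-specific CHASM classifiers,
#' two FATHMM tools, Mutation Assessor, MutationTaster, PolyPhen-2,
#' PROVEAN, SIFT, VEST) and 4 meta-predictors (three tissue-specific
#' CanDrA classifiers and Condel).
#'
#' Category merging follows the published defaults of each tool:
#' damaging/functional/driver/deleterious-style classes map to
#' non-neutral; tolerated/neutral/passenger/benign-style classes map to
#' neutral; CanDrA "no-call", Mutation Assessor "N/A" and FATHMM
#' (missense) "No weights" are equivocal. Score cutoffs are the tools'
#' default thresholds (CHASM <= 0.3, VEST >= 0.5, PROVEAN <= -2.5,
#' SIFT <= 0.05, FATHMM cancer <= -0.75), inclusive on the calling side.
#' Low-confidence bands: CHASM 0.25-0.35, FATHMM (cancer) -1.65-0.1,
#' FATHMM (missense) -2.5-0, MutationTaster probability <= 0.95 (the
#' score column must carry the probability), PROVEAN -4.1 to -1.3,
#' SIFT 0.04-0.1, VEST 0.45-0.55, Condel 0.489-0.547; PolyPhen-2
#' "possibly damaging", Mutation Assessor "low" and CanDrA "no-call" are
#' low-confidence by category.
#'
#' @return A named list of [predictor_spec()] objects.
#' @export
default_predictor_specs <- function() {
  chasm_map <- c("driver" = "non_neutral", "passenger" = "neutral")
  candra_map <- c("driver" = "non_neutral", "passenger" = "neutral",
                  "no-call" = "equivocal")
  specs <- list(
    predictor_spec("CHASM (breast)", "single", chasm_map,
                   score_rule = list(direction = "le", cutoff = 0.3),
                   low_conf_band = c(0.25, 0.35), score_range = c(0, 1)),
    predictor_spec("CHASM (lung)", "single", chasm_map,
                   score_rule = list(direction = "le", cutoff = 0.3),
                   low_conf_band = c(0.25, 0.35), score_range = c(0, 1)),
    predictor_spec("CHASM (melanoma)", "single", chasm_map,
                   score_rule = list(direction = "le", cutoff = 0.3),
                   low_conf_band = c(0.25, 0.35), score_range = c(0, 1)),
    predictor_spec("FATHMM (cancer)", "single",
                   c("cancer" = "non_neutral", "passenger/other" = "neutral"),
                   score_rule = list(direction = "le", cutoff = -0.75),
                   low_conf_band = c(-1.65, 0.1), score_range = c(-10, 10)),
    predictor_spec("FATHMM (missense)", "single",
                   c("damaging" = "non_neutral", "tolerated" = "neutral",
                     "no weights" = "equivocal"),
                   low_conf_band = c(-2.5, 0), score_range = c(-10, 10)),
    predictor_spec("Mutation Assessor", "single",
                   c("high" = "non_neutral", "medium" = "non_neutral",
                     "low" = "neutral", "neutral" = "neutral",
                     "n/a" = "equivocal"),
                   low_conf_categories = "low"),
    predictor_spec("MutationTaster", "single",
                   c("disease_causing" = "non_neutral",
                     "disease_causing_automatic" = "non_neutral",
                     "polymorphism" = "neutral",
                     "polymorphism_automatic" = "neutral"),
                   low_conf_band = c(0, 0.95), score_range = c(0, 1)),
    predictor_spec("PolyPhen-2", "single",
                   c("probably damaging" = "non_neutral",
                     "possibly damaging" = "non_neutral",
                     "benign" = "neutral"),
                   low_conf_categories = "possibly damaging"),
    predictor_spec("PROVEAN", "single",
                   c("deleterious" = "non_neutral", "neutral" = "neutral"),
                   score_rule = list(direction = "le", cutoff = -2.5),
                   low_conf_band = c(-4.1, -1.3), score_range = c(-14, 14)),
    predictor_spec("SIFT", "single",
                   c("damaging" = "non_neutral", "tolerated" = "neutral"),
                   score_rule = list(direction = "le", cutoff = 0.05),
                   low_conf_band = c(0.04, 0.1), score_range = c(0, 1)),
    predictor_spec("VEST", "single",
                   c("functional" = "non_neutral", "neutral" = "neutral"),
                   score_rule = list(direction = "ge", cutoff = 0.5),
                   low_conf_band = c(0.45, 0.55), score_range = c(0, 1)),
    predictor_spec("CanDrA (breast)", "meta", candra_map,
                   low_conf_categories = "no-call"),
    predictor_spec("CanDrA (lung)", "meta", candra_map,
                   low_conf_categories = "no-call"),
    predictor_spec("CanDrA (melanoma)", "meta", candra_map,
                   low_conf_categories = "no-call"),
    predictor_spec("Condel", "meta",
                   c("deleterious" = "non_neutral", "neutral" = "neutral"),
                   low_conf_band = c(0.489, 0.547), score_range = c(0, 1))
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Names of the single (non-meta) predictors in a spec list
#'
#' @param specs A list of [predictor_spec()] objects.
#' @return Character vector of predictor names with `kind == "single"`.
#' @export
single_predictors <- function(specs = default_predictor_specs()) {
  names(specs)[vapply(specs, `[[`, "", "kind") == "single"]
}

# Vectorised binary harmonization of one predictor column.
# Returns a character vector over CALL_LEVELS[1:3].
harmonize_column_binary <- function(spec, raw, score) {
  n <- length(raw)
  out <- rep(NA_character_, n)
  key <- norm_category(raw)
  key[is.na(raw)] <- NA_character_
  mapped <- !is.na(key) & key %in% names(spec$category_map)
  out[mapped] <- unname(spec$category_map[key[mapped]])
  todo <- is.na(out)
  has_score <- !is.na(score)
  # Unmapped raw category with no usable score path is a hard error.
  unmapped <- todo & !is.na(raw) &
    (is.null(spec$score_rule) | !has_score)
  if (any(unmapped)) {
    i <- which(unmapped)[1L]
    stop(sprintf("predictor '%s': raw category '%s' is not in the category map",
                 spec$name, raw[i]))
  }
  if (!is.null(spec$score_rule)) {
    use <- todo & has_score
    hit <- if (spec$score_rule$direction == "le") {
      score[use] <= spec$score_rule$cutoff
    } else {
      score[use] >= spec$score_rule$cutoff
    }
    out[use] <- ifelse(hit, "non_neutral", "neutral")
  }
  out
}

#' Harmonize a single predictor output into a binary call
#'
#' Maps one raw category and/or score to `non_neutral`, `neutral` or
#' `equivocal` under a predictor's [predictor_spec()]. A mapped raw
#' category takes precedence over the score; the score rule is consulted
#' when the category is missing or unmapped.
#'
#' @param spec A `predictor_spec`.
#' @param raw Raw output category, or `NA`/`NULL` if absent.
#' @param score Numeric score, or `NA`/`NULL` if absent.
#' @return A length-1 character call.
#' @examples
#' specs <- default_predictor_specs()
#' harmonize_call(specs[["PolyPhen-2"]], raw = "possibly damaging")
#' harmonize_call(specs[["CHASM (breast)"]], score = 0.30)
#' @export
harmonize_call <- function(spec, raw = NULL, score = NULL) {
  stopifnot(inherits(spec, "predictor_spec"))
  raw <- if (is.null(raw)) NA_character_ else as.character(raw)
  score <- if (is.null(score)) NA_real_ else as.numeric(score)
  if (is.na(raw) && is.na(score)) {
    stop("predictor '", spec$name, "': neither raw category nor score given")
  }
  harmonize_column_binary(spec, raw, score)
}

#' Harmonize with a low-confidence category (three-category mode)
#'
#' As [harmonize_call()], but returns `low_confidence` when the score
#' falls inside the spec's low-confidence band (closed interval) or the
#' raw category belongs to the spec's low-confidence category set.
#' Equivocal raw categories stay equivocal.
#'
#' @inheritParams harmonize_call
#' @return A length-1 character call over all four categories.
#' @examples
#' specs <- default_predictor_specs()
#' harmonize_with_confidence(specs[["PROVEAN"]], score = -2.0)
#' harmonize_with_confidence(specs[["SIFT"]], score = 0.005)
#' @export
harmonize_with_confidence <- function(spec, raw = NULL, score = NULL) {
  stopifnot(inherits(spec, "predictor_spec"))
  raw <- if (is.null(raw)) NA_character_ else as.character(raw)
  score <- if (is.null(score)) NA_real_ else as.numeric(score)
  if (is.na(raw) && is.na(score)) {
    stop("predictor '", spec$name, "': neither raw category nor score given")
  }
  harmonize_column_confidence(spec, raw, score)
}

# Vectorised three-category harmonization of one predictor column.
harmonize_column_confidence <- function(spec, raw, score) {
  out <- harmonize_column_binary(spec, raw, score)
  key <- norm_category(raw)
  # A pre-specified low-confidence category wins outright (this includes
  # classes that are equivocal in binary mode, e.g. CanDrA "no-call").
  if (!is.null(spec$low_conf_categories)) {
    hit <- !is.na(raw) & key %in% spec$low_conf_categories
    out[hit] <- "low_confidence"
  }
  # Score bands only reclassify definite (non-equivocal) calls.
  if (!is.null(spec$low_conf_band)) {
    hit <- out %in% c("non_neutral", "neutral") & !is.na(score) &
      score >= spec$low_conf_band[1] & score <= spec$low_conf_band[2]
    out[hit] <- "low_confidence"
  }
  out
}

#' Build a harmonized call matrix from a raw table
#'
#' Applies each predictor's harmonization rules cell-wise. Cells with
#' neither a raw category nor a score become `equivocal`; the number of
#' such cells is reported in a message.
#'
#' @param table A [raw_call_table()].
#' @param specs A named list of [predictor_spec()] objects; every spec
#'   must have a matching column in `table`.
#' @param mode `"binary"` (calls are non-neutral / neutral / equivocal) or
#'   `"three_category"` (adds low-confidence).
#' @return An object of class `call_matrix`: a list with `variants` (the
#'   variant records), `calls` (character matrix, variants x predictors),
#'   `specs` and `mode`.
#' @export
build_call_matrix <- function(table, specs = default_predictor_specs(),
                              mode = c("binary", "three_category")) {
  stopifnot(inherits(table, "raw_call_table"))
  mode <- match.arg(mode)
  missing_preds <- setdiff(names(specs), table$predictors)
  if (length(missing_preds)) {
    stop("table lacks predictor column(s): ",
         paste(missing_preds, collapse = ", "))
  }
  n <- nrow(table$variants)
  calls <- matrix(NA_character_, n, length(specs),
                  dimnames = list(table$variants$variant_id, names(specs)))
  n_blank <- 0L
  for (nm in names(specs)) {
    raw <- table$raw[, nm]
    score <- table$score[, nm]
    blank <- is.na(raw) & is.na(score)
    n_blank <- n_blank + sum(blank)
    col <- rep("equivocal", n)
    if (any(!blank)) {
      col[!blank] <- if (mode == "binary") {
        harmonize_column_binary(specs[[nm]], raw[!blank], score[!blank])
      } else {
        harmonize_column_confidence(specs[[nm]], raw[!blank], score[!blank])
      }
    }
    calls[, nm] <- col
  }
  if (n_blank > 0L) {
    message(n_blank, " cell(s) had neither category nor score; called equivocal")
  }
  structure(
    list(variants = table$variants, calls = calls, specs = specs, mode = mode),
    class = "call_matrix"
  )
}

#' Construct a call matrix directly from harmonized calls
#'
#' Mainly useful in tests and simulations where harmonized calls are
#' already available.
#'
#' @param variants Variant record data frame (see [raw_call_table()]).
#' @param calls Character matrix of harmonized calls with predictor
#'   column names.
#' @param mode Call vocabulary mode.
#' @param specs Optional predictor specs to attach.
#' @return A `call_matrix`.
#' @export
call_matrix <- function(variants, calls,
                        mode = c("binary", "three_category"), specs = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(calls), nrow(calls) == nrow(variants),
            !is.null(colnames(calls)))
  allowed <- if (mode == "binary") CALL_LEVELS[1:3] else CALL_LEVELS
  if (!all(calls %in% allowed)) {
    stop("calls contain values outside the ", mode, " vocabulary")
  }
  rownames(calls) <- variants$variant_id
  structure(list(variants = variants, calls = calls, specs = specs,
                 mode = mode),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("call_matrix (%s): %d variants x %d predictors\n",
              x$mode, nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

#' Variants called low-confidence by a majority of predictors
#'
#' Returns the variants that at least `threshold` predictors flagged as
#' low-confidence, the convention used to identify SNVs whose discordant
#' predictions mostly reflect unreliable calls.
#'
#' @param matrix A three-category [call_matrix()].
#' @param threshold Minimum number of low-confidence calls (default 8,
#'   a majority of a 15-predictor panel).
#' @return Character vector of `variant_id`s.
#' @export
majority_low_confidence <- function(matrix, threshold = 8L) {
  stopifnot(inherits(matrix, "call_matrix"))
  if (matrix$mode != "three_category") {
    stop("majority_low_confidence() needs a three-category call matrix")
  }
  n_lc <- rowSums(matrix$calls == "low_confidence")
  matrix$variants$variant_id[n_lc >= threshold]
}
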