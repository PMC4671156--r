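# Criterion objects and the table-level ranking pipeline.

FN_SHAPES <- c("high", "low", "central", "ends", "categorical", "sigmoid")

#' Define a selection criterion
#'
#' Binds a column of a feature table to a desirability mapping function
#' and an importance weight. The resulting objects are applied to a
#' table with [apply_criteria()] or [rank_genes()].
#'
#' Cut points for the numeric shapes can be given directly (`cuts`) or
#' as quantile probabilities (`cuts_quantiles`), in which case they are
#' resolved against the table column at application time — the "top q%
#' of the distribution gets maximum desirability" idiom.
#'
#' @param name Short label for the criterion (used for the `d_<name>`
#'   output column).
#' @param column Name of the feature-table column the criterion reads.
#' @param fn Mapping-function shape: one of `"high"`, `"low"`,
#'   `"central"`, `"ends"`, `"categorical"`, `"sigmoid"`.
#' @param cuts Numeric cut points in data units: length 2 for
#'   `"high"`/`"low"`, length 4 for `"central"`/`"ends"`.
#' @param cuts_quantiles Alternative to `cuts`: quantile probabilities
#'   of the data column to use as cut points.
#' @param mapping Named numeric vector for `fn = "categorical"`.
#' @param default Default desirability for unmapped categories
#'   (`NULL`: unmapped labels are an error).
#' @param midpoint,steepness Parameters for `fn = "sigmoid"`.
#' @param des_min,des_max Desirability band, see [d_high()].
#' @param scale Curvature exponent, see [d_high()].
#' @param weight Non-negative importance weight of this criterion in
#'   the overall desirability.
#' @return An object of class `"criterion"`.
#' @examples
#' criterion("p_value", column = "p_value", fn = "low",
#'           cuts = c(1e-4, 0.1), weight = 1)
#' criterion("annotated", column = "annotated", fn = "categorical",
#'           mapping = c(yes = 1, no = 0.2), weight = 1)
#' @export
criterion <- function(name, column, fn = FN_SHAPES,
                      cuts = NULL, cuts_quantiles = NULL,
                      mapping = NULL, default = NULL,
                      midpoint = NULL, steepness = NULL,
                      des_min = 0, des_max = 1, scale = 1, weight = 1) {
  fn <- match.arg(fn)
  if (!is.character(name) || length(name) != 1L || is.na(name) || name == "")
    stop("'name' must be a non-empty string", call. = FALSE)
  if (!is.character(column) || length(column) != 1L || is.na(column) ||
      column == "")
    stop("criterion '", name, "': 'column' must be a non-empty string",
         call. = FALSE)
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight < 0)
    stop("criterion '", name, "': 'weight' must be a finite number >= 0",
         call. = FALSE)
  check_band(des_min, des_max)
  check_scale(scale)

  n_cuts <- switch(fn, high = 2L, low = 2L, central = 4L, ends = 4L, 0L)
  if (n_cuts > 0L) {
    if (is.null(cuts) && is.null(cuts_quantiles))
      stop("criterion '", name, "' (", fn, "): supply 'cuts' or ",
           "'cuts_quantiles'", call. = FALSE)
    if (!is.null(cuts) && !is.null(cuts_quantiles))
      stop("criterion '", name, "': give only one of 'cuts' and ",
           "'cuts_quantiles'", call. = FALSE)
    if (!is.null(cuts)) {
      if (length(cuts) != n_cuts)
        stop("criterion '", name, "' (", fn, "): expected ", n_cuts,
             " cut points, got ", length(cuts), call. = FALSE)
      check_cuts(cuts)
    } else {
      if (length(cuts_quantiles) != n_cuts)
        stop("criterion '", name, "' (", fn, "): expected ", n_cuts,
             " quantile probabilities, got ", length(cuts_quantiles),
             call. = FALSE)
      if (any(is.na(cuts_quantiles)) || any(cuts_quantiles < 0) ||
          any(cuts_quantiles > 1) || is.unsorted(cuts_quantiles))
        stop("criterion '", name, "': 'cuts_quantiles' must be ",
             "non-decreasing probabilities in [0, 1]", call. = FALSE)
    }
  }
  if (fn == "categorical") {
    if (is.null(mapping))
      stop("criterion '", name, "' (categorical): supply 'mapping'",
           call. = FALSE)
    if (is.null(names(mapping)) || !is.numeric(mapping) ||
        any(is.na(mapping)) || any(mapping < 0) || any(mapping > 1))
      stop("criterion '", name, "': 'mapping' must be a named numeric ",
           "vector with values in [0, 1]", call. = FALSE)
  }
  if (fn == "sigmoid") {
    if (is.null(midpoint) || is.null(steepness))
      stop("criterion '", name, "' (sigmoid): supply 'midpoint' and ",
           "'steepness'", call. = FALSE)
    if (!is.numeric(steepness) || length(steepness) != 1L ||
        is.na(steepness) || steepness == 0)
      stop("criterion '", name, "': 'steepness' must be non-zero",
           call. = FALSE)
  }

  structure(list(name = name, column = column, fn = fn, cuts = cuts,
                 cuts_quantiles = cuts_quantiles, mapping = mapping,
                 default = default, midpoint = midpoint,
                 steepness = steepness, des_min = des_min,
                 des_max = des_max, scale = scale, weight = weight),
            class = "criterion")
}

#' @export
print.criterion <- function(x, ...) {
  cuts <- if (!is.null(x$cuts)) {
    paste0("cuts = [", paste(format(x$cuts, digits = 4), collapse = ", "), "]")
  } else if (!is.null(x$cuts_quantiles)) {
    paste0("cut quantiles = [",
           paste(format(x$cuts_quantiles), collapse = ", "), "]")
  } else if (x$fn == "categorical") {
    paste0("mapping = {",
           paste(names(x$mapping), x$mapping, sep = ": ", collapse = ", "),
           "}")
  } else {
    paste0("midpoint = ", format(x$midpoint),
           ", steepness = ", format(x$steepness))
  }
  cat(sprintf("criterion '%s': %s(%s) on column '%s', d in [%g, %g], weight %g\n",
              x$name, x$fn, cuts, x$column, x$des_min, x$des_max, x$weight))
  invisible(x)
}

criteria_names <- function(criteria) {
  vapply(criteria, function(cr) cr$name, character(1))
}

criteria_weights <- function(criteria) {
  vapply(criteria, function(cr) cr$weight, numeric(1))
}

check_criteria <- function(criteria) {
  if (inherits(criteria, "criterion")) criteria <- list(criteria)
  if (!is.list(criteria) || length(criteria) == 0L ||
      !all(vapply(criteria, inherits, logical(1), "criterion")))
    stop("'criteria' must be a non-empty list of criterion objects",
         call. = FALSE)
  nm <- criteria_names(criteria)
  if (anyDuplicated(nm))
    stop("duplicate criterion names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  criteria
}

resolve_cuts <- function(cr, x) {
  if (is.null(cr$cuts_quantiles)) return(cr)
  cr$cuts <- quantile_cuts(as.numeric(x), cr$cuts_quantiles)
  cr$cuts_quantiles <- NULL
  cr
}

apply_one_criterion <- function(cr, x) {
  if (cr$fn == "categorical") {
    if (is.numeric(x) && !all(is.na(x)))
      stop("criterion '", cr$name, "': categorical function applied to ",
           "numeric column '", cr$column, "'", call. = FALSE)
    return(d_cat(x, cr$mapping, cr$default))
  }
  if (!is.numeric(x))
    stop("criterion '", cr$name, "': column '", cr$column,
         "' is not numeric", call. = FALSE)
  cr <- resolve_cuts(cr, x)
  switch(cr$fn,
    high = d_high(x, cr$cuts[1], cr$cuts[2], cr$des_min, cr$des_max, cr$scale),
    low = d_low(x, cr$cuts[1], cr$cuts[2], cr$des_min, cr$des_max, cr$scale),
    central = d_central(x, cr$cuts[1], cr$cuts[2], cr$cuts[3], cr$cuts[4],
                        cr$des_min, cr$des_max, cr$scale),
    ends = d_ends(x, cr$cuts[1], cr$cuts[2], cr$cuts[3], cr$cuts[4],
                  cr$des_min, cr$des_max, cr$scale),
    sigmoid = d_sigmoid(x, cr$midpoint, cr$steepness, cr$des_min, cr$des_max))
}

#' Apply selection criteria to a feature table
#'
#' Maps each criterion's column through its desirability function,
#' producing a desirability matrix with one `d_<name>` column per
#' criterion, row-aligned with the input table. Missing data values
#' give missing desirabilities (resolved later by weight
#' renormalisation in [d_overall()], never silently treated as zero).
#'
#' @param table Data frame of per-feature statistics.
#' @param criteria List of [criterion()] objects (a single criterion is
#'   also accepted).
#' @return Data frame of desirabilities with columns `d_<name>`.
#' @examples
#' tab <- data.frame(p_value = c(1e-5, 0.01, 0.5))
#' apply_criteria(tab, list(
#'   criterion("p", "p_value", "low", cuts = c(1e-4, 0.1))
#' ))
#' @export
apply_criteria <- function(table, criteria) {
  criteria <- check_criteria(criteria)
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("'table' must be a non-empty data frame", call. = FALSE)
  cols <- vapply(criteria, function(cr) cr$column, character(1))
  missing_cols <- setdiff(unique(cols), names(table))
  if (length(missing_cols) > 0L)
    stop("criteria reference column(s) absent from the table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d <- lapply(criteria, function(cr) apply_one_criterion(cr, table[[cr$column]]))
  names(d) <- paste0("d_", criteria_names(criteria))
  as.data.frame(d, optional = TRUE)
}

#' Rank features from a desirability matrix
#'
#' Computes the overall desirability per feature with [d_overall()] and
#' ranks features by decreasing overall desirability, breaking ties by
#' feature ID so the ordering is deterministic and reproducible.
#'
#' @param d_matrix Matrix or data frame of per-criterion desirabilities
#'   (one row per feature).
#' @param weights Non-negative criterion weights.
#' @param feature_id Character vector of unique feature IDs, one per
#'   row (default: row numbers).
#' @return Data frame with `feature_id`, the desirability columns,
#'   `Overall_D`, `evidence_count` (number of observed, positively
#'   weighted criteria) and `rank`, sorted by rank.
#' @seealso [rank_genes()] for the table-level interface.
#' @export
rank_features <- function(d_matrix, weights,
                          feature_id = as.character(seq_len(nrow(d_matrix)))) {
  m <- as.matrix(d_matrix)
  feature_id <- as.character(feature_id)
  if (length(feature_id) != nrow(m) || anyDuplicated(feature_id) ||
      any(is.na(feature_id)))
    stop("'feature_id' must be unique, non-missing, one per row",
         call. = FALSE)
  D <- d_overall(m, weights)
  evidence <- as.integer(rowSums(!is.na(m[, weights > 0, drop = FALSE])))
  ord <- order(-D, feature_id, na.last = TRUE)
  out <- data.frame(feature_id = feature_id[ord], stringsAsFactors = FALSE)
  dm <- as.data.frame(m, optional = TRUE)
  out <- cbind(out, dm[ord, , drop = FALSE])
  out$Overall_D <- D[ord]
  out$evidence_count <- evidence[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank a feature table by overall desirability
#'
#' The main pipeline entry point: applies the criteria to the table,
#' combines the per-criterion desirabilities into an overall
#' desirability (weighted geometric mean, with the weights taken from
#' the criteria), and returns the table sorted by decreasing overall
#' desirability. Ties are broken by feature ID.
#'
#' @param table Data frame of per-feature statistics.
#' @param criteria List of [criterion()] objects.
#' @param id_col Name of the feature-ID column of `table`; IDs must be
#'   unique and non-missing.
#' @param comparison Optional name of a numeric column to rank features
#'   by as a baseline for comparison (e.g. the p-value column); adds a
#'   `comparison_rank` column computed with [comparison_rank()].
#' @param comparison_ascending Sort direction for the comparison
#'   column.
#' @return Data frame: all input columns, one `d_<name>` column per
#'   criterion, `Overall_D`, `evidence_count`, `rank` and optionally
#'   `comparison_rank`, sorted by `rank`.
#' @examples
#' tab <- data.frame(feature_id = c("a", "b", "c"),
#'                   p_value = c(1e-5, 0.01, 0.5),
#'                   logFC = c(2, -1.5, 0.1))
#' crit <- list(
#'   criterion("p", "p_value", "low", cuts = c(1e-4, 0.1), weight = 1),
#'   criterion("fc", "logFC", "ends", cuts = c(-1, -0.5, 0.5, 1), weight = 1)
#' )
#' rank_genes(tab, crit)
#' @export
rank_genes <- function(table, criteria, id_col = "feature_id",
                       comparison = NULL, comparison_ascending = TRUE) {
  criteria <- check_criteria(criteria)
  if (!is.data.frame(table))
    stop("'table' must be a data frame", call. = FALSE)
  if (!id_col %in% names(table))
    stop("feature-ID column '", id_col, "' not found in the table",
         call. = FALSE)
  ids <- as.character(table[[id_col]])
  if (any(is.na(ids)) || any(ids == "") || anyDuplicated(ids))
    stop("feature IDs in '", id_col, "' must be unique and non-missing",
         call. = FALSE)

  dmat <- apply_criteria(table, criteria)
  w <- criteria_weights(criteria)
  D <- d_overall(dmat, w)
  evidence <- as.integer(rowSums(!is.na(dmat[, w > 0, drop = FALSE])))

  out <- cbind(table, dmat)
  out$Overall_D <- D
  out$evidence_count <- evidence
  if (!is.null(comparison))
    out$comparison_rank <- comparison_rank(table, comparison,
                                           ascending = comparison_ascending)
  ord <- order(-D, ids, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "criteria") <- criteria
  out
}

#' Select top features from a ranked table
#'
#' Subsets a ranked table either to features whose overall desirability
#' strictly exceeds a threshold, or to the top `k` features. Exactly
#' one of `threshold` and `k` must be given; `k` larger than the table
#' returns the whole table.
#'
#' @param ranked Data frame with an `Overall_D` column, as returned by
#'   [rank_genes()] or [rank_features()], sorted by rank.
#' @param threshold Desirability threshold in \[0, 1\]; rows with
#'   `Overall_D > threshold` (strict) are kept.
#' @param k Positive integer: keep the top `k` rows.
#' @return The selected subset, original order preserved.
#' @examples
#' ranked <- data.frame(feature_id = c("a", "b", "c"),
#'                      Overall_D = c(0.9, 0.7, 0.5))
#' select_top(ranked, threshold = 0.7)
#' select_top(ranked, k = 2)
#' @export
select_top <- function(ranked, threshold = NULL, k = NULL) {
  if (!is.data.frame(ranked) || !"Overall_D" %in% names(ranked))
    stop("'ranked' must be a data frame with an 'Overall_D' column",
         call. = FALSE)
  if (is.null(threshold) == is.null(k))
    stop("give exactly one of 'threshold' and 'k'", call. = FALSE)
  if (!is.null(threshold)) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        is.na(threshold) || threshold < 0 || threshold > 1)
      stop("'threshold' must be a single number in [0, 1]", call. = FALSE)
    keep <- !is.na(ranked$Overall_D) & ranked$Overall_D > threshold
    return(ranked[keep, , drop = FALSE])
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 ||
      k != floor(k))
    stop("'k' must be a single positive integer", call. = FALSE)
  utils::head(ranked, n = k)
}

#' Baseline rank by a single column
#'
#' Ranks features by one numeric column (e.g. the p-value), optionally
#' after removing features with prefilters — the conventional
#' single-statistic ranking used as a point of comparison for the
#' desirability ranking. Filtered-out features receive a missing rank
#' and the survivors are ranked among themselves. Ties share the
#' smallest rank (`ties.method = "min"`).
#'
#' @param table Data frame of per-feature statistics.
#' @param column Name of the numeric column to rank by.
#' @param ascending If `TRUE` (default) the smallest value gets rank 1.
#' @param prefilter Optional prefilters applied before ranking: a
#'   logical keep-vector of `nrow(table)`, or a list of predicate
#'   functions, each taking the table and returning a logical
#'   keep-vector (e.g. `function(t) t$AveExpr >= 6`). Rows must pass
#'   every predicate to be ranked; `NA` predicate values drop the row.
#' @return Integer vector of ranks aligned with the table rows, `NA`
#'   for filtered-out rows or missing values.
#' @examples
#' tab <- data.frame(p = c(0.01, 0.001, 0.1), AveExpr = c(7, 8, 4))
#' comparison_rank(tab, "p")
#' comparison_rank(tab, "p", prefilter = list(function(t) t$AveExpr >= 6))
#' @export
comparison_rank <- function(table, column, ascending = TRUE,
                            prefilter = NULL) {
  if (!is.data.frame(table))
    stop("'table' must be a data frame", call. = FALSE)
  if (!column %in% names(table))
    stop("comparison column '", column, "' not found in the table",
         call. = FALSE)
  x <- table[[column]]
  if (!is.numeric(x))
    stop("comparison column '", column, "' is not numeric", call. = FALSE)

  keep <- rep(TRUE, nrow(table))
  if (!is.null(prefilter)) {
    preds <- if (is.logical(prefilter)) list(prefilter) else prefilter
    if (!is.list(preds))
      stop("'prefilter' must be a logical vector or a list of predicates",
           call. = FALSE)
    for (p in preds) {
      v <- if (is.function(p)) p(table) else p
      if (!is.logical(v) || length(v) != nrow(table))
        stop("each prefilter must yield a logical vector with one value ",
             "per row", call. = FALSE)
      v[is.na(v)] <- FALSE
      keep <- keep & v
    }
  }
  r <- rep(NA_integer_, nrow(table))
  xs <- x[keep]
  if (!ascending) xs <- -xs
  r[keep] <- as.integer(rank(xs, ties.method = "min", na.last = "keep"))
  r
}

#' Joint power of independent comparisons
#'
#' The probability that an effect is detected in all of `n`
#' independent comparisons, each with the same power: `power^n`. This
#' quantifies why hard per-comparison significance thresholds combined
#' with Venn-diagram intersection accumulate false negatives — with
#' power 0.7 per comparison, three comparisons jointly detect a gene
#' with probability only 0.7^3 = 0.343 — and motivates continuous
#' desirability scoring instead.
#'
#' @param power Per-comparison power in \[0, 1\].
#' @param n Number of independent comparisons.
#' @return `power^n`.
#' @examples
#' joint_power(0.7, 3)
#' @export
joint_power <- function(power, n) {
  if (any(power < 0 | power > 1, na.rm = TRUE))
    stop("'power' must lie in [0, 1]", call. = FALSE)
  if (any(n < 0, na.rm = TRUE))
    stop("'n' must be non-negative", call. = FALSE)
  power^n
}

#' Fold change from a log fold-change
#'
#' Back-transforms a log fold-change to the linear scale, e.g. a log2
#' fold-change of 1.41 is a 2^1.41 = 2.66-fold change.
#'
#' @param logfc Numeric log fold-change(s).
#' @param base Logarithm base (default 2).
#' @return `base^logfc`.
#' @examples
#' fold_change(1.41)
#' @export
fold_change <- function(logfc, base = 2) {
  if (any(base <= 0, na.rm = TRUE))
    stop("'base' must be positive", call. = FALSE)
  base^logfc
}
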