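# Side-by-side validation report for a user-prepared study table.

#' Validation report for a prepared differential-expression table
#'
#' Re-runs the published-style analysis on a user-prepared
#' differential-expression table (for example the basal-vs-luminal
#' breast-cancer comparison prepared from GEO accession GDS1329 with
#' the usual moderated-test preprocessing, which this package does not
#' perform) and reports the headline counts and the top of the ranked
#' list for side-by-side comparison:
#' the number of features passing an FDR cut-off, the number removed
#' by the low-expression / low-variance prefilters, the number whose
#' overall desirability exceeds the selection threshold, and the top
#' rows of the desirability-ranked table with their p-value-only
#' ranks.
#'
#' @param table Data frame with at least the columns referenced by the
#'   criteria, the feature-ID column, and (for the FDR count) an
#'   adjusted-p-value column.
#' @param criteria List of [criterion()] objects, e.g. from the
#'   shipped preset via [read_criteria_config()].
#' @param id_col Feature-ID column name.
#' @param fdr_col Name of the adjusted-p-value (FDR) column, or `NULL`
#'   to skip the FDR count.
#' @param fdr_cutoff FDR cut-off for the DE count (default 0.05).
#' @param threshold Overall-desirability selection threshold
#'   (default 0.7).
#' @param comparison_col Column for the baseline p-value ranking.
#' @param prefilter Prefilters for the baseline ranking, as in
#'   [comparison_rank()]; default: mean expression >= 6 and standard
#'   deviation >= 0.25 when columns named `AveExpr` and `SD` exist.
#' @param top_n Number of top rows to include in the report.
#' @return A list with `n_de_fdr`, `n_prefiltered`, `n_selected`,
#'   `threshold` and `top` (the top rows with desirabilities, overall
#'   D and comparison rank).
#' @export
validate_prepared_table <- function(table, criteria, id_col = "feature_id",
                                    fdr_col = NULL, fdr_cutoff = 0.05,
                                    threshold = 0.7,
                                    comparison_col = "p_value",
                                    prefilter = NULL, top_n = 10L) {
  criteria <- check_criteria(criteria)
  if (!is.data.frame(table))
    stop("'table' must be a data frame", call. = FALSE)
  needed <- unique(c(id_col, comparison_col,
                     vapply(criteria, function(cr) cr$column, character(1))))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0L)
    stop("required column(s) missing from the table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  if (is.null(prefilter)) {
    prefilter <- list()
    if ("AveExpr" %in% names(table))
      prefilter <- c(prefilter, list(function(t) t$AveExpr >= 6))
    if ("SD" %in% names(table))
      prefilter <- c(prefilter, list(function(t) t$SD >= 0.25))
  }

  n_de_fdr <- if (!is.null(fdr_col)) {
    if (!fdr_col %in% names(table))
      stop("FDR column '", fdr_col, "' not found in the table",
           call. = FALSE)
    sum(table[[fdr_col]] < fdr_cutoff, na.rm = TRUE)
  } else NA_integer_

  cmp <- comparison_rank(table, comparison_col, ascending = TRUE,
                         prefilter = if (length(prefilter)) prefilter)
  n_prefiltered <- sum(is.na(cmp) & !is.na(table[[comparison_col]]))

  ranked <- rank_genes(table, criteria, id_col = id_col)
  ranked$comparison_rank <- cmp[match(ranked[[id_col]], table[[id_col]])]
  n_selected <- nrow(select_top(ranked, threshold = threshold))

  list(n_de_fdr = n_de_fdr, n_prefiltered = n_prefiltered,
       n_selected = n_selected, threshold = threshold,
       top = utils::head(ranked, top_n))
}
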