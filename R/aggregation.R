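# Combining per-criterion desirabilities into an overall desirability.

check_weights <- function(weights, n = NULL) {
  if (!is.numeric(weights) || length(weights) == 0L)
    stop("weights must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(weights)))
    stop("weights must all be finite", call. = FALSE)
  if (any(weights < 0))
    stop("weights must be non-negative", call. = FALSE)
  if (all(weights == 0))
    stop("at least one weight must be positive", call. = FALSE)
  if (!is.null(n) && length(weights) != n)
    stop("expected ", n, " weights, got ", length(weights), call. = FALSE)
  invisible(NULL)
}

#' Overall desirability: weighted geometric mean
#'
#' Combines per-criterion desirabilities \eqn{d_i} with importance
#' weights \eqn{w_i} into the overall desirability
#' \deqn{D = \exp\left(\frac{\sum_i w_i \ln d_i}{\sum_i w_i}\right),}
#' the weighted geometric mean. Only the weight ratios matter: weights
#' (2, 1), (20, 10) and (1, 0.5) are equivalent. If any contributing
#' desirability is exactly zero the overall desirability is zero — an
#' unacceptable value on one criterion cannot be compensated by the
#' others. A zero weight switches a criterion off entirely, even when
#' its desirability is zero. Missing desirabilities are excluded and
#' the remaining weights renormalised, so the observed criteria keep
#' their relative importance; a feature with no observed criteria gets
#' a missing overall desirability.
#'
#' @param d Numeric vector of desirabilities in \[0, 1\] (one feature),
#'   or a matrix / data frame with one row per feature and one column
#'   per criterion. `NA` marks a missing criterion value.
#' @param weights Non-negative importance weights, one per criterion,
#'   at least one positive.
#' @return A single overall desirability in \[0, 1\] (or `NA`) for a
#'   vector input; a numeric vector with one value per row for a
#'   matrix / data frame input.
#' @examples
#' d_overall(c(0.25, 1), weights = c(1, 1))        # sqrt(0.25) = 0.5
#' d_overall(c(0, 0.9, 1), weights = c(1, 1, 1))   # zero propagates
#' d_overall(rbind(c(0.5, NA), c(0.5, 1)), weights = c(1, 3))
#' @export
d_overall <- function(d, weights) {
  vec <- is.null(dim(d))
  m <- if (vec) matrix(as.numeric(d), nrow = 1L) else as.matrix(d)
  if (!is.numeric(m))
    stop("desirabilities must be numeric", call. = FALSE)
  check_weights(weights, ncol(m))
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("desirabilities must lie in [0, 1]", call. = FALSE)

  # zero-weight criteria are switched off before anything else, so that
  # d = 0 with w = 0 never zeroes the result
  active <- weights > 0
  m <- m[, active, drop = FALSE]
  w <- weights[active]

  obs <- !is.na(m)
  wsum <- as.vector(obs %*% w)
  has_zero <- as.vector((obs & m == 0) %*% rep(1, ncol(m))) > 0

  logm <- suppressWarnings(log(m))
  logm[!obs | m == 0] <- 0  # zeros handled by short-circuit, not ln(0)
  D <- exp(as.vector(logm %*% w) / wsum)
  D <- pmin(pmax(D, 0), 1)
  D[has_zero] <- 0
  D[wsum == 0] <- NA_real_
  if (vec) D[1L] else D
}

#' Renormalised weights over observed criteria
#'
#' Missing criteria are given weight zero and the remaining weights are
#' rescaled to sum to one, preserving their pairwise ratios — criteria
#' with missing values do not influence the ranking and the observed
#' criteria keep their relative importance.
#'
#' @param weights Non-negative weights, at least one positive.
#' @param missing Logical vector marking criteria with missing values.
#' @return Numeric vector of the same length as `weights`, summing to
#'   one over the observed criteria, zero elsewhere.
#' @examples
#' effective_weights(c(1, 1, 2), missing = c(FALSE, FALSE, FALSE))
#' effective_weights(c(1, 1, 2), missing = c(FALSE, FALSE, TRUE))
#' @export
effective_weights <- function(weights, missing = rep(FALSE, length(weights))) {
  check_weights(weights)
  if (!is.logical(missing) || length(missing) != length(weights) ||
      any(is.na(missing)))
    stop("'missing' must be a logical vector matching the weights",
         call. = FALSE)
  w <- weights
  w[missing] <- 0
  s <- sum(w)
  if (s == 0)
    stop("all observed criteria have zero weight", call. = FALSE)
  w / s
}

#' Fuse experiment-level desirabilities into a second-level ranking
#'
#' Combines overall desirabilities from several experiments (e.g. a
#' microarray and a proteomics study of the same contrast) into a
#' second-level overall desirability per feature, using experiment
#' weights that reflect each study's relevance, importance, or quality.
#' Features are matched by ID with an outer join; a feature absent from
#' an experiment is treated as missing there, so its second-level value
#' uses only the experiments in which it was observed (same
#' renormalisation rule as [d_overall()]). An evidence-count column
#' records in how many experiments each feature was observed.
#'
#' @param experiments A named list of experiment-level results. Each
#'   element is either a named numeric vector of overall desirabilities
#'   (names are feature IDs) or a data frame with the feature-ID column
#'   named by `id_col` and an `Overall_D` column (as returned by
#'   [rank_genes()]).
#' @param weights Non-negative experiment weights, one per experiment
#'   (default: equal). At least one must be positive.
#' @param id_col Name of the feature-ID column for data-frame inputs.
#' @return A data frame sorted by decreasing second-level desirability
#'   with columns: the feature ID, one `D_<experiment>` column per
#'   experiment, `Overall_D`, `evidence_count` and `rank`. Ties are
#'   broken by feature ID.
#' @examples
#' fuse_experiments(list(
#'   array = c(g1 = 0.9, g2 = 0.5),
#'   proteome = c(g1 = 0.8, g3 = 0.7)
#' ), weights = c(2, 1))
#' @export
fuse_experiments <- function(experiments, weights = NULL,
                             id_col = "feature_id") {
  if (!is.list(experiments) || length(experiments) == 0L)
    stop("'experiments' must be a non-empty list", call. = FALSE)
  if (is.null(names(experiments)) || any(names(experiments) == ""))
    names(experiments) <- paste0("exp", seq_along(experiments))
  if (is.null(weights)) weights <- rep(1, length(experiments))
  check_weights(weights, length(experiments))

  as_dvec <- function(e, label) {
    if (is.data.frame(e)) {
      if (!id_col %in% names(e))
        stop("experiment '", label, "' has no '", id_col, "' column",
             call. = FALSE)
      if (!"Overall_D" %in% names(e))
        stop("experiment '", label, "' has no 'Overall_D' column",
             call. = FALSE)
      stats::setNames(e$Overall_D, as.character(e[[id_col]]))
    } else if (is.numeric(e) && !is.null(names(e))) {
      e
    } else {
      stop("experiment '", label,
           "' must be a named numeric vector or a data frame", call. = FALSE)
    }
  }
  dvecs <- Map(as_dvec, experiments, names(experiments))
  ids <- sort(unique(unlist(lapply(dvecs, names), use.names = FALSE)))
  dm <- vapply(dvecs, function(v) unname(v[ids]), numeric(length(ids)))
  dm <- matrix(dm, nrow = length(ids),
               dimnames = list(ids, names(experiments)))

  D <- d_overall(dm, weights)
  evidence <- rowSums(!is.na(dm))
  ord <- order(-D, ids, na.last = TRUE)
  out <- data.frame(ids[ord], stringsAsFactors = FALSE)
  names(out) <- id_col
  for (j in seq_len(ncol(dm)))
    out[[paste0("D_", colnames(dm)[j])]] <- dm[ord, j]
  out$Overall_D <- D[ord]
  out$evidence_count <- as.integer(evidence[ord])
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
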