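# Rank-stability analysis under perturbation of cut points and weights.

#' Define a perturbation plan
#'
#' Describes which criterion parameters to jitter, by how much, and how
#' many Monte Carlo draws to take. Each target row names a criterion, a
#' parameter and a perturbation magnitude; on every draw each targeted
#' parameter is independently perturbed by a uniform amount within its
#' magnitude. Weights (and other scale-free parameters) are usually
#' perturbed relatively, cut points absolutely in data units.
#'
#' @param targets Data frame with columns `criterion` (criterion name),
#'   `parameter` (one of `"cut1"`..`"cut4"`, `"cuts"` for all cut
#'   points at once, `"weight"`, `"des_min"`, `"des_max"`, `"scale"`,
#'   `"midpoint"`, `"steepness"`), `amount` (non-negative magnitude)
#'   and `type` (`"absolute"`: parameter + U(-a, a); `"relative"`:
#'   parameter * (1 + U(-a, a))).
#' @param n_draws Number of perturbation draws, >= 1.
#' @param seed Integer seed; the whole analysis is reproducible given
#'   the seed.
#' @return An object of class `"perturbation_plan"`.
#' @seealso [default_plan()] to build a plan covering every criterion,
#'   [perturb_and_rank()] to run it.
#' @export
perturbation_plan <- function(targets, n_draws = 50L, seed = 1L) {
  if (!is.data.frame(targets) ||
      !all(c("criterion", "parameter", "amount", "type") %in% names(targets)))
    stop("'targets' must be a data frame with columns criterion, ",
         "parameter, amount, type", call. = FALSE)
  ok_par <- c("cut1", "cut2", "cut3", "cut4", "cuts", "weight", "des_min",
              "des_max", "scale", "midpoint", "steepness")
  bad <- setdiff(unique(targets$parameter), ok_par)
  if (length(bad) > 0L)
    stop("unknown parameter(s) in plan: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(targets$type %in% c("absolute", "relative")))
    stop("perturbation 'type' must be 'absolute' or 'relative'",
         call. = FALSE)
  if (any(!is.finite(targets$amount)) || any(targets$amount < 0))
    stop("perturbation amounts must be finite and non-negative",
         call. = FALSE)
  if (!is.numeric(n_draws) || length(n_draws) != 1L || is.na(n_draws) ||
      n_draws < 1)
    stop("'n_draws' must be a positive integer", call. = FALSE)
  structure(list(targets = targets, n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "perturbation_plan")
}

#' Default perturbation plan over all criteria
#'
#' Builds a plan that jitters every criterion's weight relatively and
#' every cut point absolutely, the absolute magnitude being a fraction
#' of the criterion's cut-point span (or of `max(1, |cut|)` for a
#' degenerate span), so the perturbation is commensurate with the data
#' scale of each criterion.
#'
#' @param criteria List of [criterion()] objects.
#' @param rel Relative magnitude for weights and the cut-span fraction
#'   for cut points (default 0.1, i.e. +/-10%).
#' @param n_draws,seed Passed to [perturbation_plan()].
#' @return A `"perturbation_plan"`.
#' @export
default_plan <- function(criteria, rel = 0.1, n_draws = 50L, seed = 1L) {
  criteria <- check_criteria(criteria)
  rows <- lapply(criteria, function(cr) {
    out <- data.frame(criterion = cr$name, parameter = "weight",
                      amount = rel, type = "relative",
                      stringsAsFactors = FALSE)
    if (!is.null(cr$cuts)) {
      span <- diff(range(cr$cuts))
      if (span == 0) span <- max(1, abs(cr$cuts[1]))
      out <- rbind(out, data.frame(criterion = cr$name, parameter = "cuts",
                                   amount = rel * span, type = "absolute",
                                   stringsAsFactors = FALSE))
    }
    out
  })
  perturbation_plan(do.call(rbind, rows), n_draws = n_draws, seed = seed)
}

perturb_value <- function(value, amount, type) {
  if (amount == 0 || is.null(value)) return(value)
  u <- stats::runif(length(value), -amount, amount)
  if (type == "relative") value * (1 + u) else value + u
}

# Apply one plan row to a criterion; returns list(criterion, repaired)
perturb_criterion <- function(cr, parameter, amount, type) {
  repaired <- FALSE
  if (parameter == "cuts") {
    cr$cuts <- perturb_value(cr$cuts, amount, type)
  } else if (parameter %in% c("cut1", "cut2", "cut3", "cut4")) {
    i <- match(parameter, c("cut1", "cut2", "cut3", "cut4"))
    if (!is.null(cr$cuts) && i <= length(cr$cuts))
      cr$cuts[i] <- perturb_value(cr$cuts[i], amount, type)
  } else {
    cr[[parameter]] <- perturb_value(cr[[parameter]], amount, type)
  }
  # repair invalid draws instead of discarding them (discarding would
  # bias coverage toward the interior of the perturbation box)
  if (!is.null(cr$cuts) && is.unsorted(cr$cuts)) {
    cr$cuts <- sort(cr$cuts); repaired <- TRUE
  }
  if (cr$weight < 0) { cr$weight <- 0; repaired <- TRUE }
  if (cr$des_min < 0) { cr$des_min <- 0; repaired <- TRUE }
  if (cr$des_max > 1) { cr$des_max <- 1; repaired <- TRUE }
  if (cr$des_min > cr$des_max) {
    cr$des_min <- cr$des_max; repaired <- TRUE
  }
  if (!is.null(cr$scale) && cr$scale <= 0) {
    cr$scale <- .Machine$double.eps; repaired <- TRUE
  }
  if (!is.null(cr$steepness) && cr$steepness == 0) {
    cr$steepness <- .Machine$double.eps; repaired <- TRUE
  }
  list(criterion = cr, repaired = repaired)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Rank stability under parameter perturbation
#'
#' Recomputes the ranking under random perturbations of cut points and
#' weights and summarises how stable the result is: the top-k overlap
#' (Jaccard index) and the Spearman rank correlation between each
#' perturbed ranking and the baseline, plus how often each feature is
#' selected into the top k across draws. Cut-point quantiles in the
#' criteria are resolved against the table once, before perturbation,
#' so the perturbation acts on concrete cut values.
#'
#' Draws whose perturbed parameters violate a spec invariant (cut
#' points out of order, negative weight, desirability band outside
#' \[0, 1\]) are repaired — cuts re-sorted, values clamped — and
#' counted in `n_repaired`.
#'
#' @param table Data frame of per-feature statistics.
#' @param criteria List of [criterion()] objects (the baseline).
#' @param plan A [perturbation_plan()] or [default_plan()].
#' @param k Top-list size for the overlap statistics. Default: the
#'   baseline selection size at `threshold`, or 50 if that selection
#'   is empty.
#' @param threshold Selection threshold used to derive the default `k`
#'   (default 0.7).
#' @param id_col Feature-ID column name.
#' @return An object of class `"stability_report"`: a list with
#'   `jaccard` and `rank_cor` (one value per draw), `selection_freq`
#'   (named, per feature, in \[0, 1\]), `k`, `n_draws`, `baseline_top`
#'   (feature IDs of the baseline top k) and `n_repaired`.
#' @examples
#' tab <- data.frame(feature_id = paste0("g", 1:20),
#'                   p_value = runif(20), logFC = rnorm(20))
#' crit <- list(
#'   criterion("p", "p_value", "low", cuts = c(0.01, 0.5), weight = 1),
#'   criterion("fc", "logFC", "ends", cuts = c(-1, -0.5, 0.5, 1), weight = 1)
#' )
#' perturb_and_rank(tab, crit, default_plan(crit, n_draws = 5), k = 5)
#' @export
perturb_and_rank <- function(table, criteria, plan, k = NULL,
                             threshold = 0.7, id_col = "feature_id") {
  criteria <- check_criteria(criteria)
  if (!inherits(plan, "perturbation_plan"))
    stop("'plan' must be a perturbation_plan", call. = FALSE)
  unknown <- setdiff(unique(plan$targets$criterion), criteria_names(criteria))
  if (length(unknown) > 0L)
    stop("plan targets unknown criteria: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  # freeze quantile-derived cuts so perturbations act on concrete values
  criteria <- lapply(criteria, function(cr) {
    if (!is.null(cr$cuts_quantiles)) resolve_cuts(cr, table[[cr$column]])
    else cr
  })

  baseline <- rank_genes(table, criteria, id_col = id_col)
  n <- nrow(baseline)
  if (is.null(k)) {
    k <- nrow(select_top(baseline, threshold = threshold))
    if (k == 0L) k <- min(50L, n)
  }
  k <- min(as.integer(k), n)
  base_top <- baseline[[id_col]][seq_len(k)]
  base_rank <- stats::setNames(baseline$rank, baseline[[id_col]])

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(plan$seed)

  nm <- criteria_names(criteria)
  jac <- numeric(plan$n_draws)
  rho <- numeric(plan$n_draws)
  sel_count <- stats::setNames(numeric(n), names(base_rank))
  n_repaired <- 0L

  for (dr in seq_len(plan$n_draws)) {
    cur <- criteria
    for (i in seq_len(nrow(plan$targets))) {
      tg <- plan$targets[i, ]
      j <- match(tg$criterion, nm)
      res <- perturb_criterion(cur[[j]], tg$parameter, tg$amount, tg$type)
      cur[[j]] <- res$criterion
      if (res$repaired) n_repaired <- n_repaired + 1L
    }
    ranked <- rank_genes(table, cur, id_col = id_col)
    top <- ranked[[id_col]][seq_len(k)]
    jac[dr] <- jaccard(top, base_top)
    r2 <- stats::setNames(ranked$rank, ranked[[id_col]])
    rho[dr] <- stats::cor(base_rank, r2[names(base_rank)],
                          method = "spearman")
    sel_count[top] <- sel_count[top] + 1
  }

  structure(list(jaccard = jac, rank_cor = rho,
                 selection_freq = sel_count / plan$n_draws,
                 k = k, n_draws = plan$n_draws,
                 baseline_top = base_top, n_repaired = n_repaired,
                 seed = plan$seed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Rank-stability report (", x$n_draws, " draws, top-", x$k, ")\n",
      sep = "")
  cat(sprintf("  top-%d Jaccard overlap: median %.3f, min %.3f\n",
              x$k, stats::median(x$jaccard), min(x$jaccard)))
  cat(sprintf("  Spearman rank correlation: median %.3f, min %.3f\n",
              stats::median(x$rank_cor), min(x$rank_cor)))
  cat(sprintf("  repaired invalid draws: %d\n", x$n_repaired))
  invisible(x)
}
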