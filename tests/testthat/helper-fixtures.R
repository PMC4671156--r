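# Shared fixtures: built in code, deterministic given the seeds set in
# the tests that use them.

toy_table <- function() {
  data.frame(
    feature_id = c("g1", "g2", "g3"),
    p_value = c(1e-5, 0.01, 0.5),
    logFC = c(2, -1.5, 0.1),
    AveExpr = c(9, 7, 4),
    annotated = c("yes", "no", "yes"),
    stringsAsFactors = FALSE
  )
}

toy_criteria <- function() {
  list(
    criterion("p", "p_value", "low", cuts = c(1e-4, 0.1), weight = 1),
    criterion("fc", "logFC", "ends", cuts = c(-1, -0.5, 0.5, 1), weight = 1),
    criterion("ave", "AveExpr", "high", cuts = c(6, 9), des_min = 0.1,
              weight = 0.1)
  )
}

# random valid monotone spec (cut1 < cut2) in arbitrary data units
rand_monotone_spec <- function() {
  cuts <- sort(stats::rnorm(2, sd = 10))
  if (cuts[1] == cuts[2]) cuts[2] <- cuts[1] + 1
  band <- sort(stats::runif(2))
  list(cut1 = cuts[1], cut2 = cuts[2], des_min = band[1],
       des_max = band[2], scale = stats::runif(1, 0.2, 5))
}

rand_plateau_spec <- function() {
  cuts <- sort(stats::rnorm(4, sd = 10))
  band <- sort(stats::runif(2))
  list(cuts = cuts, des_min = band[1], des_max = band[2],
       scale = stats::runif(1, 0.2, 5))
}

# independent extended-precision oracle for the weighted geometric mean:
# plain per-row arithmetic, no matrix algebra, no short-circuit tricks
oracle_overall_D <- function(d, w) {
  keep <- w > 0 & !is.na(d)
  if (!any(keep)) return(NA_real_)
  d <- d[keep]; w <- w[keep]
  if (any(d == 0)) return(0)
  exp(sum(w * log(d)) / sum(w))
}
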