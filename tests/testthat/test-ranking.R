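test_that("criterion objects validate their parameters", {
  expect_s3_class(criterion("p", "p_value", "low", cuts = c(1e-4, 0.1)),
                  "criterion")
  expect_error(criterion("p", "p", "low", cuts = c(0.1, 1e-4)),
               "non-decreasing")
  expect_error(criterion("p", "p", "low", cuts = c(1e-4, 0.1), weight = -1),
               "weight")
  expect_error(criterion("fc", "logFC", "ends", cuts = c(-1, 1)),
               "expected 4 cut points")
  expect_error(criterion("p", "p", "low"), "cuts")
  expect_error(criterion("a", "ann", "categorical"), "mapping")
  expect_error(criterion("s", "x", "sigmoid", midpoint = 1), "steepness")
  expect_error(criterion("q", "x", "high", cuts = c(0, 1),
                         cuts_quantiles = c(0.1, 0.9)), "only one")
  expect_output(print(criterion("p", "p", "low", cuts = c(0, 1))),
                "low")
})

test_that("apply_criteria maps columns and propagates missing values", {
  tab <- data.frame(p_value = c(1e-5, 0.01, 0.5))
  d <- apply_criteria(tab, list(criterion("p", "p_value", "low",
                                          cuts = c(1e-4, 0.1))))
  expect_named(d, "d_p")
  expect_equal(d$d_p[1], 1)
  expect_equal(d$d_p[3], 0)
  expect_true(d$d_p[2] > 0 && d$d_p[2] < 1)

  tab$p_value[2] <- NA
  d2 <- apply_criteria(tab, list(criterion("p", "p_value", "low",
                                           cuts = c(1e-4, 0.1))))
  expect_true(is.na(d2$d_p[2]))
  expect_false(anyNA(d2$d_p[-2]))
})

test_that("apply_criteria reports configuration errors by name", {
  tab <- toy_table()
  expect_error(apply_criteria(tab, list()), "non-empty")
  expect_error(
    apply_criteria(tab, list(criterion("x", "no_such_col", "high",
                                       cuts = c(0, 1)))),
    "no_such_col")
  expect_error(
    apply_criteria(tab, list(criterion("a", "p_value", "categorical",
                                       mapping = c(yes = 1)))),
    "numeric column")
  expect_error(
    apply_criteria(tab, list(criterion("a", "annotated", "high",
                                       cuts = c(0, 1)))),
    "not numeric")
})

test_that("quantile-specified cuts are resolved from the data column", {
  tab <- data.frame(feature_id = paste0("g", 1:100), x = 1:100)
  cr <- criterion("x", "x", "high", cuts_quantiles = c(0.25, 0.90))
  d <- apply_criteria(tab, list(cr))$d_x
  expect_equal(d, d_high(1:100, quantile(1:100, 0.25), quantile(1:100, 0.9)))
})

test_that("ranking orders by overall desirability with deterministic ties", {
  dm <- rbind(c(1, 1), c(0.5, 0.5))
  r <- rank_features(dm, c(1, 1), feature_id = c("b", "a"))
  expect_equal(r$Overall_D, c(1, 0.5))
  expect_equal(r$rank, 1:2)
  expect_equal(r$feature_id, c("b", "a"))

  # all-identical rows: tie broken by feature ID, D equal
  dm2 <- matrix(0.5, nrow = 3, ncol = 2)
  r2 <- rank_features(dm2, c(1, 1), feature_id = c("c", "a", "b"))
  expect_equal(r2$feature_id, c("a", "b", "c"))
  expect_equal(r2$Overall_D, rep(0.5, 3))
  expect_equal(r2$rank, 1:3)
})

test_that("rank_genes produces a full ranked table over the toy fixture", {
  r <- rank_genes(toy_table(), toy_criteria(), comparison = "p_value")
  expect_equal(nrow(r), 3)
  expect_equal(r$rank, 1:3)
  expect_true(all(diff(r$Overall_D) <= 0))
  expect_true(all(c("d_p", "d_fc", "d_ave", "Overall_D", "evidence_count",
                    "comparison_rank") %in% names(r)))
  # g1 dominates: p at max desirability, extreme logFC, high expression
  expect_equal(r$feature_id[1], "g1")
  # g3 has p = 0.5 -> d = 0 -> overall 0
  expect_equal(r$Overall_D[r$feature_id == "g3"], 0)
  expect_equal(r$evidence_count, rep(3L, 3))
  expect_error(rank_genes(toy_table(), toy_criteria(), id_col = "nope"),
               "nope")
  tab <- toy_table(); tab$feature_id[2] <- "g1"
  expect_error(rank_genes(tab, toy_criteria()), "unique")
})

test_that("ranking invariances hold: zero weight, weight scaling, deletion, dominance", {
  set.seed(11)
  n <- 60
  tab <- data.frame(feature_id = sprintf("f%02d", 1:n),
                    p_value = stats::runif(n),
                    logFC = stats::rnorm(n),
                    AveExpr = stats::runif(n, 4, 12),
                    stringsAsFactors = FALSE)
  crit <- list(
    criterion("p", "p_value", "low", cuts = c(0.001, 0.5), weight = 1),
    criterion("fc", "logFC", "ends", cuts = c(-1.5, -0.5, 0.5, 1.5),
              weight = 1),
    criterion("ave", "AveExpr", "high", cuts = c(5, 10), des_min = 0.1,
              weight = 0.1))
  base <- rank_genes(tab, crit)

  # adding a zero-weight criterion changes no rank
  crit0 <- c(crit, list(criterion("dead", "AveExpr", "low", cuts = c(4, 12),
                                  weight = 0)))
  expect_equal(rank_genes(tab, crit0)$feature_id, base$feature_id)

  # multiplying all weights by a positive constant changes nothing
  crit_scaled <- lapply(crit, function(cr) { cr$weight <- cr$weight * 8; cr })
  scaled <- rank_genes(tab, crit_scaled)
  expect_equal(scaled$feature_id, base$feature_id)
  expect_equal(scaled$Overall_D, base$Overall_D, tolerance = 1e-12)

  # removing a feature preserves the relative order of the others
  drop_id <- base$feature_id[7]
  sub <- rank_genes(tab[tab$feature_id != drop_id, ], crit)
  expect_equal(sub$feature_id, setdiff(base$feature_id, drop_id))

  # weak dominance on every desirability implies D order
  dmat <- apply_criteria(tab, crit)
  w <- c(1, 1, 0.1)
  D <- d_overall(dmat, w)
  for (i in 1:20) {
    ab <- sample(n, 2)
    a <- as.numeric(dmat[ab[1], ]); b <- as.numeric(dmat[ab[2], ])
    if (all(a >= b)) expect_gte(D[ab[1]], D[ab[2]])
  }
})

test_that("selection uses a strict threshold or a clamped top-k", {
  ranked <- data.frame(feature_id = c("a", "b", "c"),
                       Overall_D = c(0.9, 0.7, 0.5))
  expect_equal(nrow(select_top(ranked, threshold = 0.7)), 1)  # strictly >
  expect_equal(nrow(select_top(ranked, threshold = 0.95)), 0)
  expect_equal(nrow(select_top(ranked, k = 10)), 3)           # clamp
  expect_equal(select_top(ranked, k = 2)$feature_id, c("a", "b"))
  expect_error(select_top(ranked, threshold = 1.2), "\\[0, 1\\]")
  expect_error(select_top(ranked), "exactly one")
  expect_error(select_top(ranked, threshold = 0.5, k = 2), "exactly one")
})

test_that("comparison ranks use min ties and prefilter semantics", {
  tab <- data.frame(p = c(0.01, 0.001, 0.1), AveExpr = c(7, 8, 4))
  expect_equal(comparison_rank(tab, "p"), c(2L, 1L, 3L))
  # prefilter removes row 3; survivors re-ranked among themselves
  r <- comparison_rank(tab, "p", prefilter = list(function(t) t$AveExpr >= 6))
  expect_equal(r, c(2L, 1L, NA))
  # ties share the smallest rank
  tab2 <- data.frame(p = c(0.5, 0.1, 0.1))
  expect_equal(comparison_rank(tab2, "p"), c(3L, 1L, 1L))
  # descending option
  expect_equal(comparison_rank(tab, "p", ascending = FALSE), c(2L, 3L, 1L))
  expect_error(comparison_rank(tab, "nope"), "nope")
  expect_error(comparison_rank(data.frame(a = "x"), "a"), "not numeric")
})

test_that("analytic helpers compute joint power and fold change", {
  expect_equal(joint_power(0.7, 3), 0.343)
  expect_equal(joint_power(1, 10), 1)
  expect_equal(fold_change(1.41), 2^1.41)
  expect_equal(fold_change(0), 1)
  expect_equal(fold_change(2, base = 10), 100)
  expect_error(joint_power(1.2, 2), "\\[0, 1\\]")
  expect_error(fold_change(1, base = -2), "positive")
})
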