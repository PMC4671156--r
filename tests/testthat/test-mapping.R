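test_that("d_high hits its plateaus and interpolates with the scale exponent", {
  expect_equal(d_high(0, 0, 2), 0)
  expect_equal(d_high(2, 0, 2), 1)
  expect_equal(d_high(1, 0, 2), 0.5)
  # (0.5 - 0)/(2 - 0) = 0.25, squared under scale = 2
  expect_equal(d_high(0.5, 0, 2, scale = 2), 0.0625)
  # band limits respected
  expect_equal(d_high(c(-10, 10), 0, 2, des_min = 0.2, des_max = 0.8),
               c(0.2, 0.8))
  # boundary values take the plateau value for any scale
  expect_equal(d_high(c(0, 2), 0, 2, scale = 3), c(0, 1))
})

test_that("d_low mirrors d_high and encodes the p-value criterion", {
  # full desirability below the lower cut, filtered out above the upper
  expect_equal(d_low(0.00005, 1e-4, 0.1), 1)
  expect_equal(d_low(0.2, 1e-4, 0.1), 0)
  cut1 <- 1e-4; cut2 <- 0.1
  expect_equal(d_low((cut1 + cut2) / 2, cut1, cut2), 0.5)
  # intermediate p-values get intermediate desirabilities, decreasing
  p <- c(0.001, 0.01, 0.05)
  d <- d_low(p, cut1, cut2)
  expect_true(all(d > 0 & d < 1))
  expect_true(all(diff(d) < 0))
})

test_that("d_central and d_ends are plateau/trough reflections", {
  cuts <- c(-2, -1, 1, 2)
  expect_equal(d_central(0, cuts[1], cuts[2], cuts[3], cuts[4]), 1)
  expect_equal(d_central(-2, cuts[1], cuts[2], cuts[3], cuts[4]), 0)
  expect_equal(d_central(-1.5, cuts[1], cuts[2], cuts[3], cuts[4]), 0.5)
  expect_equal(d_ends(0, cuts[1], cuts[2], cuts[3], cuts[4]), 0)
  expect_equal(d_ends(5, cuts[1], cuts[2], cuts[3], cuts[4]), 1)
  expect_equal(d_ends(1.5, cuts[1], cuts[2], cuts[3], cuts[4]), 0.5)
  # reflection identity at unit band and linear interpolation
  x <- seq(-3, 3, by = 0.01)
  expect_equal(d_ends(x, cuts[1], cuts[2], cuts[3], cuts[4]),
               1 - d_central(x, cuts[1], cuts[2], cuts[3], cuts[4]))
})

test_that("categorical desirabilities map labels, defaults, and errors", {
  m <- c(yes = 1, no = 0.2)
  expect_equal(d_cat("yes", m), 1)
  expect_equal(d_cat("no", m), 0.2)
  expect_equal(d_cat(c("yes", NA, "no"), m), c(1, NA, 0.2))
  expect_equal(d_cat("other", m, default = 0.5), 0.5)
  expect_error(d_cat("other", m), "unmapped")
  expect_error(d_cat("yes", c(yes = 1.5)), "\\[0, 1\\]")
})

test_that("sigmoid mapping is smooth, centred at its midpoint, directional", {
  expect_equal(d_sigmoid(3, midpoint = 3, steepness = 2), 0.5)
  expect_equal(d_sigmoid(3, 3, 2, des_min = 0.2, des_max = 0.8), 0.5)
  expect_equal(d_sigmoid(Inf, 0, 1), 1)
  expect_equal(d_sigmoid(-Inf, 0, 1), 0)
  # negative steepness flips direction
  expect_equal(d_sigmoid(Inf, 0, -1), 0)
  expect_true(is.na(d_sigmoid(NA, 0, 1)))
  expect_error(d_sigmoid(1, 0, steepness = 0), "non-zero")
})

test_that("invalid specifications are rejected with informative errors", {
  expect_error(d_high(1, cut1 = 2, cut2 = 1), "non-decreasing")
  expect_error(d_high(1, NaN, 1), "NA/NaN")
  expect_error(d_low(1, 0, 1, scale = 0), "positive")
  expect_error(d_high(1, 0, 1, des_min = 0.9, des_max = 0.1), "des_min")
  expect_error(d_high(1, 0, 1, des_min = -0.1), "des_min")
  expect_error(d_central(1, 0, -1, 1, 2), "non-decreasing")
  expect_error(d_ends(1, 0, 1, 3, 2), "non-decreasing")
})

test_that("missing data propagate as missing, never as zero", {
  expect_equal(d_high(c(NA, 1), 0, 2), c(NA, 0.5))
  expect_equal(d_low(c(0.01, NA), 1e-4, 0.1),
               c(d_low(0.01, 1e-4, 0.1), NA))
  expect_equal(d_central(NA, -2, -1, 1, 2), NA_real_)
  expect_equal(d_ends(NA, -2, -1, 1, 2), NA_real_)
})

test_that("infinite inputs map to the corresponding plateau value", {
  expect_equal(d_high(c(-Inf, Inf), 0, 2), c(0, 1))
  expect_equal(d_low(c(-Inf, Inf), 0, 2), c(1, 0))
  expect_equal(d_central(c(-Inf, Inf), -2, -1, 1, 2), c(0, 0))
  expect_equal(d_ends(c(-Inf, Inf), -2, -1, 1, 2), c(1, 1))
})

test_that("degenerate equal cuts give a right-closed step function", {
  # the implicit status quo of hard thresholding: binary 0/1 at the cut
  expect_equal(d_high(c(0.9, 1, 1.1), 1, 1), c(0, 1, 1))
  expect_equal(d_low(c(0.04, 0.05, 0.06), 0.05, 0.05), c(1, 0, 0))
})

test_that("mapping outputs stay inside the band and are monotone (property)", {
  set.seed(421)
  for (i in 1:500) {
    s <- rand_monotone_spec()
    x <- sort(stats::rnorm(25, sd = 20))
    dh <- d_high(x, s$cut1, s$cut2, s$des_min, s$des_max, s$scale)
    dl <- d_low(x, s$cut1, s$cut2, s$des_min, s$des_max, s$scale)
    expect_true(all(dh >= s$des_min - 1e-12 & dh <= s$des_max + 1e-12))
    expect_true(all(dl >= s$des_min - 1e-12 & dl <= s$des_max + 1e-12))
    expect_true(all(diff(dh) >= -1e-12))  # non-decreasing
    expect_true(all(diff(dl) <= 1e-12))   # non-increasing
    # mirror identity at scale = 1
    expect_equal(d_low(x, s$cut1, s$cut2, s$des_min, s$des_max, 1),
                 d_high(-x, -s$cut2, -s$cut1, s$des_min, s$des_max, 1))
    p <- rand_plateau_spec()
    dc <- d_central(x, p$cuts[1], p$cuts[2], p$cuts[3], p$cuts[4],
                    p$des_min, p$des_max, p$scale)
    de <- d_ends(x, p$cuts[1], p$cuts[2], p$cuts[3], p$cuts[4],
                 p$des_min, p$des_max, p$scale)
    expect_true(all(dc >= p$des_min - 1e-12 & dc <= p$des_max + 1e-12))
    expect_true(all(de >= p$des_min - 1e-12 & de <= p$des_max + 1e-12))
    # unimodality: non-decreasing then non-increasing
    dd <- diff(dc)
    first_drop <- match(TRUE, dd < -1e-12, nomatch = length(dd) + 1)
    expect_true(all(dd[seq_along(dd) >= first_drop] <= 1e-12))
  }
})

test_that("quantile cuts encode the top-q%-of-the-distribution idiom", {
  x <- 1:100
  cuts <- quantile_cuts(x, c(0.25, 0.90))
  expect_equal(cuts, unname(quantile(x, c(0.25, 0.90))))
  # the top 10% indeed sit on the maximum-desirability plateau
  d <- d_high(x, cuts[1], cuts[2])
  expect_equal(mean(d == 1), 0.10)  # 90th percentile of 1..100 is 90.1
  expect_error(quantile_cuts(x, c(0.9, 0.1)), "non-decreasing")
})
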