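# Desirability mapping functions: map a measured variable onto a 0-1 scale
# where 1 is maximally desirable and 0 is unacceptable.

check_band <- function(des_min, des_max) {
  if (!is.numeric(des_min) || length(des_min) != 1L || is.na(des_min) ||
      !is.numeric(des_max) || length(des_max) != 1L || is.na(des_max))
    stop("'des_min' and 'des_max' must be single finite numbers", call. = FALSE)
  if (des_min < 0 || des_max > 1 || des_min > des_max)
    stop("desirability band must satisfy 0 <= des_min <= des_max <= 1",
         call. = FALSE)
  invisible(NULL)
}

check_scale <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    stop("'scale' must be a single positive number", call. = FALSE)
  invisible(NULL)
}

check_cuts <- function(cuts) {
  if (any(is.na(cuts)) || any(is.nan(cuts)))
    stop("cut points must not be NA/NaN", call. = FALSE)
  if (is.unsorted(cuts))
    stop("cut points must be in non-decreasing order (",
         paste(format(cuts), collapse = ", "), ")", call. = FALSE)
  invisible(NULL)
}

# Interpolation fraction in [0, 1] between two cuts; the caller guarantees
# cut1 < cut2 and only evaluates strictly inside the interval.
interp_frac <- function(x, cut1, cut2, scale) {
  ((x - cut1) / (cut2 - cut1))^scale
}

#' Desirability when high values are desirable
#'
#' Maps a numeric variable onto the desirability scale with a piecewise
#' curve that is `des_min` below `cut1`, `des_max` above `cut2`, and a
#' power-transformed linear interpolation in between (Derringer-Suich
#' style one-sided transformation).
#'
#' @param x Numeric vector of data values. `NA` values stay missing;
#'   infinite values receive the corresponding plateau value.
#' @param cut1,cut2 Cut points in data units, `cut1 <= cut2`. Below
#'   `cut1` the desirability is `des_min`; at or above `cut2` it is
#'   `des_max`. When `cut1 == cut2` the mapping degenerates to a step
#'   function: `x < cut1` gives the low-side value, `x >= cut1` the
#'   high-side value.
#' @param des_min,des_max Minimum and maximum desirability, with
#'   `0 <= des_min <= des_max <= 1`. A non-zero `des_min` keeps a
#'   feature in play (deprioritised) instead of excluding it outright.
#' @param scale Positive curvature exponent applied to the linear
#'   interpolation fraction; 1 (the default) is linear, larger values
#'   make the rise more gradual near `cut1`.
#' @return Numeric vector of desirabilities in `[des_min, des_max]`,
#'   `NA` where `x` is missing.
#' @examples
#' d_high(c(-1, 0, 1, 2, 3), cut1 = 0, cut2 = 2)
#' @seealso [d_low()], [d_central()], [d_ends()], [d_cat()], [d_sigmoid()]
#' @export
d_high <- function(x, cut1, cut2, des_min = 0, des_max = 1, scale = 1) {
  check_cuts(c(cut1, cut2)); check_band(des_min, des_max); check_scale(scale)
  d <- rep(NA_real_, length(x))
  ok <- which(!is.na(x))
  if (cut1 == cut2) {
    d[ok] <- ifelse(x[ok] >= cut1, des_max, des_min)
    return(d)
  }
  xo <- x[ok]
  do <- rep(des_min, length(xo))
  do[xo >= cut2] <- des_max
  mid <- xo > cut1 & xo < cut2
  do[mid] <- des_min + (des_max - des_min) * interp_frac(xo[mid], cut1, cut2, scale)
  d[ok] <- do
  d
}

#' Desirability when low values are desirable
#'
#' Mirror image of [d_high()]: `des_max` at or below `cut1`, `des_min`
#' at or above `cut2`, decreasing in between. The classic use is a
#' p-value criterion, e.g. full desirability below 1e-4 and complete
#' filtering (d = 0) above 0.1.
#'
#' @inheritParams d_high
#' @param cut1,cut2 Cut points, `cut1 <= cut2`; at or below `cut1` the
#'   desirability is `des_max`, at or above `cut2` it is `des_min`.
#'   Degenerate `cut1 == cut2` is a step: `x < cut1` high-side value
#'   (`des_max`), `x >= cut1` low-side value (`des_min`).
#' @return Numeric vector of desirabilities, `NA` where `x` is missing.
#' @examples
#' d_low(c(1e-5, 0.01, 0.5), cut1 = 1e-4, cut2 = 0.1)
#' @export
d_low <- function(x, cut1, cut2, des_min = 0, des_max = 1, scale = 1) {
  check_cuts(c(cut1, cut2)); check_band(des_min, des_max); check_scale(scale)
  d <- rep(NA_real_, length(x))
  ok <- which(!is.na(x))
  if (cut1 == cut2) {
    d[ok] <- ifelse(x[ok] >= cut1, des_min, des_max)
    return(d)
  }
  xo <- x[ok]
  do <- rep(des_max, length(xo))
  do[xo >= cut2] <- des_min
  mid <- xo > cut1 & xo < cut2
  do[mid] <- des_min + (des_max - des_min) * interp_frac(-xo[mid], -cut2, -cut1, scale)
  d[ok] <- do
  d
}

#' Desirability when central values are desirable
#'
#' Trapezoidal mapping: `des_min` outside `(cut1, cut4)`, `des_max` on
#' the plateau `[cut2, cut3]`, rising on `(cut1, cut2)` and falling on
#' `(cut3, cut4)`. At a cut point the plateau value applies (closed
#' plateaus), so the curve is continuous for non-degenerate cuts.
#'
#' @inheritParams d_high
#' @param cut1,cut2,cut3,cut4 Cut points in non-decreasing order.
#' @return Numeric vector of desirabilities, `NA` where `x` is missing.
#' @examples
#' d_central(seq(-2, 2, by = 0.5), -1.5, -0.5, 0.5, 1.5)
#' @export
d_central <- function(x, cut1, cut2, cut3, cut4, des_min = 0, des_max = 1,
                      scale = 1) {
  check_cuts(c(cut1, cut2, cut3, cut4)); check_band(des_min, des_max)
  check_scale(scale)
  d <- rep(NA_real_, length(x))
  ok <- which(!is.na(x))
  xo <- x[ok]
  do <- rep(des_min, length(xo))
  rise <- xo > cut1 & xo < cut2
  do[rise] <- des_min + (des_max - des_min) * interp_frac(xo[rise], cut1, cut2, scale)
  fall <- xo > cut3 & xo < cut4
  do[fall] <- des_min + (des_max - des_min) * interp_frac(-xo[fall], -cut4, -cut3, scale)
  do[xo >= cut2 & xo <= cut3] <- des_max
  d[ok] <- do
  d
}

#' Desirability when extreme values are desirable
#'
#' Reflection of [d_central()]: `des_max` outside `(cut1, cut4)`,
#' `des_min` on the trough `[cut2, cut3]`. The classic use is a
#' bidirectional log fold-change criterion where large changes in either
#' direction are desirable. With `des_min = 0`, `des_max = 1` and
#' `scale = 1`, `d_ends(x, ...) == 1 - d_central(x, ...)` for the same
#' cuts.
#'
#' @inheritParams d_central
#' @return Numeric vector of desirabilities, `NA` where `x` is missing.
#' @examples
#' d_ends(seq(-2, 2, by = 0.5), -1, -0.5, 0.5, 1)
#' @export
d_ends <- function(x, cut1, cut2, cut3, cut4, des_min = 0, des_max = 1,
                   scale = 1) {
  check_cuts(c(cut1, cut2, cut3, cut4)); check_band(des_min, des_max)
  check_scale(scale)
  d <- rep(NA_real_, length(x))
  ok <- which(!is.na(x))
  xo <- x[ok]
  do <- rep(des_max, length(xo))
  fall <- xo > cut1 & xo < cut2
  do[fall] <- des_min + (des_max - des_min) * interp_frac(-xo[fall], -cut2, -cut1, scale)
  rise <- xo > cut3 & xo < cut4
  do[rise] <- des_min + (des_max - des_min) * interp_frac(xo[rise], cut3, cut4, scale)
  do[xo >= cut2 & xo <= cut3] <- des_min
  d[ok] <- do
  d
}

#' Desirability for a categorical variable
#'
#' Assigns each category its own desirability, e.g. genes annotated to a
#' Gene Ontology term of interest get 1 and all others 0.2 — a non-zero
#' value deprioritises rather than removes them, which also guards
#' against incomplete database annotation.
#'
#' @param x Character or factor vector of category labels. `NA` labels
#'   give `NA` desirabilities.
#' @param mapping Named numeric vector mapping category label to a
#'   desirability in \[0, 1\].
#' @param default Desirability in \[0, 1\] assigned to labels absent
#'   from `mapping`, or `NULL` (the default) to treat an unmapped label
#'   as an error.
#' @return Numeric vector of desirabilities, `NA` where `x` is missing.
#' @examples
#' d_cat(c("yes", "no", "yes"), mapping = c(yes = 1, no = 0.2))
#' @export
d_cat <- function(x, mapping, default = NULL) {
  if (is.null(names(mapping)) || !is.numeric(mapping) || length(mapping) == 0L)
    stop("'mapping' must be a non-empty named numeric vector", call. = FALSE)
  if (any(is.na(mapping)) || any(mapping < 0) || any(mapping > 1))
    stop("mapped desirabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(default)) {
    if (!is.numeric(default) || length(default) != 1L || is.na(default) ||
        default < 0 || default > 1)
      stop("'default' must be NULL or a single desirability in [0, 1]",
           call. = FALSE)
  }
  x <- as.character(x)
  d <- unname(mapping[x])
  unmapped <- is.na(d) & !is.na(x)
  if (any(unmapped)) {
    if (is.null(default))
      stop("unmapped category label(s): ",
           paste(unique(x[unmapped]), collapse = ", "), call. = FALSE)
    d[unmapped] <- default
  }
  d
}

#' Smooth sigmoidal desirability
#'
#' A logistic alternative to the piecewise-linear monotone mappings:
#' the desirability rises (or falls, for negative `steepness`) smoothly
#' from `des_min` to `des_max`, reaching exactly the midpoint of the
#' band at `x = midpoint`. Useful when a hard plateau boundary is not
#' wanted.
#'
#' @inheritParams d_high
#' @param midpoint Data value at which the desirability is halfway
#'   between `des_min` and `des_max`.
#' @param steepness Non-zero slope parameter; its sign sets the
#'   direction (positive: high values desirable) and its magnitude how
#'   sharply the curve transitions.
#' @return Numeric vector of desirabilities, `NA` where `x` is missing.
#' @examples
#' d_sigmoid(seq(-3, 3), midpoint = 0, steepness = 2)
#' @export
d_sigmoid <- function(x, midpoint, steepness, des_min = 0, des_max = 1) {
  if (!is.numeric(midpoint) || length(midpoint) != 1L || is.na(midpoint))
    stop("'midpoint' must be a single finite number", call. = FALSE)
  if (!is.numeric(steepness) || length(steepness) != 1L || is.na(steepness) ||
      steepness == 0)
    stop("'steepness' must be a single non-zero number", call. = FALSE)
  check_band(des_min, des_max)
  des_min + (des_max - des_min) * stats::plogis(steepness * (x - midpoint))
}

#' Convert distribution quantiles into cut points
#'
#' Helper for the common "the top q% of the distribution gets maximum
#' desirability" style of cut-point choice: returns the data values at
#' the requested quantile probabilities, ready to be used as cuts.
#'
#' @param x Numeric data vector (missing values ignored).
#' @param probs Quantile probabilities in \[0, 1\], one per cut point,
#'   in non-decreasing order.
#' @return Numeric vector of cut values, same length as `probs`.
#' @examples
#' # high-is-good with the top 10% at maximum desirability:
#' x <- rnorm(1000)
#' cuts <- quantile_cuts(x, c(0.25, 0.90))
#' d <- d_high(x, cuts[1], cuts[2])
#' @export
quantile_cuts <- function(x, probs) {
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1) || is.unsorted(probs))
    stop("'probs' must be non-decreasing probabilities in [0, 1]", call. = FALSE)
  unname(stats::quantile(x, probs = probs, na.rm = TRUE, names = FALSE))
}
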