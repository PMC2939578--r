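#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Surface over \code{stats::wilcox.test} with the conventions used for the
#' group comparisons in this package: the default normal approximation uses
#' the tie-corrected variance and a 0.5 continuity correction; the exact
#' method enumerates the rank-sum distribution and is only valid without
#' ties (requesting it with ties is an error rather than a silent fallback).
#' \code{method = "auto"} picks exact for tie-free samples with
#' n1 + n2 <= 20, otherwise the normal approximation.
#'
#' @param x,y numeric samples (both non-empty).
#' @param method \code{"auto"}, \code{"exact"} or \code{"normal_approx"}.
#' @param sides \code{"two"} (default), \code{"greater"} or \code{"less"}
#'   (\code{"greater"}: x tends larger than y).
#' @return A \linkS4class{TestResult} whose method tag records which route
#'   produced the p-value.
#' @examples
#' ## complete separation of two small groups
#' pValue(wilcoxonRankSum(c(5, 6, 7), c(1, 2, 3), method = "exact"))
#' @export
wilcoxonRankSum <- function(x, y, method = c("auto", "exact", "normal_approx"),
                            sides = c("two", "greater", "less")) {
  method <- match.arg(method)
  sides <- match.arg(sides)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (method == "exact" && ties)
    stop("exact method is not valid with ties; use normal_approx")
  if (method == "auto")
    method <- if (!ties && length(x) + length(y) <= 20) "exact" else "normal_approx"
  alt <- switch(sides, two = "two.sided", greater = "greater", less = "less")
  wt <- wilcox.test(x, y, alternative = alt, exact = (method == "exact"),
                    correct = TRUE)
  new("TestResult",
      statistic = setNames(unname(wt$statistic), "W"),
      pValue = max(wt$p.value, .Machine$double.xmin),
      method = method,
      alternative = sides,
      sampleSizes = c(length(x), length(y)))
}

#' Pearson product-moment correlation test
#'
#' p-value from t = R * sqrt((n - 2)/(1 - R^2)) on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, n >= 3, each with nonzero variance.
#' @param sides as in \code{\link{wilcoxonRankSum}}.
#' @return A \linkS4class{TestResult}; the statistic slot holds R.
#' @export
pearsonTest <- function(x, y, sides = c("two", "greater", "less")) {
  sides <- match.arg(sides)
  checkCorInput(x, y)
  alt <- switch(sides, two = "two.sided", greater = "greater", less = "less")
  ct <- cor.test(x, y, method = "pearson", alternative = alt)
  new("TestResult",
      statistic = setNames(unname(ct$estimate), "R"),
      pValue = max(ct$p.value, .Machine$double.xmin),
      method = "t_distribution",
      alternative = sides,
      sampleSizes = c(length(x), length(y)))
}

#' Spearman rank correlation test
#'
#' Pearson correlation of mid-ranks (ties receive average ranks); p from the
#' t approximation.
#'
#' @inheritParams pearsonTest
#' @return A \linkS4class{TestResult}; the statistic slot holds rho.
#' @export
spearmanTest <- function(x, y, sides = c("two", "greater", "less")) {
  sides <- match.arg(sides)
  checkCorInput(x, y)
  alt <- switch(sides, two = "two.sided", greater = "greater", less = "less")
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", alternative = alt, exact = FALSE))
  new("TestResult",
      statistic = setNames(unname(ct$estimate), "rho"),
      pValue = max(ct$p.value, .Machine$double.xmin),
      method = "t_approximation",
      alternative = sides,
      sampleSizes = c(length(x), length(y)))
}

checkCorInput <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in input")
  invisible(TRUE)
}
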