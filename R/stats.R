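# Shared statistical primitives: Welch's unequal-variance t-test, Pearson
# correlation, delta-delta-CT relative expression, fold/percent change and
# mean +/- SEM group summaries.

#' Group summary: n, mean, SEM
#'
#' @param x Numeric vector (NAs dropped).
#' @param label Optional group label.
#' @return A list with \code{n}, \code{mean}, \code{sem} (sample SD over
#'   \code{sqrt(n)}; \code{NA} for n = 1) and \code{label}.
#' @export
groupSummary <- function(x, label = NA_character_) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1) stop("empty group")
  list(n = n, mean = mean(x),
       sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       label = label)
}

#' Welch's two-sample t-test (unequal variances)
#'
#' Closed-form Welch statistic
#' \deqn{t = (\bar x - \bar y) / \sqrt{s_x^2/n_x + s_y^2/n_y}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value
#' from the t distribution (one-sided available via \code{alternative}).
#' Degenerate inputs where both sample variances are zero return t = 0,
#' p = 1 if the means agree, otherwise p = 0 flagged \code{degenerate}.
#'
#' @param x,y Numeric vectors of length >= 2.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return A list of class \code{"welchTest"} with \code{t}, \code{df},
#'   \code{p.value}, \code{meanX}, \code{meanY}, \code{degenerate}.
#' @examples
#' welchTTest(c(1, 2, 3), c(4, 5, 6))
#' @export
welchTTest <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  mx <- mean(x); my <- mean(y)
  if (vx == 0 && vy == 0) {
    out <- list(t = if (mx == my) 0 else sign(mx - my) * Inf,
                df = nx + ny - 2, p.value = if (mx == my) 1 else 0,
                meanX = mx, meanY = my, degenerate = TRUE)
    class(out) <- "welchTest"
    return(out)
  }
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              less = stats::pt(t, df),
              greater = stats::pt(t, df, lower.tail = FALSE))
  out <- list(t = t, df = df, p.value = p, meanX = mx, meanY = my,
              degenerate = FALSE)
  class(out) <- "welchTest"
  out
}

#' @export
print.welchTest <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4f, df = %.2f, p = %.4g\n",
              x$t, x$df, x$p.value))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A list with \code{r} and \code{r.squared}.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance")
  r <- stats::cor(x, y, method = "pearson")
  list(r = r, r.squared = r^2)
}

#' Relative expression by the delta-delta-CT method
#'
#' Per sample, computes \code{2^-(ctTarget - ctReference)} and normalises
#' by the mean of that quantity over the calibrator group, so the
#' calibrator-group mean of the result is exactly 1.
#'
#' @param ctTarget,ctReference Numeric CT vectors, one value per sample.
#' @param groups Character/factor of group labels per sample.
#' @param calibrator The calibrator group label (e.g. \code{"WT"}).
#' @return Numeric vector of normalised expression values; samples with a
#'   missing reference CT are dropped with a message.
#' @export
ddctRelativeExpression <- function(ctTarget, ctReference, groups,
                                   calibrator) {
  if (length(ctTarget) != length(ctReference) ||
      length(ctTarget) != length(groups))
    stop("ctTarget, ctReference and groups must have equal length")
  drop <- is.na(ctReference) | is.na(ctTarget)
  if (any(drop)) {
    message(sum(drop), " sample(s) dropped: missing CT")
    ctTarget <- ctTarget[!drop]; ctReference <- ctReference[!drop]
    groups <- groups[!drop]
  }
  if (!any(groups == calibrator)) stop("calibrator group is empty")
  rel <- 2^(-(ctTarget - ctReference))
  rel / mean(rel[groups == calibrator])
}

#' Fold change and percent change between two group means
#'
#' \code{fold = meanB / meanA}; \code{percent = 100 * (fold - 1)}.
#' Rounding happens only at report time: \code{foldReport} to one decimal
#' and \code{percentReport} to the nearest integer.
#'
#' @param meanA Baseline group mean (> 0) or a [groupSummary()] list.
#' @param meanB Comparison group mean or a [groupSummary()] list.
#' @return List with \code{fold}, \code{percent}, \code{foldReport},
#'   \code{percentReport}.
#' @examples
#' foldAndPercentChange(0.834, 3.102)$foldReport   # 3.7
#' foldAndPercentChange(6.961, 9.483)$percentReport # 36
#' @export
foldAndPercentChange <- function(meanA, meanB) {
  if (is.list(meanA)) meanA <- meanA$mean
  if (is.list(meanB)) meanB <- meanB$mean
  if (meanA <= 0) stop("baseline mean must be positive")
  fold <- meanB / meanA
  list(fold = fold, percent = 100 * (fold - 1),
       foldReport = round(fold, 1), percentReport = round(100 * (fold - 1)))
}
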