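# Statistical primitives: pooled-SD Cohen's d, two-sample t, Pearson r.
# Effect sizes are reported alongside p-values everywhere in this package:
# with millions of windows even negligible mean differences reach
# significance, so d is the informative measure.

#' Cohen's d with pooled standard deviation
#'
#' Computes `d = (mean(x1) - mean(x2)) / s` with
#' `s = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`, the classical
#' pooled-SD form; sample SDs use n-1 denominators. The report carries the
#' group summaries and the matching pooled two-sample t statistic
#' (`t = d * sqrt(n1 n2 / (n1 + n2))`).
#'
#' @param x1,x2 numeric vectors (each of length >= 2, finite).
#' @return an object of class `effect_size_report`: a list with elements
#'   d, x1_mean, x2_mean, s1, s2, s, n1, n2, t, p, flavor ("pooled").
#'   A pooled SD of zero leaves `d` at 0 for equal means (a zero difference
#'   is zero at any scale) and undefined (`NA`, `d_defined = FALSE`)
#'   otherwise.
#' @examples
#' cohens_d(c(2, 4), c(0, 2))  # d = sqrt(2)
#' @export
cohens_d <- function(x1, x2) {
  if (length(x1) < 2L || length(x2) < 2L) stop("both groups need n >= 2")
  if (any(!is.finite(x1)) || any(!is.finite(x2))) stop("non-finite values")
  n1 <- length(x1); n2 <- length(x2)
  m1 <- mean(x1); m2 <- mean(x2)
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  s <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  defined <- s > 0 || m1 == m2   # zero difference is zero at any scale
  d <- if (s > 0) (m1 - m2) / s else if (m1 == m2) 0 else NA_real_
  if (s > 0) {
    t <- d * sqrt(n1 * n2 / (n1 + n2))
    p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
  } else if (m1 == m2) {
    t <- 0; p <- 1
  } else {
    t <- sign(m1 - m2) * Inf; p <- 0
  }
  structure(list(d = d, d_defined = defined, x1_mean = m1, x2_mean = m2,
                 s1 = s1, s2 = s2, s = s, n1 = n1, n2 = n2,
                 t = t, p = p, flavor = "pooled"),
            class = "effect_size_report")
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat(sprintf("Cohen's d = %s  (pooled s = %.4g)\n",
              if (x$d_defined) sprintf("%.4f", x$d) else "undefined", x$s))
  cat(sprintf("  group 1: mean %.4g, sd %.4g, n %d\n", x$x1_mean, x$s1, x$n1))
  cat(sprintf("  group 2: mean %.4g, sd %.4g, n %d\n", x$x2_mean, x$s2, x$n2))
  cat(sprintf("  t = %.4g (%s), p = %.3g\n", x$t, x$flavor, x$p))
  invisible(x)
}

#' Two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] recording the flavor. Welch is the
#' default (robust to the very unequal group sizes typical of genome-wide
#' window comparisons); the pooled flavor matches the pooled-SD effect size
#' exactly via `t = d * sqrt(n1 n2/(n1+n2))`. When both groups have zero
#' variance the statistic is defined by convention (t = 0, p = 1 for equal
#' means; p = 0 otherwise) and flagged with `degenerate = TRUE`.
#'
#' @param x1,x2 numeric vectors (n >= 2 each).
#' @param flavor "welch" (default) or "pooled".
#' @return list with elements t, p, df, flavor, degenerate.
#' @export
two_sample_t <- function(x1, x2, flavor = c("welch", "pooled")) {
  flavor <- match.arg(flavor)
  if (length(x1) < 2L || length(x2) < 2L) stop("both groups need n >= 2")
  if (stats::var(x1) == 0 && stats::var(x2) == 0) {
    equal <- isTRUE(all.equal(mean(x1), mean(x2)))
    return(list(t = if (equal) 0 else sign(mean(x1) - mean(x2)) * Inf,
                p = if (equal) 1 else 0,
                df = NA_real_, flavor = flavor, degenerate = TRUE))
  }
  tt <- stats::t.test(x1, x2, var.equal = (flavor == "pooled"))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), flavor = flavor, degenerate = FALSE)
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return the sample correlation in `[-1, 1]`; `NA` with a warning when
#'   either input has zero variance (undefined correlation).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
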