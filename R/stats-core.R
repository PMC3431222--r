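# Two-sample t and Pearson chi-square, implemented as explicit formulas so
# the conventions (pooled variance, df, two-sidedness) are under package
# control; distribution tails come from stats::pt / stats::pchisq.

#' Two-sample Student's t-test
#'
#' Unpaired two-sample t statistic, either with the classical pooled
#' variance (df = n1 + n2 - 2) or with the Welch-Satterthwaite
#' approximation. P-values are two-sided. For equal group sizes the pooled
#' and Welch statistics coincide (their df differ).
#'
#' @param x,y numeric vectors of per-group values (each length >= 2).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return an object of class `two_sample_t` with elements `t`, `df`, `p`,
#'   `n1`, `n2`, `variant`.
#' @export
student_t_two_sample <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  v1 <- stats::var(x); v2 <- stats::var(y)
  d <- mean(x) - mean(y)
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    if (sp2 == 0) {
      if (d == 0) {
        tval <- 0
      } else {
        warning("zero pooled variance with unequal means: t is infinite")
        tval <- sign(d) * Inf
      }
    } else {
      tval <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
    }
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      df <- n1 + n2 - 2
      if (d == 0) {
        tval <- 0
      } else {
        warning("zero variance with unequal means: t is infinite")
        tval <- sign(d) * Inf
      }
    } else {
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      tval <- d / sqrt(se2)
    }
  }
  p <- if (is.infinite(tval)) 0 else 2 * stats::pt(-abs(tval), df)
  structure(list(t = tval, df = df, p = p, n1 = n1, n2 = n2,
                 variant = variant),
            class = "two_sample_t")
}

#' @export
print.two_sample_t <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s): t = %s, df = %s, p-value = %.4f (n = %d, %d)\n",
              x$variant, format(fmt_t(x$t)), format(round(x$df, 2)), x$p,
              x$n1, x$n2))
  invisible(x)
}

#' Pearson chi-square test
#'
#' With a matrix of observed counts and no `expected`, a contingency test
#' with expected counts from the margins and df = (rows - 1)(cols - 1)
#' (no continuity correction). With `expected` supplied, a goodness-of-fit
#' test with df = k - 1.
#'
#' @param observed non-negative counts (matrix for contingency, vector for
#'   goodness-of-fit).
#' @param expected optional expected counts (same shape as `observed`).
#' @return an object of class `chi_square_result` with `chi2`, `df`, `p`.
#' @export
chi_square <- function(observed, expected = NULL) {
  obs <- as.numeric(observed)
  if (any(obs < 0)) stop("observed counts must be non-negative", call. = FALSE)
  if (is.null(expected)) {
    if (!is.matrix(observed) || any(dim(observed) < 2L)) {
      stop("contingency form needs a matrix with at least 2 rows and 2 columns",
           call. = FALSE)
    }
    rs <- rowSums(observed); cs <- colSums(observed); tot <- sum(observed)
    expected <- outer(rs, cs) / tot
    df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  } else {
    if (length(expected) != length(obs)) {
      stop("observed and expected must have the same length", call. = FALSE)
    }
    df <- length(obs) - 1L
  }
  exp <- as.numeric(expected)
  if (any(exp <= 0)) stop("all expected counts must be positive", call. = FALSE)
  chi2 <- sum((obs - exp)^2 / exp)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: chi2 = %.4g, df = %d, p-value = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}
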