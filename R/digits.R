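#' Leading (first significant) digit of positive numbers
#'
#' Extracts the first non-zero decimal digit of each value, the quantity whose
#' distribution Benford's law describes. Extraction normalises each value to
#' scientific notation as a decimal string rather than dividing repeatedly by
#' ten, so binary floating-point artifacts (e.g. the representation of 0.1)
#' cannot shift a digit.
#'
#' @param x Numeric vector of strictly positive, finite values. Zeros,
#'   negative values, missing values and infinities are rejected: a zero has
#'   no non-zero digit, and silently mapping it to one would corrupt a digit
#'   audit.
#'
#' @return Integer vector of digits in `1:9`, same length as `x`.
#'
#' @details The result is scale invariant: `leading_digit(x)` equals
#'   `leading_digit(10 * x)` for any power of ten.
#'
#' @examples
#' leading_digit(c(348, 0.052, 7e9))
#' @export
leading_digit <- function(x) {
  if (!is.numeric(x)) {
    abort("`x` must be numeric to extract leading digits.")
  }
  if (length(x) == 0L) {
    return(integer(0))
  }
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Leading digits are only defined for positive finite values: element %d is %s.",
      i, format(x[i])
    ))
  }
  as.integer(substr(formatC(x, format = "e", digits = 15), 1L, 1L))
}

#' Benford's expected first-digit distribution
#'
#' The analytic first-digit law: a digit `d` leads a "naturally occurring"
#' number with probability `log10(1 + 1/d)`, so digit 1 leads about 30.1% of
#' values and digit 9 about 4.6%.
#'
#' @return A tibble with columns `digit` (integer, 1-9) and `expected`
#'   (probability). The probabilities sum to 1 and decrease strictly in the
#'   digit.
#'
#' @examples
#' benford_expected()
#' @export
benford_expected <- function() {
  d <- 1:9
  tibble(digit = d, expected = log10(1 + 1 / d))
}

#' Observed first-digit distribution
#'
#' Tallies the leading digits of a collection of positive values into
#' relative frequencies over digits 1-9 (digits that never occur get
#' frequency zero; 0 is never a leading digit).
#'
#' @param x Numeric vector of positive finite values; must be non-empty.
#'
#' @return A tibble with columns `digit` (1-9), `n` (count of values leading
#'   with that digit) and `freq` (relative frequency). The number of values
#'   used is attached as attribute `n_values`.
#'
#' @examples
#' digit_distribution(c(1, 1, 2, 9))
#' @export
digit_distribution <- function(x) {
  if (length(x) == 0L) {
    abort("Cannot compute a digit distribution from an empty collection.")
  }
  d <- leading_digit(x)
  n <- tabulate(d, nbins = 9L)
  out <- tibble(digit = 1:9, n = n, freq = n / length(x))
  attr(out, "n_values") <- length(x)
  out
}

#' Benford compliance statistic (regression R-squared)
#'
#' Summarises how well an observed first-digit distribution agrees with
#' Benford's law by the coefficient of determination of the ordinary
#' least-squares simple linear regression of the nine observed frequencies on
#' the nine Benford expected frequencies; with an intercept this equals the
#' squared Pearson correlation between the two 9-vectors.
#'
#' @param x Either a numeric vector of positive abundance values, or a digit
#'   distribution as returned by [digit_distribution()] (any data frame with
#'   `digit` and `freq` columns covering digits 1-9).
#' @param method `"correlation"` (default) for the regression-with-intercept
#'   R-squared, i.e. the squared Pearson correlation, always in \[0, 1\].
#'   `"expected"` treats the Benford frequencies as the prediction itself and
#'   returns `1 - SS_res / SS_tot` about the observed mean; this variant can
#'   be negative for strongly non-conforming data.
#'
#' @return A one-row tibble: `r_squared` (NA when undefined), `n_values`,
#'   `defined` (logical) and `reason` (NA or why the statistic is undefined).
#'   R-squared is undefined when the nine observed frequencies are constant
#'   (e.g. perfectly uniform digits), since the regression response then has
#'   zero variance; such data cannot demonstrate compliance and callers treat
#'   the species as non-compliant.
#'
#' @examples
#' benford_r_squared(c(12, 19, 23, 30, 45, 51, 70, 82, 95, 110))
#' @export
benford_r_squared <- function(x, method = c("correlation", "expected")) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    if (!all(c("digit", "freq") %in% names(x))) {
      abort("A digit-distribution data frame needs `digit` and `freq` columns.")
    }
    if (!setequal(x$digit, 1:9)) {
      abort("A digit distribution must cover digits 1 through 9.")
    }
    freq <- x$freq[order(x$digit)]
    n_values <- attr(x, "n_values") %||% sum(x$n %||% NA_real_)
    if (is.na(n_values)) {
      abort("Cannot recover `n_values` from this digit distribution.")
    }
  } else {
    dist <- digit_distribution(x)
    freq <- dist$freq
    n_values <- attr(dist, "n_values")
  }
  if (n_values <= 0) {
    abort("Benford R-squared requires a distribution observed from at least one value.")
  }
  expected <- benford_expected()$expected
  if (stats::sd(freq) == 0) {
    return(tibble(
      r_squared = NA_real_, n_values = as.integer(n_values),
      defined = FALSE, reason = "constant digit frequencies (zero variance)"
    ))
  }
  r2 <- switch(method,
    correlation = cor(freq, expected)^2,
    expected = 1 - sum((freq - expected)^2) / sum((freq - mean(freq))^2)
  )
  tibble(
    r_squared = r2, n_values = as.integer(n_values),
    defined = TRUE, reason = NA_character_
  )
}
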