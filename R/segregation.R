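#' Chi-square goodness-of-fit test for a phenotypic segregation ratio
#'
#' Tests whether observed mutant and wild-type-like counts fit an expected
#' Mendelian ratio (e.g. 1:3 for a single recessive locus in F2). The
#' statistic is the classical goodness-of-fit form
#' \eqn{\sum (O_i - E_i)^2 / E_i} with expected counts scaled to the
#' observed total, compared against a chi-square distribution with one
#' degree of freedom. A non-significant result (`p_value >= alpha`) means
#' the counts are consistent with the ratio — for 1:3, evidence that the
#' mutation is single-locus recessive, which selects the `RECESSIVE_BSA`
#' design.
#'
#' @param n_mutant observed mutant-phenotype count.
#' @param n_wildtype_like observed wild-type-like count.
#' @param ratio expected mutant:wild-type-like ratio as a length-2 positive
#'   integer vector (default `c(1, 3)`).
#' @param alpha significance level for the fit decision (default 0.05).
#' @param correct apply the Yates continuity correction (default `FALSE`;
#'   the uncorrected statistic is the standard for segregation ratios).
#' @return an object of class `fnb_segregation`: observed and expected
#'   counts, `chi_square`, `degrees_of_freedom` (1), `p_value`,
#'   `fits_ratio`, `alpha`, plus a small-expected-count flag.
#' @examples
#' chisq_segregation(14, 46)        # F2 counts consistent with 1:3
#' chisq_segregation(60, 0)         # clearly not 1:3
#' @export
chisq_segregation <- function(n_mutant, n_wildtype_like, ratio = c(1, 3),
                              alpha = 0.05, correct = FALSE) {
  stopifnot(length(ratio) == 2, all(ratio > 0),
            n_mutant >= 0, n_wildtype_like >= 0)
  obs <- c(mutant = n_mutant, wildtype_like = n_wildtype_like)
  total <- sum(obs)
  if (total == 0) stop("no plants counted: total of observed counts is zero")
  expd <- total * ratio / sum(ratio)
  dev <- abs(obs - expd)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi <- sum(dev^2 / expd)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  if (any(expd < 5))
    warning("expected count below 5; chi-square approximation is unreliable")
  structure(list(observed = obs, expected = setNames(expd, names(obs)),
                 expected_ratio = ratio, chi_square = chi,
                 degrees_of_freedom = 1L, p_value = p,
                 fits_ratio = p >= alpha, alpha = alpha,
                 yates = correct),
            class = "fnb_segregation")
}

#' @export
print.fnb_segregation <- function(x, ...) {
  cat("Segregation chi-square goodness-of-fit\n")
  cat(sprintf("  observed:  %d mutant : %d wild-type-like\n",
              x$observed[1], x$observed[2]))
  cat(sprintf("  expected:  %s (ratio %d:%d)\n",
              paste(format(x$expected, digits = 4), collapse = " : "),
              x$expected_ratio[1], x$expected_ratio[2]))
  cat(sprintf("  X-squared = %.6g, df = %d, p-value = %.4g%s\n",
              x$chi_square, x$degrees_of_freedom, x$p_value,
              if (x$yates) " (Yates-corrected)" else ""))
  cat(sprintf("  fits %d:%d at alpha = %g: %s\n",
              x$expected_ratio[1], x$expected_ratio[2], x$alpha,
              if (x$fits_ratio) "yes" else "no"))
  invisible(x)
}
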