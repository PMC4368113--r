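## Regression and comparison tests used in the breeding-system analysis:
## Poisson log-link GLM with a likelihood-ratio test, and Welch's t from
## summary statistics.

#' Poisson regression of reproductive success
#'
#' Maximum-likelihood fit of \eqn{\log E[y] = a + b x} (Poisson family,
#' log link, fitted by iteratively reweighted least squares with
#' deviance tolerance 1e-10 and at most 100 iterations), with a
#' likelihood-ratio chi-square test against the intercept-only model
#' (1 df).
#'
#' @param y non-negative integer response (e.g. offspring or partner
#'   counts).
#' @param x numeric covariate (e.g. fork length, partner count).
#' @return list with \code{intercept}, \code{slope}, \code{chiSquare}
#'   (likelihood-ratio statistic), \code{pValue}, \code{n}, and the
#'   underlying \code{fit} object.
#' @export
poissonGlm <- function(y, x) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  if (length(y) != length(x)) .stopf("y and x must have equal length")
  if (length(y) < 3L) .stopf("at least 3 observations are required")
  if (any(y < 0) || any(y != round(y)))
    .stopf("y must be non-negative integers")
  if (all(y == 0)) .stopf("all-zero response")
  if (!all(is.finite(x))) .stopf("x must be finite")
  if (stats::var(x) == 0) {
    ## degenerate covariate: the model collapses to the intercept-only
    ## fit, whose MLE is the log mean
    return(list(intercept = log(mean(y)), slope = 0,
                chiSquare = 0, pValue = 1, n = length(y), fit = NULL))
  }
  fit <- stats::glm(y ~ x, family = stats::poisson(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100L))
  if (!fit$converged)
    .stopf("IRLS did not converge in %d iterations (deviance %.6g)",
           fit$iter, fit$deviance)
  chi2 <- fit$null.deviance - fit$deviance
  list(intercept = unname(stats::coef(fit)[1L]),
       slope = unname(stats::coef(fit)[2L]),
       chiSquare = chi2,
       pValue = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       n = length(y),
       fit = fit)
}

#' Welch two-sample t-test from summary statistics
#'
#' Computes \eqn{t = (\bar x_1 - \bar x_2) / \sqrt{s_1^2/n_1 +
#' s_2^2/n_2}} with the Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value. Operates on printed summaries (means, SDs, sample
#' sizes) rather than raw vectors.
#'
#' @param mean1,sd1,n1 summary of the first group.
#' @param mean2,sd2,n2 summary of the second group.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @examples
#' welchT(288, 19, 57, 321, 28, 97)$t  # female vs male fork length
#' @export
welchT <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df,
       p = 2 * stats::pt(abs(t), df = df, lower.tail = FALSE))
}
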