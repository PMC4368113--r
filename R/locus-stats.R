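## Per-locus summary statistics: allele frequencies, heterozygosities,
## PIC, Hardy-Weinberg tests and probability of identity.

#' Estimate allele frequencies
#'
#' Direct gene-count estimates per locus: heterozygotes contribute one
#' copy of each allele, homozygotes two, divided by twice the number of
#' typed individuals.
#'
#' @param table a [GenotypeTable-class].
#' @return an [AlleleFreqTable-class].
#' @examples
#' tab <- GenotypeTable(
#'   matrix(c(101L, 101L), 2, 1, dimnames = list(c("i1","i2"), "L1")),
#'   matrix(c(101L, 105L), 2, 1, dimnames = list(c("i1","i2"), "L1")))
#' locusFrequencies(alleleFrequencies(tab), "L1")  # 101: 0.75, 105: 0.25
#' @export
alleleFrequencies <- function(table) {
  am <- alleleMatrices(table)
  loci <- lociNames(table)
  freqs <- vector("list", length(loci))
  names(freqs) <- loci
  n_typed <- integer(length(loci))
  names(n_typed) <- loci
  for (j in seq_along(loci)) {
    al <- c(am$a[, j], am$b[, j])
    al <- al[!is.na(al)]
    if (!length(al))
      .stopf("locus %s has no typed individuals", loci[j])
    tab <- table(al)
    freqs[[j]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
    n_typed[j] <- length(al) %/% 2L
  }
  new("AlleleFreqTable", freqs = freqs, nTyped = n_typed)
}

## Nei's unbiased expected heterozygosity from frequencies + sample size.
.unbiasedHe <- function(p, n) {
  if (length(p) < 2L) return(0)
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

## Botstein's polymorphic information content.
.pic <- function(p) {
  if (length(p) < 2L) return(0)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

## Chi-square goodness of fit of genotype counts to Hardy-Weinberg
## proportions. Genotype classes with expected count < 1 are pooled into
## a single class; df = (classes after pooling) - (number of alleles).
.hweChisq <- function(a, b, p) {
  keep <- !is.na(a)
  a <- a[keep]
  b <- b[keep]
  n <- length(a)
  alleles <- as.integer(names(p))
  k <- length(alleles)
  if (k < 2L || n < 1L) return(NA_real_)
  idx <- expand.grid(i = seq_len(k), j = seq_len(k))
  idx <- idx[idx$i <= idx$j, ]
  expd <- ifelse(idx$i == idx$j,
                 n * p[idx$i]^2,
                 2 * n * p[idx$i] * p[idx$j])
  obs <- mapply(function(i, j) {
    sum(a == alleles[i] & b == alleles[j])
  }, idx$i, idx$j)
  pool <- expd < 1
  if (any(pool)) {
    obs <- c(obs[!pool], sum(obs[pool]))
    expd <- c(expd[!pool], sum(expd[pool]))
  }
  df <- length(obs) - k
  if (df < 1L) return(NA_real_)
  chi2 <- sum((obs - expd)^2 / expd)
  stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Per-locus genetic-diversity summaries
#'
#' For every locus: allele count (Na), observed heterozygosity (Ho),
#' Nei's unbiased expected heterozygosity \eqn{He = 2n/(2n-1) (1 - \sum
#' p_i^2)}, Botstein's polymorphic information content
#' \eqn{PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}, and a
#' chi-square Hardy-Weinberg goodness-of-fit p-value (classes with
#' expected count below 1 pooled; NA for monomorphic loci or when no
#' degrees of freedom remain). A Bonferroni-adjusted p-value across loci
#' is included for multiple-testing control.
#'
#' @param table a [GenotypeTable-class].
#' @return a data.frame with columns \code{Locus}, \code{Na}, \code{n},
#'   \code{Ho}, \code{He}, \code{PIC}, \code{hwe_p}, \code{hwe_p_adj}.
#' @export
locusSummaries <- function(table) {
  af <- alleleFrequencies(table)
  am <- alleleMatrices(table)
  loci <- lociNames(table)
  out <- data.frame(Locus = loci, Na = NA_integer_, n = NA_integer_,
                    Ho = NA_real_, He = NA_real_, PIC = NA_real_,
                    hwe_p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    p <- af@freqs[[j]]
    n <- af@nTyped[[j]]
    a <- am$a[, j]
    b <- am$b[, j]
    typed <- !is.na(a)
    out$Na[j] <- length(p)
    out$n[j] <- n
    out$Ho[j] <- if (length(p) < 2L) 0 else mean(a[typed] != b[typed])
    out$He[j] <- .unbiasedHe(p, n)
    out$PIC[j] <- .pic(p)
    out$hwe_p[j] <- .hweChisq(a, b, p)
  }
  out$hwe_p_adj <- pmin(1, out$hwe_p * sum(!is.na(out$hwe_p)))
  out
}

#' Probability of identity
#'
#' Per-locus probability that two unrelated individuals share a genotype,
#' \eqn{PI = \sum p_i^4 + \sum_{i<j} (2 p_i p_j)^2}, and the multi-locus
#' product over the requested loci. Used to judge whether a multilocus
#' match analysis can safely treat identical genotypes as duplicate
#' samples of one individual.
#'
#' @param freqs an [AlleleFreqTable-class].
#' @param loci character vector of locus names (default: all).
#' @return list with \code{perLocus} (named numeric) and \code{product}.
#' @examples
#' tab <- GenotypeTable(
#'   matrix(c(1L, 1L, 2L, 1L), 4, 1, dimnames = list(paste0("i", 1:4), "L1")),
#'   matrix(c(1L, 2L, 2L, 2L), 4, 1, dimnames = list(paste0("i", 1:4), "L1")))
#' probabilityOfIdentity(alleleFrequencies(tab))$product  # 0.375 at p = q
#' @export
probabilityOfIdentity <- function(freqs, loci = NULL) {
  if (is.null(loci)) loci <- names(freqs@freqs)
  if (!length(loci)) .stopf("empty locus subset")
  bad <- setdiff(loci, names(freqs@freqs))
  if (length(bad)) .stopf("unknown locus: %s", paste(bad, collapse = ", "))
  per <- vapply(freqs@freqs[loci], function(p) {
    s2 <- sum(p^2)
    s4 <- sum(p^4)
    2 * s2^2 - s4
  }, numeric(1))
  list(perLocus = per, product = prod(per))
}
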