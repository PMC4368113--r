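## Effective number of breeders from family-size variance, with a
## percentile bootstrap over the per-candidate offspring counts.

.nbOneSex <- function(counts) {
  N <- length(counts)
  k <- mean(counts)
  V <- stats::var(counts)
  Nb <- k * (N - 1) / (1 + V / k)
  list(N = N, k = k, V = V, Nb = Nb)
}

.nbCombine <- function(Nbf, Nbm) 4 * Nbf * Nbm / (Nbf + Nbm)

#' Effective number of breeders with bootstrap CI
#'
#' Per-sex effective numbers of breeders from the mean and variance of
#' per-candidate offspring counts,
#' \deqn{N_{bf} = k_f (N_f - 1) / (1 + V_{kf} / k_f),}
#' analogously for males, combined as
#' \deqn{N_b = 4 N_{bf} N_{bm} / (N_{bf} + N_{bm}).}
#' The 95% confidence interval is a percentile bootstrap: each sex's
#' count vector is resampled with replacement (same length), the
#' combined \eqn{N_b} recomputed, and the 2.5% and 97.5% percentiles
#' taken over \code{nReps} replicates. Fully reproducible from
#' \code{seed}.
#'
#' Under the \code{"all"} convention (default) the count vectors must
#' cover every candidate breeder of each sex, zeros included; variances
#' use the n-1 denominator. \code{"successful"} restricts to breeders
#' with at least one offspring before computing anything.
#'
#' @param countsF,countsM non-negative integer vectors of offspring
#'   counts over the candidate dams and sires.
#' @param nReps bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (optional).
#' @param convention \code{"all"} or \code{"successful"}.
#' @return an [NbEstimate-class].
#' @examples
#' est <- estimateNb(rep(2L, 10), rep(2L, 10), nReps = 100, seed = 1)
#' nbOf(est)  # V = 0, so Nbf = Nbm = k (N - 1) = 18 and Nb = 18 exactly
#' @export
estimateNb <- function(countsF, countsM, nReps = 1000L, seed = NULL,
                       convention = c("all", "successful")) {
  convention <- match.arg(convention)
  countsF <- as.numeric(countsF)
  countsM <- as.numeric(countsM)
  if (any(countsF < 0) || any(countsM < 0))
    .stopf("offspring counts must be non-negative")
  if (convention == "successful") {
    countsF <- countsF[countsF > 0]
    countsM <- countsM[countsM > 0]
  }
  if (length(countsF) < 2L || length(countsM) < 2L)
    .stopf("at least 2 candidate breeders per sex are required")
  ## the estimator is a function of the count multisets; sorting makes
  ## the bootstrap bit-reproducible under permutation of the input
  countsF <- sort(countsF)
  countsM <- sort(countsM)
  if (mean(countsF) == 0 || mean(countsM) == 0)
    .stopf("no reproduction observed for one sex")
  f <- .nbOneSex(countsF)
  m <- .nbOneSex(countsM)
  nb <- .nbCombine(f$Nb, m$Nb)
  reps <- .withSeed(seed, {
    vapply(seq_len(nReps), function(r) {
      bf <- sample(countsF, replace = TRUE)
      bm <- sample(countsM, replace = TRUE)
      if (mean(bf) == 0 || mean(bm) == 0) return(NA_real_)
      .nbCombine(.nbOneSex(bf)$Nb, .nbOneSex(bm)$Nb)
    }, numeric(1))
  })
  ci <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  new("NbEstimate",
      Nf = f$N, Nm = m$N, kf = f$k, km = m$k,
      Vkf = f$V, Vkm = m$V, Nbf = f$Nb, Nbm = m$Nb, Nb = nb,
      ciLow = ci[1L], ciHigh = ci[2L],
      nReps = as.integer(nReps),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      convention = convention)
}

#' @describeIn estimateNb the combined point estimate
#' @param x an \code{NbEstimate}
#' @export
nbOf <- function(x) x@Nb

#' @describeIn estimateNb the bootstrap confidence interval as
#'   \code{c(low, high)}
#' @export
nbConfint <- function(x) c(x@ciLow, x@ciHigh)

#' @describeIn estimateNb all components as a plain list (for JSON
#'   export)
#' @export
nbAsList <- function(x) {
  list(N_f = x@Nf, N_m = x@Nm, k_f = x@kf, k_m = x@km,
       V_kf = x@Vkf, V_km = x@Vkm, N_bf = x@Nbf, N_bm = x@Nbm,
       N_b = x@Nb, ci_low = x@ciLow, ci_high = x@ciHigh,
       n_reps = x@nReps, seed = x@seed, convention = x@convention)
}

setMethod("show", "NbEstimate", function(object) {
  cat(sprintf(
    "NbEstimate (%s candidates): Nb = %.1f (95%% CI %.1f-%.1f)\n",
    object@convention, object@Nb, object@ciLow, object@ciHigh))
  cat(sprintf("  females: N = %d, k = %.2f, Vk = %.2f, Nbf = %.1f\n",
              object@Nf, object@kf, object@Vkf, object@Nbf))
  cat(sprintf("  males:   N = %d, k = %.2f, Vk = %.2f, Nbm = %.1f\n",
              object@Nm, object@km, object@Vkm, object@Nbm))
  cat(sprintf("  bootstrap: %d replicates, seed %s\n", object@nReps,
              ifelse(is.na(object@seed), "none", object@seed)))
  invisible(NULL)
})
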