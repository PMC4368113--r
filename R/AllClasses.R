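#' @import methods
NULL

#' GenotypeTable: individuals by loci codominant genotypes
#'
#' The common currency of the package: unordered diploid allele pairs
#' (integer fragment lengths in base pairs) for a set of individuals at a
#' shared locus panel, together with per-individual metadata (sex, fork
#' length, cohort). Missing genotypes are stored as \code{NA} in both
#' allele slots; a genotype is either fully present or fully missing.
#'
#' @slot alleleA integer matrix (individuals x loci) of the smaller allele
#'   of each genotype; \code{NA} = missing. Row names are individual ids,
#'   column names are locus names.
#' @slot alleleB integer matrix of the larger allele, same shape.
#' @slot sex character vector per individual: \code{"F"}, \code{"M"} or
#'   \code{"U"} (unknown).
#' @slot forkLength numeric vector per individual, fork length in mm
#'   (\code{NA} when unmeasured).
#' @slot cohort character vector per individual: \code{"ADULT"} or
#'   \code{"FRY"}.
#'
#' @seealso [GenotypeTable()] for the constructor, [readGenotypes()] for
#'   file input.
#' @export
setClass("GenotypeTable",
  representation(
    alleleA = "matrix",
    alleleB = "matrix",
    sex = "character",
    forkLength = "numeric",
    cohort = "character"
  )
)

setValidity("GenotypeTable", function(object) {
  a <- object@alleleA
  b <- object@alleleB
  msg <- character()
  if (!is.integer(a) || !is.integer(b))
    msg <- c(msg, "allele matrices must be integer")
  if (!identical(dim(a), dim(b)))
    msg <- c(msg, "allele matrices must have identical dimensions")
  if (ncol(a) < 1L)
    msg <- c(msg, "at least one locus is required")
  ids <- rownames(a)
  if (nrow(a) > 0L && (is.null(ids) || anyNA(ids) || any(ids == "")))
    msg <- c(msg, "individual ids (row names) are required")
  else if (!is.null(ids) && anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate id: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (is.null(colnames(a)) || anyDuplicated(colnames(a)))
    msg <- c(msg, "unique locus names (column names) are required")
  if (any(xor(is.na(a), is.na(b))))
    msg <- c(msg, "half-called genotypes are not allowed")
  if (any(!is.na(a) & (a < 1L | b < 1L)))
    msg <- c(msg, "alleles must be positive integers")
  if (any(!is.na(a) & a > b))
    msg <- c(msg, "alleleA must be <= alleleB")
  n <- nrow(a)
  if (length(object@sex) != n || length(object@forkLength) != n ||
      length(object@cohort) != n)
    msg <- c(msg, "metadata vectors must match the number of individuals")
  if (!all(object@sex %in% c("F", "M", "U")))
    msg <- c(msg, "sex must be one of 'F', 'M', 'U'")
  if (!all(object@cohort %in% c("ADULT", "FRY")))
    msg <- c(msg, "cohort must be 'ADULT' or 'FRY'")
  if (any(!is.na(object@forkLength) & object@forkLength <= 0))
    msg <- c(msg, "fork lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' AlleleFreqTable: per-locus allele relative frequencies
#'
#' Population allele frequencies per locus plus the number of typed
#' (non-missing) individuals behind each estimate. Drives the Mendelian
#' likelihoods, probability of identity, expected heterozygosity and PIC.
#'
#' @slot freqs named list, one element per locus: a named numeric vector
#'   of relative frequencies (names are allele sizes in bp), each summing
#'   to 1 and strictly positive.
#' @slot nTyped named integer vector, typed individuals per locus.
#'
#' @seealso [alleleFrequencies()]
#' @export
setClass("AlleleFreqTable",
  representation(freqs = "list", nTyped = "integer")
)

setValidity("AlleleFreqTable", function(object) {
  msg <- character()
  if (length(object@freqs) < 1L)
    msg <- c(msg, "at least one locus is required")
  if (is.null(names(object@freqs)) || anyDuplicated(names(object@freqs)))
    msg <- c(msg, "unique locus names are required")
  if (!identical(names(object@freqs), names(object@nTyped)))
    msg <- c(msg, "freqs and nTyped must share locus names")
  for (loc in names(object@freqs)) {
    p <- object@freqs[[loc]]
    if (is.null(names(p)))
      msg <- c(msg, sprintf("locus %s: allele names required", loc))
    if (any(p <= 0))
      msg <- c(msg, sprintf("locus %s: frequencies must be > 0", loc))
    if (abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, sprintf("locus %s: frequencies must sum to 1", loc))
    if (object@nTyped[[loc]] < 1L)
      msg <- c(msg, sprintf("locus %s: nTyped must be >= 1", loc))
  }
  if (length(msg)) msg else TRUE
})

#' NbEstimate: effective number of breeders with bootstrap CI
#'
#' Per-sex and combined effective-breeder numbers computed from the
#' family-size (offspring-count) distributions of candidate dams and
#' sires, with a percentile-bootstrap confidence interval for the
#' combined estimate.
#'
#' @slot Nf,Nm candidate female/male breeder counts.
#' @slot kf,km mean offspring per candidate, by sex.
#' @slot Vkf,Vkm variance (n-1 denominator) of offspring per candidate.
#' @slot Nbf,Nbm per-sex effective numbers of breeders.
#' @slot Nb combined effective number of breeders (harmonic combination).
#' @slot ciLow,ciHigh percentile bootstrap bounds for \code{Nb}.
#' @slot nReps number of bootstrap replicates.
#' @slot seed RNG seed used for the bootstrap (NA if none supplied).
#' @slot convention \code{"all"} (all candidates, zeros included) or
#'   \code{"successful"} (breeders with at least one offspring).
#'
#' @seealso [estimateNb()]
#' @export
setClass("NbEstimate",
  representation(
    Nf = "integer", Nm = "integer",
    kf = "numeric", km = "numeric",
    Vkf = "numeric", Vkm = "numeric",
    Nbf = "numeric", Nbm = "numeric",
    Nb = "numeric",
    ciLow = "numeric", ciHigh = "numeric",
    nReps = "integer", seed = "integer",
    convention = "character"
  )
)

setValidity("NbEstimate", function(object) {
  msg <- character()
  if (object@Nbf > object@kf * (object@Nf - 1) + 1e-9)
    msg <- c(msg, "Nbf exceeds its formula bound kf*(Nf-1)")
  if (object@Nbm > object@km * (object@Nm - 1) + 1e-9)
    msg <- c(msg, "Nbm exceeds its formula bound km*(Nm-1)")
  if (object@Nb > 2 * max(object@Nbf, object@Nbm) + 1e-9)
    msg <- c(msg, "Nb exceeds 2*max(Nbf, Nbm)")
  if (length(object@ciLow) == 1L && length(object@ciHigh) == 1L &&
      !is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh + 1e-12)
    msg <- c(msg, "ciLow must be <= ciHigh")
  if (!object@convention %in% c("all", "successful"))
    msg <- c(msg, "convention must be 'all' or 'successful'")
  if (length(msg)) msg else TRUE
})
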