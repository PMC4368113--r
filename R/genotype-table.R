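#' Construct a GenotypeTable
#'
#' Builds and validates a [GenotypeTable-class] from two allele matrices.
#' Genotypes are unordered: the pair is canonicalised so the smaller
#' allele is stored first. Half-called genotypes (exactly one allele
#' missing) are coerced to fully missing with a warning.
#'
#' @param alleleA,alleleB integer matrices (individuals x loci) of allele
#'   fragment lengths in bp; \code{NA} (or the conventional code 0, see
#'   [readGenotypes()]) marks a missing allele. Row names are individual
#'   ids, column names locus names.
#' @param sex character vector per individual (\code{"F"}, \code{"M"},
#'   \code{"U"}); defaults to unknown.
#' @param forkLength numeric vector of fork lengths in mm (\code{NA}
#'   allowed).
#' @param cohort \code{"ADULT"} or \code{"FRY"}, recycled.
#' @return a validated [GenotypeTable-class].
#' @examples
#' a <- matrix(c(101L, 103L), 1, 2,
#'             dimnames = list("ind1", c("locA", "locB")))
#' b <- matrix(c(105L, 103L), 1, 2,
#'             dimnames = list("ind1", c("locA", "locB")))
#' GenotypeTable(a, b, sex = "F", cohort = "ADULT")
#' @export
GenotypeTable <- function(alleleA, alleleB, sex = NULL, forkLength = NULL,
                          cohort = "ADULT") {
  alleleA <- as.matrix(alleleA)
  alleleB <- as.matrix(alleleB)
  storage.mode(alleleA) <- "integer"
  storage.mode(alleleB) <- "integer"
  n <- nrow(alleleA)
  if (is.null(sex)) sex <- rep("U", n)
  if (is.null(forkLength)) forkLength <- rep(NA_real_, n)
  cohort <- rep(as.character(cohort), length.out = n)
  sex <- rep(as.character(sex), length.out = n)
  forkLength <- rep(as.numeric(forkLength), length.out = n)
  pair <- .canonicalisePair(alleleA, alleleB)
  new("GenotypeTable", alleleA = pair$a, alleleB = pair$b,
      sex = sex, forkLength = forkLength, cohort = cohort)
}

#' @describeIn GenotypeTable number of individuals
#' @param x,object a \code{GenotypeTable}
#' @export
nIndividuals <- function(x) nrow(x@alleleA)

#' @describeIn GenotypeTable number of loci
#' @export
nLoci <- function(x) ncol(x@alleleA)

#' @describeIn GenotypeTable individual ids
#' @export
individualIds <- function(x) rownames(x@alleleA)

#' @describeIn GenotypeTable locus names
#' @export
lociNames <- function(x) colnames(x@alleleA)

#' @describeIn GenotypeTable per-individual sex ("F", "M" or "U")
#' @export
sexOf <- function(x) stats::setNames(x@sex, individualIds(x))

#' @describeIn GenotypeTable per-individual fork length (mm)
#' @export
forkLengthOf <- function(x) stats::setNames(x@forkLength, individualIds(x))

#' @describeIn GenotypeTable per-individual cohort
#' @export
cohortOf <- function(x) stats::setNames(x@cohort, individualIds(x))

#' @describeIn GenotypeTable the two allele matrices as a list
#'   \code{list(a = , b = )}
#' @export
alleleMatrices <- function(x) list(a = x@alleleA, b = x@alleleB)

#' @describeIn GenotypeTable logical matrix of missing genotypes
#' @export
isMissingGenotype <- function(x) is.na(x@alleleA)

#' Subset a GenotypeTable
#'
#' `x[i, j]` subsets individuals (`i`, by index, id or logical) and loci
#' (`j`, by index, name or logical), keeping metadata aligned.
#'
#' @param x a [GenotypeTable-class]
#' @param i individual selector
#' @param j locus selector
#' @param ... ignored
#' @param drop ignored (always \code{FALSE})
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nIndividuals(x))
  if (missing(j)) j <- seq_len(nLoci(x))
  if (is.character(i)) i <- match(i, individualIds(x))
  if (anyNA(i)) .stopf("unknown individual id in subset")
  ii <- seq_len(nIndividuals(x))[i]
  new("GenotypeTable",
      alleleA = x@alleleA[ii, j, drop = FALSE],
      alleleB = x@alleleB[ii, j, drop = FALSE],
      sex = x@sex[ii], forkLength = x@forkLength[ii],
      cohort = x@cohort[ii])
})

#' Combine two GenotypeTables over the same locus panel
#'
#' Stacks individuals of `x` and `y`; the locus panels must be identical
#' (same names, same order) and ids must not clash.
#'
#' @param x,y [GenotypeTable-class] objects
#' @return a combined [GenotypeTable-class]
#' @export
combineTables <- function(x, y) {
  if (!identical(lociNames(x), lociNames(y)))
    .stopf("cannot combine tables with different locus panels")
  new("GenotypeTable",
      alleleA = rbind(x@alleleA, y@alleleA),
      alleleB = rbind(x@alleleB, y@alleleB),
      sex = c(x@sex, y@sex),
      forkLength = c(x@forkLength, y@forkLength),
      cohort = c(x@cohort, y@cohort))
}

setMethod("show", "GenotypeTable", function(object) {
  n <- nIndividuals(object)
  miss <- mean(is.na(object@alleleA))
  cat(sprintf(
    "GenotypeTable: %d individuals x %d loci (%.1f%% missing)\n",
    n, nLoci(object), 100 * miss))
  tab <- table(factor(object@sex, levels = c("F", "M", "U")))
  cat(sprintf("  sex: %d F / %d M / %d unknown; cohorts: %s\n",
              tab[["F"]], tab[["M"]], tab[["U"]],
              paste(names(table(object@cohort)), table(object@cohort),
                    sep = ":", collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "AlleleFreqTable", function(object) {
  na <- vapply(object@freqs, length, integer(1))
  cat(sprintf("AlleleFreqTable: %d loci, %d-%d alleles, median n typed %d\n",
              length(object@freqs), min(na), max(na),
              as.integer(stats::median(object@nTyped))))
  invisible(NULL)
})

#' @describeIn alleleFrequencies frequencies of one locus as a named
#'   numeric vector
#' @param freqs an [AlleleFreqTable-class]
#' @param locus locus name
#' @export
locusFrequencies <- function(freqs, locus) {
  if (!locus %in% names(freqs@freqs)) .stopf("unknown locus: %s", locus)
  freqs@freqs[[locus]]
}

#' @describeIn alleleFrequencies typed-sample sizes per locus
#' @export
nTypedOf <- function(freqs) freqs@nTyped
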