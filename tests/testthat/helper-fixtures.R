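## Small in-code fixture builders shared across test files.

## Build a GenotypeTable from a list of per-individual genotype lists:
## genos = list(id1 = list(c(a, b), c(a, b), ...), ...). NA pairs mark
## missing genotypes.
makeTab <- function(genos, loci = NULL, sex = NULL, forkLength = NULL,
                    cohort = "ADULT") {
  n <- length(genos)
  L <- length(genos[[1L]])
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  a <- matrix(NA_integer_, n, L, dimnames = list(names(genos), loci))
  b <- a
  for (i in seq_len(n)) for (l in seq_len(L)) {
    g <- genos[[i]][[l]]
    if (!anyNA(g)) {
      a[i, l] <- as.integer(g[1L])
      b[i, l] <- as.integer(g[2L])
    }
  }
  GenotypeTable(a, b, sex = sex, forkLength = forkLength, cohort = cohort)
}

## A frequency table built directly from explicit frequencies.
makeFreqs <- function(freqList, nTyped = 50L) {
  new("AlleleFreqTable", freqs = freqList,
      nTyped = stats::setNames(rep(as.integer(nTyped),
                                   length(freqList)),
                               names(freqList)))
}

## Random genotype table drawn from given allele frequencies (HW), with
## optional missingness; used by property-style tests.
randomTab <- function(n, freqList, missingRate = 0, cohort = "ADULT",
                      sex = NULL, prefix = "ind") {
  L <- length(freqList)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  a <- matrix(NA_integer_, n, L, dimnames = list(ids, names(freqList)))
  b <- a
  for (l in seq_len(L)) {
    al <- as.integer(names(freqList[[l]]))
    a[, l] <- sample(al, n, replace = TRUE, prob = freqList[[l]])
    b[, l] <- sample(al, n, replace = TRUE, prob = freqList[[l]])
  }
  if (missingRate > 0) {
    mis <- matrix(stats::runif(n * L) < missingRate, n, L)
    a[mis] <- NA_integer_
    b[mis] <- NA_integer_
  }
  GenotypeTable(a, b, sex = sex, cohort = cohort)
}

## A compact study configuration that keeps simulation-heavy tests fast.
smallStudyConfig <- function(seed = 11L, ...) {
  simulationConfig(seed = seed, nDams = 12L, nSires = 16L,
                   nFry = 120L, ...)
}
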