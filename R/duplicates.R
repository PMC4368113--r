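## Multilocus match analysis: detect samples that are genotype-identical
## at every mutually typed locus (fragmented individuals genotyped more
## than once) and deduplicate the table.

#' Find duplicate samples by multilocus matching
#'
#' Two samples are declared duplicates when they carry identical
#' genotypes at every locus where both are typed, provided at least
#' \code{minSharedLoci} loci are mutually typed. Duplicate groups are the
#' transitive closure of pairwise matches. Within each group the sample
#' with the fewest missing loci is retained (ties broken by
#' lexicographically smallest id).
#'
#' @param table a [GenotypeTable-class].
#' @param minSharedLoci minimum number of mutually typed loci required
#'   before two samples can be compared (default 10).
#' @return a list with elements
#'   \describe{
#'     \item{groups}{list of id vectors, one per duplicate group (size
#'       >= 2), retained sample first;}
#'     \item{kept}{ids retained from duplicate groups;}
#'     \item{removed}{ids dropped;}
#'     \item{table}{the deduplicated [GenotypeTable-class];}
#'     \item{report}{data.frame (group, id, n_missing, retained).}
#'   }
#' @export
findDuplicates <- function(table, minSharedLoci = 10L) {
  minSharedLoci <- as.integer(minSharedLoci)
  if (minSharedLoci < 1L) .stopf("minSharedLoci must be >= 1")
  am <- alleleMatrices(table)
  n <- nIndividuals(table)
  ids <- individualIds(table)
  ## encode each genotype as a single comparable number (alleles < 1e5)
  code <- am$a * 100000 + am$b
  pairs <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      eq <- code[rest, , drop = FALSE] == rep(code[i, ], each = length(rest))
      shared <- rowSums(!is.na(eq))
      match_all <- rowSums(eq, na.rm = TRUE) == shared
      hit <- shared >= minSharedLoci & match_all
      if (any(hit))
        pairs[[length(pairs) + 1L]] <- cbind(i, rest[hit])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(), 0L, 2L)
  comp <- .unionFind(n, pairs)
  n_missing <- rowSums(is.na(am$a))
  groups <- list()
  keep <- rep(TRUE, n)
  kept <- character()
  removed <- character()
  rep_rows <- list()
  for (g in unique(comp[duplicated(comp)])) {
    members <- which(comp == g)
    ## retain fewest-missing, ties by id order
    ord <- order(n_missing[members], ids[members])
    members <- members[ord]
    groups[[length(groups) + 1L]] <- ids[members]
    kept <- c(kept, ids[members[1L]])
    removed <- c(removed, ids[members[-1L]])
    keep[members[-1L]] <- FALSE
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      group = length(groups), id = ids[members],
      n_missing = n_missing[members],
      retained = seq_along(members) == 1L,
      stringsAsFactors = FALSE)
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(group = integer(), id = character(),
               n_missing = integer(), retained = logical(),
               stringsAsFactors = FALSE)
  list(groups = groups, kept = kept, removed = removed,
       table = table[keep, ], report = report)
}
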