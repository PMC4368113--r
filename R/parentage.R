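## Parentage assignment: Mendelian transition probabilities with a
## genotyping-error mixture, exclusion (mismatch) counting, and exact
## enumeration of the categorical posterior over (dam, sire) hypotheses.

#' Parentage-analysis configuration
#'
#' Settings for [enumeratePosteriors()] and [assignParentage()]. The
#' defaults correspond to a standard stringent assignment protocol:
#' at most one allowed parent-offspring exclusion and a 90% assignment
#' probability cutoff.
#'
#' @param errorRate per-locus genotyping error rate used in the
#'   likelihood mixture \eqn{(1-e) L_{mendel} + e P_{HW}} (default 0.01).
#' @param maxMismatch maximum tolerated single-parent exclusions before a
#'   candidate is removed from the hypothesis set (default 1).
#' @param confidenceCutoff minimum posterior probability for reporting an
#'   assignment (default 0.90); posteriors exactly at the cutoff are
#'   assigned.
#' @param nUnsampledDams,nUnsampledSires prior weight of the unsampled
#'   parent class per sex; \code{NULL} (default) means half the number of
#'   sampled candidates of that sex.
#' @param minTypedLoci minimum typed loci for an offspring to be
#'   testable (default 10).
#' @return a list of class \code{ParentageConfig}.
#' @export
parentageConfig <- function(errorRate = 0.01, maxMismatch = 1L,
                            confidenceCutoff = 0.90,
                            nUnsampledDams = NULL,
                            nUnsampledSires = NULL,
                            minTypedLoci = 10L) {
  stopifnot(errorRate >= 0, errorRate < 1,
            maxMismatch >= 0,
            confidenceCutoff > 0, confidenceCutoff <= 1,
            minTypedLoci >= 1)
  if (!is.null(nUnsampledDams)) stopifnot(nUnsampledDams >= 0)
  if (!is.null(nUnsampledSires)) stopifnot(nUnsampledSires >= 0)
  structure(list(errorRate = errorRate,
                 maxMismatch = as.integer(maxMismatch),
                 confidenceCutoff = confidenceCutoff,
                 nUnsampledDams = nUnsampledDams,
                 nUnsampledSires = nUnsampledSires,
                 minTypedLoci = as.integer(minTypedLoci)),
            class = "ParentageConfig")
}

## --- scalar per-locus transition kernels ------------------------------

## both parents typed: average over the four equiprobable transmissions
.transBoth <- function(o1, o2, d1, d2, s1, s2) {
  m <- function(x, y) (x == o1 & y == o2) | (x == o2 & y == o1)
  0.25 * (m(d1, s1) + m(d1, s2) + m(d2, s1) + m(d2, s2))
}

## one parent typed: transmitted allele uniform over the parent's two,
## the other allele drawn from population frequencies p (named by allele)
.transSingle <- function(o1, o2, d1, d2, p) {
  p1 <- unname(p[as.character(o1)])
  p2 <- unname(p[as.character(o2)])
  if (o1 == o2) {
    0.5 * ((d1 == o1) + (d2 == o1)) * p1
  } else {
    0.5 * ((d1 == o1) + (d2 == o1)) * p2 +
      0.5 * ((d1 == o2) + (d2 == o2)) * p1
  }
}

## no parent: Hardy-Weinberg genotype frequency
.transNone <- function(o1, o2, p) {
  p1 <- unname(p[as.character(o1)])
  p2 <- unname(p[as.character(o2)])
  if (o1 == o2) p1^2 else 2 * p1 * p2
}

.checkAllele <- function(allele, p, locus) {
  bad <- !is.na(allele) & !(as.character(allele) %in% names(p))
  if (any(bad))
    .stopf("locus %s: allele %s absent from frequency table",
           locus, paste(unique(allele[bad]), collapse = ", "))
}

.asGenoMatrix <- function(g, loci) {
  if (is.null(g)) return(NULL)
  if (is.vector(g) && length(g) == 2L) g <- matrix(g, 1L, 2L)
  g <- as.matrix(g)
  if (ncol(g) != 2L) .stopf("genotypes must have two allele columns")
  if (nrow(g) != length(loci))
    .stopf("genotype has %d loci, expected %d", nrow(g), length(loci))
  g
}

#' Per-locus Mendelian transition likelihood
#'
#' Probability of the offspring genotype given zero, one or two parental
#' genotypes, with a genotyping-error mixture. With both parents the
#' four parental transmissions are equiprobable; with one parent the
#' transmitted allele is uniform over the parent's two alleles and the
#' other allele is drawn from the population frequencies; with no parent
#' the offspring follows Hardy-Weinberg proportions. The observed-data
#' likelihood is \eqn{(1-e) L_{mendel} + e P_{HW}(g_{off})}. A missing
#' genotype in the offspring or in a supplied parent makes that locus
#' contribute a factor of 1.
#'
#' @param offspring,dam,sire genotypes as loci-by-2 integer matrices (or
#'   length-2 vectors for a single locus); \code{dam}/\code{sire} may be
#'   \code{NULL} (unsampled). \code{NA} marks missing.
#' @param freqs an [AlleleFreqTable-class].
#' @param errorRate per-locus genotyping error rate \eqn{e \in [0, 1)}.
#' @param loci locus names the rows refer to; defaults to the row names
#'   of \code{offspring} or, failing that, the first loci of
#'   \code{freqs}.
#' @return numeric vector of per-locus likelihoods.
#' @examples
#' af <- new("AlleleFreqTable",
#'           freqs = list(L1 = c(`1` = 0.5, `2` = 0.5)),
#'           nTyped = c(L1 = 10L))
#' mendelianLikelihood(c(1L, 2L), dam = c(1L, 1L), sire = c(2L, 2L),
#'                     freqs = af)  # forced cross: 1
#' @export
mendelianLikelihood <- function(offspring, dam = NULL, sire = NULL,
                                freqs, errorRate = 0, loci = NULL) {
  stopifnot(errorRate >= 0, errorRate < 1)
  if (is.null(loci)) {
    loci <- if (is.matrix(offspring) && !is.null(rownames(offspring)))
      rownames(offspring)
    else names(freqs@freqs)[seq_len(
      if (is.matrix(offspring)) nrow(offspring) else 1L)]
  }
  off <- .asGenoMatrix(offspring, loci)
  dam <- .asGenoMatrix(dam, loci)
  sire <- .asGenoMatrix(sire, loci)
  out <- numeric(length(loci))
  for (l in seq_along(loci)) {
    p <- freqs@freqs[[loci[l]]]
    if (is.null(p)) .stopf("unknown locus: %s", loci[l])
    o1 <- off[l, 1L]; o2 <- off[l, 2L]
    .checkAllele(c(o1, o2), p, loci[l])
    if (!is.null(dam)) .checkAllele(dam[l, ], p, loci[l])
    if (!is.null(sire)) .checkAllele(sire[l, ], p, loci[l])
    if (is.na(o1) ||
        (!is.null(dam) && is.na(dam[l, 1L])) ||
        (!is.null(sire) && is.na(sire[l, 1L]))) {
      out[l] <- 1
      next
    }
    lm <- if (!is.null(dam) && !is.null(sire)) {
      .transBoth(o1, o2, dam[l, 1L], dam[l, 2L], sire[l, 1L], sire[l, 2L])
    } else if (!is.null(dam)) {
      .transSingle(o1, o2, dam[l, 1L], dam[l, 2L], p)
    } else if (!is.null(sire)) {
      .transSingle(o1, o2, sire[l, 1L], sire[l, 2L], p)
    } else {
      .transNone(o1, o2, p)
    }
    out[l] <- (1 - errorRate) * lm + errorRate * .transNone(o1, o2, p)
  }
  out
}

#' Count parent-offspring exclusions
#'
#' In single-parent mode a locus mismatches when parent and offspring
#' share no allele; in trio mode when no assignment of one allele from
#' each parent reproduces the offspring pair. Loci with a missing
#' genotype in the offspring are skipped; in trio mode a locus where
#' exactly one parent is typed falls back to the single-parent check
#' against that parent, and a locus where neither is typed is skipped.
#'
#' @param offspring loci-by-2 integer matrix (or length-2 vector).
#' @param dam,sire parental genotypes, same shape; supply one parent for
#'   single mode, both for trio mode.
#' @return integer mismatch count.
#' @export
mismatchCount <- function(offspring, dam = NULL, sire = NULL) {
  if (is.null(dam) && is.null(sire))
    .stopf("at least one parent genotype is required")
  nl <- if (is.matrix(offspring)) nrow(offspring) else 1L
  loci <- as.character(seq_len(nl))
  off <- .asGenoMatrix(offspring, loci)
  dam <- .asGenoMatrix(dam, loci)
  sire <- .asGenoMatrix(sire, loci)
  count <- 0L
  for (l in seq_len(nl)) {
    o1 <- off[l, 1L]; o2 <- off[l, 2L]
    if (is.na(o1)) next
    dTyped <- !is.null(dam) && !is.na(dam[l, 1L])
    sTyped <- !is.null(sire) && !is.na(sire[l, 1L])
    if (dTyped && sTyped) {
      if (.transBoth(o1, o2, dam[l, 1L], dam[l, 2L],
                     sire[l, 1L], sire[l, 2L]) == 0)
        count <- count + 1L
    } else if (dTyped || sTyped) {
      g <- if (dTyped) dam[l, ] else sire[l, ]
      if (!any(g %in% c(o1, o2))) count <- count + 1L
    }
  }
  count
}

## --- vectorised posterior engine --------------------------------------

## Core enumeration over the (dams + UNSAMPLED) x (sires + UNSAMPLED)
## hypothesis grid. Allele matrices are candidates x loci; offspring is a
## pair of length-L vectors. Returns log-likelihood, prior and posterior
## matrices of dimension (nd + 1) x (ns + 1); the last row/column is the
## unsampled class.
.posteriorEngine <- function(oA, oB, dA, dB, sA, sB, freqs, e, wUd, wUs) {
  nd <- nrow(dA)
  ns <- nrow(sA)
  L <- length(oA)
  ll <- matrix(0, nd + 1L, ns + 1L)
  for (l in seq_len(L)) {
    o1 <- oA[l]; o2 <- oB[l]
    if (is.na(o1)) next
    p <- freqs[[l]]
    p1 <- unname(p[as.character(o1)])
    p2 <- unname(p[as.character(o2)])
    if (is.na(p1) || is.na(p2))
      .stopf("locus %s: allele %s absent from frequency table",
             names(freqs)[l],
             paste(c(o1, o2)[is.na(c(p1, p2))], collapse = ", "))
    hw <- if (o1 == o2) p1^2 else 2 * p1 * p2
    d1 <- dA[, l]; d2 <- dB[, l]
    s1 <- sA[, l]; s2 <- sB[, l]
    ## single-parent transition for each candidate (NA where untyped)
    t1 <- function(g1, g2) {
      if (o1 == o2) 0.5 * ((g1 == o1) + (g2 == o1)) * p1
      else 0.5 * (((g1 == o1) + (g2 == o1)) * p2 +
                  ((g1 == o2) + (g2 == o2)) * p1)
    }
    t1d <- t1(d1, d2)
    t1s <- t1(s1, s2)
    ## trio transition matrix over candidate pairs
    m <- function(x, y) (x == o1 & y == o2) | (x == o2 & y == o1)
    t2 <- if (nd > 0L && ns > 0L) {
      0.25 * (outer(d1, s1, m) + outer(d1, s2, m) +
              outer(d2, s1, m) + outer(d2, s2, m))
    } else matrix(0, nd, ns)
    lmat <- matrix(hw, nd + 1L, ns + 1L)
    if (nd > 0L && ns > 0L) lmat[seq_len(nd), seq_len(ns)] <- t2
    if (nd > 0L) lmat[seq_len(nd), ns + 1L] <- t1d
    if (ns > 0L) lmat[nd + 1L, seq_len(ns)] <- t1s
    lmat <- (1 - e) * lmat + e * hw
    ## a named parent untyped at this locus: locus contributes factor 1
    if (nd > 0L) lmat[c(is.na(d1), FALSE), ] <- 1
    if (ns > 0L) lmat[, c(is.na(s1), FALSE)] <- 1
    ll <- ll + log(lmat)
  }
  priorD <- c(rep(1, nd), wUd)
  priorS <- c(rep(1, ns), wUs)
  prior <- outer(priorD, priorS)
  prior <- prior / sum(prior)
  mx <- suppressWarnings(max(ll[prior > 0]))
  post <- matrix(NA_real_, nd + 1L, ns + 1L)
  if (is.finite(mx)) {
    w <- prior * exp(ll - mx)
    tot <- sum(w)
    if (tot > 0) post <- w / tot
  }
  list(logLik = ll, prior = prior, posterior = post)
}

.tableAlleles <- function(x) {
  am <- alleleMatrices(x)
  list(a = am$a, b = am$b)
}

#' Enumerate the parentage posterior for one offspring
#'
#' Builds the full hypothesis set (candidate dams plus an unsampled-dam
#' class) x (candidate sires plus an unsampled-sire class), removes
#' sampled candidates with more single-parent exclusions against the
#' offspring than \code{config$maxMismatch}, computes each hypothesis'
#' likelihood as the product of per-locus Mendelian transition
#' probabilities (with the error mixture of [mendelianLikelihood()]),
#' multiplies by the prior (weight 1 per sampled candidate, the
#' configured weight for each unsampled class) and normalises.
#'
#' @param offspring a single-individual [GenotypeTable-class], or a
#'   loci-by-2 integer matrix with locus row names.
#' @param dams,sires candidate [GenotypeTable-class] objects (may have
#'   zero rows).
#' @param freqs an [AlleleFreqTable-class] covering the panel.
#' @param config a [parentageConfig()].
#' @return a data.frame with columns \code{dam}, \code{sire} (candidate
#'   id or \code{"UNSAMPLED"}), \code{logLik}, \code{prior},
#'   \code{posterior}, sorted by decreasing posterior. If the offspring
#'   has fewer typed loci than \code{config$minTypedLoci} the data.frame
#'   is empty with attribute \code{untestable = TRUE}.
#' @export
enumeratePosteriors <- function(offspring, dams, sires, freqs,
                                config = parentageConfig()) {
  loci <- names(freqs@freqs)
  if (is(offspring, "GenotypeTable")) {
    stopifnot(nIndividuals(offspring) == 1L)
    offspring <- cbind(offspring@alleleA[1L, loci],
                       offspring@alleleB[1L, loci])
  } else {
    offspring <- .asGenoMatrix(offspring, loci)
  }
  oA <- offspring[, 1L]
  oB <- offspring[, 2L]
  empty <- data.frame(dam = character(), sire = character(),
                      logLik = numeric(), prior = numeric(),
                      posterior = numeric(), stringsAsFactors = FALSE)
  if (sum(!is.na(oA)) < config$minTypedLoci) {
    attr(empty, "untestable") <- TRUE
    return(empty)
  }
  prep <- function(tab) {
    if (is.null(tab) || nIndividuals(tab) == 0L)
      return(list(a = matrix(NA_integer_, 0L, length(loci)),
                  b = matrix(NA_integer_, 0L, length(loci)),
                  ids = character()))
    list(a = tab@alleleA[, loci, drop = FALSE],
         b = tab@alleleB[, loci, drop = FALSE],
         ids = individualIds(tab))
  }
  dmat <- prep(dams)
  smat <- prep(sires)
  wUd <- config$nUnsampledDams
  if (is.null(wUd)) wUd <- 0.5 * length(dmat$ids)
  wUs <- config$nUnsampledSires
  if (is.null(wUs)) wUs <- 0.5 * length(smat$ids)
  keepCand <- function(mat) {
    vapply(seq_along(mat$ids), function(i) {
      mismatchCount(cbind(oA, oB),
                    dam = cbind(mat$a[i, ], mat$b[i, ])) <=
        config$maxMismatch
    }, logical(1))
  }
  kd <- keepCand(dmat)
  ks <- keepCand(smat)
  dA <- dmat$a[kd, , drop = FALSE]; dB <- dmat$b[kd, , drop = FALSE]
  sA <- smat$a[ks, , drop = FALSE]; sB <- smat$b[ks, , drop = FALSE]
  eng <- .posteriorEngine(oA, oB, dA, dB, sA, sB, freqs@freqs,
                          config$errorRate, wUd, wUs)
  damIds <- c(dmat$ids[kd], "UNSAMPLED")
  sireIds <- c(smat$ids[ks], "UNSAMPLED")
  out <- data.frame(
    dam = rep(damIds, times = length(sireIds)),
    sire = rep(sireIds, each = length(damIds)),
    logLik = as.vector(eng$logLik),
    prior = as.vector(eng$prior),
    posterior = as.vector(eng$posterior),
    stringsAsFactors = FALSE)
  out[order(-out$posterior), , drop = FALSE]
}

#' Assign parentage for a table of offspring
#'
#' Runs [enumeratePosteriors()] for every offspring against the sexed
#' adults and applies the confidence cutoff: a dam (sire) is assigned
#' when its marginal posterior, summed over all sire (dam) hypotheses,
#' reaches the cutoff; a parent pair is assigned when the joint
#' maximum-a-posteriori hypothesis names two sampled parents and its
#' posterior reaches the cutoff. The unsampled class is never reported
#' as an assignment. Deterministic given its inputs.
#'
#' @param fry offspring [GenotypeTable-class].
#' @param adults candidate-parent [GenotypeTable-class]; every adult
#'   must carry an \code{"F"} or \code{"M"} sex label.
#' @param config a [parentageConfig()].
#' @param freqs optional [AlleleFreqTable-class]; by default estimated
#'   from adults and fry combined.
#' @return a data.frame, one row per offspring, with columns
#'   \code{offspring_id}, \code{dam_id}, \code{dam_conf},
#'   \code{sire_id}, \code{sire_conf}, \code{pair} (logical),
#'   \code{pair_conf}, \code{dam_mismatch}, \code{sire_mismatch},
#'   \code{n_typed}, \code{untestable}. The attribute \code{"summary"}
#'   holds the run-level totals (offspring assigned a dam, a sire, both,
#'   and untestable).
#' @export
assignParentage <- function(fry, adults, config = parentageConfig(),
                            freqs = NULL) {
  if (any(sexOf(adults) == "U"))
    .stopf("all candidate adults must carry a sex label ('F' or 'M')")
  common <- intersect(lociNames(fry), lociNames(adults))
  if (!length(common))
    .stopf("fry and adults share no loci")
  fry <- fry[, common]
  adults <- adults[, common]
  if (is.null(freqs)) {
    pool <- combineTables(adults, fry)
    freqs <- alleleFrequencies(pool)
  }
  dams <- adults[sexOf(adults) == "F", ]
  sires <- adults[sexOf(adults) == "M", ]
  wUd <- config$nUnsampledDams
  if (is.null(wUd)) wUd <- 0.5 * nIndividuals(dams)
  wUs <- config$nUnsampledSires
  if (is.null(wUs)) wUs <- 0.5 * nIndividuals(sires)
  fA <- fry@alleleA[, common, drop = FALSE]
  fB <- fry@alleleB[, common, drop = FALSE]
  nf <- nrow(fA)
  mmD <- .mismatchMatrix(fA, fB, dams@alleleA, dams@alleleB)
  mmS <- .mismatchMatrix(fA, fB, sires@alleleA, sires@alleleB)
  damIds <- individualIds(dams)
  sireIds <- individualIds(sires)
  res <- data.frame(
    offspring_id = individualIds(fry),
    dam_id = NA_character_, dam_conf = NA_real_,
    sire_id = NA_character_, sire_conf = NA_real_,
    pair = FALSE, pair_conf = NA_real_,
    dam_mismatch = NA_integer_, sire_mismatch = NA_integer_,
    n_typed = rowSums(!is.na(fA)),
    untestable = FALSE,
    stringsAsFactors = FALSE)
  cutoff <- config$confidenceCutoff
  for (i in seq_len(nf)) {
    if (res$n_typed[i] < config$minTypedLoci) {
      res$untestable[i] <- TRUE
      next
    }
    kd <- which(mmD[i, ] <= config$maxMismatch)
    ks <- which(mmS[i, ] <= config$maxMismatch)
    eng <- .posteriorEngine(
      fA[i, ], fB[i, ],
      dams@alleleA[kd, , drop = FALSE], dams@alleleB[kd, , drop = FALSE],
      sires@alleleA[ks, , drop = FALSE], sires@alleleB[ks, , drop = FALSE],
      freqs@freqs, config$errorRate, wUd, wUs)
    post <- eng$posterior
    if (anyNA(post)) next
    nd <- length(kd)
    ns <- length(ks)
    damMarg <- rowSums(post)
    sireMarg <- colSums(post)
    if (nd > 0L) {
      best <- which.max(damMarg[seq_len(nd)])
      if (damMarg[best] >= cutoff) {
        res$dam_id[i] <- damIds[kd[best]]
        res$dam_conf[i] <- damMarg[best]
        res$dam_mismatch[i] <- mmD[i, kd[best]]
      }
    }
    if (ns > 0L) {
      best <- which.max(sireMarg[seq_len(ns)])
      if (sireMarg[best] >= cutoff) {
        res$sire_id[i] <- sireIds[ks[best]]
        res$sire_conf[i] <- sireMarg[best]
        res$sire_mismatch[i] <- mmS[i, ks[best]]
      }
    }
    map <- arrayInd(which.max(post), dim(post))
    if (nd > 0L && ns > 0L &&
        map[1L] <= nd && map[2L] <= ns &&
        post[map] >= cutoff) {
      res$pair[i] <- TRUE
      res$pair_conf[i] <- post[map]
    }
  }
  attr(res, "summary") <- list(
    n_offspring = nf,
    n_assigned_dam = sum(!is.na(res$dam_id)),
    n_assigned_sire = sum(!is.na(res$sire_id)),
    n_assigned_pair = sum(res$pair),
    n_assigned_any = sum(!is.na(res$dam_id) | !is.na(res$sire_id)),
    n_untestable = sum(res$untestable))
  res
}

## Pairwise single-parent exclusion counts: offspring x candidates.
.mismatchMatrix <- function(fA, fB, pA, pB) {
  nf <- nrow(fA)
  np <- nrow(pA)
  out <- matrix(0L, nf, np)
  for (j in seq_len(np)) {
    a1 <- rep(pA[j, ], each = nf)
    a2 <- rep(pB[j, ], each = nf)
    share <- (a1 == fA) | (a1 == fB) | (a2 == fA) | (a2 == fB)
    ## NA (either side untyped) contributes no mismatch
    out[, j] <- rowSums(!share, na.rm = TRUE)
  }
  out
}
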