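## Polygynandrous mating-system simulator: adults, mating network,
## Mendelian fry, genotyping noise, fragment duplicates — with complete
## truth tables, so every pipeline stage can be validated end to end.

#' Default microsatellite locus panel
#'
#' A 19-locus panel typical of salmonid parentage studies: allele counts
#' between 2 and 12 per locus, allele sizes evenly spaced inside
#' realistic fragment-length ranges.
#'
#' @return data.frame with columns \code{name}, \code{nAlleles}, and a
#'   list-column \code{alleles} of integer fragment lengths.
#' @export
defaultLocusPanel <- function() {
  name <- c("BFRO13", "L213", "L414", "L309", "TAR106", "BFRO10",
            "BFRO15", "BFRO18", "L207", "BFRO9", "L438", "BFRO11",
            "L313", "Ogo2", "L433b", "L445", "L415", "L214", "L407b")
  na <- c(4L, 11L, 6L, 2L, 8L, 2L, 2L, 4L, 2L, 2L, 9L, 2L, 6L, 3L,
          8L, 12L, 9L, 4L, 7L)
  lo <- c(235L, 283L, 393L, 447L, 193L, 96L, 144L, 181L, 216L, 243L,
          265L, 86L, 180L, 233L, 287L, 374L, 193L, 292L, 230L)
  hi <- c(247L, 327L, 413L, 451L, 221L, 122L, 154L, 195L, 224L, 247L,
          297L, 102L, 200L, 241L, 315L, 422L, 225L, 313L, 254L)
  alleles <- mapply(function(k, a, b) {
    as.integer(round(seq(a, b, length.out = k)))
  }, na, lo, hi, SIMPLIFY = FALSE)
  data.frame(name = name, nAlleles = na,
             alleles = I(alleles), stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic breeding-system study. The defaults
#' emulate a small stream-spawning grayling population: 57 candidate
#' dams and 97 candidate sires of which roughly 39% and 33% breed,
#' ~895 fry with highly skewed family sizes, 1-6 partners per successful
#' breeder, 19 microsatellite loci with 2-12 alleles each, ~5% duplicate
#' fry fragments, and mild genotyping error and missingness.
#'
#' @param seed integer RNG seed; the simulation is a pure function of
#'   the configuration including this seed.
#' @param nDams,nSires candidate adults per sex.
#' @param loci locus panel as from [defaultLocusPanel()].
#' @param dirichletConc concentration of the symmetric Dirichlet the
#'   per-locus allele frequencies are drawn from (default 1 =
#'   uniform on the simplex).
#' @param freqSpec optional explicit frequencies: named list (locus ->
#'   named numeric summing to 1) overriding the Dirichlet draw.
#' @param breedingPropF,breedingPropM proportion of candidates of each
#'   sex selected to breed.
#' @param meanPartners mean of the zero-truncated Poisson partner-count
#'   distribution (drawn per breeding female).
#' @param maxPartners hard cap on partners per breeder.
#' @param pairMeanOffspring,pairDispersion negative-binomial mean and
#'   dispersion (size) of the per-pair offspring count before rescaling;
#'   the defaults give the large family-size spread (SD > mean) typical
#'   of salmonid reproductive skew.
#' @param nFry total number of fry sampled (family sizes are rescaled to
#'   this total by multinomial draw proportional to the NB counts).
#' @param parentSamplingFrac fraction of each sex's candidates retained
#'   in the observed adult table.
#' @param eSim per-locus genotyping error rate applied to fry.
#' @param errorMode \code{"genotype"}: an erroneous locus is replaced by
#'   a random Hardy-Weinberg genotype (matches the likelihood model's
#'   error assumption); \code{"allele"}: a single allele is replaced by
#'   a population draw (a deliberately misspecified alternative).
#' @param missingRate per-locus missingness rate applied to fry.
#' @param duplicateRate probability a fry sample is duplicated as a
#'   second fragment with a new id.
#' @param dupExtraMissing additional per-locus missingness on duplicate
#'   fragments (fragments genotype nearly as completely as intact fry).
#' @param lengthMeanF,lengthSdF,lengthMeanM,lengthSdM normal
#'   fork-length model per sex, in mm.
#' @param lengthEffect optional log-linear effect of standardised male
#'   length on the partner-sampling weight (0 = none).
#' @return a list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nDams = 57L, nSires = 97L,
                             loci = defaultLocusPanel(),
                             dirichletConc = 1,
                             freqSpec = NULL,
                             breedingPropF = 0.39, breedingPropM = 0.33,
                             meanPartners = 2.2, maxPartners = 6L,
                             pairMeanOffspring = 18,
                             pairDispersion = 2,
                             nFry = 895L,
                             parentSamplingFrac = 1.0,
                             eSim = 0.005,
                             errorMode = c("genotype", "allele"),
                             missingRate = 0.02,
                             duplicateRate = 0.05,
                             dupExtraMissing = 0.05,
                             lengthMeanF = 288, lengthSdF = 19,
                             lengthMeanM = 321, lengthSdM = 28,
                             lengthEffect = 0) {
  errorMode <- match.arg(errorMode)
  stopifnot(nDams >= 2, nSires >= 2, nrow(loci) >= 1,
            all(loci$nAlleles >= 1L),
            dirichletConc > 0,
            breedingPropF > 0, breedingPropF <= 1,
            breedingPropM > 0, breedingPropM <= 1,
            meanPartners > 1, maxPartners >= 1,
            pairMeanOffspring > 0, pairDispersion > 0,
            nFry >= 1,
            parentSamplingFrac > 0, parentSamplingFrac <= 1,
            eSim >= 0, eSim <= 1, missingRate >= 0, missingRate <= 1,
            duplicateRate >= 0, duplicateRate <= 1,
            dupExtraMissing >= 0, dupExtraMissing <= 1,
            lengthSdF > 0, lengthSdM > 0)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate the adult population
#'
#' Draws per-locus allele frequencies (symmetric Dirichlet or explicit),
#' adult genotypes at Hardy-Weinberg proportions, sexes and fork
#' lengths. Deterministic given \code{config$seed}.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{adults} (a [GenotypeTable-class]) and
#'   \code{freqs} (the true [AlleleFreqTable-class]).
#' @export
simulatePopulation <- function(config) {
  .withSeed(config$seed, .simulatePopulationImpl(config))
}

.simulatePopulationImpl <- function(config) {
  loci <- config$loci
  L <- nrow(loci)
  freqs <- vector("list", L)
  names(freqs) <- loci$name
  for (j in seq_len(L)) {
    alleles <- loci$alleles[[j]]
    if (!is.null(config$freqSpec) &&
        loci$name[j] %in% names(config$freqSpec)) {
      p <- config$freqSpec[[loci$name[j]]]
    } else {
      g <- stats::rgamma(length(alleles), shape = config$dirichletConc)
      p <- stats::setNames(g / sum(g), as.character(alleles))
    }
    freqs[[j]] <- p
  }
  n <- config$nDams + config$nSires
  ids <- c(sprintf("F%03d", seq_len(config$nDams)),
           sprintf("M%03d", seq_len(config$nSires)))
  sex <- c(rep("F", config$nDams), rep("M", config$nSires))
  a <- matrix(NA_integer_, n, L, dimnames = list(ids, loci$name))
  b <- a
  for (j in seq_len(L)) {
    p <- freqs[[j]]
    al <- as.integer(names(p))
    a[, j] <- al[sample.int(length(al), n, replace = TRUE, prob = p)]
    b[, j] <- al[sample.int(length(al), n, replace = TRUE, prob = p)]
  }
  len <- c(stats::rnorm(config$nDams, config$lengthMeanF, config$lengthSdF),
           stats::rnorm(config$nSires, config$lengthMeanM, config$lengthSdM))
  adults <- GenotypeTable(a, b, sex = sex, forkLength = round(len),
                          cohort = "ADULT")
  ft <- new("AlleleFreqTable", freqs = freqs,
            nTyped = stats::setNames(rep(as.integer(n), L), loci$name))
  list(adults = adults, freqs = ft)
}

#' Simulate one breeding event
#'
#' Selects breeders of each sex per the breeding proportions, draws
#' partner counts (zero-truncated Poisson, capped), builds the bipartite
#' truth mating network, draws per-pair offspring counts (negative
#' binomial, rescaled to the target fry total by a multinomial draw) and
#' generates fry genotypes by Mendelian segregation (one allele
#' uniformly from each true parent per locus). No genotyping noise is
#' applied here.
#'
#' @param config a [simulationConfig()].
#' @param population output of [simulatePopulation()].
#' @return list with \code{fry} (pre-noise [GenotypeTable-class]),
#'   \code{pedigree} (data.frame fry_id, dam_id, sire_id),
#'   \code{edges} (truth mating network with offspring counts), and the
#'   selected breeder ids per sex.
#' @export
simulateBreeding <- function(config, population) {
  .withSeed(config$seed + 1L, .simulateBreedingImpl(config, population))
}

.simulateBreedingImpl <- function(config, population) {
  adults <- population$adults
  sex <- sexOf(adults)
  damsAll <- names(sex)[sex == "F"]
  siresAll <- names(sex)[sex == "M"]
  nBF <- max(1L, round(config$breedingPropF * length(damsAll)))
  nBM <- max(1L, round(config$breedingPropM * length(siresAll)))
  breedF <- sort(sample(damsAll, nBF))
  breedM <- sort(sample(siresAll, nBM))
  if (!length(breedF) || !length(breedM))
    .stopf("no breeders of one sex")
  ## male sampling weight: optional log-linear length effect
  lenM <- forkLengthOf(adults)[breedM]
  wM <- if (config$lengthEffect == 0) rep(1, length(breedM)) else
    exp(config$lengthEffect * as.numeric(scale(lenM)))
  kF <- .rztpois(length(breedF), config$meanPartners, config$maxPartners)
  deg <- stats::setNames(integer(length(breedM)), breedM)
  pairs <- list()
  for (i in seq_along(breedF)) {
    avail <- breedM[deg < config$maxPartners]
    k <- min(kF[i], length(avail))
    if (k < 1L) next
    chosen <- if (length(avail) == 1L) avail else
      sample(avail, k, prob = wM[match(avail, breedM)])
    deg[chosen] <- deg[chosen] + 1L
    pairs[[length(pairs) + 1L]] <- data.frame(
      dam = breedF[i], sire = chosen, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  ## per-pair family sizes, rescaled to the fry target
  repeat {
    raw <- stats::rnbinom(nrow(pairs), size = config$pairDispersion,
                          mu = config$pairMeanOffspring)
    if (sum(raw) > 0) break
  }
  realized <- as.integer(stats::rmultinom(1L, config$nFry,
                                          prob = raw / sum(raw)))
  keep <- realized > 0L
  edges <- data.frame(dam = pairs$dam[keep], sire = pairs$sire[keep],
                      n_offspring = realized[keep],
                      stringsAsFactors = FALSE)
  pedigree <- data.frame(
    fry_id = sprintf("FRY%04d", seq_len(sum(realized))),
    dam_id = rep(edges$dam, edges$n_offspring),
    sire_id = rep(edges$sire, edges$n_offspring),
    stringsAsFactors = FALSE)
  ## Mendelian segregation, one allele from each parent per locus
  am <- alleleMatrices(adults)
  di <- match(pedigree$dam_id, individualIds(adults))
  si <- match(pedigree$sire_id, individualIds(adults))
  nf <- nrow(pedigree)
  L <- nLoci(adults)
  pickD <- matrix(stats::runif(nf * L) < 0.5, nf, L)
  pickS <- matrix(stats::runif(nf * L) < 0.5, nf, L)
  fromDam <- ifelse(pickD, am$a[di, ], am$b[di, ])
  fromSire <- ifelse(pickS, am$a[si, ], am$b[si, ])
  dimnames(fromDam) <- list(pedigree$fry_id, lociNames(adults))
  dimnames(fromSire) <- list(pedigree$fry_id, lociNames(adults))
  fry <- GenotypeTable(fromDam, fromSire, sex = "U", cohort = "FRY")
  list(fry = fry, pedigree = pedigree, edges = edges,
       breedersF = breedF, breedersM = breedM)
}

#' Simulate a complete observed study
#'
#' Runs [simulatePopulation()] and [simulateBreeding()], then applies
#' the observation process to the fry table: per-locus genotyping error
#' at rate \code{eSim}, per-locus missingness at \code{missingRate},
#' and duplication of a fraction of fry as second "fragment" samples
#' with new ids and extra missingness. A fraction of each sex's adults
#' is retained as the observed candidate set. Truth is kept for
#' everything.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{adults} (observed candidates), \code{fry}
#'   (observed, noisy, with injected duplicates), \code{truth} (list:
#'   \code{pedigree}, \code{edges}, \code{duplicates},
#'   \code{countsF}/\code{countsM} per-candidate true offspring counts,
#'   \code{breedersF}/\code{breedersM}, \code{freqs},
#'   \code{fryPreNoise}) and \code{config}.
#' @export
simulateStudy <- function(config) {
  population <- simulatePopulation(config)
  breeding <- simulateBreeding(config, population)
  .withSeed(config$seed + 2L,
            .applyObservation(config, population, breeding))
}

.applyObservation <- function(config, population, breeding) {
  fry <- breeding$fry
  am <- alleleMatrices(fry)
  a <- am$a
  b <- am$b
  nf <- nrow(a)
  L <- ncol(a)
  freqs <- population$freqs@freqs
  ## genotyping error
  if (config$eSim > 0) {
    err <- matrix(stats::runif(nf * L) < config$eSim, nf, L)
    for (j in seq_len(L)) {
      hit <- which(err[, j])
      if (!length(hit)) next
      p <- freqs[[j]]
      al <- as.integer(names(p))
      rdraw <- function(k) al[sample.int(length(al), k, replace = TRUE,
                                         prob = p)]
      if (config$errorMode == "genotype") {
        a[hit, j] <- rdraw(length(hit))
        b[hit, j] <- rdraw(length(hit))
      } else {
        swapA <- stats::runif(length(hit)) < 0.5
        repl <- rdraw(length(hit))
        a[hit[swapA], j] <- repl[swapA]
        b[hit[!swapA], j] <- repl[!swapA]
      }
    }
  }
  ## missingness
  if (config$missingRate > 0) {
    mis <- matrix(stats::runif(nf * L) < config$missingRate, nf, L)
    a[mis] <- NA_integer_
    b[mis] <- NA_integer_
  }
  ## duplicate fragments
  dup <- which(stats::runif(nf) < config$duplicateRate)
  duplicates <- data.frame(original = character(), fragment = character(),
                           stringsAsFactors = FALSE)
  if (length(dup)) {
    da <- a[dup, , drop = FALSE]
    db <- b[dup, , drop = FALSE]
    if (config$dupExtraMissing > 0) {
      mis <- matrix(stats::runif(length(dup) * L) < config$dupExtraMissing,
                    length(dup), L)
      da[mis] <- NA_integer_
      db[mis] <- NA_integer_
    }
    fragIds <- paste0(rownames(a)[dup], "_frag")
    rownames(da) <- rownames(db) <- fragIds
    duplicates <- data.frame(original = rownames(a)[dup],
                             fragment = fragIds,
                             stringsAsFactors = FALSE)
    a <- rbind(a, da)
    b <- rbind(b, db)
  }
  fryObs <- GenotypeTable(a, b, sex = "U", cohort = "FRY")
  ## observed adults
  adults <- population$adults
  sex <- sexOf(adults)
  keepIds <- unlist(lapply(c("F", "M"), function(s) {
    ids <- names(sex)[sex == s]
    sort(sample(ids, max(2L, round(config$parentSamplingFrac *
                                   length(ids)))))
  }))
  adultsObs <- adults[keepIds, ]
  ## true per-candidate offspring counts over ALL candidates
  offDam <- tapply(rep(1L, nrow(breeding$pedigree)),
                   breeding$pedigree$dam_id, sum)
  offSire <- tapply(rep(1L, nrow(breeding$pedigree)),
                    breeding$pedigree$sire_id, sum)
  countsOf <- function(ids, tab) {
    v <- stats::setNames(integer(length(ids)), ids)
    hit <- intersect(ids, names(tab))
    v[hit] <- as.integer(tab[hit])
    v
  }
  truth <- list(
    pedigree = breeding$pedigree,
    edges = breeding$edges,
    duplicates = duplicates,
    countsF = countsOf(names(sex)[sex == "F"], offDam),
    countsM = countsOf(names(sex)[sex == "M"], offSire),
    breedersF = breeding$breedersF,
    breedersM = breeding$breedersM,
    freqs = population$freqs,
    fryPreNoise = breeding$fry)
  list(adults = adultsObs, fry = fryObs, truth = truth, config = config)
}
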