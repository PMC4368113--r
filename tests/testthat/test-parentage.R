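af2 <- makeFreqs(list(L1 = c(`1` = 0.5, `2` = 0.5)))

test_that("Mendelian transition likelihood handles the canonical cases", {
  ## forced cross AA x BB -> AB
  expect_equal(
    mendelianLikelihood(c(1L, 2L), dam = c(1L, 1L), sire = c(2L, 2L),
                        freqs = af2), 1)
  ## single parent: transmit A, draw A from the population at 0.5
  expect_equal(
    mendelianLikelihood(c(1L, 1L), dam = c(1L, 1L), freqs = af2), 0.5)
  ## exclusion at e = 0; error floor e * P_HW at e > 0
  expect_equal(
    mendelianLikelihood(c(2L, 2L), dam = c(1L, 1L), freqs = af2), 0)
  expect_equal(
    mendelianLikelihood(c(2L, 2L), dam = c(1L, 1L), freqs = af2,
                        errorRate = 0.01), 0.01 * 0.25)
  ## missing genotype in offspring or a named parent -> factor 1
  expect_equal(
    mendelianLikelihood(c(NA, NA), dam = c(1L, 1L), freqs = af2), 1)
  expect_equal(
    mendelianLikelihood(c(1L, 1L), dam = c(NA, NA), freqs = af2), 1)
  ## no parents: Hardy-Weinberg frequency
  expect_equal(
    mendelianLikelihood(c(1L, 2L), freqs = af2), 0.5)
  expect_error(
    mendelianLikelihood(c(9L, 9L), freqs = af2), "L1.*allele 9")
})

test_that("transition probabilities sum to one over offspring genotypes", {
  withr::local_seed(31)
  for (r in 1:10) {
    k <- sample(2:5, 1)
    p <- stats::rgamma(k, 1)
    p <- stats::setNames(p / sum(p), seq_len(k))
    af <- makeFreqs(list(L = p))
    alleles <- as.integer(names(p))
    pairs <- expand.grid(a = alleles, b = alleles)
    pairs <- pairs[pairs$a <= pairs$b, ]
    dam <- sample(alleles, 2, replace = TRUE)
    sire <- sample(alleles, 2, replace = TRUE)
    for (parents in list(list(dam, sire), list(dam, NULL),
                         list(NULL, NULL))) {
      tot <- sum(mapply(function(a, b) {
        mendelianLikelihood(c(a, b), dam = parents[[1]],
                            sire = parents[[2]], freqs = af)
      }, pairs$a, pairs$b))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("mismatch counting distinguishes single and trio exclusion", {
  expect_equal(mismatchCount(c(2L, 2L), dam = c(1L, 1L)), 1L)
  expect_equal(mismatchCount(c(2L, 2L), dam = c(NA, NA)), 0L)
  ## trio exclusion even though the dam alone is compatible
  expect_equal(
    mismatchCount(c(1L, 2L), dam = c(1L, 1L), sire = c(1L, 1L)), 1L)
  expect_equal(
    mismatchCount(c(1L, 2L), dam = c(1L, 1L), sire = c(2L, 2L)), 0L)
  ## multi-locus counting vs the oracle
  withr::local_seed(8)
  for (r in 1:10) {
    off <- matrix(sample(c(1:3, NA), 10, replace = TRUE), 5, 2)
    par <- matrix(sample(c(1:3, NA), 10, replace = TRUE), 5, 2)
    off[is.na(off[, 1]) | is.na(off[, 2]), ] <- NA
    par[is.na(par[, 1]) | is.na(par[, 2]), ] <- NA
    expect_equal(mismatchCount(off, dam = par), oracleMismatch(off, par))
  }
})

test_that("e = 0 likelihood is zero exactly when a single-parent locus mismatches", {
  withr::local_seed(77)
  af <- makeFreqs(list(L = c(`1` = 0.25, `2` = 0.25, `3` = 0.5)))
  for (r in 1:25) {
    off <- sample(1:3, 2, replace = TRUE)
    par <- sample(1:3, 2, replace = TRUE)
    lik <- mendelianLikelihood(off, dam = par, freqs = af)
    mm <- mismatchCount(matrix(off, 1), dam = matrix(par, 1))
    expect_equal(lik == 0, mm > 0)
  }
})

test_that("posterior enumeration collapses correctly in forced cases", {
  loci <- paste0("L", 1:12)
  fl <- stats::setNames(
    rep(list(c(`1` = 0.4, `2` = 0.3, `3` = 0.3)), 12), loci)
  af <- makeFreqs(fl)
  ## dam compatible at all loci, competitor excluded everywhere
  dams <- makeTab(list(D1 = rep(list(c(1, 2)), 12),
                       D2 = rep(list(c(3, 3)), 12)),
                  loci = loci, sex = "F")
  off <- makeTab(list(O1 = rep(list(c(1, 1)), 12)), loci = loci,
                 cohort = "FRY")
  hyp <- enumeratePosteriors(
    off, dams, dams[integer(0), ], af,
    parentageConfig(errorRate = 0, nUnsampledDams = 0,
                    nUnsampledSires = 1))
  damMarg <- tapply(hyp$posterior, hyp$dam, sum)
  expect_equal(unname(damMarg["D1"]), 1)
  expect_false("D2" %in% hyp$dam)  # excluded by the mismatch filter

  ## two identical candidate sires split the posterior evenly
  sires <- makeTab(list(S1 = rep(list(c(1, 1)), 12),
                        S2 = rep(list(c(1, 1)), 12)),
                   loci = loci, sex = "M")
  hyp2 <- enumeratePosteriors(
    off, dams[integer(0), ], sires, af,
    parentageConfig(errorRate = 0, nUnsampledDams = 1,
                    nUnsampledSires = 0))
  sireMarg <- tapply(hyp2$posterior, hyp2$sire, sum)
  expect_equal(unname(sireMarg["S1"]), unname(sireMarg["S2"]))
  expect_equal(sum(hyp2$posterior), 1, tolerance = 1e-9)

  ## too few typed loci -> untestable
  offMiss <- makeTab(list(O2 = c(rep(list(c(1, 1)), 5),
                                 rep(list(c(NA, NA)), 7))),
                     loci = loci, cohort = "FRY")
  hyp3 <- enumeratePosteriors(offMiss, dams, sires, af,
                              parentageConfig(minTypedLoci = 10))
  expect_equal(nrow(hyp3), 0L)
  expect_true(attr(hyp3, "untestable"))
})

test_that("adding a zero-likelihood hypothesis leaves posteriors unchanged", {
  loci <- paste0("L", 1:3)
  fl <- stats::setNames(
    rep(list(c(`1` = 0.4, `2` = 0.4, `3` = 0.2)), 3), loci)
  af <- makeFreqs(fl)
  off <- makeTab(list(O = rep(list(c(1, 2)), 3)), loci = loci)
  dams <- makeTab(list(D1 = rep(list(c(1, 1)), 3)), loci = loci, sex = "F")
  ## DX = (3,3) can transmit neither allele of the (1,2) offspring, so
  ## its single-parent likelihood is exactly zero at e = 0
  damsPlus <- makeTab(list(D1 = rep(list(c(1, 1)), 3),
                           DX = rep(list(c(3, 3)), 3)),
                      loci = loci, sex = "F")
  ## DX has zero trio/single likelihood for O at e = 0 only at hom loci;
  ## force retention with a permissive mismatch filter and e = 0
  cfgA <- parentageConfig(errorRate = 0, maxMismatch = 3,
                          nUnsampledDams = 1, nUnsampledSires = 1,
                          minTypedLoci = 1)
  h1 <- enumeratePosteriors(off, dams, dams[integer(0), ], af, cfgA)
  h2 <- enumeratePosteriors(off, damsPlus, dams[integer(0), ], af, cfgA)
  m1 <- tapply(h1$posterior, h1$dam, sum)
  m2 <- tapply(h2$posterior, h2$dam, sum)
  expect_equal(m1[["D1"]], m2[["D1"]], tolerance = 1e-12)
  expect_equal(m1[["UNSAMPLED"]], m2[["UNSAMPLED"]], tolerance = 1e-12)
})

test_that("exact enumeration agrees with the brute-force oracle", {
  withr::local_seed(101)
  for (r in 1:12) {
    L <- sample(1:3, 1)
    loci <- paste0("L", seq_len(L))
    fl <- stats::setNames(lapply(seq_len(L), function(l) {
      k <- sample(2:3, 1)
      p <- stats::rgamma(k, 1)
      stats::setNames(p / sum(p), seq_len(k))
    }), loci)
    af <- makeFreqs(fl)
    draw <- function() {
      vapply(seq_len(L), function(l) {
        sample(as.integer(names(fl[[l]])), 2, replace = TRUE)
      }, integer(2))
    }
    nd <- sample(0:2, 1)
    ns <- if (nd == 0L) sample(1:2, 1) else sample(0:2, 1)
    e <- sample(c(0, 0.01, 0.1), 1)
    offM <- t(draw())
    rownames(offM) <- loci
    damsL <- if (nd) stats::setNames(
      lapply(seq_len(nd), function(i) t(draw())),
      paste0("D", seq_len(nd))) else list()
    siresL <- if (ns) stats::setNames(
      lapply(seq_len(ns), function(i) t(draw())),
      paste0("S", seq_len(ns))) else list()
    asTab <- function(lst, sx) {
      if (!length(lst)) return(NULL)
      makeTab(lapply(lst, function(m) {
        lapply(seq_len(L), function(l) m[l, ])
      }), loci = loci, sex = sx)
    }
    cfg <- parentageConfig(errorRate = e, maxMismatch = 1,
                           minTypedLoci = 1)
    hyp <- enumeratePosteriors(offM, asTab(damsL, "F"),
                               asTab(siresL, "M"), af, cfg)
    orc <- oraclePosterior(offM, damsL, siresL, fl, e = e,
                           wUd = 0.5 * nd, wUs = 0.5 * ns,
                           maxMismatch = 1)
    key <- function(d) paste(d$dam, d$sire)
    expect_setequal(key(hyp), key(orc))
    m <- match(key(orc), key(hyp))
    expect_equal(hyp$posterior[m], orc$posterior, tolerance = 1e-9)
  }
})

test_that("posterior engine likelihoods equal per-locus products", {
  loci <- paste0("L", 1:4)
  fl <- stats::setNames(rep(list(c(`1` = 0.2, `2` = 0.3, `3` = 0.5)), 4),
                        loci)
  af <- makeFreqs(fl)
  withr::local_seed(55)
  dam <- sample(1:3, 2, TRUE)
  sire <- sample(1:3, 2, TRUE)
  off <- c(sample(dam, 1), sample(sire, 1))
  dams <- makeTab(list(D = rep(list(dam), 4)), loci = loci, sex = "F")
  sires <- makeTab(list(S = rep(list(sire), 4)), loci = loci, sex = "M")
  offT <- makeTab(list(O = rep(list(off), 4)), loci = loci)
  cfg <- parentageConfig(errorRate = 0.02, maxMismatch = 4,
                         minTypedLoci = 1)
  hyp <- enumeratePosteriors(offT, dams, sires, af, cfg)
  grab <- function(d, s) hyp$logLik[hyp$dam == d & hyp$sire == s]
  am <- function(tab) cbind(tab@alleleA[1, ], tab@alleleB[1, ])
  expect_equal(grab("D", "S"),
               sum(log(mendelianLikelihood(am(offT), dam = am(dams),
                                           sire = am(sires), freqs = af,
                                           errorRate = 0.02))),
               tolerance = 1e-12)
  expect_equal(grab("D", "UNSAMPLED"),
               sum(log(mendelianLikelihood(am(offT), dam = am(dams),
                                           freqs = af,
                                           errorRate = 0.02))),
               tolerance = 1e-12)
  expect_equal(grab("UNSAMPLED", "UNSAMPLED"),
               sum(log(mendelianLikelihood(am(offT), freqs = af,
                                           errorRate = 0.02))),
               tolerance = 1e-12)
})

test_that("assignment respects cutoffs, filters and input contracts", {
  study <- simulateStudy(smallStudyConfig(seed = 19L))
  dedup <- findDuplicates(study$fry)$table
  unsexed <- study$adults
  unsexed@sex[1] <- "U"
  expect_error(assignParentage(dedup, unsexed), "sex label")

  asn <- assignParentage(dedup, study$adults)
  s <- attr(asn, "summary")
  expect_true(all(asn$dam_conf[!is.na(asn$dam_id)] >= 0.90))
  expect_true(all(asn$sire_conf[!is.na(asn$sire_id)] >= 0.90))
  expect_true(all(!asn$pair | (!is.na(asn$dam_id) & !is.na(asn$sire_id))))
  expect_true(all(asn$dam_mismatch[!is.na(asn$dam_id)] <= 1))

  ## raising the cutoff can only lose assignments
  n_assigned <- vapply(c(0.80, 0.90, 0.99), function(co) {
    a <- assignParentage(dedup, study$adults,
                         parentageConfig(confidenceCutoff = co))
    sum(!is.na(a$dam_id)) + sum(!is.na(a$sire_id))
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("offspring incompatible with every candidate get no sampled parent", {
  loci <- paste0("L", 1:12)
  fl <- stats::setNames(rep(list(c(`1` = 0.4, `2` = 0.4, `3` = 0.2)), 12),
                        loci)
  af <- makeFreqs(fl)
  adults <- makeTab(list(D1 = rep(list(c(1, 1)), 12),
                         S1 = rep(list(c(1, 2)), 12)),
                    loci = loci, sex = c("F", "M"))
  off <- makeTab(list(O = rep(list(c(3, 3)), 12)), loci = loci,
                 cohort = "FRY")
  asn <- assignParentage(off, adults, parentageConfig(), freqs = af)
  expect_true(is.na(asn$dam_id))
  expect_true(is.na(asn$sire_id))
  expect_false(asn$pair)
})
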