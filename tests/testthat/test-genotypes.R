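test_that("GenePop parsing handles 2-digit coding, missing codes and errors", {
  gp <- c("toy data",
          "LocA", "LocB",
          "Pop",
          "F01 , 0102 0304",
          "F02 , 0000 0505")
  f <- withr::local_tempfile(lines = gp, fileext = ".gen")
  tab <- readGenotypes(f, "genepop")
  expect_equal(individualIds(tab), c("F01", "F02"))
  expect_equal(lociNames(tab), c("LocA", "LocB"))
  am <- alleleMatrices(tab)
  expect_equal(unname(am$a["F01", ]), c(1L, 3L))
  expect_equal(unname(am$b["F01", ]), c(2L, 4L))
  expect_true(all(is.na(c(am$a["F02", "LocA"], am$b["F02", "LocA"]))))
  expect_equal(unname(am$a["F02", "LocB"]), 5L)

  dupf <- withr::local_tempfile(
    lines = c("t", "LocA", "Pop", "F01 , 0102", "F01 , 0304"))
  expect_error(readGenotypes(dupf, "genepop"), "duplicate id.*F01")

  ragged <- withr::local_tempfile(
    lines = c("t", "LocA", "LocB", "Pop", "F01 , 0102"))
  expect_error(readGenotypes(ragged, "genepop"), "line 1.*ragged")
})

test_that("read/write round trips preserve ids, loci and genotypes", {
  withr::local_seed(7)
  freqs <- list(L1 = c(`101` = 0.4, `105` = 0.6),
                L2 = c(`200` = 0.2, `204` = 0.3, `208` = 0.5))
  tab <- randomTab(15, freqs, missingRate = 0.15, sex = "F",
                   cohort = "ADULT")
  for (fmt in c("genepop", "table")) {
    f <- withr::local_tempfile(fileext = ".txt")
    writeGenotypes(tab, f, fmt)
    back <- readGenotypes(f, fmt)
    expect_identical(individualIds(back), individualIds(tab))
    expect_identical(lociNames(back), lociNames(tab))
    expect_identical(alleleMatrices(back), alleleMatrices(tab))
  }
  ## the table dialect also round-trips metadata
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypes(tab, f, "table")
  back <- readGenotypes(f, "table")
  expect_identical(sexOf(back), sexOf(tab))
  expect_identical(cohortOf(back), cohortOf(tab))
})

test_that("writing rejects empty tables and unencodable alleles", {
  freqs <- list(L1 = c(`1001` = 0.5, `1005` = 0.5))
  withr::local_seed(1)
  big <- randomTab(3, freqs)
  f <- withr::local_tempfile()
  expect_error(writeGenotypes(big, f, "genepop"), "999")
  empty <- big[integer(0), ]
  expect_error(writeGenotypes(empty, f, "genepop"), "no individuals")
})

test_that("half-called genotypes are coerced to missing with a warning", {
  a <- matrix(c(1L, NA), 1, 2, dimnames = list("i1", c("L1", "L2")))
  b <- matrix(c(NA, 2L), 1, 2, dimnames = list("i1", c("L1", "L2")))
  expect_warning(tab <- GenotypeTable(a, b), "half-called")
  expect_true(all(isMissingGenotype(tab)))
})

test_that("allele frequencies match direct counting", {
  tab <- makeTab(list(i1 = list(c(101, 101)), i2 = list(c(101, 105))))
  p <- locusFrequencies(alleleFrequencies(tab), "L1")
  expect_equal(unname(p), c(0.75, 0.25))

  mono <- makeTab(list(i1 = list(c(7, 7)), i2 = list(c(7, 7))))
  expect_equal(unname(locusFrequencies(alleleFrequencies(mono), "L1")), 1)

  ## random 50-individual table vs the exhaustive tally oracle
  withr::local_seed(42)
  freqs <- list(La = c(`10` = 0.5, `12` = 0.3, `14` = 0.2),
                Lb = c(`20` = 0.9, `22` = 0.1))
  tab <- randomTab(50, freqs, missingRate = 0.1)
  af <- alleleFrequencies(tab)
  for (loc in names(freqs)) {
    expect_equal(locusFrequencies(af, loc), oracleLocusFreqs(tab, loc))
    expect_equal(sum(locusFrequencies(af, loc)), 1, tolerance = 1e-9)
  }
  expect_error(
    alleleFrequencies(makeTab(list(i1 = list(c(NA, NA), c(1, 2)),
                                   i2 = list(c(NA, NA), c(1, 1))))),
    "L1")
})

test_that("locus summaries reproduce closed forms and the count oracle", {
  ## p = q = 0.5 with n = 10: He = (20/19) * 0.5, PIC = 0.375
  tab <- makeTab(stats::setNames(
    lapply(c(rep("AA", 3), rep("AB", 4), rep("BB", 3)), function(g) {
      list(if (g == "AA") c(1, 1) else if (g == "AB") c(1, 2) else c(2, 2))
    }), paste0("i", 1:10)))
  s <- locusSummaries(tab)
  expect_equal(s$He, (20 / 19) * 0.5)
  expect_equal(s$PIC, 0.375)
  expect_equal(s$Ho, 0.4)

  mono <- makeTab(list(i1 = list(c(5, 5)), i2 = list(c(5, 5))))
  sm <- locusSummaries(mono)
  expect_equal(sm$Na, 1L)
  expect_equal(sm[, c("Ho", "He", "PIC")], data.frame(Ho = 0, He = 0, PIC = 0))
  expect_true(is.na(sm$hwe_p))

  ## random tables: Ho equals direct heterozygote counting; bounds hold
  withr::local_seed(9)
  for (r in 1:5) {
    freqs <- list(L1 = c(`1` = 0.3, `2` = 0.3, `3` = 0.4),
                  L2 = c(`4` = 0.8, `5` = 0.2))
    tab <- randomTab(30, freqs, missingRate = 0.1)
    s <- locusSummaries(tab)
    am <- alleleMatrices(tab)
    for (j in 1:2) {
      typed <- !is.na(am$a[, j])
      expect_equal(s$Ho[j], sum(am$a[typed, j] != am$b[typed, j]) /
                              sum(typed))
    }
    expect_true(all(s$Ho >= 0 & s$Ho <= 1))
    expect_true(all(s$He >= 0 & s$He <= 1))
    expect_true(all(s$PIC <= s$He + 1e-12))
  }
})

test_that("Hardy-Weinberg chi-square flags excess heterozygosity", {
  ## all heterozygotes at p = q = 0.5 is far from HW
  het <- makeTab(stats::setNames(rep(list(list(c(1, 2))), 100),
                                 paste0("i", 1:100)))
  expect_lt(locusSummaries(het)$hwe_p, 1e-10)
  ## a large HW-proportioned sample should not be flagged
  withr::local_seed(3)
  hw <- randomTab(500, list(L1 = c(`1` = 0.5, `2` = 0.5)))
  s <- locusSummaries(hw)
  expect_gt(s$hwe_p, 0.001)
  expect_equal(s$hwe_p_adj, pmin(1, s$hwe_p * 1))
})

test_that("probability of identity follows its closed form and product rule", {
  freqs <- makeFreqs(list(L1 = c(`1` = 0.5, `2` = 0.5),
                          L2 = c(`3` = 0.5, `4` = 0.5)))
  pi1 <- probabilityOfIdentity(freqs, "L1")
  expect_equal(unname(pi1$perLocus), 0.375)
  expect_equal(probabilityOfIdentity(freqs)$product, 0.375^2)
  expect_error(probabilityOfIdentity(freqs, character(0)), "empty")

  ## PI is non-increasing as loci are added
  withr::local_seed(5)
  for (r in 1:5) {
    fl <- lapply(1:6, function(l) {
      k <- sample(2:6, 1)
      p <- stats::rgamma(k, 1)
      stats::setNames(p / sum(p), seq_len(k))
    })
    names(fl) <- paste0("L", 1:6)
    af <- makeFreqs(fl)
    prods <- vapply(1:6, function(k) {
      probabilityOfIdentity(af, paste0("L", 1:k))$product
    }, numeric(1))
    expect_true(all(diff(prods) <= 1e-15))
    expect_lte(probabilityOfIdentity(af)$product,
               min(probabilityOfIdentity(af)$perLocus))
  }
})

test_that("duplicate detection matches, groups and retains correctly", {
  g <- lapply(1:19, function(l) c(l, l + 1))
  tab <- makeTab(list(s1 = g, s2 = g,
                      s3 = replace(g, 19, list(c(40, 41)))[1:19]))
  dup <- findDuplicates(tab, minSharedLoci = 10)
  expect_length(dup$groups, 1L)
  expect_setequal(dup$groups[[1]], c("s1", "s2"))
  expect_equal(dup$kept, "s1")  # tie on missingness -> smallest id
  expect_equal(dup$removed, "s2")
  expect_equal(nIndividuals(dup$table), 2L)

  ## one differing shared locus prevents a match
  expect_false("s3" %in% unlist(dup$groups))

  ## a sample with fewer shared loci than the threshold cannot match
  gm <- g
  gm[11:19] <- rep(list(c(NA, NA)), 9)
  tab2 <- makeTab(list(s1 = g, s2 = gm))
  expect_length(findDuplicates(tab2, minSharedLoci = 11)$groups, 0L)
  expect_length(findDuplicates(tab2, minSharedLoci = 10)$groups, 1L)

  ## retention prefers the least-missing copy
  dup2 <- findDuplicates(tab2, minSharedLoci = 10)
  expect_equal(dup2$kept, "s1")
  expect_error(findDuplicates(tab, minSharedLoci = 0), "minSharedLoci")
})

test_that("deduplication is idempotent", {
  withr::local_seed(13)
  study <- simulateStudy(smallStudyConfig(seed = 13))
  once <- findDuplicates(study$fry)
  twice <- findDuplicates(once$table)
  expect_length(twice$groups, 0L)
  expect_identical(alleleMatrices(twice$table), alleleMatrices(once$table))
})

test_that("simulator-injected fragments are recovered by multilocus matching", {
  for (s in c(21L, 22L)) {
    study <- simulateStudy(simulationConfig(seed = s, nDams = 15L,
                                            nSires = 20L, nFry = 200L))
    dup <- findDuplicates(study$fry, minSharedLoci = 10)
    truthDup <- study$truth$duplicates
    grp <- integer(nIndividuals(study$fry))
    names(grp) <- individualIds(study$fry)
    for (k in seq_along(dup$groups)) grp[dup$groups[[k]]] <- k
    found <- grp[truthDup$original] > 0 &
      grp[truthDup$original] == grp[truthDup$fragment]
    expect_true(all(found))
  }
})
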