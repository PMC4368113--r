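## End-to-end orchestration: dedupe -> locus summaries -> parentage ->
## mating network -> skew/GLM -> effective number of breeders, with all
## tables and a machine-readable run report written to an output
## directory. Logs go to standard error; outputs to files only.

#' Run the full breeding-system pipeline
#'
#' Executes, in order: duplicate-sample detection on the fry,
#' per-locus diversity summaries on the adults, parentage assignment,
#' mating-network construction with phantom partners, per-breeder skew
#' summaries, Poisson GLMs of reproductive success (offspring vs
#' partners and vs fork length, per sex, on successful breeders), the
#' Welch t comparison of male and female fork lengths, and the
#' effective-number-of-breeders estimate with bootstrap CI. The pipeline
#' is a pure function of (inputs, settings, seed): reruns with the same
#' arguments produce identical outputs.
#'
#' @param adults,fry [GenotypeTable-class] objects or file paths
#'   (interpreted per \code{format}).
#' @param format input file format when paths are given:
#'   \code{"table"} or \code{"genepop"}.
#' @param outDir output directory (created if needed); \code{NULL}
#'   skips file output and just returns the results.
#' @param parentage a [parentageConfig()].
#' @param minSharedLoci duplicate-detection threshold, see
#'   [findDuplicates()].
#' @param nbReps,nbConvention,seed bootstrap settings for
#'   [estimateNb()].
#' @param verbose emit progress messages to standard error.
#' @return (invisibly) a list with elements \code{duplicates},
#'   \code{locusSummaries}, \code{assignments}, \code{network},
#'   \code{breeders}, \code{glms}, \code{welch}, \code{nb},
#'   \code{report}.
#' @export
runPipeline <- function(adults, fry, format = c("table", "genepop"),
                        outDir = NULL,
                        parentage = parentageConfig(),
                        minSharedLoci = 10L,
                        nbReps = 1000L,
                        nbConvention = c("all", "successful"),
                        seed = 1L,
                        verbose = TRUE) {
  format <- match.arg(format)
  nbConvention <- match.arg(nbConvention)
  say <- function(...) if (verbose) message(sprintf(...))
  loadTab <- function(x, cohort) {
    if (is(x, "GenotypeTable")) return(x)
    if (!is.character(x) || !file.exists(x))
      .stopf("input file not found: %s", as.character(x))
    readGenotypes(x, format = format, cohort = cohort)
  }
  say("[pipeline] reading inputs")
  adults <- loadTab(adults, "ADULT")
  fry <- loadTab(fry, "FRY")

  say("[pipeline] stage 1/6: duplicate detection (%d fry)",
      nIndividuals(fry))
  dup <- findDuplicates(fry, minSharedLoci = minSharedLoci)
  fryU <- dup$table
  say("[pipeline]   %d duplicate group(s), %d sample(s) removed",
      length(dup$groups), length(dup$removed))

  say("[pipeline] stage 2/6: locus summaries (%d adults, %d loci)",
      nIndividuals(adults), nLoci(adults))
  ls <- locusSummaries(adults)
  pi <- probabilityOfIdentity(alleleFrequencies(adults))

  say("[pipeline] stage 3/6: parentage assignment (%d fry x %d adults)",
      nIndividuals(fryU), nIndividuals(adults))
  asn <- assignParentage(fryU, adults, config = parentage)
  s <- attr(asn, "summary")
  say("[pipeline]   dam: %d, sire: %d, pair: %d, untestable: %d",
      s$n_assigned_dam, s$n_assigned_sire, s$n_assigned_pair,
      s$n_untestable)

  say("[pipeline] stage 4/6: mating network")
  net <- buildMatingNetwork(asn, adults)
  bs <- breederSummary(net, adults)

  say("[pipeline] stage 5/6: success models")
  glms <- list()
  for (sx in c("F", "M")) {
    succ <- bs$breeders[bs$breeders$sex == sx &
                        bs$breeders$n_offspring > 0, , drop = FALSE]
    glms[[sx]] <- list(
      offspring_vs_partners = tryCatch(
        poissonGlm(succ$n_offspring, succ$n_partners)[
          c("intercept", "slope", "chiSquare", "pValue", "n")],
        error = function(e) conditionMessage(e)),
      offspring_vs_length = tryCatch(
        poissonGlm(succ$n_offspring, succ$fork_length_mm)[
          c("intercept", "slope", "chiSquare", "pValue", "n")],
        error = function(e) conditionMessage(e)),
      partners_vs_length = tryCatch(
        poissonGlm(succ$n_partners, succ$fork_length_mm)[
          c("intercept", "slope", "chiSquare", "pValue", "n")],
        error = function(e) conditionMessage(e)))
  }
  lenF <- forkLengthOf(adults)[sexOf(adults) == "F"]
  lenM <- forkLengthOf(adults)[sexOf(adults) == "M"]
  welch <- if (sum(!is.na(lenF)) >= 2 && sum(!is.na(lenM)) >= 2 &&
               stats::sd(lenF, na.rm = TRUE) > 0 &&
               stats::sd(lenM, na.rm = TRUE) > 0) {
    welchT(mean(lenF, na.rm = TRUE), stats::sd(lenF, na.rm = TRUE),
           sum(!is.na(lenF)),
           mean(lenM, na.rm = TRUE), stats::sd(lenM, na.rm = TRUE),
           sum(!is.na(lenM)))
  } else NULL

  say("[pipeline] stage 6/6: effective number of breeders (%d reps)",
      nbReps)
  countsF <- bs$breeders$n_offspring[bs$breeders$sex == "F"]
  countsM <- bs$breeders$n_offspring[bs$breeders$sex == "M"]
  nb <- tryCatch(
    estimateNb(countsF, countsM, nReps = nbReps, seed = seed,
               convention = nbConvention),
    error = function(e) conditionMessage(e))

  report <- list(
    settings = list(
      error_rate = parentage$errorRate,
      max_mismatch = parentage$maxMismatch,
      confidence_cutoff = parentage$confidenceCutoff,
      min_typed_loci = parentage$minTypedLoci,
      min_shared_loci = as.integer(minSharedLoci),
      nb_reps = as.integer(nbReps),
      nb_convention = nbConvention,
      seed = as.integer(seed)),
    counts = list(
      n_adults = nIndividuals(adults),
      n_fry_in = nIndividuals(fry),
      n_duplicates_removed = length(dup$removed),
      n_fry_unique = nIndividuals(fryU),
      n_assigned_dam = s$n_assigned_dam,
      n_assigned_sire = s$n_assigned_sire,
      n_assigned_pair = s$n_assigned_pair,
      n_assigned_any = s$n_assigned_any,
      n_untestable = s$n_untestable,
      n_edges = nrow(net)),
    probability_of_identity = pi$product)

  out <- list(duplicates = dup, locusSummaries = ls,
              assignments = asn, network = net, breeders = bs,
              glms = glms, welch = welch, nb = nb, report = report)
  if (!is.null(outDir)) .writePipelineOutputs(out, outDir)
  invisible(out)
}

.writePipelineOutputs <- function(out, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLocusSummaries(out$locusSummaries,
                      file.path(outDir, "locus_summaries.tsv"))
  wt(out$duplicates$report, "duplicates.tsv")
  wt(out$assignments, "assignments.tsv")
  wt(out$network, "network.tsv")
  wt(out$breeders$breeders, "breeders.tsv")
  wt(out$breeders$summary, "breeder_summary.tsv")
  if (is(out$nb, "NbEstimate"))
    jsonlite::write_json(nbAsList(out$nb),
                         file.path(outDir, "nb.json"),
                         auto_unbox = TRUE, digits = NA)
  report <- out$report
  report$welch_t = if (!is.null(out$welch)) out$welch else NA
  report$glms = out$glms
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
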