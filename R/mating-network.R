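## Mating-network reconstruction from parentage assignments, with the
## phantom-partner attribution rule, and per-breeder skew summaries.

#' Build the mating network from assignments
#'
#' Offspring with both parents assigned contribute to the (dam, sire)
#' edge. Offspring with only one assigned parent are attributed to a
#' single phantom (unsampled) partner of that parent: all of one dam's
#' father-unassigned offspring share one phantom sire, and symmetrically
#' for sires. Offspring with neither parent assigned contribute nothing.
#' Edge weights are offspring counts.
#'
#' @param assignments data.frame from [assignParentage()].
#' @param adults the candidate-adult [GenotypeTable-class] the
#'   assignments refer to.
#' @return a data.frame of edges with columns \code{dam}, \code{sire},
#'   \code{n_offspring}, \code{dam_is_phantom}, \code{sire_is_phantom}.
#' @export
buildMatingNetwork <- function(assignments, adults) {
  adultIds <- individualIds(adults)
  ref <- c(assignments$dam_id, assignments$sire_id)
  bad <- setdiff(ref[!is.na(ref)], adultIds)
  if (length(bad))
    .stopf("assignment references unknown adult id: %s",
           paste(bad, collapse = ", "))
  dam <- assignments$dam_id
  sire <- assignments$sire_id
  keep <- !is.na(dam) | !is.na(sire)
  dam <- dam[keep]
  sire <- sire[keep]
  damP <- is.na(dam)
  sireP <- is.na(sire)
  dam[damP] <- paste0("PHANTOM_DAM_OF_", sire[damP])
  sire[sireP] <- paste0("PHANTOM_SIRE_OF_", dam[sireP])
  if (!length(dam))
    return(data.frame(dam = character(), sire = character(),
                      n_offspring = integer(),
                      dam_is_phantom = logical(),
                      sire_is_phantom = logical(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(n_offspring = rep(1L, length(dam))),
                          by = list(dam = dam, sire = sire), FUN = sum)
  agg$dam_is_phantom <- startsWith(agg$dam, "PHANTOM_")
  agg$sire_is_phantom <- startsWith(agg$sire, "PHANTOM_")
  agg[order(agg$dam, agg$sire), , drop = FALSE]
}

#' Per-breeder reproductive success and partner counts
#'
#' Tallies, for every sampled adult, the number of offspring (sum of
#' incident edge weights) and the number of distinct partners (phantom
#' partners count as one partner each), and summarises reproductive skew
#' per sex among the successful breeders: proportion of candidates with
#' at least one assigned offspring, and mean/SD/range of offspring and
#' partner numbers.
#'
#' @param network edge data.frame from [buildMatingNetwork()].
#' @param adults candidate-adult [GenotypeTable-class].
#' @return a list with \code{breeders} (data.frame: id, sex,
#'   fork_length_mm, n_offspring, n_partners over all sampled adults)
#'   and \code{summary} (data.frame, one row per sex).
#' @export
breederSummary <- function(network, adults) {
  ids <- individualIds(adults)
  sex <- sexOf(adults)
  br <- data.frame(id = ids, sex = unname(sex),
                   fork_length_mm = unname(forkLengthOf(adults)),
                   n_offspring = 0L, n_partners = 0L,
                   stringsAsFactors = FALSE)
  if (nrow(network)) {
    offD <- tapply(network$n_offspring, network$dam, sum)
    offS <- tapply(network$n_offspring, network$sire, sum)
    partD <- tapply(network$sire, network$dam,
                    function(x) length(unique(x)))
    partS <- tapply(network$dam, network$sire,
                    function(x) length(unique(x)))
    i <- match(ids, names(offD))
    br$n_offspring <- br$n_offspring +
      ifelse(is.na(i), 0L, as.integer(offD)[i])
    br$n_partners <- br$n_partners +
      ifelse(is.na(i), 0L, as.integer(partD)[i])
    i <- match(ids, names(offS))
    br$n_offspring <- br$n_offspring +
      ifelse(is.na(i), 0L, as.integer(offS)[i])
    br$n_partners <- br$n_partners +
      ifelse(is.na(i), 0L, as.integer(partS)[i])
  }
  summ <- do.call(rbind, lapply(c("F", "M"), function(s) {
    cand <- br[br$sex == s, , drop = FALSE]
    succ <- cand[cand$n_offspring > 0L, , drop = FALSE]
    data.frame(
      sex = s,
      n_candidates = nrow(cand),
      n_successful = nrow(succ),
      prop_successful = if (nrow(cand)) nrow(succ) / nrow(cand) else NA,
      mean_offspring = if (nrow(succ)) mean(succ$n_offspring) else NA,
      sd_offspring = if (nrow(succ) > 1) stats::sd(succ$n_offspring) else NA,
      min_offspring = if (nrow(succ)) min(succ$n_offspring) else NA,
      max_offspring = if (nrow(succ)) max(succ$n_offspring) else NA,
      mean_partners = if (nrow(succ)) mean(succ$n_partners) else NA,
      sd_partners = if (nrow(succ) > 1) stats::sd(succ$n_partners) else NA,
      min_partners = if (nrow(succ)) min(succ$n_partners) else NA,
      max_partners = if (nrow(succ)) max(succ$n_partners) else NA,
      stringsAsFactors = FALSE)
  }))
  list(breeders = br, summary = summ)
}
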