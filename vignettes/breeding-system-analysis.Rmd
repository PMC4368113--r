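---
title: "Reconstructing a polygynandrous breeding system from microsatellite parentage"
author: "polyParent authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a polygynandrous breeding system from microsatellite parentage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyParent)
```

## The problem

In many externally fertilising fishes — salmonids in particular — the
breeding system cannot be observed directly: spawning happens under
water, in minutes, among dozens of candidate parents. Genetic parentage
analysis replaces observation. Candidate spawners and a sample of their
offspring (fry) are genotyped at a panel of codominant microsatellite
loci; each offspring is allocated to a dam and a sire by Mendelian
likelihood; and the resulting mating network yields the quantities that
characterise the breeding system: the proportion of adults that
reproduce, the distribution of family sizes (reproductive skew), the
number of partners per breeder, and the effective number of breeders
$N_b$ behind the cohort.

`polyParent` implements this pipeline end to end for a single spawning
event: duplicate-sample detection, per-locus diversity statistics,
Bayesian parentage assignment by exact enumeration, mating-network
reconstruction with phantom (unsampled) partners, Poisson regressions of
reproductive success, and $N_b$ with a percentile bootstrap. A
polygynandrous mating-system simulator with complete truth tables makes
every stage testable without access to field data.

## Data model

The central container is the S4 class `GenotypeTable`: an individuals
$\times$ loci array of unordered diploid allele pairs (integer fragment
lengths in base pairs), plus per-individual sex, fork length (mm) and
cohort. A genotype is either fully typed or fully missing; half-called
genotypes in input are coerced to missing with a warning, since a single
scored allele cannot be used by any downstream likelihood without
guessing the second. Files are read and written in GenePop (2- or
3-digit allele coding, code 0 = missing) and in a tab-separated dialect
that also carries the metadata.

`AlleleFreqTable` holds per-locus allele relative frequencies and typed
sample sizes. All likelihoods, the probability of identity, expected
heterozygosity and PIC are functions of it. In the pipeline the
frequencies are estimated by direct gene counting from adults and fry
combined, so that every allele segregating in the offspring has a
positive frequency even if it was missed in the adult sample.

## Per-locus statistics

For allele frequencies $p_i$ at a locus typed in $n$ individuals:

* observed heterozygosity $H_O$ — the fraction of typed individuals
  that are heterozygous;
* unbiased expected heterozygosity
  $H_E = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)$ (Nei's
  small-sample correction);
* polymorphic information content
  $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$
  (Botstein's measure of informativeness for linkage/parentage);
* a Hardy–Weinberg goodness-of-fit test: the $k(k+1)/2$ genotype
  classes are compared with their expected counts $np_i^2$ and
  $2np_ip_j$ by chi-square, classes with expected count below 1 pooled
  into one, with degrees of freedom (classes after pooling) $- k$; the
  statistic is undefined (NA) for monomorphic loci or when pooling
  exhausts the degrees of freedom. Bonferroni-adjusted p-values across
  loci are reported alongside, the simplest defensible multiple-test
  control when the original analysis named none. The chi-square variant
  was chosen over an exact Monte Carlo test to mirror the classic
  population-genetics toolchain this analysis replaces; users testing
  loci with many rare alleles should treat borderline p-values with
  care.

The probability of identity
$\mathrm{PI} = \sum_i p_i^4 + \sum_{i<j} (2p_ip_j)^2$ per locus,
multiplied across loci, estimates the chance that two unrelated
individuals share a full multilocus genotype — the quantity that
justifies treating genotype-identical samples as fragments of one
individual.

## Duplicate-sample detection

Fry drift nets shred delicate larvae; one individual can enter the
dataset as several fragments. `findDuplicates()` implements multilocus
match analysis: two samples are duplicates if they agree at every
mutually typed locus and share at least `minSharedLoci` (default 10)
typed loci; groups are the transitive closure of pairwise matches; per
group the copy with the fewest missing loci is retained (ties broken by
smallest id, a rule the original toolchain leaves unspecified).
Deduplication is idempotent.

An exact-match detector has an intrinsic identifiability limit: two
*full siblings* share a complete multilocus genotype with probability
$\prod_\ell \left(\tfrac14 + \tfrac12 S_\ell + \tfrac12 S_\ell^2 -
\tfrac14 \sum_i p_{i\ell}^4\right)$ where $S_\ell = \sum_i p_{i\ell}^2$
— around $10^{-6}$–$10^{-5}$ for a 19-locus panel of mean $H_E \approx
0.6$. A cohort of ~900 fry from ~50 mating pairs contains on the order
of $10^4$ full-sib pairs, so an expected handful of distinct sibs per
study are genuinely indistinguishable from fragment duplicates, and no
matching rule can separate them. The test suite therefore distinguishes
detector errors (grouping two samples that differ at some mutually
typed locus, which must never happen) from these collisions (which are
counted, not asserted away).

## Parentage model

For one offspring and candidate sets $D$ (dams) and $S$ (sires) the
hypothesis space is $(D \cup \{\mathrm{U}\}) \times (S \cup
\{\mathrm{U}\})$, U being the unsampled-parent class. Per locus the
Mendelian transition probability is:

* both parents named: the average over the four equiprobable
  parental-allele transmissions that reproduce the offspring pair;
* one parent named: the transmitted allele is uniform over the parent's
  two alleles, the other allele is a population draw;
* no parent: the Hardy–Weinberg genotype frequency $P_{HW}$.

Genotyping error enters as a per-locus mixture
$L = (1-e)\,L_{\mathrm{mendel}} + e\,P_{HW}(g_{\mathrm{off}})$, the
"random replacement" model: with probability $e$ the recorded genotype
is an unrelated Hardy–Weinberg draw. The default $e = 0.01$ is the
simplest setting consistent with tolerating one exclusion; it is
deliberately no smaller than the simulator's error rate so that real
errors are absorbed rather than zeroing out the true parent. A missing
genotype — in the offspring or in a named parent — contributes a factor
of 1 at that locus.

Candidates with more than `maxMismatch` (default 1) single-parent
exclusions against the offspring are removed before enumeration, the
classic "maximum one mismatch" rule. The posterior is categorical and
small enough to compute exactly: each sampled candidate has prior
weight 1 and each unsampled class weight $0.5\,|{\cdot}|$ (half the
number of sampled candidates of that sex, exposed in
`parentageConfig()`); posterior $\propto$ prior $\times$ likelihood,
normalised. Because the hypothesis set is at most a few thousand cells,
no Monte Carlo machinery is needed and there is no sampling error to
diagnose; estimating the unsampled population size from the data, and
parental covariates in the assignment model itself, are out of scope.

A dam (sire) is assigned when its marginal posterior — summed over the
other sex's hypotheses — reaches `confidenceCutoff` (default 0.90,
inclusive at the boundary); a pair is assigned when the joint MAP
hypothesis names two sampled parents at that confidence. Both marginal
and joint readings of the cutoff are reported because the original
protocol does not say which it used. Offspring with fewer than
`minTypedLoci` (default 10) typed loci are flagged untestable rather
than assigned.

## Mating network, skew and $N_b$

Offspring with both parents assigned contribute to the (dam, sire)
edge. Offspring with exactly one assigned parent are attributed to a
single *phantom* partner of that parent — all of one dam's
father-unassigned offspring are assumed to share one unsampled sire,
and symmetrically. Offspring with no assigned parent are dropped.
`breederSummary()` then tallies, for every sampled adult, offspring
(sum of incident edge weights) and partners (distinct opposite-sex
endpoints, phantoms counting as one each), and summarises per sex the
proportion successful and the mean/SD/range of offspring and partners
among successful breeders.

The per-sex effective number of breeders uses the family-size-variance
estimator
$$N_{bf} = \frac{k_f (N_f - 1)}{1 + V_{kf}/k_f},$$
with $k_f$ and $V_{kf}$ the mean and variance (n−1 denominator) of
offspring counts over all $N_f$ candidate females — zeros included,
because $N_f$ counts sexually mature candidates, not successful ones;
a `convention = "successful"` switch restricts to successful breeders
for comparison. The sexes combine harmonically,
$N_b = 4 N_{bf} N_{bm} / (N_{bf} + N_{bm})$. Confidence limits are a
percentile bootstrap: each sex's count vector is resampled with
replacement (same length), $N_b$ recomputed, and the 2.5% and 97.5%
percentiles taken over 1000 replicates (the stated "2.5 and 97
percentiles" of the source protocol are read as the standard 95%
limits). The bootstrap is bit-reproducible from its seed, and the count
vectors are treated as multisets (sorted internally) so permutations of
the input cannot change the result. Phantom partners never enter the
candidate count vectors — they are not sampled adults — but do enter
partner counts.

Reproductive-success regressions use a Poisson GLM with log link
(IRLS via `stats::glm`, deviance tolerance $10^{-10}$, at most 100
iterations), reporting the likelihood-ratio chi-square against the
intercept-only model on 1 df; a constant covariate collapses to the
closed-form intercept-only fit. The GLMs are fitted on successful
breeders, matching the sample sizes the field reports. Sex differences
in fork length are tested with Welch's $t$ computed from summary
statistics (mean, SD, n per sex), since published tables rarely carry
the raw vectors.

## The simulator

`simulateStudy()` generates a complete study under a polygynandrous
mating system, with truth retained at every step:

1. **Population.** Per-locus allele frequencies are drawn from a
   symmetric Dirichlet (concentration 1) over a 19-locus panel whose
   allele counts (2–12 per locus) follow a published grayling panel;
   with these counts the Dirichlet(1) prior gives an expected mean
   $1 - \sum p_i^2$ of about 0.6 and mean PIC near 0.52, bracketing the
   diversity of the motivating study without tuning. Adults (57
   candidate dams, 97 candidate sires by default) receive
   Hardy–Weinberg genotypes, sexes, and normal fork lengths (females
   288 ± 19 mm, males 321 ± 28 mm).
2. **Breeding.** 39% of dams and 33% of sires are selected to breed.
   Each breeding female draws a partner count from a zero-truncated
   Poisson with mean 2.2, capped at 6, and samples that many distinct
   breeding males (optionally weighted log-linearly by male length);
   male partner counts emerge from the bipartite assignment and are
   capped at 6. Per-pair offspring counts are negative binomial (mean
   18, dispersion 2 — chosen so family-size SD ≈ 13, i.e. SD > mean,
   the hallmark of salmonid reproductive skew), then rescaled to the
   895-fry target by a multinomial draw; pairs left with zero fry drop
   out of the truth network, so realised breeder numbers sit slightly
   below the selected proportions. Fry genotypes follow Mendelian
   segregation, one allele uniformly from each parent per locus.
3. **Observation.** Fry genotypes suffer per-locus error at rate
   `eSim` (default 0.005): by default an erroneous locus is replaced by
   a random Hardy–Weinberg genotype, matching the likelihood's error
   model; an alternative single-allele replacement mode provides a
   deliberately misspecified error process for robustness checks.
   Loci go missing at `missingRate` (default 0.02, typical of
   visually-checked microsatellite scoring). A fraction
   `duplicateRate` (default 0.05) of fry is duplicated as "fragment"
   samples with new ids and a little extra missingness (0.05 — the
   motivating study matched fragments exactly across the full panel,
   implying near-complete fragment genotypes). Adults are kept
   noise-free (fin-clip DNA) and optionally subsampled
   (`parentSamplingFrac`). Every operation is a pure function of the
   configuration seed.

What the simulator does **not** emulate: spatially structured spawning,
spawning-time effects, overlapping generations, null alleles,
allele-size binning errors, and fry length. Passing tests therefore
demonstrate correctness of the estimators under the stated generative
model, not robustness to every field artefact.

## Numerical choices

* Likelihoods accumulate in log space; a hypothesis set whose every
  member has zero likelihood yields "no assignment", not an error.
* Posterior normalisation subtracts the maximum log-likelihood before
  exponentiating.
* Ties at the confidence cutoff are assigned (the comparison is
  $\ge$).
* Duplicate-group retention: fewest missing loci, then lexicographic
  id.
* The bootstrap CI of a degenerate (constant-count) study has zero
  width; percentile CIs need not contain the point estimate and the
  code does not pretend otherwise.
* Fragment-length alleles above 999 bp cannot be written in 3-digit
  GenePop coding and raise an error rather than truncating.

## Known limitations

* **Sibling collisions in duplicate detection.** As derived above,
  a few genotype-identical full-sib pairs per ~900-fry cohort are
  expected at this panel's informativeness; they are inherently
  indistinguishable from fragment duplicates by any exact-match rule.
* **Phantom-partner inflation.** With very large true families (~40
  fry per successful breeder under the default configuration), even a
  ~98% per-fry single-parent assignment rate leaves most breeders with
  at least one half-assigned fry, and the one-phantom-per-parent rule
  then inflates mean partner counts by roughly 10–20% relative to the
  truth network. This is a property of the attribution rule interacting
  with the 0.90 cutoff and the unsampled-class prior, not an
  implementation artefact; the exact-recovery property is verified
  separately under perfect assignment.
* The unsampled-parent prior weight is fixed (half the candidate
  count), not estimated from the data; studies with genuinely
  incomplete adult sampling should treat the unsampled posterior mass
  as approximate.
* The Poisson GLMs carry no overdispersion correction, mirroring the
  original analysis; family-size data this skewed would fail a
  dispersion check, so the chi-squares are comparators, not inference
  one should lean on.

## Problem sizes in the test suite

The default study (57 + 97 adults, 895 fry, 19 loci) runs in a few
seconds per end-to-end pass; the test suite uses that size for the
design-recovery and duplicate-recovery checks (the latter over 20
seeds) and a 12 + 16 adult, 120-fry configuration for the faster
structural tests. Oracle-equivalence checks enumerate every panel of
1–3 loci and 0–2 candidates per sex against a brute-force
implementation.

## A worked run

```{r, eval = FALSE}
library(polyParent)

study <- simulateStudy(simulationConfig(seed = 1))
res <- runPipeline(study$adults, study$fry, outDir = "run1",
                   nbReps = 1000, seed = 1)
res$nb
res$breeders$summary
```

The run directory then contains the locus summary table, the duplicate
report, the per-offspring assignments, the mating-network edge list,
the per-breeder table, the $N_b$ JSON block and a machine-readable run
report.
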