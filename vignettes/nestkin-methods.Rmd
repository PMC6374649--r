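---
title: "Models and methods behind nestkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nestkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nestkin` estimates the spatial ecology and mating system of a bumble bee
population from multilocus microsatellite genotypes of field-sampled
workers and dissected queens. This vignette is the package's own account
of the models it fits, the assumptions they rest on, the tunable
parameters, and the design decisions taken where more than one defensible
choice existed. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The study system and its genetic structure

Bumble bees are haplodiploid: females (queens, workers) are diploid,
males haploid. A colony is headed by one queen mated to a small number of
males (here 1–5) whose sperm she stores. Two workers of the same colony
are therefore either **full sisters** — same father, sharing his single
allele plus one of the queen's two alleles — or **maternal half-sisters**
— different fathers, sharing only the maternal side. A queen's offspring
by one male form a **patriline**. Every inference in the package reduces
to exploiting this structure:

- per locus, a worker carries exactly one maternal allele (each of the
  queen's two with probability 1/2) and her patriline's paternal allele;
- unrelated workers are independent Hardy–Weinberg draws from the
  population allele frequencies;
- loci are unlinked and a father's alleles at different loci are
  independent draws, so all cross-locus dependence flows through shared
  parents.

## Locus quality control

Worker genotypes from each year are tested against Hardy–Weinberg
proportions with a Monte-Carlo **conditional exact test**: the statistic
is the probability of the genotype array given the allele counts, and the
null is sampled by shuffling the pooled alleles into random diploid
pairings (10,000 shuffles by default, seeded). Per year, p-values are
Bonferroni-corrected across loci. The correction method follows from the
corrected alpha the analysis is built around (0.05/400 = 0.000125 for the
linkage family); no other multiplicity scheme is assumed.

Null alleles — alleles that fail to amplify and inflate apparent
homozygosity — are summarized by the Chakraborty homozygote-excess
estimator `r = (He − Ho)/(He + Ho)` with unbiased expected
heterozygosity. This is a deliberate substitute for the unnamed internal
algorithm of common parentage software: it is closed-form, testable, and
may differ numerically from other estimators; negative values
(heterozygote excess) are reported, not clamped.

Linkage between locus pairs is tested by permuting one locus's
single-locus genotypes across individuals and recomputing the chi-square
statistic of the joint genotype table.

A locus is excluded from sibship analysis iff it (a) deviates from HWE
after correction in **every** tested year, (b) has a null-allele estimate
above 0.1, or (c) is significantly linked to a more informative locus.
"More informative" is ranked by expected heterozygosity; exact ties drop
the lexicographically later name, so selection is deterministic and
order-independent. All 20 polymorphic loci (not only the QC survivors)
are used for mating-frequency estimation, whose inference rests on
simulated haploid males and is insensitive to HWE deviations.

## Queen mating frequency from sperm profiles

The number of males behind a queen's stored sperm is bounded below by the
largest number of per-locus sperm alleles not attributable to the queen,
supported at two or more loci. Because spermathecal dissections can carry
queen tissue, shared alleles are screened in two steps:

1. **Expected matching rate.** For every typed locus of every queen, the
   probability that her alleles would be matched by the pooled alleles of
   two random mates (double mating being the commonest polyandrous
   class): for a heterozygote {a,b} with two mates this is `2·p_a·p_b`,
   and in general the inclusion–exclusion probability that all her
   distinct alleles appear among n haploid draws. 10,000 Bernoulli trials
   of these probabilities are summed within queens across loci; the
   critical value is the across-queen mean rate plus two standard
   deviations (upper-tail probability 0.0228 at z = 2 under normality).
   A sample matching the queen at a rate above the critical value is
   flagged as contaminated.
2. **Attribution.** In a flagged sample, a shared allele is subtracted as
   a contaminant only where the queen's *complete* genotype at that locus
   is present in the profile — a shared allele unaccompanied by a
   heterozygous queen's other allele must be a true male allele.

For a homozygous queen the "match" definition (her single allele present
at least once) is one of two defensible readings of the matching model;
the package adopts the literal one and applies it consistently in the
screen, the flagging, and the calibration, so the three stages cannot
disagree. Both the Monte-Carlo matching machinery and its analytic
binomial mean are implemented (`analytic = TRUE`); Monte Carlo is the
default because the critical value inherits its sampling spread.

The **miscount calibration** pairs each queen genotype with simulated
sperm profiles from t = 1..9 males drawn at the population frequencies,
applies the identical flagging-and-counting procedure, and tabulates
P(observed = k | true = t), averaged across queens. Under this error-free
counting model observed counts never exceed true counts, so the mean
minimum mating frequency is conservative by construction. The **maximum
likely mating frequency** given an observed maximum k is the largest t
with P(observed ≤ k | t) ≥ 0.05.

## Sibship reconstruction

The full-pedigree MCMC of dedicated parentage software is not
reimplemented. The substitute keeps the same interface contracts
(inclusion probability ≥ 0.8, within-year assignment only, polyandrous
queens / monandrous males, acceptance of colonies with at most 5
patrilines) and works in three stages:

1. **Full-sister grouping.** Exact per-locus genotype-pair probabilities
   are computed for full-sib, maternal half-sib and unrelated hypotheses
   by marginalizing queen genotypes over Hardy–Weinberg priors and father
   alleles over population frequencies, through a symmetric per-allele
   mistyping channel. Workers are agglomerated on the full-sib
   log-likelihood ratio while the summed cross-group ratio plus a single
   per-decision prior penalty stays positive.
2. **Patriline-aware colony likelihood.** Full-sister groups are merged
   into colonies under the joint probability that one queen (summed over
   Hardy–Weinberg genotype candidates per locus) mothers all groups, with
   one father allele marginalized per group per locus. This captures the
   two signals a pairwise method structurally misses: a single queen must
   explain *all* members simultaneously, and a paternal allele shared by
   a whole patriline cannot masquerade as maternal. Pairwise cross-score
   sums are unsuitable as a merge criterion because scores that share an
   individual are strongly correlated — whole unrelated groups can drift
   positive together.
3. **Worker-level refinement.** Each worker may leave its patriline for
   another colony (as a new patriline) or for singleton status whenever
   that increases the penalized colony likelihood; the final inclusion
   probability is the softmax of the worker's current placement against
   every alternative, and workers below 0.8 are left as singletons.

The sibship prior uses the mating-system algebra: with mean mating
frequency m and mean sampled patriline size n, a sample holds mn maternal
sisters per n paternal sisters; the expected full-sib : half-sib odds
among within-colony pairs are (n − 1) : (m − 1)·n, and the prior
probability that a random same-year pair is sibs defaults to
(m·n − 1)/(N − 1). The pipeline runs a first pass without mating
information to estimate n as the mean sampled patriline size, then the
final prior-informed pass. The prior enters each merge or assignment
decision once, as log prior odds — not once per pair, which would scale
the penalty quadratically in group size and veto legitimate merges.

Patrilines within an accepted colony are counted by a greedy first-fit
grouping of workers into single-father classes consistent with the
inferred queen (workers processed in id order — deterministic), and
colonies are rejected only when the count **exceeds** 5; the boundary
case (exactly the maximum) is accepted, matching the reported rejection
of colonies with more than five patrilines.

Queen genotypes are inferred per locus as the posterior over genotype
candidates given the colony's workers, with the patriline structure fixed
by the queen-free full-sister grouping; loci are retained at posterior
≥ 0.8. With per-locus father marginalization alone, a small colony whose
patrilines happen to carry worker-shared alleles is genuinely ambiguous
(the shared allele may sit in the queen); such loci simply fail the 0.8
filter rather than being guessed.

## Foraging distances and nest density

A colony's nest is placed at the mean centre of its workers' sampling
locations; the colony-specific worker foraging distance is the mean
Euclidean distance of its workers to that centre. Colonies need at least
two workers more than 4 m apart (the GPS receiver's precision). The
mean-centre estimator is biased slightly below the kernel mean for small
colonies (distances are measured to a sample centroid, a factor of about
sqrt(1 − 1/n) for n workers); the acceptance script therefore also
reports the estimator applied to the generator's true memberships as the
estimator-level oracle. As a robustness check, pairwise sampling
distances of reconstructed full sisters and half-sisters are compared by
a Welch t test: over-assignment of half-sisters would inflate the latter.

Total colony numbers are estimated with the classic abundance-based
coverage estimator over workers-per-colony counts, rare cutoff k = 10
(the estimator's standard default; the source analyses do not print
one):

S_ACE = S_abund + S_rare/C_ACE + (F1/C_ACE)·γ²,  C_ACE = 1 − F1/N_rare,

with γ² the bias-corrected squared CV of the rare class, floored at
zero. Colonies represented by a single worker enter with abundance 1 and
drive F1. When every rare colony is a singleton the coverage is zero and
the function stops with an instruction to use a Chao1-type estimator
rather than returning a silent answer. The standard error is a seeded
nonparametric bootstrap over sampled workers (1,000 replicates by
default); the delta-method variance of ACE was not implemented because
its long closed form is easy to get subtly wrong and the bootstrap is
directly testable. The 95% interval is estimate ± 1.96·SE. Nest density
divides the estimate by the core sampling area plus the outward buffer
`4·side·r + π·r²` (edge strips plus quarter-circle corners) within the
mean foraging distance r of the square's periphery.

## Lineage survival and isolation by distance

Queens inferred for the later year's accepted colonies are run through
the sibship machinery as candidate sisters of every earlier-year colony:
the queen joins a colony as one more offspring of its queen, her score is
the patriline-aware likelihood gain plus the prior log odds, and the
assignment probability is the softmax over all colonies plus a no-colony
alternative. Matches at probability ≥ 0.8 mark surviving lineages; the
survival rate is the fraction of earlier-year colonies with at least one
match. Note the estimate is structurally conservative at realistic
sampling depth: only multi-worker later-year colonies yield inferred
queens, and a surviving lineage whose source colony was never sampled
cannot be matched.

Pairwise relatedness between inferred queens uses the Queller–Goodnight
(1989) estimator, symmetrized by pooling numerators and denominators over
both directions and all shared typed loci; pairs with no shared typed
locus are excluded and logged. One of several published estimators had to
be chosen (the original analyses do not name theirs); Queller–Goodnight
is standard, closed-form, and oracle-testable. Isolation by distance is
an ordinary least-squares regression of pairwise relatedness on
**untransformed** inter-nest distance in meters, with the slope's F test
on (1, n_pairs − 2) degrees of freedom. Pairwise observations are not
independent; the F test is reported as-published convention, and a
clearly labeled Mantel permutation test (`ibd_mantel`) is provided as the
dependence-respecting alternative. Under the generator's unstructured
default the OLS test empirically holds its nominal 5% size (checked over
200 null replicates in the acceptance suite).

## The synthetic-data generator

`sim_config()` defaults describe the study conditions the analyses
assume: a 2 × 2 km arena split into 500 × 500 m sampling squares capped
at 40 workers; 20 microsatellite loci with 8 alleles each and Dirichlet(1)
frequency spectra; queens mated to 1–5 males with probabilities
(0.34, 0.46, 0.14, 0.04, 0.02) — chosen so that roughly a third of queens
are monandrous and conservative counting lands near a mean minimum of
1.7–1.9; a half-normal radial foraging kernel with 100 m mean
displacement (the kernel family is a choice; only mean distances are
reported empirically, so the generator parameterizes by the mean, with an
exponential option); 2.26% allelic mistyping and 10% per-locus
missingness; sperm-allele dropout 0.1 (sperm DNA yields are low) and
queen-tissue contamination probability 1 (essentially all real sperm
samples screen as contaminated); between-year lineage survival 0.1; 250
and 120 colonies in successive years with Poisson(1.5) sampled workers
per colony. Within-colony sperm use is equal across patrilines — the
within-colony distribution of patriline sizes is unreported anywhere, and
equal use is the flagged assumption. Immigrant queens are unrelated draws
from the same frequencies (no built-in spatial structure, matching the
null finding this class of analysis reports); `spatial_structure = TRUE`
makes surviving daughters nest near the natal nest for power studies.

What the generator does **not** emulate: temporal colony demography,
floral-resource landscapes, real microsatellite artifacts beyond
symmetric mistyping (stutter, large-allele dropout, true null alleles),
and linkage. Passing recovery tests therefore demonstrate correctness of
the inference machinery under its own model, not robustness to every
failure mode of real data.

## Numerical choices

- All per-locus machinery works on an enumeration of unordered genotype
  states (K(K+1)/2 for K alleles); joint pair tables and queen-candidate
  tables are computed once per locus and cached.
- Likelihoods are accumulated in log space; segment-wise logsumexp guards
  against underflow in colony likelihoods, and impossible configurations
  (−Inf under zero error) are propagated, never NaN.
- Monte-Carlo p-values use the add-one estimator (hits + 1)/(reps + 1)
  and are deterministic given a seed; seeded helpers restore the caller's
  RNG state.
- Ties break deterministically everywhere: locus selection by name order,
  patriline grouping and hill-climbing by worker id order.
- Degenerate inputs fail loudly: empty p-value families, zero-coverage
  ACE, zero-variance distances, queens typed at no locus, partial
  (half-missing) genotype calls.

## Problem sizes

The test suite validates partition recovery on 30 colonies × 5 workers
with 14 eight-allele loci and 2% mistyping (adjusted Rand index ≥ 0.9),
monandry recovery on 1,000 simulated queens with a 20-locus uniform
panel (within 3 percentage points, never overcounting), kernel-mean
recovery on 50 colonies × 5 workers (within 15%), IBD test size over 200
null replicates of 40 queens, and lineage-survival recovery at planted
probability 0.1 over 200 colonies (within binomial 95% bounds). The
acceptance script runs the full pipeline on 150 + 100 colonies with
Poisson(1.5) workers per colony. These sizes were chosen as the smallest
at which the statistical contracts are sharp; all scale linearly upward
through `sim_config()`.

## Known limitations

- The sibship partitioner is a greedy maximizer of a penalized colony
  likelihood, not a posterior sampler; inclusion probabilities are
  softmax approximations, not MCMC posteriors.
- Queen-genotype inference marginalizes one father per patriline per
  locus but does not track father identity across loci; per-locus
  ambiguities are filtered by the 0.8 confidence rule instead of being
  resolved jointly.
- The miscount calibration shares the counting rules with the estimator
  it calibrates (as designed), so it quantifies undercounting given the
  model, not model error itself.
- ACE assumes colonies are sampled independently with detectability
  driven by abundance; systematic under-assignment of workers inflates
  singleton counts and with them the estimated number of unsampled
  colonies.
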