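# nestkin

Molecular spatial ecology of social bees from microsatellite genotypes.

Field studies of bumble bees (*Bombus* spp.) can rarely observe nests
directly: most of what is known about foraging ranges, nest densities and
queen mating systems comes from genotyping foraging workers and dissected
queens, and reconstructing the colonies behind them. `nestkin` implements
that full inference chain for haplodiploid social insects:

- **Locus quality control** — Monte-Carlo exact tests of Hardy–Weinberg
  equilibrium per year, Chakraborty-style null-allele estimation from
  homozygote excess, genotypic linkage permutation tests, Bonferroni
  correction, and the three-rule locus exclusion battery (HWE deviation in
  every year, null-allele frequency > 0.1, linkage with a more informative
  locus).
- **Queen mating frequency** — from spermathecal sperm profiles, with a
  contamination screen (the probability that a queen's alleles would be
  matched by two random mates, locus by locus; samples matching at a rate
  above the across-queen mean + 2 SD are treated as contaminated), the
  shared-allele attribution rules, the two-locus support rule for male
  alleles, and a miscount calibration P(observed = k | true = t) that
  yields the maximum likely mating frequency.
- **Sibship reconstruction** — workers are partitioned into colonies of
  full and maternal half-sisters under haplodiploidy (full sisters share
  their father's single allele and one of two maternal alleles). Exact
  per-locus pair likelihoods seed full-sister groups, which are merged
  under a patriline-aware colony likelihood (one queen genotype summed
  over Hardy–Weinberg priors, one father per patriline marginalized at the
  population allele frequencies), refined by hill-climbing, with softmax
  inclusion probabilities and the ≥ 0.8 inclusion / ≤ 5 patriline
  acceptance rules.
- **Spatial statistics** — mean-centre nest locations, colony-specific
  worker foraging distances (with the 4 m GPS-precision rule), and the
  full- versus half-sister pairwise distance check (Welch t).
- **Nest density** — the abundance-based coverage estimator (ACE),
  treating colonies as classes and sampled workers per colony as
  abundances: S_ACE = S_abund + S_rare/C_ACE + (F1/C_ACE)·γ², divided by
  the core sampling area plus the outward buffer (4·side·r + πr²) defined
  by the mean foraging distance.
- **Lineage survival and isolation by distance** — inferred queen
  genotypes (posterior ≥ 0.8 per locus) matched across years as candidate
  sisters of the previous year's colonies, and the regression of pairwise
  Queller–Goodnight relatedness on inter-nest distance.
- **A spatially explicit synthetic-population generator** — colonies with
  queens mated to 1–5 haploid males placed in a 2 × 2 km arena, workers
  displaced by a half-normal foraging kernel and sampled on a 500 m grid
  capped at 40 workers per square, allelic mistyping, missingness, sperm
  dropout and queen-tissue contamination — carrying true colony and
  patriline labels so that every stage can be scored.

## Worked example

```r
library(nestkin)

## a synthetic population with known colony structure
cfg <- sim_config(seed = 42, n_colonies = 30, years = 2014,
                  workers_per_colony = 5, n_loci = 14,
                  alleles_per_locus = 8, missing_rate = 0,
                  mistyping_rate = 0.02)
pop <- simulate_population(cfg)
workers <- simulate_workers(pop, cfg)
obs <- apply_genotyping_error(workers$genotypes, pop$freqs,
                              mistyping_rate = 0.02, seed = 1)

## assign workers to colonies as full / maternal half sisters
freqs <- estimate_allele_frequencies(obs)
part <- reconstruct_colonies(obs, freqs,
                             priors = sibship_priors(m = 1.9, n = 2.6),
                             error_rate = 0.02)
part
#> colony_partition: 150 workers in 32 colonies (30 accepted with >= 2 workers and <= max patrilines)

## nest locations and colony-specific worker foraging distances
nests <- colony_foraging_distances(part, workers$coords)
nests
#> nest_estimates: 30 colonies, mean colony-specific foraging distance 94.4 m (max worker 241.0 m)

## nest density via the abundance-based coverage estimator
cols <- part$colonies
ab <- cols$n_workers[cols$accepted | cols$n_workers == 1]
ace <- ace_estimate(ab, seed = 1)
ace
#> ACE: 32 colonies detected, estimated total 32.43 (SE 0.97), coverage 0.987, completeness 0.99
nest_density(ace, core_area_ha = 400,
             buffer_area_ha = buffer_area(2000, nests$mean_colony_distance))
#> nest density: 0.07 colonies per ha (32.43 colonies over 478.28 ha)
```

The 30 simulated colonies are recovered almost perfectly (adjusted Rand
index 0.986 against the generator's truth), the mean colony-specific
foraging distance of 94 m reflects the 100 m kernel mean (the mean-centre
estimator sits slightly below it for small colonies), and with five
workers per colony the sample is nearly complete, so ACE adds little to
the observed colony count. Sparser sampling — many colonies represented
by a single worker — is where the coverage correction becomes large.

The whole chain, from either a synthetic scenario or GenAlEx-style CSV
inputs, runs through one call:

```r
res <- run_pipeline(pipeline_config(synthetic = cfg, out_dir = "run"))
```

which writes per-stage CSV outputs and a single `summary.json`.

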