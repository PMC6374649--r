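## Shared fixture builders: everything is generated in code, no data files.

## allele_freqs object with equifrequent (or given) frequencies at each locus
make_freqs <- function(n_loci = 1, alleles = c(100, 102, 104, 106),
                       p = NULL) {
  if (is.null(p)) p <- rep(1 / length(alleles), length(alleles))
  fr <- lapply(seq_len(n_loci), function(l) stats::setNames(p, alleles))
  names(fr) <- paste0("L", seq_len(n_loci))
  structure(fr, absent = character(0), class = "allele_freqs")
}

## genotype_table from per-locus lists of allele pairs:
## genotypes[[i]] = c(a, b) repeated across n_loci loci
make_gt <- function(pairs, n_loci = 1, year = 2014, ids = NULL) {
  n <- length(pairs)
  a1 <- matrix(vapply(pairs, function(p) p[1], numeric(1)), n, n_loci)
  a2 <- matrix(vapply(pairs, function(p) p[2], numeric(1)), n, n_loci)
  genotype_table(ids %||% paste0("w", seq_len(n)), year, a1, a2,
                 paste0("L", seq_len(n_loci)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## allele vectors from genotype class counts (nAA, nAB, nBB)
hwe_counts_to_calls <- function(naa, nab, nbb, a = 1L, b = 2L) {
  list(a1 = c(rep(a, naa), rep(a, nab), rep(b, nbb)),
       a2 = c(rep(a, naa), rep(b, nab), rep(b, nbb)))
}

## a standard small synthetic scenario used by several tests
scenario_workers <- function(seed, n_colonies = 30, workers = 5,
                             n_loci = 14, alleles = 8, error = 0.02,
                             spectrum = "dirichlet") {
  cfg <- sim_config(seed = seed, n_colonies = n_colonies, years = 2014,
                    workers_per_colony = workers, n_loci = n_loci,
                    alleles_per_locus = alleles, freq_spectrum = spectrum,
                    missing_rate = 0, mistyping_rate = error)
  pop <- simulate_population(cfg)
  ws <- simulate_workers(pop, cfg)
  obs <- if (error > 0) {
    apply_genotyping_error(ws$genotypes, pop$freqs, error, 0,
                           seed = seed + 1000L)
  } else ws$genotypes
  list(cfg = cfg, pop = pop, ws = ws, obs = obs, freqs = pop$freqs,
       truth = ws$truth)
}

## partition-like object from a truth table (for spatial/lineage tests)
truth_partition <- function(truth) {
  list(assignments = data.frame(
    id = truth$id, year = truth$year, colony = truth$colony,
    inclusion = 1, patriline = truth$patriline, accepted = TRUE))
}
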