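## brute-force oracle: P(all the queen's distinct alleles appear among
## n_males i.i.d. haploid draws), by enumeration over ordered male tuples
match_prob_oracle <- function(queen, p, n_males = 2) {
  alleles <- as.integer(names(p))
  tuples <- as.matrix(expand.grid(rep(list(seq_along(alleles)), n_males)))
  pr <- apply(tuples, 1, function(tp) prod(p[tp]))
  hit <- apply(tuples, 1, function(tp) {
    all(unique(queen) %in% alleles[tp])
  })
  sum(pr[hit])
}

test_that("locus match probability follows the two-mate sharing model", {
  p2 <- c(`1` = 0.5, `2` = 0.5)
  expect_equal(locus_match_probability(c(1, 2), p2), 0.5)
  expect_equal(locus_match_probability(c(1, 1), c(`1` = 1)), 1)
  expect_equal(locus_match_probability(c(1, 1), c(`1` = 0.3, `2` = 0.7)),
               1 - 0.7^2)
  ## arbitrary frequencies against the enumeration oracle
  p4 <- c(`1` = 0.4, `2` = 0.3, `3` = 0.2, `4` = 0.1)
  for (queen in list(c(1, 2), c(2, 2), c(3, 4))) {
    for (nm in 1:3) {
      expect_equal(locus_match_probability(queen, p4, nm),
                   match_prob_oracle(queen, p4, nm), tolerance = 1e-12)
    }
  }
  expect_error(locus_match_probability(c(1, 9), p4), "absent")
})

test_that("the matching simulation recovers binomial expectations", {
  ## 10 loci with match probability 0.5 each: ~5 expected matches, rate 0.5
  freqs <- make_freqs(n_loci = 10, alleles = c(100, 102), p = c(0.5, 0.5))
  queen <- genotype_table("Q1", 2014, matrix(100, 1, 10),
                          matrix(102, 1, 10), names(freqs))
  s1 <- run_simulation_1(queen, freqs, reps = 20000, seed = 1)
  expect_lt(abs(s1$per_queen$expected_matches - 5), 0.1)
  expect_lt(abs(s1$per_queen$expected_rate - 0.5), 0.02)
  ## analytic path equals the exact binomial mean
  s1a <- run_simulation_1(queen, freqs, analytic = TRUE)
  expect_equal(s1a$per_queen$expected_matches, 5)
  ## deterministic under a fixed seed
  s1b <- run_simulation_1(queen, freqs, reps = 2000, seed = 7)
  s1c <- run_simulation_1(queen, freqs, reps = 2000, seed = 7)
  expect_identical(s1b$per_queen, s1c$per_queen)
  ## critical value is mean + 2 SD
  expect_equal(matching_critical_value(0.369, 0.075), 0.519)
})

test_that("contamination flags compare observed rates to the critical value", {
  freqs <- make_freqs(n_loci = 4)
  queens <- genotype_table(c("Q1", "Q2"), 2014,
                           matrix(100, 2, 4), matrix(102, 2, 4),
                           names(freqs))
  both <- list(L1 = c(100L, 102L), L2 = c(100L, 102L),
               L3 = c(100L, 102L), L4 = c(100L, 102L))
  none <- list(L1 = 104L, L2 = 104L, L3 = 104L, L4 = 104L)
  prof <- sperm_profiles(list(Q1 = both, Q2 = none), names(freqs))
  fl <- flag_contamination(queens, prof, critical_value = 0.52)
  expect_equal(fl$match_rate, c(1, 0))
  expect_identical(fl$flagged, c(TRUE, FALSE))
  ## a rate just above the critical value is flagged
  fl2 <- flag_contamination(queens[1], sperm_profiles(list(Q1 = both),
                                                      names(freqs)), 0.55)
  expect_true(fl2$flagged)
  expect_false(flag_contamination(queens[1],
                                  sperm_profiles(list(Q1 = both),
                                                 names(freqs)), 1.1)$flagged)
})

test_that("minimum mate counts apply the attribution and support rules", {
  ## queen {a,b}, {c,c}, {d,e}; contaminated sperm {a,f}, {c,g}, {d,h}:
  ## locus 1 keeps a (partner allele b absent), locus 2 subtracts c
  ## (homozygous queen fully present), locus 3 keeps d -> counts (2,1,2)
  freqs <- make_freqs(n_loci = 3, alleles = seq(100, 114, 2))
  queen <- genotype_table("Q1", 2014,
                          matrix(c(100, 104, 106), 1),
                          matrix(c(102, 104, 108), 1), names(freqs))
  prof <- sperm_profiles(list(Q1 = list(
    L1 = c(100L, 110L), L2 = c(104L, 112L), L3 = c(106L, 114L))),
    names(freqs))
  res <- count_min_males(queen, prof, stats::setNames(TRUE, "Q1"))
  expect_equal(res$min_males, 2L)
  ## a single father's alleles, none shared with the queen -> 1
  prof1 <- sperm_profiles(list(Q1 = list(L1 = 110L, L2 = 112L, L3 = 114L)),
                          names(freqs))
  expect_equal(count_min_males(queen, prof1,
                               stats::setNames(FALSE, "Q1"))$min_males, 1L)
  ## two male alleles at exactly one locus are unsupported -> 1
  prof2 <- sperm_profiles(list(Q1 = list(
    L1 = c(110L, 112L), L2 = 112L, L3 = 114L)), names(freqs))
  expect_equal(count_min_males(queen, prof2,
                               stats::setNames(FALSE, "Q1"))$min_males, 1L)
  ## without the contamination flag, shared alleles count as male alleles
  res3 <- count_min_males(queen, prof, stats::setNames(FALSE, "Q1"))
  expect_equal(res3$min_males, 2L)
})

test_that("mate counting is invariant to locus order and allele relabeling", {
  freqs <- make_freqs(n_loci = 3, alleles = seq(100, 114, 2))
  queen <- genotype_table("Q1", 2014, matrix(c(100, 104, 106), 1),
                          matrix(c(102, 104, 108), 1), names(freqs))
  prof <- list(L1 = c(100L, 110L), L2 = c(104L, 112L), L3 = c(106L, 114L))
  base <- count_min_males(queen, sperm_profiles(list(Q1 = prof),
                                                names(freqs)),
                          stats::setNames(TRUE, "Q1"))$min_males
  ## permute loci
  queen_p <- subset_loci(queen, c("L3", "L1", "L2"))
  prof_p <- sperm_profiles(list(Q1 = prof[c("L3", "L1", "L2")]),
                           c("L3", "L1", "L2"))
  expect_equal(count_min_males(queen_p, prof_p,
                               stats::setNames(TRUE, "Q1"))$min_males, base)
  ## relabel alleles (shift all sizes by a constant)
  shift <- function(x) x + 40L
  freqs2 <- make_freqs(n_loci = 3, alleles = seq(140, 154, 2))
  queen2 <- genotype_table("Q1", 2014, matrix(shift(c(100, 104, 106)), 1),
                           matrix(shift(c(102, 104, 108)), 1),
                           names(freqs2))
  prof2 <- sperm_profiles(list(Q1 = lapply(prof, shift)), names(freqs2))
  expect_equal(count_min_males(queen2, prof2,
                               stats::setNames(TRUE, "Q1"))$min_males, base)
})

test_that("the miscount matrix is a calibrated counting model", {
  freqs <- make_freqs(n_loci = 20, alleles = seq(100, 118, 2),
                      p = rep(0.1, 10))
  set.seed(31)
  a1 <- matrix(sample(seq(100, 118, 2), 20 * 3, TRUE), 3, 20)
  a2 <- matrix(sample(seq(100, 118, 2), 20 * 3, TRUE), 3, 20)
  queens <- genotype_table(paste0("Q", 1:3), 2014, a1, a2, names(freqs))
  mm <- run_simulation_2(queens, freqs, critical_value = 0.9,
                         true_range = 1:5, reps = 400, seed = 5)
  ## rows are probability distributions
  expect_equal(unname(rowSums(mm$prob)), rep(1, 5), tolerance = 1e-9)
  ## error-free counting never exceeds the true number
  for (t in 1:5) expect_equal(sum(mm$prob[t, -(1:t)]), 0)
  expect_equal(unname(mm$prob[1, 1]), 1)
  ## a highly informative panel counts two mates almost surely
  expect_gte(mm$prob["2", "2"], 0.95)
  ## stochastic ordering: P(observed <= k) never increases with true t
  for (k in 1:4) {
    cum <- rowSums(mm$prob[, 1:k, drop = FALSE])
    expect_true(all(diff(cum) <= 1e-9))
  }
  ## determinism
  mm2 <- run_simulation_2(queens, freqs, critical_value = 0.9,
                          true_range = 1:5, reps = 400, seed = 5)
  expect_identical(mm$prob, mm2$prob)
})

test_that("maximum likely frequency reads the miscount tail correctly", {
  ident <- diag(5)
  dimnames(ident) <- list(1:5, 1:5)
  expect_equal(max_likely_frequency(ident, 3), 3)
  ## constructed matrix: P(obs <= 3 | 5) = 0.06, P(obs <= 3 | 6) = 0.04
  m <- matrix(0, 6, 6, dimnames = list(1:6, 1:6))
  m[1:4, ] <- diag(6)[1:4, ]
  m[5, ] <- c(0, 0.02, 0.04, 0.94, 0, 0)
  m[6, ] <- c(0, 0.01, 0.03, 0.46, 0.5, 0)
  expect_equal(max_likely_frequency(m, 3, tail = 0.05), 5)
  ## tail = 1: the largest t whose whole mass is at or below observed_max
  expect_equal(max_likely_frequency(ident, 2, tail = 1), 2)
  expect_error(max_likely_frequency(ident, 9), "outside")
})

test_that("mating frequency estimates are conservative and accurate", {
  ## simulated queens with known mate numbers, error-free sperm profiles
  cfg <- sim_config(seed = 41, n_colonies = 300, years = 2014, n_loci = 20,
                    alleles_per_locus = 8, contamination_prob = 0,
                    sperm_dropout = 0)
  pop <- simulate_population(cfg)
  sp <- simulate_sperm_samples(pop)
  mf <- estimate_mating_frequency(sp$queens, sp$profiles, pop$freqs,
                                  reps = 1000, seed = 42)
  true_n <- sp$n_mates[mf$per_queen$id]
  expect_true(all(mf$per_queen$min_males <= true_n))
  expect_lte(mf$mean_mating_frequency, mean(true_n) + 1e-9)
})
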