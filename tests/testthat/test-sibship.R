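## brute-force oracle for per-locus pair probabilities at one locus with
## error 0: enumerate queen genotypes (ordered, HW probabilities) and
## father alleles, accumulate joint offspring-pair probabilities
pair_prob_oracle <- function(p, g1, g2, relationship) {
  alleles <- as.integer(names(p))
  K <- length(p)
  match_pair <- function(off, g) setequal(off, g) &&
    (length(unique(off)) == length(unique(g)))
  total <- 0
  for (q1 in 1:K) for (q2 in 1:K) {
    pq <- p[q1] * p[q2]
    for (f1 in 1:K) for (f2 in 1:K) {
      if (relationship == "fs" && f1 != f2) next
      pf <- if (relationship == "fs") p[f1] else p[f1] * p[f2]
      for (m1 in c(q1, q2)) for (m2 in c(q1, q2)) {
        off1 <- alleles[c(m1, f1)]
        off2 <- alleles[c(m2, f2)]
        if (match_pair(off1, g1) && match_pair(off2, g2)) {
          total <- total + pq * pf * 0.25
        }
      }
    }
  }
  unname(total)
}

test_that("pairwise relationship likelihoods match exhaustive enumeration", {
  p <- c(`100` = 0.6, `102` = 0.4)
  freqs <- make_freqs(n_loci = 1, alleles = c(100, 102), p = c(0.6, 0.4))
  pairs <- list(c(100, 100), c(100, 102), c(102, 102))
  for (i in seq_along(pairs)) for (j in seq_along(pairs)) {
    gt <- make_gt(list(pairs[[i]], pairs[[j]]))
    ll <- pairwise_relationship_likelihoods(gt, freqs, error_rate = 0)
    for (rel in c("fs", "hs")) {
      expect_equal(exp(ll[[rel]][1, 2]),
                   pair_prob_oracle(p, pairs[[i]], pairs[[j]], rel),
                   tolerance = 1e-10,
                   label = sprintf("%s (%d,%d)", rel, i, j))
    }
    hw <- function(g) if (g[1] == g[2]) p[as.character(g[1])]^2 else
      2 * p[as.character(g[1])] * p[as.character(g[2])]
    expect_equal(exp(ll$u[1, 2]), unname(hw(pairs[[i]]) * hw(pairs[[j]])),
                 tolerance = 1e-10)
  }
})

test_that("sister likelihoods respect haplodiploid sharing constraints", {
  ## fully disjoint genotypes cannot be full sisters (no shared paternal
  ## allele); maternal half-sisters remain possible because each sister
  ## draws her own maternal allele from the queen's pair
  freqs <- make_freqs(alleles = c(100, 102, 104, 106))
  gt <- make_gt(list(c(100, 102), c(104, 106)))
  ll <- pairwise_relationship_likelihoods(gt, freqs, error_rate = 0)
  expect_identical(ll$fs[1, 2], -Inf)
  expect_equal(exp(ll$hs[1, 2]),
               pair_prob_oracle(c(`100` = .25, `102` = .25, `104` = .25,
                                  `106` = .25),
                                c(100, 102), c(104, 106), "hs"),
               tolerance = 1e-10)
  expect_gt(ll$u[1, 2], -Inf)
  ## sisters sharing an allele: both relationships possible
  gt2 <- make_gt(list(c(100, 102), c(100, 104)))
  ll2 <- pairwise_relationship_likelihoods(gt2, freqs, error_rate = 0)
  expect_gt(ll2$fs[1, 2], -Inf)
  ## a monomorphic locus is uninformative: all three likelihoods equal
  freqs1 <- make_freqs(alleles = 100, p = 1)
  gt1 <- make_gt(list(c(100, 100), c(100, 100)))
  ll1 <- pairwise_relationship_likelihoods(gt1, freqs1, error_rate = 0)
  expect_equal(ll1$fs[1, 2], ll1$hs[1, 2])
  expect_equal(ll1$hs[1, 2], ll1$u[1, 2])
})

test_that("single workers and identical twins partition trivially", {
  freqs <- make_freqs(n_loci = 6)
  gt <- make_gt(list(c(100, 102)), n_loci = 6)
  part <- reconstruct_colonies(gt, freqs, error_rate = 0)
  expect_equal(nrow(part$colonies), 1)
  expect_equal(part$assignments$inclusion, 1)
  ## duplicated multi-locus genotype: co-assigned with inclusion >= 0.8
  sc <- scenario_workers(19, n_colonies = 12, workers = 1, n_loci = 10,
                         error = 0)
  ids <- sc$obs$id[1]
  dup <- genotype_table(c(sc$obs$id, "copy"), 2014,
                        rbind(sc$obs$a1, sc$obs$a1[1, ]),
                        rbind(sc$obs$a2, sc$obs$a2[1, ]), sc$obs$loci)
  part <- reconstruct_colonies(dup, sc$freqs, error_rate = 1e-4)
  asg <- part$assignments
  expect_equal(asg$colony[asg$id == ids], asg$colony[asg$id == "copy"])
  expect_gte(min(asg$inclusion[asg$id %in% c(ids, "copy")]), 0.8)
})

test_that("partition recovery degrades gracefully with panel information", {
  ari <- vapply(c(4, 8), function(k) {
    sc <- scenario_workers(23, n_colonies = 15, workers = 5, n_loci = 8,
                           alleles = k, error = 0.02)
    part <- reconstruct_colonies(sc$obs, sc$freqs,
                                 sibship_priors(m = 1.9, n = 2.6),
                                 error_rate = 0.02)
    mclust::adjustedRandIndex(part$assignments$colony, sc$truth$colony)
  }, numeric(1))
  expect_gte(ari[2], ari[1] - 0.05)  # more alleles never clearly worse
  expect_gt(ari[2], 0.8)
})

test_that("patriline counting finds the minimum father classes", {
  freqs <- make_freqs(n_loci = 2, alleles = seq(100, 114, 2))
  iq <- structure(list(
    a1 = matrix(c(100L, 100L), 1, dimnames = list(NULL, c("L1", "L2"))),
    a2 = matrix(c(102L, 102L), 1, dimnames = list(NULL, c("L1", "L2"))),
    confidence = c(L1 = 1, L2 = 1), loci = c("L1", "L2")),
    class = "inferred_queen")
  ## all workers share one paternal allele per locus
  gt <- make_gt(list(c(100, 104), c(102, 104), c(100, 104)), n_loci = 2)
  pat <- count_patrilines(gt, iq)
  expect_equal(pat$count, 1)
  expect_equal(length(unique(pat$labels)), 1)
  ## two paternal allele classes at both loci
  gt2 <- make_gt(list(c(100, 104), c(102, 106), c(100, 106), c(102, 104)),
                 n_loci = 2)
  expect_equal(count_patrilines(gt2, iq)$count, 2)
  ## a constructed six-father colony is rejected at the default bound
  fathers <- seq(104, 114, 2)
  gt6 <- make_gt(lapply(fathers, function(f) c(100, f)), n_loci = 2)
  pat6 <- count_patrilines(gt6, iq)
  expect_equal(pat6$count, 6)
  expect_gt(pat6$count, 5)
})

test_that("sibship priors follow the maternal/paternal sisterhood algebra", {
  pri <- sibship_priors(m = 1.7, n = 1.44)
  expect_equal(pri$maternal_size, 2.448)
  ## all singletons -> n = 1
  part <- list(assignments = data.frame(
    id = paste0("w", 1:4), patriline = paste0("P", 1:4)))
  expect_equal(estimate_sibship_priors(part, m = 1.7)$n, 1)
  ## patriline sizes {1, 2} -> n = 1.5
  part2 <- list(assignments = data.frame(
    id = paste0("w", 1:3), patriline = c("P1", "P2", "P2")))
  expect_equal(estimate_sibship_priors(part2, m = 1.7)$n, 1.5)
  expect_error(estimate_sibship_priors(
    list(assignments = data.frame()), 1.7), "empty")
})

## oracle for the queen posterior at one locus given fixed patrilines:
## enumerate queen genotypes, marginalize one father per patriline
queen_post_oracle <- function(p, workers, patrilines) {
  alleles <- as.integer(names(p))
  K <- length(p)
  cands <- expand.grid(q1 = 1:K, q2 = 1:K)
  cands <- cands[cands$q1 <= cands$q2, ]
  post <- apply(cands, 1, function(q) {
    prior <- if (q[1] == q[2]) p[q[1]]^2 else 2 * p[q[1]] * p[q[2]]
    lik <- 1
    for (pat in unique(patrilines)) {
      members <- workers[patrilines == pat]
      lf <- 0
      for (f in 1:K) {
        pw <- prod(vapply(members, function(g) {
          tot <- 0
          for (m in q) {
            off <- sort(alleles[c(m, f)])
            if (all(off == sort(g))) tot <- tot + 0.5
          }
          tot
        }, numeric(1)))
        lf <- lf + p[f] * pw
      }
      lik <- lik * lf
    }
    prior * lik
  })
  post / sum(post)
}

test_that("queen genotype inference matches the enumeration oracle", {
  p <- c(`100` = 0.5, `102` = 0.3, `104` = 0.2)
  freqs <- make_freqs(alleles = c(100, 102, 104), p = c(0.5, 0.3, 0.2))
  workers <- list(c(100, 104), c(102, 104), c(100, 102))
  gt <- make_gt(workers)
  patl <- c(1L, 2L, 3L)
  iq <- infer_queen_genotype(gt, freqs, error_rate = 0, min_confidence = 0.8,
                             patrilines = patl)
  oracle <- queen_post_oracle(p, workers, patl)
  expect_equal(unname(iq$confidence["L1"]), max(oracle), tolerance = 1e-9)
})

test_that("queen inference pins maternal alleles via shared paternal ones", {
  ## three patrilines of two workers each, all sired at allele 104:
  ## the shared paternal allele cannot be mistaken for a maternal one
  freqs <- make_freqs(n_loci = 8, alleles = c(100, 102, 104, 106))
  pairs <- rep(list(c(100, 104), c(102, 104)), 3)
  gt <- make_gt(pairs, n_loci = 8)
  iq <- infer_queen_genotype(gt, freqs, error_rate = 0,
                             patrilines = rep(1:3, each = 2))
  expect_equal(unname(iq$a1[1, 1]), 100)
  expect_equal(unname(iq$a2[1, 1]), 102)
  expect_gte(unname(iq$confidence["L1"]), 0.8)
  ## a single worker leaves the maternal allele ambiguous: filtered
  iq1 <- infer_queen_genotype(gt[1], freqs, error_rate = 0)
  expect_true(all(is.na(iq1$a1)))
  expect_true(all(iq1$confidence < 0.8))
})

test_that("queen inference confidence grows with colony size", {
  conf <- vapply(c(2, 6, 20), function(nw) {
    cfg <- sim_config(seed = 77, n_colonies = 1, years = 2014,
                      workers_per_colony = nw, n_loci = 10,
                      alleles_per_locus = 6, missing_rate = 0,
                      mistyping_rate = 0)
    pop <- simulate_population(cfg)
    ws <- simulate_workers(pop, cfg)
    iq <- infer_queen_genotype(ws$genotypes, pop$freqs, error_rate = 0)
    mean(iq$confidence, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(conf) > -0.05))
  expect_gt(conf[3], 0.9)
})
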