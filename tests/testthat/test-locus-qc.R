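## exact-test oracle for a biallelic locus: enumerate all genotype arrays
## compatible with the allele counts and sum the probabilities of arrays
## as or less probable than the observed one
hwe_exact_p_biallelic <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na_all <- 2 * naa + nab
  logp <- function(aa, ab, bb) {
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(ab + 1) - lgamma(bb + 1) +
      ab * log(2) + lgamma(na_all + 1) + lgamma(2 * n - na_all + 1) -
      lgamma(2 * n + 1)
  }
  aa_range <- 0:(na_all %/% 2)
  probs <- vapply(aa_range, function(aa) {
    ab <- na_all - 2 * aa
    bb <- n - aa - ab
    if (ab < 0 || bb < 0) return(NA_real_)
    exp(logp(aa, ab, bb))
  }, numeric(1))
  probs <- probs[!is.na(probs)]
  obs <- exp(logp(naa, nab, nbb))
  sum(probs[probs <= obs + 1e-12])
}

test_that("HWE Monte-Carlo exact test matches enumeration and chi-square", {
  ## balanced proportions are not rejected
  calls <- hwe_counts_to_calls(25, 50, 25)
  expect_gt(hwe_test(calls$a1, calls$a2, reps = 2000, seed = 1)$p.value, 0.5)
  ## all-heterozygote array: exact enumeration oracle for n = 50
  calls <- hwe_counts_to_calls(0, 50, 0)
  p_exact <- hwe_exact_p_biallelic(0, 50, 0)
  expect_lt(p_exact, 0.001)
  p_mc <- hwe_test(calls$a1, calls$a2, reps = 5000, seed = 2)$p.value
  expect_lt(p_mc, 0.001)
  ## moderate deviation: MC p close to the exact enumeration p
  calls <- hwe_counts_to_calls(35, 40, 25)
  p_exact <- hwe_exact_p_biallelic(35, 40, 25)
  p_mc <- hwe_test(calls$a1, calls$a2, reps = 20000, seed = 3)$p.value
  expect_lt(abs(p_mc - p_exact), 0.02)
  ## large balanced sample: MC p within 0.05 of the asymptotic chi-square p
  calls <- hwe_counts_to_calls(130, 240, 130)
  n <- 500
  phat <- (2 * 130 + 240) / (2 * n)
  expected <- n * c(phat^2, 2 * phat * (1 - phat), (1 - phat)^2)
  chi <- sum((c(130, 240, 130) - expected)^2 / expected)
  p_chi <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  p_mc <- hwe_test(calls$a1, calls$a2, reps = 5000, seed = 4)$p.value
  expect_lt(abs(p_mc - p_chi), 0.05)
})

test_that("HWE test is deterministic given a seed and flags monomorphism", {
  calls <- hwe_counts_to_calls(30, 40, 30)
  p1 <- hwe_test(calls$a1, calls$a2, reps = 1000, seed = 9)
  p2 <- hwe_test(calls$a1, calls$a2, reps = 1000, seed = 9)
  expect_identical(p1$p.value, p2$p.value)
  mono <- hwe_test(rep(1L, 20), rep(1L, 20), reps = 1000, seed = 1)
  expect_false(mono$testable)
  expect_true(is.na(mono$p.value))
})

test_that("HWE Monte-Carlo p-values are near-uniform under the null", {
  set.seed(42)
  ps <- replicate(300, {
    a1 <- sample.int(4, 80, replace = TRUE)
    a2 <- sample.int(4, 80, replace = TRUE)
    hwe_test(a1, a2, reps = 499)$p.value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.05)
})

test_that("Bonferroni correction reproduces the corrected alpha", {
  cm <- correct_multiple_tests(rep(0.5, 400), alpha = 0.05)
  expect_equal(cm$corrected_alpha, 0.000125)
  expect_equal(correct_multiple_tests(0.3, 0.05)$corrected_alpha, 0.05)
  ## the smallest linkage p-value in a 400-test family is not significant
  expect_false(correct_multiple_tests(c(0.007, rep(0.5, 399)))$significant[1])
  expect_error(correct_multiple_tests(numeric(0)), "empty")
})

test_that("null-allele estimator follows the homozygote-excess formula", {
  expect_equal(estimate_null_allele_frequency(he = 0.5, ho = 0.4),
               0.1 / 0.9, tolerance = 1e-12)
  expect_equal(estimate_null_allele_frequency(he = 0.4, ho = 0.5),
               -0.1 / 0.9, tolerance = 1e-12)
  expect_equal(estimate_null_allele_frequency(he = 0.3, ho = 0.3), 0)
  expect_error(estimate_null_allele_frequency(he = 0, ho = 0), "zero")
  ## genotype-based path agrees with the He/Ho formula
  calls <- hwe_counts_to_calls(40, 20, 40)
  ho <- 0.2
  he <- expected_heterozygosity(calls$a1, calls$a2)
  expect_equal(estimate_null_allele_frequency(calls$a1, calls$a2),
               (he - ho) / (he + ho))
})

## exact 2x2 permutation oracle: under permutation the joint table is
## hypergeometric in one cell
ld_exact_p_2x2 <- function(tab) {
  ra <- rowSums(tab)
  cb <- colSums(tab)
  n <- sum(tab)
  expected <- outer(ra, cb) / n
  chi <- function(a) {
    t2 <- matrix(c(a, ra[1] - a, cb[1] - a, n - ra[1] - cb[1] + a), 2)
    sum((t2 - expected)^2 / expected)
  }
  obs <- chi(tab[1, 1])
  avals <- max(0, ra[1] + cb[1] - n):min(ra[1], cb[1])
  pr <- stats::dhyper(avals, cb[1], n - cb[1], ra[1])
  sum(pr[vapply(avals, chi, numeric(1)) >= obs - 1e-9])
}

test_that("linkage permutation test matches exact and trivial oracles", {
  ## a locus against an exact duplicate of itself is detected, n = 40
  set.seed(5)
  a1 <- sample.int(4, 40, replace = TRUE)
  a2 <- sample.int(4, 40, replace = TRUE)
  p_dup <- ld_test(a1, a2, a1, a2, reps = 9999, seed = 6)$p.value
  expect_lt(p_dup, 0.000125)
  ## a locus against an independently shuffled copy is not significant
  sh <- sample(seq_along(a1))
  p_ind <- ld_test(a1, a2, a1[sh], a2[sh], reps = 2000, seed = 7)$p.value
  expect_gt(p_ind, 0.05)
  ## 2x2 genotype table: permutation p close to the hypergeometric exact p
  ga <- rep(c(1L, 2L), c(24, 16))     # homozygote classes 1/1 and 2/2
  gb <- c(rep(1L, 18), rep(2L, 6), rep(1L, 6), rep(2L, 10))
  tab <- table(ga, gb)
  p_exact <- ld_exact_p_2x2(tab)
  p_perm <- ld_test(ga, ga, gb, gb, reps = 20000, seed = 8)$p.value
  expect_lt(abs(p_perm - p_exact), 0.05)
  ## monomorphic input is untestable
  expect_false(ld_test(rep(1L, 10), rep(1L, 10), a1[1:10], a2[1:10],
                       reps = 100)$testable)
})

test_that("mistyping rate counts mismatched alleles over compared alleles", {
  sc <- scenario_workers(11, n_colonies = 8, workers = 3, n_loci = 4,
                         error = 0)
  expect_equal(mistyping_rate(sc$obs, sc$obs)$mean, 0)
  ## one mismatched allele of 44 compared at a locus
  gt1 <- make_gt(rep(list(c(100, 102)), 22))
  pairs2 <- rep(list(c(100, 102)), 22)
  pairs2[[1]] <- c(100, 104)
  gt2 <- make_gt(pairs2)
  mr <- mistyping_rate(gt1, gt2)
  expect_equal(unname(mr$per_locus["L1"]), 1 / 44, tolerance = 1e-12)
  ## complete disagreement
  gt3 <- make_gt(rep(list(c(104, 106)), 22))
  expect_equal(mistyping_rate(gt1, gt3)$mean, 1)
})

test_that("locus selection applies the three exclusion rules", {
  loci <- sprintf("T%02d", 1:20)
  he <- stats::setNames(seq(0.5, 0.88, length.out = 20), loci)
  null_freq <- stats::setNames(rep(0.02, 20), loci)
  null_freq[4:9] <- 0.15            # six loci with null alleles > 0.1
  hwe_sig <- matrix(FALSE, 20, 2, dimnames = list(loci, 2014:2015))
  hwe_sig[4:6, ] <- TRUE            # three of them also fail HWE both years
  ld <- data.frame(locus_a = character(0), locus_b = character(0),
                   p = numeric(0), significant = logical(0))
  qc <- locus_qc_report(loci, he, null_freq,
                        hwe_p = matrix(0.5, 20, 2,
                                       dimnames = list(loci, 2014:2015)),
                        hwe_sig = hwe_sig, ld = ld)
  kept <- select_loci(qc)
  expect_equal(length(kept), 14)
  excl <- attr(kept, "exclusions")
  expect_setequal(excl$locus, loci[4:9])
  expect_setequal(unique(excl$reason), c("hwe_both_years", "null_gt_0.1"))
  ## retained + excluded partition the loci
  expect_setequal(c(kept, excl$locus), loci)
  ## no flags -> all retained
  qc0 <- qc
  qc0$hwe_sig[] <- FALSE
  qc0$null_freq[] <- 0.01
  expect_equal(length(select_loci(qc0)), 20)
  ## HWE significant in one year only does not exclude
  qc1 <- qc0
  qc1$hwe_sig[1, 1] <- TRUE
  expect_true("T01" %in% select_loci(qc1))
  ## linkage drops the less informative member; ties break by name order
  qc2 <- qc0
  qc2$ld <- data.frame(locus_a = c("T01", "T05"), locus_b = c("T02", "T06"),
                       p = c(1e-6, 1e-6), significant = TRUE)
  qc2$he[c("T05", "T06")] <- 0.7
  kept2 <- select_loci(qc2)
  expect_false("T01" %in% kept2)  # lower He than T02
  expect_true("T02" %in% kept2)
  expect_false("T06" %in% kept2)  # tie with T05: later name dropped
  expect_true("T05" %in% kept2)
  ## idempotent under repeated application of the same report
  expect_identical(as.character(kept2), as.character(select_loci(qc2)))
})
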