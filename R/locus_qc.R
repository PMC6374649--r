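## Locus quality control: Hardy-Weinberg exact tests, null-allele
## estimation, linkage permutation tests, mistyping rates, and the
## three-rule locus exclusion battery applied before sibship analysis.

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test in the Guo-Thompson style: the test statistic is
#' the probability of the observed genotype array conditional on the allele
#' counts, and the null distribution is sampled by repeatedly shuffling the
#' pooled alleles into random diploid pairings. The p-value is the
#' proportion of shuffles (plus the observed array) whose conditional
#' probability does not exceed the observed one.
#'
#' @param a1,a2 Integer vectors of allele calls at one locus (one entry per
#'   individual; `NA` pairs dropped).
#' @param reps Number of Monte-Carlo shuffles (>= 1000 recommended).
#' @param seed Optional integer seed; the result is deterministic given it.
#' @return A list of class `mc_test` with elements `p.value`, `testable`,
#'   `reps`. A monomorphic locus is untestable: `p.value` is `NA` and
#'   `testable` is `FALSE`.
#' @examples
#' a <- c(rep(1L, 25), rep(1L, 50), rep(2L, 25))
#' b <- c(rep(1L, 25), rep(2L, 50), rep(2L, 25))
#' hwe_test(a, b, reps = 2000, seed = 1)$p.value
#' @export
hwe_test <- function(a1, a2, reps = 10000, seed = NULL) {
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]
  a2 <- a2[keep]
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2 || n == 0) {
    return(structure(list(p.value = NA_real_, testable = FALSE, reps = reps),
                     class = "mc_test"))
  }
  stopifnot(reps >= 1)
  k <- length(alleles)
  i1 <- match(a1, alleles)
  i2 <- match(a2, alleles)
  pool <- c(i1, i2)
  lfact_alleles <- sum(lgamma(tabulate(pool, k) + 1))
  const <- lgamma(n + 1) + lfact_alleles - lgamma(2 * n + 1)
  log_cond_prob <- function(x, y) {
    h <- sum(x != y)
    key <- (pmin(x, y) - 1L) * k + pmax(x, y)
    tab <- tabulate(key, k * k)
    const + h * log(2) - sum(lgamma(tab[tab > 0] + 1))
  }
  obs <- log_cond_prob(i1, i2)
  p <- with_seed(seed, {
    hits <- 0L
    for (r in seq_len(reps)) {
      perm <- sample(pool)
      if (log_cond_prob(perm[1:n], perm[(n + 1):(2 * n)]) <= obs + 1e-9) {
        hits <- hits + 1L
      }
    }
    (hits + 1) / (reps + 1)
  })
  structure(list(p.value = p, testable = TRUE, reps = reps), class = "mc_test")
}

#' @export
print.mc_test <- function(x, ...) {
  if (!x$testable) {
    cat("Monte-Carlo test: untestable (monomorphic locus)\n")
  } else {
    cat(sprintf("Monte-Carlo test: p = %.4g (%d reps)\n", x$p.value, x$reps))
  }
  invisible(x)
}

#' Bonferroni correction for a family of tests
#'
#' @param p Numeric vector of p-values.
#' @param alpha Family-wise significance level in (0, 1).
#' @return List with `corrected_alpha` (`alpha` divided by the number of
#'   tests) and `significant` (logical, `p < corrected_alpha`; `NA` p-values
#'   stay `NA`).
#' @examples
#' correct_multiple_tests(runif(400))$corrected_alpha  # 0.000125
#' @export
correct_multiple_tests <- function(p, alpha = 0.05) {
  if (length(p) == 0) stop("empty p-value list")
  stopifnot(alpha > 0, alpha < 1)
  ca <- alpha / length(p)
  list(corrected_alpha = ca, significant = p < ca)
}

#' Null-allele frequency estimate from homozygote excess
#'
#' Chakraborty-style summary estimator `r = (He - Ho) / (He + Ho)`, where
#' `He` is the unbiased expected heterozygosity and `Ho` the observed
#' heterozygote proportion. Negative values (heterozygote excess) are
#' reported as-is, not clamped.
#'
#' @param a1,a2 Allele-call vectors at one locus; alternatively supply `he`
#'   and `ho` directly.
#' @param he,ho Optional expected/observed heterozygosity overriding the
#'   genotype-based computation.
#' @return Numeric estimate.
#' @examples
#' estimate_null_allele_frequency(he = 0.5, ho = 0.4)  # 0.111
#' @export
estimate_null_allele_frequency <- function(a1 = NULL, a2 = NULL,
                                           he = NULL, ho = NULL) {
  if (is.null(he) || is.null(ho)) {
    keep <- !is.na(a1) & !is.na(a2)
    a1 <- a1[keep]
    a2 <- a2[keep]
    if (length(unique(c(a1, a2))) < 2) stop("locus must be polymorphic")
    ho <- mean(a1 != a2)
    he <- expected_heterozygosity(a1, a2)
  }
  if (he + ho == 0) stop("He + Ho is zero; estimator undefined")
  (he - ho) / (he + ho)
}

#' Unbiased expected heterozygosity at one locus
#'
#' `He = 2n/(2n - 1) * (1 - sum p^2)` with `p` the sample allele
#' frequencies over `2n` non-missing alleles.
#'
#' @param a1,a2 Allele-call vectors at one locus.
#' @return Numeric in [0, 1].
#' @export
expected_heterozygosity <- function(a1, a2) {
  alleles <- c(a1, a2)
  alleles <- alleles[!is.na(alleles)]
  n2 <- length(alleles)
  if (n2 < 2) return(NA_real_)
  p <- as.numeric(table(alleles)) / n2
  n2 / (n2 - 1) * (1 - sum(p^2))
}

#' Permutation test of genotypic linkage between two loci
#'
#' Computes the chi-square statistic of the contingency table of
#' single-locus genotypes at locus A versus locus B, then permutes the
#' locus-B genotypes across individuals to build the null distribution.
#' Individuals missing either locus are dropped.
#'
#' @param ga1,ga2 Allele calls at locus A (per individual).
#' @param gb1,gb2 Allele calls at locus B.
#' @param reps Number of permutations (>= 1000 recommended).
#' @param seed Optional integer seed.
#' @return An `mc_test` list; untestable if either locus is monomorphic
#'   among the shared individuals.
#' @export
ld_test <- function(ga1, ga2, gb1, gb2, reps = 10000, seed = NULL) {
  keep <- !is.na(ga1) & !is.na(gb1)
  ga1 <- ga1[keep]; ga2 <- ga2[keep]
  gb1 <- gb1[keep]; gb2 <- gb2[keep]
  ga <- paste(pmin(ga1, ga2), pmax(ga1, ga2))
  gb <- paste(pmin(gb1, gb2), pmax(gb1, gb2))
  if (length(ga) == 0 ||
      length(unique(stats::na.omit(c(ga1, ga2)))) < 2 ||
      length(unique(stats::na.omit(c(gb1, gb2)))) < 2) {
    return(structure(list(p.value = NA_real_, testable = FALSE, reps = reps),
                     class = "mc_test"))
  }
  xa <- match(ga, unique(ga))
  xb <- match(gb, unique(gb))
  ka <- max(xa)
  kb <- max(xb)
  if (ka < 2 || kb < 2) {
    return(structure(list(p.value = NA_real_, testable = FALSE, reps = reps),
                     class = "mc_test"))
  }
  stopifnot(reps >= 1)
  n <- length(xa)
  ra <- tabulate(xa, ka)
  rb <- tabulate(xb, kb)
  expected <- outer(ra, rb) / n
  chisq <- function(xb_perm) {
    tab <- tabulate((xa - 1L) * kb + xb_perm, ka * kb)
    sum((tab - expected)^2 / expected)
  }
  obs <- chisq(xb)
  p <- with_seed(seed, {
    hits <- 0L
    for (r in seq_len(reps)) {
      if (chisq(sample(xb)) >= obs - 1e-9) hits <- hits + 1L
    }
    (hits + 1) / (reps + 1)
  })
  structure(list(p.value = p, testable = TRUE, reps = reps, statistic = obs),
            class = "mc_test")
}

#' Locus-specific allelic mistyping rate from regenotyped samples
#'
#' Compares original and repeat genotype calls for the same individuals:
#' the per-locus rate is the number of mismatched alleles over the number
#' of compared alleles (two per individual per locus where both calls are
#' non-missing). Allele pairs are compared as unordered multisets.
#'
#' @param original,repeat_ [genotype_table()]s sharing ids and loci.
#' @return List with `per_locus` (named rates, `NA` where no comparable
#'   pairs exist), `mean` (across testable loci), and `compared` (allele
#'   counts per locus).
#' @export
mistyping_rate <- function(original, repeat_) {
  ids <- intersect(original$id, repeat_$id)
  loci <- intersect(original$loci, repeat_$loci)
  if (length(ids) == 0 || length(loci) == 0) stop("no comparable records")
  o <- subset_loci(original[ids], loci)
  r <- subset_loci(repeat_[ids], loci)
  per <- compared <- stats::setNames(rep(NA_real_, length(loci)), loci)
  for (l in seq_along(loci)) {
    ok <- !is.na(o$a1[, l]) & !is.na(r$a1[, l])
    if (!any(ok)) next
    ## unordered-pair mismatch count: 2 - size of multiset intersection
    shared <- (o$a1[, l][ok] == r$a1[, l][ok]) + (o$a2[, l][ok] == r$a2[, l][ok])
    cross <- (o$a1[, l][ok] == r$a2[, l][ok]) + (o$a2[, l][ok] == r$a1[, l][ok])
    matches <- pmax(shared, pmin(cross, 2L))
    mism <- sum(2L - matches)
    compared[l] <- 2 * sum(ok)
    per[l] <- mism / compared[l]
  }
  list(per_locus = per, mean = mean(per, na.rm = TRUE), compared = compared)
}

#' Run the locus quality-control battery
#'
#' Per-year Hardy-Weinberg Monte-Carlo exact tests (with per-year Bonferroni
#' correction across loci), pooled null-allele estimates, and pairwise
#' linkage permutation tests (Bonferroni correction across all pairs and
#' years), assembled into a report consumed by [select_loci()].
#'
#' @param gt Worker [genotype_table()] covering one or two years.
#' @param hwe_reps,ld_reps Monte-Carlo replicate counts.
#' @param alpha Family-wise significance level.
#' @param seed Integer seed controlling both Monte-Carlo tests.
#' @return A `locus_qc_report` (see [locus_qc_report()]).
#' @export
locus_qc <- function(gt, hwe_reps = 10000, ld_reps = 1000, alpha = 0.05,
                     seed = 1) {
  years <- sort(unique(gt$year))
  loci <- gt$loci
  hwe_p <- matrix(NA_real_, length(loci), length(years),
                  dimnames = list(loci, years))
  for (y in seq_along(years)) {
    sub <- gt[gt$year == years[y]]
    for (l in seq_along(loci)) {
      hwe_p[l, y] <- hwe_test(sub$a1[, l], sub$a2[, l], reps = hwe_reps,
                              seed = derive_seed(seed, l * 101L + y))$p.value
    }
  }
  hwe_sig <- hwe_p
  for (y in seq_along(years)) {
    hwe_sig[, y] <- correct_multiple_tests(hwe_p[, y], alpha)$significant
  }
  he <- null_freq <- stats::setNames(rep(NA_real_, length(loci)), loci)
  for (l in seq_along(loci)) {
    he[l] <- expected_heterozygosity(gt$a1[, l], gt$a2[, l])
    poly <- length(unique(stats::na.omit(c(gt$a1[, l], gt$a2[, l])))) > 1
    if (poly) {
      null_freq[l] <- estimate_null_allele_frequency(gt$a1[, l], gt$a2[, l])
    }
  }
  pairs <- utils::combn(seq_along(loci), 2)
  ld <- do.call(rbind, lapply(seq_along(years), function(y) {
    sub <- gt[gt$year == years[y]]
    data.frame(
      locus_a = loci[pairs[1, ]], locus_b = loci[pairs[2, ]],
      year = years[y],
      p = vapply(seq_len(ncol(pairs)), function(j) {
        i <- pairs[1, j]; k <- pairs[2, j]
        ld_test(sub$a1[, i], sub$a2[, i], sub$a1[, k], sub$a2[, k],
                reps = ld_reps,
                seed = derive_seed(seed, 7919L * j + y))$p.value
      }, numeric(1))
    )
  }))
  ld$significant <- correct_multiple_tests(ld$p, alpha)$significant
  locus_qc_report(loci = loci, he = he, null_freq = null_freq,
                  hwe_p = hwe_p, hwe_sig = hwe_sig == 1, ld = ld,
                  alpha = alpha)
}

#' Construct a locus QC report
#'
#' Container consumed by [select_loci()]; [locus_qc()] builds it from data,
#' but it can also be assembled directly (e.g. from externally computed
#' statistics).
#'
#' @param loci Character vector of locus names.
#' @param he Named expected heterozygosities (informativeness ranking).
#' @param null_freq Named null-allele estimates.
#' @param hwe_p Matrix (loci x years) of HWE p-values.
#' @param hwe_sig Logical matrix (loci x years): significant after per-year
#'   correction.
#' @param ld Data frame with columns `locus_a`, `locus_b`, `p`,
#'   `significant` (one row per tested pair, possibly per year).
#' @param alpha Family-wise alpha used.
#' @return Object of class `locus_qc_report`.
#' @export
locus_qc_report <- function(loci, he, null_freq, hwe_p, hwe_sig, ld,
                            alpha = 0.05) {
  structure(list(loci = loci, he = he, null_freq = null_freq, hwe_p = hwe_p,
                 hwe_sig = hwe_sig, ld = ld, alpha = alpha),
            class = "locus_qc_report")
}

#' @export
print.locus_qc_report <- function(x, ...) {
  cat(sprintf("locus_qc_report: %d loci, %d year(s), %d linkage pairs\n",
              length(x$loci), ncol(x$hwe_p), nrow(x$ld)))
  invisible(x)
}

#' Select loci passing quality control
#'
#' A locus is excluded iff it (a) deviates significantly from
#' Hardy-Weinberg equilibrium (after correction) in every tested year,
#' (b) has an estimated null-allele frequency above `null_threshold`, or
#' (c) is significantly linked to a more informative locus (the member of a
#' significant pair with the lower expected heterozygosity is dropped; ties
#' broken by locus name order, the lexicographically later one dropped).
#'
#' @param qc A [locus_qc_report()].
#' @param null_threshold Null-allele exclusion threshold (default 0.1).
#' @return Character vector of retained loci, with attribute `exclusions`: a
#'   data frame of excluded loci and reason codes (`hwe_both_years`,
#'   `null_gt_0.1`, `linked_less_informative`). Retained plus excluded
#'   always partition the input loci.
#' @export
select_loci <- function(qc, null_threshold = 0.1) {
  stopifnot(inherits(qc, "locus_qc_report"))
  reason <- stats::setNames(rep(NA_character_, length(qc$loci)), qc$loci)
  hwe_both <- apply(qc$hwe_sig, 1, function(v) all(v %in% TRUE))
  reason[hwe_both] <- "hwe_both_years"
  null_bad <- !is.na(qc$null_freq) & qc$null_freq > null_threshold
  reason[null_bad & is.na(reason)] <- "null_gt_0.1"
  sig <- qc$ld[!is.na(qc$ld$significant) & qc$ld$significant, , drop = FALSE]
  if (nrow(sig)) {
    sig <- sig[order(sig$locus_a, sig$locus_b), , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      a <- sig$locus_a[i]
      b <- sig$locus_b[i]
      if (!is.na(reason[a]) || !is.na(reason[b])) next
      drop <- if (qc$he[a] < qc$he[b]) a
              else if (qc$he[b] < qc$he[a]) b
              else sort(c(a, b))[2]
      reason[drop] <- "linked_less_informative"
    }
  }
  retained <- qc$loci[is.na(reason)]
  excl <- data.frame(locus = names(reason)[!is.na(reason)],
                     reason = reason[!is.na(reason)], row.names = NULL)
  attr(retained, "exclusions") <- excl
  retained
}
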