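## Queen mating-frequency estimation from spermathecal sperm profiles:
## a Monte-Carlo contamination screen (per-queen expected rate at which
## two random mates would match the queen's alleles; critical value =
## across-queen mean + 2 SD), shared-allele attribution rules, the
## >=2-locus male-allele support rule, and a miscount calibration that
## simulates sperm profiles for known true mate numbers.

#' Sperm profile container
#'
#' Per-queen, per-locus sets of distinct alleles amplified from the stored
#' sperm mass. A locus with an empty allele set is unamplified.
#'
#' @param profiles Named list (by queen id) of named lists (by locus) of
#'   integer allele vectors.
#' @param loci Character vector of locus names.
#' @return Object of class `sperm_profiles`.
#' @export
sperm_profiles <- function(profiles, loci) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  profiles <- lapply(profiles, function(p) {
    p <- p[intersect(loci, names(p))]
    missing <- setdiff(loci, names(p))
    p[missing] <- list(integer(0))
    lapply(p[loci], function(v) sort(unique(as.integer(v))))
  })
  structure(list(profiles = profiles, loci = loci), class = "sperm_profiles")
}

#' @export
print.sperm_profiles <- function(x, ...) {
  amp <- vapply(x$profiles, function(p) sum(lengths(p) > 0), integer(1))
  cat(sprintf("sperm_profiles: %d queens x %d loci (median %d amplified)\n",
              length(x$profiles), length(x$loci),
              as.integer(stats::median(amp))))
  invisible(x)
}

#' Write or read sperm profiles as CSV
#'
#' Long format: one row per queen x locus with a `;`-separated allele list
#' and an `amplified` flag.
#'
#' @param profiles A [sperm_profiles()] object.
#' @param path CSV path.
#' @return `path` (write) or a `sperm_profiles` object (read).
#' @export
write_sperm_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(names(profiles$profiles), function(q) {
    p <- profiles$profiles[[q]]
    data.frame(queen_id = q, locus = names(p),
               alleles = vapply(p, paste, "", collapse = ";"),
               amplified = lengths(p) > 0)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sperm_profiles
#' @export
read_sperm_profiles <- function(path) {
  df <- utils::read.csv(path, colClasses = c(queen_id = "character",
                                             locus = "character",
                                             alleles = "character"))
  loci <- unique(df$locus)
  profs <- lapply(split(df, df$queen_id), function(d) {
    stats::setNames(lapply(d$alleles, function(a) {
      if (!nzchar(a)) integer(0) else as.integer(strsplit(a, ";")[[1]])
    }), d$locus)
  })
  sperm_profiles(profs, loci)
}

#' Probability that a queen's alleles are matched by her mates at a locus
#'
#' Probability that every distinct allele of the queen at the locus appears
#' among `n_males` independent haploid draws from the population allele
#' frequencies, by inclusion-exclusion. For a heterozygote `{a, b}` with
#' two mates this is `2 p_a p_b`; for a homozygote `{a, a}` it is
#' `1 - (1 - p_a)^n`.
#'
#' @param queen_alleles Integer vector (the queen's allele pair, or its
#'   distinct values).
#' @param freqs Named numeric vector of allele frequencies at the locus.
#' @param n_males Number of mates (default 2, the commonest mating
#'   frequency of polyandrous queens).
#' @return Probability in [0, 1].
#' @examples
#' locus_match_probability(c(1, 2), c(`1` = 0.5, `2` = 0.5))  # 0.5
#' @export
locus_match_probability <- function(queen_alleles, freqs, n_males = 2) {
  stopifnot(n_males >= 1)
  al <- unique(as.character(queen_alleles))
  if (!all(al %in% names(freqs))) {
    stop("queen allele absent from the frequency table")
  }
  p <- freqs[al]
  total <- 0
  for (m in 0:length(p)) {
    subsets <- utils::combn(length(p), m)
    for (j in seq_len(ncol(subsets))) {
      total <- total + (-1)^m * (1 - sum(p[subsets[, j]]))^n_males
    }
  }
  min(max(total, 0), 1)
}

#' Critical matching rate from the across-queen mean and SD
#'
#' @param mean_rate,sd_rate Mean and standard deviation of the per-queen
#'   expected matching rates.
#' @return `mean_rate + 2 * sd_rate` (one-sided normal screen at z = 2,
#'   upper tail probability 0.0228).
#' @export
matching_critical_value <- function(mean_rate, sd_rate) {
  mean_rate + 2 * sd_rate
}

#' Contamination screen: expected queen-sperm matching rates
#'
#' For every typed locus of every queen, computes the probability that her
#' alleles would be matched by the combined alleles of two random mates
#' (see [locus_match_probability()]), runs `reps` Bernoulli trials of each
#' probability, and counts matches within queens across loci. The per-queen
#' expected rate of matching is the mean match count over replicates
#' divided by the queen's typed-locus count; the critical value is the
#' across-queen mean plus two standard deviations.
#'
#' @param queens [genotype_table()] of queen genotypes.
#' @param freqs [allele_freqs] from the worker population.
#' @param n_males Assumed mate number (default 2).
#' @param reps Bernoulli replicates per probability.
#' @param seed Optional integer seed (results deterministic given it).
#' @param analytic If `TRUE`, skip the Monte Carlo and use the exact
#'   binomial mean (the value the trials converge to).
#' @return Object of class `sim1_result`: per-queen data frame
#'   (`id`, `n_loci`, `expected_matches`, `expected_rate`), `mean_rate`,
#'   `sd_rate`, `critical_value`.
#' @export
run_simulation_1 <- function(queens, freqs, n_males = 2, reps = 10000,
                             seed = NULL, analytic = FALSE) {
  stopifnot(inherits(queens, "genotype_table"), reps >= 1)
  with_seed(seed, {
    n <- n_individuals(queens)
    exp_matches <- n_typed <- numeric(n)
    for (i in seq_len(n)) {
      probs <- numeric(0)
      for (l in seq_along(queens$loci)) {
        a1 <- queens$a1[i, l]
        if (is.na(a1)) next
        f <- freqs[[queens$loci[l]]]
        qa <- as.character(c(a1, queens$a2[i, l]))
        if (!all(qa %in% names(f))) next
        probs <- c(probs, locus_match_probability(c(a1, queens$a2[i, l]), f,
                                                  n_males))
      }
      if (length(probs) == 0) stop("queen ", queens$id[i], " typed at no locus")
      n_typed[i] <- length(probs)
      exp_matches[i] <- if (analytic) sum(probs) else {
        mean(rowSums(matrix(stats::runif(reps * length(probs)), reps) <
                       rep(probs, each = reps)))
      }
    }
    rate <- exp_matches / n_typed
    res <- list(
      per_queen = data.frame(id = queens$id, n_loci = n_typed,
                             expected_matches = exp_matches,
                             expected_rate = rate),
      mean_rate = mean(rate), sd_rate = stats::sd(rate)
    )
    res$critical_value <- matching_critical_value(res$mean_rate, res$sd_rate)
    structure(res, class = "sim1_result")
  })
}

#' @export
print.sim1_result <- function(x, ...) {
  cat(sprintf(paste0("Contamination screen: %d queens, expected matching ",
                     "rate %.3f (SD %.3f), critical value %.3f\n"),
              nrow(x$per_queen), x$mean_rate, x$sd_rate, x$critical_value))
  invisible(x)
}

## distinct queen alleles at locus l, as integers (NULL if untyped)
queen_alleles_at <- function(queens, i, l) {
  a1 <- queens$a1[i, l]
  if (is.na(a1)) return(NULL)
  unique(c(a1, queens$a2[i, l]))
}

#' Flag sperm samples likely contaminated with queen tissue
#'
#' A queen's observed match rate is the fraction of loci (typed in the
#' queen and amplified in the sperm profile) at which all her distinct
#' alleles appear in the profile. Samples whose rate exceeds the critical
#' value are flagged: such pervasive sharing is unlikely under random
#' mating and more likely reflects contamination.
#'
#' @param queens [genotype_table()] of queen genotypes.
#' @param profiles [sperm_profiles()] for the same queens.
#' @param critical_value Critical rate from [run_simulation_1()].
#' @return Data frame `id`, `n_compared`, `match_rate`, `flagged`. Queens
#'   with no comparable locus get `NA` rate and flag.
#' @export
flag_contamination <- function(queens, profiles, critical_value) {
  stopifnot(inherits(profiles, "sperm_profiles"))
  n <- n_individuals(queens)
  rate <- rep(NA_real_, n)
  ncmp <- integer(n)
  for (i in seq_len(n)) {
    prof <- profiles$profiles[[queens$id[i]]]
    if (is.null(prof)) next
    hits <- logical(0)
    for (l in seq_along(queens$loci)) {
      qa <- queen_alleles_at(queens, i, l)
      pl <- prof[[queens$loci[l]]]
      if (is.null(qa) || length(pl) == 0) next
      hits <- c(hits, all(qa %in% pl))
    }
    ncmp[i] <- length(hits)
    if (length(hits)) rate[i] <- mean(hits)
  }
  data.frame(id = queens$id, n_compared = ncmp, match_rate = rate,
             flagged = rate > critical_value)
}

## per-locus male-attributable allele counts for one queen's profile
male_allele_counts <- function(queens, i, prof, flagged) {
  counts <- integer(0)
  for (l in seq_along(queens$loci)) {
    pl <- prof[[queens$loci[l]]]
    if (length(pl) == 0) next
    qa <- queen_alleles_at(queens, i, l)
    cnt <- if (!is.null(qa) && isTRUE(flagged) && all(qa %in% pl)) {
      ## full queen genotype present in a flagged sample: shared alleles
      ## are inferred contaminants and subtracted
      length(setdiff(pl, qa))
    } else length(pl)
    counts <- c(counts, cnt)
  }
  counts
}

## largest per-locus count supported at >= 2 loci, minimum 1
supported_count <- function(counts) {
  if (length(counts) == 0) return(NA_integer_)
  best <- 1L
  for (c in seq_len(max(counts, 1L))) {
    if (sum(counts >= c) >= 2L) best <- c
  }
  max(best, 1L)
}

#' Minimum number of male mates per queen
#'
#' Per locus, the male-attributable allele count is the number of sperm
#' alleles minus alleles inferred to be queen contaminants (a shared allele
#' is a contaminant only when the sample is flagged and the queen's full
#' genotype at that locus is present in the profile: a shared allele not
#' accompanied by the heterozygote queen's other allele is a true male
#' allele). The minimum mate count is the largest per-locus count supported
#' at two or more loci (a safeguard against genotyping error in the
#' low-yield sperm samples), and is at least 1 for any non-empty profile.
#'
#' @param queens [genotype_table()] of queen genotypes.
#' @param profiles [sperm_profiles()].
#' @param flags Data frame from [flag_contamination()] (or a logical vector
#'   named by queen id).
#' @return Data frame `id`, `min_males` (`NA` with a warning for empty
#'   profiles), `flagged`.
#' @export
count_min_males <- function(queens, profiles, flags) {
  if (is.data.frame(flags)) {
    flags <- stats::setNames(flags$flagged, flags$id)
  }
  n <- n_individuals(queens)
  out <- integer(n)
  for (i in seq_len(n)) {
    prof <- profiles$profiles[[queens$id[i]]]
    counts <- male_allele_counts(queens, i, prof, flags[[queens$id[i]]])
    out[i] <- supported_count(counts)
  }
  if (anyNA(out)) warning("queens with empty sperm profiles: ",
                          paste(queens$id[is.na(out)], collapse = ", "))
  data.frame(id = queens$id, min_males = out,
             flagged = unname(flags[queens$id]))
}

#' Estimate the queen mating system from sperm profiles
#'
#' Convenience wrapper: runs the contamination screen
#' ([run_simulation_1()]), flags contaminated samples, counts minimum mate
#' numbers, and summarizes the mating system.
#'
#' @inheritParams run_simulation_1
#' @param profiles [sperm_profiles()].
#' @return Object of class `mating_freq`: per-queen table, `sim1` result,
#'   `mean_mating_frequency`, `prop_monandrous`, `range`.
#' @export
estimate_mating_frequency <- function(queens, profiles, freqs,
                                      reps = 10000, seed = NULL) {
  sim1 <- run_simulation_1(queens, freqs, reps = reps, seed = seed)
  flags <- flag_contamination(queens, profiles, sim1$critical_value)
  counts <- count_min_males(queens, profiles, flags)
  per_queen <- merge(flags, counts[, c("id", "min_males")], by = "id",
                     sort = FALSE)
  ok <- !is.na(per_queen$min_males)
  structure(list(
    per_queen = per_queen, sim1 = sim1,
    mean_mating_frequency = mean(per_queen$min_males[ok]),
    prop_monandrous = mean(per_queen$min_males[ok] == 1L),
    range = range(per_queen$min_males[ok])
  ), class = "mating_freq")
}

#' @export
print.mating_freq <- function(x, ...) {
  cat(sprintf(paste0("Mating system: mean minimum mating frequency %.2f ",
                     "(range %d-%d), %.0f%% monandrous, critical value %.3f\n"),
              x$mean_mating_frequency, x$range[1], x$range[2],
              100 * x$prop_monandrous, x$sim1$critical_value))
  invisible(x)
}

#' Miscount calibration: observed versus true mate numbers
#'
#' For each "true" mate number `t`, pairs each queen genotype with `reps`
#' simulated sperm profiles built from `t` haploid males drawn at the
#' population allele frequencies, applies the identical flagging and
#' counting procedure used for real sperm samples, and tabulates the
#' observed mate counts. Rows are averaged across queens.
#'
#' @param queens [genotype_table()] of queen genotypes.
#' @param freqs [allele_freqs].
#' @param critical_value Critical matching rate from [run_simulation_1()].
#' @param true_range Integer vector of true mate numbers to simulate.
#' @param reps Replicates per queen per true number.
#' @param seed Optional integer seed.
#' @return Object of class `miscount_matrix`: `prob` is a matrix with rows
#'   indexed by true count and columns by observed count, rows summing to
#'   1; under this error-free counting model observed never exceeds true.
#' @export
run_simulation_2 <- function(queens, freqs, critical_value,
                             true_range = 1:9, reps = 10000, seed = NULL) {
  stopifnot(reps >= 1, all(true_range >= 1))
  with_seed(seed, {
    kmax <- max(true_range)
    acc <- matrix(0, length(true_range), kmax,
                  dimnames = list(true_range, seq_len(kmax)))
    used <- 0L
    for (i in seq_len(n_individuals(queens))) {
      typed <- which(!is.na(queens$a1[i, ]) &
                       vapply(seq_along(queens$loci), function(l) {
                         all(as.character(c(queens$a1[i, l], queens$a2[i, l]))
                             %in% names(freqs[[queens$loci[l]]]))
                       }, logical(1)))
      if (length(typed) < 2) next
      used <- used + 1L
      for (ti in seq_along(true_range)) {
        t <- true_range[ti]
        counts <- matrix(0L, reps, length(typed))
        matched <- matrix(FALSE, reps, length(typed))
        n_qa <- integer(length(typed))
        for (j in seq_along(typed)) {
          l <- typed[j]
          p <- freqs[[queens$loci[l]]]
          K <- length(p)
          draws <- matrix(sample.int(K, reps * t, replace = TRUE, prob = p),
                          reps, t)
          pres <- matrix(FALSE, reps, K)
          pres[cbind(rep(seq_len(reps), t), as.vector(draws))] <- TRUE
          qa <- match(as.character(queen_alleles_at(queens, i, l)), names(p))
          counts[, j] <- rowSums(pres)
          matched[, j] <- rowSums(pres[, qa, drop = FALSE]) == length(qa)
          n_qa[j] <- length(qa)
        }
        flagged <- rowMeans(matched) > critical_value
        ## subtract queen alleles where the sample is flagged and the full
        ## queen genotype is present (identical rule to count_min_males)
        adj <- counts - matched * flagged * rep(n_qa, each = reps)
        observed <- rep(1L, reps)
        if (t >= 2) for (c in 2:t) {
          observed <- observed + (rowSums(adj >= c) >= 2L)
        }
        tab <- tabulate(observed, kmax)
        acc[ti, ] <- acc[ti, ] + tab / reps
      }
    }
    if (used == 0L) stop("no queen typed at two or more usable loci")
    structure(list(prob = acc / used, reps = reps, true_range = true_range),
              class = "miscount_matrix")
  })
}

#' @export
print.miscount_matrix <- function(x, ...) {
  cat("Miscount calibration (rows: true mate number; cols: observed):\n")
  print(round(x$prob, 3))
  invisible(x)
}

#' Maximum likely mating frequency given an observed maximum
#'
#' The largest true mate number `t` such that the probability of observing
#' at most `observed_max` mates given `t` is at least `tail`; true numbers
#' above it would have produced a larger observed count with probability
#' greater than `1 - tail`.
#'
#' @param matrix A [run_simulation_2()] result (or a bare probability
#'   matrix with rows = true counts, columns = observed counts).
#' @param observed_max Largest observed mate count.
#' @param tail Tail probability (default 0.05).
#' @return Integer true mate number.
#' @export
max_likely_frequency <- function(matrix, observed_max, tail = 0.05) {
  prob <- if (inherits(matrix, "miscount_matrix")) matrix$prob else matrix
  true_vals <- as.integer(rownames(prob) %||% seq_len(nrow(prob)))
  if (observed_max < 1 || observed_max > ncol(prob)) {
    stop("observed_max outside the calibrated range")
  }
  cum <- rowSums(prob[, seq_len(observed_max), drop = FALSE])
  ok <- which(cum >= tail)
  if (length(ok) == 0) stop("no true count places mass at or below observed_max")
  max(true_vals[ok])
}
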