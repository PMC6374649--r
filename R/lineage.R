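## Between-year lineage survival (were the queens heading year-t+1
## colonies daughters of year-t colonies?) and fine-scale isolation by
## distance (does pairwise queen relatedness decline with inter-nest
## distance?).

#' Assemble inferred queen genotypes into a genotype table
#'
#' @param queens Named list of [infer_queen_genotype()] results (names =
#'   colony ids).
#' @param year Sampling year of the source colonies.
#' @param prefix Prefix for queen ids (default `"IQ_"`).
#' @return A [genotype_table()] with one row per inferred queen; filtered
#'   loci are missing calls.
#' @export
inferred_queens_table <- function(queens, year, prefix = "IQ_") {
  stopifnot(length(queens) >= 1, !is.null(names(queens)))
  loci <- queens[[1]]$loci
  a1 <- do.call(rbind, lapply(queens, function(q) q$a1))
  a2 <- do.call(rbind, lapply(queens, function(q) q$a2))
  genotype_table(paste0(prefix, names(queens)), year, a1, a2, loci)
}

#' Match inferred queens to the previous year's colonies
#'
#' Each inferred queen genotype is run through the sibship likelihood
#' machinery as a candidate full or half sister of every previous-year
#' colony's workers: the queen joins a colony as an additional offspring
#' of its queen (her own new patriline), and her score against the colony
#' is the gain in the patriline-aware colony log-likelihood plus the log
#' prior odds of sibship. The assignment probability is the softmax of
#' that score against all other colonies and the no-colony alternative;
#' matches are accepted at probability >= `threshold`. Filtered queen loci
#' are uninformative.
#'
#' @param queens [genotype_table()] of inferred queens (e.g. from
#'   [inferred_queens_table()]); queens with no confident locus are
#'   reported unmatched.
#' @param workers Previous-year worker [genotype_table()].
#' @param partition The previous year's `colony_partition` (or any list
#'   with an `assignments` data frame holding `id` and `colony`; patriline
#'   labels are used when present, otherwise full-sister groups are formed
#'   internally).
#' @param freqs [allele_freqs].
#' @param threshold Acceptance probability (default 0.8).
#' @param priors [sibship_priors()] used for the sibship prior odds.
#' @param error_rate Per-allele mistyping rate.
#' @return Data frame of class `lineage_matches`: `queen`,
#'   `matched_colony` (`NA` if unmatched), `probability`, `n_loci`.
#' @export
match_queens_across_years <- function(queens, workers, partition, freqs,
                                      threshold = 0.8,
                                      priors = sibship_priors(),
                                      error_rate = 0.0226) {
  stopifnot(inherits(queens, "genotype_table"))
  tables <- all_locus_tables(freqs, error_rate)
  prior <- relationship_priors(priors, n_individuals(workers))
  ps <- prior[["fs"]] + prior[["hs"]]
  kappa <- log(ps) - log1p(-ps)
  asg <- partition$assignments
  asg <- asg[match(workers$id, asg$id), ]
  ## patriline units within each previous-year colony
  states <- genotype_states(workers, freqs)
  unit <- if (!is.null(asg$patriline) && !anyNA(asg$patriline)) {
    asg$patriline
  } else {
    u <- character(nrow(asg))
    for (cid in unique(asg$colony)) {
      rows <- which(asg$colony == cid)
      labs <- fs_group_labels(workers[rows], freqs, error_rate, tables)
      u[rows] <- paste0(cid, "#", labs)
    }
    u
  }
  groups <- split(seq_len(nrow(asg)), unit)
  gs <- group_stack(states, tables, workers$loci, groups)
  gcol <- vapply(groups, function(g) asg$colony[g[1]], "")
  cols <- sort(unique(gcol))
  memb <- match(gcol, cols)
  st <- colony_cl(gs, memb, seq_along(cols))
  ## queens as candidate extra offspring (their own patriline of one)
  qstates <- genotype_states(
    genotype_table(queens$id, queens$year,
                   queens$a1[, workers$loci, drop = FALSE],
                   queens$a2[, workers$loci, drop = FALSE], workers$loci),
    freqs)
  qb <- group_stack(qstates, tables, workers$loci,
                    as.list(seq_len(n_individuals(queens))))$logW
  n_conf <- rowSums(!is.na(queens$a1))
  nq <- n_individuals(queens)
  out <- data.frame(queen = queens$id,
                    matched_colony = rep(NA_character_, nq),
                    probability = rep(NA_real_, nq), n_loci = n_conf)
  for (i in seq_len(n_individuals(queens))) {
    if (n_conf[i] == 0) next
    vals <- seg_logsumexp(st$V + qb[, i], gs$segs) - st$cl + kappa
    none <- seg_logsumexp(gs$logprior + qb[, i], gs$segs)
    post <- exp(c(vals, none) - logsumexp(c(vals, none)))
    best <- which.max(post[seq_along(cols)])
    out$probability[i] <- post[best]
    if (post[best] >= threshold) out$matched_colony[i] <- cols[best]
  }
  class(out) <- c("lineage_matches", "data.frame")
  out
}

#' Between-year lineage survival rate
#'
#' Fraction of previous-year colonies that contributed to a lineage
#' surviving into the next year, i.e. that had at least one inferred
#' next-year queen matched to them.
#'
#' @param matches A [match_queens_across_years()] result (or a character
#'   vector of matched colony ids).
#' @param n_prev_colonies Number of distinct previous-year colonies.
#' @return Survival rate in [0, 1].
#' @examples
#' lineage_survival_rate(rep("C1", 3), n_prev_colonies = 189)
#' @export
lineage_survival_rate <- function(matches, n_prev_colonies) {
  stopifnot(n_prev_colonies >= 1)
  matched <- if (is.data.frame(matches)) matches$matched_colony else matches
  length(unique(stats::na.omit(matched))) / n_prev_colonies
}

#' Pairwise Queller-Goodnight relatedness
#'
#' Symmetrized Queller-Goodnight (1989) estimator from population allele
#' frequencies: per locus and direction, the numerator is the mean
#' frequency-corrected allele sharing and the denominator the individual's
#' own heterozygosity correction; sums over loci and both directions are
#' taken before the ratio. Pairs sharing no typed locus get `NA`.
#'
#' @param gt [genotype_table()] (e.g. inferred queens).
#' @param freqs [allele_freqs].
#' @return Symmetric n x n matrix of relatedness estimates with `NA`
#'   diagonal.
#' @export
pairwise_relatedness <- function(gt, freqs) {
  n <- n_individuals(gt)
  NUM <- DEN <- matrix(0, n, n)
  shared <- matrix(0L, n, n)
  for (l in seq_along(gt$loci)) {
    p <- freqs[[gt$loci[l]]]
    if (length(p) < 1) next
    a1 <- gt$a1[, l]
    a2 <- gt$a2[, l]
    ok <- !is.na(a1)
    if (sum(ok) < 2) next
    pa <- p[as.character(a1)]
    pb <- p[as.character(a2)]
    usable <- ok & !is.na(pa) & !is.na(pb)
    if (sum(usable) < 2) next
    S <- (outer(a1, a1, "==") + outer(a1, a2, "==") +
            outer(a2, a1, "==") + outer(a2, a2, "==")) / 2
    denx <- 1 + (a1 == a2) - (pa + pb)     # row-indexed correction
    numx <- sweep(S, 1, pa + pb, "-")
    m <- outer(usable, usable, "&")
    numx[!m] <- 0
    DENL <- matrix(denx, n, n)
    DENL[!m] <- 0
    NUM <- NUM + numx + t(numx)
    DEN <- DEN + DENL + t(DENL)
    shared <- shared + m
  }
  r <- NUM / DEN
  r[shared == 0] <- NA_real_
  diag(r) <- NA_real_
  dimnames(r) <- list(gt$id, gt$id)
  r
}

#' Long-format relatedness/distance table
#'
#' @param rel Relatedness matrix from [pairwise_relatedness()].
#' @param nests Data frame `colony` (or `id`), `x`, `y` matching the
#'   matrix rows by order or name.
#' @return Data frame `i, j, r, distance_m`; pairs with `NA` relatedness
#'   (no shared typed locus) are kept but flagged `excluded`.
#' @export
relatedness_distance_table <- function(rel, nests) {
  n <- nrow(rel)
  stopifnot(nrow(nests) == n)
  pairs <- which(upper.tri(rel), arr.ind = TRUE)
  d <- sqrt((nests$x[pairs[, 1]] - nests$x[pairs[, 2]])^2 +
              (nests$y[pairs[, 1]] - nests$y[pairs[, 2]])^2)
  out <- data.frame(
    i = rownames(rel)[pairs[, 1]], j = colnames(rel)[pairs[, 2]],
    r = rel[pairs], distance_m = d)
  out$excluded <- is.na(out$r)
  out
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of pairwise relatedness on pairwise nest
#' distance (meters, untransformed), with the F test of the slope on
#' (1, n_pairs - 2) degrees of freedom. Pairwise observations are not
#' independent; the test is reported as-is (see [ibd_mantel()] for a
#' permutation alternative).
#'
#' @param tbl Data frame with columns `r` and `distance_m` (rows with `NA`
#'   relatedness dropped), e.g. from [relatedness_distance_table()].
#' @return List of class `ibd_fit`: `slope`, `intercept`, `F`, `df`,
#'   `p.value`, `r.squared`, `n_pairs`, and the underlying `lm` fit.
#' @export
ibd_regression <- function(tbl) {
  tbl <- tbl[!is.na(tbl$r), , drop = FALSE]
  if (nrow(tbl) < 3) stop("need at least 3 pairs")
  if (stats::var(tbl$distance_m) == 0) stop("zero-variance distances")
  fit <- stats::lm(r ~ distance_m, data = tbl)
  sm <- suppressWarnings(summary(fit))  # perfect toy fits warn harmlessly
  fstat <- sm$fstatistic
  if (is.null(fstat) || !is.finite(fstat[1])) {
    ## constant response: zero slope, nothing to test
    fstat <- c(value = 0, numdf = 1, dendf = nrow(tbl) - 2)
  }
  rsq <- sm$r.squared
  if (!is.finite(rsq)) rsq <- 0
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    F = unname(fstat[1]), df = unname(fstat[2:3]),
    p.value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
    r.squared = rsq, n_pairs = nrow(tbl), fit = fit
  ), class = "ibd_fit")
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat(sprintf(paste0("isolation by distance: slope %.3g, F(%d,%d) = %.3f, ",
                     "p = %.3f, R2 = %.4f (%d pairs)\n"),
              x$slope, x$df[1], x$df[2], x$F, x$p.value, x$r.squared,
              x$n_pairs))
  invisible(x)
}

#' Mantel permutation test of isolation by distance
#'
#' Permutation alternative to [ibd_regression()] that respects the dyadic
#' structure: individuals (matrix rows/columns) are permuted jointly and
#' the Pearson correlation between relatedness and distance recomputed.
#'
#' @param rel Relatedness matrix.
#' @param dist_m Matching distance matrix (m).
#' @param nperm Number of permutations.
#' @param seed Integer seed.
#' @return List: `statistic` (observed correlation), `p.value` (one-sided,
#'   greater), `nperm`.
#' @export
ibd_mantel <- function(rel, dist_m, nperm = 999, seed = 1) {
  n <- nrow(rel)
  stopifnot(identical(dim(rel), dim(dist_m)))
  ut <- upper.tri(rel)
  ok <- ut & !is.na(rel)
  obs <- stats::cor(rel[ok], dist_m[ok])
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(nperm)) {
      perm <- sample.int(n)
      rp <- rel[perm, perm]
      okp <- ut & !is.na(rp)
      if (stats::cor(rp[okp], dist_m[okp]) >= obs - 1e-12) hits <- hits + 1L
    }
    list(statistic = obs, p.value = (hits + 1) / (nperm + 1), nperm = nperm)
  })
}
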