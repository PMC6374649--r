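## Sibship reconstruction under haplodiploidy. Workers are assigned to
## colonies as full sisters (same queen, same haploid father: they share
## the father's single allele and one of two maternal alleles) or maternal
## half-sisters (same queen, different fathers). The engine computes exact
## per-locus joint genotype-pair probabilities for the three relationships
## (full sib, maternal half sib, unrelated) by marginalizing queen
## genotypes over Hardy-Weinberg priors and father alleles over population
## frequencies, with a symmetric per-allele mistyping channel, then
## partitions workers by agglomerative clustering on pairwise posterior
## sibship probabilities followed by hill-climbing reassignment.

## ---- per-locus machinery -------------------------------------------------

## index map for unordered genotypes over K alleles: G = K(K+1)/2 states
genotype_index_map <- function(K) {
  m <- matrix(NA_integer_, K, K)
  g <- 0L
  for (i in seq_len(K)) for (j in i:K) {
    g <- g + 1L
    m[i, j] <- m[j, i] <- g
  }
  m
}

## P(observed genotype | true genotype) under symmetric per-allele error:
## each true allele is read correctly with prob 1-e, otherwise replaced by
## an allele drawn at the population frequencies.
error_channel <- function(p, e) {
  K <- length(p)
  gi <- genotype_index_map(K)
  G <- K * (K + 1) / 2
  a <- (1 - e) * diag(K) + e * matrix(p, K, K, byrow = TRUE)  # a[t, o]
  E <- matrix(0, G, G)
  for (t1 in seq_len(K)) for (t2 in t1:K) {
    tg <- gi[t1, t2]
    for (o1 in seq_len(K)) for (o2 in o1:K) {
      og <- gi[o1, o2]
      E[tg, og] <- if (o1 == o2) a[t1, o1] * a[t2, o1] else {
        a[t1, o1] * a[t2, o2] + a[t1, o2] * a[t2, o1]
      }
    }
  }
  E
}

## offspring genotype distribution given queen (q1,q2) and father f:
## one maternal allele (each of the queen's with prob 1/2) plus f
offspring_given_qf <- function(q1, q2, f, gi, G) {
  v <- numeric(G)
  v[gi[q1, f]] <- v[gi[q1, f]] + 0.5
  v[gi[q2, f]] <- v[gi[q2, f]] + 0.5
  v
}

## per-locus tables reused across pairs and colonies:
##   cand     unordered queen genotype candidates (allele indices)
##   prior    Hardy-Weinberg prior per candidate
##   W        cand x G matrix: observed offspring genotype probs per queen
##   fs/hs/u  G x G joint observed-pair probability matrices
locus_tables <- function(p, e) {
  K <- length(p)
  gi <- genotype_index_map(K)
  G <- K * (K + 1) / 2
  cand <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  prior <- ifelse(cand[, 1] == cand[, 2], p[cand[, 1]]^2,
                  2 * p[cand[, 1]] * p[cand[, 2]])
  T_fs <- matrix(0, G, G)
  T_hs <- matrix(0, G, G)
  W <- matrix(0, nrow(cand), G)
  for (ci in seq_len(nrow(cand))) {
    q1 <- cand[ci, 1]
    q2 <- cand[ci, 2]
    w <- numeric(G)
    for (f in seq_len(K)) {
      v <- offspring_given_qf(q1, q2, f, gi, G)
      T_fs <- T_fs + prior[ci] * p[f] * tcrossprod(v)
      w <- w + p[f] * v
    }
    T_hs <- T_hs + prior[ci] * tcrossprod(w)
    W[ci, ] <- w
  }
  u <- as.vector(prior %*% W)  # Hardy-Weinberg offspring distribution
  T_u <- tcrossprod(u)
  E <- if (e > 0) error_channel(p, e) else diag(G)
  if (e > 0) {
    T_fs <- crossprod(E, T_fs) %*% E
    T_hs <- crossprod(E, T_hs) %*% E
    T_u <- crossprod(E, T_u) %*% E
    W <- W %*% E
  }
  ## log P(observed state | queen candidate, father allele): the unit of
  ## the patriline-aware colony likelihood
  pt <- array(NA_real_, c(nrow(cand), K, G))
  for (ci in seq_len(nrow(cand))) {
    q1 <- cand[ci, 1]
    q2 <- cand[ci, 2]
    for (f in seq_len(K)) {
      pt[ci, f, ] <- 0.5 * E[gi[q1, f], ] + 0.5 * E[gi[q2, f], ]
    }
  }
  list(cand = cand, prior = prior, W = W, fs = T_fs, hs = T_hs, u = T_u,
       gi = gi, sizes = as.integer(names(p)), p = unname(p), logpt = log(pt))
}

## cache of locus_tables for every locus of a frequency set
all_locus_tables <- function(freqs, error_rate) {
  lapply(freqs, function(p) if (length(p) < 1) NULL else
    locus_tables(p, error_rate))
}

## observed genotype state index per individual per locus (NA if missing
## or carrying an allele outside the frequency table)
genotype_states <- function(gt, freqs) {
  n <- n_individuals(gt)
  states <- matrix(NA_integer_, n, length(gt$loci))
  for (l in seq_along(gt$loci)) {
    p <- freqs[[gt$loci[l]]]
    if (length(p) < 1) next
    sizes <- as.integer(names(p))
    i1 <- match(gt$a1[, l], sizes)
    i2 <- match(gt$a2[, l], sizes)
    gi <- genotype_index_map(length(p))
    ok <- !is.na(i1) & !is.na(i2)
    states[ok, l] <- gi[cbind(i1[ok], i2[ok])]
  }
  states
}

#' Pairwise relationship log-likelihoods for worker genotypes
#'
#' Multilocus log-likelihoods of each pair of individuals being full
#' sisters, maternal half-sisters, or unrelated, as products over shared
#' typed loci of exact per-locus pair probabilities (queen genotypes
#' marginalized over Hardy-Weinberg priors, father alleles over population
#' frequencies, symmetric per-allele mistyping at `error_rate`). Loci
#' missing in either member contribute equally to all three hypotheses and
#' are skipped.
#'
#' @param gt A [genotype_table()].
#' @param freqs [allele_freqs] (population frequencies).
#' @param error_rate Per-allele mistyping rate.
#' @param tables Optional precomputed [all_locus_tables] cache.
#' @return List of three n x n matrices of log-likelihoods (`fs`, `hs`,
#'   `u`) and `n_shared`, the matrix of shared typed locus counts.
#' @export
pairwise_relationship_likelihoods <- function(gt, freqs, error_rate = 0.0226,
                                              tables = NULL) {
  n <- n_individuals(gt)
  states <- genotype_states(gt, freqs)
  if (is.null(tables)) tables <- all_locus_tables(freqs, error_rate)
  ll_fs <- ll_hs <- ll_u <- matrix(0, n, n)
  n_shared <- matrix(0L, n, n)
  for (l in seq_along(gt$loci)) {
    tab <- tables[[gt$loci[l]]]
    if (is.null(tab)) next
    s <- states[, l]
    ok <- which(!is.na(s))
    if (length(ok) < 2) next
    lf <- log(tab$fs)
    lh <- log(tab$hs)
    lu <- log(tab$u)
    idx <- cbind(rep(s[ok], times = length(ok)),
                 rep(s[ok], each = length(ok)))
    pos <- cbind(rep(ok, times = length(ok)), rep(ok, each = length(ok)))
    ll_fs[pos] <- ll_fs[pos] + lf[idx]
    ll_hs[pos] <- ll_hs[pos] + lh[idx]
    ll_u[pos] <- ll_u[pos] + lu[idx]
    n_shared[pos] <- n_shared[pos] + 1L
  }
  diag(n_shared) <- 0L
  dimnames(ll_fs) <- dimnames(ll_hs) <- dimnames(ll_u) <-
    list(gt$id, gt$id)
  list(fs = ll_fs, hs = ll_hs, u = ll_u, n_shared = n_shared)
}

## ---- priors and partitioning ---------------------------------------------

#' Sibship priors from the mating system
#'
#' With mean queen mating frequency `m` and mean sampled patriline size
#' `n`, a sample holds on average `m * n` maternal sisters for every `n`
#' paternal sisters. Among within-colony pairs the expected full-sib to
#' half-sib ratio is `(n - 1) : (m - 1) * n`, which sets the relationship
#' prior odds used by [reconstruct_colonies()].
#'
#' @param m Mean queen mating frequency (>= 1).
#' @param n Mean sampled patriline size (>= 1).
#' @param prior_sib Optional prior probability that a random same-year pair
#'   is sibs at all; if `NULL` it is set per year to
#'   `min(0.5, (m * n - 1) / (N - 1))` with `N` the year's worker count.
#' @return Object of class `sibship_priors` with `m`, `n`, `maternal_size`
#'   (`m * n`) and `prior_sib`.
#' @export
sibship_priors <- function(m = 1.7, n = 1.44, prior_sib = NULL) {
  stopifnot(m >= 1, n >= 1)
  structure(list(m = m, n = n, maternal_size = m * n, prior_sib = prior_sib),
            class = "sibship_priors")
}

#' @export
print.sibship_priors <- function(x, ...) {
  cat(sprintf(
    "sibship_priors: m = %.2f, n = %.2f (maternal sibship size %.3f)\n",
    x$m, x$n, x$maternal_size))
  invisible(x)
}

#' Estimate sibship priors from an initial partition
#'
#' `n` is the mean sampled patriline size of the partition (workers per
#' patriline label) and the expected maternal sibship size is `m * n`.
#'
#' @param partition A `colony_partition` (from a prior-free
#'   [reconstruct_colonies()] run).
#' @param m Mean queen mating frequency.
#' @return A [sibship_priors()] object.
#' @export
estimate_sibship_priors <- function(partition, m) {
  asg <- partition$assignments
  if (nrow(asg) == 0) stop("empty partition")
  n <- mean(table(asg$patriline))
  sibship_priors(m = m, n = max(n, 1))
}

## relationship prior probabilities (FS, HS, U) for a given worker count
relationship_priors <- function(priors, n_workers) {
  ps <- priors$prior_sib %||%
    min(0.5, max(priors$maternal_size - 1, 0.1) / max(n_workers - 1, 1))
  fs_w <- max(priors$n - 1, 0.1)
  hs_w <- max((priors$m - 1) * priors$n, 0.1)
  c(fs = ps * fs_w / (fs_w + hs_w), hs = ps * hs_w / (fs_w + hs_w),
    u = 1 - ps)
}

## ---- patriline-aware colony likelihood -----------------------------------
## Joint probability of a set of patrilines (full-sister groups) forming
## one colony: per locus, sum over queen genotype candidates
## (Hardy-Weinberg prior) of the product over patrilines of the
## father-marginalized probability of that group's observed genotypes
## given the queen. This captures both the shared-queen constraint across
## patrilines and the shared-father constraint within them.

## per-locus patriline vector: log L(group | queen candidate), father
## marginalized at the population frequencies; states are the group's
## non-missing observed genotype states at the locus
patriline_b <- function(tab, states) {
  nc <- nrow(tab$cand)
  if (!length(states)) return(numeric(nc))
  A <- tab$logpt[, , states[1], drop = TRUE]
  if (is.null(dim(A))) A <- matrix(A, nc)
  if (length(states) > 1) {
    for (s in states[-1]) {
      As <- tab$logpt[, , s, drop = TRUE]
      if (is.null(dim(As))) As <- matrix(As, nc)
      A <- A + As
    }
  }
  m <- A[, 1]
  if (ncol(A) > 1) for (f in 2:ncol(A)) m <- pmax(m, A[, f])
  ok <- is.finite(m)
  out <- rep(-Inf, nc)
  if (any(ok)) {
    out[ok] <- m[ok] +
      log(as.vector(exp(A[ok, , drop = FALSE] - m[ok]) %*% tab$p))
  }
  out
}

## stacked representation: rows are (locus, queen-candidate) pairs and
## columns are units (patrilines); the colony vector is the element-wise
## sum of its units' columns plus the queen-candidate log prior
group_stack <- function(states, tables, loci, groups) {
  segs <- list()
  logprior <- numeric(0)
  blocks <- list()
  loci_used <- integer(0)
  for (l in seq_along(loci)) {
    tab <- tables[[loci[l]]]
    if (is.null(tab)) next
    nc <- nrow(tab$cand)
    block <- vapply(groups, function(g) {
      s <- states[g, l]
      patriline_b(tab, s[!is.na(s)])
    }, numeric(nc))
    if (is.null(dim(block))) block <- matrix(block, nc)
    segs[[length(segs) + 1]] <- length(logprior) + seq_len(nc)
    logprior <- c(logprior, log(tab$prior))
    blocks[[length(blocks) + 1]] <- block
    loci_used <- c(loci_used, l)
  }
  list(logW = do.call(rbind, blocks), logprior = logprior, segs = segs,
       n = length(groups), loci_used = loci_used)
}

## label colony members by full-sister group (pairwise FS likelihood-ratio
## agglomeration; the queen-free step that fixes the patriline structure)
fs_group_labels <- function(gt, freqs, error_rate, tables,
                            kappa = log(0.01) - log(0.99)) {
  n <- n_individuals(gt)
  if (n == 1) return(1L)
  ll <- pairwise_relationship_likelihoods(gt, freqs, error_rate, tables)
  fs <- ll$fs - ll$u
  fs[is.nan(fs)] <- -Inf
  diag(fs) <- 0
  m <- merge_partition(fs, seq_len(n), kappa)
  m <- hillclimb_partition(fs, m, kappa)
  match(m, unique(m))
}

## column-wise sum over loci of logsumexp within each locus segment
seg_logsumexp <- function(V, segs) {
  if (is.null(dim(V))) V <- matrix(V)
  out <- numeric(ncol(V))
  for (idx in segs) {
    Vl <- V[idx, , drop = FALSE]
    m <- Vl[1, ]
    if (nrow(Vl) > 1) for (r in 2:nrow(Vl)) m <- pmax(m, Vl[r, ])
    mm <- ifelse(is.finite(m), m, 0)
    out <- out +
      ifelse(is.finite(m),
             m + log(colSums(exp(sweep(Vl, 2, mm, "-")))), -Inf)
  }
  out
}

## colony stacked vectors and log-likelihoods under a membership vector
colony_cl <- function(ms, membership, cols) {
  V <- ms$logprior +
    ms$logW %*% (outer(membership, cols, `==`) + 0)
  list(V = V, cl = seg_logsumexp(V, ms$segs))
}

## agglomerative merging on the colony likelihood: merge the pair of
## colonies with the largest gain while gain + kappa (the per-decision
## log prior odds of sibship) stays positive
cl_merge <- function(ms, membership, kappa) {
  cols <- sort(unique(membership))
  C <- length(cols)
  if (C < 2) return(membership)
  st <- colony_cl(ms, membership, cols)
  V <- st$V
  cl <- st$cl
  gain <- matrix(-Inf, C, C)
  for (a in seq_len(C - 1)) {
    rest <- (a + 1):C
    g <- seg_logsumexp(V[, rest, drop = FALSE] + (V[, a] - ms$logprior),
                       ms$segs) - cl[rest] - cl[a]
    gain[a, rest] <- g
  }
  alive <- rep(TRUE, C)
  repeat {
    best <- which.max(gain)
    if (gain[best] + kappa <= 1e-9) break
    b <- (best - 1L) %/% C + 1L
    a <- best - (b - 1L) * C
    membership[membership == cols[b]] <- cols[a]
    V[, a] <- V[, a] + V[, b] - ms$logprior
    cl[a] <- seg_logsumexp(V[, a], ms$segs)
    alive[b] <- FALSE
    gain[b, ] <- -Inf
    gain[, b] <- -Inf
    others <- which(alive & seq_len(C) != a)
    if (!length(others)) break
    g <- seg_logsumexp(V[, others, drop = FALSE] + (V[, a] - ms$logprior),
                       ms$segs) - cl[others] - cl[a]
    gain[a, ] <- -Inf
    gain[, a] <- -Inf
    gain[pmin(a, others) + (pmax(a, others) - 1L) * C] <- g
  }
  membership
}

## hill-climbing at unit (patriline) level: move each unit to the colony
## maximizing the likelihood gain + kappa, or out to its own colony
cl_hillclimb <- function(ms, membership, kappa, max_sweeps = 4) {
  for (sweep_i in seq_len(max_sweeps)) {
    moved <- FALSE
    cols <- sort(unique(membership))
    st <- colony_cl(ms, membership, cols)
    V <- st$V
    cl <- st$cl
    sizes <- tabulate(match(membership, cols), length(cols))
    for (w in seq_len(ms$n)) {
      cur <- match(membership[w], cols)
      alone <- sizes[cur] == 1L
      Vown <- V[, cur] - ms$logW[, w]
      clown <- if (alone) 0 else seg_logsumexp(Vown, ms$segs)
      Vadj <- V
      Vadj[, cur] <- Vown
      cladj <- cl
      cladj[cur] <- clown
      delta <- seg_logsumexp(Vadj + ms$logW[, w], ms$segs) - cladj
      vals <- delta + kappa
      if (alone) vals[cur] <- -Inf
      single <- seg_logsumexp(ms$logprior + ms$logW[, w], ms$segs)
      own <- if (alone) single else vals[cur]
      cand <- c(vals, single)
      best <- which.max(cand)
      if (cand[best] > own + 1e-9) {
        V[, cur] <- Vown
        cl[cur] <- seg_logsumexp(Vown, ms$segs)
        sizes[cur] <- sizes[cur] - 1L
        if (best <= length(cols)) {
          membership[w] <- cols[best]
          V[, best] <- V[, best] + ms$logW[, w]
          cl[best] <- seg_logsumexp(V[, best], ms$segs)
          sizes[best] <- sizes[best] + 1L
        } else {
          newc <- max(cols) + 1L
          membership[w] <- newc
          cols <- c(cols, newc)
          V <- cbind(V, ms$logprior + ms$logW[, w])
          cl <- c(cl, seg_logsumexp(V[, ncol(V)], ms$segs))
          sizes <- c(sizes, 1L)
        }
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  membership
}

## worker-level refinement: each worker may leave its patriline and join
## another colony as a new patriline (or become a singleton colony);
## returns the final per-worker colony membership and softmax inclusion
## probabilities; state (patriline vectors, colony stacks) is updated
## incrementally per move
worker_refine <- function(states, tables, loci, grp, gcol, kappa,
                          max_sweeps = 2) {
  n <- nrow(states)
  groups <- split(seq_len(n), grp)
  G <- length(groups)
  ms <- group_stack(states, tables, loci, groups)
  Bmat <- ms$logW
  logprior <- ms$logprior
  segs <- ms$segs
  ## singleton vectors for every worker, computed once
  Bsingle <- group_stack(states, tables, loci, as.list(seq_len(n)))$logW
  grp <- match(grp, as.integer(names(groups)))       # group index per worker
  cols <- sort(unique(gcol[as.character(names(groups))]))
  gmem <- match(gcol[as.character(names(groups))], cols)  # colony per group
  C <- length(cols)
  V <- logprior + Bmat %*% (outer(gmem, seq_len(C), `==`) + 0)
  cl <- seg_logsumexp(V, segs)
  col_alive <- tabulate(gmem, C) > 0
  incl <- numeric(n)
  for (sweep_i in seq_len(max_sweeps + 1)) {
    final <- sweep_i > max_sweeps
    moved <- FALSE
    for (w in seq_len(n)) {
      g <- grp[w]
      ci <- gmem[g]
      mates <- setdiff(which(grp == g), w)
      Bw <- Bsingle[, w]
      Bg_minus <- if (length(mates)) {
        gs <- group_stack(states, tables, loci, list(mates))
        gs$logW[, 1]
      } else NULL
      Vown <- V[, ci] - Bmat[, g] +
        (if (is.null(Bg_minus)) 0 else Bg_minus)
      colony_empty <- is.null(Bg_minus) && sum(gmem == ci, na.rm = TRUE) == 1
      clown <- if (colony_empty) 0 else seg_logsumexp(Vown, segs)
      Vadj <- V
      Vadj[, ci] <- Vown
      cladj <- cl
      cladj[ci] <- clown
      delta <- seg_logsumexp(Vadj + Bw, segs) - cladj
      vals <- delta + kappa
      vals[!col_alive] <- -Inf
      single <- seg_logsumexp(logprior + Bw, segs)
      ## own option: the actual current configuration (w inside its
      ## patriline), not w as a fresh patriline
      own <- if (colony_empty) single else cl[ci] - clown + kappa
      if (colony_empty) vals[ci] <- -Inf
      if (final) {
        incl[w] <- exp(own - logsumexp(c(vals[-ci], own, single)))
        next
      }
      cand <- c(vals, single)
      cand[ci] <- own
      best <- which.max(cand)
      if (cand[best] > own + 1e-9) {
        ## detach w from its patriline and colony
        if (length(mates)) {
          Bmat[, g] <- Bg_minus
        } else {
          Bmat[, g] <- 0
          gmem[g] <- NA_integer_
        }
        V[, ci] <- Vown
        cl[ci] <- clown
        if (colony_empty) col_alive[ci] <- FALSE
        ## attach as a fresh patriline
        Bmat <- cbind(Bmat, Bw)
        if (best <= C) {
          tci <- best
          V[, tci] <- V[, tci] + Bw
          cl[tci] <- seg_logsumexp(V[, tci], segs)
        } else {
          C <- C + 1L
          tci <- C
          V <- cbind(V, logprior + Bw)
          cl <- c(cl, seg_logsumexp(V[, C], segs))
          col_alive <- c(col_alive, TRUE)
        }
        gmem <- c(gmem, tci)
        grp[w] <- ncol(Bmat)
        moved <- TRUE
      }
    }
    if (final) break
    if (!moved) max_sweeps <- sweep_i  # converged: next pass is the final one
  }
  list(membership = gmem[grp], inclusion = incl, grp = grp)
}

## prior-free pairwise log-likelihood ratio of sibship (FS/HS mixture at
## the prior's relative odds) versus unrelated; the partition prior enters
## once per assignment decision (kappa), not once per pair
pair_sib_scores <- function(ll, prior) {
  wf <- prior[["fs"]] / (prior[["fs"]] + prior[["hs"]])
  A <- log(wf) + ll$fs
  B <- log(1 - wf) + ll$hs
  M <- pmax(A, B)
  num <- ifelse(is.finite(M), M + log1p(exp(pmin(A, B) - M)), M)
  s <- num - ll$u
  s[is.nan(s)] <- -Inf
  diag(s) <- 0
  ps <- prior[["fs"]] + prior[["hs"]]
  list(score = s, kappa = log(ps) - log1p(-ps))
}

## per-worker per-colony score sums: S[i, c] = sum_j in c score[i, j]
colony_score_sums <- function(score, membership, cols) {
  ind <- outer(membership, cols, `==`) + 0
  score %*% ind
}

## greedy agglomeration on total within-colony pairwise score: starting
## from the given membership, repeatedly merge the pair of colonies whose
## summed cross scores are largest, while that sum plus the per-merge
## prior penalty kappa stays positive
merge_partition <- function(score, membership, kappa = 0) {
  cols <- sort(unique(membership))
  if (length(cols) < 2) return(membership)
  ind <- outer(membership, cols, `==`) + 0
  M <- crossprod(ind, score %*% ind)
  alive <- rep(TRUE, length(cols))
  diag(M) <- -Inf
  repeat {
    if (sum(alive) < 2) break
    best <- which.max(M)
    if (M[best] + kappa <= 1e-12) break
    b <- (best - 1L) %/% nrow(M) + 1L
    a <- best - (b - 1L) * nrow(M)
    membership[membership == cols[b]] <- cols[a]
    M[a, ] <- M[a, ] + M[b, ]
    M[, a] <- M[, a] + M[, b]
    M[a, a] <- -Inf
    M[b, ] <- -Inf
    M[, b] <- -Inf
    alive[b] <- FALSE
  }
  membership
}

## greedy hill-climbing on total within-colony pairwise score; each worker
## may move to the colony (or a fresh singleton) maximizing its summed
## score to members plus the per-assignment prior penalty kappa;
## deterministic in worker order
hillclimb_partition <- function(score, membership, kappa = 0,
                                max_sweeps = 25) {
  n <- nrow(score)
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    cols <- sort(unique(membership))
    S <- colony_score_sums(score, membership, cols)
    sizes <- tabulate(match(membership, cols), length(cols))
    for (i in seq_len(n)) {
      cur <- match(membership[i], cols)
      alone <- sizes[cur] == 1L
      vals <- S[i, ] + kappa  # diag(score) is 0: self contributes nothing
      if (alone) vals[cur] <- -Inf
      own <- if (alone) 0 else vals[cur]
      cand <- c(vals, 0)  # final option: leave as a fresh singleton
      best <- which.max(cand)
      if (cand[best] > own + 1e-12) {
        S[, cur] <- S[, cur] - score[, i]
        sizes[cur] <- sizes[cur] - 1L
        if (best <= length(cols)) {
          membership[i] <- cols[best]
          S[, best] <- S[, best] + score[, i]
          sizes[best] <- sizes[best] + 1L
        } else {
          newc <- max(cols) + 1L
          membership[i] <- newc
          cols <- c(cols, newc)
          S <- cbind(S, score[, i])
          sizes <- c(sizes, 1L)
        }
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  membership
}

## softmax inclusion probability of each worker's assignment versus the
## alternatives: every other colony (with the per-assignment prior
## penalty) plus staying as a singleton
inclusion_probabilities <- function(score, membership, kappa = 0) {
  n <- nrow(score)
  cols <- sort(unique(membership))
  S <- colony_score_sums(score, membership, cols)
  sizes <- tabulate(match(membership, cols), length(cols))
  vapply(seq_len(n), function(i) {
    cur <- match(membership[i], cols)
    alone <- sizes[cur] == 1L
    vals <- S[i, ] + kappa
    if (alone) vals[cur] <- -Inf
    own <- if (alone) 0 else vals[cur]
    exp(own - logsumexp(c(vals, 0)))
  }, numeric(1))
}

#' Reconstruct colonies from worker genotypes
#'
#' Partitions workers into colonies of full and maternal half-sisters:
#' pairwise posterior sibship probabilities (relationship priors from
#' [sibship_priors()]) seed an average-linkage agglomerative clustering,
#' which is refined by hill-climbing reassignment maximizing the total
#' within-colony pairwise log posterior odds of sibship. Workers whose
#' inclusion probability (softmax of their colony's score against every
#' alternative, including staying single) falls below `min_inclusion` are
#' left as singletons. Workers are only ever co-assigned within a year
#' (annual colony cycle). Colonies are then annotated with patriline counts
#' (via [infer_queen_genotype()] and [count_patrilines()]) and accepted
#' when they hold at least two workers and at most `max_patrilines`
#' patrilines.
#'
#' @param gt Worker [genotype_table()] restricted to the QC-retained loci.
#' @param freqs [allele_freqs].
#' @param priors A [sibship_priors()].
#' @param min_inclusion Minimum inclusion probability (default 0.8).
#' @param error_rate Per-allele mistyping rate.
#' @param max_patrilines Acceptance bound on patriline count (default 5,
#'   the maximum likely mating frequency); colonies are rejected only when
#'   the count exceeds it.
#' @param seed Optional integer seed (partitioning is deterministic; the
#'   seed is reserved for hill-climb restarts).
#' @return Object of class `colony_partition`: `assignments` (data frame
#'   `id, year, colony, inclusion, patriline, accepted`), `colonies` (per-
#'   colony summary), and `priors`.
#' @export
reconstruct_colonies <- function(gt, freqs, priors = sibship_priors(),
                                 min_inclusion = 0.8, error_rate = 0.0226,
                                 max_patrilines = 5, seed = NULL) {
  stopifnot(inherits(gt, "genotype_table"), n_individuals(gt) >= 1)
  tables <- all_locus_tables(freqs, error_rate)
  years <- sort(unique(gt$year))
  asg <- NULL
  colony_counter <- 0L
  for (yr in years) {
    sub <- gt[gt$year == yr]
    n <- n_individuals(sub)
    if (n == 1) {
      colony_counter <- colony_counter + 1L
      asg <- rbind(asg, data.frame(id = sub$id, year = yr,
                                   colony = sprintf("C%04d", colony_counter),
                                   inclusion = 1))
      next
    }
    ll <- pairwise_relationship_likelihoods(sub, freqs, error_rate, tables)
    prior <- relationship_priors(priors, n)
    sc <- pair_sib_scores(ll, prior)
    states <- genotype_states(sub, freqs)
    ## stage 1: full-sister grouping on the pairwise FS likelihood ratio
    fs_score <- ll$fs - ll$u
    fs_score[is.nan(fs_score)] <- -Inf
    diag(fs_score) <- 0
    grp0 <- merge_partition(fs_score, seq_len(n), sc$kappa)
    grp0 <- hillclimb_partition(fs_score, grp0, sc$kappa)
    groups <- split(seq_len(n), grp0)
    ## stage 2: patriline-aware colony likelihood over the groups
    ms <- group_stack(states, tables, sub$loci, groups)
    gmem <- seq_along(groups)
    gmem <- cl_merge(ms, gmem, sc$kappa)
    gmem <- cl_hillclimb(ms, gmem, sc$kappa)
    ## stage 3: worker-level refinement and inclusion probabilities
    grp <- integer(n)
    for (g in seq_along(groups)) grp[groups[[g]]] <- g
    gcol <- stats::setNames(gmem, as.character(seq_along(groups)))
    wr <- worker_refine(states, tables, sub$loci, grp, gcol, sc$kappa)
    membership <- wr$membership
    incl <- wr$inclusion
    demote <- incl < min_inclusion &
      membership %in% membership[duplicated(membership)]
    if (any(demote)) {
      grp2 <- wr$grp
      gcol2 <- stats::setNames(membership[match(sort(unique(grp2)), grp2)],
                               as.character(sort(unique(grp2))))
      mx <- max(grp2)
      mc <- max(membership)
      for (w in which(demote)) {
        mx <- mx + 1L
        mc <- mc + 1L
        grp2[w] <- mx
        gcol2[as.character(mx)] <- mc
      }
      wr <- worker_refine(states, tables, sub$loci, grp2, gcol2, sc$kappa,
                          max_sweeps = 0)
      membership <- wr$membership
      incl <- wr$inclusion
    }
    ## stable colony ids in worker-id order
    first <- !duplicated(membership)
    relabel <- stats::setNames(
      sprintf("C%04d", colony_counter + seq_len(sum(first))),
      membership[first])
    colony_counter <- colony_counter + sum(first)
    asg <- rbind(asg, data.frame(
      id = sub$id, year = yr,
      colony = unname(relabel[as.character(membership)]),
      inclusion = incl))
  }
  asg$patriline <- NA_character_
  colonies <- NULL
  for (cid in unique(asg$colony)) {
    rows <- which(asg$colony == cid)
    workers <- gt[asg$id[rows]]
    iq <- infer_queen_genotype(workers, freqs, error_rate, tables = tables)
    pat <- count_patrilines(workers, iq)
    asg$patriline[rows] <- paste0(cid, "_P", pat$labels)
    accepted <- length(rows) >= 2 && pat$count <= max_patrilines
    colonies <- rbind(colonies, data.frame(
      colony = cid, year = asg$year[rows[1]], n_workers = length(rows),
      n_patrilines = pat$count, accepted = accepted,
      irreconcilable = pat$irreconcilable
    ))
  }
  asg$accepted <- colonies$accepted[match(asg$colony, colonies$colony)]
  structure(list(assignments = asg, colonies = colonies, priors = priors),
            class = "colony_partition")
}

#' @export
print.colony_partition <- function(x, ...) {
  acc <- x$colonies[x$colonies$accepted, , drop = FALSE]
  cat(sprintf(paste0("colony_partition: %d workers in %d colonies ",
                     "(%d accepted with >= 2 workers and <= max patrilines)\n"),
              nrow(x$assignments), nrow(x$colonies), nrow(acc)))
  invisible(x)
}

#' Write a colony partition to CSV
#'
#' One row per worker: id, year, colony id, inclusion probability,
#' patriline label, accepted flag.
#'
#' @param partition A `colony_partition`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(partition$assignments, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Infer a colony queen's genotype from her workers
#'
#' Per locus, the posterior over queen genotypes given the colony's worker
#' genotypes, with Hardy-Weinberg genotype priors. Workers are first
#' grouped into full-sister patrilines (queen-free, from the pairwise
#' full-sib likelihood ratio) and one father allele is marginalized at the
#' population frequencies per patriline, so a paternal allele shared by a
#' whole patriline is not mistaken for a maternal one. The
#' maximum-posterior genotype is retained only where its posterior reaches
#' `min_confidence`.
#'
#' @param colony_workers [genotype_table()] of one colony's workers.
#' @param freqs [allele_freqs].
#' @param error_rate Per-allele mistyping rate.
#' @param min_confidence Posterior threshold for retaining a locus
#'   (default 0.8).
#' @param tables Optional precomputed [all_locus_tables] cache.
#' @param patrilines Optional integer vector of patriline labels per
#'   worker, overriding the internal full-sister grouping.
#' @return Object of class `inferred_queen`: matrices `a1`, `a2` (1 x loci,
#'   `NA` where filtered), `confidence` (posterior of the best genotype per
#'   locus), `loci`.
#' @export
infer_queen_genotype <- function(colony_workers, freqs, error_rate = 0.0226,
                                 min_confidence = 0.8, tables = NULL,
                                 patrilines = NULL) {
  stopifnot(n_individuals(colony_workers) >= 1)
  loci <- colony_workers$loci
  if (is.null(tables)) tables <- all_locus_tables(freqs, error_rate)
  if (is.null(patrilines)) {
    patrilines <- fs_group_labels(colony_workers, freqs, error_rate, tables)
  }
  a1 <- a2 <- matrix(NA_integer_, 1, length(loci),
                     dimnames = list(NULL, loci))
  conf <- stats::setNames(rep(NA_real_, length(loci)), loci)
  states <- genotype_states(colony_workers, freqs)
  groups <- split(seq_len(n_individuals(colony_workers)), patrilines)
  gs <- group_stack(states, tables, loci, groups)
  V <- gs$logprior + rowSums(gs$logW)
  for (si in seq_along(gs$segs)) {
    l <- gs$loci_used[si]
    tab <- tables[[loci[l]]]
    logpost <- V[gs$segs[[si]]]
    post <- exp(logpost - logsumexp(logpost))
    best <- which.max(post)
    conf[l] <- post[best]
    if (post[best] >= min_confidence) {
      a1[1, l] <- tab$sizes[min(tab$cand[best, ])]
      a2[1, l] <- tab$sizes[max(tab$cand[best, ])]
    }
  }
  structure(list(a1 = a1, a2 = a2, confidence = conf, loci = loci),
            class = "inferred_queen")
}

#' @export
print.inferred_queen <- function(x, ...) {
  cat(sprintf("inferred_queen: %d of %d loci at confidence >= threshold\n",
              sum(!is.na(x$a1)), length(x$loci)))
  invisible(x)
}

#' Count patrilines in a colony
#'
#' Given the inferred (maternal) queen genotype, derives each worker's
#' paternal-allele candidates per locus (the allele not attributable to the
#' queen; ambiguous when both worker alleles are queen alleles) and
#' greedily groups workers into single-father classes consistent with
#' them, processing workers in id order and assigning each to the first
#' compatible father profile (deterministic tie-break).
#'
#' @param colony_workers [genotype_table()] of one colony's workers.
#' @param inferred_queen An [infer_queen_genotype()] result.
#' @return List: `count` (number of patrilines), `labels` (integer
#'   patriline label per worker), `irreconcilable` (TRUE if some worker
#'   shares no allele with the inferred queen at a confidently-typed
#'   locus).
#' @export
count_patrilines <- function(colony_workers, inferred_queen) {
  n <- n_individuals(colony_workers)
  loci <- colony_workers$loci
  irreconcilable <- FALSE
  ## per worker per locus: candidate paternal alleles (NULL = uninformative)
  cands <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- vector("list", length(loci))
    for (l in seq_along(loci)) {
      q1 <- inferred_queen$a1[1, l]
      if (is.na(q1)) next
      q2 <- inferred_queen$a2[1, l]
      w1 <- colony_workers$a1[i, l]
      if (is.na(w1)) next
      w2 <- colony_workers$a2[i, l]
      in_q <- c(w1 %in% c(q1, q2), w2 %in% c(q1, q2))
      if (!any(in_q)) {
        irreconcilable <- TRUE  # no maternal allele; leave uninformative
        next
      }
      cl[[l]] <- if (all(in_q)) unique(c(w1, w2)) else c(w1, w2)[!in_q]
    }
    cands[[i]] <- cl
  }
  labels <- integer(n)
  fathers <- list()  # per patriline: per-locus paternal-allele candidate sets
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_along(fathers)) {
      prof <- fathers[[k]]
      compatible <- TRUE
      for (l in seq_along(loci)) {
        a <- prof[[l]]
        b <- cands[[i]][[l]]
        if (is.null(a) || is.null(b)) next
        if (length(intersect(a, b)) == 0) {
          compatible <- FALSE
          break
        }
      }
      if (compatible) {
        for (l in seq_along(loci)) {
          a <- prof[[l]]
          b <- cands[[i]][[l]]
          upd <- if (is.null(a)) b else if (is.null(b)) a else intersect(a, b)
          if (!is.null(upd)) fathers[[k]][l] <- list(upd)
        }
        labels[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      fathers[[length(fathers) + 1]] <- cands[[i]]
      labels[i] <- length(fathers)
    }
  }
  list(count = length(fathers), labels = labels,
       irreconcilable = irreconcilable)
}
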