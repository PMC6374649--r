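## Nest locations, colony-specific worker foraging distances, sister-pair
## distance checks, and nest density via the abundance-based coverage
## estimator (ACE) with a foraging-distance buffer around the sampling
## area.

#' Mean centre of a set of planar points
#'
#' @param points Two-column matrix or data frame of (x, y) coordinates (m).
#' @return Numeric vector `c(x, y)`.
#' @examples
#' mean_centre(rbind(c(0, 0), c(10, 0)))  # c(5, 0)
#' @export
mean_centre <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point list")
  c(mean(points[, 1]), mean(points[, 2]))
}

#' Colony-specific worker foraging distances
#'
#' For each accepted colony the nest location is estimated as the mean
#' centre of its workers' sampling locations; each worker's foraging
#' distance is its Euclidean distance to that centre, and the
#' colony-specific foraging distance is the mean over the colony's
#' workers. Colonies need at least two workers whose locations are
#' separated by more than `min_separation` meters (the GPS precision);
#' colonies failing the rule are excluded and listed.
#'
#' @param partition A `colony_partition` from [reconstruct_colonies()].
#' @param coords Data frame `id, x_m, y_m` of worker sampling locations.
#' @param min_separation Minimum pairwise separation (m, default 4).
#' @param accepted_only Use accepted colonies only (default TRUE).
#' @return Object of class `nest_estimates`: `nests` (colony, year, x, y,
#'   foraging_distance, n_workers), `workers` (per-worker distances),
#'   `excluded` (colonies failing the separation rule), and summary fields
#'   `mean_colony_distance`, `max_worker_distance`.
#' @export
colony_foraging_distances <- function(partition, coords, min_separation = 4,
                                      accepted_only = TRUE) {
  asg <- partition$assignments
  if (accepted_only) asg <- asg[asg$accepted %in% TRUE, , drop = FALSE]
  asg <- merge(asg, coords[, c("id", "x_m", "y_m")], by = "id")
  nests <- NULL
  workers <- NULL
  excluded <- character(0)
  for (cid in unique(asg$colony)) {
    sub <- asg[asg$colony == cid, , drop = FALSE]
    if (nrow(sub) < 2) {
      excluded <- c(excluded, cid)
      next
    }
    pts <- cbind(sub$x_m, sub$y_m)
    if (max(stats::dist(pts)) <= min_separation) {
      excluded <- c(excluded, cid)
      next
    }
    ctr <- mean_centre(pts)
    d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    nests <- rbind(nests, data.frame(
      colony = cid, year = sub$year[1], x = ctr[1], y = ctr[2],
      foraging_distance = mean(d), n_workers = nrow(sub)))
    workers <- rbind(workers, data.frame(
      id = sub$id, colony = cid, year = sub$year, distance = d))
  }
  structure(list(
    nests = nests, workers = workers, excluded = excluded,
    mean_colony_distance = if (is.null(nests)) NA_real_ else
      mean(nests$foraging_distance),
    max_worker_distance = if (is.null(workers)) NA_real_ else
      max(workers$distance)
  ), class = "nest_estimates")
}

#' @export
print.nest_estimates <- function(x, ...) {
  cat(sprintf(paste0("nest_estimates: %d colonies, mean colony-specific ",
                     "foraging distance %.1f m (max worker %.1f m)\n"),
              if (is.null(x$nests)) 0L else nrow(x$nests),
              x$mean_colony_distance, x$max_worker_distance))
  if (length(x$excluded)) {
    cat("  excluded (separation rule):", length(x$excluded), "colonies\n")
  }
  invisible(x)
}

#' Compare sampling distances of full- versus half-sister pairs
#'
#' Within accepted colonies, pairwise distances between sampling locations
#' of reconstructed full sisters (same patriline) are compared with those
#' of maternal half-sisters (different patrilines, same colony) by a
#' two-sample Welch t test. If half-sisters were reconstructed with
#' appreciably more error, their pairwise distances would exceed the
#' full sisters'.
#'
#' @param partition A `colony_partition`.
#' @param coords Data frame `id, x_m, y_m`.
#' @return `htest` object from [stats::t.test()], with the pairwise
#'   distance vectors attached as `full_distances` / `half_distances`.
#' @export
compare_sister_distances <- function(partition, coords) {
  asg <- partition$assignments
  asg <- asg[asg$accepted %in% TRUE, , drop = FALSE]
  asg <- merge(asg, coords[, c("id", "x_m", "y_m")], by = "id")
  full <- half <- numeric(0)
  for (cid in unique(asg$colony)) {
    sub <- asg[asg$colony == cid, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
      d <- sqrt((sub$x_m[i] - sub$x_m[j])^2 + (sub$y_m[i] - sub$y_m[j])^2)
      if (sub$patriline[i] == sub$patriline[j]) full <- c(full, d)
      else half <- c(half, d)
    }
  }
  if (length(full) < 2 || length(half) < 2) {
    stop("need at least two pairs in each sister class")
  }
  ht <- stats::t.test(full, half, var.equal = FALSE)
  ht$full_distances <- full
  ht$half_distances <- half
  ht
}

#' Outward buffer area of a square sampling region
#'
#' Area of the Euclidean buffer of width `r` around a square of side
#' `side`: four edge strips plus four quarter-circle corners,
#' `4 * side * r + pi * r^2`, returned in hectares.
#'
#' @param side Square side (m).
#' @param r Buffer width (m), e.g. the mean colony-specific worker
#'   foraging distance.
#' @return Area in hectares.
#' @examples
#' buffer_area(2000, 103.6)  # 86.25 ha
#' @export
buffer_area <- function(side, r) {
  stopifnot(side > 0, r >= 0)
  (4 * side * r + pi * r^2) / 1e4
}

#' Abundance-based coverage estimator (ACE) of total colony number
#'
#' Treats colonies as classes and sampled workers per colony as
#' abundances. With rare colonies those holding at most `rare_cutoff`
#' workers, `S_ACE = S_abund + S_rare / C_ACE + (F1 / C_ACE) * gamma^2`,
#' where `C_ACE = 1 - F1 / N_rare` is the sample coverage, `F_i` counts
#' colonies with exactly `i` workers, `N_rare` the workers in rare
#' colonies, and `gamma^2` the squared coefficient of variation
#' `max[(S_rare / C_ACE) * sum(i (i - 1) F_i) / (N_rare (N_rare - 1)) - 1, 0]`.
#' The standard error comes from a seeded nonparametric bootstrap over
#' workers.
#'
#' @param abundances Integer vector of workers per detected colony.
#' @param rare_cutoff Rare-class abundance cutoff (default 10).
#' @param se_boot Bootstrap replicates for the SE (0 disables).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `ace_result`: `s_obs`, `s_rare`, `s_abund`,
#'   `f1`, `n_rare`, `coverage`, `gamma2`, `estimate`, `se`, `ci`
#'   (estimate +/- 1.96 SE), `completeness` (`s_obs / estimate`).
#' @examples
#' ace_estimate(c(1, 1, 2, 3, 12), se_boot = 0)$estimate  # 6.79
#' @export
ace_estimate <- function(abundances, rare_cutoff = 10, se_boot = 1000,
                         seed = 1) {
  abundances <- as.integer(abundances[abundances > 0])
  if (length(abundances) == 0) stop("need at least one detected colony")
  point <- function(ab) {
    rare <- ab[ab <= rare_cutoff]
    s_obs <- length(ab)
    s_abund <- sum(ab > rare_cutoff)
    s_rare <- length(rare)
    if (s_rare == 0) {
      return(list(estimate = s_obs, coverage = 1, gamma2 = 0, f1 = 0,
                  n_rare = 0, s_obs = s_obs, s_rare = 0, s_abund = s_abund))
    }
    f1 <- sum(rare == 1)
    n_rare <- sum(rare)
    coverage <- 1 - f1 / n_rare
    if (coverage == 0) {
      stop(paste("ACE undefined: every rare colony is a singleton",
                 "(sample coverage 0); use a Chao1-type estimator instead"))
    }
    fi <- tabulate(rare, rare_cutoff)
    i <- seq_len(rare_cutoff)
    gamma2 <- max(
      (s_rare / coverage) * sum(i * (i - 1) * fi) /
        (n_rare * (n_rare - 1)) - 1, 0)
    est <- s_abund + s_rare / coverage + f1 / coverage * gamma2
    list(estimate = est, coverage = coverage, gamma2 = gamma2, f1 = f1,
         n_rare = n_rare, s_obs = s_obs, s_rare = s_rare, s_abund = s_abund)
  }
  pt <- point(abundances)
  se <- NA_real_
  if (se_boot > 0) {
    n <- sum(abundances)
    probs <- abundances / n
    se <- with_seed(seed, {
      reps <- vapply(seq_len(se_boot), function(b) {
        ab <- stats::rmultinom(1, n, probs)[, 1]
        out <- tryCatch(point(ab[ab > 0])$estimate, error = function(e)
          NA_real_)
        out
      }, numeric(1))
      stats::sd(reps, na.rm = TRUE)
    })
  }
  structure(c(pt, list(
    se = se,
    ci = if (is.na(se)) c(NA_real_, NA_real_) else
      pt$estimate + c(-1.96, 1.96) * se,
    completeness = pt$s_obs / pt$estimate,
    rare_cutoff = rare_cutoff
  )), class = "ace_result")
}

#' @export
print.ace_result <- function(x, ...) {
  cat(sprintf(paste0("ACE: %d colonies detected, estimated total %.2f",
                     " (SE %.2f), coverage %.3f, completeness %.2f\n"),
              x$s_obs, x$estimate, x$se, x$coverage, x$completeness))
  invisible(x)
}

#' Nest density from an ACE estimate and sampling geometry
#'
#' Estimated total colonies divided by the core sampling area plus the
#' buffer defined by the mean worker foraging distance around its
#' periphery.
#'
#' @param ace An [ace_estimate()] result (or a bare estimate).
#' @param core_area_ha Core sampling area (ha).
#' @param buffer_area_ha Buffer area (ha), from [buffer_area()].
#' @return Object of class `density_estimate`: `estimate`, `density`
#'   (colonies per ha), `density_se`, `completeness`, `core_area_ha`,
#'   `buffer_area_ha`.
#' @examples
#' d <- nest_density(1244.21, core_area_ha = 400, buffer_area_ha = 86.25)
#' round(d$density, 2)  # 2.56
#' @export
nest_density <- function(ace, core_area_ha, buffer_area_ha) {
  stopifnot(core_area_ha > 0, buffer_area_ha >= 0)
  est <- if (inherits(ace, "ace_result")) ace$estimate else as.numeric(ace)
  se <- if (inherits(ace, "ace_result")) ace$se else NA_real_
  compl <- if (inherits(ace, "ace_result")) ace$completeness else NA_real_
  total <- core_area_ha + buffer_area_ha
  structure(list(
    estimate = est, density = est / total,
    density_se = se / total, completeness = compl,
    core_area_ha = core_area_ha, buffer_area_ha = buffer_area_ha
  ), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(paste0("nest density: %.2f colonies per ha ",
                     "(%.2f colonies over %.2f ha)\n"),
              x$density, x$estimate, x$core_area_ha + x$buffer_area_ha))
  invisible(x)
}
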