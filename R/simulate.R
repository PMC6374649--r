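## Spatially explicit synthetic populations of polyandrous haplodiploid
## colonies: queens mated to 1-5 haploid males, nests uniform in a square
## arena, workers displaced by a foraging kernel and sampled on a grid with
## a per-square cap, genotyped with allelic mistyping and missingness, and
## queens carrying sperm profiles optionally contaminated with their own
## alleles. Truth labels are carried through so every inference stage can
## be scored.

#' Simulation configuration
#'
#' Defaults emulate the study system the package's analyses assume: a
#' 2 x 2 km arena split into 500 x 500 m sampling squares capped at 40
#' workers each, 20 microsatellite loci with Dirichlet allele-frequency
#' spectra, queens mated to 1-5 haploid males, a half-normal worker
#' foraging kernel with a 100 m mean displacement, 2.26% allelic
#' mistyping, and a 0.1 between-year lineage-survival probability.
#'
#' @param seed Integer seed (mandatory); all draws derive from it.
#' @param arena_side Arena side length in meters.
#' @param n_colonies Integer vector, colonies per year (length = number of
#'   years).
#' @param years Calendar labels for the simulated years.
#' @param mating_dist Probability vector over 1..5 male mates per queen.
#' @param kernel_mean Mean worker displacement (m) of the half-normal
#'   foraging kernel.
#' @param kernel Kernel family: `"halfnormal"` or `"exponential"`.
#' @param n_loci Number of microsatellite loci.
#' @param alleles_per_locus Alleles per locus (recycled).
#' @param freq_spectrum `"dirichlet"` (concentration 1) or `"uniform"`
#'   (equifrequent alleles).
#' @param mistyping_rate Per-allele mistyping probability.
#' @param missing_rate Per-locus-call missingness probability.
#' @param contamination_prob Probability a queen's sperm sample is
#'   contaminated with her own tissue.
#' @param sperm_dropout Per-male-allele, per-locus dropout probability in
#'   sperm profiles (low sperm DNA yields).
#' @param grid_size Sampling-square side (m).
#' @param square_cap Maximum sampled workers per square per year.
#' @param worker_lambda Poisson mean of sampled-worker count per colony
#'   (before the square cap); a fixed count can be given via
#'   `workers_per_colony`.
#' @param workers_per_colony Optional fixed worker count per colony,
#'   overriding `worker_lambda`.
#' @param lineage_survival Probability a year-1 colony contributes a
#'   daughter queen founding a year-2 colony; remaining year-2 colonies are
#'   founded by unrelated immigrant queens.
#' @param spatial_structure If `TRUE`, surviving daughters nest within
#'   `daughter_dispersal_m` of the natal nest, inducing isolation by
#'   distance; the default `FALSE` matches a spatially unstructured
#'   population.
#' @param daughter_dispersal_m Mean natal dispersal distance (m) under
#'   `spatial_structure`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       arena_side = 2000,
                       n_colonies = c(250, 120),
                       years = seq(2014, length.out = length(n_colonies)),
                       mating_dist = c(0.34, 0.46, 0.14, 0.04, 0.02),
                       kernel_mean = 100,
                       kernel = c("halfnormal", "exponential"),
                       n_loci = 20,
                       alleles_per_locus = 8,
                       freq_spectrum = c("dirichlet", "uniform"),
                       mistyping_rate = 0.0226,
                       missing_rate = 0.1,
                       contamination_prob = 1,
                       sperm_dropout = 0.1,
                       grid_size = 500,
                       square_cap = 40,
                       worker_lambda = 1.5,
                       workers_per_colony = NULL,
                       lineage_survival = 0.1,
                       spatial_structure = FALSE,
                       daughter_dispersal_m = 200) {
  if (missing(seed)) stop("a seed is mandatory")
  kernel <- match.arg(kernel)
  freq_spectrum <- match.arg(freq_spectrum)
  mating_dist <- mating_dist / sum(mating_dist)
  stopifnot(
    n_loci >= 1, length(n_colonies) >= 1, all(n_colonies >= 0),
    all(mating_dist >= 0), length(mating_dist) >= 1,
    kernel_mean >= 0, square_cap >= 1,
    mistyping_rate >= 0, mistyping_rate <= 1,
    missing_rate >= 0, missing_rate <= 1,
    contamination_prob >= 0, contamination_prob <= 1,
    sperm_dropout >= 0, sperm_dropout <= 1,
    lineage_survival >= 0, lineage_survival <= 1
  )
  cfg <- as.list(environment())
  cfg$alleles_per_locus <- rep_len(alleles_per_locus, n_loci)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

## True allele frequencies for a config (deterministic given config$seed)
sim_allele_frequencies <- function(config) {
  with_seed(derive_seed(config$seed, 1L), {
    freqs <- vector("list", config$n_loci)
    names(freqs) <- sprintf("L%02d", seq_len(config$n_loci))
    for (l in seq_len(config$n_loci)) {
      k <- config$alleles_per_locus[l]
      sizes <- as.character(100L + 2L * seq_len(k))
      p <- if (config$freq_spectrum == "uniform") rep(1 / k, k) else {
        g <- stats::rgamma(k, shape = 1)
        g / sum(g)
      }
      freqs[[l]] <- stats::setNames(p, sizes)
    }
    structure(freqs, absent = character(0), class = "allele_freqs")
  })
}

## Draw one haploid genotype (allele size per locus) from freqs
draw_haploid <- function(freqs) {
  vapply(freqs, function(p) {
    as.integer(names(p))[sample.int(length(p), 1, prob = p)]
  }, integer(1))
}

#' Simulate a multi-year colony population
#'
#' Queens' diploid genotypes are Hardy-Weinberg draws at the configured
#' allele frequencies; fathers are i.i.d. haploid draws; mate numbers come
#' from the configured distribution; nests are uniform in the arena.
#' Year `t+1` queens are daughters of year-`t` colonies with the configured
#' lineage-survival probability (one daughter per surviving lineage) and
#' unrelated immigrants otherwise.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed overriding `config$seed`.
#' @return A list of class `sim_population` with `config`, true
#'   `allele_freqs`, and per-year colony tables: queen genotypes, father
#'   genotypes, nest coordinates, and (for survivors) the parent colony id.
#' @export
simulate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- sim_allele_frequencies(config)
  L <- config$n_loci
  nm <- length(config$mating_dist)
  with_seed(derive_seed(seed, 2L), {
    years <- vector("list", length(config$n_colonies))
    names(years) <- as.character(config$years)
    for (y in seq_along(config$n_colonies)) {
      C <- config$n_colonies[y]
      qa1 <- qa2 <- matrix(NA_integer_, C, L,
                           dimnames = list(NULL, names(freqs)))
      parent <- rep(NA_character_, C)
      nest <- matrix(stats::runif(2 * C, 0, config$arena_side), C, 2,
                     dimnames = list(NULL, c("x", "y")))
      slot <- 1L
      if (y > 1 && C > 0) {
        prev <- years[[y - 1]]
        survives <- stats::runif(nrow(prev$queen_a1)) < config$lineage_survival
        for (i in which(survives)) {
          if (slot > C) break
          f <- prev$fathers[[i]][sample.int(nrow(prev$fathers[[i]]), 1), ]
          m <- ifelse(stats::runif(L) < 0.5, prev$queen_a1[i, ],
                      prev$queen_a2[i, ])
          qa1[slot, ] <- pmin(m, f)
          qa2[slot, ] <- pmax(m, f)
          parent[slot] <- prev$id[i]
          if (config$spatial_structure) {
            ang <- stats::runif(1, 0, 2 * pi)
            r <- abs(stats::rnorm(1, 0,
                                  config$daughter_dispersal_m * sqrt(pi / 2)))
            nest[slot, ] <- pmin(pmax(
              prev$nest[i, ] + r * c(cos(ang), sin(ang)), 0),
              config$arena_side)
          }
          slot <- slot + 1L
        }
      }
      for (i in seq_len(C)) {
        if (i < slot) next  # survivor slots already filled
        m1 <- draw_haploid(freqs)
        m2 <- draw_haploid(freqs)
        qa1[i, ] <- pmin(m1, m2)
        qa2[i, ] <- pmax(m1, m2)
      }
      fathers <- lapply(seq_len(C), function(i) {
        k <- sample.int(nm, 1, prob = config$mating_dist)
        t(vapply(seq_len(k), function(j) draw_haploid(freqs), integer(L)))
      })
      years[[y]] <- list(
        id = sprintf("Y%s_C%03d", config$years[y], seq_len(C)),
        queen_a1 = qa1, queen_a2 = qa2, fathers = fathers,
        nest = nest, parent = parent, year = config$years[y]
      )
    }
    structure(list(config = config, freqs = freqs, years = years),
              class = "sim_population")
  })
}

#' @export
print.sim_population <- function(x, ...) {
  cat("sim_population:",
      paste(sprintf("%s (%d colonies)", names(x$years),
                    vapply(x$years, function(y) length(y$id), integer(1))),
            collapse = ", "), "\n")
  invisible(x)
}

## radial displacement draw for the foraging kernel, parameterized by mean
kernel_radius <- function(n, mean, kernel) {
  if (mean == 0) return(rep(0, n))
  if (kernel == "halfnormal") {
    abs(stats::rnorm(n, 0, mean * sqrt(pi / 2)))
  } else {
    stats::rexp(n, 1 / mean)
  }
}

#' Simulate sampled workers from a population
#'
#' Each colony contributes workers (Poisson or fixed count); a worker's
#' patriline is uniform over its queen's mates, its genotype is one
#' maternal allele plus the patriline father's allele per locus, and its
#' sampling location is the nest displaced by an isotropic foraging-kernel
#' draw. Grid-square sampling is then applied: workers landing outside the
#' arena fall in no square and are unsampled, and squares over the cap are
#' uniformly thinned. True colony and patriline labels are retained.
#'
#' @param population A [simulate_population()] result.
#' @param config A [sim_config()] (defaults to the population's).
#' @param seed Optional integer seed.
#' @return List of class `worker_sample`: `genotypes` (error-free
#'   [genotype_table()] of sampled workers), `coords` (data frame `id, x_m,
#'   y_m, year`), and `truth` (data frame with colony id, patriline label,
#'   nest coordinates, displacement, and a `sampled` flag; unsampled rows
#'   record workers thinned by the cap or landing outside the arena).
#' @export
simulate_workers <- function(population, config = population$config,
                             seed = config$seed) {
  stopifnot(inherits(population, "sim_population"))
  with_seed(derive_seed(seed, 3L), {
    rows <- list()
    for (y in population$years) {
      C <- length(y$id)
      if (C == 0) next
      n_w <- if (!is.null(config$workers_per_colony)) {
        rep(config$workers_per_colony, C)
      } else stats::rpois(C, config$worker_lambda)
      for (i in seq_len(C)) {
        if (n_w[i] == 0) next
        k <- nrow(y$fathers[[i]])
        pat <- sample.int(k, n_w[i], replace = TRUE)
        L <- ncol(y$queen_a1)
        mat <- matrix(ifelse(stats::runif(n_w[i] * L) < 0.5,
                             rep(y$queen_a1[i, ], each = n_w[i]),
                             rep(y$queen_a2[i, ], each = n_w[i])), n_w[i], L)
        patm <- y$fathers[[i]][pat, , drop = FALSE]
        r <- kernel_radius(n_w[i], config$kernel_mean, config$kernel)
        ang <- stats::runif(n_w[i], 0, 2 * pi)
        rows[[length(rows) + 1]] <- list(
          colony = rep(y$id[i], n_w[i]),
          patriline = sprintf("%s_P%d", y$id[i], pat),
          year = rep(y$year, n_w[i]),
          a1 = pmin(mat, patm), a2 = pmax(mat, patm),
          x = y$nest[i, 1] + r * cos(ang),
          y = y$nest[i, 2] + r * sin(ang),
          nest_x = rep(y$nest[i, 1], n_w[i]),
          nest_y = rep(y$nest[i, 2], n_w[i]),
          displacement = r
        )
      }
    }
    if (length(rows) == 0) {
      L <- population$config$n_loci
      empty <- genotype_table(character(0), integer(0),
                              matrix(NA_integer_, 0, L),
                              matrix(NA_integer_, 0, L),
                              names(population$freqs))
      return(structure(list(genotypes = empty,
                            coords = data.frame(id = character(0),
                                                x_m = numeric(0),
                                                y_m = numeric(0),
                                                year = integer(0)),
                            truth = data.frame()),
                       class = "worker_sample"))
    }
    a1 <- do.call(rbind, lapply(rows, `[[`, "a1"))
    a2 <- do.call(rbind, lapply(rows, `[[`, "a2"))
    truth <- data.frame(
      colony = unlist(lapply(rows, `[[`, "colony")),
      patriline = unlist(lapply(rows, `[[`, "patriline")),
      year = unlist(lapply(rows, `[[`, "year")),
      x_m = unlist(lapply(rows, `[[`, "x")),
      y_m = unlist(lapply(rows, `[[`, "y")),
      nest_x = unlist(lapply(rows, `[[`, "nest_x")),
      nest_y = unlist(lapply(rows, `[[`, "nest_y")),
      displacement = unlist(lapply(rows, `[[`, "displacement"))
    )
    truth$id <- sprintf("W%04d", seq_len(nrow(truth)))
    ## grid-square sampling with the per-square cap
    gs <- config$grid_size
    inside <- truth$x_m >= 0 & truth$x_m < config$arena_side &
      truth$y_m >= 0 & truth$y_m < config$arena_side
    square <- ifelse(inside,
                     paste(truth$year, floor(truth$x_m / gs),
                           floor(truth$y_m / gs)), NA)
    sampled <- inside
    for (sq in unique(stats::na.omit(square))) {
      idx <- which(!is.na(square) & square == sq)
      if (length(idx) > config$square_cap) {
        drop <- sample(idx, length(idx) - config$square_cap)
        sampled[drop] <- FALSE
      }
    }
    truth$sampled <- sampled
    gt <- genotype_table(truth$id, truth$year, a1, a2,
                         names(population$freqs))
    coords <- data.frame(id = truth$id, x_m = truth$x_m, y_m = truth$y_m,
                         year = truth$year)
    structure(list(genotypes = gt, coords = coords, truth = truth),
              class = "worker_sample")
  })
}

#' Apply genotyping error to a genotype table
#'
#' Each allele is independently replaced, with probability
#' `mistyping_rate`, by a random allele drawn at the locus's population
#' frequencies; each locus-level call is then set missing with probability
#' `missing_rate`.
#'
#' @param gt A [genotype_table()].
#' @param freqs [allele_freqs] used for replacement draws (defaults to
#'   frequencies estimated from `gt`).
#' @param mistyping_rate,missing_rate Probabilities in [0, 1].
#' @param seed Optional integer seed.
#' @return A `genotype_table` of observed genotypes.
#' @export
apply_genotyping_error <- function(gt, freqs = estimate_allele_frequencies(gt),
                                   mistyping_rate = 0.0226,
                                   missing_rate = 0, seed = NULL) {
  stopifnot(mistyping_rate >= 0, mistyping_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  with_seed(seed, {
    a1 <- gt$a1
    a2 <- gt$a2
    n <- nrow(a1)
    for (l in seq_along(gt$loci)) {
      p <- freqs[[gt$loci[l]]]
      sizes <- as.integer(names(p))
      for (mat in c("a1", "a2")) {
        v <- get(mat)[, l]
        hit <- !is.na(v) & stats::runif(n) < mistyping_rate
        if (any(hit)) {
          v[hit] <- sizes[sample.int(length(p), sum(hit), replace = TRUE,
                                     prob = p)]
          if (mat == "a1") a1[, l] <- v else a2[, l] <- v
        }
      }
      gone <- stats::runif(n) < missing_rate
      a1[gone, l] <- NA_integer_
      a2[gone, l] <- NA_integer_
    }
    genotype_table(gt$id, gt$year, a1, a2, gt$loci)
  })
}

#' Simulate spermathecal sperm profiles for the population's queens
#'
#' The uncontaminated profile of a queen is the union of her mates' alleles
#' per locus, with each male allele independently dropped with probability
#' `dropout` (low sperm DNA yields). With probability `contamination_prob`
#' the sample is contaminated with queen tissue: both queen alleles are
#' added at every amplified locus. A locus with no surviving male allele is
#' unamplified and carries no alleles.
#'
#' @param population A [simulate_population()] result.
#' @param contamination_prob,dropout Probabilities (default from the
#'   population's config).
#' @param seed Optional integer seed.
#' @return A list of class `sperm_sample_set`: `queens` (a
#'   [genotype_table()] of queen genotypes), `profiles` (a
#'   [sperm_profiles()] object), and truth vectors `contaminated` and
#'   `n_mates` named by queen id.
#' @export
simulate_sperm_samples <- function(population,
                                   contamination_prob =
                                     population$config$contamination_prob,
                                   dropout = population$config$sperm_dropout,
                                   seed = population$config$seed) {
  stopifnot(inherits(population, "sim_population"))
  with_seed(derive_seed(seed, 4L), {
    loci <- names(population$freqs)
    qa1 <- qa2 <- NULL
    ids <- character(0)
    years <- integer(0)
    profiles <- list()
    contaminated <- logical(0)
    n_mates <- integer(0)
    for (y in population$years) {
      for (i in seq_along(y$id)) {
        qid <- paste0("Q_", y$id[i])
        ids <- c(ids, qid)
        years <- c(years, y$year)
        qa1 <- rbind(qa1, y$queen_a1[i, ])
        qa2 <- rbind(qa2, y$queen_a2[i, ])
        fa <- y$fathers[[i]]
        contam <- stats::runif(1) < contamination_prob
        prof <- lapply(seq_along(loci), function(l) {
          al <- fa[, l]
          al <- al[stats::runif(length(al)) >= dropout]
          sort(unique(al))
        })
        names(prof) <- loci
        if (contam) {
          for (l in seq_along(loci)) {
            if (length(prof[[l]])) {
              prof[[l]] <- sort(unique(c(prof[[l]], y$queen_a1[i, l],
                                         y$queen_a2[i, l])))
            }
          }
        }
        profiles[[qid]] <- prof
        contaminated <- c(contaminated, contam)
        n_mates <- c(n_mates, nrow(fa))
      }
    }
    queens <- genotype_table(ids, years, qa1, qa2, loci)
    structure(list(queens = queens,
                   profiles = sperm_profiles(profiles, loci),
                   contaminated = stats::setNames(contaminated, ids),
                   n_mates = stats::setNames(n_mates, ids)),
              class = "sperm_sample_set")
  })
}
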