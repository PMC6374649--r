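## End-to-end orchestration: locus QC -> mating system -> sibship ->
## spatial/density -> lineage survival -> isolation by distance, from
## either a synthetic scenario or CSV inputs, with per-stage seeds and a
## single summary JSON.

#' Pipeline configuration
#'
#' Houses the input sources (a synthetic scenario or CSV paths), stage
#' toggles, and every analysis threshold in one place: inclusion
#' probability 0.8, null-allele cutoff 0.1, maximum 5 patrilines per
#' accepted colony, queen-locus confidence 0.8, 4 m GPS precision, ACE
#' rare cutoff 10.
#'
#' @param synthetic Optional [sim_config()]; when given, inputs are
#'   simulated.
#' @param genotypes,coordinates,queens,sperm CSV paths used when
#'   `synthetic` is `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, in pipeline order.
#' @param core_area_ha Core sampling area; defaults to the synthetic
#'   arena's area, else 400 ha.
#' @param min_inclusion,null_threshold,max_patrilines,queen_confidence,gps_precision,rare_cutoff
#'   Analysis thresholds (see Description).
#' @param error_rate Per-allele mistyping rate assumed by the likelihood
#'   model.
#' @param hwe_reps,ld_reps,sim1_reps,sim2_reps,se_boot Monte-Carlo sizes.
#' @param sim2_true_range True mate numbers calibrated by the miscount
#'   matrix.
#' @param seed Master integer seed; every random stage derives its own
#'   seed from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, genotypes = NULL,
                            coordinates = NULL, queens = NULL, sperm = NULL,
                            out_dir = tempfile("nestkin_run_"),
                            stages = c("qc", "mating", "sibship", "spatial",
                                       "lineage", "ibd"),
                            core_area_ha = NULL,
                            min_inclusion = 0.8, null_threshold = 0.1,
                            max_patrilines = 5, queen_confidence = 0.8,
                            gps_precision = 4, rare_cutoff = 10,
                            error_rate = 0.0226,
                            hwe_reps = 2000, ld_reps = 500,
                            sim1_reps = 10000, sim2_reps = 2000,
                            sim2_true_range = 1:9, se_boot = 1000,
                            seed = 1) {
  stopifnot(min_inclusion > 0, min_inclusion <= 1,
            null_threshold > 0, null_threshold < 1,
            max_patrilines >= 1, queen_confidence > 0, queen_confidence <= 1,
            gps_precision >= 0, rare_cutoff >= 1)
  if (is.null(synthetic)) {
    for (p in c(genotypes, coordinates)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  } else {
    stopifnot(inherits(synthetic, "sim_config"))
  }
  if (is.null(core_area_ha)) {
    core_area_ha <- if (!is.null(synthetic)) synthetic$arena_side^2 / 1e4
    else 400
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (QC, mating system, sibship,
#' spatial/density, lineage survival, isolation by distance), writes each
#' stage's table outputs plus a single `summary.json` under
#' `config$out_dir`, and returns the summary. Identical configurations and
#' seeds give identical outputs; stage failures abort with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` (the summary plus stage
#'   objects), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  summary <- list(seed = config$seed)
  res <- list(config = config)

  ## ---- inputs ----
  if (!is.null(config$synthetic)) {
    scfg <- config$synthetic
    pop <- simulate_population(scfg)
    ws <- simulate_workers(pop, scfg)
    keep <- ws$truth$sampled
    workers_true <- ws$genotypes[which(keep)]
    workers <- apply_genotyping_error(
      workers_true, pop$freqs, scfg$mistyping_rate, scfg$missing_rate,
      seed = derive_seed(scfg$seed, 5L))
    coords <- ws$coords[keep, , drop = FALSE]
    sp <- simulate_sperm_samples(pop)
    queens <- sp$queens
    profiles <- sp$profiles
    res$sperm_truth <- sp
    write_genotype_table(workers, file.path(config$out_dir, "workers.csv"))
    write_coordinates(coords, file.path(config$out_dir, "coordinates.csv"))
    utils::write.csv(ws$truth, file.path(config$out_dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    res$population <- pop
    res$worker_sample <- ws
  } else {
    workers <- read_genotype_table(config$genotypes)
    coords <- read_coordinates(config$coordinates)
    queens <- if (!is.null(config$queens)) {
      read_genotype_table(config$queens)
    }
    profiles <- if (!is.null(config$sperm)) {
      read_sperm_profiles(config$sperm)
    }
  }
  freqs <- estimate_allele_frequencies(workers)
  res$workers <- workers
  res$freqs <- freqs

  ## ---- qc ----
  retained <- workers$loci
  if ("qc" %in% config$stages) {
    stage("qc", {
      qc <- locus_qc(workers, hwe_reps = config$hwe_reps,
                     ld_reps = config$ld_reps,
                     seed = derive_seed(config$seed, 11L))
      retained <- select_loci(qc, null_threshold = config$null_threshold)
      qcdf <- data.frame(locus = qc$loci, he = qc$he,
                         null_freq = qc$null_freq)
      for (y in colnames(qc$hwe_p)) qcdf[[paste0("hwe_p_", y)]] <- qc$hwe_p[, y]
      qcdf$retained <- qc$loci %in% retained
      excl <- attr(retained, "exclusions")
      qcdf$reason <- excl$reason[match(qc$loci, excl$locus)]
      utils::write.csv(qcdf, file.path(config$out_dir, "locus_qc.csv"),
                       row.names = FALSE)
      res$qc <- qc
      summary$n_loci_retained <- length(retained)
    })
  }
  res$retained_loci <- as.character(retained)

  ## ---- mating ----
  mean_m <- 1.7  # fallback prior when the mating stage is toggled off
  if ("mating" %in% config$stages && !is.null(queens)) {
    stage("mating", {
      mf <- estimate_mating_frequency(queens, profiles, freqs,
                                      reps = config$sim1_reps,
                                      seed = derive_seed(config$seed, 13L))
      mm <- run_simulation_2(queens, freqs, mf$sim1$critical_value,
                             true_range = config$sim2_true_range,
                             reps = config$sim2_reps,
                             seed = derive_seed(config$seed, 17L))
      mlf <- max_likely_frequency(mm, max(mf$per_queen$min_males,
                                          na.rm = TRUE))
      utils::write.csv(mf$per_queen,
                       file.path(config$out_dir, "queens_mating.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(mm$prob),
                       file.path(config$out_dir, "miscount_matrix.csv"))
      res$mating <- mf
      res$miscount <- mm
      mean_m <- mf$mean_mating_frequency
      summary$mean_mating_frequency <- mf$mean_mating_frequency
      summary$prop_monandrous <- mf$prop_monandrous
      summary$critical_value <- mf$sim1$critical_value
      summary$max_likely_mating_frequency <- mlf
    })
  }

  ## ---- sibship ----
  partition <- NULL
  if ("sibship" %in% config$stages) {
    stage("sibship", {
      wsel <- subset_loci(workers, res$retained_loci)
      ## first pass without mating-frequency information to estimate the
      ## sampled patriline size, then the final prior-informed pass
      p0 <- reconstruct_colonies(wsel, freqs,
                                 priors = sibship_priors(m = 1.001, n = 1),
                                 min_inclusion = config$min_inclusion,
                                 error_rate = config$error_rate,
                                 max_patrilines = config$max_patrilines)
      pri <- estimate_sibship_priors(p0, m = max(mean_m, 1))
      partition <- reconstruct_colonies(
        wsel, freqs, priors = pri,
        min_inclusion = config$min_inclusion,
        error_rate = config$error_rate,
        max_patrilines = config$max_patrilines)
      write_partition(partition, file.path(config$out_dir, "partition.csv"))
      res$priors <- pri
      res$partition <- partition
      partition <- partition
      summary$n_colonies_detected <- nrow(partition$colonies)
      summary$n_colonies_accepted <- sum(partition$colonies$accepted)
    })
  }

  ## ---- spatial + density ----
  nest <- NULL
  if ("spatial" %in% config$stages && !is.null(partition)) {
    stage("spatial", {
      nest <- colony_foraging_distances(partition, coords,
                                        min_separation = config$gps_precision)
      utils::write.csv(nest$nests, file.path(config$out_dir, "nests.csv"),
                       row.names = FALSE)
      utils::write.csv(nest$workers,
                       file.path(config$out_dir, "worker_distances.csv"),
                       row.names = FALSE)
      res$nests <- nest
      nest <- nest
      summary$mean_foraging_distance_m <- nest$mean_colony_distance
      summary$max_worker_distance_m <- nest$max_worker_distance
      sis <- tryCatch(compare_sister_distances(partition, coords),
                      error = function(e) NULL)
      if (!is.null(sis)) {
        summary$sister_distance_t <- unname(sis$statistic)
        summary$sister_distance_p <- sis$p.value
      }
      buf <- buffer_area(sqrt(config$core_area_ha * 1e4),
                         nest$mean_colony_distance %||% 0)
      summary$buffer_area_ha <- buf
      dens <- list()
      for (yr in sort(unique(partition$colonies$year))) {
        cols <- partition$colonies[partition$colonies$year == yr, ]
        ## detected colonies: accepted multi-worker colonies plus singletons
        keep <- cols$accepted | cols$n_workers == 1
        ab <- cols$n_workers[keep]
        ace <- ace_estimate(ab, rare_cutoff = config$rare_cutoff,
                            se_boot = config$se_boot,
                            seed = derive_seed(config$seed, 19L + yr))
        d <- nest_density(ace, config$core_area_ha, buf)
        dens[[as.character(yr)]] <- list(
          colonies_detected = length(ab),
          estimate = ace$estimate, se = ace$se, ci = ace$ci,
          density = d$density, completeness = ace$completeness)
      }
      res$density <- dens
      summary$density <- dens
    })
  }

  ## ---- lineage ----
  if ("lineage" %in% config$stages && !is.null(partition) &&
      length(unique(workers$year)) >= 2) {
    stage("lineage", {
      years <- sort(unique(workers$year))
      y1 <- years[1]
      y2 <- years[length(years)]
      wsel <- subset_loci(workers, res$retained_loci)
      tables <- all_locus_tables(freqs, config$error_rate)
      cols2 <- partition$colonies[partition$colonies$year == y2 &
                                    partition$colonies$accepted, ]
      iq <- lapply(cols2$colony, function(cid) {
        ids <- partition$assignments$id[partition$assignments$colony == cid]
        infer_queen_genotype(wsel[ids], freqs, config$error_rate,
                             min_confidence = config$queen_confidence,
                             tables = tables)
      })
      names(iq) <- cols2$colony
      res$inferred_queens <- iq
      w1 <- wsel[wsel$year == y1]
      part1 <- partition
      part1$assignments <- part1$assignments[part1$assignments$year == y1, ]
      n1 <- sum(partition$colonies$year == y1 &
                  (partition$colonies$accepted |
                     partition$colonies$n_workers == 1))
      if (length(iq)) {
        qt <- inferred_queens_table(iq, y2)
        matches <- match_queens_across_years(
          qt, w1, part1, freqs, threshold = config$min_inclusion,
          priors = res$priors %||% sibship_priors(),
          error_rate = config$error_rate)
        utils::write.csv(matches,
                         file.path(config$out_dir, "lineage_matches.csv"),
                         row.names = FALSE)
        res$lineage_matches <- matches
        summary$n_lineage_matches <-
          sum(!is.na(matches$matched_colony))
        summary$lineage_survival_rate <-
          lineage_survival_rate(matches, n1)
      }
    })
  }

  ## ---- ibd ----
  if ("ibd" %in% config$stages && !is.null(res$partition) &&
      !is.null(nest)) {
    stage("ibd", {
      wsel <- subset_loci(workers, res$retained_loci)
      tables <- all_locus_tables(freqs, config$error_rate)
      acc <- partition$colonies[partition$colonies$accepted, ]
      acc <- acc[acc$colony %in% nest$nests$colony, ]
      if (nrow(acc) >= 3) {
        iq <- lapply(acc$colony, function(cid) {
          ids <- partition$assignments$id[partition$assignments$colony == cid]
          infer_queen_genotype(wsel[ids], freqs, config$error_rate,
                               min_confidence = config$queen_confidence,
                               tables = tables)
        })
        names(iq) <- acc$colony
        qt <- inferred_queens_table(iq, acc$year[1])
        rel <- pairwise_relatedness(qt, freqs)
        nests <- nest$nests[match(acc$colony, nest$nests$colony), ]
        tbl <- relatedness_distance_table(rel, nests)
        utils::write.csv(tbl, file.path(config$out_dir, "relatedness.csv"),
                         row.names = FALSE)
        fit <- ibd_regression(tbl)
        res$ibd <- fit
        summary$ibd <- list(slope = fit$slope, F = fit$F,
                            df = fit$df, p.value = fit$p.value,
                            r.squared = fit$r.squared,
                            n_pairs = fit$n_pairs,
                            n_excluded_pairs = sum(tbl$excluded))
      }
    })
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  res$summary <- summary
  class(res) <- "pipeline_result"
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (outputs in", x$config$out_dir, ")\n")
  s <- x$summary
  if (!is.null(s$mean_mating_frequency)) {
    cat(sprintf("  mean minimum mating frequency: %.2f (%.0f%% monandrous)\n",
                s$mean_mating_frequency, 100 * s$prop_monandrous))
  }
  if (!is.null(s$mean_foraging_distance_m)) {
    cat(sprintf("  mean colony-specific foraging distance: %.1f m\n",
                s$mean_foraging_distance_m))
  }
  for (yr in names(s$density)) {
    cat(sprintf("  %s: %.2f colonies/ha (completeness %.2f)\n", yr,
                s$density[[yr]]$density, s$density[[yr]]$completeness))
  }
  if (!is.null(s$lineage_survival_rate)) {
    cat(sprintf("  lineage survival rate: %.3f\n", s$lineage_survival_rate))
  }
  if (!is.null(s$ibd)) {
    cat(sprintf("  IBD: slope %.3g, p = %.3f\n", s$ibd$slope, s$ibd$p.value))
  }
  invisible(x)
}
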