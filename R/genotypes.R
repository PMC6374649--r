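#' Multilocus genotype table
#'
#' The atom of every analysis stage: one row per diploid individual, two
#' integer allele calls (microsatellite fragment sizes) per locus. A
#' locus-level call is missing as a unit: either both alleles are recorded
#' or both are `NA`. Allele pairs are unordered and stored sorted
#' (`a1 <= a2`).
#'
#' @param id Character vector of individual identifiers (unique).
#' @param year Integer vector of sampling years (recycled if length 1).
#' @param a1,a2 Integer matrices (individuals x loci) of allele calls;
#'   `NA` marks a missing locus-level call. Column names give locus names
#'   when `loci` is not supplied.
#' @param loci Character vector of locus names.
#' @return An object of class `genotype_table`.
#' @examples
#' gt <- genotype_table(
#'   id = c("w1", "w2"), year = 2014,
#'   a1 = matrix(c(100, 100, 120, 124), 2, 2),
#'   a2 = matrix(c(104, 100, 124, 124), 2, 2),
#'   loci = c("L1", "L2")
#' )
#' gt
#' @export
genotype_table <- function(id, year, a1, a2, loci = colnames(a1)) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  stopifnot(
    nrow(a1) == length(id), identical(dim(a1), dim(a2)),
    ncol(a1) == length(loci), !anyDuplicated(id), !anyDuplicated(loci)
  )
  if (any(is.na(a1) != is.na(a2))) {
    stop("partial locus calls are not allowed: a locus call is missing as a unit")
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(id, loci)
  structure(
    list(id = as.character(id), year = rep_len(as.integer(year), length(id)),
         a1 = a1, a2 = a2, loci = as.character(loci)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d individuals x %d loci (years: %s)\n",
    nrow(x$a1), length(x$loci), paste(sort(unique(x$year)), collapse = ", ")
  ))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing locus-level calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
`[.genotype_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  genotype_table(x$id[i], x$year[i],
                 x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE], x$loci)
}

#' Number of individuals in a genotype table
#' @param x A `genotype_table`.
#' @return Integer count.
#' @export
n_individuals <- function(x) length(x$id)

#' Restrict a genotype table to a set of loci
#' @param x A `genotype_table`.
#' @param loci Character vector of locus names to keep.
#' @return A `genotype_table` with only those loci.
#' @export
subset_loci <- function(x, loci) {
  j <- match(loci, x$loci)
  if (anyNA(j)) stop("unknown loci: ", paste(loci[is.na(j)], collapse = ", "))
  genotype_table(x$id, x$year, x$a1[, j, drop = FALSE],
                 x$a2[, j, drop = FALSE], x$loci[j])
}

#' Estimate population allele frequencies
#'
#' Counts observed alleles per locus over all non-missing diploid calls and
#' normalizes; missing calls are excluded from the denominator. A locus with
#' zero non-missing calls is flagged in the `absent` attribute rather than
#' silently given zero frequencies.
#'
#' @param gt A [genotype_table()].
#' @return An object of class `allele_freqs`: a named list, one element per
#'   locus, each a named numeric vector of frequencies summing to 1. The
#'   attribute `absent` lists loci with no usable calls.
#' @examples
#' gt <- genotype_table("w1", 2014, matrix(100), matrix(104), "L1")
#' estimate_allele_frequencies(gt)
#' @export
estimate_allele_frequencies <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  freqs <- vector("list", length(gt$loci))
  names(freqs) <- gt$loci
  absent <- character(0)
  for (l in seq_along(gt$loci)) {
    alleles <- c(gt$a1[, l], gt$a2[, l])
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0) {
      absent <- c(absent, gt$loci[l])
      freqs[[l]] <- numeric(0)
      next
    }
    tab <- table(alleles)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    freqs[[l]] <- f
  }
  structure(freqs, absent = absent, class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  k <- vapply(x, length, integer(1))
  cat(sprintf("allele_freqs: %d loci, %d-%d alleles per locus\n",
              length(x), min(k), max(k)))
  if (length(attr(x, "absent"))) {
    cat("  absent loci:", paste(attr(x, "absent"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a genotype table from CSV
#'
#' Expects a GenAlEx-like layout: columns `id`, `year`, then two columns per
#' locus named `<locus>.1` and `<locus>.2` holding integer allele sizes with
#' `0` meaning a missing call. A cell containing more than one allele size
#' (separated by `;` or `/`) marks an individual with more than two alleles
#' at a locus, e.g. a triploid or contaminated sample; such records are
#' rejected and reported via the `rejected` attribute.
#'
#' @param path Path to the CSV file.
#' @return A [genotype_table()]; rejected individual ids (if any) are in
#'   `attr(, "rejected")`.
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  stopifnot(all(c("id", "year") %in% names(df)))
  acols <- setdiff(names(df), c("id", "year"))
  if (length(acols) %% 2 != 0 ||
      !all(grepl("\\.[12]$", acols))) {
    stop("expected paired locus columns named <locus>.1 and <locus>.2")
  }
  loci <- unique(sub("\\.[12]$", "", acols))
  multi <- function(v) grepl("[;/]", v)
  bad <- rep(FALSE, nrow(df))
  for (cc in acols) bad <- bad | multi(df[[cc]])
  rejected <- df$id[bad]
  if (length(rejected)) {
    message(length(rejected),
            " record(s) rejected (>2 alleles at one or more loci): ",
            paste(rejected, collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  n <- nrow(df)
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(df$id, loci))
  a2 <- a1
  for (l in loci) {
    v1 <- as.integer(df[[paste0(l, ".1")]])
    v2 <- as.integer(df[[paste0(l, ".2")]])
    v1[v1 == 0L] <- NA_integer_
    v2[v2 == 0L] <- NA_integer_
    miss <- is.na(v1) | is.na(v2)
    v1[miss] <- NA_integer_
    v2[miss] <- NA_integer_
    a1[, l] <- v1
    a2[, l] <- v2
  }
  out <- genotype_table(df$id, as.integer(df$year), a1, a2, loci)
  attr(out, "rejected") <- rejected
  out
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_table()]: missing calls are written as `0`.
#'
#' @param gt A [genotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  df <- data.frame(id = gt$id, year = gt$year, check.names = FALSE)
  for (l in seq_along(gt$loci)) {
    v1 <- gt$a1[, l]
    v2 <- gt$a2[, l]
    v1[is.na(v1)] <- 0L
    v2[is.na(v2)] <- 0L
    df[[paste0(gt$loci[l], ".1")]] <- v1
    df[[paste0(gt$loci[l], ".2")]] <- v2
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write planar sampling coordinates
#'
#' Coordinates are Cartesian meters with the origin at the arena corner,
#' one row per individual: `id, x_m, y_m, year`.
#'
#' @param path CSV path.
#' @return A data frame with columns `id`, `x_m`, `y_m`, `year`.
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("id", "x_m", "y_m", "year") %in% names(df)))
  df$id <- as.character(df$id)
  df
}

#' @rdname read_coordinates
#' @param coords Data frame as returned by [read_coordinates()].
#' @export
write_coordinates <- function(coords, path) {
  utils::write.csv(coords[, c("id", "x_m", "y_m", "year")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
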