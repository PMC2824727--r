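## BAC library characterisation statistics.

#' Theoretical fold coverage of a clone library
#'
#' `n_clones * mean_insert / genome_size`, the expected number of clones
#' overlapping a random genomic position.
#'
#' @param n_clones number of recombinant clones.
#' @param mean_insert mean insert size (bp).
#' @param genome_size haploid genome size (bp).
#' @return Fold coverage (unrounded).
#' @examples
#' fold_coverage(194267, 139000, 2.8e9)  # ~9.6x
#' @export
fold_coverage <- function(n_clones, mean_insert, genome_size) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  if (n_clones < 0 || mean_insert < 0) stop("inputs must be non-negative")
  n_clones * mean_insert / genome_size
}

#' Probability that a locus is recovered from the library
#'
#' Clarke-Carbon complement `1 - exp(-c)` for coverage `c`: under a Poisson
#' model of clone starts, the chance that at least one clone overlaps a
#' given locus.
#'
#' @param coverage fold coverage, >= 0.
#' @return probability in `[0, 1)`.
#' @export
prob_locus_recovered <- function(coverage) {
  if (any(coverage < 0)) stop("coverage must be >= 0")
  1 - exp(-coverage)
}

#' Observed screening depth
#'
#' Mean number of clones hybridising per probe, after removing excluded
#' clones (e.g. clones falling in contigs not anchored to the targeted
#' locus, i.e. false-positive hybridisation).
#'
#' @param screening data.frame (probe_id, clone_id); `probe_id` should be a
#'   factor over all screened probes so that zero-hit probes count.
#' @param excluded_clone_ids clone ids to drop before averaging.
#' @return Mean hit count per probe.
#' @export
observed_depth <- function(screening, excluded_clone_ids = character(0)) {
  if (is.null(screening) || !all(c("probe_id", "clone_id") %in% names(screening)))
    stop("screening table must have probe_id and clone_id columns")
  probes <- if (is.factor(screening$probe_id)) levels(screening$probe_id)
            else unique(screening$probe_id)
  if (length(probes) == 0L) stop("screening table lists no probes")
  kept <- screening[!(screening$clone_id %in% excluded_clone_ids), ]
  nrow(kept) / length(probes)
}

#' GC fraction of sequences
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases (N) are excluded from the
#' denominator.  Computed over the sequence as given (no internal
#' trimming).
#'
#' @param x FASTA path, `Biostrings::DNAStringSet`, or character vector of
#'   sequences.
#' @return GC fraction.
#' @export
gc_fraction <- function(x) {
  dss <- if (inherits(x, "DNAStringSet")) x
         else if (is.character(x) && length(x) == 1L && file.exists(x))
           Biostrings::readDNAStringSet(x)
         else Biostrings::DNAStringSet(x)
  f <- colSums(Biostrings::letterFrequency(dss, c("A", "C", "G", "T")))
  tot <- sum(f)
  if (tot == 0) stop("no countable A/C/G/T bases")
  unname((f[["G"]] + f[["C"]]) / tot)
}

#' Chromosome-distribution uniformity test
#'
#' Pearson chi-square test of observed per-chromosome counts against
#' expectations proportional to chromosome size.  For a library made from a
#' male, the X and Y chromosomes are present in one copy against two for
#' the autosomes, so their expected weights are halved
#' (`sex_mode = "male"`); `"female"` drops the Y weight to zero (the test
#' then requires the Y category to be absent or merged); `"none"` uses raw
#' sizes.
#'
#' @param observed named vector of counts per chromosome.
#' @param chrom_sizes named vector of chromosome sizes (bp), same
#'   categories.
#' @param sex_mode one of "male", "female", "none".
#' @return list of class `chrom_dist_test`: categories, observed, expected,
#'   chi2, df, p_value.
#' @export
chrom_uniformity_test <- function(observed, chrom_sizes, sex_mode = c("male", "female", "none")) {
  sex_mode <- match.arg(sex_mode)
  if (is.null(names(observed)) || is.null(names(chrom_sizes)))
    stop("observed and chrom_sizes must be named by chromosome")
  if (!setequal(names(observed), names(chrom_sizes)))
    stop("observed and chrom_sizes categories differ")
  chrom_sizes <- chrom_sizes[names(observed)]
  w <- as.numeric(chrom_sizes)
  sexchr <- toupper(sub("^CHR", "", toupper(names(observed))))
  if (sex_mode == "male") {
    w[sexchr %in% c("X", "Y")] <- w[sexchr %in% c("X", "Y")] / 2
  } else if (sex_mode == "female") {
    w[sexchr == "Y"] <- 0
  }
  expected <- setNames(w / sum(w) * sum(observed), names(observed))
  if (any(expected == 0))
    stop("expected count of zero for category '",
         names(observed)[which(expected == 0)[1]],
         "'; merge or drop the category")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(categories = names(observed),
                 observed = as.numeric(observed), expected = expected,
                 sex_mode = sex_mode, chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE)),
            class = "chrom_dist_test")
}

#' @export
print.chrom_dist_test <- function(x, ...) {
  cat(sprintf("Chromosome-distribution chi-square: X2 = %.3g, df = %d, p = %.3g (sex_mode = %s)\n",
              x$chi2, x$df, x$p_value, x$sex_mode))
  invisible(x)
}

#' Library summary statistics
#'
#' @param n_clones,mean_insert,genome_size as in [fold_coverage()].
#' @return list of class `library_stats` with the inputs, fold coverage and
#'   locus-recovery probability.
#' @export
library_stats <- function(n_clones, mean_insert, genome_size) {
  if (any(c(n_clones, mean_insert, genome_size) <= 0))
    stop("all inputs must be > 0")
  cov <- fold_coverage(n_clones, mean_insert, genome_size)
  structure(list(n_clones = n_clones, mean_insert = mean_insert,
                 genome_size = genome_size, fold_coverage = cov,
                 p_locus_recovered = prob_locus_recovered(cov)),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("BAC library: %d clones x %.0f bp inserts / %.3g bp genome = %.2fx coverage\n",
              x$n_clones, x$mean_insert, x$genome_size, x$fold_coverage))
  cat(sprintf("P(locus recovered) = %.4f\n", x$p_locus_recovered))
  invisible(x)
}
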