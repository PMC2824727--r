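## Shared fixtures: all synthetic, built in code at test time.

g <- function(...) signed_genome(list(...))

small_config <- function(...) {
  defaults <- list(n_chromosomes = 3L, chrom_lengths = c(120e6, 90e6, 60e6),
                   n_clones = 100L, seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

## random instance set used by the oracle-equivalence and scenario tests:
## genome pairs with <= `max_n` segments on <= 3 chromosomes
random_instances <- function(n_pairs, max_n = 7L, seed = 20260909L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n_pairs), function(i) {
    n <- sample(2:max_n, 1L)
    list(a = random_signed_genome(n, max_chrom = 3L),
         b = random_signed_genome(n, max_chrom = 3L))
  })
}

## deterministic tiny marker table: two query chromosomes, one inversion
toy_marker_table <- function() {
  data.frame(
    clone_id = sprintf("MK%02d", 1:7),
    query_chrom = c("V1", "V1", "V1", "V1", "V2", "V2", "V2"),
    query_rank = c(1L, 2L, 3L, 4L, 1L, 2L, 3L),
    target_chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2", "chr3"),
    target_pos = c(10e6, 50e6, 30e6, 20e6, 60e6, 80e6, 15e6),
    stringsAsFactors = FALSE)
}

locus <- function(chrom, start, end, strand) {
  data.frame(target_chrom = chrom, start = start, end_pos = end,
             strand = strand, stringsAsFactors = FALSE)
}
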