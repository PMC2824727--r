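## The synthetic-data generator.

test_that("config validation enforces the invariants", {
  expect_error(sim_config(insert_min = 150000, insert_mean = 120000), "insert_min")
  expect_error(sim_config(gc = 1.2), "fractions")
  expect_error(sim_config(chrom_lengths = -1), "> 0")
  expect_error(sim_config(event_weights = c(1, 1)), "weights")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("ancestor grid construction is deterministic and sized correctly", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_lengths = 90e6,
                    marker_spacing = 30e6, seed = 3L)
  anc <- make_ancestor(cfg)
  expect_identical(nrow(anc$markers), 3L)
  expect_true(all(diff(anc$markers$pos) > 0))
  expect_true(all(anc$markers$pos < 90e6))
  ## n_markers = 0: empty genome, no error
  anc0 <- make_ancestor(sim_config(n_markers = 0L))
  expect_identical(nrow(anc0$markers), 0L)
  ## fixed seed -> identical genomes
  expect_identical(make_ancestor(cfg), make_ancestor(cfg))
  ## sizing error
  expect_error(make_ancestor(sim_config(n_chromosomes = 1L, chrom_lengths = 1e4,
                                        n_markers = 1000L)),
               "incompatible")
})

test_that("event application preserves markers and replays exactly", {
  cfg <- small_config()
  anc <- make_ancestor(cfg)
  ## identity
  ae0 <- apply_events(anc, k = 0L)
  expect_identical(derived_markers(ae0$derived, anc)$marker_id, anc$markers$marker_id)
  ## inversion of the middle marker reverses order and flips sign
  mk <- anc$markers[anc$markers$chrom == 1L, ]
  mid <- round((mk$pos[1:2] + mk$pos[2:3]) / 2)
  ev <- list(list(kind = "inversion", chrom = 1L, bp1 = mid[1], bp2 = mid[2]))
  inv <- apply_events(anc, events = ev)$derived
  dm <- derived_markers(inv, anc)
  dm1 <- dm[dm$chrom == 1L, ]
  expect_identical(dm1$sign[dm1$marker_id == mk$marker_id[2]], -1L)
  expect_identical(sort(dm$marker_id), sort(anc$markers$marker_id))
  ## fusion decreases chromosome count by one and concatenates marker content
  fu <- apply_events(anc, events = list(list(kind = "fusion", chrom1 = 1L,
                                             chrom2 = 2L, variant = 1L)))$derived
  expect_identical(length(fu$segments), length(anc$chrom_lengths) - 1L)
  ## fission increases it by one
  fs <- apply_events(anc, events = list(list(kind = "fission", chrom = 1L,
                                             bp = mid[1])))$derived
  expect_identical(length(fs$segments), length(anc$chrom_lengths) + 1L)
  ## random histories: marker multiset invariant + exact replay, several seeds
  for (s in 1:4) {
    ae <- apply_events(anc, k = 5L, seed = s)
    expect_identical(sort(derived_markers(ae$derived, anc)$marker_id),
                     sort(anc$markers$marker_id))
    expect_identical(replay_events(anc, ae$log)$segments, ae$derived$segments)
  }
})

test_that("illegal events are resampled or rejected", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_lengths = 60e6,
                    marker_spacing = 40e6, seed = 1L)  # one marker: no gaps
  anc <- make_ancestor(cfg)
  expect_error(apply_events(anc, k = 1L, seed = 1L, weights = c(0, 0, 0, 1)),
               "no legal event")
})

test_that("clone sampling matches the configured insert law", {
  cfg <- small_config(n_clones = 10000L)
  der <- apply_events(make_ancestor(cfg), k = 0L)$derived
  cl <- sample_clones(der, cfg)
  expect_true(all(cl$insert >= cfg$insert_min & cl$insert <= cfg$insert_max))
  ## truncated-normal mean check: empirical mean within 2 SE of 139 kb
  se <- sd(cl$insert) / sqrt(nrow(cl))
  expect_lt(abs(mean(cl$insert) - cfg$insert_mean), 2 * se + 1) # +1 bp rounding
  ## degenerate law
  cfgd <- small_config(insert_min = 150000, insert_mean = 150000,
                       insert_max = 150000, n_clones = 50L)
  cld <- sample_clones(der, cfgd)
  expect_true(all(cld$insert == 150000))
  ## truth bookkeeping: no events -> nothing straddles
  expect_false(any(cl$spans_breakpoint))
})

test_that("alignments obey the noise-free geometry", {
  cfg <- small_config(p_unmapped = 0, p_multimap = 0, n_clones = 60L)
  anc <- make_ancestor(cfg)
  der <- apply_events(anc, k = 0L)$derived
  cl <- sample_clones(der, cfg)
  al <- emit_alignments(cl, der, anc, cfg)$alignments
  expect_identical(nrow(al), 2L * nrow(cl))
  parsed <- parse_blast_tab(write_blast_tab(al, tempfile()))
  by_clone <- split(parsed, parsed$clone_id)
  for (cc in by_clone) {
    expect_identical(nrow(cc), 2L)
    expect_setequal(cc$strand, c("+", "-"))
    expect_identical(unique(cc$target_chrom), cc$target_chrom[1])
    span <- max(cc$end_pos) - min(cc$start)
    expect_identical(span, cl$insert[cl$clone_id == cc$clone_id[1]])
  }
})

test_that("multi-mapping and unmapped noise are emitted as configured", {
  cfg <- small_config(p_unmapped = 0, p_multimap = 1, n_clones = 30L)
  anc <- make_ancestor(cfg)
  der <- apply_events(anc, k = 0L)$derived
  cl <- sample_clones(der, cfg)
  al <- emit_alignments(cl, der, anc, cfg)$alignments
  hits <- table(al$qseqid)
  expect_true(all(hits >= 2L))             # every end has >= 2 candidate loci
  cfg2 <- small_config(p_unmapped = 1, n_clones = 10L)
  al2 <- emit_alignments(sample_clones(der, cfg2), der, anc, cfg2)
  expect_null(al2$alignments)
  expect_true(all(al2$truth$dropped))
})

test_that("clones straddling a translocation junction map to two chromosomes", {
  ## replay the event log to locate the junctions, pick clones whose ends
  ## flank one junction (both end reads clear of it), check emitted chroms
  cfg <- small_config(p_unmapped = 0, p_multimap = 0, n_clones = 4000L, seed = 5L)
  anc <- make_ancestor(cfg)
  ae <- apply_events(anc, k = 1L, seed = 9L, weights = c(0, 1, 0, 0))
  junc <- derived_junctions(replay_events(anc, ae$log))
  cl <- sample_clones(ae$derived, cfg)
  straddle <- cl[cl$spans_breakpoint, ]
  expect_gt(nrow(straddle), 0L)
  al <- emit_alignments(cl, ae$derived, anc, cfg)$alignments
  checked <- 0L
  for (i in seq_len(nrow(straddle))) {
    jj <- junc[junc$chrom == straddle$chrom[i], ]
    if (!any(jj$pos > straddle$start[i] + 2000 & jj$pos < straddle$end[i] - 2000)) next
    cc <- al[startsWith(al$qseqid, paste0(straddle$clone_id[i], "_")), ]
    expect_identical(length(unique(cc$sseqid)), 2L)
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("FASTA emitter matches GC, length and naming contracts", {
  ## package defaults, 1000 reads (500 clones)
  cfg <- sim_config(n_clones = 500L)
  der <- apply_events(make_ancestor(cfg), k = 0L)$derived
  cl <- sample_clones(der, cfg)
  fa <- emit_bes_fasta(cl, cfg)
  expect_identical(length(fa), 2L * nrow(cl))
  expect_setequal(sub("^CL[0-9]+_", "", names(fa)), c("T7", "SP6"))
  ## pooled GC within 2 binomial SE of 0.418
  nbase <- sum(Biostrings::width(fa))
  se <- sqrt(cfg$gc * (1 - cfg$gc) / nbase)
  expect_lt(abs(gc_fraction(fa) - cfg$gc), 2 * se)
  ## read length mean within 2 SE of 728
  w <- Biostrings::width(fa)
  expect_lt(abs(mean(w) - cfg$read_len_mean), 2 * sd(w) / sqrt(length(w)) + 1)
  ## boundary GC
  cfg1 <- small_config(gc = 1, n_clones = 5L)
  fa1 <- emit_bes_fasta(sample_clones(der, cfg1), cfg1)
  expect_identical(gc_fraction(fa1), 1)
  ## 60-column wrapping on disk and byte-identical reruns
  p1 <- tempfile(fileext = ".fa"); p2 <- tempfile(fileext = ".fa")
  emit_bes_fasta(cl, cfg, p1); emit_bes_fasta(cl, cfg, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_lte(max(nchar(readLines(p1))), 60L)
})

test_that("screening counts are Poisson with the configured depth", {
  expect_error(simulate_screening(10, -1), ">= 0")
  s0 <- simulate_screening(10, 0)
  expect_identical(nrow(s0), 0L)
  expect_identical(nlevels(s0$probe_id), 10L)
  ## variance ~ mean at large n
  s <- simulate_screening(4000, 7, seed = 2L)
  counts <- as.vector(table(s$probe_id))
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.1)
})

test_that("marker table reflects colinearity and rearrangement", {
  cfg <- small_config()
  anc <- make_ancestor(cfg)
  ## no events: colinear per chromosome
  mt0 <- emit_marker_table(apply_events(anc, k = 0L)$derived, anc, cfg)
  for (qc in unique(mt0$query_chrom)) {
    m <- mt0[mt0$query_chrom == qc, ]
    expect_identical(length(unique(m$target_chrom)), 1L)
    expect_true(all(diff(m$target_pos) > 0))
  }
  ## one inversion of >= 2 markers: non-monotone target positions
  mk <- anc$markers[anc$markers$chrom == 1L, ]
  gaps <- round((utils::head(mk$pos, -1) + mk$pos[-1]) / 2)
  inv <- apply_events(anc, events = list(list(kind = "inversion", chrom = 1L,
                                              bp1 = gaps[1], bp2 = gaps[3])))$derived
  mt1 <- emit_marker_table(inv, anc, small_config(marker_spacing = 1e6))
  m1 <- mt1[mt1$query_chrom == "V1", ]
  expect_false(all(diff(m1$target_pos) > 0) || all(diff(m1$target_pos) < 0))
  ## spacing larger than the chromosome still emits one marker per chromosome
  cfg_wide <- small_config(marker_spacing = 1e9)
  mtw <- emit_marker_table(apply_events(anc, k = 0L)$derived, anc, cfg_wide)
  expect_identical(sort(unique(mtw$query_chrom)), c("V1", "V2", "V3"))
  expect_identical(as.integer(table(mtw$query_chrom)), rep(1L, 3))
})

test_that("emitters are byte-identical across runs with one seed", {
  cfg <- small_config(n_clones = 40L, n_events = 2L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$markers, s2$markers)
  expect_identical(s1$screening, s2$screening)
})
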