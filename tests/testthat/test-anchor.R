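## Mate-pair anchoring and concordance classification.

test_that("blast tabular parsing converts conventions and reports errors", {
  tf <- tempfile()
  writeLines(c(
    "CL1_T7\tchr1\t98.5\t100\t1\t0\t1\t100\t101\t200\t1e-50\t180",
    "CL1_SP6\tchr1\t98.5\t100\t1\t0\t1\t100\t200\t101\t1e-50\t180"), tf)
  al <- parse_blast_tab(tf)
  expect_identical(al$start, c(100, 100))
  expect_identical(al$end_pos, c(200, 200))
  expect_identical(al$strand, c("+", "-"))
  expect_identical(al$clone_id, c("CL1", "CL1"))
  expect_identical(al$end, c("T7", "SP6"))
  ## empty file: empty list, not an error
  empty <- tempfile(); file.create(empty)
  expect_identical(nrow(parse_blast_tab(empty)), 0L)
  ## malformed rows are named by line
  bad <- tempfile()
  writeLines(c("CL1_T7\tchr1\t98.5\t100\t1\t0\t1\t100\t101\t200\t1e-50\t180",
               "CL2_T7\tchr1\t98.5\t100\t1\t0\t1\t100\t101\t200\tnot_a_number\t180"), bad)
  expect_error(parse_blast_tab(bad), "line\\(s\\) 2")
  badid <- tempfile()
  writeLines("CL1-T7\tchr1\t98.5\t100\t1\t0\t1\t100\t101\t200\t1e-50\t180", badid)
  expect_error(parse_blast_tab(badid), "T7\\|SP6")
})

test_that("mappability classes follow hit counts", {
  empty <- empty_hits <- parse_blast_tab({f <- tempfile(); file.create(f); f})
  expect_identical(classify_mappability(empty)$status, "unmapped")
  one <- data.frame(read_id = "C_T7", target_chrom = "chr1", start = 0,
                    end_pos = 700, strand = "+", stringsAsFactors = FALSE)
  expect_identical(classify_mappability(one)$status, "unique")
  two <- rbind(one, one)
  m <- classify_mappability(two)
  expect_identical(m$status, "multi")
  expect_identical(m$n_candidates, 2L)
})

test_that("mate rescue selects the unique concordance-compatible candidate", {
  t <- thresholds()
  mate <- locus("chr1", 0, 700, "+")
  cands <- rbind(locus("chr1", 149300, 150000, "-"),   # facing, span 150 kb
                 locus("chr5", 149300, 150000, "-"))
  anchor <- structure(list(read_id = "C_SP6", status = "multi", locus = NULL,
                           candidates = cands, n_candidates = 2L),
                      class = "read_anchor")
  resc <- rescue_multi(anchor, mate, t)
  expect_identical(resc$status, "rescued")
  expect_identical(resc$locus$target_chrom, "chr1")
  ## both candidates compatible: stays multi (ambiguous)
  both <- rbind(locus("chr1", 149300, 150000, "-"),
                locus("chr1", 119300, 120000, "-"))
  expect_identical(rescue_multi(structure(list(read_id = "C_SP6", status = "multi",
                                               locus = NULL, candidates = both,
                                               n_candidates = 2L),
                                          class = "read_anchor"), mate, t)$status,
                   "multi")
  ## none within the window: stays multi
  far <- rbind(locus("chr1", 9e6, 9.0007e6, "-"), locus("chr5", 0, 700, "-"))
  expect_identical(rescue_multi(structure(list(read_id = "C_SP6", status = "multi",
                                               locus = NULL, candidates = far,
                                               n_candidates = 2L),
                                          class = "read_anchor"), mate, t)$status,
                   "multi")
  ## never touches a unique read
  uniq <- structure(list(read_id = "C_T7", status = "unique",
                         locus = mate, candidates = mate, n_candidates = 1L),
                    class = "read_anchor")
  expect_identical(rescue_multi(uniq, mate, t), uniq)
})

test_that("pair classification implements the concordance rules", {
  t <- thresholds()
  cls <- function(a, b) classify_pair(a, b, t)$klass
  ## same chrom, facing, span 150 kb
  expect_identical(cls(locus("chr1", 0, 700, "+"), locus("chr1", 149300, 150000, "-")),
                   "concordant")
  ## same strands: inversion-type
  expect_identical(cls(locus("chr1", 0, 700, "+"), locus("chr1", 149300, 150000, "+")),
                   "discordant_inversion")
  ## opposite strands facing outward: orientation violation
  expect_identical(cls(locus("chr1", 0, 700, "-"), locus("chr1", 149300, 150000, "+")),
                   "discordant_inversion")
  ## span 250 kb: assignable indel
  expect_identical(cls(locus("chr1", 0, 700, "+"), locus("chr1", 249300, 250000, "-")),
                   "discordant_indel_assignable")
  ## span 45 kb (too short): also assignable indel
  expect_identical(cls(locus("chr1", 0, 700, "+"), locus("chr1", 44300, 45000, "-")),
                   "discordant_indel_assignable")
  ## span 2.5 Mb: large or complex
  expect_identical(cls(locus("chr1", 0, 700, "+"), locus("chr1", 2499300, 2500000, "-")),
                   "discordant_large_or_complex")
  ## different chromosomes
  expect_identical(cls(locus("chr1", 0, 700, "+"), locus("chr2", 149300, 150000, "-")),
                   "discordant_translocation")
  ## closed window boundaries
  expect_identical(cls(locus("chr1", 0, 700, "+"), locus("chr1", 89300, 90000, "-")),
                   "concordant")
  expect_identical(cls(locus("chr1", 0, 700, "+"), locus("chr1", 199300, 200000, "-")),
                   "concordant")
  ## symmetry: class invariant under swapping the ends
  pairs <- list(
    list(locus("chr1", 0, 700, "+"), locus("chr1", 149300, 150000, "-")),
    list(locus("chr1", 0, 700, "+"), locus("chr1", 249300, 250000, "-")),
    list(locus("chr1", 0, 700, "-"), locus("chr3", 0, 700, "-")),
    list(locus("chr1", 0, 700, "+"), locus("chr1", 2499300, 2500000, "-")))
  for (p in pairs)
    expect_identical(classify_pair(p[[1]], p[[2]], t)$klass,
                     classify_pair(p[[2]], p[[1]], t)$klass)
  ## assigned interval for concordant/indel classes only
  cc <- classify_pair(locus("chr1", 0, 700, "+"), locus("chr1", 149300, 150000, "-"), t)
  expect_identical(cc$assigned_interval$start, 0)
  expect_identical(cc$assigned_interval$end_pos, 150000)
  tt <- classify_pair(locus("chr1", 0, 700, "+"), locus("chr2", 0, 700, "-"), t)
  expect_null(tt$assigned_interval)
  expect_error(classify_pair(NULL, locus("chr1", 0, 700, "+"), t), "resolved")
})

test_that("clone calls compose the rules", {
  t <- thresholds()
  uniq <- function(l) structure(list(read_id = "x", status = "unique", locus = l,
                                     candidates = l, n_candidates = 1L),
                                class = "read_anchor")
  unmapped <- structure(list(read_id = "y", status = "unmapped", locus = NULL,
                             candidates = NULL, n_candidates = 0L),
                        class = "read_anchor")
  one <- anchor_clone(list(uniq(locus("chr1", 0, 700, "+")), unmapped), t, "C1")
  expect_identical(one$klass, "single_end")
  expect_identical(one$assigned_interval$target_chrom, "chr1")
  expect_identical(anchor_clone(list(unmapped, unmapped), t, "C2")$klass, "no_anchor")
  both <- anchor_clone(list(uniq(locus("chr1", 0, 700, "+")),
                            uniq(locus("chr1", 138300, 139000, "-"))), t, "C3")
  expect_identical(both$klass, "concordant")
  expect_error(anchor_clone(list(unmapped, unmapped, unmapped), t, "C4"),
               "more than two")
})

test_that("summaries count classes in fixed order", {
  df <- data.frame(clone_id = sprintf("C%d", 1:4),
                   klass = c("concordant", "concordant", "concordant",
                             "discordant_translocation"),
                   stringsAsFactors = FALSE)
  s <- summarize_anchors(df)
  expect_identical(names(s)[1:7], bacmapr:::CLONE_CLASSES)
  expect_identical(s$concordant, 3L)
  expect_identical(s$discordant_translocation, 1L)
  expect_identical(s$anchored_both, 4L)
  s0 <- summarize_anchors(df[0, ])
  expect_true(all(unlist(s0) == 0L))
})

test_that("noise-free zero-event simulation anchors every clone concordant", {
  cfg <- small_config(p_unmapped = 0, p_multimap = 0, n_clones = 150L)
  anc <- make_ancestor(cfg)
  der <- apply_events(anc, k = 0L)$derived
  cl <- sample_clones(der, cfg)
  al <- emit_alignments(cl, der, anc, cfg)$alignments
  calls <- anchor_clones(bacmapr:::normalize_alignments(al))
  expect_identical(summarize_anchors(calls)$concordant, nrow(cl))
})

test_that("rescue recovers decoy-laden ends end-to-end", {
  cfg <- small_config(p_unmapped = 0, p_multimap = 0.6, n_clones = 200L, seed = 17L)
  anc <- make_ancestor(cfg)
  der <- apply_events(anc, k = 0L)$derived
  cl <- sample_clones(der, cfg)
  em <- emit_alignments(cl, der, anc, cfg)
  calls <- anchor_clones(bacmapr:::normalize_alignments(em$alignments))
  ## rescue needs a uniquely mapped mate: restrict to clones where at least
  ## one end drew no decoy, and expect (near-)complete concordance there --
  ## a decoy can only defeat rescue by landing concordant-compatible itself
  n_unique_ends <- tapply(em$truth$n_loci == 1L, em$truth$clone_id, sum)
  rescuable <- names(n_unique_ends)[n_unique_ends >= 1L]
  got <- calls$klass[calls$clone_id %in% rescuable]
  expect_gt(mean(got == "concordant"), 0.98)
  ## and rescue genuinely fired: some rescuable clones had a multi end
  expect_gt(sum(n_unique_ends == 1L), 0L)
})
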