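## Comparative map construction.

test_that("marker table loading validates and orders", {
  mt <- load_marker_table(toy_marker_table())
  expect_identical(nrow(mt), 7L)
  expect_true(all(diff(mt$query_rank[mt$query_chrom == "V1"]) >= 0))
  ## duplicate clone ids rejected by name
  dup <- toy_marker_table(); dup$clone_id[2] <- "MK01"
  expect_error(load_marker_table(dup), "MK01")
  ## missing column named
  expect_error(load_marker_table(toy_marker_table()[, -3]), "query_rank")
  ## tied ranks accepted, ordered by target position (deterministic tie rule)
  tied <- toy_marker_table()
  tied$query_rank <- c(1L, 1L, 2L, 3L, 1L, 2L, 3L)
  tied$target_pos[1:2] <- c(50e6, 10e6)
  lt <- load_marker_table(tied)
  v1 <- lt[lt$query_chrom == "V1", ]
  expect_identical(v1$target_pos[1:2], c(10e6, 50e6))
  ## file round trip
  f <- tempfile(); write.table(toy_marker_table(), f, sep = "\t",
                               quote = FALSE, row.names = FALSE)
  expect_identical(load_marker_table(f), mt)
})

test_that("block calling finds maximal same-target runs", {
  blocks <- call_blocks(toy_marker_table())
  ## V1: chr1 x3 then chr2 x1; V2: chr2 x2 then chr3 x1
  expect_identical(nrow(blocks), 4L)
  b11 <- blocks[blocks$query_chrom == "V1" & blocks$target_chrom == "chr1", ]
  expect_identical(b11$n_markers, 3L)
  expect_identical(b11$orientation, "mixed")    # 10, 50, 30 Mb
  expect_identical(b11$target_span, 40e6)
  b22 <- blocks[blocks$query_chrom == "V2" & blocks$target_chrom == "chr2", ]
  expect_identical(b22$orientation, "+")
  expect_identical(blocks$orientation[blocks$n_markers == 1L],
                   rep("singleton", 2L))
  ## block count = 1 + number of target-chromosome changes per query chrom
  for (qc in c("V1", "V2")) {
    m <- toy_marker_table(); m <- m[m$query_chrom == qc, ]
    changes <- sum(m$target_chrom[-1] != utils::head(m$target_chrom, -1))
    expect_identical(sum(blocks$query_chrom == qc), changes + 1L)
  }
  ## descending positions give orientation "-"
  desc <- data.frame(clone_id = c("a", "b", "c"), query_chrom = "V1",
                     query_rank = 1:3, target_chrom = "chrX",
                     target_pos = c(30e6, 20e6, 10e6), stringsAsFactors = FALSE)
  expect_identical(call_blocks(desc)$orientation, "-")
})

test_that("chromosome correspondence is many-to-many with empty support", {
  corr <- chromosome_correspondence(call_blocks(toy_marker_table()))
  expect_identical(unname(attr(corr, "by_target")[["chr2"]]), 2L)  # chr2 on V1 and V2
  expect_identical(nrow(chromosome_correspondence(call_blocks(toy_marker_table())[0, ])), 0L)
  ## one target chromosome scattered over four query chromosomes
  scat <- data.frame(clone_id = sprintf("m%d", 1:4),
                     query_chrom = paste0("V", 1:4), query_rank = 1L,
                     target_chrom = "chr5", target_pos = (1:4) * 1e7,
                     stringsAsFactors = FALSE)
  cs <- chromosome_correspondence(call_blocks(scat))
  expect_identical(unname(attr(cs, "by_target")[["chr5"]]), 4L)
})

test_that("condensation collapses strips and is idempotent", {
  ## colinear single-chromosome map collapses to one segment
  colin <- data.frame(clone_id = sprintf("m%d", 1:4), query_chrom = "V1",
                      query_rank = 1:4, target_chrom = "chr1",
                      target_pos = (1:4) * 1e7, stringsAsFactors = FALSE)
  sg <- condense(colin)
  expect_identical(n_segments(sg$genome_query), 1L)
  expect_identical(genomic_distance(sg$genome_query, sg$genome_target), 0L)
  ## query order 1,3,2 of target order 1,2,3: the descending pair (3,2) is a
  ## reversed strip and collapses to one minus-signed segment
  scramble <- data.frame(clone_id = c("a", "b", "c"), query_chrom = "V1",
                         query_rank = 1:3, target_chrom = "chr1",
                         target_pos = c(1e7, 3e7, 2e7), stringsAsFactors = FALSE)
  sg3 <- condense(scramble)
  expect_identical(n_segments(sg3$genome_query), 2L)
  expect_identical(unclass(sg3$genome_query)[[1]], c(1L, -2L))
  ## a reversed run gets a minus sign
  rev2 <- data.frame(clone_id = c("a", "b", "c", "d"), query_chrom = "V1",
                     query_rank = 1:4, target_chrom = "chr1",
                     target_pos = c(1e7, 4e7, 3e7, 2e7), stringsAsFactors = FALSE)
  sgr <- condense(rev2)
  expect_identical(n_segments(sgr$genome_query), 2L)
  expect_identical(unclass(sgr$genome_query)[[1]], c(1L, -2L))
  ## idempotence: a map with no collapsible run is returned unchanged, so
  ## condensing the one-marker-per-segment representation of an already
  ## condensed map keeps the segment count
  mt4 <- data.frame(clone_id = letters[1:4], query_chrom = "V1",
                    query_rank = 1:4, target_chrom = "chr1",
                    target_pos = c(2e7, 4e7, 1e7, 3e7),  # 2,4,1,3: no run
                    stringsAsFactors = FALSE)
  once <- condense(mt4)
  expect_identical(n_segments(once$genome_query), 4L)
  again <- condense(data.frame(clone_id = paste0("s", 1:4), query_chrom = "V1",
                               query_rank = 1:4, target_chrom = "chr1",
                               target_pos = c(2e7, 4e7, 1e7, 3e7),
                               stringsAsFactors = FALSE))
  expect_identical(unclass(again$genome_query), unclass(once$genome_query))
  ## singletons are flagged ambiguous with provisional plus sign
  toy <- condense(toy_marker_table())
  expect_true(all(toy$ambiguous_segments %in% unlist(lapply(toy$genome_query, abs))))
  expect_true(all(unlist(toy$genome_query)[abs(unlist(toy$genome_query)) %in%
                                             toy$ambiguous_segments] > 0))
})

test_that("condensation on simulated inversions recovers the event structure", {
  cfg <- small_config(marker_spacing = 5e6)   # dense markers
  anc <- make_ancestor(cfg)
  mk <- anc$markers[anc$markers$chrom == 1L, ]
  gaps <- round((utils::head(mk$pos, -1) + mk$pos[-1]) / 2)
  inv <- apply_events(anc, events = list(list(kind = "inversion", chrom = 1L,
                                              bp1 = gaps[5], bp2 = gaps[12])))$derived
  mt <- emit_marker_table(inv, anc, small_config(marker_spacing = 1e6))
  sg <- condense(mt)
  ## chromosome 1 condenses to exactly three segments with the middle one
  ## inverted; untouched chromosomes condense to one segment each
  v1 <- unclass(sg$genome_query)[[which(sg$query_chrom_names == "V1")]]
  expect_identical(length(v1), 3L)
  expect_identical(as.integer(sign(v1)), c(1L, -1L, 1L))
  expect_identical(genomic_distance(sg$genome_query, sg$genome_target), 1L)
  ## distance on condensed equals distance on the uncondensed unit-marker
  ## map with strip-derived signs (strip collapse is distance-preserving)
  st <- sg$markers
  dir_of_strip <- vapply(split(seq_len(nrow(st)), st$strip), function(ix) {
    if (length(ix) == 1L) 1L
    else if (st$target_rank[ix[2]] > st$target_rank[ix[1]]) 1L else -1L
  }, 1L)
  msign <- dir_of_strip[as.character(st$strip)]
  q_raw <- signed_genome(lapply(unname(split(msign * st$target_rank,
                                             st$query_chrom)), as.integer))
  tchrom_by_rank <- st$target_chrom[order(st$target_rank)]
  t_raw <- signed_genome(lapply(unname(split(seq_len(nrow(st)),
                                             factor(tchrom_by_rank,
                                                    unique(tchrom_by_rank)))),
                                as.integer))
  expect_identical(genomic_distance(q_raw, t_raw), 1L)
})

test_that("grimm text round trips and validates", {
  gs <- list(query = g(c(1, -2, 3), c(4, 5)), target = g(1:3, 4:5))
  f <- tempfile(fileext = ".grimm")
  write_grimm(gs, f)
  lines <- readLines(f)
  expect_identical(lines[1], ">query")
  expect_identical(lines[2], "1 -2 3 $")
  back <- read_grimm(f)
  expect_identical(unclass(back$query), unclass(gs$query))
  expect_identical(unclass(back$target), unclass(gs$target))
  ## duplicate id detection
  writeLines(c(">x", "1 2 $", "2 3 $"), f)
  expect_error(read_grimm(f), "duplicate")
  writeLines(c(">x", "1 3 $"), f)
  expect_error(read_grimm(f), "missing")
  writeLines(c("1 2 $"), f)
  expect_error(read_grimm(f), "header")
})
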