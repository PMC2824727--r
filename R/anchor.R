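## BES mate-pair anchoring: mappability classes, mate-rescue of multi-mapped
## reads, and per-clone concordance calls with categorised rearrangement
## evidence.

#' Concordance thresholds
#'
#' The concordant window is the expected clone-span range on the reference
#' (closed interval, default 90-200 kb); spans above `large_indel` (default
#' 2 Mb) are classified as large/complex events rather than assignable
#' indels.
#'
#' @param concordant_min,concordant_max closed concordant span window (bp).
#' @param large_indel span ceiling (bp) for an assignable indel.
#' @return list of class `thresholds`.
#' @export
thresholds <- function(concordant_min = 90000, concordant_max = 200000,
                       large_indel = 2e6) {
  if (!(0 < concordant_min && concordant_min < concordant_max &&
        concordant_max < large_indel))
    stop("need 0 < concordant_min < concordant_max < large_indel")
  structure(list(concordant_min = concordant_min,
                 concordant_max = concordant_max,
                 large_indel = large_indel), class = "thresholds")
}

CLONE_CLASSES <- c("no_anchor", "single_end", "concordant",
                   "discordant_indel_assignable", "discordant_large_or_complex",
                   "discordant_inversion", "discordant_translocation")

#' Parse BLAST tabular (outfmt 6) alignments of BES reads
#'
#' Expects the 12 standard columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore).  Read ids must follow
#' `{clone}_{T7|SP6}`.  One-based inclusive subject coordinates are
#' converted to 0-based half-open; `sstart > send` decodes as the minus
#' strand.  Malformed rows are reported with their line numbers.
#'
#' @param path tabular file.
#' @return data.frame of class `bes_alignment` with read_id, clone_id, end,
#'   target_chrom, start, end_pos, strand, identity, bit_score, e_value.
#' @export
parse_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- tryCatch(
    read.delim(path, header = FALSE, col.names = cols,
               colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) {
      if (file.exists(path) && length(readLines(path)) == 0) return(NULL)
      stop("cannot read BLAST tabular file '", path, "': ", conditionMessage(e))
    })
  if (is.null(raw) || nrow(raw) == 0L) return(empty_bes_alignment())
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))
      stop("non-numeric '", cn, "' in BLAST tabular file at line(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    raw[[cn]] <- v
  }
  m <- regmatches(raw$qseqid, regexec("^(.+)_(T7|SP6)$", raw$qseqid))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop("read id(s) not of the form {clone}_{T7|SP6} at line(s) ",
         paste(utils::head(which(!ok), 5), collapse = ", "))
  clone <- vapply(m, `[`, "", 2L)
  endlab <- vapply(m, `[`, "", 3L)
  minus <- raw$sstart > raw$send
  out <- data.frame(read_id = raw$qseqid, clone_id = clone, end = endlab,
                    target_chrom = raw$sseqid,
                    start = ifelse(minus, raw$send, raw$sstart) - 1,
                    end_pos = ifelse(minus, raw$sstart, raw$send),
                    strand = ifelse(minus, "-", "+"),
                    identity = raw$pident, bit_score = raw$bitscore,
                    e_value = raw$evalue, stringsAsFactors = FALSE)
  if (any(out$e_value < 0)) stop("negative e-value encountered")
  class(out) <- c("bes_alignment", "data.frame")
  out
}

empty_bes_alignment <- function() {
  out <- data.frame(read_id = character(0), clone_id = character(0),
                    end = character(0), target_chrom = character(0),
                    start = numeric(0), end_pos = numeric(0),
                    strand = character(0), identity = numeric(0),
                    bit_score = numeric(0), e_value = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("bes_alignment", "data.frame")
  out
}

#' Classify the mappability of one read
#'
#' Zero hits give `unmapped`, one hit `unique` (locus adopted), two or more
#' `multi` with all candidate loci retained for mate-rescue.
#'
#' @param hits data.frame of alignments for a single read (possibly empty).
#' @return A `read_anchor`: list(read_id, status, locus, candidates,
#'   n_candidates).
#' @export
classify_mappability <- function(hits) {
  if (nrow(hits) == 0L)
    return(structure(list(read_id = NA_character_, status = "unmapped",
                          locus = NULL, candidates = NULL, n_candidates = 0L),
                     class = "read_anchor"))
  if (length(unique(hits$read_id)) != 1L)
    stop("classify_mappability expects hits of a single read")
  loci <- hits[, c("target_chrom", "start", "end_pos", "strand")]
  if (nrow(hits) == 1L)
    return(structure(list(read_id = hits$read_id[1], status = "unique",
                          locus = loci[1, ], candidates = loci,
                          n_candidates = 1L), class = "read_anchor"))
  structure(list(read_id = hits$read_id[1], status = "multi", locus = NULL,
                 candidates = loci, n_candidates = nrow(hits)),
            class = "read_anchor")
}

pair_geometry <- function(a, b) {
  ## a, b: single-row loci (target_chrom, start, end_pos, strand)
  same <- a$target_chrom == b$target_chrom
  span <- if (same) max(a$end_pos, b$end_pos) - min(a$start, b$start) else NA_real_
  facing <- FALSE
  if (same && a$strand != b$strand) {
    left <- if (a$start <= b$start) a else b
    right <- if (a$start <= b$start) b else a
    facing <- left$strand == "+" && right$strand == "-"
  }
  list(same = same, span = span, opposite = a$strand != b$strand, facing = facing)
}

#' Rescue a multi-mapped read via its uniquely mapped mate
#'
#' Among the candidate loci, looks for the one forming a concordant pair
#' with the mate (same chromosome, opposite strands facing inward, span in
#' the concordant window).  Exactly one qualifying candidate upgrades the
#' read to `rescued`; zero or several leave it `multi`.
#'
#' @param anchor a `read_anchor` with status `multi`.
#' @param mate_locus the unique mate's locus (one-row data.frame).
#' @param t a [thresholds()].
#' @return The (possibly upgraded) `read_anchor`.
#' @export
rescue_multi <- function(anchor, mate_locus, t = thresholds()) {
  if (anchor$status != "multi") return(anchor)
  ok <- vapply(seq_len(nrow(anchor$candidates)), function(i) {
    g <- pair_geometry(anchor$candidates[i, ], mate_locus)
    g$same && g$facing &&
      g$span >= t$concordant_min && g$span <= t$concordant_max
  }, TRUE)
  if (sum(ok) == 1L) {
    anchor$status <- "rescued"
    anchor$locus <- anchor$candidates[which(ok), ]
  }
  anchor
}

#' Classify a resolved mate pair
#'
#' Implements the concordance rules on two resolved loci: different
#' chromosomes give `discordant_translocation`; same chromosome and equal
#' strands give `discordant_inversion`; opposite strands facing inward are
#' `concordant` when the outer span lies in the closed
#' `[concordant_min, concordant_max]` window, `discordant_indel_assignable`
#' when outside it but at most `large_indel`, and
#' `discordant_large_or_complex` beyond that.  Opposite strands facing
#' outward violate insert geometry and are treated as inversion-type.
#'
#' @param a,b resolved loci (one-row data.frames with target_chrom, start,
#'   end_pos, strand).
#' @param t a [thresholds()].
#' @param clone_id optional clone id carried into the call.
#' @return A `clone_anchor_call` list (clone_id, klass, span,
#'   assigned_interval, loci).
#' @export
classify_pair <- function(a, b, t = thresholds(), clone_id = NA_character_) {
  if (is.null(a) || is.null(b)) stop("classify_pair requires two resolved loci")
  g <- pair_geometry(a, b)
  klass <- if (!g$same) {
    "discordant_translocation"
  } else if (!g$opposite || !g$facing) {
    "discordant_inversion"
  } else if (g$span >= t$concordant_min && g$span <= t$concordant_max) {
    "concordant"
  } else if (g$span <= t$large_indel) {
    "discordant_indel_assignable"
  } else {
    "discordant_large_or_complex"
  }
  interval <- if (klass %in% c("concordant", "discordant_indel_assignable")) {
    data.frame(target_chrom = a$target_chrom,
               start = min(a$start, b$start),
               end_pos = max(a$end_pos, b$end_pos), stringsAsFactors = FALSE)
  } else NULL
  structure(list(clone_id = clone_id, klass = klass,
                 span = if (g$same) g$span else NA_real_,
                 assigned_interval = interval,
                 loci = list(a = a, b = b)), class = "clone_anchor_call")
}

#' Call one clone from its end anchors
#'
#' Both ends resolved (unique or rescued) delegate to [classify_pair()];
#' exactly one resolved end gives `single_end` anchored at that locus; none
#' gives `no_anchor`.
#'
#' @param anchors list of 0-2 `read_anchor`s for the clone's ends.
#' @param t a [thresholds()].
#' @param clone_id clone id for the call.
#' @return A `clone_anchor_call`.
#' @export
anchor_clone <- function(anchors, t = thresholds(), clone_id = NA_character_) {
  if (length(anchors) > 2L)
    stop("clone ", clone_id, " has more than two reads; input integrity error")
  resolved <- Filter(function(a) a$status %in% c("unique", "rescued"), anchors)
  if (length(resolved) == 2L)
    return(classify_pair(resolved[[1]]$locus, resolved[[2]]$locus, t, clone_id))
  if (length(resolved) == 1L) {
    loc <- resolved[[1]]$locus
    return(structure(list(clone_id = clone_id, klass = "single_end",
                          span = NA_real_,
                          assigned_interval = data.frame(
                            target_chrom = loc$target_chrom, start = loc$start,
                            end_pos = loc$end_pos, stringsAsFactors = FALSE),
                          loci = list(a = loc, b = NULL)),
                     class = "clone_anchor_call"))
  }
  structure(list(clone_id = clone_id, klass = "no_anchor", span = NA_real_,
                 assigned_interval = NULL, loci = NULL),
            class = "clone_anchor_call")
}

#' Anchor all clones in an alignment table
#'
#' Driver for the full per-clone pipeline: classify each read's
#' mappability, run one round of mate-rescue (a multi-mapped read is
#' searched with its uniquely mapped mate's locus), then call every clone.
#'
#' @param alignments a `bes_alignment` data.frame (see [parse_blast_tab()]).
#' @param t a [thresholds()].
#' @return data.frame of per-clone calls: clone_id, klass, span and the two
#'   loci (chrom_a, start_a, end_a, strand_a, chrom_b, ...).
#' @export
anchor_clones <- function(alignments, t = thresholds()) {
  calls <- list()
  reads_by_clone <- split(alignments, alignments$clone_id)
  for (clone_id in names(reads_by_clone)) {
    cl <- reads_by_clone[[clone_id]]
    ends <- split(cl, cl$end)
    if (length(ends) > 2L)
      stop("clone ", clone_id, " has more than two read labels")
    anchors <- lapply(ends, classify_mappability)
    if (length(anchors) == 2L) {
      st <- vapply(anchors, function(a) a$status, "")
      if (any(st == "multi") && any(st == "unique")) {
        im <- which(st == "multi")[1]
        iu <- which(st == "unique")[1]
        if (im != iu)
          anchors[[im]] <- rescue_multi(anchors[[im]], anchors[[iu]]$locus, t)
      }
    }
    calls[[clone_id]] <- anchor_clone(anchors, t, clone_id)
  }
  calls_to_df(calls)
}

calls_to_df <- function(calls) {
  rows <- lapply(calls, function(cc) {
    loc <- function(l) if (is.null(l)) list(chrom = NA_character_, start = NA_real_,
                                            end = NA_real_, strand = NA_character_)
      else list(chrom = l$target_chrom, start = l$start, end = l$end_pos,
                strand = if ("strand" %in% names(l)) l$strand else NA_character_)
    a <- loc(if (!is.null(cc$loci)) cc$loci$a else NULL)
    b <- loc(if (!is.null(cc$loci)) cc$loci$b else NULL)
    data.frame(clone_id = cc$clone_id, klass = cc$klass, span = cc$span,
               chrom_a = a$chrom, start_a = a$start, end_a = a$end, strand_a = a$strand,
               chrom_b = b$chrom, start_b = b$start, end_b = b$end, strand_b = b$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(clone_id = character(0), klass = character(0),
                      span = numeric(0), chrom_a = character(0),
                      start_a = numeric(0), end_a = numeric(0),
                      strand_a = character(0), chrom_b = character(0),
                      start_b = numeric(0), end_b = numeric(0),
                      strand_b = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarise clone anchor calls
#'
#' Counts per class in fixed column order, plus totals of clones anchored
#' via one or both ends.
#'
#' @param calls data.frame from [anchor_clones()] (or list of calls).
#' @return one-row data.frame with one column per class plus
#'   `anchored_single` and `anchored_both`.
#' @export
summarize_anchors <- function(calls) {
  if (!is.data.frame(calls)) calls <- calls_to_df(calls)
  counts <- vapply(CLONE_CLASSES, function(k) sum(calls$klass == k), 1L)
  both <- sum(!(calls$klass %in% c("no_anchor", "single_end")))
  out <- as.data.frame(as.list(counts), stringsAsFactors = FALSE)
  out$anchored_single <- counts[["single_end"]]
  out$anchored_both <- both
  out
}
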