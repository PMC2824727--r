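## Comparative map construction: conserved-synteny blocks from FISH-anchored
## marker tables, condensation to signed segment permutations, and the
## GRIMM genome text format.

#' Load a marker table
#'
#' Five required columns: clone_id, query_chrom, query_rank, target_chrom,
#' target_pos.  The query side is cytogenetic: integer ranks along the
#' query chromosome, ties allowed (unresolved FISH pairs); the target side
#' gives chromosome and bp position.  Duplicate clone ids are rejected.
#'
#' @param x TSV path or data.frame.
#' @return data.frame of class `marker_table`, sorted by
#'   (query_chrom, query_rank) with the deterministic tie rule: tied ranks
#'   are ordered by target position (ascending), which minimises spurious
#'   breakpoints.
#' @export
load_marker_table <- function(x) {
  need <- c("clone_id", "query_chrom", "query_rank", "target_chrom", "target_pos")
  df <- if (is.data.frame(x)) x else read.delim(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("marker table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, need]
  if (!is.numeric(df$query_rank) || !is.numeric(df$target_pos)) {
    df$query_rank <- suppressWarnings(as.numeric(df$query_rank))
    df$target_pos <- suppressWarnings(as.numeric(df$target_pos))
    if (anyNA(df$query_rank) || anyNA(df$target_pos))
      stop("query_rank and target_pos must be numeric")
  }
  dup <- df$clone_id[duplicated(df$clone_id)]
  if (length(dup))
    stop("duplicate clone id(s): ", paste(unique(dup), collapse = ", "))
  df <- df[order(df$query_chrom, df$query_rank, df$target_chrom, df$target_pos), ]
  rownames(df) <- NULL
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Call conserved-synteny blocks
#'
#' A block is a maximal run of consecutive markers on one query chromosome
#' that all map to the same target chromosome.  Orientation is `+` when
#' target positions strictly increase with query rank, `-` when they
#' strictly decrease, `mixed` otherwise, and `singleton` for one-marker
#' blocks.
#'
#' @param markers a [load_marker_table()] table.
#' @return data.frame: query_chrom, block (index along the query
#'   chromosome), target_chrom, target_start, target_end, target_span,
#'   n_markers, orientation.
#' @export
call_blocks <- function(markers) {
  markers <- load_marker_table(markers)
  out <- list()
  for (qc in unique(markers$query_chrom)) {
    m <- markers[markers$query_chrom == qc, ]
    runs <- rle(m$target_chrom)
    idx <- cumsum(c(1L, utils::head(runs$lengths, -1L)))
    for (bi in seq_along(runs$values)) {
      rows <- m[seq.int(idx[bi], length.out = runs$lengths[bi]), ]
      pos <- rows$target_pos
      orientation <- if (nrow(rows) == 1L) "singleton"
        else if (all(diff(pos) > 0)) "+"
        else if (all(diff(pos) < 0)) "-"
        else "mixed"
      out[[length(out) + 1L]] <- data.frame(
        query_chrom = qc, block = bi, target_chrom = runs$values[bi],
        target_start = min(pos), target_end = max(pos),
        target_span = max(pos) - min(pos), n_markers = nrow(rows),
        orientation = orientation, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(query_chrom = character(0), block = integer(0),
                      target_chrom = character(0), target_start = numeric(0),
                      target_end = numeric(0), target_span = numeric(0),
                      n_markers = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  res
}

#' Chromosome correspondence table
#'
#' Many-to-many orthology between query and target chromosomes: one row
#' per (target, query) pair with at least one block, with block and marker
#' tallies.  Summaries per chromosome are in the attributes `by_target`
#' and `by_query` (number of partner chromosomes each maps to).
#'
#' @param blocks from [call_blocks()].
#' @return long-format data.frame (target_chrom, query_chrom, n_blocks,
#'   n_markers).
#' @export
chromosome_correspondence <- function(blocks) {
  if (nrow(blocks) == 0L) {
    out <- data.frame(target_chrom = character(0), query_chrom = character(0),
                      n_blocks = integer(0), n_markers = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "by_target") <- integer(0)
    attr(out, "by_query") <- integer(0)
    return(out)
  }
  agg <- aggregate(cbind(n_blocks = block, n_markers = n_markers) ~
                     target_chrom + query_chrom, data = blocks,
                   FUN = length)
  agg$n_markers <- aggregate(n_markers ~ target_chrom + query_chrom,
                             data = blocks, FUN = sum)$n_markers
  agg <- agg[order(agg$target_chrom, agg$query_chrom), ]
  rownames(agg) <- NULL
  attr(agg, "by_target") <- table(agg$target_chrom)
  attr(agg, "by_query") <- table(agg$query_chrom)
  agg
}

#' Condense a marker map to signed segment permutations
#'
#' Maximal strips (runs of markers adjacent in query order and adjacent in
#' the same direction in target order, on one target chromosome) collapse
#' to single signed segments.  Segment ids are assigned in target order, so
#' the target genome is the identity; the query genome carries the signed
#' permutation.  Singleton strips have no observable orientation (FISH
#' gives none): they are listed in `ambiguous_segments` with provisional
#' sign `+`, to be optimised downstream.
#'
#' @param markers a [load_marker_table()] table.
#' @return list of class `segmented_genomes`: `genome_query`,
#'   `genome_target` (both `signed_genome`), `ambiguous_segments`, and the
#'   per-marker strip assignment.
#' @export
condense <- function(markers) {
  markers <- load_marker_table(markers)
  if (nrow(markers) == 0L) stop("empty marker table")
  ## target order index over all markers
  ord <- order(markers$target_chrom, markers$target_pos)
  markers$target_rank <- NA_integer_
  markers$target_rank[ord] <- seq_len(nrow(markers))
  tchrom_of_rank <- markers$target_chrom[ord]

  ## strips along each query chromosome
  markers$strip <- NA_integer_
  strip_id <- 0L
  strip_rows <- list()
  for (qc in unique(markers$query_chrom)) {
    idx <- which(markers$query_chrom == qc)
    prev_rank <- NA_integer_
    dirn <- 0L
    for (j in seq_along(idx)) {
      i <- idx[j]
      r <- markers$target_rank[i]
      extend <- FALSE
      if (j > 1L) {
        same_chrom <- markers$target_chrom[i] == markers$target_chrom[idx[j - 1L]]
        if (same_chrom && abs(r - prev_rank) == 1L) {
          step <- r - prev_rank
          if (dirn == 0L || step == dirn) { extend <- TRUE; dirn <- step }
        }
      }
      if (!extend) { strip_id <- strip_id + 1L; dirn <- 0L }
      markers$strip[i] <- strip_id
      prev_rank <- r
    }
  }

  ## one segment per strip, ids in target order
  strips <- split(seq_len(nrow(markers)), markers$strip)
  strip_min_rank <- vapply(strips, function(ix) min(markers$target_rank[ix]), 1L)
  seg_of_strip <- rank(strip_min_rank)           # 1..n in target order
  n <- length(strips)

  ## query genome: signed segments along query chromosomes
  q_chroms <- list()
  ambiguous <- integer(0)
  for (qc in unique(markers$query_chrom)) {
    idx <- which(markers$query_chrom == qc)
    sids <- unique(markers$strip[idx])
    signed <- vapply(sids, function(s) {
      ix <- strips[[as.character(s)]]
      seg <- as.integer(seg_of_strip[[as.character(s)]])
      if (length(ix) == 1L) { ambiguous <<- c(ambiguous, seg); return(seg) }
      up <- markers$target_rank[ix[2L]] > markers$target_rank[ix[1L]]
      if (up) seg else -seg
    }, 1L)
    q_chroms[[qc]] <- signed
  }

  ## target genome: identity grouped by target chromosome
  seg_tchrom <- vapply(strips, function(ix) markers$target_chrom[ix][1L], "")
  seg_tchrom <- seg_tchrom[order(seg_of_strip)]
  t_chroms <- lapply(split(seq_len(n), seg_tchrom)[unique(seg_tchrom)], as.integer)

  structure(list(genome_query = signed_genome(unname(q_chroms)),
                 genome_target = signed_genome(unname(t_chroms)),
                 query_chrom_names = names(q_chroms),
                 target_chrom_names = names(t_chroms),
                 ambiguous_segments = sort(unique(ambiguous)),
                 markers = markers),
            class = "segmented_genomes")
}

#' @export
print.segmented_genomes <- function(x, ...) {
  cat("segmented genomes:", n_segments(x$genome_query), "segments;",
      length(x$ambiguous_segments), "ambiguous (singleton) segment(s)\n")
  cat("query:\n"); print(x$genome_query)
  cat("target:\n"); print(x$genome_target)
  invisible(x)
}

#' Read and write the GRIMM genome text format
#'
#' One `>name` header per genome, then one line per chromosome of
#' space-separated signed integers terminated by `$`.
#'
#' @param genomes named list of `signed_genome`s.
#' @param path file path.
#' @return `write_grimm()` the path, invisibly; `read_grimm()` a named list
#'   of `signed_genome`s.
#' @export
write_grimm <- function(genomes, path) {
  lines <- character(0)
  nm <- names(genomes)
  if (is.null(nm)) nm <- paste0("genome", seq_along(genomes))
  for (i in seq_along(genomes)) {
    lines <- c(lines, paste0(">", nm[i]),
               vapply(genomes[[i]], function(ch)
                 paste(c(ch, "$"), collapse = " "), ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_grimm
#' @export
read_grimm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur <- NULL
  cur_name <- NULL
  flush <- function() {
    if (!is.null(cur_name)) {
      ids <- unlist(cur)
      bad <- abs(ids)[duplicated(abs(ids))]
      if (length(bad))
        stop("genome '", cur_name, "': duplicate segment id(s) ",
             paste(unique(bad), collapse = ", "))
      miss <- setdiff(seq_len(max(abs(ids))), abs(ids))
      if (length(miss))
        stop("genome '", cur_name, "': missing segment id(s) ",
             paste(miss, collapse = ", "))
      out[[cur_name]] <<- signed_genome(cur)
    }
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur_name <- sub("^>\\s*", "", ln)
      cur <- list()
    } else {
      if (is.null(cur_name)) stop("chromosome line before any >name header")
      toks <- strsplit(ln, "\\s+")[[1]]
      if (utils::tail(toks, 1L) != "$")
        stop("chromosome line not terminated by $: '", ln, "'")
      vals <- suppressWarnings(as.integer(utils::head(toks, -1L)))
      if (anyNA(vals)) stop("non-integer segment id in line: '", ln, "'")
      if (length(vals)) cur[[length(cur) + 1L]] <- vals
    }
  }
  flush()
  out
}

#' Write synteny blocks as a BED-like table on target coordinates
#'
#' @param blocks from [call_blocks()].
#' @param path output TSV.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- blocks[, c("target_chrom", "target_start", "target_end",
                    "query_chrom", "orientation", "n_markers")]
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
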