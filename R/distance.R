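## Genome rearrangement distance for multichromosomal signed genomes under
## the classical model: reversals (inversions), reciprocal translocations,
## fusions and fissions, all at unit weight, with linear chromosomes and no
## circular intermediates.
##
## The implementation works on the adjacency graph of the two genomes.  The
## double-cut-and-join (DCJ) count n - C - I/2 (C cycles, I odd paths) is a
## lower bound; the restricted model pays an extra price for "knots":
## unoriented components confined to a single chromosome, which no legal
## reversal can split.  The penalty is computed from the forest of knots
## (cover cost with a fortress correction, as in inversion-distance theory)
## plus pairing of telomere-bearing semi-knots.  Correctness of the penalty
## is established empirically in the test suite against an exhaustive
## breadth-first-search oracle over the exact operation set.

tail_ext <- function(i) 2L * i - 1L
head_ext <- function(i) 2L * i

## Relabel segment ids so that genome b becomes the identity, grouped into
## its chromosomes; returns relabeled a and the b chromosome sizes.
relabel_pair <- function(a, b) {
  n <- n_segments(a)
  map <- integer(n)
  msign <- integer(n)
  t <- 0L
  for (ch in b) for (v in ch) {
    t <- t + 1L
    map[abs(v)] <- t
    msign[abs(v)] <- sign(v)
  }
  if (any(map == 0L)) stop("genomes are over different segment universes")
  a2 <- lapply(a, function(x) as.integer(map[abs(x)] * msign[abs(x)] * sign(x)))
  list(a = a2, bsizes = vapply(b, length, 1L))
}

## Build the adjacency graph of relabeled genome a against the identity
## target and traverse its components, recording everything the distance
## and penalty computations need.
rearr_graph <- function(a2, bsizes) {
  n <- sum(bsizes)
  nx <- 2L * n
  matchA <- integer(nx)
  matchB <- integer(nx)
  extChrom <- integer(nx)
  extCoord <- integer(nx)
  chromLen <- vapply(a2, length, 1L)

  ## target (identity) adjacencies per target chromosome
  stops <- cumsum(bsizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  for (ci in seq_along(bsizes)) {
    if (bsizes[ci] >= 2L) for (v in starts[ci]:(stops[ci] - 1L)) {
      matchB[head_ext(v)] <- tail_ext(v + 1L)
      matchB[tail_ext(v + 1L)] <- head_ext(v)
    }
  }

  ## query adjacencies and extremity coordinates (gene at index j occupies
  ## points 2j-1 and 2j along its chromosome)
  for (ci in seq_along(a2)) {
    x <- a2[[ci]]
    m <- length(x)
    lefts <- ifelse(x > 0L, tail_ext(abs(x)), head_ext(abs(x)))
    rights <- ifelse(x > 0L, head_ext(abs(x)), tail_ext(abs(x)))
    extChrom[lefts] <- ci; extCoord[lefts] <- 2L * seq_len(m) - 1L
    extChrom[rights] <- ci; extCoord[rights] <- 2L * seq_len(m)
    if (m >= 2L) for (j in seq_len(m - 1L)) {
      matchA[rights[j]] <- lefts[j + 1L]
      matchA[lefts[j + 1L]] <- rights[j]
    }
  }

  visited <- logical(nx)
  pieces <- list()
  np <- 0L

  record_walk <- function(e0, first_side, is_cycle) {
    blacks_chrom <- integer(0); blacks_dir <- integer(0); blacks_lo <- integer(0)
    arcs_chrom <- integer(0); arcs_lo <- integer(0); arcs_hi <- integer(0)
    cur <- e0; side <- first_side
    visited[e0] <<- TRUE
    end_side <- NA_character_
    edges <- 0L
    repeat {
      nxt <- if (side == "A") matchA[cur] else matchB[cur]
      if (nxt == 0L) { end_side <- side; break }
      if (side == "A") {
        blacks_chrom <- c(blacks_chrom, extChrom[cur])
        blacks_dir <- c(blacks_dir, if (extCoord[cur] < extCoord[nxt]) 1L else -1L)
        blacks_lo <- c(blacks_lo, min(extCoord[cur], extCoord[nxt]))
      } else if (extChrom[cur] == extChrom[nxt]) {
        arcs_chrom <- c(arcs_chrom, extChrom[cur])
        arcs_lo <- c(arcs_lo, min(extCoord[cur], extCoord[nxt]))
        arcs_hi <- c(arcs_hi, max(extCoord[cur], extCoord[nxt]))
      }
      edges <- edges + 1L
      visited[nxt] <<- TRUE
      cur <- nxt
      side <- if (side == "A") "B" else "A"
      if (is_cycle && cur == e0 && side == first_side) break
    }
    list(is_cycle = is_cycle,
         start_ext = e0, end_ext = cur,
         start_missing = if (is_cycle) NA_character_ else first_side_missing(e0, first_side),
         end_missing = end_side,
         n_black = length(blacks_chrom),
         blacks_chrom = blacks_chrom, blacks_dir = blacks_dir, blacks_lo = blacks_lo,
         arcs_chrom = arcs_chrom, arcs_lo = arcs_lo, arcs_hi = arcs_hi)
  }
  first_side_missing <- function(e0, first_side) if (first_side == "A") "B" else "A"

  ## paths first: start from every extremity missing one of its two links
  for (e in seq_len(nx)) {
    if (visited[e]) next
    missA <- matchA[e] == 0L
    missB <- matchB[e] == 0L
    if (!missA && !missB) next
    first_side <- if (missA) "B" else "A"
    pc <- record_walk(e, first_side, is_cycle = FALSE)
    np <- np + 1L
    pieces[[np]] <- pc
  }
  ## remaining components are cycles
  for (e in seq_len(nx)) {
    if (visited[e]) next
    pc <- record_walk(e, "A", is_cycle = TRUE)
    np <- np + 1L
    pieces[[np]] <- pc
  }

  n_cycles <- sum(vapply(pieces, function(p) p$is_cycle, TRUE))
  odd <- vapply(pieces, function(p) {
    !p$is_cycle && (p$start_missing != p$end_missing)
  }, TRUE)
  list(n = n, pieces = pieces, n_cycles = n_cycles, n_odd_paths = sum(odd),
       extChrom = extChrom, extCoord = extCoord, matchA = matchA, matchB = matchB,
       chromLen = chromLen)
}

## Piece classification: a piece is "suspicious" when it is confined to one
## query chromosome and unoriented, i.e. no reversal acting inside it can
## make sorting progress.  Cross-chromosome pieces are always sortable by a
## translocation (both DCJ reconnections are legal across chromosomes), and
## even paths are sortable by a fission or fusion.
piece_suspicious <- function(p, extChrom, extCoord) {
  if (p$n_black == 0L) return(FALSE)
  chroms <- unique(p$blacks_chrom)
  if (length(chroms) != 1L) return(FALSE)
  if (p$is_cycle) {
    if (p$n_black == 1L) return(FALSE)          # sorted adjacency
    return(length(unique(p$blacks_dir)) == 1L)
  }
  sm <- p$start_missing; em <- p$end_missing
  if (sm == em) return(FALSE)                   # even path: fission/fusion sorts
  ## odd path: one end is a query-genome telomere
  atel_ext <- if (sm == "A") p$start_ext else p$end_ext
  if (extChrom[atel_ext] != chroms) return(FALSE)  # telomere elsewhere: translocation
  at_left <- extCoord[atel_ext] == 1L
  pseudo <- if (sm == "A") {
    if (at_left) 1L else -1L                    # walk leaves through the cap
  } else {
    if (at_left) -1L else 1L                    # walk arrives at the cap
  }
  length(unique(c(p$blacks_dir, pseudo))) == 1L
}

arcs_cross <- function(lo1, hi1, lo2, hi2) {
  ## any arc pair strictly interleaved
  for (i in seq_along(lo1)) {
    cross <- (lo1[i] < lo2 & lo2 < hi1[i] & hi1[i] < hi2) |
             (lo2 < lo1[i] & lo1[i] < hi2 & hi2 < hi1[i])
    if (any(cross)) return(TRUE)
  }
  FALSE
}

piece_span <- function(p, chrom) {
  cc <- c(p$blacks_lo[p$blacks_chrom == chrom], p$blacks_lo[p$blacks_chrom == chrom] + 1L,
          p$arcs_lo[p$arcs_chrom == chrom], p$arcs_hi[p$arcs_chrom == chrom])
  range(cc)
}

## A piece admits a "free cut" at its black edges when cutting one of them
## is itself a sorting move: blacks of even paths (a fission there raises
## the odd-path count) and blacks of pieces spanning several chromosomes (a
## translocation with the piece's other chromosome splits it; across
## chromosomes both DCJ reconnections are legal).
piece_free_cut <- function(p, extChrom) {
  if (p$n_black == 0L) return(FALSE)
  if (length(unique(p$blacks_chrom)) > 1L) return(TRUE)
  if (p$is_cycle) return(FALSE)
  if (identical(p$start_missing, p$end_missing)) return(TRUE)
  ## odd path whose query telomere sits on another chromosome than its
  ## blacks: the cross-chromosome tail transfer joining them is free
  atel_ext <- if (p$start_missing == "A") p$start_ext else p$end_ext
  extChrom[atel_ext] != p$blacks_chrom[1L]
}

## Identify knots: crossing-closed groups of suspicious pieces not rescued
## by any crossing clean piece.  Returns a data.frame with one row per knot.
find_knots <- function(graph) {
  pieces <- graph$pieces
  susp <- vapply(pieces, piece_suspicious, TRUE,
                 extChrom = graph$extChrom, extCoord = graph$extCoord)
  if (!any(susp)) {
    return(data.frame(chrom = integer(0), lo = integer(0), hi = integer(0),
                      semi = logical(0)))
  }
  np <- length(pieces)
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  chroms_of <- function(p) unique(c(p$blacks_chrom, p$arcs_chrom))
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      if (!susp[i] && !susp[j]) next
      common <- intersect(chroms_of(pieces[[i]]), chroms_of(pieces[[j]]))
      hit <- FALSE
      for (ch in common) {
        ai <- pieces[[i]]$arcs_chrom == ch
        aj <- pieces[[j]]$arcs_chrom == ch
        if (any(ai) && any(aj) &&
            arcs_cross(pieces[[i]]$arcs_lo[ai], pieces[[i]]$arcs_hi[ai],
                       pieces[[j]]$arcs_lo[aj], pieces[[j]]$arcs_hi[aj])) {
          hit <- TRUE; break
        }
      }
      if (hit) union(i, j)
    }
  }
  roots <- vapply(seq_len(np), find, 1L)

  ## gap positions of freely cuttable black edges, per chromosome
  free <- vapply(pieces, piece_free_cut, TRUE, extChrom = graph$extChrom)
  free_chrom <- unlist(lapply(pieces[free], function(p) p$blacks_chrom))
  free_pos <- unlist(lapply(pieces[free], function(p) p$blacks_lo))
  if (is.null(free_chrom)) { free_chrom <- integer(0); free_pos <- integer(0) }

  out <- data.frame(chrom = integer(0), lo = integer(0), hi = integer(0), semi = logical(0))
  for (r in unique(roots[susp])) {
    members <- which(roots == r)
    if (!all(susp[members])) next               # rescued by a clean crossing piece
    mp <- pieces[members]
    chrom <- unique(unlist(lapply(mp, function(p) p$blacks_chrom)))
    sp <- range(unlist(lapply(mp, piece_span, chrom = chrom)))
    semi <- any(!vapply(mp, function(p) p$is_cycle, TRUE))
    ## interval whose interior a free cut must hit to unconfine the knot:
    ## the hull of its black edges, plus its telomere ends for semi-knots
    blo <- min(unlist(lapply(mp, function(p) p$blacks_lo)))
    bhi <- max(unlist(lapply(mp, function(p) p$blacks_lo))) + 1L
    if (semi) {
      for (p in mp) {
        if (p$is_cycle) next
        for (side in c("start", "end")) {
          if (identical(p[[paste0(side, "_missing")]], "A")) {
            ext <- p[[paste0(side, "_ext")]]
            if (graph$extChrom[ext] == chrom) {
              blo <- min(blo, graph$extCoord[ext])
              bhi <- max(bhi, graph$extCoord[ext])
            }
          }
        }
      }
    }
    hits <- free_chrom == chrom & free_pos > blo & free_pos + 1L < bhi
    if (any(hits)) next                         # a free cut unconfines this knot
    out <- rbind(out, data.frame(chrom = chrom, lo = sp[1], hi = sp[2], semi = semi))
  }
  out
}

## Cover cost of the nesting forest of real knots: number of leaves, plus
## one when the leaf count is odd and every leaf is protected (its parent in
## the forest contains no other leaf), the fortress configuration.
knot_forest_cost <- function(kn) {
  if (nrow(kn) == 0L) return(0L)
  m <- nrow(kn)
  parent <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    ## smallest strictly containing knot on the same chromosome
    cand <- which(kn$chrom == kn$chrom[i] & kn$lo <= kn$lo[i] & kn$hi >= kn$hi[i] &
                  (kn$lo < kn$lo[i] | kn$hi > kn$hi[i]))
    if (length(cand)) parent[i] <- cand[which.min(kn$hi[cand] - kn$lo[cand])]
  }
  is_leaf <- !(seq_len(m) %in% parent)
  leaves <- which(is_leaf)
  l <- length(leaves)
  fortress <- 0L
  if (l %% 2L == 1L) {
    protected <- vapply(leaves, function(i) {
      if (is.na(parent[i])) return(FALSE)
      ## does the parent's subtree contain any other leaf?
      desc <- which(vapply(seq_len(m), function(j) {
        k <- j
        repeat {
          if (is.na(parent[k])) return(FALSE)
          if (parent[k] == parent[i]) return(TRUE)
          k <- parent[k]
        }
      }, TRUE))
      sum(is_leaf[desc]) == 1L
    }, TRUE)
    if (all(protected)) fortress <- 1L
  }
  l + fortress
}

rearr_penalty <- function(graph) {
  kn <- find_knots(graph)
  real <- kn[!kn$semi, , drop = FALSE]
  s <- sum(kn$semi)
  knot_forest_cost(real) + as.integer(ceiling(s / 2))
}

#' Minimum rearrangement distance between two signed genomes
#'
#' Computes the exact minimum number of reversals, translocations, fusions
#' and fissions needed to transform genome `a` into genome `b` (up to
#' chromosome order and whole-chromosome flips).  This is the
#' multichromosomal signed-permutation model popularised by the GRIMM tool.
#'
#' The distance is obtained as the DCJ distance (`n - cycles - odd_paths/2`
#' on the adjacency graph) plus a penalty for unoriented components confined
#' to single chromosomes ("knots"), which cannot be split by any legal
#' reversal: real knots pay the cover cost of their nesting forest (with a
#' fortress correction), and telomere-bearing semi-knots pay one operation
#' per pair.  The test suite establishes exact agreement with an exhaustive
#' breadth-first-search oracle over the operation set.
#'
#' @param a,b `signed_genome` objects (or lists of signed integer vectors)
#'   over the same segment universe.
#' @return Integer distance; `0` iff [canonical_equal()] holds.
#' @seealso [bfs_oracle()], [sorting_scenario()], [classify_scenario()]
#' @examples
#' genomic_distance(signed_genome(list(c(1, -2, 3))), signed_genome(list(1:3)))
#' @export
genomic_distance <- function(a, b) {
  a <- as_signed_genome(a); b <- as_signed_genome(b)
  check_same_universe(a, b)
  if (n_segments(a) == 0L) return(0L)
  rl <- relabel_pair(a, b)
  graph <- rearr_graph(rl$a, rl$bsizes)
  d_dcj <- graph$n - graph$n_cycles - graph$n_odd_paths %/% 2L
  as.integer(d_dcj + rearr_penalty(graph))
}

dcj_distance <- function(a, b) {
  rl <- relabel_pair(as_signed_genome(a), as_signed_genome(b))
  graph <- rearr_graph(rl$a, rl$bsizes)
  as.integer(graph$n - graph$n_cycles - graph$n_odd_paths %/% 2L)
}

#' Exhaustive breadth-first-search distance oracle
#'
#' Independent ground truth for [genomic_distance()]: bidirectional
#' breadth-first search over all genomes reachable by single operations
#' (reversal, translocation, fusion, fission), with states deduplicated up
#' to chromosome order and whole-chromosome flips.  Exact by construction
#' but exponential, hence guarded to small instances.
#'
#' @param a,b `signed_genome` objects over the same universe.
#' @param max_states state budget; exceeding it raises a capacity error
#'   (never a wrong answer).
#' @return Integer shortest path length.
#' @export
bfs_oracle <- function(a, b, max_states = 2e6) {
  a <- as_signed_genome(a); b <- as_signed_genome(b)
  check_same_universe(a, b)
  if (n_segments(a) > 8L)
    stop("bfs_oracle is guarded to genomes with at most 8 segments")
  d <- bfs_oracle_cpp(unclass(a), unclass(b), as.double(max_states))
  if (d < 0L) stop("bfs_oracle state budget exceeded (", max_states, " states)")
  d
}
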