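#' Multichromosomal signed genomes
#'
#' A signed genome is an ordered collection of linear chromosomes, each a
#' sequence of signed segment (marker) identifiers.  Every identifier in
#' `1..n` must occur exactly once across the genome, with either sign.  Two
#' genomes are considered equivalent when they differ only by chromosome
#' order and by whole-chromosome flips (reverse the sequence and negate all
#' signs), since neither FISH data nor the rearrangement model fix a polarity
#' or an order for chromosomes.
#'
#' @param chromosomes list of integer vectors of signed segment ids, or a
#'   single integer vector for a one-chromosome genome.
#' @return An object of class `signed_genome` (a list of integer vectors).
#' @examples
#' g <- signed_genome(list(c(1, -2, 3), c(4, 5)))
#' canonical_equal(g, signed_genome(list(c(4, 5), c(-3, 2, -1))))
#' @export
signed_genome <- function(chromosomes) {
  if (is.numeric(chromosomes)) chromosomes <- list(chromosomes)
  if (!is.list(chromosomes)) stop("`chromosomes` must be a list of integer vectors")
  chromosomes <- lapply(chromosomes, function(x) as.integer(x))
  g <- structure(chromosomes, class = "signed_genome")
  validate_signed_genome(g)
  g
}

validate_signed_genome <- function(g) {
  if (any(vapply(g, length, 1L) == 0L)) stop("signed genome has an empty chromosome")
  ids <- unlist(g, use.names = FALSE)
  if (length(ids) == 0L) return(invisible(g))
  if (any(is.na(ids)) || any(ids == 0L)) stop("segment ids must be non-missing and non-zero")
  n <- length(ids)
  tab <- sort(abs(ids))
  if (!identical(tab, seq_len(n))) {
    bad <- setdiff(seq_len(max(abs(ids))), abs(ids))
    stop("segment ids must be a signed permutation of 1..n (missing/duplicated: ",
         paste(utils::head(c(bad, abs(ids)[duplicated(abs(ids))]), 10), collapse = ", "), ")")
  }
  invisible(g)
}

#' @export
print.signed_genome <- function(x, ...) {
  cat("signed genome:", n_segments(x), "segments on", length(x), "chromosome(s)\n")
  for (i in seq_along(x)) cat("  [", i, "] ", paste(x[[i]], collapse = " "), "\n", sep = "")
  invisible(x)
}

n_segments <- function(g) sum(vapply(g, length, 1L))

flip_chrom <- function(x) -rev(x)

#' @rdname signed_genome
#' @param a,b signed genomes over the same segment universe.
#' @export
canonical_equal <- function(a, b) {
  a <- as_signed_genome(a); b <- as_signed_genome(b)
  check_same_universe(a, b)
  identical(canonical_genome(a), canonical_genome(b))
}

as_signed_genome <- function(g) {
  if (inherits(g, "signed_genome")) return(g)
  signed_genome(g)
}

check_same_universe <- function(a, b) {
  if (n_segments(a) != n_segments(b))
    stop("genomes are over different segment universes (", n_segments(a),
         " vs ", n_segments(b), " segments)")
  invisible(TRUE)
}

## Canonical form: flip each chromosome to its lexicographically smaller
## variant, then sort chromosomes.  Used for equality and state hashing.
canonical_genome <- function(g) {
  ch <- lapply(unclass(g), function(x) {
    y <- flip_chrom(x)
    for (i in seq_along(x)) {
      if (x[i] < y[i]) return(x)
      if (y[i] < x[i]) return(y)
    }
    x
  })
  keys <- vapply(ch, function(x) paste(x, collapse = ","), "")
  structure(ch[order(keys)], class = "signed_genome")
}

canonical_key <- function(g) {
  paste(vapply(canonical_genome(g), paste, "", collapse = ","), collapse = ";")
}

#' Apply a single rearrangement operation
#'
#' Operations follow the classical multichromosomal model: `reversal`
#' (within one chromosome), `translocation` (reciprocal exchange of tails
#' between two chromosomes, with or without a flip), `fusion` (end-to-end
#' joining of two chromosomes) and `fission` (splitting one chromosome).
#'
#' @param g a `signed_genome`.
#' @param op a list describing the operation, as produced by
#'   [enumerate_operations()] or found in a [sorting_scenario()]:
#'   \describe{
#'     \item{reversal}{`list(kind, chrom, from, to)`: reverse and negate
#'       elements `from..to` of chromosome `chrom`.}
#'     \item{translocation}{`list(kind, chrom1, chrom2, gap1, gap2, type)`:
#'       split chromosome `i` after position `gap_i` into prefix/suffix; type
#'       1 exchanges suffixes, type 2 joins prefix 1 with the flipped prefix
#'       2 and the flipped suffix 1 with suffix 2.}
#'     \item{fusion}{`list(kind, chrom1, chrom2, variant)`: variant 1 joins
#'       `A+B`, 2 `A+flip(B)`, 3 `flip(A)+B`, 4 `flip(A)+flip(B)`.}
#'     \item{fission}{`list(kind, chrom, gap)`: split after position `gap`.}
#'   }
#' @return The rearranged `signed_genome`.
#' @export
apply_operation <- function(g, op) {
  g <- as_signed_genome(g)
  ch <- unclass(g)
  kind <- op$kind
  if (kind == "reversal") {
    x <- ch[[op$chrom]]
    stopifnot(op$from >= 1, op$to <= length(x), op$from <= op$to)
    x[op$from:op$to] <- flip_chrom(x[op$from:op$to])
    ch[[op$chrom]] <- x
  } else if (kind == "translocation") {
    if (op$chrom1 == op$chrom2) stop("translocation requires two distinct chromosomes")
    a <- ch[[op$chrom1]]; b <- ch[[op$chrom2]]
    stopifnot(op$gap1 >= 0, op$gap1 <= length(a), op$gap2 >= 0, op$gap2 <= length(b))
    a1 <- a[seq_len(op$gap1)]; a2 <- a[seq_len(length(a) - op$gap1) + op$gap1]
    b1 <- b[seq_len(op$gap2)]; b2 <- b[seq_len(length(b) - op$gap2) + op$gap2]
    if (op$type == 1L) {
      new1 <- c(a1, b2); new2 <- c(b1, a2)
    } else {
      new1 <- c(a1, flip_chrom(b1)); new2 <- c(flip_chrom(a2), b2)
    }
    ch[[op$chrom1]] <- new1
    ch[[op$chrom2]] <- new2
    ch <- ch[vapply(ch, length, 1L) > 0L]
  } else if (kind == "fusion") {
    if (op$chrom1 == op$chrom2) stop("fusion requires two distinct chromosomes")
    a <- ch[[op$chrom1]]; b <- ch[[op$chrom2]]
    joined <- switch(op$variant,
                     c(a, b),
                     c(a, flip_chrom(b)),
                     c(flip_chrom(a), b),
                     c(flip_chrom(a), flip_chrom(b)))
    ch[[op$chrom1]] <- joined
    ch <- ch[-op$chrom2]
  } else if (kind == "fission") {
    x <- ch[[op$chrom]]
    if (length(x) < 2L || op$gap < 1L || op$gap >= length(x))
      stop("fission gap must split the chromosome into two non-empty parts")
    ch[[op$chrom]] <- x[seq_len(op$gap)]
    ch <- append(ch, list(x[(op$gap + 1L):length(x)]), after = op$chrom)
  } else {
    stop("unknown operation kind: ", kind)
  }
  structure(ch, class = "signed_genome")
}

#' Enumerate candidate operations in deterministic order
#'
#' Order is: reversals (by chromosome, start, end), translocations (by
#' chromosome pair, gaps, type), fusions (by chromosome pair, variant),
#' fissions (by chromosome, gap).  Degenerate operations (whole-chromosome
#' reversals, empty-tail translocations) are excluded: they map a genome to
#' an equivalent one and can never reduce a distance.
#'
#' @param g a `signed_genome`.
#' @return list of operation descriptors (see [apply_operation()]).
#' @export
enumerate_operations <- function(g) {
  g <- as_signed_genome(g)
  lens <- vapply(g, length, 1L)
  nc <- length(g)
  ops <- list()
  k <- 0L
  add <- function(op) {
    k <<- k + 1L
    ops[[k]] <<- op
  }
  for (c1 in seq_len(nc)) {
    l <- lens[c1]
    for (i in seq_len(l)) for (j in i:l) {
      if (i == 1L && j == l) next  # whole-chromosome flip: equivalence no-op
      add(list(kind = "reversal", chrom = c1, from = i, to = j))
    }
  }
  if (nc >= 2L) {
    for (c1 in seq_len(nc - 1L)) for (c2 in (c1 + 1L):nc) {
      l1 <- lens[c1]; l2 <- lens[c2]
      ## terminal gaps allowed: tail transfers are single translocations in
      ## the capped HP/GRIMM model; skip no-ops and results with an empty
      ## chromosome (those are fusions, enumerated separately)
      for (g1 in 0:l1) for (g2 in 0:l2) {
        if (g1 + (l2 - g2) > 0L && g2 + (l1 - g1) > 0L &&
            !(g1 == 0L && g2 == 0L) && !(g1 == l1 && g2 == l2))
          add(list(kind = "translocation", chrom1 = c1, chrom2 = c2,
                   gap1 = g1, gap2 = g2, type = 1L))
        if (g1 + g2 > 0L && (l1 - g1) + (l2 - g2) > 0L &&
            !(g1 == 0L && g2 == l2) && !(g1 == l1 && g2 == 0L))
          add(list(kind = "translocation", chrom1 = c1, chrom2 = c2,
                   gap1 = g1, gap2 = g2, type = 2L))
      }
    }
    for (c1 in seq_len(nc - 1L)) for (c2 in (c1 + 1L):nc) {
      for (v in 1:4) add(list(kind = "fusion", chrom1 = c1, chrom2 = c2, variant = v))
    }
  }
  for (c1 in seq_len(nc)) {
    if (lens[c1] >= 2L) for (gp in seq_len(lens[c1] - 1L))
      add(list(kind = "fission", chrom = c1, gap = gp))
  }
  ops[seq_len(k)]
}

#' Random signed genomes and random operation histories
#'
#' `random_signed_genome()` draws a uniformly random arrangement of `n`
#' signed segments over at most `max_chrom` chromosomes; `random_operations()`
#' draws a history of `k` legal random operations (resampling an illegal draw
#' up to a retry cap) and returns the resulting genome together with the
#' operation list.
#'
#' @param n number of segments.
#' @param max_chrom maximum number of chromosomes.
#' @param kinds operation kinds to draw from.
#' @param weights sampling weights for `kinds`.
#' @return `random_signed_genome()`: a `signed_genome`;
#'   `random_operations()`: `list(genome=, ops=)`.
#' @export
random_signed_genome <- function(n, max_chrom = 3L) {
  perm <- sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
  nc <- sample.int(min(max_chrom, n), 1L)
  if (nc == 1L) return(signed_genome(list(perm)))
  cuts <- sort(sample(seq_len(n - 1L), nc - 1L))
  signed_genome(unname(split(perm, findInterval(seq_len(n) - 1L, cuts))))
}

#' @rdname random_signed_genome
#' @param g starting `signed_genome`.
#' @param k number of operations to apply.
#' @export
random_operations <- function(g, k,
                              kinds = c("reversal", "translocation", "fusion", "fission"),
                              weights = NULL) {
  g <- as_signed_genome(g)
  if (is.null(weights)) weights <- rep(1, length(kinds))
  ops <- vector("list", k)
  for (step in seq_len(k)) {
    op <- NULL
    for (try in seq_len(200L)) {
      kind <- sample(kinds, 1L, prob = weights)
      lens <- vapply(g, length, 1L)
      nc <- length(g)
      cand <- switch(kind,
        reversal = {
          ok <- which(lens >= 1L)
          c1 <- ok[sample.int(length(ok), 1L)]
          l <- lens[c1]
          if (l == 1L && nc == 1L) NULL else {
            ij <- sort(sample.int(l, 2L, replace = TRUE))
            if (ij[1] == 1L && ij[2] == l) NULL
            else list(kind = "reversal", chrom = c1, from = ij[1], to = ij[2])
          }
        },
        translocation = {
          ok <- which(lens >= 2L)
          if (length(ok) < 2L) NULL else {
            cc <- sort(sample(ok, 2L))
            list(kind = "translocation", chrom1 = cc[1], chrom2 = cc[2],
                 gap1 = sample.int(lens[cc[1]] - 1L, 1L),
                 gap2 = sample.int(lens[cc[2]] - 1L, 1L),
                 type = sample(1:2, 1L))
          }
        },
        fusion = {
          if (nc < 2L) NULL else {
            cc <- sort(sample.int(nc, 2L))
            list(kind = "fusion", chrom1 = cc[1], chrom2 = cc[2],
                 variant = sample(1:4, 1L))
          }
        },
        fission = {
          ok <- which(lens >= 2L)
          if (length(ok) == 0L) NULL else {
            c1 <- ok[sample.int(length(ok), 1L)]
            list(kind = "fission", chrom = c1, gap = sample.int(lens[c1] - 1L, 1L))
          }
        })
      if (!is.null(cand)) { op <- cand; break }
    }
    if (is.null(op)) stop("could not draw a legal operation after 200 retries")
    g <- apply_operation(g, op)
    ops[[step]] <- op
  }
  list(genome = g, ops = ops)
}
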