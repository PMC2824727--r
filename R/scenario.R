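## Parsimonious sorting scenarios and their decomposition, plus sign
## optimisation for orientation-less (FISH singleton) segments.

#' Construct one parsimonious sorting scenario
#'
#' Greedy construction: candidate operations are enumerated in a fixed
#' deterministic order (reversals, then translocations, fusions, fissions,
#' each positionally lexicographic; see [enumerate_operations()]) and the
#' first operation that reduces the remaining distance by exactly one is
#' applied, until distance zero.  The scenario length always equals the
#' initial [genomic_distance()].  Optimal scenarios are not unique; the
#' enumeration order pins down one of them.
#'
#' @param a,b `signed_genome`s over the same universe.
#' @return list of class `scenario`: `ops` (operation list), `states`
#'   (genomes after each step), `length`, `start`, `end`.
#' @export
sorting_scenario <- function(a, b) {
  a <- as_signed_genome(a); b <- as_signed_genome(b)
  d <- genomic_distance(a, b)
  g <- a
  ops <- vector("list", d)
  states <- vector("list", d)
  remaining <- d
  for (step in seq_len(d)) {
    found <- FALSE
    for (op in enumerate_operations(g)) {
      h <- apply_operation(g, op)
      if (genomic_distance(h, b) == remaining - 1L) {
        ops[[step]] <- op
        states[[step]] <- h
        g <- h
        remaining <- remaining - 1L
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("internal error: no distance-reducing operation at step ", step,
           " (this would indicate a distance bug)")
  }
  structure(list(ops = ops, states = states, length = d, start = a, end = b),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("sorting scenario of length", x$length, "\n")
  for (i in seq_along(x$ops)) {
    op <- x$ops[[i]]
    cat(sprintf("  %2d. %s %s\n", i, op$kind,
                paste(names(op)[-1], unlist(op[-1]), sep = "=", collapse = " ")))
  }
  invisible(x)
}

#' Decompose a scenario into a distance report
#'
#' Counts operations by kind; inter-chromosomal events are translocations,
#' fusions and fissions.  Because optimal scenarios are not unique, the
#' decomposition refers to the one scenario given.
#'
#' @param scenario from [sorting_scenario()].
#' @return list of class `distance_report`: d, n_reversals,
#'   n_translocations, n_fusions, n_fissions, n_inter_chromosomal.
#' @export
classify_scenario <- function(scenario) {
  kinds <- vapply(scenario$ops, function(op) op$kind, "")
  rep_ <- list(d = scenario$length,
               n_reversals = sum(kinds == "reversal"),
               n_translocations = sum(kinds == "translocation"),
               n_fusions = sum(kinds == "fusion"),
               n_fissions = sum(kinds == "fission"))
  rep_$n_inter_chromosomal <- rep_$n_translocations + rep_$n_fusions + rep_$n_fissions
  structure(rep_, class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("minimum rearrangements: %d (%d inversion(s), %d inter-chromosomal: %d translocation(s), %d fusion(s), %d fission(s))\n",
              x$d, x$n_reversals, x$n_inter_chromosomal,
              x$n_translocations, x$n_fusions, x$n_fissions))
  invisible(x)
}

flip_segment_sign <- function(g, seg) {
  structure(lapply(unclass(g), function(x) {
    x[abs(x) == seg] <- -x[abs(x) == seg]
    x
  }), class = "signed_genome")
}

#' Optimise the signs of orientation-less segments
#'
#' FISH singletons carry no orientation, so their signs in the query genome
#' are free parameters.  With at most `exhaustive_max` ambiguous segments
#' all sign assignments are enumerated (first minimum in enumeration order
#' wins, starting from all `+`); beyond that a greedy one-at-a-time hill
#' climb from all-`+` is used and the result is flagged approximate.
#'
#' @param a query `signed_genome` (provisional `+` signs on ambiguous
#'   segments).
#' @param b target `signed_genome`.
#' @param ambiguous integer ids of ambiguous segments.
#' @param exhaustive_max enumeration cutoff.
#' @return list: `genome` (signed a), `distance`, `flipped` (ids set to
#'   `-`), `approximate`.
#' @export
optimize_ambiguous_signs <- function(a, b, ambiguous = integer(0),
                                     exhaustive_max = 12L) {
  a <- as_signed_genome(a); b <- as_signed_genome(b)
  k <- length(ambiguous)
  if (k == 0L)
    return(list(genome = a, distance = genomic_distance(a, b),
                flipped = integer(0), approximate = FALSE))
  if (k <= exhaustive_max) {
    best <- NULL
    for (mask in 0:(2^k - 1)) {
      flips <- ambiguous[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L]
      g <- a
      for (s in flips) g <- flip_segment_sign(g, s)
      d <- genomic_distance(g, b)
      if (is.null(best) || d < best$distance)
        best <- list(genome = g, distance = d, flipped = flips, approximate = FALSE)
    }
    return(best)
  }
  ## greedy hill climb
  g <- a
  d <- genomic_distance(g, b)
  flips <- integer(0)
  repeat {
    improved <- FALSE
    for (s in ambiguous) {
      h <- flip_segment_sign(g, s)
      dh <- genomic_distance(h, b)
      if (dh < d) {
        g <- h; d <- dh
        flips <- if (s %in% flips) setdiff(flips, s) else c(flips, s)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(genome = g, distance = d, flipped = sort(flips), approximate = TRUE)
}
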