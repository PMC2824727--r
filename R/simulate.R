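## Synthetic data generator: ancestor/derived genome pairs with a known
## rearrangement history, BAC clones, BES reads and alignments, marker
## tables and probe-screening tables.  Everything is driven by one root
## seed; each emitter draws from its own child stream so that adding an
## emitter does not perturb the others.

#' Simulation configuration
#'
#' Captures the data-generating process of a BAC library project: a target
#' ("ancestor") genome carrying a marker grid, a derived genome obtained by
#' rearrangement events, BAC clones with inserts centred at 139 kb in the
#' 100-200 kb range, end reads of ~728 bp at 41.8% GC, and mapping noise.
#'
#' @param n_chromosomes number of ancestor chromosomes.
#' @param chrom_lengths chromosome lengths in bp (recycled to
#'   `n_chromosomes`).
#' @param n_markers total marker count, or `NULL` to place
#'   `floor(length/marker_spacing)` (at least one) markers per chromosome.
#' @param n_clones number of BAC clones to sample.
#' @param insert_mean,insert_min,insert_max insert-size distribution (bp):
#'   truncated normal on `[insert_min, insert_max]` with mean `insert_mean`.
#' @param insert_sd standard deviation of the untruncated insert law; the
#'   default puts ~95% of the mass inside the 100-200 kb range.
#' @param read_len_mean,read_len_sd BES read length law (bp), truncated
#'   below at 50 bp.
#' @param gc GC fraction of simulated reads.
#' @param p_unmapped probability that a BES fails to align.
#' @param p_multimap probability that a BES gains a decoy second locus at
#'   equal bit score.
#' @param marker_spacing target spacing of the marker grid (bp).
#' @param n_events number of rearrangement events for [simulate_dataset()].
#' @param event_weights sampling weights for the four event kinds
#'   (inversion, translocation, fusion, fission).
#' @param seed root seed (integer) for all child streams.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 5L,
                       chrom_lengths = 150e6,
                       n_markers = NULL,
                       n_clones = 1000L,
                       insert_mean = 139000,
                       insert_min = 100000,
                       insert_max = 200000,
                       insert_sd = 25000,
                       read_len_mean = 728,
                       read_len_sd = 100,
                       gc = 0.418,
                       p_unmapped = 0.5,
                       p_multimap = 0.17,
                       marker_spacing = 30e6,
                       n_events = 0L,
                       event_weights = c(inversion = 1, translocation = 1,
                                         fusion = 1, fission = 1),
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_lengths = rep_len(as.numeric(chrom_lengths), n_chromosomes),
              n_markers = if (is.null(n_markers)) NULL else as.integer(n_markers),
              n_clones = as.integer(n_clones),
              insert_mean = insert_mean, insert_min = insert_min,
              insert_max = insert_max, insert_sd = insert_sd,
              read_len_mean = read_len_mean, read_len_sd = read_len_sd,
              gc = gc, p_unmapped = p_unmapped, p_multimap = p_multimap,
              marker_spacing = marker_spacing,
              n_events = as.integer(n_events),
              event_weights = event_weights,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_chromosomes < 1L) stop("n_chromosomes must be >= 1")
    if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
    if (!is.null(n_markers) && n_markers < 0L) stop("n_markers must be >= 0")
    if (n_clones < 0L) stop("n_clones must be >= 0")
    if (!(insert_min <= insert_mean && insert_mean <= insert_max))
      stop("need insert_min <= insert_mean <= insert_max")
    if (insert_min <= 0 || insert_sd <= 0 || read_len_mean <= 0 || read_len_sd <= 0)
      stop("size parameters must be > 0")
    for (p in c(gc, p_unmapped, p_multimap))
      if (p < 0 || p > 1) stop("fractions must lie in [0, 1]")
    if (marker_spacing <= 0) stop("marker_spacing must be > 0")
    if (n_events < 0L) stop("n_events must be >= 0")
    if (length(event_weights) != 4L || any(event_weights < 0) || sum(event_weights) == 0)
      stop("event_weights must be 4 non-negative weights with a positive sum")
  })
  invisible(cfg)
}

## --- seeding -------------------------------------------------------------

child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

## Truncated normal whose *truncated* mean equals `mean`: asymmetric
## truncation (e.g. 139 kb in [100, 200] kb) would otherwise bias the mean,
## so the underlying location is re-centred by root finding.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (lo >= hi) return(rep(lo, n))
  if (is.finite(lo) && is.finite(hi)) {
    mu <- stats::uniroot(function(m) truncnorm_mean(m, sd, lo, hi) - mean,
                         interval = c(lo - 6 * sd, hi + 6 * sd))$root
  } else mu <- mean
  u <- runif(n, pnorm(lo, mu, sd), pnorm(hi, mu, sd))
  pmin(hi, pmax(lo, qnorm(u, mu, sd)))
}

## --- ancestor ------------------------------------------------------------

#' Build the ancestral (target) genome with a marker grid
#'
#' Markers are placed on a regular grid of about `marker_spacing` bp with
#' +/-20% jitter, numbered consecutively along chromosomes.  Deterministic
#' for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return Object of class `ancestral_genome`: a list with `markers` (a
#'   data.frame of marker_id, chrom, pos) and `chrom_lengths`.
#' @export
make_ancestor <- function(config) {
  validate_sim_config(config)
  lens <- config$chrom_lengths
  nm_per <- if (is.null(config$n_markers)) {
    pmax(1L, as.integer(floor(lens / config$marker_spacing)))
  } else if (config$n_markers == 0L) {
    rep(0L, length(lens))
  } else {
    alloc_proportional(config$n_markers, lens)
  }
  if (any(nm_per > floor(lens / 100)))
    stop("marker count incompatible with chromosome lengths: ",
         "cannot place ", sum(nm_per), " markers at >= 100 bp spacing")
  with_seed(child_seed(config$seed, "ancestor"), {
    rows <- vector("list", length(lens))
    next_id <- 1L
    for (ci in seq_along(lens)) {
      m <- nm_per[ci]
      if (m == 0L) { rows[[ci]] <- NULL; next }
      s <- lens[ci] / m
      pos <- (seq_len(m) - 0.5) * s + runif(m, -0.2, 0.2) * s
      pos <- round(sort(pos))
      rows[[ci]] <- data.frame(marker_id = seq.int(next_id, length.out = m),
                               chrom = ci, pos = pos)
      next_id <- next_id + m
    }
    markers <- do.call(rbind, rows)
    if (is.null(markers))
      markers <- data.frame(marker_id = integer(0), chrom = integer(0), pos = numeric(0))
    structure(list(markers = markers, chrom_lengths = lens),
              class = "ancestral_genome")
  })
}

alloc_proportional <- function(total, lens) {
  raw <- total * lens / sum(lens)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## --- derived genomes as segment lists ------------------------------------

## A derived chromosome is an ordered data.frame of segments
## (anc_chrom, anc_start, anc_end, strand) with half-open bp coordinates.

seg_len <- function(segs) sum(segs$anc_end - segs$anc_start)

new_derived <- function(ancestor) {
  segs <- lapply(seq_along(ancestor$chrom_lengths), function(ci)
    data.frame(anc_chrom = ci, anc_start = 0,
               anc_end = ancestor$chrom_lengths[ci], strand = 1L))
  structure(list(segments = segs,
                 chrom_lengths = vapply(segs, seg_len, 1)),
            class = "derived_genome")
}

split_segs <- function(segs, bp) {
  ## split a segment list at derived coordinate bp (0 < bp < length)
  ends <- cumsum(segs$anc_end - segs$anc_start)
  starts <- c(0, utils::head(ends, -1))
  i <- which(bp > starts & bp < ends)
  if (length(i) == 1L) {
    off <- bp - starts[i]
    s <- segs[i, ]
    if (s$strand == 1L) {
      left <- transform(s, anc_end = anc_start + off)
      right <- transform(s, anc_start = anc_start + off)
    } else {
      left <- transform(s, anc_start = anc_end - off)
      right <- transform(s, anc_end = anc_end - off)
    }
    list(left = rbind(segs[seq_len(i - 1L), ], left),
         right = rbind(right, segs[seq.int(i + 1L, length.out = nrow(segs) - i), ]))
  } else {
    i <- which(abs(ends - bp) < 0.5)[1]
    if (is.na(i)) stop("breakpoint outside chromosome")
    list(left = segs[seq_len(i), ],
         right = segs[seq.int(i + 1L, length.out = nrow(segs) - i), ])
  }
}

flip_segs <- function(segs) {
  if (nrow(segs) == 0L) return(segs)
  out <- segs[rev(seq_len(nrow(segs))), ]
  out$strand <- -out$strand
  rownames(out) <- NULL
  out
}

## Map derived markers: positions and orientation signs of ancestor markers
## in derived coordinates.
derived_markers <- function(derived, ancestor) {
  mk <- ancestor$markers
  out <- vector("list", length(derived$segments))
  for (ci in seq_along(derived$segments)) {
    segs <- derived$segments[[ci]]
    offs <- c(0, utils::head(cumsum(segs$anc_end - segs$anc_start), -1))
    found <- vector("list", nrow(segs))
    for (si in seq_len(nrow(segs))) {
      s <- segs[si, ]
      hit <- mk[mk$chrom == s$anc_chrom & mk$pos >= s$anc_start & mk$pos < s$anc_end, ]
      if (nrow(hit) == 0L) next
      dpos <- if (s$strand == 1L) offs[si] + (hit$pos - s$anc_start)
              else offs[si] + (s$anc_end - hit$pos)
      found[[si]] <- data.frame(marker_id = hit$marker_id, chrom = ci,
                                pos = dpos, sign = s$strand,
                                anc_chrom = hit$chrom, anc_pos = hit$pos)
    }
    res <- do.call(rbind, found)
    if (!is.null(res)) out[[ci]] <- res[order(res$pos), ]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(marker_id = integer(0), chrom = integer(0), pos = numeric(0),
                      sign = integer(0), anc_chrom = integer(0), anc_pos = numeric(0))
  rownames(res) <- NULL
  res
}

## Derived-coordinate positions of novel junctions (segment boundaries that
## are not ancestor-contiguous).
derived_junctions <- function(derived) {
  out <- vector("list", length(derived$segments))
  for (ci in seq_along(derived$segments)) {
    segs <- derived$segments[[ci]]
    if (nrow(segs) < 2L) next
    ends <- cumsum(segs$anc_end - segs$anc_start)
    novel <- logical(nrow(segs) - 1L)
    for (j in seq_len(nrow(segs) - 1L)) {
      a <- segs[j, ]; b <- segs[j + 1L, ]
      contiguous <- a$anc_chrom == b$anc_chrom && a$strand == b$strand &&
        ((a$strand == 1L && abs(a$anc_end - b$anc_start) < 0.5) ||
         (a$strand == -1L && abs(a$anc_start - b$anc_end) < 0.5))
      novel[j] <- !contiguous
    }
    if (any(novel)) out[[ci]] <- data.frame(chrom = ci, pos = ends[which(novel)])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = integer(0), pos = numeric(0))
  res
}

## --- rearrangement events ------------------------------------------------

marker_gaps <- function(derived, ancestor) {
  mk <- derived_markers(derived, ancestor)
  lapply(seq_along(derived$segments), function(ci) {
    p <- sort(mk$pos[mk$chrom == ci])
    if (length(p) < 2L) numeric(0) else round((utils::head(p, -1) + p[-1]) / 2)
  })
}

apply_one_event <- function(derived, ev) {
  segs <- derived$segments
  if (ev$kind == "inversion") {
    sp <- split_segs(segs[[ev$chrom]], ev$bp1)
    sp2 <- split_segs(sp$right, ev$bp2 - ev$bp1)
    segs[[ev$chrom]] <- rbind(sp$left, flip_segs(sp2$left), sp2$right)
  } else if (ev$kind == "translocation") {
    s1 <- split_segs(segs[[ev$chrom1]], ev$bp1)
    s2 <- split_segs(segs[[ev$chrom2]], ev$bp2)
    if (ev$type == 1L) {
      segs[[ev$chrom1]] <- rbind(s1$left, s2$right)
      segs[[ev$chrom2]] <- rbind(s2$left, s1$right)
    } else {
      segs[[ev$chrom1]] <- rbind(s1$left, flip_segs(s2$left))
      segs[[ev$chrom2]] <- rbind(flip_segs(s1$right), s2$right)
    }
  } else if (ev$kind == "fusion") {
    a <- segs[[ev$chrom1]]; b <- segs[[ev$chrom2]]
    joined <- switch(ev$variant, rbind(a, b), rbind(a, flip_segs(b)),
                     rbind(flip_segs(a), b), rbind(flip_segs(a), flip_segs(b)))
    segs[[ev$chrom1]] <- joined
    segs <- segs[-ev$chrom2]
  } else if (ev$kind == "fission") {
    sp <- split_segs(segs[[ev$chrom]], ev$bp)
    segs[[ev$chrom]] <- sp$left
    segs <- append(segs, list(sp$right), after = ev$chrom)
  } else stop("unknown event kind: ", ev$kind)
  segs <- lapply(segs, function(s) { rownames(s) <- NULL; s })
  structure(list(segments = segs, chrom_lengths = vapply(segs, seg_len, 1)),
            class = "derived_genome")
}

#' Apply rearrangement events to an ancestor genome
#'
#' Draws `k` random events (or replays a supplied list) on the marker-grid
#' genome.  Breakpoints always fall at midpoints between adjacent markers,
#' never inside a marker, so truth labels stay clean.  Events illegal for
#' the current genome (e.g. fission of a one-marker chromosome) are
#' resampled up to a retry cap.
#'
#' @param ancestor an [make_ancestor()] genome.
#' @param k number of random events to draw (ignored when `events` given).
#' @param events optional explicit event list to replay.
#' @param seed seed for the event stream (defaults derive from the config
#'   seed in [simulate_dataset()]).
#' @param weights kind-sampling weights (inversion, translocation, fusion,
#'   fission).
#' @return `list(derived = derived_genome, log = event_log)` where the log
#'   replayed on the ancestor reproduces the derived genome exactly.
#' @export
apply_events <- function(ancestor, k = 0L, events = NULL, seed = 1L,
                         weights = c(1, 1, 1, 1)) {
  derived <- new_derived(ancestor)
  if (!is.null(events)) {
    for (ev in events) derived <- apply_one_event(derived, ev)
    return(list(derived = derived,
                log = structure(list(events = events), class = "event_log")))
  }
  if (k == 0L)
    return(list(derived = derived,
                log = structure(list(events = list()), class = "event_log")))
  kinds <- c("inversion", "translocation", "fusion", "fission")
  evs <- vector("list", k)
  with_seed(seed, {
    for (step in seq_len(k)) {
      ev <- NULL
      for (try in seq_len(100L)) {
        kind <- sample(kinds, 1L, prob = weights)
        gaps <- marker_gaps(derived, ancestor)
        ng <- lengths(gaps)
        cand <- switch(kind,
          inversion = {
            ok <- which(ng >= 2L)
            if (!length(ok)) NULL else {
              ci <- ok[sample.int(length(ok), 1L)]
              gg <- sort(sample(gaps[[ci]], 2L))
              list(kind = "inversion", chrom = ci, bp1 = gg[1], bp2 = gg[2])
            }
          },
          translocation = {
            ok <- which(ng >= 1L)
            if (length(ok) < 2L) NULL else {
              cc <- sort(sample(ok, 2L))
              list(kind = "translocation", chrom1 = cc[1], chrom2 = cc[2],
                   bp1 = sample(gaps[[cc[1]]], 1L), bp2 = sample(gaps[[cc[2]]], 1L),
                   type = sample(1:2, 1L))
            }
          },
          fusion = {
            if (length(derived$segments) < 2L) NULL else {
              cc <- sort(sample.int(length(derived$segments), 2L))
              list(kind = "fusion", chrom1 = cc[1], chrom2 = cc[2],
                   variant = sample(1:4, 1L))
            }
          },
          fission = {
            ok <- which(ng >= 1L)
            if (!length(ok)) NULL else {
              ci <- ok[sample.int(length(ok), 1L)]
              list(kind = "fission", chrom = ci, bp = sample(gaps[[ci]], 1L))
            }
          })
        if (!is.null(cand)) { ev <- cand; break }
      }
      if (is.null(ev)) stop("no legal event of any requested kind after 100 retries")
      derived <- apply_one_event(derived, ev)
      evs[[step]] <- ev
    }
  })
  list(derived = derived, log = structure(list(events = evs), class = "event_log"))
}

#' @rdname apply_events
#' @param log an `event_log` from a previous [apply_events()] run.
#' @export
replay_events <- function(ancestor, log) {
  apply_events(ancestor, events = log$events)$derived
}

## --- clones --------------------------------------------------------------

#' Sample BAC clones from the derived genome
#'
#' Insert lengths follow a truncated normal on
#' `[insert_min, insert_max]`; clone starts are uniform; the truth table
#' records whether each clone straddles a rearrangement junction.
#'
#' @param derived a `derived_genome`.
#' @param config a [sim_config()].
#' @param n number of clones (defaults to `config$n_clones`).
#' @return data.frame with clone_id, chrom, start, end, insert and
#'   spans_breakpoint.
#' @export
sample_clones <- function(derived, config, n = config$n_clones) {
  lens <- derived$chrom_lengths
  if (any(lens < config$insert_max))
    stop("all derived chromosomes must be at least insert_max long")
  junc <- derived_junctions(derived)
  with_seed(child_seed(config$seed, "clones"), {
    insert <- round(rtruncnorm(n, config$insert_mean, config$insert_sd,
                               config$insert_min, config$insert_max))
    chrom <- sample.int(length(lens), n, replace = TRUE, prob = lens)
    start <- floor(runif(n, 0, lens[chrom] - insert))
    end <- start + insert
    spans <- vapply(seq_len(n), function(i) {
      j <- junc[junc$chrom == chrom[i], ]
      any(j$pos > start[i] & j$pos < end[i])
    }, TRUE)
    data.frame(clone_id = sprintf("CL%06d", seq_len(n)),
               chrom = chrom, start = start, end = end,
               insert = insert, spans_breakpoint = spans,
               stringsAsFactors = FALSE)
  })
}

## --- alignments ----------------------------------------------------------

## map a derived interval to its (majority) orthologous ancestor interval
map_to_ancestor <- function(derived, chrom, lo, hi) {
  segs <- derived$segments[[chrom]]
  ends <- cumsum(segs$anc_end - segs$anc_start)
  starts <- c(0, utils::head(ends, -1))
  ov_lo <- pmax(lo, starts); ov_hi <- pmin(hi, ends)
  i <- which.max(ov_hi - ov_lo)
  s <- segs[i, ]
  a <- max(ov_lo[i], starts[i]) - starts[i]
  b <- min(ov_hi[i], ends[i]) - starts[i]
  if (s$strand == 1L)
    list(chrom = s$anc_chrom, lo = s$anc_start + a, hi = s$anc_start + b, strand = 1L)
  else
    list(chrom = s$anc_chrom, lo = s$anc_end - b, hi = s$anc_end - a, strand = -1L)
}

#' Emit BES-to-ancestor alignments in BLAST tabular format
#'
#' Each clone end yields one alignment at its orthologous ancestor
#' position, unless dropped (probability `p_unmapped`) or duplicated to a
#' decoy locus at equal bit score (probability `p_multimap`).  End
#' orientations face inward on the ancestor for clones inside unrearranged
#' segments.  Subject coordinates are written 1-based inclusive with strand
#' encoded by `sstart > send`.
#'
#' @param clones from [sample_clones()].
#' @param derived,ancestor the genome pair the clones were sampled from.
#' @param config a [sim_config()].
#' @return `list(alignments=, truth=)`; write with [write_blast_tab()].
#' @export
emit_alignments <- function(clones, derived, ancestor, config) {
  n <- nrow(clones)
  anc_lens <- ancestor$chrom_lengths
  with_seed(child_seed(config$seed, "alignments"), {
    rows <- vector("list", 2L * n)
    truth <- vector("list", 2L * n)
    r <- 0L
    for (i in seq_len(n)) {
      for (endlab in c("T7", "SP6")) {
        r <- r + 1L
        rl <- round(rtruncnorm(1, config$read_len_mean, config$read_len_sd,
                               50, config$insert_min))
        if (endlab == "T7") {
          dl <- clones$start[i]; dh <- clones$start[i] + rl; rstrand <- 1L
        } else {
          dl <- clones$end[i] - rl; dh <- clones$end[i]; rstrand <- -1L
        }
        loc <- map_to_ancestor(derived, clones$chrom[i], dl, dh)
        strand <- rstrand * loc$strand
        read_id <- paste0(clones$clone_id[i], "_", endlab)
        dropped <- runif(1) < config$p_unmapped
        decoy <- !dropped && runif(1) < config$p_multimap
        truth[[r]] <- data.frame(read_id = read_id, clone_id = clones$clone_id[i],
                                 end = endlab, dropped = dropped,
                                 n_loci = if (dropped) 0L else 1L + decoy,
                                 anc_chrom = loc$chrom, anc_start = loc$lo,
                                 anc_end = loc$hi, strand = strand,
                                 stringsAsFactors = FALSE)
        if (dropped) next
        len <- round(loc$hi - loc$lo)
        pident <- round(runif(1, 97, 99.9), 2)
        bit <- round(1.8 * len, 1)
        mk_row <- function(chrom, lo, hi, strand) {
          data.frame(qseqid = read_id, sseqid = sprintf("chr%d", chrom),
                     pident = pident, length = len,
                     mismatch = round(len * (1 - pident / 100)), gapopen = 0L,
                     qstart = 1L, qend = len,
                     sstart = if (strand == 1L) lo + 1 else hi,
                     send = if (strand == 1L) hi else lo + 1,
                     evalue = 1e-80, bitscore = bit, stringsAsFactors = FALSE)
        }
        rows[[r]] <- mk_row(loc$chrom, loc$lo, loc$hi, strand)
        if (decoy) {
          dc <- sample.int(length(anc_lens), 1L)
          dpos <- floor(runif(1, 0, anc_lens[dc] - len))
          dstrand <- sample(c(-1L, 1L), 1L)
          rows[[r]] <- rbind(rows[[r]], mk_row(dc, dpos, dpos + len, dstrand))
        }
      }
    }
    list(alignments = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' @rdname emit_alignments
#' @param alignments alignment data.frame.
#' @param path output file.
#' @export
write_blast_tab <- function(alignments, path) {
  write.table(alignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## --- FASTA ---------------------------------------------------------------

#' Emit BES reads as FASTA
#'
#' Two records per clone, named `{clone}_T7` and `{clone}_SP6`; base
#' composition matches the configured GC fraction in expectation; lengths
#' follow the read-length law.  Sequences are random (no positional
#' realism): the emitter exists to exercise GC and read-length statistics.
#'
#' @param clones from [sample_clones()].
#' @param config a [sim_config()].
#' @param path optional output FASTA (wrapped at 60 columns).
#' @return A [Biostrings::DNAStringSet] (invisibly if `path` given).
#' @export
emit_bes_fasta <- function(clones, config, path = NULL) {
  n <- nrow(clones)
  with_seed(child_seed(config$seed, "fasta"), {
    ids <- as.vector(t(outer(clones$clone_id, c("T7", "SP6"), paste, sep = "_")))
    lens <- round(rtruncnorm(2L * n, config$read_len_mean, config$read_len_sd,
                             50, Inf))
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- vapply(lens, function(l)
      paste(sample(names(p), l, replace = TRUE, prob = p), collapse = ""), "")
    dss <- Biostrings::DNAStringSet(setNames(seqs, ids))
    if (!is.null(path)) {
      Biostrings::writeXStringSet(dss, path, width = 60L)
      return(invisible(dss))
    }
    dss
  })
}

## --- screening -----------------------------------------------------------

#' Simulate probe screening of the gridded library
#'
#' Hit counts per probe are i.i.d. Poisson with mean `depth` (the fold
#' coverage of the library); the long table lists one row per
#' (probe, clone) hit with synthetic clone ids.
#'
#' @param n_probes number of overgo probes.
#' @param depth expected clones per probe (fold coverage); must be >= 0.
#' @param seed RNG seed.
#' @return data.frame (probe_id factor over all probes, clone_id).
#' @export
simulate_screening <- function(n_probes, depth, seed = 1L) {
  if (depth < 0) stop("depth must be >= 0")
  with_seed(seed, {
    counts <- rpois(n_probes, depth)
    probes <- sprintf("P%03d", seq_len(n_probes))
    df <- data.frame(
      probe_id = factor(rep(probes, counts), levels = probes),
      clone_id = sprintf("SC%06d", seq_len(sum(counts))),
      stringsAsFactors = FALSE)
    df
  })
}

## --- marker table --------------------------------------------------------

#' Emit the FISH-style marker table of the derived genome
#'
#' Subsamples the marker grid to about one marker per `marker_spacing` bp
#' (always keeping at least one marker per derived chromosome) and reports,
#' per clone-like marker: query chromosome and integer rank (cytogenetic
#' style, orientation-free) plus target chromosome and bp position.  With
#' `tie_prob > 0`, adjacent rank pairs are collapsed to ties to emulate
#' unresolved FISH signals.
#'
#' @param derived,ancestor the genome pair.
#' @param config a [sim_config()].
#' @param tie_prob probability that two adjacent markers share a rank.
#' @param path optional TSV output.
#' @return data.frame (clone_id, query_chrom, query_rank, target_chrom,
#'   target_pos).
#' @export
emit_marker_table <- function(derived, ancestor, config, tie_prob = 0, path = NULL) {
  mk <- derived_markers(derived, ancestor)
  out <- vector("list", length(derived$segments))
  with_seed(child_seed(config$seed, "markers"), {
    for (ci in seq_along(derived$segments)) {
      m <- mk[mk$chrom == ci, ]
      if (nrow(m) == 0L) next
      m <- m[order(m$pos), ]
      keep <- logical(nrow(m))
      last <- -Inf
      for (j in seq_len(nrow(m))) {
        if (m$pos[j] - last >= config$marker_spacing || !any(keep)) {
          keep[j] <- TRUE
          last <- m$pos[j]
        }
      }
      m <- m[keep, ]
      rank <- seq_len(nrow(m))
      if (tie_prob > 0 && nrow(m) >= 2L) {
        for (j in 2:nrow(m)) if (runif(1) < tie_prob) rank[j] <- rank[j - 1L]
        rank <- as.integer(factor(rank, levels = unique(rank)))
      }
      out[[ci]] <- data.frame(
        clone_id = sprintf("MK%04d", m$marker_id),
        query_chrom = sprintf("V%d", ci),
        query_rank = rank,
        target_chrom = sprintf("chr%d", m$anc_chrom),
        target_pos = m$anc_pos,
        stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(clone_id = character(0), query_chrom = character(0),
                      query_rank = integer(0), target_chrom = character(0),
                      target_pos = numeric(0))
  rownames(res) <- NULL
  if (!is.null(path)) {
    write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}

## --- one-call orchestration ----------------------------------------------

#' Simulate a complete synthetic dataset
#'
#' Runs the generator end to end: ancestor, `config$n_events` random
#' rearrangements, clones, alignments, reads, screening and marker table.
#'
#' @param config a [sim_config()].
#' @return list with ancestor, derived, log, clones, alignments (+truth),
#'   reads, screening and markers.
#' @export
simulate_dataset <- function(config) {
  ancestor <- make_ancestor(config)
  ae <- apply_events(ancestor, k = config$n_events,
                     seed = child_seed(config$seed, "events"),
                     weights = config$event_weights)
  clones <- sample_clones(ae$derived, config)
  aln <- emit_alignments(clones, ae$derived, ancestor, config)
  reads <- emit_bes_fasta(clones, config)
  screening <- simulate_screening(54L, 10.2, seed = child_seed(config$seed, "screening"))
  markers <- emit_marker_table(ae$derived, ancestor, config)
  list(config = config, ancestor = ancestor, derived = ae$derived, log = ae$log,
       clones = clones, alignments = aln$alignments, truth = aln$truth,
       reads = reads, screening = screening, markers = markers)
}
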