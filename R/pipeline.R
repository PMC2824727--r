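## Pipeline orchestration: flat key=value config with a strict schema,
## staged execution (simulate -> anchor -> stats -> synteny -> distance) and
## a consolidated JSON report.

CONFIG_SCHEMA <- list(
  mode          = list(type = "choice", choices = c("synthetic", "real-input"), default = "synthetic"),
  seed          = list(type = "num", default = 1),
  outdir        = list(type = "chr", default = NA_character_),
  log_level     = list(type = "choice", choices = c("quiet", "info"), default = "info"),
  ## simulator
  n_chromosomes = list(type = "num", default = 5),
  chrom_lengths = list(type = "numvec", default = 150e6),
  n_markers     = list(type = "num", default = NA_real_),
  n_clones      = list(type = "num", default = 1000),
  n_events      = list(type = "num", default = 0),
  insert_mean   = list(type = "num", default = 139000),
  insert_min    = list(type = "num", default = 100000),
  insert_max    = list(type = "num", default = 200000),
  insert_sd     = list(type = "num", default = 25000),
  read_len_mean = list(type = "num", default = 728),
  read_len_sd   = list(type = "num", default = 100),
  gc            = list(type = "num", default = 0.418),
  p_unmapped    = list(type = "num", default = 0.5),
  p_multimap    = list(type = "num", default = 0.17),
  marker_spacing = list(type = "num", default = 30e6),
  tie_prob      = list(type = "num", default = 0),
  ## anchoring thresholds
  concordant_min = list(type = "num", default = 90000),
  concordant_max = list(type = "num", default = 200000),
  large_indel   = list(type = "num", default = 2e6),
  ## real-input paths
  alignments    = list(type = "chr", default = NA_character_),
  markers       = list(type = "chr", default = NA_character_),
  reads_fasta   = list(type = "chr", default = NA_character_),
  screening     = list(type = "chr", default = NA_character_),
  ## library arithmetic inputs (real-input mode)
  library_clones = list(type = "num", default = NA_real_),
  library_insert = list(type = "num", default = NA_real_),
  genome_size   = list(type = "num", default = NA_real_)
)

parse_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", ln, "'")
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Validate and default a pipeline configuration
#'
#' Accepts a flat key=value file (or a named list) against a strict schema:
#' unknown keys are errors, not warnings, and cross-field constraints
#' (threshold ordering, file existence in real-input mode) are checked.
#'
#' @param x config file path or named list.
#' @return list of class `run_config` with all keys defaulted.
#' @export
validate_config <- function(x = list()) {
  raw <- if (is.character(x) && length(x) == 1L) parse_flat_config(x) else as.list(x)
  unknown <- setdiff(names(raw), names(CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- list()
  for (key in names(CONFIG_SCHEMA)) {
    sch <- CONFIG_SCHEMA[[key]]
    val <- if (key %in% names(raw)) raw[[key]] else sch$default
    if (length(val) && !all(is.na(val))) {
      val <- switch(sch$type,
        num = {
          v <- suppressWarnings(as.numeric(val))
          if (anyNA(v)) stop("config key '", key, "' must be numeric, got '", val, "'")
          v
        },
        numvec = {
          v <- suppressWarnings(as.numeric(strsplit(paste(val, collapse = ","), ",")[[1]]))
          if (anyNA(v)) stop("config key '", key, "' must be a comma list of numbers")
          v
        },
        chr = as.character(val),
        choice = {
          v <- as.character(val)
          if (!v %in% sch$choices)
            stop("config key '", key, "' must be one of: ",
                 paste(sch$choices, collapse = ", "))
          v
        })
    }
    cfg[[key]] <- val
  }
  if (!(cfg$concordant_min < cfg$concordant_max && cfg$concordant_max < cfg$large_indel))
    stop("invalid thresholds: need concordant_min < concordant_max < large_indel")
  if (cfg$mode == "real-input") {
    for (key in c("alignments", "markers", "reads_fasta", "screening")) {
      p <- cfg[[key]]
      if (!is.na(p) && !file.exists(p))
        stop("config key '", key, "': file not found: ", p)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

run_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message("[bacmapr] ", ...)
  invisible(NULL)
}

run_stage <- function(cfg, name, expr) {
  run_log(cfg, "stage ", name)
  tryCatch(expr, error = function(e) {
    if (!is.na(cfg$outdir))
      writeLines(paste0("FAILED at stage ", name, ": ", conditionMessage(e)),
                 file.path(cfg$outdir, "FAILED"))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' In synthetic mode, generates a dataset with known ground truth, then
#' anchors clones, computes library statistics, builds the comparative map
#' and estimates the rearrangement distance, writing all artifacts plus a
#' JSON report; a truth-vs-called comparison is included.  In real-input
#' mode, stages whose inputs are absent are skipped.
#'
#' @param config a [validate_config()] result (or something coercible).
#' @return list of class `run_report`.
#' @export
run_full <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (!is.na(cfg$outdir) && !dir.exists(cfg$outdir))
    dir.create(cfg$outdir, recursive = TRUE)
  t0 <- Sys.time()
  thr <- thresholds(cfg$concordant_min, cfg$concordant_max, cfg$large_indel)
  report <- list(mode = cfg$mode, seed = cfg$seed,
                 config = unclass(cfg)[!vapply(unclass(cfg), function(v) all(is.na(v)), TRUE)])

  alignments <- reads <- screening <- markers <- NULL
  truth <- clones <- NULL

  if (cfg$mode == "synthetic") {
    sim <- run_stage(cfg, "simulate", {
      sc <- sim_config(
        n_chromosomes = cfg$n_chromosomes, chrom_lengths = cfg$chrom_lengths,
        n_markers = if (is.na(cfg$n_markers)) NULL else cfg$n_markers,
        n_clones = cfg$n_clones, insert_mean = cfg$insert_mean,
        insert_min = cfg$insert_min, insert_max = cfg$insert_max,
        insert_sd = cfg$insert_sd, read_len_mean = cfg$read_len_mean,
        read_len_sd = cfg$read_len_sd, gc = cfg$gc,
        p_unmapped = cfg$p_unmapped, p_multimap = cfg$p_multimap,
        marker_spacing = cfg$marker_spacing, n_events = cfg$n_events,
        seed = cfg$seed)
      simulate_dataset(sc)
    })
    alignments <- sim$alignments
    reads <- sim$reads
    screening <- sim$screening
    markers <- sim$markers
    truth <- sim$truth
    clones <- sim$clones
    report$simulate <- list(n_markers = nrow(sim$ancestor$markers),
                            n_clones = nrow(clones),
                            n_events = length(sim$log$events),
                            event_kinds = vapply(sim$log$events, function(e) e$kind, ""))
    if (!is.na(cfg$outdir)) {
      write_blast_tab(alignments, file.path(cfg$outdir, "alignments.tsv"))
      write.table(truth, file.path(cfg$outdir, "truth_reads.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(clones, file.path(cfg$outdir, "truth_clones.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      Biostrings::writeXStringSet(reads, file.path(cfg$outdir, "reads.fasta"), width = 60L)
      write.table(screening, file.path(cfg$outdir, "screening.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(markers, file.path(cfg$outdir, "markers.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(sim$log$events, file.path(cfg$outdir, "events.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  } else {
    if (!is.na(cfg$alignments))
      alignments <- run_stage(cfg, "read-alignments", parse_blast_tab(cfg$alignments))
    if (!is.na(cfg$reads_fasta)) reads <- cfg$reads_fasta
    if (!is.na(cfg$screening))
      screening <- run_stage(cfg, "read-screening",
                             read.delim(cfg$screening, stringsAsFactors = TRUE))
    if (!is.na(cfg$markers))
      markers <- run_stage(cfg, "read-markers", load_marker_table(cfg$markers))
  }

  if (!is.null(alignments)) {
    calls <- run_stage(cfg, "anchor", {
      cl <- anchor_clones(normalize_alignments(alignments), thr)
      if (!is.null(clones)) {
        ## clones whose reads all failed to map never reach the alignment
        ## table; they are no_anchor calls
        absent <- setdiff(clones$clone_id, cl$clone_id)
        if (length(absent))
          cl <- rbind(cl, data.frame(
            clone_id = absent, klass = "no_anchor", span = NA_real_,
            chrom_a = NA_character_, start_a = NA_real_, end_a = NA_real_,
            strand_a = NA_character_, chrom_b = NA_character_,
            start_b = NA_real_, end_b = NA_real_, strand_b = NA_character_,
            stringsAsFactors = FALSE))
      }
      cl[order(cl$clone_id), ]
    })
    report$anchor <- as.list(summarize_anchors(calls))
    report$anchor$n_clones_in <- length(unique(calls$clone_id))
    if (!is.na(cfg$outdir))
      write.table(calls, file.path(cfg$outdir, "anchor_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(truth) && !is.null(clones)) {
      cmp <- merge(calls, clones[, c("clone_id", "spans_breakpoint")], by = "clone_id")
      both <- cmp[!(cmp$klass %in% c("no_anchor", "single_end")), ]
      report$truth_comparison <- list(
        n_both_end = nrow(both),
        frac_concordant_unrearranged =
          if (any(!both$spans_breakpoint))
            mean(both$klass[!both$spans_breakpoint] == "concordant") else NA,
        frac_discordant_straddling =
          if (any(both$spans_breakpoint))
            mean(both$klass[both$spans_breakpoint] != "concordant") else NA)
    }
  }

  if (!is.null(reads) || !is.null(screening) ||
      (cfg$mode == "synthetic") || !is.na(cfg$library_clones)) {
    report$stats <- run_stage(cfg, "stats", {
      st <- list()
      if (!is.null(reads)) st$gc <- gc_fraction(reads)
      if (!is.null(screening)) st$screening_depth <- observed_depth(screening)
      if (cfg$mode == "synthetic") {
        st$library <- unclass(library_stats(cfg$n_clones, cfg$insert_mean,
                                            sum(rep_len(cfg$chrom_lengths, cfg$n_chromosomes))))
      } else if (!is.na(cfg$library_clones) && !is.na(cfg$library_insert) &&
                 !is.na(cfg$genome_size)) {
        st$library <- unclass(library_stats(cfg$library_clones, cfg$library_insert,
                                            cfg$genome_size))
      }
      st
    })
  }

  if (!is.null(markers) && nrow(markers) > 0L) {
    syn <- run_stage(cfg, "synteny", {
      blocks <- call_blocks(markers)
      list(blocks = blocks, correspondence = chromosome_correspondence(blocks),
           segmented = condense(markers))
    })
    report$synteny <- list(n_blocks = nrow(syn$blocks),
                           n_segments = n_segments(syn$segmented$genome_query),
                           n_ambiguous = length(syn$segmented$ambiguous_segments))
    if (!is.na(cfg$outdir)) {
      write_blocks_bed(syn$blocks, file.path(cfg$outdir, "blocks.tsv"))
      write_grimm(list(query = syn$segmented$genome_query,
                       target = syn$segmented$genome_target),
                  file.path(cfg$outdir, "genomes.grimm"))
    }
    report$distance <- run_stage(cfg, "distance", {
      sg <- syn$segmented
      opt <- optimize_ambiguous_signs(sg$genome_query, sg$genome_target,
                                      sg$ambiguous_segments)
      rep_ <- if (n_segments(opt$genome) <= 80L) {
        sc <- sorting_scenario(opt$genome, sg$genome_target)
        if (!is.na(cfg$outdir)) {
          steps <- data.frame(
            step = seq_along(sc$ops),
            kind = vapply(sc$ops, function(o) o$kind, ""),
            params = vapply(sc$ops, function(o)
              paste(names(o)[-1], unlist(o[-1]), sep = "=", collapse = " "), ""))
          write.table(steps, file.path(cfg$outdir, "scenario.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        }
        unclass(classify_scenario(sc))
      } else list(d = opt$distance)
      rep_$ambiguous_signs_flipped <- opt$flipped
      rep_$sign_search_approximate <- opt$approximate
      rep_
    })
  }

  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.na(cfg$outdir))
    jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  class(report) <- "run_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_alignments <- function(al) {
  if (inherits(al, "bes_alignment")) return(al)
  ## accept the simulator's raw BLAST columns
  if ("qseqid" %in% names(al)) {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    write_blast_tab(al, tmp)
    return(parse_blast_tab(tmp))
  }
  stop("unrecognised alignment input")
}

#' @export
print.run_report <- function(x, ...) {
  cat("bacmapr run report (mode:", x$mode, ", seed:", x$seed, ")\n")
  if (!is.null(x$anchor)) {
    cat("  anchoring: ")
    utils::str(x$anchor, give.attr = FALSE, indent.str = "    ")
  }
  if (!is.null(x$stats$library))
    cat(sprintf("  library: %.2fx coverage\n", x$stats$library$fold_coverage))
  if (!is.null(x$distance))
    cat(sprintf("  distance: %d (%d inversions, %d inter-chromosomal)\n",
                x$distance$d, x$distance$n_reversals %||% NA,
                x$distance$n_inter_chromosomal %||% NA))
  invisible(x)
}
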