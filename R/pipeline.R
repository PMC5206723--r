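#' Pipeline run configuration
#'
#' @param model A [transcript_model()].
#' @param sample_alignments Named list/vector: one SAM/BAM path or
#'   alignment data frame (as from [read_sam()]) per replicate.
#' @param genome Optional reference sequence, enabling the
#'   sequence-dependent stages (ambiguity flagging, NAGNAG, stop-codon
#'   screening, splice-site scoring).
#' @param out_dir Optional output directory.
#' @param min_reads,min_samples Replicate-consistency filter (defaults
#'   5 reads in 2 samples).
#' @param min_anchor Junction anchor requirement in nt (default 10).
#' @param max_shift Ambiguity scan range in nt (default 10).
#' @param seed Integer seed (stages are deterministic; the seed is
#'   recorded and used by any simulation step driven from the config).
#' @param precision Reporting precision in decimals (default 2).
#' @return List of class `run_config`.
#' @export
run_config <- function(model, sample_alignments, genome = NULL,
                       out_dir = NULL, min_reads = 5L, min_samples = 2L,
                       min_anchor = 10L, max_shift = 10L, seed = 1L,
                       precision = 2L) {
  stopifnot(min_reads >= 1L, min_samples >= 1L, min_anchor >= 1L,
            max_shift >= 0L, length(sample_alignments) >= 1L)
  structure(list(model = model, sample_alignments = sample_alignments,
                 genome = genome, out_dir = out_dir,
                 min_reads = as.integer(min_reads),
                 min_samples = as.integer(min_samples),
                 min_anchor = as.integer(min_anchor),
                 max_shift = as.integer(max_shift), seed = as.integer(seed),
                 precision = as.integer(precision)),
            class = "run_config")
}

#' Run the profiling pipeline end to end
#'
#' Stages: junction calling per replicate, novel-junction
#' classification and pseudoexon pairing, misalignment-ambiguity
#' exclusion, NAGNAG and reading-frame annotation, intron-centric
#' PSI/ASE quantification with the replicate-consistency filter, and a
#' QC report. Deterministic given the config.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result`: `events` (kept inventory),
#'   `excluded` (ambiguous events), `quant` (data frame from
#'   [quantify_events()]), `counts`, `coverage` (per sample), `qc`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  model <- config$model
  cj <- derive_canonical_junctions(model)
  samples <- seq_along(config$sample_alignments)
  counts <- list(); coverage <- list(); cooc <- list()
  reads_parsed <- integer(length(samples)); reads_skipped <- integer(length(samples))
  for (s in samples) {
    src <- config$sample_alignments[[s]]
    aln <- if (is.character(src)) read_sam(src) else src
    reads_parsed[s] <- nrow(aln)
    reads_skipped[s] <- if (!is.null(attr(aln, "n_skipped")))
      attr(aln, "n_skipped") else 0L
    counts[[s]] <- count_junctions(aln, config$min_anchor, s)
    coverage[[s]] <- coverage_profile(aln, model)
    cooc[[s]] <- cooccurrence_records(aln)
    message(sprintf("[call] sample %d: %d alignments, %d junctions, depth %.1f",
                    s, reads_parsed[s], nrow(counts[[s]]),
                    coverage[[s]]$mean))
  }
  counts <- do.call(rbind, counts)
  cooc <- do.call(rbind, cooc)
  key <- paste(counts$start, counts$end)
  ckey <- paste(cj$start, cj$end)
  novel <- unique(counts[!(key %in% ckey), c("start", "end")])
  rownames(novel) <- NULL
  message(sprintf("[annotate] %d distinct novel junctions", nrow(novel)))
  # misalignment-ambiguity exclusion happens before classification: a
  # junction whose shifted variant reproduces a canonical junction (or
  # another candidate) is an alignment artifact, not an event
  excluded <- list()
  if (!is.null(config$genome) && nrow(novel)) {
    amb <- logical(nrow(novel))
    ranges <- vector("list", nrow(novel))
    for (i in seq_len(nrow(novel))) {
      fl <- flag_ambiguous_junction(novel$start[i], novel$end[i],
                                    config$genome, model, config$max_shift,
                                    novel[-i, , drop = FALSE])
      amb[i] <- fl$ambiguous
      ranges[[i]] <- fl$shift_range
    }
    if (any(amb)) {
      excluded <- classify_junctions(novel[amb, , drop = FALSE], model)
      for (i in seq_along(excluded)) {
        excluded[[i]]$flags$ambiguous_alignment <- TRUE
        excluded[[i]]$flags$shift_range <- ranges[amb][[i]]
      }
      message(sprintf("[annotate] excluded %d shift-ambiguous junction(s)",
                      sum(amb)))
      novel <- novel[!amb, , drop = FALSE]
    }
  }
  events <- classify_junctions(novel, model)
  events <- detect_pseudoexons(events, model, cooc)
  quantifiable <- c("exon_skip", "pseudoexon", "alt3ss", "alt5ss")
  cats <- vapply(events, `[[`, character(1), "category")
  events <- events[cats %in% quantifiable]
  if (!is.null(config$genome)) {
    for (i in seq_along(events)) {
      ev <- events[[i]]
      if (ev$category == "alt3ss" && abs(ev$offset_nt) == 3L)
        ev <- detect_nagnag(ev, model, config$genome)
      ins <- NULL
      if (ev$category == "pseudoexon")
        ins <- txn_window(config$genome, model,
                          if (model$strand == "+") ev$pe_start else ev$pe_end,
                          0L, ev$pe_length)
      events[[i]] <- predict_reading_frame(ev, model, ins)
    }
  } else {
    events <- lapply(events, function(ev)
      suppressWarnings(predict_reading_frame(ev, model)))
  }
  quant <- if (length(events))
    quantify_events(events, counts, model, config$min_reads,
                    config$min_samples)
  else NULL
  canon_counts <- counts[key %in% ckey & counts$count > 0L, ]
  qc <- list(
    n_samples = length(samples),
    reads_parsed = reads_parsed,
    reads_skipped = reads_skipped,
    coverage_mean = vapply(coverage, `[[`, numeric(1), "mean"),
    coverage_sd = vapply(coverage, `[[`, numeric(1), "sd"),
    canonical_expected = nrow(cj),
    canonical_detected = length(unique(paste(canon_counts$start,
                                             canon_counts$end))),
    excluded_ambiguous = vapply(excluded, event_label, character(1)),
    zero_coverage = all(vapply(coverage, `[[`, numeric(1), "mean") == 0))
  message(sprintf("[qc] canonical junctions detected: %d/%d",
                  qc$canonical_detected, qc$canonical_expected))
  res <- structure(list(events = events, excluded = excluded,
                        quant = quant, counts = counts,
                        coverage = coverage, qc = qc, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  passing <- if (!is.null(x$quant)) sum(x$quant$passes_filter) else 0L
  cat(sprintf(paste0("<pipeline_result> %d samples, %d event(s) ",
                     "(%d passing filter), %d excluded as ambiguous\n"),
              x$qc$n_samples, length(x$events), passing,
              length(x$excluded)))
  invisible(x)
}

# Flatten the event list to a data frame for reports.
events_table <- function(events, precision = 2L) {
  if (!length(events))
    return(data.frame(event = character(0), category = character(0),
                      delta_nt = integer(0), frame = character(0),
                      flags = character(0)))
  data.frame(
    event = vapply(events, event_label, character(1)),
    event_id = vapply(events, `[[`, character(1), "event_id"),
    category = vapply(events, `[[`, character(1), "category"),
    delta_nt = as.integer(vapply(events, function(e)
      as.numeric(e$delta_nt), numeric(1))),
    frame = vapply(events, `[[`, character(1), "frame"),
    flags = vapply(events, function(e) {
      f <- e$flags[vapply(e$flags, isTRUE, logical(1))]
      if (length(f)) paste(names(f), collapse = ",") else ""
    }, character(1)))
}

#' Render the final report tables
#'
#' Event-inventory table (event name with size note, mean ASE%,
#' predicted reading frame) and, when orthogonal validation summaries
#' are supplied, a side-by-side concordance table.
#'
#' @param result A `pipeline_result`, or a list with `events` and
#'   `quant`.
#' @param validation Optional named list of data frames (`event_id`,
#'   `mean`, `sd`) from orthogonal assays, passed to
#'   [concordance_table()].
#' @param precision Decimals for reported percentages (default 2).
#' @return List with `inventory` (data frame) and optionally
#'   `concordance`.
#' @export
make_report <- function(result, validation = NULL, precision = 2L) {
  ev <- events_table(result$events, precision)
  if (!is.null(result$quant) && nrow(ev)) {
    idx <- match(ev$event_id, result$quant$event_id)
    ev$mean_ase <- round(result$quant$mean_ase[idx], precision)
    ev$sd_ase <- round(result$quant$sd_ase[idx], precision)
    ev$passes_filter <- result$quant$passes_filter[idx]
  } else if (nrow(ev)) {
    ev$mean_ase <- NA_real_; ev$sd_ase <- NA_real_
    ev$passes_filter <- NA
  } else {
    ev$mean_ase <- numeric(0); ev$sd_ase <- numeric(0)
    ev$passes_filter <- logical(0)
  }
  inventory <- ev[, c("event", "category", "delta_nt", "mean_ase",
                      "sd_ase", "frame", "passes_filter", "flags")]
  out <- list(inventory = inventory)
  if (!is.null(validation) && nrow(ev)) {
    rs <- data.frame(event_id = ev$event_id, mean = ev$mean_ase,
                     sd = ev$sd_ase)
    out$concordance <- do.call(concordance_table, c(list(rs), validation))
  }
  out
}

# Write the standard output files of a run.
write_pipeline_outputs <- function(res) {
  cfg <- res$config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  rep <- make_report(res, precision = cfg$precision)
  utils::write.table(rep$inventory, p("events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rep$inventory, p("events.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$quant))
    utils::write.table(res$quant, p("quant.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$qc, p("qc.json"), auto_unbox = TRUE, digits = NA)
  cj <- derive_canonical_junctions(cfg$model)
  write_junctions_bed(cj, p("junctions.bed"), cfg$model$chrom,
                      cfg$model$strand)
  write_junction_tsv(res$counts, p("junction_counts.tsv"),
                     cfg$model$chrom, cfg$model$strand)
  for (s in seq_along(res$coverage))
    write_bedgraph(res$coverage[[s]],
                   p(sprintf("coverage_sample%d.bedGraph", s)),
                   cfg$model$name)
  invisible(cfg$out_dir)
}
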