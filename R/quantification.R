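# Look up a junction count in a (start, end, sample, count) table;
# absent rows count 0.
jc_lookup <- function(counts, start, end, sample_id) {
  hit <- counts$start == start & counts$end == end &
    counts$sample == sample_id
  if (any(hit)) sum(counts$count[hit]) else 0L
}

#' Intron-centric PSI of one event in one sample
#'
#' Percent-spliced-in from junction-spanning read counts only.
#' Single-junction events (alternative 3'/5' splice sites):
#' `psi = i / (i + e)` with `i` the canonical competing junction and
#' `e` the alternative junction. Two-junction events: for exon skips
#' `psi = (i1 + i2) / (i1 + i2 + 2 e)` with `i1`,`i2` the canonical
#' junctions flanking the skipped block and `e` the skip junction; for
#' pseudoexons the orientation flips (`i1`,`i2` are the two pseudoexon
#' junctions, `e` the unbroken host-intron junction), so PSI is the
#' inclusion fraction of the element in every category.
#'
#' @param event A classified `splicing_event`.
#' @param counts Junction count table (`start`, `end`, `sample`,
#'   `count`).
#' @param model A [transcript_model()].
#' @param sample_id Sample to evaluate.
#' @return List: `psi` (NA when the denominator is 0), `inclusion`,
#'   `exclusion` read counts, `support` (per-sample count used by the
#'   replicate filter: the alternative junction count, for pseudoexons
#'   the minimum of the two).
#' @export
compute_psi <- function(event, counts, model, sample_id) {
  cj <- derive_canonical_junctions(model)
  cnt <- function(s, e) jc_lookup(counts, s, e, sample_id)
  if (event$category %in% c("alt3ss", "alt5ss")) {
    k <- if (event$category == "alt3ss") event$exon - 1L else event$exon
    i <- cnt(cj$start[k], cj$end[k])
    e <- cnt(event$junctions$start, event$junctions$end)
    psi <- if (i + e > 0) i / (i + e) else NA_real_
    return(list(psi = psi, inclusion = i, exclusion = e, support = e))
  }
  if (event$category == "exon_skip") {
    K <- min(event$exons_skipped); J <- max(event$exons_skipped)
    i1 <- cnt(cj$start[K - 1L], cj$end[K - 1L])
    i2 <- cnt(cj$start[J], cj$end[J])
    e <- cnt(event$junctions$start, event$junctions$end)
    denom <- i1 + i2 + 2 * e
    psi <- if (denom > 0) (i1 + i2) / denom else NA_real_
    return(list(psi = psi, inclusion = i1 + i2, exclusion = e, support = e))
  }
  if (event$category == "pseudoexon") {
    k <- event$intron_index
    i1 <- cnt(event$junctions$start[1L], event$junctions$end[1L])
    i2 <- cnt(event$junctions$start[2L], event$junctions$end[2L])
    e <- cnt(cj$start[k], cj$end[k])
    denom <- i1 + i2 + 2 * e
    psi <- if (denom > 0) (i1 + i2) / denom else NA_real_
    return(list(psi = psi, inclusion = i1 + i2, exclusion = e,
                support = min(i1, i2)))
  }
  stop(sprintf("cannot quantify category '%s'", event$category))
}

#' Convert PSI to the reported ASE percentage
#'
#' `ASE% = (1 - PSI) * 100` for exon skipping and alternative splice
#' sites; `ASE% = PSI * 100` for pseudoexon inclusion: in every
#' category the ASE is the abundance of the minor, alternative form.
#'
#' @param category Event category string.
#' @param psi PSI in `[0, 1]` (NA propagates).
#' @return ASE as a percentage.
#' @export
psi_to_ase_percent <- function(category, psi) {
  if (is.na(psi)) return(NA_real_)
  stopifnot(psi >= 0, psi <= 1)
  if (category == "pseudoexon") psi * 100 else (1 - psi) * 100
}

#' Replicate-consistency filter
#'
#' Admits an event only when it is consistently detected: at least
#' `min_reads` supporting reads (inclusive threshold) in at least
#' `min_samples` replicates.
#'
#' @param support Integer vector of per-sample supporting read counts.
#' @param min_reads Count threshold (default 5).
#' @param min_samples Replicate threshold (default 2).
#' @return Logical.
#' @export
replicate_filter <- function(support, min_reads = 5L, min_samples = 2L) {
  sum(support >= min_reads, na.rm = TRUE) >= min_samples
}

#' Mean and SD of per-sample ASE values
#'
#' Arithmetic mean and sample SD (n - 1 denominator) over samples with
#' a defined value; undefined samples are excluded, not imputed. A
#' single defined sample yields `sd = 0` by convention.
#'
#' @param ase Numeric vector of per-sample ASE percentages (NAs
#'   allowed).
#' @return List with `mean`, `sd`, `n`.
#' @export
summarize_across_samples <- function(ase) {
  v <- ase[!is.na(ase)]
  if (!length(v)) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
       n = length(v))
}

#' Theoretical detection limit of the junction-read depth
#'
#' The smallest ASE percentage expected to yield more than `min_reads`
#' supporting reads at a given mean depth: `min_reads / depth * 100`.
#'
#' @param mean_depth Mean junction-spanning read depth per base.
#' @param min_reads Reads considered reliable (default 10).
#' @return ASE percentage.
#' @export
detection_limit <- function(mean_depth, min_reads = 10) {
  stopifnot(mean_depth > 0)
  min_reads / mean_depth * 100
}

#' Expected supporting reads for an event rate
#'
#' Companion of [detection_limit()]: the expected read count at a
#' given depth, and whether it clears the reliability threshold.
#'
#' @param ase_percent Event level as ASE percentage.
#' @param mean_depth Mean read depth.
#' @param min_reads Reliability threshold (default 10; strict
#'   inequality).
#' @return List with `expected` and `detectable`.
#' @export
expected_reads <- function(ase_percent, mean_depth, min_reads = 10) {
  expected <- ase_percent / 100 * mean_depth
  list(expected = expected, detectable = expected > min_reads)
}

#' Isoform ratios from fluorescent peak areas
#'
#' Orthogonal-validation arithmetic for capillary fragment analysis
#' (or gel densitometry): per replicate, each isoform's ratio is its
#' peak area over the total area of the detected isoforms, times 100
#' (ratios sum to 100 exactly); ratios are then summarized across
#' replicates as mean +/- SD.
#'
#' @param peaks Data frame with columns `replicate`, `isoform`, `area`
#'   (areas >= 0; >= 2 isoforms per replicate).
#' @return List: `per_replicate` (data frame with `ratio`), `summary`
#'   (data frame: `isoform`, `mean`, `sd`, `n`).
#' @export
isoform_ratio_from_peaks <- function(peaks) {
  stopifnot(all(peaks$area >= 0))
  out <- do.call(rbind, lapply(split(peaks, peaks$replicate), function(p) {
    if (nrow(p) < 2L)
      stop(sprintf("replicate %s has fewer than 2 isoforms", p$replicate[1L]))
    tot <- sum(p$area)
    if (tot <= 0) stop(sprintf("replicate %s has zero total peak area",
                               p$replicate[1L]))
    p$ratio <- p$area / tot * 100
    p
  }))
  rownames(out) <- NULL
  sm <- do.call(rbind, lapply(split(out, out$isoform), function(x)
    data.frame(isoform = x$isoform[1L], mean = mean(x$ratio),
               sd = if (nrow(x) > 1L) stats::sd(x$ratio) else 0,
               n = nrow(x))))
  rownames(sm) <- NULL
  list(per_replicate = out, summary = sm)
}

#' Side-by-side concordance of sequencing and orthogonal assays
#'
#' Formats the validation comparison: sequencing-based ASE mean +/- SD
#' against each orthogonal technique, with absolute differences;
#' events missing from an assay are rendered `"nd"` (not detected).
#'
#' @param rnaseq Data frame with `event_id`, `mean`, `sd`.
#' @param ... Named data frames of the same shape, one per technique
#'   (e.g. `gel = ..., fragment = ...`).
#' @return Data frame: `event_id`, `rnaseq`, one formatted column and
#'   one `diff_` column per technique.
#' @export
concordance_table <- function(rnaseq, ...) {
  assays <- list(...)
  fmt <- function(m, s) ifelse(is.na(m), "nd",
                               sprintf("%.2f (+/-%.2f)", m, s))
  out <- data.frame(event_id = rnaseq$event_id,
                    rnaseq = fmt(rnaseq$mean, rnaseq$sd))
  for (nm in names(assays)) {
    a <- assays[[nm]]
    idx <- match(rnaseq$event_id, a$event_id)
    out[[nm]] <- fmt(a$mean[idx], a$sd[idx])
    out[[paste0("diff_", nm)]] <- round(abs(a$mean[idx] - rnaseq$mean), 2)
  }
  out
}

#' Quantify, filter and summarize a set of events
#'
#' Applies [compute_psi()] and [psi_to_ase_percent()] per sample,
#' the replicate-consistency filter on the supporting counts, and
#' [summarize_across_samples()].
#'
#' @param events List of classified `splicing_event`s (categories
#'   `exon_skip`, `pseudoexon`, `alt3ss`, `alt5ss`).
#' @param counts Junction count table with rows from all samples.
#' @param model A [transcript_model()].
#' @param min_reads,min_samples Filter thresholds (defaults 5 and 2).
#' @return Data frame (one row per event): `event_id`, `category`,
#'   `delta_nt`, per-sample `psi_<s>` and `ase_<s>` columns,
#'   `mean_ase`, `sd_ase`, `passes_filter`.
#' @export
quantify_events <- function(events, counts, model, min_reads = 5L,
                            min_samples = 2L) {
  samples <- sort(unique(counts$sample))
  rows <- lapply(events, function(ev) {
    q <- lapply(samples, function(s) compute_psi(ev, counts, model, s))
    psi <- vapply(q, `[[`, numeric(1), "psi")
    ase <- vapply(psi, function(p) psi_to_ase_percent(ev$category, p),
                  numeric(1))
    support <- vapply(q, `[[`, numeric(1), "support")
    sm <- summarize_across_samples(ase)
    row <- data.frame(event_id = ev$event_id, category = ev$category,
                      delta_nt = ev$delta_nt)
    for (i in seq_along(samples)) {
      row[[sprintf("psi_%d", samples[i])]] <- psi[i]
      row[[sprintf("ase_%d", samples[i])]] <- ase[i]
      row[[sprintf("support_%d", samples[i])]] <- support[i]
    }
    row$mean_ase <- sm$mean
    row$sd_ase <- sm$sd
    row$passes_filter <- replicate_filter(support, min_reads, min_samples)
    row
  })
  do.call(rbind, rows)
}
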