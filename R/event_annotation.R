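#' Classify a novel junction against the transcript model
#'
#' Exhaustive, mutually exclusive classification of a genomic junction
#' interval: `canonical`; `exon_skip` (both ends at canonical sites
#' with >= 1 exon omitted); `alt3ss` (canonical donor, acceptor
#' displaced into the downstream exon; exonic displacement is negative,
#' the reported convention); `alt5ss` (the symmetric donor case);
#' `pseudoexon_half` (one canonical end, the other strictly inside the
#' intron -- resolved into full events by [detect_pseudoexons()]); or
#' `unclassified`.
#'
#' @param start,end Genomic intron interval (0-based half-open, plus
#'   strand).
#' @param model A [transcript_model()].
#' @return A list of class `splicing_event` (partial for halves):
#'   `event_id`, `category`, and per category `exons_skipped`,
#'   `offset_nt`, `delta_nt`, `intron_index`, `side`, `junctions`.
#' @export
classify_junction <- function(start, end, model) {
  start <- as.integer(start); end <- as.integer(end)
  cj <- derive_canonical_junctions(model)
  ex <- model$exons
  plus <- model$strand == "+"
  donor <- if (plus) start else end
  acceptor <- if (plus) end else start
  D <- cj$donor_pos; A <- cj$acceptor_pos
  dk <- match(donor, D); ak <- match(acceptor, A)
  jdf <- data.frame(start = start, end = end)
  base <- structure(list(event_id = NA_character_, category = "unclassified",
                         junctions = jdf, delta_nt = NA_integer_,
                         frame = "unknown", flags = list()),
                    class = "splicing_event")
  span <- c(min(ex$gstart), max(ex$gend))
  if (start < span[1L] || end > span[2L]) {
    base$reason <- "outside transcript span"
    return(base)
  }
  if (!is.na(dk) && !is.na(ak)) {
    if (ak == dk) { base$category <- "canonical"; base$event_id <- cj$label[dk]
      return(base) }
    if (ak > dk) {
      skipped <- (dk + 1L):ak
      base$category <- "exon_skip"
      base$exons_skipped <- skipped
      base$event_id <- paste0("del", paste(skipped, collapse = "+"))
      base$delta_nt <- -sum(ex$length[skipped])
      return(base)
    }
    base$reason <- "acceptor upstream of donor"
    return(base)
  }
  if (!is.na(dk) && is.na(ak)) {
    # canonical donor of intron dk; where is the acceptor?
    can_acc <- A[dk]
    dn_exon <- ex[dk + 1L, ]
    inside_exon <- if (plus)
      acceptor > dn_exon$gstart & acceptor < dn_exon$gend
    else
      acceptor > dn_exon$gstart & acceptor < dn_exon$gend
    inside_intron <- acceptor > cj$start[dk] & acceptor < cj$end[dk]
    if (inside_exon) {
      disp <- if (plus) acceptor - dn_exon$gstart else dn_exon$gend - acceptor
      base$category <- "alt3ss"
      base$offset_nt <- -disp
      base$delta_nt <- -disp
      base$exon <- dn_exon$index
      base$event_id <- sprintf("a3ss_ex%d", dn_exon$index)
      return(base)
    }
    if (inside_intron) {
      base$category <- "pseudoexon_half"
      base$side <- "donor_side"
      base$intron_index <- cj$intron_index[dk]
      return(base)
    }
    base$reason <- "acceptor beyond downstream exon"
    return(base)
  }
  if (is.na(dk) && !is.na(ak)) {
    up_exon <- ex[ak, ]
    inside_exon <- donor > up_exon$gstart & donor < up_exon$gend
    inside_intron <- donor > cj$start[ak] & donor < cj$end[ak]
    if (inside_exon) {
      disp <- if (plus) up_exon$gend - donor else donor - up_exon$gstart
      base$category <- "alt5ss"
      base$offset_nt <- -disp
      base$delta_nt <- -disp
      base$exon <- up_exon$index
      base$event_id <- sprintf("a5ss_ex%d", up_exon$index)
      return(base)
    }
    if (inside_intron) {
      base$category <- "pseudoexon_half"
      base$side <- "acceptor_side"
      base$intron_index <- cj$intron_index[ak]
      return(base)
    }
    base$reason <- "donor beyond upstream exon"
    return(base)
  }
  base$reason <- "no canonical end"
  base
}

#' @export
print.splicing_event <- function(x, ...) {
  cat(sprintf("<splicing_event> %s [%s] delta %s nt, frame %s\n",
              if (is.na(x$event_id)) "?" else x$event_id, x$category,
              if (is.na(x$delta_nt)) "?" else x$delta_nt, x$frame))
  invisible(x)
}

#' Classify a table of junctions
#'
#' @param junctions Data frame with `start`, `end` columns.
#' @param model A [transcript_model()].
#' @return List of `splicing_event` (one per row).
#' @export
classify_junctions <- function(junctions, model) {
  lapply(seq_len(nrow(junctions)), function(i)
    classify_junction(junctions$start[i], junctions$end[i], model))
}

#' Pair pseudoexon half-junctions into full events
#'
#' A pseudoexon is realized by two novel junctions inside one host
#' intron: canonical donor to intronic acceptor, and intronic donor to
#' canonical acceptor. Halves are paired per intron (in transcription
#' order when several occur); unpaired halves are left as they are.
#' `single_read_verified` is set only when at least one read crosses
#' both junctions, i.e. the whole pseudoexon is contained in a single
#' read.
#'
#' @param events List of `splicing_event` as from
#'   [classify_junctions()]; non-half events pass through untouched.
#' @param model A [transcript_model()].
#' @param cooccurrence Optional data frame from
#'   [cooccurrence_records()].
#' @return List of `splicing_event` with halves replaced by paired
#'   `pseudoexon` events (appended after the pass-through events).
#' @export
detect_pseudoexons <- function(events, model, cooccurrence = NULL) {
  is_half <- vapply(events, function(e) e$category == "pseudoexon_half",
                    logical(1))
  keep <- events[!is_half]
  halves <- events[is_half]
  if (!length(halves)) return(keep)
  plus <- model$strand == "+"
  introns <- vapply(halves, `[[`, integer(1), "intron_index")
  for (k in unique(introns)) {
    dh <- halves[introns == k &
                   vapply(halves, `[[`, character(1), "side") == "donor_side"]
    ah <- halves[introns == k &
                   vapply(halves, `[[`, character(1), "side") == "acceptor_side"]
    npair <- min(length(dh), length(ah))
    if (npair == 0L) { keep <- c(keep, halves[introns == k]); next }
    # transcription-order pairing
    ord_d <- order(vapply(dh, function(e)
      if (plus) e$junctions$end else -e$junctions$start, numeric(1)))
    ord_a <- order(vapply(ah, function(e)
      if (plus) e$junctions$start else -e$junctions$end, numeric(1)))
    dh <- dh[ord_d]; ah <- ah[ord_a]
    for (p in seq_len(npair)) {
      j1 <- dh[[p]]$junctions; j2 <- ah[[p]]$junctions
      if (plus) { pe_start <- j1$end; pe_end <- j2$start }
      else      { pe_start <- j2$end; pe_end <- j1$start }
      if (pe_end <= pe_start) { keep <- c(keep, dh[p], ah[p]); next }
      verified <- FALSE
      if (!is.null(cooccurrence) && nrow(cooccurrence)) {
        key <- paste(cooccurrence$start, cooccurrence$end)
        r1 <- cooccurrence$read_id[key == paste(j1$start, j1$end)]
        r2 <- cooccurrence$read_id[key == paste(j2$start, j2$end)]
        verified <- length(intersect(r1, r2)) > 0L
      }
      suffix <- if (npair > 1L) letters[p] else "a"
      ev <- structure(list(
        event_id = sprintf("PE%d%s", k, suffix),
        category = "pseudoexon",
        intron_index = k,
        pe_start = pe_start, pe_end = pe_end,
        pe_length = pe_end - pe_start,
        junctions = rbind(j1, j2),
        delta_nt = pe_end - pe_start,
        frame = "unknown",
        flags = list(single_read_verified = verified)),
        class = "splicing_event")
      keep <- c(keep, list(ev))
    }
    if (length(dh) > npair) keep <- c(keep, dh[(npair + 1L):length(dh)])
    if (length(ah) > npair) keep <- c(keep, ah[(npair + 1L):length(ah)])
  }
  keep
}

# Transcription-oriented sequence window around an exon's acceptor
# boundary: `left` intronic bases then `right` exonic bases.
acceptor_window <- function(model, genome, exon_index, left = 3L, right = 3L) {
  seqc <- genome_sequence(genome, model$chrom)
  ex <- model$exons[exon_index, ]
  if (model$strand == "+") {
    substr(seqc, ex$gstart - left + 1L, ex$gstart + right)
  } else {
    revcomp(substr(seqc, ex$gend - right + 1L, ex$gend + left))
  }
}

#' Flag a NAGNAG tandem acceptor on an alt-3'ss event
#'
#' For an alternative acceptor exactly 3 nt into the exon, tests the
#' 6-mer spanning the canonical 3' splice site (intron -3..-1, exon
#' +1..+3 in transcription orientation) for the NAGNAG motif: two AG
#' acceptors 3 nt apart.
#'
#' @param event An `alt3ss` `splicing_event` with `offset_nt == -3`.
#' @param model A [transcript_model()].
#' @param genome Reference sequence; if `NULL` the flag is set to `NA`.
#' @return The event with `flags$nagnag` set (TRUE/FALSE/NA).
#' @export
detect_nagnag <- function(event, model, genome = NULL) {
  if (event$category != "alt3ss" || abs(event$offset_nt) != 3L)
    stop("NAGNAG evaluation requires an alt3ss event with |offset| == 3")
  if (is.null(genome)) {
    event$flags$nagnag <- NA
    message("no genomic sequence: NAGNAG flag unknown")
    return(event)
  }
  w <- acceptor_window(model, genome, event$exon, 3L, 3L)
  event$flags$nagnag <- grepl("^.AG.AG$", w)
  event
}

#' Shift-ambiguity of a junction
#'
#' Computes the maximal interval of shifts `s` (|s| <= `max_shift`)
#' such that sliding both intron ends by `s` yields an identical
#' spliced sequence -- the misalignment hazard created by homopolymers
#' and boundary-straddling repeats. The junction is flagged when any
#' shifted variant coincides with a canonical junction or another
#' candidate junction; flagged events are excluded from the final
#' inventory and reported separately.
#'
#' @param start,end Junction interval (0-based half-open, plus strand).
#' @param genome Reference sequence.
#' @param model A [transcript_model()].
#' @param max_shift Largest shift scanned (default 10 nt).
#' @param candidates Optional data frame (`start`, `end`) of other
#'   candidate junctions to test coincidence against.
#' @return List: `shift_range` (`c(left, right)`, non-positive /
#'   non-negative extents; `c(0, 0)` means unambiguous), `width`
#'   (number of non-zero equivalent shifts), `ambiguous` (logical),
#'   `coincides` (data frame of coinciding junctions).
#' @export
flag_ambiguous_junction <- function(start, end, genome, model,
                                    max_shift = 10L, candidates = NULL) {
  ch <- strsplit(genome_sequence(genome, model$chrom), "")[[1L]]
  right <- 0L
  while (right < max_shift && end + right + 1L <= length(ch) &&
         ch[start + right + 1L] == ch[end + right + 1L]) right <- right + 1L
  left <- 0L
  while (left < max_shift && start - left >= 1L &&
         ch[start - left] == ch[end - left]) left <- left + 1L
  shifts <- setdiff(seq.int(-left, right), 0L)
  cj <- derive_canonical_junctions(model)
  targets <- cj[, c("start", "end")]
  if (!is.null(candidates))
    targets <- rbind(targets, candidates[, c("start", "end")])
  coincides <- data.frame(start = integer(0), end = integer(0),
                          shift = integer(0))
  for (s in shifts) {
    hit <- targets$start == start + s & targets$end == end + s
    if (any(hit))
      coincides <- rbind(coincides,
                         data.frame(start = start + s, end = end + s,
                                    shift = s))
  }
  list(shift_range = c(-left, right), width = left + right,
       ambiguous = nrow(coincides) > 0L, coincides = coincides)
}

#' Predict the reading-frame consequence of an event
#'
#' Length arithmetic first: a length change not divisible by 3 is
#' frame-shifting. Frame-preserving insertions are additionally
#' screened for stop codons read in the transcript frame when the
#' inserted sequence is supplied; without sequence the call is
#' length-only and flagged as such. Events entirely upstream of the
#' CDS start are non-coding (`unknown`).
#'
#' @param event A `splicing_event` with `delta_nt` set.
#' @param model A [transcript_model()].
#' @param inserted_seq Optional inserted (pseudoexon) sequence in
#'   transcription orientation.
#' @return The event with `frame` set to one of `in_frame`,
#'   `out_of_frame`, `out_of_frame_stop`, `unknown`, and
#'   `flags$frame_length_only` when an insertion was judged without
#'   sequence.
#' @export
predict_reading_frame <- function(event, model, inserted_seq = NULL) {
  if (is.na(event$delta_nt)) stop("event has no delta_nt")
  cds <- model$cds_start_mrna
  ex <- model$exons
  m_end <- switch(event$category,
    exon_skip = ex$mend[max(event$exons_skipped)],
    alt3ss = ex$mstart[event$exon] + abs(event$offset_nt),
    alt5ss = ex$mend[event$exon],
    pseudoexon = ex$mend[event$intron_index],
    NA_integer_)
  if (is.na(m_end)) { event$frame <- "unknown"; return(event) }
  if (m_end <= cds) { event$frame <- "unknown"; return(event) }
  if (event$delta_nt %% 3L != 0L) {
    event$frame <- "out_of_frame"
    return(event)
  }
  if (event$delta_nt <= 0L) {            # frame-preserving deletion
    event$frame <- "in_frame"
    return(event)
  }
  # frame-preserving insertion
  if (is.null(inserted_seq)) {
    event$frame <- "in_frame"
    event$flags$frame_length_only <- TRUE
    warning("insertion judged by length only: no sequence supplied")
    return(event)
  }
  m_ins <- ex$mend[event$intron_index]   # insertion point
  phase <- (m_ins - cds) %% 3L
  o0 <- (3L - phase) %% 3L               # first full codon inside insert
  stops <- c("TAA", "TAG", "TGA")
  offs <- seq.int(o0, nchar(inserted_seq) - 3L, by = 3L)
  codons <- substring(inserted_seq, offs + 1L, offs + 3L)
  event$frame <- if (any(codons %in% stops)) "out_of_frame_stop"
                 else "in_frame"
  event
}

#' Codons removed by a frame-preserving deletion
#'
#' @param delta_nt Signed length change (must be a negative multiple
#'   of 3).
#' @return Integer codon count.
#' @export
codons_removed <- function(delta_nt) {
  stopifnot(delta_nt < 0L, delta_nt %% 3L == 0L)
  as.integer(abs(delta_nt) / 3L)
}

#' Both notations of an alternative splice-site offset
#'
#' An exonic alternative acceptor can be written as the truncation it
#' causes (e.g. -60 nt) or as the exonic position of the new acceptor
#' (e.g. "+59", counting the last truncated base 0-based); the two
#' differ by one and must not be conflated.
#'
#' @param offset_nt Signed truncation (negative).
#' @return List with `truncation_nt` and `acceptor_position`.
#' @export
alt_ss_notations <- function(offset_nt) {
  stopifnot(offset_nt < 0L)
  list(truncation_nt = as.integer(offset_nt),
       acceptor_position = as.integer(abs(offset_nt) - 1L))
}

#' Human-readable event label
#'
#' Renders the reported naming style: `del9` / `del28+29`,
#' `PE1a (162 nt)`, `3'ss exon 54 (-3 nt)`, `5'ss exon 7 (-4 nt)`.
#'
#' @param event A `splicing_event`.
#' @return Character label.
#' @export
event_label <- function(event) {
  switch(event$category,
    exon_skip = paste0("del", paste(event$exons_skipped, collapse = "+")),
    pseudoexon = sprintf("%s (%d nt)", event$event_id, event$pe_length),
    alt3ss = sprintf("3'ss exon %d (%d nt)", event$exon, event$offset_nt),
    alt5ss = sprintf("5'ss exon %d (%d nt)", event$exon, event$offset_nt),
    canonical = event$event_id,
    "unclassified")
}
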