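#' Read spliced alignments from SAM (or BAM)
#'
#' Parses the mandatory SAM fields. Unmapped records (flag 0x4) and
#' secondary/supplementary alignments (0x100/0x800) are dropped and
#' counted. BAM input is converted through [Rsamtools::asSam()] when
#' that package is installed.
#'
#' @param path SAM or BAM file.
#' @return Data frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based), `mapq`, `cigar`, and attribute `n_skipped` (unmapped or
#'   secondary records dropped).
#' @export
read_sam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("BAM input needs the Rsamtools package")
    path <- paste0(Rsamtools::asSam(path, tempfile()), "")
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(structure(data.frame(qname = character(0), flag = integer(0),
                                rname = character(0), pos = integer(0),
                                mapq = integer(0), cigar = character(0)),
                     n_skipped = 0L))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop(sprintf("malformed SAM record at line %d (%d fields < 11)",
                 which(nf < 11L)[1L], nf[nf < 11L][1L]))
  g <- function(i) vapply(fields, `[[`, character(1), i)
  aln <- data.frame(qname = g(1L), flag = as.integer(g(2L)), rname = g(3L),
                    pos = as.integer(g(4L)), mapq = as.integer(g(5L)),
                    cigar = g(6L))
  drop <- bitwAnd(aln$flag, 0x4L) != 0L |
    bitwAnd(aln$flag, 0x100L) != 0L |
    bitwAnd(aln$flag, 0x800L) != 0L |
    aln$cigar == "*"
  structure(aln[!drop, , drop = FALSE], n_skipped = sum(drop))
}

# Split a CIGAR string into an op table (len, op).
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  if (m[1L] == -1L) stop(sprintf("unparseable CIGAR '%s'", cigar))
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks))
}

#' Extract splice junctions from one alignment's CIGAR
#'
#' Walks the CIGAR from the (1-based) SAM POS: `M`, `=`, `X`, `D` and
#' `N` advance the reference, `I`, `S`, `H`, `P` do not. Every `N`
#' operation yields one junction interval (0-based, half-open). The
#' anchors are the total aligned (`M`/`=`/`X`) bases on each side of
#' the gap.
#'
#' @param pos 1-based leftmost reference position.
#' @param cigar CIGAR string.
#' @return Data frame with columns `start`, `end`, `anchor_left`,
#'   `anchor_right`, one row per `N` gap in reference order.
#' @export
extract_junctions_from_cigar <- function(pos, cigar) {
  ops <- parse_cigar(cigar)
  ref <- pos - 1L                  # 0-based
  aligned_before <- 0L
  aligned_total <- sum(ops$len[ops$op %in% c("M", "=", "X")])
  out <- list()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "N") {
      out[[length(out) + 1L]] <- data.frame(
        start = ref, end = ref + len,
        anchor_left = aligned_before,
        anchor_right = aligned_total - aligned_before)
      ref <- ref + len
    } else if (op %in% c("M", "=", "X")) {
      ref <- ref + len
      aligned_before <- aligned_before + len
    } else if (op == "D") {
      ref <- ref + len
    }                              # I/S/H/P: no reference advance
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      anchor_left = integer(0), anchor_right = integer(0)))
  do.call(rbind, out)
}

# All junctions of an alignment table, one row per (read, junction),
# in read order. Used by counting and co-occurrence.
alignment_junctions <- function(aln) {
  per_read <- lapply(seq_len(nrow(aln)), function(i) {
    j <- extract_junctions_from_cigar(aln$pos[i], aln$cigar[i])
    if (nrow(j)) cbind(qname = aln$qname[i], j) else NULL
  })
  out <- do.call(rbind, per_read)
  if (is.null(out))
    data.frame(qname = character(0), start = integer(0), end = integer(0),
               anchor_left = integer(0), anchor_right = integer(0))
  else out
}

#' Count unique junction-spanning reads
#'
#' A read contributes at most once to any junction, and only when it
#' has at least `min_anchor` aligned bases on both sides of the gap.
#' Secondary/supplementary and unmapped records are already excluded
#' by [read_sam()].
#'
#' @param aln Alignment data frame from [read_sam()] (or a SAM/BAM
#'   path).
#' @param min_anchor Minimum aligned bases required on each side of a
#'   junction (default 10).
#' @param sample_id Sample label stamped on the rows.
#' @return Data frame with columns `start`, `end`, `sample`, `count`,
#'   `anchor_min_seen` (smallest flanking anchor among counted reads).
#' @export
count_junctions <- function(aln, min_anchor = 10L, sample_id = 1L) {
  stopifnot(min_anchor >= 1L)
  if (is.character(aln)) aln <- read_sam(aln)
  jx <- alignment_junctions(aln)
  jx <- jx[jx$anchor_left >= min_anchor & jx$anchor_right >= min_anchor, ,
           drop = FALSE]
  if (!nrow(jx))
    return(data.frame(start = integer(0), end = integer(0),
                      sample = sample_id[0], count = integer(0),
                      anchor_min_seen = integer(0)))
  jx <- jx[!duplicated(jx[, c("qname", "start", "end")]), , drop = FALSE]
  jx$amin <- pmin(jx$anchor_left, jx$anchor_right)
  agg <- stats::aggregate(cbind(count = amin) ~ start + end, data = jx,
                          FUN = length)
  amin <- stats::aggregate(amin ~ start + end, data = jx, FUN = min)
  out <- merge(agg, amin, by = c("start", "end"))
  data.frame(start = out$start, end = out$end, sample = sample_id,
             count = out$count, anchor_min_seen = out$amin)
}

#' Within-read junction co-occurrence records
#'
#' One record per read that crosses at least one junction, listing the
#' junctions in read-coordinate order. Needed to verify that a whole
#' pseudoexon can be retrieved from a single read.
#'
#' @param aln Alignment data frame from [read_sam()].
#' @return Data frame with columns `read_id`, `ord`, `start`, `end`.
#' @export
cooccurrence_records <- function(aln) {
  jx <- alignment_junctions(aln)
  if (!nrow(jx))
    return(data.frame(read_id = character(0), ord = integer(0),
                      start = integer(0), end = integer(0)))
  ord <- stats::ave(seq_len(nrow(jx)), jx$qname, FUN = seq_along)
  data.frame(read_id = jx$qname, ord = ord, start = jx$start, end = jx$end)
}

#' Per-base mRNA coverage of the transcript
#'
#' Projects every aligned (`M`) block through the transcript's
#' genomic-to-mRNA map and accumulates depth over all mRNA positions
#' (positions outside annotated exons, e.g. included pseudoexons, do
#' not contribute).
#'
#' @param aln Alignment data frame from [read_sam()].
#' @param model A [transcript_model()].
#' @return List of class `coverage_track`: `depth` (integer vector of
#'   length `mrna_length`), `mean`, `sd`.
#' @export
coverage_profile <- function(aln, model) {
  L <- model$mrna_length
  delta <- numeric(L + 1L)
  ex <- model$exons
  if (nrow(aln)) {
    blocks <- do.call(rbind, lapply(seq_len(nrow(aln)), function(i) {
      ops <- parse_cigar(aln$cigar[i])
      ref <- aln$pos[i] - 1L
      gs <- integer(0); ge <- integer(0)
      for (k in seq_len(nrow(ops))) {
        if (ops$op[k] %in% c("M", "=", "X")) {
          gs <- c(gs, ref); ge <- c(ge, ref + ops$len[k])
          ref <- ref + ops$len[k]
        } else if (ops$op[k] %in% c("D", "N")) ref <- ref + ops$len[k]
      }
      data.frame(gs = gs, ge = ge)
    }))
    for (k in seq_len(nrow(ex))) {
      lo <- pmax(blocks$gs, ex$gstart[k])
      hi <- pmin(blocks$ge, ex$gend[k])
      keep <- hi > lo
      if (!any(keep)) next
      if (model$strand == "+") {
        m0 <- ex$mstart[k] + (lo[keep] - ex$gstart[k])
        m1 <- ex$mstart[k] + (hi[keep] - ex$gstart[k])
      } else {
        m0 <- ex$mstart[k] + (ex$gend[k] - hi[keep])
        m1 <- ex$mstart[k] + (ex$gend[k] - lo[keep])
      }
      delta <- delta + tabulate(m0 + 1L, nbins = L + 1L) -
        tabulate(m1 + 1L, nbins = L + 1L)
    }
  }
  depth <- cumsum(delta[seq_len(L)])
  structure(list(depth = depth, mean = mean(depth),
                 sd = stats::sd(depth)), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d mRNA positions, mean depth %.1f (+/-%.1f SD)\n",
              length(x$depth), x$mean, x$sd))
  invisible(x)
}

#' Write junction counts as a STAR-SJ-like TSV
#'
#' Columns: chrom, start, end, strand, count, sample.
#'
#' @param counts Data frame from [count_junctions()] (rows from several
#'   samples may be concatenated).
#' @param path Output file.
#' @param chrom,strand Reference name and strand.
#' @return `path`, invisibly.
#' @export
write_junction_tsv <- function(counts, path, chrom, strand = "+") {
  df <- data.frame(chrom = chrom, start = counts$start, end = counts$end,
                   strand = strand, count = counts$count,
                   sample = counts$sample)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an mRNA coverage track as bedGraph
#'
#' Adjacent equal-depth positions are collapsed into intervals; the
#' "chromosome" is the transcript, coordinates are mRNA positions.
#'
#' @param track A `coverage_track` from [coverage_profile()].
#' @param path Output file.
#' @param name Transcript name used in column 1.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name) {
  d <- track$depth
  brk <- c(0L, which(diff(d) != 0L), length(d))
  s <- brk[-length(brk)]; e <- brk[-1L]
  writeLines(sprintf("%s\t%d\t%d\t%g", name, s, e, d[s + 1L]), path)
  invisible(path)
}
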