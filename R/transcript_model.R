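#' Construct a single-isoform transcript model
#'
#' A transcript model is the ordered exon structure of one multi-exon
#' isoform, with maps between genomic and mRNA coordinates and the CDS
#' reading-frame anchor. All coordinates are 0-based, half-open (BED
#' convention) on the genomic plus strand; exon 1 is the first exon in
#' transcription direction, so on a minus-strand transcript it sits at
#' the highest genomic coordinates.
#'
#' @param name Transcript identifier.
#' @param chrom Chromosome / reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of genomic exon
#'   boundaries (0-based half-open), in any order; they are sorted into
#'   transcription direction internally.
#' @param cds_start_mrna 0-based mRNA offset of the first codon
#'   (default 0: coding from the first base).
#' @return An object of class `transcript_model` with components
#'   `name`, `chrom`, `strand`, `exons` (data frame: `index`, `gstart`,
#'   `gend`, `length`, `mstart`, `mend`), `cds_start_mrna`,
#'   `mrna_length`.
#' @examples
#' m <- transcript_model("toy", "chrT", "+", c(0, 200, 500),
#'                       c(100, 300, 650))
#' m$mrna_length
#' @export
transcript_model <- function(name, chrom, strand, exon_starts, exon_ends,
                             cds_start_mrna = 0L) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L)
  strand <- match.arg(strand, c("+", "-"))
  gs <- as.integer(exon_starts)
  ge <- as.integer(exon_ends)
  if (any(ge - gs <= 0L))
    stop("exon with non-positive length (start >= end)")
  o <- order(gs)
  gs <- gs[o]; ge <- ge[o]
  if (length(gs) > 1L) {
    gap <- gs[-1L] - ge[-length(ge)]
    bad <- which(gap < 1L)
    if (length(bad))
      stop(sprintf(
        "overlapping or abutting exons: genomic exon pair %d/%d (intron length %d < 1)",
        bad[1L], bad[1L] + 1L, gap[bad[1L]]))
  }
  # transcription order: + ascending, - descending genomic coordinates
  if (strand == "-") { gs <- rev(gs); ge <- rev(ge) }
  len <- ge - gs
  mend <- cumsum(len)
  mstart <- mend - len
  exons <- data.frame(index = seq_along(gs), gstart = gs, gend = ge,
                      length = len, mstart = mstart, mend = mend)
  mrna_length <- sum(len)
  cds_start_mrna <- as.integer(cds_start_mrna)
  if (cds_start_mrna < 0L || cds_start_mrna >= mrna_length)
    stop("cds_start_mrna outside mRNA")
  structure(list(name = name, chrom = chrom, strand = strand,
                 exons = exons, cds_start_mrna = cds_start_mrna,
                 mrna_length = mrna_length),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s%s) %d exons, mRNA %d nt, CDS start %d\n",
              x$name, x$chrom, x$strand, nrow(x$exons), x$mrna_length,
              x$cds_start_mrna))
  cat(sprintf("  genomic span: %d-%d\n",
              min(x$exons$gstart), max(x$exons$gend)))
  invisible(x)
}

#' Number of exons in a transcript model
#' @param model A `transcript_model`.
#' @return Integer exon count.
#' @export
n_exons <- function(model) nrow(model$exons)

#' Load a transcript model from GTF or BED12
#'
#' GTF exon records (attribute `transcript_id`) are read through
#' [rtracklayer::import()] and converted from 1-based inclusive to the
#' internal 0-based half-open convention at the parser boundary. BED12
#' is parsed from its block fields. If the GTF carries CDS records for
#' the transcript, the CDS start is projected into mRNA coordinates;
#' otherwise `cds_start_mrna` is 0.
#'
#' @param path Path to a GTF (`.gtf`) or BED12 (`.bed`) file.
#' @param transcript_id Identifier of the transcript to extract (GTF
#'   attribute `transcript_id`, or BED `name` column).
#' @param format `"auto"` (by extension), `"gtf"` or `"bed"`.
#' @return A [transcript_model()].
#' @export
load_transcript_model <- function(path, transcript_id,
                                  format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff")) "gtf" else "bed"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    keep <- !is.na(md$transcript_id) & md$transcript_id == transcript_id
    if (!any(keep))
      stop(sprintf("transcript '%s' not found in %s", transcript_id, path))
    gr <- gr[keep]
    ex <- gr[S4Vectors::mcols(gr)$type == "exon"]
    if (length(ex) == 0L)
      stop(sprintf("transcript '%s' has no exon records", transcript_id))
    strand <- as.character(BiocGenerics::strand(ex))[1L]
    if (strand == "*") strand <- "+"
    chrom <- as.character(GenomeInfoDb::seqnames(ex))[1L]
    gs <- BiocGenerics::start(ex) - 1L   # GTF 1-based inclusive -> 0-based
    ge <- BiocGenerics::end(ex)
    model <- transcript_model(transcript_id, chrom, strand, gs, ge)
    cds <- gr[S4Vectors::mcols(gr)$type == "CDS"]
    if (length(cds) > 0L) {
      # first coding base in transcription direction
      g_first <- if (strand == "+") min(BiocGenerics::start(cds)) - 1L
                 else               max(BiocGenerics::end(cds)) - 1L
      mp <- genome_to_mrna(model, g_first)
      if (mp$region == "exonic") model$cds_start_mrna <- mp$mrna
    }
    return(model)
  }
  # BED12
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t")
  names_col <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_,
                      character(1))
  hit <- which(names_col == transcript_id)
  if (!length(hit))
    stop(sprintf("transcript '%s' not found in %s", transcript_id, path))
  f <- fields[[hit[1L]]]
  if (length(f) < 12L)
    stop("BED line has fewer than 12 fields; BED12 required")
  chrom_start <- as.integer(f[2L])
  n_blocks <- as.integer(f[10L])
  bsize <- as.integer(strsplit(f[11L], ",")[[1L]])[seq_len(n_blocks)]
  bstart <- as.integer(strsplit(f[12L], ",")[[1L]])[seq_len(n_blocks)]
  gs <- chrom_start + bstart
  ge <- gs + bsize
  strand <- if (f[6L] %in% c("+", "-")) f[6L] else "+"
  model <- transcript_model(transcript_id, f[1L], strand, gs, ge)
  thick_start <- as.integer(f[7L])
  if (!is.na(thick_start) && thick_start > chrom_start) {
    g_first <- if (strand == "+") thick_start else as.integer(f[8L]) - 1L
    mp <- genome_to_mrna(model, g_first)
    if (mp$region == "exonic") model$cds_start_mrna <- mp$mrna
  }
  model
}

#' Derive the canonical splice junctions of a transcript model
#'
#' A canonical junction joins two transcription-consecutive exons;
#' a model with n exons therefore has exactly n - 1 of them. Junctions
#' are reported as genomic plus-strand intron intervals (0-based,
#' half-open), with the donor/acceptor roles resolved from the strand.
#'
#' @param model A [transcript_model()].
#' @return Data frame with one row per junction: `start`, `end`
#'   (genomic intron interval), `intron_index` (ordinal in
#'   transcription direction), `label` (e.g. `"ex8-ex9"`), `status`
#'   (`"canonical"`), `donor_pos`, `acceptor_pos` (genomic coordinates
#'   of the transcription-5' and -3' intron boundaries).
#' @export
derive_canonical_junctions <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L)
    return(data.frame(start = integer(0), end = integer(0),
                      intron_index = integer(0), label = character(0),
                      status = character(0), donor_pos = integer(0),
                      acceptor_pos = integer(0)))
  i <- seq_len(n - 1L)
  if (model$strand == "+") {
    start <- ex$gend[i]; end <- ex$gstart[i + 1L]
    donor <- start; acceptor <- end
  } else {
    start <- ex$gend[i + 1L]; end <- ex$gstart[i]
    donor <- end; acceptor <- start
  }
  data.frame(start = start, end = end, intron_index = i,
             label = sprintf("ex%d-ex%d", i, i + 1L),
             status = "canonical", donor_pos = donor,
             acceptor_pos = acceptor)
}

#' Map genomic positions to mRNA coordinates
#'
#' Exonic positions map bijectively onto 0-based mRNA coordinates;
#' intronic positions are flagged and annotated with the enclosing
#' intron ordinal and the offset from the intron's transcription-5'
#' boundary.
#'
#' @param model A [transcript_model()].
#' @param gpos Integer vector of genomic positions (0-based) within the
#'   transcript's genomic span.
#' @return Data frame with columns `gpos`, `region` ("exonic" or
#'   "intronic"), `mrna` (mRNA coordinate, NA if intronic),
#'   `intron_index`, `intron_offset` (NA if exonic).
#' @export
genome_to_mrna <- function(model, gpos) {
  gpos <- as.integer(gpos)
  ex <- model$exons
  span <- c(min(ex$gstart), max(ex$gend))
  if (any(gpos < span[1L] | gpos >= span[2L]))
    stop(sprintf("genomic position outside transcript span [%d, %d)",
                 span[1L], span[2L]))
  res <- data.frame(gpos = gpos, region = "intronic",
                    mrna = NA_integer_, intron_index = NA_integer_,
                    intron_offset = NA_integer_)
  for (k in seq_len(nrow(ex))) {
    in_ex <- gpos >= ex$gstart[k] & gpos < ex$gend[k]
    if (!any(in_ex)) next
    res$region[in_ex] <- "exonic"
    res$mrna[in_ex] <- if (model$strand == "+")
      ex$mstart[k] + (gpos[in_ex] - ex$gstart[k])
    else
      ex$mstart[k] + (ex$gend[k] - 1L - gpos[in_ex])
    res$intron_index[in_ex] <- NA_integer_
  }
  intronic <- res$region == "intronic"
  if (any(intronic)) {
    cj <- derive_canonical_junctions(model)
    for (k in seq_len(nrow(cj))) {
      in_i <- intronic & gpos >= cj$start[k] & gpos < cj$end[k]
      if (!any(in_i)) next
      res$intron_index[in_i] <- cj$intron_index[k]
      res$intron_offset[in_i] <- if (model$strand == "+")
        gpos[in_i] - cj$start[k]
      else
        cj$end[k] - 1L - gpos[in_i]
    }
  }
  res
}

#' Map mRNA coordinates to genomic positions
#'
#' Inverse of [genome_to_mrna()] on exonic positions:
#' `mrna_to_genome(model, genome_to_mrna(model, g)$mrna) == g`.
#'
#' @param model A [transcript_model()].
#' @param mpos Integer vector of 0-based mRNA coordinates.
#' @return Integer vector of genomic positions.
#' @export
mrna_to_genome <- function(model, mpos) {
  mpos <- as.integer(mpos)
  if (any(mpos < 0L | mpos >= model$mrna_length))
    stop("mRNA position outside transcript")
  ex <- model$exons
  k <- findInterval(mpos, ex$mstart)
  off <- mpos - ex$mstart[k]
  if (model$strand == "+") ex$gstart[k] + off else ex$gend[k] - 1L - off
}

#' Write a junction table as BED6
#'
#' One line per intron interval; `name` is the junction label, `score`
#' the read count when a `count` column is present (0 otherwise).
#'
#' @param junctions Data frame as returned by
#'   [derive_canonical_junctions()] (optionally with a `count` column).
#' @param path Output file.
#' @param chrom,strand Chromosome and strand to stamp on each line.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path, chrom, strand = "+") {
  score <- if ("count" %in% names(junctions)) junctions$count else 0L
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", chrom, junctions$start,
                   junctions$end, junctions$label, as.integer(score), strand)
  writeLines(lines, path)
  invisible(path)
}

#' Extract the mRNA sequence of a transcript model
#'
#' Concatenates the exon sequences in transcription order, reverse
#' complementing on the minus strand.
#'
#' @param model A [transcript_model()].
#' @param genome A named [Biostrings::DNAStringSet] (or character
#'   vector) holding the reference sequence for `model$chrom`.
#' @return A character scalar, the mRNA sequence.
#' @export
transcript_sequence <- function(model, genome) {
  chrom_seq <- genome_sequence(genome, model$chrom)
  ex <- model$exons
  parts <- substring(chrom_seq, ex$gstart + 1L, ex$gend)
  if (model$strand == "-") parts <- vapply(parts, revcomp, character(1))
  paste0(parts, collapse = "")
}

# Resolve a genome argument (DNAStringSet or named character) to the
# plain character sequence of one chromosome.
genome_sequence <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome))
      stop(sprintf("sequence '%s' not in genome", chrom))
    return(as.character(genome[[chrom]]))
  }
  if (is.character(genome)) {
    if (!is.null(names(genome)) && chrom %in% names(genome))
      return(unname(genome[[chrom]]))
    if (length(genome) == 1L) return(genome)
  }
  stop("genome must be a DNAStringSet or a named character vector")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
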