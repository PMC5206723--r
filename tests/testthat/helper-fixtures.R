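# Shared fixtures, built once per test run.

# Full synthetic 79-exon fixture (plus and minus strand variants).
FX <- dmd_fixture("+")
FXM <- dmd_fixture("-")

# Small 5-exon toy transcript with consensus splice sites, for fast
# unit tests. Exon lengths 100/90/120/60/110 (mRNA 480), introns 200.
toy_fixture <- function(strand = "+", seed = 42L) {
  lens <- c(100L, 90L, 120L, 60L, 110L)
  intron <- 200L
  pad <- 100L
  starts <- pad + cumsum(c(0L, head(lens, -1L) + intron))
  ends <- starts + lens
  chrlen <- max(ends) + pad
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), chrlen, replace = TRUE)
  put <- function(pos0, txt) {
    ch <- strsplit(txt, "")[[1L]]
    s[pos0 + seq_along(ch)] <<- ch
  }
  for (k in 1:4) {
    put(ends[k], "GTAAGT")
    put(starts[k + 1L] - 14L, "TTTTTTTTTTTCAG")
  }
  for (k in 2:5) {      # no spurious NAGNAG acceptors
    s1 <- starts[k] + 1L
    if (paste0(s[s1 + 1L], s[s1 + 2L]) == "AG") s[s1 + 2L] <- "C"
  }
  seqc <- paste0(s, collapse = "")
  if (strand == "-") {
    seqc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqc)))
    new_starts <- chrlen - ends
    ends <- chrlen - starts
    starts <- new_starts
  }
  genome <- Biostrings::DNAStringSet(seqc)
  names(genome) <- "chrT"
  model <- transcript_model("toy", "chrT", strand, starts, ends,
                            cds_start_mrna = 10L)
  list(model = model, genome = genome, chrom = "chrT")
}

TOY <- toy_fixture("+")

# Classify + pair the 12 fixture events; returns the full event list.
annotate_fixture_events <- function(fx, with_cooc = TRUE) {
  jx <- lapply(fx$events, event_junctions, model = fx$model)
  cls <- list()
  for (nm in names(jx)) for (r in seq_len(nrow(jx[[nm]])))
    cls[[length(cls) + 1L]] <-
      classify_junction(jx[[nm]]$start[r], jx[[nm]]$end[r], fx$model)
  cooc <- NULL
  if (with_cooc) {
    pe <- jx[vapply(fx$events, function(e) e$category == "pseudoexon",
                    logical(1))]
    cooc <- do.call(rbind, lapply(seq_along(pe), function(i)
      data.frame(read_id = sprintf("pe_read%d", i), ord = 1:2,
                 start = pe[[i]]$start, end = pe[[i]]$end)))
  }
  detect_pseudoexons(cls, fx$model, cooc)
}

# Minimal SAM alignment table.
sam_record <- function(qname, pos, cigar, flag = 0L, rname = "chrS") {
  n <- length(qname)
  data.frame(qname = qname, flag = rep_len(flag, n),
             rname = rep_len(rname, n), pos = pos,
             mapq = rep_len(60L, n), cigar = cigar)
}
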