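#' Synthetic 79-exon dystrophin-like fixture
#'
#' Builds a fully synthetic transcript model, reference sequence and
#' alternative-splicing event inventory shaped like the muscle
#' dystrophin mRNA (Dp427m): 79 exons, 11,300 nt of mRNA, and twelve
#' low-level events (five exon skips, three pseudoexons, four exonic
#' alternative 3' splice sites) at their reported tissue rates. Only
#' characteristics actually reported for the real transcript are
#' pinned -- exon 71 is 39 nt and exon 78 is 32 nt, the pseudoexons are
#' 162/66/84 nt, the alternative acceptors truncate their exons by
#' 2/3/60/4 nt, and the exon 54 acceptor is a NAGNAG tandem site; all
#' other exon/intron lengths and every base of sequence are generated
#' deterministically and are NOT the real gene.
#'
#' The reference sequence plants consensus splice sites (GTAAGT donors,
#' polypyrimidine + CAG acceptors) at every junction, a CAGCAG tandem
#' acceptor at exon 54 only, exonic AG dinucleotides realizing each
#' alternative acceptor, strong splice sites around each pseudoexon,
#' and an in-frame stop codon inside the 162-nt pseudoexon (so its
#' frame-preserving length still truncates the reading frame, as
#' observed for the real insertion).
#'
#' @param strand `"+"` (default) or `"-"`; the minus-strand fixture is
#'   the reverse complement with flipped coordinates, exercising the
#'   strand-aware code paths.
#' @return A list with components `model` ([transcript_model()]),
#'   `genome` (a [Biostrings::DNAStringSet] named `chrS`), `events`
#'   (list of [event_spec()]), and `chrom`.
#' @export
dmd_fixture <- function(strand = "+") {
  strand <- match.arg(strand, c("+", "-"))
  n <- 79L
  i <- seq_len(n)
  exon_len <- 70L + 6L * ((i * 13L) %% 23L)
  exon_len[1L] <- 180L                     # holds the CDS start at mRNA 100
  exon_len[71L] <- 39L                     # pinned: very short exon
  exon_len[78L] <- 32L                     # pinned: very short exon
  exon_len[76L] <- max(exon_len[76L], 120L)
  for (k in c(9L, 73L, 74L))               # in-frame skips: length % 3 == 0
    exon_len[k] <- exon_len[k] - exon_len[k] %% 3L
  exon_len[79L] <- 11300L - sum(exon_len[-79L])
  stopifnot(exon_len[79L] >= 60L, sum(exon_len) == 11300L)

  ii <- seq_len(n - 1L)
  intron_len <- 300L + 31L * ((ii * 7L) %% 29L)
  intron_len[1L] <- 1200L
  intron_len[21L] <- 900L
  intron_len[51L] <- 900L

  pad <- 200L
  # transcription-axis coordinates (exon 1 leftmost while building)
  t_start <- integer(n); t_end <- integer(n)
  cur <- pad
  for (k in seq_len(n)) {
    t_start[k] <- cur
    t_end[k] <- cur + exon_len[k]
    cur <- t_end[k] + if (k < n) intron_len[k] else pad
  }
  chrlen <- t_end[n] + pad

  pe_def <- list(PE1a  = list(intron = 1L,  offset = 400L, len = 162L),
                 PE21X = list(intron = 21L, offset = 300L, len = 66L),
                 PE51X = list(intron = 51L, offset = 300L, len = 84L))

  seq <- build_fixture_sequence(chrlen, t_start, t_end, intron_len,
                                exon_len, pe_def)

  if (strand == "-") {
    seq <- revcomp(seq)
    gstart <- chrlen - t_end
    gend <- chrlen - t_start
  } else {
    gstart <- t_start
    gend <- t_end
  }
  model <- transcript_model("Dp427m-like", "chrS", strand, gstart, gend,
                            cds_start_mrna = 100L)
  flip <- function(a, b) if (strand == "-") c(chrlen - b, chrlen - a) else c(a, b)
  pe_iv <- lapply(pe_def, function(p) {
    a <- t_end[p$intron] + p$offset
    flip(a, a + p$len)
  })

  rates <- c(del9 = 0.0063, del71 = 0.0180, del73 = 0.0032,
             del74 = 0.0049, del78 = 0.0248,
             PE1a = 0.0306, PE21X = 0.0040, PE51X = 0.0021,
             a3ss_ex20 = 0.0018, a3ss_ex54 = 0.0112,
             a3ss_ex76 = 0.0033, a3ss_ex78 = 0.0043)
  events <- list(
    event_spec("del9",  "exon_skip", rates[["del9"]],  exons = 9L),
    event_spec("del71", "exon_skip", rates[["del71"]], exons = 71L),
    event_spec("del73", "exon_skip", rates[["del73"]], exons = 73L),
    event_spec("del74", "exon_skip", rates[["del74"]], exons = 74L),
    event_spec("del78", "exon_skip", rates[["del78"]], exons = 78L),
    event_spec("PE1a",  "pseudoexon", rates[["PE1a"]],
               pe_start = pe_iv$PE1a[1L],  pe_end = pe_iv$PE1a[2L]),
    event_spec("PE21X", "pseudoexon", rates[["PE21X"]],
               pe_start = pe_iv$PE21X[1L], pe_end = pe_iv$PE21X[2L]),
    event_spec("PE51X", "pseudoexon", rates[["PE51X"]],
               pe_start = pe_iv$PE51X[1L], pe_end = pe_iv$PE51X[2L]),
    event_spec("a3ss_ex20", "alt3ss", rates[["a3ss_ex20"]],
               exon = 20L, offset_nt = -2L),
    event_spec("a3ss_ex54", "alt3ss", rates[["a3ss_ex54"]],
               exon = 54L, offset_nt = -3L),
    event_spec("a3ss_ex76", "alt3ss", rates[["a3ss_ex76"]],
               exon = 76L, offset_nt = -60L),
    event_spec("a3ss_ex78", "alt3ss", rates[["a3ss_ex78"]],
               exon = 78L, offset_nt = -4L))
  names(events) <- vapply(events, `[[`, character(1), "event_id")

  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chrS"
  list(model = model, genome = genome, events = events, chrom = "chrS")
}

# Deterministic sequence on the transcription axis with all splice
# features planted. Coordinates here are 0-based half-open; string
# surgery uses 1-based substr.
build_fixture_sequence <- function(chrlen, t_start, t_end, intron_len,
                                   exon_len, pe_def) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(20316L)
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, chrlen, replace = TRUE,
              prob = c(0.28, 0.22, 0.22, 0.28))

  put <- function(pos0, txt) {           # pos0: 0-based start
    ch <- strsplit(txt, "")[[1L]]
    s[pos0 + seq_along(ch)] <<- ch
  }
  n <- length(t_start)
  acc_tail <- "TTTTTTTTTTTCAG"           # 11 Py + CAG, ends at exon start
  for (k in seq_len(n - 1L)) {
    put(t_end[k], "GTAAGT")              # donor: intron first 6
    tail <- if (k == 75L) "GAAAGAAAGATAG" else substr(acc_tail, 2L, 14L)
    put(t_start[k + 1L] - nchar(tail), tail)  # acceptor tract + ..AG
  }
  # exon-start surgery (1-based positions within the chromosome string)
  for (k in 2L:n) {
    s1 <- t_start[k] + 1L
    if (k == 54L) { put(t_start[k], "CAG"); next }   # NAGNAG: ...CAG|CAG
    if (k == 20L) put(t_start[k], "AG")              # alt acceptor -2
    if (k == 78L) { if (s[s1] == "A") s[s1] <- "C"; put(t_start[k] + 2L, "AG") }
    if (paste0(s[s1 + 1L], s[s1 + 2L]) == "AG") s[s1 + 2L] <- "C"
  }
  # exon 76: strong exonic alternative acceptor 60 nt in
  put(t_start[76L] + 44L, "TTTTTTTTTTTTTT")
  put(t_start[76L] + 58L, "AG")
  # pseudoexon cassettes
  cum_mrna <- cumsum(exon_len)
  for (nm in names(pe_def)) {
    p <- pe_def[[nm]]
    A <- t_end[p$intron] + p$offset
    B <- A + p$len
    put(A - 14L, acc_tail)               # acceptor into the pseudoexon
    put(B, "GTAAGT")                     # donor out of the pseudoexon
    # reading frame of the insertion point (CDS starts at mRNA 100)
    phase <- (cum_mrna[p$intron] - 100L) %% 3L
    o0 <- (3L - phase) %% 3L             # first full internal codon offset
    offs <- seq(o0, p$len - 3L, by = 3L)
    for (o in offs) {
      cod <- paste0(s[A + o + 1:3], collapse = "")
      if (cod %in% c("TAA", "TAG", "TGA")) put(A + o, "CTG")
    }
    if (nm == "PE1a") put(A + o0 + 6L, "TAA")  # planted in-frame stop
  }
  paste0(s, collapse = "")
}

#' Table of the fixture's alternative-splicing event rates
#'
#' Convenience accessor: the twelve fixture events with category,
#' definition summary and simulated molecular rate (the fraction of
#' transcripts carrying each event, equal to ASE/100).
#'
#' @param fixture A list as returned by [dmd_fixture()] (built fresh if
#'   omitted).
#' @return Data frame with columns `event_id`, `category`, `rate`,
#'   `ase_percent`.
#' @export
fixture_event_table <- function(fixture = dmd_fixture()) {
  ev <- fixture$events
  data.frame(
    event_id = vapply(ev, `[[`, character(1), "event_id"),
    category = vapply(ev, `[[`, character(1), "category"),
    rate = vapply(ev, `[[`, numeric(1), "rate"),
    ase_percent = 100 * vapply(ev, `[[`, numeric(1), "rate"),
    row.names = NULL)
}
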