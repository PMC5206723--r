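#' Specify an alternative-splicing event for simulation and annotation
#'
#' @param event_id Short identifier (e.g. `"del9"`, `"PE1a"`).
#' @param category One of `"exon_skip"`, `"pseudoexon"`, `"alt3ss"`,
#'   `"alt5ss"`.
#' @param rate Fraction of transcript molecules carrying the event, in
#'   `[0, 1]`. Equals ASE/100 in all categories (PSI for pseudoexons,
#'   1 - PSI otherwise).
#' @param exons Integer vector of consecutive skipped exon ordinals
#'   (exon_skip only).
#' @param exon Affected exon ordinal (alt3ss/alt5ss only).
#' @param offset_nt Signed splice-site displacement in nt; negative
#'   means exonic truncation (the reported convention).
#' @param pe_start,pe_end Genomic interval of the pseudoexon (0-based
#'   half-open, plus strand; pseudoexon only).
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(event_id, category, rate, exons = NULL,
                       exon = NULL, offset_nt = NULL,
                       pe_start = NULL, pe_end = NULL) {
  category <- match.arg(category,
                        c("exon_skip", "pseudoexon", "alt3ss", "alt5ss"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (category == "exon_skip") {
    stopifnot(length(exons) >= 1L, all(diff(exons) == 1L))
  } else if (category == "pseudoexon") {
    stopifnot(!is.null(pe_start), !is.null(pe_end), pe_end > pe_start)
  } else {
    stopifnot(!is.null(exon), !is.null(offset_nt), offset_nt != 0L)
  }
  structure(list(event_id = event_id, category = category,
                 rate = as.numeric(rate),
                 exons = if (!is.null(exons)) as.integer(exons),
                 exon = if (!is.null(exon)) as.integer(exon),
                 offset_nt = if (!is.null(offset_nt)) as.integer(offset_nt),
                 pe_start = if (!is.null(pe_start)) as.integer(pe_start),
                 pe_end = if (!is.null(pe_end)) as.integer(pe_end)),
            class = "event_spec")
}

# Validate an event spec against a model; returns invisibly or stops.
validate_event <- function(model, ev) {
  n <- n_exons(model)
  cj <- derive_canonical_junctions(model)
  switch(ev$category,
    exon_skip = {
      if (min(ev$exons) < 2L || max(ev$exons) > n - 1L)
        stop(sprintf("%s: skipped exons must be internal (2..%d)",
                     ev$event_id, n - 1L))
    },
    pseudoexon = {
      host <- pe_host_intron(model, ev$pe_start, ev$pe_end)
      if (is.na(host))
        stop(sprintf("%s: pseudoexon interval not strictly inside one intron",
                     ev$event_id))
    },
    {
      len <- model$exons$length[ev$exon]
      if (abs(ev$offset_nt) >= len)
        stop(sprintf("%s: offset %d exhausts exon %d (length %d)",
                     ev$event_id, ev$offset_nt, ev$exon, len))
      if (ev$category == "alt3ss" && ev$exon < 2L)
        stop("alt3ss needs an upstream intron")
      if (ev$category == "alt5ss" && ev$exon > n - 1L)
        stop("alt5ss needs a downstream intron")
    })
  invisible(ev)
}

# Which canonical intron (transcription ordinal) strictly contains
# [pe_start, pe_end)? NA if none.
pe_host_intron <- function(model, pe_start, pe_end) {
  cj <- derive_canonical_junctions(model)
  hit <- which(cj$start < pe_start & cj$end > pe_end)
  if (length(hit) == 1L) cj$intron_index[hit] else NA_integer_
}

#' Genomic junctions realizing an event
#'
#' Returns the novel splice junction(s) that an event produces: one for
#' exon skipping and alternative splice sites, two (sharing the host
#' intron) for a pseudoexon.
#'
#' @param model A [transcript_model()].
#' @param ev An [event_spec()].
#' @return Data frame with columns `start`, `end` (genomic plus-strand
#'   intron intervals) and `role` (`"skip"`, `"alt"`, `"pe_donor_side"`
#'   = canonical donor to pseudoexon acceptor, `"pe_acceptor_side"` =
#'   pseudoexon donor to canonical acceptor).
#' @export
event_junctions <- function(model, ev) {
  validate_event(model, ev)
  cj <- derive_canonical_junctions(model)
  plus <- model$strand == "+"
  switch(ev$category,
    exon_skip = {
      K <- min(ev$exons); J <- max(ev$exons)
      up <- K - 1L; dn <- J              # flanking intron ordinals
      if (plus)
        data.frame(start = cj$start[up], end = cj$end[dn], role = "skip")
      else
        data.frame(start = cj$start[dn], end = cj$end[up], role = "skip")
    },
    alt3ss = {
      k <- ev$exon - 1L; d <- abs(ev$offset_nt)
      if (ev$offset_nt < 0) {            # exonic truncation
        if (plus)
          data.frame(start = cj$start[k], end = cj$end[k] + d, role = "alt")
        else
          data.frame(start = cj$start[k] - d, end = cj$end[k], role = "alt")
      } else {                           # intronic extension of the exon
        if (plus)
          data.frame(start = cj$start[k], end = cj$end[k] - d, role = "alt")
        else
          data.frame(start = cj$start[k] + d, end = cj$end[k], role = "alt")
      }
    },
    alt5ss = {
      k <- ev$exon; d <- abs(ev$offset_nt)
      if (ev$offset_nt < 0) {
        if (plus)
          data.frame(start = cj$start[k] - d, end = cj$end[k], role = "alt")
        else
          data.frame(start = cj$start[k], end = cj$end[k] + d, role = "alt")
      } else {
        if (plus)
          data.frame(start = cj$start[k] + d, end = cj$end[k], role = "alt")
        else
          data.frame(start = cj$start[k], end = cj$end[k] - d, role = "alt")
      }
    },
    pseudoexon = {
      k <- pe_host_intron(model, ev$pe_start, ev$pe_end)
      if (plus)
        data.frame(start = c(cj$start[k], ev$pe_end),
                   end = c(ev$pe_start, cj$end[k]),
                   role = c("pe_donor_side", "pe_acceptor_side"))
      else
        data.frame(start = c(ev$pe_end, cj$start[k]),
                   end = c(cj$end[k], ev$pe_start),
                   role = c("pe_donor_side", "pe_acceptor_side"))
    })
}

# Canonical intron ordinals whose junctions are displaced by an event.
affected_introns <- function(model, ev) {
  switch(ev$category,
    exon_skip = (min(ev$exons) - 1L):max(ev$exons),
    alt3ss = ev$exon - 1L,
    alt5ss = ev$exon,
    pseudoexon = pe_host_intron(model, ev$pe_start, ev$pe_end))
}

#' Simulation configuration for 454-style long reads
#'
#' Defaults emulate the study conditions of the targeted amplicon
#' libraries this package models: 4 replicate libraries of 69,060
#' reads with 387 nt mean read length (454 Junior scale). The read
#' length spread and error rates are not reported for those libraries;
#' the defaults (SD 120 nt, 0.1% substitutions, 0.2% homopolymer
#' indels per run) are typical of the platform and configurable.
#'
#' @param n_samples Number of replicate libraries.
#' @param reads_per_sample Reads per library.
#' @param read_length_mean,read_length_sd Read length law (truncated
#'   normal, minimum `min_read_length`).
#' @param error_rate Per-base substitution probability.
#' @param homopolymer_indel_rate Probability that a homopolymer run of
#'   length >= 4 in a read gains or loses one base.
#' @param min_read_length Shortest retained read (post-trimming floor).
#' @param seed Integer seed governing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 4L, reads_per_sample = 69060L,
                       read_length_mean = 387, read_length_sd = 120,
                       error_rate = 0.001, homopolymer_indel_rate = 0.002,
                       min_read_length = 40L, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            homopolymer_indel_rate >= 0, homopolymer_indel_rate <= 1,
            n_samples >= 1L, reads_per_sample >= 1L,
            read_length_mean >= 2 * 10)
  structure(list(n_samples = as.integer(n_samples),
                 reads_per_sample = as.integer(reads_per_sample),
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 error_rate = error_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 min_read_length = as.integer(min_read_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build the isoform mixture implied by a set of events
#'
#' Linearized mixture: the canonical isoform with weight
#' `1 - sum(rates)` plus one single-event isoform per event at its
#' rate. Joint-event molecules (products of the per-event rates, all
#' well below 1e-3 at the modelled rates) are neglected.
#'
#' @param model A [transcript_model()].
#' @param events List of [event_spec()].
#' @return List of isoforms, each `list(name, blocks, weight,
#'   mrna_length)`; `blocks` is a data frame of genomic plus-strand
#'   intervals in transcription order. Weights sum to 1 exactly.
#' @export
simulate_isoform_mixture <- function(model, events) {
  ids <- vapply(events, `[[`, character(1), "event_id")
  if (anyDuplicated(ids)) stop("duplicate event ids in mixture")
  total <- sum(vapply(events, `[[`, numeric(1), "rate"))
  if (total > 1) stop(sprintf(
    "event rates sum to %.3f > 1: mutually exclusive alternatives overflow",
    total))
  for (ev in events) validate_event(model, ev)
  canon <- list(name = "canonical",
                blocks = model$exons[, c("gstart", "gend")],
                weight = 1 - total)
  isoforms <- c(list(canon), lapply(events, function(ev)
    list(name = ev$event_id, blocks = isoform_blocks(model, ev),
         weight = ev$rate)))
  lapply(isoforms, function(iso) {
    iso$mrna_length <- sum(iso$blocks$gend - iso$blocks$gstart)
    iso
  })
}

# Exonic block structure (transcription order) of a single-event isoform.
isoform_blocks <- function(model, ev) {
  bl <- model$exons[, c("gstart", "gend")]
  plus <- model$strand == "+"
  switch(ev$category,
    exon_skip = bl[-ev$exons, , drop = FALSE],
    alt3ss = {
      k <- ev$exon; d <- ev$offset_nt   # negative: truncate txn start
      if (plus) bl$gstart[k] <- bl$gstart[k] - d
      else      bl$gend[k]   <- bl$gend[k] + d
      bl
    },
    alt5ss = {
      k <- ev$exon; d <- ev$offset_nt
      if (plus) bl$gend[k]   <- bl$gend[k] + d
      else      bl$gstart[k] <- bl$gstart[k] - d
      bl
    },
    pseudoexon = {
      k <- pe_host_intron(model, ev$pe_start, ev$pe_end)
      top <- bl[seq_len(k), , drop = FALSE]
      pe <- data.frame(gstart = ev$pe_start, gend = ev$pe_end)
      bot <- bl[(k + 1L):nrow(bl), , drop = FALSE]
      rbind(top, pe, bot)
    })
}

# mRNA sequence of an isoform (transcription orientation).
isoform_sequence <- function(iso, genome, model) {
  chrom_seq <- genome_sequence(genome, model$chrom)
  parts <- substring(chrom_seq, iso$blocks$gstart + 1L, iso$blocks$gend)
  if (model$strand == "-") parts <- vapply(parts, revcomp, character(1))
  paste0(parts, collapse = "")
}

# Junction intervals (plus-strand) crossed between consecutive blocks
# of an isoform, in transcription order.
isoform_junction_intervals <- function(iso, model) {
  b <- iso$blocks
  n <- nrow(b)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  i <- seq_len(n - 1L)
  if (model$strand == "+")
    data.frame(start = b$gend[i], end = b$gstart[i + 1L])
  else
    data.frame(start = b$gend[i + 1L], end = b$gstart[i])
}

#' Simulate 454-style reads with a truth alignment
#'
#' Draws reads from an isoform mixture: start positions uniform along
#' each molecule, lengths from a truncated normal, optional per-base
#' substitutions and homopolymer-run indels. Returns the reads, a
#' truth SAM-style alignment table (POS/CIGAR with `N` gaps across
#' every crossed intron, `I`/`D` for simulated indels, MAPQ 60), and
#' truth junction counts. Output is reproducible byte-for-byte under a
#' fixed seed.
#'
#' @param mixture As returned by [simulate_isoform_mixture()].
#' @param config A [sim_config()].
#' @param genome Reference sequence (see [transcript_sequence()]).
#' @param model The [transcript_model()] the mixture was built from.
#' @param out_dir If non-NULL, writes `sample<k>.fasta`,
#'   `sample<k>.sam`, `truth_counts.tsv` and `config.yaml` there.
#' @return List with `samples` (per sample: `reads` named character
#'   vector, `sam` data frame, `read_isoform`), `truth_counts`
#'   (junction, sample, count) and `config`.
#' @export
simulate_reads <- function(mixture, config, genome, model, out_dir = NULL) {
  set.seed(config$seed)
  strand <- model$strand
  chrom <- model$chrom
  weights <- vapply(mixture, `[[`, numeric(1), "weight")
  seqs <- vapply(mixture, isoform_sequence, character(1),
                 genome = genome, model = model)
  lens <- vapply(mixture, `[[`, numeric(1), "mrna_length")
  samples <- vector("list", config$n_samples)
  truth <- list()
  for (s in seq_len(config$n_samples)) {
    n <- config$reads_per_sample
    iso <- sample.int(length(mixture), n, replace = TRUE, prob = weights)
    rl <- pmax(config$min_read_length,
               round(stats::rnorm(n, config$read_length_mean,
                                  config$read_length_sd)))
    rl <- pmin(rl, lens[iso])
    st <- floor(stats::runif(n) * (lens[iso] - rl + 1))
    reads <- substring(seqs[iso], st + 1, st + rl)
    ids <- sprintf("s%d_r%06d", s, seq_len(n))
    aln <- mapply(read_alignment, iso, st, rl,
                  MoreArgs = list(mixture = mixture, model = model),
                  SIMPLIFY = FALSE)
    # substitution errors (sequence only; alignment coordinates keep)
    if (config$error_rate > 0) {
      nerr <- stats::rbinom(n, rl, config$error_rate)
      for (r in which(nerr > 0L)) {
        pos <- sample.int(rl[r], nerr[r])
        ch <- strsplit(reads[r], "")[[1L]]
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        reads[r] <- paste0(ch, collapse = "")
      }
    }
    if (config$homopolymer_indel_rate > 0) {
      for (r in seq_len(n)) {
        hp <- gregexpr("([ACGT])\\1{3,}", reads[r])[[1L]]
        if (hp[1L] == -1L) next
        for (h in rev(seq_along(hp))) {  # right-to-left: keep positions valid
          if (stats::runif(1) >= config$homopolymer_indel_rate) next
          at <- as.integer(hp[h])
          type <- if (stats::runif(1) < 0.5) "I" else "D"
          ch <- strsplit(reads[r], "")[[1L]]
          if (type == "I") {
            reads[r] <- paste0(paste0(ch[seq_len(at)], collapse = ""),
                               ch[at], paste0(ch[-seq_len(at)], collapse = ""))
          } else {
            reads[r] <- paste0(ch[-at], collapse = "")
          }
          aln[[r]] <- cigar_apply_indel(aln[[r]], at, type)
        }
      }
    }
    sam <- data.frame(
      qname = ids,
      flag = if (strand == "+") 0L else 16L,
      rname = chrom,
      pos = vapply(aln, function(a) a$pos1, numeric(1)),
      mapq = 60L,
      cigar = vapply(aln, function(a) cigar_string(a, strand), character(1)),
      seq = if (strand == "+") reads
            else vapply(reads, revcomp, character(1), USE.NAMES = FALSE))
    jts <- do.call(rbind, lapply(seq_len(n), function(r) {
      j <- aln[[r]]$junctions
      if (nrow(j)) cbind(j, sample = s) else NULL
    }))
    truth[[s]] <- jts
    names(reads) <- ids
    samples[[s]] <- list(reads = reads, sam = sam,
                         read_isoform = data.frame(
                           read_id = ids,
                           isoform = vapply(mixture, `[[`, character(1),
                                            "name")[iso]))
  }
  tc <- do.call(rbind, truth)
  if (is.null(tc) || nrow(tc) == 0L) {
    truth_counts <- data.frame(start = integer(0), end = integer(0),
                               sample = integer(0), count = integer(0))
  } else {
    tc$count <- 1L
    truth_counts <- stats::aggregate(count ~ start + end + sample,
                                     data = tc, FUN = sum)
  }
  out <- list(samples = samples, truth_counts = truth_counts,
              config = config, chrom = chrom, strand = strand)
  if (!is.null(out_dir)) write_simulation(out, out_dir, genome, model)
  out
}

# Alignment of a read covering mRNA interval [st, st+rl) of isoform k:
# genomic blocks, SAM POS and crossed junctions.
read_alignment <- function(k, st, rl, mixture, model) {
  iso <- mixture[[k]]
  b <- iso$blocks
  blen <- b$gend - b$gstart
  cum <- cumsum(blen)
  m0 <- st; m1 <- st + rl          # mRNA half-open interval
  first <- findInterval(m0, c(0, cum), rightmost.closed = FALSE)
  last <- findInterval(m1 - 1, c(0, cum))
  gs <- integer(0); ge <- integer(0)
  for (j in first:last) {
    lo <- max(m0, if (j == 1L) 0L else cum[j - 1L])
    hi <- min(m1, cum[j])
    off0 <- lo - (if (j == 1L) 0L else cum[j - 1L])
    off1 <- hi - (if (j == 1L) 0L else cum[j - 1L])
    if (model$strand == "+") {
      gs <- c(gs, b$gstart[j] + off0); ge <- c(ge, b$gstart[j] + off1)
    } else {
      gs <- c(gs, b$gend[j] - off1); ge <- c(ge, b$gend[j] - off0)
    }
  }
  # blocks in transcription order; junctions between consecutive ones
  nb <- length(gs)
  if (nb > 1L) {
    i <- seq_len(nb - 1L)
    junctions <- if (model$strand == "+")
      data.frame(start = ge[i], end = gs[i + 1L])
    else
      data.frame(start = ge[i + 1L], end = gs[i])
  } else junctions <- data.frame(start = integer(0), end = integer(0))
  list(gstart = gs, gend = ge, pos1 = min(gs) + 1L,
       junctions = junctions,
       ops = alignment_ops(gs, ge, model$strand))
}

# CIGAR op table in read/transcription order: M blocks with N gaps.
# On the minus strand consecutive transcription blocks descend in
# genomic coordinates, so the gap is gs[j-1] - ge[j].
alignment_ops <- function(gs, ge, strand) {
  nb <- length(gs)
  ops <- data.frame(len = ge[1L] - gs[1L], op = "M")
  if (nb > 1L) for (j in 2L:nb) {
    gap <- if (strand == "+") gs[j] - ge[j - 1L] else gs[j - 1L] - ge[j]
    ops <- rbind(ops, data.frame(len = gap, op = "N"),
                 data.frame(len = ge[j] - gs[j], op = "M"))
  }
  ops
}

# Insert a 1I or 1D at read position `at` (1-based, read orientation).
cigar_apply_indel <- function(aln, at, type) {
  ops <- aln$ops
  read_pos <- 0L
  for (i in seq_len(nrow(ops))) {
    consumes <- ops$op[i] %in% c("M", "I")
    if (!consumes) next
    if (read_pos + ops$len[i] >= at) {
      before <- at - read_pos - 1L
      ins <- data.frame(len = 1L, op = type)
      pieces <- list()
      if (before > 0L) pieces <- c(pieces, list(data.frame(len = before,
                                                           op = ops$op[i])))
      pieces <- c(pieces, list(ins))
      rest <- ops$len[i] - before - (if (type == "D") 1L else 0L)
      if (type == "I") rest <- ops$len[i] - before
      if (rest > 0L) pieces <- c(pieces, list(data.frame(len = rest,
                                                         op = ops$op[i])))
      ops <- rbind(if (i > 1L) ops[seq_len(i - 1L), ] else NULL,
                   do.call(rbind, pieces),
                   if (i < nrow(ops)) ops[(i + 1L):nrow(ops), ] else NULL)
      break
    }
    read_pos <- read_pos + ops$len[i]
  }
  aln$ops <- ops
  aln
}

# Render the op table as a CIGAR string; reference order (reverse the
# transcription-order ops on the minus strand).
cigar_string <- function(aln, strand) {
  ops <- aln$ops
  if (strand == "-") ops <- ops[rev(seq_len(nrow(ops))), ]
  paste0(ops$len, ops$op, collapse = "")
}

write_simulation <- function(sim, out_dir, genome, model) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chrlen <- nchar(genome_sequence(genome, sim$chrom))
  for (s in seq_along(sim$samples)) {
    smp <- sim$samples[[s]]
    dna <- Biostrings::DNAStringSet(smp$reads)
    Biostrings::writeXStringSet(dna, file.path(out_dir,
                                               sprintf("sample%d.fasta", s)))
    write_sam(smp$sam, file.path(out_dir, sprintf("sample%d.sam", s)),
              sim$chrom, chrlen)
  }
  utils::write.table(sim$truth_counts,
                     file.path(out_dir, "truth_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(sim$config), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Write alignments as a SAM file
#'
#' Minimal mandatory-field SAM with an `@SQ` header line.
#'
#' @param sam Data frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`.
#' @param path Output file.
#' @param chrom,chrlen Reference name and length for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path, chrom, chrlen) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrlen)), con)
  if (nrow(sam))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                       sam$qname, sam$flag, sam$rname, as.integer(sam$pos),
                       sam$mapq, sam$cigar, sam$seq), con)
  invisible(path)
}

#' Simulate per-sample junction count tables directly
#'
#' Fast path bypassing read-level simulation: `depth` transcript
#' molecules are sampled per replicate, each carrying every event
#' independently at its rate (events competing for the same canonical
#' junction are resolved in favour of the first listed, a negligible
#' correction at the modelled rates). Per event and sample the
#' alternative junction count is therefore Binomial(depth, rate) and
#' the competing canonical junctions carry the remainder.
#'
#' @param model A [transcript_model()].
#' @param events List of [event_spec()].
#' @param depth Junction-spanning molecules per replicate (>= 1).
#' @param n_samples Number of replicates.
#' @param seed Integer seed.
#' @return List with `counts` (data frame: `start`, `end`, `label`,
#'   `status`, `sample`, `count`) and `truth` (data frame: `event_id`,
#'   `sample`, `true_count`).
#' @export
simulate_junction_counts <- function(model, events, depth,
                                     n_samples = 4L, seed = 1L) {
  stopifnot(depth >= 1)
  set.seed(seed)
  for (ev in events) validate_event(model, ev)
  cj <- derive_canonical_junctions(model)
  K <- length(events)
  aff <- lapply(events, affected_introns, model = model)
  conflicts <- list()
  if (K > 1L) for (i in seq_len(K - 1L)) for (j in (i + 1L):K)
    if (length(intersect(aff[[i]], aff[[j]])))
      conflicts[[length(conflicts) + 1L]] <- c(i, j)
  counts <- list(); truth <- list()
  for (s in seq_len(n_samples)) {
    A <- matrix(stats::runif(depth * K), depth, K) <
      matrix(rep(vapply(events, `[[`, numeric(1), "rate"), each = depth),
             depth, K)
    for (cf in conflicts) A[A[, cf[1L]] & A[, cf[2L]], cf[2L]] <- FALSE
    n_k <- colSums(A)
    canon_loss <- integer(nrow(cj))
    for (k in seq_len(K))
      canon_loss[aff[[k]]] <- canon_loss[aff[[k]]] + n_k[k]
    rows <- data.frame(start = cj$start, end = cj$end, label = cj$label,
                       status = "canonical", sample = s,
                       count = depth - canon_loss)
    for (k in seq_len(K)) {
      jx <- event_junctions(model, events[[k]])
      rows <- rbind(rows, data.frame(
        start = jx$start, end = jx$end,
        label = paste0(events[[k]]$event_id,
                       if (nrow(jx) > 1L) c(".a", ".b") else ""),
        status = "novel", sample = s, count = n_k[k]))
    }
    counts[[s]] <- rows
    truth[[s]] <- data.frame(
      event_id = vapply(events, `[[`, character(1), "event_id"),
      sample = s, true_count = n_k)
  }
  list(counts = do.call(rbind, counts), truth = do.call(rbind, truth))
}

#' Decoy novel junctions for specificity checks
#'
#' Generates spurious low-rate exonic alternative-acceptor events on
#' exons not used by the real event set, emulating the background of
#' sporadic non-canonical junctions that the replicate-consistency
#' filter is meant to reject.
#'
#' @param model A [transcript_model()].
#' @param n Number of decoys.
#' @param rate_range Uniform range the decoy rates are drawn from.
#' @param exclude_exons Exons that real events already touch.
#' @param seed Integer seed.
#' @return List of [event_spec()].
#' @export
decoy_events <- function(model, n = 20L, rate_range = c(1e-4, 5e-4),
                         exclude_exons = integer(0), seed = 1L) {
  set.seed(seed)
  pool <- setdiff(2:(n_exons(model) - 1L), exclude_exons)
  pool <- pool[model$exons$length[pool] > 40L]
  exons <- sample(pool, n, replace = FALSE)
  offs <- -sample(5:30, n, replace = TRUE)
  rates <- stats::runif(n, rate_range[1L], rate_range[2L])
  lapply(seq_len(n), function(i)
    event_spec(sprintf("decoy%02d", i), "alt3ss", rates[i],
               exon = exons[i], offset_nt = offs[i]))
}

#' Plant a misalignment-prone repeat across a junction
#'
#' Copies the first `repeat_length` downstream-exon bases over the
#' donor end of the chosen intron so that the spliced product is
#' identical under a range of intron placements: the classic
#' homopolymer/sequence-homology situation that makes aligned splice
#' sites ambiguous.
#'
#' @param genome Reference sequence.
#' @param model A [transcript_model()].
#' @param intron_ordinal Intron (transcription ordinal) to corrupt.
#' @param repeat_length Repeat length in nt (0 = leave unchanged).
#' @return List with `genome` (modified, same class as input coerced to
#'   [Biostrings::DNAStringSet]) and `shift_range` (integer vector
#'   `c(left, right)`: maximal negative and positive junction shifts
#'   yielding an identical spliced sequence, found by per-base scan).
#' @export
inject_misalignment_artifact <- function(genome, model, intron_ordinal,
                                         repeat_length) {
  cj <- derive_canonical_junctions(model)
  row <- cj[cj$intron_index == intron_ordinal, ]
  s0 <- row$start; e0 <- row$end
  seqc <- genome_sequence(genome, model$chrom)
  ch <- strsplit(seqc, "")[[1L]]
  r <- as.integer(repeat_length)
  flank <- model$exons$length[model$exons$gstart == e0]  # right-side exon
  if (r > 0L) {
    if (r >= (e0 - s0) || r > flank)
      stop("repeat longer than flanking exon")
    ch[s0 + seq_len(r)] <- ch[e0 + seq_len(r)]
  }
  # realized shift range by per-base scan
  right <- 0L
  while (e0 + right + 1L <= length(ch) &&
         ch[s0 + right + 1L] == ch[e0 + right + 1L]) right <- right + 1L
  left <- 0L
  while (s0 - left >= 1L && ch[s0 - left] == ch[e0 - left]) left <- left + 1L
  g <- Biostrings::DNAStringSet(paste0(ch, collapse = ""))
  names(g) <- model$chrom
  list(genome = g, shift_range = c(-left, right))
}
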