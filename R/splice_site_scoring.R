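#' Load splice-site weight matrices
#'
#' Reads donor/acceptor position-weight matrices from a YAML config.
#' The bundled default is a pair of consensus-frequency matrices in
#' the classical weight-matrix (consensus value) style: donor window
#' exon -3..-1 / intron +1..+6, acceptor window intron -13..-1 / first
#' exon base. Scaled scores are invariant under affine transformation
#' of the weights, so any frequency-like scale can be substituted.
#'
#' @param path YAML file; default: the matrices shipped with the
#'   package.
#' @return Named list of `weight_matrix` objects (`donor`,
#'   `acceptor`), each with `site_type`, `exonic` (window bases on the
#'   exon side), `positions`, `weights` (4 x width matrix, rows
#'   A/C/G/T).
#' @export
load_weight_matrices <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "splice_matrices.yaml",
                        package = "dmdsplice")
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(m) {
    w <- do.call(rbind, m$weights[c("A", "C", "G", "T")])
    if (any(is.na(w)) || ncol(w) != length(m$positions))
      stop("weight matrix malformed: need A/C/G/T weights at every position")
    structure(list(site_type = m$site_type, exonic = as.integer(m$exonic),
                   positions = as.integer(m$positions), weights = w),
              class = "weight_matrix")
  })
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %s, window %d nt (%d exonic)\n",
              x$site_type, ncol(x$weights), x$exonic))
  invisible(x)
}

#' Consensus-value score of a splice-site window
#'
#' Sums the per-position weights of the observed bases and rescales
#' between the worst and best achievable windows:
#' `scaled = (raw - min) / (max - min) * 100`, the 0-100 scale used by
#' weight-matrix splice-site tools. Deterministic; windows containing
#' non-ACGT characters score NA and are flagged.
#'
#' @param window Character scalar, length must equal the matrix width.
#' @param matrix A `weight_matrix` from [load_weight_matrices()].
#' @return List of class `site_score`: `window`, `raw`, `scaled`,
#'   `flagged`.
#' @export
consensus_value_score <- function(window, matrix) {
  ch <- strsplit(toupper(window), "")[[1L]]
  if (length(ch) != ncol(matrix$weights))
    stop(sprintf("window length %d does not match matrix width %d",
                 length(ch), ncol(matrix$weights)))
  idx <- match(ch, c("A", "C", "G", "T"))
  if (anyNA(idx))
    return(structure(list(window = window, raw = NA_real_,
                          scaled = NA_real_, flagged = TRUE),
                     class = "site_score"))
  raw <- sum(matrix$weights[cbind(idx, seq_along(idx))])
  lo <- sum(apply(matrix$weights, 2L, min))
  hi <- sum(apply(matrix$weights, 2L, max))
  structure(list(window = window, raw = raw,
                 scaled = (raw - lo) / (hi - lo) * 100, flagged = FALSE),
            class = "site_score")
}

#' @export
print.site_score <- function(x, ...) {
  cat(sprintf("<site_score> %s raw %.1f scaled %.2f%s\n", x$window,
              x$raw, x$scaled, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

# Transcription-oriented window around a splice boundary: `up` bases
# upstream and `down` bases downstream of the (half-open) boundary
# coordinate `gpos` on the genomic plus axis.
txn_window <- function(genome, model, gpos, up, down) {
  seqc <- genome_sequence(genome, model$chrom)
  if (model$strand == "+")
    substr(seqc, gpos - up + 1L, gpos + down)
  else
    revcomp(substr(seqc, gpos - down + 1L, gpos + up))
}

# Score a donor or acceptor splice point given its plus-axis boundary
# coordinate.
score_splice_site <- function(model, genome, boundary, type, matrices) {
  m <- matrices[[type]]
  width <- ncol(m$weights)
  if (type == "donor")
    w <- txn_window(genome, model, boundary, m$exonic, width - m$exonic)
  else
    w <- txn_window(genome, model, boundary, width - m$exonic, m$exonic)
  consensus_value_score(w, m)
}

#' Score the splice sites of an event against the natural sites
#'
#' Computes consensus-value scores for the alternative site(s) an
#' event uses and the natural site(s) they compete with. Alternative
#' 3'/5' splice-site events return the (alt, natural) pair and their
#' score difference; pseudoexons return four sites ordered alt 3'ss,
#' alt 5'ss, then the host intron's flanking constitutive 5'ss and
#' 3'ss; exon skips return the natural sites of the skipped block.
#'
#' @param event A classified `splicing_event`.
#' @param model A [transcript_model()].
#' @param genome Reference sequence.
#' @param matrices Matrices from [load_weight_matrices()].
#' @return Data frame with columns `site`, `type`, `window`, `raw`,
#'   `score`; for alt-ss events an attribute `diff` (alt minus
#'   natural scaled score).
#' @export
score_event_sites <- function(event, model, genome,
                              matrices = load_weight_matrices()) {
  cj <- derive_canonical_junctions(model)
  plus <- model$strand == "+"
  acc_boundary <- function(j) if (plus) j$end else j$start
  don_boundary <- function(j) if (plus) j$start else j$end
  row <- function(site, type, boundary) {
    sc <- score_splice_site(model, genome, boundary, type, matrices)
    data.frame(site = site, type = type, window = sc$window,
               raw = sc$raw, score = sc$scaled)
  }
  if (event$category %in% c("alt3ss", "alt5ss")) {
    type <- if (event$category == "alt3ss") "acceptor" else "donor"
    k <- if (event$category == "alt3ss") event$exon - 1L else event$exon
    altb <- if (type == "acceptor") acc_boundary(event$junctions)
            else don_boundary(event$junctions)
    natb <- if (type == "acceptor") acc_boundary(cj[k, ])
            else don_boundary(cj[k, ])
    out <- rbind(row("alt", type, altb), row("natural", type, natb))
    attr(out, "diff") <- out$score[1L] - out$score[2L]
    return(out)
  }
  if (event$category == "pseudoexon") {
    k <- event$intron_index
    pe_acc <- if (plus) event$pe_start else event$pe_end
    pe_don <- if (plus) event$pe_end else event$pe_start
    out <- rbind(row("pe_alt_3ss", "acceptor", pe_acc),
                 row("pe_alt_5ss", "donor", pe_don),
                 row("flank_5ss", "donor", don_boundary(cj[k, ])),
                 row("flank_3ss", "acceptor", acc_boundary(cj[k, ])))
    return(out)
  }
  if (event$category == "exon_skip") {
    out <- do.call(rbind, lapply(event$exons_skipped, function(x)
      rbind(row(sprintf("ex%d_3ss", x), "acceptor",
                acc_boundary(cj[x - 1L, ])),
            row(sprintf("ex%d_5ss", x), "donor", don_boundary(cj[x, ])))))
    return(out)
  }
  stop(sprintf("no sites to score for category '%s'", event$category))
}

#' Scan all canonical acceptors for NAGNAG tandem motifs
#'
#' Tests the 6-mer spanning each canonical 3' splice site (intron
#' -3..-1, exon +1..+3) for the NAGNAG motif: two overlapping AG
#' acceptors 3 nt apart, each able to produce an isoform differing by
#' one codon.
#'
#' @param model A [transcript_model()].
#' @param genome Reference sequence.
#' @return Integer vector of exon ordinals whose acceptor is a NAGNAG
#'   site.
#' @export
scan_nagnag_acceptors <- function(model, genome) {
  n <- n_exons(model)
  if (n < 2L) return(integer(0))
  hits <- vapply(2:n, function(k)
    grepl("^.AG.AG$", acceptor_window(model, genome, k, 3L, 3L)),
    logical(1))
  (2:n)[hits]
}
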