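---
title: "Profiling alternative splicing in a single deep-sequenced transcript"
author: "dmdsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling alternative splicing in a single deep-sequenced transcript}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmdsplice)
```

## The problem and the design

Splicing analysis needs junction-spanning reads, so a transcript present
at a few molecules per nucleus — the muscle dystrophin mRNA Dp427m is the
motivating case — is effectively invisible to whole-transcriptome
short-read RNA-Seq: typical depths of 50–200× leave events below a few
percent indistinguishable from noise. The design this package supports
amplifies the full-length cDNA (one ~11.3 kb amplicon), sequences it with
long reads (454-style, mean ~387 nt, so most reads cross two or more
junctions), aligns with any spliced aligner, and then analyses the
alignments: the package consumes SAM/BAM, it does not align.

With four replicate libraries of ~69,000 reads the mean per-base depth is
in the thousands, and an event at 1% is expected to contribute >10
junction reads — comfortably detectable. `detection_limit()` and
`expected_reads()` expose this arithmetic.

## Data model

A `transcript_model` is one isoform: ordered exons with genomic and mRNA
coordinates (0-based, half-open throughout; GTF's 1-based inclusive
coordinates are converted at the parser boundary), the strand, and the
mRNA offset of the first codon. All junctions are stored as genomic
plus-strand intron intervals with donor/acceptor roles resolved from the
strand — dystrophin is minus-strand, and storing plus-strand intervals is
what keeps the package interoperable with SAM/BED tooling. A model with
*n* exons has exactly *n* − 1 canonical junctions.

## Junction calling

`extract_junctions_from_cigar()` walks the CIGAR from POS: `M`/`=`/`X`/`D`/`N`
advance the reference, `I`/`S` do not, and every `N` yields one junction
interval. A read counts toward a junction only with at least
`min_anchor` aligned bases on both sides (default 10 nt — long reads make
this cheap, and 1–2 nt overhangs are a classic source of spurious
junctions), at most once per junction, with secondary/supplementary and
unmapped records dropped. Duplicate reads are *not* collapsed: in
amplicon data every read is a PCR descendant and the published counting
is as-is. Coverage is accumulated on mRNA coordinates by projecting
aligned blocks through the model.

## Event classification

Against the canonical junction set, a novel junction is classified
exhaustively and mutually exclusively:

* both ends canonical, ≥1 exon omitted → **exon skip** (`del9`,
  `del28+29`, ...), Δnt = −Σ skipped exon lengths;
* canonical donor, acceptor displaced within the downstream exon →
  **alt 3'ss**, with the *negative* offset convention (−3 nt means a
  3 nt exon truncation); the symmetric donor case → **alt 5'ss**. The
  alternative rendering that counts the new acceptor's exonic position
  (off by one: −60 ↔ "+59") is exposed by `alt_ss_notations()` so the two
  are never conflated silently;
* one canonical end, the other strictly inside the intron →
  **pseudoexon half-junction**. `detect_pseudoexons()` pairs a
  canonical-donor/intronic-acceptor half with an intronic-donor/
  canonical-acceptor half of the same intron into a pseudoexon
  event; unpaired halves stay unclassified. An event is flagged
  `single_read_verified` only when one read crosses both junctions —
  long reads make the whole inserted exon retrievable from a single
  read, the strongest evidence the inclusion is real;
* anything else → unclassified, with a reason.

A design choice worth stating: a canonical-donor junction ending inside
the intron could in principle also be an intronic alt 3'ss (exon
extension). We resolve it as a pseudoexon candidate and let pairing
decide, because in this kind of data deep-intronic acceptors essentially
always come from cryptic exons; an unpaired half is reported
unclassified rather than guessed.

### Misalignment ambiguity

Homopolymers and short repeats straddling a junction let an aligner
place the same spliced read at several shifted intron positions;
published analyses of this design discarded two such loci by manual
inspection. `flag_ambiguous_junction()` formalizes the rule: it computes
the maximal shift interval under which splicing the shifted intron
yields an identical product (per-base scan, default `max_shift` 10 nt,
enough for the homopolymer runs long-read chemistry produces), and flags
the junction when a shifted variant coincides with a canonical junction
or another candidate. The pipeline excludes flagged junctions *before*
classification and lists them separately in QC — they are artifacts, not
events. `inject_misalignment_artifact()` plants such repeats in the
synthetic genome so the exclusion path is testable.

### Reading frame

Δnt mod 3 ≠ 0 is frameshifting. Frame-preserving deletions are called
in-frame with `codons_removed()` giving the codon count; frame-preserving
*insertions* are screened for stop codons read in the transcript frame
when the inserted sequence is available (an insertion of length ≡ 0
mod 3 can still truncate the protein — the 162-nt fixture pseudoexon
carries an in-frame stop for exactly this reason). Without sequence the
call is length-only and explicitly flagged. Events entirely upstream of
the CDS start are non-coding (`unknown`).

## Quantification

PSI is intron-centric, from junction reads only (see the README for the
three formulas). ASE% = (1 − PSI)·100 for skips and alternative splice
sites, PSI·100 for pseudoexons. Samples with a zero denominator are
excluded from the mean ± SD (sample SD, n − 1), never imputed as zero.
The replicate-consistency filter admits an event with ≥5 supporting
reads (inclusive) in ≥2 of the replicates; for pseudoexons the
per-sample support is conservatively the *minimum* of the two junction
counts — the published rule does not say whether it applies per junction
or per event, and the conservative reading is documented in the output
rather than hidden. Multi-exon skips use the two junctions flanking the
whole skipped block, matching the competing-junction logic.

`isoform_ratio_from_peaks()` and `concordance_table()` implement the
orthogonal-validation arithmetic (fluorescent peak areas normalized to
100 per replicate, mean ± SD across ≥3 assays, `"nd"` for undetected).

## Splice-site scoring

`consensus_value_score()` is the classical weight-matrix score: the sum
of per-position weights of the observed window bases, rescaled between
the worst and best achievable windows to 0–100. The bundled YAML
matrices are consensus-frequency tables in the classical mammalian
style (donor −3..+6, acceptor −13..+1); the windows and weights are
deliberately editable because published web tools do not fully specify
theirs, and we make no claim of reproducing any specific tool's printed
scores. Scaled scores are invariant under affine transformation of the
weights, and moving any base toward the consensus never lowers the
score — both properties are tested. `scan_nagnag_acceptors()` tests each
canonical acceptor's −3..+3 6-mer for the NAGNAG tandem motif (two AGs
3 nt apart, producing isoforms one codon apart).

## The synthetic study conditions

The simulator exists so that every stage is exercised under conditions
matching the targeted-amplicon study this package models; its defaults
*are* those conditions and are not tuned per run:

* 4 replicate libraries, 69,060 reads each, mean read length 387 nt
  (truncated normal, floor 40 nt — the post-trimming minimum). The
  length SD is not published; 120 nt is typical for the platform.
* Error model: 0.1% substitutions and a 0.2% per-run chance that a
  homopolymer ≥4 nt gains or loses one base (sequence and CIGAR stay
  consistent; flow-space simulation is out of scope).
* The fixture transcript is *synthetic*: the real 79-exon length vector
  is not published, so only reported characteristics are pinned — 79
  exons, 11,300 nt of mRNA, exon 71 = 39 nt, exon 78 = 32 nt,
  pseudoexons of 162/66/84 nt in introns 1/21/51, exonic alternative
  acceptors of −2/−3/−60/−4 nt on exons 20/54/76/78, a CAGCAG tandem
  acceptor at exon 54 only, a strong alternative acceptor inside exon
  76, and an in-frame stop inside the 162-nt pseudoexon. Everything
  else (lengths, intron sizes, sequence) is generated deterministically.
* The twelve events are planted at their reported tissue rates
  (0.18%–3.06%); event molecules are sampled independently (no
  co-occurrence data exist to calibrate anything richer), and the
  isoform mixture is linearized to single-event isoforms — joint-event
  molecules have probability ≤ ~10⁻³ at these rates and are neglected.
* The fast count-level simulator draws per-molecule event indicators and
  derives junction counts, so each event's alternative count is
  Binomial(depth, rate) and competing canonical junctions carry the
  remainder; it agrees with the read-level route within Monte-Carlo
  error (tested).

What the simulator does **not** emulate: aligner-specific error
profiles, soft-clipping behaviour, chimeric reads, template-switching
artifacts, library-prep coverage bias along the amplicon, or real
intronic sequence context. Passing tests therefore demonstrate the
*analysis* is correct under the stated generative model, not that any
given aligner's output on real libraries is artifact-free — which is
precisely why the ambiguity-exclusion and replicate-consistency stages
exist.

## Numerical and degenerate-input choices

* Coordinates: 0-based half-open everywhere internally; conversion only
  at parser/writer boundaries.
* PSI with zero denominator: NA, excluded from summaries.
* Filter thresholds are inclusive (≥5, ≥2); raising either can only
  shrink the passing set (tested monotonicity).
* Pseudoexon pairing with several halves per intron pairs them in
  transcription order; leftovers stay unclassified.
* Single-sample summaries report SD 0 by convention.
* Windows containing non-ACGT bases score NA and are flagged rather
  than silently skipped.
* All randomness flows from explicit integer seeds; fixed seed gives
  byte-identical simulator output and deterministic pipeline reports.

## Problem sizes used by the test-suite and acceptance script

Unit and property tests run on a 5-exon toy model and on the 79-exon
fixture with thousands of reads or 2,000 junction-spanning molecules per
locus — the depth regime at which the published per-junction counts sit,
and comfortable for routine test runs. The parameter-recovery check
averages 200 simulated replicate sets (depth 2,000, 4 samples) and
requires each event's mean estimated ASE% to sit within 3 Monte-Carlo
standard errors of its configured rate. The acceptance script simulates
the filter experiment over 20 seeds and reports the majority outcome. At
depth 2,000 the weakest planted event (0.18%, ~3.6 expected
reads/sample) clears the 5-read/2-sample rule with probability ≈ 0.34
per replicate set, so the modal inventory size is 11 rather than 12 —
the detection-limit arithmetic made visible; the deeper real libraries
evidently sat above this boundary at that locus.

## Known limitations

* One isoform at a time: multi-isoform gene models (e.g. the short
  dystrophin isoforms from internal promoters) are out of scope.
* Alternative splice sites displaced *into* the intron are only
  recovered as pseudoexon halves, not as intronic alt-ss events.
* Frame prediction ignores junction-spanning codons created by
  deletions (length arithmetic only) and protein-domain consequences.
* The PWM scorer is a consensus-value model; maximum-entropy scoring
  would need external model files and is intentionally not bundled.
* Event rates are treated as independent; linked events would need a
  co-occurrence-aware mixture.
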