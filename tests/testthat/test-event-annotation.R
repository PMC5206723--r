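test_that("junctions classify into the reported categories", {
  m <- FX$model
  cj <- derive_canonical_junctions(m)
  ex <- m$exons
  # canonical passes through
  expect_equal(classify_junction(cj$start[10L], cj$end[10L], m)$category,
               "canonical")
  # donor of exon 8 joined to acceptor of exon 10: skip of exon 9
  sk <- classify_junction(cj$start[8L], cj$end[9L], m)
  expect_equal(sk$category, "exon_skip")
  expect_equal(sk$exons_skipped, 9L)
  expect_equal(sk$delta_nt, -ex$length[9L])
  expect_equal(event_label(sk), "del9")
  # multi-exon skip labelling
  sk2 <- classify_junction(cj$start[27L], cj$end[29L], m)
  expect_equal(sk2$exons_skipped, c(28L, 29L))
  expect_equal(event_label(sk2), "del28+29")
  # acceptor displaced 3 nt into exon 54
  a54 <- classify_junction(cj$start[53L], cj$end[53L] + 3L, m)
  expect_equal(a54$category, "alt3ss")
  expect_equal(a54$offset_nt, -3L)
  expect_equal(a54$delta_nt, -3L)
  # acceptor displaced 60 nt into exon 76
  a76 <- classify_junction(cj$start[75L], cj$end[75L] + 60L, m)
  expect_equal(a76$offset_nt, -60L)
  # donor displaced into the upstream exon: alt 5'ss
  a5 <- classify_junction(cj$start[30L] - 6L, cj$end[30L], m)
  expect_equal(a5$category, "alt5ss")
  expect_equal(a5$offset_nt, -6L)
  # intronic one-sided junction: pseudoexon half
  h <- classify_junction(cj$start[1L], cj$start[1L] + 400L, m)
  expect_equal(h$category, "pseudoexon_half")
  expect_equal(h$side, "donor_side")
  # no canonical end
  u <- classify_junction(cj$start[1L] + 5L, cj$end[1L] - 5L, m)
  expect_equal(u$category, "unclassified")
})

test_that("classification is exhaustive and single-valued on random junctions", {
  set.seed(202)
  m <- FXM$model           # minus strand exercises the strand logic
  cj <- derive_canonical_junctions(m)
  cats <- c("canonical", "exon_skip", "alt3ss", "alt5ss",
            "pseudoexon_half", "unclassified")
  span <- range(c(cj$start, cj$end))
  for (i in 1:200) {
    s <- sample(span[1L]:(span[2L] - 2L), 1L)
    e <- sample((s + 1L):span[2L], 1L)
    # mix in canonical endpoints half the time
    if (runif(1) < 0.5) s <- sample(cj$start, 1L)
    if (runif(1) < 0.5) e <- sample(cj$end, 1L)
    if (e <= s) next
    ev <- classify_junction(s, e, m)
    expect_true(ev$category %in% cats)
    expect_length(ev$category, 1L)
  }
})

test_that("pseudoexon halves pair into verified events; orphans stay", {
  full <- annotate_fixture_events(FX)
  pe <- Filter(function(e) e$category == "pseudoexon", full)
  expect_length(pe, 3L)
  expect_setequal(vapply(pe, `[[`, integer(1), "pe_length"),
                  c(162L, 66L, 84L))
  expect_true(all(vapply(pe, function(e) e$flags$single_read_verified,
                         logical(1))))
  # without co-occurrence the events pair but are not verified
  full2 <- annotate_fixture_events(FX, with_cooc = FALSE)
  pe2 <- Filter(function(e) e$category == "pseudoexon", full2)
  expect_true(all(!vapply(pe2, function(e) e$flags$single_read_verified,
                          logical(1))))
  # a half-junction with no partner is not emitted as an event
  m <- FX$model
  cj <- derive_canonical_junctions(m)
  lone <- classify_junction(cj$start[1L], cj$start[1L] + 400L, m)
  out <- detect_pseudoexons(list(lone), m)
  expect_equal(out[[1L]]$category, "pseudoexon_half")
})

test_that("NAGNAG tandem acceptors are recognized from sequence", {
  full <- annotate_fixture_events(FX)
  a54 <- Filter(function(e) e$category == "alt3ss" && e$offset_nt == -3L,
                full)[[1L]]
  a54 <- detect_nagnag(a54, FX$model, FX$genome)
  expect_true(a54$flags$nagnag)
  # minus-strand fixture gives the same answer
  fullm <- annotate_fixture_events(FXM)
  b54 <- Filter(function(e) e$category == "alt3ss" && e$offset_nt == -3L,
                fullm)[[1L]]
  expect_true(detect_nagnag(b54, FXM$model, FXM$genome)$flags$nagnag)
  # CTTCAG: first triplet lacks AG -> not a tandem site
  toy <- toy_fixture()
  g <- as.character(toy$genome[[1L]])
  ex2 <- toy$model$exons[2L, ]
  substr(g, ex2$gstart - 2L, ex2$gstart + 3L) <- "CTTCAG"
  fake <- classify_junction(
    derive_canonical_junctions(toy$model)$start[1L],
    derive_canonical_junctions(toy$model)$end[1L] + 3L, toy$model)
  fake <- detect_nagnag(fake, toy$model, g)
  expect_false(fake$flags$nagnag)
  # precondition: only |offset| == 3 is evaluated
  a76 <- Filter(function(e) e$category == "alt3ss" && e$offset_nt == -60L,
                full)[[1L]]
  expect_error(detect_nagnag(a76, FX$model, FX$genome), "offset")
  # no sequence -> unknown
  expect_message(out <- detect_nagnag(a54, FX$model, NULL), "unknown")
  expect_true(is.na(out$flags$nagnag))
})

test_that("shift ambiguity equals a brute-force spliced-sequence scan", {
  toy <- toy_fixture()
  m <- toy$model
  cj <- derive_canonical_junctions(m)
  # brute force: splice out [s+sh, e+sh) between fixed outer anchors
  # and compare the full spliced products
  brute_force_shifts <- function(genome, s, e, max_shift = 10L) {
    ch <- as.character(genome[[1L]])
    splice <- function(sh) paste0(substr(ch, s - 30L + 1L, s + sh),
                                  substr(ch, e + sh + 1L, e + 30L))
    ref <- splice(0L)
    ok <- vapply(-max_shift:max_shift, function(sh) splice(sh) == ref,
                 logical(1))
    range((-max_shift:max_shift)[ok])
  }
  for (r in c(0L, 2L, 4L, 7L)) {
    inj <- inject_misalignment_artifact(toy$genome, m, 2L, r)
    fl <- flag_ambiguous_junction(cj$start[2L], cj$end[2L], inj$genome, m)
    expect_equal(fl$shift_range,
                 brute_force_shifts(inj$genome, cj$start[2L], cj$end[2L]),
                 info = sprintf("repeat %d", r))
  }
})

test_that("junctions shift-equivalent to a canonical one are flagged", {
  toy <- toy_fixture()
  m <- toy$model
  cj <- derive_canonical_junctions(m)
  inj <- inject_misalignment_artifact(toy$genome, m, 2L, 4L)
  # a 'novel' junction that is the canonical intron 2 shifted by +2
  fl <- flag_ambiguous_junction(cj$start[2L] + 2L, cj$end[2L] + 2L,
                                inj$genome, m)
  expect_true(fl$ambiguous)
  expect_true(any(fl$coincides$shift == -2L))
  # junctions with no canonical-coinciding shift are not flagged
  fl5 <- flag_ambiguous_junction(cj$start[4L], cj$end[4L], toy$genome, m)
  expect_false(fl5$ambiguous)
})

test_that("reading-frame prediction follows length and stop-codon rules", {
  full <- annotate_fixture_events(FX)
  m <- FX$model
  by_id <- function(id) Filter(function(e)
    identical(e$event_id, id), full)[[1L]]
  # skip of the 32-nt exon 78: frameshift
  expect_equal(predict_reading_frame(by_id("del78"), m)$frame, "out_of_frame")
  # skip of the 39-nt exon 71: in frame
  expect_equal(predict_reading_frame(by_id("del71"), m)$frame, "in_frame")
  # -60 acceptor: in frame, 20 codons removed
  a76 <- predict_reading_frame(by_id("a3ss_ex76"), m)
  expect_equal(a76$frame, "in_frame")
  expect_equal(codons_removed(a76$delta_nt), 20L)
  # -3 acceptor: removes exactly one codon
  a54 <- predict_reading_frame(by_id("a3ss_ex54"), m)
  expect_equal(a54$frame, "in_frame")
  expect_equal(codons_removed(a54$delta_nt), 1L)
  # 162-nt insertion carrying an in-frame stop
  pe1 <- Filter(function(e) e$category == "pseudoexon" &&
                  e$pe_length == 162L, full)[[1L]]
  ins <- txn_window(FX$genome, m,
                    if (m$strand == "+") pe1$pe_start else pe1$pe_end,
                    0L, pe1$pe_length)
  expect_equal(predict_reading_frame(pe1, m, ins)$frame, "out_of_frame_stop")
  # frame-preserving insertions without stops stay in frame
  pe21 <- Filter(function(e) e$category == "pseudoexon" &&
                   e$pe_length == 66L, full)[[1L]]
  ins21 <- txn_window(FX$genome, m,
                      if (m$strand == "+") pe21$pe_start else pe21$pe_end,
                      0L, pe21$pe_length)
  expect_equal(predict_reading_frame(pe21, m, ins21)$frame, "in_frame")
  # insertion without sequence: length-only with a warning
  expect_warning(lo <- predict_reading_frame(pe21, m), "length only")
  expect_equal(lo$frame, "in_frame")
  expect_true(lo$flags$frame_length_only)
  # event upstream of the CDS start is non-coding
  m2 <- TOY$model; m2$cds_start_mrna <- 400L
  ev <- classify_junction(derive_canonical_junctions(m2)$start[1L],
                          derive_canonical_junctions(m2)$end[1L] + 3L, m2)
  expect_equal(predict_reading_frame(ev, m2)$frame, "unknown")
})

test_that("both alt-acceptor offset notations are exposed", {
  n <- alt_ss_notations(-60L)
  expect_equal(n$truncation_nt, -60L)
  expect_equal(n$acceptor_position, 59L)
  expect_equal(alt_ss_notations(-3L)$acceptor_position, 2L)
})
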