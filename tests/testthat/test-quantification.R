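test_that("intron-centric PSI follows the competing-junction formulas", {
  m <- TOY$model
  cj <- derive_canonical_junctions(m)
  # alt3ss on exon 3: canonical competitor is intron 2
  alt <- classify_junction(cj$start[2L], cj$end[2L] + 6L, m)
  mk <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(start = r[[1L]], end = r[[2L]], sample = 1L,
                 count = r[[3L]])))
  }
  counts <- mk(list(cj$start[2L], cj$end[2L], 100L),
               list(alt$junctions$start, alt$junctions$end, 0L))
  expect_equal(compute_psi(alt, counts, m, 1L)$psi, 1)
  counts <- mk(list(cj$start[2L], cj$end[2L], 0L),
               list(alt$junctions$start, alt$junctions$end, 50L))
  expect_equal(compute_psi(alt, counts, m, 1L)$psi, 0)
  # zero denominator: undefined, flagged as NA
  counts <- mk(list(cj$start[2L], cj$end[2L], 0L),
               list(alt$junctions$start, alt$junctions$end, 0L))
  expect_true(is.na(compute_psi(alt, counts, m, 1L)$psi))
  # skip event: psi = (i1 + i2) / (i1 + i2 + 2e)
  sk <- classify_junction(cj$start[2L], cj$end[3L], m)
  counts <- mk(list(cj$start[2L], cj$end[2L], 994L),
               list(cj$start[3L], cj$end[3L], 994L),
               list(sk$junctions$start, sk$junctions$end, 6L))
  q <- compute_psi(sk, counts, m, 1L)
  expect_equal(q$psi, 1988 / 2000)
  expect_equal(psi_to_ase_percent("exon_skip", q$psi), 0.6)
  # pseudoexon: inclusion reads on its two junctions, exclusion on host
  fx <- FX
  full <- annotate_fixture_events(fx)
  pe <- Filter(function(e) e$category == "pseudoexon" &&
                 e$pe_length == 162L, full)[[1L]]
  cjf <- derive_canonical_junctions(fx$model)
  k <- pe$intron_index
  counts <- mk(list(pe$junctions$start[1L], pe$junctions$end[1L], 30L),
               list(pe$junctions$start[2L], pe$junctions$end[2L], 30L),
               list(cjf$start[k], cjf$end[k], 970L))
  q <- compute_psi(pe, counts, fx$model, 1L)
  expect_equal(q$psi, 60 / (60 + 1940))
  expect_equal(q$support, 30L)
})

test_that("ASE conversion matches the reported orientation per category", {
  expect_equal(round(psi_to_ase_percent("exon_skip", 0.9937), 2), 0.63)
  expect_equal(round(psi_to_ase_percent("pseudoexon", 0.0306), 2), 3.06)
  expect_equal(psi_to_ase_percent("exon_skip", 1), 0)
  expect_equal(psi_to_ase_percent("alt3ss", 0.9), 10)
  expect_true(is.na(psi_to_ase_percent("alt3ss", NA_real_)))
  # bounds always hold
  set.seed(5)
  for (p in runif(50)) {
    a <- psi_to_ase_percent(sample(c("exon_skip", "pseudoexon", "alt3ss"), 1), p)
    expect_gte(a, 0); expect_lte(a, 100)
  }
})

test_that("the replicate-consistency filter is inclusive and monotone", {
  expect_true(replicate_filter(c(6, 7, 0, 0)))
  expect_true(replicate_filter(c(5, 5, 0, 0)))   # threshold inclusive
  expect_false(replicate_filter(c(4, 9, 4, 4)))  # one sample only
  expect_true(replicate_filter(c(11, 28, 15, 19)))  # seen in all four
  # monotonicity: raising either threshold never flips fail -> pass
  set.seed(99)
  for (i in 1:100) {
    counts <- rpois(4, 4)
    for (mr in 5:7) for (ms in 2:4) {
      if (replicate_filter(counts, mr, ms))
        expect_true(replicate_filter(counts, mr - 1L, ms))
    }
  }
})

test_that("cross-sample summaries use the sample SD and drop NAs", {
  s <- summarize_across_samples(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sd(c(1, 2, 3, 4)))
  expect_equal(round(s$sd, 2), 1.29)
  expect_equal(summarize_across_samples(rep(3.06, 4))$sd, 0)
  one <- summarize_across_samples(c(NA, 7.2, NA, NA))
  expect_equal(one$mean, 7.2)
  expect_equal(one$sd, 0)
  expect_equal(one$n, 1L)
})

test_that("detection-limit arithmetic matches the depth argument", {
  expect_equal(detection_limit(1000, 10), 1)
  expect_equal(detection_limit(1363, 10), 10 / 1363 * 100)
  expect_equal(round(detection_limit(1363, 10), 3), 0.734)
  er <- expected_reads(1, 1363)
  expect_equal(er$expected, 13.63)
  expect_true(er$detectable)
  expect_false(expected_reads(0.5, 1363)$detectable)
})

test_that("peak-area ratios normalize to 100 and summarize across assays", {
  p <- data.frame(replicate = 1L, isoform = c("inc", "skip"),
                  area = c(7.56, 92.44))
  r <- isoform_ratio_from_peaks(p)
  expect_equal(r$per_replicate$ratio, c(7.56, 92.44))
  p2 <- data.frame(replicate = 1L, isoform = c("a", "b"), area = c(1, 1))
  expect_equal(isoform_ratio_from_peaks(p2)$per_replicate$ratio, c(50, 50))
  p3 <- data.frame(replicate = 1L, isoform = c("a", "b", "c"),
                   area = c(1, 1, 2))
  expect_equal(isoform_ratio_from_peaks(p3)$per_replicate$ratio,
               c(25, 25, 50))
  # property: ratios sum to 100 exactly per replicate
  set.seed(12)
  pr <- data.frame(replicate = rep(1:5, each = 3),
                   isoform = rep(c("a", "b", "c"), 5),
                   area = runif(15, 0.1, 50))
  out <- isoform_ratio_from_peaks(pr)
  sums <- tapply(out$per_replicate$ratio, out$per_replicate$replicate, sum)
  expect_equal(as.numeric(sums), rep(100, 5))
  expect_equal(sum(out$summary$mean), 100)
  expect_error(isoform_ratio_from_peaks(
    data.frame(replicate = 1, isoform = c("a", "b"), area = c(0, 0))),
    "zero total")
  expect_error(isoform_ratio_from_peaks(
    data.frame(replicate = 1, isoform = "a", area = 5)), "fewer than 2")
})

test_that("concordance tables render nd for missing assays", {
  rs <- data.frame(event_id = c("PE1a", "del71", "del78"),
                   mean = c(3.06, 1.81, 2.48), sd = c(1.00, 0.67, 0.57))
  gel <- data.frame(event_id = c("PE1a", "del71"),
                    mean = c(12.2, 7.20), sd = c(2.14, 1.63))
  frag <- data.frame(event_id = c("PE1a", "del71", "del78"),
                     mean = c(7.56, 5.28, 4.10), sd = c(3.55, 0.64, 0.30))
  tab <- concordance_table(rs, gel = gel, fragment = frag)
  expect_equal(tab$gel[3L], "nd")
  expect_equal(tab$fragment[3L], "4.10 (+/-0.30)")
  expect_equal(tab$diff_fragment[1L], 4.5)
  # identical inputs give zero differences
  same <- concordance_table(rs, again = rs)
  expect_true(all(same$diff_again == 0))
})

test_that("quantify_events recovers simulated rates and applies the filter", {
  fx <- FX
  full <- annotate_fixture_events(fx)
  sim <- simulate_junction_counts(fx$model, fx$events, depth = 2000,
                                  n_samples = 4, seed = 3)
  q <- quantify_events(full, sim$counts, fx$model)
  expect_equal(nrow(q), 12L)
  expect_true(all(q$mean_ase >= 0 & q$mean_ase <= 100))
  truth <- fixture_event_table(fx)
  # strong events (expected >= 20 reads/sample) are quantified near truth
  strong <- c("del71", "del78", "a3ss_ex54")
  for (id in strong) {
    est <- q$mean_ase[q$event_id == id]
    tru <- truth$ase_percent[truth$event_id == id]
    expect_lt(abs(est - tru) / tru, 0.5)
    expect_true(q$passes_filter[q$event_id == id])
  }
})
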