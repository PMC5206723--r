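test_that("isoform mixture weights follow the event rates and sum to 1", {
  m <- FX$model
  expect_length(simulate_isoform_mixture(m, list()), 1L)
  expect_equal(simulate_isoform_mixture(m, list())[[1L]]$weight, 1)
  one <- simulate_isoform_mixture(m, list(FX$events$del78))
  expect_equal(vapply(one, `[[`, numeric(1), "weight"), c(0.9752, 0.0248))
  # two events in distinct introns: canonical + one isoform per event,
  # weights matching the enumerated single-event law
  a <- 0.1; b <- 0.25
  two <- simulate_isoform_mixture(m, list(
    event_spec("e1", "exon_skip", a, exons = 9L),
    event_spec("e2", "pseudoexon", b,
               pe_start = FX$events$PE21X$pe_start,
               pe_end = FX$events$PE21X$pe_end)))
  expect_length(two, 3L)
  expect_equal(vapply(two, `[[`, numeric(1), "weight"), c(1 - a - b, a, b))
  expect_equal(sum(vapply(two, `[[`, numeric(1), "weight")), 1)
  expect_error(simulate_isoform_mixture(m, list(
    event_spec("x", "exon_skip", 0.7, exons = 9L),
    event_spec("y", "exon_skip", 0.7, exons = 12L))), "> 1")
})

test_that("event specs are validated against the model", {
  m <- FX$model
  expect_error(validate_event <- event_junctions(
    m, event_spec("bad", "alt3ss", 0.1, exon = 76L, offset_nt = -500L)),
    "exhausts")
  expect_error(event_junctions(
    m, event_spec("bad", "exon_skip", 0.1, exons = 1L)), "internal")
  expect_error(event_junctions(
    m, event_spec("bad", "pseudoexon", 0.1, pe_start = 0L, pe_end = 50L)),
    "intron")
})

test_that("count-level simulator matches the binomial law", {
  m <- FX$model
  # degenerate rates
  ev0 <- list(event_spec("z", "exon_skip", 0, exons = 9L))
  s0 <- simulate_junction_counts(m, ev0, depth = 500, n_samples = 3, seed = 1)
  expect_true(all(s0$truth$true_count == 0L))
  expect_true(all(s0$counts$count[s0$counts$status == "novel"] == 0L))
  ev1 <- list(event_spec("all", "exon_skip", 1, exons = 9L))
  s1 <- simulate_junction_counts(m, ev1, depth = 500, n_samples = 2, seed = 1)
  aff <- s1$counts$status == "canonical" & s1$counts$label %in% c("ex8-ex9", "ex9-ex10")
  expect_true(all(s1$counts$count[aff] == 0L))
  # binomial expectation: depth 2000 at rate 0.0063 -> mean 12.6
  ev <- list(event_spec("d", "exon_skip", 0.0063, exons = 9L))
  s <- simulate_junction_counts(m, ev, depth = 2000, n_samples = 200, seed = 9)
  mc_se <- sqrt(2000 * 0.0063 * (1 - 0.0063) / 200)
  expect_lt(abs(mean(s$truth$true_count) - 12.6), 3 * mc_se)
  # reproducibility under seed
  s2 <- simulate_junction_counts(m, ev, depth = 2000, n_samples = 200, seed = 9)
  expect_identical(s, s2)
})

test_that("error-free reads are exact mRNA substrings and deterministic", {
  m <- TOY$model
  mix <- simulate_isoform_mixture(m, list())
  cfg <- sim_config(n_samples = 1, reads_per_sample = 200,
                    read_length_mean = 150, read_length_sd = 30,
                    error_rate = 0, homopolymer_indel_rate = 0, seed = 21)
  sim <- simulate_reads(mix, cfg, TOY$genome, m)
  mrna <- transcript_sequence(m, TOY$genome)
  expect_true(all(vapply(sim$samples[[1L]]$reads, grepl, logical(1),
                         x = mrna, fixed = TRUE)))
  sim2 <- simulate_reads(mix, cfg, TOY$genome, m)
  expect_identical(sim$samples[[1L]]$reads, sim2$samples[[1L]]$reads)
  expect_identical(sim$samples[[1L]]$sam, sim2$samples[[1L]]$sam)
})

test_that("simulated coverage matches the closed form R*L/T within 10%", {
  m <- TOY$model
  mix <- simulate_isoform_mixture(m, list())
  cfg <- sim_config(n_samples = 1, reads_per_sample = 1000,
                    read_length_mean = 120, read_length_sd = 20,
                    error_rate = 0, homopolymer_indel_rate = 0, seed = 4)
  sim <- simulate_reads(mix, cfg, TOY$genome, m)
  cov <- coverage_profile(sim$samples[[1L]]$sam, m)
  expect_lt(abs(cov$mean - 1000 * 120 / m$mrna_length),
            0.1 * 1000 * 120 / m$mrna_length)
})

test_that("a pseudoexon at rate 1 puts two N gaps in every host-intron read", {
  fx <- FX
  m <- fx$model
  pe <- fx$events$PE1a
  pe$rate <- 1
  mix <- simulate_isoform_mixture(m, list(pe))
  cfg <- sim_config(n_samples = 1, reads_per_sample = 400,
                    read_length_mean = 500, read_length_sd = 50,
                    error_rate = 0, homopolymer_indel_rate = 0, seed = 6)
  sim <- simulate_reads(mix, cfg, fx$genome, m)
  jx <- event_junctions(m, pe)
  tc <- sim$truth_counts
  host <- derive_canonical_junctions(m)[1L, ]
  expect_equal(sum(tc$count[tc$start == host$start & tc$end == host$end]), 0L)
  n1 <- sum(tc$count[tc$start == jx$start[1L] & tc$end == jx$end[1L]])
  n2 <- sum(tc$count[tc$start == jx$start[2L] & tc$end == jx$end[2L]])
  expect_gt(n1, 0L)
  expect_gt(n2, 0L)
  # whole pseudoexon retrievable from single reads
  cooc <- cooccurrence_records(sim$samples[[1L]]$sam)
  ev <- detect_pseudoexons(classify_junctions(unique(tc[, c("start", "end")]),
                                              m), m, cooc)
  pe_ev <- Filter(function(e) e$category == "pseudoexon", ev)
  expect_length(pe_ev, 1L)
  expect_true(pe_ev[[1L]]$flags$single_read_verified)
  expect_equal(pe_ev[[1L]]$pe_length, 162L)
})

test_that("read-level and count-level simulators agree at matched depth", {
  # a short skipped exon (39 nt of 11,300) keeps the two isoforms'
  # junction-crossing probabilities equal to within ~0.3%, so the
  # alternative fraction among locus reads is binomial at the event rate
  m <- FX$model
  ev <- FX$events$del71
  ev$rate <- 0.1
  mix <- simulate_isoform_mixture(m, list(ev))
  cfg <- sim_config(n_samples = 1, reads_per_sample = 10000,
                    error_rate = 0, homopolymer_indel_rate = 0, seed = 13)
  sim <- simulate_reads(mix, cfg, FX$genome, m)
  tc <- sim$truth_counts
  jx <- event_junctions(m, ev)
  cj <- derive_canonical_junctions(m)
  skip_n <- sum(tc$count[tc$start == jx$start & tc$end == jx$end])
  can_n <- sum(tc$count[tc$start == cj$start[70L] & tc$end == cj$end[70L]])
  n_locus <- skip_n + can_n
  frac <- skip_n / n_locus
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n_locus))
})

test_that("homopolymer indels keep SEQ and CIGAR consistent", {
  m <- TOY$model
  mix <- simulate_isoform_mixture(m, list())
  cfg <- sim_config(n_samples = 1, reads_per_sample = 300,
                    read_length_mean = 150, read_length_sd = 30,
                    error_rate = 0.01, homopolymer_indel_rate = 0.5, seed = 8)
  sim <- simulate_reads(mix, cfg, TOY$genome, m)
  sam <- sim$samples[[1L]]$sam
  read_len_from_cigar <- function(cig) {
    ops <- regmatches(cig, gregexpr("\\d+[A-Z=]", cig))[[1L]]
    sum(as.integer(sub("[A-Z=]$", "", ops[grepl("[MI=X]$", ops)])))
  }
  expect_equal(vapply(sam$cigar, read_len_from_cigar, numeric(1),
                      USE.NAMES = FALSE), nchar(sam$seq))
  expect_true(any(grepl("[ID]", sam$cigar)))  # indels were actually simulated
})

test_that("misalignment injection widens the shift range as planted", {
  fx <- toy_fixture()
  inj0 <- inject_misalignment_artifact(fx$genome, fx$model, 2L, 0L)
  fl0 <- flag_ambiguous_junction(
    derive_canonical_junctions(fx$model)$start[2L],
    derive_canonical_junctions(fx$model)$end[2L], inj0$genome, fx$model)
  expect_equal(fl0$shift_range, inj0$shift_range)
  inj <- inject_misalignment_artifact(fx$genome, fx$model, 2L, 4L)
  expect_gte(inj$shift_range[2L], 4L)
  expect_error(inject_misalignment_artifact(fx$genome, fx$model, 2L, 5000L),
               "flank")
})

test_that("simulation files are written in standard formats", {
  m <- TOY$model
  mix <- simulate_isoform_mixture(m, list())
  cfg <- sim_config(n_samples = 2, reads_per_sample = 50,
                    read_length_mean = 120, read_length_sd = 10,
                    error_rate = 0, homopolymer_indel_rate = 0, seed = 2)
  dir <- tempfile()
  simulate_reads(mix, cfg, TOY$genome, m, out_dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("sample1.fasta", "sample2.sam", "truth_counts.tsv", "config.yaml")))))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "sample1.fasta"))
  expect_length(fa, 50L)
  cfg2 <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg2$reads_per_sample, 50L)
})
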