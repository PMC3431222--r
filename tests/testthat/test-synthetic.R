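test_that("mutate_sequence reports exact truth and is seed-deterministic", {
  s <- strrep("ACGT", 100)
  m0 <- mutate_sequence(s, 0, 0, seed = 1)
  expect_equal(m0$seq, s)
  expect_equal(m0$substitutions, 0L)
  expect_equal(m0$indel_events, 0L)

  m1 <- mutate_sequence(s, 0.1, 0.01, seed = 5)
  m2 <- mutate_sequence(s, 0.1, 0.01, seed = 5)
  expect_identical(m1, m2)

  # substitution count within the binomial 99% interval at n = 1000
  set.seed(131)
  s <- random_acgt(1000)
  counts <- vapply(1:20, function(i) {
    mutate_sequence(s, 0.05, 0)$substitutions
  }, integer(1))
  lo <- qbinom(0.005, 1000, 0.05); hi <- qbinom(0.995, 1000, 0.05)
  expect_true(all(counts >= lo & counts <= hi))
  # substituted bases never stay the same
  m <- mutate_sequence(s, 0.3, 0, seed = 6)
  expect_equal(sum(strsplit(s, "")[[1]] != strsplit(m$seq, "")[[1]]),
               m$substitutions)
})

test_that("the generator is bit-identical under a fixed seed", {
  spec <- synthetic_region_spec(seed = 23)
  p1 <- generate_homolog_pair(spec)
  p2 <- generate_homolog_pair(spec)
  expect_identical(p1$region_a$record$seq, p2$region_a$record$seq)
  expect_identical(p1$region_b$record$seq, p2$region_b$record$seq)
  expect_identical(p1$ledger, p2$ledger)
  p3 <- generate_homolog_pair(synthetic_region_spec(seed = 24))
  expect_false(identical(p1$region_a$record$seq,
                         p3$region_a$record$seq))
})

test_that("every planted microsatellite is recovered exactly", {
  pair <- generate_homolog_pair(synthetic_region_spec(seed = 25))
  truth <- pair$ledger$microsats
  for (region in list(pair$region_a, pair$region_b)) {
    found <- find_perfect_repeats(region$record$seq)
    t_sp <- truth[truth$species == region$species, ]
    for (j in seq_len(nrow(t_sp))) {
      hit <- found[found$start == t_sp$start[j] &
                     found$unit_len == t_sp$unit_len[j], ]
      expect_equal(nrow(hit), 1L, info = t_sp$motif[j])
      expect_equal(hit$motif, t_sp$motif[j])
      expect_equal(hit$repeat_count, t_sp$repeat_count[j])
      expect_equal(hit$end, t_sp$end[j])
    }
  }
  # the planted long-mers are flagged as such
  found_b <- find_perfect_repeats(pair$region_b$record$seq)
  lm <- long_mer_filter(found_b)
  expect_true("ATC" %in% lm$motif)  # the planted (ATC)10 trinucleotide
})

test_that("intergenic expansion lands within one TE unit of target", {
  spec <- synthetic_region_spec(seed = 26)
  pair <- generate_homolog_pair(spec)
  led <- pair$ledger$intergenic
  target <- spec$expansion_factor * led$total_a
  expect_gte(led$total_b, target)
  expect_lt(led$total_b, target + led$te_unit_bp)
  # ledger totals match what the annotation-driven measurement sees
  p <- pair_homologs(pair$region_a, pair$region_b)
  iv_a <- intergenic_intervals(pair$region_a, p$pairs$name)
  iv_b <- intergenic_intervals(pair$region_b, p$pairs$name)
  expect_equal(sum(iv_a$width), led$total_a)
  expect_equal(sum(iv_b$width), led$total_b)
})

test_that("planted LTR substitution counts encode the programmed ages", {
  spec <- synthetic_region_spec(seed = 27)
  pair <- generate_homolog_pair(spec)
  led <- pair$ledger$ltr
  expect_equal(led$N, round(2 * led$L * spec$K * led$age_programmed))
  expect_equal(led$age_realized, led$N / (2 * led$L * led$K))
})

test_that("segregation generator produces the designed cosegregation", {
  sim <- generate_segregation(c("ScOPA09", "ESP1", "PAB"), c(0, 0.11),
                              n = 76, seed = 29)
  expect_equal(dim(sim$seg), c(3L, 76L))
  expect_equal(recombination_fraction(sim$seg, "ScOPA09", "ESP1")$r, 0)
  sim2 <- generate_segregation(c("ScOPA09", "ESP1", "PAB"), c(0, 0.11),
                               n = 76, seed = 29)
  expect_identical(sim$seg, sim2$seg)
})

test_that("infeasible plans fail with a named item", {
  plan <- data.frame(motif = "AT", repeats = 2000L, species = "A",
                     spacer = 1L, at = 0.5)
  spec <- synthetic_region_spec(seed = 1, microsat_plan = plan)
  expect_error(generate_homolog_pair(spec), "longer than its spacer")
  expect_error(synthetic_region_spec(seed = 1,
                                     spacer_lengths = c(100L, 100L)),
               "one entry per gene gap")
})

test_that("reference fixture vectors carry the published table values", {
  ref <- silene_reference_values()
  expect_equal(unname(ref$sl_intron_bp), c(10039, 1382, 3766, 1058, 617))
  expect_equal(unname(ref$sl_exon_gc), c(42.4, 47.3, 48.3, 42.3, 48.3))
  expect_equal(unname(ref$intergenic_bp), c(115909, 71866))
  # span = exons + introns holds for every published gene row
  expect_equal(ref$sl_span_bp, ref$sl_exon_bp + ref$sl_intron_bp)
  expect_equal(ref$sv_span_bp, ref$sv_exon_bp + ref$sv_intron_bp)
})
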