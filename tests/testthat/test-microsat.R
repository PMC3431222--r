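test_that("perfect repeat detection handles canonical cases", {
  loci <- find_perfect_repeats("ATATATAT")
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$motif, "AT")
  expect_equal(loci$repeat_count, 4L)
  expect_equal(loci$end - loci$start, loci$unit_len * loci$repeat_count)

  # mononucleotide threshold is >= 12 repeats
  expect_equal(nrow(find_perfect_repeats(strrep("A", 12))), 1L)
  expect_equal(nrow(find_perfect_repeats(strrep("A", 11))), 0L)

  # partial trailing unit is not counted
  loci <- find_perfect_repeats("GATCATCATCATCAG")
  atc <- loci[loci$motif == "ATC", ]
  expect_equal(atc$repeat_count, 4L)
  expect_equal(substr("GATCATCATCATCAG", atc$start + 1, atc$end),
               strrep("ATC", 4))

  # N breaks arrays: only the post-N fragment qualifies
  loci <- find_perfect_repeats("ATATANATATAT")
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 6L)
  expect_equal(loci$repeat_count, 3L)
  expect_equal(nrow(find_perfect_repeats("ATATNATAT")), 0L)
  expect_error(find_perfect_repeats("ACGT", min_unit = 5, max_unit = 2),
               "min_unit")
})

test_that("detection matches the brute-force scanner on short strings", {
  # crafted cases: phase shifts, nested periods, Ns, boundaries
  crafted <- c("ATATATCTCTCT", "AAAAAAAAAAAAAA", "ATATATATATATAT",
               "ACACACACGTGTGTGT", "AATAATAATAAT", "ATANATATATATAT",
               strrep("AT", 15), paste0(strrep("A", 13), strrep("T", 13)),
               "AAGAAGAAGTTCTTCTTC")
  drop_flag <- function(df) df[, setdiff(names(df), "is_long_mer")]
  for (s in crafted) {
    expect_equal(drop_flag(find_perfect_repeats(s)), bf_find_repeats(s),
                 info = s)
  }
  # seeded sample over {A,T} (repeat-dense alphabet), lengths up to 30
  set.seed(91)
  for (i in 1:150) {
    s <- paste(sample(c("A", "T"), sample(5:30, 1), replace = TRUE),
               collapse = "")
    expect_equal(drop_flag(find_perfect_repeats(s)), bf_find_repeats(s),
                 info = s)
    # lower thresholds exercise more loci per string
    expect_equal(drop_flag(find_perfect_repeats(s, min_repeats = 2,
                                                mono_min_repeats = 4)),
                 bf_find_repeats(s, min_repeats = 2, mono_min_repeats = 4),
                 info = s)
  }
})

test_that("reported loci are maximal and disjoint within a unit length", {
  set.seed(92)
  for (i in 1:40) {
    s <- paste(sample(c("A", "T", "C"), 60, replace = TRUE,
                      prob = c(0.45, 0.45, 0.1)), collapse = "")
    loci <- find_perfect_repeats(s, min_repeats = 2, mono_min_repeats = 3)
    for (j in seq_len(nrow(loci))) {
      l <- loci[j, ]
      k <- l$unit_len
      # extending by one unit either side breaks perfection
      left <- substr(s, l$start - k + 1, l$start)
      right <- substr(s, l$end + 1, l$end + k)
      if (l$start - k >= 0) expect_false(left == l$motif)
      if (l$end + k <= nchar(s)) {
        expect_false(right == substr(s, l$start + 1, l$start + k))
      }
      # the substring is exactly the motif repeated
      expect_equal(substr(s, l$start + 1, l$end),
                   strrep(l$motif, l$repeat_count))
    }
    # same-unit loci never overlap
    for (k in unique(loci$unit_len)) {
      lk <- loci[loci$unit_len == k, ]
      if (nrow(lk) > 1) {
        expect_true(all(lk$start[-1] >= lk$end[-nrow(lk)]))
      }
    }
  }
})

test_that("raising min_repeats never adds loci", {
  set.seed(93)
  for (i in 1:10) {
    s <- paste(sample(c("A", "T"), 40, replace = TRUE), collapse = "")
    lo <- find_perfect_repeats(s, min_repeats = 2, mono_min_repeats = 6)
    hi <- find_perfect_repeats(s, min_repeats = 4, mono_min_repeats = 10)
    key <- function(df) paste(df$start, df$unit_len)
    expect_true(all(key(hi) %in% key(lo)))
    expect_lte(nrow(hi), nrow(lo))
  }
})

test_that("census counts classes and proportions", {
  empty <- classify_and_count(find_perfect_repeats("ACGT"))
  expect_equal(sum(empty$counts), 0L)
  expect_equal(unname(empty$proportions), rep(0, 4))

  s <- paste0("GG", strrep("AT", 5), "GG", strrep("CT", 4), "GG",
              strrep("GAT", 4), "CC")
  census <- classify_and_count(find_perfect_repeats(s))
  expect_equal(unname(census$counts[c("di", "tri")]), c(2L, 1L))
  expect_equal(unname(census$proportions), c(0, 2 / 3, 1 / 3, 0))
})

test_that("long-mer thresholds follow the class-specific rules", {
  mk_locus <- function(motif, rc) {
    find_perfect_repeats(paste0("G", strrep(motif, rc), "C"),
                         min_repeats = 2, mono_min_repeats = 2)
  }
  expect_true(long_mer_filter(mk_locus("ATC", 10))$repeat_count == 10)
  expect_equal(nrow(long_mer_filter(mk_locus("AT", 14))), 0L)
  expect_equal(nrow(long_mer_filter(mk_locus("AT", 15))), 1L)
  expect_equal(nrow(long_mer_filter(mk_locus("T", 35))), 1L)
  expect_equal(nrow(long_mer_filter(mk_locus("T", 29))), 0L)
  # no threshold for unit length >= 4
  expect_equal(nrow(long_mer_filter(mk_locus("AAGT", 50))), 0L)
})

test_that("density comparison matches the direct pooled-t formula", {
  c_equal <- list(proportions = c(0.5, 0.3, 0.15, 0.05))
  expect_equal(density_compare(c_equal, c_equal)$t, 0)
  c_b <- list(proportions = c(0.4, 0.35, 0.2, 0.05))
  expect_equal(density_compare(c_equal, c_b)$t,
               bf_pooled_t(c_equal$proportions, c_b$proportions))
})

test_that("equal-density regions rarely show significant density differences", {
  set.seed(94)
  n_sig <- 0L
  for (i in 1:100) {
    ra <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                collapse = "")
    rb <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                collapse = "")
    ca <- classify_and_count(find_perfect_repeats(ra, max_unit = 4))
    cb <- classify_and_count(find_perfect_repeats(rb, max_unit = 4))
    if (density_compare(ca, cb)$p <= 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 10L)
})
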