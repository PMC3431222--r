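toy_pair <- function(names_a, names_b, starts_a = NULL, starts_b = NULL,
                     strands_a = NULL, strands_b = NULL) {
  mk <- function(nms, starts, strands, sp) {
    starts <- starts %||% (seq_along(nms) - 1) * 20
    strands <- strands %||% rep("+", length(nms))
    genes <- Map(function(nm, s0, st) mk_gene(nm, st, c(s0, s0 + 10)),
                 nms, starts, strands)
    mk_region(strrep("ACGT", 100), unname(genes), species = sp, id = sp)
  }
  pair_homologs(mk(names_a, starts_a, strands_a, "spA"),
                mk(names_b, starts_b, strands_b, "spB"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("homologs pair by name and report unpaired genes", {
  shared <- c("ESP1", "BIP1", "ACBP1", "PAR1", "PAR2")
  p <- toy_pair(c(shared, "PAR3"), c(shared, "SVA1"))
  expect_equal(nrow(p$pairs), 5L)
  expect_equal(p$unpaired_a, "PAR3")
  expect_equal(p$unpaired_b, "SVA1")
  expect_warning(toy_pair(c("x", "y"), c("u", "v")), "no shared")
})

test_that("collinearity detects conserved, inverted and shuffled orders", {
  p <- toy_pair(paste0("g", 1:5), paste0("g", 1:5))
  expect_true(collinearity_check(p)$conserved)

  # same names, order reversed in B without strand flips: not conserved
  p <- toy_pair(paste0("g", 1:3), paste0("g", 3:1))
  res <- collinearity_check(p)
  expect_false(res$conserved)

  # whole-segment inversion: reversed order with uniformly flipped strands
  p <- toy_pair(paste0("g", 1:3), paste0("g", 3:1),
                strands_a = c("+", "+", "-"),
                strands_b = c("+", "-", "-"))
  expect_true(collinearity_check(p)$conserved)

  # single transposition: one breakpoint
  p <- toy_pair(c("g1", "g2", "g3"), c("g1", "g3", "g2"))
  res <- collinearity_check(p)
  expect_false(res$conserved)
  expect_equal(res$inversions, 1L)

  expect_error(collinearity_check(toy_pair("g1", "g1")), "fewer than 2")
})

test_that("gene size table reproduces the published intron ratio", {
  # two-gene pair whose first gene carries the published ESP1 intron
  # totals (10039 bp vs 11255 bp) split across two exons
  mk <- function(intron, sp) {
    n <- 100 + intron + 100 + 50 + 30
    genes <- list(mk_gene("ESP1", "+", c(0, 100),
                          c(100 + intron, 200 + intron)),
                  mk_gene("PAR2", "+", c(230 + intron, 260 + intron)))
    mk_region(strrep("A", n + 300), genes, species = sp, id = sp)
  }
  p <- pair_homologs(mk(10039, "Sl"), mk(11255, "Sv"))
  tab <- gene_length_table(p)
  esp <- tab[tab$gene == "ESP1", ]
  expect_equal(esp$intron_bp_a, 10039)
  expect_equal(esp$intron_bp_b, 11255)
  expect_equal(round(esp$intron_ratio_b_a, 1), 1.1)
  # single-exon gene: no introns, ratio undefined
  par2 <- tab[tab$gene == "PAR2", ]
  expect_equal(par2$intron_bp_a, 0)
  expect_true(is.na(par2$intron_ratio_b_a))
  # span identity for every row
  expect_equal(tab$span_a, tab$exon_bp_a + tab$intron_bp_a)
  expect_equal(tab$span_b, tab$exon_bp_b + tab$intron_bp_b)
})

test_that("published per-gene totals reproduce the reported size t-tests", {
  ref <- silene_reference_values()
  t_intron <- student_t_two_sample(ref$sl_intron_bp, ref$sv_intron_bp)
  expect_equal(signif(t_intron$t, 3), -0.0817)
  expect_equal(round(t_intron$p, 4), 0.9369)
  t_exon <- student_t_two_sample(ref$sl_exon_bp, ref$sv_exon_bp)
  expect_equal(signif(t_exon$t, 1), -0.005)
  expect_equal(round(t_exon$p, 4), 0.9961)
  # antisymmetry under swapping species
  expect_equal(student_t_two_sample(ref$sv_intron_bp, ref$sl_intron_bp)$t,
               -t_intron$t)
})

test_that("expansion statistics are internally consistent", {
  rep <- expansion_stats(115909, 71866)
  expect_equal(rep$difference, 44043)
  expect_equal(round(rep$ratio, 1), 1.6)
  expect_equal(round(rep$percent_increase), 61)
  expect_equal(rep$percent_increase, 100 * (rep$ratio - 1))

  rep <- expansion_stats(5000, 5000)
  expect_equal(rep$difference, 0)
  expect_equal(rep$percent_increase, 0)
  expect_error(expansion_stats(100, 0), "undefined")

  set.seed(81)
  for (i in 1:10) {
    tot <- sort(sample(1e3:1e5, 2))
    r <- expansion_stats(tot[2], tot[1])
    expect_equal(r$difference, tot[2] - tot[1])
    expect_equal(r$ratio, tot[2] / tot[1])
    expect_equal(r$percent_increase, 100 * (r$ratio - 1))
  }
})

test_that("intergenic expansion recovers the programmed factor", {
  pair <- generate_homolog_pair(synthetic_region_spec(seed = 13))
  p <- pair_homologs(pair$region_b, pair$region_a)  # expanded first
  rep <- intergenic_expansion(pair$region_b, pair$region_a, p)
  expect_lt(abs(rep$ratio - 1.6), 0.1)
  expect_equal(rep$chi2_df, 1L)
  expect_gt(rep$chi2, 0)
  # and a different programmed factor is recovered too
  pair2 <- generate_homolog_pair(synthetic_region_spec(
    seed = 13, expansion_factor = 2.0))
  p2 <- pair_homologs(pair2$region_b, pair2$region_a)
  rep2 <- intergenic_expansion(pair2$region_b, pair2$region_a, p2)
  expect_lt(abs(rep2$ratio - 2.0), 0.1)
})
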