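test_that("FASTA reading and writing round-trip records", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), path)
  recs <- read_fasta(path)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(recs[[1]]$seq, "ACGT")
  expect_equal(recs[[1]]$length, 4L)

  # round trip with multiple records, lower case and ambiguity codes
  out <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1 descr", "acgtn", ">r2",
               strrep("ACGTRYSWKMBDHV", 12L)), path)
  recs <- read_fasta(path)
  expect_equal(recs[[1]]$seq, "ACGTN")  # upper-cased on load
  write_fasta(recs, out)
  expect_identical(read_fasta(out), recs)
})

test_that("FASTA errors name the offending symbol or id", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACJT"), path)
  expect_error(read_fasta(path), "J")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), path)
  expect_error(read_fasta(path), "duplicate.*'a'")
  writeLines(character(0), path)
  expect_error(read_fasta(path), "no records")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "no such file")
})

test_that("GFF3 coordinates convert to 0-based half-open and back", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">chr", strrep("ACGT", 100L)), fa)
  rec <- read_fasta(fa)[[1]]
  region <- annotated_region("sp", rec$id, rec$seq)
  writeLines(c(
    "##gff-version 3",
    "chr\t.\tgene\t101\t200\t.\t+\t.\tID=gene:g1;Name=g1",
    "chr\t.\texon\t101\t140\t.\t+\t.\tID=e1;Parent=gene:g1",
    "chr\t.\texon\t161\t200\t.\t+\t.\tID=e2;Parent=gene:g1",
    "chr\t.\trepeat_region\t11\t30\t.\t+\t.\tID=rep1"), gff)
  region <- read_gff3(gff, region)
  g <- region$genes[["g1"]]
  expect_equal(min(g$exons$start), 100L)
  expect_equal(max(g$exons$end), 200L)
  expect_equal(exon_total(g), 80L)
  expect_equal(intron_total(g), 20L)
  expect_equal(region$repeats$start, 10L)
  expect_equal(region$repeats$end, 30L)

  # write-then-read reproduces all features
  out <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(region, out)
  again <- read_gff3(out, annotated_region("sp", rec$id, rec$seq))
  expect_equal(again$genes[["g1"]]$exons, g$exons)
  expect_equal(again$repeats$start, region$repeats$start)
})

test_that("GFF3 validation rejects orphans, overlaps and out-of-bounds", {
  fa_seq <- strrep("ACGT", 50L)
  region <- annotated_region("sp", "chr", fa_seq)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\t.\texon\t1\t10\t.\t+\t.\tID=lonely"), gff)
  expect_error(read_gff3(gff, region), "Parent")
  writeLines(c("##gff-version 3",
               "chr\t.\tgene\t1\t30\t.\t+\t.\tID=g1;Name=g1",
               "chr\t.\texon\t1\t10\t.\t+\t.\tID=e1;Parent=g1",
               "chr\t.\texon\t5\t20\t.\t+\t.\tID=e2;Parent=g1"), gff)
  expect_error(read_gff3(gff, region), "overlap")
  writeLines(c("##gff-version 3",
               "chr\t.\tgene\t150\t300\t.\t+\t.\tID=g1;Name=g1"), gff)
  expect_error(read_gff3(gff, region), "bounds")
})

test_that("gene span decomposes into exon and intron totals", {
  g <- mk_gene("g", "+", c(0, 10), c(20, 30), c(45, 60))
  expect_equal(exon_total(g), 35L)
  expect_equal(intron_total(g), 25L)
  expect_equal(gene_span(g), 60L)
  set.seed(11)
  for (i in 1:20) {
    n_ex <- sample(1:8, 1)
    bounds <- sort(sample(0:500, 2 * n_ex))
    ex <- data.frame(start = bounds[seq(1, 2 * n_ex, 2)],
                     end = bounds[seq(2, 2 * n_ex, 2)])
    ex <- ex[ex$end > ex$start, , drop = FALSE]
    if (nrow(ex) == 0) next
    g <- gene_model("g", "+", ex)
    expect_equal(exon_total(g) + intron_total(g), gene_span(g))
  }
})

test_that("extract_cds concatenates exons and honours strand", {
  r <- mk_region("ATGCCC", list(mk_gene("g", "+", c(0, 3))))
  expect_equal(extract_cds(r, "g"), "ATG")
  r <- mk_region("AAACGGG", list(mk_gene("g", "-", c(0, 3), c(4, 7))))
  expect_equal(extract_cds(r, "g"), "CCCTTT")
  expect_error(extract_cds(r, "nope"), "unknown gene")
})

test_that("synthetic genes return exactly their programmed CDS", {
  pair <- generate_homolog_pair(synthetic_region_spec(seed = 5))
  for (nm in names(pair$region_a$genes)) {
    expect_identical(extract_cds(pair$region_a, nm),
                     pair$ledger$genes[[nm]]$cds_a)
    expect_identical(extract_cds(pair$region_b, nm),
                     pair$ledger$genes[[nm]]$cds_b)
  }
})

test_that("intergenic intervals lie strictly between consecutive genes", {
  seq <- strrep("A", 100L)
  r <- mk_region(seq, list(mk_gene("g1", "+", c(0, 10)),
                           mk_gene("g2", "+", c(20, 30))))
  iv <- intergenic_intervals(r)
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start, iv$end, iv$width), c(10L, 20L, 10L))

  # adjacent genes give a zero-width interval contributing nothing
  r <- mk_region(seq, list(mk_gene("g1", "+", c(0, 10)),
                           mk_gene("g2", "+", c(10, 20))))
  iv <- intergenic_intervals(r)
  expect_equal(iv$width, 0L)

  # five genes -> exactly four intervals, disjoint from gene spans
  starts <- c(0, 20, 45, 60, 90)
  genes <- lapply(seq_along(starts), function(i) {
    mk_gene(paste0("g", i), "+", c(starts[i], starts[i] + 5))
  })
  r <- mk_region(seq, genes)
  iv <- intergenic_intervals(r)
  expect_equal(nrow(iv), 4L)
  for (j in seq_len(nrow(iv))) {
    for (g in genes) {
      expect_true(iv$end[j] <= min(g$exons$start) ||
                    iv$start[j] >= max(g$exons$end))
    }
  }
  expect_error(intergenic_intervals(r, c("g1", "nope")), "unknown gene")
  r2 <- mk_region(seq, list(mk_gene("g1", "+", c(0, 30)),
                            mk_gene("g2", "+", c(20, 50))))
  expect_error(intergenic_intervals(r2), "overlap")
})

test_that("regions reject duplicate gene names and out-of-bounds features", {
  expect_error(mk_region("ACGTACGT",
                         list(mk_gene("g", "+", c(0, 2)),
                              mk_gene("g", "+", c(4, 6)))),
               "duplicate")
  expect_error(mk_region("ACGT", list(mk_gene("g", "+", c(0, 10)))),
               "bounds")
})
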