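test_that("RepeatMasker .out parsing converts coordinates and strand", {
  f <- write_rm_out_fixture(tempfile(fileext = ".out"))
  loci <- parse_repeatmasker(f, "rm_out")
  expect_equal(nrow(loci), 6)
  expect_equal(loci$start[1], 1000)   # 1-based inclusive 1001 -> 0-based 1000
  expect_equal(loci$end[1], 1100)
  expect_equal(loci$strand[2], "-")   # "C" maps to minus
  expect_equal(loci$rep_class, c("LINE", "LINE", "LINE", "LTR", "LTR",
                                 "Simple_repeat"))
  expect_equal(loci$rep_family[5], "ERVL-MaLR")
  expect_equal(loci$rep_family[6], "Simple_repeat")  # bare class -> family = class
})

test_that("rmsk-style tables pass half-open coordinates through", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t500\t700\t+\tL1M5\tLINE\tL1",
               "chr1\t900\t1200\tC\tMLT1A\tLTR\tERVL"), f)
  loci <- parse_repeatmasker(f, "rmsk_table")
  expect_equal(loci$start, c(500, 900))
  expect_equal(loci$end, c(700, 1200))
  expect_equal(loci$strand, c("+", "-"))
})

test_that("malformed rows are rejected with a line number", {
  f <- tempfile(fileext = ".out")
  writeLines(c("h1", "h2", "", " 1000 10.0 0.5 0.5 chr1 oops"), f)
  expect_error(parse_repeatmasker(f, "rm_out"), "line 4")
})

test_that("class filtering is an order-preserving subset", {
  f <- write_rm_out_fixture(tempfile(fileext = ".out"))
  loci <- parse_repeatmasker(f, "rm_out")
  kept <- filter_re_classes(loci, c("LINE", "LTR"))
  expect_equal(nrow(kept), 5)
  expect_equal(kept$locus_id, loci$locus_id[loci$rep_class != "Simple_repeat"])
  expect_equal(nrow(filter_re_classes(loci, "SINE")), 0)
  expect_equal(filter_re_classes(loci, unique(loci$rep_class)), loci)
  expect_error(filter_re_classes(loci, character(0)))
})

test_that("gene bodies come from gene features or transcript spans", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id "GA";',
    'chr1\tsrc\tgene\t501\t900\t.\t-\t.\tgene_id "GB";',
    'chr2\tsrc\tgene\t11\t60\t.\t+\t.\tgene_id "GC";',
    'chr2\tsrc\tgene\t201\t260\t.\t-\t.\tgene_id "GD";'
  ), gtf)
  g <- parse_gene_bodies(gtf)
  expect_equal(nrow(g), 4)
  ga <- g[g$gene_id == "GA", ]
  expect_equal(ga$start, 100)
  expect_equal(ga$end, 200)
  expect_equal(ga$strand, "+")

  # no gene features: span union over transcripts
  gtf2 <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t101\t300\t.\t+\t.\tgene_id "GX"; transcript_id "T1";',
    'chr1\tsrc\ttranscript\t251\t500\t.\t+\t.\tgene_id "GX"; transcript_id "T2";'
  ), gtf2)
  g2 <- parse_gene_bodies(gtf2)
  expect_equal(nrow(g2), 1)
  expect_equal(c(g2$start, g2$end), c(100, 500))
})

test_that("same-strand gene overlap removes whole loci; antisense and abutting survive", {
  one <- re_loci(chrom = "chr1", start = 100, end = 200, strand = "+",
                 rep_name = "L1M5", rep_class = "LINE", rep_family = "L1")
  gene_over <- data.frame(gene_id = "g1", chrom = "chr1", start = 150,
                          end = 250, strand = "+")
  gene_anti <- data.frame(gene_id = "g2", chrom = "chr1", start = 150,
                          end = 250, strand = "-")
  gene_abut <- data.frame(gene_id = "g3", chrom = "chr1", start = 200,
                          end = 300, strand = "+")
  expect_equal(nrow(subtract_gene_overlaps(one, gene_over, "same_strand")), 0)
  expect_equal(nrow(subtract_gene_overlaps(one, gene_anti, "same_strand")), 1)
  expect_equal(nrow(subtract_gene_overlaps(one, gene_abut, "same_strand")), 1)
  # any_strand also removes the antisense overlap
  expect_equal(nrow(subtract_gene_overlaps(one, gene_anti, "any_strand")), 0)
  expect_error(subtract_gene_overlaps(one, gene_over, "sideways"))
})

test_that("intergenic filter leaves zero same-strand overlaps (brute force) and any_strand is stricter", {
  set.seed(42)
  n <- 60
  starts <- sort(sample(0:9000, n))
  loci <- re_loci(chrom = sample(c("chr1", "chr2"), n, TRUE),
                  start = starts, end = starts + sample(50:400, n, TRUE),
                  strand = sample(c("+", "-"), n, TRUE),
                  rep_name = "L1", rep_class = "LINE", rep_family = "L1")
  loci <- loci[!duplicated(loci$locus_id), ]
  gs <- sample(0:9000, 15)
  genes <- data.frame(gene_id = paste0("g", 1:15),
                      chrom = sample(c("chr1", "chr2"), 15, TRUE),
                      start = gs, end = gs + sample(100:800, 15, TRUE),
                      strand = sample(c("+", "-"), 15, TRUE))
  same <- subtract_gene_overlaps(loci, genes, "same_strand")
  any_ <- subtract_gene_overlaps(loci, genes, "any_strand")
  expect_equal(oracle_overlapping_pairs(same, genes, same_strand = TRUE), 0)
  expect_equal(oracle_overlapping_pairs(any_, genes, same_strand = FALSE), 0)
  expect_true(all(any_$locus_id %in% same$locus_id))
})

test_that("BED round-trip preserves core locus fields", {
  f <- write_rm_out_fixture(tempfile(fileext = ".out"))
  loci <- parse_repeatmasker(f, "rm_out")
  bed <- tempfile(fileext = ".bed")
  write_re_bed(loci, bed)
  back <- read_re_bed(bed, annotation = loci)
  expect_equal(back[, c("locus_id", "chrom", "start", "end", "strand")],
               loci[, c("locus_id", "chrom", "start", "end", "strand")])
  expect_equal(back$rep_class, loci$rep_class)
})
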