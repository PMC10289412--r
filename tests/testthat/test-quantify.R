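make_one_locus <- function() {
  re_loci(chrom = "chr1", start = 100, end = 300, strand = "+",
          rep_name = "L1M5", rep_class = "LINE", rep_family = "L1")
}

test_that("counting requires full containment and matching strand", {
  loci <- make_one_locus()
  sam <- write_sam_fixture(tempfile(fileext = ".sam"), c(chr1 = 1000),
    data.frame(chrom = "chr1",
               pos0 = c(150, 150, 150, 100, 200, 90, 0),
               len  = c(100, 200, 100, 200, 100, 100, 50),
               strand = c("+", "+", "-", "+", "+", "+", "+"),
               mapped = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)))
  res <- count_reads(sam, loci)
  # [150,250) contained; [150,350) straddles; [150,250) antisense;
  # [100,300) exactly the locus (contained); [200,300) contained;
  # [90,190) straddles the left edge; unmapped ignored
  expect_equal(unname(res$counts), 3L)
  expect_equal(res$total_mapped_reads, 6L)
})

test_that("one read can count toward multiple containing loci", {
  loci <- rbind(make_one_locus(),
                re_loci("chr1", 120, 280, "+", "L1M5", "LINE", "L1"))
  sam <- write_sam_fixture(tempfile(fileext = ".sam"), c(chr1 = 1000),
    data.frame(chrom = "chr1", pos0 = 150, len = 50, strand = "+",
               mapped = TRUE))
  res <- count_reads(sam, loci)
  expect_equal(unname(res$counts), c(1L, 1L))
})

test_that("RPKM follows count * 1e9 / (length * total)", {
  loci <- re_loci("chr1", c(0, 2000), c(1000, 2350), c("+", "+"),
                  "L1", "LINE", "L1")
  counts <- matrix(c(10L, 7L, 0L, 7L), nrow = 2,
                   dimnames = list(loci$locus_id, c("s1", "s2")))
  expr <- rpkm(counts, loci, c(s1 = 1e6, s2 = 2.5e6))
  expect_equal(expr[1, "s1"], 10.0)            # 10 reads, 1 kb, 1 M
  expect_equal(expr[2, "s2"], 8.0)             # 7 * 1e9 / (350 * 2.5e6)
  expect_equal(expr[1, "s2"], 0.0)
  # invariance under joint scaling of counts and totals
  expr2 <- rpkm(counts * 3, loci, c(s1 = 3e6, s2 = 7.5e6))
  expect_equal(expr2, expr * 1)
  expect_error(rpkm(counts, loci, c(s1 = 1e6)), "total_mapped_reads")
})

test_that("size/expression filter applies inclusive thresholds", {
  loci <- re_loci("chr1", c(0, 1000, 2000), c(150, 1200, 2500),
                  c("+", "+", "+"), "L1", "LINE", "L1")  # lengths 150,200,500
  expr <- matrix(5, nrow = 3, ncol = 2,
                 dimnames = list(loci$locus_id, c("a", "b")))
  expect_equal(nrow(size_expression_filter(expr, loci, min_length_bp = 200)), 2)
  expr2 <- matrix(c(0.5, 0.9, 0.2, 2, 2, 2), nrow = 2, byrow = TRUE,
                  dimnames = list(loci$locus_id[1:2], c("a", "b", "c")))
  out <- size_expression_filter(expr2, loci, min_length_bp = 0,
                                min_rpkm = 1, min_samples = 2)
  expect_equal(rownames(out), loci$locus_id[2])
})

test_that("differential expression matches an independent Welch evaluation", {
  normal <- c(1, 1, 1); tumor <- c(4, 4, 4.00001)
  expr <- matrix(c(normal, tumor), nrow = 1,
                 dimnames = list("L", c("n1", "n2", "n3", "t1", "t2", "t3")))
  groups <- setNames(rep(c("normal", "tumor"), each = 3), colnames(expr))
  tab <- differential_expression(expr, groups)
  expect_equal(tab$log2fc, log2(mean(tumor + 0.25) / 1.25), tolerance = 1e-12)
  expect_equal(tab$log2fc, 1.766, tolerance = 1e-3)
  expect_equal(tab$p_value, oracle_welch_p(normal, tumor), tolerance = 1e-12)
  expect_equal(tab$significant,
               tab$p_value < 0.05 & abs(tab$log2fc) > 1)
})

test_that("identical groups give log2fc 0; label swap negates log2fc only", {
  set.seed(1)
  expr <- matrix(2^rnorm(40, 5), nrow = 4,
                 dimnames = list(paste0("L", 1:4), paste0("s", 1:10)))
  groups <- setNames(rep(c("normal", "tumor"), each = 5), colnames(expr))
  flipped <- setNames(rep(c("tumor", "normal"), each = 5), colnames(expr))
  t1 <- differential_expression(expr, groups)
  t2 <- differential_expression(expr, flipped)
  m <- match(t1$feature_id, t2$feature_id)
  expect_equal(t1$log2fc, -t2$log2fc[m], tolerance = 1e-12)
  expect_equal(t1$p_value, t2$p_value[m], tolerance = 1e-12)

  const <- matrix(3, nrow = 1, ncol = 10,
                  dimnames = list("L", colnames(expr)))
  tc <- differential_expression(const, groups)
  expect_equal(tc$log2fc, 0)
  expect_equal(tc$p_value, 1)     # degenerate: both groups constant and equal
  expect_false(tc$significant)
})

test_that("differential table is sorted and significance is reproducible from its columns", {
  set.seed(2)
  expr <- matrix(2^(rnorm(200, 5) + rep(c(0, 2), each = 10) %o% rep(c(0, 1), each = 5)),
                 nrow = 20)
  rownames(expr) <- sprintf("L%02d", 1:20)
  colnames(expr) <- paste0("s", 1:10)
  groups <- setNames(rep(c("normal", "tumor"), each = 5), colnames(expr))
  tab <- differential_expression(expr, groups, alpha = 0.05, fc_threshold = 1)
  expect_true(!is.unsorted(tab$p_value))
  expect_equal(tab$significant, tab$p_value < 0.05 & abs(tab$log2fc) > 1)
  expect_error(differential_expression(expr[, c(1, 2, 6)],
                                       groups[c(1, 2, 6)]), "at least 2")
  with_adj <- differential_expression(expr, groups, adjust = TRUE)
  expect_equal(with_adj$p_adj, p.adjust(with_adj$p_value, "BH"))
})
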