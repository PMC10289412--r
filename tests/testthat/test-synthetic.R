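test_that("config arithmetic and validation", {
  cfg <- synthetic_config(seed = 3, n_re_loci = 50,
                          fraction_re_overlapping_gene_same_strand = 0.2)
  ga <- simulate_genome_annotations(cfg)
  expect_equal(sum(ga$loci$overlap_status == "same_strand"), 10)  # 0.2 * 50
  expect_error(synthetic_config(fraction_diff = 1.5))
  expect_error(synthetic_config(n_genes = 0))   # fewer than overlap genes
})

test_that("same seed gives a byte-identical corpus; parsers round-trip the manifest", {
  d1 <- file.path(tempdir(), "corpA"); d2 <- file.path(tempdir(), "corpB")
  cfg <- synthetic_config(seed = 13)
  man <- simulate_corpus(cfg, d1)
  simulate_corpus(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 10)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)

  # both repeat dialects parse back to the manifest's loci
  out <- parse_repeatmasker(file.path(d1, "repeats.out"), "rm_out")
  tsv <- parse_repeatmasker(file.path(d1, "repeats_rmsk.tsv"), "rmsk_table")
  expect_equal(nrow(out), nrow(man$loci))
  expect_equal(out[, c("chrom", "start", "end", "strand", "rep_class")],
               man$loci[, c("chrom", "start", "end", "strand", "rep_class")],
               ignore_attr = TRUE)
  expect_equal(tsv[, c("start", "end", "strand", "rep_family")],
               man$loci[, c("start", "end", "strand", "rep_family")],
               ignore_attr = TRUE)
  genes <- parse_gene_bodies(file.path(d1, "genes.gtf"))
  expect_equal(nrow(genes), nrow(man$genes))
  mir <- parse_mirna_fasta(file.path(d1, "mirnas.fa"), "syn-")
  expect_equal(mir$sequence, man$mirnas$sequence)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("intergenic filtering of the corpus equals the manifest's prediction", {
  d <- file.path(tempdir(), "corpC")
  man <- simulate_corpus(synthetic_config(seed = 17), d)
  loci <- parse_repeatmasker(file.path(d, "repeats.out"), "rm_out")
  genes <- parse_gene_bodies(file.path(d, "genes.gtf"))
  kept <- subtract_gene_overlaps(filter_re_classes(loci), genes, "same_strand")
  expect_setequal(kept$locus_id, unlist(man$intergenic_ids))
  # any_strand output is a subset of same_strand output
  kept_any <- subtract_gene_overlaps(filter_re_classes(loci), genes, "any_strand")
  expect_true(all(kept_any$locus_id %in% kept$locus_id))
  expected_any <- man$loci$locus_id[man$loci$rep_class %in% c("LINE", "LTR") &
                                      man$loci$overlap_status == "none"]
  expect_setequal(kept_any$locus_id, expected_any)
  unlink(d, recursive = TRUE)
})

test_that("labeled straddlers and antisense reads are never counted", {
  d <- file.path(tempdir(), "corpD")
  man <- simulate_corpus(synthetic_config(seed = 19), d)
  inter <- man$loci[man$loci$locus_id %in% unlist(man$intergenic_ids), ]
  cm <- count_matrix(unlist(man$sam_files), inter)
  expect_identical(unname(cm$counts[rownames(man$expected_count_matrix),
                                    colnames(man$expected_count_matrix)]),
                   unname(man$expected_count_matrix))
  expect_equal(cm$total_mapped_reads[names(man$total_mapped_reads)],
               unlist(man$total_mapped_reads))
  # straddlers/antisense exist in the files yet counts exclude them
  sam1 <- readLines(unlist(man$sam_files)[1])
  expect_true(any(grepl("^straddle", sam1)) || any(grepl("^antisense", sam1)))
  expect_true(sum(cm$counts) < sum(cm$total_mapped_reads))
  unlink(d, recursive = TRUE)
})

test_that("planted sites are recovered exactly, type by type", {
  set.seed(31)
  pats <- collapse_families(seed_patterns(simulate_mirnas(synthetic_config(seed = 31,
                                                                           n_mirnas = 3))))
  for (type in c("8M", "7M8", "7A1")) {
    for (n in c(0L, 2L, 5L)) {
      res <- plant_mre_sites(random_seq(400), pats[1, ], type, n,
                             tracked = pats)
      found <- scan_sites(res$sequence, pats)
      fam1 <- found[found$mirna_family == pats$family_key[1], ]
      expect_equal(sum(fam1$site_type == type), n,
                   label = paste(type, n))
      expect_equal(sum(fam1$site_type != type), 0)
      expect_equal(nrow(found[found$mirna_family != pats$family_key[1], ]), 0)
      expect_setequal(fam1$offset, res$offsets)
    }
  }
})

test_that("planting errors when the sequence cannot hold the request", {
  pats <- seed_patterns(c(m = "UGAGGUAGUAGGUUGUAUAGUU"))
  pats$family_key -> fk
  expect_error(plant_mre_sites("ACGTACGTACGTACGT", pats, "8M", 5),
               "could not place")
})

test_that("expression simulator realizes the planted two-group design", {
  sim <- simulate_expression_matrix(n_loci = 100, seed = 7)
  expect_equal(dim(sim$expr), c(100, 10))
  expect_equal(length(sim$true_positive_ids), 10)   # 10% of 100
  null_ids <- setdiff(rownames(sim$expr), sim$true_positive_ids)
  grp <- split(colnames(sim$expr), sim$groups)
  lfc_hat <- log2(rowMeans(sim$expr[sim$true_positive_ids, grp$tumor]) /
                    rowMeans(sim$expr[sim$true_positive_ids, grp$normal]))
  expect_equal(mean(lfc_hat), 2, tolerance = 0.3)
  lfc_null <- log2(rowMeans(sim$expr[null_ids, grp$tumor]) /
                     rowMeans(sim$expr[null_ids, grp$normal]))
  expect_equal(mean(lfc_null), 0, tolerance = 0.15)
})

test_that("target fixtures encode their own expected arithmetic", {
  tf <- simulate_target_fixtures(synthetic_config(seed = 23))
  res <- common_across_types(tf$targets_by_type)
  expect_equal(length(res$common), 99)
  expect_equal(res$common, tf$expected$common)
  final <- remove_downregulated(res$common, tf$degs)
  expect_equal(length(final), 94)
  expect_equal(final, tf$expected$final_genes)
  common_db <- intersect_targets(tf$db_lists)
  expect_equal(length(common_db), tf$expected$db_common_n)

  # no planted downs -> filter is the identity
  tf0 <- simulate_target_fixtures(synthetic_config(seed = 23,
                                                   n_down_in_common = 0))
  res0 <- common_across_types(tf0$targets_by_type)
  expect_equal(remove_downregulated(res0$common, tf0$degs), res0$common)
})
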