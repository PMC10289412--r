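test_that("miRBase FASTA parsing selects species and normalizes alphabet", {
  f <- write_mirna_fasta_fixture(tempfile(fileext = ".fa"))
  hsa <- parse_mirna_fasta(f, "hsa-")
  expect_equal(nrow(hsa), 3)
  expect_true(all(startsWith(hsa$name, "hsa-")))
  cfa <- parse_mirna_fasta(f, "cfa-")
  expect_equal(nrow(cfa), 2)
  expect_error(parse_mirna_fasta(f, "mmu-"), "mmu-")

  ft <- tempfile(fileext = ".fa")
  writeLines(c(">hsa-test", "TGAGGTAGTAGGTTGT"), ft)   # DNA letters in input
  expect_equal(parse_mirna_fasta(ft, "hsa-")$sequence, "UGAGGUAGUAGGUUGU")
  f7 <- tempfile(fileext = ".fa")
  writeLines(c(">hsa-short", "UGAGGUA"), f7)
  expect_error(parse_mirna_fasta(f7, "hsa-"), "shorter than 8")
})

test_that("seed patterns follow the 8mer/7mer-m8/7mer-A1 construction", {
  sp <- seed_patterns(c("hsa-let-7a-5p" = "UGAGGUAGUAGGUUGUAUAGUU"))
  expect_equal(sp$site_8m, "CTACCTCA")
  expect_equal(sp$site_7m8, "CTACCTC")
  expect_equal(sp$site_7a1, "TACCTCA")
  expect_equal(sp$family_key, "GAGGTAG")

  # structural identities hold for arbitrary miRNAs
  set.seed(11)
  sp2 <- seed_patterns(random_mirna_df(25))
  expect_true(all(nchar(sp2$site_8m) == 8))
  expect_true(all(substr(sp2$site_8m, 1, 7) == sp2$site_7m8))
  expect_true(all(substr(sp2$site_8m, 2, 8) == sp2$site_7a1))
  expect_true(all(endsWith(sp2$site_8m, "A")))

  expect_equal(seed_patterns(c(u8 = "UUUUUUUU"))$site_8m, "AAAAAAAA")
})

test_that("family collapsing merges shared seeds and labels sensibly", {
  mir <- data.frame(
    name = c("hsa-let-7a-5p", "hsa-let-7b-5p", "hsa-miR-30a-5p", "hsa-miR-9-5p"),
    sequence = c("UGAGGUAGUAGGUUGUAUAGUU", "UGAGGUAGUAGGUUGUGUGGUU",
                 "UGUAAACAUCCUCGACUGGAAG", "UCUUUGGUUAUCUAGCUGUAUGA"),
    stringsAsFactors = FALSE)
  fam <- collapse_families(mir)
  expect_equal(nrow(fam), 3)       # let-7a/b share positions 2-8
  let7 <- fam[grepl("let-7", fam$members), ]
  expect_equal(let7$members, "hsa-let-7a-5p,hsa-let-7b-5p")
  expect_equal(let7$label, "let-7")
  expect_equal(fam$label[grepl("miR-30a", fam$members)], "miR-30")
  single <- collapse_families(mir[4, , drop = FALSE])
  expect_equal(single$members, "hsa-miR-9-5p")
})

test_that("sequence extraction is strand-aware, keyed by locus_id, uppercased", {
  genome <- c(chrA = "ACGTACGT", chrB = "aaaacccc")
  l1 <- re_loci("chrA", 2, 6, "+", "x", "LINE", "L1")
  l2 <- re_loci("chrA", 2, 6, "-", "x", "LINE", "L1")
  l3 <- re_loci("chrB", 0, 8, "-", "x", "LINE", "L1")
  expect_equal(unname(extract_re_sequences(genome, l1)), "GTAC")
  expect_equal(unname(extract_re_sequences(genome, l2)), "GTAC")  # palindrome
  expect_equal(unname(extract_re_sequences(genome, l3)), "GGGGTTTT")
  expect_equal(names(extract_re_sequences(genome, l1)), l1$locus_id)
  bad <- re_loci("chrA", 4, 20, "+", "x", "LINE", "L1")
  expect_error(extract_re_sequences(genome, bad), bad$locus_id, fixed = TRUE)
  expect_error(extract_re_sequences(genome["chrA"],
                                    re_loci("chrZ", 0, 4, "+", "x", "LINE", "L1")),
               "chrZ")
})

test_that("scanner applies the 8M > 7M8 > 7A1 precedence rule", {
  sp <- seed_patterns(c("hsa-let-7a-5p" = "UGAGGUAGUAGGUUGUAUAGUU"))
  s8 <- scan_sites("GGCTACCTCAGG", sp)
  expect_equal(nrow(s8), 1)
  expect_equal(s8$site_type, "8M")
  expect_equal(s8$offset, 2)

  s7 <- scan_sites("GGCTACCTCGGG", sp)    # A -> G at the A1 position
  expect_equal(nrow(s7), 1)
  expect_equal(s7$site_type, "7M8")
  expect_equal(s7$offset, 2)

  sa <- scan_sites("GGTACCTCAGGG", sp)    # 7A1 alone (no m8 base before)
  expect_equal(sa$site_type, "7A1")
  expect_equal(sa$offset, 2)

  expect_equal(nrow(scan_sites("", sp)), 0)
  expect_equal(nrow(scan_sites("GGCTANCTCAGG", sp)), 0)  # N never matches
})

test_that("scanner equals the window-enumeration oracle on random cases", {
  set.seed(21)
  fams <- collapse_families(seed_patterns(random_mirna_df(10)))
  for (rep in 1:40) {
    s <- random_seq(500)
    expect_identical(scan_sites(s, fams), oracle_scan(s, fams))
  }
  # homopolymer stress: overlapping matches must all be reported
  u <- seed_patterns(c(u = "UUUUUUUUUUUU"))
  s <- "GGAAAAAAAAAAAGG"
  expect_identical(scan_sites(s, u), oracle_scan(s, u))
  expect_true(sum(scan_sites(s, u)$site_type == "8M") > 1)
})

test_that("scanner output is invariant to pattern order", {
  set.seed(22)
  fams <- collapse_families(seed_patterns(random_mirna_df(8)))
  s <- random_seq(800)
  shuffled <- fams[sample(nrow(fams)), ]
  expect_identical(scan_sites(s, fams), scan_sites(s, shuffled))
})

test_that("scan_loci tabulates per-locus site counts consistently", {
  sp <- seed_patterns(c("hsa-let-7a-5p" = "UGAGGUAGUAGGUUGUAUAGUU"))
  seqs <- c(a = "GGCTACCTCAGGCTACCTCGG",  # one 8M + one 7M8
            b = "GGGGGGGGGGGG")           # nothing
  res <- scan_loci(seqs, sp)
  expect_equal(nrow(res$sites), 2)
  expect_equal(res$site_counts$n_sites,
               c(1L, 1L))
  expect_setequal(res$site_counts$site_type, c("8M", "7M8"))
  expect_true(all(res$site_counts$locus_id == "a"))
})
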