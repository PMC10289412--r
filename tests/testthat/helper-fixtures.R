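# Shared fixtures (built in code) and independent oracles for the suite.

# six-row RepeatMasker .out fixture: 3 LINE, 2 LTR, 1 Simple_repeat
write_rm_out_fixture <- function(path) {
  writeLines(c(
    "   SW   perc perc perc  query  position in query     matching repeat",
    "score   div. del. ins.  seq    begin  end   (left)   repeat   class/family  begin end (left) ID",
    "",
    " 1000   10.0  0.5  0.5  chr1    1001   1100 (0)  +  L1M5    LINE/L1        1  100 (0)  1",
    " 1001   10.0  0.5  0.5  chr1    2001   2400 (0)  C  L2a     LINE/L2        1  400 (0)  2",
    " 1002   10.0  0.5  0.5  chr1    3001   3300 (0)  +  CR1-L3  LINE/CR1       1  300 (0)  3",
    " 1003   10.0  0.5  0.5  chr2    1501   1800 (0)  C  MER41B  LTR/ERV1       1  300 (0)  4",
    " 1004   10.0  0.5  0.5  chr2    2501   2900 (0)  +  MLT1A   LTR/ERVL-MaLR  1  400 (0)  5",
    " 1005   10.0  0.5  0.5  chr2    4001   4050 (0)  +  (TA)n   Simple_repeat  1   50 (0)  6"
  ), path)
  path
}

write_mirna_fasta_fixture <- function(path) {
  writeLines(c(
    ">hsa-let-7a-5p MIMAT0000062 Homo sapiens let-7a-5p",
    "UGAGGUAGUAGGUUGUAUAGUU",
    ">hsa-miR-30a-5p MIMAT0000087",
    "UGUAAACAUCCUCGACUGGAAG",
    ">hsa-miR-126-5p MIMAT0000444",
    "CAUUAUUACUUUUGGUACGCG",
    ">cfa-let-7a MIMAT0006607",
    "UGAGGUAGUAGGUUGUAUAGUU",
    ">cfa-miR-1 MIMAT0006592",
    "UGGAAUGUAAAGAAGUAUGUAU"
  ), path)
  path
}

# minimal single-end SAM writer; reads = data.frame(pos0, len, strand, mapped)
write_sam_fixture <- function(path, chrom_lengths, reads) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), chrom_lengths))
  recs <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    if (!isTRUE(r$mapped))
      return(sprintf("u%d\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", i))
    flag <- if (r$strand == "+") 0L else 16L
    sprintf("r%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
            i, flag, r$chrom, r$pos0 + 1L, r$len,
            paste(rep("A", r$len), collapse = ""))
  }, "")
  writeLines(c(hdr, recs), path)
  path
}

# independent brute-force seed-site oracle: enumerate every window via
# substring, compare to each site pattern, then apply the precedence rule
oracle_scan <- function(sequence, fams) {
  s <- gsub("[^ACGT]", "N", toupper(sequence))
  L <- nchar(s)
  empty <- data.frame(mirna_family = character(0), site_type = character(0),
                      offset = integer(0), stringsAsFactors = FALSE)
  if (L < 7) return(empty)
  w7 <- substring(s, 1:(L - 6), 7:L)
  w8 <- if (L >= 8) substring(s, 1:(L - 7), 8:L) else character(0)
  rows <- list()
  for (i in seq_len(nrow(fams))) {
    p8 <- which(w8 == fams$site_8m[i]) - 1L
    p7m8 <- setdiff(which(w7 == fams$site_7m8[i]) - 1L, p8)
    p7a1 <- setdiff(which(w7 == fams$site_7a1[i]) - 1L, p8 + 1L)
    nn <- c(length(p8), length(p7m8), length(p7a1))
    if (sum(nn) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      mirna_family = rep(fams$family_key[i], sum(nn)),
      site_type = rep(c("8M", "7M8", "7A1"), nn),
      offset = c(p8, p7m8, p7a1), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, out$mirna_family,
                   match(out$site_type, c("8M", "7M8", "7A1"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force all-pairs interval overlap (1bp threshold, optional strand)
oracle_overlapping_pairs <- function(loci, genes, same_strand = TRUE) {
  hits <- 0L
  for (i in seq_len(nrow(loci))) for (j in seq_len(nrow(genes))) {
    if (loci$chrom[i] != genes$chrom[j]) next
    if (same_strand && loci$strand[i] != genes$strand[j]) next
    if (loci$start[i] < genes$end[j] && genes$start[j] < loci$end[i])
      hits <- hits + 1L
  }
  hits
}

# independent Welch two-sample t-test on log2(x + eps), closed-form
oracle_welch_p <- function(a, b, eps = 0.25) {
  la <- log2(a + eps); lb <- log2(b + eps)
  na <- length(la); nb <- length(lb)
  va <- var(la); vb <- var(lb)
  se2 <- va / na + vb / nb
  t <- (mean(lb) - mean(la)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(-abs(t), df)
}

random_mirna_df <- function(n, len = 22) {
  data.frame(
    name = sprintf("tst-miR-%d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
      ""),
    stringsAsFactors = FALSE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# pipeline config pointing at a simulate_corpus() output directory
corpus_pipeline_config <- function(d, man, outdir = NULL) {
  pipeline_config(
    repeats = file.path(d, "repeats.out"), repeats_dialect = "rm_out",
    genes_gtf = file.path(d, "genes.gtf"),
    genome_fasta = file.path(d, "genome.fa"),
    mirna_fasta = file.path(d, "mirnas.fa"), species_prefix = "syn-",
    alignments = unlist(man$sam_files), groups = unlist(man$groups),
    target_files = list(file.path(d, "targets_dbA.txt"),
                        file.path(d, "targets_dbB.txt")),
    deg_table = file.path(d, "degs.tsv"),
    outdir = outdir)
}
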