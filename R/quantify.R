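## Read counting over RE loci, RPKM normalization, size/expression
## filtration and two-group differential expression.

# reference-space width of an alignment from its CIGAR (M/D/N/=/X consume
# the reference); minimal on purpose -- the counter only needs the span.
cigar_ref_width <- function(cigar) {
  u <- unique(cigar)
  w <- vapply(u, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 1L, USE.NAMES = FALSE)
  w[match(cigar, u)]
}

read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "cigar", "strand", "flag"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  list(
    rname = as.character(res$rname)[mapped],
    start = res$pos[mapped] - 1L,                       # 0-based
    end = res$pos[mapped] - 1L + cigar_ref_width(res$cigar[mapped]),
    strand = as.character(res$strand)[mapped],
    total_mapped = sum(mapped)
  )
}

#' Count strand-matched, fully-contained reads over RE loci
#'
#' An alignment is counted for a locus iff its aligned reference span is
#' fully contained in the locus interval and its strand equals the locus
#' strand (the strict full-containment, strand-aware counting contract).
#' Unmapped records are ignored; one alignment may count toward several
#' containing loci; no MAPQ or duplicate filtering is applied.
#'
#' @param alignment_file SAM or BAM file.
#' @param loci RE locus table.
#' @return list with `counts` (named integer vector per locus_id) and
#'   `total_mapped_reads` (number of mapped records in the file).
#' @export
count_reads <- function(alignment_file, loci) {
  aln <- read_alignments(alignment_file)
  counts <- setNames(integer(nrow(loci)), loci$locus_id)
  if (length(aln$rname) && !any(aln$rname %in% loci$chrom))
    warning("no alignment chromosome matches any locus chromosome")
  if (length(aln$rname)) {
    rd <- GenomicRanges::GRanges(aln$rname,
                                 IRanges::IRanges(aln$start + 1L, aln$end),
                                 strand = aln$strand)
    lg <- loci_to_granges(loci)
    hits <- GenomicRanges::findOverlaps(rd, lg, type = "within",
                                        ignore.strand = FALSE)
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(loci))
    counts[] <- tab
  }
  list(counts = counts, total_mapped_reads = aln$total_mapped)
}

#' Build a locus-by-sample count matrix from alignment files
#'
#' Convenience wrapper running [count_reads()] per sample.
#'
#' @param alignment_files named character vector (names = sample ids).
#' @param loci RE locus table.
#' @return list with `counts` (matrix loci x samples) and
#'   `total_mapped_reads` (named integer vector).
#' @export
count_matrix <- function(alignment_files, loci) {
  if (is.null(names(alignment_files)) || any(!nzchar(names(alignment_files))))
    stop("alignment_files must be named by sample id")
  per <- lapply(alignment_files, count_reads, loci = loci)
  counts <- vapply(per, `[[`, numeric(nrow(loci)), "counts")
  counts <- matrix(as.integer(counts), nrow = nrow(loci),
                   dimnames = list(loci$locus_id, names(alignment_files)))
  totals <- vapply(per, `[[`, 0L, "total_mapped_reads")
  list(counts = counts, total_mapped_reads = totals)
}

#' RPKM normalization
#'
#' RPKM = count x 1e9 / (locus_length_bp x total_mapped_reads): reads per
#' kilobase of feature per million mapped reads.
#'
#' @param counts matrix (loci x samples) of raw counts, rownames = locus_id.
#' @param loci RE locus table covering every row.
#' @param total_mapped_reads named positive integer vector per sample.
#' @return numeric matrix of RPKM values, same shape as `counts`.
#' @export
rpkm <- function(counts, loci, total_mapped_reads) {
  counts <- as.matrix(counts)
  len <- locus_lengths(loci)[rownames(counts)]
  if (anyNA(len)) stop("counts contain loci absent from the locus table")
  if (any(len <= 0)) stop("zero-length locus")
  tot <- total_mapped_reads[colnames(counts)]
  if (anyNA(tot) || any(tot <= 0))
    stop("every sample needs a positive total_mapped_reads")
  sweep(counts / len, 2, tot, "/") * 1e9
}

#' Size and expression-level filtration
#'
#' Keeps loci whose length is at least `min_length_bp` and whose RPKM is at
#' least `min_rpkm` in at least `min_samples` samples (both boundaries
#' inclusive).
#'
#' @param expr RPKM matrix (loci x samples).
#' @param loci RE locus table.
#' @param min_length_bp minimum locus length in bp (default 200).
#' @param min_rpkm minimum RPKM (default 1).
#' @param min_samples number of samples that must reach `min_rpkm` (default 1).
#' @return the filtered RPKM matrix.
#' @export
size_expression_filter <- function(expr, loci, min_length_bp = 200,
                                   min_rpkm = 1, min_samples = 1) {
  stopifnot(min_length_bp >= 0, min_rpkm >= 0, min_samples >= 0)
  len <- locus_lengths(loci)[rownames(expr)]
  keep <- len >= min_length_bp &
    rowSums(expr >= min_rpkm) >= min_samples
  expr[keep, , drop = FALSE]
}

#' Two-group differential expression of REs (or any feature matrix)
#'
#' For each feature, computes group means on the expression (RPKM) scale,
#' log2 fold change as `log2((mean_tumor + eps) / (mean_normal + eps))`, and
#' a two-sided Welch two-sample t-test on `log2(value + eps)`. A feature is
#' significant iff `p_value < alpha` and `|log2fc| > fc_threshold`. When both
#' groups are constant the test is degenerate: p = 1 if the means are equal,
#' p = 0 otherwise.
#'
#' @param expr numeric matrix (features x samples).
#' @param groups character/factor per sample with exactly two levels; the
#'   "normal"/reference level is taken as `ref_group`.
#' @param ref_group reference (denominator) group label, default `"normal"`.
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param fc_threshold |log2FC| threshold (default 1).
#' @param eps pseudocount added before ratios/logs (default 0.25).
#' @param adjust if TRUE adds a Benjamini-Hochberg `p_adj` column
#'   (significance remains on the raw p-value, mirroring a raw-p volcano
#'   screen; use `p_adj` downstream if desired).
#' @return `data.frame` sorted by p ascending (ties: |log2fc| descending,
#'   then feature id) with columns `feature_id`, `mean_normal`, `mean_tumor`,
#'   `log2fc`, `p_value`, (`p_adj`,) `significant`.
#' @export
differential_expression <- function(expr, groups, ref_group = "normal",
                                    alpha = 0.05, fc_threshold = 1,
                                    eps = 0.25, adjust = FALSE) {
  expr <- as.matrix(expr)
  groups <- as.character(groups)
  if (length(groups) != ncol(expr))
    stop("groups must have one label per sample column")
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups are required")
  if (!ref_group %in% lv)
    stop("ref_group '", ref_group, "' not among group labels")
  alt_group <- setdiff(lv, ref_group)
  a <- groups == ref_group; b <- groups == alt_group
  if (sum(a) < 2 || sum(b) < 2) stop("each group needs at least 2 samples")

  mean_normal <- rowMeans(expr[, a, drop = FALSE])
  mean_tumor <- rowMeans(expr[, b, drop = FALSE])
  log2fc <- log2((mean_tumor + eps) / (mean_normal + eps))
  lx <- log2(expr + eps)
  p_value <- vapply(seq_len(nrow(expr)), function(i) {
    xa <- lx[i, a]; xb <- lx[i, b]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      return(if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0)
    }
    stats::t.test(xb, xa, var.equal = FALSE)$p.value
  }, 1)
  out <- data.frame(
    feature_id = rownames(expr) %||% as.character(seq_len(nrow(expr))),
    mean_normal = mean_normal, mean_tumor = mean_tumor,
    log2fc = log2fc, p_value = p_value,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (adjust) out$p_adj <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha & abs(out$log2fc) > fc_threshold
  ord <- order(out$p_value, -abs(out$log2fc), out$feature_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parameters") <- list(alpha = alpha, fc_threshold = fc_threshold,
                                  eps = eps, ref_group = ref_group)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
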