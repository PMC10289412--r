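#' @import methods
#' @importFrom stats rnorm rpois runif setNames t.test p.adjust aggregate var
#' @importFrom utils read.table write.table packageVersion
"_PACKAGE"

## Internal coordinate convention: 0-based half-open [start, end), strand "+"/"-".
## RepeatMasker .out (1-based inclusive) and GTF (1-based inclusive) are
## converted on ingest; BED is emitted/read natively in this convention.

RE_LOCUS_COLS <- c("locus_id", "chrom", "start", "end", "strand",
                   "rep_name", "rep_class", "rep_family")

#' Construct a table of retroelement loci
#'
#' Builds and validates the canonical locus table used throughout the
#' package: one row per repeat-annotation interval, 0-based half-open
#' coordinates, with repeat name/class/family.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open span (`start < end`).
#' @param strand character vector, `"+"` or `"-"`.
#' @param rep_name,rep_class,rep_family repeat annotation columns
#'   (e.g. name `L1M5`, class `LINE`, family `L1`).
#' @return A `data.frame` with columns `locus_id` (chrom:start:strand,
#'   unique), `chrom`, `start`, `end`, `strand`, `rep_name`, `rep_class`,
#'   `rep_family`.
#' @export
re_loci <- function(chrom, start, end, strand, rep_name, rep_class, rep_family) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("invalid locus span: start must be < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(
    locus_id = paste(chrom, start, strand, sep = ":"),
    chrom = as.character(chrom), start = start, end = end,
    strand = as.character(strand),
    rep_name = as.character(rep_name), rep_class = as.character(rep_class),
    rep_family = as.character(rep_family),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus_id (same chrom:start:strand) in locus set")
  df
}

locus_lengths <- function(loci) setNames(loci$end - loci$start, loci$locus_id)

loci_to_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand
  )
}

#' Parse a RepeatMasker annotation file
#'
#' Reads either the native RepeatMasker `.out` format (fixed-column text with
#' three header lines, 1-based inclusive coordinates, strand `C` for the
#' reverse complement) or a UCSC rmsk-style tab-separated table (0-based
#' half-open, columns `genoName genoStart genoEnd strand repName repClass
#' repFamily`; `#` comment lines ignored). Coordinates are normalized to the
#' package's internal 0-based half-open convention, and the `repClass/repFamily`
#' string is split on `/` (a bare class gets `rep_family = rep_class`).
#'
#' @param path path to the annotation file.
#' @param dialect `"rm_out"` for RepeatMasker `.out`, `"rmsk_table"` for the
#'   UCSC-style table.
#' @return locus table as produced by [re_loci()].
#' @export
parse_repeatmasker <- function(path, dialect = c("rm_out", "rmsk_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "rm_out") {
    body <- lines[-seq_len(min(3L, length(lines)))]
    body_idx <- which(nzchar(trimws(body)))
    rows <- lapply(body_idx, function(i) {
      f <- strsplit(trimws(body[i]), "\\s+")[[1]]
      if (length(f) < 11)
        stop("malformed RepeatMasker .out row at line ", i + 3L, " of ", path)
      f
    })
    chrom  <- vapply(rows, `[[`, "", 5L)
    begin  <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 6L)))
    end    <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 7L)))
    if (anyNA(begin) || anyNA(end))
      stop("malformed RepeatMasker .out coordinates at line ",
           body_idx[which(is.na(begin) | is.na(end))[1]] + 3L, " of ", path)
    strand <- vapply(rows, `[[`, "", 9L)
    strand <- ifelse(strand == "C", "-", strand)
    name   <- vapply(rows, `[[`, "", 10L)
    clsfam <- vapply(rows, `[[`, "", 11L)
    start0 <- begin - 1L  # 1-based inclusive -> 0-based half-open
    end0   <- end
  } else {
    body_idx <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
    rows <- lapply(body_idx, function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 7)
        stop("malformed rmsk table row at line ", i, " of ", path)
      f
    })
    # columns: genoName genoStart genoEnd strand repName repClass repFamily
    chrom  <- vapply(rows, `[[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 2L)))
    end0   <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 3L)))
    if (anyNA(start0) || anyNA(end0))
      stop("malformed rmsk table coordinates at line ",
           body_idx[which(is.na(start0) | is.na(end0))[1]], " of ", path)
    strand <- vapply(rows, `[[`, "", 4L)
    strand <- ifelse(strand == "C", "-", strand)
    name   <- vapply(rows, `[[`, "", 5L)
    cls    <- vapply(rows, `[[`, "", 6L)
    fam    <- vapply(rows, `[[`, "", 7L)
    fam    <- ifelse(nzchar(fam), fam, cls)
    return(re_loci(chrom, start0, end0, strand, name, cls, fam))
  }
  cls <- sub("/.*$", "", clsfam)
  fam <- ifelse(grepl("/", clsfam), sub("^[^/]*/", "", clsfam), cls)
  re_loci(chrom, start0, end0, strand, name, cls, fam)
}

#' Keep only the repeat classes of interest
#'
#' Order-preserving subset of a locus table to the repeat classes in `keep`
#' (the study considers LINEs and LTR elements).
#'
#' @param loci locus table from [parse_repeatmasker()] / [re_loci()].
#' @param keep character vector of class names, default `c("LINE","LTR")`.
#' @return the subset locus table.
#' @export
filter_re_classes <- function(loci, keep = c("LINE", "LTR")) {
  if (length(keep) == 0) stop("'keep' must name at least one repeat class")
  loci[loci$rep_class %in% keep, , drop = FALSE]
}

#' Extract gene-body intervals from a GTF/GFF3 annotation
#'
#' Gene bodies are the full genomic span of each gene. Where the annotation
#' carries `gene` features those are used directly; otherwise the span is the
#' min-start/max-end union over each gene's transcripts/exons. GTF 1-based
#' inclusive coordinates are converted to 0-based half-open.
#'
#' @param path path to a GTF or GFF3 file (format detected by rtracklayer).
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
parse_gene_bodies <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% colnames(md)) stop("no gene_id attribute in ", path)
  is_gene <- !is.null(md$type) & as.character(md$type) == "gene"
  if (any(is_gene)) gr <- gr[is_gene]
  gid <- as.character(S4Vectors::mcols(gr)$gene_id)
  keepok <- !is.na(gid) & nzchar(gid)
  gr <- gr[keepok]; gid <- gid[keepok]
  if (length(gr) == 0) stop("no gene features found in ", path)
  sp <- split(gr, gid)
  start1 <- vapply(sp, function(g) min(GenomicRanges::start(g)), 1L)
  end1   <- vapply(sp, function(g) max(GenomicRanges::end(g)), 1L)
  chrom  <- vapply(sp, function(g) as.character(GenomicRanges::seqnames(g)[1]), "")
  strand <- vapply(sp, function(g) as.character(GenomicRanges::strand(g)[1]), "")
  data.frame(gene_id = names(sp), chrom = chrom,
             start = start1 - 1L, end = end1, strand = strand,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove retroelements overlapping gene bodies
#'
#' Drops every RE locus with at least 1 bp of overlap with at least one gene
#' body. Under `same_strand` (the default, mirroring a strand-aware
#' `intersect -s -v` subtraction) only same-strand overlaps cause removal;
#' under `any_strand` overlap on either strand does. Loci are removed whole,
#' never truncated.
#'
#' @param loci RE locus table.
#' @param genes gene-body table from [parse_gene_bodies()].
#' @param strand_mode `"same_strand"` or `"any_strand"`.
#' @return the surviving (intergenic) locus table.
#' @export
subtract_gene_overlaps <- function(loci, genes,
                                   strand_mode = c("same_strand", "any_strand")) {
  strand_mode <- match.arg(strand_mode)
  if (nrow(loci) == 0 || nrow(genes) == 0) return(loci)
  re_gr <- loci_to_granges(loci)
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  if (strand_mode == "any_strand")
    GenomicRanges::strand(gene_gr) <- "*"
  hits <- GenomicRanges::findOverlaps(re_gr, gene_gr, minoverlap = 1L,
                                      ignore.strand = FALSE)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) loci[-drop, , drop = FALSE] else loci
}

#' Write a locus table as BED6
#'
#' Emits one BED6 line per locus (`name` = locus_id, `score` = 0). BED is
#' natively 0-based half-open, so coordinates pass through unchanged.
#'
#' @param loci locus table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_re_bed <- function(loci, path) {
  bed <- data.frame(loci$chrom, loci$start, loci$end,
                    loci$locus_id, 0L, loci$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of RE loci
#'
#' Inverse of [write_re_bed()] on the core locus fields. Repeat
#' name/class/family are not carried by BED and come back as `NA`, unless an
#' `annotation` table is supplied to rejoin them by `locus_id`.
#'
#' @param path BED6 file.
#' @param annotation optional locus table to restore repeat metadata from.
#' @return locus table.
#' @export
read_re_bed <- function(path, annotation = NULL) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score", "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "character"))
  out <- re_loci(bed$chrom, bed$start, bed$end, bed$strand,
                 NA_character_, NA_character_, NA_character_)
  out$locus_id <- bed$name
  if (!is.null(annotation)) {
    m <- match(out$locus_id, annotation$locus_id)
    out$rep_name <- annotation$rep_name[m]
    out$rep_class <- annotation$rep_class[m]
    out$rep_family <- annotation$rep_family[m]
  }
  out
}
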