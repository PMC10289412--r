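## End-to-end orchestration: annotate -> count -> RPKM -> filter -> diff-RE
## -> scan -> MRE expression -> diff-MRE -> target integration, with
## provenance-stamped TSV outputs and a classed result object.

#' Build a pipeline configuration
#'
#' Collects every input path and analysis parameter; validation (all
#' referenced paths exist, thresholds in range) happens before any stage
#' runs.
#'
#' @param repeats repeat annotation file.
#' @param repeats_dialect `"rm_out"` or `"rmsk_table"`.
#' @param genes_gtf gene annotation (GTF/GFF3).
#' @param genome_fasta genome FASTA.
#' @param mirna_fasta mature miRNA FASTA.
#' @param species_prefix miRNA name prefix to keep (e.g. `"hsa-"`).
#' @param alignments named character vector of SAM/BAM paths (names =
#'   sample ids); alternatively supply `counts_tsv` + `totals_tsv`.
#' @param counts_tsv,totals_tsv bypass mode: a precomputed count table
#'   (loci x samples TSV) and a two-column sample/total_mapped_reads TSV.
#' @param groups named character vector sample -> group (two groups).
#' @param ref_group reference group label, default `"normal"`.
#' @param target_files optional list of >= 2 target-gene list files.
#' @param deg_table optional gene-level DEG TSV (gene, log2fc, p_value).
#' @param keep_classes repeat classes retained, default LINE + LTR.
#' @param strand_mode intergenic filter mode (see
#'   [subtract_gene_overlaps()]).
#' @param min_length_bp,min_rpkm,min_samples size/expression filter.
#' @param alpha,fc_threshold,eps differential-expression parameters.
#' @param mre_mode MRE aggregation mode (see [mre_expression()]).
#' @param outdir output directory for provenance-stamped tables.
#' @param seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return a `retro_cerna_config` list.
#' @export
pipeline_config <- function(repeats, repeats_dialect = "rm_out", genes_gtf,
                            genome_fasta, mirna_fasta, species_prefix,
                            alignments = NULL, counts_tsv = NULL,
                            totals_tsv = NULL, groups, ref_group = "normal",
                            target_files = NULL, deg_table = NULL,
                            keep_classes = c("LINE", "LTR"),
                            strand_mode = "same_strand",
                            min_length_bp = 200, min_rpkm = 1, min_samples = 1,
                            alpha = 0.05, fc_threshold = 1, eps = 0.25,
                            mre_mode = "count_weighted",
                            outdir = NULL, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "retro_cerna_config")
}

validate_pipeline_config <- function(cfg) {
  paths <- c(repeats = cfg$repeats, genes_gtf = cfg$genes_gtf,
             genome_fasta = cfg$genome_fasta, mirna_fasta = cfg$mirna_fasta,
             cfg$alignments, counts = cfg$counts_tsv, totals = cfg$totals_tsv,
             unlist(cfg$target_files), deg = cfg$deg_table)
  missing <- paths[!vapply(paths, file.exists, TRUE)]
  if (length(missing))
    stop("pipeline config references missing file(s): ",
         paste(missing, collapse = ", "))
  if (is.null(cfg$alignments) && (is.null(cfg$counts_tsv) || is.null(cfg$totals_tsv)))
    stop("either 'alignments' or 'counts_tsv' + 'totals_tsv' must be given")
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$fc_threshold >= 0, cfg$eps > 0,
            cfg$min_length_bp >= 0, cfg$min_rpkm >= 0, cfg$min_samples >= 0)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Relative paths in the file are resolved against its directory.
#'
#' @param path YAML or JSON file whose keys mirror [pipeline_config()].
#' @return a `retro_cerna_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    out <- ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
    if (!is.null(names(p))) names(out) <- names(p)
    out
  }
  for (k in c("repeats", "genes_gtf", "genome_fasta", "mirna_fasta",
              "counts_tsv", "totals_tsv", "deg_table"))
    raw[[k]] <- fix(raw[[k]])
  if (!is.null(raw$alignments)) raw$alignments <- fix(unlist(raw$alignments))
  if (!is.null(raw$target_files)) raw$target_files <- as.list(fix(unlist(raw$target_files)))
  if (!is.null(raw$groups)) raw$groups <- unlist(raw$groups)
  do.call(pipeline_config, raw)
}

provenance_header <- function(cfg, extra = character(0)) {
  hash <- tryCatch({
    h <- unclass(cfg)
    h$outdir <- NULL   # analysis parameters only, not output location
    tf <- tempfile(); saveRDS(h[order(names(h))], tf)
    unname(tools::md5sum(tf))
  }, error = function(e) "NA")
  c(sprintf("# retroceRNA %s", as.character(packageVersion("retroceRNA"))),
    sprintf("# config_md5=%s seed=%s", hash, cfg$seed),
    sprintf("# strand_mode=%s min_length_bp=%s min_rpkm=%s min_samples=%s alpha=%s fc_threshold=%s eps=%s mre_mode=%s",
            cfg$strand_mode, cfg$min_length_bp, cfg$min_rpkm, cfg$min_samples,
            cfg$alpha, cfg$fc_threshold, cfg$eps, cfg$mre_mode),
    extra)
}

write_stamped_tsv <- function(df, path, cfg, row_label = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(cfg), con)
  if (!is.null(row_label)) {
    df <- cbind(setNames(data.frame(rownames(df)), row_label),
                as.data.frame(df))
  }
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

read_totals_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  setNames(as.integer(df[[2]]), df[[1]])
}

#' Run the full retroelement-to-ceRNA pipeline
#'
#' Executes, in order: repeat/gene annotation parsing and class filtering;
#' same-strand intergenic filtering; strand-aware fully-contained read
#' counting (or count-table ingestion); RPKM; size/expression filtration;
#' differential RE expression; strand-aware sequence extraction of the
#' differentially expressed REs; seed-match site scanning; MRE expression
#' and differential MRE calling; site-type proportions; and (if target
#' lists are supplied) target-gene integration with down-regulated-DEG
#' removal. Identical config + inputs give identical outputs.
#'
#' @param config a `retro_cerna_config` (see [pipeline_config()] /
#'   [read_pipeline_config()]).
#' @param verbose print one summary line per stage.
#' @return an object of class `retro_cerna_run`; see
#'   [print.retro_cerna_run()].
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  validate_pipeline_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list(config = config)

  all_re <- parse_repeatmasker(config$repeats, config$repeats_dialect)
  re <- filter_re_classes(all_re, config$keep_classes)
  genes <- parse_gene_bodies(config$genes_gtf)
  intergenic <- subtract_gene_overlaps(re, genes, config$strand_mode)
  say("annotate: %d repeats -> %d %s -> %d intergenic",
      nrow(all_re), nrow(re), paste(config$keep_classes, collapse = "/"),
      nrow(intergenic))

  if (!is.null(config$alignments)) {
    cm <- count_matrix(config$alignments, intergenic)
    counts <- cm$counts
    totals <- cm$total_mapped_reads
  } else {
    counts <- read_counts_tsv(config$counts_tsv)
    counts <- counts[rownames(counts) %in% intergenic$locus_id, , drop = FALSE]
    totals <- read_totals_tsv(config$totals_tsv)
  }
  say("quantify: %d loci x %d samples, totals %s", nrow(counts), ncol(counts),
      paste(totals, collapse = ","))

  expr <- rpkm(counts, intergenic, totals)
  expr_f <- size_expression_filter(expr, intergenic, config$min_length_bp,
                                   config$min_rpkm, config$min_samples)
  say("filter: %d -> %d loci", nrow(expr), nrow(expr_f))

  groups <- config$groups[colnames(expr_f)]
  diff_re <- differential_expression(expr_f, groups, config$ref_group,
                                     config$alpha, config$fc_threshold,
                                     config$eps)
  sig_ids <- diff_re$feature_id[diff_re$significant]
  say("diff-re: %d/%d significant", length(sig_ids), nrow(diff_re))

  mirnas <- parse_mirna_fasta(config$mirna_fasta, config$species_prefix)
  fams <- collapse_families(seed_patterns(mirnas))
  sig_loci <- intergenic[intergenic$locus_id %in% sig_ids, , drop = FALSE]
  seqs <- extract_re_sequences(config$genome_fasta, sig_loci)
  scan <- scan_loci(seqs, fams)
  say("scan: %d sites on %d differentially expressed loci",
      nrow(scan$sites), nrow(sig_loci))

  res$annotation <- list(all = all_re, kept = re, intergenic = intergenic,
                         genes = genes)
  res$counts <- counts
  res$total_mapped_reads <- totals
  res$rpkm <- expr
  res$rpkm_filtered <- expr_f
  res$diff_re <- diff_re
  res$mirna_families <- fams
  res$sites <- scan$sites
  res$site_counts <- scan$site_counts

  if (nrow(scan$site_counts)) {
    mre <- mre_expression(expr_f[sig_ids, , drop = FALSE], scan$site_counts,
                          config$mre_mode)
    diff_mre <- differential_mre(mre, groups, config$ref_group, config$alpha,
                                 config$fc_threshold, config$eps)
    res$mre_expression <- mre
    res$diff_mre <- diff_mre
    res$type_proportions <- type_proportions(scan$site_counts)
    say("mre: %d MRE rows, %d significant", nrow(mre),
        sum(diff_mre$significant))
  }

  if (!is.null(config$target_files) && length(config$target_files) >= 2) {
    sets <- lapply(config$target_files, read_gene_list)
    common <- intersect_targets(sets)
    res$common_targets <- common
    if (!is.null(config$deg_table)) {
      degs <- read.table(config$deg_table, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
      degs <- classify_degs(degs, config$alpha, config$fc_threshold)
      res$released_genes <- remove_downregulated(common, degs)
      say("targets: %d common -> %d after removing down-regulated DEGs",
          length(common), length(res$released_genes))
    }
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    o <- function(f) file.path(config$outdir, f)
    write_re_bed(intergenic, o("intergenic_re.bed"))
    write_stamped_tsv(counts, o("re_counts.tsv"), config, "locus_id")
    write_stamped_tsv(expr, o("re_rpkm.tsv"), config, "locus_id")
    write_stamped_tsv(diff_re, o("diff_re.tsv"), config)
    write_stamped_tsv(res$sites, o("mre_sites.tsv"), config)
    if (!is.null(res$diff_mre)) {
      write_stamped_tsv(res$mre_expression, o("mre_expression.tsv"), config,
                        "mre_id")
      write_stamped_tsv(res$diff_mre, o("diff_mre.tsv"), config)
      write_stamped_tsv(as.data.frame(t(res$type_proportions)),
                        o("type_proportions.tsv"), config)
    }
    if (!is.null(res$released_genes))
      writeLines(c(provenance_header(config), res$released_genes),
                 o("released_genes.txt"))
  }
  structure(res, class = "retro_cerna_run")
}

#' @export
print.retro_cerna_run <- function(x, ...) {
  cat("retroceRNA pipeline run\n")
  cat(sprintf("  repeats: %d total, %d kept (%s), %d intergenic\n",
              nrow(x$annotation$all), nrow(x$annotation$kept),
              paste(x$config$keep_classes, collapse = "/"),
              nrow(x$annotation$intergenic)))
  cat(sprintf("  samples: %d (%s)\n", ncol(x$counts),
              paste(names(table(x$config$groups[colnames(x$counts)])),
                    table(x$config$groups[colnames(x$counts)]),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  differential REs: %d/%d significant (alpha=%s, |log2FC|>%s)\n",
              sum(x$diff_re$significant), nrow(x$diff_re),
              x$config$alpha, x$config$fc_threshold))
  if (!is.null(x$sites))
    cat(sprintf("  MRE sites: %d (%d MRE rows)\n", nrow(x$sites),
                if (is.null(x$mre_expression)) 0L else nrow(x$mre_expression)))
  if (!is.null(x$type_proportions))
    cat(sprintf("  site types: 8M %.1f%%, 7A1 %.1f%%, 7M8 %.1f%%\n",
                x$type_proportions[["pct_8M"]], x$type_proportions[["pct_7A1"]],
                x$type_proportions[["pct_7M8"]]))
  if (!is.null(x$released_genes))
    cat(sprintf("  genes released from miRNA control: %d\n",
                length(x$released_genes)))
  invisible(x)
}

#' @export
summary.retro_cerna_run <- function(object, k = 5, ...) {
  print(object)
  if (!is.null(object$diff_mre)) {
    up <- top_k(object$diff_mre, k, "up")
    if (nrow(up)) {
      cat(sprintf("\n  top %d increased MREs:\n", nrow(up)))
      print(up[, c("feature_id", "log2fc", "p_value")], row.names = FALSE)
    }
  }
  invisible(object)
}
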