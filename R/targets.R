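## Integration of externally predicted miRNA target-gene lists with
## differential gene expression. Target lists are flat files (one symbol
## per line, or a TSV column) exported from prediction databases; symbols
## are normalized to uppercase, whitespace-stripped and de-duplicated.

normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  unique(x[nzchar(x)])
}

#' Read a target-gene list from a flat file
#'
#' One gene symbol per line, or a TSV whose requested column holds symbols.
#' `#` comment lines and a literal header matching `column` are skipped.
#'
#' @param path input file.
#' @param column for TSV input, the column name or index (default 1).
#' @return character vector of normalized gene symbols.
#' @export
read_gene_list <- function(path, column = 1) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (length(ln) == 0) return(character(0))
  if (any(grepl("\t", ln))) {
    df <- read.table(text = ln, sep = "\t", header = is.character(column),
                     stringsAsFactors = FALSE)
    vals <- df[[column]]
  } else {
    vals <- ln
    if (is.character(column) && length(vals) && toupper(vals[1]) == toupper(column))
      vals <- vals[-1]
  }
  normalize_symbols(vals)
}

#' Intersect predicted target-gene lists
#'
#' Set intersection of two or more target lists (e.g. the genes shared by
#' two prediction databases) after symbol normalization.
#'
#' @param sets list of character vectors of gene symbols.
#' @return character vector, sorted.
#' @export
intersect_targets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2)
    stop("need at least two target sets to intersect")
  sets <- lapply(sets, normalize_symbols)
  sort(Reduce(intersect, sets))
}

#' Common target genes across the three site-type groups
#'
#' Three-way intersection of the per-site-type target sets (8M, 7A1, 7M8),
#' with the full 7-region Venn breakdown.
#'
#' @param targets_by_type named list with elements `"8M"`, `"7A1"`, `"7M8"`.
#' @return list with `common` (sorted character vector) and `venn_counts`
#'   (named integer vector over the 7 exclusive regions).
#' @export
common_across_types <- function(targets_by_type) {
  need <- c("8M", "7A1", "7M8")
  miss <- setdiff(need, names(targets_by_type))
  if (length(miss)) stop("missing site-type set(s): ", paste(miss, collapse = ", "))
  s <- lapply(targets_by_type[need], normalize_symbols)
  common <- sort(Reduce(intersect, s))
  inA <- s[["8M"]]; inB <- s[["7A1"]]; inC <- s[["7M8"]]
  venn <- c(
    "8M_only"  = length(setdiff(inA, union(inB, inC))),
    "7A1_only" = length(setdiff(inB, union(inA, inC))),
    "7M8_only" = length(setdiff(inC, union(inA, inB))),
    "8M_7A1"   = length(setdiff(intersect(inA, inB), inC)),
    "8M_7M8"   = length(setdiff(intersect(inA, inC), inB)),
    "7A1_7M8"  = length(setdiff(intersect(inB, inC), inA)),
    "all_three" = length(common)
  )
  list(common = common, venn_counts = venn)
}

#' Classify DEG direction
#'
#' Adds the `up`/`down`/`ns` direction call to a gene-level differential
#' table: `down` iff p < alpha and log2fc < -fc_threshold; `up` symmetric.
#'
#' @param degs `data.frame` with columns `gene`, `log2fc`, `p_value`.
#' @param alpha,fc_threshold thresholds (defaults 0.05 and 1).
#' @return the table with `direction` column added, symbols normalized.
#' @export
classify_degs <- function(degs, alpha = 0.05, fc_threshold = 1) {
  degs$gene <- toupper(trimws(degs$gene))
  degs$direction <- ifelse(
    degs$p_value < alpha & degs$log2fc < -fc_threshold, "down",
    ifelse(degs$p_value < alpha & degs$log2fc > fc_threshold, "up", "ns"))
  degs
}

#' Remove down-regulated DEGs from a candidate gene set
#'
#' Drops genes whose DEG direction is `down`; genes absent from the DEG
#' table are retained (only demonstrably down-regulated genes are removed).
#' The survivors are the candidate genes released from miRNA control.
#'
#' @param genes character vector of candidate gene symbols.
#' @param degs classified DEG table (see [classify_degs()]); an unclassified
#'   table is classified with the default thresholds.
#' @return sorted character vector of retained genes.
#' @export
remove_downregulated <- function(genes, degs) {
  genes <- normalize_symbols(genes)
  if (is.null(degs$direction)) degs <- classify_degs(degs)
  down <- toupper(trimws(degs$gene[degs$direction == "down"]))
  sort(setdiff(genes, down))
}
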