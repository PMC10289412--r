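## Conversion of RE expression into MRE expression and its summaries.

#' MRE expression matrix from RE expression and site counts
#'
#' Each MRE row is a (miRNA family, site type) pair. Under `count_weighted`
#' (default) its value in a sample is the site-count-weighted sum of the
#' RPKM of every RE locus carrying that site: an RE with more copies of a
#' site contributes proportionally more sponge capacity. Under `presence`
#' each carrying locus contributes its RPKM once regardless of copy number.
#'
#' @param re_expr RPKM matrix (loci x samples).
#' @param site_counts `data.frame` with `locus_id`, `mirna_family`,
#'   `site_type`, `n_sites` (as from [scan_loci()]).
#' @param mode `"count_weighted"` or `"presence"`.
#' @return numeric matrix (MRE rows x samples); rownames are
#'   `family|site_type`; the weighting mode is recorded in
#'   `attr(, "mode")`.
#' @export
mre_expression <- function(re_expr, site_counts,
                           mode = c("count_weighted", "presence")) {
  mode <- match.arg(mode)
  re_expr <- as.matrix(re_expr)
  if (nrow(site_counts) == 0) {
    out <- matrix(numeric(0), nrow = 0, ncol = ncol(re_expr),
                  dimnames = list(NULL, colnames(re_expr)))
    attr(out, "mode") <- mode
    return(out)
  }
  unknown <- setdiff(site_counts$locus_id, rownames(re_expr))
  if (length(unknown))
    stop("site table names loci absent from the expression matrix: ",
         paste(unknown, collapse = ", "))
  w <- if (mode == "count_weighted") site_counts$n_sites else
    as.numeric(site_counts$n_sites > 0)
  mre_id <- paste(site_counts$mirna_family, site_counts$site_type, sep = "|")
  ids <- sort(unique(mre_id))
  # sparse accumulation: rows of re_expr weighted and summed per MRE id
  out <- matrix(0, nrow = length(ids), ncol = ncol(re_expr),
                dimnames = list(ids, colnames(re_expr)))
  ridx <- match(mre_id, ids)
  lidx <- match(site_counts$locus_id, rownames(re_expr))
  for (k in seq_along(ridx))
    out[ridx[k], ] <- out[ridx[k], ] + w[k] * re_expr[lidx[k], ]
  attr(out, "mode") <- mode
  out
}

#' Differential MRE expression
#'
#' Identical statistical contract to [differential_expression()], applied to
#' the MRE rows of [mre_expression()].
#'
#' @inheritParams differential_expression
#' @param mre_expr MRE expression matrix.
#' @return differential table, sorted as in [differential_expression()].
#' @export
differential_mre <- function(mre_expr, groups, ref_group = "normal",
                             alpha = 0.05, fc_threshold = 1, eps = 0.25,
                             adjust = FALSE) {
  differential_expression(mre_expr, groups, ref_group = ref_group,
                          alpha = alpha, fc_threshold = fc_threshold,
                          eps = eps, adjust = adjust)
}

#' Site-type composition of a site set
#'
#' Percentage of site records per type (8M / 7A1 / 7M8) over all sites.
#'
#' @param sites site table with a `site_type` column (long table or count
#'   table; a count table's `n_sites` column is used as weights).
#' @param digits rounding precision for the percentages (default 1).
#' @return named numeric vector `c(pct_8M=, pct_7A1=, pct_7M8=)` summing to
#'   100 within rounding.
#' @export
type_proportions <- function(sites, digits = 1) {
  if (nrow(sites) == 0) stop("empty site set")
  w <- if ("n_sites" %in% names(sites)) sites$n_sites else rep(1L, nrow(sites))
  tot <- sum(w)
  pct <- vapply(c("8M", "7A1", "7M8"),
                function(tt) 100 * sum(w[sites$site_type == tt]) / tot, 1)
  round(setNames(pct, paste0("pct_", names(pct))), digits)
}

#' Top differentially expressed features by fold change
#'
#' The top `k` significant rows by |log2fc| within one direction; ties are
#' broken by p-value, then feature id. May return fewer than `k` rows.
#'
#' @param diff a differential table from [differential_expression()].
#' @param k number of rows requested.
#' @param direction `"up"` (log2fc > 0) or `"down"` (log2fc < 0).
#' @return the selected rows, ordered.
#' @export
top_k <- function(diff, k, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(k >= 1)
  sel <- diff[diff$significant &
                (if (direction == "up") diff$log2fc > 0 else diff$log2fc < 0), ,
              drop = FALSE]
  sel <- sel[order(-abs(sel$log2fc), sel$p_value, sel$feature_id), , drop = FALSE]
  rownames(sel) <- NULL
  utils::head(sel, k)
}
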