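## Deterministic synthetic corpus: genome, repeat/gene annotations, mature
## miRNAs, per-sample alignments and target-list fixtures, all tied to a
## ground-truth manifest so each pipeline stage can be checked against
## planted truth. The generator emulates a two-group (normal vs tumor)
## bulk RNA-seq design at toy scale.

DNA_BASES <- c("A", "C", "G", "T")

# base-R reverse complement used in the generator's hot loop
revcomp_plain <- function(s) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", s), ""),
         function(x) paste(rev(x), collapse = ""), "")
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

#' Configuration for the synthetic corpus
#'
#' All knobs of the generator with their default study conditions: a
#' two-group design of 5 normal vs 5 tumor libraries, log-normal baseline
#' expression (log2 RPKM ~ N(5, 1)), per-sample log-normal noise of
#' sigma = 0.3 (log2 scale), a planted log2 fold change of +2 on 10% of the
#' intergenic LINE/LTR loci, and 2 planted sites per seed-match type for
#' the designated ceRNA miRNA family on every up-regulated locus.
#'
#' @param seed integer RNG seed; the whole corpus is a pure function of it.
#' @param n_chroms,chrom_length_bp synthetic genome shape.
#' @param n_re_loci number of repeat loci to place (non-overlapping).
#' @param re_length_range_bp locus length range, bp.
#' @param n_genes number of gene bodies (must cover the overlap fractions).
#' @param fraction_re_overlapping_gene_same_strand,fraction_opposite_strand
#'   fractions of RE loci given an overlapping gene on the same / opposite
#'   strand (exercises the intergenic filter).
#' @param fraction_other_class fraction of loci drawn from non-LINE/LTR
#'   classes (exercises the class filter).
#' @param n_mirnas number of synthetic mature miRNAs (distinct seeds).
#' @param planted_sites_per_type named counts (`8M`, `7A1`, `7M8`) planted
#'   for the ceRNA family on each up-regulated locus.
#' @param n_decoy_loci_per_family null loci receiving one decoy site per
#'   non-ceRNA family.
#' @param n_normal,n_tumor group sizes.
#' @param baseline_log2_rpkm_mean,baseline_log2_rpkm_sd locus baseline
#'   expression distribution (log2 RPKM scale).
#' @param noise_sd per-locus, per-sample log2-scale noise sigma.
#' @param planted_log2fc true tumor/normal log2 fold change of non-null loci.
#' @param fraction_diff fraction of intergenic LINE/LTR loci that are
#'   non-null (up-regulated).
#' @param reads_per_sample nominal library size used to convert expected
#'   RPKM into expected read counts.
#' @param read_length read length, bp.
#' @param straddler_fraction,antisense_fraction per-locus fractions of extra
#'   labeled reads that must NOT be counted (boundary-straddling reads and
#'   contained reads on the opposite strand).
#' @param n_common_targets,n_down_in_common,n_type_extra,n_db_common,n_db_extra
#'   target-list fixture shape: size of the three-way common target set, how
#'   many of those are down-regulated DEGs, per-type exclusive extras, size
#'   of the two-database intersection and per-database extras.
#' @return a validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 2L, chrom_length_bp = 60000L,
                             n_re_loci = 60L, re_length_range_bp = c(300L, 600L),
                             n_genes = 20L,
                             fraction_re_overlapping_gene_same_strand = 0.2,
                             fraction_opposite_strand = 0.1,
                             fraction_other_class = 0.2,
                             n_mirnas = 5L,
                             planted_sites_per_type = c("8M" = 2L, "7A1" = 2L, "7M8" = 2L),
                             n_decoy_loci_per_family = 2L,
                             n_normal = 5L, n_tumor = 5L,
                             baseline_log2_rpkm_mean = 5, baseline_log2_rpkm_sd = 1,
                             noise_sd = 0.3, planted_log2fc = 2,
                             fraction_diff = 0.1,
                             reads_per_sample = 2e6, read_length = 50L,
                             straddler_fraction = 0.1, antisense_fraction = 0.1,
                             n_common_targets = 99L, n_down_in_common = 5L,
                             n_type_extra = 30L,
                             n_db_common = 317L, n_db_extra = 100L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$seed == as.integer(cfg$seed),
    cfg$n_chroms >= 1, cfg$chrom_length_bp > 0, cfg$n_re_loci >= 1,
    length(cfg$re_length_range_bp) == 2,
    cfg$re_length_range_bp[1] <= cfg$re_length_range_bp[2],
    cfg$fraction_re_overlapping_gene_same_strand >= 0,
    cfg$fraction_opposite_strand >= 0,
    cfg$fraction_re_overlapping_gene_same_strand +
      cfg$fraction_opposite_strand <= 1,
    cfg$fraction_other_class >= 0, cfg$fraction_other_class <= 1,
    cfg$n_mirnas >= 1, all(cfg$planted_sites_per_type >= 0),
    all(names(cfg$planted_sites_per_type) %in% SITE_TYPES),
    cfg$n_normal >= 2, cfg$n_tumor >= 2, cfg$noise_sd >= 0,
    is.finite(cfg$planted_log2fc),
    cfg$fraction_diff >= 0, cfg$fraction_diff <= 1,
    cfg$reads_per_sample > 0, cfg$read_length >= 20,
    cfg$straddler_fraction >= 0, cfg$antisense_fraction >= 0,
    cfg$n_down_in_common <= cfg$n_common_targets
  )
  n_overlap <- round(cfg$fraction_re_overlapping_gene_same_strand * cfg$n_re_loci) +
    round(cfg$fraction_opposite_strand * cfg$n_re_loci)
  if (cfg$n_genes < n_overlap)
    stop("n_genes must be at least the number of overlap genes (", n_overlap, ")")
  structure(cfg, class = "synthetic_config")
}

RE_CATALOG <- data.frame(
  rep_name = c("L1M5", "L2a", "CR1-L3", "MER41B", "MLT1A", "THE1B",
               "(TA)n", "MER5A"),
  rep_class = c("LINE", "LINE", "LINE", "LTR", "LTR", "LTR",
                "Simple_repeat", "DNA"),
  rep_family = c("L1", "L2", "CR1", "ERV1", "ERVL", "ERVL-MaLR",
                 "Simple_repeat", "hAT-Charlie"),
  stringsAsFactors = FALSE
)

#' Simulate a genome with repeat and gene annotations
#'
#' Places non-overlapping RE loci (padded by at least one read length from
#' each other and the chromosome ends so boundary-straddling reads stay
#' unambiguous), samples repeat classes from a small LINE/LTR/other catalog,
#' and plants gene bodies so that the configured fractions of REs overlap a
#' gene on the same / opposite strand; remaining genes land in repeat-free
#' gaps.
#'
#' @param config a [synthetic_config()].
#' @return list with `genome` (named chromosome sequences), `loci` (locus
#'   table + `overlap_status` in {none, same_strand, opposite_strand}),
#'   `genes` (gene-body table) and `intergenic_ids` — the locus_ids a
#'   same-strand intergenic filter on the LINE/LTR subset must return.
#' @export
simulate_genome_annotations <- function(config) {
  set.seed(config$seed)
  margin <- config$read_length + 10L
  gap_min <- config$read_length + 10L

  # round-robin placement with random gaps
  per_chrom <- split(seq_len(config$n_re_loci),
                     rep(seq_len(config$n_chroms), length.out = config$n_re_loci))
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  loci_rows <- list()
  for (ci in seq_len(config$n_chroms)) {
    pos <- margin
    for (i in per_chrom[[ci]]) {
      len <- sample(config$re_length_range_bp[1]:config$re_length_range_bp[2], 1)
      gap <- gap_min + sample(0:200, 1)
      start <- pos + gap
      end <- start + len
      if (end > config$chrom_length_bp - margin)
        stop("cannot place ", config$n_re_loci, " loci of the requested size ",
             "within chrom_length_bp = ", config$chrom_length_bp)
      loci_rows[[i]] <- data.frame(chrom = chrom_names[ci], start = start,
                                   end = end, stringsAsFactors = FALSE)
      pos <- end
    }
  }
  pl <- do.call(rbind, loci_rows)
  n <- nrow(pl)
  n_other <- round(config$fraction_other_class * n)
  other_idx <- which(RE_CATALOG$rep_class %in% c("Simple_repeat", "DNA"))
  main_idx <- setdiff(seq_len(nrow(RE_CATALOG)), other_idx)
  cat_idx <- c(sample(other_idx, n_other, replace = TRUE),
               sample(main_idx, n - n_other, replace = TRUE))
  cat_idx <- sample(cat_idx)   # shuffle class assignment over positions
  strand <- sample(c("+", "-"), n, replace = TRUE)
  loci <- re_loci(pl$chrom, pl$start, pl$end, strand,
                  RE_CATALOG$rep_name[cat_idx], RE_CATALOG$rep_class[cat_idx],
                  RE_CATALOG$rep_family[cat_idx])

  # overlap assignment: fractions of ALL REs get an overlapping gene
  n_same <- round(config$fraction_re_overlapping_gene_same_strand * n)
  n_opp <- round(config$fraction_opposite_strand * n)
  shuffled <- sample(seq_len(n))
  same_idx <- shuffled[seq_len(n_same)]
  opp_idx <- shuffled[n_same + seq_len(n_opp)]
  loci$overlap_status <- "none"
  loci$overlap_status[same_idx] <- "same_strand"
  loci$overlap_status[opp_idx] <- "opposite_strand"

  gene_rows <- list()
  gi <- 0L
  mk_gene <- function(chrom, start, end, strand) {
    gi <<- gi + 1L
    data.frame(gene_id = sprintf("G%04d", gi), chrom = chrom,
               start = start, end = end, strand = strand,
               stringsAsFactors = FALSE)
  }
  for (i in same_idx)
    gene_rows[[length(gene_rows) + 1L]] <-
      mk_gene(loci$chrom[i], loci$start[i] + 5L, loci$end[i] - 5L, loci$strand[i])
  for (i in opp_idx)
    gene_rows[[length(gene_rows) + 1L]] <-
      mk_gene(loci$chrom[i], loci$start[i] + 5L, loci$end[i] - 5L,
              if (loci$strand[i] == "+") "-" else "+")
  # filler genes in repeat-free gaps (the inter-locus gaps are >= gap_min)
  n_filler <- config$n_genes - n_same - n_opp
  if (n_filler > 0) {
    gaps <- do.call(rbind, lapply(split(loci, loci$chrom), function(l) {
      l <- l[order(l$start), ]
      data.frame(chrom = l$chrom[-1], lo = utils::head(l$end, -1) + 5L,
                 hi = l$start[-1] - 5L, stringsAsFactors = FALSE)
    }))
    gaps <- gaps[gaps$hi - gaps$lo >= 40L, , drop = FALSE]
    pick <- sample(seq_len(nrow(gaps)), n_filler, replace = n_filler > nrow(gaps))
    for (g in pick)
      gene_rows[[length(gene_rows) + 1L]] <-
        mk_gene(gaps$chrom[g], gaps$lo[g] + 2L, gaps$hi[g] - 2L,
                sample(c("+", "-"), 1))
  }
  genes <- do.call(rbind, gene_rows)
  # de-duplicate filler genes that landed on the same gap span
  genes <- genes[!duplicated(genes[, c("chrom", "start", "end", "strand")]), ]

  genome <- setNames(
    vapply(seq_len(config$n_chroms),
           function(i) random_dna(config$chrom_length_bp), ""),
    chrom_names)

  keep <- loci$rep_class %in% c("LINE", "LTR")
  list(genome = genome, loci = loci, genes = genes,
       intergenic_ids = loci$locus_id[keep & loci$overlap_status != "same_strand"])
}

#' Simulate mature miRNAs with distinct, non-nested seeds
#'
#' Random 22-nt RNA sequences named `syn-miR-<k>-5p`, re-drawn until every
#' pair of miRNAs has distinct position 2-7 subsequences and no miRNA's
#' 7-mer site pattern occurs as a substring of another's 8-mer site. The
#' latter guarantees that a planted site of one family can never embed a
#' match of a different tracked family, keeping planted-truth bookkeeping
#' exact.
#'
#' @param config a [synthetic_config()].
#' @return `data.frame` with `name`, `sequence` (RNA alphabet).
#' @export
simulate_mirnas <- function(config) {
  set.seed(config$seed + 1L)
  draw <- function() chartr("T", "U", random_dna(22L))
  site_strings <- function(s) {
    seed28 <- chartr("U", "T", substr(s, 2, 8))
    s8 <- paste0(revcomp_plain(seed28), "A")
    c(s8 = s8, s7m8 = substr(s8, 1, 7), s7a1 = substr(s8, 2, 8))
  }
  self_ok <- function(st) {
    occ <- function(pat) {
      g <- gregexpr(pat, st[["s8"]], fixed = TRUE)[[1]]
      if (g[1] == -1) integer(0) else as.integer(g)
    }
    identical(occ(st[["s7m8"]]), 1L) && identical(occ(st[["s7a1"]]), 2L)
  }
  compatible <- function(a, b) {
    # no 7-mer of one family inside the 8-mer of the other, no shared 7-mer
    !any(vapply(a[c("s7m8", "s7a1")], grepl, TRUE, x = b[["s8"]], fixed = TRUE)) &&
      !any(vapply(b[c("s7m8", "s7a1")], grepl, TRUE, x = a[["s8"]], fixed = TRUE)) &&
      length(intersect(a[c("s7m8", "s7a1")], b[c("s7m8", "s7a1")])) == 0
  }
  seqs <- character(config$n_mirnas)
  sites <- vector("list", config$n_mirnas)
  for (i in seq_len(config$n_mirnas)) {
    repeat {
      s <- draw()
      st <- site_strings(s)
      ok <- self_ok(st) && (i == 1 ||
        all(vapply(seq_len(i - 1), function(j) compatible(st, sites[[j]]), TRUE)))
      if (ok) break
    }
    seqs[i] <- s
    sites[[i]] <- st
  }
  data.frame(name = sprintf("syn-miR-%d-5p", seq_len(config$n_mirnas)),
             sequence = seqs, stringsAsFactors = FALSE)
}

# --- site planting --------------------------------------------------------

# all 0-based offsets of 7-mer/8-mer windows equal to each pattern, via
# vectorized substring enumeration (independent of the scanner's matcher)
window_offsets <- function(chars, patterns) {
  s <- paste(chars, collapse = "")
  L <- length(chars)
  w7 <- if (L >= 7) substring(s, 1:(L - 6), 7:L) else character(0)
  w8 <- if (L >= 8) substring(s, 1:(L - 7), 8:L) else character(0)
  lapply(patterns, function(p)
    which((if (nchar(p) == 7) w7 else w8) == p) - 1L)
}

# plant all sites in `plan` (family_key, site_type, n) into `sequence`, then
# mutate the background until no tracked pattern occurs anywhere except at
# the planted windows. Guard bases prevent a planted 7M8/7A1 from being
# promoted to an 8mer by its flanking base.
scrub_and_plant <- function(sequence, plan, tracked, max_iter = 400L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  protected <- logical(L)
  guard_forbid <- character(L)   # guard positions: any base except this one
  placements <- list()

  site_string <- function(fk, type) {
    row <- tracked[tracked$family_key == fk, ]
    switch(type, "8M" = row$site_8m, "7M8" = row$site_7m8, "7A1" = row$site_7a1)
  }

  if (nrow(plan) > 0) for (r in seq_len(nrow(plan))) {
    fk <- plan$family_key[r]; type <- plan$site_type[r]; n <- plan$n[r]
    if (n == 0) next
    s <- site_string(fk, type)
    w <- nchar(s)
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        p <- sample.int(L - w - 1L, 1L)          # 0-based offset in [1, L-w-2]
        lo <- p; hi <- p + w - 1L
        if (type == "7M8") hi <- hi + 1L         # guard base after the site
        if (type == "7A1") lo <- lo - 1L         # guard base before the site
        if (lo < 0L || hi >= L) next
        # one free base on each side so no accidental match window can be
        # fully protected (and hence unresolvable)
        guard_lo <- max(1L, lo); guard_hi <- min(L, hi + 2L)
        if (any(protected[guard_lo:guard_hi])) next
        chars[(p + 1L):(p + w)] <- strsplit(s, "")[[1]]
        if (type == "7M8") {
          chars[p + w + 1L] <- sample(setdiff(DNA_BASES, "A"), 1L)
          guard_forbid[p + w + 1L] <- "A"
        }
        if (type == "7A1") {
          fb <- substr(site_string(fk, "8M"), 1, 1)
          chars[p] <- sample(setdiff(DNA_BASES, fb), 1L)
          guard_forbid[p] <- fb
        }
        protected[(lo + 1L):(hi + 1L)] <- TRUE
        placements[[length(placements) + 1L]] <-
          data.frame(family_key = fk, site_type = type, offset = p,
                     stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ", n, " non-overlapping ", type,
             " site(s) in a sequence of length ", L)
    }
  }
  placed_df <- if (length(placements)) do.call(rbind, placements) else
    data.frame(family_key = character(0), site_type = character(0),
               offset = integer(0), stringsAsFactors = FALSE)

  # expected raw occurrence offsets per (family, pattern string)
  expected <- list()
  add_exp <- function(key, off) expected[[key]] <<- c(expected[[key]], off)
  if (nrow(placed_df) > 0) for (r in seq_len(nrow(placed_df))) {
    fk <- placed_df$family_key[r]; p <- placed_df$offset[r]
    switch(placed_df$site_type[r],
      "8M" = { add_exp(paste0(fk, "|8m"), p); add_exp(paste0(fk, "|7m8"), p)
               add_exp(paste0(fk, "|7a1"), p + 1L) },
      "7M8" = add_exp(paste0(fk, "|7m8"), p),
      "7A1" = add_exp(paste0(fk, "|7a1"), p))
  }

  pat_list <- do.call(rbind, lapply(seq_len(nrow(tracked)), function(i) {
    data.frame(key = paste0(tracked$family_key[i], c("|8m", "|7m8", "|7a1")),
               pat = c(tracked$site_8m[i], tracked$site_7m8[i], tracked$site_7a1[i]),
               stringsAsFactors = FALSE)
  }))

  for (iter in seq_len(max_iter)) {
    clean <- TRUE
    all_offs <- window_offsets(chars, pat_list$pat)
    for (j in seq_len(nrow(pat_list))) {
      bad <- setdiff(all_offs[[j]], expected[[pat_list$key[j]]] %||% integer(0))
      if (length(bad) == 0) next
      clean <- FALSE
      p <- bad[1]; w <- nchar(pat_list$pat[j])
      win <- (p + 1L):(p + w)
      free <- win[!protected[win]]
      # guard bases are protected but mutable within their own constraint
      guards <- win[protected[win] & nzchar(guard_forbid[win])]
      if (length(free)) {
        pos <- if (length(free) == 1) free else sample(free, 1L)
        chars[pos] <- sample(setdiff(DNA_BASES, chars[pos]), 1L)
      } else if (length(guards)) {
        pos <- if (length(guards) == 1) guards else sample(guards, 1L)
        choices <- setdiff(DNA_BASES, c(chars[pos], guard_forbid[pos]))
        chars[pos] <- if (length(choices) == 1) choices else sample(choices, 1L)
      } else {
        stop("unresolvable accidental match of a tracked pattern inside ",
             "planted sites")
      }
      break   # re-scan from the top after each mutation
    }
    if (clean)
      return(list(sequence = paste(chars, collapse = ""),
                  placements = placed_df))
  }
  stop("background scrub did not converge after ", max_iter, " iterations")
}

#' Plant seed-match sites of one type into a sequence
#'
#' Writes exactly `n` non-overlapping sites of `type` for the first family
#' in `patterns` into the sequence, with flanking guard bases so a 7mer site
#' is never accidentally an 8mer, then rejection-samples background
#' mutations until no tracked family matches anywhere else.
#'
#' @param sequence DNA string (long enough for `n` non-overlapping sites).
#' @param patterns seed-pattern table; row 1 is the planted family.
#' @param type `"8M"`, `"7M8"` or `"7A1"`.
#' @param n number of sites to plant.
#' @param tracked pattern table of all families that must not match
#'   accidentally (default: `patterns`).
#' @return list with `sequence` (modified) and `offsets` (0-based).
#' @export
plant_mre_sites <- function(sequence, patterns, type = c("8M", "7M8", "7A1"),
                            n, tracked = patterns) {
  type <- match.arg(type)
  stopifnot(n >= 0)
  plan <- if (n > 0)
    data.frame(family_key = patterns$family_key[1], site_type = type, n = n,
               stringsAsFactors = FALSE)
  else
    data.frame(family_key = character(0), site_type = character(0),
               n = integer(0), stringsAsFactors = FALSE)
  res <- scrub_and_plant(sequence, plan, tracked)
  list(sequence = res$sequence, offsets = res$placements$offset)
}

# write a transcript-space sequence back into the genome at a locus
write_back_locus <- function(genome, locus, transcript_seq) {
  g <- if (locus$strand == "-") revcomp_plain(transcript_seq) else transcript_seq
  chrom <- genome[[locus$chrom]]
  genome[[locus$chrom]] <- paste0(
    substr(chrom, 1, locus$start),
    g,
    substr(chrom, locus$end + 1, nchar(chrom)))
  genome
}

#' Simulate per-sample alignments (SAM) and totals
#'
#' Draws per-locus expected expression from the log-normal model (baseline
#' log2 RPKM per locus, planted log2FC added for tumor samples, per-cell
#' noise of sigma = `noise_sd`), converts it to an expected count via the
#' RPKM identity at the nominal library size, realizes counts as Poisson
#' draws, and emits for each locus: that many fully-contained, strand-matched
#' reads plus the configured fractions of boundary-straddling and antisense
#' reads which a correct counter must ignore.
#'
#' @param config a [synthetic_config()].
#' @param genome named chromosome sequences.
#' @param loci the LINE/LTR locus table reads are generated for.
#' @param true_log2fc named numeric (locus_id -> planted log2FC, 0 = null).
#' @param outdir directory for the `.sam` files.
#' @return list with `sam_files` (named by sample), `groups`,
#'   `total_mapped_reads`, and `expected_counts` (loci x samples matrix of
#'   contained, strand-matched reads — the counting oracle).
#' @export
simulate_alignments <- function(config, genome, loci, true_log2fc, outdir) {
  set.seed(config$seed + 4L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rl <- config$read_length
  nL <- nrow(loci)
  lens <- loci$end - loci$start
  baseline <- rnorm(nL, config$baseline_log2_rpkm_mean, config$baseline_log2_rpkm_sd)
  lfc <- unname(true_log2fc[loci$locus_id])
  samples <- c(sprintf("normal_%d", seq_len(config$n_normal)),
               sprintf("tumor_%d", seq_len(config$n_tumor)))
  groups <- setNames(rep(c("normal", "tumor"), c(config$n_normal, config$n_tumor)),
                     samples)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  expected <- matrix(0L, nL, length(samples),
                     dimnames = list(loci$locus_id, samples))
  totals <- setNames(integer(length(samples)), samples)
  sam_files <- setNames(file.path(outdir, paste0(samples, ".sam")), samples)

  for (s in samples) {
    mu <- baseline + if (groups[[s]] == "tumor") lfc else 0
    mu <- mu + rnorm(nL, 0, config$noise_sd)
    lambda <- 2^mu * lens * config$reads_per_sample / 1e9
    cnt <- rpois(nL, lambda)
    recs <- character(0)
    rid <- 0L
    for (i in seq_len(nL)) {
      flag <- if (loci$strand[i] == "+") 0L else 16L
      aflag <- if (loci$strand[i] == "+") 16L else 0L
      n_str <- round(config$straddler_fraction * cnt[i])
      n_anti <- round(config$antisense_fraction * cnt[i])
      starts <- if (cnt[i] > 0)
        sample(seq(loci$start[i], loci$end[i] - rl), cnt[i], replace = TRUE)
      else integer(0)
      mk <- function(tag, st, fl) {
        rid <<- rid + 1L
        sq <- substr(genome[[loci$chrom[i]]], st + 1L, st + rl)
        sprintf("%s_%s_%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                tag, loci$locus_id[i], rid, fl, loci$chrom[i], st + 1L, rl, sq)
      }
      recs <- c(recs,
                vapply(starts, function(st) mk("contained", st, flag), ""),
                vapply(rep(loci$start[i] - rl %/% 2L, n_str),
                       function(st) mk("straddle", st, flag), ""),
                vapply(if (n_anti > 0)
                         sample(seq(loci$start[i], loci$end[i] - rl), n_anti,
                                replace = TRUE) else integer(0),
                       function(st) mk("antisense", st, aflag), ""))
      expected[i, s] <- cnt[i]
    }
    totals[s] <- length(recs)
    writeLines(c(header, recs), sam_files[[s]])
  }
  list(sam_files = sam_files, groups = groups, total_mapped_reads = totals,
       expected_counts = expected)
}

#' Simulate a two-group RPKM expression matrix directly
#'
#' The expression-level view of the same generative model used by
#' [simulate_alignments()], without read realization: log2 RPKM =
#' baseline + planted log2FC (tumor) + N(0, noise_sd). Used for
#' differential-recovery studies where read-level detail is irrelevant.
#'
#' @param n_loci number of loci.
#' @param n_normal,n_tumor group sizes.
#' @param fraction_diff fraction of non-null loci.
#' @param planted_log2fc true effect of non-null loci.
#' @param baseline_mean,baseline_sd,noise_sd log2-scale model parameters.
#' @param seed RNG seed.
#' @return list with `expr` (RPKM matrix), `groups`, `true_positive_ids`.
#' @export
simulate_expression_matrix <- function(n_loci = 200L, n_normal = 5L, n_tumor = 5L,
                                       fraction_diff = 0.1, planted_log2fc = 2,
                                       baseline_mean = 5, baseline_sd = 1,
                                       noise_sd = 0.3, seed = 1L) {
  set.seed(seed)
  samples <- c(sprintf("normal_%d", seq_len(n_normal)),
               sprintf("tumor_%d", seq_len(n_tumor)))
  groups <- setNames(rep(c("normal", "tumor"), c(n_normal, n_tumor)), samples)
  ids <- sprintf("locus_%03d", seq_len(n_loci))
  n_diff <- round(fraction_diff * n_loci)
  truth <- sample(ids, n_diff)
  baseline <- rnorm(n_loci, baseline_mean, baseline_sd)
  lfc <- ifelse(ids %in% truth, planted_log2fc, 0)
  mu <- outer(baseline, rep(0, length(samples))) +
    outer(lfc, as.numeric(groups == "tumor"))
  expr <- 2^(mu + matrix(rnorm(n_loci * length(samples), 0, noise_sd),
                         n_loci, length(samples)))
  dimnames(expr) <- list(ids, samples)
  list(expr = expr, groups = groups, true_positive_ids = sort(truth))
}

#' Simulate target-list and DEG fixtures
#'
#' Builds per-site-type target sets with a known three-way common core, two
#' database-style lists with a known intersection, and a DEG table in which
#' a known subset of the common core is down-regulated — so the expected
#' post-filter gene set is fixed by construction (core minus planted downs).
#'
#' @param config a [synthetic_config()].
#' @return list with `targets_by_type`, `db_lists` (two character vectors),
#'   `degs` (gene/log2fc/p_value table) and `expected` (named list:
#'   `common`, `down_in_common`, `final_genes`, `db_common_n`).
#' @export
simulate_target_fixtures <- function(config) {
  set.seed(config$seed + 5L)
  n_universe <- config$n_common_targets + 3L * config$n_type_extra +
    config$n_db_common + 2L * config$n_db_extra + 200L
  universe <- sprintf("GENE%05d", seq_len(n_universe))
  take <- local({
    used <- 0L
    function(n) { out <- universe[used + seq_len(n)]; used <<- used + n; out }
  })
  core <- take(config$n_common_targets)
  extra <- lapply(1:3, function(i) take(config$n_type_extra))
  targets_by_type <- list(
    "8M" = c(core, extra[[1]]),
    "7A1" = c(core, extra[[2]]),
    "7M8" = c(core, extra[[3]]))
  db_core <- take(config$n_db_common)
  db_lists <- list(
    miRDB_like = sample(c(db_core, take(config$n_db_extra))),
    TargetScan_like = sample(c(db_core, take(config$n_db_extra))))
  down <- sort(sample(core, config$n_down_in_common))
  up <- take(40L)
  degs <- data.frame(
    gene = c(down, up),
    log2fc = c(rep(-2.5, length(down)), rep(2.1, length(up))),
    p_value = rep(0.001, length(down) + length(up)),
    stringsAsFactors = FALSE)
  list(targets_by_type = targets_by_type, db_lists = db_lists, degs = degs,
       expected = list(common = sort(core), down_in_common = down,
                       final_genes = sort(setdiff(core, down)),
                       db_common_n = config$n_db_common))
}

# --- file emission --------------------------------------------------------

write_repeats_out <- function(loci, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query            matching       repeat         position in repeat",
    "score   div. del. ins.  sequence  begin  end          (left)   repeat         class/family   begin  end    (left)  ID",
    "")
  rows <- vapply(seq_len(nrow(loci)), function(i) {
    clsfam <- if (loci$rep_class[i] == loci$rep_family[i]) loci$rep_class[i]
      else paste0(loci$rep_class[i], "/", loci$rep_family[i])
    sprintf("%5d %6.1f %4.1f %4.1f  %-8s %6d %6d (%d) %s %-14s %-14s %6d %6d (%d) %d",
            1000L + i, 10.0, 0.5, 0.5, loci$chrom[i],
            loci$start[i] + 1L, loci$end[i], 0L,
            if (loci$strand[i] == "-") "C" else "+",
            loci$rep_name[i], clsfam, 1L, loci$end[i] - loci$start[i], 0L, i)
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

write_repeats_rmsk <- function(loci, path) {
  df <- data.frame(loci$chrom, loci$start, loci$end, loci$strand,
                   loci$rep_name, loci$rep_class, loci$rep_family)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_genes_gtf <- function(genes, path) {
  rows <- sprintf('%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                  genes$chrom, genes$start + 1L, genes$end, genes$strand,
                  genes$gene_id)
  writeLines(rows, path)
  invisible(path)
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Generate the full synthetic corpus on disk
#'
#' Runs every generator stage under one seed and writes: genome FASTA,
#' repeats in both dialects, gene GTF, mature miRNA FASTA, per-sample SAM
#' files, a totals TSV, target-list and DEG fixtures, and a JSON ground-truth
#' manifest. Same seed, same bytes.
#'
#' The designated ceRNA family (the first synthetic miRNA) has
#' `planted_sites_per_type` sites planted on every up-regulated intergenic
#' locus and nowhere else; the remaining families receive one decoy site on
#' a few null loci; all other intergenic LINE/LTR transcript sequences are
#' scrubbed of accidental matches of any tracked family.
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory (created).
#' @return (invisibly) the manifest as an R list; also written to
#'   `manifest.json` in `outdir`.
#' @export
simulate_corpus <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ga <- simulate_genome_annotations(config)
  mirnas <- simulate_mirnas(config)
  fams <- collapse_families(seed_patterns(mirnas))
  cerna_family <- seed_patterns(mirnas[1, , drop = FALSE])$family_key

  # planted fold changes on intergenic LINE/LTR loci
  set.seed(config$seed + 2L)
  inter <- ga$loci[ga$loci$locus_id %in% ga$intergenic_ids, , drop = FALSE]
  n_diff <- max(1L, round(config$fraction_diff * nrow(inter)))
  up_ids <- sort(sample(inter$locus_id, n_diff))
  true_log2fc <- setNames(rep(0, nrow(ga$loci)), ga$loci$locus_id)
  true_log2fc[up_ids] <- config$planted_log2fc

  # site planting: ceRNA family on every up locus; decoys on null loci;
  # every other intergenic locus scrubbed of tracked patterns
  set.seed(config$seed + 3L)
  decoy_fams <- setdiff(fams$family_key, cerna_family)
  null_ids <- setdiff(inter$locus_id, up_ids)
  decoy_plan <- list()
  for (fk in decoy_fams) {
    ids <- sample(null_ids, min(config$n_decoy_loci_per_family, length(null_ids)))
    for (id in ids)
      decoy_plan[[length(decoy_plan) + 1L]] <-
        data.frame(locus_id = id, family_key = fk,
                   site_type = sample(SITE_TYPES, 1L), n = 1L,
                   stringsAsFactors = FALSE)
  }
  decoy_plan <- if (length(decoy_plan)) do.call(rbind, decoy_plan) else NULL
  genome <- as.list(ga$genome)
  site_truth <- list()
  for (id in inter$locus_id) {
    locus <- inter[inter$locus_id == id, ]
    tx <- substr(genome[[locus$chrom]], locus$start + 1L, locus$end)
    if (locus$strand == "-") tx <- revcomp_plain(tx)
    plan <- if (id %in% up_ids) {
      data.frame(family_key = cerna_family,
                 site_type = names(config$planted_sites_per_type),
                 n = as.integer(config$planted_sites_per_type),
                 stringsAsFactors = FALSE)
    } else if (!is.null(decoy_plan) && id %in% decoy_plan$locus_id) {
      decoy_plan[decoy_plan$locus_id == id, c("family_key", "site_type", "n")]
    } else {
      data.frame(family_key = character(0), site_type = character(0),
                 n = integer(0), stringsAsFactors = FALSE)
    }
    res <- scrub_and_plant(tx, plan, fams)
    genome <- write_back_locus(genome, locus, res$sequence)
    if (nrow(res$placements))
      site_truth[[length(site_truth) + 1L]] <-
        cbind(locus_id = id, res$placements, stringsAsFactors = FALSE)
  }
  genome <- unlist(genome)
  site_truth <- if (length(site_truth)) do.call(rbind, site_truth) else
    data.frame(locus_id = character(0), family_key = character(0),
               site_type = character(0), offset = integer(0))

  aln <- simulate_alignments(config, genome, inter, true_log2fc,
                             file.path(outdir, "alignments"))
  tf <- simulate_target_fixtures(config)

  # files
  write_fasta(genome, file.path(outdir, "genome.fa"))
  write_repeats_out(ga$loci, file.path(outdir, "repeats.out"))
  write_repeats_rmsk(ga$loci, file.path(outdir, "repeats_rmsk.tsv"))
  write_genes_gtf(ga$genes, file.path(outdir, "genes.gtf"))
  write_fasta(setNames(as.list(mirnas$sequence), mirnas$name),
              file.path(outdir, "mirnas.fa"))
  write.table(data.frame(sample = names(aln$total_mapped_reads),
                         total_mapped_reads = aln$total_mapped_reads),
              file.path(outdir, "totals.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(tf$db_lists$miRDB_like, file.path(outdir, "targets_dbA.txt"))
  writeLines(tf$db_lists$TargetScan_like, file.path(outdir, "targets_dbB.txt"))
  write.table(tf$degs, file.path(outdir, "degs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(
    config = unclass(config),
    loci = ga$loci,
    genes = ga$genes,
    intergenic_ids = ga$intergenic_ids,
    mirnas = mirnas,
    cerna_family = cerna_family,
    up_locus_ids = up_ids,
    true_log2fc = as.list(true_log2fc),
    planted_sites = site_truth,
    expected_counts = list(
      loci = rownames(aln$expected_counts),
      samples = colnames(aln$expected_counts),
      counts = unname(apply(aln$expected_counts, 2, as.integer, simplify = FALSE))),
    total_mapped_reads = as.list(aln$total_mapped_reads),
    groups = as.list(aln$groups),
    sam_files = as.list(setNames(file.path("alignments",
                                           basename(unlist(aln$sam_files))),
                                 names(aln$sam_files))),
    target_fixtures = tf$expected
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$sam_files <- as.list(aln$sam_files)
  manifest$expected_count_matrix <- aln$expected_counts
  manifest$targets_by_type <- tf$targets_by_type
  manifest$degs <- tf$degs
  invisible(manifest)
}
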