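## Seed-match site prediction on RE transcript sequences.
##
## A mature miRNA's positions 2-8 define its seed family. The three canonical
## site types on a target, written 5'->3' in target DNA, are
##   8mer   : reverse complement of miRNA positions 2-8, followed by 'A'
##   7mer-m8: reverse complement of miRNA positions 2-8
##   7mer-A1: reverse complement of miRNA positions 2-7, followed by 'A'
## The 'A' opposite miRNA position 1 is a literal target adenosine, not a
## complementarity requirement.

SITE_TYPES <- c("8M", "7M8", "7A1")

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Parse a miRBase-style mature miRNA FASTA
#'
#' Keeps records whose name (first whitespace-delimited header token) starts
#' with `species_prefix`; sequences are uppercased and normalized to the RNA
#' alphabet (T -> U).
#'
#' @param path FASTA of mature miRNAs (U or T alphabet).
#' @param species_prefix e.g. `"hsa-"` or `"cfa-"`.
#' @return `data.frame` with columns `name`, `sequence` (RNA, 5'->3').
#' @export
parse_mirna_fasta <- function(path, species_prefix) {
  ss <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  keep <- startsWith(nm, species_prefix)
  if (!any(keep))
    stop("no miRNA with species prefix '", species_prefix, "' in ", path)
  seqs <- chartr("Tt", "Uu", toupper(as.character(ss[keep])))
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("invalid miRNA alphabet in: ", paste(nm[keep][bad], collapse = ", "))
  short <- nchar(seqs) < 8
  if (any(short))
    stop("mature miRNA shorter than 8 nt: ",
         paste(nm[keep][short], collapse = ", "))
  data.frame(name = nm[keep], sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Seed-match site patterns for one or more miRNAs
#'
#' Derives, per miRNA, the family key (DNA transliteration of positions 2-8)
#' and the three site strings searched on target DNA.
#'
#' @param mirnas `data.frame` with `name` and `sequence` (RNA) columns, as
#'   from [parse_mirna_fasta()]; a single named character vector also works.
#' @return `data.frame` with columns `mirna_name`, `family_key`, `site_8m`
#'   (8 nt), `site_7m8` (7 nt, a prefix of `site_8m`), `site_7a1` (7 nt,
#'   `site_8m` minus its first base).
#' @export
seed_patterns <- function(mirnas) {
  if (is.character(mirnas))
    mirnas <- data.frame(name = names(mirnas), sequence = unname(mirnas),
                         stringsAsFactors = FALSE)
  sq <- toupper(mirnas$sequence)
  if (any(nchar(sq) < 8)) stop("mature miRNA shorter than 8 nt")
  seed28 <- chartr("U", "T", substr(sq, 2L, 8L))   # positions 2-8 as DNA
  seed27 <- substr(seed28, 1L, 6L)                 # positions 2-7
  data.frame(
    mirna_name = mirnas$name,
    family_key = seed28,
    site_8m = paste0(revcomp_dna(seed28), "A"),
    site_7m8 = revcomp_dna(seed28),
    site_7a1 = paste0(revcomp_dna(seed27), "A"),
    stringsAsFactors = FALSE
  )
}

#' Collapse miRNAs into seed families
#'
#' miRNAs sharing positions 2-8 form one family (this makes all three site
#' types consistent within a family). The display label is the
#' alphabetically first member with its species prefix, arm suffix (-5p/-3p)
#' and trailing paralog letter trimmed (e.g. hsa-let-7a-5p -> let-7).
#'
#' @param mirnas `data.frame` with `name`/`sequence`, or a [seed_patterns()]
#'   table.
#' @return `data.frame` with one row per family: `family_key`, `label`,
#'   `members` (comma-joined names), plus the three site columns.
#' @export
collapse_families <- function(mirnas) {
  pat <- if ("family_key" %in% names(mirnas)) mirnas else seed_patterns(mirnas)
  if (nrow(pat) == 0) stop("no miRNAs to collapse")
  sp <- split(pat, pat$family_key)
  out <- do.call(rbind, lapply(sp, function(g) {
    first <- sort(g$mirna_name)[1]
    lab <- sub("^[a-z]{2,4}-", "", first)
    lab <- sub("-(5p|3p)$", "", lab)
    lab <- sub("(?<=[0-9])[a-z]+$", "", lab, perl = TRUE)
    data.frame(family_key = g$family_key[1], label = lab,
               members = paste(sort(g$mirna_name), collapse = ","),
               site_8m = g$site_8m[1], site_7m8 = g$site_7m8[1],
               site_7a1 = g$site_7a1[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$family_key), , drop = FALSE]
}

#' Extract RE transcript sequences from a genome FASTA
#'
#' Strand-aware extraction keyed by locus_id: minus-strand loci are
#' reverse-complemented so that every returned sequence reads 5'->3' along
#' the transcribed strand. Soft-masked (lowercase) genome sequence is
#' uppercased.
#'
#' @param genome_fasta path to the genome FASTA, or a named character vector
#'   / `DNAStringSet` of chromosome sequences.
#' @param loci RE locus table.
#' @return named character vector, `locus_id` -> DNA sequence.
#' @export
extract_re_sequences <- function(genome_fasta, loci) {
  chroms <- if (is.character(genome_fasta) && length(genome_fasta) == 1 &&
                file.exists(genome_fasta)) {
    Biostrings::readDNAStringSet(genome_fasta)
  } else {
    Biostrings::DNAStringSet(genome_fasta)
  }
  names(chroms) <- vapply(strsplit(names(chroms), "\\s+"), `[[`, "", 1L)
  miss <- setdiff(unique(loci$chrom), names(chroms))
  if (length(miss)) stop("chromosome(s) absent from FASTA: ",
                         paste(miss, collapse = ", "))
  lens <- Biostrings::width(chroms)[match(loci$chrom, names(chroms))]
  oob <- loci$start < 0 | loci$end > lens
  if (any(oob)) stop("locus outside chromosome bounds: ",
                     paste(loci$locus_id[oob], collapse = ", "))
  seqs <- Biostrings::subseq(chroms[loci$chrom],
                             start = loci$start + 1L, end = loci$end)
  minus <- loci$strand == "-"
  if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  setNames(toupper(as.character(seqs)), loci$locus_id)
}

#' Precompile seed patterns for repeated scanning
#'
#' Builds the Aho-Corasick dictionaries for all three site-pattern sets
#' once. [scan_sites()] accepts either a plain pattern table (compiling on
#' the fly) or this object; precompiling pays off when scanning many
#' sequences against the same miRNA set.
#'
#' @param patterns a [seed_patterns()] or [collapse_families()] table.
#' @return an object of class `compiled_seed_patterns`.
#' @export
compile_seed_patterns <- function(patterns) {
  fams <- unique(patterns[, c("family_key", "site_8m", "site_7m8", "site_7a1")])
  if (nrow(fams) == 0)
    return(structure(list(fams = fams, pd8 = NULL, pd7m8 = NULL,
                          pd7a1 = NULL), class = "compiled_seed_patterns"))
  structure(list(
    fams = fams,
    pd8 = Biostrings::PDict(Biostrings::DNAStringSet(fams$site_8m)),
    pd7m8 = Biostrings::PDict(Biostrings::DNAStringSet(fams$site_7m8)),
    pd7a1 = Biostrings::PDict(Biostrings::DNAStringSet(fams$site_7a1))
  ), class = "compiled_seed_patterns")
}

#' Scan a sequence for seed-match sites of each miRNA family
#'
#' Reports every occurrence of the three site types with a precedence rule
#' that keeps site classes disjoint: an 8mer match at offset p suppresses
#' the 7mer-m8 match at p and the 7mer-A1 match at p+1 that it subsumes
#' (both are substrings of the 8mer window). Matches of distinct families,
#' or non-subsumed windows, are all reported. `N` (or any non-ACGT base)
#' never matches; lowercase input is uppercased before scanning. Output is
#' ordered by offset, then family, then site type.
#'
#' @param sequence a DNA string (the sense RE transcript sequence).
#' @param patterns a [seed_patterns()] / [collapse_families()] table, or a
#'   [compile_seed_patterns()] object; the family identifier used in the
#'   output is `family_key`.
#' @return `data.frame` with columns `mirna_family`, `site_type`
#'   (`8M`/`7M8`/`7A1`) and `offset` (0-based start of the site).
#' @export
scan_sites <- function(sequence, patterns) {
  sequence <- gsub("[^ACGT]", "N", toupper(sequence))
  empty <- data.frame(mirna_family = character(0), site_type = character(0),
                      offset = integer(0), stringsAsFactors = FALSE)
  cp <- if (inherits(patterns, "compiled_seed_patterns")) patterns
    else compile_seed_patterns(patterns)
  fams <- cp$fams
  if (nchar(sequence) < 7 || nrow(fams) == 0) return(empty)
  subj <- Biostrings::DNAString(sequence)
  # all three pattern sets matched in one Aho-Corasick pass each
  hit8 <- if (nchar(sequence) >= 8)
    Biostrings::startIndex(Biostrings::matchPDict(cp$pd8, subj))
  else rep(list(NULL), nrow(fams))
  hit7m8 <- Biostrings::startIndex(Biostrings::matchPDict(cp$pd7m8, subj))
  hit7a1 <- Biostrings::startIndex(Biostrings::matchPDict(cp$pd7a1, subj))
  off <- function(x) if (is.null(x)) integer(0) else x - 1L
  res <- lapply(seq_len(nrow(fams)), function(i) {
    p8 <- off(hit8[[i]])
    p7m8 <- setdiff(off(hit7m8[[i]]), p8)
    p7a1 <- setdiff(off(hit7a1[[i]]), p8 + 1L)
    nn <- c(length(p8), length(p7m8), length(p7a1))
    if (sum(nn) == 0) return(NULL)
    data.frame(
      mirna_family = rep(fams$family_key[i], sum(nn)),
      site_type = rep(SITE_TYPES, nn),
      offset = c(p8, p7m8, p7a1),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[order(out$offset, out$mirna_family,
                   match(out$site_type, SITE_TYPES)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many RE sequences and tabulate sites
#'
#' Runs [scan_sites()] over a set of locus sequences and returns the long
#' site table plus the per-locus x family x type count table consumed by
#' [mre_expression()].
#'
#' @param sequences named character vector (locus_id -> DNA), as from
#'   [extract_re_sequences()].
#' @param patterns seed-pattern table (see [scan_sites()]).
#' @return list with `sites` (locus_id, mirna_family, site_type, offset) and
#'   `site_counts` (locus_id, mirna_family, site_type, n_sites).
#' @export
scan_loci <- function(sequences, patterns) {
  cp <- if (inherits(patterns, "compiled_seed_patterns")) patterns
    else compile_seed_patterns(patterns)
  per <- lapply(names(sequences), function(id) {
    s <- scan_sites(sequences[[id]], cp)
    if (nrow(s)) cbind(locus_id = id, s, stringsAsFactors = FALSE) else NULL
  })
  sites <- do.call(rbind, per)
  if (is.null(sites))
    sites <- data.frame(locus_id = character(0), mirna_family = character(0),
                        site_type = character(0), offset = integer(0),
                        stringsAsFactors = FALSE)
  cnt <- if (nrow(sites)) {
    ag <- aggregate(list(n_sites = sites$offset),
                    by = sites[, c("locus_id", "mirna_family", "site_type")],
                    FUN = length)
    ag[order(ag$locus_id, ag$mirna_family, match(ag$site_type, SITE_TYPES)), ,
       drop = FALSE]
  } else {
    data.frame(locus_id = character(0), mirna_family = character(0),
               site_type = character(0), n_sites = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(cnt) <- NULL
  list(sites = sites, site_counts = cnt)
}
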