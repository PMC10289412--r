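---
title: "Methods: retroelement expression and ceRNA inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retroelement expression and ceRNA inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroceRNA)
```

# The model

`retroceRNA` operationalizes a simple ceRNA (competing endogenous RNA)
hypothesis for retroelements: when LINE or LTR transcripts rise in tumor
tissue, the miRNA seed-match sites they carry (miRNA responsive elements,
MREs) rise with them; if a miRNA's aggregate MRE pool grows enough, that
miRNA is titrated away from its protein-coding targets and those targets
are de-repressed. The pipeline does not model titration stoichiometry — it
quantifies the three measurable layers (RE expression, MRE expression,
target-gene sets) and screens each with explicit thresholds.

## Intergenic filtering

RE read counts are only interpretable where no gene is transcribed across
the same bases on the same strand, so every RE locus with at least 1 bp of
same-strand overlap with a gene *body* (the full gene span, not
exon-resolved) is removed whole — never clipped, because a partial locus
has no meaningful length for RPKM. Two modes exist because two defensible
notions of "intergenic" do: `same_strand` (the default; antisense overlap
is tolerated since such reads are separable by strand-aware counting) and
the stricter `any_strand`. The `any_strand` output is always a subset of
the `same_strand` output, and the suite verifies both against a
brute-force all-pairs overlap check.

Coordinates are 0-based half-open internally; RepeatMasker `.out`
(1-based inclusive, strand `C` = minus) and GTF (1-based inclusive) are
converted on ingest, and BED is read/written natively. This keeps exactly
one convention inside the package and standard dialects at its edges.

## Counting and normalization

An alignment counts toward a locus iff its reference span (from POS and
the reference-consuming CIGAR operations) is fully contained in the locus
and its strand matches. Full containment is deliberately strict: a read
straddling a locus boundary is evidence of a longer transcription unit,
not of the repeat itself. No MAPQ or duplicate filtering is applied, and a
read contained in several (nested) loci counts toward each — the counter
reproduces the raw, unfiltered counting convention rather than imposing a
multi-mapper model (EM reassignment à la TEtranscripts is out of scope).

RPKM = count × 10⁹ / (length_bp × total_mapped_reads), with
total_mapped_reads the number of mapped records in the alignment file.
The size/expression filter keeps loci with length ≥ 200 bp (shorter loci
give unstable RPKM and cannot hold many seed sites) and RPKM ≥ 1 in ≥ 1
sample; all three thresholds are exposed and echoed into output headers.

## Differential screening

The screen is a two-sided Welch two-sample t-test on log2(RPKM + ε), with
fold change log2((mean_tumor + ε)/(mean_normal + ε)) computed on the
expression scale, and a feature called significant iff p < α and
|log2FC| > t (defaults α = 0.05, t = 1). Welch rather than pooled-variance
because tumor groups are routinely more dispersed than normals; ε = 0.25
keeps log2 finite at zero expression while distorting moderate RPKM
little. Raw p-values are the default decision rule (the volcano-style
screen); Benjamini–Hochberg is available behind `adjust = TRUE` as an
extra column. Degenerate rows (both groups constant) get p = 1 when the
means agree and p = 0 otherwise. Tables are sorted by p, then |log2FC|,
then feature id, so output order is total and reproducible.

## Seed-match scanning

For a mature miRNA, positions 2–8 (the seed, extended to 8) define three
site patterns on target DNA, each written 5'→3':

| type | pattern | length |
|------|---------|--------|
| 8mer | revcomp(m2..8) + `A` | 8 |
| 7mer-m8 | revcomp(m2..8) | 7 |
| 7mer-A1 | revcomp(m2..7) + `A` | 7 |

The trailing `A` is a literal target adenosine (recognized by Argonaute),
not complementarity to miRNA position 1. Both 7-mers are substrings of
the 8mer, so every 8mer occurrence trivially contains a 7mer-m8 match at
the same offset and a 7mer-A1 match one base downstream. The scanner
therefore applies a precedence rule — 8mer suppresses exactly those two
subsumed windows — so that one physical site is classified once and the
three type classes partition the site set (their proportions meaningfully
sum to 100%). Non-subsumed overlaps, including self-overlapping matches
of periodic seeds, are all reported. `N` never matches; soft-masked
lowercase is uppercased first.

miRNAs sharing positions 2–8 are collapsed into one family (the maximal
seed any of the three types uses), which makes the three site types
consistent within a family; family labels trim the species prefix, arm
and paralog letter (hsa-let-7a-5p → let-7). Scanning runs on the
strand-aware extracted transcript sequence only — minus-strand loci are
reverse-complemented at extraction, so scanning the reverse complement
again would be double counting.

Matching uses one Aho–Corasick pass per pattern set
(`Biostrings::matchPDict`); `compile_seed_patterns()` lets callers build
the dictionaries once when scanning many sequences. The test suite and
acceptance script hold the scanner to *exact* equality with an
independent window-enumeration oracle (every window compared to every
pattern by substring equality, precedence applied afterwards).

## MRE expression and the weighting choice

An MRE row is a (family × site type) pair. Under the default
`count_weighted` mode its value in a sample is Σ over loci of
site_count × RPKM: an RE carrying three copies of a site contributes
three times the sponge capacity of a single-copy RE at equal expression.
A `presence` mode (each carrying locus contributes its RPKM once) is kept
for sensitivity analysis, because site-count weighting is a modeling
choice, not an observed quantity; the mode used is recorded in the output
provenance. `count_weighted` dominates `presence` cell-wise and is linear
in the RE expression matrix — both properties are tested.

Only differentially expressed RE loci are scanned and aggregated: the
object of interest is the *change* in sponge capacity, and restricting to
the DE set keeps the MRE matrix interpretable as "capacity carried by
REs that moved".

## Target integration

Predicted target lists are consumed as flat files from external databases
(one symbol per line or a TSV column); the package deliberately does not
reimplement target prediction. Symbols are uppercased, trimmed and
de-duplicated; no alias or ortholog mapping is attempted, so
cross-species comparisons assume the caller provides comparable symbol
spaces. After intersecting lists (and/or the three per-site-type sets,
with a full 7-region Venn breakdown), genes that are significantly
*down*-regulated are removed: a gene released from miRNA control should
not fall when its miRNA's sponge rises. Genes absent from the DEG table
are retained — only demonstrably down-regulated genes are excluded.
The gene-level α and fold-change thresholds are configuration inputs.

# The synthetic-data generator

The generator emulates a paired two-group (normal vs tumor) bulk RNA-seq
design at toy scale and is itself first-class, tested code. Defaults, all
overridable in `synthetic_config()`:

* 2 chromosomes × 60 kb; 60 repeat loci of 300–600 bp placed
  non-overlapping, padded by more than one read length from each other
  and the chromosome ends so boundary-straddling reads are unambiguous;
  ~20% of loci from non-LINE/LTR classes to exercise the class filter.
* 20% of loci get a same-strand overlapping gene and 10% an
  opposite-strand one, to exercise both intergenic modes.
* 5 normal vs 5 tumor libraries. Locus baseline log2 RPKM ~ N(5, 1);
  per-locus, per-sample log-normal noise σ = 0.3 (log2 scale); 10% of
  intergenic LINE/LTR loci carry a planted log2FC of +2 (tumor
  up-regulation). Expected counts come from the RPKM identity at a
  nominal library size and are realized as Poisson draws; the realized
  counts are written to the manifest, making read counting exactly
  checkable. Per locus, 10% extra boundary-straddling and 10% antisense
  reads are emitted and labeled — a correct counter must ignore them.
* 5 synthetic miRNAs with pairwise distinct, non-nested seed patterns
  (no family's 7-mer occurs inside another's 8-mer, and no seed is
  shift-periodic). This makes planted-truth bookkeeping exact: the first
  family (the designated ceRNA) receives 2 planted sites per type on
  every up-regulated locus, decoy families get single sites on null
  loci, and every other intergenic transcript is scrubbed — by bounded
  rejection sampling with guard bases around planted 7-mers so they are
  never accidentally promoted to 8mers — until no tracked pattern occurs
  anywhere unplanned.
* Target fixtures: three per-type target sets with a 99-gene common
  core of which 5 are down-regulated DEGs (so the post-filter answer is
  94 by construction), and two database-style lists sharing 317 genes.

Everything is a pure function of one integer seed (same seed, same
bytes), and the JSON manifest predicts — without running the pipeline —
the exact outcome of class filtering, intergenic filtering, read
counting, site scanning, type proportions and target filtering.

What the generator does *not* emulate: real transposon sequence
divergence and families of homologous copies (each locus is independent
random background), multi-mapping ambiguity between paralogous loci,
spliced or gapped alignments, GC/length biases, and library-size
imbalance beyond Poisson fluctuation. Passing the recovery tests
therefore demonstrates correctness of the pipeline's logic and its
statistical behavior under the stated generative model — not robustness
to alignment ambiguity, which real repeat data exhibit and which the
strict containment rule only partially mitigates.

# Problem sizes and numerical choices

The validation suite uses: 1,000 random 1 kb sequences × 50 random
miRNAs for scanner–oracle equivalence; a planting grid of 3 families ×
3 types × n ∈ {0, 1, 3, 10} on 700 bp sequences; one full corpus for the
exact counting/filtering checks; 100 seeded replicates of the 200-locus
expression design for sensitivity/false-positive estimation; and 100
seeded full corpus-plus-pipeline runs for end-to-end ceRNA recovery.
These sizes give stable Monte-Carlo estimates in a few minutes on one
CPU while exercising every code path.

Numerical details worth knowing:

* Ties in differential tables are broken by |log2FC| then feature id;
  `top_k` breaks effect-size ties by p then id. No ordering is left to
  the platform sort.
* The scrub-and-plant rejection loop mutates one base per iteration,
  re-scans, and errors after a bounded number of iterations (or when a
  site cannot be placed); guard bases adjacent to planted 7-mers are
  mutable only within their own constraint.
* `extract_re_sequences` refuses out-of-bounds loci by name, and the
  scanner maps any non-ACGT character to `N`, which matches nothing.
* The pipeline has no internal randomness: identical config and inputs
  produce byte-identical stamped outputs (the config hash in each header
  excludes only the output directory).

# Known limitations

* RPKM is the implemented normalization; no TMM/DESeq-style size factors
  and no RSEM-style expectation over multi-mappers.
* The screen uses per-feature Welch tests, not a shrinkage model
  (limma/DESeq2); with n = 5 + 5 and planted 4-fold effects this is
  ample, but for subtle effects a moderated test would be preferable.
* Seed matching ignores thermodynamic context, 3'-supplementary pairing,
  6mer/offset sites and site accessibility.
* Cross-species target integration is symbol-based; no ortholog mapping.
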