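---
title: "Methods: peroxiredoxin family characterization with prxfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peroxiredoxin family characterization with prxfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prxfam)
```

prxfam implements the analysis pipeline used to characterize a plant
peroxiredoxin (PRX) gene family end to end. This vignette documents the
models, the parameters, and the design decisions behind every module, and
shows each step on synthetic data with planted ground truth.

## Coordinates and data model

All genomic intervals are **1-based inclusive** `IRanges`, the native
convention of the R/Bioconductor ecosystem and of GFF3, so nothing is
converted at file boundaries. A `GeneModel` is an exon chain on one strand
of a contig (ascending genomic order, non-overlapping) plus an optional CDS
annotation; a `TranscriptModel` adds a transcript id, parent gene and
provenance. Transcription order is always derived from the strand, never
stored.

## Subfamily classification from the active site

Plant PRXs fall into six subfamilies (2-CysPRX, 1-CysPRX, PRXQ, PRXIIB,
PRXIIE, PRXIIF) distinguishable from the conserved active-site profile
alone. The classifier proceeds in three steps:

1. **Core detection.** The earliest match of `P-x-x-x-T-x-x-C` marks the
   catalytic core; the cysteine at pattern position 8 is the peroxidatic
   cysteine (Cys~P~). The downstream conserved S and aromatic W/F are
   recorded as evidence only, never used as a filter.
2. **Resolving cysteine.** The nearest downstream cysteine whose spacing
   (residues strictly between the two cysteines) is exactly 4 or exactly 24
   (each widenable by `spacing_slack`) is the candidate resolving cysteine
   (Cys~R~).
3. **Rules, in order.** Spacing 4 → PRXQ. Spacing 24 → PRXIIE or PRXIIF if
   the respective type-II diagnostic submotif matches (they differ at the
   position after Cys~P~, S vs A; ties by mismatch count, then PRXIIE),
   else PRXIIB. Otherwise, Cys~P~ inside the 2-Cys diagnostic context plus
   a distal cysteine in an `EVCP` context in the C-terminal third → 2-CysPRX.
   No resolving cysteine at all → 1-CysPRX; if the sequence still carries
   the PRXIIB context but valine at the resolving position, the call is
   annotated `reclassified_from = "PRXIIB"` — the single-substitution
   C→V pseudo-1-Cys case.

Diagnostic submotifs tolerate up to `max_mismatch` (default 2) mismatches,
but never at the catalytic residue itself. The rule order matters: the
C→V check must live *inside* the no-resolving-cysteine branch, otherwise
the plain 1-Cys rule would shadow it.

```{r classify}
sim <- gen_proteins(sim_config(seed = 7, include_reclassified = TRUE))
classify_proteins(sim$proteins)[, c("id", "label", "spacing", "reclassified_from")]
```

## Physicochemical properties

Molecular weight is the sum of ExPASy average residue masses plus one
water. The theoretical pI solves `net_charge(pH) = 0` by bisection on
[0, 14] (tolerance 1e-4); the Henderson–Hasselbalch net charge uses a
Bjellqvist-style pKa set (N-terminus 7.5, C-terminus 3.55; side chains D
4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0). The charge curve is
strictly decreasing in pH, so the root is unique; the test suite checks the
bisection against a 0.001-step grid search.

## Gene structure

`intron_count` is exons minus one; `exon_intron_table` interleaves exons
and introns in transcription order with intron *phase* defined as the
cumulative CDS bases upstream of the intron modulo 3 (UTR bases excluded,
GFF3 semantics). `utr_intron_before_tis` flags genes whose intron lies
wholly 5' of the translation initiation site — a hallmark of one gene in
the family whose first exon is pure 5'UTR.

## Ka/Ks and divergence dating

Duplicate pairs are compared with the Nei–Gojobori (1986) method:

- **Sites.** Each codon position contributes its fraction of synonymous
  one-step changes under the standard genetic code; changes to stop codons
  are excluded from the denominator. Site counts of the two sequences are
  averaged.
- **Differences.** Codons differing at multiple positions are averaged over
  all orderings of single-base substitution pathways; pathways through stop
  codons are excluded (with a fallback to all pathways when none is
  stop-free).
- **Correction.** Proportions are Jukes–Cantor corrected,
  d = −(3/4)·ln(1 − (4/3)·p); p ≥ 3/4 is a saturation error naming the
  site class.

Coding sequences are aligned at the protein level
(`Biostrings::pairwiseAlignment`, BLOSUM62, linear gap penalty of 8 per
residue) and back-threaded to codons; gapped codon columns are excluded.
Divergence time is T = Ks/(2λ) with λ = 1.5e-8 synonymous substitutions
per site per year (dicots), reported in MYA. For example, Ks = 0.03 dates
a duplication to `r divergence_time(0.03)` MYA.

```{r kaks}
dup <- gen_duplicate_pairs(sim_config(seed = 5), n_pairs = 2)
kaks_table(dup$pairs, dup$cds)
```

## Promoter cis-element scanning

Promoters are the 2500 bases 5' of the translation initiation site in
transcription orientation (reverse complemented for minus-strand genes).
Scanning uses IUPAC-aware exact matching: degenerate codes in the
consensus expand, promoter bases are literal, and an `N` in the promoter
matches nothing. Both strands are scanned (the minus strand via the
reverse-complemented consensus), hits are reported at promoter-forward
offsets, and output order is deterministic (offset, then element name).
The packaged catalogue carries 28 elements in three classes (9 abiotic
stress, 10 hormone response, 9 growth/development) and is plain replaceable
data, not code.

## qPCR fold changes

The three-step 2^−ΔCt procedure: per replicate
ΔCt1 = Ct(target) − Ct(reference); ΔCt2 compares stress ΔCt1 against the
**mean control ΔCt1 at 0 h** of the same gene; the fold change is 2^−ΔCt2,
with mean and SD taken over replicate-level fold changes. The generator
inverts the arithmetic to plant fold changes exactly at zero noise.

## Alternative splicing

`classify_events` compares an alternative transcript's exon chain against
the reference model and emits typed events in transcription order: IR
(reference intron untouched inside an alternative exon), A5SS/A3SS (donor
or acceptor shift of a replaced intron, acceptor meaning the 3' end in
transcription orientation), ES (reference exons inside one alternative
intron), and AFE/ALE (a *disjoint* alternative terminal exon with the rest
identical). Two deliberate conventions:

- A pure retention of one intron end is reported as A5SS/A3SS with
  `alias = "partial-IR"`, the vocabulary commonly used for terminal
  intron-fragment retentions in splicing tables.
- A terminal exon that merely shifts a splice boundary still overlaps its
  reference counterpart and is classified as a boundary shift, not
  AFE/ALE; only disjoint terminal exons qualify. This resolves the
  ambiguity when a boundary shift happens at the first or last intron.

Junction strings are the donor/acceptor dinucleotides of the spliced (for
IR: retained) intron; canonical means `GT..AG`. ORF detection scans all
ATGs and reports the longest ATG→stop frame, length **excluding** the stop
codon, so protein length is exactly orf_bp/3.

```{r as}
loc <- gen_ghprx14_locus(seed = 1)
classify_events(loc$gene, loc$as3)
orf_and_translate(transcript_sequence(loc$genome, loc$as3))[c("orf_bp", "protein_aa")]
```

## The packaged splice-variant locus

`gen_ghprx14_locus` rebuilds a five-exon gene whose splice-variant
arithmetic is pinned: exon lengths 190/90/104/90/171 bp, a 597-bp reference
ORF (199 aa), a 45-bp 3'UTR. Retaining the 3'-terminal 15 bases of intron 1
extends the ORF to 612 bp (204 aa); skipping exons 2–4 (284 bp, a
non-multiple of 3 made frame-neutral by the additional 14-base retention of
intron 4) yields 327 bp (109 aa). The retained segments end in `AG`
(acceptor side), and intron 1 deliberately carries an `AG` donor so the
alternative junctions are non-canonical. The generator's background is
ATG-free beyond position 1, so the designed frame provably holds the
longest ORF — verified at build time by running the package's own ORF
detector on all three transcripts.

## Synthetic data: scope and limits

All generators are seed-deterministic (same configuration, byte-identical
output) and emit truth tables consumed by round-trip tests:

- `gen_proteins` plants each subfamily's core, spacing and diagnostics in
  a background **free of C and P**, which makes the planted sites provably
  the only matches for any draw — realism is deliberately sacrificed for
  decidability.
- `gen_locus` builds one gene per subfamily (family-table exon counts), a
  5'UTR-intron gene, and the splice locus, with catalogue elements planted
  at recorded promoter offsets.
- `gen_duplicate_pairs` applies exact counts of class-verified synonymous
  and nonsynonymous single-base substitutions (one per touched codon).
- `gen_ct_table` inverts the qPCR arithmetic, with optional Gaussian
  replicate noise.

Non-goals: no codon-usage model, no indel process, no rate heterogeneity —
the generators exercise the analyses, they do not simulate evolution.
Typical problem sizes are small (tens of genes, kilobase contigs,
200-codon CDS pairs); everything runs in seconds on one CPU.
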