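---
title: "Classifying PARP-14- and ART-dependent transcription from RNA Pol II ChIP-seq: methods and design notes"
author: "polpool authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polpool methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the question

In Th2 (type-2 T helper) cells, PARP-14 (ARTD8) acts as a transcriptional
cofactor of STAT6, and its ADP-ribosyltransferase (ART) catalytic activity
can be blocked pharmacologically with the pan-PARP inhibitor PJ34.  Active
transcription of every gene is read out as the *average peak value*: the
normalized density of RNA polymerase II (phospho-Ser2) ChIP-seq tags over
the gene, measured in four samples — wild type (`WT`),
Parp14-knockout (`KO`), and each genotype treated with PJ34 (`WT_PJ34`,
`KO_PJ34`) — plus an input-chromatin control (`INPUT`).  Alongside the
peak values, a SICER peak-caller run per sample marks which genes carry a
statistically significant island of Pol II enrichment.

polpool implements the downstream analysis of such a design: a nested
fold-change decision tree that classifies every gene's dependence on
PARP-14 and on ART activity, followed by gene-set enrichment, DNA-motif
discovery and scanning, and gene-list overlap analysis.  There is no
statistical test inside the classifier — it is a deterministic decision
tree over peak-value ratios, which is why exact recovery of planted
labels (below) is a meaningful end-to-end check.

## The decision tree

Let $p_s(g)$ be gene $g$'s average peak value in sample $s$.

**Pool 1 (active transcription).**  Keep $g$ iff

$$\Big[\max_s p_s(g) > 0.5 \;\lor\; \max_s p_s(g) > p_{\mathrm{INPUT}}(g)\Big]
  \;\land\; \big[\text{SICER significant in} \ge 1 \text{ sample}\big],$$

with the maximum over the four non-input samples.  "Above" is strict.
Genes never analyzed by the peak caller carry all-FALSE flags and drop
out through the second clause.

**Pool 2 (PARP-14 dependent), with sign.**  With
$r = p_{WT}/p_{KO}$:

* *positive* if $r > 1.4$, or $r \in (1.2, 1.4)$ while
  $\max(p_{WT}, p_{KO}) > 2$;
* *negative* if $r < 0.7$, or $r \in (0.7, 0.83)$ while
  $\max(p_{WT}, p_{KO}) > 2$;
* *none* otherwise.

The band clauses rescue strongly transcribed genes whose ratio is
attenuated; the peak condition applies to either sample.  A positive
call additionally requires the SICER flag of the WT sample (the sample
with the higher signal), a negative call the KO flag.

**Pools 3/4 (ART dependence)** split Pool 2 on
$p_{WT}/p_{WT+PJ34}$: inside the closed no-change band $[0.83, 1.2]$
means ART-independent (Pool 4), outside means ART-dependent (Pool 3).
**Pools 5/6** split Pool 3 the same way on $p_{KO}/p_{KO+PJ34}$: no
change in the knockout means only PARP-14's own ART activity was in
play (Pool 5); a residual PJ34 effect without PARP-14 implicates other
PARP enzymes (Pool 6).  The ART classifications are only ever computed
for Pool 2 genes — the pools are nested by construction, so
$|P_3|+|P_4|=|P_2|$, $|P_5|+|P_6|=|P_3|$, and
$\#\mathrm{pos}+\#\mathrm{neg}=|P_2|$ hold for any input (and are
asserted by the test suite on random tables).

### Numerical choices

* **Band endpoints.**  The source thresholds are quoted as ranges
  (1.2–1.4, 0.7–0.83, 0.83–1.2) without endpoint semantics.  polpool
  makes the no-change band closed and dominant: a ratio of exactly 1.2
  or 0.83 is "no change", the rescue bands are open intervals, and the
  unconditional thresholds are strict.  Only exact floating-point ties
  are affected; the choice is regression-tested with ratios constructed
  to be exactly representable.
* **Zero denominators.**  Ratios are $(p_1 + c)/(p_2 + c)$ with
  $c = 0.01$ applied only when the denominator is zero, keeping ratios
  finite and strictly positive.  The value is configurable
  (`classifier_config(pseudocount=)`); zero peaks are rare in real
  tables because Pool 1 filters unexpressed genes first.
* **Order of operations.**  The SICER verification of the
  higher-signal sample is applied after the band rescue, i.e. to every
  provisional positive/negative call.

All thresholds surface in `active_filter_config()` and
`classifier_config()` with the values above as defaults; they are
dimensionless ratios and peak values on the normalized tag-density
scale.

## Enrichment statistics

`gene_set_enrichment()` produces a pathway-table-shaped report.  The urn
construction follows the ZOOPS enrichment convention used by promoter
motif tools: the population is *target ∪ background*, the sample is the
target list, and `hypergeom_upper_tail(k, n, K, N)` is
$P[X \ge k]$ for $X \sim \mathrm{Hypergeom}(N, K, n)$ — computed via
`stats::phyper`, whose log-space internals are numerically stable, and
cross-checked in the test suite against an independent
binomial-coefficient enumeration over every instance with $N \le 30$
(~87,000 evaluations, maximal relative error below $10^{-10}$).  A
binomial alternative (`method = "binomial"`, background hit-rate as the
success probability) is offered behind a switch.  The background must be
the *unregulated* genes, not the whole universe — the function refuses
overlapping lists.

Because the published table legend is ambiguous about its percentage
denominator, the report emits both candidates: `percent_target`
(pathway hits as a share of the regulated list) and `percent_of_set`
(share of the pathway regulated).  Multiple-testing correction is
Benjamini–Hochberg (`stats::p.adjust`), the adjustment named in the
published table.

## Motif machinery

**Scanning** (`scan_sequence`) is plain Hamming matching: a motif of
length $k$ with a mismatch budget $m$ hits every offset where the window
differs in at most $m$ positions.  `N` bases match nothing (they always
count as mismatches); motifs may not contain `N`.  The default budgets
are the published validation budgets: $\le 1$ for the 10-mer
(TCCAAGGATC) and $\le 2$ for the 12-mer (CACTGAGTGGAG).  Both strands
are scanned by default for locus work (the source never fixes a strand);
`both_strands = FALSE` gives the strictest reading and is what the
pull-down probe checks use, since those probes are printed 5'→3' with
the motif on the given strand.  The scanner is cross-checked against
`Biostrings::matchPattern` and a naive per-offset oracle.

**Promoter windows** are strand-aware: 1000 bases upstream to 100
downstream of the TSS (1100 total), reverse-complemented for minus-strand
genes so every promoter reads 5'→3' of its gene.  Locus scans cover the
gene body ±10 kb by default.  Windows clip at contig edges with a
warning.  All coordinates are 0-based half-open (BED convention)
internally; 1-based inputs convert at the reader boundary.

**De novo discovery** (`denovo_discover`) is a simplified exhaustive
k-mer search, not a PWM optimizer: every k-mer present in the target
promoters is a candidate; each is ZOOPS-counted (zero or one occurrence
per sequence) in targets and background allowing `max_mm` mismatches
(an Rcpp core enumerates the mismatch neighbourhood against a k-mer
postings index); candidates are scored with the upper-tail
hypergeometric and BH-corrected *across all candidates*.  A candidate is
reported when its target/background fold enrichment reaches 3.5 — the
published cut — **and** its BH value is at most 0.05.  The q-threshold
is a deliberate addition: with $\sim 2 \times 10^5$ candidates, tiny-count
flukes (2 target hits vs 1 background hit is "4-fold") routinely exceed
any fold cut, so fold alone selects noise; the reference tool likewise
reports hypergeometrically ranked motifs to which the fold rule is then
applied.

Counting is forward-strand on the promoter-local sequences (promoters
are already gene-oriented); the synthetic generator plants motifs in
promoter orientation accordingly.

Two structural details matter for correctness:

* **Low-complexity rejection** (`repeat_filter`): motifs that are
  tandem repeats of a unit of length ≤ 3 covering ≥ 80% of the word, or
  with mononucleotide Shannon entropy < 1 bit, are dropped as repeat
  false positives — the same pruning the published analysis applied by
  hand.  Both validated binding motifs survive this filter; `AAAAAAAAAA`
  and `ACACACACAC` do not.
* **Redundancy collapsing.**  Under a mismatch budget, a strong motif
  drags a cloud of relatives through any filter: its Hamming
  neighbours, and *frame shifts* — a 1-base shift of a planted 10-mer
  matches every planted site within 1 mismatch, because the overhanging
  base is absorbed by the budget.  Which relative scores best is then
  sampling noise.  Two words that can match the same occurrence within
  $m$ mismatches differ by at most $2m$ in a shift-aware Hamming metric
  (triangle inequality), so survivors are greedily clustered at radius
  $2m$ in order of increasing p-value, and each cluster reports its
  consensus member: the word with the highest exact-match ZOOPS count.
  This reliably returns the planted word itself rather than an
  arbitrary member of its halo.

## The synthetic data generator

`simulate_peak_table()` emulates the statistical structure the
classifier assumes, with known truth:

* **Classes.**  Each gene draws one of eight labels — inactive,
  no-change, or one of Pools 4/5/6 × {positive, negative}.  Default
  proportions reproduce the published study-scale instance (25,677
  genes, of which 8,062 active, 2,744 dependent split 1,647/756/341,
  with a 2,314:430 sign ratio applied uniformly across pools, since no
  sign-by-pool cross-tabulation is published).
* **Peaks.**  The higher-signal sample draws a log-normal baseline
  (median ≈ 1.5, log-sd 0.6 — positive and right-skewed like tag
  densities; the distribution itself is a modelling choice, nothing in
  the source constrains it), floored at $0.5 \times$ margin so the
  active filter is cleared.  The other conditions are set by dividing
  out planted ratios that clear every relevant threshold by the
  multiplicative `effect_margin` (default 1.2): e.g. a Pool-5-positive
  gene gets $WT/KO = 1.4 \times 1.2$, $WT/WT{+}PJ34 = 1.2 \times 1.2$
  (outside the band), $KO/KO{+}PJ34 = 1$ (inside).
* **Noise.**  Each condition is multiplied by log-normal noise clamped
  at two standard deviations (default `noise_sd = 0.02`).  A ratio of
  two noised values moves by at most $e^{4\sigma}$, so whenever
  $e^{4\sigma} <$ margin no planted ratio can cross a threshold and
  classifier recovery is *exact by construction* — the configuration
  warns when a parameter choice breaks this guarantee, and the test
  suite confirms both regimes (100% recovery at margin 1.2, degraded
  recovery at margin 1.02).
* **Inactive genes** get sub-threshold peaks, an input level above
  their signal, and all-FALSE SICER flags, failing every keep-clause
  independently; active genes carry TRUE flags.
* **Motif planting.**  `simulate_genome_with_motifs()` lays one gene
  per contig on i.i.d. uniform ACGT sequence, with random strands, and
  plants one copy of the configured motif in the promoter window of
  positively regulated Pool 2 genes at rate 0.4 and of all other genes
  at rate 0.05 (the design used for the discovery checks: one third
  targets, two thirds unregulated background).  Plant offsets, genomic
  coordinates and strands are recorded in the truth table.

What the generator does **not** emulate: read-level sampling noise,
fragment-size and mappability artifacts, GC or CpG composition of real
promoters (the background is uniform), correlated replicates, or
realistic gene-length and expression distributions.  Passing the
recovery tests therefore demonstrates the correctness of the decision
logic and the discovery machinery, not their robustness to the
composition biases of real chromatin data — on real promoters a
GC-matched background would be the appropriate control, and is out of
scope here.

A single integer seed drives every draw; the genome generator uses a
deterministic sub-stream (seed + 7919) so peak tables and genomes can
be generated independently yet reproducibly.  The generator restores
the caller's RNG state on exit.

## Problem sizes

The shipped analyses and checks run at desk scale, chosen to keep the
full suite fast while leaving every rate estimable: 5,000-gene peak
tables for the workflow scripts (25,677 — the study scale — in the
acceptance script), 1,000 genes for the exactness check, 600 promoters
(≈ 200 targets / 400 background) for discovery, a 20-run null ensemble
for the false-positive control, and the complete $N \le 30$ grid
(~87,000 instances) for the hypergeometric oracle.

## Limitations

* The published gene counts (8,062; 2,744; …) can only be reproduced
  exactly from the authors' per-gene supplementary tables, which are
  third-party data not shipped here; the acceptance machinery instead
  verifies the identities those counts satisfy and the classifier's
  exactness on planted data at the same scale and proportions.
  Boundary genes could additionally differ with the deposited rounding
  of peak values.
* De novo discovery is exhaustive over literal k-mers: it cannot
  represent degenerate positions within a motif (PWMs), and its runtime
  grows with $4^{\,\text{neighbourhood}}$, which is why budgets are
  capped at 2 mismatches.
* The external-regulator overlap ingests gene lists as given; it does
  not re-derive them from expression data, and identifier matching is
  by case-folded symbol (plus an optional alias table), not by a full
  orthology/alias service.
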