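---
title: "Designing and validating genus-specific 16S rRNA qPCR primers with genusprimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating genus-specific 16S rRNA qPCR primers with genusprimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genusprimer)
```

## The problem

Amplicon sequencing with universal 16S rRNA primers yields *relative*
abundances, and universal primers do not cover every species of every
genus, so the picture of a microbial community can be biased. A
complementary strategy is to design qPCR primers that are specific to one
bacterial genus, exploiting the hypervariable regions of the 16S gene,
and to quantify absolute 16S copy numbers per sample. `genusprimer`
implements that workflow end to end: candidate degenerate primer
enumeration from a labelled alignment, thermodynamic screening, in silico
PCR validation of coverage and specificity, qPCR standard-curve
quantification, and rank-correlation concordance between qPCR copy
numbers and metagenomic relative abundances. The package ships a
transcribed, wet-lab-validated 11-genus panel for fish-aquaculture
microbiomes (genera such as *Pseudomonas*, *Colwellia*, *Polaribacter*,
*Psychrobium*) as a fixture and worked example.

## The design model

Input is a multiple sequence alignment of 16S sequences with a genus
label per sequence (unlabelled sequences are retained as background —
specificity is screened against everything that is not the target). For
a target genus the per-column base frequencies of the target and
background sets form a `conservation_profile`. Every alignment window of
length 17–25 nt is a candidate:

* **Consensus.** Per column, the minimal IUPAC code covering all target
  bases with frequency at least the consensus floor (default 0.05). The
  floor keeps sequencing-noise singletons in large sets from inflating
  degeneracy; with small target sets (≤ 20 sequences) every observed base
  exceeds it, so the consensus covers the whole set. Windows overlapping
  a majority-gap column are rejected.
* **Degeneracy cap** (default 8): the product of per-column code sizes,
  i.e. how many concrete oligos the degenerate primer mixes.
* **Coverage**: the fraction of target sequences matched exactly by the
  consensus over the window (default minimum 0.8).
* **Specificity**: no background sequence may contain an exact
  (0-mismatch) site for the candidate (default background match fraction
  0). A cheap in-place screen at the homologous alignment columns rejects
  conserved windows immediately; survivors get a full off-site scan.
* **Thermodynamics**: hairpin and self-dimer ΔG at 37 °C must stay above
  −9 kcal/mol; GC content 50–55 % and the GC clamp are *soft* criteria by
  default (they penalize the ranking score rather than reject — the
  shipped validated panel itself contains primers outside the GC window,
  e.g. 61 % GC, so hard enforcement would be self-defeating; a config
  switch makes it hard).

Survivors are ranked by `w1*coverage − w2*background_fraction −
w3*soft_violations` (defaults 1, 1, 0.2). The published workflow this
formalizes designed primers manually for "maximum species coverage with
maximum specificity"; the weighted score is this package's own
formalization of that trade-off, and the weights are configuration, not
biology. Forward/reverse candidates are then paired: a pair is kept when,
on every covered template, the forward site lies upstream and the
product length — measured on the *gap-stripped* template from the first
base of the forward footprint to the last base of the reverse footprint
— falls in the inclusive 85–250 bp window. Pair coverage is re-measured
by in silico PCR rather than inferred from the single-primer coverages.

Because the full scan is exhaustive over windows, two performance valves
bound the expensive steps deterministically: thermodynamic evaluation and
off-site scanning walk the cheap-filter survivors in provisional order
(coverage descending, then leftmost, then shortest) until a per-region
candidate cap is filled, and pairing evaluates forward×reverse
combinations only when their alignment-coordinate span can plausibly
yield an in-range amplicon (±30 columns of indel slack). Raising
`max_candidates` recovers the exhaustive search on small alignments.

## Coordinates

All intervals are 1-based and closed, the R/Bioconductor convention, and
reverse-strand features are stored by their interval on the forward
strand plus an orientation flag. Amplicon length is therefore
`rv_end − fw_start + 1`, inclusive of both primer footprints — matching
how validated amplicon sizes are reported for the shipped panel (e.g.
the *Polaribacter* pair's 85 bp product of which 40 bp are the two
footprints).

## In silico PCR

`primer_matches()` reports every site where a primer aligns with at most
`max_mismatches` mismatches and **zero** mismatches in the 3'-terminal
exact zone (default 5 nt) — the strict TestPrime-style default, since
polymerase extension is far more sensitive to 3' mismatches. Reverse
primers are matched as their reverse complement on the forward strand,
so their 3' zone faces upstream. A degenerate primer code matches a
template base contained in its set; a degenerate *template* base counts
as a mismatch by default (reference 16S databases hold concrete bases
almost everywhere) with a flag to switch to set-intersection matching.
`simulate_pair()` combines forward and reverse sites into products,
guarded to 50–2000 bp against pathological pairings; a template with
several products counts as amplified once. `filter_min_length()`
reproduces the common "≥ 900 bp reference sequences only" preprocessing
(inclusive boundary), and `compare_primer_sets()` gives the
head-to-head 2×2 contingency (both / a-only / b-only / neither) used to
compare a genus-specific pair against universal primers.

## Thermodynamics

Melting temperatures use unified DNA/DNA nearest-neighbor parameters
(per-stack ΔH/ΔS, duplex initiation split by terminal base pair,
self-complementarity entropy correction) with the entropy-based
monovalent salt correction `0.368·(N−1)·ln[Na+]`, at 50 mM Na⁺ and
200 nM total strand concentration (CT/4 for non-self-complementary
duplexes) by default — the concentrations of the validated qPCR
protocol. Dimer ΔG is the most negative sum of stack ΔG₃₇ over
contiguous complementary runs across all ungapped antiparallel offsets
of the two oligos; hairpin ΔG enumerates all stem ≥ 3 bp / loop ≥ 3 nt
decompositions, scoring stem stacks plus a tabulated loop-initiation
penalty interpolated between published anchors and capped at the
30-nt value. The −9 kcal/mol screening threshold is stated without a
unit in the oligo-calculator convention it descends from; kcal/mol at
37 °C is that convention. Degenerate primers are scored pessimistically
(minimum Tm, most negative ΔG over expansions): the worst oligo in a
synthesis mix is the one that forms artefacts. Primers containing N are
rejected outright — their expansion is unbounded for screening purposes.
ΔG and Tm values are pinned in the test-suite by independent
hand-summation and brute-force-enumeration oracles, not by any external
engine; the config records a method tag so cross-validation against
other engines stays a test concern, not a dependency.

## qPCR quantification

`fit_standard_curve()` is ordinary least squares of Cq on log₁₀ copies
over a dilution series (the conventional 10²–10⁷ six-level series; at
least three distinct levels are required). Replicates are averaged per
level by default. Efficiency uses the universal convention
`E% = 100·(10^(−1/slope) − 1)`, so the textbook slope −3.3219
(= −1/log₁₀2) is 100 %, and `efficiency_qc()` checks the inclusive
92–105.5 % acceptance band within which all primers of the shipped panel
fall. Copy number inverts the curve; no correction for 16S operon copies
per genome is applied — concordance compares raw 16S copy number with
relative abundance, which is a documented caveat, not an oversight.
`spearman_rho()` is mid-rank Pearson correlation (ties averaged);
significance testing is out of scope. `concordance()` inner-joins the
qPCR and metagenomic tables per genus on sample id (requiring ≥ 3 shared
samples) and offers the copies either raw or converted to per-sample
percentages (`value = "percent"`), since either convention appears in
practice.

## The synthetic family generator

Real reference alignments are large, versioned downloads; the test-bed
instead generates 16S-like families with known ground truth. A random
conserved backbone (default 1200 bp) carries, per genus, a block of two
signature windows of 18–25 nt. Every genus owns a private variant of
*every* signature window, derived from the backbone at the background
divergence rate (default 0.25/site), so target and background differ in
signature regions and nowhere else — the caricature of conserved
16S stretches flanking hypervariable regions. Within-genus point
mutations (default 0.01/site) and rare indels (default 0.002/site,
confined to non-signature regions) add realistic noise while keeping an
exact, by-construction alignment; no aligner is involved. The two
windows of a block are separated so the block spans a value inside the
amplicon window, sampled 10 bp away from the edges so per-template indel
drift between the windows cannot push every product out of range.
Defaults (3 genera × 10 sequences) are the package's standing test
conditions.

What the generator does *not* emulate: phylogenetic correlation between
genera, gamma rate variation across sites, chimeras, or alignment error.
Passing the recovery tests therefore shows the search is correct under
its own model assumptions, not that it will find primers in any real
genus — real 16S families can lack a window that separates a genus from
its relatives at 0 mismatches, which is exactly the failure mode the
rejection tallies report.

## Numerical and degenerate-input choices

* Ties in candidate ranking break deterministically: leftmost window,
  forward before reverse, shortest primer. Reruns are byte-identical.
* `window_consensus()` failures return `NA` with a machine-readable
  `reason` attribute (`majority_gap`, `degeneracy`,
  `no_base_above_floor`) and design failures carry per-filter rejection
  tallies, so "no primer found" is always diagnosable.
* An empty background makes specificity vacuous: the profile flags it
  and every candidate passes the background screen.
* Constant vectors have no rank correlation: `spearman_rho()` returns
  `NA` with a warning, never 0.
* A non-negative standard-curve slope marks the curve invalid;
  copy-number inversion refuses it.
* The generator snapshots and restores the caller's RNG state, so
  seeded pipelines that call it mid-stream stay reproducible.

## Problem sizes used by the checks

The test-suite and the acceptance script run the full design on the
default synthetic family (3 genera × 10 sequences × 1200 bp backbone,
~1 minute), compare the in silico PCR engine against an exhaustive
brute-force matcher on 200 random instances with templates up to 500 nt,
and check dimer ΔG against brute-force offset enumeration on 500 random
oligos up to 12 nt. The synthetic type-strain FASTA shipped under
`inst/extdata/` (clearly labelled synthetic) embeds the validated
*Pseudomonas*/*Colwellia*/*Polaribacter* primer sites at their validated
spacings, so the 250/188/85 bp amplicon sizes are recomputed by the
engine rather than asserted.

## Known limitations

* Specificity at design time is exact-match only; the mismatch-tolerant
  screen lives in the in silico module, mirroring a two-stage
  design-then-validate workflow. A thermodynamic (ΔG-weighted) annealing
  model for off-target prediction is out of scope.
* Salt correction is monovalent-equivalent only; no Mg²⁺/dNTP terms.
* The linear template scan is meant for desk-scale reference sets
  (thousands of sequences), not million-sequence databases; a k-mer
  index is a stated extension point.
* Multiplexing compatibility and probe (TaqMan) design are not
  addressed.
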