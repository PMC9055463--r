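# genusprimer

Design and validation toolkit for **genus-specific 16S rRNA gene qPCR
primers** in microbiome studies.

Universal 16S primers give relative abundances and miss some species of
some genera, which can bias community profiles. A complementary approach
quantifies individual genera by qPCR with primers that target a genus's
hypervariable-region signature. `genusprimer` covers that workflow end to
end, for microbiome researchers who want taxon-specific quantitative
assays alongside amplicon sequencing:

* **seqio** — FASTA / aligned-FASTA (gap `-` and `.`), taxonomy TSV and
  primer-panel TSV ingest; aligned↔ungapped coordinate mapping;
  deterministic TSV/JSON report export.
* **thermo** — degenerate IUPAC expansion, GC%, GC clamp,
  nearest-neighbor melting temperature (unified DNA/DNA parameters,
  monovalent salt correction) and hairpin/self-dimer/heterodimer ΔG at
  37 °C, screened against the ΔG > −9 kcal/mol and 50–55 % GC criteria.
* **design** — the core search: for each genus, scan every alignment
  window of 17–25 nt in both orientations, build the minimal degenerate
  consensus over the target set, and keep windows by degeneracy (≤ 8),
  within-genus coverage (≥ 0.8), exact-match specificity against all
  non-target sequences, and the thermodynamic screen; rank by
  `w1·coverage − w2·background − w3·penalties` and pair under the
  inclusive 85–250 bp amplicon window.
* **insilico** — TestPrime-style in silico PCR: mismatch-tolerant
  IUPAC-aware matching with a 5-nt 3'-exact zone, amplicon prediction,
  per-genus coverage/specificity reports, ≥900 bp length filtering, and
  head-to-head comparison of two primer sets.
* **quant** — qPCR standard curves (OLS of Cq on log₁₀ copies),
  amplification efficiency `E% = 100·(10^(−1/slope) − 1)` with the
  92–105.5 % QC window, copy-number estimation, and Spearman
  concordance between qPCR copies and metagenomic relative abundance.
* **synthgen** — seeded generator of synthetic 16S-like genus families
  (conserved backbone + genus-private signature windows) with exact
  by-construction alignments and known truth, so everything above is
  testable offline.

The package ships a transcribed 11-genus fish-aquaculture panel
(*Alkalimarinus, Colwellia, Enterovibrio, Marinomonas, Massilia,
Oleispira, Phaeobacter, Photobacterium, Polaribacter, Pseudomonas,
Psychrobium*) with validated amplicon sizes, annealing temperatures and
qPCR efficiencies as `inst/extdata/genus_primer_panel.tsv`.

## Worked example

Screen a panel primer, predict its product, and quantify from a
standard curve:

```r
library(genusprimer)

panel <- read_panel(system.file("extdata", "genus_primer_panel.tsv",
                                package = "genusprimer"))
pair  <- panel_pair(panel, "Colwellia")
refs  <- read_fasta(system.file("extdata", "synthetic_type_strain_16s.fasta",
                                package = "genusprimer"))
simulate_pair(pair, refs)
#>                           template_id fw_start fw_end rv_start rv_end
#> 1 Colwellia_synthetic_type_strain_16S      101    118      266    288
#>   mismatches_fw mismatches_rv amplicon_len
#> 1             0             0          188
```

The predicted 188 bp product equals the panel's validated *Colwellia*
amplicon size (length is footprint-inclusive: `rv_end − fw_start + 1`).

```r
evaluate_primer("ATACGAGGGGTGCAAGCG", name = "Colw-F")
#> primer Colw-F (18 nt, degeneracy 1)
#>   GC 61.1-61.1%  Tm 56.2-56.2 C  hairpin 0.00  self-dimer -5.14 kcal/mol
#>   clamp TRUE  passes: dg,gc,clamp
```

Hairpin and self-dimer ΔG clear the −9 kcal/mol screen; the 61 % GC sits
outside the soft 50–55 % window, which penalizes ranking but does not
reject (the validated panel itself violates it).

```r
curve <- fit_standard_curve(2:7, c(28.36, 25.04, 21.72, 18.39, 15.07, 11.75))
curve
#> standard curve: Cq = -3.3226 * log10(copies) + 35.0066  (R2 1.0000, efficiency 100.0%)
copies_from_cq(curve, 20)
#> [1] 32851.37
```

A dilution series spanning 10²–10⁷ copies fits a slope of −3.32, i.e.
100 % amplification efficiency (inside the 92–105.5 % QC band), and an
unknown at Cq 20 corresponds to ≈ 3.3 × 10⁴ template copies.

Designing primers from scratch on a labelled alignment:

```r
fam <- synth_generate(synth_config(seed = 42))  # 3 genera x 10 sequences
res <- design_panel(fam$aligned)
res$panel[, c("genus", "fw_sequence", "rv_sequence", "pair_coverage")]
```

returns one forward/reverse pair per genus with full within-genus
coverage and no off-target amplification on the synthetic family.

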