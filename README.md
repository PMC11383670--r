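# redecap

Detection and interpretation of **redundant mRNA decapping activator
targeting** from multi-omics count data, with a ground-truthed
simulator.

## The problem

Most yeast mRNAs are degraded by decapping followed by 5'→3' decay.
Decapping of a transcript can be stimulated by several partially
interchangeable activators (Scd6, Edc3, Dhh1, Pat1). When two
activators serve the same transcripts redundantly, deleting either gene
alone changes nothing — the other activator covers for it — and the
targets surface only in the double mutant. The observable signature of
redundancy is therefore an epistasis pattern across a mutant panel:
**up-regulation in the double mutant only**. Detecting it reliably
requires differential testing across four genotypes, filtering of the
environmental stress response (ESR) that double mutants often mount,
spike-in normalization to see absolute per-cell changes, and Pol II
occupancy data to separate stabilization from transcriptional effects.

## What the package provides

* **Simulator** (`sim_config()`, `simulate_decap_dataset()`): a
  steady-state synthesis/decay model generating negative-binomial
  counts for RNA-seq, ribosome footprints, CAGE, 5'P degradome and
  Pol II occupancy, with spike-ins, targeting classes (including an
  OR-logic redundant class), ESR confounders, capped-fraction effects
  and framed 5'P ends — all with per-gene ground truth.
* **Normalization**: median-of-ratios size factors, TPM, ERCC and
  heterologous-chromatin spike scaling.
* **Differential testing**: NB Wald test with trend-floored
  method-of-moments dispersions, a translational-efficiency shift test,
  and NA-tolerant Benjamini–Hochberg FDR.
* **Set analysis**: strict-threshold set calling, exact three-set Venn
  arithmetic (including reconstruction of pairwise overlaps from
  published totals/exclusives/triple), hypergeometric overlap
  enrichment, ESR exclusion, and epistasis-sector classification.
* **Decapping metrics**: capped-to-total (C/T) ratios from CAGE/RNA
  TPMs, the codon protection index (CPI) from framed 5'P counts,
  codon-optimality correlation.
* **Decomposition**: spike-normalized mRNA fold change × per-cell
  ribosome factor ÷ Pol II fold change = decay component.
* **Pipeline** (`run_pipeline()`): the full simulate → normalize →
  test → classify → report chain, seed-deterministic, with tab-separated
  outputs.

## Worked example

```r
library(redecap)
report <- run_pipeline(sim_config(seed = 1))
print(report)
```

```
redecap pipeline report
  genes: 4000  samples: 8
  regulated sets (n genes):
    mRNA_up_scd6                   0
    mRNA_up_edc3                   197
    mRNA_up_scd6edc3               658
    non-iESR_mRNA_up_scd6edc3      593
    ...
  redundancy calls:
    redundant_double_only     466
    single_exclusive          5
    single_shared             192
    unclassified              3337
  ESR signature medians: iESR +0.90, rESR -1.14 (log2)
  decomposition:
          set_label normalized_mrna_fc percell_fc_reported polII_fc decay_component_fc
   mRNA_up_scd6edc3              4.235                3.00     1.03              2.889
 mRNA_down_scd6edc3              0.591                0.41     1.01              0.412
```

Neither single deletion produces an up-set remotely the size of the
double mutant's, 466 genes are called `redundant_double_only`, and the
decomposition attributes the double mutant's mRNA increase almost
entirely to decay (Pol II fold change ≈ 1). Of the 400 truly redundant
genes in this simulation, 98% are recovered.

The set-algebra helpers reproduce printed arithmetic exactly, e.g.
reconstructing pairwise overlaps of three up-sets from their totals
(591, 431, 590), exclusive regions (220, 78, 293) and triple overlap
(173):

```r
v <- solve_venn3_from_totals(c(591, 431, 590), c(220, 78, 293), 173)
v$pairwise_only          #  ab  ac  bc
                         # 127  71  53
shared_fraction(v, "B", "A")$pct   # 70
per_cell_correction(2.79, 0.7)$reported          # 2
transcription_decay_split(2.0, 1.2)              # 1.666667
hypergeometric_overlap(187, 741, 283, 5391)$fold_enrichment  # 4.807356
```

## Documentation

Every exported function carries roxygen documentation. The methods
vignette (`vignettes/decapping-redundancy-methods.Rmd`) describes the
generative model, the statistical choices (including why dispersions
are floored at the fitted trend), and the simulator's scope and
limitations.
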