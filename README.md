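# agosort

Positional sorting-signal analysis of miRNA–Argonaute association.

## The problem

A mature plant miRNA acts only after being loaded into one of several
Argonaute (AGO) effector paralogs — ten in *Arabidopsis thaliana*. The
textbook sorting signal is the miRNA's 5′-terminal nucleotide (5′-U →
AGO1, 5′-A → AGO2/AGO4, 5′-C → AGO5), but four bases cannot uniquely
address ten effectors. `agosort` is for researchers with AGO
co-immunoprecipitation (co-IP) small-RNA data who want to ask, with
proper nulls and baselines, *which* sequence positions of a mature miRNA
carry sorting information — individually or in combination.

## What it computes

Starting from co-IP read counts (or FASTQ reads, or a bundled synthetic
generator), the package:

1. **Builds a confidence set** of AGO-preferring miRNAs: reads-per-million
   normalization, a 10-RPM floor, and a strict >70% read-share rule per
   library; precursor quality filtering (> 6 duplex mismatches or a
   bulge > 3 nt rejects a record); deduplication and 5′-anchored 21-mer
   trimming.
2. **Quantifies per-position association** between the AGO label vector
   and each alignment column by mutual information,

   MI_i = Σ_{ago,base} P(ago,base) · log2[ P(ago,base) / (P(ago)·P(base)) ],

   with a per-position label-permutation null (default 10,000 draws,
   add-one empirical p) and Benjamini–Hochberg FDR over the 21 positions.
3. **Profiles composition**: 5′-base enrichment ratios against a
   background population, and sequence-logo information content
   R_i = 2 − H_i with optional small-sample correction.
4. **Infers the miRNA:miRNA\* duplex** by score-based global alignment
   (WC +2, G:U wobble +1, mismatch −1, gap −2), yielding per-position
   paired/wobble/unpaired states and pairing-frequency profiles.
5. **Hunts higher-order signals** with class-balanced random forests
   (500 trees, 20 draws per class): OOB accuracy, per-sample margins,
   unscaled mean-decrease-accuracy importance, and condition comparisons
   by the median two-sided Wilcoxon rank-sum p over repeated runs.

## Worked example

Run the whole pipeline on a synthetic cohort that mirrors the study
conditions (classes AGO1/AGO2/AGO5 with sizes 70/25/22 and the observed
5′-base profile):

```r
library(agosort)
cfg <- default_config(seed = 42)
cfg$n_perm <- 999L          # permutations per MI position
out <- run_pipeline(cfg, out_dir = "agosort-out")
out$confidence_set
#> confidence_set: 102 miRNAs (AGO1=55, AGO2=25, AGO5=22)
```

102 of the 117 simulated miRNAs survive the RPM floor, the 70% rule and
the precursor filter (AGO1 loses the most members: its planted read
preference is diluted across three libraries exactly as for the other
classes, but it is also the largest class). Every retained label matches
the generator's ground truth (`out$label_recovery` is `1`).

The MI profile finds the planted signal where it was planted — the 5′
position — and nowhere else after FDR control:

```r
prof <- out$results$mi_profile
head(prof[order(-prof$mi_bits), c("position", "mi_bits", "p_emp", "p_fdr")], 3)
#>  position    mi_bits p_emp  p_fdr
#>         1 0.67809889 0.001 0.0210
#>        19 0.10147509 0.031 0.3255
#>         5 0.09948068 0.055 0.3444
```

Position 1 carries ~0.68 bits and survives adjustment (p_fdr = 0.021);
the runner-up positions are null fluctuation. The composition table
reports the matching enrichment — e.g. 22 of 25 simulated AGO2 miRNAs
start with A, 4.4-fold over the 66/328 background frequency:

```r
comp <- out$results$composition
comp[comp$base == "A" & comp$class == "AGO2", ]
#>  class base count class_total enrichment
#>   AGO2    A    22          25   4.373333
```

Forest condition comparisons (A = class-shuffled, B = all positions but
the first, C = first only, D = all positions, E = pairing pattern):

```r
out$results$comparisons
#>       comparison     median_p mean_accuracy_a mean_accuracy_b n_runs
#>           B_vs_A 3.264034e-01       0.4789216       0.4039216     20
#>           D_vs_C 2.323674e-08       0.7333333       0.7254902     20
#>  E_vs_E_shuffled 4.412672e-01       0.4259804       0.3563725     20
```

With only the 5′ signal planted, conditions keeping position 1 (C, D)
perform well and margins differ sharply between D and C, while masking
the first position (B) leaves little signal — exactly the pattern this
design is meant to expose. Planting a conditional rule (see
`nested_rule()`) reverses the picture.

Target-set arithmetic works directly from set sizes:

```r
expected_overlap(416, 168)   # AGO1 vs AGO5 targets among 30,000 genes
#> [1] 2.3296
```

A thin command-line wrapper is at `inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --config cfg.yaml --seed 1 --out-dir out`).

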