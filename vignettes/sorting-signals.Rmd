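---
title: "Positional sorting signals in miRNA-Argonaute association: models and methods"
author: "agosort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional sorting signals in miRNA-Argonaute association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agosort)
```

## The question

Plant genomes encode many Argonaute (AGO) paralogs — ten in *Arabidopsis
thaliana* — and a mature miRNA acts only after being loaded into one of
them. The dominant view attributes this sorting decision to the identity
of the miRNA's 5'-terminal nucleotide, recognized by the MID-domain
binding pocket: 5'-U routes toward AGO1, 5'-A toward AGO2 (and AGO4),
5'-C toward AGO5. Four bases, however, cannot uniquely address ten
effectors, so the interesting question is whether positions *other* than
the first carry sorting information — individually, or only in
combination.

`agosort` implements the full analysis chain for this question: building
a labeled set of AGO-preferring miRNAs from co-immunoprecipitation
(co-IP) small-RNA read counts, quantifying per-position label-base
association by mutual information (MI) with permutation nulls, profiling
5'-base enrichment and sequence-logo information content, inferring the
miRNA:miRNA* duplex pairing pattern, and contrasting univariate against
higher-order signals with class-balanced random forests. A synthetic
generator with planted signals makes every stage testable without the
original sequencing libraries.

## From reads to the confidence set

Reads from each AGO co-IP library are adapter-trimmed (exact-substring
search, first occurrence) and truncated to 30 nt; each known mature
miRNA is then counted in each library by exact substring matching. Exact
matching of a full mature sequence inside a read is equivalent to
end-to-end exact alignment for this purpose, and a read containing
several distinct mature sequences increments each of them, since miRNAs
are matched to reads independently. Counts are normalized to reads per
million (RPM), `counts / library_total * 1e6`. Library totals default to
column sums; explicitly supplied sequencing totals (which may include
reads matching no miRNA) are accepted and flagged, since published
totals are usually of that kind and the choice changes RPM denominators.

The preference rule is deliberately simple and strict: a miRNA whose
summed RPM across libraries is below 10 is excluded; one library must
hold *more than* 70% of the miRNA's reads for a label; everything else
is ambiguous. Both cut-offs are strict inequalities, so a 70.0% share or
a 9.99-RPM total does not qualify. Shares are computed on RPM by default
(`share_basis = "count"` uses raw counts; the two differ whenever
library totals differ). Labeled miRNAs whose precursors fail the duplex
quality filter are dropped, identical mature sequences are collapsed to
one entry (identical sequences with conflicting labels are an error —
the share rule makes labels exclusive), and sequences are trimmed to
their 5'-anchored 21-mer. Matures shorter than 21 nt keep their full
sequence for the padded random-forest encoding but are excluded from the
21-mer MI alignment.

## Duplex inference and the precursor filter

The miRNA:miRNA* duplex is recovered by a global alignment of the mature
strand against the reversed star strand after removing the 2-nt 3'
overhang of each strand. Scores: Watson-Crick pair +2, G:U wobble +1,
any other aligned pair −1, gap −2 per nucleotide. The original analysis
used an external minimum-free-energy hybridization tool; a deterministic
score-based aligner was chosen here so that the structure inference is
reproducible and dependency-free, and externally computed structures can
be imported through `parse_duplex_structure()` (dot-bracket with gaps),
making the aligner swappable.

Two numerical choices matter. First, ties among optimal alignments are
resolved toward *fewer gap runs* (implemented as an infinitesimal
gap-opening surcharge in a Gotoh-style recursion) and then leftmost
placement; without this, a planted contiguous bulge whose inserted bases
coincidentally complement a neighboring position can be split into two
shorter runs at equal score, changing the filter verdict. Second,
aligned non-paired columns are counted once as mismatches (symmetric
internal loops are not double-counted), and gap runs on either strand
count as bulges. The precursor filter rejects records with more than six
mismatches or a bulge longer than three nucleotides — again strict
inequalities, so six mismatches plus a 3-nt bulge still passes.

The aligner's score is invariant under exchanging the two strands (the
same pair columns are scored). It is *not* invariant under
reverse-complementing both strands unless the duplex is wobble-free:
complementation maps G:U wobbles to C:A mismatches and A:C mismatches to
U:G wobbles, which changes the score by design. Pairing-frequency
profiles (percent of duplexes paired per position, per AGO class and for
the pooled total) stop at position 19 because the 2-nt 3' overhang makes
duplex state undefined beyond it for 21-nt matures.

## Mutual information with a per-position permutation null

For each column $i$ of the 5'-anchored, ungapped 21-mer alignment, the
association between the AGO label vector and the base column is

$$MI_i = \sum_{ago}\sum_{base} P(ago,base)\,
  \log_2 \frac{P(ago,base)}{P(ago)\,P(base)},$$

with empirical frequencies as probabilities and zero-probability cells
contributing 0. Significance comes from shuffling the label vector
against the fixed base column — each position keeps its own base
composition, so positions with skewed composition get their own null.
Permuting labels against a fixed column induces exactly the
multivariate-hypergeometric distribution over joint tables with fixed
margins, so the default null sampler draws tables directly with
`stats::r2dtable()` (Patefield's algorithm); a literal shuffling path is
retained (`method = "shuffle"`) and the two are cross-checked in the
test suite. Empirical p-values use the add-one convention
$p = (1 + \#\{MI^{null} \ge MI^{obs}\})/(n_{perm}+1)$, so no p-value is
exactly zero, and the default $n_{perm}$ is 10,000. Each profile's 21
p-values are Benjamini-Hochberg adjusted (21 tests, one per alignment
position). Class subsets (pairwise profiles such as AGO1 vs AGO5) and
star-strand input reuse the same machinery; for star strands the
alignment may anchor either on the star 5' end (the default here, via
the star sequence itself) or on mature-opposite coordinates — both views
can be fed in, as the operation only sees labeled sequences.

Enrichment ratios in the 5'-base composition table are frequency ratios,
class base frequency over background base frequency (0 for an empty
cell, flagged infinite for a zero background with a nonzero count) —
this is the statistic that reproduces the published table. Logo
information content is $R_i = 2 - H_i$ bits with optional small-sample
correction $e_n = 3/(2\ln(2)\,n)$, off by default to match common logo
tools; letter heights are frequency times $R_i$. `correlate_profiles()`
provides Pearson and Spearman coefficients with two-sided p-values for
comparing an MI profile against an external per-position
hydrogen-bond-count profile (such counts are consumed as user input; no
structural data ships with the package).

## Random forests for higher-order signals

MI and logos are univariate; conditional rules — e.g. 5'-C miRNAs
routing by the base at position 9 — are invisible to them. Forests of
classification trees capture such interactions. Features are either the
5'-aligned 24-nt sequence (shorter sequences 3'-padded with `N`) or the
duplex pairing state per position (`bound`/`wobble`/`unbound`, padded
unbound), optionally dropping position 1 to mask the known 5' signal.
Forests use the classical `randomForest` implementation with 500 trees,
`mtry = floor(sqrt(p))`, and a class-balanced stratified bootstrap of 20
draws per class (with replacement) to counter the class imbalance of
co-IP data. Exhaustive categorical split search over the ≤5-level
alphabet is the natural factor handling and preserves `mtry` semantics
(no one-hot expansion). OOB majority votes are recomputed from the vote
matrix with ties broken by fixed class order so results are
deterministic under a seed; samples never out of bag (vanishingly rare
at 500 trees) are excluded and logged. The margin of a sample is the OOB
vote fraction for its true class minus the best alternative.

Two encodings (or an encoding against its class-shuffled baseline) are
compared by training both forests repeatedly — by default 1,000 runs —
and applying a two-sided Wilcoxon rank-sum test to the margin vectors of
each run; the reported p-value is the *median* across runs, a
bootstrap-style estimate that reflects the original dataset size instead
of accumulating significance over repetitions. Within a run both
conditions share a seed, so identical conditions produce identical
forests and a median p of exactly 1. Degenerate encodings with no
variation at all (e.g. "first position only" on an all-5'-C cohort)
yield the analytic chance-level forest — uniform votes, zero margins —
rather than being handed to the tree grower, which cannot split them.
Variable importance is the unscaled mean decrease in OOB accuracy under
per-tree permutation of each feature.

One empirical subtlety the package's tests document: with *unbalanced*
class sizes (70/25/22), class-shuffled OOB accuracy settles near
$\sum_c \pi_c^2 \approx 0.44$ rather than $1/3$, because the larger
shuffled class spans more distinct training points per balanced
bootstrap and claims more feature-space volume. The chance-level
baseline check therefore uses balanced classes, where shuffled accuracy
converges to $1/3$ as expected.

## The synthetic generator

The generator emulates the statistical structure of the co-IP
experiment, not its chemistry. Defaults mirror the study conditions:
three classes AGO1/AGO2/AGO5 with sizes 70/25/22, 21-nt matures, and the
observed class-conditional 5'-base distributions (AGO1: 0, 6/70, 1/70,
63/70 over A/C/G/U; AGO2: 21/25, 0, 1/25, 3/25; AGO5: 0, 6/22, 0,
16/22); unconstrained positions draw from a uniform background. AGO4 can
be included to exercise the small-class exclusion path. Nested
conditional rules assign labels constructively from the generated bases,
so planted rules hold exactly. Hairpin precursors are mature + loop +
modified reverse-complement star arm with 2-nt 3' overhangs; wobbles,
mismatches and bulges are planted at requested positions.

Read counts follow a Dirichlet-multinomial: each miRNA draws per-library
fractions from a Dirichlet with concentration `preference_strength`
(default 20) on its true library and 1 elsewhere — the natural model for
a rule that operates on read *fractions*; concentration 20 gives
preference sharpness comparable to a clear co-IP experiment, and
infinity routes every read to the true library. Per-miRNA abundances are
lognormal; reads are the mature sequence with an optional fixed adapter
suffix (full adapter chemistry and sequencing errors are out of scope).
The default pipeline uses libraries of 20,000 reads each — deep enough
that the 10-RPM floor and 70% rule behave as in deep libraries, while
keeping an interactive run in seconds.

What passing on synthetic data does and does not show: the generator
plants independent per-position signals, exact conditional rules and
clean preference mixtures; real libraries add isomiR heterogeneity,
cross-mapping between family members, sequencing error and
non-uniform backgrounds. Synthetic recovery therefore validates the
*machinery* (estimators, nulls, protocols), not the biological effect
sizes. One known leakage is documented: planted wobbles require a G or U
mature base, so duplex patterns carry a faint echo of class-correlated
base composition; pairing-based forests can sit slightly above chance on
synthetic cohorts for this reason.

## Problem sizes and defaults

Interactive defaults are scaled so a full pipeline run completes in
seconds to minutes: 1,000 permutations per MI profile and 20 comparison
runs in `default_config()`, against 10,000 and 1,000 in the full
protocol (`run_config()` documents the full set). The package's own
verification uses 200 signal-free cohorts of 117 sequences with 999
permutations for null calibration, 50 seeds for planted-signal
recovery, 50 runs for the shuffled baseline and 100 runs for the
conditional-rule comparison — sizes chosen to give stable Monte-Carlo
estimates at a few minutes of compute.

## Known limitations

* The duplex aligner optimizes a fixed pair-score model, not free
  energy; structures from thermodynamic tools can be imported instead.
* Exact substring counting has no mismatch tolerance and no isomiR
  collapsing; reads from unannotated variants are simply not counted.
* GO enrichment treats annotations as flat (GO-slim style), with no DAG
  propagation, and target lists are inputs — no target prediction is
  performed.
* Published accuracies from the original co-IP libraries are not
  reproducible without those libraries and the matching miRNA annotation
  release; the package asserts only printed-table arithmetic and
  property-based checks on synthetic cohorts.
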