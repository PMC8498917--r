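---
title: "Quantifying TF binding to modified DNA baits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TF binding to modified DNA baits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modbindr)
library(dplyr)
```

## The experimental design this package models

In a modified-DNA pulldown screen, nuclear extract from a cell line or a
tissue is incubated with a synthetic bait — a tandem array of consensus
transcription-factor response elements — synthesized with cytosine in one of
four states: unmodified (5C), methylated (5mC), hydroxymethylated (5hmC) or
formylated (5fC). Proteins captured on each bait are identified and
quantified by mass spectrometry, one experiment per context × bait ×
replicate. Two designs recur: a panel of cell lines (e.g. HeLa, HepG2, A549,
MCF-7; four baits, three replicates each) and a developmental time course
(mouse brain at E14.5, E16.5, E17.5, P1 and W6).

The scientific question is which DNA-binding proteins *prefer* one cytosine
state — candidate "readers" of the modification — and what that preference
implies at the level of TF families, DNA-binding domains, developmental
stages and downstream target genes.

## Quantification chain

Peptide-level evidence is reduced to protein-level abundance in four steps.

1. **Identification filter.** A protein is kept in an experiment only with at
   least one unique peptide and at least two peptides whose identification
   score exceeds 20 (`identification_filter()`). The threshold is strict
   (`> 20`), so a score of exactly 20 does not count.
2. **iBAQ.** Summed peptide intensity divided by the number of theoretically
   observable tryptic peptides. The denominator uses fully tryptic peptides
   (cleavage after K/R, suppressed before P), zero missed cleavages, length
   6–30 residues — the iBAQ convention. Search engines typically tolerate
   missed cleavages when matching spectra; that setting governs
   identification, not the denominator, so `digestion_rules()` exposes
   `missed_cleavages` separately for users who want to reconcile the two.
3. **FOT.** Each protein's iBAQ divided by the experiment's total iBAQ.
   This makes experiments comparable and every column sum to one; it is the
   scale on which all downstream rules operate. Note FOT is compositional:
   spiking a large amount of bait-specific material into one experiment
   deflates every other protein's fraction there (see the generator notes
   below).
4. **Imputation.** Missing protein × experiment cells are filled with one
   tenth of the global minimum of the observed matrix, *before* replicate
   aggregation and before any geometric mean is taken — a positive floor
   keeps log-scale statistics defined. The pre-imputation matrix is always
   written alongside (`NA` cells) so the floor is recoverable.

z-scores use the sample (n−1) standard deviation; a zero-variance vector
z-scores to all zeros with a warning rather than erroring, so constant
profiles survive aggregation.

## Calling modification-restricted binders

For each protein and context, the four bait values (replicate means of
imputed FOT) are compared: the protein is called restricted to a bait when
that bait is the *strict* maximum and is at least twofold above a center
statistic of the four values (`dmr_rule()`). Two center statistics are in
circulation for this rule — the geometric mean and the median. The package
defaults to the geometric mean and offers the median as a switch; every
output records which was used, and the two can disagree (the profile
`(2, 1, 1, 1)` is called under the median but not under the geometric mean).
Ties at the maximum yield no call by default: assigning a module arbitrarily
on tied data seemed worse than abstaining.

Calls map to modules in bait order (5C → 1, 5mC → 2, 5hmC → 3, 5fC → 4) and
the same rule is applied to TFs, coregulators and other DNA-binding
proteins. Whether the published analyses called on replicate means or
required per-replicate agreement is not documented anywhere we know of;
`call_dmr()` uses replicate means and `call_dmr_consensus()` implements the
stricter per-replicate variant (same bait called in ≥ 2 of 3 replicates).

A **reader** is a protein called for the same bait in *all* assayed contexts
(`nominate_readers()`; `n_required` relaxes this). A protein called in
exactly one context is the context-exclusive (EDO) pattern
(`edo_analysis()`).

## Family and domain preference

Protein profiles are z-scored across the four baits within each context
(`member_zscores()`), which removes abundance differences so that group
aggregation mixes comparably scaled members; group values are means of
member z-scores, and a protein carrying several DNA-binding domains
contributes to each of its domains. Whether published family heatmaps
averaged z-scored or raw FOT is not stated; z-scores were chosen for
cross-context comparability.

Preference for one bait is tested with a paired Student's t-test. The
pairing unit is the (member protein, context) pair — the natural unit at
which the four bait measurements are exchangeable — and the difference is
the member's z on the candidate bait minus its mean z on the other three.
Two-sided p with n − 1 degrees of freedom; preference requires p < 0.05
*and* a positive mean difference. Raw p-values are the default (mirroring
the p < 0.05 convention for this screen); Benjamini–Hochberg is a flag.
Degenerate cases are conventions, not errors: all-zero differences report
no preference; nonzero constant differences report preference by sign with
the p-value flagged unavailable.

## Temporal modules and target-gene integration

In the time-course design each (protein, bait) profile is z-scored over the
five time points and assigned to the module of its peak time point, ties to
the earliest. How the published five modules were derived (clustering versus
peak assignment) is not documented; peak assignment was chosen because each
module's trend chart peaks at exactly one time point, and a k-means
alternative (`method = "kmeans"`, one cluster per time point, clusters
labelled by centroid peak) is provided for broad profiles. Flat profiles
stay unassigned: the peak z must clear a floor (default 0.5). "Module-core"
TFs are those assigned to the same module for all four baits.
Over-representation at a time point additionally requires the z there to
exceed a threshold (default 1.0 — a free parameter recorded in all outputs)
and to be the row maximum.

The integration stage retains a TF → target-gene edge when three conditions
hold at a time point: the TF is a bait-specific, over-represented binder
there; the target is transcriptionally upregulated (p < 0.05, fold > 2,
direction up); and the target passes p < 0.05, fold > 2 in the omic layer
matching the bait — methylome for 5mC, hydroxymethylome for 5hmC. The
transcriptome condition is directional because the rule asks for
upregulation; the modification layer accepts either direction because the
signal is required to *peak*, not to move one way. 5C and 5fC have no
matching genome-wide layer and raise an explicit error. Fold changes are
linear-scale throughout; a `log2_fold_change` column is converted at read
time. Gene identifiers join by exact match — no ortholog mapping.

## The synthetic-data generator

Every stage is testable because the generator plants known structure:

* **Design**: contexts × 4 baits × replicates, defaulting to the study
  layouts (four cell lines or five time points, three replicates).
* **Proteome**: random sequences of 200–800 residues assembled from
  observable tryptic blocks, so every protein has ≥ 3 observable peptides
  and the digestion arithmetic is exact. Sequences are i.i.d. residues —
  sufficient for digestion, with no homology structure.
* **Abundance**: base activities log-uniform over a configurable span,
  affinely rescaled on the log scale so the realized span is exactly the
  configured seven orders of magnitude.
* **Readers**: disjoint sets of TFs whose binding on one bait is multiplied
  by a fold factor (default 8) in all contexts (consensus pattern), one
  context (EDO pattern) or a subset.
* **Noise**: intensity is split equally across observable peptides (keeps
  iBAQ unbiased by construction), multiplied by unit-mean log-normal noise
  of configurable CV, and peptides drop out independently. Scores are
  uniform on [10, 60] with the first two peptides of each protein forced
  confident, and each protein has one guaranteed unique peptide with a
  configurable shared fraction — so the identification filter is exercised
  but not trivially saturated.
* **Omics**: responsive genes get the planted fold with small p-values
  (uniform on [0, 0.01]); null genes get fold ≈ 1 and uniform p-values, so
  5% pass p < 0.05 by chance.

Replicate-level variance of FOT is not reported for the original screens;
the default CV of 0.2 and dropout of 0.1 are plausible label-free values,
chosen once, and are free parameters of the generator rather than estimates
of any particular dataset. By default every protein is expressed in every
context — nuclear extracts contain the full DNA-binding proteome at varying
abundance — and context-restricted detection emerges from dropout.

What the generator does **not** emulate: correlated peptide behavior
(ionization efficiency, retention-time effects), intensity-dependent
missingness, protein inference ambiguity, batch effects, or biologically
structured co-binding. Passing recovery tests on this generator therefore
shows the *pipeline logic* is correct under its stated model, not that the
thresholds are optimal for any real instrument's noise.

One consequence of compositional FOT worth knowing: if planted readers are
stacked onto a single bait, that bait's column total inflates and the
realized FOT fold is smaller than the planted intensity fold. The default
configurations plant readers across baits — as in the real design, where
each bait captures comparable total material — so planted folds survive
normalization.

## Numerical conventions and problem sizes

Deterministic behavior: every generator takes a seed, all randomness in the
pipeline flows from the configuration seed, and `run_pipeline()` manifests
record parameters and output checksums but no timestamps, so a rerun with
the same configuration is bit-identical.

Ties: strict-max abstention in dmr calling; earliest time point in temporal
assignment (recorded in a `tie` flag); exact group-level bait ties yield no
best bait.

The test suite and the acceptance script verify the pipeline at deliberately
desk-scale sizes chosen to keep the statistical properties meaningful: the
reader-recovery study uses 500 proteins (250 TFs, 100 TCs, 150 DBPs) in the
four-cell-line design with 20 planted readers per bait at fold 8, CV 0.2,
dropout 0.1; the null calibration of the paired test uses 10,000 simulated
7-member groups; the end-to-end determinism check runs the five-time-point
pipeline at 90 proteins. These sizes are the package's own choices for
routine verification; all of them scale up by changing the configuration.

## Known limitations

* The dmr rule is threshold-based, not a significance test: it inherits the
  noise of replicate means and makes no multiplicity statement.
* FOT compositionality couples proteins within an experiment; strong
  specific binders slightly deflate everything else on their bait.
* The integration stage treats per-gene omic statistics as given input and
  joins identifiers exactly; it does not model promoter vs gene-body signal
  or cross-species mapping.
* Ordination and correlation outputs are geometric diagnostics only; no
  inferential claims are attached to them.
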