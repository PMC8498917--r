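# modbindr

Label-free proteomics pipeline for **modified-DNA pulldown screens**:
experiments in which nuclear extracts are incubated with synthetic
response-element baits carrying cytosine as 5C (unmodified), 5mC (methyl),
5hmC (hydroxymethyl) or 5fC (formyl), and the captured DNA-binding proteins
are quantified by mass spectrometry. The package is for analysts who have
(or simulate) peptide-level quantification tables from such a screen and
want to identify candidate **readers** of DNA modifications and their
downstream regulatory consequences.

## What it computes

Starting from peptide tables (`protein_id`, `peptide_seq`, `intensity`,
`score`, `is_unique`) per experiment:

1. **Quantification** — proteins are kept with ≥ 1 unique peptide and ≥ 2
   peptides with score > 20; iBAQ = Σ peptide intensity / number of
   theoretically observable tryptic peptides (fully tryptic, K/R cleavage,
   no cut before P, length 6–30); FOT = iBAQ / Σ iBAQ per experiment;
   missing cells are imputed with (global minimum)/10.
2. **Specificity** — a protein is a DNA-modification-restricted binder
   (dmrTF/dmrTC/dmrDBP) in a context when its activity on one bait is the
   strict maximum of the four and

   max ≥ 2 · center(v₅C, v₅mC, v₅hmC, v₅fC),

   with the geometric mean (default) or median as the center. Calls map to
   modules 1–4 in bait order; a protein called for the same bait in **all**
   contexts is nominated a consensus reader.
3. **Family/domain preference** — member profiles are z-scored across the
   four baits within each context; preference of a family or DNA-binding
   domain for a bait is a paired t-test on dᵢ = z(bait) − mean z(other
   baits) over (member, context) pairs, preference at p < 0.05 with mean
   d > 0.
4. **Time course** — each (protein, bait) profile over the five
   developmental time points is assigned to the module of its z-score peak;
   module-core TFs sit in the same module for all four baits.
5. **Integration** — a TF → target-gene edge survives when the TF is a
   bait-specific over-represented binder at the time point, the target is
   transcriptionally upregulated (p < 0.05, fold change > 2, up) and the
   target passes p < 0.05, |fold change| > 2 in the omic layer matching the
   bait (5mC → methylome, 5hmC → hydroxymethylome).

A synthetic-data module generates complete screens with planted ground
truth (reader identities, fold enrichments, responsive target genes), so
every stage has a recoverable answer. See the methods vignette
(`vignettes/modified-dna-binding.Rmd`) for the statistical conventions and
their rationale.

## Worked example

Simulate a four-cell-line screen with 80 proteins, six SCAN-domain TFs
planted as 5fC readers (eightfold enrichment), plus 5mC and 5hmC readers,
under replicate CV 0.2 and 10% peptide dropout; then run the full analysis:

```r
library(modbindr)
library(dplyr)

ann    <- generate_annotations(n_tf = 60, n_tc = 10, n_dbp = 10,
                               dbd_spec = c(SCAN = 6L, C2H2_ZF = 12L),
                               seed = 7)
design <- study_design(c("HeLa", "HepG2", "A549", "MCF-7"))
noise  <- noise_model(lognormal_cv = 0.2, dropout_rate = 0.1,
                      dynamic_range_orders = 7)
readers <- tibble::tibble(bait = c("5mC", "5hmC", "5fC"),
                          n_readers = c(6L, 4L, 6L), fold = 8,
                          policy = "all", dbd = c(NA, NA, "SCAN"))
truth    <- generate_truth(ann$annotations, design, readers, noise, seed = 8)
peptides <- simulate_pulldown(truth, design, ann$sequences, noise, seed = 9)

quant <- quantify_experiments(peptides, design, ann$sequences)
calls <- quant |> aggregate_replicates() |> call_dmr()
glance(calls)
#> # A tibble: 1 × 9
#>   n_proteins n_contexts n_calls n_module1 n_module2 n_module3 n_module4
#>        <int>      <int>   <int>     <int>     <int>     <int>     <int>
#> 1         80          4      64         0        24        16        24
```

64 restricted-binding calls across the four cell lines: 24 for 5mC
(module 2), 16 for 5hmC (module 3), 24 for 5fC (module 4) — each planted
reader called in each of its four contexts, and nothing called for
unmodified DNA. Nomination keeps proteins called in all four cell lines:

```r
nominate_readers(calls) |> count(bait)
#> # A tibble: 3 × 2
#>   bait      n
#>   <chr> <int>
#> 1 5fC       6
#> 2 5hmC      4
#> 3 5mC       6
```

All 16 nominations are planted readers (precision and recall 1). The screen
spans 7.58 orders of magnitude of FOT
(`dynamic_range(filter(quant, !imputed))`), and the domain-level paired
test singles out SCAN → 5fC:

```r
prefs <- quant |> aggregate_replicates() |>
  test_preferences(ann$annotations, level = "dbd")
tidy(prefs) |> filter(group == "SCAN") |>
  select(group, bait, t, p, mean_diff, preferred)
#> # A tibble: 4 × 6
#>   group bait       t        p mean_diff preferred
#>   <chr> <chr>  <dbl>    <dbl>     <dbl> <lgl>
#> 1 SCAN  5C     -257. 2.71e-41    -0.614 FALSE
#> 2 SCAN  5fC   29241. 1.44e-88     2.00  TRUE
#> 3 SCAN  5hmC   -409. 6.56e-46    -0.728 FALSE
#> 4 SCAN  5mC    -266. 1.25e-41    -0.657 FALSE
```

The positive mean difference (+2.0 z units) with p ≪ 0.05 flags the SCAN
domain as 5fC-preferring, exactly as planted. `autoplot()` methods exist
for call sets, ordinations and preference tables;
`run_pipeline(pipeline_config(out_dir))` executes the whole chain — through
temporal modules and TF–target-gene networks on the time-course design —
and writes every stage artifact with a checksummed manifest. A command-line
wrapper with `simulate`/`quantify`/`classify`/`aggregate`/`temporal`/
`integrate`/`run-all` subcommands ships in `inst/cli/` together with a
documented YAML config template.

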