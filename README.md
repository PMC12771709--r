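# scdiverge

Shared and divergent molecular signatures across paired single-cell disease
models.

Two single-cell RNA-seq studies each compare a disease condition against a
control — say, two brain-organoid models of different neurodegenerative
diseases. scdiverge asks what changes *across* them: which genes move the
same way in both diseases, which move in opposite directions, and which are
specific to one — and then carries those gene categories through pathway
enrichment, signed regulatory-network regulator ("perturbagen") ranking,
cell-cell-communication intersection analysis, and validation against
post-mortem and GWAS reference gene lists. It is aimed at computational
biologists running cross-disease or cross-model comparisons who want every
stage of that chain to be a small, separately tested function.

## The core statistics

* **Differential expression** — per gene, a Poisson likelihood-ratio test of
  a condition-specific rate against a shared rate, both with a
  `log(library size)` offset; the statistic is the closed-form deviance
  `D = 2 Σ_groups Y_g log(μ̂_g / μ̂_0)` referred to χ²(1), with Bonferroni
  (or BH) adjustment and a `|log2FC| > 0.1` gate.
* **Cross-study categories** — *shared* (significant in both studies, same
  fold-change sign), *contrasting* (both, opposite signs), *specific* to
  one study (significant there, nominal p > 0.5 in the other), otherwise
  *unclassified*.
* **Enrichment** — upper-tail hypergeometric over-representation against GMT
  collections, universe = genes tested for DE, minimum 3 mapped genes, BH
  adjustment.
* **Perturbagen score** — on a signed digraph, the number of observed
  expression changes that perturbing a node (up or down) would revert,
  where a node's predicted sign is the direction sign times the product of
  edge signs along simple paths (conflicting paths → ambiguous, not
  counted).
* **Overlap statistics** — coverage `100·|query ∩ reference|/|query|`,
  directional concordance by fold-change sign, and a one-sided Fisher exact
  test on the implied 2×2 table.

A negative-binomial synthetic-data generator with planted shared /
contrasting / specific effects, marker blocks, mitochondrial content and a
planted network regulator provides ground truth for recovery testing;
details and all modelling choices are in
`vignettes/cross-model-comparison.Rmd`.

## Worked example

Simulate a paired two-study design at 300 cells per condition, run the DE
and categorization stages, and check recovery against the planted truth:

```r
library(scdiverge)

cfg <- sim_config(n_genes = 1500, cell_types = list(Neurons = 300),
                  n_shared = 40, n_contrasting = 40,
                  n_specific_A = 20, n_specific_B = 20, seed = 1)
study_A <- simulate_study(cfg, "A")
study_B <- simulate_study(cfg, "B")
study_A$data
#> <cell_dataset> 1500 genes x 600 cells [A]
#>   mito genes: 30; normalized layer: absent
#>   cell annotations: condition, sample, cell_type

de_A <- adjust_and_flag(poisson_de(study_A$data))
de_B <- adjust_and_flag(poisson_de(study_B$data))
sum(de_A$significant)   # 99 of 1286 tested genes

cats <- categorize_degs(de_A, de_B)
dplyr::count(cats, category)
#>   category         n
#> 1 contrasting     40
#> 2 shared          40
#> 3 specific_A       6
#> 4 specific_B       7
#> 5 unclassified  1225
```

All 40 planted shared and all 40 planted contrasting genes are recovered,
with no false positives in either category (precision 1.0 at seed 1). The
`specific_*` counts are lower than the planted 20 by design: a
study-specific call additionally requires nominal p > 0.5 in the other
study, which a truly null gene satisfies only about half the time.

The printed composition test reproduces a published cell-type distribution
check from its count table alone:

```r
composition_test(rbind(c(6493, 33884, 13220), c(3002, 19514, 9511)))
#> Composition chi-squared: X2 = 343.86, df = 2, p = 2.15e-75
#> A / B ratios: A 2.16, B 1.74, C 1.39
```

`run_pipeline(pipeline_config(seed = 42, ...))` chains all eight stages
(qc → cluster → de → compare → enrich → network → ccc → overlap), writes
every stage table as TSV plus a `provenance.json`, and returns a report
object.

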