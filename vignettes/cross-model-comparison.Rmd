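---
title: "Multi-level comparison of paired single-cell disease models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level comparison of paired single-cell disease models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdiverge)
```

## The problem

Two single-cell RNA-seq studies each compare a diseased condition against a
control — for instance two brain-organoid models of different
neurodegenerative diseases. The scientific question is not what changes in
either study alone, but what changes *across* them: which genes move in the
same direction in both diseases (shared biology), which move in opposite
directions (contrasting biology), and which are specific to one disease.
scdiverge implements that comparison as a chain of small, testable stages:

1. **QC / normalization** — cell filtering on detected genes and
   mitochondrial content; library-size normalization.
2. **Clustering / annotation** — a PCA + k-means scan validated by silhouette
   widths, marker-based cell-type scoring, merging of fine labels into broad
   types comparable across studies.
3. **Differential expression** — a per-gene Poisson likelihood-ratio test
   with library-size offsets, Bonferroni adjustment, and effect-size gating.
4. **Cross-study categorization** — shared / contrasting / study-specific /
   unclassified labels per gene, with developmental-gene flagging.
5. **Over-representation analysis** — upper-tail hypergeometric tests of the
   categorized genes against GMT gene-set collections.
6. **Network perturbagen scoring** — on a signed regulatory graph, rank
   nodes by how many observed expression changes their up- or
   down-modulation would revert.
7. **Cell-cell communication integration** — intersect target genes of
   top-ranked ligands with significant ligand-receptor pairs (both consumed
   from upstream tools' output tables) and test the intersection for
   enrichment.
8. **External validation** — coverage, directional concordance and one-sided
   Fisher tests against post-mortem differential-expression tables and GWAS
   gene lists.

A synthetic-data generator with planted ground truth stands in for the raw
studies, so every stage's recovery behaviour is measurable.

## The differential-expression model

For gene $g$ and cell $c$ with raw count $y_{gc}$ and library size
$N_c = \sum_g y_{gc}$, the model is

$$y_{gc} \sim \mathrm{Poisson}\!\left(N_c \, \mu_{g,\mathrm{grp}(c)}\right),$$

and the test compares the two-rate model (one rate per condition) against a
single shared rate by the likelihood-ratio statistic referred to
$\chi^2_1$. Because the maximum-likelihood rates are simply group count
totals over group exposure totals
($\hat\mu_j = Y_j / T_j$, $\hat\mu_0 = Y/T$), the statistic has the closed
form

$$D = 2\left[Y_1 \log\frac{\hat\mu_1}{\hat\mu_0} +
             Y_0 \log\frac{\hat\mu_0^{(g)}}{\hat\mu_0}\right],$$

which `poisson_de()` evaluates vectorized over genes. The test suite pins
this to per-gene `glm(y ~ group + offset(log(N)), family = poisson)` fits at
tolerance 1e-10. Two consequences of the offset worth knowing:

* the test is invariant to the *units* of library size and to
  redistributing depth among cells within a group (only group totals enter);
* it is **not** invariant to scaling a group's counts and exposures jointly
  — more counts genuinely carry more information and sharpen the test.

The reported fold change is
$\log_2\big((m_d + 1)/(m_c + 1)\big)$ on group means of linear normalized
expression (counts scaled to `target_sum` per cell), the convention of the
mainstream single-cell toolchain; the pseudocount guards zero means and
shrinks fold changes of weakly expressed genes toward zero. Significance
requires both `p_adj < alpha` (default 0.05) and `|log2FC| > lfc_min`
(default 0.1, strict). Adjustment defaults to Bonferroni — the method named
by the toolchain this mirrors, even though its output is often loosely
called an "FDR" — with Benjamini-Hochberg available; the column is labelled
`p_adj` to avoid the misnomer.

Mixed-effects and pseudobulk alternatives are deliberately out of scope:
with two or three donors per condition they either fail to converge or
discard the cell-level replication this test relies on. The cost is that
cells are treated as independent; the type-I-error suite quantifies the
consequences under the generator's conditions.

## Cross-study categories

With per-study thresholds `alpha = 0.05`, `lfc_min = 0.1` applied
identically to both studies:

* **shared** — significant in both, same fold-change sign;
* **contrasting** — significant in both, opposite signs;
* **specific_A / specific_B** — significant in exactly one study while the
  other study's *nominal* p exceeds `ns_threshold = 0.5` (clearly not
  approaching significance);
* **unclassified** — everything else.

The three named definitions are not exhaustive: a gene significant in one
study whose nominal p in the other falls in `[0.05, 0.5]` is evidence-wise
in between, and forcing it into a category would silently overstate
certainty. It stays `unclassified`, as does a gene with a zero fold change
(sign undefined) or a gene tested in one study only. Genes from a
developmental gene list are flagged (asterisked in rendered tables) because
their cross-study differences may reflect differences in developmental
stage between models rather than disease.

## Clustering and annotation choices

The clustering stage is intentionally the simplest design that preserves
the validation criterion actually used downstream: PCA on the normalized
layer, k-means at each candidate k, and selection by mean silhouette width
(ties toward the smaller k). Iterative resolution-scanning toolchains and
graph-based community detection would be drop-in replacements; what the
package guarantees is only that the chosen partition maximizes the
silhouette criterion among the candidates, and that the silhouette itself
is exact — it is tested against a brute-force per-point evaluation at
tolerance 1e-12. Singleton clusters contribute silhouette 0.

Annotation scores each cluster per candidate cell type as the mean over
member cells of $\sum_{g \in \mathrm{pos}} w_g z_g -
\sum_{g \in \mathrm{neg}} w_g z_g$, with $z_g$ the gene-wise z-score of
normalized expression across cells (clipped to $[-10, 10]$ so near-constant
genes cannot dominate) and $w_g = 1/(\text{number of cell types listing }
g)$ a specificity weight that discounts promiscuous markers. Exact ties map
to `"Unknown"` rather than an arbitrary winner. `merge_cell_types()`
collapses fine labels into broad ones (e.g. all neuronal subclusters into
"Neurons") and conserves cell counts; unmapped labels pass through with a
warning.

The composition test is the Pearson chi-squared test of homogeneity on the
condition-by-cluster table, without continuity correction (the correction
is only defined for 2x2 tables and the test is used on R x C tables), with
disease/control ratios reported per cluster.

## Enrichment, network and communication stages

**ORA.** `p = P(X \ge x)` for hypergeometric $X$ with the universe set to
the genes actually tested for differential expression — not all annotated
genes — so the background matches the measurement process; this mirrors the
intersection-background convention of the GWAS stage. Sets mapping fewer
than `min_mapped` query genes (default 3) are dropped *before*
Benjamini-Hochberg adjustment; a stricter minimum of 5 is a plausible
alternative convention and is available via the argument. Ranking is by
adjusted then nominal p with set-name tie-breaks, so `top_pathways()` cuts
are deterministic.

**Perturbagen scoring.** On a signed digraph, perturbing node $v$ in
direction $d \in \{+1, -1\}$ predicts sign $d \cdot \prod \text{edge signs}$
at each node reachable over simple paths; if distinct simple paths disagree
the node is *ambiguous* and never counted. A node's score in direction $d$
is the number of observed-sign nodes whose predicted sign is opposite to
the observed one; each node reports its better direction and nodes are
ranked by score with name tie-breaks. Simple paths (no revisits) make the
semantics well defined on cyclic graphs; the implementation is pinned to an
independent path-enumeration oracle on random graphs. Topological roles:
hubs (total degree at or above the 0.9 degree quantile — "high number of
connections" is not otherwise quantified), central nodes (directed
betweenness, normalized by $(n-1)(n-2)$, at the same quantile), and
attractors (no incoming edges).

**Communication integration.** Ligand-activity and ligand-receptor tables
are consumed, never computed: the upstream models are large published
tools, and the step this package owns is the intersection-then-enrich
logic. The phrase "intersection of target genes and significant
ligand-receptor pairs" admits two readings, so both are implemented: a
strict gene-level intersection (default) and an augmented variant that also
admits the targets of significant-pair ligands; the chosen mode is recorded
on the result. Shared pathways across studies are ranked by the *worse* of
the two adjusted p-values, which is symmetric and conservative.

**Overlap validation.** Coverage is
$100 \times |\text{query} \cap \text{reference}| / |\text{query}|$;
percentages are rendered at one decimal with round-half-up, the convention
that reproduces printed values such as $11/130 \to 8.5$. Directional
concordance splits the intersection by fold-change sign agreement,
excluding zero fold changes. The Fisher test is fixed one-sided
(enrichment) and is symmetric in query and reference. Callers comparing
against references with finer cell-type resolution should aggregate the
reference subtypes first (e.g. via `merge_cell_types()`) so both sides
describe the same populations.

## What the generator emulates — and what it does not

`simulate_study()` draws negative-binomial counts (size parameter
`dispersion`, default 2; `Inf` gives Poisson) around per-gene baseline
means that are log-normal across genes (mean `baseline_mean = 0.5` counts
per cell, log-sd 1 — a typical sparse droplet-like depth), with:

* log-normal per-cell library-size factors (`libsize_cv = 0.3`) so the
  offset in the DE model is actually exercised;
* a mitochondrial block (`MT-` prefixed, 2% of genes) scaled to an expected
  4% of each library — between the two mitochondrial means the kind of
  organoid datasets this emulates report — so the QC filter has something
  to act on;
* per-type marker blocks (20 genes, ~4x elevated) that make cell types
  separable by the clustering stage and recoverable by the annotation
  scorer;
* planted effects at `planted_lfc = 1` (log2) multiplying the disease-cell
  means, with cross-study sign structure per category: same sign in both
  studies (shared), opposite (contrasting), or present in one with the
  other truly null (specific). Planted genes are drawn only among genes
  with baseline mean at least `min_planted_mean = 0.5` counts/cell: an
  effect planted on a gene that is undetectable at this depth has no
  recoverable truth, so including such genes would only measure sequencing
  depth, not method behaviour.

Deliberately absent: doublets, ambient RNA, and batch effects within a
study (the emulated designs process each dataset as a single batch). The
NB/Poisson mismatch is deliberate and quantified: the DE stage uses the
Poisson test on overdispersed counts exactly as the emulated analysis does,
and the recovery suites measure what that costs. Passing tests therefore
demonstrate internal correctness and recovery under these idealized
conditions — not robustness to the artifacts real droplet data add.

`simulate_signed_network()` produces a *structurally balanced* signed DAG:
each node carries a latent polarity $\sigma_v \in \{\pm 1\}$ and every edge
sign is $\sigma_u \sigma_v$, which makes all path products path-independent
(no ambiguity anywhere). The planted regulator is a source wired to reach
every node, and observed signs are set so it reverts all of them: its score
is exactly $n - 1$ and strictly maximal, since any other node reaches at
most $n - 2$ observed nodes. Balance is an idealization — real regulatory
networks contain incoherent feed-forward structures — so the
oracle-equivalence tests additionally use unbalanced random graphs where
ambiguity genuinely occurs.

## Numerical and reproducibility choices

* All generators run under a private RNG stream (seed saved and restored),
  so calling them does not perturb the caller's RNG state, and fixed seeds
  give byte-identical output.
* `0 log 0 = 0` in the deviance; the statistic is clamped at 0 before the
  chi-squared tail.
* z-scores in annotation are clipped to $[\pm 10]$; constant genes get
  z = 0.
* All ranked tables break ties lexicographically by name so output files
  are byte-stable, which is what the end-to-end determinism check hashes.
* Problem sizes in the test and acceptance suites — 300 cells per condition,
  1,500–2,000 genes, 40 networks of 12 nodes, enumeration oracles on
  universes of at most 12 genes and graphs of at most 8 nodes — were chosen
  as the smallest sizes at which the measured proportions (type-I error,
  precision/recall, top-rank rates) are stable to the tolerances asserted.

## Known limitations

* The Poisson test inherits the anticonservativeness of treating cells as
  replicates; on NB-overdispersed data nominal p-values are optimistic, and
  only the Bonferroni gate keeps the cross-study categories clean. The
  type-I suite is run at `dispersion = Inf` to check the test's own size
  separately from that modelling mismatch.
* Sign propagation enumerates simple paths; on dense cyclic graphs this is
  exponential and the implementation is intended for the sparse curated
  subnetworks the perturbagen question arises on (tens of nodes).
* The clustering stage is a validated simplification, not a reimplementation
  of any specific published pipeline; with real data, users may substitute
  their own labels and enter the pipeline at the DE stage.
* Annotation quality degrades gracefully to `"Unknown"` only on exact score
  ties; near-ties are still assigned, as in most marker-scoring schemes.
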