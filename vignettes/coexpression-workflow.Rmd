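---
title: "Signed co-expression networks, module detection and preservation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed co-expression networks, module detection and preservation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

# The model

`coexmod` analyses gene expression with the weighted co-expression framework:
genes that share regulation covary across samples, and the correlation
structure of a genes × samples matrix can be summarised as a weighted network
whose densely interconnected subsets ("modules") correspond to biological
programs or cell types. The package was built around the study design of
multi-region post-mortem brain expression panels — roughly ten regional
datasets of 65–88 arrays each, drawn from a common pool of ~100 individuals —
where the question of interest is whether a module found in one region (for
example, a microglial module containing a disease gene of interest) is
reproduced in the others.

## Network construction

For one region, pairwise Pearson correlations between the preprocessed log2
expression profiles are transformed into a **signed adjacency**

$$a_{ij} = \left(\frac{1 + \mathrm{cor}(x_i, x_j)}{2}\right)^{\beta},$$

so perfectly anti-correlated genes get weight 0 and uncorrelated genes the
negligible weight $2^{-\beta}$ (about $2.4\times10^{-4}$ at the default
$\beta = 12$). Only positive co-expression therefore carries appreciable
weight. The soft power $\beta$ defaults to 12, the conventional choice for
signed networks of this type; alternatively `pick_soft_threshold()` selects
the smallest power whose connectivity distribution is scale-free-like
(signed $R^2 \ge 0.8$ of the log-log frequency regression, computed over ten
equal-width connectivity bins — bins with no genes are dropped and at least
five usable bins are required).

Direct adjacency is then robustified into the **topological overlap
measure**

$$\mathrm{TOM}_{ij} =
 \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
      {\min(k_i, k_j) + 1 - a_{ij}},$$

which credits two genes for sharing neighbours even when their direct edge
is weak, and $1 - \mathrm{TOM}$ serves as the clustering dissimilarity. The
standard (unsigned) TOM formula is applied to the signed adjacency — the
canonical signed-network workflow. When both genes are fully isolated the
denominator degenerates gracefully: the value reduces to the direct
adjacency, which is then necessarily 0. Matrices are dense double precision;
the implementation is intended for up to roughly 6,000 genes on a 1 GB
budget, not for genome-scale block processing.

## Module detection

Genes are clustered by average linkage (UPGMA) on the TOM dissimilarity.
Modules are branches of this dendrogram, found by a tree-variant dynamic
cut in two stages:

1. A static cut at `cut_height` (default 99% of the maximal merge height)
   yields candidate branches; only branches with at least `min_size = 30`
   leaves survive.
2. Each candidate is decomposed top-down, guided by its internal merge
   heights. If the sorted height sequence shows a pronounced jump in its
   upper half — a gap wider than 15% of the branch's height range — the
   branch is split at that jump and the parts are analysed recursively.

Stage 2 exists because a pure static cut is fragile in exactly the situation
the workflow cares about: genes with chance correlation to a module's latent
factor attach to the module's branch just below the cut height, well above
the heights at which genuine members join. Those attachments show up as an
outlying jump in the branch's merge-height sequence, which is the signature
the decomposition looks for. A homogeneous branch — merge heights with no
pronounced jump — stays intact, so tight modules are not fragmented. If
splitting leaves no part of `min_size`, the whole branch is kept, making
stage 2 a refinement that can only act when there is structure to act on.
Genes in no surviving branch are labelled `"unassigned"`.

The field's other common alternative — the "Dynamic Hybrid" variant with
PAM-like reassignment — is deliberately not implemented: the tree-guided
rule is deterministic, has no tunable reassignment stage, and recovers
planted structure well (see the test suite).

**Module eigengenes.** Each module is summarised by its eigengene (ME): the
first right singular vector of the module's gene-standardized expression
matrix, a unit-norm per-sample profile. SVD leaves the sign arbitrary, so it
is anchored by requiring non-negative correlation with the module's mean
standardized profile; this makes downstream membership signs reproducible.
The proportion of variance explained is $d_1^2 / \sum_k d_k^2$.

**Merging.** Modules whose MEs correlate above 0.9 describe the same
program; they are merged by average-linkage clustering of MEs under
dissimilarity $1 - \mathrm{cor}$, cutting at `merge_height = 0.1`. The
boundary is strict — a pair at exactly 0.9 is not merged (implemented by
cutting at `merge_height - 1e-12`) — and merging repeats until no pair of
MEs is closer than the threshold, so the operation is a fixed point.

**Membership, hubs, core set.** Module membership (MM, also called kME) of
gene $g$ for module $m$ is $\mathrm{cor}(x_g, \mathrm{ME}_m)$, in $[-1, 1]$.
Within a module, members are ranked by their own-module MM (ties broken by
gene id, a documented stable sort) and assigned the quantile
$1 - \mathrm{rank}/\mathrm{size}$. A **hub** is a gene whose quantile is at
least 0.90 in at least 5 regional networks; the **core set** of a target
module is the union over regions of members with quantile strictly above
0.80. These thresholds are the conventional top-decile/top-quintile rules
for this workflow and are exposed as parameters (`hub_q`, `core_q`,
`hub_min_regions`).

## Preprocessing

Expression values arrive as log2 intensities. The stages, in order:

* **Winsorized summarisation** (`winsorized_mean`): values below the 10%
  quantile and above the 90% quantile are clipped to those quantiles before
  averaging. Quantiles use the linear-interpolation convention
  (`stats::quantile` type 7) — the most common default; no other convention
  is implied by the procedure's definition, and the tests pin this one.
* **Transcript filtering** (`filter_transcripts`): a gene is kept iff it is
  detected above background (precomputed boolean flags; the detection
  p-value computation itself is probe-level and out of scope) in at least
  50% of samples in at least one region, has a coefficient of variation
  above 5%, and reaches log2 expression 5 in at least one sample of at least
  one region. CV is computed on the linear ($2^x$) scale, where the
  coefficient of variation is a meaningful quantity, and per region with
  "any one region" passing — mirroring the other criteria; the scope is
  configurable.
* **Covariate residualization** (`residualize`): ordinary least squares of
  each gene on the covariate design (factors indicator-coded), residuals
  plus the gene's original mean. Exact for planted additive batch offsets
  and idempotent; a rank-deficient design is an error naming the collinear
  columns.
* **Outlier removal** (`detect_outlier_samples`): each sample's mean
  inter-array correlation (IAC) is compared with the cohort; samples
  strictly below mean − 3 SD are removed and the procedure iterates to a
  fixed point. The boundary is strict, so a sample exactly at the threshold
  survives; visual dendrogram inspection is replaced by this rule alone.

## Preservation

Two complementary views of cross-network reproducibility:

* **Cross-tabulation** (`module_overlap_table`, `overlap_stats`): for module
  pairs from two labelings on a shared universe, the overlap count,
  percentages relative to either module, the chance expectation
  $n_A n_B / N$, and a one-sided hypergeometric upper-tail p-value
  ($P[X \ge \mathrm{overlap}]$ — the over-representation tail, which is what
  a Fisher test reduces to in this setting). Bonferroni correction uses a
  caller-supplied denominator (e.g. 45 for all pairs of 10 regions) or
  defaults to the number of module pairs tested.
* **Composite Zsummary** (`preservation_zsummary`): observed statistics of
  the module's genes in the test data — four *density* statistics (mean
  correlation, mean adjacency, proportion of variance explained by the test
  ME, mean sign-aware kME) and three *connectivity* statistics
  (reference-vs-test correlations of intramodular connectivity, of kME, and
  of the vectorized correlation sub-matrices). The null is `n_perm` random
  same-size gene sets drawn uniformly from the test universe; each
  statistic is standardized to $Z = (s_{\mathrm{obs}} -
  \bar{s}_{\mathrm{perm}})/\mathrm{sd}_{\mathrm{perm}}$, and

  $$Z_{\mathrm{summary}} = \tfrac{1}{2}\left(\mathrm{median}(Z_{\mathrm{density}})
    + \mathrm{median}(Z_{\mathrm{connectivity}})\right).$$

  Values below 2 indicate no evidence of preservation, above 5 moderate and
  above 10 strong preservation. A statistic whose permutation SD is zero is
  dropped with a warning rather than producing an infinite Z. The exact
  statistic roster is a design choice of this package (the composite is
  defined by its density/connectivity split, not by a fixed list); the
  `medianRank` composite is out of scope.

  One behaviour worth knowing: permutation draws are uniform over the
  universe, so in small universes where the module is a large fraction of
  all genes, random draws are contaminated with module genes and the
  connectivity Z-scores shrink. At realistic scale (a module of a few
  percent of the universe) the effect is negligible; the tests exercise the
  statistic in that regime.

## Enrichment and neighbourhoods

Over-representation of annotation sets (GMT format) in a query list uses the
same one-sided hypergeometric tail plus a chi-square with Yates continuity
correction, $\sum (\max(0, |O - E| - 0.5))^2 / E$ with 1 df. The correction
is floored at zero so a table exactly at independence scores 0 — the
behaviour of mainstream statistical software; the classical uncapped form is
available behind `floor_correction = FALSE`. An explicit background universe
is always required; annotation services are never contacted. Redundant sets
collapse by single-linkage chaining of pairwise Jaccard similarity at
threshold 0.5, keeping each group's largest set as representative.

`tom_neighbors` extracts the graph induced on a module by TOM edges strictly
greater than a threshold (default 0.10) around a designated seed gene,
reporting direct neighbours and the seed's connected component; only the
edge list is produced, not a layout. `marker_mm_profile` tabulates
own-module MM of marker genes across regions (0 where a marker is not a
member), ordering rows by average-linkage clustering on Euclidean distance —
the metric is a package choice, made once.

## Regional profiles

`region_contrast` pairs samples by individual across two regions and applies
a classical paired t test on log2 values, reporting the fold change
$2^{\bar{d}}$. Unpaired individuals are dropped — the pairing is strictly by
individual id. Zero difference variance with a non-zero mean is a degenerate
input and errors (detected with a relative tolerance of $10^{-10}$, since
float subtraction of a constant shift is not exactly constant); all-zero
differences return $t = 0$, $p = 1$. `covariate_association` is OLS of one
gene on a covariate of interest plus adjusters, returning the covariate's
effect and t-test p-value; the adjuster list is free-form since covariate
codings vary between studies.

# The synthetic-data generator

`generate_multiregion_dataset` emulates the features of a multi-region
expression panel that the pipeline must respond to, with known ground truth:

* **Latent-factor modules with hub gradients.** A module's genes are
  generated as $\lambda_g f + \sqrt{1 - \lambda_g^2}\,\varepsilon$, with
  per-gene loadings $\lambda_g$ drawn once from the module's loading range
  and *shared across regions*; the factor $f$ is drawn i.i.d. standard
  normal per region. Two members' expected correlation is
  $\lambda_i \lambda_j$, giving a hub gradient (high-loading genes are the
  most connected). Sharing loadings while redrawing factors encodes
  cross-region preservation exactly as a design with disjoint sample sets
  per region produces it.
* **A designated seed gene** can be planted at a forced loading (e.g. the
  maximum of the range) to emulate a disease gene whose hub status the
  pipeline should recover.
* **Covariate structure.** Additive per-batch offsets (SD `batch_sd`) on all
  genes, a linear age trend (`age_slope` log2 units/year) on selected genes,
  individuals shared across regions with ages uniform on `age_range` —
  the simplest structures the preprocessing stage must remove or detect.
* **Background genes** are independent noise; per-gene baselines are uniform
  on log2 6–12 to resemble array intensities.
* A single RNG stream per call, seeded from the configuration, makes every
  dataset bit-reproducible.

`generate_gene_sets` builds companion "disease lists" with an exact planted
overlap against a chosen module, so enrichment p-values have a known target.

What the generator does **not** emulate: probe-level intensity artefacts,
normalisation residue, realistic annotation graphs, heavy-tailed expression
distributions, or correlated background structure. Passing tests therefore
demonstrate that the algorithms recover the factor-model structure they are
designed for — not that any particular biological dataset will behave as
cleanly.

# Numerical choices and degenerate inputs

* Merge heights from average linkage can violate monotonicity at float
  precision under ties; violations up to $10^{-8}$ are repaired by a
  running maximum before cutting, larger ones are an error.
* `scale_free_fit` requires five usable bins and treats constant
  connectivity as degenerate; its $R^2$ carries sign $-\mathrm{sign}
  (\mathrm{slope})$ so that the expected decreasing relationship scores
  positively.
* Strict-boundary conventions, pinned by tests: IAC outliers (`<`), TOM
  neighbourhood edges (`>`), ME merging (cor `> 0.9`), core-set quantile
  (`>`), hub quantile (`>=`).
* `mm_quantile` breaks ties by `(-MM, gene id)` — deterministic across
  platforms.
* Eigengene computation refuses zero-variance genes (impossible after
  filtering, but checked).

# Problem sizes used by the test suite

The suite exercises planted-structure recovery at 2,000 genes × 100 samples
(five 300-gene modules), hub recovery across 6 planted regions at 600
genes, preservation bands at 1,000 genes × 60–100 samples with 100
permutations and 10 null replicates, and oracle equivalence on hundreds of
small random instances per operation. These sizes were chosen so the full
factor-model behaviour is visible (correlations estimated from ≥ 60 samples,
modules ≥ 30 genes) while a complete run stays in the tens of seconds on one
CPU.

# Known limitations

* Dense matrices only; no block-wise or sparse TOM, no GPU path.
* The tree-variant cut has no PAM-like reassignment stage; genes that fail
  to join a branch stay unassigned rather than being rescued by kME.
* The permutation null of `preservation_zsummary` assumes the module is a
  small fraction of the universe (see above).
* GO/KEGG semantics (term graphs, parent–child tests) are out of scope; the
  enrichment module treats annotation as flat gene sets with an explicit
  universe.
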