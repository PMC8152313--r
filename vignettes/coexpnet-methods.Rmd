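---
title: "Methods: co-expression networks, module characterization and differential co-expression"
author: "coexpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks, module characterization and differential co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexpnet)
```

This vignette documents the models and procedures implemented by `coexpnet`,
the assumptions behind them, the tunable parameters and their defaults, the
numerical conventions, and the open design choices the package had to
settle. It states no empirical claim that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Input and filtering

The pipeline consumes a normalized expression matrix with **samples as rows
and genes as columns** (`readExpression` can transpose on read).
Normalization and probe/transcript-to-gene aggregation are deliberately out
of scope: both depend on the assay technology, so they are left upstream.
Correlation estimates need samples: below 3 nothing is computable, around 20
is the usual working minimum, and 100+ samples give robust networks.
`coexpnet` treats these as advisories (a warning below 20), not hard stops,
because small pilot datasets are still useful for exploration.

Two optional filters precede network construction:

* **Low counts** (`filterLowCounts`, threshold 5): genes whose counts never
  rise above background noise cannot carry co-expression signal. The
  default `at_least_one` mode (keep a gene if *any* sample reaches the
  threshold) is the most permissive of the three modes offered
  (`at_least_one`, `mean`, `all`), because over-filtering loses informative
  signal and can distort the scale-free property the network step relies
  on.
* **Low variation** (`filterLowVariation`): genes nearly constant across
  samples cluster arbitrarily. The statistic and cut are not canonical
  anywhere, so they are this package's contract: a per-gene dispersion
  (MAD by default, for robustness to outliers; variance and CV offered)
  with genes strictly below the 10% dispersion quantile removed and ties at
  the quantile kept. The quantile form makes the filter scale-free in the
  units of the data.

## Network construction

For genes $i, j$: $r_{ij}$ is the Pearson (default) or Spearman correlation;
Spearman uses average ranks on ties and is preferable when monotone but
non-linear relationships or outliers are expected. Zero-variance genes are a
hard error (filter first).

**Soft threshold.** The unsigned adjacency $a_{ij} = |r_{ij}|^\beta$
progressively suppresses weak correlations rather than cutting at an
arbitrary hard threshold. $\beta$ is selected as the smallest integer in
1..30 whose connectivity distribution $k_i = \sum_{j \ne i} a_{ij}$ is
approximately scale-free: connectivities are discretized into 10 equal-width
bins, $\log_{10}$(bin frequency) is regressed on $\log_{10}$(mean bin
connectivity) over non-empty bins with positive mean (at least 3 bins
required), and the **signed** fit index $-\mathrm{sign}(\text{slope}) R^2$
must reach 0.85. The sign makes increasing (non-power-law) relationships
fail regardless of their $R^2$. None of the bin count, grid, or cut is
standardized in the literature; 10 bins / 1..30 / 0.85 are this package's
contract, chosen as the conventional values of the method family. When no
candidate passes, the build fails with a structured "aberrant power" error
carrying the full fit table — a deliberate guard, since forcing a power onto
a network that is not scale-free silently degrades everything downstream.

**Topological overlap.** With $L_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}$ and
$k_i$ as above,
$$\mathrm{TOM}_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad \mathrm{TOM}_{ii} = 1 .$$
TOM rewards shared neighborhoods, reflecting the hierarchical organization
of co-expression networks, and is the final co-expression score used by
every later stage. The implementation is the matrix-product form
$L = A_0 A_0$ (diagonal zeroed); the test suite checks it against a naive
triple loop at $10^{-10}$.

Only **unsigned** networks are built: the downstream analyses (module
preservation, difference matrices) are defined on unsigned scores, and
signed variants would double the surface without changing the method.

## Module detection

Genes are clustered by average-linkage agglomeration of $d = 1 -
\mathrm{TOM}$. The cut is a two-stage *hybrid* procedure:

1. **Static cut** at 99% of the maximum merge height; branches with at
   least `minModuleSize = 20` genes become provisional modules.
2. **kME assignment**: provisional module eigengenes are computed, and each
   leftover gene joins the module maximizing $|kME|$ (its correlation with
   the eigengene) when that $|kME| \ge 0.30$; otherwise it goes to module 0
   (unassigned).

This is a simplified variant of the dynamic tree cut family: the full
algorithm's branch-shape criteria (core scattering, gap statistics) are a
non-goal, and the contract asserted by the tests is behavioral — planted,
well-separated modules are recovered exactly — not equivalence with any
reference implementation. A consequence worth knowing: stage 2 tests every
unassigned gene against every module, so with $n$ samples a pure-noise gene
passes the $|kME| \ge 0.30$ gate with probability roughly
$2\Phi(-0.3\sqrt{n-1})$ per module (about 2% per module at $n = 60$). On
data with many background genes a small percentage of them will therefore
be absorbed into modules; the planted-module recovery measured by the
acceptance suite (adjusted Rand index around 0.85–0.93 at 60 samples with
200 noise genes, with the module genes themselves recovered perfectly)
reflects exactly this leakage, and larger sample sizes tighten it
quadratically.

**Eigengenes.** The eigengene of a module is the first principal component
of its per-gene z-scored expression (z-scoring stops high-variance genes
from dominating), scaled to unit variance. PCA sign is arbitrary, so it is
anchored: the eigengene must correlate non-negatively with the module's
mean z-scored profile (falling back to the first gene when that mean is
degenerate), which makes results reproducible across platforms.

**Merging.** Modules whose eigengenes correlate at $\ge 0.75$
(`mergeCut = 0.25` on the dissimilarity scale) are merged iteratively,
most-correlated pair first, eigengenes recomputed after each merge; the
surviving label is the larger module's (smaller label on ties). The final
partition is renumbered 1..M by decreasing size, ties broken by the
lexicographically smallest member gene; pre-merge labels, the dendrogram
and the merge history are all retained.

## Biological integration

**Over-representation analysis** runs locally against user-supplied GMT
collections (any annotation database exportable as GMT works). For module
$n$ genes and a term of background-restricted size $K$ in a universe of $N$
genes, the p-value is the hypergeometric upper tail of the overlap $x$.
Terms outside 5..1000 background genes are skipped (tiny terms are
unstable, huge terms uninformative). The original analysis ecosystem used a
hosted enrichment service with its own proprietary multiple-testing
correction; that is service-specific and undocumented as a formula, so this
package uses local ORA with Benjamini–Hochberg FDR control — standard,
reproducible, offline. One joint BH family covers all tested
(module, term) pairs of a call; module 0 is never tested.

**Phenotype association** correlates each module eigengene with each
phenotype variable. Categorical phenotypes are dummy-encoded one-vs-rest
with *no* reference level dropped: each indicator is tested marginally by
correlation, not jointly in a regression, so dropping a level would simply
discard one test. Two-sided p-values come from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom ($|r|=1 \mapsto
p=0$); BH adjustment is joint across all (module, variable) pairs — the
multiple-testing family is not specified anywhere canonical, and one joint
family is the simplest defensible control.

## Graph topology

Co-expression networks are complete weighted graphs, so every topological
view needs an **edge filter**; `graphFrom` applies an absolute TOM
threshold (quantile selection can be emulated by passing a quantile of the
TOM). Three per-gene metrics are exposed: *degree* and *strength* depend on
the filter; *connectivity* $k_i = \sum_{j\ne i} \mathrm{TOM}_{ij}$
deliberately does not, so cross-condition connectivity comparisons never
depend on a display parameter.

**Hub genes** can be defined three ways, all threshold-based rather than
top-N (a fixed N biases comparisons across modules of different sizes):

* connectivity ≥ its 95th percentile (ties at the cut included),
* filtered degree ≥ its 95th percentile,
* Kleinberg (HITS) score ≥ 0.90 of the maximum. For an undirected graph
  the hub score is the principal eigenvector of the weight matrix,
  computed by power iteration (tolerance $10^{-10}$, at most $10^4$
  iterations) with a diagonal shift equal to the maximum row sum — the
  shift leaves the eigenvector unchanged while guaranteeing convergence on
  bipartite-like weight patterns (e.g. stars) where the unshifted
  iteration oscillates between the $\pm\lambda_{\max}$ eigvectors.

**Sub-modules** within one module are found by PAM (k-medoids; the
deterministic BUILD + SWAP algorithm) on the module's $1 - \mathrm{TOM}$
dissimilarity, with $k$ chosen over 2..min(15, m−1) by the mean silhouette
width $\bar s(k)$. If $\max_k \bar s(k) < 0.20$ the module is reported as
having no reliable substructure ($k = 1$); the 0.20 floor is this package's
contract (silhouettes below ~0.2 are conventionally read as "no substantial
structure"). Modules under 4 genes return $k = 1$ with a warning.

## Differential co-expression

Given a *discovery* condition (reference) and a *test* condition sharing a
gene universe, each discovery module is scored by **seven statistics**,
four *density* statistics evaluated on the test condition — mean
off-diagonal TOM weight (`avg.weight`); coherence (mean squared node
contribution, where the node contribution $\nu_i$ is the correlation of
gene $i$ with the module summary profile); `avg.cor` and `avg.contrib`,
the mean pairwise correlation and mean node contribution sign-anchored by
the discovery-side $\mathrm{sign}(\nu^D_i)$ — and three *connectivity*
statistics correlating discovery and test structure: off-diagonal
correlations (`cor.cor`), intramodular TOM degrees (`cor.degree`), and
node contributions (`cor.contrib`). The statistic set follows the
established module-preservation framework (4 + 3); the exact formulas as
written are this package's contract.

The null hypothesis is built by **without-replacement permutation**: each
permutation draws $|$module$|$ distinct genes uniformly from the test-side
shared universe (a flag restricts the pool to non-module genes) and
substitutes them on the test side only, keeping all discovery-side
quantities fixed. This mirrors the reading that node labels are reassigned
on the condition under test; the alternative reading (re-permuting both
sides) would only inflate the null variance. One-sided p-values use the
add-one estimator $(\#\{perm \ge obs\}+1)/(n_{perm}+1)$, so $p \ge
1/(n_{perm}+1)$ always; a two-sided option compares distances from the
permutation mean. The default 1000 permutations balance the $10^{-3}$
p-value floor against runtime.

Because non-significance cannot *establish* unpreservation, a second stage
computes per-statistic Z-scores against the permutation moments, the median
Z within each statistic group, and the **Z-summary** (mean of the two
medians). The four-way status is:

| condition | status |
|---|---|
| all 7 p-values < α | preserved |
| otherwise, Z-summary < 2 | unpreserved |
| otherwise, 2 ≤ Z-summary < 10 | moderately preserved |
| otherwise (≥ 10, or undefined) | inconclusive |

The thresholds 2 and 10 are the conventional Z-summary break-points. The
published decision tree behind this combination appears only in
supplementary material of the originating work; the mapping implemented
here is a **reconstruction** and is labeled as such. A statistic with zero
permutation spread gets a NaN Z and drops out of its median; a whole group
of NaNs makes the Z-summary (and hence the status beyond stage 1)
undefined.

`compareConditions` seeds module $i$'s RNG with `seed + i`, so results are
bit-reproducible and independent of evaluation order. The
**co-expression difference matrix** $D = \mathrm{TOM}^{test} -
\mathrm{TOM}^{disc}$ (zero diagonal; positive = gained co-expression)
localizes rewiring, ordered by the discovery dendrogram when available.

## The simulator, and what passing tests do and do not show

`simulateExpression` draws each module $m$ a latent factor $f_m \sim
N(0,1)$ over samples and generates members as
$$x = \beta_m f_m + \sqrt{1-\beta_m^2}\,\varepsilon + \sigma\,\eta,$$
with background genes pure $N(0,1)$ noise. Without extra noise the
within-module pair correlation converges to $\beta_m^2$, the module is
exactly rank-one plus noise, and the eigengene estimates $f_m$ — so
recovery, coherence, kME and preservation all have analytic anchors.
`simulateConditionPair` redraws an independent dataset (fresh factors and
noise: new samples, same population) and applies per-module perturbations:
`none`, `rewire(q)` (a fraction $q$ of members becomes independent noise),
`destroy` (all of them). `simulatePhenotype` produces variables with a
prescribed correlation to a chosen factor. An `asCounts` transform
(`round(scale·exp(x))`) gives the count filter realistic input.

The reference conditions used by the acceptance suite are 5 modules × 50
genes + 200 background genes, 60 samples, coherence 0.8, extra noise 0.2 —
large enough to exercise every stage, small enough that the whole suite
runs in minutes. What this single-factor model does **not** emulate:
negative-binomial count noise and library-size effects, batch structure,
overlapping or hierarchical modules, correlated factors, or the
heavy-tailed connectivity of real transcriptomes. Passing tests therefore
demonstrate the algorithms' correctness and calibration under a clean
generative model, not performance on real tissue data. One visible
consequence: within a planted module every pair correlation has the *same*
expectation, so the cross-condition connectivity statistics (`cor.cor`,
`cor.degree`) compare pure sampling noise between conditions and stay near
zero even for faithfully re-drawn modules; intact simulated modules
therefore often classify as "inconclusive" (huge density Z-summary, weak
connectivity correlations) where real modules — whose correlations are
heterogeneous — would show reproducible connectivity patterns and classify
as preserved. The self-comparison test, where connectivity statistics are
exactly 1, covers the other extreme.

One consequence of the clean model deserves emphasis: planted equal-size
blocks produce a *bimodal*, not scale-free, connectivity distribution, so
the soft-threshold fit — correctly — reports a poor fit at low powers and
only passes at high ones where the TOM scale collapses. The
recovery-oriented tests and the acceptance script therefore build their
networks at the conventional unsigned-network default $\beta = 6$, and the
scale-free fit is validated separately on a correlation matrix constructed
to be scale-free (product-form adjacency with heavy-tailed node weights).
This mirrors practice on real data, where the fit is run first and a
conventional default is used when the data cannot support the fit.

## Numerical conventions and degenerate inputs

* Matrices are forced exactly symmetric and clamped to their ranges after
  floating-point products; correlation inputs with zero variance yield NaN
  statistics (flagged) rather than errors inside permutation loops.
* Self-comparisons report cross-condition correlations of exactly 1 (an
  identical-input shortcut avoids reporting $1 - \epsilon$).
* Eigengene sign anchoring, size-then-gene-id module renumbering,
  smallest-pair tie-breaking in clustering, and PAM's deterministic BUILD
  initialization together make every stage reproducible bit-for-bit under
  a fixed seed (the CLI writes a manifest and the rerun is byte-identical
  apart from its timestamp).
* All-unassigned partitions, empty candidate sets, single-gene modules and
  sub-4-gene modules are handled (empty results / $k=1$ / warnings), never
  crashes.

## Known limitations

* The tree cut is the simplified two-stage hybrid described above; on
  weakly separated or nested modules it will differ from the full dynamic
  algorithm, and its stage-2 kME gate admits a small, sample-size-dependent
  fraction of noise genes.
* ORA treats gene sets as unordered and ignores inter-gene correlation
  within modules, as all hypergeometric enrichment does.
* Preservation testing is pairwise (one discovery, one test); multi-way
  designs must be looped.
* Block-wise computation for very large gene universes (>50k genes) and
  sparse TOM approximations are out of scope; matrices are dense.
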