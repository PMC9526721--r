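---
title: "Methods: co-expression modules and connectivity scoring in coexscreen"
author: "coexscreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules and connectivity scoring in coexscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexscreen)
```

# Scope

`coexscreen` implements a signature-based in-silico drug-repurposing
pipeline for two-group expression experiments: sample quality control and
quantile normalization, weighted gene co-expression network analysis
(WGCNA-style, implemented from scratch), extraction of an up/down query
signature by differential expression, and Connectivity-Map build-02 style
scoring of a compendium of ranked compound profiles with a rank-based
Kolmogorov–Smirnov (KS) statistic. Closed-form preclinical metrics
(sciatic function index, regenerating-axon totals, pupillary constriction,
qPCR fold changes) and a seeded synthetic-data generator with ground truth
round out the package. This vignette documents the models, the tunable
parameters, the numerical choices, and — importantly — what the synthetic
benchmarks can and cannot demonstrate.

# Expression preprocessing

**Input.** A gene-by-sample matrix of summarized, log-like intensities
with a two-level group factor (e.g. vehicle vs treated). Raw array
processing (CEL parsing, background correction) is out of scope; the
package starts from the summarized matrix.

**Sample QC.** Each sample's mean Pearson correlation with all other
samples is computed once on the full matrix; samples more than `k` (default
3) sample standard deviations below the average are flagged. The rule is
single-pass by design: re-estimating after each removal would make the
flag set order-dependent. Flagging requires at least 3 samples and fails
loudly on zero-variance samples, where correlations are undefined.

**Quantile normalization.** Every column is forced onto the per-rank mean
of the sorted columns. Ties receive the mean of the reference values across
their tied ranks (so a tie group of three spanning ranks 4–6 gets
`mean(ref[4:6])`, not an interpolation at the mid rank — this differs from
`limma::normalizeQuantiles(ties = TRUE)` for odd tie groups, and the two
agree exactly on tie-free data). The operation is an exact fixed point:
once all columns share the reference distribution, re-application changes
nothing, bit for bit.

**Variance filter.** The analysis retains the `n` most variable genes
(default 10,000), ties broken by input order so the selection is
deterministic. Probe-level data can be collapsed to genes first; when a
gene has several probes the maximal-variance probe is kept, a standard and
deterministic policy.

The fixed stage order is QC → quantile normalization → variance filter;
applying QC to the raw matrix keeps outlier detection independent of the
normalization that the outlier itself would distort.

# Co-expression network and modules

**Adjacency.** With Pearson correlation $r_{ij}$ across samples, the
signed adjacency is $a_{ij} = ((1 + r_{ij})/2)^\beta$ and the unsigned
variant $|r_{ij}|^\beta$, with $\beta = 16$ by default. Signed networks
are the default because anti-correlated genes should not be co-clustered;
the unsigned variant is retained behind `adjacencyType` because the
absolute-value formulation is also in common use.

**Topological overlap.** The similarity used for clustering is
$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$
with $k_i$ the connectivity of gene $i$ excluding itself, and
$\mathrm{TOM}_{ii} = 1$. Pairs with a non-positive denominator (fully
isolated) get overlap 0 and a logged note.

**Module detection.** Average-linkage hierarchical clustering of
$1 - \mathrm{TOM}$, a *static* cut at `cutHeightFraction` times the
maximal merge height, removal of clusters below `minModuleSize` (default
100; such genes become `"unassigned"`), then iterative merging of module
pairs whose eigengene dissimilarity $1 - \mathrm{cor}$ is below
`mergeDissThreshold` (default 0.1). Merging always joins the closest
qualifying pair, recomputes eigengenes, and repeats to a fixed point, so
the result does not depend on the incidental order of module labels. A
static cut was chosen over dynamic tree-cut variants because it is simple,
deterministic and directly testable; the price is one extra tunable. The
default fraction is 0.95: in simulated data, background genes chain onto
module clusters only in the top few percent of the merge-height range
(cutting at 0.99 of the maximum produces giant mixed clusters and, on
pure-noise data, spurious modules), while module clusters are complete
well below 0.95 of the maximum. Cutting lower than ~0.9 starts truncating
genuine modules.

**Eigengenes.** The module eigengene is the first right-singular vector of
the gene-standardized module submatrix — a unit-norm per-sample summary.
Its sign is fixed by requiring non-negative correlation with the module's
mean standardized profile, so module–trait correlation signs are
reproducible. The attribute `varExplained` records the fraction of
variance carried by the first component.

**Module–trait statistics.** Pearson correlation of each eigengene with a
per-sample trait (0/1 for vehicle/treated), p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n - 2$ degrees of freedom, and
Bonferroni adjustment over the number of assigned modules; significance at
adjusted $p < 0.05$.

**Over-representation.** Hypergeometric upper-tail tests of module genes
against user-supplied gene sets (GMT format), Benjamini–Hochberg adjusted
across sets. External annotation services are out of scope; the universe
and the sets are explicit arguments.

# Query signature

Differential expression uses a per-gene two-sample pooled-variance Student
t-test (Welch available via `method = "welch"`); genes with exactly zero
pooled variance get $t = 0$, $p = 1$. The pooled test is the conventional
choice for small balanced microarray designs; no moderation or fold-change
filter is applied because the signature threshold is a raw p-value cutoff:
genes with $p < \alpha$ (default $\alpha = 0.005$) enter the signature,
positive differences as up tags and negative as down tags, each list
ordered by ascending p so the written GRP files are deterministic. The KS
statistic below depends only on the tag *sets*; the ordering is purely for
reproducible serialization. No multiplicity correction is applied before
signature selection — the threshold is deliberately a raw p-value.

# Connectivity scoring

**Tag KS statistic.** For a tag set of size $t$ with sorted ranks
$V_{(1)} < \dots < V_{(t)}$ in a profile over $n$ genes,
$$a = \max_j\left(\tfrac{j}{t} - \tfrac{V_{(j)}}{n}\right), \qquad
  b = \max_j\left(\tfrac{V_{(j)}}{n} - \tfrac{j-1}{t}\right),$$
and the statistic is $a$ if $a > b$, else $-b$. This is the classic
one-sample KS construction on the tag positions; it is verified in the
test suite against an independent CDF-scan oracle over every placement for
small universes.

**Instance score.** `ks_up - ks_down` when the two statistics disagree in
sign, else 0 ("null instance"): an instance only counts when the up tags
and down tags move in opposite directions, the build-02 convention.

**Scaling.** Across the instance set, positive raw scores are divided by
the maximum and negative ones by the absolute minimum, so the strongest
concordant instance scores exactly +1 and the strongest discordant exactly
−1. Scaling is invariant to any positive rescaling of the raw scores.

**Compound summaries.** Mean scaled score over the compound's instances;
percent non-null = share of instances whose nonzero score sign agrees with
the mean's sign (0 when the mean is 0).

**Permutation p-value.** For each compound, `B` random query signatures
with the same up/down tag counts are drawn uniformly without replacement
from the universe and the compound's mean scaled score is recomputed
against its own instances, scaling within that same instance set; the
observed statistic is computed identically so observed and null draws are
exchangeable under the null. The add-one estimator
$p = (1 + \#\{|\mathrm{null}| \ge |\mathrm{obs}|\})/(B + 1)$ never returns
0. Tag-set permutation (rather than instance-label permutation) is used
because it conditions on the compendium actually being queried.

*A caveat worth knowing:* the null-instance rule makes the per-instance
score distribution atomic — under the null, a random signature zeroes an
instance with probability about one half, and for a 3-instance compound
the mean scaled score then has point masses at 0 (mass 5/16) and ±1/3
(mass 3/8). Because the estimator counts ties conservatively, permutation
p-values are *valid but conservative and visibly non-uniform* under the
null (an atom at $p = 1$ and a clump near the tie mass). This is a
property of the score's discreteness, not of the implementation; inference
based on these p-values is conservative, never anti-conservative. A
randomized (mid-p) estimator would restore exact uniformity but is not
used, to keep the estimator deterministic.

**Specificity.** The fraction of decoy signatures whose absolute mean
scaled score for the compound is at least the observed one; decoys are
user-supplied or generated, since the original fixed decoy collection of
the public reference database is not distributable.

**Ranking.** Compounds are ordered by permutation p ascending, then by
*signed* mean score descending, then by name. The signed tie-break is a
deliberate design choice: the screen looks for compounds that *mimic* the
query signature, and a strong signature-*reverser* is exactly as
significant as a strong mimic under the two-sided permutation null — with
an absolute-value tie-break the top position between a planted mimic and a
planted reverser would be a coin flip. With the signed tie-break the mimic
wins every p-tie; a strong reverser still (correctly) ranks as highly
significant, immediately after.

# Preclinical metrics

All closed-form and unit-checked:

* Sciatic function index:
  $\mathrm{SFI} = -38.3\,\frac{EPL-NPL}{NPL} + 109.5\,\frac{ETS-NTS}{NTS}
   + 13.3\,\frac{EITS-NITS}{NITS} - 8.8$; symmetric prints give exactly
  −8.8, and the value is invariant to a common rescaling of all six
  measurements. Values near 0 mean normal gait, near −100 severe
  impairment.
* Regenerating axons at distance $d$:
  $\Sigma a_d = \pi r^2 \cdot [\text{axons/mm}] / t$ with section
  thickness $t$ defaulting to 0.010 mm (10 µm). Radius and thickness carry
  explicit unit tags and must match; a diameter convenience wrapper halves
  its input, since nerve "width" measurements are usually diameters.
* Pupillary constriction: $100\,(A_\text{base} - A_\text{stim}) /
  A_\text{base}$ on areas; a diameter wrapper squares its inputs first.
  Dilation yields a negative value with a warning rather than an error.
* qPCR fold change: $2^{-\Delta\Delta C_t}$ with
  $\Delta C_t = C_t^\text{target} - C_t^\text{reference}$ per condition;
  the test/control and control/test fold changes multiply to 1 exactly.
* Paired percent recovery: $100 \cdot x_\text{injured} /
  x_\text{reference}$ against the within-animal reference.

# Synthetic data: what it emulates and what it does not

`simulateExpression()` draws, per module, a latent eigengene per sample
from a standard normal; trait-linked modules add a treated-group mean
shift of `treatmentEffect` latent SD units (default 2.0), with the shift
sign alternating across trait modules so both up- and down-regulated
planted gene sets exist (a screen needs both tag lists). A module gene is
$\rho\, e_m + \sqrt{1-\rho^2}\,\varepsilon$ with
$\rho$ = `withinModuleCor` (default 0.8); background genes are pure noise;
a per-gene baseline from Unif(6, 12) mimics intensity levels. Defaults —
10,000 genes, 6 modules of 150 genes, 4 trait-linked, 3 samples per group
— mirror a small two-group microarray study after variance filtering.
Intensities are Gaussian on a log-like scale; probe-level artifacts, batch
effects and heavy-tailed noise are deliberately not modeled. The optional
planted QC outlier is a within-sample permutation of one treated sample,
which preserves that sample's marginal distribution while destroying its
correlation with every other sample.

`simulateCompendium()` emits uniformly random rank permutations for
ordinary compounds and exponentially tilted permutations for planted
mimics/reversers: gene keys are independent Gumbel draws shifted by
$\pm\lambda$ on the planted up/down genes, and ranks follow the sorted
keys. $\lambda = 0$ is exactly uniform; $\lambda \to \infty$ pins the
planted up tags to the top ranks. The Gumbel-shift construction is the
standard exponential tilting of a random permutation and gives a single
interpretable concordance knob. The default planted compendium carries one
mimic and one reverser at $\lambda = 3$ among 50 compounds with 3
instances each.

# What the benchmarks show — and the small-$n$ reality

The test suite demonstrates, on synthetic data, that the implementation
recovers what is statistically recoverable. Two regimes matter:

* **Identifiable regime** (e.g. 10 vs 10 samples, orthogonal module
  latents): module detection recovers ≥95% of planted genes in exactly the
  planted number of modules, pure-noise data yields no modules, and the
  end-to-end screen puts the planted mimic and reverser at the top of the
  ranking with the planted signs.
* **Small-$n$ regime** (3 vs 3 samples, the default generator): with six
  samples, sample correlations have a null standard deviation of about
  0.45, so (i) two independently drawn module latents are frequently
  confusable by chance, capping any correlation-based clustering well
  below perfect recovery; (ii) roughly 12% of genes with a true
  gene–latent correlation of 0.8 *realize* a correlation too weak to
  cluster (Fisher-z: $P(\hat r < 0.4) \approx 0.12$ at $n = 6$); (iii) the
  per-gene pooled t-test at $\alpha = 0.005$ with a 1.6-SD gene-level
  shift has power ≈ 0.05, so a signature built at that threshold captures
  only a few percent of truly responding genes; and (iv) an eigengene
  shifted by 2 latent SDs has a population trait correlation of ≈ 0.71,
  far below the ≈ 0.89 needed for Bonferroni significance at $n = 6$.
  These are properties of the design, not of the algorithms; the
  acceptance suite runs this regime anyway and reports the measured rates.

Consequently, passing tests in the identifiable regime validate the
machinery, while the small-$n$ runs quantify honestly how little a
3-vs-3 design can support — which is useful context when interpreting any
real screen built on so few arrays.

# Numerical choices and problem sizes

* Quantile normalization is exactly idempotent (long-double accumulation
  in the row means makes re-application bitwise stable).
* Variance ties in gene filtering and probe collapsing break by input
  order; clustering labels are relabeled `M1, M2, ...` by decreasing size,
  so module labels are stable up to partition identity under gene
  permutations.
* All randomized components (generators, permutation tests, pipeline
  stages) take explicit seeds; the pipeline derives per-stage seeds by
  hashing the stage name with the global seed, so stages can be re-run in
  isolation and full runs are bit-reproducible. Caller RNG state is always
  restored.
* Simulation-based tests use 500–2,000 genes and 6–40 samples; the
  acceptance study-condition runs use 2,000 genes (6 modules of 150) and
  20 seeds, sizes at which the full adjacency/TOM pipeline runs in seconds
  while leaving the statistical structure of the default design intact.

# Known limitations

* The static dendrogram cut trades the adaptivity of dynamic tree-cut for
  determinism; very unevenly sized or nested modules may need a different
  `cutHeightFraction`.
* Permutation p-values are conservative (see above) and their resolution
  is $1/(B+1)$; ranking among highly significant compounds is therefore
  dominated by the tie-break at small `B`.
* Soft-threshold selection by scale-free fit is not implemented; $\beta$
  is a parameter (default 16).
* Consensus module analysis across multiple networks is out of scope.
* The compendium is synthetic or user-supplied; no public drug-profile
  database is downloaded or redistributed.
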