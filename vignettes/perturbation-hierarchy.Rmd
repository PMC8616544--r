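---
title: "Inferring a signalling hierarchy from combinatorial perturbation RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a signalling hierarchy from combinatorial perturbation RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbnem)
```

## The problem and the model

Three signalling perturbations — TGFβ treatment (`TGFB`), LATS1/2
knockdown activating YAP/TAZ (`LATS`), and Wnt-3a treatment (`WNT`) — are
applied to melanoma cells singly and in every double and triple
combination, in two cell lines with technical duplicates: 2 × 8 × 2 = 32
RNA-seq libraries. The question is the epistatic order of the three
pathways.

The nested effects model (NEM) answers it through a subset argument. If
the hierarchy contains `TGFB -> LATS`, then perturbing `TGFB` also
perturbs everything `LATS` controls, so the genes responding to the
`LATS` perturbation nest within those responding to `TGFB`. A candidate
hierarchy is a reflexive, transitively closed digraph $\Phi$ over the
three perturbed nodes (S-genes); every measured gene (E-gene) is assumed
to hang off exactly one node (its *attachment*) or off none. Under
$\Phi$, a gene attached at node $s$ is predicted to respond in exactly
the experiments that perturb some node from which $s$ is reachable. With
three S-genes there are 29 such quasi-orders, so the search is
exhaustive rather than heuristic.

### From counts to evidence

Stage one is ordinary count-based differential expression. For gene
expression $y$ across the 32 libraries we fit

$$y = \beta_0 + \beta_1 L + \beta_2\,\mathrm{TGFB} + \beta_3\,\mathrm{LATS}
    + \beta_4\,\mathrm{WNT} + \beta_5\,\mathrm{TGFB{+}LATS} + \cdots
    + \beta_8\,\mathrm{TGFB{+}LATS{+}WNT},$$

a negative-binomial log-linear model with a cell-line indicator $L$ and
one indicator per non-empty treatment combination, with
TMM/library-size offsets. Each combination coefficient is its own
contrast against control *accounting for the cell-line effect*; a
likelihood-ratio test per coefficient gives 7 p-values per gene, which
are BH-corrected within each contrast and binarized at 10% FDR for the
overlap/dominance analyses.

Stage two converts p-values into graded evidence. Pooled over all genes
and contrasts, the p-value distribution is modelled as a β-uniform
mixture

$$f(p) = \lambda + (1-\lambda)\,a\,p^{a-1}, \qquad a \in (0, 1],$$

uniform nulls plus a decreasing Beta($a$, 1) signal component. The NEM
input is the log density of the beta component,
$R = \log(a\,p^{a-1})$: because the uniform density is 1, $R$ is the
log likelihood ratio of "effect" against "no effect" — positive for
small p, and $\log a < 0$ at $p = 1$.

### Scoring hierarchies

For hierarchy $\Phi$ let $E_\Phi(s, j) \in \{0, 1\}$ be the predicted
effect of experiment $j$ on a gene attached at $s$ (with an all-zero row
for the null attachment). Gene $e$'s evidence for attachment $s$ is

$$A(e, s) = \sum_{j=1}^{7} R(e, j)\, E_\Phi(s, j),$$

so a hierarchy scores highly when positive $R$ fall on predicted 1s and
negative $R$ on predicted 0s. The attachment is a nuisance parameter and
is integrated out under a uniform prior over
$\{\mathrm{TGFB}, \mathrm{LATS}, \mathrm{WNT}, \mathrm{none}\}$:

$$\log P(R \mid \Phi) = \sum_e \log \sum_s \pi(s)\, e^{A(e, s)},$$

computed with a per-gene log-sum-exp. The best graph maximises this
marginal score over all 29 candidates; the per-gene softmax of
$A(e, \cdot)$ is the attachment posterior, and genes are assigned a
regulator when their winning posterior exceeds 0.9. Edge stability is
assessed by a nonparametric bootstrap that resamples genes with
replacement and re-runs the exhaustive search; because the per-gene
marginals depend on the graph but not on the other genes, the
genes × graphs marginal matrix is computed once and each bootstrap run
reduces to an indexed column sum, which keeps 10⁴ runs cheap.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` (binarization) | 0.10 | FDR threshold defining "responding" genes for overlaps, dominance, pattern filters |
| `prior_df` | 20 | prior degrees of freedom shrinking per-gene NB dispersions toward the pooled value |
| `prior` (NEM) | uniform over 4 | attachment prior; the `none` state absorbs non-responders so they cannot distort graph scores |
| `threshold` (regulators) | 0.9 | posterior needed to assign a gene to a node |
| `B` | 10000 | bootstrap runs; 100 suffices for the synthetic benchmark, 10⁴ matches screen-scale reporting |
| `eps` (BUM) | 1e-10 | lower clamp on p-values, since $p^{a-1}$ diverges at 0 |
| `component` | `"beta"` | evidence density; the full mixture is available behind the same flag |

Units: all fold changes are log2; dispersions are the NB
variance-inflation coefficient in $\mathrm{Var} = \mu + \phi\mu^2$
(dimensionless); p-values, FDRs and posteriors are probabilities.

## The synthetic generator

`generate_truth()` + `simulate_counts()` emulate the screen layout the
pipeline targets: two cell lines, eight conditions, technical
duplicates, and a nested response structure in which 10% of genes attach
to each hierarchy node (default chain `TGFB -> LATS -> WNT`) with
|log2 fold change| 2, per-gene NB dispersion 0.1, log-normal baselines,
a Normal(0, 0.5) per-gene log2 cell-line effect, and an expected library
size of 10⁶. Half of the Wnt-attached genes respond to the Wnt-3a single
treatment in the direction *opposite* to the upstream treatments, and an
upstream perturbation overrides the flip in combined treatments — the
two dominant empirical expression patterns, encoded so that the
concordance and dominance statistics have a known truth. These defaults
are deliberately strong-but-realistic: a 4-fold change at dispersion 0.1
and 4 libraries per condition is comfortably detectable, which is what a
recovery benchmark needs; weaker regimes can be dialled in through the
same arguments.

What the generator does **not** emulate: read-level artefacts (GC and
length bias, mapping multi-hits), biological replication across donors,
correlated gene modules, dispersion–mean trends, and genes attached to
more than one node. Passing the recovery benchmarks therefore
demonstrates correctness of the inference machinery under the model's
own assumptions, not robustness to everything real screens contain —
real-data FDR lists will also differ slightly from any specific DE
tool's empirical-Bayes variant.

## Numerical and design choices

- **Dispersion estimation.** Per-gene adjusted-profile-likelihood
  estimates shrunk toward the common dispersion with 20 prior degrees of
  freedom; a fixed-dispersion path exists for validation against an
  independently coded IRLS fit. Exact replication of any particular
  moderation trend is a non-goal.
- **Expression filter.** Genes need ≥ 1 count-per-million in ≥ 2
  samples; this conventional floor avoids degenerate GLM fits.
- **Technical duplicates** enter the model as independent observations
  (32 libraries, 9 coefficients); collapsing them first would discard
  within-condition variance information.
- **BH per contrast.** Correction is applied within each of the 7
  contrast columns; the BUM is fitted on the *pooled raw* p-values,
  since the evidence transform should reflect the global signal/null mix.
- **Beta vs mixture density.** $R$ uses the beta-component density; the
  mixture option is exposed, but the beta reading makes $R$ an exact
  log-odds against the unit-uniform null.
- **Tie-breaking.** Graph ties (identical scores, e.g. $R \equiv 0$) are
  broken toward fewer edges, then lexicographically on the adjacency
  pattern, so results are deterministic and uninformative data yield the
  empty hierarchy.
- **Reduction vs closure edges.** Bootstrap support is counted on each
  winner's transitive reduction (the display form of a hierarchy);
  closure-implied support is tallied alongside, since "no additional
  edges" claims are ambiguous between the two readings. The reduction
  keeps 2-cycles between mutually reachable (score-equivalent) nodes.
- **Gene resampling.** The bootstrap resamples E-genes, not experiments:
  with 7 informative experiments, experiment resampling would be far too
  coarse, and gene resampling is the established NEM practice.
- **Pattern 2.** Defined as: the Wnt-3a single contrast opposite in sign
  to the other six contrasts, which must agree among themselves — the
  strictest reading consistent with "Wnt regulates in the opposite
  direction of the other treatments".
- **Census eligibility.** The pattern census defaults to genes
  significant in at least one contrast at 10% FDR (a no-filter option
  exists); genes with an exactly zero fold change have no sign and are
  excluded with a logged count rather than arbitrarily signed.
- **Dominance calls** use the combined contrast's sign only; an optional
  gate additionally requires the combined contrast to be significant.
- **Wilcoxon sidedness** defaults to two-sided with one-sided options,
  and ties are mid-ranked. Fold-change clipping at |1| exists only in
  plot output, never in statistics.
- **Degenerate inputs.** p-values are clamped to `[1e-10, 1]`; all-zero
  samples, non-integer counts, unknown treatment tokens and rank-deficient
  designs raise descriptive errors; single-cell-line data make the
  batch-removal step a no-op.

## Problem sizes

The test suite exercises the full pipeline at 200–1000 genes × 32
samples, 20 seeds for chain recovery with 100-run bootstraps, 10⁴
simulated p-values for mixture recovery, and exhaustive enumeration
oracles (all 64 adjacency patterns, all $\binom{n}{m}$ rank placements
for $n \le 12$, literal 4-attachment sums). The acceptance script runs
ten full pipeline seeds plus a 1000-run bootstrap. These sizes were
chosen to make every stochastic check decisive at deterministic-grade
thresholds while keeping a complete run in the low minutes on one CPU.

## Known limitations

Exhaustive scoring is exponential in the number of S-genes and is capped
at 5; larger screens need greedy or MCMC search, which this package
deliberately omits. Each E-gene attaches to exactly one node — mixture
NEMs for heterogeneous populations are out of scope, as are hidden
S-genes. Identifier matching in the enrichment module is exact string
matching in the caller's namespace; cross-namespace mapping is the
caller's responsibility. The DE stage targets this screen's design
(two cell lines, eight fixed conditions); arbitrary designs are not the
goal.
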