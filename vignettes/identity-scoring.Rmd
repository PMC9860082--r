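---
title: "Scoring in-vitro cell identities against a reference atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring in-vitro cell identities against a reference atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scwheel)
```

## The question the pipeline answers

Differentiation protocols aim to turn pluripotent cells into a target
type — here, midbrain dopaminergic (mDA) neurons — but invariably
produce a mixture: the intended lineage at several maturation stages,
plus related ventral-midbrain types (floor-plate and midline
progenitors, neuroblasts, oculomotor/trochlear neurons) and off-target
types such as VLMCs. A useful quality metric must therefore be graded,
not categorical: for each cluster of cultured cells, *how much* does it
resemble each endogenous reference type?

`scwheel` answers this with classifier-based label transfer. A
one-vs-rest (OvR) logistic regression is trained on a labeled reference
atlas; each query cell then receives a probability vector over the
reference types, and clusters are summarized by the mean probability of
their best-matching type — the *similarity score* — banded as
moderate (0.5–0.79) or high (0.8–1.0).

## The mapping model

For reference type $k$ with training indicator $y_i \in \{0, 1\}$, the
fit minimizes the penalized negative log-likelihood

$$\sum_i \big[\log(1 + e^{\eta_i}) - y_i \eta_i\big]
  + \tfrac{\lambda}{2}\lVert w_k \rVert^2,
  \qquad \eta_i = b_k + x_i^\top w_k,$$

on log-library-size normalized expression
$x = \ln(1 + s\,c/\ell)$ (count $c$, library size $\ell$, scale
$s = 10{,}000$), with no feature standardization. At prediction time the
per-type sigmoids $\sigma(\eta_k)$ are renormalized to sum to one per
cell.

Choices worth making explicit:

* **OvR + renormalization rather than multinomial softmax.** The
  per-type similarity reading — "this cell resembles an mDA neuron with
  probability 0.9" — treats each reference type as its own membership
  question; OvR matches that reading directly, and renormalization puts
  rows on the simplex so downstream geometry (bands, wheel) is well
  defined. A softmax fit gives similar rankings on separable data but
  couples the classes; we fixed one convention and state it in the
  model object (`scheme = "ovr"`).
* **Ridge penalty $\lambda = 1$** on normalized features. The penalty
  mainly guards against the perfect separability that marker genes
  create; results are insensitive over orders of magnitude because the
  renormalization cancels common scaling.
* **Optimization.** L-BFGS from a zero start, followed by up to five
  damped Newton steps when the line search stalls before the gradient
  tolerance (infinity norm of the per-cell-averaged gradient below
  1e-6). A warning names any type that still misses the tolerance.
  The objective is strictly convex, so the fit is deterministic.

### Bands and the per-cell threshold

Band edges are the reporting convention of the field's wheel figures:
`[0.5, 0.8)` moderate, `[0.8, 1]` high, below 0.5 flagged and usually
hidden. The printed convention "0.5–0.79 / 0.8–1.0" is implemented
half-open so every score has exactly one band. The per-cluster
"fraction of highly resembling cells" uses the same 0.8 cutoff at the
cell level; a published per-cell cutoff is not available, so mirroring
the cluster-level band is the least surprising choice.

### Wheel geometry

With $K$ types at vertices $v_j = (\cos 2\pi j/K, \sin 2\pi j/K)$, a
cell with probability row $p$ is drawn at $\sum_j p_j v_j$. One-hot rows
land exactly on vertices, the uniform row at the origin, and every cell
stays inside the polygon because rows are convex weights. Vertex order
is configurable (default: reference vocabulary order); the wheel is a
projection, so cells with different probability vectors can coincide —
it is a display, not a metric space.

## Clustering

The query is clustered independently of the mapping, Cytograph-style:
PCA on the shared feature space (default $d = 50$, capped by the data
rank; component signs fixed by making the largest-magnitude loading
positive), a mutual kNN graph ($k = 15$, Euclidean, ties broken by the
lower cell index, unit weights), and Louvain modularity optimization
(resolution 1.0, `igraph` implementation, node order seeded). Labels
are re-indexed by first appearance so a fixed seed reproduces them
exactly. Louvain rather than Leiden keeps faith with the workflow this
pipeline emulates; the partition object is plain enough that a Leiden
partition can be substituted anywhere one is accepted.

## Panel statistics

**Permutation test.** The statistic is the sum over a gene panel of the
per-gene mean normalized expression in a cell group. The null permutes
*cell group labels* across the pooled focal + comparison cells —
the hypothesis concerns cell groups, so cells are the exchangeable
unit (permuting genes or residuals would test a different null). With
the alternative "greater" and the add-one estimator,
$p = (1 + \#\{T^\ast \ge T\})/(1 + n_{\mathrm{perm}})$, the p-value is
never zero and exact exchangeability holds for constant input
($p = 1$). Default $n_{\mathrm{perm}} = 1000$.

**Enrichment calls.** Marker enrichment compares detection fractions
(count ≥ 1 UMI) between a focal type and the rest via independent
binomials with Jeffreys Beta(½, ½) priors;
$P(\theta_f > \theta_r \mid \text{data})$ is computed by numerical
integration of the Beta densities (relative tolerance 1e-10) and
thresholded at 0.998. This is a deliberately simple Bayesian stand-in
for trinarization-style callers; it is monotone in the focal successes
and anti-monotone in the background successes.

## What the synthetic generator does and does not emulate

Each type is a program: lognormal per-gene baseline propensities
(meanlog 0, sdlog 1), markers multiplied by $2^{\text{log2fc}}$,
programs normalized to proportions. A cell draws a lognormal library
size and negative-binomial counts with mean `library_size x program`
and size (inverse overdispersion) 2. Defaults are the study-scale
conditions used throughout the tests: 10 types, 200 cells/type, 2,000
genes, 30 markers/type, log2 fold-change 3, and mean library sizes near
10,000 UMIs — inside the 6,753–15,482 range typical of the droplet
datasets this generator stands in for. Mixed-identity cells are *convex
mixtures* of two programs, emulating transitional progenitors; doublets
would instead add counts and inflate library size, which is exactly
what we do not want to model.

Not emulated: ambient RNA, doublets, batch effects beyond an optional
per-line library-size shift, gene–gene correlation within programs,
spliced/unspliced layers. Passing tests therefore demonstrate that the
pipeline recovers planted structure under a clean, overdispersed count
model — they do not certify performance on real data with contamination
or batch structure. The expression model itself (lognormal ×
negative binomial) is this package's choice; published descriptions of
the reference atlas do not specify one.

## Numerical and degenerate-input conventions

* QC filters cells first (on the full gene set), then genes (support
  counted on retained cells), in one pass; cell totals are not
  recomputed after gene removal. With borderline thresholds a second
  application could remove further cells; under the generator's
  conditions the margins are wide and filtering is idempotent, which
  the tests check there.
* Normalization requires strictly positive library sizes and errors
  with the offending cell ids; zeros are preserved exactly because only
  the stored nonzeros are transformed.
* Ties everywhere (argmax assignments, kNN distances, dominant mixture
  type) break to the lowest index, for determinism.
* An empty query yields empty, correctly-dimensioned outputs rather
  than errors; an all-zero cell under a zero-weight model scores the
  uniform row $1/K$.
* All stochastic stages take explicit integer seeds; the pipeline
  derives per-stage seeds from one global seed, and reruns are
  byte-identical (checked via MD5 in the manifest and tests).

## Problem sizes used in the tests

Unit tests run on compact fixtures (2–5 types, 40–100 cells/type,
100–600 genes) chosen so every oracle can be recomputed by brute force;
the end-to-end checks use the generator defaults (10 types, 2,000
cells, 2,000 genes) for mapping, 3 × 100 cells for cluster recovery,
1,000 simulations × 199 permutations for the type-I error rate, and
10⁶ Monte-Carlo draws for the Beta-posterior oracle. These sizes give
stable statistics while keeping the whole suite fast enough to run
habitually.

## Known limitations

* No cross-dataset harmonization: the classifier assumes reference and
  query share a comparable normalized scale on the intersected feature
  space. Appended reference classes from other datasets (e.g. VLMCs)
  are treated as ordinary classes.
* No rejection class: a cell unlike every reference type still gets a
  simplex row; such cells show up as low-similarity clusters rather
  than "unassigned".
* The permutation test reports raw p-values; no multiplicity
  correction is applied across panels.
* UMAP displays and trajectory analyses are out of scope; the wheel
  plot is the package's native visualization.
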