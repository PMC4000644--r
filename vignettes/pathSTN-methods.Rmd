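---
title: "Two-stage signaling-pathway inference: models, tuning and design notes"
author: "pathSTN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage signaling-pathway inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathSTN)
```

## The problem

Small-cohort expression studies (tens of samples, thousands of genes)
can rank genes by phenotype association but cannot, by themselves,
resolve the wiring of a signaling pathway. Protein–protein interaction
(PPI) graphs carry wiring but no phenotype. `pathSTN` reconstructs the
signal transduction network (STN) between a designated start protein and
end protein by combining the two: a network-constrained regression picks
the phenotype-associated genes, and an exactly solved binary program
stitches them, through correlation-weighted PPI edges, into a subnetwork
anchored at the two proteins.

## Stage 1: network-constrained gene selection

The response is the centered ordinal disease stage (0–3). The original
study never states its response variable; the ordinal stage is the
natural choice for a four-group design ordered by severity, and the
generator adopts it throughout. Predictors are standardized to mean 0 and
*unit sum of squares* per gene — the normalization under which the
penalized criterion

$$L(\lambda_1, \lambda_2, \beta) =
  (\mu - X\beta)^\top(\mu - X\beta) + \lambda_1\lVert\beta\rVert_1 +
  \lambda_2\, \beta^\top L \beta$$

is interpreted (the squared-error term is deliberately unscaled; penalty
magnitudes live on that scale). $L$ is the normalized Laplacian of the
gene network restricted to the post-filter gene set: diagonal 1 for
connected nodes, $-w(u,v)/\sqrt{d_u d_v}$ for adjacent pairs, zero rows
for genes that are isolated or absent from the network — those genes feel
a pure lasso penalty. Its eigenvalues lie in $[0, 2]$, so the quadratic
term is positive semi-definite and the criterion is convex.

Minimization goes through the standard lasso-type reduction: factor
$L = S^\top S$ by symmetric eigendecomposition (tiny negative eigenvalues,
a numerical artifact, are clamped at $-10^{-10}$), append
$\sqrt{\lambda_2}\,S$ to the design and zeros to the response, and run
cyclic coordinate descent with Gram-matrix updates. Each coordinate step
is the exact scalar soft-threshold at $\lambda_1/2$; the criterion is
evaluated after every sweep and asserted non-increasing; convergence is
$\max_j |\Delta\beta_j| < 10^{-7}$ with a budget of $10^4$ sweeps
(exceeding it is an error carrying the objective trace, never a silent
partial fit).

### The ANOVA prefilter

Genes first pass a classical one-way F-test across the phenotype groups.
The filter *retains* genes with $p < \alpha$ (default 0.05): the retained
genes are the ones treated as phenotype-relevant downstream. The
complementary reading — removing small-p genes — is preserved as
`mode = "literal"` for audit, because the verbal form of this rule is
ambiguous in the literature this package follows. Genes with zero
variance everywhere are dropped with a warning (F undefined); a gene with
zero within-group variance but distinct group means has $p = 0$ and is
retained.

### Tuning

$(\lambda_1, \lambda_2)$ are chosen by 10-fold cross-validation on mean
held-out squared prediction error. Folds come from a seeded shuffle with
sizes differing by at most one. The default grid runs $\lambda_1$
geometrically over 25 points from $\lambda_{\max} = 2\max_j |x_j^\top\mu|$
(the smallest value that zeroes every coefficient) down to
$10^{-3}\lambda_{\max}$, with $\lambda_2 \in \{0, 0.5, 2\}$ spanning
no smoothing to strong smoothing on the unit-sum-of-squares scale.
Two grid points whose CV errors differ by less than the standard error
of the minimizer's fold means are treated as tied — errors that close are
statistically indistinguishable at $n \approx 32$ — and ties resolve
toward larger $\lambda_1$, then larger $\lambda_2$: the sparser, smoother
model. This is the usual one-standard-error convention; with plain
argmin selection the CV noise at these sample sizes systematically drags
in noise genes. Genes with $|\beta| > 10^{-8}$ (strict) are reported,
ordered by magnitude.

## Stage 2: exact subnetwork extraction

Every PPI edge gets weight $w_{ij} = |r_{ij}|$, the absolute Pearson
correlation of the two genes' expression vectors. The absolute value is
a deliberate choice: the extraction objective only rewards large
weights, yet strong *negative* co-expression is equally informative of a
functional link; `signed = TRUE` keeps raw $r$ for audit. Edges with an
unmeasured or zero-variance endpoint get weight 0 — selectable for
connectivity, at pure penalty cost.

The binary program minimizes
$S = -\sum w_{ij} y_{ij} + \lambda \sum y_{ij}$ over edge indicators
$y$ and node indicators $x$, subject to $y_{ij} \le x_i, x_j$; degree
$\ge 1$ at the anchors; degree $\ge 2 x_i$ elsewhere; $x_i = 1$ for the
stage-1 genes present in the graph. The symmetric double sums are
canonicalized to one variable per unordered edge; $\lambda$ (default
0.65) is interpreted per edge. Because each selected edge contributes
$\lambda - w_{ij}$, larger $\lambda$ yields smaller networks; the
selected-edge count is non-increasing in $\lambda$, and `sweepLambda()`
tabulates the trade-off for choosing a penalty by target size. (A verbal
description of this parameter circulating in the literature has the
direction inverted; the mathematics is unambiguous.)

Two properties of the constraint system are worth knowing. First, it
does not enforce global connectivity: disjoint cycles satisfy every
degree constraint, so the optimum may be a union of components — these
are reported as such by `extractComponents()` rather than patched with
extra constraints, matching the disconnected character of real result
networks. Second, a fixed node must reach degree 2 in any feasible
solution, exactly as the constraint is written; a fixed node with graph
degree below 2, or an isolated anchor, makes the instance infeasible and
is named in a structured diagnostic before any solving.

### Solving exactly

No incumbent-with-gap or time-limited answer is ever returned: the
solver either proves optimality or raises an error. It is a depth-first
branch-and-bound over edge variables with dynamic branching (serve a
degree-deficient node's cheapest edge first; otherwise take the cheapest
objective-lowering edge; when neither exists, excluding the rest is an
optimal and lexicographically minimal completion). The lower bound
charges all undecided objective-lowering edges plus a repair term for
degree-deficient nodes — their missing incident edges at the cheapest
nonnegative costs, halved when an edge could serve two deficient
endpoints. Among optimal assignments, the lexicographically smallest
indicator vector in canonical edge order is returned; the enumeration
oracle (`bruteForceOracle()`, all $2^{|E|}$ subsets, at most 20 edges)
applies the identical tie-break, and the test suite holds the two equal
on random instances including fixed-node and infeasible cases. Every
returned solution is re-checked against the constraints by code
independent of the solver, and its objective is recomputed from the
assignment.

## The synthetic ground truth

`simulationConfig()` defines the reference study: 4 ordinal groups × 8
samples (emulating a small hippocampal cohort of about 31), 60 genes,
noise SD 1. Two structures are planted:

* **Support**: `nSupport = 5` genes carry mean
  `effectSize × group × noiseSd` (`effectSize = 2`) — the regression's
  target. Support genes are *mutually* correlated through the shared
  group effect (about 0.83 here), which is what makes selection
  non-trivial at these effect sizes.
* **Path**: a start→end chain of `pathLength = 3` intermediates whose
  genes share a per-sample latent factor with loading
  `pathCorrelation = 0.9` plus independent residual of variance
  $1 - 0.9^2$, giving pairwise Pearson correlation $0.81$ — the
  extraction stage's target. All other genes are i.i.d. noise.

The two plantings are disjoint in *expression* — overlapping them drives
the support genes' mutual correlation to ~0.97 and no sparse selector
can separate them — but adjacent in the *graph*: each support gene is
linked to two seeded path nodes, emulating transduction factors that
neighbor the pathway backbone. This adjacency is what makes fixing the
selected genes into the extraction program coherent: their mandatory
second edges attach to the backbone instead of dragging arbitrary
repair neighbors into the network. The background graph is preferential
attachment with `m = 2` (Erdős–Rényi available), vertex labels randomly
permuted, planted edges injected afterwards and deduplicated — so
planted-edge containment holds for every configuration. The default gene
count keeps the exact solver's optimality proof to seconds per instance;
the regression recovery experiments use 200 genes, where stage 1 does
not involve the solver.

What the recovery experiments show — and do not. With these conditions
the cross-validated selection attains median F1 ≈ 0.83 against the
planted support (25 replicates, 200 genes), the extraction stage
recovers all planted path edges in ≥ 90% of replicates at
`pathCorrelation = 0.95`, and the composed pipeline reaches median F1 ≈
0.9 on the planted module. These are statements about a Gaussian
latent-factor world with a single planted module and clean group
structure; real microarray data add probe-level artifacts, batch
effects, heavy tails, correlated nulls and database-dependent networks,
none of which the generator emulates. Passing these tests certifies the
*implementation* (the estimator solves its program; the solver is
exact; recovery behaves as theory predicts), not field performance on
any particular dataset.

## Numerical and degenerate-input conventions

* Zero-coefficient tolerance $10^{-8}$, strict inequality.
* Laplacian PSD clamp at $-10^{-10}$; anything more negative is an error.
* Objective ties in the extraction program: $10^{-9}$ absolute, resolved
  lexicographically as above, so reruns and the oracle agree exactly.
* Constant genes: dropped (with a warning) by the filter, a hard error
  in `standardizeExpression()` — they cannot be scaled to unit sum of
  squares.
* Duplicate edges collapse to the maximum weight; self-loops are
  discarded; negative input weights are a hard error.
* Manifests are byte-reproducible given (config, seed) except wall-clock
  fields; each pipeline stage derives its own seed from the run seed by
  a fixed label, so adding a stage never perturbs earlier stages' draws.

## Known limitations

* The extraction program is NP-hard in general; the exact solver is
  meant for the desk-scale instances the package documents (tens of
  nodes, a few hundred edges). Genome-scale PPI graphs (10⁴ nodes) are
  out of its tested envelope.
* The Laplacian penalty helps only insofar as the gene network links
  co-associated genes; with an uninformative network, CV simply prefers
  $\lambda_2 = 0$ and the method degrades to the lasso.
* Degree-1 fixed nodes make instances infeasible by construction (the
  degree-2 constraint is implemented as written); the diagnostic names
  the offending nodes so the caller can drop or re-map them.
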