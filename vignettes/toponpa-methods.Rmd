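---
title: "Scoring network perturbation from gene fold-changes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring network perturbation from gene fold-changes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toponpa)
library(tibble)
```

## The two-layer model

Curated cause-and-effect network models of a biological process come in two
layers. The *backbone* (functional layer) contains upstream biological
entities — kinase activities, transcription-factor activities, abundances of
compounds — connected by signed, directed edges: `taof(AHR) -> geneX` with a
`+` means increased AHR transcriptional activity increases the target;
a `-` means it represses it. The *transcript layer* contains the genes whose
differential expression is actually measured; each backbone node points at
the set of genes it is known to regulate. Transcript nodes are pure sinks:
no edges leave them.

The backbone quantities are not measured. Under the *backward assumption* —
observed gene expression changes are consequences of upstream activity
changes — they can be inferred from the measured gene log2 fold-changes
$\beta$. `toponpa` does this by solving the signed smoothing problem

$$\min_{f} \sum_{x \to y} w(x,y)\,\bigl(f(x) - \sigma(x \to y) f(y)\bigr)^2
  \quad \text{s.t.} \quad f|_{\text{transcript}} = \beta ,$$

a Dirichlet boundary-value problem on the graph: the transcript layer
supplies boundary values, and the fit propagates them through the signed
wiring. With $L$ the signed Laplacian of the underlying undirected graph,
$L_3$ its backbone block and $L_2$ its backbone-by-transcript block, the
unique solution is the linear map

$$f = -L_3^{-1} L_2\, \beta .$$

$L_3$ is irreducibly diagonally dominant — hence invertible — whenever the
undirected backbone is connected and at least one backbone node has a
measured downstream gene. These two conditions are exactly what
`validate_network()` enforces. The published formulation asks for strong
connectivity of the directed graph, but only the undirected backbone
condition is used by the invertibility argument, so that is what we
validate (with `largest_component = TRUE` available to proceed on the
largest piece of a fragmented model).

### Edge weights

Literature coverage is uneven: a well-studied node may have hundreds of
curated downstream genes, an obscure one a dozen. To stop coverage from
masquerading as importance, each backbone node's transcript out-edges are
weighted $1/n_x$ ($n_x$ = number of its measured downstream genes), so each
node places one unit of total weight on the transcript layer. Backbone
edges keep weight 1 unless the model supplies explicit weights.
`normalize_downstream_weights()` also intersects the transcript layer with
the measured genes first, so weights renormalize to the genes actually on
the platform.

## The perturbation score

The Network Perturbation Amplitude summarizes the inferred backbone values
into a single number,

$$\mathrm{NPA} = \frac{1}{C} \sum_{x \to y \in \text{backbone}}
   w(x,y)\bigl(f(x) + \sigma(x \to y) f(y)\bigr)^2
   \;=\; \frac{1}{C}\, f^\top Q f ,$$

an "energy" accumulated over backbone edges: a positive edge between two
co-moving nodes, or a negative edge between two opposing nodes, contributes
a large term. $Q$ is the signed Laplacian of the backbone with all signs
flipped and $C$ the backbone edge count; dividing by $C$ puts networks of
different size on the same scale (units: squared log2 fold-change per
backbone edge). An edge-based score avoids the destructive interference a
node-sum score suffers when two strongly moved subnetworks oppose each
other across a single edge.

Rayleigh quotients give the envelope
$\|f\|^2 \lambda_{\min}(Q)/C \le \mathrm{NPA} \le \|f\|^2 \lambda_{\max}(Q)/C$.
The lower end vanishes exactly when the sign-flipped backbone is *balanced*
(every cycle has positive sign product), in which case — and only then — a
nonzero profile can score zero: the kernel of $Q$ is the one-dimensional
space of profiles constant $+c$ on one side of the balance partition and
$-c$ on the other. `is_balanced()` decides this combinatorially by
two-coloring, and the test suite checks it against the spectrum of $Q$.

### Leading nodes

Writing the score as $\frac{1}{C}\sum_y (Qf)(y) f(y)$ attributes to each
node the share $100\,(Qf)(y) f(y) / (C \cdot \mathrm{NPA})$ percent.
Shares sum to 100 exactly; individual shares can be negative when a node
locally contradicts the signed structure. Nodes are ranked by decreasing
share (ties broken alphabetically so output is reproducible) and the
minimal prefix accumulating 80% of the score is flagged as the *leading
nodes* — the default threshold is a well-established empirical choice, and
`leading_nodes()` accepts any fraction in $(0,1]$. Negative shares are
accumulated in rank order; this preserves the sum-to-100 identity, at the
price that the leading set can occasionally extend past the first crossing.
Whether signed or absolute shares should feed the cumulative rule is not
settled usage; the signed choice is ours and is visible in the
`cumulative` column.

## Uncertainty

For a standard two-group comparison with homoscedastic groups, covariances
between per-gene fold-changes cancel, so
$\beta \sim N(\mu, \mathrm{diag}(\mathrm{var}\,\beta_i))$ with the per-gene
variances taken from the differential-expression fit (e.g. squared standard
errors of a limma coefficient). Linearity then gives the backbone
covariance $\Sigma_2 = M \,\mathrm{diag}(\mathrm{var}\,\beta)\, M^\top$
with $M = -L_3^{-1} L_2$, and the classical quadratic-form moments give

$$\mathrm{var}(\mathrm{NPA}) =
  \frac{2\,\mathrm{tr}(Q\Sigma_2 Q\Sigma_2) + 4\,\mu_2^\top Q\Sigma_2 Q \mu_2}{C^2}.$$

`confidence_interval()` is the CLT interval; its lower limit is not clipped
at zero because "lower limit above zero" is precisely the criterion for
significance against experimental variation. The formula is validated in
the test suite against the empirical variance of $10^5$ Gaussian draws on
twenty random systems, and interval coverage is checked at the nominal 95%
over a thousand resampled datasets.

## The companion statistics

A score can be significant against experimental noise yet owe nothing to
the network. Two permutation tests probe specificity, each with the add-one
estimator $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$ (never exactly
zero; $B = 500$ by default):

* **O** reshuffles the measured fold-changes across the transcript-layer
  positions of the network and rescores. It asks whether *which gene sits
  under which node* matters. By default values are permuted among the
  network's own transcript nodes; `pool = "all_measured"` draws from every
  measured gene instead.
* **K** replaces the backbone wiring by a uniformly random simple edge set
  of the same size over the same nodes, reassigns the original multiset of
  signs, re-infers $f$ under the rewired Laplacian, and rescores **with the
  original** $Q$ — keeping the spectral ceiling $\lambda_{\max}(Q)$ fixed
  across draws. Rewirings whose backbone is disconnected or numerically
  singular are rejected and redrawn (the count is reported). A
  `degree_preserving = TRUE` variant rewires by double-edge swaps instead.
  The published description says only that edges are "randomly permuted";
  the uniform ensemble and the redraw policy are our documented choices.

A network is reported as *specifically perturbed* when both p-values fall
below 0.05, with a 0.05–0.1 band flagged as marginal; `print()` and the
written reports mark these with the `*`, `O`/`o`, `K`/`k` convention.

### A calibration caveat for K

O is an exchangeable permutation test: under data that carry no signal its
p-value is uniform, and the suite verifies this (KS test over 400
replicates, rejection at 5% inside the binomial band). K is *not* exactly
calibrated, and the suite documents this honestly rather than hiding it:
the observed score pairs $f$ with the $Q$ of its own wiring, while every
null draw pairs a rewired fit with the original $Q$. A fit is always
smooth with respect to its own signed backbone, and smoothness on the
backbone is literally high energy on its sign-flip — so the matched
observed pairing is systematically somewhat inflated even for pure-noise
data. Across backbones of 8–30 nodes we measure null rejection of
roughly 0.07–0.16 at nominal 0.05 (for both the uniform and the
degree-preserving ensembles; the corresponding acceptance check is left
failing by design). Practically: treat K as a useful specificity screen
whose nominal level understates its false-positive rate about twofold, and
rely on the joint O-and-K call, which the power simulations show is reached
in ≥95% of strongly planted replicates.

## Sample-level signatures

Because the gene-to-backbone transform is one fixed linear map, individual
(centered) expression profiles can be pushed through it:
$B = -L_3^{-1} L_2 X_c$ maps a genes-by-samples matrix to a
backbone-by-samples matrix of per-sample differential values — a strong
dimension reduction (dozens of features instead of thousands) whose
coordinates are interpretable network nodes. Linearity guarantees
*coherence*: the difference of treated and control group means of $B$
equals the backbone values inferred from the group-mean fold-changes (the
suite asserts this to 1e-10), so scoring and classification live in the
same space. Centering is the only data-dependent step; for external-cohort
prediction the training-cohort gene means should be supplied as the
centering reference of the test cohort (the default in our examples —
re-centering a test cohort by its own means is also supported but mixes
test information into the features). Classifiers themselves are out of
scope; `inst/examples/classify_cohort.R` shows LDA on backbone features
versus raw genes, and the test suite verifies that cross-validating mapped
features equals mapping inside every fold.

## The synthetic-data generator

All validation runs on generated data with known truth; nothing is
downloaded. The generator mirrors the shape of curated models — a connected
backbone of dozens of nodes (random spanning tree plus extra edges with
probability `edge_p`, or a uniform connected edge set via
`backbone_model = "uniform"`), each node with an exclusive block of
downstream genes (default 15–25, about a thousand genes for a 50-node
backbone, with ~10% of nodes having none) and signs negative with
probability 0.3. Gene-level data implement the backward assumption
generatively: each gene's expected log2 fold-change is the sign-weighted
mean of its regulators' planted values plus Gaussian noise (default sd 0.1,
homoscedastic, matching the CI derivation; a heteroscedastic option
exists), and the default effect scale is 1 — comfortably above that noise,
as in a clear biological contrast.

Two design points deserve a note:

* **Exactly recoverable truth.** A planted profile is recovered exactly at
  zero noise only if it is stationary for the backbone part of the
  objective as well as matching the gene data. The default
  (`consistent = TRUE`) study therefore draws node polarities
  $s(x) = \pm 1$, sets backbone signs $\sigma(x,y) = s(x)s(y)$, and plants
  $f^* = c\,s$ — a profile satisfying every signed relation simultaneously.
  The suite confirms bit-level recovery at zero noise and correlation
  above 0.9 at noise sd 0.1 on the 50-node/1000-gene scale.
  `consistent = FALSE` plants i.i.d. Gaussian values instead for
  calibration and power studies.
* **Exclusive gene blocks.** Genes with a single regulator make the
  zero-noise oracle sharp. Shared downstream genes, probe-level artifacts,
  correlated noise, and annotation errors in real curated models are *not*
  simulated, so passing tests demonstrate correctness of the computations,
  not robustness to curation noise.

## Numerical choices

* $L_3$ is symmetric positive definite under the validated preconditions;
  solves use a cached Cholesky factor, never an explicit inverse. A
  condition number above 1e12 is treated as structural singularity and
  produces a connectivity diagnosis rather than garbage values.
* The quadratic-form and explicit edge-sum evaluations of the score are
  both computed on every call and must agree to 1e-10 — a free structural
  self-check of matrix assembly.
* Self-loops are rejected at validation (their degree contribution to the
  stated formulas is ambiguous); duplicate directed edges are rejected at
  construction; reciprocal backbone edges with contradictory signs are
  flagged by validation.
* Problem sizes in the test suite (backbones of 3–50 nodes, up to ~1000
  genes, $B$ of 100–200, 400-replicate calibration runs) are chosen so the
  full suite completes in a few minutes while keeping every Monte-Carlo
  band at 3 standard errors or tighter.

## A worked toy example

Two backbone nodes `a -> b` (+), one gene each, all weights 1. With
$\beta = (1, 1)$ and per-gene variance 0.01:

```{r toy}
expr <- tibble(gene = c("g1", "g2"), log2fc = c(1, 1), variance = 0.01)
fit <- npa(expr, toy_network(), B = 100, seed = 1)
fit
glance(fit)
tidy(fit)
```

Here $L_3 = \begin{pmatrix} 2 & -1 \\ -1 & 2 \end{pmatrix}$,
$f = (1,1)$, $Q$ is the all-ones matrix, $C = 1$, and the score is
$(1+1)^2 = 4$ — which also attains its spectral upper bound
$\|f\|^2 \lambda_{\max}(Q)/C = 2 \cdot 2 / 1$ because $f$ is the top
eigenvector of $Q$. Both permutation p-values are 1: with two genes of
equal fold-change every relabeling is identical, and a two-node backbone
admits exactly one wiring — the degenerate cases the report flags.

## Known limitations

* The K statistic's nominal level is optimistic (see above).
* The CI rests on homoscedasticity between groups and on a CLT
  approximation; for very small backbones the quadratic form is visibly
  skewed and coverage can dip slightly below nominal.
* Balance detection treats reciprocal contradictory edges as unbalanced by
  convention.
* The generator's exclusive-gene, homoscedastic design is the sharpest
  oracle, not the most realistic data model.
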