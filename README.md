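# toponpa

Quantifying the perturbation of two-layer cause-and-effect network models
from gene-level differential expression.

## The problem

Curated biological network models describe a process (inflammation, cell
cycle, xenobiotic metabolism, ...) as a signed, directed **backbone** of
functional nodes — kinase and transcription-factor activities, compound
abundances — each pointing at the **transcript-layer** genes it is known to
regulate. Transcriptomics measures only the gene layer. Analysts who want
to say *how strongly, and how specifically, a treatment perturbed this
network* need the unmeasured backbone quantified from the measured genes.

`toponpa` is for computational biologists doing exactly that: it infers
differential backbone values from gene log2 fold-changes, condenses them
into a single Network Perturbation Amplitude (NPA) score with confidence
interval and two permutation-based specificity statistics, decomposes the
score into leading nodes, and maps individual samples into backbone space
for use as low-dimensional classification features.

## The method in brief

Given log2 fold-changes β on the transcript layer, the backbone values f
solve the signed smoothing problem

    min_f  Σ_{x→y} w(x,y) (f(x) − σ(x→y) f(y))²   s.t.  f = β on the transcript layer,

a Dirichlet boundary-value problem on the graph with closed form
**f = −L₃⁻¹L₂β**, where L₃ and L₂ are blocks of the signed graph Laplacian.
Transcript edges of a node with n_x downstream genes are weighted 1/n_x so
literature coverage does not masquerade as importance. The score is the
edge-normalized energy

    NPA = (1/C) Σ_{backbone edges} w(x,y) (f(x) + σ(x→y) f(y))²  =  (1/C) fᵀQf,

with Q the signed Laplacian of the sign-flipped backbone and C the backbone
edge count. Per-gene variances propagate to a CLT confidence interval via
the quadratic-form variance 2·tr(QΣ₂QΣ₂) + 4·μᵀQΣ₂Qμ (scaled by 1/C²). Two
permutation tests ask whether the score is specific to the network: **O**
reshuffles fold-changes across transcript positions, **K** rewires the
backbone and rescores with the original Q. Nodes contributing the top 80%
of the score are the **leading nodes**, and **B = −L₃⁻¹L₂X** maps centered
per-sample profiles into backbone space.

## Worked example

Everything below is synthetic — the package ships a generator with known
planted truth so the whole pipeline can be exercised end to end.

```r
library(toponpa)

study <- simulate_study(n_backbone = 12, edge_p = 0.25, p_neg = 0.3,
                        genes_per_node = c(8, 12), p_no_genes = 0.1,
                        effect = 1, noise_sd = 0.1, seed = 42)
fit <- npa(study$expression, study$network, B = 500, seed = 7)
fit
#> <npa> score = 4.011 (squared log2FC per backbone edge)
#>   95% CI [3.863, 4.158] *
#>   O p = 0.001996  K p = 0.001996 (B = 500)
#>   specificity: *OK (specifically perturbed)
#>   leading nodes (80%): bb001, bb009, bb002, bb004, bb005, bb007, bb006, bb003, ...
```

The planted backbone profile has unit magnitude, so on a consistent
network the true score is the mean squared edge sum ≈ 4; the fit recovers
4.011 with a tight interval (the `*` marks a lower confidence limit above
zero, i.e. significance against experimental noise). Both permutation
p-values are at their minimum 1/(B+1) ≈ 0.002 — the signal sits exactly on
this network's wiring, so reshuffling genes (O) or rewiring the backbone
(K) destroys it; the joint call is "specifically perturbed".

Per-node results come out tidy:

```r
tidy(fit)
#> # A tibble: 4 × 7   (first rows shown)
#>   node  value contribution direction  rank cumulative leading
#> 1 bb001 1.00         14.3  +             1       14.3 TRUE
#> 2 bb009 1.00         11.9  +             2       26.3 TRUE
#> 3 bb002 1.00         11.9  +             3       38.2 TRUE
#> 4 bb004 1.000         9.51 +             4       47.7 TRUE
```

`value` is the inferred differential backbone value (same units as a log2
fold-change), `contribution` its percent share of the score (shares sum to
100), and `leading` flags the minimal ranked prefix reaching 80%.
`glance(fit)` gives the one-row summary, `autoplot(fit)` the contribution
bar chart, and `autoplot(fit$o)` / `autoplot(fit$k)` the permutation null
distributions.

On the fully hand-checkable toy network (`a -> b`, one gene each,
β = (1,1)): L₃ = [[2,−1],[−1,2]], f = (1,1), Q = [[1,1],[1,1]], C = 1,
score = (1+1)² = 4, attaining its spectral upper bound ‖f‖²λ_max(Q)/C = 4.

Per-sample signatures for classification:

```r
cohort <- simulate_study(n_backbone = 12, genes_per_node = c(8, 12),
                         cohort = TRUE, n_per_class = 25, seed = 1)
net <- normalize_downstream_weights(cohort$network)
sys <- build_laplacians(net)
b <- map_samples_to_backbone(sys, center_expression(cohort$cohort$x))
autoplot(b, labels = cohort$cohort$labels)   # samples in backbone space
```

`inst/examples/classify_cohort.R` feeds these features to an ordinary LDA;
`inst/cli/toponpa.R` wraps the pipeline as a command line
(`score | signature | simulate | validate`) over TSV/JSON files.

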