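# mfd — metadata-guided feature disentanglement for sequence-based peak prediction

Deep multi-task models that predict functional-genomics peak calls from DNA
sequence learn technical artifacts (composition biases, batch effects)
alongside genuine regulatory signal, and both leak into downstream analyses.
`mfd` separates them using the experiment **metadata** that consortia already
publish: the metadata variables are partitioned into a *biological* and a
*technical* group, each group's hypernetwork generates the corresponding half
of every class's output weights, and an adversarially learned penalty forces
the two halves of the sequence representation to be mutually unpredictable.

The prediction rule for class *i* and window *j* is

```
p_ij = sigmoid( s_j1 · w_i1 + s_j2 · w_i2 + b_i ),     w_ig = psi_g(m_i)
```

where `s_j1`/`s_j2` are the biological/technical halves of the latent
features, `psi_1`, `psi_2` are metadata embedding hypernetworks, and `b_i` is
a free per-class bias. Two perceptrons `rho12`, `rho21` are trained to
predict each half from the other; the model is penalised by the summed
squared per-dimension mini-batch Pearson correlations,

```
L_MFD = bce + lambda_indep · sum_i rho_i^2 ,     L_indep = -sum_i rho_i^2 ∈ [-C, 0]
```

Classes with identical metadata are replicates and share generated weights;
biological metadata provably cannot act through the technical half and vice
versa. On top of the fitted model the package provides bidirectional
featurization, ridge-logistic enhancer classification, subspace-swapped
zero-shot variant effect prediction (with quantile tagging and enrichment
odds ratios), and integrated-gradients attribution of latent neurons with
baseline correction. A fully seeded synthetic generator with planted motifs
and GC-linked label noise makes every stage testable without external data.

Audience: computational genomics researchers studying batch effects and
representation learning on functional-genomics compendia, and developers of
sequence-to-activity models who need a desk-scale, fully inspectable
implementation of metadata-conditioned disentanglement.

## Worked example

```r
library(mfd)

cfg <- synthetic_config(n_windows = 240, window_size = 96, n_chroms = 3, seed = 7)
ds  <- generate_dataset(cfg)
enc <- encoder_config(window_size = 96, n_features = 8, filters = c(8, 8),
                      kernels = c(6, 4), pools = c(4, 4), seed = 1)
fit <- mfd(ds, lambda = 0.01, encoder = enc, epochs = 2, batch_size = 32, seed = 3)
print(fit)
```

```
Metadata-guided feature disentanglement model
  classes: 8   latent width C: 8 (two halves of 4)
  window: 96 bp   lambda_indep: 0.01   seed: 3
  final training bce: 0.5183   sum rho^2: 1.441
  replicate groups sharing weights: 1
```

The training cross-entropy (0.52) is already below the 0.5-prediction
chance level `ln 2 ≈ 0.693`; `sum rho^2` is the dependence the adversaries
currently find between the two latent halves (bounded by `C = 8`), which the
penalty pushes down over training. One replicate pair was detected in the
metadata and shares generated output weights.

```r
vars   <- make_variants(ds, n_causal = 5, n_neutral = 5, seed = 2)
scores <- variant_effect(fit, vars, shifts = -1:1)   # variants x classes x modes
tags   <- tag_by_quantile(scores[, , "combined"], upper = 0.9)
enrichment_odds_ratio(tags, vars$causal)
```

```
Enrichment 2x2 (unique variants, any-class tagging):
      truth
tagged yes no
   yes   1  1
   no    4  4
odds ratio: 1.0000
```

At this two-epoch toy scale the enrichment is uninformative (ten variants,
a barely trained model); the packaged study below, at its full size, yields
enrichment odds ratios well above 1 for planted causal variants.

```r
am <- latent_attribution(fit, substring(ds$genome[[1]], 1, 96), node = 2)
print(am)
```

```
Attribution map for latent node 2 (96 bases)
  activation 0.5110  (reference -0.0040), completeness error 7.53e-04
```

The attribution map satisfies the integrated-gradients completeness axiom:
its per-base scores sum to the node's activation minus the activation of the
all-zero reference, up to the Riemann error shown.

A shell interface wraps the same functions
(`inst/cli/mfd.R simulate | train | featurize | enhancers | score-variants |
enrich | attribute`); every run writes its resolved configuration and seed
next to its outputs and reproduces bit-identically.

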