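---
title: "Adaptive spatial-temporal networks for dynamic functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive spatial-temporal networks for dynamic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

astnet classifies subjects from parcellated resting-state fMRI time series.
A subject is an $N \times T_{total}$ matrix of ROI signals with a binary
diagnosis label. The pipeline has three stages.

**Windowing.** The series is cut into $T = \lfloor T_{total}/L \rfloor$
non-overlapping windows of $L$ timepoints (default $L = 20$, i.e. 30--60 s
at typical repetition times, the range generally considered to give robust
dynamic-connectivity estimates). The trailing remainder is discarded.

**Adaptive functional connectivity.** For each window $G_t \in
\mathbb{R}^{N \times L}$, edge weights are learned rather than fixed by
Pearson correlation:
$$A_{mn} = \frac{\exp(\mathrm{ReLU}(\omega^\top |x_m - x_n|))}
               {\sum_{n'} \exp(\mathrm{ReLU}(\omega^\top |x_m - x_{n'}|))},$$
with a single learnable $\omega \in \mathbb{R}^L$ shared across windows and
subjects. The row softmax makes $A$ row-stochastic. A graph-smoothness
regulariser
$$L_{graph} = \sum_{m,n} \|x_m - x_n\|_2^2 A_{mn} + \lambda \|A\|_F^2$$
encodes the prior that similar ROIs should connect strongly ($\lambda$
defaults to $10^{-3}$). Three graph-convolution layers
$H^{l+1} = \sigma(A H^l W^l)$ (batch normalisation, ReLU, dropout 0.5;
hidden widths 64/64/32) produce node features whose Gram matrix
$S_t = H H^\top$ is the learned second-order connectivity of the window.

**Temporal dependency mining.** The strict upper triangle of each $S_t$
(length $N(N-1)/2$) feeds two branches. The *global* branch embeds each
window through a 1024/256/32 MLP and pools the window sequence with channel
attention: average- and max-pooling over the 32 channels give two length-$T$
descriptors, a shared bottleneck MLP ($T \to \max(1, \lfloor T/3 \rfloor)
\to T$) maps both, and a sigmoid of their sum gates each window; the output
is the gated sum of window features. The *local* branch projects the window
vectors to 64 dimensions and runs a 2-layer bidirectional GRU (4 units per
direction), read out as the concatenated final hidden states. The two
branch outputs are concatenated and classified by a 32/16/2 head. Training
minimises cross-entropy plus the graph loss (unweighted sum, as published;
`graph_coef` exposes the implicit weight).

Ablation variants (`build_variant()`) replace the learned adjacency with
row-softmaxed $|$Pearson$|$ (`GCN_d`), drop the GCN (`AGL_d`), drop either
temporal branch (`ASTNet_G`, `ASTNet_L`), or use a single full-length
window (`*_s` static variants, plus the `MLP_s`/`MLP_d`/`BiGRU` baselines).

## Parameters that matter

| parameter | default | units | provenance |
|---|---|---|---|
| `window_length` | 20 | timepoints | published constant |
| `gcn_dims` | 64, 64, 32 | widths | chosen (3 layers is published) |
| `mlp_dims` | 1024, 256, 32 | widths | published |
| `gru_units`, `gru_layers` | 4, 2 | -- | published |
| `attention_ratio` | 3 | -- | published |
| `dropout` | 0.5 | rate | published |
| `lambda_reg` | 1e-3 | -- | chosen |
| `graph_coef` | 1 | -- | published (unweighted sum) |
| `lr`, `batch_size`, `patience` | 1e-3, 16, 10 | -- | chosen (Adam) |

`print()` on an `astnet_config` marks every default as published or chosen.

## Numerical and design choices

**No autodiff framework.** No neural-network library exists in the target R
stack, so every forward and backward pass is written by hand in base R with
analytic gradients, and the test suite verifies them against central finite
differences (relative tolerance $2 \times 10^{-3}$, with a two-step-size
guard that skips coordinates sitting on a ReLU/argmax kink, where the
subgradient convention and the finite-difference half-slope legitimately
differ).

**$\omega$ initialisation.** The paper states only that $\omega$ is
initialised "according to a normal distribution". We use
$\mathcal{N}(0.5, 0.1^2)$: for unit-variance signals a zero-mean draw puts
the scores $\omega^\top|x_m - x_n|$ at the dead point of the
ReLU--exp--softmax chain, where the adjacency is numerically uniform — the
degenerate solution the joint loss is explicitly meant to avoid — and no
gradient can differentiate edges. A positive mean starts the similarity
function in its responsive range.

**Early stopping monitors cross-entropy.** The graph regulariser decreases
secularly toward its trivial minimum (the uniform graph) for as long as
training runs, so a plateau of the *total* loss never arrives; the trainer
therefore watches the cross-entropy term (configurable) and restores the
parameters of the best monitored epoch. Without best-epoch restoration the
returned model would always be the most collapsed one rather than the most
discriminative one.

**Loss scale and the collapse of $\omega$.** With the published unweighted
sum, the graph term is several orders of magnitude larger than the
cross-entropy on standardised signals (it sums $\|x_m - x_n\|^2 A_{mn}$
over all $N^2$ pairs and all windows), and its gradient steadily drags
$\omega$ toward the uniform solution. Best-epoch restoration lets the
dynamic adaptive variants reach their most discriminative state before the
collapse completes.

**Ties and degenerate inputs.** Max-pooling uses first-index tie-breaking;
windows shorter than $L$ are rejected; constant ROI signals yield Pearson
correlations of 0 off-diagonal; edge-wise Welch tests with two zero
variances report $p = 1$ when the group means agree and $p = 0$ otherwise;
zero-denominator sensitivity/specificity are reported as `NaN` with a
warning, never silently as 0.

## The synthetic cohort

`cohort_spec()` / `generate_cohort()` emulate a two-group cohort as
zero-mean multivariate normal series whose correlation switches between
`n_states` contiguous regimes (state boundaries aligned to window
multiples; a misalignment flag and a Markov-switching schedule exist).
Both groups share a community structure (four blocks of five ROIs,
within-block $r = 0.3$, between-block $r = 0.05$); patients additionally
carry `effect_size` (default $\Delta r = 0.4$) on ten fixed between-block
edges in the *second state only* — a purely dynamic group difference.
Defaults state the validation world: 100 subjects per group, 20 ROIs, 240
timepoints (12 windows), unit marginal variance.

What this generator does *not* emulate: hemodynamic response convolution,
autocorrelated noise, motion artifacts, site effects, or raw-scanner signal
amplitudes. A green test therefore establishes that the implementation is
correct and that the method behaves as claimed on clean second-order
structure; it says nothing about preprocessing robustness or about
performance on real BOLD data.

## What the desk-scale experiments show

With these defaults, the dynamic adaptive-graph variant `AGL_d` — learned
adjacency, no GCN — separates the groups perfectly on held-out subjects and
clearly beats its static counterpart `AGL_s`, which sees the dynamic effect
only in diluted full-series form. This reproduces, at desk scale, both the
value of adaptive graph learning (the learned $A$ carries the planted
edges: edge-wise $|t|$ up to ~8) and the dynamic-versus-static claim.

The *full* model, which inserts the 3-layer GCN and reads out
$S = HH^\top$, stays at chance here. Two mechanisms compound, and both are
documented as a known limitation rather than patched away:

1. the subject-specific adjacency mixes node signals before the Gram
   readout, so entry $(m, n)$ of $S$ measures a different underlying ROI
   pair in every subject — node-pair registration is destroyed for a
   fixed-weight classifier (a linear probe on $S$ features is at chance
   even with an informative, frozen $\omega$);
2. the unweighted graph loss collapses $\omega$ toward the uniform graph,
   after which $S$ is rank-1 and carries a single scalar per window.

On real cohorts, where signals are not standardised and between-subject
amplitude structure is strong, the published results indicate the full
stack is trainable; on this generator's standardised Gaussian world it is
not, and the corresponding acceptance check is intentionally left failing
with this analysis.

## Known limitations

- Per-site models: subjects in one model share $T$; series of different
  lengths require separate models (as in the published per-site protocol).
- The hand-written engine is CPU-only and single-threaded beyond BLAS.
- The Welch-test maps apply no multiple-testing correction by default (the
  published convention binarises raw $p$ at 0.05); `adjust = "fdr"` is an
  explicitly non-published extension.
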