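---
title: "Methods: connectivity-based state decoding and performance prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based state decoding and performance prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, the assumptions
behind them, and the numerical and design choices a maintainer should
know about.  No empirical claim here goes beyond what the test suite and
`scripts/acceptance.R` compute.

## 1. Connectivity features

**FC.** For each event window (>= 5 TRs at TR = 2 s) the within-subject
functional connectivity is the Pearson correlation of the ROI
time-series.  Columns are z-scored within the window first; Pearson
correlation is scale-invariant, so this changes nothing for a single
matrix but stabilizes the leave-one-out group means used by ISFC and the
Fisher-z averaging used downstream.  A zero-variance ROI in a window is
a hard error naming the ROI: it indicates degenerate input, not
something to paper over.

**ISFC.** For subject *s*, entry (i, j) correlates subject *s*'s ROI *i*
with the average of every *other* subject's ROI *j* over the same
window, and the matrix is symmetrized as (M + Mᵀ)/2.  The cited
literature leaves the estimator open; the leave-one-out-against-the-mean
form is adopted because it is deterministic, O(n) in subjects, and has
the property the method exists for: signal components that are not
time-locked across subjects (intrinsic activity, noise) shrink as
1/(n−1) in the reference mean.  Two consequences worth remembering:
the ISFC diagonal is not 1 (it is the subject-vs-group homogeneity), and
computing ISFC per window over the full cohort means test subjects
contribute to the reference means of training subjects.  This mirrors
how the feature is defined for naturalistic designs, but it is a mild
form of transduction: the features of a training subject are not fully
independent of who else is in the cohort.

**Edge statistics.** Group-level edge tests are one-sample t-tests of
Fisher-z values against zero with Benjamini–Hochberg adjustment across
the 66 unique edges (p < 0.01 by default).  Benjamini–Yekutieli is
reserved for time-series feature selection (Section 3), where it is the
named procedure.  Edge strength is classified against the 0.5
benchmark; the "approximately 0.5" moderate band is ±0.05 and exposed as
an argument.

## 2. The synthetic cohort generator

Each subject's signal in window *w* with state *state(w)* is

x(t) = a·m_age·S_w(t) + b·I(t) + c·ε(t)

* **S_w** — stimulus-evoked component, drawn once per window from
  N(0, Σ_S^state) and *shared by every subject*: this is what makes
  inter-subject correlation informative.
* **I** — subject-specific intrinsic component, N(0, Σ_I) per time
  point.
* **ε** — white noise.
* **m_age** — an age SNR multiplier (children 0.85, adults 1.0 by
  default), a modest attenuation standing in for the lower effective
  stimulus SNR of young children; it produces the qualitative age trend
  (adults decode slightly better) without modeling development.

Defaults: a = 1, b = 0.6, c = 0.4, so the stimulus carries about
two-thirds of the variance; Σ_S gives the engaged network a
within-network correlation of 0.9 and the other network 0.7 (zero
between networks); Σ_I has within-network correlation 0.4.  These were
fixed once as a realistic middle ground — strong enough coherence for
window-level estimates from 16–17 TRs to be informative, enough
intrinsic/noise share that FC and ISFC genuinely differ.

**Behavioral-group coupling.** The generator contract is that a
subject's expected mean ToM↔Pain edge correlation equals their group's
target (pass 0.8, inconsistent 0.5, fail 0.2).  Editing the *shared*
stimulus covariance cannot do this — it is common to all subjects, and
correlation-matrix geometry caps the reachable between-network
correlation well below 0.8 whenever the stimulus share of variance is
below the target.  Instead each subject's composed signal is blended
toward its own global mean component, x′ = (I + w/(N·σ_v)·J)x, and the
scalar w is solved by `uniroot` on the exact model covariance (averaged
over the two window states) so the expected between-network correlation
equals the target.  Because Pearson correlation is scale-invariant the
normalization of the blend is immaterial.  Side effects are real and
intentional: high-coupling subjects also show higher within-network
coherence and a compressed state contrast — strong global integration
necessarily makes the two networks look more alike.  The per-group
recovery of the targets within ±0.05 is asserted in the tests at 50
subjects per group.

What the generator does **not** emulate: hemodynamic response
convolution, autocorrelated noise, head motion, voxel-level structure,
age-dependent network topology.  Passing tests therefore show the
algorithms recover planted covariance structure under the model's own
assumptions, not that they work on scanner data.

## 3. Graph pipeline

Adjacency is |r| (or positive-clipped r) with zero diagonal; the
normalized Laplacian L = I − D^{−1/2} A D^{−1/2} is rescaled by its
exact largest eigenvalue (graphs are tiny; a λ_max = 2 shortcut exists
by flag).  Zero-degree nodes get ε = 10⁻⁶ degree regularization with a
warning.  Chebyshev terms follow T₀ = I, T₁ = L̃,
T_k = 2L̃T_{k−1} − T_{k−2}; the equivalence of the polynomial filter
with direct eigendecomposition filtering is the module's central test
(200 random graphs, N ≤ 12, K ≤ 5, max error < 10⁻⁸).

Time-series node features use a fixed 10-statistic catalog (mean,
variance, skewness, kurtosis, autocorrelation lags 1–3, energy, absolute
sum of changes, linear-trend slope) — a deterministic, desk-scale stand-in
for the hundreds of hypothesis-test features of the scalable-hypothesis-test
approach, selected per node-feature column by Mann–Whitney U with
Benjamini–Yekutieli adjustment; a statistic surviving for any node is
kept for all nodes so feature widths stay equal.  Node embeddings
(node2vec with p, q biased second-order walks; walklets with one
sub-embedding per skip scale) are trained by skip-gram with negative
sampling; defaults (16 dimensions, walk length 20, 50 walks/node,
p = q = 1, scales {1,2,3}) are common published values for small graphs.

How embeddings and statistical features combine into the decoder's node
features is not prescribed anywhere; concatenation is provided
(`featureMode = "rows+embedding"`, or explicit `features`).  The
*default* experiment pipeline uses each node's connectivity profile (its
matrix row) as its feature vector: it is the standard GCN input for
connectivity graphs, fully deterministic, and the only option cheap
enough to build 1,550 graphs per cohort at test time.

## 4. The state decoder

Per block: K-order Chebyshev filtering (K = 3 by default; the order is
not printed anywhere, and 3 is the common ChebNet choice), a per-node
bias, batch normalization, ReLU, pairwise max-pooling over the fixed ROI
ordering (nodes (2i−1, 2i); an odd tail passes through), then dropout.
Pooling halves the node count, so deeper blocks need a coarser graph
operator: the pooled adjacency sums the edge weights between node pairs
(Graclus-style aggregation) and the Laplacian is rebuilt.  After the
last block the node features flatten into a dense softmax head.
Batch-norm-before-ReLU is used; ties in the argmax prediction resolve to
the lower class index.

Training follows the published recipe: Adam, learning rate 0.001,
dropout 0.65, weight decay 0, batch size 32 (16/64 available), up to 100
epochs, early stopping with patience 3 on a stratified 10% validation
split.  Three numerical choices matter and were found the hard way:

* **Batch-norm re-estimation.** Statistics accumulated during
  dropout-active minibatches do not describe the dropout-free
  activations seen at inference; with dropout 0.65 the mismatch
  compounds across three BN layers and makes evaluation-mode loss
  oscillate wildly.  Before every validation check (and in the stored
  model) BN statistics are therefore recomputed exactly over the
  training set with dropout off.  This single change turns the
  validation trajectory from oscillatory to smoothly decreasing.
* **Validation cadence.** The monitor is evaluated every 5 epochs;
  patience counts consecutive *checks* without improvement, and the best
  weights seen are always restored.  A short burn-in (a fifth of the
  epoch budget) runs before stopping can engage.
* **Gradient clipping.** Global gradient-norm clipping at 1.0 tames the
  minibatch noise of heavy dropout.  `Inf` disables it.

The loss is cross-entropy with ε = 10⁻¹² clamping plus an optional
(ρ/2N_P)‖W‖² penalty (ρ = 0 by default, as printed).

The stack depth maps the published 1D/2D/3D convolution variants to 1–3
graph-convolution blocks with filter schedules 16 / 16,32 / 16,32,64; a
printed "300 neurons per layer" variant contradicts the architecture
table and is not the default.  On the synthetic cohort the 1-block and
3-block models both sit near ceiling, so the published depth ordering is
not identifiable here and is not asserted as a test; the ISFC-over-FC
feature ordering, which is the substantive claim, is asserted (10
paired seeds, one-sided p < 0.05).

## 5. The performance predictor

The encoder is two stride-2 SAME 3×3 convolutions (1→32→64 channels),
flatten, dense 32 with ReLU, and linear heads for the latent mean and
log-variance; the decoder mirrors it (dense to the coarse grid, two
stride-2 transposed convolutions 64→64→32, stride-1 sigmoid output).
For 12×12 input the spatial chain is 12→6→3→6→12 and the trainable
parameter counts are 39,392 (encoder) and 74,689 (decoder), asserted
row-by-row in the tests.  ROI-subset analyses rebuild the geometry for
N = 8 (8→4→2) and N = 6 (6→3→2); the decoder mirrors the encoder maps so
every size round-trips exactly.  Correlations are mapped from [−1, 1] to
[0, 1] before encoding because a sigmoid output cannot represent
negatives.

The loss is mean-squared-error reconstruction plus the closed-form
Gaussian KL ½Σ(μ² + σ² − 1 − log σ²).  Two numerical choices:

* **Reconstruction scaling.** `vaeLoss()` reports the per-entry mean
  MSE, but the training objective scales the reconstruction by the
  number of entries (the usual convolutional-VAE balance).  With a
  per-entry mean at 12×12, the KL term dominates from the first step.
* **KL warm-up and free bits.** Even with summed reconstruction, the KL
  term collapses the posterior to the prior (the latent means become
  constant and group prediction degenerates to the majority class): with
  one Adam update per epoch — 122 subjects and batch 128 — the encoder
  never earns back the information the KL removes.  Two standard
  mitigations are combined: the KL weight anneals linearly from 0 to 1
  over the first 30% of epochs, and a free-bits floor of 0.25 nats per
  latent dimension exempts dimensions already within their information
  budget from further KL pressure.  Reported losses are always the
  unweighted ones.

The group head is exactly as printed: three sigmoid outputs trained with
one-hot binary cross-entropy for 50 epochs by Adam, argmax decoding with
ties to the lowest group index.  Latent codes are standardized inside
the classifier, and its learning rate (unprinted) is 0.01.  Children
only (n = 122) feed this stage by default; synthetic adults carry a
placeholder "pass" label and are excluded.

## 6. Shapley attribution

Exact attribution enumerates all 2^n subsets (n ≤ 16) with the
factorial weights; sampling averages marginal contributions over random
orderings and reports per-feature standard errors.  Absent features are
imputed with a background (training-mean) value — the single-reference
convention; the background is an explicit argument.  The explained
output is the model probability of the predicted class unless a class is
named.  Efficiency, symmetry and dummy axioms are asserted exactly in
enumeration mode; sampled values must sit within 3 SE of enumeration.
ROI-level exact mode masks all edges of an ROI (12 features);
edge-level sampled mode attributes the 66 unique edges and maps each to
both endpoint ROIs before the per-ROI median ranking.

## 7. Validation protocols

All schemes split at the **subject** level — the ten windows of one
subject are statistically dependent, and window-level splitting inflates
accuracy.  Repeated 80:20 uses ⌊0.8N⌋ training subjects (124/31 at
N = 155) with fresh shuffles, stratified by class when labels are given
(proportional allocation per class, topped up to the exact size);
five-fold partitions the subjects; leave-one-out is exhaustive.
Disjointness is asserted on every split.  Metrics (accuracy, per-class
and macro precision/recall/F1, confusion matrix, ROC via pROC and
precision–recall points, one-vs-rest beyond two classes) are recomputed
from the confusion matrix in the tests.

## 8. Problem sizes and limitations

The test suite and acceptance script run the full default cohort (155
subjects, 1,550 graphs) for the headline decoding runs, a 10-seed paired
comparison with the 1-block decoder at 40 epochs, 200-graph spectral
equivalence, 100-replicate FDR null simulations, and 1,000-subject
Monte-Carlo checks of the generator's centering — sizes chosen so the
whole suite completes in minutes on one core while keeping Monte-Carlo
error well inside the asserted tolerances.

Known limitations: the generator's Gaussian, temporally white signals
are favorable to correlation estimates from 16–17 TR windows; real BOLD
autocorrelation would widen them.  ISFC computed over the full cohort
mixes test subjects into training subjects' reference means (Section 1).
The neural stacks are plain-R implementations sized for a dozen nodes
and hundreds of subjects — they are exact, not fast, and graphs beyond a
few hundred nodes are out of scope.
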