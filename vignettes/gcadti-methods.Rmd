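---
title: "Methods: locality-aware DTI prediction with gated cross-attention"
author: "gcadti authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locality-aware DTI prediction with gated cross-attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The prediction problem

Given a small molecule (SMILES) and a protein (amino-acid sequence), predict
a binary interaction label. The design premise of this model family is that
binding is driven by *local* functional structure — reactive groups and
pharmacophores on the drug side, short sequence motifs and binding-site
fragments on the protein side — so both encoders and the fusion stage are
built to preserve and align token-level (atom/residue) information rather
than collapsing each molecule to a single vector before interaction
modeling. The same property gives interpretability for free: the fusion
module's attention map is a residues-by-atoms matrix that can be read as a
soft correspondence between binding partners.

# Model and assumptions

## Drug encoder

SMILES strings are parsed by RDKit (default sanitization). Only heavy atoms
become graph nodes; hydrogens enter as count features. This follows the
attribute list used for featurization: with implicit-H and total-H counts
among the 8 attributes, explicit H nodes would be redundant.

Each atom's raw feature vector has 74 entries in 8 blocks (frozen layout in
`atom_feature_blocks()`): atom type one-hot over 43 elements + "other" (44),
degree 0–10 (11), implicit hydrogens 0–6 (7), formal charge (1), radical
electrons (1), hybridization over sp/sp²/sp³/sp³d/sp³d² (5), total hydrogens
0–3 (4), aromatic flag (1). Only the attribute list and the total width 74
are prescribed; the block widths follow the canonical 74-dimensional scheme
in common use, the only standard layout consistent with both. Out-of-range
counts clamp into the last slot and unlisted hybridizations fall back to
sp³, so every one-hot block always contains exactly one 1 — an invariant the
tests enforce.

The encoder is H⁽⁰⁾ = ReLU(XW₀) (no bias, so zero-padded dummy rows stay
exactly zero) followed by K = 4 GIN layers

h_v^(k) = MLP^(k)((1+ε^(k))·h_v^(k−1) + Σ_{u∈N(v)} h_u^(k−1)),

with batch normalization and ReLU after each layer. The MLP is a 2-layer
perceptron D→D→D with ReLU (the source describes only "a multi-layer
perceptron"; two layers is the standard minimal choice that keeps GIN's
injectivity argument). ε initializes at 0 and is learnable. Jumping-Knowledge
aggregation concatenates the K layer outputs and projects back to width D;
H⁽⁰⁾ participates only as layer 1's input, exactly as the aggregation
formula lists h⁽¹⁾…h⁽ᴷ⁾. The `use_jk = FALSE` ablation uses the last
layer's output instead. A GCN drop-in (degree-normalized mean aggregation
over the closed neighborhood, single linear map) is selectable via
`encoder_variant = "gcn"`.

**Batch normalization is mask-aware**: statistics are computed over real
(non-padding) rows only. The source is silent on padding interactions; without
this choice, real-atom embeddings would depend on how many dummy nodes share
the batch, corrupting both training and the attention-map extraction. During
training, batch statistics are used and running estimates updated
(momentum 0.1); evaluation uses the running estimates, making single-pair
inference independent of batch composition. Padding rows are re-zeroed after
every layer.

## Protein encoder

Sequences are tokenized over a 25-symbol alphabet: the 20 standard residues
plus B, Z, U, O and X, with X as the catch-all for anything else. The source
fixes only the count (25); this is the standard extended amino-acid set of
that size. Tokens index a learnable 25×D embedding table, followed by a
linear projection and ReLU. (The projection equation as printed applies W₀
to the *drug* symbol; the surrounding text makes clear it is the projected
protein lookup, and it is implemented as such.)

Each of the 2 residual blocks stacks same-padded 1-D convolutions with
kernel widths 3 → 6 → 9 **in series**, each followed by batch normalization,
ReLU (except the last, which stays pre-activation after its batchnorm) and
dropout (rate 0.1, a conventional default; the source does not state one).
The block output is Y = ReLU(F(X) + G(X)) with G a linear (1×1) shortcut.
Whether the three kernels act in series or in parallel branches is not
stated; series was chosen because it reproduces the "progressively enlarged
receptive fields" description with a single path (receptive field 3 → 8 →
16 per block), and the parallel alternative would need a fusion rule the
source never mentions. Convolutions use zero same-padding and windows never
cross sequence boundaries in batched (stacked) layouts; sequence length is
preserved for any input length ≥ 1.

## 3-mer features and random projection

The 3-mer frequency vector over the 25-letter alphabet (D = 25³ = 15,625
coordinates, lexicographic in the alphabet's own order) is normalized to sum
to 1, making it length-invariant. It is compressed by a random matrix with
i.i.d. N(0, 1/d) entries — the Johnson–Lindenstrauss regime, which
approximately preserves pairwise distances (the test suite checks a median
relative squared-distance error < 0.25 at d = 256 on realistic frequency
vectors).

Three choices were open:

* **d defaults to the latent width D** so the projected vector concatenates
  naturally with the pooled fusion features; no value is stated.
* **"Dynamically learned" projections** are implemented as making R
  trainable after its Gaussian initialization (`kmer_trainable = TRUE`, the
  default, since the ablation discussion found static mappings markedly
  weaker); `FALSE` freezes R. This reading is an interpretation — the
  dynamic variant is never defined formally.
* The k-mer vector is **sequence-level**, so it joins the fused
  representation at the head rather than being broadcast per residue; the
  frequency vector has no positional content to justify per-residue
  injection. `use_kmer = FALSE` reproduces the N-mer ablation.

The projection seed is stored in checkpoints so inference regenerates the
training-time features exactly.

## Gated cross-attention

With Q the residue matrix and K = V the atom matrix, per head
softmax(Q'K'ᵀ/√d_h)V' with d_h = D/h; heads are concatenated and linearly
mapped. The printed scale ("d_h/h") is ambiguous and the universal 1/√d_h
convention is used. The attended context A is fused with the projected
query by H = α·A + (1−α)·Proj(Q). Three gating modes mirror the ablation
axes: `static` (fixed α ∈ (0,1)), `averaged` (α = 0.5) and `dynamic`
(per-token α = Sigmoid(FcNet([A; Proj(Q)])), the default). The gate network
is zero-initialized so training starts at the neutral α = 0.5. Whether α is
scalar-per-pair or per-token in the original is unstated; per-token is
implemented because the defining equation is applied row-wise. Numerically,
α is smoothly rescaled to ε + (1−2ε)·sigmoid (ε = 1e-7) so it stays
strictly interior even when the sigmoid saturates in double precision.

The methods text defines the protein→drug direction; the concluding summary
describes bidirectional attention. Both are implemented;
`bidirectional = TRUE` is the default (each direction has its own
parameters, and the two pooled summaries are concatenated), with the flag
available to recover the unidirectional form. Which variant produced the
published benchmark numbers cannot be determined from the text.

Padded atoms/residues are masked out of every softmax (zero weight, exactly)
— unstated in the source but required for attention-map indices to align
with real atoms. Gated token outputs are pooled by non-overlapping window-3
max pooling over tokens followed by the token mean ("attention pooling size
3"); the exact composition is frozen here and in the tests.

The `use_gca = FALSE` ablation bypasses attention entirely and concatenates
the masked token means of both modalities.

## Head, loss, training protocol

Pooled fusion features (plus the projected 3-mer vector) pass through a
2-layer MLP with sigmoid output. Training minimizes binary cross-entropy —
the source never names its loss, and BCE is the canonical choice for a
sigmoid-output binary classifier evaluated by AUROC/AUPRC — with Adam.
Defaults follow the published hyperparameter table: lr 1e-5, ≤ 100 epochs,
batch 64, 2 residual blocks, 4 GIN layers, kernels [3,6,9], 4 heads,
pooling 3. The model with the best validation AUROC is kept. Training stops
early once validation AUROC reaches `stop_auroc` (default 0.999) or fails to
improve for `patience` (10) epochs — a pragmatic addition for CPU budgets
that cannot change the selected checkpoint, only save epochs after the
optimum on effectively-solved data.

The documented **fast profile** (`profile = "fast"`: 64-dim latents, 2
heads, lr 1e-3, ≤ 30 epochs) is what the test suite and the scaled-down
learning check use; the benchmark schedule is impractical in CI.

The five-run protocol re-splits 7:1:2 with a fresh seed per run (whether
the original five runs shared splits is unstated; independent splits give
the more conservative variance estimate) and reports mean ± sd per metric.

## Metrics

AUROC is computed by trapezoidal integration of the empirical ROC curve
and AUPRC as step-wise average precision; both are verified against
independent oracles (Mann–Whitney U; the precision-at-positive-ranks
identity). Accuracy, sensitivity TP/(TP+FN), specificity TN/(TN+FP) and
precision TP/(TP+FP) are reported at the F1-optimal threshold, found by
evaluating F1 at every midpoint between consecutive distinct scores plus a
candidate below the minimum; F1 ties break toward the lower threshold.
*Erratum*: the printed definitions of sensitivity and specificity in the
source are garbled (sensitivity appears as FP/(FP+TN), the false-positive
rate, and specificity as TP/(TP+FN)); the standard forms are implemented.

## Interpretability pipeline

For one pair: extract the protein→drug attention map, average over heads
(head handling is unstated; averaging is the neutral choice), drop virtual
nodes, select the top 20% of **matrix entries** — "top 20% of high-weight
indices" is read as entries (residue, atom pairs), not atoms, because the
procedure then maps the selection *back onto* the molecular graph — with
count ceil(0.2·n) and ties broken by (higher weight, lower row, lower
column), then aggregate per atom (weight = sum of selected entries) into a
highlight table. Selection is monotone in the fraction, and oversized
molecules are rejected at padding time rather than truncated so indices
always align with atoms.

# The synthetic world

The generator emulates the benchmark CSV format (smiles, sequence, label)
with a plantable, fully known signal:

* **Drugs**: 30 curated, RDKit-valid SMILES templates; half contain a
  carboxylic-acid group (the marker), detected structurally in tests (a
  carbon with one double-bonded oxygen and one terminal single-bonded
  oxygen), never by string matching.
* **Proteins**: uniform random sequences over the 20 standard residues,
  length 50–100 (scaled down from real protein lengths for CPU budgets),
  with the 5-residue motif `HWKWY` planted at a uniform position in half
  the library.
* **Labels**: positive iff marker AND motif, then flipped with probability
  `noise_rate` (default 0 — the noiseless world is the reference condition
  of the learning check; noise is an explicit knob). Default prevalence is
  the natural 0.25 (independent halves); a `prevalence` knob re-weights the
  positive cell to emulate imbalanced regimes such as low-prevalence kinase
  panels.

Everything is reproducible from one seed, and the rule itself is exposed as
an oracle classifier scoring AUROC 1.0 on noiseless data — the ceiling for
any model.

**What a green test does and does not establish.** The generator's chemistry
is trivial (small templates, one functional-group signal) and its proteins
are i.i.d. noise around one motif; real binding data has correlated
chemistry, homologous sequences, label noise far from independent, and
signals not expressible as a conjunction. A model reaching AUROC ≥ 0.9 here
demonstrates that the encoders, fusion, training loop and gradients work —
it says nothing about benchmark-level accuracy, which is explicitly out of
scope (the published numbers require external downloads and multi-hour
training).

# Numerical choices

* **Autodiff**: a tape-based reverse-mode engine on dense matrices; every
  pullback (including masked batchnorm, masked softmax, scatter-gather and
  convolution taps) is validated against central finite differences in the
  tests, and a whole-model check verifies gradients end to end.
* **Initialization**: He-scaled Gaussians for ReLU layers, N(0, 0.1) for the
  embedding table, zeros for biases and the gate network, ε = 0, γ = 1.
* **Stability**: BCE is computed from logits (softplus form); reported
  probabilities are floored into [1e-12, 1−1e-12]; gradients are clipped to
  global norm 5; batchnorm variance floor 1e-5.
* **Selection-count arithmetic**: ceil(fraction·n) is computed with a 1e-9
  slack so exact rational multiples are not bumped by floating-point excess.
* **Indexing**: atoms, residues and attention-map rows/columns are 1-based
  throughout, the R convention; all exported index contracts state this.
* **Degenerate inputs**: single-residue proteins work (padding never
  errors); molecules exceeding `max_nodes` are a hard error; empty
  sequences/SMILES are rejected; single-class label vectors make AUROC an
  explicit error rather than NA.

# Known limitations

* SMILES perception requires a Python RDKit on PATH (`GCADTI_PYTHON`
  overrides the interpreter); there is no pure-R fallback parser.
* No edge/bond features in the GIN (the featurization defines node features
  only); no 3D structure, stereochemistry beyond the 8 attributes, or
  pretrained sequence embeddings.
* Training is CPU-bound R; the benchmark-scale schedule (100 epochs on
  ~50k pairs) is out of reach — the package targets method correctness and
  scaled-down experiments, not leaderboard reproduction.
* Binary labels only; no affinity regression.
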