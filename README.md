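# gcadti — locality-aware drug–target interaction prediction

`gcadti` predicts whether a small molecule binds a protein target from the
molecule's SMILES string and the protein's amino-acid sequence, and explains
*where*: its cross-attention maps are projected back onto drug atoms to rank
the atomic regions that drive a predicted interaction. It is aimed at
computational chemists and bioinformaticians who want a trainable, fully
inspectable DTI screening model that runs on plain CPUs with no deep-learning
framework dependency — the network, including reverse-mode automatic
differentiation, is implemented in R on BLAS-backed matrices.

## The model

Three modules are composed into a binary classifier:

**Drug encoder (GIN + Jumping Knowledge).** RDKit parses the SMILES into a
heavy-atom graph; each atom gets a 74-dimensional feature vector built from 8
chemical attribute blocks (atom type, degree, implicit H, formal charge,
radical electrons, hybridization, total H, aromaticity). After a projection
H⁽⁰⁾ = ReLU(XW₀), K = 4 Graph Isomorphism Network layers update every atom:

    h_v^(k) = MLP^(k)( (1 + ε^(k)) · h_v^(k−1) + Σ_{u∈N(v)} h_u^(k−1) )

followed by mask-aware batch normalization and ReLU. Jumping-Knowledge
aggregation concatenates all K layer outputs and projects back:
h_JK = Concat(h⁽¹⁾,…,h⁽ᴷ⁾) W_JK.

**Protein encoder (residual CNN + 3-mers).** Residues over a 25-letter
alphabet are embedded via a learnable 25×D table, projected, and passed
through 2 residual blocks of same-padded 1-D convolutions (kernel widths
3 → 6 → 9) with batch normalization, ReLU and dropout:
Y = σ(F(X) + G(X)), G a linear shortcut. In parallel, the sequence's 3-mer
frequency vector x ∈ R^15625 (xᵢ = nᵢ/Σnⱼ, length-invariant) is compressed
by a Gaussian random projection R with Rᵢⱼ ~ N(0, 1/d) (trainable after
initialization by default).

**Gated cross-attention (GCA).** Protein residues query drug atoms (and, in
the default bidirectional mode, atoms query residues) with multi-head scaled
dot-product attention, scale 1/√d_h. The attended context A is mixed with the
projected query by a gate:

    H = α · A + (1 − α) · Proj(Q),   α = Sigmoid(FcNet([A; Proj(Q)]))

with static (fixed α), averaged (α = 0.5) and dynamic (per-token, learned)
gating selectable. Gated tokens are max-pooled (window 3) and averaged; the
pooled summaries plus the projected 3-mer vector feed an MLP head trained
with binary cross-entropy (Adam).

Evaluation follows the benchmark protocol: random 7:1:2
train/validation/test splits, best-validation-AUROC model selection, five
independent runs reported as mean ± sd. AUROC/AUPRC are threshold-free;
accuracy, sensitivity and specificity are reported at the F1-optimal
threshold.

**Interpretability.** For a trained model, the head-averaged protein→drug
attention map is extracted, virtual (padding) nodes are removed, the top 20%
of entries are selected (deterministic tie-breaking), and the selected pairs
are aggregated per atom into a highlight table for molecule drawing.

## Worked example

The synthetic generator plants a known signal: a drug is "active" against a
protein iff the molecule carries a carboxylic-acid group **and** the sequence
contains the motif `HWKWY`. A scaled-down model (64-dim latents, 2 heads,
learning rate 1e-3) learns this rule from 2000 pairs:

```r
library(gcadti)
spec <- synthetic_spec(n_pairs = 2000, seed = 11)
ds   <- generate_dataset(spec)
cfg  <- dti_config(profile = "fast", seed = 42)
sp   <- split_dataset(ds, seed = 42)          # 7:1:2
fit  <- train_dti(dti_model(cfg), sp$train, sp$val)
#> epoch   1 | loss 0.3243 | val AUROC 0.9416 | val AUPRC 0.8082
#> epoch   2 | loss 0.0263 | val AUROC 1.0000 | val AUPRC 1.0000
compute_metrics(predict_dti(fit$model, sp$test), sp$test$label)
#> AUROC 1.000 | AUPRC 1.000 | Acc 1.000 | Sens 1.000 | Spec 1.000 (thr 0.5159)
#>   TP 106  FP 0  TN 294  FN 0
```

The held-out AUROC of 1.000 says the model recovered the planted rule
exactly (the rule oracle is the upper bound at 1.0). Attribution on a
positive test pair lands on the planted substructure — the carboxyl carbon
and oxygen receive the attention mass:

```r
rec <- sp$test[which(sp$test$label == 1)[1], ]
res <- attribute_interaction(fit$model, rec)   # top 20% of the Att map
#> <attribution: 113 pairs (top 20%), 2 atoms, 93 residues, p = 0.999>
head(res$highlights)
#>   atom symbol    weight  relative
#> 1    4      C 43.999820 1.0000000
#> 2    5      O  9.433272 0.2143934
```

## Command-line interface

The installed script `exec/gcadti` (or `dti_cli()` in R) provides:

```sh
gcadti simulate --spec spec.yaml --out pairs.csv
gcadti train    --config cfg.yaml --data pairs.csv --checkpoint m.json [--history h.csv]
gcadti eval     --checkpoint m.json --data pairs.csv [--out metrics.csv]
gcadti predict  --checkpoint m.json --data pairs.csv --out preds.csv
gcadti explain  --checkpoint m.json --smiles "CC(=O)O" --sequence MKV... --fraction 0.2 --out report/
gcadti ablate   --config cfg.yaml --data pairs.csv --out table.csv
gcadti --version
```

Exit codes: 0 ok, 1 user error, 2 internal error. Interaction tables are
CSV with header `smiles,sequence,label`. Configs are YAML; unset keys take
the benchmark defaults (Adam, lr 1e-5, 100 epochs, batch 64, 2 residual
blocks, 4 GIN layers, kernels [3,6,9], 4 heads, pooling 3). Every ablation
(`use_jk`, `use_residual`, `use_gca`, `encoder_variant: gcn`, `use_kmer`,
`gating_mode`, `bidirectional`, `n_heads`) is a config switch. Checkpoints
are versioned JSON archives holding the config, all parameters, batchnorm
running statistics and the k-mer projection seed.

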