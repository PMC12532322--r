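---
title: "Cross-modal contrastive integration of paired RNA and ATAC profiles: models and methods"
author: "scDuet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal contrastive integration of paired RNA and ATAC profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Matched multiome assays measure transcript counts and chromatin
accessibility in the *same* cell, giving per-cell positive pairs across
two very different feature spaces (genes and peaks). scDuet embeds both
modalities into one hypersphere, then exploits the shared representation
for three downstream analyses: scoring candidate gene-peak regulatory
links with a distance-masked cross-attention transformer, predicting
expression from accessibility, and quantifying *chromatin potential* —
the temporal lead of chromatin opening over transcription — from the
residuals of that prediction.

# Preprocessing

Per modality: features detected in fewer than 5% of cells are removed,
sex-chromosome features are dropped, each cell is scaled to a total of
10,000 counts and log1p-transformed, and (for RNA) up to 2,000 highly
variable genes are retained. HVG ranking uses mean-binned normalized
dispersion: dispersion (variance/mean of the de-logged values) is
z-scored within 20 equal-frequency mean bins, ties broken by gene index.
The pipeline order is fixed as filter → sex-chromosome removal →
normalize/log → HVG. All-zero cells are retained (with a warning) rather
than dropped; they carry no depth information, so normalization leaves
them at zero. Cells are then encoded sparsely as per-cell
(index, value) pairs over the non-zero features — the token stream
consumed by the encoders.

# Encoders

Each modality has an asymmetric teacher-student pair producing a
d-dimensional cell embedding (d = 128 by default).

The **teacher** maps each non-zero feature to a learned embedding-table
row scaled by the cell's normalized count (the *token hidden*). A
one-hidden-layer tanh MLP followed by a dot product with a learned
cellular context vector scores each token; a softmax over the cell's
tokens yields scalar attention weights, and the attention-weighted sum
of the token hiddens is the cell aggregate. Batch norm, dropout
(rate 0.1) and a dense+ReLU layer produce the embedding. Two readings of
the attention text are possible (tanh applied directly vs. inside an
MLP); we implement dense(d→d)+tanh before the context dot product, which
subsumes the direct-tanh reading via an identity-initialized dense
layer. The attention weights are typed as scalars per token: the
weighted sum of d-vectors requires scalar weights. Context vectors are
per-modality by default (`share_context` reuses the RNA vector).

The **student** is deliberately coarse: batch norm over the dense count
vector, dropout, dense+ReLU.

Batch norm uses batch statistics during training (momentum-0.9 running
updates, skipped for single-cell batches) and running statistics in
eval mode, so eval-mode passes are bit-deterministic. Weights are
Glorot-uniform; context vectors are N(0, 1/d); everything is
seed-controlled.

# Cross-modal contrastive pretraining

A mini-batch of N paired cells yields 2N points. With
`sim(h1, h2) = h1'h2 / (tau |h1||h2|)` and temperature tau = 0.1, the
loss term for anchor m with positive m+ is

```
l(m, m+) = -log exp(s_{m,m+}) /
           sum_{k != m} [ exp(s_{k,m}) + exp(s_{k,m+}) ]
```

and the batch loss averages `l(m, m+) + l(m+, m)` over the N pairs. Note
the denominator convention: the sum pools every in-batch point's
similarity against *both* the anchor's and the positive's columns,
excluding only the anchor itself — the positive's self-similarity
therefore appears, and a single identical pair scores exactly log 2.
This convention is implemented literally and is verified against a
brute-force double-sum oracle in the tests.

The full objective averages the teacher-level and student-level
cross-modal NT-Xent terms. Two ablation pairings are available:
`crossed_teacher_student` (teacher RNA vs student ATAC and vice versa)
and `within_modality`. Training uses Adam for 20 epochs, batch 32, with
an exponential learning-rate decay from 1e-4 to 1e-6 (the endpoints are
honored exactly; the decay shape is a package choice). Epoch shuffling
is seeded and the final incomplete batch is kept. The joint embedding
row-stacks the two teacher outputs, RNA first.

All neural components run on a compact tape-based reverse-mode
autodifferentiation engine written in base R (matrix-level operations,
BLAS-backed); every operator's gradient is checked against central
finite differences in the test suite.

# Gene-peak interaction decoder

Per cell, the token sequences are the teacher-style token hiddens of the
cell's non-zero genes and peaks, each with a learned CLS token prepended
(position 1). Restricting tokens to non-zero features matches the sparse
input encoding and keeps desk-scale training tractable; the global
attention matrix remains G x P with never-attended pairs at zero.

The gene sequence passes one self-attention layer
(`softmax(QK'/sqrt(d)) V`, single head and single layer by default,
multi-head available). Cross-attention then uses the self-attended genes
as queries against the peak tokens, with an additive mask
(`-1e9` before the softmax) on every gene-peak pair that is *not* on
the same chromosome within 1.2 Mb of the TSS (|TSS − peak midpoint|,
boundary inclusive; CLS rows/columns stay open). A second, symmetric
cross-attention pass with the raw peak tokens as queries against the
self-attended genes — sharing the same projections — supplies the
peak-side CLS attention over genes; this is the only construction that
yields an N x (G+1) CLS attention and it keeps the parameter count
unchanged.

Training minimizes the sum of two losses for 5 epochs: (i) the NT-Xent
contrast between the two per-cell CLS outputs (the input CLS embeddings
are shared across cells, so the cell-specific CLS *outputs* of the two
cross passes are contrasted), and (ii) a matching loss: for each cell
the true (gene, peak) pairing is a positive, one negative pairing per
cell is drawn from non-matching in-batch cells with probability
proportional to the softmaxed CLS similarity (hard negatives), and a
linear classifier on the concatenated CLS outputs predicts
matched/mismatched with balanced cross-entropy. Ground-truth pairings
are always the positives; similarity only shapes negative hardness.
Gradients flow into the encoder embedding tables unless
`freeze_encoder` is set.

After training, the gene-side CLS attention over peaks (N x (P+1)) and
peak-side CLS attention over genes (N x (G+1)) are contracted over
cells, `t(attn_atac) %*% attn_rna`, the CLS row/column dropped and
masked pairs zeroed, giving the G x P global attention matrix used to
rank candidate links.

# Regulatory evaluation

Candidate pairs are all same-chromosome gene-peak pairs within the
1.2 Mb window. A promoter-capture Hi-C style table labels a candidate
positive when the gene's TSS lies within 1 kb of a bait fragment, the
peak within 1 kb of the same record's other end (both gaps inclusive,
via interval overlap with `maxgap`), and the interaction score passes 5
in at least one cell-type column. AUROC uses exact midranks (the
Wilcoxon statistic) and is cross-checked against an independent library
implementation in the tests. Top pairs are selected either by quantile
(top `ceiling(frac n)`, ties broken lexicographically) or by the knee of
the sorted-weight curve (maximum distance to the chord). Genes with at
least 10 distinct selected peaks are reported as dense peak-associated
genes.

# Expression prediction and chromatin potential

A two-layer MLP (d → 1000 hidden units, ReLU → G) maps the ATAC student
embedding to normalized log expression, trained with mean squared error
for 40 epochs (Adam, lr 1e-3 → 1e-5; the contrastive schedule's 1e-4
start is too slow for a freshly initialized head). The regression
target is the normalized log expression, consistent with the residual
definition below. `from_scratch` re-initializes the encoder for the
de-novo ablation. Residuals are predicted minus measured (both
normalized); per-gene trends along pseudotime are smoothed with a
penalized-spline GAM (`mgcv`, GCV-chosen smoothness), local extrema read
off the smooth, and genes flagged when their residual standard deviation
exceeds the 0.90 quantile (the cutoff is configurable; no canonical
value exists).

# Pseudo-bulk soft clustering and co-occurrence

Cells are sorted by pseudotime and split into 10 equal-size bins
(remainder to the early bins — equal-size stabilizes pseudo-bulk
variance; equal-width is not offered). Group means are z-scored per
feature; constant features are dropped with a warning. Fuzzy c-means
(fuzzifier from the Schwammle-Jensen estimate, override available) runs
over c = 2..20; the cluster number is chosen at the knee of the minimum
inter-centroid distance curve, with an explicit override. Alpha cores
keep profiles with maximum membership above 0.5.

Cluster-associated genes: per cluster peak, the Spearman correlation
with every gene's pseudo-bulk profile; per gene, the mean over cluster
peaks. The null re-computes the statistic over 50 background peaks per
cluster peak, matched on GC x coverage decile bins (focal peak excluded;
bins widened with a warning when under-filled), followed by a one-sided
Wilcoxon rank-sum test and BH adjustment.

Per-cell cross-modal cosine states flag cells whose teacher embeddings
disagree (cosine distance > 0.1) — candidates for actively
transitioning states. Differential expression is one-vs-rest Wilcoxon
with BH adjustment and a natural-log fold change of expm1-means with
pseudocount 1; DEGs require adjusted p < 0.01 and logFC > 0.25.

# The synthetic study conditions

The generator plants everything the downstream analyses claim to
recover. Cells carry a uniform pseudotime on [0, 1], cut into
`n_types` contiguous stages; each regulatory program is a Gaussian
activity bump (width 0.6/n_types) centred on one stage. Peaks belong to
one program; accessibility counts follow a Bernoulli-Gamma-Poisson
cascade on program activity (Gamma cv = `noise`, activity-dependent
dropout). Genes read the *realized* (Gamma-multiplied) activity of
their planted peaks — the same multiplier enters both modalities, which
is the per-pair coupling the decoder must detect beyond program-level
co-activity. Lag genes instead read program activity at `t - delta_i`
with a per-cell delay `delta_i ~ U(0, 2 lag_dt)` (default mean lag
0.25) sharing the same peak coupling. The delay is *random per cell*:
transcription catches up to chromatin asynchronously. This matters —
a deterministic lag is a smooth function of pseudotime that the
prediction head's per-gene output layer simply fits, leaving no residual
signal; only the unpredictable per-cell component makes lag genes'
residuals systematically larger, which is also the biologically
meaningful reading of chromatin potential. Genomic coordinates place
genes 2.5 Mb apart on three autosomes with peaks within ±1.1 Mb of
their anchor gene (so every planted link fits the 1.2 Mb mask) and a
2.5 kb minimum peak separation (so promoter-capture style round-trips
are exact). Expression rates use amplitude 5 over a 0.1 baseline and a
mild gene-level Gamma (cv = noise/2); these constants were fixed so the
planted effects are detectable at desk scale with comfortable margins —
an effect-size choice, not a fit to any particular run.

The desk profile (600 cells, 300 genes, 600 peaks, 3 types; the lag
analyses use `lag_frac = 0.2`, giving 60 lag genes) trains end-to-end on
one CPU in a few minutes: pretraining about 2, decoder fine-tuning about
3. What the generator does *not* emulate: doublets, batch effects,
sequence-driven GC bias (peak GC is synthetic and independent of
counts), branching trajectories, and peak co-accessibility beyond
program membership. Passing the packaged checks therefore demonstrates
correctness of the algorithms and recoverability of planted structure,
not performance on real tissue atlases.

# Numerical choices

Masking adds -1e9 before the softmax (masked weights < 1e-6 after).
NT-Xent exponentials are computed directly; at tau >= 0.05 the scaled
similarities stay well inside double range. Softmax rows subtract their
maximum. Batch norm uses eps = 1e-5. FOSCTTM counts strictly closer
cells only, so ties at the true-match distance do not penalize.
Min-max scaling in the composite scores is the identity when no peer
methods are supplied (a single method would otherwise be degenerate).
Fuzzy c-means is restarted per candidate cluster number with a
seed-derived initialization, making memberships bit-reproducible.

# Known limitations

Single attention head and a single transformer layer by default (both
configurable); no positional encodings (feature tokens are unordered);
RNA→ATAC prediction is out of scope; pseudotime is consumed, never
inferred; no batch-effect handling across experiments. The checkpoint
format is native R serialization (RDS) — inspectable from R, not
language-neutral.
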