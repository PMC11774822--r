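---
title: "Models and methods in phosfusion"
author: "phosfusion authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phosfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosfusion)
```

`phosfusion` identifies kinase phosphosites that enhance kinase activity by
fusing two views of each site: what its flanking protein sequence looks
like (via a precomputed protein-language-model embedding) and how its
phosphorylation co-varies with the rest of the phosphoproteome across many
samples (via an embedder trained on the sparse phospho-MS matrix itself).
This vignette explains each model, the parameters that matter, what the
synthetic generators do and do not emulate, and the design choices made
where the design was genuinely open.

## Preprocessing of phospho-MS matrices

Raw site-by-sample intensity matrices are heavily missing: a cell is empty
when the peptide was not observed in that sample. The pipeline is:

1. **Replicate deduplication** — within each group of replicate samples the
   column with the fewest missing cells is kept; ties keep the first in
   matrix order.
2. **Detection filtering** — a site survives if it lies on a kinase, is a
   known or predicted substrate site, or is detected in at least 10% of
   samples (`minDetectFrac = 0.10`). Exemption takes precedence over the
   threshold, so a kinase site observed nowhere is still retained: the
   downstream models need those rows even when sparse.
3. **Imputation and normalization** — missing cells become
   (global observed minimum − `eps`), `eps = 1e-4`, then the whole matrix
   is min–max scaled to [0, 1]. Because the imputed floor sits strictly
   below every observed value, originally-missing cells map to exactly 0
   and every observed cell to a value above 0 — the zero/missing encoding
   the embedder relies on. The scaling is global (one minimum, one range
   for the whole matrix), not per sample or per site: only a global scheme
   makes "0" mean "missing" uniformly. One corner is worth noting: a
   matrix with *no* missing cells min–max-scales its observed minimum to
   0; the container's `zeroMask` assay, not the value 0, is the
   authoritative missingness record.

The deduplication-then-filter order matters in principle (deduplication
changes the denominator of the detection fraction); we deduplicate first,
since the retained sample set defines the cohort the fraction should refer
to.

## The masked-autoencoding MS embedder

The embedder treats each phosphosite as one "sentence". Its tokens are the
site's values across samples; there is no positional order, and a learned
look-up embedding of the *sample identity* plays the role positional
embeddings play in language models. The model has six stages:

* **Masking.** Per site and epoch, `round(maskFraction * #nonzero)` nonzero
  cells are hidden, and *the same count* of zero cells (capped by
  availability on either side). Zeros dominate sparse matrices; masking
  equal proportions would let the model score well by always predicting
  zero. Counts are balanced per site, not per batch, so the invariant can
  be asserted row by row. Default `maskFraction = 0.15`.
* **Value embedding (autodiscretization).** A scalar in [0, 1] passes
  through a small tanh gating network and a softmax over `anchors` learned
  anchor embeddings (default 100); the token embedding is the resulting
  convex combination of anchors. This gives continuous values a learnable,
  smoothly varying discrete-like code without binning artifacts.
* **Encoder.** Value embedding plus sample embedding (elementwise sum —
  both are `dModel`-dimensional and the sum is the positional-embedding
  convention) for every *observed, unmasked, nonzero* token, through
  multi-head self-attention blocks. Padding, when token sequences are
  batched to a common length, is excluded from attention and provably does
  not perturb real tokens.
* **Reassembly and decoder.** A full-length sequence is rebuilt at the
  original sample positions: encoder outputs where observed, a learned
  mask embedding at masked positions, a learned zero embedding at
  unmasked-zero positions. Each token also receives its sample-identity
  embedding again before a position-wise linear layer: without identity at
  the decoder input, every masked position of a site would present an
  identical query and receive an identical prediction, making
  reconstruction impossible. The decoder is an attention stack whose
  backend is exact softmax attention by default, or a
  positive-random-feature linear approximation (Performer-style) for long
  sample axes; the two agree on small instances with error shrinking in
  the feature count. The linear backend is inference-only — training uses
  exact attention, which is not a practical limitation at the matrix sizes
  a single machine trains.
* **Loss and metrics.** MSE at masked positions only. Validation tracks
  masked MSE, an accuracy (fraction of masked cells with absolute error
  below `accuracyTau = 0.1`; the threshold is a package choice, as no
  standard definition exists for this quantity), and the Pearson
  correlation between predictions and truths at masked cells.
* **Site embeddings.** After training, each site's nonzero tokens pass
  through the frozen encoder and the contextual vectors are max-pooled
  componentwise into one `dModel` vector. Sites with no observed value
  yield no embedding and fall back to the sequence-only path downstream.

Blocks use the pre-LayerNorm layout (LayerNorm before each sublayer, the
residual stream unnormalized). The classic post-LN layout is also
implemented (`norm = "post"`); pre-LN is the default because the final LN
of a post-LN block normalizes each token vector and thereby discards
per-token magnitude, which at desk scale measurably slows learning of the
very quantity the decoder must output. Optimization is Adam
(`lr`, `batchSize`, early stopping on validation masked MSE with
`patience`, best weights restored). Dropout defaults to 0 so that runs are
bit-reproducible; it is implemented and can be enabled (the desk-scale
experiments below use 0.1).

Sites are split 75:25 into training and validation; validation masks are
drawn once and frozen so epochs are comparable. All randomness — split,
masks, initialization, batch order — derives from the single `seed` in
`msPretrainConfig`.

## Bimodal fusion classification

Sequence embeddings (1024-dim, from an external protein language model
over the ±30-residue window around the site) and MS embeddings (`d`-dim)
are fused by concatenation into `D = 1024 + d` dimensions — 1152 at the
defaults. Sites without an MS embedding are expanded from the sequence
embedding alone by a linear alignment layer trained *jointly* with the
classifier, so both provenances share one input space. The classifier is a
four-layer MLP with widths `D, D/2, D/4, D/8, 1` (integer division) and
LayerNorm/ReLU/dropout between layers. At very small `D` (≤ 16, far below
real use) the late layers become 2–4 units wide and LayerNorm erases most
of their information; desk-scale experiments therefore keep the MS
dimension at 32 or more.

The loss is weighted binary cross-entropy on logits with per-site weights
`w_i = wOut` for sites outside the activation loop and 1 inside
(`wOut = 4`, i.e. 2^2, the setting that balances in/out-of-loop
predictions while leaving discrimination essentially unchanged).

The training protocol mirrors the imbalance of the real problem (about one
critical site per ten kinase phosphosites): `rounds = 3` rounds, each
using all positives plus a fresh `ratio = 10`:1 negative draw taken
without replacement from a shuffled pool, so the rounds' negative sets are
pairwise disjoint (a short pool leaves later rounds the remainder, with a
warning). Within a round: stratified 8:2 train/test split, 5-fold
stratified cross-validation on the training portion, early stopping per
fold on fold-validation AUROC with best-weights restore. A cross-validated
protocol leaves open which model scores the held-out test portion; we use
the mean predicted probability of the five fold models, and `predictFusion`
applies the fold ensemble of the round with the highest test AUROC.
Reported metrics are AUROC, AUPRC (step-wise precision–recall
integration), and F1/MCC at probability 0.5.

## Kinase–substrate relation prediction

A kinase is represented by the componentwise maximum of the embeddings of
its phosphosites (all sites attributed to the kinase in the matrix);
max-pooling is permutation-invariant and idempotent under duplication.
The kinase and substrate-site embeddings are concatenated and classified
by a two-linear-layer MLP (LayerNorm/ReLU/dropout between), split 7:2:1
into train/validation/test with early stopping on validation AUROC.
Negative pairs are drawn uniformly at random excluding known pairs, pairs
scored above 0.7 by external predictors (strictly above — a score of
exactly 0.7 stays eligible), self-pairs, and duplicates.

## Substrate enrichment and survival-ready imputation

For a kinase phosphosite, samples split into a phos-group (site value
&gt; 0) and non-phos group (value 0); all sites are ranked by
`log2((mean_phos + 1e-6) / (mean_nonphos + 1e-6))` (the pseudo-count
guards empty means; ties break by site ID). The enrichment score of the
kinase's substrate set is the extremum of the weighted Kolmogorov–Smirnov
walk: hits add `|score|^p` normalized over hits, misses subtract
`1/(N - Nhits)`. The weighting exponent defaults to `p = 1` (common GSEA
practice; `p = 0` recovers the classic KS statistic and makes the score
invariant to monotone rescaling). NES divides the observed ES by the mean
|ES| of same-sign scores from `nPerm = 1000` random same-size sets; with
no same-sign permutation the NES is flagged `NA` rather than forced.

Ahead of survival modeling, sites with at least 50% missing values are
rejected and the remainder imputed from
`Normal(mu0 - 0.5 * sigma0, (0.5 * sigma0)^2)` — a left-shifted, shrunk
Gaussian relative to the observed values, the standard assumption that
missing phospho-MS intensities are low. The Cox regression itself is out
of scope; the module emits the analysis-ready table.

## Sequence and structural features

Flanking windows (±7 residues for features; ±30 for language-model input)
truncate at the termini without padding; k-mer rates divide by the number
of window placements so truncated windows stay comparable; composition
fractions include the center residue (it is a constant S/T/Y, so inclusion
is harmless and keeps the window self-contained). Feature screening keeps
non-k-mer features at two-sided rank-sum p &lt; 0.05 (exact for ≤ 8 per
class, normal approximation with tie correction above), 2-mers at
positive-class presence frequency &gt; 0.2 *and* log2 fold change &gt; 1.5
(an absent 2-mer among negatives counts as infinite fold change), then
greedily drops features correlated above |r| = 0.7 with an already-kept
feature, in order of increasing p-value. The counts reported on real data
(36 before, 28 after de-correlation) are data-dependent and not
reproduced here.

PROSITE-style signature patterns are parsed and scanned natively —
literals, alternative `[..]` and exclusion `{..}` sets, wildcards with
repeat ranges, terminal anchors — reporting every distinct match span with
per-element positions; the scanner is validated against an independent
regular-expression oracle. Conserved-residue localization takes the
position of a configured pattern element in the *first* match (kinase
domains occasionally repeat; using the first is a package choice).
Spatial distances are Euclidean Cα–Cα distances from PDB models (first
altloc kept, residue numbers assumed to equal sequence positions as in
AlphaFold-style single-chain models, with a configurable offset).
Surface/burial descriptors (ASA/CX/DPX) are ingested from an external
structural-analysis program's table, not computed.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline reads, bit-reproducibly
per seed:

* `simPhosMatrix` — a sparse site-by-sample matrix in which each kinase
  has a latent per-sample activity `a ~ U(0,1)`; planted critical sites
  track `a`, their kinases' substrates take `clip(beta * a + noise)`
  (`beta = 2` by default — strong coupling so recovery tests are about
  correctness, not power), and every site carries a multiplicative
  abundance factor in [0.3, 1] emulating site-specific abundance and
  ionization efficiency. That factor, times the shared activities, is the
  planted low-rank structure the embedder's learning-progress experiments
  measure. Missingness is completely at random at rate `sparsity`,
  *except* at critical sites, which are additionally left-censored below
  `detectionLimit` (0.15 of the site's scale): detection of a critical
  site must carry information about its level for the detection-split
  enrichment analysis to be meaningful, exactly as in real data, where
  low-abundance peptides fall below the instrument's limit. What is *not*
  emulated: batch effects, peptide-level interference, realistic motif
  grammars, and missingness that depends on the sample.
* `simKinaseSequences` — random proteins (~300 residues) carrying one
  instance each of an ATP-binding-like signature (conserved K) and an
  active-site-like signature (conserved D), an activation-loop interval
  downstream of the active site, and phosphosites; critical sites are
  placed inside the A-loop near the conserved D with flanks enriched for
  a configured letter set. Proximity is therefore planted relative to the
  catalytic D — planting it relative to the ATP-binding K as well would
  contradict A-loop residency at this protein length.
* `simSiteEmbeddings` — class-conditional unit-variance Gaussians with
  mean separation `delta` along a random direction (`delta = 4` default:
  strongly separable, so fusion tests measure the protocol rather than
  the classifier's sample efficiency).
* `simToyStructures` — Cα-only ideal helices (rise 1.5 Å, 100°/turn,
  radius chosen for 3.8 Å between consecutive Cα) written as PDB text.

Because the planted effects are strong and the geometry idealized, green
tests demonstrate that each stage recovers structure it provably contains
— not that the method attains any particular accuracy on real
phosphoproteomes; the real-data headline numbers require the original
cohort-scale MS data, curated annotations and an external language model.

## Problem sizes and numerical choices

Desk-scale experiments are sized for a single CPU: the learning-progress
experiment uses a 200 × 40 matrix, a `dModel = 32` model with one encoder
and one decoder block, 20 epochs (its validation masked MSE must fall
below both its epoch-0 value and a column-mean predictor built from the
training rows); the fusion-benefit experiment uses 30 positives and 900
negatives with 256-dim sequence and 32-dim MS surrogates over the full
3-round, 5-fold protocol; kinase–substrate recovery uses 8 kinases × 150
substrates on balanced pairs. The relation-recovery tests feed the pair
classifier the normalized value rows as site embeddings: a tiny embedder
trained for minutes produces nearly collapsed site embeddings, so using it
there would test embedder capacity rather than the relation module — a
known limitation of desk-scale pretraining that disappears with realistic
model sizes and data volumes.

Other numerical choices: Adam throughout (no schedule); early-stopping
comparisons use a 1e-9 improvement margin; attention padding uses a −1e30
score rather than −Inf to keep softmax gradients finite; the
autodiscretization gating uses tanh; weight init is Xavier-scaled normal;
equal scores in ranked lists and selections break ties by identifier so
every ordering is deterministic. Degenerate inputs are contracts, not
accidents: all-zero site rows are rejected (or dropped with a warning in
batch training), an all-missing matrix cannot be normalized, empty mask
plans cannot be scored, and a site set covering the entire ranking has no
enrichment walk.

## Known limitations

* The embedder processes one site per forward pass; batching pads to the
  per-batch maximum but there is no across-site attention, so cross-site
  information flows only through the shared sample embeddings.
* Training requires the exact attention backend; the linear backend is for
  inference at long sample axes.
* mmCIF structures are not supported (PDB only), and surface descriptors
  are ingested, never computed.
* The 5-fold/3-round protocol reports variability across rounds, not a
  full bootstrap; with very few positives the per-round test sets are
  small and the round-to-round spread is wide.
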