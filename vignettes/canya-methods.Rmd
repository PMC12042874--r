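---
title: "Modelling peptide aggregation with canya: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling peptide aggregation with canya}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canya)
```

## The problem

Short peptides can nucleate amyloid aggregation, and massively parallel
selection assays can measure an aggregation score for each of tens of
thousands of random peptides. The analytical challenge is twofold: first,
turn noisy per-peptide fitness estimates into reliable aggregator /
non-aggregator calls; second, learn a sequence model of aggregation that a
human can interrogate — which short motifs drive aggregation, with what
sign, at which positions, and whether their effects add up.

`canya` implements that full stack: the labelling pipeline, a compact
convolution–attention classifier (CANYA), replicate training with an
interpretability-based model-selection rule, motif extraction and
clustering, Global Importance Analysis (GIA), secondary-structure
enrichment scoring, and evaluation utilities — together with an NNK-library
simulator that plants a *known* aggregation grammar so that every stage can
be validated against ground truth on a desktop.

## Labelling aggregation scores

Input records are per-peptide aggregation scores with standard errors and
input read counts (the output schema of count-based fitness estimation for
deep mutational scanning). The pipeline:

1. **Read filter.** Records with fewer than 100 input reads are removed
   (the count floor below which fitness estimates are unstable).
2. **Stop truncation.** Sequences containing the amber stop `*` are
   truncated to the prefix before the first stop; duplicate truncated
   peptides are summarised by their mean score and modal label, and groups
   with an exact label tie are discarded.
3. **Mode centering.** The score distribution is shifted so its mode sits
   at zero. The mode is estimated as the argmax of a Gaussian kernel
   density (Silverman's bandwidth, 4096-point grid). Because
   non-aggregating sequences dominate the library (~80–85%), the global
   mode coincides with the non-aggregator mode; the slight circularity of
   centering before labels exist is accepted and documented here.
4. **Z test with FDR control.** Each centered score is divided by its
   error to give a z score; one-sided upper-tail normal p values are
   Benjamini–Hochberg adjusted within each library, and adjusted p ≤ 0.05
   calls an aggregator. Peptides whose score is missing because they
   produced no reads after selection are labelled non-aggregators.

On pure-null simulations the empirical false-aggregator rate stays within
the BH bound (checked at n = 10,000 over 20 replicates in the test suite).

## The CANYA model

The network takes a 24 × 20 matrix: two all-zero padding rows, the one-hot
peptide (alphabetical channel order, fixed so weights are portable), two
more padding rows, then rows of −1 masking the remainder of short
peptides. The layer stack is:

* **Convolution** — 100 filters of length 3 (the modal β-strand length in
  resolved amyloid structures), stride 1, *exponential* activation, no
  pooling. Exponential conv activations concentrate motif information in
  the first layer, which is what makes the filter → PWM reading valid.
* **Dropout 0.1.**
* **Self-attention** — a single head with key length 6 over the 22 motif
  frames, with positional encodings entering before the softmax (below),
  and an output projection back to the 100-dimensional filter space.
* **Dropout 0.1**, then a **mean-pool** over the 22 frames.
* **Dense 64, ReLU**, with an elastic-net penalty of 0.01
  (`0.01·(‖W‖₁ + ‖W‖₂²)`) on its incoming weights; **dropout 0.4**.
* **Sigmoid output.** `pre_activation()` exposes the logit; all GIA
  effects are measured on this unbounded scale.

### Positional encodings and the parameter budget

The attention internals are fixed by two requirements: positional
information must enter before the softmax, and the default network must
have exactly 17,491 trainable parameters. The decomposition used here is:

| tensor | shape | parameters |
|---|---|---|
| conv kernel + bias | 3·20×100 + 100 | 6,100 |
| content positional embeddings | 22 × 100 | 2,200 |
| key-side positional encodings | 24 × 6 | 144 |
| query / key / value projections | 3 × (100×6 + 6) | 1,818 |
| output projection | 6×100 + 100 | 700 |
| dense layer | 100×64 + 64 | 6,464 |
| sigmoid head | 64 + 1 | 65 |
| **total** | | **17,491** |

Positional information enters twice, both times before the softmax: a
content embedding table added to the convolutional feature map (one
100-vector per motif frame), and a key-space table indexed by each frame's
central padded-input row (24 rows at key length 6; the first and last rows
are allocated for the full padded length but are untouched by the 22 valid
frames). Queries, keys and values carry biases, as does the output
projection. The key bias is mathematically inert — adding a constant to
every key shifts each query's logits uniformly and cancels in the softmax
— but it is retained as part of the standard projection parameterisation.
The decomposition is asserted tensor-by-tensor in the test suite.

### Training protocol

Binary cross-entropy minimised with Adam (lr 10⁻³, β₁ = 0.9, β₂ = 0.999).
With hard 0/1 labels the binary KL divergence equals cross-entropy up to
the (zero) label entropy, so the implementation uses cross-entropy
directly. A stratified 10% validation split per library is held out;
validation AUPR (trapezoidal precision–recall integration, anchored at
recall 0) is monitored each epoch: the learning rate decays by a factor of
0.2 after 4 epochs without improvement, training stops after 10, and the
best-AUPR weights are restored. Everything — initialisation, shuffling,
dropout masks, splits — flows from a single integer seed, and two runs
with the same seed are bit-identical.

The forward and reverse passes are written directly in R matrix algebra
(batched across samples, including the attention softmax), and the
gradients are verified against central finite differences in the test
suite. Sequences longer than 20 residues are scored at every overlapping
length-20 window and summarised by the median (mean, min, max
selectable); the median is the default for its stability.

## Model selection across replicates

`train_replicates()` trains the model repeatedly (seeds `base_seed + 1 …
base_seed + n`), each with its own held-out test split, and records
per-library test AUROC/AUPR plus an **interpretability score**: the KL
divergence (nats, pseudocount 0.5 per bin over the 8,000-kmer universe)
between the distribution of 3-mers centred at each sequence's
top-attributed position and the distribution of all 3-mers in the same
sequences. Attribution is input-gradient saliency corrected by
mean-centering across the 20 channels at each position (the gradient
component orthogonal to the one-hot simplex carries no information), with
the attributed value read at the observed residue and the top position
taken by absolute value; the interface accepts precomputed positions so
alternative attribution schemes can be swapped in. `select_model()`
applies the rule: among replicates whose mean AUPR exceeds the median of
mean AUPRs, take the highest interpretability score (deterministic
tie-break by model id; if the strict filter empties — all AUPRs equal — a
non-strict filter is used and reported).

Closed forms anchor the score: matched distributions give exactly 0, and a
point mass against a uniform distribution over 8,000 kmers gives
log 8000 ≈ 8.99 nats (checked with zero pseudocount).

## Motifs, clusters and GIA

**PWMs.** A filter's activation energy for each of the 8,000 possible
3-mers is computed analytically from its weights (`exp` of the summed
selected weights plus bias) — exhaustive enumeration is exact and cheap,
so no sampling approximation is used. The kmer set for a filter is the
intersection of "within 75% of the maximum activation" and "top 10"
(descending activation, then lexicographic tie-break); the PWM is the
per-position residue frequency matrix of that set. PWMs export to MEME
minimal motif format.

**Clustering.** Each PWM is projected through BLOSUM62 (PWM · BLOSUM,
flattened to 60 features) and clustered by affinity propagation (negative
squared Euclidean similarity, median preference, damping 0.9 with one
escalation retry). Affinity propagation is implemented in the package —
the responsibility/availability updates are a page of code and no
pre-installed R package provides them — and is exercised on constructed
groups with known answers. Clusters are then pruned for sign consistency:
the sign of the member with the largest absolute GIA importance defines
the cluster sign, and discordant members are removed, so every surviving
cluster is sign-pure by construction.

**GIA.** Importance is the mean paired difference in pre-activation score
between backgrounds and the same backgrounds with a motif embedded
(sequence length preserved). Backgrounds are full-length, stop-free
training sequences confidently predicted by the model (aggregators above
probability 0.3, non-aggregators below 0.2). Kmers are sampled with
probability proportional to activation / max activation; cluster-level
experiments sample filter-first (|importance| ratios) then kmer. The five
experiment types:

* *single / cluster*: embedding at a uniform position in 1..18;
* *multiplicity*: 1–4 copies at non-overlapping positions, antecedent
  copies held fixed, with the R² of importance on copy number;
* *positional*: one fixed-position experiment per start 1..18, reported
  with percent change against the position-averaged global importance;
* *interaction*: `[f(both) + f(background)] − [f(A) + f(B)]`, with a
  paired two-sided t test and a Bonferroni threshold of α divided by the
  number of cluster pairs.

CIs are normal-approximation intervals on the mean paired difference
(background counts are large); non-overlapping placement uses bounded
resampling (100 tries) before erroring. A strictly additive surrogate
model (`canya_surrogate()`) provides exact oracles: on it, every
interaction importance is identically zero and multiplicity curves are
exactly linear — properties the acceptance tests verify to 10⁻⁶ — and a
surrogate with a planted product term recovers that term within its CI.

## Structure enrichment

For annotated sequences (per-residue labels in strand / coil / disorder),
a cluster's activation profile takes, at each kmer position, the maximum
activation across member filters, mapped to the kmer's **central** residue
(the start/centre/end choice is otherwise arbitrary; central is
symmetric), so terminal residues carry no value. Profiles and binary
structure indicators are concatenated across sequences and compared by
rank-based AUROC with a percentile bootstrap CI over residues. AUROC is
rank-based and therefore invariant to monotone transforms of the
activation — exponential activations make no difference here.

## The synthetic library and what it does (and does not) show

`sample_nnk_peptides()` draws residues at NNK codon frequencies (32
codons; leucine:methionine 3:1; the amber stop, the only stop reachable
under NNK, appears at 1/32 per position and is emitted as `*` so the
truncation logic is exercised). The default grammar plants:

* `hhh` (all-hydrophobic 3-mer, h = F/I/L/M/V/W/Y): effect **+1**;
* `ddd` (charged/proline 3-mer, d = D/E/K/R/P): effect **−1**;
* position weights declining linearly 1.8 → 0.2 over start positions
  1..18 (N-terminal emphasis);
* Gaussian measurement error, SD 0.5; negative-binomial input reads
  (mean 500, size 5), so the ≥100-read filter removes a known ~4% tail.

These values were fixed once, by a design-stage power analysis, to mimic
the qualitative structure of real random-peptide aggregation data:
non-aggregators dominate (~85% after the labelling pipeline), the latent
score ceiling is high (AUROC ≈ 0.98) but not trivially reachable from
composition alone (composition logistic regression ≈ 0.85), and the
grammar is position-dependent so motif-and-position-aware models have
headroom over composition baselines. Ground-truth labels are
`latent > 0`, which lets every downstream stage be scored against truth.

What passing these tests shows: the pipeline's machinery — labelling
calibration, optimisation, motif recovery, GIA effect signs and
linearity — behaves correctly on data whose generating process is known.
What it does not show: performance on real libraries, whose grammar is
richer (context effects, measurement error correlated with abundance,
library-specific biases), and absolute effect sizes or cluster counts,
which are properties of trained weights on real data.

## Problem sizes and numerical choices

The test suite trains on a simulated library of 20,000 peptides for 10
epochs and two seeds — sizes chosen so a complete run finishes in minutes
on one CPU while leaving the acceptance margins (held-out AUROC > 0.85,
composition gap > 0.05, GIA sign recovery) comfortably clear. Other fixed
choices: convolution pre-activations are clipped at 30 before `exp` to
guard overflow; the attention softmax subtracts row maxima; KDE mode
estimation requires ≥ 50 scored records; the degenerate case of a
numerically zero global importance flags percent change as undefined
rather than dividing by it; empty post-truncation peptides are retained
through encoding and labelling (dropping them is a documented option).

## Known limitations

* The attention parameterisation is one member of the family consistent
  with the published layer description and the exact parameter count;
  other decompositions of the same budget exist.
* The attribution scheme behind the interpretability score is a
  documented default (corrected input gradients); the score's absolute
  value depends on it, though the selection rule only uses rankings.
* The mode-centering estimator and the keep-empty-truncations policy are
  reasonable choices where the procedure is otherwise underdetermined;
  both are isolated behind single functions and easy to swap.
* Affinity propagation preferences default to the median similarity; very
  small motif sets can yield more clusters than a practitioner would keep.
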