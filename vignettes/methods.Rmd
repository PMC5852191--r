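---
title: "Methods: stacked-autoencoder embeddings of allele families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked-autoencoder embeddings of allele families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Allelic variants of a highly polymorphic locus — HLA-A is the motivating
example — differ at dozens of scattered positions along sequences hundreds
of base pairs long. No single marker position summarizes an allele family,
and a human reader cannot grasp the relationships among hundreds of such
sequences directly. `dnascape` projects every sequence to a point in the
plane so that family structure becomes visible at a glance, and attaches a
scalar (the mean silhouette) to what would otherwise be a purely visual
claim of separation.

## Sequence representations

Two encodings are provided, chosen deliberately for their complementary
properties.

**Positional one-hot.** Each base maps to a 4-digit indicator under the
fixed base order (A, T, C, G) — `A = 1000`, `T = 0100`, `C = 0010`,
`G = 0001` — and the indicators are concatenated: a sequence of length $L$
becomes a binary vector of length $4L$ (822 bp gives 3288). The encoding is
exactly invertible (`decode_one_hot()`), position-faithful, and requires
equal-length input. No padding or truncation is ever applied silently:
padding would change what each coordinate *means*, so length harmonization
is left to the user.

**Document vector.** The sequence is read as a bag of overlapping words of
length $l$: every window `1 .. L - l + 1` (stride 1) increments the count
of its word, and the counts form a histogram of length $4^l$ ($l = 5$ gives
1024). The word enumeration uses the same base order read as a base-4
number (`AAAA`, `AAAT`, `AAAC`, `AAAG`, …, `GGGG`), so both encodings share
one digit convention. Histograms are $L^1$-normalized by default (raw
counts by flag); for equal-length input the two differ only by a global
scale, but normalization makes mixed-length datasets comparable, which is
the representation's point.

Non-ACGT characters are rejected in strict mode (the default — ambiguity
codes are real in HLA data and should not pass silently) and masked in
lenient mode: an all-zero one-hot block, or skipping of affected windows.

## The embedding model

A single autoencoder here is the triple $n \to n' \to n$ ($n' < n$):
ReLU hidden units, linear output units, trained by plain stochastic
gradient descent with backpropagation to minimize squared reconstruction
error. The *stack* is trained greedily: stage 1 on the encoded matrix,
stage 2 on stage 1's hidden codes, and so on to the final 2-unit code
layer, whose activations are the embedding. The default architectures are
$3288, 1600, 800, 400, 150, 2$ (five stages, one-hot at 822 bp) and
$1024, 768, 384, 128, 2$ (four stages, $l = 5$ document vectors); tests and
the benchmark use the compact plan $1024, 128, 2$ so that a full run fits
in seconds rather than minutes. There is no end-to-end fine-tuning by
default — the greedy scheme alone defines the method — but
`train_stack(..., fine_tune = TRUE)` appends a joint SGD phase through the
unrolled network for users who want it.

The final 2-node code layer is **linear** by default. A ReLU code would
confine every embedding to the first quadrant and zero out up to half of
the signal at the narrowest point of the network; a linear code costs
nothing in reconstruction and lets clusters occupy the whole plane. Hidden
layers elsewhere are ReLU. Embedding axes carry no physical meaning, and
plots deliberately drop axis units.

## Numerical choices, and why they matter

These choices were each forced by an observed failure mode, not taken from
convention for its own sake.

**Per-stage centering and unit-RMS scaling.** Document-vector rows are
all-positive and nearly collinear (the mean histogram dominates; family
signal is a small perturbation). Feeding them to ReLU units raw makes each
unit's pre-activation share one sign across *all* samples, so a unit that
goes negative early is dead for the entire dataset — in practice every
unit died and the network collapsed to its bias. Centering each stage's
input makes pre-activations straddle zero; scaling the centered matrix to
unit root-mean-square puts every stage on one numeric scale. Both
statistics are stored in the model and re-applied at projection time.

**Scale-free learning rate.** The curvature of the reconstruction loss
grows with the squared row norm of the input, which for unit-RMS data is
proportional to $n$. A fixed absolute step size therefore either diverges
on narrow stages or freezes on wide ones; the step actually applied is
`learning_rate / n_in`, default `0.5`, stable from $n = 8$ to $n = 3288$
in our experiments. On top of this, the classic step schedule (multiply by
0.3 at one and two thirds of the epoch budget) lets plain SGD settle
instead of orbiting the optimum; it is on by default and can be disabled.

**Glorot-uniform initialization, zero biases.** Fan-in-only (He-style)
scaling puts weights of magnitude $\sqrt{6/2} \approx 1.7$ on the decoder
of any stage ending in 2 units, amplifying the initial reconstruction by
an order of magnitude and destabilizing early training; Glorot scaling
$\sqrt{6/(n + n')}$ keeps the initial output amplitude comparable to the
input for every compression ratio.

**Compute-balanced epoch budgets.** One epoch of a $1024 \to 128$ stage
costs roughly 500 times one epoch of $128 \to 2$. The per-stage budget is
`epochs * min(ceiling(d1/dk), 16)`, so cheap narrow stages — which
determine the final geometry of the embedding — train long enough to
converge rather than stopping at an arbitrary shared iteration count. The
default is 400 epochs at the first stage.

**Loss and metric.** The SGD objective is squared error summed over
features and averaged over the mini-batch (so gradient magnitudes do not
shrink with dimension); the *reported* reconstruction error is the
per-element mean square, comparable across stages and datasets.

**Degenerate inputs.** A constant stage input centers to zero; the RMS
guard then scales by 1 instead of dividing by zero, and training drives
the error to zero through the biases. Constant matrices are rejected by
PCA (undefined) but tolerated by the stack. Divergence (non-finite loss)
aborts with the stage index and a pointer at the learning rate.

**Determinism.** Every random draw — generator, initialization, epoch
shuffling — happens under a seed, inside a wrapper that restores the
caller's RNG state. Stage $k$ of a stack uses `seed + k`, so single stages
can be reproduced in isolation. Identical data, plan and config give
bit-identical models and embeddings on one platform.

## The PCA baseline and the separation score

The baseline is 2-component PCA (SVD on the centered matrix) applied to
*the same* encoded matrix the stack trains on. Axes are oriented so each
axis's largest-magnitude loading is positive, removing PCA's sign
ambiguity from outputs and tests. Separation is scored by the mean
silhouette (Euclidean distance on the 2-D coordinates, family labels as
clusters); singleton families take width 0 by convention. The silhouette
was chosen because the claims these analyses make — "families form their
own clusters", "method A separates better than method B" — are visual,
and a test needs a scalar. No significance testing is attached to score
differences, deliberately: one number per method per run is the honest
granularity.

## What the synthetic generator emulates — and what it does not

`generate_families()` produces $K$ families from one random ancestor:
each family founder carries `floor(divergence * L)` substitutions at
positions *disjoint across families*, and each member adds
`floor(noise * L)` further substitutions at random positions. The defaults
— 5 families of 40 members, 822 bp, 5% divergence, 0.2% within-family
noise — are the package's standard benchmark: sized like a single-locus
allele study, strongly clustered, fully seed-deterministic. The
`hla_family_sizes` vector (twelve families, 12–164 members, 540 total)
reproduces a realistically imbalanced census.

The generator makes clean, Hamming-separated clusters with independent
uniform substitutions. Real allelic data differ in ways that matter:
mutation rates vary along the sequence, alleles share nested haplotype
structure rather than disjoint diagnostic positions, recombination and
gene conversion blur family boundaries, and indels break the equal-length
assumption entirely. Passing the benchmark therefore demonstrates that the
pipeline *recovers strong cluster structure when it exists* and that the
stacked AE is competitive with PCA on such data — it does not certify
performance on real HLA sequences, whose separation structure is both
richer and messier. On data this clean, PCA is itself near ceiling, so the
margin between the two methods is small by construction; on real data with
more families than two linear components can spread, the nonlinear stack
has more room to differ.

## Problem sizes used by the tests

Unit tests run on small instances (tens of sequences, 100–200 bp, word
lengths 2–3, plans like $(64, 8, 2)$) chosen to finish in seconds while
still exercising every code path. The acceptance-style benchmark uses the
full default generator (200 sequences of 822 bp), $l = 5$ document vectors
and the compact plan $(1024, 128, 2)$ — about half a minute of training —
rather than the full four-stage plan, which is reserved for command-line
runs on real datasets. These sizes are the package's own testing choices;
the full plans remain the defaults of `run_pipeline()`.

## Known limitations

- One-hot mode requires pre-aligned, equal-length sequences; the package
  never aligns.
- Plain SGD with the default budget is tuned for matrices of a few hundred
  rows; much larger datasets will want more epochs or a larger batch size.
- Mini-batch training depends on row order by construction (batches are
  drawn from the shuffled index stream); only full-batch configurations
  (`batch_size >= N`) are exactly permutation-invariant.
- The silhouette compares *embeddings*, not models: a method could in
  principle score well by collapsing within-family variation that a user
  cares about. Inspect the plots alongside the score.
- Word lengths above 6 multiply the vocabulary by 4 per step and are cost-
  guarded; the sweep harness (`sweep_word_length()`) covers the useful
  range 4–6.
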