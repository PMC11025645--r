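---
title: "Methods: encoding models, linear next-word readouts, representational generality, and variance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding models, generality, variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`langenc` asks a question that recurs in language neuroscience: when one
stimulus representation predicts BOLD responses better than another, what
property of the representation is doing the work? The package implements
four measurement pipelines — voxelwise encoding models, a linearly
extractable next-word-prediction perplexity, a tournament-based
representational-generality score, and pairwise variance partitioning —
together with a synthetic-data generator whose ground truth makes every
stage testable. This vignette is the package's own account of the models,
the parameters that matter, and the design choices that were genuinely
open.

## Voxelwise encoding models

A representation instantiated on a word stream is a words × d matrix. Two
temporal steps turn it into regressors on the scanner clock: Lanczos
interpolation (3 lobes, cutoff at the TR grid's Nyquist frequency)
resamples word-anchored features onto TR times, and an FIR delay stack
concatenates copies shifted by 2, 4, 6, and 8 s so the regression can
absorb the hemodynamic lag without committing to an HRF shape. Word
features are anchored at word onsets — the perceptual event time; the
midpoint or offset would be defensible too, but onset anchoring keeps the
convention of the auditory-encoding literature. Delays must be integer
multiples of the TR and shifts are exact (zero-padded at the run start);
this keeps the variance-partitioning comparisons bit-reproducible.

Responses are conditioned the way drifting BOLD data are in practice:
a second-order Savitzky–Golay filter with a 120 s window (window length
`round(120 / tr)` forced odd) estimates and removes slow drift; 10 volumes
(20 s at TR 2 s) are trimmed from each end, absorbing onset artifact and
the filter's edge region; each voxel is z-scored. The filter reproduces
any quadratic exactly, so polynomial drift up to order 2 is annihilated by
construction — one of the identities in the test suite.

Ridge regressions are solved exactly through one SVD of the (centered)
design per training set, reused across the entire regularization path and
all voxels. The per-voxel penalty is chosen on a 10-point log-spaced grid
(1 to 1e4) by mean held-out correlation over 5 cross-validation folds
built from contiguous 40-TR chunks — chunked assignment is the standard
guard against temporal-autocorrelation leakage. Ties go to the larger
penalty (prefer the more regularized model). Models are scored by held-out
Pearson correlation per voxel; zero-variance predictions score 0 with a
warning rather than NA.

Voxel selection uses the explainable-variance noise ceiling from repeated
test runs: per voxel, the fraction of single-repeat variance explained by
the across-repeat mean, bias-corrected as
`EV = 1 - (1 - EV_raw) * n / (n - 1)` so that pure noise centers on zero —
without this correction a 5% threshold would pass noise voxels at small
repeat counts. The language-responsive mask keeps voxels with EV at or
above 5% (inclusive: "at least"). Encoding performance for a
representation is the mean correlation over masked voxels, then over
subjects; the all-voxel mean is reported alongside because the choice is
not settled for every use.

## Linearly extractable perplexity

How much next-word information can be read out of a representation
*linearly*? The readout is ordinary least squares from representation row
t to the embedding of word t+1. A predicted embedding becomes a
vocabulary distribution via a softmax over dot products with every
vocabulary embedding, divided by a temperature. The metric is the
exponentiated average cross entropy against the true next word on held-out
tokens; lower is better, and plots conventionally show negative perplexity
so that "up" means "better".

The embedding-to-distribution link is genuinely underdetermined (dot
product, cosine, or negative distance would all serve), so the package
commits to the standard embedding-decoder construction — dot-product
logits — and fits the single temperature scalar on a validation split by
golden-section search on log-temperature, with ties resolved toward 1.
The free temperature makes the metric invariant to embedding norm
conventions, and the least-squares readout makes it invariant to any
invertible rescaling of the representation (both are property tests).

Calibration has an intrinsic limit worth knowing: a temperature softmax
over dot products cannot represent an arbitrary next-word distribution.
Analytic calculation (optimal temperature, stationary-weighted cross
entropy) shows the gap to the chain's entropy-rate bound is under 1% for
high-entropy transition rows (symmetric Dirichlet concentration 5 at
vocabulary 50) but exceeds 25% for near-deterministic chains, where log
probabilities are far from linear in probabilities. The calibration test
therefore lives in the high-entropy regime; for strongly predictable
streams the metric remains a valid *comparative* score but not an
estimator of the true perplexity floor.

## Representational generality

The generality pipeline asks how well the information a representation
extracts from a universal input space transfers to every other
representation. Per representation, a bottlenecked linear encoder maps the
universal space (vocabulary embeddings of the stimulus) through a 20-dim
latent space to the representation, trained end-to-end by stochastic
gradient descent with batch size 1024 (learning rate 1e-4); in the
noiseless linear case this is reduced-rank regression, and the SGD fit is
required — and tested — to land within 1% of the closed-form optimum. The
20-dim bottleneck normalizes representations by dimensionality: the score
measures what a representation *knows*, not how many dimensions it has.
For every ordered pair, a linear decoder (learning rate 2e-5) maps the
frozen source latents to the target representation; nothing anywhere is
nonlinear, so representations that are only nonlinearly decodable from one
another are treated as distinct.

Decoders fighting over the same target are compared per held-out sample:
entry (i, j) of a target's tournament matrix is
`(wins_i + epsilon) / (wins_j + epsilon)` with exact error ties split
half-and-half. The raw ratio is undefined when one decoder wins every
sample, so a pseudo-count of `epsilon = 1` is applied throughout for
continuity (at the test-set sizes used this perturbs a 75%/25% split by
under 3%; with `epsilon = 0` the worked 75/25 example is exactly 3, which
is what the test suite asserts). Averaging the per-target matrices, then
averaging the result along its first axis, yields the generality score;
isolating a single named target's matrix yields the transfer score toward
that target (the stand-in for "transfer to a translation model"). Three
points were left open by the method's description and are resolved here:
self-target matrices are excluded from a representation's own average
(self-transfer is degenerate); the train/test split for the tournament is
a held-out token range from a separate stream of the same chain; and
ratio averaging is offered both arithmetically and in the log domain.
The pipeline's headline metric is the mean **log** win ratio (0 = even):
win ratios are multiplicative, and on a synthetic family whose members
range from nearly uninformative to fully informative the raw ratios span
orders of magnitude, where an arithmetic mean is dominated by a few
blowout entries. Both versions are written to disk.

### SGD conventions and preconditioning

The batch loss is the sum of squared errors over the batch (so the printed
learning rates scale with batch size). Inputs are whitened and targets
z-scored inside the trainers, on the training split only; the stored
transform folds back into the fitted affine map, so the model class and
the least-squares optimum are untouched. This preconditioning is what
makes fixed learning rates meaningful across data sets: without it the
gradient curvature is set by the input covariance spectrum, and strongly
correlated inputs (the interesting case — representations sharing latent
structure) sit outside the stable step range. Training runs up to 500
epochs with early stopping on a 10% validation split (patience 20,
relative improvement threshold 1e-7), keeping the best-validation
snapshot; oracle-equivalence tests instead run with `val_frac = 0` and a
large epoch budget, i.e. plain gradient descent to convergence. Because
the squared-error gradient is column-separable across targets, all
decoders sharing a source are trained in one batched pass
(`train_transfer_decoders_multi`) that takes exactly the same per-target
steps as separate training with a shared seed — an equivalence the test
suite checks to 1e-10.

## Variance partitioning

For two feature spaces A and B, three encoding models are fit per voxel —
A alone, B alone, and the column-concatenation — under the same
single-alpha-per-voxel ridge scheme. Held-out performance is converted to
signed R² (`r * |r|`), and the partition is
`unique_A = r2_AB − r2_B`, `unique_B = r2_AB − r2_A`,
`shared = r2_A + r2_B − r2_AB`; the three components sum to `r2_AB`
exactly, by construction. A banded (per-space alpha) variant is
deliberately omitted: with a single joint penalty the concatenated model
can score slightly *below* the better single space when the second space
adds covariance but no signal, which is precisely the negative-unique-
variance phenomenon the analysis is designed to expose. The dominance
property this supports — a lossy projection of a richer space explains no
unique variance anywhere while the richer space keeps its unique share —
is checked over ten generator seeds.

## The synthetic generator: what it emulates, what it does not

Every input is generated with known ground truth:

* **Word stream** — a first-order Markov chain over a finite vocabulary,
  transition rows drawn from a symmetric Dirichlet; low concentration
  gives a predictable stream. The entropy rate is computed analytically
  from the stationary distribution, giving the perplexity floor
  `exp(H)`. Word durations are i.i.d. gamma (mean 0.4 s — natural speech
  rate, shape 5 for realistic jitter); words are contiguous, so onsets
  strictly increase.
* **Representation family** — a vocabulary factor table assigns each word
  k latent scores; a representation uses a subset of factors mixed by an
  i.i.d. Gaussian loading matrix plus Gaussian noise. Factor *coverage*
  is thus a controlled notion of how much of the shared structure a
  representation sees. In the comparison pipeline the factor table is
  the top-k principal directions of the chain's mean-next-word-embedding
  map (the "predictive" basis), so coverage simultaneously controls
  encodability, transferability, and next-word information — the premise
  of the end-to-end pattern test. A generic random basis is also
  available and is what the ordering tests use.
* **BOLD** — design-times-weights plus i.i.d. Gaussian noise, with the
  same Lanczos + FIR structure used by the encoding module, so recovery
  is exact in the noiseless limit and the explainable-variance ratio
  s²/(s²+n²) is known per voxel. Repeats share the signal component
  exactly. A quarter of voxels get zero weights so the 5% mask has
  something to reject.

Not emulated: BOLD temporal autocorrelation beyond the delayed-linear
model, scanner drift nonlinearity beyond polynomial order 2 + sinusoid
test probes, heavy-tailed feature statistics of real NNLM activations,
subword tokenization, and any cortical geometry. Passing tests therefore
demonstrate correctness of the machinery and recoverability of planted
structure, not performance claims about real fMRI or real language-model
features; the numerical correlations the pipeline prints depend on the
generator's conditions and are not estimates of any published value.

## Study conditions and problem sizes

The default configuration (`default_config()`) fixes the study
conditions: vocabulary 30, 36-dim embeddings (≥ vocabulary, so word
identity is linearly decodable from the universal space), Dirichlet
concentration 0.6, k = 8 latent factors, a 72-member family with coverage
cycling 1..8 and noise σ in [0.15, 1], 2,600 train + 1,300 test words at
TR 2 s, 60 voxels (75% responsive at explainable variance 0.5), 5
repeated test runs, and a 70-point × 10,000-iteration subsample of the
metric correlations. The generality stage trains on 700 tokens for up to
100 epochs per fit — enough for the convex decoders to converge at their
fixed learning rate — and tournaments are scored on 600 held-out tokens.
The zero-coverage (pure-noise) level is exercised in the dedicated
ordering tests rather than the comparison family, where its extreme win
ratios would dominate every average. Subsampling is without replacement
(`replace = TRUE` gives a bootstrap instead); one global seed derives all
stage seeds by fixed offsets, and rerunning any configuration reproduces
every output byte for byte.

## Numerical choices and degenerate inputs

Log-sum-exp arithmetic guards every softmax; constant voxels are zeroed
with a warning (never dropped, preserving indexing); zero-variance
predictions or responses score correlation 0 with a warning; singular
directions below 1e-8 of the leading singular value are excluded from
whitening; ridge fitting rejects rank-0 designs and NaN inputs; empty
representations resample to zero matrices of the right shape. Serialization
is plain text throughout — TSV for streams, matrices, and BOLD runs
(with attribute headers), YAML for ground truth and configuration, CSV
for every result table — chosen for portability and diffability.

## Known limitations

The perplexity metric's softmax link biases it upward for low-entropy
streams (see above). The generality score depends on the chosen universal
space; with a universal space that cannot linearly express a
representation, the encoder floor rises and transfer saturates. An
encoder trained toward a pure-noise target retains its random
initialization in the unused latent directions, so even a "noise"
representation's latents carry a random projection of the universal
space; the ordering tests show trained structure still wins, but the
noise floor of the score scale is not zero information. Finally, the
single-alpha concatenated ridge is intentional (see variance
partitioning) but means `unique` components can be slightly negative;
interpret small negative values as "no unique contribution".
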