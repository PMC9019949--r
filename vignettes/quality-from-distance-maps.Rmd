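---
title: "Estimating protein model quality from distance difference maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein model quality from distance difference maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmqa)
```

## The problem

Estimation of model accuracy (EMA, also called model quality assessment)
asks: given a computed 3D model of a protein — a *decoy* — how close is it to
the native structure, without knowing that structure? A *single-model* method
scores one decoy in isolation, which lets it rank a pool of candidate models
and, unlike pool-comparison methods, assign an absolute quality to a lone
model. The quality scale used here is GDT-TS, a superposition-based global
similarity score in $[0, 1]$ (higher is better).

`dmqa` predicts GDT-TS from a single, raw input: the residual between the
inter-residue distances a sequence-based predictor *expects* and the
distances the decoy *realizes*.

## The difference-map representation

For a target of length $L$, two $L \times L$ distance matrices are compared:

* $A$ — distances predicted from the sequence alone (an external input, read
  from a plain-text matrix with `read_predicted_map()`);
* $B$ — distances measured between representative atoms of the decoy's
  residues (`model_distance_map()`).

Distances above a cutoff (16 Å by default) say little about the fold, so the
two maps are filtered *mutually*: whenever either $A_{ij}$ or $B_{ij}$
exceeds the cutoff, both entries are set to 0. The element-wise residual
$D = A^* - B^*$ of the filtered maps is symmetric, so its lower triangle and
diagonal are zeroed, leaving the upper-triangular difference map $U$ — the
network's sole input. A perfect decoy under a perfect predictor gives
$U = 0$; systematic compaction or expansion of the model shows up as signed
bands in $U$.

Choices the representation fixes:

* **Representative atom.** C-beta, falling back to C-alpha for glycine or
  when C-beta is missing — the convention of sequence-based distance
  predictors. `atom = "ca"` forces C-alpha. The convention is recorded in
  the feature store and checkpoints, and prediction refuses inputs
  featurized under a different convention.
* **Residues missing from the decoy.** Indexed by residue number within the
  target length; their rows/columns of $B$ are set above any threshold so
  the mutual filter removes them, keeping $A$ and $B$ aligned at
  $L \times L$.
* **PDB dialect.** First model, first chain, highest-occupancy alternate
  location, insertion codes in file order — the common shape of CASP decoy
  files.
* **Near-diagonal pairs** are not masked; short-range residuals carry signal
  and the filter already removes long-range noise.
* **Predicted-map hygiene.** Real-valued predictors emit nearly symmetric
  matrices; asymmetry up to 0.5 Å is averaged away, anything larger is
  treated as a corrupt file.

## The network

`build_network()` assembles, in order: four convolutional blocks (3×3
convolution, stride 1, zero padding; batch normalization; leaky rectifier),
squeeze-and-excitation (SE) channel attention in the first two blocks with
ratio 16, a global max pool over each of the final 256 channels, and four
dense blocks reducing $256 \to 64 \to 16 \to 1$. The output activation is a
plain rectifier (scores are non-negative); every other non-SE activation is
the leaky rectifier (slope 0.01). The global max pool makes the network
length-agnostic: any $L$ maps to a fixed 256-vector, and the parameter count
is independent of $L$.

An SE block squeezes each channel to its spatial mean, passes the channel
vector through a bottleneck (fully connected $C \to C/16$, leaky rectifier,
fully connected $C/16 \to C$), and gates each channel by the resulting
sigmoid weight in $[0, 1]$. Clamping every gate to 1 (`se_override = 1`)
reproduces, exactly, the no-SE network with the same remaining weights
(`strip_se_blocks()`), which is what makes an SE-ablation comparison
well-defined.

Numerical and design choices worth knowing:

* **Spatial downsampling.** A 2×2 max pool (ceil mode) follows blocks 1–3 by
  default (`pool_positions`). The global max pool makes the output
  contract independent of this choice, and per-channel positive gains
  commute with max pooling, so the SE gate acts on the pooled features. The
  resolution-preserving variant (`pool_positions = integer(0)`) computes the
  same kind of function at roughly 25× the arithmetic cost; at desk scale,
  training it on a CPU is impractical, which is why downsampling is the
  default.
* **Initialization.** Kaiming-normal weights under the config seed; biases
  zero except the output bias, which starts at 0.5, the midpoint of the
  GDT-TS range. A rectified scalar head whose pre-activation is negative for
  every training input has zero gradient and can never recover — some seeds
  are born dead. `train_network()` therefore checks liveness on the training
  batches before the first step and deterministically raises the output bias
  in 0.5 steps until at least one prediction is positive (a no-op for live
  seeds, logged when triggered).
* **Batch normalization** sits between each convolution and its activation;
  training normalizes with biased batch moments and keeps running moments
  (momentum 0.1) for evaluation, so inference is deterministic and
  batch-size independent.
* **Convolution arithmetic** runs as im2col + GEMM in single precision; the
  kernels are 3×3 (short accumulations) and activations are $O(1)$, so the
  ~1e-6 relative rounding is far below the optimizer's noise floor.
* **No clamping at 1.** The final rectifier permits predictions above 1
  although GDT-TS is bounded; ranking is unaffected, so the raw value is
  reported (a report-time clamp is available via `clamp = TRUE`).

## Training

The regression loss is the smooth L1 (Huber-like) loss on the residual
$x = \hat{y} - y$: $0.5x^2$ for $|x| < 1$, $|x| - 0.5$ otherwise — quadratic
near zero, linear in the tails, hence less outlier-sensitive than squared
error; its derivative is $x$ on $(-1, 1)$ and $\pm 1$ outside (both branches
agree at $|x| = 1$, where the closed-interval convention assigns $\pm 1$).
Optimization is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$) at a constant
learning rate of $5 \times 10^{-5}$, batch size 16, mean reduction within a
batch.

Decoys are grouped into *length-homogeneous* batches
(`make_length_batches()`) so each batch stacks into one $b \times 1 \times L
\times L$ tensor; 80% of each batch, drawn at random per batch, forms the
training set and the rest the validation set (`split_batches()`; a
single-record batch goes to training, preferring complete validation pools).
Batch order — not batch contents — reshuffles every epoch under the seed.
The epoch count is a free budget; the default of 60 was chosen from the
validation-loss curve on synthetic data, which plateaus within a few dozen
epochs at desk scale, and the returned network carries the parameters of the
epoch with the lowest validation loss. History row `epoch = 0` records the
pre-training losses, so the optimization start is visible.

## Evaluation

`evaluate_pools()` reports, per target pool:

* **Ranking loss** — $|$true GDT-TS of the pool's best model $-$ true GDT-TS
  of the model ranked first by prediction$|$; 0 means the best model was
  selected. Ties in the predicted score break by lexicographic model id.
* **Pearson correlation** between predicted and true scores; a constant
  sequence makes it undefined, and such targets are excluded from the
  average (with a count), not coerced to zero.

Aggregates: the unweighted mean of both across targets, the skewness of the
ranking-loss sample in the biased population form
$\frac{\frac1n\sum(x_i-\bar x)^3}{(\frac1n\sum(x_i-\bar x)^2)^{3/2}}$, and
two two-sample Kolmogorov–Smirnov comparisons — all true vs all predicted
scores pooled over models, and per-target best true score vs the selected
model's true score. $D_{(n,m)} = \sup_x |F_{1,n}(x) - F_{2,m}(x)|$ is
computed exactly by evaluating both empirical distribution functions at
every pooled data point; the p-value uses the asymptotic Kolmogorov series.
Because a correlation can be averaged per target, pooled over all models, or
taken between best and selected scores, the report carries all three,
labeled.

## The synthetic benchmark

Real decoy sets require large archives and a structural-superposition tool
for labels, so the package ships a generator (`generate_dataset()`) that
emulates the statistical structure the method needs while writing exactly
the external formats the pipeline consumes (PDB decoys, plain-text maps,
labels TSV):

* **Natives**: self-avoiding random walks at 3.8 Å C-alpha spacing with a
  4 Å excluded-volume radius; idealized C-beta pseudo-atoms 1.53 Å off the
  trace (about 10% glycines exercise the C-alpha fallback).
* **Decoys**: every atom perturbed by isotropic Gaussian noise; the default
  scales $\{0.25, 0.5, 1, 2, 4\}$ Å are assigned round-robin so each pool
  spans low to high quality.
* **Labels**: a superposition-free GDT-TS surrogate — the mean over cutoffs
  $\{1, 2, 4, 8\}$ Å of the fraction of residue pairs (native distance ≤
  16 Å) whose decoy-vs-native distance error is below the cutoff. It is
  rank-faithful to model quality, exactly computable, and a deterministic
  function of the same distance maps the difference map exposes, which is
  what makes the regression task learnable in principle. Under the default
  noise scales the pooled labels span roughly $[0.33, 1]$; pushing the
  minimum lower would need coordinate noise of ~8–10 Å.
* **Predictor noise**: symmetric Gaussian noise (0.5 Å by default) added to
  the native map in distance space, clipped at zero — mimicking an imperfect
  sequence-based predictor. It is shared by all decoys of a target, so it
  perturbs absolute scores more than within-target ranking.

What the generator does *not* emulate: real protein geometry (no secondary
structure, no Ramachandran statistics), CASP server error modes (fragment
swaps, register shifts, domain misassembly), or length-correlated difficulty.
Passing the desk-scale learning test therefore shows the pipeline is
implemented correctly and can extract quality signal from difference maps —
not that the trained weights transfer to real decoys.

## Desk-scale problem sizes

The shipped tests and the acceptance script run the full workflow on the
default generator spec — 30 targets, lengths 30–60, 20 decoys each, 600
difference maps, 60 training epochs — which completes in minutes on one CPU
core. Per-target validation correlation above 0.8 and a mean validation
ranking loss well under the enumerated random-selector baseline are the
expected outcome at this scale.

## Reproducibility

Every stochastic step (chain growth, decoy noise, weight initialization,
batching, splitting, epoch shuffling) is a deterministic function of the
seeds in the configuration objects; the command-line workflow writes a
resolved-config copy next to its outputs, and reruns with the same seed are
byte-identical in their manifests, history and prediction tables.
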