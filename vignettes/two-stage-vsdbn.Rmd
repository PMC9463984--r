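---
title: "Two-stage volumetric sparse DBNs for naturalistic fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage volumetric sparse DBNs for naturalistic fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Naturalistic fMRI (movie watching and similar rich stimuli) evokes brain
activity that is partly synchronized across subjects — especially in primary
sensory cortex — and partly idiosyncratic, especially in heteromodal
association cortex. A decomposition method for such data should therefore
deliver *two* linked descriptions: a group-level set of functional brain
networks (FBNs) that captures what is shared, and per-subject networks that
stay in register with the group solution while expressing individual
variation. This package implements that program as a two-stage volumetric
sparse deep belief network (vsDBN), with the network architecture chosen by a
particle-swarm search, and with a complete evaluation suite (ISC, SCC,
overlap rate, dynamic-connectivity states, SDFC) runnable end to end on
synthetic data with known ground truth.

# Data model and preprocessing scope

A subject's run is a 4D volume series reduced to a `v x m` matrix (TRs by
in-mask voxels) over a group-common mask; each voxel time course is z-scored.
The group matrix concatenates all subjects along time and is then treated
*volumetrically*: each row — a whole brain volume — is one training sample,
so the model learns spatial structure and the hidden time courses follow from
applying it row by row.

Deliberate conventions, fixed and tested:

* **Voxel ordering** is column-major (first array axis fastest), i.e. R's
  native `which()` order on the mask array. Any deterministic order works as
  long as matrices and maps agree; this one makes folding maps back into the
  volume a single indexed assignment.
* **Z-scoring uses the population standard deviation** (divide by `n`). The
  choice is invisible downstream (correlations are scale-free) but makes
  normalization exactly idempotent, which is tested.
* **Zero-variance voxels** cannot be z-scored; they are dropped with a
  warning and their indices recorded, and the mask is pruned to stay aligned.
* **Mask intersection happens before extraction and normalization**, so all
  subjects share one voxel frame before any statistics are computed.
* The TR (default 1.5 s) is carried as metadata only.

Motion correction, slice timing, smoothing, filtering and registration are
out of scope: the package starts from preprocessed volumes.

# The RBM layer

Each layer is a restricted Boltzmann machine. The Bernoulli form has energy

$$E(v, h) = -\sum_i a_i v_i - \sum_j b_j h_j - \sum_{i,j} v_i W_{ij} h_j ,$$

and because z-scored volumes are unbounded reals, the first layer defaults to
Gaussian visible units with unit variance,

$$E(v, h) = \sum_i \frac{(v_i - a_i)^2}{2} - \sum_j b_j h_j
            - \sum_{i,j} v_i W_{ij} h_j ,$$

which leaves the hidden conditional logistic in both cases,
$p(h_j = 1 \mid v) = \sigma(b_j + \sum_i v_i W_{ij})$. Upper layers are
Bernoulli RBMs fed the previous layer's mean-field activation
*probabilities* (not samples), so the deterministic parts of the stack are
exactly reproducible. The pure Bernoulli form is retained as a switch and is
what the exact-enumeration oracle tests exercise: on models with a dozen
units the full Boltzmann distribution is enumerable, and the package's
conditionals, normalization and Gibbs sampler are checked against it to
machine precision.

**Sparsity.** "Sparse" is implemented as a penalty driving the mean hidden
activation toward a target $\rho$ (default 0.1): the gradient adds
$\lambda(\rho - q_j)$ to each hidden bias, with $q_j$ the data-phase mean
activation of unit $j$. Strength $\lambda$ defaults to 1 — see *Training
defaults* below for why.

**Training** is minibatch CD-1 (configurable order) with momentum stepping
0.5 to 0.9 after 5 epochs, weight decay `2e-4`, batch 64, and a seeded
shuffle per epoch, so training is bit-reproducible. The reconstruction error
reported per epoch is the deterministic mean-field MSE.

## Training defaults

The learning rate defaults to 0.05 for Gaussian layers and 0.01 for
Bernoulli layers, and the sparsity weight to $\lambda = 1$. These were fixed
by a recovery study on the reference synthetic fixture (below): with a
timid Gaussian rate (0.001) and weak sparsity (0.1), CD learns filters that
span the signal subspace but remain mixtures of the planted networks
(best-matched spatial correlations around 0.55–0.68); the stronger settings
produce sparse-coding-like solutions that recover the planted networks
cleanly (typically 6–8 of 8 atoms above 0.7). They are defaults, not
constants — everything is settable through `train_config()` and the pipeline
configuration file.

# The two-stage vsDBN

Stage 1 trains the stack greedily on the group matrix. Stage 2 copies the
trained group model per subject (`init_subject_from_group()`), so that every
layer starts at the group weights, and then fine-tunes all layers greedily on
that subject's data at a reduced learning rate (default x0.1) for a short
budget (default 20 epochs). The weight transfer is what gives the method its
defining property: atom `k` of every subject model corresponds to atom `k`
of the group model *by construction*, with no post-hoc matching. The
zero-epoch case is an exact identity and is asserted in the tests. Whether
stage 2 should update all layers or only some is genuinely open; updating
all at a reduced rate is the default and is configurable.

**Spatial maps** are read out by the linear-combination rule: layer-1 maps
are the columns of $W_1$, layer-2 maps of $W_1 W_2$, layer-3 maps of
$W_1 W_2 W_3$. This ignores the logistic nonlinearity — an approximation
inherent to this model family, kept because it maps every hidden unit to one
voxel-space pattern. Because an RBM atom's sign is arbitrary, each map is
z-scored (optionally) and then flipped so its maximum-magnitude voxel is
positive; the flips are recorded on the result.

# Architecture search

The architecture — number of hidden layers in [2, 10] and one shared node
count in [100, 800] — is chosen by particle-swarm optimization:

$$v \leftarrow w\,v + c_1 R_1 (pbest - x) + c_2 R_2 (gbest - x), \qquad
  x \leftarrow x + v,$$

with $w = 0.1$, $c_1 = c_2 = 2$, and $R_1, R_2$ drawn per step and dimension
from $[-1, 1]$. That interval (rather than the classical $[0, 1]$) makes the
attraction terms zero-mean; what drives convergence is that the step
*variance* scales with the distance to the bests, so the swarm performs a
stochastic contraction onto the best architecture found (the per-dimension
log-contraction rate is negative). The classical interval is available as a
config switch. Positions are continuous and rounded only at evaluation,
which avoids dead discrete dynamics; they are clipped to the ranges after
every move.

Each iteration runs evaluate, then aging-evolution mutation, then the PSO
update. Mutation retires the oldest particle and inserts a perturbed copy of
the best of 3 sampled particles (layers +-1 and/or nodes +-Uniform(10, 50)),
which keeps the swarm diverse; the swarm-level best is stored outside the
population and cannot be lost. Tournament size, deltas, and one replacement
per iteration are fixed defaults (the mechanism is only loosely constrained
by precedent), all configurable.

Fitness is the held-out full-stack mean-field reconstruction MSE after a
reduced training budget (default 15 epochs per layer; the budget is part of
the run manifest). Failed trainings score `+Inf` with a warning. Fitness
values are cached per rounded architecture within a search. The number of
iterations defaults to 40; a linearly decreasing inertia schedule is
available and, on the benchmark landscape
$f(L, N) = |L - 3| + |N - 146| / 100$, behaves comparably to the fixed
$w = 0.1$. The benchmark is also the package's search-validation target: 30
particles, 40 iterations finds the optimum (3, 146) in essentially every
seeded run, with a monotone global-best trace by construction.

# Evaluation metrics

* **ISC** (inter-subject correlation) of an atom's time course, leave-one-out
  by default: each subject against the mean of the others, one value per
  atom per subject, averaged over atoms then subjects. A mean-pairwise
  variant is available; the leave-one-out form is the default because it
  yields exactly one value per subject per atom. Constant time courses are
  excluded with a warning.
* **SCC** — Pearson correlation across voxels between two maps; symmetric.
* **Overlap rate** $R(S, T) = |S \cap T| / |T|$ with `T` the group network:
  deliberately asymmetric (how much of the group network the individual
  covers). Maps are binarized at $z > 1.96$, positive side, by default; the
  threshold is a config value recorded on the binary map, since no canonical
  cutoff exists.
* **Atom matching** (needed only against ground truth or across independent
  models) maximizes total $|SCC|$ with an exact assignment solver; between
  the two stages the identity correspondence holds by construction.
* **Group comparisons** of per-network consistency scores use all pairwise
  two-sample t tests with Benjamini-Hochberg correction, reported as a
  lower-triangle table.

# Dynamic functional connectivity

Windowed connectivity uses a tapered window: a 22-TR rectangle convolved
with a Gaussian of sigma 3 TRs truncated at +-11 TRs, slid in steps of 2.
The truncation half-width is this package's convention: it is the value that
makes the effective window length 22 + 2x11 = 44 TRs, the unique
step-compatible length that yields 82 fully contained windows on a 206-TR
series — the geometry the method is calibrated to. Weights act as
observation weights in a weighted Pearson correlation per window pair.

Windowed matrices (vectorized upper triangles) are clustered with k-means,
k = 4 by convention, Euclidean distance, 20 seeded restarts. States are
relabeled by order of first occurrence, so state 1 is always the first
pattern seen. If the windows contain fewer distinct patterns than k the
result is flagged degenerate rather than erroring.

**SDFC** compares group-level and individual-level state sequences:

$$SDFC = \frac{1}{W} \sum_{i=1}^{W} \mathrm{corr}(S^g_i, S^d_i),$$

where $S^g_i, S^d_i$ are the state (centroid) matrices assigned to window
`i` at the two levels and `corr` is the Spearman rank correlation of the
off-diagonal entries. Spearman is used (the conventional name "corr2"
usually denotes Pearson, but rank correlation is the stated intent and is
invariant to monotone distortions of connectivity strength); Pearson and a
raw-window comparison are available as switches for sensitivity analysis.
On real data the atoms entering DFC would be a curated list of meaningful
networks; curation is manual and out of scope, so the pipeline takes an
explicit atom-index list and defaults to all top-layer atoms on synthetic
data.

# The synthetic generator

`make_dataset()` emulates the statistical skeleton the method targets:
`k1` primitive networks (Gaussian blobs at separated random centers inside a
brain-like super-ellipsoid mask), `k3` composite maps (sums of 2–3
primitives, the analogue of deep-layer combined networks), and per-subject
time courses
$S_s \propto (1 - \alpha) G + \alpha U_s$ mixing group-shared and
subject-specific sources, with additive Gaussian noise. The mixing ratio
$\alpha$ is the experiment's main dial: 0 gives identical subjects, 1 fully
idiosyncratic ones, and empirical ISC of the sources decreases monotonically
in between (tested over seeds).

Sources are moving-average-smoothed white noise **rectified at zero** and
standardized. Rectification matters for two reasons: it mimics the
transient, burst-like activations of stimulus-driven networks, and it makes
the sources super-Gaussian. With jointly Gaussian sources a linear mixture
is rotationally unidentifiable — any orthogonal rotation of sources and maps
yields the same data distribution — so no blind decomposition could recover
the planted maps even in principle; a recovery benchmark built on Gaussian
sources would measure nothing. A least-squares oracle (regression of
noiseless data on the true sources) recovers the maps at SCC >= 0.99, which
is tested and guarantees the fixtures are well-posed independently of any
DBN.

What the generator does **not** model: hemodynamic-response convolution,
physiological noise and scanner drift, spatial autocorrelation of noise, and
anatomically realistic network geometry. Passing the recovery suite
therefore demonstrates the correctness and calibration of the machinery on
data with the assumed mixture structure — not performance on real fMRI.

**Reference problem sizes.** The package's standard experiments use a 12^3
grid (~950–1000 in-mask voxels), n = 8 subjects, v = 100 TRs, k1 = 8
networks, noise SD 0.1, alpha 0.2; stage-1 training uses a 16-16-16
architecture for 100 epochs, stage 2 fine-tunes 20 epochs at x0.1 rate.
These sizes keep a full pipeline run in seconds on one CPU while leaving
every stage's behaviour measurable. The planted-state DFC fixture uses 4
states with rank-2 correlation structure, 100-TR dwells over 800 TRs, so
most windows sit fully inside one state segment (windows straddling a
boundary carry mixed correlation by construction and may legitimately fall
to either side).

# Numerical and degenerate-input policy

* Empty masks, mismatched grids, and shape mismatches raise immediate
  dimension errors naming the offending quantity.
* Constant maps make SCC and binarization undefined — an error, not an NA —
  while the pipeline records per-atom NA overlap for flat thresholded atoms
  and aggregates with `na.rm`.
* Windows with zero weighted variance get their correlations set to 0 with
  one warning.
* k-means uses multiple restarts under a fixed seed; degenerate clustering
  (fewer distinct patterns than k) is flagged, not fatal.
* All randomness flows from explicit integer seeds; two runs of the full
  pipeline with one seed produce byte-identical outputs, verified by the
  manifest's md5 table.

# Known limitations

* CD-1 training of Gaussian-visible RBMs is noisy at small scale; recovery
  quality on the reference fixture varies a few atoms from seed to seed.
* The linear-combination map read-out ignores the stack's nonlinearity.
* The aging-evolution details and the per-candidate budget of the
  architecture search are defaults chosen here, not canonical values.
* The synthetic data's simplifications (above) bound what the test suite can
  claim about real NfMRI.
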