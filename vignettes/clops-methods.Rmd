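---
title: "Continual learning for cardiac signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continual learning for cardiac signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A classifier deployed on streamed physiological data rarely sees one fixed
distribution. New arrhythmia classes appear, the patient mix drifts with
season, the recording modality changes, the data source switches
institutions. Trained sequentially on such a stream, an ordinary network
suffers *destructive interference*: performance on earlier tasks collapses
while it fits the current one. `clops` implements a replay-based
continual-learning strategy for single-lead ECG classification that couples
two mechanisms — importance-guided storage of instances into a replay
buffer, and uncertainty-guided acquisition of instances out of it — around
a small 1-D convolutional classifier.

## Task streams

A stream is an ordered sequence of tasks, each a labeled set of fixed-length
single-lead segments, in one of four scenarios:

* **Class-incremental** (`class_il`): consecutive disjoint class pairs
  `[0,1], [2,3], ...`; one classification head per task.
* **Time-incremental** (`time_il`): three "terms" with shared classes but
  drifting prevalence and noise; a shared head.
* **Domain-incremental** (`domain_il`): twelve lead-like tasks, each a fixed
  scalar-gain projection of the same latent traces plus lead noise; shared
  head.
* **Institute-incremental** (`institute_il`): three tasks with disjoint
  label vocabularies, different native sampling rates (resampled to the
  common grid) and noise levels; shared head.

Splits are patient-disjoint, and test instances never enter the buffer or
any gradient step.

## Task-instance parameters

Every training instance $i$ of the current task $k$ carries a learnable
coefficient $\beta_{ik}$, initialised at 1. The mini-batch objective over
the $B_k$ current-task instances is

$$\mathcal{L}_{\mathrm{current}} \;=\; \frac{1}{B_k}\sum_{i=1}^{B_k}
  \Big[\beta_{ik}\,\mathcal{L}_{ik} + \lambda(\beta_{ik}-1)^2\Big],$$

with the quadratic regulariser ($\lambda = 10$ by default) preventing the
coefficients from collapsing to zero. The coefficients are updated by
gradient descent with rate $\eta_\beta$; the exact gradient of the
objective above is $(\mathcal{L}_{ik} + 2\lambda(\beta_{ik}-1))/B_k$.
(A simplified account sometimes drops the $1/B_k$ factor; we implement the
exact gradient of the objective we optimise — the sign, which is what the
difficulty interpretation rests on, is unaffected.) Since harder instances
incur larger losses, their coefficients sink lower: $\beta$ is a proxy for
instance difficulty. Replayed instances from earlier tasks contribute an
*unweighted* mean loss, and the two parts add.

Because final-epoch $\beta$ values can swap order late in training, storage
decisions use the **area under the whole trajectory** (trapezoidal rule
over epoch-end snapshots with $\beta(0)=1$ prepended),

$$s_{ik} = \sum_{t=0}^{\tau-1}
  \frac{\beta_{ik}(t+1)+\beta_{ik}(t)}{2},$$

so a constant-1 trajectory over $\tau$ epochs scores exactly $\tau$. When a
task finishes, instances are ranked by $s$ (descending: easy to hard), and
the top fraction `b` (default 0.25, by the ceiling so a positive fraction
always stores at least one instance) enters that task's buffer slot. Slots
are per-task and never evict each other. Ties break lexicographically on
instance id so storage is deterministic.

An alternative storage rule (`loss_area_storage`) ranks by the trapezoidal
area under the per-instance *loss* trajectory instead and stores the
smallest areas; everything else is unchanged.

## Uncertainty-guided acquisition

The classifier's single dropout site sits on the penultimate
representation. Monte-Carlo sampling runs the deterministic trunk once and
applies `T` (default 20) independent dropout masks, yielding for each
buffered instance a set of `T` posterior probability vectors. The BALD
disagreement score is

$$\mathrm{BALD} = H(\bar p) - \frac{1}{T}\sum_t H(p_t),$$

with natural-log entropies ($H$ is used only for ranking, so the base is
immaterial; it is documented for reproducibility). The score is
non-negative and zero when all samples agree. On the epoch schedule below,
every slot is re-scored and the top fraction `a` (default 0.5) per task
forms the acquisition pool; each training mini-batch then appends `B_r`
instances drawn uniformly from the pool, supervised through the head of
their own task.

**Schedule.** With `tau` epochs per task, buffer scoring starts at global
epoch `tau_mc = tau + 1` and pool refreshes at `tau_s = tau_mc` (both then
recur every `mc_every` epochs, default 1), subject to the constraint
`tau_s >= tau_mc > tau`. In effect, buffered instances are re-scored and
replayed at every epoch after the first task — scoring precedes
acquisition within an epoch, so the two can share one.

## The classifier

A deliberately small network: three same-padded 1-D convolution blocks
(kernel 7, ReLU, max-pool 2; 16/32/64 channels by default), global average
pooling, one fully connected ReLU layer, dropout (p = 0.3) on that
penultimate representation, and a linear softmax head per task (or one
shared head). Optimisation is Adam at learning rate 1e-3 by default. The
forward and backward passes are implemented directly on BLAS matrix
operations (im2col convolutions in a batch-flattened layout); the test
suite checks the analytic gradients against central finite differences.

## Evaluation

After finishing the $i$-th task, the test AUC of every seen task $j$ is
recorded as $R_j^i$ (binary tasks: ROC AUC; multi-class: macro
one-vs-rest over classes present in the test split — the macro choice is
ours, made for robustness to class imbalance). From the matrix:

* average AUC $= \frac{1}{N}\sum_j R_j^N$;
* $\mathrm{BWT} = \frac{1}{N-1}\sum_{j<N} (R_j^N - R_j^j)$;
* $\mathrm{BWT}_t = \frac{1}{N-t}\sum_{j \le N-t} (R_j^{j+t} - R_j^j)$;
* $\mathrm{BWT}_\lambda = \frac{1}{N-1}\sum_{j<N}\frac{1}{N-j}
  \sum_{t=1}^{N-j}(R_j^{j+t}-R_j^j)$.

Positive backward transfer means later training *helped* earlier tasks.
$R_j^i$ is measured immediately after the last epoch of task $i$, with no
extra fine-tuning; class-incremental evaluation uses task $j$'s own head,
shared-head scenarios restrict the shared softmax to the task's classes
and renormalise.

Baselines: `fine_tuning` (no buffer, no coefficients) and `mtl`
(all tasks pooled, one shared head — in the class-incremental scenario this
becomes a single multi-class problem — trained once; only the final column
of R is defined). Ablations: `random_storage`, `random_acquisition`,
`random_both` replace the respective mechanism with uniform selection at
identical cardinalities.

## Task similarity and curricula

Per task, a Gaussian is fitted to the storage scores (sample mean and
sd, denominator $n-1$; a zero mean or zero variance is rejected as
degenerate rather than smoothed). Task difficulty is $d_k = 1/\mu_k$, and
similarity between tasks is one minus the Hellinger distance between their
Gaussians,

$$S(j,k) = 1-\sqrt{1-\sqrt{\tfrac{2\sigma_j\sigma_k}{\sigma_j^2+\sigma_k^2}}
  \exp\!\Big(-\tfrac{1}{4}\tfrac{(\mu_j-\mu_k)^2}{\sigma_j^2+\sigma_k^2}\Big)}.$$

A curriculum starts at the easiest task and greedily appends the
not-yet-visited task most similar to the *most recently added* one (the
chain view of similarity); the anti-curriculum starts at the hardest.
Ties break on the smaller task id.

## The synthetic generator

Real single-lead corpora are external and GPU-scale; the package ships a
generator whose segments are sums of Gaussian P-QRS-T wavelets per beat on
a flat baseline: beat onsets follow the class's mean rate with
multiplicative RR jitter, an ST plateau can be blended between the S and T
waves, and white noise is added. The 12-class palette is organised as six
pairs that share a base sinus morphology and differ in exactly one
clinically meaningful feature — rate, RR irregularity, ST offset, P-wave
presence, QRS width, signal quality — so the two classes of a
class-incremental task are symmetric in difficulty while the pairs span
gross to subtle contrasts.

Three variability mechanisms make instance difficulty a continuum within
every class, which real recordings exhibit and which the storage mechanism
needs to have anything meaningful to rank:

* per-instance morphology jitter (lognormal rate, amplitude and feature
  scaling);
* heteroscedastic noise (each recording's noise sd scaled by
  `U(0.3, 1.7)`), emulating variable ambulatory recording quality;
* a small fraction of corrupted annotations: flipped labels
  (`label_noise`, default 0.05) and artifact-only segments that keep their
  rhythm label (`artifact_frac`, default 0.08), emulating motion artifact
  labeled from surrounding context.

What the generator does **not** emulate: realistic 12-lead electrical
geometry, beat-level pathology sequences (bigeminy patterns, ectopy), QT
adaptation to rate, or annotation ontologies. Passing tests on these
streams therefore demonstrate the *mechanics* of the strategy —
difficulty ranking, buffer contracts, forgetting and its mitigation — not
clinical-grade arrhythmia classification.

## Scaled-down study conditions

The experiments run by the test suite and by `scripts/acceptance.R` use
desk-scale problem sizes, chosen once: segments of `L = 500` samples at
100 Hz (5 s), 64/24/48 train/val/test instances per task, 8 classes
(4 class-incremental tasks), `tau = 20`, batch 16 plus 16 replayed,
channels 8/16/16 with a 16-unit hidden layer, Adam at 2e-3, and the
canonical fractions `b = 0.25`, `a = 0.5`, `T = 20`, `lambda = 10`, over
five seeds. Full-length 10-s segments at 250 Hz remain the generator's
default for users.

One deviation from "defaults" deserves its rationale: the coefficient
learning rate is `eta_beta = 0.1` in these runs rather than the network
learning rate. With 64 instances per task there are only four gradient
steps per epoch; the equilibrium of the coefficient update is
$\beta^* = 1 - \mathcal{L}/(2\lambda)$, and reaching it within a 20-epoch
task at rate $\eta_\beta \cdot 2\lambda/B_k$ per step requires
$\eta_\beta$ of order 0.1. At production scale (hundreds of steps per
epoch) the network learning rate is an adequate default.

## Numerical choices and degenerate inputs

* Fraction-to-count conversions use the ceiling, so positive fractions
  always select at least one instance.
* All rankings (storage, acquisition, curricula) break ties
  deterministically — lexicographic instance id, or smaller task id.
* Posterior slices are validated to the simplex within 1e-6; BALD uses
  $0\log 0 = 0$.
* The stream container stores signals as flat little-endian doubles so
  write/read round trips are bitwise exact.
* Degenerate similarity inputs (zero-variance score distributions) raise
  errors instead of being smoothed.
* An empty replay pool contributes exactly zero loss; the first task of
  any stream trains without replay by construction.

## Known limitations

* The classifier and training scale are deliberately tiny; absolute AUC
  values on synthetic streams are not comparable to production systems.
* With per-task slots of only `ceiling(b * 64) = 16` instances, the
  easy-biased storage ranking can cover a task's data cloud worse than a
  uniform sample does; the relative standing of guided versus random
  replay selection at this scale is measured, not assumed — see the
  strategy comparison that `scripts/acceptance.R` recomputes. Guided
  acquisition presupposes a stored slot worth ranking.
* BALD scores use `T = 20` dropout masks on one trunk pass; with a single
  dropout site this is exact for the model class, but richer stochasticity
  (dropout in the trunk) would require full stochastic passes.
* The WFDB adapter reads single-channel format-16 records only — enough
  for the packaged fixtures and simple real-data ingestion, not a general
  WFDB implementation.
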