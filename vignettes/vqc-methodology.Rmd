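---
title: "Methods: quantum and classical classifiers for clinical tabular data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantum and classical classifiers for clinical tabular data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqcbench)
```

## What this package models

`vqcbench` compares two families of binary classifiers on coronary-artery-
disease-style tabular data: variational quantum classifiers (VQCs) simulated
exactly on a dense statevector, and classical feedforward networks. Both are
trained on the same synthetic cohorts, produced by a generator that emulates
the structure of the public Heart Disease benchmark (11 predictors, binary
outcome, 55%/45% class balance). Everything is deterministic given a seed, so
the repeated-seed accuracy studies and the sample-complexity study are pure
functions of their configuration.

## The quantum model

**State and gates.** An $n$-qubit pure state is a unit vector in
$\mathbb{C}^{2^n}$. The simulator implements the Pauli rotations
$R_x(\theta), R_y(\theta), R_z(\theta)$ and the two-qubit CNOT and CZ gates,
applying each gate by tensor contraction on the amplitude vector (never by
building the full $2^n \times 2^n$ matrix; that construction exists only as
a $\le 4$-qubit test oracle). Simulation is noiseless and exact — the
infinite-shot limit. Shot sampling and device noise are out of scope.

**Basis-label convention.** Amplitude index $i$ assigns qubit $q$ the $q$-th
least significant bit of $i$, and printed ket labels read $(q_0 q_1 \dots)$.
So the two-qubit vector $(a, b, c, d)$ is
$a|00\rangle + b|10\rangle + c|01\rangle + d|11\rangle$. This convention is
fixed everywhere and pinned by tests on worked examples
(e.g. $\mathrm{CNOT}|10\rangle = |11\rangle$ with control $q_0$).

**Encodings.**

* *Angle encoding*: each of the 11 predictors, with categorical features
  integer-coded, is min-max scaled onto $[0, 2\pi]$ and loaded as $R_y(x_i)$
  on its own qubit (11 qubits). Integer coding, rather than one-hot, is what
  makes the record fit 11 qubits.
* *Amplitude/basis hybrid*: the 5 standardized continuous features are
  padded with three zeros, L2-normalized and prepared on 3 qubits by
  Mottonen state preparation; the 10 drop-first one-hot bits of the 6
  categorical features are basis-encoded on 10 qubits — 13 qubits in total.
* *Data re-uploading (DR)*: optionally, the angle-encoding block is repeated
  before every ansatz layer, which is known to make such circuits universal
  approximators. DR is not combined with amplitude encoding: it would not
  add expressiveness there and the Mottonen circuit depth makes it
  expensive.

**Mottonen preparation.** Implemented as a cascade of uniformly controlled
$R_y$ rotations, decomposed recursively into $R_y$ and CNOT gates. Rotation
angles come from the subtree norms of the target vector; the leaf level uses
`atan2` on the signed amplitude pairs, so any *real* unit vector — including
negative entries, which standardized clinical features produce — is
reachable without an $R_z$ stage. Complex phases are unsupported by design;
the pipeline never needs them. The adjoint-circuit identity
(prepare-then-invert returns $|0\dots0\rangle$) is tested to $10^{-8}$.

**Ansatz.** Each layer applies: trainable $R_y$ on all $N$ qubits; CZ on
pairs $(0,1), (2,3), \dots$; a second trainable $R_y$ row on an interior
subset; CZ on the offset pairs $(1,2), (3,4), \dots$ within qubits
$1..N-2$. Two conventions exist for the second row because the layout prose
("excluding the first and last qubits", $2N-2$ rotations) contradicts the
parameter-count formula $(2N-1)L$. The default, `exclude_last_only`, keeps
$N-1$ second-row rotations so counts match $(2N-1)L$; the literal prose
variant is a configuration switch, and both are tested. The stated
minimum/maximum parameter ranges for the two encodings are mutually
inconsistent with the qubit counts under this formula (the rows appear
transposed), so only the formula is asserted.

**Measurement and output.** Every qubit's Pauli-Z expectation is measured;
their sum plus a classical bias passes through a sigmoid:
$p = \sigma(\sum_i \langle Z_i \rangle + b)$. Local (single-qubit)
observables are used deliberately — local cost functions mitigate barren
plateaus. Classification follows the $\{-1, 1\}$ convention with
$p > 0.5 \mapsto 1$; the exact tie $p = 0.5$ maps to $-1$, an arbitrary but
documented rule. The loss is binary cross-entropy on $\{0,1\}$ targets with
probabilities clipped to $[10^{-12}, 1 - 10^{-12}]$; the two label
conventions coexist in the protocol and are reconciled here by using
$\{0,1\}$ for the loss and $\{-1,1\}$ only for assignment.

**Gradients.** All trainable gates are Pauli rotations, so each circuit
parameter's derivative of $\sum_i \langle Z_i \rangle$ is computed exactly
by the parameter-shift rule — two circuit evaluations at
$\theta_k \pm \pi/2$, combined as half their difference — and chained
analytically through the sigmoid and cross-entropy (whose derivative in the
logit is $p - y$). The bias derivative is analytic. Gradients are verified
against central finite differences at $10^{-5}$.

**Quantum dropout.** Per optimization step: each layer is independently
selected with probability $p_L$ (default 0.1); within selected layers each
trainable rotation is removed with probability $p_G$ (default 0.1); the
marginal per-rotation drop probability is therefore $p_L p_G = 0.01$. The
protocol's wording ("the random selection of a QNN layer") could also mean
exactly one layer per step; independent selection is chosen because it
yields the stated product marginal exactly. Masks are resampled every step
and never applied at evaluation. Dropped rotations get zero gradient for
that step.

**Initialization and schedule.** Angles start at $0.01 g$ with
$g \sim \mathcal{N}(1, 1)$ — exactly as the protocol states it, giving mean
and SD $0.01$; the mean-one choice is unusual, so a zero-mean variant is
exposed (`centered = TRUE`). The bias starts at 0. Training uses Adam
(conventional moment decays $0.9/0.999$, $\epsilon = 10^{-8}$; the protocol
does not state them) with initial rate $0.01$, halved after 50
non-improving epochs, stopping after 100, where "improving" means the
epoch's full-training-set cross-entropy (dropout off) decreased by more
than $10^{-8}$. The protocol says only "the cost function"; training cost is
monitored for the quantum models, and the alternative is noted below for
the classical ones. Each epoch draws 10 batches of 64 without replacement;
a training set smaller than 640 is reshuffled and partitioned, keeping the
final short batch.

## The classical baseline

Feedforward networks with leaky-ReLU ($\alpha = 0.1$) hidden layers and a
sigmoid output, trained on binary cross-entropy with Adam at $0.001$,
halving after 100 non-improving epochs and stopping after 500 — monitored,
exactly as the protocol states, on the *test* cost. That choice leaks test
information into early stopping; it is reproduced deliberately and flagged,
with `monitor = "validation"` (an internal held-out split) and
`monitor = "train"` as alternatives. Hidden layers use He-normal weights and
Xavier-uniform biases; the perceptron uses He-uniform weights and zero
biases. Classical dropout is the standard inverted-scaling kind at rate 0.2.

The architecture grid constrains hidden widths to multiples of 4 in
$[4, 64]$, non-increasing across at most 5 layers, each shape with and
without dropout. Those constraints admit about 20k shapes — far more than
the 448 networks the benchmark reports — so the enumeration is faithful to
the constraints and a deterministic cap thins it; no unstated extra
restriction is guessed. The published best network (three hidden layers of
52, no dropout) is exposed as `reference_best_nn()`.

The default network input is a 13-column design (5 standardized continuous
features, 3 binary indicators, drop-first chest-pain indicators,
integer-coded ECG and ST-slope): 13 inputs is the only width consistent
with the stated 14-parameter minimum for the perceptron. Drop-first
(15 columns) and full one-hot (21 columns) designs are alternatives.

## The synthetic cohort generator

The generator defines the study conditions; it is not tuned per experiment.
Defaults:

* **918 records.** The source text prints "914 patient records" but also a
  70/30 split of "643 and 275 observations", which sums to 918 and is the
  split size the tests pin; both sizes are reachable through
  `cohort_spec(n_records =)`.
* **Continuous marginals** (mean, SD, min, max) for Age (53.51, 9.43, 28,
  77), RestingBP (132.40, 18.51, 0, 200), Cholesterol (198.80, 109.38, 0,
  603), MaxHR (136.80, 25.46, 60, 202) and Oldpeak (0.89, 1.07, −2.6, 6.2),
  drawn through a Gaussian copula and clipped to the stated ranges; Oldpeak
  is rounded to one decimal as in the source data.
* **Correlation targets**: Age–MaxHR $-0.38$ (strongly negative) and
  Age–Oldpeak $+0.26$ (moderately positive) on the latent Gaussian scale.
  The source reports only the signs and strength adjectives; the magnitudes
  are set once to resemble the public dataset.
* **Categorical levels** with probabilities resembling the public dataset
  (e.g. 79% male, 54% asymptomatic chest pain); only the level sets are
  stated by the source, so the probabilities are the package's choice.
* **Label model**: logistic in the standardized continuous features and
  level indicators, with clinically signed default coefficients (MaxHR
  negative; Oldpeak, exertional angina, asymptomatic chest pain positive)
  and the intercept calibrated by root finding so expected prevalence is
  0.55. The source provides no generative model — this is a synthetic
  stand-in that makes the task learnable.

What the generator does **not** emulate: the real joint distribution beyond
five marginals and two correlation signs, interactions in the label rule
beyond logistic main effects, measurement heaping (other than Oldpeak
rounding), or cohort heterogeneity across source institutions. Because the
default label rule is logistic — nearly linear in the encoded features —
low-capacity models are relatively stronger here than on the real
benchmark, and accuracy levels are not comparable to published values;
passing tests demonstrate correct mechanics and qualitative patterns, not
clinical performance.

Preprocessing is leakage-free by construction: standardization means/SDs
and min-max ranges are fitted on the training partition and applied to the
test partition, with out-of-range test values clipped to the $[0, 2\pi]$
endpoints. Whether the original study reused training statistics is not
stated; the leakage-free choice is asserted as this package's own. The
train partition takes $\lceil 0.7 n \rceil$ rows; sample-complexity subsets
use round-half-up sizes, drawn fresh per repeat while the test partition
stays fixed.

## Experiment suite

Each configuration is trained `k = 10` times by default with seeds derived
deterministically from (configuration id, repeat index, base seed); run
failures are recorded, never dropped. Aggregation reports mean accuracy, SD
and a 95% CI half-width from the Student-t distribution with $k-1$ degrees
of freedom (the source states only "95% confidence interval"; the t-based
choice is ours, and a bootstrap can be layered on the exported records).
Best-model selection is argmax mean accuracy, ties broken by smaller CI,
then fewer parameters.

The QNN grid expands six rows (amplitude/angle × plain/DR × with/without
dropout, layers 1–10 plain and 1–8 with dropout) to 54 configurations. The
benchmark states 46 architectures; excluding the DR + dropout row gives
exactly 46 and is provided as an exclusion list, recorded as a hypothesis
rather than ground truth. The sample-complexity roster holds the seven
published architectures (perceptron; 52-52-52 network; DR QNNs with 1, 4, 9
layers; dropout QNNs with 1 and 6 layers) over fractions 0.1–1.0.

## Numerical and scale choices

* Norm preservation is enforced to $10^{-9}$ at state construction and
  verified to $10^{-10}$ across random circuits; statevector-vs-dense-matrix
  equivalence is checked at $10^{-10}$ for up to 4 qubits.
* The gradient kernels advance a shared state prefix gate by gate, so each
  shifted evaluation re-runs only the circuit suffix; this halves the
  parameter-shift cost without changing its semantics.
* Degenerate inputs fail fast: zero-variance columns, constant columns
  under min-max scaling, unseen categorical levels, non-normalized
  amplitude vectors, empty training sets.
* Test-suite problem sizes: module tests train 3-qubit toy circuits and
  small networks; the comparative study in the acceptance tests runs the
  full 918-record cohort with 3 repeats per cell, 10 batches of 64 per
  epoch and a 60-epoch cap — sizes chosen once so the whole suite runs on a
  single CPU while the qualitative contrasts (capacity, data-volume trends)
  remain visible. The full published protocol (10 repeats, patience-driven
  epochs, 54-configuration grid) is expressible through the same functions
  and is a multi-day computation.

## Known limitations

* No hardware execution, shot noise, or density-matrix noise simulation;
  conclusions about trainability transfer only to the noiseless regime.
* The Mottonen implementation is real-amplitude only.
* The synthetic cohort's logistic labels flatten the capacity advantage
  that deeper models show on the real benchmark; depth comparisons at desk
  scale are therefore reported with an explicit 1-SE slack.
* Training the 13-qubit amplitude-encoded models is supported but slow in
  comparison to the 11-qubit angle models, since every record carries its
  own preparation circuit.
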