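---
title: "Real-time respiratory tumor motion prediction with adaptive neural units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time respiratory tumor motion prediction with adaptive neural units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In tracked radiotherapy of lung tumors the treatment system must aim at a
target that moves with respiration — typically 0.5 to 2.5 cm peak-to-peak,
with a dominant period around 3 s that drifts as the patient breathes
freely. Imaging, computation and mechanical actuation introduce a latency
of the order of a second, so the system has to act on where the tumor
*will* be, not where it was last seen. `respredict` implements a family of
small adaptive predictors that forecast the 3-axis marker position a fixed
horizon ahead (e.g. 1 s) from its own recent history, retraining
continuously so that slow changes in breathing dynamics are absorbed.

Two design constraints shape everything in this package:

* **Real time.** At 15–30 Hz sampling, retraining plus prediction must
  finish well within one sampling interval on ordinary hardware. This
  motivates tiny models and training rules that avoid matrix inversion.
* **Reproducibility across restarts.** A predictor whose accuracy depends
  strongly on its random initial weights is clinically awkward. Predictors
  that are *linear in their parameters* have a single optimum and hence
  reproducible accuracy; that property is a central theme below.

## Predictor architectures

All three predictors map a regressor vector of one axis' recent history,

$$x(k) = (1,\; y(k),\; y(k-1),\; \dots,\; y(k-n+1))^T,$$

to a scalar forecast $\hat y(k + n_s)$, in per-window normalized units.
One independent predictor runs per axis; the three axes are combined only
at evaluation time through the 3D error.

* **LNU** (linear neural unit): $\hat y = w \cdot x$ — an adaptive AR
  model with bias, the linear baseline. $n + 1$ weights.
* **QNU** (quadratic neural unit): $\hat y = \sum_{i \le j} w_{ij} x_i x_j
  = w \cdot \mathrm{colx}(x)$, where $\mathrm{colx}$ stacks all pairwise
  products including the bias, in fixed lexicographic order. The map is
  quadratic in the inputs but **linear in the weights**: batch training is
  a linear least-squares problem with a unique global optimum, and the
  Jacobian with respect to the weights is simply the expanded design
  matrix, independent of the weights. $(n+1)(n+2)/2$ weights ($n = 30
  \Rightarrow 496$).
* **MLP**: one hidden layer of $n_1$ sigmoidal neurons,
  $\hat y = w_{out} \cdot \phi(Wx)$ with the bipolar sigmoid
  $\phi(v) = 2/(1+e^{-v}) - 1 = \tanh(v/2)$ and a linear output neuron
  without bias. Nonconvex: accuracy depends on the initial weights.

The LNU is implemented as the first-order restriction of the QNU and is
trained by the same algorithms.

## Training rules

**Batch Levenberg–Marquardt (LM).** Per epoch and per weight block $i$,

$$\Delta w_i = (J_i^T J_i + \tfrac{1}{\mu} I)^{-1} J_i^T e,$$

with all blocks stepping from the same epoch error $e$. For the MLP the
blocks are each hidden neuron's fan-in row plus one block for the output
weights; for LNU/QNU there is a single block whose Jacobian is constant
over the window, so the damped normal equations are factorized once per
window (one Cholesky) and each epoch costs two matrix–vector products.
The damping $1/\mu$ only changes the path, not the fixed point: iterated
LM converges to the least-squares solution, which for the QNU is the
unique optimum (this is what the parameter-recovery test verifies against
a direct pseudo-inverse oracle).

**Modified, inverse-free LM (MLM).** Applying the LM formula to one
scalar weight at a time makes $J^T J$ a scalar:

$$\Delta w_j = \frac{j_j^T e}{j_j^T j_j + 1/\mu} = \tilde j_j \cdot e,$$

where $j_j$ is that weight's Jacobian column. All $\tilde j_j$ are
precomputed once per retraining window; epochs then touch only the error
vector, and all weights update simultaneously (Jacobi-style) from the
shared $e$. For the QNU the Jacobian is window-constant, so retraining
involves **no matrix inversion at all** — the property that makes a
496-weight QNU retrainable at every sample in real time. The heavy
damping used with MLM (default $\mu = 5\times10^{-5}$, i.e. $1/\mu =
20000$) keeps the simultaneous scalar updates stable; warm starting
across thousands of sliding windows supplies the effective iteration
count.

Because all weights step simultaneously from one shared error, MLM is a
Jacobi-type iteration: it contracts only while $1/\mu$ dominates the
squared norms of the Jacobian columns. With z-normalized windows this
holds comfortably when $N_{train}$ spans about two breathing cycles (the
default geometry). Much shorter windows can land on a near-flat breathing
phase whose standard deviation is tiny; the regressor samples just
outside the window then normalize to very large values, the column norms
approach $1/\mu$, and the update can amplify instead of contract. Choose
$N_{train}$ of roughly two cycles — or batch LM, which is
unconditionally stable in this respect — rather than shrinking the
window below one cycle.

**Normalized gradient descent (GD).** Sample-wise normalized-LMS
adaptation for the in-parameter-linear units:

$$\Delta w = \frac{\mu_0}{1 + \lVert \mathrm{colx}(k) \rVert^2}\, e(k)\,
\mathrm{colx}(k).$$

The norm-scaled rate makes the update contractive for $\mu_0 \le 1$ on
bounded inputs. A variant with the squared denominator
$(1+\lVert\mathrm{colx}\rVert^2)^2$ is selectable
(`gd_squared_denominator`); we default to the standard normalized-LMS
form, which is the stable, conventional reading, and expose the
alternative for comparison. GD "epochs" during pretraining are in-order
passes over the window; during online operation the default is one update
per new sample on that sample's pattern (`gd_passes = 0`), with full
window passes available as an option.

## The sliding-window engine

`track_motion()` runs the real-time loop. With lag count $n$, horizon
$n_s$ and window length $N_{train}$:

1. The earliest $N_{train}$ patterns are assembled (pattern with target
   $y(t)$ uses the regressor ending at $t - n_s$) and the predictors are
   pretrained for `epochs_pretrain` epochs (defaults: 800 for LM/MLM,
   400 for GD) from uniform $[-0.1, 0.1]$ random weights.
2. At every subsequent sample the window slides by one, each axis is
   retrained for `epochs_retrain` epochs (default 8; GD: one sample-wise
   update) warm-started from the previous weights, and a prediction for
   $k + n_s$ is emitted in millimetres.
3. Predictions are paired with measurements as they arrive; the ones whose
   target lies beyond the trace remain unscored.

**Per-window normalization.** Every window is z-normalized per axis. The
statistics are the mean and standard deviation of the $N_{train}$ raw
samples of the retraining window proper (the targets); the same statistics
normalize the regressor samples, which may reach slightly further back,
and de-normalize the prediction. Using the current window's statistics
for de-normalization is the natural choice — it is the most recent
information the engine has at emit time. With this convention the
normalized targets of every window have exactly zero mean and unit
standard deviation, which anchors the unit tests.

**Degenerate windows.** A constant (zero-variance) window cannot be
scaled; the standard deviation is clamped (values below $10^{-12}$ are
replaced by 1) and the mean is still subtracted, so training proceeds on
centred raw values and the engine's predictions remain well-defined.

**Numerical safety.** If a retraining step fails numerically or produces
non-finite weights, the engine rolls the axis back to the previous
sample's weights and keeps predicting — the real-time contract is that a
prediction is always emitted. Rollbacks are counted on the fit object.

**Causality.** The prediction emitted at sample $k$ uses only samples
$\le k$; the test suite verifies this by corrupting the future of a trace
and checking that earlier predictions are bit-identical.

## The synthetic generator

No public clinical dataset accompanies this problem, so the package ships
a seeded generator (`simulate_motion()`) used by the tests and the
benchmark. Each axis is

$$y_a(t) = b_a(t) + A_a(t)\, w(\phi(t)) + \epsilon_a(t),$$

with a shared breathing phase advancing by $2\pi/(\mathrm{period}(t)
f_s)$ per sample, and $w(\phi) = 2\cos^p(\phi/2) - 1$. The design choices:

* **Waveform.** Power $p = 2$ gives a pure sinusoid (used by the
  analytic predictability tests); the default $p = 4$ reproduces the
  flat-exhale / sharp-inhale asymmetry typical of breathing traces.
* **Nonstationarity.** The log period and log amplitudes follow slow
  random walks (per-$\sqrt{s}$ standard deviations 0.02 and 0.03),
  reflected into $[0.5\times, 1.5\times]$ of their base values so drifts
  stay physiological; the baseline drifts as a bounded-rate random walk
  (0.05 mm/$\sqrt{s}$). These magnitudes are not published for clinical
  data; they were fixed once at values that make the dominant spectral
  period wander visibly within the 2–4 s band over 100 s.
* **Scale.** Default half-amplitudes (4, 10, 6) mm put peak-to-peak
  motion at 0.8–2 cm, mid-range for lung tumors; noise defaults to
  0.05 mm, reflecting marker positions that reach the predictor after
  upstream filtering.
* **Determinism.** All randomness comes from one seeded stream drawn in
  a documented fixed order, so traces are bit-reproducible.

What the generator does **not** emulate: cardiac-induced ripple,
measurement dropouts, the detailed noise spectrum of fluoroscopic marker
detection, coughing/swallowing transients (except as parameterized
"unexpected move" offsets), and inter-patient variability of waveform
shape. Passing tests on synthetic traces therefore demonstrate the
correctness and the qualitative behaviour of the algorithms — not
clinical-grade accuracy figures.

## The benchmark and what the tests assert

The accuracy claims worth checking are *relative*, and they survive the
transfer to synthetic data:

* a noise-free sinusoid is an exactly linearly predictable signal, so the
  online LNU must drive the 3D MAE of a 10 mm sinusoid below 0.1 mm (it
  reaches the numerical noise floor, $\sim 10^{-13}$ mm);
* on a nonstationary 100 s benchmark trace (default generator, decimated
  to 15 Hz, ten repeats from different random initial weights) the QNU
  with MLM must achieve a mean 3D MAE no worse than the LNU with MLM,
  and a smaller across-seed standard deviation of MAE than the MLP with
  LM — the reproducibility advantage of in-parameter-linear units.

The benchmark operating points are the ones that work best for this
predictor family at the 1 s horizon: QNU/LNU + MLM with $n = 30$,
$N_{train} = 90$ (two breathing cycles at 15 Hz), $\mu = 5\times10^{-5}$;
MLP + LM with $n = 30$, $N_{train} = 180$, $n_1 = 3$ (the middle of the
useful 1–7 range), $\mu = 0.01$; 800 pretraining and 8 retraining epochs
throughout. Problem sizes in the test suite (100 s traces, 10 repeats,
15 Hz) keep a full suite run in a few minutes while leaving every scored
segment longer than a thousand samples.

The configuration-grid sweep (`sweep_spec()` / `run_sweep()`) reproduces
the full experiment structure — predictors × trainers × sampling (15/30
Hz) × $n$ × $N_{train}$ × $n_1$ × repeats — at whatever scale the user
asks for, with per-cell seeds derived from the master seed and the cell
description so results are independent of execution order.

## Numerical choices, in one place

* Initial weights: i.i.d. uniform $[-0.1, 0.1]$, all architectures.
* Damping defaults: $\mu = 0.01$ (LM), $5\times10^{-5}$ (MLM), GD base
  rate $\mu_0 = 0.5$. $\mu$ is fixed during a run; a classical adaptive
  schedule (×10 / ÷10 on the epoch SSE) is available behind
  `mu_schedule` and off by default.
* Standard-deviation clamp for degenerate windows: $10^{-12}$.
* The damped normal equations are solved by Cholesky; a singularity
  despite damping raises an error advising a smaller $\mu$.
* colx ordering: $i$ outer, $j$ inner, $i \le j$, bias first — fixed, so
  serialized weight vectors are portable.
* Downsampling is plain decimation; the breathing band (≈0.3 Hz) is two
  orders of magnitude below the decimated Nyquist frequency, so no
  anti-alias filter is applied.
* Sample indices are 0-based in all CSV interfaces; R-level functions use
  the language's native 1-based indices.

## Limitations

* Throughput (`sps` on the fit and sweep outputs) is measured wall-clock
  and is hardware-dependent; it is reported for orientation only.
* The engine is sample-synchronous: it models the prediction horizon in
  samples, not the latency jitter of a physical beam-delivery chain.
* Novelty detection for unexpected-move handling — flagging samples where
  the prediction is likely unreliable — is out of scope here; the
  generator can produce such events for stress-testing, but the engine
  simply tracks through them.
* GD adaptation is defined for the in-parameter-linear units only; its
  accuracy is markedly worse than MLM's and it is included as the
  baseline adaptive filter, not as a recommendation.
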