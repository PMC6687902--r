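---
title: "Modelling condition-dependent effective connectivity in the attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling condition-dependent effective connectivity in the attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdcm)
```

## The scientific problem

Evoked electrophysiological responses (ERPs/ERFs) are shaped by the
directed coupling between cortical sources. When an experimental
manipulation — here, early versus late target cancellations during a
saccadic search task — changes the gain of specific cortico-cortical
connections, those changes leave a signature in the sensor-level
evoked responses. `erpdcm` implements the full inferential chain that
turns per-condition evoked responses into statements about which
connections changed and by how much:

1. a **generative model**: a canonical-microcircuit (CMC) neural-mass
   model of a five-source attention network, mapped to sensors by a
   linear lead field;
2. **variational Laplace** inversion of that model, returning a
   Gaussian posterior over all parameters together with a free-energy
   approximation to the log model evidence;
3. **Bayesian model reduction (BMR)** over every combination of the
   condition-specific coupling changes, **posterior model
   probabilities**, and **Bayesian model averaging (BMA)**;
4. a **synthetic-data generator and recovery experiments** that
   validate the whole chain against known ground truth.

## The generative model

### Populations and dynamics

Each cortical source contains four populations: spiny stellate cells
(ss), superficial pyramidal cells (sp), inhibitory interneurons (ii)
and deep pyramidal cells (dp). Each population's postsynaptic state is
a damped second-order synaptic convolution of its afferent drive: with
voltage $v$ and conductance $g$ (entries alternating voltage and
conductance in the state vector),

$$\dot v = g, \qquad
  \dot g = \kappa \circ (\text{drive}) - 2\kappa \circ g -
  \kappa \circ \kappa \circ v,$$

where $\circ$ is the element-wise product and $\kappa$ collects
per-population rate constants. The afferent drive sums presynaptic
firing — a centred sigmoid $f(v) = \tanh(\rho v)$ with $f(0) = 0$ —
weighted by intrinsic (within-source) and extrinsic (between-source)
gains, plus exogenous input to the spiny stellate cells of the input
sources.

Extrinsic wiring follows laminar rules: ascending connections arise
from superficial pyramidal cells and excite the spiny stellate and
deep pyramidal populations of the higher source; descending
connections arise from deep pyramidal cells and inhibit the
superficial pyramidal and interneuron populations of the lower
source. Descending connections are therefore *net inhibitory*, which
is what makes "reduced descending gain" equivalent to
*disinhibition* of the lower source.

The intrinsic connection set (documented as a constant in
`cmc_intrinsic_template()`) comprises recurrent self-inhibition on
every population, stellate excitation of both pyramidal populations
and the interneurons, and interneuron inhibition of both pyramidal
populations. There are deliberately no intrinsic positive feedback
loops, so the unforced circuit is damped for any positive gain
scaling — a property asserted numerically in the tests via the
Jacobian's eigenvalues.

### Parameterization

Every coupling parameter is a **log-scaling of a fixed positive
template**: an extrinsic edge's gain is
$\text{template} \cdot e^{a}$, and a modulated edge's gain in the
condition with covariate $X_j$ is
$\text{template} \cdot e^{a + b X_j}$. Because scalings act through
the exponential, an excitatory connection can never become inhibitory
during estimation, and $b = 0$ means exactly "no condition effect".
With a linear covariate over events ($X = 0, 1, \dots$) a constant
$b$ yields a monoexponential coupling trajectory,
$100\,e^{k b}$ percent of baseline after $k$ events
(`coupling_trajectory()`).

### Default constants and their rationale

| Constant | Default | Why |
|---|---|---|
| sampling | 0–250 ms at 600 Hz (150 samples) | the sampling rate and peristimulus window of the data the pipeline emulates |
| $\kappa$ prior means | 500, 500, 62.5, 35.7 s⁻¹ (ss, sp, ii, dp) | 2 ms granular/supragranular and 16/28 ms interneuron/deep time constants; places the circuit's impulse-response peak tens of ms after input onset |
| input | Gaussian bump, onset 60 ms, dispersion 16 ms | an early geniculate volley; with the circuit lag the simulated response peaks near 70–80 ms |
| firing sigmoid slope $\rho$ | 50 | makes linearized loop gains order one under the weight templates (weights ~2–8, rates ~40–500 s⁻¹); at the default input amplitude peak sigmoid arguments stay ≲ 0.3, i.e. mildly compressive |
| input amplitude | 5 a.u. | puts source voltages at a few tenths of a mV |
| extrinsic templates | ascending 8 (→ss), 4 (→dp); descending 4 (→sp), 2 (→ii) | descending slightly weaker than ascending at baseline |
| lead field | fixed 4×5 mixed-sign matrix | the data the pipeline emulates are reduced to a few spatial modes; four channels with distinguishable source footprints suffice |

### Priors

Gaussian shrinkage priors centre every log-scaling at zero ("no
change" is the default belief): variance 1/16 for extrinsic,
modulatory, intrinsic and input-gain scalings, 1/128 for rate-constant
scalings (timing is better known than gain), unit variance for the
input amplitude and the lead-field gains. The sensor-noise
log-precision is a hyperparameter with a loose Gaussian hyperprior
(mean 0, variance 16).

## Inversion: variational Laplace

`invert_erp()` maximizes the variational free energy

$$F = \underbrace{\mathbb E_q[\log p(y \mid \theta)]}_{\text{accuracy}}
  - \underbrace{\mathrm{KL}[q(\theta)\,\|\,p(\theta)]}_{\text{complexity}},$$

under a Gaussian posterior $q$, with the expected likelihood evaluated
by local linearization of the forward model at the posterior mean. The
ascent is regularized Gauss–Newton (Levenberg–Marquardt): a candidate
step is **scored with a fresh linearization at the candidate point**
and rejected (with the regularizer increased) whenever it would lower
$F$, so the recorded free-energy trace is non-decreasing over accepted
steps by construction. The noise log-precision is updated by guarded
Newton ascent interleaved with the parameter updates (coordinate
ascent), capped 35 nats either side of its hyperprior mean — beyond
that the likelihood is numerically saturated (noise ~1e-8 of the
signal scale) and larger precisions only destabilize the curvature
algebra. Convergence is declared after four consecutive accepted steps
gaining under 0.01 nats (or when no probe within the trust region can
gain more than that); the iteration cap defaults to 128, and the
recovery experiments use 48.

Two design details are worth flagging:

- *Fresh-Jacobian scoring.* Scoring candidates with the previous
  iterate's Jacobian (as is common) made the objective inconsistent
  between iterations at the level of the finite-difference noise
  (~1e-3 nats), which blocked acceptance near the optimum. Evaluating
  each candidate with its own linearization makes $F$ a well-defined
  function of the parameters at the cost of one Jacobian per rejected
  step.
- *Derivatives.* Dynamic parameters are differentiated by central
  finite differences (step 1e-3); lead-field gains have exact analytic
  columns (the observation stage is linear in them), which the tests
  verify against finite differences.

On linear-Gaussian problems this scheme reproduces the conjugate
closed-form posterior and log evidence to machine precision, which is
the package's primary correctness oracle.

## Model comparison: BMR, posterior probabilities, BMA

Models that differ only in their priors can be scored analytically
from one full inversion. Switching an effect off means replacing its
prior with mean 0 and variance 1e-8 — a numerically stable stand-in
for the zero-variance limit. `reduce_model()` evaluates the evidence
change of the prior swap as an exponential tilt integrated against the
posterior marginal over the *changed coordinates only*. This
small-matrix, covariance-only formulation is mathematically identical
to the usual precision-difference algebra but remains accurate when
the posterior is nearly a point mass (noiseless fits), where the naive
full-dimension form loses thousands of nats to cancellation.

`enumerate_reduced_models()` spans all $2^k$ keep/remove patterns of
the $k$ switchable effects (binary counting, effect 1 least
significant; the default network has $k = 4$, hence 16 models).
Posterior model probabilities are a max-subtracted softmax of the
per-model free energies under a uniform model prior;
`bma()` moment-matches the probability-weighted mixture of reduced
posteriors. Reports quote 90% central credible intervals.

## The synthetic-data generator

`generate_dataset()` simulates the grand-average evoked responses the
analysis expects: clean per-condition predictions from the forward
model plus seeded white Gaussian sensor noise scaled to a requested
whole-dataset SNR, $10\log_{10}(\text{signal power}/\text{noise
power})$. Defining SNR over the whole epoch (not the peak) makes the
noise level insensitive to the window choice. A channel-correlated
noise option exists for robustness checks. All randomness flows
through one seeded generator, and the global RNG stream is left
untouched.

The default scenario (`default_scenario()`) modulates the four
ventral–dorsal connections with true log-slopes
$(0, +0.1, -0.4, -0.4)$: no change on the ascending connection to the
left frontal eye field, a modest increase on the ascending connection
to the right, and decreases of both descending connections. The signs
mirror the reported physiology (descending disinhibition of the
temporoparietal source); the magnitudes are fixture conventions chosen
to be detectable at moderate SNR. The default SNR of 10 dB is likewise
a fixture convention — the realized SNR of grand averages over
thousands of events is not knowable from the data the pipeline
emulates.

What the generator does *not* emulate: single-trial variability and
its averaging, eye-movement artifacts, realistic MEG forward physics
(head models, gradiometer geometry), or spatial-mode reduction.
Passing recovery tests therefore demonstrate the *inferential chain*
is correct and well calibrated under the model's own assumptions, not
that those assumptions hold for any particular recording.

## Recovery experiments and what they show

`recovery_experiment()` runs generate → invert → enumerate → reduce →
average repeatedly against ground truth and aggregates per-effect
bias, RMSE, 90%-interval coverage, sign accuracy, and the rate at
which the generating keep/remove pattern wins the model comparison.
At the default desk-scale settings (20 replicates, 10 dB, inversion
capped at 48 iterations, ~10 s per replicate on one CPU):

- the *signs* of the two descending decreases are recovered
  essentially always, and 90% intervals cover all four true slopes
  well above nominal-minus-slack;
- the *magnitudes* are shrunk toward zero (posterior-mean bias of
  roughly +0.2 on the −0.4 slopes), the expected behaviour of MAP
  estimates under 1/16-variance shrinkage priors at this SNR;
- the *full generating pattern* wins the 16-way comparison only in a
  minority of noisy replicates. The reason is identifiability, not a
  defect of the reduction: the +0.1 effect on the ascending connection
  is weak — even on numerically noiseless data its posterior z-score
  is only about 2 (mean ≈ 0.09, sd ≈ 0.045), because its sensor
  signature can be largely absorbed by correlated gain parameters. At
  10 dB the comparison cannot separate patterns that differ only in
  that effect, and the winner distributes over the patterns containing
  the two strong descending effects. On noiseless data the generating
  pattern does win.

This is the package's honest characterization of what such an
analysis can and cannot conclude at a given SNR: strong, correctly
signed evidence about the descending (disinhibitory) changes, and
weak evidence about small ascending changes.

## Numerical choices

- **Integrator**: fixed-step classical RK4 at the sampling rate with
  two internal sub-steps (1/1200 s), implemented in compiled code with
  a bit-identical pure-R reference. Fixed-step integration keeps runs
  deterministic across platforms; the step is well inside the
  stability region for the default rates (max $\kappa h \approx
  0.42$), self-convergence under refinement is ~1e-5, and agreement
  with a matrix-exponential solution of the linearized system is well
  under 1% at small amplitude.
- **Blow-up guard**: integration aborts with an error naming the
  largest log-scalings if any state magnitude exceeds 1e6.
- **PSD repairs**: posterior covariances are symmetrized and
  eigenvalue-floored at 1e-12 of the spectral radius; the number of
  floored eigenvalues is recorded on the fit.
- **Reduction feasibility**: a reduced model whose implied posterior
  precision is not positive definite fails with an error naming the
  model (the PSD condition is checked on the eigenvalues of the
  small-matrix product, where it is exact).
- **Tie-breaking**: optimizer steps with $|\Delta F|$ below 1e-9 are
  accepted and count toward convergence.

## Problem sizes used in the shipped validation

The tests and the acceptance script run: the conjugate linear oracle
(n = 40, 3 coefficients); integrator oracles on the full 40-state
network over 150 samples; two fixture inversions (noiseless and
10 dB); and one recovery experiment of 20 replicates at 10 dB with the
48-iteration cap. These sizes were chosen so the whole validation runs
in minutes on a single CPU while still exercising every stage at the
default study conditions.

## Known limitations

- Conduction delays between sources are omitted (a single lumped rate
  per population keeps the flow an ordinary ODE); the interhemispheric
  FEF–FEF and IPS–IPS edges are likewise excluded by default.
- The Laplace posterior is unimodal by construction; multi-modal
  posteriors (plausible at very low SNR) are summarized by whichever
  mode the ascent reaches, and the BMR-versus-refit agreement is only
  meaningful within one posterior basin.
- The noise model is i.i.d. Gaussian with a single shared
  log-precision; channel-specific precisions are reported but not
  separately optimized.
- The paper-scale empirical quantities (posterior probability of a
  specific winning model on real grand averages) are not reproducible
  without the original recordings; the package validates the
  machinery on synthetic ground truth instead.
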