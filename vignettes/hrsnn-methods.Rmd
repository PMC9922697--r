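---
title: "Heterogeneous recurrent spiking networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous recurrent spiking networks: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hrsnn` simulates a three-layer recurrent spiking network for
spatio-temporal classification: an input layer of encoding neurons that
convert frame sequences into spike trains, a recurrent reservoir R of
leaky integrate-and-fire (LIF) neurons trained by spike-timing-dependent
plasticity (STDP), and a non-spiking output layer whose final membrane
potentials are the feature vector for a linear classifier.

Each LIF neuron obeys

$$\tau_m \frac{dv}{dt} = a + R_m I - v,$$

spiking when $v > v_{thr}$ (strict, detected at step end), then
resetting to $v_{reset}$ and ignoring input for an absolute refractory
period during which the membrane is clamped at $v_{reset}$. Integration
is exponential Euler, which is exact for the piecewise-constant currents
the engine delivers; `dt` defaults to 1 ms and is guarded by
`dt <= min(tau_m)/2`.

The reservoir has a 4:1 excitatory:inhibitory split. Neurons sit on a
3-D integer lattice (the most-cubic box covering $N_R$ by default), and
each ordered pair connects with probability
$C\,e^{-(d/\lambda)^2}$, where $C$ depends on the (pre, post) type pair
(defaults EE 0.3, EI 0.2, IE 0.4, II 0.1 — common liquid-state-machine
practice; the literature states only that $C$ is type-dependent) and
$\lambda$ sets the spatial reach. Initial weight magnitudes are
$|N(0,1)|\cdot W_{scale}$, signed by the presynaptic type (Dale's law,
preserved under plasticity by updating magnitudes and clipping at 0).

**Heterogeneity** enters as gamma distributions over parameters,
specified as (mean, CV) rather than (shape, scale): a homogeneous
ablation is then literally `cv = 0` with the mean untouched. Membrane
time constants are drawn per neuron (excitatory mean 20 ms above
inhibitory 10 ms, as in cortex; CV 0.5 when heterogeneous), and the STDP
constants $A_+, A_-, \tau_+, \tau_-$ per synapse. Sampled $\tau_m$ are
clipped below at 2 ms: the gamma tail otherwise violates the integration
guard, and at the default means the clip touches well under 1% of the
mass.

**Plasticity** is the trace-based STDP rule

$$\frac{dW}{dt} = A_+ T_{pre} \sum_o \delta(t - t_{post}^o)
               - A_- T_{post} \sum_i \delta(t - t_{pre}^i),$$

with $\tau_\pm \dot T = -T + a_\pm \sum \delta(\cdot)$. Within a step
the order is: decay, both trace increments, potentiation before
depression. For an isolated pre/post pair this integrates exactly to the
classic window $A_+ a_+ e^{-\Delta t/\tau_+}$ (mirrored for
$\Delta t < 0$), which the tests use as an oracle at `dt = 0.1` ms.
Traces are per synapse (the decay constants are heterogeneous per
synapse); the C++ engine decays them lazily at spike times, which is
algebraically identical to per-step decay and makes plasticity cost
scale with spike count.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `dt` | 1 ms | exponential Euler is exact per step; guard `dt <= min(tau_m)/2` |
| `tau_m` means (E/I) | 20 / 10 ms | biological ordering, excitatory slower |
| heterogeneity CV | 0.5 | single knob distinguishing He from Ho ablations |
| `W_scale` | 2 | sparse working point at $N_R = 500$ (~1–8 Hz); at 5 the heterogeneous variant runs away to ~100 Hz under STDP |
| `w_max` | `3 * W_scale` | must co-scale with the initial law $|N(0,1)|W_{scale}$; a fixed bound below the initial scale collapses every touched weight |
| `A_+`, `A_-` means | 0.01 / 0.012 | slight depression dominance, the standard stabilizer for pair STDP with hard bounds |
| `P_IR`, input target fraction | 0.3, 0.3 | input projects to a fixed random 30% subset of R, pair-wise with probability `P_IR` |
| `lambda_conn` | 2 grid units | mid-density connectivity; swept in the sparsity experiment |
| `n_output` | 100 | readout capacity; also caps the measurable state-matrix rank |

The output layer integrates (LIF without threshold, $\tau$ = 20 ms) and
is read once per stimulus: the state is the output membrane vector at
the end of the spike train, after which `reset_states()` restores
membranes, traces and refractory clocks (weights persist). The linear
read-out is multinomial ridge logistic regression on column-standardized
states; standardization statistics are fitted on the training split
only.

## Encoding

Frames are converted to spikes in four stages. (1) An optional
scan-based background filter computes each frame's active bounding box
and center of gravity and re-centers a fixed-size crop there; activity
is measured above the frame minimum and crops are filled with it, so the
whole pipeline is invariant to constant intensity offsets. (2) Sensory
receptors respond to consecutive-frame differences, firing where
$|\Delta|$ reaches a configurable fraction (default 0.25) of the
sequence-wide maximum difference. (3) Max-pooling (default 2×2) maps
blocks to encoding neurons, each block firing if any pixel fired, with
the block's maximum normalized magnitude retained. (4) Square-cosine
latency coding expands each firing value $d \in [0,\pi]$ into $n$ spike
times $t_s(i) = T\cos^2(d + i\pi/n)$ inside the frame slot. The printed
raw-cosine form can produce negative times; the squared form (matching
the method's name and the $[0, T]$ contract) is the default and the raw
variant sits behind `square_cosine = FALSE`. DVS-style event streams
enter the pipeline at the pooling stage.

One non-obvious interaction: the scan filter's per-frame re-centering
removes *rigid translation*. On real video that is camera jitter and the
actor's articulated motion survives; on the synthetic task below the
object moves rigidly, so re-centering would erase the class signal
itself. The experiment drivers therefore encode with
`use_scan_filter = FALSE` (`default_experiment_encoder()`); the filter
keeps its own contract and tests.

## The synthetic task

`generate_dataset()` renders labelled clips of a bar (or blob)
translating with a class-specific direction and speed across a 16×16
frame (20 frames, 10 ms apart, wrap-around), plus Gaussian pixel noise
clipped at zero. Two deliberate choices:

* **Start positions are jittered only orthogonally to the motion
  direction.** If the phase along the motion axis were also random, the
  "left" and "right" classes would have identical class-mean frame
  tensors (each orbit averages to a uniform blur), and no linear
  functional of raw pixels could separate the classes in expectation —
  the task would be unlearnable by the package's own read-out in the
  infinite-data limit. Orthogonal jitter keeps intra-class variability
  while leaving the label in the spatio-temporal trajectory.
* **Noise defaults to sd 0.15** (intensities are 0/1). At 0.1 the
  benchmark saturates (accuracies ≥ 0.9, differences invisible); at 0.3
  receptor events are noise-dominated and accuracy floors near chance.
  0.15 puts the default task in the informative middle (~0.6–0.7). This
  level was chosen from the accuracy level alone, not from any
  between-variant comparison.

`generate_event_stream()` emulates an event camera on the noiseless
render (an event wherever a pixel changes); it equals the
temporal-difference encoding at threshold 0 by construction, and the
tests verify that equality through the independent encoding-module code
path. What a green test on this task does *not* establish: performance
on real video (texture, articulation, camera motion, class counts), or
any of the paper-scale benchmark accuracies.

## Separation metrics

`effective_rank()` computes the SVD of the stimulus-state matrix $F$
(one row per stimulus) and returns the smallest $k$ whose top-$k$
singular values hold 99% of the singular-value *sum* (closed `>=`
comparison, so an exact 99% top value counts). `count_active_neurons()`
and `average_neuronal_activation()`
($\bar\nu = \sum_i \sum_t \nu_i(t) / N_R$, recurrent neurons only)
quantify activity sparsity.

A measurement caveat discovered while testing: the effective rank is
censored at `min(n_stimuli, n_output)`. Comparisons between variants are
meaningless when both sit at the cap, so the experiment protocols build
$F$ over all stimuli of a task sized to keep the cap comfortably above
the observed rank (e.g. 100 stimuli × 100 readouts for ranks ~90).

## Distribution-level Bayesian optimization

The optimizer searches over *distributions*: a point is six gamma
specifications (neuronal and STDP heterogeneity) plus
$(\lambda, P_{IR}, W_{scale})$. The distance between points sums the
exact 1-D order-1 Wasserstein distances per parameter (each normalized
by the width of its mean's box bound) and adds Euclidean distance on the
normalized scalars. $W_1$ is computed from quantile functions (midpoint
quadrature for gammas, the sorted-sample formula for equal-size
samples). A debiased Sinkhorn divergence (log-domain, epsilon-scaled,
cost $|x-y|$) is available for the joint multivariate reading and agrees
with exact $W_1$ to ~2% at $\varepsilon = 0.01$.

The GP surrogate uses the Matérn kernel on this metric. **The default
smoothness is $\rho = 1/2$**, i.e. $\sigma^2 e^{-W/\kappa}$, and this is
a correctness choice, not a taste: summed 1-D Wasserstein distances are
conditionally negative definite (quantile functions embed $W_1$ in
$L_1$), which by Schoenberg's theorem guarantees positive
semi-definiteness of the *exponential* kernel only. Matérn-3/2 Gram
matrices are PSD on scattered random point sets but were observed
indefinite (min eigenvalue ≈ −0.06) on the clustered sets a converging
optimizer produces, which breaks the Cholesky factorization. Higher
$\rho$ remain available, with a defensive fallback in the surrogate fit.

$\sigma^2$ and $\kappa$ are refit each iteration by profile maximum
likelihood on a 5-point $\kappa$ grid around the median pairwise
distance. Acquisition is expected improvement (fitness maximization),
maximized over a 512-point uniform candidate pool — the space mixes
distribution hyperparameters and scalars, so gradient-based acquisition
search has nothing differentiable to work with. Initialization is a
Latin-hypercube design; box bounds default to ranges centered on the
biologically ordered defaults. A failing objective is recorded at the
worst observed value and the loop continues.

## Numerical choices

* Spike transmission: delta-current synapses delivering $w/dt$ for one
  step, with one-step latency for recurrent spikes; a spike therefore
  deflects the post-membrane by $\approx R_m w / \tau_m$ (the
  charge-conserving PSP).
* Threshold crossing: strict `>` at step end, no interpolation.
* Simultaneous pre+post spikes: decay, both increments, potentiation
  before depression, giving $\Delta w = A_+a_+ - A_-a_-$ at
  $\Delta t = 0$.
* Sinkhorn: log-domain iterations with epsilon scaling (anneal from
  `max(cost)` down to the target by halving), fixed-point tolerance
  1e-9, cap 1e4 iterations, warning + best iterate on non-convergence;
  arguments are canonically ordered so the divergence is exactly
  symmetric.
* Gram jitter $10^{-8}\sigma^2$; noiseless GP interpolation is
  therefore exact only to ~1e-4 in the mean and ~1e-8 in variance.
* Ties in effective rank use a `1e-12` slack on the 99% comparison so
  exact boundary cases are deterministic.

## Known limitations and open reds

Two trend claims from the source literature do not reproduce in this
package's default ablation world, and their acceptance tests are left
failing rather than re-tuned:

* **Rank ordering (heterogeneous ≥ homogeneous).** With *equal-mean*
  gamma heterogeneity and charge-conserving synapses, short-$\tau_m$
  excitatory neurons receive larger PSPs and fire more, making the
  heterogeneous network ~2.5× more active overall. The larger
  common-mode (mean state) component concentrates the singular-value
  sum — the top singular value carries ~48% vs ~36% of it — which
  lowers the *uncentered* 99% effective rank by ~2 of ~90. On centered
  state matrices the heterogeneous network is at or above the
  homogeneous one in most seeds, consistent with the separation
  argument; the stated metric is uncentered, so the criterion stays
  red.
* **Activation ordering ($\bar\nu$, heterogeneous ≤ homogeneous).**
  Same mechanism: the literature's comparison is between per-variant
  *optimized* models, where the optimizer can trade activity for
  accuracy; an equal-mean CV ablation instead adds a high-firing
  short-$\tau$ tail. The accuracy ordering itself (heterogeneous above
  homogeneous, with ~3× smaller seed-to-seed variance) does reproduce.

Other limitations: no synaptic delays or conductance synapses; output
neurons are non-spiking by design (a spiking flag exists); homeostatic
or triplet plasticity is out of scope; the BO objective at full pipeline
scale is expensive and defaults to one network evaluation per point.
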