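# hrsnn

Heterogeneous recurrent spiking neural networks (HRSNN) for
spatio-temporal classification, in R.

## What problem this addresses, and for whom

Reservoirs of spiking neurons trained with unsupervised, local
plasticity (STDP) are an energy- and data-frugal alternative to
backpropagated networks for classifying video-like spatio-temporal
input — but homogeneous reservoirs, where every neuron and synapse
shares one parameter set, underperform. This package is for
computational-neuroscience and neuromorphic-computing researchers who
want to study what *heterogeneity* — per-neuron membrane time constants
and per-synapse plasticity constants drawn from gamma distributions —
does to such networks: their accuracy, the linear separability of their
internal states, their activity sparsity, and how to search over the
heterogeneity *distributions* themselves.

## The model

A three-layer network `I -> R -> O`:

* **LIF reservoir.** Each neuron follows
  `tau_m dv/dt = a + R_m I - v`, spikes when `v > v_thr`, resets to
  `v_reset` with an absolute refractory period. The reservoir is 4:1
  excitatory:inhibitory on a 3-D lattice, wired with the
  distance-dependent probability `P(i,j) = C exp(-(d/lambda)^2)`.
  Heterogeneity: `tau_m ~ Gamma(mean, CV)`, separate distributions for
  E and I neurons.
* **Heterogeneous STDP.** Trace-based rule
  `dW/dt = A+ T_pre sum delta(t - t_post) - A- T_post sum delta(t - t_pre)`
  with per-synapse `A+, A-, tau+, tau-` drawn from gamma distributions;
  Dale's law is preserved by updating weight magnitudes clipped to
  `[0, w_max]`.
* **Encoding.** Frame sequences pass through an optional scan-based
  background filter, temporal-difference receptors thresholded on the
  sequence-wide maximum difference, max-pooling, and square-cosine
  latency coding `t_s(i) = T cos^2(d + i pi/n)`.
* **Readout.** Output neurons integrate without spiking; their final
  membrane potentials per stimulus form the state matrix `F`, fed to a
  ridge multinomial classifier. Separation is measured as the 99%
  singular-value-sum effective rank of `F`; activity as
  `nu_bar = total spikes / N_R`.
* **Distribution-level Bayesian optimization.** A GP surrogate with a
  Matérn kernel on the Wasserstein metric between parameter
  distributions (exponential member by default — the one with a PSD
  guarantee on this metric), expected-improvement acquisition, and an
  exact 1-D Wasserstein / debiased Sinkhorn distance layer.

The clock-driven simulation core is C++ (Rcpp) with an R reference
implementation cross-checked in the tests.

## Worked example

```r
library(hrsnn)

# 1. a labelled synthetic motion dataset (3 classes, 10 clips each)
task <- synthetic_task_config(clips_per_class = 10, seed = 42)
clips <- generate_dataset(task)

# 2. encode one clip into spike trains
spikes <- encode_sequence(clips[[1]], default_experiment_encoder())
print(spikes)
#> <spike_train_set 264 events, 128 sources, 190.0 ms>

# 3. heterogeneity ablation at desk scale
res <- run_ablation(clips, variants = c("HoNHoS", "HeNHeS"),
                    n_seeds = 3, n_recurrent = 200)
print(res, digits = 3)
#>   variant accuracy_mean accuracy_sd effective_rank_mean nu_bar_mean
#> 1  HoNHoS         0.489      0.1018                14.7        11.4
#> 2  HeNHeS         0.600      0.0667                14.7        16.8

# 4. per-seed results of the heterogeneous variant
raw <- attr(res, "raw")
raw[raw$variant == "HeNHeS", c("seed", "accuracy", "effective_rank", "nu_bar")]
#>   seed accuracy effective_rank nu_bar
#> 4    1    0.533             14   17.3
#> 5    2    0.667             15   16.1
#> 6    3    0.600             15   17.1

# 5. Bayesian optimization over heterogeneity distributions
target <- distribution_point(tau_m_E = gamma_spec(31, 0.5))
fit <- bo_loop(function(p) -distribution_distance(p, target),
               free = "tau_m_E.mean", budget = 20, n_init = 5, seed = 1)
#> recovered tau_m_E mean: 31.00 (target 31)
```

Reading the numbers: the heterogeneous network (HeNHeS) classifies the
held-out motion clips better than the homogeneous one (mean accuracy
0.60 vs 0.49 over three seeds) and with smaller seed-to-seed variance
(sd 0.067 vs 0.102); `effective_rank` is the number of leading singular
values holding 99% of the singular-value sum of the 15-stimulus test
state matrix (cap 15 here — use more stimuli for rank comparisons);
`nu_bar` counts total recurrent spikes per neuron over the test split,
the sparsity-of-activity measure. The optimizer recovers the target
distribution's mean exactly on the toy objective.

A command-line front end covers the file-based workflow:

```sh
exec/hrsnn generate --out clips/ --classes 3 --clips 10 --seed 1
exec/hrsnn encode   --input clips/ --out spikes/
exec/hrsnn simulate --input spikes/clip_001.txt --out record.txt
exec/hrsnn evaluate --states states.tsv --split 0.5
```

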