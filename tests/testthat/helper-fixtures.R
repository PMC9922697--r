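# Shared fixtures, built in code and memoized for the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small encoded synthetic task: n classes, few clips, scan filter off.
tiny_stimuli <- function(n_classes = 3, clips_per_class = 6, seed = 7) {
  memo(sprintf("stim_%d_%d_%d", n_classes, clips_per_class, seed), {
    cfg <- synthetic_task_config(n_classes = n_classes,
                                 clips_per_class = clips_per_class,
                                 seed = seed)
    hrsnn:::harmonize_sources(
      encode_dataset(generate_dataset(cfg), default_experiment_encoder()))
  })
}

# Minimal network whose single plastic input synapse can be controlled.
single_synapse_network <- function(weight = 1, tau_m = 20,
                                   v_threshold = 1e6) {
  pop <- neuron_population(tau_m = tau_m, is_excitatory = TRUE,
                           v_threshold = v_threshold)
  pop$position <- matrix(1, 1, 3)
  syn_in <- hrsnn:::as_synapse_set(1L, 1L, weight, "input", TRUE)
  syn_in <- hrsnn:::attach_stdp_parameters(syn_in,
                                           stdp_heterogeneity_config(),
                                           seed = 1)
  syn_rec <- hrsnn:::attach_stdp_parameters(hrsnn:::empty_synapse_set(),
                                            stdp_heterogeneity_config(),
                                            seed = 1)
  syn_out <- hrsnn:::as_synapse_set(1L, 1L, 1, "output", FALSE)
  cfg <- network_config(n_recurrent = 1, n_input = 1, n_output = 1,
                        grid_shape = c(1, 1, 1))
  structure(list(pop = pop, syn_input = syn_in, syn_recurrent = syn_rec,
                 syn_output = syn_out, config = cfg),
            class = "hrsnn_network")
}

# Random distribution point inside the default bounds.
random_point <- function() {
  b <- default_bounds()
  r <- function(nm) runif(1, b[[nm]][1], b[[nm]][2])
  distribution_point(
    tau_m_E = gamma_spec(r("tau_m_E.mean"), r("tau_m_E.cv")),
    tau_m_I = gamma_spec(r("tau_m_I.mean"), r("tau_m_I.cv")),
    A_plus = gamma_spec(r("A_plus.mean"), r("A_plus.cv")),
    A_minus = gamma_spec(r("A_minus.mean"), r("A_minus.cv")),
    tau_plus = gamma_spec(r("tau_plus.mean"), r("tau_plus.cv")),
    tau_minus = gamma_spec(r("tau_minus.mean"), r("tau_minus.cv")),
    lambda_conn = r("lambda_conn"), P_IR = r("P_IR"),
    W_scale = r("W_scale"))
}
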