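#' Simulation configuration
#'
#' @param dt integration step (ms). Must respect the stability guard
#'   `dt <= min(tau_m)/2` of the population it is used with.
#' @param duration simulated time (ms); at least `dt`.
#' @param plasticity_on apply STDP to input and recurrent synapses.
#' @param record_membrane keep the full membrane time series (one row
#'   per step, recurrent then output neurons).
#' @param spiking_output let output neurons spike; by default they are
#'   non-spiking integrators whose final membrane is the read-out state.
#' @param seed integer seed (the engine itself is deterministic; the
#'   seed is recorded for provenance).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 1, duration = 200,
                              plasticity_on = FALSE,
                              record_membrane = FALSE,
                              spiking_output = FALSE,
                              seed = 1L) {
  stopifnot(dt > 0, duration >= dt)
  structure(list(dt = dt, duration = duration,
                 plasticity_on = plasticity_on,
                 record_membrane = record_membrane,
                 spiking_output = spiking_output,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Timestamped spike events
#'
#' The lingua franca between encoding, simulation and metrics: a set of
#' (source neuron, time) events over a fixed number of sources and a
#' fixed duration.
#'
#' @param neuron integer source indices (1-based).
#' @param time event times (ms) in `[0, duration]`.
#' @param n_sources number of possible sources.
#' @param duration total duration (ms).
#' @return An object of class `spike_train_set`; events are stored
#'   sorted by time.
#' @export
spike_train_set <- function(neuron = integer(0), time = numeric(0),
                            n_sources, duration) {
  stopifnot(length(neuron) == length(time))
  if (length(time) && (min(time) < 0 || max(time) > duration))
    stop("spike_train_set: times must lie in [0, duration]", call. = FALSE)
  if (length(neuron) && (min(neuron) < 1 || max(neuron) > n_sources))
    stop("spike_train_set: neuron ids must lie in 1..n_sources",
         call. = FALSE)
  o <- order(time, neuron)
  structure(list(neuron = as.integer(neuron)[o], time = as.numeric(time)[o],
                 n_sources = as.integer(n_sources),
                 duration = as.numeric(duration)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set %d events, %d sources, %.1f ms>\n",
              length(x$time), x$n_sources, x$duration))
  invisible(x)
}

n_events <- function(spikes) length(spikes$time)

#' Simulate the full network on one input spike train
#'
#' Clock-driven loop: at each step, spikes from the previous step are
#' delivered as instantaneous current increments `w/dt` onto their
#' post-synaptic neurons (one-step transmission latency), input events
#' falling in the step are delivered likewise, the LIF populations are
#' integrated by exponential Euler, spikes are detected, and -- when
#' `plasticity_on` -- STDP traces and weights of the input and
#' recurrent synapse sets are updated. Output neurons integrate but
#' their spikes never feed back.
#'
#' @param network an `hrsnn_network` (see [build_network()]).
#' @param input_spikes a [spike_train_set()] over the encoding neurons;
#'   `n_sources` must equal `network$config$n_input`.
#' @param sim a [simulation_config()].
#' @return A `simulation_record`: list with `spikes` (recurrent-layer
#'   [spike_train_set()]), `output_spikes`, `output_membrane_final`,
#'   `membrane_history` (or `NULL`), `weight_snapshot` (list of the
#'   updated input/recurrent synapse sets), `network` (the network with
#'   post-run state, ready for the next stimulus or [reset_states()]),
#'   and `n_steps`.
#' @export
run_network <- function(network, input_spikes, sim = simulation_config()) {
  cfg <- network$config
  if (input_spikes$n_sources != cfg$n_input)
    stop("run_network: input has ", input_spikes$n_sources,
         " sources but the network expects ", cfg$n_input, call. = FALSE)
  if (sim$dt > min(network$pop$tau_m) / 2)
    stop("run_network: dt exceeds the stability guard min(tau_m)/2",
         call. = FALSE)
  n_steps <- max(1L, as.integer(ceiling(sim$duration / sim$dt)))
  step <- pmin(as.integer(floor(input_spikes$time / sim$dt)), n_steps - 1L)
  o <- order(step)

  out_pop <- network$out_pop %||% output_population(cfg$n_output)
  csim <- list(dt = sim$dt, n_steps = n_steps,
               plasticity_on = isTRUE(sim$plasticity_on),
               w_max = cfg$w_max,
               record_membrane = isTRUE(sim$record_membrane),
               spiking_output = isTRUE(sim$spiking_output),
               t0 = network$pop$time %||% 0)
  res <- .cpp_run_network(network$pop, out_pop,
                          network$syn_input, network$syn_recurrent,
                          network$syn_output,
                          step[o], input_spikes$neuron[o],
                          cfg$n_input, csim)

  t0 <- csim$t0
  network$pop$membrane <- res$membrane
  network$pop$refractory_until <- res$refractory_until
  network$pop$time <- t0 + n_steps * sim$dt
  out_pop$membrane <- res$out_membrane
  out_pop$refractory_until <- res$out_refractory_until
  network$out_pop <- out_pop
  network$syn_input$weight <- res$w_input
  network$syn_input$T_pre <- res$T_pre_input
  network$syn_input$T_post <- res$T_post_input
  network$syn_recurrent$weight <- res$w_recurrent
  network$syn_recurrent$T_pre <- res$T_pre_recurrent
  network$syn_recurrent$T_post <- res$T_post_recurrent

  dur <- n_steps * sim$dt
  structure(list(
    spikes = spike_train_set(res$spike_neuron, (res$spike_step + 1) * sim$dt,
                             n_sources = network$pop$size, duration = dur),
    output_spikes = spike_train_set(res$out_spike_neuron,
                                    (res$out_spike_step + 1) * sim$dt,
                                    n_sources = cfg$n_output, duration = dur),
    output_membrane_final = res$out_membrane,
    membrane_history = res$membrane_history,
    weight_snapshot = list(input = network$syn_input,
                           recurrent = network$syn_recurrent),
    network = network,
    n_steps = n_steps, dt = sim$dt), class = "simulation_record")
}

# Output-layer population: plain LIF integrators sharing the default
# scalar parameters; tau chosen long so the final membrane aggregates
# the whole stimulus.
output_population <- function(n_output, tau_m = 20, ...) {
  if (n_output < 1)
    stop("network has no output layer; readout is undefined", call. = FALSE)
  neuron_population(tau_m = rep(tau_m, n_output),
                    is_excitatory = rep(TRUE, n_output), ...)
}

#' Reset dynamic state between stimuli
#'
#' Sets every membrane potential back to its resting value, zeroes all
#' STDP traces and clears refractory clocks. Weights are untouched:
#' this is the per-stimulus reset of the train/read protocol, not a
#' re-initialization.
#'
#' @param network an `hrsnn_network`.
#' @return The reset network.
#' @export
reset_states <- function(network) {
  network$pop$membrane <- network$pop$a
  network$pop$refractory_until <- rep(-Inf, network$pop$size)
  network$pop$time <- 0
  if (!is.null(network$out_pop)) {
    network$out_pop$membrane <- network$out_pop$a
    network$out_pop$refractory_until <- rep(-Inf, network$out_pop$size)
  }
  for (s in c("syn_input", "syn_recurrent")) {
    if (nrow(network[[s]])) {
      network[[s]]$T_pre <- 0
      network[[s]]$T_post <- 0
    }
  }
  network
}
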