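#' Heterogeneity configuration for STDP parameters
#'
#' The STDP rule `dW/dt = A+ T_pre sum_o delta(t - t_post) -
#' A- T_post sum_i delta(t - t_pre)` with trace dynamics
#' `tau+/- dT/dt = -T + a+/- sum delta(t - t_spike)` is made
#' heterogeneous by drawing the scaling constants `A+`, `A-` and the
#' decay time constants `tau+`, `tau-` per synapse from gamma
#' distributions. The trace increments `a+`, `a-` stay scalar.
#'
#' @param A_plus_spec,A_minus_spec [gamma_spec()] for the potentiation /
#'   depression learning rates (weight units).
#' @param tau_plus_spec,tau_minus_spec [gamma_spec()] for the trace
#'   decay time constants (ms).
#' @param a_plus,a_minus scalar trace increments per spike
#'   (dimensionless).
#' @return An object of class `stdp_heterogeneity_config`.
#' @export
stdp_heterogeneity_config <- function(A_plus_spec = gamma_spec(0.01, 0.5),
                                      A_minus_spec = gamma_spec(0.012, 0.5),
                                      tau_plus_spec = gamma_spec(20, 0.5),
                                      tau_minus_spec = gamma_spec(20, 0.5),
                                      a_plus = 1, a_minus = 1) {
  stopifnot(a_plus >= 0, a_minus >= 0)
  structure(list(A_plus_spec = as_gamma_spec(A_plus_spec, "A_plus_spec"),
                 A_minus_spec = as_gamma_spec(A_minus_spec, "A_minus_spec"),
                 tau_plus_spec = as_gamma_spec(tau_plus_spec, "tau_plus_spec"),
                 tau_minus_spec = as_gamma_spec(tau_minus_spec,
                                                "tau_minus_spec"),
                 a_plus = a_plus, a_minus = a_minus),
            class = "stdp_heterogeneity_config")
}

#' Draw per-synapse STDP parameters
#'
#' @param config an [stdp_heterogeneity_config()].
#' @param n_synapses number of synapses.
#' @param seed integer seed.
#' @return A data frame with columns `A_plus`, `A_minus`, `a_plus`,
#'   `a_minus`, `tau_plus`, `tau_minus` (one row per synapse). With all
#'   CVs 0 every row is identical (homogeneous STDP).
#' @export
sample_stdp_parameters <- function(config = stdp_heterogeneity_config(),
                                   n_synapses, seed = 1L) {
  stopifnot(n_synapses >= 0)
  with_seed(seed, {
    data.frame(A_plus = sample_gamma(config$A_plus_spec, n_synapses),
               A_minus = sample_gamma(config$A_minus_spec, n_synapses),
               a_plus = rep(config$a_plus, n_synapses),
               a_minus = rep(config$a_minus, n_synapses),
               tau_plus = sample_gamma(config$tau_plus_spec, n_synapses),
               tau_minus = sample_gamma(config$tau_minus_spec, n_synapses))
  })
}

# Add STDP parameter columns and zeroed trace state to a synapse set.
attach_stdp_parameters <- function(syn, config, seed = 1L) {
  pars <- sample_stdp_parameters(config, nrow(syn), seed = seed)
  syn <- cbind(syn, pars)
  syn$T_pre <- numeric(nrow(syn))
  syn$T_post <- numeric(nrow(syn))
  syn$dale_sign <- ifelse(syn$weight < 0, -1, 1)
  syn
}

#' Advance STDP traces by one time step
#'
#' Each per-synapse trace first decays by `exp(-dt/tau)` and is then
#' incremented by `a_plus` (pre trace, when the pre neuron spiked this
#' step) or `a_minus` (post trace, on a post spike) -- the discrete
#' contribution of each spike to the trace variable.
#'
#' @param syn synapse set with STDP columns (see
#'   [sample_stdp_parameters()]) and trace columns `T_pre`, `T_post`.
#' @param pre_spiked,post_spiked per-synapse logical masks for this
#'   step.
#' @param dt step length (ms).
#' @return The synapse set with updated traces.
#' @export
update_traces <- function(syn, pre_spiked, post_spiked, dt) {
  stopifnot(dt > 0)
  syn$T_pre <- syn$T_pre * exp(-dt / syn$tau_plus) +
    syn$a_plus * as.numeric(pre_spiked)
  syn$T_post <- syn$T_post * exp(-dt / syn$tau_minus) +
    syn$a_minus * as.numeric(post_spiked)
  syn
}

#' Apply one step of STDP weight updates
#'
#' With traces already advanced to the current step, each post-synaptic
#' spike potentiates by `A_plus * T_pre` and each pre-synaptic spike
#' depresses by `A_minus * T_post`. Updates act on the weight
#' *magnitude*, clipped to `[0, w_max]`, with the sign fixed by the
#' pre-neuron type -- inhibitory weights move in mirrored sign, so
#' Dale's law survives any number of updates.
#'
#' @inheritParams update_traces
#' @param w_max hard bound on the weight magnitude.
#' @return The synapse set with updated weights.
#' @export
apply_stdp_update <- function(syn, pre_spiked, post_spiked, w_max = 1) {
  # the Dale sign must survive a weight touching 0: use the stored
  # per-synapse sign when available, the current weight's sign otherwise
  sgn <- syn$dale_sign %||% ifelse(syn$weight < 0, -1, 1)
  mag <- abs(syn$weight)
  mag <- mag + syn$A_plus * syn$T_pre * as.numeric(post_spiked)
  mag <- mag - syn$A_minus * syn$T_post * as.numeric(pre_spiked)
  syn$weight <- sgn * pmin(pmax(mag, 0), w_max)
  syn
}

#' Closed-form weight change for one isolated spike pair
#'
#' Integrating the STDP rule for exactly one pre and one post spike
#' separated by `delta_t = t_post - t_pre` gives the classic
#' asymmetric exponential window: `A+ a+ exp(-dt/tau+)` on the causal
#' branch (`delta_t > 0`), `-A- a- exp(dt/tau-)` on the acausal branch,
#' and `A+ a+ - A- a-` at coincidence under the simultaneous-update
#' convention (decay, then both trace increments, then potentiation
#' before depression). Used as the oracle for the simulated rule.
#'
#' @param delta_t signed timing difference `t_post - t_pre` (ms).
#' @param A_plus,A_minus,a_plus,a_minus,tau_plus,tau_minus STDP
#'   parameters.
#' @return The weight change (vectorized over `delta_t`).
#' @export
pair_delta_w_closed_form <- function(delta_t, A_plus = 0.01, A_minus = 0.012,
                                     a_plus = 1, a_minus = 1,
                                     tau_plus = 20, tau_minus = 20) {
  ifelse(delta_t > 0, A_plus * a_plus * exp(-delta_t / tau_plus),
         ifelse(delta_t < 0, -A_minus * a_minus * exp(delta_t / tau_minus),
                A_plus * a_plus - A_minus * a_minus))
}
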