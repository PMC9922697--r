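#' Heterogeneity configuration for LIF neuron parameters
#'
#' Excitatory and inhibitory membrane time constants are drawn from two
#' separate gamma distributions; cortical measurements place excitatory
#' time constants above inhibitory ones, so `tau_m_E$mean > tau_m_I$mean`
#' is enforced unless `allow_unordered = TRUE`. Threshold heterogeneity
#' is supported but degenerate by default.
#'
#' @param tau_m_E,tau_m_I [gamma_spec()] for excitatory / inhibitory
#'   membrane time constants (ms).
#' @param v_threshold_spec [gamma_spec()] for the firing threshold (mV);
#'   degenerate (CV 0) by default.
#' @param allow_unordered allow `tau_m_E$mean <= tau_m_I$mean`.
#' @return An object of class `heterogeneity_config`.
#' @export
heterogeneity_config <- function(tau_m_E = gamma_spec(20, 0.5),
                                 tau_m_I = gamma_spec(10, 0.5),
                                 v_threshold_spec = gamma_spec(1, 0),
                                 allow_unordered = FALSE) {
  tau_m_E <- as_gamma_spec(tau_m_E, "tau_m_E")
  tau_m_I <- as_gamma_spec(tau_m_I, "tau_m_I")
  v_threshold_spec <- as_gamma_spec(v_threshold_spec, "v_threshold_spec")
  if (!allow_unordered && tau_m_E$mean <= tau_m_I$mean)
    stop("heterogeneity_config: tau_m_E mean must exceed tau_m_I mean ",
         "(set allow_unordered = TRUE to override)", call. = FALSE)
  structure(list(tau_m_E = tau_m_E, tau_m_I = tau_m_I,
                 v_threshold_spec = v_threshold_spec),
            class = "heterogeneity_config")
}

#' Construct a neuron population
#'
#' Low-level constructor; most users will call [sample_lif_parameters()].
#' All per-neuron fields are plain numeric vectors of length `n`.
#'
#' @param tau_m membrane time constants (ms), positive.
#' @param is_excitatory logical vector, `TRUE` for excitatory neurons.
#' @param R_m membrane resistance (arbitrary units).
#' @param a resting potential (mV).
#' @param v_threshold firing threshold (mV).
#' @param v_reset post-spike reset potential (mV); must lie below threshold.
#' @param refractory absolute refractory period (ms), non-negative.
#' @return An object of class `neuron_population`.
#' @export
neuron_population <- function(tau_m, is_excitatory,
                              R_m = 1, a = 0,
                              v_threshold = 1, v_reset = 0,
                              refractory = 2) {
  n <- length(tau_m)
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  pop <- list(
    size = n,
    tau_m = as.numeric(tau_m),
    R_m = rec(as.numeric(R_m)),
    a = rec(as.numeric(a)),
    v_threshold = rec(as.numeric(v_threshold)),
    v_reset = rec(as.numeric(v_reset)),
    refractory = rec(as.numeric(refractory)),
    is_excitatory = as.logical(rec(is_excitatory)),
    position = NULL,
    membrane = rec(as.numeric(a)),
    refractory_until = rep(-Inf, n)
  )
  lens <- vapply(pop[c("tau_m", "R_m", "a", "v_threshold", "v_reset",
                       "refractory", "is_excitatory", "membrane")],
                 length, integer(1))
  if (any(lens != n))
    stop("neuron_population: per-neuron fields must share one length",
         call. = FALSE)
  if (any(pop$tau_m <= 0)) stop("tau_m must be positive", call. = FALSE)
  if (any(pop$refractory < 0)) stop("refractory must be >= 0", call. = FALSE)
  if (any(pop$v_reset >= pop$v_threshold))
    stop("v_reset must lie strictly below v_threshold", call. = FALSE)
  class(pop) <- "neuron_population"
  pop
}

#' @export
print.neuron_population <- function(x, ...) {
  cat(sprintf("<neuron_population n=%d (%d exc / %d inh), tau_m mean %.2f ms>\n",
              x$size, sum(x$is_excitatory), sum(!x$is_excitatory),
              mean(x$tau_m)))
  invisible(x)
}

#' Sample a heterogeneous LIF population
#'
#' Draws per-neuron membrane time constants (and optionally thresholds)
#' from the gamma distributions in `config`; excitatory and inhibitory
#' neurons use their own distributions. The returned population lists
#' excitatory neurons first.
#'
#' @param config a [heterogeneity_config()].
#' @param n_exc,n_inh number of excitatory / inhibitory neurons.
#' @param seed integer seed; sampling is reproducible.
#' @param tau_floor lower clip on sampled time constants (ms). The
#'   gamma tail reaches arbitrarily close to 0, which would break the
#'   `dt <= min(tau_m)/2` integration guard; clipping at 2 ms (twice
#'   the default step) removes a sub-percent fraction of the mass at
#'   the default means and CVs.
#' @param ... further scalar LIF parameters passed to
#'   [neuron_population()] (`R_m`, `a`, `v_reset`, `refractory`).
#' @return A `neuron_population` of `n_exc + n_inh` neurons.
#' @export
sample_lif_parameters <- function(config = heterogeneity_config(),
                                  n_exc, n_inh, seed = 1L,
                                  tau_floor = 2, ...) {
  stopifnot(n_exc >= 0, n_inh >= 0)
  tau <- with_seed(seed, {
    pmax(c(sample_gamma(config$tau_m_E, n_exc),
           sample_gamma(config$tau_m_I, n_inh)), tau_floor)
  })
  vth <- with_seed(seed + 1L,
                   sample_gamma(config$v_threshold_spec, n_exc + n_inh))
  neuron_population(tau_m = tau,
                    is_excitatory = rep(c(TRUE, FALSE), c(n_exc, n_inh)),
                    v_threshold = vth, ...)
}

#' Build a reservoir population with the default 4:1 E:I ratio
#'
#' @param n_total total neuron count; excitatory count is
#'   `round(n_total * 4/5)`.
#' @inheritParams sample_lif_parameters
#' @param ei_ratio excitatory:inhibitory ratio as a length-2 numeric.
#' @return A `neuron_population`.
#' @export
build_population <- function(n_total, config = heterogeneity_config(),
                             ei_ratio = c(4, 1), seed = 1L, ...) {
  n_exc <- round(n_total * ei_ratio[1] / sum(ei_ratio))
  sample_lif_parameters(config, n_exc, n_total - n_exc, seed = seed, ...)
}

#' Advance a LIF population by one time step
#'
#' Exponential-Euler update of the membrane equation
#' `tau_m dv/dt = a + R_m I - v` (exact for current held constant over
#' the step). A neuron spikes when `v > v_threshold` (strict, detected
#' at step end), its membrane is reset to `v_reset` and a refractory
#' clock of length `refractory` starts; refractory neurons are clamped
#' at `v_reset` and ignore input.
#'
#' @param pop a `neuron_population`; its `membrane`, `refractory_until`
#'   and `time` fields carry simulation state.
#' @param input_current per-neuron input current for this step.
#' @param dt step length (ms); must satisfy `dt <= min(tau_m)/2`.
#' @return A list with elements `pop` (updated population) and `spiked`
#'   (logical per-neuron vector).
#' @export
lif_step <- function(pop, input_current, dt) {
  if (dt <= 0) stop("lif_step: dt must be positive", call. = FALSE)
  if (dt > min(pop$tau_m) / 2)
    stop("lif_step: dt exceeds the stability guard min(tau_m)/2",
         call. = FALSE)
  if (length(input_current) == 1L)
    input_current <- rep(input_current, pop$size)
  t_now <- pop$time %||% 0
  refr <- t_now < pop$refractory_until
  v_inf <- pop$a + pop$R_m * input_current
  decay <- exp(-dt / pop$tau_m)
  v <- v_inf + (pop$membrane - v_inf) * decay
  v[refr] <- pop$v_reset[refr]
  spiked <- !refr & (v > pop$v_threshold)
  t_next <- t_now + dt
  v[spiked] <- pop$v_reset[spiked]
  pop$refractory_until[spiked] <- t_next + pop$refractory[spiked]
  pop$membrane <- v
  pop$time <- t_next
  list(pop = pop, spiked = spiked)
}

#' Closed-form first spike time of a LIF neuron under constant current
#'
#' For a neuron starting at its resting potential `a` with constant
#' drive `I`, the membrane follows
#' `v(t) = a + R_m I (1 - exp(-t/tau_m))`, giving the first threshold
#' crossing at `t* = tau_m log(R_m I / (a + R_m I - v_threshold))`.
#' Serves as an independent oracle for the simulated dynamics.
#'
#' @param tau_m,R_m,a,v_threshold LIF parameters (see
#'   [neuron_population()]).
#' @param current constant input current.
#' @return First spike time in ms, or `Inf` ("never") when the drive is
#'   subthreshold (`a + R_m current <= v_threshold`).
#' @export
analytic_first_spike_time <- function(current, tau_m, R_m = 1, a = 0,
                                      v_threshold = 1) {
  v_inf <- a + R_m * current
  if (v_inf <= v_threshold) return(Inf)
  tau_m * log((v_inf - a) / (v_inf - v_threshold))
}
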