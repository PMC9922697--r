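#' Network configuration for the three-layer reservoir
#'
#' Houses the structural parameters of the input -> recurrent -> output
#' architecture: recurrent size and E:I ratio, the 3-D grid the
#' reservoir is embedded in, the distance-dependent connection law
#' `P(i,j) = C exp(-(d/lambda)^2)` with per-synapse-class amplitudes
#' `C`, the input projection probability `P_IR`, and the weight scale
#' `W_scale`.
#'
#' @param n_recurrent reservoir size N_R.
#' @param n_input number of encoding (input) neurons.
#' @param n_output number of readout neurons.
#' @param ei_ratio excitatory:inhibitory ratio (default 4:1).
#' @param grid_shape integer 3-vector; defaults to the most-cubic
#'   factorization covering `n_recurrent`.
#' @param C_by_type named amplitudes for the four recurrent synapse
#'   classes EE, EI, IE, II (pre-type first), each in \[0, 1\].
#' @param lambda_conn length scale of the connection probability
#'   (grid units).
#' @param P_IR probability of an input synapse onto each selected
#'   target neuron.
#' @param input_target_fraction fraction of the reservoir eligible as
#'   input targets (drawn once per network).
#' @param W_scale multiplicative scale on initial weight magnitudes.
#' @param output_tap_fraction fraction of the reservoir each output
#'   neuron taps.
#' @param output_weight fixed (non-plastic) output synapse weight
#'   before `W_scale`.
#' @param w_max hard bound on plastic weight magnitudes; defaults to
#'   `3 * W_scale` so the bound sits above the bulk of the initial
#'   `|N(0,1)| * W_scale` magnitudes (a fixed bound below the initial
#'   scale would let plasticity collapse the weight distribution).
#' @param seed integer seed for all structural randomness.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_recurrent = 500,
                           n_input = 64,
                           n_output = 100,
                           ei_ratio = c(4, 1),
                           grid_shape = NULL,
                           C_by_type = c(EE = 0.3, EI = 0.2,
                                         IE = 0.4, II = 0.1),
                           lambda_conn = 2,
                           P_IR = 0.3,
                           input_target_fraction = 0.3,
                           W_scale = 2,
                           output_tap_fraction = 0.1,
                           output_weight = 1,
                           w_max = NULL,
                           seed = 1L) {
  if (is.null(w_max)) w_max <- 3 * W_scale
  if (is.null(grid_shape)) grid_shape <- default_grid_shape(n_recurrent)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || prod(grid_shape) < n_recurrent)
    stop("network_config: grid_shape must be a 3-vector holding at least ",
         "n_recurrent sites", call. = FALSE)
  stopifnot(lambda_conn > 0, W_scale > 0,
            P_IR >= 0, P_IR <= 1,
            all(C_by_type >= 0), all(C_by_type <= 1),
            all(c("EE", "EI", "IE", "II") %in% names(C_by_type)))
  structure(list(n_recurrent = as.integer(n_recurrent),
                 n_input = as.integer(n_input),
                 n_output = as.integer(n_output),
                 ei_ratio = ei_ratio, grid_shape = grid_shape,
                 C_by_type = C_by_type, lambda_conn = lambda_conn,
                 P_IR = P_IR,
                 input_target_fraction = input_target_fraction,
                 W_scale = W_scale,
                 output_tap_fraction = output_tap_fraction,
                 output_weight = output_weight,
                 w_max = w_max, seed = as.integer(seed)),
            class = "network_config")
}

# Most-cubic integer box with capacity >= n.
default_grid_shape <- function(n) {
  s <- ceiling(n^(1 / 3))
  a <- s
  b <- ceiling(sqrt(n / a))
  c <- ceiling(n / (a * b))
  as.integer(c(a, b, c))
}

#' Place neurons on a 3-D integer lattice
#'
#' Assigns `n` distinct lattice sites of the grid uniformly at random
#' without replacement -- the standard liquid-state-machine embedding
#' that gives the connection law a Euclidean distance to act on.
#'
#' @param n number of neurons.
#' @param grid_shape integer 3-vector of grid extents.
#' @param seed integer seed.
#' @return An `n x 3` matrix of integer coordinates (1-based).
#' @export
place_neurons_on_grid <- function(n, grid_shape, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  capacity <- prod(grid_shape)
  if (n > capacity)
    stop("place_neurons_on_grid: grid capacity ", capacity,
         " < n = ", n, call. = FALSE)
  sites <- with_seed(seed, sample.int(capacity, n))
  s0 <- sites - 1L
  cbind(x = s0 %% grid_shape[1] + 1L,
        y = (s0 %/% grid_shape[1]) %% grid_shape[2] + 1L,
        z = s0 %/% (grid_shape[1] * grid_shape[2]) + 1L)
}

#' Distance-dependent connection probability
#'
#' `P(d) = C exp(-(d / lambda)^2)`, clamped to \[0, 1\]: closer neuron
#' pairs connect with higher probability, `C` sets the amplitude per
#' synapse class and `lambda` the spatial reach.
#'
#' @param d non-negative Euclidean distance (grid units).
#' @param C amplitude in \[0, 1\].
#' @param lam length scale `lambda > 0`.
#' @return Connection probability (vectorized over `d`).
#' @export
connection_probability <- function(d, C, lam) {
  stopifnot(lam > 0, C >= 0, C <= 1)
  pmin(pmax(C * exp(-(d / lam)^2), 0), 1)
}

# Empty synapse table with the schema shared by all synapse classes.
empty_synapse_set <- function() {
  data.frame(pre = integer(0), post = integer(0), weight = numeric(0),
             class = character(0), plastic = logical(0))
}

as_synapse_set <- function(pre, post, weight, class, plastic) {
  n <- max(length(pre), length(post), length(weight))
  if (length(pre) == 0L) n <- 0L
  data.frame(pre = as.integer(rep_len(pre, n)),
             post = as.integer(rep_len(post, n)),
             weight = as.numeric(rep_len(weight, n)),
             class = rep_len(class, n), plastic = rep_len(plastic, n))
}

#' Build recurrent synapses from the distance law
#'
#' Every ordered pair (i, j), i != j, is connected independently with
#' probability [connection_probability()] evaluated with the amplitude
#' `C_by_type` keyed on (pre-type, post-type). Initial magnitudes are
#' `|N(0,1)| * W_scale`; the sign follows the pre-neuron type (Dale's
#' law), so excitatory rows are non-negative and inhibitory rows
#' non-positive. All recurrent synapses are plastic.
#'
#' @param pop a placed `neuron_population` (see
#'   [place_neurons_on_grid()]).
#' @param config a [network_config()].
#' @return A synapse set data frame with columns `pre`, `post`,
#'   `weight`, `class`, `plastic`.
#' @export
build_recurrent_synapses <- function(pop, config) {
  if (is.null(pop$position))
    stop("build_recurrent_synapses: population has no grid positions",
         call. = FALSE)
  n <- pop$size
  d <- as.matrix(stats::dist(pop$position))
  type <- ifelse(pop$is_excitatory, "E", "I")
  Cmat <- matrix(config$C_by_type[paste0(rep(type, times = n),
                                         rep(type, each = n))],
                 n, n)  # row = pre, col = post
  p <- connection_probability(d, C = 1, lam = config$lambda_conn) * Cmat
  diag(p) <- 0
  with_seed(config$seed + 101L, {
    keep <- which(matrix(runif(n * n), n, n) < p, arr.ind = TRUE)
    w <- abs(rnorm(nrow(keep))) * config$W_scale
  })
  sgn <- ifelse(pop$is_excitatory[keep[, 1]], 1, -1)
  as_synapse_set(keep[, 1], keep[, 2], sgn * w, "recurrent", TRUE)
}

#' Build input projections onto the reservoir
#'
#' A target subset of exactly `round(fraction * N_R)` reservoir neurons
#' is drawn once per network; each (encoding neuron, target) pair then
#' connects independently with probability `P_IR`. Encoding neurons are
#' excitatory, so weights are positive; input synapses are plastic.
#'
#' @param n_input number of encoding neurons.
#' @param pop reservoir `neuron_population`.
#' @param P_IR connection probability per pair.
#' @param fraction fraction of the reservoir eligible as targets.
#' @param W_scale initial weight magnitude scale.
#' @param seed integer seed.
#' @return A synapse set data frame (class `"input"`); `pre` indexes
#'   encoding neurons, `post` reservoir neurons.
#' @export
build_input_synapses <- function(n_input, pop, P_IR, fraction = 0.3,
                                 W_scale = 1, seed = 1L) {
  stopifnot(n_input >= 1, P_IR >= 0, P_IR <= 1)
  n_targets <- round(fraction * pop$size)
  with_seed(seed + 202L, {
    targets <- sort(sample.int(pop$size, n_targets))
    keep <- which(matrix(runif(n_input * n_targets),
                         n_input, n_targets) < P_IR, arr.ind = TRUE)
    w <- abs(rnorm(nrow(keep))) * W_scale
  })
  syn <- as_synapse_set(keep[, 1], targets[keep[, 2]], w, "input", TRUE)
  attr(syn, "targets") <- targets
  syn
}

#' Build fixed readout taps from the reservoir
#'
#' Each output neuron receives non-plastic, fixed-weight projections
#' from a random subset of the reservoir (default 10 percent). Only the
#' final output membrane potential is read, so these taps define which
#' reservoir neurons each state component integrates.
#'
#' @param pop reservoir `neuron_population`.
#' @param n_output number of output neurons.
#' @param fraction fraction of the reservoir tapped per output neuron.
#' @param weight fixed tap weight (positive).
#' @param seed integer seed.
#' @return A synapse set data frame (class `"output"`); `post` indexes
#'   output neurons.
#' @export
build_output_taps <- function(pop, n_output, fraction = 0.1,
                              weight = 1, seed = 1L) {
  if (n_output < 1) return(empty_synapse_set())
  k <- max(1L, round(fraction * pop$size))
  pre <- with_seed(seed + 303L,
                   unlist(lapply(seq_len(n_output),
                                 function(o) sample.int(pop$size, k))))
  as_synapse_set(pre, rep(seq_len(n_output), each = k),
                 weight, "output", FALSE)
}

#' Assemble a full heterogeneous recurrent spiking network
#'
#' Builds the population (4:1 E:I), places it on the grid, wires the
#' recurrent, input and output synapse sets, and samples per-synapse
#' STDP parameters for the plastic classes.
#'
#' @param config a [network_config()].
#' @param het a [heterogeneity_config()] for the LIF parameters.
#' @param stdp_het a [stdp_heterogeneity_config()] for the plasticity
#'   parameters.
#' @param ... scalar LIF parameters forwarded to
#'   [sample_lif_parameters()].
#' @return An object of class `hrsnn_network` with elements `pop`,
#'   `syn_input`, `syn_recurrent`, `syn_output`, `config`.
#' @export
build_network <- function(config = network_config(),
                          het = heterogeneity_config(),
                          stdp_het = stdp_heterogeneity_config(), ...) {
  pop <- build_population(config$n_recurrent, het,
                          ei_ratio = config$ei_ratio,
                          seed = config$seed, ...)
  pop$position <- place_neurons_on_grid(pop$size, config$grid_shape,
                                        seed = config$seed)
  syn_rec <- build_recurrent_synapses(pop, config)
  syn_in <- build_input_synapses(config$n_input, pop, config$P_IR,
                                 fraction = config$input_target_fraction,
                                 W_scale = config$W_scale,
                                 seed = config$seed)
  syn_out <- build_output_taps(pop, config$n_output,
                               fraction = config$output_tap_fraction,
                               weight = config$output_weight * config$W_scale,
                               seed = config$seed)
  syn_rec <- attach_stdp_parameters(syn_rec, stdp_het,
                                    seed = config$seed + 11L)
  syn_in <- attach_stdp_parameters(syn_in, stdp_het,
                                   seed = config$seed + 12L)
  structure(list(pop = pop, syn_input = syn_in, syn_recurrent = syn_rec,
                 syn_output = syn_out, config = config),
            class = "hrsnn_network")
}

#' @export
print.hrsnn_network <- function(x, ...) {
  cat(sprintf(paste0("<hrsnn_network N_R=%d (input %d, output %d); ",
                     "synapses: %d input, %d recurrent, %d output>\n"),
              x$pop$size, x$config$n_input, x$config$n_output,
              nrow(x$syn_input), nrow(x$syn_recurrent), nrow(x$syn_output)))
  invisible(x)
}
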