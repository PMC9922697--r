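test_that("quiescent network with empty input stays silent", {
  net <- build_network(network_config(n_recurrent = 40, n_input = 8,
                                      n_output = 4, seed = 1))
  empty <- spike_train_set(n_sources = 8, duration = 50)
  rec <- run_network(net, empty, simulation_config(duration = 50))
  expect_equal(length(rec$spikes$time), 0)
  expect_equal(rec$output_membrane_final, rep(0, 4))
})

test_that("runs are deterministic and plasticity-off leaves weights", {
  net <- build_network(network_config(n_recurrent = 60, n_input = 10,
                                      n_output = 6, seed = 2))
  set.seed(3)
  input <- spike_train_set(sample(10, 80, TRUE), runif(80, 0, 100),
                           n_sources = 10, duration = 100)
  sim <- simulation_config(duration = 100)
  r1 <- run_network(net, input, sim)
  r2 <- run_network(net, input, sim)   # same initial state object
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$output_membrane_final, r2$output_membrane_final)
  # frozen plasticity: weight snapshot identical to initial weights
  expect_identical(r1$weight_snapshot$recurrent$weight,
                   net$syn_recurrent$weight)

  # shape error on source-count mismatch
  bad <- spike_train_set(1L, 1, n_sources = 3, duration = 10)
  expect_error(run_network(net, bad, sim), "sources")
})

test_that("reset_states restores a fresh network and order independence", {
  net <- build_network(network_config(n_recurrent = 50, n_input = 10,
                                      n_output = 5, seed = 4))
  set.seed(5)
  a <- spike_train_set(sample(10, 40, TRUE), runif(40, 0, 80),
                       n_sources = 10, duration = 80)
  b <- spike_train_set(sample(10, 40, TRUE), runif(40, 0, 80),
                       n_sources = 10, duration = 80)
  sim <- simulation_config(duration = 80)

  # reset of a fresh network is a no-op
  expect_equal(reset_states(net)$pop$membrane, net$pop$membrane)

  run_state <- function(net, stims) {
    out <- list()
    for (s in stims) {
      r <- run_network(net, s, sim)
      out[[length(out) + 1]] <- r$output_membrane_final
      net <- reset_states(r$network)
    }
    out
  }
  ab <- run_state(net, list(a, b))
  ba <- run_state(net, list(b, a))
  expect_identical(ab[[1]], ba[[2]])
  expect_identical(ab[[2]], ba[[1]])

  # reset leaves weights untouched
  r <- run_network(net, a, simulation_config(duration = 80,
                                             plasticity_on = TRUE))
  w <- r$network$syn_recurrent$weight
  expect_identical(reset_states(r$network)$syn_recurrent$weight, w)
})

test_that("a single synapse produces the analytic PSP peak", {
  set.seed(6)
  for (rep in 1:10) {
    tau <- runif(1, 5, 40)
    w <- runif(1, 0.5, 3)
    net <- single_synapse_network(weight = w, tau_m = tau)
    input <- spike_train_set(1L, 5, n_sources = 1, duration = 40)
    dt <- 0.05
    rec <- run_network(net, input,
                       simulation_config(dt = dt, duration = 40,
                                         record_membrane = TRUE))
    peak <- max(rec$membrane_history[, 1])
    expect_lt(abs(peak - w / tau) / (w / tau), 0.01)  # R_m = 1
  }
})

test_that("doubling W_scale never decreases total spike count", {
  for (s in 1:5) {
    counts <- vapply(c(2, 4), function(ws) {
      net <- build_network(network_config(n_recurrent = 80, n_input = 16,
                                          n_output = 5, W_scale = ws,
                                          seed = s))
      set.seed(100 + s)
      input <- spike_train_set(sample(16, 150, TRUE), runif(150, 0, 150),
                               n_sources = 16, duration = 150)
      length(run_network(net, input,
                         simulation_config(duration = 150))$spikes$time)
    }, numeric(1))
    expect_gte(counts[2], counts[1])
  }
})

test_that("C++ engine matches the R reference dynamics step by step", {
  # two recurrent neurons driven by one input source, hand-wired
  pop <- neuron_population(tau_m = c(20, 12), is_excitatory = c(TRUE, TRUE),
                           v_threshold = 0.15, refractory = 2)
  pop$position <- matrix(1, 2, 3)
  syn_in <- hrsnn:::as_synapse_set(1L, 1L, 0.1, "input", TRUE)
  syn_rec <- hrsnn:::as_synapse_set(1L, 2L, 0.12, "recurrent", TRUE)
  stdp <- stdp_heterogeneity_config(A_plus_spec = gamma_spec(0.01, 0),
                                    A_minus_spec = gamma_spec(0.012, 0),
                                    tau_plus_spec = gamma_spec(20, 0),
                                    tau_minus_spec = gamma_spec(20, 0))
  syn_in <- hrsnn:::attach_stdp_parameters(syn_in, stdp, seed = 1)
  syn_rec <- hrsnn:::attach_stdp_parameters(syn_rec, stdp, seed = 1)
  syn_out <- hrsnn:::as_synapse_set(2L, 1L, 1, "output", FALSE)
  cfg <- network_config(n_recurrent = 2, n_input = 1, n_output = 1,
                        grid_shape = c(1, 1, 2), w_max = 1)
  net <- structure(list(pop = pop, syn_input = syn_in,
                        syn_recurrent = syn_rec, syn_output = syn_out,
                        config = cfg), class = "hrsnn_network")

  dt <- 1
  times <- seq(2, 190, by = 3)
  input <- spike_train_set(rep(1L, length(times)), times,
                           n_sources = 1, duration = 200)
  rec <- run_network(net, input, simulation_config(
    dt = dt, duration = 200, plasticity_on = TRUE,
    record_membrane = TRUE))

  # R reference: same semantics via lif_step + trace/weight updates
  rpop <- pop
  rin <- syn_in; rrec <- syn_rec
  out_v <- 0
  prev_spk <- c(FALSE, FALSE)
  in_steps <- floor(times / dt)
  hist <- matrix(NA_real_, 200, 2)
  for (t in 0:199) {
    I <- c(0, 0); I_out <- 0
    if (prev_spk[1]) I[2] <- I[2] + rrec$weight / dt
    if (prev_spk[2]) I_out <- I_out + 1 / dt
    in_spk <- t %in% in_steps
    if (in_spk) I[1] <- I[1] + rin$weight / dt
    st <- lif_step(rpop, I, dt)
    rpop <- st$pop
    vinf_o <- I_out
    out_v <- vinf_o + (out_v - vinf_o) * exp(-dt / 20)
    rin <- update_traces(rin, in_spk, st$spiked[1], dt)
    rin <- apply_stdp_update(rin, in_spk, st$spiked[1], w_max = 1)
    rrec <- update_traces(rrec, st$spiked[1], st$spiked[2], dt)
    rrec <- apply_stdp_update(rrec, st$spiked[1], st$spiked[2], w_max = 1)
    hist[t + 1, ] <- rpop$membrane
    prev_spk <- st$spiked
  }
  expect_equal(rec$membrane_history[, 1:2], hist, tolerance = 1e-12)
  expect_equal(rec$network$syn_input$weight, rin$weight,
               tolerance = 1e-12)
  expect_equal(rec$network$syn_recurrent$weight, rrec$weight,
               tolerance = 1e-12)
  expect_equal(rec$output_membrane_final, out_v, tolerance = 1e-12)
})

test_that("spike trains round-trip through the text format", {
  st <- spike_train_set(c(3L, 1L, 2L), c(5, 1.25, 9.5), n_sources = 4,
                       duration = 10)
  tmp <- tempfile()
  write_spike_trains(st, tmp)
  back <- read_spike_trains(tmp)
  expect_equal(back, st)
  empty <- spike_train_set(n_sources = 2, duration = 5)
  write_spike_trains(empty, tmp)
  expect_equal(read_spike_trains(tmp), empty)
})
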