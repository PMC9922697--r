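#' Heterogeneity configurations for the four ablation variants
#'
#' `Ho`/`He` on the neuron axis zeroes/keeps the CVs of the membrane
#' time constant (and threshold) distributions; on the STDP axis it
#' zeroes/keeps the CVs of the learning-rate and trace-decay
#' distributions. Means are identical across variants, so the ablation
#' isolates heterogeneity itself.
#'
#' @param variant one of `"HoNHoS"`, `"HeNHoS"`, `"HoNHeS"`,
#'   `"HeNHeS"`.
#' @param cv coefficient of variation used on the heterogeneous axes.
#' @param point a [distribution_point()] supplying the means.
#' @return List with `het` ([heterogeneity_config()]) and `stdp`
#'   ([stdp_heterogeneity_config()]).
#' @export
ablation_configs <- function(variant = c("HeNHeS", "HoNHoS", "HeNHoS",
                                         "HoNHeS"),
                             cv = 0.5, point = distribution_point()) {
  variant <- match.arg(variant)
  n_cv <- if (substr(variant, 1, 2) == "He") cv else 0
  s_cv <- if (substr(variant, 4, 5) == "He") cv else 0
  d <- point$dists
  list(het = heterogeneity_config(
         tau_m_E = gamma_spec(d$tau_m_E$mean, n_cv),
         tau_m_I = gamma_spec(d$tau_m_I$mean, n_cv)),
       stdp = stdp_heterogeneity_config(
         A_plus_spec = gamma_spec(d$A_plus$mean, s_cv),
         A_minus_spec = gamma_spec(d$A_minus$mean, s_cv),
         tau_plus_spec = gamma_spec(d$tau_plus$mean, s_cv),
         tau_minus_spec = gamma_spec(d$tau_minus$mean, s_cv)))
}

#' Default encoder for the synthetic-task experiment drivers
#'
#' The scan-based background filter re-centers every frame on the
#' object's center of gravity. On real video that removes camera
#' jitter while articulated motion survives; on the synthetic task the
#' object moves rigidly, so re-centering would cancel exactly the
#' translation that defines the classes. The experiment drivers
#' therefore encode with the filter off (there is no camera jitter to
#' remove); the filter itself stays available and tested.
#'
#' @return An [encoder_config()] with `use_scan_filter = FALSE`.
#' @export
default_experiment_encoder <- function() {
  encoder_config(use_scan_filter = FALSE)
}

#' Encode a clip dataset into labelled stimuli
#'
#' @param dataset list of [frame_sequence()]s (or already-encoded
#'   [spike_train_set()]s, passed through).
#' @param config an [encoder_config()].
#' @return List of [spike_train_set()]s with `label` attributes.
#' @export
encode_dataset <- function(dataset, config = encoder_config()) {
  lapply(dataset, function(clip) {
    if (inherits(clip, "spike_train_set")) return(clip)
    st <- encode_sequence(clip, config)
    attr(st, "label") <- clip$label
    st
  })
}

# Pad/truncate stimuli to a common source count so one network serves
# all clips (scan-filter crops can differ by a pixel across clips).
harmonize_sources <- function(stimuli, n_sources = NULL) {
  if (is.null(n_sources))
    n_sources <- max(vapply(stimuli, `[[`, integer(1), "n_sources"))
  lapply(stimuli, function(s) {
    keep <- s$neuron <= n_sources
    st <- spike_train_set(s$neuron[keep], s$time[keep], n_sources,
                          s$duration)
    attr(st, "label") <- attr(s, "label")
    st
  })
}

#' Train a network with STDP on a stimulus list
#'
#' Presents every training stimulus once per epoch with plasticity on,
#' resetting dynamic state between stimuli; weights persist. An
#' optional early stop ends training when the mean absolute weight
#' change over an epoch falls below `tol`.
#'
#' @param network an `hrsnn_network`.
#' @param stimuli list of [spike_train_set()]s.
#' @param epochs number of passes over the training set.
#' @param dt integration step (ms).
#' @param shuffle reshuffle presentation order each epoch.
#' @param tol early-stop threshold on the mean absolute weight change
#'   per epoch (0 disables).
#' @param seed integer seed for the shuffling.
#' @return The trained network (plasticity state frozen in weights).
#' @export
train_network_stdp <- function(network, stimuli, epochs = 3, dt = 1,
                               shuffle = TRUE, tol = 1e-4, seed = 1L) {
  for (ep in seq_len(epochs)) {
    ord <- if (shuffle) with_seed(seed + ep, sample(seq_along(stimuli)))
           else seq_along(stimuli)
    w_before <- c(network$syn_input$weight, network$syn_recurrent$weight)
    for (i in ord) {
      sim <- simulation_config(dt = dt,
                               duration = max(stimuli[[i]]$duration, dt),
                               plasticity_on = TRUE)
      rec <- run_network(network, stimuli[[i]], sim)
      network <- reset_states(rec$network)
    }
    w_after <- c(network$syn_input$weight, network$syn_recurrent$weight)
    if (tol > 0 && length(w_before) &&
        mean(abs(w_after - w_before)) < tol) break
  }
  network
}

# Run a stimulus list with plasticity off, collecting states and
# recurrent spike statistics.
evaluate_stimuli <- function(network, stimuli, dt = 1) {
  network <- reset_states(network)
  n_out <- network$config$n_output
  states <- matrix(NA_real_, length(stimuli), n_out)
  total_spikes <- 0
  active <- integer(0)
  for (i in seq_along(stimuli)) {
    sim <- simulation_config(dt = dt,
                             duration = max(stimuli[[i]]$duration, dt))
    rec <- run_network(network, stimuli[[i]], sim)
    states[i, ] <- extract_state(rec)
    total_spikes <- total_spikes + n_events(rec$spikes)
    active <- union(active, unique(rec$spikes$neuron))
    network <- reset_states(rec$network)
  }
  labels <- vapply(stimuli, function(s) attr(s, "label") %||% NA_real_,
                   numeric(1))
  list(states = structure(states, labels = labels,
                          class = c("state_matrix", "matrix")),
       total_spikes = total_spikes, active_neurons = length(active),
       nu_bar = total_spikes / network$pop$size)
}

# One full build/train/evaluate pipeline run; the workhorse behind all
# experiment drivers.
run_pipeline <- function(stimuli_train, stimuli_test, variant = "HeNHeS",
                         n_recurrent = 500, seed = 1L, epochs = 3, dt = 1,
                         point = distribution_point(), cv = 0.5,
                         n_output = 100) {
  cfgs <- if (identical(variant, "point")) {
    # take the heterogeneity CVs verbatim from the distribution point
    # (the mode the distribution-level optimizer uses)
    d <- point$dists
    list(het = heterogeneity_config(tau_m_E = d$tau_m_E,
                                    tau_m_I = d$tau_m_I,
                                    allow_unordered = TRUE),
         stdp = stdp_heterogeneity_config(A_plus_spec = d$A_plus,
                                          A_minus_spec = d$A_minus,
                                          tau_plus_spec = d$tau_plus,
                                          tau_minus_spec = d$tau_minus))
  } else {
    ablation_configs(variant, cv = cv, point = point)
  }
  n_input <- stimuli_train[[1]]$n_sources
  net_cfg <- network_config(n_recurrent = n_recurrent, n_input = n_input,
                            n_output = n_output,
                            lambda_conn = point$scalars$lambda_conn,
                            P_IR = point$scalars$P_IR,
                            W_scale = point$scalars$W_scale, seed = seed)
  network <- build_network(net_cfg, het = cfgs$het, stdp_het = cfgs$stdp)
  network <- train_network_stdp(network, stimuli_train, epochs = epochs,
                                dt = dt, seed = seed)
  ev_train <- evaluate_stimuli(network, stimuli_train, dt = dt)
  ev_test <- evaluate_stimuli(network, stimuli_test, dt = dt)
  model <- fit_linear_classifier(ev_train$states)
  acc <- classification_accuracy(model, ev_test$states)
  list(accuracy = acc,
       effective_rank = effective_rank(ev_test$states),
       nu_bar = ev_test$nu_bar,
       active_neurons = ev_test$active_neurons,
       network = network)
}

#' Heterogeneity ablation experiment
#'
#' For each variant and seed: build the network, train with STDP on
#' the training split, freeze plasticity, extract state matrices, fit
#' the linear read-out and evaluate held-out accuracy.
#'
#' @param dataset list of labelled [frame_sequence()]s (or encoded
#'   stimuli).
#' @param variants ablation variant names.
#' @param n_seeds independent network initializations per variant.
#' @param test_fraction held-out fraction.
#' @param encoder an [encoder_config()].
#' @param ... forwarded to `run_pipeline` (`n_recurrent`, `epochs`,
#'   `dt`, `point`, `cv`, `n_output`).
#' @return A data frame with one row per variant: mean and sd of
#'   accuracy, effective rank and average activation over seeds; the
#'   per-seed raw values are in the `raw` attribute.
#' @export
run_ablation <- function(dataset,
                         variants = c("HoNHoS", "HeNHoS", "HoNHeS",
                                      "HeNHeS"),
                         n_seeds = 5, test_fraction = 0.5,
                         encoder = default_experiment_encoder(), ...) {
  stimuli <- harmonize_sources(encode_dataset(dataset, encoder))
  raw <- list()
  for (variant in variants) {
    for (s in seq_len(n_seeds)) {
      split <- train_test_split(stimuli, test_fraction, seed = s)
      r <- run_pipeline(split$train, split$test, variant = variant,
                        seed = s, ...)
      raw[[length(raw) + 1L]] <-
        data.frame(variant = variant, seed = s, accuracy = r$accuracy,
                   effective_rank = r$effective_rank, nu_bar = r$nu_bar,
                   active_neurons = r$active_neurons)
    }
  }
  raw <- do.call(rbind, raw)
  agg <- do.call(rbind, lapply(split(raw, raw$variant), function(d)
    data.frame(variant = d$variant[1],
               accuracy_mean = mean(d$accuracy),
               accuracy_sd = if (nrow(d) > 1) sd(d$accuracy) else 0,
               effective_rank_mean = mean(d$effective_rank),
               nu_bar_mean = mean(d$nu_bar))))
  agg <- agg[match(variants, agg$variant), ]
  rownames(agg) <- NULL
  attr(agg, "raw") <- raw
  agg
}

#' Sparsity sweep over connection density and weight scale
#'
#' Sweeps the connection length scale lambda and the weight scale
#' W_scale; per grid cell, networks are built, briefly trained and
#' evaluated over `n_seeds` seeds, recording the number of active
#' neurons (>= 1 spike over the whole test set), held-out accuracy and
#' the effective rank of the test state matrix.
#'
#' @param dataset labelled clips or stimuli.
#' @param lambda_grid,wscale_grid numeric grids.
#' @param variant ablation variant.
#' @param n_seeds seeds per cell.
#' @param encoder an [encoder_config()].
#' @param ... forwarded to `run_pipeline`.
#' @return Data frame with one row per (lambda, W_scale) cell: means
#'   over seeds plus the per-seed raw values in attribute `raw`.
#' @export
sparsity_sweep <- function(dataset, lambda_grid, wscale_grid,
                           variant = "HeNHeS", n_seeds = 5,
                           test_fraction = 0.5,
                           encoder = default_experiment_encoder(), ...) {
  stopifnot(length(lambda_grid) >= 1, length(wscale_grid) >= 1)
  stimuli <- harmonize_sources(encode_dataset(dataset, encoder))
  base_point <- distribution_point()
  raw <- list()
  for (lam in lambda_grid) for (ws in wscale_grid) {
    pt <- base_point
    pt$scalars$lambda_conn <- lam
    pt$scalars$W_scale <- ws
    for (s in seq_len(n_seeds)) {
      split <- train_test_split(stimuli, test_fraction, seed = s)
      r <- run_pipeline(split$train, split$test, variant = variant,
                        seed = s, point = pt, ...)
      raw[[length(raw) + 1L]] <-
        data.frame(lambda = lam, W_scale = ws, seed = s,
                   accuracy = r$accuracy,
                   effective_rank = r$effective_rank,
                   active_neurons = r$active_neurons, nu_bar = r$nu_bar)
    }
  }
  raw <- do.call(rbind, raw)
  key <- interaction(raw$lambda, raw$W_scale, drop = TRUE)
  agg <- do.call(rbind, lapply(split(raw, key), function(d)
    data.frame(lambda = d$lambda[1], W_scale = d$W_scale[1],
               accuracy = mean(d$accuracy),
               effective_rank = mean(d$effective_rank),
               active_neurons = mean(d$active_neurons))))
  agg <- agg[order(agg$lambda, agg$W_scale), ]
  rownames(agg) <- NULL
  attr(agg, "raw") <- raw
  agg
}

#' Limited-training-data sweep
#'
#' For each training fraction, a stratified subsample of the training
#' split is used for STDP training and read-out fitting; accuracy is
#' always measured on the full test split.
#'
#' @param dataset labelled clips or stimuli.
#' @param fractions training fractions in (0, 1].
#' @param variants ablation variants to compare.
#' @param n_seeds seeds per cell.
#' @param encoder an [encoder_config()].
#' @param ... forwarded to `run_pipeline`.
#' @return Data frame of mean accuracy per (fraction, variant), raw
#'   per-seed values in attribute `raw`.
#' @export
limited_data_sweep <- function(dataset, fractions = c(0.1, 0.25, 0.5, 1),
                               variants = c("HoNHoS", "HeNHeS"),
                               n_seeds = 5, test_fraction = 0.5,
                               encoder = default_experiment_encoder(), ...) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  stimuli <- harmonize_sources(encode_dataset(dataset, encoder))
  raw <- list()
  for (s in seq_len(n_seeds)) {
    split <- train_test_split(stimuli, test_fraction, seed = s)
    for (frac in fractions) {
      train <- if (frac < 1) {
        sub <- train_test_split(split$train, 1 - frac, seed = s + 1000L)
        sub$test  # the held-in fraction of size frac
      } else split$train
      lbl <- vapply(train, function(x) attr(x, "label") %||% NA_real_,
                    numeric(1))
      if (min(table(lbl)) < 1)
        stop("limited_data_sweep: fraction ", frac,
             " leaves a class empty", call. = FALSE)
      for (variant in variants) {
        r <- run_pipeline(train, split$test, variant = variant,
                          seed = s, ...)
        raw[[length(raw) + 1L]] <-
          data.frame(fraction = frac, variant = variant, seed = s,
                     accuracy = r$accuracy)
      }
    }
  }
  raw <- do.call(rbind, raw)
  key <- interaction(raw$fraction, raw$variant, drop = TRUE)
  agg <- do.call(rbind, lapply(split(raw, key), function(d)
    data.frame(fraction = d$fraction[1], variant = d$variant[1],
               accuracy = mean(d$accuracy))))
  agg <- agg[order(agg$variant, agg$fraction), ]
  rownames(agg) <- NULL
  attr(agg, "raw") <- raw
  agg
}

#' Average-activation comparison across variants
#'
#' Trains each variant and reports the average neuronal activation
#' `nu_bar` on the test split (total recurrent spikes per recurrent
#' neuron), the sparse-coding metric.
#'
#' @inheritParams run_ablation
#' @return Data frame of per-variant mean `nu_bar` (raw per-seed
#'   values in attribute `raw`).
#' @export
activation_comparison <- function(dataset,
                                  variants = c("HoNHoS", "HeNHeS"),
                                  n_seeds = 5, test_fraction = 0.5,
                                  encoder = default_experiment_encoder(), ...) {
  res <- run_ablation(dataset, variants = variants, n_seeds = n_seeds,
                      test_fraction = test_fraction, encoder = encoder,
                      ...)
  out <- res[, c("variant", "nu_bar_mean")]
  attr(out, "raw") <- attr(res, "raw")
  out
}

#' Classification-fitness objective for the distribution optimizer
#'
#' Wraps the full pipeline into an objective for [bo_loop()]: given a
#' [distribution_point()], build and STDP-train an HRSNN at the stated
#' scale and return held-out classification accuracy.
#'
#' @param dataset labelled clips or stimuli.
#' @param encoder an [encoder_config()].
#' @param n_recurrent reservoir size for the objective evaluations.
#' @param n_seeds networks averaged per evaluation.
#' @param ... forwarded to `run_pipeline`.
#' @return A function `distribution_point -> accuracy`.
#' @export
hrsnn_objective <- function(dataset, encoder = default_experiment_encoder(),
                            n_recurrent = 100, n_seeds = 1, ...) {
  stimuli <- harmonize_sources(encode_dataset(dataset, encoder))
  function(point) {
    accs <- vapply(seq_len(n_seeds), function(s) {
      split <- train_test_split(stimuli, 0.5, seed = s)
      run_pipeline(split$train, split$test, variant = "point",
                   n_recurrent = n_recurrent, seed = s, point = point,
                   ...)$accuracy
    }, numeric(1))
    mean(accs)
  }
}
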