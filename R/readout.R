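#' Extract the read-out state of a completed simulation
#'
#' The state of the reservoir for one stimulus is the membrane
#' potential of the output neurons at the end of the spike train; the
#' caller must [reset_states()] before presenting the next stimulus
#' (the batch driver [build_state_matrix()] enforces this).
#'
#' @param record a `simulation_record` from [run_network()].
#' @return Numeric state vector of length `n_output`.
#' @export
extract_state <- function(record) {
  s <- record$output_membrane_final
  if (is.null(s) || !length(s))
    stop("extract_state: record has no output layer", call. = FALSE)
  s
}

#' Build the stimulus-state matrix F
#'
#' Presents each stimulus to the (trained, plasticity-off) network in
#' turn -- run, extract the final output membranes, reset -- and stacks
#' the states into the `N_stimuli x N_readout` matrix `F` whose rank
#' reflects the separation property of the reservoir.
#'
#' @param network an `hrsnn_network`.
#' @param stimuli list of [spike_train_set()]s.
#' @param sim a [simulation_config()]; `plasticity_on` is forced off.
#' @param labels optional per-stimulus class ids, attached as the
#'   `labels` attribute.
#' @return A numeric matrix with one row per stimulus, with attribute
#'   `labels`, of class `state_matrix`.
#' @export
build_state_matrix <- function(network, stimuli, sim = simulation_config(),
                               labels = NULL) {
  sim$plasticity_on <- FALSE
  network <- reset_states(network)
  states <- matrix(NA_real_, length(stimuli), network$config$n_output)
  for (i in seq_along(stimuli)) {
    sim_i <- sim
    sim_i$duration <- max(stimuli[[i]]$duration, sim$dt)
    rec <- run_network(network, stimuli[[i]], sim_i)
    states[i, ] <- extract_state(rec)
    network <- reset_states(rec$network)
  }
  if (is.null(labels))
    labels <- vapply(stimuli, function(s) attr(s, "label") %||% NA_integer_,
                     numeric(1))
  structure(states, labels = labels, class = c("state_matrix", "matrix"))
}

#' Effective rank at a singular-value energy threshold
#'
#' Singular value decomposition `F = U Sigma V^T`; the effective rank
#' is the smallest `k` such that the top-`k` singular values contain at
#' least `energy` (default 99 percent) of the sum of all singular
#' values. Used as the measure of the linear separation property of
#' the reservoir.
#'
#' @param F numeric matrix (a state matrix or any matrix).
#' @param energy cumulative singular-value fraction, default 0.99.
#' @return Integer effective rank; 0 for an all-zero matrix.
#' @export
effective_rank <- function(F, energy = 0.99) {
  F <- unclass(as.matrix(F))
  if (!length(F) || all(F == 0)) return(0L)
  sv <- svd(F, nu = 0, nv = 0)$d
  cum <- cumsum(sv)
  as.integer(which(cum >= energy * cum[length(cum)] - 1e-12)[1])
}

#' Fit the linear read-out classifier
#'
#' Multinomial logistic regression with an L2 (ridge) penalty on the
#' standardized state vectors -- the "linear classifier" of the
#' read-out stage. Columns are standardized with statistics fitted on
#' the training set; the fit is deterministic.
#'
#' @param F a state matrix (rows = stimuli).
#' @param labels class ids per row; defaults to `attr(F, "labels")`.
#' @param lambda_reg ridge penalty passed to [glmnet::glmnet()].
#' @return An object of class `hrsnn_classifier` holding the fitted
#'   coefficients, the standardization statistics and the class list.
#' @export
fit_linear_classifier <- function(F, labels = NULL, lambda_reg = 1e-2) {
  if (is.null(labels)) labels <- attr(F, "labels")
  F <- unclass(as.matrix(F))
  if (is.null(labels) || length(labels) != nrow(F))
    stop("fit_linear_classifier: need one label per state row",
         call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("fit_linear_classifier: need >= 2 classes", call. = FALSE)
  mu <- colMeans(F)
  sigma <- apply(F, 2, sd)
  sigma[!is.finite(sigma) | sigma < 1e-12] <- 1
  X <- scale(F, center = mu, scale = sigma)
  fit <- withCallingHandlers(
    glmnet::glmnet(X, factor(labels, levels = classes),
                   family = "multinomial", alpha = 0,
                   lambda = c(10, 1, 0.1, lambda_reg),
                   standardize = FALSE),
    warning = function(w) {
      # small per-class counts are routine at desk scale
      if (grepl("fewer than 8|dangerous", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, lambda = lambda_reg, mu = mu, sigma = sigma,
                 classes = classes),
            class = "hrsnn_classifier")
}

#' @export
predict.hrsnn_classifier <- function(object, newdata, ...) {
  X <- scale(unclass(as.matrix(newdata)), center = object$mu,
             scale = object$sigma)
  cls <- predict(object$fit, X, s = object$lambda, type = "class")
  # map back to the original label type
  object$classes[match(as.vector(cls), as.character(object$classes))]
}

#' Classification accuracy of a fitted read-out
#'
#' @param model an `hrsnn_classifier` from [fit_linear_classifier()].
#' @param F_test state matrix of held-out stimuli.
#' @param labels true labels; defaults to `attr(F_test, "labels")`.
#' @return Fraction of correctly classified rows.
#' @export
classification_accuracy <- function(model, F_test, labels = NULL) {
  if (is.null(labels)) labels <- attr(F_test, "labels")
  F_test <- unclass(as.matrix(F_test))
  if (!nrow(F_test)) stop("classification_accuracy: empty test set",
                          call. = FALSE)
  mean(predict(model, F_test) == labels)
}

#' Average neuronal activation
#'
#' `nu_bar = sum_i sum_t nu_i(t) / N_R`: the total recurrent spike
#' count across all neurons and timesteps, divided by the number of
#' recurrent neurons. A sparsity-of-activity measure: lower means
#' sparser coding for the same stimulus set.
#'
#' @param spikes a [spike_train_set()] over the recurrent layer (or a
#'   list of them, summed).
#' @param N_R number of recurrent neurons.
#' @return Non-negative real.
#' @export
average_neuronal_activation <- function(spikes, N_R) {
  if (inherits(spikes, "spike_train_set")) spikes <- list(spikes)
  total <- sum(vapply(spikes, n_events, numeric(1)))
  total / N_R
}

#' Count active neurons
#'
#' Active neurons are those that fire at least one spike over the
#' entire record (typically the whole test set).
#'
#' @param spikes a [spike_train_set()] or list of them.
#' @param N_R number of recurrent neurons (upper bound, for validation
#'   only).
#' @return Integer count of distinct spiking sources.
#' @export
count_active_neurons <- function(spikes, N_R = Inf) {
  if (inherits(spikes, "spike_train_set")) spikes <- list(spikes)
  ids <- unique(unlist(lapply(spikes, `[[`, "neuron")))
  length(ids[ids <= N_R])
}
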