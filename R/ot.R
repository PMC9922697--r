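#' One-dimensional order-1 Wasserstein distance
#'
#' For distributions on the line, `W1(X, Y)` is the integral of
#' `|F_X^{-1}(u) - F_Y^{-1}(u)|` over `u` in (0, 1). Gamma
#' specifications are integrated by midpoint quadrature of the quantile
#' functions; equal-size empirical samples reduce to the mean absolute
#' difference of the sorted values; mixed and unequal cases are
#' evaluated on a common quantile grid.
#'
#' @param X,Y each either a [gamma_spec()] (CV 0 = point mass) or a
#'   numeric sample vector.
#' @param n_quad number of quadrature/grid points.
#' @return Non-negative distance.
#' @export
wasserstein_1d <- function(X, Y, n_quad = 512L) {
  if (is.numeric(X) && is.numeric(Y) && length(X) == length(Y)) {
    if (!length(X)) stop("wasserstein_1d: empty sample", call. = FALSE)
    return(mean(abs(sort(X) - sort(Y))))  # exact for equal-size samples
  }
  qx <- w1_quantiles(X, n_quad)
  qy <- w1_quantiles(Y, n_quad)
  mean(abs(qx - qy))
}

# Quantile function evaluated at midpoints (i - 0.5)/n of (0, 1).
w1_quantiles <- function(X, n_quad) {
  u <- (seq_len(n_quad) - 0.5) / n_quad
  if (is_gamma_spec(X)) return(quantile_gamma(X, u))
  if (is.numeric(X)) {
    if (!length(X)) stop("wasserstein_1d: empty sample", call. = FALSE)
    return(quantile(X, probs = u, type = 1, names = FALSE))
  }
  stop("wasserstein_1d: inputs must be gamma_spec or numeric samples",
       call. = FALSE)
}

#' Debiased Sinkhorn divergence between 1-D samples
#'
#' Entropic-regularized optimal transport with cost `|x - y|` (matching
#' the order-1 Wasserstein distance), solved by log-domain Sinkhorn
#' iterations, in the debiased divergence form
#' `S(X,Y) = OT_eps(X,Y) - (OT_eps(X,X) + OT_eps(Y,Y)) / 2`
#' so the self-distance is ~0. For small `epsilon` this approximates
#' `W1` closely; it is the surrogate the distribution-level optimizer
#' can fall back on in higher-dimensional metric spaces.
#'
#' @param X,Y numeric sample vectors (or matrices with one row per
#'   sample for the multivariate mode, cost = Euclidean distance).
#' @param epsilon entropic regularization strength (> 0).
#' @param tol fixed-point tolerance on the potentials.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   best iterate.
#' @return Non-negative (up to numerical error) divergence.
#' @export
sinkhorn_distance <- function(X, Y, epsilon = 0.01, tol = 1e-9,
                              max_iter = 1e4) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!nrow(X) || !nrow(Y))
    stop("sinkhorn_distance: empty sample", call. = FALSE)
  # canonical argument order makes d(X, Y) == d(Y, X) exactly (the
  # alternating iteration is otherwise symmetric only up to tol)
  kx <- c(nrow(X), sum(X), sum(X^2))
  ky <- c(nrow(Y), sum(Y), sum(Y^2))
  d1 <- which(kx != ky)[1]
  if (!is.na(d1) && ky[d1] < kx[d1]) {
    tmp <- X; X <- Y; Y <- tmp
  }
  ot <- function(A, B) sinkhorn_ot_cost(A, B, epsilon, tol, max_iter)
  ot(X, Y) - 0.5 * (ot(X, X) + ot(Y, Y))
}

# Entropic OT transport cost <pi, C> between uniform empirical measures.
sinkhorn_ot_cost <- function(A, B, epsilon, tol, max_iter) {
  n <- nrow(A); m <- nrow(B)
  C <- sqrt(outer(rowSums(A^2), rep(1, m)) + outer(rep(1, n), rowSums(B^2)) -
              2 * tcrossprod(A, B))
  C[!is.finite(C) | C < 0] <- 0
  la <- -log(n); lb <- -log(m)
  f <- numeric(n); g <- numeric(m)
  lse <- function(M) {  # row-wise log-sum-exp
    mx <- apply(M, 1, max)
    mx + log(rowSums(exp(M - mx)))
  }
  # epsilon scaling: anneal from a large regularization down to the
  # target, which cuts the iteration count from O(1/eps) to tens
  eps_seq <- max(epsilon, max(C), 1)
  while (utils::tail(eps_seq, 1) > epsilon * 1.5)
    eps_seq <- c(eps_seq, utils::tail(eps_seq, 1) / 2)
  eps_seq <- c(eps_seq, epsilon)
  converged <- FALSE
  iters_left <- max_iter
  for (eps in eps_seq) {
    final <- eps == epsilon
    budget <- if (final) iters_left else min(50, iters_left)
    for (it in seq_len(max(budget, 1))) {
      f_new <- -eps * lse(t(t(-C) + g) / eps + lb)
      g_new <- -eps * lse(t(-C + f_new) / eps + la)
      delta <- max(abs(f_new - f), abs(g_new - g))
      f <- f_new; g <- g_new
      iters_left <- iters_left - 1
      if (delta < tol) break
    }
    if (final) converged <- delta < tol
  }
  if (!converged)
    warning("sinkhorn_distance: not converged; returning best iterate")
  # pi_ij = exp((f_i + g_j - C_ij)/eps - log n - log m); cost = <pi, C>
  lp <- outer(f, g, "+") - C
  P <- exp(lp / epsilon + la + lb)
  sum(P * C)
}

#' Distance between two distribution points
#'
#' The search space of the distribution-level optimizer is a tuple of
#' six gamma distributions (neuronal and STDP heterogeneity) plus three
#' structural scalars. The distance sums the 1-D Wasserstein distances
#' between corresponding gamma distributions -- each normalized by the
#' width of its mean's box bound -- and adds the Euclidean distance on
#' the normalized scalar block. A joint-sample Sinkhorn mode
#' (`method = "sinkhorn"`) is available for the multivariate reading.
#'
#' @param p,q [distribution_point()]s with matching schemas.
#' @param bounds box bounds as returned by [default_bounds()].
#' @param method `"wasserstein"` (per-parameter 1-D, default) or
#'   `"sinkhorn"` (joint samples over the six distribution axes).
#' @param n_sample sample size per axis for the sinkhorn mode.
#' @return Non-negative distance; 0 iff the points coincide (for the
#'   default method).
#' @export
distribution_distance <- function(p, q, bounds = default_bounds(),
                                  method = c("wasserstein", "sinkhorn"),
                                  n_sample = 64L) {
  method <- match.arg(method)
  if (!setequal(names(p$dists), names(q$dists)))
    stop("distribution_distance: schema mismatch", call. = FALSE)
  widths <- vapply(names(p$dists), function(nm)
    diff(bounds[[paste0(nm, ".mean")]]), numeric(1))
  if (method == "wasserstein") {
    d_dist <- sum(vapply(names(p$dists), function(nm) {
      a <- p$dists[[nm]]; b <- q$dists[[nm]]
      if (a$cv == 0 && b$cv == 0) w <- abs(a$mean - b$mean)
      else w <- wasserstein_1d(a, b)
      w / widths[[nm]]
    }, numeric(1)))
  } else {
    u <- (seq_len(n_sample) - 0.5) / n_sample
    qs <- function(pt) vapply(names(pt$dists), function(nm)
      quantile_gamma(pt$dists[[nm]], u) / widths[[nm]],
      numeric(n_sample))
    d_dist <- sinkhorn_distance(qs(p), qs(q))
  }
  sn <- names(p$scalars)
  sw <- vapply(sn, function(nm) diff(bounds[[nm]]), numeric(1))
  d_scal <- sqrt(sum(((unlist(p$scalars) - unlist(q$scalars)) / sw)^2))
  d_dist + d_scal
}
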