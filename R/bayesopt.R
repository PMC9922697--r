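#' A point in the distribution-level search space
#'
#' One candidate of the Bayesian optimizer: the hyperparameters of the
#' six heterogeneity distributions (membrane time constants tau_m_E,
#' tau_m_I; STDP scaling constants A_plus, A_minus; STDP decay
#' constants tau_plus, tau_minus), each a [gamma_spec()], plus the
#' scalar structure parameters lambda_conn, P_IR and W_scale.
#'
#' @param tau_m_E,tau_m_I,A_plus,A_minus,tau_plus,tau_minus
#'   [gamma_spec()]s (bare numbers are promoted to point masses).
#' @param lambda_conn,P_IR,W_scale structural scalars.
#' @return An object of class `distribution_point` with elements
#'   `dists` (named list of gamma_specs) and `scalars` (named list).
#' @export
distribution_point <- function(tau_m_E = gamma_spec(20, 0.5),
                               tau_m_I = gamma_spec(10, 0.5),
                               A_plus = gamma_spec(0.01, 0.5),
                               A_minus = gamma_spec(0.012, 0.5),
                               tau_plus = gamma_spec(20, 0.5),
                               tau_minus = gamma_spec(20, 0.5),
                               lambda_conn = 2, P_IR = 0.3, W_scale = 2) {
  dists <- lapply(list(tau_m_E = tau_m_E, tau_m_I = tau_m_I,
                       A_plus = A_plus, A_minus = A_minus,
                       tau_plus = tau_plus, tau_minus = tau_minus),
                  as_gamma_spec)
  stopifnot(lambda_conn > 0, P_IR >= 0, P_IR <= 1, W_scale > 0)
  structure(list(dists = dists,
                 scalars = list(lambda_conn = lambda_conn, P_IR = P_IR,
                                W_scale = W_scale)),
            class = "distribution_point")
}

#' Default box bounds of the search space
#'
#' Bounds for every free coordinate of a [distribution_point()]
#' (`<dist>.mean`, `<dist>.cv`, and the scalars). They both clip the
#' optimizer's proposals and normalize the per-parameter Wasserstein
#' distances in [distribution_distance()]. Centered on biologically
#' ordered defaults (excitatory time constants above inhibitory).
#'
#' @return Named list of length-2 numeric vectors `c(lo, hi)`.
#' @export
default_bounds <- function() {
  list(tau_m_E.mean = c(10, 40), tau_m_E.cv = c(0, 1),
       tau_m_I.mean = c(4, 20), tau_m_I.cv = c(0, 1),
       A_plus.mean = c(0.001, 0.05), A_plus.cv = c(0, 1),
       A_minus.mean = c(0.001, 0.05), A_minus.cv = c(0, 1),
       tau_plus.mean = c(5, 60), tau_plus.cv = c(0, 1),
       tau_minus.mean = c(5, 60), tau_minus.cv = c(0, 1),
       lambda_conn = c(0.5, 8), P_IR = c(0.05, 0.9),
       W_scale = c(0.5, 20))
}

# Flatten a point to the named coordinate vector used by bounds.
flatten_point <- function(p) {
  v <- c(unlist(lapply(p$dists, function(g) c(mean = g$mean, cv = g$cv))),
         unlist(p$scalars))
  names(v) <- sub("^([^.]+)\\.(mean|cv)$", "\\1.\\2", names(v))
  v
}

# Rebuild a point from a named coordinate vector.
unflatten_point <- function(v) {
  dn <- c("tau_m_E", "tau_m_I", "A_plus", "A_minus",
          "tau_plus", "tau_minus")
  args <- lapply(dn, function(nm)
    gamma_spec(v[[paste0(nm, ".mean")]], v[[paste0(nm, ".cv")]]))
  names(args) <- dn
  do.call(distribution_point,
          c(args, list(lambda_conn = v[["lambda_conn"]],
                       P_IR = v[["P_IR"]], W_scale = v[["W_scale"]])))
}

#' Matern kernel on the Wasserstein metric
#'
#' `k(p, q) = sigma2 * 2^(1-rho)/Gamma(rho) * (sqrt(2 rho) W / kappa)^rho
#'  * K_rho(sqrt(2 rho) W / kappa)` where `W` is
#' [distribution_distance()] and `K_rho` the modified Bessel function
#' of the second kind. At `W = 0` the limit value is `sigma2`. The
#' half-integer smoothness values use the closed forms (`rho = 1/2`
#' is `sigma2 exp(-W/kappa)`).
#'
#' @param p,q [distribution_point()]s, or set `W` directly.
#' @param sigma2 kernel variance.
#' @param kappa length scale (> 0).
#' @param rho smoothness, one of 1/2, 3/2, 5/2 (or any positive value
#'   via the Bessel route). The default 1/2 (exponential kernel) is the
#'   member that is provably positive semi-definite on this metric:
#'   sums of 1-D Wasserstein distances are conditionally negative
#'   definite, which Schoenberg's theorem turns into a PSD guarantee
#'   for exp(-W/kappa) only. Higher smoothness values are available but
#'   can produce indefinite Gram matrices on clustered point sets.
#' @param W optional precomputed distance(s); overrides `p`, `q`.
#' @param bounds box bounds for the distance normalization.
#' @return Covariance value(s) in (0, sigma2].
#' @export
matern_wasserstein_kernel <- function(p = NULL, q = NULL, sigma2 = 1,
                                      kappa = 1, rho = 1 / 2, W = NULL,
                                      bounds = default_bounds()) {
  stopifnot(sigma2 > 0, kappa > 0, rho > 0)
  if (is.null(W)) W <- distribution_distance(p, q, bounds)
  r <- sqrt(2 * rho) * W / kappa
  out <- if (isTRUE(all.equal(rho, 0.5))) {
    sigma2 * exp(-r)
  } else if (isTRUE(all.equal(rho, 1.5))) {
    sigma2 * (1 + r) * exp(-r)
  } else if (isTRUE(all.equal(rho, 2.5))) {
    sigma2 * (1 + r + r^2 / 3) * exp(-r)
  } else {
    k <- sigma2 * 2^(1 - rho) / gamma(rho) * r^rho * besselK(r, rho)
    k[r == 0] <- sigma2
    k
  }
  out[W == 0] <- sigma2
  out
}

#' Gram matrix of the Matern-Wasserstein kernel
#'
#' Pairwise kernel values over a point set, with jitter
#' `1e-8 * sigma2` on the diagonal. Positive semi-definiteness of this
#' matrix (up to jitter) is what makes the distribution-level kernel a
#' valid Gaussian-process covariance.
#'
#' @param points list of [distribution_point()]s.
#' @param sigma2,kappa,rho kernel parameters (see
#'   [matern_wasserstein_kernel()]).
#' @param bounds box bounds for the distance normalization.
#' @param jitter diagonal jitter relative to `sigma2`.
#' @return Symmetric `n x n` covariance matrix.
#' @export
gram_matrix <- function(points, sigma2 = 1, kappa = 1, rho = 1 / 2,
                        bounds = default_bounds(), jitter = 1e-8) {
  D <- distance_matrix(points, bounds)
  K <- matern_wasserstein_kernel(W = D, sigma2 = sigma2, kappa = kappa,
                                 rho = rho)
  K + diag(jitter * sigma2, nrow(K))
}

# Stacked quantile-table representation: one column per point holding
# the six normalized quantile functions end to end, so pairwise
# distances reduce to column operations.
point_tables <- function(points, bounds, n_quad = 256L) {
  dn <- names(points[[1]]$dists)
  widths <- vapply(dn, function(nm) diff(bounds[[paste0(nm, ".mean")]]),
                   numeric(1))
  u <- (seq_len(n_quad) - 0.5) / n_quad
  Q <- vapply(points, function(p)
    unlist(lapply(dn, function(nm)
      quantile_gamma(p$dists[[nm]], u) / widths[[nm]])),
    numeric(n_quad * length(dn)))
  sw <- vapply(names(points[[1]]$scalars), function(nm) diff(bounds[[nm]]),
               numeric(1))
  S <- vapply(points, function(p) unlist(p$scalars) / sw,
              numeric(length(sw)))
  list(Q = Q, S = rbind(S), n_quad = n_quad)
}

# Pairwise distribution_distance over a point list, sharing the
# quantile tables across pairs for speed.
distance_matrix <- function(points, bounds = default_bounds(),
                            n_quad = 256L) {
  tb <- point_tables(points, bounds, n_quad)
  n <- length(points)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cols <- seq_len(i - 1)
    if (!length(cols)) next
    dq <- colSums(abs(tb$Q[, cols, drop = FALSE] - tb$Q[, i])) / n_quad
    ds <- sqrt(colSums((tb$S[, cols, drop = FALSE] - tb$S[, i])^2))
    D[i, cols] <- D[cols, i] <- dq + ds
  }
  D
}

#' Gaussian-process posterior at a query point
#'
#' Standard GP conditional mean and variance under the
#' Matern-Wasserstein covariance, with observation noise on the
#' diagonal. The prior mean is the mean of the observed values (a
#' constant trend), to which the posterior reverts far from the data.
#'
#' @param surrogate list with `points` (list of evaluated
#'   [distribution_point()]s), `values` (observed objective values),
#'   `sigma2`, `kappa`, `rho`, `noise`, `bounds`; see [bo_loop()].
#' @param query a [distribution_point()].
#' @return List with `mean` and `variance` (variance floored at 0).
#' @export
gp_posterior <- function(surrogate, query) {
  pts <- surrogate$points
  y <- surrogate$values
  K <- gram_matrix(pts, surrogate$sigma2, surrogate$kappa, surrogate$rho,
                   surrogate$bounds)
  K <- K + diag(surrogate$noise, length(y))
  kq <- vapply(pts, function(p)
    matern_wasserstein_kernel(p, query, surrogate$sigma2, surrogate$kappa,
                              surrogate$rho, bounds = surrogate$bounds),
    numeric(1))
  mu0 <- mean(y)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y - mu0))
  vq <- backsolve(L, forwardsolve(t(L), kq))
  list(mean = mu0 + sum(kq * alpha),
       variance = max(surrogate$sigma2 - sum(kq * vq), 0))
}

#' Expected improvement acquisition
#'
#' For fitness maximization, `EI = (mu - f_best) Phi(Z) + sd phi(Z)`
#' with `Z = (mu - f_best)/sd`, where `Phi`/`phi` are the standard
#' normal CDF/PDF; at `sd = 0` it degenerates to
#' `max(mu - f_best, 0)`.
#'
#' @param mean posterior mean at the candidate.
#' @param sd posterior standard deviation (>= 0).
#' @param f_best best observed fitness so far.
#' @return Non-negative expected improvement (vectorized).
#' @export
expected_improvement <- function(mean, sd, f_best) {
  stopifnot(all(sd >= 0))
  z <- (mean - f_best) / ifelse(sd > 0, sd, 1)
  ei <- ifelse(sd > 0,
               (mean - f_best) * pnorm(z) + sd * dnorm(z),
               pmax(mean - f_best, 0))
  pmax(ei, 0)
}

#' Bayesian optimization over parameter distributions
#'
#' Maximizes a fitness (e.g. negative validation loss of the trained
#' network) over [distribution_point()]s: `n_init` Latin-hypercube
#' draws, then repeatedly fit the Matern-Wasserstein GP surrogate,
#' score a random candidate pool by expected improvement, and evaluate
#' the argmax. Kernel variance and length scale are refit by maximum
#' likelihood on a small grid each iteration. A failing objective is
#' recorded at the worst observed value and the loop continues.
#'
#' @param objective function `distribution_point -> fitness` (higher is
#'   better).
#' @param bounds box bounds; see [default_bounds()]. Coordinates
#'   absent from `free` are fixed at `base`.
#' @param free character vector of coordinate names to optimize.
#' @param base a [distribution_point()] supplying the fixed
#'   coordinates.
#' @param budget total number of objective evaluations (>= n_init).
#' @param n_init number of space-filling initial draws.
#' @param pool_size candidate pool per iteration.
#' @param rho Matern smoothness.
#' @param noise observation noise variance.
#' @param seed integer seed; the whole loop is reproducible.
#' @return List with `best_point`, `best_value`, and `history` (data
#'   frame of iteration, fitness, best-so-far, and the flattened
#'   coordinates).
#' @export
bo_loop <- function(objective, bounds = default_bounds(),
                    free = c("tau_m_E.mean", "tau_m_I.mean"),
                    base = distribution_point(), budget = 50,
                    n_init = 10, pool_size = 512, rho = 1 / 2,
                    noise = 1e-6, seed = 1L) {
  stopifnot(budget >= n_init, n_init >= 1)
  base_v <- flatten_point(base)
  stopifnot(all(free %in% names(bounds)))
  lo <- vapply(bounds[free], `[`, numeric(1), 1)
  hi <- vapply(bounds[free], `[`, numeric(1), 2)
  make_point <- function(x) {
    v <- base_v
    v[free] <- pmin(pmax(x, lo), hi)
    unflatten_point(as.list(v))
  }
  d <- length(free)
  with_seed(seed, {
    # Latin hypercube initial design
    init <- vapply(seq_len(d), function(j)
      (sample.int(n_init) - runif(n_init)) / n_init, numeric(n_init))
    init <- matrix(lo, n_init, d, byrow = TRUE) +
      init * matrix(hi - lo, n_init, d, byrow = TRUE)
    xs <- lapply(seq_len(n_init), function(i) init[i, ])
    pts <- lapply(xs, make_point)
    ys <- vapply(pts, function(p) eval_objective(objective, p), numeric(1))
    ys[!is.finite(ys)] <- min(ys[is.finite(ys)], 0)
    while (length(ys) < budget) {
      surr <- fit_surrogate(pts, ys, bounds, rho, noise)
      cand_x <- matrix(runif(pool_size * d), pool_size, d)
      cand_x <- matrix(lo, pool_size, d, byrow = TRUE) +
        cand_x * matrix(hi - lo, pool_size, d, byrow = TRUE)
      cands <- lapply(seq_len(pool_size), function(i) make_point(cand_x[i, ]))
      post <- gp_posterior_batch(surr, cands)
      ei <- expected_improvement(post$mean, sqrt(post$variance), max(ys))
      pick <- which.max(ei)
      p_new <- cands[[pick]]
      y_new <- eval_objective(objective, p_new)
      if (!is.finite(y_new)) y_new <- min(ys)
      pts <- c(pts, list(p_new))
      ys <- c(ys, y_new)
      xs <- c(xs, list(cand_x[pick, ]))
    }
  })
  coords <- do.call(rbind, lapply(pts, function(p) flatten_point(p)[free]))
  colnames(coords) <- free
  history <- data.frame(iteration = seq_along(ys), fitness = ys,
                        best_so_far = cummax(ys))
  history <- cbind(history, as.data.frame(coords))
  best <- which.max(ys)
  list(best_point = pts[[best]], best_value = ys[best], history = history)
}

eval_objective <- function(objective, p) {
  y <- tryCatch(objective(p), error = function(e) NA_real_)
  if (!is.numeric(y) || length(y) != 1L) NA_real_ else y
}

# Batched posterior sharing one Cholesky factorization.
gp_posterior_batch <- function(surrogate, queries) {
  pts <- surrogate$points
  y <- surrogate$values
  K <- gram_matrix(pts, surrogate$sigma2, surrogate$kappa, surrogate$rho,
                   surrogate$bounds) + diag(surrogate$noise, length(y))
  L <- chol(K)
  mu0 <- mean(y)
  alpha <- backsolve(L, forwardsolve(t(L), y - mu0))
  Dq <- cross_distance_matrix(pts, queries, surrogate$bounds)
  Kq <- matern_wasserstein_kernel(W = Dq, sigma2 = surrogate$sigma2,
                                  kappa = surrogate$kappa,
                                  rho = surrogate$rho)
  V <- backsolve(L, forwardsolve(t(L), Kq))
  list(mean = mu0 + drop(crossprod(Kq, alpha)),
       variance = pmax(surrogate$sigma2 - colSums(Kq * V), 0))
}

cross_distance_matrix <- function(points, queries,
                                  bounds = default_bounds(),
                                  n_quad = 256L) {
  ta <- point_tables(points, bounds, n_quad)
  tb <- point_tables(queries, bounds, n_quad)
  D <- matrix(0, length(points), length(queries))
  for (i in seq_along(points)) {
    dq <- colSums(abs(tb$Q - ta$Q[, i])) / n_quad
    ds <- sqrt(colSums((tb$S - ta$S[, i])^2))
    D[i, ] <- dq + ds
  }
  D
}

# Grid maximum-likelihood fit of (sigma2, kappa) for fixed smoothness.
fit_surrogate <- function(pts, ys, bounds, rho, noise) {
  D <- distance_matrix(pts, bounds)
  n <- length(ys)
  yc <- ys - mean(ys)
  med <- stats::median(D[upper.tri(D)])
  if (!is.finite(med) || med <= 0) med <- 1
  best <- NULL
  for (kappa in med * c(0.25, 0.5, 1, 2, 4)) {
    K1 <- matern_wasserstein_kernel(W = D, sigma2 = 1, kappa = kappa,
                                    rho = rho) + diag(1e-8, n)
    L <- tryCatch(chol(K1 + diag(noise, n)), error = function(e) NULL)
    if (is.null(L)) next
    a <- backsolve(L, forwardsolve(t(L), yc))
    sigma2 <- max(sum(yc * a) / n, 1e-12)  # profile ML variance
    nll <- n / 2 * log(sigma2) + sum(log(diag(L)))
    if (is.null(best) || nll < best$nll)
      best <- list(kappa = kappa, sigma2 = sigma2, nll = nll)
  }
  if (is.null(best)) {
    # defensive fallback: every factorization failed (possible for
    # rho > 1/2, where the kernel is not guaranteed PSD)
    best <- list(kappa = med, sigma2 = max(stats::var(ys), 1e-12))
  }
  list(points = pts, values = ys, sigma2 = best$sigma2,
       kappa = best$kappa, rho = rho,
       noise = noise * max(best$sigma2, 1), bounds = bounds)
}
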