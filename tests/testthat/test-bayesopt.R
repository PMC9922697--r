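test_that("1-D Wasserstein distance: identities, point masses, shifts", {
  g <- gamma_spec(5, 0.4)
  expect_equal(wasserstein_1d(g, g), 0)
  # point masses at 2 and 5
  expect_equal(wasserstein_1d(gamma_spec(2, 0), gamma_spec(5, 0)), 3)
  # translation equivariance on samples: gamma(k=2, theta=1) + 0.7
  set.seed(1)
  x <- rgamma(400, shape = 2, scale = 1)
  expect_equal(wasserstein_1d(x, x + 0.7), 0.7, tolerance = 1e-10)
  # quantile-integral quadrature agrees with the sorted-sample value
  y <- rgamma(400, shape = 2, scale = 1)
  expect_equal(wasserstein_1d(x, y), mean(abs(sort(x) - sort(y))),
               tolerance = 1e-9)
  expect_error(wasserstein_1d(numeric(0), x), "empty")
})

test_that("debiased Sinkhorn approximates exact 1-D Wasserstein", {
  set.seed(2)
  x <- runif(40); y <- runif(40) + 0.5
  expect_lt(sinkhorn_distance(x, x), 1e-6)             # self-distance
  expect_equal(sinkhorn_distance(x, y), sinkhorn_distance(y, x),
               tolerance = 1e-10)                       # symmetry
  w <- wasserstein_1d(x, y)
  expect_lt(abs(sinkhorn_distance(x, y, epsilon = 0.01) - w) / w, 0.02)
})

test_that("distribution distance is a normalized metric on points", {
  p <- distribution_point()
  expect_equal(distribution_distance(p, p), 0)
  # symmetry + triangle inequality on random triples
  set.seed(3)
  for (rep in 1:20) {
    a <- random_point(); b <- random_point(); cc <- random_point()
    dab <- distribution_distance(a, b)
    expect_equal(dab, distribution_distance(b, a), tolerance = 1e-9)
    expect_lte(dab,
               distribution_distance(a, cc) +
                 distribution_distance(cc, b) + 1e-9)
  }
  # differing only in tau_m_E mean by delta (CV 0): normalized delta
  b <- default_bounds()
  p1 <- distribution_point(tau_m_E = gamma_spec(20, 0))
  p2 <- distribution_point(tau_m_E = gamma_spec(23, 0))
  expect_equal(distribution_distance(p1, p2),
               3 / diff(b$tau_m_E.mean), tolerance = 1e-12)
  # schema mismatch errors
  broken <- p1; names(broken$dists)[1] <- "oops"
  expect_error(distribution_distance(broken, p2), "schema")
})

test_that("Matern-Wasserstein kernel closed forms and monotonicity", {
  expect_equal(matern_wasserstein_kernel(W = 0, sigma2 = 2), 2)
  # rho = 1/2 reduces to the exponential kernel
  expect_equal(matern_wasserstein_kernel(W = 1, sigma2 = 1, kappa = 1,
                                         rho = 0.5),
               exp(-1), tolerance = 1e-12)
  # rho = 3/2 at W = kappa
  expect_equal(matern_wasserstein_kernel(W = 2, sigma2 = 1, kappa = 2,
                                         rho = 1.5),
               (1 + sqrt(3)) * exp(-sqrt(3)), tolerance = 1e-12)
  # closed forms agree with the Bessel-function route
  for (rho in c(0.5, 1.5, 2.5)) {
    W <- c(0.3, 1, 4)
    r <- sqrt(2 * rho) * W / 1.3
    bess <- 2^(1 - rho) / gamma(rho) * r^rho * besselK(r, rho)
    expect_equal(matern_wasserstein_kernel(W = W, kappa = 1.3, rho = rho),
                 bess, tolerance = 1e-10)
  }
  # values in (0, sigma2], decreasing in W
  ks <- matern_wasserstein_kernel(W = seq(0, 5, by = 0.25), sigma2 = 1.5)
  expect_true(all(ks > 0 & ks <= 1.5))
  expect_true(all(diff(ks) < 0))
})

test_that("Gram matrices are symmetric and PSD after jitter", {
  set.seed(4)
  pts <- replicate(12, random_point(), simplify = FALSE)
  K <- gram_matrix(pts, sigma2 = 1, kappa = 1)  # default rho = 1/2
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  K1 <- gram_matrix(pts[1], sigma2 = 2)
  expect_equal(dim(K1), c(1, 1))
  expect_equal(K1[1, 1], 2 + 1e-8 * 2)
})

test_that("GP posterior interpolates, reverts to the prior, matches a
           hand-computed solve", {
  pts <- list(distribution_point(tau_m_E = gamma_spec(15, 0)),
              distribution_point(tau_m_E = gamma_spec(20, 0)),
              distribution_point(tau_m_E = gamma_spec(30, 0)))
  y <- c(0.2, 0.7, 0.4)
  surr <- list(points = pts, values = y, sigma2 = 1, kappa = 0.5,
               rho = 1.5, noise = 0, bounds = default_bounds())
  # noiseless interpolation at a training point
  post <- gp_posterior(surr, pts[[2]])
  expect_equal(post$mean, 0.7, tolerance = 1e-6)
  expect_lte(post$variance, 1e-8)
  # far query reverts to the prior mean and variance
  far <- distribution_point(tau_m_E = gamma_spec(39.9, 0),
                            W_scale = 19.9, lambda_conn = 7.9)
  post_far <- gp_posterior(surr, far)
  expect_equal(post_far$mean, mean(y), tolerance = 0.05)
  expect_equal(post_far$variance, 1, tolerance = 0.05)

  # independent 3x3 linear-algebra oracle
  q <- distribution_point(tau_m_E = gamma_spec(18, 0))
  kfun <- function(a, b) matern_wasserstein_kernel(
    W = distribution_distance(a, b), sigma2 = 1, kappa = 0.5, rho = 1.5)
  K <- outer(1:3, 1:3, Vectorize(function(i, j) kfun(pts[[i]], pts[[j]])))
  K <- K + diag(1e-8, 3)
  kq <- vapply(pts, kfun, numeric(1), b = q)
  mu0 <- mean(y)
  expect_equal(gp_posterior(surr, q)$mean,
               mu0 + drop(kq %*% solve(K, y - mu0)), tolerance = 1e-10)
  expect_equal(gp_posterior(surr, q)$variance,
               1 - drop(kq %*% solve(K, kq)), tolerance = 1e-8)
})

test_that("expected improvement matches its formula and stays >= 0", {
  expect_equal(expected_improvement(1, 0, 2), 0)  # sd 0, no improvement
  expect_equal(expected_improvement(3, 0, 2), 1)
  s <- 0.8
  expect_equal(expected_improvement(2, s, 2), s * dnorm(0))
  set.seed(5)
  ei <- expected_improvement(rnorm(50), abs(rnorm(50)), rnorm(50))
  expect_true(all(ei >= 0))
})

test_that("the BO loop improves monotonically and is reproducible", {
  target <- distribution_point(tau_m_E = gamma_spec(31, 0.5),
                               tau_m_I = gamma_spec(7, 0.5))
  obj <- function(p) -distribution_distance(p, target)
  res <- bo_loop(obj, free = c("tau_m_E.mean", "tau_m_I.mean"),
                 budget = 18, n_init = 6, pool_size = 64, seed = 1)
  expect_true(all(diff(res$history$best_so_far) >= 0))
  res2 <- bo_loop(obj, free = c("tau_m_E.mean", "tau_m_I.mean"),
                  budget = 18, n_init = 6, pool_size = 64, seed = 1)
  expect_identical(res$history, res2$history)
  # a failing objective is absorbed, not fatal
  flaky <- function(p) if (p$scalars$W_scale > 10) stop("boom") else
    -distribution_distance(p, target)
  res3 <- bo_loop(flaky, free = "W_scale", budget = 8, n_init = 4,
                  pool_size = 32, seed = 2)
  expect_equal(nrow(res3$history), 8)
  # GP posterior variance never exceeds prior sigma2 + noise
  surr <- hrsnn:::fit_surrogate(
    replicate(6, random_point(), simplify = FALSE),
    runif(6), default_bounds(), rho = 1.5, noise = 1e-6)
  v <- hrsnn:::gp_posterior_batch(
    surr, replicate(5, random_point(), simplify = FALSE))$variance
  expect_true(all(v <= surr$sigma2 + surr$noise + 1e-9))
})
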