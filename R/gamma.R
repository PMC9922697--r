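#' Gamma distribution specification in (mean, CV) form
#'
#' Heterogeneous neuron and synapse parameters are drawn from gamma
#' distributions. Rather than the usual (shape, scale) pair, a
#' specification carries the mean and the coefficient of variation
#' (CV = sd/mean): switching a parameter between homogeneous and
#' heterogeneous is then a single change of CV while the mean -- the
#' quantity compared across ablations -- stays put. Internally
#' shape = 1/CV^2 and scale = mean * CV^2, so shape * scale = mean.
#' CV = 0 denotes the degenerate distribution: every draw equals the
#' mean exactly.
#'
#' @param mean positive mean of the distribution (units of the target
#'   parameter).
#' @param cv non-negative coefficient of variation (dimensionless).
#' @return An object of class `gamma_spec`.
#' @examples
#' sample_gamma(gamma_spec(20, 0.5), 5, seed = 1)
#' sample_gamma(gamma_spec(20, 0), 3, seed = 1)  # degenerate: all 20
#' @export
gamma_spec <- function(mean, cv = 0) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("gamma_spec: 'mean' must be a single positive number", call. = FALSE)
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0)
    stop("gamma_spec: 'cv' must be a single non-negative number", call. = FALSE)
  structure(list(mean = mean, cv = cv), class = "gamma_spec")
}

#' @export
print.gamma_spec <- function(x, ...) {
  cat(sprintf("<gamma_spec mean=%g cv=%g>\n", x$mean, x$cv))
  invisible(x)
}

is_gamma_spec <- function(x) inherits(x, "gamma_spec")

as_gamma_spec <- function(x, what = "parameter") {
  if (is_gamma_spec(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(gamma_spec(x, 0))
  if (is.list(x) && !is.null(x$mean)) return(gamma_spec(x$mean, x$cv %||% 0))
  stop(sprintf("cannot interpret %s as a gamma_spec", what), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw samples from a gamma specification
#'
#' @param spec a [gamma_spec()].
#' @param n number of draws.
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return Numeric vector of length `n`. With `cv = 0` all values equal
#'   `spec$mean`.
#' @export
sample_gamma <- function(spec, n, seed = NULL) {
  spec <- as_gamma_spec(spec)
  n <- as.integer(n)
  if (n < 0L) stop("sample_gamma: n must be >= 0", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (spec$cv == 0) return(rep(spec$mean, n))
  draw <- function() {
    shape <- 1 / spec$cv^2
    rgamma(n, shape = shape, scale = spec$mean * spec$cv^2)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Gamma quantile function of a spec at probabilities u (point mass when CV=0).
quantile_gamma <- function(spec, u) {
  spec <- as_gamma_spec(spec)
  if (spec$cv == 0) return(rep(spec$mean, length(u)))
  shape <- 1 / spec$cv^2
  qgamma(u, shape = shape, scale = spec$mean * spec$cv^2)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
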