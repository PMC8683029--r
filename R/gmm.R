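#' Fit a univariate Gaussian mixture by expectation-maximization
#'
#' Fits \eqn{p(x) = \sum_{i=1}^K \phi_i N(x \mid \mu_i, \sigma_i)} with
#' \eqn{\sum \phi_i = 1} to a sample of collective-variable values.  This is
#' the density whose (scaled) value becomes the adaptive bias potential, so
#' the fitter is deliberately plain and fully reproducible: seeded
#' k-means-style initialization, standard EM updates, convergence on the
#' relative log-likelihood change, and a variance floor of `var_floor_frac`
#' times the sample range on every \eqn{\sigma_i} so no component can
#' collapse onto a single point.  Components are reported in increasing order
#' of their means.
#'
#' A note on notation: \eqn{\sigma_i} here is the component *standard
#' deviation* (it appears as \eqn{1/(\sigma_i \sqrt{2\pi})} in the density),
#' even though mixture parameters are often loosely called "variances".
#'
#' @param samples numeric vector of CV values (at least `10 * K`, all finite).
#' @param K number of components (default 3).
#' @param seed integer seed for the initialization (restored afterwards, so
#'   fitting inside a running campaign does not perturb its RNG stream).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param var_floor_frac floor on \eqn{\sigma_i} as a fraction of the sample
#'   range.
#' @param init optional explicit initialization: a list (or `gmm_model`) with
#'   `weights`, `means`, `sds` of length `K`.  Used by the adaptive bias
#'   update to warm-start each refit from the previous interval's model,
#'   which keeps consecutive bias curves on the same EM solution branch;
#'   when absent, initialization is a seeded k-means partition.
#' @return an object of class `gmm_model` with elements `K`, `weights`,
#'   `means`, `sds`, `loglik`, `loglik_trace`, `n_samples`, `iterations`,
#'   `converged`, `seed`.
#' @export
fit_gmm <- function(samples, K = 3L, seed = 1L, tol = 1e-6, max_iter = 500L,
                    var_floor_frac = 1e-3, init = NULL) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("fit_gmm: samples must be finite")
  n <- length(samples)
  K <- as.integer(K)
  if (n < 10L * K)
    stop("fit_gmm: need at least ", 10L * K, " samples for K = ", K,
         " (have ", n, "); extend the sampling interval")
  rng <- diff(range(samples))
  if (rng == 0) {
    # degenerate all-equal input: single effective component, floored width
    sd0 <- max(abs(samples[1]) * 1e-8, 1e-8)
    return(new_gmm(K, c(1, rep(0, K - 1)), rep(samples[1], K), rep(sd0, K),
                   loglik = sum(dnorm(samples, samples[1], sd0, log = TRUE)),
                   trace = numeric(), n = n, iter = 0L, converged = TRUE,
                   seed = seed))
  }
  floor_sd <- max(var_floor_frac * rng, 1e-12)

  if (!is.null(init)) {
    stopifnot(length(init$weights) == K, length(init$means) == K,
              length(init$sds) == K)
    init <- list(weights = as.numeric(init$weights) / sum(init$weights),
                 means = as.numeric(init$means),
                 sds = pmax(as.numeric(init$sds), floor_sd))
  } else init <- with_seed(seed, {
    if (length(unique(samples)) >= K) {
      km <- kmeans(samples, centers = K, nstart = 5, iter.max = 50)
      list(means = as.numeric(km$centers),
           weights = as.numeric(km$size) / n,
           sds = vapply(seq_len(K), function(k) {
             s <- sd(samples[km$cluster == k])
             if (!is.finite(s) || s < floor_sd) floor_sd else s
           }, 0))
    } else {
      qs <- stats::quantile(samples, probs = (seq_len(K) - 0.5) / K,
                            names = FALSE)
      list(means = qs, weights = rep(1 / K, K),
           sds = rep(max(sd(samples), floor_sd), K))
    }
  })
  ord <- order(init$means)
  em <- cpp_gmm_em(samples, init$weights[ord], init$means[ord],
                   init$sds[ord], floor_sd, tol, as.integer(max_iter))
  ord <- order(em$means)
  new_gmm(K, em$weights[ord] / sum(em$weights), em$means[ord], em$sds[ord],
          loglik = em$trace[length(em$trace)], trace = em$trace, n = n,
          iter = em$iterations, converged = em$converged, seed = seed)
}

new_gmm <- function(K, weights, means, sds, loglik = NA_real_,
                    trace = numeric(), n = NA_integer_, iter = NA_integer_,
                    converged = NA, seed = NA_integer_) {
  stopifnot(length(weights) == K, length(means) == K, length(sds) == K,
            all(weights >= 0), abs(sum(weights) - 1) < 1e-12, all(sds > 0))
  structure(list(K = as.integer(K), weights = as.numeric(weights),
                 means = as.numeric(means), sds = as.numeric(sds),
                 loglik = loglik, loglik_trace = trace,
                 n_samples = n, iterations = iter, converged = converged,
                 seed = seed),
            class = "gmm_model")
}

#' Construct a Gaussian-mixture model from explicit parameters
#'
#' @param weights,means,sds component parameters; weights must sum to 1.
#' @return a `gmm_model`.
#' @export
gmm_model <- function(weights, means, sds) {
  new_gmm(length(weights), weights / sum(weights), means, sds)
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> K=%d (n=%s, loglik=%s)\n", x$K,
              format(x$n_samples), format(x$loglik, digits = 6)))
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

#' Mixture density and its derivative
#'
#' `gmm_density` evaluates
#' \eqn{p(x) = \sum_i \phi_i \exp(-(x-\mu_i)^2/2\sigma_i^2)/(\sigma_i\sqrt{2\pi})};
#' `gmm_density_derivative` evaluates
#' \eqn{p'(x) = -\sum_i \phi_i N(x\mid\mu_i,\sigma_i)(x-\mu_i)/\sigma_i^2},
#' the ingredient of the bias force.
#'
#' @param model a `gmm_model`.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of densities (strictly positive) or slopes.
#' @export
gmm_density <- function(model, x) {
  out <- numeric(length(x))
  for (k in seq_len(model$K))
    out <- out + model$weights[k] * dnorm(x, model$means[k], model$sds[k])
  out
}

#' @rdname gmm_density
#' @export
gmm_density_derivative <- function(model, x) {
  out <- numeric(length(x))
  for (k in seq_len(model$K))
    out <- out - model$weights[k] * dnorm(x, model$means[k], model$sds[k]) *
      (x - model$means[k]) / model$sds[k]^2
  out
}

#' Serialize / restore a mixture model as a JSON-ready record
#'
#' @param model a `gmm_model`.
#' @return `gmm_to_list`: plain list (K, weights, means, sds, fit metadata);
#'   `gmm_from_list`: the reconstructed `gmm_model`.
#' @export
gmm_to_list <- function(model) {
  list(K = model$K, weights = model$weights, means = model$means,
       sds = model$sds, n_samples = model$n_samples,
       loglik = model$loglik, seed = model$seed)
}

#' @rdname gmm_to_list
#' @param record a list as produced by `gmm_to_list`.
#' @export
gmm_from_list <- function(record) {
  new_gmm(as.integer(record$K),
          as.numeric(unlist(record$weights)),
          as.numeric(unlist(record$means)),
          as.numeric(unlist(record$sds)),
          loglik = as.numeric(record$loglik %||% NA_real_),
          n = record$n_samples %||% NA_integer_,
          seed = record$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
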