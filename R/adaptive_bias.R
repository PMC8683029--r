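#' Per-replica adaptive bias state
#'
#' Replica `r` carries the bias \eqn{B_r(CV) = (r-1)\,\Delta\, p(x)} summed
#' over CVs, where \eqn{p} is the Gaussian-mixture density most recently
#' fitted to the pooled CV samples of all replicas.  Replica 1 (the
#' *reference* replica) always has identically zero bias, so its samples
#' follow the unbiased Boltzmann distribution; the increment \eqn{\Delta}
#' (default 4, in the system's energy units) sets the bias ladder spacing.
#' During the first, unbiased interval `models` is `NULL`.
#'
#' @param replica_index replica number `r` (1-based; 1 = reference).
#' @param increment bias increment \eqn{\Delta} (>= 0), energy units.
#' @param models `NULL`, or a named list with one [gmm_model] per CV.
#' @param interval_index index of the interval this bias is current for
#'   (0 = initial unbiased interval).
#' @return an object of class `bias_state`.
#' @export
bias_state <- function(replica_index, increment = 4, models = NULL,
                       interval_index = 0L) {
  stopifnot(replica_index >= 1, increment >= 0)
  if (!is.null(models))
    stopifnot(all(vapply(models, inherits, TRUE, "gmm_model")))
  structure(list(replica_index = as.integer(replica_index),
                 increment = increment, models = models,
                 interval_index = as.integer(interval_index)),
            class = "bias_state")
}

#' @export
print.bias_state <- function(x, ...) {
  cat(sprintf("<bias_state> replica %d, increment %g, scale %g, interval %d, %s\n",
              x$replica_index, x$increment, bias_scale(x), x$interval_index,
              if (is.null(x$models)) "no models (unbiased interval)"
              else paste0(length(x$models), " CV model(s)")))
  invisible(x)
}

#' Bias scale factor of a replica
#'
#' @param bias a [bias_state()].
#' @return \eqn{(r - 1)\,\Delta}.
#' @export
bias_scale <- function(bias) (bias$replica_index - 1) * bias$increment

#' Bias energy at given CV values
#'
#' \eqn{\sum_{cv} (r-1)\,\Delta\, p_{cv}(x_{cv})}; identically zero for the
#' reference replica and during the unbiased first interval.
#'
#' @param bias a [bias_state()].
#' @param cv_values numeric vector, one value per CV (order matching
#'   `bias$models`).
#' @return scalar bias energy (>= 0).
#' @export
bias_energy <- function(bias, cv_values) {
  s <- bias_scale(bias)
  if (s == 0 || bias$interval_index == 0L) return(0)
  if (is.null(bias$models))
    stop("bias_energy: replica ", bias$replica_index,
         " has no mixture models after the unbiased interval")
  if (length(cv_values) != length(bias$models))
    stop("bias_energy: expected ", length(bias$models), " CV value(s)")
  s * sum(vapply(seq_along(bias$models), function(i)
    gmm_density(bias$models[[i]], cv_values[i]), 0))
}

#' Bias forces on all particles
#'
#' Chain rule of the bias through each CV:
#' \eqn{F = -\sum_{cv} (r-1)\,\Delta\, p'_{cv}(x_{cv})\, \nabla x_{cv}}.
#' A CV at singular geometry (COM distance below tolerance) contributes no
#' force for that step (a warning is emitted).
#'
#' @param bias a [bias_state()].
#' @param coordinates `n x dim` matrix.
#' @param cvs list of [cv_definition()]s matching `bias$models`.
#' @return `n x dim` force matrix.
#' @export
bias_forces <- function(bias, coordinates, cvs) {
  coordinates <- as.matrix(coordinates)
  f <- matrix(0, nrow(coordinates), ncol(coordinates))
  s <- bias_scale(bias)
  if (s == 0 || bias$interval_index == 0L || is.null(bias$models)) return(f)
  if (length(cvs) != length(bias$models))
    stop("bias_forces: CV list and model list differ in length")
  for (i in seq_along(cvs)) {
    v <- compute_cv(coordinates, cvs[[i]])
    g <- cv_gradient(coordinates, cvs[[i]])
    if (isTRUE(attr(g, "singular"))) {
      warning("bias_forces: CV '", cvs[[i]]$name,
              "' is singular; its force contribution is dropped")
      next
    }
    f <- f - s * gmm_density_derivative(bias$models[[i]], v) * g
  }
  f
}

#' Refit the bias from pooled replica samples (sliding window)
#'
#' Implements the interval-cycle update: the CV samples of *all* replicas
#' over the last `window` intervals are pooled (unweighted, as sampled) and a
#' fresh `K`-component mixture is fitted per CV; every replica then receives
#' the same models, scaled by its own \eqn{(r-1)\,\Delta}.  If any CV has
#' fewer than `10 K` samples the previous bias states are retained and a
#' warning is emitted.
#'
#' @param history data frame of CV samples with columns `interval`, `replica`
#'   and one column per CV name.
#' @param cvs list of [cv_definition()]s.
#' @param K mixture components per CV (default 3).
#' @param increment bias increment \eqn{\Delta} (default 4).
#' @param n_replicas number of replicas.
#' @param window sliding-window length in intervals (default 10).
#' @param seed integer seed for the mixture fits.
#' @param previous optional list of current [bias_state()]s, returned
#'   unchanged (with a warning) when samples are insufficient.
#' @param max_fit_samples cap on the number of pooled samples handed to the
#'   mixture fit; larger pools are evenly strided down to this size.
#'   Consecutive saved samples are strongly autocorrelated, so the thinned
#'   pool carries essentially the same information at a fraction of the fit
#'   cost.
#' @return list of `n_replicas` [bias_state()]s for the next interval.
#' @export
update_bias <- function(history, cvs, K = 3L, increment = 4,
                        n_replicas = 8L, window = 10L, seed = 1L,
                        previous = NULL, max_fit_samples = 5000L) {
  cv_names <- vapply(cvs, `[[`, "", "name")
  if (!nrow(history) || !all(cv_names %in% names(history)))
    stop("update_bias: history lacks CV columns ",
         paste(setdiff(cv_names, names(history)), collapse = ", "))
  cur <- max(history$interval)
  win <- history[history$interval > cur - window, , drop = FALSE]
  next_interval <- cur + 1L
  if (any(vapply(cv_names, function(nm)
    sum(is.finite(win[[nm]])) < 10L * K, TRUE))) {
    warning("update_bias: fewer than ", 10L * K,
            " samples for at least one CV; previous bias retained")
    if (!is.null(previous))
      return(lapply(previous, function(b) {
        b$interval_index <- next_interval
        b
      }))
    return(lapply(seq_len(n_replicas), function(r)
      bias_state(r, increment, NULL, 0L)))
  }
  prev_models <- if (!is.null(previous)) previous[[length(previous)]]$models
  models <- lapply(seq_along(cvs), function(i) {
    smp <- win[[cv_names[i]]]
    if (length(smp) > max_fit_samples)
      smp <- smp[seq(1L, length(smp),
                     length.out = as.integer(max_fit_samples))]
    # warm-start from the previous interval's model (when one exists and has
    # the same K) so consecutive refits stay on one EM solution branch
    init <- prev_models[[cv_names[i]]]
    if (!is.null(init) && init$K != K) init <- NULL
    fit_gmm(smp, K = K, seed = seed + i - 1L, init = init)
  })
  names(models) <- cv_names
  lapply(seq_len(n_replicas), function(r)
    bias_state(r, increment, models, next_interval))
}
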