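#' Desk-scale simulable systems
#'
#' A `system_spec` bundles everything needed to propagate Langevin dynamics on
#' a small model system: particle count and dimensionality, masses, a named
#' potential with its parameters, the thermodynamic state (`kT`), the Langevin
#' friction coefficient and the integration time step, plus initial
#' coordinates and (for bead models) named particle groups for building
#' collective variables.  All quantities are in reduced units (`kT = 1` by
#' default).
#'
#' @param n_particles number of particles.
#' @param dim spatial dimension (1--3).
#' @param masses numeric vector of per-particle masses (> 0).
#' @param potential named list describing the potential (`type` plus
#'   parameters), consumed by the compiled core.
#' @param kT thermal energy (> 0).
#' @param friction Langevin friction coefficient (1/time).
#' @param dt integration time step (> 0).
#' @param x0 initial coordinates, an `n_particles x dim` matrix.
#' @param groups named list of particle-index vectors (1-based) usable as CV
#'   groups.
#' @param name human-readable system name.
#' @return an object of class `system_spec`.
#' @export
system_spec <- function(n_particles, dim, masses, potential, kT = 1,
                        friction = 1, dt = 0.01, x0, groups = list(),
                        name = potential$type) {
  stopifnot(n_particles >= 1, dim >= 1, dim <= 3,
            length(masses) == n_particles, all(masses > 0),
            kT > 0, friction >= 0, dt > 0)
  x0 <- as.matrix(x0)
  stopifnot(nrow(x0) == n_particles, ncol(x0) == dim, all(is.finite(x0)))
  spec <- structure(
    list(n_particles = n_particles, dim = dim, masses = as.numeric(masses),
         potential = potential, kT = kT, friction = friction, dt = dt,
         x0 = x0, groups = groups, name = name),
    class = "system_spec")
  u0 <- potential_energy(x0, spec)
  if (!is.finite(u0))
    stop("potential energy not finite at the initial coordinates")
  spec
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf("<system_spec '%s'> %d particle(s) in %dD, kT=%g, dt=%g, friction=%g\n",
              x$name, x$n_particles, x$dim, x$kT, x$dt, x$friction))
  if (length(x$groups))
    cat("  groups:", paste(sprintf("%s(%d)", names(x$groups),
                                   lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' One-dimensional harmonic well
#'
#' Single particle with potential \eqn{U(x) = k x^2 / 2}.  The equilibrium
#' variance of \eqn{x} is `kT / k`, which makes this the standard integrator
#' check.
#'
#' @param k force constant (> 0).
#' @param kT,friction,dt thermodynamic and integrator parameters.
#' @param x0 initial position.
#' @return a `system_spec`.
#' @export
make_harmonic <- function(k = 1, kT = 1, friction = 1, dt = 0.01, x0 = 0) {
  stopifnot(k > 0)
  system_spec(1, 1, 1, list(type = "harmonic", k = k), kT, friction, dt,
              matrix(x0, 1, 1), name = "harmonic")
}

#' One-dimensional symmetric double well
#'
#' Single particle with the quartic potential
#' \eqn{U(x) = h ((x/a)^2 - 1)^2}: minima at \eqn{x = \pm a} with
#' \eqn{U(\pm a) = 0} and barrier \eqn{U(0) = h}.  The barrier height in units
#' of `kT` controls how metastable the two wells are; this is the package's
#' reference benchmark for the adaptive sampler.
#'
#' @param barrier_height barrier `h` (> 0), in energy units.
#' @param well_separation half-distance `a` between the minima (> 0).
#' @param kT,friction,dt thermodynamic and integrator parameters.
#' @param x0 initial position (default: the left minimum, `-a`).
#' @return a `system_spec`.
#' @export
make_double_well <- function(barrier_height, well_separation, kT = 1,
                             friction = 1, dt = 0.01,
                             x0 = -well_separation) {
  if (!is.numeric(barrier_height) || barrier_height <= 0)
    stop("barrier_height must be positive")
  if (!is.numeric(well_separation) || well_separation <= 0)
    stop("well_separation must be positive")
  system_spec(1, 1, 1,
              list(type = "double_well", h = barrier_height,
                   a = well_separation),
              kT, friction, dt, matrix(x0, 1, 1), name = "double_well")
}

#' Mueller-Brown surface
#'
#' Single particle in 2D on the standard Mueller-Brown potential (sum of four
#' anisotropic Gaussians), scaled by `scale` so its barriers can be set
#' relative to `kT`.  At the default `scale = 0.05` the lowest saddle sits
#' roughly 5 `kT` above the deepest minimum for `kT = 1`.
#'
#' @param scale multiplicative energy scale applied to the canonical surface.
#' @param kT,friction,dt thermodynamic and integrator parameters.
#' @param x0 initial position (default: near the deepest minimum).
#' @return a `system_spec`.
#' @export
make_muller_brown <- function(scale = 0.05, kT = 1, friction = 1, dt = 0.005,
                              x0 = c(-0.558, 1.442)) {
  stopifnot(scale > 0)
  system_spec(1, 2, 1, list(type = "muller_brown", scale = scale),
              kT, friction, dt, matrix(x0, 1, 2), name = "muller_brown")
}

#' Coarse-grained domain bead model
#'
#' Builds a system of `n_domains` compact bead clusters ("domains").  Beads
#' within a domain are joined by stiff harmonic bonds (all intra-domain pairs,
#' rest lengths taken from the constructed geometry, so the start is
#' strain-free).  Consecutive domain pairs interact through a double-well
#' potential in their center-of-mass distance,
#' \eqn{U(d) = h (((d - c)/w)^2 - 1)^2} with minima at \eqn{c - w} and
#' \eqn{c + w}, giving the inter-domain distance two metastable states --- a
#' minimal stand-in for the open/closed arrangements of multi-domain proteins.
#' Domain membership is recorded in `groups` (`domain_1`, `domain_2`, ...)
#' for collective-variable construction.
#'
#' @param n_domains number of domains (>= 2).
#' @param beads_per_domain beads per domain (>= 2).
#' @param inter_domain list with elements `barrier` (well depth-to-barrier
#'   height `h`), `d_low` and `d_high` (the two metastable COM distances).
#' @param bond_k intra-domain bond force constant.
#' @param jitter uniform jitter half-width applied to the lattice placement.
#' @param seed integer seed; construction is deterministic given `seed`.
#' @param kT,friction,dt thermodynamic and integrator parameters.
#' @param min_separation minimum allowed initial bead-bead distance; closer
#'   placements are rejected with an error.
#' @return a `system_spec` with `groups` set.
#' @export
make_domain_bead_model <- function(n_domains = 2, beads_per_domain = 4,
                                   inter_domain = list(barrier = 3,
                                                       d_low = 4, d_high = 8),
                                   bond_k = 100, jitter = 0.05, seed = 1,
                                   kT = 1, friction = 1, dt = 0.005,
                                   min_separation = 0.3) {
  stopifnot(n_domains >= 2, beads_per_domain >= 2)
  inter <- modifyList(list(barrier = 3, d_low = 4, d_high = 8), inter_domain)
  stopifnot(inter$barrier > 0, inter$d_low > 0, inter$d_high > inter$d_low)
  dim <- 3
  n <- n_domains * beads_per_domain
  cc <- (inter$d_low + inter$d_high) / 2   # double-well center
  ww <- (inter$d_high - inter$d_low) / 2   # half-separation
  # bead lattice around each domain center (centers spaced at d_low along x)
  x0 <- with_seed(seed, {
    side <- ceiling(beads_per_domain^(1 / 3))
    grid <- as.matrix(expand.grid(seq_len(side), seq_len(side), seq_len(side)))
    grid <- grid[seq_len(beads_per_domain), , drop = FALSE]
    grid <- sweep(grid, 2, colMeans(grid))
    out <- matrix(0, n, dim)
    for (g in seq_len(n_domains)) {
      center <- c((g - 1) * inter$d_low, 0, 0)
      rows <- (g - 1) * beads_per_domain + seq_len(beads_per_domain)
      jit <- matrix(runif(beads_per_domain * dim, -jitter, jitter),
                    beads_per_domain, dim)
      out[rows, ] <- sweep(grid + jit, 2, center, "+")
    }
    out
  })
  dmin <- min(dist(x0))
  if (dmin < min_separation)
    stop(sprintf("initial bead placement too dense: minimum pair distance %.3g < %.3g",
                 dmin, min_separation))
  groups <- lapply(seq_len(n_domains), function(g)
    (g - 1) * beads_per_domain + seq_len(beads_per_domain))
  names(groups) <- paste0("domain_", seq_len(n_domains))
  # all intra-domain pairs bonded at their constructed distance
  bonds <- do.call(rbind, lapply(groups, function(idx) {
    pr <- t(utils::combn(idx, 2))
    r0 <- sqrt(rowSums((x0[pr[, 1], , drop = FALSE] -
                        x0[pr[, 2], , drop = FALSE])^2))
    cbind(pr, r0, bond_k)
  }))
  masses <- rep(1, n)
  gw <- lapply(groups, function(idx) masses[idx] / sum(masses[idx]))
  pairs <- cbind(seq_len(n_domains - 1), 2:n_domains,
                 inter$barrier, cc, ww)
  pot <- list(type = "bead_model", bonds = unname(bonds),
              groups = lapply(groups, as.integer),
              group_weights = gw, pairs = unname(pairs))
  system_spec(n, dim, masses, pot, kT, friction, dt, x0, groups = groups,
              name = "bead_model")
}

#' Potential energy and forces of a configuration
#'
#' @param coords `n x dim` coordinate matrix (a vector is treated as a single
#'   row for 1-particle systems).
#' @param spec a [system_spec()].
#' @return `potential_energy`: scalar energy; `potential_force`: `n x dim`
#'   matrix of forces (\eqn{-\nabla U}).
#' @export
potential_energy <- function(coords, spec) {
  coords <- coerce_coords(coords, spec)
  cpp_energy_force(coords, spec$potential)$energy
}

#' @rdname potential_energy
#' @export
potential_force <- function(coords, spec) {
  coords <- coerce_coords(coords, spec)
  cpp_energy_force(coords, spec$potential)$force
}

coerce_coords <- function(coords, spec) {
  if (!is.matrix(coords))
    coords <- matrix(coords, spec$n_particles, spec$dim, byrow = TRUE)
  stopifnot(nrow(coords) == spec$n_particles, ncol(coords) == spec$dim)
  coords
}

#' Trajectory frame
#'
#' A snapshot of one replica: step index, coordinates, the potential and bias
#' energies, and (carried along for exact restarts) the velocities.
#'
#' @param step_index integer step counter.
#' @param coordinates `n x dim` matrix.
#' @param potential_energy,bias_energy energies at this configuration.
#' @param velocities `n x dim` matrix (defaults to zero).
#' @return an object of class `md_frame`.
#' @export
md_frame <- function(step_index, coordinates, potential_energy = NA_real_,
                     bias_energy = 0, velocities = NULL) {
  coordinates <- as.matrix(coordinates)
  stopifnot(all(is.finite(coordinates)))
  if (is.null(velocities)) velocities <- coordinates * 0
  structure(list(step_index = step_index, coordinates = coordinates,
                 potential_energy = potential_energy,
                 bias_energy = bias_energy, velocities = velocities),
            class = "md_frame")
}

#' Advance a frame by Langevin dynamics
#'
#' BAOAB splitting integrator with an exact Ornstein-Uhlenbeck noise step; its
#' stationary distribution is the Boltzmann distribution at `spec$kT` for the
#' total energy (potential plus any bias implied by `extra_force`).  Randomness
#' is drawn from R's global RNG, so `set.seed()` gives bitwise-reproducible
#' trajectories.
#'
#' @param frame an [md_frame()].
#' @param spec a [system_spec()].
#' @param extra_force optional `n x dim` matrix of additional constant forces
#'   applied during the step(s) (zero when absent).
#' @param n_steps number of steps to advance (default 1).
#' @return the advanced `md_frame`.
#' @export
langevin_step <- function(frame, spec, extra_force = NULL, n_steps = 1L) {
  if (!is.null(extra_force)) {
    extra_force <- as.matrix(extra_force)
    stopifnot(identical(dim(extra_force), dim(frame$coordinates)))
    if (!all(is.finite(extra_force))) stop("non-finite extra_force")
  }
  res <- cpp_propagate(frame$coordinates, frame$velocities,
                       spec$masses, spec$potential,
                       list(), list(), 0, extra_force,
                       spec$kT, spec$friction, spec$dt,
                       as.integer(n_steps), as.integer(n_steps),
                       as.double(frame$step_index), FALSE)
  md_frame(frame$step_index + n_steps, res$coords,
           potential_energy = if (length(res$epot)) res$epot[length(res$epot)] else NA_real_,
           bias_energy = 0, velocities = res$vels)
}

#' Run plain (optionally biased) Langevin dynamics
#'
#' Propagates a single trajectory and records frames every `save_every` steps.
#' With `bias` and `cvs` supplied the run samples the biased ensemble of that
#' replica; otherwise it is plain MD.
#'
#' @param spec a [system_spec()].
#' @param n_steps total number of integration steps.
#' @param save_every save cadence in steps.
#' @param seed optional integer seed (calls `set.seed`); if `NULL` the current
#'   RNG state is used.
#' @param coords,velocities optional starting state (defaults: `spec$x0` and
#'   Maxwell-Boltzmann velocities).
#' @param cvs optional list of CV definitions to record (and bias).
#' @param bias optional [bias_state()] providing the mixture models and scale.
#' @param save_coords logical; keep full coordinate frames.
#' @return an object of class `md_trajectory`: `steps`, `epot`, `ebias`,
#'   `cv` (matrix, one column per CV), `coords` (array `n_saves x n x dim` if
#'   `save_coords`), and `final` (list with `coords`, `velocities`).
#' @export
langevin_run <- function(spec, n_steps, save_every = 10L, seed = NULL,
                         coords = NULL, velocities = NULL, cvs = NULL,
                         bias = NULL, save_coords = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(coords)) coords <- spec$x0
  coords <- coerce_coords(coords, spec)
  if (is.null(velocities))
    velocities <- matrix(rnorm(spec$n_particles * spec$dim) *
                           rep(sqrt(spec$kT / spec$masses), each = spec$dim),
                         spec$n_particles, spec$dim, byrow = TRUE)
  cvs_c <- if (is.null(cvs)) list() else lapply(cvs, cv_to_cpp)
  gmms <- if (is.null(bias) || is.null(bias$models)) {
    replicate(length(cvs_c), NULL, simplify = FALSE)
  } else {
    lapply(bias$models, function(m)
      list(weights = m$weights, means = m$means, sds = m$sds))
  }
  scale <- if (is.null(bias)) 0 else bias_scale(bias)
  res <- cpp_propagate(coords, velocities, spec$masses, spec$potential,
                       cvs_c, gmms, scale, NULL,
                       spec$kT, spec$friction, spec$dt,
                       as.integer(n_steps), as.integer(save_every), 0,
                       save_coords)
  cv <- res$cv
  if (length(cvs_c)) colnames(cv) <- vapply(cvs, `[[`, "", "name")
  out <- list(steps = res$steps, epot = res$epot, ebias = res$ebias, cv = cv,
              final = list(coords = res$coords, velocities = res$vels),
              spec = spec)
  if (save_coords)
    out$coords <- aperm(array(res$frames,
                              c(spec$dim, spec$n_particles,
                                length(res$steps))), c(3, 2, 1))
  structure(out, class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d saved frames of '%s' (last step %g)\n",
              length(x$steps), x$spec$name,
              if (length(x$steps)) x$steps[length(x$steps)] else 0))
  invisible(x)
}

#' Count transitions between the two wells of a symmetric double well
#'
#' Hysteresis (core-region) counting: a transition is recorded only when the
#' series moves from beyond `-core` to beyond `+core` or vice versa, which
#' suppresses barrier-top recrossing noise.
#'
#' @param x numeric series of positions (or a signed CV).
#' @param core half-width of the excluded central region (default half the
#'   well position is sensible; `core = 0` counts sign changes).
#' @return integer transition count.
#' @export
count_well_transitions <- function(x, core) {
  state <- 0L
  n <- 0L
  for (v in x) {
    if (v > core) {
      if (state == -1L) n <- n + 1L
      state <- 1L
    } else if (v < -core) {
      if (state == 1L) n <- n + 1L
      state <- -1L
    }
  }
  n
}

#' Analytic Boltzmann CDF of a 1D system
#'
#' Numerically normalizes \eqn{\exp(-U(x)/kT)} on a grid by trapezoidal
#' quadrature and returns the cumulative distribution as a monotone spline
#' function, suitable as the reference distribution of a Kolmogorov-Smirnov
#' test.
#'
#' @param spec a 1-particle, 1D [system_spec()].
#' @param lower,upper integration bounds (should enclose essentially all
#'   probability mass).
#' @param n_grid number of grid points.
#' @return a vectorized function `F(q)` returning the CDF.
#' @export
boltzmann_cdf <- function(spec, lower, upper, n_grid = 4001L) {
  stopifnot(spec$n_particles == 1, spec$dim == 1)
  xg <- seq(lower, upper, length.out = n_grid)
  u <- vapply(xg, function(v) potential_energy(matrix(v, 1, 1), spec), 0)
  w <- exp(-(u - min(u)) / spec$kT)
  cw <- cumsum((c(0, diff(xg))) * (w + c(w[1], head(w, -1))) / 2)
  cw <- cw / cw[length(cw)]
  f <- stats::splinefun(xg, cw, method = "hyman")
  function(q) pmin(1, pmax(0, f(pmin(upper, pmax(lower, q)))))
}
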