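# Shared fixtures, all generated in code.

# small two-domain bead system used across modules
tiny_bead <- function(seed = 1) {
  make_domain_bead_model(n_domains = 2, beads_per_domain = 4,
                         inter_domain = list(barrier = 3, d_low = 4,
                                             d_high = 8),
                         seed = seed)
}

bead_cv <- function(spec, name = "CV_1", a = "domain_1", b = "domain_2") {
  cv_definition(name,
                atom_group(a, spec$groups[[a]], spec$masses[spec$groups[[a]]]),
                atom_group(b, spec$groups[[b]], spec$masses[spec$groups[[b]]]))
}

# random thermally plausible bead configuration: short equilibration run
random_bead_state <- function(spec, seed) {
  tr <- langevin_run(spec, 400, save_every = 400, seed = seed)
  tr$final$coords
}

# three well-separated rigid templates + per-frame coordinate noise;
# families are blocked in frame order (family 1 frames first, etc.)
planted_conformers <- function(n_per_family = 250, n_particles = 12,
                               noise = 0.05, seed = 42) {
  with_seed2(seed, {
    templates <- lapply(1:3, function(k)
      matrix(rnorm(n_particles * 3, sd = 2), n_particles, 3))
    arr <- array(0, c(3 * n_per_family, n_particles, 3))
    for (k in 1:3)
      for (i in seq_len(n_per_family))
        arr[(k - 1) * n_per_family + i, , ] <-
          templates[[k]] + matrix(rnorm(n_particles * 3, sd = noise),
                                  n_particles, 3)
    arr
  })
}

# local seed helper for fixtures (mirrors the package-internal one)
with_seed2 <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# double-well campaign used by several analysis tests (kept small)
small_campaign <- function(barrier = 6, n_intervals = 25, seed = 7,
                           steps_per_interval = 4000) {
  spec <- make_double_well(barrier, 1)
  cvs <- list(cv_coordinate("CV_1"))
  sch <- schedule_config(n_replicas = 8,
                         steps_per_interval = steps_per_interval,
                         exchange_period = 80, save_period = 40,
                         n_intervals = n_intervals, window = 10, seed = seed)
  run_campaign(spec, cvs, sch)
}
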