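test_that("Boltzmann inversion recovers the harmonic free energy", {
  s <- make_harmonic(k = 1, kT = 1)
  tr <- langevin_run(s, 300000, save_every = 20, seed = 2, save_coords = TRUE)
  x <- tr$coords[, 1, 1]
  fep <- free_energy_profile(x, n_bins = 40, kT = 1, n_boot = 100, seed = 1)
  sel <- abs(fep$bin_center) <= 2 & !is.na(fep$dG)
  ref <- fep$bin_center[sel]^2 / 2
  # profiles are defined up to a constant: align offsets before comparing
  band <- pmax(fep$err[sel], 0.05)
  off <- stats::weighted.mean(fep$dG[sel] - ref, w = 1 / band^2)
  expect_true(all(abs(fep$dG[sel] - ref - off) <= 2 * band))
})

test_that("uniform samples give a flat profile within error", {
  x <- with_seed2(4, runif(20000, -1, 1))
  fep <- free_energy_profile(x, n_bins = 20, kT = 1, n_boot = 100, seed = 2)
  expect_true(all(abs(fep$dG) <= 3 * pmax(fep$err, 0.02) + 0.05))
  expect_equal(min(fep$dG, na.rm = TRUE), 0)
})

test_that("empty bins are masked, not infinite", {
  x <- c(with_seed2(1, rnorm(500, -3, .2)), with_seed2(2, rnorm(500, 3, .2)))
  fep <- free_energy_profile(x, n_bins = 30, kT = 1, n_boot = 50, seed = 3)
  expect_true(any(is.na(fep$dG)))
  expect_false(any(is.infinite(fep$dG), na.rm = TRUE))
})

test_that("profile differences are invariant to the anchoring constant", {
  x <- with_seed2(6, rnorm(5000))
  f1 <- free_energy_profile(x, n_bins = 20, kT = 1, n_boot = 10, seed = 1)
  f2 <- free_energy_profile(x, n_bins = 20, kT = 2, n_boot = 10, seed = 1)
  ok <- !is.na(f1$dG)
  d1 <- diff(f1$dG[ok]); d2 <- diff(f2$dG[ok])
  expect_equal(2 * d1, d2, tolerance = 1e-10)   # dG scales with kT only
})

test_that("RMSF is zero for a static trajectory", {
  arr <- array(rep(1:6, each = 4), c(4, 2, 3))
  expect_equal(rmsf(arr), c(0, 0))
  expect_error(rmsf(arr[1, , , drop = FALSE]), "2 frames")
})

test_that("RMSF of a densely sampled sine is sqrt(1/2)", {
  t <- seq(0, 2 * pi, length.out = 2001)[-2001]
  arr <- array(0, c(length(t), 2, 3))
  arr[, 1, 1] <- sin(t)
  arr[, 2, ] <- 5   # fixed particle
  r <- rmsf(arr)
  expect_equal(r[1], sqrt(0.5), tolerance = 1e-3)
  expect_equal(r[2], 0)
})

test_that("rigid-alignment RMSF is invariant under global rotation", {
  spec <- tiny_bead()
  tr <- langevin_run(spec, 4000, save_every = 100, seed = 8,
                     save_coords = TRUE)
  arr <- tr$coords
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- arr
  for (i in seq_len(dim(arr)[1])) rot[i, , ] <- arr[i, , ] %*% R
  expect_equal(rmsf(rot, "rigid"), rmsf(arr, "rigid"), tolerance = 1e-10)
})

test_that("best-fit RMSD agrees with an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(12)
  a <- matrix(rnorm(30), 10, 3)
  th <- 0.5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  b <- (a + matrix(rnorm(30, sd = 0.1), 10, 3)) %*% R + 3
  ours <- rmsd_fit(a, b)
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
  # superposing a rotated copy of itself gives ~0
  expect_lt(rmsd_fit(a, a %*% R + 7), 1e-10)
})

test_that("planted conformer families are recovered exactly", {
  arr <- planted_conformers(n_per_family = 250, noise = 0.05, seed = 42)
  cl <- cluster_frames(arr, eps = 1.25, min_samples = 4, frame_stride = 5,
                       sieve = 10, seed = 1)
  expect_equal(cl$n_clusters, 3)
  expect_equal(cl$n_noise, 0)
  expect_equal(sort(cl$populations), rep(1 / 3, 3), tolerance = 1e-12)
  # labels align with the planted block structure
  fam <- ceiling(cl$frame_indices / 250)
  expect_equal(length(unique(paste(fam, cl$labels))), 3)
})

test_that("fewer close frames than min_samples yield all noise", {
  base <- matrix(rnorm(36), 12, 3)
  arr <- array(0, c(3, 12, 3))
  for (i in 1:3) arr[i, , ] <- base + matrix(rnorm(36, sd = 0.01), 12, 3)
  cl <- cluster_frames(arr, eps = 1.25, min_samples = 4, frame_stride = 1,
                       sieve = 1, seed = 1)
  expect_equal(cl$n_clusters, 0)
  expect_equal(cl$n_noise, 3)
})

test_that("identical frames form a single full-population cluster", {
  base <- matrix(rnorm(36), 12, 3)
  arr <- array(0, c(40, 12, 3))
  for (i in 1:40) arr[i, , ] <- base
  cl <- cluster_frames(arr, frame_stride = 1, sieve = 4, seed = 2)
  expect_equal(cl$n_clusters, 1)
  expect_equal(cl$populations, 1)
  expect_equal(cl$n_noise, 0)
})

test_that("clustering is deterministic given the seed", {
  arr <- planted_conformers(n_per_family = 60, seed = 5)
  c1 <- cluster_frames(arr, frame_stride = 2, sieve = 5, seed = 9)
  c2 <- cluster_frames(arr, frame_stride = 2, sieve = 5, seed = 9)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$representatives, c2$representatives)
})

test_that("bias convergence drift is zero for identical snapshots", {
  mod <- gmm_to_list(gmm_model(c(0.5, 0.5), c(-1, 1), c(0.4, 0.4)))
  snaps <- lapply(1:4, function(i)
    list(interval = i, increment = 4, models = list(CV_1 = mod)))
  bc <- bias_convergence(snaps, "CV_1", seq(-3, 3, length.out = 200))
  expect_equal(bc$drift, rep(0, 3))
  expect_error(bias_convergence(snaps[1], "CV_1", 0:1), "at least 2")
})

test_that("campaign bias drift decays from early to late intervals", {
  camp <- small_campaign(barrier = 4, n_intervals = 24, seed = 23)
  grid <- seq(-2.5, 2.5, length.out = 200)
  bc <- bias_convergence(camp$bias_snapshots, "CV_1", grid)
  early <- median(bc$drift[seq_len(6)])
  late <- median(bc$drift[(nrow(bc) - 5):nrow(bc)])
  expect_lt(late, early)
})

test_that("bead-model RMSF: mobile domain exceeds internal rigidity", {
  spec <- tiny_bead()
  tr <- langevin_run(spec, 20000, save_every = 100, seed = 31,
                     save_coords = TRUE)
  r <- rmsf(tr$coords, alignment = "rigid")
  # inter-domain double well makes whole-domain motion the dominant mode:
  # every bead fluctuates more than the bond network alone would allow
  bond_scale <- sqrt(1 / 100)   # sd of a kT=1 oscillation on a k=100 bond
  expect_gt(mean(r), bond_scale)
})
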