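m1 <- gmm_model(1, 0, 1)   # standard normal "density" model

test_that("reference replica carries exactly zero bias and force", {
  b1 <- bias_state(1, 4, list(CV_1 = m1), 1L)
  expect_identical(bias_energy(b1, 0), 0)
  expect_identical(bias_energy(b1, 123), 0)
  spec <- make_double_well(6, 1)
  f <- bias_forces(b1, spec$x0, list(cv_coordinate("CV_1")))
  expect_equal(f, matrix(0, 1, 1))
})

test_that("bias energy is increment times density, linear in replica index", {
  b2 <- bias_state(2, 4, list(CV_1 = m1), 1L)
  expect_equal(bias_energy(b2, 0), 4 / sqrt(2 * pi), tolerance = 1e-9)
  expect_equal(bias_energy(b2, 0), 4 * 0.3989423, tolerance = 1e-6)
  b8 <- bias_state(8, 4, list(CV_1 = m1), 1L)
  for (x in c(-1, 0, 0.7))
    expect_equal(bias_energy(b8, x) / bias_energy(b2, x), 7, tolerance = 1e-12)
})

test_that("bias is additive over CVs", {
  ma <- gmm_model(c(0.6, 0.4), c(-1, 2), c(0.5, 0.8))
  mb <- gmm_model(1, 4, 0.6)
  b_both <- bias_state(3, 2, list(A = ma, B = mb), 1L)
  b_a <- bias_state(3, 2, list(A = ma), 1L)
  b_b <- bias_state(3, 2, list(B = mb), 1L)
  expect_equal(bias_energy(b_both, c(0.5, 3.8)),
               bias_energy(b_a, 0.5) + bias_energy(b_b, 3.8),
               tolerance = 1e-12)
})

test_that("missing models after the unbiased interval are an error", {
  b <- bias_state(2, 4, NULL, 1L)
  expect_error(bias_energy(b, 0), "no mixture models")
  b0 <- bias_state(2, 4, NULL, 0L)     # unbiased first interval is fine
  expect_identical(bias_energy(b0, 0), 0)
})

test_that("bias force pushes away from the density peak", {
  spec <- make_double_well(6, 1)
  cvs <- list(cv_coordinate("CV_1"))
  b <- bias_state(2, 4, list(CV_1 = gmm_model(1, -1, 0.3)), 1L)
  # particle to the right of the peak: pushed further right (positive force)
  f <- bias_forces(b, matrix(-0.6), cvs)
  expect_gt(f[1, 1], 0)
  # particle to the left of the peak: pushed further left
  f <- bias_forces(b, matrix(-1.4), cvs)
  expect_lt(f[1, 1], 0)
})

test_that("bias forces equal the negative gradient of the bias energy", {
  spec <- tiny_bead()
  cvs <- list(bead_cv(spec))
  mod <- gmm_model(c(0.5, 0.5), c(4, 8), c(0.7, 0.9))
  b <- bias_state(5, 4, list(CV_1 = mod), 2L)
  h <- 1e-6
  for (seed in 1:5) {
    x <- random_bead_state(spec, seed)
    f <- bias_forces(b, x, cvs)
    for (i in c(1, 4, 8)) {
      for (d in 1:3) {
        xp <- x; xp[i, d] <- xp[i, d] + h
        xm <- x; xm[i, d] <- xm[i, d] - h
        fd <- -(bias_energy(b, compute_cv(xp, cvs[[1]])) -
                  bias_energy(b, compute_cv(xm, cvs[[1]]))) / (2 * h)
        expect_equal(f[i, d], fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("compiled bias energy/force agrees with the R implementation", {
  spec <- tiny_bead()
  cv <- bead_cv(spec)
  mod <- gmm_model(c(0.3, 0.7), c(3.5, 7), c(0.6, 1.1))
  b <- bias_state(4, 4, list(CV_1 = mod), 1L)
  x <- random_bead_state(spec, seed = 17)
  cc <- ahremd:::cpp_energy_force(
    x, spec$potential, list(ahremd:::cv_to_cpp(cv)),
    list(list(weights = mod$weights, means = mod$means, sds = mod$sds)),
    bias_scale(b))
  expect_equal(cc$bias_energy, bias_energy(b, compute_cv(x, cv)),
               tolerance = 1e-10)
  expect_equal(cc$force, potential_force(x, spec) + bias_forces(b, x, list(cv)),
               tolerance = 1e-10)
})

test_that("update_bias fits pooled window samples and scales per replica", {
  set.seed(1)
  hist <- data.frame(interval = rep(0:4, each = 400),
                     replica = rep(1:8, 250),
                     CV_1 = rnorm(2000, 1.5, 0.4))
  cvs <- list(cv_coordinate("CV_1"))
  biases <- update_bias(hist, cvs, K = 3, increment = 4, n_replicas = 8,
                        window = 10, seed = 2)
  expect_length(biases, 8)
  expect_identical(bias_energy(biases[[1]], 1.5), 0)     # reference unbiased
  expect_gt(bias_energy(biases[[2]], 1.5), 0)
  # all replicas share the same models
  expect_identical(biases[[2]]$models, biases[[8]]$models)
  # unimodal pool: fitted mixture mean near the pooled sample mean
  mod <- biases[[2]]$models$CV_1
  expect_lt(abs(sum(mod$weights * mod$means) - mean(hist$CV_1)), 0.05)
  expect_equal(biases[[3]]$interval_index, 5L)
})

test_that("sliding window: old samples have no influence", {
  set.seed(2)
  old <- data.frame(interval = rep(0:1, each = 200), replica = 1,
                    CV_1 = rnorm(400, -3, 0.2))
  new <- data.frame(interval = rep(2:11, each = 200), replica = 1,
                    CV_1 = rnorm(2000, 2, 0.5))
  full <- rbind(old, new)
  b_full <- update_bias(full, list(cv_coordinate("CV_1")), window = 10, seed = 3)
  b_new <- update_bias(new, list(cv_coordinate("CV_1")), window = 10, seed = 3)
  expect_equal(b_full[[2]]$models$CV_1$means, b_new[[2]]$models$CV_1$means)
  expect_equal(b_full[[2]]$models$CV_1$weights, b_new[[2]]$models$CV_1$weights)
})

test_that("insufficient samples retain the previous bias with a warning", {
  prev <- list(bias_state(1, 4, list(CV_1 = m1), 3L),
               bias_state(2, 4, list(CV_1 = m1), 3L))
  hist <- data.frame(interval = 3, replica = 1, CV_1 = rnorm(10))
  expect_warning(
    out <- update_bias(hist, list(cv_coordinate("CV_1")), K = 3,
                       n_replicas = 2, previous = prev),
    "previous bias retained")
  expect_identical(out[[2]]$models, prev[[2]]$models)
  expect_equal(out[[2]]$interval_index, 4L)
})
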