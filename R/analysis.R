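#' Free-energy profile by Boltzmann inversion
#'
#' Histograms reference-replica CV samples and inverts the density,
#' \eqn{\Delta G(\mathrm{bin}) = -kT \ln \hat p(\mathrm{bin})}, anchored so
#' the minimum is 0.  The error band is a moving-block bootstrap with block
#' length equal to the estimated integrated autocorrelation time of the
#' series, so correlated samples do not fake precision.  Empty bins carry
#' `NA` (masked), not infinities.
#'
#' @param samples numeric CV series from the reference replica (>= 100).
#' @param n_bins number of histogram bins.
#' @param kT thermal energy.
#' @param n_boot bootstrap resamples for the error band.
#' @param seed integer seed for the bootstrap.
#' @param range optional c(lo, hi) histogram range (default: sample range).
#' @return an object of class `free_energy_profile`: data frame with columns
#'   `bin_center`, `dG`, `err`, `n_samples`.
#' @export
free_energy_profile <- function(samples, n_bins = 50L, kT = 1, n_boot = 200L,
                                seed = 1L, range = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 100) stop("free_energy_profile: need >= 100 samples")
  if (is.null(range)) range <- base::range(samples)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  centers <- (head(breaks, -1) + breaks[-1]) / 2
  width <- diff(breaks)[1]
  prof <- function(x) {
    cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                 all.inside = FALSE),
                    nbins = n_bins + 1L)[seq_len(n_bins)]
    p <- cnt / (length(x) * width)
    dg <- -kT * log(p)
    dg[!is.finite(dg)] <- NA_real_
    list(dg = dg - min(dg, na.rm = TRUE), cnt = cnt)
  }
  main <- prof(samples)
  block <- max(1L, min(ceiling(estimate_iact(samples)),
                       floor(length(samples) / 10)))
  boots <- with_seed(seed, {
    n <- length(samples)
    n_blocks <- ceiling(n / block)
    starts_max <- n - block + 1L
    vapply(seq_len(n_boot), function(b) {
      st <- sample.int(starts_max, n_blocks, replace = TRUE)
      idx <- as.vector(outer(0:(block - 1L), st, "+"))[seq_len(n)]
      prof(samples[idx])$dg
    }, numeric(n_bins))
  })
  err <- apply(boots, 1, sd, na.rm = TRUE)
  err[is.na(main$dg)] <- NA_real_
  structure(data.frame(bin_center = centers, dG = main$dg, err = err,
                       n_samples = main$cnt),
            class = c("free_energy_profile", "data.frame"),
            kT = kT, block_length = block, n_boot = n_boot)
}

#' Root-mean-square fluctuation per particle
#'
#' \eqn{RMSF_i = \sqrt{\langle |x_i(t) - \bar x_i|^2 \rangle_t}} with respect
#' to the time-average structure.  With `alignment = "rigid"` every frame is
#' first superposed onto the average structure by least-squares rigid-body
#' fitting (two refinement passes), removing global translation/rotation.
#'
#' @param trajectory coordinate array `n_frames x n_particles x dim` (e.g.
#'   the `coords` element of a saved run, or `campaign$frames[[r]]`).
#' @param alignment `"none"` or `"rigid"`.
#' @return numeric vector of per-particle fluctuations.
#' @export
rmsf <- function(trajectory, alignment = c("none", "rigid")) {
  alignment <- match.arg(alignment)
  d <- dim(trajectory)
  if (is.null(d) || length(d) != 3 || d[1] < 2)
    stop("rmsf: need an array of at least 2 frames")
  frames <- lapply(seq_len(d[1]), function(i) trajectory[i, , , drop = TRUE])
  if (d[2] == 1 || d[3] == 1)
    frames <- lapply(frames, matrix, nrow = d[2], ncol = d[3])
  if (alignment == "rigid") {
    for (pass in 1:2) {
      avg <- Reduce(`+`, frames) / length(frames)
      frames <- lapply(frames, superpose, ref = avg)
    }
  }
  avg <- Reduce(`+`, frames) / length(frames)
  msd <- Reduce(`+`, lapply(frames, function(fr) rowSums((fr - avg)^2))) /
    length(frames)
  sqrt(msd)
}

# Kabsch superposition of `mob` onto `ref` (both n x d, any d); returns the
# transformed mobile coordinates.
superpose <- function(mob, ref) {
  cm <- colMeans(mob); cr <- colMeans(ref)
  M <- sweep(mob, 2, cm); Rf <- sweep(ref, 2, cr)
  H <- crossprod(M, Rf)                 # d x d
  s <- svd(H)
  dsign <- sign(det(s$u %*% t(s$v)))
  if (dsign == 0) dsign <- 1
  D <- diag(c(rep(1, ncol(mob) - 1), dsign), ncol(mob))
  R <- s$u %*% D %*% t(s$v)
  sweep(M %*% R, 2, cr, "+")
}

#' Best-fit RMSD between two conformations
#'
#' Least-squares rigid-body superposition (Kabsch, rotations only --
#' reflections excluded) followed by the root-mean-square deviation over
#' particles; the analogue of heavy-atom RMSD for bead systems.
#'
#' @param a,b `n x dim` coordinate matrices.
#' @param fit superpose before measuring (default `TRUE`).
#' @return scalar RMSD.
#' @export
rmsd_fit <- function(a, b, fit = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (fit) b <- superpose(b, a)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Pairwise best-fit RMSD matrix of a trajectory
#'
#' @param trajectory array `n_frames x n_particles x dim`.
#' @param fit superpose each pair (default `TRUE`).
#' @return symmetric `n_frames x n_frames` distance matrix.
#' @export
rmsd_matrix <- function(trajectory, fit = TRUE) {
  d <- dim(trajectory)
  frames <- lapply(seq_len(d[1]), function(i)
    matrix(trajectory[i, , ], d[2], d[3]))
  n <- length(frames)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- rmsd_fit(frames[[i]], frames[[j]], fit = fit)
  D
}

# Classical DBSCAN on a precomputed distance matrix.  Returns integer labels,
# 0 = noise, plus the core-point flags.  minPts counts the point itself.
dbscan_distmat <- function(D, eps, minPts) {
  n <- nrow(D)
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nbrs) >= minPts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nbrs[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  list(labels = labels, core = core)
}

#' Density-based conformational clustering with sieved assignment
#'
#' The trajectory is strided (`frame_stride`, "every fifth frame" by
#' default), pairwise best-fit RMSD is the distance metric, and DBSCAN
#' (`eps`, `min_samples`) is run on a sieved subset (every `sieve`-th strided
#' frame, start offset randomized by `seed`) to form the initial clusters.
#' The sieved-out frames are then assigned to the cluster of their nearest
#' core point within `eps`, or to noise.  Representatives are cluster medoids
#' (minimum summed distance to cluster members); populations are fractions of
#' all analyzed (strided) frames, noise excluded from the numerator.
#'
#' @param trajectory array `n_frames x n_particles x dim`.
#' @param eps distance cutoff (default 1.25, the heavy-atom RMSD convention).
#' @param min_samples minimum conformations to form a cluster (default 4;
#'   counts the point itself).
#' @param frame_stride analyze every `frame_stride`-th frame (default 5).
#' @param sieve cluster every `sieve`-th strided frame first (default 10),
#'   then assign the rest; `sieve = 1` disables sieving.
#' @param seed integer seed for the sieve start offset.
#' @param fit superpose pairs before RMSD (default `TRUE`).
#' @return an object of class `cluster_result`: `labels` (per strided frame;
#'   0 = noise), `frame_indices` (original indices of the strided frames),
#'   `representatives` (original frame index of each cluster medoid),
#'   `populations`, `n_clusters`, `n_noise`.
#' @export
cluster_frames <- function(trajectory, eps = 1.25, min_samples = 4L,
                           frame_stride = 5L, sieve = 10L, seed = 1L,
                           fit = TRUE) {
  d <- dim(trajectory)
  idx <- seq(1L, d[1], by = frame_stride)
  ns <- length(idx)
  if (ns < 1L) stop("cluster_frames: no frames after striding")
  # fewer frames than min_samples is legal: DBSCAN then labels all as noise
  D <- rmsd_matrix(trajectory[idx, , , drop = FALSE], fit = fit)
  sieve <- max(1L, as.integer(sieve))
  offset <- if (sieve > 1L) with_seed(seed, sample.int(min(sieve, ns), 1L)) else 1L
  sub <- seq(offset, ns, by = sieve)
  db <- dbscan_distmat(D[sub, sub, drop = FALSE], eps, min_samples)
  labels <- integer(ns)
  labels[sub] <- db$labels
  cores <- sub[db$core & db$labels > 0L]
  rest <- setdiff(seq_len(ns), sub)
  if (length(cores)) {
    for (f in rest) {
      j <- cores[which.min(D[f, cores])]
      if (D[f, j] <= eps) labels[f] <- labels[j]
    }
  }
  cls <- sort(unique(labels[labels > 0L]))
  # relabel by decreasing population
  sizes <- vapply(cls, function(c) sum(labels == c), 0L)
  remap <- integer(max(c(0L, cls)))
  remap[cls[order(-sizes)]] <- seq_along(cls)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  cls <- seq_along(cls)
  reps <- vapply(cls, function(c) {
    members <- which(labels == c)
    members[which.min(rowSums(D[members, members, drop = FALSE]))]
  }, 0L)
  structure(list(labels = labels, frame_indices = idx,
                 representatives = idx[reps],
                 populations = vapply(cls, function(c) mean(labels == c), 0),
                 n_clusters = length(cls), n_noise = sum(labels == 0L)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d/%d frames noise\n",
              x$n_clusters, x$n_noise, length(x$labels)))
  if (x$n_clusters)
    print(data.frame(cluster = seq_len(x$n_clusters),
                     population = x$populations,
                     representative_frame = x$representatives))
  invisible(x)
}

#' Bias-convergence diagnostic
#'
#' Evaluates the (replica-2 scale, i.e. one increment) bias curve
#' \eqn{\Delta\, p_t(x)} of each interval's fitted mixture on a grid and
#' reports the root-mean-square change between consecutive intervals, both
#' absolutely and as a fraction of the current curve's maximum.  A converged
#' campaign shows the drift decaying toward zero.
#'
#' @param snapshots the `bias_snapshots` element of a campaign: a list of
#'   per-interval records with `models` (per-CV mixture records) and
#'   `increment`.
#' @param cv CV name to diagnose.
#' @param grid numeric grid of CV values.
#' @return data frame with columns `interval`, `drift` (RMS change on the
#'   grid vs the previous interval), `drift_frac` (`drift` divided by the
#'   grid maximum of the current curve), plus attribute `trend` (Spearman
#'   correlation of drift with interval; negative = decaying).
#' @export
bias_convergence <- function(snapshots, cv, grid) {
  keep <- Filter(function(s) !is.null(s$models) && cv %in% names(s$models),
                 snapshots)
  if (length(keep) < 2)
    stop("bias_convergence: need snapshots from at least 2 intervals")
  curves <- lapply(keep, function(s)
    s$increment * gmm_density(gmm_from_list(s$models[[cv]]), grid))
  iv <- vapply(keep, `[[`, 0, "interval")
  drift <- vapply(2:length(curves), function(t)
    sqrt(mean((curves[[t]] - curves[[t - 1]])^2)), 0)
  frac <- drift / vapply(2:length(curves), function(t)
    max(abs(curves[[t]])), 0)
  out <- data.frame(interval = iv[-1], drift = drift, drift_frac = frac)
  attr(out, "trend") <- suppressWarnings(
    stats::cor(out$interval, out$drift, method = "spearman"))
  out
}
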