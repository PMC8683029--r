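#' Replica-exchange schedule
#'
#' Holds the campaign geometry: number of replicas, steps per interval, the
#' exchange-attempt cadence, the save cadence, the number of intervals and
#' the sliding-window length for the bias refits.  The default cadence ratios
#' mirror the reference protocol (exchange attempts at the trajectory-save
#' cadence; window of 10 intervals of pooled sampling): exchanges every 80
#' steps, 10,000-step intervals, window 10.
#'
#' @param n_replicas number of replicas (>= 1; 1 degenerates to plain MD with
#'   periodic mixture refits and no exchanges).
#' @param steps_per_interval integration steps per interval.
#' @param exchange_period steps between exchange attempts (must divide
#'   `steps_per_interval`).
#' @param n_intervals number of intervals to run.
#' @param window sliding window (intervals) for the bias refit.
#' @param save_period steps between saved CV samples/frames (must divide
#'   `exchange_period`).
#' @param seed integer campaign seed.
#' @return an object of class `schedule_config`.
#' @export
schedule_config <- function(n_replicas = 8L, steps_per_interval = 10000L,
                            exchange_period = 80L, n_intervals = 10L,
                            window = 10L, save_period = 80L, seed = 1L) {
  n_replicas <- as.integer(n_replicas)
  stopifnot(n_replicas >= 1, steps_per_interval >= 1, exchange_period >= 1,
            n_intervals >= 1, window >= 1, save_period >= 1)
  if (steps_per_interval %% exchange_period != 0)
    stop("exchange_period must divide steps_per_interval")
  if (exchange_period %% save_period != 0)
    stop("save_period must divide exchange_period")
  structure(list(n_replicas = n_replicas,
                 steps_per_interval = as.integer(steps_per_interval),
                 exchange_period = as.integer(exchange_period),
                 n_intervals = as.integer(n_intervals),
                 window = as.integer(window),
                 save_period = as.integer(save_period),
                 seed = as.integer(seed)),
            class = "schedule_config")
}

#' @export
print.schedule_config <- function(x, ...) {
  cat(sprintf(paste0("<schedule_config> %d replicas, %d intervals x %d steps, ",
                     "exchange every %d, save every %d, window %d, seed %d\n"),
              x$n_replicas, x$n_intervals, x$steps_per_interval,
              x$exchange_period, x$save_period, x$window, x$seed))
  invisible(x)
}

#' Metropolis exchange attempt between two replicas
#'
#' At equal temperature and shared unbiased Hamiltonian, swapping the
#' *configurations* of replicas i and j changes the total energy only through
#' the bias terms, so the Metropolis exponent reduces to
#' \deqn{\Delta = [B_i(\xi(x_j)) + B_j(\xi(x_i))] - [B_i(\xi(x_i)) + B_j(\xi(x_j))]}
#' with \eqn{\xi(x)} the CV values of configuration \eqn{x}; the swap is
#' accepted with probability \eqn{\min(1, e^{-\Delta/kT})}.  Uses R's global
#' RNG for the acceptance draw.
#'
#' @param frame_i,frame_j [md_frame()]s of the two replicas.
#' @param bias_i,bias_j their [bias_state()]s (current interval).
#' @param cvs list of [cv_definition()]s.
#' @param kT thermal energy shared by both replicas.
#' @param step step index recorded in the exchange record.
#' @return list with `record` (list: `step`, `pair`, `delta`, `accepted`) and
#'   the possibly-swapped `frame_i`, `frame_j`.
#' @export
attempt_exchange <- function(frame_i, frame_j, bias_i, bias_j, cvs, kT,
                             step = frame_i$step_index) {
  xi_i <- compute_cvs(frame_i$coordinates, cvs)
  xi_j <- compute_cvs(frame_j$coordinates, cvs)
  delta <- (bias_energy(bias_i, xi_j) + bias_energy(bias_j, xi_i)) -
    (bias_energy(bias_i, xi_i) + bias_energy(bias_j, xi_j))
  if (!is.finite(delta)) stop("attempt_exchange: non-finite Metropolis exponent")
  accepted <- delta <= 0 || runif(1) < exp(-delta / kT)
  if (accepted) {
    tmp <- frame_i
    frame_i <- frame_j
    frame_j <- tmp
  }
  list(record = list(step = step,
                     pair = c(bias_i$replica_index, bias_j$replica_index),
                     delta = delta, accepted = accepted),
       frame_i = frame_i, frame_j = frame_j)
}

#' Initialize an H-REMD ensemble
#'
#' All replicas start structurally identical at `spec$x0` with
#' Maxwell-Boltzmann velocities drawn from the current RNG stream; all bias
#' states start empty (interval 0 is unbiased by construction).
#'
#' @param spec a [system_spec()].
#' @param cvs list of [cv_definition()]s.
#' @param schedule a [schedule_config()].
#' @param increment bias increment \eqn{\Delta}.
#' @return an object of class `ensemble_state`.
#' @export
init_ensemble <- function(spec, cvs, schedule, increment = 4) {
  R <- schedule$n_replicas
  sdv <- rep(sqrt(spec$kT / spec$masses), each = spec$dim)
  frames <- lapply(seq_len(R), function(r) {
    v <- matrix(rnorm(spec$n_particles * spec$dim) * sdv,
                spec$n_particles, spec$dim, byrow = TRUE)
    md_frame(0L, spec$x0, potential_energy = potential_energy(spec$x0, spec),
             bias_energy = 0, velocities = v)
  })
  biases <- lapply(seq_len(R), function(r) bias_state(r, increment, NULL, 0L))
  structure(list(frames = frames, biases = biases, interval = 0L, step0 = 0,
                 history_list = list(), exchange_list = list(),
                 bias_snapshots = list(),
                 frames_saved = lapply(seq_len(R), function(r) NULL)),
            class = "ensemble_state")
}

#' Run one H-REMD interval
#'
#' Advances every replica by `steps_per_interval` steps with its current bias
#' force applied at every step; neighbour exchanges are attempted every
#' `exchange_period` steps between alternating even/odd adjacent pairs; CV
#' values are saved every `save_period` steps and appended to the pooled
#' history; finally the bias is refit on the last `window` intervals via
#' [update_bias()] (all replicas keep zero bias during interval 0, matching
#' the unbiased first interval of the protocol).
#'
#' @param ensemble an [init_ensemble()] state.
#' @param spec a [system_spec()].
#' @param cvs list of [cv_definition()]s.
#' @param schedule a [schedule_config()].
#' @param increment,K bias increment and mixture size used at the refit.
#' @param save_coords logical; retain full coordinate frames per replica.
#' @param max_fit_samples passed to [update_bias()]: cap on the pooled
#'   samples handed to each mixture fit.
#' @return the advanced `ensemble_state`.
#' @export
run_interval <- function(ensemble, spec, cvs, schedule, increment = 4,
                         K = 3L, save_coords = FALSE,
                         max_fit_samples = 5000L) {
  R <- schedule$n_replicas
  cvs_c <- lapply(cvs, cv_to_cpp)
  cv_names <- vapply(cvs, `[[`, "", "name")
  shared <- NULL
  for (b in ensemble$biases)
    if (!is.null(b$models)) { shared <- b$models; break }
  gmms <- if (is.null(shared)) replicate(length(cvs), NULL, simplify = FALSE)
          else lapply(cv_names, function(nm)
            list(weights = shared[[nm]]$weights, means = shared[[nm]]$means,
                 sds = shared[[nm]]$sds))
  scales <- vapply(ensemble$biases, bias_scale, 0)
  res <- cpp_run_interval(
    lapply(ensemble$frames, `[[`, "coordinates"),
    lapply(ensemble$frames, `[[`, "velocities"),
    spec$masses, spec$potential, cvs_c, gmms, scales,
    spec$kT, spec$friction, spec$dt,
    schedule$steps_per_interval, schedule$exchange_period,
    schedule$save_period, ensemble$step0, save_coords)

  h <- cbind(res$history, ensemble$interval)
  colnames(h) <- c("step", "replica", "epot", "ebias", cv_names, "interval")
  ensemble$history_list[[length(ensemble$history_list) + 1L]] <- h
  if (nrow(res$exchanges)) {
    e <- cbind(res$exchanges, ensemble$interval)
    colnames(e) <- c("step", "replica_i", "replica_j", "delta", "accepted",
                     "interval")
    ensemble$exchange_list[[length(ensemble$exchange_list) + 1L]] <- e
  }
  if (save_coords) {
    ns <- sum(h[, "replica"] == 1)
    for (r in seq_len(R)) {
      arr <- aperm(array(res$frames[[r]],
                         c(spec$dim, spec$n_particles, ns)), c(3, 2, 1))
      ensemble$frames_saved[[r]] <-
        if (is.null(ensemble$frames_saved[[r]])) arr
        else abind_frames(ensemble$frames_saved[[r]], arr)
    }
  }
  ensemble$frames <- lapply(seq_len(R), function(r)
    md_frame(ensemble$step0 + schedule$steps_per_interval,
             res$coords[[r]], velocities = res$vels[[r]]))
  ensemble$step0 <- ensemble$step0 + schedule$steps_per_interval
  ensemble$interval <- ensemble$interval + 1L
  # refit bias for the next interval on the sliding window
  win <- as.data.frame(do.call(rbind,
    tail(ensemble$history_list, schedule$window)))
  ensemble$biases <- update_bias(win, cvs, K = K,
                                 increment = increment, n_replicas = R,
                                 window = schedule$window,
                                 seed = schedule$seed + ensemble$interval,
                                 previous = ensemble$biases,
                                 max_fit_samples = max_fit_samples)
  shared_new <- ensemble$biases[[min(2L, R)]]$models
  ensemble$bias_snapshots[[length(ensemble$bias_snapshots) + 1L]] <-
    list(interval = ensemble$interval, increment = increment, K = K,
         models = if (is.null(shared_new)) NULL
                  else lapply(shared_new, gmm_to_list))
  ensemble
}

abind_frames <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Run a full adaptive H-REMD campaign
#'
#' Executes `n_intervals` cycles of sampling, CV analysis and bias update
#' (interval 0 runs without bias), starting from `schedule$seed`; the run is
#' fully reproducible from (configuration, seed).  With `output_dir` set, the
#' CV history, exchange log, per-interval bias snapshots, a log file and a
#' checkpoint are written as the run progresses, and `restart = TRUE` resumes
#' from the last completed interval.
#'
#' @param spec a [system_spec()].
#' @param cvs list of [cv_definition()]s.
#' @param schedule a [schedule_config()].
#' @param increment bias increment \eqn{\Delta} (default 4, energy units).
#' @param K mixture components per CV (default 3).
#' @param output_dir optional directory for campaign outputs.
#' @param save_coords logical; retain (and, with `output_dir`, write as XYZ)
#'   coordinate frames.
#' @param restart logical; resume from `output_dir`'s checkpoint.
#' @param quiet suppress per-interval progress messages.
#' @param max_fit_samples passed to [update_bias()] at every refit.
#' @return an object of class `hremd_campaign`: `cv_history`, `exchanges`,
#'   `bias_snapshots`, `frames` (per-replica arrays if `save_coords`),
#'   `final` ensemble state, plus the inputs.
#' @export
run_campaign <- function(spec, cvs, schedule, increment = 4, K = 3L,
                         output_dir = NULL, save_coords = FALSE,
                         restart = FALSE, quiet = TRUE,
                         max_fit_samples = 5000L) {
  start_interval <- 0L
  if (restart) {
    if (is.null(output_dir)) stop("restart requires output_dir")
    ensemble <- read_checkpoint(output_dir, spec, cvs)
    start_interval <- ensemble$interval
    if (start_interval >= schedule$n_intervals) {
      if (!quiet) message("campaign already complete")
    }
  } else {
    set.seed(schedule$seed)
    ensemble <- init_ensemble(spec, cvs, schedule, increment)
    if (!is.null(output_dir)) init_output_dir(output_dir, spec, schedule)
  }
  if (!is.null(output_dir) && !quiet)
    log_line(output_dir, sprintf("campaign start: seed=%d intervals=%d",
                                 schedule$seed, schedule$n_intervals))
  for (it in seq_len(schedule$n_intervals)) {
    if (it <= start_interval) next
    ensemble <- run_interval(ensemble, spec, cvs, schedule,
                             increment = increment, K = K,
                             save_coords = save_coords,
                             max_fit_samples = max_fit_samples)
    if (!is.null(output_dir))
      write_campaign_interval(output_dir, ensemble, spec, schedule,
                              save_coords)
    if (!quiet) {
      acc <- if (!length(ensemble$exchange_list)) NA_real_ else {
        e <- ensemble$exchange_list[[length(ensemble$exchange_list)]]
        mean(e[, "accepted"])
      }
      message(sprintf("interval %d/%d done (exchange acceptance %.2f)",
                      ensemble$interval, schedule$n_intervals, acc))
    }
  }
  cv_history <- as.data.frame(do.call(rbind, ensemble$history_list))
  exchanges <- if (length(ensemble$exchange_list))
    as.data.frame(do.call(rbind, ensemble$exchange_list)) else NULL
  structure(list(spec = spec, cvs = cvs, schedule = schedule,
                 increment = increment, K = K,
                 cv_history = cv_history,
                 exchanges = exchanges,
                 bias_snapshots = ensemble$bias_snapshots,
                 frames = if (save_coords) ensemble$frames_saved else NULL,
                 final = ensemble),
            class = "hremd_campaign")
}

#' @export
print.hremd_campaign <- function(x, ...) {
  acc <- if (is.null(x$exchanges)) NA_real_ else mean(x$exchanges$accepted)
  cat(sprintf(paste0("<hremd_campaign> '%s': %d replicas, %d intervals, ",
                     "%d CV samples, exchange acceptance %.3f\n"),
              x$spec$name, x$schedule$n_replicas, x$final$interval,
              nrow(x$cv_history), acc))
  invisible(x)
}

#' Extract reference-replica samples of one CV
#'
#' Only the unbiased reference replica (replica 1) samples the Boltzmann
#' distribution; all equilibrium analysis is based on it.
#'
#' @param campaign an [run_campaign()] result (or any object with a
#'   `cv_history` data frame).
#' @param cv CV name (default: the first CV column).
#' @param replica replica index (default 1, the reference).
#' @param skip_intervals discard this many leading intervals as
#'   equilibration.
#' @return numeric vector of CV samples in time order.
#' @export
reference_samples <- function(campaign, cv = NULL, replica = 1L,
                              skip_intervals = 0L) {
  h <- campaign$cv_history
  if (is.null(cv))
    cv <- setdiff(names(h), c("step", "replica", "epot", "ebias", "interval"))[1]
  h <- h[h$replica == replica & h$interval >= skip_intervals, , drop = FALSE]
  h[[cv]][order(h$step)]
}

#' Integrated autocorrelation time and decorrelated subsampling
#'
#' `estimate_iact` uses the initial-positive-sequence estimator on the
#' empirical autocorrelation function, \eqn{\tau = 1 + 2\sum \rho_k} summed
#' while \eqn{\rho_k > 0}; `decorrelate` thins a series by `ceiling(tau)`.
#'
#' @param x numeric series.
#' @param max_lag largest lag examined.
#' @return `estimate_iact`: scalar \eqn{\tau \ge 1} (in sampling units);
#'   `decorrelate`: the thinned series.
#' @export
estimate_iact <- function(x, max_lag = min(length(x) - 1L, 2000L)) {
  if (length(x) < 10 || var(x) == 0) return(1)
  rho <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  max(1, 1 + 2 * sum(rho))
}

#' @rdname estimate_iact
#' @export
decorrelate <- function(x, max_lag = min(length(x) - 1L, 2000L)) {
  tau <- estimate_iact(x, max_lag)
  x[seq(1, length(x), by = max(1L, ceiling(tau)))]
}
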