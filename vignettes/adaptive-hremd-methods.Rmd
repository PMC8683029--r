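---
title: "Adaptive Hamiltonian replica exchange with Gaussian-mixture bias potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Hamiltonian replica exchange with Gaussian-mixture bias potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ahremd)
```

## The method

Large-scale conformational transitions — domain opening and closing in
multi-domain proteins being the canonical example — are often separated from
the starting structure by free-energy barriers that plain molecular dynamics
cannot cross in accessible simulation time.  `ahremd` implements an adaptive
Hamiltonian replica-exchange (H-REMD) scheme that accelerates such
transitions while keeping one replica rigorously unbiased:

1. $R$ replicas (default 8) of the same system run at the same temperature.
   Replica 1, the **reference replica**, never carries any bias; its samples
   follow the unbiased Boltzmann distribution and are the only ones analyzed.
2. A small set of **collective variables** (CVs) — here center-of-mass
   distances between named particle groups, or a bare coordinate for 1D
   systems — captures the slow motions of interest.
3. Time is divided into **intervals**.  After each interval the CV samples of
   *all* replicas over a sliding window of the last $W$ intervals (default
   10) are pooled, and a univariate $K$-component Gaussian mixture
   $$p(x) = \sum_{i=1}^{K} \phi_i\, \mathcal N(x \mid \mu_i, \sigma_i),
     \qquad \sum_i \phi_i = 1,$$
   with $K = 3$ by default, is fitted per CV by expectation–maximization.
4. During the next interval replica $r$ runs with the bias potential
   $$B_r(\mathrm{CV}) = (r - 1)\,\Delta\, p(x)$$
   summed over CVs, with increment $\Delta$ (default 4, in units of the
   system's thermal energy $kT$).  Because the bias is proportional to the
   *recently sampled* density, it destabilizes whatever region the ensemble
   currently occupies and pushes the biased replicas outward.
5. Configuration swaps between adjacent replicas are attempted on a fixed
   cadence with a Metropolis criterion.  At equal temperature and shared
   unbiased Hamiltonian the exponent reduces to bias terms only:
   $$\Delta_{ij} = [B_i(\xi(x_j)) + B_j(\xi(x_i))] -
                   [B_i(\xi(x_i)) + B_j(\xi(x_j))],$$
   acceptance $\min(1, e^{-\Delta_{ij}/kT})$, where $\xi(x)$ are the CV
   values of configuration $x$.  Swapped-in configurations give the
   reference replica barrier-crossing moves it could not make on its own,
   without ever distorting its stationary distribution.

The first interval runs without any bias so that the initial mixture fit
sees an unperturbed distribution.  The cycle (sample, fit, re-bias)
continues for a configured number of intervals; once the sampled
distribution stops changing, the fitted bias stops changing too, which is
the method's convergence diagnostic.

## Desk-scale model systems

The package is engine-free: a BAOAB splitting integrator (velocity
half-kick, half-drift, exact Ornstein–Uhlenbeck noise step, half-drift,
half-kick) propagates Langevin dynamics on built-in potentials in reduced
units ($kT = 1$, unit masses, friction $\gamma = 1$, time step
$\mathrm{d}t = 0.01$ unless stated):

* `make_harmonic()` — $U = kx^2/2$; used for integrator and free-energy
  checks (equipartition: $\mathrm{var}(x) = kT/k$).
* `make_double_well(h, a)` — $U = h\,((x/a)^2 - 1)^2$, minima at $\pm a$,
  barrier $h$; the reference benchmark for the sampler.
* `make_muller_brown()` — the standard 2D surface, scaled relative to $kT$.
* `make_domain_bead_model()` — domains of beads joined by stiff intra-domain
  bonds, with consecutive domain pairs coupled through a double well in
  their COM distance: a minimal analogue of open/closed domain arrangements,
  and the test bed for COM-distance CVs and their gradients.

BAOAB was chosen because its configurational sampling error is $O(\mathrm
dt^2)$ with a prefactor small enough that, at the step sizes used here, the
sampled distributions are indistinguishable from Boltzmann by a
Kolmogorov–Smirnov test at $n = 10^4$ decorrelated samples.

## Study conditions used in the validation runs

The cadence ratios mirror the reference protocol: exchange attempts and
trajectory saves every 80 steps, 10,000-step intervals, a 10-interval
window (the analogue of 8 ps / 1 ns / 10 ns).  All problem sizes below are
the package's own calibration choices; the benchmark barrier heights and
well separations have no external reference values.

* **Reference-replica correctness.** Double well $h = 6\,kT$, $a = 3$,
  8 replicas, $\Delta = 4\,kT$, $K = 3$, $W = 10$; 2,200 intervals, the
  first 60 discarded as equilibration.  The reference-replica CV series is
  thinned by its integrated autocorrelation time (~1,300 steps, dominated
  by the time a configuration takes to traverse the replica ladder and
  return) to 10,000 decorrelated samples, then compared to the analytic
  Boltzmann CDF (numerical quadrature of $e^{-U/kT}$) by a KS test at
  $\alpha = 0.01$.
* **Well separation.** $a = 3$ keeps the mixture's peak density — and hence
  the effective bias amplitude $\Delta\,(r-1)\,p(x)$ — in a regime where
  neighbour exchange rates stay high (~80%).  At $a = 1$ the same
  $\Delta$ produces per-level biases of several $kT$ at the density peak
  and a much more aggressive adaptive feedback loop; both regimes sample
  correctly, but the wider well is the better-behaved benchmark.
* **Acceleration.** Double well $h = 8\,kT$: plain MD at a 240,000-step
  budget shows essentially zero inter-well transitions (Kramers rate
  $\sim e^{-8}$), while the H-REMD reference replica shows hundreds,
  counted with hysteresis (a crossing requires passing between $x < -a/2$
  and $x > +a/2$) over 10 independent seeds.
* **Null-bias control.** With $\Delta = 0$ the campaign machinery (swaps
  included) must reproduce plain MD exactly in distribution; checked by a
  two-sample KS test on a $3\,kT$ double well.
* **Bias convergence.** Diagnosed on 40,000-step intervals with the fit
  subsample raised to 20,000: each refit then sees enough decorrelated data
  that parameter noise no longer masks the drift signal.  The reported
  statistic is the median, over the final quarter of the campaign, of the
  RMS change between consecutive bias curves (replica-2 scale, evaluated on
  a fixed grid) relative to the bias maximum.

## Numerical choices

* **Mixture fitting.** EM with a seeded k-means initialization, relative
  log-likelihood tolerance $10^{-6}$, at most 500 iterations, and a floor on
  every component width of $10^{-3}$ of the sample range (no component can
  collapse onto a point mass).  Components are reported sorted by mean.  One
  notational caveat: $\sigma_i$ is the component *standard deviation* — it
  appears as $1/(\sigma_i\sqrt{2\pi})$ in the density — although mixture
  parameters are often loosely called variances.
* **Warm-started refits.** Within a campaign each interval's refit is
  initialized from the previous interval's model rather than from a fresh
  k-means partition.  A three-component fit to a near-symmetric bimodal
  density has two nearly degenerate EM solutions (the third component can
  sit on either well's shoulder); independent initializations hop between
  those branches from interval to interval, which shows up as spurious bias
  drift.  Warm starting keeps consecutive fits on one branch, so the
  convergence diagnostic measures changes in the data rather than in the
  optimizer.  Isolated branch hops can still occur when the window's
  occupancy tips far enough; they appear as single-interval drift spikes,
  which is why the convergence statistic is a median.
* **Fit subsampling.** The pooled window (up to hundreds of thousands of
  saved CV values) is evenly strided down to at most `max_fit_samples`
  (default 5,000) before fitting.  Adjacent saved samples are strongly
  autocorrelated, so this discards almost no information while bounding the
  per-interval fit cost.
* **Bias units.** $\Delta$ multiplies a probability *density*, so the bias
  height depends on the CV's length scale: halving the CV scale doubles
  $p(x)$ at the peak.  $\Delta$ is therefore interpreted in the system's
  own energy units (default $4\,kT$), and the effective bias amplitude is a
  joint property of $\Delta$ and the CV geometry.
* **Exchanges.** Neighbour-only swaps with alternating even/odd pairing
  (segments alternate between pairs (1,2),(3,4),… and (2,3),(4,5),…), the
  standard scheme for ergodic ladder mixing.  Swaps move configurations
  (coordinates and velocities) between fixed bias slots; the reference
  replica is the fixed zero-bias slot.  The bias switches abruptly at
  interval boundaries; exchange bookkeeping always uses the current
  interval's bias.
* **Singular CV geometry.** A COM distance below $10^{-8}$ has no defined
  direction; that CV's force contribution is dropped for the step (the
  energy remains finite).
* **Determinism.** One seeded RNG stream drives everything — velocity
  initialization, Langevin noise (consumed replica-by-replica in a fixed
  order inside the compiled interval kernel), exchange draws, and mixture
  initializations (which save and restore the stream) — so a (configuration,
  seed) pair reproduces trajectories and exchange logs bitwise, including
  across checkpoint restarts.

## Analysis protocol

* **Free-energy profiles.** $\Delta G(\mathrm{bin}) = -kT\ln\hat
  p(\mathrm{bin})$ from reference-replica samples, min-anchored at zero
  (the anchoring is a convention; only differences are physical, so
  comparisons to analytic profiles align the additive constant first).
  Error bands come from a moving-block bootstrap with block length equal to
  the estimated integrated autocorrelation time; empty bins are masked.
* **RMSF** is computed against the time-average structure, optionally after
  rigid-body (Kabsch) superposition of every frame onto that average (two
  refinement passes).
* **Clustering** follows the trajectory-clustering convention: stride the
  trajectory (default every 5th frame), use pairwise best-fit RMSD as the
  metric, run DBSCAN (cutoff 1.25, minimum 4 conformations) on a sieved
  subset (every 10th strided frame, start offset seeded), then assign the
  sieved-out frames to the cluster of their nearest core point within the
  cutoff, or to noise.  "Sieve" here means cluster-a-subset-then-assign;
  the subset fraction is configurable.  Populations are fractions of all
  analyzed frames with noise excluded from the numerator; representatives
  are cluster medoids.
* **Bias convergence** evaluates each interval's fitted bias curve on a
  fixed grid and reports the RMS change between consecutive intervals,
  absolute and relative to the current curve's maximum.

## What the toy systems do and do not show

The bead models and analytic wells exercise every algorithmic component —
integrator, CV gradients, mixture fitting, bias forces, exchange
bookkeeping, analysis — under conditions where exact or brute-force answers
exist.  They do not emulate rugged all-atom landscapes, solvent friction
anisotropy, CV couplings in high dimension, or force-field error: passing
these tests demonstrates that the sampler and its analysis are implemented
correctly, not that any particular biological system will converge on a
given budget.

## Known limitations

* Biased-replica samples are pooled *unweighted* for the mixture fit (no
  reweighting to the unbiased ensemble).  This matches the scheme's design —
  the fit should describe where the ensemble currently samples — but means
  the fitted $p(x)$ is a property of the biased ensemble, not an estimate of
  the Boltzmann density.  A flag to exclude high replicas from the fit pool
  (`update_bias` on a subset of the history) supports sensitivity checks.
* With $K = 3$ on strongly bimodal data the mixture has near-degenerate
  solutions; warm starting suppresses but cannot eliminate branch hopping
  (see above).
* The sampler is sequential over replicas within a process; campaigns are
  CPU-bound single-core by design (determinism over parallel speed).
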