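// Compiled core: potential energies/forces, Gaussian-mixture bias evaluation,
// BAOAB Langevin propagation, and the replica-exchange interval kernel.
// All randomness is drawn from R's RNG (norm_rand / unif_rand) in a fixed
// order, so a single set.seed() at the R level makes runs bit-reproducible.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SQRT_2PI = 2.5066282746310002;

// ---------------------------------------------------------------------------
// Potentials
// ---------------------------------------------------------------------------
struct BeadPot {
  std::vector<int> b_i, b_j;                 // bonded pairs (0-based)
  std::vector<double> b_r0, b_k;
  std::vector< std::vector<int> > gidx;      // domain member indices (0-based)
  std::vector< std::vector<double> > gw;     // mass fractions within domain
  std::vector<int> p_a, p_b;                 // interacting domain pairs
  std::vector<double> p_h, p_c, p_w;         // double well: h*(((d-c)/w)^2-1)^2
};

struct Pot {
  int type;          // 0 harmonic, 1 double well, 2 Mueller-Brown, 3 bead model
  double k, h, a, scale;
  BeadPot bead;
};

static Pot parse_pot(const List& p) {
  Pot P;
  P.k = P.h = P.a = 0.0; P.scale = 1.0;
  std::string t = as<std::string>(p["type"]);
  if (t == "harmonic") {
    P.type = 0; P.k = as<double>(p["k"]);
  } else if (t == "double_well") {
    P.type = 1; P.h = as<double>(p["h"]); P.a = as<double>(p["a"]);
  } else if (t == "muller_brown") {
    P.type = 2; P.scale = as<double>(p["scale"]);
  } else if (t == "bead_model") {
    P.type = 3;
    NumericMatrix B = p["bonds"];            // cols: i, j (1-based), r0, k
    for (int r = 0; r < B.nrow(); ++r) {
      P.bead.b_i.push_back((int)B(r, 0) - 1);
      P.bead.b_j.push_back((int)B(r, 1) - 1);
      P.bead.b_r0.push_back(B(r, 2));
      P.bead.b_k.push_back(B(r, 3));
    }
    List G = p["groups"]; List GW = p["group_weights"];
    for (int g = 0; g < G.size(); ++g) {
      IntegerVector gi = G[g]; NumericVector gw = GW[g];
      std::vector<int> vi; std::vector<double> vw;
      for (int q = 0; q < gi.size(); ++q) { vi.push_back(gi[q] - 1); vw.push_back(gw[q]); }
      P.bead.gidx.push_back(vi); P.bead.gw.push_back(vw);
    }
    NumericMatrix PR = p["pairs"];           // cols: ga, gb (1-based), h, c, w
    for (int r = 0; r < PR.nrow(); ++r) {
      P.bead.p_a.push_back((int)PR(r, 0) - 1);
      P.bead.p_b.push_back((int)PR(r, 1) - 1);
      P.bead.p_h.push_back(PR(r, 2));
      P.bead.p_c.push_back(PR(r, 3));
      P.bead.p_w.push_back(PR(r, 4));
    }
  } else {
    stop("unknown potential type '%s'", t.c_str());
  }
  return P;
}

// Mueller-Brown constants (standard parameterization, scaled by P.scale)
static const double MB_A[4]  = {-200.0, -100.0, -170.0, 15.0};
static const double MB_a[4]  = {-1.0, -1.0, -6.5, 0.7};
static const double MB_b[4]  = {0.0, 0.0, 11.0, 0.6};
static const double MB_c[4]  = {-10.0, -10.0, -6.5, 0.7};
static const double MB_x0[4] = {1.0, 0.0, -0.5, -1.0};
static const double MB_y0[4] = {0.0, 0.5, 1.5, 1.0};

// energy; adds -grad U into f (f not zeroed here)
static double pot_energy_force(const Pot& P, const double* x, double* f,
                               int n, int dim) {
  double U = 0.0;
  if (P.type == 0) {
    for (int i = 0; i < n * dim; ++i) {
      U += 0.5 * P.k * x[i] * x[i];
      if (f) f[i] -= P.k * x[i];
    }
  } else if (P.type == 1) {
    double u = x[0] / P.a, q = u * u - 1.0;
    U = P.h * q * q;
    if (f) f[0] -= 4.0 * P.h * x[0] * q / (P.a * P.a);
  } else if (P.type == 2) {
    double X = x[0], Y = x[1];
    for (int t = 0; t < 4; ++t) {
      double dx = X - MB_x0[t], dy = Y - MB_y0[t];
      double e = P.scale * MB_A[t] *
        std::exp(MB_a[t] * dx * dx + MB_b[t] * dx * dy + MB_c[t] * dy * dy);
      U += e;
      if (f) {
        f[0] -= e * (2.0 * MB_a[t] * dx + MB_b[t] * dy);
        f[1] -= e * (MB_b[t] * dx + 2.0 * MB_c[t] * dy);
      }
    }
  } else {
    const BeadPot& B = P.bead;
    for (size_t r = 0; r < B.b_i.size(); ++r) {
      int i = B.b_i[r], j = B.b_j[r];
      double d2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        double dd = x[i * dim + d] - x[j * dim + d]; d2 += dd * dd;
      }
      double dist = std::sqrt(d2), dev = dist - B.b_r0[r];
      U += 0.5 * B.b_k[r] * dev * dev;
      if (f && dist > 1e-12) {
        double c = B.b_k[r] * dev / dist;
        for (int d = 0; d < dim; ++d) {
          double dd = x[i * dim + d] - x[j * dim + d];
          f[i * dim + d] -= c * dd;
          f[j * dim + d] += c * dd;
        }
      }
    }
    int ng = (int)B.gidx.size();
    std::vector<double> com(ng * dim);
    for (int g = 0; g < ng; ++g)
      for (int d = 0; d < dim; ++d) {
        double s = 0.0;
        for (size_t q = 0; q < B.gidx[g].size(); ++q)
          s += B.gw[g][q] * x[B.gidx[g][q] * dim + d];
        com[g * dim + d] = s;
      }
    for (size_t r = 0; r < B.p_a.size(); ++r) {
      int ga = B.p_a[r], gb = B.p_b[r];
      double d2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        double dd = com[ga * dim + d] - com[gb * dim + d]; d2 += dd * dd;
      }
      double dist = std::sqrt(d2);
      double u = (dist - B.p_c[r]) / B.p_w[r], q = u * u - 1.0;
      U += B.p_h[r] * q * q;
      if (f && dist > 1e-12) {
        double dUdd = 4.0 * B.p_h[r] * u * q / B.p_w[r];
        for (int d = 0; d < dim; ++d) {
          double unit = (com[ga * dim + d] - com[gb * dim + d]) / dist;
          for (size_t qq = 0; qq < B.gidx[ga].size(); ++qq)
            f[B.gidx[ga][qq] * dim + d] -= dUdd * B.gw[ga][qq] * unit;
          for (size_t qq = 0; qq < B.gidx[gb].size(); ++qq)
            f[B.gidx[gb][qq] * dim + d] += dUdd * B.gw[gb][qq] * unit;
        }
      }
    }
  }
  return U;
}

// ---------------------------------------------------------------------------
// Collective variables + Gaussian-mixture bias
// ---------------------------------------------------------------------------
struct CVc {
  int type;                 // 0 coordinate, 1 COM distance
  int particle, axis;       // type 0 (0-based)
  std::vector<int> ia, ib;  // type 1 member indices (0-based)
  std::vector<double> wa, wb;
  std::vector<double> gw, gmu, gsd;  // mixture (empty => no bias on this CV)
};

static std::vector<CVc> parse_cvs(const List& cvs, const List& gmms) {
  std::vector<CVc> out;
  for (int i = 0; i < cvs.size(); ++i) {
    List c = cvs[i];
    CVc cv;
    std::string t = as<std::string>(c["type"]);
    if (t == "coordinate") {
      cv.type = 0;
      cv.particle = as<int>(c["particle"]) - 1;
      cv.axis = as<int>(c["axis"]) - 1;
    } else {
      cv.type = 1;
      IntegerVector ia = c["ia"], ib = c["ib"];
      NumericVector wa = c["wa"], wb = c["wb"];
      for (int q = 0; q < ia.size(); ++q) { cv.ia.push_back(ia[q] - 1); cv.wa.push_back(wa[q]); }
      for (int q = 0; q < ib.size(); ++q) { cv.ib.push_back(ib[q] - 1); cv.wb.push_back(wb[q]); }
    }
    if (gmms.size() > i && !Rf_isNull(gmms[i])) {
      List g = gmms[i];
      NumericVector w = g["weights"], mu = g["means"], sd = g["sds"];
      for (int k = 0; k < w.size(); ++k) {
        cv.gw.push_back(w[k]); cv.gmu.push_back(mu[k]); cv.gsd.push_back(sd[k]);
      }
    }
    out.push_back(cv);
  }
  return out;
}

static double cv_value(const CVc& c, const double* x, int dim) {
  if (c.type == 0) return x[c.particle * dim + c.axis];
  double s = 0.0;
  for (int d = 0; d < dim; ++d) {
    double ca = 0.0, cb = 0.0;
    for (size_t q = 0; q < c.ia.size(); ++q) ca += c.wa[q] * x[c.ia[q] * dim + d];
    for (size_t q = 0; q < c.ib.size(); ++q) cb += c.wb[q] * x[c.ib[q] * dim + d];
    double dd = ca - cb; s += dd * dd;
  }
  return std::sqrt(s);
}

static inline void gmm_pd(const CVc& c, double v, double& p, double& dp) {
  p = 0.0; dp = 0.0;
  for (size_t k = 0; k < c.gw.size(); ++k) {
    double z = (v - c.gmu[k]) / c.gsd[k];
    double N = c.gw[k] * std::exp(-0.5 * z * z) / (c.gsd[k] * SQRT_2PI);
    p += N;
    dp -= N * z / c.gsd[k];
  }
}

// total mixture density summed over CVs (exchange bookkeeping)
static double bias_density_sum(const std::vector<CVc>& cvs, const double* x, int dim) {
  double s = 0.0;
  for (size_t i = 0; i < cvs.size(); ++i) {
    if (cvs[i].gw.empty()) continue;
    double p, dp;
    gmm_pd(cvs[i], cv_value(cvs[i], x, dim), p, dp);
    s += p;
  }
  return s;
}

// bias energy; adds bias forces into f when f != NULL
static double bias_energy_force(const std::vector<CVc>& cvs, double scale,
                                const double* x, double* f, int n, int dim) {
  if (scale <= 0.0) return 0.0;
  double U = 0.0;
  for (size_t i = 0; i < cvs.size(); ++i) {
    const CVc& c = cvs[i];
    if (c.gw.empty()) continue;
    double v = cv_value(c, x, dim), p, dp;
    gmm_pd(c, v, p, dp);
    U += scale * p;
    if (!f) continue;
    if (c.type == 0) {
      f[c.particle * dim + c.axis] -= scale * dp;
    } else if (v > 1e-8) {   // singular COM geometry: force contribution dropped
      for (int d = 0; d < dim; ++d) {
        double ca = 0.0, cb = 0.0;
        for (size_t q = 0; q < c.ia.size(); ++q) ca += c.wa[q] * x[c.ia[q] * dim + d];
        for (size_t q = 0; q < c.ib.size(); ++q) cb += c.wb[q] * x[c.ib[q] * dim + d];
        double unit = (ca - cb) / v;
        for (size_t q = 0; q < c.ia.size(); ++q)
          f[c.ia[q] * dim + d] -= scale * dp * c.wa[q] * unit;
        for (size_t q = 0; q < c.ib.size(); ++q)
          f[c.ib[q] * dim + d] += scale * dp * c.wb[q] * unit;
      }
    }
  }
  return U;
}

// ---------------------------------------------------------------------------
// BAOAB Langevin propagation
// ---------------------------------------------------------------------------
struct SaveBuf {
  std::vector<double> steps, epot, ebias, cvvals, coords;
};

static void propagate(std::vector<double>& x, std::vector<double>& v,
                      const std::vector<double>& m, const Pot& P,
                      const std::vector<CVc>& cvs, double scale,
                      const double* fext, double kT, double gamma, double dt,
                      int n_steps, int save_every, double step0,
                      int n, int dim, bool save_coords, SaveBuf& out) {
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const int nd = n * dim;
  std::vector<double> f(nd, 0.0);
  double U = pot_energy_force(P, x.data(), f.data(), n, dim);
  double Ub = bias_energy_force(cvs, scale, x.data(), f.data(), n, dim);
  if (fext) for (int i = 0; i < nd; ++i) f[i] += fext[i];
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < nd; ++i) {
      double mi = m[i / dim];
      v[i] += 0.5 * dt * f[i] / mi;
      x[i] += 0.5 * dt * v[i];
      v[i] = c1 * v[i] + c2 * std::sqrt(kT / mi) * norm_rand();
      x[i] += 0.5 * dt * v[i];
    }
    std::fill(f.begin(), f.end(), 0.0);
    U = pot_energy_force(P, x.data(), f.data(), n, dim);
    Ub = bias_energy_force(cvs, scale, x.data(), f.data(), n, dim);
    if (fext) for (int i = 0; i < nd; ++i) f[i] += fext[i];
    for (int i = 0; i < nd; ++i) {
      v[i] += 0.5 * dt * f[i] / m[i / dim];
      if (!std::isfinite(x[i]) || !std::isfinite(v[i]))
        stop("non-finite coordinate/velocity at step %d", (int)(step0 + s));
    }
    if (save_every > 0 && ((long long)step0 + s) % save_every == 0) {
      out.steps.push_back(step0 + s);
      out.epot.push_back(U);
      out.ebias.push_back(Ub);
      for (size_t c = 0; c < cvs.size(); ++c)
        out.cvvals.push_back(cv_value(cvs[c], x.data(), dim));
      if (save_coords) out.coords.insert(out.coords.end(), x.begin(), x.end());
    }
  }
}

// ---------------------------------------------------------------------------
// Exports
// ---------------------------------------------------------------------------

// EM inner loop for a univariate Gaussian mixture (log-space E step).
// Returns updated parameters and the per-iteration log-likelihood trace.
// [[Rcpp::export]]
List cpp_gmm_em(NumericVector samples, NumericVector w0, NumericVector mu0,
                NumericVector sg0, double floor_sd, double tol, int max_iter) {
  int n = samples.size(), K = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sg(sg0.begin(), sg0.end());
  std::vector<double> trace;
  std::vector<double> resp(n * K);
  double ll_old = R_NegInf;
  bool converged = false;
  int iter = 0;
  const double LOG_SQRT_2PI = 0.9189385332046727;
  for (iter = 1; iter <= max_iter; ++iter) {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double z = (samples[i] - mu[k]) / sg[k];
        double ld = std::log(std::max(w[k], 1e-300)) - std::log(sg[k]) -
          LOG_SQRT_2PI - 0.5 * z * z;
        resp[i * K + k] = ld;
        if (ld > mx) mx = ld;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(resp[i * K + k] - mx);
      double lse = mx + std::log(s);
      ll += lse;
      for (int k = 0; k < K; ++k)
        resp[i * K + k] = std::exp(resp[i * K + k] - lse);
    }
    trace.push_back(ll);
    for (int k = 0; k < K; ++k) {
      double Nk = 0.0, m1 = 0.0;
      for (int i = 0; i < n; ++i) {
        Nk += resp[i * K + k];
        m1 += resp[i * K + k] * samples[i];
      }
      if (Nk < 1e-12) Nk = 1e-12;
      w[k] = Nk / n;
      mu[k] = m1 / Nk;
      double v = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = samples[i] - mu[k];
        v += resp[i * K + k] * d * d;
      }
      sg[k] = std::max(std::sqrt(v / Nk), floor_sd);
    }
    if (R_FINITE(ll_old) && std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + 1e-10)) {
      converged = true;
      break;
    }
    ll_old = ll;
  }
  return List::create(_["weights"] = wrap(w), _["means"] = wrap(mu),
                      _["sds"] = wrap(sg), _["trace"] = wrap(trace),
                      _["iterations"] = std::min(iter, max_iter),
                      _["converged"] = converged);
}

// [[Rcpp::export]]
List cpp_energy_force(NumericMatrix coords, List pot,
                      Nullable<List> cvs_ = R_NilValue,
                      Nullable<List> gmms_ = R_NilValue,
                      double bias_scale = 0.0) {
  int n = coords.nrow(), dim = coords.ncol();
  Pot P = parse_pot(pot);
  std::vector<double> x(n * dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d) x[i * dim + d] = coords(i, d);
  std::vector<double> f(n * dim, 0.0);
  double U = pot_energy_force(P, x.data(), f.data(), n, dim);
  double Ub = 0.0;
  if (cvs_.isNotNull() && gmms_.isNotNull()) {
    std::vector<CVc> cvs = parse_cvs(cvs_.get(), gmms_.get());
    Ub = bias_energy_force(cvs, bias_scale, x.data(), f.data(), n, dim);
  }
  NumericMatrix F(n, dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d) F(i, d) = f[i * dim + d];
  return List::create(_["energy"] = U, _["bias_energy"] = Ub, _["force"] = F);
}

// [[Rcpp::export]]
List cpp_propagate(NumericMatrix coords, NumericMatrix vels, NumericVector masses,
                   List pot, List cvs, List gmms, double bias_scale,
                   Nullable<NumericMatrix> fext_, double kT, double friction,
                   double dt, int n_steps, int save_every, double step0,
                   bool save_coords) {
  int n = coords.nrow(), dim = coords.ncol();
  Pot P = parse_pot(pot);
  std::vector<CVc> C = parse_cvs(cvs, gmms);
  std::vector<double> x(n * dim), v(n * dim), m(n);
  for (int i = 0; i < n; ++i) {
    m[i] = masses[i];
    for (int d = 0; d < dim; ++d) {
      x[i * dim + d] = coords(i, d);
      v[i * dim + d] = vels(i, d);
    }
  }
  std::vector<double> fe;
  const double* fep = NULL;
  if (fext_.isNotNull()) {
    NumericMatrix fx = fext_.get();
    fe.resize(n * dim);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < dim; ++d) fe[i * dim + d] = fx(i, d);
    fep = fe.data();
  }
  SaveBuf out;
  propagate(x, v, m, P, C, bias_scale, fep, kT, friction, dt,
            n_steps, save_every, step0, n, dim, save_coords, out);
  NumericMatrix X(n, dim), V(n, dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d) {
      X(i, d) = x[i * dim + d];
      V(i, d) = v[i * dim + d];
    }
  int ns = (int)out.steps.size(), ncv = (int)C.size();
  NumericMatrix CVm(ns, ncv);
  for (int s = 0; s < ns; ++s)
    for (int c = 0; c < ncv; ++c) CVm(s, c) = out.cvvals[s * ncv + c];
  List res = List::create(
    _["coords"] = X, _["vels"] = V,
    _["steps"] = wrap(out.steps),
    _["epot"] = wrap(out.epot), _["ebias"] = wrap(out.ebias),
    _["cv"] = CVm);
  if (save_coords) res["frames"] = wrap(out.coords);
  return res;
}

// Full interval: propagate all replicas segment by segment, attempting
// neighbour exchanges between segments with alternating even/odd pairing.
// All replicas share one mixture model per CV; replica r is scaled by
// scales[r].  Exchange swaps coordinates+velocities (configuration swap).
// [[Rcpp::export]]
List cpp_run_interval(List coords_list, List vels_list, NumericVector masses,
                      List pot, List cvs, List gmms, NumericVector scales,
                      double kT, double friction, double dt,
                      int steps_per_interval, int exchange_period,
                      int save_period, double step0, bool save_coords) {
  int R = coords_list.size();
  NumericMatrix c0 = coords_list[0];
  int n = c0.nrow(), dim = c0.ncol();
  Pot P = parse_pot(pot);
  std::vector<CVc> C = parse_cvs(cvs, gmms);
  int ncv = (int)C.size();
  bool have_models = false;
  for (int c = 0; c < ncv; ++c) if (!C[c].gw.empty()) have_models = true;

  std::vector< std::vector<double> > X(R), V(R);
  std::vector<double> m(n);
  for (int i = 0; i < n; ++i) m[i] = masses[i];
  for (int r = 0; r < R; ++r) {
    NumericMatrix cr = coords_list[r], vr = vels_list[r];
    X[r].resize(n * dim); V[r].resize(n * dim);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < dim; ++d) {
        X[r][i * dim + d] = cr(i, d);
        V[r][i * dim + d] = vr(i, d);
      }
  }

  int n_seg = steps_per_interval / exchange_period;
  std::vector<SaveBuf> bufs(R);
  std::vector<double> ex_step, ex_i, ex_j, ex_delta, ex_acc;

  for (int seg = 0; seg < n_seg; ++seg) {
    for (int r = 0; r < R; ++r)
      propagate(X[r], V[r], m, P, C, scales[r], NULL, kT, friction, dt,
                exchange_period, save_period,
                step0 + (double)seg * exchange_period, n, dim,
                save_coords, bufs[r]);
    double at_step = step0 + (double)(seg + 1) * exchange_period;
    long gseg = (long)(at_step / exchange_period);   // global segment counter
    int first = (gseg % 2 == 1) ? 0 : 1;             // alternating pairing
    if (R >= 2) {
      // per-replica total mixture density (depends on configuration only)
      std::vector<double> Pd(R, 0.0);
      if (have_models)
        for (int r = 0; r < R; ++r) Pd[r] = bias_density_sum(C, X[r].data(), dim);
      for (int i = first; i + 1 < R; i += 2) {
        int j = i + 1;
        double delta = (scales[i] - scales[j]) * (Pd[j] - Pd[i]);
        double u = unif_rand();
        bool accept = (delta <= 0.0) || (u < std::exp(-delta / kT));
        if (accept) {
          std::swap(X[i], X[j]);
          std::swap(V[i], V[j]);
          std::swap(Pd[i], Pd[j]);
        }
        ex_step.push_back(at_step);
        ex_i.push_back(i + 1); ex_j.push_back(j + 1);
        ex_delta.push_back(delta); ex_acc.push_back(accept ? 1.0 : 0.0);
      }
    }
  }

  // pack results
  List Xout(R), Vout(R), Fout(R);
  for (int r = 0; r < R; ++r) {
    NumericMatrix xr(n, dim), vr(n, dim);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < dim; ++d) {
        xr(i, d) = X[r][i * dim + d];
        vr(i, d) = V[r][i * dim + d];
      }
    Xout[r] = xr; Vout[r] = vr;
    if (save_coords) Fout[r] = wrap(bufs[r].coords);
  }
  int ns = (int)bufs[0].steps.size();
  // rows: one per (save event, replica); cols: step, replica, epot, ebias, cvs
  NumericMatrix H(ns * R, 4 + ncv);
  int row = 0;
  for (int s = 0; s < ns; ++s)
    for (int r = 0; r < R; ++r) {
      H(row, 0) = bufs[r].steps[s];
      H(row, 1) = r + 1;
      H(row, 2) = bufs[r].epot[s];
      H(row, 3) = bufs[r].ebias[s];
      for (int c = 0; c < ncv; ++c) H(row, 4 + c) = bufs[r].cvvals[s * ncv + c];
      ++row;
    }
  int ne = (int)ex_step.size();
  NumericMatrix E(ne, 5);
  for (int e = 0; e < ne; ++e) {
    E(e, 0) = ex_step[e]; E(e, 1) = ex_i[e]; E(e, 2) = ex_j[e];
    E(e, 3) = ex_delta[e]; E(e, 4) = ex_acc[e];
  }
  List res = List::create(
    _["coords"] = Xout, _["vels"] = Vout,
    _["history"] = H, _["exchanges"] = E);
  if (save_coords) res["frames"] = Fout;
  return res;
}
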