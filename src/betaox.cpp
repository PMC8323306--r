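// Core numerics for the mitochondrial beta-oxidation network.
//
// Dynamic species (25, all muM, matrix compartment unless noted):
//   0        acylcarnitine C16 (carnitine moiety)
//   1..7     acyl-CoA  C16,C14,C12,C10,C8,C6,C4
//   8..14    enoyl-CoA C16..C4
//   15..21   3-ketoacyl-CoA C16..C4
//   22       acetyl-CoA
//   23       free CoA
//   24       free carnitine
// Clamped boundary species: cytosolic palmitoyl-CoA S (muM) and
// malonyl-CoA M (muM), passed separately.
//
// Two moieties are conserved: CoA (indices 1..23) and carnitine (0, 24).
// The steady-state solver works in the 23 reduced coordinates (0..22)
// with the free pools recovered from the totals.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NCHAIN = 7;           // chains 16,14,12,10,8,6,4
static const int NDYN = 25;
static const int NRED = 23;

struct BxPars {
  // vmax order: CPT1B, CACT_CPT2, VLCAD, LCAD, MCAD, SCAD, HYD_HAD, MTP, MCKAT
  arma::vec vmax;          // umol / min / mg total protein
  arma::mat km;            // 9 x 7, muM; Inf where enzyme inactive on chain
  double ki_malonyl;       // muM
  double ki_acylcarnitine; // muM, CPT1B product inhibition by C16-acylcarnitine
  double km_carnitine;     // muM, CPT1B vs free carnitine
  double km_coa_import;    // muM, CACT/CPT2 vs free CoA
  double km_coa_thiolase;  // muM, thiolases vs free CoA
  double coa_total;        // muM
  double carnitine_total;  // muM
  double k_sink;           // 1/min, first-order acetyl-CoA drain
  double vol_factor;       // muM min^-1 per (umol min^-1 mg^-1)
};

static BxPars unpack_pars(const List& pars) {
  BxPars p;
  p.vmax = as<arma::vec>(pars["vmax"]);
  p.km = as<arma::mat>(pars["km"]);
  p.ki_malonyl = as<double>(pars["ki_malonyl"]);
  p.ki_acylcarnitine = as<double>(pars["ki_acylcarnitine"]);
  p.km_carnitine = as<double>(pars["km_carnitine"]);
  p.km_coa_import = as<double>(pars["km_coa_import"]);
  p.km_coa_thiolase = as<double>(pars["km_coa_thiolase"]);
  p.coa_total = as<double>(pars["coa_total"]);
  p.carnitine_total = as<double>(pars["carnitine_total"]);
  p.k_sink = as<double>(pars["k_sink"]);
  p.vol_factor = as<double>(pars["vol_factor"]);
  if (p.vmax.n_elem != 9 || p.km.n_rows != 9 || p.km.n_cols != 7)
    stop("parameter pack must carry 9 vmax entries and a 9x7 Km matrix");
  return p;
}

// enzyme row indices in vmax/km
enum { E_CPT1B = 0, E_IMPORT = 1, E_VLCAD = 2, E_LCAD = 3, E_MCAD = 4,
       E_SCAD = 5, E_HYD = 6, E_MTP = 7, E_MCKAT = 8 };

// 34 elementary rates, muM/min. Order documented in R wrapper.
static void bx_rates_core(const arma::vec& y, double S, double M,
                          const BxPars& p, arma::vec& v) {
  const double VF = p.vol_factor;
  double ac16 = std::max(y[0], 0.0);
  double acyl[NCHAIN], enoyl[NCHAIN], keto[NCHAIN];
  for (int i = 0; i < NCHAIN; ++i) {
    acyl[i] = std::max(y[1 + i], 0.0);
    enoyl[i] = std::max(y[8 + i], 0.0);
    keto[i] = std::max(y[15 + i], 0.0);
  }
  double ac = std::max(y[22], 0.0);
  double coa = std::max(y[23], 0.0);
  double carn = std::max(y[24], 0.0);

  v.zeros(34);
  int k = 0;

  // CPT1B: S_cyt + carnitine -> acylcarnitine C16, competitive malonyl-CoA
  {
    double s = S / p.km(E_CPT1B, 0);
    double den = 1.0 + s + M / p.ki_malonyl + ac16 / p.ki_acylcarnitine;
    double fcarn = carn / (p.km_carnitine + carn);
    v[k++] = VF * p.vmax[E_CPT1B] * (s / den) * fcarn;
  }
  // CACT/CPT2 lumped import: acylcarnitine + CoA -> acyl-CoA C16 + carnitine
  {
    double s = ac16 / p.km(E_IMPORT, 0);
    double fcoa = coa / (p.km_coa_import + coa);
    v[k++] = VF * p.vmax[E_IMPORT] * (s / (1.0 + s)) * fcoa;
  }
  // acyl-CoA dehydrogenases, shared competitive denominator per enzyme
  const int acads[4] = { E_VLCAD, E_LCAD, E_MCAD, E_SCAD };
  for (int a = 0; a < 4; ++a) {
    int e = acads[a];
    double den = 1.0;
    for (int i = 0; i < NCHAIN; ++i)
      if (std::isfinite(p.km(e, i))) den += acyl[i] / p.km(e, i);
    for (int i = 0; i < NCHAIN; ++i) {
      if (!std::isfinite(p.km(e, i))) continue;
      v[k++] = VF * p.vmax[e] * (acyl[i] / p.km(e, i)) / den;
    }
  }
  // lumped hydratase + HAD on enoyl-CoAs
  {
    double den = 1.0;
    for (int i = 0; i < NCHAIN; ++i)
      if (std::isfinite(p.km(E_HYD, i))) den += enoyl[i] / p.km(E_HYD, i);
    for (int i = 0; i < NCHAIN; ++i) {
      if (!std::isfinite(p.km(E_HYD, i))) continue;
      v[k++] = VF * p.vmax[E_HYD] * (enoyl[i] / p.km(E_HYD, i)) / den;
    }
  }
  // thiolases: ketoacyl-CoA + CoA -> acyl-CoA(l-2) + acetyl-CoA
  const int thios[2] = { E_MTP, E_MCKAT };
  for (int a = 0; a < 2; ++a) {
    int e = thios[a];
    double den = 1.0;
    for (int i = 0; i < NCHAIN; ++i)
      if (std::isfinite(p.km(e, i))) den += keto[i] / p.km(e, i);
    double fcoa = coa / (p.km_coa_thiolase + coa);
    for (int i = 0; i < NCHAIN; ++i) {
      if (!std::isfinite(p.km(e, i))) continue;
      v[k++] = VF * p.vmax[e] * (keto[i] / p.km(e, i)) / den * fcoa;
    }
  }
  // first-order acetyl-CoA sink regenerating free CoA; k_sink is defined
  // at the reference volume factor (1e6 <-> 1 uL matrix water per mg), so
  // changing vol_factor rescales time uniformly across every step and
  // cancels out of all flux-control coefficients
  v[k++] = p.k_sink * (p.vol_factor * 1e-6) * ac;
  if (k != 34) stop("internal rate-count mismatch");
}

// chain masks must match bx_rates_core; columns of km carry them.
// full-space derivative (25 species)
static void bx_deriv_core(const arma::vec& y, double S, double M,
                          const BxPars& p, arma::vec& dy) {
  arma::vec v;
  bx_rates_core(y, S, M, p, v);
  dy.zeros(NDYN);
  int k = 0;
  // CPT1B
  dy[0] += v[k]; dy[24] -= v[k]; ++k;
  // import
  dy[0] -= v[k]; dy[23] -= v[k]; dy[1] += v[k]; dy[24] += v[k]; ++k;
  const int acads[4] = { E_VLCAD, E_LCAD, E_MCAD, E_SCAD };
  for (int a = 0; a < 4; ++a) {
    int e = acads[a];
    for (int i = 0; i < NCHAIN; ++i) {
      if (!std::isfinite(p.km(e, i))) continue;
      dy[1 + i] -= v[k]; dy[8 + i] += v[k]; ++k;
    }
  }
  for (int i = 0; i < NCHAIN; ++i) {
    if (!std::isfinite(p.km(E_HYD, i))) continue;
    dy[8 + i] -= v[k]; dy[15 + i] += v[k]; ++k;
  }
  const int thios[2] = { E_MTP, E_MCKAT };
  for (int a = 0; a < 2; ++a) {
    int e = thios[a];
    for (int i = 0; i < NCHAIN; ++i) {
      if (!std::isfinite(p.km(e, i))) continue;
      dy[15 + i] -= v[k]; dy[23] -= v[k];
      if (i < NCHAIN - 1) {          // C(l) -> C(l-2) + acetyl-CoA
        dy[1 + i + 1] += v[k]; dy[22] += v[k];
      } else {                       // C4 -> 2 acetyl-CoA
        dy[22] += 2.0 * v[k];
      }
      ++k;
    }
  }
  dy[22] -= v[k]; dy[23] += v[k]; ++k;  // sink
}

// reduced-space helpers -----------------------------------------------------

static void red_to_full(const arma::vec& yr, const BxPars& p, arma::vec& y) {
  y.set_size(NDYN);
  for (int i = 0; i < NRED; ++i) y[i] = yr[i];
  double esters = 0.0;
  for (int i = 1; i <= 22; ++i) esters += yr[i];
  y[23] = p.coa_total - esters;
  y[24] = p.carnitine_total - yr[0];
}

static void red_deriv(const arma::vec& yr, double S, double M,
                      const BxPars& p, arma::vec& f) {
  arma::vec y, dy;
  red_to_full(yr, p, y);
  bx_deriv_core(y, S, M, p, dy);
  f = dy.head(NRED);
}

static void red_jac(const arma::vec& yr, double S, double M, const BxPars& p,
                    const arma::vec& f0, arma::mat& J) {
  J.set_size(NRED, NRED);
  arma::vec yp = yr, f;
  for (int j = 0; j < NRED; ++j) {
    double h = 1e-7 * std::abs(yr[j]) + 1e-9;
    yp[j] = yr[j] + h;
    red_deriv(yp, S, M, p, f);
    J.col(j) = (f - f0) / h;
    yp[j] = yr[j];
  }
}

static void clamp_red(arma::vec& yr, const BxPars& p) {
  if (yr[0] < 0) yr[0] = 0;
  if (yr[0] > p.carnitine_total) yr[0] = p.carnitine_total;
  double esters = 0.0;
  for (int i = 1; i <= 22; ++i) {
    if (yr[i] < 0) yr[i] = 0;
    esters += yr[i];
  }
  if (esters > p.coa_total) {
    double sc = p.coa_total / esters;
    for (int i = 1; i <= 22; ++i) yr[i] *= sc;
  }
}

// exported ------------------------------------------------------------------

// [[Rcpp::export(name = ".bx_rates_cpp")]]
NumericVector bx_rates_cpp(NumericVector state, double S, double M, List pars) {
  BxPars p = unpack_pars(pars);
  if (state.size() != NDYN) stop("state must have 25 dynamic species");
  arma::vec y = as<arma::vec>(state), v;
  bx_rates_core(y, S, M, p, v);
  return wrap(v);
}

// [[Rcpp::export(name = ".bx_deriv_cpp")]]
NumericVector bx_deriv_cpp(NumericVector state, double S, double M, List pars) {
  BxPars p = unpack_pars(pars);
  if (state.size() != NDYN) stop("state must have 25 dynamic species");
  arma::vec y = as<arma::vec>(state), dy;
  bx_deriv_core(y, S, M, p, dy);
  return wrap(dy);
}

// Pseudo-transient continuation to quiescence plus a damped Newton polish.
// [[Rcpp::export(name = ".bx_steady_cpp")]]
List bx_steady_cpp(List pars, double S, double M,
                   Nullable<NumericVector> warm_start = R_NilValue,
                   double rtol = 1e-9, int max_iter = 5000,
                   double h_max = 1e10) {
  BxPars p = unpack_pars(pars);
  double scale = p.vol_factor * p.vmax.max() +
    p.k_sink * (p.vol_factor * 1e-6) * p.coa_total;
  if (scale <= 0) scale = 1.0;
  double tol_ptc = rtol * scale + 1e-12;
  double tol_polish = std::max(1e-13 * scale, 1e-13);

  arma::vec yr(NRED, arma::fill::zeros);
  if (warm_start.isNotNull()) {
    NumericVector w(warm_start);
    if (w.size() == NRED) yr = as<arma::vec>(w);
    else if (w.size() == NDYN) yr = as<arma::vec>(w).head(NRED);
    else stop("warm start must have 23 or 25 entries");
    clamp_red(yr, p);
  }

  arma::vec f, fnew, d;
  arma::mat J, A;
  red_deriv(yr, S, M, p, f);
  double nf = arma::norm(f, "inf");
  double h = 1e-4;
  int iter = 0;
  bool ok = true;

  while (nf > tol_ptc && iter < max_iter) {
    red_jac(yr, S, M, p, f, J);
    A = arma::eye(NRED, NRED) / h - J;
    bool solved = arma::solve(d, A, f, arma::solve_opts::no_approx);
    if (!solved) { h *= 0.25; ++iter; continue; }
    arma::vec ytry = yr + d;
    clamp_red(ytry, p);
    red_deriv(ytry, S, M, p, fnew);
    double nfn = arma::norm(fnew, "inf");
    if (std::isfinite(nfn) && nfn <= 3.0 * nf) {
      yr = ytry; f = fnew; nf = nfn;
      h = std::min(h * 2.0, h_max);
    } else {
      h *= 0.25;
      if (h < 1e-14) { ok = false; break; }
    }
    ++iter;
  }

  // Newton polish towards machine-level residuals
  int polish = 0;
  while (nf > tol_polish && polish < 50) {
    red_jac(yr, S, M, p, f, J);
    bool solved = arma::solve(d, J, -f, arma::solve_opts::no_approx);
    if (!solved) break;
    double lambda = 1.0;
    bool improved = false;
    for (int ls = 0; ls < 12; ++ls) {
      arma::vec ytry = yr + lambda * d;
      clamp_red(ytry, p);
      red_deriv(ytry, S, M, p, fnew);
      double nfn = arma::norm(fnew, "inf");
      if (std::isfinite(nfn) && nfn < nf) {
        yr = ytry; f = fnew; nf = nfn; improved = true; break;
      }
      lambda *= 0.5;
    }
    if (!improved) break;
    ++polish;
  }

  bool converged = ok && (nf <= tol_ptc);
  arma::vec y;
  red_to_full(yr, p, y);
  arma::vec v;
  bx_rates_core(y, S, M, p, v);
  double Jflux = v[0] / p.vol_factor;  // CPT1 rate, umol/min/mg

  return List::create(
    _["state"] = wrap(y),
    _["flux"] = Jflux,
    _["acylcarnitine_C16"] = y[0],
    _["residual"] = nf,
    _["converged"] = converged,
    _["iterations"] = iter + polish);
}

// Fixed-step classical RK4 on the FULL 25-species system; used to verify
// moiety conservation independently of the reduced-coordinate solver.
// [[Rcpp::export(name = ".bx_traj_cpp")]]
NumericMatrix bx_traj_cpp(NumericVector state0, double S, double M, List pars,
                          NumericVector times, int substeps = 20) {
  BxPars p = unpack_pars(pars);
  if (state0.size() != NDYN) stop("state must have 25 dynamic species");
  int nt = times.size();
  arma::vec y = as<arma::vec>(state0);
  NumericMatrix out(nt, NDYN);
  arma::vec k1, k2, k3, k4;
  for (int j = 0; j < NDYN; ++j) out(0, j) = y[j];
  for (int t = 1; t < nt; ++t) {
    double dt = (times[t] - times[t - 1]) / substeps;
    for (int s = 0; s < substeps; ++s) {
      bx_deriv_core(y, S, M, p, k1);
      bx_deriv_core(y + 0.5 * dt * k1, S, M, p, k2);
      bx_deriv_core(y + 0.5 * dt * k2, S, M, p, k3);
      bx_deriv_core(y + dt * k3, S, M, p, k4);
      y += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    }
    for (int j = 0; j < NDYN; ++j) out(t, j) = y[j];
  }
  return out;
}
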