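// Two-compartment disposition under piecewise-constant infusion input and
// the per-subject FOCE-I machinery (conditional-mode search, linearization).
// Units: amounts mg, volumes L, clearances L/h, times h, concentrations ng/mL.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Hybrid {
  double k10, k12, k21, l1, l2;
};

static Hybrid hybrid_of(double CL, double V1, double Q, double V2) {
  Hybrid h;
  h.k10 = CL / V1;
  h.k12 = Q / V1;
  h.k21 = Q / V2;
  double S = h.k10 + h.k12 + h.k21;
  double P = h.k10 * h.k21;
  double disc = std::sqrt(std::max(S * S - 4.0 * P, 0.0));
  h.l1 = 0.5 * (S + disc);
  h.l2 = 0.5 * (S - disc);
  if (h.l2 <= 0.0) h.l2 = 1e-300;  // unreachable for strictly positive params
  return h;
}

// Central-compartment concentration (mg/L) per unit infusion rate (mg/h),
// s hours after the infusion started (still running). Zero for s <= 0.
// Near-degenerate hybrid roots use the repeated-root limit g'(lambda) of
// [g(l1)-g(l2)]/(l1-l2) with g(l) = (l-k21)(1-exp(-l s))/l.
static double inf_unit(const Hybrid& h, double V1, double s) {
  if (s <= 0.0) return 0.0;
  const double l1 = h.l1, l2 = h.l2, k21 = h.k21;
  if ((l1 - l2) < 1e-8 * l1) {
    double l = 0.5 * (l1 + l2);
    double e = std::exp(-l * s);
    return ((k21 / (l * l)) * (1.0 - e) + (1.0 - k21 / l) * s * e) / V1;
  }
  double a1 = (l1 - k21) / (l1 * (l1 - l2));
  double a2 = (k21 - l2) / (l2 * (l1 - l2));
  return (a1 * (1.0 - std::exp(-l1 * s)) + a2 * (1.0 - std::exp(-l2 * s))) / V1;
}

static double conc_one(const Hybrid& h, double V1, double t,
                       const arma::vec& st, const arma::vec& rate,
                       const arma::vec& dur) {
  double c = 0.0;
  for (arma::uword e = 0; e < st.n_elem; ++e) {
    c += rate(e) * (inf_unit(h, V1, t - st(e)) -
                    inf_unit(h, V1, t - st(e) - dur(e)));
  }
  return std::max(c, 0.0) * 1000.0;  // mg/L -> ng/mL
}

// [[Rcpp::export(name = ".conc2_cpp")]]
arma::vec conc2_cpp(double CL, double V1, double Q, double V2,
                    const arma::vec& starts, const arma::vec& rates,
                    const arma::vec& durations, const arma::vec& times) {
  Hybrid h = hybrid_of(CL, V1, Q, V2);
  arma::vec out(times.n_elem);
  for (arma::uword i = 0; i < times.n_elem; ++i)
    out(i) = conc_one(h, V1, times(i), starts, rates, durations);
  return out;
}

// ---- FOCE-I per subject ---------------------------------------------------

struct SubjData {
  arma::vec y, times, st, rate, dur;
  arma::vec tp;        // typical params after covariate multipliers (CL,V1,Q,V2)
  arma::uvec iiv;      // 0-based indices into tp that carry an eta
  arma::vec om2;       // diagonal omega^2, length = iiv.n_elem
  double sp, sa;       // proportional / additive residual SD
};

static arma::vec pred_f(const SubjData& d, const arma::vec& eta) {
  arma::vec p = d.tp;
  for (arma::uword k = 0; k < d.iiv.n_elem; ++k)
    p(d.iiv(k)) *= std::exp(eta(k));
  Hybrid h = hybrid_of(p(0), p(1), p(2), p(3));
  arma::vec f(d.y.n_elem);
  for (arma::uword i = 0; i < d.y.n_elem; ++i)
    f(i) = conc_one(h, p(1), d.times(i), d.st, d.rate, d.dur);
  return f;
}

static arma::vec var_of(const SubjData& d, const arma::vec& f) {
  arma::vec v = arma::square(d.sp * f) + d.sa * d.sa;
  v.transform([](double x) { return std::max(x, 1e-10); });
  return v;
}

// Conditional (joint-density) objective: -2 log p(y|eta) - 2 log p(eta), no 2*pi
static double eta_obj(const SubjData& d, const arma::vec& eta) {
  arma::vec f = pred_f(d, eta);
  if (!f.is_finite()) return 1e30;
  arma::vec v = var_of(d, f);
  double s = arma::accu(arma::log(v) + arma::square(d.y - f) / v);
  for (arma::uword k = 0; k < eta.n_elem; ++k)
    s += eta(k) * eta(k) / d.om2(k);
  return s;
}

// Newton search with finite-difference derivatives and step halving.
static arma::vec eta_mode(const SubjData& d, const arma::vec& start, bool& ok) {
  const arma::uword m = start.n_elem;
  const double hstep = 1e-4;
  arma::vec eta = start;
  double fcur = eta_obj(d, eta);
  {  // eta = 0 is always a candidate start
    arma::vec z(m, arma::fill::zeros);
    double f0 = eta_obj(d, z);
    if (f0 < fcur) { eta = z; fcur = f0; }
  }
  ok = true;
  for (int it = 0; it < 60; ++it) {
    arma::vec g(m);
    arma::mat H(m, m);
    for (arma::uword i = 0; i < m; ++i) {
      arma::vec ep = eta, em = eta;
      ep(i) += hstep; em(i) -= hstep;
      double fp = eta_obj(d, ep), fm = eta_obj(d, em);
      g(i) = (fp - fm) / (2.0 * hstep);
      H(i, i) = (fp - 2.0 * fcur + fm) / (hstep * hstep);
    }
    for (arma::uword i = 0; i < m; ++i)
      for (arma::uword j = i + 1; j < m; ++j) {
        arma::vec epp = eta, epm = eta, emp = eta, emm = eta;
        epp(i) += hstep; epp(j) += hstep;
        epm(i) += hstep; epm(j) -= hstep;
        emp(i) -= hstep; emp(j) += hstep;
        emm(i) -= hstep; emm(j) -= hstep;
        H(i, j) = H(j, i) = (eta_obj(d, epp) - eta_obj(d, epm) -
                             eta_obj(d, emp) + eta_obj(d, emm)) /
                            (4.0 * hstep * hstep);
      }
    if (arma::norm(g, "inf") < 1e-7) break;
    arma::vec step;
    double ridge = 0.0;
    for (int tries = 0; tries < 8; ++tries) {
      arma::mat Hr = H + ridge * arma::eye(m, m);
      if (arma::rcond(Hr) > 1e-12 &&
          arma::solve(step, Hr, g, arma::solve_opts::no_approx) &&
          arma::dot(step, g) > 0.0)
        break;
      ridge = (ridge == 0.0) ? 1e-4 : ridge * 10.0;
      step.reset();
    }
    if (step.n_elem == 0) step = g / std::max(arma::norm(g), 1.0);
    double lam = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 25; ++ls) {
      arma::vec cand = eta - lam * step;
      double fc = eta_obj(d, cand);
      if (fc < fcur) { eta = cand; fcur = fc; moved = true; break; }
      lam *= 0.5;
    }
    if (!moved) break;
    if (lam * arma::norm(step, "inf") < 1e-9) break;
  }
  if (!std::isfinite(fcur)) ok = false;
  return eta;
}

// FOCE-I contribution for one subject; optionally returns the linearization.
static List subject_core(const SubjData& d, const arma::vec& eta_start,
                         bool detail) {
  const arma::uword m = d.iiv.n_elem;
  const arma::uword n = d.y.n_elem;
  if (m == 0) {
    arma::vec f = pred_f(d, arma::vec());
    arma::vec v = var_of(d, f);
    double obj = arma::accu(arma::log(v) + arma::square(d.y - f) / v);
    List out = List::create(_["obj"] = obj, _["eta"] = arma::vec(),
                            _["ok"] = true);
    if (detail) {
      out["f"] = f; out["G"] = arma::mat(n, 0); out["v"] = v;
      out["C"] = arma::diagmat(v);
    }
    return out;
  }
  bool ok = true;
  arma::vec eta = eta_mode(d, eta_start, ok);
  arma::vec f = pred_f(d, eta);
  if (!f.is_finite()) {
    return List::create(_["obj"] = 1e10, _["eta"] = eta, _["ok"] = false);
  }
  arma::vec v = var_of(d, f);  // interaction: residual variance at the mode
  const double gh = 1e-4;
  arma::mat G(n, m);
  for (arma::uword k = 0; k < m; ++k) {
    arma::vec ep = eta, em = eta;
    ep(k) += gh; em(k) -= gh;
    G.col(k) = (pred_f(d, ep) - pred_f(d, em)) / (2.0 * gh);
  }
  arma::mat C = G * arma::diagmat(d.om2) * G.t() + arma::diagmat(v);
  C = 0.5 * (C + C.t());
  if (!C.is_finite()) {
    return List::create(_["obj"] = 1e10, _["eta"] = eta, _["ok"] = false);
  }
  arma::vec r = d.y - f + G * eta;
  arma::mat L;
  if (!arma::chol(L, C, "lower")) {
    ok = false;
    C += 1e-8 * arma::eye(n, n);
    arma::chol(L, C, "lower");
  }
  arma::vec z = arma::solve(arma::trimatl(L), r, arma::solve_opts::fast);
  double obj = 2.0 * arma::accu(arma::log(L.diag())) + arma::dot(z, z);
  List out = List::create(_["obj"] = obj, _["eta"] = eta, _["ok"] = ok);
  if (detail) {
    out["f"] = f; out["G"] = G; out["v"] = v; out["C"] = C;
  }
  return out;
}

static SubjData unpack(const List& s, const arma::vec& tp,
                       const arma::uvec& iiv, const arma::vec& om2,
                       double sp, double sa) {
  SubjData d;
  d.y = as<arma::vec>(s["y"]);
  d.times = as<arma::vec>(s["times"]);
  d.st = as<arma::vec>(s["starts"]);
  d.rate = as<arma::vec>(s["rates"]);
  d.dur = as<arma::vec>(s["durations"]);
  d.tp = tp; d.iiv = iiv; d.om2 = om2; d.sp = sp; d.sa = sa;
  return d;
}

// subjects: list of list(y, times, starts, rates, durations)
// tpmat: n_subject x 4 matrix of covariate-adjusted typical values
// iiv: 0-based indices of parameters with IIV; om2: their variances
// eta_start: n_subject x m warm-start matrix
// [[Rcpp::export(name = ".foce_ofv_cpp")]]
List foce_ofv_cpp(const List& subjects, const arma::mat& tpmat,
                  const arma::uvec& iiv, const arma::vec& om2,
                  double sp, double sa, const arma::mat& eta_start) {
  const int ns = subjects.size();
  const arma::uword m = iiv.n_elem;
  arma::mat etas(ns, m, arma::fill::zeros);
  double ofv = 0.0;
  bool all_ok = true;
  for (int i = 0; i < ns; ++i) {
    SubjData d = unpack(subjects[i], tpmat.row(i).t(), iiv, om2, sp, sa);
    arma::vec e0 = (m > 0) ? eta_start.row(i).t() : arma::vec();
    List res = subject_core(d, e0, false);
    double obj = as<double>(res["obj"]);
    if (!std::isfinite(obj)) { all_ok = false; obj = 1e10; }
    ofv += obj;
    if (m > 0) etas.row(i) = as<arma::vec>(res["eta"]).t();
    if (!as<bool>(res["ok"])) all_ok = false;
  }
  return List::create(_["ofv"] = ofv, _["eta"] = etas, _["ok"] = all_ok);
}

// Per-subject detail (f at the mode, gradient G, residual variance, C) used
// for CWRES and shrinkage reporting.
// [[Rcpp::export(name = ".foce_subject_cpp")]]
List foce_subject_cpp(const List& subject, const arma::vec& tp,
                      const arma::uvec& iiv, const arma::vec& om2,
                      double sp, double sa, const arma::vec& eta_start) {
  SubjData d = unpack(subject, tp, iiv, om2, sp, sa);
  return subject_core(d, eta_start, true);
}
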