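// Piecewise-linear solver for the EpoR trafficking models.
//
// For piecewise-constant extracellular Epo, bleach pulses and synthesis
// switches, every model in the family is a linear ODE system
//   dy/dt = K y + b            (core species)
//   dc/dt = C y                (cumulative bookkeeping species)
// with (K, b, C) constant on each protocol segment.  Each segment is solved
// exactly through the eigendecomposition K = V diag(lambda) V^-1:
//   y(t)   = Re[ V ( e^{lambda t} .* a + phi(lambda,t) .* g ) ]
//   c(t)   = c0 + Re[ C V ( phi(lambda,t) .* a + psi(lambda,t) .* g ) ]
// with a = V^-1 y0, g = V^-1 b, phi = (e^{lt}-1)/l, psi = (e^{lt}-1-lt)/l^2
// (series limits near l = 0, so singular K needs no special casing).
// Defective K (ill-conditioned V) is reported via ok = false and handled by
// the lsoda fallback on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::cx_double;

// parameter slots (natural scale; structurally absent rates are zero)
enum Par {
  P_KON = 0, P_KOFF, P_KSYN, P_KDEG, P_KITOM, P_KMTOI,
  P_KMTORE, P_KRETOM, P_KRETOI, P_KDEGEX, P_KDEGI, P_KBLEACH
};

static cx_double phi_fun(const cx_double l, const double t) {
  if (std::abs(l) * t < 1e-10) return cx_double(t, 0.0) * (1.0 + l * t / 2.0);
  return (std::exp(l * t) - 1.0) / l;
}

static cx_double psi_fun(const cx_double l, const double t) {
  if (std::abs(l) * t < 1e-7)
    return cx_double(t * t / 2.0, 0.0) * (1.0 + l * t / 3.0);
  return (std::exp(l * t) - 1.0 - l * t) / (l * l);
}

// Build segment system. condition: 0 epo, 1 bleach, 2 chx.
static void build_system(const arma::vec& p, const int condition,
                         const double epo, const bool bleach_on,
                         const bool syn_on,
                         arma::mat& K, arma::vec& b, arma::mat& C) {
  const double kon = p[P_KON], koff = p[P_KOFF], ksyn = p[P_KSYN],
               kdeg = p[P_KDEG], kitom = p[P_KITOM], kmtoi = p[P_KMTOI],
               kmtore = p[P_KMTORE], kretom = p[P_KRETOM],
               kretoi = p[P_KRETOI], kdegex = p[P_KDEGEX], kdegi = p[P_KDEGI],
               kb = bleach_on ? p[P_KBLEACH] : 0.0;

  K.zeros(4, 4);
  b.zeros(4);
  C.zeros(3, 4);

  // core states: 0 EpoR_i, 1 EpoR_m, 2 EpoR*_m, 3 EpoR*_RE
  K(0, 0) = -(kdeg + kitom + kb);
  K(0, 1) = kmtoi;
  K(0, 3) = kretoi;                       // part B: recycling to the pool
  K(1, 0) = kitom;
  K(1, 1) = -(kmtoi + kon * epo + kb);
  K(1, 2) = koff;
  K(1, 3) = kretom;                       // part A: direct recycling
  K(2, 1) = kon * epo;
  K(2, 2) = -(koff + kmtore);
  K(3, 2) = kmtore;
  K(3, 3) = -(kretom + kretoi + kdegex + kdegi);

  if (syn_on) b(0) = ksyn;

  // cumulative rows: 0 Epo_deg_i, 1 Epo_deg_ext, 2 condition bookkeeping
  C(0, 3) = kretoi + kdegi;               // parts B and D accumulate Epo
  C(1, 3) = kdegex;                       // part C exports degraded Epo
  if (condition == 0) {
    C(2, 3) = kretom;                     // intact Epo released via part A
  } else if (condition == 1) {
    C(2, 0) = kb;                         // bleached (dark) receptor pool
    C(2, 1) = kb;
  } else {
    C(2, 0) = kdeg;                       // receptor degraded after CHX
  }
}

// [[Rcpp::export]]
Rcpp::List solve_traffic_cpp(const arma::vec& times, const arma::vec& y0,
                             const arma::vec& cum0, const arma::vec& params,
                             const int condition, const double epo_conc,
                             const double add_time, const double bleach_start,
                             const double bleach_end, const double chx_time) {
  const arma::uword nt = times.n_elem;
  arma::mat out(nt, 7);
  bool ok = true;

  // segment boundaries from protocol events inside the sampled window
  std::vector<double> bounds;
  bounds.push_back(times[0]);
  const double t_end = times[nt - 1];
  auto push_event = [&](double e) {
    if (e > times[0] && e < t_end) bounds.push_back(e);
  };
  if (condition == 0) push_event(add_time);
  if (condition == 1) { push_event(bleach_start); push_event(bleach_end); }
  if (condition == 2) push_event(chx_time);
  bounds.push_back(t_end);
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());

  arma::vec y = y0, cum = cum0;
  arma::uword it = 0;
  // samples at an event time belong to the pre-event segment
  while (it < nt && times[it] <= bounds[0]) {
    out(it, 0) = y(0); out(it, 1) = y(1); out(it, 2) = y(2); out(it, 3) = y(3);
    out(it, 4) = cum(0); out(it, 5) = cum(1); out(it, 6) = cum(2);
    ++it;
  }

  for (size_t s = 0; s + 1 < bounds.size() && ok; ++s) {
    const double t0 = bounds[s], t1 = bounds[s + 1];
    const double tm = 0.5 * (t0 + t1);
    const double epo = (condition == 0 && tm > add_time) ? epo_conc : 0.0;
    const bool bleach_on = (condition == 1 && tm > bleach_start && tm < bleach_end);
    const bool syn_on = !(condition == 2 && tm > chx_time);

    arma::mat K, C;
    arma::vec b;
    build_system(params, condition, epo, bleach_on, syn_on, K, b, C);

    arma::cx_vec lambda;
    arma::cx_mat V;
    if (!arma::eig_gen(lambda, V, K)) { ok = false; break; }
    if (arma::rcond(V) < 1e-12) { ok = false; break; }

    const arma::cx_vec a = arma::solve(V, arma::cx_vec(y, arma::vec(4, arma::fill::zeros)));
    const arma::cx_vec g = arma::solve(V, arma::cx_vec(b, arma::vec(4, arma::fill::zeros)));
    const arma::cx_mat CV = arma::cx_mat(C, arma::mat(3, 4, arma::fill::zeros)) * V;

    auto eval = [&](double tau, arma::vec& yt, arma::vec& ct) {
      arma::cx_vec e(4), ph(4), ps(4);
      for (arma::uword k = 0; k < 4; ++k) {
        e(k) = std::exp(lambda(k) * tau);
        ph(k) = phi_fun(lambda(k), tau);
        ps(k) = psi_fun(lambda(k), tau);
      }
      yt = arma::real(V * (e % a + ph % g));
      ct = cum + arma::real(CV * (ph % a + ps % g));
    };

    arma::vec yt(4), ct(3);
    while (it < nt && times[it] <= t1) {
      eval(times[it] - t0, yt, ct);
      out(it, 0) = yt(0); out(it, 1) = yt(1);
      out(it, 2) = yt(2); out(it, 3) = yt(3);
      out(it, 4) = ct(0); out(it, 5) = ct(1); out(it, 6) = ct(2);
      ++it;
    }
    eval(t1 - t0, yt, ct);   // advance to the segment end
    y = yt;
    cum = ct;
    if (!y.is_finite() || !cum.is_finite()) { ok = false; break; }
  }

  return Rcpp::List::create(Rcpp::Named("states") = out,
                            Rcpp::Named("ok") = ok);
}

// Weighted residuals of one cell's data block: solve, map states to the
// condition's observables, scale, apply the error model and subtract.
// mask holds 0-based column-major indices into the times x observables
// matrix. On solver failure a large constant residual is returned so the
// optimizer backs away from the degenerate region.
// [[Rcpp::export]]
arma::vec cell_resid_cpp(const arma::vec& times, const arma::vec& init2,
                         const arma::vec& params, const int condition,
                         const double epo_conc, const double add_time,
                         const double bleach_start, const double bleach_end,
                         const double chx_time, const arma::mat& Y,
                         const arma::uvec& mask, const arma::vec& scales,
                         const double sigma_rel, const arma::vec& floor_v,
                         const arma::vec& abs_v) {
  arma::vec y0 = {init2[0], init2[1], 0.0, 0.0};
  arma::vec cum0(3, arma::fill::zeros);
  Rcpp::List sol = solve_traffic_cpp(times, y0, cum0, params, condition,
                                     epo_conc, add_time, bleach_start,
                                     bleach_end, chx_time);
  if (!Rcpp::as<bool>(sol["ok"]))
    return arma::vec(mask.n_elem, arma::fill::value(1e6));
  arma::mat S = Rcpp::as<arma::mat>(sol["states"]);
  const arma::uword nt = S.n_rows;
  arma::mat pred;
  if (condition == 0) {
    pred.set_size(nt, 5);
    pred.col(0) = S.col(1) + S.col(2);        // membrane GFP
    pred.col(1) = S.col(0);                   // vesicular GFP
    pred.col(2) = S.col(3);                   // GFP in Epo vesicles
    pred.col(3) = S.col(2);                   // membrane Cy5.5
    pred.col(4) = S.col(3) + S.col(4);        // cytoplasmic Cy5.5
  } else {
    pred.set_size(nt, 2);
    pred.col(0) = S.col(1);
    pred.col(1) = S.col(0);
  }
  for (arma::uword j = 0; j < pred.n_cols; ++j) pred.col(j) *= scales[j];
  if (!pred.is_finite())
    return arma::vec(mask.n_elem, arma::fill::value(1e6));
  arma::vec out(mask.n_elem);
  for (arma::uword k = 0; k < mask.n_elem; ++k) {
    const arma::uword idx = mask[k];
    const arma::uword j = idx / nt;
    const double pv = pred[idx];
    const double sig = sigma_rel * std::max(pv, floor_v[j]) + abs_v[j];
    out[k] = (Y[idx] - pv) / sig;
  }
  return out;
}
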