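// Stiff integrator for the anti-CD66 PBPK system.
//
// The model ODE has the structure
//   dy/dt = A y + sum_t c_t * y[i_t] * AgFree_{o_t}(y) * (e_{j_t} - e_{i_t})
// where A collects every linear process (blood-flow transport, dissociation,
// degradation, delay return, metabolite exchange, physical decay/relabeling)
// and the nonlinear terms are the saturable association fluxes, bilinear in
// the source amount y[i] and the free antigen of the target organ,
//   AgFree_o(y) = max(Ag_o - w_o' y, 0),
// with w_o the occupancy weights (1 per monovalently, 2 per bivalently bound
// antibody). The Jacobian is therefore available in closed form, which makes
// a Rosenbrock method natural. We use the Kaps-Rentrop 4(3) pair with the
// Shampine parameter set and a dense LU per step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct System {
  const mat& A;
  const uvec& ai;   // association source index (0-based)
  const uvec& aj;   // association target index
  const uvec& ao;   // association organ index
  const vec& ac;    // association coefficient (1/min per nmol of antigen)
  const mat& occw;  // n_state x n_organ occupancy weights
  const vec& Ag;    // total antigen per organ (nmol)
  std::vector<uvec> osup; // support of occw per organ

  System(const mat& A_, const uvec& ai_, const uvec& aj_, const uvec& ao_,
         const vec& ac_, const mat& occw_, const vec& Ag_)
      : A(A_), ai(ai_), aj(aj_), ao(ao_), ac(ac_), occw(occw_), Ag(Ag_) {
    for (uword o = 0; o < occw.n_cols; ++o) osup.push_back(find(occw.col(o)));
  }

  vec agfree(const vec& y) const {
    vec ag = Ag - occw.t() * y;
    return clamp(ag, 0.0, datum::inf);
  }

  vec f(const vec& y) const {
    vec out = A * y;
    vec ag = agfree(y);
    for (uword t = 0; t < ac.n_elem; ++t) {
      double flux = ac[t] * y[ai[t]] * ag[ao[t]];
      out[aj[t]] += flux;
      out[ai[t]] -= flux;
    }
    return out;
  }

  void jac(const vec& y, mat& J) const {
    J = A;
    vec ag = agfree(y);
    for (uword t = 0; t < ac.n_elem; ++t) {
      const uword i = ai[t], j = aj[t], o = ao[t];
      const double c = ac[t];
      J(j, i) += c * ag[o];
      J(i, i) -= c * ag[o];
      if (ag[o] > 0.0) {
        const double cy = c * y[i];
        const uvec& sup = osup[o];
        for (uword s = 0; s < sup.n_elem; ++s) {
          const uword k = sup[s];
          const double w = occw(k, o);
          J(j, k) -= cy * w;
          J(i, k) += cy * w;
        }
      }
    }
  }
};

// Kaps-Rentrop 4(3), Shampine parameters (as in Press et al.)
const double GAM = 0.5;
const double A21 = 2.0, A31 = 48.0 / 25.0, A32 = 6.0 / 25.0;
const double C21 = -8.0, C31 = 372.0 / 25.0, C32 = 12.0 / 5.0;
const double C41 = -112.0 / 125.0, C42 = -54.0 / 125.0, C43 = -2.0 / 5.0;
const double B1 = 19.0 / 9.0, B2 = 1.0 / 2.0, B3 = 25.0 / 108.0,
             B4 = 125.0 / 108.0;
const double E1 = 17.0 / 54.0, E2 = 7.0 / 36.0, E3 = 0.0, E4 = 125.0 / 108.0;

} // namespace

// [[Rcpp::export(name = ".pbpk_rhs_eval")]]
arma::vec pbpk_rhs_eval(const arma::mat& A, const arma::uvec& ai,
                        const arma::uvec& aj, const arma::uvec& ao,
                        const arma::vec& ac, const arma::mat& occw,
                        const arma::vec& Ag, const arma::vec& y) {
  System sys(A, ai, aj, ao, ac, occw, Ag);
  return sys.f(y);
}

// [[Rcpp::export(name = ".pbpk_jac_eval")]]
arma::mat pbpk_jac_eval(const arma::mat& A, const arma::uvec& ai,
                        const arma::uvec& aj, const arma::uvec& ao,
                        const arma::vec& ac, const arma::mat& occw,
                        const arma::vec& Ag, const arma::vec& y) {
  System sys(A, ai, aj, ao, ac, occw, Ag);
  mat J(y.n_elem, y.n_elem);
  sys.jac(y, J);
  return J;
}

// Integrate from tout[0] through every requested output time.
// Returns states and derivatives at the output times.
// [[Rcpp::export(name = ".pbpk_integrate")]]
Rcpp::List pbpk_integrate(const arma::mat& A, const arma::uvec& ai,
                          const arma::uvec& aj, const arma::uvec& ao,
                          const arma::vec& ac, const arma::mat& occw,
                          const arma::vec& Ag, const arma::vec& y0,
                          const arma::vec& tout, double rtol, double atol,
                          int max_steps) {
  System sys(A, ai, aj, ao, ac, occw, Ag);
  const uword n = y0.n_elem;
  const uword nt = tout.n_elem;
  mat Y(nt, n), F(nt, n);

  vec y = y0;
  Y.row(0) = y.t();
  F.row(0) = sys.f(y).t();

  double t = tout[0];
  const double span = tout[nt - 1] - tout[0];
  double h = std::min(1e-2, span > 0 ? span / 100.0 : 1e-2);
  long nstep = 0, nreject = 0;

  mat J(n, n), L, U;
  uword iout = 1;

  while (iout < nt) {
    const double tend = tout[iout];
    if (tend <= t + 1e-12 * std::max(1.0, std::abs(t))) {
      // duplicate/zero-length interval
      Y.row(iout) = y.t();
      F.row(iout) = sys.f(y).t();
      ++iout;
      continue;
    }
    bool hit = false;
    const double hfree = h; // step size before truncation to the output point
    if (h >= tend - t) {
      h = tend - t;
      hit = true;
    }

    vec f0 = sys.f(y);
    sys.jac(y, J);
    mat W = -J;
    W.diag() += 1.0 / (GAM * h);
    mat P;
    bool ok = lu(L, U, P, W);
    if (!ok || !U.diag().is_finite() || arma::abs(U.diag()).min() == 0.0)
      Rcpp::stop("PBPK integrator: singular iteration matrix at t = %f", t);

    auto wsolve = [&](const vec& b) -> vec {
      return solve(trimatu(U), solve(trimatl(L), P * b,
                                     solve_opts::fast),
                   solve_opts::fast);
    };

    vec g1 = wsolve(f0);
    vec f1 = sys.f(y + A21 * g1);
    vec g2 = wsolve(f1 + C21 * g1 / h);
    vec f2 = sys.f(y + A31 * g1 + A32 * g2);
    vec g3 = wsolve(f2 + (C31 * g1 + C32 * g2) / h);
    vec g4 = wsolve(f2 + (C41 * g1 + C42 * g2 + C43 * g3) / h);

    vec ynew = y + B1 * g1 + B2 * g2 + B3 * g3 + B4 * g4;
    vec errv = E1 * g1 + E2 * g2 + E3 * g3 + E4 * g4;

    if (!ynew.is_finite())
      Rcpp::stop("PBPK integrator: non-finite state at t = %f (step %f)", t, h);

    vec sc = atol + rtol * max(abs(y), abs(ynew));
    double err = std::sqrt(mean(square(errv / sc)));

    if (err <= 1.0 || h <= 1e-10 * std::max(1.0, std::abs(t))) {
      t += h;
      y = ynew;
      if (hit) {
        Y.row(iout) = y.t();
        F.row(iout) = sys.f(y).t();
        ++iout;
      }
      double fac = (err > 0) ? 0.9 * std::pow(err, -0.25) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
      if (hit) h = std::max(h, hfree); // do not let output points shrink steps
    } else {
      ++nreject;
      double fac = 0.9 * std::pow(err, -1.0 / 3.0);
      h *= std::min(0.9, std::max(0.1, fac));
    }
    if (++nstep > max_steps)
      Rcpp::stop("PBPK integrator: step budget (%d) exhausted at t = %f",
                 max_steps, t);
  }

  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("f") = F,
                            Rcpp::Named("nstep") = (double)nstep,
                            Rcpp::Named("nreject") = (double)nreject);
}
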