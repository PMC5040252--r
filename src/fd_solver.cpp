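// Finite-difference kernels for the 1D transwell migration model.
//
// Mesh layout (0-based here; R passes 1-based m): nodes ordered top to
// bottom, membrane duplicated into an upper trace (index m) and a lower
// trace (m + 1) sharing the coordinate x_M. Interior nodes evolve by an
// IMEX scheme: implicit central diffusion, explicit centred advection with
// a |V|-weighted artificial-viscosity correction, explicit reaction.
// Boundary and membrane rows are algebraic constraint equations assembled
// into the implicit solve with their nonlinear coefficients (chemotactic
// velocity, Kedem-Katchalsky transmission) frozen at the previous level.
// The resulting band system (kl = ku = 2) is solved by LAPACK dgbsv.

#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Par {
  double Du, Dphi, chi1, chi2, Vt, a1, a2, a3, phibar, delta;
  double ku1, ku2, ku3, kphi, p, xbar_off, xM;
};

Par unpack(const NumericVector& pv) {
  Par P;
  P.Du = pv["D_u"]; P.Dphi = pv["D_phi"]; P.chi1 = pv["chi1"];
  P.chi2 = pv["chi2"]; P.Vt = pv["V_transp"]; P.a1 = pv["alpha1"];
  P.a2 = pv["alpha2"]; P.a3 = pv["alpha3"]; P.phibar = pv["phi_bar"];
  P.delta = pv["delta"]; P.ku1 = pv["k_u1"]; P.ku2 = pv["k_u2"];
  P.ku3 = pv["k_u3"]; P.kphi = pv["k_phi"]; P.p = pv["p_crowd"];
  P.xbar_off = pv["x_bar_offset"]; P.xM = pv["x_M"];
  return P;
}

inline double chi_of(double phi, const Par& P) {
  return P.chi1 * phi / (P.chi2 + phi);
}

// spreading weight W(x): 0 above xbar, smooth bump up to the membrane, 1 below
inline double w_of(double x, const Par& P) {
  const double xbar = P.xM - P.xbar_off;
  if (x <= xbar) return 0.0;
  if (x > P.xM) return 1.0;
  const double d2 = P.xbar_off * P.xbar_off;
  const double r = x - P.xM;
  return std::exp(-d2 / (d2 - r * r) + 1.0);
}

// trapezoid over the lower chamber (indices m+1 .. n-1)
inline double trapz_lower(const double* x, const double* f, int m, int n) {
  double s = 0.0;
  for (int i = m + 1; i < n - 1; ++i)
    s += (x[i + 1] - x[i]) * (f[i] + f[i + 1]) * 0.5;
  return s;
}

inline double trapz_upper(const double* x, const double* f, int m) {
  double s = 0.0;
  for (int i = 0; i < m; ++i)
    s += (x[i + 1] - x[i]) * (f[i] + f[i + 1]) * 0.5;
  return s;
}

// band storage for dgbsv: kl = ku = 2, ldab = 7, A(i,j) -> ab[(4+i-j) + 7*j]
struct BandSys {
  int n;
  std::vector<double> ab, b;
  std::vector<int> ipiv;
  explicit BandSys(int n_) : n(n_), ab(7 * n_), b(n_), ipiv(n_) {}
  void reset() {
    std::fill(ab.begin(), ab.end(), 0.0);
    std::fill(b.begin(), b.end(), 0.0);
  }
  inline void set(int i, int j, double v) { ab[(4 + i - j) + 7 * j] = v; }
  void solve(const char* what) {
    int kl = 2, ku = 2, nrhs = 1, ldab = 7, info = 0;
    F77_CALL(dgbsv)(&n, &kl, &ku, &nrhs, ab.data(), &ldab, ipiv.data(),
                    b.data(), &n, &info);
    if (info != 0)
      stop("%s: singular implicit system (dgbsv info = %d)", what, info);
  }
};

void check_nonneg(const std::vector<double>& f, int n, const char* what,
                  double neg_tol) {
  double mx = 1.0;
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(f[i])) stop("%s: non-finite value at node %d", what, i + 1);
    if (f[i] > mx) mx = f[i];
  }
  const double tol = -neg_tol * mx;
  for (int i = 0; i < n; ++i)
    if (f[i] < tol)
      stop("%s: negative value %g at node %d exceeds round-off tolerance; "
           "reduce dt to restore stability and non-negativity", what, f[i], i + 1);
}

// one implicit step of the serum equation
void step_phi(int n, const double* x, int m, const double* u,
              const double* phi, const Par& P, double dt, BandSys& S) {
  S.reset();
  // outer one-sided zero-gradient rows (second order)
  S.set(0, 0, -3.0); S.set(0, 1, 4.0); S.set(0, 2, -1.0);
  S.set(n - 1, n - 1, 3.0); S.set(n - 1, n - 2, -4.0); S.set(n - 1, n - 3, 1.0);
  // membrane rows: D_phi dphi/dx = k_phi (phi_B - phi_T) from both sides
  {
    const double cu = P.Dphi / (2.0 * (x[m] - x[m - 1]));
    S.set(m, m - 2, cu); S.set(m, m - 1, -4.0 * cu);
    S.set(m, m, 3.0 * cu + P.kphi); S.set(m, m + 1, -P.kphi);
    const double cl = P.Dphi / (2.0 * (x[m + 2] - x[m + 1]));
    S.set(m + 1, m, P.kphi); S.set(m + 1, m + 1, -3.0 * cl - P.kphi);
    S.set(m + 1, m + 2, 4.0 * cl); S.set(m + 1, m + 3, -cl);
  }
  for (int i = 1; i < n - 1; ++i) {
    if (i == m || i == m + 1) continue;
    const double hm = x[i] - x[i - 1], hp = x[i + 1] - x[i];
    const double cm = 2.0 / ((hm + hp) * hm), cp = 2.0 / ((hm + hp) * hp);
    S.set(i, i - 1, -P.Dphi * cm);
    S.set(i, i, 1.0 / dt + P.Dphi * (cm + cp));
    S.set(i, i + 1, -P.Dphi * cp);
    S.b[i] = phi[i] / dt - P.delta * u[i] * phi[i];
  }
  S.solve("advance_phi");
}

// one IMEX step of the cell-density equation; phi is the *same* time level
void step_u(int n, const double* x, int m, const double* u,
            const double* phi, const Par& P, double dt, BandSys& S,
            std::vector<double>& V) {
  // advective velocity V = chi(phi) dphi/dx + V_transp
  V.assign(n, P.Vt);
  V[0] += chi_of(phi[0], P) * (phi[1] - phi[0]) / (x[1] - x[0]);
  V[n - 1] += chi_of(phi[n - 1], P) *
      (phi[n - 1] - phi[n - 2]) / (x[n - 1] - x[n - 2]);
  for (int i = 1; i < n - 1; ++i) {
    if (i == m || i == m + 1) continue;
    V[i] += chi_of(phi[i], P) * (phi[i + 1] - phi[i - 1]) / (x[i + 1] - x[i - 1]);
  }
  // on the membrane the flux law gives the gradient: dphi/dx = k_phi (jump)/D_phi
  const double dphidx_M = P.kphi * (phi[m + 1] - phi[m]) / P.Dphi;
  const double chiT = chi_of(phi[m], P), chiB = chi_of(phi[m + 1], P);
  V[m] += chiT * dphidx_M;
  V[m + 1] += chiB * dphidx_M;

  const double NB = trapz_lower(x, u, m, n);
  const double ku = P.ku1 / (1.0 + P.ku2 * u[m] + P.ku3 * std::pow(NB, P.p));

  S.reset();
  {  // outer rows: D_u du/dx - V_transp u = 0 (one-sided second order)
    const double c0 = P.Du / (2.0 * (x[1] - x[0]));
    S.set(0, 0, -3.0 * c0 - P.Vt); S.set(0, 1, 4.0 * c0); S.set(0, 2, -c0);
    const double cN = P.Du / (2.0 * (x[n - 1] - x[n - 2]));
    S.set(n - 1, n - 1, 3.0 * cN - P.Vt);
    S.set(n - 1, n - 2, -4.0 * cN); S.set(n - 1, n - 3, cN);
  }
  {  // membrane rows: full flux = k_u (u_B - u_T) from both sides
    const double cT = P.Du / (2.0 * (x[m] - x[m - 1]));
    S.set(m, m - 2, cT); S.set(m, m - 1, -4.0 * cT);
    S.set(m, m, 3.0 * cT - chiT * dphidx_M - P.Vt + ku);
    S.set(m, m + 1, -ku);
    const double cB = P.Du / (2.0 * (x[m + 2] - x[m + 1]));
    S.set(m + 1, m, ku);
    S.set(m + 1, m + 1, -3.0 * cB - chiB * dphidx_M - P.Vt - ku);
    S.set(m + 1, m + 2, 4.0 * cB); S.set(m + 1, m + 3, -cB);
  }
  // centred advection + |V|-weighted artificial viscosity, written as a
  // Rusanov-type numerical flux so the update telescopes (conserves mass)
  // on the non-uniform mesh too; identical to the centred/viscosity pair
  // on uniform spacing. F[i] lives between nodes i and i+1; the
  // zero-width trace interval (m, m+1) is never referenced.
  std::vector<double> flux(n - 1, 0.0);
  for (int i = 0; i < n - 1; ++i) {
    if (i == m) continue;
    flux[i] = 0.5 * (V[i] * u[i] + V[i + 1] * u[i + 1]) -
              0.5 * (std::fabs(V[i + 1]) * u[i + 1] - std::fabs(V[i]) * u[i]);
  }
  const double fbs_norm = (P.a2 + P.phibar) / P.phibar;
  for (int i = 1; i < n - 1; ++i) {
    if (i == m || i == m + 1) continue;
    const double hm = x[i] - x[i - 1], hp = x[i + 1] - x[i];
    const double cm = 2.0 / ((hm + hp) * hm), cp = 2.0 / ((hm + hp) * hp);
    S.set(i, i - 1, -P.Du * cm);
    S.set(i, i, 1.0 / dt + P.Du * (cm + cp));
    S.set(i, i + 1, -P.Du * cp);
    const double wi = 0.5 * (x[i + 1] - x[i - 1]);
    double g = 0.0;
    if (P.a1 > 0.0) {
      g = P.a1 * u[i] * (1.0 - u[i] / P.a3) *
          (phi[i] / (P.a2 + phi[i])) * fbs_norm * w_of(x[i], P);
    }
    S.b[i] = u[i] / dt - (flux[i] - flux[i - 1]) / wi + g;
  }
  S.solve("advance_u");
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_step_phi(NumericVector x, int m1, NumericVector u,
                           NumericVector phi, NumericVector par, double dt,
                           double neg_tol) {
  const int n = x.size(), m = m1 - 1;
  Par P = unpack(par);
  BandSys S(n);
  step_phi(n, x.begin(), m, u.begin(), phi.begin(), P, dt, S);
  check_nonneg(S.b, n, "advance_phi", neg_tol);
  return NumericVector(S.b.begin(), S.b.end());
}

// [[Rcpp::export]]
NumericVector cpp_step_u(NumericVector x, int m1, NumericVector u,
                         NumericVector phi, NumericVector par, double dt,
                         double neg_tol) {
  const int n = x.size(), m = m1 - 1;
  Par P = unpack(par);
  BandSys S(n);
  std::vector<double> V;
  step_u(n, x.begin(), m, u.begin(), phi.begin(), P, dt, S, V);
  check_nonneg(S.b, n, "advance_u", neg_tol);
  return NumericVector(S.b.begin(), S.b.end());
}

// [[Rcpp::export]]
List cpp_march(NumericVector x, int m1, NumericVector u0, NumericVector phi0,
               NumericVector par, double dt, int nsteps, int sample_every,
               bool snapshots, double neg_tol) {
  const int n = x.size(), m = m1 - 1;
  Par P = unpack(par);
  BandSys Sphi(n), Su(n);
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> V;

  const int nsamp = 1 + (nsteps + sample_every - 1) / sample_every;
  NumericVector t_out(nsamp), nb_out(nsamp), ntot_out(nsamp), fbs_out(nsamp);
  NumericMatrix Usnap, Psnap;
  if (snapshots) {
    Usnap = NumericMatrix(nsamp, n);
    Psnap = NumericMatrix(nsamp, n);
  }
  int isamp = 0;
  auto record = [&](double t) {
    t_out[isamp] = t;
    nb_out[isamp] = trapz_lower(x.begin(), u.data(), m, n);
    ntot_out[isamp] = nb_out[isamp] + trapz_upper(x.begin(), u.data(), m);
    fbs_out[isamp] = trapz_lower(x.begin(), phi.data(), m, n) +
                     trapz_upper(x.begin(), phi.data(), m);
    if (snapshots) {
      for (int j = 0; j < n; ++j) {
        Usnap(isamp, j) = u[j];
        Psnap(isamp, j) = phi[j];
      }
    }
    ++isamp;
  };
  record(0.0);

  for (int k = 0; k < nsteps; ++k) {
    // both updates read the level-k cross-couplings: serum first, then cells
    step_phi(n, x.begin(), m, u.data(), phi.data(), P, dt, Sphi);
    step_u(n, x.begin(), m, u.data(), phi.data(), P, dt, Su, V);
    phi.swap(Sphi.b);
    u.swap(Su.b);
    check_nonneg(phi, n, "advance_phi", neg_tol);
    check_nonneg(u, n, "advance_u", neg_tol);
    if ((k + 1) % sample_every == 0 || k + 1 == nsteps) record((k + 1) * dt);
    if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["t"] = t_out, _["n_lower"] = nb_out, _["n_total"] = ntot_out,
      _["fbs_total"] = fbs_out,
      _["u_final"] = NumericVector(u.begin(), u.end()),
      _["phi_final"] = NumericVector(phi.begin(), phi.end()));
  if (snapshots) {
    out["u_snapshots"] = Usnap;
    out["phi_snapshots"] = Psnap;
  }
  return out;
}
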