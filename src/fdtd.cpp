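// 2D transverse-magnetic (Ez, Hx, Hy) FDTD engine on a staggered Yee grid
// with a convolutional perfectly matched layer (CPML) termination.
//
// Conventions (shared with the R wrappers):
//  * Ez lives on cell centers of the full N x N grid (interior + PML).
//  * Hx(i, j+1/2) has dims N x (N-1); Hy(i+1/2, j) has dims (N-1) x N.
//  * Row index i <-> x, column index j <-> y; 0-based here, 1-based in R.
//  * The outermost Ez ring is PEC (held at zero) behind the CPML.
//  * Update coefficients per cell: Ca = (1 - s*dt/2e)/(1 + s*dt/2e),
//    Cb = (dt/(e*dx))/(1 + s*dt/2e), with e the absolute permittivity.
//  * The source is "soft": src[n] is added to Ez at the tx cell after the
//    Ez update of step n; receivers sample Ez at cell centers at step n.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double C0   = 299792458.0;
static const double EPS0 = 8.8541878128e-12;
static const double MU0  = 1.25663706212e-6;
static const double ETA0 = 376.730313668;

// Graded CPML profile values at normalized depth d in (0, 1].
struct PmlProfile {
  arma::vec b, c, inv_kappa;
};

// pos: node positions in cell units along one axis (integer or half-integer),
// length equals the number of nodes of that field component along the axis.
static PmlProfile pml_profile(const arma::vec& pos, int n_cells, int npml,
                              double m, double smax, double kmax, double amax,
                              double dt) {
  int n = pos.n_elem;
  PmlProfile p;
  p.b = arma::zeros(n);
  p.c = arma::zeros(n);
  p.inv_kappa = arma::ones(n);
  for (int q = 0; q < n; ++q) {
    double depth = 0.0;  // in cells, from the PML/interior interface
    if (pos[q] < npml) depth = npml - pos[q];
    else if (pos[q] > n_cells - 1 - npml) depth = pos[q] - (n_cells - 1 - npml);
    if (depth <= 0.0 || npml <= 0) continue;
    double d = depth / npml;
    if (d > 1.0) d = 1.0;
    double sig = smax * std::pow(d, m);
    double kap = 1.0 + (kmax - 1.0) * std::pow(d, m);
    double alp = amax * (1.0 - d);
    double b = std::exp(-(sig / kap + alp) * dt / EPS0);
    double denom = sig + kap * alp;
    double c = (denom > 0.0) ? sig * (b - 1.0) / (denom * kap) : 0.0;
    p.b[q] = b;
    p.c[q] = c;
    p.inv_kappa[q] = 1.0 / kap;
  }
  return p;
}

// Core stepping loop. Returns receiver traces and, optionally, the staggered
// discrete energy per step and/or the final field state.
// [[Rcpp::export]]
List fdtd_core_cpp(const arma::mat& eps_r, const arma::mat& sigma,
                   double dt, double dx,
                   int npml, double pml_order, double pml_r0,
                   double pml_kappa_max, double pml_alpha_max,
                   double eps_bg,
                   const arma::vec& src, int tx_i, int tx_j,
                   const arma::imat& rx,
                   bool record_energy, bool return_fields,
                   Nullable<NumericMatrix> Ez0 = R_NilValue,
                   Nullable<NumericMatrix> Hx0 = R_NilValue,
                   Nullable<NumericMatrix> Hy0 = R_NilValue) {
  const int N = eps_r.n_rows;
  if ((int)eps_r.n_cols != N || (int)sigma.n_rows != N || (int)sigma.n_cols != N)
    stop("permittivity/conductivity maps must be square and equally sized");
  const int n_steps = src.n_elem;
  const int n_rx = rx.n_rows;

  arma::mat Ez(N, N, arma::fill::zeros);
  arma::mat Hx(N, N - 1, arma::fill::zeros);
  arma::mat Hy(N - 1, N, arma::fill::zeros);
  if (Ez0.isNotNull()) Ez = as<arma::mat>(Ez0.get());
  if (Hx0.isNotNull()) Hx = as<arma::mat>(Hx0.get());
  if (Hy0.isNotNull()) Hy = as<arma::mat>(Hy0.get());

  // Per-cell E-update coefficients.
  arma::mat eps_abs = eps_r * EPS0;
  arma::mat loss = sigma * dt / (2.0 * eps_abs);
  arma::mat Ca = (1.0 - loss) / (1.0 + loss);
  arma::mat Cb = (dt / (eps_abs * dx)) / (1.0 + loss);
  const double Dh = dt / (MU0 * dx);

  // CPML profiles: smax from the normal-incidence reflection target in the
  // background medium.
  double smax = 0.0;
  if (npml > 0)
    smax = -(pml_order + 1.0) * std::log(pml_r0) * std::sqrt(eps_bg) /
           (2.0 * ETA0 * npml * dx);

  arma::vec pos_int = arma::regspace(0, N - 1);          // Ez nodes
  arma::vec pos_half = arma::regspace(0, N - 2) + 0.5;   // staggered H nodes
  PmlProfile ex = pml_profile(pos_int, N, npml, pml_order, smax, pml_kappa_max, pml_alpha_max, dt);
  PmlProfile hx = pml_profile(pos_half, N, npml, pml_order, smax, pml_kappa_max, pml_alpha_max, dt);

  arma::mat psi_ezx(N, N, arma::fill::zeros);  // accumulates dHy/dx
  arma::mat psi_ezy(N, N, arma::fill::zeros);  // accumulates dHx/dy
  arma::mat psi_hyx(N - 1, N, arma::fill::zeros);  // dEz/dx for Hy
  arma::mat psi_hxy(N, N - 1, arma::fill::zeros);  // dEz/dy for Hx

  arma::mat traces(n_rx, n_steps, arma::fill::zeros);
  arma::vec energy;
  if (record_energy) energy.zeros(n_steps);
  arma::mat Ez_prev;

  const double inv_dx = 1.0 / dx;

  for (int n = 0; n < n_steps; ++n) {
    if (record_energy) Ez_prev = Ez;

    // H update from curl of Ez.
    for (int j = 0; j < N - 1; ++j) {
      const double bj = hx.b[j], cj = hx.c[j], ikj = hx.inv_kappa[j];
      const bool in_pml = (bj != 0.0);
      for (int i = 0; i < N; ++i) {
        double dEz = (Ez(i, j + 1) - Ez(i, j)) * inv_dx;
        if (in_pml) {
          psi_hxy(i, j) = bj * psi_hxy(i, j) + cj * dEz;
          Hx(i, j) -= dt / MU0 * (dEz * ikj + psi_hxy(i, j));
        } else {
          Hx(i, j) -= dt / MU0 * dEz;
        }
      }
    }
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < N - 1; ++i) {
        double dEz = (Ez(i + 1, j) - Ez(i, j)) * inv_dx;
        const double bi = hx.b[i], ci = hx.c[i], iki = hx.inv_kappa[i];
        if (bi != 0.0) {
          psi_hyx(i, j) = bi * psi_hyx(i, j) + ci * dEz;
          Hy(i, j) += dt / MU0 * (dEz * iki + psi_hyx(i, j));
        } else {
          Hy(i, j) += dt / MU0 * dEz;
        }
      }
    }

    // Ez update from curl of H (outermost ring PEC).
    for (int j = 1; j < N - 1; ++j) {
      const double bj = ex.b[j], cj = ex.c[j], ikj = ex.inv_kappa[j];
      for (int i = 1; i < N - 1; ++i) {
        double dHy = (Hy(i, j) - Hy(i - 1, j)) * inv_dx;
        double dHx = (Hx(i, j) - Hx(i, j - 1)) * inv_dx;
        double curl;
        const double bi = ex.b[i];
        if (bi != 0.0 || bj != 0.0) {
          if (bi != 0.0) {
            psi_ezx(i, j) = bi * psi_ezx(i, j) + ex.c[i] * dHy;
            dHy = dHy * ex.inv_kappa[i] + psi_ezx(i, j);
          }
          if (bj != 0.0) {
            psi_ezy(i, j) = bj * psi_ezy(i, j) + cj * dHx;
            dHx = dHx * ikj + psi_ezy(i, j);
          }
          curl = dHy - dHx;
        } else {
          curl = dHy - dHx;
        }
        Ez(i, j) = Ca(i, j) * Ez(i, j) + Cb(i, j) * dx * curl;
      }
    }

    // Soft source.
    Ez(tx_i, tx_j) += src[n];

    // Receivers.
    for (int r = 0; r < n_rx; ++r)
      traces(r, n) = Ez(rx(r, 0), rx(r, 1));

    if (record_energy) {
      // Staggered-time discrete energy eps/2 * Ez^n Ez^{n+1} +
      // mu0/2 * (H^{n+1/2})^2: a constant of the motion of the lossless
      // source-free leapfrog scheme in a closed (PEC) region.
      double ee = 0.5 * arma::accu(eps_abs % Ez_prev % Ez) * dx * dx;
      double eh = 0.5 * MU0 *
        (arma::accu(Hx % Hx) + arma::accu(Hy % Hy)) * dx * dx;
      energy[n] = ee + eh;
    }

    if ((n & 127) == 0 && !Ez.is_finite())
      stop("FDTD instability: non-finite field values at step %d", n + 1);
  }
  if (!Ez.is_finite())
    stop("FDTD instability: non-finite field values at step %d", n_steps);

  List out = List::create(Named("traces") = traces);
  if (record_energy) out["energy"] = energy;
  if (return_fields) {
    out["Ez"] = Ez; out["Hx"] = Hx; out["Hy"] = Hy;
  }
  return out;
}
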