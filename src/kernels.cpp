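// Numerical kernels: Debye scattering sums, coarse-grained pair energies
// and forces (harmonic bonds, Debye-Hueckel, Wang-Frenkel), a BAOAB
// Langevin integrator, and minimum-image chain adjacency for clustering.
#include <Rcpp.h>
using namespace Rcpp;

// I(q) = sum_i sum_j f_i(q) f_j(q) sin(q r_ij) / (q r_ij)
// ff: natoms x nq matrix of per-atom form factors evaluated on the grid.
// [[Rcpp::export(name = ".debye_sum")]]
NumericVector debye_sum(NumericMatrix xyz, NumericMatrix ff,
                        NumericVector q) {
  const int n = xyz.nrow(), nq = q.size();
  NumericVector I(nq);
  // self terms
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < nq; ++k) I[k] += ff(i, k) * ff(i, k);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) {
        double qr = q[k] * r;
        double sinc = (qr < 1e-12) ? 1.0 : std::sin(qr) / qr;
        I[k] += 2.0 * ff(i, k) * ff(j, k) * sinc;
      }
    }
  }
  return I;
}

static inline double min_image(double d, double box) {
  if (box > 0) {
    while (d > 0.5 * box) d -= box;
    while (d < -0.5 * box) d += box;
  }
  return d;
}

struct FF {
  double K, kappa, ke_over_eps, elec_cut;
  NumericVector rref_bond;          // per bond
  NumericMatrix wf_eps, wf_sig, wf_mu, wf_nu, wf_rc; // per type pair
};

// Wang-Frenkel energy and dU/dr for one pair
static inline void wf_pair(double r, double eps, double sig, double mu,
                           double nu, double rc, double &U, double &dUdr) {
  U = 0.0; dUdr = 0.0;
  if (r >= rc || eps <= 0.0) return;
  double rms = std::pow(rc / sig, 2.0 * mu);
  double alpha = 2.0 * nu * rms *
    std::pow((1.0 + 2.0 * nu) / (2.0 * nu * (rms - 1.0)), 2.0 * nu + 1.0);
  double A = std::pow(sig / r, 2.0 * mu);
  double B = std::pow(rc / r, 2.0 * mu);
  double Bm = B - 1.0;
  double p = std::pow(Bm, 2.0 * nu);
  U = eps * alpha * (A - 1.0) * p;
  dUdr = eps * alpha * (-2.0 * mu / r) *
    (A * p + 2.0 * nu * (A - 1.0) * std::pow(Bm, 2.0 * nu - 1.0) * B);
}

// [[Rcpp::export(name = ".energy_terms")]]
NumericVector energy_terms(NumericMatrix x, IntegerMatrix bonds,
                           NumericVector rref_bond, NumericVector charge,
                           IntegerVector type, List wf, double K,
                           double kappa, double ke_over_eps,
                           double elec_cut, double box) {
  NumericMatrix wf_eps = wf["eps"], wf_sig = wf["sig"], wf_mu = wf["mu"],
    wf_nu = wf["nu"], wf_rc = wf["rc"];
  const int n = x.nrow(), nb = bonds.nrow();
  double Ebond = 0.0, Edh = 0.0, Ewf = 0.0;
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = min_image(x(i,0) - x(j,0), box);
    double dy = min_image(x(i,1) - x(j,1), box);
    double dz = min_image(x(i,2) - x(j,2), box);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double d = r - rref_bond[b];
    Ebond += K * d * d;
  }
  // bonded exclusion set
  std::vector<std::vector<int> > excl(n);
  for (int b = 0; b < nb; ++b) {
    excl[bonds(b,0) - 1].push_back(bonds(b,1) - 1);
    excl[bonds(b,1) - 1].push_back(bonds(b,0) - 1);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool skip = false;
      for (size_t k = 0; k < excl[i].size(); ++k)
        if (excl[i][k] == j) { skip = true; break; }
      if (skip) continue;
      double dx = min_image(x(i,0) - x(j,0), box);
      double dy = min_image(x(i,1) - x(j,1), box);
      double dz = min_image(x(i,2) - x(j,2), box);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < 1e-6) stop("overlapping beads (r < 1e-6 A)");
      if (r < elec_cut && charge[i] != 0.0 && charge[j] != 0.0)
        Edh += ke_over_eps * charge[i] * charge[j] *
          std::exp(-kappa * r) / r;
      int ti = type[i] - 1, tj = type[j] - 1;
      double U, dU;
      wf_pair(r, wf_eps(ti,tj), wf_sig(ti,tj), wf_mu(ti,tj), wf_nu(ti,tj),
              wf_rc(ti,tj), U, dU);
      Ewf += U;
    }
  }
  return NumericVector::create(_["bond"] = Ebond, _["dh"] = Edh,
                               _["wf"] = Ewf);
}

static void compute_forces(NumericMatrix &x, IntegerMatrix &bonds,
                           NumericVector &rref_bond, NumericVector &charge,
                           IntegerVector &type,
                           NumericMatrix &wf_eps, NumericMatrix &wf_sig,
                           NumericMatrix &wf_mu, NumericMatrix &wf_nu,
                           NumericMatrix &wf_rc,
                           std::vector<std::vector<int> > &excl,
                           double K, double kappa, double ke_over_eps,
                           double elec_cut, double box, NumericMatrix &F,
                           double max_rc) {
  const int n = x.nrow(), nb = bonds.nrow();
  std::fill(F.begin(), F.end(), 0.0);
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b,0) - 1, j = bonds(b,1) - 1;
    double dx = min_image(x(i,0) - x(j,0), box);
    double dy = min_image(x(i,1) - x(j,1), box);
    double dz = min_image(x(i,2) - x(j,2), box);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 1e-9) continue;
    double fmag = -2.0 * K * (r - rref_bond[b]) / r; // force along +d on i
    F(i,0) += fmag * dx; F(i,1) += fmag * dy; F(i,2) += fmag * dz;
    F(j,0) -= fmag * dx; F(j,1) -= fmag * dy; F(j,2) -= fmag * dz;
  }
  double cut = std::max(elec_cut, max_rc);
  double cut2 = cut * cut;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(x(i,0) - x(j,0), box);
      if (std::fabs(dx) > cut) continue;
      double dy = min_image(x(i,1) - x(j,1), box);
      if (std::fabs(dy) > cut) continue;
      double dz = min_image(x(i,2) - x(j,2), box);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 > cut2) continue;
      bool skip = false;
      for (size_t k = 0; k < excl[i].size(); ++k)
        if (excl[i][k] == j) { skip = true; break; }
      if (skip) continue;
      double r = std::sqrt(r2);
      if (r < 1e-6) continue;
      double dUdr = 0.0;
      if (r < elec_cut && charge[i] != 0.0 && charge[j] != 0.0) {
        double e = ke_over_eps * charge[i] * charge[j] *
          std::exp(-kappa * r);
        dUdr += -e * (1.0 / (r * r) + kappa / r);
      }
      int ti = type[i] - 1, tj = type[j] - 1;
      double U, dU;
      wf_pair(r, wf_eps(ti,tj), wf_sig(ti,tj), wf_mu(ti,tj), wf_nu(ti,tj),
              wf_rc(ti,tj), U, dU);
      dUdr += dU;
      if (dUdr != 0.0) {
        double fmag = -dUdr / r;
        F(i,0) += fmag * dx; F(i,1) += fmag * dy; F(i,2) += fmag * dz;
        F(j,0) -= fmag * dx; F(j,1) -= fmag * dy; F(j,2) -= fmag * dz;
      }
    }
  }
}

// BAOAB Langevin dynamics. Units: kJ/mol, Angstrom, amu; internal time
// unit 100 fs (consistent with these energy/mass units). dt given in fs.
// gamma = 1/tau with tau the relaxation time (fs). Uses R's RNG.
// [[Rcpp::export(name = ".run_langevin_cpp")]]
List run_langevin_cpp(NumericMatrix x0, NumericVector mass,
                      NumericVector charge, IntegerVector type,
                      IntegerMatrix bonds, NumericVector rref_bond,
                      List wf, double K, double kappa, double ke_over_eps,
                      double elec_cut, double box, double dt_fs,
                      double tau_fs, double temperature, int n_steps,
                      int stride, double fmax_abort) {
  RNGScope scope;
  NumericMatrix wf_eps = wf["eps"], wf_sig = wf["sig"], wf_mu = wf["mu"],
    wf_nu = wf["nu"], wf_rc = wf["rc"];
  const int n = x0.nrow();
  const double TU = 100.0;           // fs per internal time unit
  const double dt = dt_fs / TU;
  const double kB = 0.00831446;      // kJ/(mol K)
  NumericMatrix x = clone(x0), v(n, 3), F(n, 3);
  std::vector<std::vector<int> > excl(n);
  for (int b = 0; b < bonds.nrow(); ++b) {
    excl[bonds(b,0) - 1].push_back(bonds(b,1) - 1);
    excl[bonds(b,1) - 1].push_back(bonds(b,0) - 1);
  }
  double max_rc = 0.0;
  for (int i = 0; i < wf_rc.nrow(); ++i)
    for (int j = 0; j < wf_rc.ncol(); ++j)
      if (wf_eps(i,j) > 0 && wf_rc(i,j) > max_rc) max_rc = wf_rc(i,j);
  double c1 = 1.0, kT = kB * temperature;
  bool thermostat = (tau_fs > 0);
  if (thermostat) c1 = std::exp(-dt_fs / tau_fs);
  // initial velocities from Maxwell-Boltzmann (zeroed if tau_fs <= 0)
  for (int i = 0; i < n; ++i) {
    double s = thermostat ? std::sqrt(kT / mass[i]) : 0.0;
    for (int d = 0; d < 3; ++d) v(i,d) = s * norm_rand();
  }
  compute_forces(x, bonds, rref_bond, charge, type, wf_eps, wf_sig, wf_mu,
                 wf_nu, wf_rc, excl, K, kappa, ke_over_eps, elec_cut, box,
                 F, max_rc);
  int n_frames = n_steps / stride + 1;
  NumericVector frames(n_frames * n * 3);
  NumericVector temps(n_frames), times(n_frames);
  int fi = 0;
  auto record = [&](int step) {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) ke += 0.5 * mass[i] * v(i,d) * v(i,d);
    temps[fi] = 2.0 * ke / (3.0 * n * kB);
    times[fi] = step * dt_fs;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double xi = x(i,d);
        if (box > 0) xi -= box * std::floor(xi / box); // wrap into [0, box)
        frames[fi + n_frames * (i + (size_t)n * d)] = xi;
      }
    ++fi;
  };
  record(0);
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        v(i,d) += 0.5 * dt * F(i,d) / mass[i];
        x(i,d) += 0.5 * dt * v(i,d);
      }
    if (thermostat) {
      for (int i = 0; i < n; ++i) {
        double c2 = std::sqrt(kT / mass[i] * (1.0 - c1 * c1));
        for (int d = 0; d < 3; ++d)
          v(i,d) = c1 * v(i,d) + c2 * norm_rand();
      }
    }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) x(i,d) += 0.5 * dt * v(i,d);
    compute_forces(x, bonds, rref_bond, charge, type, wf_eps, wf_sig,
                   wf_mu, wf_nu, wf_rc, excl, K, kappa, ke_over_eps,
                   elec_cut, box, F, max_rc);
    double fmax = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        v(i,d) += 0.5 * dt * F(i,d) / mass[i];
        double af = std::fabs(F(i,d));
        if (af > fmax) fmax = af;
      }
    if (fmax > fmax_abort) {
      stop("force blow-up at step %d (|F| = %g kJ/mol/A)", step, fmax);
    }
    if (step % stride == 0) record(step);
  }
  frames.attr("dim") = IntegerVector::create(n_frames, n, 3);
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["temperature"] = temps);
}

// chain-chain adjacency: chains linked iff any inter-chain bead pair is
// within cutoff under the minimum-image convention.
// [[Rcpp::export(name = ".chain_adjacency_cpp")]]
LogicalMatrix chain_adjacency_cpp(NumericMatrix x, IntegerVector chain,
                                  double box, double cutoff) {
  int n = x.nrow();
  int nc = 0;
  for (int i = 0; i < n; ++i) if (chain[i] > nc) nc = chain[i];
  LogicalMatrix A(nc, nc);
  double cut2 = cutoff * cutoff;
  for (int i = 0; i < nc; ++i) A(i,i) = true;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int ci = chain[i] - 1, cj = chain[j] - 1;
      if (ci == cj || A(ci,cj)) continue;
      double dx = min_image(x(i,0) - x(j,0), box);
      if (std::fabs(dx) > cutoff) continue;
      double dy = min_image(x(i,1) - x(j,1), box);
      if (std::fabs(dy) > cutoff) continue;
      double dz = min_image(x(i,2) - x(j,2), box);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 <= cut2) { A(ci,cj) = true; A(cj,ci) = true; }
    }
  }
  return A;
}
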