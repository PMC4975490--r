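#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Energy/force engine for the C-alpha structure-based model.
//
// Units are reduced throughout: energy in eps_h, length in nm, mass 1 per
// bead. The model list is prepared in R (see assemble()) and holds flat
// integer/numeric vectors; bead indices arrive 1-based and are used as-is
// with an offset.
//
// Terms:
//   bonds      Kr/2 (r - r0)^2
//   angles     Kth/2 (theta - theta0)^2
//   dihedrals  sum_{n=1,3} Kn (1 - cos(n (phi - phi0)))
//   contacts   eps (5 (r0/r)^12 - 6 (r0/r)^10)      (native 10-12)
//   repulsion  eps_l (sigma/r)^12                   (non-native pairs)
//   trap       k/2 |x - x0|^2 per restrained bead   (validation harness)
//   external   -f_b . x_b                           (constant pulling force)

struct Model {
  int n;
  IntegerVector bi, bj; NumericVector br0; IntegerVector bterm; double Kr;
  IntegerVector ai, aj, ak; NumericVector at0; IntegerVector aterm; double Kth;
  IntegerVector di, dj, dk, dl; NumericVector dphi0; IntegerVector dterm;
  double K1, K3;
  IntegerVector ci, cj; NumericVector cr0, ceps; IntegerVector cterm;
  IntegerVector ri, rj; double eps_l, sigma;
  bool has_trap; NumericVector trap_k; NumericMatrix trap_x0;
  bool has_fext; NumericMatrix fext;
  LogicalVector frozen;
  int nterms;
};

static Model unpack(const List& m) {
  Model M;
  M.n = as<int>(m["n"]);
  M.bi = m["bond_i"]; M.bj = m["bond_j"]; M.br0 = m["bond_r0"];
  M.bterm = m["bond_term"]; M.Kr = as<double>(m["K_r"]);
  M.ai = m["angle_i"]; M.aj = m["angle_j"]; M.ak = m["angle_k"];
  M.at0 = m["angle_t0"]; M.aterm = m["angle_term"]; M.Kth = as<double>(m["K_theta"]);
  M.di = m["dih_i"]; M.dj = m["dih_j"]; M.dk = m["dih_k"]; M.dl = m["dih_l"];
  M.dphi0 = m["dih_phi0"]; M.dterm = m["dih_term"];
  M.K1 = as<double>(m["K_phi1"]); M.K3 = as<double>(m["K_phi3"]);
  M.ci = m["con_i"]; M.cj = m["con_j"]; M.cr0 = m["con_r0"];
  M.ceps = m["con_eps"]; M.cterm = m["con_term"];
  M.ri = m["rep_i"]; M.rj = m["rep_j"];
  M.eps_l = as<double>(m["eps_l"]); M.sigma = as<double>(m["sigma"]);
  M.has_trap = as<bool>(m["has_trap"]);
  if (M.has_trap) { M.trap_k = m["trap_k"]; M.trap_x0 = as<NumericMatrix>(m["trap_x0"]); }
  M.has_fext = as<bool>(m["has_fext"]);
  if (M.has_fext) M.fext = as<NumericMatrix>(m["fext"]);
  M.frozen = m["frozen"];
  M.nterms = as<int>(m["n_terms"]);
  return M;
}

// Evaluates total energy, per-term breakdown and forces into preallocated
// buffers. coords/forces are n x 3 (column-major R matrices).
static double eval_model(const Model& M, const double* x, double* f,
                         double* ebrk) {
  const int n = M.n;
  for (int i = 0; i < 3 * n; ++i) f[i] = 0.0;
  for (int t = 0; t < M.nterms; ++t) ebrk[t] = 0.0;
  double etot = 0.0;
  const double* X = x; const double* Y = x + n; const double* Z = x + 2 * n;
  double* FX = f; double* FY = f + n; double* FZ = f + 2 * n;

  // bonds
  for (int b = 0; b < M.bi.size(); ++b) {
    int i = M.bi[b] - 1, j = M.bj[b] - 1;
    double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - M.br0[b];
    double e = 0.5 * M.Kr * dr * dr;
    etot += e; ebrk[M.bterm[b]] += e;
    double fr = -M.Kr * dr / r;  // force magnitude / r on i along (ri - rj)
    FX[i] += fr * dx; FY[i] += fr * dy; FZ[i] += fr * dz;
    FX[j] -= fr * dx; FY[j] -= fr * dy; FZ[j] -= fr * dz;
  }

  // angles
  for (int a = 0; a < M.ai.size(); ++a) {
    int i = M.ai[a] - 1, j = M.aj[a] - 1, k = M.ak[a] - 1;
    double ux = X[i] - X[j], uy = Y[i] - Y[j], uz = Z[i] - Z[j];
    double vx = X[k] - X[j], vy = Y[k] - Y[j], vz = Z[k] - Z[j];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double dth = th - M.at0[a];
    double e = 0.5 * M.Kth * dth * dth;
    etot += e; ebrk[M.aterm[a]] += e;
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) st = 1e-8;
    double dEdth = M.Kth * dth;
    // grad theta wrt ri = -(1/(|u| sin)) (v/|v| - cos * u/|u|)
    double c1 = dEdth / (st * nu), c2 = dEdth / (st * nv);
    double fix = c1 * (vx / nv - ct * ux / nu);
    double fiy = c1 * (vy / nv - ct * uy / nu);
    double fiz = c1 * (vz / nv - ct * uz / nu);
    double fkx = c2 * (ux / nu - ct * vx / nv);
    double fky = c2 * (uy / nu - ct * vy / nv);
    double fkz = c2 * (uz / nu - ct * vz / nv);
    FX[i] += fix; FY[i] += fiy; FZ[i] += fiz;
    FX[k] += fkx; FY[k] += fky; FZ[k] += fkz;
    FX[j] -= fix + fkx; FY[j] -= fiy + fky; FZ[j] -= fiz + fkz;
  }

  // dihedrals (signed, standard b1/b2/b3 formulation)
  for (int d = 0; d < M.di.size(); ++d) {
    int i = M.di[d] - 1, j = M.dj[d] - 1, k = M.dk[d] - 1, l = M.dl[d] - 1;
    double b1x = X[j] - X[i], b1y = Y[j] - Y[i], b1z = Z[j] - Z[i];
    double b2x = X[k] - X[j], b2y = Y[k] - Y[j], b2z = Z[k] - Z[j];
    double b3x = X[l] - X[k], b3y = Y[l] - Y[k], b3z = Z[l] - Z[k];
    double mx = b1y * b2z - b1z * b2y, my = b1z * b2x - b1x * b2z,
           mz = b1x * b2y - b1y * b2x;
    double nx = b2y * b3z - b2z * b3y, ny = b2z * b3x - b2x * b3z,
           nz = b2x * b3y - b2y * b3x;
    double m2 = mx * mx + my * my + mz * mz;
    double n2 = nx * nx + ny * ny + nz * nz;
    double b2n = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (m2 < 1e-12 || n2 < 1e-12) continue;  // collinear segment, undefined
    double sy = (mx * nx + my * ny + mz * nz);
    double sx = (my * nz - mz * ny) * b2x + (mz * nx - mx * nz) * b2y +
                (mx * ny - my * nx) * b2z;
    double phi = std::atan2(sx / b2n, sy);
    double dphi1 = phi - M.dphi0[d];
    double e = M.K1 * (1.0 - std::cos(dphi1)) + M.K3 * (1.0 - std::cos(3.0 * dphi1));
    etot += e; ebrk[M.dterm[d]] += e;
    double dEdphi = M.K1 * std::sin(dphi1) + 3.0 * M.K3 * std::sin(3.0 * dphi1);
    // F_i = -dV/dphi * |b2|/|m'|^2 m' with m' = r_ij x r_kj = -m, and the
    // matching expressions for the inner atoms (standard proper-dihedral
    // force decomposition)
    double fi = dEdphi * b2n / m2;
    double fl = -dEdphi * b2n / n2;
    double Fix = fi * mx, Fiy = fi * my, Fiz = fi * mz;
    double Flx = fl * nx, Fly = fl * ny, Flz = fl * nz;
    double t = (b1x * b2x + b1y * b2y + b1z * b2z) / (b2n * b2n);
    double s = (b3x * b2x + b3y * b2y + b3z * b2z) / (b2n * b2n);
    double Fjx = -Fix - t * Fix + s * Flx;
    double Fjy = -Fiy - t * Fiy + s * Fly;
    double Fjz = -Fiz - t * Fiz + s * Flz;
    double Fkx = -Flx + t * Fix - s * Flx;
    double Fky = -Fly + t * Fiy - s * Fly;
    double Fkz = -Flz + t * Fiz - s * Flz;
    FX[i] += Fix; FY[i] += Fiy; FZ[i] += Fiz;
    FX[j] += Fjx; FY[j] += Fjy; FZ[j] += Fjz;
    FX[k] += Fkx; FY[k] += Fky; FZ[k] += Fkz;
    FX[l] += Flx; FY[l] += Fly; FZ[l] += Flz;
  }

  // native contacts, 10-12
  for (int c = 0; c < M.ci.size(); ++c) {
    int i = M.ci[c] - 1, j = M.cj[c] - 1;
    double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    double q2 = (M.cr0[c] * M.cr0[c]) / r2;
    double q10 = q2 * q2 * q2 * q2 * q2;
    double q12 = q10 * q2;
    double eps = M.ceps[c];
    double e = eps * (5.0 * q12 - 6.0 * q10);
    etot += e; ebrk[M.cterm[c]] += e;
    // dE/dr = -60 eps (q12 - q10)/r ; F_i = -dE/dr * (ri-rj)/r
    double fr = 60.0 * eps * (q12 - q10) / r2;
    FX[i] += fr * dx; FY[i] += fr * dy; FZ[i] += fr * dz;
    FX[j] -= fr * dx; FY[j] -= fr * dy; FZ[j] -= fr * dz;
  }

  // repulsion (term slot nterms-3), external (nterms-2), trap (nterms-1)
  int rep_slot = M.nterms - 3, ext_slot = M.nterms - 2, trap_slot = M.nterms - 1;
  double s2 = M.sigma * M.sigma;
  for (int p = 0; p < M.ri.size(); ++p) {
    int i = M.ri[p] - 1, j = M.rj[p] - 1;
    double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    double q2 = s2 / r2;
    double q12 = q2 * q2 * q2; q12 = q12 * q12;
    double e = M.eps_l * q12;
    etot += e; ebrk[rep_slot] += e;
    double fr = 12.0 * M.eps_l * q12 / r2;
    FX[i] += fr * dx; FY[i] += fr * dy; FZ[i] += fr * dz;
    FX[j] -= fr * dx; FY[j] -= fr * dy; FZ[j] -= fr * dz;
  }

  if (M.has_fext) {
    for (int i = 0; i < n; ++i) {
      double e = -(M.fext(i, 0) * X[i] + M.fext(i, 1) * Y[i] + M.fext(i, 2) * Z[i]);
      etot += e; ebrk[ext_slot] += e;
      FX[i] += M.fext(i, 0); FY[i] += M.fext(i, 1); FZ[i] += M.fext(i, 2);
    }
  }

  if (M.has_trap) {
    for (int i = 0; i < n; ++i) {
      double k = M.trap_k[i];
      if (k <= 0.0) continue;
      double dx = X[i] - M.trap_x0(i, 0), dy = Y[i] - M.trap_x0(i, 1),
             dz = Z[i] - M.trap_x0(i, 2);
      double e = 0.5 * k * (dx * dx + dy * dy + dz * dz);
      etot += e; ebrk[trap_slot] += e;
      FX[i] -= k * dx; FY[i] -= k * dy; FZ[i] -= k * dz;
    }
  }

  // frozen beads report zero force for integration purposes
  for (int i = 0; i < n; ++i)
    if (M.frozen[i]) { FX[i] = 0.0; FY[i] = 0.0; FZ[i] = 0.0; }

  return etot;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, List model) {
  Model M = unpack(model);
  if (coords.nrow() != M.n || coords.ncol() != 3)
    stop("coords must be an n x 3 matrix matching the model");
  NumericMatrix F(M.n, 3);
  NumericVector brk(M.nterms);
  double e = eval_model(M, coords.begin(), F.begin(), brk.begin());
  return List::create(_["energy"] = e, _["breakdown"] = brk, _["forces"] = F);
}

// Langevin dynamics, BBK discretization of
//   m x'' = -zeta x' - dH/dx + Gamma(t),
// random force variance 2 zeta kT / h per Cartesian component (the 3-vector
// dot-product correlation is 6 zeta kT / h). Uses R's RNG so runs are fully
// reproducible under set.seed().
// [[Rcpp::export]]
List cpp_langevin(NumericMatrix coords0, NumericMatrix vel0, List model,
                  int n_steps, int n_relax, int save_every,
                  double h, double zeta, double kT, double e_guard) {
  Model M = unpack(model);
  const int n = M.n;
  if (coords0.nrow() != n || vel0.nrow() != n)
    stop("coords/velocities must match model size");
  std::vector<double> x(coords0.begin(), coords0.end());
  std::vector<double> v(vel0.begin(), vel0.end());
  std::vector<double> f(3 * n), g(3 * n);
  std::vector<double> brk(M.nterms);

  int n_save = 0;
  for (int s = n_relax + 1; s <= n_steps; ++s)
    if ((s - n_relax) % save_every == 0) ++n_save;
  NumericVector frames((R_xlen_t)n_save * n * 3);
  NumericVector times(n_save), epot(n_save), ekin(n_save);

  const double sd = std::sqrt(2.0 * zeta * kT / h);
  const double denom = 1.0 + 0.5 * h * zeta;
  double e = eval_model(M, x.data(), f.data(), brk.data());
  int isave = 0;
  bool aborted = false;

  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      if (M.frozen[i]) { g[i] = 0; g[i + n] = 0; g[i + 2 * n] = 0; continue; }
      g[i] = sd * norm_rand();
      g[i + n] = sd * norm_rand();
      g[i + 2 * n] = sd * norm_rand();
    }
    for (int i = 0; i < n; ++i) {
      if (M.frozen[i]) continue;
      for (int c = 0; c < 3; ++c) {
        int idx = i + c * n;
        double vh = v[idx] + 0.5 * h * (f[idx] - zeta * v[idx] + g[idx]);
        v[idx] = vh;           // half-step velocity stored
        x[idx] += h * vh;
      }
    }
    e = eval_model(M, x.data(), f.data(), brk.data());
    if (!std::isfinite(e) || std::fabs(e) > e_guard) { aborted = true; }
    for (int i = 0; i < n; ++i) {
      if (M.frozen[i]) continue;
      for (int c = 0; c < 3; ++c) {
        int idx = i + c * n;
        v[idx] = (v[idx] + 0.5 * h * (f[idx] + g[idx])) / denom;
      }
    }
    if (aborted) break;
    if (s > n_relax && (s - n_relax) % save_every == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        if (M.frozen[i]) continue;
        ke += 0.5 * (v[i] * v[i] + v[i + n] * v[i + n] +
                     v[i + 2 * n] * v[i + 2 * n]);
      }
      R_xlen_t off = (R_xlen_t)isave * n * 3;
      for (int idx = 0; idx < 3 * n; ++idx) frames[off + idx] = x[idx];
      times[isave] = s * h;
      epot[isave] = e;
      ekin[isave] = ke;
      ++isave;
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int idx = 0; idx < 3 * n; ++idx) { xout[idx] = x[idx]; vout[idx] = v[idx]; }
  frames.attr("dim") = IntegerVector::create(n, 3, n_save);
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["epot"] = epot, _["ekin"] = ekin,
                      _["coords"] = xout, _["vel"] = vout,
                      _["aborted"] = aborted, _["n_saved"] = isave,
                      _["last_energy"] = e);
}
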