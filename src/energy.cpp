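// Coarse-grained peptide model: chain geometry from backbone dihedrals,
// energy evaluation (local wells + Mie + H-bond + Debye-Hueckel) and the
// simulated-annealing Metropolis kernel.  Mirrors the pure-R reference
// implementations in R/; tests assert agreement to 1e-8 kcal/mol.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }
static inline void vunit(double* a) {
  double n = vnorm(a);
  if (n > 0) { a[0] /= n; a[1] /= n; a[2] /= n; }
}

// NeRF placement: position D bonded to C, given reference atoms A-B-C, the
// C-D bond length, the B-C-D angle and the A-B-C-D torsion (IUPAC sign).
static void nerf_place(const double* A, const double* B, const double* C,
                       double bond, double angle_deg, double torsion_deg,
                       double* D) {
  double b1[3], b2[3], n[3], m[3];
  vsub(B, A, b1);
  vsub(C, B, b2);
  vunit(b1); vunit(b2);
  vcross(b1, b2, n); vunit(n);
  vcross(n, b2, m);
  double ang = angle_deg * DEG, tor = torsion_deg * DEG;
  double d2[3];
  d2[0] = -bond * std::cos(ang);
  d2[1] = bond * std::sin(ang) * std::cos(tor);
  d2[2] = bond * std::sin(ang) * std::sin(tor);
  for (int k = 0; k < 3; ++k)
    D[k] = C[k] + d2[0] * b2[k] + d2[1] * m[k] + d2[2] * n[k];
}

struct Geom {
  double bond_n_ca, bond_ca_c, bond_c_n, bond_c_o, bond_n_h;
  double angle_n_ca_c, angle_ca_c_n, angle_c_n_ca, angle_ca_c_o;
  double angle_n_ca_sc, improper_sc, omega;
};

static Geom read_geom(const List& g) {
  Geom out;
  out.bond_n_ca = as<double>(g["bond_n_ca"]);
  out.bond_ca_c = as<double>(g["bond_ca_c"]);
  out.bond_c_n = as<double>(g["bond_c_n"]);
  out.bond_c_o = as<double>(g["bond_c_o"]);
  out.bond_n_h = as<double>(g["bond_n_h"]);
  out.angle_n_ca_c = as<double>(g["angle_n_ca_c"]);
  out.angle_ca_c_n = as<double>(g["angle_ca_c_n"]);
  out.angle_c_n_ca = as<double>(g["angle_c_n_ca"]);
  out.angle_ca_c_o = as<double>(g["angle_ca_c_o"]);
  out.angle_n_ca_sc = as<double>(g["angle_n_ca_sc"]);
  out.improper_sc = as<double>(g["improper_sc"]);
  out.omega = as<double>(g["omega"]);
  return out;
}

// Build all particle coordinates from (phi, psi).  Particle order per
// residue: N, H, CA, C, O[, SC]; index arrays are 0-based, -1 = absent.
static void build_chain_core(int L, const double* phi, const double* psi,
                             const int* iN, const int* iH, const int* iCA,
                             const int* iC, const int* iO, const int* iSC,
                             const double* sc_dist, const Geom& g,
                             double* X /* npart x 3, row-major */) {
  std::vector<double> C0(3);
  double* p;
  // seed residue 1 backbone
  p = X + 3 * iN[0]; p[0] = 0; p[1] = 0; p[2] = 0;
  p = X + 3 * iCA[0]; p[0] = g.bond_n_ca; p[1] = 0; p[2] = 0;
  {
    double th = (180.0 - g.angle_n_ca_c) * DEG;
    p = X + 3 * iC[0];
    p[0] = g.bond_n_ca + g.bond_ca_c * std::cos(th);
    p[1] = g.bond_ca_c * std::sin(th);
    p[2] = 0;
  }
  // virtual previous C so that dihedral(C0, N1, CA1, C1) = phi[0]
  nerf_place(X + 3 * iC[0], X + 3 * iCA[0], X + 3 * iN[0],
             g.bond_c_n, g.angle_c_n_ca, phi[0], C0.data());
  for (int i = 0; i < L; ++i) {
    if (i > 0) {
      nerf_place(X + 3 * iN[i - 1], X + 3 * iCA[i - 1], X + 3 * iC[i - 1],
                 g.bond_c_n, g.angle_ca_c_n, psi[i - 1], X + 3 * iN[i]);
      nerf_place(X + 3 * iCA[i - 1], X + 3 * iC[i - 1], X + 3 * iN[i],
                 g.bond_n_ca, g.angle_c_n_ca, g.omega, X + 3 * iCA[i]);
      nerf_place(X + 3 * iC[i - 1], X + 3 * iN[i], X + 3 * iCA[i],
                 g.bond_ca_c, g.angle_n_ca_c, phi[i], X + 3 * iC[i]);
    }
    // carbonyl O anti to the next N
    nerf_place(X + 3 * iN[i], X + 3 * iCA[i], X + 3 * iC[i],
               g.bond_c_o, g.angle_ca_c_o, psi[i] + 180.0, X + 3 * iO[i]);
    // amide H on the bisector, in the peptide plane
    {
      const double* Cprev = (i > 0) ? X + 3 * iC[i - 1] : C0.data();
      const double* N = X + 3 * iN[i];
      double u1[3], u2[3];
      vsub(Cprev, N, u1); vunit(u1);
      vsub(X + 3 * iCA[i], N, u2); vunit(u2);
      double b[3] = {u1[0] + u2[0], u1[1] + u2[1], u1[2] + u2[2]};
      vunit(b);
      p = X + 3 * iH[i];
      for (int k = 0; k < 3; ++k) p[k] = N[k] - g.bond_n_h * b[k];
    }
    if (iSC[i] >= 0)
      nerf_place(X + 3 * iC[i], X + 3 * iN[i], X + 3 * iCA[i],
                 sc_dist[i], g.angle_n_ca_sc, g.improper_sc, X + 3 * iSC[i]);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_build_chain(NumericVector phi, NumericVector psi,
                              IntegerVector idxN, IntegerVector idxH,
                              IntegerVector idxCA, IntegerVector idxC,
                              IntegerVector idxO, IntegerVector idxSC,
                              NumericVector sc_dist, List geom, int npart) {
  int L = phi.size();
  Geom g = read_geom(geom);
  std::vector<double> X(npart * 3);
  build_chain_core(L, phi.begin(), psi.begin(), idxN.begin(), idxH.begin(),
                   idxCA.begin(), idxC.begin(), idxO.begin(), idxSC.begin(),
                   sc_dist.begin(), g, X.data());
  NumericMatrix out(npart, 3);
  for (int i = 0; i < npart; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = X[3 * i + k];
  return out;
}

// ---------------------------------------------------------------------------

struct HBond { int donor, acceptor; double r; };

struct System {
  int L, npart;
  std::vector<int> iN, iH, iCA, iC, iO, iSC;
  std::vector<double> sc_dist;
  Geom geom;
  std::vector<int> type;              // 0-based particle type
  NumericMatrix EPS, R0, NN, MM;
  std::vector<char> keep;             // npart*npart inclusion mask
  std::vector<char> charged_sc;       // repulsive-only flag per particle
  std::vector<double> philow, phihigh, psilow, psihigh;
  double eps_phi;
  double sigma, depth, eps_a, eps_b, coop_a, coop_b, rec_frac;
  int min_sep;
  std::vector<char> donor_ok;
  bool use_dh;
  std::vector<int> cidx, resid;
  std::vector<double> cq;
  NumericMatrix SHIFT, CROSS;
  double l_dh, dw, dp, s, coul, kcross, wnear, wfar;
  int sepcut, trunc;                  // trunc: 0 clamp at k, 1 none
};

static System read_system(const List& sys) {
  System S;
  S.L = as<int>(sys["L"]);
  S.npart = as<int>(sys["npart"]);
  S.iN = as<std::vector<int> >(sys["idxN"]);
  S.iH = as<std::vector<int> >(sys["idxH"]);
  S.iCA = as<std::vector<int> >(sys["idxCA"]);
  S.iC = as<std::vector<int> >(sys["idxC"]);
  S.iO = as<std::vector<int> >(sys["idxO"]);
  S.iSC = as<std::vector<int> >(sys["idxSC"]);
  S.sc_dist = as<std::vector<double> >(sys["sc_dist"]);
  S.geom = read_geom(sys["geom"]);
  S.type = as<std::vector<int> >(sys["type"]);
  S.EPS = as<NumericMatrix>(sys["EPS"]);
  S.R0 = as<NumericMatrix>(sys["R0"]);
  S.NN = as<NumericMatrix>(sys["NN"]);
  S.MM = as<NumericMatrix>(sys["MM"]);
  LogicalMatrix keep = sys["keep"];
  S.keep.assign(S.npart * S.npart, 0);
  for (int i = 0; i < S.npart; ++i)
    for (int j = 0; j < S.npart; ++j)
      S.keep[i * S.npart + j] = keep(i, j) ? 1 : 0;
  LogicalVector ch = sys["charged_sc"];
  S.charged_sc.assign(ch.begin(), ch.end());
  S.philow = as<std::vector<double> >(sys["phi_low"]);
  S.phihigh = as<std::vector<double> >(sys["phi_high"]);
  S.psilow = as<std::vector<double> >(sys["psi_low"]);
  S.psihigh = as<std::vector<double> >(sys["psi_high"]);
  S.eps_phi = as<double>(sys["eps_phi"]);
  List hb = sys["hb"];
  S.sigma = as<double>(hb["sigma"]);
  S.depth = as<double>(hb["depth"]);
  S.eps_a = as<double>(hb["eps_alpha_hb"]);
  S.eps_b = as<double>(hb["eps_beta_hb"]);
  S.coop_a = as<double>(hb["eps_alpha_coop"]);
  S.coop_b = as<double>(hb["eps_beta_coop"]);
  S.rec_frac = as<double>(hb["record_threshold"]);
  S.min_sep = as<int>(hb["min_separation"]);
  LogicalVector dok = hb["donor_ok"];
  S.donor_ok.assign(dok.begin(), dok.end());
  List dh = sys["dh"];
  S.use_dh = as<bool>(dh["use_dh"]);
  S.cidx = as<std::vector<int> >(dh["cidx"]);
  S.cq = as<std::vector<double> >(dh["cq"]);
  S.resid = as<std::vector<int> >(sys["resid"]);
  S.SHIFT = as<NumericMatrix>(dh["shift"]);
  S.CROSS = as<NumericMatrix>(dh["crossing"]);
  S.l_dh = as<double>(dh["l_dh"]);
  S.dw = as<double>(dh["dw"]);
  S.dp = as<double>(dh["dp"]);
  S.s = as<double>(dh["s"]);
  S.coul = as<double>(dh["coulomb"]);
  S.kcross = as<double>(dh["k_cross"]);
  S.wnear = as<double>(dh["w_near"]);
  S.wfar = as<double>(dh["w_far"]);
  S.sepcut = as<int>(dh["separation_cutoff"]);
  S.trunc = as<int>(dh["trunc"]);
  return S;
}

static inline double wrap180(double x) {
  double y = x + 180.0;
  y -= 360.0 * std::floor(y / 360.0);
  return y - 180.0;
}

// periodic distance (degrees) from an angle to the nearest interval bound
static inline double well_penalty(double x, double lo, double hi,
                                  double eps) {
  x = wrap180(x);
  if (x >= lo && x <= hi) return 0.0;
  double dlo = std::fabs(wrap180(x - lo));
  double dhi = std::fabs(wrap180(x - hi));
  double d = dlo < dhi ? dlo : dhi;
  return eps * d * d;
}

static inline double mie_term(double r, double eps, double r0, double n,
                              double m) {
  double E;
  if (n == 12.0 && m == 6.0) {
    double q = (r0 * r0) / (r * r);
    double q3 = q * q * q;
    E = eps * (q3 * q3 - 2.0 * q3);
  } else {
    double rr = r0 / r;
    E = eps * (m / (n - m) * std::pow(rr, n) - n / (n - m) * std::pow(rr, m));
  }
  return E;
}

static inline double dielec(double r, double dw, double dp, double s) {
  if (r <= 0) return dp;
  double sr = s * r;
  return dw - (dw - dp) * (0.5 * sr * sr + sr + 1.0) * std::exp(-sr);
}

static void compute_energy(const double* X, const double* phi,
                           const double* psi, const System& S,
                           double comps[5], std::vector<HBond>* rec) {
  double e_local = 0, e_nb = 0, e_hb = 0, e_coop = 0, e_dh = 0;
  // local flat-bottomed wells: phi for residues 2..L, psi for 1..L-1
  for (int i = 1; i < S.L; ++i)
    e_local += well_penalty(phi[i], S.philow[i], S.phihigh[i], S.eps_phi);
  for (int i = 0; i < S.L - 1; ++i)
    e_local += well_penalty(psi[i], S.psilow[i], S.psihigh[i], S.eps_phi);
  // Mie non-bonded
  for (int i = 0; i < S.npart; ++i) {
    const double* xi = X + 3 * i;
    int ti = S.type[i];
    for (int j = i + 1; j < S.npart; ++j) {
      if (!S.keep[i * S.npart + j]) continue;
      double d0 = xi[0] - X[3 * j], d1 = xi[1] - X[3 * j + 1],
             d2 = xi[2] - X[3 * j + 2];
      double r = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
      int tj = S.type[j];
      double E = mie_term(r, S.EPS(ti, tj), S.R0(ti, tj), S.NN(ti, tj),
                          S.MM(ti, tj));
      if (S.charged_sc[i] && S.charged_sc[j] && E < 0) E = 0.0;
      e_nb += E;
    }
  }
  // pairwise H-bonds; record those beyond the threshold
  std::vector<HBond> local_rec;
  std::vector<HBond>& hbl = rec ? *rec : local_rec;
  hbl.clear();
  for (int i = 0; i < S.L; ++i) {         // donor residue
    if (!S.donor_ok[i]) continue;
    const double* Hp = X + 3 * S.iH[i];
    const double* Np = X + 3 * S.iN[i];
    for (int j = 0; j < S.L; ++j) {       // acceptor residue
      int sep = i - j;
      if (sep < 0) sep = -sep;
      if (sep < S.min_sep) continue;
      const double* Op = X + 3 * S.iO[j];
      double d0 = Hp[0] - Op[0], d1 = Hp[1] - Op[1], d2 = Hp[2] - Op[2];
      double r = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
      double q = S.sigma / r, q2 = q * q, q10 = q2 * q2 * q2 * q2 * q2;
      double mu = S.depth * (5.0 * q10 * q2 - 6.0 * q10);
      // angle N-H...O at H
      double a0 = Np[0] - Hp[0], a1 = Np[1] - Hp[1], a2 = Np[2] - Hp[2];
      double na = std::sqrt(a0 * a0 + a1 * a1 + a2 * a2);
      double cb = -(a0 * d0 + a1 * d1 + a2 * d2) / (na * r);
      double nu = (cb < 0) ? cb * cb : 0.0;
      double w = (i - j == S.min_sep) ? S.eps_a : S.eps_b;
      double munu = mu * nu;
      e_hb += w * munu;
      if (munu <= -S.rec_frac * S.depth) {
        HBond h; h.donor = i; h.acceptor = j; h.r = r;
        hbl.push_back(h);
      }
    }
  }
  // cooperative four-body term over recorded H-bond pairs
  for (size_t a = 0; a < hbl.size(); ++a) {
    for (size_t b = a + 1; b < hbl.size(); ++b) {
      int dd = hbl[b].donor - hbl[a].donor;
      int da = hbl[b].acceptor - hbl[a].acceptor;
      double w = 0;
      if (dd == 1 && da == 1) w = S.coop_a;
      else if (dd == 2 && (da == -2 || da == 2)) w = S.coop_b;
      if (w != 0) {
        double x1 = hbl[a].r - S.sigma, x2 = hbl[b].r - S.sigma;
        e_coop += w * std::exp(-0.5 * x1 * x1) * std::exp(-0.5 * x2 * x2);
      }
    }
  }
  // Debye-Hueckel over charged particle pairs
  if (S.use_dh) {
    int nc = S.cidx.size();
    for (int a = 0; a < nc; ++a) {
      int i = S.cidx[a];
      for (int b = a + 1; b < nc; ++b) {
        int j = S.cidx[b];
        if (j <= i + 1) continue;
        int rsep = S.resid[j] - S.resid[i];
        if (rsep < 0) rsep = -rsep;
        if (rsep < 1) continue;
        double d0 = X[3 * i] - X[3 * j], d1 = X[3 * i + 1] - X[3 * j + 1],
               d2 = X[3 * i + 2] - X[3 * j + 2];
        double r = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
        double rs = r + S.SHIFT(a, b);
        double qq = S.cq[a] * S.cq[b];
        double E;
        if (rs <= 1e-6) {
          E = (qq > 0 ? S.kcross : -S.kcross);
        } else {
          E = S.coul * qq * std::exp(-rs / S.l_dh) /
              (dielec(r, S.dw, S.dp, S.s) * rs);
        }
        if (S.trunc == 0 && r < S.CROSS(a, b) && std::fabs(E) > S.kcross)
          E = (E > 0 ? S.kcross : -S.kcross);
        double w = (rsep < S.sepcut) ? S.wnear : S.wfar;
        e_dh += w * E;
      }
    }
  }
  comps[0] = e_local; comps[1] = e_nb; comps[2] = e_hb;
  comps[3] = e_coop; comps[4] = e_dh;
}

static List energy_list(const double comps[5],
                        const std::vector<HBond>& rec) {
  int nh = rec.size();
  IntegerVector don(nh), acc(nh);
  NumericVector rr(nh);
  for (int i = 0; i < nh; ++i) {
    don[i] = rec[i].donor + 1;          // back to 1-based residues
    acc[i] = rec[i].acceptor + 1;
    rr[i] = rec[i].r;
  }
  return List::create(
      _["e_local"] = comps[0], _["e_nonbonded"] = comps[1],
      _["e_hb_pairwise"] = comps[2], _["e_hb_coop"] = comps[3],
      _["e_dh"] = comps[4],
      _["e_total"] = comps[0] + comps[1] + comps[2] + comps[3] + comps[4],
      _["hb_donor"] = don, _["hb_acceptor"] = acc, _["hb_r"] = rr);
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix coords, NumericVector phi, NumericVector psi,
                List sys) {
  System S = read_system(sys);
  std::vector<double> X(S.npart * 3);
  for (int i = 0; i < S.npart; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = coords(i, k);
  double comps[5];
  std::vector<HBond> rec;
  compute_energy(X.data(), phi.begin(), psi.begin(), S, comps, &rec);
  return energy_list(comps, rec);
}

// [[Rcpp::export]]
List cpp_mc_anneal(NumericVector phi0, NumericVector psi0, List sys,
                   NumericVector temps, int steps_per_temp, double max_step,
                   double p_pivot) {
  System S = read_system(sys);
  int L = S.L;
  std::vector<double> phi(phi0.begin(), phi0.end()),
      psi(psi0.begin(), psi0.end());
  std::vector<double> X(S.npart * 3), Xp(S.npart * 3);
  build_chain_core(L, phi.data(), psi.data(), S.iN.data(), S.iH.data(),
                   S.iCA.data(), S.iC.data(), S.iO.data(), S.iSC.data(),
                   S.sc_dist.data(), S.geom, X.data());
  double comps[5];
  compute_energy(X.data(), phi.data(), psi.data(), S, comps, NULL);
  double E = comps[0] + comps[1] + comps[2] + comps[3] + comps[4];
  double sd = max_step / 2.0;
  int accepted = 0, total = 0;
  for (int t = 0; t < temps.size(); ++t) {
    double T = temps[t];
    for (int step = 0; step < steps_per_temp; ++step) {
      int r = (int)std::floor(unif_rand() * L);
      if (r >= L) r = L - 1;
      double oldphi = phi[r], oldpsi = psi[r];
      if (unif_rand() < p_pivot) {
        // pivot: redraw one dihedral uniformly
        if (unif_rand() < 0.5)
          phi[r] = wrap180(unif_rand() * 360.0 - 180.0);
        else
          psi[r] = wrap180(unif_rand() * 360.0 - 180.0);
      } else {
        phi[r] = wrap180(phi[r] + norm_rand() * sd);
        psi[r] = wrap180(psi[r] + norm_rand() * sd);
      }
      build_chain_core(L, phi.data(), psi.data(), S.iN.data(), S.iH.data(),
                       S.iCA.data(), S.iC.data(), S.iO.data(), S.iSC.data(),
                       S.sc_dist.data(), S.geom, Xp.data());
      compute_energy(Xp.data(), phi.data(), psi.data(), S, comps, NULL);
      double Ep = comps[0] + comps[1] + comps[2] + comps[3] + comps[4];
      double dE = Ep - E;
      bool acc = (dE <= 0) || (unif_rand() < std::exp(-dE / T));
      ++total;
      if (acc) {
        E = Ep;
        X.swap(Xp);
        ++accepted;
      } else {
        phi[r] = oldphi;
        psi[r] = oldpsi;
      }
    }
  }
  std::vector<HBond> rec;
  compute_energy(X.data(), phi.data(), psi.data(), S, comps, &rec);
  NumericMatrix Xout(S.npart, 3);
  for (int i = 0; i < S.npart; ++i)
    for (int k = 0; k < 3; ++k) Xout(i, k) = X[3 * i + k];
  List en = energy_list(comps, rec);
  return List::create(_["phi"] = NumericVector(phi.begin(), phi.end()),
                      _["psi"] = NumericVector(psi.begin(), psi.end()),
                      _["coords"] = Xout, _["energy"] = en,
                      _["acceptance"] = (double)accepted / (double)total);
}
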