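// Geometric molecular potential for reduced-representation cyclic peptides,
// plus the hot loops that call it: torsion-space Metropolis annealing, a
// NeRF internal-coordinate builder, and an exhaustive torsion-grid
// enumerator with ring-closure reach pruning.
//
// Energy terms (kJ/mol):
//   bond      k_b (r - r0)^2                       (closure bond reported apart)
//   angle     k_a (theta - theta0)^2
//   torsion   k_t (1 + cos 3 phi)                  (soft 3-fold rotors)
//   repulsion k_rep (rmin - r)^2 for r < rmin      (soft spheres, 1-2/1-3 excluded)
//   omega     k (1 - cos(phi - phi0))              (peptide-bond planarity)
//   chirality k (1 - cos(phi - phi0))              (improper dihedrals at CA)
//   restraint k_noe * flat-bottom(d; lo, up)       (NOE distance restraints)
//   compaction k_rg (Rg - rg0)^2 for Rg > rg0      (optional, generator only)
//
// All indices arriving from R are 1-based and converted here.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline void cross3(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double *a) { return std::sqrt(dot3(a, a)); }

struct Model {
  std::vector<int> bi, bj;          // bonds
  std::vector<double> br0;
  std::vector<int> bclo;            // 1 if ring-closure bond
  double kbond;
  std::vector<int> ai, aj, ak;      // angles (vertex j)
  std::vector<double> ath0;
  double kangle;
  std::vector<int> t3a, t3b, t3c, t3d;  // 3-fold torsions
  double k3;
  std::vector<int> ha, hb, hc, hd;  // harmonic (1 - cos) torsions
  std::vector<double> hphi0, hk;
  std::vector<int> hclass;          // 0 omega, 1 chirality, 2 torsion bucket
  std::vector<int> nbi, nbj;        // soft-sphere pairs
  std::vector<double> nbrmin;
  double krep;
  std::vector<int> rri, rrj;        // restraints
  std::vector<double> rlo, rup;
  double rg_k, rg0;

  explicit Model(const List &m) {
    IntegerVector v;
    NumericVector w;
    v = m["bond_i"]; bi.assign(v.begin(), v.end());
    v = m["bond_j"]; bj.assign(v.begin(), v.end());
    w = m["bond_r0"]; br0.assign(w.begin(), w.end());
    v = m["bond_closure"]; bclo.assign(v.begin(), v.end());
    kbond = as<double>(m["k_bond"]);
    v = m["ang_i"]; ai.assign(v.begin(), v.end());
    v = m["ang_j"]; aj.assign(v.begin(), v.end());
    v = m["ang_k"]; ak.assign(v.begin(), v.end());
    w = m["ang_th0"]; ath0.assign(w.begin(), w.end());
    kangle = as<double>(m["k_angle"]);
    v = m["t3_a"]; t3a.assign(v.begin(), v.end());
    v = m["t3_b"]; t3b.assign(v.begin(), v.end());
    v = m["t3_c"]; t3c.assign(v.begin(), v.end());
    v = m["t3_d"]; t3d.assign(v.begin(), v.end());
    k3 = as<double>(m["k_torsion3"]);
    v = m["h_a"]; ha.assign(v.begin(), v.end());
    v = m["h_b"]; hb.assign(v.begin(), v.end());
    v = m["h_c"]; hc.assign(v.begin(), v.end());
    v = m["h_d"]; hd.assign(v.begin(), v.end());
    w = m["h_phi0"]; hphi0.assign(w.begin(), w.end());
    w = m["h_k"]; hk.assign(w.begin(), w.end());
    v = m["h_class"]; hclass.assign(v.begin(), v.end());
    v = m["nb_i"]; nbi.assign(v.begin(), v.end());
    v = m["nb_j"]; nbj.assign(v.begin(), v.end());
    w = m["nb_rmin"]; nbrmin.assign(w.begin(), w.end());
    krep = as<double>(m["k_rep"]);
    v = m["restr_i"]; rri.assign(v.begin(), v.end());
    v = m["restr_j"]; rrj.assign(v.begin(), v.end());
    w = m["restr_lo"]; rlo.assign(w.begin(), w.end());
    w = m["restr_up"]; rup.assign(w.begin(), w.end());
    rg_k = as<double>(m["rg_k"]);
    rg0 = as<double>(m["rg0"]);
    for (size_t q = 0; q < bi.size(); ++q) { bi[q]--; bj[q]--; }
    for (size_t q = 0; q < ai.size(); ++q) { ai[q]--; aj[q]--; ak[q]--; }
    for (size_t q = 0; q < t3a.size(); ++q) { t3a[q]--; t3b[q]--; t3c[q]--; t3d[q]--; }
    for (size_t q = 0; q < ha.size(); ++q) { ha[q]--; hb[q]--; hc[q]--; hd[q]--; }
    for (size_t q = 0; q < nbi.size(); ++q) { nbi[q]--; nbj[q]--; }
    for (size_t q = 0; q < rri.size(); ++q) { rri[q]--; rrj[q]--; }
  }
};

// Dihedral angle i-j-k-l and, optionally, its gradient wrt the four atoms.
static double dihedral_g(const double *x, int i, int j, int k, int l,
                         double g[4][3], bool want_g) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], cr[3];
  for (int d = 0; d < 3; ++d) {
    b1[d] = x[3 * j + d] - x[3 * i + d];
    b2[d] = x[3 * k + d] - x[3 * j + d];
    b3[d] = x[3 * l + d] - x[3 * k + d];
  }
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double nb2 = norm3(b2);
  cross3(n1, n2, cr);
  double phi = std::atan2(dot3(cr, b2) / nb2, dot3(n1, n2));
  if (want_g) {
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    if (n1sq < 1e-14 || n2sq < 1e-14) {
      for (int a = 0; a < 4; ++a) for (int d = 0; d < 3; ++d) g[a][d] = 0.0;
      return phi;
    }
    double A = dot3(b1, b2) / (nb2 * nb2);
    double B = dot3(b3, b2) / (nb2 * nb2);
    for (int d = 0; d < 3; ++d) {
      double gi = -nb2 / n1sq * n1[d];
      double gl = nb2 / n2sq * n2[d];
      g[0][d] = gi;
      g[3][d] = gl;
      g[1][d] = -(1.0 + A) * gi + B * gl;
      g[2][d] = A * gi - (1.0 + B) * gl;
    }
  }
  return phi;
}

// terms: 0 bond 1 angle 2 torsion 3 repulsion 4 omega 5 chirality
//        6 closure 7 restraint(RAW, unit force constant) 8 compaction
// Returned total includes the restraint term scaled by k_noe.
static double energy_all(const double *x, int n, const Model &M, double k_noe,
                         double *grad, double *terms) {
  for (int t = 0; t < 9; ++t) terms[t] = 0.0;
  if (grad) std::fill(grad, grad + 3 * n, 0.0);

  // bonds (closure bond routed to its own term)
  for (size_t q = 0; q < M.bi.size(); ++q) {
    int i = M.bi[q], j = M.bj[q];
    double d[3];
    for (int c = 0; c < 3; ++c) d[c] = x[3 * i + c] - x[3 * j + c];
    double r = norm3(d), dr = r - M.br0[q];
    terms[M.bclo[q] ? 6 : 0] += M.kbond * dr * dr;
    if (grad && r > 1e-12) {
      double f = 2.0 * M.kbond * dr / r;
      for (int c = 0; c < 3; ++c) {
        grad[3 * i + c] += f * d[c];
        grad[3 * j + c] -= f * d[c];
      }
    }
  }

  // angles
  for (size_t q = 0; q < M.ai.size(); ++q) {
    int i = M.ai[q], j = M.aj[q], k = M.ak[q];
    double u[3], v[3];
    for (int c = 0; c < 3; ++c) {
      u[c] = x[3 * i + c] - x[3 * j + c];
      v[c] = x[3 * k + c] - x[3 * j + c];
    }
    double nu = norm3(u), nv = norm3(v);
    double cth = dot3(u, v) / (nu * nv);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth), dth = th - M.ath0[q];
    terms[1] += M.kangle * dth * dth;
    if (grad) {
      double s = std::sqrt(std::max(1e-12, 1.0 - cth * cth));
      double f = 2.0 * M.kangle * dth;
      for (int c = 0; c < 3; ++c) {
        double dthdi = (cth * u[c] / (nu * nu) - v[c] / (nu * nv)) / s;
        double dthdk = (cth * v[c] / (nv * nv) - u[c] / (nu * nv)) / s;
        grad[3 * i + c] += f * dthdi;
        grad[3 * k + c] += f * dthdk;
        grad[3 * j + c] -= f * (dthdi + dthdk);
      }
    }
  }

  // 3-fold torsions
  double g4[4][3];
  for (size_t q = 0; q < M.t3a.size(); ++q) {
    double phi = dihedral_g(x, M.t3a[q], M.t3b[q], M.t3c[q], M.t3d[q], g4,
                            grad != nullptr);
    terms[2] += M.k3 * (1.0 + std::cos(3.0 * phi));
    if (grad) {
      double dEdphi = -3.0 * M.k3 * std::sin(3.0 * phi);
      int idx[4] = {M.t3a[q], M.t3b[q], M.t3c[q], M.t3d[q]};
      for (int a = 0; a < 4; ++a)
        for (int c = 0; c < 3; ++c) grad[3 * idx[a] + c] += dEdphi * g4[a][c];
    }
  }

  // harmonic (1 - cos) torsions: omega planarity, chirality impropers, etc.
  for (size_t q = 0; q < M.ha.size(); ++q) {
    double phi = dihedral_g(x, M.ha[q], M.hb[q], M.hc[q], M.hd[q], g4,
                            grad != nullptr);
    int bucket = (M.hclass[q] == 0) ? 4 : (M.hclass[q] == 1 ? 5 : 2);
    terms[bucket] += M.hk[q] * (1.0 - std::cos(phi - M.hphi0[q]));
    if (grad) {
      double dEdphi = M.hk[q] * std::sin(phi - M.hphi0[q]);
      int idx[4] = {M.ha[q], M.hb[q], M.hc[q], M.hd[q]};
      for (int a = 0; a < 4; ++a)
        for (int c = 0; c < 3; ++c) grad[3 * idx[a] + c] += dEdphi * g4[a][c];
    }
  }

  // soft-sphere repulsion
  for (size_t q = 0; q < M.nbi.size(); ++q) {
    int i = M.nbi[q], j = M.nbj[q];
    double d[3];
    for (int c = 0; c < 3; ++c) d[c] = x[3 * i + c] - x[3 * j + c];
    double r2 = dot3(d, d), rmin = M.nbrmin[q];
    if (r2 < rmin * rmin) {
      double r = std::sqrt(r2), dr = rmin - r;
      terms[3] += M.krep * dr * dr;
      if (grad && r > 1e-12) {
        double f = -2.0 * M.krep * dr / r;
        for (int c = 0; c < 3; ++c) {
          grad[3 * i + c] += f * d[c];
          grad[3 * j + c] -= f * d[c];
        }
      }
    }
  }

  // NOE flat-bottom restraints (raw, unit force constant)
  for (size_t q = 0; q < M.rri.size(); ++q) {
    int i = M.rri[q], j = M.rrj[q];
    double d[3];
    for (int c = 0; c < 3; ++c) d[c] = x[3 * i + c] - x[3 * j + c];
    double r = norm3(d);
    double viol = (r < M.rlo[q]) ? (r - M.rlo[q]) : (r > M.rup[q] ? r - M.rup[q] : 0.0);
    terms[7] += viol * viol;
    if (grad && viol != 0.0 && r > 1e-12) {
      double f = 2.0 * k_noe * viol / r;
      for (int c = 0; c < 3; ++c) {
        grad[3 * i + c] += f * d[c];
        grad[3 * j + c] -= f * d[c];
      }
    }
  }

  // optional radius-of-gyration compaction (flat-bottom above rg0)
  if (M.rg_k > 0.0 && R_finite(M.rg0)) {
    double cm[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) cm[c] += x[3 * i + c];
    for (int c = 0; c < 3; ++c) cm[c] /= n;
    double s2 = 0.0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) {
        double d = x[3 * i + c] - cm[c];
        s2 += d * d;
      }
    double rg = std::sqrt(s2 / n);
    if (rg > M.rg0) {
      double dr = rg - M.rg0;
      terms[8] += M.rg_k * dr * dr;
      if (grad && rg > 1e-12) {
        double f = 2.0 * M.rg_k * dr / (n * rg);
        for (int i = 0; i < n; ++i)
          for (int c = 0; c < 3; ++c) grad[3 * i + c] += f * (x[3 * i + c] - cm[c]);
      }
    }
  }

  return terms[0] + terms[1] + terms[2] + terms[3] + terms[4] + terms[5] +
         terms[6] + k_noe * terms[7] + terms[8];
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix xyz, List model, double k_noe, bool gradient) {
  int n = xyz.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = xyz(i, c);
  Model M(model);
  double terms[9];
  std::vector<double> g;
  double total;
  if (gradient) {
    g.resize(3 * n);
    total = energy_all(x.data(), n, M, k_noe, g.data(), terms);
  } else {
    total = energy_all(x.data(), n, M, k_noe, nullptr, terms);
  }
  NumericVector tv = NumericVector::create(
      _["bond"] = terms[0], _["angle"] = terms[1], _["torsion"] = terms[2],
      _["repulsion"] = terms[3], _["omega"] = terms[4],
      _["chirality"] = terms[5], _["closure"] = terms[6],
      _["restraint"] = k_noe * terms[7], _["compaction"] = terms[8]);
  List out = List::create(_["terms"] = tv, _["total"] = total);
  if (gradient) {
    NumericMatrix gm(n, 3);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) gm(i, c) = g[3 * i + c];
    out["grad"] = gm;
  }
  return out;
}

// Thin objective/gradient entry points for stats::optim.
// [[Rcpp::export]]
double cpp_obj(NumericVector par, List model, double k_noe) {
  int n = par.size() / 3;
  Model M(model);
  double terms[9];
  return energy_all(REAL(par), n, M, k_noe, nullptr, terms);
}

// [[Rcpp::export]]
NumericVector cpp_obj_grad(NumericVector par, List model, double k_noe) {
  int n = par.size() / 3;
  Model M(model);
  double terms[9];
  NumericVector g(3 * n);
  energy_all(REAL(par), n, M, k_noe, REAL(g), terms);
  return g;
}

static void rotate_about(std::vector<double> &x, int a, int b, double delta,
                         const std::vector<int> &atoms) {
  double u[3];
  for (int c = 0; c < 3; ++c) u[c] = x[3 * b + c] - x[3 * a + c];
  double nu = norm3(u);
  if (nu < 1e-12) return;
  for (int c = 0; c < 3; ++c) u[c] /= nu;
  double ct = std::cos(delta), st = std::sin(delta);
  for (size_t q = 0; q < atoms.size(); ++q) {
    int i = atoms[q];
    double v[3], uxv[3];
    for (int c = 0; c < 3; ++c) v[c] = x[3 * i + c] - x[3 * a + c];
    cross3(u, v, uxv);
    double udv = dot3(u, v);
    for (int c = 0; c < 3; ++c)
      x[3 * i + c] = x[3 * a + c] + v[c] * ct + uxv[c] * st +
                     u[c] * udv * (1.0 - ct);
  }
}

// Metropolis simulated annealing with single-torsion pivot moves.
// moves: list of list(a, b, atoms) -- axis a->b, downstream atom set.
// temps/k_noes/max_rot: per-step schedules (radians for max_rot).
// Uses R's RNG, so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
List cpp_anneal(NumericMatrix xyz, List model, List moves, NumericVector temps,
                NumericVector k_noes, NumericVector max_rot, double gas_const) {
  int n = xyz.nrow(), nsteps = temps.size(), nmov = moves.size();
  Model M(model);
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = xyz(i, c);

  std::vector<int> mova(nmov), movb(nmov);
  std::vector<std::vector<int>> movatoms(nmov);
  for (int m = 0; m < nmov; ++m) {
    List mv = moves[m];
    mova[m] = as<int>(mv["a"]) - 1;
    movb[m] = as<int>(mv["b"]) - 1;
    IntegerVector at = mv["atoms"];
    movatoms[m].resize(at.size());
    for (int q = 0; q < at.size(); ++q) movatoms[m][q] = at[q] - 1;
  }

  double terms[9];
  double e0 = energy_all(x.data(), n, M, 1.0, nullptr, terms);
  (void)e0;
  double cur_other = terms[0] + terms[1] + terms[2] + terms[3] + terms[4] +
                     terms[5] + terms[6] + terms[8];
  double cur_raw = terms[7];
  long accepted = 0;
  std::vector<double> saved;

  RNGScope scope;
  for (int s = 0; s < nsteps; ++s) {
    int m = (int)std::floor(unif_rand() * nmov);
    if (m >= nmov) m = nmov - 1;
    double delta = (2.0 * unif_rand() - 1.0) * max_rot[s];
    const std::vector<int> &at = movatoms[m];
    saved.resize(3 * at.size());
    for (size_t q = 0; q < at.size(); ++q)
      for (int c = 0; c < 3; ++c) saved[3 * q + c] = x[3 * at[q] + c];
    rotate_about(x, mova[m], movb[m], delta, at);
    energy_all(x.data(), n, M, 1.0, nullptr, terms);
    double new_other = terms[0] + terms[1] + terms[2] + terms[3] + terms[4] +
                       terms[5] + terms[6] + terms[8];
    double new_raw = terms[7];
    double k = k_noes[s];
    double dE = (new_other + k * new_raw) - (cur_other + k * cur_raw);
    bool acc = (dE <= 0.0) ||
               (unif_rand() < std::exp(-dE / (gas_const * temps[s])));
    if (acc) {
      cur_other = new_other;
      cur_raw = new_raw;
      ++accepted;
    } else {
      for (size_t q = 0; q < at.size(); ++q)
        for (int c = 0; c < 3; ++c) x[3 * at[q] + c] = saved[3 * q + c];
    }
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = x[3 * i + c];
  double k_end = nsteps > 0 ? k_noes[nsteps - 1] : 1.0;
  return List::create(_["xyz"] = out, _["accepted"] = (double)accepted,
                      _["energy"] = cur_other + k_end * cur_raw);
}

// NeRF placement: given placed A, B, C put D at bond length r from C, angle
// theta = B-C-D, dihedral phi = A-B-C-D.
static void nerf_place(const double *A, const double *B, const double *C,
                       double r, double theta, double phi, double *D) {
  double bc[3], ab[3], nrm[3], m[3];
  for (int c = 0; c < 3; ++c) {
    bc[c] = C[c] - B[c];
    ab[c] = B[c] - A[c];
  }
  double nbc = norm3(bc);
  for (int c = 0; c < 3; ++c) bc[c] /= nbc;
  cross3(ab, bc, nrm);
  double nn = norm3(nrm);
  if (nn < 1e-12) { nrm[0] = 0; nrm[1] = 0; nrm[2] = 1; nn = 1; }
  for (int c = 0; c < 3; ++c) nrm[c] /= nn;
  cross3(nrm, bc, m);
  double d0 = -r * std::cos(theta);
  double d1 = r * std::sin(theta) * std::cos(phi);
  double d2 = r * std::sin(theta) * std::sin(phi);
  for (int c = 0; c < 3; ++c) D[c] = C[c] + d0 * bc[c] + d1 * m[c] + d2 * nrm[c];
}

struct ZMat {
  std::vector<int> a, b, c, var;     // refs (0-based, -1 for seed rows), var idx
  std::vector<double> r, th, phi, off;
  int natoms;
  explicit ZMat(const List &zm) {
    IntegerVector ia = zm["a"], ib = zm["b"], ic = zm["c"], iv = zm["var"];
    NumericVector rr = zm["r"], tt = zm["theta"], pp = zm["phi"], oo = zm["offset"];
    natoms = ia.size();
    a.resize(natoms); b.resize(natoms); c.resize(natoms); var.resize(natoms);
    r.assign(rr.begin(), rr.end());
    th.assign(tt.begin(), tt.end());
    phi.assign(pp.begin(), pp.end());
    off.assign(oo.begin(), oo.end());
    for (int i = 0; i < natoms; ++i) {
      a[i] = ia[i] - 1; b[i] = ib[i] - 1; c[i] = ic[i] - 1;
      var[i] = iv[i];  // 0 = fixed, else 1-based variable index
    }
  }
};

static void build_from(const ZMat &Z, const NumericMatrix &seed,
                       const double *vals, double *x) {
  for (int i = 0; i < 3 && i < Z.natoms; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = seed(i, c);
  for (int i = 3; i < Z.natoms; ++i) {
    double phi = (Z.var[i] > 0) ? vals[Z.var[i] - 1] + Z.off[i] : Z.phi[i];
    nerf_place(&x[3 * Z.a[i]], &x[3 * Z.b[i]], &x[3 * Z.c[i]], Z.r[i], Z.th[i],
               phi, &x[3 * i]);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_build_zmat(List zmat, NumericMatrix seed, NumericVector vals) {
  ZMat Z(zmat);
  std::vector<double> x(3 * Z.natoms);
  build_from(Z, seed, vals.size() ? REAL(vals) : nullptr, x.data());
  NumericMatrix out(Z.natoms, 3);
  for (int i = 0; i < Z.natoms; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = x[3 * i + c];
  return out;
}

struct GridScan {
  const ZMat &Z;
  const NumericMatrix &seed;
  const Model &M;
  const std::vector<double> &grid;
  int nvar, topk, closure_i, closure_j;
  double closure_r0, gap_tol;
  std::vector<int> prune_at;          // per-atom: reach-check? (-1 no)
  std::vector<double> prune_reach;
  std::vector<double> x, vals;
  std::vector<int> assigned;          // which grid index per var (-1 unset)
  std::vector<double> best_e;
  std::vector<std::vector<double>> best_v;
  long n_leaves = 0, n_evals = 0;

  GridScan(const ZMat &Z_, const NumericMatrix &seed_, const Model &M_,
           const std::vector<double> &grid_, int nvar_, int topk_,
           int ci, int cj, double cr0, double gtol)
      : Z(Z_), seed(seed_), M(M_), grid(grid_), nvar(nvar_), topk(topk_),
        closure_i(ci), closure_j(cj), closure_r0(cr0), gap_tol(gtol),
        x(3 * Z_.natoms), vals(nvar_, 0.0), assigned(nvar_, -1) {}

  void consider_leaf() {
    ++n_leaves;
    double d[3];
    for (int c = 0; c < 3; ++c)
      d[c] = x[3 * closure_i + c] - x[3 * closure_j + c];
    if (std::fabs(norm3(d) - closure_r0) > gap_tol) return;
    double terms[9];
    double e = energy_all(x.data(), (int)Z.natoms, M, 1.0, nullptr, terms);
    ++n_evals;
    if ((int)best_e.size() < topk || e < best_e.back()) {
      size_t pos = std::upper_bound(best_e.begin(), best_e.end(), e) -
                   best_e.begin();
      best_e.insert(best_e.begin() + pos, e);
      best_v.insert(best_v.begin() + pos, vals);
      if ((int)best_e.size() > topk) {
        best_e.pop_back();
        best_v.pop_back();
      }
    }
  }

  void place(int i) {
    if (i == Z.natoms) {
      consider_leaf();
      return;
    }
    int v = Z.var[i] - 1;  // -1 if fixed
    if (v >= 0 && assigned[v] < 0) {
      for (size_t g = 0; g < grid.size(); ++g) {
        assigned[v] = (int)g;
        vals[v] = grid[g];
        place_here(i);
      }
      assigned[v] = -1;
      return;
    }
    place_here(i);
  }

  void place_here(int i) {
    if (i < 3) {
      for (int c = 0; c < 3; ++c) x[3 * i + c] = seed(i, c);
    } else {
      double phi = (Z.var[i] > 0) ? vals[Z.var[i] - 1] + Z.off[i] : Z.phi[i];
      nerf_place(&x[3 * Z.a[i]], &x[3 * Z.b[i]], &x[3 * Z.c[i]], Z.r[i],
                 Z.th[i], phi, &x[3 * i]);
    }
    if (prune_at[i] >= 0) {
      double d[3];
      for (int c = 0; c < 3; ++c)
        d[c] = x[3 * i + c] - x[3 * closure_j + c];
      if (norm3(d) > prune_reach[prune_at[i]]) return;
    }
    place(i + 1);
  }
};

// Exhaustive torsion-grid enumeration of a small cycle with ring-closure
// reach pruning; returns the top-k raw-energy closure-feasible assignments.
// [[Rcpp::export]]
List cpp_grid_scan(List zmat, NumericMatrix seed, int nvar, NumericVector grid,
                   List model, IntegerVector prune_atom,
                   NumericVector prune_reach, int closure_i, int closure_j,
                   double closure_r0, double gap_tol, int topk) {
  ZMat Z(zmat);
  Model M(model);
  std::vector<double> g(grid.begin(), grid.end());
  GridScan S(Z, seed, M, g, nvar, topk, closure_i - 1, closure_j - 1,
             closure_r0, gap_tol);
  S.prune_at.assign(Z.natoms, -1);
  S.prune_reach.assign(prune_reach.begin(), prune_reach.end());
  for (int q = 0; q < prune_atom.size(); ++q)
    S.prune_at[prune_atom[q] - 1] = q;
  S.place(0);
  int nk = (int)S.best_e.size();
  NumericMatrix vm(nk, nvar);
  NumericVector ev(nk);
  for (int i = 0; i < nk; ++i) {
    ev[i] = S.best_e[i];
    for (int v = 0; v < nvar; ++v) vm(i, v) = S.best_v[i][v];
  }
  return List::create(_["energies"] = ev, _["vars"] = vm,
                      _["n_leaves"] = (double)S.n_leaves,
                      _["n_evals"] = (double)S.n_evals);
}
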