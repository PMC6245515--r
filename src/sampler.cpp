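// Coarse-grained backbone model: NeRF torsion-space geometry, restraint
// energy (flat-bottom torsion wells, two-sigmoid pairwise terms, burial
// environment, contact wells), and a Metropolis Monte Carlo chain.
// All randomness comes from R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// ideal backbone internal coordinates (Angstrom, degrees)
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.2, A_C_N_CA = 121.7;
static const double B_C_O = 1.231, A_CA_C_O = 120.8;
static const double B_N_H = 1.010, A_C_N_H = 119.0;

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 unit(const Vec3& a) {
  double n = norm(a);
  return n > 0 ? a * (1.0 / n) : a;
}

// place atom D from A-B-C with bond length r, bond angle theta at C (deg),
// and dihedral chi = A-B-C-D (deg)
static Vec3 nerf(const Vec3& A, const Vec3& B, const Vec3& C,
                 double r, double theta, double chi) {
  double th = theta * DEG, ch = -chi * DEG;
  Vec3 bc = unit(C - B);
  Vec3 n = unit(cross(B - A, bc));
  Vec3 m = cross(n, bc);
  Vec3 d(-r * std::cos(th), r * std::sin(th) * std::cos(ch),
         r * std::sin(th) * std::sin(ch));
  return C + bc * d.x + m * d.y + n * d.z;
}

static double dihedral(const Vec3& A, const Vec3& B, const Vec3& C,
                       const Vec3& D) {
  Vec3 b1 = B - A, b2 = C - B, b3 = D - C;
  Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  Vec3 m1 = cross(n1, unit(b2));
  double x = dot(n1, n2), y = dot(m1, n2);
  return std::atan2(y, x) / DEG;
}

struct Chain {
  std::vector<Vec3> N, CA, C, O, H, CB;
  int L;
};

// build N/CA/C from torsions (omega fixed trans), then derive O, H, CB
static void build_chain(const std::vector<double>& phi,
                        const std::vector<double>& psi, Chain& ch) {
  int L = (int)phi.size();
  ch.L = L;
  ch.N.assign(L, Vec3()); ch.CA.assign(L, Vec3()); ch.C.assign(L, Vec3());
  ch.O.assign(L, Vec3()); ch.H.assign(L, Vec3()); ch.CB.assign(L, Vec3());
  ch.N[0] = Vec3(0, 0, 0);
  ch.CA[0] = Vec3(B_N_CA, 0, 0);
  double a = (180.0 - A_N_CA_C) * DEG;
  ch.C[0] = ch.CA[0] + Vec3(B_CA_C * std::cos(a), B_CA_C * std::sin(a), 0);
  for (int i = 1; i < L; ++i) {
    ch.N[i] = nerf(ch.N[i - 1], ch.CA[i - 1], ch.C[i - 1],
                   B_C_N, A_CA_C_N, psi[i - 1]);
    ch.CA[i] = nerf(ch.CA[i - 1], ch.C[i - 1], ch.N[i],
                    B_N_CA, A_C_N_CA, 180.0);          // omega trans
    ch.C[i] = nerf(ch.C[i - 1], ch.N[i], ch.CA[i],
                   B_CA_C, A_N_CA_C, phi[i]);
  }
  for (int i = 0; i < L; ++i) {
    ch.O[i] = nerf(ch.N[i], ch.CA[i], ch.C[i], B_C_O, A_CA_C_O,
                   psi[i] + 180.0);
    if (i > 0)
      ch.H[i] = nerf(ch.CA[i - 1], ch.C[i - 1], ch.N[i], B_N_H, A_C_N_H,
                     180.0);
    // idealized virtual Cbeta from the local backbone frame
    Vec3 b = ch.CA[i] - ch.N[i], c = ch.C[i] - ch.CA[i];
    Vec3 ax = cross(b, c);
    ch.CB[i] = ch.CA[i] + ax * (-0.58273431) + b * 0.56802827 +
               c * (-0.54067466);
  }
}

static void derive_from_coords(const NumericMatrix& N, const NumericMatrix& CA,
                               const NumericMatrix& C,
                               const std::vector<double>& psi, Chain& ch) {
  int L = N.nrow();
  ch.L = L;
  ch.N.resize(L); ch.CA.resize(L); ch.C.resize(L);
  ch.O.assign(L, Vec3()); ch.H.assign(L, Vec3()); ch.CB.assign(L, Vec3());
  for (int i = 0; i < L; ++i) {
    ch.N[i] = Vec3(N(i, 0), N(i, 1), N(i, 2));
    ch.CA[i] = Vec3(CA(i, 0), CA(i, 1), CA(i, 2));
    ch.C[i] = Vec3(C(i, 0), C(i, 1), C(i, 2));
  }
  for (int i = 0; i < L; ++i) {
    ch.O[i] = nerf(ch.N[i], ch.CA[i], ch.C[i], B_C_O, A_CA_C_O,
                   psi[i] + 180.0);
    if (i > 0)
      ch.H[i] = nerf(ch.CA[i - 1], ch.C[i - 1], ch.N[i], B_N_H, A_C_N_H,
                     180.0);
    Vec3 b = ch.CA[i] - ch.N[i], c = ch.C[i] - ch.CA[i];
    Vec3 ax = cross(b, c);
    ch.CB[i] = ch.CA[i] + ax * (-0.58273431) + b * 0.56802827 +
               c * (-0.54067466);
  }
}

static inline double sigmoid_term(double e, double r, double r0, double w) {
  double x = (r - r0) / w;
  if (x > 40.0) return 0.0;
  if (x < -40.0) return e;
  return e / (1.0 + std::exp(x));
}

// wrap a difference of angles into [-180, 180)
static inline double circ_diff(double a, double b) {
  double d = a - b;
  return d - 360.0 * std::floor((d + 180.0) / 360.0);
}

struct EnergyParams {
  std::vector<double> tor_phi, tor_psi;   // well centers (NaN = no restraint)
  double tor_delta, tor_k;
  double sc_e_in, sc_r_in, sc_w_in, sc_r_out, sc_w_out;
  NumericMatrix sc_e_out;                 // L x L pair attraction depths
  double hb_e_in, hb_r_in, hb_w_in, hb_e_out, hb_r_out, hb_w_out;
  std::vector<double> env_w;
  std::vector<int> con_i, con_j;
  std::vector<double> con_depth, con_width, con_rc;
  double w_tor, w_pair, w_env, w_con;
  int min_sep;                            // pairwise/env exclusion |i-j| > min_sep - 1
};

static EnergyParams read_params(const List& par) {
  EnergyParams p;
  p.tor_phi = as<std::vector<double> >(par["tor_phi"]);
  p.tor_psi = as<std::vector<double> >(par["tor_psi"]);
  p.tor_delta = as<double>(par["tor_delta"]);
  p.tor_k = as<double>(par["tor_k"]);
  NumericVector sc = par["sc_profile"];   // e_in, r_in, w_in, r_out, w_out
  p.sc_e_in = sc[0]; p.sc_r_in = sc[1]; p.sc_w_in = sc[2];
  p.sc_r_out = sc[3]; p.sc_w_out = sc[4];
  p.sc_e_out = as<NumericMatrix>(par["sc_e_out"]);
  NumericVector hb = par["hb_profile"];   // e_in, r_in, w_in, e_out, r_out, w_out
  p.hb_e_in = hb[0]; p.hb_r_in = hb[1]; p.hb_w_in = hb[2];
  p.hb_e_out = hb[3]; p.hb_r_out = hb[4]; p.hb_w_out = hb[5];
  p.env_w = as<std::vector<double> >(par["env_w"]);
  p.con_i = as<std::vector<int> >(par["con_i"]);
  p.con_j = as<std::vector<int> >(par["con_j"]);
  p.con_depth = as<std::vector<double> >(par["con_depth"]);
  p.con_width = as<std::vector<double> >(par["con_width"]);
  p.con_rc = as<std::vector<double> >(par["con_rc"]);
  NumericVector tw = par["term_weights"]; // torsion, pairwise, env, contact
  p.w_tor = tw[0]; p.w_pair = tw[1]; p.w_env = tw[2]; p.w_con = tw[3];
  p.min_sep = as<int>(par["min_sep"]);
  return p;
}

// energy breakdown: torsion, pairwise (side-chain + H-bond), environment,
// contact restraint, total
static NumericVector energy(const Chain& ch, const std::vector<double>& phi,
                            const std::vector<double>& psi,
                            const EnergyParams& p) {
  int L = ch.L;
  double e_tor = 0, e_pair = 0, e_env = 0, e_con = 0;

  if (p.w_tor != 0) {
    for (int i = 0; i < L; ++i) {
      if (!ISNAN(p.tor_phi[i])) {
        double ex = std::fabs(circ_diff(phi[i], p.tor_phi[i])) - p.tor_delta;
        if (ex > 0) e_tor += p.tor_k * ex * ex;
      }
      if (!ISNAN(p.tor_psi[i])) {
        double ex = std::fabs(circ_diff(psi[i], p.tor_psi[i])) - p.tor_delta;
        if (ex > 0) e_tor += p.tor_k * ex * ex;
      }
    }
  }

  if (p.w_pair != 0) {
    for (int i = 0; i < L; ++i) {
      for (int j = i + p.min_sep; j < L; ++j) {
        double d = norm(ch.CB[i] - ch.CB[j]);
        e_pair += sigmoid_term(p.sc_e_in, d, p.sc_r_in, p.sc_w_in) +
                  sigmoid_term(p.sc_e_out(i, j), d, p.sc_r_out, p.sc_w_out);
      }
    }
    // backbone H-bonds: amide H(i) to carbonyl O(j), |i-j| >= min_sep
    for (int i = 1; i < L; ++i) {
      for (int j = 0; j < L; ++j) {
        if (std::abs(i - j) < p.min_sep) continue;
        double d = norm(ch.H[i] - ch.O[j]);
        e_pair += sigmoid_term(p.hb_e_in, d, p.hb_r_in, p.hb_w_in) +
                  sigmoid_term(p.hb_e_out, d, p.hb_r_out, p.hb_w_out);
      }
    }
  }

  if (p.w_env != 0) {
    for (int i = 0; i < L; ++i) {
      if (p.env_w[i] == 0) continue;
      Vec3 axis = unit(ch.CB[i] - ch.CA[i]);
      double Ni = 0;
      for (int j = 0; j < L; ++j) {
        if (std::abs(i - j) <= 2) continue;
        Vec3 rij = ch.CB[j] - ch.CB[i];
        double d = norm(rij);
        double cosang = (d > 0) ? dot(unit(rij), axis) : 0.0;
        // hemisphere above Cbeta counts more: switch on -cos(angle)
        Ni += (1.0 / (1.0 + std::exp(d - 8.0))) *
              (1.0 / (1.0 + std::exp(-cosang + 0.1)));
      }
      e_env += p.env_w[i] * Ni;
    }
  }

  if (p.w_con != 0) {
    for (size_t k = 0; k < p.con_i.size(); ++k) {
      double d = norm(ch.CB[p.con_i[k] - 1] - ch.CB[p.con_j[k] - 1]);
      e_con += sigmoid_term(-p.con_depth[k], d, p.con_rc[k], p.con_width[k]);
    }
  }

  e_tor *= p.w_tor; e_pair *= p.w_pair; e_env *= p.w_env; e_con *= p.w_con;
  return NumericVector::create(_["torsion"] = e_tor, _["pairwise"] = e_pair,
                               _["environment"] = e_env, _["contact"] = e_con,
                               _["total"] = e_tor + e_pair + e_env + e_con);
}

// [[Rcpp::export]]
List cpp_build_backbone(NumericVector phi, NumericVector psi) {
  int L = phi.size();
  std::vector<double> ph(phi.begin(), phi.end()), ps(psi.begin(), psi.end());
  Chain ch;
  build_chain(ph, ps, ch);
  NumericMatrix N(L, 3), CA(L, 3), C(L, 3);
  for (int i = 0; i < L; ++i) {
    N(i, 0) = ch.N[i].x; N(i, 1) = ch.N[i].y; N(i, 2) = ch.N[i].z;
    CA(i, 0) = ch.CA[i].x; CA(i, 1) = ch.CA[i].y; CA(i, 2) = ch.CA[i].z;
    C(i, 0) = ch.C[i].x; C(i, 1) = ch.C[i].y; C(i, 2) = ch.C[i].z;
  }
  return List::create(_["N"] = N, _["CA"] = CA, _["C"] = C);
}

// [[Rcpp::export]]
List cpp_derive_atoms(NumericMatrix N, NumericMatrix CA, NumericMatrix C,
                      NumericVector psi) {
  std::vector<double> ps(psi.begin(), psi.end());
  Chain ch;
  derive_from_coords(N, CA, C, ps, ch);
  int L = ch.L;
  NumericMatrix O(L, 3), H(L, 3), CB(L, 3);
  for (int i = 0; i < L; ++i) {
    O(i, 0) = ch.O[i].x; O(i, 1) = ch.O[i].y; O(i, 2) = ch.O[i].z;
    H(i, 0) = ch.H[i].x; H(i, 1) = ch.H[i].y; H(i, 2) = ch.H[i].z;
    CB(i, 0) = ch.CB[i].x; CB(i, 1) = ch.CB[i].y; CB(i, 2) = ch.CB[i].z;
  }
  return List::create(_["O"] = O, _["H"] = H, _["CB"] = CB);
}

// [[Rcpp::export]]
NumericVector cpp_measure_torsions(NumericMatrix N, NumericMatrix CA,
                                   NumericMatrix C) {
  int L = N.nrow();
  NumericVector out(2 * L, NA_REAL);   // phi then psi
  std::vector<Vec3> vN(L), vCA(L), vC(L);
  for (int i = 0; i < L; ++i) {
    vN[i] = Vec3(N(i, 0), N(i, 1), N(i, 2));
    vCA[i] = Vec3(CA(i, 0), CA(i, 1), CA(i, 2));
    vC[i] = Vec3(C(i, 0), C(i, 1), C(i, 2));
  }
  for (int i = 1; i < L; ++i)
    out[i] = dihedral(vC[i - 1], vN[i], vCA[i], vC[i]);
  for (int i = 0; i < L - 1; ++i)
    out[L + i] = dihedral(vN[i], vCA[i], vC[i], vN[i + 1]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_energy_coords(NumericMatrix N, NumericMatrix CA,
                                NumericMatrix C, NumericVector phi,
                                NumericVector psi, List params) {
  std::vector<double> ph(phi.begin(), phi.end()), ps(psi.begin(), psi.end());
  Chain ch;
  derive_from_coords(N, CA, C, ps, ch);
  EnergyParams p = read_params(params);
  return energy(ch, ph, ps, p);
}

// [[Rcpp::export]]
List cpp_run_mc(NumericVector phi0, NumericVector psi0, List params,
                int steps, int capture_every, double temperature,
                double sigma) {
  int L = phi0.size();
  EnergyParams p = read_params(params);
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> psi(psi0.begin(), psi0.end());
  Chain ch;
  build_chain(phi, psi, ch);
  NumericVector eb = energy(ch, phi, psi, p);
  double e_cur = eb["total"];
  if (!R_finite(e_cur)) stop("input error: non-finite energy at start");

  int n_cap = steps / capture_every;
  NumericMatrix phi_frames(n_cap, L), psi_frames(n_cap, L);
  NumericVector energies(n_cap);
  long accepted = 0;
  int cap = 0;
  RNGScope scope;
  for (int s = 1; s <= steps; ++s) {
    int r = (int)(unif_rand() * L); if (r >= L) r = L - 1;
    bool move_phi = unif_rand() < 0.5;
    double old = move_phi ? phi[r] : psi[r];
    double prop = old + norm_rand() * sigma;
    prop = prop - 360.0 * std::floor((prop + 180.0) / 360.0);
    if (prop == -180.0) prop = 180.0;
    if (move_phi) phi[r] = prop; else psi[r] = prop;
    build_chain(phi, psi, ch);
    NumericVector eb_new = energy(ch, phi, psi, p);
    double e_new = eb_new["total"];
    double dE = e_new - e_cur;
    bool accept;
    if (dE <= 0) accept = true;
    else if (temperature <= 0) accept = false;
    else accept = unif_rand() < std::exp(-dE / temperature);
    if (accept) {
      e_cur = e_new;
      ++accepted;
    } else {
      if (move_phi) phi[r] = old; else psi[r] = old;
    }
    if (s % capture_every == 0) {
      for (int i = 0; i < L; ++i) {
        phi_frames(cap, i) = phi[i];
        psi_frames(cap, i) = psi[i];
      }
      energies[cap] = e_cur;
      ++cap;
    }
  }
  return List::create(_["phi"] = phi_frames, _["psi"] = psi_frames,
                      _["energies"] = energies,
                      _["acceptance_rate"] = (double)accepted / steps);
}
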