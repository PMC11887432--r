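// Simulation core: WCA + Ewald energetics and Monte Carlo move kernels.
//
// Units: lengths in nm, energies in kBT (epsilon and the Bjerrum length set
// the two energy scales). Charges in units of e. The box is cubic and
// periodic; positions are stored unwrapped and the minimum-image convention
// is applied inside all distance computations, so rigid bodies never get
// split across the boundary.
//
// Species codes (must match R/constants.R):
//   0 = nanoparticle core, 1 = ionizable site, 2 = Na+, 3 = Cl-, 4 = H+,
//   5 = OH-.
//
// All randomness goes through R's RNG (unif_rand), so set.seed() at the R
// level makes every kernel bitwise reproducible in a single thread.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;
typedef std::complex<double> cplx;

static const int NSPECIES = 6;
static const double INF = std::numeric_limits<double>::infinity();

struct Proposal {
  std::vector<int> mv_idx;                 // moved particles
  std::vector<double> mv_x, mv_y, mv_z;    // their new positions
  std::vector<int> qc_idx;                 // charge-changed particles
  std::vector<double> qc_q;                // their new charges
  std::vector<int> ins_sp;                 // inserted particles
  std::vector<double> ins_q, ins_x, ins_y, ins_z;
  std::vector<int> del_idx;                // deleted particles
  void clear() {
    mv_idx.clear(); mv_x.clear(); mv_y.clear(); mv_z.clear();
    qc_idx.clear(); qc_q.clear();
    ins_sp.clear(); ins_q.clear(); ins_x.clear(); ins_y.clear(); ins_z.clear();
    del_idx.clear();
  }
};

struct SimCore {
  // box
  double L = 0.0, V = 0.0;
  // interaction switches
  bool use_wca = true, use_coulomb = true;
  // WCA parameters
  double sigma = 0.355, eps = 1.0, rcut = 0.0;   // rcut = 2^(1/6) sigma
  std::vector<double> offm;                      // NSPECIES x NSPECIES, <0 => no WCA pair
  // electrostatics
  double lB = 0.71;
  double alpha = 0.0, r_ewald = 0.0, self_coeff = 0.0;
  int kmax = 0;
  std::vector<int> kxv, kyv, kzv;
  std::vector<double> Ak;                        // lB * 4*pi/V * exp(-k2/4a2)/k2 (half space)
  std::vector<cplx> Sk;
  // particles
  std::vector<int> sp;
  std::vector<double> q, px, py, pz;
  int n_fixed = 0;                               // cores + sites live in [0, n_fixed)
  // rigid bodies
  int n_bodies = 0;
  std::vector<int> core_of;                      // core particle index per body
  std::vector<std::vector<int>> members;         // all particle indices per body (incl. core)
  // bookkeeping
  std::vector<int> counts;                       // per-species particle counts
  double Utot = 0.0;
  bool energy_valid = false;

  int n() const { return (int)sp.size(); }

  double minimg(double d) const { return d - L * std::nearbyint(d / L); }

  double pair_energy(int si, double qi, double xi, double yi, double zi,
                     int sj, double qj, double xj, double yj, double zj) const {
    double dx = minimg(xi - xj), dy = minimg(yi - yj), dz = minimg(zi - zj);
    double r2 = dx * dx + dy * dy + dz * dz;
    double u = 0.0;
    double roff = offm[si * NSPECIES + sj];
    if (use_wca && roff >= 0.0) {
      double r = std::sqrt(r2);
      double x = r - roff;
      if (x <= 0.0) return INF;
      if (x < rcut) {
        double s2 = (sigma / x) * (sigma / x);
        double s6 = s2 * s2 * s2;
        u += 4.0 * eps * (s6 * s6 - s6) + eps;
      }
    }
    if (use_coulomb && qi != 0.0 && qj != 0.0) {
      double r = std::sqrt(r2);
      if (r < r_ewald) {
        if (r <= 0.0) return INF;
        u += lB * qi * qj * std::erfc(alpha * r) / r;
      }
    }
    return u;
  }

  void setup_ewald(double accuracy) {
    kxv.clear(); kyv.clear(); kzv.clear(); Ak.clear(); Sk.clear();
    if (!use_coulomb) { kmax = 0; alpha = 0.0; r_ewald = 0.0; self_coeff = 0.0; return; }
    // splitting parameter from the target accuracy: truncation errors of both
    // the erfc() real-space tail and the Gaussian reciprocal tail scale as
    // exp(-s^2) with s = alpha*rc = pi*kmax/(alpha*L)
    double s = std::sqrt(std::log(10.0 / accuracy));
    r_ewald = 0.5 * L;
    alpha = s / r_ewald;
    kmax = (int)std::ceil(2.0 * s * s / M_PI);
    self_coeff = lB * alpha / std::sqrt(M_PI);
    int k2max = kmax * kmax;
    for (int nx = 0; nx <= kmax; ++nx) {
      int ylo = (nx == 0) ? 0 : -kmax;
      for (int ny = ylo; ny <= kmax; ++ny) {
        int zlo = (nx == 0 && ny == 0) ? 1 : -kmax;
        for (int nz = zlo; nz <= kmax; ++nz) {
          int n2 = nx * nx + ny * ny + nz * nz;
          if (n2 == 0 || n2 > k2max) continue;
          kxv.push_back(nx); kyv.push_back(ny); kzv.push_back(nz);
          double k2 = (2.0 * M_PI / L) * (2.0 * M_PI / L) * n2;
          // half-space sum => factor 2; full prefactor lB * 2*pi/V * 2
          Ak.push_back(lB * 4.0 * M_PI / V * std::exp(-k2 / (4.0 * alpha * alpha)) / k2);
        }
      }
    }
    Sk.assign(Ak.size(), cplx(0.0, 0.0));
  }

  // exp(i k.r) tables for one particle, n = 0..kmax per axis
  void eikr_tables(double x, double y, double z,
                   std::vector<cplx>& ex, std::vector<cplx>& ey, std::vector<cplx>& ez) const {
    ex.resize(kmax + 1); ey.resize(kmax + 1); ez.resize(kmax + 1);
    double f = 2.0 * M_PI / L;
    cplx bx(std::cos(f * x), std::sin(f * x));
    cplx by(std::cos(f * y), std::sin(f * y));
    cplx bz(std::cos(f * z), std::sin(f * z));
    ex[0] = ey[0] = ez[0] = cplx(1.0, 0.0);
    for (int m = 1; m <= kmax; ++m) {
      ex[m] = ex[m - 1] * bx; ey[m] = ey[m - 1] * by; ez[m] = ez[m - 1] * bz;
    }
  }

  static cplx pick(const std::vector<cplx>& t, int m) {
    return (m >= 0) ? t[m] : std::conj(t[-m]);
  }

  // add w * exp(i k.r) of one particle into acc (length = #kvec)
  void accum_sk(std::vector<cplx>& acc, double w, double x, double y, double z) const {
    std::vector<cplx> ex, ey, ez;
    eikr_tables(x, y, z, ex, ey, ez);
    size_t nk = Ak.size();
    for (size_t k = 0; k < nk; ++k) {
      acc[k] += w * pick(ex, kxv[k]) * pick(ey, kyv[k]) * pick(ez, kzv[k]);
    }
  }

  void rebuild_sk() {
    if (!use_coulomb) return;
    std::fill(Sk.begin(), Sk.end(), cplx(0.0, 0.0));
    for (int i = 0; i < n(); ++i)
      if (q[i] != 0.0) accum_sk(Sk, q[i], px[i], py[i], pz[i]);
  }

  double recip_energy() const {
    double u = 0.0;
    for (size_t k = 0; k < Ak.size(); ++k) u += Ak[k] * std::norm(Sk[k]);
    return u;
  }

  double self_energy() const {
    double s = 0.0;
    for (int i = 0; i < n(); ++i) s += q[i] * q[i];
    return -self_coeff * s;
  }

  // fresh full energy; components: wca, real, recip, self
  void total_energy(double& uwca, double& ureal, double& urecip, double& uself) {
    uwca = 0.0; ureal = 0.0;
    int N = n();
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double dx = minimg(px[i] - px[j]), dy = minimg(py[i] - py[j]), dz = minimg(pz[i] - pz[j]);
        double r2 = dx * dx + dy * dy + dz * dz;
        double roff = offm[sp[i] * NSPECIES + sp[j]];
        if (use_wca && roff >= 0.0) {
          double r = std::sqrt(r2), x = r - roff;
          if (x <= 0.0) { uwca = INF; }
          else if (x < rcut) {
            double s2 = (sigma / x) * (sigma / x), s6 = s2 * s2 * s2;
            uwca += 4.0 * eps * (s6 * s6 - s6) + eps;
          }
        }
        if (use_coulomb && q[i] != 0.0 && q[j] != 0.0) {
          double r = std::sqrt(r2);
          if (r < r_ewald && r > 0.0) ureal += lB * q[i] * q[j] * std::erfc(alpha * r) / r;
        }
      }
    }
    if (use_coulomb) {
      rebuild_sk();
      urecip = recip_energy();
      uself = self_energy();
    } else { urecip = 0.0; uself = 0.0; }
  }

  double refresh() {
    double uw, ur, uk, us;
    total_energy(uw, ur, uk, us);
    Utot = uw + ur + uk + us;
    energy_valid = true;
    return Utot;
  }

  // Delta energy of a compound proposal; fills dSk (resized) for commit.
  // mv/qc/del index sets must be disjoint.
  double delta(const Proposal& p, std::vector<cplx>& dSk) {
    int N = n();
    std::vector<char> aff(N, 0);
    for (int i : p.mv_idx) aff[i] = 1;
    for (int i : p.qc_idx) aff[i] = 1;
    for (int i : p.del_idx) aff[i] = 1;
    // new-state entries
    std::vector<int> nsp_;
    std::vector<double> nq_, nx_, ny_, nz_;
    for (size_t m = 0; m < p.mv_idx.size(); ++m) {
      int i = p.mv_idx[m];
      nsp_.push_back(sp[i]); nq_.push_back(q[i]);
      nx_.push_back(p.mv_x[m]); ny_.push_back(p.mv_y[m]); nz_.push_back(p.mv_z[m]);
    }
    for (size_t m = 0; m < p.qc_idx.size(); ++m) {
      int i = p.qc_idx[m];
      nsp_.push_back(sp[i]); nq_.push_back(p.qc_q[m]);
      nx_.push_back(px[i]); ny_.push_back(py[i]); nz_.push_back(pz[i]);
    }
    for (size_t m = 0; m < p.ins_sp.size(); ++m) {
      nsp_.push_back(p.ins_sp[m]); nq_.push_back(p.ins_q[m]);
      nx_.push_back(p.ins_x[m]); ny_.push_back(p.ins_y[m]); nz_.push_back(p.ins_z[m]);
    }
    // new-state short-range energy first (early exit on overlap)
    double unew = 0.0;
    int na = (int)nsp_.size();
    for (int a = 0; a < na; ++a) {
      for (int j = 0; j < N; ++j) {
        if (aff[j]) continue;
        double u = pair_energy(nsp_[a], nq_[a], nx_[a], ny_[a], nz_[a],
                               sp[j], q[j], px[j], py[j], pz[j]);
        if (u == INF) return INF;
        unew += u;
      }
      for (int b = a + 1; b < na; ++b) {
        double u = pair_energy(nsp_[a], nq_[a], nx_[a], ny_[a], nz_[a],
                               nsp_[b], nq_[b], nx_[b], ny_[b], nz_[b]);
        if (u == INF) return INF;
        unew += u;
      }
    }
    // old-state short-range energy of the affected set
    std::vector<int> old_idx;
    for (int i = 0; i < N; ++i) if (aff[i]) old_idx.push_back(i);
    double uold = 0.0;
    int no = (int)old_idx.size();
    for (int a = 0; a < no; ++a) {
      int i = old_idx[a];
      for (int j = 0; j < N; ++j) {
        if (aff[j]) continue;
        uold += pair_energy(sp[i], q[i], px[i], py[i], pz[i],
                            sp[j], q[j], px[j], py[j], pz[j]);
      }
      for (int b = a + 1; b < no; ++b) {
        int j = old_idx[b];
        uold += pair_energy(sp[i], q[i], px[i], py[i], pz[i],
                            sp[j], q[j], px[j], py[j], pz[j]);
      }
    }
    double du = unew - uold;
    if (use_coulomb) {
      dSk.assign(Ak.size(), cplx(0.0, 0.0));
      double dq2 = 0.0;
      for (int i : old_idx) {
        if (q[i] != 0.0) accum_sk(dSk, -q[i], px[i], py[i], pz[i]);
        dq2 -= q[i] * q[i];
      }
      for (int a = 0; a < na; ++a) {
        if (nq_[a] != 0.0) accum_sk(dSk, nq_[a], nx_[a], ny_[a], nz_[a]);
        dq2 += nq_[a] * nq_[a];
      }
      double durec = 0.0;
      for (size_t k = 0; k < Ak.size(); ++k) {
        durec += Ak[k] * (2.0 * (Sk[k].real() * dSk[k].real() + Sk[k].imag() * dSk[k].imag())
                          + std::norm(dSk[k]));
      }
      du += durec - self_coeff * dq2;
    }
    return du;
  }

  void commit(const Proposal& p, const std::vector<cplx>& dSk, double du) {
    for (size_t m = 0; m < p.mv_idx.size(); ++m) {
      int i = p.mv_idx[m];
      px[i] = p.mv_x[m]; py[i] = p.mv_y[m]; pz[i] = p.mv_z[m];
    }
    for (size_t m = 0; m < p.qc_idx.size(); ++m) q[p.qc_idx[m]] = p.qc_q[m];
    for (size_t m = 0; m < p.ins_sp.size(); ++m) {
      sp.push_back(p.ins_sp[m]); q.push_back(p.ins_q[m]);
      px.push_back(p.ins_x[m]); py.push_back(p.ins_y[m]); pz.push_back(p.ins_z[m]);
      counts[p.ins_sp[m]]++;
    }
    if (!p.del_idx.empty()) {
      std::vector<int> del = p.del_idx;
      std::sort(del.begin(), del.end(), std::greater<int>());
      for (int i : del) {
        if (i < n_fixed) stop("internal error: attempt to delete a fixed particle");
        counts[sp[i]]--;
        int last = n() - 1;
        sp[i] = sp[last]; q[i] = q[last];
        px[i] = px[last]; py[i] = py[last]; pz[i] = pz[last];
        sp.pop_back(); q.pop_back(); px.pop_back(); py.pop_back(); pz.pop_back();
      }
    }
    if (use_coulomb)
      for (size_t k = 0; k < Ak.size(); ++k) Sk[k] += dSk[k];
    if (energy_valid) Utot += du;
  }

  // ---- selection helpers ----
  int runif_int(int m) const {            // uniform in 0..m-1
    int r = (int)std::floor(unif_rand() * m);
    return (r >= m) ? m - 1 : r;
  }

  // random site index with protonation state: proto=1 -> HA (q == 0),
  // proto=0 -> A- (q < 0); returns -1 if none
  int random_site(int proto) const {
    std::vector<int> elig;
    for (int i = 0; i < n_fixed; ++i) {
      if (sp[i] != 1) continue;
      bool isHA = (q[i] == 0.0);
      if ((proto == 1) == isHA) elig.push_back(i);
    }
    if (elig.empty()) return -1;
    return elig[runif_int((int)elig.size())];
  }

  int random_ion(int species) const {
    int m = counts[species];
    if (m <= 0) return -1;
    int k = runif_int(m);
    for (int i = n_fixed; i < n(); ++i) {
      if (sp[i] == species) { if (k == 0) return i; --k; }
    }
    return -1; // unreachable if counts are consistent
  }

  int count_sites(int proto) const {
    int c = 0;
    for (int i = 0; i < n_fixed; ++i)
      if (sp[i] == 1 && ((proto == 1) == (q[i] == 0.0))) ++c;
    return c;
  }
};

static Proposal g_prop;              // scratch proposal (single-threaded)
static std::vector<cplx> g_dSk;      // scratch delta structure factor

static SimCore* get(SEXP xp) {
  Rcpp::XPtr<SimCore> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP core_new(double L, IntegerVector species, NumericVector charge,
              NumericMatrix pos, IntegerVector body, int n_fixed,
              NumericMatrix offsets, double sigma, double eps, double lB,
              double accuracy, bool use_wca, bool use_coulomb) {
  SimCore* c = new SimCore();
  c->L = L; c->V = L * L * L;
  c->use_wca = use_wca; c->use_coulomb = use_coulomb;
  c->sigma = sigma; c->eps = eps; c->rcut = std::pow(2.0, 1.0 / 6.0) * sigma;
  c->lB = lB;
  if (offsets.nrow() != NSPECIES || offsets.ncol() != NSPECIES)
    stop("offsets must be a %d x %d matrix", NSPECIES, NSPECIES);
  c->offm.assign(offsets.begin(), offsets.end());
  int N = species.size();
  c->sp.assign(species.begin(), species.end());
  c->q.assign(charge.begin(), charge.end());
  c->px.resize(N); c->py.resize(N); c->pz.resize(N);
  for (int i = 0; i < N; ++i) { c->px[i] = pos(i, 0); c->py[i] = pos(i, 1); c->pz[i] = pos(i, 2); }
  c->n_fixed = n_fixed;
  int nb = 0;
  for (int i = 0; i < N; ++i) nb = std::max(nb, body[i] + 1);
  c->n_bodies = nb;
  c->members.assign(nb, {});
  c->core_of.assign(nb, -1);
  for (int i = 0; i < N; ++i) {
    if (body[i] >= 0) {
      c->members[body[i]].push_back(i);
      if (species[i] == 0) c->core_of[body[i]] = i;
    }
  }
  for (int b = 0; b < nb; ++b)
    if (c->core_of[b] < 0) stop("body %d has no core particle", b);
  c->counts.assign(NSPECIES, 0);
  for (int i = 0; i < N; ++i) c->counts[species[i]]++;
  c->setup_ewald(accuracy);
  c->rebuild_sk();
  Rcpp::XPtr<SimCore> xp(c, true);
  return xp;
}

// [[Rcpp::export]]
double core_refresh(SEXP xp) { return get(xp)->refresh(); }

// [[Rcpp::export]]
List core_total_energy(SEXP xp) {
  SimCore* c = get(xp);
  double uw, ur, uk, us;
  c->total_energy(uw, ur, uk, us);
  return List::create(_["wca"] = uw, _["real"] = ur, _["recip"] = uk,
                      _["self"] = us, _["coulomb"] = ur + uk + us,
                      _["total"] = uw + ur + uk + us);
}

// [[Rcpp::export]]
double core_cached_energy(SEXP xp) {
  SimCore* c = get(xp);
  if (!c->energy_valid) stop("cached energy not initialised; call core_refresh()");
  return c->Utot;
}

// [[Rcpp::export]]
IntegerVector core_counts(SEXP xp) {
  SimCore* c = get(xp);
  return IntegerVector(c->counts.begin(), c->counts.end());
}

// [[Rcpp::export]]
int core_n(SEXP xp) { return get(xp)->n(); }

// [[Rcpp::export]]
NumericMatrix core_positions(SEXP xp) {
  SimCore* c = get(xp);
  NumericMatrix m(c->n(), 3);
  for (int i = 0; i < c->n(); ++i) { m(i, 0) = c->px[i]; m(i, 1) = c->py[i]; m(i, 2) = c->pz[i]; }
  return m;
}

// [[Rcpp::export]]
NumericVector core_charges(SEXP xp) {
  SimCore* c = get(xp);
  return NumericVector(c->q.begin(), c->q.end());
}

// [[Rcpp::export]]
IntegerVector core_species(SEXP xp) {
  SimCore* c = get(xp);
  return IntegerVector(c->sp.begin(), c->sp.end());
}

// [[Rcpp::export]]
double core_total_charge(SEXP xp) {
  SimCore* c = get(xp);
  double s = 0.0;
  for (double qi : c->q) s += qi;
  return s;
}

// [[Rcpp::export]]
NumericVector core_site_charges(SEXP xp) {
  SimCore* c = get(xp);
  std::vector<double> out;
  for (int i = 0; i < c->n_fixed; ++i) if (c->sp[i] == 1) out.push_back(c->q[i]);
  return NumericVector(out.begin(), out.end());
}

// Insert one particle if it creates no hard overlap; updates S(k) and counts.
// Cached total energy becomes stale: call core_refresh() before sampling.
// [[Rcpp::export]]
bool core_try_insert(SEXP xp, int species, double charge, NumericVector pos) {
  SimCore* c = get(xp);
  for (int j = 0; j < c->n(); ++j) {
    double roff = c->offm[species * NSPECIES + c->sp[j]];
    if (!c->use_wca || roff < 0.0) continue;
    double dx = c->minimg(pos[0] - c->px[j]);
    double dy = c->minimg(pos[1] - c->py[j]);
    double dz = c->minimg(pos[2] - c->pz[j]);
    if (std::sqrt(dx * dx + dy * dy + dz * dz) <= roff) return false;
  }
  c->sp.push_back(species); c->q.push_back(charge);
  c->px.push_back(pos[0]); c->py.push_back(pos[1]); c->pz.push_back(pos[2]);
  c->counts[species]++;
  if (c->use_coulomb && charge != 0.0) c->accum_sk(c->Sk, charge, pos[0], pos[1], pos[2]);
  c->energy_valid = false;
  return true;
}

static void fill_proposal(Proposal& p,
                          IntegerVector mv_idx, NumericMatrix mv_pos,
                          IntegerVector qc_idx, NumericVector qc_q,
                          IntegerVector ins_sp, NumericVector ins_q, NumericMatrix ins_pos,
                          IntegerVector del_idx) {
  p.clear();
  for (int m = 0; m < mv_idx.size(); ++m) {
    p.mv_idx.push_back(mv_idx[m]);
    p.mv_x.push_back(mv_pos(m, 0)); p.mv_y.push_back(mv_pos(m, 1)); p.mv_z.push_back(mv_pos(m, 2));
  }
  for (int m = 0; m < qc_idx.size(); ++m) {
    p.qc_idx.push_back(qc_idx[m]); p.qc_q.push_back(qc_q[m]);
  }
  for (int m = 0; m < ins_sp.size(); ++m) {
    p.ins_sp.push_back(ins_sp[m]); p.ins_q.push_back(ins_q[m]);
    p.ins_x.push_back(ins_pos(m, 0)); p.ins_y.push_back(ins_pos(m, 1)); p.ins_z.push_back(ins_pos(m, 2));
  }
  for (int m = 0; m < del_idx.size(); ++m) p.del_idx.push_back(del_idx[m]);
}

// Energy difference of a compound move (0-based indices); no state change.
// [[Rcpp::export]]
double core_delta(SEXP xp, IntegerVector mv_idx, NumericMatrix mv_pos,
                  IntegerVector qc_idx, NumericVector qc_q,
                  IntegerVector ins_sp, NumericVector ins_q, NumericMatrix ins_pos,
                  IntegerVector del_idx) {
  SimCore* c = get(xp);
  fill_proposal(g_prop, mv_idx, mv_pos, qc_idx, qc_q, ins_sp, ins_q, ins_pos, del_idx);
  return c->delta(g_prop, g_dSk);
}

// Apply a compound move unconditionally; returns its energy difference.
// [[Rcpp::export]]
double core_apply(SEXP xp, IntegerVector mv_idx, NumericMatrix mv_pos,
                  IntegerVector qc_idx, NumericVector qc_q,
                  IntegerVector ins_sp, NumericVector ins_q, NumericMatrix ins_pos,
                  IntegerVector del_idx) {
  SimCore* c = get(xp);
  fill_proposal(g_prop, mv_idx, mv_pos, qc_idx, qc_q, ins_sp, ins_q, ins_pos, del_idx);
  double du = c->delta(g_prop, g_dSk);
  if (du == INF) stop("cannot apply a move into a hard overlap");
  c->commit(g_prop, g_dSk, du);
  return du;
}

// ---------------- Monte Carlo kernels ----------------

static bool metropolis(double ln_pref, double du) {
  if (du == INF) return false;
  double lnp = ln_pref - du;
  if (lnp >= 0.0) return true;
  return unif_rand() < std::exp(lnp);
}

// Rotate body b by angle about a uniformly random axis through its core.
static bool do_rotation(SimCore* c, int b, double max_angle) {
  // Marsaglia axis
  double a1, a2, s2;
  do { a1 = 2.0 * unif_rand() - 1.0; a2 = 2.0 * unif_rand() - 1.0; s2 = a1 * a1 + a2 * a2; }
  while (s2 >= 1.0);
  double root = std::sqrt(1.0 - s2);
  double ux = 2.0 * a1 * root, uy = 2.0 * a2 * root, uz = 1.0 - 2.0 * s2;
  double ang = unif_rand() * max_angle;
  double ca = std::cos(ang), sa = std::sin(ang);
  int ic = c->core_of[b];
  double cx = c->px[ic], cy = c->py[ic], cz = c->pz[ic];
  g_prop.clear();
  for (int i : c->members[b]) {
    double vx = c->px[i] - cx, vy = c->py[i] - cy, vz = c->pz[i] - cz;
    // Rodrigues rotation
    double dot = ux * vx + uy * vy + uz * vz;
    double rx = vx * ca + (uy * vz - uz * vy) * sa + ux * dot * (1.0 - ca);
    double ry = vy * ca + (uz * vx - ux * vz) * sa + uy * dot * (1.0 - ca);
    double rz = vz * ca + (ux * vy - uy * vx) * sa + uz * dot * (1.0 - ca);
    g_prop.mv_idx.push_back(i);
    g_prop.mv_x.push_back(cx + rx);
    g_prop.mv_y.push_back(cy + ry);
    g_prop.mv_z.push_back(cz + rz);
  }
  double du = c->delta(g_prop, g_dSk);
  if (metropolis(0.0, du)) { c->commit(g_prop, g_dSk, du); return true; }
  return false;
}

// One configurational trial: pick a unit (body or ion) uniformly; bodies
// attempt translation or rotation with probability 1/2 each.
static bool config_trial(SimCore* c, double disp_step, double rot_step) {
  int n_ions = c->n() - c->n_fixed;
  int n_units = c->n_bodies + n_ions;
  if (n_units == 0) return false;
  int u = c->runif_int(n_units);
  if (u < c->n_bodies && unif_rand() < 0.5) return do_rotation(c, u, rot_step);
  // (re-draw of the unit keeps the proposal symmetric: translation of a
  //  uniformly chosen unit)
  g_prop.clear();
  double dx = (unif_rand() - 0.5) * disp_step;
  double dy = (unif_rand() - 0.5) * disp_step;
  double dz = (unif_rand() - 0.5) * disp_step;
  if (u < c->n_bodies) {
    for (int i : c->members[u]) {
      g_prop.mv_idx.push_back(i);
      g_prop.mv_x.push_back(c->px[i] + dx);
      g_prop.mv_y.push_back(c->py[i] + dy);
      g_prop.mv_z.push_back(c->pz[i] + dz);
    }
  } else {
    int i = c->n_fixed + (u - c->n_bodies);
    g_prop.mv_idx.push_back(i);
    g_prop.mv_x.push_back(c->px[i] + dx);
    g_prop.mv_y.push_back(c->py[i] + dy);
    g_prop.mv_z.push_back(c->pz[i] + dz);
  }
  double du = c->delta(g_prop, g_dSk);
  if (metropolis(0.0, du)) { c->commit(g_prop, g_dSk, du); return true; }
  return false;
}

// Reaction / exchange move types:
//   1 acid HA -> A- + H+          (K = K_A)
//   2 acid HA -> A- + Na+         (K = K_A K_NaCl / K_HCl)
//   3 acid HA + OH- -> A-         (K = K_A / K_w)
//   4 pair 0 -> Na+ + Cl-
//   5 pair 0 -> H+  + Cl-
//   6 pair 0 -> Na+ + OH-
//   7 pair 0 -> H+  + OH-
// xi = +1 forward, -1 reverse. lnVNAc0 = ln(V * N_A * c0), the number of
// particles in the box at the reference concentration.
static const int SP_NA = 2, SP_CL = 3, SP_H = 4, SP_OH = 5;

static bool reaction_trial(SimCore* c, int type, int xi, double lnK, double lnVNAc0) {
  g_prop.clear();
  double ln_pref = xi * lnK;
  if (type <= 3) {
    int ion = (type == 1) ? SP_H : (type == 2) ? SP_NA : SP_OH;
    int nHA = c->count_sites(1), nA = c->count_sites(0);
    int nIon = c->counts[ion];
    if (xi > 0) {
      if (nHA == 0) return false;
      int s = c->random_site(1);
      g_prop.qc_idx.push_back(s); g_prop.qc_q.push_back(-1.0);
      if (type == 3) {                     // HA + OH- -> A-
        if (nIon == 0) return false;
        g_prop.del_idx.push_back(c->random_ion(SP_OH));
        ln_pref += std::log((double)nHA) + std::log((double)nIon)
                 - std::log((double)nA + 1.0) - lnVNAc0;
      } else {                             // HA -> A- + ion
        g_prop.ins_sp.push_back(ion);
        g_prop.ins_q.push_back(1.0);
        g_prop.ins_x.push_back(unif_rand() * c->L);
        g_prop.ins_y.push_back(unif_rand() * c->L);
        g_prop.ins_z.push_back(unif_rand() * c->L);
        ln_pref += std::log((double)nHA)
                 - std::log((double)nA + 1.0) - std::log((double)nIon + 1.0) + lnVNAc0;
      }
    } else {
      if (nA == 0) return false;
      int s = c->random_site(0);
      g_prop.qc_idx.push_back(s); g_prop.qc_q.push_back(0.0);
      if (type == 3) {                     // A- -> HA + OH-
        g_prop.ins_sp.push_back(SP_OH);
        g_prop.ins_q.push_back(-1.0);
        g_prop.ins_x.push_back(unif_rand() * c->L);
        g_prop.ins_y.push_back(unif_rand() * c->L);
        g_prop.ins_z.push_back(unif_rand() * c->L);
        ln_pref += std::log((double)nA)
                 - std::log((double)nHA + 1.0) - std::log((double)nIon + 1.0) + lnVNAc0;
      } else {                             // A- + ion -> HA
        if (nIon == 0) return false;
        g_prop.del_idx.push_back(c->random_ion(ion));
        ln_pref += std::log((double)nA) + std::log((double)nIon)
                 - std::log((double)nHA + 1.0) - lnVNAc0;
      }
    }
  } else {
    int si = (type == 4 || type == 6) ? SP_NA : SP_H;
    int sj = (type == 4 || type == 5) ? SP_CL : SP_OH;
    int Ni = c->counts[si], Nj = c->counts[sj];
    if (xi > 0) {
      int spec[2] = {si, sj};
      double qq[2] = {1.0, -1.0};
      for (int m = 0; m < 2; ++m) {
        g_prop.ins_sp.push_back(spec[m]);
        g_prop.ins_q.push_back(qq[m]);
        g_prop.ins_x.push_back(unif_rand() * c->L);
        g_prop.ins_y.push_back(unif_rand() * c->L);
        g_prop.ins_z.push_back(unif_rand() * c->L);
      }
      ln_pref += -std::log((double)Ni + 1.0) - std::log((double)Nj + 1.0) + 2.0 * lnVNAc0;
    } else {
      if (Ni == 0 || Nj == 0) return false;
      g_prop.del_idx.push_back(c->random_ion(si));
      g_prop.del_idx.push_back(c->random_ion(sj));
      ln_pref += std::log((double)Ni) + std::log((double)Nj) - 2.0 * lnVNAc0;
    }
  }
  double du = c->delta(g_prop, g_dSk);
  if (metropolis(ln_pref, du)) { c->commit(g_prop, g_dSk, du); return true; }
  return false;
}

// [[Rcpp::export]]
bool core_attempt_displacement(SEXP xp, double step) {
  return config_trial(get(xp), step, 0.0);
}

// [[Rcpp::export]]
bool core_attempt_rotation(SEXP xp, int body, double max_angle) {
  SimCore* c = get(xp);
  if (body < 0 || body >= c->n_bodies) stop("invalid body index");
  return do_rotation(c, body, max_angle);
}

// [[Rcpp::export]]
bool core_attempt_reaction(SEXP xp, int type, int xi, double lnK, double lnVNAc0) {
  return reaction_trial(get(xp), type, xi, lnK, lnVNAc0);
}

// Run a block of MC cycles. Each cycle: n_config configurational trials,
// then n_rxn reaction/exchange trials choosing uniformly among the enabled
// types with direction +/-1 equiprobable. Samples species counts, alpha and
// cached energy every sample_every cycles.
// [[Rcpp::export]]
List core_run_cycles(SEXP xp, int n_cycles, int n_config, double disp_step,
                     double rot_step, int n_rxn, IntegerVector rxn_types,
                     NumericVector rxn_lnK, double lnVNAc0, int sample_every,
                     int refresh_every) {
  SimCore* c = get(xp);
  if (!c->energy_valid) c->refresh();
  if (c->Utot == INF) stop("initial configuration contains hard overlaps");
  int n_types = rxn_types.size();
  int n_samp = (sample_every > 0) ? n_cycles / sample_every : 0;
  NumericMatrix samples(n_samp, 8);
  colnames(samples) = CharacterVector::create("cycle", "n_HA", "n_A", "N_Na",
                                              "N_Cl", "N_H", "N_OH", "U");
  long acc_conf = 0, att_conf = 0, acc_rxn = 0, att_rxn = 0;
  int isamp = 0;
  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    for (int m = 0; m < n_config; ++m) {
      att_conf++;
      if (config_trial(c, disp_step, rot_step)) acc_conf++;
    }
    for (int m = 0; m < n_rxn; ++m) {
      if (n_types == 0) break;
      int t = c->runif_int(n_types);
      int xi = (unif_rand() < 0.5) ? 1 : -1;
      att_rxn++;
      if (reaction_trial(c, rxn_types[t], xi, rxn_lnK[t], lnVNAc0)) acc_rxn++;
    }
    if (refresh_every > 0 && cyc % refresh_every == 0) c->refresh();
    if (sample_every > 0 && cyc % sample_every == 0 && isamp < n_samp) {
      samples(isamp, 0) = cyc;
      samples(isamp, 1) = c->count_sites(1);
      samples(isamp, 2) = c->count_sites(0);
      samples(isamp, 3) = c->counts[SP_NA];
      samples(isamp, 4) = c->counts[SP_CL];
      samples(isamp, 5) = c->counts[SP_H];
      samples(isamp, 6) = c->counts[SP_OH];
      samples(isamp, 7) = c->Utot;
      isamp++;
    }
  }
  return List::create(_["samples"] = samples,
                      _["acc_config"] = (double)acc_conf, _["att_config"] = (double)att_conf,
                      _["acc_rxn"] = (double)acc_rxn, _["att_rxn"] = (double)att_rxn);
}

// Widom test-particle insertion: n_trials random insertions of one particle
// of the given species/charge; returns the Boltzmann factors exp(-U_ins).
// [[Rcpp::export]]
NumericVector core_widom(SEXP xp, int species, double charge, int n_trials) {
  SimCore* c = get(xp);
  NumericVector out(n_trials);
  for (int t = 0; t < n_trials; ++t) {
    double x = unif_rand() * c->L, y = unif_rand() * c->L, z = unif_rand() * c->L;
    double u = 0.0;
    for (int j = 0; j < c->n(); ++j) {
      double uj = c->pair_energy(species, charge, x, y, z,
                                 c->sp[j], c->q[j], c->px[j], c->py[j], c->pz[j]);
      if (uj == INF) { u = INF; break; }
      u += uj;
    }
    out[t] = (u == INF) ? 0.0 : std::exp(-u);
  }
  return out;
}

// Ewald diagnostics (for tests): splitting parameter, real-space cutoff,
// k-space radius and number of wave vectors.
// [[Rcpp::export]]
List core_ewald_params(SEXP xp) {
  SimCore* c = get(xp);
  return List::create(_["alpha"] = c->alpha, _["r_ewald"] = c->r_ewald,
                      _["kmax"] = c->kmax, _["n_kvec"] = (int)c->Ak.size());
}
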