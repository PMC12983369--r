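// Dynamic Monte Carlo engine: event-by-event electron transport in liquid
// water with femtosecond propagation of every secondary electron in the
// time-dependent, dielectrically screened Coulomb field of its parent
// cation.
//
// Units throughout: eV, nm, fs, K.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double ME = 510998.95 / (299.792458 * 299.792458); // eV fs^2/nm^2
static const double KB = 8.617333e-5;                           // eV/K

// ---------------------------------------------------------------- RNG
// splitmix64: deterministic, counter-derivable streams so that every
// (seed, history, electron) triple owns an independent substream and
// histories are order-independent.
struct Rng {
  uint64_t s;
  bool has_norm;
  double norm_cache;
  explicit Rng(uint64_t seed) : s(seed), has_norm(false), norm_cache(0) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo() { return -std::log(unif()); }
  double norm() {
    if (has_norm) { has_norm = false; return norm_cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    norm_cache = r * std::sin(2.0 * M_PI * u2);
    has_norm = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

static uint64_t mix64(uint64_t a, uint64_t b) {
  Rng r(a * 0x9E3779B97F4A7C15ULL + b);
  return r.next();
}

// ---------------------------------------------------------------- tables
enum Kind { ELASTIC = 0, IONISATION = 1, EXC_DISCRETE = 2,
            EXC_COLLECTIVE = 3, VIBRATIONAL = 4, PHONON = 5,
            ATTACHMENT = 6 };

struct Xs {
  std::vector<double> E, logE;
  std::vector<std::vector<double> > sig; // [channel][node]
  std::vector<int> kind;
  std::vector<double> thr, transfer, lor_a;
  double dens;
  int nch, nE;
  bool dea_enabled;

  void init(const List &xs, bool dea) {
    NumericVector Ev = xs["E"], logEv = xs["logE"];
    NumericMatrix S = xs["sig"];
    IntegerVector k = xs["kind"];
    NumericVector t = xs["thr"], tr = xs["transfer"], la = xs["lor_a"];
    dens = as<double>(xs["dens"]);
    nE = Ev.size(); nch = S.ncol();
    E.assign(Ev.begin(), Ev.end());
    logE.assign(logEv.begin(), logEv.end());
    sig.resize(nch);
    for (int j = 0; j < nch; ++j) {
      sig[j].resize(nE);
      for (int i = 0; i < nE; ++i) sig[j][i] = S(i, j);
    }
    kind.assign(k.begin(), k.end());
    thr.assign(t.begin(), t.end());
    transfer.assign(tr.begin(), tr.end());
    lor_a.assign(la.begin(), la.end());
    dea_enabled = dea;
  }

  // minimum projectile energy for the channel to be open. Phonon
  // scattering is quasi-elastic and stays open at sub-quantum energies
  // (the bath exchanges energy in both directions there).
  double need(int j) const {
    if (kind[j] == IONISATION) return thr[j];
    if (kind[j] == ELASTIC || kind[j] == PHONON) return 0.0;
    return transfer[j];
  }

  double sigma1(int j, double Eq) const {
    if (Eq < E[0]) Eq = E[0]; // clamp at thermal end; sigma flat there
    if (Eq < thr[j]) return 0.0;
    // binary search for bracketing interval
    int lo = 0, hi = nE - 1;
    if (Eq >= E[hi]) return sig[j][hi];
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (E[mid] <= Eq) lo = mid; else hi = mid;
    }
    double s1 = sig[j][lo], s2 = sig[j][hi];
    if (E[lo] == Eq) return s1;
    if (s1 > 0.0 && s2 > 0.0) {
      double f = (std::log(Eq) - logE[lo]) / (logE[hi] - logE[lo]);
      return std::exp(std::log(s1) + f * (std::log(s2) - std::log(s1)));
    }
    return s1 + (Eq - E[lo]) / (E[hi] - E[lo]) * (s2 - s1);
  }

  // effective per-channel cross section: closed channels weigh zero
  double sigma_eff(int j, double Eq) const {
    if (kind[j] == ATTACHMENT && !dea_enabled) return 0.0;
    if (Eq <= need(j)) return (kind[j] == ELASTIC) ? sigma1(j, Eq) : 0.0;
    return sigma1(j, Eq);
  }

  double lambda(double Eq, std::vector<double> *per = 0) const {
    double tot = 0.0;
    for (int j = 0; j < nch; ++j) {
      double s = sigma_eff(j, Eq);
      if (per) (*per)[j] = s;
      tot += s;
    }
    return dens * tot;
  }
};

struct Diel {
  double eps_e, kcoul;
  std::vector<double> amp, tau;
  void init(const List &d) {
    eps_e = as<double>(d["eps_e"]);
    kcoul = as<double>(d["kcoul"]);
    NumericVector a = d["amp"], t = d["tau"];
    amp.assign(a.begin(), a.end());
    tau.assign(t.begin(), t.end());
  }
  double eps(double t) const {
    double e = eps_e;
    for (size_t k = 0; k < amp.size(); ++k)
      e += amp[k] * (1.0 - std::exp(-t / tau[k]));
    return e;
  }
};

struct Cfg {
  double t_horizon, t_cut, temp, dt_max, disp_cap, disp_cap_far, far_dist,
      r_soft, r_birth, r_birth_tail, lambda_th, eta0, cutoff;
  int therm_dwell;
  double therm_enter, therm_band; // multiples of kB T
  std::vector<double> snap;
  bool dea_enabled, coulomb_on;
  void init(const List &c) {
    t_horizon = as<double>(c["t_horizon"]);
    t_cut = as<double>(c["t_cut_secondary"]);
    temp = as<double>(c["temperature"]);
    dt_max = as<double>(c["dt_max"]);
    disp_cap = as<double>(c["disp_cap"]);
    disp_cap_far = as<double>(c["disp_cap_far"]);
    far_dist = as<double>(c["far_dist"]);
    r_soft = as<double>(c["r_soft"]);
    r_birth = as<double>(c["r_birth"]);
    r_birth_tail = as<double>(c["r_birth_tail"]);
    lambda_th = as<double>(c["lambda_th"]);
    eta0 = as<double>(c["eta0"]);
    cutoff = as<double>(c["tracking_cutoff"]);
    therm_dwell = as<int>(c["therm_dwell"]);
    therm_enter = as<double>(c["therm_enter"]);
    therm_band = as<double>(c["therm_band"]);
    NumericVector s = c["snapshot_times"];
    snap.assign(s.begin(), s.end());
    dea_enabled = as<bool>(c["dea_enabled"]);
    coulomb_on = as<bool>(c["coulomb_on"]);
  }
};

// ---------------------------------------------------------------- state
struct Electron {
  double x[3], v[3];
  double parent[3];
  bool has_parent;
  double birth[3];
  double birth_t0; // global clock at creation
  double birth_KE;
  double t_i;      // local clock
  double KE;
  int origin;      // 0 primary remnant, 1 ionisation channel, 2 excitation
  int status;      // 0 halted (cutoff/horizon), 1 thermalised
  int therm_count;
  double freeze_at; // local time at which a dwell-qualified electron stops
  bool remnant;
  int idx;
  size_t snap_ptr;
};

struct EventRec {
  double t0, x, y, z, transfer;
  int channel, kind, spawned;
};

struct SnapRec {
  int idx; double t, KE, dist;
};

struct Book {
  double deposits, bath_net, field_work, residual;
  Book() : deposits(0), bath_net(0), field_work(0), residual(0) {}
};

struct Engine {
  Xs xs; Diel diel; Cfg cfg;
  uint64_t stream_base;
  std::vector<Electron> done;
  std::vector<Electron> queue;
  std::vector<EventRec> events;
  std::vector<SnapRec> snaps;
  std::vector<double> prim_path; // t0,x,y,z,KE rows
  Book book;
  int next_idx;
  bool record_primary;

  Engine() : next_idx(1), record_primary(false) {}

  double ke_of(const double v[3]) const {
    return 0.5 * ME * (v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  }

  static void iso_dir(Rng &rng, double d[3]) {
    double mu = 2.0 * rng.unif() - 1.0, ph = 2.0 * M_PI * rng.unif();
    double s = std::sqrt(1.0 - mu * mu);
    d[0] = s * std::cos(ph); d[1] = s * std::sin(ph); d[2] = mu;
  }

  // rotate direction u by polar angle with cos = mu, uniform azimuth
  static void rotate_dir(Rng &rng, double u[3], double mu) {
    double ph = 2.0 * M_PI * rng.unif();
    double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
    double w[3];
    // build orthonormal basis (a, b, u)
    double a[3], b[3];
    if (std::fabs(u[2]) < 0.99) { a[0] = -u[1]; a[1] = u[0]; a[2] = 0.0; }
    else { a[0] = 0.0; a[1] = -u[2]; a[2] = u[1]; }
    double na = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
    for (int k = 0; k < 3; ++k) a[k] /= na;
    b[0] = u[1] * a[2] - u[2] * a[1];
    b[1] = u[2] * a[0] - u[0] * a[2];
    b[2] = u[0] * a[1] - u[1] * a[0];
    for (int k = 0; k < 3; ++k)
      w[k] = mu * u[k] + s * (std::cos(ph) * a[k] + std::sin(ph) * b[k]);
    double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
    for (int k = 0; k < 3; ++k) u[k] = w[k] / nw;
  }

  // Once the dwell criterion is met the electron is deemed hydrating and
  // stops at an exponentially sampled settling time (about one mean flight
  // later). Sampling the stopping epoch in time rather than at a collision
  // records the time-weighted kinetic energy, i.e. the stationary
  // (Maxwellian) distribution rather than a collision-rate-biased one.
  void maybe_arm_freeze(Electron &e, Rng &rng) {
    if (e.freeze_at >= 0.0 || e.therm_count < cfg.therm_dwell) return;
    double sp = std::sqrt(2.0 * std::max(e.KE, 1e-12) / ME);
    double lam = xs.lambda(e.KE, 0);
    double mean_flight = (lam * sp > 0) ? 1.0 / (lam * sp) : 0.0;
    e.freeze_at = e.t_i + rng.expo() * mean_flight;
  }

  double elastic_mu(Rng &rng, double E) const {
    // screened-Rutherford; eta -> infinity gives isotropy at low energy
    double eta = cfg.eta0 / std::max(E, 1e-9);
    if (eta > 1e6) eta = 1e6;
    double u = rng.unif();
    return 1.0 - 2.0 * eta * u / (1.0 + eta - u);
  }

  void set_speed(Electron &e, double KE, const double dir[3]) {
    double sp = std::sqrt(2.0 * std::max(KE, 0.0) / ME);
    for (int k = 0; k < 3; ++k) e.v[k] = sp * dir[k];
    e.KE = std::max(KE, 0.0);
  }

  void spawn(const Electron &src, int origin, double KE, Rng &rng,
             bool at_parent) {
    Electron s;
    double d[3]; iso_dir(rng, d);
    // The freed electron enters classical transport displaced radially from
    // the event position: the channel threshold (binding/transition energy)
    // already paid for escaping the molecular region, so the macroscopic
    // screened parent field acts only beyond the molecular cavity scale.
    // The entry radius is distributed (exponential tail) to reflect the
    // spatial extent of the vacated/excited orbitals, which ranges from the
    // cavity radius to diffuse Rydberg-like states around a nanometre.
    double rb = cfg.r_birth + cfg.r_birth_tail * rng.expo();
    for (int k = 0; k < 3; ++k) {
      s.parent[k] = src.x[k];
      s.x[k] = src.x[k] + rb * d[k];
      s.birth[k] = s.x[k];
    }
    (void)at_parent;
    s.has_parent = true;
    s.birth_t0 = src.birth_t0 + src.t_i;
    s.birth_KE = KE;
    s.t_i = 0.0;
    s.origin = origin;
    s.status = 0;
    s.therm_count = 0;
    s.freeze_at = -1.0;
    s.remnant = false;
    s.idx = next_idx++;
    set_speed(s, KE, d);
    queue.push_back(s);
  }

  // returns index of spawned electron or -1
  int handle_collision(Electron &e, Rng &rng) {
    double E = e.KE;
    std::vector<double> per(xs.nch);
    double lam = xs.lambda(E, &per);
    if (lam <= 0.0) return -2; // nothing can happen
    double u = rng.unif() * (lam / xs.dens), acc = 0.0;
    int j = xs.nch - 1;
    for (int c = 0; c < xs.nch; ++c) {
      acc += per[c];
      if (u <= acc) { j = c; break; }
    }
    int kind = xs.kind[j];
    bool thermal = E < cfg.therm_enter * KB * cfg.temp;
    int spawned = -1;

    if (kind == ELASTIC) {
      if (thermal) {
        // below the thermal-coupling energy the collision partner's thermal
        // motion matters: partial velocity thermalisation against the bath,
        // a Langevin-type kick satisfying detailed balance whose stationary
        // velocity distribution is Maxwellian(temp)
        double KE0 = e.KE;
        double sd = std::sqrt(KB * cfg.temp / ME);
        double keep = std::sqrt(1.0 - cfg.lambda_th);
        double kick = std::sqrt(cfg.lambda_th);
        for (int k = 0; k < 3; ++k)
          e.v[k] = keep * e.v[k] + kick * sd * rng.norm();
        e.KE = ke_of(e.v);
        book.bath_net += KE0 - e.KE;
      } else {
        double mu = elastic_mu(rng, E);
        double sp = std::sqrt(e.v[0] * e.v[0] + e.v[1] * e.v[1] +
                              e.v[2] * e.v[2]);
        double dir[3] = { e.v[0] / sp, e.v[1] / sp, e.v[2] / sp };
        rotate_dir(rng, dir, mu);
        for (int k = 0; k < 3; ++k) e.v[k] = sp * dir[k];
      }
    } else if (kind == PHONON && thermal) {
      // quasi-elastic momentum relaxation: quantum exchange with the bath
      // is balanced on average, the direction is randomised
      double sp = std::sqrt(e.v[0] * e.v[0] + e.v[1] * e.v[1] +
                            e.v[2] * e.v[2]);
      double dir[3]; iso_dir(rng, dir);
      for (int k = 0; k < 3; ++k) e.v[k] = sp * dir[k];
    } else if (kind == PHONON || kind == VIBRATIONAL) {
      double q = xs.transfer[j];
      double KE1 = std::max(0.0, e.KE - q);
      book.deposits += e.KE - KE1;
      double dir[3]; iso_dir(rng, dir);
      set_speed(e, KE1, dir);
    } else if (kind == IONISATION) {
      double B = xs.thr[j];
      double wmax = (E - B) / 2.0, a = xs.lor_a[j];
      double W = a * std::tan(rng.unif() * std::atan(wmax / a));
      book.deposits += B;
      spawned = next_idx;
      spawn(e, 1, W, rng, true);
      double sp = std::sqrt(e.v[0] * e.v[0] + e.v[1] * e.v[1] +
                            e.v[2] * e.v[2]);
      double dir[3] = { e.v[0] / sp, e.v[1] / sp, e.v[2] / sp };
      set_speed(e, E - B - W, dir);
      events.push_back(EventRec{e.birth_t0 + e.t_i, e.x[0], e.x[1], e.x[2],
                                B + W, j, kind, spawned});
    } else if (kind == EXC_DISCRETE || kind == EXC_COLLECTIVE) {
      double tr = xs.transfer[j], thr = xs.thr[j];
      book.deposits += thr;
      spawned = next_idx;
      spawn(e, 2, std::max(0.0, tr - thr), rng, true);
      double sp = std::sqrt(e.v[0] * e.v[0] + e.v[1] * e.v[1] +
                            e.v[2] * e.v[2]);
      double dir[3] = { e.v[0] / sp, e.v[1] / sp, e.v[2] / sp };
      set_speed(e, E - tr, dir);
      events.push_back(EventRec{e.birth_t0 + e.t_i, e.x[0], e.x[1], e.x[2],
                                tr, j, kind, spawned});
    } else if (kind == ATTACHMENT) {
      book.deposits += e.KE;
      double dir[3] = {0, 0, 1};
      set_speed(e, 0.0, dir);
      events.push_back(EventRec{e.birth_t0 + e.t_i, e.x[0], e.x[1], e.x[2],
                                E, j, kind, -1});
      e.status = 1; // absorbed; treat as stopped
    }

    // thermalisation dwell bookkeeping
    if (e.KE <= cfg.therm_band * KB * cfg.temp) e.therm_count++;
    else e.therm_count = 0;
    return spawned;
  }

  void record_snaps_upto(Electron &e, double tglob) {
    while (e.snap_ptr < cfg.snap.size() && cfg.snap[e.snap_ptr] <= tglob) {
      double dist = -1.0;
      if (e.has_parent) {
        double dx = e.x[0] - e.parent[0], dy = e.x[1] - e.parent[1],
               dz = e.x[2] - e.parent[2];
        dist = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      snaps.push_back(SnapRec{e.idx, cfg.snap[e.snap_ptr], e.KE, dist});
      e.snap_ptr++;
    }
  }

  void finalize_snaps(Electron &e) { record_snaps_upto(e, 1e300); }

  void accel(const Electron &e, double t, double a[3]) const {
    if (!e.has_parent || !cfg.coulomb_on) { a[0] = a[1] = a[2] = 0; return; }
    double d[3] = { e.x[0] - e.parent[0], e.x[1] - e.parent[1],
                    e.x[2] - e.parent[2] };
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    double s2 = r2 + cfg.r_soft * cfg.r_soft;
    double f = -diel.kcoul / (diel.eps(t) * s2 * std::sqrt(s2)) / ME;
    a[0] = f * d[0]; a[1] = f * d[1]; a[2] = f * d[2];
  }

  // ---------------------------------------------------- propagation
  void propagate(Electron &e, Rng &rng, bool allow_spawn_processing) {
    (void)allow_spawn_processing;
    // snapshots before this electron existed are not recorded
    while (e.snap_ptr < cfg.snap.size() && cfg.snap[e.snap_ptr] < e.birth_t0)
      e.snap_ptr++;
    double t_stop = std::min(cfg.t_cut, cfg.t_horizon - e.birth_t0);
    if (t_stop <= 0) { finalize_snaps(e); done.push_back(e); return; }

    // electrons born essentially at rest inside the deep early-time well
    // thermalise in place; integrating their sub-angstrom jitter resolves
    // nothing at the classification scale
    if (e.birth_KE < 1e-9 && e.has_parent) {
      e.status = 1;
      e.t_i = 0.0;
      finalize_snaps(e);
      done.push_back(e);
      return;
    }

    double tau_target = rng.expo(), tau_acc = 0.0;

    if (!e.has_parent || !cfg.coulomb_on) {
      // force-free: analytic exponential free flights
      while (true) {
        record_snaps_upto(e, e.birth_t0 + e.t_i);
        if (e.status == 1 || e.t_i >= t_stop) break;
        maybe_arm_freeze(e, rng);
        if (e.freeze_at >= 0.0 && e.t_i >= e.freeze_at) {
          e.status = 1; break;
        }
        double t_end = t_stop;
        if (e.freeze_at >= 0.0 && e.freeze_at < t_end) t_end = e.freeze_at;
        double lam = xs.lambda(e.KE, 0);
        double sp = std::sqrt(2.0 * e.KE / ME);
        if (lam <= 0.0 || sp <= 0.0) {
          // ballistic to stop time
          double dt = t_end - e.t_i;
          for (int k = 0; k < 3; ++k) e.x[k] += e.v[k] * dt;
          e.t_i = t_end;
          continue;
        }
        double ell = rng.expo() / lam;
        double dt = ell / sp;
        if (e.t_i + dt >= t_end) {
          double dtc = t_end - e.t_i;
          for (int k = 0; k < 3; ++k) e.x[k] += e.v[k] * dtc;
          e.t_i = t_end;
          continue;
        }
        // snapshot crossings inside the flight
        while (e.snap_ptr < cfg.snap.size() &&
               cfg.snap[e.snap_ptr] <= e.birth_t0 + e.t_i + dt) {
          double tc = cfg.snap[e.snap_ptr] - e.birth_t0 - e.t_i;
          double dist = -1.0;
          if (e.has_parent) {
            double px = e.x[0] + e.v[0] * tc - e.parent[0];
            double py = e.x[1] + e.v[1] * tc - e.parent[1];
            double pz = e.x[2] + e.v[2] * tc - e.parent[2];
            dist = std::sqrt(px * px + py * py + pz * pz);
          }
          snaps.push_back(SnapRec{e.idx, cfg.snap[e.snap_ptr], e.KE, dist});
          e.snap_ptr++;
        }
        for (int k = 0; k < 3; ++k) e.x[k] += e.v[k] * dt;
        e.t_i += dt;
        handle_collision(e, rng);
        if (record_primary && e.idx == 0) {
          prim_path.push_back(e.birth_t0 + e.t_i);
          prim_path.push_back(e.x[0]); prim_path.push_back(e.x[1]);
          prim_path.push_back(e.x[2]); prim_path.push_back(e.KE);
        }
      }
    } else {
      // velocity-Verlet integration in the screened parent field with
      // optical-depth collision sampling along the numerical trajectory
      double a0[3];
      accel(e, e.t_i, a0);
      while (true) {
        record_snaps_upto(e, e.birth_t0 + e.t_i);
        if (e.status == 1 || e.t_i >= t_stop - 1e-12) break;
        maybe_arm_freeze(e, rng);
        if (e.freeze_at >= 0.0 && e.t_i >= e.freeze_at - 1e-12) {
          e.status = 1; break;
        }

        double d[3] = { e.x[0] - e.parent[0], e.x[1] - e.parent[1],
                        e.x[2] - e.parent[2] };
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        double s2 = r2 + cfg.r_soft * cfg.r_soft;
        double dist = std::sqrt(r2);
        double sp = std::sqrt(e.v[0] * e.v[0] + e.v[1] * e.v[1] +
                              e.v[2] * e.v[2]);
        double eps = diel.eps(e.t_i);
        double om = std::sqrt(diel.kcoul / (eps * ME * s2 * std::sqrt(s2)));
        double dt = cfg.dt_max;
        if (0.2 / om < dt) dt = 0.2 / om;
        double cap = (dist < cfg.far_dist) ? cfg.disp_cap : cfg.disp_cap_far;
        if (sp > 0 && cap / sp < dt) dt = cap / sp;
        if (e.t_i + dt > t_stop) dt = t_stop - e.t_i;
        if (e.freeze_at >= 0.0 && e.t_i + dt > e.freeze_at)
          dt = e.freeze_at - e.t_i;
        if (dt < 1e-7) dt = 1e-7;

        double x0[3] = { e.x[0], e.x[1], e.x[2] };
        double v0[3] = { e.v[0], e.v[1], e.v[2] };
        double KE0 = e.KE;
        // verlet step
        for (int k = 0; k < 3; ++k)
          e.x[k] += e.v[k] * dt + 0.5 * a0[k] * dt * dt;
        double a1[3];
        accel(e, e.t_i + dt, a1);
        for (int k = 0; k < 3; ++k)
          e.v[k] += 0.5 * (a0[k] + a1[k]) * dt;
        e.KE = ke_of(e.v);

        double seg = 0.0;
        for (int k = 0; k < 3; ++k) {
          double dd = e.x[k] - x0[k];
          seg += dd * dd;
        }
        seg = std::sqrt(seg);
        double lam = xs.lambda(KE0, 0);
        double dtau = lam * seg;
        if (tau_acc + dtau >= tau_target && dtau > 0.0) {
          double f = (tau_target - tau_acc) / dtau;
          for (int k = 0; k < 3; ++k) {
            e.x[k] = x0[k] + f * (e.x[k] - x0[k]);
            e.v[k] = v0[k] + f * (e.v[k] - v0[k]);
          }
          e.t_i += f * dt;
          double KEc = ke_of(e.v);
          book.field_work += KEc - KE0;
          e.KE = KEc;
          handle_collision(e, rng);
          tau_acc = 0.0;
          tau_target = rng.expo();
          accel(e, e.t_i, a0);
        } else {
          tau_acc += dtau;
          e.t_i += dt;
          book.field_work += e.KE - KE0;
          for (int k = 0; k < 3; ++k) a0[k] = a1[k];
        }
      }
    }
    finalize_snaps(e);
    done.push_back(e);
  }

  // primary electron: force-free analytic transport along +z with all
  // channels open, retired below the tracking cutoff
  Electron run_primary(double E0, Rng &rng) {
    Electron p;
    for (int k = 0; k < 3; ++k) { p.x[k] = 0; p.parent[k] = 0; p.birth[k] = 0; }
    p.has_parent = false;
    p.birth_t0 = 0; p.birth_KE = E0; p.t_i = 0;
    p.origin = 0; p.status = 0; p.therm_count = 0; p.freeze_at = -1.0;
    p.remnant = false; p.idx = 0; p.snap_ptr = 0;
    double dir[3] = {0, 0, 1};
    set_speed(p, E0, dir);
    prim_path.push_back(0); prim_path.push_back(0); prim_path.push_back(0);
    prim_path.push_back(0); prim_path.push_back(E0);
    record_primary = true;

    double last_event[3] = {0, 0, 0};
    bool any_event = false;
    while (p.KE > cfg.cutoff && p.birth_t0 + p.t_i < cfg.t_horizon) {
      double lam = xs.lambda(p.KE, 0);
      double sp = std::sqrt(2.0 * p.KE / ME);
      if (lam <= 0) break;
      double ell = rng.expo() / lam;
      double dt = ell / sp;
      if (p.t_i + dt >= cfg.t_horizon) {
        double dtc = cfg.t_horizon - p.t_i;
        for (int k = 0; k < 3; ++k) p.x[k] += p.v[k] * dtc;
        p.t_i = cfg.t_horizon;
        break;
      }
      for (int k = 0; k < 3; ++k) p.x[k] += p.v[k] * dt;
      p.t_i += dt;
      int sp_idx = handle_collision(p, rng);
      if (sp_idx >= 0) {
        for (int k = 0; k < 3; ++k) last_event[k] = p.x[k];
        any_event = true;
      }
      prim_path.push_back(p.t_i);
      prim_path.push_back(p.x[0]); prim_path.push_back(p.x[1]);
      prim_path.push_back(p.x[2]); prim_path.push_back(p.KE);
    }
    record_primary = false;
    // remnant: hand the sub-cutoff primary to the secondary propagator,
    // anchored at the cation it most recently created (if any)
    Electron rem = p;
    rem.remnant = true;
    rem.therm_count = 0;
    rem.freeze_at = -1.0;
    rem.birth_t0 = p.t_i;
    rem.t_i = 0;
    rem.birth_KE = p.KE;
    rem.snap_ptr = 0;
    for (int k = 0; k < 3; ++k) rem.birth[k] = p.x[k];
    if (any_event) {
      rem.has_parent = true;
      for (int k = 0; k < 3; ++k) rem.parent[k] = last_event[k];
    } else {
      rem.has_parent = false;
    }
    return rem;
  }
};

static List electrons_df(const std::vector<Electron> &es) {
  int n = es.size();
  IntegerVector idx(n), origin(n), status(n), remnant(n), has_parent(n);
  NumericVector px(n), py(n), pz(n), bt(n), bke(n), fx(n), fy(n), fz(n),
      fke(n), ti(n), dist(n), bdist(n);
  for (int i = 0; i < n; ++i) {
    const Electron &e = es[i];
    idx[i] = e.idx; origin[i] = e.origin; status[i] = e.status;
    remnant[i] = e.remnant ? 1 : 0; has_parent[i] = e.has_parent ? 1 : 0;
    px[i] = e.parent[0]; py[i] = e.parent[1]; pz[i] = e.parent[2];
    bt[i] = e.birth_t0; bke[i] = e.birth_KE;
    fx[i] = e.x[0]; fy[i] = e.x[1]; fz[i] = e.x[2];
    fke[i] = e.KE; ti[i] = e.t_i;
    if (e.has_parent) {
      double dx = e.x[0] - e.parent[0], dy = e.x[1] - e.parent[1],
             dz = e.x[2] - e.parent[2];
      dist[i] = std::sqrt(dx * dx + dy * dy + dz * dz);
    } else dist[i] = NA_REAL;
    double bx = e.x[0] - e.birth[0], by = e.x[1] - e.birth[1],
           bz = e.x[2] - e.birth[2];
    bdist[i] = std::sqrt(bx * bx + by * by + bz * bz);
  }
  return DataFrame::create(
      _["index"] = idx, _["origin"] = origin, _["status"] = status,
      _["remnant"] = remnant, _["has_parent"] = has_parent,
      _["parent_x"] = px, _["parent_y"] = py, _["parent_z"] = pz,
      _["birth_t0"] = bt, _["birth_KE"] = bke,
      _["x"] = fx, _["y"] = fy, _["z"] = fz, _["KE"] = fke,
      _["t_local"] = ti, _["dist_parent"] = dist, _["dist_birth"] = bdist);
}

static List events_df(const std::vector<EventRec> &ev) {
  int n = ev.size();
  NumericVector t0(n), x(n), y(n), z(n), tr(n);
  IntegerVector ch(n), kind(n), spawned(n);
  for (int i = 0; i < n; ++i) {
    t0[i] = ev[i].t0; x[i] = ev[i].x; y[i] = ev[i].y; z[i] = ev[i].z;
    tr[i] = ev[i].transfer; ch[i] = ev[i].channel + 1;
    kind[i] = ev[i].kind; spawned[i] = ev[i].spawned;
  }
  return DataFrame::create(_["t0"] = t0, _["x"] = x, _["y"] = y, _["z"] = z,
                           _["transfer"] = tr, _["channel"] = ch,
                           _["kind"] = kind, _["spawned"] = spawned);
}

static List snaps_df(const std::vector<SnapRec> &sn) {
  int n = sn.size();
  IntegerVector idx(n);
  NumericVector t(n), ke(n), dist(n);
  for (int i = 0; i < n; ++i) {
    idx[i] = sn[i].idx; t[i] = sn[i].t; ke[i] = sn[i].KE;
    dist[i] = sn[i].dist;
  }
  return DataFrame::create(_["index"] = idx, _["time"] = t, _["KE"] = ke,
                           _["dist"] = dist);
}

// [[Rcpp::export]]
List cpp_run_history(List xs, List diel, List cfg, double E0,
                     int seed, int history, bool primary_only) {
  Engine eng;
  eng.cfg.init(cfg);
  eng.xs.init(xs, eng.cfg.dea_enabled);
  eng.diel.init(diel);
  uint64_t base = mix64((uint64_t)(uint32_t)seed, (uint64_t)history);
  Rng prim_rng(mix64(base, 0));

  Electron rem = eng.run_primary(E0, prim_rng);
  eng.queue.push_back(rem);

  if (!primary_only) {
    size_t qi = 0;
    while (qi < eng.queue.size()) {
      Electron e = eng.queue[qi++];
      e.snap_ptr = 0;
      Rng erng(mix64(base, (uint64_t)(e.idx + 1)));
      eng.propagate(e, erng, true);
    }
  } else {
    for (size_t i = 0; i < eng.queue.size(); ++i)
      eng.done.push_back(eng.queue[i]);
  }

  for (size_t i = 0; i < eng.done.size(); ++i)
    eng.book.residual += eng.done[i].KE;

  int np = eng.prim_path.size() / 5;
  NumericMatrix pp(np, 5);
  for (int i = 0; i < np; ++i)
    for (int k = 0; k < 5; ++k) pp(i, k) = eng.prim_path[5 * i + k];

  return List::create(
      _["events"] = events_df(eng.events),
      _["electrons"] = electrons_df(eng.done),
      _["snapshots"] = snaps_df(eng.snaps),
      _["primary_path"] = pp,
      _["bookkeeping"] = List::create(
          _["E0"] = E0, _["deposits"] = eng.book.deposits,
          _["bath_net"] = eng.book.bath_net,
          _["field_work"] = eng.book.field_work,
          _["residual"] = eng.book.residual));
}

// Propagate a single, explicitly specified electron. Spawned electrons are
// reported but not themselves propagated.
// [[Rcpp::export]]
List cpp_propagate(List xs, List diel, List cfg, List state, int seed) {
  Engine eng;
  eng.cfg.init(cfg);
  eng.xs.init(xs, eng.cfg.dea_enabled);
  eng.diel.init(diel);
  Rng rng(mix64((uint64_t)(uint32_t)seed, 1));

  Electron e;
  NumericVector x = state["position"], v = state["velocity"];
  for (int k = 0; k < 3; ++k) { e.x[k] = x[k]; e.v[k] = v[k]; e.birth[k] = x[k]; }
  e.has_parent = as<bool>(state["has_parent"]);
  if (e.has_parent) {
    NumericVector p = state["parent"];
    for (int k = 0; k < 3; ++k) e.parent[k] = p[k];
  } else {
    for (int k = 0; k < 3; ++k) e.parent[k] = 0;
  }
  e.birth_t0 = as<double>(state["birth_t0"]);
  e.KE = eng.ke_of(e.v);
  e.birth_KE = e.KE;
  e.t_i = 0; e.origin = as<int>(state["origin"]);
  e.status = 0; e.therm_count = 0; e.freeze_at = -1.0;
  e.remnant = false; e.idx = 1;
  e.snap_ptr = 0;

  eng.next_idx = 2;
  eng.propagate(e, rng, false);

  // the propagated electron is the first entry of done; any additional
  // queue entries are unpropagated spawns
  std::vector<Electron> spawned(eng.queue.begin(), eng.queue.end());
  return List::create(
      _["electron"] = electrons_df(eng.done),
      _["spawned"] = electrons_df(spawned),
      _["events"] = events_df(eng.events),
      _["snapshots"] = snaps_df(eng.snaps),
      _["bookkeeping"] = List::create(
          _["deposits"] = eng.book.deposits,
          _["bath_net"] = eng.book.bath_net,
          _["field_work"] = eng.book.field_work));
}

// Thermalisation-distance experiment: n force-free electrons injected
// isotropically at E_inject; returns straight-line injection-to-stop
// distances and final kinetic energies.
// [[Rcpp::export]]
List cpp_therm_experiment(List xs, List diel, List cfg, double E_inject,
                          int n, int seed) {
  Engine eng;
  eng.cfg.init(cfg);
  eng.xs.init(xs, eng.cfg.dea_enabled);
  eng.diel.init(diel);

  NumericVector dist(n), ke(n), ttime(n);
  IntegerVector status(n);
  for (int i = 0; i < n; ++i) {
    Engine e1;
    e1.cfg = eng.cfg; e1.xs = eng.xs; e1.diel = eng.diel;
    Rng rng(mix64((uint64_t)(uint32_t)seed, (uint64_t)(i + 1)));
    Electron e;
    for (int k = 0; k < 3; ++k) { e.x[k] = 0; e.parent[k] = 0; e.birth[k] = 0; }
    e.has_parent = false;
    e.birth_t0 = 0; e.birth_KE = E_inject; e.t_i = 0;
    e.origin = 1; e.status = 0; e.therm_count = 0; e.freeze_at = -1.0;
    e.remnant = false;
    e.idx = 1; e.snap_ptr = 0;
    double d[3]; Engine::iso_dir(rng, d);
    e1.set_speed(e, E_inject, d);
    for (int k = 0; k < 3; ++k) e.v[k] = d[k] *
      std::sqrt(2.0 * E_inject / ME);
    e.KE = E_inject;
    e1.propagate(e, rng, false);
    const Electron &f = e1.done[0];
    double r = 0;
    for (int k = 0; k < 3; ++k) r += f.x[k] * f.x[k];
    dist[i] = std::sqrt(r);
    ke[i] = f.KE;
    ttime[i] = f.t_i;
    status[i] = f.status;
  }
  return List::create(_["distance"] = dist, _["KE"] = ke,
                      _["t_stop"] = ttime, _["status"] = status);
}
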