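// Discrete-event core of the liver transplant waiting-list model.
//
// One replication simulates Poisson arrival streams of patients and donor
// livers over a burn-in plus a 10-year enrollment window, with AB0 matching
// (priority to acute liver failure and retransplant listings), competing
// pretransplant exits, retransplantation branching and posttransplant
// survival with a 10-year switch to life-table background mortality.
// Patients listed during the enrollment window are tracked to death;
// arrivals continue past the window until every tracked patient has left the
// list, so late-window listings face realistic competition.
//
// All randomness derives from four named 64-bit streams (arrivals,
// attributes, pretransplant, posttransplant). Every patient owns one
// substream per purpose keyed by (stream seed, replication, group, arrival
// index), so a given patient's fate draws are identical across scenarios
// sharing a master seed: common random numbers for strategy differences.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----

static inline uint64_t sm64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// uniform in [0, 1), 53-bit mantissa
static inline double u01(uint64_t &x) {
  return (sm64(x) >> 11) * (1.0 / 9007199254740992.0);
}

static inline uint64_t substream(uint64_t seed, uint64_t rep, uint64_t grp,
                                 uint64_t idx) {
  uint64_t x = seed * 0x9E3779B97F4A7C15ULL;
  x ^= (rep + 1) * 0xBF58476D1CE4E5B9ULL;
  x ^= (grp + 1) * 0x94D049BB133111EBULL;
  x ^= (idx + 1) * 0xD6E8FEB86659FD93ULL;
  sm64(x); sm64(x);
  return x;
}

// ------------------------------------------------- survival quantiles -----

// family codes: 0 exponential, 1 weibull, 2 loglogistic, 3 lognormal,
// 4 gompertz. Same closed forms as the R-level surv_quantile().
static double q_surv(int fam, double p1, double p2, double p) {
  switch (fam) {
  case 0: return -p1 * log1p(-p);
  case 1: return p2 * std::pow(-log1p(-p), 1.0 / p1);
  case 2: return p2 * std::pow(p / (1.0 - p), 1.0 / p1);
  case 3: return std::exp(p1 + p2 * R::qnorm(p, 0.0, 1.0, 1, 0));
  case 4: {
    double a = p1, b = p2;
    if (std::fabs(b) < 1e-12) return -log1p(-p) / a;
    double arg = 1.0 - (b / a) * log1p(-p);
    if (arg <= 0.0) return R_PosInf;
    return std::log(arg) / b;
  }
  }
  return R_NaReal;
}

struct Dist {
  int fam;
  double p1, p2, cap_days; // +Inf when no cap applies
};

static Dist read_dist(const NumericMatrix &m, int row) {
  Dist d;
  d.fam = (int) m(row, 0);
  d.p1 = m(row, 1);
  d.p2 = m(row, 2);
  double cy = m(row, 3);
  d.cap_days = ISNAN(cy) ? R_PosInf : cy * 365.25;
  return d;
}

// remaining-lifetime sampler on the survival ladder, integer current age;
// mirrors lt_sample_remaining() in R
static double lt_sample(const std::vector<double> &qx, int min_age, int age,
                        double u) {
  int i0 = age - min_age;
  int n = (int) qx.size() - i0;
  double s_target = 1.0 - u;
  double S_prev = 1.0, S = 1.0;
  for (int k = 1; k <= n; ++k) {
    S_prev = S;
    S *= (1.0 - qx[i0 + k - 1]);
    if (S < s_target || k == n) {
      double w = (S_prev - s_target) / (S_prev - S);
      if (!(w >= 0.0)) w = 0.0;
      if (w > 1.0) w = 1.0;
      return (k - 1) + w;
    }
  }
  return (double) n;
}

// ------------------------------------------------------------ engine ------

enum Outcome { PALLIATIVE = 0, TRANSPLANT = 1, DEATH = 2, DROPOUT = 3,
               WITHDRAW = 4, WAITING = 5 };

struct Pat {
  int id, group, diag, bt;
  double age;
  double first_listing, listing; // current spell start
  double exit_time;              // scheduled competing exit of current spell
  int exit_kind;                 // DEATH / DROPOUT / WITHDRAW
  bool matchable, priority, tracked;
  int n_tx;
  double first_tx_time;
  uint64_t pre, post; // substream states
};

struct LogRow {
  int id, group, diag, bt, priority, matchable, outcome, tracked, spell;
  double start, end, life_years;
};

// scripted first-cycle posttransplant draws (tests only)
struct ScriptU {
  double ur, uq, us, ub;
  bool used;
};

struct Params {
  double burn_in, enroll_days;
  int strategy;
  double mean_sq, mean_crlm, mean_liver;
  double pmix_blood[4], lmix_blood[4], dmix[6];
  double ages[7];
  double p_retrans, p_qualify, p_withdraw, withdraw_delay_mean;
  bool identical_abo;
  Dist post_d[7], pall, wl_death[7], wl_dropout[7];
  std::vector<double> qx;
  int lt_min_age;
  uint64_t s_arr, s_attr, s_pre, s_post;
};

static int pick_cat(double u, const double *w, int k) {
  double c = 0.0;
  for (int i = 0; i < k - 1; ++i) {
    c += w[i];
    if (u < c) return i;
  }
  return k - 1;
}

#define N_STATS 28

static double med(std::vector<double> &v) {
  if (v.empty()) return R_NaReal;
  std::sort(v.begin(), v.end());
  size_t n = v.size();
  return (n % 2) ? v[n / 2] : 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

class Sim {
public:
  const Params &P;
  uint64_t rep;
  bool collect_log;

  std::vector<Pat> pats;
  std::vector<int> q[4]; // patient ids per blood type, insertion order
  std::vector<double> waits_bt[4], waits_all;
  double stats[N_STATS];
  std::vector<LogRow> log;
  double end_enroll;
  std::vector<ScriptU> script; // empty unless scripted test mode

  Sim(const Params &P_, uint64_t rep_, bool log_)
    : P(P_), rep(rep_), collect_log(log_) {
    std::fill(stats, stats + N_STATS, 0.0);
    end_enroll = P.burn_in + P.enroll_days;
  }

  void add_spell_stats(double start, double end) {
    double a = std::max(start, P.burn_in), b = std::min(end, end_enroll);
    if (b > a) stats[24] += (b - a); // queue-length integral, normalized later
    if (start >= P.burn_in && start < end_enroll) {
      stats[25] += 1.0;
      stats[26] += (end - start);
    }
  }

  void log_spell(const Pat &p, int spell, double start, double end,
                 int outcome, double ly) {
    if (!collect_log) return;
    LogRow r;
    r.id = p.id; r.group = p.group; r.diag = p.diag; r.bt = p.bt;
    r.priority = p.priority ? 1 : 0; r.matchable = p.matchable ? 1 : 0;
    r.outcome = outcome;
    r.tracked = p.tracked ? 1 : 0; r.spell = spell;
    r.start = start; r.end = end; r.life_years = ly;
    log.push_back(r);
  }

  void finalize_le(const Pat &p, double ly) {
    if (!p.tracked) return;
    if (p.group == 0) { stats[20] += ly; stats[22] += 1.0; }
    else              { stats[21] += ly; stats[23] += 1.0; }
  }

  // competing pretransplant exits for the spell starting at `clock`
  void start_spell(Pat &p, double clock) {
    double u_w = u01(p.pre);
    bool withdrawer = (u_w < P.p_withdraw);
    double t_w = R_PosInf;
    if (withdrawer)
      t_w = -P.withdraw_delay_mean * log1p(-u01(p.pre));
    const Dist &dd = P.wl_death[p.diag];
    const Dist &dr = P.wl_dropout[p.diag];
    double t_d = q_surv(dd.fam, dd.p1, dd.p2, u01(p.pre));
    double t_r = q_surv(dr.fam, dr.p1, dr.p2, u01(p.pre));
    set_spell_exits(p, clock, t_d, t_r, withdrawer, t_w);
  }

  void set_spell_exits(Pat &p, double clock, double t_d, double t_r,
                       bool withdrawer, double t_w) {
    p.matchable = !withdrawer;
    p.exit_time = clock + t_d;
    p.exit_kind = DEATH;
    if (t_r < t_d) { p.exit_time = clock + t_r; p.exit_kind = DROPOUT; }
    if (withdrawer && t_w < std::min(t_d, t_r)) {
      p.exit_time = clock + t_w;
      p.exit_kind = WITHDRAW;
    }
  }

  void record_exit(Pat &p, int spell_no) {
    double ly = (p.n_tx > 0) ? (p.exit_time - p.first_tx_time) / 365.25 : 0.0;
    if (p.tracked) {
      if (p.exit_kind == WITHDRAW) stats[p.group == 0 ? 5 : 6] += 1.0;
      else stats[p.group == 0 ? 7 : 8] += 1.0;
    }
    finalize_le(p, ly);
    add_spell_stats(p.listing, p.exit_time);
    log_spell(p, spell_no, p.listing, p.exit_time, p.exit_kind, ly);
  }

  void purge_queue(int bt, double clock) {
    std::vector<int> &Q = q[bt];
    size_t w = 0;
    for (size_t i = 0; i < Q.size(); ++i) {
      Pat &p = pats[Q[i]];
      if (p.exit_time <= clock) record_exit(p, p.n_tx);
      else Q[w++] = Q[i];
    }
    Q.resize(w);
  }

  // posttransplant survival in years from transplant, with the cap-year
  // switch to background mortality
  double post_ly(Pat &p, const Dist &d, double u_s, double u_b) {
    if (ISNAN(u_s)) u_s = u01(p.post);
    double T = q_surv(d.fam, d.p1, d.p2, u_s);
    if (T <= d.cap_days) return T / 365.25;
    if (ISNAN(u_b)) u_b = u01(p.post);
    int age_sw = (int) std::lround(p.age + d.cap_days / 365.25);
    return d.cap_days / 365.25 + lt_sample(P.qx, P.lt_min_age, age_sw, u_b);
  }

  void transplant(Pat &p, double clock) {
    add_spell_stats(p.listing, clock);
    double wait = clock - p.listing;
    if (p.n_tx == 0) {
      p.first_tx_time = clock;
      if (p.tracked) {
        stats[p.group == 0 ? 2 : 3] += 1.0;
        waits_bt[p.bt].push_back(wait);
        waits_all.push_back(wait);
      }
    } else if (p.tracked) {
      stats[4] += 1.0;
    }
    log_spell(p, p.n_tx, p.listing, clock, TRANSPLANT, NA_REAL);
    p.n_tx += 1;

    double u_re = NA_REAL, u_q = NA_REAL, u_s = NA_REAL, u_b = NA_REAL;
    if ((size_t) p.id < script.size() && !script[p.id].used) {
      ScriptU &S = script[p.id];
      S.used = true;
      u_re = S.ur; u_q = S.uq; u_s = S.us; u_b = S.ub;
    }
    if (ISNAN(u_re)) u_re = u01(p.post);
    if (u_re < P.p_retrans) {
      if (ISNAN(u_q)) u_q = u01(p.post);
      if (u_q < P.p_qualify) {
        // relisted with priority, new competing exit times
        p.listing = clock;
        p.priority = true;
        start_spell(p, clock);
        q[p.bt].push_back(p.id);
        return;
      }
      // does not qualify for retransplant: removed, life-years to removal
      if (p.tracked) stats[9] += 1.0;
      finalize_le(p, (clock - p.first_tx_time) / 365.25);
      return;
    }
    const Dist &d = P.post_d[p.diag];
    double ly = (clock - p.first_tx_time) / 365.25 + post_ly(p, d, u_s, u_b);
    finalize_le(p, ly);
  }

  void liver_arrival(double clock, int bt) {
    bool in_window = (clock >= P.burn_in && clock < end_enroll);
    if (in_window) stats[10] += 1.0;
    // candidate recipient blood types; codes A=0, B=1, AB=2, O=3
    int cand[4];
    int ncand = 0;
    if (P.identical_abo) {
      cand[ncand++] = bt;
    } else {
      for (int r = 0; r < 4; ++r) {
        bool ok = (r == bt) || (bt == 3) ||
          (bt == 0 && r == 2) || (bt == 1 && r == 2);
        if (ok) cand[ncand++] = r;
      }
    }
    for (int c = 0; c < ncand; ++c) purge_queue(cand[c], clock);
    int best = -1;
    bool best_pri = false;
    double best_listing = R_PosInf;
    for (int c = 0; c < ncand; ++c) {
      const std::vector<int> &Q = q[cand[c]];
      for (size_t i = 0; i < Q.size(); ++i) {
        const Pat &p = pats[Q[i]];
        if (!p.matchable) continue;
        bool better = (p.priority != best_pri)
          ? p.priority
          : (p.listing < best_listing);
        if (best < 0 || better) {
          best = p.id; best_pri = p.priority; best_listing = p.listing;
        }
      }
    }
    if (best < 0) {
      if (in_window) stats[11] += 1.0; // exported
      return;
    }
    Pat &p = pats[best];
    std::vector<int> &Q = q[p.bt];
    Q.erase(std::find(Q.begin(), Q.end(), best));
    transplant(p, clock);
  }

  void add_patient(Pat p) {
    if (p.group == 1 && P.strategy == 1) {
      // palliative chemotherapy, never enters the queue
      if (p.tracked) {
        stats[1] += 1.0;
        double ly = post_ly(p, P.pall, NA_REAL, NA_REAL);
        finalize_le(p, ly);
        pats.push_back(p);
        log_spell(pats.back(), 0, p.listing, p.listing, PALLIATIVE, ly);
      }
      return;
    }
    if (p.tracked) stats[p.group == 0 ? 0 : 1] += 1.0;
    pats.push_back(p);
    q[p.bt].push_back(p.id);
  }

  void patient_arrival(double clock, int group, uint64_t idx) {
    Pat p;
    p.id = (int) pats.size();
    p.group = group;
    uint64_t attr = substream(P.s_attr, rep, group, idx);
    p.pre = substream(P.s_pre, rep, group, idx);
    p.post = substream(P.s_post, rep, group, idx);
    p.bt = pick_cat(u01(attr), P.pmix_blood, 4);
    p.diag = (group == 0) ? pick_cat(u01(attr), P.dmix, 6) : 6;
    p.age = P.ages[p.diag];
    p.first_listing = p.listing = clock;
    p.n_tx = 0;
    p.first_tx_time = R_NaReal;
    p.priority = (p.diag == 3); // ALF
    p.matchable = false;
    p.tracked = (clock >= P.burn_in && clock < end_enroll);
    if (!(p.group == 1 && P.strategy == 1)) start_spell(p, clock);
    add_patient(p);
  }

  bool tracked_pending(double t) const {
    for (int b = 0; b < 4; ++b)
      for (size_t i = 0; i < q[b].size(); ++i) {
        const Pat &p = pats[q[b][i]];
        if (p.tracked && p.exit_time > t) return true;
      }
    return false;
  }

  void finish() {
    for (int b = 0; b < 4; ++b) {
      for (size_t i = 0; i < q[b].size(); ++i) {
        Pat &p = pats[q[b][i]];
        if (R_FINITE(p.exit_time)) {
          record_exit(p, p.n_tx);
        } else {
          if (p.tracked) stats[27] += 1.0;
          add_spell_stats(p.listing, end_enroll);
          log_spell(p, p.n_tx, p.listing, NA_REAL, WAITING, NA_REAL);
        }
      }
      q[b].clear();
    }
    for (int b = 0; b < 4; ++b) stats[12 + b] = med(waits_bt[b]);
    stats[16] = med(waits_all);
    if (!waits_all.empty()) {
      stats[17] = *std::min_element(waits_all.begin(), waits_all.end());
      stats[18] = *std::max_element(waits_all.begin(), waits_all.end());
      double s = 0.0;
      for (double w : waits_all) s += w;
      stats[19] = s / waits_all.size();
    } else {
      stats[17] = stats[18] = stats[19] = R_NaReal;
    }
    double n_sq = stats[22], n_cr = stats[23];
    stats[20] = n_sq > 0 ? stats[20] / n_sq : R_NaReal; // mean LE, sums so far
    stats[21] = n_cr > 0 ? stats[21] / n_cr : R_NaReal;
    stats[22] = ISNAN(stats[20]) ? 0.0 : stats[20] * n_sq; // total life-years
    stats[23] = ISNAN(stats[21]) ? 0.0 : stats[21] * n_cr;
    stats[24] /= P.enroll_days;
  }

  void run() {
    uint64_t a_sq = substream(P.s_arr, rep, 0, 0);
    uint64_t a_cr = substream(P.s_arr, rep, 1, 0);
    uint64_t a_lv = substream(P.s_arr, rep, 2, 0);
    uint64_t l_attr = substream(P.s_attr, rep, 3, 0);
    uint64_t n_sq = 0, n_cr = 0;
    double t_sq = (P.mean_sq > 0) ? -P.mean_sq * log1p(-u01(a_sq)) : R_PosInf;
    double t_cr = (P.mean_crlm > 0) ? -P.mean_crlm * log1p(-u01(a_cr)) : R_PosInf;
    double t_lv = (P.mean_liver > 0) ? -P.mean_liver * log1p(-u01(a_lv)) : R_PosInf;
    double hard_stop = end_enroll + 365.25 * 120.0; // stall guard
    while (true) {
      double t = std::min(t_sq, std::min(t_cr, t_lv));
      if (!R_FINITE(t)) break;
      if (t > end_enroll && !tracked_pending(t)) break;
      if (t > hard_stop) { // stall guard, surfaced through stats[27]
        for (int b = 0; b < 4; ++b)
          for (size_t i = 0; i < q[b].size(); ++i) {
            const Pat &p = pats[q[b][i]];
            if (p.tracked && p.exit_time > t) stats[27] += 1.0;
          }
        break;
      }
      if (t == t_sq) {
        patient_arrival(t, 0, n_sq++);
        t_sq = t + -P.mean_sq * log1p(-u01(a_sq));
      } else if (t == t_cr) {
        patient_arrival(t, 1, n_cr++);
        t_cr = t + -P.mean_crlm * log1p(-u01(a_cr));
      } else {
        int bt = pick_cat(u01(l_attr), P.lmix_blood, 4);
        liver_arrival(t, bt);
        t_lv = t + -P.mean_liver * log1p(-u01(a_lv));
      }
    }
    finish();
  }
};

static Params build_params(List scenario, List streams) {
  Params P;
  P.burn_in = as<double>(scenario["burn_in_days"]);
  P.enroll_days = as<double>(scenario["enrollment_days"]);
  P.strategy = as<int>(scenario["strategy"]);
  P.mean_sq = as<double>(scenario["mean_sq"]);
  P.mean_crlm = as<double>(scenario["mean_crlm"]);
  P.mean_liver = as<double>(scenario["mean_liver"]);
  NumericVector pb = scenario["patient_blood_mix"], lb = scenario["liver_mix"],
    dm = scenario["patient_mix"], ag = scenario["ages"];
  for (int i = 0; i < 4; ++i) { P.pmix_blood[i] = pb[i]; P.lmix_blood[i] = lb[i]; }
  for (int i = 0; i < 6; ++i) P.dmix[i] = dm[i];
  for (int i = 0; i < 7; ++i) P.ages[i] = ag[i];
  P.p_retrans = as<double>(scenario["p_retransplant_listed"]);
  P.p_qualify = as<double>(scenario["p_retransplant_qualify"]);
  P.p_withdraw = as<double>(scenario["p_withdraw"]);
  P.withdraw_delay_mean = as<double>(scenario["withdraw_delay_mean"]);
  P.identical_abo = as<bool>(scenario["identical_abo"]);
  NumericMatrix post = scenario["post_dists"], wld = scenario["wl_death_dists"],
    wlr = scenario["wl_dropout_dists"], pall = scenario["palliative_dist"];
  for (int i = 0; i < 7; ++i) {
    P.post_d[i] = read_dist(post, i);
    P.wl_death[i] = read_dist(wld, i);
    P.wl_dropout[i] = read_dist(wlr, i);
  }
  P.pall = read_dist(pall, 0);
  NumericVector qx = scenario["lt_qx"];
  P.qx.assign(qx.begin(), qx.end());
  P.lt_min_age = as<int>(scenario["lt_min_age"]);
  P.s_arr = (uint64_t) as<double>(streams["arrivals"]);
  P.s_attr = (uint64_t) as<double>(streams["attributes"]);
  P.s_pre = (uint64_t) as<double>(streams["pretransplant"]);
  P.s_post = (uint64_t) as<double>(streams["posttransplant"]);
  return P;
}

static DataFrame log_to_df(const std::vector<LogRow> &lg) {
  size_t n = lg.size();
  IntegerVector id(n), group(n), diag(n), bt(n), priority(n), matchable(n),
    outcome(n), tracked(n), spell(n);
  NumericVector start(n), end(n), ly(n);
  for (size_t i = 0; i < n; ++i) {
    const LogRow &L = lg[i];
    id[i] = L.id; group[i] = L.group; diag[i] = L.diag; bt[i] = L.bt;
    priority[i] = L.priority; matchable[i] = L.matchable; outcome[i] = L.outcome;
    tracked[i] = L.tracked; spell[i] = L.spell;
    start[i] = L.start; end[i] = L.end; ly[i] = L.life_years;
  }
  return DataFrame::create(
    _["id"] = id, _["group"] = group, _["diagnosis"] = diag,
    _["blood_type"] = bt, _["priority"] = priority,
    _["matchable"] = matchable, _["spell"] = spell,
    _["listed"] = start, _["exited"] = end, _["outcome"] = outcome,
    _["tracked"] = tracked, _["life_years"] = ly);
}

// [[Rcpp::export]]
List cpp_run_experiment(List scenario, List streams, int n_reps,
                        bool collect_log) {
  Params P = build_params(scenario, streams);
  NumericMatrix out(n_reps, N_STATS);
  List logs = List(collect_log ? n_reps : 0);
  for (int r = 0; r < n_reps; ++r) {
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
    Sim s(P, (uint64_t) r, collect_log);
    s.run();
    for (int k = 0; k < N_STATS; ++k) out(r, k) = s.stats[k];
    if (collect_log) logs[r] = log_to_df(s.log);
  }
  return List::create(_["stats"] = out, _["logs"] = logs);
}

// Deterministic scripted replication used by unit tests: arrivals, patient
// attributes and fate draws are supplied explicitly instead of being drawn
// from streams. Columns of `patients`: time, group, diag, bt, t_death,
// t_dropout, withdrawer, withdraw_delay (all offsets in days from listing),
// u_retrans, u_qualify, u_surv, u_bg (fate draws for the FIRST transplant
// decision; NA falls back to the posttransplant stream, as do later cycles).
// `livers`: time, bt.
// [[Rcpp::export]]
List cpp_run_scripted(List scenario, List streams, DataFrame patients,
                      DataFrame livers) {
  Params P = build_params(scenario, streams);
  Sim s(P, 0, true);
  NumericVector pt = patients["time"];
  IntegerVector pg = patients["group"], pd = patients["diag"],
    pb = patients["bt"], wd = patients["withdrawer"];
  NumericVector td = patients["t_death"], tr = patients["t_dropout"],
    wdel = patients["withdraw_delay"], ur = patients["u_retrans"],
    uq = patients["u_qualify"], us = patients["u_surv"], ub = patients["u_bg"];
  NumericVector lt = livers["time"];
  IntegerVector lb = livers["bt"];

  struct Ev { double t; int kind, idx; };
  std::vector<Ev> evs;
  for (int i = 0; i < pt.size(); ++i) evs.push_back({pt[i], 0, i});
  for (int i = 0; i < lt.size(); ++i) evs.push_back({lt[i], 1, i});
  std::stable_sort(evs.begin(), evs.end(),
                   [](const Ev &a, const Ev &b) { return a.t < b.t; });

  for (const Ev &e : evs) {
    if (e.kind == 0) {
      int i = e.idx;
      Pat p;
      p.id = (int) s.pats.size();
      p.group = pg[i]; p.diag = pd[i]; p.bt = pb[i];
      p.age = P.ages[p.diag];
      p.first_listing = p.listing = e.t;
      p.n_tx = 0;
      p.first_tx_time = R_NaReal;
      p.priority = (p.diag == 3);
      p.tracked = (e.t >= P.burn_in && e.t < s.end_enroll);
      p.pre = substream(P.s_pre, 0, p.group, (uint64_t) i);
      p.post = substream(P.s_post, 0, p.group, (uint64_t) i);
      s.set_spell_exits(p, e.t, td[i], tr[i], wd[i] != 0,
                        wd[i] ? wdel[i] : R_PosInf);
      s.script.push_back({ur[i], uq[i], us[i], ub[i], false});
      s.add_patient(p);
    } else {
      s.liver_arrival(e.t, lb[e.idx]);
    }
  }
  s.finish();
  NumericMatrix out(1, N_STATS);
  for (int k = 0; k < N_STATS; ++k) out(0, k) = s.stats[k];
  return List::create(_["stats"] = out,
                      _["logs"] = List::create(log_to_df(s.log)));
}
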