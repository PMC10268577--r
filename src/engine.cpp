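// Compiled core of the learning dynamic: plays whole periods of the
// three-step stage game and the between-period logit revisions, so that
// million-period chains run in seconds. Mirrors the R-level reference
// implementation (play_round / play_period / revise_agent). Randomness
// comes from a fast local PRNG seeded from R's RNG stream, so set.seed()
// determines every run.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Fast local PRNG (xoshiro256++), seeded from R's RNG stream so that
// set.seed() fully determines a chain run. Used only inside the compiled
// engine; R-level functions draw from R's RNG directly.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed_from_r() {
    uint64_t x = (uint64_t)(unif_rand() * 9007199254740992.0);
    x ^= (uint64_t)(unif_rand() * 9007199254740992.0) << 11;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

Xoshiro rng;

struct Params {
  double b, c, w, tau, p, v, f, l, psi, delta, mu, eta, epsilon;
  double gPE, gE, gP;
  int kappa, N;
};

struct StratTab {
  // per strategy: role (0 producer, 1 enforcer), prodC (1 if CP, 0 if DP,
  // -1 for enforcers), punish/attack bits, informed, system index
  // (-1 = none/uninformed, else column in the score table)
  std::vector<int> role, prodC, a_coop, a_def, a_good, a_bad, informed, sys;
  int S = 0, nsys = 1;
  std::vector<int> sys_is_ce;  // per system column: 1 if it is the CE standard
};

inline int runif_int(int n) {  // uniform on 0..n-1
  int k = (int)(rng.unif() * n);
  return k >= n ? n - 1 : k;
}

inline bool flip(double mu) { return rng.unif() < mu; }

// expected per-round payoff of the candidate strategy `idx`, the analytic
// (mu = 0, long-period, unbounded-punishment) regime; counts include the
// candidate. Mirrors expected_payoff_counts() in R.
double expected_payoff(int idx, const std::vector<int>& counts,
                       const StratTab& st, const Params& par) {
  int nP = 0, nE = 0, nCP = 0;
  for (int s = 0; s < st.S; ++s) {
    if (st.role[s] == 0) {
      nP += counts[s];
      if (st.prodC[s] == 1) nCP += counts[s];
    } else nE += counts[s];
  }

  if (st.role[idx] == 0) {  // producer candidate
    if (nP == 1) return par.w;
    int others_cp = nCP - (st.prodC[idx] == 1 ? 1 : 0);
    double pC = (double)others_cp / (nP - 1);
    bool ownC = st.prodC[idx] == 1;
    double Epd = pC * par.b - (ownC ? par.c : 0.0);
    if (nE == 0) return par.w + Epd;
    double ppun = 0.0;
    for (int s = 0; s < st.S; ++s)
      if (st.role[s] == 1 && counts[s] > 0)
        ppun += counts[s] * (ownC ? st.a_coop[s] : st.a_def[s]);
    ppun /= nE;
    return (1.0 - par.tau) * (par.w + Epd) - par.p * ppun;
  }

  // enforcer candidate
  bool pairs = nP >= 2;
  int n_coop = pairs ? nCP : 0;
  int n_def = pairs ? nP - nCP : 0;
  double R = 0.0, cost_v = 0.0;
  if (pairs) {
    double pd_CP = nCP > 0 ? ((double)(nCP - 1) / (nP - 1)) * par.b - par.c : 0.0;
    double pd_DP = ((double)nCP / (nP - 1)) * par.b;
    double mean_pd = (nCP * pd_CP + (nP - nCP) * pd_DP) / nP;
    R = par.tau * (par.w + mean_pd) * (double)nP / nE;
    double shareC = (double)nCP / nP;
    cost_v = par.v * ((double)nP / nE) *
      (st.a_coop[idx] * shareC + st.a_def[idx] * (1.0 - shareC));
  }

  // long-run standing fixed point: bad[s][sys]; grow-only iteration
  static bool bad_buf[64][2];
  auto bad = bad_buf;
  for (int x = 0; x < st.S; ++x) bad[x][0] = bad[x][1] = false;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int si = 0; si < st.nsys; ++si) {
      for (int x = 0; x < st.S; ++x) {
        if (st.role[x] == 0 || counts[x] == 0 || bad[x][si]) continue;
        bool viol = false;
        if (st.sys_is_ce[si]) {
          if (n_coop > 0 && st.a_coop[x] == 1) viol = true;
          if (n_def > 0 && st.a_def[x] == 0) viol = true;
        }
        if (!viol && nE >= 2) {
          int own = st.sys[x];
          for (int y = 0; y < st.S && !viol; ++y) {
            if (st.role[y] == 0) continue;
            int m = counts[y] - (y == x ? 1 : 0);
            if (m <= 0) continue;
            bool y_bad_own = own >= 0 ? bad[y][own] : false;
            bool att = y_bad_own ? st.a_bad[x] == 1 : st.a_good[x] == 1;
            if (att != (bool)bad[y][si]) viol = true;
          }
        }
        if (viol) { bad[x][si] = true; changed = true; }
      }
    }
  }

  double meta = R;  // unmatched keeps revenue
  if (nE >= 2) {
    meta = 0.0;
    int own = st.sys[idx];
    for (int y = 0; y < st.S; ++y) {
      if (st.role[y] == 0) continue;
      int m = counts[y] - (y == idx ? 1 : 0);
      if (m <= 0) continue;
      bool y_bad_own = own >= 0 ? bad[y][own] : false;
      bool i_att = y_bad_own ? st.a_bad[idx] == 1 : st.a_good[idx] == 1;
      int ysys = st.sys[y];
      bool x_bad_for_y = ysys >= 0 ? bad[idx][ysys] : false;
      bool j_att = x_bad_for_y ? st.a_bad[y] == 1 : st.a_good[y] == 1;
      double cell;
      if (!i_att && !j_att) cell = R;
      else if (i_att && !j_att) cell = R + par.psi * R;
      else if (!i_att && j_att) cell = (1.0 - par.psi) * R - par.l;
      else cell = R - par.l;
      meta += ((double)m / (nE - 1)) * cell;
    }
  }
  return meta - cost_v - (st.informed[idx] ? par.f : 0.0);
}

}  // namespace

// single expected-payoff evaluation, for the exact best-reply dynamic
// [[Rcpp::export]]
double eg_expected_payoff(List rpar, IntegerMatrix strat,
                          IntegerVector sys_is_ce, IntegerVector counts,
                          int idx) {
  Params par;
  par.b = rpar["b"]; par.c = rpar["c"]; par.w = rpar["w"];
  par.tau = rpar["tau"]; par.p = rpar["p"]; par.v = rpar["v"];
  par.f = rpar["f"]; par.l = rpar["l"]; par.psi = rpar["psi"];
  par.delta = rpar["delta"]; par.mu = rpar["mu"]; par.eta = rpar["eta"];
  par.epsilon = rpar["epsilon"];
  par.gPE = rpar["gPE"]; par.gE = rpar["gE"]; par.gP = rpar["gP"];
  par.kappa = rpar["kappa"]; par.N = rpar["N"];
  StratTab st;
  st.S = strat.nrow();
  st.nsys = sys_is_ce.size();
  st.sys_is_ce.assign(sys_is_ce.begin(), sys_is_ce.end());
  for (int s = 0; s < st.S; ++s) {
    st.role.push_back(strat(s, 0));
    st.prodC.push_back(strat(s, 1));
    st.a_coop.push_back(strat(s, 2));
    st.a_def.push_back(strat(s, 3));
    st.a_good.push_back(strat(s, 4));
    st.a_bad.push_back(strat(s, 5));
    st.informed.push_back(strat(s, 6));
    st.sys.push_back(strat(s, 7));
  }
  std::vector<int> cnt(counts.begin(), counts.end());
  return expected_payoff(idx - 1, cnt, st, par);
}

// [[Rcpp::export]]
List eg_run_chain(List rpar, IntegerMatrix strat, IntegerVector sys_is_ce,
                  IntegerVector assign0, int periods, int thin) {
  Params par;
  par.b = rpar["b"]; par.c = rpar["c"]; par.w = rpar["w"];
  par.tau = rpar["tau"]; par.p = rpar["p"]; par.v = rpar["v"];
  par.f = rpar["f"]; par.l = rpar["l"]; par.psi = rpar["psi"];
  par.delta = rpar["delta"]; par.mu = rpar["mu"]; par.eta = rpar["eta"];
  par.epsilon = rpar["epsilon"];
  par.gPE = rpar["gPE"]; par.gE = rpar["gE"]; par.gP = rpar["gP"];
  par.kappa = rpar["kappa"]; par.N = rpar["N"];

  StratTab st;
  st.S = strat.nrow();
  st.nsys = sys_is_ce.size();
  st.sys_is_ce.assign(sys_is_ce.begin(), sys_is_ce.end());
  for (int s = 0; s < st.S; ++s) {
    st.role.push_back(strat(s, 0));
    st.prodC.push_back(strat(s, 1));
    st.a_coop.push_back(strat(s, 2));
    st.a_def.push_back(strat(s, 3));
    st.a_good.push_back(strat(s, 4));
    st.a_bad.push_back(strat(s, 5));
    st.informed.push_back(strat(s, 6));
    st.sys.push_back(strat(s, 7));
  }

  if (st.S > 64) stop("strategy set too large for the engine");
  rng.seed_from_r();

  const int N = par.N;
  std::vector<int> assign(assign0.begin(), assign0.end());
  std::vector<int> counts(st.S, 0);
  for (int i = 0; i < N; ++i) counts[assign[i]]++;

  std::vector<double> share_sum(st.S, 0.0);
  int ntrace = periods / thin + 1;
  IntegerMatrix trace(ntrace, st.S);
  std::vector<int> trace_periods;
  int trace_row = 0;
  double sum_T = 0.0;

  // per-round scratch
  std::vector<int> producers, enforcers, z(N * 2, 0), z_new(N * 2, 0);
  std::vector<double> total(N), revenue(N), pcost(N), meta_pay(N);
  std::vector<char> clientViol(N), attacked(N), meta_matched(N);
  std::vector<int> coplayer(N);

  // producer / enforcer / full menus
  std::vector<int> menuP, menuE, menuAll;
  for (int s = 0; s < st.S; ++s) {
    menuAll.push_back(s);
    if (st.role[s] == 0) menuP.push_back(s); else menuE.push_back(s);
  }

  std::vector<double> strat_sum(st.S), pay(st.S);
  std::vector<int> strat_n(st.S), best;

  for (int t = 0; t < periods; ++t) {
    for (int s = 0; s < st.S; ++s) share_sum[s] += counts[s];
    if (t % thin == 0 && trace_row < ntrace) {
      for (int s = 0; s < st.S; ++s) trace(trace_row, s) = counts[s];
      trace_periods.push_back(t + 1);
      trace_row++;
    }

    // ---- play one period --------------------------------------------
    producers.clear(); enforcers.clear();
    for (int i = 0; i < N; ++i)
      (st.role[assign[i]] == 0 ? producers : enforcers).push_back(i);
    int nP = producers.size(), nE = enforcers.size();
    std::fill(z.begin(), z.end(), 0);
    std::fill(total.begin(), total.end(), 0.0);

    int T = 1;
    while (rng.unif() < par.delta) T++;
    sum_T += T;

    for (int rd = 0; rd < T; ++rd) {
      // step 1: production
      for (int k = nP - 1; k > 0; --k)
        std::swap(producers[k], producers[runif_int(k + 1)]);
      int npair = nP / 2;
      for (int i = 0; i < nE; ++i) {
        int e = enforcers[i];
        revenue[e] = 0.0; pcost[e] = 0.0; clientViol[e] = 0;
      }
      for (int k = 0; k < npair; ++k) {
        int i = producers[2 * k], j = producers[2 * k + 1];
        bool Ci = st.prodC[assign[i]] == 1, Cj = st.prodC[assign[j]] == 1;
        if (par.mu > 0) { if (flip(par.mu)) Ci = !Ci; if (flip(par.mu)) Cj = !Cj; }
        double pdi = (Cj ? par.b : 0.0) - (Ci ? par.c : 0.0);
        double pdj = (Ci ? par.b : 0.0) - (Cj ? par.c : 0.0);
        double prei = par.w + pdi, prej = par.w + pdj;
        if (nE == 0) { total[i] += prei; total[j] += prej; continue; }
        // step 2: enforcement
        int e = enforcers[runif_int(nE)];
        int se = assign[e];
        revenue[e] += par.tau * (prei + prej);
        bool puni = (Ci ? st.a_coop[se] : st.a_def[se]) == 1;
        bool punj = (Cj ? st.a_coop[se] : st.a_def[se]) == 1;
        if (par.mu > 0) { if (flip(par.mu)) puni = !puni; if (flip(par.mu)) punj = !punj; }
        total[i] += (1.0 - par.tau) * prei - (puni ? par.p : 0.0);
        total[j] += (1.0 - par.tau) * prej - (punj ? par.p : 0.0);
        if (puni) pcost[e] += par.v;
        if (punj) pcost[e] += par.v;
        // CE-standard client clause violation? (punish exactly defection)
        if (puni != !Ci) clientViol[e] = 1;
        if (punj != !Cj) clientViol[e] = 1;
      }
      if (nP % 2 == 1) total[producers[nP - 1]] += par.w;  // unmatched, untaxed

      // step 3: meta-enforcement
      for (int k = nE - 1; k > 0; --k)
        std::swap(enforcers[k], enforcers[runif_int(k + 1)]);
      int nepair = nE / 2;
      for (int i = 0; i < nE; ++i) {
        int e = enforcers[i];
        meta_pay[e] = revenue[e]; meta_matched[e] = 0; coplayer[e] = -1;
        attacked[e] = 0;
      }
      for (int k = 0; k < nepair; ++k) {
        int i = enforcers[2 * k], j = enforcers[2 * k + 1];
        int si = assign[i], sj = assign[j];
        int sysi = st.sys[si] >= 0 ? st.sys[si] : 0;
        int sysj = st.sys[sj] >= 0 ? st.sys[sj] : 0;
        bool j_bad = z[j * 2 + sysi] > 0;   // coplayer standing at round entry
        bool i_bad = z[i * 2 + sysj] > 0;
        bool ai = j_bad ? st.a_bad[si] == 1 : st.a_good[si] == 1;
        bool aj = i_bad ? st.a_bad[sj] == 1 : st.a_good[sj] == 1;
        if (par.mu > 0) { if (flip(par.mu)) ai = !ai; if (flip(par.mu)) aj = !aj; }
        double Ri = revenue[i], Rj = revenue[j];
        if (!ai && !aj) { meta_pay[i] = Ri; meta_pay[j] = Rj; }
        else if (ai && !aj) { meta_pay[i] = Ri + par.psi * Rj; meta_pay[j] = (1.0 - par.psi) * Rj - par.l; }
        else if (!ai && aj) { meta_pay[i] = (1.0 - par.psi) * Ri - par.l; meta_pay[j] = Rj + par.psi * Ri; }
        else { meta_pay[i] = Ri - par.l; meta_pay[j] = Rj - par.l; }
        attacked[i] = ai; attacked[j] = aj;
        meta_matched[i] = meta_matched[j] = 1;
        coplayer[i] = j; coplayer[j] = i;
      }

      // payoffs and scoring
      for (int ii = 0; ii < nE; ++ii) {
        int e = enforcers[ii];
        total[e] += meta_pay[e] - pcost[e] -
          (st.informed[assign[e]] ? par.f : 0.0);
      }
      // compliance is judged against entry scores; commit all updates after
      for (int ii = 0; ii < nE; ++ii) {
        int e = enforcers[ii];
        for (int si = 0; si < st.nsys; ++si) {
          bool attack_ok = true;
          if (meta_matched[e]) {
            bool cop_bad = z[coplayer[e] * 2 + si] > 0;
            attack_ok = ((bool)attacked[e]) == cop_bad;
          }
          bool complied = attack_ok &&
            (st.sys_is_ce[si] ? clientViol[e] == 0 : true);
          int zi = z[e * 2 + si];
          z_new[e * 2 + si] = complied ? (zi > 0 ? zi - 1 : 0) : par.kappa;
        }
      }
      for (int ii = 0; ii < nE; ++ii) {
        int e = enforcers[ii];
        for (int si = 0; si < st.nsys; ++si)
          z[e * 2 + si] = z_new[e * 2 + si];
      }
    }

    // per-strategy realized averages
    std::fill(strat_sum.begin(), strat_sum.end(), 0.0);
    std::fill(strat_n.begin(), strat_n.end(), 0);
    for (int i = 0; i < N; ++i) {
      strat_sum[assign[i]] += total[i] / T;
      strat_n[assign[i]]++;
    }

    // ---- one revision ------------------------------------------------
    double u = rng.unif();
    int cls = u < par.gPE ? 2 : (u < par.gPE + par.gE ? 1 : 0);  // 0 P,1 E,2 PE
    if (cls == 0 && nP == 0) cls = 2;
    if (cls == 1 && nE == 0) cls = 2;
    int agent;
    const std::vector<int>* menu;
    if (cls == 0) { agent = producers[runif_int(nP)]; menu = &menuP; }
    else if (cls == 1) { agent = enforcers[runif_int(nE)]; menu = &menuE; }
    else { agent = runif_int(N); menu = &menuAll; }

    int pick;
    if (rng.unif() < par.epsilon) {
      pick = (*menu)[runif_int(menu->size())];
    } else {
      int M = menu->size();
      for (int m = 0; m < M; ++m) {
        int s = (*menu)[m];
        if (strat_n[s] > 0) pay[m] = strat_sum[s] / strat_n[s];
        else {
          counts[assign[agent]]--; counts[s]++;
          pay[m] = expected_payoff(s, counts, st, par);
          counts[s]--; counts[assign[agent]]++;
        }
      }
      if (par.eta == 0.0) {
        double mx = pay[0];
        for (int m = 1; m < M; ++m) if (pay[m] > mx) mx = pay[m];
        best.clear();
        for (int m = 0; m < M; ++m) if (pay[m] >= mx - 1e-12) best.push_back(m);
        pick = (*menu)[best[runif_int(best.size())]];
      } else {
        double mx = pay[0];
        for (int m = 1; m < M; ++m) if (pay[m] > mx) mx = pay[m];
        double tot = 0.0;
        for (int m = 0; m < M; ++m) { pay[m] = std::exp((pay[m] - mx) / par.eta); tot += pay[m]; }
        double r = rng.unif() * tot, acc = 0.0;
        pick = (*menu)[M - 1];
        for (int m = 0; m < M; ++m) { acc += pay[m]; if (r <= acc) { pick = (*menu)[m]; break; } }
      }
    }
    counts[assign[agent]]--;
    assign[agent] = pick;
    counts[pick]++;
  }

  NumericVector share(st.S);
  for (int s = 0; s < st.S; ++s) share[s] = share_sum[s] / ((double)periods * N);
  IntegerMatrix tr(trace_row, st.S);
  IntegerVector trp(trace_row);
  for (int r = 0; r < trace_row; ++r) {
    trp[r] = trace_periods[r];
    for (int s = 0; s < st.S; ++s) tr(r, s) = trace(r, s);
  }
  return List::create(
    _["share"] = share,
    _["trace"] = tr,
    _["trace_periods"] = trp,
    _["final"] = IntegerVector(assign.begin(), assign.end()),
    _["mean_T"] = sum_T / periods
  );
}
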