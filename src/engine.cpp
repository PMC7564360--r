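// Compiled simulation engine. Implements the identical rules and the
// identical random-number draw protocol as the plain-R reference
// implementation in R/season.R and R/reproduction.R, so that with the
// same seed both engines produce bit-identical trajectories. Any change
// here must keep the draw order in step with the R reference (see the
// protocol comments in those files).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Par {
  int nf, nm, slen, maxgen;
  int dom_spov, cull, different_males, poisson_enc;
  double different;
  int maxenc;
  double intake_scale, pspov;
  double mat_mean[2], mat_sd[2];
  double cw_int[2], cw_mat[2], cw_cl[2], cw_sd[2];
  double intake_mult[2], mort_f[2];
  double vol_int[2], vol_cw[2], vol_cond[2], vol_sd[2];
  double cl, meal, mort_m, esc, pmate, mfcl_attack;
  int mated_only, spov_uses_mfcl_rule, init_thirds, males_in_p;
  double p0;
  double cond_int, cond_cw, cond_sd;
  double sat_int, sat_cw, sat_cw2;
  double mal_mat_mean, mal_mat_sd;
  double off_int, off_vol;
};

void read2(const List& l, const char* name, double out[2]) {
  NumericVector v = l[name];
  out[0] = v[0];
  out[1] = v[1];
}

Par read_par(const List& l) {
  Par p;
  p.nf = as<int>(l["nf"]);
  p.nm = as<int>(l["nm"]);
  p.slen = as<int>(l["slen"]);
  p.maxgen = as<int>(l["maxgen"]);
  p.dom_spov = as<int>(l["dom_spov"]);
  p.different = as<double>(l["different"]);
  p.cull = as<int>(l["cull"]);
  p.different_males = as<int>(l["different_males"]);
  p.maxenc = as<int>(l["maxenc"]);
  p.poisson_enc = as<int>(l["poisson_enc"]);
  p.intake_scale = as<double>(l["intake_scale"]);
  p.pspov = as<double>(l["pspov"]);
  read2(l, "mat_mean", p.mat_mean);
  read2(l, "mat_sd", p.mat_sd);
  read2(l, "cw_int", p.cw_int);
  read2(l, "cw_mat", p.cw_mat);
  read2(l, "cw_cl", p.cw_cl);
  read2(l, "cw_sd", p.cw_sd);
  read2(l, "intake_mult", p.intake_mult);
  read2(l, "mort_f", p.mort_f);
  read2(l, "vol_int", p.vol_int);
  read2(l, "vol_cw", p.vol_cw);
  read2(l, "vol_cond", p.vol_cond);
  read2(l, "vol_sd", p.vol_sd);
  p.cl = as<double>(l["cl"]);
  p.meal = as<double>(l["meal"]);
  p.mort_m = as<double>(l["mort_m"]);
  p.esc = as<double>(l["esc"]);
  p.pmate = as<double>(l["pmate"]);
  p.mfcl_attack = as<double>(l["mfcl_attack"]);
  p.mated_only = as<int>(l["mated_only"]);
  p.spov_uses_mfcl_rule = as<int>(l["spov_uses_mfcl_rule"]);
  p.init_thirds = as<int>(l["init_thirds"]);
  p.p0 = as<double>(l["p0"]);
  p.males_in_p = as<int>(l["males_in_p"]);
  p.cond_int = as<double>(l["cond_int"]);
  p.cond_cw = as<double>(l["cond_cw"]);
  p.cond_sd = as<double>(l["cond_sd"]);
  p.sat_int = as<double>(l["sat_int"]);
  p.sat_cw = as<double>(l["sat_cw"]);
  p.sat_cw2 = as<double>(l["sat_cw2"]);
  p.mal_mat_mean = as<double>(l["mal_mat_mean"]);
  p.mal_mat_sd = as<double>(l["mal_mat_sd"]);
  p.off_int = as<double>(l["off_int"]);
  p.off_vol = as<double>(l["off_vol"]);
  return p;
}

struct State {
  // females
  std::vector<int> fa1, fa2, fspov, fmat, ffather, fres, fkills;
  std::vector<double> fcw, fcond, fmax;
  std::vector<int> fsat, fmated, falive;
  // males
  std::vector<int> ma, mmat, malive, mcohab, mmatings;
};

struct Tallies {
  int female_bg = 0, male_bg = 0, cann = 0;
  int matings[2] = {0, 0}; // phenotype index 0 = MFCL, 1 = spillover
};

struct Events {
  bool on = false;
  std::vector<int> day, code, male, female;
  void push(int d, int c, int m, int f) {
    if (!on) return;
    day.push_back(d);
    code.push_back(c);
    male.push_back(m);
    female.push_back(f);
  }
};

inline double round_half_up(double x) { return std::floor(x + 0.5); }

inline int clamp_day(double x, int slen) {
  int d = (int)round_half_up(x);
  if (d < 1) d = 1;
  if (d > slen) d = slen;
  return d;
}

// Life-history draws for a generation with fixed genotypes. Draw order:
// female maturation days, female CWs, female conditions, male
// maturation days (each a full pass, matching vectorized rnorm in R).
void init_life_history(State& st, const Par& par) {
  int nf = (int)st.fa1.size();
  int nm = (int)st.ma.size();
  st.fspov.resize(nf);
  st.fmat.resize(nf);
  st.fcw.resize(nf);
  st.fcond.resize(nf);
  st.fmax.resize(nf);
  st.fsat.assign(nf, 0);
  st.fmated.assign(nf, 0);
  st.ffather.assign(nf, -1);
  st.fres.assign(nf, -1);
  st.falive.assign(nf, 1);
  st.fkills.assign(nf, 0);
  st.mmat.resize(nm);
  st.malive.assign(nm, 1);
  st.mcohab.assign(nm, -1);
  st.mmatings.assign(nm, 0);

  for (int i = 0; i < nf; ++i) {
    int s = st.fa1[i] + st.fa2[i];
    st.fspov[i] = (par.dom_spov == 1) ? (s >= 1) : (s == 2);
  }
  for (int i = 0; i < nf; ++i) {
    int ph = st.fspov[i];
    double x = norm_rand() * par.mat_sd[ph] + par.mat_mean[ph];
    st.fmat[i] = clamp_day(x, par.slen);
  }
  for (int i = 0; i < nf; ++i) {
    int ph = st.fspov[i];
    double mu = par.cw_int[ph] + par.cw_mat[ph] * st.fmat[i] +
                par.cw_cl[ph] * par.cl;
    double cw = norm_rand() * par.cw_sd[ph] + mu;
    st.fcw[i] = cw > 0.01 ? cw : 0.01;
  }
  for (int i = 0; i < nf; ++i) {
    double mu = par.cond_int + par.cond_cw * st.fcw[i];
    double c = norm_rand() * par.cond_sd + mu;
    st.fcond[i] = c > 0 ? c : 0;
  }
  for (int i = 0; i < nf; ++i) {
    double cw = st.fcw[i];
    st.fmax[i] = par.sat_int + par.sat_cw * cw + par.sat_cw2 * cw * cw;
    st.fsat[i] = st.fcond[i] >= st.fmax[i];
  }
  for (int j = 0; j < nm; ++j) {
    double x = norm_rand() * par.mal_mat_sd + par.mal_mat_mean;
    st.mmat[j] = clamp_day(x, par.slen);
  }
}

// Founding genotypes: "thirds" is deterministic; Hardy-Weinberg draws
// each X copy independently (female first copies, female second copies,
// male copies).
void initial_genotypes(State& st, const Par& par) {
  st.fa1.assign(par.nf, 0);
  st.fa2.assign(par.nf, 0);
  st.ma.assign(par.nm, 0);
  if (par.init_thirds == 1) {
    int base = par.nf / 3, rem = par.nf % 3;
    int cnt[3] = {base, base, base}; // het, SS, MM
    for (int k = 0; k < rem; ++k) cnt[k]++;
    int i = 0;
    for (int k = 0; k < cnt[0]; ++k, ++i) { st.fa1[i] = 1; st.fa2[i] = 0; }
    for (int k = 0; k < cnt[1]; ++k, ++i) { st.fa1[i] = 1; st.fa2[i] = 1; }
    for (int k = 0; k < cnt[2]; ++k, ++i) { st.fa1[i] = 0; st.fa2[i] = 0; }
    int ns = par.nm / 2;
    for (int j = 0; j < par.nm; ++j) st.ma[j] = j < ns ? 1 : 0;
  } else {
    for (int i = 0; i < par.nf; ++i) st.fa1[i] = unif_rand() < par.p0;
    for (int i = 0; i < par.nf; ++i) st.fa2[i] = unif_rand() < par.p0;
    for (int j = 0; j < par.nm; ++j) st.ma[j] = unif_rand() < par.p0;
  }
}

inline double attack_prob(int spov, int mated, int sat, const Par& par) {
  if (spov && par.spov_uses_mfcl_rule == 0) return par.pspov;
  if (par.mated_only == 1) return mated ? par.mfcl_attack : 0.0;
  return (mated || !sat) ? par.mfcl_attack : 0.0;
}

// eat a male: kill count, condition gain capped at the satiation
// threshold (no gain once satiated), satiation update
inline void eat_male(State& st, int i, const Par& par) {
  st.fkills[i] += 1;
  if (!st.fsat[i]) {
    double nc = st.fcond[i] + par.meal;
    if (nc > st.fmax[i]) nc = st.fmax[i];
    st.fcond[i] = nc;
    if (nc >= st.fmax[i]) st.fsat[i] = 1;
  }
}

// One mating season. Event codes: 1 female_death, 2 male_death,
// 3 encounter, 4 attack, 5 escape, 6 cannibalism, 7 residency, 8 mating.
void season_core(State& st, const Par& par, Tallies& tal, Events& ev) {
  int nf = (int)st.fa1.size();
  int nm = (int)st.ma.size();
  std::vector<int> cand, local;
  cand.reserve(nf);
  local.reserve(nf);

  for (int t = 1; t <= par.slen; ++t) {
    // background mortality: females first, then males
    for (int i = 0; i < nf; ++i) {
      if (!st.falive[i] || st.fmat[i] > t) continue;
      double u = unif_rand();
      if (u < par.mort_f[st.fspov[i]]) {
        st.falive[i] = 0;
        tal.female_bg++;
        int r = st.fres[i];
        if (r >= 0) {
          st.mcohab[r] = -1;
          st.fres[i] = -1;
        }
        ev.push(t, 1, -1, i);
      }
    }
    for (int j = 0; j < nm; ++j) {
      if (!st.malive[j] || st.mmat[j] > t) continue;
      double u = unif_rand();
      if (u < par.mort_m) {
        st.malive[j] = 0;
        tal.male_bg++;
        int cf = st.mcohab[j];
        if (cf >= 0) {
          st.fres[cf] = -1;
          st.mcohab[j] = -1;
        }
        ev.push(t, 2, j, -1);
      }
    }

    // feeding
    for (int i = 0; i < nf; ++i) {
      if (!st.falive[i] || st.fmat[i] > t || st.fsat[i]) continue;
      double u = unif_rand();
      double nc = st.fcond[i] +
                  u * par.intake_scale * par.intake_mult[st.fspov[i]];
      if (nc > st.fmax[i]) nc = st.fmax[i];
      st.fcond[i] = nc;
      st.fsat[i] = nc >= st.fmax[i];
    }

    // male search: males visit female burrows; a not-yet-mature female
    // is simply absent, and that visit is wasted
    cand.clear();
    for (int i = 0; i < nf; ++i) {
      if (st.falive[i]) cand.push_back(i);
    }
    int ncand = (int)cand.size();
    for (int j = 0; j < nm; ++j) {
      if (!st.malive[j] || st.mmat[j] > t || st.mcohab[j] >= 0) continue;
      if (ncand == 0) continue;
      int k;
      if (par.poisson_enc == 1) {
        int draws = (int)Rf_rpois((double)par.maxenc);
        k = draws < ncand ? draws : ncand;
      } else {
        k = par.maxenc < ncand ? par.maxenc : ncand;
      }
      if (k <= 0) continue;
      local = cand;
      for (int e = 1; e <= k; ++e) {
        int remaining = ncand - e + 1;
        int r = (int)std::floor(unif_rand() * remaining);
        if (r >= remaining) r = remaining - 1;
        int pos = e - 1 + r;
        std::swap(local[e - 1], local[pos]);
        int i = local[e - 1];
        ev.push(t, 3, j, i);
        if (st.fmat[i] > t) continue; // nobody home yet
        if (st.fres[i] >= 0) continue; // prior residency excludes rivals
        double pa = attack_prob(st.fspov[i], st.fmated[i], st.fsat[i], par);
        if (unif_rand() < pa) {
          ev.push(t, 4, j, i);
          if (unif_rand() < std::exp(-st.fcw[i] * par.esc)) {
            ev.push(t, 5, j, i);
            break; // male flees; done searching today
          }
          st.malive[j] = 0;
          tal.cann++;
          eat_male(st, i, par);
          ev.push(t, 6, j, i);
          break;
        } else if (!st.fmated[i]) {
          st.fres[i] = j;
          st.mcohab[j] = i;
          ev.push(t, 7, j, i);
          break;
        }
        // mated female, no attack: male moves on
      }
    }

    // cohabitation
    for (int i = 0; i < nf; ++i) {
      if (!st.falive[i] || st.fres[i] < 0) continue;
      int j = st.fres[i];
      double pa = attack_prob(st.fspov[i], st.fmated[i], st.fsat[i], par);
      if (unif_rand() < pa) {
        ev.push(t, 4, j, i);
        if (unif_rand() < std::exp(-st.fcw[i] * par.esc)) {
          st.fres[i] = -1;
          st.mcohab[j] = -1;
          ev.push(t, 5, j, i);
        } else {
          st.malive[j] = 0;
          st.mcohab[j] = -1;
          st.fres[i] = -1;
          tal.cann++;
          eat_male(st, i, par);
          ev.push(t, 6, j, i);
        }
      } else if (unif_rand() < par.pmate) {
        st.fmated[i] = 1;
        st.ffather[i] = st.ma[j];
        st.mmatings[j] += 1;
        tal.matings[st.fspov[i]] += 1;
        st.fres[i] = -1;
        st.mcohab[j] = -1;
        ev.push(t, 8, j, i);
      }
    }
  }
}

// End-of-season reproduction and next-generation sampling. Returns
// false on extinction (no mothers / empty offspring pool for a sex).
// parental_p is the gamete-pool frequency used to classify extinctions;
// resampled flags with-replacement sampling of an undersized pool.
bool reproduce(State& st, const Par& par, double& parental_p,
               bool& resampled) {
  int nf = (int)st.fa1.size();
  std::vector<int> mothers;
  for (int i = 0; i < nf; ++i) {
    if (st.falive[i] && st.fmated[i]) mothers.push_back(i);
  }
  parental_p = NA_REAL;
  resampled = false;
  if (mothers.empty()) return false;

  long scount = 0;
  for (int i : mothers) scount += st.fa1[i] + st.fa2[i] + st.ffather[i];
  parental_p = (double)scount / (3.0 * mothers.size());

  int nmo = (int)mothers.size();
  std::vector<int> nk(nmo);
  long total = 0;
  for (int k = 0; k < nmo; ++k) {
    int i = mothers[k];
    int ph = st.fspov[i];
    double mu = par.vol_int[ph] + par.vol_cw[ph] * st.fcw[i] +
                par.vol_cond[ph] * st.fcond[i];
    double vol = norm_rand() * par.vol_sd[ph] + mu;
    if (vol < 0) vol = 0;
    double n = round_half_up(par.off_int + par.off_vol * vol);
    nk[k] = n > 0 ? (int)n : 0;
    total += nk[k];
  }
  if (total == 0) return false;

  std::vector<int> midx;
  midx.reserve(total);
  for (int k = 0; k < nmo; ++k) {
    for (int c = 0; c < nk[k]; ++c) midx.push_back(mothers[k]);
  }
  std::vector<char> is_f(total);
  for (long o = 0; o < total; ++o) is_f[o] = unif_rand() < 0.5;
  std::vector<int> maternal(total);
  for (long o = 0; o < total; ++o) {
    int i = midx[o];
    maternal[o] = (unif_rand() < 0.5) ? st.fa1[i] : st.fa2[i];
  }

  // daughters in offspring order
  std::vector<int> d_a1, d_a2;
  std::vector<char> d_spov;
  d_a1.reserve(total / 2 + 1);
  for (long o = 0; o < total; ++o) {
    if (!is_f[o]) continue;
    d_a1.push_back(maternal[o]);
    d_a2.push_back(st.ffather[midx[o]]);
    int s = d_a1.back() + d_a2.back();
    d_spov.push_back((par.dom_spov == 1) ? (s >= 1) : (s == 2));
  }
  if (par.cull == 1 && !d_a1.empty()) {
    std::vector<int> ka1, ka2;
    std::vector<char> ksp;
    for (size_t q = 0; q < d_a1.size(); ++q) {
      double w = d_spov[q] ? par.different : 1.0;
      if (unif_rand() < w) {
        ka1.push_back(d_a1[q]);
        ka2.push_back(d_a2[q]);
        ksp.push_back(d_spov[q]);
      }
    }
    d_a1.swap(ka1);
    d_a2.swap(ka2);
    d_spov.swap(ksp);
  }
  if (d_a1.empty()) return false;

  long nd = (long)d_a1.size();
  std::vector<int> sel_f(par.nf);
  if (nd >= par.nf) {
    std::vector<double> keys(nd);
    for (long q = 0; q < nd; ++q) {
      double w = (par.cull == 1) ? 1.0 : (d_spov[q] ? par.different : 1.0);
      keys[q] = exp_rand() / w;
    }
    std::vector<int> idx(nd);
    for (long q = 0; q < nd; ++q) idx[q] = (int)q;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return keys[a] < keys[b]; });
    for (int q = 0; q < par.nf; ++q) sel_f[q] = idx[q];
  } else {
    resampled = true;
    std::vector<double> cw(nd);
    double acc = 0;
    for (long q = 0; q < nd; ++q) {
      double w = (par.cull == 1) ? 1.0 : (d_spov[q] ? par.different : 1.0);
      acc += w;
      cw[q] = acc;
    }
    for (int q = 0; q < par.nf; ++q) {
      double u = unif_rand() * cw[nd - 1];
      sel_f[q] = (int)(std::upper_bound(cw.begin(), cw.end(), u) - cw.begin());
    }
  }

  // sons in offspring order
  std::vector<int> s_a;
  s_a.reserve(total / 2 + 1);
  for (long o = 0; o < total; ++o) {
    if (is_f[o]) continue;
    s_a.push_back(maternal[o]);
  }
  if (par.cull == 1 && par.different_males == 1 && !s_a.empty()) {
    std::vector<int> ka;
    for (size_t q = 0; q < s_a.size(); ++q) {
      double w = (s_a[q] == 1) ? par.different : 1.0;
      if (unif_rand() < w) ka.push_back(s_a[q]);
    }
    s_a.swap(ka);
  }
  if (s_a.empty()) return false;

  long ns = (long)s_a.size();
  std::vector<int> sel_m(par.nm);
  bool weight_sons = (par.cull == 0 && par.different_males == 1);
  if (ns >= par.nm) {
    std::vector<double> keys(ns);
    for (long q = 0; q < ns; ++q) {
      double w = weight_sons ? ((s_a[q] == 1) ? par.different : 1.0) : 1.0;
      keys[q] = exp_rand() / w;
    }
    std::vector<int> idx(ns);
    for (long q = 0; q < ns; ++q) idx[q] = (int)q;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return keys[a] < keys[b]; });
    for (int q = 0; q < par.nm; ++q) sel_m[q] = idx[q];
  } else {
    resampled = true;
    std::vector<double> cw(ns);
    double acc = 0;
    for (long q = 0; q < ns; ++q) {
      double w = weight_sons ? ((s_a[q] == 1) ? par.different : 1.0) : 1.0;
      acc += w;
      cw[q] = acc;
    }
    for (int q = 0; q < par.nm; ++q) {
      double u = unif_rand() * cw[ns - 1];
      sel_m[q] = (int)(std::upper_bound(cw.begin(), cw.end(), u) - cw.begin());
    }
  }

  std::vector<int> na1(par.nf), na2(par.nf), nma(par.nm);
  for (int q = 0; q < par.nf; ++q) {
    na1[q] = d_a1[sel_f[q]];
    na2[q] = d_a2[sel_f[q]];
  }
  for (int q = 0; q < par.nm; ++q) nma[q] = s_a[sel_m[q]];
  st.fa1.swap(na1);
  st.fa2.swap(na2);
  st.ma.swap(nma);
  return true;
}

double allele_freq(const State& st, const Par& par) {
  long s = 0, tot = 0;
  for (size_t i = 0; i < st.fa1.size(); ++i) s += st.fa1[i] + st.fa2[i];
  tot = 2 * (long)st.fa1.size();
  if (par.males_in_p == 1) {
    for (size_t j = 0; j < st.ma.size(); ++j) s += st.ma[j];
    tot += (long)st.ma.size();
  }
  return (double)s / (double)tot;
}

} // namespace

// [[Rcpp::export]]
List cpp_season(IntegerVector f_a1, IntegerVector f_a2, IntegerVector f_spov,
                IntegerVector f_mat, NumericVector f_cw, NumericVector f_cond,
                NumericVector f_maxcond, IntegerVector f_satiated,
                IntegerVector f_mated, IntegerVector f_father,
                IntegerVector f_resident, IntegerVector f_alive,
                IntegerVector f_kills, IntegerVector m_a, IntegerVector m_mat,
                IntegerVector m_alive, IntegerVector m_cohab,
                IntegerVector m_matings, List par_list, int log_events) {
  Par par = read_par(par_list);
  State st;
  st.fa1 = as<std::vector<int>>(f_a1);
  st.fa2 = as<std::vector<int>>(f_a2);
  st.fspov = as<std::vector<int>>(f_spov);
  st.fmat = as<std::vector<int>>(f_mat);
  st.fcw = as<std::vector<double>>(f_cw);
  st.fcond = as<std::vector<double>>(f_cond);
  st.fmax = as<std::vector<double>>(f_maxcond);
  st.fsat = as<std::vector<int>>(f_satiated);
  st.fmated = as<std::vector<int>>(f_mated);
  st.ffather = as<std::vector<int>>(f_father);
  st.fres = as<std::vector<int>>(f_resident);
  st.falive = as<std::vector<int>>(f_alive);
  st.fkills = as<std::vector<int>>(f_kills);
  st.ma = as<std::vector<int>>(m_a);
  st.mmat = as<std::vector<int>>(m_mat);
  st.malive = as<std::vector<int>>(m_alive);
  st.mcohab = as<std::vector<int>>(m_cohab);
  st.mmatings = as<std::vector<int>>(m_matings);

  Tallies tal;
  Events ev;
  ev.on = log_events != 0;
  season_core(st, par, tal, ev);

  List out = List::create(
      _["f_cond"] = wrap(st.fcond), _["f_satiated"] = wrap(st.fsat),
      _["f_mated"] = wrap(st.fmated), _["f_father"] = wrap(st.ffather),
      _["f_resident"] = wrap(st.fres), _["f_alive"] = wrap(st.falive),
      _["f_kills"] = wrap(st.fkills), _["m_alive"] = wrap(st.malive),
      _["m_cohab"] = wrap(st.mcohab), _["m_matings"] = wrap(st.mmatings),
      _["female_bg_deaths"] = tal.female_bg,
      _["male_bg_deaths"] = tal.male_bg,
      _["males_cannibalized"] = tal.cann,
      _["matings_mfcl"] = tal.matings[0],
      _["matings_spov"] = tal.matings[1]);
  if (ev.on) {
    out["ev_day"] = wrap(ev.day);
    out["ev_code"] = wrap(ev.code);
    out["ev_male"] = wrap(ev.male);
    out["ev_female"] = wrap(ev.female);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_generations(List par_list) {
  Par par = read_par(par_list);
  State st;
  initial_genotypes(st, par);
  init_life_history(st, par);

  std::vector<std::array<double, 10>> rec;
  int g = 0, outcome = 0, extinct = 0, resampled_gens = 0;

  for (;;) {
    double p = allele_freq(st, par);
    int n_sp = 0;
    for (int i = 0; i < par.nf; ++i) n_sp += st.fspov[i];
    int n_mf = par.nf - n_sp;
    if (p == 0.0 || p == 1.0) {
      rec.push_back({(double)g, p, (double)n_sp, (double)n_mf, NA_REAL,
                     NA_REAL, NA_REAL, NA_REAL, NA_REAL, NA_REAL});
      outcome = (p == 1.0) ? 1 : 2;
      break;
    }
    if (g >= par.maxgen) {
      rec.push_back({(double)g, p, (double)n_sp, (double)n_mf, NA_REAL,
                     NA_REAL, NA_REAL, NA_REAL, NA_REAL, NA_REAL});
      outcome = 0;
      break;
    }
    Tallies tal;
    Events ev;
    season_core(st, par, tal, ev);
    int surv_sp = 0, surv_mf = 0;
    for (int i = 0; i < par.nf; ++i) {
      if (st.falive[i]) {
        if (st.fspov[i]) surv_sp++; else surv_mf++;
      }
    }
    rec.push_back({(double)g, p, (double)n_sp, (double)n_mf, (double)surv_sp,
                   (double)surv_mf, (double)tal.matings[1],
                   (double)tal.matings[0], (double)tal.cann,
                   (double)tal.male_bg});
    double parental_p;
    bool resampled;
    bool ok = reproduce(st, par, parental_p, resampled);
    if (resampled) resampled_gens++;
    if (!ok) {
      extinct = 1;
      outcome = (!ISNA(parental_p) && parental_p >= 0.5) ? 1 : 2;
      g++;
      rec.push_back({(double)g, outcome == 1 ? 1.0 : 0.0, NA_REAL, NA_REAL,
                     NA_REAL, NA_REAL, NA_REAL, NA_REAL, NA_REAL, NA_REAL});
      break;
    }
    init_life_history(st, par);
    g++;
    if (g % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  int nr = (int)rec.size();
  NumericMatrix m(nr, 10);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < 10; ++c) m(r, c) = rec[r][c];
  }
  const auto& last = rec.back();
  return List::create(
      _["records"] = m, _["outcome"] = outcome,
      _["terminal_gen"] = (int)last[0], _["terminal_p"] = last[1],
      _["extinct"] = extinct, _["resampled"] = resampled_gens);
}
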