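// Elston-Stewart peeling engine and per-site calling driver.
//
// Genotypes inside the engine are biallelic alt-allele counts 0/1/2 over a
// chosen allele pair.  A pedigree is decomposed (in R) into nuclear
// families; the peeling schedule lists them leaves-first, each peeled into
// the connector individual shared with the family nearer the root.
// Likelihoods are propagated in linear space with per-step rescaling, so
// peeling is exact (matches brute-force enumeration to ~1e-12 in log
// space).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// A calling unit (one pedigree, or one individual in unrelated mode).
// Members may include loop-breaking clones; `glrow` maps every member to a
// column of the unit's data block, `out_col` maps original members to an
// output column (0 = clone, no output).
struct PlanC {
  int data_fam;                 // 0-based index into the data list
  int n;                        // members incl. clones
  int n_out;                    // output columns (original members)
  std::vector<int> glrow;       // member -> 0-based data column
  std::vector<int> out_col;     // member -> 0-based output column or -1
  std::vector<int> founder;     // 0/1 per member
  std::vector<std::vector<int>> sched; // {connector, fa, mo, kids...}, 0-based, connector -1 = root
  std::vector<int> singles;     // members outside nuclear families
};

static PlanC parse_plan(const List& plan) {
  PlanC p;
  p.data_fam = as<int>(plan["data_fam"]) - 1;
  p.n = as<int>(plan["n"]);
  IntegerVector glrow = plan["glrow"];
  IntegerVector out_col = plan["out_col"];
  IntegerVector founder = plan["founder"];
  p.n_out = 0;
  for (int i = 0; i < p.n; ++i) {
    p.glrow.push_back(glrow[i] - 1);
    p.out_col.push_back(out_col[i] - 1);
    if (out_col[i] > p.n_out) p.n_out = out_col[i];
    p.founder.push_back(founder[i]);
  }
  List sched = plan["sched"];
  for (int k = 0; k < sched.size(); ++k) {
    IntegerVector v = sched[k];
    std::vector<int> s(v.size());
    for (int j = 0; j < v.size(); ++j) s[j] = v[j] - 1;
    p.sched.push_back(s);
  }
  IntegerVector singles = plan["singles"];
  for (int i = 0; i < singles.size(); ++i) p.singles.push_back(singles[i] - 1);
  return p;
}

// Member log-likelihoods are linearized once per configuration (each
// member's 3-vector scaled to max 1, log-scale accumulated) so that the
// many peels of a Brent search do not re-exponentiate fixed data.
struct LinLik {
  std::vector<double> lin; // 3*n, member-major, each member max-scaled
  double logscale;
};

static void linearize(const double* ll, int n, LinLik& out) {
  out.lin.resize(3 * n);
  out.logscale = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* li = ll + 3 * i;
    double m = std::max(li[0], std::max(li[1], li[2]));
    if (!std::isfinite(m)) m = 0.0;
    for (int g = 0; g < 3; ++g) out.lin[3 * i + g] = std::exp(li[g] - m);
    out.logscale += m;
  }
}

// Core peel.  lik: linearized member likelihoods (see above).
// T: 27 transmission probabilities T[c + 3*f + 9*m].
// clamp_i >= 0 restricts member clamp_i to genotype clamp_g.
static double peel_core(const LinLik& lik, const PlanC& plan, double p,
                        const double* T, int clamp_i, int clamp_g,
                        std::vector<double>& phi) {
  const int n = plan.n;
  double prior[3] = { (1 - p) * (1 - p), 2 * p * (1 - p), p * p };
  phi.resize(3 * n);
  double total = lik.logscale;
  for (int i = 0; i < n; ++i) {
    const double* li = &lik.lin[3 * i];
    double* f = &phi[3 * i];
    for (int g = 0; g < 3; ++g) {
      double v = li[g];
      if (plan.founder[i]) v *= prior[g];
      if (clamp_i == i && g != clamp_g) v = 0.0;
      f[g] = v;
    }
    double s = std::max(f[0], std::max(f[1], f[2]));
    if (s <= 0.0) return NEG_INF;
    f[0] /= s; f[1] /= s; f[2] /= s;
    total += std::log(s);
  }
  double K[16][9]; // per-child partial sums over (gf, gm)
  for (size_t k = 0; k < plan.sched.size(); ++k) {
    const std::vector<int>& fam = plan.sched[k];
    int conn = fam[0], fa = fam[1], mo = fam[2];
    int nk = (int)fam.size() - 3;
    if (nk > 16) Rcpp::stop("more than 16 children in one nuclear family");
    const double* pf = &phi[3 * fa];
    const double* pm = &phi[3 * mo];
    int conn_child = -1;
    bool conn_is_fa = (conn == fa), conn_is_mo = (conn == mo);
    for (int c = 0; c < nk; ++c) {
      if (fam[3 + c] == conn && !conn_is_fa && !conn_is_mo) conn_child = c;
      const double* pc = &phi[3 * fam[3 + c]];
      for (int gm = 0; gm < 3; ++gm)
        for (int gf = 0; gf < 3; ++gf) {
          const double* t = T + 3 * gf + 9 * gm;
          K[c][gf + 3 * gm] = t[0] * pc[0] + t[1] * pc[1] + t[2] * pc[2];
        }
    }
    if (conn < 0) { // root family: full sum contributes to the total
      double S = 0;
      for (int gm = 0; gm < 3; ++gm)
        for (int gf = 0; gf < 3; ++gf) {
          double v = pf[gf] * pm[gm];
          for (int c = 0; c < nk; ++c) v *= K[c][gf + 3 * gm];
          S += v;
        }
      if (S <= 0.0) return NEG_INF;
      total += std::log(S);
      continue;
    }
    double msg[3] = {0, 0, 0};
    if (conn_is_fa || conn_is_mo) {
      for (int gm = 0; gm < 3; ++gm)
        for (int gf = 0; gf < 3; ++gf) {
          double v = conn_is_fa ? pm[gm] : pf[gf];
          for (int c = 0; c < nk; ++c) v *= K[c][gf + 3 * gm];
          msg[conn_is_fa ? gf : gm] += v;
        }
    } else { // connector is a child of this family
      for (int gm = 0; gm < 3; ++gm)
        for (int gf = 0; gf < 3; ++gf) {
          double v = pf[gf] * pm[gm];
          for (int c = 0; c < nk; ++c)
            if (c != conn_child) v *= K[c][gf + 3 * gm];
          const double* t = T + 3 * gf + 9 * gm;
          for (int gc = 0; gc < 3; ++gc) msg[gc] += v * t[gc];
        }
    }
    double* pco = &phi[3 * conn];
    for (int g = 0; g < 3; ++g) pco[g] *= msg[g];
    double s = std::max(pco[0], std::max(pco[1], pco[2]));
    if (s <= 0.0) return NEG_INF;
    pco[0] /= s; pco[1] /= s; pco[2] /= s;
    total += std::log(s);
  }
  for (size_t k = 0; k < plan.singles.size(); ++k) {
    const double* f = &phi[3 * plan.singles[k]];
    double S = f[0] + f[1] + f[2];
    if (S <= 0.0) return NEG_INF;
    total += std::log(S);
  }
  return total;
}

// [[Rcpp::export]]
double cpp_peel_loglik(NumericMatrix ll, List plan, double freq,
                       NumericVector cube) {
  PlanC p = parse_plan(plan);
  if (ll.nrow() != 3 || ll.ncol() != p.n)
    stop("ll must be a 3 x n_members matrix");
  std::vector<double> llv(3 * p.n), phi;
  for (int i = 0; i < p.n; ++i)
    for (int g = 0; g < 3; ++g) llv[3 * i + g] = ll(g, i);
  LinLik lik;
  linearize(llv.data(), p.n, lik);
  return peel_core(lik, p, freq, REAL(cube), -1, -1, phi);
}

// [[Rcpp::export]]
NumericMatrix cpp_peel_posteriors(NumericMatrix ll, List plan, double freq,
                                  NumericVector cube) {
  PlanC p = parse_plan(plan);
  std::vector<double> llv(3 * p.n), phi;
  for (int i = 0; i < p.n; ++i)
    for (int g = 0; g < 3; ++g) llv[3 * i + g] = ll(g, i);
  LinLik lik;
  linearize(llv.data(), p.n, lik);
  double L = peel_core(lik, p, freq, REAL(cube), -1, -1, phi);
  NumericMatrix post(3, p.n);
  for (int i = 0; i < p.n; ++i) {
    double tot = 0;
    double v[3];
    for (int g = 0; g < 3; ++g) {
      double Lg = peel_core(lik, p, freq, REAL(cube), i, g, phi);
      v[g] = std::isfinite(Lg) ? std::exp(Lg - L) : 0.0;
      tot += v[g];
    }
    for (int g = 0; g < 3; ++g) post(g, i) = tot > 0 ? v[g] / tot : 1.0 / 3;
  }
  return post;
}

// ---- Brent maximization on [a, b] ---------------------------------------

template <class F>
static double brent_max(F f, double a, double b, double tol, double* fmax) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = tol + 1e-12 * std::fabs(x);
    if (std::fabs(x - m) <= 2 * tol1 - 0.5 * (b - a)) break;
    double p = 0, q = 0, r = 0;
    bool use_para = false;
    if (std::fabs(e) > tol1) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2 * (q - r);
      if (q > 0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        use_para = true;
        d = p / q;
        double u = x + d;
        if (u - a < 2 * tol1 || b - u < 2 * tol1)
          d = (m > x) ? tol1 : -tol1;
      }
    }
    if (!use_para) {
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + (d > 0 ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fmax = fx;
  return x;
}

// profile likelihood over the alt allele frequency, summed over units
struct FreqObjective {
  const std::vector<const LinLik*>& lls;
  const std::vector<const PlanC*>& plans;
  const double* T;
  std::vector<double>* phi;
  double operator()(double p) const {
    double tot = 0;
    for (size_t f = 0; f < plans.size(); ++f) {
      double v = peel_core(*lls[f], *plans[f], p, T, -1, -1, *phi);
      if (!std::isfinite(v)) return NEG_INF;
      tot += v;
    }
    return tot;
  }
};

static const double FREQ_LO = 1e-8, FREQ_HI = 1.0 - 1e-8;

// coarse scan then Brent refinement; configurations whose coarse maximum is
// already > 50 nats below the best score are not refined (their posterior
// mass is < 2e-22 regardless)
static double maximize_freq(const FreqObjective& obj, double tol,
                            double* fmax, double skip_below) {
  static const double grid[7] = {FREQ_LO, 0.05, 0.25, 0.5, 0.75, 0.95,
                                 FREQ_HI};
  double best = NEG_INF;
  int ib = 0;
  for (int i = 0; i < 7; ++i) {
    double v = obj(grid[i]);
    if (v > best) { best = v; ib = i; }
  }
  if (best < skip_below) {
    *fmax = best;
    return grid[ib];
  }
  double a = grid[ib == 0 ? 0 : ib - 1];
  double b = grid[ib == 6 ? 6 : ib + 1];
  double fx;
  double x = brent_max(obj, a, b, tol, &fx);
  if (fx < best) { fx = best; x = grid[ib]; }
  *fmax = fx;
  return x;
}

// [[Rcpp::export]]
List cpp_estimate_freq(List lls, List plans, NumericVector cube,
                       double tol) {
  int F = plans.size();
  std::vector<PlanC> pl(F);
  std::vector<const PlanC*> plp(F);
  std::vector<LinLik> llv(F);
  std::vector<const LinLik*> llp(F);
  for (int f = 0; f < F; ++f) {
    pl[f] = parse_plan(plans[f]);
    plp[f] = &pl[f];
    NumericMatrix m = lls[f];
    std::vector<double> tmp(3 * pl[f].n);
    for (int i = 0; i < pl[f].n; ++i)
      for (int g = 0; g < 3; ++g) tmp[3 * i + g] = m(g, i);
    linearize(tmp.data(), pl[f].n, llv[f]);
    llp[f] = &llv[f];
  }
  std::vector<double> phi;
  FreqObjective obj{llp, plp, REAL(cube), &phi};
  double fmax;
  double p = maximize_freq(obj, tol, &fmax, NEG_INF);
  return List::create(_["alt_freq"] = p, _["max_loglik"] = fmax);
}

// ---- dataset driver -----------------------------------------------------

// canonical 10-genotype pair table (0-based allele indices)
static const int GT10_A[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
static const int GT10_B[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};

static int gt10_index(int a, int b) { // 0-based alleles -> 0-based index
  int lo = a < b ? a : b, hi = a < b ? b : a;
  static const int off[4] = {0, 4, 7, 9};
  return off[lo] + (hi - lo);
}

// log emission matrix logE[b][g] at constant error e
static void log_emission(double e, double logE[4][10]) {
  if (e < 1e-10) e = 1e-10;
  for (int g = 0; g < 10; ++g) {
    int a1 = GT10_A[g], a2 = GT10_B[g];
    for (int b = 0; b < 4; ++b) {
      double p1 = (b == a1) ? 1 - e : e / 3;
      double p2 = (b == a2) ? 1 - e : e / 3;
      logE[b][g] = std::log(0.5 * p1 + 0.5 * p2);
    }
  }
}

// transmission cube for allele pair (a1, a2) under a 4x4 column-major
// mutation matrix M (identity when M is null); layout T[c + 3*f + 9*m]
static void build_cube(const double* M, int a1, int a2, double* T) {
  double m11 = M ? M[a1 + 4 * a1] : 1.0;
  double m12 = M ? M[a1 + 4 * a2] : 0.0;
  double m21 = M ? M[a2 + 4 * a1] : 0.0;
  double m22 = M ? M[a2 + 4 * a2] : 1.0;
  double t[3][2];
  t[0][0] = m11; t[0][1] = m12;
  t[1][0] = 0.5 * (m11 + m21); t[1][1] = 0.5 * (m12 + m22);
  t[2][0] = m21; t[2][1] = m22;
  for (int f = 0; f < 3; ++f)
    for (int m = 0; m < 3; ++m) {
      T[0 + 3 * f + 9 * m] = t[f][0] * t[m][0];
      T[1 + 3 * f + 9 * m] = t[f][0] * t[m][1] + t[f][1] * t[m][0];
      T[2 + 3 * f + 9 * m] = t[f][1] * t[m][1];
    }
}

// [[Rcpp::export]]
List cpp_call_dataset(List data, bool is_gl, double eps, IntegerVector ref,
                      List plans, int n_founders, double theta,
                      Nullable<NumericMatrix> mutmat, double emit_threshold,
                      double p_double_factor, bool compute_denovo,
                      bool keep_pl, double freq_tol) {
  const int S = ref.size();
  const int F = plans.size();
  std::vector<PlanC> pl(F);
  std::vector<const PlanC*> plp(F);
  for (int f = 0; f < F; ++f) {
    pl[f] = parse_plan(plans[f]);
    plp[f] = &pl[f];
  }
  const int D = data.size();
  std::vector<const int*> cnts(D, nullptr);
  std::vector<const double*> gld(D, nullptr);
  std::vector<int> dn(D);
  for (int d = 0; d < D; ++d) {
    SEXP a = data[d];
    IntegerVector dim = Rf_getAttrib(a, R_DimSymbol);
    if (is_gl) {
      if (dim.size() != 3 || dim[0] != S || dim[2] != 10)
        stop("GL data block %d must have dim (n_sites, n, 10)", d + 1);
      gld[d] = REAL(a);
    } else {
      if (dim.size() != 3 || dim[0] != S || dim[2] != 4)
        stop("count data block %d must have dim (n_sites, n, 4)", d + 1);
      cnts[d] = INTEGER(a);
    }
    dn[d] = dim[1];
  }
  double logE[4][10];
  log_emission(eps, logE);
  NumericMatrix Mkeep;
  const double* M = nullptr;
  if (mutmat.isNotNull()) {
    Mkeep = NumericMatrix(mutmat.get());
    M = REAL(Mkeep);
  }

  // coalescent site prior: theta * sum_{i=1}^{2N-1} 1/i
  if (n_founders < 1) stop("need at least one founder");
  double H = 0;
  for (int i = 1; i <= 2 * n_founders - 1; ++i) H += 1.0 / i;
  double p_var = theta * H;
  if (p_var > 0.99) p_var = 0.99;
  const bool purine[4] = {true, false, true, false};

  std::vector<std::vector<double>> ll10(F), ll3(F);
  std::vector<LinLik> lin(F);
  std::vector<const LinLik*> llp(F);
  for (int f = 0; f < F; ++f) {
    ll10[f].resize(10 * pl[f].n);
    ll3[f].resize(3 * pl[f].n);
    llp[f] = &lin[f];
  }
  std::vector<double> phi;

  IntegerVector out_a1(S), out_a2(S);
  LogicalVector out_emit(S);
  NumericVector out_qual(S), out_freq(S), out_pvar(S);
  List out_gt(F), out_gq(F), out_ds(F), out_dp(F), out_pl(F), out_lr(F);
  std::vector<int*> gt_p(F), dp_p(F, nullptr), plv_p(F, nullptr);
  std::vector<double*> gq_p(F), ds_p(F), lr_p(F, nullptr);
  for (int f = 0; f < F; ++f) {
    int no = pl[f].n_out;
    IntegerMatrix gt(S, no);
    std::fill(gt.begin(), gt.end(), NA_INTEGER);
    NumericMatrix gq(S, no), ds(S, no);
    std::fill(gq.begin(), gq.end(), NA_REAL);
    std::fill(ds.begin(), ds.end(), NA_REAL);
    out_gt[f] = gt; out_gq[f] = gq; out_ds[f] = ds;
    gt_p[f] = INTEGER(out_gt[f]); gq_p[f] = REAL(out_gq[f]);
    ds_p[f] = REAL(out_ds[f]);
    if (!is_gl) {
      IntegerMatrix dp(S, no);
      out_dp[f] = dp;
      dp_p[f] = INTEGER(out_dp[f]);
    }
    if (compute_denovo) {
      NumericVector lr(S, NA_REAL);
      out_lr[f] = lr;
      lr_p[f] = REAL(out_lr[f]);
    }
    if (keep_pl) {
      IntegerVector plv(S * no * 3, NA_INTEGER);
      plv.attr("dim") = IntegerVector::create(S, no, 3);
      out_pl[f] = plv;
      plv_p[f] = INTEGER(out_pl[f]);
    }
  }

  std::vector<double> cube(27), cube_mendel(27);
  for (int s = 0; s < S; ++s) {
    int r = ref[s] - 1;
    if (r < 0 || r > 3) stop("ref allele out of range at site %d", s + 1);
    for (int f = 0; f < F; ++f) {
      const PlanC& P = pl[f];
      const int ncol = dn[P.data_fam];
      for (int i = 0; i < P.n; ++i) {
        int col = P.glrow[i];
        double* o = &ll10[f][10 * i];
        if (col < 0) { // unsequenced / absent member: flat likelihoods
          for (int g = 0; g < 10; ++g) o[g] = 0.0;
          if (dp_p[f] && P.out_col[i] >= 0)
            dp_p[f][s + (size_t)S * P.out_col[i]] = 0;
          continue;
        }
        if (is_gl) {
          const double* src = gld[P.data_fam] + s + (size_t)S * col;
          for (int g = 0; g < 10; ++g)
            o[g] = src[(size_t)S * ncol * g];
        } else {
          const int* c4 = cnts[P.data_fam];
          int c[4];
          for (int b = 0; b < 4; ++b)
            c[b] = c4[s + (size_t)S * (col + (size_t)ncol * b)];
          if (dp_p[f] && P.out_col[i] >= 0)
            dp_p[f][s + (size_t)S * P.out_col[i]] = c[0] + c[1] + c[2] + c[3];
          for (int g = 0; g < 10; ++g) {
            double v = 0;
            for (int b = 0; b < 4; ++b)
              if (c[b]) v += c[b] * logE[b][g];
            o[g] = v;
          }
        }
      }
    }
    // candidate configurations: 0 = monomorphic reference, 1 = transition,
    // 2..3 = transversions from ref, 4..6 = pairs excluding the reference
    int alts[3], k = 0;
    for (int a = 0; a < 4; ++a) if (a != r) alts[k++] = a;
    for (int i = 1; i < 3; ++i)
      if (purine[alts[i]] == purine[r]) std::swap(alts[0], alts[i]);
    int pair1[6], pair2[6];
    double logprior[7];
    logprior[0] = std::log(1 - p_var);
    for (int i = 0; i < 3; ++i) {
      pair1[i] = r; pair2[i] = alts[i];
      logprior[1 + i] = std::log(p_var * (i == 0 ? 2.0 / 3 : 1.0 / 6));
    }
    int m2 = 0;
    for (int i = 0; i < 3; ++i)
      for (int j = i + 1; j < 3; ++j) {
        pair1[3 + m2] = alts[i]; pair2[3 + m2] = alts[j];
        logprior[4 + m2] = std::log(p_var * p_double_factor / 3);
        ++m2;
      }
    double cfg_ll[7], cfg_freq[7];
    int rr = gt10_index(r, r);
    double llmono = 0;
    for (int f = 0; f < F; ++f)
      for (int i = 0; i < pl[f].n; ++i) llmono += ll10[f][10 * i + rr];
    cfg_ll[0] = llmono;
    cfg_freq[0] = 0;
    double best_score = llmono + logprior[0];
    for (int cfg = 1; cfg < 7; ++cfg) {
      int a1 = pair1[cfg - 1], a2 = pair2[cfg - 1];
      int i00 = gt10_index(a1, a1), i01 = gt10_index(a1, a2),
          i11 = gt10_index(a2, a2);
      for (int f = 0; f < F; ++f) {
        const PlanC& P = pl[f];
        for (int i = 0; i < P.n; ++i) {
          const double* o = &ll10[f][10 * i];
          double* o3 = &ll3[f][3 * i];
          o3[0] = o[i00]; o3[1] = o[i01]; o3[2] = o[i11];
        }
        linearize(ll3[f].data(), P.n, lin[f]);
      }
      build_cube(M, a1, a2, cube.data());
      FreqObjective obj{llp, plp, cube.data(), &phi};
      double fmax;
      double ph = maximize_freq(obj, freq_tol, &fmax,
                                best_score - logprior[cfg] - 50.0);
      cfg_ll[cfg] = fmax;
      cfg_freq[cfg] = ph;
      if (fmax + logprior[cfg] > best_score)
        best_score = fmax + logprior[cfg];
    }
    double mx = NEG_INF, Z = 0;
    for (int cfg = 0; cfg < 7; ++cfg) {
      double sc = cfg_ll[cfg] + logprior[cfg];
      if (sc > mx) mx = sc;
    }
    double post[7];
    for (int cfg = 0; cfg < 7; ++cfg) {
      post[cfg] = std::exp(cfg_ll[cfg] + logprior[cfg] - mx);
      Z += post[cfg];
    }
    for (int cfg = 0; cfg < 7; ++cfg) post[cfg] /= Z;
    int best_cfg = 1;
    for (int cfg = 2; cfg < 7; ++cfg)
      if (post[cfg] > post[best_cfg]) best_cfg = cfg;
    double p_variant = 1 - post[0];
    double pmono = post[0] < 1e-300 ? 1e-300 : post[0];
    out_qual[s] = -10 * std::log10(pmono);
    out_pvar[s] = p_variant;
    out_a1[s] = pair1[best_cfg - 1] + 1;
    out_a2[s] = pair2[best_cfg - 1] + 1;
    out_freq[s] = cfg_freq[best_cfg];
    bool emit = p_variant >= emit_threshold;
    out_emit[s] = emit;
    if (!emit) continue;

    // genotype calls and de novo LR under the winning configuration
    int a1 = pair1[best_cfg - 1], a2 = pair2[best_cfg - 1];
    int i00 = gt10_index(a1, a1), i01 = gt10_index(a1, a2),
        i11 = gt10_index(a2, a2);
    double ph = cfg_freq[best_cfg];
    build_cube(M, a1, a2, cube.data());
    if (compute_denovo) build_cube(nullptr, a1, a2, cube_mendel.data());
    for (int f = 0; f < F; ++f) {
      const PlanC& P = pl[f];
      for (int i = 0; i < P.n; ++i) {
        const double* o = &ll10[f][10 * i];
        double* o3 = &ll3[f][3 * i];
        o3[0] = o[i00]; o3[1] = o[i01]; o3[2] = o[i11];
      }
      linearize(ll3[f].data(), P.n, lin[f]);
      double L = peel_core(lin[f], P, ph, cube.data(), -1, -1, phi);
      for (int i = 0; i < P.n; ++i) {
        int oc = P.out_col[i];
        if (oc < 0) continue; // loop-breaking clones are not reported
        double v[3], tot = 0;
        for (int g = 0; g < 3; ++g) {
          double Lg = peel_core(lin[f], P, ph, cube.data(), i, g,
                                phi);
          v[g] = std::isfinite(Lg) ? std::exp(Lg - L) : 0;
          tot += v[g];
        }
        int modal = 0;
        double pmax = -1;
        for (int g = 0; g < 3; ++g) {
          v[g] = tot > 0 ? v[g] / tot : 1.0 / 3;
          if (v[g] > pmax) { pmax = v[g]; modal = g; } // ties -> fewer alts
        }
        gt_p[f][s + (size_t)S * oc] = modal;
        double err = 1 - pmax;
        double gq = err < 1.26e-10 ? 99.0 : -10 * std::log10(err);
        if (gq > 99) gq = 99;
        gq_p[f][s + (size_t)S * oc] = gq;
        ds_p[f][s + (size_t)S * oc] = v[1] + 2 * v[2];
        if (plv_p[f]) {
          const double* o = &ll10[f][10 * i];
          double l[3] = {o[i00], o[i01], o[i11]};
          double mxl = std::max(l[0], std::max(l[1], l[2]));
          for (int g = 0; g < 3; ++g)
            plv_p[f][s + (size_t)S * (oc + (size_t)P.n_out * g)] =
              (int)std::lround(-10 * (l[g] - mxl) / std::log(10));
        }
      }
      if (compute_denovo) {
        double Ld = peel_core(lin[f], P, ph, cube.data(), -1, -1, phi);
        double Lm = peel_core(lin[f], P, ph, cube_mendel.data(), -1, -1,
                              phi);
        lr_p[f][s] = Ld - Lm; // natural-log likelihood ratio
      }
    }
  }
  return List::create(
    _["a1"] = out_a1, _["a2"] = out_a2, _["emitted"] = out_emit,
    _["qual"] = out_qual, _["alt_freq"] = out_freq,
    _["post_variant"] = out_pvar, _["gt"] = out_gt, _["gq"] = out_gq,
    _["ds"] = out_ds, _["dp"] = out_dp, _["pl"] = out_pl,
    _["log_lr"] = out_lr);
}
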