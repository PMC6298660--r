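#include <Rcpp.h>
using namespace Rcpp;

// Effect statistics operate on a directed binary adjacency matrix x (diagonal
// zero), a centered behavior vector z (one value per actor, category code minus
// the centering constant) and a matrix of centered/static actor covariates.
//
// Network effect codes:
//   1 outdegree            2 reciprocity
//   3 transitive triplets  4 transitive reciprocated triplets
//   5 outdegree activity   6 indegree activity
//   7 alter  8 alter sq  9 ego  10 ego sq  11 ego x alter  12 same
// Covariate index per effect: 0 = the (dynamic) centered behavior, k >= 1 =
// column k of the covariate matrix, -1 = none.
//
// Behavior effect codes: 1 linear, 2 quadratic, 3 average similarity.

static inline double covval(int j, int ci, const NumericVector& z,
                            const NumericMatrix& covs) {
  if (ci == 0) return z[j];
  return covs(j, ci - 1);
}

// Change in actor i's network statistics when the tie i -> j is toggled.
// Returns an n x p matrix; row j holds the deltas for toggling i -> j, row i
// (the keep-current alternative) is zero.
// [[Rcpp::export]]
NumericMatrix net_change_stats_cpp(const IntegerMatrix& x,
                                   const NumericVector& z,
                                   const NumericMatrix& covs,
                                   const IntegerVector& code,
                                   const IntegerVector& covi,
                                   int i1) {
  const int n = x.nrow();
  const int p = code.size();
  const int i = i1 - 1;
  NumericMatrix out(n, p);

  int outdeg = 0, indeg = 0;
  std::vector<int> nbr;  // out-neighborhood of i
  for (int j = 0; j < n; ++j) {
    if (x(i, j)) { ++outdeg; nbr.push_back(j); }
    indeg += x(j, i);
  }

  // two-path bookkeeping shared by the transitivity effects, accumulated
  // over the (sparse) out-neighborhood:
  //   t1[j] = #\{h: i->h->j\},  t2[j] = #\{h: i->h, j->h\},
  //   t3[j] = #\{h: i->h, h->i, j->h\}
  bool needTrans = false;
  for (int k = 0; k < p; ++k)
    if (code[k] == 3 || code[k] == 4) needTrans = true;
  std::vector<double> t1(n, 0.0), t2(n, 0.0), t3(n, 0.0);
  if (needTrans) {
    for (int hi = 0; hi < (int)nbr.size(); ++hi) {
      const int h = nbr[hi];
      const bool mutual = x(h, i) != 0;
      for (int j = 0; j < n; ++j) {
        t1[j] += x(h, j);
        t2[j] += x(j, h);
        if (mutual) t3[j] += x(j, h);
      }
    }
  }

  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    const double d = 1.0 - 2.0 * x(i, j);
    for (int k = 0; k < p; ++k) {
      double val = 0.0;
      switch (code[k]) {
      case 1: val = d; break;
      case 2: val = d * x(j, i); break;
      case 3:
        // i->j closes two-paths i->h->j; toggling also affects triplets where
        // i->j is the i->h leg of (i->m, i->j, j->m).
        val = d * (t1[j] + t2[j]);
        break;
      case 4:
        val = d * (x(j, i) * t1[j] + t3[j]);
        break;
      case 5: val = 2.0 * d * outdeg + 1.0; break;
      case 6: val = d * indeg; break;
      case 7: val = d * covval(j, covi[k], z, covs); break;
      case 8: {
        double v = covval(j, covi[k], z, covs);
        val = d * v * v;
        break;
      }
      case 9: val = d * covval(i, covi[k], z, covs); break;
      case 10: {
        double v = covval(i, covi[k], z, covs);
        val = d * v * v;
        break;
      }
      case 11:
        val = d * covval(i, covi[k], z, covs) * covval(j, covi[k], z, covs);
        break;
      case 12:
        val = d * (covval(i, covi[k], z, covs) == covval(j, covi[k], z, covs)
                     ? 1.0 : 0.0);
        break;
      default: stop("unknown network effect code");
      }
      out(j, k) = val;
    }
  }
  return out;
}

static inline double avsim_at(const IntegerMatrix& x, const NumericVector& z,
                              int i, double zi, double range, double simC) {
  int outdeg = 0;
  double s = 0.0;
  const int n = x.nrow();
  for (int j = 0; j < n; ++j) {
    if (x(i, j)) {
      ++outdeg;
      s += 1.0 - std::abs(zi - z[j]) / range - simC;
    }
  }
  if (outdeg == 0) return 0.0;
  return s / outdeg;
}

// Change in actor i's behavior statistics for each candidate step in `deltas`.
// Returns length(deltas) x p.
// [[Rcpp::export]]
NumericMatrix beh_change_stats_cpp(const IntegerMatrix& x,
                                   const NumericVector& z,
                                   const IntegerVector& code,
                                   int i1,
                                   const NumericVector& deltas,
                                   double range, double simC) {
  const int p = code.size();
  const int i = i1 - 1;
  NumericMatrix out(deltas.size(), p);
  const double zi = z[i];
  for (int r = 0; r < deltas.size(); ++r) {
    const double d = deltas[r];
    for (int k = 0; k < p; ++k) {
      double val = 0.0;
      switch (code[k]) {
      case 1: val = d; break;
      case 2: val = (zi + d) * (zi + d) - zi * zi; break;
      case 3:
        if (d != 0.0)
          val = avsim_at(x, z, i, zi + d, range, simC) -
                avsim_at(x, z, i, zi, range, simC);
        break;
      default: stop("unknown behavior effect code");
      }
      out(r, k) = val;
    }
  }
  return out;
}

// One observation period of the continuous-time ministep process on [0, 1).
// Exponential waiting times at total intensity n_active * (lamN + lamB); at
// each event one active actor is drawn uniformly, the function proportional to
// (lamN, lamB), and a multinomial-logit choice is made among single-tie
// toggles (plus keep-current) or feasible single-category behavior steps.
// Optionally accumulates the per-coefficient score (grad log choice prob) used
// by the likelihood-ratio derivative estimator.
// [[Rcpp::export]]
List simulate_period_cpp(const IntegerMatrix& x0,
                         const NumericVector& z0,
                         const LogicalVector& active,
                         double lamN, double lamB,
                         const IntegerVector& netCode,
                         const IntegerVector& netCovi,
                         const NumericVector& thetaN,
                         const IntegerVector& behCode,
                         const NumericVector& thetaB,
                         const NumericMatrix& covs,
                         double zLo, double zHi,
                         double range, double simC,
                         bool getScores) {
  const int n = x0.nrow();
  IntegerMatrix x = clone(x0);
  NumericVector z = clone(z0);
  const int pN = netCode.size();
  const int pB = behCode.size();
  NumericVector scoreN(pN), scoreB(pB);
  int cntN = 0, cntB = 0;

  std::vector<int> act;
  for (int i = 0; i < n; ++i) if (active[i]) act.push_back(i);
  const int nAct = act.size();
  if (nAct == 0) stop("no active actors in period");

  const double tot = nAct * (lamN + lamB);
  if (tot > 0.0) {
    double t = 0.0;
    for (;;) {
      t += R::exp_rand() / tot;
      if (t >= 1.0) break;
      const int i = act[(int)(R::unif_rand() * nAct) % nAct];
      const bool isNet = R::unif_rand() < lamN / (lamN + lamB);
      if (isNet) {
        ++cntN;
        NumericMatrix M = net_change_stats_cpp(x, z, covs, netCode, netCovi,
                                               i + 1);
        NumericVector u(n);
        double umax = 0.0;  // row i has utility 0
        for (int j = 0; j < n; ++j) {
          double uj = 0.0;
          for (int k = 0; k < pN; ++k) uj += M(j, k) * thetaN[k];
          u[j] = uj;
          if (uj > umax) umax = uj;
        }
        double Z = 0.0;
        for (int j = 0; j < n; ++j) { u[j] = std::exp(u[j] - umax); Z += u[j]; }
        double r = R::unif_rand() * Z, c = 0.0;
        int jsel = n - 1;
        for (int j = 0; j < n; ++j) { c += u[j]; if (r <= c) { jsel = j; break; } }
        if (getScores) {
          for (int k = 0; k < pN; ++k) {
            double e = 0.0;
            for (int j = 0; j < n; ++j) e += (u[j] / Z) * M(j, k);
            scoreN[k] += M(jsel, k) - e;
          }
        }
        if (jsel != i) x(i, jsel) = 1 - x(i, jsel);
      } else {
        ++cntB;
        std::vector<double> ds;
        ds.push_back(0.0);
        if (z[i] - 1.0 >= zLo - 1e-9) ds.push_back(-1.0);
        if (z[i] + 1.0 <= zHi + 1e-9) ds.push_back(1.0);
        NumericVector dv(ds.begin(), ds.end());
        NumericMatrix M = beh_change_stats_cpp(x, z, behCode, i + 1, dv,
                                               range, simC);
        const int na = dv.size();
        NumericVector u(na);
        double umax = R_NegInf;
        for (int a = 0; a < na; ++a) {
          double ua = 0.0;
          for (int k = 0; k < pB; ++k) ua += M(a, k) * thetaB[k];
          u[a] = ua;
          if (ua > umax) umax = ua;
        }
        double Z = 0.0;
        for (int a = 0; a < na; ++a) { u[a] = std::exp(u[a] - umax); Z += u[a]; }
        double r = R::unif_rand() * Z, c = 0.0;
        int asel = na - 1;
        for (int a = 0; a < na; ++a) { c += u[a]; if (r <= c) { asel = a; break; } }
        if (getScores) {
          for (int k = 0; k < pB; ++k) {
            double e = 0.0;
            for (int a = 0; a < na; ++a) e += (u[a] / Z) * M(a, k);
            scoreB[k] += M(asel, k) - e;
          }
        }
        z[i] += dv[asel];
      }
    }
  }

  return List::create(_["x"] = x, _["z"] = z,
                      _["n_net_steps"] = cntN, _["n_beh_steps"] = cntB,
                      _["score_net"] = scoreN, _["score_beh"] = scoreB,
                      _["n_active"] = nAct);
}
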