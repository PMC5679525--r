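// Adaptive rejection Metropolis sampling (ARMS) within Gibbs for the
// Bayesian Poisson GAM.  The univariate full conditionals of a Poisson
// log-linear model are log-concave under flat/normal/linearized-Jeffreys
// priors, so the rejection envelope built from secants dominates the
// target and the Metropolis-Hastings correction step is a no-op in exact
// arithmetic; it is still always applied, which keeps the kernel valid
// for any target.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_BIG = -1e300;

struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t seed) : g(seed) {}
  double unif() {
    // 53-bit uniform in (0, 1)
    double u = (g() >> 11) * (1.0 / 9007199254740992.0);
    return u > 0 ? u : 5e-324;
  }
};

// ---------------------------------------------------------------------------
// Piecewise-linear upper hull on log scale
// ---------------------------------------------------------------------------

struct Hull {
  std::vector<double> x, h;   // abscissae (sorted) and log-density values
  double lo, hi;              // support
  // linear envelope segments (per interval, one-sided at abscissae)
  struct Seg { double a, b, ya, yb; };
  std::vector<Seg> segs;

  static double line(double x0, double y0, double x1, double y1, double x) {
    return y0 + (y1 - y0) * (x - x0) / (x1 - x0);
  }

  // envelope restricted to interval i (0..k between virtual endpoints
  // lo, x_0, ..., x_{k-1}, hi), evaluated by that interval's formula:
  //   boundary intervals: extended secant of the two nearest abscissae;
  //   interior [x_{i-1}, x_i]: max(chord, min(extended side secants)).
  double env_interval(size_t i, double xs) const {
    size_t k = x.size();
    if (i == 0) return line(x[0], h[0], x[1], h[1], xs);
    if (i == k) return line(x[k - 2], h[k - 2], x[k - 1], h[k - 1], xs);
    size_t a = i - 1, b = i;
    double chord = line(x[a], h[a], x[b], h[b], xs);
    double ml = (a >= 1) ? line(x[a - 1], h[a - 1], x[a], h[a], xs) : INFINITY;
    double mr = (b + 1 < k) ? line(x[b], h[b], x[b + 1], h[b + 1], xs) : INFINITY;
    double m = std::min(ml, mr);
    if (!std::isfinite(m)) return chord;
    return std::max(chord, m);
  }

  double env_at(double xs) const {
    size_t k = x.size();
    size_t i = std::upper_bound(x.begin(), x.end(), xs) - x.begin();
    if (i >= k && xs <= x[k - 1]) i = k - 1;
    return env_interval(i, xs);
  }

  // intersection of two lines, pushed if strictly inside (a, b)
  static void add_cross(double ax0, double ay0, double ax1, double ay1,
                        double bx0, double by0, double bx1, double by1,
                        double a, double b, std::vector<double>& out) {
    double s1 = (ay1 - ay0) / (ax1 - ax0);
    double s2 = (by1 - by0) / (bx1 - bx0);
    if (s1 == s2) return;
    double c1 = ay0 - s1 * ax0, c2 = by0 - s2 * bx0;
    double z = (c2 - c1) / (s1 - s2);
    if (z > a && z < b) out.push_back(z);
  }

  void rebuild() {
    size_t k = x.size();
    segs.clear();
    for (size_t i = 0; i <= k; ++i) {
      double a = (i == 0) ? lo : x[i - 1];
      double b = (i == k) ? hi : x[i];
      if (b <= a) continue;
      std::vector<double> nodes{a, b};
      if (i >= 1 && i <= k - 1) {
        size_t ia = i - 1, ib = i;
        bool hasL = (ia >= 1), hasR = (ib + 1 < k);
        if (hasL && hasR)
          add_cross(x[ia - 1], h[ia - 1], x[ia], h[ia],
                    x[ib], h[ib], x[ib + 1], h[ib + 1], a, b, nodes);
        if (hasL)
          add_cross(x[ia - 1], h[ia - 1], x[ia], h[ia],
                    x[ia], h[ia], x[ib], h[ib], a, b, nodes);
        if (hasR)
          add_cross(x[ib], h[ib], x[ib + 1], h[ib + 1],
                    x[ia], h[ia], x[ib], h[ib], a, b, nodes);
      }
      std::sort(nodes.begin(), nodes.end());
      nodes.erase(std::unique(nodes.begin(), nodes.end()), nodes.end());
      for (size_t s = 0; s + 1 < nodes.size(); ++s) {
        Seg sg;
        sg.a = nodes[s];
        sg.b = nodes[s + 1];
        sg.ya = env_interval(i, sg.a);
        sg.yb = env_interval(i, sg.b);
        segs.push_back(sg);
      }
    }
  }

  // log of integral of exp(linear) over one segment
  static double seg_logmass(double a, double b, double ya, double yb) {
    if (b <= a) return NEG_BIG;
    double d = yb - ya;
    double w = b - a;
    if (std::fabs(d) < 1e-10) {
      double ym = 0.5 * (ya + yb);
      return ym > NEG_BIG / 2 ? ym + std::log(w) : NEG_BIG;
    }
    double m = d / w;
    if (d > 0) {
      // yb + log((1 - e^{-d}) / m)
      return yb + std::log(-std::expm1(-d)) - std::log(m);
    }
    return ya + std::log(-std::expm1(d)) - std::log(-m);
  }

  // sample x from density proportional to exp(envelope); env_out gets
  // the envelope value at the sampled point (consistent by construction
  // with the density the point was drawn from)
  double sample(Rng& rng, double& env_out) const {
    size_t ns = segs.size();
    std::vector<double> lm(ns);
    double mx = NEG_BIG;
    for (size_t s = 0; s < ns; ++s) {
      lm[s] = seg_logmass(segs[s].a, segs[s].b, segs[s].ya, segs[s].yb);
      if (lm[s] > mx) mx = lm[s];
    }
    if (mx <= NEG_BIG / 2) stop("ARMS envelope has zero mass");
    double tot = 0;
    std::vector<double> w(ns);
    for (size_t s = 0; s < ns; ++s) {
      w[s] = std::exp(lm[s] - mx);
      tot += w[s];
    }
    double u = rng.unif() * tot;
    size_t s = 0;
    for (; s + 1 < ns; ++s) {
      if (u <= w[s]) break;
      u -= w[s];
    }
    double a = segs[s].a, b = segs[s].b, ya = segs[s].ya, yb = segs[s].yb;
    double d = yb - ya, wd = b - a, v = rng.unif();
    double xs;
    if (std::fabs(d) < 1e-10) {
      xs = a + v * wd;
    } else {
      double m = d / wd;
      if (d > 0) xs = b + std::log(v + (1.0 - v) * std::exp(-d)) / m;
      else xs = a + std::log1p(v * std::expm1(d)) / m;
    }
    if (xs < a) xs = a;
    if (xs > b) xs = b;
    env_out = line(a, ya, b, yb, xs);
    return xs;
  }

  void insert(double xs, double hs, size_t max_points) {
    if (x.size() >= max_points) return;
    size_t i = std::lower_bound(x.begin(), x.end(), xs) - x.begin();
    if (i < x.size() && x[i] == xs) return;
    x.insert(x.begin() + i, xs);
    h.insert(h.begin() + i, hs);
  }
};

// One ARMS transition: from current point xcur with log density hcur,
// return the next state (and its log density via hcur_out).
template <typename F>
static double arms_step(F&& logf, double xcur, double hcur,
                        const std::vector<double>& init, double lo, double hi,
                        Rng& rng, double& hcur_out, int max_reject = 500,
                        size_t max_points = 64) {
  Hull hull;
  hull.lo = lo;
  hull.hi = hi;
  for (double xi : init) {
    if (xi <= lo || xi >= hi) continue;
    hull.x.push_back(xi);
  }
  std::sort(hull.x.begin(), hull.x.end());
  hull.x.erase(std::unique(hull.x.begin(), hull.x.end()), hull.x.end());
  if (hull.x.size() < 3) stop("ARMS needs at least 3 distinct abscissae inside the support");
  hull.h.resize(hull.x.size());
  bool any_finite = false;
  for (size_t i = 0; i < hull.x.size(); ++i) {
    hull.h[i] = logf(hull.x[i]);
    if (hull.h[i] > NEG_BIG / 2) any_finite = true;
  }
  if (!any_finite) stop("ARMS: log density is -Inf at all initial abscissae");

  for (int it = 0; it < max_reject; ++it) {
    hull.rebuild();
    double hu;
    double xs = hull.sample(rng, hu);
    double hx = logf(xs);
    if (std::log(rng.unif()) <= hx - hu) {
      // accepted against envelope; Metropolis-Hastings correction
      double hucur = hull.env_at(xcur);
      double ratio = hx + std::min(hcur, hucur) - hcur - std::min(hx, hu);
      if (std::log(rng.unif()) <= ratio) {
        hcur_out = hx;
        return xs;
      }
      hcur_out = hcur;
      return xcur;
    }
    hull.insert(xs, hx, max_points);
  }
  hcur_out = hcur;
  return xcur;  // rejection budget exhausted; keep current state
}

// ---------------------------------------------------------------------------
// Standalone ARMS sampler for an R log-density (used directly and in tests)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".arms_sample_cpp")]]
NumericVector arms_sample_cpp(Function log_density, int n, double lower,
                              double upper, NumericVector init_abscissae,
                              double x_init, int seed) {
  Rng rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);
  auto logf = [&](double v) -> double {
    double r = as<double>(log_density(v));
    if (!std::isfinite(r)) return NEG_BIG;
    return r;
  };
  std::vector<double> init(init_abscissae.begin(), init_abscissae.end());
  NumericVector out(n);
  double xcur = x_init, hcur = logf(x_init);
  for (int i = 0; i < n; ++i) {
    double hnew;
    xcur = arms_step(logf, xcur, hcur, init, lower, upper, rng, hnew);
    hcur = hnew;
    out[i] = xcur;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Gibbs sampler over the coefficients of the Poisson log-linear model
// ---------------------------------------------------------------------------

// Full-conditional machinery.  For coordinate j the log conditional at
// value b (current value bcur) is
//   xty[j]*b - sum_g s_g * exp(u_g * (b - bcur)) + prior(b)
// where the data rows are grouped by the distinct values u_g of column j
// and s_g sums the current Poisson rates within each group.

struct Column {
  arma::uvec gidx;   // group index per row (0-based)
  arma::vec uvals;   // distinct column values per group
};

// prior_type: 0 flat, 1 normal with precision matrix Lambda and mean
// prior_mean (both already in the sampling parameterization), 2 Jeffreys
// via per-sweep local linearization.
// [[Rcpp::export(name = ".gibbs_poisson_cpp")]]
List gibbs_poisson_cpp(const arma::vec& y, const arma::mat& X,
                       const arma::vec& offset, List columns,
                       const arma::vec& beta_init, const arma::vec& sigma,
                       double bound, int prior_type,
                       const arma::vec& prior_mean, const arma::mat& Lambda,
                       int jeffreys_refresh, int n_iter, int burn_in, int thin,
                       int seed) {
  const arma::uword n = y.n_elem, p = X.n_cols;
  if (n_iter <= 0 || burn_in < 0 || thin <= 0)
    stop("iterations, burn-in and thinning must be positive");
  Rng rng(static_cast<uint64_t>(seed) * 2862933555777941757ULL + 3037000493ULL);

  std::vector<Column> cols(p);
  arma::vec xty(p);
  for (arma::uword j = 0; j < p; ++j) {
    List cj = columns[j];
    cols[j].gidx = as<arma::uvec>(cj["gidx"]);
    cols[j].uvals = as<arma::vec>(cj["uvals"]);
    xty[j] = arma::dot(X.col(j), y);
  }

  arma::vec beta = beta_init;
  arma::vec eta = offset + X * beta;
  arma::vec v = arma::exp(eta);
  arma::vec jslope(p, arma::fill::zeros);

  int kept_n = n_iter / thin;
  arma::mat draws(kept_n, p);
  long env_rejects = 0, mh_keep_current = 0;

  const int total = burn_in + n_iter;
  int kept = 0;

  arma::vec sg;  // group sums workspace
  std::vector<double> init_pts(5);

  for (int iter = 1; iter <= total; ++iter) {
    // refresh rates from eta to cancel multiplicative drift
    v = arma::exp(eta);

    if (prior_type == 2 &&
        ((iter - 1) % std::max(jeffreys_refresh, 1) == 0)) {
      // local linearization of Jeffreys' prior: slope of
      // 0.5*logdet(X' W X) in each coordinate at the current state,
      // 0.5 * sum_i leverage_i * mu_i * x_ij
      arma::mat M = X.t() * (X.each_col() % v);
      arma::mat R;
      if (arma::chol(R, M, "lower")) {
        arma::mat Z = arma::solve(arma::trimatl(R), X.t());
        arma::vec h = arma::sum(Z % Z, 0).t();
        jslope = 0.5 * (X.t() * (v % h));
      }
    }

    for (arma::uword j = 0; j < p; ++j) {
      const Column& cj = cols[j];
      const arma::uword G = cj.uvals.n_elem;
      sg.zeros(G);
      for (arma::uword i = 0; i < n; ++i) sg[cj.gidx[i]] += v[i];

      const double bcur = beta[j];
      const double tj = xty[j];
      const double js = jslope[j];
      double pm = 0, pp = 0, pb = 0;
      if (prior_type == 1) {
        pm = prior_mean[j];
        pp = Lambda(j, j);
        // cross term with the other coordinates of the Gaussian prior
        pb = arma::dot(Lambda.row(j).t(), beta - prior_mean) -
          pp * (bcur - pm);
      }
      auto logf = [&](double b) -> double {
        double db = b - bcur;
        double s = 0;
        for (arma::uword g = 0; g < G; ++g) {
          double e = cj.uvals[g] * db;
          if (e > 700) return NEG_BIG;
          s += sg[g] * std::exp(e);
        }
        double val = tj * b - s;
        if (prior_type == 1)
          val -= 0.5 * pp * (b - pm) * (b - pm) + pb * (b - pm);
        if (prior_type == 2) val += js * b;
        if (!std::isfinite(val)) return NEG_BIG;
        return val;
      };

      double sj = sigma[j];
      init_pts[0] = bcur - 3 * sj;
      init_pts[1] = bcur - sj;
      init_pts[2] = bcur;
      init_pts[3] = bcur + sj;
      init_pts[4] = bcur + 3 * sj;
      double lo = std::max(-bound, bcur - 50 * sj);
      double hi = std::min(bound, bcur + 50 * sj);
      double hcur = logf(bcur), hnew;
      double bnew = arms_step(logf, bcur, hcur, init_pts, lo, hi, rng, hnew);

      if (bnew != bcur) {
        double db = bnew - bcur;
        // update rates multiplicatively via the G distinct factors
        arma::vec wg(G);
        for (arma::uword g = 0; g < G; ++g)
          wg[g] = std::exp(cj.uvals[g] * db);
        for (arma::uword i = 0; i < n; ++i) {
          eta[i] += cj.uvals[cj.gidx[i]] * db;
          v[i] *= wg[cj.gidx[i]];
        }
        beta[j] = bnew;
      } else {
        ++mh_keep_current;
      }
      if (std::fabs(beta[j]) >= bound)
        stop("chain diverged: |beta| reached the support bound for coefficient %d",
             (int)(j + 1));
    }

    if (iter > burn_in && ((iter - burn_in) % thin == 0)) {
      draws.row(kept) = beta.t();
      ++kept;
      if (kept >= kept_n) {
        if (iter == total) break;
      }
    }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws,
                      _["beta_final"] = beta,
                      _["kept"] = kept,
                      _["mh_keep_current"] = mh_keep_current,
                      _["env_rejects"] = env_rejects);
}
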