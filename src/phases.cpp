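#include <Rcpp.h>

#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// Support structure held as out-adjacency lists: out[j] lists the rows i with
// c_ij = 1, i.e. the occupations that j supports. Entries of C are 0/1 so the
// support inflow (C x)_i reduces to sparse accumulation over active columns.
struct Net {
  int n;
  std::vector<std::vector<int> > out;
  std::vector<int> labels;  // 0 original, 1 derived, 2 invader
};

Net build_net(const IntegerMatrix& C, const IntegerVector& labels) {
  Net net;
  net.n = C.nrow();
  net.out.assign(net.n, std::vector<int>());
  for (int j = 0; j < net.n; ++j)
    for (int i = 0; i < net.n; ++i)
      if (C(i, j) != 0) net.out[j].push_back(i);
  net.labels.assign(labels.begin(), labels.end());
  return net;
}

// Developing phase: explicit stepping of the productivity dynamics on the
// active set until the stationarity residual max_i |a (Cx)_i / x_i - bX|
// drops below `tol`. Occupations falling below limina are eliminated (x -> 0,
// inactive) after every step and integration continues on the reduced set.
//
// rate_form 1 ("ratio"):  dx_i/dt = a (Cx)_i / x_i - bX
// rate_form 2 ("mass"):   dx_i/dt = a (Cx)_i - bX x_i
// Both share their fixed points; the mass form is stiffer at high totals, so
// its step size is bounded by a per-step estimate of the Jacobian scale.
//
// The step size is additionally limited so that no occupation moves by more
// than ELIM_RES * limina within one step: elimination order during fast
// transients (disturbance pulses, collapse cascades) is part of the model's
// behaviour and must be resolved, not an artifact of the step size.
static const double ELIM_RES = 0.05;
//
// status: 0 converged, 1 all occupations eliminated, 2 step cap reached
int develop_loop(const Net& net, std::vector<double>& x, std::vector<char>& active,
                 double a, double b, double limina, double dt, double tol,
                 double max_steps, int rate_form, double* steps_out) {
  const int n = net.n;
  std::vector<int> act;
  act.reserve(n);
  for (int i = 0; i < n; ++i)
    if (active[i]) act.push_back(i);
  *steps_out = 0;
  if (act.empty()) return 1;

  int dmax = 0;
  if (rate_form == 2) {
    std::vector<int> indeg(n, 0);
    for (int j = 0; j < n; ++j)
      for (size_t k = 0; k < net.out[j].size(); ++k) indeg[net.out[j][k]]++;
    for (int i = 0; i < n; ++i) dmax = std::max(dmax, indeg[i]);
  }

  std::vector<double> s(n), g(n);
  double steps = 0;
  int status = 2;
  while (steps < max_steps) {
    double X = 0;
    for (size_t k = 0; k < act.size(); ++k) X += x[act[k]];
    std::fill(s.begin(), s.end(), 0.0);
    for (size_t k = 0; k < act.size(); ++k) {
      const int j = act[k];
      const double xj = x[j];
      const std::vector<int>& oj = net.out[j];
      for (size_t m = 0; m < oj.size(); ++m) s[oj[m]] += xj;
    }
    const double ce = b * X;
    double maxres = 0, xmax = 0;
    for (size_t k = 0; k < act.size(); ++k) {
      const int i = act[k];
      const double res = std::fabs(a * s[i] / x[i] - ce);
      if (res > maxres) maxres = res;
      if (x[i] > xmax) xmax = x[i];
    }
    if (maxres < tol) {
      status = 0;
      break;
    }
    double dts = dt;
    double gmax = 0;
    if (rate_form == 1) {
      for (size_t k = 0; k < act.size(); ++k) {
        const int i = act[k];
        g[i] = a * s[i] / x[i] - ce;
        if (std::fabs(g[i]) > gmax) gmax = std::fabs(g[i]);
      }
    } else {
      const double bound = a * dmax + 2.0 * b * (X + n * xmax);
      dts = std::min(dt, 0.5 / std::max(bound, 1e-12));
      for (size_t k = 0; k < act.size(); ++k) {
        const int i = act[k];
        g[i] = a * s[i] - ce * x[i];
        if (std::fabs(g[i]) > gmax) gmax = std::fabs(g[i]);
      }
    }
    if (gmax * dts > ELIM_RES * limina) dts = ELIM_RES * limina / gmax;
    for (size_t k = 0; k < act.size(); ++k) x[act[k]] += dts * g[act[k]];
    steps += 1;

    bool removed = false;
    for (size_t k = 0; k < act.size(); ++k) {
      const int i = act[k];
      if (x[i] < limina) {
        x[i] = 0.0;
        active[i] = 0;
        removed = true;
      }
    }
    if (removed) {
      std::vector<int> keep;
      keep.reserve(act.size());
      for (size_t k = 0; k < act.size(); ++k)
        if (active[act[k]]) keep.push_back(act[k]);
      act.swap(keep);
      if (act.empty()) {
        status = 1;
        break;
      }
    }
  }
  *steps_out = steps;
  return status;
}

// Mutating phase: visits the occupations active at the phase start in a
// uniformly random order; each whose productivity exceeds 2*limina fires with
// probability p_m and transfers one limina quantum to a target drawn from the
// occupations currently supported by at least one active occupation.
// Own-society targets carry weight 1, other-society targets `cross_weight`.
// Targets activated mid-phase immediately count as supporters.
void mutate_loop(const Net& net, std::vector<double>& x, std::vector<char>& active,
                 double limina, double p_m, double cross_weight,
                 std::vector<int>& ev_src, std::vector<int>& ev_tgt) {
  const int n = net.n;
  std::vector<int> supported(n, 0);
  std::vector<int> act;
  for (int i = 0; i < n; ++i)
    if (active[i]) act.push_back(i);
  for (size_t k = 0; k < act.size(); ++k) {
    const std::vector<int>& oj = net.out[act[k]];
    for (size_t m = 0; m < oj.size(); ++m) supported[oj[m]]++;
  }

  const int m = (int)act.size();
  for (int k = m - 1; k > 0; --k) {
    int r = (int)std::floor(unif_rand() * (k + 1));
    if (r > k) r = k;
    std::swap(act[k], act[r]);
  }

  std::vector<double> w(n);
  for (int idx = 0; idx < m; ++idx) {
    const int src = act[idx];
    if (!(x[src] > 2.0 * limina)) continue;  // strict: exactly 2*limina cannot fire
    if (unif_rand() >= p_m) continue;
    double total = 0;
    for (int j = 0; j < n; ++j) {
      double wj = 0;
      if (j != src && supported[j] > 0)
        wj = (net.labels[j] == net.labels[src]) ? 1.0 : cross_weight;
      w[j] = wj;
      total += wj;
    }
    if (total <= 0) continue;  // nothing supported: the event is skipped
    const double u = unif_rand() * total;
    int tgt = -1;
    double acc = 0;
    for (int j = 0; j < n; ++j) {
      if (w[j] <= 0) continue;
      acc += w[j];
      if (u < acc) {
        tgt = j;
        break;
      }
    }
    if (tgt < 0) {  // guard against accumulated round-off at u ~ total
      for (int j = n - 1; j >= 0; --j)
        if (w[j] > 0) {
          tgt = j;
          break;
        }
    }
    x[src] -= limina;
    if (active[tgt]) {
      x[tgt] += limina;
    } else {
      active[tgt] = 1;
      x[tgt] = limina;
      const std::vector<int>& oj = net.out[tgt];
      for (size_t q = 0; q < oj.size(); ++q) supported[oj[q]]++;
    }
    ev_src.push_back(src + 1);
    ev_tgt.push_back(tgt + 1);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_develop(IntegerMatrix C, NumericVector x, LogicalVector active,
                 double a, double b, double limina, double dt, double tol,
                 double max_steps, int rate_form) {
  IntegerVector lab(C.nrow());
  Net net = build_net(C, lab);
  std::vector<double> xv(x.begin(), x.end());
  std::vector<char> av(active.begin(), active.end());
  double steps = 0;
  const int status =
      develop_loop(net, xv, av, a, b, limina, dt, tol, max_steps, rate_form, &steps);
  return List::create(_["x"] = NumericVector(xv.begin(), xv.end()),
                      _["active"] = LogicalVector(av.begin(), av.end()),
                      _["steps"] = steps, _["status"] = status);
}

// [[Rcpp::export]]
List cpp_mutate(IntegerMatrix C, IntegerVector labels, NumericVector x,
                LogicalVector active, double limina, double p_m,
                double cross_weight) {
  Net net = build_net(C, labels);
  std::vector<double> xv(x.begin(), x.end());
  std::vector<char> av(active.begin(), active.end());
  std::vector<int> es, et;
  mutate_loop(net, xv, av, limina, p_m, cross_weight, es, et);
  IntegerMatrix ev((int)es.size(), 2);
  for (int k = 0; k < (int)es.size(); ++k) {
    ev(k, 0) = es[k];
    ev(k, 1) = et[k];
  }
  return List::create(_["x"] = NumericVector(xv.begin(), xv.end()),
                      _["active"] = LogicalVector(av.begin(), av.end()),
                      _["events"] = ev);
}

// Runs `n_phases` develop+mutate cycles, applying any scheduled pulse
// amplification of b to the develop phase whose absolute index (phase_offset
// + local phase) matches the schedule. Records per-society totals and active
// counts after every full cycle.
// [[Rcpp::export]]
List cpp_run_phases(IntegerMatrix C, IntegerVector labels, NumericVector x,
                    LogicalVector active, double a, double b, double limina,
                    double p_m, double cross_weight, int n_phases,
                    IntegerVector disturb_phase, NumericVector disturb_rd,
                    double dt, double tol, double max_steps, int rate_form,
                    int phase_offset) {
  Net net = build_net(C, labels);
  std::vector<double> xv(x.begin(), x.end());
  std::vector<char> av(active.begin(), active.end());
  NumericMatrix rec(n_phases, 6);
  int nonconverged = 0;

  for (int p = 1; p <= n_phases; ++p) {
    double beff = b;
    for (int k = 0; k < disturb_phase.size(); ++k)
      if (disturb_phase[k] == phase_offset + p) beff *= disturb_rd[k];

    bool any_active = false;
    for (int i = 0; i < net.n; ++i)
      if (av[i]) {
        any_active = true;
        break;
      }
    if (any_active) {
      double steps = 0;
      const int status = develop_loop(net, xv, av, a, beff, limina, dt, tol,
                                      max_steps, rate_form, &steps);
      if (status == 2) nonconverged++;
      if (status != 1) {
        std::vector<int> es, et;
        mutate_loop(net, xv, av, limina, p_m, cross_weight, es, et);
      }
    }

    double X[3] = {0, 0, 0};
    int cnt[3] = {0, 0, 0};
    for (int i = 0; i < net.n; ++i)
      if (av[i]) {
        X[net.labels[i]] += xv[i];
        cnt[net.labels[i]]++;
      }
    rec(p - 1, 0) = X[0];
    rec(p - 1, 1) = X[1];
    rec(p - 1, 2) = X[2];
    rec(p - 1, 3) = cnt[0];
    rec(p - 1, 4) = cnt[1];
    rec(p - 1, 5) = cnt[2];
  }

  return List::create(_["x"] = NumericVector(xv.begin(), xv.end()),
                      _["active"] = LogicalVector(av.begin(), av.end()),
                      _["records"] = rec, _["nonconverged"] = nonconverged);
}
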