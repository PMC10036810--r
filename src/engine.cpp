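// Adaptive Bogacki-Shampine RK3(2) integrator for the coupled
// Aliev-Panfilov cell network, with stimulus-boundary segmentation,
// cubic-Hermite dense output on a fixed grid, and streaming detection
// of threshold upstroke crossings.
//
// All times here are in SECONDS; the R layer converts to/from ms.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Net {
  int n;                       // number of cells
  const double *k, *a1, *a2, *mu1, *mu2, *eps0, *ct;
  int nj;                      // number of junctions
  const int *jfrom, *jto;      // 0-based cell indices
  const double *jd, *jalpha;
};

// du_i = ct_i [ k u (u - a1) (1 - u) - v u ] + Icoupl_i + Istim_i
// dv_i = ct_i eps(u,v) [ -v - k u (u - a2 - 1) ],  eps = eps0 + mu1 v/(u+mu2)
// Coupling (junction a->b, asymmetry applied to the downstream cell b):
//   cell a: d (-u_a + alpha u_b),  cell b: d (u_a - alpha u_b)
inline void rhs(const Net &m, const double *y, const double *istim, double *dy) {
  const double *u = y, *v = y + m.n;
  double *du = dy, *dv = dy + m.n;
  for (int i = 0; i < m.n; ++i) du[i] = 0.0;
  for (int j = 0; j < m.nj; ++j) {
    const int a = m.jfrom[j], b = m.jto[j];
    const double t = m.jd[j] * (u[a] - m.jalpha[j] * u[b]);
    du[a] -= t;
    du[b] += t;
  }
  for (int i = 0; i < m.n; ++i) {
    const double ui = u[i], vi = v[i];
    du[i] += m.ct[i] * (m.k[i] * ui * (ui - m.a1[i]) * (1.0 - ui) - vi * ui)
             + istim[i];
    const double eps = m.eps0[i] + m.mu1[i] * vi / (ui + m.mu2[i]);
    dv[i] = m.ct[i] * eps * (-vi - m.k[i] * ui * (ui - m.a2[i] - 1.0));
  }
}

inline double hermite(double y0, double y1, double f0, double f1,
                      double h, double th) {
  const double th2 = th * th, th3 = th2 * th;
  return (2.0 * th3 - 3.0 * th2 + 1.0) * y0 + (th3 - 2.0 * th2 + th) * h * f0 +
         (-2.0 * th3 + 3.0 * th2) * y1 + (th3 - th2) * h * f1;
}

} // namespace

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(List cells, List junctions, List stimuli,
                  NumericVector u0, NumericVector v0,
                  double t0, double t1, double dt_out,
                  double rtol, double atol,
                  bool record_trace, double threshold, double blanking) {
  NumericVector ck = cells["k"], ca1 = cells["a1"], ca2 = cells["a2"],
                cmu1 = cells["mu1"], cmu2 = cells["mu2"],
                ceps0 = cells["eps0"], cct = cells["ct"];
  const int n = ck.size();
  IntegerVector jfrom = junctions["from"], jto = junctions["to"];
  NumericVector jd = junctions["d"], jalpha = junctions["alpha"];
  const int nj = jfrom.size();
  IntegerVector starget = stimuli["target"];
  NumericVector son = stimuli["onset"], soff = stimuli["offset"],
                samp = stimuli["amplitude"];
  const int ns = starget.size();

  Net m;
  m.n = n;
  m.k = ck.begin(); m.a1 = ca1.begin(); m.a2 = ca2.begin();
  m.mu1 = cmu1.begin(); m.mu2 = cmu2.begin();
  m.eps0 = ceps0.begin(); m.ct = cct.begin();
  m.nj = nj;
  m.jfrom = jfrom.begin(); m.jto = jto.begin();
  m.jd = jd.begin(); m.jalpha = jalpha.begin();

  if (t1 <= t0) stop("simulation horizon must exceed the start time");

  // --- segment boundaries: every stimulus onset/offset inside (t0, t1)
  std::vector<double> brk;
  brk.push_back(t0);
  for (int s = 0; s < ns; ++s) {
    if (son[s] > t0 && son[s] < t1) brk.push_back(son[s]);
    if (soff[s] > t0 && soff[s] < t1) brk.push_back(soff[s]);
  }
  brk.push_back(t1);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end()), brk.end());

  // --- output grid
  const long nt = (long)std::floor((t1 - t0) / dt_out + 1e-9) + 1;
  NumericMatrix umat, vmat;
  NumericVector tout;
  if (record_trace) {
    umat = NumericMatrix((int)nt, n);
    vmat = NumericMatrix((int)nt, n);
    tout = NumericVector((int)nt);
  }

  // --- state
  std::vector<double> y(2 * n), ynew(2 * n), ytmp(2 * n), z(2 * n);
  std::vector<double> k1(2 * n), k2(2 * n), k3(2 * n), k4(2 * n);
  std::vector<double> istim(n, 0.0);
  for (int i = 0; i < n; ++i) { y[i] = u0[i]; y[n + i] = v0[i]; }

  // streaming activation detection state (on the output grid)
  std::vector<double> uprev(n), last_act(n, -1e18);
  std::vector<std::vector<double> > acts(n);
  std::vector<double> ygrid(2 * n);

  long gi = 0; // next output grid index to fill
  double tg_prev = t0;
  // grid point at t0
  for (int i = 0; i < n; ++i) uprev[i] = y[i];
  if (record_trace) {
    tout[0] = t0;
    for (int i = 0; i < n; ++i) { umat(0, i) = y[i]; vmat(0, i) = y[n + i]; }
  }
  gi = 1;

  long nstep = 0, naccept = 0;
  const long max_steps = 200000000L;

  for (size_t seg = 0; seg + 1 < brk.size(); ++seg) {
    const double ta = brk[seg], tb = brk[seg + 1];
    // constant stimulus vector over this segment
    std::fill(istim.begin(), istim.end(), 0.0);
    const double tm = 0.5 * (ta + tb);
    for (int s = 0; s < ns; ++s)
      if (son[s] <= tm && tm < soff[s]) istim[starget[s]] += samp[s];

    double t = ta;
    double h = std::min(1e-4, tb - ta);
    rhs(m, y.data(), istim.data(), k1.data()); // FSAL seed for the segment
    bool fsal = true;

    while (t < tb - 1e-13) {
      if (++nstep > max_steps) stop("integration exceeded the step budget");
      if (h > tb - t) h = tb - t;
      if (!fsal) rhs(m, y.data(), istim.data(), k1.data());
      fsal = false;

      for (int i = 0; i < 2 * n; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
      rhs(m, ytmp.data(), istim.data(), k2.data());
      for (int i = 0; i < 2 * n; ++i) ytmp[i] = y[i] + 0.75 * h * k2[i];
      rhs(m, ytmp.data(), istim.data(), k3.data());
      for (int i = 0; i < 2 * n; ++i)
        ynew[i] = y[i] + h * (2.0 / 9.0 * k1[i] + 1.0 / 3.0 * k2[i] +
                              4.0 / 9.0 * k3[i]);
      rhs(m, ynew.data(), istim.data(), k4.data());

      // embedded 2nd-order solution for the error estimate
      double err = 0.0;
      for (int i = 0; i < 2 * n; ++i) {
        const double zi = y[i] + h * (7.0 / 24.0 * k1[i] + 0.25 * k2[i] +
                                      1.0 / 3.0 * k3[i] + 0.125 * k4[i]);
        const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                                 std::fabs(ynew[i]));
        const double e = (ynew[i] - zi) / sc;
        err += e * e;
      }
      err = std::sqrt(err / (2 * n));

      if (!std::isfinite(err)) {
        h *= 0.2;
        if (h < 1e-14)
          stop("non-finite state at t = %f s", t);
        continue;
      }

      if (err <= 1.0) {
        // accepted: fill grid points in (t, t+h]
        const double tnew = t + h;
        while (gi < nt) {
          const double tg = t0 + gi * dt_out;
          if (tg > tnew + 1e-13) break;
          const double th = (tg - t) / h;
          for (int i = 0; i < 2 * n; ++i)
            ygrid[i] = hermite(y[i], ynew[i], k1[i], k4[i], h, th);
          if (record_trace) {
            tout[gi] = tg;
            for (int i = 0; i < n; ++i) {
              umat(gi, i) = ygrid[i];
              vmat(gi, i) = ygrid[n + i];
            }
          }
          // upstroke threshold crossings with linear sub-sample interpolation
          for (int i = 0; i < n; ++i) {
            const double ua = uprev[i], ub = ygrid[i];
            if (ua < threshold && ub >= threshold && ub > ua) {
              const double tc =
                  tg_prev + dt_out * (threshold - ua) / (ub - ua);
              if (tc - last_act[i] >= blanking) {
                acts[i].push_back(tc);
                last_act[i] = tc;
              }
            }
            uprev[i] = ygrid[i];
          }
          tg_prev = tg;
          ++gi;
        }
        y.swap(ynew);
        k1.swap(k4);
        fsal = true;
        ++naccept;
        t = tnew;
        double fac = 0.9 * std::pow(std::max(err, 1e-10), -1.0 / 3.0);
        fac = std::min(5.0, std::max(0.2, fac));
        h *= fac;
      } else {
        double fac = 0.9 * std::pow(err, -1.0 / 3.0);
        h *= std::max(0.2, fac);
        if (h < 1e-14) stop("step size underflow at t = %f s", t);
      }
    }
  }

  // flatten activations
  long ntot = 0;
  for (int i = 0; i < n; ++i) ntot += (long)acts[i].size();
  IntegerVector acell((int)ntot);
  NumericVector atime((int)ntot);
  long p = 0;
  for (int i = 0; i < n; ++i)
    for (size_t q = 0; q < acts[i].size(); ++q) {
      acell[p] = i + 1;  // 1-based for R
      atime[p] = acts[i][q];
      ++p;
    }

  NumericVector uend(n), vend(n);
  for (int i = 0; i < n; ++i) { uend[i] = y[i]; vend[i] = y[n + i]; }

  List out = List::create(
      _["act_cell"] = acell, _["act_time"] = atime,
      _["u_end"] = uend, _["v_end"] = vend,
      _["nstep"] = (double)nstep, _["naccept"] = (double)naccept);
  if (record_trace) {
    out["time"] = tout;
    out["u"] = umat;
    out["v"] = vmat;
  }
  return out;
}
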