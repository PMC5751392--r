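#include <Rcpp.h>
#include <cmath>
#include <complex>
using namespace Rcpp;

// Zero-normalized cross-correlation of window A against the equally sized
// patch of B whose top-left corner is (top, left) (0-based).  Returns NaN
// when either side has zero variance.
static double ncc_at(const NumericMatrix& A, const NumericMatrix& B,
                     int top, int left) {
  const int h = A.nrow(), w = A.ncol();
  double sa = 0.0, sb = 0.0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      sa += A(i, j);
      sb += B(top + i, left + j);
    }
  const double ma = sa / (h * w), mb = sb / (h * w);
  double num = 0.0, va = 0.0, vb = 0.0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      const double da = A(i, j) - ma;
      const double db = B(top + i, left + j) - mb;
      num += da * db;
      va += da * da;
      vb += db * db;
    }
  if (va <= 0.0 || vb <= 0.0) return R_NaN;
  return num / std::sqrt(va * vb);
}

// [[Rcpp::export]]
NumericMatrix ncc_surface_cpp(NumericMatrix A, NumericMatrix B,
                              int anchor_top, int anchor_left,
                              IntegerVector dys, IntegerVector dxs) {
  const int ny = dys.size(), nx = dxs.size();
  NumericMatrix out(ny, nx);
  for (int jx = 0; jx < nx; ++jx)
    for (int iy = 0; iy < ny; ++iy) {
      const int top = anchor_top + dys[iy];
      const int left = anchor_left + dxs[jx];
      if (top < 0 || left < 0 ||
          top + A.nrow() > B.nrow() || left + A.ncol() > B.ncol()) {
        out(iy, jx) = NA_REAL;
      } else {
        out(iy, jx) = ncc_at(A, B, top, left);
      }
    }
  return out;
}

// One following-track run: greedy hill-climbing from (dy0, dx0) within
// half-range bounds about the start.  Returns final offset, its NCC, the
// steps taken and the status (0 converged, 1 hit boundary, 2 step cap).
struct TrackOut { int dy, dx, steps, status; double peak; };

static TrackOut track_one(const NumericMatrix& A, const NumericMatrix& post,
                          int top0, int left0, int calc_h, int calc_w,
                          int dy0, int dx0, int bound_h, int bound_w,
                          int max_steps, int stencil_half) {
  const int cy_lo = dy0 - bound_h, cy_hi = dy0 + bound_h;
  const int cx_lo = dx0 - bound_w, cx_hi = dx0 + bound_w;
  // clamp start into the frame
  int dy = dy0, dx = dx0;
  if (top0 + dy < 0) dy = -top0;
  if (top0 + dy + calc_h > post.nrow()) dy = post.nrow() - calc_h - top0;
  if (left0 + dx < 0) dx = -left0;
  if (left0 + dx + calc_w > post.ncol()) dx = post.ncol() - calc_w - left0;

  double cur = ncc_at(A, post, top0 + dy, left0 + dx);
  if (NumericMatrix::is_na(cur)) cur = -2.0;
  int steps = 0, status = 0;
  while (true) {
    int best_dy = dy, best_dx = dx;
    double best = cur;
    bool best_out = false;
    for (int sy = -stencil_half; sy <= stencil_half; ++sy)
      for (int sx = -stencil_half; sx <= stencil_half; ++sx) {
        if (sy == 0 && sx == 0) continue;
        const int ndy = dy + sy, ndx = dx + sx;
        const int top = top0 + ndy, left = left0 + ndx;
        if (top < 0 || left < 0 ||
            top + calc_h > post.nrow() || left + calc_w > post.ncol())
          continue;
        double v = ncc_at(A, post, top, left);
        if (NumericMatrix::is_na(v)) continue;
        bool better = v > best;
        if (!better && v == best) {
          // deterministic tie-break: smaller offset magnitude, then dy, dx
          const long m_new = (long) ndy * ndy + (long) ndx * ndx;
          const long m_old = (long) best_dy * best_dy + (long) best_dx * best_dx;
          better = m_new < m_old ||
            (m_new == m_old && (ndy < best_dy ||
                                (ndy == best_dy && ndx < best_dx)));
        }
        if (better) {
          best = v; best_dy = ndy; best_dx = ndx;
          best_out = (ndy < cy_lo || ndy > cy_hi ||
                      ndx < cx_lo || ndx > cx_hi);
        }
      }
    if (best_dy == dy && best_dx == dx) { status = 0; break; }
    if (best_out) { status = 1; break; } // best neighbour leaves the range
    dy = best_dy; dx = best_dx; cur = best;
    if (++steps >= max_steps) { status = 2; break; }
  }
  TrackOut o;
  o.dy = dy; o.dx = dx; o.steps = steps; o.status = status;
  o.peak = (cur <= -2.0) ? NA_REAL : cur;
  return o;
}

// Following tracking for a whole grid of calculation windows.  Each window
// is tracked from the delivering-strategy seed (the result of the window
// above it in the same column) and, as the error-correction fallback, from
// the initialization inherited from the coarser level; the branch ending on
// the higher correlation wins.  Offsets are integer (dy, dx) relative to
// the pre-frame window position.
// [[Rcpp::export]]
List track_grid_cpp(NumericMatrix pre, NumericMatrix post,
                    IntegerVector cy, IntegerVector cx,
                    int calc_h, int calc_w,
                    NumericMatrix init_dy, NumericMatrix init_dx,
                    int bound_h, int bound_w,
                    int max_steps, int stencil_half, bool deliver) {
  const int ny = cy.size(), nx = cx.size();
  NumericMatrix out_dy(ny, nx), out_dx(ny, nx), out_peak(ny, nx);
  IntegerMatrix out_steps(ny, nx), out_status(ny, nx);
  const int h2 = calc_h / 2, w2 = calc_w / 2;

  for (int jx = 0; jx < nx; ++jx) {
    bool have_prev = false;
    int prev_dy = 0, prev_dx = 0;
    for (int iy = 0; iy < ny; ++iy) {
      const int top0 = cy[iy] - h2, left0 = cx[jx] - w2;
      NumericMatrix A = pre(Range(top0, top0 + calc_h - 1),
                            Range(left0, left0 + calc_w - 1));
      const int iy0 = (int) std::lround(init_dy(iy, jx));
      const int ix0 = (int) std::lround(init_dx(iy, jx));
      TrackOut best = track_one(A, post, top0, left0, calc_h, calc_w,
                                (deliver && have_prev) ? prev_dy : iy0,
                                (deliver && have_prev) ? prev_dx : ix0,
                                bound_h, bound_w, max_steps, stencil_half);
      if (deliver && have_prev && (iy0 != prev_dy || ix0 != prev_dx)) {
        TrackOut alt = track_one(A, post, top0, left0, calc_h, calc_w,
                                 iy0, ix0, bound_h, bound_w, max_steps,
                                 stencil_half);
        if (!NumericMatrix::is_na(alt.peak) &&
            (NumericMatrix::is_na(best.peak) || alt.peak > best.peak))
          best = alt;
      }
      out_dy(iy, jx) = best.dy; out_dx(iy, jx) = best.dx;
      out_peak(iy, jx) = best.peak;
      out_steps(iy, jx) = best.steps; out_status(iy, jx) = best.status;
      prev_dy = best.dy; prev_dx = best.dx; have_prev = true;
    }
  }
  return List::create(_["axial"] = out_dy, _["lateral"] = out_dx,
                      _["peak"] = out_peak, _["steps"] = out_steps,
                      _["status"] = out_status);
}

// complex linear interpolation of a line at fractional index (0-based)
static inline std::complex<double> cinterp(const ComplexVector& x, double idx,
                                           bool& ok) {
  const int n = x.size();
  if (idx < 0.0 || idx > n - 1) { ok = false; return std::complex<double>(0, 0); }
  const int i0 = (int) std::floor(idx);
  const int i1 = (i0 == n - 1) ? i0 : i0 + 1;
  const double f = idx - i0;
  const std::complex<double> a(x[i0].r, x[i0].i), b(x[i1].r, x[i1].i);
  return a + f * (b - a);
}

// One phase zero-crossing Newton solve on a baseband window.
// x1 is the pre-compression window (length T), taken from samples
// t = t0 .. t0+T-1 (0-based) of its line; x2 is a full post-compression
// baseband line; the lag tau is in finest-rate samples, positive when the
// post-frame echo arrives later (motion toward greater depth).  The
// iteration is
//   tau <- tau - arg( exp(i w0 tau) * sum_t conj(x1(t)) x2(t + tau) ) / w0
// with w0 in rad/sample.
static double pz_window(const ComplexVector& x1, const ComplexVector& x2_line,
                        int t0, int T, double init_tau, double w0,
                        double tol, int max_iter,
                        int& iters, bool& converged) {
  double tau = init_tau;
  iters = 0; converged = false;
  for (int l = 0; l < max_iter; ++l) {
    std::complex<double> corr(0.0, 0.0);
    bool ok = true;
    for (int t = 0; t < T; ++t) {
      const std::complex<double> a(x1[t].r, x1[t].i);
      const std::complex<double> b = cinterp(x2_line, (t0 + t) + tau, ok);
      if (!ok) break;
      corr += std::conj(a) * b;
    }
    if (!ok) { // window slides past the line: clamp and flag
      const int n = x2_line.size();
      const double lo = (double) -t0, hi = (double) (n - 1) - (t0 + T - 1);
      tau = std::min(std::max(tau, lo), hi);
      converged = false;
      return tau;
    }
    const std::complex<double> rot(std::cos(w0 * tau), std::sin(w0 * tau));
    const double phase = std::arg(rot * corr);
    const double delta = phase / w0;
    tau -= delta;
    ++iters;
    if (std::fabs(delta) < tol) { converged = true; break; }
  }
  return tau;
}

// [[Rcpp::export]]
List phase_zero_window_cpp(ComplexVector x1, ComplexVector x2_line,
                           int t0, double init_tau, double w0,
                           double tol, int max_iter) {
  int iters; bool conv;
  double tau = pz_window(x1, x2_line, t0, x1.size(), init_tau, w0,
                         tol, max_iter, iters, conv);
  return List::create(_["tau"] = tau, _["iters"] = iters,
                      _["converged"] = conv);
}

// Whole-frame fine estimation.  centers are 1-based axial window-center
// sample indices; lines are processed independently.  When chained = true
// each window is initialized with the previous window's estimate along the
// line (the original 1D scheme); otherwise init_tau supplies per-window
// initial lags (the coarse-initialized modified scheme) and line_shift gives
// the integer lateral line offset applied to the post frame per window.
// [[Rcpp::export]]
List phase_zero_field_cpp(ComplexMatrix pre, ComplexMatrix post,
                          IntegerVector centers, int T,
                          NumericMatrix init_tau, IntegerMatrix line_shift,
                          double w0, double tol, int max_iter, bool chained) {
  const int nk = centers.size(), nl = pre.ncol();
  NumericMatrix tau(nk, nl);
  IntegerMatrix iters(nk, nl);
  LogicalMatrix conv(nk, nl);
  const int T2 = T / 2;
  for (int l = 0; l < nl; ++l) {
    ComplexVector x1_line = pre(_, l);
    double prev = 0.0;
    for (int k = 0; k < nk; ++k) {
      const int t0 = centers[k] - 1 - T2;
      ComplexVector x1 = x1_line[Range(t0, t0 + T - 1)];
      int l2 = l;
      double t_init;
      if (chained) {
        t_init = prev;
      } else {
        t_init = init_tau(k, l);
        l2 = l + line_shift(k, l);
        if (l2 < 0) l2 = 0;
        if (l2 >= nl) l2 = nl - 1;
      }
      ComplexVector x2_line = post(_, l2);
      int it; bool cv;
      const double t_hat = pz_window(x1, x2_line, t0, T, t_init, w0,
                                     tol, max_iter, it, cv);
      tau(k, l) = t_hat; iters(k, l) = it; conv(k, l) = cv;
      prev = t_hat;
    }
  }
  return List::create(_["tau"] = tau, _["iters"] = iters,
                      _["converged"] = conv);
}

// Convolution-model RF synthesis: each scatterer contributes a
// Gaussian-enveloped carrier pulse on every line, weighted by a Gaussian
// lateral beam profile.  Positions are in metres in the probe frame
// (depth >= 0 measured from the transducer face).
// [[Rcpp::export]]
NumericMatrix simulate_lines_cpp(NumericVector sx, NumericVector sz,
                                 NumericVector amp, NumericVector line_x,
                                 double fs, double f0, double c,
                                 double sigma_t, double beam_sigma,
                                 int n_samples) {
  const int nl = line_x.size(), ns = sx.size();
  NumericMatrix rf(n_samples, nl);
  const double two_pi_f0 = 2.0 * M_PI * f0;
  const double inv2st2 = 1.0 / (2.0 * sigma_t * sigma_t);
  const double inv2sb2 = 1.0 / (2.0 * beam_sigma * beam_sigma);
  const double half = 4.0 * sigma_t * fs; // pulse support in samples
  for (int l = 0; l < nl; ++l) {
    const double xl = line_x[l];
    for (int s = 0; s < ns; ++s) {
      const double dx = sx[s] - xl;
      if (std::fabs(dx) > 4.0 * beam_sigma) continue;
      if (sz[s] < 0.0) continue;
      const double w = amp[s] * std::exp(-dx * dx * inv2sb2);
      const double t0 = 2.0 * sz[s] / c;     // two-way travel time
      const double i0 = t0 * fs;
      const int lo = std::max(0, (int) std::ceil(i0 - half));
      const int hi = std::min(n_samples - 1, (int) std::floor(i0 + half));
      for (int i = lo; i <= hi; ++i) {
        const double tt = i / fs - t0;
        rf(i, l) += w * std::exp(-tt * tt * inv2st2) * std::cos(two_pi_f0 * tt);
      }
    }
  }
  return rf;
}
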