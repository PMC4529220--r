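// Fast trial engine: sensory encoding with delays, synchronous rate update,
// population-vector decode, hand kinematics. One core loop backs both the
// recording path (cpp_run_trial) and the flat-parameter fitness fast path
// (cpp_eval_params) used by the evolution strategy.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const int GRID = 11;
static const int NPPC = GRID * GRID;

// Place a continuous position (degrees) onto the 11x11 grid.
// Column-major node index: idx = c*11 + r (0-based), x=(c-5)*10, y=(5-r)*10.
// Bilinear: unit mass split over the <=4 surrounding nodes.
// Nearest: ties rounded toward zero in degree space.
static void place_nodes(double x, double y, bool nearest,
                        int idx[4], double wt[4], int &n) {
  if (nearest) {
    double kx = x / 10.0, ky = y / 10.0;
    int cx = (kx >= 0) ? (int)std::ceil(kx - 0.5) : (int)std::floor(kx + 0.5);
    int cy = (ky >= 0) ? (int)std::ceil(ky - 0.5) : (int)std::floor(ky + 0.5);
    idx[0] = (cx + 5) * GRID + (5 - cy); wt[0] = 1.0; n = 1;
    return;
  }
  double cf = x / 10.0 + 5.0;   // continuous column, 0..10
  double rf = 5.0 - y / 10.0;   // continuous row, 0..10
  int c0 = (int)std::floor(cf), r0 = (int)std::floor(rf);
  if (c0 > GRID - 2) c0 = GRID - 2;
  if (r0 > GRID - 2) r0 = GRID - 2;
  if (c0 < 0) c0 = 0;
  if (r0 < 0) r0 = 0;
  double fc = cf - c0, fr = rf - r0;
  double w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc);
  double w01 = (1 - fr) * fc,       w11 = fr * fc;
  n = 0;
  if (w00 > 0) { idx[n] = c0 * GRID + r0;             wt[n++] = w00; }
  if (w10 > 0) { idx[n] = c0 * GRID + r0 + 1;         wt[n++] = w10; }
  if (w01 > 0) { idx[n] = (c0 + 1) * GRID + r0;       wt[n++] = w01; }
  if (w11 > 0) { idx[n] = (c0 + 1) * GRID + r0 + 1;   wt[n++] = w11; }
  if (n == 0) { idx[0] = c0 * GRID + r0; wt[0] = 1.0; n = 1; }
}

static inline void accumulate_projected(double *acc, const double *W,
                                        double x, double y, bool nearest) {
  int idx[4]; double wt[4]; int n;
  place_nodes(x, y, nearest, idx, wt, n);
  for (int k = 0; k < n; ++k) {
    const double *col = W + (size_t)idx[k] * NPPC;
    const double w = wt[k];
    for (int i = 0; i < NPPC; ++i) acc[i] += w * col[i];
  }
}

static inline double clamp50(double v) {
  return v < -50.0 ? -50.0 : (v > 50.0 ? 50.0 : v);
}

// One full trial. Weight conventions: ff_w is 121x4 (PPC -> motor),
// fb_w is 121x4 (motor -> PPC, post x pre), lat_w is 121x121 (post x pre).
// Returns the summed post-movement hand-target distance; optionally records
// per-timestep hand positions, rates and distances into the *_out matrices.
static double trial_core(bool has_fb, bool has_lat,
                         const arma::mat &ff_w, const arma::mat &fb_w,
                         const arma::mat &lat_w,
                         double pb, double pk, double mb, double mk,
                         const arma::mat &w_vis, const arma::mat &w_prop,
                         double tx, double ty, int visible_steps,
                         int n_steps, int d_vis, int d_prop,
                         double v, bool nearest,
                         NumericMatrix *hand_out, NumericMatrix *ppc_out,
                         NumericMatrix *m1_out, NumericVector *dist_out) {
  arma::vec ppc(NPPC), ppc_in(NPPC);
  double m1[4], m1_in[4];
  ppc.fill(1.0 / (1.0 + std::exp(pk * pb)));
  const double m1_base = 1.0 / (1.0 + std::exp(mk * mb));
  for (int i = 0; i < 4; ++i) m1[i] = m1_base;

  // Target contribution to the delayed visual drive (constant while visible).
  arma::vec tdrive(NPPC, arma::fill::zeros);
  accumulate_projected(tdrive.memptr(), w_vis.memptr(), tx, ty, nearest);

  // hand_start[t-1]: hand position at the start of timestep t.
  std::vector<double> hsx(n_steps + 1, 0.0), hsy(n_steps + 1, 0.0);

  double hx = 0.0, hy = 0.0, total = 0.0;

  for (int t = 1; t <= n_steps; ++t) {
    // motor input reads previous PPC rates (one-timestep PPC->motor lag)
    for (int m = 0; m < 4; ++m) {
      const double *col = ff_w.colptr(m);
      double s = 0.0;
      for (int i = 0; i < NPPC; ++i) s += col[i] * ppc[i];
      m1_in[m] = s;
    }

    if (has_lat) ppc_in = lat_w * ppc;       // dgemv into existing buffer
    else ppc_in.zeros();
    if (has_fb)
      for (int m = 0; m < 4; ++m) {
        const double *col = fb_w.colptr(m);
        const double s = m1[m];
        for (int i = 0; i < NPPC; ++i) ppc_in[i] += s * col[i];
      }

    int uv = t - (d_vis - 1);   // world timestep feeding vision at t
    if (uv >= 1) {
      accumulate_projected(ppc_in.memptr(), w_vis.memptr(),
                           hsx[uv - 1], hsy[uv - 1], nearest);
      if (uv <= visible_steps) ppc_in += tdrive;
    }
    int up = t - (d_prop - 1);  // world timestep feeding proprioception at t
    if (up >= 1)
      accumulate_projected(ppc_in.memptr(), w_prop.memptr(),
                           hsx[up - 1], hsy[up - 1], nearest);

    for (int i = 0; i < NPPC; ++i)
      ppc[i] = 1.0 / (1.0 + std::exp(pk * (pb - ppc_in[i])));
    for (int m = 0; m < 4; ++m)
      m1[m] = 1.0 / (1.0 + std::exp(mk * (mb - m1_in[m])));

    // motor order: Up, Down, Left, Right
    hx = clamp50(hx + v * (m1[3] - m1[2]));
    hy = clamp50(hy + v * (m1[0] - m1[1]));
    hsx[t] = hx; hsy[t] = hy;

    const double d = std::sqrt((hx - tx) * (hx - tx) + (hy - ty) * (hy - ty));
    total += d;
    if (dist_out) (*dist_out)[t - 1] = d;
    if (hand_out) { (*hand_out)(t - 1, 0) = hx; (*hand_out)(t - 1, 1) = hy; }
    if (ppc_out)
      for (int i = 0; i < NPPC; ++i) (*ppc_out)(t - 1, i) = ppc[i];
    if (m1_out)
      for (int m = 0; m < 4; ++m) (*m1_out)(t - 1, m) = m1[m];
  }
  return total;
}

// [[Rcpp::export]]
List cpp_run_trial(bool has_fb, bool has_lat,
                   const arma::mat &ff_w, const arma::mat &fb_w,
                   const arma::mat &lat_w,
                   double ppc_bias, double ppc_gain,
                   double m1_bias, double m1_gain,
                   const arma::mat &w_vis, const arma::mat &w_prop,
                   double tx, double ty, int visible_steps,
                   int n_steps, int d_vis, int d_prop,
                   double v, bool nearest, bool record) {
  NumericVector dist(n_steps);
  if (!record) {
    trial_core(has_fb, has_lat, ff_w, fb_w, lat_w,
               ppc_bias, ppc_gain, m1_bias, m1_gain, w_vis, w_prop,
               tx, ty, visible_steps, n_steps, d_vis, d_prop, v, nearest,
               nullptr, nullptr, nullptr, &dist);
    return List::create(_["distance"] = dist);
  }
  NumericMatrix hand(n_steps, 2), ppc(n_steps, NPPC), m1(n_steps, 4);
  trial_core(has_fb, has_lat, ff_w, fb_w, lat_w,
             ppc_bias, ppc_gain, m1_bias, m1_gain, w_vis, w_prop,
             tx, ty, visible_steps, n_steps, d_vis, d_prop, v, nearest,
             &hand, &ppc, &m1, &dist);
  return List::create(_["hand"] = hand, _["ppc"] = ppc, _["m1"] = m1,
                      _["distance"] = dist);
}

// Per-trial summed distances for a genome given as matrices.
// [[Rcpp::export]]
NumericVector cpp_trial_sums(bool has_fb, bool has_lat,
                             const arma::mat &ff_w, const arma::mat &fb_w,
                             const arma::mat &lat_w,
                             double ppc_bias, double ppc_gain,
                             double m1_bias, double m1_gain,
                             const arma::mat &w_vis, const arma::mat &w_prop,
                             const arma::mat &targets, int visible_steps,
                             int n_steps, int d_vis, int d_prop,
                             double v, bool nearest) {
  int ntr = targets.n_rows;
  NumericVector sums(ntr);
  for (int n = 0; n < ntr; ++n)
    sums[n] = trial_core(has_fb, has_lat, ff_w, fb_w, lat_w,
                         ppc_bias, ppc_gain, m1_bias, m1_gain, w_vis, w_prop,
                         targets(n, 0), targets(n, 1), visible_steps,
                         n_steps, d_vis, d_prop, v, nearest,
                         nullptr, nullptr, nullptr, nullptr);
  return sums;
}

// Per-trial summed distances for a genome given as its flat parameter
// vector (the documented serialization order: ff_w by PPC index then motor
// index; fb_w likewise; lat_w presynaptic-major; ppc_bias, ppc_gain,
// m1_bias, m1_gain). Fast path for the evolution strategy.
// [[Rcpp::export]]
NumericVector cpp_eval_params(const arma::vec &params,
                              bool has_fb, bool has_lat,
                              const arma::mat &w_vis, const arma::mat &w_prop,
                              const arma::mat &targets, int visible_steps,
                              int n_steps, int d_vis, int d_prop,
                              double v, bool nearest) {
  size_t off = 0;
  arma::mat ff_w(NPPC, 4), fb_w, lat_w;
  for (int i = 0; i < NPPC; ++i)
    for (int m = 0; m < 4; ++m) ff_w(i, m) = params[off++];
  if (has_fb) {
    fb_w.set_size(NPPC, 4);
    for (int i = 0; i < NPPC; ++i)
      for (int m = 0; m < 4; ++m) fb_w(i, m) = params[off++];
  }
  if (has_lat) {
    lat_w.set_size(NPPC, NPPC);
    std::copy(params.memptr() + off, params.memptr() + off + NPPC * NPPC,
              lat_w.memptr());
    off += (size_t)NPPC * NPPC;
  }
  double pb = params[off], pk = params[off + 1];
  double mb = params[off + 2], mk = params[off + 3];
  if (off + 4 != params.n_elem)
    stop("parameter vector length does not match architecture");

  int ntr = targets.n_rows;
  NumericVector sums(ntr);
  for (int n = 0; n < ntr; ++n)
    sums[n] = trial_core(has_fb, has_lat, ff_w, fb_w, lat_w,
                         pb, pk, mb, mk, w_vis, w_prop,
                         targets(n, 0), targets(n, 1), visible_steps,
                         n_steps, d_vis, d_prop, v, nearest,
                         nullptr, nullptr, nullptr, nullptr);
  return sums;
}
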