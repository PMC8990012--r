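#include <Rcpp.h>
using namespace Rcpp;

// Strategy codes: 0 RW, 1 RT, 2 DT, 3 SP, 4 VE, 5 BT.
// Headings 0..7 = E, NE, N, NW, W, SW, S, SE (45-degree sectors, CCW from +x).
// Positions are 1-based (x = column, y = row); matrices are R rows x C cols.
static const int DX[8] = { 1, 1, 0, -1, -1, -1, 0, 1 };
static const int DY[8] = { 0, 1, 1,  1,  0, -1, -1, -1 };

static inline int round_half_up(double v) {
  return (int)std::floor(v + 0.5);
}

static inline bool in_map(int x, int y, int rows, int cols) {
  return x >= 1 && x <= cols && y >= 1 && y <= rows;
}

static inline int heading_from(double vx, double vy, int prev) {
  if (vx == 0.0 && vy == 0.0) return prev;
  double ang = std::atan2(vy, vx);          // (-pi, pi]
  double sector = ang / (M_PI / 4.0);       // units of 45 degrees
  int h = (int)std::floor(sector + 0.5);
  h %= 8;
  if (h < 0) h += 8;
  return h;
}

static inline int draw_uniform_index(int n) {
  // uniform on 0..n-1 via R's RNG
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

static inline int draw_strategy(const NumericVector& pmf) {
  double u = unif_rand();
  double cum = 0.0;
  for (int i = 0; i < 5; ++i) {
    cum += pmf[i];
    if (u < cum) return i;
  }
  return 5;
}

// Random-walk proposal: uniform over the 8 neighbors and the current cell.
static inline void propose_rw(int cx, int cy, int& px, int& py) {
  int k = draw_uniform_index(9);
  if (k == 8) { px = cx; py = cy; }
  else        { px = cx + DX[k]; py = cy + DY[k]; }
}

// One provisional update x-hat(t+1) in the body frame oriented by `heading`.
// pos_x/pos_y/beh hold the rounded-position and behavior histories (length t,
// current position last, beh = -1 for the two initial positions); `cursor` is
// the backtrack cursor, updated in place when strategy is BT.
static void propose_one(int strategy, int cx, int cy, int heading,
                        const int* pos_x, const int* pos_y, const int* beh,
                        int t, int& cursor,
                        const NumericMatrix& elevation,
                        const LogicalMatrix& features,
                        int& px, int& py) {
  int rows = elevation.nrow(), cols = elevation.ncol();
  switch (strategy) {
  case 0: { // RW
    propose_rw(cx, cy, px, py);
    break;
  }
  case 1: { // RT: uniform over feature-bearing forward cells, else RW
    int cand_x[3], cand_y[3], n = 0;
    int dirs[3] = { (heading + 7) % 8, heading, (heading + 1) % 8 };
    for (int i = 0; i < 3; ++i) {
      int nx = cx + DX[dirs[i]], ny = cy + DY[dirs[i]];
      if (in_map(nx, ny, rows, cols) && features(ny - 1, nx - 1)) {
        cand_x[n] = nx; cand_y[n] = ny; ++n;
      }
    }
    if (n > 0) {
      int k = draw_uniform_index(n);
      px = cand_x[k]; py = cand_y[k];
    } else {
      propose_rw(cx, cy, px, py);
    }
    break;
  }
  case 2: { // DT: straight ahead
    px = cx + DX[heading]; py = cy + DY[heading];
    break;
  }
  case 3: { // SP: remain in place
    px = cx; py = cy;
    break;
  }
  case 4: { // VE: argmax elevation over self + in-map neighbors
    double best = elevation(cy - 1, cx - 1);
    int tie_x[9], tie_y[9], n = 1;
    tie_x[0] = cx; tie_y[0] = cy;
    for (int k = 0; k < 8; ++k) {
      int nx = cx + DX[k], ny = cy + DY[k];
      if (!in_map(nx, ny, rows, cols)) continue;
      double e = elevation(ny - 1, nx - 1);
      if (e > best) {
        best = e; n = 1; tie_x[0] = nx; tie_y[0] = ny;
      } else if (e == best) {
        tie_x[n] = nx; tie_y[n] = ny; ++n;
      }
    }
    if (n == 1) { px = tie_x[0]; py = tie_y[0]; }
    else {
      int k = draw_uniform_index(n);
      px = tie_x[k]; py = tie_y[k];
    }
    break;
  }
  case 5: { // BT: previous position, or walk the cursor back on repeats
    if (t < 2) { px = cx; py = cy; break; }
    if (beh[t - 1] != 5) {
      cursor = t - 2;
    } else {
      int j = cursor - 1;
      while (j > 0 && beh[j] == 5) --j;
      if (j < 0) j = 0;
      cursor = j;
    }
    px = pos_x[cursor]; py = pos_y[cursor];
    break;
  }
  default:
    stop("unknown strategy code %d", strategy);
  }
}

// [[Rcpp::export]]
int cpp_heading_from(double vx, double vy, int prev) {
  return heading_from(vx, vy, prev);
}

// [[Rcpp::export]]
List cpp_init_agent(IntegerVector ipp, LogicalMatrix inaccessible) {
  int rows = inaccessible.nrow(), cols = inaccessible.ncol();
  int cx = ipp[0], cy = ipp[1];
  int cand_x[8], cand_y[8], n = 0;
  for (int k = 0; k < 8; ++k) {
    int nx = cx + DX[k], ny = cy + DY[k];
    if (in_map(nx, ny, rows, cols) && !inaccessible(ny - 1, nx - 1)) {
      cand_x[n] = nx; cand_y[n] = ny; ++n;
    }
  }
  if (n == 0) stop("initial position has no accessible neighbor");
  RNGScope scope;
  int k = draw_uniform_index(n);
  int x2 = cand_x[k], y2 = cand_y[k];
  int h = heading_from((double)(x2 - cx), (double)(y2 - cy), 0);
  return List::create(_["x2"] = IntegerVector::create(x2, y2),
                      _["heading"] = h);
}

// [[Rcpp::export]]
List cpp_propose(int strategy, IntegerVector cell, int heading,
                 IntegerVector pos_x, IntegerVector pos_y, IntegerVector beh,
                 int cursor,
                 NumericMatrix elevation, LogicalMatrix features) {
  RNGScope scope;
  int px, py;
  int cur = cursor - 1;  // R cursor is 1-based into the history
  propose_one(strategy, cell[0], cell[1], heading,
              pos_x.begin(), pos_y.begin(), beh.begin(), pos_x.size(), cur,
              elevation, features, px, py);
  return List::create(_["cell"] = IntegerVector::create(px, py),
                      _["cursor"] = cur + 1);
}

// One full time step: draw strategy, propose, smooth (one-step memory),
// enforce inaccessibility by staying put. Returns the updated state pieces;
// histories are appended on the R side.
// [[Rcpp::export]]
List cpp_step(NumericVector x_t, NumericVector x_tm1, IntegerVector cell,
              int heading, IntegerVector pos_x, IntegerVector pos_y,
              IntegerVector beh, int cursor, NumericVector pmf,
              NumericMatrix elevation, LogicalMatrix features,
              LogicalMatrix inaccessible, double alpha) {
  RNGScope scope;
  int rows = elevation.nrow(), cols = elevation.ncol();
  int cur = cursor - 1;
  int strat = draw_strategy(pmf);
  int px, py;
  propose_one(strat, cell[0], cell[1], heading,
              pos_x.begin(), pos_y.begin(), beh.begin(), pos_x.size(), cur,
              elevation, features, px, py);
  // x(t+1) = (2-a) x(t) + (a-1) x(t-1) + a v(t),  v(t) = xhat - x(t)
  double vx = px - x_t[0], vy = py - x_t[1];
  double nx = (2.0 - alpha) * x_t[0] + (alpha - 1.0) * x_tm1[0] + alpha * vx;
  double ny = (2.0 - alpha) * x_t[1] + (alpha - 1.0) * x_tm1[1] + alpha * vy;
  int rx = round_half_up(nx), ry = round_half_up(ny);
  bool stay = !in_map(rx, ry, rows, cols) || inaccessible(ry - 1, rx - 1);
  List out;
  if (stay) {
    out = List::create(_["x_t"] = x_t, _["x_tm1"] = x_tm1, _["cell"] = cell,
                       _["heading"] = heading, _["cursor"] = cur + 1,
                       _["strategy"] = strat, _["stayed"] = true,
                       _["proposed"] = IntegerVector::create(px, py));
  } else {
    int h = heading_from(nx - x_t[0], ny - x_t[1], heading);
    out = List::create(_["x_t"] = NumericVector::create(nx, ny),
                       _["x_tm1"] = x_t,
                       _["cell"] = IntegerVector::create(rx, ry),
                       _["heading"] = h, _["cursor"] = cur + 1,
                       _["strategy"] = strat, _["stayed"] = false,
                       _["proposed"] = IntegerVector::create(px, py));
  }
  return out;
}

// Full trajectory: init draw plus (n_steps - 1) strategy-driven updates,
// so the returned rounded-cell path has n_steps + 1 entries.
// [[Rcpp::export]]
List cpp_simulate(IntegerVector ipp, NumericVector pmf,
                  NumericMatrix elevation, LogicalMatrix features,
                  LogicalMatrix inaccessible, double alpha, int n_steps) {
  RNGScope scope;
  int rows = elevation.nrow(), cols = elevation.ncol();
  int len = n_steps + 1;
  IntegerVector out_x(len), out_y(len), out_beh(len);
  std::vector<int> px_hist(len), py_hist(len), beh_hist(len);

  int cx = ipp[0], cy = ipp[1];
  if (!in_map(cx, cy, rows, cols)) stop("initial position outside map");
  if (inaccessible(cy - 1, cx - 1)) stop("initial position is inaccessible");

  // initial position and the random second position
  int cand_x[8], cand_y[8], n = 0;
  for (int k = 0; k < 8; ++k) {
    int nx = cx + DX[k], ny = cy + DY[k];
    if (in_map(nx, ny, rows, cols) && !inaccessible(ny - 1, nx - 1)) {
      cand_x[n] = nx; cand_y[n] = ny; ++n;
    }
  }
  if (n == 0) stop("initial position has no accessible neighbor");
  int k0 = draw_uniform_index(n);
  double xt[2], xtm1[2];
  xtm1[0] = cx; xtm1[1] = cy;
  xt[0] = cand_x[k0]; xt[1] = cand_y[k0];
  int cell_x = cand_x[k0], cell_y = cand_y[k0];
  int heading = heading_from(xt[0] - xtm1[0], xt[1] - xtm1[1], 0);

  px_hist[0] = cx; py_hist[0] = cy; beh_hist[0] = -1;
  px_hist[1] = cell_x; py_hist[1] = cell_y; beh_hist[1] = -1;
  out_x[0] = cx; out_y[0] = cy; out_beh[0] = NA_INTEGER;
  out_x[1] = cell_x; out_y[1] = cell_y; out_beh[1] = NA_INTEGER;

  int t = 2;          // number of stored positions
  int cursor = 0;
  int stay_count = 0;

  for (int s = 2; s <= n_steps; ++s) {
    int strat = draw_strategy(pmf);
    int px, py;
    propose_one(strat, cell_x, cell_y, heading,
                px_hist.data(), py_hist.data(), beh_hist.data(), t, cursor,
                elevation, features, px, py);
    double vx = px - xt[0], vy = py - xt[1];
    double nx2 = (2.0 - alpha) * xt[0] + (alpha - 1.0) * xtm1[0] + alpha * vx;
    double ny2 = (2.0 - alpha) * xt[1] + (alpha - 1.0) * xtm1[1] + alpha * vy;
    int rx = round_half_up(nx2), ry = round_half_up(ny2);
    if (!in_map(rx, ry, rows, cols) || inaccessible(ry - 1, rx - 1)) {
      ++stay_count;  // stay put: positions and heading unchanged
    } else {
      xtm1[0] = xt[0]; xtm1[1] = xt[1];
      heading = heading_from(nx2 - xt[0], ny2 - xt[1], heading);
      xt[0] = nx2; xt[1] = ny2;
      cell_x = rx; cell_y = ry;
    }
    px_hist[t] = cell_x; py_hist[t] = cell_y; beh_hist[t] = strat;
    out_x[s] = cell_x; out_y[s] = cell_y; out_beh[s] = strat;
    ++t;
  }
  return List::create(_["x"] = out_x, _["y"] = out_y,
                      _["behavior"] = out_beh,
                      _["stay_put_count"] = stay_count);
}
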