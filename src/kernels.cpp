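// Hot-path kernels: the per-millisecond liquid simulation loop, Poisson
// input drawing, the fused readout training step (forward + backward +
// RMSProp) and replay-buffer column writes. Reference R implementations of
// every operation live under R/ (lif.R, encoding.R, readout.R, qlearning.R);
// the test suite asserts exact agreement between the two routes.
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// ---------------------------------------------------------------------------
// liquid simulation

// compressed-column view of one weight matrix (column = presynaptic
// neuron); built once per liquid_run in R (build_csc)
struct SparseCols {
  const int *p;
  const int *i;
  const double *x;
  void load(Environment &st, const char *name) {
    IntegerVector pv = st[std::string(name) + "_p"];
    IntegerVector iv = st[std::string(name) + "_i"];
    NumericVector xv = st[std::string(name) + "_x"];
    p = INTEGER(pv); i = iv.size() ? INTEGER(iv) : nullptr;
    x = xv.size() ? REAL(xv) : nullptr;
  }
  inline void add_col(int j, double *cur, double scale) const {
    for (int k = p[j]; k < p[j + 1]; ++k) cur[i[k]] += scale * x[k];
  }
};

struct LiquidRefs {
  NumericVector v, prev_e, prev_i;
  IntegerVector refrac;
  NumericMatrix ring;
  SparseCols wpe, wee_fast, wee_slow, wei, wie, wii;
  bool has_slow;
  int ring_pos, delay_slow, n_e, n_i, n, n_p;
  double v_rest, v_reset, v_thres, leak;
  int refrac_steps;

  explicit LiquidRefs(Environment st)
      : v(as<NumericVector>(st["v"])),
        prev_e(as<NumericVector>(st["prev_e"])),
        prev_i(as<NumericVector>(st["prev_i"])),
        refrac(as<IntegerVector>(st["refrac"])) {
    wpe.load(st, "wpe_t");
    wee_fast.load(st, "wee_fast_t");
    wei.load(st, "wei_t");
    wie.load(st, "wie_t");
    wii.load(st, "wii_t");
    has_slow = as<bool>(st["has_slow"]);
    ring_pos = 0; delay_slow = 0;
    if (has_slow) {
      wee_slow.load(st, "wee_slow_t");
      ring = as<NumericMatrix>(st["ring"]);
      ring_pos = as<int>(st["ring_pos"]);
      delay_slow = ring.ncol();
    }
    n_e = as<int>(st["n_e"]);
    n_i = as<int>(st["n_i"]);
    n = n_e + n_i;
    n_p = as<int>(st["n_p"]);
    v_rest = as<double>(st["v_rest"]);
    v_reset = as<double>(st["v_reset"]);
    v_thres = as<double>(st["v_thres"]);
    leak = as<double>(st["leak"]);
    refrac_steps = as<int>(st["refrac_steps"]);
  }
};

// Simulate T steps. input(s, spikes_out) must fill spikes_out (length n_p,
// values in {-1,0,1}) with the input spikes of step s.
template <typename InputFn>
static List sim_core(Environment st, LiquidRefs &L, int T, InputFn input,
                     bool record_counts, IntegerVector record_neurons) {
  std::vector<double> cur(L.n);
  std::vector<double> counts(L.n_e, 0.0);
  std::vector<double> new_e(L.n_e), new_i(L.n_i);
  std::vector<int> in_spk(L.n_p);
  NumericVector step_counts(record_counts ? T : 0);
  const int n_rec = record_neurons.size();
  NumericMatrix vtrace(n_rec, n_rec ? T : 0);

  for (int s = 0; s < T; ++s) {
    std::fill(cur.begin(), cur.end(), 0.0);
    input(s, in_spk);

    // input spikes act within their own step
    for (int l = 0; l < L.n_p; ++l)
      if (in_spk[l] != 0) L.wpe.add_col(l, cur.data(), in_spk[l]);
    // recurrent spikes arrive with a 1-step delay
    for (int j = 0; j < L.n_e; ++j) {
      if (L.prev_e[j] != 0) {
        L.wee_fast.add_col(j, cur.data(), 1.0);
        L.wei.add_col(j, cur.data() + L.n_e, 1.0);
      }
    }
    if (L.has_slow) {
      // spikes from delay_slow steps ago via the ring buffer
      for (int j = 0; j < L.n_e; ++j)
        if (L.ring(j, L.ring_pos) != 0)
          L.wee_slow.add_col(j, cur.data(), 1.0);
    }
    for (int k = 0; k < L.n_i; ++k) {
      if (L.prev_i[k] != 0) {
        L.wie.add_col(k, cur.data(), -1.0);
        L.wii.add_col(k, cur.data() + L.n_e, -1.0);
      }
    }

    // LIF update (same semantics as lif_step in R)
    int tot = 0;
    for (int i = 0; i < L.n; ++i) {
      bool spike = false;
      if (L.refrac[i] > 0) {
        L.refrac[i] -= 1;            // hold potential, cannot spike
      } else {
        L.v[i] += L.leak * (L.v_rest - L.v[i]) + cur[i];
        if (L.v[i] >= L.v_thres) {
          spike = true;
          L.v[i] = L.v_reset;
          L.refrac[i] = L.refrac_steps;
        }
      }
      if (i < L.n_e) {
        new_e[i] = spike ? 1.0 : 0.0;
        if (spike) { counts[i] += 1.0; ++tot; }
      } else {
        new_i[i - L.n_e] = spike ? 1.0 : 0.0;
      }
    }

    if (L.has_slow) {
      for (int j = 0; j < L.n_e; ++j) L.ring(j, L.ring_pos) = new_e[j];
      L.ring_pos = (L.ring_pos + 1) % L.delay_slow;
    }
    for (int j = 0; j < L.n_e; ++j) L.prev_e[j] = new_e[j];
    for (int k = 0; k < L.n_i; ++k) L.prev_i[k] = new_i[k];

    if (record_counts) step_counts[s] = tot;
    for (int r = 0; r < n_rec; ++r)
      vtrace(r, s) = L.v[record_neurons[r] - 1];
  }

  if (L.has_slow) st["ring_pos"] = L.ring_pos;
  st["step_index"] = as<int>(st["step_index"]) + T;

  NumericVector act(L.n_e);
  for (int i = 0; i < L.n_e; ++i) act[i] = counts[i] / T;
  return List::create(_["activation"] = act,
                      _["counts"] = step_counts,
                      _["vtrace"] = vtrace);
}

// Present a precomputed input spike raster (n_p x T) to the liquid.
// [[Rcpp::export]]
List lsm_present_cpp(Environment st, IntegerMatrix input_spikes,
                     bool record_counts, IntegerVector record_neurons) {
  LiquidRefs L(st);
  if (input_spikes.nrow() != L.n_p)
    stop("input spike raster has %d rows; topology expects %d inputs",
         input_spikes.nrow(), L.n_p);
  const int T = input_spikes.ncol();
  return sim_core(st, L, T,
                  [&](int s, std::vector<int> &out) {
                    for (int l = 0; l < L.n_p; ++l)
                      out[l] = input_spikes(l, s);
                  },
                  record_counts, record_neurons);
}

// Fused Poisson drawing + presentation: draws the input raster from the R
// RNG in exactly the order poisson_spikes() does (neuron index fastest),
// so the result is bit-identical to poisson_spikes() |> present().
// prob = rate/1000 per step; sign in {-1, +1}.
// [[Rcpp::export]]
NumericVector lsm_encode_present_cpp(Environment st, NumericVector prob,
                                     NumericVector sign, int steps) {
  LiquidRefs L(st);
  if (prob.size() != L.n_p)
    stop("rate vector has %d entries; topology expects %d inputs",
         (int)prob.size(), L.n_p);
  List out = sim_core(st, L, steps,
                      [&](int, std::vector<int> &o) {
                        for (int l = 0; l < L.n_p; ++l)
                          o[l] = (unif_rand() < prob[l])
                                   ? (sign[l] > 0 ? 1 : -1) : 0;
                      },
                      false, IntegerVector(0));
  return out["activation"];
}

// ---------------------------------------------------------------------------
// readout

struct ReadoutRefs {
  bool hidden;
  arma::mat W1, W2;
  arma::vec b1, b2;
  explicit ReadoutRefs(Environment par) {
    hidden = as<bool>(par["hidden"]);
    NumericMatrix w2r = par["w2"];
    NumericVector b2r = par["b2"];
    W2 = arma::mat(w2r.begin(), w2r.nrow(), w2r.ncol(), false);
    b2 = arma::vec(b2r.begin(), b2r.size(), false);
    if (hidden) {
      NumericMatrix w1r = par["w1"];
      NumericVector b1r = par["b1"];
      W1 = arma::mat(w1r.begin(), w1r.nrow(), w1r.ncol(), false);
      b1 = arma::vec(b1r.begin(), b1r.size(), false);
    }
  }
  arma::mat forward(const arma::mat &X, arma::mat &Hpre,
                    arma::mat &Hact) const {
    const arma::mat *feat = &X;
    if (hidden) {
      Hpre = W1.t() * X;
      Hpre.each_col() += b1;
      Hact = arma::clamp(Hpre, 0.0, arma::datum::inf);
      feat = &Hact;
    }
    arma::mat Q = W2.t() * (*feat);
    Q.each_col() += b2;
    return Q;
  }
};

// Q-values for a single activation vector.
// [[Rcpp::export]]
NumericVector readout_q_cpp(Environment par, NumericVector x) {
  ReadoutRefs R(par);
  arma::vec xv(x.begin(), x.size(), false);
  arma::mat Hpre, Hact;
  arma::mat Q = R.forward(xv, Hpre, Hact);
  return NumericVector(Q.begin(), Q.end());
}

static void rmsprop_inplace(arma::mat &W, const arma::mat &g, arma::mat &sq,
                            double lr, double rho, double eps) {
  sq = rho * sq + (1.0 - rho) * (g % g);
  W -= lr * (g / (arma::sqrt(sq) + eps));
}

// Forward + semi-gradient of 0.5 * mean squared Q-error + RMSProp, all in
// place on the parameter/optimizer environments. Returns the batch loss.
static double train_batch(Environment par, Environment opt,
                          const arma::mat &X, const IntegerVector &actions,
                          const arma::vec &targets) {
  const int B = X.n_cols;
  ReadoutRefs R(par);
  const double lr = as<double>(opt["lr"]);
  const double rho = as<double>(opt["smoothing"]);
  const double eps = as<double>(opt["eps_denom"]);

  arma::mat Hpre, Hact;
  arma::mat Q = R.forward(X, Hpre, Hact);
  const arma::mat &feat = R.hidden ? Hact : X;

  arma::mat dQ(Q.n_rows, B, arma::fill::zeros);
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    int a = actions[b] - 1;
    if (a < 0 || a >= (int)Q.n_rows) stop("action index out of range");
    double resid = Q(a, b) - targets[b];
    loss += 0.5 * resid * resid;
    dQ(a, b) = resid / B;
  }
  loss /= B;

  arma::mat gW2 = feat * dQ.t();
  arma::vec gb2 = arma::sum(dQ, 1);

  NumericMatrix sq_w2r = opt["sq_w2"];
  NumericVector sq_b2r = opt["sq_b2"];
  arma::mat sq_W2(sq_w2r.begin(), sq_w2r.nrow(), sq_w2r.ncol(), false);
  arma::vec sq_b2(sq_b2r.begin(), sq_b2r.size(), false);

  if (R.hidden) {
    arma::mat dH = (R.W2 * dQ) %
      arma::conv_to<arma::mat>::from(Hpre > 0);
    arma::mat gW1 = X * dH.t();
    arma::vec gb1 = arma::sum(dH, 1);
    NumericMatrix sq_w1r = opt["sq_w1"];
    NumericVector sq_b1r = opt["sq_b1"];
    arma::mat sq_W1(sq_w1r.begin(), sq_w1r.nrow(), sq_w1r.ncol(), false);
    arma::vec sq_b1(sq_b1r.begin(), sq_b1r.size(), false);
    rmsprop_inplace(R.W1, gW1, sq_W1, lr, rho, eps);
    sq_b1 = rho * sq_b1 + (1.0 - rho) * (gb1 % gb1);
    R.b1 -= lr * (gb1 / (arma::sqrt(sq_b1) + eps));
  }
  rmsprop_inplace(R.W2, gW2, sq_W2, lr, rho, eps);
  sq_b2 = rho * sq_b2 + (1.0 - rho) * (gb2 % gb2);
  R.b2 -= lr * (gb2 / (arma::sqrt(sq_b2) + eps));
  return loss;
}

// [[Rcpp::export]]
double readout_train_cpp(Environment par, Environment opt,
                         NumericMatrix Xr, IntegerVector actions,
                         NumericVector targets) {
  if (actions.size() != Xr.ncol() || targets.size() != Xr.ncol())
    stop("actions/targets must match the batch size");
  arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  arma::vec y(targets.begin(), targets.size(), false);
  return train_batch(par, opt, X, actions, y);
}

// Gather a replay mini-batch, compute Bellman targets with the current
// weights (Y = r + gamma * max_a Q(x', a), Y = r on terminals) and apply
// one fused training step. idx is 1-based into the buffer storage.
// [[Rcpp::export]]
double qlearn_update_cpp(Environment buf, Environment par, Environment opt,
                         IntegerVector idx, double gamma) {
  NumericMatrix xr = buf["x"], xnr = buf["xn"];
  IntegerVector action = buf["action"];
  NumericVector reward = buf["reward"];
  LogicalVector terminal = buf["terminal"];
  const int B = idx.size();
  const int n = xr.nrow();

  arma::mat X(n, B), Xn(n, B);
  IntegerVector a(B);
  for (int b = 0; b < B; ++b) {
    int j = idx[b] - 1;
    std::copy(&xr(0, j), &xr(0, j) + n, X.colptr(b));
    std::copy(&xnr(0, j), &xnr(0, j) + n, Xn.colptr(b));
    a[b] = action[j];
  }
  ReadoutRefs R(par);
  arma::mat Hpre, Hact;
  arma::mat Qn = R.forward(Xn, Hpre, Hact);
  arma::vec y(B);
  for (int b = 0; b < B; ++b) {
    int j = idx[b] - 1;
    double m = Qn.col(b).max();
    y[b] = reward[j] + (terminal[j] ? 0.0 : gamma * m);
  }
  return train_batch(par, opt, X, a, y);
}

// ---------------------------------------------------------------------------
// replay buffer

// Write one transition into the preallocated ring storage without copying
// the backing matrices. Ring position / size bookkeeping happens in R
// (replay_add), which also grows the storage when needed.
// [[Rcpp::export]]
void replay_store_cpp(Environment buf, int pos, NumericVector x,
                      NumericVector xn, int action, double reward,
                      bool terminal) {
  NumericMatrix xr = buf["x"], xnr = buf["xn"];
  IntegerVector a = buf["action"];
  NumericVector r = buf["reward"];
  LogicalVector t = buf["terminal"];
  const int n = xr.nrow();
  if (x.size() != n || xn.size() != n) stop("activation length mismatch");
  if (pos < 1 || pos > xr.ncol()) stop("replay position out of range");
  std::copy(x.begin(), x.end(), &xr(0, pos - 1));
  std::copy(xn.begin(), xn.end(), &xnr(0, pos - 1));
  a[pos - 1] = action;
  r[pos - 1] = reward;
  t[pos - 1] = terminal;
}
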