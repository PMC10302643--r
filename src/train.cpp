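// Two-stage batch gradient-descent training core for the tree-MPNN rate
// model. The message-passing layer is weight-tied and bias-free (the all-zero
// state is a fixed point); the readout has two sigmoid heads, the second with
// non-negative weights, scaled by two non-negative final weights. Stage 1
// regresses activation free energies, stage 2 rate constants; Adam moments
// are re-initialized and the loss window cleared at the stage switch.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <deque>

using namespace Rcpp;

static inline double leaky(double x, double s) { return x >= 0 ? x : s * x; }
static inline double dleaky(double x, double s) { return x >= 0 ? 1.0 : s; }
static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Graph {
  arma::uvec recv, send;  // 0-based state indices (0 = phosphorus root)
  arma::vec e;            // bond orders
  arma::vec h0;           // initial states, length nst
  int nst;
};

struct AdamState {
  arma::vec m, v;
  void init(int n) { m.zeros(n); v.zeros(n); }
};

struct Fwd {  // per-ligand forward tape
  std::vector<arma::vec> h;   // T+1 state vectors
  std::vector<arma::mat> Z;   // T preactivations (dm x E)
  std::vector<arma::mat> M;   // T aggregated messages (dm x nst)
  std::vector<arma::vec> U;   // T update preactivations
};

static void mpnnForward(const Graph& g, const arma::mat& Wm,
                        const arma::vec& Wu, int T, double slope, bool actU,
                        Fwd& f) {
  int dm = Wm.n_rows, E = g.recv.n_elem, nst = g.nst;
  f.h.assign(T + 1, arma::vec());
  f.Z.assign(T, arma::mat());
  f.M.assign(T, arma::mat());
  f.U.assign(T, arma::vec());
  f.h[0] = g.h0;
  for (int t = 0; t < T; ++t) {
    const arma::vec& h = f.h[t];
    arma::mat Z(dm, E), M(dm, nst, arma::fill::zeros);
    for (int k = 0; k < E; ++k) {
      double hi = h(g.recv(k)), hj = h(g.send(k)), ek = g.e(k);
      for (int d = 0; d < dm; ++d)
        Z(d, k) = Wm(d, 0) * hi + Wm(d, 1) * hj + Wm(d, 2) * ek;
    }
    for (int k = 0; k < E; ++k)
      for (int d = 0; d < dm; ++d)
        M(d, g.recv(k)) += leaky(Z(d, k), slope);
    arma::vec U(nst), hn(nst);
    for (int i = 0; i < nst; ++i) {
      double u = Wu(0) * h(i);
      for (int d = 0; d < dm; ++d) u += Wu(1 + d) * M(d, i);
      U(i) = u;
      hn(i) = actU ? leaky(u, slope) : u;
    }
    f.Z[t] = Z; f.M[t] = M; f.U[t] = U; f.h[t + 1] = hn;
  }
}

// accumulates gWm/gWu given dL/d(final states)
static void mpnnBackward(const Graph& g, const arma::mat& Wm,
                         const arma::vec& Wu, int T, double slope, bool actU,
                         const Fwd& f, arma::vec dh,
                         arma::mat& gWm, arma::vec& gWu) {
  int dm = Wm.n_rows, E = g.recv.n_elem, nst = g.nst;
  for (int t = T - 1; t >= 0; --t) {
    const arma::vec& h = f.h[t];
    arma::vec du(nst);
    for (int i = 0; i < nst; ++i)
      du(i) = dh(i) * (actU ? dleaky(f.U[t](i), slope) : 1.0);
    for (int i = 0; i < nst; ++i) {
      gWu(0) += du(i) * h(i);
      for (int d = 0; d < dm; ++d) gWu(1 + d) += du(i) * f.M[t](d, i);
    }
    arma::vec dhp(nst, arma::fill::zeros);
    for (int i = 0; i < nst; ++i) dhp(i) = Wu(0) * du(i);
    for (int k = 0; k < E; ++k) {
      int r = g.recv(k), s = g.send(k);
      double hi = h(r), hj = h(s), ek = g.e(k);
      double dx0 = 0, dx1 = 0;
      for (int d = 0; d < dm; ++d) {
        double dz = Wu(1 + d) * du(r) * dleaky(f.Z[t](d, k), slope);
        gWm(d, 0) += dz * hi;
        gWm(d, 1) += dz * hj;
        gWm(d, 2) += dz * ek;
        dx0 += Wm(d, 0) * dz;
        dx1 += Wm(d, 1) * dz;
      }
      dhp(r) += dx0;
      dhp(s) += dx1;
    }
    dh = dhp;
  }
}

static void adamStep(arma::vec& w, const arma::vec& g, AdamState& st,
                     double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  st.m = b1 * st.m + (1 - b1) * g;
  st.v = b2 * st.v + (1 - b2) * (g % g);
  double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
  w -= lr * (st.m / c1) / (arma::sqrt(st.v / c2) + eps);
}

// termination check on the trailing loss window: 0 continue, 1 converged,
// 2 rejected
static int checkWindow(const std::deque<double>& win, int window,
                       double signFrac, double mag, double convTol) {
  if ((int)win.size() < window + 1) return 0;
  std::vector<double> d(window);
  for (int i = 0; i < window; ++i) d[i] = win[i + 1] - win[i];
  double meanAbs = 0;
  for (double x : d) meanAbs += std::fabs(x);
  meanAbs /= window;
  int flips = 0;
  for (int i = 1; i < window; ++i)
    if (d[i] * d[i - 1] < 0) ++flips;
  double frac = (double)flips / (window - 1);
  if (frac >= signFrac && meanAbs > mag) return 2;
  if (meanAbs < convTol) return 1;
  return 0;
}

// [[Rcpp::export(name = ".trainCore")]]
List trainCore(List graphs, arma::mat desc, bool useGnn,
               arma::ivec ligidx, arma::mat sig,
               arma::vec dGobs, arma::vec kobs,
               arma::mat Wm, arma::vec Wu,
               arma::vec wH1, arma::vec wH2, arma::vec wF,
               List cfg, int seed) {
  const double lr = cfg["learning_rate"], slope = cfg["leaky_slope"],
      cutoff = cfg["stage1_cutoff"], fluctFrac = cfg["fluct_sign_frac"],
      fluctMag = cfg["fluct_mag"], convTol = cfg["converge_tol"],
      l2 = cfg["l2_strength"], RT = cfg["RT"], C = cfg["eyring_prefactor"];
  const int T = cfg["iterations"], batchSize = cfg["batch_size"],
      maxEpochs = cfg["max_epochs"], window = cfg["fluct_window"];
  // 1: leaky ReLU on the update output as well; 0: linear update
  const int actU = cfg["update_leaky"];
  // 0: monitor epoch-mean losses; 1: monitor raw batch losses
  const int perBatch = cfg["fluct_per_batch"];

  const int N = ligidx.n_elem;
  const int nLig = useGnn ? graphs.size() : desc.n_rows;
  const int p = wH2.n_elem;           // readout input width
  const int dm = Wm.n_rows;

  std::vector<Graph> G;
  if (useGnn) {
    G.resize(nLig);
    for (int l = 0; l < nLig; ++l) {
      List gl = graphs[l];
      arma::ivec rv = gl["recv"], sd = gl["send"];
      G[l].recv = arma::conv_to<arma::uvec>::from(rv - 1);
      G[l].send = arma::conv_to<arma::uvec>::from(sd - 1);
      G[l].e = as<arma::vec>(gl["e"]);
      G[l].h0 = as<arma::vec>(gl["h0"]);
      G[l].nst = G[l].h0.n_elem;
    }
  }

  AdamState aWm, aWu, aH1, aH2, aF;
  auto resetAdam = [&]() {
    aWm.init(Wm.n_elem); aWu.init(Wu.n_elem);
    aH1.init(wH1.n_elem); aH2.init(wH2.n_elem); aF.init(2);
  };
  resetAdam();
  int adamT = 0;

  std::mt19937 rng(seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  std::deque<double> win;
  std::vector<double> lossHist;
  lossHist.reserve((size_t)std::min(maxEpochs, 20000) *
                   std::max(1, N / std::max(1, batchSize)));
  int stage = 1, stageSwitch = NA_INTEGER, epochsRun = 0, globalBatch = 0;
  std::string status = "completed";
  bool stop = false;
  double epochLoss = 0;

  std::vector<Fwd> tapes(nLig);
  std::vector<int> batchLig;   // unique ligand ids in batch
  std::vector<int> ligPos(nLig, -1);

  for (int ep = 0; ep < maxEpochs && !stop; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    epochsRun = ep + 1;
    if (ep % 200 == 0) Rcpp::checkUserInterrupt();
    for (int b0 = 0; b0 < N && !stop; b0 += batchSize) {
      int B = std::min(batchSize, N - b0);
      // forward per unique ligand in batch
      batchLig.clear();
      for (int q = 0; q < B; ++q) {
        int l = ligidx(order[b0 + q]) - 1;
        if (ligPos[l] < 0) { ligPos[l] = batchLig.size(); batchLig.push_back(l); }
      }
      if (useGnn)
        for (int l : batchLig)
          mpnnForward(G[l], Wm, Wu, T, slope, actU, tapes[l]);

      arma::mat dgLig(p, batchLig.size(), arma::fill::zeros);
      arma::mat gWm(dm, 3, arma::fill::zeros);
      arma::vec gWu(1 + dm, arma::fill::zeros);
      arma::vec gH1(wH1.n_elem, arma::fill::zeros);
      arma::vec gH2(p, arma::fill::zeros);
      arma::vec gF(2, arma::fill::zeros);
      double loss = 0;

      for (int q = 0; q < B; ++q) {
        int r = order[b0 + q];
        int l = ligidx(r) - 1;
        arma::vec g(p);
        if (useGnn) {
          const arma::vec& hT = tapes[l].h[T];
          for (int i = 0; i < p; ++i) g(i) = hT(i + 1);  // root not emitted
        } else {
          g = desc.row(l).t();
        }
        double a1 = wH1(0) * sig(r, 0) + wH1(1) * sig(r, 1);
        for (int i = 0; i < p; ++i) a1 += wH1(2 + i) * g(i);
        double a2 = arma::dot(wH2, g);
        double hLS = sigmoid(a1), hL = sigmoid(a2);
        double dG = wF(0) * hLS + wF(1) * hL;
        double ddG;
        if (stage == 1) {
          double res = dG - dGobs(r);
          loss += std::fabs(res) / B;
          ddG = (res > 0 ? 1.0 : (res < 0 ? -1.0 : 0.0)) / B;
        } else {
          double k = C * std::exp(-dG / RT);
          double res = k - kobs(r);
          loss += std::fabs(res) / B;
          double dk = (res > 0 ? 1.0 : (res < 0 ? -1.0 : 0.0)) / B;
          ddG = dk * (-k / RT);
        }
        gF(0) += ddG * hLS;
        gF(1) += ddG * hL;
        double da1 = ddG * wF(0) * hLS * (1 - hLS);
        double da2 = ddG * wF(1) * hL * (1 - hL);
        gH1(0) += da1 * sig(r, 0);
        gH1(1) += da1 * sig(r, 1);
        for (int i = 0; i < p; ++i) {
          gH1(2 + i) += da1 * g(i);
          gH2(i) += da2 * g(i);
          dgLig(i, ligPos[l]) += da1 * wH1(2 + i) + da2 * wH2(i);
        }
      }
      gH1 += 2.0 * l2 * wH1;
      gH2 += 2.0 * l2 * wH2;

      if (useGnn) {
        for (size_t q = 0; q < batchLig.size(); ++q) {
          int l = batchLig[q];
          arma::vec dh(G[l].nst, arma::fill::zeros);
          for (int i = 0; i < p; ++i) dh(i + 1) = dgLig(i, q);
          mpnnBackward(G[l], Wm, Wu, T, slope, actU, tapes[l], dh, gWm,
                       gWu);
        }
      }
      for (int l : batchLig) ligPos[l] = -1;

      // Adam step with shared time index, then non-negativity projection
      ++adamT;
      if (useGnn) {
        arma::vec wmv = arma::vectorise(Wm), gmv = arma::vectorise(gWm);
        adamStep(wmv, gmv, aWm, lr, adamT);
        Wm = arma::reshape(wmv, dm, 3);
        adamStep(Wu, gWu, aWu, lr, adamT);
      }
      adamStep(wH1, gH1, aH1, lr, adamT);
      adamStep(wH2, gH2, aH2, lr, adamT);
      adamStep(wF, gF, aF, lr, adamT);
      wH2.transform([](double x) { return x < 0 ? 0.0 : x; });
      wF.transform([](double x) { return x < 0 ? 0.0 : x; });

      ++globalBatch;
      lossHist.push_back(loss);
      epochLoss += loss * B;
      if (perBatch) {
        if (stage == 1 && loss < cutoff) {
          stage = 2;
          stageSwitch = globalBatch;
          resetAdam();
          adamT = 0;
          win.clear();
          continue;
        }
        win.push_back(loss);
        if ((int)win.size() > window + 1) win.pop_front();
        int st = checkWindow(win, window, fluctFrac, fluctMag, convTol);
        if (st == 1) { status = "converged_early"; stop = true; }
        else if (st == 2) { status = "rejected_fluctuation"; stop = true; }
      }
    }
    if (!perBatch && !stop) {
      epochLoss /= N;
      if (stage == 1 && epochLoss < cutoff) {
        stage = 2;
        stageSwitch = globalBatch;
        resetAdam();
        adamT = 0;
        win.clear();
      } else {
        win.push_back(epochLoss);
        if ((int)win.size() > window + 1) win.pop_front();
        int st = checkWindow(win, window, fluctFrac, fluctMag, convTol);
        if (st == 1) { status = "converged_early"; stop = true; }
        else if (st == 2) { status = "rejected_fluctuation"; stop = true; }
      }
    }
    epochLoss = 0;
  }
  if (stage == 1 && maxEpochs > 0 && status == "completed")
    status = "stage1_cutoff_not_reached";

  return List::create(
      _["Wm"] = Wm, _["Wu"] = Wu, _["wH1"] = wH1, _["wH2"] = wH2,
      _["wFinal"] = wF, _["loss"] = lossHist, _["status"] = status,
      _["stageSwitch"] = stageSwitch, _["epochsRun"] = epochsRun);
}
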