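#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Joint posterior samplers for the two-sample mixture DE model.
//
// Data layout: per-sample CSR over reads (ptr 0-based, idx 0-based transcript
// columns, f alignment densities). The samplers maintain per-transcript
// allocation tallies sx/sz, the alive indicator (c), and -- for the collapsed
// sampler -- running sums that make single-site allocation updates and the
// pairwise block update of c O(1) under exchangeable hyperparameters.
//
// All randomness goes through the R RNG so set.seed() on the R side gives
// bit-reproducible chains.

namespace {

struct Csr {
  const int *ptr, *idx;
  const double *f;
  int n;  // number of reads
};

// log Dirichlet density with parameters g[0..d-1] at simplex v[0..d-1]
double ldirichlet(const std::vector<double> &v, const double *g, int d) {
  double sg = 0, out = 0;
  for (int l = 0; l < d; ++l) {
    sg += g[l];
    out += (g[l] - 1.0) * std::log(v[l]) - R::lgammafn(g[l]);
  }
  return out + R::lgammafn(sg);
}

class Model {
public:
  Csr X, Y;
  int K;
  std::vector<double> alpha, gamma_;
  bool ua, ug;            // exchangeable alpha / gamma
  double a0, g0;

  std::vector<int> xi, zz, sx, sz;
  std::vector<int> alive;
  int cp;
  double pi;

  // collapsed-sampler running sums (valid after sync_sums())
  std::vector<double> at, gl;   // per-transcript alpha-tilde, gamma_{l(k)}
  double A1, Sz1, G1;           // sum_alive(at+sx), sum_alive sz, sum_alive(gl+sz)
  double T0, T1;                // lgamma sums over dead / alive transcripts

  long blk_prop = 0, blk_move = 0;
  long b_prop = 0, b_acc = 0, d_prop = 0, d_acc = 0, unavail = 0;

  Model(Csr X_, Csr Y_, int K_, NumericVector a_, NumericVector g_)
      : X(X_), Y(Y_), K(K_),
        alpha(a_.begin(), a_.end()), gamma_(g_.begin(), g_.end()),
        xi(X_.n), zz(Y_.n), sx(K_, 0), sz(K_, 0), alive(K_, 0), cp(0),
        at(K_), gl(K_, 0.0) {
    ua = true; ug = true;
    for (int k = 1; k < K; ++k) {
      if (alpha[k] != alpha[0]) ua = false;
      if (gamma_[k] != gamma_[0]) ug = false;
    }
    a0 = alpha[0]; g0 = gamma_[0];
  }

  void init_allocations() {
    for (int i = 0; i < X.n; ++i) {
      xi[i] = draw_prop_f(X, i);
      ++sx[xi[i]];
    }
    for (int j = 0; j < Y.n; ++j) {
      zz[j] = draw_prop_f(Y, j);
      ++sz[zz[j]];
    }
  }

  int draw_prop_f(const Csr &S, int i) {
    double tot = 0;
    for (int j = S.ptr[i]; j < S.ptr[i + 1]; ++j) tot += S.f[j];
    double u = unif_rand() * tot, cum = 0;
    for (int j = S.ptr[i]; j < S.ptr[i + 1]; ++j) {
      cum += S.f[j];
      if (u <= cum) return S.idx[j];
    }
    return S.idx[S.ptr[i + 1] - 1];
  }

  // alpha-tilde / gamma_{l(k)} maps for the current alive set
  void sync_maps() {
    int kstar = K - cp, dr = 0, ar = 0;
    for (int k = 0; k < K; ++k) {
      if (alive[k]) {
        at[k] = alpha[kstar + ar];
        gl[k] = gamma_[ar];
        ++ar;
      } else {
        at[k] = alpha[dr];
        gl[k] = 0.0;
        ++dr;
      }
    }
  }

  void sync_sums() {
    A1 = Sz1 = G1 = T0 = T1 = 0;
    for (int k = 0; k < K; ++k) {
      if (alive[k]) {
        A1 += at[k] + sx[k];
        Sz1 += sz[k];
        G1 += gl[k] + sz[k];
        T1 += R::lgammafn(at[k] + sx[k]) + R::lgammafn(gl[k] + sz[k]);
      } else {
        T0 += R::lgammafn(at[k] + sx[k] + sz[k]);
      }
    }
  }

  // ---- collapsed sampler ---------------------------------------------------

  void collapsed_update_x(bool random_scan) {
    std::vector<double> cum(64);
    for (int t = 0; t < X.n; ++t) {
      int i = random_scan ? (int)(unif_rand() * X.n) : t;
      if (i >= X.n) i = X.n - 1;
      int k0 = xi[i];
      --sx[k0];
      if (alive[k0]) A1 -= 1.0;
      int lo = X.ptr[i], hi = X.ptr[i + 1], m = hi - lo;
      if ((int)cum.size() < m) cum.resize(m);
      double N1 = A1 + Sz1, tot = 0;
      for (int j = lo; j < hi; ++j) {
        int k = X.idx[j];
        double wgt = alive[k]
          ? (N1 / A1) * (at[k] + sx[k]) * X.f[j]
          : (at[k] + sx[k] + sz[k]) * X.f[j];
        tot += wgt;
        cum[j - lo] = tot;
      }
      double u = unif_rand() * tot;
      int pick = hi - 1;
      for (int j = lo; j < hi; ++j)
        if (u <= cum[j - lo]) { pick = j; break; }
      int k1 = X.idx[pick];
      xi[i] = k1;
      ++sx[k1];
      if (alive[k1]) A1 += 1.0;
    }
  }

  void collapsed_update_y(bool random_scan) {
    std::vector<double> cum(64);
    for (int t = 0; t < Y.n; ++t) {
      int j0 = random_scan ? (int)(unif_rand() * Y.n) : t;
      if (j0 >= Y.n) j0 = Y.n - 1;
      int k0 = zz[j0];
      --sz[k0];
      if (alive[k0]) { Sz1 -= 1.0; G1 -= 1.0; }
      int lo = Y.ptr[j0], hi = Y.ptr[j0 + 1], m = hi - lo;
      if ((int)cum.size() < m) cum.resize(m);
      double N1 = A1 + Sz1, tot = 0;
      for (int j = lo; j < hi; ++j) {
        int k = Y.idx[j];
        double wgt = alive[k]
          ? (N1 / G1) * (gl[k] + sz[k]) * Y.f[j]
          : (at[k] + sx[k] + sz[k]) * Y.f[j];
        tot += wgt;
        cum[j - lo] = tot;
      }
      double u = unif_rand() * tot;
      int pick = hi - 1;
      for (int j = lo; j < hi; ++j)
        if (u <= cum[j - lo]) { pick = j; break; }
      int k1 = Y.idx[pick];
      zz[j0] = k1;
      ++sz[k1];
      if (alive[k1]) { Sz1 += 1.0; G1 += 1.0; }
    }
  }

  // full O(K) collapsed log mass for an arbitrary alive configuration
  // (general, non-exchangeable hyperparameters)
  double full_logmass(const std::vector<int> &al, int cpn) {
    int kstar = K - cpn, dr = 0, ar = 0;
    double t0 = 0, t1 = 0, a1 = 0, sz1 = 0, g1 = 0;
    for (int k = 0; k < K; ++k) {
      if (al[k]) {
        double atk = alpha[kstar + ar], glk = gamma_[ar];
        ++ar;
        a1 += atk + sx[k];
        sz1 += sz[k];
        g1 += glk + sz[k];
        t1 += R::lgammafn(atk + sx[k]) + R::lgammafn(glk + sz[k]);
      } else {
        t0 += R::lgammafn(alpha[dr] + sx[k] + sz[k]);
        ++dr;
      }
    }
    double out = t0 + t1;
    if (cpn > 0) {
      double sg = 0, slg = 0;
      for (int l = 0; l < cpn; ++l) { sg += gamma_[l]; slg += R::lgammafn(gamma_[l]); }
      out += R::lgammafn(a1 + sz1) - R::lgammafn(a1) - R::lgammafn(g1)
           + R::lgammafn(sg) - slg;
    }
    return out;
  }

  void collapsed_update_c_block() {
    // sums/maps assumed in sync with current allocations
    sync_sums();
    double lpi = std::log(pi), lqi = std::log1p(-pi);
    for (int rep = 0; rep < K; ++rep) {
      int j1 = (int)(unif_rand() * K); if (j1 >= K) j1 = K - 1;
      int j2 = (int)(unif_rand() * (K - 1)); if (j2 >= K - 1) j2 = K - 2;
      if (j2 >= j1) ++j2;
      int c1 = alive[j1], c2 = alive[j2];
      double logw[4], st0[4], st1[4], sa1[4], ssz[4], sg1[4];
      int bs1[4], bs2[4], cps[4];
      int nval = 0;
      for (int b1 = 0; b1 <= 1; ++b1) for (int b2 = 0; b2 <= 1; ++b2) {
        int cpn = cp - c1 - c2 + b1 + b2;
        if (cpn == 1) continue;
        double lm;
        double t0c = T0, t1c = T1, a1c = A1, sz1c = Sz1, g1c = G1;
        if (ua && ug) {
          int js[2] = {j1, j2}, bs[2] = {b1, b2}, cs[2] = {c1, c2};
          for (int h = 0; h < 2; ++h) {
            int k = js[h];
            if (bs[h] == cs[h]) continue;
            if (bs[h]) {  // dead -> alive
              t0c -= R::lgammafn(a0 + sx[k] + sz[k]);
              t1c += R::lgammafn(a0 + sx[k]) + R::lgammafn(g0 + sz[k]);
              a1c += a0 + sx[k]; sz1c += sz[k]; g1c += g0 + sz[k];
            } else {      // alive -> dead
              t0c += R::lgammafn(a0 + sx[k] + sz[k]);
              t1c -= R::lgammafn(a0 + sx[k]) + R::lgammafn(g0 + sz[k]);
              a1c -= a0 + sx[k]; sz1c -= sz[k]; g1c -= g0 + sz[k];
            }
          }
          lm = t0c + t1c;
          if (cpn > 0)
            lm += R::lgammafn(a1c + sz1c) - R::lgammafn(a1c) - R::lgammafn(g1c)
                + R::lgammafn(cpn * g0) - cpn * R::lgammafn(g0);
        } else {
          std::vector<int> al = alive;
          al[j1] = b1; al[j2] = b2;
          lm = full_logmass(al, cpn);
        }
        logw[nval] = lm + cpn * lpi + (K - cpn) * lqi;
        st0[nval] = t0c; st1[nval] = t1c; sa1[nval] = a1c;
        ssz[nval] = sz1c; sg1[nval] = g1c;
        bs1[nval] = b1; bs2[nval] = b2; cps[nval] = cpn;
        ++nval;
      }
      double mx = logw[0];
      for (int h = 1; h < nval; ++h) if (logw[h] > mx) mx = logw[h];
      double tot = 0, cw[4];
      for (int h = 0; h < nval; ++h) { tot += std::exp(logw[h] - mx); cw[h] = tot; }
      double u = unif_rand() * tot;
      int pick = nval - 1;
      for (int h = 0; h < nval; ++h) if (u <= cw[h]) { pick = h; break; }
      ++blk_prop;
      if (bs1[pick] != c1 || bs2[pick] != c2) {
        ++blk_move;
        alive[j1] = bs1[pick]; alive[j2] = bs2[pick];
        cp = cps[pick];
        sync_maps();  // keeps at/gl valid for the allocation updates
        if (ua && ug) {
          T0 = st0[pick]; T1 = st1[pick];
          A1 = sa1[pick]; Sz1 = ssz[pick]; G1 = sg1[pick];
        } else {
          sync_sums();
        }
      }
    }
  }

  void update_pi(bool jeffreys) {
    if (jeffreys) pi = R::rbeta(cp + 0.5, K - cp + 0.5);
  }

  // ---- expression draw from the conjugate full conditional, shared code ----

  void draw_expression(std::vector<double> &theta, std::vector<double> &w) {
    int kstar = K - cp;
    std::vector<int> tau(K);
    int dr = 0, ar = 0;
    for (int k = 0; k < K; ++k) {
      if (alive[k]) tau[kstar + ar++] = k;
      else tau[dr++] = k;
    }
    std::vector<double> pooled(K), xonly(K);
    for (int k = 0; k < K; ++k) {
      pooled[k] = alpha[k] + sx[tau[k]] + sz[tau[k]];
      xonly[k] = alpha[k] + sx[tau[k]];
    }
    std::vector<double> rcp(K + 1, 0.0), rcx(K + 1, 0.0);
    for (int k = K - 1; k >= 0; --k) {
      rcp[k] = rcp[k + 1] + pooled[k];
      rcx[k] = rcx[k + 1] + xonly[k];
    }
    std::vector<double> u(K);
    double remain = 1.0;
    for (int k = 0; k < K - 1; ++k) {
      double lam = (k < kstar) ? pooled[k] : xonly[k];
      double bet = (k < kstar) ? rcp[k + 1] : rcx[k + 1];
      double zb = R::rbeta(lam, bet);
      u[k] = zb * remain;
      remain *= (1.0 - zb);
    }
    u[K - 1] = remain;
    for (int k = 0; k < K; ++k) theta[tau[k]] = u[k];
    for (int k = 0; k < K; ++k) w[k] = theta[k];
    if (cp > 0) {
      double S = 0;
      for (int k = kstar; k < K; ++k) S += u[k];
      std::vector<double> v(cp);
      double sv = 0;
      for (int l = 0; l < cp; ++l) {
        v[l] = R::rgamma(gamma_[l] + sz[tau[kstar + l]], 1.0);
        sv += v[l];
      }
      for (int l = 0; l < cp; ++l) w[tau[kstar + l]] = v[l] / sv * S;
    }
  }

  // ---- RJMCMC sampler ------------------------------------------------------

  void rj_update_allocations(const std::vector<double> &theta,
                             const std::vector<double> &w) {
    std::vector<double> cum(64);
    for (int i = 0; i < X.n; ++i) {
      int lo = X.ptr[i], hi = X.ptr[i + 1];
      if ((int)cum.size() < hi - lo) cum.resize(hi - lo);
      double tot = 0;
      for (int j = lo; j < hi; ++j) { tot += theta[X.idx[j]] * X.f[j]; cum[j - lo] = tot; }
      double u = unif_rand() * tot;
      int pick = hi - 1;
      for (int j = lo; j < hi; ++j) if (u <= cum[j - lo]) { pick = j; break; }
      --sx[xi[i]]; xi[i] = X.idx[pick]; ++sx[xi[i]];
    }
    for (int j0 = 0; j0 < Y.n; ++j0) {
      int lo = Y.ptr[j0], hi = Y.ptr[j0 + 1];
      if ((int)cum.size() < hi - lo) cum.resize(hi - lo);
      double tot = 0;
      for (int j = lo; j < hi; ++j) { tot += w[Y.idx[j]] * Y.f[j]; cum[j - lo] = tot; }
      double u = unif_rand() * tot;
      int pick = hi - 1;
      for (int j = lo; j < hi; ++j) if (u <= cum[j - lo]) { pick = j; break; }
      --sz[zz[j0]]; zz[j0] = Y.idx[pick]; ++sz[zz[j0]];
    }
  }

  // change in the u-prior log density when the alive set changes and alpha is
  // not exchangeable: sum_k (alpha-tilde'_k - alpha-tilde_k) log theta_k
  double dlog_uprior(const std::vector<int> &al_new, int cp_new,
                     const std::vector<double> &theta) {
    if (ua) return 0.0;
    std::vector<double> at_new(K);
    int kstar = K - cp_new, dr = 0, ar = 0;
    for (int k = 0; k < K; ++k) {
      if (al_new[k]) at_new[k] = alpha[kstar + ar++];
      else at_new[k] = alpha[dr++];
    }
    double out = 0;
    for (int k = 0; k < K; ++k)
      out += (at_new[k] - at[k]) * std::log(theta[k]);
    return out;
  }

  void rj_move(std::vector<double> &theta, std::vector<double> &w) {
    double lodds = std::log(pi) - std::log1p(-pi);
    if (unif_rand() < 0.5) {  // ---- birth
      if (cp == K) { ++unavail; return; }
      ++b_prop;
      if (cp == 0) {
        int j1 = (int)(unif_rand() * K); if (j1 >= K) j1 = K - 1;
        int j2 = (int)(unif_rand() * (K - 1)); if (j2 >= K - 1) j2 = K - 2;
        if (j2 >= j1) ++j2;
        if (j2 < j1) std::swap(j1, j2);
        double e = unif_rand();
        double S2 = theta[j1] + theta[j2];
        double w1 = e * S2, w2 = (1 - e) * S2;
        std::vector<double> vnew{e, 1 - e};
        std::vector<int> al = alive; al[j1] = al[j2] = 1;
        double logA =
          sz[j1] * (std::log(w1) - std::log(theta[j1])) +
          sz[j2] * (std::log(w2) - std::log(theta[j2])) +
          2.0 * lodds +
          ldirichlet(vnew, gamma_.data(), 2) +
          dlog_uprior(al, 2, theta) +
          std::log(K * (K - 1) / 2.0);
        if (std::log(unif_rand()) < logA) {
          ++b_acc;
          alive[j1] = alive[j2] = 1; cp = 2;
          w[j1] = w1; w[j2] = w2;
          sync_maps();
        }
      } else {
        int nd = K - cp;
        int pickd = (int)(unif_rand() * nd); if (pickd >= nd) pickd = nd - 1;
        int j = -1;
        for (int k = 0, h = 0; k < K; ++k)
          if (!alive[k] && h++ == pickd) { j = k; break; }
        double e = unif_rand();
        double S = 0, szalive = 0;
        for (int k = 0; k < K; ++k) if (alive[k]) { S += theta[k]; szalive += sz[k]; }
        double S2 = S + theta[j];
        double scale = (1 - e) * S2 / S;
        // old and new v vectors in alive-ascending order
        std::vector<double> vold, vnew;
        vold.reserve(cp); vnew.reserve(cp + 1);
        for (int k = 0; k < K; ++k) {
          if (k == j) vnew.push_back(e);
          if (alive[k]) { vold.push_back(w[k] / S); vnew.push_back(w[k] * (1 - e) / S); }
        }
        std::vector<int> al = alive; al[j] = 1;
        double logA =
          szalive * std::log(scale) +
          sz[j] * (std::log(e * S2) - std::log(theta[j])) +
          lodds +
          ldirichlet(vnew, gamma_.data(), cp + 1) -
          ldirichlet(vold, gamma_.data(), cp) +
          dlog_uprior(al, cp + 1, theta) +
          std::log((double)(K - cp) / (cp + 1)) +
          (cp - 1) * std::log1p(-e);
        if (std::log(unif_rand()) < logA) {
          ++b_acc;
          for (int k = 0; k < K; ++k) if (alive[k]) w[k] *= scale;
          alive[j] = 1; ++cp;
          w[j] = e * S2;
          sync_maps();
        }
      }
    } else {                  // ---- death
      if (cp == 0) { ++unavail; return; }
      ++d_prop;
      if (cp == 2) {
        int j1 = -1, j2 = -1;
        for (int k = 0; k < K; ++k) if (alive[k]) { if (j1 < 0) j1 = k; else j2 = k; }
        double e = w[j1] / (w[j1] + w[j2]);
        std::vector<double> vcur{e, 1 - e};
        std::vector<int> al = alive; al[j1] = al[j2] = 0;
        double logA =
          sz[j1] * (std::log(theta[j1]) - std::log(w[j1])) +
          sz[j2] * (std::log(theta[j2]) - std::log(w[j2])) -
          2.0 * lodds -
          ldirichlet(vcur, gamma_.data(), 2) +
          dlog_uprior(al, 0, theta) -
          std::log(K * (K - 1) / 2.0);
        if (std::log(unif_rand()) < logA) {
          ++d_acc;
          alive[j1] = alive[j2] = 0; cp = 0;
          w[j1] = theta[j1]; w[j2] = theta[j2];
          sync_maps();
        }
      } else {  // cp >= 3: single death
        int picka = (int)(unif_rand() * cp); if (picka >= cp) picka = cp - 1;
        int j = -1;
        for (int k = 0, h = 0; k < K; ++k)
          if (alive[k] && h++ == picka) { j = k; break; }
        double S = 0, szalive_rest = 0;
        for (int k = 0; k < K; ++k) if (alive[k]) S += theta[k];
        for (int k = 0; k < K; ++k) if (alive[k] && k != j) szalive_rest += sz[k];
        double e = w[j] / S;
        double Spost = S - theta[j];
        double scale = Spost / ((1 - e) * S);
        std::vector<double> vcur, vpost;
        vcur.reserve(cp); vpost.reserve(cp - 1);
        for (int k = 0; k < K; ++k) {
          if (alive[k]) {
            vcur.push_back(w[k] / S);
            if (k != j) vpost.push_back(w[k] * scale / Spost);
          }
        }
        std::vector<int> al = alive; al[j] = 0;
        double logA =
          szalive_rest * std::log(scale) +
          sz[j] * (std::log(theta[j]) - std::log(w[j])) -
          lodds +
          ldirichlet(vpost, gamma_.data(), cp - 1) -
          ldirichlet(vcur, gamma_.data(), cp) +
          dlog_uprior(al, cp - 1, theta) +
          std::log((double)cp / (K - cp + 1)) -
          (cp - 2) * std::log1p(-e);
        if (std::log(unif_rand()) < logA) {
          ++d_acc;
          for (int k = 0; k < K; ++k) if (alive[k] && k != j) w[k] *= scale;
          alive[j] = 0; --cp;
          w[j] = theta[j];
          sync_maps();
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List run_chain_cpp(IntegerVector x_ptr, IntegerVector x_idx, NumericVector x_f,
                   IntegerVector y_ptr, IntegerVector y_idx, NumericVector y_f,
                   int K, NumericVector alpha, NumericVector gamma_,
                   bool pi_jeffreys, double pi_init,
                   int n_iter, int burn_in, int thin,
                   bool collapsed, bool sample_expression,
                   bool record_states, bool random_scan) {
  Csr X{x_ptr.begin(), x_idx.begin(), x_f.begin(), (int)x_ptr.size() - 1};
  Csr Y{y_ptr.begin(), y_idx.begin(), y_f.begin(), (int)y_ptr.size() - 1};
  Model mod(X, Y, K, alpha, gamma_);
  mod.pi = pi_init;
  mod.init_allocations();
  mod.sync_maps();
  mod.sync_sums();

  std::vector<double> theta(K, 1.0 / K), w(K, 1.0 / K);
  std::vector<double> qsum(K, 0.0), thsum(K, 0.0), wsum(K, 0.0);
  double pisum = 0;
  int n_kept = 0;
  int n_keep_total = (n_iter - burn_in + thin - 1) / thin;
  std::vector<int> codes;
  if (record_states) {
    if (K > 30) stop("record_states requires K <= 30");
    codes.reserve(n_keep_total);
  }
  int ncheck = std::min(50, std::max(1, n_keep_total));
  NumericMatrix trace_q(ncheck, K);
  IntegerVector trace_iter(ncheck);
  int check_at = 0;

  bool expr = sample_expression || !collapsed;

  for (int it = 0; it < n_iter; ++it) {
    if (collapsed) {
      mod.collapsed_update_x(random_scan);
      mod.collapsed_update_y(random_scan);
      mod.collapsed_update_c_block();
      mod.update_pi(pi_jeffreys);
    } else {
      mod.rj_update_allocations(theta, w);
      mod.draw_expression(theta, w);
      for (int rep = 0; rep < K; ++rep) mod.rj_move(theta, w);
      mod.update_pi(pi_jeffreys);
    }
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      if (collapsed && expr) mod.draw_expression(theta, w);
      for (int k = 0; k < K; ++k) {
        qsum[k] += mod.alive[k];
        if (expr) { thsum[k] += theta[k]; wsum[k] += w[k]; }
      }
      pisum += mod.pi;
      ++n_kept;
      if (record_states) {
        int code = 0;
        for (int k = 0; k < K; ++k) if (mod.alive[k]) code |= (1 << k);
        codes.push_back(code);
      }
      if (check_at < ncheck &&
          n_kept >= (int)((double)(check_at + 1) / ncheck * n_keep_total)) {
        for (int k = 0; k < K; ++k) trace_q(check_at, k) = qsum[k] / n_kept;
        trace_iter[check_at] = it + 1;
        ++check_at;
      }
    }
  }

  NumericVector q(K), thm(K), wm(K);
  for (int k = 0; k < K; ++k) {
    q[k] = qsum[k] / n_kept;
    thm[k] = expr ? thsum[k] / n_kept : NA_REAL;
    wm[k] = expr ? wsum[k] / n_kept : NA_REAL;
  }
  List diag = List::create(
    _["block_proposals"] = (double)mod.blk_prop,
    _["block_moves"] = (double)mod.blk_move,
    _["birth_proposed"] = (double)mod.b_prop,
    _["birth_accepted"] = (double)mod.b_acc,
    _["death_proposed"] = (double)mod.d_prop,
    _["death_accepted"] = (double)mod.d_acc,
    _["moves_unavailable"] = (double)mod.unavail);
  return List::create(
    _["q"] = q, _["theta_mean"] = thm, _["w_mean"] = wm,
    _["pi_mean"] = pisum / n_kept, _["n_kept"] = n_kept,
    _["c_final"] = IntegerVector(mod.alive.begin(), mod.alive.end()),
    _["counts_x"] = IntegerVector(mod.sx.begin(), mod.sx.end()),
    _["counts_y"] = IntegerVector(mod.sz.begin(), mod.sz.end()),
    _["xi"] = IntegerVector(mod.xi.begin(), mod.xi.end()),
    _["z"] = IntegerVector(mod.zz.begin(), mod.zz.end()),
    _["state_codes"] = record_states
      ? IntegerVector(codes.begin(), codes.end()) : IntegerVector(0),
    _["trace_q"] = trace_q, _["trace_iter"] = trace_iter,
    _["diagnostics"] = diag);
}
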