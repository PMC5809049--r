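// Core numerical engine: codon generators, pruning, endpoint-conditioned
// stochastic mapping (uniformization), conditional Metropolis-Hastings
// updates of the site/condition random effects, and the exact Gillespie
// forward simulator. All randomness goes through R's RNG so that seeded
// runs are bit-reproducible from R.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const int NC = 61; // sense codons

struct PairTab {
  int P;
  arma::ivec from, to, n1, n2, syn, aa_from, aa_to;
  arma::imat pair_id;                  // 61x61 -> pair index or -1
  std::vector<std::vector<int>> out;   // pair indices leaving each codon
  arma::ivec aa;                       // amino acid index per codon (0..19)
  arma::imat codon_nuc;                // 61x3 nucleotide indices (0..3)
};

static PairTab make_pairtab(const List& code) {
  PairTab tb;
  IntegerVector from = code["from"], to = code["to"], n1 = code["n1"],
                n2 = code["n2"], syn = code["syn"], aaf = code["aa_from"],
                aat = code["aa_to"], aa = code["aa"];
  IntegerMatrix cn = code["codon_nuc"];
  tb.P = from.size();
  tb.from.set_size(tb.P); tb.to.set_size(tb.P); tb.n1.set_size(tb.P);
  tb.n2.set_size(tb.P); tb.syn.set_size(tb.P);
  tb.aa_from.set_size(tb.P); tb.aa_to.set_size(tb.P);
  tb.pair_id.set_size(NC, NC); tb.pair_id.fill(-1);
  tb.out.assign(NC, std::vector<int>());
  for (int p = 0; p < tb.P; ++p) {
    tb.from(p) = from[p]; tb.to(p) = to[p];
    tb.n1(p) = n1[p]; tb.n2(p) = n2[p]; tb.syn(p) = syn[p];
    tb.aa_from(p) = aaf[p]; tb.aa_to(p) = aat[p];
    tb.pair_id(from[p], to[p]) = p;
    tb.out[from[p]].push_back(p);
  }
  tb.aa.set_size(NC);
  tb.codon_nuc.set_size(NC, 3);
  for (int c = 0; c < NC; ++c) {
    tb.aa(c) = aa[c];
    for (int j = 0; j < 3; ++j) tb.codon_nuc(c, j) = cn(c, j);
  }
  return tb;
}

static double pfix(double S) {
  if (std::fabs(S) < 1e-4) return 1.0 + S / 2.0 + S * S / 12.0;
  if (S > 0) return S / (1.0 - std::exp(-S));
  return -S * std::exp(S) / (1.0 - std::exp(S));
}

// build a DS (mode 0) or OM (mode 1) generator; fit is a 20-vector of log
// fitness (DS) and om the site/condition dN/dS (OM)
static void build_R(arma::mat& R, const PairTab& tb, const arma::mat& q4,
                    int mode, const arma::vec& logfit, double om) {
  R.zeros(NC, NC);
  for (int p = 0; p < tb.P; ++p) {
    double r = q4(tb.n1(p), tb.n2(p));
    if (!tb.syn(p)) {
      r *= (mode == 0) ? pfix(logfit(tb.aa_to(p)) - logfit(tb.aa_from(p)))
                       : om;
    }
    R(tb.from(p), tb.to(p)) = r;
  }
  R.diag() = -arma::sum(R, 1);
}

// stationary distribution (closed form): piprod (* fitness under DS)
static arma::vec stat_dist(const PairTab& tb, const arma::vec& pi4, int mode,
                           const arma::vec& fit) {
  arma::vec st(NC);
  for (int c = 0; c < NC; ++c) {
    double w = pi4(tb.codon_nuc(c, 0)) * pi4(tb.codon_nuc(c, 1)) *
               pi4(tb.codon_nuc(c, 2));
    if (mode == 0) w *= fit(tb.aa(c));
    st(c) = w;
  }
  return st / arma::accu(st);
}

struct SiteGen {
  arma::mat R, V;
  arma::vec eval, st, sqst;
  double mu;
  void decompose() {
    sqst = arma::sqrt(st);
    arma::mat S = R;
    for (int i = 0; i < NC; ++i)
      for (int j = 0; j < NC; ++j)
        S(i, j) = R(i, j) * sqst(i) / sqst(j);
    S = 0.5 * (S + S.t());
    arma::eig_sym(eval, V, S);
    mu = 1.05 * (-R.diag()).max();
  }
  // v -> P(t) v   (message toward the parent in pruning)
  arma::vec propagate(double t, const arma::vec& v) const {
    arma::vec y = V.t() * (sqst % v);
    y %= arma::exp(eval * t);
    return (V * y) / sqst;
  }
  // row s of P(t)
  arma::vec prow(double t, int s) const {
    arma::vec w = V.row(s).t() % arma::exp(eval * t);
    return ((V * w) % sqst) / sqst(s);
  }
};

static int sample_unnorm(const arma::vec& w) {
  double tot = 0;
  for (int i = 0; i < (int)w.n_elem; ++i) tot += std::max(w(i), 0.0);
  if (tot <= 0) return 0;
  double u = unif_rand() * tot, c = 0;
  for (int i = 0; i < (int)w.n_elem; ++i) {
    c += std::max(w(i), 0.0);
    if (u <= c) return i;
  }
  return w.n_elem - 1;
}

// one dwell segment of a mapped/simulated history
struct Seg { int site, eidx, state; double dwell; };
struct Ev  { int site, eidx, pair; };

// endpoint-conditioned path sampling by uniformization. The powers of the
// uniformized transition matrix B = I + R/mu are accumulated by repeated
// multiplication with B itself: B is elementwise non-negative, so the
// series is free of the catastrophic cancellation a spectral evaluation of
// (B^n)_{ab} can suffer, and the stored power vectors double as the bridge
// distribution for the intermediate states.
static void sample_path(const SiteGen& g, const PairTab& tb, double t,
                        int a, int b, int site, int eidx,
                        std::vector<Seg>& segs, std::vector<Ev>& evs) {
  double mu = g.mu;
  // transition probability P(t)_{ab} from the spectral form (sets the
  // normalizing constant of the jump-count distribution)
  arma::vec gab = g.V.row(a).t() % g.V.row(b).t();
  double scale = g.sqst(b) / g.sqst(a);
  double pab = arma::accu(gab % arma::exp(g.eval * t)) * scale;
  if (pab < 1e-300) pab = 1e-300;
  int nmax = (int)std::ceil(mu * t + 12.0 * std::sqrt(mu * t + 1.0) + 40.0);
  double u = unif_rand();
  // u_m = B^m e_b, built incrementally; (B^n)_{ab} = u_n(a)
  std::vector<arma::vec> upow;
  upow.reserve(16);
  arma::vec u0(NC, arma::fill::zeros);
  u0(b) = 1.0;
  upow.push_back(u0);
  double pois = std::exp(-mu * t);
  double cum = 0;
  int n = nmax;
  for (int k = 0; k <= nmax; ++k) {
    cum += pois * upow[k](a);
    if (u <= cum / pab) { n = k; break; }
    // next power: B v = v + (R v)/mu
    arma::vec nxt = upow[k] + (g.R * upow[k]) / mu;
    upow.push_back(nxt);
    pois *= mu * t / (k + 1);
  }
  if (n == 0) {
    segs.push_back({site, eidx, a, t});
    return;
  }
  // jump times: order statistics of n uniforms on (0, t)
  arma::vec times(n);
  for (int k = 0; k < n; ++k) times(k) = unif_rand() * t;
  times = arma::sort(times);
  // bridge over the uniformized chain (may contain virtual self-jumps):
  // P(s_j = s | s_{j-1}, b) ~ B(s_{j-1}, s) (B^{n-j})_{s, b}, and B only
  // connects single-nucleotide neighbours and self
  arma::ivec states(n + 1);
  states(0) = a; states(n) = b;
  for (int j = 1; j < n; ++j) {
    const arma::vec& rem = upow[n - j];
    int s0 = states(j - 1);
    double wself = (1.0 + g.R(s0, s0) / mu) * rem(s0);
    double tot = wself;
    double wnb[16];
    int cnt_nb = (int)tb.out[s0].size();
    for (int q = 0; q < cnt_nb; ++q) {
      int idx = tb.out[s0][q];
      wnb[q] = (g.R(s0, tb.to(idx)) / mu) * rem(tb.to(idx));
      tot += wnb[q];
    }
    int chosen = s0;
    if (tot > 0) {
      double pick = unif_rand() * tot, c = wself;
      for (int q = 0; q < cnt_nb && pick > c; ++q) {
        c += wnb[q];
        chosen = tb.to(tb.out[s0][q]);
      }
      if (pick <= wself) chosen = s0;
    }
    states(j) = chosen;
  }
  // compress virtual jumps into dwell segments + real events
  double prev = 0.0;
  int cur = a;
  for (int j = 1; j <= n; ++j) {
    if (states(j) != cur) {
      int pid = tb.pair_id(cur, states(j));
      if (pid < 0) {
        // can only happen for the forced final endpoint after numerical
        // degeneracy; keep the history legal by ignoring the illegal jump
        continue;
      }
      segs.push_back({site, eidx, cur, times(j - 1) - prev});
      evs.push_back({site, eidx, pid});
      prev = times(j - 1);
      cur = states(j);
    }
  }
  segs.push_back({site, eidx, cur, t - prev});
}

// log-likelihood of the mapped suffstats of one site/condition as a function
// of a DS fitness profile (synonymous terms, constant in F, are dropped)
static double loglik_fit(const PairTab& tb, const arma::mat& q4,
                         const arma::vec& logfit, const arma::vec& wait,
                         const arma::ivec& cnt) {
  double ll = 0;
  for (int p = 0; p < tb.P; ++p) {
    if (tb.syn(p)) continue;
    double r = q4(tb.n1(p), tb.n2(p)) *
               pfix(logfit(tb.aa_to(p)) - logfit(tb.aa_from(p)));
    if (cnt(p) > 0) ll += cnt(p) * std::log(std::max(r, 1e-300));
    if (wait(tb.from(p)) > 0) ll -= wait(tb.from(p)) * r;
  }
  return ll;
}

// persistent stochastic-mapping workspace: the sampled history is kept
// across calls so that several Metropolis-Hastings rounds can condition on
// one mapping (map_mode 2) before the next refresh (map_mode 1), matching
// the alternation of one mapping with a long series of MH updates
struct MapWS {
  std::vector<Seg> segs;
  std::vector<Ev> evs;
  arma::ivec rootstate;
  arma::vec elen0; // branch lengths at map time (dwells rescale with them)
  bool valid = false;
};

// [[Rcpp::export]]
SEXP cpp_map_ws() {
  return Rcpp::XPtr<MapWS>(new MapWS(), true);
}

// map_mode: 0 = likelihood only (no mapping), 1 = draw a fresh mapping into
// the workspace, 2 = reuse the stored mapping (no pruning, no spectral work)
// [[Rcpp::export]]
Rcpp::List cpp_sweep(IntegerMatrix edge, NumericVector elen,
                     IntegerVector econd, int ntip, IntegerMatrix tips,
                     List code, NumericMatrix q4_, NumericVector pi4_,
                     int mode, NumericVector Farr, NumericMatrix Om_,
                     NumericVector alpha, NumericVector beta, int root_cond,
                     SEXP wsp, int map_mode, int nrep_re, double delta_hi,
                     double delta_lo, double sigma_om, bool return_history) {
  Rcpp::XPtr<MapWS> ws(wsp);
  if (map_mode == 2 && !ws->valid)
    stop("no stored mapping to reuse");
  PairTab tb = make_pairtab(code);
  arma::mat q4(q4_.begin(), 4, 4);
  arma::vec pi4(pi4_.begin(), 4);
  int E = edge.nrow();
  int nsites = tips.ncol();
  IntegerVector fdim = Farr.attr("dim");
  int K = (mode == 0) ? fdim[1] : Om_.ncol();
  arma::cube F;
  if (mode == 0) F = arma::cube(Farr.begin(), nsites, K, 20);
  arma::mat Om(Om_.begin(), Om_.nrow(), Om_.ncol());

  int nnode = ntip;
  for (int e = 0; e < E; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  int root = ntip; // 0-based index of root node (ape convention ntip+1)

  if (map_mode == 1) {
    ws->segs.clear();
    ws->evs.clear();
    ws->segs.reserve((size_t)E * nsites + 1024);
    ws->rootstate.set_size(nsites);
    ws->rootstate.fill(-1);
    ws->elen0 = arma::vec(elen.begin(), E);
    ws->valid = false;
  }
  std::vector<Seg>& segs = ws->segs;
  std::vector<Ev>& evs = ws->evs;
  // per-edge dwell rescaling: branch-length updates since the last mapping
  // rescale the stored history proportionally
  arma::vec escale(E, arma::fill::ones);
  if (map_mode == 2) {
    for (int e = 0; e < E; ++e)
      if (ws->elen0(e) > 0) escale(e) = elen[e] / ws->elen0(e);
  }

  arma::cube W(NC, K, nsites, arma::fill::zeros);     // waits per codon
  arma::icube CNT(tb.P, K, nsites);
  CNT.zeros();
  arma::vec loglik(nsites);
  loglik.fill(NA_REAL);
  arma::imat nodestate(nnode, nsites); nodestate.fill(-1);

  std::vector<SiteGen> gen(K);
  arma::mat partial(NC, nnode);
  arma::vec logsc(nnode);

  for (int i = 0; i < nsites && map_mode != 2; ++i) {
    // generators for this site, all conditions
    for (int k = 0; k < K; ++k) {
      arma::vec logfit(20, arma::fill::zeros), fit(20, arma::fill::ones);
      double om = 1.0;
      if (mode == 0) {
        for (int a = 0; a < 20; ++a) {
          fit(a) = F(i, k, a);
          logfit(a) = std::log(fit(a));
        }
      } else {
        om = Om(i, k);
      }
      build_R(gen[k].R, tb, q4, mode, logfit, om);
      gen[k].st = stat_dist(tb, pi4, mode, fit);
      gen[k].decompose();
    }
    arma::vec rootfreq = gen[root_cond].st;

    // pruning (edges arrive in postorder)
    partial.ones();
    logsc.zeros();
    for (int t = 0; t < ntip; ++t) {
      int obs = tips(t, i);
      if (obs >= 0) {
        partial.col(t).zeros();
        partial(obs, t) = 1.0;
      }
    }
    for (int e = 0; e < E; ++e) {
      int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      const SiteGen& g = gen[econd[e]];
      arma::vec m = g.propagate(elen[e], partial.col(ch));
      double s = m.max();
      if (s <= 0) s = 1e-300;
      partial.col(par) %= (m / s);
      logsc(par) += logsc(ch) + std::log(s);
    }
    double lik = arma::accu(rootfreq % partial.col(root));
    loglik(i) = std::log(std::max(lik, 1e-300)) + logsc(root);

    if (map_mode != 1) continue;

    // sample node states top-down, then branch paths
    ws->rootstate(i) = sample_unnorm(rootfreq % partial.col(root));
    nodestate(root, i) = ws->rootstate(i);
    for (int e = E - 1; e >= 0; --e) { // reverse postorder = preorder
      int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      const SiteGen& g = gen[econd[e]];
      int sp = nodestate(par, i);
      arma::vec w = g.prow(elen[e], sp) % partial.col(ch);
      int sc = sample_unnorm(w);
      nodestate(ch, i) = sc;
      if (elen[e] > 0) {
        sample_path(g, tb, elen[e], sp, sc, i, e, segs, evs);
      } else if (sp != sc) {
        // zero-length branch cannot change state; force identity
        nodestate(ch, i) = sp;
      }
    }
  }

  if (map_mode == 1) ws->valid = true;
  bool have_map = (map_mode == 1 || map_mode == 2) && ws->valid;
  arma::ivec rootstate = have_map ? ws->rootstate
                                  : arma::ivec(nsites, arma::fill::value(-1));

  // suffstats per site/condition from the (possibly rescaled) mapping
  for (const Seg& s : segs) {
    W(s.state, econd[s.eidx], s.site) += s.dwell * escale(s.eidx);
  }
  for (const Ev& e : evs) CNT(e.pair, econd[e.eidx], e.site) += 1;

  // ---- conditional MH updates of the site/condition random effects ----
  arma::vec piprod(NC);
  for (int c = 0; c < NC; ++c)
    piprod(c) = pi4(tb.codon_nuc(c, 0)) * pi4(tb.codon_nuc(c, 1)) *
                pi4(tb.codon_nuc(c, 2));

  double acc_f = 0, try_f = 0, acc_o = 0, try_o = 0;
  arma::uvec aau = arma::conv_to<arma::uvec>::from(tb.aa);
  if (mode == 0 && nrep_re > 0) {
    for (int i = 0; i < nsites; ++i) {
      for (int k = 0; k < K; ++k) {
        arma::vec fit(20), logfit(20);
        for (int a = 0; a < 20; ++a) fit(a) = F(i, k, a);
        logfit = arma::log(fit);
        arma::vec wait = W.slice(i).col(k);
        arma::ivec cnt = CNT.slice(i).col(k);
        double cur_ll = loglik_fit(tb, q4, logfit, wait, cnt);
        bool has_root = have_map && (k == root_cond) && rootstate(i) >= 0;
        if (has_root) {
          cur_ll += logfit(tb.aa(rootstate(i))) -
                    std::log(arma::accu(piprod % fit.elem(aau)));
        }
        for (int rep = 0; rep < nrep_re; ++rep) {
          try_f += 1;
          // kernel mixture: local Dirichlet-centered random walks (two
          // concentrations) plus an independence draw from the uniform
          // Dirichlet prior, which guarantees global mixing
          double u = unif_rand();
          bool indep = u < 0.25;
          double delta = (u < 0.625) ? delta_hi : delta_lo;
          arma::vec prop(20);
          bool ok = true;
          for (int a = 0; a < 20; ++a) {
            prop(a) = R::rgamma(indep ? 1.0 : delta * fit(a), 1.0);
            if (!std::isfinite(prop(a))) ok = false;
          }
          double tot = arma::accu(prop);
          if (!ok || tot <= 0) continue;
          prop /= tot;
          if (prop.min() < 1e-12) continue; // numerically degenerate proposal
          double lq_fwd = 0, lq_rev = 0;
          if (!indep) {
            // Hastings ratio for the Dirichlet(delta * .) random-walk;
            // for the prior independence draw proposal and prior cancel
            for (int a = 0; a < 20; ++a) {
              lq_fwd += (delta * fit(a) - 1.0) * std::log(prop(a)) -
                        R::lgammafn(delta * fit(a));
              lq_rev += (delta * prop(a) - 1.0) * std::log(fit(a)) -
                        R::lgammafn(delta * prop(a));
            }
          }
          arma::vec logprop = arma::log(prop);
          double prop_ll = loglik_fit(tb, q4, logprop, wait, cnt);
          if (has_root) {
            prop_ll += logprop(tb.aa(rootstate(i))) -
                       std::log(arma::accu(piprod % prop.elem(aau)));
          }
          double lr = prop_ll - cur_ll + lq_rev - lq_fwd;
          if (std::log(unif_rand()) < lr) {
            fit = prop; logfit = logprop; cur_ll = prop_ll;
            acc_f += 1;
          }
        }
        for (int a = 0; a < 20; ++a) F(i, k, a) = fit(a);
      }
    }
  }
  if (mode == 1 && nrep_re > 0) {
    // per site/condition: nonsynonymous event count and neutral opportunity
    for (int i = 0; i < nsites; ++i) {
      for (int k = 0; k < K; ++k) {
        double nns = 0, opp = 0;
        arma::vec wait = W.slice(i).col(k);
        arma::ivec cnt = CNT.slice(i).col(k);
        for (int p = 0; p < tb.P; ++p) {
          if (tb.syn(p)) continue;
          nns += cnt(p);
          opp += wait(tb.from(p)) * q4(tb.n1(p), tb.n2(p));
        }
        double om = Om(i, k);
        double cur_ll = nns * std::log(om) - om * opp;
        for (int rep = 0; rep < nrep_re; ++rep) {
          try_o += 1;
          double prop, lr;
          double ll;
          if (unif_rand() < 0.25) {
            // independence draw from the Gamma(alpha, beta) prior
            prop = R::rgamma(alpha[k], beta[k]);
            if (!std::isfinite(prop) || prop <= 0) continue;
            ll = nns * std::log(prop) - prop * opp;
            lr = ll - cur_ll;
          } else {
            prop = om * std::exp(sigma_om * norm_rand());
            ll = nns * std::log(prop) - prop * opp;
            lr = ll - cur_ll +
                 (alpha[k] - 1.0) * (std::log(prop) - std::log(om)) -
                 (prop - om) / beta[k] + std::log(prop) - std::log(om);
          }
          if (std::log(unif_rand()) < lr) { om = prop; cur_ll = ll; acc_o += 1; }
        }
        Om(i, k) = om;
      }
    }
  }

  // ---- aggregates for the R-side global updates (with updated effects) ----
  // ebmat(e, 4*(n1) + n2) accumulates dwell * fitness-term for mutations
  // n1 -> n2 available from the occupied codons on edge e, so that the exit
  // integral for any mutation matrix q is ebmat %*% vec(q): this lets the
  // R side re-evaluate branch-length and mutation-model proposals exactly.
  arma::vec nb(E, arma::fill::zeros);
  arma::mat ebmat(E, 16, arma::fill::zeros);
  arma::mat n12(4, 4, arma::fill::zeros);
  arma::vec condwait(K, arma::fill::zeros);
  for (const Seg& s : segs) {
    int k = econd[s.eidx];
    double dw = s.dwell * escale(s.eidx);
    condwait(k) += dw;
    double om = (mode == 1) ? Om(s.site, k) : 1.0;
    for (int idx : tb.out[s.state]) {
      double fterm = 1.0;
      if (!tb.syn(idx)) {
        fterm = (mode == 0)
          ? pfix(std::log(F(s.site, k, tb.aa_to(idx))) -
                 std::log(F(s.site, k, tb.aa_from(idx))))
          : om;
      }
      ebmat(s.eidx, 4 * tb.n1(idx) + tb.n2(idx)) += dw * fterm;
    }
  }
  for (const Ev& e : evs) {
    nb(e.eidx) += 1;
    n12(tb.n1(e.pair), tb.n2(e.pair)) += 1;
  }

  List out = List::create(
    Named("loglik") = NumericVector(loglik.begin(), loglik.end()),
    Named("F") = Farr, Named("omega") = Om_,
    Named("nb") = NumericVector(nb.begin(), nb.end()),
    Named("ebmat") = wrap(ebmat),
    Named("n12") = wrap(n12),
    Named("rootstate") = IntegerVector(rootstate.begin(), rootstate.end()),
    Named("condwait") = NumericVector(condwait.begin(), condwait.end()),
    Named("acc_f") = acc_f, Named("try_f") = try_f,
    Named("acc_o") = acc_o, Named("try_o") = try_o);
  if (mode == 0) {
    NumericVector Fout(F.begin(), F.end());
    Fout.attr("dim") = fdim;
    out["F"] = Fout;
  } else {
    NumericMatrix Oout(Om.n_rows, Om.n_cols, Om.begin());
    out["omega"] = Oout;
  }
  if (return_history) {
    int ns = segs.size(), ne = evs.size();
    IntegerVector ss(ns), se(ns), sst(ns); NumericVector sd(ns);
    for (int j = 0; j < ns; ++j) {
      ss[j] = segs[j].site + 1; se[j] = segs[j].eidx + 1;
      sst[j] = segs[j].state + 1; sd[j] = segs[j].dwell * escale(segs[j].eidx);
    }
    IntegerVector es(ne), ee(ne), ef(ne), et(ne);
    for (int j = 0; j < ne; ++j) {
      es[j] = evs[j].site + 1; ee[j] = evs[j].eidx + 1;
      ef[j] = tb.from(evs[j].pair) + 1; et[j] = tb.to(evs[j].pair) + 1;
    }
    out["segments"] = DataFrame::create(
      Named("site") = ss, Named("edge") = se, Named("state") = sst,
      Named("dwell") = sd);
    out["events"] = DataFrame::create(
      Named("site") = es, Named("edge") = ee, Named("from") = ef,
      Named("to") = et);
    out["nodestate"] = wrap(nodestate);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_simulate(IntegerMatrix edge, NumericVector elen,
                        IntegerVector econd, int ntip, List code,
                        NumericMatrix q4_, NumericVector pi4_, int mode,
                        NumericVector Farr, NumericMatrix Om_, int root_cond,
                        bool return_events) {
  PairTab tb = make_pairtab(code);
  arma::mat q4(q4_.begin(), 4, 4);
  arma::vec pi4(pi4_.begin(), 4);
  int E = edge.nrow();
  IntegerVector fdim = Farr.attr("dim");
  int nsites = (mode == 0) ? fdim[0] : Om_.nrow();
  int K = (mode == 0) ? fdim[1] : Om_.ncol();
  arma::cube F;
  if (mode == 0) F = arma::cube(Farr.begin(), nsites, K, 20);
  arma::mat Om(Om_.begin(), Om_.nrow(), Om_.ncol());
  int nnode = ntip;
  for (int e = 0; e < E; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  int root = ntip;

  // neutral per-codon synonymous / non-synonymous opportunity rates
  arma::vec syn0(NC, arma::fill::zeros), ns0(NC, arma::fill::zeros);
  for (int p = 0; p < tb.P; ++p) {
    if (tb.syn(p)) syn0(tb.from(p)) += q4(tb.n1(p), tb.n2(p));
    else ns0(tb.from(p)) += q4(tb.n1(p), tb.n2(p));
  }

  IntegerMatrix tips(ntip, nsites);
  IntegerVector rootstates(nsites);
  arma::vec nsyn(K, arma::fill::zeros), nnonsyn(K, arma::fill::zeros),
      syn_opp(K, arma::fill::zeros), ns_opp(K, arma::fill::zeros);
  arma::vec edge_subs(E, arma::fill::zeros);
  std::vector<int> ev_site, ev_edge, ev_from, ev_to;
  std::vector<double> ev_time;

  std::vector<arma::mat> R(K);
  std::vector<arma::vec> st(K);
  arma::ivec nodestate(nnode);

  for (int i = 0; i < nsites; ++i) {
    for (int k = 0; k < K; ++k) {
      arma::vec logfit(20, arma::fill::zeros), fit(20, arma::fill::ones);
      double om = 1.0;
      if (mode == 0) {
        for (int a = 0; a < 20; ++a) {
          fit(a) = F(i, k, a); logfit(a) = std::log(fit(a));
        }
      } else om = Om(i, k);
      R[k].set_size(NC, NC);
      build_R(R[k], tb, q4, mode, logfit, om);
      st[k] = stat_dist(tb, pi4, mode, fit);
    }
    nodestate.fill(-1);
    nodestate(root) = sample_unnorm(st[root_cond]);
    rootstates[i] = nodestate(root) + 1;
    for (int e = E - 1; e >= 0; --e) { // reverse postorder = top-down
      int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      int k = econd[e];
      const arma::mat& Rk = R[k];
      int s = nodestate(par);
      double t = elen[e], tau = 0;
      while (true) {
        double exr = -Rk(s, s);
        double dt = (exr > 0) ? exp_rand() / exr : t + 1;
        double dwell = std::min(dt, t - tau);
        syn_opp(k) += dwell * syn0(s);
        ns_opp(k) += dwell * ns0(s);
        if (tau + dt >= t) break;
        tau += dt;
        arma::vec w = Rk.row(s).t();
        w(s) = 0;
        int s2 = sample_unnorm(w);
        int pid = tb.pair_id(s, s2);
        if (pid >= 0 && tb.syn(pid)) nsyn(k) += 1; else nnonsyn(k) += 1;
        edge_subs(e) += 1;
        if (return_events) {
          ev_site.push_back(i + 1); ev_edge.push_back(e + 1);
          ev_from.push_back(s + 1); ev_to.push_back(s2 + 1);
          ev_time.push_back(tau);
        }
        s = s2;
      }
      nodestate(ch) = s;
      if (ch < ntip) tips(ch, i) = s + 1;
    }
  }

  List out = List::create(
    Named("tips") = tips, Named("rootstate") = rootstates,
    Named("nsyn") = NumericVector(nsyn.begin(), nsyn.end()),
    Named("nnonsyn") = NumericVector(nnonsyn.begin(), nnonsyn.end()),
    Named("syn_opp") = NumericVector(syn_opp.begin(), syn_opp.end()),
    Named("ns_opp") = NumericVector(ns_opp.begin(), ns_opp.end()),
    Named("edge_subs") = NumericVector(edge_subs.begin(), edge_subs.end()));
  if (return_events) {
    out["events"] = DataFrame::create(
      Named("site") = ev_site, Named("edge") = ev_edge,
      Named("from") = ev_from, Named("to") = ev_to,
      Named("time") = ev_time);
  }
  return out;
}

// forward Gillespie paths from a fixed start state: used as an independent
// oracle for the endpoint-conditioned path sampler
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_forward_paths(NumericMatrix R_, int a, double t,
                                      int nrep) {
  arma::mat R(R_.begin(), R_.nrow(), R_.ncol());
  int n = R.n_rows;
  IntegerMatrix out(nrep, 2);
  for (int rep = 0; rep < nrep; ++rep) {
    int s = a - 1, jumps = 0;
    double tau = 0;
    while (true) {
      double exr = -R(s, s);
      double dt = (exr > 0) ? exp_rand() / exr : t + 1;
      if (tau + dt >= t) break;
      tau += dt;
      arma::vec w = R.row(s).t();
      w(s) = 0;
      s = sample_unnorm(w);
      ++jumps;
    }
    out(rep, 0) = jumps;
    out(rep, 1) = s + 1;
    if (n == 0) break;
  }
  return out;
}
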