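#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Diploid Li-Stephens forward-backward over the ordered haplotype-pair state
// space K^2.  Each haplotype independently jumps to a uniformly random
// template with probability tau per interval, so the transition operator is
// rank-structured:
//   f'(i,j) = (1-tau)^2 f(i,j) + (1-tau)(tau/K)(r_i + c_j) + (tau/K)^2 T
// (r/c/T = row/column/total sums), giving O(K^2) work per site.  Emissions
// depend only on the template allele sum s = a_i + a_j.
//
// Numerics: per-site normalization is folded into the update coefficients
// (the state matrix is never rescaled in place), and row/column/total sums
// are accumulated in double during the same pass that writes the matrix.
// Forward matrices are checkpointed every ~sqrt(M) sites and recomputed per
// block on the backward sweep, so memory is O(K^2 sqrt(M)).  State matrices
// use double precision for small panels (where exhaustive-enumeration
// agreement at 1e-10 is meaningful) and single precision with double
// accumulators for large panels, where the per-site normalization keeps all
// entries well scaled.

static void copy_model(double lambda, double M3[3][3]) {
  // P(g | template sum s): each allele copies its template with prob 1-lambda
  const double q = 1.0 - lambda;
  M3[0][0] = q * q;           M3[0][1] = 2.0 * q * lambda;        M3[0][2] = lambda * lambda;
  M3[1][0] = q * lambda;      M3[1][1] = q * q + lambda * lambda;  M3[1][2] = q * lambda;
  M3[2][0] = lambda * lambda; M3[2][1] = 2.0 * q * lambda;        M3[2][2] = q * q;
}

template <typename real>
struct Sums { std::vector<double> r, c; double T; };

// fused step: dst = transition(src / S_src) .* e, accumulating dst sums.
// src sums (r, c, T) are for the *unnormalized* src; S_src = src total.
template <typename real>
static void fwd_step(const real* src, real* dst, int K, double tau,
                     const Sums<real>& ss, Sums<real>& ds,
                     const int* a, const double w[3],
                     std::vector<real>& e0, std::vector<real>& e1) {
  const double inv = 1.0 / ss.T;
  const double A = (1.0 - tau) * (1.0 - tau) * inv;
  const double u = tau / (double)K;
  const double B = (1.0 - tau) * u * inv;
  const double C = u * u;          // times T*inv = 1
  for (int j = 0; j < K; ++j) { e0[j] = (real)w[a[j]]; e1[j] = (real)w[a[j] + 1]; }
  std::vector<real> cadd(K);
  for (int j = 0; j < K; ++j) cadd[j] = (real)(B * ss.c[j]);
  std::fill(ds.c.begin(), ds.c.end(), 0.0);
  double T = 0.0;
  for (int i = 0; i < K; ++i) {
    const real* srow = src + (size_t)i * K;
    real* drow = dst + (size_t)i * K;
    const real* e = (a[i] == 1) ? e1.data() : e0.data();
    const real radd = (real)(B * ss.r[i] + C);
    const real Ar = (real)A;
    double rs = 0.0;
    double* cacc = ds.c.data();
    for (int j = 0; j < K; ++j) {
      const real v = (Ar * srow[j] + radd + cadd[j]) * e[j];
      drow[j] = v; rs += v; cacc[j] += v;
    }
    ds.r[i] = rs; T += rs;
  }
  ds.T = T;
}

// initial site: uniform prior times emission
template <typename real>
static void init_site(real* dst, int K, Sums<real>& ds, const int* a,
                      const double w[3], std::vector<real>& e0,
                      std::vector<real>& e1) {
  for (int j = 0; j < K; ++j) { e0[j] = (real)w[a[j]]; e1[j] = (real)w[a[j] + 1]; }
  std::fill(ds.c.begin(), ds.c.end(), 0.0);
  double T = 0.0;
  for (int i = 0; i < K; ++i) {
    real* drow = dst + (size_t)i * K;
    const real* e = (a[i] == 1) ? e1.data() : e0.data();
    double rs = 0.0;
    for (int j = 0; j < K; ++j) { const real v = e[j]; drow[j] = v; rs += v; ds.c[j] += v; }
    ds.r[i] = rs; T += rs;
  }
  ds.T = T;
}

// fused posterior + backward-emission sweep at site t:
//   S[s]   += f(i,j) b(i,j) over states with a_i + a_j = s
//   g(i,j)  = b(i,j) * e_t(i,j), with sums of g accumulated
template <typename real>
static void post_and_g(const real* f, const real* b, real* g, int K,
                       const int* a, const double w[3], double S[3],
                       Sums<real>& gs, std::vector<real>& e0,
                       std::vector<real>& e1) {
  for (int j = 0; j < K; ++j) { e0[j] = (real)w[a[j]]; e1[j] = (real)w[a[j] + 1]; }
  S[0] = S[1] = S[2] = 0.0;
  std::fill(gs.c.begin(), gs.c.end(), 0.0);
  double T = 0.0;
  for (int i = 0; i < K; ++i) {
    const real* frow = f + (size_t)i * K;
    const real* brow = b + (size_t)i * K;
    real* grow = g + (size_t)i * K;
    const real* e = (a[i] == 1) ? e1.data() : e0.data();
    double acc = 0.0, acc1 = 0.0, rs = 0.0;
    double* cacc = gs.c.data();
    for (int j = 0; j < K; ++j) {
      const double v = (double)frow[j] * (double)brow[j];
      acc += v; acc1 += v * a[j];
      const real gv = brow[j] * e[j];
      grow[j] = gv; rs += gv; cacc[j] += gv;
    }
    S[a[i]] += acc - acc1;
    S[a[i] + 1] += acc1;
    gs.r[i] = rs; T += rs;
  }
  gs.T = T;
}

// backward transition: bprev = transition(g / S_g); accumulates bprev sums
template <typename real>
static void bwd_step(const real* g, real* bprev, int K, double tau,
                     const Sums<real>& gsums, Sums<real>& bs) {
  const double inv = 1.0 / gsums.T;
  const double A = (1.0 - tau) * (1.0 - tau) * inv;
  const double u = tau / (double)K;
  const double B = (1.0 - tau) * u * inv;
  const double C = u * u;
  std::vector<real> cadd(K);
  for (int j = 0; j < K; ++j) cadd[j] = (real)(B * gsums.c[j]);
  std::fill(bs.c.begin(), bs.c.end(), 0.0);
  double T = 0.0;
  for (int i = 0; i < K; ++i) {
    const real* grow = g + (size_t)i * K;
    real* brow = bprev + (size_t)i * K;
    const real radd = (real)(B * gsums.r[i] + C);
    const real Ar = (real)A;
    double rs = 0.0;
    double* cacc = bs.c.data();
    for (int j = 0; j < K; ++j) {
      const real v = Ar * grow[j] + radd + cadd[j];
      brow[j] = v; rs += v; cacc[j] += v;
    }
    bs.r[i] = rs; T += rs;
  }
  bs.T = T;
}

template <typename real>
static NumericMatrix fb_impl(const IntegerMatrix& hap, const NumericMatrix& emis,
                             const NumericVector& tau, double lambda) {
  const int K = hap.nrow(), M = hap.ncol();
  double M3[3][3];
  copy_model(lambda, M3);

  // per-site emission weights by template sum
  std::vector<double> W((size_t)M * 3);
  for (int t = 0; t < M; ++t) {
    double tot = 0.0;
    for (int g = 0; g < 3; ++g) {
      if (emis(t, g) < 0) stop("negative emission weight at site %d", t + 1);
      tot += emis(t, g);
    }
    if (tot <= 0.0) stop("all-zero emission column at site %d", t + 1);
    for (int s = 0; s < 3; ++s) {
      double w = 0.0;
      for (int g = 0; g < 3; ++g) w += emis(t, g) * M3[s][g];
      W[(size_t)t * 3 + s] = w;
    }
  }

  const size_t KK = (size_t)K * K;
  const int blk = std::max(1, (int)std::ceil(std::sqrt((double)M)));
  const int nblk = (M + blk - 1) / blk;
  const int* hp = INTEGER(hap);

  std::vector<real> f(KK), b(KK), g(KK), e0(K), e1(K);
  Sums<real> fs, bs, gs, cs;
  for (Sums<real>* s : {&fs, &bs, &gs, &cs}) { s->r.assign(K, 0.0); s->c.assign(K, 0.0); s->T = 0.0; }
  std::vector< std::vector<real> > ckpt(nblk);
  std::vector< std::vector<double> > ckpt_r(nblk), ckpt_c(nblk);
  std::vector<double> ckpt_T(nblk);
  std::vector<real> cache((size_t)blk * KK);
  std::vector<Sums<real>> cache_s(blk);
  for (int i = 0; i < blk; ++i) { cache_s[i].r.assign(K, 0.0); cache_s[i].c.assign(K, 0.0); }

  // ---- forward pass with checkpoints ----
  init_site(f.data(), K, fs, hp, &W[0], e0, e1);
  if (fs.T <= 0.0) stop("impossible emission at site 1");
  for (int t = 0; t < M; ++t) {
    if (t % blk == 0) {
      const int bi = t / blk;
      ckpt[bi].assign(f.begin(), f.end());
      ckpt_r[bi] = fs.r; ckpt_c[bi] = fs.c; ckpt_T[bi] = fs.T;
    }
    if (t + 1 < M) {
      fwd_step(f.data(), g.data(), K, (double)tau[t], fs, bs,
               hp + (size_t)(t + 1) * K, &W[(size_t)(t + 1) * 3], e0, e1);
      std::swap(f, g); std::swap(fs, bs);
      if (!(fs.T > 0.0)) stop("impossible emission at site %d", t + 2);
    }
  }

  // ---- backward sweep with per-block forward recomputation ----
  NumericMatrix post(M, 3);
  std::fill(b.begin(), b.end(), (real)1.0);
  bs.T = (double)KK;
  std::fill(bs.r.begin(), bs.r.end(), (double)K);
  std::fill(bs.c.begin(), bs.c.end(), (double)K);

  for (int bi = nblk - 1; bi >= 0; --bi) {
    const int s0 = bi * blk;
    const int s1 = std::min(M, s0 + blk);
    std::copy(ckpt[bi].begin(), ckpt[bi].end(), cache.begin());
    cache_s[0].r = ckpt_r[bi]; cache_s[0].c = ckpt_c[bi]; cache_s[0].T = ckpt_T[bi];
    for (int t = s0 + 1; t < s1; ++t)
      fwd_step(cache.data() + (size_t)(t - 1 - s0) * KK,
               cache.data() + (size_t)(t - s0) * KK, K, (double)tau[t - 1],
               cache_s[t - 1 - s0], cache_s[t - s0],
               hp + (size_t)t * K, &W[(size_t)t * 3], e0, e1);

    for (int t = s1 - 1; t >= s0; --t) {
      const real* ft = cache.data() + (size_t)(t - s0) * KK;
      const int* at = hp + (size_t)t * K;
      const double* wt = &W[(size_t)t * 3];
      double S[3];
      post_and_g(ft, b.data(), g.data(), K, at, wt, S, gs, e0, e1);
      double pg[3], ptot = 0.0;
      for (int gg = 0; gg < 3; ++gg) {
        double v = 0.0;
        for (int s = 0; s < 3; ++s)
          if (S[s] > 0.0 && wt[s] > 0.0)
            v += S[s] * emis(t, gg) * M3[s][gg] / wt[s];
        pg[gg] = v; ptot += v;
      }
      if (!(ptot > 0.0)) stop("posterior underflow at site %d", t + 1);
      for (int gg = 0; gg < 3; ++gg) post(t, gg) = pg[gg] / ptot;
      if (t > 0) {
        bwd_step(g.data(), b.data(), K, (double)tau[t - 1], gs, bs);
        if (!(bs.T > 0.0)) stop("posterior underflow at site %d", t);
      }
    }
  }
  return post;
}

// [[Rcpp::export(name = ".fb_diploid_cpp")]]
NumericMatrix fb_diploid_cpp(IntegerMatrix hap, NumericMatrix emis,
                             NumericVector tau, double lambda) {
  const int K = hap.nrow(), M = hap.ncol();
  if (K < 1 || M < 1) stop("panel must have at least one haplotype and one site");
  if (emis.nrow() != M || emis.ncol() != 3) stop("emission matrix must be n_sites x 3");
  if (M > 1 && tau.size() != M - 1) stop("tau must have length n_sites - 1");
  if (K <= 64) return fb_impl<double>(hap, emis, tau, lambda);
  return fb_impl<float>(hap, emis, tau, lambda);
}
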