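#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Diploid Li-Stephens copying HMM: hidden state is an ordered pair (i, j) of
// reference-panel haplotypes; each haplotype switches independently with
// per-interval probability 1 - exp(-switch_rate * distance) and, on a switch,
// lands uniformly on the panel (staying put is allowed). Emissions arrive as
// per-site linear-scale likelihood triples L(g), g in {0,1,2}, so the same
// engine serves genotype-likelihood and hard-call modes.
//
// Numerics: scaled-probability recursions. Scaling constants are folded into
// the transition coefficients of the next step instead of renormalizing the
// K^2 table in place, so each site costs two passes forward and three
// backward. The uniform switch destination collapses the K^4 transition sum
// to row/column sums. Per-site emissions over states take only three values
// (copied genotype 0/1/2), precomputed as two per-column lookup vectors so
// the hot loops stay branch- and gather-free.
//
// lik is an n x M x 3 array (individual, site, genotype), column-major.
// Returns the posterior genotype probabilities as an n x M x 3 array.

// [[Rcpp::export]]
NumericVector cpp_diploid_fb(const IntegerMatrix& H, const NumericVector& pos,
                             const NumericVector& lik, double switch_rate,
                             double mu) {
  const int K = H.nrow();
  const int M = H.ncol();
  const size_t KK = (size_t)K * K;
  const int n = (int)(lik.size() / ((size_t)M * 3));

  // P(true genotype g | copied genotype d) under per-allele miscopy mu
  double P[3][3];
  const double cc = 1.0 - mu;
  P[0][0] = cc * cc;   P[0][1] = 2 * mu * cc;       P[0][2] = mu * mu;
  P[1][0] = mu * cc;   P[1][1] = cc * cc + mu * mu; P[1][2] = mu * cc;
  P[2][0] = mu * mu;   P[2][1] = 2 * mu * cc;       P[2][2] = cc * cc;

  std::vector<double> sw(M, 0.0);
  for (int m = 1; m < M; ++m)
    sw[m] = 1.0 - std::exp(-switch_rate * (pos[m] - pos[m - 1]));

  // panel columns as raw int pointers (column-major)
  const int* Hp = INTEGER(H);

  std::vector<double> A(M * KK);          // forward table, all sites
  std::vector<double> atot(M);            // its per-site sums
  std::vector<double> B(KK), Bnew(KK), gam(KK);
  std::vector<double> r(K), c(K), rg(K), cg(K);
  std::vector<double> e0(K), e1(K), h1(K), h0(K);
  NumericVector out((size_t)n * M * 3);

  for (int ind = 0; ind < n; ++ind) {
    // ---------------- forward ----------------
    for (int m = 0; m < M; ++m) {
      const int* Hm = Hp + (size_t)m * K;
      const double L0 = lik[ind + (size_t)n * (m + (size_t)M * 0)];
      const double L1 = lik[ind + (size_t)n * (m + (size_t)M * 1)];
      const double L2 = lik[ind + (size_t)n * (m + (size_t)M * 2)];
      double E[3];
      for (int d = 0; d < 3; ++d)
        E[d] = P[d][0] * L0 + P[d][1] * L1 + P[d][2] * L2;
      for (int j = 0; j < K; ++j) {       // emission for row-allele 0 / 1
        e0[j] = E[Hm[j]];
        e1[j] = E[Hm[j] + 1];
      }
      double* Am = &A[(size_t)m * KK];
      double tot = 0.0;
      if (m == 0) {
        for (int i = 0; i < K; ++i) {
          const double* e = Hm[i] ? e1.data() : e0.data();
          double* Arow = Am + (size_t)i * K;
          double rs = 0.0;
          for (int j = 0; j < K; ++j) { Arow[j] = e[j]; rs += e[j]; }
          tot += rs;
        }
      } else {
        const double* Ap = &A[(size_t)(m - 1) * KK];
        const double inv = 1.0 / atot[m - 1];
        const double s = sw[m], ns = 1.0 - s, q = s / K;
        for (int i = 0; i < K; ++i) { r[i] = 0.0; c[i] = 0.0; }
        for (int i = 0; i < K; ++i) {
          const double* row = Ap + (size_t)i * K;
          double rs = 0.0;
          for (int j = 0; j < K; ++j) { rs += row[j]; c[j] += row[j]; }
          r[i] = rs;
        }
        // scaling of the previous site folded into the coefficients;
        // the q^2 term multiplies the normalized table total, i.e. 1
        const double ns2 = ns * ns * inv, nsq = ns * q * inv,
                     qq_tot = q * q;
        for (int i = 0; i < K; ++i) {
          const double* e = Hm[i] ? e1.data() : e0.data();
          const double* Aprow = Ap + (size_t)i * K;
          double* Arow = Am + (size_t)i * K;
          const double base = nsq * r[i] + qq_tot;
          double rs = 0.0;
          for (int j = 0; j < K; ++j) {
            const double v = (ns2 * Aprow[j] + nsq * c[j] + base) * e[j];
            Arow[j] = v; rs += v;
          }
          tot += rs;
        }
      }
      if (tot <= 0.0) {  // fully contradictory emissions: reset flat
        for (size_t x = 0; x < KK; ++x) Am[x] = 1.0;
        tot = (double)KK;
      }
      atot[m] = tot;
    }

    // ---------------- backward + genotype posteriors ----------------
    double btot = (double)KK;
    for (size_t x = 0; x < KK; ++x) B[x] = 1.0;
    for (int m = M - 1; m >= 0; --m) {
      const int* Hm = Hp + (size_t)m * K;
      const double L[3] = {
        lik[ind + (size_t)n * (m + (size_t)M * 0)],
        lik[ind + (size_t)n * (m + (size_t)M * 1)],
        lik[ind + (size_t)n * (m + (size_t)M * 2)]};
      double E[3];
      for (int d = 0; d < 3; ++d)
        E[d] = P[d][0] * L[0] + P[d][1] * L[1] + P[d][2] * L[2];
      for (int j = 0; j < K; ++j) {
        e0[j] = E[Hm[j]];
        e1[j] = E[Hm[j] + 1];
        h1[j] = (double)Hm[j];
        h0[j] = 1.0 - h1[j];
      }
      const double* Am = &A[(size_t)m * KK];
      // posterior state mass grouped by copied genotype d = h_i + h_j
      double U[3] = {0.0, 0.0, 0.0};
      for (int i = 0; i < K; ++i) {
        const double* Arow = Am + (size_t)i * K;
        const double* Brow = &B[(size_t)i * K];
        double s0 = 0.0, s1 = 0.0;
        for (int j = 0; j < K; ++j) {
          const double ab = Arow[j] * Brow[j];
          s0 += ab * h0[j];
          s1 += ab * h1[j];
        }
        U[Hm[i]] += s0;
        U[Hm[i] + 1] += s1;
      }
      // P(g | data) propto L(g) * sum_d [U_d / E_d] * P(g | d): the forward
      // entries carry the factor E_d, which must be swapped for the
      // genotype-specific term.
      double gp[3], gtot = 0.0;
      for (int g = 0; g < 3; ++g) {
        double acc = 0.0;
        for (int d = 0; d < 3; ++d)
          if (E[d] > 0.0) acc += U[d] * P[d][g] / E[d];
        gp[g] = acc * L[g]; gtot += gp[g];
      }
      if (gtot <= 0.0) { gp[0] = gp[1] = gp[2] = 1.0; gtot = 3.0; }
      for (int g = 0; g < 3; ++g)
        out[ind + (size_t)n * (m + (size_t)M * g)] = gp[g] / gtot;

      if (m > 0) {
        const double s = sw[m], ns = 1.0 - s, q = s / K;
        const double inv = 1.0 / btot;
        double gtot2 = 0.0;
        for (int i = 0; i < K; ++i) { rg[i] = 0.0; cg[i] = 0.0; }
        for (int i = 0; i < K; ++i) {
          const double* e = Hm[i] ? e1.data() : e0.data();
          const double* Brow = &B[(size_t)i * K];
          double* grow = &gam[(size_t)i * K];
          double rs = 0.0;
          for (int j = 0; j < K; ++j) {
            const double v = e[j] * Brow[j];
            grow[j] = v; rs += v; cg[j] += v;
          }
          rg[i] = rs; gtot2 += rs;
        }
        const double ns2 = ns * ns * inv, nsq = ns * q * inv,
                     qq = q * q * inv * gtot2;
        double bt = 0.0;
        for (int i = 0; i < K; ++i) {
          const double base = nsq * rg[i] + qq;
          const double* grow = &gam[(size_t)i * K];
          double* brow = &Bnew[(size_t)i * K];
          double rs = 0.0;
          for (int j = 0; j < K; ++j) {
            const double v = ns2 * grow[j] + nsq * cg[j] + base;
            brow[j] = v; rs += v;
          }
          bt += rs;
        }
        if (bt <= 0.0) {
          for (size_t x = 0; x < KK; ++x) Bnew[x] = 1.0;
          bt = (double)KK;
        }
        B.swap(Bnew);
        btot = bt;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = IntegerVector::create(n, M, 3);
  return out;
}

// Mosaic haplotype generator: each new haplotype copies a uniformly chosen
// source row of H, switching source with probability 1 - exp(-switch_rate *
// distance) at each inter-site interval (uniform re-draw, staying allowed),
// and flipping the copied allele with probability mutation_rate. Uses R's
// RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
IntegerMatrix cpp_mosaic_haplotypes(const IntegerMatrix& H,
                                    const NumericVector& pos, int n_hap,
                                    double switch_rate, double mutation_rate) {
  const int K = H.nrow(), M = H.ncol();
  std::vector<double> sw(M, 0.0);
  for (int m = 1; m < M; ++m)
    sw[m] = 1.0 - std::exp(-switch_rate * (pos[m] - pos[m - 1]));
  IntegerMatrix out(n_hap, M);
  for (int h = 0; h < n_hap; ++h) {
    int k = (int)(unif_rand() * K); if (k >= K) k = K - 1;
    for (int m = 0; m < M; ++m) {
      if (m > 0 && sw[m] > 0.0 && unif_rand() < sw[m]) {
        k = (int)(unif_rand() * K); if (k >= K) k = K - 1;
      }
      int a = H(k, m);
      if (mutation_rate > 0.0 && unif_rand() < mutation_rate) a = 1 - a;
      out(h, m) = a;
    }
  }
  return out;
}
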