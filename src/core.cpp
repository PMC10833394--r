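#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Warren-Cowley / lattice machinery
// ---------------------------------------------------------------------------

static inline int wrap(int a, int n) {
  int r = a % n;
  return r < 0 ? r + n : r;
}

// labels: length L1*L2*L3 integer vector (1 = A, 0 = B), column-major in
// (n1, n2, n3). vecs: m x 3 integer matrix of lattice vectors.
// Returns p_AB(v) = fraction of A sites with B at site + v (periodic).
// [[Rcpp::export]]
NumericVector cpp_pair_probabilities(IntegerVector labels, IntegerVector dims,
                                     IntegerMatrix vecs) {
  const int L1 = dims[0], L2 = dims[1], L3 = dims[2];
  const int m = vecs.nrow();
  long nA = 0;
  for (int s = 0; s < labels.size(); ++s) nA += labels[s];
  NumericVector p(m);
  if (nA == 0) return p;
  for (int v = 0; v < m; ++v) {
    const int v1 = vecs(v, 0), v2 = vecs(v, 1), v3 = vecs(v, 2);
    long cnt = 0;
    for (int k = 0; k < L3; ++k) {
      const int kk = wrap(k + v3, L3);
      for (int j = 0; j < L2; ++j) {
        const int jj = wrap(j + v2, L2);
        for (int i = 0; i < L1; ++i) {
          const int s = i + L1 * (j + L2 * k);
          if (labels[s] == 1) {
            const int ii = wrap(i + v1, L1);
            const int t = ii + L1 * (jj + L2 * kk);
            if (labels[t] == 0) ++cnt;
          }
        }
      }
    }
    p[v] = (double)cnt / (double)nA;
  }
  return p;
}

// Count of ordered (A at r, B at r + axis unit vector) pairs for the three axes.
static void axis_counts(const IntegerVector &labels, int L1, int L2, int L3,
                        long cnt[3]) {
  cnt[0] = cnt[1] = cnt[2] = 0;
  for (int k = 0; k < L3; ++k)
    for (int j = 0; j < L2; ++j)
      for (int i = 0; i < L1; ++i) {
        const int s = i + L1 * (j + L2 * k);
        if (labels[s] != 1) continue;
        if (labels[wrap(i + 1, L1) + L1 * (j + L2 * k)] == 0) ++cnt[0];
        if (labels[i + L1 * (wrap(j + 1, L2) + L2 * k)] == 0) ++cnt[1];
        if (labels[i + L1 * (j + L2 * wrap(k + 1, L3))] == 0) ++cnt[2];
      }
}

// Metropolis annealing with composition-conserving swap moves.
// Cost = sum over axes of (alpha_axis - target_axis)^2 where
// alpha = 1 - p_AB / m_B. Geometric temperature schedule t0 -> t1.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_mc_anneal(IntegerVector labels, IntegerVector dims,
                   NumericVector targets, int sweeps, double t0, double t1) {
  const int L1 = dims[0], L2 = dims[1], L3 = dims[2];
  const long N = (long)L1 * L2 * L3;
  IntegerVector lab = clone(labels);
  long nA = 0;
  for (long s = 0; s < N; ++s) nA += lab[s];
  const long nB = N - nA;
  if (nA == 0 || nB == 0) stop("degenerate configuration: single species");
  const double mB = (double)nB / (double)N;

  long cnt[3];
  axis_counts(lab, L1, L2, L3, cnt);

  auto alpha_of = [&](long c) { return 1.0 - ((double)c / nA) / mB; };
  auto cost_of = [&](const long c[3]) {
    double cost = 0.0;
    for (int a = 0; a < 3; ++a) {
      double d = alpha_of(c[a]) - targets[a];
      cost += d * d;
    }
    return cost;
  };

  double cost = cost_of(cnt);
  const long total_moves = (long)sweeps * N;
  const double decay =
      total_moves > 1 ? std::pow(t1 / t0, 1.0 / (double)(total_moves - 1)) : 1.0;
  double temp = t0;

  // pair contribution helper: pair identified by left-site coords and axis
  const int ax1[3] = {1, 0, 0}, ax2[3] = {0, 1, 0}, ax3[3] = {0, 0, 1};
  (void)ax1; (void)ax2; (void)ax3;

  GetRNGstate();
  for (long mv = 0; mv < total_moves; ++mv, temp *= decay) {
    // pick one A site and one B site by rejection
    long si, sj;
    do { si = (long)(unif_rand() * N); if (si >= N) si = N - 1; } while (lab[si] != 1);
    do { sj = (long)(unif_rand() * N); if (sj >= N) sj = N - 1; } while (lab[sj] != 0);

    const int i1 = (int)(si % L1), i2 = (int)((si / L1) % L2), i3 = (int)(si / ((long)L1 * L2));
    const int j1 = (int)(sj % L1), j2 = (int)((sj / L1) % L2), j3 = (int)(sj / ((long)L1 * L2));

    long dcnt[3] = {0, 0, 0};
    // affected ordered pairs per axis: left sites {r - e, r} for r in {si, sj}
    for (int a = 0; a < 3; ++a) {
      int lefts[4][3];
      int nl = 0;
      int ci[3] = {i1, i2, i3}, cj[3] = {j1, j2, j3};
      int Ld[3] = {L1, L2, L3};
      // left sites of pairs containing si: (si - e_a, si) and (si, si + e_a)
      int cand[4][3] = {{ci[0], ci[1], ci[2]}, {ci[0], ci[1], ci[2]},
                        {cj[0], cj[1], cj[2]}, {cj[0], cj[1], cj[2]}};
      cand[0][a] = wrap(cand[0][a] - 1, Ld[a]);
      cand[2][a] = wrap(cand[2][a] - 1, Ld[a]);
      for (int c = 0; c < 4; ++c) {
        bool dup = false;
        for (int d = 0; d < nl; ++d)
          if (lefts[d][0] == cand[c][0] && lefts[d][1] == cand[c][1] &&
              lefts[d][2] == cand[c][2]) { dup = true; break; }
        if (!dup) {
          lefts[nl][0] = cand[c][0]; lefts[nl][1] = cand[c][1];
          lefts[nl][2] = cand[c][2]; ++nl;
        }
      }
      long before = 0, after = 0;
      for (int c = 0; c < nl; ++c) {
        int r1 = lefts[c][0], r2 = lefts[c][1], r3 = lefts[c][2];
        int q1 = r1, q2 = r2, q3 = r3;
        if (a == 0) q1 = wrap(q1 + 1, L1);
        else if (a == 1) q2 = wrap(q2 + 1, L2);
        else q3 = wrap(q3 + 1, L3);
        const long ls = r1 + (long)L1 * (r2 + (long)L2 * r3);
        const long rs = q1 + (long)L1 * (q2 + (long)L2 * q3);
        int ll = lab[ls], lr = lab[rs];
        if (ll == 1 && lr == 0) ++before;
        // after swap: labels at si and sj flip
        int lls = (ls == si || ls == sj) ? 1 - ll : ll;
        int lrs = (rs == si || rs == sj) ? 1 - lr : lr;
        if (lls == 1 && lrs == 0) ++after;
      }
      dcnt[a] = after - before;
    }

    long newc[3] = {cnt[0] + dcnt[0], cnt[1] + dcnt[1], cnt[2] + dcnt[2]};
    const double newcost = cost_of(newc);
    const double dcost = newcost - cost;
    if (dcost <= 0.0 || unif_rand() < std::exp(-dcost / temp)) {
      lab[si] = 0;
      lab[sj] = 1;
      cnt[0] = newc[0]; cnt[1] = newc[1]; cnt[2] = newc[2];
      cost = newcost;
    }
  }
  PutRNGstate();

  NumericVector achieved(3);
  for (int a = 0; a < 3; ++a) achieved[a] = alpha_of(cnt[a]);
  return List::create(_["labels"] = lab, _["cost"] = cost,
                      _["achieved"] = achieved);
}

// Cosine series over stored Warren-Cowley vectors:
// I(pixel) = sum_v weight_v * alpha_v * cos(2*pi * frac(pixel) . v)
// frac: npix x 3 fractional (h,k,l); vecs: m x 3; result unscaled.
// [[Rcpp::export]]
NumericVector cpp_cosine_plane(NumericMatrix frac, NumericMatrix vecs,
                               NumericVector alphas, NumericVector weights) {
  const int n = frac.nrow(), m = vecs.nrow();
  NumericVector out(n);
  const double twopi = 2.0 * M_PI;
  for (int v = 0; v < m; ++v) {
    const double w = weights[v] * alphas[v];
    if (w == 0.0) continue;
    const double v1 = vecs(v, 0), v2 = vecs(v, 1), v3 = vecs(v, 2);
    for (int p = 0; p < n; ++p) {
      const double ph = twopi * (frac(p, 0) * v1 + frac(p, 1) * v2 + frac(p, 2) * v3);
      out[p] += w * std::cos(ph);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Minimal conv-net primitives (column-major arrays, dims (H, W, C))
// ---------------------------------------------------------------------------

// y[i,j,co] = b[co] + sum_{u,v,ci} x[i*s - p + u, j*s - p + v, ci] * w[u,v,ci,co]
// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y((long)Ho * Wo * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int jo = 0; jo < Wo; ++jo) {
      const int j0 = jo * stride - pad;
      for (int io = 0; io < Ho; ++io) {
        const int i0 = io * stride - pad;
        double acc = bias[co];
        for (int ci = 0; ci < Cin; ++ci) {
          const long xoff = (long)H * (W * ci);
          const long woff = (long)kh * (kw * (ci + (long)Cin * co));
          for (int v = 0; v < kw; ++v) {
            const int xj = j0 + v;
            if (xj < 0 || xj >= W) continue;
            for (int u = 0; u < kh; ++u) {
              const int xi = i0 + u;
              if (xi < 0 || xi >= H) continue;
              acc += x[xi + (long)H * xj + xoff] * w[u + (long)kh * v + woff];
            }
          }
        }
        y[io + (long)Ho * jo + (long)Ho * Wo * co] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];

  NumericVector dx((long)H * W * Cin);
  dx.attr("dim") = IntegerVector::create(H, W, Cin);
  NumericVector dw((long)kh * kw * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector db(Cout);

  for (int co = 0; co < Cout; ++co) {
    for (int jo = 0; jo < Wo; ++jo) {
      const int j0 = jo * stride - pad;
      for (int io = 0; io < Ho; ++io) {
        const int i0 = io * stride - pad;
        const double g = dy[io + (long)Ho * jo + (long)Ho * Wo * co];
        if (g == 0.0) continue;
        db[co] += g;
        for (int ci = 0; ci < Cin; ++ci) {
          const long xoff = (long)H * (W * ci);
          const long woff = (long)kh * (kw * (ci + (long)Cin * co));
          for (int v = 0; v < kw; ++v) {
            const int xj = j0 + v;
            if (xj < 0 || xj >= W) continue;
            for (int u = 0; u < kh; ++u) {
              const int xi = i0 + u;
              if (xi < 0 || xi >= H) continue;
              const long xidx = xi + (long)H * xj + xoff;
              const long widx = u + (long)kh * v + woff;
              dw[widx] += g * x[xidx];
              dx[xidx] += g * w[widx];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
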