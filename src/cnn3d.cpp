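// Compact 3D convolutional regressor: stacked (conv 3x3x3 stride 2 /
// batch normalisation / ReLU) blocks, global average pooling, dropout head
// and a single linear map to the output vector. Forward and backward
// passes use im2col + BLAS matrix products. Batch-norm statistics are
// taken over the whole mini-batch during training (with running averages
// maintained for inference), and gradients flow through a masked
// mean-squared-error loss normalised by the number of unmasked entries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const int K = 3;        // kernel edge
const int STRIDE = 2;
const int PAD = 1;
const double BN_EPS = 1e-5;
const double BN_MOMENTUM = 0.1;

struct Dims { int x, y, z; int vox() const { return x * y * z; } };

Dims outDims(const Dims& d) {
  auto o = [](int n) { return (n + 2 * PAD - K) / STRIDE + 1; };
  return {o(d.x), o(d.y), o(d.z)};
}

// input feature map F: (V_in x C_in); returns (V_out x 27*C_in)
mat im2col(const mat& F, const Dims& in, const Dims& out) {
  const int Cin = F.n_cols;
  mat X(out.vox(), 27 * Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const double* src = F.colptr(c);
    for (int kz = 0; kz < K; ++kz)
      for (int ky = 0; ky < K; ++ky)
        for (int kx = 0; kx < K; ++kx) {
          const int col = 27 * c + kz * 9 + ky * 3 + kx;
          double* dst = X.colptr(col);
          for (int oz = 0; oz < out.z; ++oz) {
            const int iz = STRIDE * oz + kz - PAD;
            if (iz < 0 || iz >= in.z) continue;
            for (int oy = 0; oy < out.y; ++oy) {
              const int iy = STRIDE * oy + ky - PAD;
              if (iy < 0 || iy >= in.y) continue;
              for (int ox = 0; ox < out.x; ++ox) {
                const int ix = STRIDE * ox + kx - PAD;
                if (ix < 0 || ix >= in.x) continue;
                dst[ox + out.x * (oy + out.y * oz)] =
                    src[ix + in.x * (iy + in.y * iz)];
              }
            }
          }
        }
  }
  return X;
}

// scatter-add of column gradients back onto the input feature map
mat col2im(const mat& dX, const Dims& in, const Dims& out, int Cin) {
  mat dF(in.vox(), Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    double* dst = dF.colptr(c);
    for (int kz = 0; kz < K; ++kz)
      for (int ky = 0; ky < K; ++ky)
        for (int kx = 0; kx < K; ++kx) {
          const int col = 27 * c + kz * 9 + ky * 3 + kx;
          const double* src = dX.colptr(col);
          for (int oz = 0; oz < out.z; ++oz) {
            const int iz = STRIDE * oz + kz - PAD;
            if (iz < 0 || iz >= in.z) continue;
            for (int oy = 0; oy < out.y; ++oy) {
              const int iy = STRIDE * oy + ky - PAD;
              if (iy < 0 || iy >= in.y) continue;
              for (int ox = 0; ox < out.x; ++ox) {
                const int ix = STRIDE * ox + kx - PAD;
                if (ix < 0 || ix >= in.x) continue;
                dst[ix + in.x * (iy + in.y * iz)] +=
                    src[ox + out.x * (oy + out.y * oz)];
              }
            }
          }
        }
  }
  return dF;
}

struct Layer {       // parameter views for one conv/BN block
  mat W;             // (27*Cin x Cout), no conv bias (absorbed by BN beta)
  rowvec gamma, beta;
};

struct Net {
  std::vector<Layer> conv;
  mat Wout;          // (Clast x nOut)
  vec bout;          // nOut
};

long paramCount(const std::vector<int>& ch, int nOut) {
  long n = 0;
  int cin = 1;
  for (size_t l = 0; l < ch.size(); ++l) {
    n += 27L * cin * ch[l] + 2L * ch[l];
    cin = ch[l];
  }
  n += (long)cin * nOut + nOut;
  return n;
}

Net unpack(const vec& params, const std::vector<int>& ch, int nOut) {
  Net net;
  int cin = 1;
  size_t off = 0;
  for (size_t l = 0; l < ch.size(); ++l) {
    const int cout = ch[l];
    net.conv.push_back(Layer());
    net.conv[l].W = reshape(params.subvec(off, off + 27 * cin * cout - 1),
                            27 * cin, cout);
    off += 27 * cin * cout;
    net.conv[l].gamma = params.subvec(off, off + cout - 1).t();
    off += cout;
    net.conv[l].beta = params.subvec(off, off + cout - 1).t();
    off += cout;
    cin = cout;
  }
  net.Wout = reshape(params.subvec(off, off + (size_t)cin * nOut - 1),
                     cin, nOut);
  off += (size_t)cin * nOut;
  net.bout = params.subvec(off, off + nOut - 1);
  return net;
}

void packGrad(const Net& g, const std::vector<int>& ch, int nOut, vec& out) {
  size_t off = 0;
  int cin = 1;
  for (size_t l = 0; l < ch.size(); ++l) {
    out.subvec(off, off + 27 * cin * ch[l] - 1) = vectorise(g.conv[l].W);
    off += 27 * cin * ch[l];
    out.subvec(off, off + ch[l] - 1) = g.conv[l].gamma.t();
    off += ch[l];
    out.subvec(off, off + ch[l] - 1) = g.conv[l].beta.t();
    off += ch[l];
    cin = ch[l];
  }
  out.subvec(off, off + (size_t)cin * nOut - 1) = vectorise(g.Wout);
  off += (size_t)cin * nOut;
  out.subvec(off, off + nOut - 1) = g.bout;
}

// running batch-norm statistics: per layer (mean, var) per channel,
// concatenated [mean_1, var_1, mean_2, var_2, ...]
std::vector<std::pair<rowvec, rowvec>> unpackStats(
    const vec& stats, const std::vector<int>& ch) {
  std::vector<std::pair<rowvec, rowvec>> out;
  size_t off = 0;
  for (size_t l = 0; l < ch.size(); ++l) {
    rowvec m = stats.subvec(off, off + ch[l] - 1).t();
    off += ch[l];
    rowvec v = stats.subvec(off, off + ch[l] - 1).t();
    off += ch[l];
    out.push_back({m, v});
  }
  return out;
}

struct BlockCache {
  std::vector<mat> Xcol;   // per sample
  std::vector<mat> Ynorm;  // per sample, pre-affine normalised conv output
  std::vector<mat> relu;   // per sample, post-ReLU activation
  rowvec invstd;
  Dims in, out;
};

}  // namespace

// [[Rcpp::export]]
int cnnParamCount(Rcpp::IntegerVector channels, int nOut) {
  std::vector<int> ch(channels.begin(), channels.end());
  return (int)paramCount(ch, nOut);
}

// inference-mode forward using running statistics
// [[Rcpp::export]]
arma::mat cnnPredictCpp(const arma::vec& params, const arma::vec& runStats,
                        Rcpp::IntegerVector dims,
                        Rcpp::IntegerVector channels,
                        const arma::mat& vols, int nOut) {
  std::vector<int> ch(channels.begin(), channels.end());
  if ((long)params.n_elem != paramCount(ch, nOut))
    Rcpp::stop("parameter vector has the wrong length");
  Net net = unpack(params, ch, nOut);
  auto stats = unpackStats(runStats, ch);
  Dims d0 = {dims[0], dims[1], dims[2]};
  const int n = vols.n_cols;
  mat preds(nOut, n);
  for (int s = 0; s < n; ++s) {
    mat F = vols.col(s);
    Dims din = d0;
    for (size_t l = 0; l < ch.size(); ++l) {
      Dims dout = outDims(din);
      mat Z = im2col(F, din, dout) * net.conv[l].W;
      rowvec invstd = 1.0 / sqrt(stats[l].second + BN_EPS);
      Z.each_row() -= stats[l].first;
      Z.each_row() %= invstd % net.conv[l].gamma;
      Z.each_row() += net.conv[l].beta;
      F = Z % conv_to<mat>::from(Z > 0);
      din = dout;
    }
    rowvec f = mean(F, 0);
    preds.col(s) = net.Wout.t() * f.t() + net.bout;
  }
  return preds;
}

// training-mode loss + gradient over one mini-batch; batch-norm statistics
// are computed jointly over the batch and the updated running averages are
// returned alongside the gradient
// [[Rcpp::export]]
Rcpp::List cnnLossGradCpp(const arma::vec& params, const arma::vec& runStats,
                          Rcpp::IntegerVector dims,
                          Rcpp::IntegerVector channels,
                          const arma::mat& vols, const arma::mat& targets,
                          const arma::mat& masks, const arma::mat& dropMask,
                          int nOut) {
  std::vector<int> ch(channels.begin(), channels.end());
  if ((long)params.n_elem != paramCount(ch, nOut))
    Rcpp::stop("parameter vector has the wrong length");
  Net net = unpack(params, ch, nOut);
  auto stats = unpackStats(runStats, ch);
  Dims d0 = {dims[0], dims[1], dims[2]};
  const int n = vols.n_cols;
  const size_t L = ch.size();

  const double totalUnmasked = accu(masks == 0);
  if (totalUnmasked == 0) Rcpp::stop("batch has no unmasked target entries");

  // ---- forward, batch statistics per layer ----
  std::vector<BlockCache> cache(L);
  std::vector<mat> F(n);
  for (int s = 0; s < n; ++s) F[s] = vols.col(s);
  Dims din = d0;
  vec newStats(runStats.n_elem);
  size_t soff = 0;
  for (size_t l = 0; l < L; ++l) {
    Dims dout = outDims(din);
    cache[l].in = din;
    cache[l].out = dout;
    cache[l].Xcol.resize(n);
    cache[l].Ynorm.resize(n);
    cache[l].relu.resize(n);
    rowvec sum1(ch[l], fill::zeros), sum2(ch[l], fill::zeros);
    const double Nvox = (double)n * dout.vox();
    for (int s = 0; s < n; ++s) {
      cache[l].Xcol[s] = im2col(F[s], din, dout);
      mat Z = cache[l].Xcol[s] * net.conv[l].W;
      sum1 += sum(Z, 0);
      sum2 += sum(square(Z), 0);
      cache[l].Ynorm[s] = std::move(Z);  // normalised in place below
    }
    rowvec mu = sum1 / Nvox;
    rowvec v = sum2 / Nvox - square(mu);
    v = clamp(v, 0.0, datum::inf);
    rowvec invstd = 1.0 / sqrt(v + BN_EPS);
    cache[l].invstd = invstd;
    newStats.subvec(soff, soff + ch[l] - 1) =
        ((1 - BN_MOMENTUM) * stats[l].first + BN_MOMENTUM * mu).t();
    newStats.subvec(soff + ch[l], soff + 2 * ch[l] - 1) =
        ((1 - BN_MOMENTUM) * stats[l].second + BN_MOMENTUM * v).t();
    soff += 2 * ch[l];
    for (int s = 0; s < n; ++s) {
      mat& Z = cache[l].Ynorm[s];
      Z.each_row() -= mu;
      Z.each_row() %= invstd;
      mat A = Z;
      A.each_row() %= net.conv[l].gamma;
      A.each_row() += net.conv[l].beta;
      cache[l].relu[s] = A % conv_to<mat>::from(A > 0);
      F[s] = cache[l].relu[s];
    }
    din = dout;
  }

  // ---- head ----
  const int cLast = ch[L - 1];
  mat feats(cLast, n);
  for (int s = 0; s < n; ++s) feats.col(s) = mean(F[s], 0).t();
  mat H = feats % dropMask;
  mat Yhat = net.Wout.t() * H;
  Yhat.each_col() += net.bout;
  mat Wm = conv_to<mat>::from(masks == 0);
  mat R = (Yhat - targets) % Wm;
  double loss = accu(square(R)) / totalUnmasked;

  // ---- backward ----
  Net grad;
  int cin = 1;
  for (size_t l = 0; l < L; ++l) {
    grad.conv.push_back(Layer());
    grad.conv[l].W = mat(27 * cin, ch[l], fill::zeros);
    grad.conv[l].gamma = rowvec(ch[l], fill::zeros);
    grad.conv[l].beta = rowvec(ch[l], fill::zeros);
    cin = ch[l];
  }
  mat dY = 2.0 * R / totalUnmasked;          // (nOut x n)
  grad.Wout = H * dY.t();
  grad.bout = sum(dY, 1);
  mat dH = net.Wout * dY;                    // (cLast x n)
  mat dF = dH % dropMask;                    // grad wrt GAP features

  // per-sample grads wrt the last activation maps
  std::vector<mat> dA(n);
  for (int s = 0; s < n; ++s) {
    const int V = cache[L - 1].out.vox();
    dA[s] = repmat(dF.col(s).t() / V, V, 1);
  }
  for (int l = (int)L - 1; l >= 0; --l) {
    BlockCache& cb = cache[l];
    const double Nvox = (double)n * cb.out.vox();
    // accumulate batch-norm reduction terms over the whole batch
    rowvec sdY(ch[l], fill::zeros), sdYY(ch[l], fill::zeros);
    std::vector<mat> dZaff(n);
    for (int s = 0; s < n; ++s) {
      mat reluMask = conv_to<mat>::from(cb.relu[s] > 0);
      dZaff[s] = dA[s] % reluMask;           // grad wrt affine BN output
      grad.conv[l].beta += sum(dZaff[s], 0);
      grad.conv[l].gamma += sum(dZaff[s] % cb.Ynorm[s], 0);
      mat dYn = dZaff[s];
      dYn.each_row() %= net.conv[l].gamma;   // grad wrt normalised output
      sdY += sum(dYn, 0);
      sdYY += sum(dYn % cb.Ynorm[s], 0);
      dZaff[s] = std::move(dYn);
    }
    rowvec mdY = sdY / Nvox;
    rowvec mdYY = sdYY / Nvox;
    for (int s = 0; s < n; ++s) {
      mat dZ = dZaff[s];
      dZ.each_row() -= mdY;
      dZ -= cb.Ynorm[s] % repmat(mdYY, cb.out.vox(), 1);
      dZ.each_row() %= cb.invstd;
      grad.conv[l].W += cb.Xcol[s].t() * dZ;
      if (l > 0)
        dA[s] = col2im(dZ * net.conv[l].W.t(), cb.in, cb.out, ch[l - 1]);
    }
  }

  vec g(params.n_elem);
  packGrad(grad, ch, nOut, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = g,
                            Rcpp::Named("runStats") = newStats);
}

// [[Rcpp::export]]
arma::vec trilinearResampleCpp(const arma::vec& vol, Rcpp::IntegerVector from,
                               Rcpp::IntegerVector to) {
  const int fx = from[0], fy = from[1], fz = from[2];
  const int tx = to[0], ty = to[1], tz = to[2];
  auto coord = [](int i, int nOut, int nIn) {
    // cell-centre mapping, clamped to the valid range
    double c = (i + 0.5) * (double)nIn / nOut - 0.5;
    if (c < 0) c = 0;
    if (c > nIn - 1) c = nIn - 1;
    return c;
  };
  std::vector<int> x0(tx), y0(ty), z0(tz), x1(tx), y1(ty), z1(tz);
  std::vector<double> wx(tx), wy(ty), wz(tz);
  for (int i = 0; i < tx; ++i) {
    double c = coord(i, tx, fx);
    x0[i] = (int)std::floor(c); x1[i] = std::min(x0[i] + 1, fx - 1);
    wx[i] = c - x0[i];
  }
  for (int i = 0; i < ty; ++i) {
    double c = coord(i, ty, fy);
    y0[i] = (int)std::floor(c); y1[i] = std::min(y0[i] + 1, fy - 1);
    wy[i] = c - y0[i];
  }
  for (int i = 0; i < tz; ++i) {
    double c = coord(i, tz, fz);
    z0[i] = (int)std::floor(c); z1[i] = std::min(z0[i] + 1, fz - 1);
    wz[i] = c - z0[i];
  }
  arma::vec out((size_t)tx * ty * tz);
  auto at = [&](int x, int y, int z) {
    return vol[(size_t)x + (size_t)fx * (y + (size_t)fy * z)];
  };
  size_t o = 0;
  for (int z = 0; z < tz; ++z)
    for (int y = 0; y < ty; ++y)
      for (int x = 0; x < tx; ++x, ++o) {
        const double c00 = at(x0[x], y0[y], z0[z]) * (1 - wx[x]) +
                           at(x1[x], y0[y], z0[z]) * wx[x];
        const double c10 = at(x0[x], y1[y], z0[z]) * (1 - wx[x]) +
                           at(x1[x], y1[y], z0[z]) * wx[x];
        const double c01 = at(x0[x], y0[y], z1[z]) * (1 - wx[x]) +
                           at(x1[x], y0[y], z1[z]) * wx[x];
        const double c11 = at(x0[x], y1[y], z1[z]) * (1 - wx[x]) +
                           at(x1[x], y1[y], z1[z]) * wx[x];
        const double c0 = c00 * (1 - wy[y]) + c10 * wy[y];
        const double c1 = c01 * (1 - wy[y]) + c11 * wy[y];
        out[o] = c0 * (1 - wz[z]) + c1 * wz[z];
      }
  return out;
}
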