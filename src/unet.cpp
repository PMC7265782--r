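// Small fully-convolutional encoder-decoder ("U-net style") for lymphocyte
// segmentation, with exact backpropagation. The encoder is a ResNet-style
// stack of five stride-2 stages (each a downsampling 3x3 conv followed by a
// two-conv residual unit); the decoder is five upsampling blocks, each a
// 2x2 transposed convolution, concatenation with the matching encoder skip
// (the RGB input for the last block), and two 3x3 convolutions. A final 1x1
// conv produces per-pixel logits. Loss is mean pixelwise binary
// cross-entropy on the sigmoid output.
//
// Implemented from scratch because no deep-learning runtime is available in
// the target environment. Gradients are verified against finite differences
// in the test suite.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvCache {
  arma::mat col; // im2col of the input
  int H, W, C, Ho, Wo;
};

arma::mat im2col(const arma::cube& X, int k, int s, int p, int& Ho, int& Wo) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  Ho = (H + 2 * p - k) / s + 1;
  Wo = (W + 2 * p - k) / s + 1;
  arma::mat col(Ho * (size_t)Wo, (size_t)k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        const int cidx = c * k * k + ki * k + kj;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * s - p + kj;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * s - p + ki;
            if (i < 0 || i >= H) continue;
            col(oi + (size_t)oj * Ho, cidx) = X(i, j, c);
          }
        }
      }
  return col;
}

arma::cube col2im(const arma::mat& col, int H, int W, int C, int k, int s,
                  int p, int Ho, int Wo) {
  arma::cube X(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        const int cidx = c * k * k + ki * k + kj;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * s - p + kj;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * s - p + ki;
            if (i < 0 || i >= H) continue;
            X(i, j, c) += col(oi + (size_t)oj * Ho, cidx);
          }
        }
      }
  return X;
}

arma::cube mat_to_cube(const arma::mat& Y, int Ho, int Wo) {
  arma::cube out(Ho, Wo, Y.n_cols);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  return out;
}

arma::mat cube_to_mat(const arma::cube& X) {
  arma::mat out(X.n_rows * (size_t)X.n_cols, X.n_slices);
  std::memcpy(out.memptr(), X.memptr(), sizeof(double) * X.n_elem);
  return out;
}

arma::cube conv_fwd(const arma::cube& X, const arma::mat& Wm,
                    const arma::vec& b, int k, int s, int p, ConvCache* cc) {
  int Ho, Wo;
  arma::mat col = im2col(X, k, s, p, Ho, Wo);
  arma::mat Y = col * Wm;
  Y.each_row() += b.t();
  if (cc) {
    cc->H = X.n_rows; cc->W = X.n_cols; cc->C = X.n_slices;
    cc->Ho = Ho; cc->Wo = Wo;
    cc->col = std::move(col);
  }
  return mat_to_cube(Y, Ho, Wo);
}

arma::cube conv_bwd(const arma::cube& dY, const ConvCache& cc,
                    const arma::mat& Wm, int k, int s, int p, arma::mat& dW,
                    arma::vec& db) {
  arma::mat dYm = cube_to_mat(dY);
  dW = cc.col.t() * dYm;
  db = arma::sum(dYm, 0).t();
  arma::mat dcol = dYm * Wm.t();
  return col2im(dcol, cc.H, cc.W, cc.C, k, s, p, cc.Ho, cc.Wo);
}

// 2x2 stride-2 transposed conv; weight layout: Cin x (4*Cout), column index
// cout*4 + ki*2 + kj. Output is exactly (2H, 2W, Cout); blocks do not
// overlap, so forward/backward are pure rearrangements around a mat-mul.
arma::cube tconv_fwd(const arma::cube& X, const arma::mat& Wm,
                     const arma::vec& b) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cout = Wm.n_cols / 4;
  arma::mat Yc = cube_to_mat(X) * Wm;
  arma::cube Y(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) {
    Y.slice(co).fill(b(co));
    for (int ki = 0; ki < 2; ++ki)
      for (int kj = 0; kj < 2; ++kj) {
        const double* v = Yc.colptr(co * 4 + ki * 2 + kj);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            Y(2 * i + ki, 2 * j + kj, co) += v[i + (size_t)j * H];
      }
  }
  return Y;
}

arma::cube tconv_bwd(const arma::cube& dY, const arma::cube& Xin,
                     const arma::mat& Wm, arma::mat& dW, arma::vec& db) {
  const int H = Xin.n_rows, W = Xin.n_cols;
  const int Cout = Wm.n_cols / 4;
  arma::mat dYc(H * (size_t)W, 4 * (size_t)Cout, arma::fill::zeros);
  db.zeros(Cout);
  for (int co = 0; co < Cout; ++co) {
    db(co) = arma::accu(dY.slice(co));
    for (int ki = 0; ki < 2; ++ki)
      for (int kj = 0; kj < 2; ++kj) {
        double* v = dYc.colptr(co * 4 + ki * 2 + kj);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            v[i + (size_t)j * H] = dY(2 * i + ki, 2 * j + kj, co);
      }
  }
  arma::mat Xm = cube_to_mat(Xin);
  dW = Xm.t() * dYc;
  arma::mat dXm = dYc * Wm.t();
  arma::cube dX(H, W, Xin.n_slices);
  std::memcpy(dX.memptr(), dXm.memptr(), sizeof(double) * dXm.n_elem);
  return dX;
}

inline arma::cube relu(const arma::cube& x) { return arma::clamp(x, 0.0, arma::datum::inf); }
inline arma::cube relu_bwd(const arma::cube& dy, const arma::cube& y) {
  arma::cube dx = dy;
  dx.elem(arma::find(y <= 0)).zeros();
  return dx;
}

struct Net {
  int L;
  std::vector<int> ec;      // encoder output channels per level
  std::vector<int> dc;      // decoder output channels per level (1-based idx-1)
  std::vector<int> skipc;   // skip channels per decoder level
  int in_ch;
  std::vector<arma::mat> downW, resaW, resbW, upW, decaW, decbW;
  std::vector<arma::vec> downb, resab, resbb, upb, decab, decbb;
  arma::mat finW;
  arma::vec finb;
};

Net load_net(const List& params, const IntegerVector& widths, int in_ch) {
  Net n;
  n.L = widths.size();
  if (n.L != 5) stop("exactly five encoder stages are supported");
  n.in_ch = in_ch;
  n.ec.assign(widths.begin(), widths.end());
  n.dc.resize(n.L);
  n.skipc.resize(n.L);
  for (int j = 1; j <= n.L; ++j) {
    n.dc[j - 1] = j >= 2 ? n.ec[j - 2] : n.ec[0];
    n.skipc[j - 1] = j >= 2 ? n.ec[j - 2] : in_ch;
  }
  auto getM = [&](const std::string& nm) {
    return as<arma::mat>(params[nm]);
  };
  auto getV = [&](const std::string& nm) {
    return as<arma::vec>(params[nm]);
  };
  for (int i = 1; i <= n.L; ++i) {
    const std::string si = std::to_string(i);
    n.downW.push_back(getM("down" + si + "_W"));
    n.downb.push_back(getV("down" + si + "_b"));
    n.resaW.push_back(getM("res" + si + "a_W"));
    n.resab.push_back(getV("res" + si + "a_b"));
    n.resbW.push_back(getM("res" + si + "b_W"));
    n.resbb.push_back(getV("res" + si + "b_b"));
  }
  for (int j = 1; j <= n.L; ++j) {
    const std::string sj = std::to_string(j);
    n.upW.push_back(getM("up" + sj + "_W"));
    n.upb.push_back(getV("up" + sj + "_b"));
    n.decaW.push_back(getM("dec" + sj + "a_W"));
    n.decab.push_back(getV("dec" + sj + "a_b"));
    n.decbW.push_back(getM("dec" + sj + "b_W"));
    n.decbb.push_back(getV("dec" + sj + "b_b"));
  }
  n.finW = getM("final_W");
  n.finb = getV("final_b");
  return n;
}

struct FwdCache {
  std::vector<arma::cube> e;         // encoder outputs e[0..L-1]
  std::vector<arma::cube> xi, ai, ri;// per-level intermediates
  std::vector<ConvCache> ccd, cca, ccb;
  std::vector<arma::cube> upin, up, cat, da, cur; // decoder, index j-1
  std::vector<ConvCache> ccda, ccdb;
  ConvCache ccfin;
  arma::mat logits;
};

// forward pass; fills cache when want_grad
arma::mat forward(const Net& n, const arma::cube& x, FwdCache* fc) {
  FwdCache local;
  FwdCache& C = fc ? *fc : local;
  C.e.resize(n.L); C.xi.resize(n.L); C.ai.resize(n.L); C.ri.resize(n.L);
  C.ccd.resize(n.L); C.cca.resize(n.L); C.ccb.resize(n.L);
  C.upin.resize(n.L); C.up.resize(n.L); C.cat.resize(n.L);
  C.da.resize(n.L); C.cur.resize(n.L);
  C.ccda.resize(n.L); C.ccdb.resize(n.L);

  arma::cube cur = x;
  for (int i = 0; i < n.L; ++i) {
    arma::cube xi = relu(conv_fwd(cur, n.downW[i], n.downb[i], 3, 2, 1,
                                  fc ? &C.ccd[i] : nullptr));
    arma::cube ai = relu(conv_fwd(xi, n.resaW[i], n.resab[i], 3, 1, 1,
                                  fc ? &C.cca[i] : nullptr));
    arma::cube bi = conv_fwd(ai, n.resbW[i], n.resbb[i], 3, 1, 1,
                             fc ? &C.ccb[i] : nullptr);
    arma::cube ei = relu(xi + bi);
    if (fc) { C.xi[i] = xi; C.ai[i] = ai; }
    C.e[i] = ei; // skips are needed in the decoder even without gradients
    cur = std::move(ei);
  }
  for (int j = n.L; j >= 1; --j) {
    const int idx = j - 1;
    if (fc) C.upin[idx] = cur;
    arma::cube up = tconv_fwd(cur, n.upW[idx], n.upb[idx]);
    const arma::cube& skip = j >= 2 ? C.e[j - 2] : x;
    arma::cube upc = up.subcube(0, 0, 0, skip.n_rows - 1, skip.n_cols - 1,
                                up.n_slices - 1);
    arma::cube cat = arma::join_slices(upc, skip);
    arma::cube da = relu(conv_fwd(cat, n.decaW[idx], n.decab[idx], 3, 1, 1,
                                  fc ? &C.ccda[idx] : nullptr));
    arma::cube db = relu(conv_fwd(da, n.decbW[idx], n.decbb[idx], 3, 1, 1,
                                  fc ? &C.ccdb[idx] : nullptr));
    if (fc) { C.up[idx] = up; C.cat[idx] = cat; C.da[idx] = da; C.cur[idx] = db; }
    cur = std::move(db);
  }
  arma::cube lg = conv_fwd(cur, n.finW, n.finb, 1, 1, 0,
                           fc ? &C.ccfin : nullptr);
  arma::mat logits = lg.slice(0);
  if (fc) C.logits = logits;
  return logits;
}

} // namespace

// Parameter shapes for a given width config; the single source of truth the
// R-side initializer uses. Returns a named list of integer dims.
// [[Rcpp::export]]
List cpp_unet_shapes(const IntegerVector& widths, const int in_ch) {
  const int L = widths.size();
  if (L != 5) stop("exactly five encoder stages are supported");
  std::vector<int> ec(widths.begin(), widths.end());
  List out;
  int prev = in_ch;
  for (int i = 1; i <= L; ++i) {
    const std::string si = std::to_string(i);
    out["down" + si + "_W"] = IntegerVector::create(9 * prev, ec[i - 1]);
    out["down" + si + "_b"] = IntegerVector::create(ec[i - 1]);
    out["res" + si + "a_W"] = IntegerVector::create(9 * ec[i - 1], ec[i - 1]);
    out["res" + si + "a_b"] = IntegerVector::create(ec[i - 1]);
    out["res" + si + "b_W"] = IntegerVector::create(9 * ec[i - 1], ec[i - 1]);
    out["res" + si + "b_b"] = IntegerVector::create(ec[i - 1]);
    prev = ec[i - 1];
  }
  for (int j = L; j >= 1; --j) {
    const std::string sj = std::to_string(j);
    const int dcj = j >= 2 ? ec[j - 2] : ec[0];
    const int skip = j >= 2 ? ec[j - 2] : in_ch;
    const int upin = j == L ? ec[L - 1] : (j + 1 >= 2 ? ec[j - 1] : ec[0]);
    out["up" + sj + "_W"] = IntegerVector::create(upin, 4 * dcj);
    out["up" + sj + "_b"] = IntegerVector::create(dcj);
    out["dec" + sj + "a_W"] = IntegerVector::create(9 * (dcj + skip), dcj);
    out["dec" + sj + "a_b"] = IntegerVector::create(dcj);
    out["dec" + sj + "b_W"] = IntegerVector::create(9 * dcj, dcj);
    out["dec" + sj + "b_b"] = IntegerVector::create(dcj);
  }
  out["final_W"] = IntegerVector::create(ec[0], 1);
  out["final_b"] = IntegerVector::create(1);
  return out;
}

// Sigmoid probability map for one input patch.
// [[Rcpp::export]]
arma::mat cpp_unet_predict(const List& params, const arma::cube& x,
                           const IntegerVector& widths, const int in_ch) {
  Net n = load_net(params, widths, in_ch);
  arma::mat z = forward(n, x, nullptr);
  return 1.0 / (1.0 + arma::exp(-z));
}

// Loss ("bce" or "dice") and full gradient for one (patch, mask) pair.
// [[Rcpp::export]]
List cpp_unet_loss_grad(const List& params, const arma::cube& x,
                        const arma::mat& y, const IntegerVector& widths,
                        const int in_ch, const std::string loss_type) {
  Net n = load_net(params, widths, in_ch);
  FwdCache fc;
  arma::mat z = forward(n, x, &fc);
  if (z.n_rows != y.n_rows || z.n_cols != y.n_cols)
    stop("target mask shape does not match network output");
  const double N = z.n_elem;
  arma::mat sig = 1.0 / (1.0 + arma::exp(-z));
  double loss;
  arma::mat dz;
  if (loss_type == "bce") {
    // stable softplus-based binary cross-entropy
    arma::mat zp = arma::clamp(z, 0.0, arma::datum::inf);
    arma::mat loss_m = zp + arma::log1p(arma::exp(-arma::abs(z))) - y % z;
    loss = arma::accu(loss_m) / N;
    dz = (sig - y) / N;
  } else if (loss_type == "dice") {
    const double eps = 1.0;
    const double num = 2.0 * arma::accu(sig % y) + eps;
    const double den = arma::accu(sig) + arma::accu(y) + eps;
    loss = 1.0 - num / den;
    // d loss / d sig = -(2 y den - num) / den^2, then chain sigmoid
    arma::mat dsig = -(2.0 * y * den - num) / (den * den);
    dz = dsig % sig % (1.0 - sig);
  } else {
    stop("unknown loss type: " + loss_type);
  }

  List g;
  // final 1x1 conv
  arma::cube dzc(z.n_rows, z.n_cols, 1);
  dzc.slice(0) = dz;
  arma::mat dW; arma::vec db;
  arma::cube dcur = conv_bwd(dzc, fc.ccfin, n.finW, 1, 1, 0, dW, db);
  g["final_W"] = dW; g["final_b"] = db;

  // decoder backward j = 1..L; skip grads accumulate into encoder grads
  std::vector<arma::cube> de(n.L); // grads wrt encoder outputs
  for (int i = 0; i < n.L; ++i) de[i].zeros(fc.e[i].n_rows, fc.e[i].n_cols, fc.e[i].n_slices);
  for (int j = 1; j <= n.L; ++j) {
    const int idx = j - 1;
    const std::string sj = std::to_string(j);
    arma::cube d_db = relu_bwd(dcur, fc.cur[idx]);
    arma::cube d_da_full = conv_bwd(d_db, fc.ccdb[idx], n.decbW[idx], 3, 1, 1,
                                    dW, db);
    g["dec" + sj + "b_W"] = dW; g["dec" + sj + "b_b"] = db;
    arma::cube d_da = relu_bwd(d_da_full, fc.da[idx]);
    arma::cube d_cat = conv_bwd(d_da, fc.ccda[idx], n.decaW[idx], 3, 1, 1,
                                dW, db);
    g["dec" + sj + "a_W"] = dW; g["dec" + sj + "a_b"] = db;
    const int upch = n.dc[idx];
    arma::cube d_upc = d_cat.slices(0, upch - 1);
    arma::cube d_skip = d_cat.slices(upch, d_cat.n_slices - 1);
    if (j >= 2) de[j - 2] += d_skip; // j == 1 skips the input image: discard
    // pad cropped grad back to the full 2Hx2W transposed-conv output
    arma::cube d_up(fc.up[idx].n_rows, fc.up[idx].n_cols, upch,
                    arma::fill::zeros);
    d_up.subcube(0, 0, 0, d_upc.n_rows - 1, d_upc.n_cols - 1, upch - 1) = d_upc;
    arma::cube d_upin = tconv_bwd(d_up, fc.upin[idx], n.upW[idx], dW, db);
    g["up" + sj + "_W"] = dW; g["up" + sj + "_b"] = db;
    if (j == n.L) de[n.L - 1] += d_upin; // bottleneck feeds from e_L
    else dcur = std::move(d_upin);       // flows to decoder block j+1
  }

  // encoder backward i = L..1
  arma::cube dnext; // grad wrt input of level i+1 == e_i
  for (int i = n.L; i >= 1; --i) {
    const int idx = i - 1;
    const std::string si = std::to_string(i);
    arma::cube dei = de[idx];
    if (i < n.L) dei += dnext;
    arma::cube d_sum = relu_bwd(dei, fc.e[idx]);      // through final relu
    // residual: e = relu(xi + conv_b(relu(conv_a(xi))))
    arma::cube d_bi = d_sum;                           // into conv_b branch
    arma::cube d_ai_full = conv_bwd(d_bi, fc.ccb[idx], n.resbW[idx], 3, 1, 1,
                                    dW, db);
    g["res" + si + "b_W"] = dW; g["res" + si + "b_b"] = db;
    arma::cube d_ai = relu_bwd(d_ai_full, fc.ai[idx]);
    arma::cube d_xi_res = conv_bwd(d_ai, fc.cca[idx], n.resaW[idx], 3, 1, 1,
                                   dW, db);
    g["res" + si + "a_W"] = dW; g["res" + si + "a_b"] = db;
    arma::cube d_xi = relu_bwd(d_sum + d_xi_res, fc.xi[idx]);
    dnext = conv_bwd(d_xi, fc.ccd[idx], n.downW[idx], 3, 2, 1, dW, db);
    g["down" + si + "_W"] = dW; g["down" + si + "_b"] = db;
  }

  return List::create(_["loss"] = loss, _["grads"] = g);
}
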