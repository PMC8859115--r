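#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

// Compact CNN: 3 x [3x3 valid conv -> ReLU -> 2x2 maxpool] -> dense -> softmax.
// Weight layout for conv layer l: W (F x 9*C_in), column index ch*9 + dj*3 + di.

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H - 2, Wo = W - 2;
  mat cols(9 * C, Ho * Wo);
  for (int c = 0; c < Wo; ++c)
    for (int r = 0; r < Ho; ++r) {
      double* dst = cols.colptr(r + c * Ho);
      for (int ch = 0; ch < C; ++ch)
        for (int dj = 0; dj < 3; ++dj)
          for (int di = 0; di < 3; ++di)
            dst[ch * 9 + dj * 3 + di] = x(r + di, c + dj, ch);
    }
  return cols;
}

static cube col2im3(const mat& cols, int H, int W, int C) {
  cube out(H, W, C, fill::zeros);
  const int Ho = H - 2, Wo = W - 2;
  for (int c = 0; c < Wo; ++c)
    for (int r = 0; r < Ho; ++r) {
      const double* src = cols.colptr(r + c * Ho);
      for (int ch = 0; ch < C; ++ch)
        for (int dj = 0; dj < 3; ++dj)
          for (int di = 0; di < 3; ++di)
            out(r + di, c + dj, ch) += src[ch * 9 + dj * 3 + di];
    }
  return out;
}

static cube mat2cube(const mat& m, int Ho, int Wo) {
  const int F = m.n_rows;
  cube out(Ho, Wo, F);
  for (int f = 0; f < F; ++f)
    out.slice(f) = reshape(m.row(f), Ho, Wo);
  return out;
}

static mat cube2mat(const cube& x) {
  const int F = x.n_slices, N = x.n_rows * x.n_cols;
  mat out(F, N);
  for (int f = 0; f < F; ++f)
    out.row(f) = vectorise(x.slice(f)).t();
  return out;
}

static cube maxpool2(const cube& x, ucube& idx) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  idx.set_size(Ho, Wo, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        const int r0 = 2 * r, c0 = 2 * c;
        double best = x(r0, c0, ch);
        uword bi = r0 + c0 * H;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(r0 + di, c0 + dj, ch);
            if (v > best) { best = v; bi = (r0 + di) + (c0 + dj) * H; }
          }
        out(r, c, ch) = best;
        idx(r, c, ch) = bi;
      }
  return out;
}

struct Net {
  std::vector<mat> Wc;
  std::vector<vec> bc;
  mat Wd, Wout;
  vec bd, bout;
};

static Net unpack(const List& weights) {
  Net n;
  n.Wc.push_back(as<mat>(weights["W1"]));
  n.Wc.push_back(as<mat>(weights["W2"]));
  n.Wc.push_back(as<mat>(weights["W3"]));
  n.bc.push_back(as<vec>(weights["b1"]));
  n.bc.push_back(as<vec>(weights["b2"]));
  n.bc.push_back(as<vec>(weights["b3"]));
  n.Wd = as<mat>(weights["Wd"]);
  n.bd = as<vec>(weights["bd"]);
  n.Wout = as<mat>(weights["Wo"]);
  n.bout = as<vec>(weights["bo"]);
  return n;
}

// Forward pass for one image; caches are filled only when `train` is true.
struct Cache {
  std::vector<mat> cols, zpost;  // per conv layer
  std::vector<ucube> pidx;
  std::vector<int> Hin, Win, Cin, Ho, Wo;
  vec v, h;
};

static vec forward_one(const Net& net, const mat& x, Cache* cc) {
  cube a(x.n_rows, x.n_cols, 1);
  a.slice(0) = x;
  for (int l = 0; l < 3; ++l) {
    const int Hin = a.n_rows, Win = a.n_cols, Cin = a.n_slices;
    mat cols = im2col3(a);
    mat z = net.Wc[l] * cols;
    z.each_col() += net.bc[l];
    z.elem(find(z < 0)).zeros();
    cube zc = mat2cube(z, Hin - 2, Win - 2);
    ucube idx;
    cube p = maxpool2(zc, idx);
    if (cc) {
      cc->cols.push_back(std::move(cols));
      cc->zpost.push_back(std::move(z));
      cc->pidx.push_back(std::move(idx));
      cc->Hin.push_back(Hin); cc->Win.push_back(Win); cc->Cin.push_back(Cin);
      cc->Ho.push_back(Hin - 2); cc->Wo.push_back(Win - 2);
    }
    a = p;
  }
  vec v = vectorise(a);
  vec h = net.Wd * v + net.bd;
  h.elem(find(h < 0)).zeros();
  vec o = net.Wout * h + net.bout;
  o -= o.max();
  vec e = exp(o);
  vec p = e / accu(e);
  if (cc) { cc->v = v; cc->h = h; }
  return p;
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(List weights, const arma::cube& xb) {
  Net net = unpack(weights);
  const int B = xb.n_slices;
  const int K = net.bout.n_elem;
  mat out(B, K);
  for (int b = 0; b < B; ++b)
    out.row(b) = forward_one(net, xb.slice(b), nullptr).t();
  return out;
}

// [[Rcpp::export]]
List cnn_grad_cpp(List weights, const arma::cube& xb, const arma::ivec& y) {
  Net net = unpack(weights);
  const int B = xb.n_slices;
  std::vector<mat> gWc(3);
  std::vector<vec> gbc(3);
  for (int l = 0; l < 3; ++l) {
    gWc[l] = zeros<mat>(net.Wc[l].n_rows, net.Wc[l].n_cols);
    gbc[l] = zeros<vec>(net.bc[l].n_elem);
  }
  mat gWd = zeros<mat>(net.Wd.n_rows, net.Wd.n_cols);
  vec gbd = zeros<vec>(net.bd.n_elem);
  mat gWo = zeros<mat>(net.Wout.n_rows, net.Wout.n_cols);
  vec gbo = zeros<vec>(net.bout.n_elem);
  double loss = 0.0;
  int correct = 0;

  for (int b = 0; b < B; ++b) {
    Cache cc;
    vec p = forward_one(net, xb.slice(b), &cc);
    const int yi = y(b);
    loss += -std::log(std::max(p(yi), 1e-12));
    if ((int)p.index_max() == yi) ++correct;

    vec dzo = p;
    dzo(yi) -= 1.0;
    gWo += dzo * cc.h.t();
    gbo += dzo;
    vec dh = net.Wout.t() * dzo;
    dh.elem(find(cc.h <= 0)).zeros();
    gWd += dh * cc.v.t();
    gbd += dh;
    vec dv = net.Wd.t() * dh;

    // gradient w.r.t. the pooled output of the last conv layer
    const int Hp3 = cc.Ho[2] / 2, Wp3 = cc.Wo[2] / 2, F3 = net.bc[2].n_elem;
    cube dp(Hp3, Wp3, F3);
    std::memcpy(dp.memptr(), dv.memptr(), sizeof(double) * dv.n_elem);

    for (int l = 2; l >= 0; --l) {
      const int Ho = cc.Ho[l], Wo = cc.Wo[l];
      const int F = net.bc[l].n_elem;
      cube dz(Ho, Wo, F, fill::zeros);
      const int Hp = Ho / 2, Wp = Wo / 2;
      for (int ch = 0; ch < F; ++ch)
        for (int c = 0; c < Wp; ++c)
          for (int r = 0; r < Hp; ++r)
            dz.slice(ch)(cc.pidx[l](r, c, ch)) += dp(r, c, ch);
      mat dzm = cube2mat(dz);
      dzm.elem(find(cc.zpost[l] <= 0)).zeros();
      gWc[l] += dzm * cc.cols[l].t();
      gbc[l] += sum(dzm, 1);
      if (l > 0) {
        mat dcols = net.Wc[l].t() * dzm;
        dp = col2im3(dcols, cc.Hin[l], cc.Win[l], cc.Cin[l]);
      }
    }
  }

  const double inv = 1.0 / B;
  return List::create(
    _["grads"] = List::create(
      _["W1"] = gWc[0] * inv, _["b1"] = gbc[0] * inv,
      _["W2"] = gWc[1] * inv, _["b2"] = gbc[1] * inv,
      _["W3"] = gWc[2] * inv, _["b3"] = gbc[2] * inv,
      _["Wd"] = gWd * inv, _["bd"] = gbd * inv,
      _["Wo"] = gWo * inv, _["bo"] = gbo * inv),
    _["loss"] = loss * inv,
    _["accuracy"] = (double)correct / B);
}
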