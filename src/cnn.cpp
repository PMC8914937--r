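// Reference convolutional network: two 3x3 conv + 2x2 max-pool blocks,
// a dense ReLU layer and a softmax output, with exact gradients for
// cross-entropy loss.  Convolutions are valid (no padding), stride 1,
// implemented as im2col + GEMM; pooling is 2x2 stride 2 with floor sizing.
// Model parameters live in an R list of matrices; this file only computes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a 3x3 valid convolution over an H x W x C cube.
// Output: (9*C) x ((H-2)*(W-2)); row index = c*9 + dj*3 + di,
// column index = i + j*(H-2)  (column-major over output positions).
static mat im2col3(const cube &in) {
  const uword H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const uword Ho = H - 2, Wo = W - 2;
  mat out(9 * C, Ho * Wo);
  for (uword c = 0; c < C; ++c)
    for (uword dj = 0; dj < 3; ++dj)
      for (uword di = 0; di < 3; ++di) {
        const uword r = c * 9 + dj * 3 + di;
        for (uword j = 0; j < Wo; ++j)
          for (uword i = 0; i < Ho; ++i)
            out(r, i + j * Ho) = in(i + di, j + dj, c);
      }
  return out;
}

// scatter-add transpose of im2col3
static void col2im3(const mat &dcol, cube &dout) {
  const uword H = dout.n_rows, W = dout.n_cols, C = dout.n_slices;
  const uword Ho = H - 2, Wo = W - 2;
  dout.zeros();
  for (uword c = 0; c < C; ++c)
    for (uword dj = 0; dj < 3; ++dj)
      for (uword di = 0; di < 3; ++di) {
        const uword r = c * 9 + dj * 3 + di;
        for (uword j = 0; j < Wo; ++j)
          for (uword i = 0; i < Ho; ++i)
            dout(i + di, j + dj, c) += dcol(r, i + j * Ho);
      }
}

// activation matrix (F x P, P = Ho*Wo column-major) -> cube Ho x Wo x F
static cube act_to_cube(const mat &a, uword Ho, uword Wo) {
  cube out(Ho, Wo, a.n_rows);
  for (uword f = 0; f < a.n_rows; ++f)
    for (uword j = 0; j < Wo; ++j)
      for (uword i = 0; i < Ho; ++i)
        out(i, j, f) = a(f, i + j * Ho);
  return out;
}

static mat cube_to_act(const cube &c) {
  const uword Ho = c.n_rows, Wo = c.n_cols, F = c.n_slices;
  mat out(F, Ho * Wo);
  for (uword f = 0; f < F; ++f)
    for (uword j = 0; j < Wo; ++j)
      for (uword i = 0; i < Ho; ++i)
        out(f, i + j * Ho) = c(i, j, f);
  return out;
}

// 2x2 stride-2 max pool with argmax bookkeeping (linear index into input)
static cube maxpool2(const cube &in, ucube &argmax) {
  const uword Ho = in.n_rows / 2, Wo = in.n_cols / 2, F = in.n_slices;
  cube out(Ho, Wo, F);
  argmax.set_size(Ho, Wo, F);
  for (uword f = 0; f < F; ++f)
    for (uword j = 0; j < Wo; ++j)
      for (uword i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bidx = 0;
        for (uword dj = 0; dj < 2; ++dj)
          for (uword di = 0; di < 2; ++di) {
            const uword r = 2 * i + di, cc = 2 * j + dj;
            const double v = in(r, cc, f);
            if (v > best) { best = v; bidx = r + cc * in.n_rows; }
          }
        out(i, j, f) = best;
        argmax(i, j, f) = bidx;
      }
  return out;
}

static cube maxpool2_back(const cube &dout, const ucube &argmax,
                          uword Hin, uword Win) {
  const uword F = dout.n_slices;
  cube din(Hin, Win, F, fill::zeros);
  for (uword f = 0; f < F; ++f)
    for (uword j = 0; j < dout.n_cols; ++j)
      for (uword i = 0; i < dout.n_rows; ++i) {
        const uword lin = argmax(i, j, f);
        din(lin % Hin, lin / Hin, f) += dout(i, j, f);
      }
  return din;
}

struct Params {
  mat W1, W2, Wd, Wo;
  vec b1, b2, bd, bo;
};

static Params unpack(const Rcpp::List &p) {
  Params q;
  q.W1 = Rcpp::as<mat>(p["W1"]); q.b1 = Rcpp::as<vec>(p["b1"]);
  q.W2 = Rcpp::as<mat>(p["W2"]); q.b2 = Rcpp::as<vec>(p["b2"]);
  q.Wd = Rcpp::as<mat>(p["Wd"]); q.bd = Rcpp::as<vec>(p["bd"]);
  q.Wo = Rcpp::as<mat>(p["Wo"]); q.bo = Rcpp::as<vec>(p["bo"]);
  return q;
}

// forward pass for one image; fills the intermediates needed for backward
struct Fwd {
  mat col1, col2, a1, a2;
  ucube am1, am2;
  cube p1, p2;
  vec flat, h, prob;
  uword H1, W1, H1p, W1p, H2, W2, H2p, W2p;
};

static void forward_one(const Params &P, const cube &img, Fwd &f) {
  f.H1 = img.n_rows - 2; f.W1 = img.n_cols - 2;
  f.col1 = im2col3(img);
  f.a1 = P.W1 * f.col1;
  f.a1.each_col() += P.b1;
  f.a1.transform([](double v) { return v > 0 ? v : 0.0; });
  cube c1 = act_to_cube(f.a1, f.H1, f.W1);
  f.p1 = maxpool2(c1, f.am1);
  f.H1p = f.p1.n_rows; f.W1p = f.p1.n_cols;

  f.H2 = f.H1p - 2; f.W2 = f.W1p - 2;
  f.col2 = im2col3(f.p1);
  f.a2 = P.W2 * f.col2;
  f.a2.each_col() += P.b2;
  f.a2.transform([](double v) { return v > 0 ? v : 0.0; });
  cube c2 = act_to_cube(f.a2, f.H2, f.W2);
  f.p2 = maxpool2(c2, f.am2);
  f.H2p = f.p2.n_rows; f.W2p = f.p2.n_cols;

  f.flat = vectorise(f.p2);
  f.h = P.Wd * f.flat + P.bd;
  f.h.transform([](double v) { return v > 0 ? v : 0.0; });
  vec logits = P.Wo * f.h + P.bo;
  logits -= logits.max();
  vec e = exp(logits);
  f.prob = e / accu(e);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
Rcpp::NumericMatrix cnn_predict_cpp(Rcpp::List params, Rcpp::NumericVector X) {
  Rcpp::IntegerVector dim = X.attr("dim");
  const uword H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  Params P = unpack(params);
  const double *xp = X.begin();
  Fwd f;
  Rcpp::NumericMatrix out(N, P.Wo.n_rows);
  for (uword n = 0; n < N; ++n) {
    cube img(const_cast<double *>(xp) + n * H * W * C, H, W, C, false, true);
    forward_one(P, img, f);
    for (uword k = 0; k < f.prob.n_elem; ++k) out(n, k) = f.prob(k);
  }
  return out;
}

// mean cross-entropy loss and gradients over a batch
// [[Rcpp::export(name = ".cnn_grad_cpp")]]
Rcpp::List cnn_grad_cpp(Rcpp::List params, Rcpp::NumericVector X,
                        Rcpp::IntegerVector y) {
  Rcpp::IntegerVector dim = X.attr("dim");
  const uword H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  Params P = unpack(params);
  const double *xp = X.begin();

  mat gW1(size(P.W1), fill::zeros), gW2(size(P.W2), fill::zeros);
  mat gWd(size(P.Wd), fill::zeros), gWo(size(P.Wo), fill::zeros);
  vec gb1(P.b1.n_elem, fill::zeros), gb2(P.b2.n_elem, fill::zeros);
  vec gbd(P.bd.n_elem, fill::zeros), gbo(P.bo.n_elem, fill::zeros);
  double loss = 0;
  Rcpp::IntegerVector pred(N);
  Fwd f;

  for (uword n = 0; n < N; ++n) {
    cube img(const_cast<double *>(xp) + n * H * W * C, H, W, C, false, true);
    forward_one(P, img, f);
    const uword lab = (uword)y[n];
    loss += -std::log(std::max(f.prob(lab), 1e-12));
    pred[n] = (int)f.prob.index_max();

    // output layer
    vec dlogit = f.prob;
    dlogit(lab) -= 1.0;
    gWo += dlogit * f.h.t();
    gbo += dlogit;
    vec dh = P.Wo.t() * dlogit;
    dh.elem(find(f.h <= 0)).zeros();

    // dense layer
    gWd += dh * f.flat.t();
    gbd += dh;
    vec dflat = P.Wd.t() * dh;
    cube dp2(dflat.memptr(), f.H2p, f.W2p, P.W2.n_rows);

    // block 2
    cube dc2 = maxpool2_back(dp2, f.am2, f.H2, f.W2);
    mat da2 = cube_to_act(dc2);
    da2.elem(find(f.a2 <= 0)).zeros();
    gW2 += da2 * f.col2.t();
    gb2 += sum(da2, 1);
    mat dcol2 = P.W2.t() * da2;
    cube dp1(f.H1p, f.W1p, P.W1.n_rows);
    col2im3(dcol2, dp1);

    // block 1
    cube dc1 = maxpool2_back(dp1, f.am1, f.H1, f.W1);
    mat da1 = cube_to_act(dc1);
    da1.elem(find(f.a1 <= 0)).zeros();
    gW1 += da1 * f.col1.t();
    gb1 += sum(da1, 1);
  }

  const double inv = 1.0 / (double)N;
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss * inv,
      Rcpp::Named("pred") = pred,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("W1") = gW1 * inv, Rcpp::Named("b1") = gb1 * inv,
          Rcpp::Named("W2") = gW2 * inv, Rcpp::Named("b2") = gb2 * inv,
          Rcpp::Named("Wd") = gWd * inv, Rcpp::Named("bd") = gbd * inv,
          Rcpp::Named("Wo") = gWo * inv, Rcpp::Named("bo") = gbo * inv));
}
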