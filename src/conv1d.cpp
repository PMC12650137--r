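// Batched two-layer convolution operator (conv -> tanh -> optional dropout
// -> conv) with length-preserving replicate padding, on the (B*T, C)
// flattening used throughout the R code: shifting time by one step shifts
// flat row indices by B, so each kernel tap is a dense matrix product over
// a contiguous row block of the padded input.  Forward returns an external
// pointer holding the intermediates; backward consumes it, so nothing large
// crosses the R/C++ boundary twice.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

struct ConvmodCache {
  mat xp1, a, xp2, mask;
  bool has_mask = false;
  int B = 0, T = 0;
};

static std::vector<mat> make_taps(const Rcpp::NumericVector& W) {
  Rcpp::IntegerVector dims = W.attr("dim");
  const int k = dims[0], cin = dims[1], cout = dims[2];
  std::vector<mat> taps(k, mat(cin, cout));
  for (int j = 0; j < k; ++j)
    for (int co = 0; co < cout; ++co)
      for (int ci = 0; ci < cin; ++ci)
        taps[j](ci, co) = W[j + (R_xlen_t) k * (ci + (R_xlen_t) cin * co)];
  return taps;
}

static Rcpp::NumericVector taps_to_array(const std::vector<mat>& taps) {
  const int k = taps.size(), cin = taps[0].n_rows, cout = taps[0].n_cols;
  Rcpp::NumericVector out((R_xlen_t) k * cin * cout);
  out.attr("dim") = Rcpp::IntegerVector::create(k, cin, cout);
  for (int j = 0; j < k; ++j)
    for (int co = 0; co < cout; ++co)
      for (int ci = 0; ci < cin; ++ci)
        out[j + (R_xlen_t) k * (ci + (R_xlen_t) cin * co)] = taps[j](ci, co);
  return out;
}

// y = conv(x) with replicate padding; fills xp with the padded input
static mat conv_fwd(const mat& x, int B, int T, const std::vector<mat>& taps,
                    const vec& b, mat& xp) {
  const int k = taps.size(), p = (k - 1) / 2, cin = x.n_cols;
  xp.set_size(B * (T + 2 * p), cin);
  xp.rows(p * B, p * B + B * T - 1) = x;
  for (int j = 0; j < p; ++j) {
    xp.rows(j * B, (j + 1) * B - 1) = x.rows(0, B - 1);
    xp.rows((p + T + j) * B, (p + T + j + 1) * B - 1) =
      x.rows((T - 1) * B, T * B - 1);
  }
  mat Y(B * T, taps[0].n_cols);
  Y.each_row() = b.t();
  for (int j = 0; j < k; ++j)
    Y += xp.rows(j * B, j * B + B * T - 1) * taps[j];
  return Y;
}

static void conv_bwd(const mat& xp, const mat& G, const std::vector<mat>& taps,
                     int B, int T, mat& gx, std::vector<mat>& gW, vec& gb) {
  const int k = taps.size(), p = (k - 1) / 2, cin = xp.n_cols;
  mat gxp(xp.n_rows, cin, fill::zeros);
  gW.assign(k, mat());
  for (int j = 0; j < k; ++j) {
    gW[j] = xp.rows(j * B, j * B + B * T - 1).t() * G;
    gxp.rows(j * B, j * B + B * T - 1) += G * taps[j].t();
  }
  gb = sum(G, 0).t();
  gx = gxp.rows(p * B, p * B + B * T - 1);
  for (int j = 0; j < p; ++j) {
    gx.rows(0, B - 1) += gxp.rows(j * B, (j + 1) * B - 1);
    gx.rows((T - 1) * B, T * B - 1) +=
      gxp.rows((p + T + j) * B, (p + T + j + 1) * B - 1);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_convmod_fwd(const arma::mat& x, int B, int T,
                           const Rcpp::NumericVector& W1, const arma::vec& b1,
                           const Rcpp::NumericVector& W2, const arma::vec& b2,
                           Rcpp::Nullable<Rcpp::NumericMatrix> mask) {
  ConvmodCache* c = new ConvmodCache();
  c->B = B; c->T = T;
  std::vector<mat> t1 = make_taps(W1), t2 = make_taps(W2);
  mat h = conv_fwd(x, B, T, t1, b1, c->xp1);
  c->a = tanh(h);
  mat a2 = c->a;
  if (mask.isNotNull()) {
    c->has_mask = true;
    c->mask = Rcpp::as<arma::mat>(mask.get());
    a2 %= c->mask;
  }
  mat y = conv_fwd(a2, B, T, t2, b2, c->xp2);
  Rcpp::XPtr<ConvmodCache> ptr(c, true);
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("cache") = ptr);
}

// [[Rcpp::export]]
Rcpp::List cpp_convmod_bwd(SEXP cache_sexp, const arma::mat& G,
                           const Rcpp::NumericVector& W1,
                           const Rcpp::NumericVector& W2) {
  Rcpp::XPtr<ConvmodCache> c(cache_sexp);
  std::vector<mat> t1 = make_taps(W1), t2 = make_taps(W2);
  mat ga2, gx;
  std::vector<mat> gW1, gW2;
  vec gb1, gb2;
  conv_bwd(c->xp2, G, t2, c->B, c->T, ga2, gW2, gb2);
  if (c->has_mask) ga2 %= c->mask;
  mat ga = ga2 % (1 - square(c->a));
  conv_bwd(c->xp1, ga, t1, c->B, c->T, gx, gW1, gb1);
  return Rcpp::List::create(
    Rcpp::Named("gx") = gx,
    Rcpp::Named("gW1") = taps_to_array(gW1), Rcpp::Named("gb1") = gb1,
    Rcpp::Named("gW2") = taps_to_array(gW2), Rcpp::Named("gb2") = gb2);
}
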