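// Fused forward/backward pass for the graph regression models.
//
// Layer parameters live in one flat parameter vector; the execution plan
// (built in R) records each parameter's offset and shape so both the
// forward pass and the gradient accumulate through zero-copy Armadillo
// views. The R implementation of the same layers is the reference; the
// test suite asserts both paths agree.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

arma::mat view(double *base, const IntegerVector &spec) {
  // spec = (offset, nrow, ncol); strict=false so we can write through
  return arma::mat(base + spec[0], spec[1], spec[2], false, false);
}

} // namespace

// Executes the layer stack over one prepared batch.
//
// plan: list of layers; each layer is a list with
//   kind   : string
//   par    : named list of IntegerVector c(offset0, nrow, ncol)
//   hyper  : named list (layer specific)
// ctx: list with X, A, S, Lt (dense mats), P (n_graphs x n), gat_src,
//   gat_dst (1-based integer vectors), labels
// theta: flat parameter vector; grad accumulated into same layout.
// bn_state: list per layer (NULL except bn layers): list(mean, var)
// dropout_masks: list per layer (NULL or pre-scaled mask vector)
// train: use batch statistics / dropout; compute_grad: run backward.
//
// Returns: list(pred, grad (if requested), bn_mu/bn_var per layer, loss)
// [[Rcpp::export(name = ".engine_run_cpp")]]
List engine_run_cpp(List plan, List ctx, NumericVector theta,
                    List bn_state, List dropout_masks,
                    bool train, bool compute_grad,
                    NumericVector labels) {
  const int L = plan.size();
  double *tp = REAL(theta);

  arma::mat X = as<arma::mat>(ctx["X"]);
  arma::sp_mat A = as<arma::sp_mat>(ctx["A_sp"]);
  arma::sp_mat S = as<arma::sp_mat>(ctx["S_sp"]);
  arma::sp_mat Lt = as<arma::sp_mat>(ctx["Lt_sp"]);
  arma::mat P = as<arma::mat>(ctx["P"]);
  arma::uvec gsrc = as<arma::uvec>(ctx["gat_src"]) - 1;
  arma::uvec gdst = as<arma::uvec>(ctx["gat_dst"]) - 1;

  // caches per layer
  std::vector<std::map<std::string, arma::mat>> cache(L);
  std::vector<arma::mat> inputs(L);
  List bn_mu(L), bn_var(L);

  arma::mat H = X;
  for (int li = 0; li < L; ++li) {
    List layer = plan[li];
    std::string kind = as<std::string>(layer["kind"]);
    List par = layer["par"];
    List hyper = layer["hyper"];
    inputs[li] = H;

    if (kind == "linear") {
      arma::mat W = view(tp, par["W"]);
      arma::mat b = view(tp, par["b"]);
      H = H * W;
      H.each_row() += b.t();
    } else if (kind == "relu") {
      cache[li]["mask"] = arma::conv_to<arma::mat>::from(H > 0);
      H = H % cache[li]["mask"];
    } else if (kind == "dropout") {
      if (train && !Rf_isNull(dropout_masks[li])) {
        arma::vec mv = as<arma::vec>(dropout_masks[li]);
        arma::mat mask(mv.memptr(), H.n_rows, H.n_cols);
        cache[li]["mask"] = mask;
        H = H % mask;
      }
    } else if (kind == "bn") {
      double eps = as<double>(hyper["eps"]);
      arma::mat gamma = view(tp, par["gamma"]);
      arma::mat beta = view(tp, par["beta"]);
      arma::rowvec mu, vr;
      if (train) {
        mu = arma::mean(H, 0);
        vr = arma::mean(arma::square(H), 0) - arma::square(mu);
        bn_mu[li] = NumericVector(mu.begin(), mu.end());
        bn_var[li] = NumericVector(vr.begin(), vr.end());
      } else {
        List st = bn_state[li];
        mu = arma::rowvec(as<arma::vec>(st["mean"]).t());
        vr = arma::rowvec(as<arma::vec>(st["var"]).t());
      }
      arma::rowvec ivar = 1.0 / arma::sqrt(vr + eps);
      arma::mat xhat = H;
      xhat.each_row() -= mu;
      xhat.each_row() %= ivar;
      cache[li]["xhat"] = xhat;
      cache[li]["ivar"] = arma::mat(ivar);
      H = xhat;
      H.each_row() %= gamma.col(0).t();
      H.each_row() += beta.col(0).t();
    } else if (kind == "gin") {
      double epsv = tp[as<IntegerVector>(par["eps"])[0]];
      arma::mat W1 = view(tp, par["W1"]), W2 = view(tp, par["W2"]);
      arma::mat b1 = view(tp, par["b1"]), b2 = view(tp, par["b2"]);
      arma::mat Z = (1.0 + epsv) * H + A * H;
      arma::mat L1 = Z * W1;
      L1.each_row() += b1.t();
      arma::mat m1 = arma::conv_to<arma::mat>::from(L1 > 0);
      arma::mat R = L1 % m1;
      cache[li]["Z"] = Z;
      cache[li]["m1"] = m1;
      cache[li]["R"] = R;
      H = R * W2;
      H.each_row() += b2.t();
    } else if (kind == "arma") {
      int K = as<int>(hyper["K"]), T = as<int>(hyper["T"]);
      arma::mat X0 = H;
      arma::mat acc;
      for (int k = 1; k <= K; ++k) {
        arma::mat Xb = X0;
        for (int t = 1; t <= T; ++t) {
          std::string sfx = std::to_string(k) + "_" + std::to_string(t);
          arma::mat W = view(tp, par["W" + sfx]);
          arma::mat V = view(tp, par["V" + sfx]);
          arma::mat b = view(tp, par["b" + sfx]);
          arma::mat LXb = Lt * Xb;
          arma::mat Z = LXb * W + X0 * V;
          Z.each_row() += b.t();
          cache[li]["LXb" + sfx] = LXb;
          arma::mat mask = arma::conv_to<arma::mat>::from(Z > 0);
          cache[li]["mask" + sfx] = mask;
          Xb = Z % mask;
        }
        acc = (k == 1) ? Xb : arma::mat(acc + Xb);
      }
      H = acc / K;
    } else if (kind == "gat") {
      int heads = as<int>(hyper["heads"]);
      int d_out = as<int>(hyper["d_out"]);
      double slope = as<double>(hyper["slope"]);
      arma::mat b = view(tp, par["b"]);
      const arma::uword E = gsrc.n_elem, n = H.n_rows;
      arma::mat pre(n, d_out, arma::fill::zeros);
      for (int h = 1; h <= heads; ++h) {
        std::string hs = std::to_string(h);
        arma::mat W = view(tp, par["W" + hs]);
        arma::mat av = view(tp, par["a" + hs]);
        arma::mat Wh = H * W;
        arma::vec a1 = av.col(0).rows(0, d_out - 1);
        arma::vec a2 = av.col(0).rows(d_out, 2 * d_out - 1);
        arma::vec s_dst = Wh * a1, s_src = Wh * a2;
        arma::vec elin(E), e(E);
        for (arma::uword j = 0; j < E; ++j) {
          elin[j] = s_dst[gdst[j]] + s_src[gsrc[j]];
          e[j] = elin[j] > 0 ? elin[j] : slope * elin[j];
        }
        arma::vec gmax(n, arma::fill::value(-arma::datum::inf));
        for (arma::uword j = 0; j < E; ++j)
          if (e[j] > gmax[gdst[j]]) gmax[gdst[j]] = e[j];
        arma::vec ex(E), denom(n, arma::fill::zeros);
        for (arma::uword j = 0; j < E; ++j) {
          ex[j] = std::exp(e[j] - gmax[gdst[j]]);
          denom[gdst[j]] += ex[j];
        }
        arma::vec alpha = ex;
        for (arma::uword j = 0; j < E; ++j) alpha[j] /= denom[gdst[j]];
        arma::mat ph(n, d_out, arma::fill::zeros);
        for (arma::uword j = 0; j < E; ++j)
          ph.row(gdst[j]) += alpha[j] * Wh.row(gsrc[j]);
        std::string pfx = "h" + hs;
        cache[li][pfx + "Wh"] = Wh;
        cache[li][pfx + "elin"] = arma::mat(elin);
        cache[li][pfx + "alpha"] = arma::mat(alpha);
        pre += ph;
      }
      pre /= heads;
      pre.each_row() += b.t();
      cache[li]["mask"] = arma::conv_to<arma::mat>::from(pre > 0);
      H = pre % cache[li]["mask"];
    } else if (kind == "sgc") {
      int K = as<int>(hyper["K"]);
      arma::mat W = view(tp, par["W"]), b = view(tp, par["b"]);
      arma::mat XK = H;
      for (int i = 0; i < K; ++i) XK = S * XK;
      cache[li]["XK"] = XK;
      H = XK * W;
      H.each_row() += b.t();
    } else if (kind == "pool") {
      H = P * H;
    } else {
      stop("unknown layer kind: " + kind);
    }
  }

  arma::vec pred = H.col(0);
  double loss = NA_REAL;
  List out = List::create(Named("pred") = NumericVector(pred.begin(), pred.end()),
                          Named("bn_mu") = bn_mu, Named("bn_var") = bn_var);
  if (!compute_grad) return out;

  arma::vec lab = as<arma::vec>(labels);
  arma::vec resid = pred - lab;
  loss = arma::mean(arma::square(resid));
  out["loss"] = loss;

  NumericVector gradv(theta.size());
  double *gp = REAL(gradv);
  arma::mat dH = arma::mat(2.0 * resid / resid.n_elem);

  for (int li = L - 1; li >= 0; --li) {
    List layer = plan[li];
    std::string kind = as<std::string>(layer["kind"]);
    List par = layer["par"];
    List hyper = layer["hyper"];
    const arma::mat &Xin = inputs[li];

    if (kind == "linear") {
      arma::mat W = view(tp, par["W"]);
      arma::mat dW = view(gp, par["W"]), db = view(gp, par["b"]);
      dW += Xin.t() * dH;
      db += arma::sum(dH, 0).t();
      dH = dH * W.t();
    } else if (kind == "relu") {
      dH = dH % cache[li]["mask"];
    } else if (kind == "dropout") {
      if (cache[li].count("mask")) dH = dH % cache[li]["mask"];
    } else if (kind == "bn") {
      arma::mat gamma = view(tp, par["gamma"]);
      arma::mat dgamma = view(gp, par["gamma"]), dbeta = view(gp, par["beta"]);
      const arma::mat &xhat = cache[li]["xhat"];
      arma::rowvec ivar = cache[li]["ivar"].row(0);
      double m = (double)dH.n_rows;
      dgamma += arma::sum(dH % xhat, 0).t();
      dbeta += arma::sum(dH, 0).t();
      arma::mat dxhat = dH;
      dxhat.each_row() %= gamma.col(0).t();
      arma::rowvec sd = arma::sum(dxhat, 0);
      arma::rowvec sdx = arma::sum(dxhat % xhat, 0);
      arma::mat tmp = m * dxhat;
      tmp.each_row() -= sd;
      arma::mat x2 = xhat;
      x2.each_row() %= sdx;
      tmp -= x2;
      tmp.each_row() %= (ivar / m);
      dH = tmp;
    } else if (kind == "gin") {
      double epsv = tp[as<IntegerVector>(par["eps"])[0]];
      arma::mat W1 = view(tp, par["W1"]), W2 = view(tp, par["W2"]);
      arma::mat dR = dH * W2.t();
      arma::mat dL1 = dR % cache[li]["m1"];
      arma::mat dZ = dL1 * W1.t();
      view(gp, par["W2"]) += cache[li]["R"].t() * dH;
      view(gp, par["b2"]) += arma::sum(dH, 0).t();
      view(gp, par["W1"]) += cache[li]["Z"].t() * dL1;
      view(gp, par["b1"]) += arma::sum(dL1, 0).t();
      gp[as<IntegerVector>(par["eps"])[0]] += arma::accu(dZ % Xin);
      dH = (1.0 + epsv) * dZ + A * dZ;  // A symmetric
    } else if (kind == "arma") {
      int K = as<int>(hyper["K"]), T = as<int>(hyper["T"]);
      arma::mat dX(Xin.n_rows, Xin.n_cols, arma::fill::zeros);
      for (int k = 1; k <= K; ++k) {
        arma::mat dXb = dH / K;
        for (int t = T; t >= 1; --t) {
          std::string sfx = std::to_string(k) + "_" + std::to_string(t);
          arma::mat W = view(tp, par["W" + sfx]);
          arma::mat V = view(tp, par["V" + sfx]);
          arma::mat dZ = dXb % cache[li]["mask" + sfx];
          view(gp, par["W" + sfx]) += cache[li]["LXb" + sfx].t() * dZ;
          view(gp, par["V" + sfx]) += Xin.t() * dZ;
          view(gp, par["b" + sfx]) += arma::sum(dZ, 0).t();
          dX += dZ * V.t();
          dXb = Lt * (dZ * W.t());  // Lt symmetric
        }
        dX += dXb;  // Xbar(0) is the layer input
      }
      dH = dX;
    } else if (kind == "gat") {
      int heads = as<int>(hyper["heads"]);
      int d_out = as<int>(hyper["d_out"]);
      double slope = as<double>(hyper["slope"]);
      const arma::uword E = gsrc.n_elem, n = Xin.n_rows;
      arma::mat dpre_b = dH % cache[li]["mask"];
      view(gp, par["b"]) += arma::sum(dpre_b, 0).t();
      arma::mat dpre = dpre_b / heads;
      arma::mat dX(n, Xin.n_cols, arma::fill::zeros);
      for (int h = 1; h <= heads; ++h) {
        std::string hs = std::to_string(h);
        std::string pfx = "h" + hs;
        arma::mat W = view(tp, par["W" + hs]);
        arma::mat av = view(tp, par["a" + hs]);
        arma::vec a1 = av.col(0).rows(0, d_out - 1);
        arma::vec a2 = av.col(0).rows(d_out, 2 * d_out - 1);
        const arma::mat &Wh = cache[li][pfx + "Wh"];
        arma::vec alpha = cache[li][pfx + "alpha"].col(0);
        arma::vec elin = cache[li][pfx + "elin"].col(0);
        arma::mat dWh(n, d_out, arma::fill::zeros);
        arma::vec dalpha(E);
        for (arma::uword j = 0; j < E; ++j) {
          dWh.row(gsrc[j]) += alpha[j] * dpre.row(gdst[j]);
          dalpha[j] = arma::dot(Wh.row(gsrc[j]), dpre.row(gdst[j]));
        }
        arma::vec t1 = alpha % dalpha;
        arma::vec gsum(n, arma::fill::zeros);
        for (arma::uword j = 0; j < E; ++j) gsum[gdst[j]] += t1[j];
        arma::vec ds_dst(n, arma::fill::zeros), ds_src(n, arma::fill::zeros);
        for (arma::uword j = 0; j < E; ++j) {
          double de = t1[j] - alpha[j] * gsum[gdst[j]];
          double dl = de * (elin[j] > 0 ? 1.0 : slope);
          ds_dst[gdst[j]] += dl;
          ds_src[gsrc[j]] += dl;
        }
        dWh += ds_dst * a1.t() + ds_src * a2.t();
        arma::mat da = view(gp, par["a" + hs]);
        da.col(0).rows(0, d_out - 1) += (Wh.t() * ds_dst);
        da.col(0).rows(d_out, 2 * d_out - 1) += (Wh.t() * ds_src);
        view(gp, par["W" + hs]) += Xin.t() * dWh;
        dX += dWh * W.t();
      }
      dH = dX;
    } else if (kind == "sgc") {
      int K = as<int>(hyper["K"]);
      arma::mat W = view(tp, par["W"]);
      view(gp, par["W"]) += cache[li]["XK"].t() * dH;
      view(gp, par["b"]) += arma::sum(dH, 0).t();
      arma::mat dXK = dH * W.t();
      for (int i = 0; i < K; ++i) dXK = S * dXK;  // S symmetric
      dH = dXK;
    } else if (kind == "pool") {
      dH = P.t() * dH;
    }
  }

  out["grad"] = gradv;
  return out;
}

// In-place Adam update on the flat parameter vector.
// [[Rcpp::export(name = ".adam_update_cpp")]]
void adam_update_cpp(NumericVector theta, NumericVector grad,
                     NumericVector m, NumericVector v,
                     int t, double lr, double beta1, double beta2,
                     double eps) {
  const R_xlen_t n = theta.size();
  double *tp = REAL(theta), *gp = REAL(grad), *mp = REAL(m), *vp = REAL(v);
  const double c1 = 1.0 / (1.0 - std::pow(beta1, t));
  const double c2 = 1.0 / (1.0 - std::pow(beta2, t));
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
    tp[i] -= lr * (mp[i] * c1) / (std::sqrt(vp[i] * c2) + eps);
  }
}
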