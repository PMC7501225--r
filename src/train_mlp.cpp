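// Training loop for the feed-forward classifier.  The forward/backward pass
// mirrors the reference R implementation in R/model.R (which remains the
// documentation of record and is cross-checked in the test suite); this
// compiled version exists because cross-validation retrains the network ten
// times and an interpreted inner loop dominates the pipeline runtime.
//
// All randomness (shuffling, input noise, dropout masks) is drawn from R's
// RNG, so training is deterministic under a set R seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;

static const double BN_EPS = 1e-3;

struct Layers {
  std::vector<mat> W;
  std::vector<rowvec> b, gamma, beta, rmean, rvar;
  int nh;
};

static Layers layers_from_list(List init) {
  Layers L;
  L.nh = init.size() - 1;
  for (int l = 0; l < (int)init.size(); ++l) {
    List lay = init[l];
    L.W.push_back(as<mat>(lay["W"]));
    L.b.push_back(as<rowvec>(lay["b"]));
    if (l < L.nh) {
      L.gamma.push_back(as<rowvec>(lay["gamma"]));
      L.beta.push_back(as<rowvec>(lay["beta"]));
      L.rmean.push_back(as<rowvec>(lay["run_mean"]));
      L.rvar.push_back(as<rowvec>(lay["run_var"]));
    }
  }
  return L;
}

static List layers_to_list(const Layers& L) {
  List out(L.nh + 1);
  for (int l = 0; l <= L.nh; ++l) {
    if (l < L.nh) {
      out[l] = List::create(_["W"] = L.W[l], _["b"] = L.b[l],
                            _["gamma"] = L.gamma[l], _["beta"] = L.beta[l],
                            _["run_mean"] = L.rmean[l], _["run_var"] = L.rvar[l]);
    } else {
      out[l] = List::create(_["W"] = L.W[l], _["b"] = L.b[l]);
    }
  }
  return out;
}

static mat softmax_rows(mat z) {
  z.each_col() -= arma::max(z, 1);
  mat e = arma::exp(z);
  e.each_col() /= arma::sum(e, 1);
  return e;
}

static double cross_entropy(const mat& p, const mat& y) {
  arma::vec hit = arma::sum(p % y, 1);
  hit.transform([](double v) { return std::log(std::max(v, 1e-12)); });
  return -arma::mean(hit);
}

static mat forward_infer(const Layers& L, const mat& x, double alpha) {
  mat h = x;
  for (int l = 0; l < L.nh; ++l) {
    mat z = h * L.W[l];
    z.each_row() += L.b[l];
    rowvec inv_sd = 1.0 / arma::sqrt(L.rvar[l] + BN_EPS);
    z.each_row() -= L.rmean[l];
    z.each_row() %= inv_sd % L.gamma[l];
    z.each_row() += L.beta[l];
    h = z % (alpha + (1.0 - alpha) * arma::conv_to<mat>::from(z > 0));
  }
  mat logits = h * L.W[L.nh];
  logits.each_row() += L.b[L.nh];
  return softmax_rows(logits);
}

// fill a matrix with N(0, sd) / U(0,1) draws from R's RNG (column-major,
// matching the reference implementation's draw order)
static mat r_randn(int nr, int nc, double sd) {
  mat m(nr, nc);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = R::rnorm(0.0, sd);
  return m;
}
static mat r_dropout_mask(int nr, int nc, double keep) {
  mat m(nr, nc);
  for (arma::uword i = 0; i < m.n_elem; ++i)
    m(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

// [[Rcpp::export]]
List cpp_train_mlp(const arma::mat& X, const arma::mat& Y,
                   const arma::mat& Xval, const arma::mat& Yval,
                   List init_layers, List cfg) {
  Layers L = layers_from_list(init_layers);
  const int nh = L.nh;
  const double alpha = cfg["leaky_relu_alpha"];
  const double drop = cfg["dropout_rate"];
  const double mom = cfg["batchnorm_momentum"];
  const double noise = cfg["input_noise_std"];
  const double lr0 = cfg["learning_rate"];
  const double decay = cfg["decay"];
  const double clip = cfg["clip_norm"];
  const int batch = cfg["batch_size"];
  const int max_epochs = cfg["max_epochs"];
  const int patience = cfg["early_stop_patience"];
  const int n = X.n_rows;

  // Adam state, one slot per trainable tensor (W, b per layer; gamma, beta
  // for hidden layers), flattened bookkeeping kept per tensor
  std::vector<mat> mW(nh + 1), vW(nh + 1);
  std::vector<rowvec> mb(nh + 1), vb(nh + 1), mg(nh), vg(nh), mbe(nh), vbe(nh);
  for (int l = 0; l <= nh; ++l) {
    mW[l].zeros(L.W[l].n_rows, L.W[l].n_cols); vW[l] = mW[l];
    mb[l].zeros(L.b[l].n_elem); vb[l] = mb[l];
    if (l < nh) {
      mg[l].zeros(L.gamma[l].n_elem); vg[l] = mg[l];
      mbe[l].zeros(L.beta[l].n_elem); vbe[l] = mbe[l];
    }
  }
  const double b1 = 0.9, b2 = 0.999, aeps = 1e-7;
  long step = 0;

  std::vector<double> hist_train, hist_val;
  double best_val = R_PosInf;
  Layers best = L;
  int best_epoch = 0, wait = 0, stopped = max_epochs;

  std::vector<mat> Hin(nh), Zhat(nh), Apre(nh), Mask(nh);
  std::vector<rowvec> InvSd(nh);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // shuffled row order from R's RNG
    IntegerVector perm = Rcpp::sample(n, n, false) - 1;
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch) {
      const int stop = std::min(start + batch, n) - 1;
      const int nb = stop - start + 1;
      arma::uvec rows(nb);
      for (int i = 0; i < nb; ++i) rows[i] = perm[start + i];
      mat h = X.rows(rows);
      const mat yb = Y.rows(rows);
      if (noise > 0) h += r_randn(nb, h.n_cols, noise);

      // forward (training mode)
      for (int l = 0; l < nh; ++l) {
        Hin[l] = h;
        mat z = h * L.W[l];
        z.each_row() += L.b[l];
        rowvec mu = arma::mean(z, 0);
        z.each_row() -= mu;
        rowvec var = arma::mean(arma::square(z), 0);
        InvSd[l] = 1.0 / arma::sqrt(var + BN_EPS);
        z.each_row() %= InvSd[l];
        Zhat[l] = z;
        z.each_row() %= L.gamma[l];
        z.each_row() += L.beta[l];
        Apre[l] = z;
        mat act = z % (alpha + (1.0 - alpha) * arma::conv_to<mat>::from(z > 0));
        if (drop > 0) {
          Mask[l] = r_dropout_mask(nb, act.n_cols, 1.0 - drop);
          act %= Mask[l];
        }
        // moving statistics (Keras convention), unbiased batch variance
        double ub = nb > 1 ? (double)nb / (nb - 1) : 1.0;
        L.rmean[l] = mom * L.rmean[l] + (1.0 - mom) * mu;
        L.rvar[l] = mom * L.rvar[l] + (1.0 - mom) * (var * ub);
        h = act;
      }
      mat logits = h * L.W[nh];
      logits.each_row() += L.b[nh];
      mat probs = softmax_rows(logits);
      ep_loss += cross_entropy(probs, yb) * nb;

      // backward
      std::vector<mat> gW(nh + 1);
      std::vector<rowvec> gb(nh + 1), ggamma(nh), gbeta(nh);
      mat delta = (probs - yb) / nb;
      gW[nh] = h.t() * delta;
      gb[nh] = arma::sum(delta, 0);
      mat dh = delta * L.W[nh].t();
      for (int l = nh - 1; l >= 0; --l) {
        if (drop > 0) dh %= Mask[l];
        mat dact = dh % (alpha + (1.0 - alpha) * arma::conv_to<mat>::from(Apre[l] > 0));
        ggamma[l] = arma::sum(dact % Zhat[l], 0);
        gbeta[l] = arma::sum(dact, 0);
        mat dzhat = dact.each_row() % L.gamma[l];
        rowvec t1 = arma::sum(dzhat, 0) / nb;
        rowvec t2 = arma::sum(dzhat % Zhat[l], 0) / nb;
        mat dz = dzhat;
        dz.each_row() -= t1;
        dz -= Zhat[l].each_row() % t2;
        dz.each_row() %= InvSd[l];
        gW[l] = Hin[l].t() * dz;
        gb[l] = arma::sum(dz, 0);
        if (l > 0) dh = dz * L.W[l].t();
      }

      // global gradient-norm clip, then Adam with time-based lr decay
      double gsq = 0.0;
      for (int l = 0; l <= nh; ++l) {
        gsq += arma::accu(arma::square(gW[l])) + arma::accu(arma::square(gb[l]));
        if (l < nh)
          gsq += arma::accu(arma::square(ggamma[l])) + arma::accu(arma::square(gbeta[l]));
      }
      const double gnorm = std::sqrt(gsq);
      const double scale = gnorm > clip ? clip / gnorm : 1.0;
      ++step;
      const double lr = lr0 / (1.0 + decay * (double)step);
      const double bc1 = 1.0 - std::pow(b1, (double)step);
      const double bc2 = 1.0 - std::pow(b2, (double)step);
      auto adam_mat = [&](mat& w, mat& m, mat& v, mat g) {
        g *= scale;
        m = b1 * m + (1.0 - b1) * g;
        v = b2 * v + (1.0 - b2) * arma::square(g);
        w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + aeps);
      };
      auto adam_row = [&](rowvec& w, rowvec& m, rowvec& v, rowvec g) {
        g *= scale;
        m = b1 * m + (1.0 - b1) * g;
        v = b2 * v + (1.0 - b2) * arma::square(g);
        w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + aeps);
      };
      for (int l = 0; l <= nh; ++l) {
        adam_mat(L.W[l], mW[l], vW[l], gW[l]);
        adam_row(L.b[l], mb[l], vb[l], gb[l]);
        if (l < nh) {
          adam_row(L.gamma[l], mg[l], vg[l], ggamma[l]);
          adam_row(L.beta[l], mbe[l], vbe[l], gbeta[l]);
        }
      }
    }
    hist_train.push_back(ep_loss / n);
    const double val = cross_entropy(forward_infer(L, Xval, alpha), Yval);
    hist_val.push_back(val);
    if (val < best_val) {
      best_val = val;
      best = L;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      stopped = epoch;
      break;
    }
    if (epoch % 50 == 0) Rcpp::checkUserInterrupt();
  }
  if ((int)hist_val.size() < stopped) stopped = hist_val.size();

  return List::create(
      _["layers"] = layers_to_list(best),
      _["train_loss"] = hist_train,
      _["val_loss"] = hist_val,
      _["best_epoch"] = best_epoch,
      _["stopped_epoch"] = stopped);
}
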