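// Core mean-field coordinate-ascent engine for the latent-context eQTL model.
//
// Model, per sample n and test t:
//   y_nt ~ N( mu_t + sum_l X_nl W_lt + alpha_{i(n),t}
//             + Gm_nt F_t + Gi_nt sum_k U_nk V_kt , sigma_t^2 )
// with priors U_nk ~ N(0, gamma_k^2), V_kt, F_t, mu_t, W_lt ~ N(0,1),
// alpha_it ~ N(0, psi_t^2), and Gamma(a0,b0) priors on the precisions
// 1/gamma_k^2, 1/psi_t^2, 1/sigma_t^2 (shape-rate).
//
// Gm is the genotype entering the shared (main) eQTL effect and Gi the
// genotype entering the interaction term; they coincide except under the
// individual-level genotype permutation, which permutes Gi only.
//
// The variational family is fully factorized: a Gaussian per scalar latent
// and a Gamma per precision. Every block update below is the closed-form
// conjugate coordinate-ascent optimum; a residual matrix R = Y - E[pred] is
// maintained incrementally so each block costs O(NT) (O(NTK) for U and V).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static vec digammav(const vec& x) {
  vec out(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) out(i) = R::digamma(x(i));
  return out;
}

static vec lgammav(const vec& x) {
  vec out(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) out(i) = R::lgammafn(x(i));
  return out;
}

struct State {
  mat Umu, Us2;    // N x K
  mat Vmu, Vs2;    // K x T
  vec Fmu, Fs2;    // T
  vec mumu, mus2;  // T
  mat Wmu, Ws2;    // L x T
  mat Amu, As2;    // I x T
  vec ga, gb;      // K   (gamma precisions)
  vec pa, pb;      // T   (psi precisions)
  vec sa, sb;      // T   (sigma precisions)
};

static State unpackState(const Rcpp::List& st) {
  State s;
  s.Umu = Rcpp::as<mat>(st["Umu"]);  s.Us2 = Rcpp::as<mat>(st["Us2"]);
  s.Vmu = Rcpp::as<mat>(st["Vmu"]);  s.Vs2 = Rcpp::as<mat>(st["Vs2"]);
  s.Fmu = Rcpp::as<vec>(st["Fmu"]);  s.Fs2 = Rcpp::as<vec>(st["Fs2"]);
  s.mumu = Rcpp::as<vec>(st["mumu"]); s.mus2 = Rcpp::as<vec>(st["mus2"]);
  s.Wmu = Rcpp::as<mat>(st["Wmu"]);  s.Ws2 = Rcpp::as<mat>(st["Ws2"]);
  s.Amu = Rcpp::as<mat>(st["Amu"]);  s.As2 = Rcpp::as<mat>(st["As2"]);
  s.ga = Rcpp::as<vec>(st["ga"]);    s.gb = Rcpp::as<vec>(st["gb"]);
  s.pa = Rcpp::as<vec>(st["pa"]);    s.pb = Rcpp::as<vec>(st["pb"]);
  s.sa = Rcpp::as<vec>(st["sa"]);    s.sb = Rcpp::as<vec>(st["sb"]);
  return s;
}

static Rcpp::List packState(const State& s) {
  return Rcpp::List::create(
    Rcpp::Named("Umu") = s.Umu,  Rcpp::Named("Us2") = s.Us2,
    Rcpp::Named("Vmu") = s.Vmu,  Rcpp::Named("Vs2") = s.Vs2,
    Rcpp::Named("Fmu") = s.Fmu,  Rcpp::Named("Fs2") = s.Fs2,
    Rcpp::Named("mumu") = s.mumu, Rcpp::Named("mus2") = s.mus2,
    Rcpp::Named("Wmu") = s.Wmu,  Rcpp::Named("Ws2") = s.Ws2,
    Rcpp::Named("Amu") = s.Amu,  Rcpp::Named("As2") = s.As2,
    Rcpp::Named("ga") = s.ga,    Rcpp::Named("gb") = s.gb,
    Rcpp::Named("pa") = s.pa,    Rcpp::Named("pb") = s.pb,
    Rcpp::Named("sa") = s.sa,    Rcpp::Named("sb") = s.sb);
}

// E[prediction] under q
static mat predMean(const State& s, const mat& Gm, const mat& Gi, const mat& X,
                    const uvec& ind, bool useAlpha) {
  mat M = Gi % (s.Umu * s.Vmu);
  M += Gm.each_row() % s.Fmu.t();
  M.each_row() += s.mumu.t();
  if (X.n_cols > 0) M += X * s.Wmu;
  if (useAlpha) M += s.Amu.rows(ind);
  return M;
}

// Var[prediction] under q (mean-field independence across factors; across k
// the products U_nk V_kt are independent, so variances add:
// Var(U V) = E[U^2]E[V^2] - (E[U]E[V])^2).
static mat predVar(const State& s, const mat& Gm2, const mat& Gi2, const mat& X2,
                   const uvec& ind, bool useAlpha) {
  mat U2 = square(s.Umu) + s.Us2;
  mat V2 = square(s.Vmu) + s.Vs2;
  mat Vp = Gi2 % (U2 * V2 - square(s.Umu) * square(s.Vmu));
  Vp += Gm2.each_row() % s.Fs2.t();
  Vp.each_row() += s.mus2.t();
  if (X2.n_cols > 0) Vp += X2 * s.Ws2;
  if (useAlpha) Vp += s.As2.rows(ind);
  return Vp;
}

static void checkFinite(const vec& v, const std::string& block) {
  if (!v.is_finite())
    Rcpp::stop("numerical overflow in variational update of block '" + block + "'");
}

// ELBO assembled from the current residual matrix R = Y - E[pred] and
// prediction variance Vp; shared by the standalone entry point and the
// fused update+ELBO path.
static double elboFromParts(const State& s, const mat& R, const mat& Vp,
                            int N, int T, int L, int I, bool useAlpha,
                            double a0, double b0) {
  const int K = s.Umu.n_cols;
  const double l2pi = std::log(2.0 * M_PI);

  vec esq = sum(square(R) + Vp, 0).t();
  vec ElogTs = digammav(s.sa) - log(s.sb);
  vec ETs = s.sa / s.sb;
  double elbo = 0.5 * (double)N * accu(ElogTs - l2pi) - 0.5 * accu(ETs % esq);

  vec ElogTg = digammav(s.ga) - log(s.gb);
  vec ETg = s.ga / s.gb;
  for (int k = 0; k < K; ++k)
    elbo += 0.5 * (double)N * (ElogTg(k) - l2pi)
          - 0.5 * ETg(k) * accu(square(s.Umu.col(k)) + s.Us2.col(k));
  elbo += -0.5 * accu(square(s.Vmu) + s.Vs2) - 0.5 * (double)(K * T) * l2pi;
  elbo += -0.5 * accu(square(s.Fmu) + s.Fs2) - 0.5 * (double)T * l2pi;
  elbo += -0.5 * accu(square(s.mumu) + s.mus2) - 0.5 * (double)T * l2pi;
  if (L > 0)
    elbo += -0.5 * accu(square(s.Wmu) + s.Ws2) - 0.5 * (double)(L * T) * l2pi;

  vec ElogTp, ETp;
  if (useAlpha) {
    ElogTp = digammav(s.pa) - log(s.pb);
    ETp = s.pa / s.pb;
    vec a2 = sum(square(s.Amu) + s.As2, 0).t();
    elbo += 0.5 * (double)I * accu(ElogTp - l2pi) - 0.5 * accu(ETp % a2);
  }

  const double gconst = a0 * std::log(b0) - R::lgammafn(a0);
  elbo += (double)K * gconst + (a0 - 1.0) * accu(ElogTg) - b0 * accu(ETg);
  elbo += (double)T * gconst + (a0 - 1.0) * accu(ElogTs) - b0 * accu(ETs);
  if (useAlpha)
    elbo += (double)T * gconst + (a0 - 1.0) * accu(ElogTp) - b0 * accu(ETp);

  double ent = 0.0;
  ent += 0.5 * accu(log(s.Us2)) + 0.5 * (double)(N * K) * (1.0 + l2pi);
  ent += 0.5 * accu(log(s.Vs2)) + 0.5 * (double)(K * T) * (1.0 + l2pi);
  ent += 0.5 * accu(log(s.Fs2)) + 0.5 * (double)T * (1.0 + l2pi);
  ent += 0.5 * accu(log(s.mus2)) + 0.5 * (double)T * (1.0 + l2pi);
  if (L > 0)
    ent += 0.5 * accu(log(s.Ws2)) + 0.5 * (double)(L * T) * (1.0 + l2pi);
  if (useAlpha)
    ent += 0.5 * accu(log(s.As2)) + 0.5 * (double)(I * T) * (1.0 + l2pi);
  ent += accu(s.ga - log(s.gb) + lgammav(s.ga) + (1.0 - s.ga) % digammav(s.ga));
  ent += accu(s.sa - log(s.sb) + lgammav(s.sa) + (1.0 - s.sa) % digammav(s.sa));
  if (useAlpha)
    ent += accu(s.pa - log(s.pb) + lgammav(s.pa) + (1.0 - s.pa) % digammav(s.pa));

  return elbo + ent;
}

// [[Rcpp::export(name = ".cpp_update_blocks")]]
Rcpp::List cpp_update_blocks(Rcpp::List st,
                             const arma::mat& Y, const arma::mat& Gm,
                             const arma::mat& Gi, const arma::mat& X,
                             const arma::uvec& ind1, int I, bool useAlpha,
                             double a0, double b0,
                             std::vector<std::string> blocks,
                             bool returnElbo = false) {
  State s = unpackState(st);
  const int N = Y.n_rows, T = Y.n_cols, L = X.n_cols, K = s.Umu.n_cols;
  const uvec ind = ind1 - 1;
  const mat Gm2 = square(Gm), Gi2 = square(Gi), X2 = square(X);

  vec tau = s.sa / s.sb;  // E[1/sigma_t^2]
  mat M = predMean(s, Gm, Gi, X, ind, useAlpha);
  mat R = Y - M;

  vec ni(I, fill::zeros);
  for (int n = 0; n < N; ++n) ni(ind(n)) += 1.0;

  mat VpLast;           // prediction variance from the most recent sigma update
  bool vpCurrent = false;

  for (const std::string& block : blocks) {
    if (block == "V") {
      // q(V_kt) = N(m, s2): s2 = 1/(1 + tau_t sum_n Gi^2 E[U^2]),
      // m = s2 tau_t sum_n Gi E[U] (y - E[pred excluding V_kt])
      for (int k = 0; k < K; ++k) {
        vec u = s.Umu.col(k);
        vec u2 = square(u) + s.Us2.col(k);
        vec A = Gi2.t() * u2;
        vec s2 = 1.0 / (1.0 + tau % A);
        rowvec vold = s.Vmu.row(k);
        mat GR = Gi % R;
        vec num = GR.t() * u + (Gi2.t() * square(u)) % vold.t();
        vec mnew = s2 % (tau % num);
        checkFinite(mnew, "V");
        mat D = Gi.each_col() % u;
        D.each_row() %= (vold - mnew.t());
        R += D;
        s.Vmu.row(k) = mnew.t();
        s.Vs2.row(k) = s2.t();
      }
    } else if (block == "F") {
      vec gm2cs = sum(Gm2, 0).t();
      vec s2 = 1.0 / (1.0 + tau % gm2cs);
      vec num = sum(Gm % R, 0).t() + gm2cs % s.Fmu;
      vec mnew = s2 % (tau % num);
      checkFinite(mnew, "F");
      R += Gm.each_row() % (s.Fmu - mnew).t();
      s.Fmu = mnew;
      s.Fs2 = s2;
    } else if (block == "mu") {
      vec s2 = 1.0 / (1.0 + tau * (double)N);
      vec num = sum(R, 0).t() + (double)N * s.mumu;
      vec mnew = s2 % (tau % num);
      checkFinite(mnew, "mu");
      R.each_row() += (s.mumu - mnew).t();
      s.mumu = mnew;
      s.mus2 = s2;
    } else if (block == "W") {
      for (int l = 0; l < L; ++l) {
        vec x = X.col(l);
        double xs = accu(square(x));
        rowvec wold = s.Wmu.row(l);
        vec s2 = 1.0 / (1.0 + tau * xs);
        vec num = R.t() * x + xs * wold.t();
        vec mnew = s2 % (tau % num);
        checkFinite(mnew, "W");
        R += x * (wold - mnew.t());
        s.Wmu.row(l) = mnew.t();
        s.Ws2.row(l) = s2.t();
      }
    } else if (block == "alpha") {
      if (!useAlpha) continue;
      vec taup = s.pa / s.pb;
      mat S(I, T, fill::zeros);
      for (int n = 0; n < N; ++n) S.row(ind(n)) += R.row(n);
      mat s2a = 1.0 / (ones<vec>(I) * taup.t() + ni * tau.t());
      mat num = S + s.Amu.each_col() % ni;
      mat Anew = s2a % (num.each_row() % tau.t());
      checkFinite(vectorise(Anew), "alpha");
      for (int n = 0; n < N; ++n)
        R.row(n) += s.Amu.row(ind(n)) - Anew.row(ind(n));
      s.Amu = Anew;
      s.As2 = s2a;
    } else if (block == "U") {
      // q(U_nk): prior precision E[1/gamma_k^2], likelihood coefficient Gi V_kt
      for (int k = 0; k < K; ++k) {
        vec v = s.Vmu.row(k).t();
        vec v2 = square(v) + s.Vs2.row(k).t();
        double tg = s.ga(k) / s.gb(k);
        vec denom = Gi2 * (tau % v2) + tg;
        vec s2 = 1.0 / denom;
        vec uold = s.Umu.col(k);
        mat GR = Gi % R;
        vec num = GR * (tau % v) + (Gi2 * (tau % square(v))) % uold;
        vec mnew = s2 % num;
        checkFinite(mnew, "U");
        mat D = Gi.each_col() % (uold - mnew);
        D.each_row() %= v.t();
        R += D;
        s.Umu.col(k) = mnew;
        s.Us2.col(k) = s2;
      }
    } else if (block == "gamma") {
      for (int k = 0; k < K; ++k) {
        s.ga(k) = a0 + (double)N / 2.0;
        s.gb(k) = b0 + 0.5 * accu(square(s.Umu.col(k)) + s.Us2.col(k));
      }
      checkFinite(s.gb, "gamma");
    } else if (block == "psi") {
      if (!useAlpha) continue;
      s.pa.fill(a0 + (double)I / 2.0);
      s.pb = b0 + 0.5 * sum(square(s.Amu) + s.As2, 0).t();
      checkFinite(s.pb, "psi");
    } else if (block == "sigma") {
      VpLast = predVar(s, Gm2, Gi2, X2, ind, useAlpha);
      vpCurrent = true;
      vec esq = sum(square(R) + VpLast, 0).t();
      s.sa.fill(a0 + (double)N / 2.0);
      s.sb = b0 + 0.5 * esq;
      checkFinite(s.sb, "sigma");
      tau = s.sa / s.sb;  // later blocks in this sweep see the new precision
      continue;
    } else {
      Rcpp::stop("unknown block '" + block + "'");
    }
    vpCurrent = false;  // any mean/variance change invalidates the cached Vp
  }
  Rcpp::List out = packState(s);
  if (returnElbo) {
    if (!vpCurrent) VpLast = predVar(s, Gm2, Gi2, X2, ind, useAlpha);
    out.attr("elbo") = elboFromParts(s, R, VpLast, N, T, L, I, useAlpha, a0, b0);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_elbo")]]
double cpp_elbo(Rcpp::List st,
                const arma::mat& Y, const arma::mat& Gm,
                const arma::mat& Gi, const arma::mat& X,
                const arma::uvec& ind1, int I, bool useAlpha,
                double a0, double b0) {
  State s = unpackState(st);
  const int N = Y.n_rows, T = Y.n_cols, L = X.n_cols;
  const uvec ind = ind1 - 1;

  if (s.Us2.min() <= 0 || s.Vs2.min() <= 0 || s.Fs2.min() <= 0 ||
      s.mus2.min() <= 0 || (L > 0 && s.Ws2.min() <= 0) ||
      (useAlpha && s.As2.min() <= 0))
    Rcpp::stop("non-positive variational variance");
  if (s.ga.min() <= 0 || s.gb.min() <= 0 || s.sa.min() <= 0 || s.sb.min() <= 0 ||
      (useAlpha && (s.pa.min() <= 0 || s.pb.min() <= 0)))
    Rcpp::stop("non-positive Gamma variational parameter");

  const mat Gm2 = square(Gm), Gi2 = square(Gi), X2 = square(X);
  mat M = predMean(s, Gm, Gi, X, ind, useAlpha);
  mat R = Y - M;
  mat Vp = predVar(s, Gm2, Gi2, X2, ind, useAlpha);
  return elboFromParts(s, R, Vp, N, T, L, I, useAlpha, a0, b0);
}
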