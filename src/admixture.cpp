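// Gibbs sampler for the admixture model with correlated allele frequencies
// (F-model): each cluster's frequencies drift from shared ancestral
// frequencies; individuals carry Dirichlet(alpha) admixture proportions.
// Uses R's RNG throughout so results are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static double rgamma1(double shape) {
  // R::rgamma handles shape < 1 correctly
  return R::rgamma(shape, 1.0);
}

static void rdirichlet(const std::vector<double>& shape,
                       std::vector<double>& out) {
  if (out.size() < shape.size()) out.resize(shape.size());
  double s = 0.0;
  for (size_t i = 0; i < shape.size(); ++i) {
    out[i] = rgamma1(shape[i] > 1e-8 ? shape[i] : 1e-8);
    s += out[i];
  }
  if (s <= 0) { // degenerate; fall back to uniform
    for (size_t i = 0; i < shape.size(); ++i) out[i] = 1.0 / shape.size();
    return;
  }
  for (size_t i = 0; i < shape.size(); ++i) {
    out[i] /= s;
    if (out[i] < 1e-12) out[i] = 1e-12;
  }
}

static double logDirichletDensity(const std::vector<double>& x,
                                  const std::vector<double>& a) {
  double s = 0.0, sa = 0.0;
  for (size_t i = 0; i < x.size(); ++i) {
    s += (a[i] - 1.0) * std::log(x[i]) - R::lgammafn(a[i]);
    sa += a[i];
  }
  return s + R::lgammafn(sa);
}

// [[Rcpp::export(name = ".admixtureGibbs")]]
List admixtureGibbs(IntegerMatrix Xa, IntegerMatrix Xb,
                    IntegerVector numAlleles, int K,
                    int burnin, int reps,
                    double alphaInit, double alphaPropSD,
                    double lambda, double driftInit) {
  const int n = Xa.nrow(), L = Xa.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > n) stop("K exceeds the number of individuals");

  // state
  std::vector<std::vector<std::vector<double>>> P(K), PA1;  // P[k][l][a]
  std::vector<std::vector<double>> PA(L);                    // ancestral
  NumericMatrix Q(n, K);
  std::vector<double> Fk(K, driftInit);
  double alpha = alphaInit;

  // allele counts from data for initial frequencies
  for (int l = 0; l < L; ++l) {
    PA[l].assign(numAlleles[l], 1.0);  // +1 pseudocount
    for (int i = 0; i < n; ++i) {
      if (Xa(i, l) > 0) PA[l][Xa(i, l) - 1] += 1.0;
      if (Xb(i, l) > 0) PA[l][Xb(i, l) - 1] += 1.0;
    }
    double s = 0.0;
    for (double v : PA[l]) s += v;
    for (double& v : PA[l]) v /= s;
  }
  for (int k = 0; k < K; ++k) {
    P[k].resize(L);
    for (int l = 0; l < L; ++l) P[k][l] = PA[l];
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;

  // latent cluster-of-origin per allele copy
  IntegerMatrix Za(n, L), Zb(n, L);
  for (int i = 0; i < n; ++i) for (int l = 0; l < L; ++l) {
    Za(i, l) = (int)(R::unif_rand() * K);
    Zb(i, l) = (int)(R::unif_rand() * K);
  }

  // accumulators
  NumericMatrix Qsum(n, K);
  std::vector<std::vector<std::vector<double>>> Psum(K);
  for (int k = 0; k < K; ++k) {
    Psum[k].resize(L);
    for (int l = 0; l < L; ++l) Psum[k][l].assign(numAlleles[l], 0.0);
  }
  double llSum = 0.0, llSqSum = 0.0, alphaSum = 0.0;
  int nSaved = 0;

  int maxA = K;
  for (int l = 0; l < L; ++l) if (numAlleles[l] > maxA) maxA = numAlleles[l];
  std::vector<double> work(maxA + 1), shape(maxA + 1), prop(maxA + 1);
  const int total = burnin + reps;

  for (int sweep = 0; sweep < total; ++sweep) {
    // --- update Z (cluster of origin of each allele copy)
    for (int i = 0; i < n; ++i) for (int l = 0; l < L; ++l) {
      for (int copy = 0; copy < 2; ++copy) {
        int a = copy == 0 ? Xa(i, l) : Xb(i, l);
        if (a <= 0) continue;
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          work[k] = Q(i, k) * P[k][l][a - 1];
          s += work[k];
        }
        double u = R::unif_rand() * s, acc = 0.0;
        int z = K - 1;
        for (int k = 0; k < K; ++k) { acc += work[k]; if (u <= acc) { z = k; break; } }
        if (copy == 0) Za(i, l) = z; else Zb(i, l) = z;
      }
    }

    // --- update P | Z under the F-model prior Dir(PA * (1-F)/F)
    for (int k = 0; k < K; ++k) {
      double fr = (1.0 - Fk[k]) / Fk[k];
      for (int l = 0; l < L; ++l) {
        int A = numAlleles[l];
        shape.assign(A, 0.0);
        for (int a = 0; a < A; ++a) shape[a] = PA[l][a] * fr;
        for (int i = 0; i < n; ++i) {
          if (Xa(i, l) > 0 && Za(i, l) == k) shape[Xa(i, l) - 1] += 1.0;
          if (Xb(i, l) > 0 && Zb(i, l) == k) shape[Xb(i, l) - 1] += 1.0;
        }
        rdirichlet(shape, P[k][l]);
      }
    }

    // --- update Q | Z ~ Dirichlet(alpha + counts)
    for (int i = 0; i < n; ++i) {
      shape.assign(K, alpha);
      for (int l = 0; l < L; ++l) {
        if (Xa(i, l) > 0) shape[Za(i, l)] += 1.0;
        if (Xb(i, l) > 0) shape[Zb(i, l)] += 1.0;
      }
      rdirichlet(shape, work);
      for (int k = 0; k < K; ++k) Q(i, k) = work[k];
    }

    // --- update alpha by Metropolis (uniform prior on (0, 10))
    if (K > 1) {
      double aProp = alpha + R::norm_rand() * alphaPropSD;
      if (aProp > 0.0 && aProp < 10.0) {
        double lr = 0.0;
        for (int i = 0; i < n; ++i) {
          for (int k = 0; k < K; ++k)
            lr += (aProp - alpha) * std::log(Q(i, k));
          lr += R::lgammafn(K * aProp) - K * R::lgammafn(aProp)
              - (R::lgammafn(K * alpha) - K * R::lgammafn(alpha));
        }
        if (std::log(R::unif_rand()) < lr) alpha = aProp;
      }
    }

    // --- update drift Fk by Metropolis (uniform prior on (0, 1))
    for (int k = 0; k < K; ++k) {
      double fProp = Fk[k] + R::norm_rand() * 0.05;
      if (fProp <= 0.001 || fProp >= 0.999) continue;
      double frOld = (1.0 - Fk[k]) / Fk[k];
      double frNew = (1.0 - fProp) / fProp;
      double lr = 0.0;
      for (int l = 0; l < L; ++l) {
        int A = numAlleles[l];
        std::vector<double> aOld(A), aNew(A);
        for (int a = 0; a < A; ++a) {
          aOld[a] = std::max(PA[l][a] * frOld, 1e-8);
          aNew[a] = std::max(PA[l][a] * frNew, 1e-8);
        }
        lr += logDirichletDensity(P[k][l], aNew)
            - logDirichletDensity(P[k][l], aOld);
      }
      if (std::log(R::unif_rand()) < lr) Fk[k] = fProp;
    }

    // --- update ancestral PA by Metropolis per locus
    for (int l = 0; l < L; ++l) {
      int A = numAlleles[l];
      if (A < 2) continue;
      const double conc = 100.0;
      shape.assign(A, 0.0);
      for (int a = 0; a < A; ++a) shape[a] = conc * PA[l][a] + 0.1;
      prop.assign(A, 0.0);
      rdirichlet(shape, prop);
      std::vector<double> shapeBack(A);
      for (int a = 0; a < A; ++a) shapeBack[a] = conc * prop[a] + 0.1;
      double lr = 0.0;
      for (int k = 0; k < K; ++k) {
        double fr = (1.0 - Fk[k]) / Fk[k];
        std::vector<double> aOld(A), aNew(A);
        for (int a = 0; a < A; ++a) {
          aOld[a] = std::max(PA[l][a] * fr, 1e-8);
          aNew[a] = std::max(prop[a] * fr, 1e-8);
        }
        lr += logDirichletDensity(P[k][l], aNew)
            - logDirichletDensity(P[k][l], aOld);
      }
      // Dirichlet(lambda) prior on PA
      for (int a = 0; a < A; ++a)
        lr += (lambda - 1.0) * (std::log(prop[a]) - std::log(PA[l][a]));
      // proposal correction
      std::vector<double> paOld(PA[l]);
      lr += logDirichletDensity(paOld, shapeBack)
          - logDirichletDensity(prop, shape);
      if (std::log(R::unif_rand()) < lr) PA[l] = prop;
    }

    // --- record
    if (sweep >= burnin) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i) for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = copy == 0 ? Xa(i, l) : Xb(i, l);
          if (a <= 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) s += Q(i, k) * P[k][l][a - 1];
          ll += std::log(std::max(s, 1e-300));
        }
      }
      if (!R_finite(ll)) stop("non-finite likelihood at sweep %d", sweep);
      llSum += ll; llSqSum += ll * ll; alphaSum += alpha;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          for (int a = 0; a < numAlleles[l]; ++a)
            Psum[k][l][a] += P[k][l][a];
      ++nSaved;
    }
  }

  // posterior means
  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Qsum(i, k);
    for (int k = 0; k < K; ++k) Qmean(i, k) = Qsum(i, k) / (s > 0 ? s : 1);
  }
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix M(K, numAlleles[l]);
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int a = 0; a < numAlleles[l]; ++a) s += Psum[k][l][a];
      for (int a = 0; a < numAlleles[l]; ++a)
        M(k, a) = Psum[k][l][a] / (s > 0 ? s : 1);
    }
    Pout[l] = M;
  }
  double llMean = llSum / nSaved;
  double llVar = llSqSum / nSaved - llMean * llMean;
  return List::create(_["Q"] = Qmean, _["P"] = Pout,
                      _["logLik"] = llMean, _["logLikVar"] = llVar,
                      _["alpha"] = alphaSum / nSaved);
}
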