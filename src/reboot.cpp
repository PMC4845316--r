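#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Average ranks (ties share the mean rank), as in Spearman's rho.
static void rank_avg(const std::vector<double>& x, std::vector<double>& r) {
  const int n = (int)x.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&x](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    i = j + 1;
  }
}

// Pearson correlation of two rank vectors.
static double pearson(const std::vector<double>& a,
                      const std::vector<double>& b) {
  const int n = (int)a.size();
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (int i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// ReBoot-style null and bootstrap for all genus pairs of a
// compositional abundance matrix V (genera x samples, columns sum 1).
//
// Null for pair (i,j), i<j: permute row i across samples, renormalize
// every sample column to unit sum, recompute Spearman's rho between
// the renormalized rows i and j. Bootstrap: resample sample columns
// with replacement, recompute rho. Both streams are seeded
// deterministically: row i's permutations from mt19937_64(seed*1000 + i),
// the shared bootstrap resamples from mt19937_64(seed*1000 - 1), so a
// single pair recomputed in isolation reproduces the batch entry.
//
// [[Rcpp::export]]
List reboot_all_cpp(NumericMatrix V, int n_perm, int n_boot, double seed) {
  const int G = V.nrow(), n = V.ncol();
  NumericMatrix rho(G, G), mean_perm(G, G), var_perm(G, G),
      mean_boot(G, G), var_boot(G, G);

  std::vector<std::vector<double> > rows(G, std::vector<double>(n)),
      ranks(G, std::vector<double>(n));
  std::vector<bool> constant(G, false);
  for (int i = 0; i < G; ++i) {
    for (int s = 0; s < n; ++s) rows[i][s] = V(i, s);
    constant[i] = *std::min_element(rows[i].begin(), rows[i].end()) ==
                  *std::max_element(rows[i].begin(), rows[i].end());
    rank_avg(rows[i], ranks[i]);
  }
  for (int i = 0; i < G; ++i) {
    rho(i, i) = 1.0;
    for (int j = i + 1; j < G; ++j) {
      double r = (constant[i] || constant[j]) ? NA_REAL
                                              : pearson(ranks[i], ranks[j]);
      rho(i, j) = rho(j, i) = r;
    }
  }

  // Permutation null: row i shuffled, used for all pairs (i, j>i).
  std::vector<double> permrow(n), csnew(n), reni(n), renj(n),
      ranki(n), rankj(n);
  std::vector<int> perm(n);
  for (int i = 0; i < G; ++i) {
    if (constant[i]) continue;
    std::mt19937_64 eng((uint64_t)(seed * 1000.0) + (uint64_t)i);
    std::vector<double> s1(G, 0.0), s2(G, 0.0);
    std::vector<int> cnt(G, 0);
    for (int p = 0; p < n_perm; ++p) {
      for (int s = 0; s < n; ++s) perm[s] = s;
      for (int s = n - 1; s > 0; --s) {       // Fisher-Yates
        std::uniform_int_distribution<int> u(0, s);
        std::swap(perm[s], perm[u(eng)]);
      }
      for (int s = 0; s < n; ++s) {
        permrow[s] = rows[i][perm[s]];
        csnew[s] = 1.0 - rows[i][s] + permrow[s];
        reni[s] = permrow[s] / csnew[s];
      }
      rank_avg(reni, ranki);
      for (int j = i + 1; j < G; ++j) {
        if (constant[j]) continue;
        for (int s = 0; s < n; ++s) renj[s] = rows[j][s] / csnew[s];
        rank_avg(renj, rankj);
        const double r = pearson(ranki, rankj);
        if (!ISNAN(r)) { s1[j] += r; s2[j] += r * r; ++cnt[j]; }
      }
    }
    for (int j = i + 1; j < G; ++j) {
      if (cnt[j] > 1) {
        const double m = s1[j] / cnt[j];
        mean_perm(i, j) = mean_perm(j, i) = m;
        double v = (s2[j] - cnt[j] * m * m) / (cnt[j] - 1);
        var_perm(i, j) = var_perm(j, i) = v > 0 ? v : 0.0;
      } else {
        mean_perm(i, j) = mean_perm(j, i) = NA_REAL;
        var_perm(i, j) = var_perm(j, i) = NA_REAL;
      }
    }
  }

  // Bootstrap: shared column resamples for every pair.
  {
    std::mt19937_64 eng((uint64_t)(seed * 1000.0) - 1ULL);
    std::uniform_int_distribution<int> u(0, n - 1);
    std::vector<std::vector<double> > bs1(G, std::vector<double>(G, 0.0)),
        bs2(G, std::vector<double>(G, 0.0));
    std::vector<std::vector<int> > bcnt(G, std::vector<int>(G, 0));
    std::vector<int> take(n);
    std::vector<double> tmp(n);
    std::vector<std::vector<double> > branks(G, std::vector<double>(n));
    for (int b = 0; b < n_boot; ++b) {
      for (int s = 0; s < n; ++s) take[s] = u(eng);
      for (int i = 0; i < G; ++i) {
        for (int s = 0; s < n; ++s) tmp[s] = rows[i][take[s]];
        rank_avg(tmp, branks[i]);
      }
      for (int i = 0; i < G; ++i) {
        if (constant[i]) continue;
        for (int j = i + 1; j < G; ++j) {
          if (constant[j]) continue;
          const double r = pearson(branks[i], branks[j]);
          if (!ISNAN(r)) {
            bs1[i][j] += r; bs2[i][j] += r * r; ++bcnt[i][j];
          }
        }
      }
    }
    for (int i = 0; i < G; ++i)
      for (int j = i + 1; j < G; ++j) {
        if (bcnt[i][j] > 1) {
          const double m = bs1[i][j] / bcnt[i][j];
          mean_boot(i, j) = mean_boot(j, i) = m;
          double v = (bs2[i][j] - bcnt[i][j] * m * m) / (bcnt[i][j] - 1);
          var_boot(i, j) = var_boot(j, i) = v > 0 ? v : 0.0;
        } else {
          mean_boot(i, j) = mean_boot(j, i) = NA_REAL;
          var_boot(i, j) = var_boot(j, i) = NA_REAL;
        }
      }
  }

  return List::create(_["rho"] = rho, _["mean_perm"] = mean_perm,
                      _["var_perm"] = var_perm, _["mean_boot"] = mean_boot,
                      _["var_boot"] = var_boot);
}
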