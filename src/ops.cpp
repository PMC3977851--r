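#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All kernels index volumes as (row, column, slice) in R's column-major
// layout: linear index idx = i + nx*(j + ny*k), 0-based here.

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * (k));
}

// GrowCut cellular automaton, synchronous updates, 26-neighbourhood.
// labels: 0 = unlabeled, 1 = foreground, 2 = background (any positive int
// is treated as a competing class). strengths in [0,1]; seeds carry 1.
// Conquest rule: neighbour q attacks p; p adopts q's label iff
// g(|C_p - C_q|) * theta_q > theta_p, with g(x) = 1 - x / max|C|.
// [[Rcpp::export]]
List growcut_run_cpp(NumericVector feature, IntegerVector dims,
                     IntegerVector labels0, NumericVector strengths0,
                     int max_iters) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<int> lab(labels0.begin(), labels0.end());
  std::vector<double> th(strengths0.begin(), strengths0.end());
  std::vector<int> lab2(n);
  std::vector<double> th2(n);

  double maxc = 0.0;
  for (int i = 0; i < n; ++i) maxc = std::max(maxc, std::fabs(feature[i]));
  if (maxc <= 0.0) maxc = 1.0;

  bool converged = false;
  int iters = 0;
  for (int it = 0; it < max_iters; ++it) {
    bool changed = false;
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int p = lin(i, j, k, nx, ny);
          double best_s = th[p];
          int best_l = lab[p];
          // fixed neighbour order gives deterministic tie-breaks
          for (int dk = -1; dk <= 1; ++dk) {
            const int kk = k + dk;
            if (kk < 0 || kk >= nz) continue;
            for (int dj = -1; dj <= 1; ++dj) {
              const int jj = j + dj;
              if (jj < 0 || jj >= ny) continue;
              for (int di = -1; di <= 1; ++di) {
                const int ii = i + di;
                if (ii < 0 || ii >= nx) continue;
                if (di == 0 && dj == 0 && dk == 0) continue;
                const int q = lin(ii, jj, kk, nx, ny);
                if (lab[q] == 0) continue;
                const double g = 1.0 - std::fabs(feature[p] - feature[q]) / maxc;
                const double s = g * th[q];
                if (s > best_s) {
                  best_s = s;
                  best_l = lab[q];
                }
              }
            }
          }
          if (best_l != lab[p]) changed = true;
          lab2[p] = best_l;
          th2[p] = best_s;
        }
      }
    }
    lab.swap(lab2);
    th.swap(th2);
    iters = it + 1;
    if (!changed) { converged = true; break; }
  }

  IntegerVector out_lab(lab.begin(), lab.end());
  NumericVector out_th(th.begin(), th.end());
  out_lab.attr("dim") = dims;
  out_th.attr("dim") = dims;
  return List::create(_["labels"] = out_lab, _["strengths"] = out_th,
                      _["iterations"] = iters, _["converged"] = converged);
}

// Iterated conditional modes for the two-class Gaussian + Potts model.
// Energy: E(l) = sum_p -log N(I_p; mu_l, sd_l) + beta * sum_{p~q} [l_p != l_q].
// Raster-order sweeps (R linear index order); ties keep the current label.
// neighborhood: 6 (faces) or 26.
// [[Rcpp::export]]
List icm_run_cpp(NumericVector intensity, IntegerVector dims,
                 IntegerVector labels0, double mu0, double sd0,
                 double mu1, double sd1, double beta,
                 int neighborhood, int max_sweeps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<int> lab(labels0.begin(), labels0.end());

  const double c0 = 0.5 * std::log(2.0 * M_PI * sd0 * sd0);
  const double c1 = 0.5 * std::log(2.0 * M_PI * sd1 * sd1);
  std::vector<double> u0(n), u1(n);
  for (int i = 0; i < n; ++i) {
    const double d0 = intensity[i] - mu0;
    const double d1 = intensity[i] - mu1;
    u0[i] = c0 + d0 * d0 / (2.0 * sd0 * sd0);
    u1[i] = c1 + d1 * d1 / (2.0 * sd1 * sd1);
  }

  int sweeps = 0;
  bool converged = false;
  for (int sw = 0; sw < max_sweeps; ++sw) {
    int flips = 0;
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int p = lin(i, j, k, nx, ny);
          int n1 = 0, ntot = 0;
          for (int dk = -1; dk <= 1; ++dk) {
            const int kk = k + dk;
            if (kk < 0 || kk >= nz) continue;
            for (int dj = -1; dj <= 1; ++dj) {
              const int jj = j + dj;
              if (jj < 0 || jj >= ny) continue;
              for (int di = -1; di <= 1; ++di) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                if (neighborhood == 6 &&
                    (std::abs(di) + std::abs(dj) + std::abs(dk)) != 1) continue;
                const int ii = i + di;
                if (ii < 0 || ii >= nx) continue;
                const int q = lin(ii, jj, kk, nx, ny);
                ++ntot;
                if (lab[q] == 1) ++n1;
              }
            }
          }
          const int n0 = ntot - n1;
          const double e0 = u0[p] + beta * n1;
          const double e1 = u1[p] + beta * n0;
          int newl = lab[p];
          if (e1 < e0) newl = 1;
          else if (e0 < e1) newl = 0;
          if (newl != lab[p]) { lab[p] = newl; ++flips; }
        }
      }
    }
    sweeps = sw + 1;
    if (flips == 0) { converged = true; break; }
  }

  IntegerVector out(lab.begin(), lab.end());
  out.attr("dim") = dims;
  return List::create(_["labels"] = out, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}

// Potts + Gaussian energy of a labeling (used for the monotonicity and
// MAP-oracle checks as well as by mrf_energy()).
// [[Rcpp::export]]
double potts_energy_cpp(NumericVector intensity, IntegerVector dims,
                        IntegerVector labels, double mu0, double sd0,
                        double mu1, double sd1, double beta,
                        int neighborhood) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double e = 0.0;
  const double c0 = 0.5 * std::log(2.0 * M_PI * sd0 * sd0);
  const double c1 = 0.5 * std::log(2.0 * M_PI * sd1 * sd1);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int p = lin(i, j, k, nx, ny);
        if (labels[p] == 1) {
          const double d = intensity[p] - mu1;
          e += c1 + d * d / (2.0 * sd1 * sd1);
        } else {
          const double d = intensity[p] - mu0;
          e += c0 + d * d / (2.0 * sd0 * sd0);
        }
        // each unordered pair counted once: forward neighbours only
        static const int f6[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
        if (neighborhood == 6) {
          for (int m = 0; m < 3; ++m) {
            const int ii = i + f6[m][0], jj = j + f6[m][1], kk = k + f6[m][2];
            if (ii >= nx || jj >= ny || kk >= nz) continue;
            if (labels[p] != labels[lin(ii, jj, kk, nx, ny)]) e += beta;
          }
        } else {
          for (int dk = 0; dk <= 1; ++dk) {
            for (int dj = (dk == 0 ? 0 : -1); dj <= 1; ++dj) {
              for (int di = (dk == 0 && dj == 0 ? 1 : -1); di <= 1; ++di) {
                const int ii = i + di, jj = j + dj, kk = k + dk;
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk >= nz) continue;
                if (labels[p] != labels[lin(ii, jj, kk, nx, ny)]) e += beta;
              }
            }
          }
        }
      }
    }
  }
  return e;
}

// 3-D connected-component labeling, 26-connectivity, labels assigned in
// first-encounter raster order (flood fill with an explicit stack).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<int> lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int p0 = 0; p0 < n; ++p0) {
    if (!mask[p0] || lab[p0] != 0) continue;
    ++next;
    lab[p0] = next;
    stack.push_back(p0);
    while (!stack.empty()) {
      const int p = stack.back();
      stack.pop_back();
      const int i = p % nx;
      const int j = (p / nx) % ny;
      const int k = p / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int q = lin(ii, jj, kk, nx, ny);
            if (mask[q] && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  IntegerVector out(lab.begin(), lab.end());
  out.attr("dim") = dims;
  return out;
}
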