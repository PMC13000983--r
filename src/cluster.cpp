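#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// label connected components of suprathreshold cells on an nr x nc grid
// (4-neighborhood), keeping positive and negative t separate; returns the
// per-cell cluster label (0 = subthreshold) and per-cluster mass (sum of t)
static void label_clusters(const std::vector<double>& t, int nr, int nc,
                           double thresh, std::vector<int>& label,
                           std::vector<double>& mass) {
  int n = nr * nc;
  label.assign(n, 0);
  mass.clear();
  std::vector<int> stack;
  for (int start = 0; start < n; ++start) {
    if (label[start] != 0 || std::abs(t[start]) <= thresh) continue;
    int sgn = t[start] > 0 ? 1 : -1;
    int id = (int)mass.size() + 1;
    double m = 0.0;
    stack.clear();
    stack.push_back(start);
    label[start] = id;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      m += t[cur];
      int r = cur % nr, c = cur / nr;
      const int dr[4] = {-1, 1, 0, 0};
      const int dc[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc2 = c + dc[k];
        if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
        int nb = rr + cc2 * nr;
        if (label[nb] != 0) continue;
        if (std::abs(t[nb]) <= thresh) continue;
        if ((t[nb] > 0 ? 1 : -1) != sgn) continue;
        label[nb] = id;
        stack.push_back(nb);
      }
    }
    mass.push_back(m);
  }
}

// one-sample t per cell from column sums and fixed column sums of squares
static void cell_t(const std::vector<double>& colsum,
                   const std::vector<double>& colsumsq,
                   int n, std::vector<double>& t) {
  for (size_t j = 0; j < colsum.size(); ++j) {
    double mean = colsum[j] / n;
    double var = (colsumsq[j] - n * mean * mean) / (n - 1);
    t[j] = var > 0 ? mean / std::sqrt(var / n) : 0.0;
  }
}

// [[Rcpp::export]]
List cluster_label_cpp(NumericMatrix tmap, double thresh) {
  int nr = tmap.nrow(), nc = tmap.ncol();
  std::vector<double> t(tmap.begin(), tmap.end());
  std::vector<int> label;
  std::vector<double> mass;
  label_clusters(t, nr, nc, thresh, label, mass);
  IntegerMatrix lab(nr, nc);
  std::copy(label.begin(), label.end(), lab.begin());
  return List::create(_["labels"] = lab, _["mass"] = NumericVector(mass.begin(), mass.end()));
}

// max |cluster mass| for each sign-flip permutation. data: participants x
// cells (cells = nr*nc grid, column-major); signs: participants x n_perm.
// Sums of squares are invariant under sign flips, so per-permutation t maps
// come from flipped column sums alone.
// [[Rcpp::export]]
NumericVector perm_max_mass_cpp(NumericMatrix data, NumericMatrix signs,
                                double thresh, int nr, int nc) {
  int n = data.nrow(), ncell = data.ncol(), nperm = signs.ncol();
  if (nr * nc != ncell) stop("grid dims do not match cell count");
  std::vector<double> colsumsq(ncell, 0.0);
  for (int j = 0; j < ncell; ++j)
    for (int i = 0; i < n; ++i)
      colsumsq[j] += data(i, j) * data(i, j);

  NumericVector out(nperm);
  std::vector<double> colsum(ncell), t(ncell);
  std::vector<int> label;
  std::vector<double> mass;
  for (int p = 0; p < nperm; ++p) {
    for (int j = 0; j < ncell; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += signs(i, p) * data(i, j);
      colsum[j] = s;
    }
    cell_t(colsum, colsumsq, n, t);
    label_clusters(t, nr, nc, thresh, label, mass);
    double mx = 0.0;
    for (double m : mass) mx = std::max(mx, std::abs(m));
    out[p] = mx;
  }
  return out;
}
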