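#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Direct O(N^2) pair sums for finite clusters in vacuum (no periodic
// images, no Ewald). Short-range terms (LJ / Buckingham) respect per-pair
// cutoffs; the Coulomb term, when enabled, is summed over all pairs.
//
// style: 1 = Lennard-Jones (p1 = epsilon, p2 = sigma)
//        2 = Buckingham    (p1 = A, p2 = rho, p3 = C)
// Parameter matrices are indexed by 0-based species ids.
//
// Each pair term is split half-and-half onto its two atoms; the returned
// total is the sum of the per-atom vector in index order, so the partition
// identity total == sum(per_atom) holds exactly.

// [[Rcpp::export]]
List pair_energy_cpp(NumericMatrix pos, IntegerVector type,
                     int style,
                     NumericMatrix p1, NumericMatrix p2, NumericMatrix p3,
                     NumericMatrix cutoff,
                     NumericVector q, bool coulomb, double kcoul,
                     bool want_forces) {
  const int n = pos.nrow();
  NumericVector per_atom(n);
  NumericMatrix forces(n, 3);
  bool finite = true;

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = pos(j, 0) - pos(i, 0);
      const double dy = pos(j, 1) - pos(i, 1);
      const double dz = pos(j, 2) - pos(i, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double r = std::sqrt(r2);
      const int ti = type[i], tj = type[j];
      double e = 0.0, fr = 0.0; // fr = -dE/dr / r (force prefactor)
      if (r < 1e-12) { finite = false; continue; }

      if (r < cutoff(ti, tj)) {
        if (style == 1) {
          const double eps = p1(ti, tj), sig = p2(ti, tj);
          const double sr2 = (sig * sig) / r2;
          const double sr6 = sr2 * sr2 * sr2;
          const double sr12 = sr6 * sr6;
          e += 4.0 * eps * (sr12 - sr6);
          fr += 24.0 * eps * (2.0 * sr12 - sr6) / r2;
        } else {
          const double A = p1(ti, tj), rho = p2(ti, tj), C = p3(ti, tj);
          const double ex = A * std::exp(-r / rho);
          const double r6 = r2 * r2 * r2;
          e += ex - C / r6;
          fr += (ex / rho) / r - 6.0 * C / (r6 * r2);
        }
      }
      if (coulomb) {
        const double ec = kcoul * q[i] * q[j] / r;
        e += ec;
        fr += ec / r2;
      }
      if (e != 0.0 || fr != 0.0) {
        per_atom[i] += 0.5 * e;
        per_atom[j] += 0.5 * e;
        if (!std::isfinite(e)) finite = false;
        if (want_forces) {
          // F_j = fr * (r_j - r_i); F_i = -F_j
          forces(i, 0) -= fr * dx; forces(i, 1) -= fr * dy; forces(i, 2) -= fr * dz;
          forces(j, 0) += fr * dx; forces(j, 1) += fr * dy; forces(j, 2) += fr * dz;
        }
      }
    }
  }
  // accumulate in extended precision and in index order, exactly like
  // R's sum(), so total == sum(per_atom) holds bitwise
  long double total = 0.0;
  for (int i = 0; i < n; ++i) total += per_atom[i];
  return List::create(_["total"] = static_cast<double>(total),
                      _["per_atom"] = per_atom,
                      _["forces"] = forces, _["finite"] = finite);
}

// Neighbor lists under a per-species-pair cutoff matrix; the neighbor
// predicate is strictly "distance < cutoff". Returns 1-based indices.
// [[Rcpp::export]]
List neighbor_list_cpp(NumericMatrix pos, IntegerVector type,
                       NumericMatrix cutoff) {
  const int n = pos.nrow();
  double cmax = 0.0;
  for (int a = 0; a < cutoff.nrow(); ++a)
    for (int b = 0; b < cutoff.ncol(); ++b)
      cmax = std::max(cmax, cutoff(a, b));
  std::vector< std::vector<int> > nb(n);
  // sweep over x-sorted order so distant pairs break early
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return pos(a, 0) < pos(b, 0); });
  for (int a = 0; a < n; ++a) {
    const int i = ord[a];
    for (int b = a + 1; b < n; ++b) {
      const int j = ord[b];
      const double dx = pos(j, 0) - pos(i, 0);
      if (dx >= cmax) break;
      const double dy = pos(j, 1) - pos(i, 1);
      const double dz = pos(j, 2) - pos(i, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double c = cutoff(type[i], type[j]);
      if (r2 < c * c) { nb[i].push_back(j); nb[j].push_back(i); }
    }
  }
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::sort(nb[i].begin(), nb[i].end());
    IntegerVector v(nb[i].size());
    for (size_t k = 0; k < nb[i].size(); ++k) v[k] = nb[i][k] + 1;
    out[i] = v;
  }
  return out;
}

// Common neighbourhood parameter:
//   Q_i = (1/n_i) * sum_j | sum_{k in common(i,j)} (r_ik + r_jk) |^2
// with r_ik = r_k - r_i; zero for atoms without neighbours.
// [[Rcpp::export]]
NumericVector cnp_cpp(NumericMatrix pos, List nbrs) {
  const int n = pos.nrow();
  NumericVector Q(n);
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nbrs[i];
    nb[i].reserve(v.size());
    for (int k = 0; k < v.size(); ++k) nb[i].push_back(v[k] - 1);
  }
  for (int i = 0; i < n; ++i) {
    const size_t ni = nb[i].size();
    if (ni == 0) { Q[i] = 0.0; continue; }
    double acc = 0.0;
    for (size_t a = 0; a < ni; ++a) {
      const int j = nb[i][a];
      double sx = 0.0, sy = 0.0, sz = 0.0;
      // common neighbours via merge of the two sorted lists
      size_t p = 0, qq = 0;
      const std::vector<int>& A = nb[i];
      const std::vector<int>& B = nb[j];
      while (p < A.size() && qq < B.size()) {
        if (A[p] < B[qq]) ++p;
        else if (B[qq] < A[p]) ++qq;
        else {
          const int k = A[p];
          sx += (pos(k, 0) - pos(i, 0)) + (pos(k, 0) - pos(j, 0));
          sy += (pos(k, 1) - pos(i, 1)) + (pos(k, 1) - pos(j, 1));
          sz += (pos(k, 2) - pos(i, 2)) + (pos(k, 2) - pos(j, 2));
          ++p; ++qq;
        }
      }
      acc += sx * sx + sy * sy + sz * sz;
    }
    Q[i] = acc / static_cast<double>(ni);
  }
  return Q;
}

// Overlap guard: any pair closer than `threshold`? x-sorted sweep.
// [[Rcpp::export]]
bool has_close_pair_cpp(NumericMatrix pos, double threshold) {
  const int n = pos.nrow();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return pos(a, 0) < pos(b, 0); });
  const double t2 = threshold * threshold;
  for (int a = 0; a < n; ++a) {
    const int i = ord[a];
    for (int b = a + 1; b < n; ++b) {
      const int j = ord[b];
      const double dx = pos(j, 0) - pos(i, 0);
      if (dx >= threshold) break;
      const double dy = pos(j, 1) - pos(i, 1);
      const double dz = pos(j, 2) - pos(i, 2);
      if (dx * dx + dy * dy + dz * dz < t2) return true;
    }
  }
  return false;
}
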