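#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sample a 0/1 connectivity block with every row sum == out_deg and every
// column sum == in_deg (and an empty diagonal on request): deterministic
// margin-exact initializer followed by margin-preserving checkerboard swaps.
// Returns 1-based (row, col) edge indices.
//
// Initializer patterns (both meet the margins exactly):
//   forbid_diagonal (square): row i -> cols (i+1), ..., (i+out_deg) mod n
//   otherwise:                row i -> cols (i*out_deg + j) mod n_cols, j < out_deg
// The stride pattern is margin-exact iff (n_cols / gcd(out_deg, n_cols)) divides
// n_rows; column sums are verified and a violation is a hard error.
// [[Rcpp::export]]
List cpp_sample_block(int n_rows, int n_cols, int out_deg, int in_deg,
                      bool forbid_diagonal, double swap_factor) {
  long long n_edges = (long long)n_rows * out_deg;
  if (n_edges != (long long)n_cols * in_deg)
    stop("infeasible margins: n_rows*out_deg != n_cols*in_deg");
  if (out_deg == 0) {
    return List::create(_["i"] = IntegerVector(0), _["j"] = IntegerVector(0));
  }
  if (forbid_diagonal && (n_rows != n_cols || in_deg > n_cols - 1))
    stop("infeasible margins for a zero-diagonal block");
  if (out_deg > n_cols || in_deg > n_rows)
    stop("infeasible margins: degree exceeds population size");

  std::vector<unsigned char> A((size_t)n_rows * n_cols, 0);
  std::vector<int> tgt((size_t)n_edges);  // tgt[r*out_deg + j] = j-th target of row r

  for (int r = 0; r < n_rows; ++r) {
    for (int j = 0; j < out_deg; ++j) {
      long long c;
      if (forbid_diagonal)
        c = ((long long)r + 1 + j) % n_cols;
      else
        c = ((long long)r * out_deg + j) % n_cols;
      tgt[(size_t)r * out_deg + j] = (int)c;
      A[(size_t)r * n_cols + c] = 1;
    }
  }
  // verify column sums of the initializer
  {
    std::vector<int> colsum(n_cols, 0);
    for (int r = 0; r < n_rows; ++r)
      for (int j = 0; j < out_deg; ++j)
        colsum[tgt[(size_t)r * out_deg + j]]++;
    for (int c = 0; c < n_cols; ++c)
      if (colsum[c] != in_deg)
        stop("initializer failed to meet the column margins (block %d x %d, k_out=%d)",
             n_rows, n_cols, out_deg);
  }

  // checkerboard (margin-preserving) swap randomization. A local xorshift128+
  // generator (seeded from R's RNG stream, hence reproducible from set.seed)
  // keeps the tens of millions of draws cheap.
  uint64_t s0 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
                (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t s1 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
                (uint64_t)(unif_rand() * 4294967296.0);
  if (s0 == 0 && s1 == 0) s0 = 0x9E3779B97F4A7C15ULL;
  auto nextu = [&s0, &s1]() -> uint64_t {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  };
  auto runif_n = [&nextu](int n) -> int {
    return (int)(((nextu() >> 11) * (1.0 / 9007199254740992.0)) * n);
  };
  long long target_success = (long long)(swap_factor * (double)n_edges);
  long long max_attempts = 10 * target_success;
  long long success = 0, attempts = 0;
  while (success < target_success && attempts < max_attempts) {
    ++attempts;
    int r1 = runif_n(n_rows);
    int r2 = runif_n(n_rows);
    if (r1 == r2) continue;
    int j1 = runif_n(out_deg);
    int j2 = runif_n(out_deg);
    int c1 = tgt[(size_t)r1 * out_deg + j1];
    int c2 = tgt[(size_t)r2 * out_deg + j2];
    if (c1 == c2) continue;
    if (A[(size_t)r1 * n_cols + c2] || A[(size_t)r2 * n_cols + c1]) continue;
    if (forbid_diagonal && (r1 == c2 || r2 == c1)) continue;
    A[(size_t)r1 * n_cols + c1] = 0;
    A[(size_t)r2 * n_cols + c2] = 0;
    A[(size_t)r1 * n_cols + c2] = 1;
    A[(size_t)r2 * n_cols + c1] = 1;
    tgt[(size_t)r1 * out_deg + j1] = c2;
    tgt[(size_t)r2 * out_deg + j2] = c1;
    ++success;
  }
  if (success < target_success)
    warning("swap randomization reached only %ld of %ld target swaps",
            (long)success, (long)target_success);

  IntegerVector ri((R_xlen_t)n_edges), ci((R_xlen_t)n_edges);
  R_xlen_t k = 0;
  for (int r = 0; r < n_rows; ++r)
    for (int j = 0; j < out_deg; ++j, ++k) {
      ri[k] = r + 1;
      ci[k] = tgt[(size_t)r * out_deg + j] + 1;
    }
  return List::create(_["i"] = ri, _["j"] = ci);
}
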