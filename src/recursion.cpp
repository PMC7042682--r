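#include <Rcpp.h>
using namespace Rcpp;

// Deterministic life-cycle recursion over the gamete pool.
//
// One generation, starting from the mutated gamete pool p of generation t:
//   zygotes      X_ij  = p_i * p_j                     (random union)
//   adults       Xs_ij = X_ij * W_ij / wbar            (selection)
//   gamete pool  g_k   = sum_ij Xs_ij * T[(i,j), k]    (meiosis)
//   mutation     p'    = M g                           (per-locus, one-way)
// The pool is renormalised each generation to absorb floating-point drift.
// Convergence is diagnosed on the per-selected-locus mutant allele
// frequencies of the (zygote-forming) pool between consecutive generations.
//
// [[Rcpp::export]]
List cpp_iterate(NumericVector p0, NumericMatrix W, NumericMatrix Tmat,
                 NumericMatrix Mmat, IntegerMatrix selbits,
                 IntegerVector modbit, int max_gen, double tol,
                 bool check_tol, int track_every) {
  const int H = p0.size();
  const int L = selbits.ncol();
  if (W.nrow() != H || W.ncol() != H || Tmat.nrow() != H * H ||
      Tmat.ncol() != H || Mmat.nrow() != H || Mmat.ncol() != H)
    stop("inconsistent operator dimensions");

  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> pool(H), pm(H);
  // transmission rows repacked contiguous in the gamete index for cache
  // locality: Tt[k + H*(i + H*j)] = Tmat(i + j*H, k)
  std::vector<double> Tt((size_t)H * H * H);
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < H; ++i)
      for (int k = 0; k < H; ++k)
        Tt[(size_t)k + (size_t)H * (i + (size_t)H * j)] = Tmat(i + j * H, k);
  std::vector<double> q(L), q_prev(L);
  double modfreq = 0.0, wbar = NA_REAL, delta = NA_REAL;

  for (int l = 0; l < L; ++l) {
    double s = 0.0;
    for (int k = 0; k < H; ++k) s += p[k] * selbits(k, l);
    q_prev[l] = s;
  }

  std::vector<double> traj;
  int traj_rows = 0;
  const int traj_cols = 3 + L;  // generation, modifier freq, wbar, q_1..q_L

  bool converged = false;
  int gen = 0;
  for (gen = 1; gen <= max_gen; ++gen) {
    // selection on zygotes p_i p_j, then meiosis through T
    wbar = 0.0;
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < H; ++i) wbar += p[i] * p[j] * W(i, j);
    if (wbar <= 0.0) stop("population mean fitness is zero (extinction)");

    std::fill(pool.begin(), pool.end(), 0.0);
    for (int j = 0; j < H; ++j) {
      if (p[j] == 0.0) continue;
      for (int i = 0; i < H; ++i) {
        const double w = p[i] * p[j] * W(i, j);
        if (w == 0.0) continue;
        const double *t = &Tt[(size_t)H * (i + (size_t)H * j)];
        for (int k = 0; k < H; ++k) pool[k] += w * t[k];
      }
    }

    // mutation
    for (int k = 0; k < H; ++k) {
      double s = 0.0;
      for (int l = 0; l < H; ++l) s += Mmat(k, l) * pool[l];
      pm[k] = s;
    }
    double tot = 0.0;
    for (int k = 0; k < H; ++k) tot += pm[k];
    for (int k = 0; k < H; ++k) p[k] = pm[k] / tot;

    // census: allele frequencies in the zygote-forming pool
    delta = 0.0;
    modfreq = 0.0;
    for (int k = 0; k < H; ++k) modfreq += p[k] * modbit[k];
    for (int l = 0; l < L; ++l) {
      double s = 0.0;
      for (int k = 0; k < H; ++k) s += p[k] * selbits(k, l);
      q[l] = s;
      const double d = std::fabs(s - q_prev[l]);
      if (d > delta) delta = d;
      q_prev[l] = s;
    }

    if (track_every > 0 && (gen % track_every == 0 || gen == max_gen)) {
      traj.push_back((double)gen);
      traj.push_back(modfreq);
      traj.push_back(wbar);
      for (int l = 0; l < L; ++l) traj.push_back(q[l]);
      ++traj_rows;
    }

    if (check_tol && delta < tol) {
      converged = true;
      break;
    }
  }
  if (gen > max_gen) gen = max_gen;

  NumericVector pout(p.begin(), p.end());
  NumericVector qout(q.begin(), q.end());

  List out = List::create(
      _["pool"] = pout, _["generations"] = gen, _["converged"] = converged,
      _["final_delta"] = delta, _["allele_freqs"] = qout,
      _["modifier_freq"] = modfreq, _["mean_fitness"] = wbar);
  if (track_every > 0) {
    NumericMatrix tm(traj_cols, traj_rows);
    std::copy(traj.begin(), traj.end(), tm.begin());
    out["trajectory"] = transpose(tm);
  }
  return out;
}
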