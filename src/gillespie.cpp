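#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of the multistage birth-death-mutation
// process. Stage populations X_1..X_{K-1} evolve by per-cell symmetric
// division (beta), death (delta) and division-with-mutation (mu; one
// daughter stays at stage k, the other enters stage k+1 -- the
// convention whose lineage survival is u_k * u_{k+1});
// first-mutation cells are seeded from the unmodelled healthy pool as a
// Poisson process of rate nu. The simulation stops when any cell reaches
// K mutations (cancer onset) or at t_end.
//
// This is the independent validator for the extinction-probability ODE
// solver; it shares no code with it.

static double first_k_mutant_time(double nu, double mu, double beta,
                                  double delta, int K, double t_end,
                                  long max_events, std::vector<long> &X) {
  std::fill(X.begin(), X.end(), 0L);
  double t = 0.0;
  double per_cell = beta + delta + mu;
  long events = 0;
  long total = 0;
  while (true) {
    double R = nu + per_cell * (double)total;
    if (R <= 0.0) return NA_REAL;
    t += R::exp_rand() / R;
    if (t > t_end) return NA_REAL;
    if (++events > max_events)
      stop("Gillespie event budget exceeded (%ld events)", max_events);
    double r = R::unif_rand() * R;
    if (r < nu) { // seeding of a first-mutation cell
      if (K == 1) return t;
      X[0]++; total++;
      continue;
    }
    r -= nu;
    // pick the stage: r in [0, per_cell * total)
    int k = 0;
    double acc = 0.0;
    for (k = 0; k < K - 1; ++k) {
      acc += per_cell * (double)X[k];
      if (r < acc) break;
    }
    if (k > K - 2) k = K - 2; // guard rounding at the partition edge
    double u = R::unif_rand() * per_cell;
    if (u < beta) { X[k]++; total++; }
    else if (u < beta + delta) { X[k]--; total--; }
    else { // division with mutation: k-daughter stays, k+1-daughter added
      if (k == K - 2) return t; // produced a K-mutant
      X[k + 1]++; total++;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gillespie_onset(double nu, double mu, double beta,
                                  double delta, int K, double t_end,
                                  int n, double max_events) {
  if (K < 1) stop("K must be >= 1");
  NumericVector out(n);
  std::vector<long> X(std::max(K - 1, 1));
  long budget = (long)max_events;
  for (int i = 0; i < n; ++i)
    out[i] = first_k_mutant_time(nu, mu, beta, delta, K, t_end, budget, X);
  return out;
}

// Lineage variant: start from a single cell with k0 mutations, no seeding;
// returns TRUE if the lineage produces a K-mutant within tau.
// [[Rcpp::export]]
LogicalVector cpp_gillespie_lineage(double mu, double beta, double delta,
                                    int K, int k0, double tau, int n,
                                    double max_events) {
  if (K < 2) stop("lineage simulation needs K >= 2");
  if (k0 < 1 || k0 > K - 1) stop("k0 must be in 1..K-1");
  LogicalVector out(n);
  double per_cell = beta + delta + mu;
  long budget = (long)max_events;
  std::vector<long> X(K - 1);
  for (int i = 0; i < n; ++i) {
    std::fill(X.begin(), X.end(), 0L);
    X[k0 - 1] = 1;
    long total = 1;
    double t = 0.0;
    long events = 0;
    bool hit = false;
    while (total > 0) {
      double R = per_cell * (double)total;
      t += R::exp_rand() / R;
      if (t > tau) break;
      if (++events > budget)
        stop("Gillespie event budget exceeded (%ld events)", (long)budget);
      double r = R::unif_rand() * R;
      int k = 0;
      double acc = 0.0;
      for (k = 0; k < K - 1; ++k) {
        acc += per_cell * (double)X[k];
        if (r < acc) break;
      }
      if (k > K - 2) k = K - 2; // guard rounding at the partition edge
      double u = R::unif_rand() * per_cell;
      if (u < beta) { X[k]++; total++; }
      else if (u < beta + delta) { X[k]--; total--; }
      else { // division with mutation
        if (k == K - 2) { hit = true; break; }
        X[k + 1]++; total++;
      }
    }
    out[i] = hit;
  }
  return out;
}
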