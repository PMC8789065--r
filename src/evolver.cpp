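#include <Rcpp.h>
using namespace Rcpp;

// Couplings come in as the R array J[L, L, q, q] (column-major).
struct Landscape {
  const double *h; // L x q
  const double *J; // L x L x q x q, may be null (profile model)
  int L, q;
  double hval(int i, int a) const { return h[i + (size_t)L * a]; }
  double Jval(int i, int j, int a, int b) const {
    return J ? J[i + (size_t)L * (j + (size_t)L * (a + (size_t)q * b))] : 0.0;
  }
  // local field of candidate state b at site i given context aa
  double local(int i, int b, const int *aa) const {
    double s = hval(i, b);
    if (J) for (int j = 0; j < L; ++j) if (j != i) s += Jval(i, j, b, aa[j]);
    return s;
  }
};

static Landscape make_landscape(const NumericMatrix &h, SEXP J) {
  Landscape ls;
  ls.L = h.nrow();
  ls.q = h.ncol();
  ls.h = REAL(h);
  ls.J = Rf_isNull(J) ? nullptr : REAL(J);
  return ls;
}

// sample index 0..(n-1) from unnormalized log-weights s (max-shifted);
// argmax mode breaks ties uniformly
static int pick_state(const double *s, int n, double beta, bool argmax) {
  if (n == 1) return 0;
  if (argmax) {
    double mx = s[0];
    for (int k = 1; k < n; ++k) if (s[k] > mx) mx = s[k];
    int nt = 0, choice = 0;
    for (int k = 0; k < n; ++k)
      if (s[k] >= mx - 1e-12) { ++nt; if (unif_rand() < 1.0 / nt) choice = k; }
    return choice;
  }
  double mx = beta * s[0];
  for (int k = 1; k < n; ++k) if (beta * s[k] > mx) mx = beta * s[k];
  double tot = 0.0, w[64];
  for (int k = 0; k < n; ++k) { w[k] = std::exp(beta * s[k] - mx); tot += w[k]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < n; ++k) { acc += w[k]; if (u <= acc) return k; }
  return n - 1;
}

// codon index encoding: 0-based ci = 16*n1 + 4*n2 + n3, nucleotides A,C,G,T = 0..3
static void codon_neighbors(int ci, int *out) { // 9 single-nt neighbors
  int n[3] = { ci >> 4, (ci >> 2) & 3, ci & 3 };
  int k = 0;
  for (int pos = 0; pos < 3; ++pos)
    for (int nt = 0; nt < 4; ++nt) {
      if (nt == n[pos]) continue;
      int m[3] = { n[0], n[1], n[2] };
      m[pos] = nt;
      out[k++] = (m[0] << 4) | (m[1] << 2) | m[2];
    }
}

// One codon-level evolutionary step on (aa, codon) in place.
// codon_aa: length-64 map codon -> 0-based aa state, -1 for stops.
static void codon_step(const Landscape &ls, int *aa, int *codon,
                       const int *codon_aa, int gap_state,
                       double beta, bool argmax, int n_mutable) {
  int i;
  do { i = (int)(unif_rand() * ls.L); } while (i >= ls.L || aa[i] == gap_state);
  (void)n_mutable;
  int reach[10];
  reach[0] = codon[i];
  codon_neighbors(codon[i], reach + 1);
  // distinct accessible amino acids and their candidate codons
  int bs[10], nb = 0;
  for (int r = 0; r < 10; ++r) {
    int b = codon_aa[reach[r]];
    if (b < 0) continue; // stop codon: excluded from the proposal set
    bool seen = false;
    for (int k = 0; k < nb; ++k) if (bs[k] == b) { seen = true; break; }
    if (!seen) bs[nb++] = b;
  }
  double s[10];
  for (int k = 0; k < nb; ++k) s[k] = ls.local(i, bs[k], aa);
  int b = bs[pick_state(s, nb, beta, argmax)];
  int cand[10], nc = 0;
  for (int r = 0; r < 10; ++r)
    if (codon_aa[reach[r]] == b) cand[nc++] = reach[r];
  codon[i] = cand[(int)(unif_rand() * nc) % nc];
  aa[i] = b;
}

// [[Rcpp::export]]
List cpp_evolve_library(NumericMatrix h, SEXP J, IntegerVector aa0,
                        IntegerVector codon0, IntegerVector codon_aa,
                        double beta, bool argmax, IntegerVector snapshots,
                        int M, bool return_codons, bool check) {
  Landscape ls = make_landscape(h, J);
  const int L = ls.L, S = snapshots.size();
  if (S == 0) stop("need at least one snapshot step");
  const int gap_state = 0; // gap is always the first alphabet symbol
  int n_mut = 0;
  for (int i = 0; i < L; ++i) if (aa0[i] != gap_state) ++n_mut;
  if (n_mut == 0) stop("all-gap sequence: no mutable site");
  const int n_steps = snapshots[S - 1];
  IntegerVector out_aa(Dimension(S, M, L));
  IntegerVector out_cod = return_codons ? IntegerVector(Dimension(S, M, L))
                                        : IntegerVector(0);
  std::vector<int> aa(L), codon(L);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < L; ++i) { aa[i] = aa0[i]; codon[i] = codon0[i]; }
    int sp = 0;
    for (int t = 0; t <= n_steps; ++t) {
      if (t > 0) {
        codon_step(ls, aa.data(), codon.data(), INTEGER(codon_aa), gap_state,
                   beta, argmax, n_mut);
        if (check) {
          for (int i = 0; i < L; ++i) {
            if (aa[i] == gap_state) {
              if (codon[i] != -1) stop("consistency violation: gap with codon");
            } else if (codon_aa[codon[i]] != aa[i]) {
              stop("consistency violation: codon does not translate to aa");
            }
          }
        }
      }
      while (sp < S && snapshots[sp] == t) {
        for (int i = 0; i < L; ++i) {
          out_aa[sp + (size_t)S * (m + (size_t)M * i)] = aa[i];
          if (return_codons)
            out_cod[sp + (size_t)S * (m + (size_t)M * i)] = codon[i];
        }
        ++sp;
      }
    }
  }
  return List::create(_["aa"] = out_aa, _["codon"] = out_cod);
}

// Amino-acid-level chain (SEEC-style): substitutions drawn from `allowed`
// states at uniformly chosen non-gap sites; no codon constraint.
// [[Rcpp::export]]
IntegerVector cpp_seec_library(NumericMatrix h, SEXP J, IntegerVector aa0,
                               IntegerVector allowed, int gap_state,
                               double beta, bool argmax,
                               IntegerVector snapshots, int M) {
  Landscape ls = make_landscape(h, J);
  const int L = ls.L, S = snapshots.size(), nA = allowed.size();
  if (S == 0) stop("need at least one snapshot step");
  if (nA < 1 || nA > 64) stop("allowed set must have 1..64 states");
  int n_mut = 0;
  for (int i = 0; i < L; ++i) if (aa0[i] != gap_state) ++n_mut;
  if (n_mut == 0) stop("all-gap sequence: no mutable site");
  const int n_steps = snapshots[S - 1];
  IntegerVector out(Dimension(S, M, L));
  std::vector<int> aa(L);
  std::vector<double> s(nA);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < L; ++i) aa[i] = aa0[i];
    int sp = 0;
    for (int t = 0; t <= n_steps; ++t) {
      if (t > 0) {
        int i;
        do { i = (int)(unif_rand() * L); } while (i >= L || aa[i] == gap_state);
        for (int k = 0; k < nA; ++k) s[k] = ls.local(i, allowed[k], aa.data());
        aa[i] = allowed[pick_state(s.data(), nA, beta, argmax)];
      }
      while (sp < S && snapshots[sp] == t) {
        for (int i = 0; i < L; ++i)
          out[sp + (size_t)S * (m + (size_t)M * i)] = aa[i];
        ++sp;
      }
    }
  }
  return out;
}

// Long single SEEC chain that tallies visited states; for stationarity
// checks against exact enumeration at tiny L, q (state id = sum aa_i q^i).
// [[Rcpp::export]]
NumericVector cpp_seec_state_counts(NumericMatrix h, SEXP J, IntegerVector aa0,
                                    double beta, double n_steps, double burn_in) {
  Landscape ls = make_landscape(h, J);
  const int L = ls.L, q = ls.q;
  double nstates = std::pow((double)q, L);
  if (nstates > 2e6) stop("state space too large to tally");
  NumericVector counts((int)nstates);
  std::vector<int> aa(L);
  for (int i = 0; i < L; ++i) aa[i] = aa0[i];
  std::vector<double> s(q);
  for (double t = 0; t < n_steps; ++t) {
    int i = (int)(unif_rand() * L); if (i >= L) i = L - 1;
    for (int b = 0; b < q; ++b) s[b] = ls.local(i, b, aa.data());
    aa[i] = pick_state(s.data(), q, beta, false);
    if (t >= burn_in) {
      double id = 0, pw = 1;
      for (int k = 0; k < L; ++k) { id += aa[k] * pw; pw *= q; }
      counts[(int)id] += 1.0;
    }
  }
  return counts;
}

// Systematic-scan heat-bath sweeps over all q states at every site; states
// is n_chains x L (0-based), updated copies are returned.
// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_sweeps(NumericMatrix h, SEXP J, IntegerMatrix states,
                               double beta, int n_sweeps) {
  Landscape ls = make_landscape(h, J);
  const int L = ls.L, q = ls.q, n = states.nrow();
  if (states.ncol() != L) stop("state matrix does not match model length");
  IntegerMatrix out = clone(states);
  std::vector<int> aa(L);
  std::vector<double> s(q);
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < L; ++i) aa[i] = out(c, i);
    for (int sw = 0; sw < n_sweeps; ++sw)
      for (int i = 0; i < L; ++i) {
        for (int b = 0; b < q; ++b) s[b] = ls.local(i, b, aa.data());
        aa[i] = pick_state(s.data(), q, beta, false);
      }
    for (int i = 0; i < L; ++i) out(c, i) = aa[i];
  }
  return out;
}

// Potts energies of every row of an alignment (0-based states).
// [[Rcpp::export]]
NumericVector cpp_msa_energy(NumericMatrix h, SEXP J, IntegerMatrix msa) {
  Landscape ls = make_landscape(h, J);
  const int L = ls.L, M = msa.nrow();
  if (msa.ncol() != L) stop("alignment does not match model length");
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    double e = 0.0;
    for (int i = 0; i < L; ++i) {
      e -= ls.hval(i, msa(m, i));
      if (ls.J)
        for (int j = i + 1; j < L; ++j) e -= ls.Jval(i, j, msa(m, i), msa(m, j));
    }
    out[m] = e;
  }
  return out;
}
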