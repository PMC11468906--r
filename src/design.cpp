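// Nussinov-style folding DP and the joint MFE/CAI codon-design lattice DP.
//
// Both minimize a sum of negative pair scores over nested secondary
// structures (pairs separated by at least `min_hairpin` unpaired bases).
// The lattice DP additionally chooses, per codon, among the synonymous
// codons of the target peptide, adding -lambda * log w(codon) to the
// objective; ties on the objective are broken toward higher CAI
// (larger sum of log w), then by a fixed deterministic traceback order.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double EPS = 1e-9;

static inline int base_index(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
  }
  return -1;
}

// ---------------------------------------------------------------------------
// Plain Nussinov on a fixed sequence
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string rna, NumericMatrix pair_score,
                       int min_hairpin) {
  const int n = (int) rna.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = base_index(rna[i]);
    if (s[i] < 0) stop("non-ACGU base in RNA at position %d", i + 1);
  }
  if (n == 0)
    return List::create(_["score"] = 0.0, _["structure"] = "");

  // M[i][j], 0-based, j >= i; stored as vector of rows to keep memory flat
  std::vector<double> M((size_t) n * n, 0.0);
  auto at = [n, &M](int i, int j) -> double& { return M[(size_t) i * n + j]; };

  for (int len = min_hairpin + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = at(i, j - 1);              // j unpaired
      for (int k = i; k <= j - min_hairpin - 1; ++k) {
        double ps = pair_score(s[k], s[j]);
        if (!R_finite(ps)) continue;           // pair not allowed
        double left = (k > i) ? at(i, k - 1) : 0.0;
        double inner = (k + 1 <= j - 1) ? at(k + 1, j - 1) : 0.0;
        double cand = left + ps + inner;
        if (cand < best) best = cand;
      }
      at(i, j) = best;
    }
  }
  double score = at(0, n - 1);

  // traceback with an explicit stack (first optimal choice; j-unpaired
  // preferred, then leftmost pairing partner)
  std::string db(n, '.');
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, n - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    if (j - i < min_hairpin + 1) continue;
    if (at(i, j) >= at(i, j - 1) - EPS && at(i, j) <= at(i, j - 1) + EPS) {
      stack.push_back({i, j - 1});
      continue;
    }
    bool done = false;
    for (int k = i; k <= j - min_hairpin - 1 && !done; ++k) {
      double ps = pair_score(s[k], s[j]);
      if (!R_finite(ps)) continue;
      double left = (k > i) ? at(i, k - 1) : 0.0;
      double inner = (k + 1 <= j - 1) ? at(k + 1, j - 1) : 0.0;
      if (std::fabs(left + ps + inner - at(i, j)) <= EPS) {
        db[k] = '('; db[j] = ')';
        if (k > i) stack.push_back({i, k - 1});
        if (k + 1 <= j - 1) stack.push_back({k + 1, j - 1});
        done = true;
      }
    }
    if (!done) stack.push_back({i, j - 1});    // numeric fallback
  }
  return List::create(_["score"] = score, _["structure"] = db);
}

// ---------------------------------------------------------------------------
// Codon-lattice design DP
// ---------------------------------------------------------------------------
//
// The search space is the codon DFA of the peptide: boundary b (0..3n) holds
// the distinct codon prefixes of length (b mod 3) of the allowed codons of
// codon (b div 3 + 1). Transitions boundary b-1 -> b are labelled with a
// nucleotide; transitions that complete a codon carry -lambda*log w (and the
// secondary cost -log w used for the CAI tie-break).

struct Trans {
  int from, to;     // state ids at boundaries b-1 and b
  int nt;           // 0..3
  double cost;      // lambda-scaled contribution to the objective
  double sec;       // -log w, tie-break criterion (minimized)
};

struct Val { double obj, sec; };

static inline bool lt(const Val& a, const Val& b) {
  if (a.obj < b.obj - EPS) return true;
  if (a.obj > b.obj + EPS) return false;
  return a.sec < b.sec - EPS;
}

// [[Rcpp::export]]
List lattice_design_cpp(List codon_sets, NumericVector logw_sets_flat,
                        IntegerVector set_sizes, NumericMatrix pair_score,
                        int min_hairpin, double lambda) {
  const int n = codon_sets.size();           // codons
  const int B = 3 * n + 1;                   // boundaries 0..3n

  // enumerate states per boundary and transitions into each boundary
  std::vector<std::vector<std::string>> states(B);
  states[0].push_back("");
  std::vector<std::vector<Trans>> into(B);   // into[b]: transitions b-1 -> b

  int flat_pos = 0;
  for (int c = 0; c < n; ++c) {
    CharacterVector cods = codon_sets[c];
    int m = set_sizes[c];
    std::vector<double> lw(m);
    for (int q = 0; q < m; ++q) lw[q] = logw_sets_flat[flat_pos + q];
    flat_pos += m;

    for (int p = 1; p <= 3; ++p) {           // boundary 3c + p
      int b = 3 * c + p;
      states[b].clear();
      if (p == 3) states[b].push_back("");   // codon boundary: single state
      for (int q = 0; q < m; ++q) {
        std::string cod = as<std::string>(cods[q]);
        std::string pre_from = cod.substr(0, p - 1);
        std::string pre_to = cod.substr(0, p);
        // locate/insert target state
        int to_id;
        if (p == 3) {
          to_id = 0;
        } else {
          to_id = -1;
          for (size_t t = 0; t < states[b].size(); ++t)
            if (states[b][t] == pre_to) { to_id = (int) t; }
          if (to_id < 0) { states[b].push_back(pre_to); to_id = (int) states[b].size() - 1; }
        }
        int from_id = -1;
        for (size_t t = 0; t < states[b - 1].size(); ++t)
          if (states[b - 1][t] == pre_from) { from_id = (int) t; }
        if (from_id < 0) stop("internal: missing prefix state");
        int nt = base_index(cod[p - 1]);
        double cost = (p == 3) ? -lambda * lw[q] : 0.0;
        double sec = (p == 3) ? -lw[q] : 0.0;
        // deduplicate identical transitions (same from/to/nt); keep the
        // better (smaller cost, then smaller sec) — distinct codons sharing
        // a prefix produce distinct completing transitions, so this only
        // collapses true duplicates on p < 3
        bool dup = false;
        for (auto& t : into[b])
          if (t.from == from_id && t.to == to_id && t.nt == nt) {
            if (cost < t.cost - EPS ||
                (cost <= t.cost + EPS && sec < t.sec - EPS)) {
              t.cost = cost; t.sec = sec;
            }
            dup = true; break;
          }
        if (!dup) into[b].push_back({from_id, to_id, nt, cost, sec});
      }
    }
  }

  int S = 0;
  for (int b = 0; b < B; ++b) S = std::max(S, (int) states[b].size());

  // E[(i*S+u)*B*S + j*S + v]; P likewise (pair-closed spans)
  const size_t cells = (size_t) B * S * B * S;
  std::vector<double> Eo(cells, INF), Es(cells, 0.0);
  std::vector<double> Po(cells, INF), Ps(cells, 0.0);
  auto idx = [B, S](int i, int u, int j, int v) -> size_t {
    return (((size_t) i * S + u) * B + j) * S + v;
  };

  for (int i = 0; i < B; ++i)
    for (int u = 0; u < (int) states[i].size(); ++u)
      Eo[idx(i, u, i, u)] = 0.0;

  for (int len = 1; len < B; ++len) {
    for (int i = 0; i + len < B; ++i) {
      int j = i + len;
      int Si = (int) states[i].size(), Sj = (int) states[j].size();

      // P[i,u][j,v]: nucleotides i+1 and j paired, enclosing i+1..j
      // requires at least min_hairpin enclosed unpaired-capable bases:
      // (j - 1) - (i + 1) >= min_hairpin  <=>  len >= min_hairpin + 2
      if (len >= min_hairpin + 2) {
        for (auto& t1 : into[i + 1]) {
          for (auto& t2 : into[j]) {
            double ps = pair_score(t1.nt, t2.nt);
            if (!R_finite(ps)) continue;
            double in_o = Eo[idx(i + 1, t1.to, j - 1, t2.from)];
            if (!R_finite(in_o)) continue;
            double co = ps + t1.cost + t2.cost + in_o;
            double cs = t1.sec + t2.sec + Es[idx(i + 1, t1.to, j - 1, t2.from)];
            size_t id = idx(i, t1.from, j, t2.to);
            Val cur {Po[id], Ps[id]}, cand {co, cs};
            if (lt(cand, cur)) { Po[id] = co; Ps[id] = cs; }
          }
        }
      }

      for (int u = 0; u < Si; ++u) {
        for (int v = 0; v < Sj; ++v) {
          Val best {INF, 0.0};
          // (a) nucleotide j unpaired
          for (auto& t : into[j]) {
            if (t.to != v) continue;
            double eo = Eo[idx(i, u, j - 1, t.from)];
            if (!R_finite(eo)) continue;
            Val cand {eo + t.cost, Es[idx(i, u, j - 1, t.from)] + t.sec};
            if (lt(cand, best)) best = cand;
          }
          // (b) nucleotide j paired with nucleotide k+1, split at boundary k
          for (int k = i; k <= j - min_hairpin - 2; ++k) {
            for (int w = 0; w < (int) states[k].size(); ++w) {
              double eo = Eo[idx(i, u, k, w)];
              if (!R_finite(eo)) continue;
              double po = Po[idx(k, w, j, v)];
              if (!R_finite(po)) continue;
              Val cand {eo + po, Es[idx(i, u, k, w)] + Ps[idx(k, w, j, v)]};
              if (lt(cand, best)) best = cand;
            }
          }
          size_t id = idx(i, u, j, v);
          Eo[id] = best.obj; Es[id] = best.sec;
        }
      }
    }
  }

  const int N = 3 * n;
  double obj = Eo[idx(0, 0, B - 1, 0)];
  double sec = Es[idx(0, 0, B - 1, 0)];

  // --- traceback: fixed deterministic order ---------------------------------
  std::string seq(N, '?');
  std::string db(N, '.');
  const char* letters = "ACGU";

  // recursive lambdas via explicit stack of tagged frames
  struct Frame { int i, u, j, v; bool paired; };
  std::vector<Frame> st;
  st.push_back({0, 0, B - 1, 0, false});
  while (!st.empty()) {
    Frame f = st.back(); st.pop_back();
    int i = f.i, u = f.u, j = f.j, v = f.v;
    if (!f.paired) {
      if (j == i) continue;
      double eo = Eo[idx(i, u, j, v)], es = Es[idx(i, u, j, v)];
      bool done = false;
      // (a) in nucleotide order
      for (int nt = 0; nt < 4 && !done; ++nt) {
        for (auto& t : into[j]) {
          if (t.to != v || t.nt != nt) continue;
          double po = Eo[idx(i, u, j - 1, t.from)];
          if (!R_finite(po)) continue;
          if (std::fabs(po + t.cost - eo) <= 1e-7 &&
              std::fabs(Es[idx(i, u, j - 1, t.from)] + t.sec - es) <= 1e-7) {
            seq[j - 1] = letters[nt];
            st.push_back({i, u, j - 1, t.from, false});
            done = true; break;
          }
        }
      }
      // (b) leftmost split
      for (int k = i; k <= j - min_hairpin - 2 && !done; ++k) {
        for (int w = 0; w < (int) states[k].size() && !done; ++w) {
          double eo1 = Eo[idx(i, u, k, w)], po = Po[idx(k, w, j, v)];
          if (!R_finite(eo1) || !R_finite(po)) continue;
          if (std::fabs(eo1 + po - eo) <= 1e-7 &&
              std::fabs(Es[idx(i, u, k, w)] + Ps[idx(k, w, j, v)] - es) <= 1e-7) {
            st.push_back({i, u, k, w, false});
            st.push_back({k, w, j, v, true});
            done = true;
          }
        }
      }
      if (!done) stop("internal: traceback failed (unpaired/split)");
    } else {
      // expand a pair-closed span: choose t1 (into i+1) and t2 (into j)
      double po = Po[idx(i, u, j, v)], ps_ = Ps[idx(i, u, j, v)];
      bool done = false;
      for (int nt1 = 0; nt1 < 4 && !done; ++nt1) {
        for (int nt2 = 0; nt2 < 4 && !done; ++nt2) {
          for (auto& t1 : into[i + 1]) {
            if (t1.from != u || t1.nt != nt1) continue;
            for (auto& t2 : into[j]) {
              if (t2.to != v || t2.nt != nt2) continue;
              double pr = pair_score(t1.nt, t2.nt);
              if (!R_finite(pr)) continue;
              double in_o = Eo[idx(i + 1, t1.to, j - 1, t2.from)];
              if (!R_finite(in_o)) continue;
              if (std::fabs(pr + t1.cost + t2.cost + in_o - po) <= 1e-7 &&
                  std::fabs(t1.sec + t2.sec +
                            Es[idx(i + 1, t1.to, j - 1, t2.from)] - ps_) <= 1e-7) {
                seq[i] = letters[t1.nt];
                seq[j - 1] = letters[t2.nt];
                db[i] = '('; db[j - 1] = ')';
                st.push_back({i + 1, t1.to, j - 1, t2.from, false});
                done = true; break;
              }
            }
            if (done) break;
          }
        }
      }
      if (!done) stop("internal: traceback failed (pair)");
    }
  }

  return List::create(_["rna"] = seq, _["objective"] = obj,
                      _["neg_sum_logw"] = sec, _["structure"] = db);
}
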