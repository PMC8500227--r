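#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh), deterministic
// traceback. A gap of length L costs gapOpen + gapExt * L, so the first gap
// position costs gapOpen + gapExt and each further position gapExt.
// Traceback ties prefer diagonal over up (gap in subject) over left (gap in
// query); within a gap state, closing the gap is preferred over extending.

struct SwResult {
  int score;
  int aln_len;
  int n_ident;
};

static SwResult sw_core(const int *q, int m, const int *s, int n,
                        const IntegerMatrix &sub, int gapOpen, int gapExt,
                        bool traceback) {
  const int NEG = -1000000000;
  const int open_cost = gapOpen + gapExt;
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG); // gap in query dim (left)
  std::vector<int> F((m + 1) * (n + 1), NEG); // gap in subject dim (up)
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int idx = i * (n + 1) + j;
      int up = idx - (n + 1), left = idx - 1, diag = up - 1;
      int e = std::max(H[left] - open_cost, E[left] - gapExt);
      int f = std::max(H[up] - open_cost, F[up] - gapExt);
      int d = H[diag] + sub(q[i - 1], s[j - 1]);
      int h = std::max(0, std::max(d, std::max(f, e)));
      E[idx] = e;
      F[idx] = f;
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  SwResult res;
  res.score = best;
  res.aln_len = 0;
  res.n_ident = 0;
  if (!traceback || best == 0) return res;
  // state: 0 = H, 1 = F (up), 2 = E (left)
  int i = bi, j = bj, state = 0;
  while (true) {
    int idx = i * (n + 1) + j;
    if (state == 0) {
      if (H[idx] == 0) break;
      int diagScore = H[idx - (n + 1) - 1] + sub(q[i - 1], s[j - 1]);
      if (H[idx] == diagScore) {
        res.aln_len++;
        if (q[i - 1] == s[j - 1]) res.n_ident++;
        --i; --j;
      } else if (H[idx] == F[idx]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // gap in subject: consume q[i]
      res.aln_len++;
      int up = (i - 1) * (n + 1) + j;
      int fromH = H[up] - open_cost;
      int cur = F[idx];
      --i;
      state = (cur == fromH) ? 0 : 1;
    } else { // gap in query: consume s[j]
      res.aln_len++;
      int left = idx - 1;
      int fromH = H[left] - open_cost;
      int cur = E[idx];
      --j;
      state = (cur == fromH) ? 0 : 2;
    }
  }
  return res;
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                  int gapOpen, int gapExt) {
  SwResult r = sw_core(q.begin(), q.size(), s.begin(), s.size(), sub,
                       gapOpen, gapExt, true);
  return List::create(_["score"] = r.score, _["aln_len"] = r.aln_len,
                      _["n_ident"] = r.n_ident);
}

// All query x subject pairs at once; returns three matrices.
// [[Rcpp::export]]
List sw_all_pairs_cpp(List queries, List subjects, IntegerMatrix sub,
                      int gapOpen, int gapExt) {
  int nq = queries.size(), ns = subjects.size();
  IntegerMatrix score(nq, ns), alnLen(nq, ns), nIdent(nq, ns);
  std::vector<IntegerVector> qs(nq), ss(ns);
  for (int a = 0; a < nq; ++a) qs[a] = queries[a];
  for (int b = 0; b < ns; ++b) ss[b] = subjects[b];
  for (int a = 0; a < nq; ++a) {
    for (int b = 0; b < ns; ++b) {
      SwResult r = sw_core(qs[a].begin(), qs[a].size(), ss[b].begin(),
                           ss[b].size(), sub, gapOpen, gapExt, true);
      score(a, b) = r.score;
      alnLen(a, b) = r.aln_len;
      nIdent(a, b) = r.n_ident;
    }
  }
  return List::create(_["score"] = score, _["aln_len"] = alnLen,
                      _["n_ident"] = nIdent);
}
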