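// Local-alignment dynamic programming for profile HMM scoring.
//
// Model (identical to the R brute-force oracle used in the tests):
//   * entry: from the flank into match state k at any residue position,
//     weight 1/(L*M) (uniform over start position and entry state);
//   * core moves M->M/I/D, I->M/I, D->M/D with the profile's transition
//     probabilities; out of match state k the core mass is rescaled by
//     (1 - 1/(M-k+1)) because
//   * exit: from match state k with probability 1/(M-k+1) (uniform over
//     the remaining exit opportunities; exit from the last match state is
//     certain);
//   * flanking residues are emitted by the background and cancel against
//     the i.i.d. background null, so the DP works directly in log-odds.
//
// All scores are natural logs; the R wrappers convert to bits.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp(a < b ? a - b : b - a));
}

// Column-major index into an (M x 21) log-odds matrix.
static inline double emis(const NumericMatrix& lo, int k, int c) {
  return lo(k, c);
}

// [[Rcpp::export(name = ".fwd_score_cpp")]]
double fwd_score_cpp(IntegerVector pep, NumericMatrix lom, NumericMatrix loi,
                     NumericVector lMM, NumericVector lMI, NumericVector lMD,
                     NumericVector lIM, NumericVector lII, NumericVector lDM,
                     NumericVector lDD, NumericVector lexit) {
  const int L = pep.size(), M = lom.nrow();
  if (L < 1) stop("empty peptide");
  const double lentry = -(std::log((double)L) + std::log((double)M));
  std::vector<double> FMrow(M + 1), FIrow(M + 1), FDrow(M + 1);
  std::vector<double> FMprev(M + 1, NEG_INF), FIprev(M + 1, NEG_INF),
      FDprev(M + 1, NEG_INF);
  double total = NEG_INF;
  for (int t = 0; t < L; ++t) {
    const int c = pep[t];
    std::fill(FMrow.begin(), FMrow.end(), NEG_INF);
    std::fill(FIrow.begin(), FIrow.end(), NEG_INF);
    std::fill(FDrow.begin(), FDrow.end(), NEG_INF);
    for (int k = 1; k <= M; ++k) {
      double acc = lentry;
      if (k > 1) {
        acc = lse2(acc, FMprev[k - 1] + lMM[k - 2]);
        acc = lse2(acc, FIprev[k - 1] + lIM[k - 2]);
        acc = lse2(acc, FDprev[k - 1] + lDM[k - 2]);
      }
      FMrow[k] = emis(lom, k - 1, c) + acc;
    }
    for (int k = 2; k <= M; ++k)  // deletes consume no residue: same row
      FDrow[k] = lse2(FMrow[k - 1] + lMD[k - 2], FDrow[k - 1] + lDD[k - 2]);
    for (int k = 1; k < M; ++k)
      FIrow[k] = emis(loi, k - 1, c) +
                 lse2(FMprev[k] + lMI[k - 1], FIprev[k] + lII[k - 1]);
    for (int k = 1; k <= M; ++k)
      total = lse2(total, FMrow[k] + lexit[k - 1]);
    std::swap(FMprev, FMrow);
    std::swap(FIprev, FIrow);
    std::swap(FDprev, FDrow);
  }
  return total;
}

// [[Rcpp::export(name = ".fwd_batch_cpp")]]
NumericVector fwd_batch_cpp(List peps, NumericMatrix lom, NumericMatrix loi,
                            NumericVector lMM, NumericVector lMI,
                            NumericVector lMD, NumericVector lIM,
                            NumericVector lII, NumericVector lDM,
                            NumericVector lDD, NumericVector lexit) {
  const int n = peps.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = fwd_score_cpp(peps[i], lom, loi, lMM, lMI, lMD, lIM, lII, lDM,
                           lDD, lexit);
  return out;
}

// Viterbi with traceback.  Tie-breaking: predecessor candidates are
// examined in the order M, D, I, entry and replaced only on a strictly
// greater score, so match predecessors are preferred, then delete, then
// insert; the final cell scan runs over ascending (t, k), so the earliest
// position wins ties.
// [[Rcpp::export(name = ".vit_align_cpp")]]
List vit_align_cpp(IntegerVector pep, NumericMatrix lom, NumericMatrix loi,
                   NumericVector lMM, NumericVector lMI, NumericVector lMD,
                   NumericVector lIM, NumericVector lII, NumericVector lDM,
                   NumericVector lDD, NumericVector lexit) {
  const int L = pep.size(), M = lom.nrow();
  if (L < 1) stop("empty peptide");
  const double lentry = -(std::log((double)L) + std::log((double)M));
  // state codes for traceback: 0 = entry, 1 = M, 2 = I, 3 = D
  std::vector<double> VM((size_t)L * (M + 1), NEG_INF),
      VI((size_t)L * (M + 1), NEG_INF), VD((size_t)L * (M + 1), NEG_INF);
  std::vector<signed char> BM((size_t)L * (M + 1), 0),
      BI((size_t)L * (M + 1), 0), BD((size_t)L * (M + 1), 0);
  auto idx = [M](int t, int k) { return (size_t)t * (M + 1) + k; };
  for (int t = 0; t < L; ++t) {
    const int c = pep[t];
    for (int k = 1; k <= M; ++k) {
      double best;
      signed char who;
      if (k > 1 && t > 0) {
        best = VM[idx(t - 1, k - 1)] + lMM[k - 2];
        who = 1;
        double v = VD[idx(t - 1, k - 1)] + lDM[k - 2];
        if (v > best) { best = v; who = 3; }
        v = VI[idx(t - 1, k - 1)] + lIM[k - 2];
        if (v > best) { best = v; who = 2; }
        if (lentry > best) { best = lentry; who = 0; }
      } else {
        best = lentry;
        who = 0;
      }
      VM[idx(t, k)] = emis(lom, k - 1, c) + best;
      BM[idx(t, k)] = who;
    }
    for (int k = 2; k <= M; ++k) {
      double a = VM[idx(t, k - 1)] + lMD[k - 2];
      double b = VD[idx(t, k - 1)] + lDD[k - 2];
      if (a >= b) { VD[idx(t, k)] = a; BD[idx(t, k)] = 1; }
      else        { VD[idx(t, k)] = b; BD[idx(t, k)] = 3; }
    }
    if (t > 0)
      for (int k = 1; k < M; ++k) {
        double a = VM[idx(t - 1, k)] + lMI[k - 1];
        double b = VI[idx(t - 1, k)] + lII[k - 1];
        double e = emis(loi, k - 1, c);
        if (a >= b) { VI[idx(t, k)] = e + a; BI[idx(t, k)] = 1; }
        else        { VI[idx(t, k)] = e + b; BI[idx(t, k)] = 2; }
      }
  }
  double best = NEG_INF;
  int bt = -1, bk = -1;
  for (int t = 0; t < L; ++t)
    for (int k = 1; k <= M; ++k) {
      double v = VM[idx(t, k)] + lexit[k - 1];
      if (v > best) { best = v; bt = t; bk = k; }
    }
  if (bt < 0) return List::create(_["score"] = NEG_INF);
  // traceback
  std::vector<int> st, sk, stt;  // state code, model pos, peptide pos (1-based)
  int t = bt, k = bk, cur = 1;   // start at the exit match cell
  while (true) {
    st.push_back(cur);
    sk.push_back(k);
    stt.push_back(cur == 3 ? 0 : t + 1);
    signed char who;
    if (cur == 1) who = BM[idx(t, k)];
    else if (cur == 2) who = BI[idx(t, k)];
    else who = BD[idx(t, k)];
    if (cur == 1) {
      if (who == 0) break;            // entry reached
      cur = who;
      k -= 1;
      t -= 1;
    } else if (cur == 2) {
      cur = who;
      t -= 1;
    } else {                          // delete: same t, previous k
      cur = who;
      k -= 1;
    }
  }
  const int n = st.size();
  IntegerMatrix path(n, 3);
  colnames(path) = CharacterVector::create("state", "model_pos", "pep_pos");
  for (int i = 0; i < n; ++i) {       // reverse into alignment order
    path(n - 1 - i, 0) = st[i];
    path(n - 1 - i, 1) = sk[i];
    path(n - 1 - i, 2) = stt[i];
  }
  int ali_start = L + 1, ali_end = 0;
  for (int i = 0; i < n; ++i) {
    if (path(i, 2) > 0) {
      if (path(i, 2) < ali_start) ali_start = path(i, 2);
      if (path(i, 2) > ali_end) ali_end = path(i, 2);
    }
  }
  return List::create(_["score"] = best, _["path"] = path,
                      _["ali_start"] = ali_start, _["ali_end"] = ali_end);
}
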