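#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequences are integer vectors coded 1..4 = A,C,G,T; 0 marks a masked base.
// A window containing a masked base is skipped everywhere.

static inline int comp_code(int b) { return 5 - b; }

// Score every window of every sequence on both strands against a 4 x w
// log-odds matrix. Reverse-strand windows are scored as the reverse
// complement of the genomic word read 5'->3' on the minus strand.
// Returns parallel vectors (seq, start, strand, score); start is 1-based
// within the sequence, strand +1 / -1.
// [[Rcpp::export]]
List score_windows_cpp(List seqs, NumericMatrix lo) {
  const int w = lo.ncol();
  // precompute reverse-complement matrix
  NumericMatrix lorc(4, w);
  for (int k = 0; k < w; ++k)
    for (int b = 0; b < 4; ++b)
      lorc(b, k) = lo(3 - b, w - 1 - k);

  std::vector<int> out_seq, out_start, out_strand;
  std::vector<double> out_score;
  const int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    const int L = s.size();
    for (int p = 0; p + w <= L; ++p) {
      bool ok = true;
      double sf = 0.0, sr = 0.0;
      for (int k = 0; k < w; ++k) {
        const int b = s[p + k];
        if (b < 1 || b > 4) { ok = false; break; }
        sf += lo(b - 1, k);
        sr += lorc(b - 1, k);
      }
      if (!ok) continue;
      out_seq.push_back(i + 1);
      out_start.push_back(p + 1);
      out_strand.push_back(1);
      out_score.push_back(sf);
      out_seq.push_back(i + 1);
      out_start.push_back(p + 1);
      out_strand.push_back(-1);
      out_score.push_back(sr);
    }
  }
  return List::create(_["seq"] = wrap(out_seq), _["start"] = wrap(out_start),
                      _["strand"] = wrap(out_strand), _["score"] = wrap(out_score));
}

// ZOOPS EM for one motif width. pwm0: 4 x w initial probabilities; bg: length-4
// background; gamma0: initial per-sequence occurrence probability.
// Objective logged per iteration is the penalised observed-data log likelihood
// (relative to the background-only model) evaluated at the parameters entering
// that iteration; EM guarantees it is non-decreasing.
// [[Rcpp::export]]
List em_zoops_cpp(List seqs, NumericMatrix pwm0, NumericVector bg,
                  double gamma0, int max_iter, double tol, double pseudocount) {
  const int w = pwm0.ncol();
  const int n = seqs.size();
  NumericMatrix pwm = clone(pwm0);
  double gamma = gamma0;
  std::vector<double> obj_trace, llr_trace;
  double prev_obj = R_NegInf;
  int iter = 0;

  // per-sequence window bookkeeping reused across iterations
  for (iter = 0; iter < max_iter; ++iter) {
    NumericMatrix llo(4, w), llorc(4, w);
    for (int k = 0; k < w; ++k)
      for (int b = 0; b < 4; ++b) {
        llo(b, k) = std::log(pwm(b, k)) - std::log(bg[b]);
        llorc(b, k) = std::log(pwm(3 - b, w - 1 - k)) - std::log(bg[b]);
      }

    NumericMatrix counts(4, w);
    double llr = 0.0, sumQ = 0.0;
    int n_used = 0;

    for (int i = 0; i < n; ++i) {
      IntegerVector s = seqs[i];
      const int L = s.size();
      const int npos = L - w + 1;
      if (npos <= 0) continue;
      std::vector<double> sc(2 * npos, R_NegInf);
      std::vector<bool> valid(2 * npos, false);
      int mw = 0;
      double mx = R_NegInf;
      for (int p = 0; p < npos; ++p) {
        bool ok = true;
        double sf = 0.0, sr = 0.0;
        for (int k = 0; k < w; ++k) {
          const int b = s[p + k];
          if (b < 1 || b > 4) { ok = false; break; }
          sf += llo(b - 1, k);
          sr += llorc(b - 1, k);
        }
        if (!ok) continue;
        sc[2 * p] = sf; sc[2 * p + 1] = sr;
        valid[2 * p] = valid[2 * p + 1] = true;
        mw += 2;
        if (sf > mx) mx = sf;
        if (sr > mx) mx = sr;
      }
      if (mw == 0) continue;
      ++n_used;
      double S = 0.0;
      for (size_t j = 0; j < sc.size(); ++j)
        if (valid[j]) S += std::exp(sc[j] - mx);
      // lik_i = (1-gamma) + (gamma/mw) * sum exp(sc)
      //       = exp(mx) * ((1-gamma)exp(-mx) + (gamma/mw) S)
      const double inner = (1.0 - gamma) * std::exp(-mx) + (gamma / mw) * S;
      llr += mx + std::log(inner);
      const double denom = inner; // shared scale exp(mx)
      for (int p = 0; p < npos; ++p) {
        for (int st = 0; st < 2; ++st) {
          const int j = 2 * p + st;
          if (!valid[j]) continue;
          const double z = (gamma / mw) * std::exp(sc[j] - mx) / denom;
          if (z <= 0) continue;
          sumQ += z;
          if (st == 0) {
            for (int k = 0; k < w; ++k) counts(s[p + k] - 1, k) += z;
          } else {
            // minus-strand occurrence: motif position k reads genomic
            // position p + w - 1 - k, complemented
            for (int k = 0; k < w; ++k)
              counts(comp_code(s[p + w - 1 - k]) - 1, k) += z;
          }
        }
      }
    }

    // penalised objective at current parameters
    double prior = 0.0;
    for (int k = 0; k < w; ++k)
      for (int b = 0; b < 4; ++b)
        prior += (pseudocount / 4.0) * std::log(pwm(b, k));
    const double obj = llr + prior;
    obj_trace.push_back(obj);
    llr_trace.push_back(llr);

    if (iter > 0 && std::fabs(obj - prev_obj) < tol) { prev_obj = obj; break; }
    prev_obj = obj;

    // M-step
    if (n_used > 0) {
      gamma = sumQ / n_used;
      if (gamma < 1e-4) gamma = 1e-4;
      if (gamma > 0.999) gamma = 0.999;
    }
    for (int k = 0; k < w; ++k) {
      double tot = 0.0;
      for (int b = 0; b < 4; ++b) tot += counts(b, k);
      for (int b = 0; b < 4; ++b)
        pwm(b, k) = (counts(b, k) + pseudocount / 4.0) / (tot + pseudocount);
    }
  }

  return List::create(_["pwm"] = pwm, _["gamma"] = gamma,
                      _["objective"] = wrap(obj_trace),
                      _["llr"] = wrap(llr_trace),
                      _["iterations"] = (int)obj_trace.size());
}

// Posterior occurrence map for one motif in one set of sequences (used for
// masking and for reporting site positions). Returns, per sequence, the best
// window (MAP) and its posterior occurrence probability Q_i * z|occ.
// [[Rcpp::export]]
List zoops_map_sites_cpp(List seqs, NumericMatrix pwm, NumericVector bg, double gamma) {
  const int w = pwm.ncol();
  const int n = seqs.size();
  IntegerVector best_start(n, NA_INTEGER), best_strand(n, NA_INTEGER);
  NumericVector best_post(n, 0.0), best_score(n, NA_REAL);
  NumericMatrix llo(4, w), llorc(4, w);
  for (int k = 0; k < w; ++k)
    for (int b = 0; b < 4; ++b) {
      llo(b, k) = std::log(pwm(b, k)) - std::log(bg[b]);
      llorc(b, k) = std::log(pwm(3 - b, w - 1 - k)) - std::log(bg[b]);
    }
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    const int L = s.size();
    const int npos = L - w + 1;
    if (npos <= 0) continue;
    std::vector<double> sc(2 * npos, R_NegInf);
    std::vector<bool> valid(2 * npos, false);
    int mw = 0; double mx = R_NegInf;
    for (int p = 0; p < npos; ++p) {
      bool ok = true; double sf = 0, sr = 0;
      for (int k = 0; k < w; ++k) {
        const int b = s[p + k];
        if (b < 1 || b > 4) { ok = false; break; }
        sf += llo(b - 1, k); sr += llorc(b - 1, k);
      }
      if (!ok) continue;
      sc[2 * p] = sf; sc[2 * p + 1] = sr;
      valid[2 * p] = valid[2 * p + 1] = true;
      mw += 2;
      if (sf > mx) mx = sf;
      if (sr > mx) mx = sr;
    }
    if (mw == 0) continue;
    double S = 0.0;
    for (size_t j = 0; j < sc.size(); ++j) if (valid[j]) S += std::exp(sc[j] - mx);
    const double inner = (1.0 - gamma) * std::exp(-mx) + (gamma / mw) * S;
    double bz = -1.0; int bp = -1, bs = 0; double bsc = NA_REAL;
    for (int p = 0; p < npos; ++p)
      for (int st = 0; st < 2; ++st) {
        const int j = 2 * p + st;
        if (!valid[j]) continue;
        const double z = (gamma / mw) * std::exp(sc[j] - mx) / inner;
        if (z > bz) { bz = z; bp = p; bs = st == 0 ? 1 : -1; bsc = sc[j]; }
      }
    if (bp >= 0) {
      best_start[i] = bp + 1;
      best_strand[i] = bs;
      best_post[i] = bz;
      best_score[i] = bsc;
    }
  }
  return List::create(_["start"] = best_start, _["strand"] = best_strand,
                      _["posterior"] = best_post, _["score"] = best_score);
}

// Exact distribution of the discretised PWM score of a random background word.
// bins: 4 x w integer score bins (round(score/granularity)); bg: length 4.
// Returns the pmf over bin values origin..origin+length-1 (attr "origin").
// [[Rcpp::export]]
NumericVector score_pmf_cpp(IntegerMatrix bins, NumericVector bg) {
  const int w = bins.ncol();
  long origin = 0, top = 0;
  std::vector<int> cmin(w), cmax(w);
  for (int k = 0; k < w; ++k) {
    int mn = bins(0, k), mx = bins(0, k);
    for (int b = 1; b < 4; ++b) {
      if (bins(b, k) < mn) mn = bins(b, k);
      if (bins(b, k) > mx) mx = bins(b, k);
    }
    cmin[k] = mn; cmax[k] = mx;
    origin += mn; top += mx;
  }
  const long len = top - origin + 1;
  if (len > 50000000L) stop("score distribution too wide; increase granularity");
  std::vector<double> p(1, 1.0);
  long cur_origin = 0;
  for (int k = 0; k < w; ++k) {
    const long nl = (long)p.size() + (cmax[k] - cmin[k]);
    std::vector<double> q(nl, 0.0);
    for (int b = 0; b < 4; ++b) {
      const int off = bins(b, k) - cmin[k];
      const double wgt = bg[b];
      for (size_t j = 0; j < p.size(); ++j) q[j + off] += wgt * p[j];
    }
    p.swap(q);
    cur_origin += cmin[k];
  }
  NumericVector out(p.begin(), p.end());
  out.attr("origin") = (double)origin;
  return out;
}

// k-mer keys (base-4, first base least significant) and 1-based start
// positions of all fully-ACGT windows of width k.
// [[Rcpp::export]]
List kmer_index_cpp(IntegerVector s, int k) {
  const int n = s.size();
  std::vector<int> keys, pos;
  if (n >= k) {
    for (int p = 0; p + k <= n; ++p) {
      int key = 0; bool ok = true;
      long mult = 1;
      for (int i = 0; i < k; ++i) {
        const int b = s[p + i];
        if (b < 1 || b > 4) { ok = false; break; }
        key += (b - 1) * mult;
        mult *= 4;
      }
      if (ok) { keys.push_back(key); pos.push_back(p + 1); }
    }
  }
  return List::create(_["keys"] = wrap(keys), _["pos"] = wrap(pos));
}
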