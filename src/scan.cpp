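#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Sliding-window peak scan over one promoter's probes.
//
// A window of width `w` slid over the offset axis only changes its probe
// content at integer starts where a probe enters or leaves, so the distinct
// contents are exactly the contiguous probe runs (i..j) that are *realizable*:
// there exists an integer start s with
//   s \in (off[i-1], off[i]]  and  s + w \in (off[j], off[j+1]]
// (sentinels +/-inf at the ends).  Enumerating realizable runs is therefore
// equivalent to enumerating every integer window start, at a fraction of the
// cost.  Candidate runs (>= min_probes probes, mean >= thresh) are merged when
// their realizable window unions [s_lo, s_hi + w) overlap or share an
// endpoint; a gap of >= 1 bp keeps peaks apart.

struct PeakAcc {
    int i0, i1;      // member probe index range (0-based, within gene)
    long end;        // right edge of merged candidate-window union
    bool open;
};

static void flush_peak(const PeakAcc& acc, const std::vector<double>& cs,
                       int gene, std::vector<int>& g, std::vector<int>& a,
                       std::vector<int>& b, std::vector<double>& sc)
{
    int n = acc.i1 - acc.i0 + 1;
    g.push_back(gene);
    a.push_back(acc.i0);
    b.push_back(acc.i1);
    sc.push_back((cs[acc.i1 + 1] - cs[acc.i0]) / n);
}

static void scan_gene(const int* off, const double* val, int k,
                      int w, int min_probes, double thresh, int gene,
                      std::vector<int>& g, std::vector<int>& a,
                      std::vector<int>& b, std::vector<double>& sc,
                      std::vector<double>& cs)
{
    if (k == 0) return;
    if ((int)cs.size() < k + 1) cs.resize(k + 1);
    cs[0] = 0.0;
    for (int i = 0; i < k; ++i) cs[i + 1] = cs[i] + val[i];

    const long NEG = LONG_MIN / 4, POS = LONG_MAX / 4;
    PeakAcc acc; acc.open = false; acc.i0 = acc.i1 = 0; acc.end = NEG;

    for (int i = 0; i < k; ++i) {
        long left = (i > 0) ? (long)off[i - 1] : NEG;
        for (int j = i; j < k && off[j] - off[i] < w; ++j) {
            long right = (j + 1 < k) ? (long)off[j + 1] : POS;
            long s_lo = std::max(left + 1, (long)off[j] - w + 1);
            long s_hi = std::min((long)off[i], right - w);
            if (s_lo > s_hi) continue;               // content not realizable
            int n = j - i + 1;
            if (n < min_probes) continue;
            double mean = (cs[j + 1] - cs[i]) / n;
            if (mean < thresh) continue;
            long lo = s_lo, end = s_hi + w;
            if (acc.open && lo <= acc.end) {         // overlap or touch
                if (end > acc.end) acc.end = end;
                if (j > acc.i1) acc.i1 = j;
            } else {
                if (acc.open) flush_peak(acc, cs, gene, g, a, b, sc);
                acc.i0 = i; acc.i1 = j; acc.end = end; acc.open = true;
            }
        }
    }
    if (acc.open) flush_peak(acc, cs, gene, g, a, b, sc);
}

// [[Rcpp::export]]
DataFrame scan_peaks_cpp(IntegerVector gene_ptr, IntegerVector offsets,
                         NumericVector values, int window_bp, int min_probes,
                         double score_threshold)
{
    int n_genes = gene_ptr.size() - 1;
    std::vector<int> g, a, b;
    std::vector<double> sc, cs;
    for (int gi = 0; gi < n_genes; ++gi) {
        int lo = gene_ptr[gi], hi = gene_ptr[gi + 1];
        scan_gene(&offsets[lo], &values[lo], hi - lo, window_bp, min_probes,
                  score_threshold, gi, g, a, b, sc, cs);
    }
    return DataFrame::create(
        _["gene"] = wrap(g), _["i0"] = wrap(a), _["i1"] = wrap(b),
        _["score"] = wrap(sc));
}

// Null peak scores: shuffle log2 ratios (sample-wide across all promoters,
// or within each promoter window), re-run the identical caller, pool the
// merged peak scores over n_perm permutations. Probe positions stay fixed,
// so per-promoter probe counts are preserved in both modes. Uses R's RNG so
// results follow set.seed() on the R side.
// [[Rcpp::export]]
NumericVector scan_null_scores_cpp(IntegerVector gene_ptr,
                                   IntegerVector offsets,
                                   NumericVector values, int window_bp,
                                   int min_probes, double score_threshold,
                                   int n_perm, bool within_promoter)
{
    int n_genes = gene_ptr.size() - 1;
    int n_probes = values.size();
    std::vector<double> null_scores;
    std::vector<double> buf(values.begin(), values.end());
    std::vector<int> g, a, b;
    std::vector<double> sc, cs;

    for (int p = 0; p < n_perm; ++p) {
        if (within_promoter) {
            for (int gi = 0; gi < n_genes; ++gi) {
                int lo = gene_ptr[gi], hi = gene_ptr[gi + 1];
                for (int i = hi - lo - 1; i > 0; --i) {
                    int j = (int)(unif_rand() * (i + 1));
                    if (j > i) j = i;
                    std::swap(buf[lo + i], buf[lo + j]);
                }
            }
        } else {
            for (int i = n_probes - 1; i > 0; --i) {
                int j = (int)(unif_rand() * (i + 1));
                if (j > i) j = i;
                std::swap(buf[i], buf[j]);
            }
        }
        for (int gi = 0; gi < n_genes; ++gi) {
            int lo = gene_ptr[gi], hi = gene_ptr[gi + 1];
            g.clear(); a.clear(); b.clear(); sc.clear();
            scan_gene(&offsets[lo], &buf[lo], hi - lo, window_bp, min_probes,
                      score_threshold, gi, g, a, b, sc, cs);
            for (size_t q = 0; q < sc.size(); ++q)
                null_scores.push_back(sc[q]);
        }
    }
    return wrap(null_scores);
}
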