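#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// median of buf[0..n-1]; buf is scratch and may be reordered
static double med_inplace(double* buf, int n) {
    int h = n / 2;
    std::nth_element(buf, buf + h, buf + n);
    double m = buf[h];
    if (n % 2 == 0) {
        std::nth_element(buf, buf + h - 1, buf + h);
        m = 0.5 * (m + buf[h - 1]);
    }
    return m;
}

// type-7 quantile on a sorted vector (matches stats::quantile default)
static double quantile7(const double* x, int n, double p) {
    double h = (n - 1) * p;
    int lo = (int)std::floor(h);
    if (lo >= n - 1) return x[n - 1];
    return x[lo] + (h - lo) * (x[lo + 1] - x[lo]);
}

// Percentile bootstrap of the per-sample group median of d (participants x
// samples).  One participant resample per bootstrap iteration is applied to
// every sample, preserving the within-participant timecourse.
// Returns the median of the bootstrap medians and the [lo, hi] percentile
// envelope per sample.  Uses R's RNG.
// [[Rcpp::export(name = ".bootMedianCICpp")]]
List bootMedianCICpp(NumericMatrix d, int nBoot, double lo, double hi) {
    int P = d.nrow(), S = d.ncol();
    NumericMatrix boots(nBoot, S);
    std::vector<int> idx(P);
    std::vector<double> buf(P);
    for (int b = 0; b < nBoot; ++b) {
        for (int p = 0; p < P; ++p) {
            int k = (int)(unif_rand() * P);
            idx[p] = k >= P ? P - 1 : k;
        }
        for (int s = 0; s < S; ++s) {
            for (int p = 0; p < P; ++p) buf[p] = d(idx[p], s);
            boots(b, s) = med_inplace(buf.data(), P);
        }
    }
    NumericVector med(S), cl(S), ch(S);
    std::vector<double> col(nBoot);
    for (int s = 0; s < S; ++s) {
        for (int b = 0; b < nBoot; ++b) col[b] = boots(b, s);
        std::sort(col.begin(), col.end());
        med[s] = quantile7(col.data(), nBoot, 0.5);
        cl[s] = quantile7(col.data(), nBoot, lo);
        ch[s] = quantile7(col.data(), nBoot, hi);
    }
    return List::create(_["median"] = med, _["ciLow"] = cl, _["ciHigh"] = ch);
}

static int max_run(const std::vector<bool>& sig) {
    int best = 0, cur = 0;
    for (size_t i = 0; i < sig.size(); ++i) {
        cur = sig[i] ? cur + 1 : 0;
        if (cur > best) best = cur;
    }
    return best;
}

// Null distribution of the maximum significant-cluster size: per
// permutation, the sample axis is shuffled independently within each
// participant (the per-sample condition difference travels as a unit), the
// per-sample bootstrap test is re-run, and the longest run of samples whose
// lower percentile bound exceeds zero is recorded.
// [[Rcpp::export(name = ".maxClusterNullCpp")]]
IntegerVector maxClusterNullCpp(NumericMatrix d, int nPerm, int nBoot,
                                double lo) {
    int P = d.nrow(), S = d.ncol();
    IntegerVector out(nPerm);
    NumericMatrix work(P, S);
    NumericMatrix boots(nBoot, S);
    std::vector<int> idx(P), perm(S);
    std::vector<double> buf(P), col(nBoot);
    std::vector<bool> sig(S);
    for (int r = 0; r < nPerm; ++r) {
        for (int p = 0; p < P; ++p) {
            for (int s = 0; s < S; ++s) perm[s] = s;
            for (int s = S - 1; s > 0; --s) {    // Fisher-Yates
                int j = (int)(unif_rand() * (s + 1));
                if (j > s) j = s;
                std::swap(perm[s], perm[j]);
            }
            for (int s = 0; s < S; ++s) work(p, s) = d(p, perm[s]);
        }
        for (int b = 0; b < nBoot; ++b) {
            for (int p = 0; p < P; ++p) {
                int k = (int)(unif_rand() * P);
                idx[p] = k >= P ? P - 1 : k;
            }
            for (int s = 0; s < S; ++s) {
                for (int p = 0; p < P; ++p) buf[p] = work(idx[p], s);
                boots(b, s) = med_inplace(buf.data(), P);
            }
        }
        for (int s = 0; s < S; ++s) {
            for (int b = 0; b < nBoot; ++b) col[b] = boots(b, s);
            std::sort(col.begin(), col.end());
            sig[s] = quantile7(col.data(), nBoot, lo) > 0.0;
        }
        out[r] = max_run(sig);
    }
    return out;
}
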