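#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch with linear gap penalty.
//
// Two modes:
//   overlap = false : strict global alignment (end gaps penalized).
//   overlap = true  : end-gap-free on the *reference* (the read aligns to a
//                     contiguous reference substring; leading/trailing
//                     reference bases are skipped at no cost). The read
//                     itself is always fully aligned.
//
// Traceback tie-break is M over D over I, which places deletions at the
// smallest reference coordinate among co-optimal traces (left-alignment).

static inline int subst_score(char a, char b, int match, int mismatch) {
    // N never matches anything, including N
    if (a == b && a != 'N') return match;
    return mismatch;
}

// [[Rcpp::export(name = ".nw_align_many")]]
List nw_align_many(CharacterVector reads, std::string ref,
                   int match, int mismatch, int gap, bool overlap) {
    const int n = (int) ref.size();
    if (n == 0) stop("reference sequence is empty");
    const int R = reads.size();
    IntegerVector score(R), ref_start(R);
    CharacterVector cigar(R);

    std::vector<int> F;           // (n+1) x (m+1), row-major over ref rows
    std::string ops;              // reversed op chars during traceback

    for (int r = 0; r < R; ++r) {
        if (CharacterVector::is_na(reads[r])) stop("read sequence is NA");
        std::string read = as<std::string>(reads[r]);
        const int m = (int) read.size();
        if (m == 0) stop("read sequence is empty");

        // Fast path: for equal-length pairs with Hamming distance d, the
        // all-M alignment scores (m-d)*match + d*mismatch, while any
        // alignment containing a gap scores at most (m-1)*match + 2*gap
        // (an I/D pair loses one aligned column). When the former strictly
        // exceeds the latter the all-M trace is the unique optimum, so the
        // DP can be skipped. Covers the bulk of amplicon reads (no indel,
        // 0-1 substitutions).
        if (m == n) {
            int d = 0;
            for (int i = 0; i < n; ++i)
                if (subst_score(ref[i], read[i], match, mismatch) != match) ++d;
            if ((long long)(m - d) * match + (long long) d * mismatch >
                (long long)(m - 1) * match + 2LL * gap) {
                score[r] = (m - d) * match + d * mismatch;
                ref_start[r] = 1;
                cigar[r] = std::to_string(m) + "M";
                continue;
            }
        }

        const size_t W = (size_t) m + 1;
        F.assign((size_t)(n + 1) * W, 0);
        for (int j = 0; j <= m; ++j) F[j] = j * gap;
        for (int i = 1; i <= n; ++i) F[(size_t) i * W] = overlap ? 0 : i * gap;

        for (int i = 1; i <= n; ++i) {
            const char ci = ref[i - 1];
            const size_t row = (size_t) i * W, prev = (size_t)(i - 1) * W;
            for (int j = 1; j <= m; ++j) {
                int d = F[prev + j - 1] + subst_score(ci, read[j - 1], match, mismatch);
                int u = F[prev + j] + gap;      // D: consume reference
                int l = F[row + j - 1] + gap;   // I: consume read
                int best = d;
                if (u > best) best = u;
                if (l > best) best = l;
                F[row + j] = best;
            }
        }

        int i0 = n;
        if (overlap) {
            int best = F[W - 1 + 0];  // i = 0 row, j = m -> F[0*W + m]
            best = F[(size_t) 0 * W + m];
            i0 = 0;
            for (int i = 1; i <= n; ++i) {
                int v = F[(size_t) i * W + m];
                if (v > best) { best = v; i0 = i; }  // smallest i on ties
            }
        }
        score[r] = F[(size_t) i0 * W + m];

        // traceback
        ops.clear();
        int i = i0, j = m;
        while (i > 0 || j > 0) {
            if (overlap && j == 0) break;
            const size_t row = (size_t) i * W, prev = (size_t)(i - 1) * W;
            if (i > 0 && j > 0 &&
                F[row + j] == F[prev + j - 1] +
                    subst_score(ref[i - 1], read[j - 1], match, mismatch)) {
                ops.push_back('M'); --i; --j;
            } else if (i > 0 && F[row + j] == F[prev + j] + gap) {
                ops.push_back('D'); --i;
            } else {
                ops.push_back('I'); --j;
            }
        }
        ref_start[r] = i + 1;

        // run-length encode reversed ops into a CIGAR string
        std::string cg;
        int len = (int) ops.size();
        int k = len - 1;
        while (k >= 0) {
            char op = ops[k];
            int run = 0;
            while (k >= 0 && ops[k] == op) { ++run; --k; }
            cg += std::to_string(run);
            cg.push_back(op);
        }
        cigar[r] = cg;
    }

    return List::create(_["score"] = score,
                        _["ref_start"] = ref_start,
                        _["cigar"] = cigar);
}
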