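#include <Rcpp.h>
using namespace Rcpp;

// Fenwick (binary indexed) tree primitives over a preallocated numeric array.
// The array is modified in place; index arguments are 1-based, matching R.

// [[Rcpp::export]]
void fenwick_update_(NumericVector tree, int i, double delta) {
    int n = tree.size();
    if (i < 1 || i > n) stop("fenwick index out of range");
    for (; i <= n; i += i & (-i)) tree[i - 1] += delta;
}

// [[Rcpp::export]]
double fenwick_prefix_(NumericVector tree, int i) {
    int n = tree.size();
    if (i > n) i = n;
    double s = 0.0;
    for (; i > 0; i -= i & (-i)) s += tree[i - 1];
    return s;
}

// [[Rcpp::export]]
NumericVector fenwick_build_(NumericVector counts) {
    int n = counts.size();
    NumericVector tree(n);
    for (int i = 1; i <= n; ++i) {
        fenwick_update_(tree, i, counts[i - 1]);
    }
    return tree;
}

static inline double range_sum(const NumericVector& tree, int lo, int hi) {
    // sum of stored counts at sorted-position indices lo..hi (1-based, inclusive)
    if (hi < lo) return 0.0;
    double s = 0.0;
    int i = hi;
    int n = tree.size();
    if (i > n) i = n;
    for (; i > 0; i -= i & (-i)) s += tree[i - 1];
    for (i = lo - 1; i > 0; i -= i & (-i)) s -= tree[i - 1];
    return s;
}

// first index in sorted (ascending) with value >= x, 1-based; n+1 if none
static inline int lower_bound_idx(const IntegerVector& sorted, int x) {
    int lo = 0, hi = sorted.size();
    while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (sorted[mid] < x) lo = mid + 1; else hi = mid;
    }
    return lo + 1;
}

// last index with value <= x, 1-based; 0 if none
static inline int upper_bound_idx(const IntegerVector& sorted, int x) {
    int lo = 0, hi = sorted.size();
    while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (sorted[mid] <= x) lo = mid + 1; else hi = mid;
    }
    return lo;
}

// Iterative multi-read allocation.
//
// Alignments are flattened: pos_idx[a] is the 1-based index of alignment a's
// (chromosome, position) in the globally sorted unique position table;
// read_ptr delimits each read's alignments (read r owns alignments
// read_ptr[r-1]..read_ptr[r]-1, 0-based half-open, r = 1..n_reads).
// seg_start/seg_end delimit each chromosome's slice of the sorted position
// table so windows never cross chromosomes. Window sums use a Fenwick tree
// over stored positions only; counts from the previous iteration are used for
// all reads (synchronous update).
//
// [[Rcpp::export]]
List allocate_cpp_(IntegerVector pos_idx, IntegerVector pos_value,
                   IntegerVector sorted_pos, IntegerVector pos_chrom_seg,
                   IntegerVector seg_start, IntegerVector seg_end,
                   IntegerVector read_ptr,
                   int w, int n_iter, double tol, bool use_tol) {
    int n_aln = pos_idx.size();
    int n_pos = sorted_pos.size();
    int n_reads = read_ptr.size() - 1;

    NumericVector weight(n_aln);
    // initialization: uniform 1/k per read
    for (int r = 0; r < n_reads; ++r) {
        int a0 = read_ptr[r], a1 = read_ptr[r + 1];
        double f = 1.0 / (double)(a1 - a0);
        for (int a = a0; a < a1; ++a) weight[a] = f;
    }

    // precompute window index bounds for each alignment
    IntegerVector win_lo(n_aln), win_hi(n_aln);
    for (int a = 0; a < n_aln; ++a) {
        int seg = pos_chrom_seg[a];             // 1-based segment id
        int s0 = seg_start[seg - 1];            // 1-based bounds of chrom slice
        int s1 = seg_end[seg - 1];
        int p = pos_value[a];
        // restrict binary search to the chromosome's slice
        IntegerVector::const_iterator beg = sorted_pos.begin() + (s0 - 1);
        int len = s1 - s0 + 1;
        // lower bound for p - w
        int lo = 0, hi = len;
        while (lo < hi) { int mid = (lo + hi) / 2; if (beg[mid] < p - w) lo = mid + 1; else hi = mid; }
        win_lo[a] = s0 + lo;
        // upper bound for p + w
        lo = 0; hi = len;
        while (lo < hi) { int mid = (lo + hi) / 2; if (beg[mid] <= p + w) lo = mid + 1; else hi = mid; }
        win_hi[a] = s0 + lo - 1;
    }

    // build count tree from initial weights
    NumericVector tree(n_pos);
    for (int a = 0; a < n_aln; ++a) fenwick_update_(tree, pos_idx[a], weight[a]);

    NumericVector neww(n_aln);
    NumericVector wsum(n_aln);
    int iters_run = 0;
    double max_change = 0.0;

    for (int it = 0; it < n_iter; ++it) {
        max_change = 0.0;
        // E-like step: new fractions from the previous iteration's counts
        for (int r = 0; r < n_reads; ++r) {
            int a0 = read_ptr[r], a1 = read_ptr[r + 1];
            int k = a1 - a0;
            if (k == 1) { neww[a0] = 1.0; continue; }
            double tot = 0.0;
            for (int a = a0; a < a1; ++a) {
                double s = range_sum(tree, win_lo[a], win_hi[a]);
                wsum[a] = s;
                tot += s;
            }
            if (tot <= 0.0) {
                double f = 1.0 / (double)k;
                for (int a = a0; a < a1; ++a) neww[a] = f;
            } else {
                for (int a = a0; a < a1; ++a) neww[a] = wsum[a] / tot;
            }
        }
        // synchronous apply
        for (int a = 0; a < n_aln; ++a) {
            double d = neww[a] - weight[a];
            if (d != 0.0) {
                fenwick_update_(tree, pos_idx[a], d);
                double ad = d < 0 ? -d : d;
                if (ad > max_change) max_change = ad;
                weight[a] = neww[a];
            }
        }
        ++iters_run;
        if (use_tol && max_change < tol) break;
    }

    // guard against accumulated floating-point drift in the tree sums
    for (int a = 0; a < n_aln; ++a) {
        if (weight[a] < 0.0) weight[a] = 0.0;
        else if (weight[a] > 1.0) weight[a] = 1.0;
    }

    return List::create(_["weight"] = weight,
                        _["iterations"] = iters_run,
                        _["max_change"] = max_change);
}
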