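#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Shared helpers -----------------------------------------------------------

// number of elements of sorted vector x in [lo, hi]
static int count_in(const std::vector<int> &x, int lo, int hi)
{
    if (lo > hi) return 0;
    return (int)(std::upper_bound(x.begin(), x.end(), hi) -
                 std::lower_bound(x.begin(), x.end(), lo));
}

static std::vector<std::vector<int> > as_spike_vectors(List spike_times)
{
    const int N = spike_times.size();
    std::vector<std::vector<int> > st(N);
    for (int i = 0; i < N; ++i) {
        IntegerVector v = spike_times[i];
        st[i].assign(v.begin(), v.end());
        std::sort(st[i].begin(), st[i].end());
    }
    return st;
}

// Lagged coincidence counts ------------------------------------------------
//
// For each directed pair (i -> j) and delay d, over the support
// t = t0 + d ... t1 (so that both i_{t-d} and j_t lie inside [t0, t1]):
//   count  = #{ t : i_{t-d} = 1 and j_t = 1 }
//   ni     = #spikes of i in [t0, t1 - d]
//   nj     = #spikes of j in [t0 + d, t1]
//   n      = t1 - t0 + 1 - d
// Cross-correlation and cross-covariance are assembled from these counts at
// the R level, so both measures share one counting pass.

// [[Rcpp::export]]
List fc_count_sweep_cpp(List spike_times, IntegerMatrix pairs,
                        IntegerVector delays, int t0, int t1)
{
    std::vector<std::vector<int> > st = as_spike_vectors(spike_times);
    const int m = pairs.nrow(), nd = delays.size();
    const int T = t1 - t0 + 1;
    if (T < 1) stop("empty time range");

    IntegerMatrix count(m, nd), ni(m, nd), nj(m, nd);

    // group pair rows by receiver so the dense receiver array is built once
    const int N = st.size();
    std::vector<std::vector<int> > rows_by_recv(N);
    for (int r = 0; r < m; ++r) {
        const int j = pairs(r, 1) - 1;
        if (j < 0 || j >= N) stop("pair receiver index out of range");
        rows_by_recv[j].push_back(r);
    }

    // visit delays in ascending order so the per-spike slice can stop at
    // the end of the range
    std::vector<int> perm(nd);
    for (int q = 0; q < nd; ++q) perm[q] = q;
    std::sort(perm.begin(), perm.end(),
              [&](int a, int b) { return delays[a] < delays[b]; });
    std::vector<int> order(nd), rank_of(nd);
    for (int q = 0; q < nd; ++q) {
        order[q] = delays[perm[q]];
        rank_of[q] = perm[q];
    }

    std::vector<unsigned char> dense((size_t)T);
    for (int j = 0; j < N; ++j) {
        if (rows_by_recv[j].empty()) continue;
        std::memset(dense.data(), 0, dense.size());
        for (size_t q = 0; q < st[j].size(); ++q) {
            const int t = st[j][q];
            if (t >= t0 && t <= t1) dense[t - t0] = 1;
        }
        for (size_t rr = 0; rr < rows_by_recv[j].size(); ++rr) {
            const int r = rows_by_recv[j][rr];
            const int i = pairs(r, 0) - 1;
            if (i < 0 || i >= N) stop("pair sender index out of range");
            const std::vector<int> &si = st[i];
            // one pass over sender spikes; per spike the delay bins are
            // read as one contiguous slice of the receiver array
            std::vector<int> cnt(nd, 0);
            std::vector<int>::const_iterator lo =
                std::lower_bound(si.begin(), si.end(), t0);
            for (; lo != si.end() && *lo <= t1; ++lo) {
                const int base = *lo - t0;
                for (int q = 0; q < nd; ++q) {
                    const int idx = base + order[q];
                    if (idx >= T) break;        // delays sorted ascending
                    cnt[rank_of[q]] += dense[idx];
                }
            }
            for (int q = 0; q < nd; ++q) {
                const int d = delays[q];
                count(r, q) = cnt[q];
                ni(r, q) = count_in(si, t0, t1 - d);
                nj(r, q) = count_in(st[j], t0 + d, t1);
            }
        }
    }
    return List::create(_["count"] = count, _["ni"] = ni, _["nj"] = nj,
                        _["n_total"] = T);
}

// Transfer entropy sweep ---------------------------------------------------
//
// Plug-in transfer entropy between binary trains with a k-bin sender past
// word ending at t - d and an l-bin receiver past word ending at t - 1,
// receiver present j_t, in bits. Words encode the most recent bin in the
// least-significant bit. The support is t = t0 + max(d + k - 1, l) ... t1 so
// every referenced bin lies inside [t0, t1]. Empty cells contribute zero.
//
// Counting exploits spike sparsity: only times where the sender word is
// non-zero are visited explicitly; the sender-word == 0 slice of the joint
// table is recovered from receiver-only marginal counts accumulated in one
// reverse pass over a dense receiver code array.

// [[Rcpp::export]]
NumericMatrix fc_te_sweep_cpp(List spike_times, IntegerMatrix pairs,
                              IntegerVector delays, int t0, int t1,
                              int k, int l)
{
    if (k < 1 || l < 1) stop("word lengths k and l must be >= 1");
    if (k > 12 || l > 12) stop("word lengths above 12 bins not supported");
    std::vector<std::vector<int> > st = as_spike_vectors(spike_times);
    const int N = st.size();
    const int m = pairs.nrow(), nd = delays.size();
    const int T = t1 - t0 + 1;
    if (T < 1) stop("empty time range");

    const int WS = 1 << k;          // sender word values
    const int NC = 2 << l;          // receiver codes: j_t + (word << 1)
    if ((double)delays.size() * WS * NC > 6.7e7)
        stop("delay sweep times past-word table size is too large");
    const double log2e = 1.0 / std::log(2.0);

    NumericMatrix te(m, nd);
    std::fill(te.begin(), te.end(), NA_REAL);

    // lazily built per-sender event lists: (time s, word value) for every s
    // in [t0 + k - 1, t1] where the k-bin word ending at s is non-zero
    std::vector<std::vector<std::pair<int, int> > > sender_ev(N);
    std::vector<bool> sender_built(N, false);

    std::vector<std::vector<int> > rows_by_recv(N);
    for (int r = 0; r < m; ++r) {
        const int j = pairs(r, 1) - 1;
        if (j < 0 || j >= N) stop("pair receiver index out of range");
        rows_by_recv[j].push_back(r);
    }

    // distinct support starts across delays
    std::vector<int> tstarts(nd);
    for (int q = 0; q < nd; ++q)
        tstarts[q] = t0 + std::max(delays[q] + k - 1, l);
    std::vector<int> uniq_ts(tstarts);
    std::sort(uniq_ts.begin(), uniq_ts.end());
    uniq_ts.erase(std::unique(uniq_ts.begin(), uniq_ts.end()), uniq_ts.end());

    // delays visited in ascending order inside the per-event slice
    std::vector<int> perm(nd);
    for (int q = 0; q < nd; ++q) perm[q] = q;
    std::sort(perm.begin(), perm.end(),
              [&](int a, int b) { return delays[a] < delays[b]; });

    std::vector<unsigned char> code((size_t)T);
    std::vector<double> Rm((size_t)uniq_ts.size() * NC); // marginals per start
    std::vector<double> Call((size_t)nd * WS * NC);      // per-delay joints
    std::vector<double> n_bw(NC), n_w(NC >> 1);

    for (int j = 0; j < N; ++j) {
        if (rows_by_recv[j].empty()) continue;

        // dense receiver code array over [t0, t1]
        std::memset(code.data(), 0, code.size());
        for (size_t q = 0; q < st[j].size(); ++q) {
            const int t = st[j][q];
            if (t < t0 || t > t1) continue;
            code[t - t0] |= 1;                       // j_t
            for (int b = 1; b <= l; ++b)             // j_{t'} seen as past
                if (t + b <= t1) code[t + b - t0] |= (unsigned char)(1 << b);
        }

        // receiver marginal counts over [s, t1] for each distinct start s,
        // one reverse accumulation pass
        std::fill(Rm.begin(), Rm.end(), 0.0);
        {
            std::vector<double> acc(NC, 0.0);
            int ui = (int)uniq_ts.size() - 1;
            for (int t = t1; t >= t0 && ui >= 0; --t) {
                acc[code[t - t0]] += 1.0;
                while (ui >= 0 && uniq_ts[ui] == t) {
                    std::copy(acc.begin(), acc.end(),
                              Rm.begin() + (size_t)ui * NC);
                    --ui;
                }
            }
        }

        for (size_t rr = 0; rr < rows_by_recv[j].size(); ++rr) {
            const int r = rows_by_recv[j][rr];
            const int i = pairs(r, 0) - 1;
            if (i < 0 || i >= N) stop("pair sender index out of range");

            if (!sender_built[i]) {
                // sweep spikes of i into (time, word) events
                const std::vector<int> &si = st[i];
                std::vector<std::pair<int, int> > &ev = sender_ev[i];
                size_t lo = 0;
                for (size_t q = 0; q < si.size(); ++q) {
                    const int tau = si[q];
                    if (tau < t0 || tau > t1) continue;
                    int s_from = std::max(tau, t0 + k - 1);
                    if (!ev.empty()) s_from = std::max(s_from, ev.back().first + 1);
                    for (int s = s_from; s <= std::min(tau + k - 1, t1); ++s) {
                        while (lo < si.size() && si[lo] < s - k + 1) ++lo;
                        int word = 0;
                        for (size_t z = lo; z < si.size() && si[z] <= s; ++z)
                            word |= 1 << (s - si[z]);
                        if (word) ev.push_back(std::make_pair(s, word));
                    }
                }
                sender_built[i] = true;
            }
            const std::vector<std::pair<int, int> > &ev = sender_ev[i];

            // one pass over sender-word events; for each event the delay
            // bins form a contiguous slice of the receiver code array
            std::memset(&Call[0], 0, sizeof(double) * Call.size());
            for (size_t z = 0; z < ev.size(); ++z) {
                const int s = ev[z].first;
                double *slab = &Call[(size_t)ev[z].second * NC];
                for (int qq = 0; qq < nd; ++qq) {
                    const int q = perm[qq];
                    const int t = s + delays[q];
                    if (t > t1) break;
                    if (t < tstarts[q]) continue;
                    slab[(size_t)q * WS * NC + code[t - t0]] += 1.0;
                }
            }

            for (int q = 0; q < nd; ++q) {
                const int tstart = tstarts[q];
                const double n = (double)(t1 - tstart + 1);
                if (n < 1.0) continue;
                const int uidx = (int)(std::lower_bound(uniq_ts.begin(),
                                  uniq_ts.end(), tstart) - uniq_ts.begin());
                const double *R = &Rm[(size_t)uidx * NC];
                double *C = &Call[(size_t)q * WS * NC];

                // recover the sender-word == 0 slice from receiver marginals
                for (int cc = 0; cc < NC; ++cc) {
                    double other = 0.0;
                    for (int ws = 1; ws < WS; ++ws)
                        other += C[(size_t)ws * NC + cc];
                    C[cc] = R[cc] - other;
                }

                // marginals
                std::fill(n_bw.begin(), n_bw.end(), 0.0);
                std::fill(n_w.begin(), n_w.end(), 0.0);
                for (int cc = 0; cc < NC; ++cc) {
                    n_bw[cc] = R[cc];
                    n_w[cc >> 1] += R[cc];
                }
                // N(ws, wr) summed over j_t
                // TE = sum c/n * log2( c * N(wr) / (N(ws,wr) * N(b,wr)) )
                double val = 0.0;
                for (int ws = 0; ws < WS; ++ws) {
                    for (int wr = 0; wr < (NC >> 1); ++wr) {
                        const double c0 = C[(size_t)ws * NC + 2 * wr];
                        const double c1 = C[(size_t)ws * NC + 2 * wr + 1];
                        const double nsw_wr = c0 + c1;
                        if (nsw_wr <= 0.0) continue;
                        if (c0 > 0.0)
                            val += c0 * std::log(c0 * n_w[wr] /
                                   (nsw_wr * n_bw[2 * wr]));
                        if (c1 > 0.0)
                            val += c1 * std::log(c1 * n_w[wr] /
                                   (nsw_wr * n_bw[2 * wr + 1]));
                    }
                }
                te(r, q) = val * log2e / n;
            }
        }
    }
    return te;
}
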