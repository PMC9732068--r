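#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Millisecond-resolution simulation of a recurrent Izhikevich network with
// conduction delays and trace-based STDP.
//
// Per 1-ms step (mirroring the reference cortical-network integration order):
//   1. decay plasticity traces
//   2. neurons whose v crossed 30 mV during the previous step fire: reset,
//      potentiate their incoming excitatory synapses from the presynaptic
//      arrival traces, schedule delayed deliveries, bump own traces
//   3. deliveries due this step add their weight to I_syn and depress the
//      delivering synapse by the postsynaptic trace (post-before-arrival)
//   4. external drive: +input_mv to one uniformly chosen neuron
//   5. v advanced by two 0.5-ms Euler substeps, u by one 1-ms step
// Every 1000 steps the accumulated dw is applied (clipped to [0, w_max]),
// then carried over scaled by the memory factor.

// [[Rcpp::export]]
List sim_network_cpp(int n_neurons,
                     LogicalVector is_exc,
                     IntegerVector edge_pre,    // 1-based presynaptic index
                     IntegerVector edge_post,   // 1-based postsynaptic index
                     IntegerVector edge_delay,  // ms, >= 1
                     NumericVector edge_w0,     // initial weight, mV (signed)
                     NumericVector par_a, NumericVector par_b,
                     NumericVector par_c, NumericVector par_d,
                     int duration_ms,
                     double a_plus, double a_minus, double tau_ms,
                     double memory_factor, double w_max, double w_drift,
                     double input_mv, bool stdp_on, bool trace_additive)
{
    const int N = n_neurons;
    const int M = edge_pre.size();

    // adjacency by neuron
    std::vector<std::vector<int> > out_syn(N), in_syn(N);
    int d_max = 1;
    for (int s = 0; s < M; ++s) {
        out_syn[edge_pre[s] - 1].push_back(s);
        in_syn[edge_post[s] - 1].push_back(s);
        if (edge_delay[s] > d_max) d_max = edge_delay[s];
    }
    const int ring = d_max + 1;

    std::vector<double> v(N, -65.0), u(N);
    for (int i = 0; i < N; ++i) u[i] = par_b[i] * v[i];

    std::vector<double> w(edge_w0.begin(), edge_w0.end());
    std::vector<double> dw(M, 0.0);
    std::vector<bool>   plastic(M);
    for (int s = 0; s < M; ++s) plastic[s] = is_exc[edge_pre[s] - 1];

    // plasticity traces: E = presynaptic emission trace (ring-buffered
    // history so arrival-time values E_i(t - delay) can be read back),
    // P = postsynaptic spike trace
    const double decay = std::exp(-1.0 / tau_ms);
    std::vector<double> Ecur(N, 0.0), P(N, 0.0);
    std::vector<double> Ehist((size_t)N * ring, 0.0); // [i*ring + t%ring]

    // pending deliveries: synapse ids bucketed by arrival time modulo ring
    std::vector<std::vector<int> > bucket(ring);

    std::vector<std::vector<int> > spikes(N);
    std::vector<double> I(N);

    const int n_sec = duration_ms / 1000;
    int n_plastic = 0;
    for (int s = 0; s < M; ++s) if (plastic[s]) ++n_plastic;
    NumericMatrix w_traj(n_plastic, n_sec);
    std::vector<int> plastic_idx;
    plastic_idx.reserve(n_plastic);
    for (int s = 0; s < M; ++s) if (plastic[s]) plastic_idx.push_back(s);

    GetRNGstate();
    for (int t = 1; t <= duration_ms; ++t) {
        const int slot = t % ring;

        if (stdp_on) {
            for (int i = 0; i < N; ++i) { Ecur[i] *= decay; P[i] *= decay; }
        }

        // fire: v crossed threshold during the previous step
        for (int i = 0; i < N; ++i) I[i] = 0.0;
        for (int i = 0; i < N; ++i) {
            if (v[i] >= 30.0) {
                v[i] = par_c[i];
                u[i] += par_d[i];
                spikes[i].push_back(t);
                if (stdp_on) {
                    // potentiation: presynaptic arrival trace at time t,
                    // i.e. the emission trace of pre read delay ms back
                    for (size_t q = 0; q < in_syn[i].size(); ++q) {
                        const int s = in_syn[i][q];
                        if (!plastic[s]) continue;
                        const int ts = t - edge_delay[s];
                        if (ts < 1) continue;
                        dw[s] += a_plus *
                            Ehist[(size_t)(edge_pre[s] - 1) * ring + ts % ring];
                    }
                }
                for (size_t q = 0; q < out_syn[i].size(); ++q) {
                    const int s = out_syn[i][q];
                    bucket[(t + edge_delay[s]) % ring].push_back(s);
                }
                if (stdp_on) {
                    if (trace_additive) { Ecur[i] += 1.0; P[i] += 1.0; }
                    else                { Ecur[i] = 1.0;  P[i] = 1.0;  }
                }
            }
        }

        // deliveries due now: synaptic input + depression
        std::vector<int> &due = bucket[slot];
        for (size_t q = 0; q < due.size(); ++q) {
            const int s = due[q];
            const int j = edge_post[s] - 1;
            I[j] += w[s];
            if (stdp_on && plastic[s]) dw[s] -= a_minus * P[j];
        }
        due.clear();

        // external drive to one random neuron
        int r = (int)(unif_rand() * N);
        if (r >= N) r = N - 1;
        I[r] += input_mv;

        // integrate
        for (int i = 0; i < N; ++i) {
            double vi = v[i], ui = u[i];
            vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I[i]);
            vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I[i]);
            ui += par_a[i] * (par_b[i] * vi - ui);
            if (!std::isfinite(vi) || !std::isfinite(ui)) {
                PutRNGstate();
                stop("numerical instability in neuron %d at t = %d ms",
                     i + 1, t);
            }
            v[i] = vi; u[i] = ui;
        }

        if (stdp_on) {
            for (int i = 0; i < N; ++i)
                Ehist[(size_t)i * ring + slot] = Ecur[i];
        }

        // 1-s weight update epoch (weights frozen when plasticity is off)
        if (t % 1000 == 0) {
            const int ep = t / 1000 - 1;
            for (int q = 0; q < n_plastic; ++q) {
                const int s = plastic_idx[q];
                if (stdp_on) {
                    double ws = w[s] + dw[s] + w_drift;
                    if (ws > w_max) ws = w_max;
                    if (ws < 0.0)   ws = 0.0;
                    w[s] = ws;
                    dw[s] *= memory_factor;
                }
                if (ep < n_sec) w_traj(q, ep) = w[s];
            }
        }
    }
    PutRNGstate();

    List spk(N);
    for (int i = 0; i < N; ++i) spk[i] = wrap(spikes[i]);
    return List::create(_["spike_times"] = spk,
                        _["w_traj"]      = w_traj,
                        _["w_final"]     = wrap(w),
                        _["plastic_idx"] = wrap(plastic_idx)); // 0-based
}

// Single-neuron Izhikevich integration with a user-supplied input trace,
// using the identical substep scheme as the network simulator. Used for
// validating the integrator against an independent reference loop.
// [[Rcpp::export]]
List izh_trace_cpp(double a, double b, double c, double d,
                   NumericVector input_mv, double v0, double u0)
{
    const int T = input_mv.size();
    NumericVector v_out(T), u_out(T);
    IntegerVector spike(T);
    double v = v0, u = u0;
    for (int t = 0; t < T; ++t) {
        if (v >= 30.0) { v = c; u += d; spike[t] = 1; }
        const double I = input_mv[t];
        v += 0.5 * (0.04 * v * v + 5.0 * v + 140.0 - u + I);
        v += 0.5 * (0.04 * v * v + 5.0 * v + 140.0 - u + I);
        u += a * (b * v - u);
        if (!std::isfinite(v) || !std::isfinite(u))
            stop("numerical instability at step %d", t + 1);
        v_out[t] = v; u_out[t] = u;
    }
    return List::create(_["v"] = v_out, _["u"] = u_out, _["spiked"] = spike);
}
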