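#include <Rcpp.h>
using namespace Rcpp;

// Piecewise activation: 0 below zero, saturating tanh above.
static inline double phi_act(double x, double range) {
    return (x < 0.0) ? 0.0 : range * std::tanh(x / range);
}

// Euler integration of the 8-population (4 classes x 2 copies) stochastic
// rate model. Populations are laid out copy-pairs-adjacent: class(p) = p/2.
// Recurrent drive to every copy uses the mean rate of the two source copies
// (equivalent to W/2 from each copy), so the duplicated network matches the
// 4-population mean-field equations. Per step and trial, one shared
// feedforward and one shared top-down unit-Gaussian draw plus one private
// draw per copy enter inside the activation, scaled by the supplied
// coefficients. Draw order per step: ff, td, then the 8 privates, so results
// are reproducible from R's RNG seed.
//
// I_const: per-copy condition-dependent deterministic input (baseline plus
//   top-down for the additive model; gain-scaled baseline for the
//   multiplicative model).
// I_stim:  per-copy stimulus input at full drive; multiplied by
//   stim_scale[t] (0 / non-preferred fraction / 1) per step.
// W_signed: 4 x 4 class-level signed connectivity (row = target class).
//
// [[Rcpp::export]]
List circuit_sim_cpp(NumericVector tau8, NumericVector I_const,
                     NumericVector I_stim, NumericMatrix W_signed,
                     NumericVector c_ff, NumericVector c_td,
                     NumericVector c_priv, NumericVector stim_scale,
                     double dt, double r0, double rmax, int n_trials,
                     int pref_lo, int pref_hi, int nonpref_lo, int nonpref_hi,
                     bool store_rates, int decimate, bool freeze_noise) {
    const int NP = 8, NC = 4;
    const int n_steps = stim_scale.size();
    const double range = rmax - r0;
    bool noisy = false;
    for (int p = 0; p < NP; ++p) {
        if (c_ff[p] != 0.0 || c_td[p] != 0.0 || c_priv[p] != 0.0) noisy = true;
    }
    NumericMatrix pref_mean(n_trials, NP), nonpref_mean(n_trials, NP);
    int n_keep = store_rates ? (n_steps + decimate - 1) / decimate : 0;
    NumericVector rates(store_rates ? (R_xlen_t)n_trials * NP * n_keep : 0);

    double r[8], rbar[4], rec[4], x;
    const double pref_n = pref_hi - pref_lo, nonpref_n = nonpref_hi - nonpref_lo;
    for (int tr = 0; tr < n_trials; ++tr) {
        for (int p = 0; p < NP; ++p) r[p] = 0.0;
        double psum[8] = {0}, nsum[8] = {0};
        // frozen (per-trial) noise: one draw per source per trial, held
        // constant across the trial — quenched input fluctuations
        double fr_ff = 0.0, fr_td = 0.0, fr_p[8] = {0};
        if (noisy && freeze_noise) {
            fr_ff = norm_rand(); fr_td = norm_rand();
            for (int p = 0; p < NP; ++p) fr_p[p] = norm_rand();
        }
        int keep_idx = 0;
        for (int t = 0; t < n_steps; ++t) {
            for (int c = 0; c < NC; ++c) rbar[c] = 0.5 * (r[2 * c] + r[2 * c + 1]);
            for (int c = 0; c < NC; ++c) {
                double s = 0.0;
                for (int j = 0; j < NC; ++j) s += W_signed(c, j) * rbar[j];
                rec[c] = s;
            }
            double xi_ff = fr_ff, xi_td = fr_td;
            if (noisy && !freeze_noise) { xi_ff = norm_rand(); xi_td = norm_rand(); }
            const double ss = stim_scale[t];
            for (int p = 0; p < NP; ++p) {
                double xi_p = freeze_noise ? fr_p[p]
                                           : (noisy ? norm_rand() : 0.0);
                x = I_const[p] + ss * I_stim[p] + rec[p / 2] +
                    c_ff[p] * xi_ff + c_td[p] * xi_td + c_priv[p] * xi_p;
                r[p] += dt / tau8[p] * (-r[p] + phi_act(x, range));
                if (!std::isfinite(r[p])) {
                    stop("non-finite rate at trial %d, step %d, population %d",
                         tr + 1, t + 1, p + 1);
                }
                if (t >= pref_lo && t < pref_hi) psum[p] += r[p];
                if (t >= nonpref_lo && t < nonpref_hi) nsum[p] += r[p];
            }
            if (store_rates && t % decimate == 0) {
                for (int p = 0; p < NP; ++p) {
                    rates[(R_xlen_t)tr + (R_xlen_t)n_trials *
                          (p + (R_xlen_t)NP * keep_idx)] = r[p];
                }
                ++keep_idx;
            }
        }
        for (int p = 0; p < NP; ++p) {
            pref_mean(tr, p) = psum[p] / pref_n;
            nonpref_mean(tr, p) = nsum[p] / nonpref_n;
        }
    }
    List out = List::create(_["pref_mean"] = pref_mean,
                            _["nonpref_mean"] = nonpref_mean);
    if (store_rates) {
        rates.attr("dim") = IntegerVector::create(n_trials, NP, n_keep);
        out["rates"] = rates;
    }
    return out;
}
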