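#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-passage-time density of a Wiener diffusion (unit diffusion
// coefficient) between absorbing boundaries 0 and a, drift v, relative
// start w = z/a, at the LOWER boundary.  The density is evaluated through
// the rescaled unit problem f(t | v, a, w) = f0(t/a^2, w) / a^2 *
// exp(-v a w - v^2 t / 2), where f0 is the zero-drift unit-boundary
// density, computed by series truncation with the usual small-time /
// large-time switching rule at absolute tolerance eps.

static double wfpt_unit(double tt, double w, double eps) {
    // number of terms needed for each expansion
    double kl, ks;
    if (M_PI * tt * eps < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tt));
    }
    if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt *
                             std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * eps));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }
    double p = 0.0;
    if (ks < kl) {            // small-time expansion
        int K = (int)std::ceil(ks);
        int lo = -(int)std::floor((K - 1) / 2.0);
        int hi = (int)std::ceil((K - 1) / 2.0);
        for (int k = lo; k <= hi; ++k) {
            double u = w + 2.0 * k;
            p += u * std::exp(-u * u / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {                  // large-time expansion
        int K = (int)std::ceil(kl);
        for (int k = 1; k <= K; ++k) {
            p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
                 std::sin(k * M_PI * w);
        }
        p *= M_PI;
    }
    return p > 0.0 ? p : 0.0;
}

// density of decision time t (already ndt-subtracted) at the lower boundary
static double wfpt_lower(double t, double v, double a, double w, double eps) {
    if (t <= 0.0) return 0.0;
    double tt = t / (a * a);
    double f0 = wfpt_unit(tt, w, eps);
    return f0 / (a * a) * std::exp(-v * a * w - v * v * t / 2.0);
}

// [[Rcpp::export(name = ".wfptDensityCpp")]]
NumericVector wfptDensityCpp(NumericVector t, double v, double a, double w,
                             double ndt, bool upper, double eps = 1e-10) {
    int n = t.size();
    NumericVector out(n);
    double vv = upper ? -v : v;
    double ww = upper ? 1.0 - w : w;
    for (int i = 0; i < n; ++i) {
        double td = t[i] - ndt;
        out[i] = td > 0.0 ? wfpt_lower(td, vv, a, ww, eps) : 0.0;
    }
    return out;
}

// Trial-wise log-likelihood of choices and RTs under the drift-regression
// variants.  choice: 1 = upper boundary (face), 0 = lower (car).
// variant: 1 scale_late, 2 scale_early, 3 scale_both, 4 early_on_ndt,
//          5 behavior_only.  sgn: +1 face trials, -1 car trials (used by
// behavior_only).  theta = (g0, g1, g2, alpha, beta, ndt).
static double ddm_loglik(const NumericVector& rt, const IntegerVector& choice,
                         const NumericVector& coh, const NumericVector& yE,
                         const NumericVector& yL, const IntegerVector& sgn,
                         int variant, const double* th) {
    double g0 = th[0], g1 = th[1], g2 = th[2];
    double a = th[3], b = th[4], ndt = th[5];
    if (!(a > 0.0) || !(b > 0.0) || !(b < 1.0) || !(ndt >= 0.0))
        return R_NegInf;
    const double eps = 1e-10;
    double ll = 0.0;
    int n = rt.size();
    for (int i = 0; i < n; ++i) {
        double v, nd = ndt;
        switch (variant) {
        case 1: v = g0 + g1 * yE[i] + g2 * yL[i] * coh[i]; break;
        case 2: v = g0 + g1 * yE[i] * coh[i] + g2 * yL[i]; break;
        case 3: v = g0 + g1 * yE[i] * coh[i] + g2 * yL[i] * coh[i]; break;
        case 4: v = g0 + g2 * yL[i] * coh[i]; nd = ndt + g1 * yE[i]; break;
        case 5: v = g0 + g1 * sgn[i] * coh[i]; break;
        default: stop("unknown variant code");
        }
        if (!(nd >= 0.0)) return R_NegInf;
        double td = rt[i] - nd;
        if (td <= 0.0) return R_NegInf;   // RT <= nDT: zero likelihood
        double dens = choice[i] == 1 ? wfpt_lower(td, -v, a, 1.0 - b, eps)
                                     : wfpt_lower(td, v, a, b, eps);
        if (!(dens > 0.0)) return R_NegInf;
        ll += std::log(dens);
    }
    return ll;
}

// [[Rcpp::export(name = ".ddmLoglikCpp")]]
double ddmLoglikCpp(NumericVector rt, IntegerVector choice, NumericVector coh,
                    NumericVector yE, NumericVector yL, IntegerVector sgn,
                    int variant, NumericVector theta) {
    return ddm_loglik(rt, choice, coh, yE, yL, sgn, variant,
                      REAL(theta.get__()));
}

// One componentwise Metropolis sweep over the active parameters of a single
// participant-condition block.  Proposals are Gaussian with per-parameter
// scales; the target combines the trial likelihood with the group-level
// Gaussian prior N(mu, sigma).  Uses R's RNG so set.seed() governs draws.
// [[Rcpp::export(name = ".mhSweepCpp")]]
List mhSweepCpp(NumericVector rt, IntegerVector choice, NumericVector coh,
                NumericVector yE, NumericVector yL, IntegerVector sgn,
                int variant, NumericVector theta, NumericVector mu,
                NumericVector sigma, NumericVector scales,
                IntegerVector active, double curll) {
    NumericVector th = clone(theta);
    IntegerVector acc(theta.size());
    double prop[6];
    for (int j = 0; j < active.size(); ++j) {
        int p = active[j] - 1;   // 1-based from R
        for (int q = 0; q < 6; ++q) prop[q] = th[q];
        prop[p] = th[p] + scales[p] * norm_rand();
        double newll = ddm_loglik(rt, choice, coh, yE, yL, sgn, variant, prop);
        if (newll == R_NegInf) continue;
        double logr = newll - curll +
            R::dnorm(prop[p], mu[p], sigma[p], 1) -
            R::dnorm(th[p], mu[p], sigma[p], 1);
        if (std::log(unif_rand()) < logr) {
            th[p] = prop[p];
            curll = newll;
            acc[p] = 1;
        }
    }
    return List::create(_["theta"] = th, _["ll"] = curll, _["acc"] = acc);
}

// Euler-Maruyama simulation of the diffusion with within-step Brownian
// bridge boundary-crossing check.  drift is per-trial; returns first-passage
// RT (including ndt) and boundary hit (1 upper, 0 lower, NA if the deadline
// tmax is exceeded before absorption).
// [[Rcpp::export(name = ".simWienerCpp")]]
List simWienerCpp(NumericVector drift, double a, double beta, double ndt,
                  double dt, double tmax) {
    int n = drift.size();
    NumericVector rt(n);
    IntegerVector choice(n);
    double sq = std::sqrt(dt);
    double hardcap = 60.0;    // absolute guard against non-absorbing walks
    for (int i = 0; i < n; ++i) {
        double x = beta * a, t = 0.0;
        int ch = NA_INTEGER;
        bool done = false;
        while (!done) {
            double xn = x + drift[i] * dt + sq * norm_rand();
            t += dt;
            if (xn <= 0.0)      { ch = 0; done = true; }
            else if (xn >= a)   { ch = 1; done = true; }
            else {
                double plow = std::exp(-2.0 * x * xn / dt);
                if (unif_rand() < plow) { ch = 0; done = true; }
                else {
                    double pup = std::exp(-2.0 * (a - x) * (a - xn) / dt);
                    if (unif_rand() < pup) { ch = 1; done = true; }
                }
            }
            if (!done) {
                x = xn;
                if (ndt + t > tmax || t > hardcap) break;
            }
        }
        if (ch == NA_INTEGER) {
            rt[i] = NA_REAL;
            choice[i] = NA_INTEGER;
        } else {
            rt[i] = ndt + t;
            choice[i] = ch;
        }
    }
    return List::create(_["rt"] = rt, _["choice"] = choice);
}
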