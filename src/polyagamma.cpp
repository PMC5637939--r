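// Polya-Gamma random variates PG(b, c).
//
// PG(1, c) uses Devroye's exact alternating-series rejection sampler for the
// Jacobi-type variable J*(1, z) with z = |c|/2 (PG(1, c) = J*(1, z) / 4).
// Integer shapes below PG_APPROX are sums of unit draws; the fractional part
// of b uses a truncated infinite-sum-of-Gammas representation with a
// deterministic tail-mean correction; shapes >= PG_APPROX use a shifted-Gamma
// approximation matching the exact mean, variance and skewness. All
// randomness flows through R's RNG, so set.seed() in R makes draws
// reproducible.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const double TRUNC = 0.64;        // Devroye's left/right split point
static const double PG_APPROX = 8.0;     // moment-matched approx above this b
static const int SERIES_TERMS = 50;      // terms for fractional-shape series

// n-th coefficient of the alternating series bounding the J*(1, z) density
static double a_coef(int n, double x)
{
    double h = n + 0.5;
    if (x <= TRUNC) {
        return M_PI * h * std::pow(2.0 / (M_PI * x), 1.5) *
               std::exp(-2.0 * h * h / x);
    }
    return M_PI * h * std::exp(-0.5 * h * h * M_PI * M_PI * x);
}

// CDF of inverse-Gaussian(mu, lambda = 1) at t
static double pigauss(double t, double mu)
{
    double rt = std::sqrt(1.0 / t);
    double a = rt * (t / mu - 1.0);
    double b = -rt * (t / mu + 1.0);
    return R::pnorm(a, 0.0, 1.0, 1, 0) +
           std::exp(2.0 / mu) * R::pnorm(b, 0.0, 1.0, 1, 0);
}

// inverse-Gaussian(mu, 1) draw (Michael-Schucany-Haas)
static double rinvgauss_one(double mu)
{
    double y = R::norm_rand();
    y = y * y;
    double x = mu + 0.5 * mu * mu * y -
               0.5 * mu * std::sqrt(4.0 * mu * y + mu * mu * y * y);
    if (R::unif_rand() > mu / (mu + x))
        x = mu * mu / x;
    return x;
}

// inverse-Gaussian(1/z, 1) truncated to (0, TRUNC]
static double rtinvgauss(double z)
{
    double t = TRUNC;
    if (z < 1.0 / t) {
        // large-mean regime: sample 1/(2*Gamma)-type proposal, tilt by z
        for (;;) {
            double e1, e2;
            do {
                e1 = R::exp_rand();
                e2 = R::exp_rand();
            } while (e1 * e1 > 2.0 * e2 / t);
            double x = t / ((1.0 + t * e1) * (1.0 + t * e1));
            if (R::unif_rand() <= std::exp(-0.5 * z * z * x))
                return x;
        }
    }
    double mu = 1.0 / z;
    for (;;) {
        double x = rinvgauss_one(mu);
        if (x < t)
            return x;
    }
}

// one draw from PG(1, c) via Devroye's method
static double rpg_devroye_one(double c)
{
    double z = 0.5 * std::fabs(c);
    double fz = 0.125 * M_PI * M_PI + 0.5 * z * z; // rate on the right piece
    double p = 0.5 * M_PI / fz * std::exp(-fz * TRUNC);
    double q = 2.0 * std::exp(-z) * pigauss(TRUNC, 1.0 / std::max(z, 1e-12));
    if (z < 1e-12)
        q = 2.0 * pigauss(TRUNC, 1e12); // z -> 0 limit of exp(-z)*P(IG < t)

    for (;;) {
        double x;
        if (R::unif_rand() < p / (p + q)) {
            x = TRUNC + R::exp_rand() / fz;
        } else {
            x = rtinvgauss(std::max(z, 1e-12));
        }
        // squeeze accept/reject on the alternating series
        double s = a_coef(0, x);
        double y = R::unif_rand() * s;
        int n = 0;
        bool accept = false, reject = false;
        while (!accept && !reject) {
            ++n;
            if (n % 2 == 1) {
                s -= a_coef(n, x);
                if (y <= s) accept = true;
            } else {
                s += a_coef(n, x);
                if (y > s) reject = true;
            }
        }
        if (accept)
            return 0.25 * x;
    }
}

// PG(b, c) for fractional b in (0, 1): truncated sum-of-Gammas plus the
// analytic tail mean (tail variance is O(1e-6) relative and ignored)
static double rpg_series_one(double b, double c)
{
    double a = 0.5 * std::fabs(c) / M_PI; // c/(2*pi)
    double twopi2 = 2.0 * M_PI * M_PI;
    double out = 0.0;
    for (int k = 1; k <= SERIES_TERMS; ++k) {
        double h = k - 0.5;
        double d = h * h + a * a;
        out += R::rgamma(b, 1.0) / (twopi2 * d);
    }
    // tail mean: (b / 2 pi^2) * sum_{k > n} 1/((k - 1/2)^2 + a^2)
    double n = (double)SERIES_TERMS;
    double tail;
    if (a > 1e-8)
        tail = (0.5 * M_PI - std::atan(n / a)) / a;
    else
        tail = 1.0 / n;
    out += b * tail / twopi2;
    return out;
}

// exact moments of PG(b, c)
static double pg_mean(double b, double c)
{
    double ac = std::fabs(c);
    if (ac < 1e-8)
        return 0.25 * b * (1.0 - ac * ac / 12.0);
    return 0.5 * b / ac * std::tanh(0.5 * ac);
}

static double pg_var(double b, double c)
{
    double ac = std::fabs(c);
    if (ac < 1e-4)
        return b / 24.0;
    double ch = std::cosh(0.5 * ac);
    return 0.25 * b * (std::sinh(ac) - ac) / (ac * ac * ac * ch * ch);
}

// third cumulant of PG(b, c) via its sum-of-Gammas representation:
// kappa3 = 2b / (2 pi^2)^3 * sum_k 1/((k - 1/2)^2 + (c/2pi)^2)^3
static double pg_kappa3(double b, double c)
{
    double a2 = c * c / (4.0 * M_PI * M_PI);
    double s = 0.0;
    for (int k = 1; k <= 200; ++k) {
        double h = k - 0.5;
        double d = h * h + a2;
        s += 1.0 / (d * d * d);
    }
    double c6 = 8.0 * M_PI * M_PI * M_PI * M_PI * M_PI * M_PI;
    return 2.0 * b * s / c6;
}

// moment-matched shifted-Gamma draw: matches the exact mean, variance and
// skewness of PG(b, c); for large b the matched Gamma tends to a Normal,
// so this covers the whole b >= PG_APPROX range
static double rpg_matched_one(double b, double c)
{
    double m = pg_mean(b, c), v = pg_var(b, c), k3 = pg_kappa3(b, c);
    double skew = k3 / std::pow(v, 1.5);
    double shape = 4.0 / (skew * skew);
    double theta = std::sqrt(v / shape);
    double shift = m - shape * theta;
    double x = shift + R::rgamma(shape, theta);
    return (x > 1e-12) ? x : 1e-12;
}

static double rpg_one(double b, double c)
{
    if (b >= PG_APPROX)
        return rpg_matched_one(b, c);
    double out = 0.0;
    int bi = (int)std::floor(b);
    double frac = b - bi;
    for (int i = 0; i < bi; ++i)
        out += rpg_devroye_one(c);
    if (frac > 1e-12)
        out += rpg_series_one(frac, c);
    return out;
}

// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(int n, NumericVector b, NumericVector c)
{
    NumericVector out(n);
    int nb = b.size(), nc = c.size();
    for (int i = 0; i < n; ++i) {
        double bi = b[i % nb];
        if (!(bi > 0.0) || !std::isfinite(bi))
            stop("Polya-Gamma shape b must be positive and finite");
        out[i] = rpg_one(bi, c[i % nc]);
    }
    return out;
}
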