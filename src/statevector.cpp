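#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Dense statevector kernels. Amplitudes are stored as split real/imaginary
// double arrays so the rotation updates auto-vectorize.
//
// Gate table layout (one row per gate):
//   col 0 kind:   0 RX, 1 RY, 2 RZ, 3 CNOT, 4 CZ
//   col 1 target: 0-based qubit index (bit position in the amplitude index)
//   col 2 control: 0-based qubit index, or -1
//   col 3 angle:  fixed rotation angle (radians), ignored for 2-qubit gates
//   col 4 pslot:  trainable-parameter slot (0-based) or -1; angle = theta[pslot]
//   col 5 dslot:  data-feature index (0-based) or -1; angle = x[dslot]
// pslot and dslot are mutually exclusive; qubit q is the q-th least
// significant bit of the amplitude index.

struct SV {
    std::vector<double> re, im;
    size_t dim = 0;
    void zero_state(size_t d) {
        dim = d;
        re.assign(d, 0.0);
        im.assign(d, 0.0);
        re[0] = 1.0;
    }
};

static inline void apply_rot(SV& s, int kind, int t, double th) {
    const size_t dim = s.dim;
    const size_t step = (size_t)1 << t;
    const double c = std::cos(th / 2.0), sn = std::sin(th / 2.0);
    double* re = s.re.data();
    double* im = s.im.data();
    if (kind == 1) {          // RY: real mixing, re and im independent
        for (size_t i = 0; i < dim; i += 2 * step) {
            for (size_t j = i; j < i + step; ++j) {
                double ar = re[j], br = re[j + step];
                re[j] = c * ar - sn * br;
                re[j + step] = sn * ar + c * br;
                double ai = im[j], bi = im[j + step];
                im[j] = c * ai - sn * bi;
                im[j + step] = sn * ai + c * bi;
            }
        }
    } else if (kind == 0) {   // RX: off-diagonal -i*sin
        for (size_t i = 0; i < dim; i += 2 * step) {
            for (size_t j = i; j < i + step; ++j) {
                double ar = re[j], ai = im[j];
                double br = re[j + step], bi = im[j + step];
                re[j] = c * ar + sn * bi;
                im[j] = c * ai - sn * br;
                re[j + step] = c * br + sn * ai;
                im[j + step] = c * bi - sn * ar;
            }
        }
    } else {                  // RZ: phases exp(-i th/2), exp(+i th/2)
        for (size_t i = 0; i < dim; i += 2 * step) {
            for (size_t j = i; j < i + step; ++j) {
                double ar = re[j], ai = im[j];
                re[j] = c * ar + sn * ai;
                im[j] = c * ai - sn * ar;
                double br = re[j + step], bi = im[j + step];
                re[j + step] = c * br - sn * bi;
                im[j + step] = c * bi + sn * br;
            }
        }
    }
}

static inline void apply_2q(SV& s, int kind, int c, int t) {
    const size_t dim = s.dim;
    const size_t cm = (size_t)1 << c, tm = (size_t)1 << t;
    double* re = s.re.data();
    double* im = s.im.data();
    if (kind == 3) {          // CNOT: swap target pair where control bit set
        for (size_t i = 0; i < dim; ++i) {
            if ((i & cm) && !(i & tm)) {
                std::swap(re[i], re[i | tm]);
                std::swap(im[i], im[i | tm]);
            }
        }
    } else {                  // CZ: phase flip where both bits set
        const size_t both = cm | tm;
        for (size_t i = 0; i < dim; ++i) {
            if ((i & both) == both) {
                re[i] = -re[i];
                im[i] = -im[i];
            }
        }
    }
}

static void run_gates(SV& s, const NumericMatrix& g, int from,
                      const double* theta, const double* x) {
    const int ng = g.nrow();
    for (int k = from; k < ng; ++k) {
        int kind = (int)g(k, 0);
        int t = (int)g(k, 1);
        if (kind >= 3) {
            apply_2q(s, kind, (int)g(k, 2), t);
        } else {
            double th = g(k, 3);
            int ps = (int)g(k, 4), ds = (int)g(k, 5);
            if (ps >= 0) th = theta[ps];
            else if (ds >= 0) th = x[ds];
            apply_rot(s, kind, t, th);
        }
    }
}

// sum over all qubits of <Z_q>, via the per-index weight n - 2*popcount(i)
static double sum_z(const SV& s, const double* wz) {
    double tot = 0.0;
    const double* re = s.re.data();
    const double* im = s.im.data();
    for (size_t i = 0; i < s.dim; ++i)
        tot += (re[i] * re[i] + im[i] * im[i]) * wz[i];
    return tot;
}

static std::vector<double> z_weights(int n) {
    size_t dim = (size_t)1 << n;
    std::vector<double> w(dim);
    for (size_t i = 0; i < dim; ++i) {
        int ones = 0;
        size_t v = i;
        while (v) { ones += (int)(v & 1); v >>= 1; }
        w[i] = n - 2 * ones;
    }
    return w;
}

static void load_init_col(SV& s, const ComplexMatrix& I0, int b, size_t dim) {
    s.dim = dim;
    s.re.resize(dim);
    s.im.resize(dim);
    for (size_t i = 0; i < dim; ++i) {
        s.re[i] = I0(i, b).r;
        s.im[i] = I0(i, b).i;
    }
}

// [[Rcpp::export]]
ComplexVector cpp_run_circuit(int n, NumericMatrix gates, NumericVector theta,
                              NumericVector x, Nullable<ComplexVector> init) {
    size_t dim = (size_t)1 << n;
    SV s;
    if (init.isNotNull()) {
        ComplexVector ini = init.get();
        s.dim = dim;
        s.re.resize(dim);
        s.im.resize(dim);
        for (size_t i = 0; i < dim; ++i) {
            s.re[i] = ini[i].r;
            s.im[i] = ini[i].i;
        }
    } else {
        s.zero_state(dim);
    }
    run_gates(s, gates, 0, theta.begin(), x.begin());
    ComplexVector out(dim);
    for (size_t i = 0; i < dim; ++i) {
        out[i].r = s.re[i];
        out[i].i = s.im[i];
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_expz_all(ComplexVector state, int n) {
    size_t dim = (size_t)1 << n;
    NumericVector out(n);
    for (size_t i = 0; i < dim; ++i) {
        double p = state[i].r * state[i].r + state[i].i * state[i].i;
        for (int q = 0; q < n; ++q)
            out[q] += ((i >> q) & 1) ? -p : p;
    }
    return out;
}

// Batched forward pass: one sum-of-<Z> value per record. Records come either
// from rows of X (feature vectors feeding dslot gates) or from columns of
// `inits` (pre-encoded initial states), or both; B is always nrow(X).
// [[Rcpp::export]]
NumericVector cpp_batch_sumz(int n, NumericMatrix gates, NumericVector theta,
                             NumericMatrix X, Nullable<ComplexMatrix> inits) {
    const int B = X.nrow();
    NumericVector out(B);
    size_t dim = (size_t)1 << n;
    std::vector<double> wz = z_weights(n);
    bool have_init = inits.isNotNull();
    ComplexMatrix I0;
    if (have_init) I0 = inits.get();
    std::vector<double> xrow(std::max(1, (int)X.ncol()));
    SV s;
    for (int b = 0; b < B; ++b) {
        for (int j = 0; j < X.ncol(); ++j) xrow[j] = X(b, j);
        if (have_init) load_init_col(s, I0, b, dim);
        else s.zero_state(dim);
        run_gates(s, gates, 0, theta.begin(), xrow.data());
        out[b] = sum_z(s, wz.data());
    }
    return out;
}

// Parameter-shift gradient of sum_b resid_b * sumZ_b with respect to theta.
// Each trainable slot must appear in exactly one rotation gate (true for the
// RY/CZ ansatz family). d sumZ / d theta_k = [f(th_k + pi/2) - f(th_k - pi/2)]/2.
// The state is advanced gate by gate so each shifted evaluation only re-runs
// the circuit suffix after the shifted rotation.
// [[Rcpp::export]]
NumericVector cpp_batch_grad(int n, NumericMatrix gates, NumericVector theta,
                             NumericMatrix X, Nullable<ComplexMatrix> inits,
                             NumericVector resid) {
    const int B = X.nrow();
    const int P = theta.size();
    const int ng = gates.nrow();
    NumericVector grad(P);
    size_t dim = (size_t)1 << n;
    std::vector<double> wz = z_weights(n);
    bool have_init = inits.isNotNull();
    ComplexMatrix I0;
    if (have_init) I0 = inits.get();
    std::vector<double> xrow(std::max(1, (int)X.ncol()));
    const double half_pi = M_PI / 2.0;
    SV pre, s;

    for (int b = 0; b < B; ++b) {
        if (resid[b] == 0.0) continue;
        for (int j = 0; j < X.ncol(); ++j) xrow[j] = X(b, j);
        if (have_init) load_init_col(pre, I0, b, dim);
        else pre.zero_state(dim);
        for (int k = 0; k < ng; ++k) {
            int kind = (int)gates(k, 0);
            int t = (int)gates(k, 1);
            int ps = kind < 3 ? (int)gates(k, 4) : -1;
            if (ps >= 0) {
                s = pre;
                apply_rot(s, kind, t, theta[ps] + half_pi);
                run_gates(s, gates, k + 1, theta.begin(), xrow.data());
                double fp = sum_z(s, wz.data());
                s = pre;
                apply_rot(s, kind, t, theta[ps] - half_pi);
                run_gates(s, gates, k + 1, theta.begin(), xrow.data());
                double fm = sum_z(s, wz.data());
                grad[ps] += resid[b] * 0.5 * (fp - fm);
            }
            // advance the shared prefix with the unshifted gate
            if (kind >= 3) {
                apply_2q(pre, kind, (int)gates(k, 2), t);
            } else {
                double th = gates(k, 3);
                int ds = (int)gates(k, 5);
                if (ps >= 0) th = theta[ps];
                else if (ds >= 0) th = xrow[ds];
                apply_rot(pre, kind, t, th);
            }
        }
    }
    return grad;
}
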