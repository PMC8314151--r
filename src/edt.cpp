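#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact squared Euclidean distance transform, separable lower-envelope
// algorithm, generalized to non-unit sample spacing d along the axis.
// f holds current squared distances (+Inf where no source reaches yet);
// result written to dout. v/z are scratch of size n and n+1. An
// Inf-vs-Inf intersection is NaN and is treated as +Inf so that sourceless
// parabolas never shadow real ones.
static void edt1d(const double* f, double* dout, int* v, double* z,
                  int n, int stride, double d) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double fq = f[q * stride];
        double xq = q * d;
        double s;
        for (;;) {
            double xv = v[k] * d;
            s = ((fq + xq * xq) - (f[v[k] * stride] + xv * xv)) /
                (2.0 * (xq - xv));
            if (std::isnan(s)) s = INF;
            if (s <= z[k] && k > 0) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * d;
        while (z[k + 1] < xq) ++k;
        double dx = xq - v[k] * d;
        dout[q * stride] = dx * dx + f[v[k] * stride];
    }
}

// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector source, IntegerVector dim,
                       NumericVector spacing) {
    const int m1 = dim[0], m2 = dim[1], m3 = dim[2];
    const R_xlen_t n = (R_xlen_t)m1 * m2 * m3;
    NumericVector out(n);
    const double INF = std::numeric_limits<double>::infinity();
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = source[i] ? 0.0 : INF;

    const int mmax = std::max(m1, std::max(m2, m3));
    std::vector<int> v(mmax);
    std::vector<double> z(mmax + 1), buf(mmax), buf2(mmax);
    double* p = REAL(out);

    // axis 1 (stride 1)
    for (int k3 = 0; k3 < m3; ++k3)
        for (int k2 = 0; k2 < m2; ++k2) {
            double* row = p + (R_xlen_t)m1 * (k2 + (R_xlen_t)m2 * k3);
            for (int q = 0; q < m1; ++q) buf[q] = row[q];
            edt1d(buf.data(), row, v.data(), z.data(), m1, 1, spacing[0]);
        }
    // axis 2 (stride m1)
    for (int k3 = 0; k3 < m3; ++k3)
        for (int k1 = 0; k1 < m1; ++k1) {
            double* col = p + k1 + (R_xlen_t)m1 * m2 * k3;
            for (int q = 0; q < m2; ++q) buf[q] = col[(R_xlen_t)q * m1];
            edt1d(buf.data(), buf2.data(), v.data(), z.data(), m2, 1, spacing[1]);
            for (int q = 0; q < m2; ++q) col[(R_xlen_t)q * m1] = buf2[q];
        }
    // axis 3 (stride m1*m2)
    const R_xlen_t s3 = (R_xlen_t)m1 * m2;
    for (int k2 = 0; k2 < m2; ++k2)
        for (int k1 = 0; k1 < m1; ++k1) {
            double* col = p + k1 + (R_xlen_t)m1 * k2;
            for (int q = 0; q < m3; ++q) buf[q] = col[q * s3];
            edt1d(buf.data(), buf2.data(), v.data(), z.data(), m3, 1, spacing[2]);
            for (int q = 0; q < m3; ++q) col[q * s3] = buf2[q];
        }
    return out;
}

// Constellation codes on the half-shifted raster. Raster point (i,j,k)
// (0-based, dims n+1) neighbors voxels (i-1+di, j-1+dj, k-1+dk) for
// di,dj,dk in {0,1}; out-of-volume voxels are background. Bit index of a
// neighbor is di + 2*dj + 4*dk.
// [[Rcpp::export(name = ".surface_codes")]]
IntegerVector surface_codes(LogicalVector mask, IntegerVector dim) {
    const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
    const int m1 = n1 + 1, m2 = n2 + 1, m3 = n3 + 1;
    IntegerVector out((R_xlen_t)m1 * m2 * m3);
    const int* mk = LOGICAL(mask);
    int* o = INTEGER(out);
    for (int k = 0; k < m3; ++k)
        for (int j = 0; j < m2; ++j)
            for (int i = 0; i < m1; ++i) {
                int code = 0;
                for (int dk = 0; dk < 2; ++dk) {
                    int vk = k - 1 + dk;
                    if (vk < 0 || vk >= n3) continue;
                    for (int dj = 0; dj < 2; ++dj) {
                        int vj = j - 1 + dj;
                        if (vj < 0 || vj >= n2) continue;
                        for (int di = 0; di < 2; ++di) {
                            int vi = i - 1 + di;
                            if (vi < 0 || vi >= n1) continue;
                            if (mk[vi + (R_xlen_t)n1 * (vj + (R_xlen_t)n2 * vk)])
                                code |= 1 << (di + 2 * dj + 4 * dk);
                        }
                    }
                }
                o[i + (R_xlen_t)m1 * (j + (R_xlen_t)m2 * k)] = code;
            }
    return out;
}
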