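#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grayscale erosion with a non-flat structuring element given as offset
// triples (dy, dx, height). Pixels whose offset falls outside the image are
// ignored (min over the available support), the convention also used by the
// pure-R oracle in the test suite.
// [[Rcpp::export(name = ".gray_erode_cpp")]]
NumericMatrix gray_erode_cpp(NumericMatrix img, IntegerVector dy,
                             IntegerVector dx, NumericVector h) {
    int nr = img.nrow(), nc = img.ncol(), k = dy.size();
    NumericMatrix out(nr, nc);
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            double m = R_PosInf;
            for (int o = 0; o < k; ++o) {
                int ii = i + dy[o], jj = j + dx[o];
                if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
                double v = img(ii, jj) - h[o];
                if (v < m) m = v;
            }
            out(i, j) = m;
        }
    }
    return out;
}

// [[Rcpp::export(name = ".gray_dilate_cpp")]]
NumericMatrix gray_dilate_cpp(NumericMatrix img, IntegerVector dy,
                              IntegerVector dx, NumericVector h) {
    int nr = img.nrow(), nc = img.ncol(), k = dy.size();
    NumericMatrix out(nr, nc);
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            double m = R_NegInf;
            for (int o = 0; o < k; ++o) {
                // reflected structuring element; the ball is symmetric
                int ii = i - dy[o], jj = j - dx[o];
                if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
                double v = img(ii, jj) + h[o];
                if (v > m) m = v;
            }
            out(i, j) = m;
        }
    }
    return out;
}

// Separable Gaussian blur with replicated (clamped) edges.
// [[Rcpp::export(name = ".gauss_blur_cpp")]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
    int nr = img.nrow(), nc = img.ncol();
    if (sigma <= 0) return clone(img);
    int rad = (int)std::ceil(3.5 * sigma);
    std::vector<double> ker(2 * rad + 1);
    double s = 0.0;
    for (int t = -rad; t <= rad; ++t) {
        ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
        s += ker[t + rad];
    }
    for (int t = 0; t < 2 * rad + 1; ++t) ker[t] /= s;

    NumericMatrix tmp(nr, nc), out(nr, nc);
    for (int j = 0; j < nc; ++j) {          // vertical pass
        for (int i = 0; i < nr; ++i) {
            double acc = 0.0;
            for (int t = -rad; t <= rad; ++t) {
                int ii = i + t;
                if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
                acc += ker[t + rad] * img(ii, j);
            }
            tmp(i, j) = acc;
        }
    }
    for (int j = 0; j < nc; ++j) {          // horizontal pass
        for (int i = 0; i < nr; ++i) {
            double acc = 0.0;
            for (int t = -rad; t <= rad; ++t) {
                int jj = j + t;
                if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
                acc += ker[t + rad] * tmp(i, jj);
            }
            out(i, j) = acc;
        }
    }
    return out;
}

// Connected-component labeling (4- or 8-connectivity) by breadth-first
// search. Returns an integer label matrix, labels in column-major discovery
// order starting at 1.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> qi, qj;
    int cur = 0;
    const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
    const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
    int nn = (connectivity == 8) ? 8 : 4;
    for (int j0 = 0; j0 < nc; ++j0) {
        for (int i0 = 0; i0 < nr; ++i0) {
            if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
            ++cur;
            qi.clear(); qj.clear();
            qi.push_back(i0); qj.push_back(j0);
            lab(i0, j0) = cur;
            size_t head = 0;
            while (head < qi.size()) {
                int i = qi[head], j = qj[head]; ++head;
                for (int k = 0; k < nn; ++k) {
                    int ii = i + dy8[k], jj = j + dx8[k];
                    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
                    if (mask(ii, jj) && lab(ii, jj) == 0) {
                        lab(ii, jj) = cur;
                        qi.push_back(ii); qj.push_back(jj);
                    }
                }
            }
        }
    }
    return lab;
}

// Fill interior holes of a binary mask: background connected (4-conn) to
// the image border stays background, enclosed background becomes foreground.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalMatrix fill_holes_cpp(LogicalMatrix mask) {
    int nr = mask.nrow(), nc = mask.ncol();
    LogicalMatrix outside(nr, nc);
    std::vector<int> qi, qj;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            bool border = (i == 0 || i == nr - 1 || j == 0 || j == nc - 1);
            if (border && !mask(i, j) && !outside(i, j)) {
                outside(i, j) = true;
                qi.push_back(i); qj.push_back(j);
            }
        }
    }
    const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
    size_t head = 0;
    while (head < qi.size()) {
        int i = qi[head], j = qj[head]; ++head;
        for (int k = 0; k < 4; ++k) {
            int ii = i + dy[k], jj = j + dx[k];
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (!mask(ii, jj) && !outside(ii, jj)) {
                outside(ii, jj) = true;
                qi.push_back(ii); qj.push_back(jj);
            }
        }
    }
    LogicalMatrix out(nr, nc);
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i)
            out(i, j) = mask(i, j) || !outside(i, j);
    return out;
}
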