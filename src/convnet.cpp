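// Compute kernels for the fully convolutional tissue segmenter and the raster
// primitives that back annotation rasterization and mask post-processing.
//
// Layer activations are kept channel-major (C x H*W) so that im2col reduces
// every convolution to a single sgemm. All padding is zero "same" padding;
// pooling is 2x2/2 max with stored argmax for the backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// Fixed architecture: seven convolutions, max pool after the first three.
static const int N_LAYERS = 7;
static const int KS[N_LAYERS]   = {5, 5, 3, 3, 3, 1, 1};
static const int CIN[N_LAYERS]  = {3, 16, 32, 64, 64, 1024, 512};
static const int COUT[N_LAYERS] = {16, 32, 64, 64, 1024, 512, 2};
static const bool POOL_AFTER[N_LAYERS] = {true, true, true, false, false, false, false};

// im2col for stride-1 same-padded convolution.
// X: C x (H*W), channel-major, column index = h + H*w.
// cols: (C*k*k) x (H*W), row index = c + C*(ky + k*kx).
static void im2col_same(const fmat& X, int H, int W, int C, int k, fmat& cols) {
    const int p = k / 2;
    cols.zeros();
    for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
            const int r0 = C * (ky + k * kx);
            const int dy = ky - p, dx = kx - p;
            for (int w = 0; w < W; ++w) {
                const int sw = w + dx;
                if (sw < 0 || sw >= W) continue;
                const int h0 = std::max(0, -dy);
                const int h1 = std::min(H, H - dy);
                if (h0 >= h1) continue;
                cols.submat(r0, h0 + H * w, r0 + C - 1, h1 - 1 + H * w) =
                    X.cols(h0 + dy + H * sw, h1 - 1 + dy + H * sw);
            }
        }
    }
}

// Adjoint of im2col_same: scatter-add column gradients back onto the input.
static void col2im_same(const fmat& cols, int H, int W, int C, int k, fmat& dX) {
    const int p = k / 2;
    dX.zeros(C, H * W);
    for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
            const int r0 = C * (ky + k * kx);
            const int dy = ky - p, dx = kx - p;
            for (int w = 0; w < W; ++w) {
                const int sw = w + dx;
                if (sw < 0 || sw >= W) continue;
                const int h0 = std::max(0, -dy);
                const int h1 = std::min(H, H - dy);
                if (h0 >= h1) continue;
                dX.cols(h0 + dy + H * sw, h1 - 1 + dy + H * sw) +=
                    cols.submat(r0, h0 + H * w, r0 + C - 1, h1 - 1 + H * w);
            }
        }
    }
}

// 2x2/2 max pooling, channel-major. argmax stores the source column index of
// the winning pixel for each (channel, output position); ties go to the
// first candidate in scan order so the pass is deterministic.
static void maxpool_fwd(const fmat& X, int H, int W, fmat& out, umat& amax) {
    const int C = X.n_rows, Ho = H / 2, Wo = W / 2;
    out.set_size(C, Ho * Wo);
    amax.set_size(C, Ho * Wo);
    for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
            const int oc = i + Ho * j;
            const int s[4] = {2 * i + H * 2 * j, 2 * i + 1 + H * 2 * j,
                              2 * i + H * (2 * j + 1), 2 * i + 1 + H * (2 * j + 1)};
            for (int c = 0; c < C; ++c) {
                float best = X(c, s[0]);
                int bi = 0;
                for (int q = 1; q < 4; ++q) {
                    if (X(c, s[q]) > best) { best = X(c, s[q]); bi = q; }
                }
                out(c, oc) = best;
                amax(c, oc) = s[bi];
            }
        }
    }
}

static void maxpool_bwd(const fmat& dOut, const umat& amax, int H, int W, fmat& dX) {
    const int C = dOut.n_rows;
    dX.zeros(C, H * W);
    for (uword oc = 0; oc < dOut.n_cols; ++oc)
        for (int c = 0; c < C; ++c)
            dX(c, amax(c, oc)) += dOut(c, oc);
}

static void extract_params(const List& W, const List& b,
                           std::vector<fmat>& Wf, std::vector<fvec>& bf) {
    Wf.resize(N_LAYERS);
    bf.resize(N_LAYERS);
    for (int l = 0; l < N_LAYERS; ++l) {
        NumericMatrix wm = W[l];
        NumericVector bv = b[l];
        const int K = CIN[l] * KS[l] * KS[l];
        if (wm.nrow() != COUT[l] || wm.ncol() != K)
            stop("layer %d weight matrix must be %d x %d", l + 1, COUT[l], K);
        if (bv.size() != COUT[l])
            stop("layer %d bias must have length %d", l + 1, COUT[l]);
        Wf[l] = conv_to<fmat>::from(mat(wm.begin(), wm.nrow(), wm.ncol(), false));
        bf[l] = conv_to<fvec>::from(vec(bv.begin(), bv.size(), false));
    }
}

// Convert one sample of an (H, W, 3, N) double array to channel-major floats.
static fmat sample_to_cmajor(const double* x, int H, int W, int n) {
    fmat X(3, H * W);
    const R_xlen_t plane = (R_xlen_t)H * W;
    const double* base = x + 3 * plane * n;
    for (int c = 0; c < 3; ++c) {
        const double* src = base + c * plane;
        for (R_xlen_t p = 0; p < plane; ++p) X(c, p) = (float)src[p];
    }
    return X;
}

struct ForwardCache {
    std::vector<fmat> act;    // input of each layer (act[0] = image), length 8
    std::vector<fmat> cols;   // im2col matrices for k>1 layers
    std::vector<fmat> pooled; // pre-pool activations kept implicitly via dims
    std::vector<umat> amax;   // pool argmax per pooling stage
    std::vector<int> Hs, Ws;  // spatial dims at the input of each layer
};

// Forward pass for one sample. Returns softmax probabilities (2 x Ho*Wo).
static fmat forward_one(const fmat& img, int H, int W,
                        const std::vector<fmat>& Wf, const std::vector<fvec>& bf,
                        ForwardCache* cache) {
    fmat X = img;
    int h = H, w = W;
    if (cache) {
        cache->act.assign(N_LAYERS + 1, fmat());
        cache->cols.assign(N_LAYERS, fmat());
        cache->amax.assign(N_LAYERS, umat());
        cache->Hs.assign(N_LAYERS + 1, 0);
        cache->Ws.assign(N_LAYERS + 1, 0);
    }
    for (int l = 0; l < N_LAYERS; ++l) {
        if (cache) { cache->act[l] = X; cache->Hs[l] = h; cache->Ws[l] = w; }
        fmat Z;
        if (KS[l] == 1) {
            Z = Wf[l] * X;
        } else {
            fmat cols(CIN[l] * KS[l] * KS[l], h * w);
            im2col_same(X, h, w, CIN[l], KS[l], cols);
            Z = Wf[l] * cols;
            if (cache) cache->cols[l] = std::move(cols);
        }
        Z.each_col() += bf[l];
        if (l < N_LAYERS - 1) {
            Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
        }
        if (POOL_AFTER[l]) {
            fmat P;
            umat am;
            maxpool_fwd(Z, h, w, P, am);
            if (cache) cache->amax[l] = std::move(am);
            X = std::move(P);
            h /= 2;
            w /= 2;
        } else {
            X = std::move(Z);
        }
    }
    if (cache) { cache->act[N_LAYERS] = X; cache->Hs[N_LAYERS] = h; cache->Ws[N_LAYERS] = w; }
    // softmax over the two channels
    fmat P(2, X.n_cols);
    for (uword j = 0; j < X.n_cols; ++j) {
        const float m = std::max(X(0, j), X(1, j));
        const float e0 = std::exp(X(0, j) - m), e1 = std::exp(X(1, j) - m);
        const float s = e0 + e1;
        P(0, j) = e0 / s;
        P(1, j) = e1 / s;
    }
    return P;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_fcnn_forward")]]
NumericVector cpp_fcnn_forward(NumericVector x, List W, List b) {
    IntegerVector dims = x.attr("dim");
    if (dims.size() != 4 || dims[2] != 3) stop("input must be an (H, W, 3, N) array");
    const int H = dims[0], Wd = dims[1], N = dims[3];
    if (H % 8 != 0 || Wd % 8 != 0) stop("input sides must be multiples of 8");
    std::vector<fmat> Wf;
    std::vector<fvec> bf;
    extract_params(W, b, Wf, bf);
    const int Ho = H / 8, Wo = Wd / 8;
    NumericVector out((R_xlen_t)Ho * Wo * 2 * N);
    out.attr("dim") = IntegerVector::create(Ho, Wo, 2, N);
    for (int n = 0; n < N; ++n) {
        fmat img = sample_to_cmajor(x.begin(), H, Wd, n);
        fmat P = forward_one(img, H, Wd, Wf, bf, nullptr);
        double* o = out.begin() + (R_xlen_t)2 * Ho * Wo * n;
        for (int j = 0; j < Ho * Wo; ++j) {
            o[j] = P(0, j);              // channel 1: non-tissue
            o[j + (R_xlen_t)Ho * Wo] = P(1, j); // channel 2: tissue
        }
    }
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_fcnn_train_step")]]
List cpp_fcnn_train_step(NumericVector x, IntegerVector y, List W, List b) {
    IntegerVector dims = x.attr("dim");
    if (dims.size() != 4 || dims[2] != 3) stop("input must be an (H, W, 3, N) array");
    const int H = dims[0], Wd = dims[1], N = dims[3];
    if (H % 8 != 0 || Wd % 8 != 0) stop("input sides must be multiples of 8");
    const int Ho = H / 8, Wo = Wd / 8;
    IntegerVector ydims = y.attr("dim");
    if (ydims.size() != 3 || ydims[0] != Ho || ydims[1] != Wo || ydims[2] != N)
        stop("target array must be (H/8, W/8, N)");
    std::vector<fmat> Wf;
    std::vector<fvec> bf;
    extract_params(W, b, Wf, bf);

    std::vector<fmat> gW(N_LAYERS);
    std::vector<fvec> gb(N_LAYERS);
    for (int l = 0; l < N_LAYERS; ++l) {
        gW[l].zeros(Wf[l].n_rows, Wf[l].n_cols);
        gb[l].zeros(bf[l].n_elem);
    }
    double loss = 0.0;
    long correct = 0;
    const double total = (double)Ho * Wo * N;

    for (int n = 0; n < N; ++n) {
        fmat img = sample_to_cmajor(x.begin(), H, Wd, n);
        ForwardCache cache;
        fmat P = forward_one(img, H, Wd, Wf, bf, &cache);
        const int* yt = y.begin() + (R_xlen_t)Ho * Wo * n;
        fmat dZ(2, Ho * Wo);
        for (int j = 0; j < Ho * Wo; ++j) {
            const int t = yt[j]; // 0 = non-tissue, 1 = tissue
            const double pt = std::max((double)P(t, j), 1e-12);
            loss -= std::log(pt) / total;
            if ((P(1, j) > P(0, j) ? 1 : 0) == t) ++correct;
            dZ(0, j) = (P(0, j) - (t == 0 ? 1.0f : 0.0f)) / (float)total;
            dZ(1, j) = (P(1, j) - (t == 1 ? 1.0f : 0.0f)) / (float)total;
        }
        // backward
        fmat d = std::move(dZ);
        for (int l = N_LAYERS - 1; l >= 0; --l) {
            const int h = cache.Hs[l], w = cache.Ws[l];
            if (POOL_AFTER[l]) {
                fmat dpre;
                maxpool_bwd(d, cache.amax[l], h, w, dpre);
                d = std::move(dpre);
            }
            if (l < N_LAYERS - 1) {
                // ReLU gate, using max(Z, 0) which is what the cache holds.
                if (POOL_AFTER[l]) {
                    // The pre-pool activation is not cached, but maxpool_bwd
                    // routed gradient only to argmax positions whose value
                    // equals the pooled output, so gate on positivity there.
                    const fmat& pooled = cache.act[l + 1];
                    const umat& am = cache.amax[l];
                    for (uword oc = 0; oc < am.n_cols; ++oc)
                        for (uword c = 0; c < am.n_rows; ++c)
                            if (pooled(c, oc) <= 0.0f) d(c, am(c, oc)) = 0.0f;
                } else {
                    d %= conv_to<fmat>::from(cache.act[l + 1] > 0.0f);
                }
            }
            gb[l] += sum(d, 1);
            if (KS[l] == 1) {
                gW[l] += d * cache.act[l].t();
                if (l > 0) d = Wf[l].t() * d;
            } else {
                gW[l] += d * cache.cols[l].t();
                if (l > 0) {
                    fmat dcols = Wf[l].t() * d;
                    fmat dX;
                    col2im_same(dcols, h, w, CIN[l], KS[l], dX);
                    d = std::move(dX);
                }
            }
        }
    }

    List gWl(N_LAYERS), gbl(N_LAYERS);
    for (int l = 0; l < N_LAYERS; ++l) {
        gWl[l] = wrap(conv_to<mat>::from(gW[l]));
        gbl[l] = wrap(conv_to<vec>::from(gb[l]));
    }
    return List::create(_["loss"] = loss,
                        _["accuracy"] = correct / total,
                        _["grad_w"] = gWl,
                        _["grad_b"] = gbl);
}

// ---------------------------------------------------------------------------
// Connected-component labeling (4- or 8-connectivity), flood fill based.
//' @noRd
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
    if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
    const int H = mask.nrow(), W = mask.ncol();
    IntegerMatrix lab(H, W);
    std::vector<int> stack;
    int next = 0;
    const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
    const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
    const int nn = (connectivity == 8) ? 8 : 4;
    for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
            if (mask(i, j) == 0 || lab(i, j) != 0) continue;
            ++next;
            stack.push_back(i + H * j);
            lab(i, j) = next;
            while (!stack.empty()) {
                const int p = stack.back();
                stack.pop_back();
                const int pi = p % H, pj = p / H;
                for (int q = 0; q < nn; ++q) {
                    const int ni = pi + dy8[q], nj = pj + dx8[q];
                    if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
                    if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
                        lab(ni, nj) = next;
                        stack.push_back(ni + H * nj);
                    }
                }
            }
        }
    }
    return lab;
}

// ---------------------------------------------------------------------------
// Even-odd scanline polygon fill on pixel centers, restricted to the polygon
// bounding box. Coordinates are 0-based (x = column, y = row); a pixel (r, c)
// is inside when its center (c + 0.5, r + 0.5) is inside the polygon.
//' @noRd
// [[Rcpp::export(name = ".cpp_fill_polygon")]]
List cpp_fill_polygon(NumericVector xs, NumericVector ys, int H, int W) {
    const int n = xs.size();
    if (n < 3) stop("polygon needs at least 3 vertices");
    double xmin = xs[0], xmax = xs[0], ymin = ys[0], ymax = ys[0];
    for (int i = 1; i < n; ++i) {
        xmin = std::min(xmin, xs[i]); xmax = std::max(xmax, xs[i]);
        ymin = std::min(ymin, ys[i]); ymax = std::max(ymax, ys[i]);
    }
    int r0 = std::max(0, (int)std::floor(ymin - 0.5));
    int r1 = std::min(H - 1, (int)std::ceil(ymax));
    int c0 = std::max(0, (int)std::floor(xmin - 0.5));
    int c1 = std::min(W - 1, (int)std::ceil(xmax));
    if (r1 < r0 || c1 < c0) {
        return List::create(_["row0"] = 0, _["col0"] = 0,
                            _["mask"] = LogicalMatrix(0, 0),
                            _["clipped"] = (H > 0 && W > 0));
    }
    // one pixel of slack: polygons that merely touch the outer border are
    // not reported as clipped
    const bool clipped = (ymin < -1.5 || xmin < -1.5 ||
                          ymax > H + 0.5 || xmax > W + 0.5);
    LogicalMatrix m(r1 - r0 + 1, c1 - c0 + 1);
    std::vector<double> cross;
    for (int r = r0; r <= r1; ++r) {
        const double py = r + 0.5;
        cross.clear();
        for (int i = 0; i < n; ++i) {
            const int k = (i + 1) % n;
            const double y1 = ys[i], y2 = ys[k];
            if ((y1 > py) == (y2 > py)) continue;
            const double xc = xs[i] + (py - y1) * (xs[k] - xs[i]) / (y2 - y1);
            cross.push_back(xc);
        }
        std::sort(cross.begin(), cross.end());
        for (size_t q = 0; q + 1 < cross.size(); q += 2) {
            int ca = std::max(c0, (int)std::ceil(cross[q] - 0.5));
            int cb = std::min(c1, (int)std::floor(cross[q + 1] - 0.5 - 1e-12));
            // pixel center c + 0.5 in (cross[q], cross[q+1])
            for (int c = ca; c <= cb; ++c) {
                if (c + 0.5 > cross[q] && c + 0.5 < cross[q + 1])
                    m(r - r0, c - c0) = true;
            }
        }
    }
    return List::create(_["row0"] = r0, _["col0"] = c0, _["mask"] = m,
                        _["clipped"] = clipped);
}

// ---------------------------------------------------------------------------
// Moore-neighbour boundary tracing of every 8-connected foreground component.
// Returns one (x, y) vertex matrix per component, vertices at boundary pixel
// centers in 0-based coordinates.
//' @noRd
// [[Rcpp::export(name = ".cpp_trace_boundaries")]]
List cpp_trace_boundaries(IntegerMatrix mask) {
    const int H = mask.nrow(), W = mask.ncol();
    IntegerMatrix lab = cpp_label_components(mask, 8);
    int ncomp = 0;
    for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) ncomp = std::max(ncomp, lab(i, j));
    // first pixel of each component in scan order (column-major scan)
    std::vector<int> si(ncomp, -1), sj(ncomp, -1);
    for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
            const int l = lab(i, j);
            if (l > 0 && si[l - 1] < 0) { si[l - 1] = i; sj[l - 1] = j; }
        }
    // clockwise Moore neighbourhood starting at west, for (row, col) grid with
    // row increasing downward: W, NW, N, NE, E, SE, S, SW
    const int dy[8] = {0, -1, -1, -1, 0, 1, 1, 1};
    const int dx[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
    List out(ncomp);
    for (int c = 0; c < ncomp; ++c) {
        std::vector<double> vx, vy;
        const int bi = si[c], bj = sj[c];
        // single isolated pixel?
        bool lone = true;
        for (int q = 0; q < 8; ++q) {
            const int ni = bi + dy[q], nj = bj + dx[q];
            if (ni >= 0 && ni < H && nj >= 0 && nj < W && lab(ni, nj) == c + 1) {
                lone = false;
                break;
            }
        }
        if (lone) {
            NumericMatrix poly(4, 2);
            poly(0, 0) = bj - 0.5; poly(0, 1) = bi - 0.5;
            poly(1, 0) = bj + 0.5; poly(1, 1) = bi - 0.5;
            poly(2, 0) = bj + 0.5; poly(2, 1) = bi + 0.5;
            poly(3, 0) = bj - 0.5; poly(3, 1) = bi + 0.5;
            out[c] = poly;
            continue;
        }
        int ci = bi, cj = bj;
        int back = 0; // direction of the backtrack neighbour (start: west)
        vx.push_back(cj); vy.push_back(ci);
        int guard = 8 * H * W;
        while (guard-- > 0) {
            int found = -1;
            for (int q = 1; q <= 8; ++q) {
                const int dir = (back + q) % 8;
                const int ni = ci + dy[dir], nj = cj + dx[dir];
                if (ni >= 0 && ni < H && nj >= 0 && nj < W && lab(ni, nj) == c + 1) {
                    found = dir;
                    break;
                }
            }
            if (found < 0) break; // cannot happen for non-lone pixels
            const int pi = ci, pj = cj;
            ci += dy[found];
            cj += dx[found];
            // new backtrack: direction from the new pixel to the previous one,
            // advanced by one clockwise step so the search resumes just past it
            int rev = -1;
            for (int q = 0; q < 8; ++q)
                if (ci + dy[q] == pi && cj + dx[q] == pj) { rev = q; break; }
            back = rev;
            if (ci == bi && cj == bj) break;
            vx.push_back(cj);
            vy.push_back(ci);
        }
        NumericMatrix poly(vx.size(), 2);
        for (size_t q = 0; q < vx.size(); ++q) {
            poly(q, 0) = vx[q];
            poly(q, 1) = vy[q];
        }
        out[c] = poly;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Bilinear upsampling of a coarse probability grid by an integer factor.
// Grid cell (i, j) is taken to sit at fine coordinates (f*i + (f-1)/2,
// f*j + (f-1)/2); borders are clamped.
//' @noRd
// [[Rcpp::export(name = ".cpp_upsample_bilinear")]]
NumericMatrix cpp_upsample_bilinear(NumericMatrix g, int f, int H, int W) {
    const int gh = g.nrow(), gw = g.ncol();
    const double off = (f - 1) / 2.0;
    NumericMatrix out(H, W);
    std::vector<int> i0(H), i1(H);
    std::vector<double> wi(H);
    for (int r = 0; r < H; ++r) {
        double p = (r - off) / f;
        p = std::min(std::max(p, 0.0), gh - 1.0);
        i0[r] = (int)std::floor(p);
        i1[r] = std::min(i0[r] + 1, gh - 1);
        wi[r] = p - i0[r];
    }
    for (int cc = 0; cc < W; ++cc) {
        double p = (cc - off) / f;
        p = std::min(std::max(p, 0.0), gw - 1.0);
        const int j0 = (int)std::floor(p);
        const int j1 = std::min(j0 + 1, gw - 1);
        const double wj = p - j0;
        for (int r = 0; r < H; ++r) {
            const double a = g(i0[r], j0) * (1 - wi[r]) + g(i1[r], j0) * wi[r];
            const double b2 = g(i0[r], j1) * (1 - wi[r]) + g(i1[r], j1) * wi[r];
            out(r, cc) = a * (1 - wj) + b2 * wj;
        }
    }
    return out;
}
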