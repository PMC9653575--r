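// Compact CPU implementation of a 2D dilated residual U-Net for multi-organ
// CT segmentation: 5 encoder and 5 decoder residual cascades (two 3x3 convs
// per block, batch norm, identity/1x1 shortcut), max-pool downsampling,
// bilinear upsampling, encoder-decoder skip connections, softmax output,
// combined cross-entropy + soft-Dice loss, Adam with weight decay.
// All randomness is drawn from R's RNG so training is reproducible under
// set.seed(); the model lives behind an external pointer for the session.
#include <RcppArmadillo.h>
#include <memory>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static const double BN_EPS = 1e-5;

// ---------- layers ----------

struct Adam {
  mat mW, vW;
  vec mb, vb;
  long t = 0;
};

struct Conv {
  int in = 0, out = 0, k = 3, dil = 1;
  mat W;   // out x (in*k*k)
  vec b;   // out
  mat dW;
  vec db;
  Adam opt;
  mat cols;      // cache: (in*k*k) x (H*W)
  int cH = 0, cW = 0;

  void init() {
    const int fan_in = in * k * k;
    const double sd = std::sqrt(2.0 / fan_in);
    W.set_size(out, fan_in);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = R::norm_rand() * sd;
    b.zeros(out);
    dW.zeros(out, fan_in);
    db.zeros(out);
    opt.mW.zeros(out, fan_in); opt.vW.zeros(out, fan_in);
    opt.mb.zeros(out); opt.vb.zeros(out);
    opt.t = 0;
  }

  mat im2col(const cube& x) const {
    const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
    const int kk = k * k, half = k / 2;
    mat M(C * kk, (size_t)H * Wd, arma::fill::zeros);
    for (int ch = 0; ch < C; ++ch) {
      const mat& xs = x.slice(ch);
      for (int ki = 0; ki < k; ++ki) {
        for (int kj = 0; kj < k; ++kj) {
          const int dr = (ki - half) * dil, dc = (kj - half) * dil;
          const int row = ch * kk + ki * k + kj;
          for (int c = 0; c < Wd; ++c) {
            const int sc = c + dc;
            if (sc < 0 || sc >= Wd) continue;
            const int rlo = std::max(0, -dr), rhi = std::min(H, H - dr);
            for (int r = rlo; r < rhi; ++r)
              M(row, (size_t)r + (size_t)c * H) = xs(r + dr, sc);
          }
        }
      }
    }
    return M;
  }

  void col2im(const mat& dcols, cube& dx) const {
    const int H = dx.n_rows, Wd = dx.n_cols, C = dx.n_slices;
    const int kk = k * k, half = k / 2;
    for (int ch = 0; ch < C; ++ch) {
      mat& xs = dx.slice(ch);
      for (int ki = 0; ki < k; ++ki) {
        for (int kj = 0; kj < k; ++kj) {
          const int dr = (ki - half) * dil, dc = (kj - half) * dil;
          const int row = ch * kk + ki * k + kj;
          for (int c = 0; c < Wd; ++c) {
            const int sc = c + dc;
            if (sc < 0 || sc >= Wd) continue;
            const int rlo = std::max(0, -dr), rhi = std::min(H, H - dr);
            for (int r = rlo; r < rhi; ++r)
              xs(r + dr, sc) += dcols(row, (size_t)r + (size_t)c * H);
          }
        }
      }
    }
  }

  cube forward(const cube& x) {
    const int H = x.n_rows, Wd = x.n_cols;
    cols = im2col(x);
    cH = H; cW = Wd;
    mat o = W * cols;
    o.each_col() += b;
    cube y(H, Wd, out);
    for (int ch = 0; ch < out; ++ch)
      y.slice(ch) = arma::reshape(o.row(ch), H, Wd);
    return y;
  }

  cube backward(const cube& dy) {
    const int H = dy.n_rows, Wd = dy.n_cols;
    mat dym(out, (size_t)H * Wd);
    for (int ch = 0; ch < out; ++ch)
      dym.row(ch) = arma::vectorise(dy.slice(ch)).t();
    dW += dym * cols.t();
    db += arma::sum(dym, 1);
    mat dcols = W.t() * dym;
    cube dx(H, Wd, in, arma::fill::zeros);
    col2im(dcols, dx);
    cols.reset();
    return dx;
  }

  void step(double lr, double wd, bool train_this) {
    if (!train_this) { dW.zeros(); db.zeros(); return; }
    opt.t += 1;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    mat g = dW + wd * W;
    opt.mW = b1 * opt.mW + (1 - b1) * g;
    opt.vW = b2 * opt.vW + (1 - b2) * arma::square(g);
    const double c1 = 1.0 - std::pow(b1, (double)opt.t);
    const double c2 = 1.0 - std::pow(b2, (double)opt.t);
    W -= lr * (opt.mW / c1) / (arma::sqrt(opt.vW / c2) + eps);
    vec gb = db;  // no decay on bias
    opt.mb = b1 * opt.mb + (1 - b1) * gb;
    opt.vb = b2 * opt.vb + (1 - b2) * arma::square(gb);
    b -= lr * (opt.mb / c1) / (arma::sqrt(opt.vb / c2) + eps);
    dW.zeros(); db.zeros();
  }
};

struct BatchNorm {
  int ch = 0;
  double momentum = 0.1;
  vec g, beta, rmean, rvar;
  vec dg, dbeta;
  Adam opt;
  cube xhat;
  vec invstd;

  void init(int c) {
    ch = c;
    g.ones(c); beta.zeros(c);
    rmean.zeros(c); rvar.ones(c);
    dg.zeros(c); dbeta.zeros(c);
    opt.mW.zeros(c, 1); opt.vW.zeros(c, 1);
    opt.mb.zeros(c); opt.vb.zeros(c);
    opt.t = 0;
  }

  // The batch is a single slice, so normalization always uses the current
  // input's per-channel statistics (instance normalization); running
  // estimates cannot summarize both air-only and organ-bearing slices and
  // are kept only as optimizer-free diagnostics. `training` controls
  // whether the caches needed for backward are filled.
  cube forward(const cube& x, bool training) {
    cube y(x.n_rows, x.n_cols, ch);
    if (training) {
      xhat.set_size(x.n_rows, x.n_cols, ch);
      invstd.set_size(ch);
    }
    for (int c = 0; c < ch; ++c) {
      const mat& xs = x.slice(c);
      const double mu = arma::accu(xs) / xs.n_elem;
      const double v = arma::accu(arma::square(xs - mu)) / xs.n_elem;
      const double inv = 1.0 / std::sqrt(v + BN_EPS);
      if (training) {
        invstd(c) = inv;
        xhat.slice(c) = (xs - mu) * inv;
        y.slice(c) = g(c) * xhat.slice(c) + beta(c);
        rmean(c) = (1 - momentum) * rmean(c) + momentum * mu;
        rvar(c) = (1 - momentum) * rvar(c) + momentum * v;
      } else {
        y.slice(c) = g(c) * ((xs - mu) * inv) + beta(c);
      }
    }
    return y;
  }

  cube backward(const cube& dy) {
    cube dx(dy.n_rows, dy.n_cols, ch);
    const double N = (double)dy.n_rows * dy.n_cols;
    for (int c = 0; c < ch; ++c) {
      const mat& dys = dy.slice(c);
      const mat& xh = xhat.slice(c);
      const double sdy = arma::accu(dys);
      const double sdyx = arma::accu(dys % xh);
      dg(c) += sdyx;
      dbeta(c) += sdy;
      dx.slice(c) = (g(c) * invstd(c) / N) * (N * dys - sdy - xh * sdyx);
    }
    xhat.reset();
    return dx;
  }

  void step(double lr, double wd, bool train_this) {
    if (!train_this) { dg.zeros(); dbeta.zeros(); return; }
    (void)wd;  // no decay on BN params
    opt.t += 1;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    const double c1 = 1.0 - std::pow(b1, (double)opt.t);
    const double c2 = 1.0 - std::pow(b2, (double)opt.t);
    vec gv = dg;
    opt.mW.col(0) = b1 * opt.mW.col(0) + (1 - b1) * gv;
    opt.vW.col(0) = b2 * opt.vW.col(0) + (1 - b2) * arma::square(gv);
    g -= lr * (opt.mW.col(0) / c1) / (arma::sqrt(opt.vW.col(0) / c2) + eps);
    opt.mb = b1 * opt.mb + (1 - b1) * dbeta;
    opt.vb = b2 * opt.vb + (1 - b2) * arma::square(dbeta);
    beta -= lr * (opt.mb / c1) / (arma::sqrt(opt.vb / c2) + eps);
    dg.zeros(); dbeta.zeros();
  }
};

struct ResBlock {
  Conv c1, c2, cp;
  BatchNorm n1, n2;
  bool proj = false;
  cube a1, y;  // post-ReLU caches (masks)

  void init(int cin, int cout, int dil) {
    c1.in = cin; c1.out = cout; c1.k = 3; c1.dil = dil; c1.init();
    c2.in = cout; c2.out = cout; c2.k = 3; c2.dil = dil; c2.init();
    n1.init(cout); n2.init(cout);
    proj = (cin != cout);
    if (proj) { cp.in = cin; cp.out = cout; cp.k = 1; cp.dil = 1; cp.init(); }
  }

  cube forward(const cube& x, bool training) {
    cube h = n1.forward(c1.forward(x), training);
    h.transform([](double v) { return v > 0 ? v : 0.0; });
    if (training) a1 = h;
    cube h2 = n2.forward(c2.forward(h), training);
    cube s = proj ? cp.forward(x) : x;
    cube out = h2 + s;
    out.transform([](double v) { return v > 0 ? v : 0.0; });
    if (training) y = out;
    return out;
  }

  cube backward(cube dy) {
    dy.elem(arma::find(y == 0)).zeros();
    cube dh2 = dy;  // branch grad
    cube da1 = c2.backward(n2.backward(dh2));
    da1.elem(arma::find(a1 == 0)).zeros();
    cube dx = c1.backward(n1.backward(da1));
    if (proj) dx += cp.backward(dy);
    else dx += dy;
    a1.reset(); y.reset();
    return dx;
  }

  void step(double lr, double wd, bool t) {
    c1.step(lr, wd, t); c2.step(lr, wd, t);
    n1.step(lr, wd, t); n2.step(lr, wd, t);
    if (proj) cp.step(lr, wd, t);
  }
};

// ---------- pooling / upsampling ----------

static cube maxpool2(const cube& x, arma::ucube& idx) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube y(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int r = 2 * i + di, cc = 2 * j + dj;
            const double v = xs(r, cc);
            if (v > best) { best = v; bi = (arma::uword)r + (arma::uword)cc * x.n_rows; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return y;
}

static cube maxpool2_backward(const cube& dy, const arma::ucube& idx, int H, int W) {
  cube dx(H, W, dy.n_slices, arma::fill::zeros);
  for (arma::uword c = 0; c < dy.n_slices; ++c) {
    mat& dxs = dx.slice(c);
    for (arma::uword j = 0; j < dy.n_cols; ++j)
      for (arma::uword i = 0; i < dy.n_rows; ++i)
        dxs(idx(i, j, c)) += dy(i, j, c);
  }
  return dx;
}

// bilinear x2, align_corners = false
static void up2_coeffs(int n_out, int n_in, arma::ivec& i0, arma::ivec& i1, vec& w1) {
  i0.set_size(n_out); i1.set_size(n_out); w1.set_size(n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    int f = (int)std::floor(s);
    double w = s - f;
    int a = std::min(std::max(f, 0), n_in - 1);
    int b = std::min(std::max(f + 1, 0), n_in - 1);
    i0(i) = a; i1(i) = b; w1(i) = w;
  }
}

static cube upsample2(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::ivec r0, r1, c0, c1; vec wr, wc;
  up2_coeffs(2 * H, H, r0, r1, wr);
  up2_coeffs(2 * W, W, c0, c1, wc);
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    mat& ys = y.slice(c);
    for (int j = 0; j < 2 * W; ++j) {
      const int ca = c0(j), cb = c1(j); const double w = wc(j);
      for (int i = 0; i < 2 * H; ++i) {
        const int ra = r0(i), rb = r1(i); const double v = wr(i);
        ys(i, j) = (1 - v) * ((1 - w) * xs(ra, ca) + w * xs(ra, cb)) +
                   v * ((1 - w) * xs(rb, ca) + w * xs(rb, cb));
      }
    }
  }
  return y;
}

static cube upsample2_backward(const cube& dy, int H, int W) {
  arma::ivec r0, r1, c0, c1; vec wr, wc;
  up2_coeffs(2 * H, H, r0, r1, wr);
  up2_coeffs(2 * W, W, c0, c1, wc);
  cube dx(H, W, dy.n_slices, arma::fill::zeros);
  for (arma::uword c = 0; c < dy.n_slices; ++c) {
    mat& dxs = dx.slice(c);
    const mat& dys = dy.slice(c);
    for (int j = 0; j < 2 * W; ++j) {
      const int ca = c0(j), cb = c1(j); const double w = wc(j);
      for (int i = 0; i < 2 * H; ++i) {
        const int ra = r0(i), rb = r1(i); const double v = wr(i);
        const double d = dys(i, j);
        dxs(ra, ca) += (1 - v) * (1 - w) * d;
        dxs(ra, cb) += (1 - v) * w * d;
        dxs(rb, ca) += v * (1 - w) * d;
        dxs(rb, cb) += v * w * d;
      }
    }
  }
  return dx;
}

// ---------- the network ----------

struct UNet {
  int n_classes = 6;
  int base = 8;
  arma::ivec dil;     // per level, length 5
  ResBlock enc[5];
  ResBlock dec[5];    // dec[0..3]: levels 3..0 after upsample+concat; dec[4]: refinement
  Conv outconv;
  // forward caches
  cube e[5];
  arma::ucube pidx[4];
  int pH[4], pW[4];
  int upH[4], upW[4];
  int catUp[4];

  void init(int classes, int base_ch, const arma::ivec& dilation) {
    n_classes = classes; base = base_ch; dil = dilation;
    int C[5];
    for (int l = 0; l < 5; ++l) C[l] = base << l;
    enc[0].init(1, C[0], dil(0));
    for (int l = 1; l < 5; ++l) enc[l].init(C[l - 1], C[l], dil(l));
    for (int j = 0; j < 4; ++j) {
      const int lvl = 3 - j;                   // decoder block target level
      dec[j].init(C[lvl + 1] + C[lvl], C[lvl], dil(lvl));
    }
    dec[4].init(C[0], C[0], dil(0));
    outconv.in = C[0]; outconv.out = classes; outconv.k = 1; outconv.dil = 1;
    outconv.init();
  }

  cube forward(const cube& x, bool training) {
    cube h = enc[0].forward(x, training);
    e[0] = h;
    for (int l = 1; l < 5; ++l) {
      pH[l - 1] = h.n_rows; pW[l - 1] = h.n_cols;
      h = maxpool2(h, pidx[l - 1]);
      h = enc[l].forward(h, training);
      if (l < 5) e[l] = h;
    }
    // decoder
    for (int j = 0; j < 4; ++j) {
      const int lvl = 3 - j;
      upH[j] = h.n_rows; upW[j] = h.n_cols;
      cube u = upsample2(h);
      catUp[j] = u.n_slices;
      cube cat(u.n_rows, u.n_cols, u.n_slices + e[lvl].n_slices);
      cat.slices(0, u.n_slices - 1) = u;
      cat.slices(u.n_slices, cat.n_slices - 1) = e[lvl];
      h = dec[j].forward(cat, training);
    }
    h = dec[4].forward(h, training);
    return outconv.forward(h);  // logits H x W x K
  }

  void step(double lr, double wd, bool final_only) {
    const bool t = !final_only;
    for (int l = 0; l < 5; ++l) enc[l].step(lr, wd, t);
    for (int j = 0; j < 5; ++j) dec[j].step(lr, wd, t);
    outconv.step(lr, wd, true);
  }

  long n_params() const {
    long n = 0;
    auto cnt = [&n](const Conv& c) { n += c.W.n_elem + c.b.n_elem; };
    auto cntb = [&n](const BatchNorm& b) { n += 2 * b.ch; };
    for (int l = 0; l < 5; ++l) {
      cnt(enc[l].c1); cnt(enc[l].c2); cntb(enc[l].n1); cntb(enc[l].n2);
      if (enc[l].proj) cnt(enc[l].cp);
      cnt(dec[l].c1); cnt(dec[l].c2); cntb(dec[l].n1); cntb(dec[l].n2);
      if (dec[l].proj) cnt(dec[l].cp);
    }
    cnt(outconv);
    return n;
  }
};

static void unet_backward_full(UNet& net, const cube& dlogits) {
  cube g = net.dec[4].backward(net.outconv.backward(dlogits));
  cube dskip[4];
  for (int j = 3; j >= 0; --j) {
    const int lvl = 3 - j;
    cube dcat = net.dec[j].backward(g);
    cube du = dcat.slices(0, net.catUp[j] - 1);
    dskip[lvl] = dcat.slices(net.catUp[j], dcat.n_slices - 1);
    g = upsample2_backward(du, net.upH[j], net.upW[j]);
  }
  for (int l = 4; l >= 1; --l) {
    cube dp = net.enc[l].backward(g);
    g = maxpool2_backward(dp, net.pidx[l - 1], net.pH[l - 1], net.pW[l - 1]);
    if (l - 1 < 4) g += dskip[l - 1];
  }
  net.enc[0].backward(g);
  for (int l = 0; l < 5; ++l) net.e[l].reset();
}

// softmax over slices at each pixel
static cube softmax_cube(const cube& z) {
  cube p(z.n_rows, z.n_cols, z.n_slices);
  const int K = z.n_slices;
  for (arma::uword j = 0; j < z.n_cols; ++j) {
    for (arma::uword i = 0; i < z.n_rows; ++i) {
      double m = -arma::datum::inf;
      for (int c = 0; c < K; ++c) m = std::max(m, z(i, j, c));
      double s = 0;
      for (int c = 0; c < K; ++c) { const double e = std::exp(z(i, j, c) - m); p(i, j, c) = e; s += e; }
      for (int c = 0; c < K; ++c) p(i, j, c) /= s;
    }
  }
  return p;
}

// combined loss on probabilities; optionally fills dlogits (grad wrt logits)
static double combined_loss_core(const cube& p, const arma::imat& y, double w,
                                 cube* dlogits) {
  const int H = p.n_rows, W = p.n_cols, K = p.n_slices;
  const double N = (double)H * W;
  const double eps = 1.0;
  // cross-entropy
  double ce = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      ce -= std::log(std::max(p(i, j, y(i, j)), 1e-12));
  ce /= N;
  // Soft dice averaged over the foreground classes PRESENT in the target.
  // Absent classes are excluded: including them (via the eps smoothing in
  // the numerator) gives each a gradient of about -eps/(sp+eps)^2 per pixel
  // pushing its probability to zero on every slice it is missing from,
  // which dwarfs the per-pixel cross-entropy gradient (1/N) and makes the
  // all-background prediction a stable optimum. Cross-entropy alone
  // penalizes false positives of absent classes.
  vec num(K, arma::fill::zeros), sp(K, arma::fill::zeros), st(K, arma::fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int t = y(i, j);
      for (int c = 1; c < K; ++c) sp(c) += p(i, j, c);
      if (t >= 1) { num(t) += p(i, j, t); st(t) += 1.0; }
    }
  double dice_mean = 0;
  int n_present = 0;
  vec dnum(K), dden(K);
  for (int c = 1; c < K; ++c) {
    dnum(c) = 2.0 * num(c) + eps;
    dden(c) = sp(c) + st(c) + eps;
    if (st(c) > 0) { dice_mean += dnum(c) / dden(c); ++n_present; }
  }
  dice_mean = n_present ? dice_mean / n_present : 1.0;
  const double loss = w * ce + (1 - w) * (1.0 - dice_mean);
  if (dlogits) {
    cube& dz = *dlogits;
    dz.set_size(H, W, K);
    // dL/dp for the dice part (present classes only)
    // dice_c = (2*num_c + eps)/(den_c); d/dp_ci = (2*[t==c]*den_c - dnum_c)/den_c^2
    // L_dice = 1 - mean_{c present} dice_c -> g_ci = -(1/n_present) * d dice_c/dp_ci
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const int t = y(i, j);
        std::vector<double> gp(K);
        double dot = 0;
        for (int c = 0; c < K; ++c) {
          double gd = 0;
          if (c >= 1 && st(c) > 0 && n_present > 0) {
            const double d2 = dden(c) * dden(c);
            gd = -((2.0 * (t == c ? 1.0 : 0.0) * dden(c) - dnum(c)) / d2) / n_present;
          }
          gp[c] = (1 - w) * gd;
          dot += gp[c] * p(i, j, c);
        }
        for (int c = 0; c < K; ++c) {
          const double dice_part = p(i, j, c) * (gp[c] - dot);
          const double ce_part = w * (p(i, j, c) - (t == c ? 1.0 : 0.0)) / N;
          dz(i, j, c) = ce_part + dice_part;
        }
      }
  }
  return loss;
}

// ---------- exported interface ----------

// [[Rcpp::export]]
SEXP cpp_unet_create(int n_classes, int base, IntegerVector dilation) {
  if (dilation.size() != 5) stop("dilation must have length 5");
  arma::ivec d(5);
  for (int i = 0; i < 5; ++i) d(i) = dilation[i];
  UNet* net = new UNet();
  net->init(n_classes, base, d);
  XPtr<UNet> p(net, true);
  return p;
}

// [[Rcpp::export]]
double cpp_unet_nparams(SEXP ptr) {
  XPtr<UNet> p(ptr);
  return (double)p->n_params();
}

// [[Rcpp::export]]
NumericVector cpp_unet_predict(SEXP ptr, NumericMatrix x) {
  XPtr<UNet> p(ptr);
  cube xc(x.nrow(), x.ncol(), 1);
  std::copy(x.begin(), x.end(), xc.slice(0).begin());
  cube logits = p->forward(xc, false);
  cube probs = softmax_cube(logits);
  NumericVector out(probs.begin(), probs.end());
  out.attr("dim") = IntegerVector::create(x.nrow(), x.ncol(), p->n_classes);
  return out;
}

// [[Rcpp::export]]
double cpp_unet_train_step(SEXP ptr, NumericMatrix x, IntegerMatrix y,
                           double loss_weight, double lr, double wd,
                           bool final_only) {
  XPtr<UNet> p(ptr);
  cube xc(x.nrow(), x.ncol(), 1);
  std::copy(x.begin(), x.end(), xc.slice(0).begin());
  arma::imat ym(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i) ym(i, j) = y(i, j);
  cube logits = p->forward(xc, true);
  cube probs = softmax_cube(logits);
  cube dlogits;
  const double loss = combined_loss_core(probs, ym, loss_weight, &dlogits);
  unet_backward_full(*p, dlogits);
  p->step(lr, wd, final_only);
  return loss;
}

// [[Rcpp::export]]
double cpp_unet_eval_loss(SEXP ptr, NumericMatrix x, IntegerMatrix y,
                          double loss_weight) {
  XPtr<UNet> p(ptr);
  cube xc(x.nrow(), x.ncol(), 1);
  std::copy(x.begin(), x.end(), xc.slice(0).begin());
  arma::imat ym(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i) ym(i, j) = y(i, j);
  cube logits = p->forward(xc, false);
  cube probs = softmax_cube(logits);
  return combined_loss_core(probs, ym, loss_weight, nullptr);
}

// [[Rcpp::export]]
double cpp_combined_loss(NumericVector probs, IntegerMatrix y, double w) {
  IntegerVector d = probs.attr("dim");
  if (d.size() != 3) stop("probs must be a 3D array (H x W x K)");
  cube p(probs.begin(), d[0], d[1], d[2]);
  arma::imat ym(d[0], d[1]);
  for (int j = 0; j < d[1]; ++j)
    for (int i = 0; i < d[0]; ++i) ym(i, j) = y(i, j);
  return combined_loss_core(p, ym, w, nullptr);
}

// [[Rcpp::export]]
double cpp_unet_loss_train(SEXP ptr, NumericMatrix x, IntegerMatrix y,
                           double loss_weight) {
  // batch-statistics forward pass, loss only (no update); used by the
  // finite-difference gradient check
  XPtr<UNet> p(ptr);
  cube xc(x.nrow(), x.ncol(), 1);
  std::copy(x.begin(), x.end(), xc.slice(0).begin());
  arma::imat ym(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i) ym(i, j) = y(i, j);
  cube logits = p->forward(xc, true);
  cube probs = softmax_cube(logits);
  return combined_loss_core(probs, ym, loss_weight, nullptr);
}

// Analytic-vs-numeric gradient comparison on a sample of parameters from
// every layer type. Returns a matrix with columns (analytic, numeric).
// [[Rcpp::export]]
NumericMatrix cpp_unet_grad_check(SEXP ptr, NumericMatrix x, IntegerMatrix y,
                                  double loss_weight, double eps) {
  XPtr<UNet> p(ptr);
  cube xc(x.nrow(), x.ncol(), 1);
  std::copy(x.begin(), x.end(), xc.slice(0).begin());
  arma::imat ym(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i) ym(i, j) = y(i, j);
  // analytic gradients
  cube logits = p->forward(xc, true);
  cube probs = softmax_cube(logits);
  cube dlogits;
  combined_loss_core(probs, ym, loss_weight, &dlogits);
  unet_backward_full(*p, dlogits);
  struct Probe { double* par; double* grad; };
  std::vector<Probe> probes;
  auto addc = [&](Conv& c) {
    probes.push_back({&c.W(0, 0), &c.dW(0, 0)});
    arma::uword m = c.W.n_elem / 2;
    probes.push_back({&c.W(m), &c.dW(m)});
    probes.push_back({&c.b(0), &c.db(0)});
  };
  auto addb = [&](BatchNorm& b) {
    probes.push_back({&b.g(0), &b.dg(0)});
    probes.push_back({&b.beta(0), &b.dbeta(0)});
  };
  addc(p->enc[0].c1); addb(p->enc[0].n1);
  addc(p->enc[2].c2); addb(p->enc[2].n2);
  if (p->enc[1].proj) addc(p->enc[1].cp);
  addc(p->dec[1].c1); addb(p->dec[1].n1);
  addc(p->dec[4].c2);
  addc(p->outconv);
  NumericMatrix out(probes.size(), 2);
  NumericMatrix xm(x);
  for (size_t i = 0; i < probes.size(); ++i) {
    out(i, 0) = *probes[i].grad;
    const double orig = *probes[i].par;
    *probes[i].par = orig + eps;
    const double lp = cpp_unet_loss_train(ptr, xm, y, loss_weight);
    *probes[i].par = orig - eps;
    const double lm = cpp_unet_loss_train(ptr, xm, y, loss_weight);
    *probes[i].par = orig;
    out(i, 1) = (lp - lm) / (2 * eps);
  }
  // clear accumulated grads
  for (int l = 0; l < 5; ++l) { p->enc[l].step(0, 0, false); p->dec[l].step(0, 0, false); }
  p->outconv.step(0, 0, false);
  return out;
}

// [[Rcpp::export]]
void cpp_unet_reset_final(SEXP ptr) {
  XPtr<UNet> p(ptr);
  p->outconv.init();
}

static List conv_params(const Conv& c) {
  return List::create(_["W"] = wrap(c.W), _["b"] = wrap(c.b));
}
static List bn_params(const BatchNorm& b) {
  return List::create(_["g"] = wrap(b.g), _["beta"] = wrap(b.beta),
                      _["rmean"] = wrap(b.rmean), _["rvar"] = wrap(b.rvar));
}
static List block_params(const ResBlock& bl) {
  List out = List::create(_["c1"] = conv_params(bl.c1), _["n1"] = bn_params(bl.n1),
                          _["c2"] = conv_params(bl.c2), _["n2"] = bn_params(bl.n2));
  if (bl.proj) out["cp"] = conv_params(bl.cp);
  return out;
}

// [[Rcpp::export]]
List cpp_unet_get_params(SEXP ptr) {
  XPtr<UNet> p(ptr);
  List enc(5), dec(5);
  for (int l = 0; l < 5; ++l) { enc[l] = block_params(p->enc[l]); dec[l] = block_params(p->dec[l]); }
  IntegerVector dil(5);
  for (int i = 0; i < 5; ++i) dil[i] = p->dil(i);
  return List::create(_["n_classes"] = p->n_classes, _["base"] = p->base,
                      _["dilation"] = dil, _["enc"] = enc, _["dec"] = dec,
                      _["outconv"] = conv_params(p->outconv));
}

static void set_conv(Conv& c, List l) {
  c.W = as<mat>(l["W"]); c.b = as<vec>(l["b"]);
}
static void set_bn(BatchNorm& b, List l) {
  b.g = as<vec>(l["g"]); b.beta = as<vec>(l["beta"]);
  b.rmean = as<vec>(l["rmean"]); b.rvar = as<vec>(l["rvar"]);
}
static void set_block(ResBlock& bl, List l) {
  set_conv(bl.c1, l["c1"]); set_bn(bl.n1, l["n1"]);
  set_conv(bl.c2, l["c2"]); set_bn(bl.n2, l["n2"]);
  if (bl.proj) set_conv(bl.cp, l["cp"]);
}

// [[Rcpp::export]]
void cpp_unet_set_params(SEXP ptr, List params) {
  XPtr<UNet> p(ptr);
  List enc = params["enc"], dec = params["dec"];
  for (int l = 0; l < 5; ++l) { set_block(p->enc[l], enc[l]); set_block(p->dec[l], dec[l]); }
  set_conv(p->outconv, params["outconv"]);
}
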