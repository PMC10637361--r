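// Streamline tracking core: trilinear interpolation of the six unique
// diffusion-tensor components followed by eigen-decomposition at each
// step (interpolate-then-decompose), fixed-step Euler integration with
// per-region parameters, and vectorised FA / color-map helpers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct TensorGrid {
  const double *data;   // nx*ny*nz*6, lower-triangular dxx,dxy,dyy,dxz,dyz,dzz
  int nx, ny, nz;
  arma::mat44 w2v;      // world mm -> 0-based voxel
};

inline arma::vec3 world_to_vox(const arma::mat44 &w2v, const arma::vec3 &w) {
  arma::vec3 v;
  for (int r = 0; r < 3; ++r)
    v(r) = w2v(r,0)*w(0) + w2v(r,1)*w(1) + w2v(r,2)*w(2) + w2v(r,3);
  return v;
}

inline bool in_grid(const TensorGrid &g, const arma::vec3 &v) {
  return v(0) >= 0 && v(0) <= g.nx - 1 &&
         v(1) >= 0 && v(1) <= g.ny - 1 &&
         v(2) >= 0 && v(2) <= g.nz - 1;
}

// Trilinear interpolation of the 6 tensor components at voxel coords.
inline bool interp_tensor(const TensorGrid &g, const arma::vec3 &v,
                          arma::mat33 &D) {
  if (!in_grid(g, v)) return false;
  int x0 = std::min((int)std::floor(v(0)), g.nx - 2);
  int y0 = std::min((int)std::floor(v(1)), g.ny - 2);
  int z0 = std::min((int)std::floor(v(2)), g.nz - 2);
  x0 = std::max(x0, 0); y0 = std::max(y0, 0); z0 = std::max(z0, 0);
  double fx = v(0) - x0, fy = v(1) - y0, fz = v(2) - z0;
  double w[8] = {
    (1-fx)*(1-fy)*(1-fz), fx*(1-fy)*(1-fz), (1-fx)*fy*(1-fz), fx*fy*(1-fz),
    (1-fx)*(1-fy)*fz,     fx*(1-fy)*fz,     (1-fx)*fy*fz,     fx*fy*fz };
  int ox[8] = {0,1,0,1,0,1,0,1};
  int oy[8] = {0,0,1,1,0,0,1,1};
  int oz[8] = {0,0,0,0,1,1,1,1};
  double c[6] = {0,0,0,0,0,0};
  size_t nvox = (size_t)g.nx * g.ny * g.nz;
  for (int k = 0; k < 8; ++k) {
    size_t idx = (size_t)(x0 + ox[k]) +
                 (size_t)g.nx * ((y0 + oy[k]) + (size_t)g.ny * (z0 + oz[k]));
    for (int c6 = 0; c6 < 6; ++c6) c[c6] += w[k] * g.data[idx + nvox * c6];
  }
  D(0,0) = c[0]; D(0,1) = D(1,0) = c[1]; D(1,1) = c[2];
  D(0,2) = D(2,0) = c[3]; D(1,2) = D(2,1) = c[4]; D(2,2) = c[5];
  return true;
}

inline double fa_from_eval(const arma::vec3 &lam_in) {
  arma::vec3 lam = lam_in;
  for (int i = 0; i < 3; ++i) lam(i) = std::max(lam(i), 0.0);
  double mu = (lam(0) + lam(1) + lam(2)) / 3.0;
  double num = 0, den = 0;
  for (int i = 0; i < 3; ++i) {
    num += (lam(i) - mu) * (lam(i) - mu);
    den += lam(i) * lam(i);
  }
  if (den <= 0) return 0.0;
  double fa = std::sqrt(1.5 * num / den);
  return std::min(std::max(fa, 0.0), 1.0);
}

// Principal eigenvector and FA of the tensor at world position w.
inline bool principal_dir(const TensorGrid &g, const arma::vec3 &w,
                          arma::vec3 &e1, double &fa) {
  arma::vec3 v = world_to_vox(g.w2v, w);
  arma::mat33 D;
  if (!interp_tensor(g, v, D)) return false;
  arma::vec3 eval;
  arma::mat33 evec;
  arma::eig_sym(eval, evec, D);          // ascending
  fa = fa_from_eval(eval);
  e1 = evec.col(2);
  double n = arma::norm(e1);
  if (n <= 0) return false;
  e1 /= n;
  return true;
}

struct RegionParams {
  const int *atlas;       // may be null
  int ax, ay, az;
  arma::mat44 a_w2v;
  const int *labels;      // override labels
  int n_over;
  const double *par;      // (1+n_over) x 5 col-major: step, fa, angle, minl, maxl
  int npar_rows;

  void at(const arma::vec3 &w, double out[5]) const {
    int row = 0;
    if (atlas) {
      arma::vec3 v = world_to_vox(a_w2v, w);
      int i = (int)std::lround(v(0)), j = (int)std::lround(v(1)),
          k = (int)std::lround(v(2));
      if (i >= 0 && i < ax && j >= 0 && j < ay && k >= 0 && k < az) {
        int lab = atlas[(size_t)i + (size_t)ax * (j + (size_t)ay * k)];
        for (int q = 0; q < n_over; ++q)
          if (labels[q] == lab) { row = q + 1; break; }
      }
    }
    for (int c = 0; c < 5; ++c) out[c] = par[row + npar_rows * c];
  }
};

// Track one direction from seed; returns points (excluding the seed) and
// accumulated length. Termination reasons: low-fa, bend, out-of-grid,
// max-length.
void track_half(const TensorGrid &g, const RegionParams &rp,
                const arma::vec3 &seed, arma::vec3 dir0,
                std::vector<arma::vec3> &pts, double &len,
                int max_steps) {
  arma::vec3 pos = seed;
  arma::vec3 prev = dir0;
  len = 0.0;
  double p[5];
  for (int s = 0; s < max_steps; ++s) {
    rp.at(pos, p);
    const double step = p[0], fa_thr = p[1];
    const double cos_max = std::cos(p[2] * M_PI / 180.0);
    arma::vec3 e1;
    double fa;
    if (!principal_dir(g, pos, e1, fa)) return;      // out of grid
    if (fa < fa_thr) return;                          // low anisotropy
    if (arma::dot(e1, prev) < 0) e1 = -e1;            // sign continuity
    if (s > 0 && arma::dot(e1, prev) < cos_max) return;  // sharp bend
    arma::vec3 nxt = pos + step * e1;
    arma::vec3 nv = world_to_vox(g.w2v, nxt);
    if (!in_grid(g, nv)) return;                      // leaving the grid
    pts.push_back(nxt);
    len += step;
    pos = nxt;
    prev = e1;
    if (len >= p[4]) return;                          // max length
  }
}

} // namespace

// [[Rcpp::export]]
List track_streamline_cpp(NumericVector tensors, IntegerVector dims,
                          NumericMatrix w2v, NumericVector seed,
                          Nullable<IntegerVector> atlas_,
                          Nullable<IntegerVector> atlas_dims_,
                          Nullable<NumericMatrix> atlas_w2v_,
                          IntegerVector override_labels,
                          NumericMatrix param_table) {
  TensorGrid g;
  g.data = tensors.begin();
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) g.w2v(r,c) = w2v(r,c);

  RegionParams rp;
  rp.atlas = nullptr;
  IntegerVector atlas;
  if (atlas_.isNotNull()) {
    atlas = atlas_.get();
    IntegerVector ad = atlas_dims_.get();
    NumericMatrix aw = atlas_w2v_.get();
    rp.atlas = atlas.begin();
    rp.ax = ad[0]; rp.ay = ad[1]; rp.az = ad[2];
    for (int r = 0; r < 4; ++r)
      for (int c = 0; c < 4; ++c) rp.a_w2v(r,c) = aw(r,c);
  }
  rp.labels = override_labels.begin();
  rp.n_over = override_labels.size();
  rp.par = param_table.begin();
  rp.npar_rows = param_table.nrow();

  arma::vec3 s;
  s(0) = seed[0]; s(1) = seed[1]; s(2) = seed[2];
  arma::vec3 sv = world_to_vox(g.w2v, s);
  if (!in_grid(g, sv)) stop("seed lies outside the tensor grid");

  double p[5];
  rp.at(s, p);
  arma::vec3 e1;
  double fa;
  if (!principal_dir(g, s, e1, fa) || fa < p[1]) {
    NumericMatrix single(1, 3);
    single(0,0) = s(0); single(0,1) = s(1); single(0,2) = s(2);
    return List::create(_["points"] = single,
                        _["status"] = "rejected",
                        _["reason"] = "low-FA");
  }
  int max_steps = (int)std::ceil(p[4] / p[0]) + 16;
  if (max_steps > 1000000) max_steps = 1000000;

  std::vector<arma::vec3> fwd, bwd;
  double lf = 0, lb = 0;
  track_half(g, rp, s, e1, fwd, lf, max_steps);
  track_half(g, rp, s, -e1, bwd, lb, max_steps);

  size_t n = bwd.size() + 1 + fwd.size();
  NumericMatrix pts(n, 3);
  size_t r = 0;
  for (size_t i = bwd.size(); i-- > 0; ++r)
    for (int c = 0; c < 3; ++c) pts(r, c) = bwd[i](c);
  for (int c = 0; c < 3; ++c) pts(r, c) = s(c);
  ++r;
  for (size_t i = 0; i < fwd.size(); ++i, ++r)
    for (int c = 0; c < 3; ++c) pts(r, c) = fwd[i](c);

  double total = lf + lb;
  std::string status = "accepted", reason = "";
  if (total < p[3]) { status = "rejected"; reason = "too-short"; }
  return List::create(_["points"] = pts,
                      _["status"] = status,
                      _["reason"] = reason,
                      _["length_mm"] = total);
}

// [[Rcpp::export]]
NumericVector fa_map_cpp(NumericVector tensors) {
  IntegerVector d = tensors.attr("dim");
  size_t nvox = (size_t)d[0] * d[1] * d[2];
  NumericVector out(nvox);
  arma::mat33 D;
  arma::vec3 eval;
  for (size_t i = 0; i < nvox; ++i) {
    D(0,0) = tensors[i];            D(0,1) = D(1,0) = tensors[i + nvox];
    D(1,1) = tensors[i + 2*nvox];   D(0,2) = D(2,0) = tensors[i + 3*nvox];
    D(1,2) = D(2,1) = tensors[i + 4*nvox];
    D(2,2) = tensors[i + 5*nvox];
    arma::eig_sym(eval, D);
    out[i] = fa_from_eval(eval);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix color_map_cpp(NumericVector tensors) {
  IntegerVector d = tensors.attr("dim");
  size_t nvox = (size_t)d[0] * d[1] * d[2];
  NumericMatrix out(nvox, 3);
  arma::mat33 D, evec;
  arma::vec3 eval;
  for (size_t i = 0; i < nvox; ++i) {
    D(0,0) = tensors[i];            D(0,1) = D(1,0) = tensors[i + nvox];
    D(1,1) = tensors[i + 2*nvox];   D(0,2) = D(2,0) = tensors[i + 3*nvox];
    D(1,2) = D(2,1) = tensors[i + 4*nvox];
    D(2,2) = tensors[i + 5*nvox];
    arma::eig_sym(eval, evec, D);
    double fa = fa_from_eval(eval);
    for (int c = 0; c < 3; ++c)
      out(i, c) = std::min(1.0, fa * std::abs(evec(c, 2)));
  }
  return out;
}

namespace {
// Catmull-Rom weights for fractional offset t in [0,1], taps at -1..2.
inline void catmull_rom_w(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2*t2 - t);
  w[1] = 0.5 * (3*t3 - 5*t2 + 2);
  w[2] = 0.5 * (-3*t3 + 4*t2 + t);
  w[3] = 0.5 * (t3 - t2);
}
} // namespace

// Normalized-gradient-fields objective. Fixed-grid voxels at least
// `margin` voxels from either grid's border contribute
// 1 - <gf, R'gm(t(x))>^2 / ((|gf|^2+eps^2)(|R'gm|^2+eps^2)).
// `cubic` selects tricubic (Catmull-Rom) instead of trilinear sampling of
// the moving gradient field; the higher order suppresses the sub-voxel
// interpolation ripple that otherwise biases the optimum.
// When `sel` (0-based linear indices into the fixed grid) is non-empty the
// average runs over exactly that voxel set, with samples falling outside
// the moving grid scored as the maximal dissimilarity 1: a fixed
// evaluation domain keeps the objective free of the overlap-set shuffling
// that otherwise rewards transforms for pushing uninformative voxels out
// of view. With an empty `sel` the average runs over the transform-
// dependent overlap (the plain distance definition) and returns NA for an
// empty overlap.
// [[Rcpp::export]]
double ngf_obj_cpp(NumericVector gf, IntegerVector fdims,
                   NumericMatrix f_affine, NumericVector gm,
                   IntegerVector mdims, NumericMatrix m_w2v,
                   NumericMatrix rot, NumericVector trans,
                   double eps, int margin, bool cubic = false,
                   Nullable<IntegerVector> sel = R_NilValue) {
  const int nx = fdims[0], ny = fdims[1], nz = fdims[2];
  const int mx = mdims[0], my = mdims[1], mz = mdims[2];
  const size_t nf = (size_t)nx * ny * nz;
  const size_t nm = (size_t)mx * my * mz;
  const double *gfx = gf.begin(), *gfy = gf.begin() + nf,
               *gfz = gf.begin() + 2 * nf;
  const double *gmx = gm.begin(), *gmy = gm.begin() + nm,
               *gmz = gm.begin() + 2 * nm;
  arma::mat44 A, W;
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) { A(r,c) = f_affine(r,c); W(r,c) = m_w2v(r,c); }
  arma::mat33 R;
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) R(r,c) = rot(r,c);
  arma::vec3 tv = { trans[0], trans[1], trans[2] };
  const double e2 = eps * eps;
  double sum = 0.0;
  size_t count = 0;
  const int m = std::max(margin, cubic ? 2 : 1);
  IntegerVector selv;
  bool fixed_domain = sel.isNotNull();
  if (fixed_domain) selv = sel.get();
  const R_xlen_t nsel = fixed_domain ? selv.size() : (R_xlen_t)nf;
  for (R_xlen_t q0 = 0; q0 < nsel; ++q0) {
        int i, j, k;
        if (fixed_domain) {
          size_t li = (size_t)selv[q0];
          i = (int)(li % nx);
          j = (int)((li / nx) % ny);
          k = (int)(li / ((size_t)nx * ny));
        } else {
          size_t li = (size_t)q0;
          i = (int)(li % nx);
          j = (int)((li / nx) % ny);
          k = (int)(li / ((size_t)nx * ny));
          if (i < m || i >= nx - m || j < m || j >= ny - m ||
              k < m || k >= nz - m) continue;
        }
        arma::vec3 w;
        for (int r = 0; r < 3; ++r)
          w(r) = A(r,0)*i + A(r,1)*j + A(r,2)*k + A(r,3);
        arma::vec3 tw = R * w + tv;
        arma::vec3 v;
        for (int r = 0; r < 3; ++r)
          v(r) = W(r,0)*tw(0) + W(r,1)*tw(1) + W(r,2)*tw(2) + W(r,3);
        if (v(0) < m || v(0) > mx - 1 - m ||
            v(1) < m || v(1) > my - 1 - m ||
            v(2) < m || v(2) > mz - 1 - m) {
          if (fixed_domain) { sum += 1.0; ++count; }
          continue;
        }
        int x0 = (int)std::floor(v(0)), y0 = (int)std::floor(v(1)),
            z0 = (int)std::floor(v(2));
        double fx = v(0) - x0, fy = v(1) - y0, fz = v(2) - z0;
        arma::vec3 g = arma::zeros<arma::vec>(3);
        if (cubic) {
          double wx[4], wy[4], wz[4];
          catmull_rom_w(fx, wx); catmull_rom_w(fy, wy); catmull_rom_w(fz, wz);
          for (int c2 = 0; c2 < 4; ++c2)
            for (int b = 0; b < 4; ++b) {
              double wyz = wy[b] * wz[c2];
              size_t base = (size_t)mx * ((y0 + b - 1) +
                            (size_t)my * (z0 + c2 - 1)) + (x0 - 1);
              for (int a = 0; a < 4; ++a) {
                double wgt = wx[a] * wyz;
                g(0) += wgt * gmx[base + a];
                g(1) += wgt * gmy[base + a];
                g(2) += wgt * gmz[base + a];
              }
            }
        } else {
          double wgt[8] = {
            (1-fx)*(1-fy)*(1-fz), fx*(1-fy)*(1-fz), (1-fx)*fy*(1-fz),
            fx*fy*(1-fz), (1-fx)*(1-fy)*fz, fx*(1-fy)*fz, (1-fx)*fy*fz,
            fx*fy*fz };
          static const int ox[8] = {0,1,0,1,0,1,0,1};
          static const int oy[8] = {0,0,1,1,0,0,1,1};
          static const int oz[8] = {0,0,0,0,1,1,1,1};
          for (int q = 0; q < 8; ++q) {
            size_t idx = (size_t)(x0 + ox[q]) +
                         (size_t)mx * ((y0 + oy[q]) + (size_t)my * (z0 + oz[q]));
            g(0) += wgt[q] * gmx[idx];
            g(1) += wgt[q] * gmy[idx];
            g(2) += wgt[q] * gmz[idx];
          }
        }
        arma::vec3 gr = R.t() * g;
        size_t fi = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        double ip = gfx[fi]*gr(0) + gfy[fi]*gr(1) + gfz[fi]*gr(2);
        double nf2 = gfx[fi]*gfx[fi] + gfy[fi]*gfy[fi] + gfz[fi]*gfz[fi];
        double nm2 = gr(0)*gr(0) + gr(1)*gr(1) + gr(2)*gr(2);
        sum += 1.0 - (ip * ip) / ((nf2 + e2) * (nm2 + e2));
        ++count;
  }
  if (count == 0) return NA_REAL;
  return sum / count;
}
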