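// Compute kernels for the PIV engine: batched zero-mean normalized circular
// cross-correlation of interrogation windows (frequency domain), subpixel
// peak localization, and normalized-median vector validation.
//
// Image convention in this file: matrices are stored image-style, row 1 = top
// of the frame.  Displacements are returned in (row, col) image coordinates;
// the R layer converts to the y-up mathematical frame.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double median_of(std::vector<double>& x) {
  const size_t n = x.size();
  std::sort(x.begin(), x.end());
  if (n == 0) return datum::nan;
  return (n % 2 == 1) ? x[n / 2] : 0.5 * (x[n / 2 - 1] + x[n / 2]);
}

// Locate the correlation peak of `s` with subpixel refinement.
// Returns (row, col, valid, peak_ratio); row/col are 1-based matrix
// coordinates.  A 3-point Gaussian fit is used per axis, falling back to a
// parabolic fit when any of the three samples is non-positive.  The peak must
// be a strict interior maximum; otherwise valid = 0.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_peak_locate(const arma::mat& s) {
  Rcpp::NumericVector out(4);
  out[0] = NA_REAL; out[1] = NA_REAL; out[2] = 0.0; out[3] = NA_REAL;
  const uword nr = s.n_rows, nc = s.n_cols;
  if (nr < 3 || nc < 3 || !s.is_finite()) return out;

  uword pi = 0, pj = 0;
  double pk = -datum::inf;
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i)
      if (s(i, j) > pk) { pk = s(i, j); pi = i; pj = j; }

  // strict maximum: no other cell may attain the peak value
  uword ties = 0;
  for (uword j = 0; j < nc && ties < 2; ++j)
    for (uword i = 0; i < nr; ++i)
      if (s(i, j) == pk) ++ties;
  if (ties != 1) return out;
  if (pi == 0 || pj == 0 || pi == nr - 1 || pj == nc - 1) return out;

  auto fit1d = [](double cm, double c0, double cp) -> double {
    if (cm > 0.0 && c0 > 0.0 && cp > 0.0) {
      const double den = std::log(cm) + std::log(cp) - 2.0 * std::log(c0);
      if (den < 0.0) return 0.5 * (std::log(cm) - std::log(cp)) / den;
    }
    const double den = cm - 2.0 * c0 + cp;
    if (den < 0.0) return 0.5 * (cm - cp) / den;
    return 0.0;
  };
  const double dr = fit1d(s(pi - 1, pj), s(pi, pj), s(pi + 1, pj));
  const double dc = fit1d(s(pi, pj - 1), s(pi, pj), s(pi, pj + 1));

  // peak ratio: primary peak over highest value outside its 3x3 neighborhood
  double second = -datum::inf;
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i) {
      if (std::abs((int)i - (int)pi) <= 1 && std::abs((int)j - (int)pj) <= 1)
        continue;
      if (s(i, j) > second) second = s(i, j);
    }
  double ratio;
  if (second <= 1e-12) ratio = 1e6; else ratio = pk / second;

  out[0] = (double)(pi + 1) + dr;
  out[1] = (double)(pj + 1) + dc;
  out[2] = 1.0;
  out[3] = ratio;
  return out;
}

// Batched windowed ZNCC between frames a and b.
// top_row/top_col: 1-based top-left corners of the interrogation windows in
// frame a.  pred_r/pred_c: integer predictor displacement applied to the
// window extracted from frame b (clamped to stay in-bounds).  Returned dr/dc
// include the (effective) predictor.  Surfaces are fftshifted so that zero
// lag sits at index win/2 + 1 (1-based).
// [[Rcpp::export]]
Rcpp::List cpp_cc_batch(const arma::mat& a, const arma::mat& b,
                        const arma::ivec& top_row, const arma::ivec& top_col,
                        const int win,
                        const arma::ivec& pred_r, const arma::ivec& pred_c,
                        const bool want_surfaces) {
  const int H = (int)a.n_rows, W = (int)a.n_cols;
  const int k = (int)top_row.n_elem;
  const int w2 = win / 2;
  vec dr(k), dc(k), ratio(k);
  ivec valid(k), degen(k), eff_pr(k), eff_pc(k);
  cube surf;
  if (want_surfaces) surf.set_size(win, win, k);

  for (int m = 0; m < k; ++m) {
    const int r0 = top_row(m) - 1, c0 = top_col(m) - 1;
    int pr = pred_r(m), pc = pred_c(m);
    // clamp predictor so the shifted window stays inside frame b
    pr = std::max(-r0, std::min(pr, H - win - r0));
    pc = std::max(-c0, std::min(pc, W - win - c0));
    eff_pr(m) = pr; eff_pc(m) = pc;

    mat A = a.submat(r0, c0, r0 + win - 1, c0 + win - 1);
    mat B = b.submat(r0 + pr, c0 + pc, r0 + pr + win - 1, c0 + pc + win - 1);
    A -= accu(A) / (double)(win * win);
    B -= accu(B) / (double)(win * win);
    const double sa = std::sqrt(accu(A % A)), sb = std::sqrt(accu(B % B));

    if (sa < 1e-10 || sb < 1e-10) {
      degen(m) = 1; valid(m) = 0;
      dr(m) = datum::nan; dc(m) = datum::nan; ratio(m) = datum::nan;
      if (want_surfaces) surf.slice(m).fill(datum::nan);
      continue;
    }
    degen(m) = 0;

    cx_mat FA = fft2(A), FB = fft2(B);
    mat C = real(ifft2(conj(FA) % FB)) / (sa * sb);
    // fftshift: S(i,j) holds the correlation at lag (i - w2, j - w2);
    // divide by the per-lag window-overlap fraction (unbiased estimator) so
    // that loss-of-pairs does not pull the peak toward zero displacement
    mat S(win, win);
    for (int j = 0; j < win; ++j)
      for (int i = 0; i < win; ++i) {
        const double wfac =
          ((double)(win - std::abs(i - w2)) / win) *
          ((double)(win - std::abs(j - w2)) / win);
        S(i, j) = C((i + w2) % win, (j + w2) % win) / wfac;
      }
    if (want_surfaces) surf.slice(m) = S;

    // the overlap correction amplifies wrap-around noise at extreme lags,
    // so the peak search is confined to |lag| <= win/4
    mat Sm = S;
    const int rmax = win / 4;
    for (int j = 0; j < win; ++j)
      for (int i = 0; i < win; ++i)
        if (std::abs(i - w2) > rmax || std::abs(j - w2) > rmax)
          Sm(i, j) = -1e30;

    Rcpp::NumericVector pk = cpp_peak_locate(Sm);
    if (pk[2] > 0.5) {
      valid(m) = 1;
      dr(m) = (pk[0] - 1.0 - w2) + pr;
      dc(m) = (pk[1] - 1.0 - w2) + pc;
      ratio(m) = pk[3];
    } else {
      valid(m) = 0;
      dr(m) = datum::nan; dc(m) = datum::nan; ratio(m) = datum::nan;
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("dr") = dr, Rcpp::Named("dc") = dc,
    Rcpp::Named("peak_ratio") = ratio,
    Rcpp::Named("valid") = valid, Rcpp::Named("degenerate") = degen,
    Rcpp::Named("pred_r") = eff_pr, Rcpp::Named("pred_c") = eff_pc);
  if (want_surfaces) out["surfaces"] = surf;
  return out;
}

// Normalized-median-test validation and one-pass replacement on a regular
// vector grid.  u, v, valid, peak_ratio are nx x ny matrices (any consistent
// orientation).  A valid cell is flagged when the magnitude of its deviation
// from the 3x3 neighborhood median exceeds thr * (median neighbor residual +
// eps), or when its peak ratio falls below min_ratio.  Flagged cells are
// replaced by the component-wise median of their valid, unflagged neighbors
// (one iteration); with no such neighbor the cell becomes invalid.
// [[Rcpp::export]]
Rcpp::List cpp_validate(const arma::mat& u, const arma::mat& v,
                        const arma::imat& valid, const arma::mat& peak_ratio,
                        const double thr, const double eps,
                        const double min_ratio) {
  const int nx = (int)u.n_rows, ny = (int)u.n_cols;
  imat flag(nx, ny, fill::zeros);
  mat uo = u, vo = v;
  imat vout(valid);
  int n_replaced = 0;

  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!valid(i, j)) continue;
      if (std::isfinite(peak_ratio(i, j)) && peak_ratio(i, j) < min_ratio) {
        flag(i, j) = 1;
        continue;
      }
      std::vector<double> un, vn;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
          if (!valid(ii, jj)) continue;
          un.push_back(u(ii, jj));
          vn.push_back(v(ii, jj));
        }
      if (un.empty()) continue;
      std::vector<double> uc = un, vc = vn;
      const double mu = median_of(uc), mv = median_of(vc);
      std::vector<double> res(un.size());
      for (size_t q = 0; q < un.size(); ++q)
        res[q] = std::hypot(un[q] - mu, vn[q] - mv);
      const double rm = median_of(res);
      const double ri = std::hypot(u(i, j) - mu, v(i, j) - mv);
      if (ri > thr * (rm + eps)) flag(i, j) = 1;
    }
  }

  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!flag(i, j)) continue;
      std::vector<double> un, vn;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
          if (!valid(ii, jj) || flag(ii, jj)) continue;
          un.push_back(u(ii, jj));
          vn.push_back(v(ii, jj));
        }
      if (un.empty()) {
        vout(i, j) = 0;
        uo(i, j) = datum::nan;
        vo(i, j) = datum::nan;
      } else {
        uo(i, j) = median_of(un);
        vo(i, j) = median_of(vn);
        vout(i, j) = 1;
        ++n_replaced;
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("u") = uo, Rcpp::Named("v") = vo,
    Rcpp::Named("valid") = vout, Rcpp::Named("flagged") = flag,
    Rcpp::Named("n_replaced") = n_replaced);
}

// Accumulate isotropic Gaussian spots into an H x W image (image-row
// convention).  rowc/colc are real-valued spot centers; each spot is
// truncated at +/- hw pixels from its rounded center.
// [[Rcpp::export]]
arma::mat cpp_render_spots(const int H, const int W,
                           const arma::vec& rowc, const arma::vec& colc,
                           const arma::vec& intensity, const double sigma,
                           const int hw) {
  mat img(H, W, fill::zeros);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (uword k = 0; k < rowc.n_elem; ++k) {
    const int r0 = (int)std::lround(rowc(k));
    const int c0 = (int)std::lround(colc(k));
    for (int dc = -hw; dc <= hw; ++dc) {
      const int c = c0 + dc;
      if (c < 1 || c > W) continue;
      const double gx = std::exp(-(c - colc(k)) * (c - colc(k)) * inv2s2);
      for (int dr = -hw; dr <= hw; ++dr) {
        const int r = r0 + dr;
        if (r < 1 || r > H) continue;
        img(r - 1, c - 1) += intensity(k) * gx *
          std::exp(-(r - rowc(k)) * (r - rowc(k)) * inv2s2);
      }
    }
  }
  return img;
}
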