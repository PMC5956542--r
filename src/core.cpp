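// Numerical kernels: heterogeneous scalar shear-wave stepping, scatterer
// deposition, separable convolution, and windowed complex correlation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double harm(double a, double b) {
  // harmonic mean: series compliance across a cell edge; exact zero-stiffness
  // edges stay zero
  double s = a + b;
  return (s > 0.0) ? 2.0 * a * b / s : 0.0;
}

// Leapfrog time stepping of rho u_tt = div(mu grad u) on a cell-centred grid.
// Boundary fluxes are zero at the top (traction-free) and the two sides
// (roller surrogate); the bottom row is clamped to u = 0 (fixed support).
// Rod cells follow the prescribed push A sin(2 pi f t) while t <= push_dur.
// [[Rcpp::export]]
arma::cube fd_wave_solve_cpp(const arma::mat& mu, const arma::mat& rho,
                             double dx, double frame_dt, int nframes, int nsub,
                             const arma::uvec& rod_cells, double amp,
                             double freq, double push_dur) {
  const int nx = mu.n_rows, ny = mu.n_cols;
  const double dt = frame_dt / nsub;
  const double c2 = dt * dt / (dx * dx);

  mat cx(nx - 1, ny), cy(nx, ny - 1);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx - 1; ++i) cx(i, j) = harm(mu(i, j), mu(i + 1, j));
  for (int j = 0; j < ny - 1; ++j)
    for (int i = 0; i < nx; ++i) cy(i, j) = harm(mu(i, j), mu(i, j + 1));

  mat u(nx, ny, fill::zeros), uold(nx, ny, fill::zeros), unew(nx, ny);
  cube out(nx, ny, nframes);
  out.slice(0) = u;

  double t = 0.0;
  const double twopif = 2.0 * M_PI * freq;

  for (int f = 1; f < nframes; ++f) {
    for (int s = 0; s < nsub; ++s) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          double fxp = (i < nx - 1) ? cx(i, j) * (u(i + 1, j) - u(i, j)) : 0.0;
          double fxm = (i > 0) ? cx(i - 1, j) * (u(i, j) - u(i - 1, j)) : 0.0;
          double fyp = (j < ny - 1) ? cy(i, j) * (u(i, j + 1) - u(i, j)) : 0.0;
          double fym = (j > 0) ? cy(i, j - 1) * (u(i, j) - u(i, j - 1)) : 0.0;
          unew(i, j) =
              2.0 * u(i, j) - uold(i, j) + c2 * (fxp - fxm + fyp - fym) / rho(i, j);
        }
      }
      t += dt;
      // fixed bottom support
      for (int i = 0; i < nx; ++i) unew(i, ny - 1) = 0.0;
      if (t <= push_dur + 1e-12) {
        const double val = amp * std::sin(twopif * t);
        for (uword k = 0; k < rod_cells.n_elem; ++k) {
          unew(rod_cells[k]) = val;
        }
      }
      uold = u;
      u = unew;
    }
    if (!u.is_finite())
      Rcpp::stop("wave solver diverged (non-finite displacement) at frame %d", f);
    out.slice(f) = u;
  }
  return out;
}

// Amplitude-weighted bilinear deposition of point scatterers onto the RF
// sample/beam lattice. Positions are fractional 1-based indices; out-of-grid
// contributions are dropped.
// [[Rcpp::export]]
arma::mat splat_cpp(const arma::vec& ax, const arma::vec& bm,
                    const arma::vec& amp, int nax, int nb) {
  mat out(nax, nb, fill::zeros);
  for (uword k = 0; k < ax.n_elem; ++k) {
    double p = ax[k] - 1.0, q = bm[k] - 1.0;
    int i0 = (int)std::floor(p), j0 = (int)std::floor(q);
    double fr = p - i0, fc = q - j0;
    double w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc), w01 = (1 - fr) * fc,
           w11 = fr * fc;
    if (i0 >= 0 && i0 < nax && j0 >= 0 && j0 < nb) out(i0, j0) += amp[k] * w00;
    if (i0 + 1 >= 0 && i0 + 1 < nax && j0 >= 0 && j0 < nb)
      out(i0 + 1, j0) += amp[k] * w10;
    if (i0 >= 0 && i0 < nax && j0 + 1 >= 0 && j0 + 1 < nb)
      out(i0, j0 + 1) += amp[k] * w01;
    if (i0 + 1 >= 0 && i0 + 1 < nax && j0 + 1 >= 0 && j0 + 1 < nb)
      out(i0 + 1, j0 + 1) += amp[k] * w11;
  }
  return out;
}

// Separable 'same' convolution with zero padding (kAx along rows/axial,
// kLat along columns/lateral).
// [[Rcpp::export]]
arma::mat conv_sep_cpp(const arma::mat& img, const arma::vec& kAx,
                       const arma::vec& kLat) {
  const uword nr = img.n_rows, nc = img.n_cols;
  mat tmp(nr, nc);
  for (uword c = 0; c < nc; ++c) tmp.col(c) = conv(img.col(c), kAx, "same");
  mat t2 = tmp.t();
  for (uword r = 0; r < nr; ++r) t2.col(r) = conv(t2.col(r), kLat, "same");
  return t2.t();
}

// Normalized complex cross-correlation over a lag window, at a set of
// estimation points. gs/gb are 1-based kernel-centre sample/beam indices.
// corr is (nG, nLagAx, nLagLat); valid marks in-bounds windows.
// [[Rcpp::export]]
Rcpp::List corr_volume_cpp(const arma::cx_mat& A, const arma::cx_mat& B,
                           const arma::ivec& gs, const arma::ivec& gb,
                           int hk_ax, int hk_lat, int hl_ax, int hl_lat) {
  const int nG = gs.n_elem;
  const int nla = 2 * hl_ax + 1, nll = 2 * hl_lat + 1;
  const int nax = A.n_rows, nb = A.n_cols;
  cx_cube corr(nG, nla, nll, fill::zeros);
  cube valid(nG, nla, nll, fill::zeros);

  for (int g = 0; g < nG; ++g) {
    const int s0 = gs[g] - 1, b0 = gb[g] - 1;
    if (s0 - hk_ax < 0 || s0 + hk_ax >= nax || b0 - hk_lat < 0 ||
        b0 + hk_lat >= nb)
      continue;
    double sumA2 = 0.0;
    for (int c = -hk_lat; c <= hk_lat; ++c)
      for (int r = -hk_ax; r <= hk_ax; ++r)
        sumA2 += std::norm(A(s0 + r, b0 + c));
    if (sumA2 <= 0.0) continue;
    for (int ll = -hl_lat; ll <= hl_lat; ++ll) {
      for (int la = -hl_ax; la <= hl_ax; ++la) {
        const int ss = s0 + la, bb = b0 + ll;
        if (ss - hk_ax < 0 || ss + hk_ax >= nax || bb - hk_lat < 0 ||
            bb + hk_lat >= nb)
          continue;
        std::complex<double> num(0.0, 0.0);
        double sumB2 = 0.0;
        for (int c = -hk_lat; c <= hk_lat; ++c) {
          for (int r = -hk_ax; r <= hk_ax; ++r) {
            const std::complex<double> a = A(s0 + r, b0 + c);
            const std::complex<double> b = B(ss + r, bb + c);
            num += a * std::conj(b);
            sumB2 += std::norm(b);
          }
        }
        if (sumB2 > 0.0) {
          corr(g, la + hl_ax, ll + hl_lat) = num / std::sqrt(sumA2 * sumB2);
          valid(g, la + hl_ax, ll + hl_lat) = 1.0;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("corr") = corr,
                            Rcpp::Named("valid") = valid);
}

// Bilinear interpolation of a gridded field at scattered points (fractional
// 1-based indices); points outside are clamped to the grid edge.
// [[Rcpp::export]]
arma::vec interp2_cpp(const arma::mat& f, const arma::vec& xi,
                      const arma::vec& yi) {
  const int nx = f.n_rows, ny = f.n_cols;
  vec out(xi.n_elem);
  for (uword k = 0; k < xi.n_elem; ++k) {
    double p = xi[k] - 1.0, q = yi[k] - 1.0;
    if (p < 0) p = 0;
    if (p > nx - 1.0) p = nx - 1.0;
    if (q < 0) q = 0;
    if (q > ny - 1.0) q = ny - 1.0;
    int i0 = (int)std::floor(p), j0 = (int)std::floor(q);
    if (i0 > nx - 2) i0 = nx - 2;
    if (j0 > ny - 2) j0 = ny - 2;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    double fr = p - i0, fc = q - j0;
    out[k] = f(i0, j0) * (1 - fr) * (1 - fc) + f(i0 + 1, j0) * fr * (1 - fc) +
             f(i0, j0 + 1) * (1 - fr) * fc + f(i0 + 1, j0 + 1) * fr * fc;
  }
  return out;
}
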