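// Hot loops of the ptychography model: patch extraction/scatter, per-pattern
// orthonormal FFTs, Poisson ML cost and gradient. Everything is double
// precision; stacks are (S, S, n) cubes matching R's column-major arrays.
// Scan positions arrive 0-based (row, col), validated again here so a bad
// caller cannot read out of bounds.
//
// FFTs go through FFTW with one cached plan (and aligned workspace) per
// transform size and direction; patches are copied through the workspace,
// which costs far less than re-planning per call. A square column-major
// matrix can be handed to FFTW's row-major 2-D interface directly because
// the 2-D DFT commutes with transposition.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <fftw3.h>
#include <map>

using namespace arma;

namespace {

struct PlanCache {
  fftw_plan plan = nullptr;
  fftw_complex* buf = nullptr;
  uword S = 0;
};

PlanCache& get_plan(uword S, int sign) {
  static std::map<std::pair<uword, int>, PlanCache> cache;
  PlanCache& pc = cache[{S, sign}];
  if (!pc.plan) {
    pc.S = S;
    pc.buf = fftw_alloc_complex(S * S);
    pc.plan = fftw_plan_dft_2d((int)S, (int)S, pc.buf, pc.buf, sign,
                               FFTW_MEASURE);
  }
  return pc;
}

// in-place orthonormal 2-D DFT of a square S x S block
inline void fft2_ortho(cx_double* x, uword S, int sign) {
  PlanCache& pc = get_plan(S, sign);
  std::memcpy(pc.buf, x, sizeof(cx_double) * S * S);
  fftw_execute(pc.plan);
  const double scale = 1.0 / (double)S;  // unitary: 1/sqrt(S*S)
  const cx_double* b = reinterpret_cast<cx_double*>(pc.buf);
  for (uword k = 0; k < S * S; ++k) x[k] = b[k] * scale;
}

void check_positions(const imat& pos, uword S, uword H, uword W) {
  if (pos.n_cols != 2) Rcpp::stop("positions must be an n x 2 matrix");
  for (uword j = 0; j < pos.n_rows; ++j) {
    const sword r = pos(j, 0), c = pos(j, 1);
    if (r < 0 || c < 0 || r + (sword)S > (sword)H || c + (sword)S > (sword)W)
      Rcpp::stop("scan position %d (row=%d, col=%d) places the %dx%d probe footprint outside the %dx%d object",
                 (int)(j + 1), (int)r, (int)c, (int)S, (int)S, (int)H, (int)W);
  }
}

void check_stack_dims(const cube& d, uword S, uword n) {
  if (d.n_rows != S || d.n_cols != S || d.n_slices != n)
    Rcpp::stop("diffraction stack shape does not match probe/scan geometry");
}

}  // namespace

// [[Rcpp::export(rng = false)]]
arma::cx_cube apply_Q_cpp(const arma::cx_mat& obj, const arma::cx_mat& probe,
                          const arma::imat& pos) {
  const uword S = probe.n_rows, n = pos.n_rows;
  check_positions(pos, S, obj.n_rows, obj.n_cols);
  cx_cube out(S, S, n);
  for (uword j = 0; j < n; ++j) {
    const uword r = pos(j, 0), c = pos(j, 1);
    out.slice(j) = probe % obj.submat(r, c, r + S - 1, c + S - 1);
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
arma::cx_mat apply_QH_cpp(const arma::cx_cube& patches, const arma::cx_mat& probe,
                          const arma::imat& pos, int H, int W) {
  const uword S = probe.n_rows;
  check_positions(pos, S, (uword)H, (uword)W);
  const cx_mat pc = conj(probe);
  cx_mat out((uword)H, (uword)W, fill::zeros);
  for (uword j = 0; j < patches.n_slices; ++j) {
    const uword r = pos(j, 0), c = pos(j, 1);
    out.submat(r, c, r + S - 1, c + S - 1) += pc % patches.slice(j);
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
arma::cx_cube forward_cpp(const arma::cx_mat& obj, const arma::cx_mat& probe,
                          const arma::imat& pos) {
  const uword S = probe.n_rows, n = pos.n_rows;
  check_positions(pos, S, obj.n_rows, obj.n_cols);
  cx_cube out(S, S, n);
  for (uword j = 0; j < n; ++j) {
    const uword r = pos(j, 0), c = pos(j, 1);
    out.slice(j) = probe % obj.submat(r, c, r + S - 1, c + S - 1);
    fft2_ortho(out.slice_memptr(j), S, FFTW_FORWARD);
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
arma::cx_mat adjoint_cpp(const arma::cx_cube& waves, const arma::cx_mat& probe,
                         const arma::imat& pos, int H, int W) {
  const uword S = probe.n_rows;
  check_positions(pos, S, (uword)H, (uword)W);
  const cx_mat pc = conj(probe);
  cx_mat out((uword)H, (uword)W, fill::zeros);
  cx_mat tmp(S, S);
  for (uword j = 0; j < waves.n_slices; ++j) {
    const uword r = pos(j, 0), c = pos(j, 1);
    tmp = waves.slice(j);
    fft2_ortho(tmp.memptr(), S, FFTW_BACKWARD);
    out.submat(r, c, r + S - 1, c + S - 1) += pc % tmp;
  }
  return out;
}

// Poisson ML cost: sum_j sum_px |G psi|^2 - 2 d log|G psi|, |G psi| clamped
// below at eps inside the log; d == 0 pixels contribute the first term only.
// [[Rcpp::export(rng = false)]]
double cost_cpp(const arma::cx_mat& obj, const arma::cx_mat& probe,
                const arma::imat& pos, const arma::cube& d, double eps) {
  const uword S = probe.n_rows, n = pos.n_rows;
  check_positions(pos, S, obj.n_rows, obj.n_cols);
  check_stack_dims(d, S, n);
  double acc = 0.0;
  cx_mat w(S, S);
  for (uword j = 0; j < n; ++j) {
    const uword r = pos(j, 0), c = pos(j, 1);
    w = probe % obj.submat(r, c, r + S - 1, c + S - 1);
    fft2_ortho(w.memptr(), S, FFTW_FORWARD);
    const double* dj = d.slice_memptr(j);
    const cx_double* wj = w.memptr();
    for (uword k = 0; k < S * S; ++k) {
      const double a2 = std::norm(wj[k]);
      acc += a2;
      if (dj[k] > 0.0)
        acc -= dj[k] * std::log(std::max(a2, eps * eps));  // 2 log|w| = log|w|^2
    }
  }
  return acc;
}

// Wirtinger gradient dF/dpsi* = G^H (G psi - d / (G psi)^*); the elementwise
// division keeps the far-field phase and clamps the modulus at eps.
// [[Rcpp::export(rng = false)]]
arma::cx_mat grad_cpp(const arma::cx_mat& obj, const arma::cx_mat& probe,
                      const arma::imat& pos, const arma::cube& d, double eps) {
  const uword S = probe.n_rows, n = pos.n_rows;
  check_positions(pos, S, obj.n_rows, obj.n_cols);
  check_stack_dims(d, S, n);
  const cx_mat pc = conj(probe);
  cx_mat out(obj.n_rows, obj.n_cols, fill::zeros);
  cx_mat w(S, S);
  const double eps2 = eps * eps;
  for (uword j = 0; j < n; ++j) {
    const uword r = pos(j, 0), c = pos(j, 1);
    w = probe % obj.submat(r, c, r + S - 1, c + S - 1);
    fft2_ortho(w.memptr(), S, FFTW_FORWARD);
    const double* dj = d.slice_memptr(j);
    cx_double* wj = w.memptr();
    for (uword k = 0; k < S * S; ++k) {
      // d / conj(w) = d * w / |w|^2, modulus clamped, phase kept
      const double a2 = std::max(std::norm(wj[k]), eps2);
      wj[k] -= dj[k] * wj[k] / a2;
    }
    fft2_ortho(wj, S, FFTW_BACKWARD);
    out.submat(r, c, r + S - 1, c + S - 1) += pc % w;
  }
  return out;
}
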