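// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Kabsch optimal superposition: rotate+translate `mobile` onto `target`
// minimizing RMSD, proper rotation (det +1) enforced.

static double kabsch_one(const arma::mat& A, const arma::mat& B,
                         arma::mat& out) {
  arma::rowvec cA = arma::mean(A, 0), cB = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - cA;
  arma::mat Bc = B.each_row() - cB;
  arma::mat H = Ac.t() * Bc;
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  arma::mat R = U * D * V.t();
  arma::mat AR = Ac * R;
  double rmsd = std::sqrt(arma::accu(arma::square(AR - Bc)) / A.n_rows);
  out = AR.each_row() + cB;
  return rmsd;
}

// [[Rcpp::export]]
List kabsch_superpose_cpp(const arma::mat& mobile, const arma::mat& target) {
  arma::mat out;
  double rmsd = kabsch_one(mobile, target, out);
  return List::create(_["coords"] = out, _["rmsd"] = rmsd);
}

// frames: F x (3n) matrix, row f = (x_1..x_n, y_1..y_n, z_1..z_n)
// target: n x 3 matrix
// [[Rcpp::export]]
List superpose_frames_cpp(const arma::mat& frames, const arma::mat& target) {
  const arma::uword F = frames.n_rows;
  const arma::uword n = target.n_rows;
  arma::mat out(F, 3 * n);
  arma::vec rmsd(F);
  for (arma::uword f = 0; f < F; ++f) {
    arma::mat A(3, n);
    A.row(0) = frames(f, arma::span(0, n - 1));
    A.row(1) = frames(f, arma::span(n, 2 * n - 1));
    A.row(2) = frames(f, arma::span(2 * n, 3 * n - 1));
    arma::mat sup;
    rmsd(f) = kabsch_one(A.t(), target, sup);
    out(f, arma::span(0, n - 1)) = sup.col(0).t();
    out(f, arma::span(n, 2 * n - 1)) = sup.col(1).t();
    out(f, arma::span(2 * n, 3 * n - 1)) = sup.col(2).t();
  }
  return List::create(_["coords"] = out, _["rmsd"] = rmsd);
}

// RMSD of each frame against target without fitting (frames already aligned)
// [[Rcpp::export]]
arma::vec rmsd_nofit_cpp(const arma::mat& frames, const arma::mat& target,
                         const arma::uvec& atom_idx0) {
  const arma::uword F = frames.n_rows;
  const arma::uword n = target.n_rows; // full atom count of frames
  const arma::uword k = atom_idx0.n_elem;
  arma::vec out(F);
  for (arma::uword f = 0; f < F; ++f) {
    double ss = 0.0;
    for (arma::uword a = 0; a < k; ++a) {
      arma::uword i = atom_idx0(a);
      double dx = frames(f, i) - target(i, 0);
      double dy = frames(f, n + i) - target(i, 1);
      double dz = frames(f, 2 * n + i) - target(i, 2);
      ss += dx * dx + dy * dy + dz * dz;
    }
    out(f) = std::sqrt(ss / k);
  }
  return out;
}
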