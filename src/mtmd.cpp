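// Core numerical kernels: internal-coordinate derivatives (hyper-dual AD),
// molecular force fields with periodic cells, diatomic mass-matrix blocks,
// and block-diagonal linear algebra used by the integrator.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "hyperdual.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// internal coordinates
// ---------------------------------------------------------------------------

// evaluate one internal coordinate from hyper-dual atom positions
// type: 0 = bond length, 1 = angle, 2 = dihedral
static HD eval_coord_hd(int type, const HD3 *p) {
  if (type == 0) {
    return hd3_norm(hd3_sub(p[1], p[0]));
  } else if (type == 1) {
    HD3 u = hd3_sub(p[0], p[1]);
    HD3 v = hd3_sub(p[2], p[1]);
    HD c = hd3_dot(u, v) / (hd3_norm(u) * hd3_norm(v));
    return hd_acos(c);
  } else {
    HD3 b1 = hd3_sub(p[1], p[0]);
    HD3 b2 = hd3_sub(p[2], p[1]);
    HD3 b3 = hd3_sub(p[3], p[2]);
    HD3 n1 = hd3_cross(b1, b2);
    HD3 n2 = hd3_cross(b2, b3);
    HD y = hd3_dot(hd3_cross(n1, n2), b2) / hd3_norm(b2);
    HD x = hd3_dot(n1, n2);
    return hd_atan2(y, x);
  }
}

static int coord_natoms(int type) { return type == 0 ? 2 : (type == 1 ? 3 : 4); }

// set up HD positions for one coordinate with probe directions a and b
// (local variable indices within the 3*k variables of the involved atoms)
static void fill_hd_positions(const double *x, const int *at, int k, int a, int b,
                              HD3 *p) {
  for (int m = 0; m < k; ++m) {
    double vx = x[3 * at[m]], vy = x[3 * at[m] + 1], vz = x[3 * at[m] + 2];
    p[m].x = HD(vx);
    p[m].y = HD(vy);
    p[m].z = HD(vz);
  }
  if (a >= 0) {
    HD *slot = (a % 3 == 0) ? &p[a / 3].x : (a % 3 == 1 ? &p[a / 3].y : &p[a / 3].z);
    slot->d1 = 1.0;
  }
  if (b >= 0) {
    HD *slot = (b % 3 == 0) ? &p[b / 3].x : (b % 3 == 1 ? &p[b / 3].y : &p[b / 3].z);
    slot->d2 = 1.0;
  }
}

// Values, Wilson B matrix and (optionally) per-coordinate second derivative
// matrices for a list of internal coordinates over positions x (length 3n).
// atoms: nq x 4 matrix of 0-based atom indices into x (-1 padded).
// [[Rcpp::export]]
List eval_internals_cpp(NumericVector x, IntegerVector type, IntegerMatrix atoms,
                        bool second) {
  int nq = type.size();
  int n3 = x.size();
  NumericVector values(nq);
  NumericMatrix B(nq, n3);
  List d2list(nq), vidx(nq);
  const double *xp = REAL(x);

  HD3 p[4];
  int at[4];
  for (int q = 0; q < nq; ++q) {
    int k = coord_natoms(type[q]);
    for (int m = 0; m < k; ++m) at[m] = atoms(q, m);
    int nv = 3 * k;
    IntegerVector vi(nv);
    for (int m = 0; m < k; ++m)
      for (int c = 0; c < 3; ++c) vi[3 * m + c] = 3 * at[m] + c;

    NumericMatrix H2(second ? nv : 0, second ? nv : 0);
    // gradient (and value) from paired single-direction evaluations
    for (int a = 0; a < nv; a += 2) {
      int b = (a + 1 < nv) ? a + 1 : -1;
      fill_hd_positions(xp, at, k, a, b, p);
      HD r = eval_coord_hd(type[q], p);
      if (a == 0) values[q] = r.f;
      B(q, vi[a]) = r.d1;
      if (b >= 0) B(q, vi[b]) = r.d2;
      if (second && b >= 0) { H2(a, b) = r.d12; H2(b, a) = r.d12; }
    }
    if (second) {
      for (int a = 0; a < nv; ++a) {
        for (int b = a; b < nv; ++b) {
          if (b == a + 1 && a % 2 == 0) continue;  // already done above
          fill_hd_positions(xp, at, k, a, b, p);
          HD r = eval_coord_hd(type[q], p);
          H2(a, b) = r.d12;
          H2(b, a) = r.d12;
        }
      }
      d2list[q] = H2;
    }
    vidx[q] = vi;
  }
  List out = List::create(_["values"] = values, _["B"] = B, _["vidx"] = vidx);
  if (second) out["d2q"] = d2list;
  return out;
}

// ---------------------------------------------------------------------------
// force field kernel: harmonic bonds + harmonic angles (intramolecular)
// and Lennard-Jones between atoms of different molecules (minimum image)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List ff_kernel_cpp(const arma::mat &s, const arma::mat &h, const arma::imat &bonds,
                   const arma::vec &bond_k, const arma::vec &bond_r0,
                   const arma::imat &angles, const arma::vec &ang_k,
                   const arma::vec &ang_0, const arma::ivec &molid, double eps,
                   double rm, double cutoff, double ushift) {
  int N = s.n_cols;
  arma::mat x = h * s;
  arma::mat gx(3, N, arma::fill::zeros);       // total dU/dx
  arma::mat gxi(3, N, arma::fill::zeros);      // intramolecular part (for dU/dh)
  arma::mat dUdh(3, 3, arma::fill::zeros);
  double U = 0.0;

  // bonds: positions taken as whole molecules (no minimum image)
  for (arma::uword b = 0; b < bonds.n_cols; ++b) {
    int i = bonds(0, b), j = bonds(1, b);
    arma::vec u = x.col(j) - x.col(i);
    double r = arma::norm(u);
    double dr = r - bond_r0(b);
    U += 0.5 * bond_k(b) * dr * dr;
    arma::vec g = bond_k(b) * dr * (u / r);
    gxi.col(j) += g;
    gxi.col(i) -= g;
  }

  // harmonic angles
  for (arma::uword a = 0; a < angles.n_cols; ++a) {
    int i = angles(0, a), j = angles(1, a), k = angles(2, a);
    arma::vec u = x.col(i) - x.col(j);
    arma::vec v = x.col(k) - x.col(j);
    double nu = arma::norm(u), nv = arma::norm(v);
    arma::vec uh = u / nu, vh = v / nv;
    double c = arma::dot(uh, vh);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double st = std::sqrt(1.0 - c * c);
    if (st < 1e-10) st = 1e-10;
    double dth = th - ang_0(a);
    U += 0.5 * ang_k(a) * dth * dth;
    arma::vec gi = (c * uh - vh) / (nu * st);
    arma::vec gk = (c * vh - uh) / (nv * st);
    arma::vec gj = -(gi + gk);
    gxi.col(i) += ang_k(a) * dth * gi;
    gxi.col(j) += ang_k(a) * dth * gj;
    gxi.col(k) += ang_k(a) * dth * gk;
  }

  // Lennard-Jones over intermolecular pairs, minimum image in fractional space
  double rc2 = cutoff * cutoff;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (molid(i) == molid(j)) continue;
      arma::vec ds = s.col(i) - s.col(j);
      ds -= arma::round(ds);
      arma::vec r = h * ds;
      double r2 = arma::dot(r, r);
      if (r2 >= rc2) continue;
      double rn = std::sqrt(r2);
      double p6 = std::pow(rm / rn, 6);
      double p12 = p6 * p6;
      U += eps * (p12 - 2.0 * p6) - ushift;
      double dudr = -12.0 * eps * (p12 - p6) / rn;
      arma::vec g = dudr * (r / rn);
      gx.col(i) += g;
      gx.col(j) -= g;
      dUdh += g * ds.t();
    }
  }

  dUdh += gxi * s.t();
  gx += gxi;
  return List::create(_["U"] = U, _["gx"] = gx, _["dU_dh"] = dUdh);
}

// ---------------------------------------------------------------------------
// diatomic mass-matrix blocks (mode-resolved decomposition)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List diatomic_blocks_cpp(const arma::mat &x, const arma::imat &bonds, double mt,
                         double mr, double mv, bool deriv) {
  int nb = bonds.n_cols;
  arma::cube A(6, 6, nb);
  NumericVector dA(deriv ? 6 * 6 * 6 * nb : 0);
  double *dp = deriv ? REAL(dA) : nullptr;

  arma::mat I3 = arma::eye(3, 3);
  for (int b = 0; b < nb; ++b) {
    int i = bonds(0, b), j = bonds(1, b);
    arma::vec u = x.col(j) - x.col(i);
    double r = arma::norm(u);
    arma::vec d = u / r;
    arma::mat D = d * d.t();
    // plus/minus 2x2 mode structure of the Kronecker construction
    arma::mat block(6, 6);
    arma::mat Tt = 0.5 * mt * I3;           // translational, [[1,1],[1,1]]/2
    arma::mat Rr = 0.5 * mr * (I3 - D);     // rotational,    [[1,-1],[-1,1]]/2
    arma::mat Vv = 0.5 * mv * D;            // vibrational
    arma::mat diag3 = Tt + Rr + Vv;
    arma::mat off3 = Tt - Rr - Vv;
    block.submat(0, 0, 2, 2) = diag3;
    block.submat(3, 3, 5, 5) = diag3;
    block.submat(0, 3, 2, 5) = off3;
    block.submat(3, 0, 5, 2) = off3;
    A.slice(b) = block;

    if (deriv) {
      // dD/dx_{j,a} = (e_a d^T + d e_a^T - 2 d_a D)/r ; dD/dx_i = -dD/dx_j
      for (int k = 0; k < 6; ++k) {
        int a = k % 3;
        double sign = (k < 3) ? -1.0 : 1.0;
        arma::mat dD(3, 3, arma::fill::zeros);
        for (int c = 0; c < 3; ++c) {
          dD(a, c) += d(c);
          dD(c, a) += d(c);
        }
        dD -= 2.0 * d(a) * D;
        dD *= sign / r;
        arma::mat ddiag = 0.5 * (mv - mr) * dD;
        arma::mat doff = -ddiag;
        // layout (6, 6, 6, nb)
        for (int cj = 0; cj < 3; ++cj) {
          for (int ci = 0; ci < 3; ++ci) {
            double vdiag = ddiag(ci, cj), voff = doff(ci, cj);
            dp[(ci) + 6 * ((cj) + 6 * (k + 6 * b))] = vdiag;
            dp[(ci + 3) + 6 * ((cj + 3) + 6 * (k + 6 * b))] = vdiag;
            dp[(ci) + 6 * ((cj + 3) + 6 * (k + 6 * b))] = voff;
            dp[(ci + 3) + 6 * ((cj) + 6 * (k + 6 * b))] = voff;
          }
        }
      }
    }
  }
  List out = List::create(_["A"] = A);
  if (deriv) {
    dA.attr("dim") = IntegerVector::create(6, 6, 6, nb);
    out["dA"] = dA;
  }
  return out;
}

// ---------------------------------------------------------------------------
// internal-coordinate Hessian mass-matrix blocks: A = w B^T Hq0 B + Mp
// ---------------------------------------------------------------------------

// mols: list per molecule with elements
//   vidx  : 0-based indices of the molecule's Cartesian variables in x (length d)
//   type  : coordinate types, catoms: nq x 4 local atom indices
//   Hq0   : nq x nq reference Hessian in internal coordinates
//   Mp    : d x d constant base mass matrix
// [[Rcpp::export]]
List internal_mass_blocks_cpp(NumericVector x, List mols, double w, bool deriv) {
  int nmol = mols.size();
  List first = mols[0];
  int d = as<IntegerVector>(first["vidx"]).size();
  arma::cube A(d, d, nmol);
  NumericVector dA(deriv ? d * d * d * nmol : 0);
  double *dp = deriv ? REAL(dA) : nullptr;
  const double *xp = REAL(x);

  for (int m = 0; m < nmol; ++m) {
    List mol = mols[m];
    IntegerVector vidx = mol["vidx"];
    IntegerVector type = mol["type"];
    IntegerMatrix catoms = mol["catoms"];
    arma::mat Hq0 = as<arma::mat>(mol["Hq0"]);
    arma::mat Mp = as<arma::mat>(mol["Mp"]);
    int nq = type.size();

    NumericVector xloc(d);
    for (int i = 0; i < d; ++i) xloc[i] = xp[vidx[i]];

    List ev = eval_internals_cpp(xloc, type, catoms, deriv);
    arma::mat B = as<arma::mat>(ev["B"]);  // nq x d
    arma::mat P = Hq0 * B;                 // nq x d
    arma::mat Am = w * B.t() * P + Mp;
    A.slice(m) = 0.5 * (Am + Am.t());

    if (deriv) {
      List d2list = ev["d2q"];
      List vloc = ev["vidx"];
      double *base = dp + (size_t)d * d * d * m;
      std::fill(base, base + (size_t)d * d * d, 0.0);
      for (int q = 0; q < nq; ++q) {
        NumericMatrix H2 = d2list[q];
        IntegerVector vi = vloc[q];  // indices into local d variables
        int nv = vi.size();
        // dA_k += w (dBk^T P + P^T dBk), dBk(q, j) = H2(j, k)
        for (int kk = 0; kk < nv; ++kk) {
          int k = vi[kk];
          double *slab = base + (size_t)d * d * k;
          for (int jj = 0; jj < nv; ++jj) {
            int j = vi[jj];
            double hv = w * H2(jj, kk);
            if (hv == 0.0) continue;
            for (int l = 0; l < d; ++l) {
              double contrib = hv * P(q, l);
              slab[j + d * l] += contrib;
              slab[l + d * j] += contrib;
            }
          }
        }
      }
    }
  }
  List out = List::create(_["A"] = A);
  if (deriv) {
    dA.attr("dim") = IntegerVector::create(d, d, d, nmol);
    out["dA"] = dA;
  }
  return out;
}

// ---------------------------------------------------------------------------
// block-diagonal helpers (blocks of equal size d, one per molecule)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube cube_inv_cpp(const arma::cube &A) {
  arma::cube out(A.n_rows, A.n_cols, A.n_slices);
  for (arma::uword b = 0; b < A.n_slices; ++b)
    out.slice(b) = arma::inv_sympd(arma::symmatu(A.slice(b)));
  return out;
}

// [[Rcpp::export]]
double cube_logdet_cpp(const arma::cube &A) {
  double s = 0.0;
  for (arma::uword b = 0; b < A.n_slices; ++b) {
    double val, sign;
    arma::log_det(val, sign, arma::symmatu(A.slice(b)));
    s += val;
  }
  return s;
}

// Y_b = M_b X_b  for X arranged as (d x nb)
// [[Rcpp::export]]
arma::mat block_apply_cpp(const arma::cube &M, const arma::mat &X) {
  arma::mat out(X.n_rows, X.n_cols);
  for (arma::uword b = 0; b < M.n_slices; ++b)
    out.col(b) = M.slice(b) * X.col(b);
  return out;
}

// Q(k, b) = z_b^T dA[,,k,b] z_b    (dA has dim (d, d, d, nb))
// [[Rcpp::export]]
arma::mat block_quad_cpp(NumericVector dA, const arma::mat &z) {
  IntegerVector dim = dA.attr("dim");
  int d = dim[0], dloc = dim[2], nb = dim[3];
  const double *dp = REAL(dA);
  arma::mat Q(dloc, nb, arma::fill::zeros);
  for (int b = 0; b < nb; ++b) {
    const double *zb = z.colptr(b);
    for (int k = 0; k < dloc; ++k) {
      const double *slab = dp + (size_t)d * d * (k + (size_t)dloc * b);
      double acc = 0.0;
      for (int j = 0; j < d; ++j) {
        double zj = zb[j];
        if (zj == 0.0) continue;
        const double *col = slab + (size_t)d * j;
        double inner = 0.0;
        for (int i = 0; i < d; ++i) inner += col[i] * zb[i];
        acc += zj * inner;
      }
      Q(k, b) = acc;
    }
  }
  return Q;
}

// T(k, b) = tr(Ainv_b dA[,,k,b])
// [[Rcpp::export]]
arma::mat block_trace_cpp(NumericVector dA, const arma::cube &Ainv) {
  IntegerVector dim = dA.attr("dim");
  int d = dim[0], dloc = dim[2], nb = dim[3];
  const double *dp = REAL(dA);
  arma::mat T(dloc, nb, arma::fill::zeros);
  for (int b = 0; b < nb; ++b) {
    const arma::mat &Ai = Ainv.slice(b);
    for (int k = 0; k < dloc; ++k) {
      const double *slab = dp + (size_t)d * d * (k + (size_t)dloc * b);
      double acc = 0.0;
      for (int j = 0; j < d; ++j) {
        const double *col = slab + (size_t)d * j;
        for (int i = 0; i < d; ++i) acc += Ai(j, i) * col[i];
      }
      T(k, b) = acc;
    }
  }
  return T;
}

// J_b[, k] = Ainv_b (dA[,,k,b] z_b): block Jacobian pieces, cube (d, dloc, nb)
// [[Rcpp::export]]
arma::cube block_jac_cpp(NumericVector dA, const arma::cube &Ainv,
                         const arma::mat &z) {
  IntegerVector dim = dA.attr("dim");
  int d = dim[0], dloc = dim[2], nb = dim[3];
  const double *dp = REAL(dA);
  arma::cube J(d, dloc, nb);
  arma::vec tmp(d);
  for (int b = 0; b < nb; ++b) {
    const double *zb = z.colptr(b);
    for (int k = 0; k < dloc; ++k) {
      const double *slab = dp + (size_t)d * d * (k + (size_t)dloc * b);
      tmp.zeros();
      for (int j = 0; j < d; ++j) {
        double zj = zb[j];
        if (zj == 0.0) continue;
        const double *col = slab + (size_t)d * j;
        for (int i = 0; i < d; ++i) tmp(i) += col[i] * zj;
      }
      J.slice(b).col(k) = Ainv.slice(b) * tmp;
    }
  }
  return J;
}

// solve D_b x_b = X_b per slice (general square blocks)
// [[Rcpp::export]]
arma::mat cube_solve_cpp(const arma::cube &D, const arma::mat &X) {
  arma::mat out(X.n_rows, X.n_cols);
  for (arma::uword b = 0; b < D.n_slices; ++b)
    out.col(b) = arma::solve(D.slice(b), X.col(b));
  return out;
}

// Per-slice congruence-like transform: rows of each block are grouped in
// threes (atoms) and multiplied by hl; column groups are multiplied by hr.
// [[Rcpp::export]]
arma::cube block_sandwich_cpp(const arma::cube &K, const arma::mat &hl,
                              const arma::mat &hr) {
  int d = K.n_rows, nb = K.n_slices, natm = d / 3;
  arma::cube out(d, d, nb);
  for (int b = 0; b < nb; ++b) {
    arma::mat tmp(d, d);
    for (int m = 0; m < natm; ++m)
      tmp.rows(3 * m, 3 * m + 2) = hl * K.slice(b).rows(3 * m, 3 * m + 2);
    for (int m = 0; m < natm; ++m)
      out.slice(b).cols(3 * m, 3 * m + 2) =
          tmp.cols(3 * m, 3 * m + 2) * hr;
  }
  return out;
}

// C_b = sum_k dA[,,k,b] * W(k, b): directional derivative of each block
// [[Rcpp::export]]
arma::cube block_contract_cpp(NumericVector dA, const arma::mat &W) {
  IntegerVector dim = dA.attr("dim");
  int d = dim[0], dloc = dim[2], nb = dim[3];
  const double *dp = REAL(dA);
  arma::cube out(d, d, nb, arma::fill::zeros);
  for (int b = 0; b < nb; ++b) {
    for (int k = 0; k < dloc; ++k) {
      double wv = W(k, b);
      if (wv == 0.0) continue;
      const double *slab = dp + (size_t)d * d * (k + (size_t)dloc * b);
      double *op = out.slice(b).memptr();
      for (int ij = 0; ij < d * d; ++ij) op[ij] += wv * slab[ij];
    }
  }
  return out;
}

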