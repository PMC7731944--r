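#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Projected gradient (optionally FISTA-accelerated with function-value
// restart) on the Lagrangian dual of the fusion-penalized least-squares
// problem. Dual blocks for mode d are stored row-major as an |E_d| x n_{-d}
// array.
//
// All edge-difference work happens in a per-mode scratch layout where the
// mode-d subarray a occupies a contiguous block of n_{-d} doubles, so each
// edge touches two contiguous runs. Moving between the column-major tensor
// vectorization and that layout is a block permutation: with stride
// s_d = prod_{j<d} n_j and hop = s_d * n_d, the (a, c_high) block of length
// s_d sits at a*s_d + c_high*hop in the vectorization and at
// a*n_{-d} + c_high*s_d in the scratch layout.

namespace {

struct ModeOps {
  long nd;
  long stride;        // prod of earlier mode lengths
  long nouter;        // prod of later mode lengths
  long ncol;          // n_{-d} = stride * nouter
  std::vector<int> head, tail;  // 0-based edge endpoints
  std::vector<double> radii;    // gamma * w
};

std::vector<ModeOps> build_modes(const IntegerVector& dims, const List& edges,
                                 const List& weights, double gamma, long n) {
  const int D = dims.size();
  std::vector<ModeOps> modes(D);
  long stride = 1;
  for (int d = 0; d < D; ++d) {
    IntegerMatrix e = edges[d];
    NumericVector w = weights[d];
    ModeOps& m = modes[d];
    m.nd = dims[d];
    m.stride = stride;
    m.ncol = n / dims[d];
    m.nouter = m.ncol / stride;
    m.head.resize(e.nrow());
    m.tail.resize(e.nrow());
    m.radii.resize(e.nrow());
    for (int l = 0; l < e.nrow(); ++l) {
      m.head[l] = e(l, 0) - 1;
      m.tail[l] = e(l, 1) - 1;
      m.radii[l] = gamma * w[l];
    }
    stride *= dims[d];
  }
  return modes;
}

// vectorization -> fiber-contiguous scratch
void permute_to(const double* u, double* Ud, const ModeOps& m) {
  const long hop = m.stride * m.nd;
  if (m.stride >= 8) {
    for (long a = 0; a < m.nd; ++a) {
      for (long ch = 0; ch < m.nouter; ++ch) {
        std::memcpy(Ud + a * m.ncol + ch * m.stride,
                    u + a * m.stride + ch * hop,
                    sizeof(double) * m.stride);
      }
    }
  } else {
    for (long a = 0; a < m.nd; ++a) {
      double* dst = Ud + a * m.ncol;
      const double* base = u + a * m.stride;
      for (long ch = 0; ch < m.nouter; ++ch) {
        const double* src = base + ch * hop;
        for (long cl = 0; cl < m.stride; ++cl) dst[ch * m.stride + cl] = src[cl];
      }
    }
  }
}

// scratch -> vectorization, accumulating with sign
void accumulate_from(const double* Gd, double* out, const ModeOps& m,
                     double sign) {
  const long hop = m.stride * m.nd;
  for (long a = 0; a < m.nd; ++a) {
    const double* src = Gd + a * m.ncol;
    double* base = out + a * m.stride;
    for (long ch = 0; ch < m.nouter; ++ch) {
      double* dst = base + ch * hop;
      const double* s = src + ch * m.stride;
      for (long cl = 0; cl < m.stride; ++cl) dst[cl] += sign * s[cl];
    }
  }
}

// out += sign * A^T lambda using a scratch buffer G (length n)
void add_at_lambda(std::vector<double>& out,
                   const std::vector<ModeOps>& modes,
                   const std::vector<std::vector<double>>& lambda,
                   double sign, std::vector<double>& G) {
  for (size_t d = 0; d < modes.size(); ++d) {
    const ModeOps& m = modes[d];
    if (m.head.empty()) continue;
    std::fill(G.begin(), G.end(), 0.0);
    for (size_t l = 0; l < m.head.size(); ++l) {
      const double* row = lambda[d].data() + l * m.ncol;
      double* gh = G.data() + (long)m.head[l] * m.ncol;
      double* gt = G.data() + (long)m.tail[l] * m.ncol;
      for (long c = 0; c < m.ncol; ++c) {
        gh[c] += row[c];
        gt[c] -= row[c];
      }
    }
    accumulate_from(G.data(), out.data(), m, sign);
  }
}

double sq_norm(const std::vector<double>& v) {
  double s = 0.0;
  for (double x : v) s += x * x;
  return s;
}

} // namespace

// applies sum_d A_d^T A_d to a vector (used by the power-iteration step
// bound); returns the result
// [[Rcpp::export(name = ".coco_ata_apply")]]
NumericVector coco_ata_apply(NumericVector v, IntegerVector dims, List edges) {
  const long n = v.size();
  const int D = dims.size();
  List unit_w(D);
  for (int d = 0; d < D; ++d) {
    IntegerMatrix e = edges[d];
    unit_w[d] = NumericVector(e.nrow(), 1.0);
  }
  std::vector<ModeOps> modes = build_modes(dims, edges, unit_w, 1.0, n);
  std::vector<double> vin(v.begin(), v.end()), out(n, 0.0);
  std::vector<double> Ud(n), Gd(n);
  for (int d = 0; d < D; ++d) {
    const ModeOps& m = modes[d];
    if (m.head.empty()) continue;
    permute_to(vin.data(), Ud.data(), m);
    std::fill(Gd.begin(), Gd.end(), 0.0);
    for (size_t l = 0; l < m.head.size(); ++l) {
      const double* vh = Ud.data() + (long)m.head[l] * m.ncol;
      const double* vt = Ud.data() + (long)m.tail[l] * m.ncol;
      double* gh = Gd.data() + (long)m.head[l] * m.ncol;
      double* gt = Gd.data() + (long)m.tail[l] * m.ncol;
      for (long c = 0; c < m.ncol; ++c) {
        double diff = vh[c] - vt[c];
        gh[c] += diff;
        gt[c] -= diff;
      }
    }
    accumulate_from(Gd.data(), out.data(), m, 1.0);
  }
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".coco_dual_pg")]]
List coco_dual_pg(NumericVector xvec, IntegerVector dims, List edges,
                  List weights, double gamma, double eta, int max_iter,
                  double tol, bool accelerate, int check_every,
                  Nullable<List> lambda0) {
  const long n = xvec.size();
  const int D = dims.size();
  std::vector<ModeOps> modes = build_modes(dims, edges, weights, gamma, n);
  std::vector<double> x(xvec.begin(), xvec.end());

  // dual blocks, row-major per mode
  std::vector<std::vector<double>> lambda(D), momentum(D), new_lambda(D);
  for (int d = 0; d < D; ++d) {
    size_t sz = modes[d].head.size() * (size_t)modes[d].ncol;
    lambda[d].assign(sz, 0.0);
    if (lambda0.isNotNull()) {
      List l0(lambda0);
      NumericMatrix L0 = l0[d];  // public convention: n_{-d} x |E_d|
      for (size_t l = 0; l < modes[d].head.size(); ++l) {
        // project the warm start onto the current feasible set
        double nrm = 0.0;
        for (long c = 0; c < modes[d].ncol; ++c) {
          double v = L0((int)c, (int)l);
          nrm += v * v;
        }
        nrm = std::sqrt(nrm);
        double scale = (nrm > modes[d].radii[l] && nrm > 0.0)
                           ? modes[d].radii[l] / nrm : 1.0;
        for (long c = 0; c < modes[d].ncol; ++c) {
          lambda[d][l * modes[d].ncol + c] = scale * L0((int)c, (int)l);
        }
      }
    }
    momentum[d] = lambda[d];
    new_lambda[d] = lambda[d];
  }

  const double x_sq = sq_norm(x);
  std::vector<double> u(n), res(n), G(n), Ud(n);
  double t_acc = 1.0, obj_prev = -INFINITY;
  double gap = INFINITY, F_val = NA_REAL, G_val = NA_REAL;
  int iters = 0;
  bool converged = false;

  for (int m_it = 1; m_it <= max_iter; ++m_it) {
    iters = m_it;
    const std::vector<std::vector<double>>& base = accelerate ? momentum : lambda;

    // u = x - A^T base
    u.assign(x.begin(), x.end());
    add_at_lambda(u, modes, base, -1.0, G);
    for (long p = 0; p < n; ++p) {
      if (!std::isfinite(u[p])) stop("non-finite values encountered in solver");
    }

    // gradient step + per-block ball projection, mode by mode on the
    // fiber-contiguous copy of u
    for (int d = 0; d < D; ++d) {
      ModeOps& m = modes[d];
      if (m.head.empty()) continue;
      permute_to(u.data(), Ud.data(), m);
      const std::vector<double>& b = base[d];
      std::vector<double>& nl = new_lambda[d];
      for (size_t l = 0; l < m.head.size(); ++l) {
        double* row = nl.data() + l * m.ncol;
        const double* brow = b.data() + l * m.ncol;
        const double* uh = Ud.data() + (long)m.head[l] * m.ncol;
        const double* ut = Ud.data() + (long)m.tail[l] * m.ncol;
        double nrm = 0.0;
        for (long c = 0; c < m.ncol; ++c) {
          double v = brow[c] + eta * (uh[c] - ut[c]);
          row[c] = v;
          nrm += v * v;
        }
        nrm = std::sqrt(nrm);
        if (nrm > m.radii[l] && nrm > 0.0) {
          double scale = m.radii[l] / nrm;
          for (long c = 0; c < m.ncol; ++c) row[c] *= scale;
        }
      }
    }

    if (accelerate) {
      // function-value restart on the dual objective
      res.assign(x.begin(), x.end());
      add_at_lambda(res, modes, new_lambda, -1.0, G);
      double obj = -0.5 * sq_norm(res);
      if (obj < obj_prev) {
        t_acc = 1.0;
        for (int d = 0; d < D; ++d) momentum[d] = lambda[d];
        obj_prev = -INFINITY;
        continue;
      }
      obj_prev = obj;
      double t_new = (1.0 + std::sqrt(1.0 + 4.0 * t_acc * t_acc)) / 2.0;
      double coef = (t_acc - 1.0) / t_new;
      for (int d = 0; d < D; ++d) {
        std::vector<double>& mo = momentum[d];
        const std::vector<double>& nl = new_lambda[d];
        const std::vector<double>& la = lambda[d];
        for (size_t q = 0; q < nl.size(); ++q) {
          mo[q] = nl[q] + coef * (nl[q] - la[q]);
        }
      }
      t_acc = t_new;
    }
    for (int d = 0; d < D; ++d) lambda[d].swap(new_lambda[d]);

    if (m_it % check_every == 0 || m_it == max_iter) {
      // duality gap at the current (projected, feasible) iterate
      u.assign(x.begin(), x.end());
      add_at_lambda(u, modes, lambda, -1.0, G);
      double fit = 0.0;
      for (long p = 0; p < n; ++p) {
        double r = x[p] - u[p];
        fit += r * r;
      }
      double pen = 0.0;
      for (int d = 0; d < D; ++d) {
        ModeOps& m = modes[d];
        if (m.head.empty()) continue;
        permute_to(u.data(), Ud.data(), m);
        for (size_t l = 0; l < m.head.size(); ++l) {
          const double* uh = Ud.data() + (long)m.head[l] * m.ncol;
          const double* ut = Ud.data() + (long)m.tail[l] * m.ncol;
          double nrm = 0.0;
          for (long c = 0; c < m.ncol; ++c) {
            double diff = uh[c] - ut[c];
            nrm += diff * diff;
          }
          pen += m.radii[l] * std::sqrt(nrm);  // radii already = gamma * w
        }
      }
      F_val = 0.5 * fit + pen;
      G_val = 0.5 * x_sq - 0.5 * sq_norm(u);
      gap = (F_val - G_val) / std::max(1.0, std::fabs(F_val));
      if (gap <= tol) {
        converged = true;
        break;
      }
    }
  }

  // final primal recovery and per-edge norms
  u.assign(x.begin(), x.end());
  add_at_lambda(u, modes, lambda, -1.0, G);
  List lam_out(D), diff_out(D), dual_out(D);
  for (int d = 0; d < D; ++d) {
    ModeOps& m = modes[d];
    int ne = (int)m.head.size();
    NumericMatrix L((int)m.ncol, ne);  // column-major public convention
    NumericVector dn(ne), ln(ne);
    if (ne > 0) {
      permute_to(u.data(), Ud.data(), m);
      for (int l = 0; l < ne; ++l) {
        const double* uh = Ud.data() + (long)m.head[l] * m.ncol;
        const double* ut = Ud.data() + (long)m.tail[l] * m.ncol;
        const double* lrow = lambda[d].data() + (size_t)l * m.ncol;
        double nrm_d = 0.0, nrm_l = 0.0;
        for (long c = 0; c < m.ncol; ++c) {
          double diff = uh[c] - ut[c];
          nrm_d += diff * diff;
          nrm_l += lrow[c] * lrow[c];
          L((int)c, l) = lrow[c];
        }
        dn[l] = std::sqrt(nrm_d);
        ln[l] = std::sqrt(nrm_l);
      }
    }
    lam_out[d] = L;
    diff_out[d] = dn;
    dual_out[d] = ln;
  }
  NumericVector u_out(u.begin(), u.end());
  return List::create(_["u"] = u_out, _["lambda"] = lam_out,
                      _["diff_norms"] = diff_out, _["dual_norms"] = dual_out,
                      _["iterations"] = iters, _["gap"] = gap,
                      _["converged"] = converged, _["primal"] = F_val,
                      _["dual"] = G_val);
}
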