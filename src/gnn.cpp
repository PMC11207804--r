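// Bottom-up bond-substructure graph attention network: forward pass and
// analytic backpropagation.
//
// The network (per molecule):
//   Module 1 (complete / convolutional variants): for each bond class
//     k in {single, double, triple, aromatic}, two stacked multi-head graph
//     attention layers on the class adjacency A_k (first concatenated,
//     second head-averaged), then a masked sum over the four branches gated
//     by diag(A_k).
//   Module 2: multi-head attention (concatenated) on the full adjacency
//     A_1 - or a symmetric-normalized graph convolution in the
//     "convolutional" ablation - followed by gated global attention pooling.
//   Module 3: batch normalization + MLP with LeakyReLU hidden units and a
//     single linear (regression) or sigmoid (classification) output.
//
// Parameters travel as one flat vector; `layout` maps parameter names to
// (offset, nrow, ncol) triplets so R and C++ share a single canonical
// packing (see model_layout() on the R side). Gradients are returned in the
// same flat layout. Correctness of every backward formula is checked
// against numerical differentiation in the test suite.

#include <RcppArmadillo.h>
#include <array>
#include <string>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static inline double lrelu(double x, double s) { return x > 0 ? x : s * x; }
static inline double dlrelu(double x, double s) { return x > 0 ? 1.0 : s; }

static mat lrelu_mat(const mat& x, double s) {
  mat out = x;
  out.transform([s](double v) { return lrelu(v, s); });
  return out;
}

static mat dlrelu_mat(const mat& x, double s) {
  mat out = x;
  out.transform([s](double v) { return dlrelu(v, s); });
  return out;
}

// ---------------------------------------------------------------------------
// Flat parameter access

class ParamView {
 public:
  ParamView(double* base, const List& layout) : base_(base) {
    CharacterVector nm = layout.names();
    for (int i = 0; i < layout.size(); ++i) {
      IntegerVector d = layout[i];
      info_[as<std::string>(nm[i])] = {d[0], d[1], d[2]};
    }
  }
  // writable views into the flat buffer (no copy)
  mat m(const std::string& name) {
    const std::array<int, 3>& d = at(name);
    return mat(base_ + d[0], d[1], d[2], false, true);
  }
  vec v(const std::string& name) {
    const std::array<int, 3>& d = at(name);
    return vec(base_ + d[0], d[1], false, true);
  }
  bool has(const std::string& name) const { return info_.count(name) > 0; }

 private:
  const std::array<int, 3>& at(const std::string& name) const {
    auto it = info_.find(name);
    if (it == info_.end())
      stop("internal error: parameter '" + name + "' missing from layout");
    return it->second;
  }
  double* base_;
  std::map<std::string, std::array<int, 3>> info_;
};

// ---------------------------------------------------------------------------
// Graph attention head

struct HeadCache {
  mat Z;    // N x F transformed features
  mat lam;  // N x N attention weights (0 where no edge)
  mat u;    // N x N pre-activation attention logits
  mat s;    // N x F pre-activation aggregated features
};

// Forward pass of one attention head given already-transformed features Z.
// Neighborhoods are the nonzero entries of each row of A (self included when
// the diagonal entry is set); rows with empty neighborhoods yield zeros.
static mat gat_head_forward(const mat& Z, const mat& A, const vec& a,
                            double slope, HeadCache* cache) {
  const arma::uword N = Z.n_rows, F = Z.n_cols;
  vec c1 = Z * a.head(F);
  vec c2 = Z * a.tail(F);
  mat lam(N, N, arma::fill::zeros), u(N, N, arma::fill::zeros);
  mat s(N, F, arma::fill::zeros);
  for (arma::uword j = 0; j < N; ++j) {
    double emax = -arma::datum::inf;
    std::vector<arma::uword> nb;
    for (arma::uword l = 0; l < N; ++l) {
      if (A(j, l) != 0) {
        nb.push_back(l);
        double uu = c1(j) + c2(l);
        u(j, l) = uu;
        double e = lrelu(uu, slope);
        if (e > emax) emax = e;
      }
    }
    if (nb.empty()) continue;
    double zsum = 0;
    for (arma::uword l : nb) {
      double w = std::exp(lrelu(u(j, l), slope) - emax);
      lam(j, l) = w;
      zsum += w;
    }
    for (arma::uword l : nb) {
      lam(j, l) /= zsum;
      s.row(j) += lam(j, l) * Z.row(l);
    }
  }
  if (cache) {
    cache->Z = Z;
    cache->lam = lam;
    cache->u = u;
    cache->s = s;
  }
  return lrelu_mat(s, slope);
}

// Backward pass: accumulates dZ and da given the gradient w.r.t. the head
// output. A identifies the neighborhoods used in the forward pass.
static void gat_head_backward(const mat& dOut, const HeadCache& C,
                              const mat& A, const vec& a, double slope,
                              mat& dZ, vec& da) {
  const arma::uword N = C.Z.n_rows, F = C.Z.n_cols;
  mat ds = dOut % dlrelu_mat(C.s, slope);
  vec dc1(N, arma::fill::zeros), dc2(N, arma::fill::zeros);
  for (arma::uword j = 0; j < N; ++j) {
    std::vector<arma::uword> nb;
    for (arma::uword l = 0; l < N; ++l)
      if (A(j, l) != 0) nb.push_back(l);
    if (nb.empty()) continue;
    // d lambda and the softmax Jacobian
    double dot = 0;
    std::vector<double> dlam(nb.size());
    for (size_t t = 0; t < nb.size(); ++t) {
      arma::uword l = nb[t];
      dlam[t] = arma::dot(ds.row(j), C.Z.row(l));
      dot += C.lam(j, l) * dlam[t];
      dZ.row(l) += C.lam(j, l) * ds.row(j);
    }
    for (size_t t = 0; t < nb.size(); ++t) {
      arma::uword l = nb[t];
      double de = C.lam(j, l) * (dlam[t] - dot);
      double du = de * dlrelu(C.u(j, l), slope);
      dc1(j) += du;
      dc2(l) += du;
    }
  }
  da.head(F) += C.Z.t() * dc1;
  da.tail(F) += C.Z.t() * dc2;
  dZ += dc1 * a.head(F).t();
  dZ += dc2 * a.tail(F).t();
}

// ---------------------------------------------------------------------------
// Sparse one-hot feature helpers: fi is n x 6 with 0-based column indices
// into the D-wide vocabulary, or -1 on padded rows.

static mat onehot_mm(const arma::imat& fi, const mat& W) {
  mat Z(fi.n_rows, W.n_cols, arma::fill::zeros);
  for (arma::uword j = 0; j < fi.n_rows; ++j)
    for (arma::uword t = 0; t < fi.n_cols; ++t) {
      int idx = fi(j, t);
      if (idx >= 0) Z.row(j) += W.row(idx);
    }
  return Z;
}

static void onehot_mm_backward(const arma::imat& fi, const mat& dZ, mat& dW) {
  for (arma::uword j = 0; j < fi.n_rows; ++j)
    for (arma::uword t = 0; t < fi.n_cols; ++t) {
      int idx = fi(j, t);
      if (idx >= 0) dW.row(idx) += dZ.row(j);
    }
}

// ---------------------------------------------------------------------------
// Model configuration and per-molecule data

enum Variant { COMPLETE = 0, WHOLE_MOLECULE = 1, CONVOLUTIONAL = 2 };

struct Config {
  int variant, F, K, Q, P, D, task;
  double slope;
  std::vector<int> mlp;
};

static Config read_config(const List& cfg) {
  Config c;
  c.variant = as<int>(cfg["variant"]);
  c.F = as<int>(cfg["F"]);
  c.K = as<int>(cfg["K"]);
  c.Q = as<int>(cfg["Q"]);
  c.P = as<int>(cfg["P"]);
  c.D = as<int>(cfg["D"]);
  c.task = as<int>(cfg["task"]);
  c.slope = as<double>(cfg["slope"]);
  IntegerVector h = cfg["mlp"];
  c.mlp = std::vector<int>(h.begin(), h.end());
  return c;
}

struct MolData {
  arma::imat fi;          // n x 6 one-hot indices, -1 padded
  std::array<mat, 5> A;   // full, single, double, triple, aromatic
  uvec real;              // indices of real (non-padded) atoms
};

static MolData read_mol(const List& mol) {
  MolData m;
  IntegerMatrix fi = mol["fi"];
  m.fi = arma::imat(fi.nrow(), fi.ncol());
  for (int i = 0; i < fi.nrow(); ++i)
    for (int j = 0; j < fi.ncol(); ++j) m.fi(i, j) = fi(i, j) - 1;  // 0-based
  List A = mol["A"];
  for (int k = 0; k < 5; ++k) m.A[k] = as<mat>(A[k]);
  std::vector<arma::uword> real;
  for (arma::uword j = 0; j < m.fi.n_rows; ++j)
    if (m.fi(j, 0) >= 0) real.push_back(j);
  m.real = uvec(real);
  return m;
}

static std::string b_name(int k, int layer, int h, const char* part) {
  char buf[64];
  std::snprintf(buf, sizeof(buf), "m1.b%d.l%d.h%d.%s", k + 1, layer, h + 1,
                part);
  return std::string(buf);
}

static std::string m2_name(int h, const char* part) {
  char buf[64];
  std::snprintf(buf, sizeof(buf), "m2.h%d.%s", h + 1, part);
  return std::string(buf);
}

static std::string mlp_name(size_t i, const char* part) {
  char buf[64];
  std::snprintf(buf, sizeof(buf), "mlp.%d.%s", static_cast<int>(i + 1), part);
  return std::string(buf);
}

// Caches for one molecule's graph-side forward pass
struct MolCache {
  std::array<std::array<std::vector<HeadCache>, 2>, 4> branch;
  std::array<mat, 4> X1;  // branch layer-1 concat outputs
  std::array<mat, 4> Ht;  // branch outputs (head-averaged)
  mat m2in;               // masked-sum output (empty for whole_molecule)
  std::vector<HeadCache> m2;
  mat Snorm;    // normalized adjacency (convolutional)
  mat gc_mid;   // m2in * Wgc
  mat gc_pre;   // Snorm * gc_mid
  mat Hstar;    // N x Q node features entering the pool
  mat G1, Sg, G2;  // pooling gates
};

// Symmetric degree-normalized adjacency with zero-degree rows bypassed.
static mat norm_adjacency(const mat& A) {
  vec d = arma::sum(A, 1);
  vec dinv(d.n_elem);
  for (arma::uword i = 0; i < d.n_elem; ++i)
    dinv(i) = d(i) > 0 ? 1.0 / std::sqrt(d(i)) : 0.0;
  return (A.each_col() % dinv).each_row() % dinv.t();
}

// Graph-side forward for one molecule: returns the pooled vector X (length P).
static vec mol_forward(const MolData& md, ParamView& P, const Config& cfg,
                       MolCache& C) {
  const arma::uword N = md.fi.n_rows;
  mat m2in;
  if (cfg.variant != WHOLE_MOLECULE) {
    for (int k = 0; k < 4; ++k) {
      const mat& A = md.A[k + 1];
      C.branch[k][0].resize(cfg.K);
      C.branch[k][1].resize(cfg.K);
      mat X1(N, cfg.K * cfg.F);
      for (int h = 0; h < cfg.K; ++h) {
        mat Z = onehot_mm(md.fi, P.m(b_name(k, 1, h, "W")));
        X1.cols(h * cfg.F, (h + 1) * cfg.F - 1) = gat_head_forward(
            Z, A, P.v(b_name(k, 1, h, "a")), cfg.slope, &C.branch[k][0][h]);
      }
      C.X1[k] = X1;
      mat Ht(N, cfg.F, arma::fill::zeros);
      for (int h = 0; h < cfg.K; ++h) {
        mat Z = X1 * P.m(b_name(k, 2, h, "W"));
        Ht += gat_head_forward(Z, A, P.v(b_name(k, 2, h, "a")), cfg.slope,
                               &C.branch[k][1][h]);
      }
      C.Ht[k] = Ht / cfg.K;
    }
    // masked sum: gate branch k's row j by diag(A_k)[j]
    m2in.zeros(N, cfg.F);
    for (int k = 0; k < 4; ++k) {
      const mat& A = md.A[k + 1];
      for (arma::uword j = 0; j < N; ++j)
        if (A(j, j) != 0) m2in.row(j) += C.Ht[k].row(j);
    }
    C.m2in = m2in;
  }

  const mat& Afull = md.A[0];
  mat Hstar;
  if (cfg.variant == CONVOLUTIONAL) {
    C.Snorm = norm_adjacency(Afull);
    C.gc_mid = C.m2in * P.m("m2.gc.W");
    C.gc_pre = C.Snorm * C.gc_mid;
    Hstar = lrelu_mat(C.gc_pre, cfg.slope);
  } else {
    C.m2.resize(cfg.K);
    Hstar.set_size(N, cfg.K * cfg.F);
    for (int h = 0; h < cfg.K; ++h) {
      mat Z = (cfg.variant == WHOLE_MOLECULE)
                  ? onehot_mm(md.fi, P.m(m2_name(h, "W")))
                  : mat(C.m2in * P.m(m2_name(h, "W")));
      Hstar.cols(h * cfg.F, (h + 1) * cfg.F - 1) =
          gat_head_forward(Z, Afull, P.v(m2_name(h, "a")), cfg.slope, &C.m2[h]);
    }
  }
  C.Hstar = Hstar;

  // gated global attention pooling over real atoms only
  C.G1 = Hstar * P.m("pool.W1");
  C.G1.each_row() += P.v("pool.b1").t();
  C.Sg = 1.0 / (1.0 + arma::exp(-C.G1));
  C.G2 = Hstar * P.m("pool.W2");
  C.G2.each_row() += P.v("pool.b2").t();
  vec X(cfg.P, arma::fill::zeros);
  for (arma::uword t = 0; t < md.real.n_elem; ++t) {
    arma::uword j = md.real(t);
    X += (C.Sg.row(j) % C.G2.row(j)).t();
  }
  return X;
}

// Graph-side backward for one molecule: dX is the gradient w.r.t. the pooled
// vector; parameter gradients accumulate into G.
static void mol_backward(const MolData& md, ParamView& P, ParamView& G,
                         const Config& cfg, MolCache& C, const vec& dX) {
  const arma::uword N = md.fi.n_rows;
  // pooling
  mat dG1(N, cfg.P, arma::fill::zeros), dG2(N, cfg.P, arma::fill::zeros);
  for (arma::uword t = 0; t < md.real.n_elem; ++t) {
    arma::uword j = md.real(t);
    arma::rowvec dxr = dX.t();
    arma::rowvec dS = dxr % C.G2.row(j);
    dG2.row(j) = dxr % C.Sg.row(j);
    dG1.row(j) = dS % C.Sg.row(j) % (1.0 - C.Sg.row(j));
  }
  {
    mat dW1 = G.m("pool.W1"), dW2 = G.m("pool.W2");
    vec db1 = G.v("pool.b1"), db2 = G.v("pool.b2");
    dW1 += C.Hstar.t() * dG1;
    dW2 += C.Hstar.t() * dG2;
    db1 += arma::sum(dG1, 0).t();
    db2 += arma::sum(dG2, 0).t();
  }
  mat W1 = P.m("pool.W1"), W2 = P.m("pool.W2");
  mat dHstar = dG1 * W1.t() + dG2 * W2.t();

  const mat& Afull = md.A[0];
  mat dm2in;
  if (cfg.variant == CONVOLUTIONAL) {
    mat dpre = dHstar % dlrelu_mat(C.gc_pre, cfg.slope);
    mat dmid = C.Snorm.t() * dpre;
    mat dWgc = G.m("m2.gc.W");
    dWgc += C.m2in.t() * dmid;
    dm2in = dmid * P.m("m2.gc.W").t();
  } else {
    if (cfg.variant == COMPLETE) dm2in.zeros(N, cfg.F);
    for (int h = 0; h < cfg.K; ++h) {
      mat dZ(N, cfg.F, arma::fill::zeros);
      vec da = G.v(m2_name(h, "a"));
      gat_head_backward(dHstar.cols(h * cfg.F, (h + 1) * cfg.F - 1), C.m2[h],
                        Afull, P.v(m2_name(h, "a")), cfg.slope, dZ, da);
      mat dW = G.m(m2_name(h, "W"));
      if (cfg.variant == WHOLE_MOLECULE) {
        onehot_mm_backward(md.fi, dZ, dW);
      } else {
        dW += C.m2in.t() * dZ;
        dm2in += dZ * P.m(m2_name(h, "W")).t();
      }
    }
  }
  if (cfg.variant == WHOLE_MOLECULE) return;

  // masked sum
  for (int k = 0; k < 4; ++k) {
    const mat& A = md.A[k + 1];
    mat dHt(N, cfg.F, arma::fill::zeros);
    for (arma::uword j = 0; j < N; ++j)
      if (A(j, j) != 0) dHt.row(j) = dm2in.row(j);
    // layer 2 (head average)
    mat dX1(N, cfg.K * cfg.F, arma::fill::zeros);
    mat dOut2 = dHt / cfg.K;
    for (int h = 0; h < cfg.K; ++h) {
      mat dZ(N, cfg.F, arma::fill::zeros);
      vec da = G.v(b_name(k, 2, h, "a"));
      gat_head_backward(dOut2, C.branch[k][1][h], A,
                        P.v(b_name(k, 2, h, "a")), cfg.slope, dZ, da);
      mat dW = G.m(b_name(k, 2, h, "W"));
      dW += C.X1[k].t() * dZ;
      dX1 += dZ * P.m(b_name(k, 2, h, "W")).t();
    }
    // layer 1 (concat, one-hot input)
    for (int h = 0; h < cfg.K; ++h) {
      mat dZ(N, cfg.F, arma::fill::zeros);
      vec da = G.v(b_name(k, 1, h, "a"));
      gat_head_backward(dX1.cols(h * cfg.F, (h + 1) * cfg.F - 1),
                        C.branch[k][0][h], A, P.v(b_name(k, 1, h, "a")),
                        cfg.slope, dZ, da);
      mat dW = G.m(b_name(k, 1, h, "W"));
      onehot_mm_backward(md.fi, dZ, dW);
    }
  }
}

// ---------------------------------------------------------------------------
// Module 3 (batch level): batch norm + MLP

// [[Rcpp::export]]
List cpp_batch_grad(List mols, NumericVector theta, List layout, List cfgList,
                    NumericVector y, NumericVector sw, NumericVector bn_mean,
                    NumericVector bn_var, double bn_momentum) {
  Config cfg = read_config(cfgList);
  ParamView P(REAL(theta), layout);
  NumericVector gradR(theta.size());
  ParamView G(REAL(gradR), layout);
  const int B = mols.size();
  if (y.size() != B || sw.size() != B)
    stop("labels/weights length does not match the batch size");

  std::vector<MolData> md(B);
  std::vector<MolCache> mc(B);
  mat Xmat(B, cfg.P);
  for (int b = 0; b < B; ++b) {
    md[b] = read_mol(mols[b]);
    Xmat.row(b) = mol_forward(md[b], P, cfg, mc[b]).t();
  }

  // batch normalization (training statistics)
  const double eps = 1e-5;
  arma::rowvec mu = arma::mean(Xmat, 0);
  mat Xc = Xmat.each_row() - mu;
  arma::rowvec var = arma::mean(arma::square(Xc), 0);
  arma::rowvec sd = arma::sqrt(var + eps);
  mat Xhat = Xc.each_row() / sd;
  vec gamma = P.v("bn.gamma"), beta = P.v("bn.beta");
  mat act = (Xhat.each_row() % gamma.t()).each_row() + beta.t();

  NumericVector new_mean(cfg.P), new_var(cfg.P);
  for (int p = 0; p < cfg.P; ++p) {
    new_mean[p] = bn_momentum * bn_mean[p] + (1 - bn_momentum) * mu(p);
    new_var[p] = bn_momentum * bn_var[p] + (1 - bn_momentum) * var(p);
  }

  // MLP forward
  size_t L = cfg.mlp.size();
  std::vector<mat> pre(L + 1), a(L + 1);
  mat cur = act;
  for (size_t i = 0; i <= L; ++i) {
    pre[i] = cur * P.m(mlp_name(i, "W"));
    pre[i].each_row() += P.v(mlp_name(i, "b")).t();
    if (i < L) {
      a[i] = lrelu_mat(pre[i], cfg.slope);
      cur = a[i];
    }
  }
  vec out = pre[L].col(0);  // linear output (logit for classification)

  // loss + gradient w.r.t. the output unit
  double loss;
  vec dout(B);
  NumericVector preds(B);
  const double clip = 1e-7;
  if (cfg.task == 1) {  // classification: weighted BCE on sigmoid outputs
    double acc = 0;
    for (int b = 0; b < B; ++b) {
      double p = 1.0 / (1.0 + std::exp(-out(b)));
      preds[b] = p;
      double pc = std::min(std::max(p, clip), 1.0 - clip);
      acc += -sw[b] * (y[b] * std::log(pc) + (1 - y[b]) * std::log(1 - pc));
      dout(b) = sw[b] * (p - y[b]) / B;
    }
    loss = acc / B;
  } else {  // regression: weighted RMSE
    double acc = 0;
    for (int b = 0; b < B; ++b) {
      preds[b] = out(b);
      double e = out(b) - y[b];
      acc += sw[b] * e * e;
    }
    loss = std::sqrt(acc / B);
    for (int b = 0; b < B; ++b)
      dout(b) = loss > 1e-12 ? sw[b] * (out(b) - y[b]) / (B * loss) : 0.0;
  }

  // MLP backward
  mat dcur = mat(dout);
  for (int i = static_cast<int>(L); i >= 0; --i) {
    if (static_cast<size_t>(i) < L) dcur = dcur % dlrelu_mat(pre[i], cfg.slope);
    mat dW = G.m(mlp_name(i, "W"));
    vec db = G.v(mlp_name(i, "b"));
    const mat& input = (i == 0) ? act : a[i - 1];
    dW += input.t() * dcur;
    db += arma::sum(dcur, 0).t();
    dcur = dcur * P.m(mlp_name(i, "W")).t();
  }

  // batch norm backward
  {
    vec dgamma = G.v("bn.gamma"), dbeta = G.v("bn.beta");
    dgamma += arma::sum(dcur % Xhat, 0).t();
    dbeta += arma::sum(dcur, 0).t();
  }
  mat dXhat = dcur.each_row() % gamma.t();
  arma::rowvec dvar =
      arma::sum(dXhat % Xc, 0) % (-0.5 * arma::pow(var + eps, -1.5));
  arma::rowvec dmu = arma::sum(dXhat, 0) % (-1.0 / sd) +
                     dvar % (arma::sum(Xc, 0) * (-2.0 / B));
  mat dXmat = dXhat.each_row() / sd;
  dXmat += (Xc.each_row() % (dvar * (2.0 / B)));
  dXmat.each_row() += dmu / B;

  for (int b = 0; b < B; ++b)
    mol_backward(md[b], P, G, cfg, mc[b], dXmat.row(b).t());

  return List::create(Named("loss") = loss, Named("grad") = gradR,
                      Named("preds") = preds, Named("bn_mean") = new_mean,
                      Named("bn_var") = new_var);
}

// [[Rcpp::export]]
NumericVector cpp_batch_predict(List mols, NumericVector theta, List layout,
                                List cfgList, NumericVector bn_mean,
                                NumericVector bn_var) {
  Config cfg = read_config(cfgList);
  ParamView P(REAL(theta), layout);
  const int B = mols.size();
  const double eps = 1e-5;
  vec gamma = P.v("bn.gamma"), beta = P.v("bn.beta");
  size_t L = cfg.mlp.size();
  NumericVector preds(B);
  for (int b = 0; b < B; ++b) {
    MolData md = read_mol(mols[b]);
    MolCache C;
    vec X = mol_forward(md, P, cfg, C);
    vec xhat(cfg.P);
    for (int p = 0; p < cfg.P; ++p)
      xhat(p) = (X(p) - bn_mean[p]) / std::sqrt(bn_var[p] + eps);
    vec cur = gamma % xhat + beta;
    for (size_t i = 0; i <= L; ++i) {
      vec z = P.m(mlp_name(i, "W")).t() * cur + P.v(mlp_name(i, "b"));
      if (i < L) z.transform([&cfg](double v) { return lrelu(v, cfg.slope); });
      cur = z;
    }
    preds[b] =
        cfg.task == 1 ? 1.0 / (1.0 + std::exp(-cur(0))) : cur(0);
  }
  return preds;
}

// ---------------------------------------------------------------------------
// Exported layer primitives (used by the R-level layer API)

// [[Rcpp::export]]
NumericMatrix cpp_gat_head(NumericMatrix H, NumericMatrix A, NumericMatrix W,
                           NumericVector a, double slope) {
  mat Hm = as<mat>(H), Am = as<mat>(A), Wm = as<mat>(W);
  vec av = as<vec>(a);
  if (Hm.n_cols != Wm.n_rows)
    stop("attention head: ncol(H) must equal nrow(W)");
  if (Am.n_rows != Hm.n_rows || Am.n_cols != Hm.n_rows)
    stop("attention head: A must be N x N with N = nrow(H)");
  if (av.n_elem != 2 * Wm.n_cols)
    stop("attention head: length(a) must equal 2 * ncol(W)");
  mat Z = Hm * Wm;
  mat out = gat_head_forward(Z, Am, av, slope, nullptr);
  return wrap(out);
}

// As cpp_gat_head, but also returns the attention weight matrix lambda
// (row j holds the normalized attention of atom j over its neighborhood).
// [[Rcpp::export]]
List cpp_gat_head_attn(NumericMatrix H, NumericMatrix A, NumericMatrix W,
                       NumericVector a, double slope) {
  mat Hm = as<mat>(H), Am = as<mat>(A), Wm = as<mat>(W);
  vec av = as<vec>(a);
  if (Hm.n_cols != Wm.n_rows)
    stop("attention head: ncol(H) must equal nrow(W)");
  mat Z = Hm * Wm;
  HeadCache C;
  mat out = gat_head_forward(Z, Am, av, slope, &C);
  return List::create(Named("output") = out, Named("lambda") = C.lam);
}

// [[Rcpp::export]]
NumericMatrix cpp_graph_conv(NumericMatrix H, NumericMatrix A, NumericMatrix W,
                             double slope) {
  mat Hm = as<mat>(H), Am = as<mat>(A), Wm = as<mat>(W);
  if (Hm.n_cols != Wm.n_rows)
    stop("graph convolution: ncol(H) must equal nrow(W)");
  if (Am.n_rows != Hm.n_rows || Am.n_cols != Hm.n_rows)
    stop("graph convolution: A must be N x N with N = nrow(H)");
  mat S = norm_adjacency(Am);
  mat out = lrelu_mat(S * (Hm * Wm), slope);
  return wrap(out);
}
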