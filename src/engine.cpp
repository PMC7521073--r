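// Network engine: two valid convolutions with 2x2 max pooling, global max
// pooling, a fully connected hidden layer (the dropout target) and a linear
// output head.  Convolutions are computed as one GEMM per kernel offset over
// the channel dimension, batched across a whole minibatch: feature maps are
// stored as (batch*positions x channels) matrices, image i occupying a
// contiguous block of rows, in column-major (row-fastest) spatial order
// matching R arrays.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::umat;
using arma::uvec;
using arma::uword;

namespace {

struct NetShapes {
  int H, W, k1, f1, k2, f2, fc, K;
  bool pool;
  int oh1, ow1, ph1, pw1, oh2, ow2, ph2, pw2;
  int n1, m1, n2, m2;  // positions: conv1 out, pool1 out, conv2 out, pool2 out
};

NetShapes parse_shapes(const List& s) {
  NetShapes ns;
  ns.H  = as<int>(s["input_rows"]);
  ns.W  = as<int>(s["input_cols"]);
  ns.k1 = as<int>(s["kernel1"]);
  ns.f1 = as<int>(s["filters1"]);
  ns.k2 = as<int>(s["kernel2"]);
  ns.f2 = as<int>(s["filters2"]);
  ns.fc = as<int>(s["fc_units"]);
  ns.K  = as<int>(s["n_classes"]);
  ns.pool = as<bool>(s["pool"]);
  ns.oh1 = ns.H - ns.k1 + 1;
  ns.ow1 = ns.W - ns.k1 + 1;
  if (ns.oh1 < 1 || ns.ow1 < 1)
    stop("conv1 kernel (%d) larger than input (%dx%d)", ns.k1, ns.H, ns.W);
  if (ns.pool) {
    if (ns.oh1 < 2 || ns.ow1 < 2)
      stop("conv1 output %dx%d too small for 2x2 pooling", ns.oh1, ns.ow1);
    ns.ph1 = ns.oh1 / 2;
    ns.pw1 = ns.ow1 / 2;
  } else {
    ns.ph1 = ns.oh1;
    ns.pw1 = ns.ow1;
  }
  ns.oh2 = ns.ph1 - ns.k2 + 1;
  ns.ow2 = ns.pw1 - ns.k2 + 1;
  if (ns.oh2 < 1 || ns.ow2 < 1)
    stop("conv2 kernel (%d) larger than its input (%dx%d)", ns.k2, ns.ph1, ns.pw1);
  if (ns.pool) {
    if (ns.oh2 < 2 || ns.ow2 < 2)
      stop("conv2 output %dx%d too small for 2x2 pooling", ns.oh2, ns.ow2);
    ns.ph2 = ns.oh2 / 2;
    ns.pw2 = ns.ow2 / 2;
  } else {
    ns.ph2 = ns.oh2;
    ns.pw2 = ns.ow2;
  }
  ns.n1 = ns.oh1 * ns.ow1;
  ns.m1 = ns.ph1 * ns.pw1;
  ns.n2 = ns.oh2 * ns.ow2;
  ns.m2 = ns.ph2 * ns.pw2;
  return ns;
}

struct NetParams {
  mat W1;  // (k1*k1 x f1), single input channel
  vec b1;  // f1
  mat W2;  // (k2*k2*f1 x f2), row index ki + k2*kj + k2*k2*ic
  vec b2;  // f2
  mat Wf;  // (f2 x fc)
  vec bf;  // fc
  mat Wo;  // (fc x K)
  vec bo;  // K
};

mat flat_mat(SEXP x, int nrow, int ncol, const char* name) {
  NumericVector v(x);
  if (static_cast<int>(v.size()) != nrow * ncol)
    stop("parameter '%s' has %d values, expected %d", name,
         static_cast<int>(v.size()), nrow * ncol);
  return mat(v.begin(), nrow, ncol);  // copies
}

vec flat_vec(SEXP x, int n, const char* name) {
  NumericVector v(x);
  if (static_cast<int>(v.size()) != n)
    stop("parameter '%s' has %d values, expected %d", name,
         static_cast<int>(v.size()), n);
  return vec(v.begin(), n);
}

NetParams parse_params(const List& p, const NetShapes& ns) {
  NetParams np;
  np.W1 = flat_mat(p["W1"], ns.k1 * ns.k1, ns.f1, "W1");
  np.b1 = flat_vec(p["b1"], ns.f1, "b1");
  np.W2 = flat_mat(p["W2"], ns.k2 * ns.k2 * ns.f1, ns.f2, "W2");
  np.b2 = flat_vec(p["b2"], ns.f2, "b2");
  np.Wf = flat_mat(p["Wf"], ns.f2, ns.fc, "Wf");
  np.bf = flat_vec(p["bf"], ns.fc, "bf");
  np.Wo = flat_mat(p["Wo"], ns.fc, ns.K, "Wo");
  np.bo = flat_vec(p["bo"], ns.K, "bo");
  return np;
}

NumericVector wrap_dim(const mat& m, IntegerVector dm) {
  NumericVector out(m.begin(), m.end());
  out.attr("dim") = dm;
  return out;
}

List wrap_params(const NetParams& np, const NetShapes& ns) {
  return List::create(
      _["W1"] = wrap_dim(np.W1, IntegerVector::create(ns.k1, ns.k1, 1, ns.f1)),
      _["b1"] = NumericVector(np.b1.begin(), np.b1.end()),
      _["W2"] = wrap_dim(np.W2, IntegerVector::create(ns.k2, ns.k2, ns.f1, ns.f2)),
      _["b2"] = NumericVector(np.b2.begin(), np.b2.end()),
      _["Wf"] = wrap_dim(np.Wf, IntegerVector::create(ns.f2, ns.fc)),
      _["bf"] = NumericVector(np.bf.begin(), np.bf.end()),
      _["Wo"] = wrap_dim(np.Wo, IntegerVector::create(ns.fc, ns.K)),
      _["bo"] = NumericVector(np.bo.begin(), np.bo.end()));
}

// Per-offset (in-channels x out-channels) weight slices, shared by a batch.
std::vector<mat> weight_slices(const mat& W2, int k2, int f1, int f2) {
  std::vector<mat> out(k2 * k2, mat(f1, f2));
  for (int off = 0; off < k2 * k2; ++off)
    for (int ic = 0; ic < f1; ++ic)
      out[off].row(ic) = W2.row(off + k2 * k2 * ic);
  return out;
}

// 2x2 stride-2 max pooling of one image block (n_pos x C -> m_pos x C);
// trailing row/column of an odd spatial dimension is dropped.  Ties resolve
// to the first candidate in column-major order, matching which.max() on the
// flattened window.  Indices are local to the image block.
void maxpool2_block(const double* a, int oh, int ow, int C, int lda,
                    double* out, uword* idx, int ldo) {
  const int ph = oh / 2, pw = ow / 2;
  for (int c = 0; c < C; ++c) {
    const double* col = a + static_cast<size_t>(c) * lda;
    double* ocol = out + static_cast<size_t>(c) * ldo;
    uword* icol = idx + static_cast<size_t>(c) * ldo;
    for (int j = 0; j < pw; ++j) {
      for (int i = 0; i < ph; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        const int l00 = i0 + oh * j0;
        const int l10 = l00 + 1;
        const int l01 = i0 + oh * (j0 + 1);
        const int l11 = l01 + 1;
        int best = l00;
        double bv = col[l00];
        if (col[l10] > bv) { bv = col[l10]; best = l10; }
        if (col[l01] > bv) { bv = col[l01]; best = l01; }
        if (col[l11] > bv) { bv = col[l11]; best = l11; }
        ocol[i + ph * j] = bv;
        icol[i + ph * j] = static_cast<uword>(best);
      }
    }
  }
}

struct BatchCache {
  int nb = 0;
  mat P1;                 // (nb*n1 x k1*k1)
  mat a1;                 // (nb*n1 x f1) post-ReLU
  mat in2;                // (nb*m1 x f1)
  umat idx1;              // indices local to each image block
  std::vector<mat> P2;    // per offset (nb*n2 x f1)
  mat a2;                 // (nb*n2 x f2) post-ReLU
  mat in3;                // (nb*m2 x f2)
  umat idx2;
  umat gidx;              // (nb x f2), row within each image's in3 block
  mat latent;             // (f2 x nb)
  mat hpre, h;            // (fc x nb); h post-ReLU, post-dropout
};

inline void relu_inplace(mat& m) {
  double* p = m.memptr();
  const size_t n = m.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (p[i] < 0.0) p[i] = 0.0;
}

// Forward a batch of images (slices `lo..hi-1` of X taken through `pick`,
// which maps batch position to slice index).  masks: fc x nb matrix of 0/1
// columns (one per sample) or a single column used for the whole batch;
// empty = no dropout.
mat forward_batch(const NetParams& np, const NetShapes& ns, const cube& X,
                  const std::vector<int>& pick, const mat& masks,
                  double scale, const std::vector<mat>& Wslice,
                  BatchCache& c) {
  const int nb = static_cast<int>(pick.size());
  c.nb = nb;

  // conv1 (single input channel)
  c.P1.set_size(static_cast<uword>(nb) * ns.n1, ns.k1 * ns.k1);
  for (int b = 0; b < nb; ++b) {
    const mat img(const_cast<double*>(X.slice_memptr(pick[b])), ns.H, ns.W,
                  false, true);
    for (int kj = 0; kj < ns.k1; ++kj)
      for (int ki = 0; ki < ns.k1; ++ki) {
        mat dstv(c.P1.colptr(ki + ns.k1 * kj) +
                     static_cast<size_t>(b) * ns.n1,
                 ns.oh1, ns.ow1, false, true);
        dstv = img.submat(ki, kj, ki + ns.oh1 - 1, kj + ns.ow1 - 1);
      }
  }
  c.a1 = c.P1 * np.W1;
  c.a1.each_row() += np.b1.t();
  relu_inplace(c.a1);

  // pool1
  if (ns.pool) {
    c.in2.set_size(static_cast<uword>(nb) * ns.m1, ns.f1);
    c.idx1.set_size(static_cast<uword>(nb) * ns.m1, ns.f1);
    for (int b = 0; b < nb; ++b)
      maxpool2_block(c.a1.memptr() + static_cast<size_t>(b) * ns.n1,
                     ns.oh1, ns.ow1, ns.f1, c.a1.n_rows,
                     c.in2.memptr() + static_cast<size_t>(b) * ns.m1,
                     c.idx1.memptr() + static_cast<size_t>(b) * ns.m1,
                     c.in2.n_rows);
  } else {
    c.in2 = c.a1;
  }

  // conv2: one batched GEMM per kernel offset
  c.a2.set_size(static_cast<uword>(nb) * ns.n2, ns.f2);
  c.a2.each_row() = np.b2.t();
  c.P2.assign(ns.k2 * ns.k2, mat());
  for (int kj = 0; kj < ns.k2; ++kj) {
    for (int ki = 0; ki < ns.k2; ++ki) {
      const int off = ki + ns.k2 * kj;
      mat& P = c.P2[off];
      P.set_size(static_cast<uword>(nb) * ns.n2, ns.f1);
      for (int b = 0; b < nb; ++b)
        for (int ic = 0; ic < ns.f1; ++ic) {
          const mat chan(const_cast<double*>(c.in2.colptr(ic)) +
                             static_cast<size_t>(b) * ns.m1,
                         ns.ph1, ns.pw1, false, true);
          mat dstv(P.colptr(ic) + static_cast<size_t>(b) * ns.n2,
                   ns.oh2, ns.ow2, false, true);
          dstv = chan.submat(ki, kj, ki + ns.oh2 - 1, kj + ns.ow2 - 1);
        }
      c.a2 += P * Wslice[off];
    }
  }
  relu_inplace(c.a2);

  // pool2
  if (ns.pool) {
    c.in3.set_size(static_cast<uword>(nb) * ns.m2, ns.f2);
    c.idx2.set_size(static_cast<uword>(nb) * ns.m2, ns.f2);
    for (int b = 0; b < nb; ++b)
      maxpool2_block(c.a2.memptr() + static_cast<size_t>(b) * ns.n2,
                     ns.oh2, ns.ow2, ns.f2, c.a2.n_rows,
                     c.in3.memptr() + static_cast<size_t>(b) * ns.m2,
                     c.idx2.memptr() + static_cast<size_t>(b) * ns.m2,
                     c.in3.n_rows);
  } else {
    c.in3 = c.a2;
  }

  // global max pooling
  c.latent.set_size(ns.f2, nb);
  c.gidx.set_size(nb, ns.f2);
  const int mpos = ns.pool ? ns.m2 : ns.n2;
  for (int b = 0; b < nb; ++b)
    for (int ch = 0; ch < ns.f2; ++ch) {
      const double* col = c.in3.colptr(ch) + static_cast<size_t>(b) * mpos;
      uword best = 0;
      double bv = col[0];
      for (int i = 1; i < mpos; ++i)
        if (col[i] > bv) { bv = col[i]; best = i; }
      c.latent(ch, b) = bv;
      c.gidx(b, ch) = best;
    }

  // fully connected (engram) layer with optional dropout, then output head
  c.hpre = np.Wf.t() * c.latent;
  c.hpre.each_col() += np.bf;
  c.h = c.hpre;
  relu_inplace(c.h);
  if (masks.n_elem) {
    if (static_cast<int>(masks.n_cols) == nb) {
      c.h %= masks * scale;
    } else {
      c.h.each_col() %= masks.col(0) * scale;
    }
  }
  mat z = np.Wo.t() * c.h;
  z.each_col() += np.bo;
  return z;  // (K x nb)
}

const int LOSS_BCE = 0;      // per-class sigmoid, mean binary cross-entropy
const int LOSS_SOFTMAX = 1;  // softmax, categorical cross-entropy

// Loss (and optionally d loss / d logits) for one image.  Probabilities are
// clipped to [eps, 1-eps]; the gradient of a clipped coordinate is zero, so
// analytic gradients agree with finite differences of the clipped loss.
double loss_grad_z(const vec& z, int y, int variant, double eps, vec* dz) {
  const int K = static_cast<int>(z.n_elem);
  if (dz) dz->zeros(K);
  if (variant == LOSS_BCE) {
    double loss = 0.0;
    for (int k = 0; k < K; ++k) {
      const double p = 1.0 / (1.0 + std::exp(-z(k)));
      const double t = (k == y) ? 1.0 : 0.0;
      const double pc = std::min(std::max(p, eps), 1.0 - eps);
      loss += -(t * std::log(pc) + (1.0 - t) * std::log(1.0 - pc));
      if (dz && p > eps && p < 1.0 - eps) (*dz)(k) = (p - t) / K;
    }
    return loss / K;
  }
  // softmax categorical cross-entropy
  const double m = z.max();
  vec e = arma::exp(z - m);
  vec p = e / arma::accu(e);
  const double py = p(y);
  const double pc = std::min(std::max(py, eps), 1.0 - eps);
  if (dz && py > eps && py < 1.0 - eps) {
    *dz = p;
    (*dz)(y) -= 1.0;
  }
  return -std::log(pc);
}

NetParams zero_like(const NetParams& np) {
  NetParams g;
  g.W1.zeros(np.W1.n_rows, np.W1.n_cols);
  g.b1.zeros(np.b1.n_elem);
  g.W2.zeros(np.W2.n_rows, np.W2.n_cols);
  g.b2.zeros(np.b2.n_elem);
  g.Wf.zeros(np.Wf.n_rows, np.Wf.n_cols);
  g.bf.zeros(np.bf.n_elem);
  g.Wo.zeros(np.Wo.n_rows, np.Wo.n_cols);
  g.bo.zeros(np.bo.n_elem);
  return g;
}

// Backward a batch given dZ (K x nb, already scaled for the batch mean);
// accumulates parameter gradients into g.
void backward_batch(const NetParams& np, const NetShapes& ns,
                    const BatchCache& c, const mat& dZ, const mat& masks,
                    double scale, const std::vector<mat>& Wslice,
                    NetParams& g) {
  const int nb = c.nb;
  g.Wo += c.h * dZ.t();
  g.bo += arma::sum(dZ, 1);
  mat dH = np.Wo * dZ;  // (fc x nb)
  if (masks.n_elem) {
    if (static_cast<int>(masks.n_cols) == nb) {
      dH %= masks * scale;
    } else {
      dH.each_col() %= masks.col(0) * scale;
    }
  }
  for (uword i = 0; i < dH.n_elem; ++i)
    if (c.hpre(i) <= 0.0) dH(i) = 0.0;
  g.Wf += c.latent * dH.t();
  g.bf += arma::sum(dH, 1);
  mat dLatent = np.Wf * dH;  // (f2 x nb)

  // global max pooling routes each channel's gradient to its argmax
  mat din3(c.in3.n_rows, c.in3.n_cols, arma::fill::zeros);
  const int mpos = ns.pool ? ns.m2 : ns.n2;
  for (int b = 0; b < nb; ++b)
    for (int ch = 0; ch < ns.f2; ++ch)
      din3(static_cast<uword>(b) * mpos + c.gidx(b, ch), ch) =
          dLatent(ch, b);

  // pool2 / ReLU2
  mat da2(c.a2.n_rows, c.a2.n_cols, arma::fill::zeros);
  if (ns.pool) {
    for (int b = 0; b < nb; ++b)
      for (int ch = 0; ch < ns.f2; ++ch) {
        const double* src = din3.colptr(ch) + static_cast<size_t>(b) * ns.m2;
        const uword* idx = c.idx2.colptr(ch) + static_cast<size_t>(b) * ns.m2;
        double* dst = da2.colptr(ch) + static_cast<size_t>(b) * ns.n2;
        for (int i = 0; i < ns.m2; ++i) dst[idx[i]] += src[i];
      }
  } else {
    da2 = din3;
  }
  for (uword i = 0; i < da2.n_elem; ++i)
    if (c.a2(i) <= 0.0) da2(i) = 0.0;

  // conv2 backward: one batched GEMM pair per kernel offset
  mat din2(c.in2.n_rows, c.in2.n_cols, arma::fill::zeros);
  for (int kj = 0; kj < ns.k2; ++kj) {
    for (int ki = 0; ki < ns.k2; ++ki) {
      const int off = ki + ns.k2 * kj;
      const mat& P = c.P2[off];
      mat dWs = P.t() * da2;  // (f1 x f2)
      for (int ic = 0; ic < ns.f1; ++ic)
        g.W2.row(off + ns.k2 * ns.k2 * ic) += dWs.row(ic);
      mat dP = da2 * Wslice[off].t();  // (nb*n2 x f1)
      for (int b = 0; b < nb; ++b)
        for (int ic = 0; ic < ns.f1; ++ic) {
          mat chan(din2.colptr(ic) + static_cast<size_t>(b) * ns.m1,
                   ns.ph1, ns.pw1, false, true);
          const mat dPv(const_cast<double*>(dP.colptr(ic)) +
                            static_cast<size_t>(b) * ns.n2,
                        ns.oh2, ns.ow2, false, true);
          chan.submat(ki, kj, ki + ns.oh2 - 1, kj + ns.ow2 - 1) += dPv;
        }
    }
  }
  g.b2 += arma::sum(da2, 0).t();

  // pool1 / ReLU1
  mat da1(c.a1.n_rows, c.a1.n_cols, arma::fill::zeros);
  if (ns.pool) {
    for (int b = 0; b < nb; ++b)
      for (int ch = 0; ch < ns.f1; ++ch) {
        const double* src = din2.colptr(ch) + static_cast<size_t>(b) * ns.m1;
        const uword* idx = c.idx1.colptr(ch) + static_cast<size_t>(b) * ns.m1;
        double* dst = da1.colptr(ch) + static_cast<size_t>(b) * ns.n1;
        for (int i = 0; i < ns.m1; ++i) dst[idx[i]] += src[i];
      }
  } else {
    da1 = din2;
  }
  for (uword i = 0; i < da1.n_elem; ++i)
    if (c.a1(i) <= 0.0) da1(i) = 0.0;

  g.W1 += c.P1.t() * da1;
  g.b1 += arma::sum(da1, 0).t();
}

mat masks_as_mat(const NumericMatrix& masks, int col_from, int ncols) {
  mat m(masks.nrow(), ncols);
  for (int j = 0; j < ncols; ++j)
    std::copy(&masks(0, col_from + j), &masks(0, col_from + j) + masks.nrow(),
              m.colptr(j));
  return m;
}

void check_labels(const IntegerVector& labels, int K, int N) {
  if (static_cast<int>(labels.size()) != N)
    stop("label count (%d) does not match image count (%d)",
         static_cast<int>(labels.size()), N);
  for (int i = 0; i < N; ++i)
    if (labels[i] < 0 || labels[i] >= K)
      stop("label %d out of range [0, %d)", labels[i], K);
}

std::vector<int> iota_pick(int lo, int hi) {
  std::vector<int> v(hi - lo);
  for (int i = lo; i < hi; ++i) v[i - lo] = i;
  return v;
}

}  // namespace

// [[Rcpp::export]]
List cpp_net_forward(List params, List shapes, const arma::cube& images,
                     NumericVector mask, double scale) {
  const NetShapes ns = parse_shapes(shapes);
  const NetParams np = parse_params(params, ns);
  const int N = images.n_slices;
  if (static_cast<int>(images.n_rows) != ns.H ||
      static_cast<int>(images.n_cols) != ns.W)
    stop("images are %dx%d, network expects %dx%d",
         static_cast<int>(images.n_rows), static_cast<int>(images.n_cols),
         ns.H, ns.W);
  mat m;
  if (mask.size()) {
    if (static_cast<int>(mask.size()) != ns.fc)
      stop("dropout mask length (%d) != fc width (%d)",
           static_cast<int>(mask.size()), ns.fc);
    m = mat(mask.begin(), mask.size(), 1);
  }
  const std::vector<mat> Wslice = weight_slices(np.W2, ns.k2, ns.f1, ns.f2);
  BatchCache c;
  mat logits = forward_batch(np, ns, images, iota_pick(0, N), m, scale,
                             Wslice, c);
  return List::create(_["logits"] = logits, _["fc"] = c.h,
                      _["latent"] = c.latent);
}

// [[Rcpp::export]]
double cpp_net_loss(List params, List shapes, const arma::cube& images,
                    IntegerVector labels, NumericVector mask, double scale,
                    int loss_variant, double clip_eps) {
  const NetShapes ns = parse_shapes(shapes);
  const NetParams np = parse_params(params, ns);
  const int N = images.n_slices;
  check_labels(labels, ns.K, N);
  mat m;
  if (mask.size()) m = mat(mask.begin(), mask.size(), 1);
  const std::vector<mat> Wslice = weight_slices(np.W2, ns.k2, ns.f1, ns.f2);
  BatchCache c;
  mat logits = forward_batch(np, ns, images, iota_pick(0, N), m, scale,
                             Wslice, c);
  double total = 0.0;
  for (int i = 0; i < N; ++i)
    total += loss_grad_z(logits.col(i), labels[i], loss_variant, clip_eps,
                         nullptr);
  return total / N;
}

// [[Rcpp::export]]
List cpp_net_grad(List params, List shapes, const arma::cube& images,
                  IntegerVector labels, NumericVector mask, double scale,
                  int loss_variant, double clip_eps) {
  const NetShapes ns = parse_shapes(shapes);
  const NetParams np = parse_params(params, ns);
  const int N = images.n_slices;
  check_labels(labels, ns.K, N);
  mat m;
  if (mask.size()) m = mat(mask.begin(), mask.size(), 1);
  const std::vector<mat> Wslice = weight_slices(np.W2, ns.k2, ns.f1, ns.f2);
  BatchCache c;
  mat logits = forward_batch(np, ns, images, iota_pick(0, N), m, scale,
                             Wslice, c);
  mat dZ(ns.K, N);
  double total = 0.0;
  vec dz;
  for (int i = 0; i < N; ++i) {
    total += loss_grad_z(logits.col(i), labels[i], loss_variant, clip_eps,
                         &dz);
    dZ.col(i) = dz / N;  // gradient of the batch-mean loss
  }
  NetParams g = zero_like(np);
  backward_batch(np, ns, c, dZ, m, scale, Wslice, g);
  return List::create(_["loss"] = total / N,
                      _["grads"] = wrap_params(g, ns));
}

// One epoch of SGD.  `order` is the 0-based visiting order (already
// shuffled); masks has one column per batch (fresh mask each optimization
// step) or per sample position, or zero columns for no dropout.  Returns the
// updated parameters and the sample-weighted mean training loss.
// [[Rcpp::export]]
List cpp_train_epoch(List params, List shapes, const arma::cube& images,
                     IntegerVector labels, IntegerVector order,
                     int batch_size, double learning_rate,
                     NumericMatrix masks, double scale, int loss_variant,
                     double clip_eps) {
  const NetShapes ns = parse_shapes(shapes);
  NetParams np = parse_params(params, ns);
  const int N = images.n_slices;
  check_labels(labels, ns.K, N);
  if (static_cast<int>(order.size()) != N) stop("order must index every sample");
  if (batch_size < 1) stop("batch_size must be >= 1");
  const int nbatch = (N + batch_size - 1) / batch_size;
  const bool use_mask = masks.ncol() > 0;
  bool per_sample = false;
  if (use_mask) {
    if (masks.nrow() != ns.fc)
      stop("mask rows (%d) != fc width (%d)", masks.nrow(), ns.fc);
    if (masks.ncol() == N) per_sample = true;
    else if (masks.ncol() != nbatch)
      stop("need one mask per batch (%d) or per sample (%d), got %d",
           nbatch, N, masks.ncol());
  }

  double total = 0.0;
  BatchCache c;
  vec dz;
  for (int b = 0; b < nbatch; ++b) {
    const int lo = b * batch_size;
    const int hi = std::min(lo + batch_size, N);
    const int nb = hi - lo;
    std::vector<int> pick(nb);
    for (int s = lo; s < hi; ++s) {
      const int i = order[s];
      if (i < 0 || i >= N) stop("order entry out of range");
      pick[s - lo] = i;
    }
    mat m;
    if (use_mask)
      m = per_sample ? masks_as_mat(masks, lo, nb) : masks_as_mat(masks, b, 1);
    // weight slices must track the updated W2 each step
    const std::vector<mat> Wslice = weight_slices(np.W2, ns.k2, ns.f1, ns.f2);
    mat logits = forward_batch(np, ns, images, pick, m, scale, Wslice, c);
    mat dZ(ns.K, nb);
    for (int j = 0; j < nb; ++j) {
      const double li = loss_grad_z(logits.col(j), labels[pick[j]],
                                    loss_variant, clip_eps, &dz);
      if (!std::isfinite(li))
        stop("non-finite training loss at batch %d", b + 1);
      total += li;
      dZ.col(j) = dz / nb;
    }
    NetParams g = zero_like(np);
    backward_batch(np, ns, c, dZ, m, scale, Wslice, g);
    np.W1 -= learning_rate * g.W1; np.b1 -= learning_rate * g.b1;
    np.W2 -= learning_rate * g.W2; np.b2 -= learning_rate * g.b2;
    np.Wf -= learning_rate * g.Wf; np.bf -= learning_rate * g.bf;
    np.Wo -= learning_rate * g.Wo; np.bo -= learning_rate * g.bo;
  }
  return List::create(_["params"] = wrap_params(np, ns),
                      _["loss"] = total / N);
}

// Accuracy and mean loss over a dataset; masks (one column per evaluation
// batch) model test-phase dropout, empty matrix means plain inference.
// [[Rcpp::export]]
List cpp_evaluate(List params, List shapes, const arma::cube& images,
                  IntegerVector labels, int batch_size, NumericMatrix masks,
                  double scale, int loss_variant, double clip_eps) {
  const NetShapes ns = parse_shapes(shapes);
  const NetParams np = parse_params(params, ns);
  const int N = images.n_slices;
  check_labels(labels, ns.K, N);
  if (batch_size < 1) stop("batch_size must be >= 1");
  const int nbatch = (N + batch_size - 1) / batch_size;
  const bool use_mask = masks.ncol() > 0;
  if (use_mask && (masks.nrow() != ns.fc || masks.ncol() != nbatch))
    stop("evaluation masks must be fc x n_batches");
  const std::vector<mat> Wslice = weight_slices(np.W2, ns.k2, ns.f1, ns.f2);
  double total = 0.0;
  int correct = 0;
  BatchCache c;
  // without masks, process in large chunks for GEMM efficiency
  const int chunk = use_mask ? batch_size : std::max(batch_size, 128);
  const int nchunk = (N + chunk - 1) / chunk;
  for (int b = 0; b < nchunk; ++b) {
    const int lo = b * chunk;
    const int hi = std::min(lo + chunk, N);
    mat m;
    if (use_mask) m = masks_as_mat(masks, b, 1);
    mat logits = forward_batch(np, ns, images, iota_pick(lo, hi), m, scale,
                               Wslice, c);
    for (int i = lo; i < hi; ++i) {
      const vec z = logits.col(i - lo);
      total += loss_grad_z(z, labels[i], loss_variant, clip_eps, nullptr);
      if (static_cast<int>(z.index_max()) == labels[i]) ++correct;
    }
  }
  return List::create(_["accuracy"] = static_cast<double>(correct) / N,
                      _["loss"] = total / N);
}

// Stand-alone layer operations (shape-generic, used by the layer-level API).

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector input, NumericVector weights,
                         NumericVector bias) {
  IntegerVector di = input.attr("dim");
  IntegerVector dw = weights.attr("dim");
  if (di.size() != 3) stop("input must be a (height, width, channels) array");
  if (dw.size() != 4) stop("weights must be a (k, k, in, out) array");
  const int H = di[0], W = di[1], Cin = di[2];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k) stop("only square kernels are supported");
  if (dw[2] != Cin)
    stop("weight input channels (%d) != input channels (%d)", dw[2], Cin);
  if (static_cast<int>(bias.size()) != Cout)
    stop("bias length (%d) != filter count (%d)",
         static_cast<int>(bias.size()), Cout);
  const int oh = H - k + 1, ow = W - k + 1;
  if (oh < 1 || ow < 1) stop("kernel (%dx%d) larger than input (%dx%d)",
                             k, k, H, W);
  const cube in(input.begin(), H, W, Cin);
  const mat Wm(weights.begin(), k * k * Cin, Cout);
  mat out(oh * ow, Cout);
  for (int f = 0; f < Cout; ++f) out.col(f).fill(bias[f]);
  mat P(oh * ow, Cin);
  mat Ws(Cin, Cout);
  for (int kj = 0; kj < k; ++kj) {
    for (int ki = 0; ki < k; ++ki) {
      for (int ic = 0; ic < Cin; ++ic) {
        P.col(ic) = arma::vectorise(
            in.slice(ic).submat(ki, kj, ki + oh - 1, kj + ow - 1));
        Ws.row(ic) = Wm.row(ki + k * kj + k * k * ic);
      }
      out += P * Ws;
    }
  }
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(oh, ow, Cout);
  return res;
}

// [[Rcpp::export]]
List cpp_maxpool2(NumericVector input) {
  IntegerVector di = input.attr("dim");
  if (di.size() != 3) stop("input must be a (height, width, channels) array");
  const int H = di[0], W = di[1], C = di[2];
  if (H < 2 || W < 2)
    stop("spatial dimensions (%dx%d) too small for 2x2 pooling", H, W);
  const int ph = H / 2, pw = W / 2;
  mat out(ph * pw, C);
  umat idx(ph * pw, C);
  maxpool2_block(input.begin(), H, W, C, H * W, out.memptr(), idx.memptr(),
                 ph * pw);
  NumericVector o(out.begin(), out.end());
  o.attr("dim") = IntegerVector::create(ph, pw, C);
  IntegerVector ix(idx.n_elem);
  for (uword i = 0; i < idx.n_elem; ++i) ix[i] = static_cast<int>(idx(i)) + 1;
  ix.attr("dim") = IntegerVector::create(ph, pw, C);
  return List::create(_["output"] = o, _["argmax"] = ix);
}

// [[Rcpp::export]]
List cpp_global_maxpool(NumericVector input) {
  IntegerVector di = input.attr("dim");
  if (di.size() != 3) stop("input must be a (height, width, channels) array");
  const int H = di[0], W = di[1], C = di[2];
  if (H * W < 1) stop("input has no spatial positions");
  const mat a(input.begin(), H * W, C);
  NumericVector vals(C);
  IntegerVector idx(C);
  for (int c = 0; c < C; ++c) {
    uword im;
    vals[c] = a.col(c).max(im);
    idx[c] = static_cast<int>(im) + 1;
  }
  return List::create(_["output"] = vals, _["argmax"] = idx);
}
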