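// Minimal fully-convolutional network engine (float32) for desk-scale
// enhancement networks at scale factor 1. Supports plain conv stacks with
// ReLU, residual skip connections (output of a layer += input of an earlier
// layer) and a global input skip. Single-channel input/output; "same"
// zero padding; weights stored R-side as (k, k, cin, cout) arrays.
//
// Activation layout: one column per sample, channel planes concatenated
// (pixel (r,c) of channel ch at index ch*H*W + c*H + r, matching the R
// array layout). The im2col buffer is (H*W) x (k*k*cin) so that every
// kernel offset is a contiguous shifted copy of a channel plane and the
// conv is a single sgemm per sample.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <vector>
#include <cstring>

using namespace Rcpp;

namespace {

struct LayerSpec {
  int k, cin, cout;
  bool relu;
  int add_input_of;  // 1-based layer index whose input is added to this output, 0 = none
};

struct Arch {
  std::vector<LayerSpec> layers;
  bool global_skip;
};

Arch parse_arch(List arch) {
  Arch a;
  List layers = arch["layers"];
  for (int i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    LayerSpec s;
    s.k = as<int>(l["k"]);
    s.cin = as<int>(l["cin"]);
    s.cout = as<int>(l["cout"]);
    s.relu = as<std::string>(l["act"]) == "relu";
    s.add_input_of = l.containsElementNamed("add_input_of") ? as<int>(l["add_input_of"]) : 0;
    a.layers.push_back(s);
  }
  a.global_skip = as<bool>(arch["global_skip"]);
  return a;
}

struct Cache {
  std::vector<arma::fmat> acts;  // acts[0] = input, acts[j] = output of layer j
  int H, W, N;
};

// column t = dr + k*dc + k*k*ch holds the channel-ch plane shifted by the
// kernel offset (dr-p, dc-p), zero-filled at the border
void im2col(const float* a, int H, int W, int C, int k, arma::fmat& X) {
  const int p = (k - 1) / 2, HW = H * W;
  if ((int)X.n_rows != HW || (int)X.n_cols != k * k * C)
    X.set_size(HW, k * k * C);
  for (int ch = 0; ch < C; ++ch) {
    const float* plane = a + (size_t)ch * HW;
    for (int dc = 0; dc < k; ++dc) {
      const int oc = dc - p;
      for (int dr = 0; dr < k; ++dr) {
        const int orr = dr - p;
        float* dst = X.colptr((ch * k + dc) * k + dr);
        const int c0 = std::max(0, -oc), c1 = std::min(W, W - oc);
        const int r0 = std::max(0, -orr), r1 = std::min(H, H - orr);
        // zero only the border stripes, copy the interior
        for (int c = 0; c < c0; ++c)
          std::memset(dst + (size_t)c * H, 0, (size_t)H * sizeof(float));
        for (int c = c1; c < W; ++c)
          std::memset(dst + (size_t)c * H, 0, (size_t)H * sizeof(float));
        if (r1 <= r0) continue;
        for (int c = c0; c < c1; ++c) {
          float* d = dst + (size_t)c * H;
          if (r0 > 0) std::memset(d, 0, (size_t)r0 * sizeof(float));
          if (r1 < H) std::memset(d + r1, 0, (size_t)(H - r1) * sizeof(float));
          std::memcpy(d + r0, plane + (size_t)(c + oc) * H + r0 + orr,
                      (size_t)(r1 - r0) * sizeof(float));
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add the shifted planes back; row0 selects a
// sample's row block inside a batched (HW*N) x kkc matrix
void col2im_add(const arma::fmat& X, size_t row0, int H, int W, int C, int k,
                float* a) {
  const int p = (k - 1) / 2, HW = H * W;
  for (int ch = 0; ch < C; ++ch) {
    float* plane = a + (size_t)ch * HW;
    for (int dc = 0; dc < k; ++dc) {
      const int oc = dc - p;
      for (int dr = 0; dr < k; ++dr) {
        const int orr = dr - p;
        const float* src = X.colptr((ch * k + dc) * k + dr) + row0;
        const int c0 = std::max(0, -oc), c1 = std::min(W, W - oc);
        const int r0 = std::max(0, -orr), r1 = std::min(H, H - orr);
        if (r1 <= r0) continue;
        for (int c = c0; c < c1; ++c) {
          float* dp = plane + (size_t)(c + oc) * H + r0 + orr;
          const float* sp = src + (size_t)c * H + r0;
          for (int r = 0; r < r1 - r0; ++r) dp[r] += sp[r];
        }
      }
    }
  }
}

std::vector<arma::fmat> parse_weights(List params, const Arch& arch,
                                      std::vector<arma::frowvec>& biases) {
  std::vector<arma::fmat> Ws;
  for (size_t j = 0; j < arch.layers.size(); ++j) {
    List pj = params[j];
    NumericVector W = pj["W"];
    NumericVector b = pj["b"];
    const LayerSpec& s = arch.layers[j];
    const int kkc = s.k * s.k * s.cin;
    if (W.size() != kkc * s.cout || (int)b.size() != s.cout)
      stop("parameter shape mismatch at layer %d", (int)j + 1);
    arma::fmat Wm(kkc, s.cout);
    for (int i = 0; i < kkc * s.cout; ++i) Wm(i % kkc, i / kkc) = (float)W[i];
    Ws.push_back(Wm);
    arma::frowvec bv(s.cout);
    for (int i = 0; i < s.cout; ++i) bv[i] = (float)b[i];
    biases.push_back(bv);
  }
  return Ws;
}

void forward_pass(const Arch& arch, const std::vector<arma::fmat>& Ws,
                  const std::vector<arma::frowvec>& bs, Cache& cache) {
  const int H = cache.H, W = cache.W, N = cache.N, HW = H * W;
  arma::fmat X, Y;
  for (size_t j = 0; j < arch.layers.size(); ++j) {
    const LayerSpec& s = arch.layers[j];
    arma::fmat out((size_t)HW * s.cout, N);
    for (int n = 0; n < N; ++n) {
      im2col(cache.acts[j].colptr(n), H, W, s.cin, s.k, X);
      Y = X * Ws[j];            // (HW x cout), columns are channel planes
      Y.each_row() += bs[j];
      std::memcpy(out.colptr(n), Y.memptr(), (size_t)HW * s.cout * sizeof(float));
    }
    if (s.add_input_of > 0) out += cache.acts[s.add_input_of - 1];
    if (s.relu) out.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    cache.acts.push_back(std::move(out));
  }
  if (arch.global_skip) cache.acts.back() += cache.acts[0];
}

}  // namespace

typedef Rcpp::XPtr<Cache> CachePtr;

// x: numeric array dim (H, W, N), single channel. Returns pred (H, W, N)
// and, if keep_cache, an external pointer for the backward pass.
// [[Rcpp::export]]
List cpp_cnn_forward(List arch_r, List params, NumericVector x, bool keep_cache) {
  Arch arch = parse_arch(arch_r);
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 3) stop("x must be (H, W, N)");
  const int H = dims[0], W = dims[1], N = dims[2], HW = H * W;
  if (arch.layers.front().cin != 1 || arch.layers.back().cout != 1)
    stop("network must map 1 channel to 1 channel");
  Cache* cache = new Cache();
  cache->H = H; cache->W = W; cache->N = N;
  arma::fmat a0(HW, N);
  for (size_t i = 0; i < (size_t)x.size(); ++i)
    a0((arma::uword)(i % HW), (arma::uword)(i / HW)) = (float)x[i];
  cache->acts.push_back(std::move(a0));
  std::vector<arma::frowvec> bs;
  std::vector<arma::fmat> Ws = parse_weights(params, arch, bs);
  forward_pass(arch, Ws, bs, *cache);
  NumericVector pred(x.size());
  const arma::fmat& last = cache->acts.back();
  for (size_t i = 0; i < (size_t)pred.size(); ++i)
    pred[i] = (double)last((arma::uword)(i % HW), (arma::uword)(i / HW));
  pred.attr("dim") = dims;
  if (keep_cache) {
    CachePtr ptr(cache, true);
    return List::create(_["pred"] = pred, _["cache"] = ptr);
  }
  delete cache;
  return List::create(_["pred"] = pred);
}

// dpred: gradient of the scalar loss wrt the prediction, dim (H, W, N).
// Returns per-layer gradients (W array, b vector) as doubles.
// [[Rcpp::export]]
List cpp_cnn_backward(List arch_r, List params, SEXP cache_sexp, NumericVector dpred) {
  Arch arch = parse_arch(arch_r);
  CachePtr cache(cache_sexp);
  const int H = cache->H, W = cache->W, N = cache->N, HW = H * W;
  const int L = (int)arch.layers.size();
  if (cache->acts.size() != (size_t)L + 1) stop("stale cache");
  std::vector<arma::frowvec> bs;
  std::vector<arma::fmat> Ws = parse_weights(params, arch, bs);

  std::vector<arma::fmat> dact(L + 1);
  for (int j = 0; j <= L; ++j)
    dact[j].zeros(cache->acts[j].n_rows, N);
  for (size_t i = 0; i < (size_t)dpred.size(); ++i)
    dact[L]((arma::uword)(i % HW), (arma::uword)(i / HW)) = (float)dpred[i];

  std::vector<arma::fmat> dWs(L);
  std::vector<arma::frowvec> dbs(L);
  arma::fmat X, dXb;
  for (int j = L; j >= 1; --j) {
    const LayerSpec& s = arch.layers[j - 1];
    // through ReLU, in place (a > 0 <=> z > 0); dact[j] is final by now
    arma::fmat& dz = dact[j];
    if (s.relu) {
      const arma::fmat& a = cache->acts[j];
      for (arma::uword i = 0; i < dz.n_elem; ++i)
        if (a[i] <= 0.0f) dz[i] = 0.0f;
    }
    if (s.add_input_of > 0) dact[s.add_input_of - 1] += dz;
    dWs[j - 1].zeros(Ws[j - 1].n_rows, Ws[j - 1].n_cols);
    dbs[j - 1].zeros(s.cout);
    for (int n = 0; n < N; ++n) {
      const arma::fmat dz_mat(const_cast<float*>(dz.colptr(n)), HW, s.cout,
                              false, true);
      im2col(cache->acts[j - 1].colptr(n), H, W, s.cin, s.k, X);
      dWs[j - 1] += X.t() * dz_mat;
      dbs[j - 1] += arma::sum(dz_mat, 0);
      dXb = dz_mat * Ws[j - 1].t();  // HW x kkc
      col2im_add(dXb, 0, H, W, s.cin, s.k, dact[j - 1].colptr(n));
    }
  }
  // global skip adds dpred to dact[0]; input gradients are not needed

  List out(L);
  for (int j = 0; j < L; ++j) {
    const LayerSpec& s = arch.layers[j];
    NumericVector Wg(dWs[j].n_elem);
    for (size_t i = 0; i < (size_t)Wg.size(); ++i) Wg[i] = (double)dWs[j][i];
    Wg.attr("dim") = IntegerVector::create(s.k, s.k, s.cin, s.cout);
    NumericVector bg(s.cout);
    for (int i = 0; i < s.cout; ++i) bg[i] = (double)dbs[j][i];
    out[j] = List::create(_["W"] = Wg, _["b"] = bg);
  }
  return out;
}
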