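#include <Rcpp.h>
using namespace Rcpp;

// Right-hand-side evaluator for a compiled GMA model, kept in C++ because the
// screening pipeline integrates thousands of trajectories. The context mirrors
// compile_gma(): terms are ordered auxiliary-equation terms first (topological
// order), then dynamic-equation terms.
struct GmaCtx {
  int nd, na, n_aux_terms, nt, nv;
  std::vector<int> eq;      // 0-based target index (dyn 0..nd-1, aux nd..nd+na-1)
  std::vector<double> sign; // +1 production, -1 consumption (aux terms +1)
  std::vector<double> G;    // nt x nv, row-major: exponents over (dyn, aux)
  std::vector<double> cf;   // per-term coefficient value at the parameter point
};

// [[Rcpp::export]]
SEXP gma_ctx_new(int nd, int na, IntegerVector eq, NumericVector sign,
                 NumericMatrix G, NumericVector cf, int n_aux_terms) {
  GmaCtx* ctx = new GmaCtx();
  ctx->nd = nd;
  ctx->na = na;
  ctx->n_aux_terms = n_aux_terms;
  ctx->nt = G.nrow();
  ctx->nv = G.ncol();
  ctx->eq.assign(eq.begin(), eq.end());
  ctx->sign.assign(sign.begin(), sign.end());
  ctx->cf.assign(cf.begin(), cf.end());
  ctx->G.resize((size_t)ctx->nt * ctx->nv);
  for (int t = 0; t < ctx->nt; ++t)
    for (int k = 0; k < ctx->nv; ++k)
      ctx->G[(size_t)t * ctx->nv + k] = G(t, k);
  XPtr<GmaCtx> p(ctx, true);
  return p;
}

// [[Rcpp::export]]
NumericVector gma_ctx_set_cf(SEXP ctx_, NumericVector cf) {
  XPtr<GmaCtx> ctx(ctx_);
  ctx->cf.assign(cf.begin(), cf.end());
  return cf;
}

static inline double term_value(const GmaCtx* c, int t, const std::vector<double>& u) {
  double v = c->cf[t];
  const double* g = &c->G[(size_t)t * c->nv];
  for (int k = 0; k < c->nv; ++k) {
    double e = g[k];
    if (e == 0.0) continue;
    if (e == 1.0) v *= u[k];
    else if (e == 2.0) v *= u[k] * u[k];
    else if (e == -1.0) v /= u[k];
    else v *= std::pow(u[k], e);
  }
  return v;
}

// [[Rcpp::export]]
NumericVector gma_rhs(SEXP ctx_, NumericVector y) {
  XPtr<GmaCtx> ctx(ctx_);
  const GmaCtx* c = ctx.get();
  NumericVector out(c->nd);
  std::vector<double> u(c->nv, 0.0);
  for (int i = 0; i < c->nd; ++i) {
    double yi = y[i];
    if (!(yi > 0.0) || !R_finite(yi)) {
      std::fill(out.begin(), out.end(), R_NaN);
      return out;
    }
    u[i] = yi;
  }
  for (int t = 0; t < c->n_aux_terms; ++t) {
    u[c->eq[t]] += term_value(c, t, u);
  }
  std::vector<double> dy(c->nd, 0.0);
  for (int t = c->n_aux_terms; t < c->nt; ++t) {
    dy[c->eq[t]] += c->sign[t] * term_value(c, t, u);
  }
  for (int i = 0; i < c->nd; ++i) out[i] = dy[i];
  return out;
}

// Classic deSolve compiled-function interface: the active context is set from
// R immediately before each integration (single-threaded use).
static GmaCtx* g_active = nullptr;

// [[Rcpp::export]]
void gma_set_active(SEXP ctx_) {
  XPtr<GmaCtx> ctx(ctx_);
  g_active = ctx.get();
}

extern "C" void gma_derivs(int* neq, double* t, double* y, double* ydot,
                           double* yout, int* ip) {
  const GmaCtx* c = g_active;
  (void)t; (void)yout; (void)ip;
  std::vector<double> u(c->nv, 0.0);
  for (int i = 0; i < c->nd; ++i) {
    double yi = y[i];
    if (!(yi > 0.0) || !R_finite(yi)) {
      for (int k = 0; k < *neq; ++k) ydot[k] = R_NaN;
      return;
    }
    u[i] = yi;
  }
  for (int tt = 0; tt < c->n_aux_terms; ++tt) u[c->eq[tt]] += term_value(c, tt, u);
  for (int i = 0; i < c->nd; ++i) ydot[i] = 0.0;
  for (int tt = c->n_aux_terms; tt < c->nt; ++tt)
    ydot[c->eq[tt]] += c->sign[tt] * term_value(c, tt, u);
}

// Registration: the Rcpp .Call wrappers (defined in RcppExports.cpp) plus the
// deSolve-facing derivative routine, which deSolve looks up by name.
extern "C" {
SEXP _oscidesign_gma_ctx_new(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP _oscidesign_gma_ctx_set_cf(SEXP, SEXP);
SEXP _oscidesign_gma_rhs(SEXP, SEXP);
SEXP _oscidesign_gma_set_active(SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"_oscidesign_gma_ctx_new", (DL_FUNC) &_oscidesign_gma_ctx_new, 7},
    {"_oscidesign_gma_ctx_set_cf", (DL_FUNC) &_oscidesign_gma_ctx_set_cf, 2},
    {"_oscidesign_gma_rhs", (DL_FUNC) &_oscidesign_gma_rhs, 2},
    {"_oscidesign_gma_set_active", (DL_FUNC) &_oscidesign_gma_set_active, 1},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"gma_derivs", (DL_FUNC) &gma_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_oscidesign(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
}
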