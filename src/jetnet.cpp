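// Taylor-jet propagation through fully connected networks.
//
// A feedforward network y = N(x) is evaluated together with directional
// Taylor coefficients along user-supplied directions v: writing
// u(t) = N(x + t v), the jet carries T_k = (1/k!) d^k u / dt^k for
// k = 1..M (M <= 4).  Mixed spatial derivatives and Laplacian-type
// operators are recovered in R from small sets of directions.  The
// reverse pass accumulates exact gradients of any scalar function of
// (y, T) with respect to every weight and bias, which is what the
// inverse-PINN training loop needs: PDE/constitutive/traction residuals
// are functions of network values *and* their coordinate derivatives.
//
// All D*M coefficient states are stacked row-wise into one matrix per
// layer so each affine map is a single GEMM; the forward pass can leave a
// tape (an external pointer) from which the reverse pass runs without
// re-evaluating the network.
//
// Hidden activation is swish, s(z) = z * sigmoid(z); the reverse pass
// through an order-M jet needs s^(M+1), so analytic derivative tables up
// to order 5 are coded below.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
using namespace Rcpp;
using arma::mat;
using arma::span;

static const double C16 = 1.0 / 6.0;
static const double C124 = 1.0 / 24.0;

// Derivative tables of swish at Z: phi[j] = s^(j)(Z), j = 0..K (K <= 5).
// sigma^(n) = sum_k (-1)^(k-1) (k-1)! S(n+1,k) g^k (Stirling numbers) and
// s^(k) = z sigma^(k) + k sigma^(k-1).
static void swish_tables(const mat& Z, int K, std::vector<mat>& phi) {
  // sigmoid via an explicit loop: with -fno-math-errno the compiler can
  // vectorize the exp calls, which dominate the whole forward pass
  mat g(Z.n_rows, Z.n_cols);
  {
    const double* z = Z.memptr();
    double* o = g.memptr();
    const arma::uword N = Z.n_elem;
    for (arma::uword i = 0; i < N; ++i) o[i] = 1.0 / (1.0 + std::exp(-z[i]));
  }
  std::vector<mat> sg(K + 1);
  sg[0] = g;
  mat g2, g3, g4, g5;
  if (K >= 1) { g2 = arma::square(g); sg[1] = g - g2; }
  if (K >= 2) { g3 = g2 % g; sg[2] = g - 3.0 * g2 + 2.0 * g3; }
  if (K >= 3) { g4 = g3 % g; sg[3] = g - 7.0 * g2 + 12.0 * g3 - 6.0 * g4; }
  if (K >= 4) { g5 = g4 % g;
    sg[4] = g - 15.0 * g2 + 50.0 * g3 - 60.0 * g4 + 24.0 * g5; }
  if (K >= 5) sg[5] = g - 31.0 * g2 + 180.0 * g3 - 390.0 * g4 +
    360.0 * g5 - 120.0 * (g5 % g);
  phi.resize(K + 1);
  phi[0] = Z % g;
  for (int j = 1; j <= K; ++j) phi[j] = Z % sg[j] + double(j) * sg[j - 1];
}

// Per-direction monomials of the pre-activation coefficients u_1..u_M,
// shared by all composition brackets of one layer/direction.
struct DirMono {
  std::vector<mat> u;          // u[1..M]
  mat q2, q3, q4, p12, p13, p112;
};

// rows of state (d, k) inside a stack with n rows per state
static inline span blk_rows(int d, int k, int M, int n) {
  int s = (d * M + (k - 1)) * n;
  return span(s, s + n - 1);
}

static void build_mono(const mat& stack, int d, int M, int n, DirMono& dm) {
  dm.u.resize(M + 1);
  for (int k = 1; k <= M; ++k) dm.u[k] = stack(blk_rows(d, k, M, n), span::all);
  if (M >= 2) dm.q2 = arma::square(dm.u[1]);
  if (M >= 3) { dm.q3 = dm.q2 % dm.u[1]; dm.p12 = dm.u[1] % dm.u[2]; }
  if (M >= 4) {
    dm.q4 = dm.q3 % dm.u[1];
    dm.p13 = dm.u[1] % dm.u[3] + 0.5 * arma::square(dm.u[2]);
    dm.p112 = dm.q2 % dm.u[2];
  }
}

// Composition bracket B_m^shift for the truncated composition c = phi(u):
// with shift = 0, c_k = B_k^0 (k >= 1); the adjoints are
// dc_k/du_j = B_{k-j}^1 (j >= 1) and dc_k/du_0 = B_k^1.
static mat bracket(const std::vector<mat>& phi, const DirMono& dm,
                   int m, int shift) {
  switch (m) {
  case 0: return phi[shift];
  case 1: return phi[1 + shift] % dm.u[1];
  case 2: return phi[1 + shift] % dm.u[2] + 0.5 * phi[2 + shift] % dm.q2;
  case 3: return phi[1 + shift] % dm.u[3] + phi[2 + shift] % dm.p12 +
    C16 * phi[3 + shift] % dm.q3;
  case 4: return phi[1 + shift] % dm.u[4] + phi[2 + shift] % dm.p13 +
    0.5 * phi[3 + shift] % dm.p112 + C124 * phi[4 + shift] % dm.q4;
  }
  stop("jet order > 4 not supported");
  return mat();
}

struct JetTape {
  int L, D, M, n;
  std::vector<mat> W;       // weights (copied for the reverse pass)
  std::vector<mat> Ain;     // layer input values
  std::vector<mat> Cin;     // layer input coefficient stacks (D*M*n rows)
  std::vector<std::vector<mat>> PHI; // swish derivative tables per hidden layer
  std::vector<std::vector<DirMono>> MONO; // pre-activation monomials per layer
  mat Y;
  mat T;                    // output coefficient stack
};

static void jet_run(const List& Wl, const List& bl, const mat& X,
                    const List& V, int M, int Kphi, JetTape& tp) {
  int L = Wl.size();
  int D = V.size();
  int n = X.n_rows;
  tp.L = L; tp.D = D; tp.M = M; tp.n = n;
  tp.W.resize(L);
  tp.Ain.resize(L);
  tp.Cin.resize(L);
  tp.PHI.resize(L);
  tp.MONO.resize(L);

  mat A = X;
  mat C;
  if (D > 0) {
    C.zeros(D * M * n, X.n_cols);
    for (int d = 0; d < D; ++d)
      C(blk_rows(d, 1, M, n), span::all) = as<mat>(V[d]);
  }
  for (int l = 0; l < L; ++l) {
    tp.W[l] = as<mat>(Wl[l]);
    arma::rowvec b = as<arma::rowvec>(bl[l]);
    mat Z = A * tp.W[l];
    Z.each_row() += b;
    mat ZC;
    if (D > 0) ZC = C * tp.W[l];
    tp.Ain[l] = std::move(A);
    tp.Cin[l] = std::move(C);
    if (l < L - 1) {
      std::vector<mat> phi;
      swish_tables(Z, Kphi, phi);
      A = phi[0];
      std::vector<DirMono>& mono = tp.MONO[l];
      mono.resize(D);
      if (D > 0) {
        C.set_size(ZC.n_rows, ZC.n_cols);
        for (int d = 0; d < D; ++d) {
          build_mono(ZC, d, M, n, mono[d]);
          for (int k = 1; k <= M; ++k)
            C(blk_rows(d, k, M, n), span::all) = bracket(phi, mono[d], k, 0);
        }
      }
      tp.PHI[l] = std::move(phi);
    } else {
      A = std::move(Z);
      C = std::move(ZC);
    }
  }
  tp.Y = std::move(A);
  tp.T = std::move(C);
}

// Tapes live in a process-local registry and are freed explicitly by the
// reverse pass (training creates one tape per network per iteration; R
// garbage collection is far too lazy for that traffic).
static std::map<int, JetTape*>& tape_registry() {
  static std::map<int, JetTape*> reg;
  return reg;
}

// [[Rcpp::export(name = ".jet_forward")]]
List jet_forward_cpp(List W, List b, arma::mat X, List V, int M,
                     bool tape = false) {
  static int next_id = 1;
  int Kphi = tape ? std::max(M, 1) + 1 : std::max(M, 1);
  JetTape* tp = new JetTape();
  jet_run(W, b, X, V, M, Kphi, *tp);
  int D = V.size(), n = X.n_rows;
  List Tout(D);
  for (int d = 0; d < D; ++d) {
    List Td(M);
    for (int k = 1; k <= M; ++k)
      Td[k - 1] = mat(tp->T(blk_rows(d, k, M, n), span::all));
    Tout[d] = Td;
  }
  List out = List::create(_["y"] = tp->Y, _["T"] = Tout);
  if (tape) {
    int id = next_id++;
    tape_registry()[id] = tp;
    out["tape"] = id;
  } else delete tp;
  return out;
}

// [[Rcpp::export(name = ".jet_tape_drop")]]
void jet_tape_drop_cpp(int tape) {
  std::map<int, JetTape*>& reg = tape_registry();
  std::map<int, JetTape*>::iterator it = reg.find(tape);
  if (it != reg.end()) { delete it->second; reg.erase(it); }
}

// [[Rcpp::export(name = ".jet_backward")]]
List jet_backward_cpp(int tape, Nullable<NumericMatrix> ybar, List Tbar,
                      bool free_tape = true) {
  std::map<int, JetTape*>::iterator it = tape_registry().find(tape);
  if (it == tape_registry().end()) stop("tape not found (already freed?)");
  JetTape* tp = it->second;
  int L = tp->L, D = tp->D, M = tp->M, n = tp->n;
  int dout = tp->Y.n_cols;

  mat Abar;
  if (ybar.isNotNull()) Abar = as<mat>(ybar.get());
  else Abar.zeros(n, dout);
  mat Cbar;
  if (D > 0) {
    Cbar.zeros(D * M * n, dout);
    for (int d = 0; d < D; ++d) {
      List Td = Tbar[d];
      for (int k = 1; k <= M; ++k)
        if (k <= Td.size() && !Rf_isNull(Td[k - 1]))
          Cbar(blk_rows(d, k, M, n), span::all) = as<mat>(Td[k - 1]);
    }
  }

  List gW(L), gb(L);
  for (int l = L - 1; l >= 0; --l) {
    mat Zbar_v;
    mat Zbar_c;
    if (l < tp->L - 1) {
      const std::vector<mat>& phi = tp->PHI[l];
      Zbar_v = Abar % phi[1];
      if (D > 0) {
        Zbar_c.set_size(Cbar.n_rows, Cbar.n_cols);
        for (int d = 0; d < D; ++d) {
          const DirMono& dm = tp->MONO[l][d];
          std::vector<mat> cb(M + 1);
          for (int k = 1; k <= M; ++k)
            cb[k] = Cbar(blk_rows(d, k, M, n), span::all);
          // shifted brackets B_1^1..B_M^1, reused across j
          std::vector<mat> B(M + 1);
          for (int m = 1; m <= M; ++m) B[m] = bracket(phi, dm, m, 1);
          for (int k = 1; k <= M; ++k) Zbar_v += cb[k] % B[k];
          for (int j = 1; j <= M; ++j) {
            mat acc = cb[j] % phi[1];
            for (int k = j + 1; k <= M; ++k) acc += cb[k] % B[k - j];
            Zbar_c(blk_rows(d, j, M, n), span::all) = acc;
          }
        }
      }
    } else {
      Zbar_v = Abar;
      Zbar_c = Cbar;
    }
    mat gWl = tp->Ain[l].t() * Zbar_v;
    if (D > 0) gWl += tp->Cin[l].t() * Zbar_c;
    gW[l] = gWl;
    gb[l] = arma::rowvec(arma::sum(Zbar_v, 0));
    if (l > 0) {
      Abar = Zbar_v * tp->W[l].t();
      if (D > 0) Cbar = Zbar_c * tp->W[l].t();
    }
  }
  if (free_tape) jet_tape_drop_cpp(tape);
  return List::create(_["gW"] = gW, _["gb"] = gb);
}
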