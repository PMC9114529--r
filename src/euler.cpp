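#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// shifted Hill: lam + (1 - lam) / (1 + (x / x0)^n)
static inline double hs(double x, double x0, double lam, double n) {
  return lam + (1.0 - lam) / (1.0 + std::pow(x / x0, n));
}

// Explicit-Euler integration of the VEGF-Notch row model for a whole
// Monte-Carlo ensemble. States are passed as a 6 x M x nrep array with the
// species order N, D, J, I, VR, V. Parameters arrive as a numeric vector in
// the fixed order established by params_vector() on the R side:
//  0 N0, 1 D0, 2 J0, 3 VR0, 4 gamma, 5 gamma_S, 6 k_C, 7 k_T, 8 V_ext,
//  9 I0, 10 V0, 11 n_N, 12 n_D, 13 n_J, 14 n_F, 15 n_VR,
// 16 l_I_N, 17 l_I_D, 18 l_I_J, 19 l_I_VR, 20 l_V_D, 21 l_F_D, 22 l_F_J.
// checkpoint_steps (1-based step counts, sorted ascending) select steps
// after which the activated-VEGFR column is recorded; step 0 = initial
// state. Any species going negative or non-finite aborts with a diagnostic.
// [[Rcpp::export]]
List euler_ensemble_cpp(NumericVector init, NumericVector par,
                        IntegerVector on_line, double d_line, double j_line,
                        double dt, int n_steps, IntegerVector checkpoint_steps) {
  IntegerVector dims = init.attr("dim");
  if (dims.size() != 3 || dims[0] != 6)
    stop("init must be a 6 x M x nrep array");
  const int M = dims[1], nrep = dims[2];
  if (on_line.size() != M) stop("on_line mask must have length M");
  if (par.size() != 23) stop("parameter vector must have 23 entries");

  const double N0 = par[0], D0 = par[1], J0 = par[2], VR0 = par[3];
  const double gamma = par[4], gamma_S = par[5];
  const double kC = par[6], kT = par[7], Vext = par[8];
  const double I0 = par[9], V0 = par[10];
  const double nN = par[11], nD = par[12], nJ = par[13], nF = par[14],
               nVR = par[15];
  const double lIN = par[16], lID = par[17], lIJ = par[18], lIVR = par[19],
               lVD = par[20], lFD = par[21], lFJ = par[22];

  const int ncheck = checkpoint_steps.size();
  NumericVector out(init.size());
  out.attr("dim") = dims;
  NumericVector vcheck(ncheck > 0 ? (double) M * nrep * ncheck : 0);
  if (ncheck > 0)
    vcheck.attr("dim") = IntegerVector::create(M, nrep, ncheck);

  static const char *species[6] = {"N", "D", "J", "I", "VR", "V"};
  std::vector<double> cur(6 * M), nxt(6 * M);

  for (int r = 0; r < nrep; ++r) {
    const double *src = &init[(R_xlen_t) r * 6 * M];
    for (int k = 0; k < 6 * M; ++k) cur[k] = src[k];
    int ci = 0;
    // checkpoint at step 0 = initial state
    while (ci < ncheck && checkpoint_steps[ci] == 0) {
      for (int i = 0; i < M; ++i)
        vcheck[(R_xlen_t) ci * M * nrep + (R_xlen_t) r * M + i] =
          cur[6 * i + 5];
      ++ci;
    }
    for (int s = 1; s <= n_steps; ++s) {
      for (int i = 0; i < M; ++i) {
        const int il = (i == 0) ? M - 1 : i - 1;
        const int ir = (i == M - 1) ? 0 : i + 1;
        const double *c = &cur[6 * i];
        const double N = c[0], D = c[1], J = c[2], I = c[3], VR = c[4],
                     V = c[5];
        const double on = on_line[i] ? 1.0 : 0.0;
        const double Next = 0.5 * (cur[6 * il + 0] + cur[6 * ir + 0]);
        const double Dext = 0.5 * (cur[6 * il + 1] + cur[6 * ir + 1]) +
                            on * d_line;
        const double Jext = 0.5 * (cur[6 * il + 2] + cur[6 * ir + 2]) +
                            on * j_line;
        const double HfD = hs(I, I0, lFD, nF), HfJ = hs(I, I0, lFJ, nF);
        double *o = &nxt[6 * i];
        o[0] = N + dt * (N0 * hs(I, I0, lIN, nN) -
                         N * ((kC * D + kT * Dext) * HfD +
                              (kC * J + kT * Jext) * HfJ) -
                         gamma * N);
        o[1] = D + dt * (D0 * hs(I, I0, lID, nD) * hs(V, V0, lVD, nD) -
                         D * (kC * HfD * N + kT * Next) - gamma * D);
        o[2] = J + dt * (J0 * hs(I, I0, lIJ, nJ) -
                         J * (kC * HfJ * N + kT * Next) - gamma * J);
        o[3] = I + dt * (kT * N * (Dext * HfD + Jext * HfJ) - gamma_S * I);
        o[4] = VR + dt * (VR0 * hs(I, I0, lIVR, nVR) - kT * VR * Vext -
                          gamma * VR);
        o[5] = V + dt * (kT * VR * Vext - gamma_S * V);
      }
      for (int i = 0; i < M; ++i)
        for (int k = 0; k < 6; ++k) {
          const double v = nxt[6 * i + k];
          if (!std::isfinite(v) || v < 0.0)
            stop("integration failure in replicate %d at step %d: species "
                 "%s of cell %d became %g",
                 r + 1, s, species[k], i + 1, v);
        }
      cur.swap(nxt);
      while (ci < ncheck && checkpoint_steps[ci] == s) {
        for (int i = 0; i < M; ++i)
          vcheck[(R_xlen_t) ci * M * nrep + (R_xlen_t) r * M + i] =
            cur[6 * i + 5];
        ++ci;
      }
    }
    double *dst = &out[(R_xlen_t) r * 6 * M];
    for (int k = 0; k < 6 * M; ++k) dst[k] = cur[k];
  }
  return List::create(_["final"] = out, _["v_checkpoints"] = vcheck);
}
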