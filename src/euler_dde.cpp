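#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Explicit Euler for the reduced equal-delay loop model with a history buffer.
// history: (d + 1) x 4 matrix of states at t = -d*h, ..., -h, 0 (row d is t = 0),
// where d = round(T/h) delay steps (the delay is realized on the step grid).
// Returns an (n_steps + 1) x 4 matrix of states at t = 0, h, ..., duration.
// [[Rcpp::export(name = ".euler_dde_cpp")]]
NumericMatrix euler_dde_cpp(NumericVector par, NumericMatrix history,
                            double duration, double h) {
  const double tau = par["tau"];
  const double wSG = par["w_SG"], wGS = par["w_GS"], wCC = par["w_CC"],
               wCS = par["w_CS"], wGG = par["w_GG"];
  const double Cin = par["C"], Str = par["Str"];
  const double MS = par["M_S"], BS = par["B_S"], MG = par["M_G"], BG = par["B_G"],
               ME = par["M_E"], BE = par["B_E"], MI = par["M_I"], BI = par["B_I"];
  const double T = par["T"];

  const int d = (T <= 0) ? 0 : (int)std::llround(T / h);
  const int n = (int)std::llround(duration / h);
  if (history.nrow() != d + 1 || history.ncol() != 4)
    stop("history must be a (round(T/h) + 1) x 4 matrix");

  const int len = d + n + 1;
  std::vector<double> S(len), G(len), E(len), I(len);
  for (int i = 0; i <= d; ++i) {
    S[i] = history(i, 0); G[i] = history(i, 1);
    E[i] = history(i, 2); I[i] = history(i, 3);
  }

  // sigmoid constants precomputed: F(x) = M / (1 + k * exp(-4 x / M))
  const double kS = (MS - BS) / BS, kG = (MG - BG) / BG,
               kE = (ME - BE) / BE, kI = (MI - BI) / BI;
  const double rS = -4.0 / MS, rG = -4.0 / MG, rE = -4.0 / ME, rI = -4.0 / MI;
  const double a = h / tau;

  for (int k = d; k < d + n; ++k) {
    const int kd = k - d;  // index of state at t - T
    const double FS = MS / (1.0 + kS * std::exp(rS * (wCS * E[kd] - wGS * G[kd])));
    const double FG = MG / (1.0 + kG * std::exp(rG * (wSG * S[kd] - wGG * G[kd] - Str)));
    const double FE = ME / (1.0 + kE * std::exp(rE * (Cin - wCC * I[kd])));
    const double FI = MI / (1.0 + kI * std::exp(rI * (wCC * E[kd])));
    S[k + 1] = S[k] + a * (FS - S[k]);
    G[k + 1] = G[k] + a * (FG - G[k]);
    E[k + 1] = E[k] + a * (FE - E[k]);
    I[k + 1] = I[k] + a * (FI - I[k]);
    if (!std::isfinite(S[k + 1]) || !std::isfinite(G[k + 1]) ||
        !std::isfinite(E[k + 1]) || !std::isfinite(I[k + 1]))
      stop("integration produced a non-finite state at step %d", k - d + 1);
  }

  NumericMatrix out(n + 1, 4);
  double *o0 = &out(0, 0), *o1 = &out(0, 1), *o2 = &out(0, 2), *o3 = &out(0, 3);
  for (int i = 0; i <= n; ++i) {
    o0[i] = S[d + i]; o1[i] = G[d + i]; o2[i] = E[d + i]; o3[i] = I[d + i];
  }
  return out;
}
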