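# Center-manifold / normal-form computation at a Hopf crossing.
#
# Everything is computed in the time-rescaled frame t -> t/T with the delay
# normalized to 1, so the center-subspace rotation rate is omega0*T0 and the
# Taylor coefficients g_ij carry explicit T0 factors; the classification
# scalars convert back through the period expansion T(eps) = (2 pi/omega0)(1 +
# T2 eps^2 + ...).

# Linear input functional of each population applied to a (possibly complex)
# deviation vector v = (S, G, E, I): the argument of the sigmoid deviation.
.input_functionals <- function(p) {
  list(
    S = function(v) p$w_CS * v[3] - p$w_GS * v[2],
    G = function(v) p$w_SG * v[1] - p$w_GG * v[2],
    E = function(v) -p$w_CC * v[4],
    I = function(v) p$w_CC * v[3]
  )
}

#' Right and adjoint eigenvectors at a Hopf crossing
#'
#' Computes the right eigenvector `q = (1, chi, beta, gamma)` of the delayed
#' Jacobian at `lambda = i omega0`, i.e.
#' `(i omega0 I - B1 - B2 e^{-i omega0 T0}) q = 0`, the adjoint (left) null
#' vector `(1, chi*, beta*, gamma*)`, and the normalization constant `rho`
#' making the delay bilinear pairing satisfy `<q*, q> = 1` (and automatically
#' `<q*, conj(q)> = 0`). Closed forms follow the block structure of `B2`; for
#' a crossing of the STN-GPe factor the cortical components `beta`, `gamma`
#' vanish identically.
#'
#' @param lin A `bg_linearization`.
#' @param T0,omega0 A verified crossing (ms, rad/ms).
#' @return A `bg_hopf_eigvec` object: complex vectors `q`, `p_bar`
#'   (conjugated adjoint components as they enter the coefficient formulas),
#'   scalar `rho_bar`, and the residuals of the two eigen-identities.
#' @export
hopf_eigenvectors <- function(lin, T0, omega0) {
  tau <- lin$tau
  L <- 1i * omega0 + 1 / tau
  Ex <- exp(-1i * omega0 * T0)
  D1 <- characteristic_value(1i * omega0, T0, lin, "loop1")
  D2 <- characteristic_value(1i * omega0, T0, lin, "loop2")
  if (Mod(D1 * D2) > 1e-6) stop("(T0, omega0) is not a characteristic root")
  scale <- max(abs(c(lin$a12, lin$a13, lin$a21, lin$a22, lin$a34, lin$a43, 1 / tau)))
  den_q <- L - lin$a22 * Ex
  if (abs(lin$a13) < 1e-12 * scale || Mod(den_q) < 1e-12 * scale || Mod(L) < 1e-12 * scale)
    stop("degenerate eigenvector denominator")
  chi   <- lin$a21 * Ex / den_q
  beta  <- D1 / (lin$a13 * Ex * den_q)
  gamma <- lin$a43 * Ex * beta / L
  q <- c(1 + 0i, chi, beta, gamma)

  # left null vector: conj(p)^T (i w I - B1 - B2 Ex) = 0; p_bar holds conj(p)
  if (abs(lin$a21) < 1e-12 * scale || Mod(D2) < 1e-12 * scale^2)
    stop("degenerate adjoint denominator")
  chi_b   <- L / (lin$a21 * Ex)
  beta_b  <- lin$a13 * Ex * L / D2
  gamma_b <- lin$a34 * Ex * beta_b / L
  p_bar <- c(1 + 0i, chi_b, beta_b, gamma_b)

  rho_bar <- sum(p_bar * q) + T0 * Ex * drop(p_bar %*% lin$B2 %*% q)
  if (Mod(rho_bar) < 1e-12) stop("degenerate normalization constant rho")

  Mmat <- 1i * omega0 * diag(4) - lin$B1 - lin$B2 * Ex
  res_q <- max(Mod(Mmat %*% q))
  res_p <- max(Mod(p_bar %*% Mmat))
  structure(list(q = q, p_bar = p_bar, rho_bar = rho_bar,
                 chi = chi, beta = beta, gamma = gamma,
                 chi_star = Conj(chi_b), beta_star = Conj(beta_b),
                 gamma_star = Conj(gamma_b),
                 residual_q = res_q, residual_adjoint = res_p,
                 T0 = T0, omega0 = omega0),
            class = "bg_hopf_eigvec")
}

# Bilinear delay pairing <psi, phi> for exponential eigenfunctions
# phi(theta) = f e^{i nu theta}, psi(s) = (1/rho) p e^{i mu s}; used in tests.
.bilinear_pairing <- function(p_bar, f, nu, mu, T0, B2) {
  # <psi, phi> = conj(psi(0)) f + T0 * conj(psi)^T B2 f * int_{-1}^0 e^{-i mu (xi+1)} e^{i nu xi} dxi
  I <- if (abs(nu - mu) < 1e-14) exp(-1i * mu) else
    exp(-1i * mu) * (exp(1i * (nu - mu) * 0) - exp(-1i * (nu - mu))) / (1i * (nu - mu))
  sum(p_bar * f) + T0 * drop(p_bar %*% B2 %*% f) * I
}

#' Second-order Taylor coefficients of the reduced flow on the center manifold
#'
#' Assembles `g20`, `g11`, `g02` from the quadratic part of the nonlinearity,
#' `f2_X = c_X * (input deviation)^2`, evaluated in the direction of the
#' delayed eigenvector `q e^{-i omega0 T0}`, weighted by the conjugated
#' adjoint components and `T0 / rho_bar`.
#'
#' @param ev A `bg_hopf_eigvec` from [hopf_eigenvectors()].
#' @param lin A `bg_linearization`.
#' @return Named complex list `g20`, `g11`, `g02`, plus the per-population
#'   directional inputs `zeta`.
#' @export
g_second_order <- function(ev, lin) {
  p <- lin$params
  Lf <- .input_functionals(p)
  Ex <- exp(-1i * ev$omega0 * ev$T0)
  zeta <- vapply(.bg_pops, function(X) Lf[[X]](ev$q) * Ex, complex(1))
  cX <- as.complex(lin$c[.bg_pops])
  w <- ev$T0 / ev$rho_bar * ev$p_bar
  list(g20 = sum(w * 2 * cX * zeta^2),
       g11 = sum(w * 2 * cX * zeta * Conj(zeta)),
       g02 = sum(w * 2 * cX * Conj(zeta)^2),
       zeta = zeta)
}

#' Center-manifold correction terms
#'
#' Solves the two 4x4 linear systems for the correction vectors `E1` (matrix
#' `2 i omega0 I - B1 - B2 e^{-2 i omega0 T0}`, right-hand side the pure `z^2`
#' quadratic coefficients) and `E2` (delay-free matrix `-(B1 + B2)`,
#' right-hand side the `z zbar` coefficients), then evaluates the
#' second-order manifold terms `W20`, `W11` at the delayed argument
#' `theta = -1`.
#'
#' @param ev A `bg_hopf_eigvec`.
#' @param lin A `bg_linearization`.
#' @param g Output of [g_second_order()].
#' @return List with complex 4-vectors `E1`, `E2`, `W20_m1`, `W11_m1` and the
#'   two linear-solve residuals.
#' @export
center_manifold_terms <- function(ev, lin, g) {
  w0 <- ev$omega0; T0 <- ev$T0
  Ex <- exp(-1i * w0 * T0)
  cX <- as.complex(lin$c[.bg_pops])
  F20 <- 2 * cX * g$zeta^2
  F11 <- 2 * cX * g$zeta * Conj(g$zeta)
  M1 <- (2i * w0) * diag(4) - lin$B1 - lin$B2 * Ex^2
  M2 <- -(lin$B1 + lin$B2)
  if (min(svd(M1)$d) < 1e-12 || min(svd(M2)$d) < 1e-12)
    stop("singular center-manifold system (2 i omega0 resonance)")
  E1 <- solve(M1, F20)
  E2 <- solve(M2, F11 + 0i)
  res1 <- max(Mod(M1 %*% E1 - F20))
  res2 <- max(Mod(M2 %*% E2 - F11))
  q <- ev$q
  W20_m1 <- (1i * g$g20 / (w0 * T0)) * q * Ex +
    (1i * Conj(g$g02) / (3 * w0 * T0)) * Conj(q) * Conj(Ex) + E1 * Ex^2
  W11_m1 <- (-1i * g$g11 / (w0 * T0)) * q * Ex +
    (1i * Conj(g$g11) / (w0 * T0)) * Conj(q) * Conj(Ex) + E2
  list(E1 = E1, E2 = E2, W20_m1 = W20_m1, W11_m1 = W11_m1,
       residual_E1 = res1, residual_E2 = res2)
}

#' Third-order coefficient g21
#'
#' Sum of the pure cubic contribution, `6 e_X zeta^2 conj(zeta)` from
#' `f3_X = e_X (input deviation)^3`, and the quadratic-times-manifold
#' contribution `2 c_X (2 zeta L_X(W11(-1)) + conj(zeta) L_X(W20(-1)))`,
#' where `L_X` is the synaptic input functional of population X.
#'
#' @param ev A `bg_hopf_eigvec`.
#' @param lin A `bg_linearization`.
#' @param g Output of [g_second_order()].
#' @param cm Output of [center_manifold_terms()].
#' @return Complex scalar `g21`.
#' @export
g21_coefficient <- function(ev, lin, g, cm) {
  p <- lin$params
  Lf <- .input_functionals(p)
  cX <- as.complex(lin$c[.bg_pops])
  eX <- as.complex(lin$e[.bg_pops])
  LW20 <- vapply(.bg_pops, function(X) Lf[[X]](cm$W20_m1), complex(1))
  LW11 <- vapply(.bg_pops, function(X) Lf[[X]](cm$W11_m1), complex(1))
  w <- ev$T0 / ev$rho_bar * ev$p_bar
  cubic <- 6 * eX * g$zeta^2 * Conj(g$zeta)
  quadW <- 2 * cX * (2 * g$zeta * LW11 + Conj(g$zeta) * LW20)
  sum(w * (cubic + quadW))
}

#' Normal-form coefficients and Hopf classification
#'
#' Computes the first Lyapunov-type coefficient
#' `c1(0) = i (g20 g11 - 2 |g11|^2 - |g02|^2 / 3) / (2 omega0 T0) + g21 / 2`
#' (rescaled frame, rotation rate `omega0 T0`) and the classification scalars
#' `mu2 = -Re c1 / Re lambda'`, `beta2 = 2 Re c1`,
#' `T2 = -(Im c1 + mu2 Im lambda') / (omega0 T0)`, with `lambda'` the
#' transversality derivative `d lambda/d T` at the crossing. Signs classify
#' the bifurcation: `mu2 > 0` supercritical, `beta2 < 0` stable periodic
#' orbit, `T2 > 0` period grows with the delay.
#'
#' @param lin A `bg_linearization`.
#' @param T0,omega0 A verified crossing.
#' @param lambda_prime Complex `d lambda / d T` from [transversality()]
#'   (computed afresh if omitted).
#' @return A `bg_normal_form` object with the eigenvectors, `g20, g11, g02,
#'   g21`, `E1`, `E2`, `W20_m1`, `W11_m1`, `c1`, `mu2`, `beta2`, `T2` and
#'   the three labels.
#' @export
normal_form_coefficients <- function(lin, T0, omega0, lambda_prime = NULL) {
  if (is.null(lambda_prime)) lambda_prime <- transversality(T0, omega0, lin)$lambda_prime
  if (Re(lambda_prime) == 0) stop("transversality violated: Re lambda' = 0")
  ev <- hopf_eigenvectors(lin, T0, omega0)
  g <- g_second_order(ev, lin)
  cm <- center_manifold_terms(ev, lin, g)
  g21 <- g21_coefficient(ev, lin, g, cm)
  wt <- omega0 * T0
  c1 <- 1i * (g$g20 * g$g11 - 2 * Mod(g$g11)^2 - Mod(g$g02)^2 / 3) / (2 * wt) + g21 / 2
  mu2 <- -Re(c1) / Re(lambda_prime)
  beta2 <- 2 * Re(c1)
  T2 <- -(Im(c1) + mu2 * Im(lambda_prime)) / wt
  structure(list(eigenvectors = ev, g20 = g$g20, g11 = g$g11, g02 = g$g02,
                 g21 = g21, zeta = g$zeta, E1 = cm$E1, E2 = cm$E2,
                 W20_m1 = cm$W20_m1, W11_m1 = cm$W11_m1,
                 c1 = c1, mu2 = mu2, beta2 = beta2, T2 = T2,
                 lambda_prime = lambda_prime, T0 = T0, omega0 = omega0,
                 direction = if (mu2 > 0) "supercritical" else "subcritical",
                 orbit_stability = if (beta2 < 0) "stable" else "unstable",
                 period_trend = if (T2 > 0) "increasing" else "decreasing"),
            class = "bg_normal_form")
}

#' @export
print.bg_normal_form <- function(x, ...) {
  cat("<bg_normal_form>\n")
  cat(sprintf("  c1(0) = %.6g %+.6gi\n", Re(x$c1), Im(x$c1)))
  cat(sprintf("  mu2 = %.5g (%s), beta2 = %.5g (orbit %s), T2 = %.5g (period %s)\n",
              x$mu2, x$direction, x$beta2, x$orbit_stability, x$T2, x$period_trend))
  invisible(x)
}
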