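# Shared oracle utilities. Each oracle recomputes a quantity by a route
# independent of the implementation it checks.

pop_names <- c("S", "G", "E", "I")

# Independent transliteration of the vector field (kept deliberately naive).
rhs_oracle <- function(state, delayed, p) {
  sig <- function(x, M, B) M / (1 + ((M - B) / B) * exp(-4 * x / M))
  S <- delayed[1]; G <- delayed[2]; E <- delayed[3]; I <- delayed[4]
  c((sig(p$w_CS * E - p$w_GS * G, p$M_S, p$B_S) - state[1]) / p$tau,
    (sig(p$w_SG * S - p$w_GG * G - p$Str, p$M_G, p$B_G) - state[2]) / p$tau,
    (sig(-p$w_CC * I + p$C, p$M_E, p$B_E) - state[3]) / p$tau,
    (sig(p$w_CC * E, p$M_I, p$B_I) - state[4]) / p$tau)
}

# Explicit 4x4 complex determinant of the delayed characteristic matrix.
char_det_oracle <- function(lambda, T, lin) {
  M <- lambda * diag(4) - lin$B1 - lin$B2 * exp(-lambda * T)
  # cofactor expansion; base det() refuses complex matrices
  det2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  det3 <- function(m) {
    m[1, 1] * det2(m[2:3, 2:3]) - m[1, 2] * det2(m[2:3, c(1, 3)]) +
      m[1, 3] * det2(m[2:3, 1:2])
  }
  s <- 0 + 0i
  for (j in 1:4) {
    s <- s + (-1)^(1 + j) * M[1, j] * det3(M[2:4, setdiff(1:4, j)])
  }
  s
}

# Input weight matrix of the synaptic arguments (rows S, G, E, I).
input_matrix <- function(p) {
  rbind(c(0, -p$w_GS, p$w_CS, 0),
        c(p$w_SG, -p$w_GG, 0, 0),
        c(0, 0, 0, -p$w_CC),
        c(0, 0, p$w_CC, 0))
}

# Pure nonlinear remainder of the flow (linear part subtracted), used by the
# directional-derivative oracles for the g coefficients.
nonlinearity_fn <- function(p, eq) {
  Wm <- input_matrix(p)
  off <- c(0, -p$Str, p$C, 0)
  in0 <- drop(Wm %*% eq$u0) + off
  M <- c(p$M_S, p$M_G, p$M_E, p$M_I); B <- c(p$B_S, p$B_G, p$B_E, p$B_I)
  F0 <- M / (1 + ((M - B) / B) * exp(-4 * in0 / M))
  Fp <- 4 * F0 * (M - F0) / M^2
  function(v) {
    inp <- in0 + drop(Wm %*% v)
    Fv <- M / (1 + ((M - B) / B) * exp(-4 * inp / M))
    (Fv - F0 - Fp * drop(Wm %*% v)) / p$tau
  }
}

# k-th directional derivative D^k N[dir, ..., dir] by central differences on
# the real function s -> N(s * dir); complex directions are handled by
# polarization over real/imaginary parts done by the callers.
directional_deriv <- function(Nf, dir, k, h = 1e-2) {
  g <- function(s) Nf(s * dir)
  switch(as.character(k),
    "2" = (g(h) - 2 * g(0) + g(-h)) / h^2,
    "3" = (g(2 * h) - 2 * g(h) + 2 * g(-h) - g(-2 * h)) / (2 * h^3),
    stop("k must be 2 or 3"))
}

# Symmetric bilinear/trilinear forms of N via polarization of directional
# derivatives; complex-valued directions u, v (and w).
bilinear_oracle <- function(Nf, u, v, h = 1e-2) {
  B_real <- function(a, b) {
    (directional_deriv(Nf, a + b, 2, h) - directional_deriv(Nf, a - b, 2, h)) / 4
  }
  ur <- Re(u); ui <- Im(u); vr <- Re(v); vi <- Im(v)
  B_real(ur, vr) - B_real(ui, vi) + 1i * (B_real(ur, vi) + B_real(ui, vr))
}

trilinear_oracle <- function(Nf, u, v, w, h = 5e-2) {
  C_real <- function(a, b, cc) {
    # polarization of the third directional derivative
    (directional_deriv(Nf, a + b + cc, 3, h) - directional_deriv(Nf, a + b - cc, 3, h) -
     directional_deriv(Nf, a - b + cc, 3, h) + directional_deriv(Nf, a - b - cc, 3, h)) / 24
  }
  comb <- function(a, b, cc) C_real(a, b, cc)
  parts <- list(list(Re(u), 1), list(Im(u), 1i))
  out <- 0 + 0i
  for (pu in parts) for (pv in list(list(Re(v), 1), list(Im(v), 1i)))
    for (pw in list(list(Re(w), 1), list(Im(w), 1i))) {
      out <- out + pu[[2]] * pv[[2]] * pw[[2]] * comb(pu[[1]], pv[[1]], pw[[1]])
    }
  out
}

# Rightmost-root tracker: Newton continuation of all four zero-delay
# eigenvalues in T; returns the smallest T in (0, T_max] where the maximal
# real part crosses zero (bisection refinement), or NA.
delay_scan_oracle <- function(lin, T_max = 40, step = 0.01, tol = 1e-7) {
  Delta <- function(lam, T) characteristic_value(lam, T, lin)
  dDelta <- function(lam, T, eps = 1e-7) {
    (Delta(lam + eps, T) - Delta(lam - eps, T)) / (2 * eps)
  }
  newton_root <- function(lam, T) {
    for (i in 1:60) {
      f <- Delta(lam, T)
      lam2 <- lam - f / dDelta(lam, T)
      if (Mod(lam2 - lam) < 1e-12) return(lam2)
      lam <- lam2
    }
    lam
  }
  roots <- eigen(lin$B1 + lin$B2)$values + 0i
  max_re <- function(T, rts) max(Re(rts))
  Ts <- seq(step, T_max, by = step)
  prev_T <- 0
  for (T in Ts) {
    roots <- vapply(roots, newton_root, complex(1), T = T)
    if (max(Re(roots)) > 0) {
      lo <- prev_T; hi <- T
      roots_lo <- roots
      for (i in 1:50) {
        mid <- (lo + hi) / 2
        rm <- vapply(roots_lo, newton_root, complex(1), T = mid)
        if (max(Re(rm)) > 0) hi <- mid else { lo <- mid }
      }
      return((lo + hi) / 2)
    }
    prev_T <- T
  }
  NA_real_
}

# Physical-time characteristic-matrix normal-form oracle for c1(0), using SVD
# null vectors and Delta-inverse solves; independent of the center-manifold
# assembly under test.
c1_oracle <- function(p, lin, T0, w0) {
  tau_d <- T0
  Delta <- function(lam) lam * diag(4) - lin$B1 - lin$B2 * exp(-lam * tau_d)
  M <- Delta(1i * w0)
  sv <- svd(M)
  q <- sv$v[, 4]; q <- q / q[1]
  pL <- Conj(sv$u[, 4])
  pL <- pL / drop(pL %*% (diag(4) + tau_d * lin$B2 * exp(-1i * w0 * tau_d)) %*% q)
  Lm <- input_matrix(p)
  cX <- as.complex(lin$c); eX <- as.complex(lin$e)
  Bf <- function(u, v) 2 * cX * (Lm %*% u) * (Lm %*% v)
  Cf <- function(u, v, w) 6 * eX * (Lm %*% u) * (Lm %*% v) * (Lm %*% w)
  Ed <- exp(-1i * w0 * tau_d)
  phi_d <- q * Ed; phib_d <- Conj(q) * Conj(Ed)
  h20_d <- exp(-2i * w0 * tau_d) * solve(Delta(2i * w0), Bf(phi_d, phi_d))
  h11_d <- solve(Delta(0 + 0i), Bf(phi_d, phib_d))
  0.5 * drop(pL %*% (Cf(phi_d, phi_d, phib_d) + Bf(phib_d, h20_d) + 2 * Bf(phi_d, h11_d)))
}

# A small deterministic pool of admissible random parameter sets (cached per
# session; generation re-checks crossings which is mildly expensive).
random_admissible <- local({
  cache <- list()
  function(n, seed = 42) {
    key <- paste(n, seed)
    if (is.null(cache[[key]])) cache[[key]] <<- generate_fixtures(seed, n)
    cache[[key]]
  }
})
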