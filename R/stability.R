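# Characteristic equation of the delayed linearization, imaginary-axis
# crossings, transversality, and zero-delay Routh-Hurwitz stability.

#' Characteristic function of the linearized delay system
#'
#' The characteristic determinant factorizes over the two feedback loops,
#' `Delta(lambda) = Delta_1(lambda) * Delta_2(lambda)`, with
#' `Delta_1 = (lambda + 1/tau)^2 - (lambda + 1/tau) a22 e^{-lambda T}
#'            - a12 a21 e^{-2 lambda T}` (STN-GPe loop) and
#' `Delta_2 = (lambda + 1/tau)^2 - a34 a43 e^{-2 lambda T}`
#' (cortical excitatory-inhibitory loop).
#'
#' @param lambda Complex argument(s) (1/ms).
#' @param T Transmission delay (ms).
#' @param lin A `bg_linearization` from [linearize()].
#' @param factor `"both"` (product), `"loop1"` or `"loop2"`.
#' @return Complex value(s) of the chosen factor.
#' @export
characteristic_value <- function(lambda, T, lin, factor = c("both", "loop1", "loop2")) {
  factor <- match.arg(factor)
  L <- lambda + 1 / lin$tau
  Ex <- exp(-lambda * T)
  d1 <- L^2 - L * lin$a22 * Ex - lin$a12 * lin$a21 * Ex^2
  d2 <- L^2 - lin$a34 * lin$a43 * Ex^2
  switch(factor, both = d1 * d2, loop1 = d1, loop2 = d2)
}

# Real positive roots z of z^4 + k1 z^3 + k2 z^2 + k3 z + k4, via companion
# matrix eigenvalues. Roots with |Im| < im_tol and Re > re_tol count.
.quartic_positive_roots <- function(k, im_tol = 1e-9, re_tol = 1e-10) {
  Cm <- rbind(c(-k[1], -k[2], -k[3], -k[4]), cbind(diag(3), 0))
  ev <- eigen(Cm, only.values = TRUE)$values
  z <- Re(ev[abs(Im(ev)) < im_tol * max(1, abs(ev)) & Re(ev) > re_tol])
  sort(unique(z))
}

# Candidate delays for a crossing frequency omega solving
# P x^2 + L a22 x - L^2 = 0 (loop 1) in x = e^{-i omega T}: unit-modulus roots
# give the crossing phase; branches j shift by 2 pi / omega.
.delays_from_phase <- function(omega, theta, j_max = 2) {
  # e^{-i omega T} has argument -omega T = theta (mod 2pi) => T = (-theta + 2 pi j)/omega
  T0 <- (-theta) %% (2 * pi) / omega
  T0 + 2 * pi * (0:j_max) / omega
}

#' Imaginary-axis crossings of the STN-GPe loop factor
#'
#' Builds the quartic in `z = omega^2` obtained by eliminating the delay from
#' `Delta_1(i omega) = 0` (coefficients `k1..k4`), extracts its real positive
#' roots via companion-matrix eigenvalues, and for each frequency recovers the
#' candidate delays from the unit-modulus roots of the quadratic
#' `a12 a21 x^2 + (i omega + 1/tau) a22 x - (i omega + 1/tau)^2 = 0` in
#' `x = e^{-i omega T}`, which enforces the sine and cosine branch conditions
#' jointly. Spurious algebraic roots (the elimination squares a factor) are
#' discarded by the unit-modulus and residual filters.
#'
#' @param lin A `bg_linearization`.
#' @param j_max Number of extra `2 pi j / omega` branches to attach.
#' @param residual_tol Acceptance threshold on `|Delta_1(i omega)|`.
#' @return A tibble with columns `omega` (rad/ms), `T` (ms), `loop` (1),
#'   `j` (branch index); zero rows when the loop cannot resonate.
#' @export
loop1_crossings <- function(lin, j_max = 2, residual_tol = 1e-8) {
  tau <- lin$tau; a22 <- lin$a22; P <- lin$a12 * lin$a21
  m2 <- 1 / tau^2
  k <- c(4 * m2 - a22^2,
         6 * m2^2 - 3 * a22^2 * m2 - 2 * P * (P + a22^2),
         4 * m2^3 - 3 * a22^2 * m2^2 - 4 * P * (P + a22^2) * m2 - a22^2 * P^2,
         m2^4 - a22^2 * m2^3 - 2 * P * (P + a22^2) * m2^2 - a22^2 * P^2 * m2 + P^4)
  z <- .quartic_positive_roots(k)
  om <- Tt <- jj <- numeric(0)
  for (zz in z) {
    omega <- sqrt(zz)
    L <- 1i * omega + 1 / tau
    xs <- if (abs(P) > 1e-14) {
      disc <- sqrt(L^2 * a22^2 + 4 * P * L^2 + 0i)
      c((-L * a22 + disc) / (2 * P), (-L * a22 - disc) / (2 * P))
    } else if (abs(a22) > 1e-14) {
      L / a22
    } else next
    xs <- xs[abs(Mod(xs) - 1) < 1e-6]
    for (x in xs) {
      Ts <- .delays_from_phase(omega, Arg(x), j_max)
      Ts <- Ts[Ts > 0]
      ok <- Mod(characteristic_value(1i * omega, Ts, lin, "loop1")) < residual_tol
      om <- c(om, rep(omega, sum(ok))); Tt <- c(Tt, Ts[ok])
      jj <- c(jj, seq_along(Ts)[ok] - 1)
    }
  }
  # the two quadratic roots can describe the same crossing to rounding error
  keep <- !duplicated(data.frame(round(om, 9), round(Tt, 6)))
  ord <- order(Tt[keep])
  tibble::tibble(omega = om[keep][ord], T = Tt[keep][ord], loop = 1L,
                 j = as.integer(jj[keep][ord]))
}

#' Imaginary-axis crossings of the cortical loop factor
#'
#' A real crossing of `Delta_2` exists iff `-a34 a43 > 1/tau^2`, with
#' frequency `omega5 = sqrt(-a34 a43 - 1/tau^2)` fixed by the modulus
#' condition `omega^2 + 1/tau^2 = |a34 a43|`; candidate delays follow from the
#' phase of `e^{-2 i omega T} = (i omega + 1/tau)^2 / (a34 a43)`, which
#' enforces the sine and cosine conditions jointly.
#'
#' @inheritParams loop1_crossings
#' @return A tibble like [loop1_crossings()] with `loop = 2`; zero rows when
#'   the discriminant is non-positive.
#' @export
loop2_crossings <- function(lin, j_max = 3, residual_tol = 1e-8) {
  tau <- lin$tau; R <- lin$a34 * lin$a43
  disc <- -R - 1 / tau^2
  if (disc <= 0) return(tibble::tibble(omega = numeric(), T = numeric(),
                                       loop = integer(), j = integer()))
  omega <- sqrt(disc)
  L <- 1i * omega + 1 / tau
  x2 <- L^2 / R                        # = e^{-2 i omega T}, unit modulus by construction
  theta <- Arg(x2)
  Ts <- ((-theta) %% (2 * pi) + 2 * pi * (0:j_max)) / (2 * omega)
  Ts <- Ts[Ts > 0]
  keep <- Mod(characteristic_value(1i * omega, Ts, lin, "loop2")) < residual_tol
  tibble::tibble(omega = omega, T = Ts[keep], loop = 2L, j = seq_along(Ts[keep]) - 1L)
}

#' Minimal critical delay over both loops
#'
#' Merges the loop-1 and loop-2 crossing candidates and identifies the minimal
#' positive critical delay `T0` with its frequency `omega0` and the loop that
#' produces it (resonance attribution: STN-GPe loop vs cortical E-I loop). If
#' several frequencies tie for the minimal delay, all are recorded and the
#' largest frequency is designated for downstream analysis.
#'
#' @param lin A `bg_linearization`.
#' @param tie_tol Delay difference (ms) treated as a tie.
#' @return A `bg_crossings` object: the candidate tibble with attributes
#'   `T0`, `omega0`, `loop0`, `f0_hz`, `tie`; `T0` is `NA` when no crossing
#'   exists (no Hopf crossing verdict).
#' @export
critical_delays <- function(lin, tie_tol = 1e-9) {
  cand <- dplyr::arrange(dplyr::bind_rows(loop1_crossings(lin), loop2_crossings(lin)),
                         .data$T)
  if (nrow(cand) == 0) {
    return(structure(cand, T0 = NA_real_, omega0 = NA_real_, loop0 = NA_integer_,
                     f0_hz = NA_real_, tie = FALSE, class = c("bg_crossings", class(cand))))
  }
  tied <- cand[cand$T - cand$T[1] < tie_tol, ]
  pick <- tied[which.max(tied$omega), ]
  structure(cand, T0 = pick$T, omega0 = pick$omega, loop0 = pick$loop,
            f0_hz = 1000 * pick$omega / (2 * pi), tie = nrow(tied) > 1L,
            class = c("bg_crossings", class(cand)))
}

#' Transversality derivative at a crossing
#'
#' Evaluates the reciprocal eigenvalue speed `(d lambda / d T)^{-1}` at
#' `lambda = i omega0` from the implicit derivative of
#' `Delta = Delta_1 Delta_2`:
#' `(d lambda/d T)^{-1} = -(d1 Delta_1 + d2 Delta_2) / (d3 Delta_1 + d4 Delta_2)`
#' with `d1 = dDelta_2/dlambda`, `d2 = dDelta_1/dlambda`,
#' `d3 = dDelta_2/dT`, `d4 = dDelta_1/dT`. The transversality condition (H2)
#' is `Re` of the reciprocal non-zero, equivalently `P_R Q_R + P_I Q_I != 0`
#' for numerator `P` and denominator `Q`.
#'
#' @param T0,omega0 A verified crossing (ms, rad/ms).
#' @param lin A `bg_linearization`.
#' @return A list with `lambda_prime` (complex `d lambda/d T`),
#'   `inv_lambda_prime`, `re_inv` (`= -(P_R Q_R + P_I Q_I)/(Q_R^2 + Q_I^2)`),
#'   the components `P_R, P_I, Q_R, Q_I`, and logical `H2`.
#' @export
transversality <- function(T0, omega0, lin) {
  tau <- lin$tau; a22 <- lin$a22
  P2 <- lin$a12 * lin$a21; R2 <- lin$a34 * lin$a43
  lam <- 1i * omega0
  L <- lam + 1 / tau
  Ex <- exp(-lam * T0)
  D1 <- L^2 - L * a22 * Ex - P2 * Ex^2
  D2 <- L^2 - R2 * Ex^2
  d1 <- 2 * L + 2 * T0 * R2 * Ex^2                      # dDelta2/dlambda
  d2 <- 2 * L + a22 * Ex * (T0 * L - 1) + 2 * T0 * P2 * Ex^2  # dDelta1/dlambda
  d3 <- 2 * lam * R2 * Ex^2                             # dDelta2/dT
  d4 <- lam * L * a22 * Ex + 2 * lam * P2 * Ex^2        # dDelta1/dT
  num <- d1 * D1 + d2 * D2
  den <- d3 * D1 + d4 * D2
  if (Mod(den) == 0) stop("degenerate crossing: denominator Q vanishes")
  inv <- -num / den
  PR <- Re(num); PI <- Im(num); QR <- Re(den); QI <- Im(den)
  re_inv <- -(PR * QR + PI * QI) / (QR^2 + QI^2)
  list(lambda_prime = 1 / inv, inv_lambda_prime = inv, re_inv = re_inv,
       P_R = PR, P_I = PI, Q_R = QR, Q_I = QI,
       H2 = abs(PR * QR + PI * QI) > 0)
}

#' Zero-delay stability by the Routh-Hurwitz criterion
#'
#' At `T = 0` the characteristic equation is the quartic
#' `lambda^4 + d3 lambda^3 + d2 lambda^2 + d1 lambda + d0 = 0`, the
#' characteristic polynomial of `B1 + B2` obtained by expanding the product of
#' the two loop factors. Condition (H3) holds iff all `d_i > 0`,
#' `d3 d2 > d1`, and `d3 d2 d1 > d1^2 + d3^2 d0`.
#'
#' @param lin A `bg_linearization`.
#' @return A `bg_rh` object: coefficients `d0..d3`, the individual condition
#'   flags, and the overall `H3` verdict.
#' @export
zero_delay_stability <- function(lin) {
  m <- 1 / lin$tau; a <- lin$a22
  P <- lin$a12 * lin$a21; R <- lin$a34 * lin$a43
  # (lambda^2 + b1 lambda + b0)(lambda^2 + q1 lambda + q0)
  b1 <- 2 * m - a; b0 <- m^2 - a * m - P
  q1 <- 2 * m;     q0 <- m^2 - R
  d3 <- b1 + q1
  d2 <- b0 + q0 + b1 * q1
  d1 <- b1 * q0 + q1 * b0
  d0 <- b0 * q0
  flags <- c(d0 = d0 > 0, d1 = d1 > 0, d2 = d2 > 0, d3 = d3 > 0,
             hurwitz2 = d3 * d2 > d1,
             hurwitz3 = d3 * d2 * d1 > d1^2 + d3^2 * d0)
  structure(list(d0 = d0, d1 = d1, d2 = d2, d3 = d3, flags = flags,
                 H3 = all(flags)), class = "bg_rh")
}

#' Full Hopf-existence report for a parameter set
#'
#' Orchestrates equilibrium, linearization, (H1) imaginary-axis crossings,
#' (H2) transversality at the minimal crossing, and (H3) zero-delay
#' Routh-Hurwitz stability. The model undergoes a Hopf bifurcation at
#' `T = T0` when all three hold; the report records the verdict, the crossing
#' set, the resonance attribution, and (optionally) the normal-form
#' coefficients and classification.
#'
#' @param p A [bg_params()] parameter set (its `T` field is not used by the
#'   analysis; `T0` is computed from scratch).
#' @param normal_form If `TRUE`, attach [normal_form_coefficients()] at the
#'   minimal crossing.
#' @return A `hopf_report` object. Use [glance()][generics::glance] for a
#'   one-row summary and [tidy()][generics::tidy] for the crossing table.
#' @examples
#' rep <- hopf_report(bg_params())
#' glance(rep)
#' @export
hopf_report <- function(p, normal_form = FALSE) {
  validate_bg_params(p)
  eq <- solve_equilibrium(p)
  lin <- linearize(p, eq)
  cross <- critical_delays(lin)
  rh <- zero_delay_stability(lin)
  T0 <- attr(cross, "T0"); omega0 <- attr(cross, "omega0")
  H1 <- !is.na(T0)
  tv <- if (H1) transversality(T0, omega0, lin) else NULL
  H2 <- if (H1) tv$H2 else FALSE
  verdict <- H1 && H2 && rh$H3
  reason <- if (verdict) sprintf("Hopf at T0 = %.4f ms", T0)
            else if (!H1) "(H1) fails: no imaginary-axis crossing"
            else if (!H2) "(H2) fails: transversality derivative vanishes"
            else "(H3) fails: equilibrium already unstable at T = 0"
  nf <- if (normal_form && verdict) {
    normal_form_coefficients(lin, T0, omega0, tv$lambda_prime)
  } else NULL
  structure(list(params = p, equilibrium = eq, linearization = lin,
                 crossings = cross, transversality = tv, zero_delay = rh,
                 T0 = T0, omega0 = omega0, f0_hz = attr(cross, "f0_hz"),
                 loop0 = attr(cross, "loop0"),
                 decoupled_cortex_drive = p$w_CS == 0,
                 H1 = H1, H2 = H2, H3 = rh$H3, hopf = verdict, reason = reason,
                 normal_form = nf),
            class = "hopf_report")
}

#' @export
print.hopf_report <- function(x, ...) {
  cat("<hopf_report>\n  ", x$reason, "\n", sep = "")
  if (x$H1) {
    cat(sprintf("  omega0 = %.5f rad/ms (f0 = %.3f Hz), loop %d (%s)\n",
                x$omega0, x$f0_hz, x$loop0,
                if (x$loop0 == 1) "STN-GPe" else "cortical E-I"))
    cat(sprintf("  Re(dlambda/dT) = %.5g at the crossing\n",
                Re(x$transversality$lambda_prime)))
  }
  cat(sprintf("  H1=%s H2=%s H3=%s\n", x$H1, x$H2, x$H3))
  if (!is.null(x$normal_form)) print(x$normal_form)
  invisible(x)
}
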