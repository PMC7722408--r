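# Reduced vector field, equilibrium solver and delayed linearization.

# Synaptic input map: in = W %*% state + offset, rows ordered (S, G, E, I).
# S gets  w_CS*E - w_GS*G
# G gets  w_SG*S - w_GG*G - Str
# E gets -w_CC*I + C
# I gets  w_CC*E
.input_map <- function(p) {
  W <- matrix(0, 4, 4, dimnames = list(.bg_pops, .bg_pops))
  W["S", "G"] <- -p$w_GS; W["S", "E"] <- p$w_CS
  W["G", "S"] <-  p$w_SG; W["G", "G"] <- -p$w_GG
  W["E", "I"] <- -p$w_CC
  W["I", "E"] <-  p$w_CC
  list(W = W, offset = c(S = 0, G = -p$Str, E = p$C, I = 0))
}

.apply_F <- function(p, inputs) {
  vapply(seq_along(.bg_pops), function(i) {
    MB <- .pop_MB(p, .bg_pops[i])
    activation(inputs[i], MB[1], MB[2])
  }, numeric(1))
}

#' Right-hand side of the reduced delay system
#'
#' Evaluates the vector field of the reduced equal-delay model,
#' `dX/dt = (F_X(inputs from the delayed state) - X) / tau`, with synaptic
#' inputs `S: w_CS E(t-T) - w_GS G(t-T)`, `G: w_SG S(t-T) - w_GG G(t-T) - Str`,
#' `E: -w_CC I(t-T) + C`, `I: w_CC E(t-T)`.
#'
#' @param state Current state, named or unnamed numeric vector `(S, G, E, I)`
#'   in spk/s.
#' @param delayed State at time `t - T`, same layout.
#' @param p A [bg_params()] parameter set.
#' @return Named derivative vector (spk/s per ms).
#' @examples
#' p <- bg_params()
#' eq <- solve_equilibrium(p)
#' max(abs(reduced_rhs(eq$u0, eq$u0, p)))  # ~ 0 at the fixed point
#' @export
reduced_rhs <- function(state, delayed, p) {
  validate_bg_params(p)
  state <- as.numeric(state); delayed <- as.numeric(delayed)
  stopifnot(length(state) == 4, length(delayed) == 4)
  if (!all(is.finite(state)) || !all(is.finite(delayed))) stop("non-finite state")
  im <- .input_map(p)
  inputs <- drop(im$W %*% delayed) + im$offset
  d <- (.apply_F(p, inputs) - state) / p$tau
  names(d) <- .bg_pops
  d
}

#' Solve for the equilibrium firing rates
#'
#' Finds the fixed point `u0 = (S*, G*, E*, I*)` of the reduced model, which is
#' independent of the transmission delay. The cortical pair `(E, I)` decouples
#' from the basal-ganglia pair and each 2-D subsystem is solved by damped
#' fixed-point iteration followed by a Newton polish on the full 4-D residual.
#' Eight deterministic multistart seeds on a coarse grid of the state box
#' `(0, M_X)^4` are used to flag non-uniqueness.
#'
#' @param p A [bg_params()] parameter set.
#' @param tol Convergence tolerance on the maximum absolute component of
#'   `reduced_rhs` (spk/s per ms).
#' @param max_iter Iteration cap per start.
#' @return A `bg_equilibrium` object: list with `u0` (named rates), `residual`
#'   (max abs fixed-point defect, spk/s per ms), and `unique_flag`.
#' @export
solve_equilibrium <- function(p, tol = 1e-10, max_iter = 30) {
  validate_bg_params(p)
  im <- .input_map(p)
  W <- im$W; off <- im$offset
  M <- c(p$M_S, p$M_G, p$M_E, p$M_I)
  B <- c(p$B_S, p$B_G, p$B_E, p$B_I)
  kap <- (M - B) / B
  Ff <- function(inp) M / (1 + kap * exp(-4 * inp / M))
  gfun <- function(x) Ff(drop(W %*% x) + off)
  rhs_norm <- function(x) max(abs(gfun(x) - x)) / p$tau

  newton <- function(x) {
    r_old <- Inf
    for (k in seq_len(40)) {
      inputs <- drop(W %*% x) + off
      Fv <- Ff(inputs)
      r <- Fv - x
      if (max(abs(r)) / p$tau < tol * 1e-2) break
      Fp <- 4 * Fv * (M - Fv) / M^2
      J <- Fp * W - diag(4)
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1                       # damp if the full step worsens the residual
      repeat {
        xn <- x + lam * step
        if (max(abs(gfun(xn) - xn)) <= max(abs(r)) || lam < 1e-4) break
        lam <- lam / 2
      }
      if (max(abs(xn - x)) == 0) break
      x <- xn
    }
    x
  }

  fracs <- rbind(
    c(.2, .2, .2, .2), c(.8, .8, .8, .8), c(.2, .8, .2, .8), c(.8, .2, .8, .2),
    c(.5, .5, .2, .8), c(.5, .5, .8, .2), c(.2, .8, .8, .2), c(.8, .2, .2, .8))
  sols <- list()
  for (s in seq_len(nrow(fracs))) {
    x <- fracs[s, ] * M
    for (k in seq_len(max_iter)) {            # damped fixed-point pass
      xn <- 0.7 * x + 0.3 * gfun(x)
      if (max(abs(xn - x)) < 1e-3) { x <- xn; break }
      x <- xn
    }
    x <- newton(x)
    if (rhs_norm(x) < tol) sols[[length(sols) + 1L]] <- x
  }
  if (!length(sols)) stop("equilibrium solver failed to converge from all starts")
  S <- do.call(rbind, sols)
  # cluster coincident solutions
  uniq <- S[1, , drop = FALSE]
  for (i in seq_len(nrow(S))[-1]) {
    if (all(apply(uniq, 1, function(u) max(abs(u - S[i, ])) > 1e-6))) {
      uniq <- rbind(uniq, S[i, ])
    }
  }
  u0 <- uniq[1, ]
  names(u0) <- .bg_pops
  structure(list(u0 = u0, residual = rhs_norm(u0), unique_flag = nrow(uniq) == 1L,
                 n_found = nrow(uniq)),
            class = "bg_equilibrium")
}

#' @export
print.bg_equilibrium <- function(x, ...) {
  cat("<bg_equilibrium>\n  u0: ",
      paste(sprintf("%s*=%.4f", names(x$u0), x$u0), collapse = ", "),
      sprintf("\n  residual %.3g spk/s per ms; %s\n", x$residual,
              if (x$unique_flag) "unique over multistart" else
                sprintf("%d distinct fixed points found", x$n_found)))
  invisible(x)
}

#' Linearize the model about an equilibrium
#'
#' Computes the entries of the delayed Jacobian `B2` (all feedback is delayed,
#' the instantaneous part is the leak `B1 = -I/tau`) together with the
#' quadratic and cubic Taylor coefficients of the sigmoid nonlinearity used by
#' the normal-form computation:
#' `a_ij = (sign) w_ij F'_X(in*)/tau`, `c_X = F''_X(in*)/(2 tau)`,
#' `e_X = F'''_X(in*)/(6 tau)`, all evaluated at the equilibrium input `in*`.
#'
#' @param p A [bg_params()] parameter set.
#' @param eq A `bg_equilibrium` from [solve_equilibrium()]; solved afresh if
#'   omitted.
#' @return A `bg_linearization` object with fields `a12, a13, a21, a22, a34,
#'   a43` (1/ms), `c` and `e` (named per population), `tau`, the matrices
#'   `B1`, `B2`, and the equilibrium.
#' @export
linearize <- function(p, eq = NULL) {
  validate_bg_params(p)
  if (is.null(eq)) eq <- solve_equilibrium(p)
  stopifnot(inherits(eq, "bg_equilibrium"))
  if (eq$residual > 1e-8) stop("equilibrium residual too large for linearization")
  u0 <- eq$u0
  for (X in .bg_pops) {
    M <- p[[paste0("M_", X)]]
    if (u0[X] < 1e-9 || M - u0[X] < 1e-9) {
      stop("equilibrium component ", X, " at the sigmoid saturation boundary; ",
           "derivative formulas are degenerate")
    }
  }
  im <- .input_map(p)
  inputs <- drop(im$W %*% u0) + im$offset
  Fp  <- numeric(4); Fpp <- numeric(4); Fppp <- numeric(4)
  for (i in 1:4) {
    MB <- .pop_MB(p, .bg_pops[i])
    Fp[i]   <- activation_deriv(inputs[i], MB[1], MB[2], 1)
    Fpp[i]  <- activation_deriv(inputs[i], MB[1], MB[2], 2)
    Fppp[i] <- activation_deriv(inputs[i], MB[1], MB[2], 3)
  }
  names(Fp) <- names(Fpp) <- names(Fppp) <- .bg_pops
  tau <- p$tau
  lin <- list(
    a12 = -p$w_GS * Fp["S"] / tau,
    a13 =  p$w_CS * Fp["S"] / tau,
    a21 =  p$w_SG * Fp["G"] / tau,
    a22 = -p$w_GG * Fp["G"] / tau,
    a34 = -p$w_CC * Fp["E"] / tau,
    a43 =  p$w_CC * Fp["I"] / tau,
    c = Fpp / (2 * tau),
    e = Fppp / (6 * tau),
    Fprime = Fp,
    tau = tau,
    params = p,
    equilibrium = eq
  )
  lin[c("a12", "a13", "a21", "a22", "a34", "a43")] <-
    lapply(lin[c("a12", "a13", "a21", "a22", "a34", "a43")], unname)
  lin$B1 <- -diag(4) / tau
  lin$B2 <- matrix(c(0, lin$a12, lin$a13, 0,
                     lin$a21, lin$a22, 0, 0,
                     0, 0, 0, lin$a34,
                     0, 0, lin$a43, 0), 4, 4, byrow = TRUE,
                   dimnames = list(.bg_pops, .bg_pops))
  structure(lin, class = "bg_linearization")
}

#' @export
print.bg_linearization <- function(x, ...) {
  cat("<bg_linearization>\n")
  cat(sprintf("  a12=%.5g a13=%.5g a21=%.5g a22=%.5g a34=%.5g a43=%.5g (1/ms)\n",
              x$a12, x$a13, x$a21, x$a22, x$a34, x$a43))
  cat("  c:", paste(sprintf("%s=%.4g", .bg_pops, x$c), collapse = " "), "\n")
  cat("  e:", paste(sprintf("%s=%.4g", .bg_pops, x$e), collapse = " "), "\n")
  invisible(x)
}
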