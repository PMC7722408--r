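# Euler simulation of the delay system and attractor summaries.

#' Simulate the reduced delay model by explicit Euler integration
#'
#' Integrates the four firing rates with a fixed step `h`, reading delayed
#' values from a history buffer of `round(T/h)` steps (the delay is realized
#' on the step grid). The default history is the equilibrium held constant on
#' `[-T, 0]` with a `+1` spk/s perturbation of the STN rate, which is needed
#' to leave the fixed point when it is unstable.
#'
#' @param p A [bg_params()] parameter set (`p$T` is the delay used).
#' @param duration Run length (ms).
#' @param h Euler step (ms).
#' @param history Either `NULL` (equilibrium plus `perturb`), a named state
#'   vector held constant on `[-T, 0]`, or a `bg_trace`/matrix whose tail
#'   supplies the history (for ramped continuation).
#' @param perturb Named perturbation (spk/s) added to the constant history
#'   when `history` is `NULL`.
#' @param thin Keep every `thin`-th sample in the returned trace (the
#'   integration itself always uses step `h`).
#' @return A `bg_trace` tibble with columns `t, S, G, E, I` and attributes
#'   `params`, `h`, `duration`.
#' @examples
#' p <- bg_params(T = 2.5)
#' tr <- simulate_bg(p, duration = 200)
#' summarize_attractor(tr)
#' @export
simulate_bg <- function(p, duration = 3000, h = 0.01, history = NULL,
                        perturb = c(S = 1, G = 0, E = 0, I = 0), thin = 1L) {
  validate_bg_params(p)
  stopifnot(h > 0, duration > 0)
  d <- if (p$T <= 0) 0L else as.integer(round(p$T / h))
  hist_mat <- if (is.null(history) || (is.numeric(history) && !is.matrix(history))) {
    x0 <- if (is.null(history)) {
      pert <- c(S = 0, G = 0, E = 0, I = 0)
      pert[names(perturb)] <- perturb
      solve_equilibrium(p)$u0 + pert
    } else {
      stopifnot(length(history) == 4)
      as.numeric(history)
    }
    matrix(rep(as.numeric(x0), each = d + 1L), d + 1L, 4)
  } else {
    m <- if (inherits(history, "data.frame")) {
      as.matrix(history[, c("S", "G", "E", "I")])
    } else as.matrix(history)
    stopifnot(ncol(m) == 4)
    if (nrow(m) < d + 1L) {      # pad short histories with their first row
      m <- rbind(matrix(rep(m[1, ], each = d + 1L - nrow(m)), ncol = 4), m)
    }
    m[(nrow(m) - d):nrow(m), , drop = FALSE]
  }
  out <- .euler_dde_cpp(unlist(p[.bg_param_names]), hist_mat, duration, h)
  idx <- seq(1L, nrow(out), by = as.integer(thin))
  tr <- tibble::tibble(t = (idx - 1L) * h,
                       S = out[idx, 1], G = out[idx, 2],
                       E = out[idx, 3], I = out[idx, 4])
  structure(tr, params = p, h = h, duration = duration,
            class = c("bg_trace", class(tr)))
}

# Local maxima of x above a prominence floor; returns indices.
.find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  if (!length(cand)) return(integer())
  floorv <- min(x) + 0.5 * (max(x) - min(x))
  cand[x[cand] >= floorv]
}

# Dominant frequency (Hz) from the FFT of a demeaned series sampled every dt ms.
.spectral_peak <- function(x, dt) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  sp[1] <- 0
  fr <- (seq_len(floor(n / 2)) - 1) / (n * dt) * 1000
  fr[which.max(sp)]
}

#' Summarize the attractor of a simulated trace
#'
#' Discards an initial transient, then classifies the post-transient window as
#' a fixed point or an oscillation by the peak-to-trough excursion of the STN
#' rate. For oscillations the dominant frequency is estimated from mean
#' inter-peak intervals (robust for non-sinusoidal cycles) and cross-checked
#' against the spectral peak; a discrepancy above 5 percent sets
#' `freq_flagged`.
#'
#' @param trace A `bg_trace` (or data frame with columns `t, S, G, E, I`).
#' @param transient_fraction Fraction of the run discarded as transient.
#' @param amp_threshold Peak-to-trough STN excursion (spk/s) below which the
#'   trace counts as a fixed point.
#' @param sustained If `TRUE`, additionally require the excursion not to be
#'   decaying across the analysis window: the peak-to-trough amplitude of the
#'   last quarter of the run must reach `sustained_ratio` times that of the
#'   preceding quarter, unless it exceeds `sustained_override` (clearly a
#'   finite attractor). This rejects the slowly decaying resonant ring left by
#'   a perturbation near (but below) a Hopf point, where critical slowing
#'   down makes a plain threshold unreliable.
#' @param sustained_ratio,sustained_override Tuning constants for `sustained`.
#' @return One-row tibble: `kind`, `amplitude` (spk/s, max - min of S),
#'   `frequency` (Hz, `NA` for fixed points), `band`, `freq_spectral`,
#'   `freq_flagged`, and per-population `*_min`/`*_max` over the window.
#' @export
summarize_attractor <- function(trace, transient_fraction = 0.5, amp_threshold = 1e-3,
                                sustained = FALSE, sustained_ratio = 0.9,
                                sustained_override = Inf) {
  stopifnot(all(c("t", "S", "G", "E", "I") %in% names(trace)))
  n <- nrow(trace)
  win <- trace[seq.int(max(1L, floor(n * transient_fraction)), n), ]
  if (nrow(win) < 8) stop("post-transient window too short")
  rng <- lapply(c("S", "G", "E", "I"), function(v) range(win[[v]]))
  names(rng) <- c("S", "G", "E", "I")
  amp <- diff(rng$S)
  oscillatory <- amp > amp_threshold
  if (oscillatory && sustained) {
    q4 <- trace$S[seq.int(max(1L, floor(n * 0.75)), n)]
    q3 <- trace$S[seq.int(max(1L, floor(n * 0.5)), floor(n * 0.75))]
    a4 <- diff(range(q4)); a3 <- diff(range(q3))
    if (a4 < sustained_override && a4 < sustained_ratio * a3) {
      oscillatory <- FALSE
      amp <- a4
    }
  }
  freq <- freq_sp <- NA_real_
  flagged <- FALSE
  if (oscillatory) {
    pk <- .find_peaks(win$S)
    dt <- mean(diff(win$t))
    if (length(pk) >= 3) {
      freq <- 1000 / (mean(diff(pk)) * dt)
      freq_sp <- .spectral_peak(win$S, dt)
      flagged <- is.finite(freq_sp) && freq_sp > 0 && abs(freq - freq_sp) / freq > 0.05
    } else {
      freq <- .spectral_peak(win$S, dt)
      freq_sp <- freq
    }
  }
  tibble::tibble(
    kind = if (oscillatory) "oscillation" else "fixed_point",
    amplitude = if (oscillatory) amp else 0,
    frequency = freq,
    band = classify_band(freq, oscillatory = oscillatory),
    freq_spectral = freq_sp, freq_flagged = flagged,
    S_min = rng$S[1], S_max = rng$S[2], G_min = rng$G[1], G_max = rng$G[2],
    E_min = rng$E[1], E_max = rng$E[2], I_min = rng$I[1], I_max = rng$I[2])
}

#' Classify an oscillation frequency into a band
#'
#' Band boundaries: alpha 8-13 Hz, beta 13-30 Hz (both endpoints inclusive to
#' beta), gamma above 30 Hz; slower rhythms are labelled `"slow"` and
#' non-oscillatory traces `"steady"`.
#'
#' @param f Frequency in Hz (vectorised; `NA` allowed).
#' @param oscillatory Logical; `FALSE` forces the `"steady"` label.
#' @return Character vector of band labels.
#' @examples
#' classify_band(c(10, 20, 35))
#' @export
classify_band <- function(f, oscillatory = TRUE) {
  lab <- function(fi, osc) {
    if (!osc || is.na(fi)) return("steady")
    if (fi > 30) "gamma"
    else if (fi >= 13) "beta"
    else if (fi >= 8) "alpha"
    else "slow"
  }
  mapply(lab, f, rep_len(oscillatory, length(f)), USE.NAMES = FALSE)
}
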