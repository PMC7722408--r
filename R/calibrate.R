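# Calibration of the four cortical sigmoid constants against the reference
# critical delay.

#' Calibrate the cortical sigmoid constants to a reference critical delay
#'
#' The four cortical activation constants (`M_E`, `B_E`, `M_I`, `B_I`) are
#' known only as admissible ranges, so the package fixes them operationally: a
#' coarse-to-fine grid search over the ranges retains the completions whose
#' minimal critical delay matches a reference value (default the model's
#' reference Hopf delay, 3.6807 ms). For a crossing of the STN-GPe loop the
#' critical delay depends on the completion only through the cortical
#' excitatory equilibrium rate `E*`, so the matching completions form a
#' family; any member yields the same downstream normal-form coefficients.
#'
#' @param p_base Parameter set providing all non-cortical constants.
#' @param target_T0 Reference critical delay (ms).
#' @param tol Acceptance half-width on `|T0 - target_T0|` (ms).
#' @param coarse_n Grid points per axis in the first pass.
#' @param refine_rounds Number of local refinement rounds around the best cell.
#' @param require_beta If `TRUE`, only completions whose onset frequency lies
#'   in the beta band (13-30 Hz) qualify.
#' @return A `bg_calibration` object: `best` (a full `bg_params` with the
#'   chosen completion), `T0`, `f0_hz`, `matches` (tibble of all completions
#'   within `tol` seen during the search), and `n_evaluated`.
#' @export
calibrate_cortex <- function(p_base = bg_params(), target_T0 = 3.6807, tol = 1e-3,
                             coarse_n = 9, refine_rounds = 4, require_beta = TRUE) {
  rng <- .cortex_ranges
  eval_completion <- function(M_E, B_E, M_I, B_I) {
    p <- tryCatch(bg_params(base = p_base, M_E = M_E, B_E = B_E, M_I = M_I, B_I = B_I),
                  error = function(e) NULL)
    if (is.null(p)) return(NULL)
    cr <- tryCatch(critical_delays(linearize(p)), error = function(e) NULL)
    if (is.null(cr)) return(NULL)
    tibble::tibble(M_E = M_E, B_E = B_E, M_I = M_I, B_I = B_I,
                   T0 = attr(cr, "T0"), f0_hz = attr(cr, "f0_hz"),
                   loop = attr(cr, "loop0"))
  }
  grid_eval <- function(ME_g, BE_g, MI_g, BI_g) {
    g <- expand.grid(M_E = ME_g, B_E = BE_g, M_I = MI_g, B_I = BI_g)
    dplyr::bind_rows(purrr::pmap(g, eval_completion))
  }
  axis <- function(b, n) seq(b[1], b[2], length.out = n + 2)[-c(1, n + 2)]
  res <- grid_eval(axis(rng$M_E, coarse_n), axis(rng$B_E, coarse_n),
                   axis(rng$M_I, coarse_n), axis(rng$B_I, coarse_n))
  n_eval <- nrow(res)
  score <- function(r) {
    ok <- !is.na(r$T0)
    if (require_beta) ok <- ok & !is.na(r$f0_hz) & r$f0_hz >= 13 & r$f0_hz <= 30
    ifelse(ok, abs(r$T0 - target_T0), Inf)
  }
  all_res <- res
  best <- res[which.min(score(res)), ]
  span <- vapply(rng, diff, numeric(1)) / (coarse_n + 1)
  for (round in seq_len(refine_rounds)) {
    span <- span / 3
    loc <- function(v, nm) {
      lo <- max(rng[[nm]][1], v - 3 * span[[nm]]); hi <- min(rng[[nm]][2], v + 3 * span[[nm]])
      seq(lo, hi, length.out = 5)
    }
    res <- grid_eval(loc(best$M_E, "M_E"), loc(best$B_E, "B_E"),
                     loc(best$M_I, "M_I"), loc(best$B_I, "B_I"))
    n_eval <- n_eval + nrow(res)
    all_res <- dplyr::bind_rows(all_res, res)
    cand <- res[which.min(score(res)), ]
    if (is.finite(score(cand)) && score(cand) <= score(best)) best <- cand
  }
  matches <- all_res[score(all_res) <= tol, ]
  if (!is.finite(score(best))) stop("calibration failed: no completion admits a qualifying crossing")
  chosen <- bg_params(base = p_base, M_E = best$M_E, B_E = best$B_E,
                      M_I = best$M_I, B_I = best$B_I)
  structure(list(best = chosen, T0 = best$T0, f0_hz = best$f0_hz,
                 loop = best$loop, target_T0 = target_T0,
                 matches = matches, n_evaluated = n_eval,
                 within_tol = abs(best$T0 - target_T0) <= tol),
            class = "bg_calibration")
}

#' @export
print.bg_calibration <- function(x, ...) {
  cat("<bg_calibration>\n")
  cat(sprintf("  target T0 = %.4f ms; attained T0 = %.6f ms (f0 = %.2f Hz, loop %d)\n",
              x$target_T0, x$T0, x$f0_hz, x$loop))
  cat(sprintf("  completion: M_E=%.5f B_E=%.5f M_I=%.5f B_I=%.5f\n",
              x$best$M_E, x$best$B_E, x$best$M_I, x$best$B_I))
  cat(sprintf("  %d completions evaluated, %d within tolerance\n",
              x$n_evaluated, nrow(x$matches)))
  invisible(x)
}
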