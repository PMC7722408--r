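# One- and two-parameter bifurcation scans.

.scannable <- c("T", "w_SG", "w_GS", "w_CS", "w_CC", "w_GG", "C", "Str")

#' Ramped one-parameter bifurcation scan
#'
#' Integrates the model sequentially along a parameter grid, carrying the
#' final history of each grid point as the initial history of the next
#' (ramped continuation). The first point runs for `settle` ms from the
#' perturbed equilibrium; each subsequent point runs `duration` ms. Attractor
#' summaries come from [summarize_attractor()] on the post-transient window.
#'
#' @param p Base [bg_params()] set.
#' @param param Scanned field name, one of `T, w_SG, w_GS, w_CS, w_CC, w_GG,
#'   C, Str`.
#' @param grid Monotone numeric grid of parameter values.
#' @param direction `"up"` (grid order), `"down"` (reversed), or `"both"`.
#' @param duration,settle,h Integration lengths and step (ms).
#' @param kick Probe perturbation (spk/s) added to the STN and cortical
#'   excitatory rates of the carried history at every grid point. Near a critical point the carried deviation
#'   decays to roundoff on the stable side, which would delay onset detection
#'   by many grid steps; the kick re-seeds each point so that decay (stable)
#'   vs growth (oscillatory) is decided locally; the sustained-amplitude
#'   check of [summarize_attractor()] then rejects kick rings that are merely
#'   decaying slowly.
#' @param transient_fraction Passed to [summarize_attractor()].
#' @return A `bg_scan` tibble: `param`, `value`, `direction`, the summary
#'   columns, and a `failed` marker per grid point; attribute
#'   `analytic_critical` holds the analytic onset value when computable.
#' @examples
#' \donttest{
#' sc <- ramp_scan(bg_params(), "T", seq(2, 6, length.out = 20))
#' }
#' @export
ramp_scan <- function(p, param, grid, direction = c("up", "down", "both"),
                      duration = 1500, settle = 2500, h = 0.01, kick = 1,
                      transient_fraction = 0.5) {
  direction <- match.arg(direction)
  stopifnot(param %in% .scannable, length(grid) >= 2)
  if (is.unsorted(grid) && is.unsorted(rev(grid))) stop("grid must be monotone")
  if (direction == "both") {
    up <- ramp_scan(p, param, grid, "up", duration, settle, h, kick,
                    transient_fraction)
    dn <- ramp_scan(p, param, grid, "down", duration, settle, h, kick,
                    transient_fraction)
    out <- dplyr::bind_rows(up, dn)
    attr(out, "analytic_critical") <- attr(up, "analytic_critical")
    class(out) <- unique(c("bg_scan", class(out)))
    return(out)
  }
  g <- if (direction == "down") rev(grid) else grid
  carry <- NULL
  thr <- max(1e-3, 0.5 * kick)
  rows <- vector("list", length(g))
  for (i in seq_along(g)) {
    pi <- p
    pi[[param]] <- g[i]
    dur <- if (i == 1L) settle else duration
    rows[[i]] <- tryCatch({
      if (!is.null(carry) && kick > 0) {
        # seed both feedback loops: the cortical pair receives no input from
        # the basal ganglia, so an S-only probe could never excite it
        carry[nrow(carry), c(1, 3)] <- carry[nrow(carry), c(1, 3)] + kick
      }
      tr <- simulate_bg(pi, duration = dur, h = h, history = carry,
                        perturb = c(S = kick, E = kick))
      carry <- utils::tail(as.matrix(tr[, c("S", "G", "E", "I")]),
                           max(2L, as.integer(round(max(grid) / h)) + 1L))
      dplyr::bind_cols(
        tibble::tibble(param = param, value = g[i], direction = direction,
                       failed = FALSE),
        summarize_attractor(tr, transient_fraction, amp_threshold = thr,
                            sustained = TRUE,
                            sustained_override = max(20 * kick, 1)))
    }, error = function(e) {
      tibble::tibble(param = param, value = g[i], direction = direction,
                     failed = TRUE, kind = NA_character_)
    })
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "analytic_critical") <- .analytic_critical(p, param, range(grid))
  class(out) <- unique(c("bg_scan", class(out)))
  out
}

# Analytic onset along a scan: for T the minimal critical delay; for other
# fields the value where the minimal critical delay crosses p$T (bisection).
.analytic_critical <- function(p, param, bounds) {
  T0_of <- function(val) {
    pi <- p; pi[[param]] <- val
    out <- tryCatch(attr(critical_delays(linearize(pi)), "T0"), error = function(e) NA_real_)
    if (is.na(out)) Inf else out
  }
  if (param == "T") {
    t0 <- T0_of(p$T)
    return(if (is.finite(t0)) t0 else NA_real_)
  }
  f <- function(v) T0_of(v) - p$T       # sign change marks the onset
  lo <- bounds[1]; hi <- bounds[2]
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || sign(flo) == sign(fhi)) {
    # look for an interior sign change (e.g. two-onset windows in w_CS)
    vs <- seq(lo, hi, length.out = 17)
    fs <- vapply(vs, f, numeric(1))      # Inf where no crossing exists (stable side)
    k <- which(diff(sign(fs)) != 0)
    if (!length(k)) return(NA_real_)
    lo <- vs[k[1]]; hi <- vs[k[1] + 1]; flo <- fs[k[1]]
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2; fm <- f(mid)
    if (!is.finite(fm)) fm <- Inf
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Codimension-two Hopf boundary map
#'
#' Classifies every cell of a two-parameter grid as stable or oscillatory.
#' In `"analysis"` mode a cell is stable iff its delay is below the minimal
#' critical delay at the cell's parameters (or no crossing exists), and
#' oscillatory cells are banded by the onset frequency `omega0`; the Hopf
#' boundary is refined by bisection along the second axis. In `"simulation"`
#' mode each row of the grid is a [ramp_scan()] along the first axis and
#' cells are banded by the measured frequency.
#'
#' @param p Base parameter set.
#' @param x,y Scanned field names (see [ramp_scan()]).
#' @param x_grid,y_grid Monotone grids.
#' @param mode `"analysis"` or `"simulation"`.
#' @param ... Passed to [ramp_scan()] in simulation mode.
#' @return A `bg_map` tibble: `x`, `y`, `stable`, `frequency`, `band`;
#'   attribute `boundary` is a tibble of refined boundary points (analysis
#'   mode), attribute `axes` the field names.
#' @export
hopf_boundary_2d <- function(p, x, y, x_grid, y_grid,
                             mode = c("analysis", "simulation"), ...) {
  mode <- match.arg(mode)
  stopifnot(x %in% .scannable, y %in% .scannable, x != y)
  if (mode == "analysis") {
    cell <- function(xv, yv) {
      pi <- p; pi[[x]] <- xv; pi[[y]] <- yv
      cr <- tryCatch(critical_delays(linearize(pi)), error = function(e) NULL)
      T0 <- if (is.null(cr)) NA_real_ else attr(cr, "T0")
      Tcell <- pi$T
      stable <- is.null(cr) || is.na(T0) || Tcell < T0
      f0 <- if (!stable) attr(cr, "f0_hz") else NA_real_
      tibble::tibble(x = xv, y = yv, stable = stable, frequency = f0,
                     band = classify_band(f0, oscillatory = !stable))
    }
    cells <- dplyr::bind_rows(purrr::map(y_grid, function(yv)
      dplyr::bind_rows(purrr::map(x_grid, cell, yv = yv))))
    boundary <- .refine_boundary(p, x, y, x_grid, y_grid, cells)
  } else {
    rows <- purrr::map(y_grid, function(yv) {
      pi <- p; pi[[y]] <- yv
      sc <- ramp_scan(pi, x, x_grid, direction = "up", ...)
      tibble::tibble(x = sc$value, y = yv, stable = sc$kind == "fixed_point",
                     frequency = sc$frequency, band = sc$band)
    })
    cells <- dplyr::bind_rows(rows)
    boundary <- NULL
  }
  structure(cells, boundary = boundary, axes = c(x = x, y = y), mode = mode,
            class = c("bg_map", class(cells)))
}

# Bisection along y at each x column where the stability verdict flips.
.refine_boundary <- function(p, x, y, x_grid, y_grid, cells) {
  stab <- function(xv, yv) {
    pi <- p; pi[[x]] <- xv; pi[[y]] <- yv
    cr <- tryCatch(critical_delays(linearize(pi)), error = function(e) NULL)
    T0 <- if (is.null(cr)) NA_real_ else attr(cr, "T0")
    is.na(T0) || pi$T < T0
  }
  pts <- list()
  for (xv in x_grid) {
    col <- cells[cells$x == xv, ]
    col <- col[order(col$y), ]
    flips <- which(diff(col$stable) != 0)
    for (k in flips) {
      lo <- col$y[k]; hi <- col$y[k + 1]
      slo <- col$stable[k]
      for (i in 1:30) {
        mid <- (lo + hi) / 2
        if (stab(xv, mid) == slo) lo <- mid else hi <- mid
      }
      pts[[length(pts) + 1L]] <- tibble::tibble(x = xv, y = (lo + hi) / 2)
    }
  }
  if (length(pts)) dplyr::bind_rows(pts) else tibble::tibble(x = numeric(), y = numeric())
}

#' Oscillation frequency profile along the delay axis
#'
#' Simulation-based frequency of the post-transient attractor as a function
#' of the transmission delay, at a fixed cortex-to-STN weight. With strong
#' cortical drive the band sequence with increasing delay is
#' gamma -> beta -> alpha.
#'
#' @param p Base parameter set.
#' @param T_grid Monotone delay grid (ms).
#' @param w_CS_fixed Cortex-to-STN weight during the profile.
#' @param ... Passed to [ramp_scan()].
#' @return Tibble with `T`, `frequency` (Hz), `band`, `amplitude`.
#' @export
frequency_profile <- function(p, T_grid, w_CS_fixed = 8.0, ...) {
  pi <- p
  pi$w_CS <- w_CS_fixed
  sc <- ramp_scan(pi, "T", T_grid, direction = "up", ...)
  tibble::tibble(T = sc$value, frequency = sc$frequency, band = sc$band,
                 amplitude = sc$amplitude)
}
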