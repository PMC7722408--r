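# Parameter handling for the reduced cortex-STN-GPe loop model.

# Point values for the basal-ganglia side and the loop weights/inputs; the four
# cortical sigmoid constants (M_E, B_E, M_I, B_I) are only known as ranges and
# are completed by calibrate_cortex() against the reference critical delay
# (see ?calibrate_cortex). The values below are that calibrated completion.
.bg_defaults <- list(
  tau  = 10,
  w_SG = 2.56, w_GS = 3.22, w_CC = 2.75, w_CS = 6.60, w_GG = 0.90,
  C    = 277.94, Str = 40.51,
  M_S  = 300, B_S = 10, M_G = 400, B_G = 20,
  M_E  = 72.444444444444, B_E = 10.257565981468, M_I = 211.740740740741,
  B_I  = 4.370370370370,
  T    = 8
)

# Table-1 admissible ranges for the cortical sigmoid constants (spk/s).
.cortex_ranges <- list(
  M_E = c(50, 80), B_E = c(0, 20), M_I = c(20, 330), B_I = c(0, 20)
)

.bg_param_names <- names(.bg_defaults)
.bg_weight_names <- c("w_SG", "w_GS", "w_CC", "w_CS", "w_GG")
.bg_pops <- c("S", "G", "E", "I")

#' Construct a parameter set for the cortex-STN-GPe loop model
#'
#' Builds and validates the full constant set of the reduced four-population
#' firing-rate model: a common membrane time constant `tau` (ms), five
#' non-negative connection weights, the constant cortical drive `C` and
#' striatal inhibition `Str` (spk/s), per-population sigmoid maxima `M_X` and
#' baselines `B_X` (spk/s), and the common transmission delay `T` (ms).
#'
#' Defaults are the reference point values for the basal-ganglia populations
#' and loop weights, with the four cortical sigmoid constants filled in by the
#' packaged calibration (see [calibrate_cortex()]); any field can be
#' overridden by name.
#'
#' @param ... Named fields to override, e.g. `bg_params(T = 2.5, w_SG = 3)`.
#' @param base A `bg_params` object (or named list) used as the starting point
#'   instead of the package defaults.
#' @return A `bg_params` object (named list of scalars).
#' @examples
#' p <- bg_params(T = 2.5)
#' p$w_SG
#' @export
bg_params <- function(..., base = NULL) {
  p <- if (is.null(base)) .bg_defaults else {
    stopifnot(is.list(base))
    utils::modifyList(.bg_defaults, base[intersect(names(base), .bg_param_names)])
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .bg_param_names)
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown or unnamed parameter field(s): ", paste(bad, collapse = ", "))
    }
    p <- utils::modifyList(p, over)
  }
  p <- lapply(p, as.numeric)
  class(p) <- "bg_params"
  validate_bg_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks the admissibility invariants: `tau > 0`, `T >= 0`, all connection
#' weights non-negative, and `0 < B_X < M_X` for every population.
#'
#' @param p A `bg_params` object or named list with the full field set.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_bg_params <- function(p) {
  miss <- setdiff(.bg_param_names, names(p))
  if (length(miss)) stop("missing parameter field(s): ", paste(miss, collapse = ", "))
  num <- vapply(p[.bg_param_names], function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) stop("non-finite or non-scalar parameter field(s): ",
                      paste(.bg_param_names[!num], collapse = ", "))
  if (p$tau <= 0) stop("tau must be positive")
  if (p$T < 0) stop("transmission delay T must be non-negative")
  w <- unlist(p[.bg_weight_names])
  if (any(w < 0)) stop("connection weights must be non-negative")
  for (X in .bg_pops) {
    M <- p[[paste0("M_", X)]]; B <- p[[paste0("B_", X)]]
    if (!(B > 0 && B < M)) {
      stop(sprintf("population %s: need 0 < B_%s < M_%s (got B=%g, M=%g)", X, X, X, B, M))
    }
  }
  invisible(p)
}

#' @export
print.bg_params <- function(x, ...) {
  cat("<bg_params> cortex-STN-GPe loop model constants\n")
  cat(sprintf("  tau = %g ms, delay T = %g ms\n", x$tau, x$T))
  cat(sprintf("  weights: w_SG=%g w_GS=%g w_CC=%g w_CS=%g w_GG=%g\n",
              x$w_SG, x$w_GS, x$w_CC, x$w_CS, x$w_GG))
  cat(sprintf("  inputs:  C=%g, Str=%g spk/s\n", x$C, x$Str))
  for (X in .bg_pops) {
    cat(sprintf("  %s: M=%g, B=%g spk/s\n", X, x[[paste0("M_", X)]], x[[paste0("B_", X)]]))
  }
  invisible(x)
}

#' Read / write parameter sets as structured config files
#'
#' Parameter sets are stored as flat key-value maps with keys exactly the
#' field names of [bg_params()]. JSON is the native dialect; files ending in
#' `.yml`/`.yaml` are read and written with the yaml package if installed.
#' Unknown keys are ignored on read (so files may carry provenance comments
#' in a `comment` field).
#'
#' @param path File path.
#' @return `read_bg_params()` returns a validated `bg_params` object.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_bg_params(bg_params(T = 4), f)
#' read_bg_params(f)$T
#' @export
read_bg_params <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required for YAML configs")
    raw <- yaml::read_yaml(path)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  bg_params(base = raw)
}

#' @param p A `bg_params` object.
#' @rdname read_bg_params
#' @export
write_bg_params <- function(p, path) {
  validate_bg_params(p)
  x <- p[.bg_param_names]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required for YAML configs")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# Sigmoid constants (M, B) for population X.
.pop_MB <- function(p, X) c(p[[paste0("M_", X)]], p[[paste0("B_", X)]])
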