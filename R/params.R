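#' Parameter set for the socially buffered stress-response model
#'
#' Builds the full parameter set of the model: the nine rate constants
#' `k1`..`k9` describing how perceived stress (X), stress-related ill-health
#' symptoms (Y) and social support in use (Z) interact, plus the
#' environmental-stress and forcing parameters. The `"table1"` preset is the
#' reference parameterisation used throughout the package:
#' A0 = 1, S0 = 10, beta = 0.5, k1 = 1, k2 = 1, k3 = 0.01, k4 = 2,
#' k5 = 0.3, k6 = 0.01, k7 = 0.01, k8 = 0.1, k9 = 0.01.
#'
#' `B` is the kindling parameter (stress building more stress), `A0` the
#' baseline environmental stress, and `rho`/`omega` the amplitude and angular
#' frequency of the periodic forcing A(t) = A0 + rho * sin(omega * t).
#' `S0` is the total available social support and `beta` the fraction of
#' support depleted by buffering.
#'
#' @param ... Named overrides of individual parameters, e.g. `B = 2.2`,
#'   `rho = 11`.
#' @param preset Name of a parameter preset; currently only `"table1"`.
#'
#' @return An object of class `stress_params`: a named list with elements
#'   `k1`..`k9`, `A0`, `S0`, `beta`, `B`, `rho`, `omega`.
#'
#' @examples
#' stress_params(B = 2.2, rho = 11, omega = 1.5)
#' @export
stress_params <- function(..., preset = "table1") {
  presets <- list(
    table1 = list(
      A0 = 1, S0 = 10, beta = 0.5,
      k1 = 1, k2 = 1, k3 = 0.01, k4 = 2, k5 = 0.3,
      k6 = 0.01, k7 = 0.01, k8 = 0.1, k9 = 0.01,
      B = 2.2, rho = 0, omega = 1.5
    )
  )
  if (!preset %in% names(presets)) {
    abort(sprintf("unknown preset '%s'", preset), class = "stressdyn_config_error")
  }
  p <- presets[[preset]]
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      abort("parameter overrides must be named", class = "stressdyn_config_error")
    }
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      abort(sprintf("unknown parameter(s): %s", paste(bad, collapse = ", ")),
            class = "stressdyn_config_error")
    }
    p[names(dots)] <- dots
  }
  validate_stress_params(structure(p, class = "stress_params"))
}

validate_stress_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    abort("all parameters must be finite numeric scalars",
          class = "stressdyn_config_error")
  }
  ks <- unlist(p[paste0("k", 1:9)])
  if (any(ks < 0)) abort("rate constants k1..k9 must be >= 0",
                         class = "stressdyn_config_error")
  if (p$S0 <= 0) abort("S0 must be > 0", class = "stressdyn_config_error")
  if (p$beta < 0 || p$beta > 1) abort("beta must lie in [0, 1]",
                                      class = "stressdyn_config_error")
  if (p$rho < 0) abort("rho must be >= 0", class = "stressdyn_config_error")
  if (p$omega < 0) abort("omega must be >= 0", class = "stressdyn_config_error")
  p
}

#' @export
print.stress_params <- function(x, ...) {
  cat("<stress_params>\n")
  cat("  rates: ", paste(sprintf("k%d=%g", 1:9, unlist(x[paste0("k", 1:9)])),
                         collapse = " "), "\n")
  cat(sprintf("  environment: A0=%g B=%g S0=%g beta=%g\n",
              x$A0, x$B, x$S0, x$beta))
  cat(sprintf("  forcing: rho=%g omega=%g\n", x$rho, x$omega))
  invisible(x)
}

# named vector in the order the C++ field expects
params_vector <- function(p) {
  stopifnot(inherits(p, "stress_params"))
  unlist(p)[c(paste0("k", 1:9), "A0", "S0", "beta", "B", "rho", "omega")]
}

as_stress_params <- function(p) {
  if (inherits(p, "stress_params")) return(p)
  if (is.list(p)) return(do.call(stress_params, p))
  abort("expected a stress_params object", class = "stressdyn_config_error")
}

check_orders <- function(q, n = 3) {
  if (!is.numeric(q) || !length(q) %in% c(1, n) || any(!is.finite(q))) {
    abort(sprintf("orders q must be numeric of length 1 or %d", n),
          class = "stressdyn_config_error")
  }
  if (any(q <= 0 | q > 1)) {
    abort("fractional orders must lie in (0, 1]", class = "stressdyn_config_error")
  }
  rep(q, length.out = n)
}
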