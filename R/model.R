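#' Periodically forced environmental stress
#'
#' Environmental stress seen by the subject at time `t`:
#' `A(t) = A0 + rho * sin(omega * t)`. With `rho = 0` this reduces to the
#' constant baseline `A0`.
#'
#' @param t Time (numeric vector).
#' @param params A [stress_params()] object.
#' @return Numeric vector of forcing values, one per element of `t`.
#' @examples
#' p <- stress_params(rho = 11, omega = 1.5)
#' forcing_amplitude(c(0, pi / 3), p)
#' @export
forcing_amplitude <- function(t, params) {
  params <- as_stress_params(params)
  stopifnot(is.numeric(t), all(is.finite(t)))
  params$A0 + params$rho * sin(params$omega * t)
}

#' Vector field of the stress-response model
#'
#' Right-hand side of the three coupled equations: perceived stress X is
#' driven by environmental stress (k1 A), kindling ((k2 B - k6) X), symptom
#' feedback (k3 Y), buffering by support in use (-k4 X Z) and self-limitation
#' (-k5 X^2); symptoms Y track stress (k6 X - k7 Y); support in use Z is
#' recruited from the free pool (k8 (S0 - Z) Y), consumed by buffering
#' (-beta k4 X Z) and decays (-k9 Z).
#'
#' @param state Numeric length-3 state `(X, Y, Z)`.
#' @param t Time at which the forcing is evaluated (default 0).
#' @param params A [stress_params()] object.
#' @return Numeric length-3 derivative vector.
#' @export
stress_rhs <- function(state, t = 0, params) {
  params <- as_stress_params(params)
  if (!is.numeric(state) || length(state) != 3 || any(!is.finite(state))) {
    abort("state must be a finite numeric vector (X, Y, Z)",
          class = "stressdyn_divergence_error")
  }
  A <- forcing_amplitude(t, params)
  X <- state[[1]]; Y <- state[[2]]; Z <- state[[3]]
  with(params, c(
    k1 * A + (k2 * B - k6) * X + k3 * Y - k4 * X * Z - k5 * X^2,
    k6 * X - k7 * Y,
    k8 * (S0 - Z) * Y - beta * k4 * X * Z - k9 * Z
  ))
}

#' Jacobian of the stress-response vector field
#'
#' Partial derivatives of the vector field with respect to `(X, Y, Z)` at the
#' autonomous point (the forcing enters additively, so it does not appear).
#'
#' @inheritParams stress_rhs
#' @return A 3 x 3 numeric matrix.
#' @export
stress_jacobian <- function(state, params) {
  params <- as_stress_params(params)
  stopifnot(is.numeric(state), length(state) == 3, all(is.finite(state)))
  X <- state[[1]]; Y <- state[[2]]; Z <- state[[3]]
  with(params, matrix(c(
    k2 * B - k6 - k4 * Z - 2 * k5 * X, k3, -k4 * X,
    k6, -k7, 0,
    -beta * k4 * Z, k8 * (S0 - Z), -k8 * Y - beta * k4 * X - k9
  ), nrow = 3, byrow = TRUE))
}

#' Characteristic polynomial of a 3 x 3 matrix
#'
#' Coefficients `(c2, c1, c0)` of `det(lambda I - m) =
#' lambda^3 + c2 lambda^2 + c1 lambda + c0`: `c2 = -trace(m)`, `c1` is the
#' sum of the principal 2 x 2 minors and `c0 = -det(m)`.
#'
#' @param m A real 3 x 3 matrix.
#' @return Named numeric vector `c(c2, c1, c0)`.
#' @export
characteristic_polynomial <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)), is.numeric(m))
  minor <- function(i) det(m[-i, -i, drop = FALSE])
  c(c2 = -sum(diag(m)),
    c1 = minor(1) + minor(2) + minor(3),
    c0 = -det(m))
}

#' Matignon stability of a commensurate fractional linear system
#'
#' A commensurate Caputo system of order `q` linearised at an equilibrium is
#' asymptotically stable iff every eigenvalue satisfies
#' `|arg(lambda)| > q * pi / 2` (principal argument in (-pi, pi]; a positive
#' real eigenvalue has argument 0, a negative real one pi). Eigenvalues
#' within `tol` of the stability boundary are flagged marginal and classified
#' unstable, so the classification is deterministic.
#'
#' @param eigenvalues Complex (or numeric) vector of eigenvalues.
#' @param q Fractional order(s) in (0, 1]; may be a vector.
#' @param tol Width of the marginal band around the boundary.
#' @return Character vector over `q` with values `"stable"` / `"unstable"`,
#'   carrying a logical `marginal` attribute of the same length.
#' @examples
#' matignon_stability(c(-1, -2, -3), q = 0.9)
#' @export
matignon_stability <- function(eigenvalues, q, tol = 1e-9) {
  stopifnot(length(eigenvalues) >= 1)
  if (any(q <= 0 | q > 1)) {
    abort("q must lie in (0, 1]", class = "stressdyn_config_error")
  }
  a <- abs(Arg(as.complex(eigenvalues)))
  out <- character(length(q))
  marg <- logical(length(q))
  for (i in seq_along(q)) {
    bound <- q[i] * pi / 2
    marg[i] <- any(abs(a - bound) <= tol)
    out[i] <- if (!marg[i] && all(a > bound)) "stable" else "unstable"
  }
  structure(out, marginal = marg)
}

#' Stationary states of the unforced stress-response model
#'
#' Locates all real stationary states of the autonomous system (forcing
#' treated as absent: `rho = 0`, `A = A0`). The symptom equation forces
#' `Y* = (k6 / k7) X*`; eliminating `Z*` from the support equation reduces
#' the problem to a cubic in `X*`, whose real roots are polished by damped
#' Newton iteration on the full system. Each state is reported with its
#' residual, characteristic polynomial and eigenvalues. The Z coordinate of
#' ill-conditioned states (steep dependence of Z* on X*) is only meaningful
#' after this refinement.
#'
#' @param params A [stress_params()] object; `k7` must be positive.
#' @param tol Newton convergence tolerance on the residual norm.
#' @return A tibble of class `equilibrium_report` with one row per stationary
#'   state: columns `X`, `Y`, `Z`, `residual_norm`, `c2`, `c1`, `c0` and a
#'   list-column `eigenvalues` of complex vectors.
#' @examples
#' find_equilibria(stress_params(B = 2.2))
#' @export
find_equilibria <- function(params, tol = 1e-12) {
  params <- as_stress_params(params)
  if (params$k7 <= 0) {
    abort("k7 must be > 0 (otherwise Y is unconstrained at stationarity)",
          class = "stressdyn_config_error")
  }
  p <- params
  cc <- p$k6 / p$k7
  # f3 = 0 gives Z* = k8 S0 c X / (a X + k9), a = k8 c + beta k4;
  # substituting into f1 = 0 and clearing the denominator yields a cubic.
  a <- p$k8 * cc + p$beta * p$k4
  m <- p$k2 * p$B - p$k6 + p$k3 * cc
  coefs <- c(p$k1 * p$A0 * p$k9,
             p$k1 * p$A0 * a + m * p$k9,
             m * a - p$k5 * p$k9 - p$k4 * p$k8 * p$S0 * cc,
             -p$k5 * a)
  roots <- polyroot(coefs)
  xs <- Re(roots[abs(Im(roots)) < 1e-8])
  unforced <- p
  unforced$rho <- 0
  refine <- function(x0) {
    s <- c(x0, cc * x0, p$k8 * p$S0 * cc * x0 / (a * x0 + p$k9))
    for (it in 1:200) {
      fv <- stress_rhs(s, 0, unforced)
      if (sqrt(sum(fv^2)) < tol) break
      J <- stress_jacobian(s, p)
      step <- tryCatch(solve(J, fv), error = function(e) fv * 0)
      lam <- 1
      repeat { # damped Newton: accept only residual-reducing steps
        s_new <- s - lam * step
        f_new <- stress_rhs(s_new, 0, unforced)
        if (sum(f_new^2) <= sum(fv^2) || lam < 1e-6) break
        lam <- lam / 2
      }
      s <- s_new
    }
    s
  }
  states <- lapply(sort(xs), refine)
  rows <- purrr::map(states, function(s) {
    J <- stress_jacobian(s, p)
    cp <- characteristic_polynomial(J)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    tibble(
      X = s[1], Y = s[2], Z = s[3],
      residual_norm = sqrt(sum(stress_rhs(s, 0, unforced)^2)),
      c2 = cp[["c2"]], c1 = cp[["c1"]], c0 = cp[["c0"]],
      eigenvalues = list(as.complex(ev))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("equilibrium_report", class(out))
  attr(out, "params") <- params
  out
}

#' Fractional stability classification of stationary states
#'
#' Applies the Matignon criterion to each stationary state in an
#' [find_equilibria()] report over a set of fractional orders.
#'
#' @param equilibria An `equilibrium_report` tibble.
#' @param q Vector of fractional orders in (0, 1].
#' @return A long tibble with columns `equilibrium` (row index), `X`, `q`,
#'   `stability`.
#' @export
equilibrium_stability <- function(equilibria, q) {
  stopifnot(inherits(equilibria, "equilibrium_report"))
  purrr::map_dfr(seq_len(nrow(equilibria)), function(i) {
    st <- matignon_stability(equilibria$eigenvalues[[i]], q)
    tibble(equilibrium = i, X = equilibria$X[i], q = q,
           stability = as.character(st))
  })
}

#' @export
tidy.equilibrium_report <- function(x, ...) {
  tibble::as_tibble(x)
}
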