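#' Variational (tangent) field of the stress-response model
#'
#' Time derivative of a matrix of tangent vectors transported by the
#' linearised flow: `J(state) %*% tangent`. The combined state-plus-tangent
#' system shares the fractional orders of the state equations and is what
#' the Benettin-Wolf procedure integrates.
#'
#' @param state Numeric length-3 state.
#' @param tangent 3 x k matrix of tangent vectors.
#' @param params A [stress_params()] object.
#' @return A 3 x k matrix of tangent derivatives.
#' @export
tangent_rhs <- function(state, tangent, params) {
  stopifnot(is.matrix(tangent), nrow(tangent) == 3)
  stress_jacobian(state, params) %*% tangent
}

#' Lyapunov spectrum by the Benettin-Wolf procedure
#'
#' Co-integrates the forced fractional stress system with an orthonormal
#' tangent frame, applying Gram-Schmidt reorthonormalisation every
#' `renorm_interval` steps and accumulating the log column norms; the
#' exponents are the accumulated logs divided by the elapsed time after the
#' transient. The tangent subsystem shares the state's fractional orders;
#' its fractional memory restarts from the orthonormalised frame at each
#' renormalisation, which keeps Gram-Schmidt meaningful under the power-law
#' memory kernel (a pragmatic approximation discussed in the package
#' vignette). In `mode = "restart"` the state's memory is restarted at each
#' renormalisation as well, so every leg is a fresh Caputo initial value
#' problem; `mode = "continuous"` (default) keeps the state memory across
#' the whole run.
#'
#' @param params A [stress_params()] object.
#' @param q Fractional order(s) in (0, 1].
#' @param t_total Total integration horizon (time units).
#' @param transient Initial span discarded from the exponent averages.
#' @param h Step size.
#' @param renorm_interval Steps between Gram-Schmidt renormalisations.
#' @param state0 Initial state.
#' @param memory_horizon Short-memory horizon (steps) for the state
#'   history in `"continuous"` mode; `NULL` = full memory.
#' @param mode `"continuous"` or `"restart"` (see Details).
#' @param blowup Divergence threshold.
#' @return An object of class `lyapunov_spectrum`: a list with `exponents`
#'   (sorted descending), `history` (tibble of running estimates vs time),
#'   `converged` (last-decile drift of every exponent below 5 percent of
#'   `|LE3|`) and the configuration.
#' @examples
#' \donttest{
#' p <- stress_params(B = 2.2, rho = 11, omega = 1.5)
#' ly <- lyapunov_spectrum(p, q = 0.99, t_total = 200, transient = 50)
#' glance(ly)
#' }
#' @export
lyapunov_spectrum <- function(params, q, t_total = 500, transient = 100,
                              h = 0.01, renorm_interval = 10,
                              state0 = c(1, 1, 1), memory_horizon = 1000,
                              mode = c("continuous", "restart"),
                              blowup = 1e8) {
  params <- as_stress_params(params)
  q <- check_orders(q, 3)
  mode <- match.arg(mode)
  stopifnot(transient < t_total, renorm_interval >= 1)
  nsteps <- ceiling(round(t_total / h, 8))
  if (mode == "continuous") {
    L <- check_memory_horizon(memory_horizon)
    res <- benettin_stress_cpp(params_vector(params), q, h, nsteps,
                               as.numeric(state0), L, blowup,
                               as.integer(renorm_interval))
    if (res$diverged) {
      abort("trajectory diverged during Lyapunov integration",
            class = "stressdyn_divergence_error",
            history = res)
    }
    lognorms <- res$lognorms
    times <- res$times
  } else {
    K <- as.integer(renorm_interval)
    nlegs <- nsteps %/% K
    yy <- c(as.numeric(state0), as.vector(diag(3)))
    q12 <- rep(q, 4)
    lognorms <- matrix(NA_real_, nlegs, 3)
    times <- numeric(nlegs)
    tcur <- 0
    for (l in seq_len(nlegs)) {
      leg <- abm_stress_tangent_cpp(params_vector(params), q12, h, K, yy,
                                    0L, blowup, 1L, tcur)
      if (leg$diverged) {
        abort("trajectory diverged during Lyapunov integration",
              class = "stressdyn_divergence_error")
      }
      yy <- leg$states[K + 1, ]
      tcur <- tcur + K * h
      gs <- gram_schmidt(matrix(yy[4:12], 3, 3))
      lognorms[l, ] <- log(gs$norms)
      times[l] <- tcur
      yy[4:12] <- as.vector(gs$basis)
    }
  }
  build_lyapunov_spectrum(lognorms, times, transient,
                          config = list(params = unclass(params), q = q,
                                        t_total = t_total,
                                        transient = transient, h = h,
                                        renorm_interval = renorm_interval,
                                        state0 = state0,
                                        memory_horizon = memory_horizon,
                                        mode = mode))
}

gram_schmidt <- function(M) {
  d <- ncol(M)
  norms <- numeric(d)
  for (c in seq_len(d)) {
    v <- M[, c]
    if (c > 1) for (cp in seq_len(c - 1)) v <- v - sum(v * M[, cp]) * M[, cp]
    norms[c] <- sqrt(sum(v^2))
    M[, c] <- v / norms[c]
  }
  list(basis = M, norms = norms)
}

build_lyapunov_spectrum <- function(lognorms, times, transient, config) {
  keep <- times > transient
  if (sum(keep) < 10) {
    abort("too few renormalisation events after the transient",
          class = "stressdyn_config_error")
  }
  span <- max(times[keep]) - transient
  exps <- colSums(lognorms[keep, , drop = FALSE]) / span
  hist_time <- times[keep]
  running <- apply(lognorms[keep, , drop = FALSE], 2, cumsum) /
    (hist_time - transient)
  ord <- order(-exps)
  history <- tibble(
    time = hist_time,
    le1 = running[, ord[1]], le2 = running[, ord[2]], le3 = running[, ord[3]]
  )
  dec <- history[history$time >= max(history$time) -
                   0.1 * (max(history$time) - transient), ]
  drift <- vapply(dec[c("le1", "le2", "le3")],
                  function(x) max(x) - min(x), numeric(1))
  exponents <- sort(exps, decreasing = TRUE)
  structure(
    list(exponents = exponents,
         history = history,
         converged = all(drift < 0.05 * abs(exponents[3])),
         config = config),
    class = "lyapunov_spectrum")
}

#' Lyapunov spectrum of a linear system (validation helper)
#'
#' Benettin-Wolf estimation for the linear field `y' = A y` integrated with
#' the same fractional machinery. For a diagonal stable matrix at `q = 1`
#' the exponents equal the diagonal entries exactly, which makes this the
#' standard correctness check for the tangent propagation.
#'
#' @param A Real 3 x 3 matrix.
#' @inheritParams lyapunov_spectrum
#' @return A `lyapunov_spectrum` object.
#' @export
lyapunov_spectrum_linear <- function(A, q = 1, t_total = 200, transient = 10,
                                     h = 0.01, renorm_interval = 10,
                                     state0 = c(1, 1, 1),
                                     memory_horizon = NULL, blowup = 1e8) {
  stopifnot(is.matrix(A), all(dim(A) == c(3, 3)))
  q <- check_orders(q, 3)
  nsteps <- ceiling(round(t_total / h, 8))
  L <- check_memory_horizon(memory_horizon)
  res <- benettin_linear_cpp(A, q, h, nsteps, as.numeric(state0), L, blowup,
                             as.integer(renorm_interval))
  build_lyapunov_spectrum(res$lognorms, res$times, transient,
                          config = list(A = A, q = q, t_total = t_total,
                                        transient = transient, h = h,
                                        renorm_interval = renorm_interval))
}

#' Kaplan-Yorke dimension of a Lyapunov spectrum
#'
#' Two conventions are provided. `"standard_kaplan_yorke"` is the usual
#' interpolation `j + sum(LE_1..LE_j) / |LE_(j+1)|` with `j` the largest
#' index at which the partial sum is still nonnegative (0 when every partial
#' sum is negative). `"paper_variant"` is `3 - LE1 / |LE3|`, an alternative
#' convention found in parts of the fractional-chaos literature; both are
#' reported by [glance.lyapunov_spectrum()] so results under either
#' convention can be compared.
#'
#' @param spectrum A `lyapunov_spectrum` object or a numeric vector of
#'   exponents sorted in decreasing order.
#' @param convention `"standard_kaplan_yorke"` or `"paper_variant"`.
#' @return One-row tibble with columns `value` and `convention`.
#' @examples
#' kaplan_yorke(c(0.203, 0, -12.707), "standard_kaplan_yorke")
#' kaplan_yorke(c(0.203, 0, -12.707), "paper_variant")
#' @export
kaplan_yorke <- function(spectrum,
                         convention = c("standard_kaplan_yorke",
                                        "paper_variant")) {
  convention <- match.arg(convention)
  le <- if (inherits(spectrum, "lyapunov_spectrum")) spectrum$exponents
        else as.numeric(spectrum)
  if (is.unsorted(rev(le))) {
    abort("exponents must be sorted in decreasing order",
          class = "stressdyn_config_error")
  }
  value <- if (convention == "paper_variant") {
    length(le) - le[1] / abs(le[length(le)])
  } else {
    ps <- cumsum(le)
    j <- suppressWarnings(max(which(ps >= 0)))
    if (!is.finite(j)) 0
    else if (j == length(le)) length(le)
    else j + ps[j] / abs(le[j + 1])
  }
  tibble(value = value, convention = convention)
}

#' @export
print.lyapunov_spectrum <- function(x, ...) {
  cat("<lyapunov_spectrum>\n")
  cat("  exponents:", paste(signif(x$exponents, 4), collapse = ", "), "\n")
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' @export
tidy.lyapunov_spectrum <- function(x, ...) {
  tibble(term = paste0("le", 1:3), estimate = x$exponents)
}

#' @export
glance.lyapunov_spectrum <- function(x, ...) {
  tibble(
    le1 = x$exponents[1], le2 = x$exponents[2], le3 = x$exponents[3],
    dim_kaplan_yorke = kaplan_yorke(x, "standard_kaplan_yorke")$value,
    dim_paper_variant = kaplan_yorke(x, "paper_variant")$value,
    converged = x$converged
  )
}

#' @export
autoplot.lyapunov_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, cols = c("le1", "le2", "le3"),
                              names_to = "exponent", values_to = "estimate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$estimate,
                                     colour = .data$exponent)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "running exponent estimate")
}
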