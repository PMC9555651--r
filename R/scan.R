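#' Distinct peak values of a trajectory variable
#'
#' Values at strict local maxima (`x[i-1] < x[i] > x[i+1]`) of a trajectory
#' column after discarding the leading transient, deduplicated at a fixed
#' resolution. The distinct-peak count is the working signature used by the
#' bifurcation scans: one value for a period-1 orbit, a handful for
#' higher-period orbits, dense sets on a chaotic attractor.
#'
#' @param traj A trajectory tibble or a plain numeric vector.
#' @param var Column to analyse when `traj` is a tibble.
#' @param transient_fraction Leading fraction of samples discarded.
#' @param tol Deduplication resolution (peak values are rounded to this).
#' @return Sorted numeric vector of distinct peak values; empty (with a
#'   `diverged` attribute) for a diverged trajectory.
#' @export
extract_peaks <- function(traj, var = "X", transient_fraction = 0.5,
                          tol = 1e-4) {
  if (is.numeric(traj)) {
    x <- traj
    div <- FALSE
  } else {
    x <- traj[[var]]
    div <- is_diverged(traj)
  }
  if (div) return(structure(numeric(0), diverged = TRUE))
  x <- x[(floor(length(x) * transient_fraction) + 1):length(x)]
  n <- length(x)
  if (n < 3) return(structure(numeric(0), diverged = FALSE))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1
  structure(sort(unique(round(x[i] / tol) * tol)), diverged = FALSE)
}

scan_axes <- c("q", "B", "rho", "omega", "Y0", "Z0")

apply_axis <- function(axis, value, params, q, state0) {
  switch(axis,
    q = list(params = params, q = value, state0 = state0),
    B = list(params = modify_params(params, B = value), q = q, state0 = state0),
    rho = list(params = modify_params(params, rho = value), q = q,
               state0 = state0),
    omega = list(params = modify_params(params, omega = value), q = q,
                 state0 = state0),
    Y0 = list(params = params, q = q, state0 = c(state0[1], value, state0[3])),
    Z0 = list(params = params, q = q, state0 = c(state0[1], state0[2], value)),
    abort(sprintf("unknown scan axis '%s' (use one of %s)", axis,
                  paste(scan_axes, collapse = ", ")),
          class = "stressdyn_config_error")
  )
}

modify_params <- function(params, ...) {
  p <- unclass(params)
  p[names(list(...))] <- list(...)
  validate_stress_params(structure(p, class = "stress_params"))
}

#' Bifurcation scan over a model, forcing or initial-condition axis
#'
#' One integration and peak extraction per grid point. Defaults follow the
#' package's sweep policy: t_end = 1000 with the leading half discarded and a
#' short-memory horizon of 1000 steps. The long horizon matters: the model's
#' periodic orbits approach their attractor slowly (contraction rates of
#' order 0.01), and shorter sweeps leave transient-smeared peak sets that
#' blur the periodic/chaotic distinction. Diverged points are recorded in the
#' `diverged` column and carry an empty peak set.
#'
#' @param axis One of `"q"`, `"B"`, `"rho"`, `"omega"`, `"Y0"`, `"Z0"`.
#' @param values Grid of axis values (length >= 2).
#' @param params Base [stress_params()] object.
#' @param q Fractional order used when `axis` is not `"q"`.
#' @param state0 Base initial state (IC axes override one component).
#' @param h,t_end,memory_horizon Solver settings per point.
#' @param transient_fraction Transient dropped before peak extraction.
#' @param tol Peak deduplication resolution.
#' @return A tibble of class `bifurcation_scan` with columns `axis`,
#'   `value`, `peaks` (list-column), `n_peaks`, `diverged`.
#' @examples
#' \donttest{
#' p <- stress_params(B = 2.2, rho = 11, omega = 1.5)
#' bif <- bifurcation_scan("q", seq(0.9, 1, by = 0.05), p)
#' }
#' @export
bifurcation_scan <- function(axis, values, params, q = 0.99,
                             state0 = c(1, 1, 1), h = 0.01, t_end = 1000,
                             memory_horizon = 1000,
                             transient_fraction = 0.5, tol = 1e-4) {
  params <- as_stress_params(params)
  stopifnot(length(values) >= 2, all(is.finite(values)))
  rows <- purrr::map(values, function(v) {
    pt <- apply_axis(axis, v, params, q, state0)
    traj <- simulate_stress(pt$params, pt$q, h = h, t_end = t_end,
                            state0 = pt$state0,
                            memory_horizon = memory_horizon)
    pk <- extract_peaks(traj, transient_fraction = transient_fraction,
                        tol = tol)
    tibble(axis = axis, value = v, peaks = list(as.numeric(pk)),
           n_peaks = length(pk), diverged = is_diverged(traj))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bifurcation_scan", class(out))
  attr(out, "config") <- list(params = unclass(params), q = q,
                              state0 = state0, h = h, t_end = t_end,
                              memory_horizon = memory_horizon,
                              transient_fraction = transient_fraction)
  out
}

#' Metric scan over one or two axes
#'
#' Per grid point: integrate, window the perceived-stress series per the
#' [signal_window()] policy, and compute the requested summary —
#' spectral entropy (`"se"`), C0 complexity (`"c0"`), both (`"both"`), or
#' the leading Lyapunov exponent (`"le1"`). Metric scans integrate to
#' t_end = 1000 by default so the analysis window matches the single-run
#' policy; shorter windows systematically depress spectral entropy.
#'
#' @param axis,values First axis name and grid.
#' @param axis2,values2 Optional second axis (a full grid is formed).
#' @param summary One of `"se"`, `"c0"`, `"both"`, `"le1"`.
#' @param params Base [stress_params()] object.
#' @param q Fractional order used when no axis is `"q"`.
#' @param state0 Base initial state.
#' @param h,t_end,memory_horizon Solver settings per point.
#' @param transient_fraction Transient dropped before windowing.
#' @param n Window length.
#' @param r C0 control parameter.
#' @return A tibble of class `metric_scan`, long format: axis columns,
#'   metric column(s) and `diverged`.
#' @export
metric_scan <- function(axis, values, axis2 = NULL, values2 = NULL,
                        summary = c("both", "se", "c0", "le1"),
                        params, q = 0.99, state0 = c(1, 1, 1),
                        h = 0.01, t_end = 1000, memory_horizon = 1000,
                        transient_fraction = 0.5, n = 4096, r = 1) {
  summary <- match.arg(summary)
  params <- as_stress_params(params)
  stopifnot(length(values) >= 2)
  if (!is.null(axis2)) {
    stopifnot(!identical(axis, axis2), length(values2) >= 2)
    grid <- tidyr::expand_grid(v1 = values, v2 = values2)
  } else {
    grid <- tibble(v1 = values)
  }
  rows <- purrr::pmap(grid, function(v1, v2 = NULL) {
    pt <- apply_axis(axis, v1, params, q, state0)
    if (!is.null(v2)) {
      pt2 <- apply_axis(axis2, v2, pt$params, pt$q, pt$state0)
      pt <- pt2
    }
    base <- if (is.null(v2)) tibble("{axis}" := v1)
            else tibble("{axis}" := v1, "{axis2}" := v2)
    if (summary == "le1") {
      sp <- tryCatch(
        lyapunov_spectrum(pt$params, pt$q, t_total = t_end,
                          transient = t_end * transient_fraction, h = h,
                          state0 = pt$state0,
                          memory_horizon = memory_horizon),
        stressdyn_divergence_error = function(e) NULL)
      return(dplyr::bind_cols(base, tibble(
        le1 = if (is.null(sp)) NA_real_ else sp$exponents[1],
        diverged = is.null(sp))))
    }
    traj <- simulate_stress(pt$params, pt$q, h = h, t_end = t_end,
                            state0 = pt$state0,
                            memory_horizon = memory_horizon)
    if (is_diverged(traj)) {
      met <- tibble(se = NA_real_, c0 = NA_real_, diverged = TRUE)
    } else {
      w <- signal_window(traj, n = n, transient_fraction = transient_fraction)
      met <- tibble(se = spectral_entropy(w),
                    c0 = c0_complexity(remove_mean(w), r),
                    diverged = FALSE)
    }
    met <- switch(summary, se = met[c("se", "diverged")],
                  c0 = met[c("c0", "diverged")], both = met)
    dplyr::bind_cols(base, met)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metric_scan", class(out))
  attr(out, "config") <- list(params = unclass(params), q = q,
                              state0 = state0, h = h, t_end = t_end,
                              memory_horizon = memory_horizon,
                              transient_fraction = transient_fraction,
                              n = n, r = r, summary = summary)
  out
}

#' Classify a regime from its spectral summaries
#'
#' Conjunctive threshold rule: a point is labelled `"chaotic"` iff its
#' spectral entropy exceeds `se_threshold` AND its C0 complexity exceeds
#' `c0_threshold`; otherwise `"stable_or_periodic"`. The default thresholds
#' (0.4 and 0.12) are the discrimination values separating stable and
#' chaotic behaviour of the forced stress model.
#'
#' @param result A data frame with columns `se` and `c0` (e.g. a
#'   [metric_scan()] or [complexity_metrics()] result), or a numeric
#'   spectral entropy when `c0` is given separately.
#' @param c0 C0 value(s) when `result` is numeric.
#' @param se_threshold,c0_threshold Positive discrimination thresholds.
#' @return For data-frame input, the input with an added `label` column;
#'   for numeric input, a character vector of labels.
#' @examples
#' classify_regime(0.6, 0.2)
#' @export
classify_regime <- function(result, c0 = NULL, se_threshold = 0.4,
                            c0_threshold = 0.12) {
  stopifnot(se_threshold > 0, c0_threshold > 0)
  lab <- function(se, c0v) {
    dplyr::if_else(!is.na(se) & !is.na(c0v) &
                     se > se_threshold & c0v > c0_threshold,
                   "chaotic", "stable_or_periodic")
  }
  if (is.data.frame(result)) {
    stopifnot(all(c("se", "c0") %in% names(result)))
    result$label <- lab(result$se, result$c0)
    return(result)
  }
  lab(result, c0)
}

#' @export
autoplot.bifurcation_scan <- function(object, ...) {
  pts <- tidyr::unnest(object, "peaks")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$value, y = .data$peaks)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.5) +
    ggplot2::labs(x = object$axis[1], y = "X peak values")
}

#' @export
autoplot.metric_scan <- function(object, ...) {
  cfg <- attr(object, "config")
  metric_cols <- intersect(c("se", "c0", "le1"), names(object))
  axes <- setdiff(names(object), c(metric_cols, "diverged", "label"))
  long <- tidyr::pivot_longer(object, cols = dplyr::all_of(metric_cols),
                              names_to = "metric", values_to = "value")
  if (length(axes) == 1) {
    ggplot2::ggplot(long, ggplot2::aes(x = .data[[axes[1]]],
                                       y = .data$value,
                                       colour = .data$metric)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = axes[1], y = NULL)
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data[[axes[1]]],
                                       y = .data[[axes[2]]],
                                       fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~metric) +
      ggplot2::labs(x = axes[1], y = axes[2])
  }
}
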