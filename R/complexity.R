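#' Remove the mean of a signal
#'
#' First step of both spectral summaries: subtracts the sample mean so the
#' DC bin carries no power.
#'
#' @param samples Nonempty numeric vector.
#' @return Zero-mean numeric vector of the same length.
#' @export
remove_mean <- function(samples) {
  stopifnot(length(samples) >= 1, all(is.finite(samples)))
  samples - mean(samples)
}

#' Relative one-sided power spectral density
#'
#' `P(k) = |X(k)|^2 / sum_{k=0}^{N/2-1} |X(k)|^2` for `k = 0..N/2 - 1`,
#' where `X` is the discrete Fourier transform of the (zero-mean) signal.
#' The normalisation runs over the one-sided spectrum up to (and excluding)
#' the Nyquist bin, so the returned densities sum to exactly 1.
#'
#' @param samples Zero-mean numeric vector of even length.
#' @return Numeric vector of `N/2` nonnegative densities summing to 1.
#' @export
relative_psd <- function(samples) {
  N <- length(samples)
  stopifnot(N %% 2 == 0, N >= 4)
  pw <- Mod(fft(samples)[1:(N / 2)])^2
  tot <- sum(pw)
  if (tot == 0) {
    abort("all-zero signal: relative PSD is undefined",
          class = "stressdyn_signal_error")
  }
  pw / tot
}

entropy_of_psd <- function(P) {
  nz <- P > 0
  -sum(P[nz] * log(P[nz])) / log(length(P))
}

#' Spectral entropy of a signal
#'
#' Shannon entropy of the relative one-sided power spectrum, normalised by
#' its maximum `ln(N/2)` so the result lies in `[0, 1]`: near 0 when all
#' power sits in a single frequency bin (periodic, predictable), near 1 for
#' a flat broadband spectrum (chaotic or noisy). The mean is removed
#' internally.
#'
#' @param samples Numeric vector of even length `N >= 64`.
#' @return Spectral entropy in `[0, 1]`.
#' @examples
#' spectral_entropy(sin(2 * pi * 32 * (0:4095) / 4096)) # ~ 0
#' @export
spectral_entropy <- function(samples) {
  stopifnot(length(samples) >= 64, length(samples) %% 2 == 0)
  entropy_of_psd(relative_psd(remove_mean(samples)))
}

#' C0 complexity of a signal
#'
#' Energy fraction of the irregular part of a signal. Spectral bins whose
#' power exceeds `G_N = (2 r / N) * sum_{k=0}^{N/2-1} |X(k)|^2` (the mean
#' spectral power scaled by the control parameter `r`) are kept as the
#' regular part; the rest are zeroed (the strict inequality is applied over
#' the full two-sided spectrum, which is conjugate-symmetric for real input,
#' so the reconstruction is real). The inverse transform of the kept bins
#' gives the regular component and C0 is the relative energy of what
#' remains: 0 for a pure tone (its bin always survives), 1 when no bin
#' strictly exceeds the threshold. Larger values mean a more complex,
#' less spectrally concentrated signal; C0 is nondecreasing in `r`.
#'
#' The input is used as supplied; pass it through [remove_mean()] first (or
#' use [complexity_metrics()], which does) so the DC bin carries no power.
#'
#' @param samples Numeric vector of even length `N >= 64`.
#' @param r Positive control parameter (default 1).
#' @return C0 complexity in `[0, 1]`.
#' @export
c0_complexity <- function(samples, r = 1) {
  N <- length(samples)
  stopifnot(N >= 64, N %% 2 == 0, r > 0)
  X <- fft(samples)
  pw <- Mod(X)^2
  if (sum(pw) == 0) {
    abort("all-zero signal: C0 complexity is undefined",
          class = "stressdyn_signal_error")
  }
  G <- 2 * r / N * sum(pw[1:(N / 2)])
  Xk <- ifelse(pw > G, X, 0 + 0i)
  xt <- Re(fft(Xk, inverse = TRUE)) / N
  sum((samples - xt)^2) / sum(samples^2)
}

#' Both spectral summaries of a signal
#'
#' Removes the mean, then computes spectral entropy and C0 complexity.
#'
#' @inheritParams c0_complexity
#' @return One-row tibble with columns `se`, `c0`, `r`, `n`.
#' @export
complexity_metrics <- function(samples, r = 1) {
  x <- remove_mean(samples)
  tibble(se = spectral_entropy(x), c0 = c0_complexity(x, r),
         r = r, n = length(x))
}

#' Analysis window from a trajectory
#'
#' Standard windowing policy for the spectral summaries: drop the leading
#' `transient_fraction` of samples, then take `n` evenly spaced samples
#' from the remainder. With the package defaults (h = 0.01, t_end = 1000,
#' n = 4096) the window spans 500 time units, i.e. on the order of a
#' hundred forcing periods at omega = 1.5.
#'
#' @param traj A trajectory tibble (e.g. from [simulate_stress()]).
#' @param var Column to extract (default `"X"`, the perceived stress).
#' @param n Window length (even, default 4096).
#' @param transient_fraction Leading fraction of samples discarded.
#' @return Numeric vector of length `n`.
#' @export
signal_window <- function(traj, var = "X", n = 4096,
                          transient_fraction = 0.5) {
  stopifnot(var %in% names(traj), n %% 2 == 0, n >= 64,
            transient_fraction >= 0, transient_fraction < 1)
  x <- traj[[var]]
  x <- x[(floor(length(x) * transient_fraction) + 1):length(x)]
  if (length(x) < n) {
    abort("trajectory too short for the requested window",
          class = "stressdyn_signal_error")
  }
  x[round(seq(1, length(x), length.out = n))]
}
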