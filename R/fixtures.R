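#' Deterministic reference signals for metric validation
#'
#' Generates the fixture signals used to validate the spectral summaries:
#' a unit sinusoid at an exact FFT bin (all power in one bin, spectral
#' entropy ~ 0), seeded standard Gaussian white noise (flat spectrum,
#' entropy near 1), iterates of the fully chaotic logistic map
#' `x <- r x (1 - x)` at `r = 4` (broadband, deterministic chaos), and a
#' constant. Identical arguments always give bit-identical samples; the
#' random-number state of the session is left untouched.
#'
#' @param kind One of `"sine"`, `"white_noise"`, `"logistic_map"`,
#'   `"constant"`.
#' @param n Signal length (even, >= 64).
#' @param seed Integer seed for the stochastic kinds (and the logistic
#'   map's initial point).
#' @param freq_bin FFT bin of the sinusoid (cycles per window).
#' @param noise_sd Standard deviation of the white noise.
#' @param logistic_r Logistic-map parameter (default 4, fully chaotic).
#' @param burn_in Discarded leading logistic-map iterates.
#' @return Numeric vector of length `n`.
#' @examples
#' se <- spectral_entropy(fixture_signal("sine", 4096))
#' @export
fixture_signal <- function(kind = c("sine", "white_noise", "logistic_map",
                                    "constant"),
                           n = 4096, seed = 1, freq_bin = 32, noise_sd = 1,
                           logistic_r = 4, burn_in = 1000) {
  kind <- match.arg(kind)
  stopifnot(n %% 2 == 0, n >= 64)
  if (kind == "sine") {
    return(sin(2 * pi * freq_bin * (0:(n - 1)) / n))
  }
  if (kind == "constant") {
    return(rep(1, n))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  if (kind == "white_noise") {
    return(stats::rnorm(n, sd = noise_sd))
  }
  # logistic map: x0 drawn from the seed, away from the unstable fixed points
  x <- stats::runif(1, 0.1, 0.9)
  for (i in seq_len(burn_in)) x <- logistic_r * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- logistic_r * x * (1 - x)
    out[i] <- x
  }
  out
}
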