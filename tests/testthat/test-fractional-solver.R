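test_that("corrector weights match their closed forms", {
  expect_equal(corrector_weight(6, 5, 0.7), 1) # j = n + 1
  expect_equal(corrector_weight(0, 0, 1), 1)   # classical trapezoid endpoint
  for (q in c(0.5, 0.9, 1)) {
    for (n in c(1, 5, 20)) {
      w <- corrector_weight(0:(n + 1), n, q)
      expect_true(all(w > 0))
    }
  }
  expect_error(corrector_weight(7, 5, 0.7), class = "stressdyn_index_error")
})

test_that("predictor weights telescope and reduce to forward Euler", {
  h <- 0.02
  expect_equal(predictor_weight(0:7, 7, 1, h), rep(h, 8))
  expect_equal(predictor_weight(5, 5, 0.6, h), h^0.6 / 0.6)
  n <- 12; q <- 0.8
  expect_equal(sum(predictor_weight(0:n, n, q, h)),
               h^q * (n + 1)^q / q)
  expect_error(predictor_weight(13, 12, 0.8, h),
               class = "stressdyn_index_error")
})

test_that("a vanishing field leaves the state constant for any order", {
  for (q in list(1, 0.5, c(0.4, 0.7, 1))) {
    tr <- fode_solve(function(t, y) rep(0, 3), q, h = 0.05, t_end = 2,
                     y0 = c(2, -1, 0.5))
    expect_true(all(abs(tr$y1 - 2) == 0))
    expect_true(all(abs(tr$y2 + 1) == 0))
    expect_true(all(abs(tr$y3 - 0.5) == 0))
  }
})

test_that("linear relaxation matches the Mittag-Leffler solution", {
  tr <- fode_solve(function(t, y) -y, q = 0.9, h = 1e-3, t_end = 1, y0 = 1)
  exact <- mittag_leffler(0.9, -1)
  expect_lt(abs(tr$y1[nrow(tr)] - exact), 1e-4)
})

test_that("q = 1 integration of the stress model matches a classical reference", {
  skip_if_not_installed("deSolve")
  p <- chaotic_params()
  f <- function(t, y, parms) list(stress_rhs(y, t, p))
  ref <- deSolve::ode(c(1, 1, 1), seq(0, 10, by = 1e-3), f, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  tr <- simulate_stress(p, q = 1, h = 1e-3, t_end = 10)
  expect_lt(max(abs(as.matrix(tr[, c("X", "Y", "Z")]) - ref[, 2:4])), 1e-3)
})

test_that("compiled and R drivers implement the same discretization", {
  p <- chaotic_params()
  f <- function(t, y) stress_rhs(y, t, p)
  tr_r <- fode_solve(f, q = 0.9, h = 0.01, t_end = 5, y0 = c(1, 1, 1),
                     var_names = c("X", "Y", "Z"))
  tr_c <- simulate_stress(p, q = 0.9, h = 0.01, t_end = 5)
  expect_lt(max(abs(as.matrix(tr_r[, -1]) - as.matrix(tr_c[, -1]))), 1e-10)
})

test_that("at q = 1 the scheme equals the classical cumulative PECE iterates", {
  h <- 0.01; n <- 100; y0 <- 1
  f <- function(t, y) -y
  Fh <- numeric(n + 1); Fh[1] <- f(0, y0)
  yc <- numeric(n + 1); yc[1] <- y0
  for (k in 0:(n - 1)) {
    yp <- y0 + h * sum(Fh[1:(k + 1)])
    yv <- y0 + h / 2 * (f((k + 1) * h, yp) + Fh[1] +
                          2 * sum(Fh[seq_len(k) + 1]))
    yc[k + 2] <- yv
    Fh[k + 2] <- f((k + 1) * h, yv)
  }
  tr <- fode_solve(f, 1, h, 1, 1)
  expect_lt(max(abs(tr$y1 - yc)), 1e-12)
})

test_that("Caputo quadrature oracle reproduces closed forms", {
  expect_equal(caputo_derivative(function(s) 5, 0.5, 2), 0, tolerance = 1e-10)
  expect_equal(caputo_derivative(function(s) s, 0.5, 1), 1 / gamma(1.5),
               tolerance = 1e-6)
  # D^q t^2 = 2 t^(2-q) / Gamma(3 - q)
  expect_equal(caputo_derivative(function(s) s^2, 0.3, 1.5),
               2 * 1.5^1.7 / gamma(2.7), tolerance = 1e-5)
  expect_error(caputo_derivative(identity, 1, 1),
               class = "stressdyn_config_error")
})

test_that("Caputo derivative approaches the classical derivative as q -> 1", {
  errs <- vapply(c(0.9, 0.95, 0.99), function(q) {
    abs(caputo_derivative(sin, q, 2, fprime = cos) - cos(2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))   # error shrinks with 1 - q
  expect_lt(errs[3], 0.05)
})

test_that("empirical convergence order is min(2, 1 + q)", {
  hs <- c(0.02, 0.01, 0.005, 0.0025)
  s05 <- empirical_convergence_order(function(t, y) -y, 0.5, 1, 1, hs,
                                     function(t) mittag_leffler(0.5, -t^0.5))
  expect_equal(as.numeric(s05), 1.5, tolerance = 0.2)
  s10 <- empirical_convergence_order(function(t, y) -y, 1, 1, 1, hs,
                                     function(t) exp(-t))
  expect_equal(as.numeric(s10), 2, tolerance = 0.2)
  errs <- attr(s05, "errors")
  expect_equal(which.min(errs$error), nrow(errs)) # finest h, smallest error
})

test_that("short-memory horizon approximates full memory and improves with length", {
  p <- chaotic_params()
  full <- simulate_stress(p, 0.99, t_end = 50)
  l1 <- simulate_stress(p, 0.99, t_end = 50, memory_horizon = 1000)
  l2 <- simulate_stress(p, 0.99, t_end = 50, memory_horizon = 2000)
  d1 <- max(abs(as.matrix(l1[, -1]) - as.matrix(full[, -1])))
  d2 <- max(abs(as.matrix(l2[, -1]) - as.matrix(full[, -1])))
  # truncation activates at t = 10; exponential sensitivity amplifies the
  # small scheme difference afterwards, so agreement is asserted on a
  # short post-truncation window and monotone improvement on the full one
  d1_short <- max(abs(as.matrix(l1[1:2001, -1]) - as.matrix(full[1:2001, -1])))
  expect_lt(d1_short, 0.05)
  expect_lt(d2, d1)
  expect_error(simulate_stress(p, 0.99, t_end = 1, memory_horizon = 50),
               class = "stressdyn_config_error")
})

test_that("identical configurations give bit-identical trajectories", {
  p <- chaotic_params()
  a <- simulate_stress(p, 0.97, t_end = 20, memory_horizon = 1000)
  b <- simulate_stress(p, 0.97, t_end = 20, memory_horizon = 1000)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("refining the grid shrinks the solution change at the predicted rate", {
  p <- chaotic_params()
  g1 <- simulate_stress(p, 0.98, h = 0.01, t_end = 20)
  g2 <- simulate_stress(p, 0.98, h = 0.005, t_end = 20)
  g3 <- simulate_stress(p, 0.98, h = 0.0025, t_end = 20)
  e1 <- max(abs(unlist(g1[nrow(g1), -1]) - unlist(g3[nrow(g3), -1])))
  e2 <- max(abs(unlist(g2[nrow(g2), -1]) - unlist(g3[nrow(g3), -1])))
  expect_lt(e2, e1 / 2) # order min(2, 1 + q) predicts a factor ~3.9
})

test_that("blow-up truncates the trajectory and sets the diverged flag", {
  tr <- fode_solve(function(t, y) y^2, 1, h = 0.01, t_end = 5, y0 = 2)
  expect_true(is_diverged(tr))
  expect_lt(nrow(tr), 501)
  expect_true(all(is.finite(tr$y1)))
  # the forced model genuinely escapes at strongly fractional orders
  tr2 <- simulate_stress(chaotic_params(), 0.2, t_end = 100)
  expect_true(is_diverged(tr2))
})

test_that("orders outside (0, 1] are rejected", {
  expect_error(simulate_stress(stress_params(), 1.5, t_end = 1),
               class = "stressdyn_config_error")
  expect_error(simulate_stress(stress_params(), 0, t_end = 1),
               class = "stressdyn_config_error")
})
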