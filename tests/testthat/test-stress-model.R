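test_that("forcing amplitude follows A0 + rho sin(omega t)", {
  p <- stress_params(A0 = 1, rho = 11, omega = 1.5)
  expect_equal(forcing_amplitude(0, p), 1)
  p0 <- stress_params(A0 = 1, rho = 0)
  expect_equal(forcing_amplitude(c(0.3, 7, 123), p0), rep(1, 3))
  expect_equal(forcing_amplitude(pi / 3, p), 12)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(stress_params(beta = 1.5), class = "stressdyn_config_error")
  expect_error(stress_params(k4 = -1), class = "stressdyn_config_error")
  expect_error(stress_params(S0 = 0), class = "stressdyn_config_error")
  expect_error(stress_params(nosuch = 1), class = "stressdyn_config_error")
  expect_equal(stress_params()$k5, 0.3)
})

test_that("vector field at the origin reduces to environmental drive", {
  p <- stress_params(B = 2.2, rho = 0)
  expect_equal(stress_rhs(c(0, 0, 0), 0, p), c(1, 0, 0))
  expect_error(stress_rhs(c(Inf, 0, 0), 0, p),
               class = "stressdyn_divergence_error")
})

test_that("vector field nearly vanishes at the printed positive equilibrium", {
  p <- stress_params(B = 2.2, rho = 0)
  # residual is nonzero only because the printed coordinates are rounded
  # to two decimals; the exact value at (2.58, 2.58, 0.90) is ~0.035
  expect_lt(max(abs(stress_rhs(printed_E1, 0, p))), 0.05)
})

test_that("jacobian matches finite differences of the field", {
  p <- chaotic_params()
  set.seed(11)
  eps <- 1e-6
  for (rep in 1:10) {
    s <- stats::runif(3, -2, 3)
    J <- stress_jacobian(s, p)
    for (i in 1:3) {
      e <- replace(numeric(3), i, eps)
      fd <- (stress_rhs(s + e, 0, p) - stress_rhs(s - e, 0, p)) / (2 * eps)
      expect_equal(fd, J[, i], tolerance = 1e-5)
    }
  }
  expect_equal(stress_jacobian(c(0, 0, 0), stress_params())[2, ],
               c(0.01, -0.01, 0))
})

test_that("characteristic polynomial at the printed equilibrium matches the known coefficients", {
  J <- stress_jacobian(printed_E1, stress_params(B = 2.2))
  cp <- characteristic_polynomial(J)
  expect_equal(unname(cp), c(4.016, -1.306, 0.033), tolerance = 5e-4)
})

test_that("characteristic polynomial passes algebraic checks", {
  expect_equal(unname(characteristic_polynomial(diag(3))), c(-3, 3, -1))
  set.seed(21)
  m <- matrix(stats::rnorm(9), 3, 3)
  cp <- characteristic_polynomial(m)
  for (ev in eigen(m)$values) {
    expect_lt(Mod(ev^3 + cp[["c2"]] * ev^2 + cp[["c1"]] * ev + cp[["c0"]]),
              1e-8)
  }
})

test_that("equilibria of the unforced system match the known stationary states", {
  eq <- table1_equilibria()
  expect_equal(nrow(eq), 3)
  expect_true(all(eq$residual_norm < 1e-10))
  xs <- sort(eq$X)
  expect_equal(round(xs[1], 2), -1.31)
  expect_equal(round(xs[2], 3), -0.009)
  expect_equal(round(xs[3], 2), 2.58)
  e2 <- eq[which.min(eq$Z), ]
  expect_lt(abs(e2$Z / -54.8 - 1), 0.05)
  pos <- eq$X > 0 & eq$Y > 0 & eq$Z > 0
  expect_equal(sum(pos), 1)
})

test_that("the origin is stationary when baseline stress vanishes", {
  eq <- find_equilibria(stress_params(A0 = 0, B = 1.7))
  d <- sqrt(eq$X^2 + eq$Y^2 + eq$Z^2)
  expect_true(any(d < 1e-10))
})

test_that("k7 = 0 leaves the symptom equation degenerate", {
  expect_error(find_equilibria(stress_params(k7 = 0)),
               class = "stressdyn_config_error")
})

test_that("eigenvalues satisfy Vieta's relations against the polynomial", {
  eq <- table1_equilibria()
  for (i in seq_len(nrow(eq))) {
    ev <- eq$eigenvalues[[i]]
    expect_lt(Mod(sum(ev) + eq$c2[i]), 1e-9)
    expect_lt(Mod(prod(ev) + eq$c0[i]), 1e-9 * max(1, Mod(prod(ev))))
  }
})

test_that("Matignon criterion classifies canonical spectra", {
  qs <- seq(0.05, 1, by = 0.05)
  st <- matignon_stability(c(-1, -2, -3), qs)
  expect_true(all(st == "stable"))
  ev <- c(-5, complex(argument = pi / 4), complex(argument = -pi / 4))
  expect_equal(as.character(matignon_stability(ev, 0.4)), "stable")
  expect_equal(as.character(matignon_stability(ev, 0.6)), "unstable")
  # boundary q = 1/2 is marginal and reported unstable
  st_b <- matignon_stability(ev, 0.5)
  expect_equal(as.character(st_b), "unstable")
  expect_true(attr(st_b, "marginal"))
  expect_error(matignon_stability(c(-1), 1.2), class = "stressdyn_config_error")
})

test_that("Matignon at q = 1 reduces to the sign of the real part", {
  set.seed(31)
  for (rep in 1:100) {
    ev <- complex(real = stats::rnorm(3), imaginary = stats::rnorm(3))
    classical <- if (all(Re(ev) < 0)) "stable" else "unstable"
    expect_equal(as.character(matignon_stability(ev, 1)), classical)
  }
})

test_that("positive equilibrium is unstable across the kindling range", {
  # For B >= 1.2 the unstable eigenvalues are positive reals, so the state
  # is unstable at every order. At B = 1.0-1.1 they form a complex pair
  # with |arg| ~ 0.87 rad, which the Matignon sector classifies stable for
  # small q; instability then holds only from q ~ 0.56 upward.
  qs <- seq(0.05, 1, by = 0.05)
  for (B in seq(1.2, 2.2, by = 0.1)) {
    eq <- find_equilibria(stress_params(B = B))
    expect_equal(nrow(eq), 3)
    pos <- which(eq$X > 0 & eq$Y > 0 & eq$Z > 0)
    expect_length(pos, 1)
    st <- matignon_stability(eq$eigenvalues[[pos]], qs)
    expect_true(all(st == "unstable"))
  }
  for (B in c(1.0, 1.1)) {
    eq <- find_equilibria(stress_params(B = B))
    pos <- which(eq$X > 0 & eq$Y > 0 & eq$Z > 0)
    ev <- eq$eigenvalues[[pos]]
    expect_true(all(matignon_stability(ev, seq(0.6, 1, by = 0.05)) ==
                      "unstable"))
  }
  # the stability window at weak kindling is real, not a numerical artifact
  eqB1 <- find_equilibria(stress_params(B = 1))
  posB1 <- which(eqB1$X > 0 & eqB1$Y > 0 & eqB1$Z > 0)
  expect_equal(as.character(matignon_stability(eqB1$eigenvalues[[posB1]],
                                               0.3)), "stable")
})

test_that("equilibrium stability table covers every state and order", {
  eq <- table1_equilibria()
  tab <- equilibrium_stability(eq, c(0.5, 0.99))
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$stability %in% c("stable", "unstable")))
})
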