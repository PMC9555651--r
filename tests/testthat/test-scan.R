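test_that("peak extraction counts distinct local maxima", {
  tt <- seq(0, 20 * pi, length.out = 4000)
  expect_length(extract_peaks(sin(tt), transient_fraction = 0), 1)
  decay <- exp(-seq(0, 10, length.out = 1000)) # monotone: no interior maxima
  expect_length(extract_peaks(decay, transient_fraction = 0), 0)
  pk <- extract_peaks(chaotic_traj())
  expect_gt(length(pk), 50) # dense peak set: chaotic attractor signature
})

test_that("diverged trajectories yield an empty flagged peak set", {
  tr <- simulate_stress(chaotic_params(), 0.2, t_end = 100)
  pk <- extract_peaks(tr)
  expect_length(pk, 0)
  expect_true(attr(pk, "diverged"))
})

test_that("bifurcation scan resolves periodic and chaotic windows in q", {
  bif <- bifurcation_scan("q", c(0.9, 0.95, 0.99), chaotic_params())
  expect_s3_class(bif, "bifurcation_scan")
  expect_equal(bif$axis, rep("q", 3))
  expect_lt(bif$n_peaks[1], 10)   # periodic at q = 0.9
  expect_gt(bif$n_peaks[3], 50)   # chaotic at q = 0.99
  expect_false(any(bif$diverged))
})

test_that("the unforced system shows no chaos", {
  p0 <- stress_params(B = 2.2, rho = 0)
  bif <- bifurcation_scan("q", c(0.9, 1.0), p0)
  expect_true(all(bif$n_peaks < 10))
})

test_that("scans are deterministic", {
  a <- bifurcation_scan("q", c(0.95, 0.99), chaotic_params(), t_end = 100)
  b <- bifurcation_scan("q", c(0.95, 0.99), chaotic_params(), t_end = 100)
  expect_identical(as.data.frame(a[names(a) != "peaks"]),
                   as.data.frame(b[names(b) != "peaks"]))
  expect_identical(a$peaks, b$peaks)
})

test_that("metric scan computes windowed summaries per grid point", {
  ms <- metric_scan("omega", c(1.0, 1.5), params = chaotic_params(),
                    q = 0.99)
  expect_equal(names(ms), c("omega", "se", "c0", "diverged"))
  expect_gt(ms$se[ms$omega == 1.5], ms$se[ms$omega == 1.0])
  expect_false(any(ms$diverged))
  # 2D grid is fully crossed
  ms2 <- metric_scan("B", c(2.0, 2.2), axis2 = "q", values2 = c(0.98, 0.99),
                     params = chaotic_params(), t_end = 200, n = 1024)
  expect_equal(nrow(ms2), 4)
  expect_true(all(c("B", "q") %in% names(ms2)))
})

test_that("divergent grid points are masked, not fatal", {
  ms <- metric_scan("q", c(0.2, 0.99), params = chaotic_params(),
                    t_end = 200, n = 1024)
  expect_true(ms$diverged[1])
  expect_true(is.na(ms$se[1]))
  expect_false(ms$diverged[2])
  expect_true(is.finite(ms$se[2]))
})

test_that("regime classification applies the conjunctive threshold rule", {
  expect_equal(classify_regime(0.6, 0.2), "chaotic")
  expect_equal(classify_regime(0.05, 0.01), "stable_or_periodic")
  expect_equal(classify_regime(0.6, 0.05), "stable_or_periodic")
  expect_equal(classify_regime(0.2, 0.3), "stable_or_periodic")
  df <- tibble::tibble(se = c(0.6, 0.1), c0 = c(0.2, 0.01))
  out <- classify_regime(df)
  expect_equal(out$label, c("chaotic", "stable_or_periodic"))
})

test_that("initial conditions alone can switch the regime label", {
  # multistability: identical parameters, different symptom initial value
  p <- chaotic_params()
  runs <- lapply(list(c(1, 1, 1), c(1, 30, 1)), function(ic) {
    tr <- simulate_stress(p, 1.0, t_end = 1000, state0 = ic,
                          memory_horizon = 1000)
    classify_regime(complexity_metrics(signal_window(tr)))$label
  })
  expect_equal(runs[[1]], "chaotic")
  expect_equal(runs[[2]], "stable_or_periodic")
})

test_that("chaotic-labelled points carry far denser peak sets", {
  qs <- c(0.9, 0.95, 1.0)
  bif <- bifurcation_scan("q", qs, chaotic_params())
  ms <- metric_scan("q", qs, params = chaotic_params())
  lab <- classify_regime(ms)$label
  expect_true(any(lab == "chaotic"))
  expect_gt(median(bif$n_peaks[lab == "chaotic"]),
            10 * median(bif$n_peaks[lab == "stable_or_periodic"]))
})

test_that("scan inputs are validated", {
  expect_error(bifurcation_scan("nope", c(1, 2), stress_params()),
               class = "stressdyn_config_error")
  expect_error(bifurcation_scan("q", 0.99, stress_params()))
  expect_error(classify_regime(0.5, 0.1, se_threshold = -1))
})

test_that("scan plots build", {
  bif <- bifurcation_scan("q", c(0.95, 0.99), chaotic_params(), t_end = 100)
  expect_s3_class(autoplot(bif), "ggplot")
  ms <- metric_scan("omega", c(1.0, 1.5), params = chaotic_params(),
                    t_end = 200, n = 1024)
  expect_s3_class(autoplot(ms), "ggplot")
})
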