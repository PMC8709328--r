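test_that("a flat series takes the constant tie-break", {
  s <- tic_series(120:200, rep(-60, 81))
  f <- fit_washout(s)
  expect_identical(unname(coef(f)), c(0, -60, 0))
  expect_equal(f$mse, 0)
  expect_equal(f$area, 0)
  expect_equal(f$gradient0, 0)
  expect_equal(f$ttopk, 0)   # all-equal peak ties to the first frame
})

test_that("noiseless series are recovered to 1e-3 relative error", {
  truth <- c(A = 10, k = 0.05, B = -57)
  s <- make_series(truth[["A"]], truth[["k"]], truth[["B"]], 120:240)
  f <- fit_washout(s)
  expect_lt(abs(coef(f)[["A"]] / truth[["A"]] - 1), 1e-3)
  expect_lt(abs(coef(f)[["k"]] / truth[["k"]] - 1), 1e-3)
  expect_lt(abs(coef(f)[["B"]] / truth[["B"]] - 1), 1e-3)
  expect_lt(f$mse, 1e-6)

  # refit idempotence: fitting the model's own output reproduces it
  f2 <- fit_washout(tic_series(s$times, fitted(f)))
  expect_equal(unname(coef(f2)), unname(coef(f)), tolerance = 1e-6)
})

test_that("fit MSE never exceeds the best constant fit", {
  for (seed in 1:12) {
    set.seed(seed)
    s <- make_series(A = runif(1, -20, 20), k = runif(1, 0, 0.2),
                     B = runif(1, -70, -40), times = seq(120, 300, 2),
                     noise_sd = runif(1, 0, 5), seed = seed + 100)
    f <- fit_washout(s)
    const_mse <- mean((s$intensities - mean(s$intensities))^2)
    expect_lte(f$mse, const_mse + 1e-9)
    expect_true(f$converged)
  }
})

test_that("gradient at the start frame matches the numerical derivative", {
  s <- make_series(A = 15, k = 0.03, B = -60, times = 120:280,
                   noise_sd = 0.5, seed = 7)
  f <- fit_washout(s)
  h <- 1e-4
  g_num <- (predict(f, 120 + h) - predict(f, 120 - h)) / (2 * h)
  expect_equal(f$gradient0, g_num,
               tolerance = 1e-6 + 1e-9 / max(abs(f$gradient0), 1e-12))
  expect_equal(f$gradient0, -coef(f)[["A"]] * coef(f)[["k"]])
})

test_that("profiled least squares matches an independent Levenberg fit", {
  skip_if_not_installed("minpack.lm")
  for (seed in c(3, 11, 42)) {
    s <- make_series(A = 12, k = 0.04, B = -58, times = 120:260,
                     noise_sd = 1.5, seed = seed)
    f <- fit_washout(s)
    tau <- s$times - 120
    y <- s$intensities
    nls_fit <- minpack.lm::nlsLM(
      y ~ A * exp(-k * tau) + B,
      start = list(A = y[1] - y[length(y)], B = y[length(y)],
                   k = 2 / max(tau)),
      lower = c(A = -Inf, B = -Inf, k = 0),
      upper = c(A = Inf, B = Inf, k = 10))
    rss_ref <- sum(residuals(nls_fit)^2)
    expect_lte(f$mse * length(y), rss_ref + 1e-6)
    expect_equal(unname(coef(f)), unname(coef(nls_fit)[c("A", "B", "k")]),
                 tolerance = 1e-4)
  }
})

test_that("AREA inversion matches a quadrature oracle and its limits", {
  expect_equal(params_from_area(0, 0.1, -60, 100)$A, 0)

  p <- params_from_area(-10, 0.1, -60, 100)
  expect_equal(p$A, 11.11106, tolerance = 1e-5)
  dev <- function(t) p$A * exp(-p$k * t) + p$B - (p$A + p$B)
  expect_equal(stats::integrate(dev, 0, 100)$value / 100, -10,
               tolerance = 1e-8)

  # as k*T grows the whole amplitude washes out: A -> -AREA + O(1/kT)
  expect_equal(params_from_area(-10, 10, -60, 100)$A, 10, tolerance = 2e-3)
  expect_error(params_from_area(-10, 1e-16, -60, 1), "degenerate")
})

test_that("AREA of the fitted curve agrees with direct integration", {
  s <- make_series(A = 20, k = 0.015, B = -62, times = seq(120, 300, 1))
  f <- fit_washout(s)
  cf <- coef(f)
  dev <- function(t) cf[["A"]] * exp(-cf[["k"]] * t) - cf[["A"]]
  oracle <- stats::integrate(dev, 0, 180)$value / 180
  expect_equal(f$area, oracle, tolerance = 1e-8)
  expect_equal(compute_area(f, normalize = FALSE), f$area * 180)
})

test_that("raw-sample AREA of a linear fall is its hand value", {
  # 0.2 dB/s linear fall over a 100 s window: mean deviation is -10 dB
  tt <- seq(0, 100, 1)
  f <- fit_washout(tic_series(120 + tt, -50 - 0.2 * tt))
  expect_equal(compute_area(f, mode = "raw"), -10)
})

test_that("AREA is linear in A with negative slope", {
  k <- 0.05; B <- -60; times <- 120:240
  avals <- c(-10, -5, 5, 10, 20)
  areas <- vapply(avals, function(A) {
    fit_washout(make_series(A, k, B, times))$area
  }, numeric(1))
  expect_true(all(diff(areas) < 0))      # larger A, more negative AREA
  slopes <- diff(areas) / diff(avals)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-6)
  expect_lt(slopes[1], 0)
})

test_that("time to peak scans to the first maximum", {
  expect_equal(time_to_peak(120:180, seq(0, -30, length.out = 61)), 0)
  tt <- 120:180
  y <- -60 + dnorm(tt, 127, 2)    # unique max at t = 127
  expect_equal(time_to_peak(tt, y), 7)
  expect_equal(time_to_peak(tt, rep(-55, 61)), 0)
  expect_error(time_to_peak(numeric(0), numeric(0)), "empty")
})

test_that("curve intersection detects crossings and only crossings", {
  les <- fit_washout(make_series(A = 20, k = 0.02, B = -70, times = 120:300))
  par_flat <- fit_washout(tic_series(120:300, rep(-58, 181)))
  # lesion starts at -50, decays towards -70: crosses the -58 parenchyma
  hit <- curves_intersect(les, par_flat)
  expect_true(hit)
  ct <- attr(hit, "crossing_time")
  expect_gt(ct, 120); expect_lt(ct, 300)
  expect_equal(predict(les, ct), -58, tolerance = 1e-6)

  expect_false(curves_intersect(les, les))               # identical
  below <- fit_washout(tic_series(120:300, rep(-20, 181)))
  expect_false(curves_intersect(les, below))             # never meets
})

test_that("TIC simulation is exact at zero noise and seed-reproducible", {
  p <- list(A = 8, B = -55, k = 0.03, t0 = 0)
  tt <- seq(120, 300, 0.5)
  s0 <- simulate_tic(p, tt, noise_sd = 0)
  expect_equal(s0$intensities, 8 * exp(-0.03 * (tt - 120)) - 55)

  s1 <- simulate_tic(p, tt, noise_sd = 2, seed = 99)
  s2 <- simulate_tic(p, tt, noise_sd = 2, seed = 99)
  s3 <- simulate_tic(p, tt, noise_sd = 2, seed = 100)
  expect_identical(s1$intensities, s2$intensities)
  expect_false(identical(s1$intensities, s3$intensities))
  expect_error(simulate_tic(p, numeric(0)), "empty")
})
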