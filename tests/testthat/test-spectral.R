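test_that("autocorrelation matches direct summation", {
  x <- c(1, -1, 1, -1, 1, -1)
  expect_equal(serial_acf(x, 1), -5/6)

  set.seed(41)
  y <- as.numeric(arima.sim(list(ar = 0.6), 200))
  r <- serial_acf(y, 5)
  for (k in 1:5) expect_equal(r[k], acf_brute(y, k), tolerance = 1e-12)

  expect_error(serial_acf(rep(2, 30), 3), "constant")
})

test_that("partial autocorrelation: lag 1 equals acf, recursion matches stats::pacf", {
  set.seed(42)
  y <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 150))
  pf <- serial_pacf(y, 6)
  expect_equal(pf$pacf[1], serial_acf(y, 1)[1], tolerance = 1e-10)
  expect_equal(pf$pacf, c(stats::pacf(y, 6, plot = FALSE)$acf), tolerance = 1e-10)
  # t statistic is pacf * sqrt(n) exactly; se is 1/sqrt(n)
  expect_identical(pf$t_stat, pf$pacf * sqrt(150))
  expect_equal(pf$se, rep(1 / sqrt(150), 6))
  expect_error(serial_pacf(y, 80), "n/2")
})

test_that("pacf significance uses the large-sample normal upper tail", {
  expect_equal(pacf_significance(0, 100)$p_one_sided, 0.5)
  expect_equal(pacf_significance(0.5, 16)$t_stat, 2)
  s <- pacf_significance(0.39, 25)
  expect_equal(s$t_stat, 1.95)
  expect_equal(s$p_one_sided, pnorm(1.95, lower.tail = FALSE))
  expect_error(pacf_significance(1.2, 10), "\\[-1, 1\\]")
  expect_error(pacf_significance(0.5, 1))
})

test_that("Fourier coefficients recover unit sinusoids and match naive summation", {
  t <- 0:9
  expect_equal(unname(fourier_coefficients(cos(2 * pi * 0.1 * t), 0.1)),
               c(1, 0), tolerance = 1e-12)
  expect_equal(unname(fourier_coefficients(sin(2 * pi * 0.1 * t), 0.1)),
               c(0, 1), tolerance = 1e-12)
  set.seed(43)
  x <- rnorm(37)
  for (f in c(0.1, 0.27, 0.5)) {
    expect_equal(unname(fourier_coefficients(x, f)), fourier_brute(x, f),
                 tolerance = 1e-12)
  }
  expect_error(fourier_coefficients(x, 0), "frequency")
  expect_error(fourier_coefficients(x, 0.6), "frequency")
})

test_that("periodogram concentrates sinusoids on their ordinates and obeys Parseval", {
  N <- 40
  x <- cos(2 * pi * 0.1 * (0:(N - 1)))
  pg <- periodogram(x)
  expect_equal(pg$frequency[which.max(pg$intensity)], 0.1)

  # two exact Fourier ordinates hold all the intensity
  y <- 2 * cos(2 * pi * (2 / N) * (0:(N - 1))) + sin(2 * pi * (5 / N) * (0:(N - 1)))
  pgy <- periodogram(y)
  on_grid <- pgy$frequency %in% c(2 / N, 5 / N)
  expect_lt(sum(pgy$intensity[!on_grid]), 1e-20 * sum(pgy$intensity))

  set.seed(44)
  z <- rnorm(31)   # odd length
  pgz <- periodogram(z)
  expect_equal(sum((pgz$cosine^2 + pgz$sine^2) / 2),
               mean((z - mean(z))^2), tolerance = 1e-10)
  expect_error(periodogram(rep(1, 20)), "constant")
})

test_that("Fisher's g-test gives the exact white-noise tail and handles extremes", {
  # equal intensities: g is 1/m and the statistic is at its null floor
  gt <- fisher_g_test(c(2, 2, 2, 2))
  expect_equal(gt$g, 0.25)
  expect_equal(gt$p_value, 1, tolerance = 1e-10)
  # one dominant ordinate: g = 1, p underflows cleanly to 0
  g1 <- fisher_g_test(c(0, 5, 0))
  expect_equal(g1$g, 1)
  expect_equal(g1$p_value, 0)
  # p is non-increasing in g at fixed m
  m <- 20
  gs <- seq(0.06, 0.9, by = 0.02)
  ps <- vapply(gs, function(g) branchcycles:::fisher_g_pvalue(g, m), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  # a strong injected sinusoid is detected
  N <- 50
  xs <- 3 * cos(2 * pi * (6 / N) * (0:(N - 1))) + rnorm(N)
  expect_lt(fisher_g_test(periodogram(xs))$p_value, 0.05)
  expect_error(fisher_g_test(c(1, 2)), "at least 3")
  expect_error(fisher_g_test(c(0, 0, 0)), "zero")
})

test_that("the exact g p-value agrees with a Monte-Carlo white-noise null", {
  set.seed(4)
  N <- 50
  x <- 0.8 * cos(2 * pi * (6 / N) * (0:(N - 1))) + rnorm(N)
  gt <- fisher_g_test(periodogram(x))
  gs <- replicate(10000, fisher_g_test(periodogram(rnorm(N)))$g)
  emp <- mean(gs >= gt$g)
  mc_sd <- sqrt(gt$p_value * (1 - gt$p_value) / 10000)
  expect_lt(abs(emp - gt$p_value), 3 * mc_sd)
})

test_that("spectral statistics are invariant to reversal and added constants", {
  set.seed(45)
  x <- rpois(50, 2)
  xr <- rev(x)
  xc <- x + 7
  expect_equal(serial_acf(x, 5), serial_acf(xc, 5), tolerance = 1e-12)
  expect_equal(serial_acf(x, 5), serial_acf(xr, 5), tolerance = 1e-12)
  expect_equal(serial_pacf(x, 5)$pacf, serial_pacf(xr, 5)$pacf, tolerance = 1e-12)
  expect_equal(periodogram(x)$intensity, periodogram(xc)$intensity, tolerance = 1e-10)
  expect_equal(periodogram(x)$intensity, periodogram(xr)$intensity, tolerance = 1e-10)
  expect_equal(fisher_g_test(periodogram(x))$g,
               fisher_g_test(periodogram(xr))$g, tolerance = 1e-12)
})

test_that("frequency/period conversion is reciprocal in the bin width", {
  expect_equal(frequency_to_period(0.25, 0.1), 0.4)
  expect_equal(period_to_frequency(0.4, 0.1), 0.25)
  expect_equal(period_to_frequency(frequency_to_period(0.2, 0.05), 0.05), 0.2)
})
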