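test_that("the forced rate law evaluates exactly", {
  expect_equal(rate_at(forcing_model(2), c(0, 1, 5)), rep(2, 3))
  m <- forcing_model(1, periods = 0.4, amplitudes = 1)
  expect_equal(rate_at(m, 0), exp(1))
  expect_equal(rate_at(m, 0.2), exp(-1))
  # phase shifts the crest
  mp <- forcing_model(1, periods = 0.4, amplitudes = 1, phases = pi)
  expect_equal(rate_at(mp, 0), exp(-1))
  expect_error(forcing_model(0), "base_rate > 0")
  expect_error(forcing_model(1, periods = 0.4, amplitudes = -1))
})

test_that("the eccentricity preset carries the 400- and 100-kyr bands", {
  m <- eccentricity_preset()
  expect_equal(m$periods, c(0.4, 0.1))
  expect_equal(m$amplitudes, c(1, 0.5))
  m0 <- m; m0$amplitudes <- c(0, 0)
  expect_equal(rate_at(m0, seq(0, 1, 0.1)), rep(m$base_rate, 11))
})

test_that("event simulation is seed-deterministic and refuses runaways", {
  m <- eccentricity_preset()
  e1 <- simulate_events(m, 10, seed = 42)
  e2 <- simulate_events(m, 10, seed = 42)
  expect_identical(e1, e2)
  expect_false(identical(e1, simulate_events(m, 10, seed = 43)))
  expect_true(all(e1 >= 0 & e1 <= 10))
  expect_false(is.unsorted(e1))
  expect_error(simulate_events(forcing_model(1e7), 10), "runaway")
})

test_that("with zero amplitude the event count is Poisson with mean rate x span", {
  set.seed(51)
  counts <- replicate(400, length(simulate_events(forcing_model(5), 20)))
  # mean 100, sd 10 per draw; the mean of 400 draws has sd 0.5
  expect_lt(abs(mean(counts) - 100), 3 * 0.5)
  expect_lt(abs(var(counts) - 100), 4 * sqrt(2 * 100^2 / 399))
})

test_that("the mean simulated count matches the numeric integral of the rate law", {
  m <- eccentricity_preset(base_rate = 2.5)
  expected <- expected_events(m, 10)
  set.seed(52)
  counts <- replicate(500, length(simulate_events(m, 10)))
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 500))
})

test_that("thinning reproduces the target intensity profile across phase windows", {
  m <- tune_base_rate(forcing_model(1, periods = 0.4, amplitudes = 1), 1e5, 10)
  ev <- simulate_events(m, 10, seed = 3)
  # fold event ages into phase over one forcing period, 20 windows
  obs <- tabulate(floor((ev %% 0.4) / 0.02) + 1L, 20L)
  mid <- (0:19) * 0.02 + 0.01
  dens <- exp(cos(2 * pi * mid / 0.4))
  expd <- dens / sum(dens) * length(ev)
  chi2 <- sum((obs - expd)^2 / expd)
  expect_gt(pchisq(chi2, df = 19, lower.tail = FALSE), 0.001)
})

test_that("pure-birth trees are ultrametric with true ages matching extraction", {
  sim <- simulate_tree(forcing_model(0.5, 0.4, 1), 6, seed = 9)
  expect_equal(length(sim$tree$tip.label), length(sim$ages) + 1L)
  expect_silent(assert_ultrametric(sim$tree))
  expect_equal(sort(extract_ages(sim$tree)$mean), sort(sim$ages),
               tolerance = 1e-9)
  expect_identical(simulate_tree(forcing_model(0.5), 6, seed = 10)$ages,
                   simulate_tree(forcing_model(0.5), 6, seed = 10)$ages)
  expect_error(simulate_tree(forcing_model(1e-6), 0.01, seed = 1),
               "no branching events")
})

test_that("at zero amplitude the tree process reduces to a constant-rate Yule process", {
  # inter-split gaps scaled by the number of extant lineages are Exp(lambda0)
  set.seed(53)
  lam <- 0.5
  gaps <- numeric(0)
  for (r in 1:300) {
    st <- tryCatch(simulate_tree(forcing_model(lam), 8), error = function(e) NULL)
    if (is.null(st)) next
    splits <- sort(st$ages, decreasing = TRUE)
    times <- c(8, splits)
    k <- seq_along(splits)
    gaps <- c(gaps, (times[k] - times[k + 1]) * k)
  }
  expect_gt(length(gaps), 500)
  expect_gt(stats::ks.test(gaps, "pexp", lam)$p.value, 0.01)
})

test_that("dating noise has the requested coefficient of variation and keeps intervals valid", {
  ages <- spalax_node_ages()
  expect_identical(add_dating_noise(ages, 0), ages)
  n1 <- add_dating_noise(ages, 0.3, seed = 6)
  expect_identical(n1, add_dating_noise(ages, 0.3, seed = 6))
  expect_true(all(n1$low <= n1$mean & n1$mean <= n1$high))

  big <- node_ages(paste0("x", 1:10000), rep(1, 10000))
  nz <- add_dating_noise(big, 0.3, seed = 7)
  expect_lt(abs(sd(nz$mean) / mean(nz$mean) - 0.3), 0.02)
})

test_that("the full tree pipeline recovers a strong injected forcing period", {
  # newick write -> read -> age extraction -> binning -> periodogram; the
  # pure-birth growth trend is removed with linear detrending
  set.seed(54)
  m <- forcing_model(0.34, periods = 0.4, amplitudes = 2)
  ok <- 0L; usable <- 0L
  for (r in 1:40) {
    st <- tryCatch(simulate_tree(m, 6), error = function(e) NULL)
    if (is.null(st) || length(st$ages) < 10L) next
    usable <- usable + 1L
    ages <- extract_ages(read_chronogram(write_chronogram(st$tree)))
    s <- bin_events(ages, bin_width = 0.1, t_min = 0, t_max = 6)
    pg <- periodogram(detrend(s, "linear"), bin_width = 0.1)
    if (abs(pg$period[which.max(pg$intensity)] - 0.4) < 1e-9) ok <- ok + 1L
  }
  expect_gt(usable, 20L)
  expect_gte(ok / usable, 0.8)
})

test_that("detection rate grows with forcing amplitude from a calibrated floor", {
  ps <- power_study(c(0, 1, 2), period = 0.4, target_events = 100, span = 10,
                    bin_width = 0.1, n_reps = 200, seed = 11)
  expect_equal(nrow(ps), 3L)
  # amplitude-0 row is the empirical type-I error near the nominal level
  expect_lt(ps$detection_rate[1], 0.12)
  # monotone non-decreasing up to two binomial standard errors
  se <- sqrt(0.25 / 200)
  expect_true(all(diff(ps$detection_rate) >= -2 * se))
  expect_gte(ps$detection_rate[3], 0.8)
})
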