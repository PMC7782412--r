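test_that("baseline modulation values are Normal(1, mod_sd^2)", {
  times <- seq(0, by = 0.1, length.out = 10000)
  v <- computeModulationValues(times, modulationParams(), seed = 1)
  expect_lt(abs(mean(v) - 1), 0.002)
  expect_lt(abs(sd(v) - 0.05), 0.002)
  expect_error(computeModulationValues(c(2, 1)), "sorted")
})

test_that("burst events are bounded by spike count and reset in between", {
  # constant 10 ms ISIs, deterministic values (mod_sd = 0)
  times <- seq(0, by = 0.01, length.out = 30)
  v <- computeModulationValues(times, modulationParams(
    bursting = TRUE, mod_sd = 0, max_spikes_per_burst = 5))
  groups <- split(v, rep(seq_len(6), each = 5))
  for (g in groups) {
    expect_true(all(diff(g) < 0))   # strictly decreasing within an event
    expect_equal(g[1], 1)           # depression resets at event start
  }
  # all events follow the same depression profile
  expect_equal(groups[[1]], groups[[4]], ignore_attr = TRUE)
})

test_that("burst events are bounded by their maximum duration", {
  times <- seq(0, by = 0.01, length.out = 40)
  v <- computeModulationValues(times, modulationParams(
    bursting = TRUE, mod_sd = 0, max_burst_duration = 75,
    max_spikes_per_burst = 1000))
  resets <- which(v == 1)
  # events close once they span >= 75 ms: resets every 8 spikes (span 70 ms)
  expect_true(all(diff(resets) == 8))
  spans <- times[resets[-1] - 1] - times[resets[-length(resets)]]
  expect_true(all(spans <= 0.075))
})

test_that("burst depression weakens for longer within-burst intervals", {
  p <- modulationParams(bursting = TRUE, mod_sd = 0, burst_isi_threshold = 50)
  vShort <- computeModulationValues(seq(0, by = 0.005, length.out = 5), p)
  vLong <- computeModulationValues(seq(0, by = 0.040, length.out = 5), p)
  expect_lt(vShort[5], vLong[5])
})

test_that("shape stretching widens the trough and preserves sample count", {
  # synthetic negative-trough template on 2 channels
  t <- seq(-3, 4, by = 1 / 32)
  w <- -exp(-(t / 0.4)^2)
  tpl <- rbind(40 * w, 15 * w)

  expect_identical(stretchTemplate(tpl, 1, 30), tpl)

  fwhm <- function(v) {
    half <- min(v) / 2
    sum(v <= half)
  }
  s10 <- stretchTemplate(tpl, 0.7, 10)
  s30 <- stretchTemplate(tpl, 0.7, 30)
  expect_equal(dim(s10), dim(tpl))
  expect_gt(fwhm(s10[1, ]), fwhm(tpl[1, ]))
  expect_gt(fwhm(s30[1, ]), fwhm(s10[1, ]))
  # trough sample index unchanged
  expect_equal(which.min(s30[1, ]), which.min(tpl[1, ]))
  expect_error(stretchTemplate(tpl, 0, 30), "modulation")
})

test_that("jittered templates keep shape and amplitude", {
  t <- seq(-2, 5, by = 1 / 32)
  tpl <- rbind(-50 * exp(-(t / 0.3)^2), -20 * exp(-(t / 0.3)^2))
  set.seed(3)
  j <- jitterTemplates(tpl, n_jitters = 8, upsample_factor = 10)
  expect_equal(dim(j), c(8, 2, ncol(tpl)))
  expect_equal(j[1, , ], tpl)   # first version is unshifted
  for (k in 2:8) {
    a0 <- abs(min(tpl[1, ]))
    ak <- abs(min(j[k, 1, ]))
    expect_lt(abs(ak - a0) / a0, 0.05)
  }
  j1 <- jitterTemplates(tpl, n_jitters = 1)
  expect_equal(j1[1, , ], tpl)
})
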