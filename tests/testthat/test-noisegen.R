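test_that("uncorrelated Gaussian noise has the requested level and no cross-talk", {
  expect_equal(uncorrelatedGaussian(0, 4, 100), matrix(0, 4, 100))
  n <- uncorrelatedGaussian(10, 4, 320000, seed = 1)
  sds <- apply(n, 1, sd)
  expect_true(all(abs(sds - 10) < 0.1))
  cc <- cor(t(n))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02)
})

test_that("distance-correlated noise decays with inter-electrode distance", {
  tet <- buildProbe("tetrode")
  n <- distanceCorrelatedGaussian(10, tet, lambda = 30, n_samples = 300000,
                                  seed = 2)
  cc <- cor(t(n))
  d <- pairwiseDistances(tet)
  # nearest pair (25 um) more correlated than the diagonal pair (~35 um)
  near <- which(d == min(d[d > 0]), arr.ind = TRUE)[1, ]
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  rNear <- cc[near[1], near[2]]
  rFar <- cc[far[1], far[2]]
  seDiff <- sqrt(2 / 300000) * 3
  expect_gt(rNear - rFar, seDiff)
  # theoretical correlations exp(-d/lambda)
  expect_lt(abs(rNear - exp(-25 / 30)), 0.01)

  # single channel reduces to white noise at the right level
  one <- distanceCorrelatedGaussian(10, matrix(0, 1, 3), 30, 100000, seed = 3)
  expect_lt(abs(sd(one[1, ]) - 10), 0.15)
})

test_that("coloured noise concentrates power at the resonance and keeps level", {
  fs <- 32000
  white <- uncorrelatedGaussian(10, 2, 300000, seed = 4)
  col <- colorNoise(white, fs, peak = 300, q = 1, floor_fraction = 0.3,
                    level = 10)
  sds <- apply(col, 1, sd)
  expect_true(all(abs(sds - 10) < 0.1))

  sp <- spec.pgram(col[1, ], spans = 51, plot = FALSE, taper = 0)
  densAt <- function(f) sp$spec[which.min(abs(sp$freq * fs - f))]
  expect_gt(densAt(300), densAt(3000))

  # colouring preserves distance correlation ordering
  tet <- buildProbe("tetrode")
  dcor <- distanceCorrelatedGaussian(10, tet, 30, 200000, seed = 5)
  cdc <- colorNoise(dcor, fs, 300, 1, 0.3, 10)
  cc <- cor(t(cdc))
  d <- pairwiseDistances(tet)
  near <- which(d == min(d[d > 0]), arr.ind = TRUE)[1, ]
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_gt(cc[near[1], near[2]] - cc[far[1], far[2]], 3 * sqrt(2 / 200000))

  expect_error(colorNoise(white, fs, peak = 20000), "Nyquist")
})

test_that("far-neurons noise is sub-threshold, level-matched and left-skewed", {
  tet <- buildProbe("tetrode")
  bank <- defaultCellBank(0)
  spec <- noiseSpec("far-neurons", level = 10, far_n = 40)
  res <- farNeuronsNoise(tet, bank, spec, duration = 20, fs = 32000,
                         seed = 6, fm = forwardModelParams(min_amplitude = 0),
                         return_templates = TRUE)
  # every contributing template stays below the amplitude threshold
  maxAmps <- apply(res$templates, 1, function(t) {
    max(apply(matrix(t, nrow = 4), 1, function(v) abs(min(v))))
  })
  expect_true(all(maxAmps < spec$far_amp_threshold))
  # channel-wise sd matches the requested level after rescaling
  expect_true(all(abs(apply(res$noise, 1, sd) - 10) < 0.1))
  # spike troughs skew the amplitude distribution to negative values
  expect_true(all(apply(res$noise, 1, skewness) < 0))
})

test_that("generateNoise dispatches and is deterministic per seed", {
  tet <- buildProbe("tetrode")
  a <- generateNoise(noiseSpec("uncorrelated", level = 5), tet, 0.5, 32000, 9)
  b <- generateNoise(noiseSpec("uncorrelated", level = 5), tet, 0.5, 32000, 9)
  expect_identical(a, b)
  c1 <- generateNoise(noiseSpec("colored-distance-correlated", level = 5),
                      tet, 0.5, 32000, 9)
  expect_equal(dim(c1), c(4, 16000))
  expect_false(identical(a, c1))
  z <- generateNoise(noiseSpec(level = 0), tet, 0.1, 32000, 1)
  expect_equal(z, matrix(0, 4, 3200))
})
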