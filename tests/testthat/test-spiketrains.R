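test_that("renewal spike trains have the right rate and respect refractoriness", {
  expect_length(generateSpikeTrain(0, 0, 10), 0)
  expect_error(generateSpikeTrain(-1, 0, 10), "rate")
  expect_error(generateSpikeTrain(5, 10, 10), "t_stop")

  # Poisson moments: mean count over trials close to rate * duration
  set.seed(100)
  nTrials <- 400
  counts <- vapply(seq_len(nTrials), function(i) {
    length(generateSpikeTrain(5, 0, 100, "poisson", refractory = 0))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 500), 3 * sqrt(500 / nTrials))

  # ISIs never violate the dead time, for either process
  set.seed(101)
  for (proc in c("poisson", "gamma")) {
    tr <- generateSpikeTrain(30, 0, 60, proc, refractory = 0.002)
    expect_true(all(diff(tr) >= 0.002))
  }
})

test_that("spike-train sets have the right composition and are seed-deterministic", {
  s1 <- generateSpikeTrainSet(4, 2, duration = 10, seed = 0)
  expect_length(trains(s1), 6)
  expect_equal(celltypes(s1), c(rep("excitatory", 4), rep("inhibitory", 2)))
  s2 <- generateSpikeTrainSet(4, 2, duration = 10, seed = 0)
  expect_identical(trains(s1), trains(s2))
  expect_error(generateSpikeTrainSet(0, 0, 10), "unit")

  # inhibitory cells fire faster than excitatory ones by default
  s3 <- generateSpikeTrainSet(1, 1, duration = 300, seed = 1)
  nE <- length(trains(s3)[[1]]); nI <- length(trains(s3)[[2]])
  # 3 sigma on the count difference under the nominal rates
  expect_gt(nI - nE, -3 * sqrt(nI + nE))
  expect_gt(nI, nE)
})

test_that("collision detection matches a brute-force double loop", {
  expect_equal(nrow(findCollisions(c(0.1), c(0.1005), 0.001)), 1)
  expect_equal(findCollisions(c(0.1), c(0.1005), 0.001)[1, ],
               c(i = 1L, j = 1L))
  expect_equal(nrow(findCollisions(c(1), c(2), 0.001)), 0)

  set.seed(5)
  a <- sort(runif(200, 0, 10))
  b <- sort(runif(200, 0, 10))
  w <- 0.01
  got <- findCollisions(a, b, w)
  ref <- NULL
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (abs(a[i] - b[j]) <= w) ref <- rbind(ref, c(i, j))
  }
  expect_equal(nrow(got), nrow(ref))
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               ref[order(ref[, 1], ref[, 2]), , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("synchrony control: unset is identity, zero removes all collisions", {
  set.seed(2)
  sts <- generateSpikeTrainSet(2, 0, duration = 120,
                               spikeTrainParams(rate_exc = 10), seed = 3)
  pair <- matrix(c(1, 2), 1)

  same <- applySynchrony(sts, pair, synchronyParams(sync_rate = NULL))
  expect_identical(trains(same), trains(sts))

  rm0 <- applySynchrony(sts, pair, synchronyParams(sync_rate = 0))
  cl <- findCollisions(trains(rm0)[[1]], trains(rm0)[[2]], 0.001)
  expect_equal(nrow(cl), 0)

  # idempotence: removing twice equals removing once
  rm00 <- applySynchrony(rm0, pair, synchronyParams(sync_rate = 0))
  expect_identical(trains(rm00), trains(rm0))

  expect_error(applySynchrony(sts, pair, synchronyParams(sync_rate = 0.5),
                              seed = 1), NA)
  expect_error(synchronyParams(sync_rate = 1.5), "sync_rate")
})

test_that("synchrony injection reaches the target rate and conserves counts", {
  sts <- generateSpikeTrainSet(2, 0, duration = 300,
                               spikeTrainParams(rate_exc = 5), seed = 4)
  before <- lengths(trains(sts))
  pair <- matrix(c(1, 2), 1)
  out <- applySynchrony(sts, pair, synchronyParams(sync_rate = 0.05), seed = 9)
  after <- lengths(trains(out))
  expect_equal(after, before)   # spikes are moved, never created

  nColl <- nrow(findCollisions(trains(out)[[1]], trains(out)[[2]], 0.001))
  frac <- nColl / min(after)
  expect_gt(frac, 0.05 * 0.8)
  expect_lt(frac, 0.05 * 1.2)

  # result is still a valid spike train set (sorted, in range, refractory)
  expect_true(validObject(out))
  expect_true(all(diff(trains(out)[[2]]) >= 0.002 - 1e-12))
})

test_that("synchrony edits are deterministic per seed", {
  sts <- generateSpikeTrainSet(2, 0, duration = 100, seed = 8)
  pair <- matrix(c(1, 2), 1)
  o1 <- applySynchrony(sts, pair, synchronyParams(sync_rate = 0.1), seed = 5)
  o2 <- applySynchrony(sts, pair, synchronyParams(sync_rate = 0.1), seed = 5)
  expect_identical(trains(o1), trains(o2))
})
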