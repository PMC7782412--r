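test_that("drift trajectories are linear with exact endpoints", {
  tr <- makeDriftTrajectory(c(0, 0, 0), c(0, 0, 29), 30)
  expect_equal(dim(tr), c(30, 3))
  expect_equal(tr[1, ], c(0, 0, 0))
  expect_equal(tr[30, ], c(0, 0, 29))
  steps <- diff(tr)
  expect_equal(steps, matrix(rep(c(0, 0, 1), each = 29), ncol = 3),
               tolerance = 1e-12)

  same <- makeDriftTrajectory(c(1, 2, 3), c(1, 2, 3), 5)
  expect_equal(same, matrix(rep(c(1, 2, 3), each = 5), ncol = 3))

  expect_error(makeDriftTrajectory(c(0, 0, 0), c(1, 0, 0), 1), "n_steps")
})

test_that("libraries have n_per_model templates per model above min_amplitude", {
  lib <- smallLibrary()
  expect_equal(dim(templates(lib))[1], 2 * 13)
  expect_equal(sum(celltypes(lib) == "excitatory"), 20)
  expect_equal(sum(celltypes(lib) == "inhibitory"), 6)
  amps <- apply(templates(lib), 1, function(t) {
    max(apply(matrix(t, nrow = 4), 1, function(v) abs(min(v))))
  })
  expect_true(all(amps >= simInfo(lib)$min_amplitude))
  expect_equal(simInfo(lib)$seed, 11)
})

test_that("template generation is bit-reproducible per seed", {
  bank <- defaultCellBank(0)[c(1, 11)]
  probe <- buildProbe("tetrode")
  l1 <- generateTemplates(bank, probe, n_per_model = 2, seed = 5)
  l2 <- generateTemplates(bank, probe, n_per_model = 2, seed = 5)
  expect_identical(templates(l1), templates(l2))
  expect_identical(locations(l1), locations(l2))
  expect_identical(rotations(l1), rotations(l2))
  l3 <- generateTemplates(bank, probe, n_per_model = 2, seed = 6)
  expect_false(identical(templates(l1), templates(l3)))
})

test_that("drifting libraries carry one template and location per drift step", {
  dlib <- smallDriftingLibrary()
  d <- dim(templates(dlib))
  expect_length(d, 4)
  expect_equal(d[1:2], c(6, 10))
  expect_equal(dim(locations(dlib)), c(6, 10, 3))
  # consecutive displacements along each trajectory are equal (linear drift)
  for (i in seq_len(d[1])) {
    steps <- diff(locations(dlib)[i, , ])
    expect_lt(max(abs(sweep(steps, 2, steps[1, ]))), 1e-9)
    span <- sum(sqrt(rowSums(steps^2)))
    expect_gte(span, 20 - 1e-9)
    expect_lte(span, 60 + 1e-9)
  }
})

test_that("amplitude statistics are insensitive to a fixed pre-rotation", {
  # with full 3d random rotations, rotating the morphology beforehand must
  # not change the distribution of template amplitudes
  model <- defaultCellBank(0)[[1]]
  params <- forwardModelParams(min_amplitude = 0)
  probe <- buildProbe("tetrode")
  preR <- SpikeForge:::.rotationMatrix(c(0.2, -0.1, 1.3))
  rotated <- model
  segs <- model@segments
  segs[, 1:3] <- segs[, 1:3, drop = FALSE] %*% t(preR)
  segs[, 4:6] <- segs[, 4:6, drop = FALSE] %*% t(preR)
  rotated@segments <- segs
  set.seed(21)
  a1 <- sampleAmplitudes(model, probe, 200, params)
  set.seed(22)
  a2 <- sampleAmplitudes(rotated, probe, 200, params)
  expect_gt(suppressWarnings(stats::ks.test(a1, a2)$p.value), 0.01)
})

test_that("an unattainable amplitude threshold raises a descriptive error", {
  bank <- defaultCellBank(0)[1]
  probe <- buildProbe("tetrode")
  expect_error(
    generateTemplates(bank, probe, n_per_model = 1,
                      params = forwardModelParams(min_amplitude = 1e7),
                      seed = 1),
    "min_amplitude")
})
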