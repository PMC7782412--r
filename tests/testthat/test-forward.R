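test_that("line-source kernel basics: linearity, conductivity scaling, clamp", {
  seg <- c(0, 0, -5, 0, 0, 5)
  pt <- c(30, 0, 0)
  expect_equal(lineSourcePotential(seg, numeric(10), pt), numeric(10))
  phi1 <- lineSourcePotential(seg, 1, pt, sigma = 0.3)
  expect_equal(lineSourcePotential(seg, 2, pt, sigma = 0.3), 2 * phi1)
  expect_equal(lineSourcePotential(seg, 1, pt, sigma = 0.6), phi1 / 2)
  # clamped at 1 um: a point on the line gives a finite value
  expect_true(is.finite(lineSourcePotential(seg, 1, c(0, 0, 0))))
})

test_that("the line source matches the point source in the far field", {
  # at 100x the segment length the line-source potential agrees with the
  # analytic point-source kernel I / (4 pi sigma r) within 1%
  segLen <- 10
  seg <- c(0, 0, -segLen / 2, 0, 0, segLen / 2)
  sigma <- 0.3
  for (dir in list(c(1, 0, 0), c(1, 1, 1) / sqrt(3), c(0, 1, 2) / sqrt(5))) {
    pt <- dir * 100 * segLen
    r <- sqrt(sum(pt^2))
    pointSource <- 1e3 * 1 / (4 * pi * sigma * r)   # uV per nA
    lineSource <- lineSourcePotential(seg, 1, pt, sigma)
    expect_lt(abs(lineSource - pointSource) / pointSource, 0.01)
  }
})

test_that("placeCell is a rigid transform with uniform soma locations", {
  model <- defaultCellBank(0)[[1]]
  probe <- buildProbe("tetrode")
  lenRef <- sqrt(rowSums((model@segments[, 4:6] - model@segments[, 1:3])^2))

  # degenerate bounds + no rotation: pure translation
  pinned <- forwardModelParams(position_bounds = cbind(c(20, 0, 0), c(20, 0, 0)),
                               rotation_mode = "none")
  set.seed(1)
  pl <- placeCell(model, probe, pinned)
  expect_equal(pl$location, c(20, 0, 0))
  expect_equal(pl$segments[, 1:3] - model@segments[, 1:3],
               matrix(rep(c(20, 0, 0), each = nrow(model@segments)), ncol = 3),
               tolerance = 1e-12)

  set.seed(7)
  params <- forwardModelParams()
  locs <- t(replicate(1000, {
    pl <- placeCell(model, probe, params)
    len <- sqrt(rowSums((pl$segments[, 4:6] - pl$segments[, 1:3])^2))
    expect_equal(len, lenRef, tolerance = 1e-9)
    pl$location
  }))
  # empirical mean within 3 standard errors of the bounds centre
  bounds <- rbind(c(10, 80), range(channelPositions(probe)[, 2]) + c(-30, 30),
                  range(channelPositions(probe)[, 3]) + c(-30, 30))
  for (ax in 1:3) {
    ctr <- mean(bounds[ax, ])
    se <- diff(bounds[ax, ]) / sqrt(12) / sqrt(1000)
    expect_lt(abs(mean(locs[, ax]) - ctr), 3 * se)
  }
})

test_that("computeEAP equals a brute-force per-segment, per-channel sum", {
  model <- defaultCellBank(0)[[3]]
  probe <- buildProbe("tetrode")
  params <- forwardModelParams(min_amplitude = 0)
  dt <- 1000 / params$fs
  cur <- simulateTransmembraneCurrents(model, dt, sum(params$cut_out) + 10,
                                       params$cut_out[1] + 1)
  set.seed(3)
  pl <- placeCell(model, probe, params)
  eap <- computeEAP(pl$segments, cur, probe, params)

  # independent loop oracle over (segment, channel) pairs, then identical trim
  nCh <- nChannels(probe)
  full <- matrix(0, nCh, ncol(cur))
  for (ch in seq_len(nCh)) {
    for (sg in seq_len(nrow(pl$segments))) {
      full[ch, ] <- full[ch, ] +
        lineSourcePotential(pl$segments[sg, 1:6], cur[sg, ],
                            channelPositions(probe)[ch, ], params$sigma)
    }
  }
  troughIdx <- which(full == min(full), arr.ind = TRUE)[1, 2]
  preN <- round(params$cut_out[1] / 1000 * params$fs)
  postN <- round(params$cut_out[2] / 1000 * params$fs)
  expect_equal(eap, full[, (troughIdx - preN):(troughIdx + postN)],
               tolerance = 1e-9)

  # a single-segment source reduces to one kernel evaluation
  oneSeg <- pl$segments[1, , drop = FALSE]
  oneCur <- cur[1, , drop = FALSE]
  eap1 <- computeEAP(oneSeg, oneCur, probe, params)
  ref1 <- lineSourcePotential(oneSeg[1, 1:6], oneCur[1, ],
                              channelPositions(probe)[1, ], params$sigma)
  trough1 <- which.min(apply(eap1, 2, min))
  expect_equal(ncol(eap1), preN + postN + 1)
  expect_equal(max(abs(eap1[1, ])), max(abs(ref1)), tolerance = 1e-9)
})

test_that("template amplitude decays with distance from the soma", {
  model <- defaultCellBank(0)[[1]]
  params <- forwardModelParams(min_amplitude = 0,
                               position_bounds = cbind(c(30, 0, 0), c(30, 0, 0)),
                               rotation_mode = "none")
  dt <- 1000 / params$fs
  cur <- simulateTransmembraneCurrents(model, dt, sum(params$cut_out) + 10,
                                       params$cut_out[1] + 1)
  set.seed(1)
  # probe points along a ray moving away from the soma, beyond 50 um
  dists <- seq(50, 250, by = 25)
  amps <- vapply(dists, function(d) {
    probe <- new("Probe", name = "ray", planeAxes = c(2L, 3L),
                 description = "",
                 positions = rbind(c(30 + d, 0, 0), c(30 + d, 0, 1)))
    pl <- placeCell(model, probe, params)
    eap <- computeEAP(pl$segments, cur, probe, params)
    max(abs(eap))
  }, numeric(1))
  expect_true(all(diff(amps) <= 0))
})
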