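test_that("template amplitudes and the max channel follow the trough rule", {
  tpl <- matrix(0, 4, 50)
  tpl[3, 25] <- -40
  a <- templateAmplitudes(tpl)
  expect_equal(a$max_channel, 3)
  expect_equal(a$amplitudes[3], 40)

  z <- templateAmplitudes(matrix(0, 4, 50))
  expect_equal(z$max_channel, 1)          # ties break to the lowest index
  expect_equal(z$amplitudes, rep(0, 4))

  set.seed(1)
  r <- matrix(rnorm(200), 4, 50)
  a2 <- templateAmplitudes(r)
  ref <- vapply(1:4, function(ch) abs(min(r[ch, ])), numeric(1))
  expect_equal(a2$amplitudes, ref)
  expect_equal(a2$max_channel, which.max(ref))
})

test_that("the spatial-overlap classifier switches exactly at the threshold", {
  # template A peaks on channel 2; B peaks on channel 4
  mkT <- function(peakCh, amps) {
    tpl <- matrix(0, 4, 60)
    for (ch in 1:4) tpl[ch, 30] <- -amps[ch]
    tpl
  }
  tA <- mkT(2, c(5, 50, 5, 5))
  mkB <- function(fracOnCh2) mkT(4, c(1, fracOnCh2 * 30, 1, 30))
  expect_true(isSpatiallyOverlapping(tA, mkB(0.91), 0.9))
  expect_false(isSpatiallyOverlapping(tA, mkB(0.89), 0.9))
  expect_true(isSpatiallyOverlapping(tA, tA, 1))
  # the condition is symmetric in the pair
  expect_true(isSpatiallyOverlapping(mkB(0.91), tA, 0.9))
})

test_that("template selection honours composition, distance and determinism", {
  lib <- smallLibrary()
  sel <- selectTemplates(lib, selectionRules(4, 2, min_dist = 10), temp_seed = 1)
  expect_length(sel, 6)
  expect_equal(celltypes(lib)[sel], c(rep("excitatory", 4), rep("inhibitory", 2)))
  locs <- locations(lib)[sel, ]
  d <- as.matrix(dist(locs))
  expect_true(all(d[upper.tri(d)] >= 10))

  sel2 <- selectTemplates(lib, selectionRules(4, 2, min_dist = 10), temp_seed = 1)
  expect_identical(sel, sel2)

  expect_error(selectTemplates(lib, selectionRules(4, 2, min_dist = 1e5)),
               "min_dist|candidates|constraint")
})

test_that("convolution places modulated templates exactly at the spikes", {
  tpl <- matrix(0, 2, 33)
  tpl[1, ] <- -40 * exp(-((seq_len(33) - 9) / 3)^2)
  tpl[2, ] <- 0.5 * tpl[1, ]
  jit <- array(tpl, c(1, 2, 33))
  fs <- 1000
  out <- convolveUnit(0.5, jit, 1, fs, 1000, trough_idx = 9)
  # the trough lands exactly on the spike sample
  expect_equal(which.min(out[1, ]), 501)
  expect_equal(out[, 493:525], tpl, ignore_attr = TRUE)
  expect_equal(sum(out != 0), sum(tpl != 0))

  # linearity: two distant spikes equal the sum of single-spike outputs
  out2 <- convolveUnit(c(0.2, 0.7), jit, c(1, 1), fs, 1000, 9)
  oA <- convolveUnit(0.2, jit, 1, fs, 1000, 9)
  oB <- convolveUnit(0.7, jit, 1, fs, 1000, 9)
  expect_equal(out2, oA + oB)

  # amplitude modulation scales the inserted waveform
  half <- convolveUnit(0.5, jit, 0.5, fs, 1000, 9)
  expect_equal(half, 0.5 * out)

  # spikes at the very edge are truncated, not dropped
  edge <- convolveUnit(0.001, jit, 1, fs, 1000, 9)
  expect_equal(edge[1, 1:26], tpl[1, 8:33])
})

test_that("a forced collision sums the two waveforms sample-wise", {
  tplA <- matrix(-40 * exp(-((seq_len(33) - 17) / 3)^2), 1, 33)
  tplB <- matrix(-25 * exp(-((seq_len(33) - 17) / 4)^2), 1, 33)
  fs <- 1000
  a <- convolveUnit(0.5, array(tplA, c(1, 1, 33)), 1, fs, 1000, 17)
  b <- convolveUnit(0.5005, array(tplB, c(1, 1, 33)), 1, fs, 1000, 17)
  both <- a + b
  # the recorded waveform at the collision is the sample-wise sum
  win <- 480:520
  expect_equal(both[1, win], a[1, win] + b[1, win])
  expect_lt(min(both), min(a))
})

test_that("zero-phase filtering rejects DC and preserves in-band tones", {
  fs <- 32000
  n <- 16000
  dc <- matrix(7, 2, n)
  hp <- filterRecording(dc, "highpass", 300, 3, fs)
  # away from the edge transients the offset is rejected completely
  interior <- 4000:12000
  expect_lt(max(abs(rowMeans(hp[, interior]))), 1e-6 * 7)

  tt <- seq_len(n) / fs
  tone <- matrix(sin(2 * pi * 1000 * tt), 1, n)
  bp <- filterRecording(tone, "bandpass", c(300, 6000), 3, fs)
  core <- 2000:14000   # avoid edge transients
  expect_lt(abs(max(abs(bp[1, core])) - 1), 0.01)

  # filtering twice with the same band changes an in-band tone little
  bp2 <- filterRecording(bp, "bandpass", c(300, 6000), 3, fs)
  expect_lt(max(abs(bp2[1, core] - bp[1, core])), 0.02)

  expect_error(filterRecording(dc, "bandpass", c(300, 20000), 3, fs),
               "cutoff")
})

test_that("noise-free recordings match their ground truth on the max channel", {
  lib <- smallLibrary()
  rec <- assembleRecording(
    lib, selectionRules(2, 1),
    mod_params = modulationParams(mod_sd = 0, bursting = FALSE),
    noise = noiseSpec(level = 0),
    rec_params = recordingParams(duration = 5, n_jitters = 1))
  expect_true(validObject(rec))
  info <- simInfo(rec)
  allTrains <- trains(spikeTrains(rec))
  for (u in 1:3) {
    tpl <- templates(rec)[u, 1, , ]
    maxCh <- templateAmplitudes(matrix(tpl, nrow = 4))$max_channel
    tr <- allTrains[[u]]
    others <- sort(unlist(allTrains[-u]))
    # keep spike windows free of other units' spikes (no collisions there)
    isolated <- tr[vapply(tr, function(t0) {
      all(abs(others - t0) > 0.008)
    }, logical(1))]
    pre <- round(info$cut_out[1] / 1000 * info$fs)
    win <- unlist(lapply(isolated, function(t0) {
      s <- round(t0 * info$fs) + 1
      (s - pre):(s + pre)
    }))
    win <- win[win >= 1 & win <= ncol(recordings(rec))]
    expect_gt(cor(recordings(rec)[maxCh, win], spikeTraces(rec)[u, win]), 0.99)
  }
})

test_that("the four seed streams are separable", {
  lib <- smallLibrary()
  base <- recordingParams(duration = 2, n_jitters = 2)
  mk <- function(...) {
    rp <- recordingParams(duration = 2, n_jitters = 2, ...)
    assembleRecording(lib, selectionRules(2, 1), rec_params = rp)
  }
  r1 <- mk()
  r2 <- mk(noise_seed = 99)
  # changing only the noise seed: same spikes, same units, different traces
  expect_identical(trains(spikeTrains(r1)), trains(spikeTrains(r2)))
  expect_identical(simInfo(r1)$selected_indices, simInfo(r2)$selected_indices)
  expect_false(identical(recordings(r1), recordings(r2)))

  r3 <- mk(st_seed = 77)
  # changing only the spike-train seed: selection fixed, spikes differ
  expect_identical(simInfo(r1)$selected_indices, simInfo(r3)$selected_indices)
  expect_false(identical(trains(spikeTrains(r1)), trains(spikeTrains(r3))))

  r4 <- mk()
  expect_identical(recordings(r1), recordings(r4))  # full reproducibility
})

test_that("chunked and unchunked convolution give identical recordings", {
  lib <- smallLibrary()
  mk <- function(chunk) {
    assembleRecording(lib, selectionRules(2, 1),
                      rec_params = recordingParams(duration = 5, n_jitters = 3,
                                                   chunk_duration = chunk))
  }
  chunked <- mk(2)        # three chunks
  whole <- mk(10)         # single chunk covering the recording
  expect_identical(recordings(chunked), recordings(whole))
  expect_identical(spikeTraces(chunked), spikeTraces(whole))
})

test_that("voltage peaks store the signed trough of each unit's template", {
  lib <- smallLibrary()
  rec <- assembleRecording(lib, selectionRules(2, 1),
                           rec_params = recordingParams(duration = 1))
  sel <- simInfo(rec)$selected_indices
  for (u in seq_along(sel)) {
    ref <- apply(matrix(templates(lib)[sel[u], , ], nrow = 4), 1, min)
    expect_equal(voltagePeaks(rec)[u, ], ref)
    expect_true(all(voltagePeaks(rec)[u, ] <= 0))
  }
  expect_equal(timestamps(rec), seq(0, by = 1 / 32000, length.out = 32000))
})

test_that("drifting recordings play the templates back along the trajectory", {
  dlib <- smallDriftingLibrary()
  rec <- assembleRecording(
    dlib, selectionRules(1, 1, min_dist = 0),
    drift = driftParams("slow", velocity = 60),
    noise = noiseSpec(level = 0),
    rec_params = recordingParams(duration = 2, n_jitters = 1))
  d <- dim(templates(rec))
  expect_length(d, 5)           # neurons x steps x jitters x channels x points
  expect_equal(d[2], 10)
  expect_true(isTRUE(simInfo(rec)$drifting))
})
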