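# Shared fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

# small tetrode template library reused by recgen / io / acceptance tests
smallLibrary <- function() {
  if (is.null(.fixtures$lib)) {
    .fixtures$lib <- generateTemplates(defaultCellBank(0), buildProbe("tetrode"),
                                       n_per_model = 2, seed = 11)
  }
  .fixtures$lib
}

smallDriftingLibrary <- function() {
  if (is.null(.fixtures$dlib)) {
    .fixtures$dlib <- generateTemplates(
      defaultCellBank(0)[c(1, 2, 11)], buildProbe("tetrode"),
      n_per_model = 2, drifting = TRUE, n_drift_steps = 10, seed = 12)
  }
  .fixtures$dlib
}

# a two-channel toy probe written directly (valid YAML dialect)
writeToyProbeFile <- function(path) {
  writeLines(c(
    "name: toy-2",
    "positions:",
    "- [0.0, 0.0, 0.0]",
    "- [0.0, 0.0, 50.0]"
  ), path)
  path
}

# sample maximum template amplitudes for one model by repeated placement
sampleAmplitudes <- function(model, probe, n, params) {
  dt <- 1000 / params$fs
  cur <- simulateTransmembraneCurrents(model, dt, sum(params$cut_out) + 10,
                                       params$cut_out[1] + 1)
  vapply(seq_len(n), function(i) {
    pl <- placeCell(model, probe, params)
    eap <- computeEAP(pl$segments, cur, probe, params)
    max(apply(eap, 1, function(v) abs(min(v))))
  }, numeric(1))
}

skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
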