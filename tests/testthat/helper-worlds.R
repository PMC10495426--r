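# Shared fixtures: a tiny noise-free world (exact-recovery regime) and its
# pipeline run, built once per test session.

.fixtures <- new.env(parent = emptyenv())

tinyWorldConfig <- function(seed = 7, ...) {
  worldConfig(seed = seed, nRows = 12, nCols = 12, nCountries = 2,
              countiesPerCountry = 2, noiseSd = 0, ...)
}

getTinyWorld <- function() {
  if (is.null(.fixtures$world))
    .fixtures$world <- generateWorld(tinyWorldConfig())
  .fixtures$world
}

getTinyRun <- function() {
  if (is.null(.fixtures$run))
    .fixtures$run <- suppressWarnings(
      runPipeline(getTinyWorld(), list(useDefaultLogit = TRUE)))
  .fixtures$run
}

# independent brute-force greedy allocator for the no-till oracle test:
# plain loop, re-sorting and accumulating one cell at a time
bruteForceGreedy <- function(target, potential, probability) {
  contrib <- potential * probability
  remaining <- order(-probability, seq_along(probability))
  out <- numeric(length(potential))
  got <- 0
  for (idx in remaining) {
    if (got >= target) break
    take <- min(contrib[idx], target - got)
    out[idx] <- take
    got <- got + take
  }
  out
}
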