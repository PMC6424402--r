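# Shared fixtures and independent oracles for the test suite.

# Exhaustive O(n^2) nearest-neighbour oracle, deliberately written as a
# plain double loop, independent of the package implementation.
bruteNN <- function(xy) {
  n <- nrow(xy)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Observed-pole emulation: hex-grid patterns at the 64 nm mean spacing of
# the real motor/relic grids, 5-10 structures, clipped to pole ellipses
# with semi-axes in 150-300 nm. Used as templates for null-cohort
# calibration.
makeGridTemplates <- function(nPoles = 20, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    lapply(seq_len(nPoles), function(k) {
      ax <- stats::runif(2, 150, 300)
      n <- sample(5:10, 1)
      simulatePole(patternModel("grid", n, semiAxes = ax,
                                latticeSpacing = 64, jitterSD = 6),
                   poleId = sprintf("tmpl%d", k))
    })
  })
}

# Relative root-mean-square difference between two arrays.
relRMS <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
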