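test_that("uniform pole patterns are contained and centred", {
  p <- simulatePole(patternModel("uniform", 6, semiAxes = c(200, 150)),
                    seed = 1)
  expect_equal(length(p), 6)
  xy <- poleCoords(p)
  expect_true(all((xy[, 1] / 200)^2 + (xy[, 2] / 150)^2 <= 1))
  # law of large numbers: centroid of 1e4 points within 3 SE of centre
  big <- simulatePole(patternModel("uniform", 1e4, semiAxes = c(200, 150)),
                      seed = 2)
  xy <- poleCoords(big)
  se <- apply(xy, 2, sd) / sqrt(nrow(xy))
  expect_true(all(abs(colMeans(xy)) <= 3 * se))
})

test_that("generators are deterministic given parameters and seed", {
  for (kind in c("uniform", "hardcore", "grid", "cluster")) {
    m <- patternModel(kind, 7, jitterSD = 3)
    expect_equal(poleCoords(simulatePole(m, seed = 9)),
                 poleCoords(simulatePole(m, seed = 9)), info = kind)
  }
})

test_that("hard-core patterns respect the exclusion distance and report saturation", {
  for (s in 1:20) {
    p <- simulatePole(patternModel("hardcore", 8, semiAxes = c(200, 150),
                                   exclusionDiameter = 45), seed = s)
    expect_gte(min(nearestNeighborDistances(p)), 45)
  }
  expect_error(patternModel("hardcore", 40, semiAxes = c(150, 120),
                            exclusionDiameter = 45), "infeasible")
})

test_that("grid patterns sit on a jittered hexagonal lattice inside the ellipse", {
  p <- simulatePole(patternModel("grid", 12, semiAxes = c(280, 220),
                                 latticeSpacing = 64, jitterSD = 0),
                    seed = 4)
  xy <- poleCoords(p)
  expect_true(all((xy[, 1] / 280)^2 + (xy[, 2] / 220)^2 <= 1))
  # zero jitter: every inter-point distance is a lattice vector length;
  # the shortest is the lattice constant
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  expect_equal(min(d), 64, tolerance = 1e-9)
  pj <- simulatePole(patternModel("grid", 12, semiAxes = c(280, 220),
                                  latticeSpacing = 64, jitterSD = 5),
                     seed = 5)
  xyj <- poleCoords(pj)
  expect_true(all((xyj[, 1] / 280)^2 + (xyj[, 2] / 220)^2 <= 1))
})

test_that("uniform patterns pass a chi-square uniformity check in >= 95 of 100 seeds", {
  pass <- 0L
  for (s in 1:100) {
    p <- simulatePole(patternModel("uniform", 200, semiAxes = c(200, 150)),
                      seed = 1000 + s)
    xy <- poleCoords(p)
    # under uniformity on the ellipse, u = (x/a)^2 + (y/b)^2 is Uniform(0,1)
    u <- (xy[, 1] / 200)^2 + (xy[, 2] / 150)^2
    counts <- tabulate(pmin(floor(u * 10) + 1L, 10L), 10L)
    pval <- stats::chisq.test(counts)$p.value
    if (pval > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 95)
})

test_that("detached flagella carry hooks per break mode", {
  base <- simulateDetachedFlagella(100, "base_of_hook", seed = 1)
  expect_equal(sum(base$end1_hook) + sum(base$end2_hook), 100)
  expect_true(all(xor(base$end1_hook, base$end2_hook)))
  mid <- simulateDetachedFlagella(70, "midfilament", seed = 2)
  expect_equal(sum(mid$end1_hook) + sum(mid$end2_hook), 0)
  mixed <- simulateDetachedFlagella(
    60, rep(c("base_of_hook", "midfilament"), 30), seed = 3)
  expect_equal(sum(mixed$end1_hook) + sum(mixed$end2_hook), 30)
})

test_that("population simulator conserves flagella at zero rates", {
  m <- populationModel("polar_ejection", assemblyRate = 0, ejectionRate = 0)
  sim <- simulatePopulation(m, c(0, 1, 2, 3), nCells = 40, seed = 5)
  expect_true(all(apply(sim$counts, 1, function(r) all(r == r[1]))))
  expect_equal(sim$timepoints$mean_flagella,
               rep(sim$timepoints$mean_flagella[1], 4))
})

test_that("per-cell mean trajectory matches the birth-death closed form", {
  # independent oracle: dm/dt = a - e*m, so m(t) = m0 + a*t before the
  # trigger and a/e + (m(tT) - a/e) exp(-e (t - tT)) after it
  m <- populationModel("polar_ejection", assemblyRate = 0.5,
                       ejectionRate = 2, initialMeanFlagella = 5)
  tt <- c(0, 0.5, 1, 1.5, 2, 2.5, 3)
  sim <- simulatePopulation(m, tt, nCells = 400, seed = 8)
  tT <- sim$triggerTime
  pred <- vapply(tt, function(t) {
    if (t <= tT) 5 + 0.5 * t
    else {
      mT <- 5 + 0.5 * tT
      0.5 / 2 + (mT - 0.5 / 2) * exp(-2 * (t - tT))
    }
  }, 0)
  obs <- colMeans(sim$counts)
  se <- apply(sim$counts, 2, sd) / sqrt(nrow(sim$counts))
  expect_true(all(abs(obs - pred) <= 3 * se + 0.05))
})

test_that("polar ejection depletes absolute flagella after the trigger", {
  m <- populationModel("polar_ejection")
  tt <- seq(0, 3, by = 0.5)
  sim <- simulatePopulation(m, tt, nCells = 200, seed = 9)
  tp <- sim$timepoints
  post <- tp$t_h >= sim$triggerTime
  expect_gte(sum(post), 2)
  expect_lt(tp$absolute_flagella[which.max(tp$t_h)],
            tp$absolute_flagella[which(post)[1]])
})

test_that("peritrichous dilution halves counts without ejection", {
  m <- populationModel("peritrichous_dilution", assemblyRate = 0)
  sim <- simulatePopulation(m, c(0, 1, 2), nCells = 400, seed = 10)
  mu <- colMeans(sim$counts)
  # E[flagella] after Poisson(r t) halvings: m0 * exp(-r t / 2)
  pred <- 5 * exp(-m$growthRate * c(0, 1, 2) / 2)
  expect_true(all(abs(mu - pred) / pred < 0.25))
  expect_true(all(diff(mu) < 0))
})

test_that("population tables round-trip through TSV", {
  sim <- simulatePopulation(populationModel(), c(0, 1, 2), nCells = 20,
                            seed = 11)
  f <- tempfile(fileext = ".tsv")
  writePopulationTable(sim, f)
  back <- readPopulationTable(f)
  expect_equal(back$counts, sim$counts)
  expect_equal(back$timepoints$od600, sim$timepoints$od600,
               tolerance = 1e-6)
})

test_that("track simulator recovers configured speeds", {
  tr0 <- simulateTracks(3, speedMean = 25, speedSD = 0, duration = 2,
                        frameDt = 0.1, headingSD = 0, seed = 1)
  for (id in unique(tr0$track_id))
    expect_equal(unname(trackSpeed(tr0[tr0$track_id == id, ])["speed"]), 25)
  # heading noise bends the path but leaves frame steps intact
  trh <- simulateTracks(3, speedMean = 25, speedSD = 0, headingSD = 0.4,
                        duration = 2, frameDt = 0.1, seed = 2)
  for (id in unique(trh$track_id))
    expect_equal(unname(trackSpeed(trh[trh$track_id == id, ])["speed"]), 25)
  tr <- simulateTracks(1000, speedMean = 40, speedSD = 5, duration = 2,
                       frameDt = 0.2, seed = 3)
  s <- cohortSpeedSummary(tr)
  expect_lte(abs(s[["mean_speed"]] - 40), 3 * s[["se"]])
})

test_that("periplasm simulator reproduces configured spread", {
  zero <- simulatePeriplasmMeasurements(
    data.frame(klass = "motor", mean_nm = 20, range_nm = 0),
    nPerClass = 25, seed = 1)
  expect_equal(summarizeDistances(zero, "motor")$range, 0)
  big <- simulatePeriplasmMeasurements(nPerClass = 1e4, seed = 2)
  for (k in c("motor", "relic")) {
    cfg <- c(motor = 7.9, relic = 13.9)[[k]]
    sdHat <- sd(big$distance_nm[big$klass == k])
    expect_lte(abs(sdHat - cfg / sqrt(12)) / (cfg / sqrt(12)), 0.05)
  }
})

test_that("phantoms expose plug state and degenerate symmetry", {
  motor <- buildPhantom(phantomSpec(plug = FALSE))
  relic <- buildPhantom(phantomSpec(plug = TRUE))
  zMem <- round(attr(motor, "zMembrane"))
  ctr <- (dim(voxels(motor))[1] + 1) / 2
  axisMotor <- voxels(motor)[round(ctr), round(ctr), zMem]
  axisRelic <- voxels(relic)[round(ctr), round(ctr), zMem]
  expect_lt(axisMotor, 0.1)   # open aperture: solvent on the axis
  expect_gt(axisRelic, 1)     # plug density above membrane level
  smooth <- detectSymmetryOrder(buildPhantom(phantomSpec(nSubunits = 1)),
                                radiusRange = c(16, 28))
  expect_true(is.na(smooth))
  expect_true(attr(smooth, "noSymmetry"))
})

test_that("generated T-ring diameter matches the spec via the radial-profile oracle", {
  ph <- buildPhantom(phantomSpec(tRingDiameter = 44))
  vox <- voxels(ph)
  zR <- round(attr(ph, "zRing"))
  ctr <- (dim(vox)[1] + 1) / 2
  x <- (seq_len(dim(vox)[1]) - ctr)
  R <- sqrt(outer(x^2, x^2, "+"))
  prof <- tapply(as.numeric(vox[, , zR]), floor(as.numeric(R)), mean)
  peakR <- as.numeric(names(prof))[which.max(prof)] + 0.5
  expect_lte(abs(2 * peakR - 44), 1)
})
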