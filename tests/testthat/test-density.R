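test_that("C1 symmetrization is the identity and Cn conserves density", {
  ph <- buildPhantom(phantomSpec())
  expect_identical(voxels(rotationalSymmetrize(ph, 1)), voxels(ph))
  s13 <- rotationalSymmetrize(ph, 13)
  expect_equal(sum(voxels(s13)), sum(voxels(ph)), tolerance = 5e-3)
  expect_error(rotationalSymmetrize(ph, 0), "positive integer")
  aniso <- DensityMap(array(0, c(8, 8, 8)), voxelSize = c(1, 1, 2))
  expect_error(rotationalSymmetrize(aniso, 2), "cubic")
})

test_that("symmetrized maps are invariant under the symmetry and idempotent", {
  ph <- buildPhantom(phantomSpec(nSubunits = 13))
  s <- rotationalSymmetrize(ph, 13)
  rot <- flagrelics:::.rotateZ(voxels(s), 2 * pi / 13)
  # trilinear interpolation on voxel-scale features: a few percent RMS
  expect_lt(relRMS(rot, voxels(s)), 0.05)
  s2 <- rotationalSymmetrize(s, 13)
  expect_lt(relRMS(voxels(s2), voxels(s)), 0.05)
})

test_that("symmetry order detection recovers generator ground truth at SNR 2", {
  expect_equal(detectSymmetryOrder(
    buildPhantom(phantomSpec(nSubunits = 13), snr = 2, seed = 1),
    radiusRange = c(16, 28)), 13, ignore_attr = TRUE)
  expect_equal(detectSymmetryOrder(
    buildPhantom(phantomSpec(nSubunits = 6), snr = 2, seed = 2),
    radiusRange = c(16, 28)), 6, ignore_attr = TRUE)
  # sweep of orders with seeded noise replicates
  hits <- 0L; total <- 0L
  for (n in c(3, 5, 9, 14, 17)) {
    for (s in 1:4) {
      got <- detectSymmetryOrder(
        buildPhantom(phantomSpec(nSubunits = n), snr = 2, seed = 100 + s),
        radiusRange = c(16, 28), orders = 2:20)
      total <- total + 1L
      if (!is.na(got) && got == n) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
  expect_error(detectSymmetryOrder(
    DensityMap(array(0, c(24, 24, 24)), 1), c(5, 10)), "density")
})

test_that("FSC is 1 for identical maps, ~0 for independent noise, and symmetric", {
  ph <- buildPhantom(phantomSpec())
  cv <- fsc(ph, ph)
  expect_equal(cv$correlation, rep(1, nrow(cv)), tolerance = 1e-9)
  expect_true(all(cv$correlation >= -1 & cv$correlation <= 1))
  set.seed(91)
  n1 <- DensityMap(array(rnorm(32^3), c(32, 32, 32)), 1)
  n2 <- DensityMap(array(rnorm(32^3), c(32, 32, 32)), 1)
  cn <- fsc(n1, n2)
  expect_lt(max(abs(cn$correlation[cn$shell > 0])), 0.5)
  expect_lt(abs(mean(cn$correlation[cn$shell > 0])), 0.1)
  # symmetry in arguments and invariance to intensity scaling
  expect_equal(fsc(n2, n1)$correlation, cn$correlation)
  scaled <- DensityMap(3.7 * voxels(n2), 1)
  expect_equal(fsc(n1, scaled)$correlation, cn$correlation)
  small <- DensityMap(array(0, c(16, 16, 16)), 1)
  expect_error(fsc(n1, small), "dimensions")
})

test_that("threshold resolution matches the per-shell SNR closed form", {
  ph <- buildPhantom(phantomSpec())
  N <- dim(voxels(ph))[1]
  sg <- 0.5
  set.seed(93)
  A <- DensityMap(voxels(ph) + array(rnorm(N^3, 0, sg), rep(N, 3)), 1)
  B <- DensityMap(voxels(ph) + array(rnorm(N^3, 0, sg), rep(N, 3)), 1)
  res <- resolutionAt(fsc(A, B), 0.5)
  # analytic oracle: E[FSC] = P_s / (P_s + m_s N^3 sigma^2) per shell
  S <- fft(voxels(ph))
  fax <- c(0:(N / 2), -(N / 2 - 1):-1) / N
  sh <- round(sqrt(outer(outer(fax^2, fax^2, "+"), fax^2, "+")) * N)
  keep <- sh <= N / 2
  Ps <- tapply(Mod(S[keep])^2, sh[keep], sum)
  ms <- tapply(sh[keep], sh[keep], length)
  pred <- Ps / (Ps + ms * N^3 * sg^2)
  idx <- as.integer(names(pred))
  i <- which(pred < 0.5 & idx > 0)[1]
  fPred <- (idx[i - 1] + (pred[i - 1] - 0.5) / (pred[i - 1] - pred[i]) *
              (idx[i] - idx[i - 1])) / N
  expect_lte(abs(1 / res - fPred), 1 / N)  # within one shell
  # identical maps never cross the threshold
  expect_warning(flat <- resolutionAt(fsc(ph, ph)), "Nyquist")
  expect_true(is.na(flat))
})

test_that("composite merge stitches and reconstructs through masks", {
  ph <- buildPhantom(phantomSpec())
  d <- dim(voxels(ph))
  # identical inputs: any masks give back the input
  mt <- softZMask(d, zCenter = 30, softWidth = 6, side = "above")
  mb <- softZMask(d, zCenter = 30, softWidth = 6, side = "below")
  same <- compositeMerge(ph, ph, mt, mb)
  expect_equal(voxels(same), voxels(ph), tolerance = 1e-12)
  # complementary binary masks stitch exactly
  top <- DensityMap(array(2, d), 1)
  bottom <- DensityMap(array(5, d), 1)
  hb <- softZMask(d, zCenter = 28.5, softWidth = 0, side = "below")
  ht <- softZMask(d, zCenter = 28.5, softWidth = 0, side = "above")
  st <- compositeMerge(top, bottom, ht, hb)
  expect_true(all(voxels(st)[, , 1:28] == 5))
  expect_true(all(voxels(st)[, , 29:d[3]] == 2))
  # overlapping-soft-half round trip recovers the phantom
  rec <- compositeMerge(ph, ph, softZMask(d, 28.5, 8, "above"),
                        softZMask(d, 28.5, 8, "below"))
  expect_lt(relRMS(voxels(rec), voxels(ph)), 1e-10)
  # zero-weight voxels are flagged and set to solvent
  gap <- compositeMerge(top, bottom,
                        softZMask(d, 20, 0, "above") * 0,
                        softZMask(d, 20, 0, "below") * 0,
                        solvent = -1)
  expect_true(all(voxels(gap) == -1))
  expect_equal(attr(gap, "flaggedVoxels"), prod(d))
})

test_that("ring morphometry recovers printed geometry within one voxel", {
  got <- measureRing(buildPhantom(phantomSpec()))
  expect_lte(abs(got$ringDiameter - 44), 1)
  expect_lte(abs(got$axialOffset - 19), 1)
  expect_lte(abs(got$apertureDiameter - 15), 1)
  expect_false(got$occluded)
  # same nm geometry at twice the voxel size: identical nm answers
  coarse <- measureRing(buildPhantom(phantomSpec(voxelSize = 2,
                                                 boxSize = 28)))
  expect_lte(abs(coarse$ringDiameter - 44), 2)
  expect_lte(abs(coarse$axialOffset - 19), 2)
  expect_lte(abs(coarse$apertureDiameter - 15), 2)
  # plugged relic: aperture reported occluded
  relic <- measureRing(buildPhantom(phantomSpec(plug = TRUE)))
  expect_true(relic$occluded)
  expect_true(is.na(relic$apertureDiameter))
  expect_error(buildPhantom(phantomSpec(tRingDiameter = 80,
                                        boxSize = 40)), "box")
})
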