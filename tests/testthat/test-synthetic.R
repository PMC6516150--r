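test_that("vesselModel derives a 3 mmHg-consistent sigmaOrig or wallCsa", {
  vm <- vesselModel(D00 = 200, beta = 5, wallCsa = 1.8e4)
  wt0 <- wallThicknessAt(200, 1.8e4)
  expect_equal(vm@sigmaOrig, 3 * 133.4e3 * 200 / (2 * wt0))
  ## inverse parameterisation reproduces the same geometry
  vm2 <- vesselModel(D00 = 200, beta = 5, sigmaOrig = vm@sigmaOrig)
  expect_equal(vm2@wallCsa, 1.8e4, tolerance = 1e-10)
  ## inconsistent pair is rejected by validity
  expect_error(new("VesselModel", D00 = 200, wallCsa = 1.8e4, beta = 5,
                   sigmaOrig = 1e5, noiseSd = 0, seed = 1L),
               "inconsistent")
})

test_that("noiseless pressure series round-trips beta and sigmaOrig exactly", {
  for (b in c(3, 5, 8)) {
    ps <- makePressureSeries(refVessel(beta = b))
    mech <- passiveMechanics(ps)
    expect_lt(abs(stiffnessBeta(mech) - b) / b, 1e-3)
    expect_lt(abs(sigmaOrig(mech) - refVessel(beta = b)@sigmaOrig) /
                refVessel(beta = b)@sigmaOrig, 1e-3)
  }
})

test_that("generated diameters are monotone in pressure and in beta", {
  ps3 <- makePressureSeries(refVessel(beta = 3))
  ps8 <- makePressureSeries(refVessel(beta = 8))
  expect_true(all(diff(innerDiameter(ps3)) >= 0))
  expect_true(all(diff(innerDiameter(ps8)) >= 0))
  ## stiffer wall distends less at 120 mmHg
  expect_lt(innerDiameter(ps8)[7], innerDiameter(ps3)[7])
})

test_that("generators are deterministic under a fixed seed", {
  a <- makePressureSeries(refVessel(noiseSd = 1, seed = 42L))
  b <- makePressureSeries(refVessel(noiseSd = 1, seed = 42L))
  expect_identical(innerDiameter(a), innerDiameter(b))
  w1 <- makeWireCurve(0.01, 800, noiseSd = 0.05, seed = 7L)
  w2 <- makeWireCurve(0.01, 800, noiseSd = 0.05, seed = 7L)
  expect_identical(w1@tension, w2@tension)
  f1 <- makeFiberImage(fiberSpec(5, 60, seed = 3L))
  f2 <- makeFiberImage(fiberSpec(5, 60, seed = 3L))
  expect_identical(f1$image, f2$image)
  ## and emitted files are byte-identical
  d <- withr::local_tempdir()
  writeGrayTiff(f1$image, file.path(d, "a.tif"))
  writeGrayTiff(f2$image, file.path(d, "b.tif"))
  expect_identical(readBin(file.path(d, "a.tif"), "raw", 1e6),
                   readBin(file.path(d, "b.tif"), "raw", 1e6))
})

test_that("generators leave the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(makePressureSeries(refVessel(noiseSd = 1, seed = 9L)))
  invisible(makeFiberImage(fiberSpec(5, 60, seed = 9L)))
  expect_identical(.Random.seed, before)
})

test_that("wire generator round-trips and scales linearly", {
  cv <- makeWireCurve(0.01, 800, noiseSd = 0)
  fit <- fitDiameterTension(cv)
  expect_equal(fit@slope, 0.01, tolerance = 1e-12)
  expect_equal(fit@y0Diameter, 800, tolerance = 1e-9)
  cv2 <- makeWireCurve(0.02, 800, noiseSd = 0)
  expect_equal(fitDiameterTension(cv2)@slope, 2 * fit@slope,
               tolerance = 1e-12)
})

test_that("area waveform has the stated true ascending slope", {
  cv <- makeAreaWaveform(aDia = 1.0, aSys = 1.2, riseMs = 20,
                         noiseSd = 0)
  expect_equal(ascendingSlope(cv), 0.01, tolerance = 1e-12)
  flat <- makeAreaWaveform(aDia = 1.0, aSys = 1.0, noiseSd = 0)
  expect_equal(ascendingSlope(flat), 0, tolerance = 1e-12)
})

test_that("fiber ground truth matches quadrature and is monotone in amplitude", {
  ## amplitude 0 -> exactly 1
  f0 <- makeFiberImage(fiberSpec(0, 60, seed = 1L))
  expect_identical(f0$rectilinearity, 1)
  ## a = lambda/(2 pi): slope amplitude 1; oracle by independent quadrature
  lam <- 64
  fi <- makeFiberImage(fiberSpec(lam / (2 * pi), lam, seed = 1L))
  expect_equal(fi$rectilinearity, sineRectOracle(lam / (2 * pi), lam),
               tolerance = 2e-3)
  ## strictly decreasing in amplitude at fixed wavelength/phase
  gts <- vapply(c(2, 4, 6, 8, 10),
                function(a) makeFiberImage(
                  fiberSpec(a, 60, seed = 5L))$rectilinearity, 0)
  expect_true(all(diff(gts) < 0))
})

test_that("fibers that do not fit with margin are rejected", {
  expect_error(makeFiberImage(fiberSpec(100, 60,
                                        imageShape = c(64L, 64L))),
               "margin")
})
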