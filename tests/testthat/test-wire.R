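test_that("force converts to wall tension over two wall strips", {
  expect_equal(tensionFromForce(4, 2), 1)
  expect_equal(tensionFromForce(0, 2), 0)
  expect_equal(tensionFromForce(8, 2), 2 * tensionFromForce(4, 2))
  expect_error(tensionFromForce(1, 0), "positive")
})

test_that("diameter-tension OLS recovers exact lines and flags flat ones", {
  d <- seq(820, 1000, by = 20)
  cv <- new("WireMyoCurve", segmentId = "s", segmentLength = 2,
            diameter = d, tension = 0.01 * (d - 800))
  fit <- fitDiameterTension(cv)
  expect_equal(fit@slope, 0.01, tolerance = 1e-12)
  expect_equal(fit@y0Diameter, 800, tolerance = 1e-9)
  expect_equal(fit@r2, 1)
  ## constant tension: slope 0, undefined y0
  cvc <- new("WireMyoCurve", segmentId = "s", segmentLength = 2,
             diameter = d, tension = rep(1, length(d)))
  fitc <- fitDiameterTension(cvc)
  expect_false(fitc@defined)
  expect_true(is.na(fitc@y0Diameter))
})

test_that("OLS minimises the residual sum of squares", {
  for (seed in 1:5) {
    cv <- makeWireCurve(0.012, 750, noiseSd = 0.1, seed = seed)
    fit <- fitDiameterTension(cv)
    rss <- function(s, b) sum((cv@tension - s * cv@diameter - b)^2)
    base <- rss(fit@slope, fit@intercept)
    expect_gt(rss(fit@slope * 1.01, fit@intercept), base)
    expect_gt(rss(fit@slope * 0.99, fit@intercept), base)
  }
})

test_that("d100 follows the Laplace isobar", {
  ## flat recording at T = 0.3333 mN/mm crosses the 100 mmHg isobar at
  ## 50 um: 13332.2 Pa * 25e-6 m = 0.33331 N/m
  flat <- new("WireMyoFit", slope = 0, intercept = 0.33331,
              y0Diameter = NA_real_, d100 = NA_real_, r2 = 1,
              defined = FALSE)
  d <- estimateD100(flat, 100)@d100
  expect_equal(d, 50, tolerance = 1e-3)
  ## a line parallel to the isobar has no intersection
  k <- 100 * 133.322e-6 / 2
  par <- new("WireMyoFit", slope = k, intercept = 0.1,
             y0Diameter = NA_real_, d100 = NA_real_, r2 = 1,
             defined = TRUE)
  expect_error(estimateD100(par, 100), "parallel")
  ## negative intersection is rejected
  neg <- new("WireMyoFit", slope = k * 2, intercept = 0.1,
             y0Diameter = NA_real_, d100 = NA_real_, r2 = 1,
             defined = TRUE)
  expect_error(estimateD100(neg, 100), "not positive")
})

test_that("d100 from synthetic tension pairs matches the generator root", {
  for (b in c(3, 5, 8)) {
    vm <- refVessel(beta = b)
    ps <- makePressureSeries(vm, pressureSteps = c(3, seq(60, 120, 10)))
    fit <- analyzeWireCurve(tensionPairsFromPressure(ps))
    dTrue <- vasomech:::.solveDi(100, vm@D00, vm@wallCsa, vm@beta,
                                 vm@sigmaOrig)
    expect_lt(abs(fit@d100 - dTrue) / dTrue, 0.01)
  }
})

test_that("wire round trip at zero noise recovers slope, y0 and d100", {
  vm <- refVessel()
  ps <- makePressureSeries(vm, pressureSteps = c(3, seq(60, 120, 10)))
  cv <- tensionPairsFromPressure(ps)
  fit <- analyzeWireCurve(cv)
  fit2 <- analyzeWireCurve(cv)     # idempotent
  expect_identical(fit@slope, fit2@slope)
  expect_identical(fit@d100, fit2@d100)
  ## exact linear generator: everything to <= 0.1%
  cvl <- makeWireCurve(0.011, 820, noiseSd = 0)
  fl <- analyzeWireCurve(cvl)
  expect_lt(abs(fl@slope - 0.011) / 0.011, 1e-3)
  expect_lt(abs(fl@y0Diameter - 820) / 820, 1e-3)
})

test_that("noisy wire slopes are unbiased over many seeds", {
  slopes <- vapply(1:100, function(s)
    fitDiameterTension(makeWireCurve(0.01, 800, noiseSd = 0.05,
                                     seed = s))@slope, 0)
  expect_lt(abs(mean(slopes) - 0.01) / 0.01, 0.02)
})

test_that("channel discalibration QC uses a strict 5-unit threshold", {
  expect_true(qcKeepChannel(4))
  expect_false(qcKeepChannel(6))
  expect_true(qcKeepChannel(5))
  expect_error(qcKeepChannel(-1), "non-negative")
})
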