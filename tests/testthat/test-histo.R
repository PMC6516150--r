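test_that("trichrome fractions classify hue bands inside the media", {
  media <- matrix(1L, 64, 64)
  green <- solidRGB(120)
  expect_equal(trichromeFractions(green, media)$pctCollagen, 100)
  expect_equal(trichromeFractions(green, media)$pctMuscle, 0)
  ## half green / half red
  half <- solidRGB(120)
  redcol <- grDevices::col2rgb(grDevices::hsv(0, 1, 1)) / 255
  for (ch in 1:3) half[33:64, , ch] <- redcol[ch]
  fr <- trichromeFractions(half, media)
  expect_equal(fr$pctCollagen, 50)
  expect_equal(fr$pctMuscle, 50)
  expect_error(trichromeFractions(green, matrix(0L, 64, 64)), "empty")
})

test_that("generated two-class stains are recovered within tolerance", {
  st <- makeStainImage(0.30, hueA = 120, hueB = 0, hueJitterDeg = 5,
                       dim = c(128L, 128L), seed = 2L)
  fr <- trichromeFractions(st$rgb, st$mask)
  expect_lt(abs(fr$pctCollagen - 30), 2)
  expect_lt(abs(fr$pctMuscle - 70), 2)
  ## area fractions are invariant to integer upscaling
  up <- array(0, c(256, 256, 3))
  for (ch in 1:3) up[, , ch] <- st$rgb[rep(1:128, each = 2),
                                       rep(1:128, each = 2), ch]
  frUp <- trichromeFractions(up, matrix(1L, 256, 256))
  expect_lt(abs(frUp$pctCollagen - fr$pctCollagen), 1)
})

test_that("media morphometry matches analytic circles and annuli", {
  lumen <- diskMask(100)
  m <- mediaMorphometry(lumen, diskMask(120) - lumen)
  expect_equal(m$lumenPerimeterUm, 2 * pi * 100, tolerance = 0.01)
  expect_equal(m$mediaThicknessUm, 20, tolerance = 0.05)
  ## ellipse perimeter vs Ramanujan approximation
  xg <- matrix(seq_len(256), 256, 256)
  yg <- matrix(seq_len(256), 256, 256, byrow = TRUE)
  a <- 100; b <- 60
  ell <- matrix(as.integer(((xg - 128) / a)^2 + ((yg - 128) / b)^2 <= 1),
                256, 256)
  h <- ((a - b) / (a + b))^2
  ram <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  m2 <- mediaMorphometry(ell, diskMask(120) - ell)
  expect_equal(m2$lumenPerimeterUm, ram, tolerance = 0.01)
  ## two lumen components are rejected
  two <- diskMask(20, c0 = c(60, 60)) + diskMask(20, c0 = c(180, 180))
  expect_error(mediaMorphometry(two, diskMask(120)), "components")
})

test_that("picrosirius classes split birefringent pixels by hue", {
  adv <- matrix(1L, 64, 64)
  orange <- solidRGB(40)
  po <- picrosiriusClasses(orange, adv)
  expect_equal(po$pctOrange, 100)
  expect_equal(po$pctGreen, 0)
  ## black image: nothing birefringent
  black <- array(0, c(64, 64, 3))
  pb <- picrosiriusClasses(black, adv)
  expect_equal(pb$birefringentAreaUm2, 0)
  ## 70/30 mixed synthetic with hue jitter
  st <- makeStainImage(0.70, hueA = 40, hueB = 120, hueJitterDeg = 5,
                       dim = c(128L, 128L), seed = 4L)
  pm <- picrosiriusClasses(st$rgb, st$mask)
  expect_lt(abs(pm$pctOrange - 70), 3)
  expect_lt(abs(pm$pctGreen - 30), 3)
})

test_that("maximum-entropy threshold equals the exhaustive maximizer", {
  ## two-delta histogram: threshold strictly between the modes,
  ## integrated density = 200 * n_bright
  v <- c(rep(10, 90), rep(200, 10))
  th <- maxEntropyThreshold(v)
  expect_gt(th, 10); expect_lt(th, 200)
  img <- matrix(v, 10, 10)
  expect_equal(ifIntensity(img, matrix(1L, 10, 10), "maxentropy"),
               200 * 10)
  ## oracle equivalence on random 8-bit histograms: with values 0..255
  ## and 256 bins the package binning maps value v to bin v+1, so the
  ## package cutpoint and the naive exhaustive maximizer must coincide
  set.seed(99)
  for (i in 1:25) {
    counts <- rpois(256, exp(runif(256, 0, 4)))
    counts[1] <- counts[1] + 1L; counts[256] <- counts[256] + 1L
    vals <- rep(0:255, counts)
    thPkg <- maxEntropyThreshold(vals, nBins = 256L)
    tPkg <- round(thPkg * 256 / 255)
    expect_equal(tPkg, maxentBrute(counts))
  }
  expect_error(maxEntropyThreshold(rep(5, 10)), "single-valued")
})

test_that("control-median normalisation maps the control median to 1", {
  vals <- c(2, 4, 6, 8, 1, 9)
  grp <- c("ctl", "ctl", "ctl", "mut", "mut", "mut")
  nv <- normalizeToControlMedian(vals, grp, "ctl")
  expect_equal(median(nv[grp == "ctl"]), 1)
  ## uniform image over ROI, control median 100 -> 1.0
  img <- matrix(100, 8, 8)
  v <- ifIntensity(img, matrix(1L, 8, 8), "mean")
  expect_equal(normalizeToControlMedian(v, "ctl", "ctl"), 1)
})

test_that("SHG texture moments match analytic distributions", {
  ## symmetric two-point distribution: skewness 0
  img <- matrix(c(0, 2), 10, 10)
  tex <- shgTexture(img, threshold = 1)
  expect_equal(tex$skewness, 0)
  expect_equal(tex$signalAreaUm2, 50)
  expect_equal(tex$density, 2)
  ## exponential intensities: skewness 2, Pearson kurtosis 9
  x <- withr::with_seed(7, rexp(1e6))
  texE <- shgTexture(matrix(x, 1000, 1000), threshold = 0)
  expect_equal(texE$skewness, 2, tolerance = 0.025)
  expect_equal(texE$kurtosis, 9, tolerance = 0.05)
  ## excess-kurtosis flag
  expect_equal(shgTexture(img, threshold = 1, excess = TRUE)$kurtosis,
               shgTexture(img, threshold = 1)$kurtosis - 3)
  expect_error(shgTexture(matrix(1, 5, 5)), "variance")
})

test_that("nuclei counting finds planted disks", {
  ni <- makeNucleiImage(7, dim = c(128L, 128L), radius = 4, seed = 5L)
  expect_equal(countNuclei(ni$image), 7L)
  expect_equal(countNuclei(matrix(0, 64, 64)), 0L)
  ## touching pair: merged without watershed, split with it
  img <- matrix(0, 64, 64)
  img[(row(img) - 28)^2 + (col(img) - 32)^2 <= 25] <- 1
  img[(row(img) - 37)^2 + (col(img) - 32)^2 <= 25] <- 1
  expect_equal(countNuclei(img), 1L)
  expect_equal(countNuclei(img, watershed = TRUE), 2L)
})
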