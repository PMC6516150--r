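test_that("preprocessing flattens background and removes impulse noise", {
  ## constant image -> all zero after background subtraction
  cst <- matrix(0.5, 80, 80)
  expect_true(all(preprocessFibers(cst, 1, 10) == 0))
  ## a single hot pixel vanishes under median radius 1
  hot <- matrix(0, 80, 80); hot[40, 40] <- 1
  expect_equal(max(preprocessFibers(hot, 1, 10)), 0)
  ## bright fiber on a smooth gradient: residual background < 5% of
  ## the fiber amplitude
  grad <- matrix(rep(seq(0, 0.4, length.out = 120), each = 120), 120, 120)
  fib <- rasterizePolyline(cbind(seq(10, 110), 60), c(120L, 120L), 3)
  img <- grad + fib
  out <- preprocessFibers(img, 1, 10)
  bgResidual <- max(out[fib == 0 & row(out) > 20 & row(out) < 100])
  expect_lt(bgResidual, 0.05 * 1)
  expect_error(preprocessFibers(cst, 1, 100), "smaller than the image")
  expect_error(preprocessFibers(cst, 0.5, 10), ">= 1")
})

test_that("segmentation thresholds inside the ROI", {
  img <- matrix(0, 60, 60); img[20:40, 20:40] <- 1
  m <- segmentFibers(img, method = "otsu")
  expect_identical(which(m == 1L), which(img == 1))
  ## fixed threshold above the maximum -> empty-mask error
  expect_error(segmentFibers(img, method = 2), "empty mask")
  ## ROI restriction (0-based half-open)
  m2 <- segmentFibers(img, roi = c(0, 0, 30, 60), method = 0.5)
  expect_true(all(which(m2 == 1L, arr.ind = TRUE)[, 1] <= 30))
  expect_error(segmentFibers(img, roi = c(0, 0, 100, 60)), "roi")
})

test_that("skeletonization thins ribbons to centre lines and prunes", {
  ## 5 x 100 ribbon -> a ~1 px horizontal line of close to 100 px
  rib <- matrix(0L, 120, 40); rib[11:110, 18:22] <- 1L
  sk <- skeletonizeFibers(rib, minComponentPx = 20)
  expect_true(all(sk[rib == 0L] == 0L))            # skeleton within mask
  expect_gte(sum(sk), 90); expect_lte(sum(sk), 110)
  ## the skeleton is a single 1-px path: no pixel has > 2 neighbors
  expect_true(all(vasomech:::neighborCount(sk)[sk == 1L] <= 2L))
  ## small components below the cutoff are removed
  two <- matrix(0L, 120, 60)
  two[11:110, 15:19] <- 1L                          # 500 px
  two[11:15, 50:51] <- 1L                           # 10 px
  sk2 <- skeletonizeFibers(two, minComponentPx = 50)
  expect_true(all(which(sk2 == 1L, arr.ind = TRUE)[, 2] < 30))
  expect_warning(skeletonizeFibers(matrix(0L, 20, 20), 10), "empty")
})

test_that("branch measurement follows the skeleton-length conventions", {
  ## horizontal 100 px line: length = distance = 99 px
  hl <- matrix(0L, 120, 20); hl[11:110, 10] <- 1L
  br <- fiberBranches(hl, pixelSize = 1)
  expect_equal(nrow(br), 1L)
  expect_equal(br$lengthUm, 99)
  expect_equal(br$distanceUm, 99)
  ## 45-degree diagonal of 100 px: chain-code length 99*sqrt(2)
  dg <- matrix(0L, 120, 120); dg[cbind(11:110, 11:110)] <- 1L
  brd <- fiberBranches(dg, lengthMethod = "steps")
  expect_equal(brd$lengthUm, 99 * sqrt(2))
  expect_equal(fiberBranches(dg)$lengthUm, 99 * sqrt(2))  # straight: same
  ## L-shaped path 50 + 50 px: step length 98, chord 50*sqrt(2) scale
  el <- matrix(0L, 80, 80)
  el[cbind(11:60, rep(10, 50))] <- 1L
  el[cbind(rep(60, 50), 10:59)] <- 1L
  brl <- fiberBranches(el, lengthMethod = "steps")
  expect_equal(brl$lengthUm, 98)
  expect_equal(brl$distanceUm, 49 * sqrt(2))
  brp <- fiberBranches(el)                 # polygon cuts the corner a bit
  expect_gt(brp$lengthUm, 96); expect_lte(brp$lengthUm, 98)
  ## a closed loop is flagged cyclic with a max-pairwise chord
  th <- seq(0, 2 * pi, length.out = 720)
  ring <- rasterizePolyline(cbind(40 + 15 * cos(th), 40 + 15 * sin(th)),
                            c(80L, 80L), 1)
  sk <- skeletonize(ring)
  brc <- fiberBranches(sk)
  expect_true(any(brc$cyclic))
  expect_equal(brc$distanceUm[brc$cyclic][1], 30, tolerance = 0.1)
})

test_that("rectilinearity oracles: straight, half-circle, sinusoid", {
  ## straight fiber: exactly 1
  straight <- sineImage(0, 60)
  expect_identical(measureRect(straight), 1)
  ## half-circle: chord/arc = 2/pi within 2%
  expect_equal(measureRect(halfCircleImage()), 2 / pi, tolerance = 0.02)
  ## sinusoid a = lambda/(2 pi): quadrature oracle, within 2%
  lam <- 64; a <- lam / (2 * pi)
  expect_equal(measureRect(sineImage(a, lam)), sineRectOracle(a, lam),
               tolerance = 0.02)
})

test_that("rectilinearity is invariant to fiber thickness and pose", {
  lam <- 64; a <- lam / (2 * pi)
  r3 <- measureRect(sineImage(a, lam, thickness = 3))
  r9 <- measureRect(sineImage(a, lam, thickness = 9))
  expect_lt(abs(r3 - r9) / r3, 0.02)
  ## rotation/translation: same sinusoid at 30 degrees
  x <- seq(0, 256, by = 0.25)
  y <- a * sin(2 * pi * x / lam)
  ang <- pi / 6
  pts <- cbind(20 + x * cos(ang) - y * sin(ang),
               30 + x * sin(ang) + y * cos(ang))
  rot <- rasterizePolyline(pts, c(280L, 200L), 3)
  expect_lt(abs(measureRect(rot) - r3) / r3, 0.02)
})

test_that("measured rectilinearity decreases monotonically with amplitude", {
  rs <- vapply(c(2, 4, 6, 8, 10, 12),
               function(a) measureRect(sineImage(a, 64)), 0)
  expect_identical(cor(rs, seq_along(rs), method = "spearman"), -1)
})

test_that("segmentation of noisy synthetic fibers overlaps ground truth", {
  fi <- makeFiberImage(fiberSpec(6, 60, nFibers = 4L, snr = 5,
                                 imageShape = c(220L, 150L), seed = 3L))
  pp <- preprocessFibers(fi$image, 1, 20)
  mask <- segmentFibers(pp, method = "otsu")
  dice <- 2 * sum(mask & fi$mask) / (sum(mask) + sum(fi$mask))
  expect_gte(dice, 0.8)
})

test_that("full-toolbox recovery tracks the generated ground truth", {
  for (a in c(3, 8)) {
    fi <- makeFiberImage(fiberSpec(a, 60, nFibers = 4L, snr = 5,
                                   imageShape = c(220L, 150L),
                                   seed = 11L))
    res <- analyzeRectilinearity(fi$image, ballRadiusPx = 20,
                                 medianRadiusPx = 1,
                                 minComponentPx = 40)
    expect_lt(abs(rectilinearity(res) - fi$rectilinearity), 0.03)
  }
})
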