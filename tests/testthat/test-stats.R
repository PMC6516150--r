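test_that("Grubbs statistic and critical value follow the t-based formula", {
  x <- c(1, 1.1, 0.9, 1.05, 8)
  g <- grubbsExclude(x)
  expect_identical(g$excluded, 5L)
  ## oracle: hand-computed G and critical value
  G <- max(abs(x - mean(x))) / sd(x)
  t <- qt(1 - 0.05 / (2 * 5), df = 3)
  Gc <- (4 / sqrt(5)) * sqrt(t^2 / (3 + t^2))
  expect_gt(G, Gc)
  expect_equal(g$G[1], G)
  expect_equal(grubbsCritical(5), Gc)
})

test_that("Grubbs keeps tight and degenerate samples", {
  ## {1,2,3}: G = 1 < G_c(3, 0.05), nothing excluded
  g <- grubbsExclude(c(1, 2, 3))
  expect_length(g$excluded, 0)
  expect_equal(max(abs(c(1, 2, 3) - 2)) / sd(c(1, 2, 3)), 1)
  expect_gt(grubbsCritical(3), 1)
  ## constant sample: warning, nothing excluded
  expect_warning(gc <- grubbsExclude(rep(2, 6)), "zero variance")
  expect_length(gc$excluded, 0)
  expect_error(grubbsExclude(c(1, 2)), "n >= 3")
})

test_that("Grubbs removals are capped at floor(n/5)", {
  x <- c(rnorm(20), 50, 60, 70, 80, 90, 100)
  g <- grubbsExclude(x)
  expect_lte(length(g$excluded), floor(length(x) / 5))
})

test_that("Sidak adjustment is monotone and exact for k = 1", {
  p <- c(0.01, 0.05, 0.2)
  expect_equal(sidakAdjust(p, 1), p)
  expect_true(all(sidakAdjust(p, 3) >= p))
  k <- 1:10
  adj <- vapply(k, function(kk) sidakAdjust(0.05, kk), 0)
  expect_true(all(diff(adj) > 0))
  expect_equal(sidakAdjust(0.05, 3), 1 - (1 - 0.05)^3)
})

test_that("group comparisons handle identical and shifted groups", {
  tab <- data.frame(value = rep(c(1, 2, 3, 4), 2),
                    group = rep(c("a", "b"), each = 4))
  expect_equal(compareGroups(tab, "t")$p, 1)
  expect_equal(compareGroups(tab, "welch-t")$p, 1)
  ## clear shift is detected
  tab2 <- data.frame(value = c(rnorm(10, 0, 0.1), rnorm(10, 3, 0.1)),
                     group = rep(c("a", "b"), each = 10))
  expect_lt(compareGroups(tab2, "t")$p, 1e-6)
  expect_lt(compareGroups(tab2, "mann-whitney")$p, 0.001)
  expect_error(compareGroups(data.frame(value = 1:3,
                                        group = c("a", "a", "b")), "t"),
               "at least 2")
})

test_that("one-way ANOVA with Sidak produces adjusted pairwise p-values", {
  set.seed(1)
  tab <- data.frame(value = c(rnorm(6), rnorm(6, 4), rnorm(6)),
                    group = rep(c("a", "b", "c"), each = 6))
  res <- compareGroups(tab, "anova1+sidak")
  expect_lt(res$p, 0.001)
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$pSidak >= res$pairwise$p))
})

test_that("two-way ANOVA compares diameter-pressure curves", {
  set.seed(2)
  p <- rep(c(20, 60, 100), times = 8)
  grp <- rep(c("a", "b"), each = 12)
  val <- 100 + p * 0.5 + ifelse(grp == "b", -15, 0) + rnorm(24, 0, 2)
  tab <- data.frame(value = val, group = grp, x = p)
  res <- compareGroups(tab, "anova2+sidak")
  expect_lt(res$p, 1e-4)
  expect_equal(nrow(res$pairwise), 3L)
})

test_that("planted mean shifts are detected with high power", {
  set.seed(3)
  hits <- vapply(1:200, function(i) {
    tab <- data.frame(value = c(rnorm(10), rnorm(10, 3)),
                      group = rep(c("a", "b"), each = 10))
    compareGroups(tab, "t")$p < 0.05
  }, NA)
  expect_gt(mean(hits), 0.95)
})

test_that("slope comparison works on per-animal fits and via ANCOVA", {
  mkFits <- function(slopes) lapply(slopes, function(s)
    fitDiameterTension(makeWireCurve(s, 800, noiseSd = 0.02,
                                     seed = round(s * 1e4))))
  a <- mkFits(c(0.010, 0.011, 0.0105, 0.0095))
  b <- mkFits(c(0.020, 0.021, 0.0205, 0.0195))
  res <- compareSlopes(a, b)
  expect_lt(res$p, 0.001)
  ## identical slope sets: p = 1
  same <- compareSlopes(a, a)
  expect_equal(same$p, 1)
  expect_error(compareSlopes(a[1], b), "at least 2")
  ## ANCOVA route detects the interaction
  cvA <- lapply(1:4, function(i) makeWireCurve(0.010, 800,
                                               noiseSd = 0.05, seed = i))
  cvB <- lapply(1:4, function(i) makeWireCurve(0.020, 800,
                                               noiseSd = 0.05,
                                               seed = 100 + i))
  anc <- compareSlopes(a, b, method = "ancova", curvesA = cvA,
                       curvesB = cvB)
  expect_lt(anc$p, 1e-6)
})

test_that("slope-comparison type-I error is near nominal under the null", {
  set.seed(4)
  mkFit <- function(s) new("WireMyoFit", slope = s, intercept = 0,
                           y0Diameter = 0, d100 = NA_real_, r2 = 1,
                           defined = TRUE)
  rejections <- vapply(1:2000, function(i) {
    a <- lapply(rnorm(6, 0.01, 0.001), mkFit)
    b <- lapply(rnorm(6, 0.01, 0.001), mkFit)
    compareSlopes(a, b)$p < 0.05
  }, NA)
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})
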