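# Shared fixture builders. All fixtures are generated in code; nothing
# is read from disk except files the tests themselves write.

# rectilinearity of a clean binary curve image, skipping preprocessing
measureRect <- function(img, minComponentPx = 20, lengthMethod = "polygon") {
  rectilinearity(analyzeRectilinearity(
    img, method = 0.5, preprocess = FALSE,
    minComponentPx = minComponentPx, lengthMethod = lengthMethod))
}

# binary image of a sinusoidal fiber y = a sin(2 pi x / lambda)
sineImage <- function(a, lambda, dim = c(300L, 110L), thickness = 3,
                      x0 = 20, x1 = dim[1] - 21, yc = dim[2] / 2) {
  x <- seq(x0, x1, by = 0.25)
  rasterizePolyline(cbind(x, yc + a * sin(2 * pi * (x - x0) / lambda)),
                    dim, thickness)
}

# analytic chord/arc ratio of the same sinusoid (quadrature oracle,
# independent of the generator)
sineRectOracle <- function(a, lambda) {
  k <- 2 * pi / lambda
  arc <- stats::integrate(function(x) sqrt(1 + (a * k * cos(k * x))^2),
                          0, lambda, rel.tol = 1e-10)$value
  lambda / arc
}

# binary image of a half-circle arc
halfCircleImage <- function(r = 60, dim = c(300L, 110L), thickness = 3) {
  th <- seq(0, pi, length.out = 50 * r)
  rasterizePolyline(cbind(dim[1] / 2 + r * cos(th), 20 + r * sin(th)),
                    dim, thickness)
}

# filled disk mask
diskMask <- function(r, dim = c(256L, 256L),
                     c0 = c(dim[1] / 2, dim[2] / 2)) {
  xg <- matrix(seq_len(dim[1]), dim[1], dim[2])
  yg <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  matrix(as.integer((xg - c0[1])^2 + (yg - c0[2])^2 <= r^2),
         dim[1], dim[2])
}

# solid-color RGB array
solidRGB <- function(hueDeg, dim = c(64L, 64L), s = 1, v = 1) {
  col <- grDevices::col2rgb(grDevices::hsv(hueDeg / 360, s, v)) / 255
  arr <- array(0, c(dim[1], dim[2], 3))
  for (ch in 1:3) arr[, , ch] <- col[ch]
  arr
}

# naive exhaustive maximum-entropy threshold over an integer histogram
# (independent oracle for maxEntropyThreshold)
maxentBrute <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  best <- -Inf; bestT <- NA_integer_
  for (t in seq_len(length(counts) - 1L)) {
    Pb <- sum(p[1:t])
    if (Pb <= 0 || Pb >= 1) next
    pb <- p[1:t] / Pb
    pw <- p[(t + 1):length(counts)] / (1 - Pb)
    H <- -sum(pb[pb > 0] * log(pb[pb > 0])) -
          sum(pw[pw > 0] * log(pw[pw > 0]))
    if (H > best) { best <- H; bestT <- t }
  }
  bestT
}

# reference vessel used across wire/pressure tests
refVessel <- function(beta = 5, noiseSd = 0, seed = 1L) {
  vesselModel(D00 = 200, beta = beta, wallCsa = 1.8e4,
              noiseSd = noiseSd, seed = seed)
}
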