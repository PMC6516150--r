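## Seeded generators producing every input the analysis modules consume,
## with known ground truth so each downstream stage supports
## parameter-recovery testing. All generators take explicit integer
## seeds and leave the global RNG state untouched.

#' Evaluate with a local RNG seed, restoring global state
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Wall thickness of an incompressible wall at a given inner diameter
#'
#' With constant wall cross-sectional area `csa` (um2), the outer
#' diameter at inner diameter `di` satisfies
#' pi/4 (De^2 - Di^2) = csa, hence
#' WT = (sqrt(Di^2 + 4 csa / pi) - Di) / 2.
#'
#' @param di inner diameter (um).
#' @param csa wall cross-sectional area (um2).
#' @return wall thickness (um).
#' @export
wallThicknessAt <- function(di, csa) {
  (sqrt(di^2 + 4 * csa / pi) - di) / 2
}

#' Construct a generative vessel model
#'
#' The constitutive law is sigma = sigmaOrig * exp(beta * epsilon) with
#' epsilon = (Di - D00)/D00 and D00 the inner diameter at 3 mmHg.
#' Because the 3 mmHg state is the zero-strain reference, mechanical
#' equilibrium there fixes sigmaOrig = 3 * 133.4e3 * D00 / (2 * WT(D00));
#' supply either `wallCsa` or `sigmaOrig` and the other is derived. If
#' both are supplied they must agree (class validity enforces this).
#'
#' @param D00 inner diameter at 3 mmHg (um).
#' @param beta dimensionless stiffness exponent (> 0).
#' @param wallCsa wall cross-sectional area (um2), or NULL to derive
#'   from `sigmaOrig`.
#' @param sigmaOrig stress at `D00` (dyn/cm2), or NULL to derive from
#'   `wallCsa`.
#' @param noiseSd Gaussian measurement noise on diameters (um).
#' @param seed integer RNG seed.
#' @return a \linkS4class{VesselModel}.
#' @examples
#' vesselModel(D00 = 200, beta = 5, wallCsa = pi * 25 * 225)
#' @export
vesselModel <- function(D00, beta, wallCsa = NULL, sigmaOrig = NULL,
                        noiseSd = 0, seed = 1L) {
  if (is.null(wallCsa) && is.null(sigmaOrig))
    stop("supply wallCsa or sigmaOrig")
  if (is.null(sigmaOrig)) {
    sigmaOrig <- 3 * MMHG_DYN_CM2 * D00 / (2 * wallThicknessAt(D00, wallCsa))
  } else if (is.null(wallCsa)) {
    ## invert sigmaOrig = 3*k*D00/(2*WT) for WT, then CSA
    wt0 <- 3 * MMHG_DYN_CM2 * D00 / (2 * sigmaOrig)
    wallCsa <- pi * wt0 * (D00 + wt0)
  }
  new("VesselModel", D00 = D00, wallCsa = wallCsa, beta = beta,
      sigmaOrig = sigmaOrig, noiseSd = noiseSd, seed = as.integer(seed))
}

## inner diameter solving constitutive = load equilibrium at pressure P
.solveDi <- function(P, D00, csa, beta, sigmaOrig, tol = 1e-6) {
  f <- function(di) {
    sigmaOrig * exp(beta * (di - D00) / D00) -
      P * MMHG_DYN_CM2 * di / (2 * wallThicknessAt(di, csa))
  }
  grid <- seq(D00 * (1 - 1e-6), 10 * D00, length.out = 256L)
  fg <- vapply(grid, f, 0)
  sc <- which(diff(sign(fg)) != 0)
  if (!length(sc))
    stop(sprintf(
      "pressure-series generation failure: equilibrium root not bracketed in (D00, 10*D00) for P = %g mmHg (D00 = %g, wallCsa = %g, beta = %g, sigmaOrig = %g)",
      P, D00, csa, beta, sigmaOrig))
  i <- sc[1]
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = tol)$root
}

#' Generate a passive pressure-diameter series from a vessel model
#'
#' For each pressure the inner diameter solves
#' sigmaOrig * exp(beta * epsilon) = P * 133.4e3 * Di / (2 WT(Di))
#' by bracketed root-finding (tolerance 1e-6 um); the outer diameter
#' follows from wall incompressibility. Gaussian noise of sd
#' `model@noiseSd` is added to both diameters. With zero noise the
#' output is exactly self-consistent with the pressure-myography
#' formulas, so refitting recovers beta and sigmaOrig.
#'
#' @param model a \linkS4class{VesselModel}.
#' @param pressureSteps strictly increasing pressures (mmHg), first
#'   3 mmHg; defaults to the 3-to-120 mmHg staircase in 20 mmHg steps
#'   (final step 103 to 120).
#' @param animalId identifier stored in the series.
#' @return a \linkS4class{PressureDiameterSeries}.
#' @export
makePressureSeries <- function(model,
                               pressureSteps = c(seq(3, 103, by = 20), 120),
                               animalId = "sim") {
  stopifnot(is(model, "VesselModel"))
  if (any(diff(pressureSteps) <= 0) || pressureSteps[1] != 3)
    stop("pressureSteps must be strictly increasing and start at 3 mmHg")
  di <- vapply(pressureSteps, .solveDi, 0, D00 = model@D00,
               csa = model@wallCsa, beta = model@beta,
               sigmaOrig = model@sigmaOrig)
  de <- di + 2 * wallThicknessAt(di, model@wallCsa)
  if (model@noiseSd > 0) {
    noise <- withSeed(model@seed,
                      stats::rnorm(2L * length(di), sd = model@noiseSd))
    di <- di + noise[seq_along(di)]
    de <- de + noise[length(di) + seq_along(di)]
    ## keep geometry physical under noise
    de <- pmax(de, di + 0.1)
  }
  new("PressureDiameterSeries", animalId = animalId,
      pressure = as.numeric(pressureSteps), innerDiameter = di,
      outerDiameter = de,
      metadata = list(truth = list(beta = model@beta,
                                   sigmaOrig = model@sigmaOrig,
                                   D00 = model@D00,
                                   wallCsa = model@wallCsa)))
}

#' Generate a linear wire-myography diameter-tension curve
#'
#' tension_i = slope * (d_i - y0) + Gaussian noise, at `nSteps` equally
#' spaced diameters above `y0`.
#'
#' @param slope tension change per unit diameter (mN/mm per um), > 0.
#' @param y0 diameter at zero tension (um).
#' @param nSteps number of stretch steps (>= 3).
#' @param noiseSd Gaussian noise on tension (mN/mm).
#' @param seed integer RNG seed.
#' @param diameterSpan range of diameters above `y0` (um) covered by the
#'   steps.
#' @param segmentId,segmentLength stored ring metadata.
#' @return a \linkS4class{WireMyoCurve}.
#' @export
makeWireCurve <- function(slope, y0, nSteps = 10L, noiseSd = 0, seed = 1L,
                          diameterSpan = c(25, 250), segmentId = "sim",
                          segmentLength = 2) {
  stopifnot(slope > 0, nSteps >= 3L)
  d <- y0 + seq(diameterSpan[1], diameterSpan[2], length.out = nSteps)
  tn <- slope * (d - y0)
  if (noiseSd > 0)
    tn <- tn + withSeed(seed, stats::rnorm(nSteps, sd = noiseSd))
  new("WireMyoCurve", segmentId = segmentId, segmentLength = segmentLength,
      diameter = d, tension = tn,
      metadata = list(truth = list(slope = slope, y0 = y0)))
}

#' Generate a pulsatile lumen-area waveform
#'
#' Piecewise-linear rise from diastolic to systolic area over `riseMs`,
#' followed by a smooth (half-cosine) decay back to the diastolic level
#' at the end of the cardiac period. The true initial ascending slope is
#' (aSys - aDia)/riseMs.
#'
#' @param aDia,aSys diastolic and systolic lumen areas (mm2), aSys > aDia
#'   (equal areas give a flat waveform).
#' @param riseMs systolic rise time (ms), >= 20 so that the 20 ms fit
#'   window lies inside the rise.
#' @param periodMs cardiac period (ms).
#' @param nSamples number of samples over one period.
#' @param noiseSd Gaussian noise on area (mm2).
#' @param seed integer RNG seed.
#' @param animalId,sliceId stored identifiers.
#' @return an \linkS4class{AreaTimeCurve}.
#' @export
makeAreaWaveform <- function(aDia = 1.0, aSys = 1.2, riseMs = 20,
                             periodMs = 150, nSamples = 30L, noiseSd = 0,
                             seed = 1L, animalId = "sim",
                             sliceId = "upper") {
  stopifnot(aSys >= aDia, riseMs >= 20)
  tt <- seq(0, periodMs, length.out = nSamples + 1L)[seq_len(nSamples)]
  a <- ifelse(tt <= riseMs,
              aDia + (aSys - aDia) * tt / riseMs,
              aDia + (aSys - aDia) *
                (1 + cos(pi * (tt - riseMs) / (periodMs - riseMs))) / 2)
  if (noiseSd > 0)
    a <- a + withSeed(seed, stats::rnorm(length(a), sd = noiseSd))
  a <- pmax(a, 1e-6)
  new("AreaTimeCurve", animalId = animalId, sliceId = sliceId,
      time = tt, area = a, heartPeriod = periodMs)
}

#' Construct a fiber image specification
#'
#' @param amplitude sine amplitude (um).
#' @param wavelength sine wavelength (um), > 0.
#' @param thicknessPx drawn thickness (px).
#' @param nFibers number of fibers.
#' @param imageShape image dimensions c(nx, ny) in px.
#' @param pixelSize um per px.
#' @param snr fiber intensity over background noise sd.
#' @param seed integer RNG seed.
#' @return a \linkS4class{FiberSpec}.
#' @export
fiberSpec <- function(amplitude, wavelength, thicknessPx = 3,
                      nFibers = 4L, imageShape = c(256L, 192L),
                      pixelSize = 1, snr = 5, seed = 1L) {
  new("FiberSpec", amplitude = amplitude, wavelength = wavelength,
      thicknessPx = thicknessPx, nFibers = as.integer(nFibers),
      imageShape = as.integer(imageShape), pixelSize = pixelSize,
      snr = snr, seed = as.integer(seed))
}

## trapezoidal quadrature of f sampled on an equispaced grid
.trapz <- function(f, h) h * (sum(f) - (f[1] + f[length(f)]) / 2)

#' Generate a wavy-fiber image with known ground-truth rectilinearity
#'
#' Draws `nFibers` horizontal sinusoids y = a sin(2 pi x / lambda +
#' phase) as polylines of the requested thickness, with additive
#' Gaussian background noise at the requested SNR. The per-fiber ground
#' truth is the chord-to-arc ratio obtained by numerical quadrature
#' (amplitude 0 gives exactly 1). Fibers are stacked with margins; if
#' the vertical bands of adjacent fibers intersect the result is
#' flagged `overlapping`.
#'
#' @param spec a \linkS4class{FiberSpec}.
#' @return list with `image` (numeric matrix, fiber intensity 1),
#'   `mask` (noise-free binary ground truth), `truth` (data.frame of
#'   per-fiber rectilinearity), `rectilinearity` (ground-truth pooled
#'   ratio), and `overlapping` flag.
#' @export
makeFiberImage <- function(spec) {
  stopifnot(is(spec, "FiberSpec"))
  nx <- spec@imageShape[1]; ny <- spec@imageShape[2]
  aPx <- spec@amplitude / spec@pixelSize
  lamPx <- spec@wavelength / spec@pixelSize
  margin <- aPx + spec@thicknessPx / 2 + 4
  if (2 * margin >= ny || margin >= nx / 4)
    stop("fibers do not fit inside the image with margin")
  xs <- seq(8, nx - 9)
  yc <- seq(margin, ny - margin, length.out = spec@nFibers)
  overlapping <- spec@nFibers > 1L &&
    any(diff(yc) < 2 * aPx + spec@thicknessPx + 1)
  phases <- withSeed(spec@seed, stats::runif(spec@nFibers, 0, 2 * pi))
  mask <- matrix(0L, nx, ny)
  span <- max(xs) - min(xs)
  for (i in seq_len(spec@nFibers)) {
    ys <- yc[i] + aPx * sin(2 * pi * (xs - min(xs)) / lamPx + phases[i])
    mask <- pmax(mask, rasterizePolyline(cbind(xs, ys), c(nx, ny),
                                         spec@thicknessPx))
  }
  ## ground truth per fiber by quadrature; pooled = sum(chord)/sum(arc)
  x <- seq(0, span, length.out = 20001L)
  k <- 2 * pi / lamPx
  arcs <- vapply(seq_len(spec@nFibers), function(i) {
    dy <- aPx * k * cos(k * x + phases[i])
    .trapz(sqrt(1 + dy^2), span / (length(x) - 1L))
  }, 0)
  chords <- vapply(seq_len(spec@nFibers), function(i) {
    y0 <- aPx * sin(phases[i]); y1 <- aPx * sin(k * span + phases[i])
    sqrt(span^2 + (y1 - y0)^2)
  }, 0)
  img <- matrix(as.numeric(mask), nx, ny)
  if (is.finite(spec@snr)) {
    noise <- withSeed(spec@seed + 1L,
                      stats::rnorm(nx * ny, sd = 1 / spec@snr))
    img <- pmax(img + matrix(noise, nx, ny), 0)
  }
  list(image = img, mask = mask,
       truth = data.frame(fiber = seq_len(spec@nFibers),
                          rectilinearity = chords / arcs),
       rectilinearity = sum(chords) / sum(arcs),
       overlapping = overlapping)
}

#' Generate a two-class stained-section image
#'
#' Pixels inside the mask are assigned to class A with probability
#' `fracA`, colored with the class hue plus Gaussian hue jitter (full
#' saturation and value). Emulates trichrome (green collagen vs red
#' muscle) and polarized picrosirius (orange thick vs green thin
#' bundles) sections for recovery testing.
#'
#' @param fracA fraction of class-A pixels (0..1).
#' @param hueA,hueB class hues in degrees (e.g. 120 green, 0 red,
#'   40 orange).
#' @param hueJitterDeg sd of Gaussian hue jitter (degrees).
#' @param dim image dimensions c(nx, ny).
#' @param mask optional binary matrix restricting stained pixels
#'   (default: whole image).
#' @param seed integer RNG seed.
#' @return list with `rgb` (nx x ny x 3 array in [0,1]), `classA`
#'   binary matrix, `mask`.
#' @export
makeStainImage <- function(fracA, hueA, hueB, hueJitterDeg = 5,
                           dim = c(128L, 128L), mask = NULL, seed = 1L) {
  nx <- dim[1]; ny <- dim[2]
  if (is.null(mask)) mask <- matrix(1L, nx, ny)
  inside <- which(mask > 0)
  draws <- withSeed(seed, list(
    cls = stats::runif(length(inside)) < fracA,
    jit = stats::rnorm(length(inside), sd = hueJitterDeg)))
  hue <- ifelse(draws$cls, hueA, hueB) + draws$jit
  hue <- (hue %% 360) / 360
  cols <- grDevices::hsv(hue, 1, 1)
  rgbArr <- array(0, c(nx, ny, 3))
  rgbv <- grDevices::col2rgb(cols) / 255
  for (ch in 1:3) {
    plane <- matrix(0, nx, ny)
    plane[inside] <- rgbv[ch, ]
    rgbArr[, , ch] <- plane
  }
  classA <- matrix(0L, nx, ny)
  classA[inside] <- as.integer(draws$cls)
  list(rgb = rgbArr, classA = classA, mask = mask)
}

#' Generate a DAPI-like nuclei image
#'
#' Plants `k` disjoint bright disks of the given radius at random
#' positions (rejection-sampled for a minimum separation) on a dark
#' background with Gaussian noise.
#'
#' @param k number of nuclei.
#' @param dim image dimensions c(nx, ny).
#' @param radius disk radius (px).
#' @param noiseSd background noise sd (signal = 1).
#' @param seed integer RNG seed.
#' @param minSep minimum centre separation (px).
#' @return list with `image` and `centers` (k x 2).
#' @export
makeNucleiImage <- function(k, dim = c(128L, 128L), radius = 4,
                            noiseSd = 0.05, seed = 1L,
                            minSep = 3 * radius) {
  nx <- dim[1]; ny <- dim[2]
  centers <- withSeed(seed, {
    acc <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(acc) < k && tries < 10000L) {
      p <- c(stats::runif(1, radius + 2, nx - radius - 1),
             stats::runif(1, radius + 2, ny - radius - 1))
      if (!nrow(acc) || min(sqrt(rowSums(sweep(acc, 2, p)^2))) >= minSep)
        acc <- rbind(acc, p)
      tries <- tries + 1L
    }
    acc
  })
  if (nrow(centers) < k)
    stop("could not place ", k, " nuclei with the requested separation")
  img <- matrix(0, nx, ny)
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (i in seq_len(k)) {
    img[(xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <= radius^2] <- 1
  }
  if (noiseSd > 0) {
    img <- img + matrix(withSeed(seed + 1L,
                                 stats::rnorm(nx * ny, sd = noiseSd)),
                        nx, ny)
    img <- pmax(img, 0)
  }
  list(image = img, centers = centers)
}
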