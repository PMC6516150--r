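#' @import methods
NULL

## Unit conventions used throughout:
##   diameters um, pressures mmHg, wall tension mN/mm (== N/m),
##   circumferential stress dyn/cm2, areas mm2 (MRI), times ms.
## 1 mmHg = 133.4e3 dyn/cm2 on the stress side; 133.322 Pa on the
## wire-tension (Laplace isobar) side.

#' Conversion constants
#'
#' `MMHG_DYN_CM2`: dyn/cm2 per mmHg used in the circumferential stress
#' computation. `MMHG_PA`: Pa per mmHg used when expressing the Laplace
#' isobar wall tension in mN/mm.
#'
#' @name unit-constants
#' @keywords internal
MMHG_DYN_CM2 <- 133.4e3
MMHG_PA <- 133.322

#' WireMyoCurve: a stepwise diameter-tension recording
#'
#' One passive distension recording of an arterial ring mounted on a wire
#' myograph: at each stretch step the internal diameter (um) and the wall
#' tension (mN/mm, force normalised to twice the segment length) are
#' recorded.
#'
#' @slot segmentId character identifier of the ring.
#' @slot segmentLength numeric, ring length in mm.
#' @slot diameter numeric vector, internal diameters (um), strictly
#'   increasing across steps.
#' @slot tension numeric vector, wall tension (mN/mm), same length.
#' @slot metadata list of group labels (genotype, treatment, ...).
#' @exportClass WireMyoCurve
setClass("WireMyoCurve",
  representation(segmentId = "character", segmentLength = "numeric",
                 diameter = "numeric", tension = "numeric",
                 metadata = "list"),
  prototype(segmentId = NA_character_, segmentLength = NA_real_,
            metadata = list()))

setValidity("WireMyoCurve", function(object) {
  msg <- character(0)
  if (length(object@diameter) != length(object@tension))
    msg <- c(msg, "diameter and tension must have equal length")
  if (length(object@diameter) < 3L)
    msg <- c(msg, "at least 3 diameter-tension points are required")
  if (any(diff(object@diameter) <= 0))
    msg <- c(msg, "diameters must be strictly increasing across steps")
  if (!all(is.finite(object@tension)))
    msg <- c(msg, "tensions must be finite")
  if (!is.na(object@segmentLength) && object@segmentLength <= 0)
    msg <- c(msg, "segmentLength must be positive")
  if (length(msg)) msg else TRUE
})

#' WireMyoFit: linear diameter-tension fit of a wire recording
#'
#' Ordinary least-squares fit of wall tension on internal diameter. The
#' slope (mN/mm per um) quantifies stiffness; the zero-tension intercept
#' diameter `y0Diameter` and the Laplace-estimated diameter at 100 mmHg
#' `d100` quantify remodeling. When the slope is non-positive the
#' recording is non-physiologic and `y0Diameter`/`d100` are `NA` with
#' `defined == FALSE`.
#'
#' @slot slope,intercept numeric OLS coefficients (mN/mm per um; mN/mm).
#' @slot y0Diameter numeric, extrapolated diameter at zero tension (um).
#' @slot d100 numeric, estimated diameter at 100 mmHg (um).
#' @slot r2 numeric, coefficient of determination.
#' @slot defined logical, FALSE when slope <= 0.
#' @exportClass WireMyoFit
setClass("WireMyoFit",
  representation(slope = "numeric", intercept = "numeric",
                 y0Diameter = "numeric", d100 = "numeric",
                 r2 = "numeric", defined = "logical"),
  prototype(d100 = NA_real_, defined = TRUE))

#' PressureDiameterSeries: passive pressure myography recording
#'
#' Inner and outer diameters of a cannulated artery measured under
#' passive (0 Ca2+) conditions over a staircase of intraluminal
#' pressures. The reference (zero-strain) diameter is the inner diameter
#' at the lowest pressure of the protocol, nominally 3 mmHg.
#'
#' @slot animalId character.
#' @slot pressure numeric vector of pressures (mmHg), strictly increasing.
#' @slot innerDiameter,outerDiameter numeric vectors (um).
#' @slot metadata list of group labels.
#' @exportClass PressureDiameterSeries
setClass("PressureDiameterSeries",
  representation(animalId = "character", pressure = "numeric",
                 innerDiameter = "numeric", outerDiameter = "numeric",
                 metadata = "list"),
  prototype(animalId = NA_character_, metadata = list()))

setValidity("PressureDiameterSeries", function(object) {
  msg <- character(0)
  n <- length(object@pressure)
  if (length(object@innerDiameter) != n || length(object@outerDiameter) != n)
    msg <- c(msg, "pressure, innerDiameter and outerDiameter lengths differ")
  if (n && any(diff(object@pressure) <= 0))
    msg <- c(msg, "pressures must be strictly increasing")
  if (n && any(object@outerDiameter <= object@innerDiameter))
    msg <- c(msg, "outer diameter must exceed inner diameter at every pressure")
  if (n && any(object@innerDiameter <= 0))
    msg <- c(msg, "diameters must be positive")
  if (length(msg)) msg else TRUE
})

#' PassiveMechanics: derived passive structural/mechanical parameters
#'
#' Per-pressure wall geometry and mechanics of a
#' \linkS4class{PressureDiameterSeries}, plus the per-animal exponential
#' stress-strain fit sigma = sigmaOrig * exp(beta * epsilon).
#'
#' @slot animalId character.
#' @slot pressure numeric (mmHg).
#' @slot wallThickness numeric (um), (De - Di)/2.
#' @slot wallToLumen numeric, (De - Di)/(2 Di).
#' @slot incrDistensibility numeric of length n-1, percent diameter
#'   change per mmHg over each pressure step.
#' @slot strain numeric, (Di - D00)/D00.
#' @slot stress numeric (dyn/cm2), P*133.4e3*Di/(2 WT).
#' @slot beta numeric, dimensionless stiffness exponent.
#' @slot sigmaOrig numeric (dyn/cm2), stress at the reference diameter.
#' @slot r2 numeric, fit R^2 on the log scale.
#' @exportClass PassiveMechanics
setClass("PassiveMechanics",
  representation(animalId = "character", pressure = "numeric",
                 wallThickness = "numeric", wallToLumen = "numeric",
                 incrDistensibility = "numeric", strain = "numeric",
                 stress = "numeric", beta = "numeric",
                 sigmaOrig = "numeric", r2 = "numeric"),
  prototype(animalId = NA_character_))

#' AreaTimeCurve: ECG-gated aortic lumen area vs time
#'
#' @slot animalId,sliceId character; sliceId distinguishes the upper and
#'   lower imaging planes.
#' @slot time numeric (ms from the ECG R wave), strictly increasing.
#' @slot area numeric (mm2), positive.
#' @slot heartPeriod numeric (ms).
#' @exportClass AreaTimeCurve
setClass("AreaTimeCurve",
  representation(animalId = "character", sliceId = "character",
                 time = "numeric", area = "numeric",
                 heartPeriod = "numeric"),
  prototype(animalId = NA_character_, sliceId = "upper",
            heartPeriod = NA_real_))

setValidity("AreaTimeCurve", function(object) {
  msg <- character(0)
  if (length(object@time) != length(object@area))
    msg <- c(msg, "time and area lengths differ")
  if (length(object@time) && any(diff(object@time) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@area) && any(!is.na(object@area) & object@area <= 0))
    msg <- c(msg, "areas must be positive")
  if (length(msg)) msg else TRUE
})

#' AortaKinetics: distensibility metrics of an area-time curve
#'
#' @slot animalId character.
#' @slot time numeric grid (ms).
#' @slot ascSlope numeric (mm2/ms), OLS slope over the first 20 ms.
#' @slot incrementalArea numeric (mm2), area difference from the first
#'   point.
#' @slot strainCurve numeric, radius increase over initial radius.
#' @slot totalStrain numeric (ms), trapezoidal integral of the strain
#'   curve over the analysis window.
#' @exportClass AortaKinetics
setClass("AortaKinetics",
  representation(animalId = "character", time = "numeric",
                 ascSlope = "numeric", incrementalArea = "numeric",
                 strainCurve = "numeric", totalStrain = "numeric"),
  prototype(animalId = NA_character_))

#' VesselModel: generative exponential-wall vessel
#'
#' Ground-truth model used by [makePressureSeries()]: an incompressible
#' wall of constant cross-sectional area obeying
#' sigma = sigmaOrig * exp(beta * epsilon) with epsilon referenced to the
#' inner diameter at 3 mmHg (`D00`). Mechanical equilibrium at 3 mmHg
#' ties `sigmaOrig` to the geometry, so [vesselModel()] derives one of
#' `sigmaOrig`/`wallCsa` from the other.
#'
#' @slot D00 numeric, inner diameter at 3 mmHg (um).
#' @slot wallCsa numeric, wall cross-sectional area (um2), constant
#'   across pressures (incompressibility).
#' @slot beta numeric, dimensionless stiffness exponent.
#' @slot sigmaOrig numeric, stress at `D00` (dyn/cm2).
#' @slot noiseSd numeric, measurement noise on diameters (um).
#' @slot seed integer RNG seed.
#' @exportClass VesselModel
setClass("VesselModel",
  representation(D00 = "numeric", wallCsa = "numeric", beta = "numeric",
                 sigmaOrig = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("VesselModel", function(object) {
  msg <- character(0)
  if (object@D00 <= 0) msg <- c(msg, "D00 must be positive")
  if (object@wallCsa <= 0) msg <- c(msg, "wallCsa must be positive")
  if (object@beta <= 0) msg <- c(msg, "beta must be positive")
  if (object@sigmaOrig <= 0) msg <- c(msg, "sigmaOrig must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  ## 3 mmHg equilibrium consistency (see vesselModel())
  wt0 <- wallThicknessAt(object@D00, object@wallCsa)
  s0 <- 3 * MMHG_DYN_CM2 * object@D00 / (2 * wt0)
  if (abs(s0 - object@sigmaOrig) / s0 > 1e-3)
    msg <- c(msg, sprintf(
      "sigmaOrig (%.4g) inconsistent with 3 mmHg equilibrium (%.4g); use vesselModel() to derive one from the other",
      object@sigmaOrig, s0))
  if (length(msg)) msg else TRUE
})

#' FiberSpec: ground-truth sinusoidal fiber image specification
#'
#' @slot amplitude numeric, sine amplitude (um), >= 0.
#' @slot wavelength numeric, sine wavelength (um), > 0.
#' @slot thicknessPx numeric, drawn fiber thickness (px).
#' @slot nFibers integer, number of fibers.
#' @slot imageShape integer vector c(nx, ny) in px.
#' @slot pixelSize numeric, um per px.
#' @slot snr numeric, fiber amplitude over background noise sd.
#' @slot seed integer RNG seed.
#' @exportClass FiberSpec
setClass("FiberSpec",
  representation(amplitude = "numeric", wavelength = "numeric",
                 thicknessPx = "numeric", nFibers = "integer",
                 imageShape = "integer", pixelSize = "numeric",
                 snr = "numeric", seed = "integer"))

setValidity("FiberSpec", function(object) {
  msg <- character(0)
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
    msg <- c(msg, "imageShape must be two dimensions of at least 16 px")
  if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
  if (length(msg)) msg else TRUE
})

#' RectilinearityResult: branch table and chord-to-arc ratio
#'
#' Output of the elastin rectilinearity toolbox. `branches` has one row
#' per skeleton branch with geodesic length and endpoint chord distance
#' (um). The rectilinearity is the ratio of the accumulated chord
#' distance to the accumulated geodesic length over all retained
#' branches; 1 means perfectly straight, smaller means wavier.
#'
#' @slot branches data.frame with columns `lengthUm`, `distanceUm`,
#'   `nPixels`, `cyclic`.
#' @slot rectilinearity numeric in (0, 1].
#' @slot pixelSize numeric, um/px.
#' @exportClass RectilinearityResult
setClass("RectilinearityResult",
  representation(branches = "data.frame", rectilinearity = "numeric",
                 pixelSize = "numeric"))

setValidity("RectilinearityResult", function(object) {
  msg <- character(0)
  if (length(object@rectilinearity) == 1 &&
      is.finite(object@rectilinearity) &&
      (object@rectilinearity <= 0 || object@rectilinearity > 1 + 1e-12))
    msg <- c(msg, "rectilinearity must lie in (0, 1]")
  if (nrow(object@branches) &&
      any(object@branches$distanceUm > object@branches$lengthUm * (1 + 1e-9)))
    msg <- c(msg, "branch chord distance cannot exceed geodesic length")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "WireMyoCurve", function(object) {
  cat("WireMyoCurve '", object@segmentId, "': ",
      length(object@diameter), " steps, diameter ",
      round(min(object@diameter)), "-", round(max(object@diameter)),
      " um, segment ", object@segmentLength, " mm\n", sep = "")
})

setMethod("show", "WireMyoFit", function(object) {
  cat("WireMyoFit: slope ", signif(object@slope, 4), " mN/mm/um, Y0 ",
      signif(object@y0Diameter, 5), " um, d100 ",
      signif(object@d100, 5), " um, R2 ", signif(object@r2, 4),
      if (!object@defined) " [undefined: non-positive slope]", "\n",
      sep = "")
})

setMethod("show", "PressureDiameterSeries", function(object) {
  cat("PressureDiameterSeries '", object@animalId, "': ",
      length(object@pressure), " pressures (",
      min(object@pressure), "-", max(object@pressure), " mmHg), Di ",
      round(min(object@innerDiameter)), "-",
      round(max(object@innerDiameter)), " um\n", sep = "")
})

setMethod("show", "PassiveMechanics", function(object) {
  cat("PassiveMechanics '", object@animalId, "': beta ",
      signif(object@beta, 4), ", sigmaOrig ",
      signif(object@sigmaOrig, 4), " dyn/cm2, R2(log) ",
      signif(object@r2, 4), "\n", sep = "")
})

setMethod("show", "AreaTimeCurve", function(object) {
  cat("AreaTimeCurve '", object@animalId, "/", object@sliceId, "': ",
      length(object@time), " samples over ",
      round(max(object@time)), " ms, area ",
      signif(min(object@area, na.rm = TRUE), 3), "-",
      signif(max(object@area, na.rm = TRUE), 3), " mm2\n", sep = "")
})

setMethod("show", "AortaKinetics", function(object) {
  cat("AortaKinetics '", object@animalId, "': ascending slope ",
      signif(object@ascSlope, 4), " mm2/ms, total strain ",
      signif(object@totalStrain, 4), " ms\n", sep = "")
})

setMethod("show", "VesselModel", function(object) {
  cat("VesselModel: D00 ", object@D00, " um, wall CSA ",
      signif(object@wallCsa, 5), " um2, beta ", object@beta,
      ", sigmaOrig ", signif(object@sigmaOrig, 5),
      " dyn/cm2, noise ", object@noiseSd, " um\n", sep = "")
})

setMethod("show", "RectilinearityResult", function(object) {
  cat("RectilinearityResult: ", nrow(object@branches), " branches, ",
      "rectilinearity ", signif(object@rectilinearity, 4), "\n", sep = "")
})
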