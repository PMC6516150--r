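## Wire myography: stepwise diameter-tension recordings of aortic
## rings. Stiffness is read from the slope of the linear
## diameter-tension regression; remodeling from the zero-tension
## diameter Y0 and from the Laplace-estimated diameter at 100 mmHg.

#' Convert transducer force to wall tension
#'
#' The mounted ring resists stretch with two wall strips, so the force
#' recorded by the transducer distributes over twice the segment
#' length: T = F / (2 L).
#'
#' @param force force (mN).
#' @param segmentLength ring length (mm), > 0.
#' @return wall tension (mN/mm).
#' @examples
#' tensionFromForce(4, 2)   # 1 mN/mm
#' @export
tensionFromForce <- function(force, segmentLength) {
  if (any(segmentLength <= 0))
    stop("segmentLength must be positive")
  force / (2 * segmentLength)
}

#' Fit the linear diameter-tension relationship
#'
#' Ordinary least squares of wall tension on internal diameter. The
#' zero-tension diameter is Y0 = -intercept/slope. A non-positive slope
#' signals a non-physiologic recording: the fit is returned with Y0 and
#' d100 undefined (`NA`, `defined = FALSE`).
#'
#' @param curve a \linkS4class{WireMyoCurve}.
#' @return a \linkS4class{WireMyoFit}. `d100` is filled in by
#'   [estimateD100()]; this function leaves it `NA`.
#' @export
fitDiameterTension <- function(curve) {
  stopifnot(is(curve, "WireMyoCurve"))
  d <- curve@diameter; tn <- curve@tension
  if (stats::var(d) == 0) stop("diameter variance is zero")
  fit <- stats::lm.fit(cbind(1, d), tn)
  b <- unname(fit$coefficients)
  ssTot <- sum((tn - mean(tn))^2)
  r2 <- if (ssTot > 0) 1 - sum(fit$residuals^2) / ssTot else 1
  defined <- is.finite(b[2]) && b[2] > 0
  new("WireMyoFit", slope = b[2], intercept = b[1],
      y0Diameter = if (defined) -b[1] / b[2] else NA_real_,
      d100 = NA_real_, r2 = r2, defined = defined)
}

#' Laplace isobar coefficient
#'
#' Wall tension along the isobar of pressure P is T = P d / 2. With P in
#' mmHg (133.322 Pa/mmHg) and d in um, T in mN/mm (= N/m) is k * d with
#' k = P * 133.322e-6 / 2 per um.
#' @keywords internal
laplaceCoefficient <- function(pressure) {
  pressure * MMHG_PA * 1e-6 / 2
}

#' Estimate the physiological diameter at a target pressure
#'
#' Intersects the fitted linear diameter-tension relationship with the
#' Laplace isobar T = P d / 2 expressed in mN/mm per um, i.e. solves
#' slope * d + intercept = k * d. The intersection must be positive and
#' unique; a slope equal to the isobar coefficient (parallel lines) or a
#' non-positive intersection is an error.
#'
#' @param fit a \linkS4class{WireMyoFit}.
#' @param pressure target pressure (mmHg), default 100.
#' @return the fit with `d100` filled in (um).
#' @examples
#' # flat recording at T = 0.3333 mN/mm crosses the 100 mmHg isobar
#' # near d = 50 um (13332.2 Pa * 25e-6 m = 0.3333 N/m)
#' @export
estimateD100 <- function(fit, pressure = 100) {
  stopifnot(is(fit, "WireMyoFit"))
  if (!is.finite(fit@slope)) {
    fit@d100 <- NA_real_
    return(fit)
  }
  k <- laplaceCoefficient(pressure)
  if (abs(fit@slope - k) < 1e-12)
    stop("estimateD100: fitted line is parallel to the Laplace isobar")
  d <- -fit@intercept / (fit@slope - k)
  if (!is.finite(d) || d <= 0)
    stop("estimateD100: intersection with the isobar is not positive")
  fit@d100 <- d
  fit
}

#' Full wire-myography analysis of one curve
#'
#' Convenience wrapper: linear fit plus d100 at the requested pressure.
#' Non-physiologic recordings (slope <= 0) keep d100 undefined rather
#' than erroring.
#'
#' @param curve a \linkS4class{WireMyoCurve}.
#' @param pressure isobar pressure (mmHg).
#' @return a \linkS4class{WireMyoFit}.
#' @export
analyzeWireCurve <- function(curve, pressure = 100) {
  fit <- fitDiameterTension(curve)
  if (fit@defined) fit <- estimateD100(fit, pressure)
  fit
}

#' Channel discalibration QC
#'
#' Recordings whose force readout differs between the myograph unit and
#' the acquisition software by more than 5 units are excluded. The
#' threshold is a strict inequality: a discrepancy of exactly 5 is
#' kept.
#'
#' @param channelDiscrepancy non-negative discrepancy (mN).
#' @param threshold exclusion threshold, default 5.
#' @return logical: TRUE = keep, FALSE = exclude.
#' @export
qcKeepChannel <- function(channelDiscrepancy, threshold = 5) {
  if (any(channelDiscrepancy < 0))
    stop("channelDiscrepancy must be non-negative")
  channelDiscrepancy <= threshold
}

#' Convert a pressure-diameter series to wire-style tension pairs
#'
#' Maps each (P, Di) sample of a passive pressure series to the Laplace
#' wall tension T = P Di / 2 (mN/mm), yielding the diameter-tension
#' pairs a wire myograph would record for the same vessel. The stretch
#' protocol of a wire myograph probes the high-tension quasi-linear
#' regime, so the default window keeps pressures between 60 and
#' 120 mmHg; over that window the linear-fit d100 tracks the true
#' 100 mmHg diameter closely.
#'
#' @param series a \linkS4class{PressureDiameterSeries}.
#' @param window pressure window (mmHg) retained, default c(60, 120).
#' @param segmentLength nominal ring length (mm) stored in the result.
#' @return a \linkS4class{WireMyoCurve}.
#' @export
tensionPairsFromPressure <- function(series, window = c(60, 120),
                                     segmentLength = 2) {
  stopifnot(is(series, "PressureDiameterSeries"))
  sel <- series@pressure >= window[1] & series@pressure <= window[2]
  if (sum(sel) < 3L)
    stop("fewer than 3 pressure samples inside the window; widen it or refine the pressure grid")
  d <- series@innerDiameter[sel]
  tn <- laplaceCoefficient(series@pressure[sel]) * d
  new("WireMyoCurve", segmentId = series@animalId,
      segmentLength = segmentLength, diameter = d, tension = tn,
      metadata = series@metadata)
}
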