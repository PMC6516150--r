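## Pressure myography: passive structural and mechanical parameters of
## cannulated resistance arteries from inner/outer diameter vs pressure
## staircases recorded in 0 Ca2+ medium.

#' Wall geometry per pressure
#'
#' WT = (De - Di)/2 and wall:lumen = (De - Di)/(2 Di) at every pressure
#' of the series.
#'
#' @param series a \linkS4class{PressureDiameterSeries}.
#' @return data.frame with columns `pressure`, `wallThickness` (um),
#'   `wallToLumen`.
#' @export
wallGeometry <- function(series) {
  stopifnot(is(series, "PressureDiameterSeries"))
  di <- series@innerDiameter; de <- series@outerDiameter
  if (any(de <= di)) stop("invalid geometry: outer diameter <= inner diameter")
  data.frame(pressure = series@pressure,
             wallThickness = (de - di) / 2,
             wallToLumen = (de - di) / (2 * di))
}

#' Incremental distensibility per pressure step
#'
#' Percentage change in internal diameter per mmHg over each pressure
#' step: 100 * (Di_hi - Di_lo) / (Di_ref * (P_hi - P_lo)). The reference
#' diameter is the lower-pressure diameter of the step by default, or
#' the step midpoint diameter with `reference = "midpoint"`.
#'
#' @param series a \linkS4class{PressureDiameterSeries} with >= 2
#'   pressures.
#' @param reference "lower" (default) or "midpoint".
#' @return data.frame with `pressureLow`, `pressureHigh`,
#'   `distensibility` (%/mmHg).
#' @export
incrementalDistensibility <- function(series,
                                      reference = c("lower", "midpoint")) {
  stopifnot(is(series, "PressureDiameterSeries"))
  reference <- match.arg(reference)
  p <- series@pressure; di <- series@innerDiameter
  if (length(p) < 2L) stop("at least 2 pressures are required")
  dP <- diff(p)
  if (any(dP == 0)) stop("zero pressure step")
  ref <- if (reference == "lower") di[-length(di)]
         else (di[-length(di)] + di[-1]) / 2
  data.frame(pressureLow = p[-length(p)], pressureHigh = p[-1],
             distensibility = 100 * diff(di) / (ref * dP))
}

#' Circumferential wall strain and stress
#'
#' strain epsilon = (Di - D00)/D00 with D00 the inner diameter at the
#' lowest (3 mmHg) pressure; stress sigma = P * 133.4e3 * Di / (2 WT)
#' in dyn/cm2 (1 mmHg = 133.4e3 dyn/cm2; diameter units cancel).
#'
#' @param series a \linkS4class{PressureDiameterSeries}.
#' @return data.frame with `pressure`, `strain`, `stress`.
#' @export
stressStrain <- function(series) {
  stopifnot(is(series, "PressureDiameterSeries"))
  geo <- wallGeometry(series)
  if (any(geo$wallThickness <= 0)) stop("non-positive wall thickness")
  d00 <- referenceDiameter(series)
  if (d00 <= 0) stop("non-positive reference diameter")
  di <- series@innerDiameter
  data.frame(pressure = series@pressure,
             strain = (di - d00) / d00,
             stress = series@pressure * MMHG_DYN_CM2 * di /
               (2 * geo$wallThickness))
}

#' Fit the exponential stress-strain law
#'
#' Least-squares fit of ln sigma = ln sigmaOrig + beta * epsilon
#' (log-linear, variance-stabilizing and closed-form). The incremental
#' elastic modulus follows as E_inc = beta * sigma, strictly increasing
#' in beta at fixed sigma.
#'
#' @param strain,stress numeric vectors (>= 3 points, strain spanning a
#'   positive range, all stresses positive).
#' @return list with `beta`, `sigmaOrig`, `r2` (log scale) and `eincAt`,
#'   a function of sigma returning E_inc.
#' @examples
#' ss <- stressStrain(makePressureSeries(vesselModel(200, 5, wallCsa = 2e4)))
#' fitStressStrain(ss$strain, ss$stress)$beta   # 5
#' @export
fitStressStrain <- function(strain, stress) {
  if (length(strain) != length(stress)) stop("length mismatch")
  if (length(strain) < 3L) stop("at least 3 stress-strain points required")
  bad <- which(stress <= 0)
  if (length(bad))
    stop("non-positive stress at index ", paste(bad, collapse = ", "))
  if (max(strain) - min(strain) <= 0) stop("strain does not span a range")
  fit <- stats::lm.fit(cbind(1, strain), log(stress))
  b <- unname(fit$coefficients)
  ssTot <- sum((log(stress) - mean(log(stress)))^2)
  r2 <- if (ssTot > 0) 1 - sum(fit$residuals^2) / ssTot else 1
  beta <- b[2]
  list(beta = beta, sigmaOrig = exp(b[1]), r2 = r2,
       eincAt = function(sigma) beta * sigma)
}

#' Full passive-mechanics analysis of one pressure series
#'
#' Computes geometry, incremental distensibility, stress-strain and the
#' per-animal exponential fit, bundled as a
#' \linkS4class{PassiveMechanics} object.
#'
#' @param series a \linkS4class{PressureDiameterSeries}.
#' @param reference step reference for incremental distensibility.
#' @return a \linkS4class{PassiveMechanics}.
#' @export
passiveMechanics <- function(series, reference = "lower") {
  geo <- wallGeometry(series)
  ss <- stressStrain(series)
  dist <- incrementalDistensibility(series, reference)
  fit <- fitStressStrain(ss$strain, ss$stress)
  new("PassiveMechanics", animalId = series@animalId,
      pressure = series@pressure, wallThickness = geo$wallThickness,
      wallToLumen = geo$wallToLumen,
      incrDistensibility = dist$distensibility,
      strain = ss$strain, stress = ss$stress,
      beta = fit$beta, sigmaOrig = fit$sigmaOrig, r2 = fit$r2)
}

#' Incremental elastic modulus at a stress value
#'
#' E_inc = beta * sigma.
#'
#' @param mech a \linkS4class{PassiveMechanics} (or a number, taken as
#'   beta).
#' @param sigma stress (dyn/cm2).
#' @return E_inc (dyn/cm2).
#' @export
incrementalModulus <- function(mech, sigma) {
  beta <- if (is(mech, "PassiveMechanics")) mech@beta else as.numeric(mech)
  beta * sigma
}
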