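## In vivo hemodynamics: aortic lumen-area kinetics from ECG-gated cine
## MRI and transit-time pulse wave velocity.

#' Resample an area-time curve onto a uniform grid
#'
#' Linear interpolation onto a `dt`-spaced grid from 0 to `tMax` ms
#' (curves are cut at 150 ms because differing cycle lengths prevent
#' alignment beyond that point). Missing samples (`NA` areas) are first
#' substituted from the time-matched secondary slice when one is
#' supplied.
#'
#' @param curve an \linkS4class{AreaTimeCurve} (primary, upper slice).
#' @param dt grid spacing (ms).
#' @param tMax truncation time (ms).
#' @param fillFrom optional secondary \linkS4class{AreaTimeCurve} used
#'   to fill missing samples.
#' @return an \linkS4class{AreaTimeCurve} on the uniform grid.
#' @export
resampleAreaCurve <- function(curve, dt = 1, tMax = 150,
                              fillFrom = NULL) {
  stopifnot(is(curve, "AreaTimeCurve"))
  tt <- curve@time; aa <- curve@area
  if (!is.null(fillFrom)) {
    stopifnot(is(fillFrom, "AreaTimeCurve"))
    miss <- which(is.na(aa))
    if (length(miss)) {
      sub <- stats::approx(fillFrom@time, fillFrom@area, tt[miss],
                           rule = 2, ties = "ordered")$y
      aa[miss] <- sub
    }
  }
  keep <- !is.na(aa)
  tt <- tt[keep]; aa <- aa[keep]
  if (sum(tt >= 0 & tt <= tMax) < 2L)
    stop("fewer than 2 samples inside [0, tMax]")
  gap <- max(diff(sort(c(0, tt[tt <= tMax], tMax))))
  period <- curve@heartPeriod
  if (is.finite(period) && gap > period / 4)
    stop(sprintf(
      "coverage gap of %.0f ms exceeds a quarter heart period (%.0f ms) and no secondary curve fills it",
      gap, period))
  grid <- seq(0, tMax, by = dt)
  area <- stats::approx(tt, aa, grid, rule = 2, ties = "ordered")$y
  new("AreaTimeCurve", animalId = curve@animalId, sliceId = curve@sliceId,
      time = grid, area = area, heartPeriod = curve@heartPeriod)
}

#' Initial ascending slope of the area-time curve
#'
#' OLS slope of area on time over the first `window` ms of systole
#' (default 20 ms). This area-time slope (mm2/ms) is the distensibility
#' readout used for the in vivo comparison; it is not pressure
#' normalized.
#'
#' @param curve an \linkS4class{AreaTimeCurve}.
#' @param window fit window (ms).
#' @return slope (mm2/ms).
#' @export
ascendingSlope <- function(curve, window = 20) {
  stopifnot(is(curve, "AreaTimeCurve"))
  sel <- curve@time >= 0 & curve@time <= window & !is.na(curve@area)
  if (sum(sel) < 3L)
    stop("fewer than 3 samples in the first ", window, " ms")
  unname(stats::lm.fit(cbind(1, curve@time[sel]),
                       curve@area[sel])$coefficients[2])
}

#' Incremental area, strain curve and total strain
#'
#' Radius from area as r = sqrt(A/pi); strain(t) = (r(t) - r(0))/r(0);
#' incremental area = A(t) - A(0); total strain = trapezoidal integral
#' of the strain curve over the analysis window (units ms, strain being
#' dimensionless).
#'
#' @param curve an \linkS4class{AreaTimeCurve} (typically resampled).
#' @return an \linkS4class{AortaKinetics}.
#' @export
strainMetrics <- function(curve) {
  stopifnot(is(curve, "AreaTimeCurve"))
  a <- curve@area; tt <- curve@time
  if (any(a <= 0)) stop("non-positive area")
  r <- sqrt(a / pi)
  strain <- (r - r[1]) / r[1]
  total <- sum(diff(tt) * (strain[-1] + strain[-length(strain)]) / 2)
  new("AortaKinetics", animalId = curve@animalId, time = tt,
      ascSlope = ascendingSlope(curve),
      incrementalArea = a - a[1], strainCurve = strain,
      totalStrain = total)
}

#' Transit-time pulse wave velocity
#'
#' PWV = path distance / (t_femoral - t_aorta), where the times are
#' measured from the ECG R wave to the foot of the pulse waveform at
#' the ascending aorta and the femoral artery.
#'
#' @param pathDistance distance between measurement points (mm), > 0.
#' @param tAorta,tFemoral R-to-foot times (ms); tFemoral > tAorta.
#' @return PWV in m/s (mm/ms == m/s).
#' @examples
#' computePWV(40, 2, 10)   # 5 m/s
#' @export
computePWV <- function(pathDistance, tAorta, tFemoral) {
  if (any(pathDistance <= 0)) stop("path distance must be positive")
  tt <- tFemoral - tAorta
  if (any(tt <= 0)) stop("transit time must be positive")
  pathDistance / tt
}

#' Foot-of-wave detection by intersecting tangents (experimental)
#'
#' Locates the waveform foot as the intersection of the baseline with
#' the tangent at the steepest upstroke. The study this package models
#' measured feet manually; this detector is provided for exploratory
#' use only and is not part of the validated pipeline.
#'
#' @param time,signal waveform samples.
#' @return estimated foot time.
#' @export
detectFoot <- function(time, signal) {
  stopifnot(length(time) == length(signal), length(time) >= 5L)
  dv <- diff(signal) / diff(time)
  i <- which.max(dv)
  tm <- (time[i] + time[i + 1]) / 2
  vm <- (signal[i] + signal[i + 1]) / 2
  base <- min(signal)
  tm - (vm - base) / dv[i]
}

#' Per-timepoint group mean and SD of resampled curves
#'
#' Assembles the group mean +/- SD area curve on the common grid, the
#' form used to plot cohort kinetics.
#'
#' @param curves list of \linkS4class{AreaTimeCurve}s on identical
#'   grids.
#' @return data.frame with `time`, `mean`, `sd`, `n`.
#' @export
groupAreaCurve <- function(curves) {
  stopifnot(length(curves) >= 1L)
  grid <- curves[[1]]@time
  for (cv in curves)
    if (!isTRUE(all.equal(cv@time, grid)))
      stop("curves are not on a common time grid; resample first")
  m <- vapply(curves, function(cv) cv@area, numeric(length(grid)))
  data.frame(time = grid,
             mean = rowMeans(m),
             sd = apply(m, 1, stats::sd),
             n = length(curves))
}
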