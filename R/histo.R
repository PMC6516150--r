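## Stained-section quantification: trichrome area fractions, media
## morphometry, polarized picrosirius color classes, immunofluorescence
## intensity (mean / maximum-entropy integrated density) with
## control-median normalisation, SHG texture moments, nuclei counts.

## default HSV hue bands (degrees) and saturation/value floors; the
## study's own bands were implicit in interactive color picking, so
## these are explicit, configurable equivalents
.hueBands <- list(red = c(0, 30, 330, 360), green = c(70, 170),
                  orange = c(20, 60))
.satFloor <- 0.15
.valFloor <- 0.15

## per-pixel hue (deg), saturation, value from an nx x ny x 3 array
.hsvOf <- function(rgbArr) {
  n <- dim(rgbArr)[1] * dim(rgbArr)[2]
  m <- rbind(as.vector(rgbArr[, , 1]), as.vector(rgbArr[, , 2]),
             as.vector(rgbArr[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = hsv[1, ] * 360, s = hsv[2, ], v = hsv[3, ])
}

.inHueBand <- function(h, band) {
  if (length(band) == 4)
    (h >= band[1] & h <= band[2]) | (h >= band[3] & h <= band[4])
  else
    h >= band[1] & h <= band[2]
}

#' Trichrome area fractions in the medial layer
#'
#' Classifies pixels inside the media mask by hue: green pixels are
#' collagen, red pixels are smooth muscle. Fractions are percentages of
#' the medial area and need not sum to 100.
#'
#' @param rgbArr nx x ny x 3 array in [0, 1].
#' @param mediaMask binary matrix (non-empty).
#' @param greenBand,redBand hue bands in degrees; red may wrap
#'   (c(lo1, hi1, lo2, hi2)).
#' @param satFloor,valFloor minimum saturation and value for a pixel to
#'   be classified.
#' @return list with `pctCollagen`, `pctMuscle`.
#' @export
trichromeFractions <- function(rgbArr, mediaMask,
                               greenBand = .hueBands$green,
                               redBand = .hueBands$red,
                               satFloor = .satFloor,
                               valFloor = .valFloor) {
  inside <- which(mediaMask > 0)
  if (!length(inside)) stop("empty media mask")
  hsv <- .hsvOf(rgbArr)
  ok <- hsv$s >= satFloor & hsv$v >= valFloor
  green <- ok & .inHueBand(hsv$h, greenBand)
  red <- ok & .inHueBand(hsv$h, redBand)
  list(pctCollagen = 100 * sum(green[inside]) / length(inside),
       pctMuscle = 100 * sum(red[inside]) / length(inside))
}

#' Media thickness and lumen perimeter
#'
#' The lumen perimeter is the traced contour length of the lumen mask;
#' media thickness is the media area divided by the midline length,
#' approximated by the mean of the inner (lumen) and outer
#' (media-plus-lumen) contour lengths. Robust to irregular,
#' non-circular sections.
#'
#' @param lumenMask,mediaMask binary matrices; the lumen must be a
#'   single connected component.
#' @param pixelSize um per px.
#' @return list with `mediaThicknessUm`, `lumenPerimeterUm`.
#' @export
mediaMorphometry <- function(lumenMask, mediaMask, pixelSize = 1) {
  lab <- labelComponents(lumenMask)
  ncomp <- max(lab)
  if (ncomp == 0L) stop("empty lumen mask")
  if (ncomp > 1L) stop("lumen mask has ", ncomp,
                       " components; expected a single lumen")
  innerLen <- contourPerimeter(lumenMask)
  outer <- (lumenMask > 0) | (mediaMask > 0)
  outerLen <- contourPerimeter(outer)
  mediaArea <- sum(mediaMask > 0)
  list(mediaThicknessUm = mediaArea / ((innerLen + outerLen) / 2) *
         pixelSize,
       lumenPerimeterUm = innerLen * pixelSize)
}

#' Polarized picrosirius color classes
#'
#' Under polarized light, dense thick collagen bundles appear
#' yellow-orange and thin bundles green. Birefringent pixels inside the
#' adventitia mask (above the value floor) are split by hue band; the
#' two classes are reported as percentages of the birefringent area.
#'
#' @param rgbArr nx x ny x 3 array in [0, 1].
#' @param adventitiaMask binary matrix (non-empty).
#' @param orangeBand,greenBand hue bands (degrees).
#' @param satFloor,valFloor classification floors.
#' @param pixelSize um per px.
#' @return list with `pctOrange`, `pctGreen`, `birefringentAreaUm2`.
#' @export
picrosiriusClasses <- function(rgbArr, adventitiaMask,
                               orangeBand = .hueBands$orange,
                               greenBand = .hueBands$green,
                               satFloor = .satFloor,
                               valFloor = .valFloor, pixelSize = 1) {
  inside <- which(adventitiaMask > 0)
  if (!length(inside)) stop("empty adventitia mask")
  hsv <- .hsvOf(rgbArr)
  bire <- (hsv$s >= satFloor & hsv$v >= valFloor)[inside]
  h <- hsv$h[inside]
  nb <- sum(bire)
  if (nb == 0)
    return(list(pctOrange = 0, pctGreen = 0, birefringentAreaUm2 = 0))
  list(pctOrange = 100 * sum(bire & .inHueBand(h, orangeBand)) / nb,
       pctGreen = 100 * sum(bire & .inHueBand(h, greenBand)) / nb,
       birefringentAreaUm2 = nb * pixelSize^2)
}

#' Immunofluorescence intensity quantification
#'
#' `mode = "mean"`: mean intensity over the ROI. `mode = "maxentropy"`:
#' Kapur maximum-entropy threshold on the ROI histogram, then
#' integrated density (sum of intensities) over the supra-threshold
#' pixels — the background-robust readout. Raw values are normalised
#' against the control group with [normalizeToControlMedian()].
#'
#' @param img numeric intensity matrix.
#' @param roiMask binary matrix selecting the quantified layer.
#' @param mode "mean" or "maxentropy".
#' @return a single intensity value (arbitrary units).
#' @export
ifIntensity <- function(img, roiMask, mode = c("mean", "maxentropy")) {
  mode <- match.arg(mode)
  v <- img[roiMask > 0]
  if (!length(v)) stop("empty ROI")
  if (mode == "mean") return(mean(v))
  th <- maxEntropyThreshold(v)
  sum(v[v > th])
}

#' Normalize per-animal values to the control-group median
#'
#' Divides every value by the median of the designated control group,
#' so the control group's median maps to exactly 1.
#'
#' @param values numeric vector (one per animal).
#' @param group group label per value.
#' @param control the control group label.
#' @return normalized values.
#' @export
normalizeToControlMedian <- function(values, group, control) {
  med <- stats::median(values[group == control])
  if (!is.finite(med) || med == 0)
    stop("control group median is zero or undefined")
  values / med
}

#' Second-harmonic generation texture statistics
#'
#' Histogram moments of the intensity distribution inside the mask:
#' Pearson kurtosis m4/m2^2 (normal = 3; peakedness) and skewness
#' m3/m2^1.5 (asymmetry), plus the amount (supra-threshold pixel area)
#' and density (mean supra-threshold intensity) of the collagen signal.
#' The signal threshold defaults to the maximum-entropy cutoff.
#'
#' @param img numeric intensity matrix.
#' @param mask binary matrix (default: whole image).
#' @param threshold signal threshold, or NULL for maximum entropy.
#' @param excess logical: report excess kurtosis (normal = 0) instead
#'   of Pearson kurtosis.
#' @param pixelSize um per px.
#' @return list with `signalAreaUm2`, `density`, `kurtosis`,
#'   `skewness`.
#' @export
shgTexture <- function(img, mask = NULL, threshold = NULL,
                       excess = FALSE, pixelSize = 1) {
  v <- if (is.null(mask)) as.numeric(img) else img[mask > 0]
  if (length(unique(v)) < 2L) stop("zero intensity variance in mask")
  m <- mean(v)
  m2 <- mean((v - m)^2); m3 <- mean((v - m)^3); m4 <- mean((v - m)^4)
  kurt <- m4 / m2^2
  if (excess) kurt <- kurt - 3
  th <- if (is.null(threshold)) maxEntropyThreshold(v) else threshold
  sup <- v[v > th]
  list(signalAreaUm2 = length(sup) * pixelSize^2,
       density = if (length(sup)) mean(sup) else 0,
       kurtosis = kurt,
       skewness = m3 / m2^1.5)
}

#' Count nuclei in a DAPI channel
#'
#' Otsu threshold, connected components, size filter. Optionally splits
#' touching nuclei by watershed on the distance map.
#'
#' @param img numeric nuclear-channel matrix.
#' @param mask optional binary matrix restricting the count.
#' @param minAreaPx minimum component area (px).
#' @param watershed logical: split touching nuclei.
#' @return integer count.
#' @export
countNuclei <- function(img, mask = NULL, minAreaPx = 5L,
                        watershed = FALSE) {
  x <- img
  if (!is.null(mask)) x[mask == 0] <- 0
  r <- range(x)
  if (r[1] == r[2]) return(0L)
  th <- otsuThreshold(x)
  bin <- x > th
  if (!any(bin)) return(0L)
  if (watershed) {
    dm <- EBImage::distmap(EBImage::Image(matrix(as.numeric(bin),
                                                 nrow(x), ncol(x))))
    lab <- EBImage::imageData(EBImage::watershed(dm))
  } else {
    lab <- labelComponents(bin)
  }
  sizes <- tabulate(as.integer(lab[lab > 0]))
  sum(sizes >= minAreaPx)
}
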