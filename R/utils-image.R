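## Low-level image primitives shared by the elastin and histology
## modules. Images are numeric matrices indexed [x, y] with 0-based
## pixel-centre coordinates at (col-1, row-1); intensities are
## non-negative on an arbitrary scale.

#' Shift a matrix by an integer offset, zero-padding
#' @keywords internal
shiftMat <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0L, nx, ny)
  xs <- seq_len(nx) - dx; ys <- seq_len(ny) - dy
  okx <- xs >= 1L & xs <= nx; oky <- ys >= 1L & ys <= ny
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

## 8-neighborhood p2..p9 clockwise starting "north" (+y)
.neigh8 <- function(m) {
  list(shiftMat(m, 0L, 1L), shiftMat(m, 1L, 1L), shiftMat(m, 1L, 0L),
       shiftMat(m, 1L, -1L), shiftMat(m, 0L, -1L), shiftMat(m, -1L, -1L),
       shiftMat(m, -1L, 0L), shiftMat(m, -1L, 1L))
}

#' Number of ON 8-neighbors per skeleton pixel
#' @keywords internal
neighborCount <- function(m) {
  Reduce(`+`, .neigh8(m)) * m
}

#' Crossing number: 0->1 transitions around the 8-neighborhood
#'
#' A path pixel has 2 (or 1 at an endpoint); a junction has >= 3.
#' @keywords internal
crossingNumber <- function(m) {
  p <- .neigh8(m)
  A <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) A <- A + (p[[i]] == 0L & p[[i %% 8 + 1]] == 1L)
  A * m
}

#' Guo-Hall thinning to a one-pixel-wide skeleton
#'
#' Iterative two-subcycle thinning of a binary mask down to 8-connected
#' centre lines. The result is a subset of the input mask with clean
#' unit-width paths (no redundant staircase pixels), suitable for branch
#' decomposition.
#'
#' @param mask binary matrix (non-zero = foreground).
#' @return integer 0/1 matrix of the same dimensions.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  it <- 0L
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      p <- .neigh8(m)
      C <- ((1L - p[[1]]) * (p[[2]] | p[[3]])) +
           ((1L - p[[3]]) * (p[[4]] | p[[5]])) +
           ((1L - p[[5]]) * (p[[6]] | p[[7]])) +
           ((1L - p[[7]]) * (p[[8]] | p[[1]]))
      N1 <- (p[[8]] | p[[1]]) + (p[[2]] | p[[3]]) +
            (p[[4]] | p[[5]]) + (p[[6]] | p[[7]])
      N2 <- (p[[1]] | p[[2]]) + (p[[3]] | p[[4]]) +
            (p[[5]] | p[[6]]) + (p[[7]] | p[[8]])
      N <- pmin(N1, N2)
      mm <- if (sub == 0L) (p[[5]] | p[[6]] | (1L - p[[8]])) & p[[7]]
            else           (p[[1]] | p[[2]] | (1L - p[[4]])) & p[[3]]
      del <- m == 1L & C == 1L & N >= 2L & N <= 3L & mm == 0L
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    it <- it + 1L
    if (!changed || it > 1000L) break
  }
  m
}

#' 8-connected component labelling of a binary matrix
#'
#' Flood-fill labelling with diagonal adjacency, needed for one-pixel
#' skeletons (4-connected labelling shreds diagonal runs).
#'
#' @param mask binary matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  on <- mask > 0
  lab <- matrix(0L, nx, ny)
  offs <- c(-1L - nx, -nx, 1L - nx, -1L, 1L, nx - 1L, nx, nx + 1L)
  cur <- 0L
  fg <- which(on)
  for (start in fg) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      x <- (i - 1L) %% nx + 1L
      cand <- i + offs
      ## drop neighbors that wrap across matrix edges
      keep <- rep(TRUE, 8L)
      if (x == 1L) keep[c(1L, 4L, 6L)] <- FALSE
      if (x == nx) keep[c(3L, 5L, 8L)] <- FALSE
      cand <- cand[keep]
      cand <- cand[cand >= 1L & cand <= nx * ny]
      cand <- cand[on[cand] & lab[cand] == 0L]
      if (length(cand)) {
        lab[cand] <- cur
        stack <- c(stack, cand)
      }
    }
  }
  lab
}

#' Remove connected components smaller than a pixel count
#' @param mask binary matrix.
#' @param minPx minimum component size in pixels.
#' @return binary integer matrix.
#' @export
removeSmallComponents <- function(mask, minPx = 64) {
  lab <- labelComponents(mask)
  if (!any(lab > 0L)) return(matrix(0L, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab)
  keep <- which(sizes >= minPx)
  matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
}

#' Geodesic length of an ordered pixel path
#'
#' `method = "polygon"` (default) measures the length of the polygonal
#' chain through every `spacing`-th path pixel (endpoints always
#' included). This suppresses the orientation-dependent overestimation
#' of raw chain codes while remaining exact on straight paths and never
#' shorter than the endpoint chord. `method = "steps"` is the classical
#' chain-code sum (1 per orthogonal step, sqrt(2) per diagonal step).
#'
#' @param path n x 2 matrix of pixel coordinates (ordered).
#' @param method "polygon" or "steps".
#' @param spacing resampling interval in pixels for "polygon".
#' @return length in pixel units.
#' @export
pathLength <- function(path, method = c("polygon", "steps"), spacing = 4L) {
  method <- match.arg(method)
  n <- nrow(path)
  if (n < 2L) return(0)
  if (method == "steps") {
    return(sum(sqrt(rowSums(diff(path)^2))))
  }
  idx <- unique(c(seq(1L, n, by = max(1L, as.integer(spacing))), n))
  sum(sqrt(rowSums(diff(path[idx, , drop = FALSE])^2)))
}

#' Rasterize a polyline into a binary image
#'
#' Draws the polyline with the given thickness by marking the nearest
#' pixel of densely resampled curve points and dilating with a disc.
#' Used by the synthetic fiber generator and by tests that need curves
#' of known geometry.
#'
#' @param pts n x 2 matrix of (x, y) positions in pixel units (0-based).
#' @param dim image dimensions c(nx, ny).
#' @param thickness drawn thickness in pixels.
#' @return binary integer matrix.
#' @export
rasterizePolyline <- function(pts, dim, thickness = 3) {
  stopifnot(nrow(pts) >= 2L)
  seglen <- sqrt(rowSums(diff(pts)^2))
  total <- sum(seglen)
  n <- max(2L, ceiling(total * 3))
  tt <- seq(0, 1, length.out = n)
  cum <- c(0, cumsum(seglen)) / total
  xs <- stats::approx(cum, pts[, 1], tt, ties = "ordered")$y
  ys <- stats::approx(cum, pts[, 2], tt, ties = "ordered")$y
  img <- matrix(0L, dim[1], dim[2])
  ix <- pmin(pmax(round(xs) + 1L, 1L), dim[1])
  iy <- pmin(pmax(round(ys) + 1L, 1L), dim[2])
  img[cbind(ix, iy)] <- 1L
  if (thickness > 1) {
    br <- EBImage::makeBrush(2L * floor(thickness / 2) + 1L, shape = "disc")
    img <- matrix(as.integer(EBImage::imageData(
      EBImage::dilate(EBImage::Image(img), br)) > 0), dim[1], dim[2])
  }
  img
}

#' Kapur maximum-entropy threshold
#'
#' Chooses the intensity cutoff maximizing the sum of Shannon entropies
#' of the sub- and supra-threshold histogram classes. Intensities are
#' binned on \code{nBins} levels spanning the value range.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nBins number of histogram bins (256 emulates 8-bit data).
#' @return the threshold on the intensity scale; values strictly above
#'   it form the bright class.
#' @export
maxEntropyThreshold <- function(x, nBins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  r <- range(v)
  if (r[1] == r[2])
    stop("maxEntropyThreshold: single-valued histogram, no threshold exists")
  ## bin to nBins levels over [min, max]
  b <- pmin(floor((v - r[1]) / (r[2] - r[1]) * nBins) + 1L, nBins)
  h <- tabulate(b, nBins)
  p <- h / sum(h)
  Pb <- cumsum(p)                       # P(class <= t)
  ## entropy accumulators; 0 log 0 := 0
  plogp <- ifelse(p > 0, p * log(p), 0)
  Sb <- cumsum(plogp)
  St <- sum(plogp)
  t <- seq_len(nBins - 1L)
  valid <- Pb[t] > 0 & Pb[t] < 1
  Hb <- log(Pb[t]) - Sb[t] / Pb[t]
  Hw <- log(1 - Pb[t]) - (St - Sb[t]) / (1 - Pb[t])
  Htot <- ifelse(valid, Hb + Hw, -Inf)
  tbest <- t[which.max(Htot)]
  ## threshold on the original scale: upper edge of bin tbest
  r[1] + tbest / nBins * (r[2] - r[1])
}

#' Otsu threshold on an arbitrary intensity scale
#' @keywords internal
otsuThreshold <- function(x, nBins = 256L) {
  v <- as.numeric(x)
  r <- range(v, finite = TRUE)
  if (r[1] == r[2]) return(r[1])
  img <- EBImage::Image((matrix(v, nrow = 1) - r[1]) / (r[2] - r[1]))
  th <- EBImage::otsu(img, range = c(0, 1), levels = nBins)
  r[1] + th * (r[2] - r[1])
}

#' Perimeter of the largest object in a binary mask
#'
#' Traces the object contour (EBImage) and measures its closed polygonal
#' length with the same resampled-chord estimator used for skeleton
#' branches, which keeps digital circles within ~1% of 2*pi*r.
#'
#' @keywords internal
contourPerimeter <- function(mask, spacing = 4L) {
  oc <- EBImage::ocontour(EBImage::Image(matrix(as.integer(mask > 0),
                                                nrow(mask), ncol(mask))))
  if (!length(oc)) stop("contourPerimeter: empty mask")
  cont <- oc[[which.max(vapply(oc, nrow, 0L))]]
  n <- nrow(cont)
  idx <- unique(c(seq(1L, n, by = max(1L, as.integer(spacing))), n))
  p <- cont[idx, , drop = FALSE]
  p <- rbind(p, p[1, ])                  # close the loop
  sum(sqrt(rowSums(diff(p)^2)))
}
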