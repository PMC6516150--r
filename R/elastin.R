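## Elastin rectilinearity toolbox: preprocess autofluorescence images,
## segment lamellae, skeletonize, decompose into branches, and measure
## the chord-to-arc ("fiber distance" over "fiber length") ratio.
## Rectilinearity 1 means perfectly straight lamellae; lower values mean
## wavier fibers.

#' Preprocess a fiber image
#'
#' Median filtering (impulse-noise removal) followed by rolling-ball
#' background subtraction: the smooth background is estimated by
#' grayscale morphological opening with a disc structuring element of
#' the given radius and subtracted; output is clamped at zero.
#'
#' @param img numeric matrix of intensities.
#' @param medianRadiusPx median filter radius (px), >= 1.
#' @param ballRadiusPx rolling-ball radius (px), >= 1 and smaller than
#'   the image.
#' @return numeric matrix, non-negative.
#' @export
preprocessFibers <- function(img, medianRadiusPx = 2, ballRadiusPx = 25) {
  if (medianRadiusPx < 1 || ballRadiusPx < 1)
    stop("filter radii must be >= 1")
  if (2 * ballRadiusPx + 1 >= min(dim(img)))
    stop("ball radius must be smaller than the image")
  hi <- max(img)
  x <- if (hi > 0) img / hi else img
  x <- EBImage::imageData(EBImage::medianFilter(EBImage::Image(x),
                                                as.integer(medianRadiusPx)))
  br <- EBImage::makeBrush(2L * as.integer(ballRadiusPx) + 1L,
                           shape = "disc")
  bg <- EBImage::imageData(EBImage::opening(EBImage::Image(x), br))
  out <- pmax(x - bg, 0) * hi
  matrix(out, nrow(img), ncol(img))
}

#' Segment fibers inside a region of interest
#'
#' Thresholds the (preprocessed) image inside the ROI. The threshold is
#' either chosen automatically (Otsu or Kapur maximum entropy on the
#' ROI histogram) or fixed by the user, which is the reproducible
#' counterpart of an interactively chosen cutoff.
#'
#' @param img numeric matrix.
#' @param roi ROI as c(x0, y0, x1, y1), 0-based half-open
#'   (x0 <= x < x1); NULL = whole image.
#' @param method "otsu", "maxentropy", or a single numeric threshold.
#'   Pixels strictly above the threshold are foreground.
#' @return binary integer matrix (foreground inside the ROI only).
#' @export
segmentFibers <- function(img, roi = NULL, method = "otsu") {
  nx <- nrow(img); ny <- ncol(img)
  if (is.null(roi)) roi <- c(0L, 0L, nx, ny)
  if (roi[1] < 0 || roi[2] < 0 || roi[3] > nx || roi[4] > ny ||
      roi[3] <= roi[1] || roi[4] <= roi[2])
    stop("roi must lie within the image (0-based, half-open)")
  xs <- (roi[1] + 1L):roi[3]; ys <- (roi[2] + 1L):roi[4]
  sub <- img[xs, ys, drop = FALSE]
  th <- if (is.numeric(method)) {
    method
  } else {
    switch(match.arg(method, c("otsu", "maxentropy")),
           otsu = otsuThreshold(sub),
           maxentropy = maxEntropyThreshold(sub))
  }
  mask <- matrix(0L, nx, ny)
  mask[xs, ys] <- as.integer(sub > th)
  if (!any(mask > 0))
    stop("empty mask: nothing to skeletonize (threshold too high?)")
  mask
}

#' Skeletonize a fiber mask after removing small components
#'
#' Connected components smaller than `minComponentPx` (8-connected) are
#' discarded; the remainder is thinned to one-pixel-wide centre lines
#' (see [skeletonize()]), which extracts each lamella's centre line
#' independently of its intensity or thickness.
#'
#' @param mask binary matrix.
#' @param minComponentPx minimum component size (px), default 64.
#' @return binary integer skeleton (subset of the mask). An all-zero
#'   skeleton is allowed and signalled with a warning.
#' @export
skeletonizeFibers <- function(mask, minComponentPx = 64) {
  m <- removeSmallComponents(mask, minComponentPx)
  sk <- skeletonize(m)
  if (!any(sk > 0)) warning("empty skeleton after pruning")
  sk
}

## ordered path tracing of junction-free skeleton components
.traceBranches <- function(skel) {
  nx <- nrow(skel); ny <- ncol(skel)
  cr <- crossingNumber(skel)
  body <- skel == 1L & cr < 3L          # cut at junction pixels
  pix <- which(body, arr.ind = TRUE)
  n <- nrow(pix)
  if (!n) return(list())
  idmat <- matrix(0L, nx, ny)
  idmat[pix] <- seq_len(n)
  offs <- cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
                dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))
  nbrsOf <- function(i) {
    x <- pix[i, 1] + offs[, 1]; y <- pix[i, 2] + offs[, 2]
    ok <- x >= 1L & x <= nx & y >= 1L & y <= ny
    v <- idmat[cbind(x[ok], y[ok])]
    v[v > 0L]
  }
  visited <- logical(n)
  out <- list()
  for (s in seq_len(n)) {
    if (visited[s]) next
    ## collect the component
    comp <- s; visited[s] <- TRUE; queue <- s
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      for (nb in nbrsOf(cur)) if (!visited[nb]) {
        visited[nb] <- TRUE; queue <- c(queue, nb); comp <- c(comp, nb)
      }
    }
    deg <- vapply(comp, function(i) length(nbrsOf(i)), 0L)
    ends <- comp[deg <= 1L]
    if (!length(ends)) {               # closed loop: no endpoints
      out[[length(out) + 1L]] <- list(path = pix[comp, , drop = FALSE],
                                      cyclic = TRUE)
      next
    }
    cur <- ends[1]                      # row-major first endpoint
    path <- cur
    repeat {
      cand <- setdiff(nbrsOf(cur), path)
      if (!length(cand)) break
      cur <- cand[1]                    # ties: row-major offset order
      path <- c(path, cur)
    }
    out[[length(out) + 1L]] <- list(path = pix[path, , drop = FALSE],
                                    cyclic = FALSE)
  }
  out
}

#' Decompose a skeleton into branches and measure them
#'
#' Cuts the one-pixel skeleton at junction pixels (crossing number
#' >= 3), traces each remaining path end-to-end, and measures the
#' geodesic "fiber length" and the endpoint "fiber distance" (Euclidean
#' chord), both in um. Closed loops have no endpoints; their chord is
#' taken as the maximum pairwise pixel distance and they are flagged
#' cyclic.
#'
#' @param skeleton binary matrix from [skeletonizeFibers()].
#' @param pixelSize um per px.
#' @param lengthMethod geodesic estimator passed to [pathLength()]:
#'   "polygon" (default; resampled-chord, orientation-unbiased) or
#'   "steps" (classical 1/sqrt(2) chain code).
#' @param minBranchPx branches shorter than this many pixels (junction
#'   debris) are dropped; default 3.
#' @return data.frame with `lengthUm`, `distanceUm`, `nPixels`,
#'   `cyclic`.
#' @export
fiberBranches <- function(skeleton, pixelSize = 1,
                          lengthMethod = c("polygon", "steps"),
                          minBranchPx = 3L) {
  lengthMethod <- match.arg(lengthMethod)
  br <- .traceBranches(skeleton)
  br <- Filter(function(b) nrow(b$path) >= minBranchPx, br)
  if (!length(br))
    return(data.frame(lengthUm = numeric(0), distanceUm = numeric(0),
                      nPixels = integer(0), cyclic = logical(0)))
  len <- vapply(br, function(b) pathLength(b$path, lengthMethod), 0)
  dist <- vapply(br, function(b) {
    p <- b$path
    if (b$cyclic) {
      ## chord of a loop: maximum pairwise distance
      d2 <- as.matrix(stats::dist(p))
      max(d2)
    } else {
      sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    }
  }, 0)
  data.frame(lengthUm = len * pixelSize, distanceUm = dist * pixelSize,
             nPixels = vapply(br, function(b) nrow(b$path), 0L),
             cyclic = vapply(br, function(b) b$cyclic, NA))
}

#' Pooled rectilinearity of a branch table
#'
#' Ratio of the accumulated fiber distance to the accumulated fiber
#' length over all retained branches, in (0, 1].
#'
#' @param branches data.frame from [fiberBranches()].
#' @param pixelSize um per px (stored in the result).
#' @return a \linkS4class{RectilinearityResult}.
#' @export
rectilinearityOf <- function(branches, pixelSize = 1) {
  if (!nrow(branches) || sum(branches$lengthUm) <= 0)
    stop("no branches with positive length")
  new("RectilinearityResult", branches = branches,
      rectilinearity = sum(branches$distanceUm) / sum(branches$lengthUm),
      pixelSize = pixelSize)
}

#' End-to-end rectilinearity analysis of a fiber image
#'
#' Preprocess, segment, skeletonize, decompose, measure: the full
#' toolbox in one call.
#'
#' @param img numeric intensity matrix.
#' @param pixelSize um per px.
#' @param roi optional ROI c(x0, y0, x1, y1), 0-based half-open.
#' @param method threshold method or value (see [segmentFibers()]).
#' @param medianRadiusPx,ballRadiusPx preprocessing radii; set
#'   `preprocess = FALSE` to skip preprocessing.
#' @param minComponentPx small-component cutoff before thinning.
#' @param lengthMethod geodesic estimator (see [fiberBranches()]).
#' @param preprocess logical.
#' @return a \linkS4class{RectilinearityResult}.
#' @export
analyzeRectilinearity <- function(img, pixelSize = 1, roi = NULL,
                                  method = "otsu", medianRadiusPx = 2,
                                  ballRadiusPx = 25,
                                  minComponentPx = 64,
                                  lengthMethod = "polygon",
                                  preprocess = TRUE) {
  if (preprocess)
    img <- preprocessFibers(img, medianRadiusPx, ballRadiusPx)
  mask <- segmentFibers(img, roi, method)
  sk <- skeletonizeFibers(mask, minComponentPx)
  br <- fiberBranches(sk, pixelSize, lengthMethod)
  rectilinearityOf(br, pixelSize)
}
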