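## Statistical layer: Grubbs outlier exclusion, two-group and
## multi-group comparisons of derived scalars (slopes, beta, d100,
## rectilinearity, ...), and Sidak adjustment for planned comparisons.

#' Grubbs critical value
#'
#' G_c = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)) with t the upper
#' alpha/(2n) quantile of Student's t with n-2 degrees of freedom
#' (two-sided maximum normalized residual test).
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return critical value for G = max|x - mean|/sd.
#' @export
grubbsCritical <- function(n, alpha = 0.05) {
  if (n < 3L) stop("Grubbs test requires n >= 3")
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative Grubbs outlier exclusion
#'
#' Repeatedly removes the most extreme point (largest normalized
#' residual G = max|x - mean|/sd) while G exceeds the critical value at
#' level `alpha`, recomputing mean and sd after each removal. At most
#' floor(n/5) points are removed (safety cap against eroding small
#' samples). A zero-variance sample excludes nothing, with a warning.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level, default 0.05.
#' @param maxRemovals cap on removals; default floor(n/5), at least 1.
#' @return list with `values` (retained), `excluded` (indices into the
#'   input, possibly empty), `G` (statistics at each removal).
#' @examples
#' grubbsExclude(c(1, 1.1, 0.9, 1.05, 8))$excluded   # 5
#' @export
grubbsExclude <- function(values, alpha = 0.05,
                          maxRemovals = max(1L, floor(length(values) / 5))) {
  n0 <- length(values)
  if (n0 < 3L) stop("Grubbs test requires n >= 3")
  keep <- seq_len(n0)
  excluded <- integer(0)
  Gs <- numeric(0)
  repeat {
    x <- values[keep]
    n <- length(x)
    if (n < 3L || length(excluded) >= maxRemovals) break
    s <- stats::sd(x)
    if (s == 0) {
      if (!length(excluded))
        warning("zero variance: no outliers can be identified")
      break
    }
    res <- abs(x - mean(x)) / s
    G <- max(res)
    if (G <= grubbsCritical(n, alpha)) break
    i <- which.max(res)
    excluded <- c(excluded, keep[i])
    Gs <- c(Gs, G)
    keep <- keep[-i]
  }
  list(values = values[keep], excluded = excluded, G = Gs)
}

#' Sidak adjustment for k planned comparisons
#'
#' p' = 1 - (1 - p)^k; monotone in k, p' >= p, and p' = p for k = 1.
#'
#' @param p p-value(s).
#' @param k number of planned comparisons.
#' @return adjusted p-value(s), capped at 1.
#' @export
sidakAdjust <- function(p, k) {
  stopifnot(k >= 1)
  pmin(1, 1 - (1 - p)^k)
}

#' Compare a per-animal metric between groups
#'
#' Designs: `"t"` (pooled-variance Student t), `"welch-t"`,
#' `"mann-whitney"` (exact/normal Wilcoxon rank sum), `"anova1+sidak"`
#' (one-way ANOVA followed by Sidak-adjusted pairwise t comparisons),
#' `"anova2+sidak"` (two-way ANOVA for curve data, factors `group` and
#' `x`, Sidak-adjusted per-level group contrasts). Each compared group
#' must have at least 2 observations.
#'
#' @param table data.frame with columns `value`, `group`, and for the
#'   two-way design a covariate column `x` (e.g. pressure or time).
#' @param design one of the designs above.
#' @param alpha significance threshold recorded in the output.
#' @return list with `design`, the overall `p`, a `pairwise`
#'   data.frame (comparison, p, pSidak) where applicable, and
#'   `significant` (overall p < alpha).
#' @export
compareGroups <- function(table,
                          design = c("t", "welch-t", "mann-whitney",
                                     "anova1+sidak", "anova2+sidak"),
                          alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(all(c("value", "group") %in% names(table)))
  table$group <- factor(table$group)
  ns <- table(table$group)
  if (any(ns < 2L))
    stop("every compared group needs at least 2 observations; offending: ",
         paste(names(ns)[ns < 2], collapse = ", "))
  lv <- levels(table$group)
  out <- list(design = design, alpha = alpha)
  if (design %in% c("t", "welch-t", "mann-whitney")) {
    if (length(lv) != 2L)
      stop("two-group designs need exactly 2 groups")
    a <- table$value[table$group == lv[1]]
    b <- table$value[table$group == lv[2]]
    out$p <- switch(design,
      "t" = stats::t.test(a, b, var.equal = TRUE)$p.value,
      "welch-t" = stats::t.test(a, b)$p.value,
      "mann-whitney" = stats::wilcox.test(a, b)$p.value)
    out$effect <- mean(a) - mean(b)
  } else if (design == "anova1+sidak") {
    fit <- stats::aov(value ~ group, data = table)
    out$p <- summary(fit)[[1]][["Pr(>F)"]][1]
    cmb <- utils::combn(lv, 2)
    k <- ncol(cmb)
    pw <- apply(cmb, 2, function(gp) {
      stats::t.test(table$value[table$group == gp[1]],
                    table$value[table$group == gp[2]],
                    var.equal = TRUE)$p.value
    })
    out$pairwise <- data.frame(
      comparison = apply(cmb, 2, paste, collapse = " vs "),
      p = pw, pSidak = sidakAdjust(pw, k))
  } else {                                # anova2+sidak
    if (!"x" %in% names(table))
      stop("two-way design needs a covariate column 'x'")
    table$x <- factor(table$x)
    fit <- stats::aov(value ~ group * x, data = table)
    sm <- summary(fit)[[1]]
    out$p <- sm[["Pr(>F)"]][1]            # main group effect
    out$pInteraction <- sm[["Pr(>F)"]][3]
    if (length(lv) == 2L) {
      xs <- levels(table$x)
      pw <- vapply(xs, function(xi) {
        sub <- table[table$x == xi, ]
        if (all(table(sub$group) >= 2))
          stats::t.test(value ~ group, data = sub,
                        var.equal = TRUE)$p.value
        else NA_real_
      }, 0)
      out$pairwise <- data.frame(comparison = paste("x =", xs), p = pw,
                                 pSidak = sidakAdjust(pw, length(xs)))
    }
  }
  out$significant <- is.finite(out$p) && out$p < alpha
  out
}

#' Compare wire-myography regression slopes between two groups
#'
#' Default design: two-sample comparison of the per-animal slopes (one
#' linear fit per vessel segment, then a group test). Alternative:
#' pooled ANCOVA on the raw diameter-tension points, testing the
#' group-by-diameter interaction (common-slope test).
#'
#' @param fitsA,fitsB lists of \linkS4class{WireMyoFit} (>= 2 each) for
#'   the per-animal design.
#' @param method "t", "welch-t", "mann-whitney", or "ancova".
#' @param curvesA,curvesB lists of \linkS4class{WireMyoCurve}, required
#'   for "ancova".
#' @return list with `p`, `slopesA`, `slopesB` (or the ANCOVA fit
#'   summary).
#' @export
compareSlopes <- function(fitsA, fitsB, method = c("t", "welch-t",
                                                   "mann-whitney",
                                                   "ancova"),
                          curvesA = NULL, curvesB = NULL) {
  method <- match.arg(method)
  if (method == "ancova") {
    if (is.null(curvesA) || is.null(curvesB))
      stop("ancova needs the raw curves")
    df <- do.call(rbind, c(
      lapply(curvesA, function(cv)
        data.frame(d = cv@diameter, tn = cv@tension, grp = "A")),
      lapply(curvesB, function(cv)
        data.frame(d = cv@diameter, tn = cv@tension, grp = "B"))))
    fit <- stats::lm(tn ~ d * grp, data = df)
    p <- stats::anova(fit)[["Pr(>F)"]][3]
    return(list(p = p, method = "ancova"))
  }
  slopesOf <- function(fits) vapply(fits, function(f) f@slope, 0)
  sa <- slopesOf(fitsA); sb <- slopesOf(fitsB)
  if (length(sa) < 2L || length(sb) < 2L)
    stop("at least 2 fits per group are required")
  tab <- data.frame(value = c(sa, sb),
                    group = rep(c("A", "B"), c(length(sa), length(sb))))
  res <- compareGroups(tab, design = method)
  list(p = res$p, slopesA = sa, slopesB = sb, method = method)
}
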