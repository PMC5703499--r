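#' Welch two-sample t statistic
#'
#' t statistic and Welch-Satterthwaite degrees of freedom for the mean
#' difference `mean(x) - mean(y)` without assuming equal variances:
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)`.
#'
#' @param x,y numeric vectors with at least 2 finite values each.
#' @return list with `t` and `df` (df kept as a real number).
#' @examples
#' welchT(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
welchT <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("welchT needs at least 2 finite observations on each side")
  }
  fit <- t.test(x, y, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter))
}

#' Family-by-trait matrix of between-climate Welch t statistics
#'
#' For every sire family and every trait, compares the family's TEMP and
#' TROP offspring with a Welch t test; the statistic is oriented as the
#' reference climate minus the other (TEMP - TROP), so a family whose
#' weight drops more in the hot climate has a larger `t_BW`.
#'
#' @param study a [HeatStudy], normally after [sequentialAdjust()].
#' @param traits traits to contrast (default ADFI, BW, RT).
#' @param referenceClimate climate whose mean enters with positive sign.
#' @return a [TStatMatrix], rows ordered by family label.
#' @export
buildTMatrix <- function(study, traits = sensTraits(),
                         referenceClimate = "TEMP") {
  stopifnot(is(study, "HeatStudy"))
  cd <- as.data.frame(colData(study))
  miss <- setdiff(traits, colnames(cd))
  if (length(miss)) stop("trait(s) not present: ",
    paste(miss, collapse = ", "))
  other <- setdiff(c("TEMP", "TROP"), referenceClimate)
  fams <- sort(unique(as.character(cd$family)))
  for (f in fams) {
    present <- unique(cd$climate[cd$family == f])
    if (!all(c(referenceClimate, other) %in% present)) {
      stop("family ", f, " is missing from climate ",
        setdiff(c(referenceClimate, other), present))
    }
  }
  dims <- list(fams, paste0("t_", traits))
  stat <- df <- nT <- nP <- matrix(NA_real_, length(fams), length(traits),
    dimnames = dims)
  for (f in fams) {
    for (j in seq_along(traits)) {
      xs <- cd[[traits[j]]][cd$family == f & cd$climate == referenceClimate]
      ys <- cd[[traits[j]]][cd$family == f & cd$climate == other]
      xs <- xs[is.finite(xs)]
      ys <- ys[is.finite(ys)]
      w <- welchT(xs, ys)
      stat[f, j] <- w$t
      df[f, j] <- w$df
      nT[f, j] <- length(xs)
      nP[f, j] <- length(ys)
    }
  }
  new("TStatMatrix", stats = stat, df = df, nTemp = nT, nTrop = nP)
}

#' Composite sensitivity index from the Welch-t matrix
#'
#' Principal component analysis of the families x traits t matrix
#' (column-centered; unscaled by default since the t statistics are
#' already unit-free) summarises each family's climate response in one
#' score: its coordinate on the first component. The component is
#' oriented so the `t_BW` loading is positive — a larger body-weight drop
#' in the hot climate means a larger, more sensitive index value.
#'
#' @param tm a [TStatMatrix] (or plain families x traits matrix) with at
#'   least 3 families.
#' @param scale logical; scale t columns to unit variance before the PCA
#'   (default FALSE, both conventions available).
#' @return a [SensitivityIndex] with per-family scores, percent inertia
#'   per component and percent contribution of each variable to PC1
#'   (squared loading, in %).
#' @export
computeIsens <- function(tm, scale = FALSE) {
  m <- if (is(tm, "TStatMatrix")) tm@stats else as.matrix(tm)
  if (nrow(m) < 3) stop("need at least 3 families")
  if (all(apply(m, 2, var) < 1e-24)) {
    stop("no variation between families")
  }
  pc <- prcomp(m, center = TRUE, scale. = scale)
  rot <- pc$rotation
  scores <- pc$x
  bwCol <- grep("BW", colnames(m))
  orientCol <- if (length(bwCol)) bwCol[1] else 1
  if (rot[orientCol, 1] < 0) {
    rot[, 1] <- -rot[, 1]
    scores[, 1] <- -scores[, 1]
  }
  inertia <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * rot[, 1]^2
  new("SensitivityIndex",
    scores = setNames(scores[, 1], rownames(m)),
    inertia = inertia,
    contributions = setNames(contrib, colnames(m)),
    loadings = rot,
    scaled = scale)
}

#' Select the extreme robust and sensitive families
#'
#' The `k` families with the lowest sensitivity index form the robust
#' reference group and the `k` highest the sensitive one (ties broken
#' deterministically by family label).
#'
#' @param idx a [SensitivityIndex] or a named numeric vector of index
#'   values.
#' @param k families per extreme (default 2).
#' @return list with `robust` and `sensitive` character vectors.
#' @export
selectExtremes <- function(idx, k = 2) {
  s <- if (is(idx, "SensitivityIndex")) isensScores(idx) else idx
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("k must be > 0")
  k <- as.integer(k)
  if (length(s) < 2 * k) {
    stop("need at least 2k families (have ", length(s), ", k = ", k, ")")
  }
  ord <- order(s, names(s))
  list(
    robust = names(s)[ord[seq_len(k)]],
    sensitive = names(s)[rev(ord)[seq_len(k)]]
  )
}
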