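#' Remove a batch effect by parametric empirical Bayes
#'
#' Location/scale batch correction with empirical-Bayes shrinkage: each
#' feature is standardized by a linear model containing the batch and the
#' covariates, per-batch location and scale estimates are shrunk toward
#' pooled priors (normal prior on locations, inverse-gamma on scales,
#' hyper-parameters estimated from the across-feature moments, parametric
#' iterative updates), the shrunken effects are subtracted/rescaled and
#' the covariate fit restored.
#'
#' Features constant within every batch are passed through unchanged.
#' With a single batch level there is nothing to remove and the input is
#' returned as is. Features containing missing values are adjusted by a
#' plain per-feature location model on the complete cases (no shrinkage).
#'
#' @param X numeric matrix, features x samples.
#' @param batch factor (or coercible) of batch labels, one per sample;
#'   every level needs at least 2 samples.
#' @param covariates optional data.frame of factors whose fit must be
#'   preserved (e.g. climate, family, sex).
#' @param conv convergence tolerance of the EB iteration.
#' @return list with `adjusted` (same shape as `X`) and `model`
#'   (an [AdjustmentModel]).
#' @export
ebAdjust <- function(X, batch, covariates = NULL, conv = 1e-4) {
  X <- as.matrix(X)
  if (is.null(rownames(X)) || anyDuplicated(rownames(X)) ||
      any(rownames(X) == "")) {
    rownames(X) <- paste0("f", seq_len(nrow(X)))
  }
  batch <- droplevels(as.factor(batch))
  n <- ncol(X)
  if (length(batch) != n) stop("batch must have one entry per sample")
  nb <- nlevels(batch)
  p <- nrow(X)

  if (nb < 2) {
    model <- new("AdjustmentModel", batch = levels(batch),
      features = rownames(X),
      gammaStar = matrix(0, p, nb, dimnames = list(rownames(X),
        levels(batch))),
      deltaStar = matrix(1, p, nb, dimnames = list(rownames(X),
        levels(batch))),
      gammaHat = matrix(0, p, nb), deltaHat = matrix(1, p, nb),
      priors = list(), varPooled = rep(NA_real_, p),
      covariates = names(covariates) %||% character(0),
      passthrough = character(0))
    return(list(adjusted = X, model = model))
  }
  tab <- table(batch)
  if (any(tab < 2)) {
    stop("batch level(s) with a single sample: ",
      paste(names(tab)[tab < 2], collapse = ", "))
  }

  Bmat <- model.matrix(~ batch - 1)
  colnames(Bmat) <- levels(batch)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates[] <- lapply(covariates, function(v)
      if (is.numeric(v)) v else droplevels(as.factor(v)))
    covMat <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  } else {
    covMat <- matrix(0, n, 0)
  }
  covFull <- cbind("(Intercept)" = rep(1, n), covMat)
  qrC <- qr(covFull)
  if (qrC$rank < ncol(covFull)) {
    dropped <- colnames(covFull)[qrC$pivot[seq(qrC$rank + 1,
      ncol(covFull))]]
    stop("singular covariate design; collinear term(s): ",
      paste(dropped, collapse = ", "))
  }
  design <- cbind(Bmat, covMat)
  # when batches are nested in a covariate (e.g. contemporary groups
  # within climate) the joint design is singular; the covariate fit is
  # then estimated first and the batch model applied to its residuals,
  # so preserved effects never leak into the batch estimates
  joint <- qr(design)$rank == ncol(design)

  # per-feature handling of missing values: complete-case location model
  hasNA <- rowSums(!is.finite(X)) > 0
  Xadj <- X
  if (any(hasNA)) {
    for (i in which(hasNA)) {
      Xadj[i, ] <- locationAdjust(X[i, ], design, nb, tab)
    }
  }
  Xc <- X[!hasNA, , drop = FALSE]
  pc <- nrow(Xc)

  nk <- as.numeric(tab)
  if (joint) {
    Bhat <- solve(crossprod(design), crossprod(design, t(Xc)))
    grand <- as.numeric(crossprod(nk / n,
      Bhat[seq_len(nb), , drop = FALSE]))
    standMean <- matrix(grand, pc, n)
    if (ncol(covMat)) {
      standMean <- standMean +
        t(covMat %*% Bhat[-seq_len(nb), , drop = FALSE])
    }
    resid <- Xc - t(design %*% Bhat)
  } else {
    beta <- solve(crossprod(covFull), crossprod(covFull, t(Xc)))
    fitCov <- t(covFull %*% beta)
    R <- Xc - fitCov
    Bb <- solve(crossprod(Bmat), crossprod(Bmat, t(R)))
    grand0 <- as.numeric(crossprod(nk / n, Bb))
    standMean <- fitCov + matrix(grand0, pc, n)
    resid <- R - t(Bmat %*% Bb)
  }
  varPooled <- rowMeans(resid^2)

  # features with no within-batch variation cannot be standardized
  withinVar <- matrix(sapply(levels(batch), function(k) {
    idx <- batch == k
    apply(Xc[, idx, drop = FALSE], 1, var)
  }), nrow = pc)
  pass <- rowSums(withinVar > 1e-24) == 0 | varPooled < 1e-24
  act <- which(!pass)

  Z <- (Xc[act, , drop = FALSE] - standMean[act, , drop = FALSE]) /
    sqrt(varPooled[act])

  gammaHat <- (Z %*% Bmat) %*% diag(1 / nk, nb)
  deltaHat <- sapply(seq_len(nb), function(k)
    apply(Z[, batch == levels(batch)[k], drop = FALSE], 1, var))
  gammaHat <- matrix(gammaHat, ncol = nb)
  deltaHat <- matrix(deltaHat, ncol = nb)

  if (length(act) >= 2) {
    gammaBar <- colMeans(gammaHat)
    t2 <- apply(gammaHat, 2, var)
    m <- colMeans(deltaHat)
    s2 <- apply(deltaHat, 2, var)
    aPrior <- (2 * s2 + m^2) / s2
    bPrior <- (m * s2 + m^3) / s2
    gammaStar <- gammaHat
    deltaStar <- deltaHat
    for (k in seq_len(nb)) {
      if (!is.finite(t2[k]) || !is.finite(aPrior[k]) || s2[k] < 1e-24) next
      idx <- batch == levels(batch)[k]
      g <- gammaHat[, k]
      d <- deltaHat[, k]
      repeat {
        gNew <- (nk[k] * t2[k] * gammaHat[, k] + d * gammaBar[k]) /
          (nk[k] * t2[k] + d)
        sum2 <- rowSums((Z[, idx, drop = FALSE] - gNew)^2)
        dNew <- (0.5 * sum2 + bPrior[k]) / (nk[k] / 2 + aPrior[k] - 1)
        change <- max(abs(gNew - g) / (abs(g) + 1e-12),
          abs(dNew - d) / (abs(d) + 1e-12))
        g <- gNew
        d <- dNew
        if (change < conv) break
      }
      gammaStar[, k] <- g
      deltaStar[, k] <- d
    }
    priors <- list(gammaBar = gammaBar, t2 = t2, aPrior = aPrior,
      bPrior = bPrior)
  } else {
    # a single active feature: across-feature priors are undefined,
    # the location/scale estimates are used unshrunken
    gammaStar <- gammaHat
    deltaStar <- deltaHat
    priors <- list()
  }

  bi <- as.integer(batch)
  Zadj <- (Z - gammaStar[, bi, drop = FALSE]) /
    sqrt(deltaStar[, bi, drop = FALSE])
  XactAdj <- Zadj * sqrt(varPooled[act]) + standMean[act, , drop = FALSE]

  out <- Xc
  out[act, ] <- XactAdj
  Xadj[!hasNA, ] <- out

  featNames <- rownames(Xc)
  gFull <- matrix(0, pc, nb, dimnames = list(featNames, levels(batch)))
  dFull <- matrix(1, pc, nb, dimnames = list(featNames, levels(batch)))
  gHatF <- gFull
  dHatF <- dFull
  gFull[act, ] <- gammaStar
  dFull[act, ] <- deltaStar
  gHatF[act, ] <- gammaHat
  dHatF[act, ] <- deltaHat

  model <- new("AdjustmentModel",
    batch = levels(batch),
    features = featNames,
    gammaStar = gFull, deltaStar = dFull,
    gammaHat = gHatF, deltaHat = dHatF,
    priors = priors,
    varPooled = setNames(varPooled, featNames),
    covariates = names(covariates) %||% character(0),
    passthrough = c(featNames[pass], rownames(X)[hasNA]))
  list(adjusted = Xadj, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Non-EB fallback for features with missing values: remove the batch
# component of a least-squares fit on complete cases.
locationAdjust <- function(x, design, nb, tab) {
  ok <- is.finite(x)
  D <- design[ok, , drop = FALSE]
  beta <- qr.coef(qr(D), x[ok])
  beta[!is.finite(beta)] <- 0
  bcoef <- beta[seq_len(nb)]
  grand <- sum(as.numeric(tab) / sum(tab) * bcoef)
  x[ok] <- x[ok] - design[ok, seq_len(nb), drop = FALSE] %*% bcoef + grand
  x
}

#' Sequentially adjust a study for batch and sex effects
#'
#' Applies [ebAdjust()] to both data blocks of a study (traits and
#' buckets, each treated as a features x animals matrix): first for the
#' batch factor with climate, family and sex as preserved covariates,
#' then for sex with climate and family preserved. PVCA variance
#' fractions are computed before and after on each block so the removal
#' can be audited.
#'
#' @param study a [HeatStudy].
#' @param order character, which nuisance factor to remove first;
#'   `c("batch", "sex")` (default) or `c("sex", "batch")`.
#' @param runPvca logical; compute [pvca()] diagnostics (default TRUE).
#' @param pvcaThreshold cumulative-variance threshold passed to [pvca()].
#' @return list with `study` (adjusted [HeatStudy], labels preserved),
#'   `pvcaBefore`/`pvcaAfter` (lists over blocks, or NULL), and `models`
#'   (the fitted [AdjustmentModel]s per block and step).
#' @export
sequentialAdjust <- function(study, order = c("batch", "sex"),
                             runPvca = TRUE, pvcaThreshold = 0.6) {
  stopifnot(is(study, "HeatStudy"))
  order <- match.arg(order, c("batch", "sex"), several.ok = TRUE)
  if (length(order) != 2 || anyDuplicated(order)) {
    stop("order must be a permutation of c('batch', 'sex')")
  }
  cd <- colData(study)
  factors <- data.frame(
    climate = factor(cd$climate), family = factor(cd$family),
    batch = factor(cd$batch), sex = factor(cd$sex)
  )
  blocks <- list(
    phenotypes = traitMatrix(study),
    buckets = bucketMatrix(study)
  )
  pvcaBefore <- pvcaAfter <- NULL
  if (runPvca) {
    pvcaBefore <- lapply(blocks, function(b)
      pvca(b[stats::complete.cases(b), , drop = FALSE], factors,
        threshold = pvcaThreshold))
  }
  models <- list()
  for (i in seq_along(order)) {
    step <- order[i]
    # the nuisance factor not yet removed is preserved as a covariate in
    # the first pass (batch pass keeps climate + family + sex); once a
    # factor has been removed it is dropped from the covariate design
    covNames <- c("climate", "family",
      setdiff(c("batch", "sex"), order[seq_len(i)]))
    for (nm in names(blocks)) {
      fit <- ebAdjust(blocks[[nm]], batch = factors[[step]],
        covariates = factors[, covNames, drop = FALSE])
      models[[paste(nm, step, sep = ".")]] <- fit$model
      blocks[[nm]] <- fit$adjusted
    }
  }
  if (runPvca) {
    pvcaAfter <- lapply(blocks, function(b)
      pvca(b[stats::complete.cases(b), , drop = FALSE], factors,
        threshold = pvcaThreshold))
  }
  adj <- study
  assay(adj, "buckets") <- blocks$buckets
  tm <- blocks$phenotypes
  for (t in rownames(tm)) colData(adj)[[t]] <- as.numeric(tm[t, ])
  list(study = adj, pvcaBefore = pvcaBefore, pvcaAfter = pvcaAfter,
    models = models)
}
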