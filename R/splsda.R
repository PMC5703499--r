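#' Fit a sparse PLS-DA model
#'
#' Two-class sparse partial least squares discriminant analysis. The
#' predictor matrix is centered and unit-variance scaled and the class
#' factor dummy-coded and centered; per component, the X-weight is the
#' dominant singular direction of the X'Y covariance, soft-thresholded so
#' that exactly `keepX[h]` entries stay nonzero (the retained magnitudes
#' are shrunk by the (keepX+1)-th largest magnitude, a Lasso-like
#' penalty with an exact-cardinality parameterization) and renormalized
#' to unit norm; scores are `t = X w`, and both X and Y are deflated by
#' regression on `t` (regression mode). With `keepX = ncol(X)` the fit
#' reduces to a dense PLS-DA.
#'
#' @param X numeric matrix, samples x buckets, no missing values;
#'   colnames identify the buckets.
#' @param y class labels, coercible to a 2-level factor; the second
#'   level is treated as the positive ("sensitive") class.
#' @param keepX integer vector, number of buckets retained per component;
#'   its length sets the number of components.
#' @return an [SplsdaModel].
#' @seealso [predict,SplsdaModel-method], [vip()], [crossValidate()]
#' @export
splsda <- function(X, y, keepX = rep(ncol(X), 2)) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("y must have exactly 2 classes")
  if (length(y) != nrow(X)) stop("X and y sizes differ")
  if (any(!is.finite(X))) stop("X contains missing or non-finite values")
  p <- ncol(X)
  keepX <- as.integer(keepX)
  H <- length(keepX)
  if (any(keepX < 1) || any(keepX > p)) {
    stop("keepX entries must lie in [1, ", p, "]")
  }
  cx <- colMeans(X)
  sx <- apply(X, 2, sd)
  if (any(sx < 1e-12)) {
    stop("constant bucket(s), scaling undefined: ",
      paste(colnames(X)[sx < 1e-12], collapse = ", "))
  }
  Xs <- scale(X, center = cx, scale = sx)
  Y <- model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  yMeans <- colMeans(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)

  n <- nrow(Xs)
  ssX0 <- sum(Xs^2)
  W <- C <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
  D <- matrix(0, 2, H, dimnames = list(levels(y), NULL))
  Tm <- matrix(0, n, H, dimnames = list(rownames(X), NULL))
  explX <- explY <- numeric(H)
  Xd <- Xs
  Yd <- Yc
  for (h in seq_len(H)) {
    M <- crossprod(Xd, Yd)
    sv <- svd(M, nu = 1, nv = 1)
    w <- sv$u[, 1]
    # deterministic sign: dominant entry positive
    if (w[which.max(abs(w))] < 0) w <- -w
    w <- softThreshold(w, keepX[h])
    w <- w / sqrt(sum(w^2))
    t <- as.numeric(Xd %*% w)
    tt <- sum(t^2)
    cc <- as.numeric(crossprod(Xd, t)) / tt
    dd <- as.numeric(crossprod(Yd, t)) / tt
    Xd <- Xd - tcrossprod(t, cc)
    Yd <- Yd - tcrossprod(t, dd)
    W[, h] <- w
    C[, h] <- cc
    D[, h] <- dd
    Tm[, h] <- t
    explX[h] <- tt * sum(cc^2) / ssX0
    explY[h] <- tt * sum(dd^2)
  }
  centroids <- rbind(
    colMeans(Tm[y == levels(y)[1], , drop = FALSE]),
    colMeans(Tm[y == levels(y)[2], , drop = FALSE])
  )
  rownames(centroids) <- levels(y)
  new("SplsdaModel",
    weights = W, xLoadings = C, yLoadings = D, scores = Tm,
    keepX = keepX, center = cx, scale = sx,
    yLevels = levels(y), y = y, yMeans = yMeans,
    centroids = centroids, explVarX = explX, explVarY = explY)
}

# Keep the k largest |w|, shrink them toward zero by the (k+1)-th largest
# magnitude, zero the rest. Exact ties at the boundary keep their rank
# order (stable), and shrunken magnitudes are floored at a tiny positive
# value so the nonzero count is exactly k.
softThreshold <- function(w, k) {
  p <- length(w)
  if (k >= p) return(w)
  ord <- order(abs(w), decreasing = TRUE)
  keep <- ord[seq_len(k)]
  lambda <- max(abs(w[ord[k + 1]]), 0)
  out <- numeric(p)
  out[keep] <- sign(w[keep]) *
    pmax(abs(w[keep]) - lambda, .Machine$double.xmin)
  out
}

#' Predict classes and continuous scores for new samples
#'
#' New samples are standardized by the training statistics, projected
#' through the deflation sequence to latent scores, and classified by the
#' nearest training-class centroid in score space (default) or by the
#' maximum predicted dummy response. The continuous score used for ROC
#' thresholds is the predicted-response margin of the positive class.
#'
#' @param object an [SplsdaModel].
#' @param newdata samples x buckets matrix containing the training
#'   buckets (matched by name; extra columns are ignored).
#' @param rule `"centroid"` (default) or `"response"`.
#' @return list with `class` (factor), `score` (numeric, larger means
#'   more confidently positive) and `scores` (latent score matrix).
#' @export
setMethod("predict", "SplsdaModel",
  function(object, newdata, rule = c("centroid", "response")) {
  rule <- match.arg(rule)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object@center)) {
      stop("newdata without colnames must match the training width")
    }
    colnames(newdata) <- names(object@center)
  }
  miss <- setdiff(names(object@center), colnames(newdata))
  if (length(miss)) {
    stop("newdata is missing training bucket(s): ",
      paste(head(miss, 10), collapse = ", "),
      if (length(miss) > 10) paste0(" (and ", length(miss) - 10, " more)"))
  }
  Xn <- newdata[, names(object@center), drop = FALSE]
  Xn <- scale(Xn, center = object@center, scale = object@scale)
  H <- ncol(object@weights)
  n <- nrow(Xn)
  Tnew <- matrix(0, n, H)
  Xd <- Xn
  for (h in seq_len(H)) {
    t <- as.numeric(Xd %*% object@weights[, h])
    Xd <- Xd - tcrossprod(t, object@xLoadings[, h])
    Tnew[, h] <- t
  }
  Yhat <- Tnew %*% t(object@yLoadings)
  Yhat <- sweep(Yhat, 2, object@yMeans, "+")
  colnames(Yhat) <- object@yLevels
  score <- Yhat[, 2] - Yhat[, 1]
  cls <- switch(rule,
    centroid = {
      d1 <- rowSums(sweep(Tnew, 2, object@centroids[1, ])^2)
      d2 <- rowSums(sweep(Tnew, 2, object@centroids[2, ])^2)
      ifelse(d2 < d1, object@yLevels[2], object@yLevels[1])
    },
    response = object@yLevels[max.col(Yhat, ties.method = "first")]
  )
  list(
    class = factor(cls, levels = object@yLevels),
    score = setNames(as.numeric(score), rownames(newdata)),
    scores = Tnew
  )
})

#' Balanced error rate
#'
#' `BER = 1 - 0.5 * (sensitivity + specificity)`, i.e. the average of the
#' two class-wise error rates — robust to class imbalance.
#'
#' @param tp,fn,tn,fp confusion counts (positives: `tp + fn > 0`;
#'   negatives: `tn + fp > 0`).
#' @return balanced error rate in `[0, 1]`.
#' @examples
#' ber(9, 1, 8, 2)  # 0.15
#' @export
ber <- function(tp, fn, tn, fp) {
  if (tp + fn <= 0 || tn + fp <= 0) {
    stop("both classes must be represented (tp + fn > 0 and tn + fp > 0)")
  }
  1 - 0.5 * (tp / (tp + fn) + tn / (tn + fp))
}

# ROC curve from pooled continuous scores; positive predicted when
# score >= threshold, thresholds swept over the observed scores.
rocCurve <- function(score, truth, positive) {
  pos <- truth == positive
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  # collapse tied scores to single operating points
  last <- !duplicated(score[ord], fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  data.frame(fpr = fpr, tpr = tpr)
}

trapezoidAuc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Tune the per-component number of selected buckets
#'
#' Sequential cross-validated tuning of `keepX`: with the sizes of
#' components `1..h-1` frozen at their chosen values, every candidate
#' size for component `h` is evaluated by stratified repeated k-fold
#' cross-validation, and the smallest size whose mean balanced error rate
#' is within `tol` of the minimum is chosen (the "minimum number of
#' buckets with the lowest BER" rule).
#'
#' @param X samples x buckets matrix.
#' @param y 2-level class factor.
#' @param ncomp number of components to tune (default 3).
#' @param grid candidate sizes (default 5 to 20).
#' @param folds,repeats cross-validation layout.
#' @param seed integer seed for the fold draws.
#' @param rule prediction rule passed to the predictor.
#' @param tol BER tolerance of the "lowest" rule.
#' @return list with `keepX` (chosen sizes) and `curves` (data.frame of
#'   component, size, mean BER — the tuning-curve analogue).
#' @export
tuneKeepX <- function(X, y, ncomp = 3, grid = 5:20, folds = 10,
                      repeats = 3, seed = 1, rule = "centroid",
                      tol = 1e-3) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1) || any(grid > ncol(X))) {
    stop("grid must lie within [1, ", ncol(X), "]")
  }
  if (nrow(X) < folds) stop("fewer samples than folds")
  foldSets <- lapply(subSeeds(seed, repeats), function(s)
    withSeed(s, stratifiedFolds(y, folds)))
  chosen <- integer(0)
  curves <- list()
  for (h in seq_len(ncomp)) {
    meanBer <- sapply(grid, function(size) {
      keepX <- c(chosen, size)
      bers <- unlist(lapply(foldSets, function(fa) {
        sapply(seq_len(folds), function(k) {
          tr <- fa != k
          fit <- splsda(X[tr, , drop = FALSE], y[tr], keepX)
          pr <- predict(fit, X[!tr, , drop = FALSE], rule = rule)
          confusionBer(pr$class, y[!tr], levels(y)[2])
        })
      }))
      mean(bers)
    })
    best <- grid[meanBer <= min(meanBer) + tol][1]
    chosen <- c(chosen, best)
    curves[[h]] <- data.frame(component = h, size = grid, ber = meanBer)
  }
  list(keepX = chosen, curves = do.call(rbind, curves))
}

confusionBer <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  ber(tp, fn, tn, fp)
}

#' Cross-validate a sparse PLS-DA model
#'
#' Stratified repeated k-fold cross-validation at fixed `keepX`: per
#' resample the model is refit on the training folds and the held-out
#' fold predicted; confusion counts are pooled into BER, sensitivity and
#' specificity; the pooled continuous scores give the ROC curve and its
#' trapezoid AUC; and each bucket's selection-stability frequency is the
#' fraction of the `folds x repeats` fits that selected it on any
#' component.
#'
#' @param X samples x buckets matrix.
#' @param y 2-level class factor (second level = positive class).
#' @param keepX per-component selection sizes.
#' @param folds,repeats layout (default 10 x 10, i.e. 100 resample fits).
#' @param seed integer seed; a fixed seed makes the report reproducible.
#' @param rule prediction rule.
#' @return a [CvReport].
#' @export
crossValidate <- function(X, y, keepX, folds = 10, repeats = 10,
                          seed = 1, rule = "centroid") {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  pos <- levels(y)[2]
  foldSets <- lapply(subSeeds(seed, repeats), function(s)
    withSeed(s, stratifiedFolds(y, folds)))
  conf <- c(TP = 0, FN = 0, TN = 0, FP = 0)
  scoreAll <- numeric(0)
  truthAll <- character(0)
  selCount <- setNames(numeric(ncol(X)), colnames(X))
  nFits <- 0L
  for (fa in foldSets) {
    for (k in seq_len(folds)) {
      tr <- fa != k
      fit <- splsda(X[tr, , drop = FALSE], y[tr], keepX)
      pr <- predict(fit, X[!tr, , drop = FALSE], rule = rule)
      tv <- y[!tr]
      conf <- conf + c(
        TP = sum(pr$class == pos & tv == pos),
        FN = sum(pr$class != pos & tv == pos),
        TN = sum(pr$class != pos & tv != pos),
        FP = sum(pr$class == pos & tv != pos)
      )
      scoreAll <- c(scoreAll, pr$score)
      truthAll <- c(truthAll, as.character(tv))
      selCount[selectedBuckets(fit)] <- selCount[selectedBuckets(fit)] + 1
      nFits <- nFits + 1L
    }
  }
  roc <- rocCurve(scoreAll, truthAll, pos)
  new("CvReport",
    confusion = conf,
    ber = ber(conf["TP"], conf["FN"], conf["TN"], conf["FP"]),
    sensitivity = unname(conf["TP"] / (conf["TP"] + conf["FN"])),
    specificity = unname(conf["TN"] / (conf["TN"] + conf["FP"])),
    roc = roc, auc = trapezoidAuc(roc),
    stability = selCount / nFits,
    nResamples = nFits,
    folds = as.integer(folds), repeats = as.integer(repeats))
}

#' Variable importance in projection
#'
#' Standard PLS VIP over all components:
#' `VIP_j = sqrt( p * sum_h SS_h w_jh^2 / sum_h SS_h )` with `SS_h` the Y
#' sum of squares explained by component h and unit-norm weights, so that
#' `mean(VIP^2) = 1`. Buckets with VIP > 1 are conventionally read as
#' important contributors.
#'
#' @param model an [SplsdaModel].
#' @return named numeric vector of VIP scores, one per bucket.
#' @export
vip <- function(model) {
  stopifnot(is(model, "SplsdaModel"))
  ss <- model@explVarY
  if (sum(ss) <= 0) stop("model explains no Y variance")
  W2 <- model@weights^2
  p <- nrow(W2)
  setNames(sqrt(p * as.numeric(W2 %*% ss) / sum(ss)),
    rownames(model@weights))
}
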