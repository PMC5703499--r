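# Independent oracles and shared fixtures, built in code at test time.

# Dense PLS-DA reference by NIPALS power iteration (independent of the
# package's svd-based fit): standardized X, centered dummy Y, regression
# -mode deflation.
densePlsOracle <- function(X, y, ncomp = 2) {
  Xs <- scale(as.matrix(X))
  Y <- model.matrix(~ factor(y) - 1)
  Yd <- scale(Y, center = TRUE, scale = FALSE)
  Xd <- Xs
  n <- nrow(Xs)
  p <- ncol(Xs)
  W <- C <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  D <- matrix(0, ncol(Y), ncomp)
  for (h in seq_len(ncomp)) {
    u <- Yd[, 1]
    w <- rep(1 / sqrt(p), p)
    for (it in 1:500) {
      w.new <- as.numeric(crossprod(Xd, u))
      w.new <- w.new / sqrt(sum(w.new^2))
      t <- as.numeric(Xd %*% w.new)
      q <- as.numeric(crossprod(Yd, t)) / sum(t^2)
      u <- as.numeric(Yd %*% q) / sum(q^2)
      if (sum((w.new - w)^2) < 1e-24) {
        w <- w.new
        break
      }
      w <- w.new
    }
    t <- as.numeric(Xd %*% w)
    cc <- as.numeric(crossprod(Xd, t)) / sum(t^2)
    dd <- as.numeric(crossprod(Yd, t)) / sum(t^2)
    Xd <- Xd - tcrossprod(t, cc)
    Yd <- Yd - tcrossprod(t, dd)
    W[, h] <- w
    C[, h] <- cc
    D[, h] <- dd
    Tm[, h] <- t
  }
  list(weights = W, loadings = C, yloadings = D, scores = Tm)
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(q, 1))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Two Gaussian classes separated on `nInf` planted buckets among `p`.
plantedData <- function(n = 100, p = 100, nInf = 2, delta = 3, seed = 42) {
  set.seed(seed)
  y <- factor(rep(c("robust", "sensitive"), each = n / 2))
  X <- matrix(rnorm(n * p), n, p,
    dimnames = list(sprintf("s%03d", seq_len(n)),
      sprintf("b%03d", seq_len(p))))
  X[y == "sensitive", seq_len(nInf)] <- X[y == "sensitive",
    seq_len(nInf)] + delta
  list(X = X, y = y, informative = sprintf("b%03d", seq_len(nInf)))
}

# A small study configuration keeping simulation-based tests fast.
smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nFamilies = 6, offspringPerCell = 20, offspringSD = 3,
    nBatchesTemp = 4, nBatchesTrop = 4, nBuckets = 60, nInformative = 10,
    seed = 1)
  do.call(studyConfig, utils::modifyList(defaults, args))
}
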