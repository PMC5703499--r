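#' Principal variance component analysis
#'
#' Attributes the variance of a feature matrix to design factors: a PCA
#' of the (feature-centered) data retains the fewest principal components
#' whose cumulative variance reaches `threshold`; each retained PC score
#' vector is decomposed by a REML random-effects model with every factor
#' as an independent random intercept (interactions excluded, negative
#' components truncated at zero by the fitter); the per-PC variance
#' fractions are averaged with eigenvalue weights and scaled to percent
#' (WAPV, "weighted average proportion of variance").
#'
#' The result is invariant to scaling all features by a positive
#' constant. Factors with fewer than two levels contribute zero.
#'
#' @param X numeric matrix, features x samples.
#' @param factors data.frame of categorical factors, one row per sample
#'   (e.g. climate, family, batch, sex).
#' @param threshold cumulative variance fraction in (0, 1] deciding how
#'   many PCs are retained (default 0.60).
#' @param scaleFeatures standardize features to unit variance before the
#'   PCA (default TRUE; essential when features are on different units,
#'   as trait panels are). Zero-variance features are dropped.
#' @return a [PvcaResult]; `wapv(x)` gives the percent per factor plus
#'   `"residual"`, summing to 100.
#' @export
pvca <- function(X, factors, threshold = 0.6, scaleFeatures = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  X <- as.matrix(X)
  factors <- as.data.frame(factors)
  if (ncol(X) != nrow(factors)) {
    stop("factors must have one row per sample (column of X)")
  }
  factors[] <- lapply(factors, function(v) droplevels(as.factor(v)))
  usable <- vapply(factors, nlevels, 0L) >= 2
  if (!any(usable)) stop("no factor with at least 2 levels")

  if (scaleFeatures) {
    sds <- apply(X, 1, sd)
    X <- X[sds > 1e-12, , drop = FALSE] / sds[sds > 1e-12]
  }
  Xc <- X - rowMeans(X)
  p <- nrow(Xc)
  n <- ncol(Xc)
  if (p <= n) {
    e <- eigen(tcrossprod(Xc) / (n - 1), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    scores <- crossprod(Xc, e$vectors)
  } else {
    e <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    scores <- e$vectors
  }
  pos <- lam > max(lam) * 1e-12
  lam <- lam[pos]
  scores <- scores[, pos, drop = FALSE]
  k <- which(cumsum(lam) / sum(lam) >= threshold - 1e-12)[1]
  k <- max(1L, k)

  terms <- names(factors)[usable]
  form <- stats::as.formula(paste("score ~",
    paste(sprintf("(1 | %s)", terms), collapse = " + ")))
  fracs <- matrix(0, nrow = length(terms) + 1, ncol = k,
    dimnames = list(c(terms, "residual"), NULL))
  dat <- factors
  for (i in seq_len(k)) {
    dat$score <- scores[, i]
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(form, data = dat, REML = TRUE,
        control = lme4::lmerControl(calc.derivs = FALSE,
          check.conv.singular = "ignore"))
    ))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
      vc$grp))
    fracs[names(v), i] <- v / sum(v)
  }
  w <- lam[seq_len(k)] / sum(lam[seq_len(k)])
  wapv <- as.numeric(fracs %*% w) * 100
  names(wapv) <- rownames(fracs)
  full <- setNames(numeric(ncol(factors) + 1),
    c(names(factors), "residual"))
  full[names(wapv)] <- wapv
  new("PvcaResult", wapv = full, nPC = as.integer(k),
    weights = w, threshold = threshold)
}
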