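test_that("saturated keepX reproduces the dense PLS-DA oracle to 1e-8", {
  pd <- plantedData(n = 40, p = 15, nInf = 3, delta = 1, seed = 51)
  fit <- splsda(pd$X, pd$y, keepX = c(15, 15))
  ref <- densePlsOracle(pd$X, pd$y, ncomp = 2)
  for (h in 1:2) {
    sgn <- sign(sum(fit@weights[, h] * ref$weights[, h]))
    expect_lt(max(abs(fit@weights[, h] - sgn * ref$weights[, h])), 1e-8)
    expect_lt(max(abs(fit@scores[, h] - sgn * ref$scores[, h])), 1e-8)
    expect_lt(max(abs(fit@xLoadings[, h] - sgn * ref$loadings[, h])), 1e-8)
  }
})

test_that("one-component dense PLS equals the closed-form X'y direction", {
  pd <- plantedData(n = 30, p = 10, nInf = 2, delta = 1, seed = 52)
  fit <- splsda(pd$X, pd$y, keepX = 10)
  Xs <- scale(pd$X)
  Yc <- scale(model.matrix(~ pd$y - 1), center = TRUE, scale = FALSE)
  # the dominant singular direction of X'Y for a centered two-class dummy
  # is proportional to X' d where d is the class contrast
  w <- as.numeric(crossprod(Xs, Yc[, 2] - Yc[, 1]))
  w <- w / sqrt(sum(w^2))
  sgn <- sign(sum(w * fit@weights[, 1]))
  expect_lt(max(abs(fit@weights[, 1] - sgn * w)), 1e-10)
})

test_that("sparsity contract: exactly keepX nonzeros, unit norms, orthogonal scores", {
  pd <- plantedData(n = 60, p = 50, nInf = 4, delta = 1.5, seed = 53)
  fit <- splsda(pd$X, pd$y, keepX = c(7, 13, 21))
  expect_equal(unname(colSums(fit@weights != 0)), c(7, 13, 21))
  expect_equal(unname(sqrt(colSums(fit@weights^2))), rep(1, 3),
    tolerance = 1e-12)
  cc <- cor(fit@scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
})

test_that("planted support is recovered exactly and predicts the training data", {
  pd <- plantedData()
  fit <- splsda(pd$X, pd$y, keepX = 2)
  expect_setequal(selectedBuckets(fit, 1), pd$informative)
  pr <- predict(fit, pd$X)
  expect_lte(sum(pr$class != pd$y), 1)

  # raw-space class centroid maps to its own class
  cen <- colMeans(pd$X[pd$y == "sensitive", ])
  prc <- predict(fit, matrix(cen, 1, dimnames = list("c", names(cen))))
  expect_equal(as.character(prc$class), "sensitive")

  # permuting columns (with labels) leaves predictions unchanged
  perm <- sample(ncol(pd$X))
  pr2 <- predict(fit, pd$X[, perm])
  expect_identical(pr2$class, pr$class)
  expect_error(predict(fit, pd$X[, 1:50]), "missing training bucket")
})

test_that("degenerate fits are rejected with informative errors", {
  pd <- plantedData(n = 30, p = 10)
  expect_error(splsda(pd$X, pd$y, keepX = 11), "keepX")
  expect_error(splsda(pd$X, factor(rep("one", 30)), keepX = 2),
    "2 classes")
  Xc <- pd$X
  Xc[, 3] <- 7
  expect_error(splsda(Xc, pd$y, keepX = 2), "b003")
  Xna <- pd$X
  Xna[1, 1] <- NA
  expect_error(splsda(Xna, pd$y, keepX = 2), "missing")
})

test_that("the balanced error rate follows its definition", {
  expect_equal(ber(10, 0, 10, 0), 0)
  expect_equal(ber(5, 5, 5, 5), 0.5)
  expect_equal(ber(9, 1, 8, 2), 0.15)
  expect_error(ber(0, 0, 5, 5), "both classes")
})

test_that("cross-validation separates planted data and is seed-reproducible", {
  pd <- plantedData()
  cv1 <- crossValidate(pd$X, pd$y, keepX = 2, folds = 5, repeats = 3,
    seed = 9)
  cv2 <- crossValidate(pd$X, pd$y, keepX = 2, folds = 5, repeats = 3,
    seed = 9)
  expect_identical(cv1@confusion, cv2@confusion)
  expect_identical(stability(cv1), stability(cv2))
  expect_lt(cv1@ber, 0.05)
  expect_gt(cv1@auc, 0.99)
  expect_equal(unname(stability(cv1)[pd$informative]), c(1, 1))
  expect_lte(median(stability(cv1)[setdiff(names(stability(cv1)),
    pd$informative)]), 0.1)
  # stability frequencies are multiples of 1/nResamples
  expect_equal(stability(cv1) * cv1@nResamples,
    round(stability(cv1) * cv1@nResamples), tolerance = 1e-9)
})

test_that("the trapezoid AUC matches pROC and is invariant to monotone transforms", {
  set.seed(56)
  score <- rnorm(80)
  truth <- ifelse(runif(80) < plogis(2 * score), "pos", "neg")
  auc1 <- metaboSens:::trapezoidAuc(metaboSens:::rocCurve(score, truth,
    "pos"))
  auc2 <- metaboSens:::trapezoidAuc(metaboSens:::rocCurve(exp(3 * score),
    truth, "pos"))
  expect_equal(auc1, auc2, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, levels = c("neg",
    "pos"), direction = "<", quiet = TRUE)))
  expect_equal(auc1, ref, tolerance = 1e-10)
})

test_that("keepX tuning is parsimonious on separable data and flat on noise", {
  pd <- plantedData()
  tn <- tuneKeepX(pd$X, pd$y, ncomp = 1, grid = 1:10, folds = 5,
    repeats = 2, seed = 3)
  expect_lte(tn$keepX[1], 3)
  expect_true(all(tn$curves$size %in% 1:10))

  set.seed(54)
  Xn <- matrix(rnorm(200 * 60), 200, 60,
    dimnames = list(NULL, sprintf("b%02d", 1:60)))
  yn <- factor(rep(c("a", "b"), each = 100))
  tn2 <- tuneKeepX(Xn, yn, ncomp = 1, grid = seq(5, 20, by = 3),
    folds = 5, repeats = 2, seed = 4)
  expect_lt(max(tn2$curves$ber) - min(tn2$curves$ber), 0.15)
  expect_error(tuneKeepX(pd$X, pd$y, grid = 200), "grid")
})

test_that("VIP obeys its algebraic identities and ranks planted buckets first", {
  pd <- plantedData(n = 80, p = 40, nInf = 3, delta = 2, seed = 55)
  fit <- splsda(pd$X, pd$y, keepX = c(40, 40))
  v <- vip(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-12)
  expect_equal(sum(v^2), 40, tolerance = 1e-10)
  sparse <- splsda(pd$X, pd$y, keepX = c(3, 5))
  vs <- vip(sparse)
  expect_setequal(names(sort(vs, decreasing = TRUE))[1:3],
    pd$informative)
  # single component with uniform weights gives VIP = 1 everywhere
  uni <- sparse
  uni@weights <- matrix(rep(1 / 2, 4), 4, 1,
    dimnames = list(letters[1:4], NULL))
  uni@keepX <- 4L
  uni@explVarY <- 1
  expect_equal(unname(vip(uni)), rep(1, 4), tolerance = 1e-12)
})

test_that("dense fits agree with the reference mixOmics PLS-DA up to component sign", {
  skip_if_not_installed("mixOmics")
  pd <- plantedData(n = 40, p = 15, nInf = 3, delta = 1, seed = 57)
  fit <- splsda(pd$X, pd$y, keepX = c(15, 15))
  mo <- suppressMessages(mixOmics::plsda(pd$X, pd$y, ncomp = 2,
    scale = TRUE))
  for (h in 1:2) {
    expect_gt(abs(cor(fit@scores[, h], mo$variates$X[, h])), 1 - 1e-8)
  }
})
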