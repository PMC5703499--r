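test_that("a pure additive batch offset is removed (up to the preserved grand mean)", {
  set.seed(3)
  X0 <- matrix(rnorm(60 * 200), 60, 200)
  off <- 2
  Xoff <- X0
  Xoff[, 101:200] <- Xoff[, 101:200] + off
  b <- factor(rep(1:2, each = 100))
  a1 <- ebAdjust(Xoff, b)$adjusted
  a0 <- ebAdjust(X0, b)$adjusted
  # the adjustment preserves the batch-size-weighted grand mean, so the
  # two adjusted matrices differ by the constant off * n2/n everywhere
  expect_lt(max(abs(a1 - a0 - off * 0.5)), 0.05 * off)
})

test_that("a single batch level is a no-op and tiny batches are rejected", {
  X <- matrix(rnorm(60), 6, 10)
  one <- ebAdjust(X, rep("b1", 10))
  expect_equal(one$adjusted, X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(ebAdjust(X, c(rep("a", 9), "b")), "single sample")
})

test_that("EB location estimates are shrunken but bracket zero and the raw difference", {
  set.seed(11)
  n <- 30
  X <- matrix(rnorm(2 * n, sd = 1), 1, 2 * n)
  X[, (n + 1):(2 * n)] <- X[, (n + 1):(2 * n)] + 10
  b <- factor(rep(1:2, each = n))
  fit <- ebAdjust(X, b)
  gs <- fit$model@gammaStar[1, ] * sqrt(fit$model@varPooled[1])
  rawDiff <- mean(X[1, b == 2]) - mean(X[1, b == 1])
  # batch effects are expressed around the grand mean: each gamma* sits
  # strictly between 0 and the raw batch-mean difference in magnitude
  expect_true(all(abs(gs) > 0))
  expect_true(all(abs(gs) < abs(rawDiff)))
  expect_gt(gs[2], 0)
  expect_lt(gs[1], 0)
})

test_that("parametric EB matches the reference ComBat implementation", {
  skip_if_not_installed("sva")
  set.seed(2)
  p <- 50
  X <- matrix(rnorm(p * 60), p, 60)
  batch <- factor(rep(1:3, each = 20))
  cov <- data.frame(g = factor(rep(c("a", "b"), 30)))
  X[, batch == 2] <- X[, batch == 2] + 0.8
  X[, batch == 3] <- X[, batch == 3] * 1.4
  mine <- ebAdjust(X, batch, cov)$adjusted
  ref <- suppressMessages(sva::ComBat(X, batch = batch,
    mod = model.matrix(~g, cov), par.prior = TRUE))
  expect_lt(max(abs(mine - ref)), 1e-5)
})

test_that("re-adjusting adjusted data changes little (approximate idempotence)", {
  set.seed(4)
  X <- matrix(rnorm(80 * 60), 80, 60)
  b <- factor(rep(1:3, each = 20))
  X[, b == 2] <- X[, b == 2] + 1
  once <- ebAdjust(X, b)$adjusted
  twice <- ebAdjust(once, b)$adjusted
  d1 <- norm(once - X, "F") / norm(X, "F")
  d2 <- norm(twice - once, "F") / norm(once, "F")
  # EB shrinkage leaves a residual of order (1 - shrinkage): the second
  # pass must be far smaller than the first, though not exactly zero
  expect_lt(d2, d1 / 5)
  expect_lt(d2, 0.05)
})

test_that("covariate-explained group structure survives the adjustment", {
  # strong climate x family signal over many features, crossed batches
  set.seed(6)
  n <- 240
  climate <- factor(rep(c("TEMP", "TROP"), each = n / 2))
  family <- factor(rep(rep(paste0("SF", 1:4), each = n / 8), 2))
  batch <- factor(rep(1:4, n / 4))
  p <- 100
  eff <- matrix(rnorm(p * 8, sd = 4), p, 8)
  cell <- as.integer(interaction(climate, family))
  X <- eff[, cell] + matrix(rnorm(p * n), p, n)
  X[, batch == 2] <- X[, batch == 2] + 1.5
  adj <- ebAdjust(X, batch,
    covariates = data.frame(climate = climate, family = family))$adjusted
  cm <- function(M) sapply(1:8, function(k)
    mean(M[, cell == k, drop = FALSE]))
  beforeAll <- cm(X) - c(tapply(as.numeric(batch == 2) * 1.5, cell, mean))
  after <- cm(adj)
  # compare cell-mean *structure*: the adjustment redistributes the
  # removed batch mass into the preserved weighted grand mean
  d <- (after - mean(after)) - (beforeAll - mean(beforeAll))
  expect_lt(max(abs(d)), 0.01 * diff(range(beforeAll)))
})

test_that("features constant within all batches pass through; collinear covariates error", {
  X <- rbind(matrix(rnorm(40), 4, 10), rep(5, 10))
  rownames(X) <- paste0("feat", 1:5)
  b <- factor(rep(1:2, each = 5))
  fit <- ebAdjust(X, b)
  expect_equal(fit$adjusted[5, ], X[5, ])
  expect_true("feat5" %in% fit$model@passthrough)
  cov <- data.frame(u = factor(rep(c("x", "y"), 5)),
    v = factor(rep(c("x", "y"), 5)))
  expect_error(ebAdjust(X, b, cov), "collinear")
})

test_that("sequential adjustment removes batch and sex variance but keeps climate", {
  cfg <- smallConfig(nFamilies = 6, offspringPerCell = 30, nBuckets = 80,
    seed = 12)
  st <- generateStudy(cfg)$study
  adj <- sequentialAdjust(st)
  for (block in c("phenotypes", "buckets")) {
    after <- wapv(adj$pvcaAfter[[block]])
    expect_lt(after["batch"], 1)
    expect_lt(after["sex"], 1)
  }
  expect_identical(dimnames(bucketMatrix(adj$study)),
    dimnames(bucketMatrix(st)))
  expect_identical(rownames(phenotypeTable(adj$study)),
    rownames(phenotypeTable(st)))
})

test_that("zero nuisance effects leave the data essentially untouched", {
  cfg <- smallConfig(seed = 13, offspringPerCell = 40, batchSD = 0,
    sexEffect = 0, bucketBatchSD = 0, bucketSexSD = 0)
  st <- generateStudy(cfg)$study
  adj <- sequentialAdjust(st, runPvca = FALSE)$study
  relB <- norm(bucketMatrix(adj) - bucketMatrix(st), "F") /
    norm(bucketMatrix(st), "F")
  relT <- norm(traitMatrix(adj) - traitMatrix(st), "F") /
    norm(traitMatrix(st), "F")
  expect_lt(relB, 0.05)
  expect_lt(relT, 0.05)
})

test_that("misaligned animal ids are reported", {
  cfg <- smallConfig(seed = 1)
  st <- generateStudy(cfg)$study
  ph <- phenotypeTable(st)
  rownames(ph)[1] <- "GHOST"
  expect_error(HeatStudy(bucketMatrix(st), ph), "GHOST")
})
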