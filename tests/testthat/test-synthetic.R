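test_that("generation is deterministic under a fixed seed and respects the design", {
  cfg <- smallConfig(seed = 7)
  a <- generateStudy(cfg)
  b <- generateStudy(cfg)
  expect_identical(bucketMatrix(a$study), bucketMatrix(b$study))
  expect_identical(phenotypeTable(a$study), phenotypeTable(b$study))
  expect_identical(a$truth, b$truth)
  c <- generateStudy(smallConfig(seed = 8))
  expect_false(identical(bucketMatrix(a$study), bucketMatrix(c$study)))

  st <- a$study
  tab <- table(st$family, st$climate)
  expect_equal(dim(tab), c(6, 2))
  expect_true(all(tab >= 10))
  expect_setequal(unique(st$climate), c("TEMP", "TROP"))
  expect_setequal(unique(st$sex), c("female", "castrated male"))
  tm <- traitMatrix(st)
  expect_true(all(is.finite(tm)))
  expect_equal(rownames(tm), traitNames())
})

test_that("bucket tables are unit-sum normalized regardless of effect sizes", {
  for (cfg in list(smallConfig(seed = 2),
    smallConfig(seed = 3, bucketEffectSize = 2, bucketBatchSD = 1))) {
    st <- generateStudy(cfg)$study
    expect_true(all(bucketMatrix(st) >= 0))
    expect_lt(max(abs(colSums(bucketMatrix(st)) - 1)), 1e-9)
  }
  expect_false(anyDuplicated(rownames(generateStudy(smallConfig())$study)) > 0)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(studyConfig(nFamilies = 0), "nFamilies")
  expect_error(studyConfig(nBuckets = 10, nInformative = 20), "nInformative")
  expect_error(studyConfig(bucketEffectSize = NaN), "bucketEffectSize")
  expect_error(studyConfig(familySensitivity = c(1, 2)), "one entry per family")
  expect_error(studyConfig(climateEffect = c(XX = 1)), "unknown trait")
})

test_that("null generator (no climate or sensitivity effects) gives null Welch t", {
  tvals <- unlist(lapply(1:50, function(s) {
    cfg <- smallConfig(nFamilies = 4, offspringPerCell = 15, nBuckets = 4,
      nInformative = 1, seed = 100 + s, climateEffect = 0,
      sensitivityScaling = 0, batchSD = 0, sexEffect = 0)
    tStats(buildTMatrix(generateStudy(cfg)$study))
  }))
  expect_lt(abs(mean(tvals)), 0.2)
  # and the spread is Student-t-like, not inflated
  expect_lt(sd(tvals), 1.5)
})

test_that("with all effects zero, TEMP and TROP trait draws are exchangeable", {
  pvals <- sapply(1:40, function(s) {
    cfg <- smallConfig(nFamilies = 3, offspringPerCell = 15, nBuckets = 4,
      nInformative = 1, seed = 200 + s, climateEffect = 0,
      sensitivityScaling = 0, batchSD = 0, sexEffect = 0)
    ph <- phenotypeTable(generateStudy(cfg)$study)
    suppressWarnings(stats::ks.test(ph$BW[ph$climate == "TEMP"],
      ph$BW[ph$climate == "TROP"])$p.value)
  })
  # KS p-values should look uniform: no mass collapse near 0
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("strong sensitivity scaling makes the index recover the latent truth", {
  cfg <- smallConfig(nFamilies = 8, offspringPerCell = 30, seed = 5)
  sim <- generateStudy(cfg)
  idx <- computeIsens(buildTMatrix(sim$study))
  truth <- sim$truth$sensitivity
  expect_gt(cor(isensScores(idx)[names(truth)], truth,
    method = "spearman"), 0.9)
})

test_that("informative buckets are depleted in sensitive families under TEMP", {
  cfg <- smallConfig(seed = 9)
  sim <- generateStudy(cfg)
  st <- sim$study
  B <- bucketMatrix(st)
  temp <- st$climate == "TEMP"
  s <- sim$truth$sensitivity
  slopes <- sapply(sim$truth$informativeBuckets, function(bk) {
    med <- tapply(B[bk, temp], st$family[temp], median)
    cor(med[names(s)], s)
  })
  expect_gt(mean(slopes < 0), 0.9)
})
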