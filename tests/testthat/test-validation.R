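test_that("membership rates are percentages per family, order-invariant", {
  pred <- factor(c("s", "s", "s", "r", "s", "r"), levels = c("r", "s"))
  fam <- c("A", "A", "A", "B", "B", "B")
  mr <- membershipRate(pred, fam, positive = "s")
  expect_equal(unname(mr[c("A", "B")]), c(100, 100 / 3))
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(membershipRate(pred[perm], fam[perm], positive = "s"), mr)
  expect_error(membershipRate(pred, c(fam[-1], NA)), "family label")
})

test_that("MR-index correlation is exact on affine data and symmetric", {
  s <- setNames(c(-2, -1, 0, 1, 2), paste0("SF", 1:5))
  mr <- 50 + 20 * s
  out <- mrIsensCorrelation(mr, s)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(mrIsensCorrelation(s, mr)$r, out$r)
  expect_error(mrIsensCorrelation(setNames(rep(3, 5), names(s)), s),
    "zero variance")
  expect_error(mrIsensCorrelation(mr[1:2], s[1:2]), "at least 3")
})

test_that("Wilcoxon screening: exchangeable data gives p = 1, planted shifts are found", {
  set.seed(61)
  base <- matrix(rnorm(20 * 10), 20, 10,
    dimnames = list(paste0("b", 1:20), NULL))
  X <- cbind(base, base)
  g <- factor(rep(c("r", "s"), each = 10))
  same <- differentialBuckets(X, g)
  expect_true(all(same$p == 1))

  n <- 100
  Xp <- matrix(rnorm(100 * n), 100, n,
    dimnames = list(sprintf("b%03d", 1:100), NULL))
  gp <- factor(rep(c("r", "s"), each = n / 2))
  Xp["b001", gp == "s"] <- Xp["b001", gp == "s"] + 5
  res <- differentialBuckets(Xp, gp)
  expect_lt(res$fdr[res$bucket == "b001"], 0.05)
  expect_gt(median(res$fdr[res$bucket != "b001"]), 0.5)
  expect_equal(res$direction[res$bucket == "b001"], "higher-in-s")

  # an all-tied bucket is flagged, not an error
  Xp["b002", ] <- 1
  res2 <- differentialBuckets(Xp, gp)
  expect_equal(res2$p[res2$bucket == "b002"], 1)
  expect_true(res2$tie[res2$bucket == "b002"])
})

test_that("BH adjustment equals the brute-force step-up rule", {
  set.seed(62)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, method = "BH"), bruteBH(p),
      tolerance = 1e-12)
  }
  # and FDR values re-monotonized over sorted p are nondecreasing
  p <- runif(30)
  adj <- bruteBH(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("the correlation panel has the contracted shape and exact affine cells", {
  cfg <- smallConfig(seed = 63)
  sim <- generateStudy(cfg)
  st <- sim$study
  fams <- sort(unique(st$family))
  s <- setNames(seq(-1, 1, length.out = length(fams)), fams)
  mr <- setNames(50 + 30 * s, fams)
  vipScores <- setNames(rep(0.5, nrow(st)), rownames(st))
  vipScores[1:4] <- 2
  panel <- bucketPhenotypePanel(st, vipScores, s, mr)
  expect_equal(nrow(panel), 4 * (7 * 2 + 2))
  expect_setequal(unique(panel$bucket), rownames(st)[1:4])

  # construct a bucket whose family medians are an affine image of the
  # family-mean BW in TEMP: its panel r must be 1
  ph <- phenotypeTable(st)
  temp <- ph$climate == "TEMP"
  bwMean <- tapply(ph$BW[temp], ph$family[temp], mean)
  B <- bucketMatrix(st)
  B[2, temp] <- 0.001 * bwMean[ph$family[temp]] + 0.05
  st2 <- HeatStudy(B, ph, bucketAnnotations(st))
  panel2 <- bucketPhenotypePanel(st2, vipScores, s, mr)
  cell <- panel2[panel2$bucket == rownames(st)[2] &
    panel2$variable == "BW.TEMP", ]
  expect_equal(cell$r, 1, tolerance = 1e-9)

  # a missing trait yields NA cells, not an error
  ph3 <- ph
  ph3$ST <- NULL
  st3 <- HeatStudy(bucketMatrix(st), ph3, bucketAnnotations(st))
  panel3 <- bucketPhenotypePanel(st3, vipScores, s, mr)
  expect_true(all(is.na(panel3$r[panel3$variable == "ST.TEMP"])))
})

test_that("informative buckets correlate negatively with sensitivity-ordered MR", {
  cfg <- smallConfig(seed = 64, nFamilies = 8, offspringPerCell = 30)
  sim <- generateStudy(cfg)
  st <- sim$study
  s <- sim$truth$sensitivity
  mr <- setNames(50 + 25 * s / max(abs(s)), names(s))
  vipScores <- setNames(rep(0, nrow(st)), rownames(st))
  vipScores[sim$truth$informativeBuckets] <- 2
  panel <- bucketPhenotypePanel(st, vipScores, s, mr)
  rs <- panel$r[panel$variable == "MR"]
  expect_gt(mean(rs < 0), 0.9)
})

test_that("the type-III group ANOVA isolates a planted climate effect", {
  cfg <- smallConfig(seed = 65, nFamilies = 4, offspringPerCell = 50,
    nBuckets = 10, nInformative = 2,
    climateEffect = c(ADFI = -0.5), sensitivityScaling = 0,
    batchSD = 0, sexEffect = 0)
  cfg@climateEffect[setdiff(traitNames(), "ADFI")] <- 0
  st <- generateStudy(cfg)$study
  g <- groupComparisonTable(st,
    list(robust = c("SF1", "SF2"), sensitive = c("SF3", "SF4")),
    traits = "ADFI")
  expect_lt(g$p[g$term == "C"], 0.001)
  expect_true(all(g$p[!g$term %in% "C"] > 0.05))
  expect_equal(g$code[g$term == "C"], "***")
})

test_that("type III equals type I on a perfectly balanced design", {
  set.seed(66)
  d <- expand.grid(C = c("TEMP", "TROP"), G = c("r", "s"),
    S = c("f", "m"), SF = c("1", "2"), rep = 1:6)
  d$y <- rnorm(nrow(d)) + (d$C == "TROP") * 1 + (d$G == "s") * 0.5
  fit <- lm(y ~ C + G + S + G:SF + C:G + C:G:SF, data = d,
    contrasts = list(C = "contr.sum", G = "contr.sum", S = "contr.sum",
      SF = "contr.sum"))
  t3 <- car::Anova(fit, type = 3)
  t1 <- anova(fit)
  shared <- intersect(rownames(t3), rownames(t1))
  expect_equal(t3[shared, "Sum Sq"], t1[shared, "Sum Sq"],
    tolerance = 1e-8)
})

test_that("duplicating every row doubles sums of squares but keeps F ordering", {
  cfg <- smallConfig(seed = 67, nFamilies = 4, nBuckets = 10,
    nInformative = 2)
  st <- generateStudy(cfg)$study
  groups <- list(robust = c("SF1", "SF2"), sensitive = c("SF3", "SF4"))
  g1 <- groupComparisonTable(st, groups, traits = "BW")
  B <- bucketMatrix(st)
  ph <- phenotypeTable(st)
  ph2 <- rbind(ph, setNames(ph, colnames(ph)))
  rownames(ph2) <- c(rownames(ph), paste0(rownames(ph), "_d"))
  B2 <- cbind(B, B)
  colnames(B2) <- rownames(ph2)
  st2 <- HeatStudy(B2, ph2)
  g2 <- groupComparisonTable(st2, groups, traits = "BW")
  expect_equal(order(g1$F), order(g2$F))
})
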