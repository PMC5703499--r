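#' Per-family membership rate to the sensitive class
#'
#' `MR_f` is the percentage of family `f`'s animals predicted into the
#' positive ("sensitive") class — the predicted indicator of that
#' family's heat-stress sensitivity.
#'
#' @param predictions per-animal predicted classes (factor or character).
#' @param families per-animal family labels, same length.
#' @param positive the class counted as sensitive; defaults to the last
#'   factor level of `predictions`.
#' @return named numeric vector of rates in `[0, 100]`, one per family.
#' @export
membershipRate <- function(predictions, families, positive = NULL) {
  if (length(predictions) != length(families)) {
    stop("predictions and families must have the same length")
  }
  if (any(is.na(families)) || any(families == "")) {
    stop("every animal needs a family label")
  }
  predictions <- as.factor(predictions)
  if (is.null(positive)) positive <- levels(predictions)[nlevels(predictions)]
  tab <- table(families)
  if (any(tab == 0)) stop("empty family level(s)")
  sens <- tapply(predictions == positive, families, mean)
  setNames(100 * as.numeric(sens), names(sens))
}

#' Correlate predicted (MR) and observed (index) family sensitivity
#'
#' Pearson correlation with its two-sided t-based p value between the
#' per-family membership rate and the composite sensitivity index,
#' aligned by family name.
#'
#' @param mr named per-family membership rates.
#' @param isens a [SensitivityIndex] or named numeric index values.
#' @param families optional subset of families to use (e.g. only the
#'   validation families); default all shared names.
#' @return list with `r`, `p`, and `families` used.
#' @export
mrIsensCorrelation <- function(mr, isens, families = NULL) {
  s <- if (is(isens, "SensitivityIndex")) isensScores(isens) else isens
  common <- intersect(names(mr), names(s))
  if (!is.null(families)) common <- intersect(common, families)
  if (length(common) < 3) stop("need at least 3 families in common")
  x <- mr[common]
  y <- s[common]
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    stop("zero variance in MR or index over the selected families")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, families = common)
}

#' Differential bucket abundance between two groups
#'
#' Two-sided Wilcoxon rank-sum test per bucket (normal approximation)
#' with Benjamini-Hochberg adjustment across all buckets, and the
#' direction of the group-median difference. Buckets in which every
#' value is tied get `p = 1` and a tie flag rather than an error.
#'
#' @param X numeric matrix, buckets x samples.
#' @param groups 2-level factor over the samples.
#' @return data.frame with `bucket`, `statistic`, `p`, `fdr`,
#'   `direction` (`"higher-in-<level>"` or `"none"`) and `tie`.
#' @export
differentialBuckets <- function(X, groups) {
  X <- as.matrix(X)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (any(table(groups) < 2)) stop("both groups need at least 2 samples")
  g1 <- groups == levels(groups)[1]
  res <- t(apply(X, 1, function(v) {
    if (max(v) - min(v) < 1e-24) return(c(NA_real_, 1, 1))
    wt <- suppressWarnings(wilcox.test(v[g1], v[!g1], exact = FALSE))
    c(unname(wt$statistic), wt$p.value, 0)
  }))
  med1 <- apply(X[, g1, drop = FALSE], 1, median)
  med2 <- apply(X[, !g1, drop = FALSE], 1, median)
  direction <- ifelse(med1 > med2,
    paste0("higher-in-", levels(groups)[1]),
    ifelse(med2 > med1, paste0("higher-in-", levels(groups)[2]), "none"))
  data.frame(
    bucket = rownames(X),
    statistic = res[, 1],
    p = res[, 2],
    fdr = p.adjust(res[, 2], method = "BH"),
    direction = direction,
    tie = res[, 3] == 1,
    row.names = NULL
  )
}

#' Bucket-median versus phenotype-mean correlation panel
#'
#' For every bucket with VIP above the threshold: its median abundance
#' per family among thermoneutral (TEMP) animals is correlated (Pearson,
#' across families) with the per-family mean of each trait in each
#' climate, and with the membership rate and the sensitivity index.
#'
#' @param study a [HeatStudy] (adjusted); bucket medians are taken over
#'   its TEMP animals.
#' @param vipScores named VIP vector from [vip()].
#' @param isens a [SensitivityIndex] or named numeric.
#' @param mr named per-family membership rates.
#' @param traits traits to include (default all seven).
#' @param vipThreshold VIP cutoff (default 1).
#' @param alpha significance flag level (default 0.05).
#' @return data.frame with one row per (bucket, variable) pair:
#'   `bucket`, `variable` (e.g. `"BW.TROP"`, `"MR"`, `"I_sens"`), `r`,
#'   `p`, `significant`; traits absent from the study yield `NA` cells.
#' @export
bucketPhenotypePanel <- function(study, vipScores, isens, mr,
                                 traits = traitNames(),
                                 vipThreshold = 1, alpha = 0.05) {
  stopifnot(is(study, "HeatStudy"))
  s <- if (is(isens, "SensitivityIndex")) isensScores(isens) else isens
  fams <- sort(intersect(names(s), unique(as.character(study$family))))
  if (length(fams) < 3) stop("need at least 3 families")
  sel <- names(vipScores)[vipScores > vipThreshold]
  sel <- intersect(sel, rownames(study))
  if (!length(sel)) stop("no bucket exceeds the VIP threshold")

  B <- bucketMatrix(study)
  cd <- as.data.frame(colData(study))
  temp <- cd$climate == "TEMP"
  med <- sapply(fams, function(f)
    apply(B[sel, temp & cd$family == f, drop = FALSE], 1, median))
  med <- matrix(med, nrow = length(sel),
    dimnames = list(sel, fams))

  vars <- c(as.vector(outer(traits, c("TEMP", "TROP"), paste, sep = ".")),
    "MR", "I_sens")
  valueOf <- function(v) {
    if (v == "MR") return(mr[fams])
    if (v == "I_sens") return(s[fams])
    tr <- sub("\\.(TEMP|TROP)$", "", v)
    cl <- sub("^.*\\.", "", v)
    if (!tr %in% colnames(cd)) return(rep(NA_real_, length(fams)))
    sapply(fams, function(f)
      mean(cd[[tr]][cd$family == f & cd$climate == cl], na.rm = TRUE))
  }
  rows <- lapply(vars, function(v) {
    val <- valueOf(v)
    if (all(is.na(val)) || sd(val, na.rm = TRUE) < 1e-12) {
      return(data.frame(bucket = sel, variable = v, r = NA_real_,
        p = NA_real_, significant = NA))
    }
    est <- t(apply(med, 1, function(m) {
      ct <- cor.test(m, val, method = "pearson")
      c(unname(ct$estimate), ct$p.value)
    }))
    data.frame(bucket = sel, variable = v, r = est[, 1], p = est[, 2],
      significant = est[, 2] < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Type-III ANOVA comparison of extreme groups
#'
#' Reporting utility mirroring the phenotype comparison of the robust
#' and sensitive reference groups: per trait, a type-III analysis of
#' variance with climate (C), group (G), sex (S), sire family nested in
#' group (SF(G)) and the CxG and CxSF(G) interactions, using sum-to-zero
#' contrasts. Significance codes: `***` p < 0.001, `*` p < 0.05,
#' `#` p < 0.10.
#'
#' @param study a [HeatStudy].
#' @param groups named list of family labels, e.g.
#'   `list(robust = ..., sensitive = ...)`; animals of other families
#'   are dropped.
#' @param traits traits to analyse (default all present).
#' @return data.frame with `trait`, `term`, `df`, `F`, `p`, `code`.
#' @export
groupComparisonTable <- function(study, groups, traits = NULL) {
  stopifnot(is(study, "HeatStudy"))
  cd <- as.data.frame(colData(study))
  if (is.null(traits)) traits <- intersect(traitNames(), colnames(cd))
  grp <- rep(NA_character_, nrow(cd))
  for (g in names(groups)) grp[cd$family %in% groups[[g]]] <- g
  keep <- !is.na(grp)
  d <- data.frame(
    C = factor(cd$climate[keep]), G = factor(grp[keep]),
    S = factor(cd$sex[keep]), family = factor(cd$family[keep])
  )
  # recode families by their index within group so the nested SF(G) term
  # has no structurally empty cells
  idx <- integer(nrow(d))
  for (g in levels(d$G)) {
    ing <- d$G == g
    idx[ing] <- as.integer(factor(as.character(d$family[ing])))
  }
  d$SF <- factor(idx)
  ctr <- list(C = "contr.sum", G = "contr.sum", S = "contr.sum",
    SF = "contr.sum")
  out <- lapply(traits, function(tr) {
    d$y <- cd[[tr]][keep]
    fit <- lm(y ~ C + G + S + G:SF + C:G + C:G:SF,
      data = d[is.finite(d$y), ], contrasts = ctr)
    al <- alias(fit)$Complete
    if (!is.null(al) && nrow(al)) {
      stop("aliased terms in the design for trait ", tr, ": ",
        paste(rownames(al), collapse = ", "))
    }
    a <- car::Anova(fit, type = 3)
    a <- a[!rownames(a) %in% c("(Intercept)", "Residuals"), ]
    p <- a[["Pr(>F)"]]
    data.frame(
      trait = tr,
      term = rownames(a),
      df = a$Df,
      F = a[["F value"]],
      p = p,
      code = ifelse(p < 0.001, "***",
        ifelse(p < 0.05, "*", ifelse(p < 0.10, "#", ""))),
      row.names = NULL
    )
  })
  do.call(rbind, out)
}
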