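#' Study design and effect-size configuration for the synthetic generator
#'
#' Holds the design of a two-climate sire-family study: family and batch
#' structure, per-trait climate and sensitivity effects, nuisance (batch,
#' sex, residual) magnitudes for both the phenotype and the bucket block,
#' and the latent per-family sensitivity gradient. Construct with
#' [studyConfig()].
#'
#' @slot nFamilies number of sire families.
#' @slot offspringPerCell mean offspring per family per climate.
#' @slot offspringSD standard deviation of the per-cell offspring count.
#' @slot nBatchesTemp,nBatchesTrop contemporary groups per climate.
#' @slot nBuckets number of NMR buckets.
#' @slot nInformative number of buckets whose thermoneutral abundance
#'   tracks family sensitivity.
#' @slot familySensitivity latent per-family sensitivity (centered).
#' @slot traitBase,climateEffect,sensitivityScaling,residualSD,batchSD,sexEffect
#'   named numeric vectors over the seven traits.
#' @slot bucketEffectSize slope of informative-bucket log-abundance on the
#'   latent sensitivity (thermoneutral animals).
#' @slot bucketBaseSD,bucketClimateSD,bucketBatchSD,bucketSexSD,bucketResidualSD
#'   log-scale magnitudes for the bucket block.
#' @slot seed integer RNG seed.
#' @export
setClass("StudyConfig",
  representation(
    nFamilies = "integer",
    offspringPerCell = "numeric",
    offspringSD = "numeric",
    nBatchesTemp = "integer",
    nBatchesTrop = "integer",
    nBuckets = "integer",
    nInformative = "integer",
    familySensitivity = "numeric",
    traitBase = "numeric",
    climateEffect = "numeric",
    sensitivityScaling = "numeric",
    residualSD = "numeric",
    batchSD = "numeric",
    sexEffect = "numeric",
    bucketEffectSize = "numeric",
    bucketBaseSD = "numeric",
    bucketClimateSD = "numeric",
    bucketBatchSD = "numeric",
    bucketSexSD = "numeric",
    bucketResidualSD = "numeric",
    seed = "integer"
  )
)

setValidity("StudyConfig", function(object) {
  msg <- character(0)
  counts <- c(
    nFamilies = object@nFamilies, offspringPerCell = object@offspringPerCell,
    nBatchesTemp = object@nBatchesTemp, nBatchesTrop = object@nBatchesTrop,
    nBuckets = object@nBuckets, nInformative = object@nInformative
  )
  if (any(counts <= 0)) {
    msg <- c(msg, paste0("counts must be > 0: ",
      paste(names(counts)[counts <= 0], collapse = ", ")))
  }
  if (object@nInformative > object@nBuckets) {
    msg <- c(msg, "nInformative must not exceed nBuckets")
  }
  if (length(object@familySensitivity) != object@nFamilies) {
    msg <- c(msg, "familySensitivity must have one entry per family")
  }
  num <- c("offspringPerCell", "offspringSD", "familySensitivity",
    "traitBase", "climateEffect", "sensitivityScaling", "residualSD",
    "batchSD", "sexEffect", "bucketEffectSize", "bucketBaseSD",
    "bucketClimateSD", "bucketBatchSD", "bucketSexSD", "bucketResidualSD")
  for (s in num) {
    if (any(!is.finite(slot(object, s)))) {
      msg <- c(msg, paste0("non-finite value in field '", s, "'"))
    }
  }
  for (s in c("traitBase", "climateEffect", "sensitivityScaling",
    "residualSD", "batchSD", "sexEffect")) {
    v <- slot(object, s)
    if (!identical(names(v), traitNames())) {
      msg <- c(msg, paste0("field '", s, "' must be named over: ",
        paste(traitNames(), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Two-climate sire-family study container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with NMR buckets as rows
#' (assay `"buckets"`; each animal's spectrum is a column, unit-sum
#' normalized at generation/import), animals as columns, and the design plus
#' trait phenotypes in `colData` (`family`, `climate`, `batch`, `sex`, and
#' the traits ADFI, BW, RT, ADG, FCR, ABFT, ST). Bucket chemical-shift
#' labels (rownames, ppm strings) and metabolite annotations live in
#' `rowData`.
#'
#' @export
setClass("HeatStudy", contains = "SummarizedExperiment")

setValidity("HeatStudy", function(object) {
  msg <- character(0)
  if (!"buckets" %in% assayNames(object)) {
    msg <- c(msg, "assay 'buckets' is required")
  }
  need <- c("family", "climate", "batch", "sex")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss)) {
    msg <- c(msg, paste0("missing colData columns: ",
      paste(miss, collapse = ", ")))
  }
  if ("climate" %in% colnames(colData(object))) {
    bad <- setdiff(unique(as.character(object$climate)), c("TEMP", "TROP"))
    if (length(bad)) {
      msg <- c(msg, paste0("unknown climate values: ",
        paste(bad, collapse = ", ")))
    }
  }
  if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "duplicated bucket labels")
  }
  if (anyDuplicated(colnames(object))) {
    msg <- c(msg, "duplicated animal ids")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted empirical-Bayes batch-adjustment model
#'
#' Per-feature, per-batch shrunken location (`gammaStar`) and scale
#' (`deltaStar`) estimates together with the normal / inverse-gamma
#' hyper-parameters of the parametric empirical-Bayes priors, as estimated
#' by [ebAdjust()].
#'
#' @slot batch batch factor levels.
#' @slot features feature names.
#' @slot gammaStar,deltaStar feature x batch matrices of shrunken
#'   location/scale estimates (deltaStar > 0).
#' @slot gammaHat,deltaHat unshrunken per-batch estimates.
#' @slot priors list with `gammaBar`, `t2`, `aPrior`, `bPrior` per batch.
#' @slot varPooled per-feature pooled variance used for standardization.
#' @slot covariates names of covariate factors preserved.
#' @slot passthrough features left untouched (constant within all batches).
#' @export
setClass("AdjustmentModel",
  representation(
    batch = "character",
    features = "character",
    gammaStar = "matrix",
    deltaStar = "matrix",
    gammaHat = "matrix",
    deltaHat = "matrix",
    priors = "list",
    varPooled = "numeric",
    covariates = "character",
    passthrough = "character"
  )
)

setValidity("AdjustmentModel", function(object) {
  active <- setdiff(object@features, object@passthrough)
  d <- object@deltaStar[active, , drop = FALSE]
  if (length(d) && any(d <= 0)) return("deltaStar must be > 0")
  TRUE
})

#' Principal variance component analysis result
#'
#' Eigenvalue-weighted average proportion of variance (WAPV, in %) per
#' design factor plus residual, with the retained principal components and
#' their weights. Produced by [pvca()].
#'
#' @slot wapv named numeric, percent of variance per factor + `"residual"`;
#'   entries are nonnegative and sum to 100.
#' @slot nPC number of principal components retained.
#' @slot weights eigenvalue weights of the retained components.
#' @slot threshold cumulative variance threshold used.
#' @export
setClass("PvcaResult",
  representation(
    wapv = "numeric",
    nPC = "integer",
    weights = "numeric",
    threshold = "numeric"
  )
)

setValidity("PvcaResult", function(object) {
  if (any(object@wapv < -1e-8)) return("WAPV entries must be >= 0")
  if (abs(sum(object@wapv) - 100) > 0.1) {
    return("WAPV entries must sum to 100 (+/- 0.1)")
  }
  TRUE
})

#' Family-by-trait Welch t-statistic matrix
#'
#' One row per sire family; columns `t_ADFI`, `t_BW`, `t_RT` hold the Welch
#' t statistic of the between-climate contrast (TEMP minus TROP) for that
#' family, with the Welch-Satterthwaite degrees of freedom and per-climate
#' sample sizes alongside. Produced by [buildTMatrix()].
#'
#' @slot stats family x trait matrix of Welch t statistics.
#' @slot df matching matrix of Welch degrees of freedom.
#' @slot nTemp,nTrop matching matrices of per-climate sample sizes.
#' @export
setClass("TStatMatrix",
  representation(
    stats = "matrix",
    df = "matrix",
    nTemp = "matrix",
    nTrop = "matrix"
  )
)

setValidity("TStatMatrix", function(object) {
  if (!all(is.finite(object@stats))) return("t statistics must be finite")
  if (any(object@nTemp < 2) || any(object@nTrop < 2)) {
    return("sample sizes must be >= 2 in each climate")
  }
  TRUE
})

#' Composite family sensitivity index
#'
#' Per-family scores on the first principal component of the Welch-t
#' matrix, oriented so that larger scores mean greater sensitivity to the
#' hot climate, with PCA diagnostics. Produced by [computeIsens()].
#'
#' @slot scores named per-family index values (sum to 0: centered PCA).
#' @slot inertia percent of total inertia per principal component.
#' @slot contributions percent contribution of each t variable to PC1.
#' @slot loadings full PCA rotation matrix (after orientation).
#' @slot scaled whether t columns were scaled to unit variance before PCA.
#' @export
setClass("SensitivityIndex",
  representation(
    scores = "numeric",
    inertia = "numeric",
    contributions = "numeric",
    loadings = "matrix",
    scaled = "logical"
  )
)

setValidity("SensitivityIndex", function(object) {
  if (abs(sum(object@scores)) > 1e-9 * max(1, max(abs(object@scores)))) {
    return("index scores must sum to 0 (centered PCA)")
  }
  if (abs(sum(object@inertia) - 100) > 0.1) {
    return("inertia fractions must sum to 100")
  }
  TRUE
})

#' Fitted sparse PLS-DA model
#'
#' Sparse partial least squares discriminant analysis fit: per-component
#' X-weights with exactly `keepX[h]` nonzero entries (soft-thresholded and
#' renormalized), X- and Y-loadings from regression-mode deflation, latent
#' scores, training standardization statistics and class centroids in score
#' space. Produced by [splsda()].
#'
#' @slot weights p x H matrix of sparse, unit-norm X-weights.
#' @slot xLoadings p x H matrix of X-loadings (deflation regressors).
#' @slot yLoadings class x H matrix of Y-loadings.
#' @slot scores n x H latent score matrix of the training samples.
#' @slot keepX per-component number of buckets retained.
#' @slot center,scale training per-bucket mean and standard deviation.
#' @slot yLevels class labels; the second level is the "positive"
#'   (sensitive) class for scores and ROC curves.
#' @slot y training class factor.
#' @slot yMeans column means of the centered dummy response.
#' @slot centroids class x H training class means in score space.
#' @slot explVarX per-component fraction of (standardized) X variance.
#' @slot explVarY per-component Y sum of squares explained (VIP weights).
#' @export
setClass("SplsdaModel",
  representation(
    weights = "matrix",
    xLoadings = "matrix",
    yLoadings = "matrix",
    scores = "matrix",
    keepX = "integer",
    center = "numeric",
    scale = "numeric",
    yLevels = "character",
    y = "factor",
    yMeans = "numeric",
    centroids = "matrix",
    explVarX = "numeric",
    explVarY = "numeric"
  )
)

setValidity("SplsdaModel", function(object) {
  nz <- colSums(object@weights != 0)
  if (!all(nz == object@keepX)) {
    return("nonzero count per component must equal keepX")
  }
  nrm <- sqrt(colSums(object@weights^2))
  if (any(abs(nrm - 1) > 1e-8)) return("weight vectors must be unit-norm")
  TRUE
})

#' Cross-validation report for a sparse PLS-DA classifier
#'
#' Pooled confusion counts, balanced error rate, sensitivity/specificity,
#' ROC points and trapezoid AUC over stratified repeated cross-validation,
#' plus per-bucket selection-stability frequencies. Produced by
#' [crossValidate()].
#'
#' @slot confusion named counts `TP`, `FN`, `TN`, `FP` pooled over folds.
#' @slot ber balanced error rate in `[0, 1]`.
#' @slot sensitivity,specificity true positive / true negative rates.
#' @slot roc data.frame of (FPR, TPR) pairs, from (0,0) to (1,1).
#' @slot auc trapezoid area under the ROC curve.
#' @slot stability named per-bucket selection frequency in `[0, 1]`.
#' @slot nResamples number of fold-fits behind the stability frequencies.
#' @slot folds,repeats cross-validation layout.
#' @export
setClass("CvReport",
  representation(
    confusion = "numeric",
    ber = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    roc = "data.frame",
    auc = "numeric",
    stability = "numeric",
    nResamples = "integer",
    folds = "integer",
    repeats = "integer"
  )
)

setValidity("CvReport", function(object) {
  if (object@ber < 0 || object@ber > 1) return("BER must be in [0, 1]")
  if (object@auc < 0 || object@auc > 1) return("AUC must be in [0, 1]")
  r <- object@roc
  if (nrow(r)) {
    if (any(diff(r$fpr) < -1e-12) || any(diff(r$tpr) < -1e-12)) {
      return("ROC must be nondecreasing in both coordinates")
    }
    if (abs(r$fpr[1]) > 1e-12 || abs(r$tpr[1]) > 1e-12 ||
        abs(r$fpr[nrow(r)] - 1) > 1e-12 || abs(r$tpr[nrow(r)] - 1) > 1e-12) {
      return("ROC must run from (0,0) to (1,1)")
    }
  }
  TRUE
})

#' Validation report: membership rates and correlation panels
#'
#' Per-family membership rate to the sensitive class (percent of animals
#' predicted sensitive), its Pearson correlation with the sensitivity
#' index, the per-bucket Wilcoxon/BH differential-abundance table and the
#' bucket-median x phenotype-mean correlation panel. Assembled by
#' [runWorkflow()].
#'
#' @slot mr named per-family membership rate, percent.
#' @slot mrIsens list with `r`, `p`, and the families used.
#' @slot differential data.frame from [differentialBuckets()].
#' @slot panel data.frame from [bucketPhenotypePanel()].
#' @export
setClass("ValidationReport",
  representation(
    mr = "numeric",
    mrIsens = "list",
    differential = "data.frame",
    panel = "data.frame"
  )
)

setValidity("ValidationReport", function(object) {
  if (length(object@mr) && (any(object@mr < 0) || any(object@mr > 100))) {
    return("membership rates must lie in [0, 100]")
  }
  TRUE
})
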