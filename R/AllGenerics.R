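#' @name accessors
#' @title Accessors for metaboSens result objects
#'
#' @description Small accessor layer over the S4 result classes:
#' `bucketMatrix()` and `traitMatrix()` return the feature x animal blocks
#' of a [HeatStudy]; `bucketAnnotations()` the per-bucket metabolite
#' annotations; `tStats()` the Welch-t matrix; `isensScores()` the
#' per-family sensitivity index; `selectedBuckets()` the buckets retained
#' by a sparse PLS-DA fit (per component or pooled); `stability()` the
#' per-bucket selection frequencies of a cross-validation run; `wapv()`
#' the PVCA variance fractions; `membershipRates()` the per-family
#' membership rates of a validation report.
#'
#' @param x,object an object of the documented class.
#' @param ... passed to methods.
NULL

#' @rdname accessors
#' @export
setGeneric("bucketMatrix", function(x, ...) standardGeneric("bucketMatrix"))

#' @rdname accessors
#' @export
setGeneric("traitMatrix", function(x, ...) standardGeneric("traitMatrix"))

#' @rdname accessors
#' @export
setGeneric("bucketAnnotations",
  function(x, ...) standardGeneric("bucketAnnotations"))

#' @rdname accessors
#' @export
setGeneric("tStats", function(x, ...) standardGeneric("tStats"))

#' @rdname accessors
#' @export
setGeneric("isensScores", function(x, ...) standardGeneric("isensScores"))

#' @rdname accessors
#' @export
setGeneric("selectedBuckets",
  function(x, ...) standardGeneric("selectedBuckets"))

#' @rdname accessors
#' @export
setGeneric("stability", function(x, ...) standardGeneric("stability"))

#' @rdname accessors
#' @export
setGeneric("wapv", function(x, ...) standardGeneric("wapv"))

#' @rdname accessors
#' @export
setGeneric("membershipRates",
  function(x, ...) standardGeneric("membershipRates"))

#' @rdname accessors
#' @export
setMethod("bucketMatrix", "HeatStudy", function(x, ...) {
  assay(x, "buckets")
})

#' @rdname accessors
#' @export
setMethod("traitMatrix", "HeatStudy", function(x, ...) {
  cd <- colData(x)
  tr <- intersect(traitNames(), colnames(cd))
  m <- t(as.matrix(as.data.frame(cd[, tr, drop = FALSE])))
  colnames(m) <- colnames(x)
  m
})

#' @rdname accessors
#' @export
setMethod("bucketAnnotations", "HeatStudy", function(x, ...) {
  ann <- rowData(x)$annotation
  if (is.null(ann)) ann <- rep("unknown", nrow(x))
  setNames(as.character(ann), rownames(x))
})

#' @rdname accessors
#' @export
setMethod("tStats", "TStatMatrix", function(x, ...) x@stats)

#' @rdname accessors
#' @export
setMethod("isensScores", "SensitivityIndex", function(x, ...) x@scores)

#' @param component integer component index, or `NULL` for the union over
#'   all components.
#' @rdname accessors
#' @export
setMethod("selectedBuckets", "SplsdaModel", function(x, component = NULL, ...) {
  w <- x@weights
  if (is.null(component)) {
    rownames(w)[rowSums(w != 0) > 0]
  } else {
    rownames(w)[w[, component] != 0]
  }
})

#' @rdname accessors
#' @export
setMethod("stability", "CvReport", function(x, ...) x@stability)

#' @rdname accessors
#' @export
setMethod("wapv", "PvcaResult", function(x, ...) x@wapv)

#' @rdname accessors
#' @export
setMethod("membershipRates", "ValidationReport", function(x, ...) x@mr)

setMethod("show", "StudyConfig", function(object) {
  cat("StudyConfig:", object@nFamilies, "families x 2 climates,",
    "~", object@offspringPerCell, "offspring/cell;",
    object@nBuckets, "buckets (", object@nInformative, "informative);",
    "seed", object@seed, "\n")
})

setMethod("show", "AdjustmentModel", function(object) {
  cat("AdjustmentModel:", length(object@features), "features,",
    length(object@batch), "batch levels; covariates:",
    paste(object@covariates, collapse = ", "), "\n")
  if (length(object@passthrough)) {
    cat("  passed through unchanged:", length(object@passthrough),
      "constant feature(s)\n")
  }
})

setMethod("show", "PvcaResult", function(object) {
  cat("PVCA (", object@nPC, " PCs >= ", object@threshold * 100,
    "% variance) -- WAPV (%):\n", sep = "")
  print(round(object@wapv, 2))
})

setMethod("show", "TStatMatrix", function(object) {
  cat("Welch t matrix (TEMP - TROP),", nrow(object@stats), "families:\n")
  print(round(object@stats, 2))
})

setMethod("show", "SensitivityIndex", function(object) {
  cat("Sensitivity index (PC1 of the Welch-t matrix,",
    if (object@scaled) "scaled" else "unscaled", "columns)\n")
  cat("  inertia (%):", paste(round(object@inertia, 1), collapse = " / "),
    "\n  PC1 contributions (%):\n")
  print(round(object@contributions, 1))
  cat("  scores:\n")
  print(round(sort(object@scores), 2))
})

setMethod("show", "SplsdaModel", function(object) {
  cat("Sparse PLS-DA model:", ncol(object@weights), "components, keepX = (",
    paste(object@keepX, collapse = ", "), "),",
    length(selectedBuckets(object)), "buckets selected overall\n")
  cat("  classes:", paste(object@yLevels, collapse = " vs "),
    "(positive =", object@yLevels[2], ")\n")
  cat("  X variance explained per component:",
    paste(signif(object@explVarX, 3), collapse = ", "), "\n")
})

setMethod("show", "CvReport", function(object) {
  cat("Cross-validation (", object@folds, "-fold x ", object@repeats,
    " repeats): BER = ", round(object@ber, 3),
    ", sensitivity = ", round(object@sensitivity, 3),
    ", specificity = ", round(object@specificity, 3),
    ", AUC = ", round(object@auc, 3), "\n", sep = "")
})

setMethod("show", "ValidationReport", function(object) {
  cat("Validation report -- membership rate to the sensitive class (%):\n")
  print(round(sort(object@mr), 1))
  if (length(object@mrIsens)) {
    cat("  Pearson(MR, I_sens): r =", round(object@mrIsens$r, 3),
      ", p =", signif(object@mrIsens$p, 3), "\n")
  }
})
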