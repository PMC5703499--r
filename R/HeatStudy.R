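#' Construct a HeatStudy container
#'
#' Bundles a bucket abundance matrix and the per-animal phenotype table
#' into a [HeatStudy] (a `SummarizedExperiment` with buckets as rows).
#'
#' @param buckets numeric matrix, buckets x animals; rownames are ppm
#'   labels (strings), colnames are animal ids.
#' @param phenotypes data.frame, one row per animal, with `family`,
#'   `climate` (TEMP/TROP), `batch`, `sex` and trait columns; rownames (or
#'   an `animal_id` column) must match the bucket matrix columns.
#' @param annotations optional character vector of metabolite annotations,
#'   one per bucket; missing entries default to `"unknown"`.
#' @return a [HeatStudy].
#' @export
HeatStudy <- function(buckets, phenotypes, annotations = NULL) {
  buckets <- as.matrix(buckets)
  if ("animal_id" %in% colnames(phenotypes)) {
    rownames(phenotypes) <- phenotypes$animal_id
    phenotypes$animal_id <- NULL
  }
  if (is.null(colnames(buckets)) || is.null(rownames(phenotypes))) {
    stop("animal ids are required on both the bucket matrix and phenotypes")
  }
  mism <- c(
    setdiff(colnames(buckets), rownames(phenotypes)),
    setdiff(rownames(phenotypes), colnames(buckets))
  )
  if (length(mism)) {
    stop("animal ids do not align between buckets and phenotypes: ",
      paste(unique(mism), collapse = ", "))
  }
  phenotypes <- phenotypes[colnames(buckets), , drop = FALSE]
  if (is.null(annotations)) {
    annotations <- rep("unknown", nrow(buckets))
  }
  annotations <- rep_len(as.character(annotations), nrow(buckets))
  rd <- S4Vectors::DataFrame(
    ppm = rownames(buckets),
    annotation = annotations,
    row.names = rownames(buckets)
  )
  se <- SummarizedExperiment(
    assays = list(buckets = buckets),
    colData = S4Vectors::DataFrame(phenotypes),
    rowData = rd
  )
  new("HeatStudy", se)
}

#' Normalize spectra to unit total area
#'
#' Divides each animal's bucket vector by its total so every spectrum sums
#' to one, the standard total-area normalization for NMR bucket tables.
#'
#' @param x a buckets x animals matrix, or a [HeatStudy].
#' @return object of the same kind with unit-sum columns.
#' @export
normalizeBuckets <- function(x) {
  if (is(x, "HeatStudy")) {
    assay(x, "buckets") <- normalizeBuckets(assay(x, "buckets"))
    return(x)
  }
  tot <- colSums(x)
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    stop("cannot normalize: spectra with non-positive total area")
  }
  sweep(x, 2, tot, "/")
}

#' Phenotype table of a study
#'
#' @param x a [HeatStudy].
#' @return data.frame with design columns and traits, one row per animal.
#' @export
phenotypeTable <- function(x) {
  stopifnot(is(x, "HeatStudy"))
  as.data.frame(colData(x))
}
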