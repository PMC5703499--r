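#' Read a phenotype table
#'
#' Reads a delimited phenotype file (one row per animal) and maps its
#' columns onto the canonical names. Climate values are normalized to
#' `TEMP`/`TROP` (case-insensitive; unknown values are rejected). Missing
#' trait values are kept as `NA` — the row is retained.
#'
#' @param path CSV path; lines starting with `#` are treated as comments.
#' @param mapping named list giving the file's column names for `id`,
#'   `family`, `climate`, `batch`, `sex`, and a named character vector
#'   `traits` (canonical name -> file column). Defaults assume canonical
#'   names already.
#' @return data.frame with rownames = animal ids, design columns and
#'   trait columns.
#' @export
readPhenotypes <- function(path, mapping = list()) {
  defaults <- list(id = "animal_id", family = "family",
    climate = "climate", batch = "batch", sex = "sex",
    traits = setNames(traitNames(), traitNames()))
  mapping <- utils::modifyList(defaults, mapping)
  raw <- read.csv(path, comment.char = "#", check.names = FALSE,
    stringsAsFactors = FALSE)
  need <- c(unlist(mapping[c("id", "family", "climate", "batch", "sex")]),
    mapping$traits)
  miss <- setdiff(need, colnames(raw))
  if (length(miss)) {
    stop("mapped column(s) not found: ", paste(miss, collapse = ", "),
      "; available: ", paste(colnames(raw), collapse = ", "))
  }
  ids <- as.character(raw[[mapping$id]])
  if (anyDuplicated(ids)) {
    stop("duplicated animal_id: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  climate <- toupper(trimws(as.character(raw[[mapping$climate]])))
  bad <- setdiff(unique(climate), c("TEMP", "TROP"))
  if (length(bad)) {
    stop("unknown climate value(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(
    family = as.character(raw[[mapping$family]]),
    climate = climate,
    batch = as.character(raw[[mapping$batch]]),
    sex = as.character(raw[[mapping$sex]]),
    row.names = ids, stringsAsFactors = FALSE
  )
  for (tr in names(mapping$traits)) {
    out[[tr]] <- as.numeric(raw[[mapping$traits[tr]]])
  }
  out
}

#' Read a bucket table
#'
#' Reads an animals x buckets CSV whose bucket columns are named by
#' chemical shift (`B2.705` or plain `2.705`; labels are kept as strings
#' and compared by string equality). An optional annotation CSV with
#' columns `bucket` and `annotation` supplies metabolite names; buckets
#' absent from it default to `"unknown"`.
#'
#' @param path bucket CSV (first column = animal id unless named
#'   `animal_id`).
#' @param annotationPath optional annotation CSV.
#' @param renormalize logical; rescale each spectrum to unit total area.
#' @param excludeWindow optional `c(lo, hi)` ppm window to drop (the
#'   water region of raw tables; off by default since deposited tables
#'   are already water-excluded).
#' @return list with `buckets` (buckets x animals matrix, ppm rownames)
#'   and `annotations` (named character).
#' @export
readBuckets <- function(path, annotationPath = NULL, renormalize = FALSE,
                        excludeWindow = NULL) {
  raw <- read.csv(path, comment.char = "#", check.names = FALSE,
    stringsAsFactors = FALSE)
  idCol <- if ("animal_id" %in% colnames(raw)) "animal_id" else
    colnames(raw)[1]
  ids <- as.character(raw[[idCol]])
  keep <- colnames(raw) != idCol
  # validate labels on the raw header: data.frame subsetting would
  # silently uniquify duplicated column names
  labels <- sub("^B", "", colnames(raw)[keep])
  if (anyDuplicated(labels)) {
    stop("duplicated bucket label(s): ",
      paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  m <- as.matrix(raw[, keep, drop = FALSE])
  colnames(m) <- labels
  if (any(!is.finite(m)) || any(m < 0)) {
    bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)[1, ]
    stop("negative or missing abundance at row ", ids[bad[1]],
      ", bucket ", labels[bad[2]])
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  B <- t(m)
  if (!is.null(excludeWindow)) {
    ppm <- as.numeric(labels)
    B <- B[!(ppm >= excludeWindow[1] & ppm <= excludeWindow[2]), ,
      drop = FALSE]
  }
  if (renormalize) B <- normalizeBuckets(B)
  ann <- setNames(rep("unknown", nrow(B)), rownames(B))
  if (!is.null(annotationPath)) {
    at <- read.csv(annotationPath, comment.char = "#",
      stringsAsFactors = FALSE)
    at$bucket <- sub("^B", "", as.character(at$bucket))
    hit <- intersect(at$bucket, names(ann))
    ann[hit] <- at$annotation[match(hit, at$bucket)]
  }
  list(buckets = B, annotations = ann)
}

#' Read a full study from phenotype + bucket files
#'
#' @param phenoPath,bucketPath,annotationPath file paths.
#' @param ... passed to [readBuckets()].
#' @inheritParams readPhenotypes
#' @return a [HeatStudy].
#' @export
readStudy <- function(phenoPath, bucketPath, annotationPath = NULL,
                      mapping = list(), ...) {
  ph <- readPhenotypes(phenoPath, mapping)
  bk <- readBuckets(bucketPath, annotationPath, ...)
  HeatStudy(bk$buckets, ph, bk$annotations)
}

metaHeader <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("metaboSens"))
  paste0("# metaboSens ", ver,
    if (!is.null(seed)) paste0("; seed=", seed),
    if (!is.null(config)) paste0("; config=", config))
}

writeCsvWithHeader <- function(df, path, seed = NULL, config = NULL,
                               rowLabel = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metaHeader(seed, config), con)
  if (!is.null(rowLabel)) {
    df <- cbind(setNames(data.frame(rownames(df)), rowLabel), df)
  }
  write.csv(df, con, row.names = FALSE)
}

#' Write a study to CSV files
#'
#' Writes `phenotypes.csv` (one row per animal), `buckets.csv` (one row
#' per animal, bucket columns named `B<ppm>`) and `annotations.csv`
#' (bucket -> metabolite or `"unknown"`), each with a comment header
#' carrying the package version and seed. Round-trips through
#' [readStudy()].
#'
#' @param study a [HeatStudy].
#' @param dir output directory (created if needed).
#' @param seed optional seed recorded in the headers.
#' @return invisibly, the paths written.
#' @export
writeStudy <- function(study, dir, seed = NULL) {
  stopifnot(is(study, "HeatStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- as.data.frame(colData(study))
  bk <- as.data.frame(t(bucketMatrix(study)))
  colnames(bk) <- paste0("B", rownames(study))
  an <- data.frame(bucket = rownames(study),
    annotation = bucketAnnotations(study))
  paths <- file.path(dir, c("phenotypes.csv", "buckets.csv",
    "annotations.csv"))
  writeCsvWithHeader(ph, paths[1], seed, rowLabel = "animal_id")
  writeCsvWithHeader(bk, paths[2], seed, rowLabel = "animal_id")
  writeCsvWithHeader(an, paths[3], seed)
  invisible(paths)
}

#' Run the full sensitivity-prediction workflow
#'
#' Chains the three analysis steps on one study: (1) empirical-Bayes
#' adjustment for batch and sex with PVCA auditing; (2) the Welch-t /
#' PCA sensitivity index and selection of the extreme robust and
#' sensitive reference families; (3) sparse PLS-DA tuning, fitting and
#' cross-validation on the thermoneutral metabolomes of the extremes,
#' prediction of every family's membership rate to the sensitive class,
#' its correlation with the index, and the differential-bucket and
#' bucket-phenotype correlation tables.
#'
#' @param study a [HeatStudy]; if `NULL`, one is generated from `config`.
#' @param config [StudyConfig] used when `study` is `NULL`.
#' @param outDir optional directory; when given, every result table is
#'   written as a commented CSV.
#' @param k families per extreme group.
#' @param ncomp,grid,tuneFolds,tuneRepeats sparse PLS-DA tuning layout.
#' @param folds,repeats cross-validation layout for the reported BER /
#'   AUC / stability.
#' @param seed integer seed driving every random draw of the run.
#' @param rule prediction rule (`"centroid"` or `"response"`).
#' @param adjust logical; skip the adjustment step on pre-adjusted
#'   inputs with `FALSE`.
#' @param runPvca logical; compute PVCA diagnostics (requires `adjust`).
#' @param pvcaThreshold PVCA cumulative-variance threshold.
#' @param mrFamilies `"all"` (default) correlates MR with the index over
#'   all families; `"validation"` restricts to the non-extreme ones.
#' @param verbose print stage-by-stage headline numbers.
#' @return list with `study` (adjusted), `pvcaBefore`, `pvcaAfter`,
#'   `tmatrix`, `isens`, `extremes`, `tuning`, `model`, `cv`, `vip`,
#'   `predictions`, and `validation` (a [ValidationReport]).
#' @export
runWorkflow <- function(study = NULL, config = studyConfig(),
                        outDir = NULL, k = 2, ncomp = 3, grid = 5:20,
                        tuneFolds = 10, tuneRepeats = 3, folds = 10,
                        repeats = 10, seed = 1, rule = "centroid",
                        adjust = TRUE, runPvca = TRUE,
                        pvcaThreshold = 0.6, mrFamilies = c("all",
                          "validation"), verbose = FALSE) {
  mrFamilies <- match.arg(mrFamilies)
  say <- function(...) if (verbose) message(...)
  if (is.null(study)) {
    say("generating synthetic study (seed ", config@seed, ")")
    study <- generateStudy(config)$study
  }
  seeds <- subSeeds(seed, 2)

  if (adjust) {
    say("adjusting for batch and sex effects")
    adj <- sequentialAdjust(study, runPvca = runPvca,
      pvcaThreshold = pvcaThreshold)
    adjusted <- adj$study
    if (runPvca && verbose) {
      say("  PVCA after (buckets): ",
        paste(sprintf("%s=%.1f%%", names(wapv(adj$pvcaAfter$buckets)),
          wapv(adj$pvcaAfter$buckets)), collapse = " "))
    }
  } else {
    adj <- list(pvcaBefore = NULL, pvcaAfter = NULL, models = list())
    adjusted <- study
  }

  tm <- buildTMatrix(adjusted)
  idx <- computeIsens(tm)
  ext <- selectExtremes(idx, k = k)
  say("extremes: robust = ", paste(ext$robust, collapse = ", "),
    "; sensitive = ", paste(ext$sensitive, collapse = ", "))

  cd <- as.data.frame(colData(adjusted))
  temp <- cd$climate == "TEMP"
  trainIdx <- temp & cd$family %in% c(ext$robust, ext$sensitive)
  Xtrain <- t(bucketMatrix(adjusted)[, trainIdx, drop = FALSE])
  ytrain <- factor(ifelse(cd$family[trainIdx] %in% ext$sensitive,
    "sensitive", "robust"), levels = c("robust", "sensitive"))

  say("tuning keepX over ", min(grid), "..", max(grid))
  tuning <- tuneKeepX(Xtrain, ytrain, ncomp = ncomp, grid = grid,
    folds = tuneFolds, repeats = tuneRepeats, seed = seeds[1],
    rule = rule)
  say("  keepX = (", paste(tuning$keepX, collapse = ", "), ")")
  model <- splsda(Xtrain, ytrain, keepX = tuning$keepX)
  cv <- crossValidate(Xtrain, ytrain, keepX = tuning$keepX,
    folds = folds, repeats = repeats, seed = seeds[2], rule = rule)
  say("  CV: BER = ", round(cv@ber, 3), ", AUC = ", round(cv@auc, 3))
  vipScores <- vip(model)

  Xall <- t(bucketMatrix(adjusted)[, temp, drop = FALSE])
  pred <- predict(model, Xall, rule = rule)
  mr <- membershipRate(pred$class, cd$family[temp],
    positive = "sensitive")
  valFams <- if (mrFamilies == "validation") {
    setdiff(names(mr), c(ext$robust, ext$sensitive))
  } else NULL
  mrCor <- mrIsensCorrelation(mr, idx, families = valFams)
  say("  Pearson(MR, I_sens) = ", round(mrCor$r, 3))

  diffTab <- differentialBuckets(t(Xtrain), ytrain)
  panel <- bucketPhenotypePanel(adjusted, vipScores, idx, mr)
  validation <- new("ValidationReport", mr = mr, mrIsens = mrCor,
    differential = diffTab, panel = panel)

  res <- list(study = adjusted, pvcaBefore = adj$pvcaBefore,
    pvcaAfter = adj$pvcaAfter, tmatrix = tm, isens = idx,
    extremes = ext, tuning = tuning, model = model, cv = cv,
    vip = vipScores, predictions = pred, validation = validation)
  cfgTag <- paste0("k", k, ".ncomp", ncomp, ".grid", min(grid), "-",
    max(grid), ".cv", folds, "x", repeats, ".rule-", rule)
  if (!is.null(outDir)) writeWorkflow(res, outDir, seed, cfgTag)
  res
}

pvcaFrame <- function(pv) {
  do.call(rbind, lapply(names(pv), function(b) data.frame(
    block = b, factor = names(wapv(pv[[b]])), wapv = wapv(pv[[b]]),
    row.names = NULL)))
}

# Writes the workflow's result bundle as commented CSVs.
writeWorkflow <- function(res, outDir, seed, config = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, rowLabel = NULL) {
    writeCsvWithHeader(df, file.path(outDir, name), seed, config,
      rowLabel = rowLabel)
  }
  writeStudy(res$study, outDir, seed)
  if (!is.null(res$pvcaBefore)) {
    w(pvcaFrame(res$pvcaBefore), "pvca_before.csv")
    w(pvcaFrame(res$pvcaAfter), "pvca_after.csv")
  }
  w(as.data.frame(tStats(res$tmatrix)), "t_matrix.csv",
    rowLabel = "family")
  w(data.frame(family = names(isensScores(res$isens)),
    isens = isensScores(res$isens)), "isens.csv")
  w(res$tuning$curves, "tuning_curves.csv")
  w(data.frame(bucket = names(res$vip), vip = res$vip), "vip.csv")
  w(data.frame(bucket = names(stability(res$cv)),
    stability = stability(res$cv)), "stability.csv")
  w(res$cv@roc, "roc.csv")
  w(data.frame(family = names(membershipRates(res$validation)),
    mr = membershipRates(res$validation)), "mr.csv")
  w(res$validation@differential, "differential_buckets.csv")
  w(res$validation@panel, "correlation_panel.csv")
  invisible(outDir)
}
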