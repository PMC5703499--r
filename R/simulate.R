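#' Configure the synthetic two-climate sire-family study
#'
#' Builds a [StudyConfig] describing the design the generator emulates:
#' ten sire families phenotyped in a temperate (TEMP) and a tropical
#' (TROP) environment (about 56 +/- 5 offspring per family per climate,
#' females and castrated males, 11 and 12 contemporary batches), a latent
#' per-family sensitivity gradient that scales the TROP drop in feed
#' intake and body weight and the TROP rise in rectal temperature, and a
#' 445-bucket NMR metabolome in which a subset of buckets tracks the
#' latent sensitivity already under thermoneutral conditions (robust
#' families richer). Trait residual standard deviations default to the
#' root-mean-square errors of the study's phenotype models.
#'
#' @param nFamilies number of sire families.
#' @param offspringPerCell mean offspring per family per climate.
#' @param offspringSD sd of the per-cell count (counts are clipped at 10).
#' @param nBatchesTemp,nBatchesTrop batches per climate.
#' @param nBuckets number of NMR buckets.
#' @param nInformative buckets carrying the sensitivity signal.
#' @param familySensitivity latent per-family sensitivity values
#'   (centered); default is an evenly spaced gradient over `[-1.5, 1.5]`.
#' @param traitBase TEMP trait means (named over [traitNames()]).
#' @param climateEffect additive TROP shift per trait.
#' @param sensitivityScaling per-trait multiplier of the latent
#'   sensitivity in the TROP shift; negative for traits that drop more in
#'   sensitive families (ADFI, BW, ADG), positive for RT.
#' @param residualSD per-trait residual sd.
#' @param batchSD per-trait sd of batch effects; default 0.3 x residual.
#' @param sexEffect additive trait shift for castrated males.
#' @param bucketEffectSize slope of informative-bucket log-abundance on
#'   the latent sensitivity for TEMP animals (sign flipped internally so
#'   robust families are richer).
#' @param bucketBaseSD,bucketClimateSD,bucketBatchSD,bucketSexSD,bucketResidualSD
#'   log-scale magnitudes of the bucket baseline spread, per-bucket
#'   climate shifts, batch effects, sex coefficients and residual noise.
#' @param seed integer RNG seed.
#' @details Per-trait arguments accept a full named vector over
#'   [traitNames()], a partial named vector (unnamed traits keep their
#'   default), or a single unnamed value applied to every trait.
#' @return a validated [StudyConfig].
#' @export
studyConfig <- function(nFamilies = 10,
                        offspringPerCell = 56,
                        offspringSD = 5,
                        nBatchesTemp = 11,
                        nBatchesTrop = 12,
                        nBuckets = 445,
                        nInformative = 30,
                        familySensitivity = NULL,
                        traitBase = NULL,
                        climateEffect = NULL,
                        sensitivityScaling = NULL,
                        residualSD = NULL,
                        batchSD = NULL,
                        sexEffect = NULL,
                        bucketEffectSize = 0.25,
                        bucketBaseSD = 1,
                        bucketClimateSD = 0.15,
                        bucketBatchSD = 0.09,
                        bucketSexSD = 0.07,
                        bucketResidualSD = 0.4,
                        seed = 1L) {
  if (is.null(familySensitivity)) {
    familySensitivity <- if (nFamilies == 1) 0 else
      seq(-1.5, 1.5, length.out = nFamilies)
  }
  tr <- traitNames()
  fill <- function(v, def) {
    def <- setNames(def, tr)
    if (is.null(v)) return(def)
    if (is.null(names(v))) {
      if (!length(v) %in% c(1L, length(tr))) {
        stop("per-trait vectors must be named, scalar, or length ",
          length(tr))
      }
      return(setNames(rep_len(as.numeric(v), length(tr)), tr))
    }
    bad <- setdiff(names(v), tr)
    if (length(bad)) stop("unknown trait name(s): ",
      paste(bad, collapse = ", "))
    def[names(v)] <- v
    def
  }
  traitBase <- fill(traitBase,
    c(2.25, 101.5, 39.25, 806, 2.8, 20.4, 34.35))
  climateEffect <- fill(climateEffect,
    c(-0.5, -15, 0.25, -70, -0.4, -4.6, 1.25))
  sensitivityScaling <- fill(sensitivityScaling,
    c(-0.15, -4.5, 0.1, -30, 0, 0, 0))
  residualSD <- fill(residualSD, c(0.42, 9, 0.3, 136, 0.54, 2.7, 0.7))
  sexEffect <- fill(sexEffect, c(0.15, 3, -0.05, 25, 0.1, 1.5, 0))
  batchSD <- fill(batchSD, 0.3 * residualSD)
  new("StudyConfig",
    nFamilies = as.integer(nFamilies),
    offspringPerCell = offspringPerCell,
    offspringSD = offspringSD,
    nBatchesTemp = as.integer(nBatchesTemp),
    nBatchesTrop = as.integer(nBatchesTrop),
    nBuckets = as.integer(nBuckets),
    nInformative = as.integer(nInformative),
    familySensitivity = familySensitivity,
    traitBase = traitBase,
    climateEffect = climateEffect,
    sensitivityScaling = sensitivityScaling,
    residualSD = residualSD,
    batchSD = batchSD,
    sexEffect = sexEffect,
    bucketEffectSize = bucketEffectSize,
    bucketBaseSD = bucketBaseSD,
    bucketClimateSD = bucketClimateSD,
    bucketBatchSD = bucketBatchSD,
    bucketSexSD = bucketSexSD,
    bucketResidualSD = bucketResidualSD,
    seed = as.integer(seed)
  )
}

# Bucket ppm labels: 0.01-ppm bucket centers walking up from 0.705 ppm,
# skipping the water window (4.50-5.10 ppm).
bucketLabels <- function(n) {
  ppm <- seq(0.705, by = 0.01, length.out = n + 70)
  ppm <- ppm[ppm < 4.50 | ppm > 5.10]
  sprintf("%.3f", ppm[seq_len(n)])
}

#' Generate a synthetic study
#'
#' Draws a phenotype table and a unit-sum-normalized bucket table with the
#' structure the analysis assumes: per-cell offspring counts
#' `round(Normal(offspring, sd))` clipped at 10; TROP trait means shifted
#' by `climateEffect + sensitivityScaling * s_f`; batch effects (round-robin
#' batch assignment within climate) and sex effects (alternating sexes) on
#' both blocks; log-normal bucket abundances in which the informative
#' buckets' thermoneutral mean decreases with family sensitivity, then
#' total-area normalization. The latent truth is returned separately so
#' tests never read it through the pipeline path.
#'
#' @param config a [StudyConfig]; same seed gives identical output.
#' @return list with `study` (a [HeatStudy]) and `truth` (list with
#'   `sensitivity`, the named latent per-family values, and
#'   `informativeBuckets`, the ppm labels of the signal-carrying buckets).
#' @examples
#' sim <- generateStudy(studyConfig(nFamilies = 4, offspringPerCell = 15,
#'   nBuckets = 40, nInformative = 6, seed = 7))
#' table(sim$study$family, sim$study$climate)
#' @export
generateStudy <- function(config = studyConfig()) {
  validObject(config)
  withSeed(config@seed, {
    nf <- config@nFamilies
    fams <- sprintf("SF%d", seq_len(nf))
    sf <- setNames(config@familySensitivity, fams)
    climates <- c("TEMP", "TROP")
    nBatches <- c(TEMP = config@nBatchesTemp, TROP = config@nBatchesTrop)

    counts <- matrix(
      pmax(10, round(rnorm(nf * 2, config@offspringPerCell,
        config@offspringSD))),
      nrow = nf, dimnames = list(fams, climates)
    )

    pheno <- do.call(rbind, lapply(climates, function(cl) {
      do.call(rbind, lapply(fams, function(f) {
        data.frame(family = f, climate = cl,
          stringsAsFactors = FALSE)[rep(1, counts[f, cl]), , drop = FALSE]
      }))
    }))
    # balanced nuisance structure: round-robin batches within climate,
    # alternating sexes
    pheno$batch <- NA_character_
    for (cl in climates) {
      i <- which(pheno$climate == cl)
      pheno$batch[i] <- sprintf("%s_B%02d", cl,
        rep_len(seq_len(nBatches[cl]), length(i)))
    }
    pheno$sex <- rep_len(c("female", "castrated male"), nrow(pheno))
    rownames(pheno) <- sprintf("A%04d", seq_len(nrow(pheno)))

    tr <- traitNames()
    batchLevels <- sort(unique(pheno$batch))
    batchEff <- sapply(tr, function(t)
      setNames(rnorm(length(batchLevels), 0, config@batchSD[t]),
        batchLevels))
    isTrop <- pheno$climate == "TROP"
    isMale <- pheno$sex == "castrated male"
    sAnimal <- sf[pheno$family]
    for (t in tr) {
      mu <- config@traitBase[t] +
        isTrop * (config@climateEffect[t] +
          config@sensitivityScaling[t] * sAnimal) +
        batchEff[pheno$batch, t] +
        isMale * config@sexEffect[t]
      pheno[[t]] <- mu + rnorm(nrow(pheno), 0, config@residualSD[t])
    }

    nb <- config@nBuckets
    labels <- bucketLabels(nb)
    informative <- sort(sample.int(nb, config@nInformative))
    mu0 <- rnorm(nb, 3, config@bucketBaseSD)
    climCoef <- rnorm(nb, 0, config@bucketClimateSD)
    bucketBatch <- matrix(rnorm(length(batchLevels) * nb, 0,
      config@bucketBatchSD), nrow = length(batchLevels),
      dimnames = list(batchLevels, NULL))
    sexCoef <- rnorm(nb, 0, config@bucketSexSD)

    n <- nrow(pheno)
    logA <- matrix(rep(mu0, each = n), nrow = n) +
      outer(as.numeric(isTrop), climCoef) +
      bucketBatch[pheno$batch, ] +
      outer(as.numeric(isMale), sexCoef)
    # informative buckets: thermoneutral abundance decreases with family
    # sensitivity (robust families richer)
    shift <- outer(ifelse(isTrop, 0, -config@bucketEffectSize * sAnimal),
      as.numeric(seq_len(nb) %in% informative))
    logA <- logA + shift + matrix(rnorm(n * nb, 0,
      config@bucketResidualSD), nrow = n)
    buckets <- normalizeBuckets(t(exp(logA)))
    dimnames(buckets) <- list(labels, rownames(pheno))

    nAnnot <- min(nb, max(0, round(nb * 333 / 445)))
    annotations <- c(sprintf("metabolite_%03d", seq_len(nAnnot)),
      rep("unknown", nb - nAnnot))

    study <- HeatStudy(buckets, pheno, annotations)
    list(
      study = study,
      truth = list(
        sensitivity = sf,
        informativeBuckets = labels[informative]
      )
    )
  })
}
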