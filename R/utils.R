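#' Trait names handled by the pipeline
#'
#' The seven phenotypes, in canonical order: average daily feed intake
#' (ADFI, kg/d), body weight (BW, kg), rectal temperature (RT, degC),
#' average daily gain (ADG, g/d), feed conversion ratio (FCR, kg/kg),
#' average backfat thickness (ABFT, mm) and skin temperature (ST, degC).
#'
#' @return character vector of trait names.
#' @export
traitNames <- function() {
  c("ADFI", "BW", "RT", "ADG", "FCR", "ABFT", "ST")
}

# The three traits entering the sensitivity index.
sensTraits <- function() c("ADFI", "BW", "RT")

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so simulation calls do not perturb user code.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Stratified fold assignment: indices of each class are shuffled and dealt
# round-robin, so every fold's training part contains both classes.
stratifiedFolds <- function(y, folds) {
  y <- factor(y)
  if (min(table(y)) < folds) {
    stop("cannot stratify: a class has fewer samples (",
      min(table(y)), ") than folds (", folds, ")")
  }
  assign <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# Derive a stream of sub-seeds from one seed, kept below 2^31.
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}
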