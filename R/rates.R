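#' Point mutation-rate estimate
#'
#' The basic mutation-accumulation rate: observed mutations divided by
#' (cumulative generations x target sites). Full precision is kept
#' internally; display rounding (2 significant figures) happens only in
#' `show`/reports.
#'
#' @param m non-negative mutation count.
#' @param generations cumulative generations summed over lines (> 0).
#' @param sites number of surveyed sites in bp (> 0).
#' @return a [RateEstimate-class].
#' @examples
#' pointRate(25, 3e5, 941000)  # 8.9e-11 per bp per generation
#' @export
pointRate <- function(m, generations, sites) {
  stopifnot(m >= 0, generations > 0, sites > 0)
  new("RateEstimate", numMutations = m, generations = generations,
      sites = sites, rate = m / (generations * sites))
}

#' Numeric rate per bp per generation
#'
#' @param x a [RateEstimate-class], [GenomeRate-class] or plain number.
#' @return numeric(1).
#' @export
ratePerBp <- function(x) {
  if (is(x, "RateEstimate")) x@rate
  else if (is(x, "GenomeRate")) x@ratePerBp
  else as.numeric(x)
}

#' @rdname ratePerBp
#' @export
ratePerGenome <- function(x) {
  if (is(x, "GenomeRate")) x@ratePerGenome
  else as.numeric(x)
}

#' Scale a per-bp rate to a whole genome
#'
#' @param rate a [RateEstimate-class] or per-bp numeric rate.
#' @param genomeSize genome length in bp (> 0).
#' @return a [GenomeRate-class].
#' @examples
#' perGenomeRate(pointRate(25, 3e5, 941000), 4629812)  # 0.00041
#' @export
perGenomeRate <- function(rate, genomeSize) {
  stopifnot(genomeSize > 0)
  r <- ratePerBp(rate)
  new("GenomeRate", ratePerBp = r, genomeSize = genomeSize,
      ratePerGenome = r * genomeSize)
}

#' Expected substitution-class counts over an experiment
#'
#' Chained products: total = genome rate x generations; coding = total x
#' coding fraction; synonymous = coding x synonymous fraction. The default
#' fractions (0.86 coding, 0.25 synonymous-within-coding) are typical for a
#' gene-dense bacterial genome with near-equal base composition and can be
#' overridden.
#'
#' @param genomeRate per genome per generation ([GenomeRate-class] or
#'   numeric).
#' @param generations experiment duration T.
#' @param codingFraction,synonymousFraction fractions in \[0, 1\].
#' @return an [ExpectedCounts-class].
#' @examples
#' expectedClassCounts(0.0025, 40000)  # 100 total, 86 coding, 21.5 synonymous
#' @export
expectedClassCounts <- function(genomeRate, generations,
                                codingFraction = 0.86,
                                synonymousFraction = 0.25) {
  stopifnot(generations >= 0,
            codingFraction >= 0, codingFraction <= 1,
            synonymousFraction >= 0, synonymousFraction <= 1)
  r <- ratePerGenome(genomeRate)
  total <- r * generations
  coding <- total * codingFraction
  new("ExpectedCounts", generations = generations, genomeRate = r,
      codingFraction = codingFraction, synonymousFraction = synonymousFraction,
      total = total, coding = coding, synonymous = coding * synonymousFraction)
}

#' Fold difference between two rates
#'
#' @param a,b rates (objects or numerics); `b` must be positive.
#' @return a / b.
#' @examples
#' foldDifference(0.0025, 0.00041)  # 6.1
#' @export
foldDifference <- function(a, b) {
  av <- if (is(a, "GenomeRate")) a@ratePerGenome else ratePerBp(a)
  bv <- if (is(b, "GenomeRate")) b@ratePerGenome else ratePerBp(b)
  if (bv <= 0) stop("denominator rate must be positive")
  av / bv
}

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate: %g / (%g generations x %g sites) = %s per bp per generation\n",
              object@numMutations, object@generations, object@sites,
              format(signif(object@rate, 2))))
})

setMethod("show", "GenomeRate", function(object) {
  cat(sprintf("GenomeRate: %s per bp x %g bp = %s per genome per generation\n",
              format(signif(object@ratePerBp, 2)), object@genomeSize,
              format(signif(object@ratePerGenome, 2))))
})

setMethod("show", "ExpectedCounts", function(object) {
  cat(sprintf(
    "ExpectedCounts over %g generations at %s/genome/generation:\n  total %.4g, coding %.4g, synonymous %.4g\n",
    object@generations, format(signif(object@genomeRate, 2)),
    object@total, object@coding, object@synonymous))
})

#' Expected-counts accessors
#'
#' @param x an [ExpectedCounts-class].
#' @return numeric(1).
#' @export
totalCount <- function(x) { stopifnot(is(x, "ExpectedCounts")); x@total }

#' @rdname totalCount
#' @export
codingCount <- function(x) { stopifnot(is(x, "ExpectedCounts")); x@coding }

#' @rdname totalCount
#' @export
synonymousCount <- function(x) { stopifnot(is(x, "ExpectedCounts")); x@synonymous }
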