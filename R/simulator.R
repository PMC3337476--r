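#' Construct a serial-transfer regime
#'
#' @param bottleneckCells cells transferred at each bottleneck (default
#'   5e6, a 1:100 dilution of an overnight culture).
#' @param growthFactor fold growth per cycle (default 100), giving
#'   `log2(growthFactor)` binary-fission generations per cycle (~6.64).
#' @param totalGenerations nominal experiment length (default 40000).
#' @return a [RegimeSpec-class].
#' @export
regimeSpec <- function(bottleneckCells = 5e6, growthFactor = 100,
                       totalGenerations = 4e4) {
  new("RegimeSpec", bottleneckCells = bottleneckCells,
      growthFactor = growthFactor, totalGenerations = totalGenerations)
}

#' Regime accessors
#'
#' @param x a [RegimeSpec-class].
#' @return `bottleneckCells`, `growthFactor`, `totalGenerations`: the
#'   stored constants; `generationsPerCycle`: `log2(growthFactor)`;
#'   `nCycles`: `totalGenerations / generationsPerCycle`.
#' @export
bottleneckCells <- function(x) { stopifnot(is(x, "RegimeSpec")); x@bottleneckCells }

#' @rdname bottleneckCells
#' @export
growthFactor <- function(x) { stopifnot(is(x, "RegimeSpec")); x@growthFactor }

#' @rdname bottleneckCells
#' @export
totalGenerations <- function(x) { stopifnot(is(x, "RegimeSpec")); x@totalGenerations }

#' @rdname bottleneckCells
#' @export
generationsPerCycle <- function(x) {
  stopifnot(is(x, "RegimeSpec")); log2(x@growthFactor)
}

#' @rdname bottleneckCells
#' @export
nCycles <- function(x) {
  stopifnot(is(x, "RegimeSpec"))
  x@totalGenerations / generationsPerCycle(x)
}

setMethod("show", "RegimeSpec", function(object) {
  cat(sprintf(
    "RegimeSpec: %.3g-cell bottleneck, %gx growth (%.3f generations/cycle), %g generations (%.0f cycles)\n",
    object@bottleneckCells, object@growthFactor,
    generationsPerCycle(object), object@totalGenerations, nCycles(object)))
})

#' Deterministic within-cycle selection update
#'
#' Relative-fitness update of a mutant frequency over g generations of
#' exponential growth: `f' = f (1+s)^g / (f (1+s)^g + 1 - f)`. With s = 0
#' this is the identity; f = 0 and f = 1 are absorbing.
#'
#' @param f mutant frequency(ies) in \[0, 1\].
#' @param s per-generation selection coefficient (> -1).
#' @param g generations of growth.
#' @return updated frequency(ies).
#' @export
growthUpdate <- function(f, s, g) {
  stopifnot(all(f >= 0), all(f <= 1))
  if (1 + s <= 0) stop("1 + s must be positive")
  w <- (1 + s)^g
  f * w / (f * w + 1 - f)
}

#' Binomial bottleneck sampling
#'
#' Drift at transfer: the next founder population is a binomial sample of
#' `nB` cells at the current mutant frequency.
#'
#' @param f mutant frequency(ies) in \[0, 1\].
#' @param nB bottleneck size in cells.
#' @return sampled frequency(ies) `X / nB`, `X ~ Binomial(nB, f)`.
#' @export
bottleneckSample <- function(f, nB) {
  stopifnot(all(f >= 0), all(f <= 1), nB >= 1)
  rbinom(length(f), nB, f) / nB
}

## One replicate matrix of lineages through nC cycles. Uses
## qbinom(runif(...)) rather than rbinom so that runs with the same seed
## but different s consume identical uniforms (common random numbers):
## the paired depression ratio is then exactly 1 at s = 0 and smooth in s.
runLineages <- function(s, regime, nC, replicates, f0, threshold) {
  nB <- bottleneckCells(regime)
  g <- generationsPerCycle(regime)
  f <- rep(f0, replicates)
  for (i in seq_len(nC)) {
    u <- runif(replicates)           # full-length draw keeps streams aligned
    alive <- which(f > 0 & f < 1)
    if (length(alive)) {
      fg <- growthUpdate(f[alive], s, g)
      f[alive] <- qbinom(u[alive], nB, fg) / nB
    }
    if (!any(f > 0)) break
  }
  mean(f >= threshold & f > 0)
}

#' Probability that a new mutant lineage survives the bottleneck regime
#'
#' Each replicate lineage starts as a single mutant cell in a fresh
#' bottleneck population (`f0 = 1/bottleneckCells`) and passes through
#' `floor(horizon / generationsPerCycle)` cycles of deterministic growth
#' under selection followed by binomial transfer sampling. Retention means
#' presence at one or more copies in the final bottleneck sample (or at
#' frequency >= `threshold` when set, mimicking a detection limit).
#'
#' @param s per-generation selection coefficient.
#' @param regime a [RegimeSpec-class].
#' @param horizon generations to simulate (>= one cycle).
#' @param replicates independent lineages.
#' @param seed RNG seed (`NULL` uses the current stream).
#' @param origin `"bottleneck"`: the mutant is among the cells founding a
#'   cycle (default); `"growth"`: it arises during growth, entering the
#'   first transfer at frequency `1/(bottleneckCells * growthFactor)`.
#' @param threshold detection frequency; default 0 means >= 1 copy.
#' @return list with `retention`, its binomial `se`, `replicates`,
#'   `cycles` and `s`.
#' @export
retentionProbability <- function(s, regime = regimeSpec(),
                                 horizon = 200, replicates = 10000,
                                 seed = NULL,
                                 origin = c("bottleneck", "growth"),
                                 threshold = 0) {
  stopifnot(replicates >= 1)
  origin <- match.arg(origin)
  g <- generationsPerCycle(regime)
  nC <- floor(horizon / g + 1e-9)
  if (nC < 1) stop("horizon shorter than one growth+bottleneck cycle")
  f0 <- if (origin == "bottleneck") 1 / bottleneckCells(regime)
        else 1 / (bottleneckCells(regime) * growthFactor(regime))
  r <- withSeed(seed,
    runLineages(s, regime, nC, replicates, f0, threshold))
  list(retention = r, se = sqrt(r * (1 - r) / replicates),
       replicates = replicates, cycles = nC, s = s)
}

#' Rate-depression ratio implied by selection
#'
#' The factor by which purifying selection depresses the apparent
#' mutation-accumulation rate: the retention probability of a neutral
#' lineage divided by that of a lineage with coefficient s, both simulated
#' with the same seed (paired common random numbers, so the ratio is
#' exactly 1 at s = 0 and its Monte-Carlo noise largely cancels).
#'
#' @inheritParams retentionProbability
#' @return list with `ratio`, delta-method `se`, the two retention
#'   results (`neutral`, `selected`) and an `infinite` flag set when no
#'   selected lineage survived.
#' @export
rateDepressionRatio <- function(s, regime = regimeSpec(), horizon = 200,
                                replicates = 10000, seed = NULL,
                                origin = c("bottleneck", "growth"),
                                threshold = 0) {
  origin <- match.arg(origin)
  r0 <- retentionProbability(0, regime, horizon, replicates, seed,
                             origin, threshold)
  rs <- retentionProbability(s, regime, horizon, replicates, seed,
                             origin, threshold)
  if (rs$retention == 0)
    return(list(ratio = Inf, se = NA_real_, neutral = r0, selected = rs,
                infinite = TRUE))
  ratio <- r0$retention / rs$retention
  se <- ratio * sqrt((r0$se / r0$retention)^2 + (rs$se / rs$retention)^2)
  list(ratio = ratio, se = se, neutral = r0, selected = rs,
       infinite = FALSE)
}

#' Selection coefficient implied by an observed rate depression
#'
#' Inverts the simulated depression-ratio curve: finds the s <= 0 whose
#' paired-seed [rateDepressionRatio()] matches the observed ratio, by
#' bisection on the (seed-fixed, hence deterministic and monotone) curve
#' until the bracket is narrower than `tol`. The Monte-Carlo standard
#' error is propagated through the local slope of the curve.
#'
#' @param observedRatio observed neutral-to-selected rate ratio, >= 1.
#' @inheritParams retentionProbability
#' @param sMin most negative coefficient tried when bracketing (the
#'   bracket is extended towards -1 if needed).
#' @param tol bisection tolerance on s.
#' @return a [SelectionEstimate-class].
#' @export
inferSelectionCoefficient <- function(observedRatio, regime = regimeSpec(),
                                      horizon = 200, replicates = 10000,
                                      seed = NULL, sMin = -0.1,
                                      tol = 1e-4) {
  if (observedRatio < 1) stop("observedRatio must be >= 1")
  if (is.null(seed)) seed <- as.integer(runif(1, 1, 2^30))
  ratioAt <- function(s)
    rateDepressionRatio(s, regime, horizon, replicates, seed)
  seedNum <- as.numeric(seed)
  if (observedRatio == 1)
    return(new("SelectionEstimate", sHat = 0, se = 0,
               replicates = as.numeric(replicates), seed = seedNum))
  lo <- sMin
  rl <- ratioAt(lo)
  while (!rl$infinite && rl$ratio < observedRatio) {
    if (lo <= -0.95)
      stop("bracket failure: ratio ", observedRatio,
           " not achievable at this horizon (max simulated ", rl$ratio, ")")
    lo <- max(-0.95, 2 * lo)
    rl <- ratioAt(lo)
  }
  hi <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    rm <- ratioAt(mid)
    if (!rm$infinite && rm$ratio < observedRatio) hi <- mid else lo <- mid
  }
  sHat <- (lo + hi) / 2
  delta <- max(5e-4, abs(sHat) / 10)
  rAbove <- ratioAt(min(0, sHat + delta))
  rBelow <- ratioAt(sHat - delta)
  slope <- (rBelow$ratio - rAbove$ratio) /
           ((sHat - delta) - min(0, sHat + delta))
  rHat <- ratioAt(sHat)
  se <- if (is.finite(slope) && slope != 0) abs(rHat$se / slope) else NA_real_
  new("SelectionEstimate", sHat = sHat, se = se,
      replicates = as.numeric(replicates), seed = seedNum)
}

#' Simulate a mutant/parental mixture trajectory
#'
#' Reconstruction-control simulator: starts a mixture at frequency `f0`
#' and follows it through growth + bottleneck cycles, recording the
#' post-transfer frequency after each cycle. With `stochastic = FALSE`
#' the bottleneck is skipped and the trajectory is the deterministic
#' selection curve.
#'
#' @param f0 starting mutant frequency in (0, 1).
#' @param s per-generation selection coefficient.
#' @param regime a [RegimeSpec-class].
#' @param cycles number of growth + transfer cycles.
#' @param seed RNG seed.
#' @param stochastic include binomial bottleneck noise (default `TRUE`).
#' @return data.frame with columns `cycle` (0..cycles) and `f`.
#' @export
simulateMixtureTrajectory <- function(f0, s, regime = regimeSpec(),
                                      cycles = 20, seed = NULL,
                                      stochastic = TRUE) {
  stopifnot(f0 > 0, f0 < 1, cycles >= 1)
  g <- generationsPerCycle(regime)
  nB <- bottleneckCells(regime)
  f <- numeric(cycles + 1)
  f[1] <- f0
  withSeed(seed, {
    for (i in seq_len(cycles)) {
      fg <- growthUpdate(f[i], s, g)
      f[i + 1] <- if (stochastic) bottleneckSample(fg, nB) else fg
    }
  })
  data.frame(cycle = 0:cycles, f = f)
}

#' Fit a selection coefficient from a mixture trajectory
#'
#' Under the deterministic update, the log-odds of the mutant frequency is
#' linear in elapsed generations with slope `ln(1 + s)`. The fit is a
#' least-squares regression of `logit(f)` on `cycle * g`, back-transformed
#' to s; its standard error comes from the regression slope.
#'
#' @param trajectory data.frame with columns `cycle` and `f` (frequencies
#'   strictly inside (0, 1) are used; at least 2 such points required).
#' @param g generations per cycle (default `log2(100)`).
#' @return a [SelectionEstimate-class].
#' @export
fitSelectionFromMixture <- function(trajectory, g = log2(100)) {
  stopifnot(all(c("cycle", "f") %in% names(trajectory)))
  keep <- trajectory$f > 0 & trajectory$f < 1
  if (sum(keep) < 2L)
    stop("need at least 2 trajectory points strictly inside (0, 1)")
  tr <- trajectory[keep, ]
  if (is.unsorted(tr$cycle, strictly = TRUE))
    stop("cycle indices must be strictly increasing")
  fit <- lm(qlogis(f) ~ I(cycle * g), data = tr)
  slope <- coef(fit)[[2L]]
  seSlope <- suppressWarnings(summary(fit)$coefficients[2L, 2L])
  new("SelectionEstimate", sHat = exp(slope) - 1,
      se = exp(slope) * seSlope, replicates = NA_real_, seed = NA_real_)
}

#' SelectionEstimate accessors
#'
#' @param x a [SelectionEstimate-class].
#' @return numeric(1).
#' @export
sHat <- function(x) { stopifnot(is(x, "SelectionEstimate")); x@sHat }

#' @rdname sHat
#' @export
sHatSE <- function(x) { stopifnot(is(x, "SelectionEstimate")); x@se }

setMethod("show", "SelectionEstimate", function(object) {
  cat(sprintf("SelectionEstimate: s = %.5g +/- %.3g%s\n",
              object@sHat, object@se,
              if (!is.na(object@replicates))
                sprintf(" (%g replicates, seed %g)",
                        object@replicates, object@seed) else ""))
})
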