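#' Two-class goodness-of-fit G statistic
#'
#' The likelihood-ratio statistic for an observed count O out of n against
#' a null proportion p:
#' `G = 2 * (O * ln(O / (n p)) + (n - O) * ln((n - O) / (n (1 - p))))`,
#' with the `0 * ln(0)` terms taken as 0. Asymptotically chi-square with
#' 1 df. Vectorised over `O` (and `n`, `p`).
#'
#' @param O observed count(s), `0 <= O <= n`.
#' @param n number of trials per replicate.
#' @param p null proportion, strictly inside (0, 1).
#' @return non-negative G value(s).
#' @examples
#' gGof(18, 23, 0.508)  # 7.390
#' @export
gGof <- function(O, n, p) {
  stopifnot(all(O >= 0), all(O <= n), all(p > 0), all(p < 1))
  m <- max(length(O), length(n), length(p))
  O <- rep_len(O, m); n <- rep_len(n, m); p <- rep_len(p, m)
  2 * (xlogxe(O, n * p) + xlogxe(n - O, n * (1 - p)))
}

#' Chi-square upper-tail probability
#'
#' Survival function of the chi-square distribution (the regularized upper
#' incomplete gamma function), as attached to G statistics.
#'
#' @param x statistic value(s), >= 0.
#' @param df degrees of freedom.
#' @return upper-tail probability.
#' @examples
#' chiSqTail(14.7, 9)  # 0.0995
#' @export
chiSqTail <- function(x, df) {
  stopifnot(all(x >= 0), all(df > 0))
  pchisq(x, df, lower.tail = FALSE)
}

#' Williams small-sample correction for G
#'
#' Divides G by `q = 1 + (a^2 - 1) / (6 n nu)` where `a` is the number of
#' classes (2 for the G/C vs A/T dichotomy), `n` the total observations and
#' `nu` the degrees of freedom. Opt-in: the replicated decomposition is
#' reported uncorrected by default.
#'
#' @param G uncorrected statistic(s).
#' @param n total observations behind the statistic.
#' @param a number of classes (default 2).
#' @param nu degrees of freedom of the statistic (default 1).
#' @return corrected G.
#' @export
williamsCorrect <- function(G, n, a = 2, nu = 1) {
  stopifnot(n > 0, a >= 2, nu >= 1)
  G / (1 + (a^2 - 1) / (6 * n * nu))
}

#' Replicated goodness-of-fit G decomposition
#'
#' Partitions the deviation of k replicate two-class counts (each O out of
#' n, against the same null proportion p) into a pooled component
#' `G_P = G(sum O, k n, p)` with 1 df, measuring overall departure from p,
#' and a heterogeneity component `G_H = G_T - G_P` with k-1 df, measuring
#' disagreement among replicates, where `G_T = sum of per-replicate G`
#' with k df. The identity `G_T = G_P + G_H` holds exactly by
#' construction. Chi-square upper tails are attached to every statistic.
#'
#' @param counts numeric(k >= 2) of per-replicate observed counts, named
#'   (e.g. by flanking offset) or not.
#' @param n trials per replicate (constant across replicates).
#' @param p null proportion.
#' @param williams apply the Williams correction to each statistic
#'   (per-position and pooled G divided by their respective q; the total
#'   re-summed so the additive identity is preserved).
#' @return a [GofDecomposition-class].
#' @examples
#' replicatedGof(c(16, 10, 16, 18, 15, 15, 10, 13, 10, 11), 23, 0.508)
#' @export
replicatedGof <- function(counts, n, p, williams = FALSE) {
  k <- length(counts)
  if (k < 2L) stop("need at least 2 replicate counts")
  stopifnot(length(n) == 1L, n > 0)
  perG <- gGof(counts, n, p)
  GP <- gGof(sum(counts), k * n, p)
  if (williams) {
    perG <- williamsCorrect(perG, n = n, nu = 1)
    GP <- williamsCorrect(GP, n = k * n, nu = 1)
  }
  GT <- sum(perG)
  GH <- GT - GP
  if (is.null(names(counts))) names(perG) <- as.character(seq_len(k))
  else names(perG) <- names(counts)
  df <- c(GP = 1, GH = k - 1, GT = k)
  pv <- list(perPosition = chiSqTail(perG, 1),
             GP = chiSqTail(GP, 1),
             GH = chiSqTail(max(GH, 0), k - 1),
             GT = chiSqTail(GT, k))
  new("GofDecomposition", perPositionG = perG, GP = GP, GH = GH, GT = GT,
      df = df, pValues = pv, williamsApplied = williams)
}

#' Context goodness-of-fit analysis
#'
#' Runs the replicated G decomposition on a flanking-base
#' [ContextProfile-class]. By default the mutated site itself (offset 0)
#' is excluded, so a `-flank..+flank` profile contributes `2 * flank`
#' replicate positions (10 for the standard flank of 5, giving 9
#' heterogeneity df); `includeCenter = TRUE` keeps it. Per-position P
#' values come from the chi-square tail of each position's G by default,
#' or from the exact two-tailed binomial test.
#'
#' @param profile a [ContextProfile-class].
#' @param includeCenter include offset 0 in the decomposition.
#' @param williams apply the Williams correction (see [williamsCorrect()]).
#' @param perPositionTest `"g"` (chi-square tail of per-position G) or
#'   `"binomial"` (exact two-tailed, doubling convention).
#' @return a [GofDecomposition-class].
#' @export
contextGof <- function(profile, includeCenter = FALSE, williams = FALSE,
                       perPositionTest = c("g", "binomial")) {
  stopifnot(is(profile, "ContextProfile"))
  perPositionTest <- match.arg(perPositionTest)
  keep <- if (includeCenter) rep(TRUE, length(profile@offsets))
          else profile@offsets != 0L
  counts <- setNames(profile@counts[keep],
                     as.character(profile@offsets[keep]))
  dec <- replicatedGof(counts, profile@n, profile@p, williams = williams)
  if (perPositionTest == "binomial")
    dec@pValues$perPosition <- setNames(
      vapply(counts, gcCompositionTest, numeric(1),
             n = profile@n, p = profile@p),
      names(counts))
  dec
}

#' GofDecomposition accessors
#'
#' @param x a [GofDecomposition-class].
#' @return `pooledG`, `heterogeneityG`, `totalG`: the named statistic;
#'   `perPositionG`: named numeric(k); `gofDf`: named df vector;
#'   `gofPValues`: list of tail probabilities.
#' @export
pooledG <- function(x) { stopifnot(is(x, "GofDecomposition")); x@GP }

#' @rdname pooledG
#' @export
heterogeneityG <- function(x) { stopifnot(is(x, "GofDecomposition")); x@GH }

#' @rdname pooledG
#' @export
totalG <- function(x) { stopifnot(is(x, "GofDecomposition")); x@GT }

#' @rdname pooledG
#' @export
perPositionG <- function(x) { stopifnot(is(x, "GofDecomposition")); x@perPositionG }

#' @rdname pooledG
#' @export
gofDf <- function(x) { stopifnot(is(x, "GofDecomposition")); x@df }

#' @rdname pooledG
#' @export
gofPValues <- function(x) { stopifnot(is(x, "GofDecomposition")); x@pValues }

setMethod("show", "GofDecomposition", function(object) {
  fmt <- function(g, df, p)
    sprintf("%.3g (%d df, P = %.4f)", g, df, p)
  cat("Replicated goodness-of-fit G decomposition",
      if (object@williamsApplied) "(Williams-corrected)" else "", "\n")
  cat("  G_P =", fmt(object@GP, object@df["GP"], object@pValues$GP), "\n")
  cat("  G_H =", fmt(object@GH, object@df["GH"], object@pValues$GH), "\n")
  cat("  G_T =", fmt(object@GT, object@df["GT"], object@pValues$GT), "\n")
})
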