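#' The six strand-collapsed substitution classes
#'
#' Base-pair-level mutation categories that merge complementary strand
#' descriptions (G>A on either strand is the pair change `GC>AT`, and so
#' on). `GC>AT` and `AT>GC` are the two transitions; the rest are
#' transversions.
#'
#' @format character(6).
#' @export
SUBSTITUTION_CLASSES <- c("GC>AT", "GC>TA", "GC>CG", "AT>GC", "AT>CG", "AT>TA")

## forward-strand single-base change -> pair class
.CLASS_OF <- c(
  "G>A" = "GC>AT", "C>T" = "GC>AT",
  "G>T" = "GC>TA", "C>A" = "GC>TA",
  "G>C" = "GC>CG", "C>G" = "GC>CG",
  "A>G" = "AT>GC", "T>C" = "AT>GC",
  "A>C" = "AT>CG", "T>G" = "AT>CG",
  "A>T" = "AT>TA", "T>A" = "AT>TA")

#' Collapse a base substitution to its strand-symmetric pair class
#'
#' @param ref,alt single bases (vectorised); `ref != alt` elementwise.
#' @return character vector of classes from [SUBSTITUTION_CLASSES].
#' @examples
#' collapseSubstitution("G", "A")  # "GC>AT"
#' collapseSubstitution("C", "T")  # "GC>AT" (same pair change)
#' @export
collapseSubstitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop("ref and alt must be single A/C/G/T bases")
  if (any(ref == alt)) stop("ref and alt must differ")
  unname(.CLASS_OF[paste0(ref, ">", alt)])
}

#' Is a substitution class a transition?
#'
#' @param class character vector of classes from [SUBSTITUTION_CLASSES].
#' @return logical vector; `TRUE` only for `GC>AT` and `AT>GC`.
#' @export
isTransition <- function(class) {
  if (any(!class %in% SUBSTITUTION_CLASSES))
    stop("unknown substitution class")
  class %in% c("GC>AT", "AT>GC")
}

#' Summarise a mutation set into a strand-collapsed spectrum
#'
#' @param records mutation table (data.frame with `ref`, `alt`), or a
#'   zero-row table for the empty spectrum.
#' @return a [SpectrumSummary-class].
#' @export
summarizeSpectrum <- function(records) {
  counts <- setNames(integer(length(SUBSTITUTION_CLASSES)),
                     SUBSTITUTION_CLASSES)
  if (nrow(records) > 0L) {
    cls <- collapseSubstitution(records$ref, records$alt)
    tab <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
    counts[] <- as.integer(tab)
  }
  new("SpectrumSummary", counts = counts)
}

#' Spectrum accessors
#'
#' `spectrumCounts` returns the six per-class counts; `nTotal` their sum;
#' `transitionCount` the number of transitions (GC>AT + AT>GC);
#' `gcToWeakCount` the grouped G/C -> A/T-or-T/A count (GC>AT + GC>TA),
#' the class grouping conventionally reported for the GC->weak bias.
#'
#' @param x a [SpectrumSummary-class].
#' @return integer.
#' @export
spectrumCounts <- function(x) { stopifnot(is(x, "SpectrumSummary")); x@counts }

#' @rdname spectrumCounts
#' @export
nTotal <- function(x) { stopifnot(is(x, "SpectrumSummary")); sum(x@counts) }

#' @rdname spectrumCounts
#' @export
transitionCount <- function(x) {
  stopifnot(is(x, "SpectrumSummary"))
  sum(x@counts[c("GC>AT", "AT>GC")])
}

#' @rdname spectrumCounts
#' @export
gcToWeakCount <- function(x) {
  stopifnot(is(x, "SpectrumSummary"))
  sum(x@counts[c("GC>AT", "GC>TA")])
}

setMethod("show", "SpectrumSummary", function(object) {
  cat("SpectrumSummary (", nTotal(object), " mutations)\n", sep = "")
  print(object@counts)
  cat(sprintf("transitions: %d; GC->AT/TA grouped: %d\n",
              transitionCount(object), gcToWeakCount(object)))
})
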