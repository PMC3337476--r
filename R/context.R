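#' Flanking-base G/C context profile around mutated sites
#'
#' For every validated mutation, examines the window from `-flank` through
#' the mutated site to `+flank` and counts, at each offset, how many
#' mutations carry a G or C there. Offset 0 uses the pre-mutation
#' (reference) base. On a linear genome a record whose window would cross
#' either end is skipped entirely (recorded in the profile) so each offset
#' rests on the same n; on a circular genome the window wraps. Windows
#' containing masked (`N`) bases are likewise skipped.
#'
#' @param genome a [Genome-class].
#' @param records mutation table validated with [validateAgainstGenome()].
#' @param flank window half-width in bp (>= 1, default 5).
#' @param p expected G/C proportion for the surveyed region; defaults to
#'   the genome-wide [gcFraction()], but should be the regional value when
#'   the mutations come from a compositionally distinct locus.
#' @return a [ContextProfile-class].
#' @export
extractContext <- function(genome, records, flank = 5L, p = gcFraction(genome)) {
  stopifnot(is(genome, "Genome"))
  flank <- as.integer(flank)
  if (flank < 1L) stop("flank must be >= 1")
  records <- validateAgainstGenome(records, genome)
  L <- length(genome)
  s <- as.character(genomeSeq(genome))
  offsets <- seq.int(-flank, flank)
  counts <- setNames(numeric(length(offsets)), as.character(offsets))
  skipped <- character()
  n <- 0L
  circular <- genomeTopology(genome) == "circular"
  for (i in seq_len(nrow(records))) {
    pos <- records$position[i]
    idx <- pos + offsets
    if (circular) {
      idx <- ((idx - 1L) %% L) + 1L
    } else if (any(idx < 1L) || any(idx > L)) {
      skipped <- c(skipped, records$id[i])
      next
    }
    win <- substring(s, idx, idx)
    win[offsets == 0L] <- records$ref[i]
    if (any(win == "N")) {
      skipped <- c(skipped, records$id[i])
      next
    }
    counts <- counts + (win %in% c("G", "C"))
    n <- n + 1L
  }
  if (n == 0L) stop("all records skipped; no usable context windows")
  new("ContextProfile", offsets = offsets, counts = counts, n = n,
      p = p, flank = flank, skipped = skipped)
}

#' ContextProfile accessors
#'
#' @param x a [ContextProfile-class].
#' @return `contextCounts`: named numeric of per-offset G/C counts;
#'   `contextN`: contributing mutations; `expectedGC`: `n * p`, the
#'   expected G/C count per offset; `skippedRecords`: ids excluded.
#' @export
contextCounts <- function(x) { stopifnot(is(x, "ContextProfile")); x@counts }

#' @rdname contextCounts
#' @export
contextN <- function(x) { stopifnot(is(x, "ContextProfile")); x@n }

#' @rdname contextCounts
#' @export
expectedGC <- function(x) { stopifnot(is(x, "ContextProfile")); x@n * x@p }

#' @rdname contextCounts
#' @export
skippedRecords <- function(x) { stopifnot(is(x, "ContextProfile")); x@skipped }

setMethod("show", "ContextProfile", function(object) {
  cat(sprintf("ContextProfile: n = %d mutations, flank = %d, p = %.3f (expected %.1f per offset)\n",
              object@n, object@flank, object@p, expectedGC(object)))
  print(object@counts)
  if (length(object@skipped))
    cat("skipped:", paste(object@skipped, collapse = ", "), "\n")
})
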