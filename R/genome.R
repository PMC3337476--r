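#' @importClassesFrom Biostrings DNAString
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet alphabetFrequency GENETIC_CODE reverseComplement
NULL

#' Construct a Genome from a sequence
#'
#' @param sequence character(1) or `DNAString`. Upper-cased on input.
#' @param id sequence label.
#' @param topology `"linear"` (default) or `"circular"`.
#' @param mask if `TRUE`, letters outside A/C/G/T are masked to `N`
#'   (and later excluded from context windows); if `FALSE` (default) any
#'   such letter is an error, reported with its position.
#' @return a [Genome-class] object.
#' @examples
#' g <- genome("ACGT")
#' gcFraction(g)  # 0.5
#' @export
genome <- function(sequence, id = "genome", topology = c("linear", "circular"),
                   mask = FALSE) {
  topology <- match.arg(topology)
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% BASES)
  if (length(bad)) {
    if (mask) {
      chars[bad] <- "N"
      sequence <- paste(chars, collapse = "")
    } else {
      stop("non-ACGT character(s) '",
           paste(unique(chars[bad]), collapse = "','"),
           "' at position(s) ",
           paste(utils::head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) ", ..." else "")
    }
  }
  new("Genome", id = id, sequence = DNAString(sequence), topology = topology)
}

#' Read a genome from a FASTA file
#'
#' Reads the first (or a named) record of a FASTA file and validates it.
#'
#' @param path FASTA file.
#' @param record `NULL` for the first record, or the name of the record to
#'   take.
#' @inheritParams genome
#' @return a [Genome-class].
#' @export
readGenome <- function(path, record = NULL, topology = c("linear", "circular"),
                       mask = FALSE) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  if (is.null(record)) {
    i <- 1L
  } else {
    i <- match(record, sub("\\s.*$", "", names(set)))
    if (is.na(i)) stop("record '", record, "' not found in ", path)
  }
  if (length(set[[i]]) == 0L) stop("empty FASTA record in ", path)
  genome(as.character(set[[i]]), id = sub("\\s.*$", "", names(set)[i]),
         topology = topology, mask = mask)
}

#' Write a genome to FASTA
#'
#' @param x a [Genome-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(x, path) {
  stopifnot(is(x, "Genome"))
  set <- DNAStringSet(x@sequence)
  names(set) <- x@id
  writeXStringSet(set, path)
  invisible(path)
}

#' @describeIn genome genome length in bp.
#' @export
setMethod("length", "Genome", function(x) length(x@sequence))

#' Genome accessors
#'
#' `gcFraction` returns (G + C) / (A + C + G + T); with no masked bases this
#' is exactly (G + C) / length. `genomeSeq` returns the `DNAString`,
#' `genomeId` the label and `genomeTopology` the topology.
#'
#' @param x a [Genome-class].
#' @return `gcFraction`: numeric in \[0, 1\].
#' @export
gcFraction <- function(x) {
  stopifnot(is(x, "Genome"))
  freq <- alphabetFrequency(x@sequence)
  sum(freq[c("G", "C")]) / sum(freq[BASES])
}

#' @rdname gcFraction
#' @export
genomeSeq <- function(x) {
  stopifnot(is(x, "Genome"))
  x@sequence
}

#' @rdname gcFraction
#' @export
genomeId <- function(x) {
  stopifnot(is(x, "Genome"))
  x@id
}

#' @rdname gcFraction
#' @export
genomeTopology <- function(x) {
  stopifnot(is(x, "Genome"))
  x@topology
}

#' Bases at 1-based positions
#'
#' Vectorised lookup of genome bases; positions must lie in
#' `[1, length(x)]` (no wrapping).
#'
#' @param x a [Genome-class].
#' @param positions integer vector of 1-based coordinates.
#' @return character vector of single bases.
#' @export
baseAt <- function(x, positions) {
  stopifnot(is(x, "Genome"), all(positions >= 1), all(positions <= length(x)))
  s <- as.character(x@sequence)
  substring(s, positions, positions)
}

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome '%s': %d bp, %s, G+C = %.1f%%\n",
              object@id, length(object), object@topology,
              100 * gcFraction(object)))
})
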