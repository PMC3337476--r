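#' Read a mutation table
#'
#' Mutation tables are tab-separated with a header line and required columns
#' `id`, `position`, `ref`, `alt`; any further columns (`gene`,
#' `codon_before`, `codon_after`, `strand`, ...) are preserved as given.
#' Coordinates are 1-based, inclusive, on the forward strand.
#'
#' @param path TSV file.
#' @return data.frame of mutation records, in file order.
#' @export
readMutationTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  validateMutationTable(tab)
}

#' Validate an in-memory mutation table
#'
#' Checks the schema invariants (required columns, integer positions,
#' unique ids, `ref != alt`, single ACGT bases). Offending rows are
#' reported by row number; parsing never silently drops rows.
#'
#' @param tab data.frame with at least `id`, `position`, `ref`, `alt`.
#' @return the table with `position` as integer and bases upper-cased.
#' @export
validateMutationTable <- function(tab) {
  required <- c("id", "position", "ref", "alt")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  pos <- suppressWarnings(as.numeric(tab$position))
  bad <- which(is.na(pos) | pos < 1 | pos != floor(pos))
  if (length(bad))
    stop("unparsable or non-positive position at row(s): ",
         paste(bad, collapse = ", "))
  tab$position <- as.integer(pos)
  dup <- which(duplicated(tab$id))
  if (length(dup))
    stop("duplicate id(s): ", paste(unique(tab$id[dup]), collapse = ", "))
  tab$ref <- toupper(tab$ref)
  tab$alt <- toupper(tab$alt)
  badbase <- which(!(tab$ref %in% BASES) | !(tab$alt %in% BASES))
  if (length(badbase))
    stop("ref/alt not a single A/C/G/T base at row(s): ",
         paste(badbase, collapse = ", "))
  same <- which(tab$ref == tab$alt)
  if (length(same))
    stop("ref == alt at row(s): ", paste(same, collapse = ", "))
  tab
}

#' Write a mutation table
#'
#' @param tab data.frame of mutation records.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
writeMutationTable <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate mutation records against a genome
#'
#' Every record must satisfy `genome[position] == ref`; positions must lie
#' within the genome. Any mismatch is an error listing the offending ids.
#' The check is idempotent: validated records validate again unchanged.
#'
#' @param records data.frame from [readMutationTable()].
#' @param genome a [Genome-class].
#' @return the records, unchanged, for piping.
#' @export
validateAgainstGenome <- function(records, genome) {
  stopifnot(is(genome, "Genome"))
  records <- validateMutationTable(records)
  out <- which(records$position > length(genome))
  if (length(out))
    stop("position beyond genome end for id(s): ",
         paste(records$id[out], collapse = ", "))
  ref <- baseAt(genome, records$position)
  bad <- which(ref != records$ref)
  if (length(bad))
    stop("reference-base mismatch for id(s): ",
         paste(records$id[bad], collapse = ", "),
         " (genome has ", paste(ref[bad], collapse = ","), ")")
  records
}
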