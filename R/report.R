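#' Flatten a result object to a report list
#'
#' Internal generic behind [writeReport()]: converts a result object into
#' a named list of plain vectors with a stable field order.
#'
#' @param x a result object.
#' @return named list.
#' @keywords internal
setGeneric("reportFields", function(x) standardGeneric("reportFields"))

setMethod("reportFields", "GofDecomposition", function(x) {
  list(per_position_G = as.list(x@perPositionG),
       G_P = x@GP, G_H = x@GH, G_T = x@GT,
       dfs = as.list(x@df),
       p_values = list(per_position = as.list(x@pValues$perPosition),
                       G_P = x@pValues$GP, G_H = x@pValues$GH,
                       G_T = x@pValues$GT),
       williams_applied = x@williamsApplied)
})

setMethod("reportFields", "RateEstimate", function(x) {
  list(num_mutations = x@numMutations, generations = x@generations,
       target_sites = x@sites, rate_per_bp_per_gen = x@rate)
})

setMethod("reportFields", "GenomeRate", function(x) {
  list(rate_per_bp_per_gen = x@ratePerBp, genome_size = x@genomeSize,
       rate_per_genome_per_gen = x@ratePerGenome)
})

setMethod("reportFields", "ExpectedCounts", function(x) {
  list(generations = x@generations, genome_rate = x@genomeRate,
       coding_fraction = x@codingFraction,
       synonymous_fraction = x@synonymousFraction,
       total = x@total, coding = x@coding, synonymous = x@synonymous)
})

setMethod("reportFields", "SpectrumSummary", function(x) {
  list(counts = as.list(x@counts), n_total = nTotal(x),
       transitions = transitionCount(x), gc_to_at_or_ta = gcToWeakCount(x))
})

setMethod("reportFields", "ContextProfile", function(x) {
  list(offsets = x@offsets, counts = as.list(x@counts), n = x@n, p = x@p,
       expected_per_offset = expectedGC(x), flank = x@flank,
       skipped = x@skipped)
})

setMethod("reportFields", "SelectionEstimate", function(x) {
  list(s_hat = x@sHat, monte_carlo_se = x@se, replicates = x@replicates,
       seed = x@seed)
})

setMethod("reportFields", "list", function(x) x)

signifDeep <- function(x, digits) {
  if (is.list(x)) lapply(x, signifDeep, digits = digits)
  else if (is.double(x)) signif(x, digits)
  else x
}

#' Write a machine-readable report
#'
#' Serialises a stage result (rate estimate, spectrum summary, context
#' profile, G decomposition, selection estimate, or a plain named list)
#' with deterministic field order. JSON writes the nested structure
#' directly; TSV flattens it to `field <TAB> value` rows. Floats are
#' written at 6 significant digits by default.
#'
#' @param x the result object.
#' @param path output file.
#' @param format `"json"` (default) or `"tsv"`.
#' @param digits significant digits for floats.
#' @return `path`, invisibly.
#' @export
writeReport <- function(x, path, format = c("json", "tsv"), digits = 6) {
  format <- match.arg(format)
  fields <- signifDeep(reportFields(x), digits)
  if (format == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                         null = "list")
  } else {
    flat <- unlist(fields)
    df <- data.frame(field = names(flat), value = as.character(flat))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path file written by [writeReport()] with `format = "json"`.
#' @return nested named list.
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
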