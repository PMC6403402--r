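#' Round half away from zero
#'
#' Integer percentages in the classification summaries are rounded to the
#' nearest integer with ties going away from zero (so 14.5 -> 15), matching
#' how the published summary tables round. Base `round()` rounds half to
#' even and would give different printed percentages.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @keywords internal
#' @noRd
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

BASES <- c("A", "C", "G", "T")
COUNT_COLS <- paste0("count_", BASES)
GENOMOTYPES <- c("PP", "AA", "PA", "PAA")
HYBRID_GENOMOTYPES <- c("PA", "PAA")

#' Validate a library metadata table
#'
#' Checks the invariants of the library sheet: known genomotypes, ploidy
#' consistent with the genomotype (PP/AA/PA are diploid, PAA triploid), and
#' that only parental (PP or AA) libraries can be flagged for bias
#' estimation.
#'
#' @param meta A data frame with columns `library_id`, `genomotype`,
#'   `tissue`, `ploidy`, `use_for_bias`.
#' @return The validated metadata as a tibble (invisibly usable in pipes).
#' @export
validate_library_meta <- function(meta) {
  meta <- as_tibble(meta)
  required <- c("library_id", "genomotype", "tissue", "ploidy", "use_for_bias")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0("library metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$library_id)) {
    abort("duplicate library_id in library metadata")
  }
  bad_geno <- setdiff(unique(meta$genomotype), GENOMOTYPES)
  if (length(bad_geno) > 0) {
    abort(paste0("unknown genomotype(s): ", paste(bad_geno, collapse = ", ")))
  }
  expected_ploidy <- ifelse(meta$genomotype == "PAA", 3L, 2L)
  if (any(meta$ploidy != expected_ploidy)) {
    off <- meta$library_id[meta$ploidy != expected_ploidy]
    abort(paste0("ploidy inconsistent with genomotype for: ",
                 paste(off, collapse = ", ")))
  }
  meta$use_for_bias <- as.logical(meta$use_for_bias)
  bad_bias <- meta$use_for_bias & !(meta$genomotype %in% c("PP", "AA"))
  if (any(bad_bias)) {
    abort(paste0("use_for_bias may only be TRUE for parental (PP/AA) libraries: ",
                 paste(meta$library_id[bad_bias], collapse = ", ")))
  }
  meta
}

#' Validate a long-format allele count table
#'
#' @param counts A data frame with one row per (transcript, position,
#'   library) holding the four base counts; see [read_count_table()] for the
#'   column contract.
#' @return The validated counts as a tibble.
#' @export
validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  required <- c("transcript_id", "pos", "transcript_length", "ref_base",
                "consensus_quality", "library_id", COUNT_COLS)
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    abort(paste0("count table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  cts <- as.matrix(counts[COUNT_COLS])
  if (any(is.na(cts)) || any(cts < 0)) {
    bad <- which(rowSums(is.na(cts) | cts < 0) > 0)[1]
    abort(paste0("negative or missing base count at row ", bad, " (",
                 counts$transcript_id[bad], ":", counts$pos[bad], ")"))
  }
  if (any(!counts$ref_base %in% BASES)) {
    bad <- which(!counts$ref_base %in% BASES)[1]
    abort(paste0("malformed ref_base at row ", bad, ": '",
                 counts$ref_base[bad], "'"))
  }
  if (any(counts$pos < 1 | counts$pos > counts$transcript_length)) {
    bad <- which(counts$pos < 1 | counts$pos > counts$transcript_length)[1]
    abort(paste0("position outside transcript at row ", bad, " (",
                 counts$transcript_id[bad], ":", counts$pos[bad], ")"))
  }
  dup <- duplicated(counts[c("transcript_id", "pos", "library_id")])
  if (any(dup)) {
    bad <- which(dup)[1]
    abort(paste0("duplicate (transcript, position, library) record: ",
                 counts$transcript_id[bad], ":", counts$pos[bad], " in ",
                 counts$library_id[bad]))
  }
  counts
}

# per-row total read depth of a count table chunk
site_depth <- function(counts) {
  rowSums(as.matrix(counts[COUNT_COLS]))
}
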