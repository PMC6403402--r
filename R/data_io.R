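#' Read a library metadata sheet
#'
#' The metadata sheet is a tab-separated file with one row per RNA-seq
#' library and columns `library_id`, `genomotype` (one of PP, AA, PA, PAA),
#' `tissue` (free label such as "liver" or "juvenile"), `ploidy` (2 or 3)
#' and `use_for_bias` (logical; whether a parental library contributes to
#' reference-bias estimation). Parental libraries contaminated by other
#' ploidies can be excluded from bias estimation by setting `use_for_bias`
#' to FALSE while still contributing to diagnostic SNP identification.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the validated metadata.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("library_id\tgenomotype\ttissue\tploidy\tuse_for_bias",
#'              "liv-PA\tPA\tliver\t2\tFALSE"), tf)
#' read_library_meta(tf)
read_library_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            library_id = readr::col_character(),
                            genomotype = readr::col_character(),
                            tissue = readr::col_character(),
                            ploidy = readr::col_integer(),
                            use_for_bias = readr::col_logical()
                          ))
  validate_library_meta(meta)
}

#' Write a library metadata sheet
#'
#' @param meta A validated metadata tibble (see [read_library_meta()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_meta <- function(meta, path) {
  meta <- validate_library_meta(meta)
  readr::write_tsv(meta, path)
  invisible(path)
}

#' Read a per-site allele count table
#'
#' Reads the project's tab-separated count dialect. The file has one row per
#' transcript position with columns `transcript_id`, `pos` (1-based on the
#' transcript), `length` (transcript length, bp), `ref` (assembly reference
#' base at the position), `qual` (phred-like consensus quality), followed by
#' four columns `<library_id>:A`, `<library_id>:C`, `<library_id>:G`,
#' `<library_id>:T` per library. Every library declared in `meta` must have
#' its four columns present; libraries in the header that are absent from
#' `meta` are an error, as are duplicate (transcript, position) rows and
#' negative counts.
#'
#' @param path Path to the TSV file.
#' @param meta Library metadata tibble (see [read_library_meta()]).
#' @return A long-format tibble with one row per (transcript, position,
#'   library): columns `transcript_id`, `pos`, `transcript_length`,
#'   `ref_base`, `consensus_quality`, `library_id`, `count_A`, `count_C`,
#'   `count_G`, `count_T`, ordered by (transcript_id, pos, library_id).
#' @export
read_count_table <- function(path, meta) {
  meta <- validate_library_meta(meta)
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  fixed_cols <- c("transcript_id", "pos", "length", "ref", "qual")
  missing_fixed <- setdiff(fixed_cols, names(wide))
  if (length(missing_fixed) > 0) {
    abort(paste0("count table is missing column(s): ",
                 paste(missing_fixed, collapse = ", ")))
  }
  lib_cols <- setdiff(names(wide), fixed_cols)
  header_libs <- unique(sub(":[ACGT]$", "", lib_cols))
  unknown <- setdiff(header_libs, meta$library_id)
  if (length(unknown) > 0) {
    abort(paste0("count table declares libraries absent from metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  for (lib in meta$library_id) {
    want <- paste0(lib, ":", BASES)
    if (!all(want %in% lib_cols)) {
      abort(paste0("count table is missing columns for library '", lib, "'"))
    }
  }
  if (anyDuplicated(wide[c("transcript_id", "pos")])) {
    i <- which(duplicated(wide[c("transcript_id", "pos")]))[1]
    abort(paste0("duplicate (transcript, position) row: ",
                 wide$transcript_id[i], ":", wide$pos[i]))
  }
  long <- tidyr::pivot_longer(
    wide,
    cols = dplyr::all_of(paste0(rep(meta$library_id, each = 4), ":", BASES)),
    names_to = c("library_id", "base"),
    names_sep = ":",
    values_to = "count"
  )
  long <- tidyr::pivot_wider(long, names_from = "base",
                             values_from = "count", names_prefix = "count_")
  long <- dplyr::rename(long,
                        transcript_length = "length",
                        ref_base = "ref",
                        consensus_quality = "qual")
  long <- dplyr::arrange(long, .data$transcript_id, .data$pos,
                         .data$library_id)
  long <- dplyr::relocate(long, "transcript_id", "pos", "transcript_length",
                          "ref_base", "consensus_quality", "library_id")
  validate_counts(long)
}

#' Write a per-site allele count table
#'
#' Writes the long-format count tibble back to the wide TSV dialect read by
#' [read_count_table()]. Column order is deterministic: the five site
#' columns, then four count columns per library with libraries in
#' lexicographic order; rows are ordered by (transcript_id, pos). Writing the
#' same data twice produces byte-identical files.
#'
#' @param counts Long-format count tibble (see [read_count_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_counts(counts)
  if (nrow(counts) == 0) {
    writeLines("transcript_id\tpos\tlength\tref\tqual", path)
    return(invisible(path))
  }
  libs <- sort(unique(counts$library_id))
  long <- tidyr::pivot_longer(counts, cols = dplyr::all_of(COUNT_COLS),
                              names_to = "base", names_prefix = "count_",
                              values_to = "count")
  long$column <- paste0(long$library_id, ":", long$base)
  wide <- tidyr::pivot_wider(
    dplyr::select(long, "transcript_id", "pos", "transcript_length",
                  "ref_base", "consensus_quality", "column", "count"),
    names_from = "column", values_from = "count"
  )
  wide <- dplyr::rename(wide, length = "transcript_length",
                        ref = "ref_base", qual = "consensus_quality")
  col_order <- c("transcript_id", "pos", "length", "ref", "qual",
                 paste0(rep(libs, each = 4), ":", BASES))
  wide <- dplyr::arrange(wide[col_order], .data$transcript_id, .data$pos)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Import per-sample allele depths from a VCF
#'
#' Imports biallelic SNVs with per-sample allele depth (`AD`) annotation
#' into the same long count-table layout produced by [read_count_table()].
#' The reference depth is assigned to the REF base and the alternate depth
#' to the ALT base; the other two base counts are zero. Indels and
#' multiallelic records are skipped (the pipeline considers single-variant
#' sites only) and the number skipped is attached as attribute `n_skipped`
#' and reported as a message. Positions stay 1-based as in the VCF; the
#' record QUAL field is used as the consensus quality. Transcript lengths
#' are taken from the `##contig` header lines unless supplied explicitly.
#'
#' @param path Path to a VCF 4.x file (uncompressed or bgzipped).
#' @param sample_map Named character vector mapping `library_id` to the VCF
#'   sample name, e.g. `c("liv-PA" = "sample1")`. Every mapped sample must
#'   exist in the VCF header.
#' @param transcript_lengths Optional named integer vector of transcript
#'   lengths, overriding the VCF contig headers.
#' @return A long-format count tibble (see [read_count_table()]), with
#'   attribute `n_skipped` counting rejected indel/multiallelic records.
#' @export
read_vcf_allele_depths <- function(path, sample_map,
                                   transcript_lengths = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("VCF import requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  vcf_samples <- colnames(vcf)
  missing <- setdiff(unname(sample_map), vcf_samples)
  if (length(missing) > 0) {
    abort(paste0("sample(s) absent from VCF header: ",
                 paste(missing, collapse = ", ")))
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt1 <- rep(NA_character_, length(vcf))
  alt1[n_alt == 1] <- as.character(unlist(alt_list[n_alt == 1]))
  keep <- n_alt == 1 & ref %in% BASES & alt1 %in% BASES
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(paste0("skipped ", n_skipped,
                  " indel/multiallelic/non-SNV record(s)"))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  ad <- VariantAnnotation::geno(vcf)$AD[keep, , drop = FALSE]
  if (is.null(ad)) abort("VCF has no AD (allele depth) FORMAT field")
  tx <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  qual <- rr$QUAL
  qual[is.na(qual)] <- 0
  if (is.null(transcript_lengths)) {
    transcript_lengths <- GenomeInfoDb::seqlengths(rr)
  }
  if (any(is.na(transcript_lengths[tx]))) {
    abort(paste0("transcript length unavailable for: ",
                 paste(unique(tx[is.na(transcript_lengths[tx])]),
                       collapse = ", "),
                 "; supply transcript_lengths or add ##contig headers"))
  }
  ref_k <- ref[keep]
  alt_k <- alt1[keep]
  rows <- purrr::map(names(sample_map), function(lib) {
    sample <- sample_map[[lib]]
    depths <- ad[, sample]
    mat <- matrix(0, nrow = length(ref_k), ncol = 4,
                  dimnames = list(NULL, BASES))
    for (i in seq_along(ref_k)) {
      d <- depths[[i]]
      mat[i, ref_k[i]] <- d[1]
      mat[i, alt_k[i]] <- d[2]
    }
    tibble(
      transcript_id = tx, pos = as.integer(pos),
      transcript_length = as.integer(transcript_lengths[tx]),
      ref_base = ref_k,
      consensus_quality = as.numeric(qual),
      library_id = lib,
      count_A = unname(mat[, "A"]), count_C = unname(mat[, "C"]),
      count_G = unname(mat[, "G"]), count_T = unname(mat[, "T"])
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$transcript_id,
                        .data$pos, .data$library_id)
  out <- validate_counts(out)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a functional annotation table
#'
#' Reads a transcript-to-term mapping (TSV with columns `transcript_id`,
#' `term_id` and optionally `namespace` and `description`). Namespaces
#' follow the usual ontology categories (BP, CC, MF) plus KEGG. Duplicate
#' (transcript, term) memberships are collapsed.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `transcript_id`, `term_id`, `namespace`,
#'   `description` (one row per unique membership).
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(ann) == 0) abort("annotation file is empty")
  if (!all(c("transcript_id", "term_id") %in% names(ann))) {
    abort("annotation file needs columns transcript_id and term_id")
  }
  if (!"namespace" %in% names(ann)) ann$namespace <- "BP"
  if (!"description" %in% names(ann)) ann$description <- NA_character_
  if (any(!nzchar(ann$transcript_id) | is.na(ann$transcript_id))) {
    abort("annotation contains empty transcript ids")
  }
  ann <- dplyr::distinct(ann, .data$transcript_id, .data$term_id,
                         .keep_all = TRUE)
  as_tibble(ann[c("transcript_id", "term_id", "namespace", "description")])
}
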