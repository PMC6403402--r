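#' Extract per-site P/A read counts for hybrid libraries
#'
#' For every diagnostic SNP and hybrid library, pulls the reads carrying the
#' P-genome variant and the A-genome variant out of the count table. Reads
#' of the other two bases (sequencing noise) are ignored. In triploid PAA
#' libraries the two A homoeolog copies cannot be distinguished at the read
#' level, so `reads_A` pools them.
#'
#' @param counts Long-format count tibble.
#' @param diagnostic Diagnostic SNP tibble from
#'   [identify_diagnostic_snps()].
#' @param meta Library metadata; hybrid (PA, PAA) libraries are extracted.
#' @return Tibble `library_id`, `transcript_id`, `pos`, `ref_matches`,
#'   `reads_P`, `reads_A` — one row per (hybrid library, diagnostic site)
#'   with any coverage of either variant.
#' @export
count_diagnostic_reads <- function(counts, diagnostic, meta) {
  counts <- validate_counts(counts)
  meta <- validate_library_meta(meta)
  hybrids <- meta$library_id[meta$genomotype %in% HYBRID_GENOMOTYPES]
  sub <- counts %>%
    dplyr::filter(.data$library_id %in% hybrids) %>%
    dplyr::inner_join(as_tibble(diagnostic),
                      by = c("transcript_id", "pos"))
  if (nrow(sub) == 0) {
    return(tibble(library_id = character(), transcript_id = character(),
                  pos = integer(), ref_matches = character(),
                  reads_P = numeric(), reads_A = numeric()))
  }
  cts <- as.matrix(sub[COUNT_COLS])
  idx <- seq_len(nrow(sub))
  sub$reads_P <- cts[cbind(idx, match(sub$p_base, BASES))]
  sub$reads_A <- cts[cbind(idx, match(sub$a_base, BASES))]
  sub %>%
    dplyr::filter(.data$reads_P + .data$reads_A > 0) %>%
    dplyr::select("library_id", "transcript_id", "pos", "ref_matches",
                  "reads_P", "reads_A") %>%
    dplyr::arrange(.data$library_id, .data$transcript_id, .data$pos)
}

#' Filter sites by minimum supporting reads
#'
#' Keeps sites with at least `min_reads` SNV-supporting reads (the sum of
#' reads carrying either diagnostic variant). By default the threshold is
#' applied to the raw, uncorrected counts: it is a data-quality filter on
#' sequencing evidence, and the bias correction then rescales the retained
#' counts. Set `use_corrected = TRUE` for the alternative reading in which
#' the corrected counts are thresholded.
#'
#' @param site_counts Per-site hybrid counts (see
#'   [count_diagnostic_reads()]), possibly after [apply_correction()].
#' @param min_reads Minimum supporting reads per site, default 20.
#' @param use_corrected Threshold the corrected counts instead of the raw
#'   ones (requires `corrected_P`/`corrected_A` columns).
#' @return The retained rows of `site_counts`.
#' @export
filter_min_reads <- function(site_counts, min_reads = 20,
                             use_corrected = FALSE) {
  site_counts <- as_tibble(site_counts)
  if (use_corrected) {
    if (!all(c("corrected_P", "corrected_A") %in% names(site_counts))) {
      abort("use_corrected = TRUE requires corrected_P/corrected_A columns")
    }
    keep <- site_counts$corrected_P + site_counts$corrected_A >= min_reads
  } else {
    keep <- site_counts$reads_P + site_counts$reads_A >= min_reads
  }
  site_counts[keep, ]
}

#' Aggregate per-site counts into per-transcript homoeolog fractions
#'
#' For each hybrid library and transcript, computes the arithmetic mean of
#' the (corrected, when available) P and A read counts over the transcript's
#' retained sites, and the A-genome fraction
#' `f_A = mean_reads_A / (mean_reads_A + mean_reads_P)` — the axis on which
#' transcripts are classified. `f_A` is invariant under uniform scaling of
#' the site counts and under site reordering.
#'
#' @param site_counts Retained per-site counts (see [filter_min_reads()]);
#'   corrected columns are used when present, raw counts otherwise.
#' @return Tibble `library_id`, `transcript_id`, `n_sites`, `mean_reads_P`,
#'   `mean_reads_A`, `f_A`, sorted by (library_id, transcript_id).
#' @export
transcript_fractions <- function(site_counts) {
  site_counts <- as_tibble(site_counts)
  if (nrow(site_counts) == 0) {
    return(tibble(library_id = character(), transcript_id = character(),
                  n_sites = integer(), mean_reads_P = numeric(),
                  mean_reads_A = numeric(), f_A = numeric()))
  }
  has_corr <- all(c("corrected_P", "corrected_A") %in% names(site_counts))
  p_col <- if (has_corr) "corrected_P" else "reads_P"
  a_col <- if (has_corr) "corrected_A" else "reads_A"
  out <- site_counts %>%
    dplyr::group_by(.data$library_id, .data$transcript_id) %>%
    dplyr::summarise(
      n_sites = dplyr::n(),
      mean_reads_P = mean(.data[[p_col]]),
      mean_reads_A = mean(.data[[a_col]]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(f_A = .data$mean_reads_A /
                    (.data$mean_reads_A + .data$mean_reads_P)) %>%
    dplyr::arrange(.data$library_id, .data$transcript_id)
  if (any(!is.finite(out$f_A))) {
    abort("transcript with zero total reads reached aggregation")
  }
  out
}
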