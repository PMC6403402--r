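#' SNV acceptance criteria
#'
#' The site-level quality rules applied before any variant is considered:
#' consensus quality at least `min_consensus_quality`, read depth at least
#' `min_depth` in every library with coverage at the site, distance from the
#' previously kept candidate at least `min_spacing`, and distance from both
#' transcript borders strictly greater than `min_border_distance`.
#'
#' One documented deviation from upstream variant callers: the "depth of the
#' site and the flanking sequences" rule is applied to the site depth only,
#' because per-flanking-base depth is an aligner-level quantity that a
#' per-site count table does not carry.
#'
#' @param min_consensus_quality Phred-like threshold, default 20.
#' @param min_depth Minimum reads per evaluated library, default 3.
#' @param min_spacing Minimum bp between consecutive kept candidates,
#'   default 5.
#' @param min_border_distance Minimum bp to either transcript end (strict),
#'   default 5.
#' @return An object of class `heb_snv_criteria`.
#' @export
snv_filter_criteria <- function(min_consensus_quality = 20,
                                min_depth = 3,
                                min_spacing = 5,
                                min_border_distance = 5) {
  vals <- c(min_consensus_quality, min_depth, min_spacing,
            min_border_distance)
  if (any(vals < 0)) abort("all filter thresholds must be >= 0")
  structure(
    list(min_consensus_quality = min_consensus_quality,
         min_depth = min_depth,
         min_spacing = min_spacing,
         min_border_distance = min_border_distance),
    class = "heb_snv_criteria"
  )
}

#' @export
print.heb_snv_criteria <- function(x, ...) {
  cat("SNV acceptance criteria\n")
  cat(sprintf("  consensus quality >= %g\n", x$min_consensus_quality))
  cat(sprintf("  depth per covered library >= %g\n", x$min_depth))
  cat(sprintf("  spacing to previous kept candidate >= %g bp\n",
              x$min_spacing))
  cat(sprintf("  distance to transcript borders > %g bp\n",
              x$min_border_distance))
  invisible(x)
}

#' Filter candidate SNV sites
#'
#' Applies the SNV acceptance criteria to a count table. A site survives if
#' its consensus quality meets the threshold, every library with any
#' coverage at the site has at least `min_depth` reads there, and
#' `min(pos - 1, length - pos)` strictly exceeds `min_border_distance`.
#' The spacing rule is then applied greedily left-to-right within each
#' transcript: a surviving candidate is kept only if it lies at least
#' `min_spacing` bp from the previously kept candidate. The filter is
#' idempotent. Input must already be sorted by (transcript_id, pos).
#'
#' @param counts Long-format count tibble (see [read_count_table()]).
#' @param criteria A [snv_filter_criteria()].
#' @return The filtered count tibble, same layout, with attribute
#'   `n_sites_removed`.
#' @export
call_candidate_sites <- function(counts, criteria = snv_filter_criteria()) {
  counts <- validate_counts(counts)
  if (nrow(counts) == 0) return(counts)
  key <- order(counts$transcript_id, counts$pos, method = "radix")
  if (is.unsorted(key)) {
    abort("counts must be sorted by (transcript_id, pos)")
  }
  counts$`..depth` <- site_depth(counts)
  site_ok <- counts %>%
    dplyr::group_by(.data$transcript_id, .data$pos) %>%
    dplyr::summarise(
      transcript_length = .data$transcript_length[1],
      qual_ok = .data$consensus_quality[1] >= criteria$min_consensus_quality,
      depth_ok = all(.data$`..depth`[.data$`..depth` > 0] >=
                       criteria$min_depth),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      border_ok = pmin(.data$pos - 1, .data$transcript_length - .data$pos) >
        criteria$min_border_distance,
      pass = .data$qual_ok & .data$depth_ok & .data$border_ok
    )
  # greedy spacing on the survivors, per transcript, left to right
  keep_spacing <- function(pos) {
    keep <- logical(length(pos))
    last <- -Inf
    for (i in seq_along(pos)) {
      if (pos[i] - last >= criteria$min_spacing) {
        keep[i] <- TRUE
        last <- pos[i]
      }
    }
    keep
  }
  kept <- site_ok %>%
    dplyr::filter(.data$pass) %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::arrange(.data$pos, .by_group = TRUE) %>%
    dplyr::mutate(keep = keep_spacing(.data$pos)) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$keep)
  n_before <- nrow(site_ok)
  out <- dplyr::semi_join(counts, kept, by = c("transcript_id", "pos"))
  out$`..depth` <- NULL
  attr(out, "n_sites_removed") <- n_before - nrow(kept)
  out
}

#' Partition parental sites into fixed and intragenomic heterozygous calls
#'
#' For every (site, parental library) pair, bases supported by at least
#' `min_minor_count` reads making up at least `min_minor_fraction` of the
#' library's coverage there are treated as called alleles. One called allele
#' gives a fixed call for the library; two give an intragenomic heterozygous
#' site (only usable for bias calibration when one of the two alleles is the
#' assembly reference base); zero coverage, or more than two called alleles,
#' leaves the library uninformative at the site. Singleton reads of a second
#' base are ignored rather than allowed to destroy a fixed call, since the
#' upstream caller's error model is not available at the count level.
#'
#' @param counts Long-format count tibble, usually after
#'   [call_candidate_sites()].
#' @param meta Library metadata; only PP and AA libraries are used.
#' @param min_minor_count Reads required to call a second allele, default 2.
#' @param min_minor_fraction Minimum fraction of site coverage for a called
#'   allele, default 0.1.
#' @return A list with
#'   \describe{
#'     \item{fixed}{tibble `transcript_id`, `pos`, `ref_base`, `library_id`,
#'       `genomotype`, `base` — one fixed call per informative library/site}
#'     \item{het}{tibble `library_id`, `transcript_id`, `pos`, `count_ref`,
#'       `count_alt` — heterozygous sites oriented to the reference base,
#'       both counts > 0}
#'   }
#' @export
partition_polymorphisms <- function(counts, meta, min_minor_count = 2,
                                    min_minor_fraction = 0.1) {
  counts <- validate_counts(counts)
  meta <- validate_library_meta(meta)
  parental <- dplyr::filter(meta, .data$genomotype %in% c("PP", "AA"))
  sub <- dplyr::inner_join(counts,
                           dplyr::select(parental, "library_id",
                                         "genomotype"),
                           by = "library_id")
  if (nrow(sub) == 0) {
    return(list(
      fixed = tibble(transcript_id = character(), pos = integer(),
                     ref_base = character(), library_id = character(),
                     genomotype = character(), base = character()),
      het = tibble(library_id = character(), transcript_id = character(),
                   pos = integer(), count_ref = numeric(),
                   count_alt = numeric())
    ))
  }
  cts <- as.matrix(sub[COUNT_COLS])
  total <- rowSums(cts)
  called <- cts >= min_minor_count &
    cts >= min_minor_fraction * total & total > 0
  n_called <- rowSums(called)
  # single observed base below the minor-count threshold is still a fixed
  # call (e.g. one read of one base, nothing else)
  single_base <- rowSums(cts > 0) == 1 & total > 0
  fixed_i <- which(n_called == 1 | (n_called == 0 & single_base))
  top_base <- BASES[max.col(cts, ties.method = "first")]

  fixed <- tibble(
    transcript_id = sub$transcript_id[fixed_i],
    pos = sub$pos[fixed_i],
    ref_base = sub$ref_base[fixed_i],
    library_id = sub$library_id[fixed_i],
    genomotype = sub$genomotype[fixed_i],
    base = top_base[fixed_i]
  ) %>%
    dplyr::arrange(.data$transcript_id, .data$pos, .data$library_id)

  het_i <- which(n_called == 2)
  if (length(het_i) > 0) {
    ref_idx <- match(sub$ref_base[het_i], BASES)
    ref_called <- called[cbind(het_i, ref_idx)]
    ref_count <- cts[cbind(het_i, ref_idx)]
    alt_count <- vapply(seq_along(het_i), function(k) {
      i <- het_i[k]
      alt <- which(called[i, ] & seq_len(4) != ref_idx[k])
      sum(cts[i, alt])
    }, 0)
    keep <- ref_called          # orientable: reference base is one allele
    het <- tibble(
      library_id = sub$library_id[het_i][keep],
      transcript_id = sub$transcript_id[het_i][keep],
      pos = sub$pos[het_i][keep],
      count_ref = unname(ref_count[keep]),
      count_alt = unname(alt_count[keep])
    ) %>%
      dplyr::arrange(.data$library_id, .data$transcript_id, .data$pos)
  } else {
    het <- tibble(library_id = character(), transcript_id = character(),
                  pos = integer(), count_ref = numeric(),
                  count_alt = numeric())
  }
  list(fixed = fixed, het = het)
}

#' Identify genome-diagnostic SNPs
#'
#' A site is diagnostic when every required AA library carries the same
#' fixed base, every required PP library carries the same fixed base, and
#' the two bases differ. The reference-matching genome is recorded by
#' comparing the assembly reference base with the two variants; sites whose
#' reference base equals neither variant are excluded and counted in the
#' `n_ref_mismatch` attribute (an assembly/variant inconsistency).
#'
#' @param fixed Fixed-call tibble from [partition_polymorphisms()].
#' @param meta Library metadata.
#' @param n_AA_required,n_PP_required Number of parental libraries that must
#'   carry a fixed call at the site; defaults to all AA (resp. PP) libraries
#'   in `meta`, i.e. strict all-library coverage.
#' @return A tibble of diagnostic SNPs: `transcript_id`, `pos`, `p_base`,
#'   `a_base`, `ref_matches` ("P" or "A"), sorted by (transcript, pos),
#'   with attribute `n_ref_mismatch`.
#' @export
identify_diagnostic_snps <- function(fixed, meta,
                                     n_AA_required = NULL,
                                     n_PP_required = NULL) {
  meta <- validate_library_meta(meta)
  n_AA_required <- n_AA_required %||% sum(meta$genomotype == "AA")
  n_PP_required <- n_PP_required %||% sum(meta$genomotype == "PP")
  if (n_AA_required < 1 || n_PP_required < 1) {
    abort("need at least one required library per parental genome group")
  }
  cand <- fixed %>%
    dplyr::group_by(.data$transcript_id, .data$pos) %>%
    dplyr::summarise(
      ref_base = .data$ref_base[1],
      n_AA = sum(.data$genomotype == "AA"),
      n_PP = sum(.data$genomotype == "PP"),
      a_fixed = dplyr::n_distinct(.data$base[.data$genomotype == "AA"]) == 1,
      p_fixed = dplyr::n_distinct(.data$base[.data$genomotype == "PP"]) == 1,
      a_base = .data$base[.data$genomotype == "AA"][1],
      p_base = .data$base[.data$genomotype == "PP"][1],
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_AA >= n_AA_required, .data$n_PP >= n_PP_required,
                  .data$a_fixed, .data$p_fixed,
                  .data$a_base != .data$p_base)
  mismatch <- cand$ref_base != cand$p_base & cand$ref_base != cand$a_base
  n_ref_mismatch <- sum(mismatch)
  if (n_ref_mismatch > 0) {
    inform(paste0("excluded ", n_ref_mismatch, " site(s) whose reference ",
                  "base matches neither parental variant"))
  }
  out <- cand %>%
    dplyr::filter(!mismatch) %>%
    dplyr::transmute(.data$transcript_id, .data$pos, .data$p_base,
                     .data$a_base,
                     ref_matches = ifelse(.data$ref_base == .data$a_base,
                                          "A", "P")) %>%
    dplyr::arrange(.data$transcript_id, .data$pos)
  attr(out, "n_ref_mismatch") <- n_ref_mismatch
  out
}
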