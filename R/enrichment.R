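MGE_GROUP_IDS <- c("liver_P", "liver_A", "juv_P", "juv_A",
                   "PA_P", "PA_A", "PAA_P", "PAA_A")

#' Assemble monogenomic-expression groups
#'
#' Organises transcripts with monogenomic expression into the eight groups
#' used for functional enrichment: silenced-for-A (MGE_P) and silenced-for-P
#' (MGE_A) transcripts pooled within each tissue type (liver, juvenile)
#' irrespective of ploidy, and within each hybrid genomotype (PA, PAA)
#' irrespective of tissue. Union semantics within an axis: a transcript
#' enters `liver_P` if it is MGE_P in any liver library, and so on; group
#' assembly is idempotent and order-independent. Axes with no contributing
#' libraries yield empty groups with a warning.
#'
#' @param calls Classified calls from [classify_transcripts()] for the
#'   hybrid libraries.
#' @param meta Library metadata (supplies `tissue` and `genomotype`).
#' @param liver_tissue,juvenile_tissue Tissue labels defining the two
#'   tissue-pooled axes; defaults "liver" and "juvenile".
#' @return Tibble `group_id`, `transcript_id`, one row per membership, with
#'   `group_id` a factor over all eight group ids (empty groups represented
#'   by absent rows).
#' @export
assemble_mge_groups <- function(calls, meta, liver_tissue = "liver",
                                juvenile_tissue = "juvenile") {
  calls <- as_tibble(calls)
  meta <- validate_library_meta(meta)
  joined <- dplyr::inner_join(
    dplyr::filter(calls, .data$mge != "none"),
    dplyr::select(meta, "library_id", "genomotype", "tissue"),
    by = "library_id"
  )
  axes <- list(
    liver = function(d) d$tissue == liver_tissue,
    juv = function(d) d$tissue == juvenile_tissue,
    PA = function(d) d$genomotype == "PA",
    PAA = function(d) d$genomotype == "PAA"
  )
  hybrid_meta <- dplyr::filter(meta,
                               .data$genomotype %in% HYBRID_GENOMOTYPES)
  groups <- purrr::imap(axes, function(pred, axis) {
    if (!any(pred(hybrid_meta))) {
      warn(paste0("no hybrid libraries on the '", axis,
                  "' axis; its groups are empty"))
      return(NULL)
    }
    sub <- joined[pred(joined), ]
    dplyr::bind_rows(
      tibble(group_id = paste0(axis, "_P"),
             transcript_id = unique(sub$transcript_id[sub$mge == "MGE_P"])),
      tibble(group_id = paste0(axis, "_A"),
             transcript_id = unique(sub$transcript_id[sub$mge == "MGE_A"]))
    )
  })
  out <- dplyr::bind_rows(groups)
  if (nrow(out) == 0) {
    out <- tibble(group_id = character(), transcript_id = character())
  }
  out$group_id <- factor(out$group_id, levels = MGE_GROUP_IDS)
  dplyr::arrange(out, .data$group_id, .data$transcript_id)
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' Tests each annotation term for over-representation in a transcript group
#' against a background set, using the exact upper-tail hypergeometric
#' probability `P(X >= k)` where `k` of the `n` group members carry the term
#' and `K` of the `N` background transcripts do. This is a transparent
#' substitute for web-service enrichment tools; `ease = TRUE` subtracts one
#' success (scoring `P(X >= k - 1)`) to emulate the more conservative EASE
#' variant. Adjusted p-values are Benjamini-Hochberg within each
#' (group, namespace) stratum, mirroring per-category report listings.
#'
#' @param groups Group membership tibble from [assemble_mge_groups()] (or
#'   any tibble with `group_id`, `transcript_id`).
#' @param background Character vector of background transcript ids (all
#'   quantified transcripts). Group members must be a subset.
#' @param annotation Annotation tibble from [read_annotation()].
#' @param ease Use the EASE-style conservative score.
#' @return Tibble `group_id`, `term_id`, `namespace`, `description`, `k`,
#'   `K`, `n`, `N`, `p_value`, `p_adjusted`, sorted by group and adjusted
#'   p-value.
#' @export
hypergeometric_enrichment <- function(groups, background, annotation,
                                      ease = FALSE) {
  groups <- as_tibble(groups)
  background <- unique(background)
  N <- length(background)
  if (N == 0) abort("background transcript set is empty")
  stray <- setdiff(unique(groups$transcript_id), background)
  if (length(stray) > 0) {
    abort(paste0(length(stray),
                 " group transcript(s) missing from the background"))
  }
  ann <- dplyr::filter(as_tibble(annotation),
                       .data$transcript_id %in% background)
  term_info <- ann %>%
    dplyr::group_by(.data$term_id, .data$namespace) %>%
    dplyr::summarise(K = dplyr::n_distinct(.data$transcript_id),
                     description = .data$description[1], .groups = "drop")
  results <- groups %>%
    dplyr::group_by(.data$group_id) %>%
    dplyr::group_map(function(members, key) {
      n <- dplyr::n_distinct(members$transcript_id)
      k_by_term <- ann %>%
        dplyr::filter(.data$transcript_id %in% members$transcript_id) %>%
        dplyr::distinct(.data$transcript_id, .data$term_id) %>%
        dplyr::count(.data$term_id, name = "k")
      res <- term_info %>%
        dplyr::left_join(k_by_term, by = "term_id") %>%
        dplyr::mutate(k = dplyr::coalesce(.data$k, 0L))
      k_eff <- if (ease) pmax(res$k - 1L, 0L) else res$k
      res$p_value <- phyper(k_eff - 1, res$K, N - res$K, n,
                            lower.tail = FALSE)
      res %>%
        dplyr::mutate(group_id = key$group_id, n = n, N = N) %>%
        dplyr::group_by(.data$namespace) %>%
        dplyr::mutate(p_adjusted = benjamini_hochberg(.data$p_value)) %>%
        dplyr::ungroup()
    }) %>%
    dplyr::bind_rows()
  if (nrow(results) == 0) {
    return(tibble(group_id = character(), term_id = character(),
                  namespace = character(), description = character(),
                  k = integer(), K = integer(), n = integer(), N = integer(),
                  p_value = numeric(), p_adjusted = numeric()))
  }
  results %>%
    dplyr::select("group_id", "term_id", "namespace", "description",
                  "k", "K", "n", "N", "p_value", "p_adjusted") %>%
    dplyr::arrange(.data$group_id, .data$p_adjusted, .data$p_value,
                   .data$term_id)
}
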