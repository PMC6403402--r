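#' Classifier configuration for homoeolog expression categories
#'
#' Holds the ploidy-specific balance windows and the silencing cutoff used
#' to classify per-transcript A-genome fractions (`f_A`). A transcript is
#' called balanced (BHE) when `f_A` lies strictly inside the window for its
#' ploidy; at or below the lower bound it is biased toward the P genome
#' (HEB_P), at or above the upper bound biased toward A (HEB_A). Within the
#' biased calls, a fraction of the minor genome strictly below
#' `silencing_cutoff` (or above `1 - silencing_cutoff`) is monogenomic
#' expression (MGE), i.e. allelic silencing of the other genome.
#'
#' The defaults encode balanced expression as less than 70% preference for
#' either homoeolog in diploids, giving the window (0.3, 0.7), and the
#' proportional extrapolation to triploids carrying one P and two A genomes
#' (expected balanced A fraction 2/3), giving (0.5, 0.9). The silencing
#' cutoff is 0.1. Note the triploid geometry: because the upper balance
#' bound 0.9 equals `1 - silencing_cutoff`, the triploid HEB_A region equals
#' the MGE_A region plus the single point `f_A = 0.9`.
#'
#' @param diploid_window Numeric length-2, open balance window on `f_A` for
#'   diploid hybrids. Default `c(0.3, 0.7)`.
#' @param triploid_window Numeric length-2, open balance window for triploid
#'   (PAA) hybrids. Default `c(0.5, 0.9)`.
#' @param silencing_cutoff Strict cutoff on the minor-genome fraction below
#'   which expression is called monogenomic. Default `0.1`.
#' @return An object of class `heb_classifier_config`.
#' @export
#' @examples
#' cfg <- classifier_config()
#' classify_fraction(c(0.65, 0.05, 0.95), ploidy = 2, config = cfg)
classifier_config <- function(diploid_window = c(0.3, 0.7),
                              triploid_window = c(0.5, 0.9),
                              silencing_cutoff = 0.1) {
  check_window <- function(w, name) {
    if (length(w) != 2 || !is.numeric(w) || w[1] >= w[2]) {
      abort(paste0(name, " must be an increasing numeric pair"))
    }
    if (!(silencing_cutoff > 0 && silencing_cutoff < w[1] && w[2] < 1)) {
      abort(paste0("need 0 < silencing_cutoff < ", name, "[1] < ",
                   name, "[2] < 1"))
    }
  }
  check_window(diploid_window, "diploid_window")
  check_window(triploid_window, "triploid_window")
  structure(
    list(diploid_window = as.numeric(diploid_window),
         triploid_window = as.numeric(triploid_window),
         silencing_cutoff = as.numeric(silencing_cutoff)),
    class = "heb_classifier_config"
  )
}

#' @export
print.heb_classifier_config <- function(x, ...) {
  cat("Homoeolog expression classifier\n")
  cat(sprintf("  diploid balance window : (%.2f, %.2f)\n",
              x$diploid_window[1], x$diploid_window[2]))
  cat(sprintf("  triploid balance window: (%.2f, %.2f)\n",
              x$triploid_window[1], x$triploid_window[2]))
  cat(sprintf("  silencing cutoff       : %.2f (strict)\n",
              x$silencing_cutoff))
  invisible(x)
}

balance_window <- function(config, ploidy) {
  if (ploidy == 2) config$diploid_window
  else if (ploidy == 3) config$triploid_window
  else abort(paste0("unsupported ploidy: ", ploidy))
}

#' A-fraction interval occupied by an expression class
#'
#' Returns the half-open/open interval of true A-genome fractions consistent
#' with a class label at a given ploidy under a classifier configuration.
#' Used by the synthetic-data generator so that simulated truth labels and
#' classifier geometry agree by construction. At the default triploid
#' settings the HEB_A (biased but not silenced) interval degenerates to the
#' single point 0.9.
#'
#' @param class One of "BHE", "HEB_P", "HEB_A", "MGE_P", "MGE_A".
#' @param ploidy 2 or 3.
#' @param config A [classifier_config()].
#' @return Numeric length-2 interval `c(lo, hi)` (possibly degenerate).
#' @export
class_interval <- function(class, ploidy, config = classifier_config()) {
  w <- balance_window(config, ploidy)
  tau <- config$silencing_cutoff
  switch(class,
    MGE_P = c(0, tau),
    HEB_P = c(tau, w[1]),
    BHE   = w,
    HEB_A = c(w[2], 1 - tau),
    MGE_A = c(1 - tau, 1),
    abort(paste0("unknown class: ", class))
  )
}

#' Classify A-genome fractions into expression categories
#'
#' Vectorised core of the classifier. Balanced (BHE) is the open interval
#' `(L, U)` for the ploidy; `f_A <= L` is HEB_P and `f_A >= U` is HEB_A.
#' Monogenomic expression is strict: MGE_P when `f_A < silencing_cutoff`,
#' MGE_A when `f_A > 1 - silencing_cutoff`. Boundary values therefore fall
#' to the biased (HEB) side but not to MGE.
#'
#' @param f_A Numeric vector of A-genome fractions in \[0, 1\].
#' @param ploidy Integer scalar or vector (2 or 3), recycled against `f_A`.
#' @param config A [classifier_config()].
#' @return A tibble with columns `f_A`, `ploidy`, `category` (BHE/HEB_P/
#'   HEB_A) and `mge` (none/MGE_P/MGE_A).
#' @export
classify_fraction <- function(f_A, ploidy, config = classifier_config()) {
  if (any(is.na(f_A)) || any(f_A < 0 | f_A > 1)) {
    abort("f_A must lie in [0, 1]")
  }
  if (!all(ploidy %in% c(2L, 3L))) {
    abort(paste0("unsupported ploidy: ",
                 paste(setdiff(unique(ploidy), c(2L, 3L)), collapse = ", ")))
  }
  n <- max(length(f_A), length(ploidy))
  f_A <- rep_len(f_A, n)
  ploidy <- rep_len(as.integer(ploidy), n)
  L <- ifelse(ploidy == 2, config$diploid_window[1], config$triploid_window[1])
  U <- ifelse(ploidy == 2, config$diploid_window[2], config$triploid_window[2])
  tau <- config$silencing_cutoff
  category <- dplyr::case_when(
    f_A <= L ~ "HEB_P",
    f_A >= U ~ "HEB_A",
    TRUE ~ "BHE"
  )
  mge <- dplyr::case_when(
    f_A < tau ~ "MGE_P",
    f_A > 1 - tau ~ "MGE_A",
    TRUE ~ "none"
  )
  tibble(f_A = f_A, ploidy = ploidy, category = category, mge = mge)
}

#' Classify per-transcript homoeolog fractions for hybrid libraries
#'
#' Applies [classify_fraction()] to a table of per-transcript A-genome
#' fractions (the output of [transcript_fractions()]), using each library's
#' ploidy from the metadata sheet.
#'
#' @param ase Tibble with columns `library_id`, `transcript_id`, `f_A` (and
#'   usually `n_sites`, `mean_reads_P`, `mean_reads_A`).
#' @param meta Library metadata (see [read_library_meta()]).
#' @param config A [classifier_config()].
#' @return The input tibble with `ploidy`, `category` and `mge` columns
#'   added; one row per (library, transcript).
#' @export
classify_transcripts <- function(ase, meta, config = classifier_config()) {
  meta <- validate_library_meta(meta)
  ase <- as_tibble(ase)
  unknown <- setdiff(unique(ase$library_id), meta$library_id)
  if (length(unknown) > 0) {
    abort(paste0("libraries absent from metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  ase <- dplyr::left_join(ase,
                          dplyr::select(meta, "library_id", "ploidy"),
                          by = "library_id")
  cls <- classify_fraction(ase$f_A, ase$ploidy, config)
  ase$category <- cls$category
  ase$mge <- cls$mge
  dplyr::arrange(ase, .data$library_id, .data$transcript_id)
}

#' Summarise classification calls per library
#'
#' Produces the per-library category counts and integer percentages in the
#' shape of the published per-library summary tables: balanced (BHE), total
#' biased (HEB), biased toward each genome (HEB_P, HEB_A) and monogenomic
#' expression of each genome (MGE_P, MGE_A; subsets of the corresponding
#' HEB counts). Percentages are of the per-library transcript total,
#' rounded to the nearest integer with ties away from zero.
#'
#' @param calls Classified calls from [classify_transcripts()].
#' @return A tibble with one row per library: counts `n_BHE`, `n_HEB`,
#'   `n_HEB_P`, `n_HEB_A`, `n_MGE_P`, `n_MGE_A`, `n_total` and matching
#'   `pct_*` columns.
#' @export
summarize_classification <- function(calls) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) abort("no classification calls to summarise")
  out <- calls %>%
    dplyr::group_by(.data$library_id) %>%
    dplyr::summarise(
      n_BHE = sum(.data$category == "BHE"),
      n_HEB_P = sum(.data$category == "HEB_P"),
      n_HEB_A = sum(.data$category == "HEB_A"),
      n_MGE_P = sum(.data$mge == "MGE_P"),
      n_MGE_A = sum(.data$mge == "MGE_A"),
      n_total = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(n_HEB = .data$n_HEB_P + .data$n_HEB_A)
  pct <- function(n) round_half_up(100 * n / out$n_total)
  out %>%
    dplyr::mutate(
      pct_BHE = pct(.data$n_BHE),
      pct_HEB = pct(.data$n_HEB),
      pct_HEB_P = pct(.data$n_HEB_P),
      pct_HEB_A = pct(.data$n_HEB_A),
      pct_MGE_P = pct(.data$n_MGE_P),
      pct_MGE_A = pct(.data$n_MGE_A),
      pct_MGE = pct(.data$n_MGE_P + .data$n_MGE_A)
    ) %>%
    dplyr::select("library_id", "n_BHE", "n_HEB", "n_HEB_P", "n_HEB_A",
                  "n_MGE_P", "n_MGE_A", "n_total", dplyr::starts_with("pct_"))
}

#' Transcripts with consistent monogenomic expression across libraries
#'
#' Identifies transcripts silenced for the same genome in every library
#' considered. Strict membership: a transcript qualifies only if it is
#' quantified in all requested libraries and carries the same MGE flag in
#' each of them.
#'
#' @param calls Classified calls from [classify_transcripts()].
#' @param libraries Character vector of library ids to require; defaults to
#'   all libraries present in `calls`.
#' @return A tibble with columns `transcript_id` and `mge` ("MGE_P" or
#'   "MGE_A"), one row per consistently monogenomic transcript.
#' @export
consistent_mge <- function(calls, libraries = NULL) {
  calls <- as_tibble(calls)
  libraries <- libraries %||% sort(unique(calls$library_id))
  sub <- dplyr::filter(calls, .data$library_id %in% libraries)
  sub %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(
      n_libs = dplyr::n_distinct(.data$library_id),
      all_P = all(.data$mge == "MGE_P"),
      all_A = all(.data$mge == "MGE_A"),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_libs == length(libraries),
                  .data$all_P | .data$all_A) %>%
    dplyr::transmute(.data$transcript_id,
                     mge = ifelse(.data$all_P, "MGE_P", "MGE_A")) %>%
    dplyr::arrange(.data$transcript_id)
}
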