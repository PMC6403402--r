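#' Allelic ratio at a heterozygous site
#'
#' The per-site deviation from the 1:1 expectation at an intragenomic
#' heterozygous site, oriented as reference-matching reads over
#' other-allele reads. Under no mapping bias its expectation is 1; a
#' reference-mapping bias inflates it.
#'
#' @param count_ref Reads carrying the assembly reference base.
#' @param count_alt Reads carrying the other allele (> 0; zero-count sites
#'   are not heterozygous and must be excluded upstream).
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' site_ratio(10, 10)   # 1: no deviation
#' site_ratio(30, 10)   # 3
site_ratio <- function(count_ref, count_alt) {
  if (any(count_alt <= 0)) {
    abort("count_alt must be > 0: heterozygous sites carry both alleles")
  }
  if (any(count_ref < 0)) abort("count_ref must be >= 0")
  count_ref / count_alt
}

#' Estimate the global reference-bias correction factor
#'
#' For each parental library flagged `use_for_bias`, the mean allelic ratio
#' over its intragenomic heterozygous sites is computed (the per-sample mean
#' deviation from the 1:1 expectation); the correction factor `C` is the
#' mean of these per-sample means. The default uses arithmetic means of raw
#' ratios, the literal form of the deviation; `log_mean = TRUE` averages on
#' the log scale instead (geometric mean), which removes the upward bias of
#' raw ratio means at low depth, and is off by default.
#'
#' @param het_sites Heterozygous-site tibble from
#'   [partition_polymorphisms()] (columns `library_id`, `count_ref`,
#'   `count_alt`).
#' @param meta Library metadata; only libraries with `use_for_bias = TRUE`
#'   contribute.
#' @param log_mean Average log-ratios instead of raw ratios.
#' @param assume_no_bias Skip estimation and return `C = 1` explicitly.
#' @return An object of class `heb_bias_model` with elements `per_sample`
#'   (tibble `library_id`, `mean_ratio`, `n_sites`), `correction_factor`,
#'   `excluded_libraries` and `log_mean`.
#' @export
estimate_correction_factor <- function(het_sites, meta, log_mean = FALSE,
                                       assume_no_bias = FALSE) {
  meta <- validate_library_meta(meta)
  usable <- meta$library_id[meta$use_for_bias]
  excluded <- meta$library_id[meta$genomotype %in% c("PP", "AA") &
                                !meta$use_for_bias]
  if (assume_no_bias) {
    model <- list(per_sample = tibble(library_id = character(),
                                      mean_ratio = numeric(),
                                      n_sites = integer()),
                  correction_factor = 1,
                  excluded_libraries = excluded,
                  log_mean = log_mean)
    class(model) <- "heb_bias_model"
    return(model)
  }
  het <- dplyr::filter(as_tibble(het_sites), .data$library_id %in% usable)
  if (nrow(het) == 0) {
    abort(paste0("cannot estimate bias: no heterozygous sites in any ",
                 "use_for_bias library (use assume_no_bias = TRUE to set ",
                 "C = 1)"))
  }
  ratios <- site_ratio(het$count_ref, het$count_alt)
  per_sample <- het %>%
    dplyr::mutate(ratio = ratios) %>%
    dplyr::group_by(.data$library_id) %>%
    dplyr::summarise(
      mean_ratio = if (log_mean) exp(mean(log(.data$ratio)))
                   else mean(.data$ratio),
      n_sites = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$library_id)
  model <- list(per_sample = per_sample,
                correction_factor = mean(per_sample$mean_ratio),
                excluded_libraries = excluded,
                log_mean = log_mean)
  class(model) <- "heb_bias_model"
  model
}

#' @export
print.heb_bias_model <- function(x, ...) {
  cat("Reference-bias model\n")
  cat(sprintf("  correction factor C = %.4f (%s mean of per-sample means)\n",
              x$correction_factor,
              if (x$log_mean) "geometric" else "arithmetic"))
  if (nrow(x$per_sample) > 0) {
    cat(sprintf("  %d contributing librar%s, %d het sites total\n",
                nrow(x$per_sample),
                if (nrow(x$per_sample) == 1) "y" else "ies",
                sum(x$per_sample$n_sites)))
  } else {
    cat("  no estimation performed (C fixed at 1)\n")
  }
  if (length(x$excluded_libraries) > 0) {
    cat("  excluded from estimation:",
        paste(x$excluded_libraries, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname estimate_correction_factor
#' @param x A `heb_bias_model`.
#' @param ... Unused.
#' @method tidy heb_bias_model
#' @export
tidy.heb_bias_model <- function(x, ...) {
  x$per_sample
}

#' @rdname estimate_correction_factor
#' @method glance heb_bias_model
#' @export
glance.heb_bias_model <- function(x, ...) {
  tibble(correction_factor = x$correction_factor,
         n_libraries = nrow(x$per_sample),
         n_sites = sum(x$per_sample$n_sites),
         log_mean = x$log_mean,
         n_excluded_libraries = length(x$excluded_libraries))
}

#' Apply the reference-bias correction to per-site allele counts
#'
#' Divides the count of the reference-matching variant at each diagnostic
#' site by the correction factor `C`, leaving the other variant's count
#' unchanged. Corrected counts may be fractional. With `C = 1` this is the
#' identity.
#'
#' @param site_counts Tibble with per-site hybrid counts: columns `reads_P`,
#'   `reads_A` and `ref_matches` ("P" or "A"); see
#'   [count_diagnostic_reads()].
#' @param model A `heb_bias_model`, or a single positive number used as `C`
#'   directly.
#' @return The input tibble with `corrected_P` and `corrected_A` columns
#'   added.
#' @export
apply_correction <- function(site_counts, model) {
  C <- if (inherits(model, "heb_bias_model")) model$correction_factor
       else as.numeric(model)
  if (!is.finite(C) || C <= 0) abort("correction factor must be > 0")
  site_counts <- as_tibble(site_counts)
  if (!all(c("reads_P", "reads_A", "ref_matches") %in% names(site_counts))) {
    abort("site_counts needs columns reads_P, reads_A, ref_matches")
  }
  site_counts %>%
    dplyr::mutate(
      corrected_P = ifelse(.data$ref_matches == "P",
                           .data$reads_P / C, .data$reads_P),
      corrected_A = ifelse(.data$ref_matches == "A",
                           .data$reads_A / C, .data$reads_A)
    )
}
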