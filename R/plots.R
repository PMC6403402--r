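#' Plot the distribution of A-genome fractions
#'
#' Histogram of per-transcript A-genome contribution per hybrid library,
#' with the ploidy-specific balance-window boundaries marked — the standard
#' way to display genome-specific expression in hybrid libraries.
#'
#' @param calls Classified calls from [classify_transcripts()] (needs
#'   `f_A` and `ploidy`), or an `ase` table plus `meta`.
#' @param meta Optional library metadata, required when `calls` lacks a
#'   `ploidy` column.
#' @param config A [classifier_config()] for the boundary lines.
#' @param bins Histogram bins, default 40.
#' @return A ggplot object, faceted by library.
#' @export
plot_fraction_distribution <- function(calls, meta = NULL,
                                       config = classifier_config(),
                                       bins = 40) {
  calls <- as_tibble(calls)
  if (!"ploidy" %in% names(calls)) {
    if (is.null(meta)) abort("supply meta when calls lack a ploidy column")
    meta <- validate_library_meta(meta)
    calls <- dplyr::left_join(calls,
                              dplyr::select(meta, "library_id", "ploidy"),
                              by = "library_id")
  }
  windows <- calls %>%
    dplyr::distinct(.data$library_id, .data$ploidy) %>%
    dplyr::mutate(
      lower = ifelse(.data$ploidy == 2, config$diploid_window[1],
                     config$triploid_window[1]),
      upper = ifelse(.data$ploidy == 2, config$diploid_window[2],
                     config$triploid_window[2])
    ) %>%
    tidyr::pivot_longer(c("lower", "upper"), values_to = "boundary")
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$f_A)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0,
                            fill = "grey35", colour = "white",
                            linewidth = 0.2) +
    ggplot2::geom_vline(data = windows,
                        ggplot2::aes(xintercept = .data$boundary),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$library_id), scales = "free_y") +
    ggplot2::labs(x = "A-genome expression fraction (f_A)",
                  y = "transcripts") +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_correction_factor Dot plot of per-sample mean
#'   allelic ratios with the global correction factor marked.
#' @param object A `heb_bias_model`.
#' @method autoplot heb_bias_model
#' @export
autoplot.heb_bias_model <- function(object, ...) {
  if (nrow(object$per_sample) == 0) {
    abort("nothing to plot: bias model was not estimated")
  }
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(x = .data$mean_ratio,
                               y = .data$library_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$correction_factor,
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 1, colour = "grey60") +
    ggplot2::labs(x = "mean allelic ratio (reference / other)",
                  y = NULL,
                  caption = sprintf("correction factor C = %.3f",
                                    object$correction_factor)) +
    ggplot2::theme_minimal()
}

#' Stacked category composition per library
#'
#' Bar chart of the classification summary: balanced, biased-not-silenced
#' and monogenomic fractions per hybrid library.
#'
#' @param object A summary tibble from [summarize_classification()] or a
#'   `heb_pipeline` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot heb_pipeline
#' @export
autoplot.heb_pipeline <- function(object, ...) {
  plot_classification_summary(object$summary)
}

#' @rdname autoplot.heb_pipeline
#' @export
plot_classification_summary <- function(object) {
  summary <- as_tibble(object)
  long <- summary %>%
    dplyr::transmute(
      .data$library_id,
      BHE = .data$n_BHE,
      `HEB (not silenced)` = .data$n_HEB - .data$n_MGE_P - .data$n_MGE_A,
      `MGE(P)` = .data$n_MGE_P,
      `MGE(A)` = .data$n_MGE_A
    ) %>%
    tidyr::pivot_longer(-"library_id", names_to = "category",
                        values_to = "n") %>%
    dplyr::mutate(category = factor(.data$category,
                                    levels = c("BHE", "HEB (not silenced)",
                                               "MGE(P)", "MGE(A)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$library_id, y = .data$n,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "fraction of transcripts", fill = NULL) +
    ggplot2::theme_minimal()
}
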