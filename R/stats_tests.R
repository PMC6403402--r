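new_heb_test <- function(statistic, df, p_value, direction, method) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value,
         direction = direction, method = method),
    class = "heb_test"
  )
}

#' @export
print.heb_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  X-squared = %.4g, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$direction)) cat("  direction:", x$direction, "\n")
  invisible(x)
}

#' @rdname direction_test
#' @param x A `heb_test`.
#' @param ... Unused.
#' @method tidy heb_test
#' @export
tidy.heb_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         direction = x$direction %||% NA_character_, method = x$method)
}

#' @rdname direction_test
#' @method glance heb_test
#' @export
glance.heb_test <- function(x, ...) {
  tidy(x)
}

#' Chi-squared test of homoeolog bias direction
#'
#' Pearson goodness-of-fit test of the counts of transcripts biased toward
#' each genome against an expected equal split, df = 1, no continuity
#' correction. When the null is rejected at level `alpha`, the direction is
#' the genome with the larger count; otherwise "none". Swapping the
#' arguments preserves the statistic and flips the direction.
#'
#' @param n_heb_p,n_heb_a Numbers of transcripts with homoeolog expression
#'   bias toward the P and the A genome.
#' @param alpha Significance level, default 0.05.
#' @return A `heb_test` with `statistic`, `df`, `p_value` and `direction`
#'   ("toward_P", "toward_A" or "none").
#' @export
#' @examples
#' direction_test(255, 102)   # strongly toward P
direction_test <- function(n_heb_p, n_heb_a, alpha = 0.05) {
  if (n_heb_p < 0 || n_heb_a < 0) abort("counts must be >= 0")
  total <- n_heb_p + n_heb_a
  if (total < 1) abort("need at least one biased transcript")
  expected <- total / 2
  statistic <- (n_heb_p - expected)^2 / expected +
    (n_heb_a - expected)^2 / expected
  p_value <- pchisq(statistic, df = 1, lower.tail = FALSE)
  direction <- if (p_value < alpha) {
    if (n_heb_p > n_heb_a) "toward_P" else "toward_A"
  } else {
    "none"
  }
  new_heb_test(statistic, 1L, p_value, direction,
               "Chi-squared goodness-of-fit test of bias direction")
}

#' Chi-squared test of a ploidy effect on bias prevalence
#'
#' Pearson chi-squared test of independence on a 2x2 table of biased (HEB)
#' versus balanced (BHE) transcript counts in the diploid and the triploid
#' library, df = 1, no continuity correction.
#'
#' @param table A 2x2 matrix `rbind(c(HEB_2n, BHE_2n), c(HEB_3n, BHE_3n))`
#'   (any 2x2 count table with positive margins is accepted).
#' @param alpha Significance level, default 0.05.
#' @return A `heb_test`; `direction` is "ploidy_effect" when the null is
#'   rejected, "none" otherwise.
#' @export
#' @examples
#' ploidy_test(rbind(c(357, 764), c(289, 649)))   # livers: no ploidy effect
ploidy_test <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("table must be 2x2")
  if (any(table < 0)) abort("counts must be >= 0")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("every margin of the 2x2 table must be > 0")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  statistic <- sum((table - expected)^2 / expected)
  p_value <- pchisq(statistic, df = 1, lower.tail = FALSE)
  direction <- if (p_value < alpha) "ploidy_effect" else "none"
  new_heb_test(statistic, 1L, p_value, direction,
               "Chi-squared test of independence (ploidy x bias)")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, preserving input order. Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
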