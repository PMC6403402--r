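#' Run the full homoeolog expression analysis
#'
#' Orchestrates every stage: SNV filtering, partition of parental sites into
#' fixed and intragenomic heterozygous calls, diagnostic SNP identification,
#' reference-bias estimation and correction, the minimum-read filter,
#' per-transcript homoeolog fractions, classification, chi-squared tests of
#' bias direction (per hybrid library) and of a ploidy effect (per tissue
#' with both ploidies present), monogenomic-expression group assembly and,
#' when an annotation is supplied, hypergeometric term enrichment. Every
#' threshold used is recorded in the run log.
#'
#' @param counts Long-format count tibble (see [read_count_table()]).
#' @param meta Library metadata (see [read_library_meta()]).
#' @param annotation Optional annotation tibble (see [read_annotation()]).
#' @param criteria [snv_filter_criteria()].
#' @param classifier [classifier_config()].
#' @param min_reads Minimum SNV-supporting reads per quantified site,
#'   default 20.
#' @param alpha Significance level for the chi-squared tests, default 0.05.
#' @param n_AA_required,n_PP_required Parental-library coverage requirements
#'   for diagnostic SNPs (default: all libraries of each parental group).
#' @param assume_no_bias,log_mean Bias-model options passed to
#'   [estimate_correction_factor()].
#' @param filter_after_correction Apply the minimum-read filter to corrected
#'   rather than raw counts.
#' @param liver_tissue,juvenile_tissue Tissue labels for the MGE pooling
#'   axes; axes without libraries are skipped silently here (unlike
#'   [assemble_mge_groups()] run standalone).
#' @return An object of class `heb_pipeline`: a list with `diagnostic`,
#'   `bias_model`, `site_counts`, `ase`, `calls`, `summary`, `tests`,
#'   `groups`, `enrichment` (NULL without annotation), `log` (character) and
#'   `params`.
#' @export
run_pipeline <- function(counts, meta, annotation = NULL,
                         criteria = snv_filter_criteria(),
                         classifier = classifier_config(),
                         min_reads = 20, alpha = 0.05,
                         n_AA_required = NULL, n_PP_required = NULL,
                         assume_no_bias = FALSE, log_mean = FALSE,
                         filter_after_correction = FALSE,
                         liver_tissue = "liver",
                         juvenile_tissue = "juvenile") {
  meta <- validate_library_meta(meta)
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  note("thresholds: quality>=%g depth>=%g spacing>=%g border>%g min_reads=%g alpha=%g",
       criteria$min_consensus_quality, criteria$min_depth,
       criteria$min_spacing, criteria$min_border_distance, min_reads, alpha)
  note("classifier: diploid (%g,%g) triploid (%g,%g) silencing<%g",
       classifier$diploid_window[1], classifier$diploid_window[2],
       classifier$triploid_window[1], classifier$triploid_window[2],
       classifier$silencing_cutoff)

  counts <- stage("data_io", validate_counts(counts))
  n_sites_in <- nrow(dplyr::distinct(counts, .data$transcript_id,
                                     .data$pos))
  filtered <- stage("snv_filter",
                    call_candidate_sites(counts, criteria))
  n_sites_kept <- nrow(dplyr::distinct(filtered, .data$transcript_id,
                                       .data$pos))
  note("snv_filter: %d of %d sites pass acceptance criteria",
       n_sites_kept, n_sites_in)

  parts <- stage("partition", partition_polymorphisms(filtered, meta))
  note("partition: %d fixed parental calls, %d intragenomic het sites",
       nrow(parts$fixed), nrow(parts$het))

  diagnostic <- stage("diagnostic_snps",
                      identify_diagnostic_snps(parts$fixed, meta,
                                               n_AA_required,
                                               n_PP_required))
  note("diagnostic_snps: %d diagnostic SNPs over %d transcripts",
       nrow(diagnostic), dplyr::n_distinct(diagnostic$transcript_id))

  bias_model <- stage("bias_correction",
                      estimate_correction_factor(parts$het, meta,
                                                 log_mean = log_mean,
                                                 assume_no_bias =
                                                   assume_no_bias))
  note("bias_correction: C = %.4f from %d het sites",
       bias_model$correction_factor, sum(bias_model$per_sample$n_sites))

  site_counts <- stage("ase_quant", {
    sc <- count_diagnostic_reads(filtered, diagnostic, meta)
    sc <- apply_correction(sc, bias_model)
    filter_min_reads(sc, min_reads, use_corrected = filter_after_correction)
  })
  hybrids <- meta$library_id[meta$genomotype %in% HYBRID_GENOMOTYPES]
  empty <- setdiff(hybrids, unique(site_counts$library_id))
  if (length(empty) > 0) {
    abort(paste0("pipeline stage 'ase_quant' failed: no diagnostic sites ",
                 "survive the filters in library '",
                 paste(empty, collapse = "', '"), "'"))
  }
  ase <- stage("ase_quant", transcript_fractions(site_counts))
  for (lib in hybrids) {
    sub <- dplyr::filter(ase, .data$library_id == lib)
    note("ase_quant[%s]: %d SNVs over %d transcripts", lib,
         sum(sub$n_sites), nrow(sub))
  }

  calls <- stage("classification",
                 classify_transcripts(ase, meta, classifier))
  summary <- stage("classification", summarize_classification(calls))

  tests <- stage("stats_tests",
                 pipeline_tests(summary, meta, alpha))

  groups <- stage("mge_groups", suppressWarnings(
    assemble_mge_groups(calls, meta, liver_tissue, juvenile_tissue)))
  note("mge_groups: %d memberships over %d groups", nrow(groups),
       dplyr::n_distinct(groups$group_id))

  enrichment <- NULL
  if (!is.null(annotation)) {
    background <- sort(unique(calls$transcript_id))
    enrichment <- stage("enrichment",
                        hypergeometric_enrichment(groups, background,
                                                  annotation))
    note("enrichment: %d (group, term) tests, %d significant at 0.05",
         nrow(enrichment), sum(enrichment$p_adjusted <= 0.05))
  }

  out <- list(diagnostic = diagnostic, bias_model = bias_model,
              site_counts = site_counts, ase = ase, calls = calls,
              summary = summary, tests = tests, groups = groups,
              enrichment = enrichment, log = log_lines,
              params = list(criteria = criteria, classifier = classifier,
                            min_reads = min_reads, alpha = alpha,
                            assume_no_bias = assume_no_bias,
                            log_mean = log_mean,
                            filter_after_correction =
                              filter_after_correction))
  class(out) <- "heb_pipeline"
  out
}

# direction test per hybrid library; ploidy test per tissue where both a
# diploid and a triploid hybrid library exist
pipeline_tests <- function(summary, meta, alpha) {
  summary <- dplyr::left_join(summary,
                              dplyr::select(meta, "library_id", "tissue",
                                            "ploidy", "genomotype"),
                              by = "library_id")
  rows <- list()
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    if (s$n_HEB_P + s$n_HEB_A >= 1) {
      t <- direction_test(s$n_HEB_P, s$n_HEB_A, alpha)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        tidy(t), comparison = paste0("direction:", s$library_id),
        .before = 1)
    }
  }
  for (tis in unique(summary$tissue)) {
    sub <- dplyr::filter(summary, .data$tissue == tis)
    di <- dplyr::filter(sub, .data$ploidy == 2)
    tri <- dplyr::filter(sub, .data$ploidy == 3)
    if (nrow(di) == 1 && nrow(tri) == 1) {
      tab <- rbind(c(di$n_HEB, di$n_BHE), c(tri$n_HEB, tri$n_BHE))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        t <- ploidy_test(tab, alpha)
        rows[[length(rows) + 1]] <- dplyr::mutate(
          tidy(t), comparison = paste0("ploidy:", tis), .before = 1)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(comparison = character(), statistic = numeric(),
                  df = integer(), p_value = numeric(),
                  direction = character(), method = character()))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.heb_pipeline <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `diagnostic.tsv`, `ase.tsv`, `calls.tsv`, `summary.tsv`,
#' `tests.tsv`, `groups.tsv`, `enrichment.tsv` (when computed),
#' `bias_model.tsv` and `run_log.txt` under `dir`.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  if (!inherits(result, "heb_pipeline")) {
    abort("result must come from run_pipeline()")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$diagnostic, file.path(dir, "diagnostic.tsv"))
  readr::write_tsv(result$ase, file.path(dir, "ase.tsv"))
  readr::write_tsv(result$calls, file.path(dir, "calls.tsv"))
  readr::write_tsv(result$summary, file.path(dir, "summary.tsv"))
  readr::write_tsv(result$tests, file.path(dir, "tests.tsv"))
  readr::write_tsv(result$groups, file.path(dir, "groups.tsv"))
  if (!is.null(result$enrichment)) {
    readr::write_tsv(result$enrichment, file.path(dir, "enrichment.tsv"))
  }
  bias <- dplyr::mutate(tidy(result$bias_model),
                        correction_factor =
                          result$bias_model$correction_factor)
  readr::write_tsv(bias, file.path(dir, "bias_model.tsv"))
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Render a human-readable pipeline report
#'
#' Markdown summary of a pipeline run: the correction factor, the
#' per-library classification table with counts and integer percentages,
#' the chi-squared tests, and the enrichment outcome (stating explicitly
#' when nothing is significant).
#'
#' @param result A [run_pipeline()] result.
#' @return A character vector of markdown lines.
#' @export
render_report <- function(result) {
  if (!inherits(result, "heb_pipeline")) {
    abort("result must come from run_pipeline()")
  }
  for (member in c("diagnostic", "bias_model", "ase", "calls", "summary",
                   "tests", "groups")) {
    if (is.null(result[[member]])) {
      abort(paste0("report bundle is missing '", member, "'"))
    }
  }
  lines <- c("# Homoeolog expression analysis", "")
  lines <- c(lines, sprintf("Reference-bias correction factor C = %.4f",
                            result$bias_model$correction_factor), "")
  lines <- c(lines, "## Genome-specific expression fractions", "")
  lines <- c(lines,
             "| library | BHE | HEB | HEB(P) | HEB(A) | MGE(P) | MGE(A) | total |",
             "|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(result$summary))) {
    s <- result$summary[i, ]
    lines <- c(lines, sprintf(
      "| %s | %d (%d%%) | %d (%d%%) | %d (%d%%) | %d (%d%%) | %d (%d%%) | %d (%d%%) | %d |",
      s$library_id, s$n_BHE, s$pct_BHE, s$n_HEB, s$pct_HEB,
      s$n_HEB_P, s$pct_HEB_P, s$n_HEB_A, s$pct_HEB_A,
      s$n_MGE_P, s$pct_MGE_P, s$n_MGE_A, s$pct_MGE_A, s$n_total))
  }
  lines <- c(lines, "", "## Chi-squared tests", "")
  if (nrow(result$tests) == 0) {
    lines <- c(lines, "No tests computed.")
  } else {
    lines <- c(lines, "| comparison | X-squared | df | p | direction |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(result$tests))) {
      t <- result$tests[i, ]
      lines <- c(lines, sprintf("| %s | %.3f | %d | %.3g | %s |",
                                t$comparison, t$statistic, t$df, t$p_value,
                                t$direction))
    }
  }
  lines <- c(lines, "", "## Functional enrichment", "")
  if (is.null(result$enrichment)) {
    lines <- c(lines, "No annotation supplied; enrichment not run.")
  } else {
    sig <- dplyr::filter(result$enrichment, .data$p_adjusted <= 0.05)
    if (nrow(sig) == 0) {
      lines <- c(lines, "No significant enrichment (NS in every group).")
    } else {
      lines <- c(lines,
                 "| group | term | namespace | k | adjusted p |",
                 "|---|---|---|---|---|")
      for (i in seq_len(nrow(sig))) {
        e <- sig[i, ]
        lines <- c(lines, sprintf("| %s | %s | %s | %d | %.2e |",
                                  e$group_id, e$term_id, e$namespace, e$k,
                                  e$p_adjusted))
      }
    }
  }
  lines
}
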