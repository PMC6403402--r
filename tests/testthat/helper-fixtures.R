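# Shared fixtures and independent oracles for the test suite.

# small metadata sheet: two libraries per parental genome, one diploid and
# one triploid hybrid, all liver
toy_meta <- function() {
  tibble::tibble(
    library_id = c("PP-1", "PP-2", "AA-1", "AA-2", "liv-PA", "liv-PAA"),
    genomotype = c("PP", "PP", "AA", "AA", "PA", "PAA"),
    tissue = "liver",
    ploidy = c(2L, 2L, 2L, 2L, 2L, 3L),
    use_for_bias = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

# one count-table row block: a site with given per-library base counts
site_block <- function(tx, pos, len, ref, qual, counts_by_lib) {
  purrr::imap_dfr(counts_by_lib, function(cts, lib) {
    tibble::tibble(
      transcript_id = tx, pos = as.integer(pos),
      transcript_length = as.integer(len), ref_base = ref,
      consensus_quality = qual, library_id = lib,
      count_A = cts[["A"]], count_C = cts[["C"]],
      count_G = cts[["G"]], count_T = cts[["T"]]
    )
  })
}

cnt <- function(A = 0L, C = 0L, G = 0L, T = 0L) {
  c(A = as.integer(A), C = as.integer(C), G = as.integer(G),
    T = as.integer(T))
}

# Hand-built 12-transcript golden fixture. One diagnostic site per
# transcript (P base C, A base T), plus transcript H1 carrying the
# intragenomic heterozygous sites that calibrate the bias model.
#
# Bias design: PP-1 het ratios {2.0, 0.5} -> D = 1.25; AA-1 het ratios
# {1.0, 1.0} -> D = 1.0; C = mean(1.25, 1.0) = 1.125. All hand-computed
# expectations below assume corrected counts = ref-matching count / 1.125.
golden_fixture <- function() {
  meta <- toy_meta()
  len <- 500L
  # per transcript: reference genome, hybrid raw counts (P reads, A reads)
  # refg "P" means the assembly reference base is the P variant (C)
  spec <- tibble::tribble(
    ~tx,    ~refg, ~pa_P, ~pa_A, ~paa_P, ~paa_A,
    "T01",  "P",    45L,   40L,   27L,    48L,
    "T02",  "A",    40L,   45L,   20L,    45L,
    "T03",  "P",    90L,   10L,   45L,    40L,
    "T04",  "A",     5L,   95L,    4L,   108L,
    "T05",  "P",    96L,    4L,   90L,     8L,
    "T06",  "A",    30L,   45L,   20L,    45L,
    "T07",  "P",    27L,   36L,    9L,    72L,
    "T08",  "P",    18L,   54L,   90L,    32L,
    "T09",  "P",    90L,    8L,   90L,     8L,
    "T10",  "A",     4L,   90L,    4L,    90L,
    "T11",  "P",    90L,    8L,   27L,    48L,
    "T12",  "P",    10L,    9L,   27L,    48L
  )
  blocks <- purrr::pmap(spec, function(tx, refg, pa_P, pa_A, paa_P, paa_A) {
    ref <- if (refg == "P") "C" else "T"
    site_block(tx, 50L, len, ref, 30, list(
      `PP-1` = cnt(C = 30), `PP-2` = cnt(C = 30),
      `AA-1` = cnt(T = 30), `AA-2` = cnt(T = 30),
      `liv-PA` = cnt(C = pa_P, T = pa_A),
      `liv-PAA` = cnt(C = paa_P, T = paa_A)
    ))
  })
  het <- dplyr::bind_rows(
    site_block("H1", 50L, len, "G", 30, list(
      `PP-1` = cnt(G = 20, A = 10), `PP-2` = cnt(G = 30),
      `AA-1` = cnt(G = 15, A = 15), `AA-2` = cnt(G = 30),
      `liv-PA` = cnt(G = 30), `liv-PAA` = cnt(G = 30)
    )),
    site_block("H1", 60L, len, "G", 30, list(
      `PP-1` = cnt(G = 10, A = 20), `PP-2` = cnt(G = 30),
      `AA-1` = cnt(G = 12, A = 12), `AA-2` = cnt(G = 30),
      `liv-PA` = cnt(G = 30), `liv-PAA` = cnt(G = 30)
    ))
  )
  counts <- dplyr::arrange(dplyr::bind_rows(c(blocks, list(het))),
                           transcript_id, pos, library_id)
  # hand-computed per-library expectations (corrected with C = 1.125)
  expected_calls <- dplyr::bind_rows(
    tibble::tibble(
      library_id = "liv-PA",
      transcript_id = c("T01", "T02", "T03", "T04", "T05", "T06", "T07",
                        "T08", "T09", "T10", "T11"),
      f_A = c(0.5, 0.5, 10 / 90, (95 / 1.125) / (5 + 95 / 1.125),
              4 / (96 / 1.125 + 4), 40 / 70, 36 / 60, 54 / 70, 8 / 88,
              (90 / 1.125) / (4 + 90 / 1.125), 8 / 88),
      category = c("BHE", "BHE", "HEB_P", "HEB_A", "HEB_P", "BHE", "BHE",
                   "HEB_A", "HEB_P", "HEB_A", "HEB_P"),
      mge = c("none", "none", "none", "MGE_A", "MGE_P", "none", "none",
              "none", "MGE_P", "MGE_A", "MGE_P")
    ),
    tibble::tibble(
      library_id = "liv-PAA",
      transcript_id = sprintf("T%02d", 1:12),
      f_A = c(48 / 72, 40 / 60, 0.5, 96 / 100, 8 / 88, 40 / 60, 72 / 80,
              24 / 84, 8 / 88, 80 / 84, 48 / 72, 48 / 72),
      category = c("BHE", "BHE", "HEB_P", "HEB_A", "HEB_P", "BHE", "HEB_A",
                   "HEB_P", "HEB_P", "HEB_A", "BHE", "BHE"),
      mge = c("none", "none", "none", "MGE_A", "MGE_P", "none", "none",
              "none", "MGE_P", "MGE_A", "none", "none")
    )
  )
  expected_summary <- tibble::tibble(
    library_id = c("liv-PA", "liv-PAA"),
    n_BHE = c(4L, 5L), n_HEB = c(7L, 7L),
    n_HEB_P = c(4L, 4L), n_HEB_A = c(3L, 3L),
    n_MGE_P = c(3L, 2L), n_MGE_A = c(2L, 2L),
    n_total = c(11L, 12L),
    pct_BHE = c(36, 42), pct_HEB = c(64, 58),
    pct_HEB_P = c(36, 33), pct_HEB_A = c(27, 25),
    pct_MGE_P = c(27, 17), pct_MGE_A = c(18, 17),
    pct_MGE = c(45, 33)
  )
  list(counts = counts, meta = meta,
       C = 1.125,
       n_diagnostic = 12L,
       expected_calls = expected_calls,
       expected_summary = expected_summary,
       consistent_P = c("T05", "T09"),
       consistent_A = c("T04", "T10"))
}

# ---- independent oracles -------------------------------------------------

# Pearson chi-squared via stats::chisq.test, the independent route
oracle_gof <- function(a, b) {
  suppressWarnings(stats::chisq.test(c(a, b), p = c(0.5, 0.5),
                                     correct = FALSE))
}
oracle_independence <- function(tbl) {
  suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
}

# hypergeometric upper tail by explicit subset enumeration (N <= 12):
# probability that a uniformly drawn size-n subset of the background hits
# at least k of the K annotated transcripts
oracle_hyper_enum <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hits <- utils::combn(N, n, FUN = function(idx) sum(idx <= K))
  mean(hits >= k)
}

# expected mean allelic ratio at accepted heterozygous sites, by exact
# summation over the negative-binomial depth law and the binomial allele
# split; mirrors the het acceptance rules (both alleles >= min_count and
# >= min_frac of depth)
oracle_expected_ratio <- function(b, depth_mean, depth_dispersion,
                                  min_count = 2, min_frac = 0.1,
                                  dmax = NULL) {
  q <- b / (1 + b)
  dmax <- dmax %||% stats::qnbinom(1 - 1e-10, size = depth_dispersion,
                                   mu = depth_mean)
  num <- 0
  den <- 0
  for (d in seq(2 * min_count, dmax)) {
    wd <- stats::dnbinom(d, size = depth_dispersion, mu = depth_mean)
    r <- 0:d
    ok <- r >= min_count & (d - r) >= min_count &
      pmin(r, d - r) >= min_frac * d
    if (!any(ok)) next
    pr <- stats::dbinom(r[ok], d, q)
    num <- num + wd * sum(pr * r[ok] / (d - r[ok]))
    den <- den + wd * sum(pr)
  }
  num / den
}

`%||%` <- function(a, b) if (is.null(a)) b else a
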