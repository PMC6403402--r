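test_that("pointwise SNV acceptance rules drop the right sites", {
  meta <- toy_meta()
  libs_fixed <- function(n) {
    setNames(lapply(meta$library_id, function(x) cnt(C = n)),
             meta$library_id)
  }
  counts <- dplyr::bind_rows(
    site_block("T1", 100L, 500L, "C", 19, libs_fixed(30)),   # low quality
    site_block("T1", 150L, 500L, "C", 30, libs_fixed(30)),   # clean
    site_block("T2", 5L, 500L, "C", 30, libs_fixed(30)),     # left border
    site_block("T2", 496L, 500L, "C", 30, libs_fixed(30)),   # right border
    site_block("T3", 100L, 500L, "C", 30, libs_fixed(30)),   # clean
    site_block("T3", 103L, 500L, "C", 30, libs_fixed(30))    # spacing 3 < 5
  ) %>% dplyr::arrange(transcript_id, pos, library_id)
  out <- call_candidate_sites(counts)
  kept <- dplyr::distinct(out, transcript_id, pos)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$pos, c(150L, 100L))
  expect_equal(attr(out, "n_sites_removed"), 4)

  # shallow depth in one covered library kills the site
  shallow <- libs_fixed(30); shallow[["AA-1"]] <- cnt(C = 2)
  counts2 <- site_block("T4", 100L, 500L, "C", 30, shallow)
  expect_equal(nrow(call_candidate_sites(counts2)), 0)

  # boundary: exactly 6 bp from the border passes (strict > 5)
  counts3 <- site_block("T5", 7L, 500L, "C", 30, libs_fixed(30))
  expect_equal(nrow(call_candidate_sites(counts3)), nrow(counts3))

  expect_error(call_candidate_sites(counts[rev(seq_len(nrow(counts))), ]),
               "sorted")
})

test_that("the acceptance filter is idempotent", {
  sim <- simulate_complex(simulation_config(n_transcripts = 40, seed = 21,
                                            decoys_per_criterion = 2))
  once <- call_candidate_sites(sim$counts)
  twice <- call_candidate_sites(once)
  attr(once, "n_sites_removed") <- NULL
  attr(twice, "n_sites_removed") <- NULL
  expect_identical(twice, once)
})

test_that("appending decoys changes nothing but the decoys", {
  sim <- simulate_complex(simulation_config(n_transcripts = 30, seed = 13))
  clean <- call_candidate_sites(sim$counts)
  dec <- emit_decoy_sites(sim$counts, per_criterion = 2)
  withdec <- dplyr::arrange(dplyr::bind_rows(sim$counts, dec$counts),
                            transcript_id, pos, library_id)
  filtered <- call_candidate_sites(withdec)
  attr(clean, "n_sites_removed") <- NULL
  attr(filtered, "n_sites_removed") <- NULL
  expect_identical(as.data.frame(filtered), as.data.frame(clean))
})

test_that("parental sites partition into fixed and heterozygous calls", {
  meta <- toy_meta()
  counts <- dplyr::bind_rows(
    # AA-1 fixed G, zero elsewhere -> uninformative for other libraries
    site_block("T1", 100L, 500L, "G", 30, list(
      `AA-1` = cnt(G = 30), `AA-2` = cnt(), `PP-1` = cnt(), `PP-2` = cnt(),
      `liv-PA` = cnt(), `liv-PAA` = cnt())),
    # AA-1 heterozygous G/T (ref G)
    site_block("T2", 100L, 500L, "G", 30, list(
      `AA-1` = cnt(G = 18, T = 12), `AA-2` = cnt(G = 30), `PP-1` = cnt(),
      `PP-2` = cnt(), `liv-PA` = cnt(), `liv-PAA` = cnt())),
    # singleton second base is ignored: fixed G
    site_block("T3", 100L, 500L, "G", 30, list(
      `AA-1` = cnt(G = 30, T = 1), `AA-2` = cnt(), `PP-1` = cnt(),
      `PP-2` = cnt(), `liv-PA` = cnt(), `liv-PAA` = cnt()))
  )
  parts <- partition_polymorphisms(counts, meta)
  f <- parts$fixed
  expect_equal(f$base[f$transcript_id == "T1" & f$library_id == "AA-1"], "G")
  expect_equal(f$base[f$transcript_id == "T3" & f$library_id == "AA-1"], "G")
  # zero-coverage libraries appear in neither bin
  expect_false(any(f$library_id %in% c("PP-1", "PP-2") &
                     f$transcript_id == "T1"))
  h <- parts$het
  expect_equal(nrow(h), 1)
  expect_equal(h$count_ref, 18)  # oriented to the reference base G
  expect_equal(h$count_alt, 12)
  # the heterozygous site is fixed in AA-2, so bins are disjoint per library
  expect_true(any(f$transcript_id == "T2" & f$library_id == "AA-2"))
  expect_false(any(f$transcript_id == "T2" & f$library_id == "AA-1"))
})

test_that("diagnostic SNPs require fixed, different variants in all parental libraries", {
  meta <- toy_meta()
  mk_fixed <- function(tx, aa1, aa2, pp1, pp2, ref) {
    tibble::tibble(
      transcript_id = tx, pos = 100L, ref_base = ref,
      library_id = c("AA-1", "AA-2", "PP-1", "PP-2"),
      genomotype = c("AA", "AA", "PP", "PP"),
      base = c(aa1, aa2, pp1, pp2)
    )
  }
  fixed <- dplyr::bind_rows(
    mk_fixed("T1", "T", "T", "C", "C", "C"),   # diagnostic, ref matches P
    mk_fixed("T2", "T", "C", "C", "C", "C"),   # AA not fixed
    mk_fixed("T3", "T", "T", "T", "T", "T"),   # no inter-genomic difference
    mk_fixed("T4", "T", "T", "C", "C", "G")    # ref matches neither
  )
  snps <- suppressMessages(identify_diagnostic_snps(fixed, meta))
  expect_equal(snps$transcript_id, "T1")
  expect_equal(snps$p_base, "C")
  expect_equal(snps$a_base, "T")
  expect_equal(snps$ref_matches, "P")
  expect_equal(attr(snps, "n_ref_mismatch"), 1)

  # missing coverage in one AA library excludes the site under strict mode
  partial <- mk_fixed("T5", "T", "T", "C", "C", "C")[-2, ]
  expect_equal(nrow(suppressMessages(
    identify_diagnostic_snps(partial, meta))), 0)
  # ... but passes with a relaxed library requirement
  expect_equal(nrow(suppressMessages(
    identify_diagnostic_snps(partial, meta, n_AA_required = 1))), 1)
})

test_that("diagnostic recovery on clean simulated data is essentially complete", {
  sim <- simulate_complex(simulation_config(n_transcripts = 150,
                                            depth_mean = 60,
                                            seed = 17))
  filtered <- call_candidate_sites(sim$counts)
  parts <- partition_polymorphisms(filtered, sim$meta)
  snps <- suppressMessages(identify_diagnostic_snps(parts$fixed, sim$meta))
  truth <- dplyr::filter(sim$truth$sites, is_diagnostic)
  found <- paste(snps$transcript_id, snps$pos)
  expected <- paste(truth$transcript_id, truth$pos)
  sensitivity <- mean(expected %in% found)
  expect_gte(sensitivity, 0.99)   # dropouts only via coverage gaps
  # no false positives: nothing outside the truth-diagnostic set
  expect_true(all(found %in% expected))
  # diagnostic sites never intersect the het-bearing sites
  het_key <- paste(sim$truth$het_sites$transcript_id,
                   sim$truth$het_sites$pos)
  expect_length(intersect(found, het_key), 0)
  # variant assignment is exact where recovered
  m <- dplyr::inner_join(snps, sim$truth$sites, by = c("transcript_id", "pos"))
  expect_equal(m$p_base.x, m$p_base.y)
  expect_equal(m$a_base.x, m$a_base.y)
  expect_equal(m$ref_matches, ifelse(m$ref_is_A, "A", "P"))
})
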