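test_that("site count simulation matches the effective-probability model", {
  # degenerate: all expression from one genome
  set.seed(1)
  d <- simulate_site_counts(1, depth = 50, b = 1.7, ref_is_A = TRUE)
  expect_equal(d$reads_P, 0)
  expect_equal(d$reads_A, 50)
  d0 <- simulate_site_counts(0, depth = 50, b = 1.7, ref_is_A = FALSE)
  expect_equal(d0$reads_A, 0)

  # symmetry at b = 1: fraction 0.5 within 3 binomial sigma
  n <- 1e6
  d <- simulate_site_counts(0.5, depth = n, b = 1)
  expect_lt(abs(d$reads_A / n - 0.5), 3 * sqrt(0.25 / n))

  # closed-form effective probability under bias: theta 0.5, b 2,
  # reference on the A side -> P(A read) = 2/3
  d <- simulate_site_counts(0.5, depth = n, b = 2, ref_is_A = TRUE)
  p <- 2 / 3
  expect_lt(abs(d$reads_A / n - p), 3 * sqrt(p * (1 - p) / n))
  # and the mirrored case favours P
  d <- simulate_site_counts(0.5, depth = n, b = 2, ref_is_A = FALSE)
  expect_lt(abs(d$reads_A / n - 1 / 3), 3 * sqrt(p * (1 - p) / n))

  expect_error(simulate_site_counts(1.2, 10, 1), "theta")
  expect_error(simulate_site_counts(0.5, 10, 0), "b must be")
})

test_that("law of large numbers: mean simulated A fraction converges to theta", {
  set.seed(42)
  for (theta in c(0.2, 0.5, 0.8)) {
    depth <- 200
    n <- 2000
    d <- simulate_site_counts(rep(theta, n), rep(depth, n), b = 1)
    f <- d$reads_A / depth
    se <- sqrt(theta * (1 - theta) / depth / n)
    expect_lt(abs(mean(f) - theta), 3 * se)
  }
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(n_transcripts = 25, seed = 11,
                           decoys_per_criterion = 1)
  s1 <- simulate_complex(cfg)
  s2 <- simulate_complex(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  # and byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("an empty experiment yields empty records and truth", {
  sim <- simulate_complex(simulation_config(n_transcripts = 0, seed = 1))
  expect_equal(nrow(sim$counts), 0)
  expect_equal(nrow(sim$truth$transcripts), 0)
  expect_equal(nrow(sim$truth$sites), 0)
  expect_equal(nrow(sim$meta), 11)   # libraries exist even with no data
})

test_that("every emitted site appears exactly once in the ground truth", {
  sim <- simulate_complex(simulation_config(n_transcripts = 40, seed = 3))
  emitted <- dplyr::distinct(sim$counts, transcript_id, pos)
  truth_key <- paste(sim$truth$sites$transcript_id, sim$truth$sites$pos)
  expect_equal(sort(paste(emitted$transcript_id, emitted$pos)),
               sort(truth_key))
  expect_false(any(duplicated(truth_key)))
})

test_that("true thetas are consistent with their class intervals", {
  sim <- simulate_complex(simulation_config(n_transcripts = 300, seed = 5))
  tr <- sim$truth$transcripts
  cfg <- classifier_config()
  for (i in seq_len(nrow(tr))) {
    iv2 <- class_interval(tr$class[i], 2L, cfg)
    iv3 <- class_interval(tr$class[i], 3L, cfg)
    expect_true(tr$theta_diploid[i] >= iv2[1] &&
                  tr$theta_diploid[i] <= iv2[2])
    expect_true(tr$theta_triploid[i] >= iv3[1] &&
                  tr$theta_triploid[i] <= iv3[2])
  }
})

test_that("the class mixture must be a probability vector", {
  expect_error(simulation_config(class_mixture = c(BHE = 0.9, HEB_P = 0.2,
                                                   HEB_A = 0, MGE_P = 0,
                                                   MGE_A = 0)),
               "sum to 1")
})

test_that("decoy sites each violate exactly one acceptance criterion", {
  sim <- simulate_complex(simulation_config(n_transcripts = 20, seed = 9))
  dec <- emit_decoy_sites(sim$counts, per_criterion = 1)
  expect_equal(nrow(dec$truth), 4)
  expect_setequal(dec$truth$criterion,
                  c("quality", "depth", "spacing", "border"))
  crit <- snv_filter_criteria()
  for (i in seq_len(nrow(dec$truth))) {
    rows <- dplyr::filter(dec$counts,
                          transcript_id == dec$truth$transcript_id[i],
                          pos == dec$truth$pos[i])
    depths <- rowSums(rows[paste0("count_", c("A", "C", "G", "T"))])
    qual_bad <- rows$consensus_quality[1] < crit$min_consensus_quality
    depth_bad <- any(depths > 0 & depths < crit$min_depth)
    border_bad <- min(rows$pos[1] - 1,
                      rows$transcript_length[1] - rows$pos[1]) <=
      crit$min_border_distance
    expected <- c(quality = qual_bad, depth = depth_bad,
                  border = border_bad)
    if (dec$truth$criterion[i] %in% names(expected)) {
      expect_true(expected[[dec$truth$criterion[i]]])
      expect_equal(sum(expected), 1)
    } else {
      # spacing decoy: clean on the pointwise rules, too close to a
      # clean site on the same transcript
      expect_equal(sum(expected), 0)
      near <- dplyr::filter(
        dplyr::distinct(sim$counts, transcript_id, pos),
        transcript_id == dec$truth$transcript_id[i])
      expect_lt(min(abs(near$pos - dec$truth$pos[i])), crit$min_spacing)
    }
  }
  # zero decoys requested -> empty
  none <- emit_decoy_sites(sim$counts, per_criterion = 0)
  expect_equal(nrow(none$counts), 0)
})
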