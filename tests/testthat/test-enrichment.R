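test_that("MGE groups pool by tissue and by ploidy with union semantics", {
  meta <- tibble::tibble(
    library_id = c("liv-PA", "liv-PAA", "juv-PA", "juv-PAA"),
    genomotype = c("PA", "PAA", "PA", "PAA"),
    tissue = c("liver", "liver", "juvenile", "juvenile"),
    ploidy = c(2L, 3L, 2L, 3L),
    use_for_bias = FALSE
  )
  calls <- tibble::tibble(
    library_id = c("liv-PA", "juv-PA", "juv-PAA", "liv-PAA"),
    transcript_id = c("T1", "T2", "T2", "T3"),
    f_A = c(0.02, 0.95, 0.95, 0.5),
    category = c("HEB_P", "HEB_A", "HEB_A", "BHE"),
    mge = c("MGE_P", "MGE_A", "MGE_A", "none")
  )
  g <- assemble_mge_groups(calls, meta)
  members <- function(id) g$transcript_id[g$group_id == id]
  expect_equal(members("liver_P"), "T1")    # MGE_P in liv-PA only
  expect_equal(members("PA_P"), "T1")
  expect_length(members("liver_A"), 0)
  expect_equal(members("juv_A"), "T2")      # MGE_A in both juvenile libraries
  expect_equal(members("PA_A"), "T2")
  expect_equal(members("PAA_A"), "T2")
  expect_length(members("PAA_P"), 0)

  # idempotent and order-independent
  g2 <- assemble_mge_groups(calls[sample(nrow(calls)), ], meta)
  expect_equal(g, g2)

  # no MGE calls anywhere -> all groups empty
  none <- dplyr::mutate(calls, mge = "none")
  expect_equal(nrow(assemble_mge_groups(none, meta)), 0)

  # a missing axis warns and leaves its groups empty
  expect_warning(assemble_mge_groups(calls, meta[1:2, ]), "juv")
})

test_that("hypergeometric enrichment on hand-enumerable cases", {
  ann <- tibble::tibble(
    transcript_id = c("T1", "T2"), term_id = "GO:1",
    namespace = "BP", description = "term one"
  )
  background <- c("T1", "T2", "T3", "T4")
  groups <- tibble::tibble(group_id = "liver_P",
                           transcript_id = c("T1", "T2"))
  res <- hypergeometric_enrichment(groups, background, ann)
  # both annotated transcripts drawn in a group of 2 from 4: p = 1/6
  expect_equal(res$p_value, 1 / 6)
  expect_equal(res$k, 2L)
  expect_equal(res$K, 2L)

  # term absent from the group: p = 1
  groups0 <- tibble::tibble(group_id = "liver_P",
                            transcript_id = c("T3", "T4"))
  expect_equal(hypergeometric_enrichment(groups0, background, ann)$p_value, 1)

  # group = background: nothing can be enriched
  groups_all <- tibble::tibble(group_id = "liver_P",
                               transcript_id = background)
  expect_true(all(
    hypergeometric_enrichment(groups_all, background, ann)$p_value == 1))

  expect_error(hypergeometric_enrichment(groups, character(0), ann),
               "empty")
  expect_error(
    hypergeometric_enrichment(
      tibble::tibble(group_id = "liver_P", transcript_id = "T9"),
      background, ann),
    "missing from the background")
})

test_that("enrichment p-values match subset enumeration for N <= 12", {
  set.seed(6)
  for (i in 1:40) {
    N <- sample(4:12, 1)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    background <- sprintf("T%02d", 1:N)
    ann <- tibble::tibble(transcript_id = background[1:K], term_id = "GO:1",
                          namespace = "BP", description = NA_character_)
    members <- sample(background, n)
    res <- hypergeometric_enrichment(
      tibble::tibble(group_id = "PA_P", transcript_id = members),
      background, ann)
    k <- sum(members %in% background[1:K])
    expect_equal(res$p_value, oracle_hyper_enum(k, K, n, N),
                 tolerance = 1e-9)
  }
})

test_that("the EASE variant is more conservative", {
  background <- sprintf("T%02d", 1:20)
  ann <- tibble::tibble(transcript_id = background[1:6], term_id = "GO:1",
                        namespace = "BP", description = NA_character_)
  groups <- tibble::tibble(group_id = "PA_P",
                           transcript_id = background[1:5])
  std <- hypergeometric_enrichment(groups, background, ann)
  ease <- hypergeometric_enrichment(groups, background, ann, ease = TRUE)
  expect_gt(ease$p_value, std$p_value)
})

test_that("a planted over-represented term is detected reliably", {
  set.seed(55)
  hits <- logical(20)
  for (r in seq_along(hits)) {
    N <- 500
    background <- sprintf("T%03d", 1:N)
    group <- sample(background, 40)
    in_group <- background %in% group
    # planted term: ~50% prevalence inside the group, ~10% outside
    planted <- runif(N) < ifelse(in_group, 0.5, 0.1)
    ann <- dplyr::bind_rows(
      tibble::tibble(transcript_id = background[planted],
                     term_id = "GO:planted", namespace = "BP",
                     description = NA_character_),
      # thirty null terms at 15% background prevalence
      purrr::map_dfr(1:30, function(j) {
        tibble::tibble(transcript_id = background[runif(N) < 0.15],
                       term_id = sprintf("GO:null%02d", j),
                       namespace = "BP", description = NA_character_)
      })
    )
    res <- hypergeometric_enrichment(
      tibble::tibble(group_id = "liver_P", transcript_id = group),
      background, ann)
    hits[r] <- res$p_adjusted[res$term_id == "GO:planted"] <= 0.05
  }
  expect_gte(mean(hits), 0.9)
})
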