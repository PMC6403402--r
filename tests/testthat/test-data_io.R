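test_that("count tables round-trip through the TSV dialect", {
  fix <- golden_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(fix$counts, path)
  back <- read_count_table(path, fix$meta)
  expect_equal(as.data.frame(back), as.data.frame(fix$counts))
  # import never alters counts
  expect_equal(sum(as.matrix(back[paste0("count_", c("A", "C", "G", "T"))])),
               sum(as.matrix(fix$counts[paste0("count_",
                                               c("A", "C", "G", "T"))])))
  # two writes are byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(fix$counts, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("randomised simulated counts survive write-then-read", {
  sim <- simulate_complex(simulation_config(n_transcripts = 30, seed = 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(sim$counts, path)
  back <- read_count_table(path, sim$meta)
  expect_equal(as.data.frame(back), as.data.frame(sim$counts))
})

test_that("malformed count tables are rejected with informative errors", {
  fix <- golden_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(fix$counts, path)

  # missing library columns
  expect_error(read_count_table(path, fix$meta[-5, ]),
               "absent from metadata")
  meta_extra <- dplyr::bind_rows(
    fix$meta,
    tibble::tibble(library_id = "ghost", genomotype = "PA",
                   tissue = "liver", ploidy = 2L, use_for_bias = FALSE))
  expect_error(read_count_table(path, meta_extra), "ghost")

  # negative count
  lines <- readLines(path)
  bad <- sub("\t15\t", "\t-1\t", lines[2])   # first base-count column
  writeLines(c(lines[1], bad, lines[-(1:2)]), path)
  expect_error(read_count_table(path, fix$meta), "negative")

  # duplicate (transcript, position)
  writeLines(c(lines, lines[2]), path)
  expect_error(read_count_table(path, fix$meta), "duplicate")
})

test_that("writing an empty collection yields a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  empty <- golden_fixture()$counts[0, ]
  write_count_table(empty, path)
  expect_length(readLines(path), 1)
})

test_that("library metadata invariants are enforced", {
  meta <- toy_meta()
  expect_silent(validate_library_meta(meta))
  bad <- meta; bad$ploidy[6] <- 2L
  expect_error(validate_library_meta(bad), "ploidy")
  bad <- meta; bad$use_for_bias[5] <- TRUE
  expect_error(validate_library_meta(bad), "use_for_bias")
  bad <- meta; bad$genomotype[1] <- "XX"
  expect_error(validate_library_meta(bad), "genomotype")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library_meta(meta, path)
  expect_equal(as.data.frame(read_library_meta(path)), as.data.frame(meta))
})

write_test_vcf <- function(path, extra_records = character()) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=TX1,length=500>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "TX1\t50\t.\tC\tT\t30\tPASS\t.\tGT:AD\t0/1:12,8",
    extra_records
  ), path)
}

test_that("VCF allele depths map to base counts; non-SNVs are skipped", {
  skip_if_not_installed("VariantAnnotation")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    "TX1\t100\t.\tCT\tC\t30\tPASS\t.\tGT:AD\t0/1:5,5",     # indel
    "TX1\t200\t.\tG\tA,T\t30\tPASS\t.\tGT:AD\t1/2:1,4,5"   # multiallelic
  ))
  counts <- suppressMessages(
    read_vcf_allele_depths(path, c("lib1" = "S1")))
  expect_equal(nrow(counts), 1)
  expect_equal(attr(counts, "n_skipped"), 2)
  expect_equal(counts$count_C, 12)
  expect_equal(counts$count_T, 8)
  expect_equal(counts$pos, 50L)
  expect_equal(counts$transcript_length, 500L)
  expect_error(read_vcf_allele_depths(path, c("lib1" = "nope")),
               "absent from VCF header")
})

test_that("VCF and the equivalent TSV give identical record collections", {
  skip_if_not_installed("VariantAnnotation")
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(vcf_path)
  from_vcf <- read_vcf_allele_depths(vcf_path, c("lib1" = "S1"))
  attr(from_vcf, "n_skipped") <- NULL

  meta <- tibble::tibble(library_id = "lib1", genomotype = "PA",
                         tissue = "liver", ploidy = 2L, use_for_bias = FALSE)
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tpos\tlength\tref\tqual\tlib1:A\tlib1:C\tlib1:G\tlib1:T",
               "TX1\t50\t500\tC\t30\t0\t12\t0\t8"), tsv_path)
  from_tsv <- read_count_table(tsv_path, meta)
  expect_equal(as.data.frame(from_vcf), as.data.frame(from_tsv))
})

test_that("annotation import deduplicates and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tterm_id\tnamespace",
               "T01\tGO:1\tBP",
               "T01\tGO:1\tBP",
               "T02\tGO:1\tBP",
               "T02\tGO:2\tCC",
               "T02\tGO:3\tMF"), path)
  ann <- read_annotation(path)
  expect_equal(nrow(ann), 4)
  expect_equal(sum(ann$transcript_id == "T02"), 3)

  # round-trip against a programmatically built map
  built <- tibble::tibble(
    transcript_id = c("T01", "T02", "T02", "T02"),
    term_id = c("GO:1", "GO:1", "GO:2", "GO:3"),
    namespace = c("BP", "BP", "CC", "MF"),
    description = NA_character_
  )
  expect_equal(as.data.frame(ann), as.data.frame(built))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("transcript_id\tterm_id", empty)
  expect_error(read_annotation(empty), "empty")
})
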