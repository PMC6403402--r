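#' Configuration for the allele-count simulator
#'
#' Describes a synthetic allopolyploid RNA-seq experiment: parental (PP and
#' AA) libraries fixed for their own variant at inter-genomic sites, hybrid
#' libraries drawing reads from both genomes, a multiplicative
#' reference-mapping bias, and transcript-level true A-genome fractions from
#' a mixture of balanced / biased / silenced classes.
#'
#' Defaults follow the study design this generator emulates: 5 PP and 4 AA
#' parental libraries, one diploid (PA) and one triploid (PAA) hybrid
#' library, about 2.5 diagnostic sites per quantified transcript, and a
#' class mixture matching the published diploid liver proportions (68%
#' balanced, 12% silenced for A, 3% silenced for P, remainder biased but not
#' silenced). Read depth per site and library is negative binomial to mimic
#' RNA-seq overdispersion. The reference bias default of 1.2 is a plausible
#' placeholder magnitude: the original analysis reports the existence and
#' correction of the bias but never its size.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param transcript_length_mean Mean transcript length (bp); lengths are
#'   gamma-distributed with shape 4 and floored at 60 bp.
#' @param sites_per_transcript_mean Expected diagnostic SNVs per transcript;
#'   at least one site is always placed.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth mean and
#'   size parameter per site per library.
#' @param class_mixture Named probabilities for classes BHE, HEB_P, HEB_A,
#'   MGE_P, MGE_A; must sum to 1.
#' @param class_theta Named list of Beta shape pairs; the true A fraction of
#'   a class is drawn from this Beta rescaled to the class's `f_A` interval
#'   at the library's ploidy (see [class_interval()]).
#' @param reference_bias Multiplicative mapping-efficiency factor `b > 0`
#'   favouring reads that carry the assembly reference base.
#' @param ref_is_A_prob Probability that the assembly reference base at a
#'   site equals the A-genome variant.
#' @param parental_het_rate Per-site, per-parental-library probability of an
#'   intragenomic heterozygous site (true allele ratio 1:1, distorted only
#'   by the reference bias); these sites calibrate the bias correction.
#' @param n_PP_libs,n_AA_libs Numbers of parental libraries.
#' @param hybrids Tibble describing hybrid libraries to emit, with columns
#'   `library_id`, `genomotype` (PA or PAA) and `tissue`.
#' @param consensus_quality_mean Mean phred-like site consensus quality
#'   (drawn as 20 + Poisson(mean - 20), so clean sites pass the >= 20
#'   filter).
#' @param decoys_per_criterion Number of filter-violating decoy sites to add
#'   per criterion (see [emit_decoy_sites()]).
#' @param classifier [classifier_config()] defining the class geometry.
#' @param seed Integer seed; a fixed seed makes [simulate_complex()] output
#'   byte-identical across calls.
#' @return An object of class `heb_sim_config` (a validated list).
#' @export
simulation_config <- function(n_transcripts = 500,
                              transcript_length_mean = 1000,
                              sites_per_transcript_mean = 2.5,
                              depth_mean = 50,
                              depth_dispersion = 5,
                              class_mixture = c(BHE = 0.68, HEB_P = 0.11,
                                                HEB_A = 0.06, MGE_P = 0.12,
                                                MGE_A = 0.03),
                              class_theta = list(BHE = c(5, 5),
                                                 HEB_P = c(5, 5),
                                                 HEB_A = c(5, 5),
                                                 MGE_P = c(2, 8),
                                                 MGE_A = c(8, 2)),
                              reference_bias = 1.2,
                              ref_is_A_prob = 0.5,
                              parental_het_rate = 0.05,
                              n_PP_libs = 5,
                              n_AA_libs = 4,
                              hybrids = tibble(
                                library_id = c("hyb-PA", "hyb-PAA"),
                                genomotype = c("PA", "PAA"),
                                tissue = "synthetic"
                              ),
                              consensus_quality_mean = 40,
                              decoys_per_criterion = 0,
                              classifier = classifier_config(),
                              seed = 1L) {
  classes <- c("BHE", "HEB_P", "HEB_A", "MGE_P", "MGE_A")
  if (!setequal(names(class_mixture), classes)) {
    abort("class_mixture must be named with BHE, HEB_P, HEB_A, MGE_P, MGE_A")
  }
  class_mixture <- class_mixture[classes]
  if (abs(sum(class_mixture) - 1) > 1e-12) {
    abort("class_mixture must sum to 1")
  }
  if (any(class_mixture < 0)) abort("class_mixture must be non-negative")
  if (!setequal(names(class_theta), classes)) {
    abort("class_theta must be named with BHE, HEB_P, HEB_A, MGE_P, MGE_A")
  }
  if (reference_bias <= 0) abort("reference_bias must be > 0")
  if (ref_is_A_prob < 0 || ref_is_A_prob > 1) {
    abort("ref_is_A_prob must lie in [0, 1]")
  }
  if (parental_het_rate < 0 || parental_het_rate > 1) {
    abort("parental_het_rate must lie in [0, 1]")
  }
  hybrids <- as_tibble(hybrids)
  if (nrow(hybrids) > 0 &&
      !all(hybrids$genomotype %in% HYBRID_GENOMOTYPES)) {
    abort("hybrid genomotypes must be PA or PAA")
  }
  if (consensus_quality_mean < 20) {
    abort("consensus_quality_mean must be >= 20 so clean sites pass filters")
  }
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         transcript_length_mean = transcript_length_mean,
         sites_per_transcript_mean = sites_per_transcript_mean,
         depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         class_mixture = class_mixture,
         class_theta = class_theta[classes],
         reference_bias = reference_bias,
         ref_is_A_prob = ref_is_A_prob,
         parental_het_rate = parental_het_rate,
         n_PP_libs = as.integer(n_PP_libs),
         n_AA_libs = as.integer(n_AA_libs),
         hybrids = hybrids,
         consensus_quality_mean = consensus_quality_mean,
         decoys_per_criterion = as.integer(decoys_per_criterion),
         classifier = classifier,
         seed = as.integer(seed)),
    class = "heb_sim_config"
  )
}

#' Simulate allele counts at one or more sites
#'
#' Draws P- and A-assigned read counts at diagnostic sites under a
#' multiplicative reference-mapping bias. Reads are binomial with an
#' effective A probability of `theta * b / (theta * b + (1 - theta))` when
#' the assembly reference base is the A variant, and
#' `theta / (theta + (1 - theta) * b)` when it is the P variant: reads
#' carrying the reference base map with efficiency multiplied by `b`.
#'
#' @param theta_A True A-genome expression fraction(s) in \[0, 1\].
#' @param depth Total read depth(s), non-negative integers.
#' @param b Reference-bias factor (> 0).
#' @param ref_is_A Logical; whether the reference base is the A variant
#'   (recycled).
#' @return A tibble with columns `reads_P` and `reads_A`
#'   (`reads_P + reads_A == depth` row-wise).
#' @export
#' @examples
#' set.seed(1)
#' simulate_site_counts(0.5, depth = 100, b = 2, ref_is_A = TRUE)
simulate_site_counts <- function(theta_A, depth, b = 1, ref_is_A = TRUE) {
  if (any(theta_A < 0 | theta_A > 1)) abort("theta_A must lie in [0, 1]")
  if (b <= 0) abort("b must be > 0")
  if (any(depth < 0)) abort("depth must be >= 0")
  n <- max(length(theta_A), length(depth), length(ref_is_A))
  theta_A <- rep_len(theta_A, n)
  depth <- rep_len(as.integer(depth), n)
  ref_is_A <- rep_len(ref_is_A, n)
  p_A <- ifelse(ref_is_A,
                theta_A * b / (theta_A * b + (1 - theta_A)),
                theta_A / (theta_A + (1 - theta_A) * b))
  reads_A <- rbinom(n, depth, p_A)
  tibble(reads_P = depth - reads_A, reads_A = reads_A)
}

# draw a true A fraction inside the class interval for a ploidy;
# degenerate intervals (triploid HEB_A at defaults) collapse to a point
draw_theta <- function(class, ploidy, config) {
  iv <- class_interval(class, ploidy, config$classifier)
  if (iv[1] == iv[2]) return(iv[1])
  shape <- config$class_theta[[class]]
  iv[1] + (iv[2] - iv[1]) * rbeta(1, shape[1], shape[2])
}

# pick a base different from `not` (vectorised over nothing; scalar)
other_base <- function(not) {
  sample(setdiff(BASES, not), 1)
}

#' Simulate a full parental-plus-hybrid allele-count experiment
#'
#' Generates per-site allele counts for all configured libraries together
#' with the ground truth needed to score every downstream stage. Parental
#' libraries are homozygous for their own genome's variant at inter-genomic
#' sites, except where an intragenomic heterozygous site is drawn (allele
#' ratio 1:1 distorted only by the reference bias; these are the sites the
#' bias correction is calibrated on, and they disqualify the position as a
#' diagnostic SNP). Hybrid libraries draw counts from the transcript's true
#' A fraction at the library's ploidy. Site positions respect the filter
#' geometry (spacing >= 5 bp, border distance > 5 bp) so that, with decoys
#' disabled, every emitted non-het site is recoverable as diagnostic.
#'
#' @param config A [simulation_config()].
#' @return A list of class `heb_simulation` with elements
#'   \describe{
#'     \item{counts}{long-format count tibble (see [read_count_table()])}
#'     \item{meta}{library metadata tibble}
#'     \item{truth}{list with `transcripts` (class label and true theta per
#'       ploidy), `sites` (variant bases, reference assignment, decoy flag,
#'       diagnostic status), `het_sites` (which parental library is
#'       heterozygous where) and `b` (the simulated reference bias)}
#'   }
#' @export
simulate_complex <- function(config = simulation_config()) {
  if (!inherits(config, "heb_sim_config")) {
    abort("config must come from simulation_config()")
  }
  set.seed(config$seed)
  meta <- dplyr::bind_rows(
    tibble(library_id = sprintf("PP-%d", seq_len(config$n_PP_libs)),
           genomotype = "PP", tissue = "synthetic", ploidy = 2L,
           use_for_bias = TRUE),
    tibble(library_id = sprintf("AA-%d", seq_len(config$n_AA_libs)),
           genomotype = "AA", tissue = "synthetic", ploidy = 2L,
           use_for_bias = TRUE),
    tibble(library_id = config$hybrids$library_id,
           genomotype = config$hybrids$genomotype,
           tissue = config$hybrids$tissue,
           ploidy = ifelse(config$hybrids$genomotype == "PAA", 3L, 2L),
           use_for_bias = FALSE)
  )
  meta <- validate_library_meta(meta)
  empty_truth <- list(
    transcripts = tibble(transcript_id = character(), class = character(),
                         theta_diploid = numeric(),
                         theta_triploid = numeric()),
    sites = tibble(transcript_id = character(), pos = integer(),
                   p_base = character(), a_base = character(),
                   ref_is_A = logical(), is_diagnostic = logical(),
                   decoy = character()),
    het_sites = tibble(transcript_id = character(), pos = integer(),
                       library_id = character()),
    b = config$reference_bias
  )
  if (config$n_transcripts == 0) {
    out <- list(counts = empty_counts(), meta = meta, truth = empty_truth,
                config = config)
    class(out) <- "heb_simulation"
    return(out)
  }

  classes <- sample(names(config$class_mixture), config$n_transcripts,
                    replace = TRUE, prob = config$class_mixture)
  lengths <- pmax(60L, as.integer(round(
    rgamma(config$n_transcripts, shape = 4,
           scale = config$transcript_length_mean / 4))))
  transcripts <- tibble(
    transcript_id = sprintf("TX%05d", seq_len(config$n_transcripts)),
    transcript_length = lengths,
    class = classes,
    theta_diploid = vapply(classes, draw_theta, 0, ploidy = 2L,
                           config = config),
    theta_triploid = vapply(classes, draw_theta, 0, ploidy = 3L,
                            config = config)
  )

  # place sites: uniform draw on the admissible grid, then stretched so
  # consecutive sites sit >= 5 bp apart and > 5 bp from both borders
  site_list <- purrr::pmap(
    list(transcripts$transcript_id, transcripts$transcript_length),
    function(tx, len) {
      k <- 1L + rpois(1, max(config$sites_per_transcript_mean - 1, 0))
      span <- (len - 6L) - 7L          # admissible positions 7 .. len - 6
      k <- min(k, span %/% 5L + 1L)
      if (k < 1L) return(NULL)
      slack <- span - (k - 1L) * 5L
      offsets <- sort(sample.int(slack + 1L, k, replace = FALSE) - 1L)
      pos <- 7L + offsets + (seq_len(k) - 1L) * 5L
      p_base <- sample(BASES, k, replace = TRUE)
      a_base <- vapply(p_base, other_base, "")
      tibble(transcript_id = tx, pos = pos, p_base = p_base,
             a_base = unname(a_base),
             ref_is_A = runif(k) < config$ref_is_A_prob)
    }
  )
  sites <- dplyr::bind_rows(site_list)
  sites$ref_base <- ifelse(sites$ref_is_A, sites$a_base, sites$p_base)
  sites$consensus_quality <- 20 + rpois(nrow(sites),
                                        config$consensus_quality_mean - 20)
  sites <- dplyr::left_join(
    sites,
    dplyr::select(transcripts, "transcript_id", "transcript_length",
                  "class", "theta_diploid", "theta_triploid"),
    by = "transcript_id"
  )

  b <- config$reference_bias
  n_sites <- nrow(sites)
  parental <- dplyr::filter(meta, .data$genomotype %in% c("PP", "AA"))
  hybrid <- dplyr::filter(meta, .data$genomotype %in% HYBRID_GENOMOTYPES)

  lib_blocks <- vector("list", nrow(meta))
  het_blocks <- list()
  for (j in seq_len(nrow(parental))) {
    lib <- parental$library_id[j]
    own <- if (parental$genomotype[j] == "PP") sites$p_base else sites$a_base
    depth <- rnbinom(n_sites, mu = config$depth_mean,
                     size = config$depth_dispersion)
    het <- runif(n_sites) < config$parental_het_rate & depth > 0
    mat <- matrix(0L, nrow = n_sites, ncol = 4, dimnames = list(NULL, BASES))
    fixed_idx <- which(!het)
    mat[cbind(fixed_idx, match(own[fixed_idx], BASES))] <- depth[fixed_idx]
    if (any(het)) {
      # het alleles are the assembly reference base plus one alternate:
      # the library's own variant when it differs from the reference,
      # otherwise the other genome's variant
      hi <- which(het)
      ref_b <- sites$ref_base[hi]
      alt_b <- ifelse(own[hi] != ref_b, own[hi],
                      ifelse(sites$p_base[hi] != ref_b, sites$p_base[hi],
                             sites$a_base[hi]))
      ref_reads <- rbinom(length(hi), depth[hi], b / (1 + b))
      mat[cbind(hi, match(ref_b, BASES))] <- ref_reads
      mat[cbind(hi, match(alt_b, BASES))] <-
        mat[cbind(hi, match(alt_b, BASES))] + (depth[hi] - ref_reads)
      het_blocks[[length(het_blocks) + 1]] <-
        tibble(transcript_id = sites$transcript_id[hi],
               pos = sites$pos[hi], library_id = lib)
    }
    lib_blocks[[j]] <- tibble(
      transcript_id = sites$transcript_id, pos = sites$pos,
      transcript_length = sites$transcript_length,
      ref_base = sites$ref_base,
      consensus_quality = sites$consensus_quality,
      library_id = lib,
      count_A = mat[, "A"], count_C = mat[, "C"],
      count_G = mat[, "G"], count_T = mat[, "T"]
    )
  }
  for (j in seq_len(nrow(hybrid))) {
    lib <- hybrid$library_id[j]
    theta <- if (hybrid$ploidy[j] == 3L) sites$theta_triploid
             else sites$theta_diploid
    depth <- rnbinom(n_sites, mu = config$depth_mean,
                     size = config$depth_dispersion)
    draws <- simulate_site_counts(theta, depth, b, sites$ref_is_A)
    mat <- matrix(0L, nrow = n_sites, ncol = 4, dimnames = list(NULL, BASES))
    mat[cbind(seq_len(n_sites), match(sites$p_base, BASES))] <- draws$reads_P
    mat[cbind(seq_len(n_sites), match(sites$a_base, BASES))] <-
      mat[cbind(seq_len(n_sites), match(sites$a_base, BASES))] + draws$reads_A
    lib_blocks[[nrow(parental) + j]] <- tibble(
      transcript_id = sites$transcript_id, pos = sites$pos,
      transcript_length = sites$transcript_length,
      ref_base = sites$ref_base,
      consensus_quality = sites$consensus_quality,
      library_id = lib,
      count_A = mat[, "A"], count_C = mat[, "C"],
      count_G = mat[, "G"], count_T = mat[, "T"]
    )
  }
  counts <- dplyr::bind_rows(lib_blocks)
  het_sites <- if (length(het_blocks) > 0) {
    dplyr::arrange(dplyr::bind_rows(het_blocks), .data$transcript_id,
                   .data$pos, .data$library_id)
  } else {
    empty_truth$het_sites
  }

  truth_sites <- sites %>%
    dplyr::mutate(is_diagnostic = !(paste(.data$transcript_id, .data$pos) %in%
                                      paste(het_sites$transcript_id,
                                            het_sites$pos)),
                  decoy = NA_character_) %>%
    dplyr::select("transcript_id", "pos", "p_base", "a_base", "ref_is_A",
                  "is_diagnostic", "decoy")

  if (config$decoys_per_criterion > 0) {
    dec <- emit_decoy_sites(counts, per_criterion =
                              config$decoys_per_criterion)
    counts <- dplyr::bind_rows(counts, dec$counts)
    truth_sites <- dplyr::bind_rows(
      truth_sites,
      dplyr::mutate(dec$truth, p_base = NA_character_,
                    a_base = NA_character_, ref_is_A = NA,
                    is_diagnostic = FALSE)
    )
  }

  counts <- dplyr::arrange(counts, .data$transcript_id, .data$pos,
                           .data$library_id)
  counts <- validate_counts(counts)
  truth_sites <- dplyr::arrange(truth_sites, .data$transcript_id, .data$pos)

  out <- list(
    counts = counts,
    meta = meta,
    truth = list(
      transcripts = dplyr::select(transcripts, "transcript_id", "class",
                                  "theta_diploid", "theta_triploid"),
      sites = truth_sites,
      het_sites = het_sites,
      b = b
    ),
    config = config
  )
  class(out) <- "heb_simulation"
  out
}

empty_counts <- function() {
  tibble(transcript_id = character(), pos = integer(),
         transcript_length = integer(), ref_base = character(),
         consensus_quality = numeric(), library_id = character(),
         count_A = integer(), count_C = integer(), count_G = integer(),
         count_T = integer())
}

#' @export
print.heb_simulation <- function(x, ...) {
  cat("Synthetic homoeolog-expression experiment\n")
  cat(sprintf("  %d transcripts, %d sites, %d libraries (bias b = %.3g)\n",
              nrow(x$truth$transcripts),
              nrow(x$truth$sites), nrow(x$meta), x$truth$b))
  invisible(x)
}

#' Emit filter-violating decoy sites
#'
#' Constructs sites that each violate exactly one SNV acceptance criterion —
#' consensus quality below threshold, read depth below threshold in one
#' library, spacing closer than the minimum to an existing site, or position
#' within the forbidden border zone — while satisfying all the others.
#' Appended to a clean count table, they exercise [call_candidate_sites()]:
#' the filter must remove exactly the decoys.
#'
#' @param counts A clean long-format count tibble to attach decoys to.
#' @param per_criterion Number of decoys per criterion.
#' @param criteria Character subset of
#'   `c("quality", "depth", "spacing", "border")`.
#' @param filter [snv_filter_criteria()] the decoys should violate.
#' @return A list with `counts` (decoy rows, same layout as `counts`) and
#'   `truth` (tibble `transcript_id`, `pos`, `criterion`).
#' @export
emit_decoy_sites <- function(counts, per_criterion = 1,
                             criteria = c("quality", "depth", "spacing",
                                          "border"),
                             filter = snv_filter_criteria()) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (per_criterion == 0 || length(criteria) == 0) {
    return(list(counts = empty_counts(),
                truth = tibble(transcript_id = character(), pos = integer(),
                               criterion = character())))
  }
  counts <- validate_counts(counts)
  if (nrow(counts) == 0) abort("need a non-empty clean count table")
  libs <- sort(unique(counts$library_id))
  sites <- dplyr::distinct(counts, .data$transcript_id, .data$pos,
                           .data$transcript_length)
  good_depth <- max(filter$min_depth, 20)

  decoy_rows <- list()
  truth_rows <- list()
  used <- paste(counts$transcript_id, counts$pos)

  make_site <- function(tx, pos, len, qual, shallow_lib = NULL) {
    depth <- ifelse(libs %in% shallow_lib, filter$min_depth - 1, good_depth)
    tibble(transcript_id = tx, pos = as.integer(pos),
           transcript_length = as.integer(len), ref_base = "A",
           consensus_quality = qual, library_id = libs,
           count_A = as.integer(depth), count_C = 0L, count_G = 0L,
           count_T = 0L)
  }
  # a position respecting every rule relative to already-used positions
  free_pos <- function(tx, len, min_gap) {
    taken <- counts$pos[counts$transcript_id == tx]
    extra <- vapply(truth_rows, function(t)
      if (t$transcript_id[1] == tx) t$pos[1] else NA_integer_, 0L)
    taken <- c(taken, extra[!is.na(extra)])
    cand <- setdiff(seq(filter$min_border_distance + 2L,
                        len - filter$min_border_distance - 1L), taken)
    cand <- cand[vapply(cand, function(p) all(abs(p - taken) >= min_gap),
                        TRUE)]
    if (length(cand) == 0) NA_integer_ else cand[1]
  }

  for (crit in criteria) {
    for (i in seq_len(per_criterion)) {
      placed <- FALSE
      for (s in seq_len(nrow(sites))) {
        tx <- sites$transcript_id[s]
        len <- sites$transcript_length[s]
        ok_q <- filter$min_consensus_quality + 10
        row <- switch(crit,
          quality = {
            p <- free_pos(tx, len, filter$min_spacing)
            if (!is.na(p))
              make_site(tx, p, len, filter$min_consensus_quality - 1)
          },
          depth = {
            p <- free_pos(tx, len, filter$min_spacing)
            if (!is.na(p))
              make_site(tx, p, len, ok_q, shallow_lib = libs[1])
          },
          spacing = {
            anchor <- sites$pos[s]
            p <- anchor + filter$min_spacing - 2L
            ok <- p <= len - filter$min_border_distance - 1L &&
              !(paste(tx, p) %in% used)
            if (ok) make_site(tx, p, len, ok_q)
          },
          border = {
            p <- filter$min_border_distance - 2L
            taken <- counts$pos[counts$transcript_id == tx]
            ok <- p >= 1 && !(paste(tx, p) %in% used) &&
              all(abs(p - taken) >= filter$min_spacing)
            if (ok) make_site(tx, p, len, ok_q)
          }
        )
        if (!is.null(row)) {
          decoy_rows[[length(decoy_rows) + 1]] <- row
          truth_rows[[length(truth_rows) + 1]] <-
            tibble(transcript_id = tx, pos = row$pos[1], criterion = crit)
          used <- c(used, paste(tx, row$pos[1]))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0("could not place a '", crit, "' decoy in the fixture"))
      }
    }
  }
  list(counts = dplyr::bind_rows(decoy_rows),
       truth = dplyr::bind_rows(truth_rows))
}

#' Write a simulated experiment to disk
#'
#' Writes `counts.tsv` (project count dialect), `meta.tsv`,
#' `truth_transcripts.tsv`, `truth_sites.tsv` and `truth_het_sites.tsv`
#' under `dir`.
#'
#' @param sim A [simulate_complex()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!inherits(sim, "heb_simulation")) {
    abort("sim must come from simulate_complex()")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  write_library_meta(sim$meta, file.path(dir, "meta.tsv"))
  readr::write_tsv(sim$truth$transcripts,
                   file.path(dir, "truth_transcripts.tsv"))
  readr::write_tsv(sim$truth$sites, file.path(dir, "truth_sites.tsv"))
  readr::write_tsv(sim$truth$het_sites,
                   file.path(dir, "truth_het_sites.tsv"))
  invisible(dir)
}
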