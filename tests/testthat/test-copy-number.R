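make_bins <- function(values, chrom = "chr1", width = 10) {
  tibble::tibble(
    chromosome = chrom,
    start = (seq_along(values) - 1) * width,
    end = seq_along(values) * width,
    log2_ratio = values
  )
}

test_that("reference normalization is bin-wise subtraction", {
  p <- make_bins(c(0.6, 0.6))
  r <- make_bins(c(0.1, 0.2))
  expect_equal(normalize_to_reference(p, r)$log2_ratio, c(0.5, 0.4))
  expect_equal(normalize_to_reference(p, p)$log2_ratio, c(0, 0))
  expect_equal(normalize_to_reference(p, make_bins(c(0, 0)))$log2_ratio,
               p$log2_ratio)
  expect_error(normalize_to_reference(p, make_bins(c(0, 0, 0))), "grid")
})

seg_row <- function(chrom, start, end, mean, sample = "S1") {
  tibble::tibble(sample_id = sample, chromosome = chrom, start = start,
                 end = end, n_bins = 1L, seg_mean = mean, seg_median = mean)
}

test_that("arm calls follow the threshold and coverage rules", {
  gn <- make_genome(1, 2, seed = 1)
  p_arm <- gn$arms[gn$arms$arm == "p", ]

  full_gain <- seg_row("chr1", 0, gn$chrom_lengths[["chr1"]], 0.25)
  calls <- suppressWarnings(call_arm_events(full_gain, gn))
  expect_equal(calls$direction[calls$arm == "p"], "gain")

  below <- seg_row("chr1", 0, gn$chrom_lengths[["chr1"]], 0.15)
  expect_equal(suppressWarnings(call_arm_events(below, gn))$direction,
               c("neutral", "neutral"))

  # gain covering exactly 70% of the p arm stays neutral (0.70 <= 0.75)
  partial <- dplyr::bind_rows(
    seg_row("chr1", p_arm$start, floor(0.7 * p_arm$end), 0.4),
    seg_row("chr1", floor(0.7 * p_arm$end), gn$chrom_lengths[["chr1"]], 0)
  )
  part_calls <- call_arm_events(partial, gn)
  p_row <- part_calls[part_calls$arm == "p", ]
  expect_equal(p_row$direction, "neutral")
  expect_equal(p_row$altered_fraction, 0.7, tolerance = 1e-6)
})

test_that("aneuploidy score counts non-neutral autosomal arms", {
  calls <- tibble::tibble(
    sample_id = "S1",
    chromosome = c("chr1", "chr1", "chr2", "chr2", "chrX"),
    arm = c("p", "q", "p", "q", "p"),
    altered_fraction = c(1, 1, 1, 0, 1),
    direction = c("gain", "loss", "gain", "neutral", "gain")
  )
  expect_equal(aneuploidy_score(calls)$as, 3L)
  expect_equal(aneuploidy_score(calls, autosomes_only = FALSE)$as, 4L)
  neutral <- dplyr::mutate(calls, direction = "neutral")
  expect_equal(aneuploidy_score(neutral)$as, 0L)
})

test_that("raising the log2 threshold never increases the aneuploidy score", {
  gn <- make_genome(4, 5, seed = 8)
  kt <- karyotype(gn, c(chr1p = 3, chr2q = 1, chr3p = 4))
  bins <- simulate_binned_profile(kt, gn, noise_sd = 0.15, seed = 3)
  prof <- segment_profile(bins, n_perm = 200, seed = 4)
  thresholds <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  scores <- purrr::map_int(thresholds, function(th) {
    suppressWarnings(
      aneuploidy_score(call_arm_events(prof, gn, log2_threshold = th))$as
    )
  })
  expect_true(all(diff(scores) <= 0))
})

test_that("the WGD filter retains only samples strictly below the cutoff", {
  rec <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                        ploidy = c(3.9, 2.0, 2.5, NA))
  expect_warning(kept <- filter_wgd(rec), "without ploidy")
  expect_equal(kept, "b")
})

test_that("total relative DNA evaluates the rounding heuristic", {
  zero <- seg_row("chr1", 0, 5e6, 0)
  expect_equal(total_relative_dna(zero)$total_relative_dna, 0)

  tri <- seg_row("chr1", 0, 1e6, log2(3 / 2))
  expect_equal(total_relative_dna(tri)$total_relative_dna, 1e6)

  mixed <- dplyr::bind_rows(
    seg_row("chr1", 0, 2e6, log2(3 / 2)),
    seg_row("chr1", 2e6, 3e6, -1)
  )
  expect_equal(total_relative_dna(mixed, signed = TRUE)$total_relative_dna, 1e6)
  expect_equal(total_relative_dna(mixed)$total_relative_dna, 3e6)

  # sex chromosomes never contribute
  with_x <- dplyr::bind_rows(tri, seg_row("chrX", 0, 1e6, 1))
  expect_equal(total_relative_dna(with_x)$total_relative_dna, 1e6)
})

test_that("total relative DNA matches planted karyotypes without noise", {
  gn <- make_genome(3, 4, seed = 2)
  kt <- karyotype(gn, c(chr1p = 3, chr3q = 1))
  bins <- simulate_binned_profile(kt, gn, noise_sd = 0, seed = 1)
  prof <- segment_profile(bins, n_perm = 200, seed = 2)
  arm_len <- function(lab) {
    a <- gn$arms[paste0(gn$arms$chromosome, gn$arms$arm) == lab, ]
    a$end - a$start
  }
  truth <- arm_len("chr1p") + arm_len("chr3q")
  expect_equal(total_relative_dna(prof)$total_relative_dna, truth)
})
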