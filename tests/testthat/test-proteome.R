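small_annotations <- function(n_per_group = 3) {
  tidyr::expand_grid(line_id = c("WT", "Ts"), replicate = seq_len(n_per_group)) |>
    dplyr::mutate(sample_id = paste0(line_id, "_r", replicate),
                  passage = 0L, batch = paste0("b", replicate))
}

test_that("preprocessing removes flagged rows and planted batch offsets", {
  ann <- small_annotations()
  set.seed(2)
  vals <- matrix(2^rnorm(5 * 6, 20, 1), nrow = 5)
  raw <- tibble::as_tibble(vals, .name_repair = ~ann$sample_id) |>
    dplyr::mutate(protein_id = paste0("p", 1:5),
                  contaminant = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                  .before = 1)
  im <- preprocess_intensities(raw, ann)
  expect_false("p1" %in% rownames(im$log2))
  expect_equal(nrow(im$log2), 4)

  # two batches, exact planted offset: removed to numerical precision
  ann2 <- small_annotations(4) |>
    dplyr::mutate(batch = rep(c("b1", "b2"), 4))
  base <- matrix(rnorm(6 * 8, 20, 1), nrow = 6)
  delta <- 0.7
  shifted <- base + rep(ifelse(ann2$batch == "b2", delta, 0), each = 6)
  raw2 <- tibble::as_tibble(2^shifted, .name_repair = ~ann2$sample_id) |>
    dplyr::mutate(protein_id = paste0("p", 1:6), .before = 1)
  im2 <- preprocess_intensities(raw2, ann2)
  b1 <- rowMeans(im2$log2[, ann2$sample_id[ann2$batch == "b1"]])
  b2 <- rowMeans(im2$log2[, ann2$sample_id[ann2$batch == "b2"]])
  expect_lt(max(abs(b1 - b2)), 1e-10)

  all_bad <- dplyr::mutate(raw, contaminant = TRUE)
  expect_error(preprocess_intensities(all_bad, ann), "filtered out")
})

test_that("moderated statistics behave at their limits", {
  set.seed(3)
  mat <- matrix(rnorm(200 * 6, 0, 0.3), nrow = 200,
                dimnames = list(paste0("p", 1:200), paste0("s", 1:6)))
  g1 <- paste0("s", 1:3); g2 <- paste0("s", 4:6)

  # identical groups: FC exactly 0, p exactly 1
  dup <- cbind(mat[, g1], mat[, g1])
  colnames(dup) <- paste0("s", 1:6)
  same <- moderated_diff_abundance(dup, g1, g2)
  expect_true(all(same$log2fc == 0))
  expect_true(all(same$p_value == 1))

  # d0 = 0 recovers the ordinary two-sample pooled t-statistic
  plain <- moderated_diff_abundance(mat, g1, g2, d0 = 0)
  oracle <- apply(mat, 1, function(v) {
    t.test(v[1:3], v[4:6], var.equal = TRUE)$statistic
  })
  expect_equal(plain$t, unname(oracle), tolerance = 1e-10)

  expect_error(moderated_diff_abundance(mat, "s1", g2), "2 replicates")
})

test_that("moderated statistics agree with the established empirical-Bayes fit", {
  set.seed(4)
  n <- 300
  mat <- matrix(rnorm(n * 6, 0, rep(exp(rnorm(n, -1, 0.4)), 6)), nrow = n,
                dimnames = list(paste0("p", 1:n), paste0("s", 1:6)))
  mat[1:30, 1:3] <- mat[1:30, 1:3] + 1
  ours <- moderated_diff_abundance(mat, paste0("s", 1:3), paste0("s", 4:6))

  design <- cbind(grp1 = rep(c(1, 0), each = 3), grp2 = rep(c(0, 1), each = 3))
  fit <- limma::lmFit(mat, design)
  fit <- limma::contrasts.fit(fit, c(1, -1))
  fit <- limma::eBayes(fit)
  expect_equal(ours$log2fc, unname(fit$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(ours$t, unname(fit$t[, 1]), tolerance = 1e-6)
  expect_equal(ours$p_value, unname(fit$p.value[, 1]), tolerance = 1e-6)
})

test_that("arm dosage compensation reproduces trivial geometries", {
  gn <- make_genome(1, 20, seed = 5)
  len <- gn$chrom_lengths[["chr1"]]
  dna <- tibble::tibble(sample_id = "S1", chromosome = "chr1", start = 0,
                        end = len, n_bins = 10L,
                        seg_mean = log2(3 / 2), seg_median = log2(3 / 2))
  fc_equal <- tibble::tibble(gene_id = gn$genes$gene_id, log2fc = log2(3 / 2))
  comp <- arm_dosage_compensation(dna, fc_equal, gn)
  expect_true(all(abs(comp$compensation) < 1e-12))

  fc_zero <- tibble::tibble(gene_id = gn$genes$gene_id, log2fc = 0)
  comp2 <- arm_dosage_compensation(dna, fc_zero, gn)
  expect_true(all(abs(comp2$compensation - log2(3 / 2)) < 1e-12))

  # arm without proteins is omitted with a warning
  fc_p_only <- dplyr::semi_join(fc_zero,
                                dplyr::filter(gn$genes, arm == "p"),
                                by = "gene_id")
  expect_warning(res <- arm_dosage_compensation(dna, fc_p_only, gn),
                 "no quantified proteins")
  expect_equal(res$arm, "p")
})

test_that("scaling classification detects true scaling and true buffering", {
  fx <- scaling_fixture(log2(3 / 2))
  res <- classify_arm_scaling(fx$deltas, fx$arm_gains, fx$gn)
  expect_gt(mean(res$class == "scaling"), 0.9)
  # true-scaling proteins almost never called non_scaling
  expect_lte(mean(res$class == "non_scaling"), 0.05)

  fx0 <- scaling_fixture(0, seed = 2)
  res0 <- classify_arm_scaling(fx0$deltas, fx0$arm_gains, fx0$gn)
  expect_gt(mean(res0$class == "non_scaling"), 0.9)
})

test_that("scaling classification gives up at hopeless sample sizes", {
  fx <- scaling_fixture(log2(3 / 2), n_side = 3, seed = 3)
  res <- classify_arm_scaling(fx$deltas, fx$arm_gains, fx$gn)
  expect_gt(mean(res$class == "unclassified"), 0.5)
})
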