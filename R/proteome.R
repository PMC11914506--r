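#' Preprocess a protein intensity matrix
#'
#' Applies the standard cleanup for multiplexed proteome quantifications:
#' rows flagged as contaminant, reverse hit or identified-by-site-only are
#' removed; rows with any missing (or non-positive, when log-transforming)
#' intensity are removed (complete cases); intensities are log2-transformed;
#' per-protein batch means are removed by least squares with the biological
#' design preserved; samples are then scale-normalized to a common median.
#'
#' @param raw Tibble with a `protein_id` column, optional logical flag
#'   columns `contaminant`, `reverse`, `site_only`, and one numeric column
#'   per sample.
#' @param annotations Tibble with columns `sample_id`, `line_id`, `passage`,
#'   `replicate`, `batch` covering all sample columns.
#' @param log2_transform Set to `FALSE` when `raw` is already on the log2
#'   scale.
#' @param reference_samples Optional sample ids whose per-protein median
#'   serves as the scaling reference (e.g. the parental line); by default
#'   all samples contribute.
#' @return An `intensity_matrix` object: list with `log2` (protein x sample
#'   matrix) and `samples` (the annotations).
#' @export
preprocess_intensities <- function(raw, annotations, log2_transform = TRUE,
                                   reference_samples = NULL) {
  if (!all(annotations$sample_id %in% names(raw))) {
    abort("Annotations must cover all sample columns of `raw`.")
  }
  for (fl in c("contaminant", "reverse", "site_only")) {
    if (fl %in% names(raw)) raw <- filter(raw, !(.data[[fl]] %in% TRUE))
  }
  mat <- as.matrix(raw[annotations$sample_id])
  rownames(mat) <- raw$protein_id
  if (log2_transform) {
    mat[mat <= 0] <- NA
    mat <- log2(mat)
  }
  mat <- mat[complete.cases(mat), , drop = FALSE]
  if (nrow(mat) == 0) abort("All protein groups were filtered out.")

  # per-sample scale normalization on the log2 scale via the median of
  # log-ratios to a per-protein reference (robust to a minority of genuinely
  # shifted proteins, e.g. a gained chromosome arm), then per-protein batch
  # cleaning (last, so batch means are removed exactly)
  ref_cols <- reference_samples %||% colnames(mat)
  ref <- apply(mat[, ref_cols, drop = FALSE], 1, median)
  offs <- apply(mat - ref, 2, median)
  mat <- sweep(mat, 2, offs - mean(offs))
  group <- interaction(annotations$line_id, annotations$passage, drop = TRUE)
  if (length(unique(annotations$batch)) > 1) {
    mat <- limma::removeBatchEffect(
      mat,
      batch = annotations$batch,
      design = model.matrix(~group)
    )
  }

  structure(list(log2 = mat, samples = annotations), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d samples (%d batches)\n",
              nrow(x$log2), ncol(x$log2), length(unique(x$samples$batch))))
  invisible(x)
}

# Newton solve of trigamma(y) = x (monotone decreasing), as used in the
# standard method-of-moments fit of the variance prior.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Method-of-moments estimate of the inverse-chisquare variance prior
# (d0, s0^2) from per-protein sample variances s2 on d residual df.
estimate_variance_prior <- function(s2, d, d0_cap = 1e6) {
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2) * n / (n - 1) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- min(2 * trigamma_inverse(evar), d0_cap)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- d0_cap
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated differential abundance between two sample groups
#'
#' Per protein: the log2 fold change is the mean difference between the two
#' groups; the residual variance is moderated toward a prior estimated from
#' all proteins by the method of moments
#' (`s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`), giving an empirical-Bayes
#' moderated t-statistic on `d0 + d` degrees of freedom, two-sided p-values
#' and Benjamini-Hochberg FDR.
#'
#' @param x An [preprocess_intensities()] result or a log2 matrix.
#' @param samples1,samples2 Column names of the two groups (>= 2 each);
#'   the fold change is group 1 minus group 2.
#' @param comparison Label stored in the output.
#' @param group Optional comparison-group label (e.g. `"G1"`).
#' @param d0 Override for the prior degrees of freedom (0 recovers the
#'   ordinary two-sample t-statistic; `NULL` estimates it from the data).
#' @return A `fold_change_table` tibble: gene_id, comparison, group,
#'   log2fc, t, df, p_value, fdr.
#' @export
moderated_diff_abundance <- function(x, samples1, samples2,
                                     comparison = "contrast", group = NA_character_,
                                     d0 = NULL) {
  mat <- if (inherits(x, "intensity_matrix")) x$log2 else as.matrix(x)
  miss <- setdiff(c(samples1, samples2), colnames(mat))
  if (length(miss)) abort(paste0("Unknown samples: ", paste(miss, collapse = ", ")))
  n1 <- length(samples1); n2 <- length(samples2)
  d <- n1 + n2 - 2
  if (n1 < 2 || n2 < 2) abort("At least 2 replicates per side are required.")
  m1 <- rowMeans(mat[, samples1, drop = FALSE])
  m2 <- rowMeans(mat[, samples2, drop = FALSE])
  v1 <- apply(mat[, samples1, drop = FALSE], 1, var)
  v2 <- apply(mat[, samples2, drop = FALSE], 1, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d

  if (is.null(d0)) {
    prior <- estimate_variance_prior(s2, d)
  } else {
    prior <- list(d0 = d0, s0_2 = if (d0 > 0) mean(s2) else 0)
  }
  s2_tilde <- (prior$d0 * prior$s0_2 + d * s2) / (prior$d0 + d)
  fc <- m1 - m2
  tstat <- fc / sqrt(s2_tilde * (1 / n1 + 1 / n2))
  df_total <- min(prior$d0 + d, 1e6)
  p <- 2 * pt(-abs(tstat), df = df_total)

  out <- tibble(
    gene_id = rownames(mat),
    comparison = comparison,
    group = group,
    log2fc = unname(fc),
    t = unname(tstat),
    df = df_total,
    p_value = unname(p),
    fdr = unname(bh_adjust(p))
  )
  new_result_tbl(out, "fold_change_table")
}

#' Differential abundance for a whole comparison design
#'
#' Convenience wrapper running [moderated_diff_abundance()] for every row of
#' a comparison table (as produced by [polysomy_design()]) against one
#' preprocessed intensity matrix.
#'
#' @param x An [preprocess_intensities()] result.
#' @param comparisons Tibble with columns `comparison`, `line_a`,
#'   `passage_a`, `line_b`, `passage_b`, `group`.
#' @param ... Passed to [moderated_diff_abundance()].
#' @return A `fold_change_table` tibble stacking all comparisons.
#' @export
diff_abundance_design <- function(x, comparisons, ...) {
  ann <- x$samples
  pick <- function(line, passage) {
    ann$sample_id[ann$line_id == line & ann$passage == passage]
  }
  out <- purrr::pmap(comparisons, function(comparison, line_a, passage_a,
                                           line_b, passage_b, group, ...) {
    moderated_diff_abundance(
      x,
      samples1 = pick(line_a, passage_a),
      samples2 = pick(line_b, passage_b),
      comparison = comparison, group = group
    )
  }) |> list_rbind()
  new_result_tbl(out, "fold_change_table")
}

#' Arm-level dosage compensation
#'
#' Dosage compensation per chromosome arm is the difference between the
#' average genomic log2 copy-number ratio of the arm and the average log2
#' protein abundance fold change of genes on that arm, both relative to the
#' same parental reference. 0 means protein fully scales with DNA; a value
#' equal to the DNA ratio means full buffering.
#'
#' @param dna_profile A [segment_profile()] result for the DNA, normalized
#'   to the parental line.
#' @param protein_fc Tibble with columns `gene_id`, `log2fc` (one
#'   comparison).
#' @param catalog A [make_genome()] catalog.
#' @param arms Optional character vector of arm labels (e.g. `"chr1p"`) to
#'   restrict to; default all arms.
#' @return A `compensation_table` tibble: chromosome, arm, dna_log2,
#'   protein_log2, compensation, n_proteins. Arms without proteins are
#'   omitted with a warning.
#' @export
arm_dosage_compensation <- function(dna_profile, protein_fc, catalog,
                                    arms = NULL) {
  fc <- inner_join(protein_fc, catalog$genes, by = "gene_id")
  tab <- purrr::pmap(catalog$arms, function(chromosome, arm, start, end) {
    lab <- paste0(chromosome, arm)
    if (!is.null(arms) && !lab %in% arms) return(NULL)
    segs <- filter(dna_profile, .data$chromosome == .env$chromosome)
    ov <- pmax(pmin(segs$end, end) - pmax(segs$start, start), 0)
    dna <- if (sum(ov) > 0) sum(segs$seg_mean * ov) / sum(ov) else NA_real_
    genes_on <- filter(fc, .data$chromosome == .env$chromosome, .data$arm == .env$arm)
    if (nrow(genes_on) == 0) {
      warn(sprintf("Arm %s has no quantified proteins; omitted.", lab))
      return(NULL)
    }
    prot <- mean(genes_on$log2fc)
    tibble(chromosome = chromosome, arm = arm, dna_log2 = dna,
           protein_log2 = prot, compensation = dna - prot,
           n_proteins = nrow(genes_on))
  }) |> list_rbind()
  new_result_tbl(tab, "compensation_table")
}

#' Classify proteins as scaling or not scaling with chromosome-arm gain
#'
#' Tumor-minus-normal abundance deltas are compared between tumors with and
#' without gain of the protein's encoding arm using Welch's t-tests. First a
#' one-sided test asks whether the mean difference is significantly lower
#' than the single-copy-gain expectation `log2(3/2)`; proteins significant
#' after Benjamini-Hochberg adjustment (FDR < `fdr_cutoff`) are
#' `non_scaling`. Among the rest, a two-sided test for a non-zero difference
#' classifies proteins with a significant positive change as `scaling`;
#' everything else is `unclassified`.
#'
#' @param cohort A `cohort_omics` object (or a gene x patient delta matrix).
#' @param arm_gains Tibble with columns `patient_id`, `chromosome`, `arm`,
#'   `gained` (logical) giving, per patient, which arms are gained.
#' @param catalog A [make_genome()] catalog mapping genes to arms.
#' @param fdr_cutoff FDR threshold for both tests.
#' @return Tibble: gene_id, arm, n_gain, n_nogain, diff,
#'   p_nonscaling, fdr_nonscaling, p_change, fdr_change, class, low_n.
#' @export
classify_arm_scaling <- function(cohort, arm_gains, catalog,
                                 fdr_cutoff = 0.05) {
  deltas <- if (inherits(cohort, "cohort_omics")) cohort$deltas else as.matrix(cohort)
  genes <- catalog$genes |> filter(.data$gene_id %in% rownames(deltas))
  gene_arm <- setNames(paste0(genes$chromosome, genes$arm), genes$gene_id)

  gain_lookup <- arm_gains |>
    mutate(lab = paste0(.data$chromosome, .data$arm))
  gained_patients <- split(
    gain_lookup$patient_id[gain_lookup$gained],
    gain_lookup$lab[gain_lookup$gained]
  )

  scaling_lfc <- log2(3 / 2)
  res <- map(rownames(deltas), function(g) {
    lab <- gene_arm[[g]]
    if (is.null(lab) || is.na(lab)) return(NULL)
    gp <- intersect(gained_patients[[lab]] %||% character(), colnames(deltas))
    np <- setdiff(colnames(deltas), gp)
    x <- deltas[g, gp]; y <- deltas[g, np]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble(gene_id = g, arm = lab, n_gain = length(x),
                    n_nogain = length(y), diff = NA_real_,
                    p_nonscaling = NA_real_, p_change = NA_real_,
                    low_n = TRUE))
    }
    d <- mean(x) - mean(y)
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    df <- se^4 / ((var(x) / length(x))^2 / (length(x) - 1) +
                    (var(y) / length(y))^2 / (length(y) - 1))
    tibble(
      gene_id = g, arm = lab,
      n_gain = length(x), n_nogain = length(y), diff = d,
      p_nonscaling = pt((d - scaling_lfc) / se, df),
      p_change = 2 * pt(-abs(d / se), df),
      low_n = FALSE
    )
  }) |> list_rbind()

  res$fdr_nonscaling <- bh_adjust(res$p_nonscaling)
  res$fdr_change <- bh_adjust(res$p_change)
  res$class <- dplyr::case_when(
    res$low_n ~ "unclassified",
    res$fdr_nonscaling < fdr_cutoff ~ "non_scaling",
    res$fdr_change < fdr_cutoff & res$diff > 0 ~ "scaling",
    TRUE ~ "unclassified"
  )
  res
}
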