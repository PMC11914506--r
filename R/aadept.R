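#' Prepare tumor-minus-normal expression deltas for a cohort
#'
#' Applies the cohort preprocessing used before correlation scoring: genes
#' with valid (non-missing, positive) values in fewer than
#' `min_valid_fraction` of samples are dropped; every sample is divided by
#' its upper quartile (75th percentile of positive values) and
#' log2-transformed; patient-matched normal values are subtracted from tumor
#' values; and patients whose tumors have undergone whole-genome doubling
#' (ploidy at or above the cutoff) are removed via [filter_wgd()].
#'
#' @param tumor,normal Gene x patient matrices (or tibbles with a `gene_id`
#'   column) of non-negative expression values on the linear scale, sharing
#'   genes and patients.
#' @param patients Tibble with columns `patient_id`, `as` (aneuploidy
#'   score) and `ploidy`.
#' @param min_valid_fraction Minimum fraction of samples (tumor and normal
#'   pooled) in which a gene must be valid.
#' @param wgd_cutoff Ploidy cutoff passed to [filter_wgd()].
#' @return A `cohort_omics` object (deltas matrix, patients, genes).
#' @export
prepare_expression_deltas <- function(tumor, normal, patients,
                                      min_valid_fraction = 0.6,
                                      wgd_cutoff = 2.5) {
  as_mat <- function(x) {
    if (is_tibble(x) || is.data.frame(x)) {
      m <- as.matrix(x[setdiff(names(x), "gene_id")])
      rownames(m) <- x$gene_id
      m
    } else as.matrix(x)
  }
  tumor <- as_mat(tumor); normal <- as_mat(normal)
  common_p <- intersect(colnames(tumor), colnames(normal))
  n_unmatched <- length(union(colnames(tumor), colnames(normal))) - length(common_p)
  if (n_unmatched > 0) {
    inform(sprintf("%d patients without matched tumor/normal data dropped.", n_unmatched))
  }
  common_p <- intersect(common_p, patients$patient_id)
  keep_p <- intersect(common_p, filter_wgd(
    rename(patients, sample_id = "patient_id"), cutoff = wgd_cutoff
  ))
  if (length(keep_p) == 0) abort("No patients remain after matching and WGD filtering.")
  tumor <- tumor[, keep_p, drop = FALSE]
  normal <- normal[, keep_p, drop = FALSE]

  valid_t <- !is.na(tumor) & tumor > 0
  valid_n <- !is.na(normal) & normal > 0
  frac <- (rowSums(valid_t) + rowSums(valid_n)) / (2 * length(keep_p))
  keep_g <- frac >= min_valid_fraction
  if (!any(keep_g)) abort("No genes pass the valid-fraction filter.")
  tumor <- tumor[keep_g, , drop = FALSE]
  normal <- normal[keep_g, , drop = FALSE]

  uq_log2 <- function(m) {
    m[!is.na(m) & m <= 0] <- NA
    uq <- apply(m, 2, function(v) quantile(v[!is.na(v) & v > 0], 0.75))
    log2(sweep(m, 2, uq, "/"))
  }
  deltas <- uq_log2(tumor) - uq_log2(normal)

  pat <- patients |>
    filter(.data$patient_id %in% keep_p) |>
    arrange(match(.data$patient_id, keep_p))
  new_cohort_omics(deltas, pat,
                   tibble(gene_id = rownames(deltas), planted = NA))
}

#' AADEPT scores: aneuploidy-associated differential expression
#'
#' For every gene, the Spearman rank correlation between the per-patient
#' tumor-minus-normal expression delta and the patient's aneuploidy score.
#' p-values use the asymptotic t approximation for the rank correlation
#' (average ranks for ties), with Benjamini-Hochberg FDR across genes.
#'
#' @param cohort A `cohort_omics` object ([simulate_cohort()] or
#'   [prepare_expression_deltas()]).
#' @return An `aadept_table` tibble: gene_id, rho, n, p_value, fdr. Genes
#'   with constant deltas get `NA` rho.
#' @export
aadept_scores <- function(cohort) {
  deltas <- cohort$deltas
  as_vec <- cohort$patients$as[match(colnames(deltas), cohort$patients$patient_id)]
  if (length(unique(as_vec)) < 2) {
    abort("Aneuploidy score is constant across patients; correlation undefined.")
  }
  if (ncol(deltas) < 3) abort("At least 3 patients are required.")

  res <- map(rownames(deltas), function(g) {
    d <- deltas[g, ]
    ok <- !is.na(d)
    n <- sum(ok)
    if (n < 3 || length(unique(d[ok])) < 2) {
      return(tibble(gene_id = g, rho = NA_real_, n = n, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(d[ok], as_vec[ok], method = "spearman", exact = FALSE)
    )
    tibble(gene_id = g, rho = unname(ct$estimate), n = n,
           p_value = ct$p.value)
  }) |> list_rbind()
  res$fdr <- bh_adjust(res$p_value)
  new_result_tbl(res, "aadept_table")
}
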