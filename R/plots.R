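# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_col
#'   geom_line geom_hline geom_errorbar facet_wrap labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a segmented copy-number profile
#'
#' Segments as horizontal bars at their mean log2 ratio, faceted by
#' chromosome; optionally overlays the underlying bins.
#'
#' @param object A `segmented_profile` tibble.
#' @param bins Optional bin tibble (chromosome, start, end, log2_ratio).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot segmented_profile
#' @export
autoplot.segmented_profile <- function(object, bins = NULL, ...) {
  p <- ggplot(object)
  if (!is.null(bins)) {
    p <- p + geom_point(
      data = bins,
      aes(x = (.data$start + .data$end) / 2e6, y = .data$log2_ratio),
      colour = "grey70", size = 0.4
    )
  }
  p +
    geom_segment(
      aes(x = .data$start / 1e6, xend = .data$end / 1e6,
          y = .data$seg_mean, yend = .data$seg_mean),
      colour = "firebrick", linewidth = 1
    ) +
    facet_wrap(~chromosome, scales = "free_x") +
    labs(x = "Position (Mb)", y = "log2 copy-number ratio") +
    theme_minimal()
}

#' Volcano-style view of AADEPT scores
#'
#' @param object An `aadept_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aadept_table
#' @export
autoplot.aadept_table <- function(object, ...) {
  ggplot(object, aes(x = .data$rho, y = -log10(.data$fdr))) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    labs(x = "AADEPT score (Spearman rho)", y = "-log10 FDR") +
    theme_minimal()
}

#' Enrichment-score view of a set collection
#'
#' With exactly two dimensions, a 2D scatter of per-set scores; otherwise a
#' bar chart per dimension.
#'
#' @param object An `enrichment_result`.
#' @param fdr_cutoff Sets above this FDR are dimmed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, fdr_cutoff = 0.05, ...) {
  object <- mutate(object, significant = .data$fdr < fdr_cutoff)
  dims <- unique(object$dimension)
  if (length(dims) == 2) {
    wide <- tidyr::pivot_wider(object, id_cols = c("set", "fdr", "significant"),
                               names_from = "dimension", values_from = "score")
    return(
      ggplot(wide, aes(x = .data[[dims[1]]], y = .data[[dims[2]]],
                       colour = .data$significant)) +
        geom_point() +
        geom_hline(yintercept = 0, linetype = "dotted") +
        labs(x = paste("Score:", dims[1]), y = paste("Score:", dims[2])) +
        theme_minimal()
    )
  }
  ggplot(object, aes(x = .data$set, y = .data$score, fill = .data$significant)) +
    geom_col() +
    facet_wrap(~dimension) +
    labs(x = NULL, y = "Enrichment score") +
    theme_minimal()
}

#' Bootstrap AUC fold changes with confidence intervals
#'
#' @param object An `auc_estimate` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot auc_estimate
#' @export
autoplot.auc_estimate <- function(object, ...) {
  ggplot(object, aes(x = .data$sample_id, y = .data$mean_auc_fold_change)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.2) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = NULL, y = "AUC fold change vs reference") +
    theme_minimal()
}

#' Arm-level dosage compensation
#'
#' DNA ratio and protein fold change side by side per arm.
#'
#' @param object A `compensation_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot compensation_table
#' @export
autoplot.compensation_table <- function(object, ...) {
  long <- object |>
    mutate(arm_label = paste0(.data$chromosome, .data$arm)) |>
    tidyr::pivot_longer(c("dna_log2", "protein_log2"),
                        names_to = "level", values_to = "log2_value")
  ggplot(long, aes(x = .data$arm_label, y = .data$log2_value, fill = .data$level)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "log2 ratio vs parental") +
    theme_minimal()
}

#' Relevance scores against their empirical p-values
#'
#' @param object A `relevance_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot relevance_result
#' @export
autoplot.relevance_result <- function(object, ...) {
  ggplot(object, aes(x = .data$score, y = -log10(.data$p_value))) +
    geom_point(alpha = 0.6, size = 0.8) +
    labs(x = "Relevance score", y = "-log10 empirical p") +
    theme_minimal()
}

#' Growth curves by line and run
#'
#' @param curves Tibble (sample_id, run_id, time_h, replicate, rlu).
#' @param normalized Normalize to the initial timepoint before plotting.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(curves, normalized = TRUE) {
  if (normalized) curves <- normalize_luminescence(curves)
  curves |>
    group_by(.data$sample_id, .data$run_id, .data$time_h) |>
    summarise(rlu = mean(.data$rlu), .groups = "drop") |>
    ggplot(aes(x = .data$time_h, y = .data$rlu,
               colour = .data$sample_id, linetype = .data$run_id)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "Time (h)", y = if (normalized) "Normalized RLU" else "RLU") +
    theme_minimal()
}

#' @importFrom generics tidy glance
#' @method tidy cohort_omics
#' @export
tidy.cohort_omics <- function(x, ...) {
  as_tibble(x$deltas, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "patient_id",
                        values_to = "delta") |>
    left_join(x$patients, by = "patient_id")
}

#' @method glance cohort_omics
#' @export
glance.cohort_omics <- function(x, ...) {
  tibble(
    n_genes = nrow(x$deltas),
    n_patients = ncol(x$deltas),
    as_min = min(x$patients$as),
    as_max = max(x$patients$as),
    n_planted = sum(x$genes$planted %in% TRUE)
  )
}
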