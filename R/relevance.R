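#' Group scaled fold-change ranks by comparison type
#'
#' Ranks every comparison's log2 fold changes across proteins, scales the
#' ranks to `[-1, 1]` (see [scale_ranks()]), and organizes them by
#' comparison group: G1 = unevolved polysomic vs parental wild type, G2 =
#' evolved polysomic vs its unevolved counterpart, G3 = evolved wild-type
#' control vs unevolved. Only proteins quantified in every comparison are
#' kept (count of exclusions reported).
#'
#' @param fold_changes A `fold_change_table` tibble with columns `gene_id`,
#'   `comparison`, `group` (G1/G2/G3) and `log2fc`.
#' @return A `grouped_rank_set` object: list with `ranks` (protein x
#'   comparison matrix of scaled ranks) and `groups` (named character vector
#'   per comparison column).
#' @export
group_fold_change_ranks <- function(fold_changes) {
  needed <- c("gene_id", "comparison", "group", "log2fc")
  if (!all(needed %in% names(fold_changes))) {
    abort("`fold_changes` needs columns gene_id, comparison, group, log2fc.")
  }
  wide <- fold_changes |>
    select(dplyr::all_of(needed)) |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "comparison",
                       values_from = "log2fc")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$gene_id
  cc <- complete.cases(mat)
  if (any(!cc)) {
    inform(sprintf("%d proteins not quantified in all comparisons excluded.",
                   sum(!cc)))
  }
  mat <- mat[cc, , drop = FALSE]
  if (nrow(mat) < 2) abort("At least 2 proteins present in all comparisons are required.")
  groups <- fold_changes |>
    distinct(.data$comparison, .data$group)
  grp <- setNames(groups$group, groups$comparison)[colnames(mat)]
  structure(
    list(ranks = scale_ranks(mat), groups = grp),
    class = "grouped_rank_set"
  )
}

#' @export
print.grouped_rank_set <- function(x, ...) {
  cat(sprintf("<grouped_rank_set> %d proteins x %d comparisons (%s)\n",
              nrow(x$ranks), ncol(x$ranks),
              paste(sprintf("%s:%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

# core score: |sum(G1) + sum(G2) - penalty|, penalty = the G3 rank of
# maximal magnitude whose sign matches sign(sum(G2)); 0 if none or if
# sum(G2) == 0.
relevance_score_matrix <- function(ranks, groups) {
  row_sum <- function(g) {
    cols <- which(groups == g)
    if (!length(cols)) return(numeric(nrow(ranks)))
    rowSums(ranks[, cols, drop = FALSE])
  }
  s1 <- row_sum("G1")
  s2 <- row_sum("G2")
  g3 <- which(groups == "G3")
  if (length(g3)) {
    cols <- lapply(g3, function(j) ranks[, j])
    pos_max <- Reduce(pmax, lapply(cols, function(v) pmax(v, 0)))
    neg_min <- Reduce(pmin, lapply(cols, function(v) pmin(v, 0)))
  } else {
    pos_max <- neg_min <- numeric(nrow(ranks))
  }
  penalty <- ifelse(s2 > 0, pos_max, ifelse(s2 < 0, neg_min, 0))
  list(score = abs(s1 + s2 - penalty), sum_g1 = s1, sum_g2 = s2,
       penalty = penalty)
}

#' Protein relevance scores for aneuploidy-adaptation patterns
#'
#' For every protein, the scaled fold-change ranks of group 1 (unevolved
#' polysomic vs wild type) and group 2 (evolved vs unevolved polysomic) are
#' summed; the group 3 (control evolution) rank of maximal magnitude with
#' the same sign as the group 2 sum is subtracted (0 if there is none, and
#' a zero group 2 sum matches no sign), discounting changes attributable to
#' prolonged passaging; the absolute value of the result is the relevance
#' score.
#'
#' @param ranks A [group_fold_change_ranks()] object, or a protein x
#'   comparison matrix of scaled ranks (then supply `groups`).
#' @param groups Character vector of group labels (G1/G2/G3) per column,
#'   when `ranks` is a bare matrix.
#' @return Tibble: gene_id, sum_g1, sum_g2, penalty, score (score >= 0).
#' @export
relevance_scores <- function(ranks, groups = NULL) {
  if (inherits(ranks, "grouped_rank_set")) {
    groups <- ranks$groups
    ranks <- ranks$ranks
  }
  if (is.null(groups) || length(groups) != ncol(ranks)) {
    abort("`groups` must label every comparison column.")
  }
  parts <- relevance_score_matrix(ranks, groups)
  tibble(
    gene_id = rownames(ranks) %||% paste0("p", seq_len(nrow(ranks))),
    sum_g1 = unname(parts$sum_g1), sum_g2 = unname(parts$sum_g2),
    penalty = unname(parts$penalty), score = unname(parts$score)
  )
}

#' Permutation-based empirical p-values for relevance scores
#'
#' Null relevance scores are generated by permuting protein labels
#' independently within every comparison column (breaking each protein's
#' cross-comparison dependence while preserving the marginal rank
#' distributions) and recomputing the score. The empirical p-value uses the
#' add-one estimator `p = (1 + #(null >= observed)) / (1 + n_perm)`, so p is
#' never 0 and a score of 0 gets p = 1.
#'
#' @param ranks A [group_fold_change_ranks()] object.
#' @param n_perm Number of permutations (default 100000; a warning is
#'   issued below 100, where the p floor is coarse).
#' @param seed Integer seed.
#' @return A `relevance_result` tibble: gene_id, score, p_value, n_perm,
#'   sorted by decreasing score.
#' @export
empirical_pvalues <- function(ranks, n_perm = 100000L, seed = 1L) {
  if (!inherits(ranks, "grouped_rank_set")) {
    abort("`ranks` must be a grouped_rank_set; see group_fold_change_ranks().")
  }
  if (nrow(ranks$ranks) < 2) abort("At least 2 proteins are required.")
  if (n_perm < 100) warn("Fewer than 100 permutations: the p-value floor is unstable.")
  R <- ranks$ranks
  groups <- ranks$groups
  P <- nrow(R)
  obs <- relevance_score_matrix(R, groups)$score
  withr::local_seed(seed)

  cnt <- numeric(P)
  Rp <- R
  for (b in seq_len(n_perm)) {
    for (j in seq_len(ncol(R))) Rp[, j] <- R[sample.int(P), j]
    cnt <- cnt + (relevance_score_matrix(Rp, groups)$score >= obs)
  }
  out <- tibble(
    gene_id = rownames(R),
    score = unname(obs),
    p_value = unname((1 + cnt) / (1 + n_perm)),
    n_perm = as.integer(n_perm)
  ) |> arrange(dplyr::desc(.data$score))
  new_result_tbl(out, "relevance_result")
}
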