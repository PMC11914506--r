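#' Scale values to signed ranks in [-1, 1]
#'
#' Values are ranked (average ranks for ties) and the ranks mapped linearly
#' so the lowest value becomes -1 and the highest +1:
#' `2 * (r - 1) / (n - 1) - 1`. NA values stay NA and do not consume ranks.
#'
#' @param x Numeric vector, or a data frame / matrix whose columns are
#'   scaled independently (one dimension each).
#' @return Same shape as the input, values in `[-1, 1]`.
#' @examples
#' scale_ranks(c(5, 1, 3))
#' @export
scale_ranks <- function(x) {
  scale1 <- function(v) {
    out <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    n <- sum(ok)
    if (n == 1) {
      warn("Only one item to rank; scaled rank set to 0.")
      out[ok] <- 0
      return(out)
    }
    r <- rank(v[ok], ties.method = "average")
    out[ok] <- 2 * (r - 1) / (n - 1) - 1
    out
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, scale1)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (is.data.frame(x)) {
    x[] <- lapply(x, scale1)
    return(x)
  }
  scale1(x)
}

#' One-dimensional rank enrichment of a set
#'
#' Enrichment score = mean scaled rank of the set minus the mean scaled rank
#' of all other items; significance from a univariate two-group ANOVA of the
#' ranks against set membership.
#'
#' @param ranks Numeric vector of scaled ranks (see [scale_ranks()]).
#' @param members Logical vector (same length) or integer/character index of
#'   the set's items.
#' @return Tibble with `score` and `p_value`.
#' @export
enrich_1d <- function(ranks, members) {
  members <- as_membership(members, ranks)
  ok <- !is.na(ranks)
  ranks <- ranks[ok]; members <- members[ok]
  if (!any(members) || all(members)) {
    abort("The set must be a non-empty proper subset of the items.")
  }
  score <- mean(ranks[members]) - mean(ranks[!members])
  p <- anova(lm(ranks ~ members))[["Pr(>F)"]][1]
  tibble(score = score, p_value = p)
}

as_membership <- function(members, ranks) {
  if (is.logical(members)) {
    if (length(members) != NROW(ranks)) abort("Membership length mismatch.")
    return(members)
  }
  if (is.character(members)) {
    nm <- if (is.null(dim(ranks))) names(ranks) else rownames(ranks)
    if (is.null(nm)) abort("Named ranks are required for character membership.")
    return(nm %in% members)
  }
  m <- rep(FALSE, NROW(ranks))
  m[members] <- TRUE
  m
}

#' Multi-dimensional rank enrichment of a set
#'
#' Per-dimension enrichment scores as in [enrich_1d()]; one overall p-value
#' from a two-group multivariate ANOVA (Pillai's trace with its F
#' approximation) testing whether the set's mean scaled-rank vector differs
#' from the background's. Items missing any dimension are dropped listwise.
#' With a single dimension this reduces exactly to [enrich_1d()].
#'
#' @param ranks Matrix or data frame of scaled ranks, one column per
#'   dimension (see [scale_ranks()]).
#' @param members As in [enrich_1d()].
#' @return Tibble with one row per dimension (`dimension`, `score`) plus
#'   the shared `p_value` and `n_used`.
#' @export
enrich_nd <- function(ranks, members) {
  mat <- as.matrix(ranks)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("dim", seq_len(ncol(mat)))
  members <- as_membership(members, mat)
  cc <- complete.cases(mat)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) inform(sprintf("%d items dropped (incomplete dimensions).", n_dropped))
  mat <- mat[cc, , drop = FALSE]; members <- members[cc]
  if (!any(members) || all(members)) {
    abort("The set must be a non-empty proper subset of the items.")
  }
  if (nrow(mat) <= ncol(mat)) abort("More items than dimensions are required.")

  scores <- colMeans(mat[members, , drop = FALSE]) -
    colMeans(mat[!members, , drop = FALSE])

  if (ncol(mat) == 1) {
    p <- enrich_1d(mat[, 1], members)$p_value
  } else {
    centred <- mat
    centred[members, ] <- sweep(mat[members, , drop = FALSE], 2,
                                colMeans(mat[members, , drop = FALSE]))
    centred[!members, ] <- sweep(mat[!members, , drop = FALSE], 2,
                                 colMeans(mat[!members, , drop = FALSE]))
    if (qr(centred)$rank < ncol(mat)) {
      abort(paste0(
        "Within-group covariance is singular; collinear dimensions: ",
        paste(colnames(mat), collapse = ", ")
      ))
    }
    fit <- manova(mat ~ members)
    p <- summary(fit, test = "Pillai")$stats[1, "Pr(>F)"]
  }
  tibble(dimension = colnames(mat), score = unname(scores),
         p_value = p, n_used = nrow(mat))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up false-discovery-rate adjustment: order the m p-values,
#' compute `p_(i) * m / i`, and enforce monotonicity by a cumulative
#' minimum from the largest p downward. NA p-values are carried through and
#' do not count toward m.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of FDR-adjusted values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok], decreasing = TRUE)
  adj <- pmin(1, cummin((m / seq(m, 1)) * p[ok][o]))
  out[ok[o]] <- adj
  out
}

#' Rank enrichment across a collection of gene sets
#'
#' Runs [enrich_nd()] for every set of a collection against a shared
#' scaled-rank matrix and adjusts the overall p-values by
#' Benjamini-Hochberg within the collection.
#'
#' @param ranks Matrix or data frame of scaled ranks with item rownames.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param min_size Sets with fewer members among the ranked items are
#'   skipped.
#' @return An `enrichment_result` tibble: set, dimension, score, p_value,
#'   fdr, set_size.
#' @export
enrich_gene_sets <- function(ranks, sets, min_size = 3L) {
  mat <- as.matrix(ranks)
  items <- rownames(mat)
  if (is.null(items)) abort("`ranks` needs item rownames.")
  rows <- purrr::imap(sets, function(genes, set) {
    members <- items %in% genes
    if (sum(members) < min_size || all(members)) return(NULL)
    enrich_nd(mat, members) |>
      mutate(set = set, set_size = sum(members), .before = 1)
  }) |> list_rbind()
  if (is.null(rows) || nrow(rows) == 0) abort("No sets of sufficient size.")
  # one p per set; adjust once per set, then broadcast back to dimensions
  per_set <- distinct(rows, .data$set, .data$p_value)
  per_set$fdr <- bh_adjust(per_set$p_value)
  rows <- left_join(rows, select(per_set, "set", "fdr"), by = "set")
  new_result_tbl(rows, "enrichment_result")
}

#' Hypergeometric overrepresentation with enrichment strength
#'
#' Tests each gene set for overrepresentation among a hit list drawn from a
#' background of `background_size` measured items. The p-value is the upper
#' tail `P(X >= q)` of the hypergeometric distribution; the strength of the
#' overrepresentation is the log ratio of observed to expected overlap,
#' `s = log10(N * q / (k * m))`, undefined (NA) when the overlap is 0.
#' FDR adjustment is applied within each set category.
#'
#' @param hits Character vector of differentially abundant items (must be a
#'   subset of the background when `background` is supplied).
#' @param sets Named list of character vectors, or a tibble with columns
#'   `set`, `gene_id` and optionally `category`.
#' @param background Character vector of all measured items; sets and hits
#'   are intersected with it. Alternatively give `background_size` directly.
#' @param background_size Size N of the background when only counts matter.
#' @return An `overrep_result` tibble: set, category, overlap, set_size,
#'   n_hits, background_size, p_value, fdr, strength.
#' @export
overrepresentation <- function(hits, sets, background = NULL,
                               background_size = NULL) {
  if (is.null(background) && is.null(background_size)) {
    abort("Supply `background` or `background_size`.")
  }
  sl <- as_set_list(sets)
  if (!is.null(background)) {
    if (!all(hits %in% background)) abort("`hits` must be a subset of the background.")
    sl$sets <- map(sl$sets, function(s) intersect(s, background))
    N <- length(background)
  } else {
    N <- background_size
  }
  k <- length(unique(hits))
  if (N < k) abort("Background smaller than the hit list.")
  rows <- purrr::imap(sl$sets, function(genes, set) {
    m <- length(unique(genes))
    if (N < m) abort("Background smaller than a set.")
    q <- length(intersect(unique(hits), unique(genes)))
    tibble(
      set = set,
      category = sl$category[[set]] %||% "sets",
      overlap = q, set_size = m, n_hits = k, background_size = N,
      p_value = phyper(q - 1, m, N - m, k, lower.tail = FALSE),
      strength = if (q > 0) log10(N * q / (k * m)) else NA_real_
    )
  }) |> list_rbind()
  rows <- rows |>
    group_by(.data$category) |>
    mutate(fdr = bh_adjust(.data$p_value)) |>
    ungroup() |>
    select("set", "category", "overlap", "set_size", "n_hits",
           "background_size", "p_value", "fdr", "strength")
  new_result_tbl(rows, "overrep_result")
}

as_set_list <- function(sets) {
  if (is.data.frame(sets)) {
    lst <- split(sets$gene_id, sets$set)
    cats <- if ("category" %in% names(sets)) {
      as.list(setNames(
        sets$category[!duplicated(sets$set)],
        sets$set[!duplicated(sets$set)]
      ))
    } else setNames(vector("list", length(lst)), names(lst))
    return(list(sets = lst, category = cats))
  }
  list(sets = sets, category = setNames(vector("list", length(sets)), names(sets)))
}
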