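# Change-point engine: recursive binary segmentation of an ordered numeric
# series into constant-mean segments, with permutation-based acceptance of
# each candidate split (the CBS family of algorithms).

# max two-sample t over all admissible splits of x; returns list(stat, split)
# split k means segments 1..k and (k+1)..n
best_split_stat <- function(x, min_width) {
  n <- length(x)
  if (n < 2 * min_width) return(list(stat = -Inf, split = NA_integer_))
  rng <- diff(range(x))
  if (rng == 0) return(list(stat = 0, split = NA_integer_))
  k <- seq.int(min_width, n - min_width)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  nl <- k
  nr <- n - k
  ml <- cs[k] / nl
  mr <- (cs[n] - cs[k]) / nr
  ssl <- cs2[k] - nl * ml^2
  ssr <- (cs2[n] - cs2[k]) - nr * mr^2
  df <- n - 2
  s2 <- pmax(ssl + ssr, 0) / df
  se <- sqrt(s2 * (1 / nl + 1 / nr))
  stat <- abs(ml - mr) / se
  # zero pooled variance: infinite evidence if the means genuinely differ
  # (beyond accumulated rounding), none otherwise
  stat[se == 0] <- ifelse(abs(ml - mr)[se == 0] > 1e-8 * rng, Inf, 0)
  i <- which.max(stat)
  list(stat = stat[i], split = k[i])
}

# permutation p-value for the best split of x
split_pvalue <- function(x, obs, min_width, n_perm) {
  if (!is.finite(obs)) return(if (obs > 0) 1 / (n_perm + 1) else 1)
  null <- vapply(seq_len(n_perm), function(i) {
    best_split_stat(sample(x), min_width)$stat
  }, numeric(1))
  (1 + sum(null >= obs)) / (n_perm + 1)
}

bin_seg_breaks <- function(x, alpha, min_width, n_perm) {
  n <- length(x)
  if (n < 2 * min_width) return(integer(0))
  bs <- best_split_stat(x, min_width)
  if (is.na(bs$split) || bs$stat <= 0) return(integer(0))
  p <- split_pvalue(x, bs$stat, min_width, n_perm)
  if (p >= alpha) return(integer(0))
  k <- bs$split
  c(
    bin_seg_breaks(x[seq_len(k)], alpha, min_width, n_perm),
    k,
    k + bin_seg_breaks(x[seq.int(k + 1, n)], alpha, min_width, n_perm)
  )
}

segment_series <- function(x, alpha, min_width, n_perm) {
  breaks <- bin_seg_breaks(x, alpha, min_width, n_perm)
  ends <- c(breaks, length(x))
  starts <- c(1L, head(ends, -1L) + 1L)
  tibble(
    first = starts, last = ends,
    n_bins = ends - starts + 1L,
    seg_mean = map_dbl(seq_along(starts), function(i) mean(x[starts[i]:ends[i]])),
    seg_median = map_dbl(seq_along(starts), function(i) median(x[starts[i]:ends[i]]))
  )
}

#' Segment a binned copy-number profile
#'
#' Partitions each chromosome's ordered log2 ratios into constant-mean
#' segments by recursive binary segmentation; every candidate change point
#' must pass a within-segment permutation test at level `alpha` before it is
#' accepted. Per-segment mean and median log2 ratios are reported.
#'
#' @param bins Tibble with columns `chromosome`, `start`, `end`,
#'   `log2_ratio` and optionally `sample_id` (as produced by
#'   [simulate_binned_profile()] or [read_seg()] bins).
#' @param alpha Significance level for accepting a change point.
#' @param min_width Minimum segment width in bins.
#' @param n_perm Number of within-segment permutations.
#' @param seed Integer seed; identical seeds give identical segmentations.
#' @return A `segmented_profile` tibble: sample_id, chromosome, start, end,
#'   n_bins, seg_mean, seg_median; segments per chromosome are sorted,
#'   non-overlapping and half-open.
#' @export
segment_profile <- function(bins, alpha = 0.01, min_width = 3L,
                            n_perm = 1000L, seed = 1L) {
  if (!all(c("chromosome", "start", "end", "log2_ratio") %in% names(bins))) {
    abort("`bins` needs columns chromosome, start, end, log2_ratio.")
  }
  if (!"sample_id" %in% names(bins)) bins$sample_id <- "S1"
  withr::local_seed(seed)

  out <- bins |>
    group_by(.data$sample_id, .data$chromosome) |>
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, .data$start)
      if (nrow(d) == 0) {
        warn(paste0("Chromosome ", key$chromosome, " has no bins; skipped."))
        return(tibble())
      }
      seg <- segment_series(d$log2_ratio, alpha, min_width, n_perm)
      tibble(
        start = d$start[seg$first],
        end = d$end[seg$last],
        n_bins = seg$n_bins,
        seg_mean = seg$seg_mean,
        seg_median = seg$seg_median
      )
    }) |>
    ungroup()
  new_result_tbl(out, "segmented_profile")
}

#' Segment protein fold changes along the genome
#'
#' Orders per-protein log2 fold changes by the genomic position of their
#' encoding genes and applies the same binary segmentation as
#' [segment_profile()], yielding a piecewise-constant fold-change profile
#' comparable with the DNA copy-number profile.
#'
#' @param fold_changes Tibble with columns `gene_id` and `log2fc`.
#' @param catalog A [make_genome()] catalog supplying gene coordinates.
#' @param sample_id Label for the output profile.
#' @inheritParams segment_profile
#' @return A `segmented_profile` tibble; `n_bins` counts proteins and
#'   segment bounds span from the first to the last gene in the segment.
#'   Proteins absent from the catalog are dropped (count reported).
#' @export
segment_fold_changes <- function(fold_changes, catalog, sample_id = "FC",
                                 alpha = 0.01, min_width = 3L,
                                 n_perm = 1000L, seed = 1L) {
  mapped <- inner_join(fold_changes, catalog$genes, by = "gene_id")
  n_drop <- nrow(fold_changes) - nrow(mapped)
  if (n_drop > 0) {
    rlang::inform(sprintf("%d proteins without genomic coordinates excluded.", n_drop))
  }
  if (nrow(mapped) == 0) abort("No proteins could be mapped to coordinates.")
  bins <- mapped |>
    arrange(match(.data$chromosome, names(catalog$chrom_lengths)), .data$start) |>
    mutate(sample_id = .env$sample_id, log2_ratio = .data$log2fc) |>
    select("sample_id", "chromosome", "start", "end", "log2_ratio")
  segment_profile(bins, alpha = alpha, min_width = min_width,
                  n_perm = n_perm, seed = seed)
}
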