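#' Normalize a binned profile to a reference line
#'
#' Subtracts the reference log2 ratios bin-wise, so the output expresses
#' copy number relative to the (typically unevolved wild-type) reference.
#' Both profiles must be on the same bin grid.
#'
#' @param profile_bins,reference_bins Tibbles with columns `chromosome`,
#'   `start`, `end`, `log2_ratio`.
#' @return `profile_bins` with `log2_ratio` replaced by the difference.
#' @export
normalize_to_reference <- function(profile_bins, reference_bins) {
  key <- function(b) paste(b$chromosome, b$start, b$end)
  if (nrow(profile_bins) != nrow(reference_bins) ||
      !identical(key(profile_bins), key(reference_bins))) {
    abort("Profile and reference are not on the same bin grid.")
  }
  mutate(profile_bins,
         log2_ratio = .data$log2_ratio - reference_bins$log2_ratio)
}

#' Call arm-level copy-number events
#'
#' A segment is considered gained (lost) when its mean log2 ratio exceeds
#' `log2_threshold` (falls below its negative). An arm is called gained or
#' lost when same-direction altered segments cover more than
#' `coverage_threshold` of its length; gains and losses on one arm never sum.
#'
#' @param profile A [segment_profile()] result.
#' @param catalog A [make_genome()] catalog with arm definitions.
#' @param log2_threshold Absolute log2-ratio threshold for an altered segment.
#' @param coverage_threshold Minimum altered fraction of the arm length
#'   (strict inequality) required to call the arm.
#' @return An `arm_call_table` tibble: sample_id, chromosome, arm,
#'   altered_fraction, direction (gain/loss/neutral).
#' @export
call_arm_events <- function(profile, catalog, log2_threshold = 0.2,
                            coverage_threshold = 0.75) {
  assert_nonneg(log2_threshold, "log2_threshold")
  samples <- unique(profile$sample_id)
  out <- purrr::map(samples, function(sid) {
    segs <- filter(profile, .data$sample_id == sid)
    purrr::pmap(catalog$arms, function(chromosome, arm, start, end) {
      s <- filter(segs, .data$chromosome == .env$chromosome)
      ov_start <- pmax(s$start, start)
      ov_end <- pmin(s$end, end)
      ov <- pmax(ov_end - ov_start, 0)
      arm_len <- end - start
      covered <- sum(ov)
      gain_frac <- sum(ov[s$seg_mean > log2_threshold]) / arm_len
      loss_frac <- sum(ov[s$seg_mean < -log2_threshold]) / arm_len
      if (covered == 0) {
        warn(sprintf("Arm %s%s of %s has no covered bp; reported neutral.",
                     chromosome, arm, sid))
        return(tibble(sample_id = sid, chromosome = chromosome, arm = arm,
                      altered_fraction = 0, direction = "neutral"))
      }
      frac <- max(gain_frac, loss_frac)
      dir <- if (gain_frac > coverage_threshold) "gain"
        else if (loss_frac > coverage_threshold) "loss"
        else "neutral"
      tibble(sample_id = sid, chromosome = chromosome, arm = arm,
             altered_fraction = frac, direction = dir)
    }) |> list_rbind()
  }) |> list_rbind()
  new_result_tbl(out, "arm_call_table")
}

is_sex_chromosome <- function(chromosome) {
  gsub("^chr", "", chromosome) %in% c("X", "Y", "23", "24")
}

#' Aneuploidy score
#'
#' Counts, per sample, the chromosome arms called gained or lost. With
#' `autosomes_only = TRUE` (the default) sex-chromosome arms are excluded
#' from the count.
#'
#' @param calls An [call_arm_events()] table.
#' @param autosomes_only Exclude chrX/chrY arms from the count.
#' @return Tibble (sample_id, as).
#' @export
aneuploidy_score <- function(calls, autosomes_only = TRUE) {
  if (autosomes_only) {
    calls <- filter(calls, !is_sex_chromosome(.data$chromosome))
  }
  calls |>
    group_by(.data$sample_id) |>
    summarise(as = sum(.data$direction != "neutral"), .groups = "drop") |>
    mutate(as = as.integer(.data$as))
}

#' Filter out whole-genome-doubled samples
#'
#' Retains samples whose genome-average copy number (ploidy) lies strictly
#' below the cutoff; samples at or above it are treated as having undergone
#' whole-genome doubling and removed from cohort analyses.
#'
#' @param records Tibble with columns `sample_id` and `ploidy`.
#' @param cutoff Ploidy cutoff (default 2.5; strict inequality).
#' @return Character vector of retained sample ids.
#' @export
filter_wgd <- function(records, cutoff = 2.5) {
  missing <- is.na(records$ploidy)
  if (any(missing)) {
    warn(sprintf("%d samples without ploidy dropped.", sum(missing)))
    records <- records[!missing, ]
  }
  records$sample_id[records$ploidy < cutoff]
}

#' Total relative DNA
#'
#' Heuristic estimate of the amount of autosomal DNA gained or lost relative
#' to the reference line: each segment's log2 ratio q is converted to an
#' approximate integer copy-number difference `round(2 * (2^q - 1))`
#' (half away from zero) and weighted by the segment length, `D = sum(
#' round(R_i) * L_i)`. In unsigned mode (the default) the absolute
#' copy-number differences are summed, giving the total amount of altered
#' DNA; in signed mode gains and losses cancel.
#'
#' @param profile A [segment_profile()] result, normalized to the wild type;
#'   sex chromosomes are excluded.
#' @param signed Use the signed copy-number differences (`FALSE` by default:
#'   absolute differences).
#' @return Tibble (sample_id, total_relative_dna, mode).
#' @export
total_relative_dna <- function(profile, signed = FALSE) {
  profile |>
    filter(!is_sex_chromosome(.data$chromosome)) |>
    group_by(.data$sample_id) |>
    summarise(
      total_relative_dna = {
        r <- round_half_away(2 * (2^.data$seg_mean - 1))
        if (!signed) r <- abs(r)
        sum(r * (.data$end - .data$start))
      },
      .groups = "drop"
    ) |>
    mutate(mode = if (signed) "signed" else "unsigned")
}
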