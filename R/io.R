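# Interchange formats. Coordinates are 0-based half-open in memory; SEG
# files are written 1-based inclusive (the common convention) and converted
# at the boundary. BED stays 0-based half-open as the format defines.

#' Read / write SEG-like segment tables
#'
#' Tab-separated with columns sample, chrom, loc.start, loc.end, num.mark,
#' seg.mean (1-based inclusive coordinates on disk).
#'
#' @param profile A `segmented_profile` tibble.
#' @param path File path.
#' @return `read_seg()` returns a `segmented_profile` tibble (0-based
#'   half-open); `write_seg()` returns `path` invisibly.
#' @export
write_seg <- function(profile, path) {
  tibble(
    sample = profile$sample_id,
    chrom = profile$chromosome,
    loc.start = profile$start + 1,
    loc.end = profile$end,
    num.mark = profile$n_bins,
    seg.mean = profile$seg_mean
  ) |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  out <- tibble(
    sample_id = as.character(d$sample),
    chromosome = as.character(d$chrom),
    start = d$loc.start - 1,
    end = d$loc.end,
    n_bins = as.integer(d$num.mark),
    seg_mean = d$seg.mean,
    seg_median = if ("seg.median" %in% names(d)) d$seg.median else d$seg.mean
  )
  new_result_tbl(out, "segmented_profile")
}

#' Read / write chromosome-arm definitions as BED
#'
#' BED4: chrom, start, end, name where name is the arm ("p"/"q"); 0-based
#' half-open, as the format defines.
#'
#' @param catalog A `genome_catalog` (its `arms` are written).
#' @param path File path.
#' @return `read_arm_bed()` returns an arms tibble (chromosome, arm, start,
#'   end).
#' @export
write_arm_bed <- function(catalog, path) {
  arms <- if (inherits(catalog, "genome_catalog")) catalog$arms else catalog
  readr::write_tsv(
    tibble(chrom = arms$chromosome, start = arms$start, end = arms$end,
           name = arms$arm),
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_arm_bed
#' @export
read_arm_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                       show_col_types = FALSE)
  tibble(chromosome = as.character(d$chrom), arm = as.character(d$name),
         start = d$start, end = d$end)
}

#' Read / write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[`, "", 1))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  writeLines(
    vapply(names(sets), function(nm) {
      paste(c(nm, nm, sets[[nm]]), collapse = "\t")
    }, ""),
    path
  )
  invisible(path)
}

#' Read / write a gene-by-sample matrix as TSV
#'
#' First column `gene_id`, remaining columns samples.
#'
#' @param mat Numeric matrix with gene rownames.
#' @param path File path.
#' @return `read_matrix_tsv()` returns a numeric matrix with gene rownames.
#' @export
write_matrix_tsv <- function(mat, path) {
  readr::write_tsv(
    bind_cols(tibble(gene_id = rownames(mat)), as_tibble(mat)),
    path
  )
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[-1])
  rownames(m) <- d$gene_id
  m
}
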