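#' Build a synthetic genome catalog
#'
#' Creates a compact genome model for simulation: `n_chromosomes` autosomes,
#' each split at a centromere into a p and a q arm, with `genes_per_arm`
#' non-overlapping genes placed on every arm. Coordinates are 0-based,
#' half-open; the two arms of a chromosome are disjoint and tile it, and
#' every gene lies entirely within one arm.
#'
#' @param n_chromosomes Number of autosomes to generate (>= 1).
#' @param genes_per_arm Number of genes on each arm (>= 1).
#' @param seed Integer seed; the same seed always yields an identical catalog.
#' @param chrom_length Chromosome length in bp (default 100 Mb).
#' @return An object of class `genome_catalog`: a list with
#'   * `arms` — tibble (chromosome, arm, start, end),
#'   * `genes` — tibble (gene_id, chromosome, start, end, arm), coordinate
#'     sorted within chromosomes,
#'   * `chrom_lengths` — named numeric vector.
#' @examples
#' gn <- make_genome(2, 5, seed = 1)
#' gn$arms
#' @export
make_genome <- function(n_chromosomes, genes_per_arm, seed = 1L,
                        chrom_length = 1e8) {
  assert_scalar_count(n_chromosomes, "n_chromosomes")
  assert_scalar_count(genes_per_arm, "genes_per_arm")
  withr::local_seed(seed)

  chroms <- paste0("chr", seq_len(n_chromosomes))
  # centromere position varies between 30% and 70% of the chromosome
  centro <- floor(chrom_length * runif(n_chromosomes, 0.3, 0.7))

  arms <- tibble(
    chromosome = rep(chroms, each = 2L),
    arm = rep(c("p", "q"), n_chromosomes),
    start = as.numeric(rbind(0, centro)),
    end = as.numeric(rbind(centro, chrom_length))
  )

  genes <- purrr::pmap(arms, function(chromosome, arm, start, end) {
    len <- end - start
    # evenly spaced gene slots with jitter; gene length 10 kb, always inside
    # its slot so genes never overlap and never cross the arm boundary
    slot <- len / genes_per_arm
    gene_len <- min(1e4, floor(slot / 2))
    offs <- floor(runif(genes_per_arm, 0, slot - gene_len))
    gs <- start + (seq_len(genes_per_arm) - 1) * slot + offs
    tibble(
      chromosome = chromosome,
      start = floor(gs),
      end = floor(gs) + gene_len,
      arm = arm
    )
  }) |> list_rbind()
  genes <- genes |>
    arrange(match(.data$chromosome, chroms), .data$start) |>
    mutate(gene_id = sprintf("g%04d", row_number()), .before = 1)

  structure(
    list(
      arms = arms,
      genes = genes,
      chrom_lengths = setNames(rep(chrom_length, n_chromosomes), chroms)
    ),
    class = "genome_catalog"
  )
}

#' @export
print.genome_catalog <- function(x, ...) {
  cat(sprintf(
    "<genome_catalog> %d chromosomes, %d arms, %d genes\n",
    length(x$chrom_lengths), nrow(x$arms), nrow(x$genes)
  ))
  invisible(x)
}

#' Arm labels of a genome catalog
#'
#' @param catalog A `genome_catalog`.
#' @return Character vector like `"chr1p"`, `"chr1q"`, ...
#' @export
arm_labels <- function(catalog) {
  paste0(catalog$arms$chromosome, catalog$arms$arm)
}
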