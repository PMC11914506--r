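#' Build an arm-level karyotype
#'
#' A karyotype is a per-arm integer copy number relative to a diploid
#' reference (copy number 2). The derived `log2_ratio` is `log2(cn / 2)`,
#' so a neutral arm has ratio 0.
#'
#' @param catalog A [make_genome()] catalog.
#' @param alterations Named integer vector of copy numbers for altered arms,
#'   e.g. `c(chr1p = 3, chr2q = 1)`; all other arms stay at 2.
#' @return Tibble (chromosome, arm, copy_number, log2_ratio).
#' @examples
#' gn <- make_genome(2, 3, seed = 1)
#' karyotype(gn, c(chr1p = 3))
#' @export
karyotype <- function(catalog, alterations = NULL) {
  kt <- catalog$arms |>
    select("chromosome", "arm") |>
    mutate(copy_number = 2L)
  if (length(alterations)) {
    lab <- paste0(kt$chromosome, kt$arm)
    bad <- setdiff(names(alterations), lab)
    if (length(bad)) abort(paste0("Unknown arms: ", paste(bad, collapse = ", ")))
    if (any(alterations < 0)) abort("Copy numbers must be >= 0.")
    kt$copy_number[match(names(alterations), lab)] <- as.integer(alterations)
  }
  mutate(kt, log2_ratio = log2(.data$copy_number / 2))
}

#' Simulate a patient cohort with aneuploidy-linked expression changes
#'
#' Each patient receives a random arm-level karyotype; the aneuploidy score
#' (AS) is the number of altered autosomal arms. Tumor-minus-normal
#' expression deltas are then drawn for every gene: a planted subset tracks
#' the aneuploidy score linearly (`delta = effect_size * AS + noise`) while
#' the remainder is pure noise. Truth labels are returned so downstream
#' scoring can be benchmarked against ground truth.
#'
#' @param catalog A [make_genome()] catalog.
#' @param n_patients Cohort size (>= 3).
#' @param effect_size Delta units gained per AS unit for planted genes.
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param planted_gene_fraction Fraction of genes carrying the planted
#'   association.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A `cohort_omics` object: list with `deltas` (gene x patient
#'   matrix), `patients` (tibble: patient_id, as, ploidy) and `genes`
#'   (tibble: gene_id, planted).
#' @export
simulate_cohort <- function(catalog, n_patients = 200, effect_size = 0.2,
                            noise_sd = 1, planted_gene_fraction = 0.05,
                            seed = 1L) {
  if (n_patients < 3) abort("`n_patients` must be >= 3.")
  assert_nonneg(noise_sd, "noise_sd")
  withr::local_seed(seed)

  n_arms <- nrow(catalog$arms)
  genes <- catalog$genes$gene_id
  n_genes <- length(genes)

  # per-patient alteration propensity spreads AS across its whole range
  prop <- runif(n_patients, 0, 0.5)
  n_alt <- rbinom(n_patients, n_arms, prop)

  patients <- tibble(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    as = as.integer(n_alt),
    ploidy = 2
  )

  planted <- rep(FALSE, n_genes)
  planted[sample.int(n_genes, max(1L, round(planted_gene_fraction * n_genes)))] <- TRUE

  deltas <- matrix(
    rnorm(n_genes * n_patients, sd = noise_sd),
    nrow = n_genes, dimnames = list(genes, patients$patient_id)
  )
  deltas[planted, ] <- deltas[planted, ] +
    matrix(effect_size * patients$as, nrow = sum(planted), ncol = n_patients,
           byrow = TRUE)

  new_cohort_omics(deltas, patients, tibble(gene_id = genes, planted = planted))
}

new_cohort_omics <- function(deltas, patients, genes) {
  stopifnot(ncol(deltas) == nrow(patients))
  structure(
    list(deltas = deltas, patients = patients, genes = genes),
    class = "cohort_omics"
  )
}

#' @export
print.cohort_omics <- function(x, ...) {
  cat(sprintf(
    "<cohort_omics> %d genes x %d patients; AS range %d-%d\n",
    nrow(x$deltas), ncol(x$deltas), min(x$patients$as), max(x$patients$as)
  ))
  invisible(x)
}

#' Standard polysomic cell-line panel design
#'
#' Builds the karyotypes, sample design and comparison table for a panel of
#' engineered polysomic lines and their parental wild type, each observed
#' unevolved (passage 0) and after in vitro evolution (passage 50).
#' Comparison groups follow the relevance-score convention:
#' G1 = unevolved polysomic vs parental wild type, G2 = evolved polysomic vs
#' its unevolved counterpart, G3 = evolved wild-type control vs unevolved.
#'
#' @param catalog A [make_genome()] catalog.
#' @param polysomies Named integer vector: names are arm labels (or bare
#'   chromosome names, meaning both arms), values the copy number (3 =
#'   trisomy, 4 = tetrasomy). One line is created per entry.
#' @return List with `karyotypes` (tibble: line_id, chromosome, arm,
#'   copy_number), `design` (tibble: line_id, parental_id, passage) and
#'   `comparisons` (tibble: comparison, line_a, line_b, group).
#' @export
polysomy_design <- function(catalog, polysomies = c(chr1 = 3L, chr2 = 3L)) {
  arms <- arm_labels(catalog)
  expand1 <- function(name, cn) {
    hit <- if (name %in% arms) name else grep(paste0("^", name, "[pq]$"), arms, value = TRUE)
    if (!length(hit)) abort(paste0("Unknown chromosome or arm: ", name))
    setNames(rep(cn, length(hit)), hit)
  }
  lines <- imap(as.list(polysomies), function(cn, nm) {
    list(line_id = paste0(if (cn >= 4) "Tet_" else "Ts_", nm),
         alt = expand1(nm, cn))
  })

  kts <- c(
    list(WT = karyotype(catalog)),
    setNames(
      map(lines, function(l) karyotype(catalog, l$alt)),
      map(lines, "line_id")
    )
  )
  karyotypes <- imap(kts, function(kt, id) mutate(kt, line_id = id, .before = 1)) |>
    list_rbind() |>
    select("line_id", "chromosome", "arm", "copy_number")

  line_ids <- names(kts)
  design <- tidyr::expand_grid(line_id = line_ids, passage = c(0L, 50L)) |>
    mutate(parental_id = "WT")

  poly <- setdiff(line_ids, "WT")
  comparisons <- bind_rows(
    tibble(comparison = paste0(poly, "_p0_vs_WT_p0"),
           line_a = poly, passage_a = 0L, line_b = "WT", passage_b = 0L,
           group = "G1"),
    tibble(comparison = paste0(poly, "_p50_vs_p0"),
           line_a = poly, passage_a = 50L, line_b = poly, passage_b = 0L,
           group = "G2"),
    tibble(comparison = "WT_p50_vs_p0",
           line_a = "WT", passage_a = 50L, line_b = "WT", passage_b = 0L,
           group = "G3")
  )
  list(karyotypes = karyotypes, design = design, comparisons = comparisons)
}

#' Simulate cell-line proteomes with dosage effects and planted adaptation
#'
#' Generates log2 protein intensities for a panel of cell lines. Genes on
#' gained arms show an expected log2 fold change of
#' `(1 - compensation) * log2(dosage ratio)` relative to the parental line;
#' a planted set of "adaptation" genes is additionally shifted at passage 0
#' in polysomic lines, with the shift continuing in the same direction
#' through evolution (doubled by passage 50) and absent from wild-type
#' evolution — the aneuploidy-specific pattern the relevance score targets —
#' half the genes upward and half downward. Batch offsets and replicate
#' noise are layered on top. Truth labels and noise-free expected fold
#' changes are returned for benchmarking.
#'
#' @param catalog A [make_genome()] catalog.
#' @param panel A [polysomy_design()] list (karyotypes, design, comparisons).
#' @param compensation Dosage compensation factor c in `[0, 1]`; 0 = full
#'   scaling with DNA, 1 = complete buffering.
#' @param adaptation_fraction Fraction of genes planted as adaptation genes.
#' @param adaptation_shift Absolute log2 shift of adaptation genes at p0.
#' @param replicate_sd Replicate-level Gaussian noise sd (log2 scale).
#' @param batch_offsets Numeric vector, one mean log2 offset per batch;
#'   replicate r of every line is measured in batch r.
#' @param n_replicates Replicates per line/passage (>= 2).
#' @param seed Integer seed.
#' @return A `proteome_sim` object: list with `intensities` (protein x
#'   sample matrix), `samples`, `comparisons`, `truth` (gene_id, adaptation,
#'   direction), `expected_fc` (gene_id, comparison, expected_log2fc).
#' @export
simulate_cellline_proteomes <- function(catalog, panel,
                                        compensation = 0.3,
                                        adaptation_fraction = 0.02,
                                        adaptation_shift = 1,
                                        replicate_sd = 0.1,
                                        batch_offsets = NULL,
                                        n_replicates = 3,
                                        seed = 1L) {
  if (compensation < 0 || compensation > 1) abort("`compensation` must be in [0, 1].")
  assert_nonneg(replicate_sd, "replicate_sd")
  if (n_replicates < 2) abort("At least 2 replicates are required.")
  design <- panel$design
  if (!all(design$parental_id %in% design$line_id)) {
    abort("Every line needs a parental reference present in the design.")
  }
  withr::local_seed(seed)
  batch_offsets <- batch_offsets %||% seq(0, by = 0.25, length.out = n_replicates)
  if (length(batch_offsets) != n_replicates) {
    abort("`batch_offsets` must have one entry per replicate batch.")
  }

  genes <- catalog$genes
  n_genes <- nrow(genes)
  gene_arm <- paste0(genes$chromosome, genes$arm)

  # per-arm log2 dosage ratio vs parental, attenuated by compensation
  kt_wide <- panel$karyotypes |>
    mutate(lab = paste0(.data$chromosome, .data$arm)) |>
    select("line_id", "lab", "copy_number")
  cn_of <- function(line) {
    v <- filter(kt_wide, .data$line_id == line)
    setNames(v$copy_number, v$lab)
  }
  dosage_fc <- function(line, parental) {
    (1 - compensation) * log2(cn_of(line)[gene_arm] / cn_of(parental)[gene_arm])
  }

  n_adapt <- round(adaptation_fraction * n_genes)
  adapt_idx <- sample.int(n_genes, n_adapt)
  direction <- integer(n_genes)
  direction[adapt_idx] <- rep_len(c(1L, -1L), n_adapt)
  truth <- tibble(
    gene_id = genes$gene_id,
    adaptation = direction != 0L,
    direction = direction
  )

  base_abund <- rnorm(n_genes, mean = 25, sd = 2)
  # protein-specific batch effects centred on the planted batch offsets
  batch_eff <- vapply(batch_offsets, function(m) rnorm(n_genes, m, 0.05),
                      numeric(n_genes))

  poly_lines <- unique(filter(panel$comparisons, .data$group == "G1")$line_a)
  expected_shift <- function(line, passage) {
    # adaptation shift appears in polysomic lines at p0 and deepens in the
    # same direction during evolution; absent from wild-type evolution
    if (!line %in% poly_lines) return(numeric(n_genes))
    direction * adaptation_shift * (if (passage == 0) 1 else 2)
  }

  samples <- tidyr::expand_grid(design, replicate = seq_len(n_replicates)) |>
    mutate(
      sample_id = sprintf("%s_p%d_r%d", .data$line_id, .data$passage, .data$replicate),
      batch = paste0("b", .data$replicate)
    )

  expected_level <- vapply(seq_len(nrow(samples)), function(i) {
    base_abund +
      dosage_fc(samples$line_id[i], samples$parental_id[i]) +
      expected_shift(samples$line_id[i], samples$passage[i])
  }, numeric(n_genes))
  noise <- vapply(samples$replicate, function(r) {
    batch_eff[, r] + rnorm(n_genes, 0, replicate_sd)
  }, numeric(n_genes))
  intens <- expected_level + noise
  dimnames(intens) <- list(genes$gene_id, samples$sample_id)

  level_of <- function(line, passage) {
    i <- which(samples$line_id == line & samples$passage == passage)[1]
    expected_level[, i]
  }
  expected_fc <- purrr::pmap(panel$comparisons, function(comparison, line_a,
                                                        passage_a, line_b,
                                                        passage_b, group) {
    tibble(
      gene_id = genes$gene_id,
      comparison = comparison,
      group = group,
      expected_log2fc = level_of(line_a, passage_a) - level_of(line_b, passage_b)
    )
  }) |> list_rbind()

  structure(
    list(
      intensities = intens,
      samples = select(samples, "sample_id", "line_id", "passage",
                       "replicate", "batch"),
      comparisons = panel$comparisons,
      truth = truth,
      expected_fc = expected_fc
    ),
    class = "proteome_sim"
  )
}

#' @export
print.proteome_sim <- function(x, ...) {
  cat(sprintf(
    "<proteome_sim> %d proteins x %d samples; %d comparisons; %d adaptation genes\n",
    nrow(x$intensities), ncol(x$intensities), nrow(x$comparisons),
    sum(x$truth$adaptation)
  ))
  invisible(x)
}

#' Simulate luminescence growth curves
#'
#' Raw relative light units follow
#' `RLU(t) = baseline + amplitude * (exp(rate * t) - 1) * exp(eps)`, with
#' `eps ~ N(0, sdlog)` lognormal measurement noise on the growth term
#' (`sdlog` chosen so the noise coefficient of variation equals `cv`).
#' Replicate traces share the deterministic trend; every line is measured in
#' every experimental run.
#'
#' @param rates Named numeric vector of exponential growth rates per hour,
#'   one entry per cell line.
#' @param times Measurement times in hours (>= 2 timepoints, non-negative).
#' @param baseline Seeding-density RLU offset at time 0.
#' @param amplitude Scale of the exponential growth term; a scalar shared by
#'   all lines, or a named vector matching `rates`.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Technical replicates per timepoint.
#' @param n_runs Independent experimental runs.
#' @param seed Integer seed.
#' @return A `growth_sim` object: list with `curves` (tibble: sample_id,
#'   run_id, time_h, replicate, rlu) and `truth` (tibble: sample_id,
#'   true_auc — trapezoid area of the noise-free normalized curve).
#' @export
simulate_growth_curves <- function(rates, times = seq(0, 120, by = 24),
                                   baseline = 1000, amplitude = 2000,
                                   cv = 0.05, n_replicates = 3, n_runs = 2,
                                   seed = 1L) {
  if (length(times) < 2) abort("At least 2 timepoints are required.")
  if (any(times < 0)) abort("Times must be non-negative.")
  if (is.null(names(rates))) abort("`rates` must be a named vector of lines.")
  assert_nonneg(cv, "cv")
  withr::local_seed(seed)
  times <- sort(times)
  sdlog <- sqrt(log(1 + cv^2))
  amp <- if (length(amplitude) == 1) setNames(rep(amplitude, length(rates)),
                                              names(rates)) else amplitude
  if (!all(names(rates) %in% names(amp))) {
    abort("`amplitude` must be a scalar or named like `rates`.")
  }

  curves <- tidyr::expand_grid(
    sample_id = names(rates),
    run_id = paste0("run", seq_len(n_runs)),
    time_h = times,
    replicate = seq_len(n_replicates)
  ) |>
    mutate(
      trend = unname(amp[.data$sample_id] *
                       (exp(rates[.data$sample_id] * .data$time_h) - 1)),
      rlu = baseline + .data$trend * exp(rnorm(n(), 0, sdlog))
    ) |>
    select(-"trend")

  truth <- tibble(
    sample_id = names(rates),
    true_auc = map_dbl(names(rates), function(l) {
      trapezoid_area(times, amp[[l]] * (exp(rates[[l]] * times) - 1))
    })
  )
  structure(list(curves = curves, truth = truth), class = "growth_sim")
}

#' Simulate a binned copy-number profile
#'
#' Tiles every chromosome of the catalog with fixed-width bins and assigns
#' each bin the log2 ratio of its arm's copy number plus Gaussian noise —
#' the input expected by [segment_profile()].
#'
#' @param kt A [karyotype()] tibble.
#' @param catalog A [make_genome()] catalog.
#' @param bin_size Bin width in bp (> 0).
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param seed Integer seed.
#' @param sample_id Sample label carried through to the output.
#' @return Tibble (sample_id, chromosome, start, end, log2_ratio); bins are
#'   0-based half-open and tile each chromosome.
#' @export
simulate_binned_profile <- function(kt, catalog, bin_size = 1e6,
                                    noise_sd = 0.1, seed = 1L,
                                    sample_id = "S1") {
  if (bin_size <= 0) abort("`bin_size` must be > 0.")
  assert_nonneg(noise_sd, "noise_sd")
  withr::local_seed(seed)

  arm_ratio <- setNames(kt$log2_ratio, paste0(kt$chromosome, kt$arm))
  # bins tile each arm, so arm boundaries always fall on bin edges
  bins <- purrr::pmap(catalog$arms, function(chromosome, arm, start, end) {
    bs <- seq(start, end - 1, by = bin_size)
    ratio <- arm_ratio[[paste0(chromosome, arm)]]
    tibble(chromosome = chromosome, start = bs, end = pmin(bs + bin_size, end),
           log2_ratio = ratio)
  }) |> list_rbind()

  sid <- sample_id
  bins |>
    mutate(
      sample_id = sid,
      log2_ratio = .data$log2_ratio + rnorm(n(), 0, noise_sd),
      .before = 1
    )
}
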