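# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are coded straight from first principles, without reusing
# package internals.

# mean-difference enrichment score by explicit loops
oracle_enrich_score <- function(ranks, members) {
  s_in <- 0; n_in <- 0; s_out <- 0; n_out <- 0
  for (i in seq_along(ranks)) {
    if (members[i]) { s_in <- s_in + ranks[i]; n_in <- n_in + 1 }
    else { s_out <- s_out + ranks[i]; n_out <- n_out + 1 }
  }
  s_in / n_in - s_out / n_out
}

# relevance score by explicit per-protein loops
oracle_relevance <- function(R, groups) {
  vapply(seq_len(nrow(R)), function(i) {
    g1 <- R[i, groups == "G1"]
    g2 <- R[i, groups == "G2"]
    g3 <- R[i, groups == "G3"]
    s2 <- sum(g2)
    pen <- 0
    if (s2 != 0 && length(g3)) {
      same <- g3[sign(g3) == sign(s2)]
      if (length(same)) pen <- same[which.max(abs(same))]
    }
    abs(sum(g1) + s2 - pen)
  }, numeric(1))
}

# exact upper-tail hypergeometric probability by enumerating all k-subsets
oracle_hyper_upper <- function(N, m, k, q) {
  hits <- utils::combn(N, k, function(s) sum(s <= m) >= q)
  mean(hits)
}

# tiny genome shared by many tests
tiny_genome <- function(seed = 11) make_genome(3, 10, seed = seed)

# raw (linear-scale) intensity tibble from a proteome simulation
raw_from_sim <- function(sim) {
  dplyr::mutate(tibble::as_tibble(2^sim$intensities),
                protein_id = rownames(sim$intensities), .before = 1)
}

# tumor cohort with a uniform planted delta on gained arms
scaling_fixture <- function(true_delta, n_side = 50, sd = 0.2, seed = 1,
                            n_genes = 60) {
  gn <- make_genome(2, n_genes / 4, seed = 99)
  patients <- paste0("P", seq_len(2 * n_side))
  gained_pat <- patients[seq_len(n_side)]
  set.seed(seed)
  deltas <- matrix(rnorm(n_genes * 2 * n_side, 0, sd), nrow = n_genes,
                   dimnames = list(gn$genes$gene_id, patients))
  deltas[, gained_pat] <- deltas[, gained_pat] + true_delta
  arm_gains <- tidyr::expand_grid(patient_id = patients,
                                  gn$arms[c("chromosome", "arm")]) |>
    dplyr::mutate(gained = patient_id %in% gained_pat)
  list(gn = gn, deltas = deltas, arm_gains = arm_gains)
}
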