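grs_from_matrix <- function(R, groups) {
  structure(list(ranks = R, groups = groups), class = "grouped_rank_set")
}

test_that("relevance scores reproduce hand-worked cases", {
  # G1={0.5}, G2={0.4,0.6}, G3={0.2,-0.3}: sum2=1.0>0, penalty=0.2 -> 1.3
  R1 <- matrix(c(0.5, 0.4, 0.6, 0.2, -0.3), nrow = 1,
               dimnames = list("p1", NULL))
  g1 <- c("G1", "G2", "G2", "G3", "G3")
  expect_equal(relevance_scores(R1, g1)$score, 1.3)

  # G1={-0.5}, G2={-0.4}, G3={0.3}: negative sum, no negative G3 -> 0.9
  R2 <- matrix(c(-0.5, -0.4, 0.3), nrow = 1, dimnames = list("p1", NULL))
  expect_equal(relevance_scores(R2, c("G1", "G2", "G3"))$score, 0.9)

  # all-zero ranks score 0; sign(0) matches nothing so no penalty applies
  R0 <- matrix(0, nrow = 1, ncol = 4, dimnames = list("p1", NULL))
  expect_equal(relevance_scores(R0, c("G1", "G2", "G3", "G3"))$score, 0)
})

test_that("relevance scores match an independent evaluator on random cases", {
  set.seed(8)
  for (i in 1:20) {
    n_comp <- sample(3:5, 1)
    groups <- c("G1", "G2", "G3",
                sample(c("G1", "G2", "G3"), n_comp - 3, replace = TRUE))
    R <- matrix(runif(10 * n_comp, -1, 1), nrow = 10,
                dimnames = list(paste0("p", 1:10), NULL))
    expect_equal(relevance_scores(R, groups)$score,
                 oracle_relevance(R, groups), tolerance = 1e-12)
  }
})

test_that("scores are invariant to comparison order within a group", {
  set.seed(9)
  R <- matrix(runif(8 * 5, -1, 1), nrow = 8)
  groups <- c("G1", "G1", "G2", "G2", "G3")
  shuffled <- R[, c(2, 1, 4, 3, 5)]
  expect_equal(relevance_scores(R, groups)$score,
               relevance_scores(shuffled, groups)$score)
})

test_that("growing the same-sign control penalty never raises the score when signs agree", {
  set.seed(10)
  checked <- 0
  for (i in 1:400) {
    g1 <- runif(1, -1, 1); g2 <- runif(2, -1, 1); g3 <- runif(1, -1, 1)
    s2 <- sum(g2)
    if (s2 == 0 || sign(g1 + s2) != sign(s2) || sign(g3) != sign(s2)) next
    # grow the penalty without letting it overshoot past the sum
    cap <- min(1, abs(g1 + s2))
    if (abs(g3) >= cap) next
    bigger <- sign(g3) * runif(1, abs(g3), cap)
    base <- relevance_scores(matrix(c(g1, g2, g3), nrow = 1),
                             c("G1", "G2", "G2", "G3"))$score
    grown <- relevance_scores(matrix(c(g1, g2, bigger), nrow = 1),
                              c("G1", "G2", "G2", "G3"))$score
    expect_lte(round(grown - base, 12), 0)
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("empirical p-values hit their formula limits deterministically", {
  set.seed(11)
  groups <- c("G1", rep("G2", 6), "G3")
  R <- scale_ranks(matrix(rnorm(30 * 8), nrow = 30,
                          dimnames = list(paste0("p", 1:30), NULL)))
  # plant one protein at the extreme of every G1/G2 column: its score (7) is
  # only attainable by a permutation aligning all seven extremes on one
  # protein, which no finite run will draw
  R[1, ] <- c(rep(1, 7), 0)
  grs <- grs_from_matrix(R, groups)
  res <- empirical_pvalues(grs, n_perm = 400, seed = 3)
  top <- res[res$gene_id == "p1", ]
  expect_equal(top$p_value, 1 / 401)

  # a zero score can never beat the nonnegative null: p = 1
  Rz <- R; Rz[2, ] <- 0
  rz <- empirical_pvalues(grs_from_matrix(Rz, groups),
                          n_perm = 200, seed = 4)
  expect_equal(rz$p_value[rz$gene_id == "p2"], 1)

  expect_identical(empirical_pvalues(grs, n_perm = 200, seed = 5),
                   empirical_pvalues(grs, n_perm = 200, seed = 5))
  expect_warning(empirical_pvalues(grs, n_perm = 50, seed = 1), "100 permutations")
})

test_that("planted adaptation genes top the relevance ranking end to end", {
  gn <- make_genome(4, 25, seed = 2)
  panel <- polysomy_design(gn, c(chr1 = 3, chr2 = 4))
  sim <- simulate_cellline_proteomes(gn, panel, replicate_sd = 0.1, seed = 6)
  im <- preprocess_intensities(raw_from_sim(sim), sim$samples)
  fc <- diff_abundance_design(im, sim$comparisons)
  grs <- group_fold_change_ranks(fc)
  scores <- relevance_scores(grs)
  ord <- scores$gene_id[order(-scores$score)]
  planted <- sim$truth$gene_id[sim$truth$adaptation]
  med_rank <- median(match(planted, ord))
  expect_lte(med_rank, 0.1 * nrow(scores))
})
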