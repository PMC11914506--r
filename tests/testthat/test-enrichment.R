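test_that("rank scaling maps extremes to +/-1 and handles ties", {
  expect_equal(scale_ranks(c(5, 1, 3)), c(1, -1, 0))
  # invariant to strictly monotone transforms
  x <- c(2.3, -1, 0.5, 7)
  expect_equal(scale_ranks(exp(x)), scale_ranks(x))
  # two-way tie at the top of n = 4: average rank 3.5 -> 2/3
  expect_equal(scale_ranks(c(1, 2, 3, 3)), c(-1, -1 / 3, 2 / 3, 2 / 3))
  # tie-free columns are mean-centred by symmetry
  set.seed(1)
  m <- matrix(rnorm(40), ncol = 2)
  expect_equal(colMeans(scale_ranks(m)), c(0, 0), tolerance = 1e-12)
  expect_warning(one <- scale_ranks(1.5), "one item")
  expect_equal(one, 0)
})

test_that("1D enrichment equals the brute-force mean difference on all subsets", {
  ranks <- scale_ranks(c(-1, -1 / 3, 1 / 3, 1))
  top2 <- enrich_1d(ranks, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(top2$score, 4 / 3)

  set.seed(2)
  r12 <- scale_ranks(rnorm(12))
  all_bits <- seq_len(2^12 - 2)
  got <- want <- numeric(length(all_bits))
  for (bits in all_bits) {
    members <- as.logical(bitwAnd(bits, 2^(0:11)))
    got[bits] <- enrich_1d(r12, members)$score
    want[bits] <- oracle_enrich_score(r12, members)
  }
  expect_equal(got, want, tolerance = 1e-12)

  balanced <- c(-1, 1, -0.5, 0.5)
  expect_equal(enrich_1d(balanced, c(TRUE, TRUE, FALSE, FALSE))$score, 0)
  expect_error(enrich_1d(r12, rep(TRUE, 12)), "proper subset")
  expect_error(enrich_1d(r12, rep(FALSE, 12)), "proper subset")
})

test_that("ND enrichment reduces to 1D and flags collinearity", {
  set.seed(3)
  r <- scale_ranks(rnorm(50))
  members <- c(rep(TRUE, 10), rep(FALSE, 40))
  one <- enrich_1d(r, members)
  nd <- enrich_nd(matrix(r, ncol = 1), members)
  expect_equal(nd$p_value, one$p_value, tolerance = 1e-12)
  expect_equal(nd$score, one$score)

  dup <- cbind(a = r, b = r)
  expect_error(enrich_nd(dup, members), "singular|collinear")
})

test_that("a planted 2D shift is detected with the right scores", {
  set.seed(4)
  n <- 1000
  vals <- cbind(d1 = rnorm(n), d2 = rnorm(n))
  idx <- 1:50
  vals[idx, ] <- vals[idx, ] + 1.8   # strong shift on both dimensions
  rk <- scale_ranks(vals)
  members <- seq_len(n) %in% idx
  res <- enrich_nd(rk, members)
  expect_lt(res$p_value[1], 1e-6)
  expect_gt(min(res$score), 0.3)
})

test_that("BH adjustment matches the reference step-up exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(1000)
    expect_identical(bh_adjust(p), p.adjust(p, "BH"))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("overrepresentation reproduces exact hypergeometric quantities", {
  # strength s = log10(N q / (k m))
  r <- overrepresentation(paste0("g", 1:100),
                          list(s = paste0("g", c(1:10, 200:239))),
                          background_size = 1000)
  expect_equal(r$overlap, 10)
  expect_equal(r$strength, log10(2), tolerance = 1e-12)

  # observed equals expected overlap: s = 0
  r0 <- overrepresentation(paste0("g", 1:100),
                           list(s = paste0("g", c(1:10, 101:190))),
                           background_size = 1000)
  expect_equal(r0$strength, 0, tolerance = 1e-12)

  # exact enumeration example: N=10, k=5, m=4, q=4 -> 6/252
  hits <- paste0("g", 1:5)
  st <- paste0("g", c(1:4))
  r4 <- overrepresentation(hits, list(s = st), background = paste0("g", 1:10))
  expect_equal(r4$p_value, 6 / 252, tolerance = 1e-12)

  # zero overlap reports NA strength, never -Inf
  rz <- overrepresentation(paste0("g", 1:5), list(s = paste0("g", 6:8)),
                           background_size = 100)
  expect_true(is.na(rz$strength))
  expect_error(overrepresentation(paste0("g", 1:20), list(s = "g1"),
                                  background_size = 10), "smaller")
})

test_that("hypergeometric p matches subset enumeration for small backgrounds", {
  set.seed(6)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    m <- sample(2:(N - 2), 1)
    k <- sample(2:(N - 2), 1)
    bg <- paste0("g", 1:N)
    hits <- sample(bg, k)
    st <- bg[1:m]
    q <- length(intersect(hits, st))
    got <- overrepresentation(hits, list(s = st), background = bg)
    expect_equal(got$p_value, oracle_hyper_upper(N, m, k, q), tolerance = 1e-12)
  }
})

test_that("set-collection enrichment recovers a planted set", {
  set.seed(7)
  vals <- cbind(a = rnorm(300), b = rnorm(300))
  rownames(vals) <- paste0("g", 1:300)
  vals[1:25, ] <- vals[1:25, ] + 2
  rk <- scale_ranks(vals)
  sets <- list(planted = paste0("g", 1:25),
               random = paste0("g", sample(300, 25)))
  res <- enrich_gene_sets(rk, sets)
  planted <- res[res$set == "planted", ]
  expect_lt(planted$fdr[1], 0.01)
  expect_true(all(planted$score > 0.3))
})
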