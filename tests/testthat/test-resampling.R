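test_that("single-gene draws respect the degenerate cases", {
  expect_identical(draw_gene_replicate(V = 5, C = 0),
                   list(multihit_drawn = 0L, any_multihit = FALSE))
  # pigeonhole: two draws from one site always collide
  set.seed(1)
  for (i in 1:10)
    expect_identical(draw_gene_replicate(V = 1, C = 2),
                     list(multihit_drawn = 1L, any_multihit = TRUE))
  expect_error(draw_gene_replicate(V = 0, C = 3), "V >= 1")
})

test_that("V=3, C=3 collision probability matches the 27-outcome enumeration", {
  # exact: P(any multihit) = 1 - 3!/3^3 = 7/9
  pmf <- enumerate_multihit_pmf(3, 3)
  p_any <- 1 - pmf[["0"]]
  expect_equal(p_any, 7 / 9)
  n <- 10000
  set.seed(33)
  hits <- replicate(n, draw_gene_replicate(3, 3)$any_multihit)
  se <- sqrt(p_any * (1 - p_any) / n)
  expect_lt(abs(mean(hits) - p_any), 3 * se)
})

test_that("closed-form expected multihit equals exhaustive enumeration for V,C <= 4", {
  for (V in 1:4) for (C in 0:4) {
    pmf <- enumerate_multihit_pmf(V, C)
    exact_mean <- sum(as.numeric(names(pmf)) * pmf)
    expect_equal(expected_multihit(V, C), exact_mean, tolerance = 1e-12,
                 info = sprintf("V=%d C=%d", V, C))
  }
})

test_that("two-tail P-values follow the doubled-tail-with-ties rule", {
  null <- 1:100
  expect_equal(two_tail_p(95, null), 0.12)  # 2 * min(6, 95) / 100
  # observed at the median of a symmetric null caps at 1
  expect_equal(two_tail_p(50.5, null), 1)
  # beyond every replicate: add-one convention, never exactly zero
  expect_equal(two_tail_p(1000, null), 2 / 101)
  expect_gt(two_tail_p(1000, null), 0)
  # infinite replicates participate in the tail counts
  expect_equal(two_tail_p(Inf, c(1, 2, Inf, Inf)), 1)
})

test_that("central band check uses inclusive empirical quantiles", {
  null <- 1:1000
  expect_true(central_band_check(500, null))
  expect_true(central_band_check(50, null))    # exactly at the 5% point
  expect_false(central_band_check(9, null))    # below the 1st percentile
  expect_false(central_band_check(999, null, level = 0.5))
})

test_that("null distribution is reproducible and gene-order invariant", {
  s <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  strand = c("leading", "leading", "lagging", "lagging"),
                  V = c(10, 8, 12, 5), C = c(4, 6, 7, 3),
                  multihit_sites = c(1, 0, 2, 0),
                  has_multihit = c(TRUE, FALSE, TRUE, FALSE))
  a <- null_distribution(s, n_replicates = 200, seed = 99)
  b <- null_distribution(s, n_replicates = 200, seed = 99)
  expect_identical(a[c("r_n_null", "r_g_null", "p_n", "p_g")],
                   b[c("r_n_null", "r_g_null", "p_n", "p_g")])
  shuffled <- s[c(3, 1, 4, 2), ]
  c0 <- null_distribution(shuffled, n_replicates = 200, seed = 99)
  expect_identical(a$r_n_null, c0$r_n_null)
  expect_identical(a$r_g_null, c0$r_g_null)
  d <- null_distribution(s, n_replicates = 200, seed = 100)
  expect_false(identical(a$r_n_null, d$r_n_null))
})

test_that("degenerate inputs give the neutral ratio and P = 1", {
  s <- data.frame(gene_id = c("g1", "g2"), strand = c("leading", "lagging"),
                  V = c(10, 10), C = c(1, 1), multihit_sites = c(0, 0),
                  has_multihit = c(FALSE, FALSE))
  nl <- null_distribution(s, n_replicates = 100, seed = 1)
  expect_true(all(nl$r_n_null == 1))  # 0/0 -> 1 by the both-zero rule
  expect_equal(nl$r_n_obs, 1)
  expect_equal(nl$p_n, 1)
  # a gene with changes but no variable sites is excluded with a warning
  s2 <- rbind(s, data.frame(gene_id = "g3", strand = "lagging", V = 0, C = 2,
                            multihit_sites = 0, has_multihit = FALSE))
  expect_warning(null_distribution(s2, n_replicates = 50, seed = 1), "excluding")
})

test_that("a guaranteed-collision lagging gene raises observed multihit by one", {
  s <- data.frame(gene_id = c("g1", "g2"), strand = c("leading", "lagging"),
                  V = c(10, 10), C = c(5, 5), multihit_sites = c(2, 1),
                  has_multihit = c(TRUE, TRUE))
  base <- null_distribution(s, n_replicates = 100, seed = 7)
  s2 <- rbind(s, data.frame(gene_id = "pin", strand = "lagging", V = 1, C = 2,
                            multihit_sites = 1, has_multihit = TRUE))
  more <- null_distribution(s2, n_replicates = 100, seed = 7)
  # observed lagging multihit numerator grows by exactly 1: 1/2 -> 2/2
  expect_equal(base$r_n_obs, 1 / 2)
  expect_equal(more$r_n_obs, 1)
  # in the null, the V=1/C=2 gene contributes one multihit site to every
  # replicate, so the lagging numerator (hence the ratio) is never zero
  expect_true(all(more$r_n_null > 0))
  expect_true(all(more$r_g_null > 0))
})

test_that("replicate sums match exhaustive enumeration for a tiny dataset", {
  # two genes, one per strand; the lagging strand's multihit-sum distribution
  # from Monte Carlo must match exact enumeration within 3 SE per outcome
  s <- data.frame(gene_id = c("lead1", "lag1"), strand = c("leading", "lagging"),
                  V = c(3, 4), C = c(3, 4), multihit_sites = c(0, 0),
                  has_multihit = c(FALSE, FALSE))
  n <- 10000
  nl <- null_distribution(s, n_replicates = n, seed = 5)
  # reconstruct per-replicate lagging multihit counts from the ratio:
  # r_n_null = lag/lead with 0/0 -> 1 and k/0 -> Inf, so recover via a
  # direct re-draw under the same per-gene stream
  lag_counts <- strandbalance:::local_seed(
    strandbalance:::gene_stream_seed(5, "lag1"),
    strandbalance:::gene_replicates_vec(4, 4, n))
  pmf <- enumerate_multihit_pmf(4, 4)
  for (k in names(pmf)) {
    p <- pmf[[k]]
    obs <- mean(lag_counts == as.integer(k))
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
  # and the replicate mean matches the closed form within 3 SE
  mu <- expected_multihit(4, 4)
  expect_lt(abs(mean(lag_counts) - mu), 3 * sd(lag_counts) / sqrt(n))
})
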