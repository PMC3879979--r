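test_that("config validation rejects bad parameters", {
  expect_error(simulation_config(variable_fraction = 1.2), "variable_fraction")
  expect_error(simulation_config(rate_multiplier_lagging = -1), "rate_multiplier")
  expect_error(simulation_config(outgroup_divergence = NaN), "outgroup_divergence")
  tr <- default_strain_tree()
  tr$edge.length[1] <- -0.1
  expect_error(simulation_config(tree = tr), "non-negative")
  tr2 <- default_strain_tree()
  tr2$edge.length <- NULL
  expect_error(simulation_config(tree = tr2), "branch lengths")
})

test_that("the no-mutation limit produces an invariant dataset", {
  cfg <- simulation_config(n_leading = 3, n_lagging = 2, gene_length = 40,
                           tree = default_strain_tree(branch_length = 0),
                           outgroup_divergence = 0, seed = 8)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$truth), 0L)
  for (aln in ds$alignments) {
    expect_equal(length(unique(aln$seqs)), 1L)  # every row identical to root
    expect_equal(sum(variable_sites(aln, "observed")), 0L)
  }
  ts <- truth_summary(ds)
  expect_true(all(ts$C == 0))
  expect_true(all(ts$multihit_sites == 0))
})

test_that("generation is deterministic in the seed, byte for byte", {
  cfg <- simulation_config(n_leading = 4, n_lagging = 4, gene_length = 80,
                           seed = 42)
  a <- generate_dataset(cfg)
  b <- generate_dataset(simulation_config(n_leading = 4, n_lagging = 4,
                                          gene_length = 80, seed = 42))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_dataset(simulation_config(n_leading = 4, n_lagging = 4,
                                           gene_length = 80, seed = 43))
  expect_false(identical(a$truth, c2$truth))
})

test_that("mean change count matches the Poisson branch-length expectation", {
  # single focal branch of length 0.01 (the other branch of the 2-leaf tree
  # has length 0), 1000 fully variable sites: E[C per gene] = 1000 * 0.01
  tr <- default_strain_tree(2, branch_length = 0)
  tr$edge.length[1] <- 0.01
  cfg <- simulation_config(n_leading = 1000, n_lagging = 0, gene_length = 1000,
                           tree = tr, variable_fraction = 1, n_outgroups = 0,
                           seed = 17)
  ds <- generate_dataset(cfg)
  c_per_gene <- setNames(rep(0, 1000), names(ds$alignments))
  tc <- table(ds$truth$gene_id)
  c_per_gene[names(tc)] <- tc
  mu <- 1000 * 0.01
  se <- sd(c_per_gene) / sqrt(length(c_per_gene))
  expect_lt(abs(mean(c_per_gene) - mu), 3 * se)
})

test_that("truth events stay on eligible sites and existing branches", {
  cfg <- simulation_config(n_leading = 10, n_lagging = 10, gene_length = 100,
                           variable_fraction = 0.3, seed = 13)
  ds <- generate_dataset(cfg)
  ids <- strandbalance:::branch_ids(ds$tree)
  expect_true(all(ds$truth$branch %in% ids))
  expect_true(all(ds$truth$site >= 0 & ds$truth$site < 100))
  for (id in unique(ds$truth$gene_id)) {
    ev <- ds$truth[ds$truth$gene_id == id, ]
    expect_true(all(ev$site %in% ds$eligible[[id]]))
  }
  expect_true(all(ds$truth$from != ds$truth$to))
  # strand table covers every gene exactly once
  expect_identical(sort(ds$strand_table$gene_id), sort(names(ds$alignments)))
})

test_that("lagging genes accumulate more changes as the multiplier grows", {
  mean_c <- function(mult, seed) {
    cfg <- simulation_config(n_leading = 0, n_lagging = 150, gene_length = 150,
                             rate_multiplier_lagging = mult, n_outgroups = 0,
                             seed = seed)
    ds <- generate_dataset(cfg)
    nrow(ds$truth) / 150
  }
  m1 <- mean_c(1, 19)
  m2 <- mean_c(2, 19)
  m5 <- mean_c(5, 19)
  expect_lt(m1, m2)
  expect_lt(m2, m5)
})

test_that("truth summaries follow their definitions on a hand-built dataset", {
  aln <- gene_alignment("g1", c(s1 = "AKV", s2 = "AKV", s3 = "AKV",
                                s4 = "AKV", s5 = "AKV"),
                        focal = paste0("s", 1:5), strand = "leading")
  ds <- structure(list(
    alignments = list(g1 = aln),
    strand_table = data.frame(gene_id = "g1", strand = "leading"),
    tree = default_strain_tree(),
    truth = data.frame(gene_id = character(), site = integer(),
                       branch = character(), from = character(),
                       to = character()),
    eligible = list(g1 = 0:2),
    config = NULL), class = "strand_dataset")
  ts <- truth_summary(ds)
  expect_equal(ts$C, 0L)
  expect_equal(ts$multihit_sites, 0L)
  # two events at the same site make exactly one multihit site
  ds$truth <- data.frame(gene_id = c("g1", "g1"), site = c(1L, 1L),
                         branch = c("s1", "s2"), from = c("K", "K"),
                         to = c("R", "Q"), stringsAsFactors = FALSE)
  ts2 <- truth_summary(ds)
  expect_equal(ts2$C, 2L)
  expect_equal(ts2$multihit_sites, 1L)
})

test_that("outgroup gap option introduces gaps only in outgroup rows", {
  cfg <- simulation_config(n_leading = 3, n_lagging = 0, gene_length = 60,
                           outgroup_gap_prob = 0.1, seed = 23)
  ds <- generate_dataset(cfg)
  for (aln in ds$alignments) {
    focal_chars <- unlist(strsplit(aln$seqs[aln$focal], ""))
    expect_false("-" %in% focal_chars)
  }
  og_chars <- unlist(strsplit(unlist(lapply(ds$alignments, function(a)
    a$seqs[outgroup_labels(a)])), ""))
  expect_true("-" %in% og_chars)
})

test_that("datasets round trip through plain-text files", {
  cfg <- simulation_config(n_leading = 2, n_lagging = 2, gene_length = 50,
                           n_outgroups = 2, seed = 31)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_setequal(names(back$alignments), names(ds$alignments))
  for (id in names(ds$alignments))
    expect_identical(back$alignments[[id]]$seqs, ds$alignments[[id]]$seqs)
  expect_identical(back$strand_table, ds$strand_table)
  expect_setequal(back$tree$tip.label, ds$tree$tip.label)
})
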