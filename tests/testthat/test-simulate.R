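test_that("clone mutation counts accumulate along the chain", {
  truth <- simulate_truth(n_clones = 3, truncal_muts = 15,
                          private_muts = c(0, 8, 28), seed = 1)
  counts <- rowSums(truth$clone_genotypes > 0)
  expect_equal(unname(counts[c("c1", "c2", "c3")]), c(15, 23, 43))
  expect_equal(unname(counts["normal"]), 0)
  # perfect phylogeny: every clone carries the full truncal block and
  # the private blocks are pairwise disjoint
  truncal <- truth$clone_genotypes["c1", ] > 0
  for (k in 1:3) {
    expect_true(all(truth$clone_genotypes[paste0("c", k), truncal] > 0))
  }
  priv2 <- truth$clone_genotypes["c2", ] > 0 & !truncal
  priv3 <- truth$clone_genotypes["c3", ] > 0 & !truncal
  expect_false(any(priv2 & priv3))
  # the generating tree is the caterpillar with MRCA at its base
  expect_true(all(c("MRCA", "A1", "A2") %in% truth$clone_tree$parent))
})

test_that("monoclonal truth puts every tumor mutation on the trunk", {
  truth <- simulate_truth(n_clones = 1, truncal_muts = 10,
                          private_muts = 0, n_variants = 20, seed = 2)
  expect_equal(sum(truth$clone_genotypes["c1", ] > 0), 10)
  expect_equal(sum(truth$clone_genotypes["normal", ] > 0), 0)
})

test_that("truth generation is deterministic under seed and errors on infeasible budgets", {
  t1 <- simulate_truth(seed = 99)
  t2 <- simulate_truth(seed = 99)
  expect_identical(t1, t2)
  expect_error(simulate_truth(n_variants = 10, truncal_muts = 15),
               "budget")
})

test_that("doublet counts follow the binomial law and respect edge cases", {
  truth <- simulate_truth(seed = 3)
  cells <- simulate_cells(truth, 4000, seed = 3)
  p <- truth$doublet_rate
  sd3 <- 3 * sqrt(p * (1 - p) / 4000)
  expect_lt(abs(mean(cells$is_doublet) - p), sd3)

  t0 <- simulate_truth(doublet_rate = 0, seed = 4)
  expect_false(any(simulate_cells(t0, 500, seed = 4)$is_doublet))

  t1 <- simulate_truth(n_clones = 1, clone_proportions = c(1, 0),
                       doublet_rate = 0, seed = 5)
  expect_true(all(simulate_cells(t1, 200, seed = 5)$clone == "c1"))
})

test_that("the noise-free limit reproduces truth exactly", {
  truth <- simulate_truth(n_clones = 2, n_variants = 30, n_amplicons = 40,
                          truncal_muts = 5, private_muts = c(0, 5),
                          doublet_rate = 0, cna_events = NA, seed = 6)
  cells <- simulate_cells(truth, 50, seed = 6)
  sim <- simulate_observations(truth, cells, seed = 6, noise = FALSE)
  expect_equal(unname(sim$bundle$layers$NGT),
               unname(truth$clone_genotypes[cells$clone, ]))
  # and ratio-based CN equals clone_cn / 2 after two-step normalization
  normals <- cells$cell_id[cells$clone == "normal"]
  r <- estimate_copy_ratios(sim$counts, normals)
  expect_equal(max(abs(r - 1)), 0, tolerance = 1e-12)
})

test_that("allelic dropout hits true-het sites at the configured rate", {
  truth <- simulate_truth(n_clones = 1, n_variants = 50, n_amplicons = 60,
                          truncal_muts = 0, private_muts = 0,
                          germline_het = 50, doublet_rate = 0,
                          error_rate = 0, cna_events = NA, seed = 7)
  cells <- simulate_cells(truth, 500, seed = 7)
  sim <- simulate_observations(truth, cells, seed = 7)
  ngt <- sim$bundle$layers$NGT
  obs_hom <- mean(ngt %in% c(0L, 2L)) / mean(!is.na(ngt))
  n <- sum(!is.na(ngt))
  sd3 <- 3 * sqrt(0.09 * 0.91 / n)
  expect_lt(abs(obs_hom - 0.09), sd3)
})

test_that("zero-efficiency amplicons yield all-zero columns", {
  truth <- simulate_truth(n_variants = 5, n_amplicons = 10,
                          truncal_muts = 2, private_muts = c(0, 1, 1),
                          cna_events = NA, seed = 8)
  truth$amplicon_efficiency[3] <- 0
  cells <- simulate_cells(truth, 40, seed = 8)
  sim <- simulate_observations(truth, cells, seed = 8)
  expect_true(all(sim$counts[, 3] == 0))
})

test_that("observed counts are reproducible and seeds differentiate", {
  truth <- simulate_truth(seed = 9)
  cells <- simulate_cells(truth, 100, seed = 9)
  s1 <- simulate_observations(truth, cells, seed = 10)
  s2 <- simulate_observations(truth, cells, seed = 10)
  s3 <- simulate_observations(truth, cells, seed = 11)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("mean counts converge to the stated formula", {
  truth <- simulate_truth(n_clones = 1, n_variants = 5, n_amplicons = 8,
                          truncal_muts = 1, private_muts = 0,
                          clone_proportions = c(1, 0), doublet_rate = 0,
                          capture_sigma = 0, cna_events = NA,
                          mean_depth = 100, seed = 12)
  cells <- simulate_cells(truth, 3000, seed = 12)
  sim <- simulate_observations(truth, cells, seed = 12)
  mu <- 100 * truth$amplicon_efficiency  # diploid, capture 1
  for (a in seq_len(8)) {
    x <- sim$counts[, a]
    se3 <- 3 * sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mu[a]), se3 + 1e-9)
  }
})

test_that("pseudo-bulk identities match hand computations", {
  # single diploid clone, het variant -> VAF 0.5
  t1 <- simulate_truth(n_clones = 1, n_variants = 2, n_amplicons = 2,
                       truncal_muts = 1, private_muts = 0,
                       private_ngt = 1L, truncal_ngt = 1L,
                       clone_proportions = c(1, 0), cna_events = NA,
                       seed = 13)
  pb1 <- derive_pseudobulk(t1)
  expect_equal(pb1$vaf$bulk_vaf[1], 0.5)

  # two equal clones, hom-alt (CN 2) in one, absent in other -> 0.5
  t2 <- simulate_truth(n_clones = 2, n_variants = 2, n_amplicons = 2,
                       truncal_muts = 0, private_muts = c(0, 1),
                       private_ngt = 2L,
                       clone_proportions = c(0.5, 0.5, 0),
                       cna_events = NA, seed = 14)
  pb2 <- derive_pseudobulk(t2)
  expect_equal(pb2$vaf$bulk_vaf[1], 0.5)  # (2 + 0) / (2 + 2)

  # CN mixture mean: 50/50 clones at CN 4 and CN 2 -> bulk CN 3
  t3 <- simulate_truth(n_clones = 2, n_variants = 2, n_amplicons = 2,
                       truncal_muts = 1, private_muts = c(0, 0),
                       clone_proportions = c(0.5, 0.5, 0),
                       cna_events = tibble::tibble(clone = 2, amplicon = 1,
                                                   cn = 4),
                       seed = 15)
  pb3 <- derive_pseudobulk(t3)
  expect_equal(pb3$cn$bulk_cn[1], 3.0)
})
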