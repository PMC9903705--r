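test_that("gini matches its definition on worked and random cases", {
  expect_equal(gini(rep(5, 10)), 0)
  expect_equal(gini(c(0, 0, 0, 1)), 0.75)
  set.seed(81)
  for (i in 1:25) {
    x <- rpois(sample(5:200, 1), lambda = sample(1:50, 1)) +
      (i %% 3 == 0) * runif(1)
    if (all(x == 0)) x[1] <- 1
    expect_equal(gini(x), gini_bruteforce(x), tolerance = 1e-12)
  }
})

test_that("gini is scale-invariant and rejects degenerate input", {
  set.seed(82)
  x <- rpois(50, 10)
  expect_equal(gini(3.7 * x), gini(x), tolerance = 1e-12)
  expect_error(gini(numeric(0)), "empty")
  expect_error(gini(rep(0, 5)), "all-zero")
  expect_error(gini(c(1, -1)), "non-negative")
})

test_that("amplicon success applies the 0.2 x grand-mean rule", {
  # grand mean 100: amplicon means 15 (fail), 25 (pass), 260 (pass)
  cnt <- cbind(a1 = rep(15, 50), a2 = rep(25, 50), a3 = rep(260, 50))
  rownames(cnt) <- paste0("c", 1:50)
  met <- coverage_metrics(cnt)
  expect_equal(met$amplicon_success_pct, 100 * 2 / 3)
  # constant matrix: all GI and CV zero, success 100%
  cst <- matrix(7, 20, 10, dimnames = list(paste0("c", 1:20),
                                           paste0("a", 1:10)))
  m2 <- coverage_metrics(cst)
  expect_equal(m2$gini_amplicons, 0)
  expect_equal(m2$gini_cells, 0)
  expect_equal(m2$cv_amplicons, 0)
  expect_equal(m2$cv_cells, 0)
  expect_equal(m2$amplicon_success_pct, 100)
})

test_that("the ADO estimator recovers the simulated dropout rate", {
  truth <- simulate_truth(n_clones = 1, n_variants = 50, n_amplicons = 60,
                          truncal_muts = 0, private_muts = 0,
                          germline_het = 50, doublet_rate = 0,
                          error_rate = 0, cna_events = NA, seed = 83)
  cells <- simulate_cells(truth, 800, seed = 83)
  sim <- simulate_observations(truth, cells, seed = 83)
  met <- coverage_metrics(sim$counts, sim$bundle,
                          known_het_sites = truth$germline_het_variants)
  expect_lt(abs(met$ado_pct / 100 - 0.09), 0.02)
  expect_error(coverage_metrics(sim$counts, sim$bundle,
                                known_het_sites = "nope"),
               "known het")
})

test_that("aggregated single-cell VAF matches its definition", {
  ngt <- matrix(c(0L, 1L, 2L), 3, 1,
                dimnames = list(paste0("c", 1:3), "v1"))
  ngt <- cbind(ngt, v2 = c(0L, 0L, 1L), v3 = c(2L, 2L, NA))
  b <- mpt_bundle(ngt)
  asg <- tibble::tibble(cell_id = paste0("c", 1:3), cluster = 1L,
                        role = "tumor")
  bulk <- tibble::tibble(variant_id = c("v1", "v2", "v3"),
                         bulk_vaf = c(0.5, 0.2, 0.9))
  res <- concordance(b, asg, bulk)
  # v1: (0+1+2)/(2*3) = 0.5 enters the correlation
  keep <- asg$cell_id
  sc <- colSums(ngt, na.rm = TRUE) / (2 * colSums(!is.na(ngt)))
  expect_equal(unname(sc["v1"]), 0.5)
  expect_equal(res$r_vaf, cor(sc, bulk$bulk_vaf))
})

test_that("noise-free simulations give near-perfect pseudo-bulk concordance", {
  sim <- simulate_sample(n_cells = 1500, seed = 84, doublet_rate = 0,
                         cna_events = NA, noise = FALSE)
  pb <- derive_pseudobulk(sim$truth)
  asg <- tibble::tibble(cell_id = sim$cells$cell_id, cluster = 1L,
                        role = "tumor")
  res <- concordance(sim$bundle, asg, pb$vaf)
  expect_gte(res$r_vaf, 0.999)
})

test_that("degenerate concordance inputs are refused or flagged", {
  b <- tiny_bundle()
  asg <- tibble::tibble(cell_id = b$cell_ids, cluster = 1L,
                        role = "tumor")
  expect_error(
    concordance(b, asg, tibble::tibble(variant_id = "v1",
                                       bulk_vaf = 0.5)),
    "3 shared"
  )
  ngt <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L), 3, 3,
                dimnames = list(paste0("c", 1:3), paste0("v", 1:3)))
  b3 <- mpt_bundle(ngt)
  asg3 <- tibble::tibble(cell_id = paste0("c", 1:3), cluster = 1L,
                         role = "tumor")
  const <- tibble::tibble(variant_id = paste0("v", 1:3), bulk_vaf = 0.4)
  expect_warning(res <- concordance(b3, asg3, const), "constant")
  expect_true(is.na(res$r_vaf))
})

test_that("binomial depth thinning preserves the relative amplicon profile", {
  sim <- simulate_sample(n_cells = 500, seed = 85, doublet_rate = 0)
  cnt <- sim$counts
  set.seed(85)
  p <- 0.25
  thinned <- matrix(rbinom(length(cnt), as.vector(cnt), p),
                    nrow(cnt), dimnames = dimnames(cnt))
  prof_before <- colMeans(cnt) / mean(cnt)
  prof_after <- colMeans(thinned) / mean(thinned)
  se3 <- 3 * apply(thinned, 2, sd) / (sqrt(nrow(cnt)) * mean(thinned))
  expect_true(all(abs(prof_after - prof_before) < se3 + 0.02))
})

test_that("downsampling at full scale reproduces the full-data cluster count", {
  sim <- simulate_sample(n_cells = 600, seed = 86, doublet_rate = 0)
  full_k <- detected_clusters(sim$bundle, sim$counts, sc_filter_config(),
                              8, NULL)
  ds <- downsample_experiment(sim$bundle, sim$counts, axis = "mutations",
                              levels = ncol(sim$bundle$layers$NGT),
                              seeds = 1:3)
  expect_true(all(ds$k_detected == full_k))
})

test_that("downsampling levels above the data scale warn and no-op", {
  sim <- simulate_sample(n_cells = 80, seed = 87, doublet_rate = 0)
  expect_warning(
    ds <- downsample_experiment(sim$bundle, sim$counts, axis = "cells",
                                levels = 500, seeds = 1),
    "no-op"
  )
})

test_that("cells below the minimum cluster mass cap the detectable clusters", {
  # with min_cluster_size = 20 and 50 cells, at most 2 clusters of
  # viable mass can exist; true k is 4
  sim <- simulate_sample(n_cells = 1000, seed = 88, doublet_rate = 0)
  ds <- downsample_experiment(sim$bundle, sim$counts, axis = "cells",
                              levels = 50, seeds = 1:5)
  expect_true(all(ds$k_detected <= 2))
})
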