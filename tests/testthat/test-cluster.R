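test_that("embedding separates distinct genotype blocks", {
  b <- two_block_bundle()
  emb <- embed_cells(b, seed = 5)
  labels <- rep(1:2, each = 60)
  sil <- cluster::silhouette(labels,
                             dist(as.matrix(emb[c("UMAP1", "UMAP2")])))
  expect_gt(mean(sil[, 3]), 0.9)
})

test_that("embedding is deterministic under seed and degenerate-safe", {
  b <- two_block_bundle()
  e1 <- embed_cells(b, seed = 42)
  e2 <- embed_cells(b, seed = 42)
  expect_equal(e1, e2)

  same <- mpt_bundle(matrix(1L, 20, 4,
                            dimnames = list(paste0("c", 1:20),
                                            paste0("v", 1:4))))
  e3 <- embed_cells(same, seed = 1)
  expect_true(all(e3$UMAP1 == 0) && all(e3$UMAP2 == 0))
  expect_error(embed_cells(tiny_bundle()[, 1]), "2 variants")
})

test_that("clustering recovers clear clonal structure with correct roles", {
  sim <- simulate_sample(n_cells = 800, seed = 51, doublet_rate = 0)
  fb <- filter_single_cell_matrix(sim$bundle)$bundle
  cl <- cluster_cells(fb)
  expect_equal(cl$k, 4)
  m <- merge(cl$assignment, sim$cells, by = "cell_id")
  ari <- mclust::adjustedRandIndex(m$cluster, m$clone)
  expect_gte(ari, 0.95)
  # the normal role lands on the cluster dominated by diploid cells
  norm_cl <- cl$sizes$cluster[cl$sizes$role == "normal"]
  expect_equal(names(which.max(table(
    m$clone[m$cluster == norm_cl]))), "normal")
})

test_that("forced k and degenerate inputs behave as specified", {
  b <- two_block_bundle()
  cl1 <- cluster_cells(b, k = 1)
  expect_equal(cl1$k, 1)
  expect_equal(unique(cl1$assignment$cluster), 1L)

  same <- mpt_bundle(matrix(2L, 30, 4,
                            dimnames = list(paste0("c", 1:30),
                                            paste0("v", 1:4))))
  expect_error(cluster_cells(same, k = 2), "identical")
  expect_error(cluster_cells(b[1, ]), "2 cells")
})

test_that("small stray groups are labelled outlier", {
  set.seed(52)
  main <- matrix(rnorm(200 * 5), 200, 5)
  stray <- matrix(rnorm(5 * 5, mean = 50), 5, 5)
  x <- rbind(main, stray)
  rownames(x) <- sprintf("c%03d", seq_len(nrow(x)))
  cl <- cluster_cells(x, k = 2, min_cluster_size = 20)
  expect_true(all(cl$assignment$role[201:205] == "outlier"))
  expect_true(all(cl$assignment$role[1:200] != "outlier"))
})

test_that("cluster labels are invariant to cell order", {
  set.seed(53)
  x <- rbind(matrix(rnorm(100 * 6), 100, 6),
             matrix(rnorm(80 * 6, mean = 8), 80, 6))
  rownames(x) <- sprintf("c%03d", 1:180)
  cl1 <- cluster_cells(x, k = 2)
  perm <- sample(1:180)
  cl2 <- cluster_cells(x[perm, ], k = 2)
  m <- merge(cl1$assignment, cl2$assignment, by = "cell_id")
  expect_equal(mclust::adjustedRandIndex(m$cluster.x, m$cluster.y), 1)
})

test_that("noise-free data yields one cluster per distinct genotype profile", {
  sim <- simulate_sample(n_cells = 400, seed = 54, doublet_rate = 0,
                         noise = FALSE)
  b <- sim$bundle
  cl <- cluster_cells(b, min_cluster_size = 2)
  n_profiles <- nrow(unique(as.data.frame(b$layers$NGT)))
  expect_equal(cl$k, n_profiles)
})

test_that("consensus genotypes use the modal non-missing code with low ties", {
  ngt <- matrix(NA_integer_, 10, 3,
                dimnames = list(paste0("c", 1:10), c("v1", "v2", "v3")))
  ngt[, "v1"] <- c(rep(2L, 9), NA)            # 90% hom, 10% missing
  ngt[, "v2"] <- rep(c(1L, 2L), 5)            # 50/50 tie of 1 and 2
  # v3 left all-missing
  b <- mpt_bundle(ngt)
  asg <- tibble::tibble(cell_id = paste0("c", 1:10), cluster = 1L,
                        role = "tumor")
  prof <- consensus_profiles(b, asg)
  expect_equal(prof$consensus_ngt[prof$variant_id == "v1"], 2L)
  expect_equal(prof$consensus_ngt[prof$variant_id == "v2"], 1L)
  expect_true(is.na(prof$consensus_ngt[prof$variant_id == "v3"]))
  expect_true(is.na(prof$frac_mutated[prof$variant_id == "v3"]))
})

test_that("consensus equals truth for sizeable clusters despite dropout", {
  sim <- simulate_sample(n_cells = 600, seed = 55, doublet_rate = 0)
  cl_truth <- tibble::tibble(
    cell_id = sim$cells$cell_id,
    cluster = as.integer(factor(sim$cells$clone)),
    role = ifelse(sim$cells$clone == "normal", "normal", "tumor")
  )
  prof <- consensus_profiles(sim$bundle, cl_truth)
  clone_of <- levels(factor(sim$cells$clone))
  sizes <- table(cl_truth$cluster)
  for (g in names(sizes)[sizes >= 30]) {
    truth_g <- sim$truth$clone_genotypes[clone_of[as.integer(g)], ]
    got <- prof$consensus_ngt[prof$cluster == as.integer(g)]
    names(got) <- prof$variant_id[prof$cluster == as.integer(g)]
    expect_equal(unname(got[names(truth_g)]), unname(truth_g))
  }
})

test_that("consensus of identical clusters merged equals each part", {
  b <- two_block_bundle()
  asg_split <- tibble::tibble(
    cell_id = b$cell_ids,
    cluster = rep(c(1L, 2L), each = 60), role = "tumor"
  )
  asg_split$cluster[1:30] <- 3L  # split block 1 into clusters 3 and 1
  prof <- consensus_profiles(b, asg_split)
  p1 <- prof$consensus_ngt[prof$cluster == 1]
  p3 <- prof$consensus_ngt[prof$cluster == 3]
  expect_equal(p1, p3)
})
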