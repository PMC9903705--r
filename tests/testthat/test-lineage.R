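test_that("NJ recovers the worked 4-taxon clonal topology", {
  # normal = all reference; c3 carries 15 truncal; c1 adds 5 privates;
  # c2 adds 8 different privates (all mutations homozygous)
  m <- matrix(0L, 4, 28,
              dimnames = list(c("normal", "c3", "c1", "c2"), NULL))
  m["c3", 1:15] <- 2L
  m["c1", c(1:15, 16:20)] <- 2L
  m["c2", c(1:15, 21:28)] <- 2L
  colnames(m) <- paste0("v", 1:28)
  lin <- build_nj_tree(m, normal = "normal")
  tree <- lin$tree
  # topology (normal,(c3,(c1,c2)))
  expect_true(ape::is.monophyletic(tree, c("c1", "c2")))
  expect_true(ape::is.monophyletic(tree, c("c1", "c2", "c3")))
  # MRCA is the ancestor of all three tumor leaves
  expect_equal(sort(ape::extract.clade(tree, lin$mrca_node)$tip.label),
               c("c1", "c2", "c3"))
})

test_that("truncal mutations land on the root-to-MRCA branch", {
  m <- matrix(0L, 4, 28,
              dimnames = list(c("normal", "c3", "c1", "c2"),
                              paste0("v", 1:28)))
  m["c3", 1:15] <- 2L
  m["c1", c(1:15, 16:20)] <- 2L
  m["c2", c(1:15, 21:28)] <- 2L
  prof <- tibble::tibble(
    cluster = rep(rownames(m), each = 28),
    role = rep(c("normal", "tumor", "tumor", "tumor"), each = 28),
    variant_id = rep(colnames(m), 4),
    consensus_ngt = as.integer(t(m)),
    frac_mutated = as.numeric(t(m) > 0),
    n_cells = 100L, n_genotyped = 100L
  )
  class(prof) <- c("mpt_profiles", class(prof))
  lin <- build_nj_tree(prof, normal = "normal")
  lin <- annotate_lineage_events(lin, prof)
  ev <- lin$events
  truncal <- ev$id[ev$truncal]
  expect_equal(sort(truncal), sort(paste0("v", 1:15)))
  expect_true(all(ev$branch_node[ev$truncal] == "MRCA"))
  # c1 privates sit on the branch above the c1 leaf
  expect_true(all(ev$branch_node[ev$id %in% paste0("v", 16:20)] == "c1"))
  expect_true(all(ev$branch_node[ev$id %in% paste0("v", 21:28)] == "c2"))
  # event accounting: every mutant variant appears exactly once
  expect_equal(sort(unique(ev$id[ev$type == "mutation"])),
               sort(paste0("v", 1:28)))
  expect_equal(nrow(ev[ev$type == "mutation", ]), 28)
})

test_that("NJ reconstructs random additive matrices (vs exhaustive search)", {
  for (s in 1:15) {
    n_leaves <- 4 + s %% 2
    ref <- random_additive_matrix(n_leaves, seed = s)
    lin <- build_nj_tree(ref$d, normal = attr(ref$d, "Labels")[1])
    expect_equal(phylo_splits(lin$tree), nj_exhaustive_best(ref$d),
                 info = paste("seed", s))
    # and NJ reproduces the generating tree itself
    expect_equal(phylo_splits(lin$tree), ref$splits,
                 info = paste("gen seed", s))
  }
})

test_that("identical clusters are joined by a zero-length branch", {
  m <- rbind(normal = rep(0L, 10), a = rep(2L, 10), b = rep(2L, 10),
             c = c(rep(2L, 5), rep(0L, 5)))
  colnames(m) <- paste0("v", 1:10)
  lin <- build_nj_tree(m, normal = "normal")
  cop <- ape::cophenetic.phylo(lin$tree)
  expect_equal(cop["a", "b"], 0)
})

test_that("two-taxon input degenerates with a warning", {
  m <- rbind(normal = rep(0L, 6), t1 = rep(2L, 6))
  colnames(m) <- paste0("v", 1:6)
  expect_warning(lin <- build_nj_tree(m, normal = "normal"), "2-leaf")
  expect_equal(sort(lin$tree$tip.label), c("normal", "t1"))
})

test_that("subclonal CNA events are placed on the carrying clade", {
  m <- matrix(0L, 4, 6,
              dimnames = list(c("normal", "c3", "c1", "c2"),
                              paste0("v", 1:6)))
  m["c3", 1] <- 2L; m["c1", 1:3] <- 2L; m["c2", c(1, 4:6)] <- 2L
  prof <- tibble::tibble(
    cluster = rep(rownames(m), each = 6),
    role = rep(c("normal", "tumor", "tumor", "tumor"), each = 6),
    variant_id = rep(colnames(m), 4),
    consensus_ngt = as.integer(t(m)),
    frac_mutated = as.numeric(t(m) > 0),
    n_cells = 100L, n_genotyped = 100L
  )
  class(prof) <- c("mpt_profiles", class(prof))
  lin <- build_nj_tree(prof, normal = "normal")
  cn <- tibble::tibble(
    cluster = rep(c("c3", "c1", "c2"), each = 2),
    role = "tumor",
    amplicon_id = rep(c("ampA", "ampB"), 3),
    median_ratio = c(1, 1, 0.7, 1, 0.7, 1),
    log2_ratio = log2(c(1, 1, 0.7, 1, 0.7, 1)),
    call = c("neutral", "neutral", "loss", "neutral", "loss", "neutral")
  )
  lin <- annotate_lineage_events(lin, prof, cn)
  cna <- lin$events[lin$events$type == "cna", ]
  # loss in c1 and c2 but not their relative c3: placed at their MRCA
  expect_equal(nrow(cna), 1)
  expect_equal(cna$call, "loss")
  got_node <- cna$branch_node
  tips <- ape::extract.clade(
    lin$tree,
    length(lin$tree$tip.label) +
      match(got_node, lin$tree$node.label))$tip.label
  expect_true(setequal(intersect(tips, c("c1", "c2", "c3")),
                       c("c1", "c2")) || cna$conflict)
})

test_that("non-clade mutation patterns are flagged as conflicts", {
  m <- matrix(0L, 4, 3,
              dimnames = list(c("normal", "a", "b", "c"),
                              paste0("v", 1:3)))
  m["a", 1] <- 2L; m["a", 2] <- 2L; m["b", 2] <- 2L
  m["b", 3] <- 2L; m["c", 1] <- 2L  # v1 in a and c: check clade-ness
  prof <- tibble::tibble(
    cluster = rep(rownames(m), each = 3),
    role = rep(c("normal", "tumor", "tumor", "tumor"), each = 3),
    variant_id = rep(colnames(m), 4),
    consensus_ngt = as.integer(t(m)),
    frac_mutated = as.numeric(t(m) > 0),
    n_cells = 50L, n_genotyped = 50L
  )
  class(prof) <- c("mpt_profiles", class(prof))
  lin <- build_nj_tree(prof, normal = "normal")
  expect_warning(lin <- annotate_lineage_events(lin, prof),
                 "perfect phylogeny")
  ev <- lin$events
  expect_true(any(ev$conflict))
  expect_equal(sum(ev$type == "mutation"), 3)
})

test_that("impact ranking applies the PolyPhen/SIFT gate and CADD order", {
  v <- tibble::tibble(
    gene = paste0("G", 1:5),
    polyphen = c(0.9, 0.5, NA, 0.95, 0.2),
    sift = c(0.5, 0.3, 0.05, 0.1, NA),
    cadd = c(24, 18, 33, 12, 28)
  )
  r <- rank_deleterious(v)
  # G1 passes by polyphen; G2 fails both ((1-sift)=0.7); G3 passes by
  # sift; G4 passes; G5 fails (missing sift, low polyphen)
  expect_equal(r$pass[match(paste0("G", 1:5), r$gene)],
               c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(r$gene[which(r$rank == 1)], "G3")  # highest CADD passer
  expect_equal(r$cadd_band[match(c("G3", "G1", "G4"), r$gene)],
               c("top 0.1%", "top 1%", "top 10%"))
})

test_that("only the top 30 passers are retained", {
  v <- tibble::tibble(
    gene = paste0("G", 1:40), polyphen = 0.9, sift = 0.5,
    cadd = seq(40, 1.25, length.out = 40)
  )
  r <- rank_deleterious(v)
  expect_equal(sum(!is.na(r$rank)), 30)
  expect_equal(sum(r$pass), 30)
  expect_equal(r$gene[which(r$rank == 30)], "G30")
})

test_that("newick export writes the tree and its event table", {
  m <- matrix(0L, 4, 10,
              dimnames = list(c("normal", "c3", "c1", "c2"),
                              paste0("v", 1:10)))
  m["c3", 1:4] <- 2L; m["c1", 1:7] <- 2L; m["c2", c(1:4, 8:10)] <- 2L
  prof <- tibble::tibble(
    cluster = rep(rownames(m), each = 10),
    role = rep(c("normal", "tumor", "tumor", "tumor"), each = 10),
    variant_id = rep(colnames(m), 4),
    consensus_ngt = as.integer(t(m)),
    frac_mutated = as.numeric(t(m) > 0),
    n_cells = 10L, n_genotyped = 10L
  )
  class(prof) <- c("mpt_profiles", class(prof))
  lin <- annotate_lineage_events(build_nj_tree(prof), prof)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_lineage_newick(lin, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, rownames(m))
  ev <- readr::read_tsv(paste0(path, ".events.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(ev), nrow(lin$events))
})
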