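# Shared small fixtures, built in code.

# tiny bundle with explicit layers
tiny_bundle <- function() {
  ngt <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), 3, 2,
                dimnames = list(paste0("c", 1:3), paste0("v", 1:2)))
  dp <- matrix(20L, 3, 2, dimnames = dimnames(ngt))
  gq <- matrix(90L, 3, 2, dimnames = dimnames(ngt))
  af <- matrix(c(0, 0.5, 1, 0.5, 0.55, 0.01), 3, 2,
               dimnames = dimnames(ngt))
  mpt_bundle(ngt, dp = dp, gq = gq, af = af)
}

# genotype bundle with two perfectly separated genotype blocks
two_block_bundle <- function(n_per = 60, n_var = 20, seed = 7) {
  set.seed(seed)
  g1 <- matrix(0L, n_per, n_var)
  g2 <- matrix(2L, n_per, n_var)
  ngt <- rbind(g1, g2)
  dimnames(ngt) <- list(sprintf("cell%03d", seq_len(2 * n_per)),
                        sprintf("v%02d", seq_len(n_var)))
  mpt_bundle(ngt)
}

# the hand-enumerated 10-cell x 8-variant cascade fixture:
# one violation of each cascade rule (see test-qc for the enumeration)
cascade_fixture <- function() {
  cells <- paste0("c", sprintf("%02d", 1:10))
  vars <- paste0("v", 1:8)
  ngt <- matrix(1L, 10, 8, dimnames = list(cells, vars))
  dp <- matrix(50L, 10, 8, dimnames = list(cells, vars))
  gq <- matrix(90L, 10, 8, dimnames = list(cells, vars))
  af <- matrix(0.5, 10, 8, dimnames = list(cells, vars))

  # v1 is the healthy variant: make it clearly polymorphic, not germline
  ngt[, "v1"] <- c(rep(1L, 5), rep(0L, 5))
  # stage 1a: single entry with low GQ -> masked
  gq["c01", "v1"] <- 25L
  # stage 1b: single entry with low DP -> masked
  dp["c02", "v1"] <- 5L
  # stage 1c: alt call with AF below 20% -> masked
  af["c03", "v1"] <- 0.10
  ngt["c03", "v1"] <- 1L
  # stage 2: v2 genotyped in only 4/10 cells (< 50%)
  ngt[5:10, "v2"] <- NA_integer_
  ngt[1:4, "v2"] <- c(1L, 1L, 0L, 0L)
  # stage 4: v3 mutated in 0/10 genotyped cells (< 1%)
  ngt[, "v3"] <- 0L
  # stage 5: v4 heterozygous in 10/10 genotyped cells (> 95%) -> germline
  ngt[, "v4"] <- 1L
  # v5..v8 healthy polymorphic variants
  for (v in c("v5", "v6", "v7", "v8")) ngt[, v] <- c(rep(2L, 6), rep(0L, 4))
  # stage 3: cell c10 genotyped at < 50% of variants
  # (with v2 already NA for c10, NAs at v1, v5, v6, v7 leave 3/7 after
  # v2 is dropped)
  ngt["c10", c("v1", "v5", "v6", "v7")] <- NA_integer_
  # stage 6: cell c09 has NAs concentrated in surviving variants; its
  # missingness only crosses 50% (3/5) after stages 4-5 drop v3 and v4
  ngt["c09", c("v5", "v6", "v7")] <- NA_integer_
  mpt_bundle(ngt, dp = dp, gq = gq, af = af)
}

# expected cascade outcome, enumerated by hand:
#   stage 1 masks 3 entries (c01/v1 GQ, c02/v1 DP, c03/v1 AF)
#   stage 2 drops v2 (4/10 genotyped)
#   stage 3 drops c10 (3/7 variants genotyped)
#   stage 4 drops v3 (0% mutated)
#   stage 5 drops v4 (100% het germline)
#   stage 6 drops c09 (3/5 missing after v3/v4 removal)
#   final matrix: 8 cells x 5 variants (v1, v5, v6, v7, v8)
cascade_expected <- function() {
  list(
    masked = 3L,
    removals = tibble::tibble(
      stage = c(2L, 3L, 4L, 5L, 6L),
      axis = c("variant", "cell", "variant", "variant", "cell"),
      id = c("v2", "c10", "v3", "v4", "c09")
    ),
    final_cells = paste0("c", sprintf("%02d", 1:8)),
    final_variants = c("v1", "v5", "v6", "v7", "v8")
  )
}
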