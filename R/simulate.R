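#' Simulate the ground truth of a clonally structured tumor sample
#'
#' Builds the generative truth for a targeted single-cell DNA-seq sample:
#' a diploid normal population plus tumor subclones hanging off a
#' caterpillar ancestor chain (root - MRCA - A1 - A2 - ...), related by
#' perfect phylogeny with no back mutation. Truncal mutations are shared
#' by all tumor clones; each clone additionally carries its own disjoint
#' private mutation block, so clone k holds `truncal + private[k]`
#' mutations. Copy-number events with `clone = 1` are truncal (carried by
#' every tumor clone); events with `clone = k > 1` arise on the ancestor
#' branch above clone k's divergence and are carried by clones `k..K`.
#'
#' Defaults emulate the conditions of a multi-patient targeted breast
#' tumor run: ~330 amplicons at ~164x mean depth, ~9% allelic dropout,
#' ~8% doublets, a 20% diploid fraction and three subclones carrying
#' 15 truncal plus 0/8/28 private mutations.
#'
#' @param n_clones number of tumor clones (>= 1).
#' @param n_variants total panel variants; variants beyond the mutation
#'   budget (and germline SNPs) are reference-only sites, as in a
#'   multi-patient panel where other patients' sites read reference.
#' @param n_amplicons number of panel amplicons.
#' @param truncal_muts number of truncal mutations shared by all clones.
#' @param private_muts integer vector (length `n_clones`): size of each
#'   clone's disjoint private mutation block, so clone k carries
#'   `truncal_muts + private_muts[k]` mutations.
#' @param germline_het number of germline SNP variants heterozygous in
#'   every clone including the normal population (used for allelic-dropout
#'   estimation).
#' @param cna_events tibble with columns `clone` (1-based tumor clone
#'   index at which the event arises), `amplicon` (index) and `cn`
#'   (integer state != 2), inherited by descendant clones. `NULL` gives a
#'   content-balanced default spanning states {1, 3, 4}; `NA` disables
#'   CNA events.
#' @param clone_proportions simplex over (tumor clones, normal); default
#'   puts `normal_fraction` on the diploid population and splits the rest
#'   with mild decay across clones.
#' @param normal_fraction diploid population fraction used when
#'   `clone_proportions` is NULL.
#' @param doublet_rate,ado_rate,error_rate doublet fraction, allelic
#'   dropout probability per true-het entry, genotype error probability.
#' @param mean_depth mean reads per cell per amplicon for a diploid cell
#'   at an average-efficiency amplicon.
#' @param nb_size negative-binomial size (dispersion) of counts; smaller
#'   is noisier. `Inf` gives Poisson counts.
#' @param capture_sigma lognormal sigma of the per-cell capture factor.
#' @param efficiency_sdlog lognormal sdlog of per-amplicon efficiency.
#' @param truncal_ngt,private_ngt genotype codes given to truncal (default
#'   homozygous, 2) and private (default heterozygous, 1) mutations.
#' @param seed integer seed; the truth is reproducible under it.
#' @return An object of class `mpt_sim_truth`.
#' @export
simulate_truth <- function(n_clones = 3,
                           n_variants = 69,
                           n_amplicons = 330,
                           truncal_muts = 15,
                           private_muts = c(0, 8, 28),
                           germline_het = 0,
                           cna_events = NULL,
                           clone_proportions = NULL,
                           normal_fraction = 0.2,
                           doublet_rate = 0.08,
                           ado_rate = 0.09,
                           error_rate = 0.005,
                           mean_depth = 164,
                           nb_size = 10,
                           capture_sigma = 0.3,
                           efficiency_sdlog = 0.6,
                           truncal_ngt = 2L,
                           private_ngt = 1L,
                           seed = 1L) {
  stopifnot(n_clones >= 1)
  private_muts <- rep_len(as.integer(private_muts), n_clones)
  budget <- truncal_muts + sum(private_muts) + germline_het
  if (budget > n_variants) {
    abort(sprintf(
      "mutation budget (%d truncal + %d private + %d germline) exceeds n_variants = %d",
      truncal_muts, sum(private_muts), germline_het, n_variants
    ))
  }
  set.seed(as.integer(seed))

  clones <- c(paste0("c", seq_len(n_clones)), "normal")
  variant_ids <- sprintf("v%03d", seq_len(n_variants))
  amplicon_ids <- sprintf("amp%03d", seq_len(n_amplicons))

  geno <- matrix(0L, n_clones + 1L, n_variants,
                 dimnames = list(clones, variant_ids))
  trunc_idx <- seq_len(truncal_muts)
  geno[seq_len(n_clones), trunc_idx] <- truncal_ngt
  nxt <- truncal_muts
  for (k in seq_len(n_clones)) {
    if (private_muts[k] > 0) {
      idx <- nxt + seq_len(private_muts[k])
      # leaf-private block: carried by clone k only
      geno[k, idx] <- private_ngt
      nxt <- nxt + private_muts[k]
    }
  }
  germ_idx <- integer(0)
  if (germline_het > 0) {
    germ_idx <- nxt + seq_len(germline_het)
    geno[, germ_idx] <- 1L
  }

  cn <- matrix(2L, n_clones + 1L, n_amplicons,
               dimnames = list(clones, amplicon_ids))
  if (is.null(cna_events)) {
    cna_events <- default_cna_events(n_clones, n_variants, n_amplicons)
  } else if (length(cna_events) == 1 && is.na(cna_events[[1]])) {
    cna_events <- tibble(clone = integer(), amplicon = integer(),
                         cn = integer())
  }
  if (nrow(cna_events)) {
    stopifnot(all(cna_events$clone >= 1), all(cna_events$clone <= n_clones),
              all(cna_events$amplicon >= 1),
              all(cna_events$amplicon <= n_amplicons),
              all(cna_events$cn != 2))
    for (i in seq_len(nrow(cna_events))) {
      k <- cna_events$clone[i]
      cn[k:n_clones, cna_events$amplicon[i]] <- as.integer(cna_events$cn[i])
    }
  }

  if (is.null(clone_proportions)) {
    w <- rev(seq_len(n_clones)) + n_clones / 2
    clone_proportions <- c((1 - normal_fraction) * w / sum(w),
                           normal_fraction)
  }
  stopifnot(length(clone_proportions) == n_clones + 1,
            abs(sum(clone_proportions) - 1) < 1e-8)
  names(clone_proportions) <- clones

  efficiency <- rlnorm(n_amplicons, meanlog = -efficiency_sdlog^2 / 2,
                       sdlog = efficiency_sdlog)
  efficiency <- efficiency / mean(efficiency)
  names(efficiency) <- amplicon_ids

  variant_amplicon <- amplicon_ids[(seq_len(n_variants) - 1L) %%
                                     n_amplicons + 1L]
  names(variant_amplicon) <- variant_ids

  structure(
    list(
      clones = clones,
      clone_tree = clone_tree_edges(n_clones),
      clone_genotypes = geno,
      clone_cn = cn,
      clone_proportions = clone_proportions,
      cna_events = cna_events,
      germline_het_variants = variant_ids[germ_idx],
      doublet_rate = doublet_rate,
      ado_rate = ado_rate,
      error_rate = error_rate,
      mean_depth = mean_depth,
      nb_size = nb_size,
      capture_sigma = capture_sigma,
      amplicon_efficiency = efficiency,
      variant_amplicon = variant_amplicon,
      variant_ids = variant_ids,
      amplicon_ids = amplicon_ids,
      seed = as.integer(seed)
    ),
    class = "mpt_sim_truth"
  )
}

# caterpillar clone tree: diploid root, then an ancestor chain
# (MRCA, A1, A2, ...) with one tumor clone leaf hanging off each node
clone_tree_edges <- function(n_clones) {
  anc <- c("MRCA", if (n_clones > 1) paste0("A", seq_len(n_clones - 1)))
  edges <- list(tibble(parent = "normal", child = "MRCA"))
  for (k in seq_len(n_clones)) {
    edges[[length(edges) + 1]] <-
      tibble(parent = anc[k], child = paste0("c", k))
    if (k < n_clones) {
      edges[[length(edges) + 1]] <-
        tibble(parent = anc[k], child = anc[k + 1])
    }
  }
  bind_rows(edges)
}

# content-balanced default CNA set: losses and gains cancel so each
# clone's total genomic content stays ~diploid (CN recovery is then
# unbiased by the per-cell compositional normalization). CNA amplicons
# are placed after the variant-bearing ones when room allows.
default_cna_events <- function(n_clones, n_variants, n_amplicons) {
  base <- if (n_amplicons > n_variants + 30) n_variants else 0L
  avail <- n_amplicons - base
  if (avail < 14) {
    return(tibble(clone = integer(), amplicon = integer(), cn = integer()))
  }
  a <- function(off, len) base + off + seq_len(len)
  ev <- list(
    tibble(clone = 1L, amplicon = a(0, 8), cn = 1L),   # truncal losses
    tibble(clone = 1L, amplicon = a(8, 4), cn = 3L),   # truncal gains
    tibble(clone = 1L, amplicon = a(12, 2), cn = 4L)   # truncal amp
  )
  if (n_clones >= 2 && avail >= 20) {
    ev <- c(ev, list(
      tibble(clone = 2L, amplicon = a(14, 3), cn = 1L),
      tibble(clone = 2L, amplicon = a(17, 3), cn = 3L)
    ))
  }
  if (n_clones >= 3 && avail >= 24) {
    ev <- c(ev, list(
      tibble(clone = 3L, amplicon = a(20, 2), cn = 1L),
      tibble(clone = 3L, amplicon = a(22, 2), cn = 3L)
    ))
  }
  bind_rows(ev)
}

#' @export
print.mpt_sim_truth <- function(x, ...) {
  nc <- length(x$clones) - 1L
  cat(sprintf(
    "<mpt_sim_truth> %d tumor clone(s) + normal; %d variants, %d amplicons\n",
    nc, length(x$variant_ids), length(x$amplicon_ids)
  ))
  cat(sprintf("  clone mutation counts: %s\n", paste(
    rowSums(x$clone_genotypes[seq_len(nc), , drop = FALSE] > 0),
    collapse = "/"
  )))
  cat(sprintf("  ADO %.0f%%, doublets %.0f%%, mean depth %gx\n",
              100 * x$ado_rate, 100 * x$doublet_rate, x$mean_depth))
  invisible(x)
}

#' Draw per-cell clone identities and doublet status
#'
#' Clone labels are drawn from the truth's clone proportions; a
#' `doublet_rate` fraction of cells are doublets formed from two
#' independently drawn clones (the pair may coincide).
#'
#' @param truth an [simulate_truth()] object.
#' @param n_cells number of cell barcodes to draw.
#' @param seed integer seed.
#' @return A tibble with `cell_id`, `clone`, `clone2` (NA for singlets)
#'   and `is_doublet`.
#' @export
simulate_cells <- function(truth, n_cells, seed = 1L) {
  stopifnot(inherits(truth, "mpt_sim_truth"), n_cells >= 1)
  set.seed(as.integer(seed))
  p <- truth$clone_proportions
  clone1 <- sample(names(p), n_cells, replace = TRUE, prob = p)
  is_dbl <- runif(n_cells) < truth$doublet_rate
  clone2 <- rep(NA_character_, n_cells)
  clone2[is_dbl] <- sample(names(p), sum(is_dbl), replace = TRUE, prob = p)
  tibble(
    cell_id = sprintf("cell%05d", seq_len(n_cells)),
    clone = clone1,
    clone2 = clone2,
    is_doublet = is_dbl
  )
}

#' Simulate the observed count and genotype matrices
#'
#' Counts follow a negative binomial with mean
#' `mean_depth * capture_c * efficiency_a * content[c,a] / 2`, where
#' `content` is the cell's integer copy number at the amplicon — the sum
#' of both contributing clones for a doublet, so doublets carry ~2x total
#' content before per-cell capture noise. Genotypes start from the true
#' clone genotype (allele-pooled for doublets), then allelic dropout turns
#' a `doublet_rate`-independent `ado_rate` fraction of het entries into
#' either homozygote, and `error_rate` replaces entries with a random
#' other code. `DP` is the count at the variant's amplicon, `AF` binomial
#' read sampling consistent with the recorded genotype, and `GQ` is high
#' for concordant calls and low for errored ones.
#'
#' @param truth an [simulate_truth()] object.
#' @param cells tibble from [simulate_cells()].
#' @param seed integer seed.
#' @param noise if `FALSE`, the noise-free limit: counts equal their
#'   expectation exactly (capture factor 1), genotypes equal truth, AF is
#'   exact. Used for identities and concordance checks.
#' @return A list of class `mpt_sim` with elements `counts` (cells x
#'   amplicons), `bundle` (an [mpt_bundle()]) and `cells`.
#' @export
simulate_observations <- function(truth, cells, seed = 1L, noise = TRUE) {
  stopifnot(inherits(truth, "mpt_sim_truth"))
  set.seed(as.integer(seed))
  n <- nrow(cells)
  n_amp <- length(truth$amplicon_ids)
  n_var <- length(truth$variant_ids)

  # per-cell integer content per amplicon (doublets: sum of both cells)
  content <- truth$clone_cn[cells$clone, , drop = FALSE]
  if (any(cells$is_doublet)) {
    content[cells$is_doublet, ] <- content[cells$is_doublet, , drop = FALSE] +
      truth$clone_cn[cells$clone2[cells$is_doublet], , drop = FALSE]
  }
  capture <- if (noise) {
    rlnorm(n, meanlog = -truth$capture_sigma^2 / 2,
           sdlog = truth$capture_sigma)
  } else {
    rep(1, n)
  }
  mu <- (truth$mean_depth / 2) * capture * content *
    rep(truth$amplicon_efficiency, each = n)
  counts <- if (!noise) {
    matrix(mu, n, n_amp)
  } else if (is.infinite(truth$nb_size)) {
    matrix(rpois(n * n_amp, mu), n, n_amp)
  } else {
    matrix(rnbinom(n * n_amp, mu = mu, size = truth$nb_size), n, n_amp)
  }
  dimnames(counts) <- list(cells$cell_id, truth$amplicon_ids)

  # true genotype per cell (allele pooling for doublets)
  g1 <- truth$clone_genotypes[cells$clone, , drop = FALSE]
  g_true <- g1
  if (any(cells$is_doublet)) {
    g2 <- truth$clone_genotypes[cells$clone2[cells$is_doublet], ,
                                drop = FALSE]
    pooled <- g1[cells$is_doublet, , drop = FALSE] + g2  # alt copies of 4
    g_true[cells$is_doublet, ] <-
      ifelse(pooled == 0L, 0L, ifelse(pooled == 4L, 2L, 1L))
  }
  dimnames(g_true) <- list(cells$cell_id, truth$variant_ids)

  ngt <- g_true
  errored <- matrix(FALSE, n, n_var)
  if (noise) {
    het <- ngt == 1L
    drop_mask <- het & matrix(runif(n * n_var) < truth$ado_rate, n, n_var)
    ngt[drop_mask] <- sample(c(0L, 2L), sum(drop_mask), replace = TRUE)
    errored <- matrix(runif(n * n_var) < truth$error_rate, n, n_var)
    if (any(errored)) {
      cur <- ngt[errored]
      shift <- sample(1:2, sum(errored), replace = TRUE)
      ngt[errored] <- (cur + shift) %% 3L
    }
  }

  amp_idx <- match(truth$variant_amplicon, truth$amplicon_ids)
  dp <- counts[, amp_idx, drop = FALSE]
  colnames(dp) <- truth$variant_ids

  p_alt <- c(`0` = 0.002, `1` = 0.5, `2` = 0.998)[as.character(ngt)]
  if (noise) {
    alt_reads <- rbinom(n * n_var, size = as.vector(dp), prob = p_alt)
    af <- matrix(ifelse(as.vector(dp) > 0, alt_reads / as.vector(dp),
                        NA_real_), n, n_var)
  } else {
    af <- matrix(as.vector(ngt) / 2, n, n_var)
  }
  gq <- matrix(sample(80:99, n * n_var, replace = TRUE), n, n_var)
  gq[errored] <- sample(10:49, sum(errored), replace = TRUE)
  no_reads <- dp == 0
  ngt[no_reads] <- NA_integer_
  gq[no_reads] <- 0L
  af[no_reads] <- NA_real_
  dimnames(af) <- dimnames(gq) <- dimnames(ngt)
  storage.mode(dp) <- "integer"
  storage.mode(gq) <- "integer"

  structure(
    list(
      counts = counts,
      bundle = mpt_bundle(ngt, dp = dp, gq = gq, af = af),
      cells = cells
    ),
    class = "mpt_sim"
  )
}

#' Exact pseudo-bulk references implied by a simulation truth
#'
#' Mixture identities, no sampling: the bulk VAF of a variant is the
#' proportion-weighted alternate copy fraction
#' `sum_k p_k cn_k ngt_k / 2 / sum_k p_k cn_k` (heterozygous = half the
#' copies, homozygous = all), with copies taken at the variant's amplicon;
#' the bulk copy number of an amplicon is the proportion-weighted mean
#' clone copy number.
#'
#' @param truth an [simulate_truth()] object.
#' @return A list with tibbles `vaf` (`variant_id`, `bulk_vaf`) and
#'   `cn` (`amplicon_id`, `bulk_cn`).
#' @export
derive_pseudobulk <- function(truth) {
  stopifnot(inherits(truth, "mpt_sim_truth"))
  p <- truth$clone_proportions
  amp_idx <- match(truth$variant_amplicon, truth$amplicon_ids)
  cn_at_var <- truth$clone_cn[, amp_idx, drop = FALSE]
  alt_copies <- cn_at_var * truth$clone_genotypes / 2
  vaf <- colSums(p * alt_copies) / colSums(p * cn_at_var)
  bulk_cn <- colSums(p * truth$clone_cn)
  list(
    vaf = tibble(variant_id = truth$variant_ids, bulk_vaf = unname(vaf)),
    cn = tibble(amplicon_id = truth$amplicon_ids, bulk_cn = unname(bulk_cn))
  )
}

#' One-call synthetic sample
#'
#' Convenience wrapper chaining [simulate_truth()], [simulate_cells()] and
#' [simulate_observations()] with seeds derived from one master seed.
#'
#' @param n_cells cells to draw.
#' @param seed master seed; stage seeds are derived from it.
#' @param noise passed to [simulate_observations()].
#' @param ... passed to [simulate_truth()].
#' @return An `mpt_sim` list with the `truth` attached.
#' @export
simulate_sample <- function(n_cells = 4000, seed = 1L, noise = TRUE, ...) {
  seed <- as.integer(seed)
  truth <- simulate_truth(seed = derive_seed(seed, "truth"), ...)
  cells <- simulate_cells(truth, n_cells, seed = derive_seed(seed, "cells"))
  sim <- simulate_observations(truth, cells,
                               seed = derive_seed(seed, "obs"),
                               noise = noise)
  sim$truth <- truth
  sim
}

# deterministic per-stage seed below 2^31, derived from a master seed
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
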