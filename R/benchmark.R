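#' Gini index of a non-negative vector
#'
#' Mean-absolute-difference form
#' `sum_ij |x_i - x_j| / (2 n^2 mean(x))`, computed via the equivalent
#' sorted closed form in O(n log n). 0 means perfectly even coverage;
#' scale-invariant.
#'
#' @param x non-negative numeric vector, not all zero.
#' @return The Gini index, in `[0, 1)`.
#' @examples
#' gini(c(0, 0, 0, 1))  # 0.75
#' @export
gini <- function(x) {
  if (!length(x)) abort("empty vector")
  if (any(is.na(x)) || any(x < 0)) abort("x must be non-negative, no NA")
  if (all(x == 0)) abort("all-zero vector has no defined Gini index")
  n <- length(x)
  xs <- sort(x)
  (2 * sum(seq_len(n) * xs) / (n * sum(xs))) - (n + 1) / n
}

#' Coverage-uniformity and dropout benchmarking metrics
#'
#' Per-amplicon Gini indices (inequality across cells) and per-cell Gini
#' indices (inequality across amplicons) summarised by their means;
#' coefficients of variation (sample SD / mean, in percent) summarised
#' the same way; allelic dropout estimated from known heterozygous sites
#' as the fraction of genotyped entries called homozygous; and amplicon
#' success, the percentage of amplicons whose mean reads exceed
#' `0.2 x` the grand mean reads per cell per amplicon.
#'
#' @param counts cells-by-amplicons count matrix.
#' @param bundle optional [mpt_bundle()] aligned with `counts`.
#' @param known_het_sites variant ids that are truly heterozygous in all
#'   cells (germline SNPs); `NULL` leaves ADO absent.
#' @param doublet_pct optional known/estimated doublet percentage to
#'   carry through.
#' @return A one-row tibble of class `mpt_qc_metrics`: `gini_amplicons`,
#'   `gini_cells`, `cv_amplicons`, `cv_cells`, `ado_pct`, `doublet_pct`,
#'   `amplicon_success_pct`; per-amplicon Gini as attribute
#'   `amplicon_gini`.
#' @export
coverage_metrics <- function(counts, bundle = NULL, known_het_sites = NULL,
                             doublet_pct = NA_real_) {
  nz_cols <- colSums(counts) > 0
  nz_rows <- rowSums(counts) > 0
  gi_amp <- apply(counts[nz_rows, nz_cols, drop = FALSE], 2, gini)
  gi_cell <- apply(counts[nz_rows, nz_cols, drop = FALSE], 1, gini)
  cv <- function(v) 100 * sd(v) / mean(v)
  cv_amp <- apply(counts[nz_rows, nz_cols, drop = FALSE], 2, cv)
  cv_cell <- apply(counts[nz_rows, nz_cols, drop = FALSE], 1, cv)

  ado_pct <- NA_real_
  if (!is.null(known_het_sites)) {
    if (is.null(bundle)) abort("known_het_sites given without a bundle")
    sites <- intersect(known_het_sites, bundle$variant_ids)
    if (!length(sites)) abort("no known het sites present in the bundle")
    ngt <- bundle$layers$NGT[, sites, drop = FALSE]
    ado_pct <- 100 * mean(ngt %in% c(0L, 2L)) / mean(!is.na(ngt))
  }
  grand <- mean(counts)
  amp_mean <- colMeans(counts)
  success <- 100 * mean(amp_mean > 0.2 * grand)

  out <- tibble(
    gini_amplicons = mean(gi_amp), gini_cells = mean(gi_cell),
    cv_amplicons = mean(cv_amp), cv_cells = mean(cv_cell),
    ado_pct = ado_pct, doublet_pct = doublet_pct,
    amplicon_success_pct = success
  )
  attr(out, "amplicon_gini") <-
    tibble(amplicon_id = names(gi_amp), gini = unname(gi_amp))
  class(out) <- c("mpt_qc_metrics", class(out))
  out
}

#' Single-cell versus bulk concordance
#'
#' The aggregated single-cell VAF of a variant is
#' `sum(NGT) / (2 x n genotyped)` over singlet (non-doublet,
#' non-outlier) cells; its Pearson correlation with the bulk VAF is
#' `r_vaf`. For copy number, the tumor-cluster-size-weighted mean copy
#' ratio per amplicon is correlated with the bulk copy number (`r_cn`);
#' Pearson correlation is scale-free, so ratio scale against integer
#' scale is immaterial.
#'
#' @param bundle an [mpt_bundle()].
#' @param clusters an `mpt_clusters` or assignment tibble (used to drop
#'   doublet/outlier cells and to weight tumor clusters).
#' @param bulk_vaf tibble `variant_id`, `bulk_vaf`.
#' @param bulk_cn optional tibble `amplicon_id`, `bulk_cn`.
#' @param ratios optional `mpt_ratio` matrix (needed for `r_cn`).
#' @return A one-row tibble: `r_vaf`, `r_cn`, `n_variants`,
#'   `n_amplicons`.
#' @export
concordance <- function(bundle, clusters, bulk_vaf, bulk_cn = NULL,
                        ratios = NULL) {
  asg <- cluster_assignment(clusters)
  keep <- asg$cell_id[!asg$role %in% c("doublet", "outlier")]
  keep <- intersect(keep, bundle$cell_ids)
  ngt <- bundle$layers$NGT[keep, , drop = FALSE]
  sc_vaf <- colSums(ngt, na.rm = TRUE) / (2 * colSums(!is.na(ngt)))
  shared <- intersect(names(sc_vaf), bulk_vaf$variant_id)
  if (length(shared) < 3) abort("fewer than 3 shared variants")
  bv <- bulk_vaf$bulk_vaf[match(shared, bulk_vaf$variant_id)]
  sv <- sc_vaf[shared]
  ok <- complete.cases(bv, sv)
  if (sd(bv[ok]) == 0 || sd(sv[ok]) == 0) {
    warn("constant VAF vector; correlation undefined")
    r_vaf <- NA_real_
  } else {
    r_vaf <- cor(sv[ok], bv[ok])
  }

  r_cn <- NA_real_
  n_amp <- NA_integer_
  if (!is.null(bulk_cn) && !is.null(ratios)) {
    tum <- asg[asg$role == "tumor" & asg$cell_id %in% rownames(ratios), ]
    mean_ratio <- colMeans(ratios[tum$cell_id, , drop = FALSE])
    shared_a <- intersect(names(mean_ratio), bulk_cn$amplicon_id)
    if (length(shared_a) < 3) abort("fewer than 3 shared amplicons")
    bc <- bulk_cn$bulk_cn[match(shared_a, bulk_cn$amplicon_id)]
    mr <- mean_ratio[shared_a]
    ok <- complete.cases(bc, mr)
    n_amp <- sum(ok)
    if (sd(bc[ok]) == 0 || sd(mr[ok]) == 0) {
      warn("constant CN vector; correlation undefined")
    } else {
      r_cn <- cor(mr[ok], bc[ok])
    }
  }
  tibble(r_vaf = r_vaf, r_cn = r_cn,
         n_variants = length(shared), n_amplicons = n_amp)
}

#' Downsampling sensitivity experiment
#'
#' Reruns the standard filter-and-cluster pipeline on downsampled data
#' and records how many clusters of at least `min_cluster_size` cells
#' remain detectable. Depth downsampling uses binomial thinning of the
#' count matrix (statistically equivalent to read-level subsampling of
#' independent reads) followed by re-masking of the genotype layers by
#' the depth filter; mutation and cell downsampling draw uniform random
#' subsets.
#'
#' @param bundle an (unfiltered) [mpt_bundle()].
#' @param counts aligned count matrix.
#' @param axis one of `"depth"`, `"mutations"`, `"cells"`.
#' @param levels descending levels: target mean depth for `"depth"`,
#'   numbers of variants / cells otherwise.
#' @param seeds integer vector of replicate seeds.
#' @param cfg an [sc_filter_config()].
#' @param k_max,min_cluster_size clustering settings (see
#'   [cluster_cells()]).
#' @return A tibble of class `mpt_downsample`: `axis`, `level`, `seed`,
#'   `k_detected`; medians via [glance()].
#' @export
downsample_experiment <- function(bundle, counts,
                                  axis = c("mutations", "cells", "depth"),
                                  levels, seeds = 1:10,
                                  cfg = sc_filter_config(),
                                  k_max = 8, min_cluster_size = NULL) {
  axis <- match.arg(axis)
  stopifnot(!is.unsorted(rev(levels)))
  cur_depth <- mean(counts)
  rows <- list()
  for (level in levels) {
    for (s in seeds) {
      set.seed(derive_seed(s, paste0("downsample_", axis, "_", level)))
      sub <- downsample_once(bundle, counts, axis, level, cur_depth, cfg)
      k <- detected_clusters(sub$bundle, sub$counts, cfg, k_max,
                             min_cluster_size)
      rows[[length(rows) + 1]] <-
        tibble(axis = axis, level = level, seed = s, k_detected = k)
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("mpt_downsample", class(out))
  out
}

downsample_once <- function(bundle, counts, axis, level, cur_depth, cfg) {
  if (axis == "depth") {
    if (level > cur_depth) {
      warn("requested depth above current mean depth; no-op")
      return(list(bundle = bundle, counts = counts))
    }
    p <- level / cur_depth
    thinned <- matrix(rbinom(length(counts), as.vector(counts), p),
                      nrow(counts), dimnames = dimnames(counts))
    dp <- bundle$layers$DP
    # re-derive DP by thinning the variant-level depths proportionally
    dp2 <- matrix(rbinom(length(dp), as.vector(dp), p), nrow(dp),
                  dimnames = dimnames(dp))
    ngt <- bundle$layers$NGT
    ngt[dp2 < cfg$min_dp] <- NA_integer_
    b <- bundle
    b$layers$NGT <- ngt
    b$layers$DP <- dp2
    return(list(bundle = b, counts = thinned))
  }
  if (axis == "mutations") {
    if (level > length(bundle$variant_ids)) {
      warn("level above variant count; no-op")
      return(list(bundle = bundle, counts = counts))
    }
    keep <- sort(sample(seq_along(bundle$variant_ids), level))
    return(list(bundle = bundle[, keep], counts = counts))
  }
  if (level > length(bundle$cell_ids)) {
    warn("level above cell count; no-op")
    return(list(bundle = bundle, counts = counts))
  }
  keep <- sort(sample(seq_along(bundle$cell_ids), level))
  list(bundle = bundle[keep, ], counts = counts[keep, , drop = FALSE])
}

# the same detection pipeline the full analysis runs: filter cascade,
# overclustered doublet screen, removal, silhouette clustering; the
# detected count is the number of tumor/normal clusters of viable mass
detected_clusters <- function(bundle, counts, cfg, k_max,
                              min_cluster_size, k_screen = 12,
                              n_perm = 99) {
  fr <- suppressWarnings(filter_single_cell_matrix(bundle, cfg))
  if (fr$all_filtered) return(0L)
  b <- fr$bundle
  if (nrow(b$layers$NGT) < 3 || ncol(b$layers$NGT) < 2) return(0L)
  b2 <- tryCatch({
    ks <- min(k_screen, nrow(b$layers$NGT) - 1L)
    screen <- cluster_cells(b, k = ks, k_max = ks,
                            min_cluster_size = min_cluster_size)
    normal_cl <- screen$sizes$cluster[screen$sizes$role == "normal"]
    normal_cells <- screen$assignment$cell_id[
      screen$assignment$cluster %in% normal_cl]
    ratios <- estimate_copy_ratios(counts[b$cell_ids, , drop = FALSE],
                                   normal_cells,
                                   per_cell_normalize = FALSE)
    dbl <- suppressWarnings(
      detect_doublet_clusters(ratios, screen, iterate = TRUE,
                              n_perm = n_perm))
    drop_cells <- dbl$assignment$cell_id[
      dbl$assignment$role %in% c("doublet", "outlier")]
    b[setdiff(b$cell_ids, drop_cells), ]
  }, error = function(e) b)
  if (nrow(b2$layers$NGT) < 3) return(0L)
  cl <- tryCatch(
    cluster_cells(b2, k_max = k_max, min_cluster_size = min_cluster_size),
    error = function(e) NULL
  )
  if (is.null(cl)) return(0L)
  main <- cl$sizes$cluster[cl$sizes$role %in% c("tumor", "normal")]
  if (length(main) < 2) return(length(main))
  # count *major* genotype profiles: clusters whose consensus genotypes
  # differ by fewer than 2 allele counts are one profile — a single
  # allelic-dropout flip away is an artifact class, not a subclone
  prof <- consensus_profiles(b2, cl)
  pm <- profile_matrix(prof[prof$cluster %in% main, ])
  d <- as.matrix(dist(pm, method = "manhattan"))
  d[is.na(d)] <- 0
  merged <- igraph_free_components(d < 2)
  length(unique(merged))
}

# connected components of a small logical adjacency matrix
igraph_free_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      new <- min(comp[c(i, nb)])
      if (any(comp[c(i, nb)] != new)) {
        comp[c(i, nb)] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' @method glance mpt_downsample
#' @export
glance.mpt_downsample <- function(x, ...) {
  x |>
    group_by(.data$axis, .data$level) |>
    summarise(median_k = median(.data$k_detected),
              min_k = min(.data$k_detected),
              max_k = max(.data$k_detected), .groups = "drop") |>
    arrange(.data$axis, desc(.data$level))
}
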