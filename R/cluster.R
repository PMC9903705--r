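#' Numeric genotype feature matrix
#'
#' Genotype codes as numerics with missing entries imputed as reference
#' (0) for embedding and distance computations only; missing entries are
#' never imputed for consensus or fraction statistics.
#' @noRd
genotype_features <- function(bundle) {
  m <- bundle$layers$NGT
  m[is.na(m)] <- 0L
  storage.mode(m) <- "double"
  m
}

#' Embed cells with PCA followed by UMAP
#'
#' Principal components are computed first (the smallest number
#' explaining at least 90% of variance, capped at 10, unless
#' `n_components` is given), then a 2-D UMAP embedding with the targeted
#' scDNA-seq settings `n_neighbors = 15, a = 1, b = 1`. The inter-patient
#' preset of `a = b = 1.2` is available through those arguments.
#'
#' @param bundle an [mpt_bundle()] (filtered; missing genotypes are
#'   treated as reference for the embedding only).
#' @param n_components number of principal components; `NULL` selects by
#'   the 90% variance rule.
#' @param n_neighbors,a,b UMAP parameters.
#' @param seed integer seed; the embedding is deterministic under it.
#' @return A tibble with `cell_id`, `UMAP1`, `UMAP2`, carrying the PCA
#'   variance profile as attribute `pca_var`.
#' @export
embed_cells <- function(bundle, n_components = NULL, n_neighbors = 15,
                        a = 1, b = 1, seed = 1L) {
  m <- genotype_features(bundle)
  if (ncol(m) < 2) abort("need at least 2 variants to embed")
  if (all(apply(m, 2, var) == 0)) {
    # degenerate: identical cells collapse to the origin
    out <- tibble(cell_id = rownames(m), UMAP1 = 0, UMAP2 = 0)
    attr(out, "pca_var") <- numeric(0)
    return(out)
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  vfrac <- pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(n_components)) {
    n_components <- min(which(cumsum(vfrac) >= 0.9), 10L)
  }
  n_components <- max(2L, min(n_components, ncol(pc$x)))
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  nn <- min(n_neighbors, nrow(m) - 1L)
  set.seed(as.integer(seed))
  emb <- uwot::umap(scores, n_neighbors = nn, a = a, b = b,
                    n_threads = 1, n_sgd_threads = 1)
  out <- tibble(cell_id = rownames(m), UMAP1 = emb[, 1], UMAP2 = emb[, 2])
  attr(out, "pca_var") <- vfrac[seq_len(n_components)]
  out
}

#' Hierarchically cluster cells and assign cluster roles
#'
#' Agglomerative clustering with complete linkage and Euclidean distance
#' on genotype space. If `k` is not given it is chosen by the largest
#' mean silhouette width over `2..k_max`. Clusters smaller than
#' `min_cluster_size` (default: 20 cells or 1% of cells, whichever is
#' larger) are labelled `outlier`; among the rest, the cluster whose
#' consensus genotype carries the fewest mutant calls is labelled
#' `normal` and the others `tumor`.
#'
#' @param x an [mpt_bundle()], or a numeric cells-by-features matrix with
#'   rownames (e.g. a copy-ratio matrix).
#' @param k number of clusters; `NULL` selects by silhouette.
#' @param k_max largest k tried during selection.
#' @param min_cluster_size minimum cells for a non-outlier cluster;
#'   `NULL` gives the default rule.
#' @param linkage,metric hierarchical clustering settings.
#' @return An object of class `mpt_clusters`: tibble `assignment`
#'   (`cell_id`, `cluster`, `role`) plus `k`, `silhouette` profile and
#'   cluster `sizes`.
#' @export
cluster_cells <- function(x, k = NULL, k_max = 8, min_cluster_size = NULL,
                          linkage = "complete", metric = "euclidean") {
  feats <- if (inherits(x, "mpt_bundle")) genotype_features(x) else {
    stopifnot(is.matrix(x), !is.null(rownames(x)))
    x
  }
  n <- nrow(feats)
  if (n < 2) abort("need at least 2 cells to cluster")
  if (is.null(min_cluster_size)) {
    min_cluster_size <- max(20, ceiling(0.01 * n))
  }
  d <- dist(feats, method = metric)
  degenerate <- max(d, na.rm = TRUE) == 0
  if (degenerate && !is.null(k) && k > 1) {
    abort("all cells identical; cannot split into k > 1 clusters")
  }
  sil_profile <- tibble(k = integer(), mean_silhouette = numeric())
  if (degenerate) {
    cl <- rep(1L, n)
    k <- 1L
  } else {
    h <- hclust(d, method = linkage)
    if (is.null(k)) {
      ks <- seq(2L, max(2L, min(k_max, n - 1L)))
      sil <- vapply(ks, function(kk) {
        mean(cluster::silhouette(cutree(h, kk), d)[, 3])
      }, numeric(1))
      sil_profile <- tibble(k = ks, mean_silhouette = sil)
      k <- ks[which.max(sil)]
    }
    cl <- if (k == 1L) rep(1L, n) else cutree(h, k)
  }

  sizes <- table(cl)
  roles <- rep("tumor", length(sizes))
  names(roles) <- names(sizes)
  roles[sizes < min_cluster_size] <- "outlier"
  main <- names(roles)[roles != "outlier"]
  if (length(main)) {
    if (inherits(x, "mpt_bundle")) {
      ngt <- x$layers$NGT
      burden <- vapply(main, function(g) {
        sub <- ngt[cl == as.integer(g), , drop = FALSE]
        cons <- consensus_codes(sub)
        sum(cons > 0, na.rm = TRUE) +
          mean(sub > 0, na.rm = TRUE)  # tie-break on mean mutant fraction
      }, numeric(1))
    } else {
      burden <- vapply(main, function(g) {
        mean(feats[cl == as.integer(g), , drop = FALSE])
      }, numeric(1))
    }
    roles[main[which.min(burden)]] <- "normal"
  }

  assignment <- tibble(
    cell_id = rownames(feats),
    cluster = as.integer(cl),
    role = unname(roles[as.character(cl)])
  )
  structure(
    list(assignment = assignment, k = k,
         silhouette = sil_profile,
         sizes = tibble(cluster = as.integer(names(sizes)),
                        n_cells = as.integer(sizes),
                        role = unname(roles)),
         min_cluster_size = min_cluster_size),
    class = "mpt_clusters"
  )
}

# modal non-missing genotype code per column; ties toward the lower code
consensus_codes <- function(ngt) {
  apply(ngt, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_integer_)
    tab <- tabulate(col + 1L, nbins = 3L)
    which.max(tab) - 1L  # which.max takes the first (lowest code) on ties
  })
}

#' @export
print.mpt_clusters <- function(x, ...) {
  cat(sprintf("<mpt_clusters> k = %d\n", x$k))
  print(x$sizes)
  invisible(x)
}

#' @method tidy mpt_clusters
#' @export
tidy.mpt_clusters <- function(x, ...) x$assignment

#' @method glance mpt_clusters
#' @export
glance.mpt_clusters <- function(x, ...) {
  tibble(
    k = x$k,
    n_cells = nrow(x$assignment),
    n_tumor_clusters = sum(x$sizes$role == "tumor"),
    n_outlier_clusters = sum(x$sizes$role == "outlier"),
    best_silhouette = if (nrow(x$silhouette))
      max(x$silhouette$mean_silhouette) else NA_real_
  )
}

#' Per-cluster consensus genotype profiles
#'
#' For every cluster and variant: the modal non-missing genotype code
#' (ties broken toward the lower code; all-missing gives `NA`) and the
#' fraction of genotyped cells carrying a mutant call.
#'
#' @param bundle an [mpt_bundle()].
#' @param clusters an `mpt_clusters` object or its assignment tibble.
#' @param include_outliers include outlier-role clusters.
#' @return A tibble of class `mpt_profiles`: `cluster`, `role`,
#'   `variant_id`, `consensus_ngt`, `frac_mutated`, `n_cells`,
#'   `n_genotyped`.
#' @export
consensus_profiles <- function(bundle, clusters, include_outliers = FALSE) {
  asg <- cluster_assignment(clusters)
  asg <- asg[asg$cell_id %in% bundle$cell_ids, , drop = FALSE]
  if (!include_outliers) asg <- asg[asg$role != "outlier", , drop = FALSE]
  ngt <- bundle$layers$NGT
  out <- lapply(split(asg, asg$cluster), function(grp) {
    sub <- ngt[grp$cell_id, , drop = FALSE]
    tibble(
      cluster = grp$cluster[1],
      role = grp$role[1],
      variant_id = colnames(sub),
      consensus_ngt = as.integer(consensus_codes(sub)),
      frac_mutated = colMeans(sub > 0, na.rm = TRUE),
      n_cells = nrow(sub),
      n_genotyped = colSums(!is.na(sub))
    )
  })
  out <- bind_rows(out)
  out$frac_mutated[is.nan(out$frac_mutated)] <- NA_real_
  class(out) <- c("mpt_profiles", class(out))
  out
}

cluster_assignment <- function(clusters) {
  if (inherits(clusters, "mpt_clusters")) clusters$assignment else {
    stopifnot(all(c("cell_id", "cluster") %in% names(clusters)))
    if (!"role" %in% names(clusters)) clusters$role <- "tumor"
    clusters
  }
}

#' Consensus genotype matrix (clusters x variants)
#'
#' @param profiles an `mpt_profiles` tibble from [consensus_profiles()].
#' @return Integer matrix, one row per cluster.
#' @export
profile_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(
    profiles[c("cluster", "variant_id", "consensus_ngt")],
    names_from = "variant_id", values_from = "consensus_ngt"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- as.character(wide$cluster)
  m
}
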