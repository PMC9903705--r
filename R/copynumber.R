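#' Two-step amplicon read-depth normalization
#'
#' Step 1 divides each cell's counts by that cell's total reads across
#' all amplicons; step 2 divides each amplicon by the median of the
#' normalized values over the reference (normal) cells. The result is a
#' copy-number ratio with 1.0 representing diploid-equivalent
#' representation. Amplicons whose reference median is zero are flagged
#' undefined (`NA` columns); cells with zero total reads are excluded
#' and flagged.
#'
#' Step 1 makes ratios per-cell compositional (scale invariant), which
#' is what copy-number estimation needs but exactly cancels total-content
#' signals; set `per_cell_normalize = FALSE` to retain total content
#' (used by doublet screening, where the ~2x content of a doublet is the
#' signal of interest).
#'
#' @param counts cells-by-amplicons matrix.
#' @param normal_cells character vector of reference (normal) cell ids.
#' @param per_cell_normalize apply step 1.
#' @return A cells-by-amplicons matrix of class `mpt_ratio` with
#'   attributes `normal_cells`, `undefined_amplicons`, `excluded_cells`
#'   and `per_cell_normalize`.
#' @examples
#' cnt <- rbind(N1 = c(10, 10), N2 = c(20, 20), T1 = c(30, 10))
#' colnames(cnt) <- c("a1", "a2")
#' estimate_copy_ratios(cnt, c("N1", "N2"))["T1", "a1"]  # 1.5
#' @export
estimate_copy_ratios <- function(counts, normal_cells,
                                 per_cell_normalize = TRUE) {
  if (length(normal_cells) == 0) abort("empty normal reference set")
  if (!all(normal_cells %in% rownames(counts))) {
    abort("normal_cells not all present in the count matrix")
  }
  totals <- rowSums(counts)
  excluded <- rownames(counts)[totals == 0]
  if (any(totals[normal_cells] == 0)) {
    abort("reference cells with zero total reads")
  }
  keep <- totals > 0
  m <- counts[keep, , drop = FALSE]
  if (per_cell_normalize) m <- m / rowSums(m)
  ref_median <- apply(m[normal_cells, , drop = FALSE], 2, median)
  undefined <- colnames(m)[ref_median == 0]
  ratio <- sweep(m, 2, ref_median, "/")
  ratio[, ref_median == 0] <- NA_real_
  structure(ratio, class = c("mpt_ratio", "matrix", "array"),
            normal_cells = normal_cells,
            undefined_amplicons = undefined,
            excluded_cells = excluded,
            per_cell_normalize = per_cell_normalize)
}

#' Per-cluster median copy ratios and CNA calls
#'
#' The median copy ratio of each amplicon within each cluster, with a
#' gain called at `log2(median) >= gain_log2` and a loss at
#' `log2(median) <= loss_log2` (defaults +/-0.32, about 1.25x / 0.8x).
#'
#' @param ratios an `mpt_ratio` matrix from [estimate_copy_ratios()].
#' @param clusters an `mpt_clusters` object or assignment tibble.
#' @param gain_log2,loss_log2 log2-ratio call thresholds.
#' @param include_outliers include outlier-role clusters.
#' @return A tibble of class `mpt_cluster_cn`: `cluster`, `role`,
#'   `amplicon_id`, `median_ratio`, `log2_ratio`, `call`.
#' @export
summarize_cluster_cn <- function(ratios, clusters, gain_log2 = 0.32,
                                 loss_log2 = -0.32,
                                 include_outliers = FALSE) {
  asg <- cluster_assignment(clusters)
  if (!include_outliers) asg <- asg[asg$role != "outlier", , drop = FALSE]
  missing_cl <- !asg$cell_id %in% rownames(ratios)
  asg_in <- asg[!missing_cl, , drop = FALSE]
  if (!all(unique(asg$cluster) %in% unique(asg_in$cluster))) {
    abort("cluster with no cells present in the ratio matrix")
  }
  out <- lapply(split(asg_in, asg_in$cluster), function(grp) {
    med <- apply(ratios[grp$cell_id, , drop = FALSE], 2, median,
                 na.rm = TRUE)
    tibble(
      cluster = grp$cluster[1], role = grp$role[1],
      amplicon_id = colnames(ratios),
      median_ratio = unname(med),
      log2_ratio = log2(unname(med))
    )
  })
  out <- bind_rows(out)
  out$call <- dplyr::case_when(
    is.na(out$log2_ratio) ~ NA_character_,
    out$log2_ratio >= gain_log2 ~ "gain",
    out$log2_ratio <= loss_log2 ~ "loss",
    TRUE ~ "neutral"
  )
  class(out) <- c("mpt_cluster_cn", class(out))
  out
}

#' Integer copy-number profile from segment ratios and FACS ploidy
#'
#' Scales segment copy ratios by the FACS-derived mean ploidy (2 x the
#' aneuploid/diploid peak position ratio) and rounds half away from zero
#' to integer copy number; the consensus profile is the per-segment
#' median over cells.
#'
#' @param segment_ratios numeric vector (one cell) or cells-by-segments
#'   matrix of positive copy ratios.
#' @param ploidy mean ploidy (> 0), or a list/ploidy model with
#'   `diploid_peak` and `aneuploid_peak` positions from which
#'   `2 * aneuploid/diploid` is taken.
#' @return A list: `cn` (integer profile(s)) and `consensus` (per-segment
#'   median across cells).
#' @export
integer_cn_profile <- function(segment_ratios, ploidy) {
  if (is.list(ploidy)) {
    stopifnot(ploidy$diploid_peak > 0, ploidy$aneuploid_peak > 0)
    ploidy <- 2 * ploidy$aneuploid_peak / ploidy$diploid_peak
  }
  if (!is.numeric(ploidy) || ploidy <= 0) abort("ploidy must be positive")
  if (any(segment_ratios <= 0, na.rm = TRUE)) {
    abort("segment ratios must be positive")
  }
  m <- if (is.matrix(segment_ratios)) segment_ratios else
    matrix(segment_ratios, nrow = 1)
  cn <- round_half_away(m * ploidy)
  consensus <- apply(cn, 2, median, na.rm = TRUE)
  list(cn = if (is.matrix(segment_ratios)) cn else cn[1, ],
       consensus = consensus, ploidy = ploidy)
}

# round half away from zero (avoids banker's rounding surprises at .5)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
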