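#' Per-cluster normalized-ratio summaries
#'
#' For each non-outlier cluster: the per-variant mean copy ratio vector
#' and the log2 of the grand mean ratio — the summary used to screen for
#' doublet clusters, whose roughly doubled genomic content shows as an
#' elevated normalized ratio.
#'
#' @param ratios an `mpt_ratio` matrix; for doublet screening it should
#'   be computed with `per_cell_normalize = FALSE`, since per-cell total
#'   normalization cancels the content signal.
#' @param clusters an `mpt_clusters` object or assignment tibble.
#' @param columns optional subset of ratio columns (e.g. the mutation
#'   amplicons) over which to summarise.
#' @return A tibble: `cluster`, `role`, `n_cells`, `log2_mean_ratio`,
#'   with the clusters-by-variants mean matrix as attribute `means`.
#' @export
cluster_ratio_summary <- function(ratios, clusters, columns = NULL) {
  asg <- cluster_assignment(clusters)
  asg <- asg[asg$role != "outlier" & asg$cell_id %in% rownames(ratios), ,
             drop = FALSE]
  m <- ratios[asg$cell_id, , drop = FALSE]
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  means <- rowsum(m, asg$cluster) / as.vector(table(asg$cluster))
  out <- tibble(
    cluster = as.integer(rownames(means)),
    role = asg$role[match(as.integer(rownames(means)), asg$cluster)],
    n_cells = as.integer(table(asg$cluster)),
    log2_mean_ratio = log2(rowMeans(means))
  )
  attr(out, "means") <- means
  out
}

#' Detect doublet clusters from normalized ratio values
#'
#' The candidate is the cluster with the highest log2 mean normalized
#' ratio; its per-variant mean ratio vector is compared with the
#' per-variant mean over the remaining tumor clusters by a one-sided
#' paired t-test across variants (pairing over variants, as in the
#' reference procedure). Because the candidate is a maximum and per-cell
#' capture noise shifts all variants of a cluster coherently, the
#' analytic Student p-value is anti-conservative; the flagging decision
#' therefore uses a label-permutation reference distribution of the same
#' max-selected paired statistic, which is exactly calibrated under the
#' null. Both p-values are reported.
#'
#' Small clusters (including outlier-role ones) are eligible candidates —
#' the doublet cluster of a sample is typically itself a small outlier
#' cluster — but a cluster needs at least `min_candidate_cells` for a
#' stable mean. Since a doublet carries ~2x genomic content, a flag
#' additionally requires the candidate's elevation to be on that content
#' scale (`min_log2_diff`, default 0.5 ~ 1.4x); clusters that are merely
#' contaminated by a few per-cent of residual doublets are elevated far
#' less and are deliberately not removed wholesale.
#'
#' @param ratios an `mpt_ratio` matrix, computed with
#'   `per_cell_normalize = FALSE` (see [estimate_copy_ratios()]).
#' @param clusters an `mpt_clusters` object or assignment tibble.
#' @param alpha one-sided significance level for flagging.
#' @param columns optional ratio column subset (mutation amplicons).
#' @param iterate keep testing the next-highest cluster after a flag.
#' @param min_log2_diff minimum log2 elevation of the candidate's grand
#'   mean ratio over the rest for a flag.
#' @param min_candidate_cells smallest cluster considered as candidate.
#' @param n_perm permutation draws for the reference distribution.
#' @param seed seed for the permutation draws.
#' @return A list of class `mpt_doublet_test`: `assignment` (roles
#'   updated, flagged clusters become `"doublet"`) and `report` (one row
#'   per test: `cluster`, `t`, `df`, `mean_diff`, `ci_lo`, `ci_hi`,
#'   `p_t`, `p_perm`, `flagged`).
#' @export
detect_doublet_clusters <- function(ratios, clusters, alpha = 0.05,
                                    columns = NULL, iterate = FALSE,
                                    min_log2_diff = 0.5,
                                    min_candidate_cells = 10,
                                    n_perm = 199, seed = 1L) {
  asg <- cluster_assignment(clusters)
  set.seed(as.integer(seed))
  report <- list()
  repeat {
    active <- asg[asg$role != "doublet" &
                    asg$cell_id %in% rownames(ratios), , drop = FALSE]
    m <- ratios[active$cell_id, , drop = FALSE]
    if (!is.null(columns)) {
      m <- m[, intersect(columns, colnames(m)), drop = FALSE]
    }
    m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
    if (ncol(m) < 5) abort("need at least 5 amplicons with defined ratios")
    labs <- active$cluster
    if (length(unique(labs)) < 2) {
      if (!length(report)) {
        warn("fewer than two clusters; doublet test is a no-op")
      }
      break
    }
    obs <- max_paired_stat(m, labs, min_candidate_cells)
    # analytic paired t-test, reported in the reference style
    tt <- t.test(obs$cand_means, obs$rest_means, paired = TRUE,
                 alternative = "greater")
    perm <- vapply(seq_len(n_perm), function(i) {
      max_paired_stat(m, sample(labs), min_candidate_cells)$t
    }, numeric(1))
    p_perm <- (1 + sum(perm >= obs$t)) / (n_perm + 1)
    log2_diff <- log2(mean(obs$cand_means)) - log2(mean(obs$rest_means))
    flagged <- is.finite(obs$t) && obs$t > 0 && p_perm < alpha &&
      log2_diff >= min_log2_diff
    ci <- tryCatch(
      t.test(obs$cand_means, obs$rest_means, paired = TRUE)$conf.int,
      error = function(e) c(NA_real_, NA_real_)
    )
    report[[length(report) + 1]] <- tibble(
      cluster = obs$candidate,
      t = unname(tt$statistic), df = unname(tt$parameter),
      mean_diff = mean(obs$cand_means - obs$rest_means),
      log2_diff = log2_diff,
      ci_lo = ci[1], ci_hi = ci[2],
      p_t = tt$p.value, p_perm = p_perm, flagged = flagged
    )
    if (!flagged) break
    asg$role[asg$cluster == obs$candidate] <- "doublet"
    if (!iterate) break
  }
  structure(
    list(assignment = asg,
         report = if (length(report)) bind_rows(report) else
           tibble(cluster = integer(), t = numeric(), df = numeric(),
                  mean_diff = numeric(), log2_diff = numeric(),
                  ci_lo = numeric(), ci_hi = numeric(), p_t = numeric(),
                  p_perm = numeric(), flagged = logical()),
         alpha = alpha),
    class = "mpt_doublet_test"
  )
}

# candidate = cluster with max grand mean ratio (among clusters of
# at least min_cells); paired-t statistic of its per-variant means
# against the mean of the remaining clusters' means
max_paired_stat <- function(m, labs, min_cells = 10) {
  sizes <- table(labs)
  means <- rowsum(m, labs) / as.vector(sizes)
  grand <- rowMeans(means)
  grand[sizes < min_cells] <- -Inf
  cand <- which.max(grand)
  cand_means <- means[cand, ]
  rest <- means[-cand, , drop = FALSE]
  rest_means <- colMeans(rest)
  d <- cand_means - rest_means
  t_stat <- if (sd(d) == 0) {
    if (mean(d) > 0) Inf else 0
  } else {
    mean(d) / (sd(d) / sqrt(length(d)))
  }
  list(candidate = as.integer(rownames(means)[cand]), t = t_stat,
       cand_means = cand_means, rest_means = rest_means)
}

#' @export
print.mpt_doublet_test <- function(x, ...) {
  cat("<mpt_doublet_test>\n")
  print(x$report)
  invisible(x)
}

#' @method tidy mpt_doublet_test
#' @export
tidy.mpt_doublet_test <- function(x, ...) x$report

#' @method glance mpt_doublet_test
#' @export
glance.mpt_doublet_test <- function(x, ...) {
  tibble(
    n_flagged_clusters = sum(x$report$flagged),
    n_doublet_cells = sum(x$assignment$role == "doublet"),
    alpha = x$alpha
  )
}
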