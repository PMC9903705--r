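#' Assemble a pipeline run configuration
#'
#' One master seed drives every stochastic stage through per-stage
#' derived seeds, so partial reruns reproduce exactly.
#'
#' @param sim list of [simulate_truth()] arguments (plus `n_cells`), or
#'   `NULL` when `input` supplies data.
#' @param input optional list with `counts` and `bundle` for real data;
#'   must include `normal_cells` or rely on clustering to find them.
#' @param filter an [sc_filter_config()].
#' @param k,k_max clustering settings (`k = NULL` selects by silhouette).
#' @param k_screen overclustering level of the doublet-screening pass.
#' @param gain_log2,loss_log2 CNA call thresholds.
#' @param doublet_alpha doublet flag significance level.
#' @param compute_embedding compute the UMAP embedding (reporting only).
#' @param seed master seed.
#' @return A list of class `mpt_run_config`.
#' @export
run_config <- function(sim = list(n_cells = 4000), input = NULL,
                       filter = sc_filter_config(), k = NULL, k_max = 8,
                       k_screen = 12, gain_log2 = 0.32, loss_log2 = -0.32,
                       doublet_alpha = 0.05, compute_embedding = FALSE,
                       seed = 1L) {
  structure(as.list(environment()), class = "mpt_run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  y$filter <- if (!is.null(y$filter)) do.call(sc_filter_config, y$filter)
  do.call(run_config, modifyList(cfg[setdiff(names(cfg), "filter")],
                                 y[!vapply(y, is.null, logical(1))]))
}

#' Run the end-to-end analysis pipeline
#'
#' Stages, in fixed order: simulate (or ingest) - cell calling - genotype
#' filter cascade - overclustered genotype clustering for doublet
#' screening - copy-ratio estimation - doublet flagging and removal -
#' final clustering with silhouette model selection - consensus profiles
#' and cluster copy number - neighbor-joining lineage with event
#' annotation - benchmarking metrics. Doublet screening runs on an
#' overclustered assignment (`k = k_screen`) because doublet classes are
#' small and would be absorbed at the silhouette-selected k; flagged
#' clusters and outlier clusters are removed before the final clustering.
#' Genotype-identical doublets (two cells of the same clone) are not
#' separable in genotype space and a fraction of them remains inside the
#' clone clusters by design. Every stage derives its seed from the
#' master seed, so a rerun with the same config is identical.
#'
#' @param config an [run_config()] (or YAML path).
#' @param out_dir optional directory; when given, all artifacts (matrix
#'   dialect files, assignment, profiles, CN tables, Newick tree, QC
#'   report, manifest JSON) are written there.
#' @return A list of class `mpt_run` with elements `truth` (if
#'   simulated), `cells`, `counts`, `bundle`, `filter`, `clusters`,
#'   `ratios`, `doublets`, `profiles`, `cluster_cn`, `lineage`,
#'   `metrics`, `concordance`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "mpt_run_config"))
  seed <- as.integer(config$seed)
  res <- list(config = config)

  if (!is.null(config$input)) {
    counts <- config$input$counts
    bundle <- config$input$bundle
    if (is.null(counts) || is.null(bundle)) {
      abort("input must provide both `counts` and `bundle`")
    }
  } else {
    sim_args <- config$sim
    n_cells <- sim_args$n_cells %||% 4000
    sim_args$n_cells <- NULL
    truth <- do.call(simulate_truth,
                     c(sim_args, list(seed = derive_seed(seed, "truth"))))
    cells <- simulate_cells(truth, n_cells,
                            seed = derive_seed(seed, "cells"))
    sim <- simulate_observations(truth, cells,
                                 seed = derive_seed(seed, "obs"))
    counts <- sim$counts
    bundle <- sim$bundle
    res$truth <- truth
    res$cells <- cells
  }

  called <- call_cells(counts, config$filter)
  keep <- called$cell_id[called$retained]
  counts <- counts[keep, , drop = FALSE]
  bundle <- bundle[keep, ]
  res$counts <- counts
  res$cell_calling <- called

  fr <- filter_single_cell_matrix(bundle, config$filter)
  res$filter <- fr
  if (fr$all_filtered) abort("all cells or variants filtered; nothing to analyse")
  fb <- fr$bundle

  # overclustered screening assignment: doublet classes are small and
  # would be absorbed at the silhouette-selected k
  k_screen <- config$k_screen %||% 12L
  screen <- cluster_cells(fb, k = k_screen, k_max = k_screen)
  normal_cluster <- screen$sizes$cluster[screen$sizes$role == "normal"]
  if (!length(normal_cluster)) {
    abort("no normal (reference) cluster identified; copy-number stage needs reference cells")
  }
  normal_cells <- screen$assignment$cell_id[
    screen$assignment$cluster == normal_cluster]

  var_amps <- NULL
  if (!is.null(res$truth)) {
    var_amps <- unique(unname(
      res$truth$variant_amplicon[colnames(fb$layers$NGT)]))
  }
  ratios_content <- estimate_copy_ratios(counts, normal_cells,
                                         per_cell_normalize = FALSE)
  dbl <- detect_doublet_clusters(
    ratios_content, screen, alpha = config$doublet_alpha,
    columns = var_amps, iterate = TRUE,
    seed = derive_seed(seed, "doublets")
  )
  res$doublet_screen <- dbl
  drop_cells <- dbl$assignment$cell_id[
    dbl$assignment$role %in% c("doublet", "outlier")]
  clean <- setdiff(fb$cell_ids, drop_cells)
  fb2 <- fb[clean, ]

  clusters <- cluster_cells(fb2, k = config$k, k_max = config$k_max)
  res$clusters <- clusters
  res$doublets <- dbl

  final_norm_cluster <- clusters$sizes$cluster[clusters$sizes$role == "normal"]
  final_normal_cells <- clusters$assignment$cell_id[
    clusters$assignment$cluster %in% final_norm_cluster]
  ratios <- estimate_copy_ratios(counts[fb2$cell_ids, , drop = FALSE],
                                 final_normal_cells)
  res$ratios <- ratios

  profiles <- consensus_profiles(fb2, clusters)
  keep_roles <- clusters$sizes$cluster[
    clusters$sizes$role %in% c("tumor", "normal")]
  profiles <- profiles[profiles$cluster %in% keep_roles, ]
  class(profiles) <- c("mpt_profiles", "tbl_df", "tbl", "data.frame")
  res$profiles <- profiles
  cluster_cn <- summarize_cluster_cn(ratios, clusters,
                                     gain_log2 = config$gain_log2,
                                     loss_log2 = config$loss_log2)
  cluster_cn <- cluster_cn[cluster_cn$cluster %in% keep_roles, ]
  res$cluster_cn <- cluster_cn

  if (length(unique(profiles$cluster)) >= 2) {
    lin <- build_nj_tree(profiles)
    lin <- suppressWarnings(
      annotate_lineage_events(lin, profiles, cluster_cn))
    res$lineage <- lin
  }

  if (isTRUE(config$compute_embedding)) {
    res$embedding <- embed_cells(fb2, seed = derive_seed(seed, "umap"))
  }

  doublet_pct <- 100 * length(unique(dbl$assignment$cell_id[
    dbl$assignment$role == "doublet"])) / nrow(bundle$layers$NGT)
  res$metrics <- coverage_metrics(counts, doublet_pct = doublet_pct)
  if (!is.null(res$truth)) {
    pb <- derive_pseudobulk(res$truth)
    res$concordance <- tryCatch(
      concordance(fb2, clusters, pb$vaf, pb$cn, ratios),
      error = function(e) NULL
    )
  }

  res$manifest <- build_manifest(res, seed)
  class(res) <- "mpt_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

build_manifest <- function(res, seed) {
  list(
    package_version = as.character(utils::packageVersion("mptsc")),
    master_seed = seed,
    stage_seeds = lapply(
      setNames(nm = c("truth", "cells", "obs", "doublets", "umap")),
      function(s) derive_seed(seed, s)
    ),
    n_cells_called = nrow(res$counts),
    filter = glance(res$filter),
    k = res$clusters$k,
    cluster_sizes = res$clusters$sizes,
    n_doublet_cells = sum(res$doublets$assignment$role == "doublet"),
    metrics = res$metrics
  )
}

#' @export
print.mpt_run <- function(x, ...) {
  cat("<mpt_run>\n")
  cat(sprintf("  %d cells called, k = %d final clusters\n",
              nrow(x$counts), x$clusters$k))
  print(x$clusters$sizes)
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}

#' @method glance mpt_run
#' @export
glance.mpt_run <- function(x, ...) {
  tibble(
    n_cells = nrow(x$counts),
    k = x$clusters$k,
    n_clusters_nondoublet = sum(x$clusters$sizes$role %in%
                                  c("tumor", "normal")),
    n_doublet_cells = sum(x$doublets$assignment$role == "doublet"),
    r_vaf = if (!is.null(x$concordance)) x$concordance$r_vaf else NA_real_,
    r_cn = if (!is.null(x$concordance)) x$concordance$r_cn else NA_real_
  )
}

write_run <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_count_matrix(res$counts, file.path(out_dir, "COUNT.tsv"))
  write_matrix_bundle(res$filter$bundle %||% res$filter$bundle,
                      file.path(out_dir, "filtered"))
  readr::write_tsv(res$clusters$assignment,
                   file.path(out_dir, "assignment.tsv"), progress = FALSE)
  readr::write_tsv(res$profiles, file.path(out_dir, "profiles.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$cluster_cn, file.path(out_dir, "cluster_cn.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$doublets$report,
                   file.path(out_dir, "doublet_report.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$filter$ledger, file.path(out_dir, "filter_ledger.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$metrics, file.path(out_dir, "qc_metrics.tsv"),
                   progress = FALSE)
  if (!is.null(res$lineage)) {
    write_lineage_newick(res$lineage, file.path(out_dir, "lineage.nwk"))
  }
  if (!is.null(res$embedding)) {
    readr::write_tsv(res$embedding, file.path(out_dir, "embedding.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
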