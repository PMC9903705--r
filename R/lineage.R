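#' Build a neighbor-joining lineage tree over clone profiles
#'
#' Classical neighbor joining on pairwise distances between cluster
#' consensus genotype vectors (or any taxa-by-features matrix; per-cell
#' trees are obtained by passing the cell matrix). The default distance
#' is Manhattan over genotype codes — the number of allele differences —
#' with missing entries handled pairwise-complete and the sum rescaled by
#' the fraction observed (as `stats::dist` does). The tree is rooted on
#' the branch to the normal cluster; the MRCA is the most rootward
#' internal node ancestral to all tumor leaves. Internal nodes are named
#' `MRCA`, `A1`, `A2`, ... in order of increasing distance from the root.
#' Negative NJ branch lengths are clamped to zero (noted in the object).
#'
#' @param profiles an `mpt_profiles` tibble, or a numeric matrix with
#'   taxa rownames.
#' @param normal taxon name of the normal population used as outgroup;
#'   by default the cluster with role `"normal"` (or the lowest-burden
#'   row of a matrix input).
#' @param metric distance metric passed to [stats::dist()].
#' @return A list of class `mpt_lineage`: `tree` (an [ape::phylo] rooted
#'   at the normal leaf), `normal`, `mrca_node`, `clamped` (number of
#'   negative branches clamped), `taxa`.
#' @export
build_nj_tree <- function(profiles, normal = NULL, metric = "manhattan") {
  if (inherits(profiles, "dist")) {
    return(nj_from_dist(profiles, normal, metric = "precomputed"))
  }
  m <- if (inherits(profiles, "mpt_profiles")) {
    prof_roles <- unique(profiles[c("cluster", "role")])
    if (is.null(normal)) {
      normal <- as.character(prof_roles$cluster[prof_roles$role == "normal"][1])
    }
    profile_matrix(profiles)
  } else {
    stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
    profiles
  }
  if (is.null(normal) || is.na(normal)) {
    normal <- rownames(m)[which.min(rowSums(m > 0, na.rm = TRUE))]
  }
  normal <- as.character(normal)
  stopifnot(normal %in% rownames(m))
  nj_from_dist(dist(m, method = metric), normal, metric)
}

nj_from_dist <- function(d, normal, metric) {
  labels <- attr(d, "Labels")
  if (is.null(normal) || is.na(normal)) normal <- labels[1]
  stopifnot(normal %in% labels)
  n_taxa <- length(labels)
  if (n_taxa < 3) {
    warn("fewer than 3 taxa; returning a degenerate 2-leaf tree")
    tree <- ape::read.tree(
      text = sprintf("(%s:%f,%s:%f);", labels[1], as.numeric(d) / 2,
                     labels[2], as.numeric(d) / 2)
    )
  } else {
    tree <- ape::nj(d)
  }
  clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree <- ape::root(tree, outgroup = normal, resolve.root = TRUE)

  tumor_leaves <- setdiff(tree$tip.label, normal)
  mrca_node <- if (length(tumor_leaves) >= 2) {
    ape::getMRCA(tree, tumor_leaves)
  } else {
    # single tumor leaf: its attachment point
    tree$edge[tree$edge[, 2] == match(tumor_leaves, tree$tip.label), 1]
  }
  tree <- name_internal_nodes(tree, mrca_node)
  structure(
    list(tree = tree, normal = normal, mrca_node = mrca_node,
         clamped = clamped, taxa = labels, metric = metric),
    class = "mpt_lineage"
  )
}

name_internal_nodes <- function(tree, mrca_node) {
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  internal <- seq(n_tip + 1L, n_tip + tree$Nnode)
  labs <- rep("", tree$Nnode)
  labs[mrca_node - n_tip] <- "MRCA"
  others <- setdiff(internal, c(mrca_node, n_tip + 1L))
  others <- others[order(depths[others])]
  if (length(others)) {
    labs[others - n_tip] <- paste0("A", seq_along(others))
  }
  labs[labs == ""] <- "root"
  # the root node keeps the name "root" unless it coincides with the MRCA
  tree$node.label <- labs
  tree
}

#' Annotate mutations and CNA events onto lineage branches
#'
#' Each mutation is placed on the branch above the smallest clade
#' containing every cluster whose consensus genotype is mutant
#' (perfect-phylogeny placement); mutations mutant in all tumor clusters
#' land on the root-to-MRCA branch and are truncal. CNA events (per
#' amplicon, gains and losses separately) are placed the same way from
#' the cluster CNA calls. A mutant set that is not a clade is flagged as
#' a conflict and placed at the MRCA of its members.
#'
#' @param lineage an `mpt_lineage` from [build_nj_tree()].
#' @param profiles an `mpt_profiles` tibble (consensus genotypes).
#' @param cluster_cn optional `mpt_cluster_cn` tibble for CNA placement.
#' @return The lineage with an `events` tibble attached: `type`
#'   (`mutation`/`cna`), `id`, `call`, `branch_node` (the node below the
#'   placed branch, using `MRCA`/`A*`/leaf labels), `truncal`,
#'   `conflict`.
#' @export
annotate_lineage_events <- function(lineage, profiles, cluster_cn = NULL) {
  tree <- lineage$tree
  n_tip <- length(tree$tip.label)
  tumor_leaves <- setdiff(tree$tip.label, lineage$normal)

  node_name <- function(node) {
    if (node <= n_tip) tree$tip.label[node] else
      tree$node.label[node - n_tip]
  }
  clade_tips <- function(node) {
    if (node <= n_tip) tree$tip.label[node] else
      ape::extract.clade(tree, node)$tip.label
  }
  place <- function(members, id, type, call) {
    members <- intersect(as.character(members), tree$tip.label)
    if (!length(members)) return(NULL)
    if (setequal(members, tumor_leaves)) {
      return(tibble(type = type, id = id, call = call,
                    branch_node = node_name(lineage$mrca_node),
                    truncal = TRUE, conflict = FALSE))
    }
    node <- if (length(members) == 1) {
      match(members, tree$tip.label)
    } else {
      ape::getMRCA(tree, members)
    }
    conflict <- !setequal(intersect(clade_tips(node), tumor_leaves),
                          members)
    tibble(type = type, id = id, call = call, branch_node = node_name(node),
           truncal = FALSE, conflict = conflict)
  }

  events <- list()
  for (v in unique(profiles$variant_id)) {
    sub <- profiles[profiles$variant_id == v & profiles$role != "normal", ]
    mutant <- sub$cluster[!is.na(sub$consensus_ngt) & sub$consensus_ngt > 0]
    if (length(mutant)) {
      g <- sub$consensus_ngt[match(mutant, sub$cluster)]
      call <- if (all(g == 2L)) "hom" else if (all(g == 1L)) "het" else "mixed"
      events[[length(events) + 1]] <- place(mutant, v, "mutation", call)
    }
  }
  if (!is.null(cluster_cn)) {
    cn_t <- cluster_cn[cluster_cn$role != "normal" &
                         !is.na(cluster_cn$call) &
                         cluster_cn$call != "neutral", ]
    for (key in unique(paste(cn_t$amplicon_id, cn_t$call))) {
      sub <- cn_t[paste(cn_t$amplicon_id, cn_t$call) == key, ]
      events[[length(events) + 1]] <-
        place(sub$cluster, sub$amplicon_id[1], "cna", sub$call[1])
    }
  }
  lineage$events <- if (length(events)) bind_rows(events) else
    tibble(type = character(), id = character(), call = character(),
           branch_node = character(), truncal = logical(),
           conflict = logical())
  n_conf <- sum(lineage$events$conflict)
  if (n_conf) {
    warn(sprintf("%d event(s) violate perfect phylogeny; placed at the MRCA of their carriers", n_conf))
  }
  lineage
}

#' Rank variants by predicted deleterious impact
#'
#' A variant passes if `polyphen > 0.8` or `(1 - sift) > 0.8` (missing
#' scores fail); passers are ranked by CADD descending and the top 30
#' retained. The CADD scaled-percentile band is reported
#' (`>10` top 10%, `>20` top 1%, `>30` top 0.1%).
#'
#' @param variants tibble with `polyphen`, `sift`, `cadd` columns and an
#'   id column (`gene` or `variant_id`).
#' @param top_n passers kept after ranking.
#' @return The input with `pass`, `cadd_band` and `rank` (NA for
#'   non-passers / beyond `top_n`), ordered by rank.
#' @export
rank_deleterious <- function(variants, top_n = 30) {
  v <- variants
  v$pass <- (!is.na(v$polyphen) & v$polyphen > 0.8) |
    (!is.na(v$sift) & (1 - v$sift) > 0.8)
  v$pass[is.na(v$cadd)] <- FALSE
  v$cadd_band <- dplyr::case_when(
    is.na(v$cadd) ~ NA_character_,
    v$cadd > 30 ~ "top 0.1%",
    v$cadd > 20 ~ "top 1%",
    v$cadd > 10 ~ "top 10%",
    TRUE ~ "below top 10%"
  )
  v$rank <- NA_integer_
  idx <- which(v$pass)
  idx <- idx[order(-v$cadd[idx])]
  idx <- head(idx, top_n)
  v$rank[idx] <- seq_along(idx)
  v$pass[setdiff(which(v$pass), idx)] <- FALSE  # beyond top_n: not retained
  arrange(v, !is.na(.data$rank) * -1, .data$rank)
}

#' Write a lineage tree as Newick with an event table
#'
#' The tree (with `MRCA`/`A*` internal labels) goes to `path`; branch
#' events, if annotated, to `paste0(path, ".events.tsv")`.
#'
#' @param lineage an `mpt_lineage`.
#' @param path output Newick path.
#' @export
write_lineage_newick <- function(lineage, path) {
  ape::write.tree(lineage$tree, file = path)
  if (!is.null(lineage$events)) {
    readr::write_tsv(lineage$events, paste0(path, ".events.tsv"),
                     progress = FALSE)
  }
  invisible(path)
}

#' @export
print.mpt_lineage <- function(x, ...) {
  cat(sprintf("<mpt_lineage> %d taxa, rooted at '%s'",
              length(x$taxa), x$normal))
  if (x$clamped) cat(sprintf(" (%d negative branch(es) clamped)", x$clamped))
  cat("\n")
  if (!is.null(x$events)) {
    cat(sprintf("  %d events (%d truncal, %d conflicts)\n",
                nrow(x$events), sum(x$events$truncal),
                sum(x$events$conflict)))
  }
  invisible(x)
}

#' @method tidy mpt_lineage
#' @export
tidy.mpt_lineage <- function(x, ...) {
  if (is.null(x$events)) {
    abort("no events annotated; run annotate_lineage_events() first")
  }
  x$events
}
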