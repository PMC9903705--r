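# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# O(n^2) pairwise Gini oracle (mean absolute difference form)
gini_bruteforce <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# enumerate all unrooted topologies for 4 or 5 leaves as split sets,
# fit branch lengths by unconstrained least squares on path indicators,
# and return the topology (as a canonical split string) with minimal SS
nj_exhaustive_best <- function(d) {
  labels <- attr(d, "Labels")
  n <- length(labels)
  stopifnot(n %in% c(4, 5))
  trees <- all_unrooted_trees(labels)
  dv <- as.vector(d)
  fits <- vapply(trees, function(tr) {
    X <- path_indicator_matrix(tr, labels)
    fit <- stats::lm.fit(X, dv)
    sum(fit$residuals^2)
  }, numeric(1))
  canonical_splits(trees[[which.min(fits)]], labels)
}

# unrooted binary trees as edge lists over labels + internal nodes
all_unrooted_trees <- function(labels) {
  # build by stepwise leaf insertion into every edge
  base <- list(rbind(c("i1", labels[1]), c("i1", labels[2]),
                     c("i1", labels[3])))
  trees <- base
  for (k in 4:length(labels)) {
    new_trees <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        node <- paste0("i", k - 2)
        t2 <- tr
        old <- t2[e, ]
        t2 <- t2[-e, , drop = FALSE]
        t2 <- rbind(t2, c(old[1], node), c(node, old[2]),
                    c(node, labels[k]))
        new_trees[[length(new_trees) + 1]] <- t2
      }
    }
    trees <- new_trees
  }
  trees
}

tree_paths <- function(tr, labels) {
  nodes <- unique(as.vector(tr))
  adj <- lapply(setNames(nm = nodes), function(nd) {
    c(tr[tr[, 1] == nd, 2], tr[tr[, 2] == nd, 1])
  })
  path_edges <- function(a, b) {
    # BFS recording parent edges
    prev <- setNames(rep(NA_character_, length(nodes)), nodes)
    seen <- setNames(logical(length(nodes)), nodes)
    queue <- a; seen[a] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (cur == b) break
      for (nb in adj[[cur]]) {
        if (!seen[nb]) {
          seen[nb] <- TRUE
          prev[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
    out <- character(0)
    cur <- b
    while (!is.na(prev[cur])) {
      out <- c(out, paste(sort(c(cur, prev[cur])), collapse = "|"))
      cur <- prev[cur]
    }
    out
  }
  pairs <- utils::combn(labels, 2)
  lapply(seq_len(ncol(pairs)),
         function(j) path_edges(pairs[1, j], pairs[2, j]))
}

path_indicator_matrix <- function(tr, labels) {
  edges <- apply(tr, 1, function(e) paste(sort(e), collapse = "|"))
  paths <- tree_paths(tr, labels)
  X <- t(vapply(paths, function(p) as.numeric(edges %in% p),
                numeric(length(edges))))
  X
}

# canonical representation: the set of nontrivial splits
canonical_splits <- function(tr, labels) {
  edges_int <- tr[grepl("^i", tr[, 1]) & grepl("^i", tr[, 2]), ,
                  drop = FALSE]
  if (!nrow(edges_int)) return("star")
  splits <- apply(edges_int, 1, function(e) {
    t2 <- tr[!(tr[, 1] == e[1] & tr[, 2] == e[2]), , drop = FALSE]
    # leaves reachable from e[1]
    nodes <- unique(as.vector(t2))
    adj <- lapply(setNames(nm = nodes), function(nd) {
      c(t2[t2[, 1] == nd, 2], t2[t2[, 2] == nd, 1])
    })
    seen <- e[1]; queue <- e[1]
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) if (!nb %in% seen) {
        seen <- c(seen, nb); queue <- c(queue, nb)
      }
    }
    side <- sort(intersect(seen, labels))
    other <- sort(setdiff(labels, side))
    paste(paste(side, collapse = ","),
          paste(other, collapse = ","), sep = " vs ")
  })
  paste(sort(vapply(splits, function(s) {
    parts <- sort(strsplit(s, " vs ")[[1]])
    paste(parts, collapse = " vs ")
  }, character(1))), collapse = " ; ")
}

# splits of an ape::phylo tree for comparison with the oracle
phylo_splits <- function(tree) {
  labels <- sort(tree$tip.label)
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  internal_edges <- tree$edge[tree$edge[, 2] > n_tip, , drop = FALSE]
  if (!nrow(internal_edges)) return("star")
  splits <- apply(internal_edges, 1, function(e) {
    clade <- ape::extract.clade(tree, e[2])$tip.label
    side <- sort(clade)
    other <- sort(setdiff(labels, side))
    parts <- sort(c(paste(side, collapse = ","),
                    paste(other, collapse = ",")))
    paste(parts, collapse = " vs ")
  })
  paste(sort(unique(splits)), collapse = " ; ")
}

# random additive (tree-metric) distance matrix with its true splits
random_additive_matrix <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   tip.label = paste0("t", seq_len(n_leaves)))
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 3)
  d <- stats::as.dist(ape::cophenetic.phylo(tr))
  list(d = d, splits = phylo_splits(tr))
}

expect_no_na <- function(x) expect_false(anyNA(x))
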