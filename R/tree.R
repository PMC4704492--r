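#' metaTAD merge tree
#'
#' Rooted binary tree over an ordered array of TADs, stored in
#' `hclust`-style form: row `j` of `merge` gives the two children of
#' internal node `j` (negative entries are leaf TAD ids, positive entries
#' earlier merge rows).  Because merging is adjacency-constrained, every
#' internal node spans a contiguous TAD index range.
#'
#' @param merge (K-1) x 2 integer matrix of merges, in merge order
#'   (`merge_rank` 1 = first merge).
#' @param score per-merge contact score (`I` of the merge), or `NA`.
#' @param tads optional [tad_set()] giving the leaves; enables genomic
#'   lengths `d`.
#' @param linkage linkage used to build the tree (metadata).
#' @return object of class `metatad_tree` with elements `merge`, `score`,
#'   `span` ((K-1) x 2 contiguous TAD index range per node), `n` (leaf
#'   count per node), `d` (genomic length per node, bp; `NA` without
#'   `tads`), `K`, `tads`, `linkage`.
#' @export
metatad_tree <- function(merge, score = rep(NA_real_, nrow(merge)),
                         tads = NULL, linkage = NA_character_) {
  merge <- matrix(as.integer(merge), ncol = 2)
  K <- nrow(merge) + 1L
  span <- matrix(0L, K - 1L, 2L)
  n <- integer(K - 1L)
  child_span <- function(c, j) {
    if (c < 0) c(-c, -c) else span[c, ]
  }
  for (j in seq_len(K - 1L)) {
    s1 <- child_span(merge[j, 1], j)
    s2 <- child_span(merge[j, 2], j)
    lo <- min(s1[1], s2[1]); hi <- max(s1[2], s2[2])
    if (hi - lo + 1L != (s1[2] - s1[1] + 1L) + (s2[2] - s2[1] + 1L)) {
      stop("merge ", j, " does not join adjacent spans")
    }
    span[j, ] <- c(lo, hi)
    n[j] <- hi - lo + 1L
  }
  if (n[K - 1L] != K) stop("root does not span all TADs")
  d <- rep(NA_real_, K - 1L)
  if (!is.null(tads)) {
    stopifnot(nrow(tads) == K)
    w <- tads$end - tads$start
    d <- vapply(seq_len(K - 1L), function(j) sum(w[span[j, 1]:span[j, 2]]),
                numeric(1))
  }
  structure(list(merge = merge, score = as.numeric(score), span = span,
                 n = n, d = d, K = K, tads = tads, linkage = linkage),
            class = "metatad_tree")
}

#' @export
print.metatad_tree <- function(x, ...) {
  cat(sprintf("<metatad_tree> %d TADs, %d merges (linkage: %s)\n",
              x$K, x$K - 1L, x$linkage))
  invisible(x)
}

#' Node summary table
#'
#' @param tree a [metatad_tree()].
#' @return data.frame with one row per internal node: `merge_rank`,
#'   `score`, `n`, `d`, `span_lo`, `span_hi`.
#' @export
node_table <- function(tree) {
  data.frame(merge_rank = seq_len(tree$K - 1L), score = tree$score,
             n = tree$n, d = tree$d, span_lo = tree$span[, 1],
             span_hi = tree$span[, 2])
}

# parent id per node; leaves 1..K, internal node j -> id K + j
tree_parents <- function(tree) {
  K <- tree$K
  parent <- integer(2L * K - 1L)
  for (j in seq_len(K - 1L)) {
    for (c in tree$merge[j, ]) {
      id <- if (c < 0) -c else K + c
      parent[id] <- K + j
    }
  }
  parent  # root has parent 0
}

# list of ancestor chains (self first, root last) per leaf
leaf_ancestors <- function(tree) {
  parent <- tree_parents(tree)
  lapply(seq_len(tree$K), function(u) {
    chain <- u
    while (parent[chain[length(chain)]] != 0L) {
      chain <- c(chain, parent[chain[length(chain)]])
    }
    chain
  })
}

#' Leaf-pair tree distances
#'
#' Tree distance between two TADs is the number of edges on the leaf-to-leaf
#' path through the tree, minus one, so that siblings are at distance 1 and
#' a leaf is at distance 0 from itself.
#'
#' @param tree a [metatad_tree()].
#' @return K x K symmetric integer matrix of tree distances.
#' @export
tree_distances <- function(tree) {
  K <- tree$K
  anc <- leaf_ancestors(tree)
  D <- matrix(0L, K, K)
  for (u in seq_len(K - 1L)) {
    au <- anc[[u]]
    pos_u <- seq_along(au) - 1L  # edges from u up to each ancestor
    for (v in (u + 1L):K) {
      av <- anc[[v]]
      m <- match(au, av)
      k <- which(!is.na(m))[1]  # lowest common ancestor
      edges <- pos_u[k] + (m[k] - 1L)
      D[u, v] <- D[v, u] <- edges - 1L
    }
  }
  D
}

#' Random neighbour trees
#'
#' Null ensemble for tree-based statistics: trees built by the same
#' adjacency-constrained agglomeration but with uniformly random choices of
#' which adjacent pair to merge, so they share the leaf set, leaf order and
#' node count of a real metaTAD tree while carrying no contact information.
#'
#' @param K number of leaves (or a [tad_set()], from which K is taken).
#' @param n_trees ensemble size.
#' @param seed RNG seed.
#' @return list of [metatad_tree()] objects.
#' @export
random_neighbour_trees <- function(K, n_trees, seed = 1L) {
  tads <- NULL
  if (inherits(K, "tad_set")) { tads <- K; K <- nrow(K) }
  stopifnot(K >= 2, n_trees >= 1)
  set.seed(seed)
  replicate(n_trees, random_neighbour_tree(K, tads), simplify = FALSE)
}

random_neighbour_tree <- function(K, tads = NULL) {
  # active domains left-to-right; value: negative leaf or merge row
  act <- -seq_len(K)
  merge <- matrix(0L, K - 1L, 2L)
  for (j in seq_len(K - 1L)) {
    i <- if (length(act) == 2L) 1L else sample.int(length(act) - 1L, 1L)
    merge[j, ] <- c(act[i], act[i + 1L])
    act <- c(act[seq_len(i - 1L)], j,
             if (i + 2L <= length(act)) act[(i + 2L):length(act)])
  }
  metatad_tree(merge, tads = tads, linkage = "random")
}

#' Convert to ape phylo / write Newick
#'
#' Tip labels are `TAD<k>`; internal node labels carry the TAD count and
#' merge score as `n=<count>|I=<score>`.
#'
#' @param tree a [metatad_tree()].
#' @return an [ape::as.phylo] object.
#' @export
as_phylo <- function(tree) {
  K <- tree$K
  # ape wants internal ids K+1..2K-1 with root K+1; our rows merge in order,
  # root is row K-1: map row j -> K + (K - j)
  map_id <- function(c) if (c < 0) -c else K + (K - c)
  edge <- matrix(0L, 2L * (K - 1L), 2L)
  r <- 1L
  for (j in seq_len(K - 1L)) {
    for (c in tree$merge[j, ]) {
      edge[r, ] <- c(K + (K - j), map_id(c))
      r <- r + 1L
    }
  }
  lab <- sprintf("n=%d|I=%s", tree$n, signif(tree$score, 6))
  phy <- list(edge = edge, tip.label = paste0("TAD", seq_len(K)),
              Nnode = K - 1L,
              node.label = lab[order(K - seq_len(K - 1L))],
              edge.length = rep(1, nrow(edge)))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' @rdname as_phylo
#' @param path output file for [write_newick()].
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}
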