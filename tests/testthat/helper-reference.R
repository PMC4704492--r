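# Independent reference implementations used as oracles.  These are kept
# deliberately naive (quadratic/cubic scans, explicit recursion) and
# separate from the package code paths they check.

# naive O(K^3) constrained agglomeration: full rescan of all adjacent
# domain pairs at every step, domains as explicit index vectors
ref_greedy_merge <- function(t_mat, linkage = "single") {
  K <- nrow(t_mat)
  domains <- lapply(seq_len(K), identity)
  labels <- as.list(-seq_len(K))
  merges <- matrix(0L, K - 1L, 2L)
  scores <- numeric(K - 1L)
  for (step in seq_len(K - 1L)) {
    best <- -Inf; best_i <- 1L
    for (i in seq_len(length(domains) - 1L)) {
      v <- t_mat[domains[[i]], domains[[i + 1L]], drop = FALSE]
      s <- if (linkage == "single") max(v) else mean(v)
      if (s > best + 1e-12) { best <- s; best_i <- i }
    }
    merges[step, ] <- c(labels[[best_i]], labels[[best_i + 1L]])
    scores[step] <- best
    domains[[best_i]] <- c(domains[[best_i]], domains[[best_i + 1L]])
    labels[[best_i]] <- step
    domains[[best_i + 1L]] <- NULL
    labels[[best_i + 1L]] <- NULL
  }
  list(merge = merges, score = scores)
}

# brute-force leaf-pair path length through explicit parent chains,
# walking the nested-list form of the tree
ref_tree_distances <- function(tree) {
  K <- tree$K
  paths <- vector("list", K)
  walk <- function(c, chain) {
    if (c < 0) {
      paths[[-c]] <<- chain
      return(invisible())
    }
    walk(tree$merge[c, 1], c(chain, c))
    walk(tree$merge[c, 2], c(chain, c))
  }
  walk(K - 1L, integer())
  D <- matrix(0L, K, K)
  for (u in seq_len(K - 1L)) for (v in (u + 1L):K) {
    pu <- paths[[u]]; pv <- paths[[v]]
    shared <- length(intersect(pu, pv))
    edges <- (length(pu) - shared + 1L) + (length(pv) - shared + 1L)
    D[u, v] <- D[v, u] <- edges - 1L
  }
  D
}

ref_cophenetic <- function(tree_a, tree_b) {
  da <- ref_tree_distances(tree_a)
  db <- ref_tree_distances(tree_b)
  cor(da[upper.tri(da)], db[upper.tri(db)])
}

# enumerate the merge matrices of every contiguous binary tree over K
# ordered leaves (Catalan number of shapes)
enumerate_contiguous_trees <- function(K) {
  build <- function(lo, hi) {
    if (lo == hi) return(list(list(ref = -lo, merge = matrix(0L, 0, 2))))
    out <- list()
    for (k in lo:(hi - 1L)) {
      for (l in build(lo, k)) for (r in build(k + 1L, hi)) {
        shift <- nrow(l$merge)
        rm_ <- r$merge
        if (nrow(rm_)) rm_[rm_ > 0] <- rm_[rm_ > 0] + shift
        rref <- if (r$ref < 0) r$ref else r$ref + shift
        mm <- rbind(l$merge, rm_, c(l$ref, rref))
        out[[length(out) + 1L]] <- list(ref = nrow(mm), merge = mm)
      }
    }
    out
  }
  lapply(build(1L, K), function(x) x$merge)
}

# canonical form of a tree topology: sorted span strings
span_key <- function(tree) {
  paste(sort(paste(tree$span[, 1], tree$span[, 2])), collapse = ";")
}
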