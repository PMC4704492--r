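#' Plant a synthetic TAD hierarchy
#'
#' Generates a contiguous array of TADs tiling one synthetic chromosome and
#' a random binary merge tree over them, the ground truth against which
#' tree reconstruction is validated.  By default all TADs have equal width
#' `mean_tad_size` (rounded to whole bins): with equal widths the distance
#' decay contributes the same factor to every junction's TAD-level contact,
#' so the planted boost hierarchy alone determines the merge order and
#' noiseless tree recovery is exact.  `width_dispersion = "poisson"` draws
#' widths (in bins) as `2 + Poisson(mean_tad_size/bin_size - 2)` instead,
#' for robustness studies with realistic size variation.  Contact boosts
#' are multiplicative per tree
#' level: a node at height `h` (leaves at height 0, root at height `H`)
#' carries boost `boost_leaf * (boost_root/boost_leaf)^(h/H)`, geometric
#' from the TAD level down to the root, so nesting is strongest at the
#' bottom of the tree.
#'
#' @param n_tads number of TADs (>= 2).
#' @param mean_tad_size mean TAD width in bp (>= 2 * bin_size).
#' @param bin_size bin width in bp.
#' @param seed RNG seed; the whole hierarchy is deterministic given it.
#' @param decay_exponent power-law exponent of the distance decay.
#' @param boost_leaf,boost_root level-boost endpoints (> 0).
#' @param noise `"poisson"` (counts sampled at sequencing `depth`),
#'   `"lognormal"` (multiplicative, log-sd `sigma`) or `"none"`.
#' @param depth sequencing depth for Poisson noise: counts are
#'   `Poisson(depth * expected) / depth`.
#' @param sigma log-sd for lognormal noise.
#' @param shape `"random"` (recursive uniform bisection) or `"balanced"`
#'   (midpoint bisection; deterministic topology).
#' @param width_dispersion `"none"` (equal widths, default) or
#'   `"poisson"`.
#' @return object of class `planted_hierarchy`: `tads` ([tad_set()]),
#'   `tree` ([metatad_tree()]), `boost_by_height`, `node_boost`,
#'   `node_height`, plus the generator parameters.
#' @export
plant_hierarchy <- function(n_tads, mean_tad_size = 5e5, bin_size = 5e4,
                            seed = 1L, decay_exponent = 1,
                            boost_leaf = 3, boost_root = 1.05,
                            noise = c("poisson", "none", "lognormal"),
                            depth = 10, sigma = 0.3,
                            shape = c("random", "balanced"),
                            width_dispersion = c("none", "poisson")) {
  noise <- match.arg(noise)
  shape <- match.arg(shape)
  width_dispersion <- match.arg(width_dispersion)
  if (n_tads < 2) stop("n_tads must be >= 2")
  if (mean_tad_size < 2 * bin_size) stop("mean_tad_size must be >= 2 bins")
  if (bin_size <= 0 || boost_leaf <= 0 || boost_root <= 0) {
    stop("sizes and boosts must be positive")
  }
  set.seed(seed)
  mb <- mean_tad_size / bin_size
  widths <- if (width_dispersion == "none") {
    rep(round(mb), n_tads) * bin_size
  } else {
    (2 + rpois(n_tads, mb - 2)) * bin_size
  }
  ends <- cumsum(widths)
  tads <- tad_set(c(0, head(ends, -1)), ends)

  # random contiguous binary tree by recursive bisection, merge rows in
  # postorder (children always precede parents)
  merge <- matrix(0L, max(n_tads - 1L, 1L), 2L)
  row <- 0L
  bisect <- function(lo, hi) {
    if (lo == hi) return(-lo)
    k <- if (shape == "balanced") lo + (hi - lo + 1L) %/% 2L - 1L
         else lo + sample.int(hi - lo, 1L) - 1L
    left <- bisect(lo, k)
    right <- bisect(k + 1L, hi)
    row <<- row + 1L
    merge[row, ] <<- c(left, right)
    row
  }
  bisect(1L, n_tads)
  tree <- metatad_tree(merge, tads = tads, linkage = "planted")

  height <- node_heights(tree)
  H <- max(height)
  boost_by_height <- boost_leaf * (boost_root / boost_leaf)^((0:H) / max(H, 1))
  structure(
    list(tads = tads, tree = tree, bin_size = as.integer(bin_size),
         decay_exponent = decay_exponent,
         boost_by_height = boost_by_height,
         node_height = height, node_boost = boost_by_height[height + 1L],
         leaf_boost = boost_leaf, noise = noise, depth = depth,
         sigma = sigma, seed = seed),
    class = "planted_hierarchy"
  )
}

# height of each internal node (leaves are height 0)
node_heights <- function(tree) {
  h <- integer(tree$K - 1L)
  for (j in seq_len(tree$K - 1L)) {
    ch <- tree$merge[j, ]
    h[j] <- 1L + max(ifelse(ch < 0, 0L, h[pmax(ch, 1L)]))
  }
  h
}

#' @export
print.planted_hierarchy <- function(x, ...) {
  cat(sprintf("<planted_hierarchy> %d TADs, %d bins of %d bp, noise %s\n",
              x$tree$K, max(x$tads$end) / x$bin_size, x$bin_size, x$noise))
  invisible(x)
}

# K x K matrix of log boost products per TAD pair: product over all tree
# nodes (leaf TADs included) whose span contains both TADs
planted_log_boost <- function(h) {
  K <- h$tree$K
  lb <- matrix(0, K, K)
  diag(lb) <- log(h$leaf_boost)
  for (j in seq_len(K - 1L)) {
    sp <- h$tree$span[j, ]
    idx <- sp[1]:sp[2]
    lb[idx, idx] <- lb[idx, idx] + log(h$node_boost[j])
  }
  lb
}

# noiseless expected bin-level matrix
planted_expectation <- function(h, scale = 1) {
  bs <- h$bin_size
  nb <- max(h$tads$end) / bs
  tob <- tad_of_bin(h$tads, bs)
  lb <- planted_log_boost(h)
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  scale * (d + 1)^(-h$decay_exponent) * exp(lb[tob, tob])
}

#' Simulate a Hi-C contact matrix from a planted hierarchy
#'
#' Expected contact between bins i and j is
#' `scale * (|i-j| + 1)^(-decay_exponent)` times the product of the level
#' boosts of every tree node (including the leaf TAD) containing both
#' bins, with the hierarchy's noise model applied on top.
#'
#' @param h a [plant_hierarchy()] result.
#' @param scale overall contact scale `A`.
#' @param seed RNG seed for the noise draw (defaults to the hierarchy's).
#' @return a [contact_matrix()].
#' @export
simulate_contact_matrix <- function(h, scale = 1, seed = h$seed) {
  stopifnot(inherits(h, "planted_hierarchy"))
  mu <- planted_expectation(h, scale)
  set.seed(seed)
  x <- switch(h$noise,
    none = mu,
    poisson = {
      nb <- nrow(mu)
      up <- which(upper.tri(mu, diag = TRUE))
      v <- rpois(length(up), h$depth * mu[up]) / h$depth
      out <- matrix(0, nb, nb)
      out[up] <- v
      out + t(out) - diag(diag(out))
    },
    lognormal = {
      nb <- nrow(mu)
      up <- which(upper.tri(mu, diag = TRUE))
      v <- mu[up] * rlnorm(length(up), -h$sigma^2 / 2, h$sigma)
      out <- matrix(0, nb, nb)
      out[up] <- v
      out + t(out) - diag(diag(out))
    })
  contact_matrix(x, chrom = h$tads$chrom[1], bin_size = h$bin_size)
}

#' Simulate a tree-correlated feature track
#'
#' Every tree node (leaves included) receives an independent Gaussian
#' effect of sd `level_sd`; a TAD's value is the sum of effects along its
#' root-to-leaf path, so TADs that are close in the tree share most of
#' their effects and their values decorrelate with tree distance.  Per-bin
#' values add Gaussian jitter of sd `bin_jitter_sd`.
#'
#' @param h a [plant_hierarchy()] result.
#' @param level_sd per-node effect sd (>= 0).
#' @param bin_jitter_sd per-bin jitter sd (>= 0).
#' @param seed RNG seed.
#' @return list with `track` (per-bin bedGraph-style data.frame `chrom`,
#'   `start`, `end`, `value`) and `tad_values` (numeric, one per TAD).
#' @export
simulate_feature_track <- function(h, level_sd = 1, bin_jitter_sd = 0.2,
                                   seed = h$seed) {
  stopifnot(inherits(h, "planted_hierarchy"), level_sd >= 0,
            bin_jitter_sd >= 0)
  set.seed(seed)
  tree <- h$tree
  K <- tree$K
  eff <- rnorm(2L * K - 1L, 0, level_sd)  # leaves 1..K, internal K+j
  anc <- leaf_ancestors(tree)
  tad_values <- vapply(anc, function(chain) sum(eff[chain]), numeric(1))
  bs <- h$bin_size
  nb <- max(h$tads$end) / bs
  tob <- tad_of_bin(h$tads, bs)
  vals <- tad_values[tob] + rnorm(nb, 0, bin_jitter_sd)
  track <- data.frame(chrom = h$tads$chrom[1],
                      start = (seq_len(nb) - 1) * bs,
                      end = seq_len(nb) * bs, value = vals)
  list(track = track, tad_values = tad_values)
}

#' Plan a controlled rewiring between two time points
#'
#' @param swapped_nodes internal-node merge ranks of the hierarchy whose
#'   local merge order is inverted in time point B; their spans must be
#'   disjoint and each must contain at least 3 TADs.
#' @param expression_shift multiplicative expression change applied to the
#'   TADs of each shifted subtree.
#' @param coherent_fraction fraction of shifted subtrees whose member TADs
#'   all move in the same direction.
#' @return object of class `rewiring_plan`.
#' @export
rewiring_plan <- function(swapped_nodes = integer(),
                          expression_shift = 2,
                          coherent_fraction = 1) {
  stopifnot(coherent_fraction >= 0, coherent_fraction <= 1,
            expression_shift > 0)
  structure(list(swapped_nodes = as.integer(swapped_nodes),
                 expression_shift = expression_shift,
                 coherent_fraction = coherent_fraction),
            class = "rewiring_plan")
}

# ---- nested-node helpers for subtree rotation --------------------------

tree_to_nested <- function(tree) {
  build <- function(c) {
    if (c < 0) return(list(leaf = -c))
    list(left = build(tree$merge[c, 1]), right = build(tree$merge[c, 2]))
  }
  build(tree$K - 1L)
}

nested_to_tree <- function(node, tads = NULL, linkage = "planted") {
  merge <- matrix(0L, 0L, 2L)
  walk <- function(nd) {
    if (!is.null(nd$leaf)) return(-nd$leaf)
    l <- walk(nd$left); r <- walk(nd$right)
    merge <<- rbind(merge, c(l, r))
    nrow(merge)
  }
  walk(node)
  metatad_tree(merge, tads = tads, linkage = linkage)
}

# invert the merge preference below a node: ((LL,LR),R) -> (LL,(LR,R)),
# or (L,(RL,RR)) -> ((L,RL),RR) when the left child is a leaf
rotate_node <- function(nd) {
  if (is.null(nd$left$leaf)) {
    list(left = nd$left$left,
         right = list(left = nd$left$right, right = nd$right))
  } else if (is.null(nd$right$leaf)) {
    list(left = list(left = nd$left, right = nd$right$left),
         right = nd$right$right)
  } else {
    stop("cannot rewire a node with two leaf children")
  }
}

nested_span <- function(nd) {
  if (!is.null(nd$leaf)) return(c(nd$leaf, nd$leaf))
  c(nested_span(nd$left)[1], nested_span(nd$right)[2])
}

#' Simulate a rewired time-point pair
#'
#' Produces matched contact matrices and per-TAD expression tables for two
#' time points.  Time point B's hierarchy differs from A by inverting the
#' local merge order inside each node of `plan$swapped_nodes`; contact
#' boosts outside those subtrees are untouched (nodes whose span is
#' unchanged keep their boost).  Expression in B multiplies the TADs of
#' each shifted subtree by `expression_shift`, upward for coherent
#' subtrees and in per-TAD random directions otherwise; both tables carry
#' multiplicative lognormal measurement noise of log-sd `expr_noise_sd`.
#'
#' @param h a [plant_hierarchy()] result (time point A).
#' @param plan a [rewiring_plan()].
#' @param base_expr_meanlog,base_expr_sdlog lognormal baseline expression
#'   parameters (FPKM-like units).
#' @param expr_noise_sd measurement noise log-sd (0 = noiseless).
#' @param seed RNG seed.
#' @return list: `mat_a`, `mat_b` ([contact_matrix()]), `expr_a`, `expr_b`
#'   (numeric per TAD), `hierarchy_b` (`planted_hierarchy` of B),
#'   `changed_tads` (ground-truth TAD ids inside swapped nodes).
#' @export
simulate_timepoint_pair <- function(h, plan, base_expr_meanlog = 2.5,
                                    base_expr_sdlog = 1,
                                    expr_noise_sd = 0.05, seed = h$seed) {
  stopifnot(inherits(h, "planted_hierarchy"), inherits(plan, "rewiring_plan"))
  sw <- plan$swapped_nodes
  if (length(sw)) {
    if (any(sw < 1 | sw > h$tree$K - 1L)) stop("swapped node out of range")
    sp <- h$tree$span[sw, , drop = FALSE]
    o <- order(sp[, 1])
    if (any(sp[o, 1][-1] <= sp[o, 2][-length(sw)])) {
      stop("swapped nodes must be disjoint")
    }
  }
  # build hierarchy B by rotating each swapped subtree
  nested <- tree_to_nested(h$tree)
  spans_to_swap <- if (length(sw)) h$tree$span[sw, , drop = FALSE]
                   else matrix(0L, 0L, 2L)
  rewire <- function(nd) {
    if (!is.null(nd$leaf)) return(nd)
    sp <- nested_span(nd)
    hit <- which(spans_to_swap[, 1] == sp[1] & spans_to_swap[, 2] == sp[2])
    if (length(hit)) nd <- rotate_node(nd)
    nd$left <- rewire(nd$left); nd$right <- rewire(nd$right)
    nd
  }
  tree_b <- nested_to_tree(rewire(nested), tads = h$tads)
  h_b <- h
  h_b$tree <- tree_b
  height_b <- node_heights(tree_b)
  # nodes with a span present in A keep A's boost; new nodes get the boost
  # of their height in B (capped at the boost table length)
  key_a <- paste(h$tree$span[, 1], h$tree$span[, 2])
  key_b <- paste(tree_b$span[, 1], tree_b$span[, 2])
  idx <- match(key_b, key_a)
  bt <- h$boost_by_height
  hb <- pmin(height_b, length(bt) - 1L)
  h_b$node_boost <- ifelse(is.na(idx), bt[hb + 1L], h$node_boost[idx])
  h_b$node_height <- height_b

  set.seed(seed)
  expr_a <- rlnorm(h$tree$K, base_expr_meanlog, base_expr_sdlog)
  expr_b <- expr_a
  changed <- integer(0)
  if (length(sw)) {
    coherent <- runif(length(sw)) < plan$coherent_fraction
    for (i in seq_along(sw)) {
      ids <- h$tree$span[sw[i], 1]:h$tree$span[sw[i], 2]
      changed <- c(changed, ids)
      if (coherent[i]) {
        expr_b[ids] <- expr_b[ids] * plan$expression_shift
      } else {
        dir <- sample(c(TRUE, FALSE), length(ids), replace = TRUE)
        expr_b[ids] <- expr_b[ids] *
          ifelse(dir, plan$expression_shift, 1 / plan$expression_shift)
      }
    }
  }
  if (expr_noise_sd > 0) {
    expr_a <- expr_a * rlnorm(length(expr_a), 0, expr_noise_sd)
    expr_b <- expr_b * rlnorm(length(expr_b), 0, expr_noise_sd)
  }
  mat_a <- simulate_contact_matrix(h, seed = seed + 1L)
  mat_b <- simulate_contact_matrix(h_b, seed = seed + 2L)
  list(mat_a = mat_a, mat_b = mat_b, expr_a = expr_a, expr_b = expr_b,
       hierarchy_b = h_b, changed_tads = sort(changed))
}
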