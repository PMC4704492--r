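#' TAD-level contact matrix
#'
#' Entry (p, q) is the mean balanced contact over all unmasked bin pairs
#' with one bin in TAD p and the other in TAD q; the diagonal is the
#' intra-TAD mean.  With `correction = "oe"` the means are computed on the
#' observed/expected matrix, removing 1D proximity effects.
#'
#' @param m a [contact_matrix()].
#' @param tads a [tad_set()] tiling the region covered by `m`.
#' @param correction `"none"` or `"oe"`.
#' @return K x K symmetric matrix of class `tad_contact_matrix`;
#'   fully-masked TADs give `NA` rows/columns.
#' @export
tad_contact_matrix <- function(m, tads, correction = c("none", "oe")) {
  correction <- match.arg(correction)
  stopifnot(inherits(m, "contact_matrix"), inherits(tads, "tad_set"))
  if (correction == "oe") m <- oe_normalize(m)
  x <- m$counts
  bs <- m$bin_size
  K <- nrow(tads)
  idx <- lapply(seq_len(K), function(p) {
    (tads$start[p] / bs + 1):(tads$end[p] / bs)
  })
  t_mat <- matrix(NA_real_, K, K)
  for (p in seq_len(K)) {
    for (q in p:K) {
      v <- x[idx[[p]], idx[[q]], drop = FALSE]
      t_mat[p, q] <- t_mat[q, p] <-
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  structure(t_mat, class = c("tad_contact_matrix", "matrix", "array"),
            bin_size = bs, chrom = m$chrom)
}

#' Fraction of TADs whose strongest partner is a nearest neighbour
#'
#' For every TAD, finds the off-diagonal argmax of its TAD-level contacts;
#' reports the fraction for which that partner is the flanking TAD at
#' index +/- 1.  Ties involving a neighbour are broken toward the
#' neighbour and counted (the count of ties is reported as an attribute).
#'
#' @param t_mat a [tad_contact_matrix()] (or plain symmetric matrix).
#' @return fraction in `[0, 1]`; `attr(, "ties")` = number of TADs where
#'   the top score was tied.
#' @export
nearest_neighbour_fraction <- function(t_mat) {
  K <- nrow(t_mat)
  stopifnot(K >= 2)
  hits <- logical(K)
  ties <- 0L
  for (p in seq_len(K)) {
    v <- t_mat[p, ]
    v[p] <- NA
    top <- max(v, na.rm = TRUE)
    best <- which(v == top)
    if (length(best) > 1) ties <- ties + 1L
    hits[p] <- any(abs(best - p) == 1L)
  }
  structure(mean(hits), ties = ties)
}

#' Build the metaTAD tree by constrained agglomeration
#'
#' Iteratively merges the two most strongly interacting *genomically
#' adjacent* domains until the whole chromosome (arm) is a single domain.
#' The candidate score of an adjacent domain pair is, under `single`
#' linkage, the maximum TAD-level contact across the pair, and under
#' `average` linkage the mean of all cross TAD-level contacts.  Ties are
#' broken toward the leftmost genomic position (no RNG is used).
#'
#' @param t_mat a [tad_contact_matrix()].
#' @param linkage `"single"` or `"average"`.
#' @param tads optional [tad_set()] carried into the tree for genomic
#'   lengths.
#' @return a [metatad_tree()]; `merge_rank` is the merge order and `score`
#'   the candidate score at which each metaTAD formed.
#' @export
build_metatad_tree <- function(t_mat, linkage = c("single", "average"),
                               tads = NULL) {
  linkage <- match.arg(linkage)
  K0 <- nrow(t_mat)
  stopifnot(K0 >= 2)
  dropped <- which(vapply(seq_len(K0), function(p) {
    all(is.na(t_mat[p, -p]))
  }, logical(1)))
  if (length(dropped)) {
    stop("fully-masked TADs present (", paste(dropped, collapse = ", "),
         "); drop them from the TAD set first")
  }
  K <- K0
  act <- -seq_len(K)            # active domains, left-to-right
  lo <- hi <- seq_len(K)        # TAD index range per active domain
  merge <- matrix(0L, K - 1L, 2L)
  score <- numeric(K - 1L)
  pair_score <- function(i) {
    v <- t_mat[lo[i]:hi[i], lo[i + 1L]:hi[i + 1L], drop = FALSE]
    if (all(is.na(v))) return(NA_real_)
    if (linkage == "single") max(v, na.rm = TRUE) else mean(v, na.rm = TRUE)
  }
  sc <- vapply(seq_len(K - 1L), pair_score, numeric(1))
  for (j in seq_len(K - 1L)) {
    if (all(is.na(sc)) || max(sc, na.rm = TRUE) == 0 && all(sc == 0, na.rm = TRUE)) {
      if (j == 1L) warning("all candidate scores zero; merging leftmost pairs")
      i <- 1L
    } else {
      i <- which.max(sc)  # leftmost maximum
    }
    merge[j, ] <- c(act[i], act[i + 1L])
    score[j] <- sc[i]
    act[i] <- j
    hi[i] <- hi[i + 1L]
    act <- act[-(i + 1L)]; lo <- lo[-(i + 1L)]; hi <- hi[-(i + 1L)]
    sc <- sc[-i]  # pairs (i-1, i) now flank the merged domain
    if (length(act) > 1L) {
      if (i > 1L) sc[i - 1L] <- pair_score(i - 1L)
      if (i <= length(act) - 1L) sc[i] <- pair_score(i)
    }
  }
  metatad_tree(merge, score = score, tads = tads, linkage = linkage)
}

#' Shuffle a contact matrix within diagonals
#'
#' Permutes entries independently within each diagonal (constant |i-j|),
#' then restores symmetry.  Distance decay is preserved exactly while all
#' positional (TAD/metaTAD) structure is destroyed; this is the randomized
#' control matrix for enrichment statistics.
#'
#' @param m a [contact_matrix()].
#' @param seed RNG seed.
#' @return a [contact_matrix()].
#' @export
shuffle_matrix_by_diagonal <- function(m, seed = 1L) {
  stopifnot(inherits(m, "contact_matrix"))
  set.seed(seed)
  x <- m$counts
  nb <- nrow(x)
  out <- matrix(NA_real_, nb, nb)
  for (d in 0:(nb - 1)) {
    i <- seq_len(nb - d)
    v <- x[cbind(i, i + d)]
    v <- v[sample.int(length(v))]
    out[cbind(i, i + d)] <- v
    out[cbind(i + d, i)] <- v
  }
  res <- m
  res$counts <- out
  res
}

# sample one placement of two pseudo-domains of widths w1, w2 (bins)
# flanking a random TAD junction other than `exclude`; returns NULL if no
# junction fits
sample_flank_placement <- function(junctions, w1, w2, nb, exclude) {
  cand <- setdiff(junctions, exclude)
  cand <- cand[cand - w1 >= 1 & cand + w2 - 1 <= nb]
  if (!length(cand)) return(NULL)
  b <- cand[sample.int(length(cand), 1L)]
  list(left = (b - w1):(b - 1L), right = b:(b + w2 - 1L))
}

#' Inter-domain contact enrichment along the tree (I / I_C)
#'
#' For every merge that creates a metaTAD of `n` TADs, `I` is the mean
#' contact between the two merged domains.  The background `I_C` is the
#' mean over `n_placements` random placements of two pseudo-domains of the
#' same genomic sizes flanking the junction of any other neighbouring TAD
#' pair on the same chromosome.  The curve is aggregated over merges with
#' equal `n`.
#'
#' @param m a [contact_matrix()] (the same matrix the tree was built from).
#' @param tads the [tad_set()] of the tree leaves.
#' @param tree a [metatad_tree()] built from these TADs.
#' @param n_placements placements per merge.
#' @param seed RNG seed for placements.
#' @return data.frame of class `enrichment_curve`: one row per distinct
#'   `n` with columns `n`, `I`, `I_C`, `ratio`, `sd_C` (placement standard
#'   deviation), `n_merges`, `n_placed`.
#' @export
inter_domain_enrichment <- function(m, tads, tree, n_placements = 100,
                                    seed = 1L) {
  enrichment_curve(m, tads, tree, n_placements, seed, intra = FALSE)
}

#' Intra-domain contact enrichment along the tree (J / J_C)
#'
#' As [inter_domain_enrichment()], but `J` is the mean contact among all
#' bin pairs inside the whole metaTAD, and `J_C` comes from size-matched
#' windows whose left edge is anchored at the junction of a random other
#' neighbouring TAD pair.
#'
#' @inheritParams inter_domain_enrichment
#' @return data.frame of class `enrichment_curve` with columns `n`, `J`,
#'   `J_C`, `ratio`, `sd_C`, `n_merges`, `n_placed`.
#' @export
intra_domain_enrichment <- function(m, tads, tree, n_placements = 100,
                                    seed = 1L) {
  enrichment_curve(m, tads, tree, n_placements, seed, intra = TRUE)
}

enrichment_curve <- function(m, tads, tree, n_placements, seed, intra) {
  stopifnot(inherits(m, "contact_matrix"), inherits(tree, "metatad_tree"))
  set.seed(seed)
  x <- m$counts
  nb <- n_bins(m)
  bs <- m$bin_size
  first_bin <- tads$start / bs + 1L
  last_bin <- tads$end / bs
  junctions <- first_bin[-1]  # bin index starting TAD p+1, p = 1..K-1
  K <- tree$K
  obs <- numeric(K - 1L)
  bg_mean <- bg_sd <- rep(NA_real_, K - 1L)
  placed <- integer(K - 1L)
  for (j in seq_len(K - 1L)) {
    ch <- tree$merge[j, ]
    sp <- lapply(ch, function(c) {
      if (c < 0) c(-c, -c) else tree$span[c, ]
    })
    left_bins <- first_bin[sp[[1]][1]]:last_bin[sp[[1]][2]]
    right_bins <- first_bin[sp[[2]][1]]:last_bin[sp[[2]][2]]
    w1 <- length(left_bins); w2 <- length(right_bins)
    own_junction <- first_bin[sp[[2]][1]]
    if (intra) {
      bins <- c(left_bins, right_bins)
      obs[j] <- mean(x[bins, bins], na.rm = TRUE)
    } else {
      obs[j] <- mean(x[left_bins, right_bins], na.rm = TRUE)
    }
    vals <- numeric(0)
    for (r in seq_len(n_placements)) {
      pl <- sample_flank_placement(junctions, w1, w2, nb, own_junction)
      if (is.null(pl)) next
      v <- if (intra) {
        bins <- c(pl$left, pl$right)
        mean(x[bins, bins], na.rm = TRUE)
      } else {
        mean(x[pl$left, pl$right], na.rm = TRUE)
      }
      vals <- c(vals, v)
    }
    placed[j] <- length(vals)
    if (length(vals)) {
      bg_mean[j] <- mean(vals, na.rm = TRUE)
      bg_sd[j] <- sd(vals)
    }
  }
  keep <- placed > 0
  if (!all(keep)) {
    warning(sum(!keep), " merges excluded: no background placement fits")
  }
  nn <- tree$n[keep]
  agg <- function(v) tapply(v, nn, mean, na.rm = TRUE)
  out <- data.frame(
    n = as.integer(names(agg(obs[keep]))),
    obs = as.numeric(agg(obs[keep])),
    bg = as.numeric(agg(bg_mean[keep])),
    sd_C = as.numeric(agg(bg_sd[keep])),
    n_merges = as.integer(table(nn)),
    n_placed = as.numeric(tapply(placed[keep], nn, mean))
  )
  out$ratio <- out$obs / out$bg
  names(out)[2:3] <- if (intra) c("J", "J_C") else c("I", "I_C")
  out <- out[order(out$n), c("n", names(out)[2:3], "ratio", "sd_C",
                             "n_merges", "n_placed")]
  class(out) <- c("enrichment_curve", "data.frame")
  rownames(out) <- NULL
  out
}
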