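#' Aggregate a per-bin feature track over TADs
#'
#' @param track data.frame with `start`, `end`, `value` (bedGraph-style,
#'   0-based half-open, bp).
#' @param tads a [tad_set()].
#' @return numeric vector of per-TAD coverage-weighted means; `NA` for
#'   TADs with no covered bases.
#' @export
aggregate_feature_per_tad <- function(track, tads) {
  vapply(seq_len(nrow(tads)), function(i) {
    ov <- pmin(track$end, tads$end[i]) - pmax(track$start, tads$start[i])
    w <- pmax(ov, 0)
    if (sum(w) == 0) return(NA_real_)
    sum(w * track$value) / sum(w)
  }, numeric(1))
}

#' Feature correlation as a function of tree or linear distance
#'
#' For every distance `d` on the chosen axis, computes the Pearson (or
#' Spearman) correlation of per-TAD feature values across all unordered
#' TAD pairs at that distance, together with the pair count and the mean
#' genomic separation (midpoint to midpoint) of those pairs.
#'
#' @param values per-TAD feature values (NA values drop the TAD).
#' @param distances either a `tree_distances()` matrix or the string
#'   `"linear"` for TAD index offsets.
#' @param tads a [tad_set()] (for genomic separations; required).
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame of class `correlation_profile`: `distance`,
#'   `correlation`, `n_pairs`, `mean_separation` (bp); distances with
#'   fewer than 2 pairs are omitted.
#' @export
correlation_vs_distance <- function(values, distances, tads,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  K <- length(values)
  stopifnot(nrow(tads) == K)
  if (is.character(distances) && distances == "linear") {
    distances <- abs(outer(seq_len(K), seq_len(K), "-"))
    axis <- "linear"
  } else {
    stopifnot(is.matrix(distances), nrow(distances) == K)
    axis <- "tree"
  }
  mid <- (tads$start + tads$end) / 2
  ok <- which(!is.na(values))
  pairs <- which(upper.tri(distances), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] %in% ok & pairs[, 2] %in% ok, , drop = FALSE]
  d <- distances[pairs]
  sep <- abs(mid[pairs[, 1]] - mid[pairs[, 2]])
  out <- do.call(rbind, lapply(sort(unique(d)), function(dd) {
    sel <- d == dd
    if (sum(sel) < 2) return(NULL)
    # unordered pairs entered once, (min id, max id) orientation
    u <- values[pairs[sel, 1]]; v <- values[pairs[sel, 2]]
    r <- suppressWarnings(cor(u, v, method = method))
    data.frame(distance = dd, correlation = r, n_pairs = sum(sel),
               mean_separation = mean(sep[sel]))
  }))
  attr(out, "axis") <- axis
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Correlation length of a profile
#'
#' Smallest genomic separation at which the correlation first drops below
#' `threshold`, linearly interpolated between adjacent profile points.  A
#' profile that never drops below the threshold returns its largest mean
#' separation flagged `censored`; one that starts below returns 0 flagged
#' `below_threshold`.
#'
#' @param profile a [correlation_vs_distance()] result.
#' @param threshold correlation threshold (default 0.2, i.e. 20%).
#' @return length in bp with attribute `flag` (`"ok"`, `"censored"` or
#'   `"below_threshold"`).
#' @export
correlation_length <- function(profile, threshold = 0.2) {
  p <- profile[is.finite(profile$correlation), ]
  p <- p[order(p$mean_separation), ]
  if (!nrow(p)) stop("empty correlation profile")
  r <- p$correlation; s <- p$mean_separation
  if (r[1] < threshold) {
    return(structure(0, flag = "below_threshold"))
  }
  below <- which(r < threshold)
  if (!length(below)) {
    return(structure(s[length(s)], flag = "censored"))
  }
  k <- below[1]
  frac <- (r[k - 1] - threshold) / (r[k - 1] - r[k])
  structure(s[k - 1] + frac * (s[k] - s[k - 1]), flag = "ok")
}

#' P-values against the random-neighbour-tree null
#'
#' Compares an observed tree-axis correlation profile with profiles
#' computed from an ensemble of [random_neighbour_trees()]; the one-sided
#' p-value at each distance is the fraction of random trees whose
#' correlation at that distance is >= the observed one, with a +1
#' pseudocount in numerator and denominator.
#'
#' @param values per-TAD feature values.
#' @param tads a [tad_set()].
#' @param observed observed `correlation_profile` on the tree axis.
#' @param ensemble list of trees from [random_neighbour_trees()].
#' @param method correlation method.
#' @return data.frame `distance`, `correlation`, `p`, `n_trees`.
#' @export
correlation_pvalue <- function(values, tads, observed, ensemble,
                               method = "pearson") {
  rand <- lapply(ensemble, function(tr) {
    correlation_vs_distance(values, tree_distances(tr), tads, method)
  })
  out <- observed[, c("distance", "correlation")]
  out$p <- NA_real_
  out$n_trees <- length(ensemble)
  for (i in seq_len(nrow(out))) {
    rc <- vapply(rand, function(p) {
      j <- match(out$distance[i], p$distance)
      if (is.na(j)) NA_real_ else p$correlation[j]
    }, numeric(1))
    rc <- rc[!is.na(rc)]
    out$p[i] <- (sum(rc >= out$correlation[i]) + 1) / (length(rc) + 1)
  }
  out
}

#' A/B compartments from the first principal component
#'
#' Computes the Pearson correlation matrix of the observed/expected map
#' and takes its first principal component; bins are labelled A or B by
#' the sign of their score.  With a `reference` track (gene density or GC
#' content) the sign is oriented so that A has the higher mean reference
#' value; otherwise the first unmasked bin is fixed positive.
#'
#' @param m a balanced [contact_matrix()].
#' @param reference optional per-bin reference values (length = bins).
#' @return data.frame of class `compartment_track`: `bin`, `score`,
#'   `label` (`"A"`/`"B"`, `NA` for masked bins).
#' @export
compartments_pc1 <- function(m, reference = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (all(is.na(m$counts)) || max(m$counts, na.rm = TRUE) == 0) {
    stop("degenerate (rank-0) matrix")
  }
  oe <- oe_normalize(m)$counts
  keep <- which(!apply(is.na(oe), 1, all))
  x <- oe[keep, keep, drop = FALSE]
  x[is.na(x)] <- 1
  reliable <- TRUE
  if (max(apply(x, 2, sd)) < 1e-10) {
    # structureless map: no compartment signal
    warning("uniform O/E matrix: compartment labels unreliable")
    reliable <- FALSE
    score <- rep(0, length(keep))
  } else {
    cc <- suppressWarnings(cor(x))
    cc[is.na(cc)] <- 0
    pc <- prcomp(cc, center = TRUE, scale. = FALSE)
    score <- pc$x[, 1]
  }
  if (!is.null(reference)) {
    ra <- mean(reference[keep][score > 0], na.rm = TRUE)
    rb <- mean(reference[keep][score <= 0], na.rm = TRUE)
    if (isTRUE(rb > ra)) score <- -score
  } else if (score[1] < 0) {
    score <- -score
  }
  out <- data.frame(bin = seq_len(nrow(oe)), score = NA_real_,
                    label = NA_character_)
  out$score[keep] <- score
  if (reliable) out$label[keep] <- ifelse(score > 0, "A", "B")
  attr(out, "reliable") <- reliable
  class(out) <- c("compartment_track", "data.frame")
  out
}

#' Per-TAD majority compartment label
#'
#' @param comp a [compartments_pc1()] result.
#' @param tads a [tad_set()].
#' @param bin_size bin width in bp.
#' @return data.frame `id`, `label` (majority), `frac_a` (fraction of
#'   labelled bins in A).
#' @export
tad_compartment <- function(comp, tads, bin_size) {
  tob <- tad_of_bin(tads, bin_size)
  vapply(seq_len(nrow(tads)), function(i) {
    lab <- comp$label[which(tob == i)]
    mean(lab == "A", na.rm = TRUE)
  }, numeric(1)) -> frac_a
  data.frame(id = tads$id,
             label = ifelse(is.nan(frac_a), NA_character_,
                            ifelse(frac_a >= 0.5, "A", "B")),
             frac_a = frac_a)
}

#' Same-compartment frequency versus tree distance
#'
#' For each tree distance, the fraction of TAD pairs sharing their
#' majority compartment label, with the same quantity computed over
#' linear (TAD index) distance as baseline.
#'
#' @param tree a [metatad_tree()].
#' @param labels per-TAD compartment labels (`"A"`/`"B"`).
#' @return data.frame `distance`, `freq_tree`, `n_tree`, `freq_linear`,
#'   `n_linear`.
#' @export
co_compartment_vs_tree <- function(tree, labels) {
  K <- tree$K
  stopifnot(length(labels) == K)
  td <- tree_distances(tree)
  ld <- abs(outer(seq_len(K), seq_len(K), "-"))
  same <- outer(labels, labels, "==")
  up <- upper.tri(td)
  ok <- up & !is.na(same)
  freq_at <- function(dm) {
    ds <- sort(unique(dm[ok]))
    data.frame(distance = ds,
               freq = vapply(ds, function(d) mean(same[ok & dm == d]),
                             numeric(1)),
               n = vapply(ds, function(d) sum(ok & dm == d), numeric(1)))
  }
  ft <- freq_at(td); fl <- freq_at(ld)
  names(ft) <- c("distance", "freq_tree", "n_tree")
  names(fl) <- c("distance", "freq_linear", "n_linear")
  merge(ft, fl, by = "distance", all = TRUE)
}

#' Average feature profiles across TAD and metaTAD boundaries
#'
#' Means of a per-bin feature in offset bins around every internal TAD
#' boundary and around the outer boundaries of metaTADs whose genomic
#' length falls in `size_range`, with 95% confidence intervals
#' (mean +/- 1.96 SE).  Boundaries whose window would run off the
#' chromosome are excluded.
#'
#' @param track per-bin track data.frame (`start`, `end`, `value`).
#' @param tads a [tad_set()].
#' @param tree a [metatad_tree()] over the TADs.
#' @param flank flank size in bp on each side.
#' @param size_range metaTAD genomic length range in bp (default 10-40 Mb).
#' @return data.frame `class` (`"TAD"`/`"metaTAD"`), `offset` (bp, bin
#'   midpoint relative to boundary), `mean`, `lo`, `hi`, `n_boundaries`.
#' @export
boundary_profiles <- function(track, tads, tree, flank = 9e5,
                              size_range = c(1e7, 4e7)) {
  bs <- track$end[1] - track$start[1]
  nb <- nrow(track)
  w <- as.integer(round(flank / bs))
  tad_bounds <- tads$start[-1]
  meta <- which(tree$d >= size_range[1] & tree$d <= size_range[2])
  meta_bounds <- unique(unlist(lapply(meta, function(j) {
    c(tads$start[tree$span[j, 1]], tads$end[tree$span[j, 2]])
  })))
  meta_bounds <- setdiff(meta_bounds, c(min(tads$start), max(tads$end)))
  profile_for <- function(bounds, cls) {
    rows <- lapply(bounds, function(b) {
      cb <- b / bs  # boundary sits between bins cb and cb+1
      if (cb - w + 1 < 1 || cb + w > nb) return(NULL)
      track$value[(cb - w + 1):(cb + w)]
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) return(NULL)
    mu <- colMeans(rows)
    se <- apply(rows, 2, sd) / sqrt(nrow(rows))
    data.frame(class = cls,
               offset = (seq_len(2 * w) - w - 0.5) * bs,
               mean = mu, lo = mu - 1.96 * se, hi = mu + 1.96 * se,
               n_boundaries = nrow(rows))
  }
  rbind(profile_for(tad_bounds, "TAD"),
        profile_for(meta_bounds, "metaTAD"))
}

#' Coincidence of boundaries with LAD transitions
#'
#' A boundary is coincident when a transition between lamina-associated
#' and lamina-detached state lies within `window` bp.  Significance comes
#' from `n_perm` circular shifts of the boundary set along the chromosome
#' (one-sided, +1 pseudocount).
#'
#' @param boundaries boundary positions in bp.
#' @param lads data.frame of LAD intervals (`start`, `end`, bp).
#' @param chrom_length chromosome length in bp (circularization span).
#' @param window coincidence window in bp (default 100 kb).
#' @param n_perm number of circular permutations.
#' @param seed RNG seed.
#' @return list `fraction` (coincident fraction), `p`, `transitions`.
#' @export
lad_transition_coincidence <- function(boundaries, lads, chrom_length,
                                       window = 1e5, n_perm = 1000,
                                       seed = 1L) {
  trans <- sort(unique(c(lads$start, lads$end)))
  trans <- trans[trans > 0 & trans < chrom_length]
  if (!length(trans)) {
    return(list(fraction = 0, p = 1, transitions = 0))
  }
  frac_fun <- function(b) {
    mean(vapply(b, function(p) any(abs(trans - p) <= window), logical(1)))
  }
  obs <- frac_fun(boundaries)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    frac_fun((boundaries + runif(1, 0, chrom_length)) %% chrom_length)
  }, numeric(1))
  list(fraction = obs, p = (sum(null >= obs) + 1) / (n_perm + 1),
       transitions = length(trans))
}
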