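# restrict two trees' leaf-pair distance matrices to a shared-leaf mapping
shared_distances <- function(tree_a, tree_b, shared = NULL) {
  if (is.null(shared)) {
    stopifnot(tree_a$K == tree_b$K)
    shared <- data.frame(id_a = seq_len(tree_a$K), id_b = seq_len(tree_a$K))
  }
  da <- tree_distances(tree_a)[shared$id_a, shared$id_a, drop = FALSE]
  db <- tree_distances(tree_b)[shared$id_b, shared$id_b, drop = FALSE]
  list(da = da, db = db, shared = shared)
}

#' Cophenetic correlation between two metaTAD trees
#'
#' Global tree-similarity measure: the Pearson correlation between the
#' leaf-pair tree-distance vectors of the two trees, restricted to shared
#' leaves (e.g. conserved TADs from [match_boundaries()]).
#'
#' @param tree_a,tree_b [metatad_tree()] objects.
#' @param shared optional data.frame (`id_a`, `id_b`) mapping shared
#'   leaves; `NULL` when both trees have identical leaf sets.
#' @return correlation in `[-1, 1]`; `NA` with a warning when either
#'   restricted distance vector is constant.
#' @export
cophenetic_correlation <- function(tree_a, tree_b, shared = NULL) {
  sd_ <- shared_distances(tree_a, tree_b, shared)
  if (nrow(sd_$shared) < 3) stop("need >= 3 shared leaves")
  up <- upper.tri(sd_$da)
  va <- sd_$da[up]; vb <- sd_$db[up]
  if (sd(va) == 0 || sd(vb) == 0) {
    warning("constant distance vector: cophenetic correlation undefined")
    return(NA_real_)
  }
  cor(va, vb)
}

#' Local tree change around each TAD
#'
#' For every shared TAD `t`, takes its tree neighbourhood in A out to the
#' distance of the third-closest shared leaf, and scores the mean absolute
#' change of tree distance to those neighbours between time points; the
#' score is symmetrized by averaging with the same computation anchored on
#' B, then standardized to z-scores across the scored set.
#'
#' @inheritParams cophenetic_correlation
#' @return data.frame of class `local_tree_change`: `id_a`, `id_b`,
#'   `raw`, `z`, and the binary calls `changed_z` (`z > 0`) and
#'   `changed_raw` (`raw > 1`).
#' @export
local_tree_change <- function(tree_a, tree_b, shared = NULL) {
  sd_ <- shared_distances(tree_a, tree_b, shared)
  da <- sd_$da; db <- sd_$db
  n <- nrow(da)
  anchor_score <- function(d_ref, d_other) {
    vapply(seq_len(n), function(t) {
      d <- d_ref[t, -t]
      delta <- abs(d_ref[t, -t] - d_other[t, -t])
      r <- sort(d)[min(3L, length(d))]  # distance of 3rd-closest leaf
      mean(delta[d <= r])
    }, numeric(1))
  }
  raw <- (anchor_score(da, db) + anchor_score(db, da)) / 2
  z <- if (sd(raw) > 0) (raw - mean(raw)) / sd(raw) else {
    warning("degenerate standardization: all raw scores equal")
    rep(0, n)
  }
  out <- data.frame(id_a = sd_$shared$id_a, id_b = sd_$shared$id_b,
                    raw = raw, z = z,
                    changed_z = z > 0, changed_raw = raw > 1)
  class(out) <- c("local_tree_change", "data.frame")
  out
}

#' Classify per-TAD expression changes
#'
#' A TAD is called up- or down-regulated only when BOTH criteria pass:
#' fold change above `fold_thresh` (computed with a pseudocount so that
#' zero-expression TADs are defined) and absolute difference above
#' `iqr_frac` times the interquartile range of the absolute per-TAD
#' differences of the transition.  The absolute-difference criterion
#' excludes TADs with large fold changes at negligible expression.
#'
#' @param expr_a,expr_b non-negative per-TAD expression (FPKM-like).
#' @param fold_thresh fold-change threshold (default 1.5).
#' @param iqr_frac fraction of the IQR (default 0.25, i.e. IQR/4).
#' @param pseudocount added to both values in the fold change.
#' @return data.frame of class `expression_change`: `diff`, `fold`,
#'   `class` (`"up"`, `"down"`, `"unchanged"`); `attr(, "iqr_threshold")`
#'   records the absolute-difference cutoff used.
#' @export
classify_expression_change <- function(expr_a, expr_b, fold_thresh = 1.5,
                                       iqr_frac = 0.25, pseudocount = 0.1) {
  stopifnot(length(expr_a) == length(expr_b),
            all(expr_a >= 0), all(expr_b >= 0))
  diff <- expr_b - expr_a
  fold <- pmax(expr_a + pseudocount, expr_b + pseudocount) /
          pmin(expr_a + pseudocount, expr_b + pseudocount)
  thr <- iqr_frac * IQR(abs(diff))
  changed <- fold > fold_thresh & abs(diff) > thr
  cls <- ifelse(!changed, "unchanged", ifelse(diff > 0, "up", "down"))
  out <- data.frame(diff = diff, fold = fold, class = cls)
  attr(out, "iqr_threshold") <- thr
  class(out) <- c("expression_change", "data.frame")
  out
}

# per-chromosome merged IRanges from a chrom/start/end data.frame
as_ranges_list <- function(x) {
  lapply(split(x, x$chrom), function(d) {
    IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
  })
}

#' Jaccard index of two genomic interval sets
#'
#' Intersection length over union length in bp; each set is internally
#' merged first, so the index is invariant to interval fragmentation.
#'
#' @param a,b data.frames with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Jaccard index in `[0, 1]`; `NA` with a warning when both sets
#'   are empty.
#' @export
jaccard_overlap <- function(a, b) {
  if (!nrow(a) && !nrow(b)) {
    warning("both interval sets empty: Jaccard undefined")
    return(NA_real_)
  }
  ra <- as_ranges_list(a); rb <- as_ranges_list(b)
  chroms <- union(names(ra), names(rb))
  inter <- union_ <- 0
  for (ch in chroms) {
    ia <- ra[[ch]]; ib <- rb[[ch]]
    wa <- if (is.null(ia)) 0 else sum(IRanges::width(ia))
    wb <- if (is.null(ib)) 0 else sum(IRanges::width(ib))
    wi <- if (is.null(ia) || is.null(ib)) 0 else
      sum(IRanges::width(IRanges::intersect(ia, ib)))
    inter <- inter + wi
    union_ <- union_ + wa + wb - wi
  }
  inter / union_
}

# circularly shift an interval set by `offset` bp on a chromosome of
# length `len`, splitting intervals that wrap
shift_intervals <- function(d, offset, len) {
  s <- (d$start + offset) %% len
  e <- s + (d$end - d$start)
  wrap <- e > len
  out <- rbind(
    data.frame(chrom = d$chrom[!wrap], start = s[!wrap], end = e[!wrap]),
    data.frame(chrom = d$chrom[wrap], start = s[wrap],
               end = rep(len, sum(wrap))),
    data.frame(chrom = d$chrom[wrap], start = rep(0, sum(wrap)),
               end = e[wrap] - len))
  out[out$end > out$start, ]
}

#' Circular permutation test of interval overlap
#'
#' Significance of the Jaccard overlap of two interval sets: each
#' permutation circularly shifts set A by an independent uniform offset on
#' each chromosome (intervals wrap around), preserving interval lengths
#' and per-chromosome coverage; the one-sided p-value is
#' `(#{J_perm >= J_obs} + 1) / (n_perm + 1)`.
#'
#' @inheritParams jaccard_overlap
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_perm number of permutations (> 0).
#' @param seed RNG seed.
#' @return list of class `overlap_result`: `jaccard`, `p`, `n_perm`,
#'   `seed`, `null` (permuted Jaccard values).
#' @export
circular_permutation_test <- function(a, b, chrom_lengths, n_perm = 10000,
                                      seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  j_obs <- jaccard_overlap(a, b)
  set.seed(seed)
  by_chr <- split(a, a$chrom)
  null <- vapply(seq_len(n_perm), function(i) {
    shifted <- do.call(rbind, lapply(names(by_chr), function(ch) {
      shift_intervals(by_chr[[ch]], runif(1, 0, chrom_lengths[[ch]]),
                      chrom_lengths[[ch]])
    }))
    jaccard_overlap(shifted, b)
  }, numeric(1))
  structure(list(jaccard = j_obs,
                 p = (sum(null >= j_obs) + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, null = null),
            class = "overlap_result")
}

#' Labelled genomic interval sets of structural and expression change
#'
#' Combines per-TAD local tree-change calls, expression-change calls and
#' compartment labels at two time points into labelled interval sets (one
#' per class) over the conserved-TAD intervals: tree change (`z > 0`) /
#' conservation, expression up / down / unchanged, and compartment
#' stays-A / stays-B / A-B transition, where a transition requires the
#' per-TAD A-coverage fraction to change by more than
#' `change_coverage_thresh`.
#'
#' @param tads the time-point-A [tad_set()] (intervals reported in A
#'   coordinates).
#' @param tree_change a [local_tree_change()] result.
#' @param expr_change a [classify_expression_change()] result for the same
#'   conserved-TAD set (rows aligned with `tree_change`).
#' @param comp_a,comp_b per-TAD A-coverage fractions (`frac_a` from
#'   [tad_compartment()]) at the two time points, aligned with
#'   `tree_change$id_a` / `id_b`.
#' @param change_coverage_thresh coverage-change threshold (default 0.25).
#' @return named list of interval data.frames (`chrom`, `start`, `end`):
#'   `tree_change`, `tree_conserved`, `expr_up`, `expr_down`,
#'   `expr_unchanged`, `stays_A`, `stays_B`, `AB_transition`.  TADs with a
#'   missing compartment fraction are excluded from the compartment sets.
#' @export
change_region_sets <- function(tads, tree_change, expr_change,
                               comp_a, comp_b,
                               change_coverage_thresh = 0.25) {
  ids <- tree_change$id_a
  iv <- function(sel) {
    d <- tads[tads$id %in% ids[sel], c("chrom", "start", "end")]
    rownames(d) <- NULL
    d
  }
  dcov <- abs(comp_b - comp_a)
  comp_ok <- !is.na(dcov)
  trans <- comp_ok & dcov > change_coverage_thresh
  stays_a <- comp_ok & !trans & comp_a >= 0.5
  stays_b <- comp_ok & !trans & comp_a < 0.5
  list(tree_change = iv(tree_change$changed_z),
       tree_conserved = iv(!tree_change$changed_z),
       expr_up = iv(expr_change$class == "up"),
       expr_down = iv(expr_change$class == "down"),
       expr_unchanged = iv(expr_change$class == "unchanged"),
       stays_A = iv(stays_a), stays_B = iv(stays_b),
       AB_transition = iv(trans))
}

#' Coherent expression change at conserved tree distances
#'
#' For each tree distance `d` up to `max_tree_distance`, takes the TAD
#' pairs whose tree distance equals `d` in both trees (conserved pairs)
#' and computes the fraction with identical expression-change class (both
#' up, both down, or both unchanged).  The null permutes class labels over
#' TADs; the p-value is one-sided with a +1 pseudocount.
#'
#' @inheritParams cophenetic_correlation
#' @param classes per-shared-TAD expression classes (`"up"`, `"down"`,
#'   `"unchanged"`), aligned with the shared mapping.
#' @param max_tree_distance largest tree distance reported.
#' @param n_perm label permutations.
#' @param seed RNG seed.
#' @return data.frame `distance`, `coherent`, `null_mean`, `p`,
#'   `n_pairs`; distances with no conserved pairs are omitted.
#' @export
coherent_change_enrichment <- function(tree_a, tree_b, classes,
                                       shared = NULL,
                                       max_tree_distance = 5,
                                       n_perm = 1000, seed = 1L) {
  sd_ <- shared_distances(tree_a, tree_b, shared)
  n <- nrow(sd_$da)
  stopifnot(length(classes) == n)
  up <- which(upper.tri(sd_$da), arr.ind = TRUE)
  conserved <- sd_$da[up] == sd_$db[up]
  d <- sd_$da[up]
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  out <- do.call(rbind, lapply(seq_len(max_tree_distance), function(dd) {
    sel <- conserved & d == dd
    if (!any(sel)) return(NULL)
    i <- up[sel, 1]; j <- up[sel, 2]
    obs <- mean(classes[i] == classes[j])
    null <- vapply(seq_len(n_perm), function(k) {
      p <- perms[, k]
      mean(classes[p[i]] == classes[p[j]])
    }, numeric(1))
    data.frame(distance = dd, coherent = obs, null_mean = mean(null),
               p = (sum(null >= obs) + 1) / (n_perm + 1),
               n_pairs = sum(sel))
  }))
  out
}
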