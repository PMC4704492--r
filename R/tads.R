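#' Ordered set of TAD intervals
#'
#' @param start,end interval bounds in bp, 0-based half-open, sorted and
#'   non-overlapping.
#' @param chrom chromosome name.
#' @return data.frame of class `tad_set` with columns `chrom`, `start`,
#'   `end`, `id` (1..K in genomic order).
#' @export
tad_set <- function(start, end, chrom = "chrS") {
  stopifnot(length(start) == length(end), all(end > start))
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (any(start[-1] < end[-length(end)])) stop("TAD intervals overlap")
  structure(
    data.frame(chrom = chrom, start = as.numeric(start),
               end = as.numeric(end), id = seq_along(start)),
    class = c("tad_set", "data.frame")
  )
}

#' Map bins to TADs
#'
#' @param tads a [tad_set()].
#' @param bin_size bin width in bp.
#' @return integer vector over bins covered by the TADs: TAD id of each bin
#'   (bin assigned by its start coordinate).
#' @export
tad_of_bin <- function(tads, bin_size) {
  nb <- max(tads$end) / bin_size
  starts <- (seq_len(nb) - 1) * bin_size
  findInterval(starts, tads$start)
}

#' Directionality index track
#'
#' For every bin, contrasts the upstream contact sum `A` and downstream
#' contact sum `B` within `window` bp:
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)` with `E = (A+B)/2`.
#' Bins nearer than `window` to a chromosome edge use the truncated window;
#' `A = B` (including `A = B = 0`) gives `DI = 0`.
#'
#' @param m a [contact_matrix()].
#' @param window window in bp on each side (>= 2 bins).
#' @return data.frame with columns `bin`, `A`, `B`, `di`;
#'   `attr(, "window")` records the window.
#' @export
directionality_index <- function(m, window = 2e6) {
  stopifnot(inherits(m, "contact_matrix"))
  nb <- n_bins(m)
  w <- max(2L, as.integer(round(window / m$bin_size)))
  if (w > nb) stop("window exceeds chromosome span")
  x <- m$counts
  x[is.na(x)] <- 0
  A <- B <- numeric(nb)
  for (i in seq_len(nb)) {
    up <- seq(max(1L, i - w), i - 1L)
    dn <- seq(i + 1L, min(nb, i + w))
    A[i] <- if (i > 1) sum(x[i, up]) else 0
    B[i] <- if (i < nb) sum(x[i, dn]) else 0
  }
  E <- (A + B) / 2
  di <- ifelse(E > 0, sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E), 0)
  out <- data.frame(bin = seq_len(nb), A = A, B = B, di = di)
  attr(out, "window") <- window
  class(out) <- c("di_track", "data.frame")
  out
}

#' Call TADs from a directionality index track
#'
#' Simplified segmentation: the DI track is median-filtered (width 3), bins
#' are classed strong-positive / strong-negative when `|DI|` exceeds the
#' chromosome-wise median absolute deviation of the track, and a boundary is
#' placed wherever a strong-negative run is followed by a strong-positive
#' run (the downstream-biased start of a new domain).  Every bin is assigned
#' to exactly one TAD; TADs shorter than `min_tad_bins` are merged into the
#' neighbour with the higher mean contact.
#'
#' @param di a `di_track` from [directionality_index()].
#' @param m the [contact_matrix()] the track came from (used to resolve
#'   short-TAD merges).
#' @param min_tad_bins minimum TAD length in bins.
#' @return a [tad_set()] tiling the chromosome.
#' @export
call_tads <- function(di, m, min_tad_bins = 3) {
  stopifnot(inherits(di, "di_track"), inherits(m, "contact_matrix"))
  nb <- n_bins(m)
  v <- stats::runmed(di$di, 3)
  thr <- mad(v[v != 0])
  if (!is.finite(thr) || thr == 0) thr <- mad(v)
  state <- integer(nb)
  state[v > thr] <- 1L
  state[v < -thr] <- -1L
  if (all(state == 0)) {
    warning("all-zero DI: single TAD spanning chromosome")
    return(tad_set(0, nb * m$bin_size, chrom = m$chrom))
  }
  # boundary where the most recent strong state was negative and a positive
  # strong run begins
  bounds <- integer(0)
  last_strong <- 0L
  for (i in seq_len(nb)) {
    if (state[i] == 1L && last_strong == -1L) bounds <- c(bounds, i)
    if (state[i] != 0L) last_strong <- state[i]
  }
  cuts <- sort(unique(c(1L, bounds, nb + 1L)))
  starts <- head(cuts, -1L)
  ends <- tail(cuts, -1L)
  # merge short TADs into the neighbour with higher mean contact
  x <- m$counts
  repeat {
    len <- ends - starts
    k <- which(len < min_tad_bins)
    if (!length(k) || length(starts) == 1L) break
    k <- k[1]
    bins_k <- starts[k]:(ends[k] - 1L)
    score <- function(j) {
      bins_j <- starts[j]:(ends[j] - 1L)
      mean(x[bins_k, bins_j], na.rm = TRUE)
    }
    left <- if (k > 1) score(k - 1) else -Inf
    right <- if (k < length(starts)) score(k + 1) else -Inf
    if (!is.finite(left) && !is.finite(right)) left <- 0
    if (left >= right) {
      starts <- starts[-k]; ends <- ends[-(k - 1)]
    } else {
      starts <- starts[-(k + 1)]; ends <- ends[-k]
    }
  }
  tad_set((starts - 1) * m$bin_size, (ends - 1) * m$bin_size, chrom = m$chrom)
}

#' Match TAD boundaries between two segmentations
#'
#' A boundary of `a` is conserved when some boundary of `b` lies within
#' `tol` bp.  A TAD of `a` is conserved when both of its boundaries are
#' conserved; each conserved TAD is mapped to the TAD of `b` with maximal
#' overlap.
#'
#' @param a,b [tad_set()] objects on the same chromosome.
#' @param tol matching tolerance in bp.
#' @param internal_only if `TRUE` (default) only internal boundaries (the
#'   K-1 junctions) enter the conserved-fraction numerator/denominator;
#'   chromosome ends always match.
#' @return list with `fraction` (conserved boundary fraction of `a`),
#'   `conserved_tads` (ids in `a`), and `tad_map` (data.frame `id_a`,
#'   `id_b`).
#' @export
match_boundaries <- function(a, b, tol, internal_only = TRUE) {
  stopifnot(inherits(a, "tad_set"), inherits(b, "tad_set"))
  if (a$chrom[1] != b$chrom[1]) stop("mismatched chromosomes")
  ba <- if (internal_only) a$start[-1] else unique(c(a$start, a$end))
  bb <- unique(c(b$start, b$end))
  conserved <- vapply(ba, function(p) any(abs(bb - p) <= tol), logical(1))
  fraction <- if (length(ba)) mean(conserved) else 1
  # per-TAD: both boundaries conserved (chromosome ends count as matched)
  edge_ok <- function(p) {
    p %in% c(min(a$start), max(a$end)) || any(abs(bb - p) <= tol)
  }
  tad_ok <- vapply(seq_len(nrow(a)), function(i) {
    edge_ok(a$start[i]) && edge_ok(a$end[i])
  }, logical(1))
  conserved_tads <- a$id[tad_ok]
  map <- vapply(conserved_tads, function(i) {
    ov <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start)
    which.max(ov)
  }, integer(1))
  list(fraction = fraction, conserved_tads = conserved_tads,
       tad_map = data.frame(id_a = conserved_tads, id_b = as.integer(map)))
}
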