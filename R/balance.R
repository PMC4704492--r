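#' Iterative correction (ICE) of a contact matrix
#'
#' Removes multiplicative per-bin biases by iteratively dividing each entry
#' by the product of its row and column marginal until all unmasked row sums
#' agree.  Bins whose raw marginal falls below `mask_quantile` of the
#' marginal distribution (or is zero) are masked before correction, the
#' standard practice for low-coverage bins.
#'
#' @param m a [contact_matrix()].
#' @param tol convergence tolerance on the maximum relative deviation of
#'   unmasked row sums from their mean.
#' @param max_iter maximum number of sweeps; if not converged the partial
#'   result is returned with a warning and `attr(, "converged") = FALSE`.
#' @param mask_quantile coverage quantile below which bins are masked.
#' @return a balanced [contact_matrix()] (row sums normalized to 1 over
#'   unmasked bins); per-bin biases in `attr(, "bias")`.
#' @export
ice_balance <- function(m, tol = 1e-6, max_iter = 200, mask_quantile = 0.02) {
  stopifnot(inherits(m, "contact_matrix"), tol > 0)
  x <- m$counts
  marg <- rowSums(x, na.rm = TRUE)
  thresh <- quantile(marg[marg > 0], mask_quantile, na.rm = TRUE)
  masked <- sort(unique(c(m$masked, which(marg <= 0 | marg < thresh))))
  keep <- setdiff(seq_len(nrow(x)), masked)
  if (length(keep) < 2) stop("fewer than 2 unmasked bins; cannot balance")
  y <- x[keep, keep, drop = FALSE]
  bias <- rep(1, length(keep))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(y)
    dev <- max(abs(s / mean(s) - 1))
    if (dev < tol) { converged <- TRUE; break }
    b <- sqrt(s / mean(s))  # damped update: plain s/mean can oscillate
    y <- y / outer(b, b)
    bias <- bias * b
  }
  if (!converged) warning("ice_balance did not converge in ", max_iter,
                          " iterations (residual ", signif(dev, 3), ")")
  y <- y / mean(rowSums(y))  # normalize unmasked row sums to 1
  out <- matrix(NA_real_, nrow(x), ncol(x))
  out[keep, keep] <- y
  res <- contact_matrix(out, chrom = m$chrom, bin_size = m$bin_size,
                        balanced = TRUE, masked = masked)
  full_bias <- rep(NA_real_, nrow(x))
  full_bias[keep] <- bias
  attr(res, "bias") <- full_bias
  attr(res, "converged") <- converged
  res
}

#' Mean contact as a function of genomic distance
#'
#' @param m a [contact_matrix()].
#' @return numeric vector `e` of length `n_bins`, `e[d + 1]` = mean of
#'   unmasked entries at bin offset `d`; `NA` where a whole diagonal is
#'   masked.
#' @export
expected_by_distance <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  x <- m$counts
  nb <- nrow(x)
  vapply(0:(nb - 1), function(d) {
    i <- seq_len(nb - d)
    v <- x[cbind(i, i + d)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Observed/expected normalization
#'
#' Divides every entry by the mean contact at its genomic distance,
#' correcting the map for 1D proximity effects.  The mean of each
#' unmasked diagonal of the result is 1 by construction.
#'
#' @param m a [contact_matrix()] (typically balanced).
#' @param background_subtract experimental: subtract the per-distance
#'   minimum before normalizing (off by default; provided because some
#'   pipelines apply an additional background subtraction whose exact form
#'   is not standardized).
#' @return a [contact_matrix()] of O/E ratios.
#' @export
oe_normalize <- function(m, background_subtract = FALSE) {
  stopifnot(inherits(m, "contact_matrix"))
  x <- m$counts
  nb <- nrow(x)
  d <- abs(row(x) - col(x))
  if (background_subtract) {
    mins <- vapply(0:(nb - 1), function(k) {
      i <- seq_len(nb - k)
      v <- x[cbind(i, i + k)]
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    }, numeric(1))
    x <- x - matrix(mins[d + 1], nb, nb)
    m2 <- m; m2$counts <- x
    e <- expected_by_distance(m2)
  } else {
    e <- expected_by_distance(m)
  }
  e[!is.na(e) & e == 0] <- NA_real_
  oe <- x / matrix(e[d + 1], nb, nb)
  res <- m
  res$counts <- (oe + t(oe)) / 2
  res
}
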