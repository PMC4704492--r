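#' Binned Hi-C contact matrix
#'
#' Container for a symmetric per-chromosome binned contact map.  Coordinates
#' are 0-based half-open throughout; bin `i` (1-based index) covers
#' `[(i-1)*bin_size, i*bin_size)`.
#'
#' @param counts square numeric matrix of contact counts (symmetric,
#'   non-negative, finite).
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param balanced logical; has iterative correction been applied?
#' @param masked integer vector of bin indices excluded as low coverage.
#'   Masked rows/columns are set to `NA`.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom = "chrS", bin_size = 50000L,
                           balanced = FALSE, masked = integer()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("contact matrix must be square")
  }
  if (any(counts < 0, na.rm = TRUE)) {
    stop("contact matrix entries must be non-negative")
  }
  if (!isSymmetric(unname(counts), tol = 1e-8)) {
    warning("asymmetric input symmetrized by averaging")
    counts <- (counts + t(counts)) / 2
  } else {
    counts <- (counts + t(counts)) / 2  # exact symmetry
  }
  dimnames(counts) <- NULL
  masked <- sort(unique(as.integer(masked)))
  if (length(masked)) {
    counts[masked, ] <- NA_real_
    counts[, masked] <- NA_real_
  }
  structure(
    list(chrom = chrom, bin_size = as.integer(bin_size), counts = counts,
         balanced = isTRUE(balanced), masked = masked),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins x %d bp%s, %d masked\n",
              x$chrom, nrow(x$counts), x$bin_size,
              if (x$balanced) " (balanced)" else "", length(x$masked)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

n_bins <- function(m) nrow(m$counts)

unmasked_bins <- function(m) setdiff(seq_len(n_bins(m)), m$masked)

#' Read a contact matrix from disk
#'
#' Supports a dense TSV (square table, optionally upper-triangular with the
#' lower triangle zero or empty) and a long-format TSV with columns
#' `bin_i`, `bin_j`, `count` (1-based bin indices).  Asymmetric dense input
#' is symmetrized by averaging with a warning; an upper-triangular-only
#' matrix is mirrored without warning.
#'
#' @param path file path.
#' @param format one of `"dense_tsv"`, `"long_tsv"`.  The cooler/HDF5 and
#'   npz containers used by Python tooling are not supported by this build
#'   and raise an informative error.
#' @inheritParams contact_matrix
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("dense_tsv", "long_tsv",
                                                 "cooler_h5", "npz"),
                                chrom = "chrS", bin_size = 50000L) {
  format <- match.arg(format)
  if (format %in% c("cooler_h5", "npz")) {
    stop("format '", format, "' requires an HDF5/NumPy reader that is not ",
         "available; use dense_tsv or long_tsv")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dense_tsv") {
    x <- as.matrix(data.table::fread(path, header = FALSE))
    if (nrow(x) != ncol(x)) stop("dense contact matrix must be square")
    lower <- x[lower.tri(x)]
    upper <- t(x)[lower.tri(x)]
    if (all(lower == 0) && any(upper != 0)) {
      # upper-triangular storage: mirror
      x[lower.tri(x)] <- upper
    }
    return(contact_matrix(x, chrom = chrom, bin_size = bin_size))
  }
  dt <- data.table::fread(path, header = TRUE)
  nb <- max(dt$bin_i, dt$bin_j)
  x <- matrix(0, nb, nb)
  x[cbind(dt$bin_i, dt$bin_j)] <- dt$count
  x[cbind(dt$bin_j, dt$bin_i)] <- dt$count
  contact_matrix(x, chrom = chrom, bin_size = bin_size)
}

#' Write a contact matrix as dense TSV
#'
#' `NA` (masked) entries are written as 0 in dense format.
#'
#' @param m a [contact_matrix()].
#' @param path output file.
#' @export
write_contact_matrix <- function(m, path) {
  x <- m$counts
  x[is.na(x)] <- 0
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
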