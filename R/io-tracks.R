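# Plain-text genomic track IO (BED / bedGraph / TSV).  All coordinates are
# 0-based half-open, matching BED conventions.

#' Write intervals as BED
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `id`
#'   (name column) and `score`.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end",
            intersect(c("id", "score"), names(x)))
  data.table::fwrite(x[, cols], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file as a [tad_set()] (3+ columns) or plain data.frame
#'
#' @param path BED file.
#' @param as_tads coerce to [tad_set()] (requires a single chromosome).
#' @export
read_bed <- function(path, as_tads = FALSE) {
  d <- data.table::fread(path, header = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  d <- as.data.frame(d)
  if (as_tads) {
    stopifnot(length(unique(d$chrom)) == 1)
    return(tad_set(d$start, d$end, chrom = d$chrom[1]))
  }
  d
}

#' Write / read a per-bin track as bedGraph
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path file path.
#' @export
write_bedgraph <- function(track, path) {
  data.table::fwrite(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  d <- as.data.frame(data.table::fread(path, header = FALSE))
  names(d)[1:4] <- c("chrom", "start", "end", "value")
  d
}
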