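#' Genome-wide bin grid
#'
#' Partition every chromosome into fixed-width bins and set up the global
#' linear bin index used by all contact matrices. Bin \code{k} (0-based
#' ordinal) of a chromosome covers \code{[k*res, (k+1)*res)} in 0-based
#' half-open coordinates; the last bin of each chromosome is truncated at the
#' chromosome end. Linear indices are 1-based and run chromosome by
#' chromosome in the order given.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bases.
#' @param res Bin resolution in bases (typically 9000 or 3000).
#' @return An object of class \code{bin_grid}.
#' @examples
#' g <- bin_grid(c(chr1 = 25000, chr2 = 10000), res = 9000)
#' g$nbins  # 3 bins on chr1 (last truncated), 2 on chr2
#' @export
bin_grid <- function(chrom_lengths, res) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  res <- as.integer(res)
  if (is.na(res) || res <= 0) stop("res must be a positive integer")
  nbins <- as.integer(ceiling(chrom_lengths / res))
  offsets <- c(0L, cumsum(nbins))[seq_along(nbins)]
  names(offsets) <- names(chrom_lengths)
  structure(list(
    chroms  = names(chrom_lengths),
    lengths = chrom_lengths,
    res     = res,
    nbins   = stats::setNames(nbins, names(chrom_lengths)),
    offsets = offsets,
    total   = sum(nbins)
  ), class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d chromosome(s), %d bp resolution, %d bins\n",
              length(x$chroms), x$res, x$total))
  invisible(x)
}

#' Map genomic positions to global bin indices
#'
#' @param grid A \code{bin_grid}.
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 0-based positions.
#' @return Integer vector of 1-based global bin indices.
#' @export
bin_index <- function(grid, chrom, pos) {
  ci <- match(chrom, grid$chroms)
  if (anyNA(ci)) stop("unknown chromosome: ",
                      paste(unique(chrom[is.na(ci)]), collapse = ", "))
  if (any(pos < 0) || any(pos >= grid$lengths[ci]))
    stop("position outside chromosome bounds")
  as.integer(grid$offsets[ci] + floor(pos / grid$res) + 1L)
}

#' Bin coordinates for global bin indices
#'
#' Inverse of \code{\link{bin_index}}: returns chromosome and 0-based
#' half-open interval of each bin.
#'
#' @param grid A \code{bin_grid}.
#' @param idx Integer vector of 1-based global bin indices (default: all).
#' @return data.frame with columns bin, chrom, start, end.
#' @export
bin_coords <- function(grid, idx = seq_len(grid$total)) {
  if (any(idx < 1L | idx > grid$total)) stop("bin index out of range")
  ci <- findInterval(idx - 1L, grid$offsets)
  ord <- (idx - 1L) - grid$offsets[ci]
  start <- ord * grid$res
  data.frame(
    bin = as.integer(idx),
    chrom = grid$chroms[ci],
    start = start,
    end = pmin(start + grid$res, grid$lengths[ci]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# chromosome index (1-based position in grid$chroms) of each global bin
.bin_chrom_index <- function(grid, idx = seq_len(grid$total)) {
  findInterval(idx - 1L, grid$offsets)
}
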