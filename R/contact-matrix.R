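#' Bin valid ditags into a sparse contact matrix
#'
#' Each ditag increments exactly one upper-triangle entry (i <= j) of the
#' genome-wide symmetric contact matrix; the diagonal is allowed. Total
#' matrix mass equals the number of binned ditags.
#'
#' @param ditags data.frame of bona fide ditags.
#' @param grid A \code{bin_grid}.
#' @param bins Optional per-bin annotation from \code{\link{annotate_bins}};
#'   defaults to sites = NA, mapability = 1.
#' @return Object of class \code{contact_matrix}: the grid, a per-bin table
#'   (flags enriched/valid filled in by later steps), and a triplet table
#'   \code{counts} (i, j, n) with i <= j.
#' @export
bin_contacts <- function(ditags, grid, bins = NULL) {
  if (nrow(ditags)) {
    i <- bin_index(grid, ditags$chrom1, ditags$pos1)
    j <- bin_index(grid, ditags$chrom2, ditags$pos2)
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- (lo - 1) * as.double(grid$total) + hi
    agg <- rowsum(rep(1L, length(key)), group = key)
    k <- as.double(rownames(agg))
    counts <- data.frame(i = as.integer((k - 1) %/% grid$total + 1),
                         j = as.integer((k - 1) %% grid$total + 1),
                         n = as.numeric(agg[, 1]))
  } else {
    counts <- data.frame(i = integer(0), j = integer(0), n = numeric(0))
  }
  if (is.null(bins)) {
    bins <- bin_coords(grid)
    bins$sites <- NA_integer_
    bins$mapability <- 1
  }
  bins$enriched <- FALSE
  bins$valid <- TRUE
  structure(list(grid = grid, bins = bins, counts = counts,
                 mass = sum(counts$n)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(paste0("contact_matrix: %d bins at %d bp, %d populated entries,",
                     " mass %.0f\n"),
              x$grid$total, x$grid$res, nrow(x$counts), sum(x$counts$n)))
  cat(sprintf("  enriched bins: %d; valid bins: %d\n",
              sum(x$bins$enriched), sum(x$bins$valid)))
  invisible(x)
}

#' Flag capture-enriched bins
#'
#' A bin is enriched iff it overlaps at least one bait interval by >= 1 bp.
#'
#' @param m A \code{contact_matrix}.
#' @param baits data.frame (chrom, start, end), 0-based half-open, or NULL.
#' @return The matrix with \code{bins$enriched} updated.
#' @export
mark_enriched_bins <- function(m, baits) {
  m$bins$enriched <- FALSE
  if (is.null(baits) || nrow(baits) == 0) return(m)
  keep <- baits$chrom %in% m$grid$chroms
  baits <- baits[keep, , drop = FALSE]
  if (nrow(baits) == 0) return(m)
  gr_bins <- GenomicRanges::GRanges(m$bins$chrom,
    IRanges::IRanges(m$bins$start + 1L, m$bins$end))
  gr_bait <- GenomicRanges::GRanges(baits$chrom,
    IRanges::IRanges(baits$start + 1L, baits$end))
  m$bins$enriched <- GenomicRanges::countOverlaps(gr_bins, gr_bait) > 0
  m
}

#' Capture-enrichment class of a bin pair
#'
#' @param m A \code{contact_matrix} with enriched flags set.
#' @param i,j Global bin indices (vectors).
#' @return Character vector in {"EE", "EN", "NN"}: both, exactly one, or
#'   neither bin capture-enriched. Symmetric in (i, j).
#' @export
classify_pair <- function(m, i, j) {
  ne <- m$bins$enriched[i] + m$bins$enriched[j]
  c("NN", "EN", "EE")[ne + 1L]
}

#' Apply the valid-bin filter
#'
#' Bins with no restriction site or mean mapability not exceeding
#' \code{mapability_min} (strict) are marked invalid and their rows/columns
#' removed from the triplet store; downstream analysis never sees them.
#' Idempotent.
#'
#' @param m A \code{contact_matrix} with site/mapability annotation.
#' @param mapability_min Threshold, default 0.5 (bins must be strictly above).
#' @return Filtered \code{contact_matrix}.
#' @export
filter_valid_bins <- function(m, mapability_min = 0.5) {
  sites <- m$bins$sites
  sites[is.na(sites)] <- 1L  # unannotated bins are not excluded
  m$bins$valid <- sites > 0L & m$bins$mapability > mapability_min
  ok <- m$bins$valid[m$counts$i] & m$bins$valid[m$counts$j]
  m$counts <- m$counts[ok, , drop = FALSE]
  m
}

#' Intra-chromosomal window tiling
#'
#' Splits every chromosome into \code{ceiling(length / window)} windows of
#' as-equal-as-possible bin counts (a 20 Mb chromosome at 9 kb with a
#' 10 Mb window gives windows of 1112 and 1111 bins). Every
#' intra-chromosomal matrix entry falls in the window of its anchor bin,
#' so the union of views covers the cis entries exactly once. Used for
#' heatmap export and per-interval significance fits.
#'
#' @param m A \code{contact_matrix}.
#' @param window Window size in bases, default 10 Mb; must be >= resolution.
#' @return data.frame (chrom, win, bin_lo, bin_hi) of global bin ranges.
#' @export
window_views <- function(m, window = 1e7) {
  g <- m$grid
  if (window < g$res) stop("window must be at least one bin")
  out <- lapply(seq_along(g$chroms), function(ci) {
    nb <- g$nbins[ci]
    nw <- max(1L, as.integer(ceiling(g$lengths[ci] / window)))
    sizes <- rep(nb %/% nw, nw) + (seq_len(nw) <= nb %% nw)
    hi <- cumsum(sizes)
    lo <- hi - sizes + 1L
    data.frame(chrom = g$chroms[ci], win = seq_len(nw),
               bin_lo = g$offsets[ci] + lo, bin_hi = g$offsets[ci] + hi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# window ordinal (per chromosome) of each global bin index
.window_of <- function(m, idx, window = 1e7) {
  g <- m$grid
  ci <- .bin_chrom_index(g, idx)
  ord <- idx - g$offsets[ci]   # 1-based ordinal within chromosome
  nw <- pmax(1L, as.integer(ceiling(g$lengths[ci] / window)))
  nb <- g$nbins[ci]
  base <- nb %/% nw
  rem <- nb %% nw
  # first rem windows hold base+1 bins
  cut <- rem * (base + 1L)
  as.integer(ifelse(ord <= cut,
                    (ord - 1L) %/% (base + 1L) + 1L,
                    rem + (ord - cut - 1L) %/% pmax(base, 1L) + 1L))
}

#' Export a window of the matrix as a dense array
#'
#' @param m A \code{contact_matrix}.
#' @param bin_lo,bin_hi Global bin range (inclusive).
#' @param values Which entry values to use: "n" (raw) or "norm".
#' @return Dense symmetric numeric matrix with bin indices as dimnames.
#' @export
dense_window <- function(m, bin_lo, bin_hi, values = c("n", "norm")) {
  values <- match.arg(values)
  sel <- m$counts$i >= bin_lo & m$counts$i <= bin_hi &
         m$counts$j >= bin_lo & m$counts$j <= bin_hi
  cc <- m$counts[sel, , drop = FALSE]
  nb <- bin_hi - bin_lo + 1L
  out <- matrix(0, nb, nb, dimnames = list(bin_lo:bin_hi, bin_lo:bin_hi))
  v <- if (values == "norm") cc$norm else cc$n
  out[cbind(cc$i - bin_lo + 1L, cc$j - bin_lo + 1L)] <- v
  out[cbind(cc$j - bin_lo + 1L, cc$i - bin_lo + 1L)] <- v
  out
}
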