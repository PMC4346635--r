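#' In-silico restriction digestion of a genome
#'
#' Scans every chromosome for occurrences of the enzyme recognition pattern
#' (overlapping occurrences included) and places a cut at
#' \code{occurrence_start + cut_offset}. The default is HindIII (A^AGCTT),
#' which cuts one base into its palindromic site. Sequence is upper-cased
#' before matching; IUPAC ambiguity codes in the subject never match.
#'
#' All coordinates are 0-based half-open. Fragments tile each chromosome
#' without gaps or overlaps; a chromosome with no site yields one fragment
#' spanning the whole sequence.
#'
#' @param genome A named character vector of sequences, a
#'   \code{Biostrings::DNAStringSet}, or the path to a FASTA file.
#' @param pattern Recognition sequence over A/C/G/T. Default \code{"AAGCTT"}.
#' @param cut_offset Cut position within the pattern, \code{0..nchar(pattern)}.
#' @return An object of class \code{fragment_map} with per-chromosome cut
#'   positions, sequence lengths, and the digestion parameters.
#' @examples
#' fm <- digest_genome(c(chrA = "GGGAAGCTTGGG"))
#' fm$cuts$chrA      # 4
#' fragments(fm)     # [0,4) and [4,12)
#' @export
digest_genome <- function(genome, pattern = "AAGCTT", cut_offset = 1L) {
  seqs <- .as_dna(genome)
  if (length(seqs) == 0) stop("empty genome")
  pattern <- toupper(pattern)
  if (!nzchar(pattern) || grepl("[^ACGT]", pattern))
    stop("pattern must be a non-empty string over A/C/G/T")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(pattern))
    stop("cut_offset must be in 0..nchar(pattern)")
  lens <- Biostrings::width(seqs)
  names(lens) <- names(seqs)
  cuts <- lapply(seq_along(seqs), function(k) {
    if (lens[k] < nchar(pattern)) return(integer(0))
    m <- Biostrings::matchPattern(pattern, seqs[[k]], fixed = TRUE)
    cc <- BiocGenerics::start(m) - 1L + cut_offset
    # cuts at 0 or at the sequence end would create empty fragments
    sort(unique(cc[cc > 0L & cc < lens[k]]))
  })
  names(cuts) <- names(seqs)
  structure(list(cuts = cuts, seqlengths = lens,
                 pattern = pattern, cut_offset = cut_offset),
            class = "fragment_map")
}

.as_dna <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 0)
    return(Biostrings::DNAStringSet())
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("unsupported genome input")
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("fragment_map: %d chromosome(s), %d cut site(s), pattern %s (offset +%d)\n",
              length(x$cuts), sum(lengths(x$cuts)), x$pattern, x$cut_offset))
  invisible(x)
}

#' Restriction fragments of a digested genome
#'
#' @param fmap A \code{fragment_map}.
#' @return data.frame (chrom, start, end, fragment_id) of half-open fragment
#'   intervals tiling every chromosome.
#' @export
fragments <- function(fmap) {
  out <- lapply(names(fmap$cuts), function(ch) {
    b <- c(0, fmap$cuts[[ch]], fmap$seqlengths[[ch]])
    data.frame(chrom = ch, start = b[-length(b)], end = b[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$fragment_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Distance to the nearest restriction cut site
#'
#' @param fmap A \code{fragment_map}.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s), within chromosome bounds.
#' @return Numeric vector of minimum absolute distances in bases;
#'   \code{Inf} for a chromosome with no cut site.
#' @export
nearest_site_distance <- function(fmap, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  if (anyNA(match(chrom, names(fmap$cuts))))
    stop("unknown chromosome: ",
         paste(setdiff(unique(chrom), names(fmap$cuts)), collapse = ", "))
  if (any(pos < 0 | pos >= fmap$seqlengths[chrom]))
    stop("position outside chromosome bounds")
  out <- numeric(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    cc <- fmap$cuts[[ch]]
    if (length(cc) == 0) { out[sel] <- Inf; next }
    p <- pos[sel]
    i <- findInterval(p, cc)
    lo <- ifelse(i >= 1L, abs(p - cc[pmax(i, 1L)]), Inf)
    hi <- ifelse(i < length(cc), abs(cc[pmin(i + 1L, length(cc))] - p), Inf)
    out[sel] <- pmin(lo, hi)
  }
  out
}

# 1-based fragment ordinal within chromosome: fragment f covers
# [cut_{f-1}, cut_f) with sentinels 0 and seqlength
fragment_of <- function(fmap, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- integer(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- findInterval(pos[sel], fmap$cuts[[ch]]) + 1L
  }
  out
}

#' Per-bin restriction-site counts and mean mapability
#'
#' Annotates every bin of a grid with the number of cut sites falling inside
#' it and its length-weighted mean mapability. Portions of a bin not covered
#' by any mapability interval count as 0; with no track supplied all bins get
#' mapability 1, so a downstream \code{>0.5} filter passes vacuously.
#'
#' @param grid A \code{bin_grid}.
#' @param fmap A \code{fragment_map} on the same chromosomes.
#' @param mapability Optional data.frame (chrom, start, end, score) with
#'   0-based half-open intervals and scores in [0,1].
#' @return data.frame: bin, chrom, start, end, sites, mapability.
#' @export
annotate_bins <- function(grid, fmap, mapability = NULL) {
  bins <- bin_coords(grid)
  bins$sites <- 0L
  for (ch in grid$chroms) {
    cc <- fmap$cuts[[ch]]
    if (is.null(cc) || length(cc) == 0) next
    idx <- bin_index(grid, rep(ch, length(cc)), cc)
    tab <- table(idx)
    bins$sites[as.integer(names(tab))] <- as.integer(tab)
  }
  bins$mapability <- 1
  if (!is.null(mapability) && nrow(mapability)) {
    mp <- mapability
    if (any(mp$score < 0 | mp$score > 1)) stop("mapability scores must be in [0,1]")
    ci <- match(mp$chrom, grid$chroms)
    if (anyNA(ci)) stop("mapability track on unknown chromosome")
    if (any(mp$start < 0 | mp$end > grid$lengths[ci]))
      stop("mapability interval outside chromosome bounds")
    bins$mapability <- 0
    gr_bins <- GenomicRanges::GRanges(bins$chrom,
      IRanges::IRanges(bins$start + 1L, bins$end))
    gr_map <- GenomicRanges::GRanges(mp$chrom,
      IRanges::IRanges(mp$start + 1L, mp$end))
    ov <- GenomicRanges::findOverlaps(gr_bins, gr_map)
    if (length(ov)) {
      w <- BiocGenerics::width(IRanges::pintersect(
        IRanges::ranges(gr_bins)[S4Vectors::queryHits(ov)],
        IRanges::ranges(gr_map)[S4Vectors::subjectHits(ov)]))
      contrib <- w * mp$score[S4Vectors::subjectHits(ov)]
      agg <- rowsum(contrib, group = S4Vectors::queryHits(ov))
      bi <- as.integer(rownames(agg))
      bins$mapability[bi] <- agg[, 1] / (bins$end[bi] - bins$start[bi])
    }
  }
  bins
}
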