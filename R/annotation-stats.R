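# overlap of ditag ends with a set of intervals (0-based half-open)
.end_on_target <- function(chrom, pos, targets) {
  if (is.null(targets) || nrow(targets) == 0) return(rep(FALSE, length(chrom)))
  gr_t <- GenomicRanges::GRanges(targets$chrom,
    IRanges::IRanges(targets$start + 1L, targets$end))
  gr_p <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  GenomicRanges::countOverlaps(gr_p, gr_t) > 0
}

#' Capture enrichment factor
#'
#' Fold increase of the on-target read fraction in a captured test library
#' over a size-matched uncaptured reference. Both libraries are first
#' subsampled to the same number of raw ditags (uniform, honouring the
#' session RNG so callers can seed); a ditag is on-target when either end
#' falls in a target interval. Optionally also reports the per-bin mean
#' count ratio between target-overlapping and other bins of the test
#' library.
#'
#' @param test,reference Ditag data.frames.
#' @param targets data.frame (chrom, start, end) of capture targets.
#' @param subsample_size Raw ditags drawn from each library; default the
#'   smaller library size.
#' @param grid Optional \code{bin_grid} for the per-bin summary.
#' @return Object of class \code{enrichment_result}.
#' @export
enrichment_factor <- function(test, reference, targets,
                              subsample_size = NULL, grid = NULL) {
  if (nrow(test) == 0 || nrow(reference) == 0)
    stop("both libraries must be non-empty")
  if (is.null(subsample_size))
    subsample_size <- min(nrow(test), nrow(reference))
  if (subsample_size > min(nrow(test), nrow(reference)))
    stop("subsample_size exceeds a library size")
  ts <- test[sample.int(nrow(test), subsample_size), , drop = FALSE]
  rs <- reference[sample.int(nrow(reference), subsample_size), , drop = FALSE]
  on_t <- .end_on_target(ts$chrom1, ts$pos1, targets) |
          .end_on_target(ts$chrom2, ts$pos2, targets)
  on_r <- .end_on_target(rs$chrom1, rs$pos1, targets) |
          .end_on_target(rs$chrom2, rs$pos2, targets)
  f_t <- mean(on_t); f_r <- mean(on_r)
  if (f_r == 0) {
    warning("reference library has no on-target reads; fold is infinite")
    fold <- Inf
  } else fold <- f_t / f_r
  bin_ratio <- NA_real_
  if (!is.null(grid)) {
    counts <- numeric(grid$total)
    idx <- c(bin_index(grid, ts$chrom1, ts$pos1),
             bin_index(grid, ts$chrom2, ts$pos2))
    tb <- table(idx)
    counts[as.integer(names(tb))] <- as.numeric(tb)
    bc <- bin_coords(grid)
    on_bin <- .end_on_target(bc$chrom, bc$start, targets) |
              GenomicRanges::countOverlaps(
                GenomicRanges::GRanges(bc$chrom,
                  IRanges::IRanges(bc$start + 1L, bc$end)),
                GenomicRanges::GRanges(targets$chrom,
                  IRanges::IRanges(targets$start + 1L, targets$end))) > 0
    bin_ratio <- mean(counts[on_bin]) / mean(counts[!on_bin])
  }
  structure(list(frac_test = f_t, frac_reference = f_r, fold = fold,
                 bin_ratio = bin_ratio, subsample_size = subsample_size),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_factor: %.3g (on-target %.4f vs %.4f, n = %d)\n",
              x$fold, x$frac_test, x$frac_reference, x$subsample_size))
  if (!is.na(x$bin_ratio))
    cat(sprintf("  per-bin on/off-target mean count ratio: %.3g\n", x$bin_ratio))
  invisible(x)
}

#' Association-signal overlap test
#'
#' Two-sided Fisher exact test for whether significantly interacting bins
#' preferentially overlap strong association signals, from the four counts:
#' all test bins, bins overlapping low association P values, significant
#' bins, and significant bins overlapping low association P values.
#'
#' @param all_bins,overlap_bins,sig_bins,sig_overlap_bins Counts.
#' @return The \code{htest} from \code{fisher.test}, with the 2x2 table in
#'   \code{$table}.
#' @export
association_overlap_test <- function(all_bins, overlap_bins, sig_bins,
                                     sig_overlap_bins) {
  if (sig_overlap_bins > min(sig_bins, overlap_bins) ||
      sig_bins > all_bins || overlap_bins > all_bins)
    stop("inconsistent contingency counts")
  tab <- matrix(c(sig_overlap_bins, sig_bins - sig_overlap_bins,
                  overlap_bins - sig_overlap_bins,
                  all_bins - sig_bins - overlap_bins + sig_overlap_bins),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("significant", "other"),
                                c("overlap", "no_overlap")))
  ht <- stats::fisher.test(tab, alternative = "two.sided")
  ht$table <- tab
  ht
}

#' Flag bins overlapping low association P values
#'
#' Within each test region, a SNP qualifies when its P value is within one
#' order of magnitude of the region's lowest P value; a bin is flagged when
#' it contains at least one qualifying SNP (SNP position in bin).
#'
#' @param assoc data.frame (chrom, pos, p) of SNP association P values.
#' @param regions data.frame (chrom, start, end) of test regions; each must
#'   contain at least one SNP.
#' @param grid A \code{bin_grid}.
#' @return Logical vector over all bins of the grid.
#' @export
low_association_mask <- function(assoc, regions, grid) {
  mask <- rep(FALSE, grid$total)
  for (r in seq_len(nrow(regions))) {
    inr <- assoc$chrom == regions$chrom[r] &
           assoc$pos >= regions$start[r] & assoc$pos < regions$end[r]
    if (!any(inr)) stop("region ", r, " contains no SNP")
    pmin_r <- min(assoc$p[inr])
    qual <- inr & assoc$p <= 10 * pmin_r
    if (any(qual))
      mask[unique(bin_index(grid, assoc$chrom[qual], assoc$pos[qual]))] <- TRUE
  }
  mask
}

#' Monte Carlo overlap of significant bins with regulatory elements
#'
#' Compares the proportion of significantly interacting bins overlapping
#' each regulatory-element class against random same-size samples of bins
#' drawn (without replacement within a draw) from the valid-bin universe.
#' P = m/N where m counts samples with overlap proportion at least the
#' observed one; m = 0 is reported as the bound "<1/N".
#'
#' @param sig_bins Global indices of significant bins.
#' @param elements Named list of data.frames (chrom, start, end), one per
#'   element class.
#' @param grid A \code{bin_grid}.
#' @param universe Global indices of candidate bins. Default: all bins.
#' @param n_mc Number of Monte Carlo samples. Default 1e4.
#' @return data.frame per class: observed proportion, m, n_mc, p.value
#'   (m/N, with 1/N substituted when m = 0), label.
#' @export
regulatory_overlap_mc <- function(sig_bins, elements, grid,
                                  universe = seq_len(grid$total),
                                  n_mc = 1e4) {
  stopifnot(length(sig_bins) >= 1, n_mc >= 1)
  k <- length(sig_bins)
  bc <- bin_coords(grid, universe)
  gr_u <- GenomicRanges::GRanges(bc$chrom,
    IRanges::IRanges(bc$start + 1L, bc$end))
  hit <- lapply(elements, function(el) {
    gr_e <- GenomicRanges::GRanges(el$chrom,
      IRanges::IRanges(el$start + 1L, el$end))
    GenomicRanges::countOverlaps(gr_u, gr_e) > 0
  })
  pos_of <- match(sig_bins, universe)
  if (anyNA(pos_of)) stop("sig_bins must be inside the universe")
  draws <- matrix(0L, n_mc, k)
  for (s in seq_len(n_mc))
    draws[s, ] <- sample.int(length(universe), k)
  out <- lapply(names(hit), function(cl) {
    h <- hit[[cl]]
    obs <- mean(h[pos_of])
    null_prop <- rowMeans(matrix(h[draws], nrow = n_mc))
    m <- sum(null_prop >= obs)
    data.frame(class = cl, observed = obs, m = m, n_mc = n_mc,
               p.value = if (m == 0) 1 / n_mc else m / n_mc,
               label = if (m == 0) sprintf("<%g", 1 / n_mc)
                       else sprintf("%g", m / n_mc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Shared transcription-factor binding at interaction pairs
#'
#' For every interaction, counts the transcription factors with at least one
#' peak in both the test bin and the interactor bin, then compares against
#' permuted control pairs (interactor bins reshuffled across calls,
#' excluding pairs whose bins come from the same test region) with a
#' two-sided Mann-Whitney U test.
#'
#' @param calls data.frame with columns bin_test, bin_int (global bin
#'   indices) and region (test-region id of the test bin).
#' @param peaks Named list of data.frames (chrom, start, end), one per TF.
#' @param grid A \code{bin_grid}.
#' @param n_pairs Number of control pairs. Default: number of calls.
#' @return list(shared_real, shared_control, p.value, statistic, degenerate).
#' @export
tf_sharing_test <- function(calls, peaks, grid, n_pairs = nrow(calls)) {
  stopifnot(all(c("bin_test", "bin_int", "region") %in% names(calls)))
  bins <- sort(unique(c(calls$bin_test, calls$bin_int)))
  bc <- bin_coords(grid, bins)
  gr_b <- GenomicRanges::GRanges(bc$chrom,
    IRanges::IRanges(bc$start + 1L, bc$end))
  member <- vapply(peaks, function(pk) {
    gr_p <- GenomicRanges::GRanges(pk$chrom,
      IRanges::IRanges(pk$start + 1L, pk$end))
    GenomicRanges::countOverlaps(gr_b, gr_p) > 0
  }, logical(length(bins)))
  member <- matrix(member, nrow = length(bins))
  it <- match(calls$bin_test, bins)
  ii <- match(calls$bin_int, bins)
  shared_real <- rowSums(member[it, , drop = FALSE] &
                         member[ii, , drop = FALSE])
  # controls: for each slot, an interactor from a call of another region
  shared_control <- numeric(n_pairs)
  slot <- sample.int(nrow(calls), n_pairs, replace = n_pairs > nrow(calls))
  for (s in seq_len(n_pairs)) {
    pool <- which(calls$region != calls$region[slot[s]])
    if (!length(pool)) pool <- seq_len(nrow(calls))  # single-region fallback
    pick <- pool[sample.int(length(pool), 1)]
    shared_control[s] <- sum(member[it[slot[s]], ] & member[ii[pick], ])
  }
  degenerate <- all(shared_real == shared_control[1]) &&
                all(shared_control == shared_control[1])
  if (degenerate) {
    p <- 1; stat <- NA_real_
    warning("degenerate shared-TF counts; P value set to 1")
  } else {
    wt <- stats::wilcox.test(shared_real, shared_control,
                             alternative = "two.sided", exact = FALSE)
    p <- wt$p.value; stat <- unname(wt$statistic)
  }
  list(shared_real = shared_real, shared_control = shared_control,
       p.value = p, statistic = stat, degenerate = degenerate)
}

#' Regroup a chromatin-state segmentation to a simplified scheme
#'
#' Maps every state label to one of the simplified classes (typically
#' promoter / enhancer / transcribed / other) and merges adjacent
#' same-class intervals. Order-invariant: input is sorted before merging.
#'
#' @param segmentation data.frame (chrom, start, end, state).
#' @param mapping Named character vector: input label -> simplified class.
#' @return data.frame (chrom, start, end, class), sorted and merged.
#' @export
regroup_chromatin_states <- function(segmentation, mapping) {
  missing_lab <- setdiff(unique(segmentation$state), names(mapping))
  if (length(missing_lab))
    stop("unmapped state label(s): ", paste(missing_lab, collapse = ", "))
  df <- segmentation
  df$class <- unname(mapping[df$state])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (r in seq_len(nrow(df))) {
    row <- df[r, ]
    if (!is.null(cur) && cur$chrom == row$chrom && cur$class == row$class &&
        row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- row[, c("chrom", "start", "end", "class")]
    }
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
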