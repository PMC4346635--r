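#' Directionality index of each bin
#'
#' For every bin, A is the sum of contacts to bins strictly upstream within
#' the flanking window and B the downstream sum; the directionality value is
#' D = |A - B| * (B - A) / (A + B), i.e. sign(B - A) times (A - B)^2/(A + B),
#' and 0 when A + B = 0. Chromosome-edge bins use the available truncated
#' window. Computed on bias-corrected (not distance-normalized) counts:
#' distance normalization would whiten the directional signal the index is
#' designed to detect.
#'
#' Near a chromosome end the window is truncated symmetrically: both
#' flanks shrink to the available side, so an unbiased edge bin stays
#' unbiased (a one-sided window would make every chromosome end look
#' structurally directional). Bins with no room on one side get D = 0.
#'
#' @param m A \code{contact_matrix}.
#' @param window Flanking window in bases. Default 495000.
#' @return Object of class \code{dix_track}: data.frame bin, chrom, start,
#'   end, A, B, D.
#' @export
directionality_index <- function(m, window = 495000) {
  g <- m$grid
  wb <- max(1L, as.integer(floor(window / g$res)))
  chrom_i <- .bin_chrom_index(g, seq_len(g$total))
  ord <- seq_len(g$total) - g$offsets[chrom_i]   # 1-based ordinal in chrom
  wsym <- pmin(ord - 1L, g$nbins[chrom_i] - ord, wb)
  cc <- m$counts
  ci <- .bin_chrom_index(g, cc$i); cj <- .bin_chrom_index(g, cc$j)
  sep <- cc$j - cc$i
  cis <- ci == cj & sep > 0 & sep <= wb
  A <- B <- numeric(g$total)
  if (any(cis)) {
    # entry (i, j), i < j: j is downstream of i and i upstream of j
    bs <- cis & sep <= wsym[cc$i]
    as_ <- cis & sep <= wsym[cc$j]
    if (any(bs)) {
      bsum <- rowsum(cc$n[bs], group = cc$i[bs])
      B[as.integer(rownames(bsum))] <- bsum[, 1]
    }
    if (any(as_)) {
      asum <- rowsum(cc$n[as_], group = cc$j[as_])
      A[as.integer(rownames(asum))] <- asum[, 1]
    }
  }
  tot <- A + B
  D <- ifelse(tot > 0, abs(A - B) * (B - A) / tot, 0)
  out <- bin_coords(g)
  out$A <- A; out$B <- B; out$D <- D
  structure(out, class = c("dix_track", "data.frame"),
            window = window, res = g$res)
}

#' Null draws of the directionality statistic
#'
#' Under no directional bias, the upstream sum A of a bin with total
#' contacts A + B = total is Binomial(total, 1/2), and the magnitude
#' |D| = (A - B)^2 / (A + B) is asymptotically chi-squared with 1 d.f.
#' Returns Monte Carlo draws of |D| for checking that relation.
#'
#' @param total Total contact count A + B (> 0).
#' @param reps Number of draws.
#' @return Numeric vector of |D| draws.
#' @export
dix_null_check <- function(total, reps) {
  if (total <= 0) stop("total must be positive")
  A <- stats::rbinom(reps, total, 0.5)
  B <- total - A
  (A - B)^2 / total
}

# Viterbi decoding of a 3-state HMM with Gaussian emissions.
# states: 1 = upstream-biased (negative D), 2 = none, 3 = downstream-biased
# missing observations (bins with no usable signal) get neutral emissions
# so a run can bridge them
.viterbi3 <- function(y, mu, sigma, self = 0.9, missing = NULL) {
  n <- length(y)
  ltrans <- log(matrix((1 - self) / 2, 3, 3) + diag(rep(self - (1 - self) / 2, 3)))
  lem <- vapply(1:3, function(s) stats::dnorm(y, mu[s], sigma, log = TRUE),
                numeric(n))
  lem <- matrix(lem, nrow = n)
  if (!is.null(missing) && any(missing)) lem[missing, ] <- 0
  if (n == 1) return(which.max(lem[1, ]))
  delta <- matrix(-Inf, n, 3)
  psi <- matrix(0L, n, 3)
  delta[1, ] <- log(1 / 3) + lem[1, ]
  for (t in 2:n) {
    for (s in 1:3) {
      cand <- delta[t - 1, ] + ltrans[, s]
      psi[t, s] <- which.max(cand)
      delta[t, s] <- cand[psi[t, s]] + lem[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Call topological domains from a directionality track
#'
#' Decodes a 3-state hidden Markov model (downstream-biased / unbiased /
#' upstream-biased) over the variance-stabilized directionality signal
#' sign(D) * sqrt(|D|), with sticky transitions and Gaussian emissions whose
#' location/scale are estimated from the track. A domain spans from the
#' first bin of a downstream-biased run to the last bin of the next
#' upstream-biased run; calls shorter than \code{min_bins} are dropped.
#' Invariant to global scaling of the contact matrix up to the emission
#' re-estimation.
#'
#' @param dix A \code{dix_track}.
#' @param min_bins Minimum domain length in bins. Default 3.
#' @param self_prob HMM self-transition probability. Default 0.9.
#' @return Object of class \code{domain_set}: data.frame chrom, start, end
#'   (0-based half-open), with the per-bin state path in attr "states".
#' @export
call_domains <- function(dix, min_bins = 3, self_prob = 0.9) {
  y <- sign(dix$D) * sqrt(abs(dix$D))
  y[!is.finite(y)] <- 0
  states <- rep(2L, nrow(dix))
  doms <- list()
  if (any(abs(y) > 0)) {
    # sign(D)*sqrt(|D|) is standard normal for an unbiased bin, so the
    # robust MAD of the track estimates the noise scale while staying
    # insensitive to boundary spikes (and keeps calls invariant to global
    # matrix scaling); biased states sit well outside the noise
    act <- abs(y) > 0
    s <- stats::mad(y[act])
    if (!is.finite(s) || s == 0) s <- stats::sd(y[act])
    if (!is.finite(s) || s == 0) s <- 1
    mu <- c(-6 * s, 0, 6 * s)
    miss <- (dix$A + dix$B) == 0
    for (ch in unique(dix$chrom)) {
      sel <- which(dix$chrom == ch)
      path <- .viterbi3(y[sel], mu, s, self = self_prob,
                        missing = miss[sel])
      states[sel] <- path
      r <- rle(path)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      # single-bin biased runs are noise spikes: genuine boundary runs
      # persist over the half-window the directional contrast spans
      r$values[r$lengths < 2L & r$values != 2L] <- 2L
      emit <- function(open, close) {
        if (close - open + 1L >= min_bins)
          doms[[length(doms) + 1L]] <<-
            data.frame(chrom = ch, start = dix$start[open],
                       end = dix$end[close], stringsAsFactors = FALSE)
      }
      # a domain runs from the start of a downstream-biased run to the end
      # of the next upstream-biased run; a chromosome end can stand in for
      # the missing flank of a domain flush against the edge (its outside
      # flank has nothing to contrast with)
      run_nm <- function(k) {
        run <- starts[k]:ends[k]
        run[!miss[sel[run]]]   # boundaries sit on informative bins
      }
      bseq <- Filter(function(k) length(run_nm(k)), which(r$values != 2L))
      bstate <- r$values[bseq]
      pending <- NA_integer_
      seen_biased <- FALSE
      k <- 1L
      while (k <= length(bseq)) {
        if (bstate[k] == 3L) {
          if (is.na(pending)) pending <- sel[run_nm(bseq[k])[1]]
          k <- k + 1L
        } else {
          # a boundary ramp may fragment into several upstream-biased runs
          # separated by brief neutral stretches; the domain ends with the
          # last run of the block
          j <- k
          while (j + 1L <= length(bseq) && bstate[j + 1L] == 1L) j <- j + 1L
          nm <- run_nm(bseq[j])
          close <- sel[nm[length(nm)]]
          if (!is.na(pending)) {
            emit(pending, close)
            pending <- NA_integer_
          } else if (!seen_biased) {
            emit(sel[1], close)  # domain flush against the chromosome start
          }
          k <- j + 1L
        }
        seen_biased <- TRUE
      }
      if (!is.na(pending)) emit(pending, sel[length(sel)])
    }
  }
  out <- if (length(doms)) do.call(rbind, doms)
         else data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("domain_set", "data.frame"), states = states)
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("domain_set: %d domain(s)\n", nrow(x)))
  if (nrow(x)) print(as.data.frame(x))
  invisible(x)
}
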