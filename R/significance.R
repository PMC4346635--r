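#' Three-sample overlap probability
#'
#' Probability of observing k or more common elements among three
#' independent uniform samples, sample i of size n_i drawn from a universe
#' S_i of size N_i with S_1 nested in S_2 nested in S_3. The default exact
#' evaluation conditions on the overlap of the first two samples
#' (hypergeometric chain): |s1 ∩ s2| is Hyper(N2; n1, n2) and, given that
#' overlap m, |s1 ∩ s2 ∩ s3| is Hyper(N3; m, n3). The binomial
#' approximation treats each element of S_1 as independently present in all
#' three samples with probability p = prod(n_i/N_i), K ~ Binomial(N_1, p).
#' Both are evaluated in log space so extreme tails never underflow.
#'
#' @param k Observed overlap count.
#' @param n Sample sizes, length 3.
#' @param N Universe sizes, length 3 (non-decreasing).
#' @param method "exact" (default), or "binomial".
#' @return Object of class \code{overlap_test}: p.value, log10_p, label
#'   (a "<1e-16"-style bound when p underflows printed precision), inputs.
#' @examples
#' combinatorial_overlap_pvalue(2, n = c(5, 5, 5), N = c(10, 10, 10))
#' @export
combinatorial_overlap_pvalue <- function(k, n, N,
                                         method = c("exact", "binomial")) {
  method <- match.arg(method)
  stopifnot(length(n) == 3, length(N) == 3)
  if (any(n > N)) stop("sample sizes cannot exceed universe sizes")
  ord <- order(N)  # nesting S1 in S2 in S3: sort (n, N) pairs by universe
  n <- n[ord]; N <- N[ord]
  if (k > min(n)) stop("overlap cannot exceed the smallest sample")
  if (k <= 0) {
    lp <- 0
  } else if (method == "binomial") {
    p1 <- prod(n / N)
    lp <- stats::pbinom(k - 1, N[1], p1, lower.tail = FALSE, log.p = TRUE)
  } else {
    m <- 0:min(n[1], n[2])
    ld <- stats::dhyper(m, n[1], N[2] - n[1], n[2], log = TRUE)
    keep <- ld > max(ld) - 745  # below this a term cannot register
    m <- m[keep]; ld <- ld[keep]
    lt <- vapply(m, .lhyper_upper_tail, numeric(1),
                 k = k, nd = n[3], Ntot = N[3])
    lp <- .logsumexp(ld + lt)
    lp <- min(lp, 0)
  }
  log10p <- lp / log(10)
  structure(list(p.value = exp(lp), log10_p = log10p,
                 label = if (log10p < -16) "P < 1e-16"
                         else sprintf("P = %.3g", exp(lp)),
                 k = k, n = n, N = N, method = method),
            class = "overlap_test")
}

# log P(X >= k) for X ~ Hyper(white = m, black = Ntot - m, draws = nd),
# robust deep in the upper tail
.lhyper_upper_tail <- function(m, k, nd, Ntot) {
  hi <- min(m, nd)
  if (k > hi) return(-Inf)
  lp <- stats::phyper(k - 1, m, Ntot - m, nd,
                      lower.tail = FALSE, log.p = TRUE)
  if (is.finite(lp) && lp > log(1e-280)) return(lp)
  # direct log-space summation; terms decay fast beyond the mode
  x <- k:min(hi, k + 2000L)
  .logsumexp(stats::dhyper(x, m, Ntot - m, nd, log = TRUE))
}

.logsumexp <- function(lx) {
  lx <- lx[is.finite(lx) | lx == -Inf]
  mx <- max(lx)
  if (!is.finite(mx)) return(-Inf)
  mx + log(sum(exp(lx - mx)))
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("three-sample overlap test (%s): k = %d, %s (log10 P = %.2f)\n",
              x$method, x$k, x$label, x$log10_p))
  invisible(x)
}

# ---- interaction calling ---------------------------------------------------

# distance stratum (log2 octave above min_sep) for cis E-N pairs; the
# variance of 1/f(d)-normalized counts grows with separation, so null fits
# are stratified by distance octave within each interval
.call_stratum <- function(d, min_sep) {
  pmax(0L, as.integer(floor(log2(d / min_sep))))
}

# context key per eligible entry; interactor = non-enriched bin of an E-N
# pair; cis contexts carry a distance-octave suffix
.call_context <- function(m, i, j, window, min_sep) {
  ei <- m$bins$enriched[i]; ej <- m$bins$enriched[j]
  ci <- .bin_chrom_index(m$grid, i); cj <- .bin_chrom_index(m$grid, j)
  ctx <- character(length(i))
  ee <- ei & ej
  ctx[ee] <- "test"
  en <- xor(ei, ej)
  intb <- ifelse(ei, j, i)  # interactor bin
  kind <- ifelse(ci == cj, "cis", "trans")
  wi <- .window_of(m, intb, window)
  cint <- .bin_chrom_index(m$grid, intb)
  ctx[en] <- paste(kind[en], m$grid$chroms[cint[en]], wi[en], sep = ":")
  cis_en <- en & ci == cj
  if (any(cis_en)) {
    d <- abs(j[cis_en] - i[cis_en]) * as.double(m$grid$res)
    ctx[cis_en] <- paste(ctx[cis_en], .call_stratum(d, min_sep), sep = ":o")
  }
  ctx
}

# per-context universe sizes: number of eligible (valid, E-E or E-N,
# separation-passing) bin pairs, populated or not
.context_universe <- function(m, min_sep, window) {
  g <- m$grid
  valid <- m$bins$valid
  E <- which(m$bins$enriched & valid)
  NV <- which(!m$bins$enriched & valid)
  if (!length(E)) return(numeric(0))
  chromE <- .bin_chrom_index(g, E)
  res <- as.double(g$res)
  uni <- new.env(parent = emptyenv())
  add <- function(key, cnt) {
    cur <- if (!is.null(uni[[key]])) uni[[key]] else 0
    uni[[key]] <- cur + cnt
  }
  # test: unordered E-E pairs passing separation (trans E-E always pass)
  if (length(E) > 1) {
    cnt <- 0
    for (a in seq_len(length(E) - 1)) {
      rest <- (a + 1):length(E)
      ok <- chromE[rest] != chromE[a] |
            (E[rest] - E[a]) * res > min_sep
      cnt <- cnt + sum(ok)
    }
    add("test", cnt)
  }
  # E-N: for each enriched bin, count valid non-enriched partners per
  # (kind, chrom, window[, octave]) interval of the partner
  chromN <- .bin_chrom_index(g, NV)
  winN <- .window_of(m, NV, window)
  keyN <- paste(g$chroms[chromN], winN, sep = ":")
  for (a in seq_along(E)) {
    same <- chromN == chromE[a]
    d <- abs(NV - E[a]) * res
    pass <- same & d > min_sep
    if (any(pass)) {
      kk2 <- paste0("cis:", keyN[pass], ":o", .call_stratum(d[pass], min_sep))
      tc <- table(kk2)
      for (kk in names(tc)) add(kk, as.integer(tc[kk]))
    }
    if (any(!same)) {
      tc <- table(keyN[!same])
      for (kk in names(tc)) add(paste0("trans:", kk), as.integer(tc[kk]))
    }
  }
  keys <- ls(uni)
  stats::setNames(vapply(keys, function(kk) uni[[kk]], numeric(1)), keys)
}

#' Call significant chromatin interactions
#'
#' Fits the zero-inflated Weibull null to bias- and distance-normalized
#' contact strengths and assigns each eligible bin pair a P value and a
#' Benjamini-Hochberg q-value. Eligible pairs involve valid bins, are E-E
#' or E-N (at least one capture-enriched bin), and in cis are separated by
#' more than \code{min_sep} (long-range calls only). Test-region (E-E)
#' contacts are pooled into one fit; E-N contacts get a separate fit per
#' (cis/trans, chromosome, window) interval of the interactor bin, with
#' cis intervals further stratified by distance octave — dividing counts
#' by the expected frequency f(d) inflates their variance as 1/f(d), so
#' pooling all separations under one Weibull would understate the far
#' tail. Groups fall back to coarser pools (interval, chromosome, kind)
#' when they hold fewer than \code{min_obs} nonzero observations. Counts
#' are dithered by a uniform draw over their last unit before fitting
#' (randomized-quantile construction), which keeps the continuous null
#' honest on small discrete counts; this uses the session RNG, so seed
#' for exact reproducibility. Unobserved eligible pairs enter each fit as
#' zeros and count toward the multiple-testing burden. With several
#' libraries, a pair is shared-significant iff q < \code{fdr} in every
#' library.
#'
#' @param matrices A \code{contact_matrix} (normalized, with counts$norm)
#'   or a list of them (one per library, same grid and enrichment design).
#' @param fdr Significance threshold on q. Default 0.05.
#' @param min_sep Minimum cis separation in bases (strict). Default 10 kb.
#' @param window Interval width for per-interval fits. Default 10 Mb.
#' @param truncation_q,min_obs Passed to \code{\link{fit_ziw}}.
#' @return Object of class \code{interaction_calls}: one row per bin pair
#'   significant in at least one library, with per-library strength/p/q/sig
#'   columns and a \code{shared} flag; fits and universe sizes attached as
#'   attributes.
#' @export
call_interactions <- function(matrices, fdr = 0.05, min_sep = 1e4,
                              window = 1e7, truncation_q = 0.95,
                              min_obs = 200) {
  if (inherits(matrices, "contact_matrix")) matrices <- list(matrices)
  nlib <- length(matrices)
  m0 <- matrices[[1]]
  universe <- .context_universe(m0, min_sep, window)
  m_total <- sum(universe)
  per_lib <- vector("list", nlib)
  fits_all <- vector("list", nlib)
  for (L in seq_len(nlib)) {
    m <- matrices[[L]]
    if (is.null(m$counts$norm))
      stop("matrix ", L, " has no normalized values; run distance_normalize()")
    cc <- m$counts
    ci <- .bin_chrom_index(m$grid, cc$i); cj <- .bin_chrom_index(m$grid, cc$j)
    ei <- m$bins$enriched[cc$i]; ej <- m$bins$enriched[cc$j]
    vv <- m$bins$valid[cc$i] & m$bins$valid[cc$j]
    sep_ok <- ci != cj | (cc$j - cc$i) * as.double(m$grid$res) > min_sep
    elig <- vv & (ei | ej) & sep_ok & cc$n > 0
    cc <- cc[elig, , drop = FALSE]
    ctx <- .call_context(m, cc$i, cc$j, window, min_sep)
    # randomized-quantile dithering: spread the discrete count atoms over
    # the unit below each value so a continuous null can be fitted and the
    # resulting P values are calibrated (Dunn-Smyth residual construction);
    # negligible for large counts
    raw <- if (!is.null(cc$raw)) cc$raw else cc$n
    x <- cc$norm * (1 - stats::runif(nrow(cc)) / pmax(raw, 1))
    # fallback: drop one grouping level (octave, window, chromosome) until
    # the group holds at least min_obs nonzero observations
    grp <- ctx
    for (pass in 1:3) {
      npos <- table(grp)
      small <- grp %in% names(npos)[npos < min_obs] & grepl(":", grp)
      if (!any(small)) break
      grp[small] <- sub(":[^:]+$", "", grp[small])
    }
    final_groups <- unique(grp)
    # a fallback group pools every entry under its prefix, not only the
    # orphans that fell back into it
    has_prefix <- function(keys, gk)
      keys == gk | startsWith(keys, paste0(gk, ":"))
    p <- numeric(nrow(cc))
    fits <- list()
    for (gk in final_groups) {
      sel <- grp == gk
      pool <- has_prefix(ctx, gk)
      uu <- sum(universe[has_prefix(names(universe), gk)])
      fit <- suppressWarnings(
        fit_ziw(x[pool], truncation_q = truncation_q, min_n = min_obs))
      fit$pi <- 1 - sum(pool) / max(uu, sum(pool))  # true zero share
      fits[[gk]] <- fit
      p[sel] <- ziw_pvalue(x[sel], fit)
      if (fit$n_pos < min_obs) {
        # too few observations to trust tail extrapolation: no P value may
        # beat the empirical resolution of the pool
        p[sel] <- pmax(p[sel], (1 - fit$pi) / (fit$n_pos + 1))
      }
    }
    q <- fdr_qvalues(p, m = max(m_total, length(p)))
    per_lib[[L]] <- data.frame(i = cc$i, j = cc$j, context = ctx,
                               strength = cc$norm, p = p, q = q,
                               stringsAsFactors = FALSE)
    fits_all[[L]] <- fits
  }
  # merge on pairs significant in >= 1 library
  keys <- unique(do.call(rbind, lapply(per_lib, function(d)
    d[d$q < fdr, c("i", "j")])))
  if (is.null(keys) || nrow(keys) == 0) {
    keys <- data.frame(i = integer(0), j = integer(0))
  }
  keys <- keys[order(keys$i, keys$j), , drop = FALSE]
  out <- keys
  kk <- paste(keys$i, keys$j)
  ctx_out <- rep(NA_character_, nrow(keys))
  for (L in seq_len(nlib)) {
    d <- per_lib[[L]]
    idx <- match(kk, paste(d$i, d$j))
    out[[paste0("strength_", L)]] <- ifelse(is.na(idx), 0, d$strength[idx])
    out[[paste0("p_", L)]] <- ifelse(is.na(idx), 1, d$p[idx])
    out[[paste0("q_", L)]] <- ifelse(is.na(idx), 1, d$q[idx])
    out[[paste0("sig_", L)]] <- !is.na(idx) & d$q[idx] < fdr
    ctx_out[!is.na(idx)] <- d$context[idx[!is.na(idx)]]
  }
  out$context <- ctx_out
  out$shared <- Reduce(`&`, lapply(seq_len(nlib), function(L)
    out[[paste0("sig_", L)]]))
  b1 <- bin_coords(m0$grid, if (nrow(out)) out$i else integer(0))
  b2 <- bin_coords(m0$grid, if (nrow(out)) out$j else integer(0))
  out$chrom1 <- b1$chrom; out$start1 <- b1$start; out$end1 <- b1$end
  out$chrom2 <- b2$chrom; out$start2 <- b2$start; out$end2 <- b2$end
  rownames(out) <- NULL
  structure(out, class = c("interaction_calls", "data.frame"),
            n_tests = m_total, fits = fits_all, fdr = fdr, nlib = nlib)
}

#' @export
print.interaction_calls <- function(x, ...) {
  nlib <- attr(x, "nlib")
  cat(sprintf("interaction_calls: %d pair(s) significant in >=1 of %d library(ies); %d shared\n",
              nrow(x), nlib, sum(x$shared)))
  cat(sprintf("  %d eligible pairs tested at FDR %.2f\n",
              attr(x, "n_tests"), attr(x, "fdr")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Write interaction calls as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name,
#' score (-10 log10 of the worst per-library q), ".", ".", then per-library
#' strength/p/q/sig columns and the shared flag.
#'
#' @param calls An \code{interaction_calls} object.
#' @param path Output path.
#' @export
write_interactions_bedpe <- function(calls, path) {
  nlib <- attr(calls, "nlib")
  qcols <- paste0("q_", seq_len(nlib))
  worst_q <- do.call(pmax, c(as.data.frame(calls)[qcols], list(1e-300)))
  df <- data.frame(calls$chrom1, calls$start1, calls$end1,
                   calls$chrom2, calls$start2, calls$end2,
                   name = sprintf("contact_%d", seq_len(nrow(calls))),
                   score = round(-10 * log10(pmax(worst_q, 1e-300)), 2),
                   s1 = ".", s2 = ".")
  extra <- as.data.frame(calls)[, c(grep("^(strength|p|q|sig)_",
                                         names(calls), value = TRUE),
                                    "shared"), drop = FALSE]
  utils::write.table(cbind(df, extra), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
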