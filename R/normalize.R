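#' Per-bin interactivity weights from trans contacts
#'
#' For every bin i the raw weight w_i counts reads mapping to bin i at
#' trans-loci (partners on other chromosomes); N_i counts the populated
#' trans entries in row i. W and A are the respective global totals. The
#' normalized weight of a bin is its per-populated-entry trans rate relative
#' to the genome average, \eqn{\hat w_i = (w_i/N_i)/(W/A)}, whose fixed
#' point under iteration is unity. Restricting N_i to the trans entries the
#' weights are built from keeps the unit fixed point attainable: counting
#' cis entries as well would prescribe per-chromosome trans row sums that
#' are mutually inconsistent, and the recursion would stall short of unity.
#'
#' @param m A \code{contact_matrix} (valid-bin filtered).
#' @return Object of class \code{norm_state}: vectors w, N over all bins,
#'   totals W and A, normalized weights what (NA for bins with N_i = 0).
#' @export
compute_weights <- function(m) {
  nb <- m$grid$total
  w <- numeric(nb)
  N <- numeric(nb)
  cc <- m$counts
  if (nrow(cc)) {
    ci <- .bin_chrom_index(m$grid, cc$i)
    cj <- .bin_chrom_index(m$grid, cc$j)
    trans <- ci != cj
    if (any(trans)) {
      ti <- rowsum(cc$n[trans], group = cc$i[trans])
      tj <- rowsum(cc$n[trans], group = cc$j[trans])
      w[as.integer(rownames(ti))] <- w[as.integer(rownames(ti))] + ti[, 1]
      w[as.integer(rownames(tj))] <- w[as.integer(rownames(tj))] + tj[, 1]
    } else {
      warning("contact matrix has no trans entries; ",
              "all weights are zero (degenerate input)")
    }
    pop <- cc$n > 0 & trans
    Ni <- table(factor(c(cc$i[pop], cc$j[pop]), levels = seq_len(nb)))
    N <- as.numeric(Ni)
  }
  W <- sum(w); A <- sum(N)
  what <- rep(NA_real_, nb)
  ok <- N > 0
  if (A > 0 && W > 0) what[ok] <- (w[ok] / N[ok]) / (W / A)
  structure(list(w = w, N = N, W = W, A = A, what = what),
            class = "norm_state")
}

#' @export
print.norm_state <- function(x, ...) {
  cat(sprintf("norm_state: W = %.0f trans reads over A = %.0f populated entries\n",
              x$W, x$A))
  if (any(!is.na(x$what)))
    cat(sprintf("  normalized weights: max |what - 1| = %.4g\n",
                max(abs(x$what - 1), na.rm = TRUE)))
  invisible(x)
}

#' Iterative capture-aware bias correction
#'
#' Removes multiplicative per-bin visibility bias (capture efficiency,
#' fragment-length, GC, mapability) by iterating: compute normalized
#' weights \eqn{\hat w_i} from trans contacts, divide every entry
#' \eqn{M_{ij}} by \eqn{\hat w_i \hat w_j}, recompute, until
#' \eqn{\max_i |\hat w_i - 1| \le tol}. Before iterating, bins whose initial
#' weight falls more than three standard deviations below the mean weight
#' are discarded (they cannot reach the unit fixed point); bins with zero
#' trans weight are likewise uncorrectable and are excluded. After
#' convergence the total matrix mass is rescaled to the input mass, so the
#' correction only redistributes counts.
#'
#' @param m A \code{contact_matrix} (valid-bin filtered).
#' @param tol Convergence tolerance on max |what - 1|. Default 1e-3.
#' @param max_iter Iteration cap; non-convergence is flagged, not hidden.
#' @return \code{m} with \code{counts$n} replaced by corrected values (raw
#'   kept in \code{counts$raw}) and an attached \code{norm} record:
#'   final state, iterations, converged flag, excluded bins.
#' @export
iterative_bias_correct <- function(m, tol = 1e-3, max_iter = 100) {
  state <- compute_weights(m)
  pop <- state$N > 0
  mu <- mean(state$w[pop]); sdev <- stats::sd(state$w[pop])
  low <- pop & state$w < mu - 3 * sdev
  zero_w <- pop & state$w <= 0
  excluded <- which(low | zero_w)
  retained <- which(pop & !(low | zero_w))
  if (length(retained) < 2)
    stop("fewer than two bins retained after weight-based exclusion")
  m$bins$valid[excluded] <- FALSE
  keep <- !(m$counts$i %in% excluded) & !(m$counts$j %in% excluded)
  m$counts <- m$counts[keep, , drop = FALSE]
  m$counts$raw <- m$counts$n
  mass_in <- sum(m$counts$n)

  converged <- FALSE
  it <- 0L
  repeat {
    state <- suppressWarnings(compute_weights(m))
    dev <- abs(state$what[retained] - 1)
    if (all(is.na(dev))) break
    if (max(dev, na.rm = TRUE) <= tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    it <- it + 1L
    wh <- state$what
    wh[is.na(wh) | wh <= 0] <- 1
    m$counts$n <- m$counts$n / (wh[m$counts$i] * wh[m$counts$j])
  }
  if (!converged)
    warning(sprintf("bias correction did not converge in %d iterations", max_iter))
  mass_out <- sum(m$counts$n)
  if (mass_out > 0) m$counts$n <- m$counts$n * (mass_in / mass_out)
  attr(m, "norm") <- list(state = state, iterations = it,
                          converged = converged, excluded = excluded,
                          tol = tol)
  m
}

#' Expected contact frequency versus genomic distance
#'
#' Estimates the distance-decay template f(d): the mean corrected contact
#' count per valid intra-chromosomal bin pair at each bin separation,
#' kernel-smoothed on the log-distance axis (Gaussian weights, bandwidth in
#' decades, observations weighted by the number of pair slots), with
#' monotone non-increase enforced by isotonic regression. Power-law
#' exponents are then fitted by least squares of log10 f on log10 d over
#' the short-range (9 kb to 0.5 Mb) and long-range (0.5 Mb to 7 Mb)
#' regimes.
#'
#' @param m A bias-corrected \code{contact_matrix}.
#' @param bandwidth Smoothing bandwidth in decades of distance. Default 0.1.
#' @param short_range,long_range Length-2 fit ranges in bases.
#' @return Object of class \code{distance_template}: profile data.frame
#'   (d, f_raw, f, npairs), alpha_short, alpha_long, bandwidth.
#' @export
estimate_distance_template <- function(m, bandwidth = 0.1,
                                       short_range = c(9e3, 5e5),
                                       long_range = c(5e5, 7e6)) {
  g <- m$grid
  cc <- m$counts
  ci <- .bin_chrom_index(g, cc$i)
  cj <- .bin_chrom_index(g, cc$j)
  cis <- ci == cj & cc$i != cc$j
  sep <- cc$j[cis] - cc$i[cis]
  if (!length(sep)) stop("no off-diagonal cis entries; cannot build template")
  kmax <- max(sep)
  tot <- rowsum(cc$n[cis], group = sep)
  counts_k <- numeric(kmax)
  counts_k[as.integer(rownames(tot))] <- tot[, 1]
  # pair slots at each separation, valid bins only
  npairs <- numeric(kmax)
  for (chi in seq_along(g$chroms)) {
    nb <- g$nbins[chi]
    v <- as.numeric(m$bins$valid[g$offsets[chi] + seq_len(nb)])
    for (k in seq_len(min(kmax, nb - 1L)))
      npairs[k] <- npairs[k] +
        sum(v[seq_len(nb - k)] * v[seq_len(nb - k) + k])
  }
  ks <- which(npairs > 0)
  d <- ks * as.double(g$res)
  f_raw <- counts_k[ks] / npairs[ks]
  # local-linear kernel smoothing of log f on log10 d (local-constant
  # smoothing would flatten the profile at the range boundaries), weights =
  # pair slots; zero-count separations carry no log signal and are smoothed
  # over
  pos <- f_raw > 0
  ld <- log10(d)
  lf <- rep(NA_real_, length(d))
  x <- ld[pos]
  lw <- log(f_raw[pos])
  w0 <- npairs[ks][pos]
  for (q in seq_along(d)) {
    kw <- stats::dnorm(x - ld[q], sd = bandwidth) * w0
    xc <- x - ld[q]
    sw <- sum(kw); sx <- sum(kw * xc); sxx <- sum(kw * xc^2)
    sy <- sum(kw * lw); sxy <- sum(kw * xc * lw)
    det <- sw * sxx - sx^2
    lf[q] <- if (det > 0) (sxx * sy - sx * sxy) / det else sy / sw
  }
  # enforce monotone non-increasing f
  iso <- stats::isoreg(ld, -lf)
  lf <- -iso$yf
  prof <- data.frame(d = d, f_raw = f_raw, f = exp(lf), npairs = npairs[ks])
  fit_alpha <- function(range) {
    sel <- prof$d >= range[1] & prof$d <= range[2] & prof$f > 0
    if (sum(sel) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(log10(f) ~ log10(d), data = prof[sel, ]))[2])
  }
  structure(list(profile = prof,
                 alpha_short = fit_alpha(short_range),
                 alpha_long = fit_alpha(long_range),
                 short_range = short_range, long_range = long_range,
                 bandwidth = bandwidth, res = g$res),
            class = "distance_template")
}

#' @export
print.distance_template <- function(x, ...) {
  cat(sprintf("distance_template: %d separations, %d bp bins\n",
              nrow(x$profile), x$res))
  cat(sprintf("  alpha (%.0f kb - %.1f Mb): %.3f\n",
              x$short_range[1] / 1e3, x$short_range[2] / 1e6, x$alpha_short))
  cat(sprintf("  alpha (%.1f - %.0f Mb): %.3f\n",
              x$long_range[1] / 1e6, x$long_range[2] / 1e6, x$alpha_long))
  invisible(x)
}

#' Interpolate the expected contact frequency at given distances
#'
#' Log-log linear interpolation of the smoothed template; constant
#' extrapolation beyond its support.
#'
#' @param template A \code{distance_template}.
#' @param d Distances in bases (> 0).
#' @return Expected frequency f(d).
#' @export
expected_frequency <- function(template, d) {
  p <- template$profile
  if (nrow(p) == 1) return(rep(p$f, length(d)))
  10^stats::approx(log10(p$d), log10(p$f), xout = log10(d), rule = 2)$y
}

#' Distance normalization of cis contacts
#'
#' Divides every off-diagonal intra-chromosomal entry by the expected
#' frequency at its bin separation. Optionally the strength of the
#' correction is attenuated for pairs involving bins with low capture
#' coverage: the correction exponent gamma(c) = min(1, (c/c_ref)^lambda)
#' shrinks toward 0 as coverage c drops below the reference c_ref (median
#' coverage over enriched bins), so a zero-coverage interactor bin is left
#' unnormalized. This attenuation is a configurable extension (off by
#' default); the qualitative contract is that low coverage makes the
#' normalization less penalizing. Trans entries and the diagonal are
#' unchanged.
#'
#' @param m A bias-corrected \code{contact_matrix}.
#' @param template A \code{distance_template}.
#' @param coverage Optional per-bin coverage vector (length = total bins);
#'   NULL disables attenuation.
#' @param lambda_cov Attenuation exponent. Default 1.
#' @return \code{m} with a \code{counts$norm} column.
#' @export
distance_normalize <- function(m, template, coverage = NULL, lambda_cov = 1) {
  cc <- m$counts
  ci <- .bin_chrom_index(m$grid, cc$i)
  cj <- .bin_chrom_index(m$grid, cc$j)
  cis <- ci == cj & cc$i != cc$j
  cc$norm <- cc$n
  if (any(cis)) {
    d <- (cc$j[cis] - cc$i[cis]) * as.double(m$grid$res)
    f <- expected_frequency(template, d)
    gam <- 1
    if (!is.null(coverage)) {
      cref <- stats::median(coverage[m$bins$enriched])
      if (!is.finite(cref) || cref <= 0) cref <- stats::median(coverage[coverage > 0])
      cpair <- pmin(coverage[cc$i[cis]], coverage[cc$j[cis]])
      gam <- pmin(1, pmax(0, cpair / cref)^lambda_cov)
    }
    cc$norm[cis] <- cc$n[cis] / f^gam
  }
  m$counts <- cc
  m
}
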