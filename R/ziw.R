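#' Fit a zero-inflated Weibull null distribution
#'
#' The null model for normalized contact strengths is a point mass at zero
#' (probability pi) mixed with a Weibull(shape, scale) tail. The zero mass
#' is estimated as the observed zero fraction. To keep genuine interactions
#' from inflating the tail, the Weibull parameters are estimated from the
#' nonzero values at or below their \code{truncation_q} empirical quantile,
#' maximizing the right-truncated likelihood (each density term renormalized
#' by the Weibull CDF at the truncation point).
#'
#' @param values Non-negative strengths.
#' @param truncation_q Truncation quantile of the nonzero values. Default
#'   0.95 (the lowest 95 percentiles enter the fit).
#' @param min_n Minimum number of nonzero values for a stable fit; fewer
#'   yields a flagged (non-converged) result. Default 200.
#' @return Object of class \code{ziw}: pi, shape, scale, trunc_q,
#'   trunc_value, n, n_pos, loglik, converged.
#' @examples
#' set.seed(1)
#' fit <- fit_ziw(rziw(5000, pi = 0.4, shape = 0.9, scale = 2))
#' coef(fit)
#' @export
fit_ziw <- function(values, truncation_q = 0.95, min_n = 200) {
  if (any(values < 0)) stop("strengths must be non-negative")
  n <- length(values)
  x <- values[values > 0]
  pi_hat <- 1 - length(x) / n
  out <- list(pi = pi_hat, shape = NA_real_, scale = NA_real_,
              trunc_q = truncation_q, trunc_value = NA_real_,
              n = n, n_pos = length(x), loglik = NA_real_,
              converged = FALSE)
  if (length(x) == 0) {
    out$pi <- 1
    out$converged <- TRUE
    return(structure(out, class = "ziw"))
  }
  if (length(x) < 2 || stats::sd(x) == 0) {
    warning("all nonzero strengths identical; Weibull shape degenerates")
    out$shape <- Inf
    out$scale <- x[1]
    return(structure(out, class = "ziw"))
  }
  tv <- stats::quantile(x, truncation_q, names = FALSE)
  xt <- x[x <= tv]
  out$trunc_value <- tv
  nll <- function(par) {
    k <- exp(par[1]); l <- exp(par[2])
    if (!is.finite(k) || !is.finite(l) || k <= 0 || l <= 0) return(1e300)
    v <- suppressWarnings(
      sum(stats::dweibull(xt, k, l, log = TRUE)) -
        length(xt) * stats::pweibull(tv, k, l, log.p = TRUE))
    if (!is.finite(v)) return(1e300)
    -v
  }
  # moment-style start: shape from log-spread, scale from mean
  sl <- stats::sd(log(xt))
  k0 <- if (is.finite(sl) && sl > 0) max(0.2, min(5, 1.2 / sl)) else 1
  l0 <- mean(xt) / gamma(1 + 1 / k0)
  if (!is.finite(l0) || l0 <= 0) l0 <- stats::median(xt)
  opt <- try(stats::optim(c(log(k0), log(l0)), nll, method = "BFGS"),
             silent = TRUE)
  if (inherits(opt, "try-error"))
    opt <- try(stats::optim(c(log(k0), log(l0)), nll, method = "Nelder-Mead"),
               silent = TRUE)
  if (inherits(opt, "try-error"))
    stop("Weibull likelihood optimization failed: ",
         attr(opt, "condition")$message)
  out$shape <- exp(opt$par[1])
  out$scale <- exp(opt$par[2])
  out$loglik <- -opt$value
  out$converged <- opt$convergence == 0 && length(x) >= min_n
  structure(out, class = "ziw")
}

#' @export
print.ziw <- function(x, ...) {
  cat("zero-inflated Weibull fit\n")
  cat(sprintf("  pi (zero mass): %.4f   shape: %.4f   scale: %.4f\n",
              x$pi, x$shape, x$scale))
  cat(sprintf("  n = %d (%d nonzero), truncated at q%.2f = %.4g, converged: %s\n",
              x$n, x$n_pos, x$trunc_q, x$trunc_value, x$converged))
  invisible(x)
}

#' @method coef ziw
#' @export
coef.ziw <- function(object, ...) {
  c(pi = object$pi, shape = object$shape, scale = object$scale)
}

#' @method logLik ziw
#' @export
logLik.ziw <- function(object, ...) {
  structure(object$loglik, df = 3L, class = "logLik")
}

#' Random draws from a zero-inflated Weibull
#'
#' @param n Number of draws.
#' @param pi Zero mass.
#' @param shape,scale Weibull parameters.
#' @return Numeric vector.
#' @export
rziw <- function(n, pi, shape, scale) {
  z <- stats::runif(n) < pi
  out <- numeric(n)
  out[!z] <- stats::rweibull(sum(!z), shape, scale)
  out
}

#' Upper-tail P value under a fitted zero-inflated Weibull
#'
#' Probability of a contact equally strong or stronger than x: 1 for x = 0
#' (every draw qualifies), and (1 - pi) * exp(-(x/scale)^shape) for x > 0.
#' Non-increasing in x.
#'
#' @param x Strengths (vector).
#' @param fit A \code{ziw} fit.
#' @return P values in [0, 1].
#' @export
ziw_pvalue <- function(x, fit) {
  if (any(x < 0)) stop("strengths must be non-negative")
  p <- rep(1, length(x))
  pos <- x > 0
  if (is.na(fit$shape)) {
    p[pos] <- if (fit$pi >= 1) 0 else NA_real_
    return(p)
  }
  if (is.infinite(fit$shape)) {
    # degenerate point mass at scale: beyond it the tail cannot be
    # estimated; report a conservative empirical-style bound instead of 0
    p[pos] <- (1 - fit$pi) *
      ifelse(x[pos] <= fit$scale, 1, 1 / (fit$n_pos + 1))
    return(p)
  }
  p[pos] <- (1 - fit$pi) * exp(-(x[pos] / fit$scale)^fit$shape)
  p
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up q-values; monotone non-decreasing in sorted p. The number of
#' tests m may exceed length(p) when untested (zero-count) pairs carry
#' P = 1 implicitly.
#'
#' @param p P values in [0, 1].
#' @param m Number of tests. Default length(p).
#' @return q-values.
#' @export
fdr_qvalues <- function(p, m = length(p)) {
  if (length(p) && (min(p) < 0 || max(p) > 1)) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH", n = max(m, length(p)))
}
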