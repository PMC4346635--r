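test_that("zero-inflated Weibull parameters are recovered from simulated draws", {
  set.seed(61)
  x <- rziw(1e5, pi = 0.6, shape = 0.8, scale = 2.0)
  f <- fit_ziw(x)
  expect_true(f$converged)
  # n = 1e5: Monte-Carlo error on pi ~ sqrt(.6*.4/1e5) = 0.0015
  expect_lt(abs(f$pi - 0.6), 3 * 0.0016)
  expect_lt(abs(f$shape - 0.8), 0.02)
  expect_lt(abs(f$scale - 2.0), 0.06)

  # refit on data simulated from the fitted model (self-consistency)
  set.seed(62)
  f2 <- fit_ziw(rziw(1e5, f$pi, f$shape, f$scale))
  expect_lt(abs(f2$shape - f$shape), 0.02)
  expect_lt(abs(f2$scale - f$scale), 0.06)
})

test_that("degenerate strength vectors never yield a silent successful fit", {
  f1 <- fit_ziw(rep(0, 500))
  expect_equal(f1$pi, 1)
  expect_true(is.na(f1$shape))
  expect_warning(f2 <- fit_ziw(c(rep(0, 100), rep(2.5, 300))), "identical")
  expect_true(is.infinite(f2$shape))
  expect_false(f2$converged)
})

test_that("ZIW tail probabilities follow the closed form and are monotone", {
  fit <- structure(list(pi = 0.5, shape = 1, scale = 1, n_pos = 100),
                   class = "ziw")
  expect_equal(ziw_pvalue(0, fit), 1)
  expect_equal(ziw_pvalue(log(2), fit), 0.25)
  x <- seq(0, 10, by = 0.1)
  p <- ziw_pvalue(x, fit)
  expect_true(all(diff(p) <= 0))
  expect_equal(ziw_pvalue(1e-9, fit), 0.5, tolerance = 1e-6)  # -> 1 - pi
  expect_lt(p[length(p)], 1e-4)

  # P values of a model-simulated null sample are super-uniform (zeros at 1)
  set.seed(63)
  xx <- rziw(20000, 0.4, 0.9, 1.5)
  f <- fit_ziw(xx)
  pv <- ziw_pvalue(xx, f)
  u <- seq(0.01, 0.6, by = 0.01)
  ecdf_p <- ecdf(pv)
  expect_true(all(ecdf_p(u) <= u + 0.02))
})

test_that("BH q-values match the hand-computed step-up", {
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.9)), c(0.04, 0.04, 0.04, 0.9))
  expect_equal(fdr_qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_qvalues(0.123), 0.123)
  # sorted q-values are monotone
  set.seed(64)
  p <- runif(200)
  q <- fdr_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # implicit untested zeros enlarge the burden
  expect_equal(fdr_qvalues(0.01, m = 10), 0.1)
})

test_that("three-sample overlap probability matches exhaustive enumeration on small universes", {
  got <- combinatorial_overlap_pvalue(2, n = c(2, 3, 4), N = c(4, 5, 6))
  expect_equal(got$p.value, overlap_pvalue_enum(2, c(2, 3, 4), c(4, 5, 6)),
               tolerance = 1e-12)
  got2 <- combinatorial_overlap_pvalue(1, n = c(3, 3, 3), N = c(6, 7, 8))
  expect_equal(got2$p.value, overlap_pvalue_enum(1, c(3, 3, 3), c(6, 7, 8)),
               tolerance = 1e-12)
  expect_equal(combinatorial_overlap_pvalue(0, c(5, 5, 5), c(10, 10, 10))$p.value, 1)
})

test_that("three-sample overlap probability matches Monte Carlo sampling", {
  got <- combinatorial_overlap_pvalue(2, n = c(5, 5, 5), N = c(10, 10, 10))
  set.seed(65)
  reps <- 20000
  hit <- 0
  for (r in seq_len(reps)) {
    s1 <- sample.int(10, 5); s2 <- sample.int(10, 5); s3 <- sample.int(10, 5)
    if (length(intersect(intersect(s1, s2), s3)) >= 2) hit <- hit + 1
  }
  mc <- hit / reps
  se <- sqrt(mc * (1 - mc) / reps)
  expect_lt(abs(got$p.value - mc), 3 * se)
})

test_that("the printed three-library overlap is vanishingly unlikely by chance", {
  ot <- combinatorial_overlap_pvalue(147, n = c(216379, 177893, 217396),
                                     N = c(97376960, 95608750, 92912739))
  expect_lt(ot$log10_p, -16)
  expect_match(ot$label, "1e-16")
  ob <- combinatorial_overlap_pvalue(147, n = c(216379, 177893, 217396),
                                     N = c(97376960, 95608750, 92912739),
                                     method = "binomial")
  expect_lt(ob$log10_p, -16)
})

# --- interaction calling on constructed normalized matrices -----------------

# a grid with one enriched block per chromosome and ZIW-null strengths; known
# strong pairs planted on top
make_lib_matrix <- function(grid, enriched, pairs_strong, seed,
                            null_frac = 0.3) {
  set.seed(seed)
  m <- bin_contacts(data.frame(chrom1 = character(0)), grid)
  m$bins$sites <- 1L
  m$bins$enriched[enriched] <- TRUE
  # populated E-N cis pairs: enriched bin x sample of partners
  cand <- list()
  for (e in enriched) {
    ci <- chicflow:::.bin_chrom_index(grid, e)
    partners <- setdiff(which(chicflow:::.bin_chrom_index(grid,
                          seq_len(grid$total)) == ci), enriched)
    partners <- partners[abs(partners - e) * grid$res > 1e4]
    pick <- sample(partners, round(length(partners) * null_frac))
    cand[[length(cand) + 1]] <- data.frame(i = pmin(e, pick),
                                           j = pmax(e, pick))
  }
  cc <- unique(do.call(rbind, cand))
  cc$n <- rweibull(nrow(cc), shape = 2, scale = 10)
  for (r in seq_len(nrow(pairs_strong))) {
    sel <- cc$i == pairs_strong$i[r] & cc$j == pairs_strong$j[r]
    if (!any(sel))
      cc <- rbind(cc, data.frame(i = pairs_strong$i[r], j = pairs_strong$j[r],
                                 n = 0))
    cc$n[cc$i == pairs_strong$i[r] & cc$j == pairs_strong$j[r]] <- 80
  }
  cc <- cc[order(cc$i, cc$j), ]
  m$counts <- data.frame(i = cc$i, j = cc$j, n = cc$n, raw = 1e6,
                         norm = cc$n)
  m
}

test_that("shared-significant calls are exactly the loops common to all libraries", {
  grid <- bin_grid(c(a = 2e7, b = 2e7), 9000)
  enriched <- c(500, 501, 2800, 2801)
  common <- data.frame(i = 500, j = c(600:604, 700:704))      # 10 shared
  priv <- lapply(1:3, function(L)
    data.frame(i = 501, j = 800 + (L - 1) * 20 + 0:9))        # 10 private each
  mats <- lapply(1:3, function(L)
    make_lib_matrix(grid, enriched, rbind(common, priv[[L]]), seed = 70 + L))
  set.seed(80)
  calls <- call_interactions(mats)
  ck <- paste(calls$i, calls$j)
  common_k <- paste(common$i, common$j)
  expect_setequal(ck[calls$shared], common_k)
  # private loops are significant in their own library only
  p1 <- paste(priv[[1]]$i, priv[[1]]$j)
  expect_true(all(p1 %in% ck[calls$sig_1]))
  expect_false(any(p1 %in% ck[calls$shared]))
})

test_that("a pure-null library yields FDR-consistent calls", {
  grid <- bin_grid(c(a = 2e7, b = 2e7), 9000)
  enriched <- c(500, 501, 2800, 2801)
  mats <- make_lib_matrix(grid, enriched,
                          data.frame(i = integer(0), j = integer(0)),
                          seed = 74)
  set.seed(81)
  calls <- call_interactions(mats)
  n_tested <- attr(calls, "n_tests")
  expect_lt(sum(calls$sig_1) / n_tested, 0.05)
})
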