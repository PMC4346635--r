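test_that("identical libraries give an enrichment factor of one", {
  set.seed(101)
  d <- data.frame(read_id = sprintf("r%d", 1:2000),
                  chrom1 = "c", pos1 = sample(1e6, 2000), strand1 = "+", mapq1 = 60,
                  chrom2 = "c", pos2 = sample(1e6, 2000), strand2 = "-", mapq2 = 60,
                  stringsAsFactors = FALSE)
  targets <- data.frame(chrom = "c", start = 2e5, end = 3e5)
  ef <- enrichment_factor(d, d, targets, subsample_size = 2000)
  expect_equal(ef$fold, 1)
  # zero on-target reference: infinity sentinel with a warning, no crash
  far <- transform(d, pos1 = pos1 + 5e6, pos2 = pos2 + 5e6, chrom1 = "c",
                   chrom2 = "c")
  far$chrom1 <- "c"; far$chrom2 <- "c"
  expect_warning(ef2 <- enrichment_factor(d, far, targets), "infinite")
  expect_true(is.infinite(ef2$fold))
  expect_error(enrichment_factor(d[0, ], d, targets), "non-empty")
})

test_that("the simulated capture boost is measured back within 15 percent", {
  base <- list(chrom_lengths = c(simA = 2e7, simB = 2e7), n_ditags = 2e5,
               bias_sigma = 0.2, trans_frac = 0.05,
               frac_self_ligation = 0, frac_non_digested = 0,
               frac_circularized = 0, frac_no_site = 0, frac_duplicate = 0)
  cfgT <- do.call(sim_config, c(base, list(capture_boost = 130, seed = 102)))
  cfgR <- do.call(sim_config, c(base, list(capture_boost = 1, baits = NULL,
                                           seed = 103)))
  sg <- simulate_genome(cfgT, sequence = FALSE)
  libT <- simulate_library(cfgT, sg$fmap)
  libR <- simulate_library(cfgR, sg$fmap)
  set.seed(104)
  ef <- enrichment_factor(libT$ditags, libR$ditags, cfgT$baits)
  expect_lt(abs(ef$fold - 130) / 130, 0.15)
  # reciprocal swap: fold(test, ref) * fold(ref, test) ~ 1
  set.seed(105)
  ef_rev <- enrichment_factor(libR$ditags, libT$ditags, cfgT$baits)
  expect_equal(ef$fold * ef_rev$fold, 1, tolerance = 0.1)
})

test_that("association overlap reproduces the printed Fisher result and the enumeration oracle", {
  ht <- association_overlap_test(366, 88, 61, 23)
  expect_equal(ht$p.value, 8.54e-3, tolerance = 1e-3)  # printed precision
  # identical proportions in both groups: no signal
  ht2 <- association_overlap_test(200, 100, 40, 20)
  expect_gt(ht2$p.value, 0.99)
  expect_error(association_overlap_test(100, 10, 20, 15), "inconsistent")

  set.seed(106)
  for (r in 1:20) {
    all_b <- sample(20:50, 1)
    ov <- sample(1:(all_b - 1), 1)
    sg <- sample(1:(all_b - 1), 1)
    so <- sample(0:min(ov, sg), 1)
    if (all_b - sg - ov + so < 0) next
    ht <- association_overlap_test(all_b, ov, sg, so)
    tab <- matrix(c(so, sg - so, ov - so, all_b - sg - ov + so), 2,
                  byrow = TRUE)
    expect_equal(ht$p.value, fisher_two_sided_enum(tab), tolerance = 1e-9)
  }
})

test_that("low-association bins require a SNP within a decade of the region minimum", {
  grid <- bin_grid(c(c1 = 9e5), 9000)
  assoc <- data.frame(chrom = "c1",
                      pos = c(1000, 50000, 100000, 200000),
                      p = c(1e-8, 5e-8, 1e-6, 0.5))
  regions <- data.frame(chrom = "c1", start = 0, end = 3e5)
  msk <- low_association_mask(assoc, regions, grid)
  expect_equal(which(msk), c(1L, 6L))  # 1e-6 is outside one decade of 1e-8
  # all SNPs equal: every SNP-containing bin flagged
  assoc2 <- transform(assoc, p = 0.2)
  expect_equal(which(low_association_mask(assoc2, regions, grid)),
               c(1L, 6L, 12L, 23L))
  expect_error(low_association_mask(assoc, data.frame(chrom = "c1",
                                                      start = 5e5, end = 6e5),
                                    grid), "no SNP")
  # brute-force oracle on random tracks
  set.seed(107)
  for (r in 1:10) {
    a <- data.frame(chrom = "c1", pos = sort(sample(0:(9e5 - 1), 40)),
                    p = 10^runif(40, -9, -1))
    got <- low_association_mask(a, regions, grid)
    inr <- a$pos >= 0 & a$pos < 3e5
    thr <- 10 * min(a$p[inr])
    oracle <- rep(FALSE, grid$total)
    for (s in which(inr & a$p <= thr))
      oracle[floor(a$pos[s] / 9000) + 1] <- TRUE
    expect_equal(got, oracle)
  }
})

test_that("Monte Carlo regulatory overlap handles saturation, exclusivity and enrichment", {
  grid <- bin_grid(c(c1 = 9e5, c2 = 9e5), 9000)  # 200 bins
  whole <- list(all = data.frame(chrom = c("c1", "c2"), start = 0, end = 9e5))
  set.seed(108)
  r1 <- regulatory_overlap_mc(1:20, whole, grid, n_mc = 500)
  expect_equal(r1$p.value, 1)  # every sample ties the observed proportion 1
  # elements covering exactly the significant bins
  bc <- bin_coords(grid, 1:20)
  only <- list(sig = data.frame(chrom = bc$chrom, start = bc$start, end = bc$end))
  set.seed(109)
  r2 <- regulatory_overlap_mc(1:20, only, grid, n_mc = 1e4)
  expect_equal(r2$m, 0)
  expect_match(r2$label, "^<")
  expect_equal(r2$p.value, 1e-4)
  # planted twofold enrichment
  set.seed(110)
  el_bins <- sort(c(1:30, sample(31:200, 40)))  # sig bins overlap at ~0.75
  bc3 <- bin_coords(grid, el_bins)
  els <- list(e = data.frame(chrom = bc3$chrom, start = bc3$start, end = bc3$end))
  sig <- c(1:15, sample(setdiff(el_bins, 1:30), 3), sample(setdiff(31:200, el_bins), 2))
  r3 <- regulatory_overlap_mc(sig, els, grid, n_mc = 1e4)
  expect_lt(r3$p.value, 0.01)
})

test_that("Monte Carlo P values are stable across seeds within binomial error", {
  grid <- bin_grid(c(c1 = 9e5, c2 = 9e5), 9000)
  set.seed(111)
  el_bins <- sample(200, 80)
  bc <- bin_coords(grid, el_bins)
  els <- list(e = data.frame(chrom = bc$chrom, start = bc$start, end = bc$end))
  sig <- c(el_bins[1:12], setdiff(1:200, el_bins)[1:8])
  ps <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    regulatory_overlap_mc(sig, els, grid, n_mc = 1e4)$p.value
  }, numeric(1))
  p0 <- mean(ps)
  expect_lt(max(abs(ps - p0)), 4 * sqrt(p0 * (1 - p0) / 1e4) + 1e-4)
})

test_that("shared-TF counting separates real pairs from permuted controls", {
  grid <- bin_grid(c(c1 = 9e6, c2 = 9e6), 9000)
  # no peaks anywhere: degenerate, P = 1
  calls <- data.frame(bin_test = rep(c(10, 1010), each = 5),
                      bin_int = c(101:105, 1101:1105),
                      region = rep(c("r1", "r2"), each = 5))
  expect_warning(t0 <- tf_sharing_test(calls, list(), grid), "degenerate")
  expect_equal(t0$p.value, 1)

  # planted: 3 TFs bind both ends of every real pair; permuted pairs share none
  set.seed(112)
  n_pairs <- 147
  regions <- rep(1:7, length.out = n_pairs)
  bin_test <- 10 + regions            # one test bin per region
  bin_int <- 300 + seq_len(n_pairs) * 3
  calls <- data.frame(bin_test = bin_test, bin_int = bin_int, region = regions)
  peak_for <- function(bins) {
    bc <- bin_coords(grid, bins)
    data.frame(chrom = bc$chrom, start = bc$start + 10, end = bc$start + 60)
  }
  peaks <- list()
  for (tf in 1:3) {
    # each TF binds the test bin of region r and the interactors of region r
    peaks[[paste0("tf", tf)]] <-
      peak_for(c(unique(bin_test), bin_int))
  }
  # make control pairs share nothing: interactors of other regions lack the
  # test bin's TFs -> but here all share; instead restrict TF binding per region
  peaks <- list()
  for (r in 1:7) {
    peaks[[paste0("tfA", r)]] <- peak_for(c(10 + r, bin_int[regions == r]))
    peaks[[paste0("tfB", r)]] <- peak_for(c(10 + r, bin_int[regions == r]))
    peaks[[paste0("tfC", r)]] <- peak_for(c(10 + r, bin_int[regions == r]))
  }
  tt <- tf_sharing_test(calls, peaks, grid)
  expect_equal(unname(as.vector(tt$shared_real)), rep(3, n_pairs))
  expect_true(all(tt$shared_control == 0))
  expect_lt(tt$p.value, 1e-3)
})

test_that("the TF-sharing test is calibrated when real pairs equal controls", {
  grid <- bin_grid(c(c1 = 9e6, c2 = 9e6), 9000)
  set.seed(113)
  n_pairs <- 147
  regions <- rep(1:7, length.out = n_pairs)
  calls <- data.frame(bin_test = 10 + regions,
                      bin_int = sample(300:900, n_pairs),
                      region = regions)
  # TFs bind random bins: no structural difference real vs permuted
  peaks <- lapply(1:5, function(tf) {
    bc <- bin_coords(grid, sample(c(10:17, 300:900), 250))
    data.frame(chrom = bc$chrom, start = bc$start, end = bc$end)
  })
  names(peaks) <- paste0("tf", 1:5)
  rej <- 0
  for (r in 1:100) {
    tt <- suppressWarnings(tf_sharing_test(calls, peaks, grid))
    if (!is.na(tt$p.value) && tt$p.value < 0.05) rej <- rej + 1
  }
  expect_lt(rej / 100, 0.05 + 0.05)
})

test_that("chromatin-state regrouping merges adjacent same-class intervals order-invariantly", {
  seg <- data.frame(chrom = "c1", start = c(0, 100, 200, 400),
                    end = c(100, 200, 300, 500),
                    state = c("E1", "E2", "Tx", "E1"),
                    stringsAsFactors = FALSE)
  map <- c(E1 = "enhancer", E2 = "enhancer", Tx = "transcribed")
  out <- regroup_chromatin_states(seg, map)
  expect_equal(out$start, c(0, 200, 400))
  expect_equal(out$end, c(200, 300, 500))
  expect_equal(out$class, c("enhancer", "transcribed", "enhancer"))
  # unmapped label lists the offenders
  expect_error(regroup_chromatin_states(
    transform(seg, state = c("E1", "Zz", "Tx", "Qq")), map), "Zz")
  # shuffled input gives identical merged output
  set.seed(114)
  shuf <- seg[sample(nrow(seg)), ]
  expect_equal(regroup_chromatin_states(shuf, map), out)
})
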