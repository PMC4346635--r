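# shared fixtures and small utilities for the suite

# random DNA with no accidental AAGCTT unless planted
random_dna <- function(n, exclude = "AAGCTT") {
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  repeat {
    h <- gregexpr(exclude, s, fixed = TRUE)[[1]]
    if (h[1] < 0) return(s)
    for (p in h) substr(s, p + 3, p + 3) <- "A"  # break GCTT -> GATT? keep simple
    substr(s, h[1] + 2, h[1] + 2) <- "T"
  }
}

# snap a position forward to a 9-kb bin containing at least one cut site
snap_to_sited_bin <- function(fmap, chrom, pos, res = 9000) {
  cc <- fmap$cuts[[chrom]]
  repeat {
    b <- floor(pos / res)
    if (any(cc >= b * res & cc < (b + 1) * res)) return(pos)
    pos <- pos + res
  }
}

# simulate a library and push it through filter/bin/normalize
sim_to_normalized <- function(cfg, fmap, bins = NULL, grid = NULL) {
  if (is.null(grid)) grid <- bin_grid(cfg$chrom_lengths, cfg$res)
  if (is.null(bins)) bins <- annotate_bins(grid, fmap)
  lib <- simulate_library(cfg, fmap)
  fb <- filter_bona_fide(lib$ditags, fmap)
  m <- bin_contacts(fb$ditags, grid, bins)
  m <- mark_enriched_bins(m, cfg$baits)
  m <- filter_valid_bins(m)
  m <- suppressWarnings(iterative_bias_correct(m))
  m <- distance_normalize(m, estimate_distance_template(m))
  list(m = m, lib = lib, grid = grid)
}

# hand-built contact matrix from a triplet table (counts on a given grid)
toy_matrix <- function(grid, i, j, n, sites = 1L) {
  m <- bin_contacts(data.frame(chrom1 = character(0), pos1 = numeric(0),
                               chrom2 = character(0), pos2 = numeric(0)),
                    grid)
  m$counts <- data.frame(i = as.integer(i), j = as.integer(j), n = n)
  m$bins$sites <- sites
  m
}

# exhaustive three-sample overlap oracle for small nested universes:
# S1 = 1..N1 within S2 = 1..N2 within S3 = 1..N3
overlap_pvalue_enum <- function(k, n, N) {
  s1 <- utils::combn(N[1], n[1], simplify = FALSE)
  s2 <- utils::combn(N[2], n[2], simplify = FALSE)
  s3 <- utils::combn(N[3], n[3], simplify = FALSE)
  hits <- 0; tot <- 0
  for (a in s1) for (b in s2) {
    ab <- intersect(a, b)
    for (d in s3) {
      tot <- tot + 1
      if (length(intersect(ab, d)) >= k) hits <- hits + 1
    }
  }
  hits / tot
}

# two-sided Fisher P by direct hypergeometric enumeration
fisher_two_sided_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  x <- tab[1, 1]
  supp <- max(0, kk - n):min(kk, m)
  d <- stats::dhyper(supp, m, n, kk)
  sum(d[d <= stats::dhyper(x, m, n, kk) * (1 + 1e-7)])
}
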