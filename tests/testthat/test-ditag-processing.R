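mk_end <- function(id, chrom, pos, strand = "+", mapq = 60)
  data.frame(read_id = id, chrom = chrom, pos = pos, strand = strand,
             mapq = mapq, stringsAsFactors = FALSE)

test_that("ditag assembly enforces strict MAPQ on both ends and drops singletons", {
  al <- rbind(mk_end("r1", "c1", 100, "+", 31), mk_end("r1", "c1", 5000, "-", 31),
              mk_end("r2", "c1", 200, "+", 30), mk_end("r2", "c1", 6000, "-", 60),
              mk_end("r3", "c1", 300, "+", 60))
  out <- assemble_ditags(al, mapq_min = 30)
  expect_equal(nrow(out$ditags), 1)          # r1 retained (31 > 30)
  expect_equal(out$ditags$read_id, "r1")
  expect_equal(unname(out$counts["sub_mapq"]), 1)   # r2: 30 is not > 30
  expect_equal(unname(out$counts["singleton"]), 1)  # r3
  expect_error(assemble_ditags(rbind(al, mk_end("r1", "c2", 1, "+", 60))),
               "malformed")
})

test_that("canonical ordering puts the lower-coordinate end first", {
  al <- rbind(mk_end("r1", "c2", 100, "+", 60), mk_end("r1", "c1", 5000, "-", 60))
  d <- assemble_ditags(al)$ditags
  expect_equal(d$chrom1, "c1")
  expect_equal(d$pos1, 5000)
  expect_equal(d$strand1, "-")
})

test_that("duplicate removal collapses identical coordinate/strand pairs, including swapped ends", {
  d <- data.frame(read_id = c("a", "b", "c"),
                  chrom1 = c("c1", "c1", "c1"), pos1 = c(100, 100, 900),
                  strand1 = c("+", "+", "-"), mapq1 = 60,
                  chrom2 = c("c1", "c1", "c1"), pos2 = c(900, 900, 100),
                  strand2 = c("-", "-", "+"), mapq2 = 60,
                  stringsAsFactors = FALSE)
  # c is (B, A) of the same molecule: swapped ends still collapse
  out <- remove_duplicates(d)
  expect_equal(nrow(out$ditags), 1)
  expect_equal(out$n_duplicates, 2)
  expect_equal(out$ditags$read_id, "a")  # first encountered survives

  # 10,000 random ditags with planted duplication vs independent key oracle
  set.seed(21)
  n <- 10000
  base <- data.frame(read_id = sprintf("r%05d", 1:n),
                     chrom1 = sample(c("c1", "c2"), n, TRUE),
                     pos1 = sample(1e5, n, TRUE), strand1 = sample(c("+", "-"), n, TRUE),
                     mapq1 = 60,
                     chrom2 = sample(c("c1", "c2"), n, TRUE),
                     pos2 = sample(1e5, n, TRUE), strand2 = sample(c("+", "-"), n, TRUE),
                     mapq2 = 60, stringsAsFactors = FALSE)
  dup_idx <- sample(n, 500)
  stream <- rbind(base, transform(base[dup_idx, ], read_id = sprintf("d%04d", 1:500)))
  got <- remove_duplicates(stream)
  # oracle: canonical key via explicit per-row sort of the two end tuples
  key_of <- function(df) apply(df, 1, function(r) {
    e1 <- paste(r["chrom1"], as.numeric(r["pos1"]), r["strand1"])
    e2 <- paste(r["chrom2"], as.numeric(r["pos2"]), r["strand2"])
    paste(sort(c(e1, e2)), collapse = "|")
  })
  expect_equal(unname(sort(unique(key_of(stream)))),
               unname(sort(key_of(got$ditags))))
  expect_equal(got$n_duplicates, nrow(stream) - length(unique(key_of(stream))))
})

test_that("artifact classification follows the orientation/distance rule table", {
  # fragments: [0,1000), [1000,2000), [2000,12000) on a 12 kb chromosome
  fm <- structure(list(cuts = list(c = c(1000, 2000)), seqlengths = c(c = 12000),
                       pattern = "AAGCTT", cut_offset = 1L),
                  class = "fragment_map")
  mk <- function(p1, s1, p2, s2, c2 = "c")
    data.frame(read_id = "x", chrom1 = "c", pos1 = p1, strand1 = s1, mapq1 = 60,
               chrom2 = c2, pos2 = p2, strand2 = s2, mapq2 = 60,
               stringsAsFactors = FALSE)
  # same fragment, inward (+ upstream) -> non-digested
  expect_equal(classify_artifact(mk(1100, "+", 1900, "-"), fm), "non_digested")
  # same fragment, outward -> self-ligation
  expect_equal(classify_artifact(mk(1100, "-", 1900, "+"), fm), "self_ligation")
  # same fragment, tandem strands -> valid
  expect_equal(classify_artifact(mk(1100, "+", 1900, "+"), fm), "valid")
  # adjacent fragments, outward -> circularized
  expect_equal(classify_artifact(mk(900, "-", 1100, "+"), fm), "circularized")
  # adjacent fragments, inward -> kept valid
  expect_equal(classify_artifact(mk(900, "+", 1100, "-"), fm), "valid")
  # either end farther than the limit from any cut -> no_site, with priority
  expect_equal(classify_artifact(mk(2900, "-", 11000, "+"), fm,
                                 max_site_distance = 800), "no_site")
  # distances measured on both ends
  expect_equal(classify_artifact(mk(900, "+", 5000, "-"), fm, 800), "no_site")
  # classification is invariant to end order
  a <- classify_artifact(mk(900, "-", 1100, "+"), fm)
  b <- classify_artifact(mk(1100, "+", 900, "-"), fm)
  expect_identical(a, b)
})

test_that("bona fide filtering conserves counts and matches simulator ground truth", {
  cfg <- sim_config(chrom_lengths = c(simA = 4e6, simB = 4e6), n_ditags = 4e4,
                    capture_boost = 1, baits = NULL, d_max = 2e6, seed = 31)
  sg <- simulate_genome(cfg, sequence = FALSE)
  lib <- simulate_library(cfg, sg$fmap)
  fb <- filter_bona_fide(lib$ditags, sg$fmap)
  r <- fb$report
  expect_equal(unname(r["input"]),
               unname(sum(r[c("duplicates", "self_ligation", "non_digested",
                              "circularized", "no_site", "valid")])))
  # ground-truth confusion: every planted no_site and same-fragment artifact
  # is recovered as its own class
  lab <- lib$truth$label
  cls <- classify_artifact(remove_duplicates(lib$ditags)$ditags, sg$fmap)
  d <- lib$ditags
  swap <- d$chrom2 < d$chrom1 | (d$chrom1 == d$chrom2 & d$pos2 < d$pos1)
  k1 <- paste(d$chrom1, d$pos1, d$strand1)
  k2 <- paste(d$chrom2, d$pos2, d$strand2)
  key <- paste(ifelse(swap, k2, k1), ifelse(swap, k1, k2))
  lab_nodup <- lab[!duplicated(key)]
  for (cl in c("no_site", "self_ligation", "non_digested")) {
    expect_true(all(cls[lab_nodup == cl] == cl), info = cl)
  }
  expect_true(all(cls[lab_nodup %in% c("background", "background_trans",
                                       "loop", "capture_boost")] == "valid"))

  # empty stream
  empty <- lib$ditags[0, ]
  fb0 <- filter_bona_fide(empty, sg$fmap)
  expect_equal(nrow(fb0$ditags), 0)
  expect_true(all(fb0$report == 0))
})

test_that("filtering commutes with binning on the valid fraction", {
  cfg <- sim_config(chrom_lengths = c(simA = 2e6, simB = 2e6), n_ditags = 2e4,
                    capture_boost = 1, baits = NULL, d_max = 1e6, seed = 32)
  sg <- simulate_genome(cfg, sequence = FALSE)
  lib <- simulate_library(cfg, sg$fmap)
  grid <- bin_grid(cfg$chrom_lengths, cfg$res)
  fb <- filter_bona_fide(lib$ditags, sg$fmap)
  m1 <- bin_contacts(fb$ditags, grid)
  # pre-filtered stream binned directly
  m2 <- bin_contacts(filter_bona_fide(fb$ditags, sg$fmap)$ditags, grid)
  expect_equal(m1$counts, m2$counts)
})
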