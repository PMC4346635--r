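#' Simulation configuration
#'
#' Bundles every knob of the ditag-level capture Hi-C simulator. The
#' defaults describe a desk-scale experiment: two 20 Mb chromosomes,
#' HindIII-like sites at a mean spacing of 3 kb, one 18 kb capture target
#' per chromosome boosted 130-fold, a two-regime power-law distance decay
#' (exponent -0.52 below 0.5 Mb, -0.97 from 0.5 to 7 Mb), log-normal
#' per-bin bias, and realistic artifact fractions.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param site_spacing Mean restriction-site spacing in bases.
#' @param pattern,cut_offset Recognition site planted by
#'   \code{\link{simulate_genome}}.
#' @param res Bin resolution used by the contact generator.
#' @param baits data.frame (chrom, start, end) of capture targets, or NULL.
#' @param capture_boost Fold enrichment of bait-touching ditags.
#' @param alpha_short,alpha_long,breakpoint Distance-decay power-law:
#'   exponent below / above the breakpoint (continuity enforced).
#' @param d_min,d_max Support of the cis separation distribution in bases.
#'   Separations shorter than two bins are never generated: at the scale of
#'   a bin they would be conflated with re-ligation geometry.
#' @param trans_frac Fraction of background ditags that are trans.
#' @param bias_sigma Log-normal sigma of per-bin visibility bias (mean 1).
#' @param loops data.frame (chrom1, pos1, chrom2, pos2, fold) of planted
#'   loop anchors, or NULL.
#' @param domains data.frame (chrom, start, end, ratio) of planted domains
#'   (within-domain contact rate multiplied by ratio), or NULL.
#' @param frac_self_ligation,frac_non_digested,frac_circularized,frac_no_site
#'   Artifact fractions of the library.
#' @param frac_duplicate PCR-duplicate fraction of the final stream.
#' @param n_ditags Background library size before loops and duplicates.
#' @param seed Integer seed; runs are bit-reproducible.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(chrom_lengths = c(simA = 2e7, simB = 2e7),
                       site_spacing = 3000,
                       pattern = "AAGCTT", cut_offset = 1L,
                       res = 9000,
                       baits = data.frame(
                         chrom = c("simA", "simB"),
                         start = c(5e6, 5e6),
                         end = c(5e6 + 18000, 5e6 + 18000),
                         stringsAsFactors = FALSE),
                       capture_boost = 130,
                       alpha_short = -0.52, alpha_long = -0.97,
                       breakpoint = 5e5,
                       d_min = 9000, d_max = 7e6,
                       trans_frac = 0.05,
                       bias_sigma = 0.3,
                       loops = NULL, domains = NULL,
                       frac_self_ligation = 0.02,
                       frac_non_digested = 0.03,
                       frac_circularized = 0.02,
                       frac_no_site = 0.02,
                       frac_duplicate = 0.05,
                       n_ditags = 5e5,
                       seed = 1L) {
  fr <- c(frac_self_ligation, frac_non_digested, frac_circularized,
          frac_no_site, frac_duplicate)
  if (any(fr < 0) || any(fr > 1) || sum(fr) >= 1)
    stop("artifact fractions must be in [0,1] and sum to < 1")
  if (any(chrom_lengths < 10 * site_spacing))
    stop("chromosomes must be at least 10x the site spacing")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d chromosome(s) (%.1f Mb), %d ditags, seed %d\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              x$n_ditags, x$seed))
  invisible(x)
}

#' Simulate a genome with planted restriction sites
#'
#' Plants the recognition pattern at exponentially spaced positions (mean
#' \code{site_spacing}) and, when sequence is requested, fills the rest
#' with random bases from which accidental pattern occurrences are
#' scrubbed, so an in-silico digest recovers exactly the planted sites.
#'
#' @param cfg A \code{sim_config}.
#' @param sequence Generate actual sequence (TRUE) or only the site
#'   coordinates (FALSE; much faster for large genomes).
#' @return list(genome = DNAStringSet or NULL, fmap = \code{fragment_map}
#'   built from the planted cut positions, sites = planted pattern starts).
#' @export
simulate_genome <- function(cfg, sequence = TRUE) {
  set.seed(cfg$seed)
  plen <- nchar(cfg$pattern)
  sites <- lapply(cfg$chrom_lengths, function(L) {
    n_guess <- ceiling(L / cfg$site_spacing * 1.5) + 10
    pos <- cumsum(stats::rexp(n_guess, 1 / cfg$site_spacing))
    while (max(pos) < L)
      pos <- c(pos, max(pos) + cumsum(stats::rexp(n_guess, 1 / cfg$site_spacing)))
    pos <- floor(pos[pos >= 1 & pos <= L - plen - 1])
    # planted patterns must not overlap
    pos <- pos[c(TRUE, diff(pos) >= plen)]
    as.integer(pos)
  })
  cuts <- lapply(sites, function(s) s + cfg$cut_offset)
  fmap <- structure(list(cuts = cuts, seqlengths = cfg$chrom_lengths,
                         pattern = cfg$pattern, cut_offset = cfg$cut_offset),
                    class = "fragment_map")
  genome <- NULL
  if (sequence) {
    pat_chars <- strsplit(cfg$pattern, "")[[1]]
    seqs <- lapply(seq_along(cfg$chrom_lengths), function(ci) {
      L <- cfg$chrom_lengths[ci]
      v <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      s <- sites[[ci]]
      idx <- rep(s, each = plen) + rep(seq_len(plen) - 1L, length(s))
      v[idx + 1L] <- rep(pat_chars, length(s))
      str <- paste(v, collapse = "")
      planted <- s + 1L  # 1-based starts of planted occurrences
      repeat {
        hits <- gregexpr(cfg$pattern, str, fixed = TRUE)[[1]]
        stray <- setdiff(hits[hits > 0], planted)
        if (!length(stray)) break
        # break each stray occurrence by flipping its middle base
        for (h in stray) {
          mid <- h + plen %/% 2
          old <- substr(str, mid, mid)
          substr(str, mid, mid) <- setdiff(c("A", "C", "G", "T"), old)[1]
        }
      }
      str
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(cfg$chrom_lengths)
  }
  list(genome = genome, fmap = fmap, sites = sites)
}

# two-regime power law, continuous at the breakpoint
.decay_f0 <- function(d, alpha_short, alpha_long, breakpoint) {
  C <- breakpoint^(alpha_short - alpha_long)
  ifelse(d < breakpoint, d^alpha_short, C * d^alpha_long)
}

# draw one cut site per requested bin (global bin indices), with a uniform
# offset; positions stay inside the bin and within 400 bp of the site
.materialize_positions <- function(bins, grid, sites_by_bin) {
  pos <- numeric(length(bins))
  groups <- split(seq_along(bins), bins)
  for (bn in names(groups)) {
    b <- as.integer(bn)
    sel <- groups[[bn]]
    ss <- sites_by_bin[[b]]
    site <- ss[sample.int(length(ss), length(sel), replace = TRUE)]
    off <- sample(-400:400, length(sel), replace = TRUE)
    ci <- .bin_chrom_index(grid, b)
    lo <- (b - 1L - grid$offsets[ci]) * grid$res
    hi <- min(lo + grid$res, grid$lengths[ci]) - 1
    pos[sel] <- pmin(pmax(site + off, lo), hi)
  }
  pos
}

#' Simulate a capture Hi-C ditag library with ground truth
#'
#' Generates background cis ditags with per-pair contact probability
#' proportional to the configured two-regime power law of genomic
#' separation, uniform trans ditags, log-normal per-bin bias (by rejection),
#' planted domains (within-domain rate multiplied), capture enrichment
#' (additional independent bait-touching ditags, calibrated so a
#' size-matched enrichment-factor measurement returns the configured boost
#' in expectation), planted loops (excess Poisson mass at anchor bin pairs,
#' fold times the expected background at that separation), artifact ditags
#' with the exact geometry of each background class, and PCR duplicates.
#' Both ends of every non-artifact ditag fall within 400 bp of a
#' restriction site, in bins containing at least one site (bins without
#' sites are invisible to Hi-C and are exactly the ones the valid-bin
#' filter drops).
#'
#' @param cfg A \code{sim_config}.
#' @param fmap A \code{fragment_map}, typically from
#'   \code{\link{simulate_genome}}.
#' @return list(ditags = pairs-style data.frame, truth = list(label,
#'   bias, loops, domains, bait_bins, grid, ...)).
#' @export
simulate_library <- function(cfg, fmap) {
  set.seed(cfg$seed + 1L)
  grid <- bin_grid(fmap$seqlengths, cfg$res)
  nbch <- grid$nbins
  res <- as.double(grid$res)

  # site-containing bins and their sites
  sites_by_bin <- vector("list", grid$total)
  for (ci in seq_along(grid$chroms)) {
    cc <- fmap$cuts[[grid$chroms[ci]]]
    if (!length(cc)) next
    bi <- grid$offsets[ci] + floor(cc / res) + 1
    for (b in unique(bi)) sites_by_bin[[b]] <- cc[bi == b]
  }
  elig <- !vapply(sites_by_bin, is.null, logical(1))

  bias <- stats::rlnorm(grid$total, -cfg$bias_sigma^2 / 2, cfg$bias_sigma)
  if (cfg$bias_sigma == 0) bias <- rep(1, grid$total)

  # planted domain lookup: domain id per bin (0 = none)
  dom_id <- integer(grid$total)
  if (!is.null(cfg$domains) && nrow(cfg$domains)) {
    for (r in seq_len(nrow(cfg$domains))) {
      b1 <- bin_index(grid, cfg$domains$chrom[r], cfg$domains$start[r])
      b2 <- bin_index(grid, cfg$domains$chrom[r],
                      min(cfg$domains$end[r] - 1,
                          grid$lengths[cfg$domains$chrom[r]] - 1))
      dom_id[b1:b2] <- r
    }
  }
  dom_fac <- function(i, j) {
    f <- rep(1, length(i))
    same <- dom_id[i] > 0 & dom_id[i] == dom_id[j]
    if (any(same)) f[same] <- cfg$domains$ratio[dom_id[i[same]]]
    f
  }
  max_dom <- if (!is.null(cfg$domains) && nrow(cfg$domains))
    max(1, cfg$domains$ratio) else 1
  bmax2 <- max(bias)^2 * max_dom

  kmin <- max(2L, as.integer(ceiling(cfg$d_min / res)))
  f0 <- function(d) .decay_f0(d, cfg$alpha_short, cfg$alpha_long,
                              cfg$breakpoint)

  # per-chromosome proposal weights over separations
  kmax_ch <- pmin(as.integer(floor(cfg$d_max / res)), nbch - 1L)
  kw <- lapply(seq_along(grid$chroms), function(ci) {
    if (kmax_ch[ci] < kmin) return(numeric(0))
    k <- kmin:kmax_ch[ci]
    f0(k * res) * (nbch[ci] - k)
  })
  chrom_w <- vapply(kw, sum, numeric(1))
  if (all(chrom_w == 0)) stop("no admissible cis separations; check d_min/d_max")

  n_art <- round(cfg$n_ditags * c(self = cfg$frac_self_ligation,
                                  nond = cfg$frac_non_digested,
                                  circ = cfg$frac_circularized,
                                  nosite = cfg$frac_no_site))
  n_bg <- cfg$n_ditags - sum(n_art)
  n_trans <- round(n_bg * cfg$trans_frac)
  n_cis <- n_bg - n_trans

  sample_cis <- function(n_needed) {
    out_i <- integer(0); out_j <- integer(0)
    while (length(out_i) < n_needed) {
      b <- ceiling((n_needed - length(out_i)) * 2.5 / max(0.3, mean(elig)^2))
      b <- min(b, 5e6)
      ch <- sample.int(length(grid$chroms), b, replace = TRUE,
                       prob = chrom_w)
      k <- integer(b)
      for (ci in unique(ch)) {
        s <- ch == ci
        k[s] <- (kmin:kmax_ch[ci])[sample.int(length(kw[[ci]]), sum(s),
                                              replace = TRUE, prob = kw[[ci]])]
      }
      i0 <- floor(stats::runif(b) * (nbch[ch] - k)) + 1
      gi <- as.integer(grid$offsets[ch] + i0)
      gj <- gi + k
      acc <- elig[gi] & elig[gj] &
        stats::runif(b) < bias[gi] * bias[gj] * dom_fac(gi, gj) / bmax2
      out_i <- c(out_i, gi[acc]); out_j <- c(out_j, gj[acc])
    }
    list(i = out_i[seq_len(n_needed)], j = out_j[seq_len(n_needed)])
  }

  sample_trans <- function(n_needed) {
    if (length(grid$chroms) < 2 && n_needed > 0)
      stop("trans ditags require at least two chromosomes")
    out_i <- integer(0); out_j <- integer(0)
    while (length(out_i) < n_needed) {
      b <- ceiling((n_needed - length(out_i)) * 2.5 / max(0.3, mean(elig)^2))
      b <- min(b, 5e6)
      gi <- sample.int(grid$total, b, replace = TRUE)
      gj <- sample.int(grid$total, b, replace = TRUE)
      diffc <- .bin_chrom_index(grid, gi) != .bin_chrom_index(grid, gj)
      acc <- diffc & elig[gi] & elig[gj] &
        stats::runif(b) < bias[gi] * bias[gj] / bmax2
      out_i <- c(out_i, pmin(gi[acc], gj[acc]))
      out_j <- c(out_j, pmax(gi[acc], gj[acc]))
    }
    list(i = out_i[seq_len(n_needed)], j = out_j[seq_len(n_needed)])
  }

  cis <- sample_cis(n_cis)
  trn <- if (n_trans > 0) sample_trans(n_trans) else list(i = integer(0), j = integer(0))

  # exact cis partition function for expected pair counts
  eb <- bias * elig
  Zc <- 0
  for (ci in seq_along(grid$chroms)) {
    if (kmax_ch[ci] < kmin) next
    v <- eb[grid$offsets[ci] + seq_len(nbch[ci])]
    for (k in kmin:kmax_ch[ci])
      Zc <- Zc + f0(k * res) * sum(v[seq_len(nbch[ci] - k)] *
                                     v[seq_len(nbch[ci] - k) + k])
  }
  if (!is.null(cfg$domains) && nrow(cfg$domains)) {
    for (ci in seq_along(grid$chroms)) {
      off <- grid$offsets[ci]
      ids <- dom_id[off + seq_len(nbch[ci])]
      for (r in unique(ids[ids > 0])) {
        db <- off + which(ids == r)
        if (length(db) < 2) next
        pr <- utils::combn(db, 2)
        k <- pr[2, ] - pr[1, ]
        ok <- k >= kmin & k <= kmax_ch[ci]
        Zc <- Zc + sum((cfg$domains$ratio[r] - 1) *
                         f0(k[ok] * res) * eb[pr[1, ok]] * eb[pr[2, ok]])
      }
    }
  }
  exp_cis_pair <- function(i, j) {
    n_cis * f0((j - i) * res) * bias[i] * bias[j] * dom_fac(i, j) / Zc
  }

  # capture boost: extra independent bait-touching ditags
  bait_bins <- integer(0)
  boost <- list(i = integer(0), j = integer(0))
  mult <- 1
  if (!is.null(cfg$baits) && nrow(cfg$baits) && cfg$capture_boost > 1) {
    mtmp <- mark_enriched_bins(
      bin_contacts(data.frame(chrom1 = character(0), pos1 = numeric(0),
                              chrom2 = character(0), pos2 = numeric(0)),
                   grid), cfg$baits)
    bait_bins <- which(mtmp$bins$enriched & elig)
    n_touch <- sum(cis$i %in% bait_bins | cis$j %in% bait_bins) +
               sum(trn$i %in% bait_bins | trn$j %in% bait_bins)
    q0 <- n_touch / n_bg
    F <- cfg$capture_boost
    if (F * q0 >= 0.9)
      stop("capture boost times on-target fraction too large; shrink baits")
    if (n_touch > 0) {
      mult <- F * (1 - q0) / (1 - F * q0)
      n_extra <- round((mult - 1) * n_touch)
      # candidate bait-touching pairs, weights on the generator's scale
      cand_i <- integer(0); cand_j <- integer(0); cand_w <- numeric(0)
      for (b in bait_bins) {
        ci <- .bin_chrom_index(grid, b)
        o <- b - grid$offsets[ci]
        if (kmax_ch[ci] >= kmin) {
          k <- kmin:kmax_ch[ci]
          up <- o - k; dn <- o + k
          for (side in 1:2) {
            pp <- if (side == 1) up else dn
            okp <- pp >= 1 & pp <= nbch[ci]
            gp <- grid$offsets[ci] + pp[okp]
            okp2 <- elig[gp]
            gp <- gp[okp2]
            kk <- k[okp][okp2]
            ii <- pmin(gp, b); jj <- pmax(gp, b)
            w <- n_cis * f0(kk * res) * bias[ii] * bias[jj] *
                 dom_fac(ii, jj) / Zc
            cand_i <- c(cand_i, ii); cand_j <- c(cand_j, jj); cand_w <- c(cand_w, w)
          }
        }
        other <- which(elig & .bin_chrom_index(grid, seq_len(grid$total)) != ci)
        if (length(other) && n_trans > 0) {
          # trans generator: cross-chromosome pairs weighted by bias;
          # weights rescaled to expected counts after the loop
          cand_i <- c(cand_i, pmin(other, b))
          cand_j <- c(cand_j, pmax(other, b))
          cand_w <- c(cand_w, bias[b] * bias[other])
        }
      }
      # both-bait pairs were added twice; halve their weight
      key <- paste(cand_i, cand_j)
      dupk <- duplicated(key) | duplicated(key, fromLast = TRUE)
      cand_w[dupk & cand_i %in% bait_bins & cand_j %in% bait_bins] <-
        cand_w[dupk & cand_i %in% bait_bins & cand_j %in% bait_bins] / 2
      # rescale trans candidate weights to expected counts
      is_tr <- .bin_chrom_index(grid, cand_i) != .bin_chrom_index(grid, cand_j)
      if (any(is_tr) && n_trans > 0) {
        Zt <- 0
        for (c1 in seq_along(grid$chroms)) {
          v1 <- sum(eb[grid$offsets[c1] + seq_len(nbch[c1])])
          v2 <- sum(eb) - v1
          Zt <- Zt + v1 * v2
        }
        Zt <- Zt / 2
        cand_w[is_tr] <- n_trans * cand_w[is_tr] / Zt
      } else cand_w[is_tr] <- 0
      if (n_extra > 0 && sum(cand_w) > 0) {
        pick <- sample.int(length(cand_w), n_extra, replace = TRUE,
                           prob = cand_w)
        boost <- list(i = cand_i[pick], j = cand_j[pick])
      }
    }
  }

  # planted loops: excess Poisson mass at anchor bin pairs
  loop_tab <- NULL
  loops <- list(i = integer(0), j = integer(0))
  if (!is.null(cfg$loops) && nrow(cfg$loops)) {
    li <- bin_index(grid, cfg$loops$chrom1, cfg$loops$pos1)
    lj <- bin_index(grid, cfg$loops$chrom2, cfg$loops$pos2)
    swap <- lj < li
    tmp <- li[swap]; li[swap] <- lj[swap]; lj[swap] <- tmp
    if (any(!elig[li] | !elig[lj]))
      stop("loop anchors must fall in bins containing restriction sites")
    e_bg <- numeric(length(li))
    for (r in seq_along(li)) {
      cis_anchor <- .bin_chrom_index(grid, li[r]) == .bin_chrom_index(grid, lj[r])
      e <- if (cis_anchor) exp_cis_pair(li[r], lj[r]) else {
        Zt <- 0
        for (c1 in seq_along(grid$chroms)) {
          v1 <- sum(eb[grid$offsets[c1] + seq_len(nbch[c1])])
          Zt <- Zt + v1 * (sum(eb) - v1)
        }
        n_trans * bias[li[r]] * bias[lj[r]] / (Zt / 2)
      }
      bfac <- if (li[r] %in% bait_bins || lj[r] %in% bait_bins) mult else 1
      e_bg[r] <- e * bfac
      extra <- stats::rpois(1, (cfg$loops$fold[r] - 1) * e_bg[r])
      loops$i <- c(loops$i, rep(li[r], extra))
      loops$j <- c(loops$j, rep(lj[r], extra))
    }
    loop_tab <- data.frame(bin1 = li, bin2 = lj, fold = cfg$loops$fold,
                           expected_bg = e_bg)
  }

  all_i <- c(cis$i, trn$i, boost$i, loops$i)
  all_j <- c(cis$j, trn$j, boost$j, loops$j)
  label <- c(rep("background", length(cis$i)),
             rep("background_trans", length(trn$i)),
             rep("capture_boost", length(boost$i)),
             rep("loop", length(loops$i)))

  pos1 <- .materialize_positions(all_i, grid, sites_by_bin)
  pos2 <- .materialize_positions(all_j, grid, sites_by_bin)
  bc_all <- grid$chroms[.bin_chrom_index(grid, all_i)]
  bc_all2 <- grid$chroms[.bin_chrom_index(grid, all_j)]
  strand1 <- sample(c("+", "-"), length(all_i), replace = TRUE)
  strand2 <- sample(c("+", "-"), length(all_j), replace = TRUE)
  # guard rare same/adjacent-fragment geometry on cis pairs
  same_ch <- bc_all == bc_all2
  if (any(same_ch)) {
    fr1 <- fragment_of(fmap, bc_all[same_ch], pos1[same_ch])
    fr2 <- fragment_of(fmap, bc_all2[same_ch], pos2[same_ch])
    dfr <- abs(fr2 - fr1)
    adj <- which(same_ch)[dfr == 1L]
    sam <- which(same_ch)[dfr == 0L]
    strand1[adj] <- "+"; strand2[adj] <- "-"   # adjacent inward: kept valid
    strand1[sam] <- "+"; strand2[sam] <- "+"   # tandem: never an artifact
  }

  df <- data.frame(chrom1 = bc_all, pos1 = pos1, strand1 = strand1,
                   chrom2 = bc_all2, pos2 = pos2, strand2 = strand2,
                   stringsAsFactors = FALSE)

  art <- .simulate_artifacts(cfg, fmap, grid, sites_by_bin, elig, n_art)
  df <- rbind(df, art$df)
  label <- c(label, art$label)

  # PCR duplicates of already-emitted ditags
  if (cfg$frac_duplicate > 0 && nrow(df) > 0) {
    n_dup <- round(cfg$frac_duplicate / (1 - cfg$frac_duplicate) * nrow(df))
    pick <- sample.int(nrow(df), n_dup, replace = TRUE)
    df <- rbind(df, df[pick, ])
    label <- c(label, rep("duplicate", n_dup))
  }

  ord <- sample.int(nrow(df))
  df <- df[ord, ]; label <- label[ord]
  out <- data.frame(read_id = sprintf("sim%09d", seq_len(nrow(df))),
                    chrom1 = df$chrom1, pos1 = df$pos1, strand1 = df$strand1,
                    mapq1 = 60L,
                    chrom2 = df$chrom2, pos2 = df$pos2, strand2 = df$strand2,
                    mapq2 = 60L, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(ditags = out,
       truth = list(label = label, bias = bias, loops = loop_tab,
                    domains = cfg$domains, bait_bins = bait_bins,
                    grid = grid, boost_multiplicity = mult,
                    n_background = n_bg))
}

# artifact ditags with the exact geometry of each class
.simulate_artifacts <- function(cfg, fmap, grid, sites_by_bin, elig, n_art) {
  empty <- data.frame(chrom1 = character(0), pos1 = numeric(0),
                      strand1 = character(0), chrom2 = character(0),
                      pos2 = numeric(0), strand2 = character(0),
                      stringsAsFactors = FALSE)
  if (sum(n_art) == 0) return(list(df = empty, label = character(0)))
  # interior fragments (both boundaries are genuine cuts), length >= 200
  frs <- fragments(fmap)
  interior <- unlist(lapply(names(fmap$cuts), function(ch) {
    w <- which(frs$chrom == ch)
    if (length(w) > 2) w[-c(1, length(w))] else integer(0)
  }))
  interior <- interior[frs$end[interior] - frs$start[interior] >= 200]
  if (!length(interior) && sum(n_art[c("self", "nond", "circ")]) > 0)
    stop("no interior fragments long enough for artifact simulation")
  draw_same_frag <- function(n, strands) {
    f <- interior[sample.int(length(interior), n, replace = TRUE)]
    len <- frs$end[f] - frs$start[f]
    u1 <- 1 + floor(stats::runif(n) * pmin(400, len / 3))
    u2 <- 1 + floor(stats::runif(n) * pmin(400, len / 3))
    data.frame(chrom1 = frs$chrom[f], pos1 = frs$start[f] + u1,
               strand1 = strands[1],
               chrom2 = frs$chrom[f], pos2 = frs$end[f] - u2,
               strand2 = strands[2], stringsAsFactors = FALSE)
  }
  dfs <- list(); labs <- character(0)
  if (n_art["self"] > 0) {
    dfs <- c(dfs, list(draw_same_frag(n_art["self"], c("-", "+"))))
    labs <- c(labs, rep("self_ligation", n_art["self"]))
  }
  if (n_art["nond"] > 0) {
    dfs <- c(dfs, list(draw_same_frag(n_art["nond"], c("+", "-"))))
    labs <- c(labs, rep("non_digested", n_art["nond"]))
  }
  if (n_art["circ"] > 0) {
    # adjacent interior fragment pairs
    adjpool <- interior[(interior + 1L) %in% interior]
    if (!length(adjpool)) stop("no adjacent interior fragment pairs")
    f <- adjpool[sample.int(length(adjpool), n_art["circ"], replace = TRUE)]
    len1 <- frs$end[f] - frs$start[f]
    len2 <- frs$end[f + 1L] - frs$start[f + 1L]
    u1 <- 1 + floor(stats::runif(n_art["circ"]) * pmin(400, len1 / 2))
    u2 <- 1 + floor(stats::runif(n_art["circ"]) * pmin(400, len2 / 2))
    dfs <- c(dfs, list(data.frame(
      chrom1 = frs$chrom[f], pos1 = frs$start[f] + u1, strand1 = "-",
      chrom2 = frs$chrom[f + 1L], pos2 = frs$end[f + 1L] - u2, strand2 = "+",
      stringsAsFactors = FALSE)))
    labs <- c(labs, rep("circularized", n_art["circ"]))
  }
  if (n_art["nosite"] > 0) {
    # positions > 800 bp from every cut: centres of long inter-site gaps
    gap_ch <- character(0); gap_lo <- numeric(0); gap_hi <- numeric(0)
    for (ch in names(fmap$cuts)) {
      cc <- fmap$cuts[[ch]]
      if (length(cc) < 2) next
      gl <- diff(cc)
      w <- which(gl > 2200)
      gap_ch <- c(gap_ch, rep(ch, length(w)))
      gap_lo <- c(gap_lo, cc[w] + 801)
      gap_hi <- c(gap_hi, cc[w + 1] - 801)
    }
    if (!length(gap_ch))
      stop("no inter-site gap long enough for no-site artifact simulation")
    g <- sample.int(length(gap_ch), n_art["nosite"], replace = TRUE)
    p1 <- gap_lo[g] + floor(stats::runif(n_art["nosite"]) *
                              (gap_hi[g] - gap_lo[g] + 1))
    # partner end: ordinary near-site end
    pb <- which(elig)[sample.int(sum(elig), n_art["nosite"], replace = TRUE)]
    p2 <- .materialize_positions(pb, grid, sites_by_bin)
    dfs <- c(dfs, list(data.frame(
      chrom1 = gap_ch[g], pos1 = p1,
      strand1 = sample(c("+", "-"), n_art["nosite"], replace = TRUE),
      chrom2 = grid$chroms[.bin_chrom_index(grid, pb)], pos2 = p2,
      strand2 = sample(c("+", "-"), n_art["nosite"], replace = TRUE),
      stringsAsFactors = FALSE)))
    labs <- c(labs, rep("no_site", n_art["nosite"]))
  }
  list(df = do.call(rbind, dfs), label = labs)
}
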