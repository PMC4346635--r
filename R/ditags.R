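#' Read a pairs-style ditag table
#'
#' Tab-delimited, one ditag per line:
#' readID, chrom1, pos1, strand1, mapq1, chrom2, pos2, strand2, mapq2.
#' Positions are 0-based 5' alignment starts.
#'
#' @param path File path.
#' @return data.frame of ditags.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("read_id", "chrom1", "pos1", "strand1",
                                        "mapq1", "chrom2", "pos2", "strand2",
                                        "mapq2"))
  df
}

#' Write a pairs-style ditag table
#' @param ditags data.frame of ditags.
#' @param path Output path.
#' @export
write_pairs <- function(ditags, path) {
  cols <- c("read_id", "chrom1", "pos1", "strand1", "mapq1",
            "chrom2", "pos2", "strand2", "mapq2")
  utils::write.table(ditags[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# canonical end order: lower (chrom, pos) end first
.canonicalize_ditags <- function(d) {
  swap <- d$chrom2 < d$chrom1 | (d$chrom1 == d$chrom2 & d$pos2 < d$pos1)
  if (any(swap)) {
    for (f in c("chrom", "pos", "strand", "mapq")) {
      a <- paste0(f, "1"); b <- paste0(f, "2")
      tmp <- d[[a]][swap]
      d[[a]][swap] <- d[[b]][swap]
      d[[b]][swap] <- tmp
    }
  }
  d
}

#' Assemble aligned read ends into ditags
#'
#' Pairs single-end alignment records by read id, keeps only pairs where
#' both ends exceed the mapping-quality threshold (strict inequality, the
#' conventional MAPQ>30 unique-alignment filter), and orders the two ends
#' canonically (lower (chrom, pos) first).
#'
#' @param alignments data.frame with columns read_id, chrom, pos, strand,
#'   mapq — one row per aligned end. Each read id may appear at most twice.
#' @param mapq_min Both ends must satisfy mapq > mapq_min. Default 30.
#' @return list(ditags = data.frame, counts = c(input_reads, singleton,
#'   sub_mapq, paired)).
#' @export
assemble_ditags <- function(alignments, mapq_min = 30) {
  stopifnot(all(c("read_id", "chrom", "pos", "strand", "mapq") %in%
                names(alignments)))
  tab <- table(alignments$read_id)
  if (any(tab > 2))
    stop("malformed input: read id(s) with >2 aligned ends: ",
         paste(utils::head(names(tab)[tab > 2], 3), collapse = ", "))
  singles <- names(tab)[tab == 1]
  al <- alignments[order(match(alignments$read_id, names(tab))), ]
  paired <- al[al$read_id %in% names(tab)[tab == 2], ]
  n2 <- nrow(paired) / 2
  if (n2 > 0) {
    e1 <- paired[seq(1, nrow(paired), by = 2), ]
    e2 <- paired[seq(2, nrow(paired), by = 2), ]
    d <- data.frame(read_id = e1$read_id,
                    chrom1 = e1$chrom, pos1 = e1$pos,
                    strand1 = e1$strand, mapq1 = e1$mapq,
                    chrom2 = e2$chrom, pos2 = e2$pos,
                    strand2 = e2$strand, mapq2 = e2$mapq,
                    stringsAsFactors = FALSE)
    keep <- d$mapq1 > mapq_min & d$mapq2 > mapq_min
    sub_mapq <- sum(!keep)
    d <- .canonicalize_ditags(d[keep, , drop = FALSE])
  } else {
    d <- data.frame()
    sub_mapq <- 0L
  }
  list(ditags = d,
       counts = c(input_reads = nrow(alignments),
                  singleton = length(singles),
                  sub_mapq = sub_mapq,
                  paired = if (is.null(nrow(d))) 0L else nrow(d)))
}

#' Remove PCR duplicates
#'
#' Ditags identical on chromosome, position and strand of both canonically
#' ordered ends collapse to the first-encountered representative.
#'
#' @param ditags data.frame of canonically ordered ditags.
#' @return list(ditags, n_duplicates).
#' @export
remove_duplicates <- function(ditags) {
  if (nrow(ditags) == 0) return(list(ditags = ditags, n_duplicates = 0L))
  d <- .canonicalize_ditags(ditags)
  key <- paste(d$chrom1, d$pos1, d$strand1, d$chrom2, d$pos2, d$strand2,
               sep = "\r")
  dup <- duplicated(key)
  list(ditags = d[!dup, , drop = FALSE], n_duplicates = sum(dup))
}

#' Classify experimental-background ditags
#'
#' Deterministic rule table over read orientation and restriction-site
#' geometry, applied to canonically ordered ends (end 1 upstream):
#' \itemize{
#'   \item \code{no_site}: either end farther than \code{max_site_distance}
#'     from any cut site — the sonication fragment cannot reach a ligation
#'     junction;
#'   \item same fragment, inward (+/−): \code{non_digested};
#'   \item same fragment, outward (−/+): \code{self_ligation};
#'   \item adjacent fragments, outward: \code{circularized};
#'   \item everything else: \code{valid}.
#' }
#' Inter-chromosomal ditags can only be \code{no_site} or \code{valid}.
#'
#' @param ditags data.frame of ditags.
#' @param fmap A \code{fragment_map}.
#' @param max_site_distance Bases; default 800 (sonication peak ~500 bp).
#' @return Character vector of categories, one per ditag.
#' @export
classify_artifact <- function(ditags, fmap, max_site_distance = 800) {
  n <- nrow(ditags)
  if (n == 0) return(character(0))
  d <- .canonicalize_ditags(ditags)
  dist1 <- nearest_site_distance(fmap, d$chrom1, d$pos1)
  dist2 <- nearest_site_distance(fmap, d$chrom2, d$pos2)
  cat <- rep("valid", n)
  same_chrom <- d$chrom1 == d$chrom2
  frag1 <- frag2 <- rep(NA_integer_, n)
  if (any(same_chrom)) {
    frag1[same_chrom] <- fragment_of(fmap, d$chrom1[same_chrom],
                                     d$pos1[same_chrom])
    frag2[same_chrom] <- fragment_of(fmap, d$chrom2[same_chrom],
                                     d$pos2[same_chrom])
  }
  # end 1 is upstream after canonical ordering
  inward  <- d$strand1 == "+" & d$strand2 == "-"
  outward <- d$strand1 == "-" & d$strand2 == "+"
  same_frag <- same_chrom & frag1 == frag2
  adj_frag  <- same_chrom & abs(frag2 - frag1) == 1L
  cat[same_frag & inward]  <- "non_digested"
  cat[same_frag & outward] <- "self_ligation"
  cat[adj_frag & outward]  <- "circularized"
  cat[dist1 > max_site_distance | dist2 > max_site_distance] <- "no_site"
  cat
}

#' Filter a ditag stream down to bona fide Hi-C contacts
#'
#' Removes PCR duplicates, classifies the remainder against the artifact
#' rule table, and keeps only \code{valid} ditags. The report's categories
#' are disjoint and sum to the input count.
#'
#' @param ditags data.frame of ditags (MAPQ-filtered).
#' @param fmap A \code{fragment_map}.
#' @param max_site_distance Passed to \code{\link{classify_artifact}}.
#' @return list(ditags, report) where report is a named integer vector with
#'   entries input, duplicates, self_ligation, non_digested, circularized,
#'   no_site, valid.
#' @export
filter_bona_fide <- function(ditags, fmap, max_site_distance = 800) {
  n_in <- nrow(ditags)
  dd <- remove_duplicates(ditags)
  cat <- classify_artifact(dd$ditags, fmap, max_site_distance)
  report <- c(input = n_in,
              duplicates = dd$n_duplicates,
              self_ligation = sum(cat == "self_ligation"),
              non_digested = sum(cat == "non_digested"),
              circularized = sum(cat == "circularized"),
              no_site = sum(cat == "no_site"),
              valid = sum(cat == "valid"))
  list(ditags = dd$ditags[cat == "valid", , drop = FALSE], report = report)
}
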