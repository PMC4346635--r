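#' Read a BED file
#'
#' Minimal BED reader: tab-separated, 0-based half-open, optional name and
#' score columns. Track/browser lines and comments are skipped.
#'
#' @param path File path.
#' @param extra_names Names for columns beyond chrom/start/end, e.g.
#'   c("name", "score").
#' @return data.frame with chrom, start, end and any extra columns.
#' @export
read_bed <- function(path, extra_names = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end")
  extra <- if (ncol(df) > 3) {
    if (!is.null(extra_names)) extra_names[seq_len(ncol(df) - 3)]
    else paste0("V", 4:ncol(df))
  } else character(0)
  names(df) <- c(base, extra)
  df
}

#' Read a bedGraph track
#' @param path File path.
#' @return data.frame chrom, start, end, score.
#' @export
read_bedgraph <- function(path) {
  df <- read_bed(path, extra_names = "score")
  if (!"score" %in% names(df)) stop("bedGraph needs a fourth (score) column")
  df$score <- as.numeric(df$score)
  df
}

#' Write intervals as BED
#' @param df data.frame with chrom, start, end and optional further columns.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a fragment map as BED
#' @param fmap A \code{fragment_map}.
#' @param path Output path.
#' @export
write_fragments_bed <- function(fmap, path) {
  write_bed(fragments(fmap), path)
}

#' Write a directionality track as bedGraph
#' @param dix A \code{dix_track}.
#' @param path Output path.
#' @export
write_dix_bedgraph <- function(dix, path) {
  write_bed(data.frame(dix$chrom, dix$start, dix$end, signif(dix$D, 6)), path)
}

#' Write a contact matrix as a COO-style TSV
#'
#' Columns: bin_i, bin_j, raw count, and any normalized columns present.
#'
#' @param m A \code{contact_matrix}.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  cc <- m$counts
  cols <- intersect(c("i", "j", "raw", "n", "norm"), names(cc))
  utils::write.table(cc[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the per-bin annotation table as TSV
#' @param m A \code{contact_matrix}.
#' @param path Output path.
#' @export
write_bin_table <- function(m, path) {
  utils::write.table(m$bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
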