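#' Pipeline configuration
#'
#' Paths and thresholds driving \code{\link{run_pipeline}}. Every threshold
#' default is the value the analysis is designed around: MAPQ > 30,
#' maximum 800 bp to the nearest restriction site, mean bin mapability
#' > 0.5, FDR 0.05, minimum call separation 10 kb, 10 Mb working window,
#' 9 kb genome-wide resolution with an optional 3 kb close-cis pass
#' restricted to within 5 Mb of the capture targets.
#'
#' @param genome Path to a FASTA file.
#' @param pairs Path(s) to pairs-style ditag tables, one per library.
#' @param baits Path to a BED file of capture targets.
#' @param outdir Output directory.
#' @param mapability Optional bedGraph path.
#' @param pattern,cut_offset Restriction enzyme definition.
#' @param res Primary (genome-wide) resolution.
#' @param res_close Close-cis resolution; NULL disables the second pass.
#' @param close_cis_margin Half-width of the close-cis region around baits.
#' @param mapq_min,max_site_distance,mapability_min,fdr,min_sep,window,tol,
#'   max_iter Stage thresholds.
#' @param dix_window Directionality window for domain calling.
#' @param seed Seed for any stochastic step.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(genome, pairs, baits, outdir,
                            mapability = NULL,
                            pattern = "AAGCTT", cut_offset = 1L,
                            res = 9000, res_close = NULL,
                            close_cis_margin = 5e6,
                            mapq_min = 30, max_site_distance = 800,
                            mapability_min = 0.5,
                            fdr = 0.05, min_sep = 1e4, window = 1e7,
                            tol = 1e-3, max_iter = 100,
                            dix_window = 495000, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full capture Hi-C pipeline
#'
#' digest -> filter -> bin -> bias-correct -> distance-normalize ->
#' call interactions -> call domains, writing every stage product under
#' \code{cfg$outdir} and returning a manifest. Any stage failure aborts
#' with the stage name.
#'
#' @param cfg A \code{pipeline_config}.
#' @return Manifest list (inputs, parameters, per-stage outputs, seed),
#'   also written as \code{manifest.json} in the output directory.
#' @export
run_pipeline <- function(cfg) {
  for (p in c(cfg$genome, cfg$pairs, cfg$baits))
    if (!file.exists(p)) stop("input file not found: ", p)
  if (!is.null(cfg$mapability) && !file.exists(cfg$mapability))
    stop("input file not found: ", cfg$mapability)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  manifest <- list(inputs = cfg[c("genome", "pairs", "baits", "mapability")],
                   parameters = cfg[setdiff(names(cfg),
                                            c("genome", "pairs", "baits",
                                              "mapability", "outdir"))],
                   outputs = list(), stages = character(0))
  stage <- function(name, expr) {
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    out
  }

  fmap <- stage("digest", {
    fm <- digest_genome(cfg$genome, cfg$pattern, cfg$cut_offset)
    write_fragments_bed(fm, file.path(cfg$outdir, "fragments.bed"))
    fm
  })
  baits <- read_bed(cfg$baits)
  mapab <- if (!is.null(cfg$mapability)) read_bedgraph(cfg$mapability) else NULL
  grid <- bin_grid(fmap$seqlengths, cfg$res)
  bins <- annotate_bins(grid, fmap, mapab)

  libs <- stage("filter", {
    lapply(seq_along(cfg$pairs), function(L) {
      raw <- read_pairs(cfg$pairs[L])
      keep <- raw$mapq1 > cfg$mapq_min & raw$mapq2 > cfg$mapq_min
      fb <- filter_bona_fide(raw[keep, , drop = FALSE], fmap,
                             cfg$max_site_distance)
      rep_path <- file.path(cfg$outdir, sprintf("filter_report_L%d.tsv", L))
      utils::write.table(data.frame(category = names(fb$report),
                                    count = as.integer(fb$report)),
                         rep_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      fb
    })
  })

  mats <- stage("bin", {
    lapply(seq_along(libs), function(L) {
      m <- bin_contacts(libs[[L]]$ditags, grid, bins)
      m <- mark_enriched_bins(m, baits)
      m <- filter_valid_bins(m, cfg$mapability_min)
      write_bin_table(m, file.path(cfg$outdir, sprintf("bins_L%d.tsv", L)))
      m
    })
  })

  mats <- stage("normalize", {
    lapply(seq_along(mats), function(L) {
      m <- iterative_bias_correct(mats[[L]], tol = cfg$tol,
                                  max_iter = cfg$max_iter)
      tmpl <- estimate_distance_template(m)
      utils::write.table(tmpl$profile,
                         file.path(cfg$outdir,
                                   sprintf("distance_template_L%d.tsv", L)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      m <- distance_normalize(m, tmpl)
      write_matrix_tsv(m, file.path(cfg$outdir,
                                    sprintf("matrix_L%d.tsv", L)))
      m
    })
  })

  calls <- stage("call", {
    cl <- call_interactions(mats, fdr = cfg$fdr, min_sep = cfg$min_sep,
                            window = cfg$window)
    write_interactions_bedpe(cl, file.path(cfg$outdir, "interactions.bedpe"))
    cl
  })

  doms <- stage("domains", {
    dix <- directionality_index(mats[[1]], window = cfg$dix_window)
    write_dix_bedgraph(dix, file.path(cfg$outdir, "dix.bedgraph"))
    dd <- call_domains(dix)
    write_bed(as.data.frame(dd), file.path(cfg$outdir, "domains.bed"))
    dd
  })

  manifest$outputs <- list(
    fragments = "fragments.bed",
    filter_reports = sprintf("filter_report_L%d.tsv", seq_along(libs)),
    matrices = sprintf("matrix_L%d.tsv", seq_along(mats)),
    interactions = "interactions.bedpe",
    domains = "domains.bed")
  manifest$n_calls <- nrow(calls)
  manifest$n_shared <- sum(calls$shared)
  manifest$n_domains <- nrow(doms)
  manifest$seed <- cfg$seed
  outfiles <- list.files(cfg$outdir, pattern = "\\.(bed|tsv|bedpe|bedgraph)$",
                         full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(outfiles))
  names(manifest$checksums) <- basename(outfiles)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
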