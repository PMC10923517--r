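# End-to-end orchestration: one configuration object drives
# filter -> DE calls -> annotate -> intersect -> network -> enrich, writing
# every result table plus a machine-readable run manifest. Identical
# configuration and seed give byte-identical outputs.

CONFIG_DEFAULTS <- list(
  cpm_threshold = 0.5, min_libraries = 2L, fdr_threshold = 0.05,
  tss_window = 10000L, promoter_window = 3000L, motif_window = 50L,
  tss_half_width = 5000L, bin = 100L,
  nearest_only = FALSE, seed = 1L)

#' Build a pipeline configuration
#'
#' Thresholds default to the conventions used throughout the package: genes
#' are expressed at >= 0.5 CPM in >= 2 libraries, differential expression is
#' called at FDR <= 0.05, peaks annotate genes within 10 kb of the TSS with
#' a 3 kb putative-promoter radius, motif windows are +/- 50 bp, and the
#' TSS binding comparison spans +/- 5 kb in 100 bp bins.
#'
#' @param paths named list of input paths: \code{genes}, \code{counts},
#'   \code{peaks_a}, \code{peaks_b}, \code{de_a}, \code{de_b}; optional
#'   \code{gene_sets}, \code{coverage_a}, \code{coverage_b}.
#' @param tfs length-2 factor labels (attached to the two peak files).
#' @param out_dir output directory.
#' @param ... threshold overrides (see defaults above).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(paths, tfs = c("TF_A", "TF_B"), out_dir = "results", ...) {
  over <- list(...)
  bad <- setdiff(names(over), names(CONFIG_DEFAULTS))
  if (length(bad)) stopf("unknown configuration key '%s'", bad[1L])
  cfg <- utils::modifyList(CONFIG_DEFAULTS, over)
  for (k in c("cpm_threshold", "min_libraries", "fdr_threshold", "tss_window",
              "promoter_window", "motif_window", "tss_half_width", "bin"))
    check_positive(cfg[[k]], k)
  required <- c("genes", "counts", "peaks_a", "peaks_b", "de_a", "de_b")
  miss <- setdiff(required, names(paths))
  if (length(miss)) stopf("configuration is missing input path '%s'", miss[1L])
  if (length(tfs) != 2L || tfs[1L] == tfs[2L]) stopf("'tfs' must be two distinct labels")
  structure(c(list(paths = paths, tfs = as.character(tfs), out_dir = out_dir), cfg),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (k in names(CONFIG_DEFAULTS))
    cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  cat(sprintf("  %-16s %s + %s\n", "tfs", x$tfs[1L], x$tfs[2L]))
  for (k in names(x$paths)) cat(sprintf("  path %-12s %s\n", k, x$paths[[k]]))
  invisible(x)
}

#' Write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration written by [write_config()]
#'
#' The round-trip is lossless: \code{read_config(write_config(x))} equals
#' \code{x}.
#' @param path YAML path.
#' @return a \code{pipeline_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- yaml::read_yaml(path)
  over <- x[names(CONFIG_DEFAULTS)]
  over <- over[!vapply(over, is.null, TRUE)]
  for (k in c("min_libraries", "tss_window", "promoter_window", "motif_window",
              "tss_half_width", "bin", "seed"))
    if (!is.null(over[[k]])) over[[k]] <- as.integer(over[[k]])
  do.call(pipeline_config,
          c(list(paths = x$paths, tfs = x$tfs, out_dir = x$out_dir), over))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full co-regulated network pipeline
#'
#' Executes, in order: expression filtering, DE calling and Venn
#' partitioning of the two contrasts, peak-to-TSS annotation for both
#' factors, the dual-bound/dual-down intersection, network construction and
#' export (GraphML, SIF, TSV), and — when gene sets are supplied — the
#' hypergeometric enrichment of network members against the
#' expression-filtered universe. A run manifest (YAML) records the
#' configuration hash, seed, package version, and per-stage counts; with an
#' identical configuration the TSV/GraphML outputs are byte-identical
#' across runs. An empty bound or co-regulated set is a warning with stage
#' statistics, never a silent success.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, list with the result objects (\code{network},
#'   \code{venn}, \code{coregulated}, \code{enrichment}, \code{manifest})
#'   and \code{files} (paths written).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stopf("'config' must be a pipeline_config")
  for (k in names(config$paths)) {
    if (!file.exists(config$paths[[k]]))
      stopf("input file for config key '%s' not found: %s", k, config$paths[[k]])
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  genes <- run_stage("read_genes", read_gene_models(config$paths$genes, "gtf"))
  counts <- run_stage("read_counts", read_counts(config$paths$counts))
  peaks_a <- run_stage("read_peaks_a",
                       read_peaks(config$paths$peaks_a, "narrowPeak", tf = config$tfs[1L]))
  peaks_b <- run_stage("read_peaks_b",
                       read_peaks(config$paths$peaks_b, "narrowPeak", tf = config$tfs[2L]))
  de_a <- run_stage("read_de_a", read_de_table(config$paths$de_a,
                    columns = c(gene_id = "gene_id", logfc = "logfc", fdr = "fdr")))
  de_b <- run_stage("read_de_b", read_de_table(config$paths$de_b,
                    columns = c(gene_id = "gene_id", logfc = "logfc", fdr = "fdr")))

  expressed <- run_stage("filter_expressed",
                         filter_expressed(counts, config$cpm_threshold, config$min_libraries))
  universe <- rownames(expressed)

  # DE status is only defined on expressed genes
  calls_a <- run_stage("call_de",
                       call_de(de_a[de_a$gene_id %in% universe, ], config$fdr_threshold))
  calls_b <- run_stage("call_de",
                       call_de(de_b[de_b$gene_id %in% universe, ], config$fdr_threshold))
  venn <- venn_partition(calls_a, calls_b)

  index <- tss_index(genes)
  ann_a <- run_stage("annotate", annotate_peaks(peaks_a, index, config$tss_window,
                                                config$promoter_window, config$nearest_only))
  ann_b <- run_stage("annotate", annotate_peaks(peaks_b, index, config$tss_window,
                                                config$promoter_window, config$nearest_only))
  annotations <- rbind(ann_a, ann_b)
  bound_a <- genes_bound(annotations, config$tfs[1L])
  bound_b <- genes_bound(annotations, config$tfs[2L])
  if (!length(bound_a) || !length(bound_b))
    warnf("empty bound set (%s: %d genes, %s: %d genes): network will be empty",
          config$tfs[1L], length(bound_a), config$tfs[2L], length(bound_b))

  called <- call_coregulated(venn$down_both, bound_a, bound_b)
  if (!length(called$coregulated))
    warnf("no co-regulated genes (down_both = %d, bound_both = %d)",
          length(venn$down_both), length(called$bound_both))
  net <- run_stage("network",
                   coreg_network(called$coregulated, annotations, de_a, de_b,
                                 tfs = config$tfs))

  enrichment <- NULL
  if (!is.null(config$paths$gene_sets)) {
    sets <- run_stage("read_gene_sets", read_gmt(config$paths$gene_sets))
    enrichment <- run_stage("enrich",
                            gene_set_enrichment(intersect(called$coregulated, universe),
                                                universe, sets))
  }

  files <- list(
    targets = file.path(out, "targets.tsv"),
    venn = file.path(out, "venn.tsv"),
    coregulated = file.path(out, "coregulated.tsv"),
    network_graphml = file.path(out, "network.graphml"),
    network_sif = file.path(out, "network.sif"),
    network_tsv = file.path(out, "network_edges.tsv"),
    manifest = file.path(out, "manifest.yaml"))
  write_targets(annotations, files$targets)
  venn_df <- data.frame(category = names(venn$sizes), size = unname(venn$sizes),
                        genes = vapply(names(venn$sizes), function(k)
                          paste(sort(venn[[k]]), collapse = ","), character(1)),
                        stringsAsFactors = FALSE)
  utils::write.table(venn_df, files$venn, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = called$coregulated), files$coregulated,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(net, files$network_graphml, "graphml")
  write_network(net, files$network_sif, "sif")
  write_network(net, files$network_tsv, "tsv")
  if (!is.null(enrichment)) {
    files$enrichment <- file.path(out, "enrichment.tsv")
    utils::write.table(enrichment, files$enrichment, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  cfg_tmp <- tempfile(fileext = ".yaml")
  write_config(config, cfg_tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tfcoreg")),
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    seed = config$seed,
    stage_counts = list(
      genes = nrow(genes), expressed = length(universe),
      peaks_a = nrow(peaks_a), peaks_b = nrow(peaks_b),
      annotations = nrow(annotations),
      bound_a = length(bound_a), bound_b = length(bound_b),
      down_both = length(venn$down_both),
      coregulated = length(called$coregulated),
      edges = nrow(net$edges),
      enriched_sets_tested = if (is.null(enrichment)) 0L else nrow(enrichment)))
  unlink(cfg_tmp)
  yaml::write_yaml(manifest, files$manifest)

  invisible(list(network = net, venn = venn, coregulated = called,
                 enrichment = enrichment, annotations = annotations,
                 universe = universe, manifest = manifest, files = files))
}
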