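# Co-regulated target calling and the dual-TF regulatory network.
#
# Network membership rule: a gene belongs to the co-regulated network iff it
# is down-regulated upon deletion of BOTH factors (FDR <= 0.05 in each
# contrast independently) AND bound by both factors within the annotation
# window. The network is bipartite: two TF nodes, one node per target gene,
# and one edge per (TF, gene, peak) annotation, attributed with the target
# class, the signed summit-to-TSS distance, and the gene's per-contrast
# logFC/FDR.

#' Call co-regulated target genes
#'
#' \code{down_both} intersected with both bound sets. The pairwise partial
#' intersections are reported for diagnostics (how much each condition
#' cuts).
#'
#' @param down_both genes down-regulated in both knockout contrasts.
#' @param bound_a,bound_b genes bound by each factor ([genes_bound()]).
#' @return list: \code{coregulated} plus the pairwise intersections
#'   \code{down_and_bound_a}, \code{down_and_bound_b}, \code{bound_both}.
#' @export
call_coregulated <- function(down_both, bound_a, bound_b) {
  list(coregulated = sort(intersect(intersect(down_both, bound_a), bound_b)),
       down_and_bound_a = sort(intersect(down_both, bound_a)),
       down_and_bound_b = sort(intersect(down_both, bound_b)),
       bound_both = sort(intersect(bound_a, bound_b)))
}

most_specific_class <- function(classes) {
  TARGET_CLASSES[min(match(classes, TARGET_CLASSES))]
}

#' Build the dual-TF co-regulated network
#'
#' Constructor for the central result object: a bipartite network of the two
#' transcription factors and their co-regulated target genes. Every target
#' gene must carry at least one annotation from EACH factor (that is the
#' membership definition; a violation is an error, not a warning). All
#' (TF, gene, peak) edges are kept; the most specific class across a gene's
#' peaks (promoter > proximal > putative_promoter > putative_distal) is
#' recorded as the gene-level class.
#'
#' @param coregulated character vector of co-regulated gene ids
#'   (from [call_coregulated()]).
#' @param annotations annotation data frame ([annotate_peaks()], both TFs).
#' @param de_a,de_b DE tables (\code{gene_id}, \code{logfc}, \code{fdr}) for
#'   the two knockout contrasts.
#' @param tfs length-2 character vector naming the factors; defaults to the
#'   two TF labels present in \code{annotations}.
#' @param keep_tf_nodes keep the two TF nodes when the target set is empty
#'   (default TRUE).
#' @return object of class \code{coreg_network}: list with \code{nodes} and
#'   \code{edges} data frames, \code{tfs}, and \code{coregulated}.
#' @export
coreg_network <- function(coregulated, annotations, de_a, de_b,
                          tfs = NULL, keep_tf_nodes = TRUE) {
  if (is.null(tfs)) tfs <- sort(unique(annotations$tf))
  if (length(tfs) != 2L) stopf("exactly two TF labels are required")
  coregulated <- sort(unique(as.character(coregulated)))
  ann <- annotations[annotations$gene_id %in% coregulated, , drop = FALSE]
  for (g in coregulated) {
    have <- unique(ann$tf[ann$gene_id == g])
    miss <- setdiff(tfs, have)
    if (length(miss))
      stopf("co-regulated gene '%s' has no annotation for TF '%s'", g, miss[1L])
  }
  fc_a <- stats::setNames(de_a$logfc, de_a$gene_id)
  q_a <- stats::setNames(de_a$fdr, de_a$gene_id)
  fc_b <- stats::setNames(de_b$logfc, de_b$gene_id)
  q_b <- stats::setNames(de_b$fdr, de_b$gene_id)

  edges <- data.frame(tf = ann$tf, gene_id = ann$gene_id, peak_id = ann$peak_id,
                      target_class = ann$target_class,
                      signed_distance = ann$signed_distance,
                      logfc_a = unname(fc_a[ann$gene_id]),
                      fdr_a = unname(q_a[ann$gene_id]),
                      logfc_b = unname(fc_b[ann$gene_id]),
                      fdr_b = unname(q_b[ann$gene_id]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$gene_id, edges$peak_id), , drop = FALSE]
  rownames(edges) <- NULL

  gene_class <- if (nrow(edges))
    vapply(split(edges$target_class, edges$gene_id), most_specific_class, character(1))
  else character(0)
  gene_nodes <- data.frame(id = coregulated,
                           type = rep("gene", length(coregulated)),
                           target_class = unname(gene_class[coregulated]),
                           logfc_a = unname(fc_a[coregulated]),
                           fdr_a = unname(q_a[coregulated]),
                           logfc_b = unname(fc_b[coregulated]),
                           fdr_b = unname(q_b[coregulated]),
                           stringsAsFactors = FALSE)
  tf_nodes <- data.frame(id = tfs, type = "tf", target_class = NA_character_,
                         logfc_a = NA_real_, fdr_a = NA_real_,
                         logfc_b = NA_real_, fdr_b = NA_real_,
                         stringsAsFactors = FALSE)
  nodes <- if (length(coregulated) || keep_tf_nodes)
    rbind(tf_nodes, gene_nodes) else gene_nodes
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, tfs = tfs,
                 coregulated = coregulated),
            class = "coreg_network")
}

#' @export
print.coreg_network <- function(x, ...) {
  cat(sprintf("Co-regulated network: %s + %s\n", x$tfs[1L], x$tfs[2L]))
  cat(sprintf("  %d target genes, %d TF->gene edges\n",
              length(x$coregulated), nrow(x$edges)))
  invisible(x)
}

#' @method summary coreg_network
#' @export
summary.coreg_network <- function(object, ...) {
  cls <- table(factor(object$nodes$target_class[object$nodes$type == "gene"],
                      levels = TARGET_CLASSES))
  by_tf <- table(factor(object$edges$tf, levels = object$tfs))
  out <- list(n_targets = length(object$coregulated),
              n_edges = nrow(object$edges),
              edges_per_tf = by_tf,
              gene_class = cls,
              mean_abs_distance = if (nrow(object$edges))
                mean(abs(object$edges$signed_distance)) else NA_real_)
  class(out) <- "summary.coreg_network"
  out
}

#' @export
print.summary.coreg_network <- function(x, ...) {
  cat(sprintf("Targets: %d   Edges: %d\n", x$n_targets, x$n_edges))
  cat("Edges per TF:\n"); print(x$edges_per_tf)
  cat("Gene-level class (most specific across peaks):\n"); print(x$gene_class)
  if (is.finite(x$mean_abs_distance))
    cat(sprintf("Mean |summit-to-TSS| distance: %.0f bp\n", x$mean_abs_distance))
  invisible(x)
}

#' Convert a co-regulated network to igraph
#' @param x a \code{coreg_network}.
#' @param ... unused.
#' @return an igraph graph with node \code{type} and all edge attributes.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @rdname as_igraph
#' @export
as_igraph.coreg_network <- function(x, ...) {
  el <- x$edges
  igraph::graph_from_data_frame(
    d = data.frame(from = el$tf, to = el$gene_id,
                   el[setdiff(names(el), c("tf", "gene_id"))],
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = x$nodes)
}

#' Plot a co-regulated network
#'
#' Bipartite layout with the two TF nodes highlighted and gene nodes
#' colored by their most specific target class.
#' @param x a \code{coreg_network}.
#' @param ... passed to \code{plot.igraph}.
#' @method plot coreg_network
#' @export
plot.coreg_network <- function(x, ...) {
  g <- as_igraph(x)
  pal <- c(promoter = "#d62728", proximal = "#ff7f0e",
           putative_promoter = "#2ca02c", putative_distal = "#1f77b4")
  vcol <- ifelse(igraph::V(g)$type == "tf", "grey20",
                 pal[igraph::V(g)$target_class])
  vcol[is.na(vcol)] <- "grey70"
  igraph::plot.igraph(g, vertex.color = vcol,
                      vertex.label.color = ifelse(igraph::V(g)$type == "tf", "white", "black"),
                      vertex.size = ifelse(igraph::V(g)$type == "tf", 18, 7),
                      edge.arrow.size = 0.3, ...)
  invisible(x)
}

#' Export a network to GraphML, SIF or TSV
#'
#' GraphML preserves node type and every edge attribute (Cytoscape-loadable
#' and round-trippable through [read_network_graphml()]); SIF writes
#' \code{TF <tab> target_class <tab> gene} interaction lines; TSV writes the
#' edge table.
#'
#' @param net a \code{coreg_network}.
#' @param path output path.
#' @param format \code{"graphml"}, \code{"sif"} or \code{"tsv"}.
#' @export
write_network <- function(net, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", net$edges$tf, net$edges$target_class,
                       net$edges$gene_id), path)
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a GraphML network export
#' @param path GraphML path written by [write_network()].
#' @return an igraph graph.
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  igraph::read_graph(path, format = "graphml")
}

#' Hypergeometric gene-set enrichment of the network members
#'
#' For each supplied set, tests over-representation of \code{members} by
#' the upper hypergeometric tail \code{P(X >= k)} with population
#' \code{N = |universe|}, successes \code{K = |set in universe|} and draws
#' \code{n = |members|}; Benjamini-Hochberg adjustment across sets. The
#' universe should be the genes on which membership was decidable (e.g. all
#' expression-filtered genes), and members must lie inside it.
#'
#' @param members gene set to test (e.g. the co-regulated targets).
#' @param universe background gene set.
#' @param sets named list of gene-id vectors ([read_gmt()]).
#' @return data frame ordered by p: \code{set}, \code{set_size} (in
#'   universe), \code{overlap}, \code{expected}, \code{ratio}, \code{p},
#'   \code{q}.
#' @export
gene_set_enrichment <- function(members, universe, sets) {
  members <- unique(as.character(members))
  universe <- unique(as.character(universe))
  if (!all(members %in% universe))
    stopf("members must be a subset of the universe (%d outside)",
          sum(!members %in% universe))
  if (!length(sets)) stopf("no gene sets supplied")
  N <- length(universe); n <- length(members)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, members))
    expected <- n * K / N
    data.frame(set = nm, set_size = K, overlap = k, expected = expected,
               ratio = if (expected > 0) k / expected else NA_real_,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
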