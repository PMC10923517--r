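# Strand-aware assignment of ChIP-seq peaks to genes near their TSS, with
# the four-class scheme used to build the co-regulatory network:
#
#   promoter           the peak interval contains the TSS base
#   proximal           the peak overlaps the gene body (without the TSS)
#   putative_promoter  anchor within 3 kb of the TSS, up- or downstream
#   putative_distal    anchor between 3 kb and 10 kb of the TSS
#
# A peak's anchor is its summit when one was called, else the interval
# midpoint. Classes are assigned per candidate gene by that precedence
# (most specific wins). Distances are classified by absolute value — the
# scheme is symmetric around the TSS — but reported strand-signed, negative
# meaning upstream of the TSS in the gene's own orientation. Boundary
# conventions are inclusive toward the nearer class: exactly 3 kb is
# putative_promoter, exactly 10 kb is still assigned.

#' Build a TSS/gene-body interval index
#'
#' Precomputes per-chromosome interval structures (IRanges) so that window
#' queries against thousands of peaks don't scan all genes. Query results
#' are identical to a brute-force scan over the catalog.
#'
#' @param genes gene catalog (see [gene_catalog()]).
#' @return object of class \code{tss_index}.
#' @export
tss_index <- function(genes) {
  genes <- gene_catalog(genes)
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  chroms <- lapply(by_chrom, function(i) {
    list(rows = i,
         # internal 0-based half-open -> IRanges 1-based inclusive
         tss = IRanges::IRanges(start = genes$tss[i] + 1L, width = 1L),
         body = IRanges::IRanges(start = genes$start[i] + 1L, end = genes$end[i]))
  })
  structure(list(genes = genes, chroms = chroms), class = "tss_index")
}

#' @export
print.tss_index <- function(x, ...) {
  cat(sprintf("TSS index: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(x$chroms)))
  invisible(x)
}

# Genes whose TSS lies in the closed window [lo, hi] (0-based positions).
tss_in_window <- function(index, chrom, lo, hi) {
  ch <- index$chroms[[chrom]]
  if (is.null(ch) || hi < lo) return(integer(0))
  q <- IRanges::IRanges(start = max(lo, 0L) + 1L, end = hi + 1L)
  ch$rows[S4Vectors::queryHits(IRanges::findOverlaps(ch$tss, q))]
}

# Genes whose body overlaps the half-open interval [s, e).
body_overlap <- function(index, chrom, s, e) {
  ch <- index$chroms[[chrom]]
  if (is.null(ch)) return(integer(0))
  q <- IRanges::IRanges(start = s + 1L, end = e)
  ch$rows[S4Vectors::queryHits(IRanges::findOverlaps(ch$body, q))]
}

empty_annotation <- function() {
  data.frame(peak_id = character(), tf = character(), gene_id = character(),
             target_class = character(), signed_distance = integer(),
             is_nearest_gene = logical(), stringsAsFactors = FALSE)
}

# Classify one peak against one candidate gene row; NA when out of range.
classify_pair <- function(p_start, p_end, anchor, g_start, g_end, tss,
                          tss_window, promoter_window) {
  if (p_start <= tss && tss < p_end) return("promoter")
  if (p_start < g_end && g_start < p_end) return("proximal")
  d <- abs(anchor - tss)
  if (d <= promoter_window) return("putative_promoter")
  if (d <= tss_window) return("putative_distal")
  NA_character_
}

#' Annotate peaks against genes within the TSS window
#'
#' For each peak, candidate genes are those whose TSS lies within
#' \code{tss_window} of the peak anchor (summit, else midpoint) plus those
#' whose gene body overlaps the peak interval; each candidate receives one
#' annotation row with its target class and signed anchor-to-TSS distance.
#' A peak may annotate several genes; \code{is_nearest_gene} flags the
#' candidate(s) at minimal absolute distance, and \code{nearest_only = TRUE}
#' keeps only those. Peaks with no candidate contribute no rows.
#'
#' @param peaks peak table (see [peak_table()]).
#' @param index a [tss_index()] (a gene catalog is accepted and indexed).
#' @param tss_window maximum anchor-to-TSS distance in bp (default 10000,
#'   inclusive).
#' @param promoter_window putative-promoter radius in bp (default 3000,
#'   inclusive).
#' @param nearest_only keep only the nearest candidate gene per peak.
#' @return data frame with columns \code{peak_id}, \code{tf}, \code{gene_id},
#'   \code{target_class}, \code{signed_distance}, \code{is_nearest_gene}.
#' @export
annotate_peaks <- function(peaks, index, tss_window = 10000L,
                           promoter_window = 3000L, nearest_only = FALSE) {
  peaks <- peak_table(peaks)
  if (!inherits(index, "tss_index")) index <- tss_index(index)
  check_positive(tss_window, "tss_window")
  check_positive(promoter_window, "promoter_window")
  if (promoter_window > tss_window)
    stopf("promoter_window must not exceed tss_window")
  genes <- index$genes
  if (!nrow(peaks) || !nrow(genes)) return(empty_annotation())

  rows <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$start[i]; e <- peaks$end[i]
    anchor <- if (!is.na(peaks$summit[i])) peaks$summit[i] else (s + e) %/% 2L
    cand <- union(tss_in_window(index, peaks$chrom[i], anchor - tss_window, anchor + tss_window),
                  body_overlap(index, peaks$chrom[i], s, e))
    if (!length(cand)) next
    cls <- vapply(cand, function(g) {
      classify_pair(s, e, anchor, genes$start[g], genes$end[g], genes$tss[g],
                    tss_window, promoter_window)
    }, character(1))
    cand <- cand[!is.na(cls)]; cls <- cls[!is.na(cls)]
    if (!length(cand)) next
    # signed distance: negative = upstream of the TSS in gene orientation
    raw <- anchor - genes$tss[cand]
    signed <- ifelse(genes$strand[cand] == "+", raw, -raw)
    nearest <- abs(signed) == min(abs(signed))
    df <- data.frame(peak_id = peaks$peak_id[i], tf = peaks$tf[i],
                     gene_id = genes$gene_id[cand], target_class = cls,
                     signed_distance = as.integer(signed),
                     is_nearest_gene = nearest, stringsAsFactors = FALSE)
    if (nearest_only) df <- df[df$is_nearest_gene, , drop = FALSE]
    rows[[i]] <- df
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_annotation())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes bound by a transcription factor
#'
#' @param annotations output of [annotate_peaks()].
#' @param tf transcription-factor label.
#' @param classes optional subset of target classes to restrict to.
#' @return character vector of gene ids with >= 1 qualifying annotation.
#' @export
genes_bound <- function(annotations, tf, classes = NULL) {
  keep <- annotations$tf == tf
  if (!is.null(classes)) {
    bad <- setdiff(classes, TARGET_CLASSES)
    if (length(bad)) stopf("unknown target class '%s'", bad[1L])
    keep <- keep & annotations$target_class %in% classes
  }
  sort(unique(annotations$gene_id[keep]))
}

#' Export classified peaks as a colored BED track
#'
#' One BED9 row per annotation (a multiply-assigned peak appears once per
#' gene), colored by target class for genome-browser inspection.
#'
#' @param annotations output of [annotate_peaks()].
#' @param peaks the peak table the annotations came from.
#' @param path output path.
#' @export
write_classified_bed <- function(annotations, peaks, path) {
  colors <- c(promoter = "214,39,40", proximal = "255,127,14",
              putative_promoter = "44,160,44", putative_distal = "31,119,180")
  m <- match(annotations$peak_id, peaks$peak_id)
  if (anyNA(m)) stopf("annotation refers to a peak absent from the peak table")
  lines <- sprintf("%s\t%d\t%d\t%s|%s|%s\t0\t.\t%d\t%d\t%s",
                   peaks$chrom[m], peaks$start[m], peaks$end[m],
                   annotations$peak_id, annotations$gene_id,
                   annotations$target_class,
                   peaks$start[m], peaks$end[m],
                   colors[annotations$target_class])
  writeLines(lines, path)
  invisible(path)
}
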