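# Count preprocessing and differential-expression table logic.
#
# The RNA-seq conventions implemented here: genes are filtered as
# non-expressed if they have < 0.5 CPM in fewer than two libraries;
# between-library scaling uses the trimmed-mean-of-M-values (TMM) estimator;
# counts are converted to RPKM for plotting; genes are called differentially
# expressed at FDR <= 0.05. DE statistics (logFC, FDR) arrive as tables from
# an upstream model fit — nothing here estimates dispersions or p-values.

#' Counts per million mapped reads
#'
#' \code{CPM = count / library_size * 1e6}, with library size the raw column
#' sum. On the log scale a prior count is added before taking log2.
#'
#' @param counts non-negative matrix (genes x libraries).
#' @param log2 return \code{log2(CPM + prior)}?
#' @param prior prior count added on the log scale only.
#' @return numeric matrix of the same shape.
#' @export
#' @examples
#' m <- matrix(c(5, 0, 12, 8), 2, dimnames = list(c("g1", "g2"), c("L1", "L2")))
#' cpm(m)
cpm <- function(counts, log2 = FALSE, prior = 0.5) {
  counts <- as.matrix(counts)
  libs <- colSums(counts)
  if (any(libs <= 0)) stopf("library '%s' has zero size", colnames(counts)[libs <= 0][1L] %||% which(libs <= 0)[1L])
  out <- sweep(counts, 2L, libs, "/") * 1e6
  if (log2) out <- base::log2(out + prior)
  out
}

#' Filter non-expressed genes
#'
#' A gene is kept iff its CPM reaches \code{cpm_threshold} in at least
#' \code{min_libraries} libraries (computed on raw library sizes, before any
#' between-library normalization). The operation is idempotent: filtering a
#' filtered matrix changes nothing, because removing low-count genes barely
#' perturbs library sizes — and the retained genes are recomputed against the
#' new sizes, so the fixed point is checked, not assumed.
#'
#' @param counts count matrix.
#' @param cpm_threshold minimum CPM (default 0.5).
#' @param min_libraries minimum number of libraries at or above the
#'   threshold (default 2).
#' @return the filtered count matrix (library order preserved; a
#'   \code{lengths} attribute, if present, is subset alongside).
#' @export
filter_expressed <- function(counts, cpm_threshold = 0.5, min_libraries = 2L) {
  check_positive(cpm_threshold, "cpm_threshold")
  check_positive(min_libraries, "min_libraries")
  x <- cpm(counts)
  keep <- rowSums(x >= cpm_threshold) >= min_libraries
  out <- counts[keep, , drop = FALSE]
  len <- attr(counts, "lengths")
  if (!is.null(len)) attr(out, "lengths") <- len[rownames(out)]
  out
}

# Upper-quartile CPM of one library (reference-selection statistic).
upper_quartile_cpm <- function(col, lib) {
  stats::quantile(col / lib * 1e6, 0.75, names = FALSE, type = 7)
}

#' Trimmed mean of M-values normalization factors
#'
#' Implements the published TMM estimator. The reference library is the one
#' whose upper-quartile CPM is closest to the mean upper-quartile. For each
#' library, per-gene log ratios M and log abundances A are computed over
#' genes with positive counts in both the library and the reference; the
#' most extreme 30\% of M (two-sided) and 5\% of A are trimmed; the factor
#' is 2 to the precision-weighted mean of the retained M, with weights from
#' the delta-method (binomial) variance of M. Factors are rescaled to have
#' geometric mean 1, so they are relative depth corrections only.
#'
#' @param counts count matrix, >= 2 libraries.
#' @param logratio_trim two-sided trim fraction on M (default 0.30).
#' @param sum_trim two-sided trim fraction on A (default 0.05).
#' @return named positive vector of per-library factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stopf("TMM needs >= 2 libraries")
  libs <- colSums(counts)
  if (any(libs <= 0)) stopf("library with zero size")
  uq <- vapply(seq_len(ncol(counts)), function(j) upper_quartile_cpm(counts[, j], libs[j]), 0)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_factor(counts[, j], counts[, ref], libs[j], libs[ref],
                    logratio_trim, sum_trim)
  }, 0)
  f <- f / geometric_mean(f)
  stats::setNames(f, colnames(counts))
}

# One library against the reference. Genes must be positive in both.
tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref, logratio_trim, sum_trim) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) stopf("TMM: no gene is positive in both a library and the reference")
  obs <- obs[pos]; ref <- ref[pos]
  p_obs <- obs / lib_obs
  p_ref <- ref / lib_ref
  M <- log2(p_obs / p_ref)
  A <- (log2(p_obs) + log2(p_ref)) / 2
  # asymptotic (delta-method) variance of M under binomial sampling
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (max(abs(M)) < 1e-10) return(1)  # identical relative profiles
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1;      hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Reads per kilobase per million mapped reads
#'
#' \code{RPKM = count / (library_size / 1e6) / (length / 1e3)}.
#'
#' @param counts count matrix carrying gene lengths (bp) in
#'   \code{attr(counts, "lengths")}, or supplied via \code{lengths}.
#' @param lengths optional named vector of gene lengths in bp.
#' @return numeric matrix.
#' @export
rpkm <- function(counts, lengths = attr(counts, "lengths")) {
  counts <- as.matrix(counts)
  if (is.null(lengths)) stopf("gene lengths are required for RPKM")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts) || anyNA(lengths) || any(lengths <= 0))
    stopf("gene lengths must be positive and cover every gene")
  libs <- colSums(counts)
  if (any(libs <= 0)) stopf("library with zero size")
  sweep(counts, 2L, libs / 1e6, "/") / (lengths / 1e3)
}

#' Call differentially expressed genes from a DE table
#'
#' A gene is differentially expressed iff it attains the FDR level
#' (\code{fdr <= fdr_threshold}, inclusive); direction is the sign of its
#' log fold change. A significant gene with logFC exactly 0 is directionless
#' and lands in \code{unchanged}.
#'
#' @param de data frame with \code{gene_id}, \code{logfc}, \code{fdr}.
#' @param fdr_threshold FDR level (default 0.05).
#' @return list of character vectors \code{up}, \code{down},
#'   \code{unchanged}.
#' @export
call_de <- function(de, fdr_threshold = 0.05) {
  check_positive(fdr_threshold, "fdr_threshold")
  if (anyDuplicated(de$gene_id))
    stopf("duplicate gene_id in DE table: '%s'", de$gene_id[duplicated(de$gene_id)][1L])
  sig <- de$fdr <= fdr_threshold
  list(up = de$gene_id[sig & de$logfc > 0],
       down = de$gene_id[sig & de$logfc < 0],
       unchanged = de$gene_id[!sig | de$logfc == 0])
}

#' Venn partition of two knockout contrasts
#'
#' Partitions all genes differentially expressed in either contrast into
#' seven disjoint categories: down or up in both, down or up in one contrast
#' only, and discordant (opposite directions). Category sizes sum to the
#' number of DE genes in either contrast.
#'
#' @param calls_a,calls_b outputs of [call_de()] for the two contrasts.
#' @return list with the seven gene-id vectors and a named \code{sizes}
#'   integer vector.
#' @export
venn_partition <- function(calls_a, calls_b) {
  down_both <- intersect(calls_a$down, calls_b$down)
  up_both <- intersect(calls_a$up, calls_b$up)
  discordant <- union(intersect(calls_a$up, calls_b$down),
                      intersect(calls_a$down, calls_b$up))
  de_b <- union(calls_b$up, calls_b$down)
  de_a <- union(calls_a$up, calls_a$down)
  out <- list(
    down_both = down_both,
    up_both = up_both,
    down_a_only = setdiff(calls_a$down, de_b),
    down_b_only = setdiff(calls_b$down, de_a),
    up_a_only = setdiff(calls_a$up, de_b),
    up_b_only = setdiff(calls_b$up, de_a),
    discordant = discordant)
  out$sizes <- vapply(out, length, 0L)
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' \code{dCt} of the target against the reference gene is computed in the
#' treated and control conditions; the relative quantity is
#' \code{2^-(dCt_treated - dCt_control)}. All arguments vectorize.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   PCR cycle-threshold values.
#' @return positive relative-expression value(s).
#' @export
#' @examples
#' ddct(25, 20, 23, 20)  # ddCt = 2 -> 0.25
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stopf("all CT values must be finite")
  d_treated <- ct_target_treated - ct_ref_treated
  d_control <- ct_target_control - ct_ref_control
  2^(-(d_treated - d_control))
}

#' Cross-species logFC concordance over orthologs
#'
#' Inner-joins two DE tables on an ortholog map, counts the four
#' sign-quadrants of the joined logFC pairs (genes with logFC exactly 0 in
#' either species are excluded from quadrants) and reports the Spearman rank
#' correlation of the pairs.
#'
#' @param de1,de2 DE data frames (\code{gene_id}, \code{logfc}, \code{fdr}).
#' @param ortholog_map two-column data frame mapping \code{de1} ids (column
#'   1) to \code{de2} ids (column 2).
#' @param collapse how to treat one-to-many map entries: \code{"error"}
#'   (default) or \code{"best_fdr"} (keep the pair with the smallest
#'   combined FDR).
#' @return list: \code{pairs} (joined data frame), \code{quadrants} (named
#'   counts \code{up_up}, \code{up_down}, \code{down_up}, \code{down_down}),
#'   \code{spearman} (rho, or NA when fewer than 2 pairs).
#' @export
ortholog_concordance <- function(de1, de2, ortholog_map,
                                 collapse = c("error", "best_fdr")) {
  collapse <- match.arg(collapse)
  map <- data.frame(id1 = as.character(ortholog_map[[1L]]),
                    id2 = as.character(ortholog_map[[2L]]),
                    stringsAsFactors = FALSE)
  pairs <- merge(map, stats::setNames(de1, c("id1", "logfc1", "fdr1")), by = "id1")
  pairs <- merge(pairs, stats::setNames(de2, c("id2", "logfc2", "fdr2")), by = "id2")
  dup <- anyDuplicated(pairs$id1) || anyDuplicated(pairs$id2)
  if (dup) {
    if (collapse == "error")
      stopf("one-to-many ortholog entries; set collapse = \"best_fdr\" to resolve")
    pairs <- pairs[order(pairs$fdr1 + pairs$fdr2), , drop = FALSE]
    pairs <- pairs[!duplicated(pairs$id1), , drop = FALSE]
    pairs <- pairs[!duplicated(pairs$id2), , drop = FALSE]
  }
  pairs <- pairs[order(pairs$id1), c("id1", "id2", "logfc1", "fdr1", "logfc2", "fdr2")]
  rownames(pairs) <- NULL
  nz <- pairs$logfc1 != 0 & pairs$logfc2 != 0
  q <- c(up_up = sum(nz & pairs$logfc1 > 0 & pairs$logfc2 > 0),
         up_down = sum(nz & pairs$logfc1 > 0 & pairs$logfc2 < 0),
         down_up = sum(nz & pairs$logfc1 < 0 & pairs$logfc2 > 0),
         down_down = sum(nz & pairs$logfc1 < 0 & pairs$logfc2 < 0))
  rho <- if (nrow(pairs) >= 2L)
    suppressWarnings(stats::cor(pairs$logfc1, pairs$logfc2, method = "spearman"))
  else NA_real_
  list(pairs = pairs, quadrants = q, spearman = rho)
}
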