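# Independent brute-force oracles. These re-derive expected results from
# first principles by exhaustive scanning/enumeration and deliberately share
# no code with the implementations they check.

# Quadratic all-pairs peak-to-gene classifier, straight from the rules:
# candidate if the gene body overlaps the peak or the TSS is within
# tss_window of the anchor; class by precedence promoter > proximal >
# putative_promoter > putative_distal; distances signed by gene orientation.
oracle_annotate <- function(peaks, genes, tss_window = 10000, promoter_window = 3000) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    anchor <- if (!is.na(peaks$summit[i])) peaks$summit[i]
              else (peaks$start[i] + peaks$end[i]) %/% 2L
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      tss <- genes$tss[j]
      body_ov <- peaks$start[i] < genes$end[j] && genes$start[j] < peaks$end[i]
      d_abs <- abs(anchor - tss)
      if (!body_ov && d_abs > tss_window) next
      cls <- if (peaks$start[i] <= tss && tss < peaks$end[i]) "promoter"
        else if (body_ov) "proximal"
        else if (d_abs <= promoter_window) "putative_promoter"
        else "putative_distal"
      d <- anchor - tss
      if (genes$strand[j] == "-") d <- -d
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = peaks$peak_id[i], tf = peaks$tf[i],
        gene_id = genes$gene_id[j], target_class = cls,
        signed_distance = as.integer(d), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(peak_id = character(), tf = character(),
                      gene_id = character(), target_class = character(),
                      signed_distance = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # nearest flag per peak by minimal absolute distance
  out$is_nearest_gene <- NA
  split_rows <- split(seq_len(nrow(out)), out$peak_id)
  for (p in names(split_rows)) {
    idx <- split_rows[[p]]
    out$is_nearest_gene[idx] <- abs(out$signed_distance[idx]) ==
      min(abs(out$signed_distance[idx]))
  }
  out[order(out$peak_id, out$gene_id), ]
}

sort_ann <- function(a) {
  a <- a[order(a$peak_id, a$gene_id), c("peak_id", "tf", "gene_id",
                                        "target_class", "signed_distance",
                                        "is_nearest_gene")]
  rownames(a) <- NULL
  a
}

# Exhaustive position x strand PWM scoring with explicit complement lookup.
oracle_pwm_best <- function(seq, pwm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(seq), "")[[1L]]
  rc <- rev(unname(comp[chars]))
  L <- ncol(pwm)
  score_at <- function(v, off) {
    s <- 0
    for (p in seq_len(L)) {
      b <- v[off + p]
      s <- s + if (b %in% rownames(pwm)) pwm[b, p] else min(pwm[, p])
    }
    s
  }
  n <- length(chars)
  if (n < L) return(-Inf)
  best <- -Inf
  for (off in 0:(n - L)) {
    best <- max(best, score_at(chars, off), score_at(rc, off))
  }
  best
}

# Hypergeometric upper tail by exhaustive enumeration of all n-subsets of a
# universe of N elements whose first K are the successes.
oracle_hyper_tail <- function(k, N, K, n) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

random_seq <- function(n, seed = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

dinuc_counts <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  if (length(chars) < 2) return(table(character(0)))
  table(paste0(chars[-length(chars)], chars[-1L]))
}

# A crafted single-gene catalog for boundary tests: plus-strand gene at
# [100000, 105000), TSS = 100000.
boundary_gene <- function(strand = "+") {
  gene_catalog(data.frame(gene_id = "g1", chrom = "chr1",
                          start = 100000L, end = 105000L, strand = strand,
                          stringsAsFactors = FALSE))
}

# Random dense gene catalog (overlaps allowed) plus random peaks, for
# oracle-equivalence checks.
random_fixture <- function(n_genes, n_peaks, n_chroms = 2, span = 2e6, seed = 1) {
  set.seed(seed)
  genes <- gene_catalog(data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(paste0("chr", seq_len(n_chroms)), n_genes, replace = TRUE),
    start = st <- sample.int(span, n_genes),
    end = st + sample(500:20000, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE))
  ps <- sample.int(span, n_peaks)
  w <- sample(100:1000, n_peaks, replace = TRUE)
  summit <- ifelse(runif(n_peaks) < 0.7, ps + sample(50, n_peaks, replace = TRUE) %% w, NA)
  peaks <- peak_table(data.frame(
    peak_id = sprintf("p%04d", seq_len(n_peaks)),
    tf = sample(c("TF_A", "TF_B"), n_peaks, replace = TRUE),
    chrom = sample(paste0("chr", seq_len(n_chroms + 1L)), n_peaks, replace = TRUE),
    start = ps, end = ps + w, summit = as.integer(summit),
    score = rep(NA_real_, n_peaks),
    stringsAsFactors = FALSE))
  list(genes = genes, peaks = peaks)
}
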