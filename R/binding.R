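# TSS-centered binding comparison and motif-window scanning.
#
# The binding comparison averages a coverage track in fixed-width bins
# across [TSS - half_width, TSS + half_width) for every gene, orients rows
# 5'->3' (minus-strand rows are reversed), and contrasts two factors as a
# pseudocounted log2 ratio. Motif occurrence is scored in +/-50 bp windows
# around binding-site anchors, either as exact IUPAC consensus matches or as
# best log-odds PWM hits, always on both strands.

#' Bin coverage around every TSS
#'
#' For each gene, coverage is averaged within each \code{bin}-bp bin of the
#' window \code{[tss - half_width, tss + half_width)}. Rows of minus-strand
#' genes are reversed so bins read 5' to 3'. Positions without a coverage
#' run (including beyond chromosome bounds) contribute 0.
#'
#' @param track coverage data frame (see [coverage_track()]).
#' @param genes gene catalog.
#' @param half_width window half-width in bp (default 5000).
#' @param bin bin width in bp (default 100); must divide \code{half_width}.
#' @return numeric matrix (genes x bins) with gene ids as rownames and
#'   attributes \code{half_width} and \code{bin}; column names give the bin
#'   start offset relative to the TSS in gene orientation.
#' @export
tss_matrix <- function(track, genes, half_width = 5000L, bin = 100L) {
  genes <- gene_catalog(genes)
  track <- coverage_track(track)
  check_positive(half_width, "half_width")
  check_positive(bin, "bin")
  if (half_width %% bin != 0) stopf("'bin' must divide 'half_width'")
  nb <- as.integer(2L * half_width / bin)
  m <- matrix(0, nrow(genes), nb,
              dimnames = list(genes$gene_id,
                              as.character(seq(-half_width, half_width - bin, by = bin))))
  by_chrom <- split(track, track$chrom)
  for (i in seq_len(nrow(genes))) {
    runs <- by_chrom[[genes$chrom[i]]]
    if (is.null(runs) || !nrow(runs)) next
    lo <- genes$tss[i] - half_width
    edges <- lo + bin * (0:nb)
    m[i, ] <- binned_means(runs$start, runs$end, runs$value, edges)
  }
  flip <- genes$strand == "-"
  m[flip, ] <- m[flip, nb:1, drop = FALSE]
  attr(m, "half_width") <- as.integer(half_width)
  attr(m, "bin") <- as.integer(bin)
  m
}

# Mean of a run-length coverage over each [edges[k], edges[k+1]) bin.
binned_means <- function(rs, re, rv, edges) {
  nb <- length(edges) - 1L
  out <- numeric(nb)
  for (k in seq_len(nb)) {
    a <- edges[k]; b <- edges[k + 1L]
    ov <- pmin(re, b) - pmax(rs, a)
    pos <- ov > 0
    if (any(pos)) out[k] <- sum(rv[pos] * ov[pos]) / (b - a)
  }
  out
}

#' Log2 binding ratio of two TSS matrices
#'
#' Elementwise \code{log2((A + pc) / (B + pc))} over two TSS matrices on the
#' same gene order and bin grid, antisymmetric under swapping the factors.
#' The per-gene summary (maximum bin value per factor, and the log2 ratio of
#' those maxima) supports co-binding scatter/heat displays.
#'
#' @param matrix_a,matrix_b outputs of [tss_matrix()] for the two factors.
#' @param pseudocount added to both before the ratio (default 1).
#' @return list: \code{log2_ratio} matrix and \code{summary} data frame
#'   (\code{gene_id}, \code{max_a}, \code{max_b}, \code{log2_max_ratio}).
#' @export
tss_log2_comparison <- function(matrix_a, matrix_b, pseudocount = 1) {
  if (!identical(dim(matrix_a), dim(matrix_b)) ||
      !identical(dimnames(matrix_a), dimnames(matrix_b)) ||
      !identical(attr(matrix_a, "bin"), attr(matrix_b, "bin")) ||
      !identical(attr(matrix_a, "half_width"), attr(matrix_b, "half_width")))
    stopf("TSS matrices must share gene order and bin grid")
  check_positive(pseudocount, "pseudocount")
  ratio <- log2((matrix_a + pseudocount) / (matrix_b + pseudocount))
  max_a <- apply(matrix_a, 1L, max)
  max_b <- apply(matrix_b, 1L, max)
  list(log2_ratio = ratio,
       summary = data.frame(gene_id = rownames(matrix_a),
                            max_a = max_a, max_b = max_b,
                            log2_max_ratio = log2((max_a + pseudocount) / (max_b + pseudocount)),
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Define a motif model
#'
#' Either an IUPAC consensus string (exact-match mode) or a 4 x L position
#' weight matrix of per-position base log-odds with a score threshold
#' (scoring mode).
#'
#' @param name motif label.
#' @param consensus IUPAC consensus string (e.g. \code{"GGAW"}).
#' @param pwm numeric matrix with rownames \code{A,C,G,T}, one column per
#'   motif position, entries in log-odds.
#' @param threshold minimum best log-odds score to call a hit (PWM mode).
#' @return object of class \code{motif_model}.
#' @export
motif_model <- function(name, consensus = NULL, pwm = NULL, threshold = NULL) {
  if (is.null(consensus) == is.null(pwm))
    stopf("provide exactly one of 'consensus' or 'pwm'")
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    if (!nzchar(consensus)) stopf("consensus must be non-empty")
    if (grepl("[^ACGTRYSWKMBDHVN]", consensus))
      stopf("consensus contains non-IUPAC letters")
  } else {
    pwm <- as.matrix(pwm)
    if (!identical(rownames(pwm), c("A", "C", "G", "T")))
      stopf("PWM rows must be A, C, G, T in order")
    if (is.null(threshold)) stopf("PWM mode requires a score threshold")
  }
  structure(list(name = name, consensus = consensus, pwm = pwm,
                 threshold = threshold), class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  mode <- if (is.null(x$pwm)) sprintf("consensus %s", x$consensus)
          else sprintf("PWM, %d positions, threshold %.3g", ncol(x$pwm), x$threshold)
  cat(sprintf("Motif '%s' (%s)\n", x$name, mode))
  invisible(x)
}

motif_width <- function(motif) {
  if (is.null(motif$pwm)) nchar(motif$consensus) else ncol(motif$pwm)
}

# Best PWM score over all offsets of one strand; N scores as the worst base
# of its column. Returns -Inf for sequences shorter than the motif.
pwm_best_score_one_strand <- function(seq, pwm) {
  L <- ncol(pwm)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  code <- match(chars, c("A", "C", "G", "T"))
  n <- length(code)
  if (n < L) return(-Inf)
  scored <- rbind(pwm, apply(pwm, 2L, min))  # row 5: N = worst base
  code[is.na(code)] <- 5L
  best <- -Inf
  for (off in 0:(n - L)) {
    s <- sum(scored[cbind(code[(off + 1):(off + L)], seq_len(L))])
    if (s > best) best <- s
  }
  best
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scan sequence windows for a motif
#'
#' Both strands are always scanned. In consensus mode a window is a hit iff
#' an exact IUPAC match occurs (ambiguity codes in the motif expand; N in
#' the window never matches). In PWM mode the best log-odds score over all
#' positions and strands is compared to the motif threshold; N in the window
#' scores as the worst base of its column. Windows shorter than the motif
#' are flagged and never hit.
#'
#' @param sequences character vector of window sequences over
#'   \code{A,C,G,T,N} (case-insensitive), e.g. anchor +/- 50 bp.
#' @param motif a [motif_model()].
#' @return data frame: \code{window} (name or index), \code{hit},
#'   \code{best_score} (NA in consensus mode), \code{too_short}.
#' @export
scan_motif <- function(sequences, motif) {
  if (!inherits(motif, "motif_model")) stopf("'motif' must be a motif_model")
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGTN]", sequences)))
    stopf("sequences may contain only A, C, G, T, N")
  nm <- names(sequences) %||% as.character(seq_along(sequences))
  w <- motif_width(motif)
  too_short <- nchar(sequences) < w
  if (is.null(motif$pwm)) {
    subj <- Biostrings::DNAStringSet(ifelse(too_short, strrep("N", w), sequences))
    fwd <- Biostrings::vcountPattern(motif$consensus, subj, fixed = "subject") > 0
    rev <- Biostrings::vcountPattern(motif$consensus,
                                     Biostrings::reverseComplement(subj),
                                     fixed = "subject") > 0
    hit <- (fwd | rev) & !too_short
    score <- rep(NA_real_, length(sequences))
  } else {
    score <- vapply(seq_along(sequences), function(i) {
      if (too_short[i]) return(NA_real_)
      max(pwm_best_score_one_strand(sequences[i], motif$pwm),
          pwm_best_score_one_strand(revcomp(sequences[i]), motif$pwm))
    }, 0)
    hit <- !too_short & !is.na(score) & score >= motif$threshold
  }
  data.frame(window = nm, hit = hit, best_score = score,
             too_short = too_short, row.names = NULL, stringsAsFactors = FALSE)
}

#' Motif enrichment of target windows over a background
#'
#' Compares the hit rate in target windows against the rate in background
#' windows (e.g. dinucleotide-shuffled targets): the enrichment ratio is
#' \code{(k/n) / (k0/n0)} and the p-value is the upper binomial tail of k
#' hits in n windows at the background rate. A background with zero hits
#' yields an infinite ratio; its p-value uses a half-count corrected rate
#' and is flagged.
#'
#' @param k,n hit count and window count in the targets.
#' @param k0,n0 hit count and window count in the background.
#' @return list: \code{ratio}, \code{p_value}, \code{rate_target},
#'   \code{rate_background}, \code{zero_background} flag.
#' @export
motif_enrichment <- function(k, n, k0, n0) {
  if (n <= 0 || n0 <= 0) stopf("window counts must be positive")
  if (k < 0 || k > n || k0 < 0 || k0 > n0) stopf("hit counts out of range")
  zero_bg <- k0 == 0
  rate0 <- if (zero_bg) 0.5 / n0 else k0 / n0
  ratio <- if (zero_bg) Inf else (k / n) / (k0 / n0)
  p <- stats::pbinom(k - 1, n, rate0, lower.tail = FALSE)
  list(ratio = ratio, p_value = p, rate_target = k / n, rate_background = k0 / n0,
       zero_background = zero_bg)
}

#' Dinucleotide-preserving shuffle of sequence windows
#'
#' Generates background windows for [motif_enrichment()] by shuffling each
#' sequence while preserving its exact dinucleotide counts (random Eulerian
#' walk on the dinucleotide transition multigraph).
#'
#' @param sequences character vector of windows.
#' @param times shuffles per window (default 10).
#' @param seed RNG seed.
#' @return character vector of \code{length(sequences) * times} shuffled
#'   windows.
#' @export
shuffle_windows <- function(sequences, times = 10L, seed = 1L) {
  sequences <- toupper(sequences)
  with_seed(seed, {
    unlist(lapply(sequences, function(s) {
      vapply(seq_len(times), function(i) dinucleotide_shuffle(s), character(1))
    }))
  })
}

# One dinucleotide-preserving shuffle: a uniformly ordered Eulerian trail on
# the letter-transition multigraph, with the last-edge-to-sink constraint
# handled by retry (windows are short; retries are cheap).
dinucleotide_shuffle <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 3L) return(s)
  for (attempt in 1:100) {
    edges <- split(chars[-1L], chars[-n])
    edges <- lapply(edges, sample)
    out <- character(n)
    out[1L] <- chars[1L]
    ptr <- lapply(edges, function(e) 1L)
    ok <- TRUE
    cur <- chars[1L]
    for (i in 2:n) {
      avail <- edges[[cur]]
      p <- ptr[[cur]] %||% 1L
      if (is.null(avail) || p > length(avail)) { ok <- FALSE; break }
      nxt <- avail[p]
      ptr[[cur]] <- p + 1L
      out[i] <- nxt
      cur <- nxt
    }
    if (ok && all(vapply(names(edges), function(k) ptr[[k]] > length(edges[[k]]), TRUE)))
      return(paste(out, collapse = ""))
  }
  s  # give up: return the original (preserves counts trivially)
}

#' Extract anchor-centered windows from peaks
#'
#' Helper for motif scanning: returns the \code{[anchor - flank, anchor +
#' flank]} window of each peak as (chrom, start, end) rows, anchored at the
#' summit when called, else the midpoint.
#'
#' @param peaks peak table.
#' @param flank half-width in bp (default 50).
#' @return data frame \code{peak_id}, \code{chrom}, \code{start}, \code{end}.
#' @export
peak_windows <- function(peaks, flank = 50L) {
  peaks <- peak_table(peaks)
  anchor <- ifelse(is.na(peaks$summit), (peaks$start + peaks$end) %/% 2L, peaks$summit)
  data.frame(peak_id = peaks$peak_id, chrom = peaks$chrom,
             start = pmax(anchor - as.integer(flank), 0L),
             end = anchor + as.integer(flank) + 1L,
             stringsAsFactors = FALSE)
}
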