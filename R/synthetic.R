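# Synthetic data with planted ground truth. Every generator is a pure
# function of (parameters, seed) — the global RNG stream is untouched — and
# every ground-truth claim is verifiable by running the downstream modules
# on the generated data (self-validating fixtures).
#
# The default geometry keeps planted peaks unambiguous: genes are separated
# by at least ~25 kb of intergenic space, so a peak planted within 10 kb of
# its gene's TSS can never fall within 10 kb of a neighboring TSS, and
# noise peaks can be placed so they receive no assignment at all.

#' Generate a toy genome of stranded, non-overlapping genes
#'
#' Genes are laid down sequentially per chromosome with random lengths,
#' random strands and random intergenic gaps, round-robin across
#' chromosomes.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chroms number of chromosomes (default 2).
#' @param gene_length_range min/max gene length in bp.
#' @param intergenic_range min/max intergenic gap in bp. Keep the minimum
#'   above ~21 kb if noise peaks (> 10 kb from every TSS) must be placeable.
#' @param seed RNG seed.
#' @return gene catalog with a \code{chrom_lengths} attribute.
#' @export
generate_genome <- function(n_genes, n_chroms = 2L,
                            gene_length_range = c(2000L, 20000L),
                            intergenic_range = c(25000L, 60000L),
                            seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1L) stopf("'n_genes' must be >= 1")
  check_positive(n_chroms, "n_chroms")
  if (any(gene_length_range <= 0) || diff(gene_length_range) < 0)
    stopf("'gene_length_range' must be a positive increasing range")
  if (any(intergenic_range <= 0) || diff(intergenic_range) < 0)
    stopf("'intergenic_range' must be a positive increasing range")
  n_genes <- as.integer(n_genes); n_chroms <- as.integer(n_chroms)
  with_seed(seed, {
    chrom_of <- rep(paste0("chr", seq_len(n_chroms)), length.out = n_genes)
    lens <- sample(gene_length_range[1L]:gene_length_range[2L], n_genes, replace = TRUE)
    gaps <- sample(intergenic_range[1L]:intergenic_range[2L], n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    start <- integer(n_genes); end <- integer(n_genes)
    pos <- stats::setNames(rep(0L, n_chroms), paste0("chr", seq_len(n_chroms)))
    for (i in seq_len(n_genes)) {
      ch <- chrom_of[i]
      start[i] <- pos[[ch]] + gaps[i]
      end[i] <- start[i] + lens[i]
      pos[[ch]] <- end[i]
    }
    chrom_lengths <- pos + as.integer(mean(intergenic_range))
    out <- gene_catalog(data.frame(
      gene_id = sprintf("gene_%03d", seq_len(n_genes)),
      chrom = chrom_of, start = start, end = end, strand = strand,
      stringsAsFactors = FALSE))
    attr(out, "chrom_lengths") <- chrom_lengths
    out
  })
}

# Place one peak of the intended class on a gene. Returns c(start, end,
# summit) or NULL when the class cannot be placed on this gene.
place_peak_for_class <- function(gene, class, width) {
  tss <- gene$tss; half <- width %/% 2L
  if (class == "promoter") {
    k <- sample(seq(50L, width - 50L), 1L)
    start <- tss - k
    if (start < 0L) return(NULL)
    return(c(start, start + width, start + half))
  }
  if (class == "proximal") {
    lo <- gene$start + (gene$strand == "+")
    hi <- gene$end - (gene$strand == "-") - width
    if (hi < lo) return(NULL)
    start <- if (hi == lo) lo else sample(seq(lo, hi), 1L)
    return(c(start, start + width, start + half))
  }
  d_range <- if (class == "putative_promoter")
    c(half + 100L, 2800L) else c(3200L, 9500L)
  if (d_range[2L] < d_range[1L]) return(NULL)
  d <- sample(seq(d_range[1L], d_range[2L]), 1L)
  summit <- if (gene$strand == "+") tss - d else tss + d  # upstream side
  start <- summit - half
  if (start < 0L) return(NULL)
  c(start, start + width, summit)
}

#' Generate two planted ChIP-seq peak sets
#'
#' Selects a co-bound gene subset (one peak from each factor) plus
#' factor-specific bound genes (disjoint, so the co-bound set is exactly as
#' planted), placing each peak so that the four-class annotation returns
#' the intended class for its gene; each placement is verified against the
#' classifier and re-sampled on failure. Noise peaks are placed farther
#' than the TSS window from every TSS and outside every gene body, so they
#' receive no assignment downstream.
#'
#' @param genes catalog from [generate_genome()].
#' @param fraction_bound_a,fraction_bound_b fraction of genes bound by each
#'   factor (each >= \code{fraction_cobound}).
#' @param fraction_cobound fraction of genes bound by both.
#' @param class_mix named proportions over the four target classes
#'   (must sum to 1).
#' @param peak_width peak width in bp (default 400; summit at center).
#' @param noise_peaks number of unassignable noise peaks (total, split
#'   between the factors).
#' @param tfs length-2 factor labels.
#' @param tss_window,promoter_window annotation windows the placements are
#'   verified against.
#' @param max_retries placement attempts per gene before giving up.
#' @param seed RNG seed.
#' @return list: \code{peaks_a}, \code{peaks_b} (peak tables) and
#'   \code{ground_truth} (list with \code{cobound}, \code{bound_a},
#'   \code{bound_b}, \code{planted_classes} data frame, \code{noise_peaks}
#'   ids, \code{params}).
#' @export
generate_peaks <- function(genes,
                           fraction_bound_a = 0.30, fraction_bound_b = 0.30,
                           fraction_cobound = 0.15,
                           class_mix = c(promoter = 0.4, proximal = 0.2,
                                         putative_promoter = 0.2,
                                         putative_distal = 0.2),
                           peak_width = 400L, noise_peaks = 0L,
                           tfs = c("TF_A", "TF_B"),
                           tss_window = 10000L, promoter_window = 3000L,
                           max_retries = 20L, seed = 1L) {
  genes <- gene_catalog(genes)
  check_fraction(fraction_bound_a, "fraction_bound_a")
  check_fraction(fraction_bound_b, "fraction_bound_b")
  check_fraction(fraction_cobound, "fraction_cobound")
  if (fraction_cobound > min(fraction_bound_a, fraction_bound_b))
    stopf("'fraction_cobound' cannot exceed either bound fraction")
  if (!setequal(names(class_mix), TARGET_CLASSES) || abs(sum(class_mix) - 1) > 1e-8)
    stopf("'class_mix' must be named proportions over the four classes summing to 1")
  if (length(tfs) != 2L || tfs[1L] == tfs[2L]) stopf("'tfs' must be two distinct labels")
  n <- nrow(genes)
  n_co <- round(fraction_cobound * n)
  n_a <- round(fraction_bound_a * n)
  n_b <- round(fraction_bound_b * n)

  with_seed(seed, {
    co <- sample(genes$gene_id, n_co)
    rest <- setdiff(genes$gene_id, co)
    only_a <- if (n_a > n_co) sample(rest, n_a - n_co) else character(0)
    rest <- setdiff(rest, only_a)
    only_b <- if (n_b > n_co) sample(rest, n_b - n_co) else character(0)
    bound_a <- c(co, only_a); bound_b <- c(co, only_b)

    plant_one <- function(gene_id, tf, idx) {
      g <- genes[genes$gene_id == gene_id, ]
      for (try in seq_len(max_retries)) {
        cls <- sample(TARGET_CLASSES, 1L, prob = class_mix[TARGET_CLASSES])
        pos <- place_peak_for_class(g, cls, as.integer(peak_width))
        if (is.null(pos)) next
        got <- classify_pair(pos[1L], pos[2L], pos[3L], g$start, g$end, g$tss,
                             tss_window, promoter_window)
        if (identical(got, cls))
          return(data.frame(peak_id = sprintf("%s_peak_%04d", tf, idx), tf = tf,
                            chrom = g$chrom, start = pos[1L], end = pos[2L],
                            summit = pos[3L], score = round(stats::runif(1, 5, 50), 3),
                            gene_id = gene_id, class = cls,
                            stringsAsFactors = FALSE))
      }
      stopf("could not place a peak on gene '%s' after %d attempts", gene_id, max_retries)
    }
    planted_a <- lapply(seq_along(bound_a), function(i) plant_one(bound_a[i], tfs[1L], i))
    planted_b <- lapply(seq_along(bound_b), function(i) plant_one(bound_b[i], tfs[2L], i))
    planted <- do.call(rbind, c(planted_a, planted_b))

    # noise: margin-conservative placement inside large intergenic segments
    noise <- noise_segments(genes, margin = tss_window + 1L + peak_width %/% 2L + 1L)
    noise_rows <- NULL
    if (noise_peaks > 0L) {
      if (!nrow(noise))
        stopf("no intergenic segment is large enough for noise peaks")
      seg <- sample(nrow(noise), noise_peaks, replace = TRUE, prob = noise$hi - noise$lo)
      summit <- noise$lo[seg] + floor(stats::runif(noise_peaks) * (noise$hi[seg] - noise$lo[seg] + 1))
      tf_of <- rep(tfs, length.out = noise_peaks)
      noise_rows <- data.frame(
        peak_id = sprintf("%s_noise_%04d", tf_of, seq_len(noise_peaks)),
        tf = tf_of, chrom = noise$chrom[seg],
        start = as.integer(summit - peak_width %/% 2L),
        end = as.integer(summit - peak_width %/% 2L + peak_width),
        summit = as.integer(summit),
        score = round(stats::runif(noise_peaks, 1, 10), 3),
        gene_id = NA_character_, class = NA_character_,
        stringsAsFactors = FALSE)
    }
    all_rows <- rbind(planted, noise_rows)
    peaks <- peak_table(all_rows[PEAK_COLUMNS])
    list(peaks_a = peaks[peaks$tf == tfs[1L], , drop = FALSE],
         peaks_b = peaks[peaks$tf == tfs[2L], , drop = FALSE],
         ground_truth = list(
           cobound = sort(co),
           bound_a = sort(bound_a), bound_b = sort(bound_b),
           planted_classes = planted[c("peak_id", "tf", "gene_id", "class")],
           noise_peaks = if (is.null(noise_rows)) character(0) else noise_rows$peak_id,
           tfs = tfs,
           params = list(fraction_bound_a = fraction_bound_a,
                         fraction_bound_b = fraction_bound_b,
                         fraction_cobound = fraction_cobound,
                         class_mix = as.list(class_mix),
                         peak_width = peak_width, noise_peaks = noise_peaks,
                         tss_window = tss_window,
                         promoter_window = promoter_window, seed = seed)))
  })
}

# Intergenic segments in which a summit is > `margin` bp from every gene
# boundary (hence from every TSS) on its chromosome.
noise_segments <- function(genes, margin) {
  out <- lapply(split(genes, genes$chrom), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    lo <- c(0L, g$end) + margin
    hi <- c(g$start, max(g$end) + 3L * margin) - margin
    keep <- hi >= lo
    data.frame(chrom = g$chrom[1L], lo = lo[keep], hi = hi[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate two knockout DE tables with planted dual-down genes
#'
#' Ground-truth co-bound genes are planted as down-regulated in BOTH
#' contrasts (logFC near \code{effect_logfc}, FDR = \code{fdr_planted});
#' further genes are planted as down in one contrast only; every other gene
#' is null (logFC ~ Normal(0, null_sd), FDR drawn above the 0.05 call
#' threshold — uniform on [0.05, 1], or concentrated just above/below the
#' threshold in hard mode to exercise the boundary).
#'
#' @param genes gene catalog.
#' @param ground_truth ground truth from [generate_peaks()] (supplies the
#'   co-bound set).
#' @param n_down_a_only,n_down_b_only genes planted down in one contrast
#'   only (drawn outside the co-bound set).
#' @param effect_logfc planted log2 fold change (negative).
#' @param null_sd standard deviation of null logFC.
#' @param fdr_planted FDR assigned to planted genes (< 0.05).
#' @param hard_mode draw borderline null FDRs around the threshold.
#' @param seed RNG seed.
#' @return list: \code{de_a}, \code{de_b} (DE data frames over all genes)
#'   and \code{ground_truth} extended with \code{down_both},
#'   \code{down_a_only}, \code{down_b_only}.
#' @export
generate_de_tables <- function(genes, ground_truth,
                               n_down_a_only = 20L, n_down_b_only = 20L,
                               effect_logfc = -2, null_sd = 0.25,
                               fdr_planted = 0.001, hard_mode = FALSE,
                               seed = 1L) {
  genes <- gene_catalog(genes)
  if (effect_logfc >= 0) stopf("'effect_logfc' must be negative")
  if (fdr_planted >= 0.05) stopf("'fdr_planted' must be < 0.05")
  co <- ground_truth$cobound
  if (length(co) + n_down_a_only + n_down_b_only > nrow(genes))
    stopf("cannot plant %d + %d single-contrast genes outside %d co-bound in a %d-gene catalog",
          n_down_a_only, n_down_b_only, length(co), nrow(genes))
  with_seed(seed, {
    pool <- setdiff(genes$gene_id, co)
    a_only <- if (n_down_a_only > 0L) sample(pool, n_down_a_only) else character(0)
    pool <- setdiff(pool, a_only)
    b_only <- if (n_down_b_only > 0L) sample(pool, n_down_b_only) else character(0)

    make_table <- function(down_genes) {
      n <- nrow(genes)
      logfc <- stats::rnorm(n, 0, null_sd)
      fdr <- if (hard_mode) stats::runif(n, 0.045, 0.2) else stats::runif(n, 0.05, 1)
      i <- match(down_genes, genes$gene_id)
      logfc[i] <- pmin(effect_logfc + stats::rnorm(length(i), 0, 0.1 * abs(effect_logfc)), -0.1)
      fdr[i] <- fdr_planted
      data.frame(gene_id = genes$gene_id, logfc = logfc, fdr = fdr,
                 stringsAsFactors = FALSE)
    }
    de_a <- make_table(c(co, a_only))
    de_b <- make_table(c(co, b_only))
    gt <- ground_truth
    gt$down_both <- sort(co)
    gt$down_a_only <- sort(a_only)
    gt$down_b_only <- sort(b_only)
    list(de_a = de_a, de_b = de_b, ground_truth = gt)
  })
}

#' Generate plateau coverage tracks from peaks
#'
#' Coverage equals \code{background} everywhere a gene or peak lives, plus
#' \code{peak_height} across each peak interval (stacking where peaks
#' overlap). Optional Gaussian noise can be added per run.
#'
#' @param peaks peak table (one or both factors; tracks are returned per
#'   TF label).
#' @param genes gene catalog (fixes the chromosome extents, via the
#'   \code{chrom_lengths} attribute when present).
#' @param peak_height plateau height above background.
#' @param background baseline coverage (>= 0, < peak_height).
#' @param noise_sd per-run Gaussian noise SD (default 0 = deterministic).
#' @param seed RNG seed (used only when \code{noise_sd > 0}).
#' @return named list of coverage data frames, one per TF label.
#' @export
generate_coverage <- function(peaks, genes, peak_height = 8, background = 0.5,
                              noise_sd = 0, seed = 1L) {
  peaks <- peak_table(peaks)
  genes <- gene_catalog(genes)
  if (peak_height <= background || background < 0)
    stopf("need peak_height > background >= 0")
  ext <- attr(genes, "chrom_lengths")
  if (is.null(ext)) {
    ext <- tapply(pmax(genes$end, 0L), genes$chrom, max) + 20000L
  }
  build <- function(pk) {
    out <- lapply(names(ext), function(ch) {
      L <- as.integer(ext[[ch]])
      p <- pk[pk$chrom == ch, , drop = FALSE]
      cuts <- sort(unique(c(0L, pmin(p$start, L), pmin(p$end, L), L)))
      if (length(cuts) < 2L) return(NULL)
      s <- cuts[-length(cuts)]; e <- cuts[-1L]
      depth <- vapply(s, function(x) sum(p$start <= x & p$end > x), 0L)
      data.frame(chrom = ch, start = s, end = e,
                 value = background + peak_height * depth,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, out)
    if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                      end = integer(), value = numeric())
    if (noise_sd > 0) {
      df$value <- pmax(df$value + stats::rnorm(nrow(df), 0, noise_sd), 0)
    }
    coverage_track(df[df$value > 0, , drop = FALSE])
  }
  with_seed(seed, {
    tracks <- lapply(split(peaks, peaks$tf), build)
    tracks
  })
}

#' Generate clonotype tables with a planted dominant clone
#'
#' Each sample gets one dominant clone at exactly
#' \code{dominant_fraction} of the total count; the remainder is
#' multinomially distributed over the other clones.
#'
#' @param n_clones clones per sample.
#' @param dominant_fraction planted dominance in (0, 1].
#' @param total_count reads per sample.
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @return list: \code{table} (clonotype data frame) and \code{ground_truth}
#'   (per-sample dominant clone id and the planted fraction).
#' @export
generate_clonotypes <- function(n_clones = 50L, dominant_fraction = 0.6,
                                total_count = 10000L, n_samples = 1L,
                                seed = 1L) {
  check_positive(n_clones, "n_clones")
  check_fraction(dominant_fraction, "dominant_fraction")
  if (dominant_fraction <= 0) stopf("'dominant_fraction' must be positive")
  with_seed(seed, {
    rows <- list(); dominant <- character(n_samples)
    for (s in seq_len(n_samples)) {
      sid <- sprintf("S%02d", s)
      ids <- sprintf("%s_clone_%03d", sid, seq_len(n_clones))
      dom <- sample(ids, 1L)
      dom_count <- round(dominant_fraction * total_count)
      rest <- total_count - dom_count
      others <- setdiff(ids, dom)
      counts <- stats::setNames(rep(0L, length(ids)), ids)
      counts[dom] <- dom_count
      if (rest > 0L && length(others)) {
        w <- stats::rexp(length(others))
        repeat {
          draw <- stats::rmultinom(1L, rest, w / sum(w))[, 1L]
          if (max(draw) < dom_count || dominant_fraction == 1) break
        }
        counts[others] <- draw
      }
      counts <- counts[counts > 0L]
      rows[[s]] <- data.frame(clone_id = names(counts), sample_id = sid,
                              count = as.integer(counts), stringsAsFactors = FALSE)
      dominant[s] <- dom
    }
    list(table = clonotype_table(do.call(rbind, rows)),
         ground_truth = list(dominant = stats::setNames(dominant, sprintf("S%02d", seq_len(n_samples))),
                             dominant_fraction = dominant_fraction))
  })
}

#' Generate gene-set collections with one planted enriched set
#'
#' One set is planted to contain a stated fraction of the co-regulated
#' genes (emulating a strongly enriched functional category such as
#' ribosome biogenesis); the remaining sets are drawn uniformly from the
#' catalog.
#'
#' @param genes gene catalog.
#' @param coregulated planted co-regulated gene ids (ground truth).
#' @param n_sets number of sets (>= 2).
#' @param planted_set_size size of the planted set.
#' @param planted_fraction fraction of the planted set drawn from the
#'   co-regulated genes (default 0.8).
#' @param set_size_range size range of the background sets.
#' @param seed RNG seed.
#' @return list: \code{sets} (named list, GMT-writable) and
#'   \code{ground_truth} (\code{planted_set} name).
#' @export
generate_gene_sets <- function(genes, coregulated, n_sets = 20L,
                               planted_set_size = 30L, planted_fraction = 0.8,
                               set_size_range = c(15L, 60L), seed = 1L) {
  genes <- gene_catalog(genes)
  if (n_sets < 2L) stopf("'n_sets' must be >= 2")
  check_fraction(planted_fraction, "planted_fraction")
  if (!length(coregulated)) stopf("'coregulated' must be non-empty")
  with_seed(seed, {
    nm <- sprintf("GS%02d", seq_len(n_sets))
    planted_name <- sample(nm, 1L)
    n_from_co <- min(round(planted_fraction * planted_set_size), length(coregulated))
    planted <- sample(coregulated, n_from_co)
    filler <- setdiff(genes$gene_id, planted)
    if (planted_set_size > n_from_co)
      planted <- c(planted, sample(filler, planted_set_size - n_from_co))
    sets <- lapply(nm, function(x) {
      if (x == planted_name) return(sort(planted))
      size <- min(sample(set_size_range[1L]:set_size_range[2L], 1L), nrow(genes))
      sort(sample(genes$gene_id, size))
    })
    names(sets) <- nm
    attr(sets, "descriptions") <- stats::setNames(
      ifelse(nm == planted_name, "synthetic planted enriched set", "synthetic background set"), nm)
    list(sets = sets, ground_truth = list(planted_set = planted_name))
  })
}

#' Generate a raw count matrix over the toy genome
#'
#' Negative-binomial counts for every gene across libraries, with a random
#' subset of genes silenced (zero in all but at most one library) so the
#' 0.5-CPM / 2-library expression filter has something to remove. Genes
#' named in \code{keep_expressed} are never silenced.
#'
#' @param genes gene catalog.
#' @param n_libraries number of libraries (default 4).
#' @param mean_count negative-binomial mean (default 100).
#' @param dispersion NB dispersion (default 0.3).
#' @param frac_silent fraction of silenceable genes (default 0.1).
#' @param keep_expressed gene ids protected from silencing.
#' @param seed RNG seed.
#' @return count matrix with gene lengths (bp) in \code{attr(, "lengths")};
#'   the silenced gene ids are in \code{attr(, "silent")}.
#' @export
generate_counts <- function(genes, n_libraries = 4L, mean_count = 100,
                            dispersion = 0.3, frac_silent = 0.1,
                            keep_expressed = character(0), seed = 1L) {
  genes <- gene_catalog(genes)
  check_positive(n_libraries, "n_libraries")
  check_fraction(frac_silent, "frac_silent")
  n <- nrow(genes)
  with_seed(seed, {
    m <- matrix(stats::rnbinom(n * n_libraries, mu = mean_count, size = 1 / dispersion),
                n, n_libraries,
                dimnames = list(genes$gene_id, sprintf("lib_%d", seq_len(n_libraries))))
    pool <- setdiff(genes$gene_id, keep_expressed)
    silent <- sample(pool, round(frac_silent * n))
    m[silent, ] <- 0L
    if (length(silent)) {
      # one stray count in one library: still below the 2-library rule
      m[cbind(match(silent, rownames(m)),
              sample(n_libraries, length(silent), replace = TRUE))] <- 1L
    }
    attr(m, "lengths") <- stats::setNames(genes$end - genes$start, genes$gene_id)
    attr(m, "silent") <- sort(silent)
    m
  })
}

#' Simulate a complete on-disk dataset with ground truth
#'
#' Runs every generator with one master seed and writes the files the
#' pipeline reads: gene models (GTF), two narrowPeak files, two bedGraph
#' tracks, a count matrix, two DE tables, a GMT collection, a clonotype
#' table, and the ground truth (YAML). A pipeline run needs no other input.
#'
#' @param dir output directory (created if absent).
#' @param n_genes,n_chroms genome size (defaults 200 genes, 2 chromosomes).
#' @param fraction_cobound,fraction_bound_a,fraction_bound_b binding plan.
#' @param n_down_a_only,n_down_b_only single-contrast down-regulated plants.
#' @param noise_peaks unassignable noise peaks.
#' @param n_sets gene-set collection size.
#' @param tfs factor labels.
#' @param hard_mode borderline null FDRs (see [generate_de_tables()]).
#' @param seed master seed; stage seeds are derived from it.
#' @return invisibly, list with \code{paths} (named file paths) and
#'   \code{ground_truth}.
#' @export
simulate_dataset <- function(dir, n_genes = 200L, n_chroms = 2L,
                             fraction_cobound = 0.15,
                             fraction_bound_a = 0.30, fraction_bound_b = 0.30,
                             n_down_a_only = 20L, n_down_b_only = 20L,
                             noise_peaks = 50L, n_sets = 20L,
                             tfs = c("TF_A", "TF_B"),
                             hard_mode = FALSE, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- as.integer(seed)
  genes <- generate_genome(n_genes, n_chroms, seed = seed)
  pk <- generate_peaks(genes, fraction_bound_a = fraction_bound_a,
                       fraction_bound_b = fraction_bound_b,
                       fraction_cobound = fraction_cobound,
                       noise_peaks = noise_peaks, tfs = tfs,
                       seed = seed + 1L)
  de <- generate_de_tables(genes, pk$ground_truth,
                           n_down_a_only = n_down_a_only,
                           n_down_b_only = n_down_b_only,
                           hard_mode = hard_mode, seed = seed + 2L)
  gt <- de$ground_truth
  counts <- generate_counts(genes,
                            keep_expressed = c(gt$cobound, gt$down_a_only, gt$down_b_only),
                            seed = seed + 3L)
  cov <- generate_coverage(rbind(pk$peaks_a, pk$peaks_b), genes, seed = seed + 4L)
  gs <- generate_gene_sets(genes, gt$cobound, n_sets = n_sets, seed = seed + 5L)
  cl <- generate_clonotypes(n_samples = 3L, seed = seed + 6L)
  gt$planted_set <- gs$ground_truth$planted_set
  gt$dominant_clones <- as.list(cl$ground_truth$dominant)
  gt$silent_genes <- attr(counts, "silent")
  gt$seed <- seed

  paths <- list(
    genes = file.path(dir, "genes.gtf"),
    peaks_a = file.path(dir, sprintf("peaks_%s.narrowPeak", tfs[1L])),
    peaks_b = file.path(dir, sprintf("peaks_%s.narrowPeak", tfs[2L])),
    coverage_a = file.path(dir, sprintf("coverage_%s.bedGraph", tfs[1L])),
    coverage_b = file.path(dir, sprintf("coverage_%s.bedGraph", tfs[2L])),
    counts = file.path(dir, "counts.tsv"),
    de_a = file.path(dir, sprintf("de_%s.tsv", tfs[1L])),
    de_b = file.path(dir, sprintf("de_%s.tsv", tfs[2L])),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    clonotypes = file.path(dir, "clonotypes.tsv"),
    ground_truth = file.path(dir, "ground_truth.yaml"))
  write_gene_models(genes, paths$genes, format = "gtf")
  write_peaks(pk$peaks_a, paths$peaks_a)
  write_peaks(pk$peaks_b, paths$peaks_b)
  write_coverage(cov[[tfs[1L]]], paths$coverage_a)
  write_coverage(cov[[tfs[2L]]], paths$coverage_b)
  write_counts(counts, paths$counts)
  write_de_table(de$de_a, paths$de_a)
  write_de_table(de$de_b, paths$de_b)
  write_gmt(gs$sets, paths$gene_sets)
  write_clonotypes(cl$table, paths$clonotypes)
  yaml::write_yaml(serialize_ground_truth(gt), paths$ground_truth)
  invisible(list(paths = paths, ground_truth = gt))
}

serialize_ground_truth <- function(gt) {
  gt$planted_classes <- as.list(gt$planted_classes)
  gt
}
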