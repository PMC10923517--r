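# Readers and writers for the external formats the pipeline consumes and
# produces. One internal coordinate convention is used throughout: 0-based,
# half-open [start, end), the BED convention. GTF (1-based, inclusive) is
# converted on ingest and back on export, so a GTF -> internal -> GTF
# round-trip reproduces the original coordinates exactly.
#
# All readers validate their dialect and refuse malformed input (naming the
# offending line) rather than silently coercing.

GENE_COLUMNS <- c("gene_id", "chrom", "start", "end", "strand", "tss")
PEAK_COLUMNS <- c("peak_id", "tf", "chrom", "start", "end", "summit", "score")
TARGET_CLASSES <- c("promoter", "proximal", "putative_promoter", "putative_distal")

#' Construct and validate a gene catalog
#'
#' A gene catalog is a data frame with one row per gene: \code{gene_id},
#' \code{chrom}, \code{start}, \code{end} (0-based half-open), \code{strand}
#' (\code{+}/\code{-}) and the derived \code{tss}. The transcriptional start
#' site is the first transcribed base: \code{start} on the plus strand and
#' \code{end - 1} (the last covered base) on the minus strand.
#'
#' @param df data frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}; \code{tss} is (re)derived.
#' @return validated gene catalog data frame.
#' @export
gene_catalog <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("gene catalog is missing column(s): %s", paste(miss, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  if (anyNA(df$start) || anyNA(df$end) || any(df$start < 0))
    stopf("gene coordinates must be non-negative integers")
  if (any(df$start >= df$end)) {
    bad <- df$gene_id[df$start >= df$end][1L]
    stopf("gene '%s' has start >= end", bad)
  }
  if (!all(df$strand %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'")
  if (anyDuplicated(df$gene_id))
    stopf("duplicate gene_id in catalog: '%s'", df$gene_id[duplicated(df$gene_id)][1L])
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  rownames(df) <- NULL
  df[GENE_COLUMNS]
}

parse_gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, "[ =]+\"?([^\";]+)\"?"), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, character(1))
}

#' Read gene models from GTF or BED6
#'
#' GTF coordinates (1-based, inclusive) are converted to the internal 0-based
#' half-open convention. When a GTF carries several feature records for one
#' gene (exons, transcripts), the gene model is the union span (min start,
#' max end); transcript-level TSS selection is not attempted. BED6 input is
#' taken as one gene per row, already 0-based half-open, with the name column
#' as \code{gene_id}.
#'
#' @param path file path.
#' @param format \code{"gtf"} or \code{"bed6"}.
#' @param chrom_style passed to [normalize_chroms()]; default leaves names
#'   untouched (matching is exact string equality).
#' @return gene catalog (see [gene_catalog()]).
#' @export
read_gene_models <- function(path, format = c("gtf", "bed6"),
                             chrom_style = "none") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) stopf("no feature lines in %s", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)

  if (format == "gtf") {
    nf <- lengths(fields)
    if (any(nf < 9L))
      stopf("%s line %d: expected 9 tab-separated GTF fields, found %d",
            path, idx[which(nf < 9L)[1L]], nf[nf < 9L][1L])
    chrom <- vapply(fields, `[`, "", 1L)
    start1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
    end1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
    strand <- vapply(fields, `[`, "", 7L)
    attrs <- vapply(fields, `[`, "", 9L)
    bad <- which(is.na(start1) | is.na(end1) | start1 < 1L | end1 < start1)
    if (length(bad))
      stopf("%s line %d: malformed GTF coordinates", path, idx[bad[1L]])
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad))
      stopf("%s line %d: strand must be '+' or '-'", path, idx[bad[1L]])
    gene_id <- parse_gtf_attr(attrs, "gene_id")
    bad <- which(is.na(gene_id))
    if (length(bad))
      stopf("%s line %d: no gene_id attribute", path, idx[bad[1L]])
    # 1-based inclusive -> 0-based half-open
    rec <- data.frame(gene_id = gene_id, chrom = normalize_chroms(chrom, chrom_style),
                      start = start1 - 1L, end = end1, strand = strand,
                      stringsAsFactors = FALSE)
    # gene-level model = union span of a gene's records
    sp <- split(rec, rec$gene_id)
    out <- do.call(rbind, lapply(sp, function(g) {
      if (length(unique(g$chrom)) > 1L)
        stopf("gene '%s' has records on conflicting chromosomes (%s)",
              g$gene_id[1L], paste(unique(g$chrom), collapse = ", "))
      if (length(unique(g$strand)) > 1L)
        stopf("gene '%s' has records on conflicting strands", g$gene_id[1L])
      data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
                 start = min(g$start), end = max(g$end),
                 strand = g$strand[1L], stringsAsFactors = FALSE)
    }))
    return(gene_catalog(out))
  }

  # bed6
  nf <- lengths(fields)
  if (any(nf < 6L))
    stopf("%s line %d: BED6 needs 6 columns, found %d",
          path, idx[which(nf < 6L)[1L]], nf[nf < 6L][1L])
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start)
  if (length(bad))
    stopf("%s line %d: malformed BED coordinates", path, idx[bad[1L]])
  gene_catalog(data.frame(
    gene_id = vapply(fields, `[`, "", 4L),
    chrom = normalize_chroms(vapply(fields, `[`, "", 1L), chrom_style),
    start = start, end = end,
    strand = vapply(fields, `[`, "", 6L),
    stringsAsFactors = FALSE))
}

#' Write gene models
#'
#' GTF output converts internal 0-based half-open coordinates back to GTF's
#' 1-based inclusive convention, so write -> read round-trips exactly.
#'
#' @param genes gene catalog.
#' @param path output path.
#' @param format \code{"gtf"} or \code{"bed6"}.
#' @param source source field for GTF output.
#' @export
write_gene_models <- function(genes, path, format = c("gtf", "bed6"),
                              source = "tfcoreg") {
  format <- match.arg(format)
  genes <- gene_catalog(genes)
  if (format == "gtf") {
    lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                     genes$chrom, source, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     genes$chrom, genes$start, genes$end, genes$gene_id, genes$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct and validate a peak table
#'
#' Peaks are 0-based half-open intervals attributed to one transcription
#' factor, with an optional absolute summit position and score.
#' @param df data frame with columns \code{peak_id}, \code{tf}, \code{chrom},
#'   \code{start}, \code{end}, and optionally \code{summit}, \code{score}.
#' @return validated peak data frame.
#' @export
peak_table <- function(df) {
  need <- c("peak_id", "tf", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("peak table is missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(df$summit)) df$summit <- NA_integer_
  if (is.null(df$score)) df$score <- NA_real_
  df$peak_id <- as.character(df$peak_id)
  df$tf <- as.character(df$tf)
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$summit <- as.integer(df$summit)
  df$score <- as.numeric(df$score)
  if (any(df$start < 0) || any(df$start >= df$end))
    stopf("peak intervals must satisfy 0 <= start < end")
  has <- !is.na(df$summit)
  if (any(has & (df$summit < df$start | df$summit >= df$end))) {
    bad <- df$peak_id[has & (df$summit < df$start | df$summit >= df$end)][1L]
    stopf("peak '%s': summit outside [start, end)", bad)
  }
  rownames(df) <- NULL
  df[PEAK_COLUMNS]
}

#' Read ChIP-seq peaks from BED or ENCODE narrowPeak
#'
#' narrowPeak requires exactly 10 columns; column 10 (summit offset from
#' \code{start}) is converted to an absolute position, with the sentinel
#' \code{-1} meaning "no summit called". The \code{signalValue} column is
#' kept as the peak score. Plain BED needs at least 3 columns; summit and
#' score are absent unless columns 4/5 provide a name/score.
#'
#' @param path file path.
#' @param format \code{"bed"} or \code{"narrowPeak"}.
#' @param tf transcription-factor label attached to every peak.
#' @param chrom_style passed to [normalize_chroms()].
#' @return peak table (see [peak_table()]).
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak"), tf,
                       chrom_style = "none") {
  format <- match.arg(format)
  if (missing(tf) || !is.character(tf) || length(tf) != 1L)
    stopf("'tf' label is required")
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) stopf("no peak lines in %s", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  minc <- if (format == "narrowPeak") 10L else 3L
  if (any(nf < minc))
    stopf("%s line %d: %s needs %d columns, found %d", path,
          idx[which(nf < minc)[1L]], format, minc, nf[nf < minc][1L])
  chrom <- normalize_chroms(vapply(fields, `[`, "", 1L), chrom_style)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start)
  if (length(bad))
    stopf("%s line %d: malformed peak coordinates", path, idx[bad[1L]])
  name <- if (all(nf >= 4L)) vapply(fields, `[`, "", 4L) else sprintf("%s_peak_%d", tf, seq_along(idx))
  name[!nzchar(name) | name == "."] <- sprintf("%s_peak_%d", tf, which(!nzchar(name) | name == "."))
  if (format == "narrowPeak") {
    score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 7L)))
    offset <- suppressWarnings(as.integer(vapply(fields, `[`, "", 10L)))
    if (anyNA(offset))
      stopf("%s line %d: narrowPeak summit offset is not an integer",
            path, idx[which(is.na(offset))[1L]])
    summit <- ifelse(offset == -1L, NA_integer_, start + offset)
    oob <- which(!is.na(summit) & (summit < start | summit >= end))
    if (length(oob))
      stopf("%s line %d: summit offset outside the peak interval", path, idx[oob[1L]])
  } else {
    score <- if (all(nf >= 5L))
      suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L))) else NA_real_
    summit <- NA_integer_
  }
  peak_table(data.frame(peak_id = name, tf = tf, chrom = chrom, start = start,
                        end = end, summit = summit, score = score,
                        stringsAsFactors = FALSE))
}

#' Write peaks as ENCODE narrowPeak
#' @param peaks peak table.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  peaks <- peak_table(peaks)
  offset <- ifelse(is.na(peaks$summit), -1L, peaks$summit - peaks$start)
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   format(score, trim = TRUE, scientific = FALSE), offset)
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' DE statistics are consumed, not fitted: each row carries a gene's log2
#' fold change and its precomputed false-discovery rate for one knockout
#' contrast. Column names are configurable to match whatever the upstream
#' fit exported.
#'
#' @param path TSV path with a header row.
#' @param columns named character vector mapping internal names
#'   (\code{gene_id}, \code{logfc}, \code{fdr}) to file column names.
#' @return data frame with columns \code{gene_id}, \code{logfc}, \code{fdr}.
#' @export
read_de_table <- function(path,
                          columns = c(gene_id = "gene_id", logfc = "logFC", fdr = "FDR")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (k in c("gene_id", "logfc", "fdr")) {
    if (!columns[[k]] %in% names(df))
      stopf("%s: required column '%s' (%s) not found", path, columns[[k]], k)
  }
  out <- data.frame(gene_id = as.character(df[[columns[["gene_id"]]]]),
                    logfc = as.numeric(df[[columns[["logfc"]]]]),
                    fdr = as.numeric(df[[columns[["fdr"]]]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$fdr)) || any(out$fdr < 0) || any(out$fdr > 1))
    stopf("%s: FDR values must lie in [0, 1]", path)
  out
}

#' Write a differential-expression table
#' @param de data frame with \code{gene_id}, \code{logfc}, \code{fdr}.
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[c("gene_id", "logfc", "fdr")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix
#'
#' Expects a TSV whose first column holds gene identifiers and whose header
#' names the libraries. An optional \code{length} column (gene length in bp,
#' needed only for RPKM) is split off into the \code{"lengths"} attribute.
#'
#' @param path TSV path.
#' @return integer matrix (genes x libraries) with rownames; gene lengths,
#'   if present, in \code{attr(x, "lengths")}.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stopf("%s: count table needs gene ids plus >= 1 library", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stopf("%s: duplicate gene ids", path)
  df <- df[-1L]
  lengths <- NULL
  if ("length" %in% names(df)) {
    lengths <- as.integer(df[["length"]])
    names(lengths) <- ids
    df <- df[setdiff(names(df), "length")]
  }
  m <- as.matrix(df)
  mode(m) <- "numeric"
  if (anyNA(m) || any(m < 0)) stopf("%s: counts must be non-negative numbers", path)
  rownames(m) <- ids
  if (!is.null(lengths)) attr(m, "lengths") <- lengths
  m
}

#' Write a count matrix
#' @param counts matrix with rownames; optional \code{lengths} attribute.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  len <- attr(counts, "lengths")
  if (!is.null(len)) df$length <- as.integer(len[rownames(counts)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Runs must be non-overlapping within a chromosome; overlapping runs are an
#' error, not merged. Output is sorted by (chrom, start). Positions without a
#' run are implicitly zero coverage.
#'
#' @param path bedGraph path (4 columns: chrom, start, end, value).
#' @return data frame \code{chrom}, \code{start}, \code{end}, \code{value}.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) return(coverage_track(data.frame(
    chrom = character(), start = integer(), end = integer(), value = numeric())))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stopf("%s line %d: bedGraph needs 4 columns", path, idx[which(nf < 4L)[1L]])
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = suppressWarnings(as.integer(vapply(fields, `[`, "", 2L))),
                   end = suppressWarnings(as.integer(vapply(fields, `[`, "", 3L))),
                   value = suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L))),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value))
  if (length(bad)) stopf("%s line %d: malformed bedGraph record", path, idx[bad[1L]])
  coverage_track(df)
}

#' Construct and validate a coverage track
#' @param df data frame \code{chrom}, \code{start}, \code{end}, \code{value}.
#' @return sorted, validated coverage data frame.
#' @export
coverage_track <- function(df) {
  need <- c("chrom", "start", "end", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("coverage track is missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[need]
  if (nrow(df)) {
    if (any(df$start < 0) || any(df$start >= df$end))
      stopf("coverage runs must satisfy 0 <= start < end")
    if (any(df$value < 0)) stopf("coverage values must be non-negative")
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    ov <- unlist(lapply(split(seq_len(nrow(df)), df$chrom), function(i) {
      if (length(i) < 2L) return(logical(0))
      df$start[i[-1L]] < df$end[i[-length(i)]]
    }))
    if (any(ov)) stopf("coverage track has overlapping runs")
  }
  rownames(df) <- NULL
  df
}

#' Write a coverage track as bedGraph
#' @param track coverage data frame.
#' @param path output path.
#' @export
write_coverage <- function(track, path) {
  track <- coverage_track(track)
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                   format(track$value, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT: one set per line, tab-separated: name, description, then member
#' gene ids. Returns a named list of character vectors with descriptions in
#' \code{attr(x, "descriptions")}.
#'
#' @param path GMT path.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("%s line %d: GMT needs name, description and >= 1 gene",
          path, which(nf < 3L)[1L])
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm)) stopf("%s: duplicate set name '%s'", path, nm[duplicated(nm)][1L])
  sets <- lapply(fields, function(x) unique(x[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[`, "", 2L), nm)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of gene-id vectors; optional \code{descriptions}
#'   attribute.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write annotated peak-to-gene targets as TSV
#'
#' The TSV round-trips losslessly through [read_targets()].
#' @param annotations annotated-target data frame from [annotate_peaks()].
#' @param path output path.
#' @export
write_targets <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotated-target TSV written by [write_targets()]
#' @param path TSV path.
#' @return annotated-target data frame.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peak_id", "tf", "gene_id", "target_class", "signed_distance", "is_nearest_gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  df$is_nearest_gene <- as.logical(df$is_nearest_gene)
  df
}

#' Read a clonotype table
#'
#' Schema: one row per (clone, sample) with a positive read/UMI count;
#' frequencies are always computed downstream, never stored. Column names
#' are configurable for compatibility with MiXCR clone exports.
#'
#' @param path TSV path.
#' @param columns named mapping for \code{clone_id}, \code{sample_id},
#'   \code{count}.
#' @return data frame \code{clone_id}, \code{sample_id}, \code{count}.
#' @export
read_clonotypes <- function(path,
                            columns = c(clone_id = "clone_id",
                                        sample_id = "sample_id",
                                        count = "count")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (k in names(columns)) {
    if (!columns[[k]] %in% names(df))
      stopf("%s: required column '%s' (%s) not found", path, columns[[k]], k)
  }
  clonotype_table(data.frame(clone_id = as.character(df[[columns[["clone_id"]]]]),
                             sample_id = as.character(df[[columns[["sample_id"]]]]),
                             count = as.numeric(df[[columns[["count"]]]]),
                             stringsAsFactors = FALSE))
}

#' Validate a clonotype table
#' @param df data frame \code{clone_id}, \code{sample_id}, \code{count}.
#' @return validated data frame.
#' @export
clonotype_table <- function(df) {
  need <- c("clone_id", "sample_id", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("clonotype table is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(is.na(df$count)) || any(df$count <= 0))
    stopf("clonotype counts must be positive")
  if (anyDuplicated(df[c("clone_id", "sample_id")]))
    stopf("duplicate (clone_id, sample_id) rows")
  rownames(df) <- NULL
  df[need]
}

#' Write a clonotype table
#' @param df clonotype data frame.
#' @param path output path.
#' @export
write_clonotypes <- function(df, path) {
  utils::write.table(clonotype_table(df), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
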