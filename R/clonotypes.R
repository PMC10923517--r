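# Immunoglobulin heavy-chain clonotype dominance summaries. Clone tables
# (e.g. MiXCR exports) arrive as (clone_id, sample_id, count) rows; all
# frequencies are computed here, never stored upstream.

#' Top clonotype frequencies per sample
#'
#' Relative frequency = clone count / total sample count; the \code{n} most
#' frequent clones per sample are returned (all of them when a sample has
#' fewer), ties broken by clone_id so output is deterministic. For samples
#' pooled from several mice, the per-mouse normalized frequency divides the
#' relative frequency by the pool size, leaving single-mouse samples
#' unchanged.
#'
#' @param table clonotype data frame (see [clonotype_table()]).
#' @param n clones to keep per sample (default 10).
#' @param pool_size single number or named per-sample vector of mice pooled
#'   (default 1).
#' @return data frame \code{sample_id}, \code{rank}, \code{clone_id},
#'   \code{frequency}, \code{per_mouse_frequency}.
#' @export
top_clone_frequencies <- function(table, n = 10L, pool_size = 1L) {
  table <- clonotype_table(table)
  check_positive(n, "n")
  samples <- unique(table$sample_id)
  pool <- if (length(pool_size) == 1L && is.null(names(pool_size)))
    stats::setNames(rep(pool_size, length(samples)), samples) else pool_size
  if (!all(samples %in% names(pool)))
    stopf("pool_size missing for sample '%s'", setdiff(samples, names(pool))[1L])
  if (any(pool <= 0)) stopf("pool sizes must be positive")
  out <- lapply(samples, function(s) {
    rows <- table[table$sample_id == s, , drop = FALSE]
    total <- sum(rows$count)
    rows <- rows[order(-rows$count, rows$clone_id), , drop = FALSE]
    rows <- utils::head(rows, n)
    data.frame(sample_id = s, rank = seq_len(nrow(rows)),
               clone_id = rows$clone_id,
               frequency = rows$count / total,
               per_mouse_frequency = rows$count / total / pool[[s]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Clonal dominance of a sample
#'
#' The relative frequency of the most frequent clone: 1 for a monoclonal
#' sample, 1/k for k equal clones.
#'
#' @param table clonotype data frame.
#' @param sample sample id.
#' @return dominance in (0, 1].
#' @export
dominance_index <- function(table, sample) {
  table <- clonotype_table(table)
  rows <- table[table$sample_id == sample, , drop = FALSE]
  if (!nrow(rows)) stopf("sample '%s' not present", sample)
  max(rows$count) / sum(rows$count)
}

#' Track clone frequencies across timepoints
#'
#' Joins per-timepoint clone tables on clone_id; a clone absent from a
#' timepoint has frequency 0 there.
#'
#' @param tables named list of clonotype data frames, one per timepoint,
#'   each treated as one repertoire.
#' @return data frame: \code{clone_id} plus one frequency column per
#'   timepoint, ordered by decreasing final-timepoint frequency.
#' @export
clone_tracking <- function(tables) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stopf("'tables' must be a named list (timepoint names)")
  freqs <- lapply(tables, function(tb) {
    tb <- clonotype_table(tb)
    agg <- stats::aggregate(count ~ clone_id, tb, sum)
    stats::setNames(agg$count / sum(agg$count), agg$clone_id)
  })
  clones <- sort(unique(unlist(lapply(freqs, names))))
  out <- data.frame(clone_id = clones, stringsAsFactors = FALSE)
  for (tp in names(freqs)) {
    v <- freqs[[tp]][clones]
    v[is.na(v)] <- 0
    out[[tp]] <- unname(v)
  }
  out[order(-out[[length(tables) + 1L]], out$clone_id), , drop = FALSE]
}
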