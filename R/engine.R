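# The streaming sparse computation Y = G x B.
#
# Genotypes are streamed in SNP chunks in ascending ordinal order; for each
# variant only the gene-model columns with nonzero weight are visited, and
# each update is decomposed into row chunks across samples.  An output
# column's accumulator is allocated when its first contributing variant is
# touched and flushed to the sink when its last one has been processed, so
# peak memory scales with the number of simultaneously active columns plus
# one genotype chunk — never with the full n x k output.
#
# Accumulation is always double precision; single-precision output rounds
# at flush.  Variants are processed in ascending genotype ordinal and,
# within a variant, columns in ascending position, so results are
# bit-reproducible and independent of chunk sizes.

#' Engine configuration
#'
#' @param snp_chunk_size Variants per streamed genotype block.
#' @param row_chunk_size Samples per accumulation slice.
#' @param value_precision Output storage precision, `"double"` or `"single"`.
#' @param flush_batch_size Completed columns exported per batch.
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(snp_chunk_size = 1024L, row_chunk_size = 8192L,
                          value_precision = c("double", "single"),
                          flush_batch_size = 64L) {
  value_precision <- match.arg(value_precision)
  stopifnot(snp_chunk_size >= 1L, row_chunk_size >= 1L, flush_batch_size >= 1L)
  structure(list(snp_chunk_size = as.integer(snp_chunk_size),
                 row_chunk_size = as.integer(row_chunk_size),
                 value_precision = value_precision,
                 flush_batch_size = as.integer(flush_batch_size)),
            class = "engine_config")
}

#' Stream dosages through the sparse weight index into a .grom writer
#'
#' Executes the chunked sparse product for one chromosome's matched index:
#' per SNP chunk, per variant with entries, the dosage transform is applied
#' (`flip`: d -> 2 - d), then each (column, weight) pair adds
#' `weight * transformed dosage` into the column's accumulator over row
#' chunks of samples. Columns are allocated at their first contributing
#' variant and flushed when their remaining-contribution counter reaches
#' zero; flushing happens at SNP-chunk boundaries in batches.
#'
#' @param source A `dosage_source` (see [open_genotype_source()]).
#' @param matched A `matched_index` from [build_matched_index()].
#' @param sample_set The `sample_set` the source was opened with.
#' @param config An [engine_config()].
#' @param sink A `grom_writer`; must be preallocated for
#'   `length(sample_set$analyzed)` rows.
#' @param col_offset Offset added to matched column positions when writing
#'   (used when several chromosomes share one writer; default 0).
#' @param finalize Write all-zero columns for catalog columns with no
#'   matched variants and require every column flushed (set `FALSE` when
#'   other chromosomes still have columns to contribute).
#' @return Run summary list: `columns_written`, `variants_processed`,
#'   `entries_applied`, `peak_active_columns`, `n_imputed_missing`.
#' @export
stream_impute <- function(source, matched, sample_set, config = engine_config(),
                          sink, col_offset = 0L, finalize = TRUE) {
  stopifnot(inherits(matched, "matched_index"), inherits(config, "engine_config"),
            inherits(sink, "grom_writer"))
  n <- length(sample_set$analyzed)
  if (sink$n_rows != n) {
    stop(sprintf("sink has %d row(s) but %d sample(s) are analyzed",
                 sink$n_rows, n), call. = FALSE)
  }
  entries <- matched$entries
  span <- matched$column_span[matched_count > 0L]
  m <- source$n_variants
  if (nrow(span) && max(span$last_ordinal) >= m) {
    stop("matched index refers to ordinals beyond the genotype source: index/source mismatch",
         call. = FALSE)
  }
  # per-variant entry slices, resolved once before streaming
  ord_of <- entries$ordinal
  first_of <- integer(0); remaining <- integer(0)
  acc <- vector("list", 0)
  active <- new.env(parent = emptyenv())
  remaining <- setNames(span$matched_count, as.character(span$col))
  first_ord <- setNames(span$first_ordinal, as.character(span$col))
  row_starts <- seq.int(1L, n, by = config$row_chunk_size)
  peak_active <- 0L
  n_active <- 0L
  columns_written <- 0L
  entries_applied <- 0L
  variants_processed <- 0L
  n_imputed <- 0
  flush_queue <- list()
  flush_batch <- function(force = FALSE) {
    while (length(flush_queue) >= config$flush_batch_size ||
           (force && length(flush_queue))) {
      take <- head(seq_along(flush_queue), config$flush_batch_size)
      for (q in flush_queue[take]) {
        vals <- q$values
        if (any(!is.finite(vals))) {
          stop(sprintf("non-finite accumulator in column %d", q$col), call. = FALSE)
        }
        write_column(sink, q$col + col_offset, vals)
      }
      flush_queue <<- flush_queue[-take]
      columns_written <<- columns_written + length(take)
    }
  }
  chunk_starts <- if (m > 0L) seq.int(0L, m - 1L, by = config$snp_chunk_size) else integer(0)
  ent_by_chunk <- split(seq_len(nrow(entries)),
                        ord_of %/% config$snp_chunk_size)
  for (cs in chunk_starts) {
    len <- min(config$snp_chunk_size, m - cs)
    idx <- ent_by_chunk[[as.character(cs %/% config$snp_chunk_size)]]
    variants_processed <- variants_processed + len
    if (is.null(idx)) next
    chunk <- read_dosage_chunk(source, cs, len)
    n_imputed <- n_imputed + sum(chunk$n_imputed)
    vals <- chunk$values
    # entries are sorted by (ordinal, col); process one variant at a time,
    # releasing columns completed by that variant only after all of its
    # column updates are done
    e_pos <- 1L
    n_idx <- length(idx)
    while (e_pos <= n_idx) {
      ord <- ord_of[idx[e_pos]]
      e_end <- e_pos
      while (e_end < n_idx && ord_of[idx[e_end + 1L]] == ord) e_end <- e_end + 1L
      d <- vals[, ord - cs + 1L]
      d_flip <- NULL
      completed <- integer(0)
      for (e in idx[e_pos:e_end]) {
        colpos <- entries$col[e]
        key <- as.character(colpos)
        a <- active[[key]]
        if (is.null(a)) {
          a <- numeric(n)
          n_active <- n_active + 1L
          if (n_active > peak_active) peak_active <- n_active
        }
        if (entries$flip[e]) {
          if (is.null(d_flip)) d_flip <- 2 - d
          dd <- d_flip
        } else dd <- d
        w <- entries$weight[e]
        for (rs in row_starts) {
          re <- min(rs + config$row_chunk_size - 1L, n)
          a[rs:re] <- a[rs:re] + w * dd[rs:re]
        }
        active[[key]] <- a
        entries_applied <- entries_applied + 1L
        remaining[key] <- remaining[key] - 1L
        if (remaining[key] == 0L) completed <- c(completed, colpos)
      }
      for (colpos in completed) {
        key <- as.character(colpos)
        flush_queue[[length(flush_queue) + 1L]] <-
          list(col = colpos, values = active[[key]])
        rm(list = key, envir = active)
        n_active <- n_active - 1L
      }
      e_pos <- e_end + 1L
    }
    flush_batch()
  }
  flush_batch(force = TRUE)
  if (length(ls(active))) {
    stop(sprintf(
      "source exhausted with %d unflushed column(s): index/source mismatch",
      length(ls(active))), call. = FALSE)
  }
  if (finalize) {
    zero_cols <- matched$column_span[matched_count == 0L, col]
    for (z in zero_cols) {
      write_column(sink, z + col_offset, numeric(n))
      columns_written <- columns_written + 1L
    }
  }
  list(columns_written = columns_written,
       variants_processed = variants_processed,
       entries_applied = entries_applied,
       peak_active_columns = peak_active,
       n_imputed_missing = n_imputed)
}

#' Dense reference computation of Y = G x B
#'
#' Materializes the weight matrix densely and computes the product in one
#' full matrix operation, splitting entries by dosage transform:
#' `Y = G %*% B_identity + (2 - G) %*% B_flip`. Test-scale correctness
#' oracle for [stream_impute()] — an independent route to the same result.
#'
#' @param dosages Full dosage matrix, analyzed samples x variants (column j
#'   = genotype ordinal j-1), already mean-imputed.
#' @param matched A `matched_index`.
#' @param catalog The `grom_catalog` defining the k output columns.
#' @return Dense numeric matrix, samples x k.
#' @export
dense_oracle_impute <- function(dosages, matched, catalog) {
  stopifnot(inherits(matched, "matched_index"), inherits(catalog, "grom_catalog"))
  m <- ncol(dosages)
  k <- catalog$k
  e <- matched$entries
  if (nrow(e) && max(e$ordinal) >= m) {
    stop("matched index refers to ordinals beyond the dosage matrix", call. = FALSE)
  }
  B_id <- matrix(0, nrow = m, ncol = k)
  B_fl <- matrix(0, nrow = m, ncol = k)
  if (nrow(e)) {
    idx_id <- !e$flip
    B_id[cbind(e$ordinal[idx_id] + 1L, e$col[idx_id] + 1L)] <- e$weight[idx_id]
    B_fl[cbind(e$ordinal[!idx_id] + 1L, e$col[!idx_id] + 1L)] <- e$weight[!idx_id]
  }
  dosages %*% B_id + (2 - dosages) %*% B_fl
}

#' Plan the allocate/flush lifecycle per SNP chunk
#'
#' From each column's contributing-ordinal span, computes which columns are
#' allocated (chunk containing the first contributing variant) and flushed
#' (chunk containing the last) per chunk, plus the simulated peak number of
#' simultaneously active columns (the running allocated-minus-flushed
#' count, evaluated within each chunk before its flushes).
#'
#' @param matched A `matched_index`.
#' @param snp_chunk_size Variants per chunk.
#' @param n_variants Total variants in the source (defaults to the largest
#'   contributing ordinal + 1).
#' @return List: `chunks` (data.table with `chunk`, `start`, `allocate`,
#'   `flush` list-columns of column positions), `peak_active_columns`.
#' @export
column_lifecycle_plan <- function(matched, snp_chunk_size,
                                  n_variants = NULL) {
  stopifnot(inherits(matched, "matched_index"), snp_chunk_size >= 1L)
  span <- matched$column_span[matched_count > 0L]
  if (is.null(n_variants)) {
    n_variants <- if (nrow(span)) max(span$last_ordinal) + 1L else 0L
  }
  starts <- if (n_variants > 0L) seq.int(0L, n_variants - 1L, by = snp_chunk_size)
            else integer(0)
  alloc_chunk <- span$first_ordinal %/% snp_chunk_size
  flush_chunk <- span$last_ordinal %/% snp_chunk_size
  chunks <- data.table::data.table(
    chunk = seq_along(starts) - 1L, start = starts)
  chunks[, allocate := lapply(chunk, function(ci) sort(span$col[alloc_chunk == ci]))]
  chunks[, flush := lapply(chunk, function(ci) sort(span$col[flush_chunk == ci]))]
  # allocated-minus-flushed running count, swept at variant granularity: a
  # column is active from its first contributing ordinal through its last
  peak <- 0L
  if (nrow(span)) {
    events <- data.table::data.table(
      ord = c(span$first_ordinal, span$last_ordinal + 1L),
      delta = rep(c(1L, -1L), each = nrow(span)))
    events <- events[, .(delta = sum(delta)), by = ord][order(ord)]
    peak <- max(cumsum(events$delta))
  }
  list(chunks = chunks[], peak_active_columns = peak)
}
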