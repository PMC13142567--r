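# Concordance evaluation between two prediction sets: per gene-model
# column Pearson correlation and RMSE, with min/max headline summaries.

#' @noRd
as_prediction_matrix <- function(x) {
  if (inherits(x, "grom_dataset")) return(x$values)
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(paste0(x, ".grom"))) return(grom_read(x)$values)
    if (file.exists(x)) {
      dt <- data.table::fread(x, sep = "\t", colClasses = list(character = "IID"))
      if (!"IID" %in% names(dt)) {
        stop(sprintf("prediction table %s lacks an IID column", x), call. = FALSE)
      }
      mat <- as.matrix(dt[, !"IID"])
      rownames(mat) <- dt$IID
      return(mat)
    }
    stop(sprintf("no .grom dataset or prediction table at %s", x), call. = FALSE)
  }
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("prediction matrices need sample rownames and column names", call. = FALSE)
    }
    return(x)
  }
  stop("unsupported prediction source (want .grom prefix, TSV path, matrix, or grom_dataset)",
       call. = FALSE)
}

#' Per-column concordance between two prediction sets
#'
#' Aligns columns by gene-model identifier and rows by sample id, then
#' computes per-column Pearson correlation and RMSE on the raw predicted
#' values, with the minimum correlation and maximum RMSE as headline
#' summaries. Constant columns (zero variance in either source) have no
#' defined correlation: they are excluded from the Pearson summary and
#' reported as skipped, but their RMSE is still computed.
#'
#' @param a,b Prediction sources: a `.grom` prefix, a TSV prediction table
#'   (`IID` + one column per gene-model pair), a named matrix, or a
#'   `grom_dataset`.
#' @param sample_draw Optional `list(count, seed)`: compare on `count`
#'   shared samples drawn once without replacement under `seed`.
#' @return A list of class `concordance_report`: `per_column` (data.table
#'   with `column`, `pearson_r`, `rmse`, `n_used`), `summary` (list:
#'   `min_pearson`, `max_rmse`, `columns_compared`, `columns_skipped_constant`,
#'   `n_samples_used`).
#' @export
concordance <- function(a, b, sample_draw = NULL) {
  ma <- as_prediction_matrix(a)
  mb <- as_prediction_matrix(b)
  cols <- intersect(colnames(ma), colnames(mb))
  rows <- intersect(rownames(ma), rownames(mb))
  if (!length(cols)) stop("no shared gene-model columns between sources", call. = FALSE)
  if (!length(rows)) stop("no shared samples between sources", call. = FALSE)
  if (!is.null(sample_draw)) {
    count <- sample_draw[[1]]
    seed <- sample_draw[[2]]
    if (count < length(rows)) {
      rows <- with_seed(seed, sample(rows, count))
      rows <- rows[order_c(match(rows, rownames(ma)))]  # keep file order
    }
  }
  ma <- ma[rows, cols, drop = FALSE]
  mb <- mb[rows, cols, drop = FALSE]
  sd_a <- apply(ma, 2, sd)
  sd_b <- apply(mb, 2, sd)
  constant <- sd_a == 0 | sd_b == 0
  r <- rep(NA_real_, length(cols))
  for (j in which(!constant)) r[j] <- cor(ma[, j], mb[, j])
  rmse <- sqrt(colMeans((ma - mb)^2))
  per_column <- data.table::data.table(
    column = cols, pearson_r = r, rmse = rmse, n_used = length(rows),
    skipped_constant = constant)
  structure(list(
    per_column = per_column[],
    summary = list(
      min_pearson = if (any(!constant)) min(r[!constant]) else NA_real_,
      max_rmse = max(rmse),
      columns_compared = sum(!constant),
      columns_skipped_constant = sum(constant),
      n_samples_used = length(rows))),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<concordance_report> %d column(s) on %d sample(s): min Pearson r = %s, ",
           "max RMSE = %s (%d constant column(s) skipped for Pearson)\n"),
    s$columns_compared + s$columns_skipped_constant, s$n_samples_used,
    format(s$min_pearson, digits = 6), format(s$max_rmse, digits = 6),
    s$columns_skipped_constant))
  invisible(x)
}
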