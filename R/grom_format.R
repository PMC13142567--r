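# The .grom/.gid/.sid output trio.
#
# .grom layout (frozen for this artifact):
#   bytes 0..7    magic "GROMv001"
#   bytes 8..15   n_rows, little-endian unsigned 64-bit (samples)
#   bytes 16..23  n_cols, little-endian unsigned 64-bit (gene-model pairs)
#   byte  24      value code: 1 = double (8 bytes), 2 = single (4 bytes)
#   bytes 25..31  reserved, zero-filled
#   bytes 32..    values, contiguous column-major; column j starts at
#                 32 + j * n_rows * value_size
# File size is exactly 32 + n_rows * n_cols * value_size.  .gid and .sid
# are header-bearing TSV sidecars mapping columns to gene-model identifiers
# and rows to samples, analogous to .pvar/.psam.

GROM_MAGIC <- "GROMv001"
GROM_HEADER_LEN <- 32L

#' @noRd
value_size <- function(code) if (code == 1L) 8L else 4L

#' @noRd
precision_code <- function(precision) {
  switch(match.arg(precision, c("double", "single")), double = 1L, single = 2L)
}

#' Create a preallocated .grom dataset and its sidecar manifests
#'
#' Preallocates the binary value matrix to its exact final size (all values
#' zero) so disk-space failures surface before computation, and writes the
#' `.gid` (column -> ancestry/model/gene, with matched-variant counts) and
#' `.sid` (row -> sample) manifests. Columns are then written individually,
#' in any order, via [write_column()].
#'
#' @param prefix Output path prefix (creates `prefix.grom`, `prefix.gid`,
#'   `prefix.sid`).
#' @param gid `data.frame`/`data.table` with columns `ancestry`, `model_ID`,
#'   `gene` and optionally `matched_variants`, in output column order.
#' @param sample_ids Analyzed sample identifiers, in output row order.
#' @param precision `"double"` (default) or `"single"` storage.
#' @param overwrite Allow replacing an existing dataset at `prefix`.
#' @return A `grom_writer` handle.
#' @export
grom_create <- function(prefix, gid, sample_ids, precision = "double",
                        overwrite = FALSE) {
  gid <- data.table::as.data.table(gid)
  need <- c("ancestry", "model_ID", "gene")
  if (!all(need %in% names(gid))) {
    stop(sprintf(".gid manifest requires columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!"matched_variants" %in% names(gid)) gid[, matched_variants := NA_integer_]
  n <- length(sample_ids)
  k <- nrow(gid)
  if (n < 1L || k < 1L) stop("a .grom dataset needs at least one row and one column",
                             call. = FALSE)
  code <- precision_code(precision)
  paths <- paste0(prefix, c(".grom", ".gid", ".sid"))
  if (any(file.exists(paths)) && !overwrite) {
    stop(sprintf("output exists at prefix %s (pass overwrite = TRUE to replace)",
                 prefix), call. = FALSE)
  }
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  con <- file(paths[1], "w+b")
  ok <- FALSE
  on.exit(if (!ok) { close(con); unlink(paths) })
  writeBin(charToRaw(GROM_MAGIC), con)
  write_u64(con, n)
  write_u64(con, k)
  writeBin(as.raw(c(code, rep(0L, 7L))), con)
  # preallocate: stream zero blocks to the exact final size
  total <- as.numeric(n) * k
  zeros <- numeric(min(total, 2^20))
  left <- total
  while (left > 0) {
    take <- min(left, length(zeros))
    writeBin(zeros[seq_len(take)], con, size = value_size(code), endian = "little")
    left <- left - take
  }
  flush(con)
  gid_out <- data.table::data.table(
    column_ordinal = seq_len(k) - 1L,
    ancestry = as.character(gid$ancestry),
    model_ID = as.character(gid$model_ID),
    gene = as.character(gid$gene),
    matched_variants = gid$matched_variants)
  data.table::fwrite(gid_out, paths[2], sep = "\t", na = "NA", quote = FALSE)
  sid_out <- data.table::data.table(row_ordinal = seq_len(n) - 1L,
                                    IID = as.character(sample_ids))
  data.table::fwrite(sid_out, paths[3], sep = "\t", quote = FALSE)
  ok <- TRUE
  w <- new.env(parent = emptyenv())
  w$con <- con
  w$prefix <- prefix
  w$n_rows <- n
  w$n_cols <- k
  w$value_code <- code
  w$written <- logical(k)
  w$open <- TRUE
  class(w) <- "grom_writer"
  w
}

#' Write one completed column into a .grom dataset
#'
#' Columns land at `32 + ordinal * n_rows * value_size` and may arrive in
#' any order; rewriting an ordinal is an error (it indicates a lifecycle
#' bug upstream). Accumulation happens in double precision regardless of
#' storage precision; single-precision datasets round here, at flush.
#'
#' @param writer A `grom_writer` from [grom_create()].
#' @param ordinal 0-based column ordinal.
#' @param values Numeric vector of length `n_rows`.
#' @export
write_column <- function(writer, ordinal, values) {
  stopifnot(inherits(writer, "grom_writer"))
  if (!writer$open) stop("grom_writer is closed", call. = FALSE)
  if (ordinal < 0L || ordinal >= writer$n_cols) {
    stop(sprintf("column ordinal %d outside [0, %d)", ordinal, writer$n_cols),
         call. = FALSE)
  }
  if (length(values) != writer$n_rows) {
    stop(sprintf("column %d: expected %d value(s), got %d",
                 ordinal, writer$n_rows, length(values)), call. = FALSE)
  }
  if (writer$written[ordinal + 1L]) {
    stop(sprintf("column %d written twice: upstream lifecycle bug", ordinal),
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop(sprintf("column %d contains non-finite value(s)", ordinal), call. = FALSE)
  }
  vs <- value_size(writer$value_code)
  seek(writer$con, where = GROM_HEADER_LEN + as.numeric(ordinal) * writer$n_rows * vs,
       origin = "start", rw = "write")
  writeBin(as.numeric(values), writer$con, size = vs, endian = "little")
  writer$written[ordinal + 1L] <- TRUE
  invisible(writer)
}

#' Finalize and close a .grom writer
#'
#' @param writer A `grom_writer`.
#' @param require_complete Error if any column was never written.
#' @export
grom_close <- function(writer, require_complete = TRUE) {
  stopifnot(inherits(writer, "grom_writer"))
  if (!writer$open) return(invisible(writer))
  if (require_complete && !all(writer$written)) {
    missing <- which(!writer$written) - 1L
    close(writer$con); writer$open <- FALSE
    stop(sprintf("%d column(s) never written (first: %d)",
                 length(missing), missing[1]), call. = FALSE)
  }
  flush(writer$con)
  close(writer$con)
  writer$open <- FALSE
  invisible(writer)
}

#' @export
print.grom_writer <- function(x, ...) {
  cat(sprintf("<grom_writer> %s: %d x %d, %s, %d/%d column(s) written\n",
              x$prefix, x$n_rows, x$n_cols,
              if (x$value_code == 1L) "double" else "single",
              sum(x$written), x$n_cols))
  invisible(x)
}

#' @noRd
read_grom_header <- function(path) {
  size <- file.size(path)
  if (is.na(size) || size < GROM_HEADER_LEN) {
    stop(sprintf("%s: missing or too small to hold a header", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 8L))
  if (!identical(magic, GROM_MAGIC)) {
    stop(sprintf("%s: bad magic %s (not a .grom file)", path, deparse(magic)),
         call. = FALSE)
  }
  n <- read_u64(con)
  k <- read_u64(con)
  code <- as.integer(readBin(con, "raw", n = 1L))
  if (!code %in% c(1L, 2L)) {
    stop(sprintf("%s: unknown value code %d", path, code), call. = FALSE)
  }
  expected <- GROM_HEADER_LEN + n * k * value_size(code)
  if (size != expected) {
    stop(sprintf("%s: corrupt dataset — file size %.0f, header implies %.0f",
                 path, size, expected), call. = FALSE)
  }
  list(n_rows = n, n_cols = k, value_code = code)
}

#' Read a .grom dataset, optionally selecting models, genes, or samples
#'
#' Selectors filter the `.gid`/`.sid` manifests: `models` and `genes` filter
#' columns (intersection when both are given), `samples` filters rows.
#' Returned columns and rows follow file order, not request order. Reading
#' is selective at the byte level: only the byte ranges of requested columns
#' are touched (32 header bytes plus `n_rows * value_size` per requested
#' column, reported in the `"bytes_read"` attribute).
#'
#' @param prefix Dataset path prefix.
#' @param models,genes,samples Optional character vectors of identifiers;
#'   unknown identifiers are an error.
#' @return A list of class `grom_dataset`: `values` (matrix, samples x
#'   columns, dimnames IID x `ancestry.model_ID.gene`), `gid`, `sid`
#'   (manifest slices). Attribute `bytes_read` counts value+header bytes
#'   touched.
#' @export
grom_read <- function(prefix, models = NULL, genes = NULL, samples = NULL) {
  paths <- paste0(prefix, c(".grom", ".gid", ".sid"))
  for (p in paths) {
    if (!file.exists(p)) stop(sprintf("missing dataset file: %s", p), call. = FALSE)
  }
  hdr <- read_grom_header(paths[1])
  gid <- data.table::fread(paths[2], sep = "\t", colClasses = list(
    character = c("ancestry", "model_ID", "gene")))
  sid <- data.table::fread(paths[3], sep = "\t", colClasses = list(character = "IID"))
  if (nrow(gid) != hdr$n_cols) {
    stop(sprintf("%s: %d row(s) but .grom holds %d column(s)",
                 paths[2], nrow(gid), hdr$n_cols), call. = FALSE)
  }
  if (nrow(sid) != hdr$n_rows) {
    stop(sprintf("%s: %d row(s) but .grom holds %d row(s)",
                 paths[3], nrow(sid), hdr$n_rows), call. = FALSE)
  }
  col_keep <- rep(TRUE, nrow(gid))
  if (!is.null(models)) {
    unknown <- setdiff(models, gid$model_ID)
    if (length(unknown)) stop(sprintf("unknown model id(s): %s",
                                      paste(unknown, collapse = ", ")), call. = FALSE)
    col_keep <- col_keep & gid$model_ID %in% models
  }
  if (!is.null(genes)) {
    unknown <- setdiff(genes, gid$gene)
    if (length(unknown)) stop(sprintf("unknown gene id(s): %s",
                                      paste(unknown, collapse = ", ")), call. = FALSE)
    col_keep <- col_keep & gid$gene %in% genes
  }
  row_keep <- rep(TRUE, nrow(sid))
  if (!is.null(samples)) {
    unknown <- setdiff(samples, sid$IID)
    if (length(unknown)) stop(sprintf("unknown sample id(s): %s",
                                      paste(unknown, collapse = ", ")), call. = FALSE)
    row_keep <- sid$IID %in% samples
  }
  if (!any(col_keep) || !any(row_keep)) {
    stop("selectors produced an empty column/row set", call. = FALSE)
  }
  sel_cols <- which(col_keep)  # 1-based, file order
  vs <- value_size(hdr$value_code)
  con <- file(paths[1], "rb")
  on.exit(close(con))
  out <- matrix(0, nrow = sum(row_keep), ncol = length(sel_cols))
  bytes_read <- GROM_HEADER_LEN
  rows_idx <- which(row_keep)
  for (j in seq_along(sel_cols)) {
    ord <- sel_cols[j] - 1L
    seek(con, where = GROM_HEADER_LEN + as.numeric(ord) * hdr$n_rows * vs,
         origin = "start")
    colvals <- readBin(con, "double", n = hdr$n_rows, size = vs, endian = "little")
    if (length(colvals) != hdr$n_rows) {
      stop(sprintf("%s: truncated read at column %d", paths[1], ord), call. = FALSE)
    }
    bytes_read <- bytes_read + hdr$n_rows * vs
    out[, j] <- colvals[rows_idx]
  }
  gid_slice <- gid[sel_cols]
  sid_slice <- sid[rows_idx]
  dimnames(out) <- list(sid_slice$IID,
                        paste(gid_slice$ancestry, gid_slice$model_ID,
                              gid_slice$gene, sep = "."))
  res <- structure(list(values = out, gid = gid_slice[], sid = sid_slice[],
                        precision = if (hdr$value_code == 1L) "double" else "single"),
                   class = "grom_dataset")
  attr(res, "bytes_read") <- bytes_read
  res
}

#' @export
print.grom_dataset <- function(x, ...) {
  cat(sprintf("<grom_dataset> %d sample(s) x %d gene-model column(s), %s precision\n",
              nrow(x$values), ncol(x$values), x$precision))
  invisible(x)
}

#' Export a .grom dataset (or a selection) to TSV
#'
#' Header is `IID` followed by `ancestry.model_ID.gene` column names; values
#' are printed with 17 significant digits so double-precision datasets
#' round-trip losslessly through the text form.
#'
#' @inheritParams grom_read
#' @param out_path Output TSV path.
#' @return `out_path`, invisibly.
#' @export
grom_export_tsv <- function(prefix, out_path, models = NULL, genes = NULL,
                            samples = NULL) {
  ds <- grom_read(prefix, models = models, genes = genes, samples = samples)
  dt <- data.table::data.table(IID = ds$sid$IID)
  vals <- ds$values
  for (j in seq_len(ncol(vals))) {
    dt[[colnames(vals)[j]]] <- sprintf("%.17g", vals[, j])
  }
  data.table::fwrite(dt, out_path, sep = "\t", quote = FALSE)
  invisible(out_path)
}
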