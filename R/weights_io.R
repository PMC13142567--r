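# Loading and indexing of GReX prediction weights.
#
# Weight tables are tab-delimited, one file per transcriptomic imputation
# model bundle, with mandatory columns chromosome, ancestry, model_ID, gene,
# rsid, weight.  effect_allele / other_allele are accepted when present;
# records without an effect allele are assumed to be oriented to the
# genotype ALT allele (post-QC convention).

WEIGHT_MANDATORY <- c("chromosome", "ancestry", "model_ID", "gene", "rsid", "weight")

#' Load a tab-delimited GReX weight table
#'
#' Parses a header-bearing delimited weight file into a validated record
#' table. Column order in the file is irrelevant; extra columns are ignored.
#' Rows with weight exactly zero are dropped (their count is attached as the
#' `"n_zero_dropped"` attribute and logged), because zero weights carry no
#' signal and would corrupt the per-column contribution counts that drive
#' the streaming engine's column flush lifecycle.
#'
#' @param path Path to the weight file.
#' @param delimiter Field separator, default tab.
#' @param verbose Emit progress messages.
#' @return A `data.table` of weight records with columns `chromosome`,
#'   `ancestry`, `model_ID`, `gene`, `rsid`, `effect_allele`, `other_allele`
#'   (both `NA` when absent from the file) and `weight`, one row per retained
#'   record.
#' @export
load_weight_table <- function(path, delimiter = "\t", verbose = FALSE) {
  if (!file.exists(path)) stop(sprintf("weight file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          colClasses = list(character = "chromosome"),
                          na.strings = NULL, data.table = TRUE)
  missing_cols <- setdiff(WEIGHT_MANDATORY, names(dt))
  if (length(missing_cols)) {
    stop(sprintf("weight file %s is missing mandatory column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (opt in c("effect_allele", "other_allele")) {
    if (!opt %in% names(dt)) dt[[opt]] <- NA_character_
  }
  dt <- dt[, c(WEIGHT_MANDATORY[1:5], "effect_allele", "other_allele", "weight"),
           with = FALSE]
  if (nrow(dt) == 0L) {
    warning(sprintf("weight file %s contains no data rows", path), call. = FALSE)
    return(empty_weight_records(n_zero = 0L))
  }
  # weight must parse to a finite number; "." and "" are not permitted
  w_chr <- as.character(dt$weight)
  w <- suppressWarnings(as.numeric(w_chr))
  bad <- which(!is.finite(w) | w_chr %in% c("", "."))
  if (length(bad)) {
    stop(sprintf(
      "weight file %s: unparseable or non-finite weight %s on line %d (data row %d)",
      path, deparse(w_chr[bad[1]]), bad[1] + 1L, bad[1]), call. = FALSE)
  }
  dt[, weight := w]
  assert_chromosome(dt$chromosome, "weight-table chromosome")
  n_zero <- sum(dt$weight == 0)
  if (n_zero > 0L) {
    dt <- dt[weight != 0]
    grom_log("dropped %d zero-weight record(s) from %s", n_zero, path, verbose = verbose)
  }
  if (nrow(dt) == 0L) {
    warning(sprintf("weight file %s is empty after zero-weight filtering", path),
            call. = FALSE)
  }
  for (col in c("ancestry", "model_ID", "gene", "rsid", "effect_allele", "other_allele")) {
    data.table::set(dt, j = col, value = as.character(dt[[col]]))
  }
  dt[effect_allele %in% c("", "."), effect_allele := NA_character_]
  dt[other_allele %in% c("", "."), other_allele := NA_character_]
  data.table::setattr(dt, "n_zero_dropped", n_zero)
  dt[]
}

#' @noRd
empty_weight_records <- function(n_zero = 0L) {
  dt <- data.table::data.table(
    chromosome = character(), ancestry = character(), model_ID = character(),
    gene = character(), rsid = character(), effect_allele = character(),
    other_allele = character(), weight = numeric())
  data.table::setattr(dt, "n_zero_dropped", n_zero)
  dt
}

#' Import a PrediXcan-style SQLite weight model
#'
#' Reads the `weights` table (`rsid`, `gene`, `weight`, `ref_allele`,
#' `eff_allele`) of a PrediXcan `.db` model into the same record layout as
#' [load_weight_table()]. PrediXcan models identify the tissue/model by file
#' name only and carry no ancestry or chromosome, so `model_id` and
#' `ancestry` must be supplied by the caller; the chromosome of each record
#' is resolved later against the genotype variant manifests.
#'
#' The database is read through the system `python3` interpreter (standard
#' library `sqlite3`), declared in the package's SystemRequirements.
#'
#' @param path Path to the `.db` file.
#' @param model_id Model identifier to assign to every record.
#' @param ancestry Ancestry label to assign to every record.
#' @param verbose Emit progress messages.
#' @return A `data.table` of weight records (see [load_weight_table()]);
#'   `chromosome` is `NA` and `other_allele` carries the model's
#'   `ref_allele`.
#' @export
load_predixcan_db <- function(path, model_id, ancestry = "unspecified", verbose = FALSE) {
  if (!file.exists(path)) stop(sprintf(".db file not found: %s", path), call. = FALSE)
  if (missing(model_id) || !nzchar(model_id)) {
    stop("load_predixcan_db() requires a caller-supplied model_id", call. = FALSE)
  }
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  script <- paste(
    "import sys, sqlite3, csv",
    "db, out = sys.argv[1], sys.argv[2]",
    "con = sqlite3.connect(db)",
    "cur = con.cursor()",
    "tabs = {r[0] for r in cur.execute(\"SELECT name FROM sqlite_master WHERE type='table'\")}",
    "if 'weights' not in tabs:",
    "    sys.stderr.write('NO_WEIGHTS_TABLE'); sys.exit(3)",
    "cols = [r[1] for r in cur.execute('PRAGMA table_info(weights)')]",
    "need = ['rsid', 'gene', 'weight', 'ref_allele', 'eff_allele']",
    "miss = [c for c in need if c not in cols]",
    "if miss:",
    "    sys.stderr.write('MISSING_FIELD:' + ','.join(miss)); sys.exit(4)",
    "w = csv.writer(open(out, 'w', newline=''), delimiter='\\t')",
    "w.writerow(need)",
    "for row in cur.execute('SELECT rsid, gene, weight, ref_allele, eff_allele FROM weights'):",
    "    w.writerow(row)",
    sep = "\n")
  res <- suppressWarnings(
    system2(python_binary(), c("-c", shQuote(script), shQuote(path), shQuote(out)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    msg <- paste(res, collapse = " ")
    if (grepl("NO_WEIGHTS_TABLE", msg)) {
      stop(sprintf("%s is not a PrediXcan weight model: no 'weights' table", path),
           call. = FALSE)
    }
    if (grepl("MISSING_FIELD:", msg)) {
      fields <- sub(".*MISSING_FIELD:", "", msg)
      stop(sprintf("%s: weights table lacks expected field(s): %s", path, fields),
           call. = FALSE)
    }
    stop(sprintf("failed to read SQLite database %s: %s", path, msg), call. = FALSE)
  }
  raw <- data.table::fread(out, sep = "\t", header = TRUE, na.strings = NULL)
  dt <- data.table::data.table(
    chromosome = NA_character_,
    ancestry = as.character(ancestry),
    model_ID = as.character(model_id),
    gene = as.character(raw$gene),
    rsid = as.character(raw$rsid),
    effect_allele = as.character(raw$eff_allele),
    other_allele = as.character(raw$ref_allele),
    weight = as.numeric(raw$weight))
  bad <- which(!is.finite(dt$weight))
  if (length(bad)) {
    stop(sprintf("%s: non-finite weight in weights table row %d", path, bad[1]),
         call. = FALSE)
  }
  n_zero <- sum(dt$weight == 0)
  if (n_zero > 0L) dt <- dt[weight != 0]
  if (nrow(dt) == 0L) {
    warning(sprintf("%s: weights table empty after filtering", path), call. = FALSE)
  }
  grom_log("imported %d weight record(s) from %s as model '%s'",
           nrow(dt), path, model_id, verbose = verbose)
  data.table::setattr(dt, "n_zero_dropped", n_zero)
  dt[]
}

#' Build the column catalog and variant-indexed sparse weight structure
#'
#' The catalog enumerates the distinct (ancestry, model_ID, gene) triples —
#' the k output columns — in deterministic sorted (C-locale) order, so the
#' output column space is a function of the weight records alone, regardless
#' of file or row order. The sparse index groups weight entries by variant
#' identifier so the engine can visit, per genotype variant, only the
#' columns with nonzero weight.
#'
#' @param records Weight records from [load_weight_table()] /
#'   [load_predixcan_db()] (several inputs may be concatenated with `rbind`).
#' @return A list with elements `catalog` (class `grom_catalog`: `columns`
#'   data.table with 0-based `col`, `ancestry`, `model_ID`, `gene`; `k`) and
#'   `index` (class `grom_weight_index`: `entries` keyed by `rsid`,
#'   `n_variants_with_weights`, `per_column_variant_count`).
#' @export
build_weight_index <- function(records) {
  records <- data.table::as.data.table(records)
  cols <- unique(records[, .(ancestry, model_ID, gene)])
  cols <- cols[order_c(ancestry, model_ID, gene)]
  cols[, col := seq_len(.N) - 1L]
  data.table::setcolorder(cols, c("col", "ancestry", "model_ID", "gene"))
  catalog <- structure(list(columns = cols[], k = nrow(cols)), class = "grom_catalog")

  entries <- merge(records, cols, by = c("ancestry", "model_ID", "gene"), sort = FALSE)
  dup <- entries[, .N, by = .(rsid, col)][N > 1L]
  if (nrow(dup)) {
    ex <- merge(dup[1, .(rsid, col)], entries, by = c("rsid", "col"))[1]
    stop(sprintf(
      paste0("duplicate weight entry for variant %s in column (%s, %s, %s): ",
             "ambiguous model specification"),
      ex$rsid, ex$ancestry, ex$model_ID, ex$gene), call. = FALSE)
  }
  entries <- entries[, .(rsid, chromosome, effect_allele, other_allele, col, weight)]
  entries <- entries[order_c(rsid, col)]
  data.table::setkey(entries, rsid)
  per_col <- integer(catalog$k)
  if (nrow(entries)) {
    cnt <- entries[, .N, by = col]
    per_col[cnt$col + 1L] <- cnt$N
  }
  index <- structure(list(
    entries = entries[],
    n_variants_with_weights = data.table::uniqueN(entries$rsid),
    per_column_variant_count = per_col), class = "grom_weight_index")
  list(catalog = catalog, index = index)
}

#' @export
print.grom_catalog <- function(x, ...) {
  cat(sprintf("<grom_catalog> %d gene-model column(s), %d model(s), %d gene(s)\n",
              x$k, data.table::uniqueN(x$columns$model_ID),
              data.table::uniqueN(x$columns$gene)))
  invisible(x)
}

#' @export
print.grom_weight_index <- function(x, ...) {
  cat(sprintf("<grom_weight_index> %d entrie(s) over %d variant(s), %d column(s)\n",
              nrow(x$entries), x$n_variants_with_weights,
              length(x$per_column_variant_count)))
  invisible(x)
}
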