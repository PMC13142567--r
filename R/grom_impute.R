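# End-to-end imputation pipeline: discover chromosome filesets, load and
# index weights, harmonize, stream, and write the .grom/.gid/.sid trio plus
# the meta/ audit directory.

#' Impute individual-level GReX into a .grom dataset
#'
#' Runs the full pipeline over chromosome-split genotype filesets: loads
#' weights (TSV and/or PrediXcan `.db`), builds the global column catalog,
#' resolves each chromosome's fileset by exact chr-token matching,
#' harmonizes every weight entry to a genotype ordinal and dosage
#' transform, streams dosages in SNP chunks, and writes predictions into a
#' preallocated column-major `.grom` with `.gid`/`.sid` manifests.
#' Chromosomes are processed in natural order (chr1, chr2, ..., chr10, ...)
#' so output columns and audit files are reproducible byte for byte across
#' runs.
#'
#' Audit outputs land in `meta/` beside the output prefix: the
#' chromosome-to-fileset mapping, the per-entry harmonization report, the
#' per-column coverage table, and a run summary (no timestamps, so repeated
#' runs are byte-identical).
#'
#' Each gene-model column must be chromosome-local (cis models are); a
#' column whose matched variants span chromosomes is a hard error. `.db`
#' records carry no chromosome and are routed to the (single) chromosome
#' whose `.pvar` contains their rsid; rsids found on several chromosomes
#' are reported unmatched.
#'
#' @param weights_path Path(s) to tab-delimited weight tables (may be
#'   `NULL` when only `db` inputs are given).
#' @param pgen_dir Directory holding the chromosome-split filesets.
#' @param grom_pfx Output prefix for the `.grom`/`.gid`/`.sid` trio.
#' @param samples Optional path to a sample-subset file (one IID per line)
#'   or character vector of IIDs.
#' @param db Optional named list/vector of PrediXcan `.db` paths; names (or
#'   `db_model_id`) supply the model identifiers.
#' @param db_model_id,db_ancestry Model/ancestry labels for `.db` imports
#'   (recycled across `db`).
#' @param config An [engine_config()].
#' @param overwrite Replace an existing dataset at `grom_pfx`.
#' @param verbose Log progress to stderr.
#' @return Invisibly, a run summary list: per-chromosome engine summaries,
#'   entry accounting (`n_loaded` = `n_matched` + `n_unmatched` +
#'   `n_ambiguous`), catalog size, output paths.
#' @export
grom_impute <- function(weights_path = NULL, pgen_dir, grom_pfx,
                        samples = NULL, db = NULL, db_model_id = names(db),
                        db_ancestry = "unspecified",
                        config = engine_config(), overwrite = FALSE,
                        verbose = TRUE) {
  if (is.null(weights_path) && is.null(db)) {
    stop("no weights given: supply weights_path and/or db", call. = FALSE)
  }
  records <- list()
  for (p in weights_path) {
    records[[length(records) + 1L]] <- load_weight_table(p, verbose = verbose)
  }
  if (!is.null(db)) {
    if (is.null(db_model_id)) {
      stop(".db imports need model identifiers (db_model_id or names(db))",
           call. = FALSE)
    }
    db_ancestry <- rep_len(db_ancestry, length(db))
    db_model_id <- rep_len(db_model_id, length(db))
    for (i in seq_along(db)) {
      records[[length(records) + 1L]] <-
        load_predixcan_db(db[[i]], model_id = db_model_id[[i]],
                          ancestry = db_ancestry[[i]], verbose = verbose)
    }
  }
  records <- data.table::rbindlist(records)
  if (nrow(records) == 0L) stop("no weight records loaded", call. = FALSE)
  built <- build_weight_index(records)
  catalog <- built$catalog
  index <- built$index
  grom_log("loaded %d weight record(s) over %d column(s)",
           nrow(records), catalog$k, verbose = verbose)

  # chromosome set: stated labels plus NA (.db) records routed by rsid below
  chroms <- chrom_sort(unique(records$chromosome[!is.na(records$chromosome)]))
  has_na_chrom <- anyNA(records$chromosome)
  if (!length(chroms) && has_na_chrom) {
    # .db-only input: consider every discoverable chromosome
    pvars <- list.files(pgen_dir, pattern = "\\.pvar$")
    toks <- regmatches(pvars, regexpr("chr[0-9XY]+", pvars))
    chroms <- chrom_sort(unique(toks))
    if (!length(chroms)) {
      stop(sprintf("no chromosome-split filesets discoverable in %s", pgen_dir),
           call. = FALSE)
    }
  }
  file_map <- discover_chromosome_files(pgen_dir, chroms)

  manifests <- lapply(chroms, function(ch) parse_pvar(paste0(file_map[[ch]], ".pvar")))
  names(manifests) <- chroms

  # sample set: identical .psam contents are required across chromosomes
  sets <- lapply(chroms, function(ch) parse_psam(paste0(file_map[[ch]], ".psam")))
  for (s in sets[-1]) {
    if (!identical(s$all_ids, sets[[1]]$all_ids)) {
      stop("chromosome filesets disagree on .psam sample lists", call. = FALSE)
    }
  }
  sample_set <- sets[[1]]
  if (!is.null(samples)) {
    ids <- if (length(samples) == 1L && file.exists(samples))
      readLines(samples) else as.character(samples)
    ids <- ids[nzchar(ids)]
    sample_set <- subset_samples(sample_set, ids)
  }
  n <- length(sample_set$analyzed)

  # route records lacking a chromosome (.db imports) by rsid lookup
  if (has_na_chrom) {
    na_idx <- which(is.na(records$chromosome))
    for (i in na_idx) {
      hits <- chroms[vapply(chroms, function(ch) {
        o <- manifests[[ch]]$id_index[[records$rsid[i]]]
        !is.null(o) && o >= 0L
      }, logical(1))]
      records$chromosome[i] <- if (length(hits) == 1L) hits else NA_character_
    }
  }

  # harmonize per chromosome
  matched_list <- list()
  reports <- list()
  for (ch in chroms) {
    recs_ch <- records[records$chromosome %in% ch]
    if (nrow(recs_ch) == 0L) next
    matched_list[[ch]] <- suppressWarnings(
      build_matched_index(recs_ch, catalog, manifests[[ch]], index))
    rep_ch <- data.table::copy(matched_list[[ch]]$report)
    rep_ch[, chromosome := ch]
    reports[[ch]] <- rep_ch
    grom_log("%s: %d matched / %d unmatched / %d ambiguous entrie(s)",
             ch, matched_list[[ch]]$n_matched, matched_list[[ch]]$n_unmatched,
             matched_list[[ch]]$n_ambiguous, verbose = verbose)
  }
  # records still without a chromosome (.db rsids absent or on >1 chromosome)
  n_unrouted <- sum(is.na(records$chromosome))
  if (n_unrouted > 0L) {
    unrouted <- records[is.na(records$chromosome)]
    ur <- merge(unrouted, catalog$columns, by = c("ancestry", "model_ID", "gene"),
                sort = FALSE)
    reports[["unrouted"]] <- data.table::data.table(
      rsid = ur$rsid, ancestry = ur$ancestry, model_ID = ur$model_ID,
      gene = ur$gene, col = ur$col, status = "unmatched",
      genotype_ordinal = NA_integer_, dosage_transform = NA_character_,
      chromosome = NA_character_)
  }
  report <- data.table::rbindlist(reports)

  # a column's matched variants must be chromosome-local
  col_chroms <- unique(report[!status %in% c("unmatched", "ambiguous_strand"),
                              .(col, chromosome)])
  split_cols <- col_chroms[, .N, by = col][N > 1L]
  if (nrow(split_cols)) {
    ex <- catalog$columns[col == split_cols$col[1]]
    stop(sprintf(
      "column (%s, %s, %s) has matched variants on multiple chromosomes; gene-model columns must be chromosome-local",
      ex$ancestry, ex$model_ID, ex$gene), call. = FALSE)
  }

  # coverage and gid manifest
  coverage <- report[, .(
    n_weights = .N,
    matched_variants = sum(!status %in% c("unmatched", "ambiguous_strand"))),
    by = col]
  coverage <- merge(data.table::data.table(col = catalog$columns$col), coverage,
                    by = "col", all.x = TRUE, sort = TRUE)
  coverage[is.na(n_weights), `:=`(n_weights = 0L, matched_variants = 0L)]
  coverage[, coverage_fraction := ifelse(n_weights > 0L,
                                         matched_variants / n_weights, 0)]
  gid <- data.table::copy(catalog$columns)
  gid[, matched_variants := coverage$matched_variants]

  writer <- grom_create(grom_pfx, gid = gid, sample_ids = sample_set$analyzed,
                        precision = config$value_precision, overwrite = overwrite)
  ok <- FALSE
  on.exit(if (!ok) {
    try(grom_close(writer, require_complete = FALSE), silent = TRUE)
    unlink(paste0(grom_pfx, c(".grom", ".gid", ".sid")))
  })

  summaries <- list()
  zero_written <- 0L
  for (ch in names(matched_list)) {
    src <- open_genotype_source(file_map[[ch]], sample_set,
                                manifest = manifests[[ch]])
    summaries[[ch]] <- stream_impute(src, matched_list[[ch]], sample_set,
                                     config = config, sink = writer,
                                     finalize = FALSE)
    grom_log("%s: %d variant(s) streamed, %d column(s) flushed, peak %d active",
             ch, summaries[[ch]]$variants_processed,
             summaries[[ch]]$columns_written,
             summaries[[ch]]$peak_active_columns, verbose = verbose)
  }
  # catalog columns untouched by any chromosome: all-zero predictions
  never <- which(!writer$written) - 1L
  for (z in never) {
    write_column(writer, z, numeric(n))
    zero_written <- zero_written + 1L
  }
  grom_close(writer)
  ok <- TRUE

  # meta/ audit directory
  meta_dir <- file.path(dirname(grom_pfx), "meta")
  dir.create(meta_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(
    data.table::data.table(chromosome = chroms, fileset_prefix = unname(file_map)),
    file.path(meta_dir, "chromosome_file_map.tsv"), sep = "\t", quote = FALSE)
  triples <- catalog$columns
  report_out <- report[order_c(chromosome, rsid, col)]
  data.table::fwrite(report_out, file.path(meta_dir, "match_report.tsv"),
                     sep = "\t", quote = FALSE, na = "NA")
  cov_out <- merge(triples, coverage, by = "col", sort = TRUE)
  data.table::fwrite(cov_out, file.path(meta_dir, "column_coverage.tsv"),
                     sep = "\t", quote = FALSE)
  accounting <- list(
    n_loaded = nrow(report),
    n_matched = sum(!report$status %in% c("unmatched", "ambiguous_strand")),
    n_unmatched = sum(report$status == "unmatched"),
    n_ambiguous = sum(report$status == "ambiguous_strand"))
  run <- data.table::data.table(
    setting = c("n_samples_analyzed", "n_columns", "n_chromosomes",
            "n_entries_loaded", "n_entries_matched", "n_entries_unmatched",
            "n_entries_ambiguous", "n_zero_matched_columns",
            "snp_chunk_size", "row_chunk_size", "value_precision",
            "flush_batch_size", "peak_active_columns", "n_imputed_missing"),
    value = c(n, catalog$k, length(chroms),
              accounting$n_loaded, accounting$n_matched,
              accounting$n_unmatched, accounting$n_ambiguous,
              sum(gid$matched_variants == 0L),
              config$snp_chunk_size, config$row_chunk_size,
              config$value_precision, config$flush_batch_size,
              max(c(0L, vapply(summaries, `[[`, integer(1), "peak_active_columns"))),
              sum(vapply(summaries, `[[`, numeric(1), "n_imputed_missing"))))
  data.table::fwrite(run, file.path(meta_dir, "run_summary.tsv"),
                     sep = "\t", quote = FALSE)
  grom_log("wrote %s.grom (%d x %d) + manifests + meta/", grom_pfx, n, catalog$k,
           verbose = verbose)
  invisible(list(grom_pfx = grom_pfx, meta_dir = meta_dir,
                 accounting = accounting, catalog_k = catalog$k,
                 n_samples = n, chromosomes = chroms,
                 engine = summaries))
}
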