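# Chromosome-split genotype filesets: manifest parsing, discovery, and
# chunked dosage streaming.
#
# A fileset is <prefix>.pvar + <prefix>.psam + one genotype payload:
#   <prefix>.pgen        fixed-width 2-bit hard-call payload (PLINK1
#                        variant-major .bed layout, magic 6C 1B 01 — a valid
#                        PLINK2 .pgen storage mode); dosage-precision pgen
#                        storage modes require pgenlib and are rejected.
#   <prefix>.dosage.tsv  plain-text dosage matrix fallback (one row per
#                        variant in .pvar order, one column per .psam
#                        sample, "NA" for missing) — a fixture/testing
#                        format, not a production input.
# Dosages count copies of the .pvar ALT allele; missing values are
# mean-imputed per variant over the analyzed samples at read time.

#' Parse a PLINK2 .pvar variant manifest
#'
#' Reads `##` header lines then the `#CHROM POS ID REF ALT` table. All
#' records must share one chromosome (the chromosome-split contract).
#' Multi-allelic records (comma-separated ALT) are retained in the ID index
#' but flagged non-matchable for harmonization.
#'
#' @param path Path to the `.pvar` file.
#' @return An object of class `pvar_manifest`: `records` (data.table with
#'   0-based `ordinal`, `id`, `chromosome`, `position`, `ref`, `alt`,
#'   `biallelic`), `chromosome`, `n_variants`, `id_index` and `cpra_index`
#'   (environments mapping key -> 0-based ordinal).
#' @export
parse_pvar <- function(path) {
  if (!file.exists(path)) stop(sprintf(".pvar not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  body_at <- which(!startsWith(lines, "##"))
  if (!length(body_at) || !startsWith(lines[body_at[1]], "#CHROM")) {
    stop(sprintf("%s: missing #CHROM header line", path), call. = FALSE)
  }
  hdr <- strsplit(sub("^#", "", lines[body_at[1]]), "\t", fixed = TRUE)[[1]]
  need <- c("CHROM", "POS", "ID", "REF", "ALT")
  if (!all(need %in% hdr)) {
    stop(sprintf("%s: .pvar header lacks column(s): %s", path,
                 paste(setdiff(need, hdr), collapse = ", ")), call. = FALSE)
  }
  dt <- data.table::fread(text = lines[seq(body_at[1] + 1L, length(lines))],
                          sep = "\t", header = FALSE, col.names = hdr,
                          colClasses = "character")
  rec <- data.table::data.table(
    ordinal = seq_len(nrow(dt)) - 1L,
    id = dt$ID,
    chromosome = dt$CHROM,
    position = as.integer(dt$POS),
    ref = dt$REF,
    alt = dt$ALT)
  chroms <- unique(rec$chromosome)
  if (length(chroms) > 1L) {
    stop(sprintf("%s: mixed chromosomes in one .pvar (%s); filesets must be chromosome-split",
                 path, paste(chroms, collapse = ", ")), call. = FALSE)
  }
  rec[, biallelic := !grepl(",", alt, fixed = TRUE)]
  id_index <- new.env(parent = emptyenv(), size = nrow(rec))
  cpra_index <- new.env(parent = emptyenv(), size = nrow(rec))
  for (i in seq_len(nrow(rec))) {
    id <- rec$id[i]
    if (!is.null(id_index[[id]])) {
      # duplicated IDs cannot be matched by rsid; mark ambiguous
      id_index[[id]] <- -1L
    } else {
      id_index[[id]] <- rec$ordinal[i]
    }
    if (rec$biallelic[i]) {
      cpra_index[[cpra_key(rec$position[i], rec$ref[i], rec$alt[i])]] <- rec$ordinal[i]
    }
  }
  structure(list(records = rec[], chromosome = chroms, n_variants = nrow(rec),
                 id_index = id_index, cpra_index = cpra_index),
            class = "pvar_manifest")
}

#' @noRd
cpra_key <- function(position, ref, alt) paste(position, ref, alt, sep = ":")

#' @export
print.pvar_manifest <- function(x, ...) {
  cat(sprintf("<pvar_manifest> %s: %d variant(s), %d biallelic\n",
              x$chromosome, x$n_variants, sum(x$records$biallelic)))
  invisible(x)
}

#' Parse a PLINK2 .psam sample manifest
#'
#' @param path Path to the `.psam` file (`#IID` or `#FID IID` header).
#' @return An object of class `sample_set`: `all_ids` (file order),
#'   `analyzed` (ids), `analyzed_ordinals` (0-based positions in `all_ids`).
#' @export
parse_psam <- function(path) {
  if (!file.exists(path)) stop(sprintf(".psam not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (!"IID" %in% hdr) stop(sprintf("%s: .psam header lacks IID", path), call. = FALSE)
  dt <- data.table::fread(text = lines[-1], sep = "\t", header = FALSE,
                          col.names = hdr, colClasses = "character")
  ids <- dt$IID
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate IID(s): %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  structure(list(all_ids = ids, analyzed = ids,
                 analyzed_ordinals = seq_along(ids) - 1L),
            class = "sample_set")
}

#' Restrict a sample set to a subset of individuals
#'
#' The analyzed subset preserves `.psam` order regardless of request order,
#' so downstream buffers and output rows are sized and ordered identically
#' for any permutation of the same request.
#'
#' @param sample_set A `sample_set` from [parse_psam()].
#' @param ids Character vector of sample identifiers to analyze.
#' @return The `sample_set` with `analyzed`/`analyzed_ordinals` restricted.
#' @export
subset_samples <- function(sample_set, ids) {
  stopifnot(inherits(sample_set, "sample_set"))
  unknown <- setdiff(ids, sample_set$all_ids)
  if (length(unknown)) {
    stop(sprintf("unknown sample id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  keep <- sample_set$all_ids %in% ids
  sample_set$analyzed <- sample_set$all_ids[keep]
  sample_set$analyzed_ordinals <- which(keep) - 1L
  sample_set
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d sample(s), %d analyzed\n",
              length(x$all_ids), length(x$analyzed)))
  invisible(x)
}

#' Discover chromosome-split genotype filesets by chr token
#'
#' Scans a directory for `.pvar` filesets whose names contain the literal
#' requested chromosome token. Matching is token-exact: the label must be
#' delimited by non-alphanumeric characters or string boundaries, so a
#' request for `chr1` never matches a `chr11` fileset. Zero or multiple
#' candidates for a requested chromosome are hard errors — ambiguity is
#' never resolved silently.
#'
#' @param pgen_dir Directory containing the filesets.
#' @param chromosomes Character vector of `chr*` labels to resolve.
#' @return Named character vector mapping chromosome label -> fileset prefix
#'   (path without extension).
#' @export
discover_chromosome_files <- function(pgen_dir, chromosomes) {
  if (!dir.exists(pgen_dir)) {
    stop(sprintf("genotype directory not found: %s", pgen_dir), call. = FALSE)
  }
  assert_chromosome(chromosomes, "requested chromosome")
  pvars <- list.files(pgen_dir, pattern = "\\.pvar$", full.names = TRUE)
  prefixes <- sub("\\.pvar$", "", pvars)
  out <- character(0)
  for (chrom in chromosomes) {
    # token-exact: chr label bounded by non-alphanumerics or string edges
    pat <- paste0("(^|[^A-Za-z0-9])", chrom, "($|[^A-Za-z0-9])")
    hits <- prefixes[grepl(pat, basename(prefixes))]
    if (length(hits) == 0L) {
      stop(sprintf("no genotype fileset found for %s in %s", chrom, pgen_dir),
           call. = FALSE)
    }
    if (length(hits) > 1L) {
      stop(sprintf("ambiguous genotype filesets for %s: %s", chrom,
                   paste(basename(hits), collapse = ", ")), call. = FALSE)
    }
    psam <- paste0(hits, ".psam")
    if (!file.exists(psam)) {
      stop(sprintf("fileset %s lacks companion .psam", basename(hits)), call. = FALSE)
    }
    if (!file.exists(paste0(hits, ".pgen")) &&
        !file.exists(paste0(hits, ".dosage.tsv"))) {
      stop(sprintf("fileset %s lacks a genotype payload (.pgen or .dosage.tsv)",
                   basename(hits)), call. = FALSE)
    }
    out[chrom] <- hits
  }
  out
}

#' Open a streaming dosage source for a fileset
#'
#' Returns a source whose [read_dosage_chunk()] yields dosage blocks already
#' restricted to the analyzed samples, so downstream buffers are sized only
#' to the analyzed individuals. Missing dosages are mean-imputed per variant
#' over the analyzed samples (0 if all missing); imputation events are
#' counted on the source.
#'
#' Two backends satisfy the same contract: the binary 2-bit hard-call
#' payload (`.pgen`) and the plain-text dosage matrix (`.dosage.tsv`, used
#' by the fixture generator). When both are present the binary payload wins.
#'
#' @param prefix Fileset prefix (path without extension).
#' @param sample_set A `sample_set`; its analyzed subset drives row selection.
#' @param manifest Optional pre-parsed `pvar_manifest` (parsed from
#'   `<prefix>.pvar` when omitted); variant counts are cross-checked.
#' @param backend `"auto"`, `"pgen"` or `"text"`.
#' @return An object of class `dosage_source`.
#' @export
open_genotype_source <- function(prefix, sample_set, manifest = NULL,
                                 backend = c("auto", "pgen", "text")) {
  backend <- match.arg(backend)
  stopifnot(inherits(sample_set, "sample_set"))
  if (is.null(manifest)) manifest <- parse_pvar(paste0(prefix, ".pvar"))
  stopifnot(inherits(manifest, "pvar_manifest"))
  pgen <- paste0(prefix, ".pgen")
  txt <- paste0(prefix, ".dosage.tsv")
  if (backend == "auto") backend <- if (file.exists(pgen)) "pgen" else "text"
  src <- if (backend == "pgen") {
    open_pgen_source(pgen, manifest, sample_set)
  } else {
    open_text_source(txt, manifest, sample_set)
  }
  src
}

#' Read a contiguous block of variants from a dosage source
#'
#' @param source A `dosage_source` from [open_genotype_source()].
#' @param start 0-based first variant ordinal of the block.
#' @param length Number of variants to read.
#' @return A list: `variant_ordinals` (0-based), `values` (matrix, analyzed
#'   samples x variants, every value in `[0, 2]` after mean imputation),
#'   `n_imputed` (per-variant count of imputed missing entries).
#' @export
read_dosage_chunk <- function(source, start, length) {
  UseMethod("read_dosage_chunk")
}

#' @noRd
check_chunk_bounds <- function(source, start, length) {
  if (length < 1L || start < 0L || start + length > source$n_variants) {
    stop(sprintf(
      "chunk [%d, %d) outside variant range [0, %d): read past end of source",
      start, start + length, source$n_variants), call. = FALSE)
  }
}

# mean-impute missing entries per variant over the analyzed samples
#' @noRd
impute_missing <- function(values) {
  n_imputed <- integer(ncol(values))
  miss <- is.na(values)
  if (any(miss)) {
    for (j in which(colSums(miss) > 0L)) {
      mj <- miss[, j]
      mu <- if (all(mj)) 0 else mean(values[!mj, j])
      values[mj, j] <- mu
      n_imputed[j] <- sum(mj)
    }
  }
  list(values = values, n_imputed = n_imputed)
}

## ---- text backend -------------------------------------------------------

#' @noRd
open_text_source <- function(path, manifest, sample_set) {
  if (!file.exists(path)) stop(sprintf("dosage file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, na.strings = "NA")
  if (nrow(dt) != manifest$n_variants) {
    stop(sprintf("%s: %d dosage row(s) but .pvar lists %d variant(s)",
                 path, nrow(dt), manifest$n_variants), call. = FALSE)
  }
  if (ncol(dt) != length(sample_set$all_ids)) {
    stop(sprintf("%s: %d dosage column(s) but .psam lists %d sample(s)",
                 path, ncol(dt), length(sample_set$all_ids)), call. = FALSE)
  }
  # variants are rows in the file; keep samples x variants in memory
  full <- t(as.matrix(dt))
  dimnames(full) <- NULL
  rng <- range(full, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop(sprintf("%s: dosage values outside [0, 2]", path), call. = FALSE)
  }
  structure(list(
    kind = "text", path = path,
    n_variants = manifest$n_variants,
    sample_ids = sample_set$analyzed,
    row_sel = sample_set$analyzed_ordinals + 1L,
    full = full,
    n_imputed_total = 0L),
    class = c("text_dosage_source", "dosage_source"))
}

#' @export
read_dosage_chunk.text_dosage_source <- function(source, start, length) {
  check_chunk_bounds(source, start, length)
  cols <- seq.int(start + 1L, start + length)
  vals <- source$full[source$row_sel, cols, drop = FALSE]
  imp <- impute_missing(vals)
  list(variant_ordinals = cols - 1L, values = imp$values, n_imputed = imp$n_imputed)
}

## ---- 2-bit hard-call binary backend -------------------------------------

# decode table: byte -> 4 dosage codes (low bits first), .bed convention:
# 00 = 2 ALT copies, 10 = het, 11 = 0 copies, 01 = missing (NA)
#' @noRd
bed_decode_table <- function() {
  codes <- c(2, NA, 1, 0)  # index by 2-bit value + 1
  tab <- matrix(0, nrow = 256, ncol = 4)
  for (b in 0:255) {
    tab[b + 1L, ] <- codes[c(
      bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
      bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L)) + 1L]
  }
  tab
}

#' @noRd
open_pgen_source <- function(path, manifest, sample_set) {
  if (!file.exists(path)) stop(sprintf(".pgen not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 3L)
  close(con)
  if (length(magic) < 3L || magic[1] != as.raw(0x6c) || magic[2] != as.raw(0x1b)) {
    stop(sprintf("%s: not a .pgen file (bad magic)", path), call. = FALSE)
  }
  if (magic[3] != as.raw(0x01)) {
    stop(sprintf(
      paste0("%s: unsupported .pgen storage mode 0x%02x; only the fixed-width ",
             "2-bit hard-call payload (mode 0x01) is supported"),
      path, as.integer(magic[3])), call. = FALSE)
  }
  n_all <- length(sample_set$all_ids)
  bpv <- ceiling(n_all / 4)  # bytes per variant
  expected <- 3 + bpv * manifest$n_variants
  actual <- file.size(path)
  if (actual != expected) {
    stop(sprintf(
      "%s: size %d does not match %d variant(s) x %d sample(s) from manifests (expected %d)",
      path, actual, manifest$n_variants, n_all, expected), call. = FALSE)
  }
  structure(list(
    kind = "pgen", path = path,
    n_variants = manifest$n_variants,
    n_all = n_all, bytes_per_variant = bpv,
    sample_ids = sample_set$analyzed,
    row_sel = sample_set$analyzed_ordinals + 1L,
    decode = bed_decode_table(),
    n_imputed_total = 0L),
    class = c("pgen_dosage_source", "dosage_source"))
}

#' @export
read_dosage_chunk.pgen_dosage_source <- function(source, start, length) {
  check_chunk_bounds(source, start, length)
  con <- file(source$path, "rb")
  on.exit(close(con))
  seek(con, where = 3 + source$bytes_per_variant * start, origin = "start")
  raw <- readBin(con, "raw", n = source$bytes_per_variant * length)
  if (length(raw) < source$bytes_per_variant * length) {
    stop(sprintf("%s: truncated genotype payload", source$path), call. = FALSE)
  }
  # decode bytes -> 4 samples each, variant-major; then cut to n_all rows
  dec <- source$decode[as.integer(raw) + 1L, , drop = FALSE]
  # dec rows follow raw order: for each variant, bpv bytes x 4 codes
  per_var <- source$bytes_per_variant * 4L
  vals <- matrix(t(dec), nrow = per_var)[seq_len(source$n_all), , drop = FALSE]
  vals <- vals[source$row_sel, , drop = FALSE]
  imp <- impute_missing(vals)
  list(variant_ordinals = seq.int(start, start + length - 1L),
       values = imp$values, n_imputed = imp$n_imputed)
}

#' Write a 2-bit hard-call genotype payload
#'
#' Encodes integer dosage hard calls (0/1/2 copies of ALT, `NA` missing) in
#' the fixed-width variant-major 2-bit layout read by the binary backend.
#' Used by the fixture generator; exported so round-trip behaviour is
#' testable.
#'
#' @param path Output `.pgen` path.
#' @param dosages Integer matrix, samples x variants, values 0/1/2/`NA`.
#' @export
write_pgen_hardcalls <- function(path, dosages) {
  stopifnot(is.matrix(dosages))
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok)) stop("hard-call payload admits only dosages 0/1/2/NA", call. = FALSE)
  n <- nrow(dosages); m <- ncol(dosages)
  # dosage -> 2-bit code: 2->00, NA->01, 1->10, 0->11
  code <- matrix(3L, nrow = n, ncol = m)
  code[which(dosages == 1L)] <- 2L
  code[which(is.na(dosages))] <- 1L
  code[which(dosages == 2L)] <- 0L
  pad <- (-n) %% 4
  if (pad) code <- rbind(code, matrix(0L, nrow = pad, ncol = m))
  b1 <- code[seq(1, nrow(code), by = 4), , drop = FALSE]
  b2 <- code[seq(2, nrow(code), by = 4), , drop = FALSE]
  b3 <- code[seq(3, nrow(code), by = 4), , drop = FALSE]
  b4 <- code[seq(4, nrow(code), by = 4), , drop = FALSE]
  bytes <- b1 + b2 * 4L + b3 * 16L + b4 * 64L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(path)
}
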