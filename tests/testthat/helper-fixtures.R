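# In-code fixture builders shared across test files.

# write a minimal chromosome fileset (pvar/psam + text dosages, optionally
# the binary hard-call payload) and return its prefix
write_mini_fileset <- function(dir, chrom = "chr1",
                               ids = c("rs1", "rs2", "rs3"),
                               pos = NULL, ref = NULL, alt = NULL,
                               dosages = NULL, samples = NULL,
                               basename = paste0("mini_", chrom),
                               pgen = FALSE) {
  m <- length(ids)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = m)
  if (is.null(ref)) ref <- rep_len(c("A", "C", "G"), m)
  if (is.null(alt)) alt <- rep_len(c("G", "T", "A"), m)
  if (is.null(samples)) samples <- sprintf("S%02d", 1:4)
  n <- length(samples)
  if (is.null(dosages)) {
    dosages <- matrix(rep_len(0:2, n * m), nrow = n)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- file.path(dir, basename)
  writeLines(c("##fileformat=PVARv1.0",
               "#CHROM\tPOS\tID\tREF\tALT",
               paste(chrom, pos, ids, ref, alt, sep = "\t")),
             paste0(prefix, ".pvar"))
  writeLines(c("#IID", samples), paste0(prefix, ".psam"))
  txt <- apply(t(dosages), 1, paste, collapse = "\t")  # NA prints as "NA"
  writeLines(txt, paste0(prefix, ".dosage.tsv"))
  if (pgen) write_pgen_hardcalls(paste0(prefix, ".pgen"), dosages)
  prefix
}

# write a weight table from a data.frame-like list of rows
write_weights_tsv <- function(path, df) {
  data.table::fwrite(data.table::as.data.table(df), path, sep = "\t",
                     quote = FALSE, na = "")
  path
}

# straightforward two-pass Pearson and RMSE, independent of the package
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
naive_rmse <- function(x, y) sqrt(sum((x - y)^2) / length(x))

# exhaustive case analysis of biallelic orientation matching, written as
# plain set comparisons (the brute-force oracle for match_variant)
oracle_match_status <- function(eff, oth, ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- comp[[eff]] == oth
  if (eff == alt && oth == ref) return("exact")
  if (eff == ref && oth == alt) {
    return(if (ambiguous) "ambiguous_strand" else "swapped")
  }
  if (comp[[eff]] == alt && comp[[oth]] == ref) {
    return(if (ambiguous) "ambiguous_strand" else "complement")
  }
  if (comp[[eff]] == ref && comp[[oth]] == alt) {
    return(if (ambiguous) "ambiguous_strand" else "complement_swapped")
  }
  "unmatched"
}

# stream a matched index through a fresh writer and read the matrix back
run_engine <- function(source, matched, sample_set, catalog,
                       config = engine_config(), dir = tempfile("eng")) {
  gid <- data.table::copy(catalog$columns)
  prefix <- file.path(dir, "out")
  w <- grom_create(prefix, gid = gid, sample_ids = sample_set$analyzed,
                   precision = config$value_precision, overwrite = TRUE)
  summary <- stream_impute(source, matched, sample_set, config = config, sink = w)
  grom_close(w)
  list(values = grom_read(prefix)$values, summary = summary, prefix = prefix)
}

# build matched index + source for a generated cohort chromosome
cohort_chromosome <- function(fx, chrom, backend = "auto") {
  recs <- load_weight_table(fx$weights_path)
  bw <- build_weight_index(recs)
  manifest <- parse_pvar(paste0(fx$prefixes[[chrom]], ".pvar"))
  sample_set <- parse_psam(paste0(fx$prefixes[[chrom]], ".psam"))
  matched <- suppressWarnings(build_matched_index(
    recs[recs$chromosome == chrom, ], bw$catalog, manifest, bw$index))
  source <- open_genotype_source(fx$prefixes[[chrom]], sample_set,
                                 manifest = manifest, backend = backend)
  list(records = recs, catalog = bw$catalog, index = bw$index,
       manifest = manifest, sample_set = sample_set, matched = matched,
       source = source)
}
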