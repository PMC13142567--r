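# Seeded synthetic cohort generator.
#
# Emits exactly the formats the production paths consume — a weight TSV,
# chromosome-split .pvar/.psam manifests with both genotype payloads
# (binary 2-bit hard calls and the text dosage fallback) — together with
# its own dense ground truth (full G after mean imputation, the expected
# prediction matrix Y, and per-entry harmonization verdicts), so every
# downstream module can be tested against analytic expectations rather
# than another module's output.
#
# Dosages are drawn per variant as binomial(2, maf) (Hardy-Weinberg) with
# maf uniform in the stated range; gene weight vectors draw
# variants_per_gene sites per gene with N(0, 0.3^2) weights; stated
# fractions of weight entries are re-encoded with swapped or
# strand-complemented alleles, and a stated fraction of sites is
# strand-ambiguous (A/T or C/G), for harmonization tests.

#' Describe a synthetic cohort
#'
#' @param n_samples Individuals in the cohort.
#' @param n_variants Variants per chromosome (scalar, recycled).
#' @param chromosomes Chromosome labels (`chr*`).
#' @param n_models Number of prediction models (tissues).
#' @param genes_per_model Genes per model; every model covers the same gene
#'   pool, with independent variant sets and weights (as tissue panels do).
#' @param variants_per_gene Nonzero weights per gene-model column.
#' @param maf_range Minor-allele-frequency range, uniform per variant.
#' @param missing_rate Fraction of dosage entries masked missing.
#' @param swap_frac Fraction of weight entries re-encoded with swapped
#'   effect/other alleles.
#' @param complement_frac Fraction re-encoded on the opposite strand.
#' @param ambiguous_frac Fraction of genotype sites that are
#'   strand-ambiguous (A/T or C/G).
#' @param seed RNG seed; generation is a pure function of this spec.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_samples = 200L, n_variants = 250L,
                         chromosomes = c("chr1", "chr2"), n_models = 2L,
                         genes_per_model = 10L, variants_per_gene = 8L,
                         maf_range = c(0.05, 0.5), missing_rate = 0.01,
                         swap_frac = 0.1, complement_frac = 0.1,
                         ambiguous_frac = 0.05, seed = 1L) {
  assert_chromosome(chromosomes, "fixture chromosome")
  stopifnot(n_samples >= 1L, all(n_variants >= 1L), n_models >= 1L,
            genes_per_model >= 1L, variants_per_gene >= 1L,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate <= 1,
            swap_frac >= 0, complement_frac >= 0,
            swap_frac + complement_frac <= 1,
            ambiguous_frac >= 0, ambiguous_frac <= 1)
  n_variants <- rep(as.integer(n_variants), length.out = length(chromosomes))
  names(n_variants) <- chromosomes
  structure(list(n_samples = as.integer(n_samples), n_variants = n_variants,
                 chromosomes = chromosomes, n_models = as.integer(n_models),
                 genes_per_model = as.integer(genes_per_model),
                 variants_per_gene = as.integer(variants_per_gene),
                 maf_range = maf_range, missing_rate = missing_rate,
                 swap_frac = swap_frac, complement_frac = complement_frac,
                 ambiguous_frac = ambiguous_frac, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic cohort on disk with its ground truth
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param prefix Fileset basename stem; files are named
#'   `<prefix>_<chrom>.pvar` etc., plus `<prefix>_weights.tsv`.
#' @return Invisibly, a list: `dir`, `weights_path`, `prefixes` (per
#'   chromosome), `sample_ids`, `expected` (entry counts by harmonization
#'   status), `truth` (list with `catalog` — sorted triples with 0-based
#'   `col` —, `Y` — expected dense prediction matrix —, `G` — per-chromosome
#'   mean-imputed dosage matrices —, `entries` — per weight entry: rsid,
#'   column, weight, encoding, expected status/flip).
#' @export
generate_cohort <- function(spec, dir, prefix = "cohort") {
  stopifnot(inherits(spec, "fixture_spec"))
  if (any(spec$variants_per_gene > spec$n_variants)) {
    stop(sprintf("variants_per_gene (%d) exceeds variants on a chromosome (%d)",
                 spec$variants_per_gene, min(spec$n_variants)), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_samples
    sample_ids <- sprintf("S%05d", seq_len(n))
    bases <- c("A", "C", "G", "T")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    prefixes <- character(0)
    pvar_all <- list()
    G_imp <- list()

    for (chrom in spec$chromosomes) {
      m <- spec$n_variants[[chrom]]
      pos <- sort(sample.int(10 * m + 1000L, m))
      ambiguous <- runif(m) < spec$ambiguous_frac
      ref <- character(m); alt <- character(m)
      amb_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                          ncol = 2, byrow = TRUE)
      for (i in seq_len(m)) {
        if (ambiguous[i]) {
          p <- amb_pairs[sample.int(4L, 1L), ]
          ref[i] <- p[1]; alt[i] <- p[2]
        } else {
          ref[i] <- sample(bases, 1L)
          alt[i] <- sample(setdiff(bases, c(ref[i], comp[[ref[i]]])), 1L)
        }
      }
      rsid <- sprintf("rs_%s_%05d", chrom, seq_len(m))
      maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
      dos <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
      if (spec$missing_rate > 0) {
        dos[runif(n * m) < spec$missing_rate] <- NA_integer_
      }
      fp <- file.path(dir, paste0(prefix, "_", chrom))
      prefixes[chrom] <- fp
      pvar_dt <- data.table::data.table(
        CHROM = chrom, POS = pos, ID = rsid, REF = ref, ALT = alt)
      writeLines(c("##fileformat=PVARv1.0",
                   paste0("#", paste(names(pvar_dt), collapse = "\t")),
                   pvar_dt[, do.call(paste, c(.SD, sep = "\t"))]),
                 paste0(fp, ".pvar"))
      writeLines(c("#IID", sample_ids), paste0(fp, ".psam"))
      write_pgen_hardcalls(paste0(fp, ".pgen"), dos)
      data.table::fwrite(data.table::as.data.table(t(dos)),
                         paste0(fp, ".dosage.tsv"),
                         sep = "\t", col.names = FALSE, na = "NA", quote = FALSE)
      # mean-imputed dense truth for the oracle path
      gi <- dos
      for (j in seq_len(m)) {
        mj <- is.na(gi[, j])
        if (any(mj)) gi[mj, j] <- if (all(mj)) 0 else mean(gi[!mj, j])
      }
      storage.mode(gi) <- "double"
      G_imp[[chrom]] <- gi
      pvar_all[[chrom]] <- data.table::data.table(
        chromosome = chrom, ordinal = seq_len(m) - 1L, rsid = rsid,
        ref = ref, alt = alt, ambiguous = ambiguous)
    }
    sites <- data.table::rbindlist(pvar_all)

    # shared gene pool; each gene lives on one chromosome
    n_genes <- spec$genes_per_model
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    gene_chrom <- sample(spec$chromosomes, n_genes, replace = TRUE)
    models <- sprintf("model%02d", seq_len(spec$n_models))
    ancestries <- rep_len(c("EUR", "AFR"), spec$n_models)

    rows <- list()
    for (mi in seq_len(spec$n_models)) {
      for (gi in seq_len(n_genes)) {
        chrom <- gene_chrom[gi]
        chrom_sites <- sites[chromosome == chrom]
        pick <- sort(sample.int(nrow(chrom_sites), spec$variants_per_gene))
        sel <- chrom_sites[pick]
        w <- rnorm(spec$variants_per_gene) * 0.3
        w[w == 0] <- 0.1  # keep every drawn entry a genuine nonzero weight
        u <- runif(spec$variants_per_gene)
        encoding <- ifelse(u < spec$swap_frac, "swap",
                           ifelse(u < spec$swap_frac + spec$complement_frac,
                                  "complement", "exact"))
        eff <- character(spec$variants_per_gene)
        oth <- character(spec$variants_per_gene)
        status <- character(spec$variants_per_gene)
        flip <- logical(spec$variants_per_gene)
        for (v in seq_len(spec$variants_per_gene)) {
          r <- sel$ref[v]; a <- sel$alt[v]
          if (encoding[v] == "exact") {
            eff[v] <- a; oth[v] <- r
            status[v] <- "exact"; flip[v] <- FALSE
          } else if (encoding[v] == "swap") {
            eff[v] <- r; oth[v] <- a
            if (sel$ambiguous[v]) { status[v] <- "ambiguous_strand"; flip[v] <- FALSE }
            else { status[v] <- "swapped"; flip[v] <- TRUE }
          } else {
            eff[v] <- comp[[a]]; oth[v] <- comp[[r]]
            if (sel$ambiguous[v]) { status[v] <- "ambiguous_strand"; flip[v] <- FALSE }
            else { status[v] <- "complement"; flip[v] <- FALSE }
          }
        }
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chromosome = chrom, ancestry = ancestries[mi], model_ID = models[mi],
          gene = genes[gi], rsid = sel$rsid, effect_allele = eff,
          other_allele = oth, weight = w, ordinal = sel$ordinal,
          encoding = encoding, expected_status = status, expected_flip = flip)
      }
    }
    entries <- data.table::rbindlist(rows)
    weights_path <- file.path(dir, paste0(prefix, "_weights.tsv"))
    data.table::fwrite(
      entries[, .(chromosome, ancestry, model_ID, gene, rsid, effect_allele,
                  other_allele, weight)],
      weights_path, sep = "\t", quote = FALSE)

    # the generator's own analytic expectation of Y, in sorted catalog order
    catalog <- unique(entries[, .(ancestry, model_ID, gene)])
    catalog <- catalog[order_c(ancestry, model_ID, gene)]
    catalog[, col := seq_len(.N) - 1L]
    entries <- merge(entries, catalog, by = c("ancestry", "model_ID", "gene"),
                     sort = FALSE)
    Y <- matrix(0, nrow = n, ncol = nrow(catalog),
                dimnames = list(sample_ids,
                                paste(catalog$ancestry, catalog$model_ID,
                                      catalog$gene, sep = ".")))
    matched <- entries[!expected_status %in% c("ambiguous_strand", "unmatched")]
    for (i in seq_len(nrow(matched))) {
      g <- G_imp[[matched$chromosome[i]]][, matched$ordinal[i] + 1L]
      if (matched$expected_flip[i]) g <- 2 - g
      Y[, matched$col[i] + 1L] <- Y[, matched$col[i] + 1L] + matched$weight[i] * g
    }
    expected <- list(
      n_entries = nrow(entries),
      n_matched = nrow(matched),
      n_ambiguous = sum(entries$expected_status == "ambiguous_strand"),
      n_unmatched = sum(entries$expected_status == "unmatched"),
      status_counts = table(entries$expected_status))
    invisible(list(dir = dir, weights_path = weights_path, prefixes = prefixes,
                   sample_ids = sample_ids, spec = spec, expected = expected,
                   truth = list(catalog = catalog[], Y = Y, G = G_imp,
                                entries = entries[])))
  })
}

#' Mirror a weight fixture as a PrediXcan-style SQLite model
#'
#' Writes the given records into a `.db` with the PrediXcan `weights` table
#' schema (`rsid`, `gene`, `weight`, `ref_allele`, `eff_allele`) plus a
#' small `extra` table (which importers must ignore). Uses the system
#' `python3` sqlite3 bridge.
#'
#' @param records Weight records (as loaded by [load_weight_table()]) or a
#'   path to a weight TSV.
#' @param db_path Output `.db` path.
#' @return `db_path`, invisibly.
#' @export
generate_predixcan_db <- function(records, db_path) {
  if (is.character(records) && length(records) == 1L) {
    records <- load_weight_table(records)
  }
  records <- data.table::as.data.table(records)
  tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(tsv), add = TRUE)
  data.table::fwrite(
    records[, .(rsid, gene, weight,
                ref_allele = other_allele, eff_allele = effect_allele)],
    tsv, sep = "\t", quote = FALSE, na = "")
  script <- paste(
    "import sys, sqlite3, csv",
    "tsv, db = sys.argv[1], sys.argv[2]",
    "import os",
    "if os.path.exists(db): os.remove(db)",
    "con = sqlite3.connect(db)",
    "cur = con.cursor()",
    "cur.execute('CREATE TABLE weights (rsid TEXT, gene TEXT, weight REAL, ref_allele TEXT, eff_allele TEXT)')",
    "cur.execute('CREATE TABLE extra (n_snps_in_model INTEGER, gene TEXT)')",
    "with open(tsv) as fh:",
    "    rd = csv.DictReader(fh, delimiter='\\t')",
    "    for row in rd:",
    "        cur.execute('INSERT INTO weights VALUES (?,?,?,?,?)',",
    "                    (row['rsid'], row['gene'], float(row['weight']),",
    "                     row['ref_allele'] or None, row['eff_allele'] or None))",
    "con.commit(); con.close()",
    sep = "\n")
  res <- suppressWarnings(
    system2(python_binary(), c("-c", shQuote(script), shQuote(tsv), shQuote(db_path)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop(sprintf("failed to write SQLite fixture %s: %s", db_path,
                 paste(res, collapse = " ")), call. = FALSE)
  }
  invisible(db_path)
}
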