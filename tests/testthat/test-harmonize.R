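test_that("allele complementation is base-wise and reversed for multi-base alleles", {
  expect_equal(complement_allele("A"), "T")
  expect_equal(complement_allele("C"), "G")
  expect_equal(complement_allele("AG"), "CT")
  expect_equal(complement_allele("ACGT"), "ACGT")
  expect_error(complement_allele("N"), "A/C/G/T")
  expect_error(complement_allele(""), "A/C/G/T")
})

test_that("match_variant resolves orientation, transform, and strand ambiguity", {
  dir <- tempfile("match")
  prefix <- write_mini_fileset(dir, ids = c("rs1", "rs2"),
                               pos = c(100L, 200L),
                               ref = c("A", "A"), alt = c("G", "T"))
  man <- parse_pvar(paste0(prefix, ".pvar"))
  key <- function(eff, oth, pos = 100L) {
    list(chromosome = "chr1", position = pos, effect_allele = eff, other_allele = oth)
  }
  r <- match_variant(key("G", "A"), man)
  expect_equal(r$status, "exact"); expect_equal(r$dosage_transform, "identity")
  expect_equal(r$genotype_ordinal, 0L)
  r <- match_variant(key("A", "G"), man)
  expect_equal(r$status, "swapped"); expect_equal(r$dosage_transform, "flip")
  # C/T is the strand complement of G/A
  r <- match_variant(key("C", "T"), man)
  expect_equal(r$status, "complement"); expect_equal(r$dosage_transform, "identity")
  r <- match_variant(key("T", "C"), man)
  expect_equal(r$status, "complement_swapped"); expect_equal(r$dosage_transform, "flip")
  # A/T site: exact orientation matches, anything needing strand inference fails
  r <- match_variant(key("T", "A", 200L), man)
  expect_equal(r$status, "exact")
  r <- match_variant(key("A", "T", 200L), man)
  expect_equal(r$status, "ambiguous_strand")
  expect_true(is.na(r$genotype_ordinal))
  r <- match_variant(key("C", "G"), man)
  expect_equal(r$status, "unmatched")
  expect_error(match_variant(list(chromosome = "chr2", position = 100L,
                                  effect_allele = "G", other_allele = "A"), man),
               "chromosome")
})

test_that("match_variant agrees with exhaustive orientation case analysis", {
  bases <- c("A", "C", "G", "T")
  site_pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  site_pairs <- site_pairs[site_pairs$ref != site_pairs$alt, ]
  key_pairs <- expand.grid(eff = bases, oth = bases, stringsAsFactors = FALSE)
  key_pairs <- key_pairs[key_pairs$eff != key_pairs$oth, ]
  n_checked <- 0L
  for (s in seq_len(nrow(site_pairs))) {
    dir <- tempfile("truth")
    prefix <- write_mini_fileset(dir, ids = "rsX", pos = 500L,
                                 ref = site_pairs$ref[s], alt = site_pairs$alt[s])
    man <- parse_pvar(paste0(prefix, ".pvar"))
    for (k in seq_len(nrow(key_pairs))) {
      eff <- key_pairs$eff[k]; oth <- key_pairs$oth[k]
      got <- match_variant(list(chromosome = "chr1", position = 500L,
                                effect_allele = eff, other_allele = oth), man)
      want <- oracle_match_status(eff, oth, site_pairs$ref[s], site_pairs$alt[s])
      expect_equal(got$status, want,
                   label = sprintf("site %s/%s key %s/%s", site_pairs$ref[s],
                                   site_pairs$alt[s], eff, oth))
      expect_equal(got$dosage_transform,
                   if (want %in% c("swapped", "complement_swapped")) "flip" else "identity")
      expect_equal(is.na(got$genotype_ordinal),
                   want %in% c("ambiguous_strand", "unmatched"))
      n_checked <- n_checked + 1L
    }
    unlink(dir, recursive = TRUE)
  }
  expect_equal(n_checked, 144L)
})

test_that("matching is a pure function of its inputs", {
  dir <- tempfile("pure")
  prefix <- write_mini_fileset(dir, ids = c("rs1", "rs2"), ref = c("A", "C"),
                               alt = c("G", "T"))
  man <- parse_pvar(paste0(prefix, ".pvar"))
  key <- list(chromosome = "chr1", position = 100L,
              effect_allele = "C", other_allele = "T")
  first <- match_variant(key, man)
  for (i in 1:5) expect_identical(match_variant(key, man), first)
})

test_that("build_matched_index resolves, excludes, and accounts for every entry", {
  dir <- tempfile("bmi")
  prefix <- write_mini_fileset(dir, ids = c("rs1", "rs2", "rs3"),
                               ref = c("A", "C", "A"), alt = c("G", "T", "T"),
                               pos = c(100L, 200L, 300L))
  man <- parse_pvar(paste0(prefix, ".pvar"))
  rec <- data.table::data.table(
    chromosome = "chr1", ancestry = "EUR", model_ID = "m1",
    gene = c("g1", "g1", "g1", "g2"),
    rsid = c("rs1", "rs2", "rs_absent", "rs3"),
    effect_allele = c("G", "C", "A", "A"),  # exact, swapped, -, ambiguous(swap at A/T)
    other_allele = c("A", "T", "G", "T"),
    weight = c(0.5, -0.25, 1.0, 0.7))
  built <- build_weight_index(rec)
  expect_warning(
    mi <- build_matched_index(rec, built$catalog, man, built$index),
    "all-zero")
  expect_equal(mi$n_matched, 2L)
  expect_equal(mi$n_unmatched, 1L)
  expect_equal(mi$n_ambiguous, 1L)
  expect_equal(nrow(mi$entries), 2L)
  expect_equal(mi$n_matched + mi$n_unmatched + mi$n_ambiguous, nrow(rec))
  # flips recorded where the effect allele is REF
  expect_equal(mi$entries[order(ordinal)]$flip, c(FALSE, TRUE))
  # column that lost everything is still in the span table with zero count
  g2col <- merge(mi$column_span, built$catalog$columns, by = "col")[gene == "g2"]
  expect_equal(g2col$matched_count, 0L)
  expect_equal(sort(unique(mi$report$status)),
               sort(c("exact", "swapped", "unmatched", "ambiguous_strand")))
})

test_that("records without alleles match by rsid under the ALT-orientation convention", {
  dir <- tempfile("rsidonly")
  prefix <- write_mini_fileset(dir, ids = c("rs1", "rs2"), ref = c("A", "C"),
                               alt = c("G", "T"))
  man <- parse_pvar(paste0(prefix, ".pvar"))
  rec <- data.table::data.table(
    chromosome = "chr1", ancestry = "EUR", model_ID = "m1", gene = "g1",
    rsid = c("rs1", "rs2"), effect_allele = NA_character_,
    other_allele = NA_character_, weight = c(0.3, 0.4))
  built <- build_weight_index(rec)
  mi <- build_matched_index(rec, built$catalog, man, built$index)
  expect_equal(mi$n_matched, 2L)
  expect_equal(mi$entries$flip, c(FALSE, FALSE))
  expect_equal(unique(mi$report$status), "exact")
})

test_that("effect-allele-only records resolve orientation against REF/ALT", {
  dir <- tempfile("effonly")
  prefix <- write_mini_fileset(dir, ids = c("rs1", "rs2", "rs3", "rs4"),
                               ref = c("A", "A", "A", "A"),
                               alt = c("G", "G", "G", "T"),
                               pos = c(100L, 200L, 300L, 400L))
  man <- parse_pvar(paste0(prefix, ".pvar"))
  rec <- data.table::data.table(
    chromosome = "chr1", ancestry = "EUR", model_ID = "m1", gene = "g1",
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "C", "T", "A"),  # swapped, complement, c-swapped, ambiguous
    other_allele = NA_character_,
    weight = c(1, 1, 1, 1))
  built <- build_weight_index(rec)
  mi <- build_matched_index(rec, built$catalog, man, built$index)
  got <- mi$report[order(rsid)]
  expect_equal(got$status, c("swapped", "complement", "complement_swapped",
                             "ambiguous_strand"))
  expect_equal(got$dosage_transform[1:3], c("flip", "identity", "flip"))
})

test_that("multi-allelic and duplicate-id variants are excluded from matching", {
  dir <- tempfile("multi")
  prefix <- write_mini_fileset(dir, ids = c("rs1", "rs1", "rs2"),
                               ref = c("A", "A", "C"), alt = c("G", "T", "G,T"),
                               pos = c(100L, 150L, 200L))
  man <- parse_pvar(paste0(prefix, ".pvar"))
  rec <- data.table::data.table(
    chromosome = "chr1", ancestry = "EUR", model_ID = "m1", gene = c("g1", "g2"),
    rsid = c("rs1", "rs2"), effect_allele = c("G", "G"),
    other_allele = c("A", "C"), weight = c(1, 1))
  built <- build_weight_index(rec)
  mi <- suppressWarnings(build_matched_index(rec, built$catalog, man, built$index))
  expect_equal(mi$n_unmatched, 2L)
  expect_equal(mi$n_matched, 0L)
})
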