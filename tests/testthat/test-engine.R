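# A hand-built matched index over a text fixture, used by several blocks
make_engine_fixture <- function(n = 6L, m = 5L, dosages = NULL, entries = NULL,
                                k = 2L) {
  if (is.null(dosages)) {
    set.seed(99)
    dosages <- matrix(rbinom(n * m, 2, 0.4), nrow = n)
  }
  dir <- tempfile("engfx")
  prefix <- write_mini_fileset(dir, ids = sprintf("rs%d", 1:m),
                               ref = rep("A", m), alt = rep("G", m),
                               dosages = dosages,
                               samples = sprintf("S%02d", 1:n))
  ss <- parse_psam(paste0(prefix, ".psam"))
  src <- open_genotype_source(prefix, ss)
  catalog <- structure(list(
    columns = data.table::data.table(
      col = seq_len(k) - 1L, ancestry = "EUR", model_ID = "m1",
      gene = sprintf("g%d", seq_len(k))),
    k = k), class = "grom_catalog")
  if (is.null(entries)) {
    entries <- data.table::data.table(ordinal = 0L, col = 0L,
                                      weight = 0.5, flip = FALSE)
  }
  span <- entries[, .(first_ordinal = min(ordinal), last_ordinal = max(ordinal),
                      matched_count = .N), by = col]
  column_span <- merge(data.table::data.table(col = catalog$columns$col), span,
                       by = "col", all.x = TRUE, sort = TRUE)
  column_span[is.na(matched_count), matched_count := 0L]
  matched <- structure(list(entries = entries[order(ordinal, col)],
                            column_span = column_span,
                            report = NULL, chromosome = "chr1",
                            n_matched = nrow(entries), n_unmatched = 0L,
                            n_ambiguous = 0L), class = "matched_index")
  list(source = src, matched = matched, catalog = catalog, sample_set = ss,
       dosages = dosages)
}

test_that("a single weighted variant produces its scaled dosage column", {
  dos <- matrix(c(0, 1, 2), nrow = 3, ncol = 1)
  fx <- make_engine_fixture(n = 3L, m = 1L, dosages = dos, k = 1L,
                            entries = data.table::data.table(
                              ordinal = 0L, col = 0L, weight = 0.5, flip = FALSE))
  out <- run_engine(fx$source, fx$matched, fx$sample_set, fx$catalog)
  expect_equal(unname(out$values[, 1]), c(0, 0.5, 1))
})

test_that("opposite weights on identical dosage columns cancel to zero", {
  dos <- matrix(rep(c(0, 1, 2, 1), 2), nrow = 4)
  fx <- make_engine_fixture(n = 4L, m = 2L, dosages = dos, k = 1L,
                            entries = data.table::data.table(
                              ordinal = c(0L, 1L), col = 0L,
                              weight = c(1, -1), flip = FALSE))
  out <- run_engine(fx$source, fx$matched, fx$sample_set, fx$catalog)
  expect_equal(unname(out$values[, 1]), rep(0, 4))
})

test_that("flipped entries contribute weight * (2 - dosage)", {
  dos <- matrix(c(0, 1, 2), nrow = 3)
  fx <- make_engine_fixture(n = 3L, m = 1L, dosages = dos, k = 1L,
                            entries = data.table::data.table(
                              ordinal = 0L, col = 0L, weight = 0.5, flip = TRUE))
  out <- run_engine(fx$source, fx$matched, fx$sample_set, fx$catalog)
  expect_equal(unname(out$values[, 1]), c(1, 0.5, 0))
})

test_that("dense oracle: unit weight copies the (transformed) dosage column; zero B is zero", {
  set.seed(31)
  dos <- matrix(rbinom(24, 2, 0.5), nrow = 6)
  fx <- make_engine_fixture(n = 6L, m = 4L, dosages = dos, k = 2L,
                            entries = data.table::data.table(
                              ordinal = 2L, col = 1L, weight = 1, flip = FALSE))
  Y <- dense_oracle_impute(fx$dosages + 0, fx$matched, fx$catalog)
  expect_equal(Y[, 2], dos[, 3] + 0)
  expect_equal(Y[, 1], rep(0, 6))
  # flip identity: w(2-d) = 2w - wd
  fx2 <- make_engine_fixture(n = 6L, m = 4L, dosages = dos, k = 2L,
                             entries = data.table::data.table(
                               ordinal = 2L, col = 1L, weight = 0.7, flip = TRUE))
  Y2 <- dense_oracle_impute(dos + 0, fx2$matched, fx2$catalog)
  expect_equal(Y2[, 2], 2 * 0.7 - 0.7 * dos[, 3], tolerance = 1e-12)
})

test_that("streamed output equals the dense oracle across chunk-size combinations", {
  combos <- expand.grid(snp = c(1L, 7L, 64L, NA), row = c(1L, 13L, NA))
  for (i in seq_len(nrow(combos))) {
    seed <- 100L + i
    sp <- fixture_spec(n_samples = 20L + (i %% 3) * 7L, n_variants = 40L + i,
                       chromosomes = "chr1", n_models = 2L, genes_per_model = 4L,
                       variants_per_gene = 5L, missing_rate = 0.02,
                       ambiguous_frac = 0.1, seed = seed)
    fx <- generate_cohort(sp, tempfile("oracle"))
    ch <- cohort_chromosome(fx, "chr1",
                            backend = if (i %% 2) "pgen" else "text")
    m <- ch$manifest$n_variants
    n <- length(ch$sample_set$analyzed)
    cfg <- engine_config(
      snp_chunk_size = if (is.na(combos$snp[i])) m else combos$snp[i],
      row_chunk_size = if (is.na(combos$row[i])) n else combos$row[i])
    out <- run_engine(ch$source, ch$matched, ch$sample_set, ch$catalog, config = cfg)
    oracle <- dense_oracle_impute(fx$truth$G[["chr1"]], ch$matched, ch$catalog)
    expect_lt(max(abs(unname(out$values) - oracle)), 1e-9)
    # and both agree with the generator's own analytic expectation
    expect_lt(max(abs(unname(out$values) - unname(fx$truth$Y))), 1e-9)
  }
})

test_that("outputs are invariant to chunk sizes at tight tolerance", {
  sp <- fixture_spec(n_samples = 30L, n_variants = 70L, chromosomes = "chr1",
                     n_models = 2L, genes_per_model = 5L, variants_per_gene = 6L,
                     seed = 202L)
  fx <- generate_cohort(sp, tempfile("inv"))
  ch <- cohort_chromosome(fx, "chr1")
  ref <- NULL
  for (cfg in list(engine_config(1L, 1L), engine_config(7L, 13L),
                   engine_config(70L, 30L), engine_config(64L, 8192L))) {
    ch <- cohort_chromosome(fx, "chr1")
    out <- run_engine(ch$source, ch$matched, ch$sample_set, ch$catalog, config = cfg)
    if (is.null(ref)) ref <- out$values
    else {
      denom <- pmax(abs(ref), 1)
      expect_lt(max(abs(out$values - ref) / denom), 1e-12)
    }
  }
})

test_that("imputation is linear in the weights", {
  sp <- fixture_spec(n_samples = 25L, n_variants = 50L, chromosomes = "chr1",
                     seed = 303L)
  fx <- generate_cohort(sp, tempfile("lin"))
  ch <- cohort_chromosome(fx, "chr1")
  out1 <- run_engine(ch$source, ch$matched, ch$sample_set, ch$catalog)
  doubled <- ch$matched
  doubled$entries <- data.table::copy(ch$matched$entries)[, weight := weight * 2]
  ch2 <- cohort_chromosome(fx, "chr1")
  out2 <- run_engine(ch2$source, doubled, ch$sample_set, ch$catalog)
  # flipped entries add a constant 2w offset, so linearity holds elementwise
  expect_equal(out2$values, 2 * out1$values, tolerance = 1e-12)
})

test_that("column lifecycle: allocation/flush plan matches the instrumented run", {
  # disjoint spans with a chunk per span: one active column at a time
  fxd <- make_engine_fixture(n = 4L, m = 4L, k = 2L,
                             dosages = matrix(rbinom(16, 2, 0.5), nrow = 4),
                             entries = data.table::data.table(
                               ordinal = c(0L, 1L, 2L, 3L), col = c(0L, 0L, 1L, 1L),
                               weight = 1, flip = FALSE))
  plan <- column_lifecycle_plan(fxd$matched, snp_chunk_size = 2L, n_variants = 4L)
  expect_equal(plan$peak_active_columns, 1L)
  expect_equal(plan$chunks$allocate[[1]], 0L)
  expect_equal(plan$chunks$flush[[2]], 1L)
  out <- run_engine(fxd$source, fxd$matched, fxd$sample_set, fxd$catalog,
                    config = engine_config(snp_chunk_size = 2L))
  expect_equal(out$summary$peak_active_columns, 1L)

  # all columns sharing one variant: peak equals k
  k <- 5L
  catalog_k <- k
  fxs <- make_engine_fixture(n = 3L, m = 1L, k = catalog_k,
                             dosages = matrix(c(0, 1, 2), nrow = 3),
                             entries = data.table::data.table(
                               ordinal = 0L, col = seq_len(k) - 1L,
                               weight = 1, flip = FALSE))
  plan <- column_lifecycle_plan(fxs$matched, snp_chunk_size = 1L, n_variants = 1L)
  expect_equal(plan$peak_active_columns, k)
  out <- run_engine(fxs$source, fxs$matched, fxs$sample_set, fxs$catalog)
  expect_equal(out$summary$peak_active_columns, k)

  # random spans: planned peak equals instrumented peak, never exceeds k
  for (seed in 1:6) {
    sp <- fixture_spec(n_samples = 15L, n_variants = 60L, chromosomes = "chr1",
                       n_models = 2L, genes_per_model = 5L,
                       variants_per_gene = 4L, seed = 400L + seed)
    fx <- generate_cohort(sp, tempfile("plan"))
    ch <- cohort_chromosome(fx, "chr1")
    for (csize in c(1L, 8L, 60L)) {
      plan <- column_lifecycle_plan(ch$matched, snp_chunk_size = csize,
                                    n_variants = 60L)
      ch2 <- cohort_chromosome(fx, "chr1")
      out <- run_engine(ch2$source, ch2$matched, ch2$sample_set, ch2$catalog,
                        config = engine_config(snp_chunk_size = csize))
      expect_equal(out$summary$peak_active_columns, plan$peak_active_columns)
      expect_lte(plan$peak_active_columns, ch$catalog$k)
      expect_equal(out$summary$columns_written, ch$catalog$k)
    }
  }
})

test_that("an index pointing past the source is a hard error", {
  fx <- make_engine_fixture(n = 4L, m = 2L, k = 1L,
                            entries = data.table::data.table(
                              ordinal = 5L, col = 0L, weight = 1, flip = FALSE))
  gid <- fx$catalog$columns
  w <- grom_create(file.path(tempfile("bad"), "out"), gid = gid,
                   sample_ids = fx$sample_set$analyzed)
  expect_error(stream_impute(fx$source, fx$matched, fx$sample_set,
                             sink = w), "mismatch")
  grom_close(w, require_complete = FALSE)
})
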