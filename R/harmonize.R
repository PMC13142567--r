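# Allele harmonization: match weight predictors to genotype variants and
# resolve effect-allele orientation into a per-entry dosage transform.
#
# Matching is by chromosome-position-reference-alternate (CPRA) with
# complementary-allele matches permitted.  When the effect allele is the
# genotype REF allele the dosage transform d -> 2 - d applies (flip).
# Strand-ambiguous sites (allele pair {A,T} or {C,G}) are accepted in exact
# orientation only: for such sites a strand complement is indistinguishable
# from an allele swap, so a complement-only match cannot determine the sign
# of the contribution and is reported as ambiguous_strand.

MATCH_STATUSES <- c("exact", "swapped", "complement", "complement_swapped",
                    "ambiguous_strand", "unmatched")

#' Complement an allele sequence
#'
#' Base-wise complement for single bases (A<->T, C<->G); reverse complement
#' for multi-base alleles.
#'
#' @param allele Allele string over `{A,C,G,T}`.
#' @return The (reverse-)complemented allele string.
#' @export
complement_allele <- function(allele) {
  if (length(allele) != 1L || is.na(allele) || !nzchar(allele) ||
      grepl("[^ACGT]", allele)) {
    stop(sprintf("cannot complement allele %s: alleles must be nonempty A/C/G/T strings",
                 deparse(allele)), call. = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(allele, "", fixed = TRUE)[[1]]]), collapse = "")
}

#' @noRd
is_acgt <- function(a) !is.na(a) & nzchar(a) & !grepl("[^ACGT]", a)

#' @noRd
is_ambiguous_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

# Orientation of a weight's (effect, other) alleles against one genotype
# record's (ref, alt).  Core of both matching paths; `other` may be NA
# (rsid-only schema), in which case only the effect allele is compared.
#' @noRd
match_alleles <- function(effect, other, ref, alt) {
  res <- function(status, flip = FALSE) list(status = status, flip = flip)
  if (!is_acgt(effect) || !is_acgt(ref) || !is_acgt(alt)) return(res("unmatched"))
  snv <- nchar(ref) == 1L && nchar(alt) == 1L && nchar(effect) == 1L &&
    (is.na(other) || nchar(other) == 1L)
  ambiguous_site <- snv && is_ambiguous_pair(ref, alt)
  if (is.na(other)) {
    if (effect == alt) return(res("exact"))
    if (effect == ref) {
      if (ambiguous_site) return(res("ambiguous_strand"))
      return(res("swapped", flip = TRUE))
    }
    if (snv) {
      ce <- complement_allele(effect)
      if (ce == alt) return(res("complement"))
      if (ce == ref) return(res("complement_swapped", flip = TRUE))
    }
    return(res("unmatched"))
  }
  if (!is_acgt(other)) return(res("unmatched"))
  if (effect == alt && other == ref) return(res("exact"))
  complement_hit <- FALSE
  if (effect == ref && other == alt) {
    if (!ambiguous_site) return(res("swapped", flip = TRUE))
    complement_hit <- TRUE  # swap at an ambiguous site == complement match
  }
  both_snv <- snv && nchar(other) == 1L
  if (both_snv) {
    ce <- complement_allele(effect)
    co <- complement_allele(other)
    if (ce == alt && co == ref) {
      if (ambiguous_site) complement_hit <- TRUE else return(res("complement"))
    }
    if (ce == ref && co == alt) {
      if (ambiguous_site) complement_hit <- TRUE
      else return(res("complement_swapped", flip = TRUE))
    }
  }
  if (complement_hit) return(res("ambiguous_strand"))
  res("unmatched")
}

#' Match one variant key against a .pvar manifest
#'
#' Tries, in order: effect=ALT/other=REF (exact, identity transform);
#' effect=REF/other=ALT (swapped, flip d -> 2 - d); the same two with
#' complemented alleles (complement, complement_swapped). Strand-ambiguous
#' keys accept exact orientation only; when only a swap/complement would
#' succeed the verdict is `ambiguous_strand` with no genotype ordinal. All
#' failures are statuses, never errors — they feed the harmonization report.
#'
#' Complementation is attempted for single-base alleles only; indels and
#' MNVs match in exact or swapped orientation.
#'
#' @param key List/record with `chromosome`, `position`, `effect_allele`,
#'   `other_allele`.
#' @param manifest A `pvar_manifest` for the same chromosome.
#' @return A list (`match_result`): `status`, `genotype_ordinal` (0-based or
#'   `NA`), `dosage_transform` (`"identity"` or `"flip"`).
#' @export
match_variant <- function(key, manifest) {
  stopifnot(inherits(manifest, "pvar_manifest"))
  if (!identical(key$chromosome, manifest$chromosome)) {
    stop(sprintf("variant key chromosome %s does not match manifest chromosome %s",
                 key$chromosome, manifest$chromosome), call. = FALSE)
  }
  eff <- key$effect_allele
  oth <- key$other_allele
  lookup <- function(ref, alt) {
    ord <- manifest$cpra_index[[cpra_key(key$position, ref, alt)]]
    if (is.null(ord)) NA_integer_ else ord
  }
  verdict <- function(status, ordinal = NA_integer_) {
    structure(list(status = status,
                   genotype_ordinal = if (status %in% c("ambiguous_strand", "unmatched"))
                     NA_integer_ else ordinal,
                   dosage_transform = if (status %in% c("swapped", "complement_swapped"))
                     "flip" else "identity"),
              class = "match_result")
  }
  if (!is_acgt(eff) || !is_acgt(oth)) return(verdict("unmatched"))
  ord <- lookup(oth, eff)
  if (!is.na(ord)) return(verdict("exact", ord))
  snv <- nchar(eff) == 1L && nchar(oth) == 1L
  ambiguous <- snv && is_ambiguous_pair(eff, oth)
  ord <- lookup(eff, oth)
  if (!is.na(ord)) {
    if (ambiguous) return(verdict("ambiguous_strand"))
    return(verdict("swapped", ord))
  }
  if (snv) {
    ce <- complement_allele(eff)
    co <- complement_allele(oth)
    ord <- lookup(co, ce)
    if (!is.na(ord)) {
      if (ambiguous) return(verdict("ambiguous_strand"))
      return(verdict("complement", ord))
    }
    ord <- lookup(ce, co)
    if (!is.na(ord)) {
      if (ambiguous) return(verdict("ambiguous_strand"))
      return(verdict("complement_swapped", ord))
    }
  }
  verdict("unmatched")
}

#' Resolve every weight entry against a chromosome's variant manifest
#'
#' Pre-resolves each sparse weight entry, once and before streaming, to
#' (genotype ordinal, column, weight, dosage transform). Entries whose
#' variant cannot be found, is multi-allelic, or is strand-ambiguous under a
#' complement-only match are excluded and reported with reasons. Matched
#' per-column variant counts are recomputed on the matched subset; these
#' drive the engine's allocate/flush lifecycle. A column that loses every
#' variant raises a warning and is still emitted (all-zero prediction).
#'
#' Weight records carrying an `other_allele` are oriented by the full allele
#' pair; records with `effect_allele` only are located by rsid and oriented
#' by the effect allele against the record's REF/ALT; records with neither
#' allele are assumed ALT-oriented (identity) — the post-QC convention.
#'
#' @param records Weight records restricted to `manifest`'s chromosome (or
#'   with `NA` chromosome, e.g. `.db` imports routed here by rsid).
#' @param catalog `grom_catalog` from [build_weight_index()].
#' @param manifest `pvar_manifest` for one chromosome.
#' @param index `grom_weight_index` from [build_weight_index()] (supplies
#'   column positions for the records).
#' @return An object of class `matched_index`: `entries` (data.table:
#'   `ordinal`, `col`, `weight`, `flip`, sorted by ordinal then column),
#'   `column_span` (per catalog column: `first_ordinal`, `last_ordinal`,
#'   `matched_count`), `report` (per input entry: rsid, triple, status,
#'   ordinal, transform), `n_matched`, `n_unmatched`, `n_ambiguous`.
#' @export
build_matched_index <- function(records, catalog, manifest, index) {
  stopifnot(inherits(catalog, "grom_catalog"), inherits(manifest, "pvar_manifest"),
            inherits(index, "grom_weight_index"))
  records <- data.table::as.data.table(records)
  entries <- merge(records,
                   catalog$columns, by = c("ancestry", "model_ID", "gene"),
                   sort = FALSE)
  if (nrow(entries) != nrow(records)) {
    stop("records contain (ancestry, model_ID, gene) triples absent from the catalog",
         call. = FALSE)
  }
  entries <- entries[order_c(rsid, col)]
  n <- nrow(entries)
  status <- character(n)
  ordinal <- rep(NA_integer_, n)
  flip <- logical(n)
  ref_v <- manifest$records$ref
  alt_v <- manifest$records$alt
  bi_v <- manifest$records$biallelic
  for (i in seq_len(n)) {
    rid <- entries$rsid[i]
    row_ord <- manifest$id_index[[rid]]
    if (is.null(row_ord)) { status[i] <- "unmatched"; next }
    if (row_ord < 0L) { status[i] <- "unmatched"; next }  # duplicated ID in .pvar
    if (!bi_v[row_ord + 1L]) { status[i] <- "unmatched"; next }
    eff <- entries$effect_allele[i]
    if (is.na(eff)) {
      # no allele information: assume post-QC ALT orientation
      status[i] <- "exact"; ordinal[i] <- row_ord; flip[i] <- FALSE
      next
    }
    m <- match_alleles(eff, entries$other_allele[i], ref_v[row_ord + 1L],
                       alt_v[row_ord + 1L])
    status[i] <- m$status
    if (!m$status %in% c("ambiguous_strand", "unmatched")) {
      ordinal[i] <- row_ord
      flip[i] <- m$flip
    }
  }
  report <- data.table::data.table(
    rsid = entries$rsid, ancestry = entries$ancestry, model_ID = entries$model_ID,
    gene = entries$gene, col = entries$col, status = status,
    genotype_ordinal = ordinal,
    dosage_transform = ifelse(is.na(ordinal), NA_character_,
                              ifelse(flip, "flip", "identity")))
  keep <- !is.na(ordinal)
  matched <- data.table::data.table(
    ordinal = ordinal[keep], col = entries$col[keep],
    weight = entries$weight[keep], flip = flip[keep])
  matched <- matched[order_c(ordinal, col)]
  span <- matched[, .(first_ordinal = min(ordinal), last_ordinal = max(ordinal),
                      matched_count = .N), by = col]
  column_span <- data.table::data.table(col = catalog$columns$col)
  column_span <- merge(column_span, span, by = "col", all.x = TRUE, sort = TRUE)
  column_span[is.na(matched_count), matched_count := 0L]
  touched <- unique(entries$col)
  lost <- column_span[matched_count == 0L & col %in% touched]
  if (nrow(lost)) {
    warning(sprintf(
      "%d column(s) lost all variants during harmonization and will be all-zero",
      nrow(lost)), call. = FALSE)
  }
  structure(list(
    entries = matched[], column_span = column_span[], report = report[],
    chromosome = manifest$chromosome,
    n_matched = sum(keep),
    n_unmatched = sum(status == "unmatched"),
    n_ambiguous = sum(status == "ambiguous_strand")),
    class = "matched_index")
}

#' @export
print.matched_index <- function(x, ...) {
  cat(sprintf("<matched_index> %s: %d matched, %d unmatched, %d strand-ambiguous\n",
              x$chromosome, x$n_matched, x$n_unmatched, x$n_ambiguous))
  invisible(x)
}
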