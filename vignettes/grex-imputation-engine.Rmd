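---
title: "Streaming GReX imputation: model, harmonization, and file format"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming GReX imputation: model, harmonization, and file format}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gromr)
```

## The model

Genetically regulated gene expression (GReX) imputation applies trained cis
prediction weights to individual-level genotypes:

$$Y = G \times B$$

with $G \in \mathbb{R}^{n \times m}$ the matrix of alternate-allele dosages
($n$ individuals, $m$ variants, every entry in $[0, 2]$),
$B \in \mathbb{R}^{m \times k}$ the sparse weight matrix over $k$
gene-model columns (one column per gene under one tissue/cell-type/ancestry
model), and $Y \in \mathbb{R}^{n \times k}$ the imputed expression matrix.
The model is a fixed linear map: there is no fitting, no uncertainty
propagation, and no dependence between individuals. Everything this package
does is an exercise in evaluating that product faithfully, at scale, under
real-world input messiness (allele encodings, chromosome-split files,
missing genotypes).

Two implementations of the product coexist deliberately:

* `stream_impute()` — the production path: SNP-chunked, sparsity-driven,
  with the active-column lifecycle described below.
* `dense_oracle_impute()` — a reference path that materializes $B$ densely
  and performs one full matrix product, splitting entries by dosage
  transform: $Y = G B_\text{identity} + (2 - G) B_\text{flip}$.

The two routes share no accumulation code, so their agreement (asserted to
$10^{-9}$ absolute on seeded fixtures across chunk regimes, and measured as
per-column Pearson/RMSE at cohort scale) is a genuine cross-check rather
than a tautology.

## Column identity and ordering

A column is the triple (ancestry, model_ID, gene). The ancestry label is
part of column identity: the same model/gene trained in two populations
yields two columns. Collapsing over ancestry is a view operation on the
output, whereas merging at build time would lose information. The catalog
orders triples by C-locale radix sort, so the output column space is a
deterministic function of the weight records alone — independent of file
order, row order, or locale. This is what makes end-to-end byte-identity
across reruns testable.

Zero weights are dropped at load time, not at multiply time: the per-column
contributing-variant counts drive the flush lifecycle, and a zero weight
that survived to the engine would inflate those counts without affecting
any value. Duplicate (variant, column) weight entries are a hard error
rather than a silent sum — duplicates in model exports are almost always a
malformed file, and summing would mask that.

## Allele harmonization

Weight predictors are matched to genotype records by
chromosome–position–reference–alternate (CPRA) identity with complementary
alleles permitted; rsid is carried for reporting but is never the matching
authority when a full allele pair is available. The orientation cases, in
tie-break order:

| weight (effect/other) vs pvar (REF/ALT) | status | dosage transform |
|---|---|---|
| effect = ALT, other = REF | `exact` | identity |
| effect = REF, other = ALT | `swapped` | $d \to 2 - d$ |
| complement(effect) = ALT, complement(other) = REF | `complement` | identity |
| complement(effect) = REF, complement(other) = ALT | `complement_swapped` | $d \to 2 - d$ |

Strand-ambiguous sites — allele pairs {A,T} or {C,G} — are the genuinely
undecidable case: the strand complement of such a pair *is* its swap, so a
complement-only match cannot distinguish "same allele, opposite strand"
(identity) from "opposite allele" (flip), and the sign of the contribution
would be a coin toss. These sites match in exact orientation only; anything
that would require strand inference is reported `ambiguous_strand` and
excluded. For the same reason, in the rsid-located single-allele path an
effect allele equal to REF at an ambiguous site is ambiguous, not swapped.
Complementation is attempted only for single-base alleles; indels match in
exact or swapped orientation.

Two pragmatic rules cover the schema variants seen in the wild:

* Records with an effect allele but no other allele (the common TSV layout)
  are located by rsid, then oriented by the effect allele against that
  row's REF/ALT.
* Records with no allele columns at all are assumed ALT-oriented
  (identity). This is the post-QC convention: pipelines that pre-harmonize
  their weights upstream emit tables whose orientation is already
  consistent, and refusing them would be gratuitous.

Every entry's verdict is written to `meta/match_report.tsv`, and the
accounting always closes: matched + unmatched + ambiguous = loaded.

Matching correctness is tested against a brute-force oracle that enumerates
all 144 ordered (effect/other) × (REF/ALT) biallelic orientation cases, and
by a re-encoding invariance property: swapping REF/ALT in the genotype
fileset while complementing dosages ($d \to 2 - d$) must leave every
prediction unchanged to $10^{-12}$ relative.

## The streaming engine

Variants are processed in strictly ascending genotype ordinal; within a
variant, columns are updated in ascending column position; accumulation is
always double precision. Those three choices make the output
bit-reproducible and independent of `snp_chunk_size` and `row_chunk_size`,
which therefore are pure performance knobs:

| parameter | default | meaning |
|---|---|---|
| `snp_chunk_size` | 1024 | variants fetched per read; bounds the dosage block held in memory (n × chunk doubles) |
| `row_chunk_size` | 8192 | samples per accumulation slice; keeps updates on contiguous cache-friendly ranges |
| `value_precision` | double | storage precision of the output file; accumulation stays double, single rounds at flush |
| `flush_batch_size` | 64 | completed columns exported per write batch |

A column's accumulator is allocated at its first contributing variant and
released once its last contributing variant has been processed (columns
completed by a variant are released only after all of that variant's
updates, so simultaneous completion is counted honestly).
`column_lifecycle_plan()` predicts the allocate/flush schedule and the peak
number of simultaneously active columns from the matched index alone, by
sweeping each column's [first, last] contributing-ordinal span; tests
assert the plan's peak equals the instrumented peak of an actual run. This
peak — not $n \times k$ — is what governs memory, and it is the structural
property behind the approach's practicality at biobank scale.

Chromosomes are processed sequentially in natural order (chr1, chr2, …,
chr10, …, chrX, chrY), each flushing its own columns into the shared
preallocated output. Gene-model columns must therefore be
chromosome-local; a column whose matched variants span two chromosomes is
a hard error. Cis prediction models satisfy this by construction, and
rejecting the exception is safer than silently carrying accumulators
across files. Columns that lose every variant in harmonization are still
emitted (all zeros) and flagged, so the output column space equals the
catalog and `.gid` is a function of the weights alone.

Missing dosages are mean-imputed per variant over the *analyzed* samples
at read time (zero if all are missing), with imputation counts logged.
This is the dominant convention in GReX scoring tools; note the
consequence, exercised in the tests, that subsetting samples changes the
imputation means and hence (slightly) the predictions for individuals
with missing calls.

## Genotype input

Filesets are PLINK2-style chromosome-split trios (`.pvar`/`.psam` plus a
genotype payload) discovered by exact chr-token matching: the label must be
delimited by non-alphanumerics or string boundaries, so `chr1` can never
capture a `chr11` file, and two candidates for one chromosome are an error
rather than a choice. The streaming source is a small contract
(`read_dosage_chunk(start, length)` returning analyzed-samples × variants
blocks) with two interchangeable backends:

* a binary 2-bit hard-call payload (the fixed-width variant-major layout
  that PLINK's `.bed` files use and PLINK2's `.pgen` container accepts as
  storage mode 0x01) — dosages are the hard calls {0, 1, 2} with a missing
  code, mean-imputed as above; dosage-precision `.pgen` storage modes are
  detected and rejected with a clear message, since decoding them requires
  pgenlib;
* a plain-text dosage matrix (`.dosage.tsv`, one row per `.pvar` variant,
  one column per `.psam` sample, `NA` for missing) — a fixture/testing
  format, documented but not advertised for production.

Both backends are exercised by the same contract tests, including
chunk-concatenation identity (any chunking reproduces the full matrix
exactly) and byte-identical agreement with each other on fixtures written
through both.

## The .grom/.gid/.sid trio

The binary layout is frozen for this artifact: 8-byte magic `GROMv001`,
little-endian unsigned 64-bit row and column counts, a value-code byte
(1 = double, 2 = single), zero-filled reserved bytes to a 32-byte header,
then values in contiguous column-major order. File size is exactly
`32 + n·k·value_size`, checked on open, and column `j` starts at byte
`32 + j·n·value_size` — which is what makes selective reads cheap: reading
`c` columns touches exactly `32 + c·n·value_size` bytes, a property the
tests assert through an instrumented byte counter. `.gid` and `.sid` are
header-bearing TSVs, analogous to `.pvar`/`.psam`. The format is
property-compatible with, but not byte-compatible with, other tools'
binary outputs; it is this package's own layout, chosen so the writer,
reader, and tests can pin bit-exact round trips. Rewriting a column is an
error (it would indicate a lifecycle bug upstream), and the file is
preallocated in full before streaming so disk-space failures surface
before any computation.

Double precision is the storage default: the concordance bounds this
package targets (minimum Pearson $r > 0.999$, maximum RMSE $< 0.001$
against an independent dense reference) leave orders-of-magnitude headroom
in double, and desk-scale storage cost is irrelevant. Single precision
halves the file and still meets those bounds (relative error ~$10^{-7}$).

## Concordance evaluation

`concordance()` aligns two prediction sets by column triple and sample id
and reports per-column Pearson correlation and RMSE on raw predicted
values, summarized by the minimum correlation and maximum RMSE — the
worst-case view appropriate for claiming two implementations agree.
Constant columns (zero variance in either source) have no defined
correlation; they are excluded from the Pearson summary and counted as
skipped rather than letting an all-zero column poison the headline with
`NaN`, but their RMSE is still computed. RMSE is deliberately
unstandardized: near-unity correlations pair with raw-scale error.
An optional seeded sample draw compares on a fixed random subset of shared
individuals; one draw serves the whole report (a per-column redraw would
make column summaries incomparable across columns).

## What the synthetic cohorts do and do not emulate

`generate_cohort()` writes exactly the files the production paths consume
and carries its own dense ground truth (full post-imputation $G$, expected
$Y$, and per-entry harmonization verdicts), so every module is tested
against analytic expectations rather than another module's output.
Emulated: Hardy–Weinberg dosages at uniform MAF in a stated range
(default [0.05, 0.5]), per-entry missingness (default 1%), sparse
cis-local weight vectors (default standard-normal weights scaled by 0.3),
multiple models sharing a gene pool over one or two ancestry labels, and
deliberate allele re-encodings — swapped, strand-complemented, and
strand-ambiguous sites — with the matcher's expected verdict recorded at
generation time.

Not emulated: linkage disequilibrium, population structure, relatedness,
imputation-quality gradients, or real reference-panel weight
distributions. This is a deliberate scope choice: the computation under
test is a fixed linear map, so correlation structure among columns of $G$
affects no tested contract — passing tests demonstrate numerical and
structural correctness of the engine, harmonizer, and format, not
biological validity of any particular weight panel.

Problem sizes in the test suite are chosen for coverage per second: the
chunk-regime equivalence property runs 24 seeded fixtures of roughly
20–40 samples × 45–80 variants × 8 columns across snp-chunk sizes
{1, 7, 64, full} × row-chunk sizes {1, 13, full}; the cohort-scale
concordance check uses 2,000 samples × 5,000 variants × 300 columns from
4 models, in both double and single precision. At that scale the
streaming engine and dense reference agree to ~$3 \times 10^{-16}$ RMSE,
about twelve orders of magnitude inside the target bounds.

## Numerical and degenerate-input choices

* Accumulation order is fixed (ascending ordinal, then ascending column),
  so equality across chunk regimes is exact up to the non-associativity of
  a *fixed* summation order — i.e., bit-identical, asserted at
  $10^{-12}$ relative.
* All-missing variants impute to dosage 0 (no information, no
  contribution beyond the flip offset).
* Empty weight files after zero-filtering warn and return empty results;
  an empty catalog is an error at dataset creation (a 0-column output has
  no meaning).
* Multi-allelic `.pvar` records stay addressable by id but are
  non-matchable; duplicated variant ids in a `.pvar` make rsid-located
  matching ambiguous and those entries unmatch.
* Non-finite values anywhere — weights at load, accumulators at flush —
  are hard errors naming the offender, never propagated.

## Limitations

* Single-threaded by design; the determinism contract is single-stream.
  Parallelism across chromosomes would be the natural extension.
* Dosage-precision `.pgen` storage modes (0x10+) are not decodable without
  pgenlib; hard calls and the text format cover the supported surface.
* No liftover, no frequency-based disambiguation of strand-ambiguous
  sites, no FUSION `.RDat` weight import, and no model training or
  refitting — this package evaluates existing weight panels.
* `.db` imports rely on a system `python3` for SQLite access, declared in
  `SystemRequirements`.
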