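---
title: "The metadata-sheet model: design, validation and export"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metadata-sheet model: design, validation and export}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasheet)
```

## The model

A metadata sheet describes one experimental design crossed with one
measurement type, in three sections that mirror the phases of an
experiment and must be filled in order.

**Planning** holds contact/project information, the experimental system,
and the comparison groups. A comparison group is a contrasting setting —
one of `diet`, `treatment`, `genotype`, `age`, `temperature` or `other` —
with at least one named instance. We adopt six categories: although the
prose convention in the field sometimes speaks of five "contrasting
settings", the operative enumeration has six labels, and `other` is the
designed escape hatch for anything not covered.

**Conduction** holds everything created at the bench: the final groups,
covariates/constants, an optional interrupted timeline, sample
preparation, the measurement segment and the data-file linkage. The
*final groups* are the factorial expansion of the comparison groups: for
instance sets $I_1, \dots, I_k$ the generator emits the Cartesian product
with $\prod_j |I_j|$ elements. Replicate counts are entered afterwards,
per group, and are **never defaulted** — a silently assumed $n = 1$ hides
design mistakes, so a missing count is a validation error.

**Measurement-Matching** is the ID-specific table: one column per
measured unit, with fixed rows (`personal_ID`, final-group label, one
assignment row per comparison category, a 1-based replicate index, and
literal `yes`/`no` subsample flags) plus one dynamic row per covariate
and per `CHANGES`-promoted key. Sample partitioning — up to two levels,
e.g. organs from a mouse and then technical replicates of an extract —
expands into subsample/subsubsample tables whose `parent_ID` rows
reference the level above. The measurement ID always belongs to the
deepest populated table, because that is where the measurement actually
happens.

Two open points in the table layout were settled as follows: the fixed
row set above is taken as the minimal required row set, and sample-level
personal IDs may coexist with deepest-level measurement IDs (each
subtable carries its own optional `personal_ID` row). Both choices are
visible in the reader/writer dialect and in `generate_id_table()`.

## Controlled vocabulary and dependent keys

Every key has a validation type: `freetext`, `date`, `dropdown` or
`dropdown_multi`. Vocabulary matching is case-insensitive on canonical
forms (whitespace-trimmed and collapsed), while stored values keep the
vocabulary's canonical spelling — tolerant entry, consistent storage.
Multi-select values are serialized as a `;`-delimited list and each token
must validate individually. Dates are ISO 8601 internally; the reader
normalizes dotted (`15.01.2024`), slashed and spreadsheet-serial forms.

Dependent keys — the extra keys required once an experimental system or
measurement type is chosen — live in a registry keyed by
(category, instance). The registry can be *extended but not changed*:
`extend_registry()` appends a new key and creates its vocabulary entry in
the same step, refuses to redefine an existing key's type, and leaves all
pre-existing content untouched. Groups can ship a subset vocabulary
(`Validation_[Group]`); `check_subset()` enforces that it restricts the
master (same types, allowed values a subset). `merge_vocabularies()`
unites two independently extended vocabularies, reporting type clashes as
conflicts instead of guessing.

The `CHANGES` keyword switches a key:value pair to a per-measurement
table row. It is matched case-sensitively and uppercase-only, so that an
ordinary value that happens to spell "changes" is never promoted by
accident.

## Validation semantics

`validate_sheet()` reports, it never corrects. Severity policy:
vocabulary and structural violations are errors; unknown-but-well-formed
extra keys are warnings (the standard is explicitly extensible); values
that are merely *not yet filled* are warnings too, hardening into errors
only at export time (`export_geo()` refuses on gaps) — a sheet is a live
document and incompleteness is its normal state for most of its life.

Sections gate sequentially: Conduction content is checked only against a
valid Planning section, Measurement-Matching only against a valid
Conduction section. When an upstream section has errors, downstream
checks are replaced by a single `blocked-by-upstream` issue rather than a
cascade of secondary findings. The generators enforce the same rule: they
raise a sequential-integrity error rather than generating from an invalid
predecessor. One practical consequence, which the test-suite fuzzers
respect: an injected fault is only *counted once and where it sits* — a
broken Planning value does not additionally surface as a flood of
Conduction errors.

## Generation choices

The product order of `generate_final_groups()` is row-major in
declaration order, the last-declared group varying fastest. The layout
leaves this open; a fixed order makes output deterministic and testable.
Display labels join instance labels with `" × "`, but the structured
assignment remains authoritative. Regenerating final groups or the
matching table replaces the segment; a warning is raised when replicate
counts or entered IDs are discarded.

## Data-file linkage

`resolve_datafiles()` interprets all filenames relative to the sheet's
directory. Substring matching of IDs in file basenames is the stated
contract of `id_in_filename` mode (matching is against basenames, not
paths — the documented resolution of an open layout question). Substring
matching is genuinely ambiguous when one ID is a prefix/substring of
another (`S1` matches `S10_counts.tsv`), so resolution additionally warns
whenever the ID set has that property; the shipped fixture generator
zero-pads IDs to avoid it, but real data may not. Multiple files per ID
are legitimate (paired-end reads) and returned as a lexicographically
sorted list.

## Exports

- **Plain workbook**: macro-free XLSX; a UID (UUID v4) is assigned on
  first export and kept thereafter. UUIDs are drawn from R's RNG so that
  seeded fixture generation is fully reproducible, byte-for-byte.
- **GEO**: study/samples/protocols blocks; one sample row per
  deepest-level column; characteristics columns from group assignments,
  covariates and constants. The column map lives in a versioned JSON
  config (`inst/extdata/geo-template.json`) because the upstream template
  evolves independently of this package; the shipped map is a synthetic
  minimal rendering of the public template's fields.
- **Ontology individuals**: RDF/XML or OWL/XML, one individual per sheet
  and per measured unit, properties resolved against an ontology document
  (a small synthetic stand-in ontology ships in `inst/extdata/`). Keys
  without a property mapping are emitted under a generic annotation
  property, with a warning. Values embedding a CURIE (`PREFIX:digits`,
  e.g. BTO tissue terms) additionally get a term-IRI reference; all other
  values stay plain literals.
- **Experiment bundle**: the bulk-omics converter accepts
  `bulk-transcriptomics`, `bulk-metabolomics` and `bulk-lipidomics`
  (an alias table maps common spellings such as `bulk_RNA_seq`; the
  authoritative mapping is unavoidably conventional, so the table is
  exported data, not hidden logic) and refuses anything else. The bundle
  is serialized language-neutrally (TSV + JSON);
  `bundle_to_summarized_experiment()` places the matching table in
  `colData`, the matrix in `assays`, sheet-level pairs in `metadata`.

## Templates

`from_template()` copies Planning and Conduction verbatim and clears
every `personal_ID` and `parent_ID` — templates exist precisely so that
stale IDs never survive into a new experiment. Per-measurement covariate
values and promoted-row values are cleared too: they describe the old
samples, and keeping declarations while dropping values is the
conservative reading of "update the ID information". The operation is
idempotent. A template with an unusable Conduction section degrades to
Planning-only, with a warning.

## The fixture generator

`generate_sheet()` emulates completed showcase-style sheets: a mouse
study with a diet comparison group (six instances, five replicates by
default — a 30-column matching table), system- and measurement-dependent
keys filled from the demo vocabulary, optional covariates, up to two
division levels and all three linkage modes. `generate_datafiles()`
writes matching dummy measurement files; counts are drawn from a
negative-binomial distribution (`size = 2`, `mu = 100`) purely so bulk
matrices look plausible — the values carry no biological claim, there is
no differential signal, no library-size structure, no missingness. What
passing tests on this corpus demonstrate is therefore *structural*
correctness (counts, alignment, round-trips, referential integrity), not
robustness to the messiness of real acquisitions: hand-edited workbooks
with style-only segment cues, merged cells or stray notes are outside
what the corpus represents.

Determinism is part of the contract: the same seed and design parameters
produce identical sheets, and — because the workbook writer pins part
order and timestamps — byte-identical files.

## Problem sizes and numerical choices

The property suites run at deliberate desk scale: 500 random designs (at
most 4 groups × 5 instances) against a brute-force nested-loop oracle for
the factorial expansion and for the column-count identity, 50 seeded
workbooks for the read∘write identity, and 50 random templates for the
ID-clearing property. These sizes exhaust the small-design space many
times over while keeping the default test run fast; the generators are
linear in the number of measured units, so nothing new happens at larger
sizes. Consortium-scale corpora (dozens of groups contributing sheets)
are represented only by this synthetic collection.

There is no floating-point machinery anywhere in the model — all
comparisons are exact string/integer comparisons after canonicalization,
which is why the suites assert identity rather than tolerance.

## Known limitations

- The reader recognizes segments by canonical header strings; it does not
  use cell styling, so workbooks whose segment structure is conveyed only
  by formatting need their headers intact.
- One group-subset vocabulary per workbook is supported on read.
- Linkage mode `changes` combined with sample divisions is modeled (the
  promoted row lives in the main table) but not produced by the fixture
  generator, which keeps per-ID filenames flat.
- The GEO export targets the spreadsheet's field structure, not the
  submission transport; nothing is uploaded anywhere.
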