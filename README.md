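# metasheet

Structured experiment metadata along the biomedical data-lifecycle —
parse, validate, generate and export, headlessly and scriptably.

## The problem

Most metadata standards bite at publication time: a repository asks for a
filled template, and someone reconstructs months-old experimental detail
from lab books. `metasheet` implements a metadata *sheet* standard that
instead follows the experiment itself. One sheet captures one experimental
design crossed with one measurement type, in three sections that fill in
order:

1. **Planning** — contact and project information, the experimental system
   (mouse, rat, human-derived, cell line, patient) with its
   system-dependent keys (e.g. `line` and `genotype` once `mouse` is
   chosen), and the *comparison groups*: contrasting settings drawn from
   `diet`, `treatment`, `genotype`, `age`, `temperature`, `other`, each
   with named instances.
2. **Conduction** — the *final groups* (the factorial expansion of the
   comparison groups) with replicate counts, covariates and constants, an
   optional interrupted timeline (`continued` / `discontinued`), sample
   preparation with up to two levels of sample partitioning, the
   measurement type with its dependent keys, and the data-file linkage.
3. **Measurement-Matching** — the ID-specific table: one column per
   measured unit, carrying the unique `personal_ID` that ties each
   metadata column to its measurement file(s).

Every key is constrained by a controlled vocabulary (free text, date,
single- or multi-select dropdown), kept in a `Validation` sheet that
groups can subset and extend; dependent keys live in a `dependentFields`
sheet. The package is aimed at wet-lab scientists' data managers and
bioinformaticians who want the workbook's logic — validation, generation,
export — available from scripts and pipelines rather than a spreadsheet
macro runtime.

## The core machinery

- **Factorial expansion.** For comparison groups `G_1 … G_k` with instance
  sets `I_1 … I_k`, the design generator emits the Cartesian product
  `I_1 × … × I_k` in declaration order (last group varying fastest):
  `|final groups| = ∏ |I_j|`. Six diets × two genotypes → 12 final groups.
- **ID-table generation.** With replicate counts `n_1 … n_m` over the
  final groups, the matching table has `Σ n_i` columns; declared
  covariates and any key whose value is the reserved token `CHANGES`
  become per-measurement rows; sample divisions expand into subsample and
  subsubsample tables with parent references.
- **Validation.** Value-level checks against the vocabulary, dependent-key
  completeness, structural invariants (ID uniqueness, parent references,
  column counts, the two-level division limit) and *sequential integrity*:
  a section is only checked against a valid predecessor.
- **Linkage resolution.** `personal_ID → file(s)` under three modes: a
  single shared file, substring matching of the ID in file names (with an
  ambiguity warning when one ID is a substring of another), or per-ID
  filenames promoted into the table via `CHANGES`.
- **Exports.** A plain macro-free workbook, a GEO-style submission
  spreadsheet, RDF/XML or OWL/XML ontology individuals, and an experiment
  bundle (assay TSV + column metadata TSV + JSON) that loads as a
  Bioconductor `SummarizedExperiment` for bulk transcriptomics,
  metabolomics and lipidomics.

## Worked example

```r
library(metasheet)

fx <- generate_sheet(seed = 1)      # showcase-shaped synthetic sheet
fx$sheet
#> <metadatasheet>uid=83601c6a-d1a2-4449-8d96-8e4488d4419d
#>  planning:   system=mouse, 1 comparison group(s)
#>  conduction: 6 final group(s), type=bulk_RNA_seq
#>  matching:   30 measured unit column(s)

validate_sheet(fx$sheet, fx$vocab, fx$registry)
#> <validation report> ok = TRUE - 0 issue(s)

length(generate_final_groups(fx$sheet$planning$comparison_groups))
#> [1] 6

root <- tempdir()
generate_datafiles(fx$sheet, root, seed = 1)
res <- resolve_datafiles(fx$sheet$matching, fx$sheet$conduction$linkage, root)
res$S01
#> [1] "counts.tsv"

se <- bundle_to_summarized_experiment(to_experiment_bundle(fx$sheet, root))
se
#> class: SummarizedExperiment
#> dim: 50 30
#> assays(1): counts
#> colnames(30): S01 S02 ... S29 S30
#> colData names(6): personal_ID final_group ... subsamples subsubsamples
```

One diet comparison group with six instances and five replicates each
yields six final groups and a 30-column matching table; every measured
unit resolves to the shared counts file and lands, with its metadata, in
the `SummarizedExperiment`'s `colData`.

The same operations are available from a shell via the bundled script:

```sh
metasheet demo --seed 1 --out demo/
metasheet validate demo/metadatasheet.xlsx
metasheet export bundle demo/metadatasheet.xlsx --out demo/bundle --root demo/
```

(after installation the script lives at `system.file("..", "exec", "metasheet")`-style
paths; run it with `Rscript` or put it on `PATH`).

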