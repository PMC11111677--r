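# Exporters: NCBI GEO metadata spreadsheet, OWL/XML / RDF/XML ontology
# individuals, and the language-neutral experiment bundle (assay matrix +
# column metadata + sheet metadata) that loads as a SummarizedExperiment.

GEO_ORGANISMS <- c(mouse = "Mus musculus", rat = "Rattus norvegicus",
                   "human-derived" = "Homo sapiens",
                   patient = "Homo sapiens", "cell-line" = "Homo sapiens")

geo_template_path <- function() {
  system.file("extdata", "geo-template.json", package = "metasheet",
              mustWork = TRUE)
}

# deepest-level column -> index of its ancestor column in the main table
main_ancestor_cols <- function(tab) {
  deep <- deepest_table(tab)
  if (identical(dim(deep), dim(tab$main)) &&
      all(deep["personal_ID", ] == tab$main["personal_ID", ])) {
    return(seq_len(ncol(tab$main)))
  }
  lookup <- function(child, parent) {
    match(child["parent_ID", ], parent["personal_ID", ])
  }
  if (!is.null(tab$subsubsample)) {
    mid <- lookup(tab$subsubsample, tab$subsample)
    lookup(tab$subsample, tab$main)[mid]
  } else {
    lookup(tab$subsample, tab$main)
  }
}

#' Export a sheet as a GEO-style metadata spreadsheet
#'
#' Assembles the study, samples and protocols blocks of the NCBI GEO
#' submission metadata spreadsheet: one sample row per measured unit,
#' characteristics columns derived from the comparison-group assignments,
#' covariates and constants, protocol fields from the Preparation and
#' Measurement segments, and raw/processed file columns from the resolved
#' data-file linkage. The column map (including which fields are
#' mandatory) is read from a versioned configuration file.
#'
#' @param sheet A validated [metadatasheet()].
#' @param resolved Named list from [resolve_datafiles()].
#' @param path Optional output `.xlsx`; when given, the blocks are written
#'   as STUDY / SAMPLES / PROTOCOLS worksheets.
#' @param template Path to the GEO column-map JSON.
#' @return Object of class `ms_geo_metadata` (list of `study`, `samples`,
#'   `protocols`), invisibly when `path` is given.
#' @export
export_geo <- function(sheet, resolved, path = NULL,
                       template = geo_template_path()) {
  stopifnot(inherits(sheet, "ms_metadatasheet"))
  cfg <- jsonlite::read_json(template, simplifyVector = TRUE)
  tab <- sheet$matching
  if (is.null(tab)) {
    stop("GEO export requires the Measurement-Matching table", call. = FALSE)
  }
  ids <- measurement_ids(sheet)
  g <- sheet$planning$general
  sys <- sheet$planning$system$system
  organism <- if (!is.na(sys) && tolower(sys) %in% names(GEO_ORGANISMS)) {
    GEO_ORGANISMS[[tolower(sys)]]
  } else sys

  study <- list(
    title = g$project_title,
    contributor = g$name,
    summary = paste0("Experiment on ", sys, " measured by ",
                     sheet$conduction$measurement$measurement_type),
    `overall design` = paste(vapply(sheet$conduction$final_groups,
                                    final_group_label, character(1)),
                             collapse = "; "))

  gaps <- character(0)
  for (f in cfg$mandatory_study) {
    if (!nzchar(canonicalize(study[[f]] %||% ""))) {
      gaps <- c(gaps, paste0("study field '", f, "'"))
    }
  }
  if (!all(nzchar(ids))) gaps <- c(gaps, "sample personal_IDs (unfilled)")
  if (!nzchar(canonicalize(organism %||% ""))) {
    gaps <- c(gaps, "sample field 'organism' (experimental system unset)")
  }
  if (length(gaps)) {
    stop("GEO export blocked; missing mandatory field(s): ",
         paste(gaps, collapse = ", "), call. = FALSE)
  }

  anc <- main_ancestor_cols(tab)
  cats <- vapply(sheet$planning$comparison_groups, function(x) x$category,
                 character(1))
  pre <- cfg$characteristics_prefix
  tissue <- sheet$planning$system$dependent_values[["tissue"]] %||% ""

  samples <- data.frame(`library name` = ids, title = ids,
                        organism = organism,
                        `source name` = if (nzchar(tissue)) tissue else
                          as.character(sys),
                        molecule = cfg$default_molecule %||% "total RNA",
                        check.names = FALSE, stringsAsFactors = FALSE)
  for (cat in cats) {
    samples[[paste0(pre, cat)]] <- unname(tab$main[cat, anc])
  }
  for (cv in sheet$conduction$covariates) {
    col <- paste0(pre, cv$name,
                  if (nzchar(cv$unit)) paste0(" (", cv$unit, ")") else "")
    samples[[col]] <- if (cv$role == "constant") {
      rep(cv$constant_value, length(ids))
    } else if (cv$name %in% rownames(tab$main)) {
      unname(tab$main[cv$name, anc])
    } else rep("", length(ids))
  }
  fcol <- if (sheet$conduction$linkage$availability == "raw") "raw file"
          else "processed data file"
  samples[[fcol]] <- vapply(ids, function(id)
    paste(resolved[[id]], collapse = ", "), character(1))

  protocols <- list(
    `growth protocol` = paste(vapply(sheet$planning$comparison_groups,
                                     function(x) x$category, character(1)),
                              collapse = ", "),
    `treatment protocol` = sheet$conduction$preparation$protocol %||% "",
    `extract protocol` = paste(
      unlist(sheet$conduction$measurement$dependent_values), collapse = "; "),
    `data processing` = sheet$conduction$linkage$processing_procedure %||%
      "none (raw data)")

  out <- structure(list(study = study, samples = samples,
                        protocols = protocols, config_version = cfg$version),
                   class = "ms_geo_metadata")
  if (!is.null(path)) {
    kv_grid <- function(l) pad_rows(lapply(names(l), function(k)
      c(k, as.character(l[[k]]))))
    samples_grid <- rbind(colnames(samples), as.matrix(samples))
    write_xlsx_grids(list(STUDY = kv_grid(study), SAMPLES = samples_grid,
                          PROTOCOLS = kv_grid(protocols)), path)
    return(invisible(out))
  }
  out
}

# ---------------------------------------------------------------------------
# ontology individuals export

MS_BASE_IRI <- "http://example.org/metadatasheet#"
MS_IND_IRI <- "http://example.org/metadatasheet/individual#"
OBO_IRI <- "http://purl.obolibrary.org/obo/"

default_ontology_path <- function() {
  system.file("extdata", "metadatasheet-ontology-synthetic.owl",
              package = "metasheet", mustWork = TRUE)
}

# key -> property IRI map from an RDF/XML ontology: DatatypeProperty nodes,
# keyed by rdfs:label (canonical, lower) and IRI fragment
ontology_property_map <- function(ontology_path) {
  doc <- xml2::read_xml(ontology_path)
  props <- xml2::xml_find_all(doc, "//owl:DatatypeProperty")
  map <- list()
  for (p in props) {
    iri <- xml2::xml_attr(p, "about")
    if (is.na(iri)) next
    frag <- sub("^.*[#/]", "", iri)
    map[[tolower(gsub("_", " ", frag))]] <- iri
    lab <- xml2::xml_find_first(p, "rdfs:label")
    if (!inherits(lab, "xml_missing")) {
      map[[tolower(canonicalize(xml2::xml_text(lab)))]] <- iri
    }
  }
  map
}

lookup_property <- function(map, key) {
  map[[tolower(gsub("_", " ", canonicalize(key)))]]
}

# CURIE like BTO:0000759 embedded in a value -> OBO-style IRI
embedded_curie_iri <- function(value) {
  m <- regmatches(value, regexpr("[A-Za-z][A-Za-z0-9]*:[0-9]+", value))
  if (length(m) == 0L) return(NULL)
  paste0(OBO_IRI, sub(":", "_", m[[1]]))
}

# flatten a sheet's planning + conduction key:value pairs
sheet_kv_pairs <- function(sheet) {
  g <- sheet$planning$general
  kv <- list(name = g$name, affiliation = g$affiliation, email = g$email,
             project_title = g$project_title)
  es <- sheet$planning$system
  if (!is.na(es$system)) kv[["experimental_system"]] <- es$system
  kv <- c(kv, es$dependent_values)
  me <- sheet$conduction$measurement
  if (!is.na(me$measurement_type)) kv[["measurement_type"]] <-
    me$measurement_type
  kv <- c(kv, me$dependent_values)
  for (cv in sheet$conduction$covariates) {
    if (cv$role == "constant") kv[[cv$name]] <- cv$constant_value
  }
  Filter(function(v) nzchar(canonicalize(as.character(v))), kv)
}

#' Export sheets as ontology individuals (RDF/XML or OWL/XML)
#'
#' Emits one individual per sheet (typed as the ontology's Metadatasheet
#' class) and one per measured unit (typed MeasuredUnit, linked to its
#' sheet), with a property assertion for every filled key. Keys with no
#' property in the ontology are emitted under a generic annotation
#' property, with a warning. Values embedding an ontology CURIE
#' (`PREFIX:digits`, e.g. a BRENDA Tissue Ontology term) additionally get
#' a resource reference to the term IRI.
#'
#' @param sheets List of validated [metadatasheet()]s (possibly empty).
#' @param ontology Path to the ontology (RDF/XML). Defaults to the
#'   synthetic ontology shipped with the package.
#' @param format `"rdfxml"` or `"owlxml"`.
#' @return An `xml2::xml_document`; serialize with [xml2::write_xml()].
#' @export
export_xml <- function(sheets, ontology = default_ontology_path(),
                       format = c("rdfxml", "owlxml")) {
  format <- match.arg(format)
  if (inherits(sheets, "ms_metadatasheet")) sheets <- list(sheets)
  map <- ontology_property_map(ontology)

  unmapped <- character(0)
  # per-individual assertions as (property IRI or NULL, key, value, resource)
  assertions <- function(kv) {
    out <- list()
    for (k in names(kv)) {
      iri <- lookup_property(map, k)
      if (is.null(iri)) {
        unmapped <<- c(unmapped, k)
        iri <- paste0(MS_BASE_IRI, "annotation")
      }
      out[[length(out) + 1L]] <- list(iri = iri, key = k,
                                      value = as.character(kv[[k]]),
                                      resource = embedded_curie_iri(
                                        as.character(kv[[k]])))
    }
    out
  }

  individuals <- list()
  for (sheet in sheets) {
    uid <- sheet$uid %||% "unassigned"
    sheet_iri <- paste0(MS_IND_IRI, "sheet-", uid)
    individuals[[length(individuals) + 1L]] <- list(
      iri = sheet_iri, class = paste0(MS_BASE_IRI, "Metadatasheet"),
      parent = NULL, props = assertions(sheet_kv_pairs(sheet)))
    if (!is.null(sheet$matching)) {
      tab <- sheet$matching
      deep <- deepest_table(tab)
      anc <- main_ancestor_cols(tab)
      for (j in seq_len(ncol(deep))) {
        id <- deep["personal_ID", j]
        if (!nzchar(id)) next
        kv <- as.list(tab$main[, anc[j]])
        names(kv) <- rownames(tab$main)
        if (!identical(dim(deep), dim(tab$main))) {
          kv[["personal_ID"]] <- id
          kv[["instance"]] <- deep["instance", j]
        }
        kv <- Filter(function(v) nzchar(canonicalize(v)), kv)
        individuals[[length(individuals) + 1L]] <- list(
          iri = paste0(MS_IND_IRI, "unit-", uid, "-", id),
          class = paste0(MS_BASE_IRI, "MeasuredUnit"),
          parent = sheet_iri, props = assertions(kv))
      }
    }
  }
  if (length(unmapped)) {
    warning("key(s) with no ontology property mapping emitted under the ",
            "generic annotation property: ",
            paste(sort(unique(unmapped)), collapse = ", "), call. = FALSE)
  }

  doc <- if (format == "rdfxml") render_rdfxml(individuals)
         else render_owlxml(individuals)
  xml2::read_xml(doc)
}

render_rdfxml <- function(individuals) {
  body <- vapply(individuals, function(ind) {
    lines <- c(sprintf('  <rdf:Description rdf:about="%s">', ind$iri),
               sprintf('    <rdf:type rdf:resource="%s"/>', ind$class))
    if (!is.null(ind$parent)) {
      lines <- c(lines, sprintf('    <ms:partOfSheet rdf:resource="%s"/>',
                                ind$parent))
    }
    for (p in ind$props) {
      local <- sub("^.*[#/]", "", p$iri)
      ns <- substr(p$iri, 1, nchar(p$iri) - nchar(local))
      lines <- c(lines,
                 sprintf('    <p:%s xmlns:p="%s" rdf:datatype="http://www.w3.org/2001/XMLSchema#string">%s</p:%s>',
                         local, xml_escape(ns), xml_escape(p$value), local))
      if (!is.null(p$resource)) {
        lines <- c(lines, sprintf('    <ms:hasTerm rdf:resource="%s"/>',
                                  p$resource))
      }
    }
    paste(c(lines, "  </rdf:Description>"), collapse = "\n")
  }, character(1))
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
         'xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#" ',
         'xmlns:ms="', MS_BASE_IRI, '">\n',
         paste(body, collapse = "\n"), "\n</rdf:RDF>\n")
}

render_owlxml <- function(individuals) {
  decl <- vapply(individuals, function(ind) {
    lines <- c(sprintf('  <Declaration><NamedIndividual IRI="%s"/></Declaration>',
                       ind$iri),
               sprintf(paste0('  <ClassAssertion><Class IRI="%s"/>',
                              '<NamedIndividual IRI="%s"/></ClassAssertion>'),
                       ind$class, ind$iri))
    if (!is.null(ind$parent)) {
      lines <- c(lines, sprintf(paste0(
        '  <ObjectPropertyAssertion><ObjectProperty IRI="%spartOfSheet"/>',
        '<NamedIndividual IRI="%s"/><NamedIndividual IRI="%s"/>',
        '</ObjectPropertyAssertion>'), MS_BASE_IRI, ind$iri, ind$parent))
    }
    for (p in ind$props) {
      lines <- c(lines, sprintf(paste0(
        '  <DataPropertyAssertion><DataProperty IRI="%s"/>',
        '<NamedIndividual IRI="%s"/>',
        '<Literal datatypeIRI="http://www.w3.org/2001/XMLSchema#string">%s',
        '</Literal></DataPropertyAssertion>'),
        p$iri, ind$iri, xml_escape(p$value)))
    }
    paste(lines, collapse = "\n")
  }, character(1))
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<Ontology xmlns="http://www.w3.org/2002/07/owl#" ',
         'ontologyIRI="', MS_BASE_IRI, 'export">\n',
         paste(decl, collapse = "\n"), "\n</Ontology>\n")
}

#' Count the individuals in an exported document
#'
#' @param doc An `xml2::xml_document` from [export_xml()].
#' @return Integer count of individuals.
#' @export
count_individuals <- function(doc) {
  ns <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          owl = "http://www.w3.org/2002/07/owl#")
  n_rdf <- length(xml2::xml_find_all(doc, "//rdf:Description[@rdf:about]",
                                     ns))
  if (n_rdf > 0L) return(n_rdf)
  length(xml2::xml_find_all(doc, "//owl:Declaration/owl:NamedIndividual",
                            ns))
}

# ---------------------------------------------------------------------------
# experiment bundle (assay + column metadata + sheet metadata)

BULK_FAMILIES <- c("bulk-transcriptomics", "bulk-metabolomics",
                   "bulk-lipidomics")
BULK_ALIASES <- c("bulk_RNA_seq" = "bulk-transcriptomics",
                  "bulk RNASeq" = "bulk-transcriptomics",
                  "bulk proteomics" = NA,  # not a supported family
                  "bulk-transcriptomics" = "bulk-transcriptomics",
                  "bulk-metabolomics" = "bulk-metabolomics",
                  "metabolomics (13 C glucose)" = "bulk-metabolomics",
                  "bulk-lipidomics" = "bulk-lipidomics",
                  "bulk lipidomics" = "bulk-lipidomics")

resolve_bulk_family <- function(measurement_type) {
  mt <- canonicalize(measurement_type)
  hit <- match(tolower(mt), tolower(names(BULK_ALIASES)))
  fam <- if (!is.na(hit)) BULK_ALIASES[[hit]] else NA_character_
  if (is.na(fam)) {
    stop("measurement type '", measurement_type, "' is not convertible; ",
         "conversion supports the bulk omics families ",
         paste(BULK_FAMILIES, collapse = ", "), call. = FALSE)
  }
  fam
}

read_delim_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Convert a sheet plus its measurement data to an experiment bundle
#'
#' The converter for bulk omics: checks that the measurement type belongs
#' to one of the convertible bulk families (transcriptomics, metabolomics,
#' lipidomics; common spellings are alias-resolved), locates the assay
#' matrix as directed by the DataFiles-Linkage segment with the sheet's
#' directory as root, aligns its columns to the measurement IDs, and packs
#' the Measurement-Matching section as column metadata. When the named
#' single file is absent, candidate delimited files found by extension are
#' listed in the error so the caller can clarify.
#'
#' @param sheet A validated [metadatasheet()] with filled IDs.
#' @param root Directory holding the measurement data (the sheet's
#'   location).
#' @return Object of class `ms_bundle`: `assay` (features x measured
#'   units), `col_data` (one row per measured unit, the ID-table rows as
#'   columns) and `sheet_meta` (planning/conduction key:value pairs).
#' @export
to_experiment_bundle <- function(sheet, root) {
  stopifnot(inherits(sheet, "ms_metadatasheet"))
  family <- resolve_bulk_family(sheet$conduction$measurement$measurement_type)
  linkage <- sheet$conduction$linkage
  if (is.null(linkage) || is.null(sheet$matching)) {
    stop("conversion requires completed linkage and matching sections",
         call. = FALSE)
  }
  ids <- measurement_ids(sheet)

  if (linkage$mode == "single_file_for_all") {
    fn <- file.path(root, canonicalize(linkage$comment))
    if (!file.exists(fn)) {
      ext <- tools::file_ext(canonicalize(linkage$comment))
      if (!nzchar(ext)) ext <- "tsv|csv|txt"
      candidates <- list.files(root, pattern = paste0("\\.(", ext, ")$"),
                               recursive = TRUE)
      stop("named data file '", canonicalize(linkage$comment),
           "' not found under ", root,
           if (length(candidates)) paste0("; candidate file(s) by ",
                                          "extension: ",
                                          paste(candidates, collapse = ", "))
           else "; no candidate files found",
           call. = FALSE)
    }
    m <- read_delim_matrix(fn)
    missing <- setdiff(ids, colnames(m))
    if (length(missing)) {
      stop("assay matrix misaligned: no column for ID(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    assay <- m[, ids, drop = FALSE]
  } else {
    resolved <- resolve_datafiles(sheet$matching, linkage, root)
    cols <- lapply(ids, function(id) {
      df <- utils::read.table(file.path(root, resolved[[id]][[1]]),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
      stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
    })
    feats <- names(cols[[1]])
    assay <- vapply(cols, function(x) {
      if (!identical(names(x), feats)) {
        stop("assay matrix misaligned: per-ID files disagree on features",
             call. = FALSE)
      }
      unname(x)
    }, numeric(length(feats)))
    rownames(assay) <- feats
    colnames(assay) <- ids
  }

  tab <- sheet$matching
  deep <- deepest_table(tab)
  anc <- main_ancestor_cols(tab)
  col_data <- as.data.frame(t(tab$main[, anc, drop = FALSE]),
                            stringsAsFactors = FALSE)
  rownames(col_data) <- NULL
  if (!identical(dim(deep), dim(tab$main))) {
    col_data$personal_ID <- unname(deep["personal_ID", ])
    col_data$instance <- unname(deep["instance", ])
    col_data$parent_ID <- unname(deep["parent_ID", ])
  }
  col_data <- col_data[, unique(c("personal_ID",
                                  setdiff(names(col_data), "personal_ID"))),
                       drop = FALSE]
  stopifnot(identical(col_data$personal_ID, ids))

  meta <- sheet_kv_pairs(sheet)
  meta$uid <- sheet$uid %||% ""
  meta$bulk_family <- family

  structure(list(assay = assay, col_data = col_data, sheet_meta = meta),
            class = "ms_bundle")
}

#' Write an experiment bundle to a directory
#'
#' Serializes the bundle language-neutrally: `assay.tsv` (feature column +
#' one numeric column per measured unit), `coldata.tsv` (one row per
#' measured unit) and `metadata.json`.
#'
#' @param bundle An `ms_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ms_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  assay_df <- data.frame(feature = rownames(bundle$assay), bundle$assay,
                         check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(assay_df, file.path(dir, "assay.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$col_data, file.path(dir, "coldata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$sheet_meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read an experiment bundle back from a directory
#'
#' @param dir Directory written by [write_bundle()].
#' @return An `ms_bundle`.
#' @export
read_bundle <- function(dir) {
  assay_df <- utils::read.table(file.path(dir, "assay.tsv"), sep = "\t",
                                header = TRUE, check.names = FALSE,
                                stringsAsFactors = FALSE)
  assay <- as.matrix(assay_df[, -1, drop = FALSE])
  storage.mode(assay) <- "double"
  rownames(assay) <- as.character(assay_df[[1]])
  col_data <- utils::read.table(file.path(dir, "coldata.tsv"), sep = "\t",
                                header = TRUE, check.names = FALSE,
                                colClasses = "character",
                                stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  structure(list(assay = assay, col_data = col_data, sheet_meta = meta),
            class = "ms_bundle")
}

#' Build a SummarizedExperiment from a bundle
#'
#' The Measurement-Matching section lands in the `colData` slot; the assay
#' matrix in `assays`; sheet-level metadata in `metadata()`.
#'
#' @param bundle An `ms_bundle` (or a directory written by
#'   [write_bundle()]).
#' @return A `SummarizedExperiment::SummarizedExperiment`.
#' @export
bundle_to_summarized_experiment <- function(bundle) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "ms_bundle"))
  if (!requireNamespace("SummarizedExperiment", quietly = TRUE)) {
    stop("the SummarizedExperiment package is required for this converter",
         call. = FALSE)
  }
  cd <- S4Vectors::DataFrame(bundle$col_data)
  rownames(cd) <- bundle$col_data$personal_ID
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = bundle$assay), colData = cd,
    metadata = bundle$sheet_meta)
}
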