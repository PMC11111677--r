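make_resolved_fixture <- function(seed, ...) {
  fx <- generate_sheet(seed, ...)
  root <- withr::local_tempdir(.local_envir = parent.frame())
  generate_datafiles(fx$sheet, root, seed = seed)
  resolved <- resolve_datafiles(fx$sheet$matching,
                                fx$sheet$conduction$linkage, root)
  list(fx = fx, root = root, resolved = resolved)
}

test_that("GEO export emits one sample row per measured unit", {
  h <- make_resolved_fixture(61)
  geo <- export_geo(h$fx$sheet, h$resolved)
  expect_identical(nrow(geo$samples), 30L)
  expect_identical(geo$samples$organism[1], "Mus musculus")
  # constant characteristics fill every row
  col <- "characteristics: cell type"
  expect_true(col %in% names(geo$samples))
  expect_true(all(geo$samples[[col]] == "Kupffer Cells"))
  expect_true(all(geo$samples$`raw file` == "counts.tsv"))

  # sample rows follow the deepest table when divisions are present
  h2 <- make_resolved_fixture(62, division_levels = 1,
                              linkage_mode = "id_in_filename",
                              instances_per_group = 2, replicates = 2)
  geo2 <- export_geo(h2$fx$sheet, h2$resolved)
  deep <- metasheet:::deepest_table(h2$fx$sheet$matching)
  expect_identical(nrow(geo2$samples), ncol(deep))
  # group assignment is inherited from the parent sample
  expect_identical(unname(geo2$samples$`characteristics: diet`),
                   unname(h2$fx$sheet$matching$main[
                     "diet", metasheet:::main_ancestor_cols(
                       h2$fx$sheet$matching)]))
})

test_that("GEO export enumerates missing mandatory fields", {
  h <- make_resolved_fixture(63)
  sheet <- h$fx$sheet
  sheet$planning$general$name <- ""
  err <- tryCatch(export_geo(sheet, h$resolved), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "contributor")
})

test_that("GEO workbook rendering carries the three blocks", {
  h <- make_resolved_fixture(64)
  path <- withr::local_tempfile(fileext = ".xlsx")
  export_geo(h$fx$sheet, h$resolved, path = path)
  expect_identical(readxl::excel_sheets(path),
                   c("STUDY", "SAMPLES", "PROTOCOLS"))
  samples <- suppressMessages(readxl::read_excel(path, sheet = "SAMPLES"))
  expect_identical(nrow(samples), 30L)
})

test_that("ontology export emits sheet and unit individuals that parse back", {
  # empty input: a valid document with zero individuals
  empty <- export_xml(list())
  expect_identical(count_individuals(empty), 0L)

  fx <- generate_sheet(65)
  doc <- export_xml(list(fx$sheet))
  expect_gte(count_individuals(doc), 31L)

  # parse-back through a fresh XML read preserves the individual count
  path <- withr::local_tempfile(fileext = ".rdf")
  xml2::write_xml(doc, path)
  expect_identical(count_individuals(xml2::read_xml(path)),
                   count_individuals(doc))

  # OWL/XML flavour carries the same individuals
  owl <- export_xml(list(fx$sheet), format = "owlxml")
  expect_identical(count_individuals(owl), count_individuals(doc))

  # BTO-style CURIE values get a term IRI reference
  expect_true(length(xml2::xml_find_all(
    doc, "//ms:hasTerm", c(ms = "http://example.org/metadatasheet#"))) > 0)
})

test_that("keys without an ontology property fall back to the annotation property with a warning", {
  fx <- generate_sheet(66, n_covariates = 1)  # 'body weight' is unmapped
  expect_warning(doc <- export_xml(list(fx$sheet)), "body weight")
  ns <- c(ms = "http://example.org/metadatasheet#")
  expect_true(length(xml2::xml_find_all(doc, "//ms:annotation", ns)) > 0)
})

test_that("RDF/XML output is valid RDF for an independent parser", {
  fx <- generate_sheet(67)
  path <- withr::local_tempfile(fileext = ".rdf")
  xml2::write_xml(export_xml(list(fx$sheet)), path)
  script <- paste0(
    "import rdflib,sys\n",
    "g=rdflib.Graph(); g.parse(sys.argv[1], format='xml')\n",
    "subs={s for s in g.subjects() if 'individual#' in str(s)}\n",
    "print(len(subs))")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script),
                                              shQuote(path)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    fail(paste("rdflib rejected the export:", paste(out, collapse = " ")))
  }
  expect_identical(as.integer(out[length(out)]), 31L)
})

test_that("bundle conversion aligns assay columns, metadata rows and IDs", {
  h <- make_resolved_fixture(68)
  bundle <- to_experiment_bundle(h$fx$sheet, h$root)
  expect_identical(colnames(bundle$assay), bundle$col_data$personal_ID)
  expect_identical(bundle$col_data$personal_ID,
                   measurement_ids(h$fx$sheet))
  expect_identical(ncol(bundle$assay), 30L)
  expect_identical(bundle$sheet_meta$bulk_family, "bulk-transcriptomics")

  # per-ID files route
  h2 <- make_resolved_fixture(69, linkage_mode = "id_in_filename",
                              instances_per_group = 2, replicates = 2)
  b2 <- to_experiment_bundle(h2$fx$sheet, h2$root)
  expect_identical(colnames(b2$assay), measurement_ids(h2$fx$sheet))
})

test_that("non-bulk measurement types are refused by the converter", {
  fx <- generate_sheet(70, measurement_type = "FACS")
  err <- tryCatch(to_experiment_bundle(fx$sheet, tempdir()),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "bulk-transcriptomics")
  expect_match(conditionMessage(err), "not convertible")
})

test_that("a missing named file yields a clarification error listing candidates", {
  fx <- generate_sheet(71)
  root <- withr::local_tempdir()
  generate_datafiles(fx$sheet, root, seed = 71)
  file.rename(file.path(root, "counts.tsv"),
              file.path(root, "renamed_counts.tsv"))
  err <- tryCatch(to_experiment_bundle(fx$sheet, root), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "renamed_counts.tsv")
})

test_that("bundles round-trip through their on-disk form", {
  h <- make_resolved_fixture(72, instances_per_group = 2, replicates = 2)
  bundle <- to_experiment_bundle(h$fx$sheet, h$root)
  dir <- withr::local_tempdir()
  write_bundle(bundle, dir)
  expect_setequal(list.files(dir),
                  c("assay.tsv", "coldata.tsv", "metadata.json"))
  back <- read_bundle(dir)
  expect_equal(back$assay, bundle$assay)
  expect_equal(back$col_data, bundle$col_data)
  expect_identical(back$sheet_meta$uid, bundle$sheet_meta$uid)
})

test_that("a bundle loads as a SummarizedExperiment with matching dimensions", {
  h <- make_resolved_fixture(73, instances_per_group = 2, replicates = 2)
  bundle <- to_experiment_bundle(h$fx$sheet, h$root)
  se <- bundle_to_summarized_experiment(bundle)
  expect_identical(dim(se), dim(bundle$assay))
  expect_identical(colnames(se), measurement_ids(h$fx$sheet))
  cd <- SummarizedExperiment::colData(se)
  expect_identical(unname(cd$diet),
                   unname(h$fx$sheet$matching$main["diet", ]))
})
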